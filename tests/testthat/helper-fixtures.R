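# shared fixture builders (everything generated in code; no stored data)

# hand-built deterministic trial table
toy_trials <- function() {
  trial_table(data.frame(
    participant = rep(c("s1", "s2"), each = 4),
    condition = rep(c("cued", "cued", "miscued", "miscued"), 2),
    response_side = rep(c("left", "right"), 4),
    correct = TRUE,
    rt_ms = c(300, 320, 330, 350, 400, 410, 420, 450)))
}

# grid of parameter sets spanning the working region
param_grid <- function() {
  list(ddm_params(v = 0, a = 1.5, z = 0.5, t0 = 0.2),
       ddm_params(v = 1.0, a = 1.2, z = 0.5, t0 = 0.3),
       ddm_params(v = -1.5, a = 0.8, z = 0.35, t0 = 0.25),
       ddm_params(v = 2.5, a = 2.0, z = 0.6, t0 = 0.15),
       ddm_params(v = 4.0, a = 0.5, z = 0.2, t0 = 0.1),
       ddm_params(v = -4.0, a = 3.0, z = 0.8, t0 = 0.4),
       ddm_params(v = 0.5, a = 2.5, z = 0.3, t0 = 0.35),
       ddm_params(v = -0.5, a = 1.0, z = 0.7, t0 = 0.2),
       ddm_params(v = 3.0, a = 1.8, z = 0.45, t0 = 0.3),
       ddm_params(v = -2.0, a = 1.4, z = 0.55, t0 = 0.25),
       ddm_params(v = 1.5, a = 0.7, z = 0.25, t0 = 0.3),
       ddm_params(v = 2.0, a = 1.1, z = 0.75, t0 = 0.2))
}

# quadrature of one boundary's defective density over all decision times
integrate_density <- function(boundary, p) {
  stats::integrate(function(t) wfpt_density(t, boundary, p),
                   lower = p$t0, upper = Inf, rel.tol = 1e-9)$value
}

# fast simulated participant for fitting tests
quick_participant <- function(mechanism = "simple", effects = list(),
                              n_per_condition = 100, seed = 1) {
  generate_participant(mechanism, effects = effects,
                       n_per_condition = n_per_condition, seed = seed,
                       dt = 2e-4)
}

# write a delimited fixture file and return its path
write_fixture_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
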