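#' Generate one synthetic participant from a known mechanism
#'
#' Simulates two-choice localisation trials whose cued/miscued behaviour
#' is produced by a known DDM mechanism: `"simple"` (no condition
#' difference), `"t0"` (non-decision-time gap), `"z"` (start-point shift
#' toward the cued side), `"v"` (drift gap), or any other catalogue
#' variant. Condition-specific parameters come from
#' [expand_parameters()], trials from the Euler-Maruyama simulator; the
#' upper boundary maps to a correct response and RTs are emitted in ms.
#'
#' @param mechanism a [model_catalogue()] name.
#' @param base a [ddm_params()] giving the shared v, a, t0 (and s).
#' @param effects named list of effect sizes for the varying parameters:
#'   `delta_t0` (s), `z_c`, `delta_v`. Entries irrelevant to
#'   `mechanism` must be absent.
#' @param n_per_condition trials per condition.
#' @param participant participant id for the emitted table.
#' @param seed RNG seed.
#' @param dt simulator step (s).
#' @return `list(trials = trial_table, truth = one-row data.frame)`; the
#'   truth row records the mechanism and the exact generating parameters
#'   per condition.
#' @export
generate_participant <- function(mechanism, base = ddm_params(v = 3, a = 1.2,
                                                              z = 0.5,
                                                              t0 = 0.30),
                                 effects = list(), n_per_condition = 250,
                                 participant = "p1", seed = 1, dt = 1e-4) {
  specs <- model_catalogue()
  if (!mechanism %in% names(specs))
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  spec <- specs[[mechanism]]
  need <- setdiff(spec$free_params, c("v", "a", "t0"))
  if (!setequal(names(effects), need))
    stop("mechanism '", mechanism, "' needs effects {",
         paste(need, collapse = ", "), "}", call. = FALSE)
  fv <- c(v = base$v, a = base$a, t0 = base$t0, unlist(effects))
  pp <- expand_parameters(spec, fv[spec$free_params], s = base$s)
  set.seed(seed)
  sim_cond <- function(cond) {
    p <- pp[[cond]]
    sim <- simulate_ddm_cpp(as.integer(n_per_condition), p$v, p$a, p$z,
                            p$t0, p$s, dt)
    correct <- sim$upper == 1L
    target <- sample(c("left", "right"), n_per_condition, replace = TRUE)
    data.frame(participant = participant, condition = cond,
               response_side = ifelse(correct, target,
                                      ifelse(target == "left", "right",
                                             "left")),
               correct = correct, rt_ms = sim$rt * 1000,
               stringsAsFactors = FALSE)
  }
  trials <- trial_table(rbind(sim_cond("cued"), sim_cond("miscued")))
  truth <- data.frame(participant = participant, mechanism = mechanism,
                      v_c = pp$cued$v, v_m = pp$miscued$v, a = pp$cued$a,
                      z_c = pp$cued$z, z_m = pp$miscued$z,
                      t0_c = pp$cued$t0, t0_m = pp$miscued$t0,
                      stringsAsFactors = FALSE)
  list(trials = trials, truth = truth)
}

#' Cohort generation profile
#'
#' States the world a synthetic cohort is drawn from: cohort size, trials
#' per condition, the mixture of generating mechanisms, effect-size and
#' base-parameter distributions, and contaminant rates. Defaults follow
#' the qualitative picture of the localisation gaze-cueing literature:
#' base parameters (v = 3, a = 1.2, t0 = 0.30 s, s = 1) give accuracies
#' in the 94-99% range and mean RTs of a few hundred ms; the mechanism
#' mixture is 0.55 t0 / 0.25 z / 0.05 v / 0.10 simple / 0.05 t0-z
#' (non-decision time most prevalent, start point a minority, drift
#' rare).
#'
#' @param n_participants cohort size, >= 1.
#' @param trials_per_condition trials per condition per participant
#'   (scalar or per-participant vector).
#' @param mixture named proportions over mechanisms, summing to 1.
#' @param base_sd named SDs of the across-participant base-parameter
#'   draws (truncated normals around the `base` values).
#' @param effect_means,effect_sds across-participant effect-size
#'   distributions: `delta_t0` (s), `z_c`, `delta_v`; gaps are truncated
#'   at 0 and `z_c` at 0.5, respecting the positive-effect direction.
#' @param contaminant_fast,contaminant_slow fractions of RTs replaced by
#'   anticipations (< 100 ms) and lapses (> 5000 ms), each in \[0, 0.05\].
#' @param base a [ddm_params()] of central base values.
#' @param seed RNG seed.
#' @return a `generative_profile` list.
#' @export
generative_profile <- function(n_participants = 20,
                               trials_per_condition = 250,
                               mixture = c(t0 = 0.55, z = 0.25, v = 0.05,
                                           simple = 0.10, `t0-z` = 0.05),
                               base_sd = c(v = 0.5, a = 0.12, t0 = 0.03),
                               effect_means = c(delta_t0 = 0.05, z_c = 0.60,
                                                delta_v = 0.5),
                               effect_sds = c(delta_t0 = 0.015, z_c = 0.04,
                                              delta_v = 0.25),
                               contaminant_fast = 0, contaminant_slow = 0,
                               base = ddm_params(v = 3, a = 1.2, z = 0.5,
                                                 t0 = 0.30), seed = 1) {
  if (n_participants < 1) stop("`n_participants` must be >= 1",
                               call. = FALSE)
  if (abs(sum(mixture) - 1) > 1e-8)
    stop("mechanism mixture must sum to 1", call. = FALSE)
  if (!all(names(mixture) %in% names(model_catalogue())))
    stop("unknown mechanism in mixture", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_condition = trials_per_condition,
                 mixture = mixture, base_sd = base_sd,
                 effect_means = effect_means, effect_sds = effect_sds,
                 contaminant_fast = contaminant_fast,
                 contaminant_slow = contaminant_slow, base = base,
                 seed = as.integer(seed)),
            class = "generative_profile")
}

#' Cohort presets emulating the three analysed data-set shapes
#'
#' `"ds1-like"`: 41 participants x 120 trials/condition (240/participant);
#' `"ds2-like"`: 50 x 128 (~256); `"ds3-like"`: 71 x 750 (~1500).
#'
#' @param preset preset name.
#' @param ... overrides passed on to [generative_profile()].
#' @export
cohort_preset <- function(preset = c("ds1-like", "ds2-like", "ds3-like"),
                          ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
                 "ds1-like" = list(n_participants = 41,
                                   trials_per_condition = 120),
                 "ds2-like" = list(n_participants = 50,
                                   trials_per_condition = 128),
                 "ds3-like" = list(n_participants = 71,
                                   trials_per_condition = 750))
  do.call(generative_profile, utils::modifyList(args, list(...)))
}

#' Generate a synthetic cohort
#'
#' Draws each participant's mechanism from the profile's mixture, base
#' parameters and effect sizes from their distributions, simulates the
#' trials, and optionally plants contaminant RTs.
#'
#' @param profile a [generative_profile()].
#' @return `list(trials = trial_table, truth = data.frame)`; when
#'   contaminants are planted the trial table carries a logical
#'   `contaminant` column.
#' @export
generate_cohort <- function(profile) {
  stopifnot(inherits(profile, "generative_profile"))
  set.seed(profile$seed)
  n <- profile$n_participants
  mech <- sample(names(profile$mixture), n, replace = TRUE,
                 prob = profile$mixture)
  npc <- rep(profile$trials_per_condition, length.out = n)
  b <- profile$base; bs <- profile$base_sd
  em <- profile$effect_means; es <- profile$effect_sds
  all_tr <- vector("list", n); all_truth <- vector("list", n)
  for (i in seq_len(n)) {
    base_i <- ddm_params(v = rtnorm(1, b$v, bs[["v"]], 0.2, 10),
                         a = rtnorm(1, b$a, bs[["a"]], 0.3, 5),
                         z = 0.5,
                         t0 = rtnorm(1, b$t0, bs[["t0"]], 0.05, 1),
                         s = b$s)
    spec <- model_catalogue()[[mech[i]]]
    need <- setdiff(spec$free_params, c("v", "a", "t0"))
    eff <- list()
    if ("delta_t0" %in% need)
      eff$delta_t0 <- rtnorm(1, em[["delta_t0"]], es[["delta_t0"]], 0, 0.5)
    if ("z_c" %in% need)
      eff$z_c <- rtnorm(1, em[["z_c"]], es[["z_c"]], 0.5, 0.9)
    if ("delta_v" %in% need)
      eff$delta_v <- rtnorm(1, em[["delta_v"]], es[["delta_v"]], 0, 5)
    gp <- generate_participant(mech[i], base_i, eff, npc[i],
                               participant = sprintf("p%02d", i),
                               seed = derive_seed(profile$seed, i))
    all_tr[[i]] <- gp$trials
    all_truth[[i]] <- gp$truth
  }
  trials <- trial_table(do.call(rbind, all_tr))
  if (profile$contaminant_fast > 0 || profile$contaminant_slow > 0)
    trials <- contaminate(trials, profile$contaminant_fast,
                          profile$contaminant_slow,
                          seed = derive_seed(profile$seed, 10^6))
  list(trials = trials, truth = do.call(rbind, all_truth))
}

#' Plant contaminant response times
#'
#' Replaces the stated fractions of RTs with anticipations drawn uniform
#' on (20, 99) ms and lapses uniform on (5001, 8000) ms, flagging them in
#' a logical `contaminant` column, so the exclusion filters can be
#' exercised against known truth.
#'
#' @param table a [trial_table()].
#' @param fast_rate,slow_rate replacement fractions, each in \[0, 0.05\].
#' @param seed RNG seed.
#' @return the table with modified `rt_ms` and a `contaminant` column.
#' @export
contaminate <- function(table, fast_rate, slow_rate, seed = 1) {
  stopifnot(inherits(table, "trial_table"))
  if (fast_rate < 0 || fast_rate > 0.05 || slow_rate < 0 ||
      slow_rate > 0.05)
    stop("contaminant rates must lie in [0, 0.05]", call. = FALSE)
  set.seed(seed)
  n <- nrow(table)
  n_fast <- round(fast_rate * n); n_slow <- round(slow_rate * n)
  idx <- sample.int(n, n_fast + n_slow)
  table$contaminant <- FALSE
  if (n_fast > 0) {
    i <- idx[seq_len(n_fast)]
    table$rt_ms[i] <- runif(n_fast, 20, 99)
    table$contaminant[i] <- TRUE
  }
  if (n_slow > 0) {
    i <- idx[n_fast + seq_len(n_slow)]
    table$rt_ms[i] <- runif(n_slow, 5001, 8000)
    table$contaminant[i] <- TRUE
  }
  table
}

#' Write a cohort as delimited text plus a truth sidecar
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths of the two files, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, paste0(prefix, "_trials.csv"))
  sp <- file.path(dir, paste0(prefix, "_truth.csv"))
  write.csv(as.data.frame(cohort$trials), tp, row.names = FALSE)
  write.csv(cohort$truth, sp, row.names = FALSE)
  invisible(c(trials = tp, truth = sp))
}
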