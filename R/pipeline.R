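#' Configuration for an end-to-end pipeline run
#'
#' @param input a file path to a delimited trial table, a
#'   [trial_table()], or a [generative_profile()] to simulate from.
#' @param out_dir directory for artifacts (created if needed).
#' @param seed master seed; every stage derives its own seeds from it.
#' @param rt_min_ms,rt_max_ms,min_accuracy exclusion thresholds.
#' @param stage2 an [mcmc_config()] (full scale is `mcmc_config()`, the
#'   CI scale [reduced_mcmc_config()]).
#' @param stage3 a [hier_config()].
#' @param priors a `prior_spec` for Stage 2.
#' @param column_map,condition_map,adapter passed to [read_trial_table()]
#'   when `input` is a path.
#' @return a `run_config` list.
#' @export
run_config <- function(input, out_dir = tempfile("gazecue_run_"), seed = 1,
                       rt_min_ms = 100, rt_max_ms = 5000,
                       min_accuracy = 0.80,
                       stage2 = reduced_mcmc_config(seed = seed),
                       stage3 = hier_config(seed = seed),
                       priors = default_priors(),
                       column_map = NULL, condition_map = NULL,
                       adapter = NULL) {
  if (rt_min_ms <= 0 || rt_max_ms <= rt_min_ms || min_accuracy < 0 ||
      min_accuracy > 1)
    stop("invalid exclusion thresholds", call. = FALSE)
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms,
                 min_accuracy = min_accuracy, stage2 = stage2,
                 stage3 = stage3, priors = priors, column_map = column_map,
                 condition_map = condition_map, adapter = adapter),
            class = "run_config")
}

resolve_input <- function(config) {
  x <- config$input
  if (inherits(x, "trial_table")) return(x)
  if (inherits(x, "generative_profile")) return(generate_cohort(x)$trials)
  if (is.character(x) && length(x) == 1L) {
    args <- list(path = x)
    if (!is.null(config$column_map)) args$column_map <- config$column_map
    if (!is.null(config$condition_map))
      args$condition_map <- config$condition_map
    if (!is.null(config$adapter)) args$adapter <- config$adapter
    return(do.call(read_trial_table, args))
  }
  stop("`input` must be a path, trial_table or generative_profile",
       call. = FALSE)
}

config_fingerprint <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  slim <- config[c("seed", "rt_min_ms", "rt_max_ms", "min_accuracy")]
  slim$stage2 <- unclass(config$stage2)
  slim$stage3 <- unclass(config$stage3)
  slim$priors <- as.data.frame(config$priors)
  jsonlite::write_json(slim, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

write_manifest <- function(config, stage, extras = list()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- c(list(stage = stage, seed = config$seed,
                config_hash = config_fingerprint(config),
                timestamp = format(Sys.time(), tz = "UTC")), extras)
  jsonlite::write_json(man,
                       file.path(config$out_dir,
                                 paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Stage 1: exclusions and descriptive cueing magnitudes
#'
#' Applies the exclusion rules, computes per-participant cueing
#' magnitudes and the cohort summary, and writes
#' `stage1_magnitudes.csv`, `stage1_summary.json` and
#' `stage1_exclusions.json` (each manifest embeds the seed and a config
#' hash).
#'
#' @param config a [run_config()].
#' @return `list(trials = , summary = , report = )` invisibly-ish (the
#'   kept trials feed Stages 2-3).
#' @export
run_stage1 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  trials <- resolve_input(config)
  if (nrow(trials) == 0L) stop("empty input", call. = FALSE)
  ex <- apply_exclusions(trials, config$rt_min_ms, config$rt_max_ms,
                         config$min_accuracy)
  cs <- cueing_magnitudes(ex$trials)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(cs),
            file.path(config$out_dir, "stage1_magnitudes.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(mean_ms = attr(cs, "mean_ms"), sd_ms = attr(cs, "sd_ms"),
         smc = attr(cs, "smc"), smc_method = attr(cs, "smc_method"),
         n_positive = attr(cs, "n_positive"), n_participants = nrow(cs)),
    file.path(config$out_dir, "stage1_summary.json"), auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(unclass(ex$report),
                       file.path(config$out_dir, "stage1_exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(config, "stage1",
                 list(n_trials_analysed = ex$report$n_trials_out))
  list(trials = ex$trials, summary = cs, report = ex$report)
}

#' Stage 2: individual-level model comparison
#'
#' Fits the eight-variant catalogue to every included participant,
#' writes the per-participant selection table (`stage2_selection.csv`,
#' the stacked-weight data behind a per-participant weight figure), the
#' BIC inclusion table (`stage2_inclusion.csv`), the cohort summary
#' (`stage2_cohort.csv`, the Tables 3-5-style Probability-% and raw-score
#' columns) and the model-catalogue registry.
#'
#' @param config a [run_config()].
#' @param stage1 optional result of [run_stage1()]; recomputed otherwise.
#' @return `list(selection = , cohort = , stage1 = )`.
#' @export
run_stage2 <- function(config, stage1 = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(stage1)) stage1 <- run_stage1(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sel <- fit_cohort(stage1$trials, priors = config$priors,
                    config = config$stage2,
                    resume_file = file.path(config$out_dir,
                                            "stage2_progress.csv"))
  bad <- sel$table$participant[sel$table$max_rhat > 1.1]
  if (length(bad))
    warning("possible non-convergence (split-Rhat > 1.1) for: ",
            paste(unique(bad), collapse = ", "), call. = FALSE)
  co <- cohort_summary(sel)
  write.csv(sel$table, file.path(config$out_dir, "stage2_selection.csv"),
            row.names = FALSE)
  write.csv(sel$inclusion,
            file.path(config$out_dir, "stage2_inclusion.csv"),
            row.names = FALSE)
  write.csv(co, file.path(config$out_dir, "stage2_cohort.csv"),
            row.names = FALSE)
  write_model_catalogue(file.path(config$out_dir, "model_catalogue.json"))
  write_manifest(config, "stage2",
                 list(n_participants = length(unique(sel$table$participant))))
  list(selection = sel, cohort = co, stage1 = stage1)
}

#' Stage 3: hierarchical group-level differences
#'
#' For each target parameter in {t0, z, v}, fits the constrained
#' hierarchical model and writes the posterior draws of the group-level
#' cued-minus-miscued difference (`stage3_<target>_draws.csv`) and a
#' combined summary (`stage3_differences.csv`).
#'
#' @param config a [run_config()].
#' @param stage1 optional result of [run_stage1()]; recomputed otherwise.
#' @param targets which target parameters to fit.
#' @return named list of `ddm_group_difference` objects.
#' @export
run_stage3 <- function(config, stage1 = NULL,
                       targets = c("t0", "z", "v")) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(stage1)) stage1 <- run_stage1(config)
  out <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    cfg <- config$stage3
    cfg$seed <- derive_seed(config$stage3$seed, 1000L + ti)
    fit <- fit_hierarchical(stage1$trials, tg, cfg)
    gd <- group_difference(fit)
    write.csv(data.frame(draw = gd$draws),
              file.path(config$out_dir,
                        paste0("stage3_", tg, "_draws.csv")),
              row.names = FALSE)
    out[[tg]] <- gd
  }
  summ <- do.call(rbind, lapply(out, function(g)
    data.frame(target = g$target, mean = g$mean, ci_lower = g$ci[1],
               ci_upper = g$ci[2], plausible_direction =
                 g$plausible_direction, plausible_mass = g$plausible_mass,
               row.names = NULL)))
  write.csv(summ, file.path(config$out_dir, "stage3_differences.csv"),
            row.names = FALSE)
  write_manifest(config, "stage3", list(targets = targets))
  out
}
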