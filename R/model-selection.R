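#' BIC and AIC from a maximum log-likelihood
#'
#' `BIC = k log(n) - 2 max_log_lik`, `AIC = 2k - 2 max_log_lik`; lower is
#' better. `n` is the participant's analysed (post-exclusion) trial
#' count, so BIC penalties are per participant.
#'
#' @param max_log_lik maximum log-likelihood over retained samples.
#' @param k number of free parameters, >= 1.
#' @param n number of trials, >= 1.
#' @return `list(bic = , aic = )`.
#' @export
information_criteria <- function(max_log_lik, k, n) {
  if (!is.numeric(k) || k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  list(bic = k * log(n) - 2 * max_log_lik, aic = 2 * k - 2 * max_log_lik)
}

#' Akaike weights over a set of model scores
#'
#' Converts one criterion's scores (BIC or AIC; lower better) to relative
#' model probabilities `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`
#' with `delta_i = score_i - min(score)` for numerical stability.
#'
#' @param scores named numeric vector of finite criterion scores.
#' @return weights summing to 1, same names.
#' @export
model_weights <- function(scores) {
  bad <- !is.finite(scores)
  if (any(bad))
    stop("non-finite score for model(s): ",
         paste(names(scores)[bad] %||% which(bad), collapse = ", "),
         call. = FALSE)
  d <- scores - min(scores)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Parameter-inclusion probabilities
#'
#' For each parameter theta in {t0, z, v}, the summed weight of the four
#' variants in which theta varies across cueing conditions (for drift:
#' v, t0-v, z-v, complex), i.e. the relative probability that the data
#' are best described by a model making that assumption. Inclusion and
#' exclusion masses sum to 1.
#'
#' @param weights named weights over the full eight-model catalogue, as
#'   returned by [model_weights()].
#' @return named vector `c(t0 = , z = , v = )`.
#' @export
inclusion_probabilities <- function(weights) {
  cat_ <- model_catalogue()
  if (!setequal(names(weights), names(cat_)))
    stop("weights must cover the full eight-model catalogue", call. = FALSE)
  vapply(c(t0 = "t0_varies", z = "z_varies", v = "v_varies"),
         function(flag) sum(weights[vapply(cat_, `[[`, logical(1), flag)]),
         numeric(1))
}

#' Fit the full model catalogue to every participant
#'
#' Runs [fit_participant()] for each participant x model variant and
#' assembles the per-participant selection table: raw BIC/AIC, Akaike
#' weights per criterion, best model per criterion (ties broken toward
#' fewer free parameters, then lexicographic name), and the BIC
#' parameter-inclusion probabilities.
#'
#' @param trials a multi-participant [trial_table()] (post-exclusion).
#' @param priors a `prior_spec`.
#' @param config an [mcmc_config()]; each participant x model fit gets a
#'   seed derived from `config$seed`.
#' @param specs model list, defaults to the full catalogue.
#' @param keep_fits retain the full `ddm_fit` objects (memory-heavy).
#' @param progress print one line per participant.
#' @param resume_file optional CSV path: finished participants' rows are
#'   appended there as the run proceeds, and participants already present
#'   are skipped on restart. Per-participant seeds are derived by
#'   position, so a resumed run equals an uninterrupted one.
#' @return a `ddm_selection` list: `table` (one row per participant x
#'   model), `inclusion` (one row per participant), `fits` (optional).
#' @export
fit_cohort <- function(trials, priors = default_priors(),
                       config = reduced_mcmc_config(),
                       specs = model_catalogue(), keep_fits = FALSE,
                       progress = FALSE, resume_file = NULL) {
  stopifnot(inherits(trials, "trial_table"))
  parts <- unique(trials$participant)
  rows <- list(); incl <- list(); fits <- list()
  prev <- if (!is.null(resume_file) && file.exists(resume_file))
    read.csv(resume_file, stringsAsFactors = FALSE) else NULL
  for (pi in seq_along(parts)) {
    if (!is.null(prev) && as.character(parts[pi]) %in%
          as.character(prev$participant)) {
      d <- prev[prev$participant == parts[pi], , drop = FALSE]
      rows[[pi]] <- d[, setdiff(names(d), c("inc_t0", "inc_z", "inc_v"))]
      incl[[pi]] <- data.frame(participant = parts[pi],
                               t0 = d$inc_t0[1], z = d$inc_z[1],
                               v = d$inc_v[1], row.names = NULL)
      next
    }
    ptr <- trials[trials$participant == parts[pi], , drop = FALSE]
    res <- lapply(seq_along(specs), function(si) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, pi * 64L + si)
      suppressWarnings(fit_participant(ptr, specs[[si]], priors, cfg))
    })
    names(res) <- names(specs)
    bic <- vapply(res, `[[`, numeric(1), "bic")
    aic <- vapply(res, `[[`, numeric(1), "aic")
    wb <- model_weights(bic); wa <- model_weights(aic)
    rows[[pi]] <- data.frame(participant = parts[pi], model = names(specs),
                             k = vapply(res, `[[`, numeric(1), "k"),
                             n_trials = vapply(res, `[[`, numeric(1),
                                               "n_trials"),
                             max_log_lik = vapply(res, `[[`, numeric(1),
                                                  "max_log_lik"),
                             bic = bic, aic = aic, weight_bic = wb,
                             weight_aic = wa,
                             max_rhat = vapply(res, function(f)
                               max(f$diagnostics$rhat), numeric(1)),
                             row.names = NULL)
    ip <- inclusion_probabilities(wb)
    incl[[pi]] <- data.frame(participant = parts[pi],
                             t0 = ip[["t0"]], z = ip[["z"]], v = ip[["v"]],
                             row.names = NULL)
    if (!is.null(resume_file)) {
      chunk <- cbind(rows[[pi]], inc_t0 = ip[["t0"]], inc_z = ip[["z"]],
                     inc_v = ip[["v"]])
      write.table(chunk, resume_file, sep = ",", row.names = FALSE,
                  col.names = !file.exists(resume_file), append =
                    file.exists(resume_file))
    }
    if (keep_fits) fits[[as.character(parts[pi])]] <- res
    if (progress)
      message(sprintf("participant %s (%d/%d): best BIC model '%s'",
                      parts[pi], pi, length(parts),
                      best_model(bic, rows[[pi]]$k)))
  }
  structure(list(table = do.call(rbind, rows),
                 inclusion = do.call(rbind, incl),
                 fits = if (keep_fits) fits else NULL,
                 models = names(specs)),
            class = "ddm_selection")
}

# lowest score wins; ties toward fewer free parameters, then name
best_model <- function(scores, k) {
  cand <- which(scores <= min(scores) + 1e-12)
  cand <- cand[order(k[cand], names(scores)[cand])]
  names(scores)[cand[1]]
}

#' Cohort-level model-comparison summary
#'
#' Collapses the per-participant selection table across participants:
#' mean Akaike weight (as %) and mean raw score per model per criterion,
#' plus the count of participants whose best model is each variant.
#'
#' @param sel a `ddm_selection` from [fit_cohort()].
#' @return a data.frame with one row per model and columns
#'   `prob_bic_pct`, `raw_bic`, `n_best_bic`, `prob_aic_pct`, `raw_aic`,
#'   `n_best_aic`.
#' @export
cohort_summary <- function(sel) {
  stopifnot(inherits(sel, "ddm_selection"))
  tb <- sel$table
  models <- sel$models
  by_model <- function(col) vapply(models, function(m)
    mean(tb[[col]][tb$model == m]), numeric(1))
  bests <- lapply(split(tb, tb$participant), function(d) {
    sc_b <- setNames(d$bic, d$model); sc_a <- setNames(d$aic, d$model)
    c(best_model(sc_b, d$k), best_model(sc_a, d$k))
  })
  nb <- table(factor(vapply(bests, `[`, character(1), 1), levels = models))
  na_ <- table(factor(vapply(bests, `[`, character(1), 2), levels = models))
  data.frame(model = models,
             prob_bic_pct = 100 * by_model("weight_bic"),
             raw_bic = by_model("bic"),
             n_best_bic = as.integer(nb),
             prob_aic_pct = 100 * by_model("weight_aic"),
             raw_aic = by_model("aic"),
             n_best_aic = as.integer(na_),
             row.names = NULL)
}

#' Correlation between simple-model probability and cueing magnitude
#'
#' Pearson correlation between participants' probability of being best
#' described by the no-difference (simple) model and their cueing
#' magnitudes, with a default-prior Bayes factor for the correlation.
#' The Bayes factor integrates the Fisher-z likelihood of the observed
#' correlation over a stretched-beta prior on rho (uniform on (-1, 1)
#' when `kappa = 1`) against the point null rho = 0.
#'
#' @param simple_probs per-participant weight of the simple model.
#' @param magnitudes per-participant cueing magnitudes (ms).
#' @param kappa stretched-beta prior width (1 = uniform).
#' @return `list(r = , bf10 = , n = , estimator = )`.
#' @export
magnitude_weight_correlation <- function(simple_probs, magnitudes,
                                         kappa = 1) {
  if (length(simple_probs) != length(magnitudes))
    stop("vectors must be paired", call. = FALSE)
  n <- length(simple_probs)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(simple_probs) == 0 || sd(magnitudes) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- cor(simple_probs, magnitudes)
  zobs <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  m1 <- integrate(function(rho)
    dnorm(zobs, atanh(rho), se) *
      stats::dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2,
    -1 + 1e-9, 1 - 1e-9, rel.tol = 1e-10)$value
  m0 <- dnorm(zobs, 0, se)
  list(r = r, bf10 = m1 / m0, n = n,
       estimator = "Fisher-z likelihood, stretched-beta prior")
}
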