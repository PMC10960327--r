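#' Sampler configuration for the individual-level fits
#'
#' Defaults follow the analysis settings: 3k chains (k = number of free
#' parameters), 4,000 iterations with the first 2,000 discarded as
#' burn-in. Proposals are differential-evolution moves,
#' `gamma * (chain_m - chain_n)` plus small uniform jitter, with
#' `gamma = 2.38 / sqrt(2k)` unless overridden. [reduced_mcmc_config()]
#' is a cheaper preset (chains capped at 12, 1,000 iterations) for
#' continuous-integration-scale runs.
#'
#' @param iterations total DE-MCMC iterations.
#' @param burn_in iterations discarded; must be < `iterations`.
#' @param chains_per_free_param chain multiplier (3k chains by default).
#' @param max_chains upper cap on the chain count.
#' @param de_gamma DE proposal scale; `NULL` for `2.38 / sqrt(2k)`.
#' @param jitter half-width of the uniform proposal jitter.
#' @param seed integer RNG seed.
#' @param min_trials warn when fitting fewer trials than this.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(iterations = 4000, burn_in = 2000,
                        chains_per_free_param = 3, max_chains = Inf,
                        de_gamma = NULL, jitter = 1e-4, seed = 1,
                        min_trials = 50) {
  if (burn_in >= iterations)
    stop("`burn_in` must be smaller than `iterations`", call. = FALSE)
  if (iterations < 1 || chains_per_free_param < 1)
    stop("invalid sampler configuration", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 chains_per_free_param = as.integer(chains_per_free_param),
                 max_chains = max_chains, de_gamma = de_gamma,
                 jitter = jitter, seed = as.integer(seed),
                 min_trials = min_trials),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
reduced_mcmc_config <- function(seed = 1, iterations = 1000, burn_in = 500,
                                max_chains = 12) {
  mcmc_config(iterations = iterations, burn_in = burn_in,
              max_chains = max_chains, seed = seed)
}

# seconds / correctness / condition vectors for one participant
trial_arrays <- function(trials) {
  stopifnot(inherits(trials, "trial_table"))
  list(rt = trials$rt_ms / 1000,
       correct = as.integer(trials$correct),
       cued = as.integer(trials$condition == "cued"))
}

#' Log-likelihood of one participant's trials under a model variant
#'
#' Sum over trials of the floored log defective density at the observed
#' (rt, correctness) under that trial's condition-specific parameters.
#' The upper boundary codes the correct response; on cued trials the
#' starting point toward the correct boundary is `z_c`, on miscued trials
#' `1 - z_c`. RTs are converted ms -> seconds. A free vector outside the
#' prior support yields `-Inf` (rejected, not an error).
#'
#' @param trials a [trial_table()] for a single participant.
#' @param spec a `ddm_model_spec`.
#' @param fv named free-parameter vector for `spec`.
#' @param priors a `prior_spec`; support defines the parameter domain.
#' @param s diffusion coefficient.
#' @param floor per-trial log-density floor.
#' @return a single log-likelihood value.
#' @export
participant_log_likelihood <- function(trials, spec, fv,
                                       priors = default_priors(), s = 1,
                                       floor = -700) {
  fv <- unlist(fv)
  if (!setequal(names(fv), spec$free_params))
    stop("free vector must supply exactly {",
         paste(spec$free_params, collapse = ", "), "}", call. = FALSE)
  theta <- matrix(fv[spec$free_params], nrow = 1,
                  dimnames = list(NULL, spec$free_params))
  pr <- prior_rows(priors, spec)
  if (any(theta[1, ] < pr$lower | theta[1, ] > pr$upper)) return(-Inf)
  arr <- trial_arrays(trials)
  ddm_loglik_cpp(arr$rt, arr$correct, arr$cued, expand_matrix(theta, spec),
                 s, floor)[1]
}

#' Fit one model variant to one participant by DE-MCMC
#'
#' Samples the posterior over the variant's free parameters with
#' differential-evolution MCMC: each chain proposes its current state
#' plus `gamma` times the difference of two other randomly chosen chains
#' plus uniform jitter, accepted by a Metropolis step on the log
#' posterior (likelihood + truncated-normal priors). Chains start at
#' independent prior draws, re-drawn until the posterior is finite.
#' Per-sample log-likelihoods are cached so the maximum-likelihood
#' extraction needs no recomputation.
#'
#' @inheritParams participant_log_likelihood
#' @param config an [mcmc_config()].
#' @return a `ddm_fit` with elements `model` (name), `samples` (retained
#'   iterations x chains x k array), `log_lik` and `log_prior` (retained
#'   iterations x chains), `ml_params`, `max_log_lik`, `bic`, `aic`,
#'   `n_trials`, `k`, `diagnostics` (split-Rhat per parameter, acceptance
#'   rate), `config`.
#' @export
fit_participant <- function(trials, spec, priors = default_priors(),
                            config = mcmc_config(), s = 1, floor = -700) {
  stopifnot(inherits(spec, "ddm_model_spec"),
            inherits(config, "mcmc_config"))
  arr <- trial_arrays(trials)
  n <- length(arr$rt)
  if (n < 1) stop("no trials to fit", call. = FALSE)
  if (n < config$min_trials)
    warning("only ", n, " trials; fit may be unreliable", call. = FALSE)
  pr <- prior_rows(priors, spec)
  k <- free_parameter_count(spec)
  nch <- max(4L, min(config$chains_per_free_param * k,
                     as.integer(min(config$max_chains, 10000))))
  gamma <- config$de_gamma %||% (2.38 / sqrt(2 * k))
  set.seed(config$seed)

  # Initialisation: prior draws until the posterior is finite *without*
  # the log-density floor, i.e. every trial has positive density. Draws
  # on the floored plateau (e.g. t0 above the fastest RT) are rejected:
  # differential-evolution proposals cannot rescue a chain stranded
  # there once the remaining chains have contracted.
  theta <- matrix(NA_real_, nch, k, dimnames = list(NULL, spec$free_params))
  ll <- lp <- rep(NA_real_, nch)
  deep <- -1e9 # sentinel floor: any floored trial drags the sum below -1e8
  for (i in seq_len(nch)) {
    for (try in 1:200) {
      cand <- rtnorm(k, pr$mean, pr$sd, pr$lower, pr$upper)
      cand_lp <- sum(dtnorm(cand, pr$mean, pr$sd, pr$lower, pr$upper,
                            log = TRUE))
      cand_ll <- ddm_loglik_cpp(arr$rt, arr$correct, arr$cued,
                                expand_matrix(matrix(cand, 1,
                                                     dimnames = list(NULL, spec$free_params)),
                                              spec), s, deep)[1]
      if (is.finite(cand_lp) && cand_ll > -1e8) {
        theta[i, ] <- cand
        ll[i] <- ddm_loglik_cpp(arr$rt, arr$correct, arr$cued,
                                expand_matrix(theta[i, , drop = FALSE],
                                              spec), s, floor)[1]
        lp[i] <- cand_lp
        break
      }
    }
    if (anyNA(theta[i, ]))
      stop("chain initialisation failed: no finite posterior draw found",
           call. = FALSE)
  }

  kept <- config$iterations - config$burn_in
  samples <- array(NA_real_, c(kept, nch, k),
                   dimnames = list(NULL, NULL, spec$free_params))
  ll_store <- lp_store <- matrix(NA_real_, kept, nch)
  n_acc <- 0L
  for (it in seq_len(config$iterations)) {
    r1 <- sample.int(nch, nch, replace = TRUE)
    r2 <- sample.int(nch, nch, replace = TRUE)
    idx <- seq_len(nch)
    while (any(bad <- (r1 == idx | r2 == idx | r1 == r2))) {
      r1[bad] <- sample.int(nch, sum(bad), replace = TRUE)
      r2[bad] <- sample.int(nch, sum(bad), replace = TRUE)
    }
    prop <- theta + gamma * (theta[r1, , drop = FALSE] -
                               theta[r2, , drop = FALSE]) +
      matrix(runif(nch * k, -config$jitter, config$jitter), nch, k)
    lp_prop <- prior_logdens_matrix(prop, pr)
    ll_prop <- rep(-Inf, nch)
    ok <- is.finite(lp_prop)
    if (any(ok))
      ll_prop[ok] <- ddm_loglik_cpp(arr$rt, arr$correct, arr$cued,
                                    expand_matrix(prop[ok, , drop = FALSE],
                                                  spec), s, floor)
    logr <- (ll_prop + lp_prop) - (ll + lp)
    acc <- is.finite(logr) & log(runif(nch)) < logr
    if (any(acc)) {
      theta[acc, ] <- prop[acc, , drop = FALSE]
      ll[acc] <- ll_prop[acc]; lp[acc] <- lp_prop[acc]
    }
    n_acc <- n_acc + sum(acc)
    if (it > config$burn_in) {
      j <- it - config$burn_in
      samples[j, , ] <- theta
      ll_store[j, ] <- ll
      lp_store[j, ] <- lp
    }
  }

  ml <- extract_max_likelihood(list(samples = samples, log_lik = ll_store))
  ic <- information_criteria(ml$max_log_lik, k, n)
  structure(list(model = spec$name, spec = spec, samples = samples,
                 log_lik = ll_store, log_prior = lp_store,
                 ml_params = ml$ml_params, max_log_lik = ml$max_log_lik,
                 bic = ic$bic, aic = ic$aic, n_trials = n, k = k,
                 diagnostics = list(
                   rhat = split_rhat(samples),
                   acceptance_rate = n_acc / (config$iterations * nch)),
                 config = config),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "<ddm_fit> model '%s': %d trials, k = %d; max log-lik %.2f; BIC %.2f, AIC %.2f; max split-Rhat %.3f\n",
    x$model, x$n_trials, x$k, x$max_log_lik, x$bic, x$aic,
    max(x$diagnostics$rhat)))
  invisible(x)
}

#' Serialise a fit summary to structured text
#'
#' Writes the model name, maximum-likelihood parameter set and
#' log-likelihood, information criteria, diagnostics and sampler
#' configuration as JSON. Chains are omitted by default (they dominate
#' the file size); `keep_chains = TRUE` inlines them as arrays.
#'
#' @param fit a `ddm_fit`.
#' @param path output file.
#' @param keep_chains include the retained samples.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, keep_chains = FALSE) {
  stopifnot(inherits(fit, "ddm_fit"))
  out <- list(model = fit$model, n_trials = fit$n_trials, k = fit$k,
              ml_params = as.list(fit$ml_params),
              max_log_lik = fit$max_log_lik, bic = fit$bic, aic = fit$aic,
              diagnostics = list(
                rhat = as.list(fit$diagnostics$rhat),
                acceptance_rate = fit$diagnostics$acceptance_rate),
              config = unclass(fit$config))
  if (keep_chains) out$samples <- fit$samples
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Retained sample with the highest data likelihood
#'
#' Returns the retained posterior sample maximising the *likelihood* (not
#' the posterior). Ties are broken by first occurrence in (chain,
#' iteration) order.
#'
#' @param fit a `ddm_fit`, or a list with elements `samples` (iterations
#'   x chains x k) and `log_lik` (iterations x chains).
#' @return `list(ml_params = named vector, max_log_lik = value)`.
#' @export
extract_max_likelihood <- function(fit) {
  samples <- fit$samples; ll <- fit$log_lik
  if (is.null(samples) || length(ll) == 0L)
    stop("empty chains", call. = FALSE)
  # column-major over (iterations x chains) is exactly (chain, iteration)
  # scan order, so which.max's first-occurrence rule is the tie-break
  best <- which.max(as.vector(ll))
  it <- (best - 1L) %% nrow(ll) + 1L
  ch <- (best - 1L) %/% nrow(ll) + 1L
  list(ml_params = setNames(samples[it, ch, ], dimnames(samples)[[3]]),
       max_log_lik = ll[it, ch])
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain
#' in half.
#'
#' @param samples iterations x chains x parameters array.
#' @return named vector of Rhat values per parameter.
#' @export
split_rhat <- function(samples) {
  d <- dim(samples)
  half <- d[1] %/% 2L
  vapply(seq_len(d[3]), function(j) {
    x <- samples[, , j, drop = FALSE]
    halves <- cbind(x[seq_len(half), , 1], x[half + seq_len(half), , 1])
    m <- ncol(halves); nn <- nrow(halves)
    mu <- colMeans(halves)
    w <- mean(apply(halves, 2, stats::var))
    b <- nn * stats::var(mu)
    if (w <= 0) return(1)
    sqrt(((nn - 1) / nn * w + b / nn) / w)
  }, numeric(1)) -> rh
  setNames(rh, dimnames(samples)[[3]])
}
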