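#' Specification of a single-target hierarchical model
#'
#' Stage-3 models estimate, for one target parameter theta in
#' {t0, z, v}, the group-level cued-minus-miscued difference while the
#' other parameters keep their directional individual-level constraints.
#' Concretely: (i) the target's cued and miscued values are free per
#' participant, each drawn from its own condition-specific truncated-
#' normal group distribution whose means are unconstrained in order;
#' (ii) every non-target directional parameter is modelled as base +
#' nonnegative gap (z via `z_c >= 0.5`), with group distributions
#' truncated at the constraint boundary; (iii) `a` is shared across
#' conditions with one group distribution.
#'
#' @param target `"t0"`, `"z"` or `"v"`.
#' @return a `ddm_hier_spec` with the individual-level parameter table
#'   (domains and group hyperpriors) and the target's group-mean names.
#' @export
hierarchical_spec <- function(target = c("t0", "z", "v")) {
  target <- match.arg(target)
  row <- function(name, lower, upper, mu_mean, mu_sd, sigma_scale)
    data.frame(name = name, lower = lower, upper = upper, mu_mean = mu_mean,
               mu_sd = mu_sd, sigma_scale = sigma_scale,
               stringsAsFactors = FALSE)
  tab <- rbind(
    row("a", 0.1, 5, 1.5, 2, 1),
    if (target == "t0") rbind(row("t0_c", 0.03, 1, 0.3, 0.5, 0.3),
                              row("t0_m", 0.03, 1, 0.3, 0.5, 0.3))
    else rbind(row("t0", 0.03, 1, 0.3, 0.5, 0.3),
               row("delta_t0", 0, 1, 0, 0.5, 0.3)),
    if (target == "z") rbind(row("z_c", 0.01, 0.99, 0.5, 0.5, 0.2),
                             row("z_m", 0.01, 0.99, 0.5, 0.5, 0.2))
    else row("z_c", 0.5, 0.99, 0.5, 0.5, 0.2),
    if (target == "v") rbind(row("v_c", 0, 10, 2, 5, 2),
                             row("v_m", 0, 10, 2, 5, 2))
    else rbind(row("v", 0, 10, 2, 5, 2),
               row("delta_v", 0, 10, 0, 0.5, 2)))
  rownames(tab) <- NULL
  structure(list(target = target, params = tab,
                 mu_names = paste0("mu_",
                                   switch(target,
                                          t0 = c("t0_c", "t0_m"),
                                          z = c("z_c", "z_m"),
                                          v = c("v_c", "v_m")))),
            class = "ddm_hier_spec")
}

#' @export
print.ddm_hier_spec <- function(x, ...) {
  cat(sprintf("<ddm_hier_spec> target '%s'; individual parameters: %s\n",
              x$target, paste(x$params$name, collapse = ", ")))
  invisible(x)
}

# individual-parameter matrix (rows = states) -> 7-col likelihood matrix
hier_expand <- function(ind, spec) {
  nm <- spec$params$name
  g <- function(p) ind[, match(p, nm)]
  v_c <- if (spec$target == "v") g("v_c") else g("v") + g("delta_v")
  v_m <- if (spec$target == "v") g("v_m") else g("v")
  t0_c <- if (spec$target == "t0") g("t0_c") else g("t0")
  t0_m <- if (spec$target == "t0") g("t0_m") else g("t0") + g("delta_t0")
  z_c <- g("z_c")
  z_m <- if (spec$target == "z") g("z_m") else 1 - g("z_c")
  cbind(v_c, v_m, g("a"), z_c, z_m, t0_c, t0_m)
}

#' Hierarchical log posterior at a single state
#'
#' Sum over participants of the trial log-likelihood, plus the
#' truncated-normal population density of every individual parameter
#' given its group (mu, sigma), plus the group-level hyperprior density.
#' Out-of-domain states return `-Inf`.
#'
#' @param spec a [hierarchical_spec()].
#' @param state `list(ind = participants x parameters matrix, mu = ,
#'   sigma = )` with `mu`/`sigma` in the order of `spec$params`.
#' @param trials a multi-participant [trial_table()].
#' @param s diffusion coefficient.
#' @param floor per-trial log-density floor.
#' @return a single log-density value.
#' @export
hierarchical_log_posterior <- function(spec, state, trials, s = 1,
                                       floor = -700) {
  stopifnot(inherits(spec, "ddm_hier_spec"))
  tab <- spec$params
  ind <- state$ind; mu <- state$mu; sigma <- state$sigma
  if (any(sigma <= 1e-4)) return(-Inf)
  if (any(t(ind) < tab$lower | t(ind) > tab$upper)) return(-Inf)
  if (any(mu < tab$lower | mu > tab$upper)) return(-Inf)
  parts <- unique(trials$participant)
  if (nrow(ind) != length(parts))
    stop("`state$ind` must have one row per participant", call. = FALSE)
  ll <- 0
  par7 <- hier_expand(ind, spec)
  for (i in seq_along(parts)) {
    arr <- trial_arrays(trials[trials$participant == parts[i], ,
                               drop = FALSE])
    ll <- ll + ddm_loglik_cpp(arr$rt, arr$correct, arr$cued,
                              par7[i, , drop = FALSE], s, floor)[1]
  }
  pop <- sum(dtnorm(t(ind), mu, sigma, tab$lower, tab$upper, log = TRUE))
  hyper <- sum(dtnorm(mu, tab$mu_mean, tab$mu_sd, tab$lower, tab$upper,
                      log = TRUE)) +
    sum(dtnorm(sigma, 0, tab$sigma_scale, 1e-4, Inf, log = TRUE))
  ll + pop + hyper
}

#' Sampler configuration for the hierarchical fits
#'
#' Blocked DE-MCMC: per iteration each participant's parameter block is
#' updated conditional on the group level, then each group-level
#' (mu, sigma) pair conditional on all individuals. Defaults mirror the
#' individual-level settings at a reduced scale.
#'
#' @param chains number of chains.
#' @param iterations,burn_in total and discarded iterations.
#' @param jitter uniform proposal jitter half-width.
#' @param seed RNG seed.
#' @param keep_individuals store individual-level chains too.
#' @return a `hier_config` list.
#' @export
hier_config <- function(chains = 24, iterations = 1500, burn_in = 750,
                        jitter = 1e-4, seed = 1, keep_individuals = FALSE) {
  if (burn_in >= iterations)
    stop("`burn_in` must be smaller than `iterations`", call. = FALSE)
  if (chains < 4) stop("need at least 4 chains", call. = FALSE)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), jitter = jitter,
                 seed = as.integer(seed),
                 keep_individuals = keep_individuals),
            class = "hier_config")
}

#' Fit a single-target hierarchical model by blocked DE-MCMC
#'
#' @param trials a multi-participant [trial_table()] (post-exclusion),
#'   RTs in ms.
#' @param target `"t0"`, `"z"` or `"v"`.
#' @param config a [hier_config()].
#' @param s diffusion coefficient.
#' @param floor per-trial log-density floor.
#' @return a `ddm_hier_fit`: `spec`, retained `group` chains (iterations
#'   x chains x (mu, sigma) parameters), optional `individuals` array,
#'   `diagnostics` (split-Rhat of group parameters, block acceptance
#'   rates), `config`.
#' @export
fit_hierarchical <- function(trials, target = c("t0", "z", "v"),
                             config = hier_config(), s = 1, floor = -700) {
  spec <- hierarchical_spec(match.arg(target))
  stopifnot(inherits(trials, "trial_table"), inherits(config, "hier_config"))
  tab <- spec$params
  nk <- nrow(tab)
  parts <- unique(trials$participant)
  np <- length(parts)
  if (np < 2) stop("hierarchical estimation needs >= 2 participants",
                   call. = FALSE)
  arrs <- lapply(parts, function(p)
    trial_arrays(trials[trials$participant == p, , drop = FALSE]))
  nch <- config$chains
  g_ind <- 2.38 / sqrt(2 * nk)
  g_grp <- 2.38 / sqrt(2 * 2) # per-(mu_j, sigma_j) block
  sg_min <- 1e-4
  set.seed(config$seed)

  # log hyperprior of (mu_j, sigma_j) columns: chains x nk
  hyper_mat <- function(mu, sg) {
    matrix(dtnorm(as.vector(mu), rep(tab$mu_mean, each = nch),
                  rep(tab$mu_sd, each = nch), rep(tab$lower, each = nch),
                  rep(tab$upper, each = nch), log = TRUE), nch, nk) +
      matrix(dtnorm(as.vector(sg), 0, rep(tab$sigma_scale, each = nch),
                    sg_min, Inf, log = TRUE), nch, nk)
  }
  # per-parameter population terms for one participant block: chains x nk
  pop_block <- function(x, mu, sg) {
    matrix(dtnorm(as.vector(x), as.vector(mu), as.vector(pmax(sg, sg_min)),
                  rep(tab$lower, each = nch), rep(tab$upper, each = nch),
                  log = TRUE), nch, nk)
  }
  donors <- function() {
    r1 <- sample.int(nch, nch, replace = TRUE)
    r2 <- sample.int(nch, nch, replace = TRUE)
    idx <- seq_len(nch)
    while (any(bad <- (r1 == idx | r2 == idx | r1 == r2))) {
      r1[bad] <- sample.int(nch, sum(bad), replace = TRUE)
      r2[bad] <- sample.int(nch, sum(bad), replace = TRUE)
    }
    list(r1, r2)
  }

  # --- initialisation -------------------------------------------------
  # Group level starts overdispersed around the hyperprior centres;
  # individuals are drawn from their group distribution and re-drawn
  # until no trial sits on the floored-likelihood plateau (same rationale
  # as the individual-level fitter).
  mu <- matrix(NA_real_, nch, nk); sg <- matrix(NA_real_, nch, nk)
  for (j in seq_len(nk)) {
    mu[, j] <- rtnorm(nch, tab$mu_mean[j], tab$mu_sd[j] / 4, tab$lower[j],
                      tab$upper[j])
    sg[, j] <- rtnorm(nch, tab$sigma_scale[j] / 2, tab$sigma_scale[j] / 4,
                      1e-3, Inf)
  }
  ind <- array(NA_real_, c(nch, np, nk))
  ll <- matrix(NA_real_, nch, np) # data log-lik per chain x participant
  deep <- -1e9
  j_t0 <- match("t0", tab$name)
  for (p in seq_len(np)) {
    # initial non-decision times must leave every RT in-support: cap them
    # below the participant's fastest RT (initialisation only — the
    # sampler itself is free to propose anywhere in the domain)
    rt_cap <- max(0.95 * min(arrs[[p]]$rt), 0.031)
    need <- rep(TRUE, nch)
    for (try in 1:300) {
      if (!any(need)) break
      for (j in seq_len(nk)) {
        up <- rep(tab$upper[j], nch)
        if (tab$name[j] %in% c("t0", "t0_c", "t0_m")) up <- pmin(up, rt_cap)
        if (tab$name[j] == "delta_t0")
          up <- pmax(pmin(up, rt_cap - ind[, p, j_t0]), 1e-6)
        ind[need, p, j] <- rtnorm(sum(need), mu[need, j], sg[need, j],
                                  tab$lower[j], up[need])
      }
      cand <- matrix(ind[, p, ], nch, nk)
      lls <- ddm_loglik_cpp(arrs[[p]]$rt, arrs[[p]]$correct, arrs[[p]]$cued,
                            hier_expand(cand, spec), s, deep)
      ll[need, p] <- lls[need]
      need <- ll[, p] < -1e8
    }
    if (any(need))
      stop("hierarchical initialisation failed for participant ", parts[p],
           call. = FALSE)
    # recompute at the working floor
    ll[, p] <- ddm_loglik_cpp(arrs[[p]]$rt, arrs[[p]]$correct,
                              arrs[[p]]$cued,
                              hier_expand(matrix(ind[, p, ], nch, nk), spec),
                              s, floor)
  }
  pop3 <- array(NA_real_, c(nch, np, nk)) # population term per ch x p x j
  for (p in seq_len(np))
    pop3[, p, ] <- pop_block(matrix(ind[, p, ], nch, nk), mu, sg)
  hyp <- hyper_mat(mu, sg)

  kept <- config$iterations - config$burn_in
  grp_store <- array(NA_real_, c(kept, nch, 2 * nk),
                     dimnames = list(NULL, NULL,
                                     c(paste0("mu_", tab$name),
                                       paste0("sigma_", tab$name))))
  ind_store <- if (config$keep_individuals)
    array(NA_real_, c(kept, nch, np, nk)) else NULL
  acc_ind <- 0; acc_grp <- 0

  for (it in seq_len(config$iterations)) {
    # participant blocks, conditional on the group level
    for (p in seq_len(np)) {
      d <- donors()
      cur <- matrix(ind[, p, ], nch, nk)
      prop <- cur + g_ind * (matrix(ind[d[[1]], p, ], nch, nk) -
                               matrix(ind[d[[2]], p, ], nch, nk)) +
        matrix(runif(nch * nk, -config$jitter, config$jitter), nch, nk)
      in_dom <- rowSums(sweep(prop, 2, tab$lower, `<`) |
                          sweep(prop, 2, tab$upper, `>`)) == 0
      ll_prop <- rep(-Inf, nch)
      if (any(in_dom))
        ll_prop[in_dom] <- ddm_loglik_cpp(arrs[[p]]$rt, arrs[[p]]$correct,
                                          arrs[[p]]$cued,
                                          hier_expand(prop[in_dom, ,
                                                           drop = FALSE],
                                                      spec), s, floor)
      pop_prop <- pop_block(prop, mu, sg)
      logr <- (ll_prop + rowSums(pop_prop)) - (ll[, p] + rowSums(pop3[, p, ]))
      acc <- in_dom & is.finite(logr) & log(runif(nch)) < logr
      if (any(acc)) {
        ind[acc, p, ] <- prop[acc, , drop = FALSE]
        ll[acc, p] <- ll_prop[acc]
        pop3[acc, p, ] <- pop_prop[acc, , drop = FALSE]
      }
      acc_ind <- acc_ind + sum(acc)
    }
    # group level, one (mu_j, sigma_j) pair at a time
    for (j in seq_len(nk)) {
      d <- donors()
      cur <- cbind(mu[, j], sg[, j])
      prop <- cur + g_grp * (cur[d[[1]], , drop = FALSE] -
                               cur[d[[2]], , drop = FALSE]) +
        matrix(runif(nch * 2, -config$jitter, config$jitter), nch, 2)
      mu_p <- prop[, 1]; sg_p <- prop[, 2]
      in_dom <- mu_p >= tab$lower[j] & mu_p <= tab$upper[j] & sg_p > sg_min
      sg_eval <- pmax(sg_p, sg_min)
      hyp_p <- dtnorm(mu_p, tab$mu_mean[j], tab$mu_sd[j], tab$lower[j],
                      tab$upper[j], log = TRUE) +
        dtnorm(sg_eval, 0, tab$sigma_scale[j], sg_min, Inf, log = TRUE)
      # population term of parameter j for every participant
      xj <- matrix(ind[, , j], nch, np)
      pop_p <- matrix(dtnorm(as.vector(xj), mu_p, sg_eval, tab$lower[j],
                             tab$upper[j], log = TRUE), nch, np)
      logr <- (hyp_p + rowSums(pop_p)) - (hyp[, j] + rowSums(pop3[, , j]))
      acc <- in_dom & is.finite(logr) & log(runif(nch)) < logr
      if (any(acc)) {
        mu[acc, j] <- mu_p[acc]; sg[acc, j] <- sg_p[acc]
        hyp[acc, j] <- hyp_p[acc]
        pop3[acc, , j] <- pop_p[acc, , drop = FALSE]
      }
      acc_grp <- acc_grp + sum(acc)
    }

    if (it > config$burn_in) {
      jj <- it - config$burn_in
      grp_store[jj, , ] <- cbind(mu, sg)
      if (config$keep_individuals) ind_store[jj, , , ] <- ind
    }
  }

  structure(list(spec = spec, group = grp_store, individuals = ind_store,
                 participants = parts,
                 diagnostics = list(
                   rhat = split_rhat(grp_store),
                   acceptance_individual =
                     acc_ind / (config$iterations * np * nch),
                   acceptance_group =
                     acc_grp / (config$iterations * nk * nch)),
                 config = config),
            class = "ddm_hier_fit")
}

#' @export
print.ddm_hier_fit <- function(x, ...) {
  gd <- group_difference(x)
  cat(sprintf(
    "<ddm_hier_fit> target '%s': %d participants; mean group difference %.4f, 95%% CI [%.4f, %.4f]; max group split-Rhat %.3f\n",
    x$spec$target, length(x$participants), gd$mean, gd$ci[1], gd$ci[2],
    max(x$diagnostics$rhat)))
  invisible(x)
}

#' Posterior of the group-level cued-minus-miscued difference
#'
#' Per retained draw, the difference `mu_theta_cued - mu_theta_miscued`
#' of the group means for the target parameter, with the equal-tailed
#' 95% credible interval and the fraction of mass in the theoretically
#' plausible direction (negative for t0; positive for z and v).
#'
#' @param fit a `ddm_hier_fit`, or an iterations x chains x parameters
#'   group-chain array with dimnames matching the spec's `mu` names.
#' @param spec the [hierarchical_spec()] (taken from `fit` when omitted).
#' @param level credible-interval mass.
#' @param hdi use the highest-density interval instead of equal-tailed.
#' @return a `ddm_group_difference`: `target`, `draws`, `mean`, `ci`,
#'   `plausible_direction`, `plausible_mass`.
#' @export
group_difference <- function(fit, spec = NULL, level = 0.95, hdi = FALSE) {
  if (inherits(fit, "ddm_hier_fit")) {
    spec <- fit$spec
    chains <- fit$group
  } else chains <- fit
  if (is.null(spec)) stop("`spec` required when passing raw chains",
                          call. = FALSE)
  nms <- dimnames(chains)[[3]]
  j <- match(spec$mu_names, nms)
  if (anyNA(j))
    stop("chains are missing group mean(s): ",
         paste(spec$mu_names[is.na(j)], collapse = ", "), call. = FALSE)
  draws <- as.vector(chains[, , j[1]] - chains[, , j[2]])
  ci <- if (hdi) hdi_interval(draws, level) else
    unname(quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
  plaus <- if (spec$target == "t0") "negative" else "positive"
  mass <- if (plaus == "negative") mean(draws < 0) else mean(draws > 0)
  structure(list(target = spec$target, draws = draws, mean = mean(draws),
                 ci = ci, level = level, plausible_direction = plaus,
                 plausible_mass = mass),
            class = "ddm_group_difference")
}

hdi_interval <- function(draws, level) {
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, floor(level * n))
  w <- x[(m:n)] - x[seq_len(n - m + 1L)]
  i <- which.min(w)
  c(x[i], x[i + m - 1L])
}

#' @export
print.ddm_group_difference <- function(x, ...) {
  cat(sprintf(
    "<group_difference> %s (cued - miscued): mean %.4f, %g%% CI [%.4f, %.4f]; %.1f%% of mass in the plausible (%s) direction\n",
    x$target, x$mean, 100 * x$level, x$ci[1], x$ci[2],
    100 * x$plausible_mass, x$plausible_direction))
  invisible(x)
}
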