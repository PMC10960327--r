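test_that("participant log-likelihood equals the sum of per-trial log densities", {
  tb <- quick_participant("t0", list(delta_t0 = 0.05), 30, seed = 9)$trials
  spec <- model_catalogue()$t0
  fv <- c(v = 2.5, a = 1.1, t0 = 0.25, delta_t0 = 0.04)
  got <- participant_log_likelihood(tb, spec, fv)
  # independent R-level path: expand, pick condition parameters per trial
  pp <- expand_parameters(spec, fv)
  expected <- sum(vapply(seq_len(nrow(tb)), function(i) {
    p <- if (tb$condition[i] == "cued") pp$cued else pp$miscued
    b <- if (tb$correct[i]) "upper" else "lower"
    trial_log_density(tb$rt_ms[i] / 1000, b, p)
  }, numeric(1)))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("log-likelihood is order-invariant and -Inf outside the prior support", {
  tb <- quick_participant("simple", n_per_condition = 40, seed = 2)$trials
  spec <- model_catalogue()$simple
  fv <- c(v = 3, a = 1.2, t0 = 0.28)
  shuffled <- tb[rev(seq_len(nrow(tb))), ]
  expect_equal(participant_log_likelihood(tb, spec, fv),
               participant_log_likelihood(shuffled, spec, fv))
  expect_identical(participant_log_likelihood(tb, spec,
                                              c(v = 11, a = 1.2, t0 = 0.28)),
                   -Inf)
})

test_that("the likelihood prefers the generating parameters over a distorted drift", {
  spec <- model_catalogue()$simple
  truth <- c(v = 3, a = 1.2, t0 = 0.3)
  wins <- 0
  for (seed in 1:10) {
    tb <- quick_participant("simple", n_per_condition = 100, seed = seed)$trials
    d <- participant_log_likelihood(tb, spec, truth) -
      participant_log_likelihood(tb, spec, c(v = 6, a = 1.2, t0 = 0.3))
    wins <- wins + (d > 0)
  }
  expect_gte(wins, 9)
})

test_that("sampler configuration validates its invariants", {
  expect_error(mcmc_config(iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(iterations = 0, burn_in = -1), "burn_in|invalid")
  cfg <- reduced_mcmc_config(seed = 3)
  expect_equal(cfg$iterations, 1000)
  expect_equal(cfg$max_chains, 12)
})

test_that("DE-MCMC is bitwise reproducible under a seed", {
  tb <- quick_participant("simple", n_per_condition = 60, seed = 4)$trials
  spec <- model_catalogue()$simple
  cfg <- mcmc_config(iterations = 120, burn_in = 60, seed = 99,
                     min_trials = 10)
  f1 <- fit_participant(tb, spec, config = cfg)
  f2 <- fit_participant(tb, spec, config = cfg)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$log_lik, f2$log_lik)
  expect_identical(f1$ml_params, f2$ml_params)
})

test_that("maximum-likelihood extraction takes the argmax with chain-major ties", {
  samples <- array(0, c(3, 2, 1), dimnames = list(NULL, NULL, "v"))
  samples[, 1, 1] <- c(10, 20, 30)
  samples[, 2, 1] <- c(40, 50, 60)
  ll <- matrix(c(-10, -5, -8, -9, -5, -7), nrow = 3)
  got <- extract_max_likelihood(list(samples = samples, log_lik = ll))
  # two ties at -5; first in (chain, iteration) order is chain 1, iter 2
  expect_equal(got$max_log_lik, -5)
  expect_equal(unname(got$ml_params), 20)
  one <- extract_max_likelihood(list(
    samples = array(7, c(1, 1, 1), dimnames = list(NULL, NULL, "v")),
    log_lik = matrix(-3)))
  expect_equal(unname(one$ml_params), 7)
  expect_error(extract_max_likelihood(list(samples = NULL,
                                           log_lik = numeric(0))), "empty")
})

test_that("a fit recovers a planted non-decision-time gap", {
  gp <- generate_participant("t0", effects = list(delta_t0 = 0.06),
                             n_per_condition = 500, seed = 31, dt = 2e-4)
  fit <- suppressWarnings(
    fit_participant(gp$trials, model_catalogue()$t0,
                    config = reduced_mcmc_config(seed = 8)))
  post_mean <- mean(fit$samples[, , "delta_t0"])
  expect_lt(abs(post_mean - 0.06), 0.02)
  # the likelihood at the posterior mean is attainable by the retained
  # argmax up to sampling resolution (0.5 log-units at reduced settings)
  expect_gte(fit$max_log_lik + 0.5,
             participant_log_likelihood(gp$trials, model_catalogue()$t0,
                                        colMeans(apply(fit$samples, 3, c))))
  expect_lt(max(fit$diagnostics$rhat), 1.2)
  expect_equal(fit$bic,
               fit$k * log(fit$n_trials) - 2 * fit$max_log_lik)
})

test_that("fit summaries serialise to JSON with the run configuration", {
  tb <- quick_participant("simple", n_per_condition = 60, seed = 4)$trials
  fit <- fit_participant(tb, model_catalogue()$simple,
                         config = mcmc_config(iterations = 120,
                                              burn_in = 60, seed = 2,
                                              min_trials = 10))
  path <- tempfile(fileext = ".json")
  write_fit_result(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$model, "simple")
  expect_equal(back$max_log_lik, fit$max_log_lik)
  expect_equal(back$config$seed, 2)
  expect_null(back$samples)
})

test_that("too few trials triggers the reliability warning", {
  tb <- quick_participant("simple", n_per_condition = 10, seed = 6)$trials
  expect_warning(fit_participant(tb, model_catalogue()$simple,
                                 config = mcmc_config(iterations = 60,
                                                      burn_in = 30,
                                                      seed = 1)),
                 "unreliable")
})
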