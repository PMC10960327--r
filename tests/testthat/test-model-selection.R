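test_that("information criteria implement the closed forms", {
  ic <- information_criteria(100, k = 4, n = 240)
  expect_equal(ic$bic, -178.0774, tolerance = 1e-4)
  expect_equal(ic$aic, -192)
  expect_error(information_criteria(10, k = 0, n = 100), "k")
  expect_error(information_criteria(10, k = 2, n = 0), "n")
  # BIC - AIC = k (ln n - 2), positive beyond n = e^2
  for (n in c(5, 10, 240)) {
    ic <- information_criteria(-50, k = 3, n = n)
    expect_equal(ic$bic - ic$aic, 3 * (log(n) - 2))
  }
})

test_that("Akaike weights normalise, match the two-model case, and shift-invariantly rank", {
  eq <- model_weights(setNames(rep(4.2, 8), names(model_catalogue())))
  expect_equal(unname(eq), rep(1 / 8, 8))
  two <- model_weights(c(m1 = 10, m2 = 12))
  expect_equal(unname(two), c(0.7310586, 0.2689414), tolerance = 1e-6)
  set.seed(5)
  for (i in 1:25) {
    sc <- setNames(rnorm(8, sd = 20), names(model_catalogue()))
    w <- model_weights(sc)
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_identical(which.max(w), which.min(sc))
    expect_equal(w, model_weights(sc + 1234), tolerance = 1e-12)
  }
  expect_error(model_weights(c(good = 1, bad = Inf)), "bad")
})

test_that("inclusion probabilities use the published membership sets", {
  nm <- names(model_catalogue())
  unif <- setNames(rep(1 / 8, 8), nm)
  expect_equal(inclusion_probabilities(unif),
               c(t0 = 0.5, z = 0.5, v = 0.5))
  onehot <- function(m) setNames(as.numeric(nm == m), nm)
  expect_equal(inclusion_probabilities(onehot("complex")),
               c(t0 = 1, z = 1, v = 1))
  expect_equal(inclusion_probabilities(onehot("t0-z")),
               c(t0 = 1, z = 1, v = 0))
  # drift membership: {v, t0-v, z-v, complex} vs the rest
  v_set <- c("v", "t0-v", "z-v", "complex")
  w <- setNames(runif(8), nm); w <- w / sum(w)
  expect_equal(inclusion_probabilities(w)[["v"]], sum(w[v_set]))
  # each parameter splits the catalogue 4 vs 4
  cat_ <- model_catalogue()
  for (flag in c("t0_varies", "z_varies", "v_varies"))
    expect_equal(sum(vapply(cat_, `[[`, logical(1), flag)), 4)
  expect_error(inclusion_probabilities(unif[-1]), "catalogue")
})

test_that("inclusion and exclusion masses always sum to one", {
  set.seed(11)
  nm <- names(model_catalogue())
  cat_ <- model_catalogue()
  flags <- c(t0 = "t0_varies", z = "z_varies", v = "v_varies")
  for (i in 1:20) {
    w <- model_weights(setNames(rnorm(8, sd = 10), nm))
    inc <- inclusion_probabilities(w)
    for (th in names(flags)) {
      excl_set <- nm[!vapply(cat_, `[[`, logical(1), flags[[th]])]
      expect_lt(abs(inc[[th]] + sum(w[excl_set]) - 1), 1e-12)
    }
    expect_true(all(inc >= 0 & inc <= 1))
  }
})

test_that("cohort summary collapses participant rows arithmetically", {
  nm <- names(model_catalogue())
  row_for <- function(pid, best) {
    bic <- setNames(rep(0, 8), nm); bic[best] <- -20
    data.frame(participant = pid, model = nm,
               k = c(3, 4, 4, 4, 5, 5, 5, 6), n_trials = 100,
               max_log_lik = 0, bic = bic, aic = bic,
               weight_bic = unname(model_weights(bic)),
               weight_aic = unname(model_weights(bic)), max_rhat = 1,
               row.names = NULL)
  }
  sel1 <- structure(list(table = row_for("p1", "t0"), models = nm),
                    class = "ddm_selection")
  co1 <- cohort_summary(sel1)
  expect_equal(co1$prob_bic_pct, 100 * sel1$table$weight_bic)
  expect_equal(co1$n_best_bic[co1$model == "t0"], 1)
  sel2 <- structure(list(table = rbind(row_for("p1", "t0"),
                                       row_for("p2", "z")), models = nm),
                    class = "ddm_selection")
  co2 <- cohort_summary(sel2)
  expect_equal(co2$n_best_bic[co2$model %in% c("t0", "z")], c(1, 1))
  expect_equal(co2$prob_bic_pct,
               100 * (row_for("p1", "t0")$weight_bic +
                        row_for("p2", "z")$weight_bic) / 2)
})

test_that("best-model ties break toward fewer parameters then name", {
  sc <- setNames(c(5, 5, 5, 5, 5, 5, 5, 5), names(model_catalogue()))
  expect_identical(gazecue:::best_model(sc, c(3, 4, 4, 4, 5, 5, 5, 6)),
                   "simple")
  sc2 <- sc; sc2[c("z", "t0")] <- 1
  expect_identical(gazecue:::best_model(sc2, c(3, 4, 4, 4, 5, 5, 5, 6)),
                   "t0") # equal k = 4: lexicographic
})

test_that("the magnitude correlation matches a textbook hand computation", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  got <- magnitude_weight_correlation(x, y)
  expect_equal(got$r, 0.8219949, tolerance = 1e-6)
  anti <- magnitude_weight_correlation(c(1, 2, 3, 4), c(8, 6, 4, 2))
  expect_equal(anti$r, -1)
  expect_error(magnitude_weight_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(magnitude_weight_correlation(1:2, 2:3), "3 pairs")
})

test_that("the correlation Bayes factor favours strong dependence over nulls", {
  set.seed(21)
  x <- rnorm(41); y <- 0.8 * x + rnorm(41, sd = 0.4)
  strong <- magnitude_weight_correlation(x, y)
  expect_gt(strong$bf10, 10)
  # independent vectors rarely reach |r| > 0.5 at n = 41
  hits <- 0
  for (i in 1:300) {
    r <- cor(rnorm(41), rnorm(41))
    hits <- hits + (abs(r) >= 0.5)
  }
  expect_lte(hits / 300, 0.05)
  null <- magnitude_weight_correlation(rnorm(41), rnorm(41))
  expect_lt(null$bf10, 3)
})
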