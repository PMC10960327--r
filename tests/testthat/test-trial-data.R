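test_that("a delimited fixture round-trips through the loader", {
  df <- data.frame(subj = c("a", "a", "b", "b"),
                   validity = c("cued", "miscued", "cued", "miscued"),
                   side = c("left", "right", "left", "right"),
                   acc = c(1, 1, 0, 1), rt = c(310, 340, 305, 332))
  path <- write_fixture_csv(df)
  tb <- read_trial_table(path,
                         column_map = c(participant = "subj",
                                        condition = "validity",
                                        response_side = "side",
                                        correct = "acc", rt_ms = "rt"))
  expect_s3_class(tb, "trial_table")
  expect_equal(nrow(tb), 4)
  expect_identical(tb$correct, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(tb$rt_ms, df$rt)
})

test_that("an adapter keeps only the gaze-cue rows of a mixed-cue fixture", {
  df <- data.frame(subj = "a", cue_type = c("gaze", "arrow", "line", "gaze"),
                   validity = c("cued", "cued", "miscued", "miscued"),
                   acc = 1, rt = c(300, 310, 320, 330))
  path <- write_fixture_csv(df)
  tb <- read_trial_table(path,
                         column_map = c(participant = "subj",
                                        condition = "validity",
                                        correct = "acc", rt_ms = "rt"),
                         adapter = function(d) d[d$cue_type == "gaze", ])
  expect_equal(nrow(tb), 2)
  expect_equal(tb$rt_ms, c(300, 330))
})

test_that("unmapped condition labels are dropped with a message, not silently", {
  df <- data.frame(subj = "a",
                   validity = c("cued", "forward", "miscued"),
                   acc = 1, rt = c(300, 310, 320))
  path <- write_fixture_csv(df)
  expect_message(
    tb <- read_trial_table(path,
                           column_map = c(participant = "subj",
                                          condition = "validity",
                                          correct = "acc", rt_ms = "rt")),
    "not mapped")
  expect_equal(nrow(tb), 2)
})

test_that("loader errors name missing columns and bad response times by row", {
  df <- data.frame(subj = "a", validity = "cued", acc = 1, rt = 300)
  path <- write_fixture_csv(df)
  expect_error(read_trial_table(path,
                                column_map = c(participant = "subj",
                                               condition = "validity",
                                               correct = "acc",
                                               rt_ms = "latency")),
               "latency")
  df2 <- data.frame(subj = "a", validity = c("cued", "miscued"),
                    acc = 1, rt = c("300", "fast"))
  path2 <- write_fixture_csv(df2)
  expect_error(read_trial_table(path2,
                                column_map = c(participant = "subj",
                                               condition = "validity",
                                               correct = "acc",
                                               rt_ms = "rt")),
               "row")
})

test_that("dataset adapter presets wire into the loader", {
  df <- data.frame(participant = "a",
                   cue_type = c("gaze", "arrow", "gaze"),
                   condition = c("cued", "cued", "miscued"),
                   correct = 1, rt_ms = c(300, 310, 330))
  path <- write_fixture_csv(df)
  tb <- do.call(read_trial_table, c(list(path = path),
                                    dataset_adapters("ds1")))
  expect_equal(nrow(tb), 2) # arrow row filtered by the preset adapter
  ad2 <- dataset_adapters("ds2")
  expect_false("forward" %in% ad2$condition_map)
})

test_that("the RT window keeps exactly 100 and 5000 ms and drops outside", {
  tb <- trial_table(data.frame(participant = "a", condition = "cued",
                               correct = TRUE,
                               rt_ms = c(99, 100, 5000, 5001)))
  out <- apply_exclusions(tb)
  expect_equal(sort(out$trials$rt_ms), c(100, 5000))
  expect_equal(out$report$n_trials_rt_excluded, 2)
})

test_that("participants below 80% accuracy are removed entirely and reported", {
  set.seed(1)
  tb <- trial_table(data.frame(
    participant = rep(c("good", "bad"), each = 100),
    condition = rep(c("cued", "miscued"), 100),
    correct = c(rep(TRUE, 95), rep(FALSE, 5),
                rep(TRUE, 79), rep(FALSE, 21)),
    rt_ms = 400))
  out <- apply_exclusions(tb)
  expect_identical(out$report$participants_excluded_accuracy, "bad")
  expect_false("bad" %in% out$trials$participant)
  expect_equal(out$report$n_trials_out, 100)
  expect_error(apply_exclusions(out$trials[0, ]), "empty")
})

test_that("exclusions are idempotent and conserve trial counts", {
  set.seed(7)
  tb <- trial_table(data.frame(
    participant = sample(c("a", "b", "c"), 400, TRUE),
    condition = sample(c("cued", "miscued"), 400, TRUE),
    correct = runif(400) < 0.9,
    rt_ms = exp(rnorm(400, log(400), 1))))
  once <- apply_exclusions(tb)
  twice <- apply_exclusions(once$trials)
  expect_equal(as.data.frame(twice$trials), as.data.frame(once$trials))
  expect_equal(twice$report$n_trials_rt_excluded, 0)
  r <- once$report
  expect_equal(r$n_trials_out,
               r$n_trials_in - r$n_trials_rt_excluded -
                 r$n_trials_accuracy_excluded)
})

test_that("cueing magnitudes do the arithmetic and count positive effects", {
  tb <- toy_trials()
  cs <- cueing_magnitudes(tb)
  expect_equal(cs$magnitude_ms[cs$participant == "s1"], 30)
  expect_equal(cs$magnitude_ms[cs$participant == "s2"], 30)
  tb2 <- trial_table(data.frame(
    participant = rep(c("p1", "p2", "p3"), each = 2),
    condition = rep(c("cued", "miscued"), 3),
    correct = TRUE,
    rt_ms = c(300, 310, 305, 300, 300, 325)))
  cs2 <- cueing_magnitudes(tb2)
  expect_equal(sort(cs2$magnitude_ms), c(-5, 10, 25))
  expect_equal(attr(cs2, "mean_ms"), 10)
  expect_equal(attr(cs2, "n_positive"), 2)
})

test_that("magnitudes are invariant to trial order and participant relabelling", {
  set.seed(3)
  tb <- quick_participant("t0", list(delta_t0 = 0.05), 80, seed = 5)$trials
  tb2 <- quick_participant("t0", list(delta_t0 = 0.05), 80, seed = 6)$trials
  tb2$participant <- "other"
  both <- trial_table(rbind(as.data.frame(tb), as.data.frame(tb2)))
  shuffled <- both[sample(nrow(both)), ]
  a <- cueing_magnitudes(both)
  b <- cueing_magnitudes(shuffled)
  expect_equal(sort(a$magnitude_ms), sort(b$magnitude_ms))
  expect_equal(attr(a, "mean_ms"), attr(b, "mean_ms"))
})

test_that("participants missing a condition are warned about and omitted", {
  tb <- trial_table(data.frame(
    participant = c("a", "a", "b"), condition = c("cued", "miscued", "cued"),
    correct = TRUE, rt_ms = c(300, 320, 500)))
  expect_warning(cs <- cueing_magnitudes(tb), "b")
  expect_equal(nrow(cs), 1)
})

test_that("standardised mean change matches a hand-computed oracle", {
  cued <- c(300, 310, 295, 320, 305)
  miscued <- c(312, 315, 300, 335, 310)
  # by hand: d = (12, 5, 5, 15, 5), mean 8.4, sd 4.774935,
  # correction 1 - 3/15 = 0.8 -> 0.8 * 8.4 / 4.774935
  expect_equal(standardized_mean_change(cued, miscued), 1.407349,
               tolerance = 1e-6)
  expect_equal(standardized_mean_change(cued, miscued, method = "raw"),
               0.6987123, tolerance = 1e-6)
  expect_equal(standardized_mean_change(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_gt(standardized_mean_change(cued, miscued), 0)
  expect_lt(standardized_mean_change(miscued, cued), 0)
  expect_error(standardized_mean_change(1, 2), "2 participants")
})
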