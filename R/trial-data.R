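#' Construct and validate a trial table
#'
#' A long-format table of two-choice localisation trials: one row per
#' trial with participant id, cue validity condition (`cued`/`miscued`),
#' response side, correctness and response time in milliseconds.
#'
#' @param df a data.frame with columns `participant`, `condition`,
#'   `correct`, `rt_ms` and optionally `response_side`.
#' @return the validated table with class `trial_table`.
#' @export
trial_table <- function(df) {
  req <- c("participant", "condition", "correct", "rt_ms")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(df$condition %in% c("cued", "miscued")))
    stop("`condition` must be 'cued' or 'miscued'", call. = FALSE)
  if (!is.logical(df$correct)) {
    if (all(df$correct %in% c(0, 1))) df$correct <- df$correct == 1
    else stop("`correct` must be logical or 0/1", call. = FALSE)
  }
  if (!is.numeric(df$rt_ms) || any(!is.finite(df$rt_ms)) || any(df$rt_ms <= 0))
    stop("`rt_ms` must be positive finite numeric", call. = FALSE)
  df$condition <- factor(df$condition, levels = c("cued", "miscued"))
  class(df) <- unique(c("trial_table", class(df)))
  df
}

#' Read a delimited trial table
#'
#' Reads comma- or tab-separated text with a header and maps source
#' columns onto the canonical trial fields. Rows failing to parse are
#' reported by index, never silently dropped. A per-dataset `adapter`
#' function can recode or filter the raw table before mapping (e.g. keep
#' only gaze cues, drop forward-gaze trials).
#'
#' @param path file path.
#' @param column_map named list/character vector mapping canonical names
#'   (`participant`, `condition`, `correct`, `rt_ms`, optionally
#'   `response_side`) to source column names.
#' @param condition_map named character vector recoding source condition
#'   labels to `cued`/`miscued`; source labels absent from it are dropped
#'   (with a message) so non-directional cue types can be excluded.
#' @param adapter optional `function(raw_df) raw_df` applied first.
#' @param sep field separator; `NULL` auto-detects comma vs tab.
#' @return a [trial_table()].
#' @export
read_trial_table <- function(path,
                             column_map = c(participant = "participant",
                                            condition = "condition",
                                            response_side = "response_side",
                                            correct = "correct",
                                            rt_ms = "rt_ms"),
                             condition_map = c(cued = "cued",
                                               miscued = "miscued"),
                             adapter = NULL, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(adapter)) raw <- adapter(raw)
  column_map <- unlist(column_map)
  req <- c("participant", "condition", "correct", "rt_ms")
  miss <- setdiff(req, names(column_map))
  if (length(miss))
    stop("column_map must name: ", paste(miss, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent))
    stop("input is missing mapped column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  df <- data.frame(participant = as.character(raw[[column_map[["participant"]]]]),
                   condition = as.character(raw[[column_map[["condition"]]]]),
                   correct = raw[[column_map[["correct"]]]],
                   stringsAsFactors = FALSE)
  if ("response_side" %in% names(column_map) &&
      column_map[["response_side"]] %in% names(raw))
    df$response_side <- as.character(raw[[column_map[["response_side"]]]])
  rt_raw <- raw[[column_map[["rt_ms"]]]]
  rt <- suppressWarnings(as.numeric(rt_raw))
  bad <- which(is.na(rt) & !is.na(rt_raw))
  if (length(bad))
    stop("non-numeric response time in row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  df$rt_ms <- rt
  # recode / filter conditions
  keep <- df$condition %in% unname(condition_map)
  if (!all(keep))
    message("dropping ", sum(!keep),
            " trial(s) whose condition is not mapped to cued/miscued")
  df <- df[keep, , drop = FALSE]
  lut <- setNames(names(condition_map), unname(condition_map))
  df$condition <- unname(lut[df$condition])
  trial_table(df)
}

#' Adapter presets for the three published data-set layouts
#'
#' Ready-made `read_trial_table()` argument sets for the table layouts of
#' the three localisation gaze-cueing deposits this pipeline was built
#' around: `"ds1"` (three cue types; only gaze cues analysed), `"ds2"`
#' (three validity levels; non-directional forward-gaze trials dropped)
#' and `"ds3"` (plain cued/miscued). Source column names differ between
#' deposits and re-hosting copies, so each preset exposes its
#' `column_map` for overriding.
#'
#' @param name preset name.
#' @return a list of `read_trial_table()` arguments (`column_map`,
#'   `condition_map`, and for `"ds1"` an `adapter`).
#' @examples
#' ad <- dataset_adapters("ds2")
#' names(ad)
#' @export
dataset_adapters <- function(name = c("ds1", "ds2", "ds3")) {
  name <- match.arg(name)
  base_map <- c(participant = "participant", condition = "condition",
                correct = "correct", rt_ms = "rt_ms")
  switch(name,
         ds1 = list(column_map = base_map,
                    condition_map = c(cued = "cued", miscued = "miscued"),
                    adapter = function(d) {
                      if ("cue_type" %in% names(d)) d[d$cue_type == "gaze", ]
                      else d
                    }),
         ds2 = list(column_map = base_map,
                    # forward-gaze rows carry a third label and are dropped
                    condition_map = c(cued = "cued", miscued = "miscued")),
         ds3 = list(column_map = base_map,
                    condition_map = c(cued = "cued", miscued = "miscued")))
}

#' Apply the response-time and accuracy exclusion rules
#'
#' Removes trials with response time below `rt_min_ms` or above
#' `rt_max_ms` (strict inequalities: exactly 100 and 5000 ms are kept),
#' then removes entirely any participant whose accuracy over their
#' remaining trials is below `min_accuracy`.
#'
#' @param table a [trial_table()].
#' @param rt_min_ms,rt_max_ms response-time window in ms.
#' @param min_accuracy minimum proportion correct.
#' @return `list(trials = , report = )` where `report` is an
#'   `exclusion_report` tallying both filters.
#' @export
apply_exclusions <- function(table, rt_min_ms = 100, rt_max_ms = 5000,
                             min_accuracy = 0.80) {
  stopifnot(inherits(table, "trial_table"))
  if (nrow(table) == 0L) stop("empty trial table", call. = FALSE)
  n_in <- nrow(table)
  ok_rt <- table$rt_ms >= rt_min_ms & table$rt_ms <= rt_max_ms
  n_rt_excl <- sum(!ok_rt)
  kept <- table[ok_rt, , drop = FALSE]
  acc <- tapply(kept$correct, kept$participant, mean)
  bad_p <- names(acc)[acc < min_accuracy]
  n_acc_trials <- sum(kept$participant %in% bad_p)
  kept <- kept[!(kept$participant %in% bad_p), , drop = FALSE]
  report <- structure(list(n_trials_in = n_in,
                           n_trials_rt_excluded = n_rt_excl,
                           participants_excluded_accuracy = bad_p,
                           n_trials_accuracy_excluded = n_acc_trials,
                           n_trials_out = nrow(kept)),
                      class = "exclusion_report")
  stopifnot(report$n_trials_out ==
              report$n_trials_in - report$n_trials_rt_excluded -
              report$n_trials_accuracy_excluded)
  list(trials = kept, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf(
    "<exclusion_report> %d trials in; %d removed by RT window; %d removed with %d accuracy-excluded participant(s); %d trials analysed\n",
    x$n_trials_in, x$n_trials_rt_excluded, x$n_trials_accuracy_excluded,
    length(x$participants_excluded_accuracy), x$n_trials_out))
  invisible(x)
}

#' Per-participant cueing magnitudes and cohort summary
#'
#' The cueing magnitude is each participant's mean miscued RT minus mean
#' cued RT in ms; positive values mean faster responses at the cued
#' location. The cohort summary carries the mean and SD of the
#' magnitudes, the count of participants with a positive magnitude, and
#' the standardised mean change.
#'
#' @param table a [trial_table()] (normally after [apply_exclusions()]).
#' @param correct_only restrict RT means to correct trials (default TRUE;
#'   with accuracies in the 94-99% range this moves means by < 1 ms).
#' @param smc_method passed to [standardized_mean_change()].
#' @return a `cueing_summary`: data.frame of per-participant condition
#'   means and magnitudes, with cohort statistics as attributes
#'   `mean_ms`, `sd_ms`, `smc`, `n_positive`.
#' @export
cueing_magnitudes <- function(table, correct_only = TRUE,
                              smc_method = c("change", "raw")) {
  stopifnot(inherits(table, "trial_table"))
  smc_method <- match.arg(smc_method)
  tbl <- if (correct_only) table[table$correct, , drop = FALSE] else table
  m <- aggregate(rt_ms ~ participant + condition, data = tbl, FUN = mean)
  wide <- merge(m[m$condition == "cued", c("participant", "rt_ms")],
                m[m$condition == "miscued", c("participant", "rt_ms")],
                by = "participant", all = TRUE,
                suffixes = c("_cued", "_miscued"))
  incomplete <- wide$participant[is.na(wide$rt_ms_cued) |
                                   is.na(wide$rt_ms_miscued)]
  if (length(incomplete)) {
    warning("participant(s) missing a condition, omitted from cohort ",
            "statistics: ", paste(incomplete, collapse = ", "),
            call. = FALSE)
    wide <- wide[!(wide$participant %in% incomplete), , drop = FALSE]
  }
  wide$magnitude_ms <- wide$rt_ms_miscued - wide$rt_ms_cued
  smc <- if (nrow(wide) >= 2L)
    tryCatch(standardized_mean_change(wide$rt_ms_cued, wide$rt_ms_miscued,
                                      method = smc_method),
             error = function(e) NA_real_) else NA_real_
  structure(wide,
            mean_ms = mean(wide$magnitude_ms),
            sd_ms = sd(wide$magnitude_ms),
            smc = unname(smc),
            smc_method = smc_method,
            n_positive = sum(wide$magnitude_ms > 0),
            class = c("cueing_summary", "data.frame"))
}

#' @export
print.cueing_summary <- function(x, ...) {
  cat(sprintf(
    "<cueing_summary> %d participants; mean magnitude %.1f ms (SD %.1f); %d/%d positive; SMC (%s) = %.3f\n",
    nrow(x), attr(x, "mean_ms"), attr(x, "sd_ms"), attr(x, "n_positive"),
    nrow(x), attr(x, "smc_method"), attr(x, "smc")))
  invisible(as.data.frame(x))
}

#' Standardised mean change for paired condition means
#'
#' Effect size for the within-participant cued-vs-miscued difference.
#' The default `"change"` variant standardises the mean change by the SD
#' of the per-participant change scores, with the small-sample bias
#' correction `1 - 3 / (4(n - 1) - 1)`. The `"raw"` variant standardises
#' by the SD of the cued-condition means instead (same correction).
#'
#' @param cued,miscued per-participant mean RTs (paired vectors).
#' @param method `"change"` or `"raw"`.
#' @return the (bias-corrected) standardised mean change; its sign equals
#'   the sign of the mean magnitude.
#' @export
standardized_mean_change <- function(cued, miscued,
                                     method = c("change", "raw")) {
  method <- match.arg(method)
  if (length(cued) != length(miscued))
    stop("`cued` and `miscued` must be paired vectors", call. = FALSE)
  n <- length(cued)
  if (n < 2L) stop("need at least 2 participants", call. = FALSE)
  change <- miscued - cued
  denom <- if (method == "change") sd(change) else sd(cued)
  if (denom == 0) {
    if (all(change == 0)) return(0)
    stop("zero standardiser SD", call. = FALSE)
  }
  j <- 1 - 3 / (4 * (n - 1) - 1)
  j * mean(change) / denom
}
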