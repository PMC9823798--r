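#' Short-term analysis design around the drug timestamp
#'
#' Because the exact administration time is uncertain at the bedside, a
#' 1-minute gap is left on each side of the noted timestamp. The baseline
#' window is 12 min (extended from 10 min to buy headroom against baseline
#' artifacts), the post-drug window 10 min, and both are cut into 2.5-min
#' epochs.
#'
#' @param baseline_length Baseline window length, seconds.
#' @param post_length Post-drug window length, seconds.
#' @param gap Gap on each side of the drug timestamp, seconds.
#' @param epoch_length Epoch length, seconds.
#' @param anchor Epoch anchoring within each window (see [epoch_grid()]).
#' @return List of class `short_term_design`.
#' @export
short_term_design <- function(baseline_length = 720, post_length = 600,
                              gap = 60, epoch_length = 150,
                              anchor = "start") {
  stopifnot(baseline_length >= epoch_length, post_length >= epoch_length,
            gap > 0, epoch_length > 0)
  structure(list(baseline_length = baseline_length, post_length = post_length,
                 gap = gap, epoch_length = epoch_length, anchor = anchor),
            class = "short_term_design")
}

#' Baseline and post-drug analysis windows
#'
#' With the defaults and the half-open time convention:
#' baseline `[drug - 13 min, drug - 1 min)`, post `[drug + 1 min,
#' drug + 11 min)`, each divided into consecutive complete 2.5-min epochs
#' anchored at the window start (incomplete remainders dropped).
#'
#' @param drug_time Drug timestamp, seconds from recording start.
#' @param design A [short_term_design()].
#' @param rec_duration Optional recording duration for a coverage check.
#' @return List with `baseline`, `post` (each `c(start, end)`),
#'   `baseline_epochs`, `post_epochs` (epoch grids).
#' @export
short_term_windows <- function(drug_time, design = short_term_design(),
                               rec_duration = NULL) {
  b0 <- drug_time - design$gap - design$baseline_length
  b1 <- drug_time - design$gap
  p0 <- drug_time + design$gap
  p1 <- drug_time + design$gap + design$post_length
  if (!is.null(rec_duration) && (b0 < 0 || p1 > rec_duration))
    stop(sprintf("recording does not cover the analysis span [%g, %g) s", b0, p1))
  list(baseline = c(b0, b1), post = c(p0, p1),
       baseline_epochs = epoch_grid(b0, b1, design$epoch_length, design$anchor),
       post_epochs = epoch_grid(p0, p1, design$epoch_length, design$anchor))
}

#' Baseline/post medians and the delta value
#'
#' The per-side summary is the median over valid epoch values; the delta is
#' the post-drug median minus the baseline median (absolute change). A side
#' with no valid epochs makes the result missing.
#'
#' @param baseline_values,post_values Epoch feature values (may contain
#'   `NA`).
#' @param subject_id,feature,comparison Labels carried into the result row.
#' @return One-row data frame: `subject_id`, `feature`, `comparison`,
#'   `baseline_median`, `post_median`, `delta`, `n_epochs_baseline`,
#'   `n_epochs_post`.
#' @export
short_term_result <- function(baseline_values, post_values,
                              subject_id = "anon", feature = "rEEG",
                              comparison = "") {
  bv <- baseline_values[!is.na(baseline_values)]
  pv <- post_values[!is.na(post_values)]
  bm <- if (length(bv)) median(bv) else NA_real_
  pm <- if (length(pv)) median(pv) else NA_real_
  data.frame(subject_id = subject_id, feature = feature,
             comparison = comparison, baseline_median = bm, post_median = pm,
             delta = pm - bm, n_epochs_baseline = length(bv),
             n_epochs_post = length(pv))
}

#' Cohort long-term trend table
#'
#' Aligns per-subject epoch trends on time relative to the drug timestamp
#' and adds the cohort mean over subjects with non-missing values at each
#' epoch, driving the classic trend display (grey per-subject lines, red
#' cohort mean).
#'
#' @param subject_trends Named list (by subject) of data frames with columns
#'   `start` (epoch start, seconds relative to the drug timestamp) and
#'   `value`.
#' @return List with `subjects` (tidy long table: `subject_id`, `time`,
#'   `value`) and `cohort` (`time`, `mean`, `n`).
#' @export
long_term_trend <- function(subject_trends) {
  long <- do.call(rbind, lapply(names(subject_trends), function(id) {
    tr <- subject_trends[[id]]
    data.frame(subject_id = id, time = tr$start, value = tr$value)
  }))
  agg_mean <- tapply(long$value, long$time, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  agg_n <- tapply(!is.na(long$value), long$time, sum)
  times <- as.numeric(names(agg_mean))
  o <- order(times)
  list(subjects = long,
       cohort = data.frame(time = times[o], mean = as.numeric(agg_mean)[o],
                           n = as.integer(agg_n)[o]))
}
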