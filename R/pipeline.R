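#' Short-term feature analysis for one subject
#'
#' End-to-end per-recording pipeline: derivation construction, 0.2--35 Hz
#' zero-phase band-pass, automated artifact masking, rEEG / ASI epoch values
#' over the baseline and post-drug windows, and the per-side medians and
#' delta.
#'
#' @param rec An [eeg_recording()].
#' @param design A [short_term_design()].
#' @param plan A [default_comparison_plan()]; only its comparisons are
#'   computed.
#' @param features Character subset of `c("rEEG", "ASI")`.
#' @param band Band-pass edges, Hz.
#' @param asi_par An [asi_params()].
#' @param artifact_args Extra arguments passed to [detect_artifacts()].
#' @param pool_windows If `TRUE`, the rEEG side medians are taken over all
#'   valid 2-s window values in the window rather than over the per-epoch
#'   means (the default unit entering the medians is the epoch).
#' @return Data frame of [short_term_result()] rows (one per feature x
#'   comparison), or `NULL` with a message if the recording does not cover
#'   the analysis span.
#' @export
analyze_short_term <- function(rec, design = short_term_design(),
                               plan = default_comparison_plan(),
                               features = c("rEEG", "ASI"),
                               band = c(0.2, 35),
                               asi_par = asi_params(),
                               artifact_args = list(),
                               pool_windows = FALSE) {
  win <- tryCatch(short_term_windows(rec$drug_time, design, duration(rec)),
                  error = function(e) {
                    message(sprintf("subject %s excluded: %s",
                                    rec$subject_id, conditionMessage(e)))
                    NULL
                  })
  if (is.null(win)) return(NULL)

  pairs <- asi_pairs()
  needed <- character(0)
  if ("rEEG" %in% features) needed <- union(needed, plan$reeg)
  if ("ASI" %in% features)
    needed <- union(needed, unlist(pairs[plan$asi], use.names = FALSE))

  sig <- list(); mask <- list()
  for (d in needed) {
    pd <- prep_derivation(derive(rec, d), rec$sfreq, band, artifact_args)
    sig[[d]] <- pd$signal
    mask[[d]] <- pd$mask
  }

  rows <- list()
  if ("rEEG" %in% features) {
    for (d in plan$reeg) {
      tr <- reeg(sig[[d]], rec$sfreq, mask = mask[[d]])
      if (pool_windows) {
        grab <- function(iv) tr$value[tr$time >= iv[1] & tr$time < iv[2]]
        bvals <- grab(win$baseline); pvals <- grab(win$post)
      } else {
        bvals <- reeg_epochs(tr, win$baseline_epochs)$value
        pvals <- reeg_epochs(tr, win$post_epochs)$value
      }
      rows[[length(rows) + 1]] <-
        short_term_result(bvals, pvals, rec$subject_id, "rEEG", d)
    }
  }
  if ("ASI" %in% features) {
    for (pname in plan$asi) {
      pr <- pairs[[pname]]
      ep_asi <- function(grid) {
        vapply(seq_len(nrow(grid)), function(i)
          as.numeric(asi(sig[[pr[1]]], sig[[pr[2]]], rec$sfreq, asi_par,
                         mask_a = mask[[pr[1]]], mask_b = mask[[pr[2]]],
                         interval = c(grid$start[i], grid$end[i]))),
          numeric(1))
      }
      rows[[length(rows) + 1]] <-
        short_term_result(ep_asi(win$baseline_epochs), ep_asi(win$post_epochs),
                          rec$subject_id, "ASI", pname)
    }
  }
  do.call(rbind, rows)
}

# Band-pass one derivation and detect artifacts sharing a single forward
# FFT (the responses multiply, so this equals bandpass() followed by
# detect_artifacts() up to negligible edge effects).
prep_derivation <- function(raw, sfreq, band = c(0.2, 35),
                            artifact_args = list()) {
  prep <- fft_prep(raw, sfreq)
  rb <- function(f) butter_response2(f, band[1], "high", 2) *
    butter_response2(f, band[2], "low", 4)
  xb <- fft_apply(prep, rb)
  hf <- fft_apply(prep, function(f) rb(f) * butter_response2(f, 25, "high", 4))
  lf <- fft_apply(prep, function(f) rb(f) * butter_response2(f, 0.5, "low", 4))
  mask <- do.call(mask_from_components, c(list(xb, hf, lf, sfreq), artifact_args))
  list(signal = xb, mask = mask)
}

#' Short-term results for a whole cohort
#'
#' @param recordings List of [eeg_recording()]s, or a character vector of
#'   EDF paths (read one at a time to bound memory).
#' @param ... Passed to [analyze_short_term()].
#' @return Combined short-term result table.
#' @export
cohort_short_term <- function(recordings, ...) {
  get_rec <- function(r) {
    if (inherits(r, "eeg_recording")) r
    else read_recording(r)$recording
  }
  do.call(rbind, lapply(recordings, function(r) analyze_short_term(get_rec(r), ...)))
}

#' Long-term (multi-hour) cohort trend of one feature
#'
#' Divides each recording into consecutive 2.5-min epochs, computes the
#' feature per epoch (rEEG: mean of valid 2-s windows; ASI: one value per
#' epoch segment), aligns subjects on time relative to the drug timestamp
#' and averages across the cohort.
#'
#' @param recordings List of [eeg_recording()]s or EDF paths.
#' @param feature `"rEEG"` or `"ASI"`.
#' @param comparison rEEG derivation name or ASI pairing name.
#' @param epoch_length Epoch length, seconds.
#' @param band Band-pass edges, Hz.
#' @param asi_par An [asi_params()].
#' @param artifact_args Extra arguments for [detect_artifacts()].
#' @return A [long_term_trend()] result.
#' @export
cohort_long_term <- function(recordings, feature = "rEEG",
                             comparison = "P3-P4", epoch_length = 150,
                             band = c(0.2, 35), asi_par = asi_params(),
                             artifact_args = list()) {
  trends <- list()
  for (r in recordings) {
    rec <- if (inherits(r, "eeg_recording")) r else read_recording(r)$recording
    grid <- epoch_grid(0, duration(rec), epoch_length)
    if (feature == "rEEG") {
      x <- bandpass(derive(rec, comparison), rec$sfreq, band[1], band[2])
      m <- do.call(detect_artifacts, c(list(x, rec$sfreq), artifact_args))
      ep <- reeg_epochs(reeg(x, rec$sfreq, mask = m), grid)
    } else {
      pr <- asi_pairs()[[comparison]]
      masks <- list()
      sigs <- list()
      for (d in pr) {
        sigs[[d]] <- bandpass(derive(rec, d), rec$sfreq, band[1], band[2])
        masks[[d]] <- do.call(detect_artifacts,
                              c(list(sigs[[d]], rec$sfreq), artifact_args))
      }
      ep <- grid
      ep$value <- vapply(seq_len(nrow(grid)), function(i)
        as.numeric(asi(sigs[[pr[1]]], sigs[[pr[2]]], rec$sfreq, asi_par,
                       mask_a = masks[[pr[1]]], mask_b = masks[[pr[2]]],
                       interval = c(grid$start[i], grid$end[i]))),
        numeric(1))
    }
    ep$start <- ep$start - rec$drug_time
    trends[[rec$subject_id]] <- ep
  }
  long_term_trend(trends)
}
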