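# Squared-magnitude (double-pass) Butterworth response on a frequency grid:
# what forward-backward filtering of an order-`order` filter applies.
butter_response2 <- function(f, fc, type = c("low", "high"), order = 4) {
  type <- match.arg(type)
  if (type == "low") 1 / (1 + (f / fc)^(2 * order))
  else 1 / (1 + (fc / f)^(2 * order))  # f = 0 -> Inf -> response 0
}

# Forward FFT of a reflection-padded signal (pad_s seconds each side against
# circular wrap-around, zero-padded to a 2-3-5-smooth length), kept so that
# several zero-phase filters can share one forward transform.
fft_prep <- function(x, sfreq, pad_s = 10) {
  n <- length(x)
  pad <- min(n - 1, round(pad_s * sfreq))
  xp <- if (pad > 0) c(x[(pad + 1):2], x, x[(n - 1):(n - pad)]) else x
  m <- stats::nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, numeric(m - length(xp)))
  f <- (0:(m - 1)) * (sfreq / m)
  structure(list(fx = stats::fft(xp), f = pmin(f, sfreq - f), n = n,
                 pad = pad, m = m), class = "fft_prep")
}

fft_apply <- function(prep, response) {
  y <- Re(stats::fft(prep$fx * response(prep$f), inverse = TRUE)) / prep$m
  y[(prep$pad + 1):(prep$pad + prep$n)]
}

# Zero-phase filtering by multiplying the FFT with a real response.
fft_zerophase <- function(x, sfreq, response, pad_s = 10) {
  fft_apply(fft_prep(x, sfreq, pad_s), response)
}

#' Zero-phase band-pass filter
#'
#' The conventional clinical band for neonatal EEG is 0.2--35 Hz. Filtering
#' is zero-phase Butterworth -- the double-pass (squared-magnitude) response
#' of a 2nd-order high-pass at `low` and a 4th-order low-pass at `high` --
#' applied in the frequency domain on a reflection-padded signal, which is
#' fast on multi-hour recordings and leaves burst timing undistorted. One
#' octave outside the band the attenuation exceeds 20 dB (24 dB/octave on
#' each skirt).
#'
#' @param x Numeric signal, microvolts.
#' @param sfreq Sampling rate, Hz.
#' @param low,high Band edges, Hz; `0 < low < high < sfreq / 2` required.
#' @return Filtered signal, same length.
#' @export
bandpass <- function(x, sfreq, low = 0.2, high = 35) {
  if (!(low > 0 && low < high && high < sfreq / 2))
    stop(sprintf("invalid band [%g, %g] Hz at %g Hz sampling", low, high, sfreq))
  fft_zerophase(x, sfreq, function(f)
    butter_response2(f, low, "high", 2) * butter_response2(f, high, "low", 4))
}

#' Automated artifact detection on one derivation
#'
#' Three detectors over non-overlapping 2-second segments of a band-passed
#' signal, mirroring bedside quantitative-EEG practice:
#' \describe{
#'   \item{amplitude}{any sample exceeding `amp_max` (movement, electrode
#'     pops; cortical activity stays far below 500 uV);}
#'   \item{high_freq}{power above 25 Hz exceeding fraction `hf_ratio` of the
#'     segment's total in-band power (muscle, electrical noise);}
#'   \item{low_freq}{power below 0.5 Hz exceeding fraction `lf_ratio` of
#'     total power (sweating, respiration, electrode drift).}
#' }
#' Band components are extracted once by zero-phase filtering of the whole
#' signal (25 Hz high-pass and 0.5 Hz low-pass), which gives the per-segment
#' ratios sub-segment frequency resolution. A flagged segment invalidates
#' `guard` neighbouring segments on each side, since artifact onsets rarely
#' respect segment boundaries.
#'
#' @param x Band-passed signal, microvolts.
#' @param sfreq Sampling rate, Hz.
#' @param segment_length Segment length in seconds (2 s, the rEEG grid).
#' @param amp_max Absolute amplitude threshold, microvolts.
#' @param hf_ratio,lf_ratio Relative-power thresholds.
#' @param guard Number of neighbouring segments invalidated on each side of
#'   a flagged segment.
#' @return An `artifact_mask`: data frame with `segment_start` (s), `valid`,
#'   and logical detector columns `amplitude`, `high_freq`, `low_freq`.
#' @export
detect_artifacts <- function(x, sfreq, segment_length = 2, amp_max = 500,
                             hf_ratio = 0.5, lf_ratio = 0.9, guard = 1) {
  prep <- fft_prep(x, sfreq)
  hf <- fft_apply(prep, function(f) butter_response2(f, 25, "high", 4))
  lf <- fft_apply(prep, function(f) butter_response2(f, 0.5, "low", 4))
  mask_from_components(x, hf, lf, sfreq, segment_length, amp_max,
                       hf_ratio, lf_ratio, guard)
}

# Shared segment-flagging logic given the signal and its high/low frequency
# components.
mask_from_components <- function(x, hf, lf, sfreq, segment_length = 2,
                                 amp_max = 500, hf_ratio = 0.5,
                                 lf_ratio = 0.9, guard = 1) {
  n <- length(x)
  spseg <- round(segment_length * sfreq)
  nseg <- ceiling(n / spseg)
  seg_sum <- function(v) {
    # zero-pad the trailing partial segment; zeros do not affect sums
    colSums(matrix(c(v, numeric(nseg * spseg - n)), nrow = spseg))
  }
  p_tot <- seg_sum(x^2)
  p_hf <- seg_sum(hf^2)
  p_lf <- seg_sum(lf^2)
  amp_hit <- seg_sum(abs(x) > amp_max) > 0
  eps <- .Machine$double.eps
  hf_hit <- p_hf / pmax(p_tot, eps) > hf_ratio
  lf_hit <- p_lf / pmax(p_tot, eps) > lf_ratio

  flagged <- amp_hit | hf_hit | lf_hit
  invalid <- flagged
  if (guard > 0 && any(flagged)) {
    for (k in seq_len(guard)) {
      invalid <- invalid | c(rep(FALSE, k), head(flagged, -k)) |
        c(tail(flagged, -k), rep(FALSE, k))
    }
  }
  structure(data.frame(segment_start = (seq_len(nseg) - 1) * segment_length,
                       valid = !invalid, amplitude = amp_hit,
                       high_freq = hf_hit, low_freq = lf_hit),
            segment_length = segment_length, class = c("artifact_mask", "data.frame"))
}

#' Apply an artifact mask to a feature series on the 2-s grid
#'
#' Values whose window falls in an invalid segment become missing; retained
#' values are never altered. Downstream epoch summaries treat `NA` as
#' excluded and mark an epoch missing when fewer than half its segments are
#' valid.
#'
#' @param values Feature values, one per 2-s window.
#' @param mask An `artifact_mask` from [detect_artifacts()] (or a logical
#'   vector of the same length as `values`).
#' @return `values` with invalid entries set to `NA`.
#' @export
apply_mask <- function(values, mask) {
  valid <- if (is.data.frame(mask)) mask$valid else as.logical(mask)
  k <- min(length(values), length(valid))
  out <- values
  out[seq_len(k)][!valid[seq_len(k)]] <- NA
  if (length(valid) < length(values))
    out[(length(valid) + 1):length(values)] <- NA
  out
}

# Fraction of valid segments whose start falls in [t0, t1).
valid_fraction <- function(mask, t0, t1) {
  sel <- mask$segment_start >= t0 & mask$segment_start < t1
  if (!any(sel)) return(0)
  mean(mask$valid[sel])
}
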