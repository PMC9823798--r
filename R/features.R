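#' Range-EEG (rEEG): per-window peak-to-peak amplitude
#'
#' The rEEG value of a window is its maximum minus its minimum amplitude,
#' computed over non-overlapping 2-second windows. It is an objective
#' analogue of the aEEG amplitude trend and emphasises peak-to-peak
#' variation of the spontaneous signal. Only complete windows are used. A
#' companion running mean (centred over `smooth_k` windows, shrinking at the
#' edges) is provided for trend display; the raw per-window values feed all
#' epoch statistics.
#'
#' @param x Signal in microvolts.
#' @param sfreq Sampling rate, Hz.
#' @param window Window length, seconds.
#' @param mask Optional `artifact_mask` (or logical vector per window);
#'   invalid windows become `NA`.
#' @param smooth_k Running-mean span in windows (default 5, i.e. 10 s).
#' @return A data frame of class `feature_trend` with `time` (window start,
#'   s), `value` (uV) and `smooth` (running mean, uV).
#' @export
reeg <- function(x, sfreq, window = 2, mask = NULL, smooth_k = 5) {
  stopifnot(window > 0)
  spw <- round(window * sfreq)
  nwin <- floor(length(x) / spw)
  if (nwin < 1) {
    return(structure(data.frame(time = numeric(0), value = numeric(0),
                                smooth = numeric(0)),
                     feature = "rEEG", window = window,
                     class = c("feature_trend", "data.frame")))
  }
  m <- matrix(x[seq_len(nwin * spw)], nrow = spw)
  v <- apply(m, 2, max) - apply(m, 2, min)
  if (!is.null(mask)) v <- apply_mask(v, mask)
  structure(data.frame(time = (seq_len(nwin) - 1) * window, value = v,
                       smooth = running_mean(v, smooth_k)),
            feature = "rEEG", window = window,
            class = c("feature_trend", "data.frame"))
}

#' Centred running mean with shrinking edges
#'
#' @param v Numeric vector (may contain `NA`, which are ignored).
#' @param k Span in samples; the window shrinks near the edges.
#' @return Smoothed vector, same length.
#' @export
running_mean <- function(v, k = 5) {
  n <- length(v)
  if (n == 0) return(v)
  h <- floor(k / 2)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' ASI tuning parameters
#'
#' Constants of the Activation Synchrony Index computation:
#' envelope bin length (seconds of RMS amplitude), the number of quantile
#' quantization levels, the surrogate count for the time-shifted null, and
#' the minimum circular shift (seconds) separating surrogate alignments from
#' the true one.
#'
#' @param envelope_window Envelope RMS bin, seconds.
#' @param n_bins Quantization levels (quantile edges), `>= 2`.
#' @param n_surrogates Surrogate shifts, `>= 20`.
#' @param min_shift Minimum circular shift, seconds.
#' @param rng_seed Optional seed for the surrogate shifts.
#' @return List of class `asi_params`.
#' @export
asi_params <- function(envelope_window = 1, n_bins = 4, n_surrogates = 100,
                       min_shift = 30, rng_seed = NULL) {
  stopifnot(envelope_window > 0, n_bins >= 2, n_surrogates >= 20,
            min_shift > 0)
  structure(list(envelope_window = envelope_window, n_bins = n_bins,
                 n_surrogates = n_surrogates, min_shift = min_shift,
                 rng_seed = rng_seed), class = "asi_params")
}

# Plug-in (joint histogram) mutual information in bits between two integer
# code vectors; pairs with any NA are dropped.
mutual_information <- function(a, b, n_bins) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(NA_real_)
  counts <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins)
  p <- matrix(counts / length(a), n_bins, n_bins, byrow = TRUE)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

#' Activation Synchrony Index between two derivations
#'
#' Quantifies how often activity bursts co-occur between two signals,
#' normalized against a time-shifted surrogate null, so that independent
#' channels score about 0 regardless of their amplitudes:
#' \enumerate{
#'   \item amplitude envelopes = RMS in `envelope_window` bins over valid
#'     data;
#'   \item each envelope quantized into `n_bins` levels at its own empirical
#'     quantiles (making the index invariant to monotone amplitude
#'     rescaling of either channel);
#'   \item `I0` = mutual information (bits, plug-in estimate) between the
#'     paired quantized envelopes at zero lag;
#'   \item null: `n_surrogates` mutual informations after circular shifts of
#'     the second envelope by uniform random shifts in
#'     `[min_shift, T - min_shift]`;
#'   \item ASI = `log2(I0 / median(surrogate I))`, both floored at 1e-6 bits
#'     to avoid division blow-up.
#' }
#'
#' @param a,b Signals in microvolts covering the same span.
#' @param sfreq Sampling rate, Hz.
#' @param params An [asi_params()].
#' @param mask_a,mask_b Optional `artifact_mask`s for the two derivations;
#'   envelope bins touching an invalid 2-s segment in either channel are
#'   dropped.
#' @param interval Optional `c(t0, t1)` seconds restricting the computation
#'   to a segment (e.g. one 2.5-min epoch).
#' @return ASI value (unitless; larger = more burst co-occurrence, about 0
#'   under independence; `NA` if under half the segment is valid or an
#'   envelope has no variance). Attributes `mi0` and `surrogates` carry the
#'   zero-lag MI and the null sample.
#' @export
asi <- function(a, b, sfreq, params = asi_params(),
                mask_a = NULL, mask_b = NULL, interval = NULL) {
  stopifnot(length(a) == length(b))
  t_total <- length(a) / sfreq
  if (is.null(interval)) interval <- c(0, t_total)
  i0 <- floor(interval[1] * sfreq) + 1L
  i1 <- min(length(a), floor(interval[2] * sfreq))
  a <- a[i0:i1]; b <- b[i0:i1]
  ew <- params$envelope_window
  nb <- floor(length(a) / (ew * sfreq))
  if (nb < 4) return(NA_real_)
  seg_dur <- nb * ew
  if (params$min_shift >= seg_dur / 2)
    stop("min_shift must be below half the segment duration")

  spb <- round(ew * sfreq)
  env <- function(x) {
    m <- matrix(x[seq_len(nb * spb)], nrow = spb)
    sqrt(colMeans(m^2))
  }
  ea <- env(a); eb <- env(b)

  # bin validity from the 2-s artifact grid (absolute segment times)
  bin_start <- interval[1] + (seq_len(nb) - 1) * ew
  bin_ok <- function(mask) {
    if (is.null(mask)) return(rep(TRUE, nb))
    sl <- attr(mask, "segment_length") %||% 2
    seg <- floor(bin_start / sl) + 1L
    seg <- pmin(seg, nrow(mask))
    mask$valid[seg]
  }
  ok <- bin_ok(mask_a) & bin_ok(mask_b)
  if (mean(ok) < 0.5) return(NA_real_)
  ea[!ok] <- NA; eb[!ok] <- NA

  quantize <- function(e) {
    br <- unique(quantile(e, probs = seq_len(params$n_bins - 1) / params$n_bins,
                          na.rm = TRUE, names = FALSE))
    if (!length(br) || sd(e, na.rm = TRUE) == 0) return(NULL)
    findInterval(e, br, left.open = TRUE) + 1L
  }
  qa <- quantize(ea); qb <- quantize(eb)
  if (is.null(qa) || is.null(qb)) {
    warning("zero-variance envelope; ASI undefined")
    return(NA_real_)
  }
  mi0 <- mutual_information(qa, qb, params$n_bins)

  min_bins <- ceiling(params$min_shift / ew)
  compute <- function() {
    shifts <- sample(min_bins:(nb - min_bins), params$n_surrogates,
                     replace = TRUE)
    vapply(shifts, function(s) {
      qs <- c(tail(qb, s), head(qb, nb - s))
      mutual_information(qa, qs, params$n_bins)
    }, numeric(1))
  }
  mis <- if (!is.null(params$rng_seed)) with_seed(params$rng_seed, compute())
         else compute()
  flo <- 1e-6
  out <- log2(max(mi0, flo) / max(median(mis, na.rm = TRUE), flo))
  attr(out, "mi0") <- mi0
  attr(out, "surrogates") <- mis
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The four a-priori ASI channel pairings
#'
#' Interhemispheric synchrony is assessed between the two intrahemispheric
#' bipolar derivations (F3-P3 vs F4-P4); intrahemispheric synchrony between
#' the referential frontal and parietal channels of one hemisphere; and a
#' frontal comparison between the two frontal channels.
#'
#' @return Named list of derivation pairs.
#' @export
asi_pairs <- function() {
  list(interhemispheric = c("F3-P3", "F4-P4"),
       intrahemispheric_left = c("F3", "P3"),
       intrahemispheric_right = c("F4", "P4"),
       frontal = c("F3", "F4"))
}

#' Consecutive complete epochs over an interval
#'
#' Divides `[t0, t1)` into consecutive `epoch_length` epochs; only complete
#' epochs are kept (an incomplete trailing remainder is dropped). Epochs are
#' anchored at the interval start by default; `anchor = "end"` aligns them
#' to the interval end instead.
#'
#' @param t0,t1 Interval bounds, seconds.
#' @param epoch_length Epoch length, seconds (default 150 s = 2.5 min).
#' @param anchor `"start"` or `"end"`.
#' @return Data frame with `start` and `end` columns (half-open epochs).
#' @export
epoch_grid <- function(t0, t1, epoch_length = 150, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  k <- floor((t1 - t0) / epoch_length)
  if (k < 1) return(data.frame(start = numeric(0), end = numeric(0)))
  starts <- if (anchor == "start") t0 + (0:(k - 1)) * epoch_length
            else t1 - (k:1) * epoch_length
  data.frame(start = starts, end = starts + epoch_length)
}

#' Per-epoch summary of a masked rEEG window series
#'
#' The epoch value is the mean of the valid 2-s window values inside it
#' (this feeds the long-term trend); an epoch with under `min_valid` of its
#' windows valid is missing.
#'
#' @param trend A `feature_trend` from [reeg()] (mask already applied).
#' @param epochs Epoch grid from [epoch_grid()].
#' @param min_valid Minimum valid fraction (default 0.5).
#' @return Data frame `start`, `end`, `value`, `n_valid`, `n_windows`.
#' @export
reeg_epochs <- function(trend, epochs, min_valid = 0.5) {
  out <- epochs
  out$value <- NA_real_; out$n_valid <- 0L; out$n_windows <- 0L
  for (i in seq_len(nrow(epochs))) {
    sel <- trend$time >= epochs$start[i] & trend$time < epochs$end[i]
    v <- trend$value[sel]
    out$n_windows[i] <- length(v)
    out$n_valid[i] <- sum(!is.na(v))
    if (length(v) && out$n_valid[i] / length(v) >= min_valid)
      out$value[i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Per-epoch ASI for a derivation pair
#'
#' ASI is computed once per epoch segment; epochs with under half their
#' samples valid in either channel are missing.
#'
#' @param rec An [eeg_recording()].
#' @param pair Two derivation names (see [asi_pairs()]).
#' @param epochs Epoch grid from [epoch_grid()].
#' @param params An [asi_params()].
#' @param masks Named list of `artifact_mask`s per derivation (optional).
#' @param band Band-pass edges applied to each derivation before the
#'   envelope, Hz.
#' @return Data frame `start`, `end`, `value`.
#' @export
asi_epochs <- function(rec, pair, epochs, params = asi_params(),
                       masks = NULL, band = c(0.2, 35)) {
  a <- bandpass(derive(rec, pair[1]), rec$sfreq, band[1], band[2])
  b <- bandpass(derive(rec, pair[2]), rec$sfreq, band[1], band[2])
  ma <- masks[[pair[1]]]; mb <- masks[[pair[2]]]
  out <- epochs
  out$value <- vapply(seq_len(nrow(epochs)), function(i) {
    v <- asi(a, b, rec$sfreq, params, mask_a = ma, mask_b = mb,
             interval = c(epochs$start[i], epochs$end[i]))
    as.numeric(v)
  }, numeric(1))
  out
}
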