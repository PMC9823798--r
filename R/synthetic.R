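#' Per-subject simulation parameters
#'
#' Describes one synthetic neonate: the discontinuous (trace-discontinu-like)
#' background is a renewal process of high-amplitude bursts (spontaneous
#' activity transients) separated by low-amplitude interburst intervals.
#' Interhemispheric burst sharing is controlled by `sync_level`; a sedative
#' effect is modelled as a step at the drug timestamp that multiplies burst
#' amplitude (and synchrony) by `max(0, 1 - drug_effect_slope *
#' normalized_baseline)`, so subjects with higher baseline activity are
#' suppressed more.
#'
#' @param subject_id Identifier.
#' @param baseline_amplitude Burst peak-to-peak amplitude, microvolts.
#' @param sync_level Probability in `[0, 1]` that a burst is shared across
#'   hemispheres (shared onsets jittered by at most 0.2 s).
#' @param drug_effect_slope Fractional reduction per unit of normalized
#'   baseline, `>= 0`; 0 means no drug effect.
#' @param normalized_baseline Subject baseline divided by the cohort maximum
#'   (set by [synthesize_cohort()]; 1 for a standalone subject).
#' @param burst_rate Bursts per minute; must agree with
#'   `60 / (burst_duration_mean + ibi_mean)` within 20%.
#' @param burst_duration_mean Mean burst duration, seconds.
#' @param ibi_mean Mean interburst interval, seconds.
#' @param intra_sync Probability that a hemisphere's frontal burst is shared
#'   by its parietal channel (fixed high: channels within a hemisphere are
#'   tightly coupled but not identical).
#' @param channel_gain Named per-channel amplitude multipliers.
#' @param artifact_spec List of artifacts, each
#'   `list(class = "amplitude"|"high_freq"|"low_freq", onset = s,
#'   duration = s, channels = NULL)` (`NULL` = all channels).
#' @param rng_seed Integer seed.
#' @return A list of class `subject_sim_params`.
#' @export
sim_subject_params <- function(subject_id = "S01",
                               baseline_amplitude = 75,
                               sync_level = 0.8,
                               drug_effect_slope = 0,
                               normalized_baseline = 1,
                               burst_rate = 6,
                               burst_duration_mean = 3,
                               ibi_mean = 7,
                               intra_sync = 0.9,
                               channel_gain = c(F3 = 1, F4 = 1, P3 = 1, P4 = 1),
                               artifact_spec = list(),
                               rng_seed = 1L) {
  stopifnot(sync_level >= 0, sync_level <= 1,
            baseline_amplitude > 0, drug_effect_slope >= 0,
            burst_duration_mean > 0, ibi_mean > 0, burst_rate > 0,
            intra_sync >= 0, intra_sync <= 1)
  implied <- 60 / (burst_duration_mean + ibi_mean)
  if (abs(implied - burst_rate) / burst_rate > 0.2)
    stop(sprintf("burst_rate (%g/min) inconsistent with durations (implies %.2f/min)",
                 burst_rate, implied))
  structure(list(subject_id = subject_id,
                 baseline_amplitude = baseline_amplitude,
                 sync_level = sync_level,
                 drug_effect_slope = drug_effect_slope,
                 normalized_baseline = normalized_baseline,
                 burst_rate = burst_rate,
                 burst_duration_mean = burst_duration_mean,
                 ibi_mean = ibi_mean,
                 intra_sync = intra_sync,
                 channel_gain = channel_gain,
                 artifact_spec = artifact_spec,
                 rng_seed = as.integer(rng_seed)),
            class = "subject_sim_params")
}

#' Cohort simulation configuration
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param duration_pre,duration_post Seconds of recording before/after the
#'   drug timestamp (defaults: 2-hour epochs each side).
#' @param sfreq Sampling rate in Hz.
#' @param channels Channel subset to synthesize.
#' @param rng_seed Integer seed for cohort-level draws.
#' @return A list of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_subjects = 21, duration_pre = 7200,
                              duration_post = 7200, sfreq = 250,
                              channels = c("F3", "F4", "P3", "P4"),
                              rng_seed = 1L) {
  stopifnot(n_subjects >= 2, duration_pre > 0, duration_post > 0,
            sfreq > 2 * 35, all(channels %in% c("F3", "F4", "P3", "P4")))
  structure(list(n_subjects = as.integer(n_subjects),
                 duration_pre = duration_pre, duration_post = duration_post,
                 sfreq = sfreq, channels = channels,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_cohort_config")
}

# Renewal burst train over [0, dur): next onset = onset + burst_dur + ibi,
# with lognormal ibi (sd 0.5 log-units) and lognormal burst durations
# (sd 0.3 log-units), so bursts within one train never overlap.
gen_burst_train <- function(dur, burst_duration_mean, ibi_mean) {
  sd_ibi <- 0.5; sd_dur <- 0.3
  ml_ibi <- log(ibi_mean) - sd_ibi^2 / 2
  ml_dur <- log(burst_duration_mean) - sd_dur^2 / 2
  n_guess <- ceiling(dur / (burst_duration_mean + ibi_mean) * 1.6) + 10
  repeat {
    ibis <- rlnorm(n_guess, ml_ibi, sd_ibi)
    durs <- rlnorm(n_guess, ml_dur, sd_dur)
    onsets <- runif(1, 0, ibi_mean) + cumsum(c(0, head(durs + ibis, -1)))
    if (onsets[n_guess] > dur) break
    n_guess <- n_guess * 2
  }
  keep <- onsets < dur
  data.frame(onset = onsets[keep], dur = durs[keep])
}

# Thin a train keeping each burst with time-dependent probability p(onset).
thin_train <- function(train, p_fun) {
  keep <- runif(nrow(train)) < p_fun(train$onset)
  train[keep, , drop = FALSE]
}

# Couple a parent train onto a follower channel: each parent burst is shared
# with probability p (onset jitter <= jitter s); the follower additionally
# draws its own bursts from an independent train thinned to rate (1 - p).
couple_train <- function(parent, p_fun, indep, jitter) {
  shared <- thin_train(parent, p_fun)
  if (nrow(shared))
    shared$onset <- pmax(0, shared$onset + runif(nrow(shared), -jitter, jitter))
  own <- thin_train(indep, function(t) 1 - p_fun(t))
  out <- rbind(shared, own)
  out[order(out$onset), , drop = FALSE]
}

#' Synthesize one discontinuous neonatal-like EEG recording
#'
#' Bursts are 0.5--20 Hz band-limited noise under a half-sine envelope, each
#' rescaled to the target peak-to-peak amplitude; the interburst background
#' is the same carrier at under 15% of burst amplitude. Bursts on the left
#' hemisphere are shared with the right with probability `sync_level`, and
#' frontal bursts are shared with the ipsilateral parietal channel with
#' probability `intra_sync`. After the drug timestamp (fixed at
#' `duration_pre`), burst amplitude and interhemispheric sharing are both
#' multiplied by `max(0, 1 - drug_effect_slope * normalized_baseline)` as an
#' instantaneous step. Requested artifacts are then added: `amplitude` =
#' rail-to-rail square excursions (+/- 1200 uV), `high_freq` = sustained
#' 30 Hz oscillation (100 uV), `low_freq` = 0.25 Hz drift (300 uV amplitude).
#'
#' @param params A [sim_subject_params()].
#' @param cfg A [sim_cohort_config()] (its `n_subjects` is ignored here).
#' @return An [eeg_recording()] with extra fields `bursts` (per-channel burst
#'   tables: onset, duration, target amplitude) and `sim_params`.
#' @export
synthesize_recording <- function(params, cfg = sim_cohort_config()) {
  stopifnot(inherits(params, "subject_sim_params"))
  fs <- cfg$sfreq
  dp <- cfg$duration_pre
  dur_total <- cfg$duration_pre + cfg$duration_post
  if (dur_total < params$burst_duration_mean + params$ibi_mean)
    stop("recording duration too short to contain a single burst cycle")
  n <- round(dur_total * fs)
  m_drug <- max(0, 1 - params$drug_effect_slope * params$normalized_baseline)
  amp_mult <- function(t) ifelse(t < dp, 1, m_drug)
  sync_fun <- function(t) params$sync_level * amp_mult(t)
  intra_fun <- function(t) rep(params$intra_sync, length(t))

  with_seed(params$rng_seed, {
    left <- gen_burst_train(dur_total, params$burst_duration_mean, params$ibi_mean)
    indep_r <- gen_burst_train(dur_total, params$burst_duration_mean, params$ibi_mean)
    right <- couple_train(left, sync_fun, indep_r, jitter = 0.2)
    trains <- list(
      F3 = left,
      F4 = right,
      P3 = couple_train(left, intra_fun,
                        gen_burst_train(dur_total, params$burst_duration_mean,
                                        params$ibi_mean), jitter = 0.1),
      P4 = couple_train(right, intra_fun,
                        gen_burst_train(dur_total, params$burst_duration_mean,
                                        params$ibi_mean), jitter = 0.1))

    # band-limited (0.5-20 Hz) carrier noise; response precomputed once
    m_fft <- stats::nextn(n, c(2, 3, 5))
    f_grid <- (0:(m_fft - 1)) * (fs / m_fft)
    f_grid <- pmin(f_grid, fs - f_grid)
    resp <- butter_response2(f_grid, 0.5, "high", 4) *
      butter_response2(f_grid, 20, "low", 4)
    samples <- matrix(0, length(cfg$channels), n)
    bursts_out <- list()
    for (ci in seq_along(cfg$channels)) {
      ch <- cfg$channels[ci]
      gain <- params$channel_gain[[ch]]
      carrier <- Re(stats::fft(stats::fft(c(rnorm(n), numeric(m_fft - n))) * resp,
                               inverse = TRUE))[seq_len(n)] / m_fft
      carrier <- carrier / sd(carrier)
      tr <- trains[[ch]]
      amp <- params$baseline_amplitude * gain * amp_mult(tr$onset)
      # interburst background: ~9% of (time-local) burst p2p
      x <- carrier * (0.015 * params$baseline_amplitude * gain)
      if (m_drug != 1) {
        post_idx <- (round(dp * fs) + 1L):n
        x[post_idx] <- x[post_idx] * m_drug
      }
      for (b in seq_len(nrow(tr))) {
        i0 <- floor(tr$onset[b] * fs) + 1L
        i1 <- min(n, i0 + round(tr$dur[b] * fs) - 1L)
        if (i1 <= i0) next
        idx <- i0:i1
        env <- sin(pi * seq(0, 1, length.out = length(idx)))
        w <- carrier[idx] * env
        p2p <- max(w) - min(w)
        if (p2p > 0) x[idx] <- x[idx] + w * (amp[b] / p2p)
      }
      samples[ci, ] <- x
      bursts_out[[ch]] <- data.frame(onset = tr$onset, dur = tr$dur, amp = amp)
    }

    # injected artifacts
    for (a in params$artifact_spec) {
      chans <- if (is.null(a$channels)) cfg$channels else a$channels
      i0 <- floor(a$onset * fs) + 1L
      i1 <- min(n, i0 + round(a$duration * fs) - 1L)
      if (i1 <= i0) next
      tt <- (0:(i1 - i0)) / fs
      wav <- switch(a$class,
        amplitude = 1200 * sign(sin(2 * pi * 1 * tt + 1e-9)),
        high_freq = 100 * sin(2 * pi * 30 * tt),
        low_freq  = 300 * sin(2 * pi * 0.25 * tt),
        stop(sprintf("unknown artifact class '%s'", a$class)))
      for (ch in chans) {
        ci <- match(ch, cfg$channels)
        if (!is.na(ci)) samples[ci, i0:i1] <- samples[ci, i0:i1] + wav
      }
    }

    rec <- eeg_recording(samples, fs, labels = cfg$channels,
                         drug_time = dp, subject_id = params$subject_id)
    rec$bursts <- bursts_out
    rec$sim_params <- params
    rec
  })
}

#' Synthesize a cohort with known ground truth
#'
#' Draws per-subject parameters reproducibly from `cfg$rng_seed`, normalizes
#' each subject's baseline by the cohort maximum (so the drug effect
#' multiplier stays in `[0, 1]`), and synthesizes each recording. With a
#' common positive `drug_effect_slope` the true amplitude change is, by
#' construction, more negative for higher-baseline subjects. Clinical
#' covariates (gestational age, fentanyl, diagnosis group) are drawn to
#' resemble a heterogeneous NICU cohort and are independent of the EEG.
#'
#' @param cfg A [sim_cohort_config()].
#' @param heterogeneity List with `baseline_amplitude` and `sync_level`
#'   ranges (`c(lo, hi)`) from which subjects are drawn uniformly.
#' @param drug_effect_slope Common slope for all subjects.
#' @param out_dir If non-`NULL`, EDF files and a `cohort.csv` ground-truth /
#'   covariate table are written there and recordings are not kept in
#'   memory.
#' @return List with `truth` (data frame: drawn parameters, covariates,
#'   true post-drug multiplier, per-subject seed) and either `recordings`
#'   (list of [eeg_recording()]) or `files` (EDF paths).
#' @export
synthesize_cohort <- function(cfg = sim_cohort_config(),
                              heterogeneity = list(
                                baseline_amplitude = c(25, 150),
                                sync_level = c(0.4, 0.9)),
                              drug_effect_slope = 0,
                              out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  rng <- function(range, n) {
    if (diff(range(range)) == 0) {
      warning("degenerate heterogeneity (zero variance); proceeding")
      rep(range[1], n)
    } else runif(n, range[1], range[2])
  }
  with_seed(cfg$rng_seed, {
    ns <- cfg$n_subjects
    amp <- rng(heterogeneity$baseline_amplitude, ns)
    syn <- rng(heterogeneity$sync_level, ns)
    ga <- round(runif(ns, 27 * 7, 42 * 7))
    fent <- rbinom(ns, 1, 12 / 21)
    dx <- sample(0:3, ns, replace = TRUE, prob = c(5, 8, 6, 2) / 21)
    seeds <- sample.int(1e8, ns)
    ids <- sprintf("S%02d", seq_len(ns))
    norm_base <- amp / max(amp)
    truth <- data.frame(subject_id = ids, baseline_amplitude = amp,
                        sync_level = syn, drug_effect_slope = drug_effect_slope,
                        normalized_baseline = norm_base,
                        post_multiplier = pmax(0, 1 - drug_effect_slope * norm_base),
                        gestational_age_days = ga, fentanyl = fent,
                        diagnosis_group = dx, drug_time_s = cfg$duration_pre,
                        seed = seeds)
    recs <- vector("list", ns)
    files <- character(0)
    for (i in seq_len(ns)) {
      p <- sim_subject_params(subject_id = ids[i], baseline_amplitude = amp[i],
                              sync_level = syn[i],
                              drug_effect_slope = drug_effect_slope,
                              normalized_baseline = norm_base[i],
                              rng_seed = seeds[i])
      rec <- synthesize_recording(p, cfg)
      if (is.null(out_dir)) {
        recs[[i]] <- rec
      } else {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        f <- file.path(out_dir, paste0(ids[i], ".edf"))
        write_edf(rec, f)
        files <- c(files, f)
      }
    }
    if (is.null(out_dir)) {
      list(truth = truth, recordings = stats::setNames(recs, ids))
    } else {
      write.csv(truth, file.path(out_dir, "cohort.csv"), row.names = FALSE)
      list(truth = truth, files = files)
    }
  })
}

#' Fraction of bursts co-occurring between two channels
#'
#' A burst on channel `a` co-occurs if channel `b` has a burst onset within
#' `tol` seconds of it. Used to validate the generator's synchrony control.
#'
#' @param rec A recording from [synthesize_recording()].
#' @param a,b Channel labels.
#' @param tol Onset tolerance, seconds.
#' @param interval Optional `c(t0, t1)` restricting to bursts with onsets in
#'   `[t0, t1)`.
#' @return Fraction in `[0, 1]`.
#' @export
burst_cooccurrence <- function(rec, a = "F3", b = "F4", tol = 0.5,
                               interval = NULL) {
  oa <- rec$bursts[[a]]$onset
  ob <- rec$bursts[[b]]$onset
  if (!is.null(interval)) oa <- oa[oa >= interval[1] & oa < interval[2]]
  if (!length(oa)) return(NA_real_)
  hit <- vapply(oa, function(t) any(abs(ob - t) <= tol), logical(1))
  mean(hit)
}
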