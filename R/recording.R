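#' EEG recording container
#'
#' A light container for a multi-channel neonatal EEG recording: a channels x
#' samples matrix in microvolts, the sampling rate, channel labels, and the
#' drug-administration timestamp in seconds from recording start. Time is
#' 0-based and all intervals in the package are half-open `[t0, t1)`.
#'
#' @param samples Numeric matrix, channels x samples, microvolts.
#' @param sfreq Sampling rate in Hz.
#' @param labels Channel labels; must contain F3, F4, P3, P4 after
#'   normalization (see [normalize_label()]).
#' @param drug_time Drug timestamp, seconds from start; must lie strictly
#'   inside the recording (or `NA` when unknown).
#' @param subject_id Subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sfreq, labels = rownames(samples),
                          drug_time = NA_real_, subject_id = "anon") {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.numeric(sfreq), sfreq > 0)
  labels <- normalize_label(labels)
  if (length(labels) != nrow(samples))
    stop("one label per channel required")
  dur <- ncol(samples) / sfreq
  if (!is.na(drug_time) && (drug_time <= 0 || drug_time >= dur))
    stop("drug_time must fall strictly inside the recording")
  rownames(samples) <- labels
  structure(list(samples = samples, sfreq = sfreq, labels = labels,
                 drug_time = drug_time, subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s: %d ch x %.1f s @ %g Hz, drug at %s s>\n",
              x$subject_id, nrow(x$samples), ncol(x$samples) / x$sfreq,
              x$sfreq, format(x$drug_time)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @export
duration <- function(rec) ncol(rec$samples) / rec$sfreq

#' Normalize EDF channel labels
#'
#' EDF label dialects vary ("EEG F3-Fz", "F3-REF", "f3"). Labels are matched
#' case-insensitively after stripping an "EEG " prefix and a reference suffix
#' ("-Fz", "-Cz", "-ref", "-REF", "-A1"...).
#'
#' @param labels Character vector of raw labels.
#' @return Canonical labels ("F3" etc.); unrecognized labels are returned
#'   trimmed but otherwise unchanged.
#' @export
normalize_label <- function(labels) {
  x <- trimws(labels)
  x <- sub("^EEG[ _]+", "", x, ignore.case = TRUE)
  x <- sub("-(Fz|Cz|ref|A1|A2|M1|M2)$", "", x, ignore.case = TRUE)
  canon <- c("F3", "F4", "P3", "P4")
  m <- match(toupper(x), canon)
  ifelse(is.na(m), x, canon[m])
}

#' The eight analysis derivations
#'
#' Referential derivations are the recorded channels against the common
#' reference; bipolar derivations are sample-wise differences used to probe
#' intra- (F3-P3, F4-P4) and interhemispheric (F3-F4, P3-P4) activity.
#'
#' @return Character vector of the eight derivation names.
#' @export
all_derivations <- function() {
  c("F3", "F4", "P3", "P4", "F3-P3", "F4-P4", "F3-F4", "P3-P4")
}

#' Build a single-channel signal from a derivation name
#'
#' @param rec An [eeg_recording()].
#' @param name Derivation: a bare channel label ("F3", equivalently "F3-ref")
#'   for referential, or "A-B" for the bipolar difference A minus B.
#' @return Numeric vector of samples in microvolts.
#' @export
derive <- function(rec, name) {
  stopifnot(inherits(rec, "eeg_recording"))
  name <- sub("-ref$", "", name, ignore.case = TRUE)
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  get_ch <- function(lab) {
    i <- match(toupper(lab), toupper(rec$labels))
    if (is.na(i)) stop(sprintf("channel '%s' not present", lab))
    rec$samples[i, ]
  }
  if (length(parts) == 1) get_ch(parts) else get_ch(parts[1]) - get_ch(parts[2])
}

#' Read a recording and its clinical covariates
#'
#' Reads an EDF/EDF+ file, normalizes channel labels, checks that all four
#' required channels are present, and resolves the drug timestamp: an EDF+
#' `"DEX"` annotation takes precedence over a `drug_time_s` column in the
#' covariates table.
#'
#' @param path EDF file.
#' @param covariates_path Optional CSV with columns `subject_id`,
#'   `gestational_age_days`, `fentanyl` (0/1), `diagnosis_group` (0-3) and
#'   optionally `drug_time_s`.
#' @param subject_id Subject id used to look up the covariate row; defaults
#'   to the EDF file name without extension.
#' @return List with `recording` ([eeg_recording()]) and `clinical` (one-row
#'   data frame or `NULL`).
#' @export
read_recording <- function(path, covariates_path = NULL, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  edf <- read_edf(path)
  labels <- normalize_label(edf$labels)
  need <- c("F3", "F4", "P3", "P4")
  missing_ch <- setdiff(need, labels)
  if (length(missing_ch))
    stop(sprintf("required channel(s) missing from %s: %s",
                 basename(path), paste(missing_ch, collapse = ", ")))
  if (abs(edf$sfreq - 250) > 1e-9)
    warning(sprintf("sampling rate is %g Hz, not 250 Hz; analyses are defined in seconds and proceed", edf$sfreq))

  clinical <- NULL
  drug_time <- edf$drug_time
  if (!is.null(covariates_path)) {
    cov <- read.csv(covariates_path, stringsAsFactors = FALSE)
    row <- cov[cov$subject_id == subject_id, , drop = FALSE]
    if (nrow(row) == 1) {
      clinical <- row
      if (is.na(drug_time) && "drug_time_s" %in% names(row))
        drug_time <- row$drug_time_s
    }
  }
  if (is.na(drug_time))
    stop("no drug timestamp: neither a DEX annotation nor a drug_time_s covariate found")
  keep <- match(need, labels)
  rec <- eeg_recording(edf$samples[keep, , drop = FALSE], edf$sfreq,
                       labels = need, drug_time = drug_time,
                       subject_id = subject_id)
  list(recording = rec, clinical = clinical)
}
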