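#' Write an EEG recording to European Data Format (EDF+)
#'
#' Writes a 16-bit EDF file with one data record per second. When the
#' recording carries a drug-administration timestamp, an EDF+ annotation
#' channel is added holding a `"DEX"` event at that onset, so the timestamp
#' survives a round trip through the file.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param phys_range Physical range in microvolts mapped onto the full
#'   16-bit digital range. Samples outside it are clipped. The default
#'   (+/- 2000 uV) leaves headroom for movement artifacts well beyond
#'   cortical amplitudes; the quantization step is about 0.06 uV.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = c(-2000, 2000)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sfreq
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- ncol(rec$samples)
  n_rec <- floor(n / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  labels <- rec$labels
  nsig <- length(labels)
  has_annot <- !is.null(rec$drug_time) && is.finite(rec$drug_time)
  annot_spr <- 32L # samples (2 bytes each) reserved per record for TALs
  ns_total <- nsig + if (has_annot) 1L else 0L

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = -w, flag = " ")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  # -- fixed 256-byte header
  wr(pad("0", 8))
  wr(pad(paste0("X X X ", rec$subject_id), 80))
  wr(pad("Startdate 01-JAN-2000 X X X", 80))
  wr(pad("01.01.00", 8))
  wr(pad("00.00.00", 8))
  wr(pad(256 * (ns_total + 1), 8))
  wr(pad(if (has_annot) "EDF+C" else "", 44))
  wr(pad(n_rec, 8))
  wr(pad("1", 8))
  wr(pad(ns_total, 4))

  sig_labels <- labels
  if (has_annot) sig_labels <- c(sig_labels, "EDF Annotations")
  spr <- c(rep(fs, nsig), if (has_annot) annot_spr)
  pmin_ <- c(rep(phys_range[1], nsig), if (has_annot) -32768)
  pmax_ <- c(rep(phys_range[2], nsig), if (has_annot) 32767)
  dims <- c(rep("uV", nsig), if (has_annot) "")
  for (s in sig_labels) wr(pad(s, 16))
  for (s in sig_labels) wr(pad("", 80))          # transducer
  for (s in dims) wr(pad(s, 8))
  for (v in pmin_) wr(pad(v, 8))
  for (v in pmax_) wr(pad(v, 8))
  for (s in sig_labels) wr(pad(-32768, 8))
  for (s in sig_labels) wr(pad(32767, 8))
  for (s in sig_labels) wr(pad("", 80))          # prefiltering
  for (v in spr) wr(pad(v, 8))
  for (s in sig_labels) wr(pad("", 32))

  # -- digitize
  gain <- (phys_range[2] - phys_range[1]) / 65535
  dig <- round((rec$samples - phys_range[1]) / gain) - 32768
  dig[dig < -32768] <- -32768
  dig[dig > 32767] <- 32767
  storage.mode(dig) <- "integer"

  drug_rec <- if (has_annot) floor(rec$drug_time) else -1
  for (r in seq_len(n_rec) - 1L) {
    idx <- (r * fs + 1L):((r + 1L) * fs)
    for (ch in seq_len(nsig)) writeBin(dig[ch, idx], con, size = 2, endian = "little")
    if (has_annot) {
      # \x01 is a placeholder for the NUL that terminates each TAL
      tal <- sprintf("+%d\x14\x14\x01", r)
      if (r == drug_rec)
        tal <- paste0(tal, sprintf("+%s\x14DEX\x14\x01",
                                   format(rec$drug_time, trim = TRUE)))
      raw_tal <- charToRaw(tal)
      raw_tal[raw_tal == as.raw(1)] <- as.raw(0)
      writeBin(c(raw_tal, raw(2 * annot_spr - length(raw_tal))), con)
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Minimal reader for 16-bit EDF with identical digital ranges per ordinary
#' signal. Annotation channels are parsed for a `"DEX"` event, whose onset
#' (seconds from recording start) is returned as the drug timestamp.
#'
#' @param path EDF file path.
#' @return A list with `samples` (channels x time matrix, physical units),
#'   `labels` (raw signal labels as stored), `sfreq`, `drug_time` (`NA` if no
#'   DEX annotation), and `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  rd(8)                                   # header bytes
  rd(44)                                  # reserved (EDF+C)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  is_annot <- grepl("annotation", labels, ignore.case = TRUE)
  sig <- which(!is_annot)
  out <- lapply(spr, function(k) vector("list", n_rec))
  annot_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        annot_raw <- c(annot_raw, readBin(con, "raw", 2 * spr[i]))
      } else {
        out[[i]][[r]] <- readBin(con, "integer", spr[i], size = 2,
                                 signed = TRUE, endian = "little")
      }
    }
  }
  samples <- do.call(rbind, lapply(sig, function(i) {
    d <- unlist(out[[i]], use.names = FALSE)
    (d - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) + pmin_[i]
  }))
  rownames(samples) <- labels[sig]

  drug_time <- NA_real_
  if (length(annot_raw)) {
    txt <- rawToChar(annot_raw[annot_raw != as.raw(0)])
    tals <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
    hit <- which(tals == "DEX")
    if (length(hit)) {
      onset <- tals[hit[1] - 1]
      onset <- sub("\x15.*$", "", onset)
      drug_time <- as.numeric(onset)
    }
  }
  list(samples = samples, labels = labels[sig],
       sfreq = spr[sig[1]] / rec_dur, drug_time = drug_time,
       n_records = n_rec)
}
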