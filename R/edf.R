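# Minimal 16-bit EDF (European Data Format) reader and writer.
# EDF is the standard clinical EEG container: a 256-byte fixed header,
# 256 bytes of header per signal, then data records of little-endian int16
# samples. One-second data records are assumed throughout, which is the
# common layout for clinical scalp EEG.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  sprintf(paste0("%-", width, "s"), x)
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 1L, width = 1L)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  .edf_pad(s, width)
}

# Labels that are never scalp EEG; used by the read-time channel filter.
.non_eeg_pattern <- paste0(
  "(ECG|EKG|EMG|EOG|RESP|SPO2|SAO2|PLET|PULSE|HR\\b|TEMP|MARKER|\\bMK\\b|",
  "ANNOTATION|STATUS|EVENT|FLOW|SNORE|ABD|THOR|BODY|POS|LIGHT)"
)

.clean_label <- function(label) {
  x <- trimws(label)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("[-_ ](REF|A1|A2|LE|AVG).*$", "", x, ignore.case = TRUE)
  trimws(x)
}

#' Write a recording to an EDF file
#'
#' Emits a standard 16-bit EDF with one-second data records. Samples are
#' linearly quantized onto the signed 16-bit range between `-phys_max` and
#' `phys_max` microvolts, so the round-trip error is at most half a
#' quantization step (`phys_max / 32767.5`). The recording is truncated to a
#' whole number of seconds.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param phys_max physical range bound in microvolts; defaults to the
#'   per-recording transducer maximum, or to 1.05 x the absolute signal
#'   maximum when that is not finite.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_max = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- ncol(rec$signal)
  if (is.null(phys_max)) {
    phys_max <- rec$transducer_max
    if (!all(is.finite(phys_max)))
      phys_max <- rep(max(abs(rec$signal)) * 1.05, nch)
  }
  phys_max <- rep_len(phys_max, nch)
  n_rec <- nrow(rec$signal) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record")

  con <- file(path, "wb")
  on.exit(close(con))
  meta <- rec$meta
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(if (!is.null(meta$patient_id)) meta$patient_id else "X", 80),
    .edf_pad(if (!is.null(meta$record_id)) meta$record_id else "X", 80),
    .edf_pad(if (!is.null(meta$start_date)) meta$start_date else "01.01.00", 8),
    .edf_pad(if (!is.null(meta$start_time)) meta$start_time else "00.00.00", 8),
    .edf_pad(256L * (1L + nch), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad("1", 8),
    .edf_pad(nch, 4)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  field <- function(f) writeChar(paste0(f, collapse = ""), con, eos = NULL,
                                 useBytes = TRUE)
  labels <- ifelse(grepl("^EEG", rec$channel_labels, ignore.case = TRUE),
                   rec$channel_labels, paste("EEG", rec$channel_labels))
  field(vapply(labels, .edf_pad, "", width = 16))
  field(vapply(rep("AgAgCl electrode", nch), .edf_pad, "", width = 80))
  field(vapply(rep("uV", nch), .edf_pad, "", width = 8))
  field(vapply(-phys_max, .edf_num, "", width = 8))
  field(vapply(phys_max, .edf_num, "", width = 8))
  field(vapply(rep(-32768L, nch), .edf_pad, "", width = 8))
  field(vapply(rep(32767L, nch), .edf_pad, "", width = 8))
  field(vapply(rep("", nch), .edf_pad, "", width = 80))
  field(vapply(rep(fs, nch), .edf_pad, "", width = 32))
  field(vapply(rep("", nch), .edf_pad, "", width = 32))

  # re-read the written physical bounds so quantization matches the header
  pmax_hdr <- as.numeric(vapply(phys_max, .edf_num, "", width = 8))
  pmin_hdr <- as.numeric(vapply(-phys_max, .edf_num, "", width = 8))
  slope <- 65535 / (pmax_hdr - pmin_hdr)

  n_keep <- n_rec * fs
  dig <- matrix(0L, nrow = n_keep, ncol = nch)
  for (ch in seq_len(nch)) {
    d <- round((rec$signal[seq_len(n_keep), ch] - pmin_hdr[ch]) * slope[ch]) - 32768
    dig[, ch] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  # interleave: per record, all samples of signal 1, then signal 2, ...
  idx <- matrix(seq_len(n_keep), nrow = fs)  # fs x n_rec
  out <- integer(n_keep * nch)
  pos <- 0L
  block <- fs * nch
  for (r in seq_len(n_rec)) {
    out[pos + seq_len(block)] <- as.vector(dig[idx[, r], ])
    pos <- pos + block
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF recording
#'
#' Parses a 16-bit EDF file, converts samples to physical units
#' (microvolts) and, by default, drops channels whose labels identify them
#' as non-EEG modalities (ECG, EMG, EOG, respiration, annotations, ...).
#' Channel labels are normalized by stripping the `"EEG "` prefix and
#' reference suffixes. The per-channel physical maximum from the header is
#' kept as the transducer maximum for the noisy-record screen.
#'
#' @param path EDF file path.
#' @param drop_non_eeg drop channels matched by the non-EEG label filter
#'   (default `TRUE`).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, drop_non_eeg = TRUE) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not a valid EDF file (truncated header)")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  rd(8)                       # version
  patient <- trimws(rd(80))
  record <- trimws(rd(80))
  start_date <- trimws(rd(8))
  start_time <- trimws(rd(8))
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur))
    stop("not a valid EDF file (malformed header)")
  if (sz < 256 * (1 + ns)) stop("not a valid EDF file (truncated header)")
  rds <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- rds(16)
  rds(80)                     # transducer
  rds(8)                      # physical dimension
  pmin <- as.numeric(rds(8))
  pmax <- as.numeric(rds(8))
  dmin <- as.numeric(rds(8))
  dmax <- as.numeric(rds(8))
  rds(80)                     # prefiltering
  spr <- as.integer(rds(32))  # samples per record
  rds(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop("not a valid EDF file (malformed signal headers)")

  tpr <- sum(spr)
  expected <- hdr_bytes + 2 * tpr * n_rec
  if (sz < expected) stop("not a valid EDF file (truncated data)")
  raw <- readBin(con, integer(), n = tpr * n_rec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < tpr * n_rec) stop("not a valid EDF file (truncated data)")
  raw <- matrix(raw, nrow = tpr, ncol = n_rec)

  keep <- rep(TRUE, ns)
  if (drop_non_eeg)
    keep <- !grepl(.non_eeg_pattern, toupper(labels)) &
      !grepl("^EDF ANNOTATIONS$", toupper(labels))
  if (!any(keep)) stop("no EEG channels found in ", path)
  fs_all <- spr / rec_dur
  fs <- fs_all[keep][1]
  if (any(fs_all[keep] != fs))
    stop("EEG channels have differing sampling rates")

  offsets <- c(0L, cumsum(spr))
  sig <- matrix(0, nrow = n_rec * spr[which(keep)[1]], ncol = sum(keep))
  out_labels <- character(sum(keep))
  tmax <- numeric(sum(keep))
  j <- 0L
  for (s in which(keep)) {
    j <- j + 1L
    d <- as.vector(raw[(offsets[s] + 1L):offsets[s + 1L], , drop = FALSE])
    slope <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
    sig[, j] <- (d - dmin[s]) * slope + pmin[s]
    out_labels[j] <- .clean_label(labels[s])
    tmax[j] <- max(abs(pmin[s]), abs(pmax[s]))
  }
  out_labels <- make.unique(out_labels, sep = "_")
  eeg_recording(
    sig, fs, out_labels, transducer_max = tmax,
    meta = list(record_id = record, patient_id = patient,
                start_date = start_date, start_time = start_time,
                source = path)
  )
}

#' Read or write sidecar seizure annotations (JSON)
#'
#' The sidecar schema is
#' `{"record_id": str, "seizures": [{"onset_s": num, "offset_s": num}]}`.
#'
#' @param path JSON file path.
#' @return `read_annotations()` returns a list with `record_id` and an
#'   `events` data frame as built by [seizure_events()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$seizures) || NROW(x$seizures) == 0L)
    return(list(record_id = x$record_id,
                events = seizure_events(numeric(0), numeric(0))))
  list(
    record_id = x$record_id,
    events = seizure_events(x$seizures$onset_s, x$seizures$offset_s)
  )
}

#' @rdname read_annotations
#' @param record_id record identifier stored in the sidecar.
#' @param events a [seizure_events()] data frame.
#' @export
write_annotations <- function(record_id, events, path) {
  jsonlite::write_json(
    list(record_id = record_id,
         seizures = events[, c("onset_s", "offset_s"), drop = FALSE]),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Parse a Siena Scalp EEG Database seizure-list file
#'
#' Adapter for the plain-text `Seizures-list-PNxx.txt` files distributed
#' with the Siena Scalp EEG Database, which give the registration start
#' clock time and per-seizure start/end clock times (`hh.mm.ss`). Clock
#' times are converted to seconds from registration start; times that fall
#' before it are assumed to have wrapped past midnight.
#'
#' @param path text file path.
#' @return A [seizure_events()] data frame.
#' @export
read_siena_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_times <- function(pattern) {
    m <- regmatches(lines, regexpr(paste0(pattern,
      "[^0-9]*([0-9]{1,2})[.:]([0-9]{2})[.:]([0-9]{2})"), lines, perl = TRUE))
    vapply(m, function(s) {
      p <- as.numeric(regmatches(s, gregexpr("[0-9]+", s))[[1]])
      n <- length(p)
      p[n - 2] * 3600 + p[n - 1] * 60 + p[n]
    }, numeric(1))
  }
  reg <- get_times("Registration start time")
  if (!length(reg)) stop("no registration start time found in ", path)
  onset <- get_times("Seizure start time")
  offset <- get_times("Seizure end time")
  if (length(onset) != length(offset))
    stop("mismatched seizure start/end entries in ", path)
  wrap <- function(t) ifelse(t < reg[1], t + 86400 - reg[1], t - reg[1])
  seizure_events(wrap(onset), wrap(offset))
}
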