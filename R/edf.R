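# Minimal EDF (European Data Format) writer/reader for continuous multichannel
# recordings: 256-byte fixed header, 256 bytes per signal header, then
# 1-second data records of 16-bit little-endian integers with per-channel
# physical scaling from the channel's min/max. Covers exactly what the
# pipeline needs; no annotations, uniform sampling only.

.pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Physical scaling is set per channel from the data range; quantization is
#' the EDF 16-bit step, i.e. (max - min) / 65535 per channel.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  ns <- nrow(x)
  fs <- recording$sample_rate
  if (fs != as.integer(fs)) stop("EDF writer requires an integer sample rate")
  record_len <- as.integer(fs)  # 1-second records
  n_rec <- floor(ncol(x) / record_len)
  if (n_rec < 1) stop("recording shorter than one data record")
  x <- x[, seq_len(n_rec * record_len), drop = FALSE]

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  digital <- round((x - pmin_) * scale + dmin)
  storage.mode(digital) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(ifelse(is.na(recording$subject_id), "X", recording$subject_id), 80)
  wr(ifelse(is.na(recording$session_id), "X", recording$session_id), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)                       # record duration, seconds
  wr(as.character(ns), 4)
  for (lab in recording$channel_names) wr(lab, 16)
  for (i in seq_len(ns)) wr("AgAgCl electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 8), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 8), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(record_len), 8)
  for (i in seq_len(ns)) wr("", 32)

  # Data: records x channels x samples, channel-major within a record.
  dim(digital) <- c(ns, record_len, n_rec)
  writeBin(as.integer(aperm(digital, c(2, 1, 3))), con, size = 2,
           endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain continuous EDF)
#'
#' @param path EDF file path.
#' @return An `eeg_recording`; samples are reconstructed to within the
#'   16-bit quantization step of the physical range.
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (missing or truncated header)")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  subject_id <- rd(80)
  session_id <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur)) {
    stop("malformed EDF header")
  }
  if (sz < 256 + 256 * ns) stop("truncated EDF: incomplete signal headers")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nspr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nspr)) != 1) stop("EDF reader requires uniform sampling")
  expected <- header_bytes + 2 * sum(as.numeric(nspr)) * n_rec
  if (sz < expected) {
    stop(sprintf("truncated EDF: %d bytes, expected %d", sz, expected))
  }
  raw <- readBin(con, "integer", n = sum(nspr) * n_rec, size = 2,
                 signed = TRUE, endian = "little")
  dim(raw) <- c(nspr[1], ns, n_rec)
  digital <- aperm(raw, c(2, 1, 3))
  dim(digital) <- c(ns, nspr[1] * n_rec)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- (digital - dmin) * scale + pmin_
  rownames(data) <- labels
  new_eeg_recording(data, nspr[1] / rec_dur, labels,
                    if (subject_id == "X") NA_character_ else subject_id,
                    if (session_id == "X") NA_character_ else session_id)
}
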