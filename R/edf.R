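# Minimal EDF (European Data Format) I/O: 16-bit integer encoding, one data
# record per second, identical sampling rate per channel.  Covers the subset
# of EDF/EDF+ needed for referential neonatal EEG exchange.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Encodes each channel as 16-bit integers with per-channel physical
#' min/max, physical dimension uV, and one data record per second.  Samples
#' beyond the last whole second are dropped (EDF records are whole
#' seconds).
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readEDF}}
#' @export
writeEDF <- function(rec, path) {
  sig <- rec@signal
  fs <- rec@fs
  if (fs != round(fs))
    stop("EDF writer requires an integer sampling rate")
  n_rec <- floor(nrow(sig) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  sig <- sig[seq_len(n_rec * fs), , drop = FALSE]
  ns <- ncol(sig)

  pmin_ <- apply(sig, 2, min)
  pmax_ <- apply(sig, 2, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1      # avoid zero-span scaling
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edfPad("0", 8),
    edfPad(paste("infant", rec@infantId), 80),
    edfPad(paste("recording", rec@recordingId, "pma_days", rec@pmaDays), 80),
    edfPad("01.01.00", 8), edfPad("00.00.00", 8),
    edfPad(256 + ns * 256, 8),
    edfPad("", 44),
    edfPad(n_rec, 8), edfPad(1, 8), edfPad(ns, 4)), con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, edfPad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(rec@channels, 16)
  fld(rep("AgAgCl electrode", ns), 80)
  fld(rep("uV", ns), 8)
  fld(sprintf("%.8g", pmin_), 8)
  fld(sprintf("%.8g", pmax_), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("HP:0.0Hz", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)

  # digital = (phys - pmin) / (pmax - pmin) * (dmax - dmin) + dmin
  scl <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- sweep(sig, 2, pmin_, "-")
  dig <- sweep(dig, 2, scl, "*") + dmin
  dig <- round(pmin(pmax(dig, dmin), dmax))
  # interleave: record-by-record, channel-by-channel
  arr <- array(dig, dim = c(fs, n_rec, ns))
  out <- aperm(arr, c(1, 3, 2))      # sample, channel, record
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' Reads the subset of EDF written by \code{\link{writeEDF}} and typical
#' clinical exports: uniform sampling rate, 16-bit samples.  Channel labels
#' are normalised with \code{\link{normaliseChannelLabels}}; annotation
#' channels (\code{"EDF Annotations"}) are dropped.  The physical dimension
#' must be uV (or mV, converted).
#'
#' @param path EDF file path.
#' @param infantId,recordingId,pmaDays recording metadata (EDF headers do
#'   not carry PMA; supply it from the cohort manifest).
#' @return An \linkS4class{EEGRecording}.
#' @seealso \code{\link{writeEDF}}, \code{\link{readManifest}}
#' @export
readEDF <- function(path, infantId = "?", recordingId = basename(path),
                    pmaDays = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")

  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (length(unique(spr[keep])) != 1)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[keep][1] / rec_dur
  badu <- keep & !tolower(dims) %in% c("uv", "µv", "mv", "")
  if (any(badu))
    stop("physical dimension must be uV or mV; found: ",
         paste(unique(dims[badu]), collapse = ", "))

  total_per_rec <- sum(spr)
  raw <- readBin(con, integer(), n = n_rec * total_per_rec, size = 2,
                 endian = "little")
  sig <- matrix(0, nrow = n_rec * spr[keep][1], ncol = sum(keep))
  offs <- c(0, cumsum(spr))
  col <- 0
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    col <- col + 1
    idx <- as.vector(outer(offs[i] + seq_len(spr[i]),
                           (seq_len(n_rec) - 1) * total_per_rec, "+"))
    d <- raw[idx]
    phys <- pmin_[i] + (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    if (tolower(dims[i]) == "mv") phys <- phys * 1000
    sig[, col] <- phys
  }
  colnames(sig) <- normaliseChannelLabels(labels[keep])
  EEGRecording(sig, fs = fs, infantId = infantId, recordingId = recordingId,
               pmaDays = pmaDays)
}

#' Read a cohort manifest CSV
#'
#' The manifest is the contract between EDF storage and the pipeline:
#' columns \code{infant_id}, \code{recording_id}, \code{edf_path},
#' \code{pma_days}.
#'
#' @param path CSV path.
#' @param base_dir directory against which relative \code{edf_path}s are
#'   resolved (default: the manifest's own directory).
#' @return A data.frame with an absolute \code{edf_path} column.
#' @export
readManifest <- function(path, base_dir = dirname(path)) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("infant_id", "recording_id", "edf_path", "pma_days")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$edf_path)
  m$edf_path[rel] <- file.path(base_dir, m$edf_path[rel])
  m
}
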