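#' Zero-phase band-pass filter
#'
#' Filters an EEG trace with Butterworth high-pass (order 4 at 0.5 Hz) and
#' low-pass (order 8 at 32 Hz) stages applied forward and backward
#' (\code{signal::filtfilt}), so the output has no group delay and SAT
#' interval timestamps stay aligned with the input.  The orders are chosen
#' so the squared (zero-phase) response keeps 1--25 Hz tones within 5\% and
#' attenuates 0.1 and 45 Hz by more than 20 dB.  Splitting the band-pass
#' into HP + LP cascades keeps the recursion numerically stable at the
#' narrow normalised low cut-off (0.5 Hz at 256 Hz).
#'
#' @param x numeric vector or samples x channels matrix, uV.
#' @param fs sampling rate in Hz; must exceed \code{2 * f_high}.
#' @param f_low,f_high cut-off frequencies in Hz (defaults 0.5 and 32).
#' @return Filtered signal, same shape as \code{x}.
#' @examples
#' fs <- 256; t <- seq(0, 4, by = 1/fs)
#' x <- sin(2 * pi * 10 * t)               # passband tone
#' y <- bandpassFilter(x, fs)
#' max(abs(y[fs:(3 * fs)]))                 # ~1
#' @export
bandpassFilter <- function(x, fs, f_low = 0.5, f_high = 32) {
  if (fs <= 2 * f_high)
    stop("invalid-sampling-rate: fs = ", fs, " must exceed 2*f_high = ",
         2 * f_high)
  if (!all(is.finite(x)))
    stop("invalid-signal: non-finite samples")
  hp <- signal::butter(4, f_low / (fs / 2), type = "high")
  lp <- signal::butter(8, f_high / (fs / 2), type = "low")
  filt1 <- function(v) {
    if (length(v) < 24)
      stop("invalid-signal: sequence shorter than filter warm-up")
    signal::filtfilt(lp, signal::filtfilt(hp, v))
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, filt1)
    dimnames(out) <- dimnames(x)
    out
  } else {
    filt1(x)
  }
}

#' Resample a band-limited signal to 64 Hz
#'
#' Assumes the 32 Hz low-pass has already been applied (see
#' \code{\link{bandpassFilter}}), so integer decimation needs no further
#' anti-alias stage; non-integer ratios use polyphase resampling
#' (\code{signal::resample}) trimmed to \code{round(n * 64 / fs)} samples.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fs native sampling rate in Hz; must be at least 64.
#' @return A list with \code{signal} (resampled) and \code{fs} (64).
#' @examples
#' r <- resampleTo64(sin(2 * pi * 10 * seq(0, 10, by = 1/256)), 256)
#' r$fs
#' @export
resampleTo64 <- function(x, fs) {
  if (fs < 64)
    stop("upsampling-not-supported: native rate ", fs, " Hz below 64 Hz")
  res1 <- function(v) {
    n_out <- round(length(v) * 64 / fs)
    if (fs == 64) return(v)
    if (fs %% 64 == 0) {
      v[seq(1, length(v), by = fs / 64)][seq_len(n_out)]
    } else {
      r <- signal::resample(v, 64, fs)
      length(r) <- n_out          # pad/trim boundary samples
      r[is.na(r)] <- 0
      r
    }
  }
  sig <- if (is.matrix(x)) {
    out <- apply(x, 2, res1)
    dimnames(out) <- list(NULL, colnames(x))
    out
  } else res1(x)
  list(signal = sig, fs = 64)
}

#' Re-montage a referential recording to bipolar derivations
#'
#' Each bipolar channel is the minuend electrode minus the subtrahend
#' electrode, in the exact order of the montage definition.  The referential
#' signals are retained by the caller for the referential artefact rule.
#'
#' @param rec an \linkS4class{EEGRecording} or a samples x electrodes
#'   matrix with electrode column names.
#' @param montage two-column character matrix of electrode pairs; default
#'   the standard 8-derivation montage (\code{\link{standardMontage}}).
#' @return samples x derivations matrix with derivation labels as column
#'   names.
#' @examples
#' sig <- matrix(rnorm(8 * 2560), ncol = 8,
#'               dimnames = list(NULL, c("Fp1","Fp2","C3","C4","T3","T4","O1","O2")))
#' b <- toBipolar(sig)
#' colnames(b)
#' @export
toBipolar <- function(rec, montage = standardMontage()) {
  sig <- if (is(rec, "EEGRecording")) rec@signal else rec
  need <- unique(as.vector(montage))
  missing <- setdiff(need, colnames(sig))
  if (length(missing))
    stop("missing-channel: electrode(s) absent: ",
         paste(missing, collapse = ", "))
  out <- sig[, montage[, 1], drop = FALSE] - sig[, montage[, 2], drop = FALSE]
  colnames(out) <- montageLabels(montage)
  out
}

#' Cut a preprocessed recording into overlapping epochs
#'
#' Epochs start at 0, \code{step_s}, 2\code{step_s}, ... seconds; only
#' epochs fully inside the recording are emitted (no padding), so a
#' recording of duration T yields \code{floor((T - epoch_s)/step_s) + 1}
#' epochs.
#'
#' @param bipolar samples x derivations matrix at 64 Hz.
#' @param referential samples x electrodes matrix at 64 Hz (same window).
#' @param params \code{\link{emaParams}}; supplies epoch length and step.
#' @param infantId,recordingId,pmaDays provenance for the emitted epochs.
#' @return List of \linkS4class{BipolarEpoch}.
#' @export
segmentEpochs <- function(bipolar, referential, params = emaParams(),
                          infantId = "?", recordingId = "?", pmaDays = NA_real_) {
  fs <- params$fs
  n_epoch <- round(params$epoch_s * fs)
  n_step <- round(params$step_s * fs)
  n <- nrow(bipolar)
  if (n < n_epoch)
    stop("recording-too-short: ", n / fs, " s < epoch length ",
         params$epoch_s, " s")
  starts <- seq(0L, n - n_epoch, by = n_step)
  lapply(starts, function(s0) {
    idx <- (s0 + 1L):(s0 + n_epoch)
    new("BipolarEpoch",
        bipolar = bipolar[idx, , drop = FALSE],
        referential = referential[idx, , drop = FALSE],
        channelLabels = colnames(bipolar), fs = fs,
        startOffset = s0 / fs, infantId = as.character(infantId),
        recordingId = as.character(recordingId), pmaDays = pmaDays)
  })
}

#' Preprocess a raw recording into analysis epochs
#'
#' Applies the standard chain: band-pass filter the referential channels
#' (0.5--32 Hz), resample to 64 Hz, re-montage to bipolar derivations, and
#' cut into overlapping epochs.  Filtering precedes montage construction;
#' both are linear so the order does not change the bipolar output.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param params \code{\link{emaParams}}.
#' @param montage electrode-pair matrix, default \code{standardMontage()}.
#' @return List of \linkS4class{BipolarEpoch}; empty list (with a message)
#'   if the recording is shorter than one epoch.
#' @examples
#' cohort <- generateCohort(simConfig(n_infants = 1, rec_dur_s = 600,
#'                                    recordings_min = 1, recordings_max = 1),
#'                          seed = 1)
#' eps <- preprocessRecording(cohort$recordings[[1]], emaParams(epoch_s = 600))
#' length(eps)
#' @export
preprocessRecording <- function(rec, params = emaParams(),
                                montage = standardMontage()) {
  filt <- bandpassFilter(rec@signal, rec@fs, params$f_low, params$f_high)
  res <- resampleTo64(filt, rec@fs)
  ref <- res$signal
  bip <- toBipolar(ref, montage)
  n_epoch <- round(params$epoch_s * params$fs)
  if (nrow(bip) < n_epoch) {
    message("recording ", rec@recordingId, " shorter than one epoch; skipped")
    return(list())
  }
  segmentEpochs(bip, ref, params, rec@infantId, rec@recordingId, rec@pmaDays)
}

#' Normalise raw EDF-style channel labels to electrode names
#'
#' Strips an \code{"EEG "} prefix and a reference suffix
#' (\code{"Fp1-Cz"} -> \code{"Fp1"}) and matches case-insensitively
#' against the standard electrode names.
#'
#' @param labels character vector of raw labels.
#' @return Cleaned labels (unknown labels are returned stripped but
#'   otherwise unchanged).
#' @examples
#' normaliseChannelLabels(c("EEG Fp1-Cz", "C3-REF", "t4"))
#' @export
normaliseChannelLabels <- function(labels) {
  x <- sub("^\\s*EEG\\s+", "", labels, ignore.case = TRUE)
  x <- sub("-(Cz|REF|A1|A2|M1|M2)\\s*$", "", x, ignore.case = TRUE)
  x <- trimws(x)
  std <- c(REQUIRED_ELECTRODES, "Cz")
  hit <- match(tolower(x), tolower(std))
  ifelse(is.na(hit), x, std[hit])
}
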