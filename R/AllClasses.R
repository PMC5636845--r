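#' @import methods
#' @importFrom IRanges IRanges
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

REQUIRED_ELECTRODES <- c("Fp1", "Fp2", "C3", "C4", "T3", "T4", "O1", "O2")

#' EEGRecording: referential multichannel neonatal EEG
#'
#' One continuous EEG recording in a referential (Cz) montage, with the
#' infant identity and post-menstrual age (PMA) in days at the start of the
#' recording.  Amplitudes are in uV.
#'
#' @slot signal numeric matrix, samples x channels; columns named with
#'   electrode labels.
#' @slot channels character, electrode labels (column order of
#'   \code{signal}).
#' @slot fs numeric, sampling rate in Hz.
#' @slot infantId,recordingId character identifiers; all recordings of an
#'   infant share \code{infantId}, which is the cross-validation grouping
#'   unit.
#' @slot pmaDays numeric, post-menstrual age in days.
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(signal = "matrix", channels = "character", fs = "numeric",
                 infantId = "character", recordingId = "character",
                 pmaDays = "numeric"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (ncol(object@signal) != length(object@channels))
    msg <- c(msg, "signal column count must match channel labels")
  if (length(object@fs) != 1 || object@fs <= 64)
    msg <- c(msg, "native sampling rate must be a single value > 64 Hz")
  missing <- setdiff(REQUIRED_ELECTRODES, object@channels)
  if (length(missing))
    msg <- c(msg, paste("missing required electrodes:",
                        paste(missing, collapse = ", ")))
  if (anyDuplicated(object@channels))
    msg <- c(msg, "duplicated channel labels")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param signal samples x channels numeric matrix in uV, referential to Cz.
#' @param channels electrode labels (defaults to \code{colnames(signal)}).
#' @param fs native sampling rate in Hz (> 64).
#' @param infantId,recordingId identifiers.
#' @param pmaDays post-menstrual age at recording start, in days.  Values
#'   outside [150, 290] trigger a warning (implausible for a preterm
#'   cohort).
#' @return An \linkS4class{EEGRecording}.
#' @examples
#' sig <- matrix(rnorm(8 * 2560), ncol = 8,
#'               dimnames = list(NULL, c("Fp1","Fp2","C3","C4","T3","T4","O1","O2")))
#' rec <- EEGRecording(sig, fs = 256, infantId = "i1", recordingId = "r1",
#'                     pmaDays = 200)
#' @export
EEGRecording <- function(signal, channels = colnames(signal), fs,
                         infantId, recordingId, pmaDays) {
  if (is.null(channels))
    stop("channel labels required (signal column names or `channels`)")
  colnames(signal) <- channels
  if (!all(is.finite(signal)))
    stop("invalid-signal: non-finite samples in recording ", recordingId)
  if (pmaDays < 150 || pmaDays > 290)
    warning("pmaDays = ", pmaDays,
            " is outside the realistic preterm range [150, 290]")
  new("EEGRecording", signal = signal, channels = channels, fs = fs,
      infantId = as.character(infantId),
      recordingId = as.character(recordingId), pmaDays = pmaDays)
}

#' BipolarEpoch: one analysis epoch in the bipolar montage
#'
#' A fixed-length window of band-passed, 64 Hz EEG in a bipolar montage,
#' with the referential signals retained for the referential artefact rule.
#'
#' @slot bipolar numeric matrix, samples x derivations, uV.
#' @slot referential numeric matrix, samples x electrodes, uV (same window).
#' @slot channelLabels derivation labels, e.g. \code{"Fp1-C3"}.
#' @slot fs sampling rate (64 Hz).
#' @slot startOffset seconds from recording start.
#' @slot infantId,recordingId,pmaDays provenance of the parent recording.
#'
#' @exportClass BipolarEpoch
setClass("BipolarEpoch",
  representation(bipolar = "matrix", referential = "matrix",
                 channelLabels = "character", fs = "numeric",
                 startOffset = "numeric", infantId = "character",
                 recordingId = "character", pmaDays = "numeric"))

setValidity("BipolarEpoch", function(object) {
  msg <- character()
  if (ncol(object@bipolar) != length(object@channelLabels))
    msg <- c(msg, "bipolar column count must match channel labels")
  if (length(object@fs) != 1 || object@fs != 64)
    msg <- c(msg, "epoch sampling rate must be 64 Hz")
  if (nrow(object@referential) != nrow(object@bipolar))
    msg <- c(msg, "referential and bipolar windows differ in length")
  if (length(msg)) msg else TRUE
})

#' SATAnnotation: spontaneous activity transient intervals
#'
#' Per-channel SAT intervals plus the epoch-level consensus annotation
#' (intervals supported by at least half of the valid channels).  Intervals
#' are stored at sample resolution as \link[IRanges]{IRanges}.
#'
#' @slot channel named list of \code{IRanges}, one per derivation.
#' @slot consensus \code{IRanges}, the consensus annotation.
#' @slot fs sampling rate the sample indices refer to.
#' @slot nSamples epoch length in samples.
#'
#' @exportClass SATAnnotation
setClass("SATAnnotation",
  representation(channel = "list", consensus = "IRanges", fs = "numeric",
                 nSamples = "integer"))

setValidity("SATAnnotation", function(object) {
  msg <- character()
  for (ch in names(object@channel)) {
    ir <- object@channel[[ch]]
    if (!is(ir, "IRanges")) {
      msg <- c(msg, paste0("channel ", ch, " is not an IRanges"))
      next
    }
    if (length(ir)) {
      if (is.unsorted(IRanges::start(ir)))
        msg <- c(msg, paste0("channel ", ch, " intervals not sorted"))
      if (min(IRanges::start(ir)) < 1 ||
          max(IRanges::end(ir)) > object@nSamples)
        msg <- c(msg, paste0("channel ", ch, " intervals outside epoch"))
      if (length(ir) > 1 &&
          any(IRanges::start(ir)[-1] <= IRanges::end(ir)[-length(ir)]))
        msg <- c(msg, paste0("channel ", ch, " intervals overlap"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ArtefactReport: outcome of the amplitude artefact rules for one epoch
#'
#' @slot excludedChannels derivation labels excluded by the low-amplitude
#'   rules.
#' @slot exclusionReason named character,
#'   \code{"low-amplitude-bipolar"} or
#'   \code{"low-amplitude-referential-derived"} per excluded channel.
#' @slot artefactIntervals \code{IRanges} of artefactual (high-amplitude)
#'   SAT time, union over channels, sample resolution.
#' @slot contamFraction fraction of the epoch covered by artefactual SATs.
#' @slot accepted logical; TRUE iff no channel excluded and contamination
#'   at most the configured bound.
#'
#' @exportClass ArtefactReport
setClass("ArtefactReport",
  representation(excludedChannels = "character", exclusionReason = "character",
                 artefactIntervals = "IRanges", contamFraction = "numeric",
                 accepted = "logical"))

setValidity("ArtefactReport", function(object) {
  msg <- character()
  if (object@contamFraction < 0 || object@contamFraction > 1)
    msg <- c(msg, "contamination fraction outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' FeatureSet: per-epoch maturational features
#'
#' A thin wrapper around \link[SummarizedExperiment]{SummarizedExperiment}
#' holding the 46-feature matrix (features x epochs, assay
#' \code{"features"}) with per-epoch provenance (\code{infant_id},
#' \code{recording_id}, \code{epoch_index}, \code{pma_days},
#' \code{n_valid_channels}) in \code{colData}.
#'
#' @exportClass FeatureSet
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  msg <- character()
  if (!identical(rownames(object), featureRoster()))
    msg <- c(msg, "rownames must be the canonical 46-feature roster")
  need <- c("infant_id", "recording_id", "epoch_index", "pma_days")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData lacks:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' EMAModel: a fitted EEG maturational age regressor
#'
#' Support vector regression model with its selected feature subset,
#' training-fold standardisation constants and imputation medians.
#'
#' @slot fit fitted \code{e1071::svm} object (radial kernel,
#'   eps-regression).
#' @slot features selected feature names, a subset of
#'   \code{featureRoster()}.
#' @slot center,scale named numeric, training-fold mean and sd per selected
#'   feature.
#' @slot imputeMedians named numeric, training-fold medians used to fill
#'   missing feature values.
#' @slot hyper list with elements \code{cost}, \code{epsilon},
#'   \code{gamma}.
#' @slot trainInfo list of training metadata (fold id, seed, inner-CV MSE).
#'
#' @exportClass EMAModel
setClass("EMAModel",
  representation(fit = "ANY", features = "character", center = "numeric",
                 scale = "numeric", imputeMedians = "numeric",
                 hyper = "list", trainInfo = "list"))

setValidity("EMAModel", function(object) {
  msg <- character()
  if (!all(object@features %in% featureRoster()))
    msg <- c(msg, "selected features must belong to the 46-feature roster")
  if (any(object@scale[object@features] <= 0))
    msg <- c(msg, "standardisation sd must be > 0 for selected features")
  if (length(msg)) msg else TRUE
})
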