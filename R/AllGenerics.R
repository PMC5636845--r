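#' Accessors for neoEMA objects
#'
#' @param object an \linkS4class{EEGRecording}, \linkS4class{BipolarEpoch},
#'   \linkS4class{SATAnnotation}, \linkS4class{ArtefactReport} or
#'   \linkS4class{EMAModel}.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("infantId", function(object) standardGeneric("infantId"))
#' @rdname accessors
#' @export
setGeneric("recordingId", function(object) standardGeneric("recordingId"))
#' @rdname accessors
#' @export
setGeneric("pmaDays", function(object) standardGeneric("pmaDays"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("epochAccepted", function(object) standardGeneric("epochAccepted"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname accessors
setMethod("infantId", "EEGRecording", function(object) object@infantId)
#' @rdname accessors
setMethod("infantId", "BipolarEpoch", function(object) object@infantId)
#' @rdname accessors
setMethod("recordingId", "EEGRecording", function(object) object@recordingId)
#' @rdname accessors
setMethod("recordingId", "BipolarEpoch", function(object) object@recordingId)
#' @rdname accessors
setMethod("pmaDays", "EEGRecording", function(object) object@pmaDays)
#' @rdname accessors
setMethod("pmaDays", "BipolarEpoch", function(object) object@pmaDays)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "BipolarEpoch", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "SATAnnotation", function(object) object@fs)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(object) object@channels)
#' @rdname accessors
setMethod("channelLabels", "BipolarEpoch", function(object) object@channelLabels)
#' @rdname accessors
setMethod("epochAccepted", "ArtefactReport", function(object) object@accepted)
#' @rdname accessors
setMethod("selectedFeatures", "EMAModel", function(object) object@features)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording", object@recordingId, "(infant", object@infantId, ")\n")
  cat(sprintf("  %d channels x %.1f s @ %g Hz, PMA %.0f d (%.1f wk)\n",
              ncol(object@signal), nrow(object@signal) / object@fs,
              object@fs, object@pmaDays, object@pmaDays / 7))
  cat("  electrodes:", paste(object@channels, collapse = " "), "\n")
})

setMethod("show", "BipolarEpoch", function(object) {
  cat("BipolarEpoch of", object@recordingId,
      sprintf("@ %.0f s (%.0f s long, %g Hz)\n", object@startOffset,
              nrow(object@bipolar) / object@fs, object@fs))
  cat("  derivations:", paste(object@channelLabels, collapse = " "), "\n")
})

setMethod("show", "SATAnnotation", function(object) {
  ncons <- length(object@consensus)
  cat(sprintf("SATAnnotation: %d channels, %d consensus SATs (%.1f%% coverage)\n",
              length(object@channel), ncons,
              100 * sum(IRanges::width(object@consensus)) / object@nSamples))
})

setMethod("show", "ArtefactReport", function(object) {
  cat("ArtefactReport:", if (object@accepted) "ACCEPTED" else "REJECTED", "\n")
  cat(sprintf("  contamination %.1f%%; %d channel(s) excluded%s\n",
              100 * object@contamFraction, length(object@excludedChannels),
              if (length(object@excludedChannels))
                paste0(" (", paste(object@excludedChannels, collapse = ", "), ")")
              else ""))
})

setMethod("show", "EMAModel", function(object) {
  cat("EMAModel:", length(object@features), "features,",
      sprintf("C=%g eps=%g gamma=%g\n", object@hyper$cost,
              object@hyper$epsilon, object@hyper$gamma))
})
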