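#' Construct a FeatureSet
#'
#' @param values numeric matrix, 46 roster features x epochs.
#' @param colData data.frame or DataFrame of per-epoch provenance
#'   (\code{infant_id}, \code{recording_id}, \code{epoch_index},
#'   \code{pma_days}, ...).
#' @return A \linkS4class{FeatureSet}.
#' @export
FeatureSet <- function(values, colData) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    colData = S4Vectors::DataFrame(colData))
  new("FeatureSet", se)
}

#' Flatten features to the tabular contract
#'
#' One row per epoch: provenance columns followed by the 46 feature
#' columns.  This table is the interface between feature extraction and
#' modelling (and the CSV format of \code{\link{writeFeatureCSV}}).
#'
#' @param x a \linkS4class{FeatureSet} or an already-flat data.frame
#'   (validated to contain the provenance and roster columns).
#' @return data.frame.
#' @export
featureTable <- function(x) {
  if (is(x, "FeatureSet")) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    ft <- as.data.frame(t(SummarizedExperiment::assay(x, "features")))
    rownames(cd) <- rownames(ft) <- NULL
    return(cbind(cd, ft))
  }
  x <- as.data.frame(x)
  need <- c("infant_id", "recording_id", "pma_days", featureRoster())
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("feature table lacks column(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  x
}

#' Run the full extraction pipeline on a set of recordings
#'
#' For every recording: preprocess (filter, resample, bipolar montage,
#' epoch segmentation), annotate SATs, apply the artefact rules, and
#' extract the 46-feature vector from each accepted epoch.  Rejected
#' epochs are counted, not extracted; recordings shorter than one epoch or
#' with no accepted epoch are dropped with a message.
#'
#' @param recordings list of \linkS4class{EEGRecording}.
#' @param params \code{\link{emaParams}}.
#' @param montage electrode-pair matrix (default the standard 8
#'   derivations).
#' @param verbose emit a message per rejected epoch / dropped recording.
#' @return A \linkS4class{FeatureSet}; its \code{metadata} holds an
#'   \code{artefact_summary} data.frame (one row per epoch:
#'   \code{recording_id}, \code{epoch_index}, \code{accepted},
#'   \code{n_channels_excluded}, \code{contamination_fraction}).
#' @export
buildFeatureSet <- function(recordings, params = emaParams(),
                            montage = standardMontage(), verbose = FALSE) {
  vals <- list(); prov <- NULL; art <- NULL
  for (rec in recordings) {
    epochs <- preprocessRecording(rec, params, montage)
    for (k in seq_along(epochs)) {
      ep <- epochs[[k]]
      ann <- annotateSATs(ep, params)
      rep_ <- artefactReport(ep, ann, params)
      art <- rbind(art, data.frame(
        recording_id = ep@recordingId, epoch_index = k,
        accepted = rep_@accepted,
        n_channels_excluded = length(rep_@excludedChannels),
        contamination_fraction = rep_@contamFraction))
      if (!rep_@accepted) {
        if (verbose)
          message("epoch ", k, " of ", ep@recordingId, " rejected (",
                  length(rep_@excludedChannels), " channel(s) excluded, ",
                  sprintf("%.1f%%", 100 * rep_@contamFraction),
                  " contaminated)")
        next
      }
      mask <- suppressWarnings(
        lowSATSegment(satPercent(ann, params), params))
      fv <- extractFeatures(ep, ann, mask, rep_, params)
      vals[[length(vals) + 1L]] <- fv
      prov <- rbind(prov, data.frame(
        infant_id = ep@infantId, recording_id = ep@recordingId,
        epoch_index = k, pma_days = ep@pmaDays,
        start_offset_s = ep@startOffset,
        n_valid_channels = attr(fv, "n_valid_channels")))
    }
  }
  if (!length(vals))
    stop("no accepted epochs in the supplied recordings")
  m <- do.call(cbind, lapply(vals, as.numeric))
  rownames(m) <- featureRoster()
  colnames(m) <- paste0(prov$recording_id, "_e", prov$epoch_index)
  fs <- FeatureSet(m, prov)
  S4Vectors::metadata(fs)$artefact_summary <- art
  fs
}

#' Write the feature table CSV
#'
#' @param x \linkS4class{FeatureSet} or feature table data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureCSV <- function(x, path) {
  utils::write.csv(featureTable(x), path, row.names = FALSE)
  invisible(path)
}

#' Write SAT annotations as CSV
#'
#' One row per interval: \code{epoch_id}, \code{channel} (or
#' \code{"consensus"}), \code{onset_s}, \code{duration_s}.
#'
#' @param ann a \linkS4class{SATAnnotation}.
#' @param epoch_id identifier written in the first column.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSATAnnotationCSV <- function(ann, epoch_id, path) {
  fs <- ann@fs
  rows <- function(ir, ch) {
    if (!length(ir)) return(NULL)
    data.frame(epoch_id = epoch_id, channel = ch,
               onset_s = (IRanges::start(ir) - 1) / fs,
               duration_s = IRanges::width(ir) / fs)
  }
  out <- do.call(rbind, c(
    lapply(names(ann@channel), function(ch) rows(ann@channel[[ch]], ch)),
    list(rows(ann@consensus, "consensus"))))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
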