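#' High-amplitude SAT artefact rule
#'
#' A SAT interval on any channel that contains a sample with \code{|v|}
#' above the voltage bound (500 uV by default) is artefactual -- typical of
#' movement or electrode-pop contamination.  The epoch-level contamination
#' is the union of artefactual intervals over channels.
#'
#' @param epoch a \linkS4class{BipolarEpoch} (rule evaluated on the
#'   filtered 64 Hz signal, where the annotations live).
#' @param ann a \linkS4class{SATAnnotation} with per-channel intervals.
#' @param params \code{\link{emaParams}}.
#' @return List with \code{intervals} (\code{IRanges}, union over
#'   channels), \code{fraction} (covered seconds / epoch seconds) and
#'   \code{perChannel} (list of artefactual \code{IRanges} per channel).
#' @export
flagHighAmplitudeSATs <- function(epoch, ann, params = emaParams()) {
  n <- nrow(epoch@bipolar)
  per <- lapply(names(ann@channel), function(ch) {
    ir <- ann@channel[[ch]]
    if (!length(ir)) return(IRanges::IRanges())
    x <- epoch@bipolar[, ch]
    bad <- vapply(seq_along(ir), function(i) {
      max(abs(x[IRanges::start(ir)[i]:IRanges::end(ir)[i]])) >
        params$high_amp_uv
    }, logical(1))
    ir[bad]
  })
  names(per) <- names(ann@channel)
  all_bad <- IRanges::reduce(do.call(c, unname(per)))
  list(intervals = all_bad,
       fraction = sum(IRanges::width(all_bad)) / n,
       perChannel = per)
}

#' Low-amplitude channel rules
#'
#' Detects electrode shorting (electrodes placed too closely together),
#' which depresses the amplitude of the affected channels for the whole
#' epoch.  Two clauses, both on the amplitude envelope (magnitude of the
#' analytic associate):
#' \itemize{
#'   \item bipolar: a derivation is excluded if its median envelope over
#'     time is less than half the median envelope over time and channels.
#'     When several channels are depressed the pooled median is itself
#'     dragged down, so the rule iterates to a fixed point, removing the
#'     lowest-amplitude violating channel first and re-pooling.
#'   \item referential: an electrode is flagged if its median envelope is
#'     less than half the pooled referential median \emph{and} the 95th
#'     percentile of its envelope is below 25 uV; every derivation using a
#'     flagged electrode is excluded.
#' }
#' Ties (exactly 50\%, exactly 25 uV) are non-exclusions: the rules use
#' strict inequalities.
#'
#' @param epoch a \linkS4class{BipolarEpoch}.
#' @param params \code{\link{emaParams}}.
#' @return List with \code{excluded} (derivation labels) and \code{reason}
#'   (named character).
#' @export
flagLowAmplitudeChannels <- function(epoch, params = emaParams()) {
  env_bip <- apply(epoch@bipolar, 2, envelope)
  med_bip <- apply(env_bip, 2, stats::median)
  labs <- epoch@channelLabels

  excluded <- character()
  active <- labs
  repeat {
    if (!length(active)) break
    pooled <- stats::median(env_bip[, active])
    if (pooled < 1e-9) {           # degenerate: everything flat
      excluded <- union(excluded, active)
      break
    }
    viol <- active[med_bip[active] < params$lowamp_ratio * pooled]
    if (!length(viol)) break
    worst <- viol[which.min(med_bip[viol])]
    excluded <- c(excluded, worst)
    active <- setdiff(active, worst)
  }
  reason <- stats::setNames(rep("low-amplitude-bipolar", length(excluded)),
                            excluded)

  env_ref <- apply(epoch@referential, 2, envelope)
  med_ref <- apply(env_ref, 2, stats::median)
  pooled_ref <- stats::median(env_ref)
  p95_ref <- apply(env_ref, 2, stats::quantile, probs = 0.95, names = FALSE)
  flagged <- colnames(epoch@referential)[
    med_ref < params$lowamp_ratio * pooled_ref & p95_ref < params$ref_p95_uv]
  if (length(flagged)) {
    uses <- labs[vapply(strsplit(labs, "-", fixed = TRUE),
                        function(p) any(p %in% flagged), logical(1))]
    add <- setdiff(uses, excluded)
    reason <- c(reason,
                stats::setNames(rep("low-amplitude-referential-derived",
                                    length(add)), add))
    excluded <- union(excluded, uses)
  }
  list(excluded = excluded, reason = reason)
}

#' Evaluate both artefact rules on an epoch
#'
#' @param epoch a \linkS4class{BipolarEpoch}.
#' @param ann a \linkS4class{SATAnnotation}; computed with
#'   \code{\link{annotateSATs}} when omitted.
#' @param params \code{\link{emaParams}}.
#' @return An \linkS4class{ArtefactReport}.  The epoch is accepted iff no
#'   channel is excluded and at most 20\% of the epoch is contaminated by
#'   high-amplitude artefact.
#' @export
artefactReport <- function(epoch, ann = NULL, params = emaParams()) {
  if (is.null(ann)) ann <- annotateSATs(epoch, params)
  high <- flagHighAmplitudeSATs(epoch, ann, params)
  low <- flagLowAmplitudeChannels(epoch, params)
  new("ArtefactReport",
      excludedChannels = low$excluded,
      exclusionReason = low$reason,
      artefactIntervals = high$intervals,
      contamFraction = high$fraction,
      accepted = length(low$excluded) == 0 &&
                 high$fraction <= params$contam_max)
}

#' Accept or reject an epoch from its artefact report
#'
#' @param report an \linkS4class{ArtefactReport}.
#' @return Logical: accepted iff zero excluded channels and contamination
#'   fraction at most the configured bound (default 0.20; "more than 20\%"
#'   rejects, exactly 20\% does not).
#' @export
epochAccept <- function(report) report@accepted
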