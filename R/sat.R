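#' Smoothed nonlinear energy operator
#'
#' The cross-form (Teager-like) nonlinear energy operator with rectification,
#' \deqn{\psi[n] = | x[n] x[n-3] - x[n-1] x[n-2] |,}
#' smoothed by a centred moving average (default 1.5 s).  The NLEO responds
#' to the product of squared amplitude and frequency, which makes the
#' high-amplitude SAT bursts of preterm EEG stand far out of the
#' low-amplitude inter-SAT background.  Edge samples (first three, and the
#' moving-average margins) are zero-padded so the output has the input
#' length.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param smooth_s moving-average length in seconds.
#' @return Nonnegative numeric vector, \code{length(x)}.
#' @examples
#' nleo(rep(3, 100), 64)        # constant signal -> all zero
#' @export
nleo <- function(x, fs, smooth_s = 1.5) {
  n <- length(x)
  if (n < 4) stop("sequence too short for the nonlinear energy operator")
  psi <- numeric(n)
  i <- 4:n
  psi[i] <- abs(x[i] * x[i - 3L] - x[i - 1L] * x[i - 2L])
  k <- max(1L, round(smooth_s * fs))
  pad <- numeric(k)
  sm <- stats::filter(c(pad, psi, pad), rep(1 / k, k), sides = 2)
  as.numeric(sm[(k + 1):(k + n)])
}

ir_from_logical <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  IRanges::IRanges(start = starts[r$values], end = ends[r$values])
}

#' Detect spontaneous activity transients on one channel
#'
#' Samples where the smoothed NLEO exceeds the detection threshold form
#' candidate intervals; below-threshold gaps shorter than the merge gap are
#' bridged, then intervals shorter than the minimum SAT duration are
#' dropped.  Returns sample-resolution intervals, sorted and disjoint.
#'
#' @param x numeric vector, one filtered 64 Hz channel, uV.
#' @param fs sampling rate in Hz.
#' @param params \code{\link{emaParams}} (threshold, minimum duration,
#'   merge gap, smoothing length).
#' @return An \link[IRanges]{IRanges} of SAT intervals (sample indices).
#' @examples
#' detectSATs(numeric(640), 64)     # silent channel -> no SATs
#' @export
detectSATs <- function(x, fs = 64, params = emaParams()) {
  psi <- nleo(x, fs, params$nleo_smooth_s)
  above <- psi > params$sat_threshold
  if (!any(above)) return(IRanges::IRanges())
  ir <- ir_from_logical(above)
  # the long centred smoother advances/delays boundaries by up to half its
  # length; refine them on a short (0.25 s) smoother inside each candidate
  psi_f <- nleo(x, fs, 0.25)
  st <- IRanges::start(ir); en <- IRanges::end(ir)
  for (i in seq_along(ir)) {
    idx <- st[i]:en[i]
    # relative floor keeps the refinement from latching onto broadband
    # noise inside the smoothing margin
    thr <- max(params$sat_threshold, 0.1 * max(psi_f[idx]))
    hot <- idx[psi_f[idx] > thr]
    if (length(hot)) { st[i] <- hot[1]; en[i] <- hot[length(hot)] }
  }
  ir <- IRanges::IRanges(st, en)
  gap <- round(params$sat_merge_gap_s * fs)
  if (gap > 0) ir <- IRanges::reduce(ir, min.gapwidth = gap + 1L)
  ir[IRanges::width(ir) >= round(params$sat_min_dur_s * fs)]
}

#' Annotate SATs on every channel of an epoch, with a consensus
#'
#' Runs \code{\link{detectSATs}} per bipolar derivation and builds the
#' epoch-level consensus annotation: the set of samples where at least half
#' of the (non-excluded) channels detect SAT activity.  SATs are spatially
#' widespread events, so the consensus drives SAT\%, SAT-timing features and
#' the low-SAT\% segmentation, while the per-channel annotations feed the
#' high-amplitude artefact rule.
#'
#' @param epoch a \linkS4class{BipolarEpoch}.
#' @param params \code{\link{emaParams}}.
#' @param exclude channel labels to leave out of the consensus (e.g.
#'   artefact-excluded channels).
#' @return A \linkS4class{SATAnnotation}.
#' @export
annotateSATs <- function(epoch, params = emaParams(), exclude = character()) {
  labs <- epoch@channelLabels
  ann <- lapply(seq_along(labs), function(j)
    detectSATs(epoch@bipolar[, j], epoch@fs, params))
  names(ann) <- labs
  new("SATAnnotation", channel = ann,
      consensus = consensusSAT(ann[setdiff(labs, exclude)],
                               nrow(epoch@bipolar)),
      fs = epoch@fs, nSamples = nrow(epoch@bipolar))
}

#' Consensus SAT intervals across channels
#'
#' @param annList named list of per-channel \code{IRanges}.
#' @param nSamples epoch length in samples.
#' @param minChannels minimum number of supporting channels; default half
#'   of the channels, rounded up.
#' @return \code{IRanges} of consensus intervals.
#' @export
consensusSAT <- function(annList, nSamples,
                         minChannels = ceiling(length(annList) / 2)) {
  if (!length(annList)) return(IRanges::IRanges())
  cov <- Reduce(`+`, lapply(annList, IRanges::coverage, width = nSamples))
  sl <- IRanges::slice(cov, lower = minChannels, rangesOnly = TRUE)
  IRanges::reduce(sl)
}

#' SAT percentage trace
#'
#' Fraction of each sliding window covered by consensus SAT activity,
#' expressed in percent.  The standard analysis uses a 5-minute window
#' advancing by 1 minute (4-minute overlap) over the 1-h epoch, giving 56
#' windows.
#'
#' @param consensus \code{IRanges} of consensus SAT intervals (samples), or
#'   a \linkS4class{SATAnnotation}.
#' @param params \code{\link{emaParams}}.
#' @param nSamples epoch length in samples (taken from the annotation when
#'   one is supplied).
#' @return data.frame with \code{window_start_s} and \code{sat_percent}.
#' @examples
#' ann <- IRanges::IRanges(1, 150 * 64)   # one SAT covering [0, 150) s
#' satPercent(ann, emaParams(), nSamples = 3600 * 64)[1:2, ]
#' @export
satPercent <- function(consensus, params = emaParams(), nSamples = NULL) {
  if (is(consensus, "SATAnnotation")) {
    nSamples <- consensus@nSamples
    consensus <- consensus@consensus
  }
  fs <- params$fs
  stopifnot(!is.null(nSamples))
  win <- round(params$satp_win_s * fs)
  step <- round(params$satp_step_s * fs)
  starts <- seq(0L, nSamples - win, by = step)
  covered <- cumsum(as.numeric(
    IRanges::coverage(consensus, width = nSamples) > 0))
  covered <- c(0, covered)
  satp <- 100 * (covered[starts + win + 1L] - covered[starts + 1L]) / win
  data.frame(window_start_s = starts / fs, sat_percent = satp)
}

#' Delimit the low-SAT\% (quiet-sleep proxy) segment
#'
#' Quiet sleep in preterm infants shows discontinuous EEG with low SAT\%.
#' The segment is defined from the SAT\% trace by thresholding at the 25th
#' percentile, eliminating below-threshold runs shorter than the minimum
#' run length (5 min at full epoch scale), and -- in the default two-pass
#' reading -- recomputing the 25th-percentile threshold from the remaining
#' windows before emitting the final mask.
#'
#' @param trace data.frame from \code{\link{satPercent}}.
#' @param params \code{\link{emaParams}}.
#' @return Logical vector, one element per second of the epoch; TRUE marks
#'   the low-SAT\% segment.
#' @export
lowSATSegment <- function(trace, params = emaParams()) {
  v <- trace$sat_percent
  if (length(v) < 4) stop("SAT% trace too short (need >= 4 windows)")
  epoch_s <- round(params$epoch_s)
  win <- params$satp_win_s
  step <- params$satp_step_s
  if (max(v) - min(v) < .Machine$double.eps^0.5) {
    warning("constant SAT% trace: no discrimination possible, ",
            "marking the whole epoch as low-SAT%")
    return(rep(TRUE, epoch_s))
  }
  run_info <- function(below) {
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
  }
  # run duration = time the trace stays below threshold (windows x step);
  # the window span itself always exceeds the window length, which would
  # make the minimum-duration rule vacuous
  run_dur <- function(runs)
    (runs[, "end"] - runs[, "start"] + 1) * step

  t1 <- stats::quantile(v, 0.25, names = FALSE)
  below1 <- v <= t1
  runs <- run_info(below1)
  long <- run_dur(runs) >= params$lowsat_min_run_s
  if (!any(long)) {
    warning("no low-SAT% run reaches the minimum duration; ",
            "using the longest below-threshold run")
    long <- seq_len(nrow(runs)) == which.max(run_dur(runs))
  }
  surviving <- runs[long, , drop = FALSE]
  in_surviving <- rep(FALSE, length(v))
  for (i in seq_len(nrow(surviving)))
    in_surviving[surviving[i, 1]:surviving[i, 2]] <- TRUE

  if (params$lowsat_method == "two_pass") {
    eliminated <- below1 & !in_surviving
    t2 <- stats::quantile(v[!eliminated], 0.25, names = FALSE)
    final_win <- in_surviving & v <= t2
    if (!any(final_win)) final_win <- in_surviving
  } else {
    final_win <- in_surviving
  }

  mask <- rep(FALSE, epoch_s)
  for (w in which(final_win)) {
    s0 <- trace$window_start_s[w]
    idx <- (floor(s0) + 1):min(epoch_s, floor(s0) + win)
    mask[idx] <- TRUE
  }
  mask
}
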