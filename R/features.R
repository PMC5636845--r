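FEATURE_BASE <- c("env_p50", "env_p95",
                  "reeg_p5", "reeg_p50", "reeg_p95",
                  "pow_total", "pow_delta", "pow_theta", "pow_alpha",
                  "pow_beta", "relpow_delta", "relpow_theta",
                  "relpow_alpha", "relpow_beta",
                  "sats_per_hour", "sat_dur_p5", "sat_dur_p50", "sat_dur_p95",
                  "isi_p5", "isi_p50", "isi_p95", "isi_rms", "asi")

#' The canonical 46-feature roster
#'
#' 23 computational features, each estimated on the full epoch
#' (\code{_full}) and on the low-SAT\% segment (\code{_lowsat}): envelope
#' percentiles (50, 95), range-EEG percentiles (5, 50, 95), absolute and
#' relative band powers (delta 0--3, theta 3--8, alpha 8--15, beta 15--30
#' Hz, plus total 0--30 Hz), SAT timing statistics (SATs per hour, SAT
#' duration percentiles 5/50/95, inter-SAT interval percentiles 5/50/95 and
#' RMS) and the activation synchrony index.  The roster order is canonical:
#' ties in feature selection are broken towards the lower index.
#'
#' @return Character vector of 46 feature names.
#' @examples
#' head(featureRoster())
#' @export
featureRoster <- function() {
  c(paste0(FEATURE_BASE, "_full"), paste0(FEATURE_BASE, "_lowsat"))
}

#' Amplitude envelope (magnitude of the analytic associate)
#'
#' Computes the analytic signal via the frequency-domain Hilbert
#' transformer and returns its magnitude per sample.
#'
#' @param x numeric vector.
#' @return Nonnegative numeric vector, \code{length(x)}.
#' @examples
#' e <- envelope(sin(2 * pi * 10 * seq(0, 2, by = 1/64)))
#' median(e)   # ~1
#' @export
envelope <- function(x) {
  n <- length(x)
  if (n < 2) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Range-EEG: per-window peak-to-peak amplitude
#'
#' The range EEG summarises the amplitude distribution as the
#' peak-to-peak voltage in consecutive non-overlapping windows (2 s by
#' convention).  A trailing partial window is dropped.
#'
#' @param x numeric vector, uV.
#' @param fs sampling rate in Hz.
#' @param win_s window length in seconds.
#' @return Numeric vector of per-window max minus min, uV.
#' @examples
#' reeg(sin(2 * pi * 2 * seq(0, 10, by = 1/64)), 64)   # all ~2
#' @export
reeg <- function(x, fs = 64, win_s = 2) {
  L <- round(win_s * fs)
  k <- floor(length(x) / L)
  if (k < 1) stop("signal shorter than one range-EEG window")
  m <- matrix(x[seq_len(k * L)], nrow = L)
  apply(m, 2, max) - apply(m, 2, min)
}

# Welch averaged periodogram over 50%-overlapping Hamming-tapered segments.
# `maskIR` (sample-resolution IRanges) restricts segments to those fully
# inside a masked block; NULL means the whole signal.
welchPSD <- function(x, fs, win_s = 2, maskIR = NULL) {
  L <- round(win_s * fs)
  half <- floor(L / 2)
  blocks <- if (is.null(maskIR))
    cbind(1L, length(x))
  else
    cbind(IRanges::start(maskIR), IRanges::end(maskIR))
  starts <- integer()
  for (i in seq_len(nrow(blocks))) {
    b0 <- blocks[i, 1]; b1 <- blocks[i, 2]
    if (b1 - b0 + 1L >= L)
      starts <- c(starts, seq(b0, b1 - L + 1L, by = half))
  }
  if (!length(starts)) return(NULL)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(L) / (L + 1))   # Hamming
  seg <- vapply(starts, function(s) x[s:(s + L - 1L)] * w, numeric(L))
  P <- Mod(stats::mvfft(seg))^2 / (fs * sum(w^2))
  nf <- floor(L / 2) + 1L
  psd <- rowMeans(P)[seq_len(nf)]
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]      # one-sided
  list(f = (seq_len(nf) - 1L) * fs / L, psd = psd, df = fs / L)
}

#' Spectral band powers
#'
#' Welch power spectral density (2 s Hamming segments, 50\% overlap)
#' integrated over the delta (0--3 Hz), theta (3--8), alpha (8--15) and
#' beta (15--30) bands.  Total power is the 0--30 Hz integral (the sum of
#' the four bands), and relative powers are each band divided by the
#' total, so they sum to 1.
#'
#' @param x numeric vector, uV.
#' @param fs sampling rate in Hz.
#' @param params \code{\link{emaParams}} (band edges, Welch window).
#' @param maskIR optional sample-resolution \code{IRanges} restricting the
#'   estimate to masked blocks.
#' @return Named numeric of length 9: \code{pow_total}, \code{pow_*},
#'   \code{relpow_*}.  A zero signal yields zero absolute powers and
#'   \code{NA} relative powers.
#' @examples
#' bp <- bandPowers(sin(2 * pi * 10 * seq(0, 64, by = 1/64)), 64)
#' bp["relpow_alpha"]   # ~1
#' @export
bandPowers <- function(x, fs = 64, params = emaParams(), maskIR = NULL) {
  out <- stats::setNames(rep(NA_real_, 9),
    c("pow_total", "pow_delta", "pow_theta", "pow_alpha", "pow_beta",
      "relpow_delta", "relpow_theta", "relpow_alpha", "relpow_beta"))
  W <- welchPSD(x, fs, params$welch_win_s, maskIR)
  if (is.null(W)) return(out)
  absp <- vapply(params$bands, function(b)
    sum(W$psd[W$f >= b[1] & W$f < b[2]]) * W$df, numeric(1))
  total <- sum(absp)
  out[paste0("pow_", names(absp))] <- absp
  out["pow_total"] <- total
  if (total > 0) out[paste0("relpow_", names(absp))] <- absp / total
  out
}

SAT_STAT_NAMES <- c("sats_per_hour", "sat_dur_p5", "sat_dur_p50",
                    "sat_dur_p95", "isi_p5", "isi_p50", "isi_p95", "isi_rms")

irIndices <- function(ir)
  unlist(mapply(seq.int, IRanges::start(ir), IRanges::end(ir),
                SIMPLIFY = FALSE), use.names = FALSE)

# per-second mask -> sample-resolution IRanges
maskToSampleIR <- function(maskSeconds, fs) {
  if (is.null(maskSeconds)) return(NULL)
  ir <- ir_from_logical(maskSeconds)
  IRanges::IRanges(start = (IRanges::start(ir) - 1L) * fs + 1L,
                   end = IRanges::end(ir) * fs)
}

#' SAT timing statistics
#'
#' Counts and duration/interval statistics of consensus SATs within an
#' analysis segment.  Inter-SAT intervals (ISIs) are the gaps between the
#' offset of one SAT and the onset of the next, computed only between SATs
#' lying in the same contiguous segment block (gaps spanning a hole in the
#' low-SAT\% mask are not ISIs).
#'
#' @param consensus \code{IRanges} of consensus SAT intervals, samples.
#' @param fs sampling rate in Hz.
#' @param maskIR optional sample-resolution \code{IRanges} segment
#'   restriction; NULL means the full epoch.
#' @param nSamples epoch length in samples.
#' @return Named numeric of length 8: \code{sats_per_hour},
#'   \code{sat_dur_p5/p50/p95}, \code{isi_p5/p50/p95}, \code{isi_rms}.
#'   ISI entries are \code{NA} when fewer than two SATs fall in a block.
#' @examples
#' sats <- IRanges::IRanges(start = (0:59) * 640 + 1, width = 128)
#' satStats(sats, 64, nSamples = 64 * 600)["sats_per_hour"]   # 360
#' @export
satStats <- function(consensus, fs = 64, maskIR = NULL, nSamples) {
  out <- stats::setNames(rep(NA_real_, 8), SAT_STAT_NAMES)
  blocks <- if (is.null(maskIR)) IRanges::IRanges(1L, nSamples) else maskIR
  dur_s <- sum(IRanges::width(blocks)) / fs
  if (dur_s <= 0) return(out)
  sats <- IRanges::reduce(IRanges::intersect(consensus, blocks))
  out["sats_per_hour"] <- length(sats) * 3600 / dur_s
  if (!length(sats)) return(out)
  w <- IRanges::width(sats) / fs
  out[c("sat_dur_p5", "sat_dur_p50", "sat_dur_p95")] <-
    stats::quantile(w, c(0.05, 0.5, 0.95), names = FALSE)
  hit <- IRanges::findOverlaps(sats, blocks, select = "first")
  isi <- numeric()
  for (b in unique(hit)) {
    s <- sats[which(hit == b)]
    if (length(s) >= 2)
      isi <- c(isi, (IRanges::start(s)[-1] -
                     IRanges::end(s)[-length(s)] - 1L) / fs)
  }
  if (length(isi)) {
    out[c("isi_p5", "isi_p50", "isi_p95")] <-
      stats::quantile(isi, c(0.05, 0.5, 0.95), names = FALSE)
    out["isi_rms"] <- sqrt(mean(isi^2))
  }
  out
}

#' Activation synchrony index
#'
#' Interhemispheric co-occurrence of SAT activity.  Per homologous
#' derivation pair (e.g. Fp1-T3 vs Fp2-T4), both channels' SAT annotations
#' are binarised at 1 s resolution and the coincidence ratio
#' \deqn{CR = P(L \wedge R) / (P(L) P(R))} is computed from the empirical
#' fractions of active seconds; the index is the median CR over valid
#' pairs (pairs with a zero marginal are dropped).  CR is 1 under
#' independence, above 1 for synchronous and 0 for anti-phased activity.
#'
#' @param ann a \linkS4class{SATAnnotation} (per-channel intervals).
#' @param maskSeconds optional per-second logical restricting the analysis
#'   segment.
#' @return Scalar ASI, or \code{NA} if no pair is valid.
#' @export
activationSynchronyIndex <- function(ann, maskSeconds = NULL) {
  fs <- ann@fs
  n_sec <- floor(ann@nSamples / fs)
  labs <- names(ann@channel)
  active_sec <- function(ch) {
    cov <- as.numeric(IRanges::coverage(ann@channel[[ch]],
                                        width = ann@nSamples) > 0)
    csum <- c(0, cumsum(cov))
    (csum[seq_len(n_sec) * fs + 1L] - csum[(seq_len(n_sec) - 1L) * fs + 1L]) > 0
  }
  keep <- if (is.null(maskSeconds)) rep(TRUE, n_sec)
          else maskSeconds[seq_len(n_sec)]
  crs <- numeric()
  for (lab in leftLabels(labs)) {
    rlab <- homologueLabel(lab)
    if (!rlab %in% labs) next
    L <- active_sec(lab)[keep]
    R <- active_sec(rlab)[keep]
    pL <- mean(L); pR <- mean(R)
    if (pL == 0 || pR == 0) next
    crs <- c(crs, mean(L & R) / (pL * pR))
  }
  if (!length(crs)) return(NA_real_)
  stats::median(crs)
}

#' Extract the 46-feature vector from one accepted epoch
#'
#' Amplitude and spectral features are estimated per channel and summarised
#' with the median across non-excluded channels; SAT timing features come
#' from the consensus annotation; every feature is computed on the full
#' epoch and again restricted to the low-SAT\% segment.
#'
#' @param epoch a \linkS4class{BipolarEpoch}.
#' @param ann a \linkS4class{SATAnnotation}; computed if omitted.
#' @param mask per-second logical low-SAT\% mask; computed from the SAT\%
#'   trace if omitted.
#' @param report an \linkS4class{ArtefactReport}; computed if omitted.
#'   Its excluded channels are left out of the cross-channel medians.
#' @param params \code{\link{emaParams}}.
#' @return Named numeric of length 46 (see \code{\link{featureRoster}})
#'   with attributes \code{n_valid_channels} and \code{accepted}.  Features
#'   that cannot be estimated (e.g. fewer than two SATs in the segment)
#'   are \code{NA}; they are imputed with training-fold medians at model
#'   time.
#' @export
extractFeatures <- function(epoch, ann = NULL, mask = NULL, report = NULL,
                            params = emaParams()) {
  if (is.null(ann)) ann <- annotateSATs(epoch, params)
  if (is.null(report)) report <- artefactReport(epoch, ann, params)
  if (is.null(mask))
    mask <- lowSATSegment(satPercent(ann, params), params)
  fs <- epoch@fs
  n <- nrow(epoch@bipolar)
  valid <- setdiff(epoch@channelLabels, report@excludedChannels)
  if (!length(valid)) stop("no valid channels: epoch should be rejected")

  maskIR <- maskToSampleIR(mask, fs)
  segs <- list(full = NULL, lowsat = maskIR)
  med <- function(m) apply(m, 1, stats::median, na.rm = TRUE)

  per_channel <- vapply(valid, function(ch) {
    x <- epoch@bipolar[, ch]
    env <- envelope(x)
    rv <- reeg(x, fs, params$reeg_win_s)
    rv_starts <- (seq_along(rv) - 1L) * round(params$reeg_win_s * fs) + 1L
    rv_ir <- IRanges::IRanges(rv_starts,
                              width = round(params$reeg_win_s * fs))
    unlist(lapply(names(segs), function(sg) {
      ir <- segs[[sg]]
      env_seg <- if (is.null(ir)) env else env[irIndices(ir)]
      in_seg <- if (is.null(ir)) rep(TRUE, length(rv))
        else IRanges::overlapsAny(rv_ir, ir, type = "within")
      r_seg <- rv[in_seg]
      c(env = stats::quantile(env_seg, c(0.5, 0.95), names = FALSE),
        reeg = if (length(r_seg))
                 stats::quantile(r_seg, c(0.05, 0.5, 0.95), names = FALSE)
               else rep(NA_real_, 3),
        bandPowers(x, fs, params, ir))
    }))
  }, numeric(28))

  chan_med <- med(per_channel)    # 14 per segment, full block then lowsat
  vals <- stats::setNames(rep(NA_real_, 46), featureRoster())
  for (sg in c("full", "lowsat")) {
    off <- if (sg == "full") 0 else 14
    sfx <- paste0("_", sg)
    vals[paste0(c("env_p50", "env_p95", "reeg_p5", "reeg_p50", "reeg_p95"),
                sfx)] <- chan_med[off + 1:5]
    pw <- chan_med[off + 6:14]
    # cross-channel medians are not additive: renormalise the relative
    # powers so the four bands sum to one exactly
    rel_sum <- sum(pw[6:9])
    if (is.finite(rel_sum) && rel_sum > 0) pw[6:9] <- pw[6:9] / rel_sum
    vals[paste0(c("pow_total", "pow_delta", "pow_theta", "pow_alpha",
                  "pow_beta", "relpow_delta", "relpow_theta",
                  "relpow_alpha", "relpow_beta"), sfx)] <- pw
    ir <- segs[[sg]]
    vals[paste0(SAT_STAT_NAMES, sfx)] <- satStats(ann@consensus, fs, ir, n)
    vals[paste0("asi", sfx)] <-
      activationSynchronyIndex(ann, if (sg == "full") NULL else mask)
  }
  attr(vals, "n_valid_channels") <- length(valid)
  attr(vals, "accepted") <- report@accepted
  vals
}
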