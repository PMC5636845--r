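# Synthetic preterm-EEG cohort generator.  Emulates the two salient
# maturational trends of early preterm EEG -- shortening inter-SAT
# intervals and growing burst amplitude -- as piecewise burst/inter-burst
# activity on the standard 8-electrode referential layout, with known
# ground-truth burst schedules and injectable artefacts.

#' Configuration of a synthetic preterm cohort
#'
#' All maturational trends are linear in post-menstrual age between 24 and
#' 38 weeks; each is given as \code{c(value_at_24wk, value_at_38wk)}.
#' Defaults: mean inter-SAT interval 30 -> 6 s (strictly decreasing), mean
#' SAT duration 3 -> 5 s, burst amplitude 15 -> 35 uV RMS (strictly
#' increasing), inter-SAT floor 0.85 -> 1.15 uV RMS per referential electrode (about 1.2 -> 1.6 uV in the bipolar derivations), interhemispheric
#' synchrony probability 0.5 -> 0.9, and a burst spectral profile whose
#' beta weight rises with age.  A quiet-sleep block (30\% of the
#' recording) doubles the local inter-SAT interval, normalised so the
#' recording-wide mean ISI stays at its nominal value.
#'
#' @param n_infants number of infants.
#' @param recordings_min,recordings_max serial recordings per infant.
#' @param pma_min_wk,pma_max_wk cohort PMA range in weeks.
#' @param start_pma_min_wk,start_pma_max_wk PMA range of each infant's
#'   first recording.
#' @param spacing_min_d,spacing_max_d days between consecutive recordings.
#' @param rec_dur_s recording duration in seconds.
#' @param fs native sampling rate in Hz (256 exercises the resampling
#'   path).
#' @param isi_mean_s,sat_dur_mean_s,burst_rms_uv,floor_rms_uv,sync_prob
#'   trend endpoints, \code{c(at 24 wk, at 38 wk)}.
#' @param burst_weights_24,burst_weights_38 burst band-power weights
#'   (delta, theta, alpha, beta) at the range ends.
#' @param floor_weights inter-SAT floor band weights (fixed, strongly
#'   delta-dominant).
#' @param quiet_frac fraction of the recording in the quiet-sleep state.
#' @param quiet_isi_factor multiplier of the inter-SAT interval in quiet
#'   sleep (before normalisation).
#' @param artefact_high_prob probability that a recording receives
#'   high-amplitude (>500 uV) artefact injection.
#' @param artefact_high_frac fraction of SAT time pushed above 500 uV in
#'   an injected recording.
#' @param artefact_flat_prob probability that a recording has one
#'   electrode flattened (scaled to 5\% amplitude).
#' @return A validated list of class \code{"simConfig"}.
#' @examples
#' cfg <- simConfig(n_infants = 2, rec_dur_s = 600)
#' @export
simConfig <- function(n_infants = 30,
                      recordings_min = 2, recordings_max = 4,
                      pma_min_wk = 24, pma_max_wk = 38,
                      start_pma_min_wk = 24, start_pma_max_wk = 32,
                      spacing_min_d = 18, spacing_max_d = 30,
                      rec_dur_s = 3600, fs = 256,
                      isi_mean_s = c(30, 6),
                      sat_dur_mean_s = c(3, 5),
                      burst_rms_uv = c(15, 35),
                      floor_rms_uv = c(0.85, 1.15),
                      sync_prob = c(0.5, 0.9),
                      burst_weights_24 = c(0.70, 0.20, 0.07, 0.03),
                      burst_weights_38 = c(0.55, 0.25, 0.12, 0.08),
                      floor_weights = c(0.90, 0.08, 0.015, 0.005),
                      quiet_frac = 0.3, quiet_isi_factor = 2,
                      artefact_high_prob = 0, artefact_high_frac = 0.25,
                      artefact_flat_prob = 0) {
  cfg <- as.list(environment())
  stopifnot(isi_mean_s[1] > isi_mean_s[2],        # strictly decreasing
            all(burst_rms_uv > 0), all(floor_rms_uv > 0),
            burst_rms_uv[2] > burst_rms_uv[1],
            all(sync_prob >= 0), all(sync_prob <= 1),
            all(sat_dur_mean_s > 0),
            quiet_frac >= 0, quiet_frac < 1,
            rec_dur_s > 0, fs > 64,
            pma_min_wk < pma_max_wk)
  class(cfg) <- "simConfig"
  cfg
}

# linear trend in PMA weeks between the 24 wk and 38 wk anchors
trendValue <- function(ends, pma_days) {
  wk <- pma_days / 7
  ends[1] + (wk - 24) * (ends[2] - ends[1]) / 14
}

# spectrally shaped Gaussian noise of unit RMS via frequency-domain
# weighting (flat within each band, power proportional to the weights)
shapedNoise <- function(n, fs, weights) {
  bands <- list(c(0.5, 3), c(3, 8), c(8, 15), c(15, 30))
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  amp <- numeric(n)
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    sel <- f >= b[1] & f < b[2]
    if (any(sel)) amp[sel] <- sqrt(weights[i] / (b[2] - b[1]))
  }
  x <- Re(stats::fft(X * amp, inverse = TRUE) / n)
  x / stats::sd(x)
}

# burst schedule for one hemisphere: onset/duration pairs with a
# quiet-sleep block where the local mean ISI is boosted
hemisphereSchedule <- function(dur_s, isi_mean, sat_dur_mean, quiet) {
  norm <- 1 - quiet$frac + quiet$frac * quiet$factor
  onsets <- numeric(); durs <- numeric()
  t <- stats::rexp(1, 1 / isi_mean)
  while (t < dur_s) {
    d <- stats::rlnorm(1, log(sat_dur_mean) - 0.08, 0.4)
    d <- max(d, 1.5)
    if (t + d > dur_s) break
    onsets <- c(onsets, t); durs <- c(durs, d)
    local_isi <- isi_mean / norm *
      (if (t >= quiet$start && t < quiet$end) quiet$factor else 1)
    t <- t + d + stats::rgamma(1, shape = 4, scale = local_isi / 4)
  }
  data.frame(onset_s = onsets, duration_s = durs)
}

# smooth 0/1 burst envelope with 0.5 s raised-cosine edges
burstEnvelope <- function(n, fs, schedule) {
  env <- numeric(n)
  ramp_n <- round(0.5 * fs)
  ramp <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  for (i in seq_len(nrow(schedule))) {
    a <- max(1L, round(schedule$onset_s[i] * fs))
    b <- min(n, round((schedule$onset_s[i] + schedule$duration_s[i]) * fs))
    if (b <= a) next
    seg <- numeric(b - a + 1) + 1
    k <- min(ramp_n, length(seg))
    seg[seq_len(k)] <- pmax(seg[seq_len(k)] - 1 + ramp[seq_len(k)], 0)
    seg[length(seg) - seq_len(k) + 1] <-
      pmin(seg[length(seg) - seq_len(k) + 1], rev(ramp[seq_len(k)]))
    env[a:b] <- pmax(env[a:b], seg)
  }
  env
}

#' Generate one synthetic referential recording
#'
#' Produces alternating inter-SAT (low-amplitude, delta-dominant filtered
#' noise) and SAT (high-amplitude, band-weighted burst) activity per
#' hemisphere on the 8 scalp electrodes (referential to Cz), with
#' homologous channels sharing burst onsets with the age-dependent
#' synchrony probability.  Deterministic given \code{seed}.
#'
#' @param pma_days post-menstrual age in days.
#' @param config \code{\link{simConfig}}.
#' @param seed integer seed.
#' @param infantId,recordingId identifiers for the emitted recording.
#' @return List: \code{recording} (\linkS4class{EEGRecording}),
#'   \code{schedule} (data.frame \code{hemisphere}, \code{onset_s},
#'   \code{duration_s} -- the ground truth), \code{quiet}
#'   (the quiet-sleep block), \code{params} (nominal generative values at
#'   this age).
#' @examples
#' g <- generateEpoch(175, simConfig(rec_dur_s = 120), seed = 1)
#' nrow(g$schedule)
#' @export
generateEpoch <- function(pma_days, config = simConfig(), seed = 1,
                          infantId = "sim", recordingId = "sim_rec") {
  set.seed(seed %% .Machine$integer.max)
  fs <- config$fs
  dur <- config$rec_dur_s
  n <- round(dur * fs)
  isi <- trendValue(config$isi_mean_s, pma_days)
  sdur <- trendValue(config$sat_dur_mean_s, pma_days)
  brms <- trendValue(config$burst_rms_uv, pma_days)
  frms <- trendValue(config$floor_rms_uv, pma_days)
  rho <- min(1, max(0, trendValue(config$sync_prob, pma_days)))
  wb <- config$burst_weights_24 +
    (pma_days / 7 - 24) / 14 *
    (config$burst_weights_38 - config$burst_weights_24)
  wb <- wb / sum(wb)

  q_start <- stats::runif(1, 0.2, 0.6) * dur
  quiet <- list(start = q_start,
                end = min(dur, q_start + config$quiet_frac * dur),
                frac = config$quiet_frac, factor = config$quiet_isi_factor)

  left <- hemisphereSchedule(dur, isi, sdur, quiet)
  shared <- stats::runif(nrow(left)) < rho
  own <- hemisphereSchedule(dur, isi, sdur, quiet)
  own <- own[stats::runif(nrow(own)) >= rho, , drop = FALSE]
  right <- rbind(
    data.frame(onset_s = pmax(0, left$onset_s[shared] +
                                stats::runif(sum(shared), -0.2, 0.2)),
               duration_s = left$duration_s[shared]),
    own)
  right <- right[order(right$onset_s), , drop = FALSE]

  hemis <- list(left = c("Fp1", "C3", "T3", "O1"),
                right = c("Fp2", "C4", "T4", "O2"))
  scheds <- list(left = left, right = right)
  sig <- matrix(0, n, 8,
                dimnames = list(NULL, unlist(hemis, use.names = FALSE)))
  for (h in names(hemis)) {
    env <- burstEnvelope(n, fs, scheds[[h]])
    for (el in hemis[[h]]) {
      gain <- stats::runif(1, 0.85, 1.15)
      floor_x <- shapedNoise(n, fs, config$floor_weights) * frms
      burst_x <- shapedNoise(n, fs, wb) * brms
      sig[, el] <- gain * (floor_x + env * burst_x)
    }
  }
  rec <- EEGRecording(sig, fs = fs, infantId = infantId,
                      recordingId = recordingId, pmaDays = pma_days)
  tag <- function(h, df) {
    if (nrow(df)) return(cbind(hemisphere = h, df))
    data.frame(hemisphere = character(), onset_s = numeric(),
               duration_s = numeric())
  }
  sched <- rbind(tag("left", left), tag("right", right))
  list(recording = rec, schedule = sched, quiet = quiet,
       params = list(isi_mean_s = isi, sat_dur_mean_s = sdur,
                     burst_rms_uv = brms, floor_rms_uv = frms,
                     sync_prob = rho))
}

#' Inject amplitude artefacts into a recording
#'
#' Two injection types matching the artefact rules: (a) high-amplitude
#' excursions -- a chosen fraction of ground-truth SAT time is rescaled so
#' the referential voltage exceeds 500 uV (targets the 500 uV SAT rule and
#' the 20\% contamination rule); (b) a near-flat channel -- one electrode
#' scaled to 5\% amplitude (targets the low-amplitude envelope rules).
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param schedule ground-truth burst schedule of the recording.
#' @param seed integer seed.
#' @param high_frac fraction of SAT time to push above 500 uV (0 for
#'   none).
#' @param flat_channel electrode label to flatten, or NULL.
#' @return List: \code{recording} (contaminated), \code{labels} (list with
#'   \code{high} data.frame of injected intervals and \code{flat}
#'   channels).
#' @export
injectArtefacts <- function(rec, schedule, seed = 1, high_frac = 0,
                            flat_channel = NULL) {
  set.seed(seed %% .Machine$integer.max)
  sig <- rec@signal
  fs <- rec@fs
  high <- data.frame(onset_s = numeric(), duration_s = numeric())
  if (high_frac > 0 && nrow(schedule)) {
    sched <- schedule[order(stats::runif(nrow(schedule))), ]
    need <- high_frac * sum(schedule$duration_s)
    take <- which(cumsum(sched$duration_s) <= need + max(sched$duration_s))
    take <- take[cumsum(sched$duration_s[take]) -
                   sched$duration_s[take] < need]
    for (i in take) {
      a <- max(1L, round(sched$onset_s[i] * fs))
      b <- min(nrow(sig), round((sched$onset_s[i] +
                                 sched$duration_s[i]) * fs))
      peak <- max(abs(sig[a:b, ]))
      if (peak > 0) sig[a:b, ] <- sig[a:b, ] * (650 / peak)
    }
    high <- sched[take, c("onset_s", "duration_s")]
  }
  flat <- character()
  if (!is.null(flat_channel)) {
    sig[, flat_channel] <- sig[, flat_channel] * 0.05
    flat <- flat_channel
  }
  out <- rec
  out@signal <- sig
  list(recording = out, labels = list(high = high, flat = flat))
}

#' Generate a synthetic cohort with serial recordings
#'
#' Each infant receives 2--4 recordings at increasing PMA; trends,
#' durations and artefact rates come from the \code{\link{simConfig}}.
#' With \code{dir} set, recordings are written as EDF files with a
#' manifest CSV (\code{infant_id}, \code{recording_id}, \code{edf_path},
#' \code{pma_days}) and a ground-truth CSV; otherwise everything stays in
#' memory.
#'
#' @param config \code{\link{simConfig}}.
#' @param seed integer; the whole cohort derives from it.
#' @param dir optional output directory for EDF + CSV export.
#' @return List: \code{recordings} (list of \linkS4class{EEGRecording}),
#'   \code{manifest} (data.frame incl. the nominal generative values
#'   \code{true_isi_mean_s}, \code{true_burst_rms_uv} per recording),
#'   \code{truth} (burst schedules), \code{artefacts} (injection labels).
#' @examples
#' co <- generateCohort(simConfig(n_infants = 2, rec_dur_s = 300), seed = 1)
#' co$manifest
#' @export
generateCohort <- function(config = simConfig(), seed = 1, dir = NULL) {
  set.seed(seed %% .Machine$integer.max)
  recs <- list(); manifest <- NULL; truth <- NULL; artefacts <- list()
  pma_cap <- config$pma_max_wk * 7
  for (i in seq_len(config$n_infants)) {
    inf <- sprintf("inf%02d", i)
    n_r <- if (config$recordings_min == config$recordings_max)
      config$recordings_min
    else sample(config$recordings_min:config$recordings_max, 1)
    pma <- round(stats::runif(1, config$start_pma_min_wk * 7,
                              config$start_pma_max_wk * 7))
    isi_jit <- stats::runif(1, 0.92, 1.08)
    amp_jit <- stats::runif(1, 0.90, 1.10)
    for (r in seq_len(n_r)) {
      if (pma > pma_cap) break
      rid <- sprintf("%s_r%d", inf, r)
      rec_seed <- (seed + 1009L * i + 31L * r) %% .Machine$integer.max
      cfg_i <- config
      cfg_i$isi_mean_s <- config$isi_mean_s * isi_jit
      cfg_i$burst_rms_uv <- config$burst_rms_uv * amp_jit
      g <- generateEpoch(pma, cfg_i, seed = rec_seed, infantId = inf,
                         recordingId = rid)
      lab <- list(high = NULL, flat = character())
      do_high <- stats::runif(1) < config$artefact_high_prob
      do_flat <- stats::runif(1) < config$artefact_flat_prob
      if (do_high || do_flat) {
        inj <- injectArtefacts(
          g$recording, g$schedule, seed = rec_seed + 1L,
          high_frac = if (do_high) config$artefact_high_frac else 0,
          flat_channel = if (do_flat)
            sample(REQUIRED_ELECTRODES, 1) else NULL)
        g$recording <- inj$recording
        lab <- inj$labels
      }
      recs[[rid]] <- g$recording
      manifest <- rbind(manifest, data.frame(
        infant_id = inf, recording_id = rid, pma_days = pma,
        true_isi_mean_s = g$params$isi_mean_s * isi_jit,
        true_burst_rms_uv = g$params$burst_rms_uv * amp_jit,
        injected_high = do_high, injected_flat = do_flat))
      truth <- rbind(truth, cbind(infant_id = inf, recording_id = rid,
                                  g$schedule))
      artefacts[[rid]] <- lab
      pma <- pma + round(stats::runif(1, config$spacing_min_d,
                                      config$spacing_max_d))
    }
  }
  out <- list(recordings = recs, manifest = manifest, truth = truth,
              artefacts = artefacts)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$manifest$edf_path <- paste0(out$manifest$recording_id, ".edf")
    for (rid in names(recs))
      writeEDF(recs[[rid]], file.path(dir, paste0(rid, ".edf")))
    utils::write.csv(out$manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  out
}
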