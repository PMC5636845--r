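# toy epochs are 600 s at 64 Hz unless noted
toyParams <- emaParams(epoch_s = 600)

# epoch with bursts on every channel; optionally push one SAT beyond
# 500 uV or rescale SATs covering a given fraction of the epoch
toyEpoch <- function(high_s = NULL, seed = 1) {
  set.seed(seed)
  chans <- lapply(1:8, function(j)
    burstTrain(600, burst_amp = 40, floor_sd = 1)$x)
  bip <- bipMatrix(600 * 64, chans)
  if (!is.null(high_s)) {
    for (iv in high_s) {
      idx <- (iv[1] * 64 + 1):(iv[2] * 64)
      bip[idx, ] <- bip[idx, ] * (650 / max(abs(bip[idx, ])))
    }
  }
  makeEpoch(bip)
}

test_that("the 500 uV rule flags exactly the excessive SATs", {
  p <- toyParams
  ep <- toyEpoch()
  ann <- annotateSATs(ep, p)
  clean <- flagHighAmplitudeSATs(ep, ann, p)
  expect_equal(clean$fraction, 0)
  expect_length(clean$intervals, 0)

  # one SAT (the burst at 10-12 s) pushed to 650 uV
  ep2 <- toyEpoch(high_s = list(c(10, 12)))
  ann2 <- annotateSATs(ep2, p)
  high <- flagHighAmplitudeSATs(ep2, ann2, p)
  expect_gt(high$fraction, 0)
  expect_lt(high$fraction, 0.02)
  on_s <- (IRanges::start(high$intervals) - 1) / 64
  expect_true(any(abs(on_s - 10) < 1))
  rep2 <- artefactReport(ep2, ann2, p)
  expect_true(rep2@accepted)          # 2 s of 600 s is far below 20%
})

test_that("epochs with more than 20% contamination are rejected", {
  p <- toyParams
  # push bursts covering ~25% of the epoch beyond 500 uV: bursts are 2 s
  # every 10 s, so contaminate 150 s worth in a 600 s epoch
  high <- lapply(seq(0, 590, by = 10)[1:60], function(o) c(o, o + 2.5))
  ep <- toyEpoch(high_s = high)
  rep_ <- artefactReport(ep, params = p)
  expect_gt(rep_@contamFraction, 0.20)
  expect_false(rep_@accepted)
  expect_false(epochAccept(rep_))
})

test_that("epoch acceptance combines both rules with strict thresholds", {
  mk <- function(excl, frac)
    new("ArtefactReport", excludedChannels = excl,
        exclusionReason = setNames(rep("low-amplitude-bipolar",
                                       length(excl)), excl),
        artefactIntervals = IRanges::IRanges(),
        contamFraction = frac, accepted = length(excl) == 0 && frac <= 0.2)
  expect_true(epochAccept(mk(character(), 0.19)))
  expect_true(epochAccept(mk(character(), 0.20)))   # tie: not "more than"
  expect_false(epochAccept(mk("Fp1-C3", 0)))
  expect_false(epochAccept(mk(character(), 0.21)))
})

test_that("low-amplitude bipolar rule excludes depressed channels", {
  set.seed(9)
  n <- 600 * 64
  chans <- lapply(1:8, function(j) tone(4, 64, 600, amp = 40) + rnorm(n))
  chans[[5]] <- chans[[5]] * 0.15          # one depressed channel
  ep <- makeEpoch(bipMatrix(n, chans))
  low <- flagLowAmplitudeChannels(ep, toyParams)
  expect_equal(low$excluded, "Fp2-C4")
  expect_equal(unname(low$reason["Fp2-C4"]), "low-amplitude-bipolar")
  # identical channels: ratio 1 everywhere, nothing excluded
  same <- makeEpoch(bipMatrix(n, rep(chans[1], 8)))
  expect_length(flagLowAmplitudeChannels(same, toyParams)$excluded, 0)
})

test_that("bipolar ratio rule is scale invariant, referential clause is not", {
  set.seed(10)
  n <- 600 * 64
  chans <- lapply(1:8, function(j) tone(4, 64, 600, amp = 40) + rnorm(n))
  chans[[3]] <- chans[[3]] * 0.2
  ref <- refMatrix(n)
  ref[] <- tone(4, 64, 600, amp = 30) + rnorm(n * 8)
  for (k in c(1, 10)) {
    ep <- makeEpoch(bipMatrix(n, lapply(chans, `*`, k)), ref * k)
    low <- flagLowAmplitudeChannels(ep, toyParams)
    expect_equal(low$excluded, "Fp1-T3", label = paste("scale", k))
  }
  # referential clause has an absolute 25 uV arm: a uniformly tiny
  # recording (all envelopes < 25 uV) still excludes nothing because the
  # 50% relative arm never fires when all channels shrink together
  ep_small <- makeEpoch(bipMatrix(n, lapply(chans[c(1, 2, 4:8, 5)], `*`, 0.1)),
                        ref * 0.1)
  expect_length(flagLowAmplitudeChannels(ep_small, toyParams)$excluded, 0)
})

test_that("a flat referential electrode excludes its derived channels", {
  set.seed(12)
  n <- 600 * 64
  ref <- refMatrix(n)
  ref[] <- tone(4, 64, 600, amp = 30) + rnorm(n * 8)
  ref[, "C3"] <- rnorm(n, sd = 0.5)        # flat electrode: p95 << 25 uV
  bip <- toBipolar(ref)
  ep <- makeEpoch(bip, ref)
  low <- flagLowAmplitudeChannels(ep, toyParams)
  expect_true(all(c("Fp1-C3", "C3-O1") %in% low$excluded))
  expect_equal(unname(low$reason["C3-O1"]),
               "low-amplitude-referential-derived")
  expect_false(artefactReport(ep, params = toyParams)@accepted)
})

test_that("injected artefacts drive the expected exclusions end to end", {
  cfg <- simConfig(rec_dur_s = 600)
  p <- emaParams(epoch_s = 600)
  g <- generateEpoch(220, cfg, seed = 31)
  # flatten C3
  inj <- injectArtefacts(g$recording, g$schedule, seed = 1,
                         flat_channel = "C3")
  ep <- preprocessRecording(inj$recording, p)[[1]]
  rep_ <- artefactReport(ep, params = p)
  expect_true(all(c("Fp1-C3", "C3-O1") %in% rep_@excludedChannels))
  expect_false(rep_@accepted)
  # push ~25% of SAT time over 500 uV: rejected by the 20% rule only if
  # contamination eventually exceeds 0.2 of the epoch -- here it checks
  # the contamination accounting itself
  inj2 <- injectArtefacts(g$recording, g$schedule, seed = 2,
                          high_frac = 0.25)
  ep2 <- preprocessRecording(inj2$recording, p)[[1]]
  rep2 <- artefactReport(ep2, params = p)
  expect_gt(rep2@contamFraction, 0)
  expect_equal(sum(inj2$labels$high$duration_s) / 600,
               rep2@contamFraction, tolerance = 0.25)
})
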