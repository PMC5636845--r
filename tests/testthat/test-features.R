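test_that("envelope recovers tone amplitude and slow modulators", {
  x <- tone(10, 64, 20)
  e <- envelope(x)
  mid <- 128:(length(e) - 128)
  expect_true(all(abs(e[mid] - 1) < 0.02))
  expect_equal(envelope(numeric(100)), numeric(100))
  # slowly varying amplitude modulation is recovered within 5%
  t <- seq(0, 20 - 1 / 64, by = 1 / 64)
  a <- 2 + sin(2 * pi * 0.1 * t)
  em <- envelope(a * sin(2 * pi * 10 * t))
  expect_lt(max(abs(em[mid] - a[mid]) / a[mid]), 0.05)
})

test_that("range-EEG equals the brute-force per-window peak-to-peak", {
  expect_equal(reeg(rep(3, 640), 64), rep(0, 5))
  expect_equal(reeg(tone(2, 64, 10), 64), rep(2, 5), tolerance = 1e-3)
  set.seed(7)
  for (rep_i in 1:100) {
    n <- sample(300:2000, 1)
    x <- rnorm(n) * 10
    win <- sample(c(1, 2, 4), 1)
    got <- reeg(x, 64, win)
    L <- win * 64
    k <- floor(n / L)
    brute <- vapply(seq_len(k), function(i) {
      w <- x[((i - 1) * L + 1):(i * L)]
      max(w) - min(w)
    }, 1)
    expect_identical(got, brute)
  }
})

test_that("band powers concentrate on the right bands and sum to one", {
  p <- emaParams()
  a <- bandPowers(tone(10, 64, 64), 64, p)
  expect_gt(a[["relpow_alpha"]], 0.99)
  d <- bandPowers(tone(1, 64, 64), 64, p)
  expect_gt(d[["relpow_delta"]], 0.99)
  two <- bandPowers(tone(1, 64, 64) + tone(20, 64, 64), 64, p)
  expect_equal(two[["relpow_delta"]], 0.5, tolerance = 0.02)
  expect_equal(two[["relpow_beta"]], 0.5, tolerance = 0.02)
  rel <- two[c("relpow_delta", "relpow_theta", "relpow_alpha", "relpow_beta")]
  expect_equal(sum(rel), 1, tolerance = 1e-6)
  # Parseval: total power approximates the signal variance
  set.seed(2)
  x <- rnorm(64 * 64)
  expect_equal(bandPowers(x, 64, p)[["pow_total"]], var(x), tolerance = 0.1)
  # zero signal: zero absolute power, undefined relative power
  z <- bandPowers(numeric(64 * 64), 64, p)
  expect_equal(z[["pow_total"]], 0)
  expect_true(is.na(z[["relpow_delta"]]))
})

test_that("SAT statistics reproduce hand-computed timing values", {
  fs <- 64
  n <- 3600 * fs
  # 60 uniform 2 s SATs every 10 s -> constant 8 s gaps
  on <- seq(0, 590, by = 10)
  ir <- IRanges::IRanges(on * fs + 1, width = 2 * fs)
  s <- satStats(ir, fs, nSamples = 600 * fs)
  expect_equal(s[["sats_per_hour"]], 60 * 3600 / 600)
  expect_equal(unname(s[c("isi_p5", "isi_p50", "isi_p95", "isi_rms")]),
               rep(8, 4), tolerance = 1e-6)
  # mixed gaps {4, 8, 12}: rms = sqrt((16+64+144)/3)
  on2 <- cumsum(c(0, 2 + 4, 2 + 8, 2 + 12, 2 + 4, 2 + 8, 2 + 12))
  ir2 <- IRanges::IRanges(on2 * fs + 1, width = 2 * fs)
  s2 <- satStats(ir2, fs, nSamples = 100 * fs)
  expect_equal(s2[["isi_rms"]], sqrt((16 + 64 + 144) / 3), tolerance = 0.01)
  # fewer than two SATs: ISI features missing
  s3 <- satStats(IRanges::IRanges(1, 100), fs, nSamples = n)
  expect_true(is.na(s3[["isi_p50"]]))
  expect_equal(s3[["sats_per_hour"]], 1)
})

test_that("ISIs never span holes in the analysis mask", {
  fs <- 64
  # two mask blocks; one SAT in each: no ISI despite two SATs
  mask <- c(rep(TRUE, 100), rep(FALSE, 100), rep(TRUE, 100))
  ir <- IRanges::IRanges(c(10, 210) * fs + 1, width = 2 * fs)
  s <- satStats(ir, fs, maskToSampleIR(mask, fs), 300 * fs)
  expect_equal(s[["sats_per_hour"]], 2 * 3600 / 200)
  expect_true(is.na(s[["isi_rms"]]))
})

test_that("activation synchrony index hits its closed-form anchors", {
  fs <- 64
  n <- 1200 * fs
  mkann <- function(left, right) {
    chans <- list(left, left, right, right)
    names(chans) <- c("Fp1-T3", "T3-O1", "Fp2-T4", "T4-O2")
    new("SATAnnotation", channel = chans,
        consensus = IRanges::reduce(c(left, right)), fs = fs,
        nSamples = as.integer(n))
  }
  # identical streams with activity fraction 1/4 -> CR = 4
  act <- IRanges::IRanges(seq(1, n - 8 * fs, by = 8 * fs), width = 2 * fs)
  expect_equal(activationSynchronyIndex(mkann(act, act)), 4, tolerance = 0.05)
  # anti-phased streams -> CR = 0
  anti <- IRanges::shift(act, 4 * fs)
  expect_equal(activationSynchronyIndex(mkann(act, anti)), 0)
  # independent random streams -> CR ~ 1
  set.seed(14)
  rnd <- function() IRanges::reduce(IRanges::IRanges(
    sort(sample.int(n - 2 * fs, 150)), width = 2 * fs))
  crs <- replicate(20, activationSynchronyIndex(mkann(rnd(), rnd())))
  expect_equal(mean(crs), 1, tolerance = 0.1)
})

test_that("feature extraction aggregates channels and segments correctly", {
  p <- emaParams(epoch_s = 600)
  set.seed(15)
  one <- burstTrain(600, burst_amp = 40, floor_sd = 1)$x
  ep <- makeEpoch(bipMatrix(600 * 64, rep(list(one), 8)))
  ann <- annotateSATs(ep, p)
  rep_ <- artefactReport(ep, ann, p)
  full_mask <- rep(TRUE, 600)
  fv <- extractFeatures(ep, ann, full_mask, rep_, p)
  expect_length(fv, 46)
  expect_named(fv, featureRoster())
  # identical channels: cross-channel median equals the single-channel value
  e1 <- envelope(ep@bipolar[, 1])
  expect_equal(fv[["env_p50_full"]], unname(quantile(e1, 0.5)))
  # mask = full epoch: lowsat features equal full features
  expect_equal(unname(fv[paste0(neoEMA:::FEATURE_BASE, "_lowsat")]),
               unname(fv[paste0(neoEMA:::FEATURE_BASE, "_full")]))
})

test_that("percentile families are ordered and amplitudes equivariant", {
  p <- emaParams(epoch_s = 600)
  g <- generateEpoch(210, simConfig(rec_dur_s = 600), seed = 77)
  ep <- preprocessRecording(g$recording, p)[[1]]
  fv <- extractFeatures(ep, params = p)
  for (fam in list(c("reeg_p5", "reeg_p50", "reeg_p95"),
                   c("sat_dur_p5", "sat_dur_p50", "sat_dur_p95"),
                   c("isi_p5", "isi_p50", "isi_p95"))) {
    for (sfx in c("_full", "_lowsat")) {
      v <- fv[paste0(fam, sfx)]
      expect_true(!is.unsorted(v), label = paste(fam[1], sfx))
    }
  }
  rel <- fv[c("relpow_delta_full", "relpow_theta_full",
              "relpow_alpha_full", "relpow_beta_full")]
  expect_equal(sum(rel), 1, tolerance = 1e-6)

  # scale the epoch by k: amplitude features scale by k, powers by k^2,
  # relative powers and ASI unchanged (annotations fixed)
  k <- 3
  ep2 <- ep; ep2@bipolar <- ep@bipolar * k; ep2@referential <- ep@referential * k
  ann <- annotateSATs(ep, p)
  rep_ <- artefactReport(ep, ann, p)
  mask <- suppressWarnings(lowSATSegment(satPercent(ann, p), p))
  f1 <- extractFeatures(ep, ann, mask, rep_, p)
  f2 <- extractFeatures(ep2, ann, mask, rep_, p)
  expect_equal(f2[["reeg_p95_full"]], k * f1[["reeg_p95_full"]])
  expect_equal(f2[["env_p50_full"]], k * f1[["env_p50_full"]])
  expect_equal(f2[["pow_total_full"]], k^2 * f1[["pow_total_full"]],
               tolerance = 1e-8)
  expect_equal(f2[["relpow_delta_full"]], f1[["relpow_delta_full"]])
  expect_equal(f2[["asi_full"]], f1[["asi_full"]])
})

test_that("burst-rate features recover the generator ground truth", {
  p <- emaParams(epoch_s = 600)
  g <- generateEpoch(190, simConfig(rec_dur_s = 600), seed = 99)
  ep <- preprocessRecording(g$recording, p)[[1]]
  ann <- annotateSATs(ep, p)
  fv <- suppressWarnings(extractFeatures(ep, ann, params = p))
  truth <- IRanges::reduce(IRanges::IRanges(
    round(g$schedule$onset_s * 64) + 1L,
    width = pmax(1L, round(g$schedule$duration_s * 64))))
  expect_equal(fv[["sats_per_hour_full"]],
               length(truth) * 6, tolerance = 0.1)
})
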