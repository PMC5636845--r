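test_that("nonlinear energy operator matches its defining formula", {
  # brute-force oracle: psi[n] = |x[n]x[n-3] - x[n-1]x[n-2]|, then a
  # centred zero-padded moving average
  nleo_oracle <- function(x, fs, smooth_s = 1.5) {
    n <- length(x)
    psi <- numeric(n)
    for (i in 4:n) psi[i] <- abs(x[i] * x[i - 3] - x[i - 1] * x[i - 2])
    k <- round(smooth_s * fs)
    out <- numeric(n)
    for (i in seq_len(n)) {     # centred; even windows lean forward
      lo <- i - (k - 1) %/% 2
      hi <- i + k %/% 2
      idx <- max(1, lo):min(n, hi)
      out[i] <- sum(psi[idx]) / k
    }
    out
  }
  set.seed(11)
  x <- tone(5, 64, 4) + rnorm(256, sd = 0.3)
  expect_equal(nleo(x, 64), nleo_oracle(x, 64), tolerance = 1e-10)
  # constants and silence produce zero energy
  expect_equal(nleo(rep(7, 500), 64), rep(0, 500))
  expect_equal(nleo(numeric(500), 64), rep(0, 500))
})

test_that("SAT detection recovers a constructed burst train", {
  p <- emaParams(epoch_s = 600)
  bt <- burstTrain(600, burst_amp = 50, floor_sd = 1, seed = 3)
  ir <- detectSATs(bt$x, 64, p)
  expect_lte(abs(length(ir) - length(bt$onsets)), 1)
  det_on <- (IRanges::start(ir) - 1) / 64
  matched <- vapply(bt$onsets, function(o) min(abs(det_on - o)), 1)
  expect_true(all(matched <= 0.5))
  # silence and saturation edge cases
  expect_length(detectSATs(numeric(600 * 64), 64, p), 0)
  cont <- detectSATs(tone(4, 64, 600, amp = 50), 64, p)
  expect_length(cont, 1)
  expect_gte(sum(IRanges::width(cont)) / (600 * 64), 0.99)
})

test_that("SAT detection is invariant to sign flip", {
  p <- emaParams(epoch_s = 120)
  for (s in 1:5) {
    bt <- burstTrain(120, burst_amp = 40, seed = s)
    expect_identical(detectSATs(bt$x, 64, p), detectSATs(-bt$x, 64, p))
  }
})

test_that("SAT% trace implements the sliding-window coverage", {
  p <- emaParams()     # 3600 s epoch, 300 s window, 60 s step
  n <- 3600 * 64
  # single SAT covering [0, 150) s
  tr <- satPercent(IRanges::IRanges(1, 150 * 64), p, nSamples = n)
  expect_equal(nrow(tr), 56)
  expect_equal(tr$sat_percent[1], 50)
  expect_equal(tr$sat_percent[tr$window_start_s == 60], 30)
  # no SATs / full coverage
  expect_true(all(satPercent(IRanges::IRanges(), p, nSamples = n)$sat_percent == 0))
  expect_true(all(satPercent(IRanges::IRanges(1, n), p, nSamples = n)$sat_percent == 100))
})

test_that("SAT% equals a brute-force window computation on random annotations", {
  p <- emaParams(epoch_s = 600)
  n <- 600 * 64
  set.seed(21)
  for (rep in 1:100) {
    k <- sample(0:25, 1)
    if (k == 0) { ir <- IRanges::IRanges() } else {
      st <- sort(sample.int(n - 200, k))
      ir <- IRanges::reduce(IRanges::IRanges(st, width = sample(10:600, k,
                                                                TRUE)))
      ir <- IRanges::restrict(ir, 1L, n)
    }
    tr <- satPercent(ir, p, nSamples = n)
    cov <- as.integer(IRanges::coverage(ir, width = n) > 0)
    win <- p$satp_win_s * 64; step <- p$satp_step_s * 64
    brute <- vapply(seq_len(nrow(tr)), function(w) {
      i0 <- (w - 1) * step
      100 * sum(cov[(i0 + 1):(i0 + win)]) / win
    }, 1)
    expect_equal(tr$sat_percent, brute)
  }
})

test_that("non-overlapping SAT% windows conserve total SAT time", {
  p <- emaParams(satp_step_s = 300)    # step = window: no overlap
  n <- 3600 * 64
  set.seed(5)
  st <- sort(sample.int(n - 3000, 40))
  ir <- IRanges::reduce(IRanges::IRanges(st, width = sample(64:1920, 40, TRUE)))
  tr <- satPercent(ir, p, nSamples = n)
  expect_equal(mean(tr$sat_percent),
               100 * sum(IRanges::width(ir)) / n, tolerance = 1e-12)
})

test_that("low-SAT% segmentation selects long below-threshold runs", {
  p <- emaParams()
  # 6-window runs alternating low (10) and high (90): all runs survive
  v <- rep(rep(c(10, 90), each = 6), length.out = 56)
  tr <- data.frame(window_start_s = (0:55) * 60, sat_percent = v)
  mask <- lowSATSegment(tr, p)
  # oracle: paint [start, start+300) for every low window
  exp_mask <- rep(FALSE, 3600)
  for (w in which(v <= 10)) {
    s0 <- (w - 1) * 60
    exp_mask[(s0 + 1):min(3600, s0 + 300)] <- TRUE
  }
  expect_equal(mask, exp_mask)
  expect_gt(sum(mask), 0)

  # an isolated 3-min low run is eliminated; mask comes from surviving runs
  v2 <- rep(60, 56)
  v2[10:12] <- 5                     # 3 windows x 60 s = 180 s < 300 s
  v2[30:40] <- 20                    # 11 windows = 660 s, survives
  tr2 <- data.frame(window_start_s = (0:55) * 60, sat_percent = v2)
  mask2 <- lowSATSegment(tr2, p)
  sec_of_run <- function(w) ((w - 1) * 60 + 1):min(3600, (w - 1) * 60 + 300)
  expect_false(any(mask2[sec_of_run(10)[1:60]]))   # eliminated run start
  expect_true(all(mask2[unlist(lapply(30:40, sec_of_run))]))

  # constant trace: degenerate full mask with a warning
  tr3 <- data.frame(window_start_s = (0:55) * 60, sat_percent = rep(40, 56))
  expect_warning(m3 <- lowSATSegment(tr3, p), "constant")
  expect_true(all(m3))
})

test_that("consensus requires support from half the channels", {
  n <- 640L
  a <- IRanges::IRanges(1, 320)
  b <- IRanges::IRanges(161, 480)
  ann <- list(c1 = a, c2 = a, c3 = b, c4 = b)
  cons <- consensusSAT(ann, n)        # >= 2 of 4 channels
  expect_equal(IRanges::start(cons), 1)
  expect_equal(IRanges::end(cons), 480)
  strict <- consensusSAT(ann, n, minChannels = 3)
  expect_equal(IRanges::start(strict), 161)
  expect_equal(IRanges::end(strict), 320)
})
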