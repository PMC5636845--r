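# shared fixtures, all generated in code

tone <- function(f, fs, dur_s, amp = 1, phase = 0)
  amp * sin(2 * pi * f * seq(0, dur_s - 1 / fs, by = 1 / fs) + phase)

# referential matrix with the 8 standard electrodes
refMatrix <- function(n, fill = 0) {
  matrix(fill, nrow = n, ncol = 8,
         dimnames = list(NULL, c("Fp1", "Fp2", "C3", "C4",
                                 "T3", "T4", "O1", "O2")))
}

# build a BipolarEpoch directly from a bipolar matrix (referential zeros
# unless given); fs is always 64
makeEpoch <- function(bipolar, referential = NULL, pma = 210,
                      recordingId = "toy") {
  if (is.null(referential)) referential <- refMatrix(nrow(bipolar))
  new("BipolarEpoch", bipolar = bipolar, referential = referential,
      channelLabels = colnames(bipolar), fs = 64, startOffset = 0,
      infantId = "toy_inf", recordingId = recordingId, pmaDays = pma)
}

# bipolar matrix of the standard 8 derivations filled per channel
bipMatrix <- function(n, values = NULL) {
  labs <- c("Fp1-C3", "C3-O1", "Fp1-T3", "T3-O1",
            "Fp2-C4", "C4-O2", "Fp2-T4", "T4-O2")
  m <- matrix(0, n, 8, dimnames = list(NULL, labs))
  if (!is.null(values)) for (j in 1:8) m[, j] <- values[[j]]
  m
}

# burst train channel: bursts of `burst_amp` uV sine on a noise floor
burstTrain <- function(dur_s, fs = 64, burst_dur = 2, period = 10,
                       burst_amp = 50, floor_sd = 1, f_burst = 4,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- dur_s * fs
  x <- rnorm(n, sd = floor_sd)
  onsets <- seq(0, dur_s - burst_dur, by = period)
  for (o in onsets) {
    idx <- (o * fs + 1):((o + burst_dur) * fs)
    x[idx] <- x[idx] + tone(f_burst, fs, burst_dur, amp = burst_amp)
  }
  list(x = x, onsets = onsets, burst_dur = burst_dur)
}

# small synthetic cohort shared by several modelling tests (cached)
smallCohortFeatures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generateCohort(simConfig(n_infants = 4, rec_dur_s = 600,
                                     recordings_min = 2,
                                     recordings_max = 2), seed = 42)
      cache <<- suppressMessages(
        buildFeatureSet(co$recordings, emaParams(epoch_s = 600)))
    }
    cache
  }
})
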