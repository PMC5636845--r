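#' Analysis parameters for the EMA pipeline
#'
#' Bundles every tunable constant of the preprocessing, SAT detection,
#' artefact and feature-extraction stages.  Defaults reproduce the standard
#' analysis: 0.5--32 Hz band-pass, 64 Hz working rate, 1-h epochs with 75\%
#' overlap, SAT\% computed in 5-min windows advancing by 1 min, and the
#' amplitude artefact rules (500 uV SAT rule, 50\% envelope rule, 25 uV
#' referential rule, 20\% contamination rule).
#'
#' When a shorter epoch length is chosen (e.g. for simulation studies) the
#' SAT\% window, its step and the minimum low-SAT\% run length scale
#' proportionally, keeping the epoch:window ratio of the full-length
#' analysis (3600:300:60).
#'
#' @param epoch_s Epoch length in seconds (default 3600, i.e. 1 h).
#' @param fs Working sampling rate in Hz after resampling.
#' @param f_low,f_high Band-pass cut-off frequencies in Hz.
#' @param step_s Epoch advance in seconds; default \code{epoch_s/4} (75\%
#'   overlap).
#' @param satp_win_s,satp_step_s SAT\% window length and step in seconds.
#' @param lowsat_min_run_s Minimum duration of a low-SAT\% run in seconds;
#'   shorter runs are eliminated before the threshold is recomputed.
#' @param lowsat_method \code{"two_pass"} (threshold, eliminate short runs,
#'   re-threshold; the default) or \code{"single_pass"}.
#' @param sat_threshold Detection threshold on the smoothed nonlinear energy
#'   operator, in uV^2.
#' @param sat_min_dur_s Minimum SAT duration in seconds.
#' @param sat_merge_gap_s Below-threshold gaps shorter than this are merged
#'   into the surrounding SAT.
#' @param nleo_smooth_s Moving-average length applied to the rectified
#'   nonlinear energy operator, in seconds.
#' @param high_amp_uv Voltage bound of the high-amplitude SAT artefact rule
#'   (uV); a SAT containing any sample with \code{|v|} above this is
#'   artefactual.
#' @param contam_max Maximum tolerated fraction of the epoch covered by
#'   artefactual SATs; epochs with more are rejected.
#' @param lowamp_ratio Low-amplitude channel rule: a channel is excluded if
#'   its median envelope is below this fraction of the median envelope over
#'   time and channels.
#' @param ref_p95_uv Referential clause of the low-amplitude rule: a
#'   referential electrode is flagged only if, in addition, the 95th
#'   percentile of its envelope is below this many uV.
#' @param reeg_win_s Range-EEG window length in seconds (non-overlapping).
#' @param welch_win_s Welch segment length in seconds (50\% overlap, Hamming
#'   taper).
#' @param bands Named list of frequency bands in Hz.
#'
#' @return A named list of class \code{"emaParams"}.
#' @examples
#' p <- emaParams()
#' p$satp_win_s                 # 300 s
#' emaParams(epoch_s = 600)$satp_win_s  # scaled to 50 s
#' @export
emaParams <- function(epoch_s = 3600,
                      fs = 64,
                      f_low = 0.5,
                      f_high = 32,
                      step_s = epoch_s / 4,
                      satp_win_s = epoch_s / 12,
                      satp_step_s = epoch_s / 60,
                      lowsat_min_run_s = epoch_s / 12,
                      lowsat_method = c("two_pass", "single_pass"),
                      sat_threshold = 1.5,
                      sat_min_dur_s = 1,
                      sat_merge_gap_s = 1,
                      nleo_smooth_s = 1.5,
                      high_amp_uv = 500,
                      contam_max = 0.20,
                      lowamp_ratio = 0.5,
                      ref_p95_uv = 25,
                      reeg_win_s = 2,
                      welch_win_s = 2,
                      bands = list(delta = c(0, 3), theta = c(3, 8),
                                   alpha = c(8, 15), beta = c(15, 30))) {
  lowsat_method <- match.arg(lowsat_method)
  stopifnot(epoch_s > 0, fs >= 2 * f_high, f_low < f_high,
            step_s > 0, satp_win_s > 0, satp_step_s > 0,
            sat_threshold > 0, contam_max >= 0, contam_max <= 1)
  p <- list(epoch_s = epoch_s, fs = fs, f_low = f_low, f_high = f_high,
            step_s = step_s, satp_win_s = satp_win_s,
            satp_step_s = satp_step_s, lowsat_min_run_s = lowsat_min_run_s,
            lowsat_method = lowsat_method, sat_threshold = sat_threshold,
            sat_min_dur_s = sat_min_dur_s, sat_merge_gap_s = sat_merge_gap_s,
            nleo_smooth_s = nleo_smooth_s, high_amp_uv = high_amp_uv,
            contam_max = contam_max, lowamp_ratio = lowamp_ratio,
            ref_p95_uv = ref_p95_uv, reeg_win_s = reeg_win_s,
            welch_win_s = welch_win_s, bands = bands)
  class(p) <- "emaParams"
  p
}

#' The standard bipolar montage and reduced variants
#'
#' The standard double-banana style neonatal montage has eight derivations:
#' Fp1-C3, C3-O1, Fp1-T3, T3-O1, Fp2-C4, C4-O2, Fp2-T4, T4-O2.  Reduced
#' montages mirror common limited-electrode practice (e.g. 2-channel aEEG
#' monitors); each is symmetric across hemispheres.
#'
#' @param name One of \code{"m8"}, \code{"fp_t.t_o"}, \code{"fp_c.c_o"},
#'   \code{"fp_t"}, \code{"t_o"}, \code{"fp_c"}, \code{"c_o"}, \code{"c_t"}.
#' @return A two-column character matrix (minuend, subtrahend electrode),
#'   one row per derivation.
#' @examples
#' standardMontage()          # 8 derivations
#' standardMontage("fp_t")    # Fp1-T3, Fp2-T4
#' @export
standardMontage <- function(name = "m8") {
  pair <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                               dimnames = list(NULL, c("minuend", "subtrahend")))
  presets <- list(
    m8      = pair("Fp1","C3", "C3","O1", "Fp1","T3", "T3","O1",
                   "Fp2","C4", "C4","O2", "Fp2","T4", "T4","O2"),
    fp_t.t_o = pair("Fp1","T3", "T3","O1", "Fp2","T4", "T4","O2"),
    fp_c.c_o = pair("Fp1","C3", "C3","O1", "Fp2","C4", "C4","O2"),
    fp_t    = pair("Fp1","T3", "Fp2","T4"),
    t_o     = pair("T3","O1", "T4","O2"),
    fp_c    = pair("Fp1","C3", "Fp2","C4"),
    c_o     = pair("C3","O1", "C4","O2"),
    c_t     = pair("C3","T3", "C4","T4"))
  if (!name %in% names(presets))
    stop("unknown montage preset: ", name)
  presets[[name]]
}

montageLabels <- function(montage) {
  paste(montage[, 1], montage[, 2], sep = "-")
}

# map a left-hemisphere derivation label to its right homologue
homologueLabel <- function(label) {
  swaps <- c(Fp1 = "Fp2", C3 = "C4", T3 = "T4", O1 = "O2")
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  out <- vapply(parts, function(e) if (e %in% names(swaps)) swaps[[e]] else e, "")
  paste(out, collapse = "-")
}

leftLabels <- function(labels) {
  labels[grepl("1|3", labels) & !grepl("2|4", labels)]
}
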