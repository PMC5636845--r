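#' Repeated-measures correlation between EMA and PMA
#'
#' Serial recordings are repeated measures within infants, so the
#' EMA--PMA association is modelled with a linear mixed model
#' \deqn{EMA_{ij} = \beta_0 + \beta_1 PMA_{ij} + b_i + \epsilon_{ij}}
#' with a fixed slope and a random intercept per infant (restricted ML).
#' The adjusted correlation is the Pearson correlation between PMA and the
#' random-intercept-corrected EMA (\code{ema - b_i}), i.e. the within- plus
#' between-infant association after removing stable per-infant offsets.
#' A singular fit (zero intercept variance) falls back to ordinary least
#' squares with a warning.
#'
#' @param ema,pma numeric vectors, days.
#' @param infant infant identifiers (grouping factor).
#' @return List: \code{adjusted_r}, \code{slope}, \code{slope_ci} (95\%
#'   Wald), \code{intercept}, \code{ranef_sd}, \code{resid_sd},
#'   \code{model}.
#' @examples
#' p <- rep(seq(170, 250, by = 40), 4)
#' i <- rep(1:4, each = 3)
#' fitLMM(p + i * 2, p, i)$adjusted_r   # offsets absorbed: r = 1
#' @export
fitLMM <- function(ema, pma, infant) {
  stopifnot(length(ema) == length(pma), length(ema) == length(infant))
  if (length(unique(infant)) < 2 || length(ema) < 3)
    stop("need >= 2 infants and >= 3 recordings")
  d <- data.frame(ema = ema, pma = pma, infant = factor(infant))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(ema ~ pma + (1 | infant), data = d, REML = TRUE))),
    error = function(e) NULL)
  singular <- is.null(fit) ||
    tryCatch(lme4::isSingular(fit, tol = 1e-5), error = function(e) TRUE) ||
    is.null(tryCatch(stats::coef(summary(fit)), error = function(e) NULL))
  if (singular) {
    warning("singular mixed-model fit (zero intercept variance); ",
            "falling back to ordinary regression")
    ols <- stats::lm(ema ~ pma, data = d)
    ci <- stats::confint(ols)["pma", ]
    return(list(adjusted_r = stats::cor(d$pma, d$ema),
                slope = stats::coef(ols)[["pma"]],
                slope_ci = unname(ci),
                intercept = stats::coef(ols)[[1]],
                ranef_sd = 0, resid_sd = stats::sigma(ols), model = ols))
  }
  b <- lme4::ranef(fit)$infant[, "(Intercept)"]
  names(b) <- rownames(lme4::ranef(fit)$infant)
  corrected <- d$ema - b[as.character(d$infant)]
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- stats::coef(summary(fit))["pma", "Std. Error"]
  est <- lme4::fixef(fit)[["pma"]]
  list(adjusted_r = stats::cor(d$pma, corrected),
       slope = est,
       slope_ci = c(est - 1.96 * se, est + 1.96 * se),
       intercept = lme4::fixef(fit)[[1]],
       ranef_sd = vc$sdcor[vc$grp == "infant"],
       resid_sd = vc$sdcor[vc$grp == "Residual"],
       model = fit)
}

#' Agreement metrics between EMA and PMA
#'
#' With error \code{e = ema - pma} (days): mean squared error, bias
#' (mean error), error standard deviation, percentage error (mean
#' absolute error as a percentage of mean PMA) and the percentage of
#' recordings within 1 and 2 weeks of the PMA.
#'
#' @param ema,pma paired numeric vectors, days.
#' @return Named list: \code{mse_days2}, \code{sd_days},
#'   \code{se_percent}, \code{bias_days}, \code{pct_within_1wk},
#'   \code{pct_within_2wk}, \code{n}.
#' @examples
#' errorMetrics(c(207, 193), c(200, 200))   # errors +7/-7
#' @export
errorMetrics <- function(ema, pma) {
  if (length(ema) != length(pma)) stop("length mismatch")
  if (!all(is.finite(ema)) || !all(is.finite(pma)))
    stop("non-finite values")
  e <- ema - pma
  list(mse_days2 = mean(e^2),
       sd_days = stats::sd(e),
       se_percent = 100 * mean(abs(e)) / mean(pma),
       bias_days = mean(e),
       pct_within_1wk = 100 * mean(abs(e) <= 7),
       pct_within_2wk = 100 * mean(abs(e) <= 14),
       n = length(e))
}

#' Serial growth analysis of EMA trajectories
#'
#' For each infant with at least two recordings (ordered by PMA): does the
#' EMA increase between the first and last recording, and between each
#' consecutive pair?  Non-increasing (deviant) pairs are attributed to
#' outlier recordings, defined as \code{|EMA - PMA| > 14} days.
#'
#' @param ema_table data.frame with \code{infant_id}, \code{pma_days},
#'   \code{ema_days} (one row per recording).
#' @return List: \code{n_infants}, \code{n_serial} (with >= 2
#'   recordings), \code{n_increasing_first_last},
#'   \code{pct_increasing_first_last}, \code{n_pairs},
#'   \code{n_pairs_increasing}, \code{pct_pairs_increasing},
#'   \code{n_pairs_deviant}, \code{deviant} (data.frame of deviant pairs
#'   with the outlier attribution), \code{outlier_recordings}.
#' @export
growthAnalysis <- function(ema_table) {
  sp <- split(ema_table, ema_table$infant_id)
  n_first_last <- 0L; n_serial <- 0L
  n_pairs <- 0L; n_pairs_inc <- 0L
  deviant <- NULL
  outliers <- ema_table$recording_id[
    abs(ema_table$ema_days - ema_table$pma_days) > 14]
  for (d in sp) {
    d <- d[order(d$pma_days), ]
    if (nrow(d) < 2) next
    n_serial <- n_serial + 1L
    if (d$ema_days[nrow(d)] > d$ema_days[1]) n_first_last <- n_first_last + 1L
    inc <- diff(d$ema_days) > 0
    n_pairs <- n_pairs + length(inc)
    n_pairs_inc <- n_pairs_inc + sum(inc)
    for (k in which(!inc)) {
      pair_rec <- d$recording_id[c(k, k + 1)]
      deviant <- rbind(deviant, data.frame(
        infant_id = d$infant_id[1],
        recording_id_1 = pair_rec[1], recording_id_2 = pair_rec[2],
        outlier_attributed = any(pair_rec %in% outliers)))
    }
  }
  list(n_infants = length(sp), n_serial = n_serial,
       n_increasing_first_last = n_first_last,
       pct_increasing_first_last =
         if (n_serial) 100 * n_first_last / n_serial else NA_real_,
       n_pairs = n_pairs, n_pairs_increasing = n_pairs_inc,
       pct_pairs_increasing =
         if (n_pairs) 100 * n_pairs_inc / n_pairs else NA_real_,
       n_pairs_deviant = n_pairs - n_pairs_inc,
       deviant = deviant, outlier_recordings = unique(outliers))
}

#' Full evaluation report for a cross-validated EMA table
#'
#' @param ema_table data.frame with \code{infant_id}, \code{recording_id},
#'   \code{pma_days}, \code{ema_days} (e.g. \code{runLOIO()$ema}).
#' @return List combining \code{\link{errorMetrics}},
#'   \code{\link{fitLMM}} (as \code{adjusted_r}, \code{slope}) and
#'   \code{\link{growthAnalysis}} (as \code{growth}), plus
#'   \code{n_recordings} and \code{n_infants}.
#' @export
evaluateEMA <- function(ema_table) {
  em <- errorMetrics(ema_table$ema_days, ema_table$pma_days)
  lmm <- fitLMM(ema_table$ema_days, ema_table$pma_days,
                ema_table$infant_id)
  c(em[setdiff(names(em), "n")],
    list(adjusted_r = lmm$adjusted_r, slope = lmm$slope,
         n_recordings = nrow(ema_table),
         n_infants = length(unique(ema_table$infant_id)),
         growth = growthAnalysis(ema_table)))
}

#' Write an evaluation report as JSON
#'
#' @param report list from \code{\link{evaluateEMA}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEvaluationJSON <- function(report, path) {
  report$growth$deviant <- NULL          # nested frame: keep JSON flat
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Compare EMA accuracy across electrode montages
#'
#' Reruns the full pipeline (feature extraction and leave-one-infant-out
#' EMA) for each montage variant on the same recordings and tests each
#' variant's per-recording squared errors against the reference montage
#' with a paired two-sided Wilcoxon signed-rank test (zero differences
#' dropped, the Wilcoxon convention).  Recordings missing from a variant
#' are dropped from its test with a warning.
#'
#' @param recordings list of \linkS4class{EEGRecording}.
#' @param montages named list of electrode-pair matrices (see
#'   \code{\link{standardMontage}}); the first entry is the reference.
#' @param params \code{\link{emaParams}}.
#' @param featureSelection passed to \code{\link{runLOIO}} (default FALSE:
#'   montage comparisons use all features).
#' @param seed integer seed.
#' @return data.frame, one row per montage: \code{montage},
#'   \code{mse_days2}, \code{adjusted_r}, \code{p_value} (NA for the
#'   reference), \code{n}.
#' @export
compareMontages <- function(recordings,
                            montages = list(m8 = standardMontage(),
                                            fp_t = standardMontage("fp_t"),
                                            t_o = standardMontage("t_o")),
                            params = emaParams(), featureSelection = FALSE,
                            seed = 1) {
  if (is.null(names(montages)) || any(names(montages) == ""))
    stop("montages must be a named list")
  runs <- lapply(names(montages), function(nm) {
    fs <- buildFeatureSet(recordings, params, montage = montages[[nm]])
    cv <- runLOIO(fs, featureSelection = featureSelection, seed = seed)
    cv$ema
  })
  names(runs) <- names(montages)
  ref <- runs[[1]]
  ref_err <- stats::setNames((ref$ema_days - ref$pma_days)^2,
                             ref$recording_id)
  out <- NULL
  for (nm in names(montages)) {
    v <- runs[[nm]]
    em <- errorMetrics(v$ema_days, v$pma_days)
    lmm <- fitLMM(v$ema_days, v$pma_days, v$infant_id)
    p <- NA_real_
    if (nm != names(montages)[1]) {
      common <- intersect(v$recording_id, names(ref_err))
      if (length(common) < nrow(ref))
        warning("montage ", nm, ": ", nrow(ref) - length(common),
                " unpaired recording(s) dropped from the signed-rank test")
      verr <- stats::setNames((v$ema_days - v$pma_days)^2, v$recording_id)
      d <- verr[common] - ref_err[common]
      p <- if (all(d == 0)) 1
        else suppressWarnings(
          stats::wilcox.test(verr[common], ref_err[common],
                             paired = TRUE)$p.value)
    }
    out <- rbind(out, data.frame(montage = nm, mse_days2 = em$mse_days2,
                                 adjusted_r = lmm$adjusted_r,
                                 p_value = p, n = nrow(v)))
  }
  rownames(out) <- NULL
  out
}
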