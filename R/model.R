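#' Fit the EMA support vector regression on a training fold
#'
#' Standardises the features with training-fold mean and sd (the target
#' stays in days), optimises the radial-kernel SVR hyperparameters
#' (regularisation C, eps-insensitive margin, kernel width gamma) by
#' internal cross-validation over a log-spaced grid, and refits on the full
#' training fold with the winning setting.
#'
#' @param X numeric matrix, recordings x features (no missing values; see
#'   \code{\link{runLOIO}} for the imputation policy).
#' @param y numeric, post-menstrual age in days.
#' @param grid hyperparameter grid, default \code{\link{defaultSVRGrid}}.
#' @param innerFolds number of internal CV folds (default 3).
#' @param groups optional grouping (infant ids) kept intact across inner
#'   folds; defaults to one group per row.
#' @param seed integer seed for the inner fold assignment.
#' @param allowConstant permit a constant target (otherwise a degenerate
#'   fit is an error).
#' @return An \linkS4class{EMAModel}.
#' @examples
#' X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, featureRoster()[1:3]))
#' y <- 200 + 20 * X[, 1] + rnorm(40)
#' m <- fitSVR(X, y, grid = defaultSVRGrid(3)[c(10, 100, 200), ], seed = 1)
#' @export
fitSVR <- function(X, y, grid = defaultSVRGrid(ncol(X)), innerFolds = 3,
                   groups = NULL, seed = 1, allowConstant = FALSE) {
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (stats::var(y) == 0 && !allowConstant)
    stop("degenerate-fit: constant target")
  if (anyNA(X)) stop("X contains missing values; impute first")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  if (is.null(groups)) groups <- seq_len(nrow(X))
  foldId <- groupedFolds(groups, innerFolds, seed)
  best <- svrGridSearch(Xs, y, grid, foldId)
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    cost = best$cost, epsilon = best$epsilon,
                    gamma = best$gamma, scale = FALSE, fitted = FALSE)
  med <- apply(X, 2, stats::median)
  new("EMAModel", fit = fit, features = colnames(X),
      center = stats::setNames(ctr, colnames(X)),
      scale = stats::setNames(scl, colnames(X)),
      imputeMedians = stats::setNames(med, colnames(X)),
      hyper = best[c("cost", "epsilon", "gamma")],
      trainInfo = list(seed = seed, inner_cv_mse = best$cv_mse,
                       n_train = nrow(X)))
}

#' Backward feature elimination with cross-validated MSE
#'
#' Produces the complete elimination path from all candidate features down
#' to one: at each step the feature whose removal yields the lowest k-fold
#' CV MSE is eliminated (ties broken towards the lower roster index).  The
#' selected subset is the one at the path minimum MSE; among ties the
#' smallest subset wins.  SVR hyperparameters are optimised by grid search
#' at the full feature set and held fixed along the path (see the package
#' vignette for the rationale).
#'
#' @param X numeric matrix, rows x candidate features (columns in roster
#'   order; no missing values).
#' @param y target in days.
#' @param groups grouping (infant ids) kept intact across CV folds.
#' @param nFolds number of CV folds for the selection (default 10).
#' @param hyper list with \code{cost}, \code{epsilon}, \code{gamma}; when
#'   NULL a grid search at the full feature set supplies it.
#' @param grid hyperparameter grid for that search.
#' @param seed integer seed for the fold assignment.
#' @return List: \code{selected} (feature names), \code{path} (data.frame
#'   with \code{n_features}, \code{removed}, \code{cv_mse}), \code{hyper}.
#'   A warning is emitted when the best CV MSE is not clearly below the
#'   target variance (selection uninformative, as with all-noise
#'   features).
#' @export
backwardFeatureSelection <- function(X, y, groups = NULL, nFolds = 10,
                                     hyper = NULL,
                                     grid = defaultSVRGrid(ncol(X)),
                                     seed = 1) {
  if (anyNA(X)) stop("X contains missing values; impute first")
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  if (is.null(groups)) groups <- seq_len(nrow(X))
  foldId <- groupedFolds(groups, nFolds, seed)
  if (is.null(hyper))
    hyper <- svrGridSearch(Xs, y, grid, foldId)
  # gamma follows the grid convention (proportional to 1/n_features), so
  # the kernel bandwidth per feature stays constant along the path
  p_full <- ncol(X)
  cvm <- function(cols)
    svrCVMSE(Xs[, cols, drop = FALSE], y, foldId,
             hyper$gamma * p_full / length(cols), hyper$cost,
             hyper$epsilon)

  current <- colnames(X)
  path_n <- integer(); path_rm <- character(); path_mse <- numeric()
  path_sets <- list()
  path_n[1] <- length(current); path_rm[1] <- NA_character_
  path_mse[1] <- cvm(current); path_sets[[1]] <- current
  step <- 1L
  while (length(current) > 1) {
    cand_mse <- vapply(current, function(f)
      cvm(setdiff(current, f)), numeric(1))
    drop_f <- current[which.min(cand_mse)]   # first minimum = lower index
    current <- setdiff(current, drop_f)
    step <- step + 1L
    path_n[step] <- length(current)
    path_rm[step] <- drop_f
    path_mse[step] <- cand_mse[drop_f]
    path_sets[[step]] <- current
  }
  minima <- which(path_mse <= min(path_mse) * (1 + 1e-9))
  pick <- minima[length(minima)]             # smallest subset among ties
  if (min(path_mse) > 0.9 * stats::var(y) * (length(y) - 1) / length(y))
    warning("feature selection uninformative: best CV MSE close to the ",
            "target variance")
  list(selected = path_sets[[pick]],
       path = data.frame(n_features = path_n, removed = path_rm,
                         cv_mse = path_mse),
       hyper = hyper)
}

#' Predict the EEG maturational age for feature vectors
#'
#' Missing feature values are imputed with the model's training-fold
#' medians; a selected feature absent from the input is an error.
#' Predictions are reported in days and clamped to the plausible range
#' [140, 320] with a warning.
#'
#' @param model an \linkS4class{EMAModel}.
#' @param fv named numeric vector, matrix or data.frame of feature values.
#' @return Numeric vector of EMA estimates in days.
#' @export
predictEMA <- function(model, fv) {
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1,
                                     dimnames = list(NULL, names(fv)))
  fv <- as.matrix(as.data.frame(fv)[, , drop = FALSE])
  miss <- setdiff(model@features, colnames(fv))
  if (length(miss))
    stop("incomplete-vector: selected feature(s) absent: ",
         paste(miss, collapse = ", "))
  X <- fv[, model@features, drop = FALSE]
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- model@imputeMedians[model@features[j]]
  }
  Xs <- scale(X, model@center[model@features], model@scale[model@features])
  p <- as.numeric(stats::predict(model@fit, Xs))
  if (any(p < 140 | p > 320)) {
    warning("EMA prediction outside the reporting range [140, 320] days; ",
            "clamped")
    p <- pmin(pmax(p, 140), 320)
  }
  p
}

# collapse epoch rows to per-recording feature vectors (mean over epochs)
recordingLevel <- function(tab) {
  feats <- featureRoster()
  sp <- split(tab, tab$recording_id)
  out <- lapply(sp, function(d) {
    fv <- colMeans(d[, feats, drop = FALSE], na.rm = TRUE)
    fv[is.nan(fv)] <- NA_real_
    data.frame(infant_id = d$infant_id[1], recording_id = d$recording_id[1],
               pma_days = d$pma_days[1], n_epochs = nrow(d),
               as.list(fv), check.names = FALSE)
  })
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r[order(r$infant_id, r$pma_days), ]
}

#' Leave-one-infant-out cross-validated EMA
#'
#' Runs the full training/testing protocol: per infant-fold, epoch feature
#' vectors are averaged to one vector per recording, missing values are
#' imputed with training-fold medians, features are optionally selected by
#' backward elimination with a 10-fold CV, SVR hyperparameters are
#' optimised in an internal 3-fold CV, and the held-out infant's
#' recordings are predicted.  All recordings of an infant live in exactly
#' one test fold, so no infant contributes to both sides of a split.
#'
#' @param features a \linkS4class{FeatureSet} or a feature table
#'   data.frame (one row per epoch, the 46 roster columns plus
#'   \code{infant_id}, \code{recording_id}, \code{pma_days}).
#' @param featureSelection run backward elimination per fold (default
#'   TRUE).
#' @param grid hyperparameter grid.
#' @param selectionFolds CV folds inside the selection (default 10).
#' @param innerFolds folds of the hyperparameter optimisation (default 3).
#' @param perRecording average epoch features within a recording and
#'   predict once (default, mirroring per-recording evaluation); when
#'   FALSE, epochs are predicted individually and their EMAs averaged.
#' @param seed integer; every random choice (fold assignments) derives
#'   from it, so a fixed seed gives identical selections and predictions.
#' @return List with \code{ema} (data.frame: \code{infant_id},
#'   \code{recording_id}, \code{pma_days}, \code{ema_days}),
#'   \code{selection} (per-fold selected feature lists),
#'   \code{selectionCounts} (how often each feature was selected),
#'   \code{hyper} (per-fold winning hyperparameters) and \code{folds}.
#' @examples
#' \donttest{
#' cohort <- generateCohort(simConfig(n_infants = 4, rec_dur_s = 600),
#'                          seed = 2)
#' fs <- buildFeatureSet(cohort$recordings, emaParams(epoch_s = 600))
#' cv <- runLOIO(fs, featureSelection = FALSE, seed = 2)
#' head(cv$ema)
#' }
#' @export
runLOIO <- function(features, featureSelection = TRUE,
                    grid = NULL, selectionFolds = 10, innerFolds = 3,
                    perRecording = TRUE, seed = 1) {
  tab <- featureTable(features)
  rec <- recordingLevel(tab)
  infants <- unique(rec$infant_id)
  if (length(infants) < 3) stop("need at least 3 infants for LOIO CV")
  feats <- featureRoster()
  if (is.null(grid)) grid <- defaultSVRGrid(length(feats))

  ema <- NULL
  selection <- list()
  hyper <- list()
  for (i in seq_along(infants)) {
    inf <- infants[i]
    tr <- rec[rec$infant_id != inf, ]
    te <- rec[rec$infant_id == inf, ]
    fold_seed <- (seed + 7919L * i) %% .Machine$integer.max
    Xtr <- as.matrix(tr[, feats])
    med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (j in seq_len(ncol(Xtr)))
      Xtr[is.na(Xtr[, j]), j] <- med[j]
    ytr <- tr$pma_days

    sel <- feats
    if (featureSelection) {
      bs <- backwardFeatureSelection(Xtr, ytr, groups = tr$infant_id,
                                     nFolds = selectionFolds, grid = grid,
                                     seed = fold_seed)
      sel <- bs$selected
    }
    model <- fitSVR(Xtr[, sel, drop = FALSE], ytr, grid = grid,
                    innerFolds = innerFolds, groups = tr$infant_id,
                    seed = fold_seed)
    model@imputeMedians <- med[sel]

    if (perRecording) {
      pred <- suppressWarnings(predictEMA(model, te[, feats]))
      ema_i <- data.frame(infant_id = te$infant_id,
                          recording_id = te$recording_id,
                          pma_days = te$pma_days, ema_days = pred)
    } else {
      tei <- tab[tab$infant_id == inf, ]
      p_epoch <- suppressWarnings(predictEMA(model, tei[, feats]))
      agg <- tapply(p_epoch, tei$recording_id, mean)
      ema_i <- data.frame(infant_id = inf, recording_id = names(agg),
                          pma_days = te$pma_days[match(names(agg),
                                                       te$recording_id)],
                          ema_days = as.numeric(agg))
    }
    ema <- rbind(ema, ema_i)
    selection[[as.character(inf)]] <- sel
    hyper[[as.character(inf)]] <- model@hyper
  }
  counts <- table(factor(unlist(selection), levels = feats))
  rownames(ema) <- NULL
  list(ema = ema, selection = selection,
       selectionCounts = as.integer(counts),
       selectionCountNames = feats, hyper = hyper, folds = infants)
}
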