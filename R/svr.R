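# Lean radial-kernel eps-SVR engine used in the cross-validation hot loops.
#
# Backward feature selection evaluates ~1000 candidate subsets per training
# fold, each with a 10-fold CV, i.e. hundreds of thousands of SVR fits per
# cohort.  e1071::svm spends most of its time in R-side bookkeeping, so the
# hot loops call libsvm's registered training routine directly with fixed
# arguments (dense matrix, radial kernel, eps-regression) and predict from
# the support-vector expansion in vectorised R.  Equality with e1071::svm
# is asserted in the test suite; if the native symbol cannot be resolved the
# code falls back to e1071::svm transparently.

.svrEnv <- new.env(parent = emptyenv())

svrNativeSym <- function() {
  if (!is.null(.svrEnv$sym)) return(.svrEnv$sym)
  sym <- tryCatch(getNativeSymbolInfo("svmtrain", PACKAGE = "e1071"),
                  error = function(e) NULL)
  .svrEnv$sym <- sym
  sym
}

# returns list(SV, coefs, rho); prediction = K(newX, SV) %*% coefs - rho
svrTrain <- function(X, y, gamma, cost, eps) {
  sym <- svrNativeSym()
  if (is.null(sym)) {
    fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      cost = cost, epsilon = eps, gamma = gamma,
                      scale = FALSE, fitted = FALSE)
    return(list(SV = fit$SV, coefs = as.numeric(fit$coefs), rho = fit$rho))
  }
  n <- nrow(X)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(sym, as.double(t(X)), as.integer(n), as.integer(ncol(X)),
             as.double(y), as.integer(0), as.integer(0),
             as.integer(3L),          # eps-regression
             as.integer(2L),          # radial kernel
             as.integer(3L), as.double(gamma), as.double(0),
             as.double(cost), as.double(0.5), as.integer(NULL),
             as.double(NULL), as.integer(0L), as.double(40),
             as.double(0.001), as.double(eps), as.integer(1L),
             as.integer(0L), as.integer(0L), as.integer(0L),
             nclasses = integer(1), nr = integer(1), index = integer(n),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(n), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (cret$error != err) stop("libsvm: ", trimws(cret$error))
  idx <- cret$index[seq_len(cret$nr)]
  list(SV = X[idx, , drop = FALSE], coefs = cret$coefs[seq_len(cret$nr)],
       rho = cret$rho[1])
}

svrPredict <- function(m, newX, gamma) {
  d2 <- outer(rowSums(newX^2), rowSums(m$SV^2), "+") -
    2 * tcrossprod(newX, m$SV)
  as.vector(exp(-gamma * pmax(d2, 0)) %*% m$coefs) - m$rho
}

# k-fold CV mean squared error for one hyperparameter setting
svrCVMSE <- function(X, y, foldId, gamma, cost, eps) {
  sse <- 0
  for (k in unique(foldId)) {
    tr <- foldId != k
    m <- svrTrain(X[tr, , drop = FALSE], y[tr], gamma, cost, eps)
    p <- svrPredict(m, X[!tr, , drop = FALSE], gamma)
    sse <- sse + sum((p - y[!tr])^2)
  }
  sse / length(y)
}

# assign k CV folds, keeping all rows of a group in one fold
groupedFolds <- function(groups, k, seed) {
  u <- unique(groups)
  k <- min(k, length(u))
  set.seed(seed)
  gf <- stats::setNames(sample(rep_len(seq_len(k), length(u))), u)
  unname(gf[as.character(groups)])
}

#' Default hyperparameter grid for the EMA support vector regression
#'
#' Log-spaced radial-kernel SVR grid bracketing day-scale targets:
#' regularisation C in 2^-2..2^6, eps-insensitive margin in
#' \{0.5, 1, 2, 4, 8\} days, kernel width gamma in 2^-6..2^2 divided by the
#' number of features.
#'
#' @param n_features number of features the model will see.
#' @return data.frame with columns \code{cost}, \code{epsilon},
#'   \code{gamma}.
#' @export
defaultSVRGrid <- function(n_features) {
  expand.grid(cost = 2^seq(-2, 6, by = 1),
              epsilon = c(0.5, 1, 2, 4, 8),
              gamma = 2^seq(-6, 2, by = 1) / n_features)
}

# Grid search by k-fold CV with the one-standard-error rule: among the
# settings whose CV MSE lies within one standard error of the minimum,
# pick the least complex (largest eps-margin, then smallest cost, then
# smallest gamma).  With hundreds of candidate settings and a noisy
# few-fold MSE estimate, picking the raw minimum systematically overfits
# the CV folds (winner's curse); the 1-SE rule is the standard guard.
# Returns list(cost, epsilon, gamma, cv_mse).
svrGridSearch <- function(X, y, grid, foldId) {
  ks <- unique(foldId)
  mse_fold <- vapply(seq_len(nrow(grid)), function(i) {
    vapply(ks, function(k) {
      tr <- foldId != k
      m <- svrTrain(X[tr, , drop = FALSE], y[tr], grid$gamma[i],
                    grid$cost[i], grid$epsilon[i])
      mean((svrPredict(m, X[!tr, , drop = FALSE], grid$gamma[i]) -
              y[!tr])^2)
    }, numeric(1))
  }, numeric(length(ks)))
  w <- vapply(ks, function(k) sum(foldId == k), numeric(1))
  mse <- colSums(mse_fold * w) / sum(w)
  b <- which.min(mse)
  se <- stats::sd(mse_fold[, b]) / sqrt(length(ks))
  ok <- which(mse <= mse[b] + se)
  i <- ok[order(-grid$epsilon[ok], grid$cost[ok], grid$gamma[ok])][1]
  list(cost = grid$cost[i], epsilon = grid$epsilon[i],
       gamma = grid$gamma[i], cv_mse = mse[i])
}
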