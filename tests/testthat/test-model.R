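# feature matrices here use roster names (the model requires them)
rosterX <- function(n, p_used, seed) {
  set.seed(seed)
  matrix(rnorm(n * p_used), n,
         dimnames = list(NULL, featureRoster()[seq_len(p_used)]))
}

test_that("the lean SVR engine is exact against e1071", {
  set.seed(1)
  X <- matrix(rnorm(60 * 8), 60)
  y <- rnorm(60, 210, 20)
  for (hp in list(c(1, 1, 0.1), c(16, 4, 0.02), c(0.5, 0.5, 0.3))) {
    ref <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      cost = hp[1], epsilon = hp[2], gamma = hp[3],
                      scale = FALSE, fitted = FALSE)
    lean <- neoEMA:::svrTrain(X, y, gamma = hp[3], cost = hp[1], eps = hp[2])
    expect_equal(neoEMA:::svrPredict(lean, X[1:10, ], hp[3]),
                 unname(predict(ref, X[1:10, ])), tolerance = 1e-10)
  }
})

test_that("SVR recovers a linear relationship and respects the eps tube", {
  n <- 60
  X <- rosterX(n, 6, seed = 2)
  y <- 210 + 15 * X[, 1] + rnorm(n, sd = 1)
  m <- fitSVR(X[1:45, ], y[1:45], seed = 1)
  expect_s4_class(m, "EMAModel")
  pred <- predictEMA(m, X[46:60, ])
  expect_lt(mean((pred - y[46:60])^2), var(y) / 4)
  # a feature equal to y: held-out predictions within eps + tolerance
  X2 <- rosterX(n, 3, seed = 3)
  y2 <- 180 + 40 * stats::runif(n)
  X2[, 1] <- y2
  m2 <- fitSVR(X2, y2, seed = 1)
  p2 <- predictEMA(m2, X2)
  expect_lt(max(abs(p2 - y2)), m2@hyper$epsilon + 2)
  # duplicate of a training row predicts close to its target
  expect_lt(abs(predictEMA(m2, X2[5, , drop = FALSE]) - y2[5]),
            m2@hyper$epsilon + 2)
  expect_error(fitSVR(X2, rep(200, n)), "degenerate-fit")
})

test_that("permuted labels destroy the fit (no spurious skill)", {
  n <- 80
  X <- rosterX(n, 10, seed = 4)
  y <- 200 + 12 * X[, 1] + rnorm(n, sd = 2)
  set.seed(5)
  yp <- sample(y)
  tr <- 1:60; te <- 61:80
  m_real <- fitSVR(X[tr, ], y[tr], seed = 1)
  m_perm <- fitSVR(X[tr, ], yp[tr], seed = 1)
  mse_real <- mean((predictEMA(m_real, X[te, ]) - y[te])^2)
  mse_perm <- mean((predictEMA(m_perm, X[te, ]) - yp[te])^2)
  expect_lt(mse_real, 0.5 * var(y))
  expect_gt(mse_perm, 0.5 * var(yp))
})

test_that("backward elimination keeps informative features, drops duplicates", {
  # 3 informative + 12 noise features
  n <- 60
  X <- rosterX(n, 15, seed = 6)
  y <- 200 + 10 * X[, 1] - 8 * X[, 2] + 6 * X[, 3] + rnorm(n, sd = 2)
  sel <- backwardFeatureSelection(X, y, seed = 1)
  expect_true(all(colnames(X)[1:3] %in% sel$selected))
  expect_lt(length(sel$selected), 15)
  expect_equal(nrow(sel$path), 15)
  expect_equal(sel$path$n_features, 15:1)
  # one feature duplicated: redundancy collapses towards a single copy
  Xd <- matrix(rep(X[, 1], 8), n,
               dimnames = list(NULL, featureRoster()[1:8]))
  yd <- 200 + 10 * X[, 1] + rnorm(n, sd = 1)
  seld <- backwardFeatureSelection(Xd, yd, seed = 1)
  expect_length(seld$selected, 1)
  # all-noise features: no crash, warning, MSE near target variance
  Xn <- rosterX(n, 10, seed = 7)
  yn <- rnorm(n, 210, 15)
  expect_warning(seln <- backwardFeatureSelection(Xn, yn, seed = 1),
                 "uninformative")
  expect_lt(min(seln$path$cv_mse), 3 * var(yn))
})

test_that("LOIO folds isolate infants and the run is deterministic", {
  fs <- smallCohortFeatures()
  cv <- runLOIO(fs, featureSelection = FALSE, seed = 9)
  tab <- featureTable(fs)
  expect_equal(sort(unique(cv$ema$infant_id)),
               sort(unique(tab$infant_id)))
  expect_length(cv$folds, 4)
  # selection-frequency counts are bounded by the number of folds
  expect_true(all(cv$selectionCounts <= length(cv$folds)))
  # determinism: identical predictions and selections on a rerun
  cv2 <- runLOIO(fs, featureSelection = FALSE, seed = 9)
  expect_identical(cv$ema, cv2$ema)
  expect_identical(cv$selection, cv2$selection)
})

test_that("no leakage: test-fold perturbations in the table do not matter", {
  fs <- smallCohortFeatures()
  tab <- featureTable(fs)
  cv <- runLOIO(tab, featureSelection = FALSE, seed = 3)
  # corrupt one infant's rows, then hold that infant out: its training
  # folds never saw the corruption, so all predictions are byte-identical
  tab2 <- tab
  bad <- tab2$infant_id == tab2$infant_id[1]
  tab2[bad, featureRoster()] <- tab2[bad, featureRoster()] * 5 + 1
  cv_ref <- runLOIO(tab, featureSelection = FALSE, seed = 3)
  expect_identical(cv$ema, cv_ref$ema)
  cv_pert <- runLOIO(tab2, featureSelection = FALSE, seed = 3)
  other <- cv$ema$infant_id != tab$infant_id[1]
  expect_false(identical(cv$ema$ema_days[!other],
                         cv_pert$ema$ema_days[!other]))
  # rows of unaffected infants change only through training-set rows of
  # the corrupted infant; removing that infant entirely makes the rest
  # independent of the corruption
  tab_wo <- tab[!bad, ]
  tab2_wo <- tab2[!bad, ]
  expect_identical(runLOIO(tab_wo, featureSelection = FALSE, seed = 3)$ema,
                   runLOIO(tab2_wo, featureSelection = FALSE, seed = 3)$ema)
})

test_that("predictEMA enforces completeness and the reporting range", {
  X <- rosterX(50, 4, seed = 8)
  y <- 200 + 10 * X[, 1] + rnorm(50)
  m <- fitSVR(X, y, seed = 1)
  expect_error(predictEMA(m, X[, 1:3]), "incomplete-vector")
  # imputation: NA features filled with training medians, prediction sane
  xna <- X[1, ]; xna[2] <- NA
  p <- predictEMA(m, xna)
  expect_true(p >= 140 && p <= 320)
  # mean feature vector predicts within the training target range
  expect_true(predictEMA(m, colMeans(X)) >= min(y) - 10)
  expect_true(predictEMA(m, colMeans(X)) <= max(y) + 10)
})
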