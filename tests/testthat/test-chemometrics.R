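# PCA-SVM classification against eigendecomposition and QP-dual oracles.

test_that("PCA matches the covariance eigendecomposition on random matrices", {
  set.seed(101)
  for (rep in 1:3) {
    X <- matrix(rnorm(20 * 50), 20, 50)
    pf <- fit_pca(X, n_components = 5)
    C <- cov(X)
    ev <- eigen(C, symmetric = TRUE)
    evr_oracle <- ev$values / sum(diag(C))
    expect_equal(pf$model$explained_variance_ratio,
                 evr_oracle[1:5], tolerance = 1e-8)
    # scores match up to the fixed sign convention (applied to oracle too)
    Xc <- sweep(X, 2, colMeans(X))
    V <- ev$vectors[, 1:5]
    for (k in 1:5) if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
    expect_equal(pf$scores, Xc %*% V, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("PCA satisfies orthonormality, variance ordering and the rank-1 case", {
  set.seed(7)
  u <- rnorm(30); v <- rnorm(40)
  pf1 <- fit_pca(outer(u, v), n_components = 1)
  expect_equal(pf1$model$explained_variance_ratio[1], 1, tolerance = 1e-10)

  X <- matrix(rnorm(25 * 60), 25, 60)
  pf <- fit_pca(X, n_components = 4)
  L <- pf$model$loadings
  expect_equal(L %*% t(L), diag(4), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(pf$model$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pf$model$explained_variance_ratio), 1 + 1e-12)
  # sign convention: largest-magnitude loading element is positive
  for (k in 1:4) expect_gt(L[k, which.max(abs(L[k, ]))], 0)
  expect_error(fit_pca(X, n_components = 25), "exceeds")
})

test_that("PCA on the default two-class set concentrates variance in two components", {
  sim <- simulate_dose_ladder(doses = c(0, 1), viable_fractions = c(0.99, 0.13),
                              n_cells = 400, batch = 2L, seed = 61L)
  basis <- fixture_basis(default_axis())
  pp <- preprocess_spectra(sim$spectra, basis)
  pf <- fit_pca(pp$spectra, 2)
  expect_gt(sum(pf$model$explained_variance_ratio), 0.8)
})

test_that("SVM separates separable clouds and matches the dual-QP oracle", {
  cl <- fixture_clouds(n_per = 20, delta = 6, sigma = 0.5, seed = 3L)
  m <- train_svm(cl$scores, cl$labels, standardize = FALSE)
  expect_equal(unname(predict_labels(m, cl$scores)), cl$labels)
  expect_gt(sqrt(sum(m$weights^2)), 0)

  # brute-force SMO solution of the dual on the same <= 40-point instance
  y <- ifelse(cl$labels == "viable", 1, -1)
  o <- oracle_svm_dual(cl$scores, y, C = 1)
  expect_lt(max(abs(decision_values(m, cl$scores) -
                    (cl$scores %*% o$w + o$b))), 1e-4)

  # a non-separable instance too
  cl2 <- fixture_clouds(n_per = 18, delta = 1.5, sigma = 1, seed = 5L)
  m2 <- train_svm(cl2$scores, cl2$labels, standardize = FALSE)
  y2 <- ifelse(cl2$labels == "viable", 1, -1)
  o2 <- oracle_svm_dual(cl2$scores, y2, C = 1)
  expect_lt(max(abs(decision_values(m2, cl2$scores) -
                    (cl2$scores %*% o2$w + o2$b))), 1e-4)
})

test_that("label flip negates the decision function and single-class input errors", {
  cl <- fixture_clouds(seed = 9L)
  m <- train_svm(cl$scores, cl$labels, standardize = FALSE)
  flipped <- ifelse(cl$labels == "viable", "non_viable", "viable")
  mf <- train_svm(cl$scores, flipped, standardize = FALSE)
  expect_equal(mf$weights, -m$weights, tolerance = 1e-5)
  expect_equal(mf$bias, -m$bias, tolerance = 1e-5)
  expect_error(train_svm(cl$scores, rep("viable", nrow(cl$scores))),
               "both classes")
})

test_that("internal standardization is exactly the scale-fold-back identity", {
  cl <- fixture_clouds(seed = 13L)
  sc <- cl$scores %*% diag(c(0.01, 5))   # wildly different dimension scales
  m_std <- train_svm(sc, cl$labels, standardize = TRUE)
  mu <- colMeans(sc); sdv <- apply(sc, 2, sd)
  Z <- sweep(sweep(sc, 2, mu), 2, sdv, "/")
  m_raw <- train_svm(Z, cl$labels, standardize = FALSE)
  expect_equal(decision_values(m_std, sc), decision_values(m_raw, Z),
               tolerance = 1e-8)
})

test_that("cross-validated cost is zero on separable data and tracks the Bayes rate", {
  cl <- fixture_clouds(n_per = 60, delta = 6, sigma = 0.5, seed = 21L)
  expect_equal(crossval_cost(cl$scores, cl$labels, folds = 10, seed = 1), 0)
  expect_equal(crossval_cost(cl$scores, cl$labels, folds = 2, seed = 1), 0)

  # overlap tuned to a ~5% Bayes error: delta/(2*sigma) = qnorm(0.95)
  sigma <- 1; delta <- 2 * sigma * qnorm(0.95)
  bayes <- oracle_gaussian_bayes_error(delta, sigma)
  cl2 <- fixture_clouds(n_per = 1000, delta = delta, sigma = sigma, seed = 22L)
  cost <- crossval_cost(cl2$scores, cl2$labels, folds = 10, seed = 2)
  expect_lt(abs(cost - bayes), 0.02)

  expect_error(crossval_cost(cl$scores[c(1:6, 61:66), ],
                             cl$labels[c(1:6, 61:66)], folds = 10),
               "at least")
})

test_that("viability prediction is self-consistent and guards provenance", {
  sim <- simulate_dose_ladder(doses = c(0, 0.5), viable_fractions = c(0.99, 0.3),
                              n_cells = 300, batch = 2L, seed = 71L)
  basis <- fixture_basis(default_axis())
  pp <- preprocess_spectra(sim$spectra, basis)
  cls <- train_classifier(pp$spectra, train_batch = 2L,
                          control_label = "control", highdose_label = "0.5 uM",
                          seed = 3L)
  pred <- predict_viability(pp$spectra, cls$pca, cls$svm)
  # in-sample predictions equal train-time predictions exactly
  tr_rows <- pp$spectra$meta$condition_label %in% c("control", "0.5 uM")
  expect_identical(pred$per_cell[tr_rows],
                   unname(predict_labels(cls$svm, cls$train_scores)))
  # training-set percent viable is within cv_cost of the label percentage
  ctrl_pct <- pred$per_condition$percent_viable[
    pred$per_condition$condition_label == "control"]
  expect_lt(abs(ctrl_pct - 100) / 100, cls$svm$cv_cost + 0.05)
  expect_equal(pred$per_condition$percent_viable,
               100 * pred$per_condition$n_viable_predicted /
                 pred$per_condition$n_cells)

  # provenance mismatch: different region windows must be named
  other <- preprocess_spectra(sim$spectra, basis,
                              regions = region_spec(list(c(615, 1700),
                                                         c(2790, 3010))))
  # area_normalize is the first step whose recorded windows diverge
  expect_error(predict_viability(other$spectra, cls$pca, cls$svm),
               "area_normalize")
})

test_that("all-viable wells predict >= 95% viable", {
  sim <- simulate_dose_ladder(doses = c(0, 1), viable_fractions = c(1, 0.13),
                              n_cells = 400, batch = 2L, seed = 81L)
  basis <- fixture_basis(default_axis())
  pp <- preprocess_spectra(sim$spectra, basis)
  cls <- train_classifier(pp$spectra, 2L, "control", "1 uM", seed = 4L)
  pred <- predict_viability(pp$spectra, cls$pca, cls$svm)
  expect_gte(pred$per_condition$percent_viable[
    pred$per_condition$condition_label == "control"], 95)
})

test_that("reconstruction satisfies the zero, completeness and Parseval identities", {
  set.seed(31)
  X <- matrix(rnorm(15 * 30), 15, 30)
  full <- fit_pca(X, n_components = 14)
  # zero scores + mean = mean spectrum
  z <- reconstruct_spectra(matrix(0, 1, 14), full$model, add_mean = TRUE)
  expect_equal(z[1, ], colMeans(X), tolerance = 1e-12, ignore_attr = TRUE)
  # all components reconstruct the data exactly
  rec <- reconstruct_spectra(full$scores, full$model, add_mean = TRUE)
  expect_equal(rec, X, tolerance = 1e-10, ignore_attr = TRUE)
  # 2-component reconstruction error equals the discarded variance (SVD oracle)
  two <- fit_pca(X, n_components = 2)
  rec2 <- reconstruct_spectra(two$scores, two$model, add_mean = TRUE)
  err2 <- sum((X - rec2)^2)
  d2 <- svd(sweep(X, 2, colMeans(X)))$d^2
  expect_equal(err2, sum(d2[-(1:2)]), tolerance = 1e-8)
  expect_error(reconstruct_spectra(matrix(0, 1, 3), two$model), "do not match")
})

test_that("boundary spectra cross the decision hyperplane analytically", {
  set.seed(41)
  X <- matrix(rnorm(30 * 25), 30, 25)
  pf <- fit_pca(X, n_components = 2)
  svm <- structure(list(weights = c(1, 0), bias = 0,
                        classes = c("viable", "non_viable")),
                   class = "svm_model")
  out <- boundary_spectra(pf$model, svm, pc2_value = 0.7,
                          pc1_range = c(-2, 2), n_points = 9)
  expect_equal(unname(out$crossing["PC1"]), 0)
  expect_lt(abs(out$decision_values[out$threshold_index]), 1e-10)
  # general weights: crossing decision value still 0 by construction
  svm2 <- structure(list(weights = c(0.8, -0.4), bias = 0.3,
                         classes = c("viable", "non_viable")),
                    class = "svm_model")
  out2 <- boundary_spectra(pf$model, svm2, pc2_value = -0.5,
                           pc1_range = c(-5, 5))
  expect_lt(abs(out2$decision_values[out2$threshold_index]), 1e-10)
  expect_equal(out2$threshold_spectrum,
               reconstruct_spectra(matrix(out2$crossing, 1), pf$model,
                                   add_mean = TRUE)[1, ])
  # a line that cannot cross
  svm3 <- structure(list(weights = c(0, 1), bias = 0.1,
                         classes = c("viable", "non_viable")),
                    class = "svm_model")
  expect_error(boundary_spectra(pf$model, svm3, 0, c(-2, 2)), "parallel")
  expect_error(boundary_spectra(pf$model, svm2, -0.5, c(4.9, 5)), "does not cross")
})

test_that("boundary-line spectra differ across classes like the class means do", {
  sim <- simulate_dose_ladder(doses = c(0, 1), viable_fractions = c(1, 0),
                              n_cells = 200, batch = 2L, seed = 91L)
  basis <- fixture_basis(default_axis())
  pp <- preprocess_spectra(sim$spectra, basis)
  cls <- train_classifier(pp$spectra, 2L, "control", "1 uM", seed = 5L)
  pred <- predict_viability(pp$spectra, cls$pca, cls$svm)
  med2 <- median(pred$scores[, 2])
  r <- range(pred$scores[, 1])
  out <- boundary_spectra(cls$pca, cls$svm, pc2_value = med2,
                          pc1_range = r, n_points = 11, add_mean = FALSE)
  viable_side <- out$decision_values > 0
  dline <- colMeans(out$spectra[viable_side, , drop = FALSE]) -
    colMeans(out$spectra[!viable_side, , drop = FALSE])
  truth <- pp$spectra$meta$ground_truth_label
  dclass <- colMeans(pp$spectra$intensities[truth == "viable", ]) -
    colMeans(pp$spectra$intensities[truth == "non_viable", ])
  # sign agreement at the strongly discriminative channels
  strong <- abs(dclass) > stats::quantile(abs(dclass), 0.9)
  agree <- mean(sign(dline[strong]) == sign(dclass[strong]))
  expect_gt(agree, 0.9)
})
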