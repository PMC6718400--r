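# PCA on preprocessed spectra, linear SVM on the first two principal-
# component scores, cross-validated cost, mixed-population viability
# prediction, spectral reconstruction, and decision-boundary spectra.

#' Principal component analysis of a spectra set
#'
#' Mean-centered singular value decomposition. Loading signs are fixed so
#' that each loading's element of largest absolute value is positive (first
#' such element on ties), making scores deterministic across runs and
#' platforms.
#'
#' @param s A `spectra_set`, or a plain numeric matrix (cells x channels).
#' @param n_components Number of components to keep (default 2).
#' @return List with `model` (class `pca_model`: `mean_spectrum`, `loadings`
#'   as a components x channels matrix with orthonormal rows,
#'   `explained_variance_ratio`, `n_components_kept`, `axis`, and the
#'   training provenance) and `scores` (cells x components matrix).
#' @export
fit_pca <- function(s, n_components = 2) {
  if (inherits(s, "spectra_set")) {
    X <- s$intensities; axis <- s$axis; prov <- s$provenance
  } else {
    X <- as.matrix(s); axis <- seq_len(ncol(X)); prov <- list()
  }
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p))
    stop("n_components (", n_components, ") exceeds min(rows - 1, channels) = ",
         min(n - 1, p))
  if (n < n_components + 1)
    stop("need at least n_components + 1 rows (", n_components + 1, "), got ", n)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n - 1, p))
  d2 <- sv$d[seq_len(min(n - 1, p))]^2
  evr <- d2 / sum(d2)
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  scores <- Xc %*% V
  model <- structure(list(mean_spectrum = mu,
                          loadings = t(V),
                          explained_variance_ratio = evr[seq_len(n_components)],
                          explained_variance_ratio_all = evr,
                          n_components_kept = n_components,
                          axis = axis, provenance = prov),
                     class = "pca_model")
  list(model = model, scores = scores)
}

#' Project spectra onto a fitted PCA model
#'
#' @param s A `spectra_set` or matrix on the training axis.
#' @param pca A `pca_model`.
#' @return Scores matrix (cells x kept components).
#' @export
project_pca <- function(s, pca) {
  X <- if (inherits(s, "spectra_set")) s$intensities else as.matrix(s)
  if (ncol(X) != length(pca$mean_spectrum))
    stop("channel count does not match the PCA model")
  sweep(X, 2, pca$mean_spectrum) %*% t(pca$loadings)
}

# ---- SVM -------------------------------------------------------------------

#' Train a linear soft-margin SVM on PC scores
#'
#' Two classes, `viable` and `non_viable`, separated by the hyperplane
#' `weights . z + bias = 0` with the sign convention `f(z) > 0` implies
#' viable. The solver is a standard soft-margin dual solver with box
#' constraint `C`; `alpha_init` is carried as solver-initialization metadata
#' and does not affect the converged model.
#'
#' @param train_scores Numeric matrix of scores (rows = cells).
#' @param train_labels Character/factor with values `"viable"` /
#'   `"non_viable"`; both classes must be present.
#' @param C Box constraint (default 1).
#' @param alpha_init Recorded initialization value (default 0.5; metadata).
#' @param tolerance Solver termination tolerance.
#' @param standardize Center and unit-scale each score dimension before
#'   solving (default `TRUE`: PC scores of area-normalized spectra carry
#'   arbitrary small units, and a fixed `C` is only meaningful on a fixed
#'   feature scale). The transformation is folded back into `weights` and
#'   `bias`, so the returned model is an exact linear function of the raw
#'   scores either way.
#' @return Object of class `svm_model` with `weights`, `bias`, `C`,
#'   `alpha_init`, `classes`, and `cv_cost` (NA until [crossval_cost()]).
#' @export
train_svm <- function(train_scores, train_labels, C = 1, alpha_init = 0.5,
                      tolerance = 1e-7, standardize = TRUE) {
  train_scores <- as.matrix(train_scores)
  lab <- as.character(train_labels)
  if (!all(lab %in% c("viable", "non_viable")))
    stop("labels must be 'viable' or 'non_viable'")
  if (length(unique(lab)) < 2)
    stop("both classes must be present in the training labels")
  if (standardize) {
    mu <- colMeans(train_scores)
    sdv <- apply(train_scores, 2, sd)
    sdv[sdv <= 0] <- 1
    X <- sweep(sweep(train_scores, 2, mu), 2, sdv, "/")
  } else {
    mu <- rep(0, ncol(train_scores)); sdv <- rep(1, ncol(train_scores))
    X <- train_scores
  }
  fit <- e1071::svm(x = X, y = factor(lab), kernel = "linear",
                    cost = C, scale = FALSE, tolerance = tolerance)
  w_std <- as.vector(t(fit$coefs) %*% fit$SV)
  w <- w_std / sdv
  b <- -fit$rho - sum(w_std * mu / sdv)
  f <- as.vector(train_scores %*% w + b)
  if (mean(f[lab == "viable"]) < mean(f[lab == "non_viable"])) {
    w <- -w; b <- -b
  }
  structure(list(weights = w, bias = b, C = C, alpha_init = alpha_init,
                 classes = c("viable", "non_viable"), cv_cost = NA_real_),
            class = "svm_model")
}

#' Decision values of a linear SVM
#' @param model An `svm_model`.
#' @param scores Score matrix or vector.
#' @return Numeric decision values `weights . z + bias`.
#' @export
decision_values <- function(model, scores) {
  scores <- if (is.null(dim(scores))) matrix(scores, nrow = 1) else as.matrix(scores)
  as.vector(scores %*% model$weights + model$bias)
}

#' Predict class labels from scores
#' @param model An `svm_model`.
#' @param scores Score matrix.
#' @return Character vector, `"viable"` where the decision value is > 0.
#' @export
predict_labels <- function(model, scores) {
  ifelse(decision_values(model, scores) > 0, "viable", "non_viable")
}

#' Stratified k-fold cross-validated misclassification cost
#'
#' Stratified folds (seeded shuffle within each class), per-fold retraining,
#' pooled misclassification rate over all held-out points.
#'
#' @param train_scores Score matrix.
#' @param train_labels Labels (`"viable"` / `"non_viable"`).
#' @param C Box constraint.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Misclassification rate in `[0, 1]`.
#' @export
crossval_cost <- function(train_scores, train_labels, C = 1, folds = 10,
                          seed = 1L) {
  train_scores <- as.matrix(train_scores)
  lab <- as.character(train_labels)
  if (folds < 2) stop("folds must be >= 2")
  if (length(unique(lab)) < 2)
    stop("both classes must be present for cross-validation")
  counts <- table(lab)
  if (any(counts < folds))
    stop("each class needs at least `folds` members (have ",
         paste(counts, collapse = "/"), " for ", folds, " folds)")
  set.seed(seed)
  fold_of <- integer(length(lab))
  for (cl in unique(lab)) {
    idx <- sample(which(lab == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  wrong <- 0L
  for (k in seq_len(folds)) {
    te <- fold_of == k
    m <- train_svm(train_scores[!te, , drop = FALSE], lab[!te], C = C)
    wrong <- wrong + sum(predict_labels(m, train_scores[te, , drop = FALSE]) != lab[te])
  }
  wrong / length(lab)
}

# ---- viability prediction --------------------------------------------------

# provenance steps that must match between training and prediction data
prov_fingerprint <- function(prov) {
  keep <- c("select_regions", "area_normalize", "smooth")
  Filter(function(r) r$op %in% keep, prov)
}

check_provenance_match <- function(train_prov, pred_prov) {
  a <- prov_fingerprint(train_prov)
  b <- prov_fingerprint(pred_prov)
  ops_a <- vapply(a, `[[`, "", "op")
  ops_b <- vapply(b, `[[`, "", "op")
  if (!identical(ops_a, ops_b))
    stop("preprocessing provenance mismatch: training ran [",
         paste(ops_a, collapse = ", "), "] but prediction data ran [",
         paste(ops_b, collapse = ", "), "]")
  for (i in seq_along(a)) {
    if (!isTRUE(all.equal(a[[i]]$params, b[[i]]$params)))
      stop("preprocessing provenance mismatch at step '", a[[i]]$op,
           "': parameters differ between training and prediction data")
  }
  invisible(TRUE)
}

#' Predict viability of a mixed population
#'
#' Projects preprocessed spectra onto the kept PCA loadings (using the
#' training mean), classifies each cell with the linear SVM, and aggregates
#' the percentage of viable cells per condition and batch. The prediction
#' data must have been preprocessed identically to the training data; the
#' recorded provenance is compared and a divergent step is named.
#'
#' @param s Preprocessed `spectra_set`.
#' @param pca A `pca_model`.
#' @param svm An `svm_model`.
#' @return Object of class `viability_prediction`: `per_condition` data
#'   frame (`condition_label`, `batch`, `dose`, `n_cells`,
#'   `n_viable_predicted`, `percent_viable`), `per_cell` labels aligned to
#'   rows, and the score matrix.
#' @export
predict_viability <- function(s, pca, svm) {
  validate_spectra_set(s)
  check_provenance_match(pca$provenance, s$provenance)
  scores <- project_pca(s, pca)
  labels <- predict_labels(svm, scores)
  grp <- interaction(s$meta$condition_label, s$meta$batch, drop = TRUE)
  per_condition <- do.call(rbind, lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    data.frame(condition_label = s$meta$condition_label[idx[1]],
               batch = s$meta$batch[idx[1]],
               dose = s$meta$dose[idx[1]],
               n_cells = length(idx),
               n_viable_predicted = sum(labels[idx] == "viable"),
               stringsAsFactors = FALSE)
  }))
  per_condition$percent_viable <- 100 * per_condition$n_viable_predicted /
    per_condition$n_cells
  per_condition <- per_condition[order(per_condition$batch, per_condition$dose), ]
  rownames(per_condition) <- NULL
  structure(list(per_condition = per_condition, per_cell = labels,
                 scores = scores),
            class = "viability_prediction")
}

#' @export
print.viability_prediction <- function(x, ...) {
  cat("<viability_prediction>\n")
  print(x$per_condition)
  invisible(x)
}

# ---- reconstruction and boundary spectra -----------------------------------

#' Reconstruct spectra from PC scores
#'
#' `scores %*% loadings`, optionally adding the training mean spectrum.
#' Reconstruction without the mean isolates the spectral variation the
#' kept components encode.
#'
#' @param scores Matrix with one column per kept component.
#' @param pca A `pca_model`.
#' @param add_mean Add the mean spectrum (default `FALSE`).
#' @return Spectra matrix (rows x channels).
#' @export
reconstruct_spectra <- function(scores, pca, add_mean = FALSE) {
  scores <- if (is.null(dim(scores))) matrix(scores, nrow = 1) else as.matrix(scores)
  if (ncol(scores) != nrow(pca$loadings))
    stop("score columns (", ncol(scores), ") do not match kept components (",
         nrow(pca$loadings), ")")
  out <- scores %*% pca$loadings
  if (add_mean) out <- sweep(out, 2, pca$mean_spectrum, "+")
  out
}

#' Reconstructed spectra along a line crossing the decision boundary
#'
#' Reconstructs spectra whose scores lie on a line parallel to the PC1 axis
#' at a fixed PC2 value, and solves the boundary crossing analytically from
#' `weights . z + bias = 0`. The crossing spectrum is the spectral-domain
#' decision threshold between viable and non-viable cells.
#'
#' @param pca A `pca_model` (2 kept components).
#' @param svm An `svm_model`.
#' @param pc2_value Fixed PC2 coordinate of the line.
#' @param pc1_range Length-2 numeric range of PC1 values.
#' @param n_points Number of points along the line (default 7).
#' @param add_mean Add the mean spectrum to reconstructions (default `TRUE`).
#' @return List with `scores` (line points plus the crossing, ordered by
#'   PC1), `spectra`, `decision_values`, `crossing` (score coordinates of
#'   the boundary point), `threshold_index` and `threshold_spectrum`.
#' @export
boundary_spectra <- function(pca, svm, pc2_value, pc1_range, n_points = 7,
                             add_mean = TRUE) {
  if (pca$n_components_kept != 2)
    stop("boundary_spectra requires a 2-component PCA model")
  w <- svm$weights
  if (abs(w[1]) < .Machine$double.eps)
    stop("line parallel to the PC1 axis never crosses the decision boundary ",
         "(PC1 weight is zero)")
  t_cross <- -(svm$bias + w[2] * pc2_value) / w[1]
  if (t_cross < min(pc1_range) || t_cross > max(pc1_range))
    stop("the line does not cross the decision boundary inside pc1_range ",
         "(crossing at PC1 = ", format(t_cross), ")")
  t_grid <- sort(unique(c(seq(min(pc1_range), max(pc1_range),
                              length.out = n_points), t_cross)))
  scores <- cbind(PC1 = t_grid, PC2 = pc2_value)
  spectra <- reconstruct_spectra(scores, pca, add_mean = add_mean)
  dv <- decision_values(svm, scores)
  ti <- which(t_grid == t_cross)[1]
  list(scores = scores, spectra = spectra, decision_values = dv,
       crossing = c(PC1 = t_cross, PC2 = pc2_value),
       threshold_index = ti, threshold_spectrum = spectra[ti, ])
}

#' Train the PCA-SVM classifier on selected conditions
#'
#' Mirrors the assay protocol: the training set is one control condition plus
#' the highest-dose condition of one batch, with condition-level labels
#' (control rows labelled viable, high-dose rows non-viable), accepting the
#' label noise of the underlying reference viabilities.
#'
#' @param s Preprocessed `spectra_set` (all conditions).
#' @param train_batch Batch whose conditions are used for training.
#' @param control_label,highdose_label Condition labels of the two training
#'   wells.
#' @param n_components Kept components (default 2).
#' @param C Box constraint.
#' @param folds,seed Cross-validation parameters.
#' @return List with `pca`, `svm` (with `cv_cost` filled), `train_scores`,
#'   `train_labels`.
#' @export
train_classifier <- function(s, train_batch, control_label, highdose_label,
                             n_components = 2, C = 1, folds = 10, seed = 1L) {
  sel <- s$meta$batch == train_batch &
    s$meta$condition_label %in% c(control_label, highdose_label)
  if (!any(sel)) stop("no rows match the requested training conditions")
  tr <- subset_spectra(s, sel)
  pf <- fit_pca(tr, n_components = n_components)
  labels <- ifelse(tr$meta$condition_label == control_label, "viable", "non_viable")
  svm <- train_svm(pf$scores, labels, C = C)
  svm$cv_cost <- crossval_cost(pf$scores, labels, C = C, folds = folds, seed = seed)
  list(pca = pf$model, svm = svm, train_scores = pf$scores, train_labels = labels)
}
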