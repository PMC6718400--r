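# Independent oracles used across the suite. Each is a brute-force or
# closed-form route that never shares code with the implementation it checks.

# Soft-margin linear SVM dual solved by plain pairwise SMO to tight KKT
# tolerance; y must be +/-1. Independent of the package's solver.
oracle_svm_dual <- function(X, y, C = 1, tol = 1e-12) {
  n <- nrow(X)
  K <- X %*% t(X)
  a <- rep(0, n)
  for (sweep in 1:10000) {
    changed <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      f <- as.vector(K %*% (a * y))
      Ei <- f[i] - y[i]; Ej <- f[j] - y[j]
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta <= 1e-14) next
      ajn <- a[j] + y[j] * (Ei - Ej) / eta
      if (y[i] != y[j]) {
        L <- max(0, a[j] - a[i]); H <- min(C, C + a[j] - a[i])
      } else {
        L <- max(0, a[i] + a[j] - C); H <- min(C, a[i] + a[j])
      }
      ajn <- min(H, max(L, ajn))
      d <- ajn - a[j]
      if (abs(d) < tol) next
      a[j] <- ajn
      a[i] <- a[i] - y[i] * y[j] * d
      changed <- changed + 1L
    }
    if (changed == 0L) break
  }
  w <- colSums(a * y * X)
  free <- which(a > 1e-8 & a < C - 1e-8)
  b <- if (length(free)) mean(y[free] - X[free, , drop = FALSE] %*% w) else {
    fv <- as.vector(X %*% w)
    -(max(fv[y == -1]) + min(fv[y == 1])) / 2
  }
  list(alpha = a, w = w, b = b)
}

# Savitzky-Golay smoothing-matrix row for the centered window, built directly
# from the least-squares projection onto local polynomials.
oracle_sg_center_row <- function(window, polyorder) {
  half <- (window - 1) / 2
  A <- outer(-half:half, 0:polyorder, "^")
  H <- A %*% solve(t(A) %*% A) %*% t(A)
  H[half + 1, ]
}

# Per-spectrum EMSC correction via an independent generic OLS solve (lm.fit),
# one spectrum at a time.
oracle_emsc_row <- function(y, design) {
  fit <- lm.fit(design, y)
  b <- fit$coefficients
  other <- design[, -1, drop = FALSE] %*% b[-1]
  as.vector((y - other) / b[1])
}

# Bayes error of two equal-prior spherical Gaussian classes in the plane.
oracle_gaussian_bayes_error <- function(delta, sigma) pnorm(-delta / (2 * sigma))
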