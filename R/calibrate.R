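# Wavelength (pixel -> wavenumber) and intensity (instrument response)
# calibration against a reference-band spectrum and a calibration-lamp pair.

#' Construct a calibration model
#'
#' @param wl_coeffs Polynomial coefficients (increasing powers) mapping
#'   0-based pixel index to wavenumber (cm^-1).
#' @param response Optional strictly positive instrument-response vector over
#'   channels (unit mean), from [fit_response()].
#' @param reference_residuals Per-band wavelength-fit residuals (cm^-1).
#' @param px_count Number of detector pixels the model was fitted over.
#' @return Object of class `calibration_model`.
#' @export
calibration_model <- function(wl_coeffs, response = NULL,
                              reference_residuals = numeric(0),
                              px_count = NULL) {
  m <- structure(list(wl_coeffs = as.numeric(wl_coeffs),
                      wl_degree = length(wl_coeffs) - 1L,
                      response = response,
                      reference_residuals = reference_residuals,
                      px_count = px_count),
                 class = "calibration_model")
  if (!is.null(px_count)) {
    ax <- polyval_inc(m$wl_coeffs, seq(0, px_count - 1))
    if (any(diff(ax) <= 0))
      stop("calibration polynomial is not strictly increasing over the pixel range")
  }
  if (!is.null(response) && any(response <= 0))
    stop("instrument response must be strictly positive")
  m
}

# local maxima above a relative prominence threshold, centers refined by
# 3-point parabolic interpolation; returns 0-based pixel positions and heights
detect_peaks <- function(y, prominence_frac = 0.05) {
  n <- length(y)
  thr <- prominence_frac * max(y)
  idx <- which(y[-c(1, 2)] < y[-c(1, n)] & y[-c(n - 1, n)] < y[-c(1, n)]) + 1L
  idx <- idx[y[idx] >= thr]
  if (!length(idx)) return(data.frame(px = numeric(0), height = numeric(0)))
  delta <- (y[idx - 1] - y[idx + 1]) / (2 * (y[idx - 1] - 2 * y[idx] + y[idx + 1]))
  data.frame(px = idx - 1 + delta, height = y[idx])
}

#' Fit the pixel-to-wavenumber polynomial from a reference spectrum
#'
#' Detects bands of a reference compound (e.g. paracetamol) in the pixel
#' domain, matches them in order to the known band positions, and fits a
#' least-squares polynomial pixel -> cm^-1.
#'
#' @param reference Numeric pixel-domain reference spectrum.
#' @param known_centers Sorted known band positions (cm^-1).
#' @param degree Polynomial degree (default 3).
#' @param prominence_frac Peak-detection threshold as a fraction of the
#'   spectrum maximum.
#' @param residual_tol Maximum tolerated absolute band residual (cm^-1).
#' @return A `calibration_model` (wavelength part only).
#' @export
fit_wavelength <- function(reference, known_centers, degree = 3,
                           prominence_frac = 0.05, residual_tol = 2) {
  known_centers <- sort(known_centers)
  if (length(known_centers) < degree + 1)
    stop("underdetermined fit: ", length(known_centers),
         " known centers for polynomial degree ", degree)
  pk <- detect_peaks(reference, prominence_frac)
  if (nrow(pk) < length(known_centers))
    stop("detected only ", nrow(pk), " peaks for ", length(known_centers),
         " known band positions")
  if (nrow(pk) > length(known_centers)) {
    pk <- pk[order(pk$height, decreasing = TRUE)[seq_along(known_centers)], ]
  }
  px <- sort(pk$px)
  X <- outer(px, seq(0, degree), "^")
  fit <- lm.fit(X, known_centers)
  coeffs <- fit$coefficients
  coeffs[is.na(coeffs)] <- 0
  res <- known_centers - as.vector(X %*% coeffs)
  if (max(abs(res)) > residual_tol)
    stop("wavelength fit residuals exceed tolerance: max |residual| = ",
         format(max(abs(res))), " cm^-1 > ", residual_tol)
  calibration_model(coeffs, reference_residuals = res,
                    px_count = length(reference))
}

#' Fit the instrument response from a lamp pair
#'
#' The response is the smoothed channel-wise ratio of the measured lamp
#' spectrum to its known true relative irradiance, rescaled to unit mean
#' (the absolute scale is arbitrary and absorbed).
#'
#' @param measured_lamp Measured lamp spectrum.
#' @param true_irradiance True relative irradiance on the same axis; must be
#'   strictly positive.
#' @param window Savitzky-Golay smoothing window (odd; default 31).
#' @param polyorder Savitzky-Golay polynomial order.
#' @return Strictly positive unit-mean response vector.
#' @export
fit_response <- function(measured_lamp, true_irradiance, window = 31,
                         polyorder = 3) {
  if (length(measured_lamp) != length(true_irradiance))
    stop("lamp spectra must share one axis")
  if (any(true_irradiance <= 0))
    stop("true irradiance must be strictly positive on every channel")
  ratio <- measured_lamp / true_irradiance
  resp <- if (window < length(ratio)) {
    signal::sgolayfilt(ratio, p = polyorder, n = window)
  } else ratio
  resp <- resp / mean(resp)
  if (any(resp <= 0))
    stop("fitted response is not strictly positive; check the lamp spectra")
  resp
}

#' Apply a calibration model to pixel-domain spectra
#'
#' Divides intensities by the instrument response, maps the pixel axis
#' through the wavelength polynomial, and linearly interpolates every
#' spectrum onto a common target wavenumber axis. No extrapolation: the
#' target axis must lie inside the calibrated range.
#'
#' @param raw A `spectra_set` in the pixel domain (axis = 0-based pixel
#'   indices).
#' @param model A `calibration_model`.
#' @param target_axis Target wavenumber axis (cm^-1).
#' @return A `spectra_set` on `target_axis`, metadata preserved.
#' @export
apply_calibration <- function(raw, model, target_axis) {
  stopifnot(inherits(raw, "spectra_set"), inherits(model, "calibration_model"))
  native <- polyval_inc(model$wl_coeffs, raw$axis)
  if (any(diff(native) <= 0))
    stop("calibration polynomial is not strictly increasing over these pixels")
  if (min(target_axis) < min(native) || max(target_axis) > max(native))
    stop("target axis [", format(min(target_axis)), ", ", format(max(target_axis)),
         "] extends beyond the calibrated range [", format(min(native)), ", ",
         format(max(native)), "]; extrapolation is not performed")
  Y <- raw$intensities
  if (!is.null(model$response)) {
    if (length(model$response) != ncol(Y))
      stop("response length does not match channel count")
    Y <- sweep(Y, 2, model$response, "/")
  }
  out <- t(apply(Y, 1, function(y) approx(native, y, xout = target_axis)$y))
  if (nrow(Y) == 1) out <- matrix(out, nrow = 1)
  s <- spectra_set(target_axis, out, raw$meta, raw$provenance)
  add_provenance(s, "apply_calibration",
                 list(model = model, target_axis = target_axis))
}
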