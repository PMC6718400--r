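# Spectral cleanup chain: cosmic-spike removal, third-order EMSC background
# correction, Savitzky-Golay smoothing, area normalization, region selection
# and empty-spectrum rejection. The enforced order is
#   spikes -> EMSC -> smoothing -> area normalization -> region selection ->
#   rejection
# and every stage appends a replayable provenance record.

#' Construct a region specification
#'
#' Half-open wavenumber windows `[low, high)` in cm^-1; windows must be
#' disjoint and sorted.
#'
#' @param windows List of length-2 numeric vectors `c(low, high)`.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(windows) {
  windows <- lapply(windows, as.numeric)
  for (w in windows) {
    if (length(w) != 2 || w[1] >= w[2]) stop("each window must be c(low, high) with low < high")
  }
  lows <- vapply(windows, `[`, 0, 1)
  highs <- vapply(windows, `[`, 0, 2)
  o <- order(lows)
  windows <- windows[o]
  if (length(windows) > 1 && any(highs[o][-length(windows)] > lows[o][-1]))
    stop("region windows must be disjoint")
  structure(list(windows = windows), class = "region_spec")
}

#' Default analysis regions
#'
#' The fingerprint region 615-1800 cm^-1 and the high-wavenumber (C-H
#' stretch) region 2790-3010 cm^-1; the band-poor silent region between them
#' is omitted.
#'
#' @return A `region_spec`.
#' @export
default_regions <- function() region_spec(list(c(615, 1800), c(2790, 3010)))

region_mask <- function(axis, regions) {
  stopifnot(inherits(regions, "region_spec"))
  mask <- rep(FALSE, length(axis))
  for (w in regions$windows) mask <- mask | (axis >= w[1] & axis < w[2])
  mask
}

# ---- cosmic spikes ---------------------------------------------------------

#' Remove cosmic spikes
#'
#' Detects narrow high-amplitude artifacts as channels whose residual
#' against a running median exceeds `z_thresh` robust standard deviations
#' (MAD of the residual, per spectrum) and replaces them by the local
#' median. Cosmic hits are confined to single channels, so a flagged
#' channel must additionally be isolated: its residual must exceed five times
#' the residual of both immediate neighbours. Genuine Raman bands leave a
#' smooth residual hump under the running median and fail that criterion,
#' so band tops are never clipped.
#'
#' @param s A `spectra_set`.
#' @param z_thresh Robust z-score threshold (default 8).
#' @param window Odd running-median window (default 7).
#' @return List with `spectra` (corrected set), and `report`: a data frame
#'   with per-row correction counts plus a `positions` list-column of
#'   corrected channel indices.
#' @export
remove_spikes <- function(s, z_thresh = 8, window = 7) {
  validate_spectra_set(s)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (window >= n_channels(s)) stop("window must be smaller than the channel count")
  Y <- s$intensities
  positions <- vector("list", nrow(Y))
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    med <- stats::runmed(y, k = window, endrule = "median")
    r <- y - med
    sdev <- stats::mad(r)
    if (sdev <= 0) sdev <- sd(r)
    if (!is.finite(sdev) || sdev <= 0) { positions[[i]] <- integer(0); next }
    ra <- abs(r)
    left <- c(0, ra[-length(ra)])
    right <- c(ra[-1], 0)
    hit <- which(ra > z_thresh * sdev & ra > 5 * left & ra > 5 * right)
    if (length(hit)) Y[i, hit] <- med[hit]
    positions[[i]] <- hit
  }
  report <- data.frame(row = seq_len(nrow(Y)),
                       n_corrected = lengths(positions))
  report$positions <- positions
  s$intensities <- Y
  s <- add_provenance(s, "remove_spikes", list(z_thresh = z_thresh, window = window))
  list(spectra = s, report = report)
}

# ---- EMSC ------------------------------------------------------------------

#' Construct an EMSC basis
#'
#' Design matrix for extended multiplicative signal correction: a pure-cell
#' reference spectrum, named interferent spectra (water, fluorescence), and
#' polynomial baseline terms up to `poly_order` in the (rescaled) wavenumber.
#'
#' @param reference Pure-cell reference spectrum on `axis`.
#' @param axis Shared wavenumber axis.
#' @param interferents Named list of interferent spectra on `axis`.
#' @param poly_order Baseline polynomial order (default 3, i.e. third-order
#'   EMSC).
#' @return Object of class `emsc_basis` carrying the full-rank design matrix.
#' @export
emsc_basis <- function(reference, axis, interferents = list(), poly_order = 3) {
  stopifnot(length(reference) == length(axis))
  if (length(interferents) && is.null(names(interferents)))
    stop("interferents must be a named list")
  for (nm in names(interferents)) {
    if (length(interferents[[nm]]) != length(axis))
      stop("interferent '", nm, "' is not on the shared axis")
  }
  v <- if (length(axis) > 1) 2 * (axis - min(axis)) / diff(range(axis)) - 1 else axis
  P <- outer(v, seq(0, poly_order), "^")
  colnames(P) <- paste0("poly_", seq(0, poly_order))
  X <- cbind(b_ref = reference,
             if (length(interferents)) do.call(cbind, interferents),
             P)
  if (!all(is.finite(X))) stop("EMSC basis contains non-finite values")
  if (qr(X)$rank < ncol(X))
    stop("EMSC design matrix is rank deficient; components are collinear")
  structure(list(reference = reference, interferents = interferents,
                 poly_order = poly_order, axis = axis, design = X),
            class = "emsc_basis")
}

#' Estimate a pure-cell reference spectrum from data
#'
#' Ordinary least squares of the mean spectrum of (presumed mostly cellular)
#' rows on the interferent + baseline part of the EMSC design; the residual
#' is the background-free cell contribution, usable as the EMSC reference.
#'
#' @param s A `spectra_set` (e.g. a control well after spike removal).
#' @param interferents Named list of interferent spectra on the axis.
#' @param poly_order Baseline polynomial order.
#' @return Numeric reference spectrum.
#' @export
estimate_pure_cell <- function(s, interferents, poly_order = 3) {
  validate_spectra_set(s)
  v <- 2 * (s$axis - min(s$axis)) / diff(range(s$axis)) - 1
  X <- cbind(do.call(cbind, interferents), outer(v, seq(0, poly_order), "^"))
  m <- colMeans(s$intensities)
  as.vector(m - X %*% qr.coef(qr(X), m))
}

#' EMSC background correction
#'
#' For each spectrum `y`, ordinary least squares on the EMSC design yields a
#' reference coefficient `b_ref`, interferent coefficients and baseline
#' coefficients; the corrected spectrum is
#' `(y - interferent and baseline parts) / b_ref`. Rows with `b_ref` at or
#' below `b_ref_min` carry no cell signal: they are flagged
#' `"no_cell_signal"` and their output is the raw full-model residual.
#'
#' @param s A `spectra_set` on the basis axis.
#' @param basis An [emsc_basis()].
#' @param b_ref_min Minimum reference coefficient treated as cell signal.
#' @return List with `spectra` (corrected set; `meta$emsc_b_ref` filled) and
#'   `coefficients` (per-spectrum coefficient data frame).
#' @export
emsc_correct <- function(s, basis, b_ref_min = 1e-6) {
  validate_spectra_set(s)
  stopifnot(inherits(basis, "emsc_basis"))
  if (!isTRUE(all.equal(basis$axis, s$axis)))
    stop("EMSC basis is not on the spectra axis")
  X <- basis$design
  qrX <- qr(X)
  Yt <- t(s$intensities)                      # channels x n
  B <- qr.coef(qrX, Yt)                       # ncol(X) x n
  b_ref <- B[1, ]
  other <- X[, -1, drop = FALSE] %*% B[-1, , drop = FALSE]
  good <- b_ref > b_ref_min
  corrected <- Yt
  if (any(good))
    corrected[, good] <- sweep(Yt[, good, drop = FALSE] - other[, good, drop = FALSE],
                               2, b_ref[good], "/")
  if (any(!good))
    corrected[, !good] <- Yt[, !good, drop = FALSE] - X %*% B[, !good, drop = FALSE]
  coefs <- as.data.frame(t(B))
  names(coefs) <- colnames(X)
  s$intensities <- t(corrected)
  s$meta$emsc_b_ref <- b_ref
  flag <- !good
  s$meta$qc_flags <- ifelse(flag,
                            trimws(paste(s$meta$qc_flags, "no_cell_signal")),
                            s$meta$qc_flags)
  s <- add_provenance(s, "emsc_correct", list(basis = basis, b_ref_min = b_ref_min))
  list(spectra = s, coefficients = coefs)
}

# ---- smoothing, normalization, regions, rejection --------------------------

#' Savitzky-Golay smoothing
#'
#' Applies the Savitzky-Golay filter row-wise; polynomials up to
#' `polyorder` pass through unchanged, including at the edges.
#'
#' @param s A `spectra_set`.
#' @param window Odd filter window (default 9).
#' @param polyorder Polynomial order (default 3); must be `< window`.
#' @return Smoothed `spectra_set`.
#' @export
smooth_spectra <- function(s, window = 9, polyorder = 3) {
  validate_spectra_set(s)
  if (polyorder >= window) stop("polyorder must be smaller than the window")
  if (window %% 2 == 0) stop("window must be odd")
  if (window >= n_channels(s)) stop("window must be smaller than the channel count")
  sm <- t(apply(s$intensities, 1, signal::sgolayfilt, p = polyorder, n = window))
  if (nrow(s$intensities) == 1) sm <- matrix(sm, nrow = 1)
  s$intensities <- sm
  add_provenance(s, "smooth", list(window = window, polyorder = polyorder))
}

row_region_integral <- function(axis, Y, regions) {
  mask <- region_mask(axis, regions)
  if (!any(mask)) stop("regions do not overlap the axis")
  total <- numeric(nrow(Y))
  for (w in regions$windows) {
    idx <- which(axis >= w[1] & axis < w[2])
    if (length(idx) >= 2) {
      dx <- diff(axis[idx])
      A <- abs(Y[, idx, drop = FALSE])
      total <- total + as.vector((A[, -1, drop = FALSE] +
                                  A[, -length(idx), drop = FALSE]) %*% dx) / 2
    }
  }
  total
}

#' Area normalization
#'
#' Divides each spectrum by the trapezoidal integral of its absolute value
#' over the selected regions, cancelling per-spectrum multiplicative gain
#' (laser intensity fluctuation). Computed over the analysis windows so the
#' silent region never influences the norm. Zero-integral rows are flagged
#' `"zero_integral"` and left undivided.
#'
#' @param s A `spectra_set`.
#' @param regions A `region_spec` (default [default_regions()]).
#' @return Normalized `spectra_set`.
#' @export
area_normalize <- function(s, regions = default_regions()) {
  validate_spectra_set(s)
  a <- row_region_integral(s$axis, s$intensities, regions)
  zero <- a <= 0
  if (any(!zero))
    s$intensities[!zero, ] <- s$intensities[!zero, , drop = FALSE] / a[!zero]
  s$meta$qc_flags <- ifelse(zero, trimws(paste(s$meta$qc_flags, "zero_integral")),
                            s$meta$qc_flags)
  add_provenance(s, "area_normalize", list(regions = regions))
}

#' Select analysis regions
#'
#' Drops all channels outside the half-open windows, keeping axis and matrix
#' aligned.
#'
#' @param s A `spectra_set`.
#' @param regions A `region_spec`.
#' @return Cropped `spectra_set`.
#' @export
select_regions <- function(s, regions = default_regions()) {
  validate_spectra_set(s)
  mask <- region_mask(s$axis, regions)
  if (!any(mask)) stop("region selection is empty: no axis channel falls in the windows")
  s$axis <- s$axis[mask]
  s$intensities <- s$intensities[, mask, drop = FALSE]
  add_provenance(s, "select_regions", list(regions = regions))
}

#' Reject empty spectra
#'
#' Removes rows that carry no cell signal: rows flagged `"no_cell_signal"`
#' by [emsc_correct()], plus rows whose EMSC reference coefficient falls
#' below `rel_threshold` times the median reference coefficient of their
#' well (anchored per well to tolerate dose-dependent intensity shifts) or
#' below the absolute floor `abs_threshold` (a row contributing less than a
#' few percent of one reference-cell spectrum is background regardless of
#' its well, which also catches wells that are empty throughout).
#'
#' @param s A `spectra_set` with `meta$emsc_b_ref` present.
#' @param rel_threshold Fraction of the per-well median `b_ref` below which a
#'   row is rejected (default 0.05).
#' @param abs_threshold Absolute `b_ref` floor (default 0.02, in units of the
#'   reference spectrum amplitude).
#' @return List with `spectra` (kept rows), `report` (per-well data frame of
#'   totals, rejections and rejected fraction) and `rejected_idx`.
#' @export
reject_empty <- function(s, rel_threshold = 0.05, abs_threshold = 0.02) {
  validate_spectra_set(s)
  if (is.null(s$meta$emsc_b_ref))
    stop("reject_empty requires emsc_correct to have run (meta$emsc_b_ref missing)")
  b <- s$meta$emsc_b_ref
  wells <- interaction(s$meta$batch, s$meta$well, drop = TRUE)
  reject <- grepl("no_cell_signal", s$meta$qc_flags)
  for (w in levels(wells)) {
    idx <- which(wells == w)
    thr <- max(rel_threshold * median(b[idx]), abs_threshold)
    reject[idx] <- reject[idx] | b[idx] < thr
  }
  rep_df <- do.call(rbind, lapply(levels(wells), function(w) {
    idx <- which(wells == w)
    data.frame(batch = s$meta$batch[idx[1]], well = s$meta$well[idx[1]],
               condition_label = s$meta$condition_label[idx[1]],
               n_total = length(idx), n_rejected = sum(reject[idx]),
               rejected_fraction = mean(reject[idx]))
  }))
  for (i in seq_len(nrow(rep_df))) {
    if (rep_df$n_rejected[i] == rep_df$n_total[i])
      warning("all ", rep_df$n_total[i], " spectra rejected in well ",
              rep_df$well[i], " (batch ", rep_df$batch[i], ")")
  }
  kept <- subset_spectra(s, !reject)
  kept <- add_provenance(kept, "reject_empty",
                         list(rel_threshold = rel_threshold,
                              abs_threshold = abs_threshold))
  list(spectra = kept, report = rep_df, rejected_idx = which(reject))
}

#' Run the full preprocessing chain
#'
#' Enforces the pipeline order: spike removal, EMSC background correction,
#' Savitzky-Golay smoothing, area normalization over the analysis regions,
#' region selection, and empty-spectrum rejection.
#'
#' @param s Raw `spectra_set` (wavenumber domain).
#' @param basis An [emsc_basis()] on the raw axis.
#' @param regions A `region_spec` (default [default_regions()]).
#' @param spike_z,spike_window Spike-removal parameters.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param b_ref_min EMSC no-signal threshold.
#' @param reject_rel_threshold Per-well relative rejection threshold.
#' @param reject_abs_threshold Absolute rejection floor on `b_ref`.
#' @return List with `spectra`, `spike_report`, `emsc_coefficients`,
#'   `rejection_report`.
#' @export
preprocess_spectra <- function(s, basis, regions = default_regions(),
                               spike_z = 8, spike_window = 7,
                               sg_window = 9, sg_polyorder = 3,
                               b_ref_min = 1e-6, reject_rel_threshold = 0.05,
                               reject_abs_threshold = 0.02) {
  sp <- remove_spikes(s, z_thresh = spike_z, window = spike_window)
  em <- emsc_correct(sp$spectra, basis, b_ref_min = b_ref_min)
  sm <- smooth_spectra(em$spectra, window = sg_window, polyorder = sg_polyorder)
  no <- area_normalize(sm, regions)
  se <- select_regions(no, regions)
  rj <- reject_empty(se, rel_threshold = reject_rel_threshold,
                     abs_threshold = reject_abs_threshold)
  list(spectra = rj$spectra, spike_report = sp$report,
       emsc_coefficients = em$coefficients, rejection_report = rj$report)
}
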