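#' Construct a spectra set
#'
#' A `spectra_set` is the container every pipeline stage consumes and returns:
#' a shared wavenumber (or pixel) axis, an intensity matrix with one row per
#' cell, per-row metadata, and an append-only provenance log of the operations
#' applied so far.
#'
#' @param axis Numeric vector of axis values (cm^-1, or pixel indices for
#'   uncalibrated data); must be strictly increasing and match the number of
#'   intensity columns.
#' @param intensities Numeric matrix, cells in rows and channels in columns.
#' @param meta Data frame with one row per spectrum. Recognised columns are
#'   `condition_label`, `dose`, `batch`, `well`, `qc_flags` and
#'   `ground_truth_label`; missing ones are filled with defaults.
#' @param provenance List of provenance records (normally left empty; stages
#'   append their own records via [add_provenance()]).
#'
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(axis, intensities, meta = NULL, provenance = list()) {
  if (is.vector(intensities)) intensities <- matrix(intensities, nrow = 1)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  axis <- as.numeric(axis)
  n <- nrow(intensities)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(max(n, 0L)))[seq_len(n), , drop = FALSE]
  meta <- as.data.frame(meta)
  if (is.null(meta$condition_label)) meta$condition_label <- rep("unspecified", n)
  if (is.null(meta$dose)) meta$dose <- rep(NA_real_, n)
  if (is.null(meta$batch)) meta$batch <- rep(1L, n)
  if (is.null(meta$well)) meta$well <- rep("w1", n)
  if (is.null(meta$qc_flags)) meta$qc_flags <- rep("", n)
  rownames(meta) <- NULL
  s <- structure(list(axis = axis, intensities = intensities,
                      meta = meta, provenance = provenance),
                 class = "spectra_set")
  validate_spectra_set(s)
  s
}

#' Validate a spectra set
#'
#' Checks the structural invariants: strictly increasing axis, axis length
#' equal to the column count, and metadata row count equal to the spectrum
#' count.
#'
#' @param s A `spectra_set`.
#' @return `s`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_spectra_set <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (length(s$axis) != ncol(s$intensities))
    stop("axis length (", length(s$axis), ") does not match channel count (",
         ncol(s$intensities), ")")
  if (length(s$axis) > 1 && any(diff(s$axis) <= 0))
    stop("axis must be strictly increasing")
  if (nrow(s$meta) != nrow(s$intensities))
    stop("metadata rows (", nrow(s$meta), ") do not match spectra rows (",
         nrow(s$intensities), ")")
  if (!all(is.finite(s$axis))) stop("axis contains non-finite values")
  invisible(s)
}

#' Number of spectra in a set
#' @param s A `spectra_set`.
#' @return Integer row count.
#' @export
n_spectra <- function(s) nrow(s$intensities)

#' Number of channels in a set
#' @param s A `spectra_set`.
#' @return Integer channel count.
#' @export
n_channels <- function(s) ncol(s$intensities)

#' Append a provenance record
#'
#' Provenance is append-only: each pipeline stage records its name and the
#' parameters needed to replay it, so a processed set can be reproduced from
#' the raw input (see [replay_provenance()]).
#'
#' @param s A `spectra_set`.
#' @param op Character scalar naming the operation.
#' @param params Named list of parameters.
#' @return The modified `spectra_set`.
#' @export
add_provenance <- function(s, op, params = list()) {
  s$provenance <- c(s$provenance, list(list(op = op, params = params)))
  s
}

#' Subset a spectra set by row
#'
#' @param s A `spectra_set`.
#' @param idx Integer or logical row index.
#' @return A `spectra_set` with the selected rows; provenance is carried over
#'   unchanged (row subsetting is bookkeeping, not a spectral operation).
#' @export
subset_spectra <- function(s, idx) {
  s$intensities <- s$intensities[idx, , drop = FALSE]
  s$meta <- s$meta[idx, , drop = FALSE]
  rownames(s$meta) <- NULL
  s
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", n_spectra(x), " spectra x ", n_channels(x),
      " channels, axis ", format(min(x$axis)), "..", format(max(x$axis)), "\n", sep = "")
  if (length(unique(x$meta$condition_label)) > 1)
    cat("  conditions:", paste(unique(x$meta$condition_label), collapse = ", "), "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "op"), collapse = " -> "), "\n")
  invisible(x)
}

#' Replay a provenance log on a raw spectra set
#'
#' Re-applies, in order, every recorded operation to `raw`. Because each
#' stage stores the full parameter set it was called with, replaying the log
#' reproduces the processed set bit-identically.
#'
#' @param raw The raw `spectra_set` the log was produced from.
#' @param provenance A provenance list as stored in `$provenance`.
#' @return The reprocessed `spectra_set`.
#' @export
replay_provenance <- function(raw, provenance) {
  s <- raw
  for (rec in provenance) {
    s <- switch(rec$op,
      remove_spikes  = remove_spikes(s, z_thresh = rec$params$z_thresh,
                                     window = rec$params$window)$spectra,
      emsc_correct   = emsc_correct(s, rec$params$basis,
                                    b_ref_min = rec$params$b_ref_min)$spectra,
      smooth         = smooth_spectra(s, window = rec$params$window,
                                      polyorder = rec$params$polyorder),
      area_normalize = area_normalize(s, rec$params$regions),
      select_regions = select_regions(s, rec$params$regions),
      reject_empty   = reject_empty(s, rel_threshold = rec$params$rel_threshold,
                                    abs_threshold = rec$params$abs_threshold)$spectra,
      apply_calibration = apply_calibration(s, rec$params$model, rec$params$target_axis),
      stop("unknown provenance op: ", rec$op)
    )
  }
  s
}

# trapezoidal integral, used for area normalization and unit-area scaling
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
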