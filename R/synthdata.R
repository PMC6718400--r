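#' @importFrom stats approx coef fitted lm median pnorm qnorm resid rnorm
#'   rpois runif sd setNames var rbinom rlnorm predict quantile
#' @importFrom utils read.delim write.table modifyList head tail
NULL

# ---- band primitives -------------------------------------------------------

# Lorentzian / Gaussian line shapes parameterized by FWHM; peak height = amp.
lorentz_band <- function(x, center, fwhm, amp) {
  g <- fwhm / 2
  amp * g^2 / ((x - center)^2 + g^2)
}

gauss_band <- function(x, center, fwhm, amp) {
  amp * exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

#' Evaluate a band table on an axis
#'
#' Sums Lorentzian or Gaussian lines defined by a band table. Band widths are
#' full widths at half maximum and amplitudes are peak heights.
#'
#' @param axis Numeric wavenumber axis (cm^-1).
#' @param bands Data frame with columns `center`, `width`, `amplitude` and
#'   optionally `shape` (`"lorentzian"` default, or `"gaussian"`).
#' @return Numeric vector of intensities on `axis`.
#' @export
evaluate_bands <- function(axis, bands) {
  stopifnot(all(c("center", "width", "amplitude") %in% names(bands)))
  if (any(bands$width <= 0)) stop("band widths must be > 0")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be >= 0")
  shape <- if (is.null(bands$shape)) rep("lorentzian", nrow(bands)) else bands$shape
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    fn <- switch(shape[i], lorentzian = lorentz_band, gaussian = gauss_band,
                 stop("unknown band shape: ", shape[i]))
    y <- y + fn(axis, bands$center[i], bands$width[i], bands$amplitude[i])
  }
  y
}

unit_area <- function(axis, y) {
  a <- trapz(axis, abs(y))
  if (a <= 0) stop("cannot area-normalize a spectrum with zero integral")
  y / a
}

# ---- component library -----------------------------------------------------

#' Band catalogue of the macromolecular components
#'
#' Raman marker bands used to synthesize pure-component spectra for the
#' macromolecular pools (protein, lipid, nucleic acid) and for intracellular
#' doxorubicin. Centers are literature marker positions (cm^-1); widths
#' (FWHM) and relative amplitudes follow common values for cellular Raman
#' spectra of fixed cells.
#'
#' @return Data frame with columns `component`, `center`, `width`,
#'   `amplitude`, `assignment`.
#' @export
component_bands <- function() {
  rbind(
    data.frame(component = "protein",
               center = c(760, 830, 1004, 1263, 1660, 2930),
               width = c(14, 12, 10, 16, 18, 30),
               amplitude = c(0.5, 0.4, 1.0, 0.5, 0.9, 1.2),
               assignment = c("tryptophan ring breathing",
                              "tyrosine ring breathing",
                              "phenylalanine symmetric ring breathing",
                              "amide III", "amide I", "CH3 stretching")),
    data.frame(component = "lipid",
               center = c(1096, 1263, 1303, 1441, 1660, 1740, 2851, 2890),
               width = c(14, 16, 14, 16, 18, 14, 24, 26),
               amplitude = c(0.3, 0.4, 0.7, 1.0, 0.5, 0.3, 1.3, 0.8),
               assignment = c("chain C-C stretching", "=C-H in-plane cis",
                              "CH2 twist", "CH2 scissor",
                              "C=C cis stretching", "ester C=O stretching",
                              "CH2 symmetric stretching",
                              "CH2 asymmetric stretching")),
    data.frame(component = "nucleic_acid",
               center = c(783, 813, 830, 1096, 1340, 1575),
               width = c(12, 12, 12, 14, 16, 14),
               amplitude = c(1.0, 0.5, 0.4, 0.7, 0.4, 0.5),
               assignment = c("U/C/T ring breathing", "RNA O-P-O stretching",
                              "DNA B-form O-P-O asymmetric stretching",
                              "DNA PO2- symmetric stretching",
                              "adenine/guanine", "guanine/adenine ring")),
    data.frame(component = "dox",
               center = c(1086, 1215, 1247, 1435),
               width = c(14, 14, 14, 16),
               amplitude = c(0.6, 0.8, 1.0, 0.5),
               assignment = c("C-O", "C-O-H", "C-H", "ring stretching"))
  )
}

#' Water background profile
#'
#' Broad water contribution of measurements in aqueous medium: the bending
#' mode near 1640 cm^-1 and the low-wavenumber tail of the OH stretch,
#' area-normalized on the given axis.
#'
#' @param axis Numeric wavenumber axis (cm^-1).
#' @return Non-negative unit-area numeric vector.
#' @export
water_profile <- function(axis) {
  y <- gauss_band(axis, 1640, 220, 0.25) + gauss_band(axis, 3250, 900, 1.0)
  unit_area(axis, y)
}

#' Fluorescence background profile
#'
#' Smooth broadband fluorescence shape: a low-order ramp plus a broad
#' Gaussian centered in the fingerprint region, area-normalized. Its
#' amplitude in a simulated spectrum scales with drug dose (strongly
#' absorbing/fluorescing compounds raise the background as they accumulate
#' in the cell).
#'
#' @param axis Numeric wavenumber axis (cm^-1).
#' @return Non-negative unit-area numeric vector.
#' @export
fluorescence_profile <- function(axis) {
  t <- (axis - min(axis)) / max(diff(range(axis)), 1)
  y <- 0.9 - 0.5 * t + gauss_band(axis, 1300, 1400, 0.8)
  if (any(y < 0)) y <- y - min(y)
  unit_area(axis, y)
}

#' Pure-component spectrum library
#'
#' Evaluates every component on an axis and area-normalizes each, so mixture
#' weights are interpretable fractions.
#'
#' @param axis Numeric wavenumber axis (cm^-1).
#' @return Named list of unit-area numeric vectors: `protein`, `lipid`,
#'   `nucleic_acid`, `dox`, `water`, `fluorescence`.
#' @export
component_library <- function(axis) {
  cb <- component_bands()
  comps <- lapply(split(cb, cb$component), function(b) unit_area(axis, evaluate_bands(axis, b)))
  comps$water <- water_profile(axis)
  comps$fluorescence <- fluorescence_profile(axis)
  for (nm in names(comps)) {
    if (any(comps[[nm]] < 0)) stop("component '", nm, "' is negative on the axis")
  }
  comps[c("protein", "lipid", "nucleic_acid", "dox", "water", "fluorescence")]
}

# ---- axis ------------------------------------------------------------------

# Horner evaluation of a polynomial with coefficients in increasing powers.
polyval_inc <- function(coeffs, x) {
  y <- numeric(length(x))
  for (c_i in rev(coeffs)) y <- y * x + c_i
  y
}

#' Build a wavenumber axis from a pixel-to-wavenumber polynomial
#'
#' Mirrors the detector geometry: channel `px` (0-based) maps to wavenumber
#' `sum(coeffs * px^(0:d))`. The polynomial must be strictly increasing over
#' the pixel range so the axis is a valid spectral axis.
#'
#' @param px_count Number of detector pixels (>= 2).
#' @param coeffs Polynomial coefficients in increasing powers
#'   (intercept first).
#' @return Strictly increasing numeric axis of length `px_count`.
#' @export
make_axis <- function(px_count, coeffs) {
  if (px_count < 2) stop("px_count must be >= 2")
  axis <- polyval_inc(coeffs, seq(0, px_count - 1))
  if (any(diff(axis) <= 0))
    stop("pixel-to-wavenumber polynomial is not strictly increasing over the pixel range")
  axis
}

#' Default analysis axis
#'
#' 1400 channels at 2 cm^-1 spacing spanning 300-3098 cm^-1, covering the
#' fingerprint (615-1800 cm^-1) and high-wavenumber (2790-3010 cm^-1)
#' regions with the silent region in between.
#'
#' @return Numeric axis.
#' @export
default_axis <- function() make_axis(1400, c(300, 2))

# ---- population spec -------------------------------------------------------

#' Specification of a simulated cell population
#'
#' Bundles every knob of the generator for one condition (one well). The
#' defaults describe the study conditions the pipeline is designed for:
#' roughly one spectrum in ten is an empty (background-only) detection,
#' fluorescence grows linearly with dose, the laser gain fluctuates by ~10%
#' between cells, and viable/non-viable cells differ in their macromolecular
#' composition (non-viable: lipid up, nucleic acid down).
#'
#' @param condition_label Condition name, e.g. `"0.05 uM"`.
#' @param dose Drug concentration in uM (>= 0).
#' @param n_cells Number of spectra to draw.
#' @param viable_fraction Probability a (non-empty) cell is viable.
#' @param composition_viable,composition_nonviable Named weights over
#'   `protein`, `lipid`, `nucleic_acid`, `dox`; each must be non-negative and
#'   sum to 1.
#' @param fluorescence_scale Fluorescence amplitude (area units relative to
#'   the unit-area cell mixture); default `0.5 + 5 * dose`.
#' @param water_scale Water background amplitude (area units).
#' @param noise_sd Additive detector noise standard deviation.
#' @param gain_cv Coefficient of variation of the per-spectrum multiplicative
#'   gain (log-normal, mean 1).
#' @param weight_jitter_sd Per-cell Gaussian jitter on composition weights
#'   (renormalized), emulating biological variability.
#' @param spike_rate Expected cosmic spikes per spectrum (Poisson).
#' @param empty_rate Probability a row is an empty detection (default 0.1,
#'   i.e. approximately one in ten).
#' @param dose_shift_viable,dose_shift_nonviable Named per-uM composition
#'   shifts applied before renormalization (dose-dependent macromolecular
#'   drift of each class).
#' @param dox_uptake Added dox weight per uM of dose.
#' @param batch,well Metadata labels.
#' @param seed Integer seed; identical specs give bit-identical output.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(condition_label = "control",
                            dose = 0,
                            n_cells = 1000,
                            viable_fraction = 1,
                            composition_viable = c(protein = 0.45, lipid = 0.25,
                                                   nucleic_acid = 0.30, dox = 0),
                            composition_nonviable = c(protein = 0.50, lipid = 0.35,
                                                      nucleic_acid = 0.15, dox = 0),
                            fluorescence_scale = 0.5 + 5 * dose,
                            water_scale = 1,
                            noise_sd = 1e-4,
                            gain_cv = 0.1,
                            weight_jitter_sd = 0.02,
                            spike_rate = 0.03,
                            empty_rate = 0.1,
                            dose_shift_viable = c(lipid = 0.03, nucleic_acid = -0.03),
                            dose_shift_nonviable = c(protein = 0.04, nucleic_acid = -0.04),
                            dox_uptake = 0.02,
                            batch = 1L, well = "w1",
                            seed = 1L) {
  spec <- list(condition_label = condition_label, dose = dose, n_cells = n_cells,
               viable_fraction = viable_fraction,
               composition_viable = composition_viable,
               composition_nonviable = composition_nonviable,
               fluorescence_scale = fluorescence_scale, water_scale = water_scale,
               noise_sd = noise_sd, gain_cv = gain_cv,
               weight_jitter_sd = weight_jitter_sd,
               spike_rate = spike_rate, empty_rate = empty_rate,
               dose_shift_viable = dose_shift_viable,
               dose_shift_nonviable = dose_shift_nonviable,
               dox_uptake = dox_uptake, batch = batch, well = well,
               seed = as.integer(seed))
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$dose < 0) stop("dose must be >= 0")
  if (spec$viable_fraction < 0 || spec$viable_fraction > 1)
    stop("viable_fraction must be in [0, 1]")
  if (spec$empty_rate < 0 || spec$empty_rate > 1)
    stop("empty_rate must be in [0, 1]")
  for (nm in c("composition_viable", "composition_nonviable")) {
    w <- spec[[nm]]
    if (any(w < 0)) stop(nm, " has negative weights")
    if (abs(sum(w) - 1) > 1e-8) stop(nm, " weights must sum to 1")
  }
  if (spec$fluorescence_scale < 0) stop("fluorescence_scale must be >= 0")
  if (spec$noise_sd < 0 || spec$gain_cv < 0 || spec$spike_rate < 0)
    stop("noise_sd, gain_cv and spike_rate must be >= 0")
  invisible(spec)
}

# dose-shifted, renormalized composition for one class
effective_composition <- function(spec, viable) {
  w <- if (viable) spec$composition_viable else spec$composition_nonviable
  shift <- if (viable) spec$dose_shift_viable else spec$dose_shift_nonviable
  for (nm in names(shift)) w[nm] <- w[nm] + shift[[nm]] * spec$dose
  w["dox"] <- w["dox"] + spec$dox_uptake * spec$dose
  w <- pmax(w, 0)
  w / sum(w)
}

# ---- population simulation -------------------------------------------------

#' Simulate a single-cell Raman population
#'
#' Draws `n_cells` spectra: each cell spectrum is
#' `gain * (sum(weights * component) + fluorescence_scale * fluorescence +
#' water_scale * water) + noise + spikes`. Empty detections contain the
#' background terms only. Ground-truth labels (`viable`, `non_viable`,
#' `empty`) and injected spike positions are recorded.
#'
#' @param spec A [population_spec()].
#' @param components A [component_library()] on `axis` (or a compatible named
#'   list); must contain every name used by the compositions plus `water` and
#'   `fluorescence`.
#' @param axis Numeric wavenumber axis.
#' @return List with elements `spectra` (a `spectra_set` whose meta carries
#'   `ground_truth_label`), and `spike_positions` (list of injected channel
#'   indices per row).
#' @export
simulate_population <- function(spec, components = component_library(axis),
                                axis = default_axis()) {
  validate_population_spec(spec)
  needed <- unique(c(names(spec$composition_viable), names(spec$composition_nonviable),
                     "water", "fluorescence"))
  missing_comp <- setdiff(needed, names(components))
  if (length(missing_comp))
    stop("component library is missing: ", paste(missing_comp, collapse = ", "))
  p <- length(axis)
  n <- spec$n_cells
  if (n == 0) {
    return(list(spectra = spectra_set(axis, matrix(numeric(0), 0, p)),
                spike_positions = list()))
  }
  comp_names <- setdiff(needed, c("water", "fluorescence"))
  M <- do.call(cbind, components[comp_names])  # channels x components
  bg <- spec$fluorescence_scale * components$fluorescence +
    spec$water_scale * components$water

  set.seed(spec$seed)
  empty <- runif(n) < spec$empty_rate
  viable <- runif(n) < spec$viable_fraction
  label <- ifelse(empty, "empty", ifelse(viable, "viable", "non_viable"))
  gain <- if (spec$gain_cv > 0) {
    s <- sqrt(log(1 + spec$gain_cv^2))
    rlnorm(n, meanlog = -s^2 / 2, sdlog = s)   # mean 1, CV = gain_cv
  } else rep(1, n)

  Y <- matrix(0, n, p)
  spike_positions <- vector("list", n)
  for (i in seq_len(n)) {
    if (empty[i]) {
      sig <- bg
    } else {
      w <- effective_composition(spec, viable[i])
      if (spec$weight_jitter_sd > 0) {
        w <- pmax(w + rnorm(length(w), 0, spec$weight_jitter_sd), 0)
        w <- w / sum(w)
      }
      sig <- as.vector(M %*% w[comp_names]) + bg
    }
    y <- gain[i] * sig
    if (spec$noise_sd > 0) y <- y + rnorm(p, 0, spec$noise_sd)
    nspk <- rpois(1, spec$spike_rate)
    if (nspk > 0) {
      pos <- sample.int(p, nspk)
      amp <- runif(nspk, 5, 50) * pmax(abs(y[pos]), median(abs(y)))
      y[pos] <- y[pos] + amp
      spike_positions[[i]] <- sort(pos)
    } else spike_positions[[i]] <- integer(0)
    Y[i, ] <- y
  }
  meta <- data.frame(condition_label = spec$condition_label, dose = spec$dose,
                     batch = spec$batch, well = spec$well, qc_flags = "",
                     ground_truth_label = label, stringsAsFactors = FALSE)
  s <- spectra_set(axis, Y, meta)
  s <- add_provenance(s, "simulate_population",
                      list(condition_label = spec$condition_label,
                           seed = spec$seed, n_cells = n))
  list(spectra = s, spike_positions = spike_positions)
}

#' Simulate a full dose ladder
#'
#' Convenience wrapper building one [population_spec()] per condition and
#' binding the simulated wells into one `spectra_set`.
#'
#' @param doses Numeric vector of doses (uM).
#' @param viable_fractions Ground-truth viable fraction per condition.
#' @param n_cells Cells per condition (scalar or vector).
#' @param labels Condition labels (default derived from doses).
#' @param batch Batch id.
#' @param seed Base seed; condition `i` uses `seed + i - 1`.
#' @param ... Further arguments passed to [population_spec()].
#' @return List with `spectra` (combined `spectra_set`) and `spike_positions`.
#' @export
simulate_dose_ladder <- function(doses, viable_fractions, n_cells = 1000,
                                 labels = NULL, batch = 1L, seed = 1L, ...) {
  stopifnot(length(doses) == length(viable_fractions))
  if (is.null(labels))
    labels <- ifelse(doses == 0, "control",
                     paste0(vapply(doses, format, ""), " uM"))
  n_cells <- rep_len(n_cells, length(doses))
  axis <- default_axis()
  comps <- component_library(axis)
  sets <- list(); spikes <- list()
  for (i in seq_along(doses)) {
    spec <- population_spec(condition_label = labels[i], dose = doses[i],
                            n_cells = n_cells[i],
                            viable_fraction = viable_fractions[i],
                            batch = batch, well = paste0("w", i),
                            seed = as.integer(seed) + i - 1L, ...)
    sim <- simulate_population(spec, comps, axis)
    sets[[i]] <- sim$spectra
    spikes <- c(spikes, sim$spike_positions)
  }
  combined <- sets[[1]]
  if (length(sets) > 1) {
    combined$intensities <- do.call(rbind, lapply(sets, `[[`, "intensities"))
    combined$meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
    rownames(combined$meta) <- NULL
  }
  combined$provenance <- list(list(op = "simulate_dose_ladder",
                                   params = list(doses = doses, seed = seed)))
  list(spectra = combined, spike_positions = spikes)
}

# ---- calibration references ------------------------------------------------

#' Reference band positions of paracetamol
#'
#' Well-characterized Raman shift standard positions (cm^-1) commonly used
#' for wavelength calibration.
#'
#' @return Numeric vector of band centers, sorted.
#' @export
paracetamol_band_centers <- function() {
  c(651.6, 797.2, 857.9, 968.7, 1168.5, 1236.8, 1323.9, 1561.6, 1648.4)
}

#' Simulate a paracetamol reference spectrum
#'
#' Renders isolated reference bands on the given axis (which may be a
#' pixel-mapped wavenumber axis), for exercising the wavelength-calibration
#' fit. At least 6 resolvable bands must fit inside the axis range.
#'
#' @param axis Numeric axis (cm^-1 values at each channel).
#' @param noise_sd Additive noise standard deviation (default 0).
#' @param width Band FWHM in cm^-1.
#' @param shape `"lorentzian"` (default) or `"gaussian"`.
#' @param seed Seed used when `noise_sd > 0`.
#' @return List with `spectrum` (numeric vector) and `bands` (data frame of
#'   the rendered centers, widths and amplitudes).
#' @export
simulate_paracetamol <- function(axis, noise_sd = 0, width = 12,
                                 shape = "lorentzian", seed = 1L) {
  centers <- paracetamol_band_centers()
  margin <- 3 * width
  keep <- centers > min(axis) + margin & centers < max(axis) - margin
  centers <- centers[keep]
  if (length(centers) < 6)
    stop("axis too short: only ", length(centers),
         " resolvable reference bands fit inside the axis range (need >= 6)")
  amps <- rep_len(c(0.6, 1.0, 0.8, 0.5, 0.9, 0.7, 0.6, 0.8, 0.5), length(centers))
  bands <- data.frame(center = centers, width = width, amplitude = amps,
                      shape = shape)
  y <- evaluate_bands(axis, bands)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(axis), 0, noise_sd)
  }
  list(spectrum = y, bands = bands)
}

#' Simulate a calibration-lamp pair
#'
#' Produces a measured lamp spectrum and the corresponding true relative
#' irradiance, related by a smooth strictly positive instrument response:
#' `measured = true * response`.
#'
#' @param axis Numeric axis.
#' @param response Optional response vector (must be > 0 everywhere); the
#'   default is a smooth ramp from 0.5 to 1.5 with mild curvature.
#' @return List with `measured`, `true` and `response` numeric vectors.
#' @export
simulate_lamp_pair <- function(axis, response = NULL) {
  t <- (axis - min(axis)) / diff(range(axis))
  if (is.null(response)) response <- 0.5 + t + 0.1 * sin(2 * pi * t)
  if (length(response) != length(axis))
    stop("response length must match the axis")
  if (any(response <= 0)) stop("instrument response must be strictly positive")
  true <- 0.3 + exp(-((t - 0.45) / 0.35)^2)   # smooth lamp irradiance curve
  list(measured = true * response, true = true, response = response)
}
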