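# Readers/writers, run configuration and the end-to-end pipeline driver.
# Spectra travel as TSV (header row = axis values) with a JSON metadata
# sidecar; models and results are written as JSON.

#' Write a spectra set to TSV + JSON sidecar
#'
#' @param s A `spectra_set`.
#' @param path TSV output path (header row carries the axis values).
#' @param sidecar_path JSON sidecar path (per-row metadata records).
#' @return Invisibly, `c(path, sidecar_path)`.
#' @export
write_spectra <- function(s, path, sidecar_path) {
  validate_spectra_set(s)
  m <- s$intensities
  colnames(m) <- format(s$axis, digits = 12, trim = TRUE, scientific = FALSE)
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(meta = s$meta, provenance = s$provenance),
                       sidecar_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(path, sidecar_path))
}

#' Read a spectra set from TSV + JSON sidecar
#'
#' Validates the axis (monotone), the matrix (fully numeric, rectangular)
#' and the row-count agreement between matrix and sidecar.
#'
#' @param path TSV path with a header row of axis values.
#' @param sidecar_path JSON sidecar path.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path, sidecar_path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  axis <- suppressWarnings(as.numeric(names(df)))
  if (any(is.na(axis)))
    stop("non-numeric axis value in header column ", which(is.na(axis))[1])
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) mat <- matrix(mat, nrow = 1)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at row ", bad[1], ", column ", bad[2])
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  meta <- as.data.frame(side$meta)
  if (nrow(meta) != nrow(mat))
    stop("sidecar has ", nrow(meta), " metadata records for ", nrow(mat),
         " spectra rows")
  prov <- if (is.null(side$provenance)) list() else
    jsonlite::read_json(sidecar_path, simplifyVector = FALSE)$provenance
  spectra_set(axis, mat, meta, provenance = prov)
}

# ---- run configuration -----------------------------------------------------

run_config_defaults <- function() {
  list(
    seed = 1L,
    regions = list(c(615, 1800), c(2790, 3010)),
    spike_z = 8, spike_window = 7,
    emsc_poly_order = 3, b_ref_min = 1e-6,
    sg_window = 9, sg_polyorder = 3,
    reject_rel_threshold = 0.05, reject_abs_threshold = 0.02,
    n_components = 2, svm_C = 1, svm_alpha_init = 0.5, cv_folds = 10,
    train_batch = 2L, train_control = "control", train_highdose = "1 uM",
    ic50_lower_max = 30,
    paths = list(spectra = NULL, sidecar = NULL, reference_table = NULL,
                 output_dir = NULL)
  )
}

#' Build a validated run configuration
#'
#' Every tunable of the pipeline with its default; unknown keys are
#' rejected so typos cannot silently fall back to defaults. A run is
#' reproducible from the configuration and the inputs alone.
#'
#' @param ... Overrides of the defaults (see `run_config_defaults` in the
#'   source for the full list: seed, regions, spike/EMSC/smoothing/rejection
#'   parameters, classifier settings, training-set selector, IC50 bound,
#'   and input/output paths).
#' @return Object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- run_config_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file of overrides.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

# ---- pipeline driver -------------------------------------------------------

#' Run the full analysis chain
#'
#' Preprocess -> PCA-SVM training -> viability prediction -> dose-response
#' fit, plus the assay comparison when a reference table is supplied.
#' Intended for wavenumber-domain input; pixel-domain data should go through
#' [apply_calibration()] first.
#'
#' @param s Raw wavenumber-domain `spectra_set` (or `NULL` to read from
#'   `config$paths$spectra` / `config$paths$sidecar`).
#' @param config A [run_config()].
#' @param basis Optional [emsc_basis()]; by default the pure-cell reference
#'   is estimated from the training-batch control rows after spike removal
#'   and combined with the water and fluorescence profiles.
#' @param reference_table Optional data frame (`condition_label`, `batch`,
#'   `reference_percent`) for the assay comparison.
#' @return List of class `pipeline_result`: `prediction`
#'   (`viability_prediction`), `dose_response` (`dose_response_fit`), `pca`,
#'   `svm`, `comparison` (or `NULL`), `reports` (spike, EMSC, rejection, row
#'   accounting), `config_hash`.
#' @export
run_pipeline <- function(s = NULL, config = run_config(), basis = NULL,
                         reference_table = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(s)) {
    if (is.null(config$paths$spectra) || is.null(config$paths$sidecar))
      stop("no spectra given and no input paths configured")
    s <- read_spectra(config$paths$spectra, config$paths$sidecar)
  }
  regions <- region_spec(config$regions)
  if (is.null(basis)) {
    ctrl <- s$meta$batch == config$train_batch &
      s$meta$condition_label == config$train_control
    if (!any(ctrl))
      stop("preprocess stage: cannot build the EMSC basis - no rows match ",
           "the training control condition '", config$train_control,
           "' in batch ", config$train_batch)
    interf <- list(water = water_profile(s$axis),
                   fluorescence = fluorescence_profile(s$axis))
    ctrl_clean <- remove_spikes(subset_spectra(s, ctrl),
                                z_thresh = config$spike_z,
                                window = config$spike_window)$spectra
    reference <- estimate_pure_cell(ctrl_clean, interf,
                                    poly_order = config$emsc_poly_order)
    basis <- emsc_basis(reference, s$axis, interferents = interf,
                        poly_order = config$emsc_poly_order)
  }
  pp <- preprocess_spectra(s, basis, regions,
                           spike_z = config$spike_z,
                           spike_window = config$spike_window,
                           sg_window = config$sg_window,
                           sg_polyorder = config$sg_polyorder,
                           b_ref_min = config$b_ref_min,
                           reject_rel_threshold = config$reject_rel_threshold,
                           reject_abs_threshold = config$reject_abs_threshold)
  cls <- train_classifier(pp$spectra, train_batch = config$train_batch,
                          control_label = config$train_control,
                          highdose_label = config$train_highdose,
                          n_components = config$n_components,
                          C = config$svm_C, folds = config$cv_folds,
                          seed = config$seed)
  cls$svm$alpha_init <- config$svm_alpha_init
  pred <- predict_viability(pp$spectra, cls$pca, cls$svm)
  pooled <- pool_dose_response(pred$per_condition)
  dr <- fit_ic50(pooled$dose, pooled$percent_viable,
                 lower_max = config$ic50_lower_max)
  comparison <- if (!is.null(reference_table))
    compare_assays(pred, reference_table) else NULL
  accounting <- data.frame(
    stage = c("acquired", "after_rejection", "classified"),
    n = c(n_spectra(s), n_spectra(pp$spectra), length(pred$per_cell)))
  result <- list(prediction = pred, dose_response = dr, pca = cls$pca,
                 svm = cls$svm, comparison = comparison,
                 reports = list(spikes = pp$spike_report,
                                emsc = pp$emsc_coefficients,
                                rejection = pp$rejection_report,
                                accounting = accounting),
                 config_hash = config_hash(config))
  class(result) <- "pipeline_result"
  if (!is.null(config$paths$output_dir)) write_pipeline_result(result, config)
  result
}

#' Write pipeline artifacts to an output directory
#'
#' JSON results (predictions, dose-response, models, reports), each carrying
#' the configuration hash; re-running with the same configuration and inputs
#' overwrites identically.
#'
#' @param result A `pipeline_result`.
#' @param config The `run_config` used.
#' @return Invisibly, the output directory.
#' @export
write_pipeline_result <- function(result, config) {
  dir <- config$paths$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(x, file) jsonlite::write_json(
    c(list(config_hash = result$config_hash), x), file.path(dir, file),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  put(list(per_condition = result$prediction$per_condition),
      "viability_prediction.json")
  put(result$dose_response[c("lower", "upper", "slope", "ic50", "rss",
                             "extrapolated", "non_inhibitory")],
      "dose_response.json")
  put(list(explained_variance_ratio = result$pca$explained_variance_ratio,
           weights = result$svm$weights, bias = result$svm$bias,
           cv_cost = result$svm$cv_cost), "model.json")
  put(list(rejection = result$reports$rejection,
           accounting = result$reports$accounting), "reports.json")
  invisible(dir)
}
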