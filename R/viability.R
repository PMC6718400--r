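# Dose-response analysis of predicted viability percentages: four-parameter
# log-logistic IC50 estimation and comparison against the reference assay.

ll4 <- function(dose, lower, upper, slope, ic50) {
  lower + (upper - lower) / (1 + (dose / ic50)^slope)
}

#' Fit a log-logistic dose-response curve and estimate IC50
#'
#' Four-parameter log-logistic `f(d) = lower + (upper - lower) /
#' (1 + (d / ic50)^slope)`. The upper asymptote is anchored to the mean
#' zero-dose (control) viability, the lower asymptote is bounded in
#' `[0, 30]` (percentage units; scaled if the input is in fractions), and
#' `slope` and `ic50` are fitted by multi-start nonlinear least squares on
#' the positive-dose points. The best start by residual sum of squares wins;
#' ties cannot occur with a deterministic grid and optimizer, so the fit is
#' reproducible.
#'
#' @param doses Dose vector (uM); must contain 0 (control anchor) and at
#'   least 3 distinct positive doses.
#' @param viability_percent Observed viability, same length; either percent
#'   (0-100) or fraction (0-1) scale.
#' @param lower_max Upper bound of the lower asymptote, in percent units
#'   (default 30); rescaled automatically for fraction input.
#' @return Object of class `dose_response_fit`: `lower`, `upper`, `slope`,
#'   `ic50`, `rss`, `per_point_fit` (dose, observed, predicted),
#'   `extrapolated` flag, `non_inhibitory` flag, and `n_starts_converged`.
#' @export
fit_ic50 <- function(doses, viability_percent, lower_max = 30) {
  doses <- as.numeric(doses); v <- as.numeric(viability_percent)
  if (length(doses) != length(v)) stop("doses and viability must align")
  if (!all(is.finite(doses)) || !all(is.finite(v)))
    stop("non-finite dose or viability values")
  if (!any(doses == 0)) stop("a zero-dose (control) anchor is required")
  if (length(unique(doses[doses > 0])) < 3)
    stop("need at least 3 distinct positive dose levels")
  scale <- if (max(v) > 1.5) 1 else 0.01      # percent vs fraction input
  lmax <- lower_max * scale
  upper <- mean(v[doses == 0])
  d <- doses[doses > 0]; y <- v[doses > 0]
  lo_d <- min(d); hi_d <- max(d)

  starts <- expand.grid(slope = c(0.5, 1, 2, 4),
                        lic50 = log(exp(seq(log(lo_d / 5), log(hi_d * 5),
                                            length.out = 7))),
                        lower = c(0, lmax / 2))
  best <- NULL; n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ ll4(d, lower, upper, slope, exp(lic50)),
                        start = list(lower = starts$lower[i],
                                     slope = starts$slope[i],
                                     lic50 = starts$lic50[i]),
                        lower = c(0, -10, log(lo_d / 100)),
                        upper = c(lmax, 10, log(hi_d * 100)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(rss = rss, par = coef(fit))
  }
  if (is.null(best))
    stop("no start of the multi-start grid converged; slope grid ",
         paste(unique(starts$slope), collapse = "/"), ", ic50 grid ",
         format(exp(range(starts$lic50))), collapse = "..")
  lower <- unname(best$par["lower"]); slope <- unname(best$par["slope"])
  ic50 <- unname(exp(best$par["lic50"]))
  non_inhibitory <- slope <= 0
  if (non_inhibitory)
    warning("fitted slope is not positive: viability does not decrease with ",
            "dose (non-inhibitory fit)")
  extrapolated <- ic50 < lo_d / 10 || ic50 > hi_d * 10
  if (extrapolated)
    warning("IC50 = ", format(ic50), " lies outside [", format(lo_d / 10), ", ",
            format(hi_d * 10), "]; flagged as extrapolated")
  per_point <- data.frame(dose = doses, observed = v,
                          predicted = ll4(doses, lower, upper, slope, ic50))
  structure(list(lower = lower, upper = upper, slope = slope, ic50 = ic50,
                 rss = best$rss, per_point_fit = per_point,
                 extrapolated = extrapolated, non_inhibitory = non_inhibitory,
                 n_starts_converged = n_conv),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> IC50 =", format(x$ic50), " slope =", format(x$slope),
      "\n  asymptotes:", format(x$lower), "..", format(x$upper),
      " RSS =", format(x$rss), "\n")
  if (x$extrapolated) cat("  [flag] IC50 extrapolated beyond the dose range\n")
  if (x$non_inhibitory) cat("  [flag] non-inhibitory (slope <= 0)\n")
  invisible(x)
}

#' Pool predicted viabilities into dose-response points
#'
#' Averages the control (zero-dose) conditions within each batch into one
#' zero-dose anchor per batch and keeps the positive-dose conditions as-is,
#' pooling batches for a joint fit.
#'
#' @param per_condition Data frame with `dose`, `batch`, `percent_viable`
#'   (as in a `viability_prediction`).
#' @return Data frame with `dose` and `percent_viable`.
#' @export
pool_dose_response <- function(per_condition) {
  stopifnot(all(c("dose", "batch", "percent_viable") %in% names(per_condition)))
  out <- list()
  for (b in unique(per_condition$batch)) {
    pb <- per_condition[per_condition$batch == b, ]
    ctrl <- pb$dose == 0
    if (any(ctrl))
      out[[length(out) + 1]] <- data.frame(dose = 0,
                                           percent_viable = mean(pb$percent_viable[ctrl]))
    out[[length(out) + 1]] <- pb[!ctrl, c("dose", "percent_viable")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare predicted viabilities with a reference assay table
#'
#' Row-wise deviations `raman_percent - reference_percent`, matched on
#' condition label and batch.
#'
#' @param pred A `viability_prediction`, or a data frame with
#'   `condition_label`, `batch`, `percent_viable`.
#' @param reference Data frame with `condition_label`, `batch`,
#'   `reference_percent`.
#' @return Object of class `assay_comparison`: `rows` (condition, batch,
#'   raman_percent, reference_percent, deviation) and `max_abs_deviation`.
#' @export
compare_assays <- function(pred, reference) {
  if (inherits(pred, "viability_prediction")) pred <- pred$per_condition
  stopifnot(all(c("condition_label", "batch") %in% names(pred)),
            all(c("condition_label", "batch", "reference_percent") %in% names(reference)))
  pcol <- if ("percent_viable" %in% names(pred)) "percent_viable" else "raman_percent"
  key_p <- paste(pred$condition_label, pred$batch, sep = "|")
  key_r <- paste(reference$condition_label, reference$batch, sep = "|")
  missing_ref <- setdiff(key_p, key_r)
  if (length(missing_ref))
    stop("conditions missing from the reference table: ",
         paste(missing_ref, collapse = ", "))
  m <- match(key_p, key_r)
  rows <- data.frame(condition_label = pred$condition_label,
                     batch = pred$batch,
                     raman_percent = pred[[pcol]],
                     reference_percent = reference$reference_percent[m])
  rows$deviation <- rows$raman_percent - rows$reference_percent
  structure(list(rows = rows, max_abs_deviation = max(abs(rows$deviation))),
            class = "assay_comparison")
}

#' @export
print.assay_comparison <- function(x, ...) {
  cat("<assay_comparison> max |deviation| =", format(x$max_abs_deviation),
      "percentage points\n")
  print(x$rows)
  invisible(x)
}

#' Reference viability table of the doxorubicin assay
#'
#' The published per-condition viability percentages of DOX-treated THP-1
#' cells: Raman-predicted percentages alongside the trypan-blue reference
#' assay, for two biological replicates (each with a leading and a trailing
#' control well). Shipped as a plain-text fixture; this is the table the
#' printed-data dose-response fit and deviation arithmetic run on.
#'
#' @return Data frame with `condition_label`, `dose`, `batch`, `well_order`,
#'   `raman_percent`, `reference_percent`.
#' @export
dox_viability_table <- function() {
  path <- system.file("extdata", "dox_thp1_viability.csv",
                      package = "ramanviability", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
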