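#!/usr/bin/env Rscript
# Step 2: instrument calibration on synthetic reference measurements.
#
# A paracetamol reference spectrum rendered in the pixel domain through a
# known quadratic pixel-to-wavenumber map, and a calibration-lamp pair with
# a known instrument response. Fitting both and checking the recovery error
# validates the calibration stage on this instrument geometry; the main
# dataset of step 1 is already simulated in the wavenumber domain, so this
# step is a self-contained check rather than a prerequisite of step 3.

suppressMessages(library(ramanviability))
dir.create("results", showWarnings = FALSE)

true_coeffs <- c(310, 2.05, 1e-4)       # 1340-pixel detector, ~2.1 cm^-1/px
npx <- 1340
axis_px <- make_axis(npx, true_coeffs)

par <- simulate_paracetamol(axis_px, width = 14)
model <- fit_wavelength(par$spectrum, par$bands$center, degree = 3)

lamp <- simulate_lamp_pair(axis_px)
resp <- fit_response(lamp$measured, lamp$true)
resp_err <- max(abs(resp - lamp$response / mean(lamp$response)) /
                (lamp$response / mean(lamp$response)))

recovered_axis <- vapply(seq(0, npx - 1), function(px)
  sum(model$wl_coeffs * px^(seq_along(model$wl_coeffs) - 1)), 0)

summary <- data.frame(
  quantity = c("n_reference_bands", "poly_degree",
               "max_band_residual_cm1", "max_axis_error_cm1",
               "max_rel_response_error"),
  value = c(nrow(par$bands), model$wl_degree,
            max(abs(model$reference_residuals)),
            max(abs(recovered_axis - axis_px)),
            resp_err))
write.csv(summary, "results/02_calibration_summary.csv", row.names = FALSE)

cat("Wavelength fit:", nrow(par$bands), "bands, degree", model$wl_degree,
    "- max band residual", format(max(abs(model$reference_residuals)), digits = 3),
    "cm^-1\n")
cat("Axis recovered to", format(max(abs(recovered_axis - axis_px)), digits = 3),
    "cm^-1; response recovered to",
    format(100 * resp_err, digits = 3), "% relative.\n")
cat("Wrote results/02_calibration_summary.csv\n")
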