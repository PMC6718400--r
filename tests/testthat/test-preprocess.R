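# Spectral cleanup chain: despiking, EMSC, smoothing, normalization, region
# selection and empty-spectrum rejection, each against a constructed or
# brute-force oracle.

test_that("spike removal is a no-op on clean spectra and recovers injected spikes", {
  axis <- default_axis()
  clean <- simulate_population(population_spec(n_cells = 20, spike_rate = 0,
                                               seed = 4L),
                               axis = axis)$spectra
  out <- remove_spikes(clean)
  expect_equal(out$spectra$intensities, clean$intensities)
  expect_true(all(out$report$n_corrected == 0))

  spiky <- simulate_population(population_spec(n_cells = 300, spike_rate = 0.5,
                                               seed = 14L), axis = axis)
  truth <- spiky$spike_positions
  res <- remove_spikes(spiky$spectra)
  n_inj <- sum(lengths(truth))
  n_hit <- sum(vapply(seq_along(truth), function(i)
    length(intersect(truth[[i]], res$report$positions[[i]])), 0L))
  expect_gt(n_inj, 50)
  expect_gte(n_hit / n_inj, 0.95)
  false_corr <- sum(vapply(seq_along(truth), function(i)
    length(setdiff(res$report$positions[[i]], truth[[i]])), 0L))
  expect_lt(false_corr / (300 * n_channels(spiky$spectra)), 0.01)
})

test_that("a single large spike is replaced by the local median", {
  axis <- default_axis()
  s <- simulate_population(population_spec(n_cells = 1, spike_rate = 0,
                                           noise_sd = 0, seed = 2L),
                           axis = axis)$spectra
  ch <- 700
  y <- s$intensities[1, ]
  s$intensities[1, ch] <- y[ch] + 50 * max(abs(y))
  res <- remove_spikes(s)
  expect_true(ch %in% res$report$positions[[1]])
  local_med <- median(y[(ch - 3):(ch + 3)])
  expect_lt(abs(res$spectra$intensities[1, ch] - local_med),
            0.1 * abs(local_med) + 1e-12)
  expect_error(remove_spikes(s, window = 4), "odd")
  expect_error(remove_spikes(s, window = n_channels(s) + 1), "smaller")
})

test_that("EMSC recovers exact in-span constructions", {
  axis <- default_axis()
  basis <- fixture_basis(axis)
  ref <- basis$reference
  v <- 2 * (axis - min(axis)) / diff(range(axis)) - 1
  y1 <- 2 * ref + 0.3 - 0.2 * v + 0.5 * v^2 + 0.1 * v^3
  y2 <- ref + 5 * basis$interferents$water
  s <- spectra_set(axis, rbind(y1, y2))
  out <- emsc_correct(s, basis)
  expect_equal(out$spectra$intensities[1, ], ref, tolerance = 1e-9)
  expect_equal(out$coefficients$b_ref[1], 2, tolerance = 1e-9)
  expect_equal(out$spectra$intensities[2, ], ref, tolerance = 1e-9)
  expect_equal(out$coefficients$water[2], 5, tolerance = 1e-9)
  expect_equal(out$coefficients$b_ref[2], 1, tolerance = 1e-9)
})

test_that("EMSC equals an independent per-spectrum OLS solve", {
  axis <- default_axis()
  basis <- fixture_basis(axis)
  batch <- simulate_population(population_spec(n_cells = 200, dose = 0.5,
                                               viable_fraction = 0.6,
                                               seed = 21L), axis = axis)$spectra
  out <- emsc_correct(batch, basis)
  ok <- !grepl("no_cell_signal", out$spectra$meta$qc_flags)
  worst <- 0
  for (i in which(ok)) {
    o <- oracle_emsc_row(batch$intensities[i, ], basis$design)
    worst <- max(worst, max(abs(out$spectra$intensities[i, ] - o)))
  }
  expect_lt(worst, 1e-10)
})

test_that("EMSC flags rows without cell signal and is idempotent on its output", {
  axis <- default_axis()
  basis <- fixture_basis(axis)
  bg <- 2 * basis$interferents$fluorescence + basis$interferents$water
  s <- spectra_set(axis, rbind(bg, basis$reference + bg))
  out <- emsc_correct(s, basis)
  expect_match(out$spectra$meta$qc_flags[1], "no_cell_signal")
  expect_equal(out$spectra$meta$qc_flags[2], "")
  # idempotence: re-running on corrected in-span output gives b_ref = 1,
  # interferents 0
  again <- emsc_correct(subset_spectra(out$spectra, 2), basis)
  expect_equal(again$coefficients$b_ref, 1, tolerance = 1e-8)
  expect_lt(abs(again$coefficients$water), 1e-8)
  expect_lt(abs(again$coefficients$fluorescence), 1e-8)
  # rank-deficient basis is rejected at construction
  expect_error(emsc_basis(basis$reference, axis,
                          interferents = list(water = basis$interferents$water,
                                              again = basis$interferents$water)),
               "rank deficient")
})

test_that("Savitzky-Golay preserves low-order polynomials and matches the LS kernel", {
  axis <- seq_len(101)
  p <- 2 + 0.5 * axis - 0.01 * axis^2 + 1e-4 * axis^3
  s <- spectra_set(axis, matrix(p, 1))
  sm <- smooth_spectra(s, window = 9, polyorder = 3)
  expect_equal(sm$intensities[1, ], p, tolerance = 1e-12)
  # white noise loses variance
  set.seed(9)
  noise <- rnorm(101)
  sn <- smooth_spectra(spectra_set(axis, matrix(noise, 1)))
  expect_lt(var(sn$intensities[1, ]), var(noise))
  # impulse response equals the independently built projection-matrix row
  imp <- numeric(101); imp[51] <- 1
  si <- smooth_spectra(spectra_set(axis, matrix(imp, 1)), window = 9, polyorder = 3)
  expect_equal(si$intensities[1, 47:55], oracle_sg_center_row(9, 3),
               tolerance = 1e-12)
  expect_error(smooth_spectra(s, window = 9, polyorder = 9), "smaller")
})

test_that("area normalization cancels gain and flags zero rows", {
  axis <- default_axis()
  regions <- default_regions()
  s <- simulate_population(population_spec(n_cells = 1, noise_sd = 0,
                                           spike_rate = 0, seed = 3L),
                           axis = axis)$spectra
  y <- s$intensities[1, ]
  pair <- spectra_set(axis, rbind(y, 3.14 * y, 0 * y))
  out <- area_normalize(pair, regions)
  expect_equal(out$intensities[1, ], out$intensities[2, ], tolerance = 1e-10)
  expect_match(out$meta$qc_flags[3], "zero_integral")
  expect_equal(out$intensities[3, ], 0 * y)
  # post-normalization integral over the regions is exactly 1
  i1 <- ramanviability:::row_region_integral(axis, out$intensities[1, , drop = FALSE],
                                             regions)
  expect_equal(i1, 1, tolerance = 1e-12)
})

test_that("gain-perturbed copies of one cell coincide after normalization", {
  axis <- default_axis()
  spec <- population_spec(n_cells = 2, noise_sd = 0, gain_cv = 0.3,
                          weight_jitter_sd = 0, spike_rate = 0, empty_rate = 0,
                          seed = 17L)
  s <- simulate_population(spec, axis = axis)$spectra
  expect_gt(max(abs(s$intensities[1, ] - s$intensities[2, ])), 0)
  out <- area_normalize(s, default_regions())
  expect_equal(out$intensities[1, ], out$intensities[2, ], tolerance = 1e-10)
})

test_that("region selection keeps exactly the channels in the windows", {
  axis <- make_axis(1400, c(300, 2))
  s <- simulate_population(population_spec(n_cells = 2, seed = 5L), axis = axis)$spectra
  regions <- default_regions()
  out <- select_regions(s, regions)
  n_expected <- sum(axis >= 615 & axis < 1800) + sum(axis >= 2790 & axis < 3010)
  expect_equal(n_channels(out), n_expected)
  expect_equal(length(out$axis), ncol(out$intensities))
  full <- select_regions(s, region_spec(list(range(axis) + c(-1, 1))))
  expect_equal(full$intensities, s$intensities)
  expect_error(select_regions(s, region_spec(list(c(5000, 6000)))), "empty")
  expect_error(region_spec(list(c(600, 1800), c(1700, 3000))), "disjoint")
})

test_that("empty-spectrum rejection recovers the empty rate", {
  axis <- default_axis()
  basis <- fixture_basis(axis)
  s <- simulate_population(population_spec(n_cells = 2000, empty_rate = 0.1,
                                           seed = 31L), axis = axis)$spectra
  pp <- preprocess_spectra(s, basis)
  frac <- pp$rejection_report$rejected_fraction
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
  # and rejections agree with ground truth exactly on this clean generator
  truth_empty <- mean(s$meta$ground_truth_label == "empty")
  expect_equal(frac, truth_empty, tolerance = 1e-12)

  clean <- simulate_population(population_spec(n_cells = 300, empty_rate = 0,
                                               seed = 32L), axis = axis)$spectra
  pp2 <- preprocess_spectra(clean, basis)
  expect_equal(pp2$rejection_report$n_rejected, 0L)

  allbg <- simulate_population(population_spec(n_cells = 50, empty_rate = 1,
                                               seed = 33L), axis = axis)$spectra
  expect_warning(preprocess_spectra(allbg, basis), "all 50 spectra rejected")
  expect_error(reject_empty(clean), "emsc_correct")
})

test_that("provenance replay reproduces the processed set bit-identically", {
  axis <- default_axis()
  basis <- fixture_basis(axis)
  raw <- simulate_population(population_spec(n_cells = 80, seed = 41L),
                             axis = axis)$spectra
  pp <- preprocess_spectra(raw, basis)
  ops <- vapply(pp$spectra$provenance, `[[`, "", "op")
  expect_equal(ops[-1], c("remove_spikes", "emsc_correct", "smooth",
                          "area_normalize", "select_regions", "reject_empty"))
  replayed <- replay_provenance(raw, pp$spectra$provenance[-1])
  expect_identical(replayed$intensities, pp$spectra$intensities)
  expect_identical(replayed$axis, pp$spectra$axis)
})

test_that("pipeline PCA scores are invariant to pre-pipeline multiplicative gain", {
  axis <- default_axis()
  basis <- fixture_basis(axis)
  spec <- population_spec(n_cells = 40, noise_sd = 0, gain_cv = 0,
                          weight_jitter_sd = 0.03, spike_rate = 0,
                          empty_rate = 0, viable_fraction = 0.5, seed = 51L)
  s <- simulate_population(spec, axis = axis)$spectra
  s2 <- s
  set.seed(52)
  s2$intensities <- s$intensities * runif(n_spectra(s), 0.5, 2)
  p1 <- fit_pca(preprocess_spectra(s, basis)$spectra, 2)
  p2 <- fit_pca(preprocess_spectra(s2, basis)$spectra, 2)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-8)
})
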