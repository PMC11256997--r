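test_that("ALS baseline removes a pure cubic background", {
  s <- make_spectrum(function(w) {
    u <- (w - 600) / 1200
    2 + 1.5 * u - 0.8 * u^2 + 0.4 * u^3
  })
  corrected <- baseline_correct(s)
  expect_lt(max(abs(corrected$intensity)),
            0.01 * diff(range(s$intensity)))
  expect_true("baseline_corrected" %in% corrected$state)
})

test_that("ALS preserves band height over a flat baseline", {
  s <- make_spectrum(function(w) 5 + pv_profile(w, 1001, 8))
  corrected <- baseline_correct(s)
  height <- corrected$intensity[s$wavenumber == 1001]
  expect_equal(height, 1, tolerance = 0.05)
})

test_that("baseline correction is numerically idempotent", {
  s <- simulate_spectra(quick_spectra_config(seed = 2, n_cells = 1,
                                             n_labelled = 0))[[1]]
  once <- baseline_correct(s)
  twice <- baseline_correct(once)
  rms_change <- sqrt(mean((twice$intensity - once$intensity)^2))
  expect_lt(rms_change, 0.01 * diff(range(s$intensity)))
})

test_that("vector normalisation yields unit norm, is idempotent and gain-invariant", {
  s <- simulate_spectra(quick_spectra_config(seed = 3, n_cells = 1,
                                             n_labelled = 1))[[1]]
  n1 <- vector_normalize(s)
  expect_equal(sqrt(sum(n1$intensity^2)), 1, tolerance = 1e-9)
  n2 <- vector_normalize(n1)
  expect_equal(n1$intensity, n2$intensity)
  s10 <- s; s10$intensity <- 10 * s$intensity
  expect_equal(vector_normalize(s10)$intensity, n1$intensity)
  zero <- make_spectrum(function(w) rep(0, length(w)))
  expect_error(vector_normalize(zero), "all-zero")
})

test_that("band detection locates the labelled and unlabelled bands on noiseless cells", {
  cfg <- sim_spectra_config(n_cells = 2, n_labelled = 1, noise_sd = 0,
                            amplitude_jitter_sd = 0)
  sp <- lapply(simulate_spectra(cfg), preprocess_spectrum)
  lab <- detect_phenylalanine_band(sp[[1]])
  expect_equal(lab$labelled$position, 968, tolerance = 1 / 968)
  expect_null(lab$unlabelled)
  unlab <- detect_phenylalanine_band(sp[[2]])
  expect_equal(unlab$unlabelled$position, 1001, tolerance = 1 / 1001)
  expect_null(unlab$labelled)
})

test_that("a flat spectrum yields no band calls", {
  flat <- make_spectrum(function(w) rep(1, length(w)))
  det <- detect_phenylalanine_band(flat)
  expect_null(det$labelled)
  expect_null(det$unlabelled)
})

test_that("peak finding agrees with an exhaustive local-maxima scan", {
  for (seed in 1:5) {
    set.seed(seed)
    w <- seq(600, 1800, length.out = 1500)
    y <- pv_profile(w, 968, 8) + 0.6 * pv_profile(w, 1450, 10) +
      rnorm(length(w), 0, 0.03)
    s <- raman_spectrum("c", "13C", w, y)
    peaks <- find_peaks(s)
    idx <- oracle_local_maxima(y)
    expect_equal(peaks$position, w[idx])
    expect_equal(peaks$height, y[idx])
    # prominence of the dominant peak approaches its height above the floor
    top <- which.max(peaks$height)
    expect_gt(peaks$prominence[top], 0.8 * peaks$height[top] - min(y))
  }
})

test_that("the labelling decision follows the redshift rule", {
  # peak only at 968
  only968 <- preprocess_spectrum(make_spectrum(function(w) {
    1 + pv_profile(w, 968, 8) + 0.3 * pv_profile(w, 1450, 8)
  }))
  call <- classify_label(only968)
  expect_true(call$labelled)
  expect_equal(call$shift_cm1, -33, tolerance = 1 / 33)
  # peak only at 1001
  only1001 <- preprocess_spectrum(make_spectrum(function(w) {
    1 + pv_profile(w, 1001, 8) + 0.3 * pv_profile(w, 1450, 8)
  }))
  call <- classify_label(only1001)
  expect_false(call$labelled)
  expect_equal(call$band_position, 1001)
  # both bands, 968 weaker -> unlabelled
  both <- preprocess_spectrum(make_spectrum(function(w) {
    1 + 0.4 * pv_profile(w, 968, 8) + pv_profile(w, 1001, 8)
  }))
  expect_false(classify_label(both)$labelled)
  # both bands, 968 stronger -> labelled
  both2 <- preprocess_spectrum(make_spectrum(function(w) {
    1 + pv_profile(w, 968, 8) + 0.4 * pv_profile(w, 1001, 8)
  }))
  expect_true(classify_label(both2)$labelled)
})

test_that("classification on default-noise cells recovers the ground truth", {
  cfg <- quick_spectra_config(seed = 12, n_cells = 30, n_labelled = 10)
  sp <- simulate_spectra(cfg)
  calls <- classify_cells(sp)
  truth <- vapply(sp, function(s) s$meta$true_labelled, logical(1))
  expect_identical(calls$labelled, unname(truth))
})

test_that("band-intensity ANOVA behaves at its boundary cases", {
  # identical groups -> F = 0, p = 1
  calls <- data.frame(intensity_968 = rep(c(0.1, 0.2, 0.3), 3),
                      intensity_1001 = rep(c(0.3, 0.2, 0.1), 3))
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- compare_band_intensities(calls, grp)
  expect_equal(res$F, c(0, 0), tolerance = 1e-12)
  expect_equal(res$p, c(1, 1), tolerance = 1e-12)
  # two-group ANOVA equals the squared pooled t statistic
  set.seed(5)
  two <- data.frame(intensity_968 = c(rnorm(8, 1), rnorm(8, 1.5)),
                    intensity_1001 = c(rnorm(8, 2), rnorm(8, 2.2)))
  g2 <- rep(c("x", "y"), each = 8)
  res2 <- compare_band_intensities(two, g2)
  t968 <- t.test(intensity_968 ~ g2, data = two, var.equal = TRUE)$statistic
  t1001 <- t.test(intensity_1001 ~ g2, data = two, var.equal = TRUE)$statistic
  expect_equal(res2$F, unname(c(t968^2, t1001^2)))
  # a group with < 2 cells is rejected
  expect_error(compare_band_intensities(two[1:9, ], c(rep("x", 8), "y")),
               ">= 2 cells")
})

test_that("band intensities separate the three cell groups strongly", {
  sp13 <- simulate_spectra(sim_spectra_config(seed = 31, n_cells = 60,
                                              n_labelled = 20,
                                              treatment = "13C"))
  sp12 <- simulate_spectra(sim_spectra_config(seed = 32, n_cells = 30,
                                              n_labelled = 0,
                                              treatment = "12C"))
  calls13 <- classify_cells(sp13)
  calls12 <- classify_cells(sp12)
  calls <- rbind(calls13, calls12)
  grp <- c(ifelse(calls13$labelled, "labelled_13C", "unlabelled_13C"),
           rep("12C", nrow(calls12)))
  res <- compare_band_intensities(calls, grp)
  expect_lt(res$p[res$band == "968"], 0.001)
  expect_lt(res$p[res$band == "1001"], 0.001)
})

test_that("the sorting manifest lists exactly the labelled cells", {
  cfg <- quick_spectra_config(seed = 13, n_cells = 20, n_labelled = 6)
  sp <- simulate_spectra(cfg)
  calls <- classify_cells(sp)
  manifest <- build_sorting_manifest(calls)
  truth_ids <- vapply(sp[vapply(sp, function(s) s$meta$true_labelled,
                                logical(1))],
                      function(s) s$cell_id, character(1))
  expect_identical(manifest$n, length(truth_ids))
  expect_setequal(manifest$cells$cell_id, truth_ids)
  expect_false(anyDuplicated(manifest$cells$cell_id) > 0)
  # zero labelled -> empty manifest
  none <- classify_cells(simulate_spectra(quick_spectra_config(
    seed = 14, n_cells = 4, n_labelled = 0)))
  expect_identical(build_sorting_manifest(none)$n, 0L)
})
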