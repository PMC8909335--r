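test_that("window plan implements the 10-wavelength, 94%-overlap geometry", {
  cfg <- acq_config()
  expect_equal(window_side(cfg), 2.2e-3)
  roi <- matrix(TRUE, cfg$n_samples, cfg$n_lines)
  plan <- plan_windows(roi, cfg)
  wp <- attr(plan, "win_px"); st <- attr(plan, "step_px")
  expect_equal(unname(wp["ax"]), round(2.2e-3 / axial_pitch(cfg)))
  ## 6% step: 0.132 mm axially (~7 samples); lateral snaps to one line
  expect_equal(unname(st["ax"]), 7)
  expect_equal(unname(st["lat"]), 1)
  ## all planned windows lie fully inside the ROI
  expect_true(all(plan$ax + wp["ax"] - 1 <= nrow(roi)))
  expect_true(all(plan$lat + wp["lat"] - 1 <= ncol(roi)))

  ## ROI of exactly one window -> exactly one origin
  roi1 <- matrix(FALSE, cfg$n_samples, cfg$n_lines)
  roi1[101:(100 + wp["ax"]), 5:(4 + wp["lat"])] <- TRUE
  p1 <- plan_windows(roi1, cfg)
  expect_equal(nrow(p1), 1L)
  expect_equal(c(p1$ax, p1$lat), c(101L, 5L))

  ## too-small ROI -> empty plan with warning
  roi0 <- matrix(FALSE, cfg$n_samples, cfg$n_lines)
  roi0[1:20, 1:3] <- TRUE
  expect_warning(p0 <- plan_windows(roi0, cfg), "smaller")
  expect_equal(nrow(p0), 0L)
  expect_error(plan_windows(matrix(FALSE, 10, 10), cfg), "empty")
})

test_that("windowed power spectrum matches physics and a brute-force DFT", {
  cfg <- acq_config()
  wp <- c(ax = 115, lat = 9)
  t <- (0:(cfg$n_samples - 1)) / cfg$sampling_rate
  frame <- matrix(sin(2 * pi * 5e6 * t), cfg$n_samples, cfg$n_lines)
  ps <- window_power_spectrum(frame, c(1, 1), cfg)
  expect_equal(ps$freq[which.max(ps$power)], 5e6, tolerance = 0.02)
  ## +6.02 dB when amplitude doubles
  ps2 <- window_power_spectrum(2 * frame, c(1, 1), cfg)
  nz <- ps$power > max(ps$power) * 1e-12
  expect_equal(10 * log10(ps2$power[nz] / ps$power[nz]),
               rep(20 * log10(2), sum(nz)), tolerance = 1e-9)

  ## brute-force DFT oracle on a 64-sample window
  cfg64 <- acq_config(sampling_rate = 40e6, center_frequency = 12.5e6,
                      band_low = 8e6, band_high = 18e6,
                      line_pitch = 0.616e-3, n_samples = 128L, n_lines = 4L)
  set.seed(42)
  fr <- matrix(rnorm(128 * 4), 128, 4)
  ps64 <- window_power_spectrum(fr, c(1, 1), cfg64, nfft = 64L)
  n <- 64
  w <- 0.5 - 0.5 * cos(2 * pi * (1:n) / (n + 1))
  oracle <- sapply(1:2, function(l) {
    x <- fr[1:n, l] * w
    sapply(0:(n / 2), function(k)
      Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))^2 / sum(w^2))
  })
  expect_equal(ps64$power, rowMeans(oracle), tolerance = 1e-10)

  ## all-zero window flagged
  psz <- window_power_spectrum(matrix(0, 128, 4), c(1, 1), cfg64)
  expect_true(attr(psz, "all_zero"))
  expect_error(window_power_spectrum(fr, c(120, 1), cfg64), "bounds")
})

test_that("normalisation and attenuation correction follow the closed form", {
  s <- flat_ps(10); r <- flat_ps(1)
  ns <- normalize_and_correct(s, r, depth = 0.01, ace_assumed = 0)
  expect_equal(ns$values, rep(10, length(ns$values)))
  expect_true(all(ns$freq >= 4e6 & ns$freq <= 9e6))
  ## correction term: 2 * ace * f_MHz * (2 * depth_cm) -> +28 dB at 7 MHz,
  ## 1 cm, 1 dB/cm/MHz
  ns1 <- normalize_and_correct(r, r, depth = 0.01, ace_assumed = 1)
  i7 <- which.min(abs(ns1$freq - 7e6))
  expect_equal(ns1$values[i7], 2 * 1 * (ns1$freq[i7] / 1e6) * 2, tolerance = 1e-12)
  ## zero reference bins are named errors
  bad <- r; bad$power[300] <- 0
  expect_error(normalize_and_correct(s, bad, 0.01), "non-positive")
  s2 <- s; s2$freq <- s2$freq + 1
  expect_error(normalize_and_correct(s2, r, 0.01), "grids differ")
})

test_that("MBF/SS/SI line fit is exact on lines and matches normal equations", {
  cfg <- acq_config()
  f <- seq(4e6, 9e6, by = 0.05e6)
  flat <- structure(list(freq = f, values = rep(5, length(f)), depth = 0.01),
                    class = "normalized_spectrum")
  expect_equal(unname(fit_mbf_ss_si(flat, cfg)), c(5, 0, 5))
  line <- flat; line$values <- 2 * f / 1e6
  expect_equal(unname(fit_mbf_ss_si(line, cfg)), c(14, 2, 0), tolerance = 1e-12)
  ## noisy spectrum vs explicit normal equations
  set.seed(1)
  noisy <- flat; noisy$values <- 3 - 1.5 * f / 1e6 + rnorm(length(f))
  got <- fit_mbf_ss_si(noisy, cfg)
  X <- cbind(1, f / 1e6)
  beta <- solve(t(X) %*% X, t(X) %*% noisy$values)
  expect_equal(got[["SI"]], beta[1], tolerance = 1e-9)
  expect_equal(got[["SS"]], beta[2], tolerance = 1e-9)
  expect_equal(got[["MBF"]], got[["SI"]] + got[["SS"]] * 7, tolerance = 1e-12)
  short <- flat; short$freq <- short$freq[1:2]; short$values <- short$values[1:2]
  expect_error(fit_mbf_ss_si(short, cfg), "3 in-band")
})

test_that("SAS reads a synthetic ripple and flags aperiodic spectra", {
  f <- seq(3e6, 11e6, by = 20e3)
  ## ripple with period 0.77 MHz -> spacing c/(2 * 0.77 MHz) = 1.0 mm
  ripple <- 2 * cos(2 * pi * f / 0.77e6)
  expect_equal(estimate_sas(f, ripple, sound_speed = 1540), 1.0,
               tolerance = 0.01)
  ## smooth spectrum: no non-trivial periodicity
  expect_true(is.na(estimate_sas(f, 30 - 2 * (f / 1e6), sound_speed = 1540)))
  expect_error(estimate_sas(f[1:5], ripple[1:5], 1540), "band too narrow")
  expect_error(estimate_sas(f[c(1, 3, 4, 8)], ripple[c(1, 3, 4, 8)], 1540),
               "regular")
})

test_that("BSC estimation obeys the reference-ratio identities", {
  f <- seq(4e6, 9e6, by = 0.1e6)
  zero <- structure(list(freq = f, values = rep(0, length(f))),
                    class = "normalized_spectrum")
  bsc <- estimate_bsc(zero)
  expect_equal(bsc$bsc, (f / 1e6)^4)   # sample = reference -> reference BSC
  ten <- zero; ten$values <- rep(10, length(f))
  expect_equal(estimate_bsc(ten)$bsc, 10 * (f / 1e6)^4)
})

test_that("form factors have the correct limits and the ASD/AAC fit round-trips", {
  f <- seq(4e6, 9e6, by = 0.05e6)
  expect_equal(form_factor_gaussian(f, 0), rep(1, length(f)))
  expect_lt(max(form_factor_anderson(f, 150e-6)), 1 + 1e-9)
  expect_equal(form_factor_anderson(c(1e4, 2e4), 100e-6), c(1, 1),
               tolerance = 1e-3)
  ## Gaussian FF -> 1 as f -> 0 so BSC -> A f^4 in the low band
  expect_equal(form_factor_gaussian(1e4, 100e-6), 1, tolerance = 1e-5)

  ## noise-free generate-and-fit round trip, both form factors
  for (kind in c("gaussian", "anderson")) {
    d_true <- 100e-6; a_true_db <- 12
    bsc <- list(freq = f,
                bsc = 10^(a_true_db / 10) * (f / 1e6)^4 *
                  if (kind == "gaussian") form_factor_gaussian(f, d_true)
                  else form_factor_anderson(f, d_true))
    fit <- fit_asd_aac(bsc, form_factor_kind = kind)
    expect_equal(fit[["ASD"]], 100, tolerance = 0.01)
    expect_equal(fit[["AAC"]], 12, tolerance = 0.01 * 12)
    expect_false(attr(fit, "at_bound"))
  }
  expect_error(fit_asd_aac(list(freq = f, bsc = rep(-1, length(f)))),
               "positive")
})

test_that("speckle-phantom recovery: ASD, AAC, ACE and the map contract", {
  qm <- speckle_maps()   # truth: ASD 120 um, AAC 30 dB, ACE 1.0
  expect_equal(qm$means[["ASD"]], 120, tolerance = 0.10)
  expect_equal(qm$means[["AAC"]], 30, tolerance = 0.15)
  expect_equal(qm$ace, 1.0, tolerance = 0.15)
  ## MBF = SI + SS * fc holds cell-wise across the maps
  mismatch <- abs(qm$maps$MBF$grid - (qm$maps$SI$grid + qm$maps$SS$grid * 7))
  expect_lt(max(mismatch, na.rm = TRUE), 1e-9)
  ## mean feature = arithmetic mean of finite map cells, exactly
  for (p in names(qm$maps)) {
    g <- qm$maps[[p]]$grid
    expect_identical(qm$means[[p]], mean(g[is.finite(g)]))
  }
  ## homogeneous phantom -> spatially stable ASD map
  g <- qm$maps$ASD$grid
  expect_lt(sd(g[is.finite(g)]) / mean(g[is.finite(g)]), 0.25)
})

test_that("ACE requires depth spread and is stable across ROIs", {
  cfg <- small_cfg()
  ref <- small_reference()
  ph <- phantom_spec(scatterer_diameter = 100e-6, acoustic_concentration = 20,
                     attenuation = 0.8, rng_seed = 55L)
  fr <- simulate_rf_frame(ph, cfg)
  roi_a <- matrix(FALSE, cfg$n_samples, cfg$n_lines); roi_a[120:420, 4:16] <- TRUE
  roi_b <- matrix(FALSE, cfg$n_samples, cfg$n_lines); roi_b[120:420, 17:29] <- TRUE
  ace_a <- estimate_ace(fr, roi_a, ref, cfg)
  ace_b <- estimate_ace(fr, roi_b, ref, cfg)
  expect_equal(ace_a, 0.8, tolerance = 0.3)
  expect_lt(abs(ace_a - ace_b), 0.3)
  ## single-depth ROI: one axial row of windows only
  wp <- attr(plan_windows(roi_a, cfg), "win_px")
  roi_1 <- matrix(FALSE, cfg$n_samples, cfg$n_lines)
  roi_1[200:(199 + wp["ax"]), 4:29] <- TRUE
  expect_error(estimate_ace(fr, roi_1, ref, cfg), "single depth")
})

test_that("lattice phantom SAS is recovered and diffuse windows are sentinels", {
  cfg <- small_cfg()
  ph <- phantom_spec(scatterer_diameter = 60e-6, acoustic_concentration = 25,
                     attenuation = 0.3, mean_spacing = 1e-3, rng_seed = 11L)
  fr <- simulate_rf_frame(ph, cfg)
  qm <- build_parametric_maps(fr, small_roi(cfg), small_reference(), cfg)
  sas <- qm$maps$SAS$grid
  expect_equal(median(sas[is.finite(sas)]), 1.0, tolerance = 0.05)
  ## diffuse phantom: most windows carry the no-periodicity sentinel
  qm0 <- speckle_maps()
  expect_gt(qm0$n_sas_sentinel / nrow(qm0$plan), 0.5)
})
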