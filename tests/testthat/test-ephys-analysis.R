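test_that("noiseless sigmoid parameters are recovered exactly", {
  df <- sigmoid_table(V0 = 20, logR = -2.5, n = 1.0)
  fit <- fit_intensity_response(df)
  expect_equal(fit$V0, 20, tolerance = 1e-6)
  expect_equal(fit$logR, -2.5, tolerance = 1e-6)
  expect_equal(fit$n, 1.0, tolerance = 1e-6)
  expect_equal(fit$branch, "depolarizing")
  # hyperpolarizing branch: sign carried in V0
  dfh <- df; dfh$response_mV <- -dfh$response_mV
  fith <- fit_intensity_response(dfh)
  expect_equal(fith$V0, -20, tolerance = 1e-6)
  expect_equal(fith$branch, "hyperpolarizing")
})

test_that("noisy G+ parameters are recovered near the generative values", {
  set.seed(42)
  logI <- rep(seq(-4.5, -1, by = 0.25), each = 2)
  I <- 10^logI
  v <- 25 * I^0.86 / (I^0.86 + (10^-2.51)^0.86) + stats::rnorm(length(I), 0, 0.5)
  fit <- fit_intensity_response(data.frame(log10_intensity = logI,
                                           response_mV = v))
  # bootstrap CI of the estimates covers the generative truth
  set.seed(43)
  boots <- t(replicate(200, {
    idx <- sample(length(logI), replace = TRUE)
    f <- tryCatch(fit_intensity_response(
      data.frame(log10_intensity = logI[idx], response_mV = v[idx])),
      error = function(e) NULL)
    if (is.null(f)) c(NA, NA) else c(f$logR, f$n)
  }))
  ci_logR <- stats::quantile(boots[, 1], c(0.025, 0.975), na.rm = TRUE)
  ci_n <- stats::quantile(boots[, 2], c(0.025, 0.975), na.rm = TRUE)
  expect_gt(-2.51, ci_logR[1]); expect_lt(-2.51, ci_logR[2])
  expect_gt(0.86, ci_n[1]); expect_lt(0.86, ci_n[2])
})

test_that("degenerate intensity-response input is rejected", {
  flat <- data.frame(log10_intensity = seq(-3, 0, 0.5), response_mV = 5)
  expect_error(fit_intensity_response(flat), "degenerate")
  short <- data.frame(log10_intensity = c(-2, -1, 0), response_mV = c(1, 5, 9))
  expect_error(fit_intensity_response(short), "4")
})

test_that("the exclusion window drops the requested intensities", {
  df <- sigmoid_table(20, -2.5, 1, logI = seq(-4, 0, 0.5))
  # corrupt the bright end; excluding it must restore the fit
  df$response_mV[df$log10_intensity > -1] <- 19
  fit <- fit_intensity_response(df, exclude = c(-1 + 1e-9, Inf))
  expect_equal(fit$logR, -2.5, tolerance = 1e-6)
})

test_that("reverse transformation matches a bisection inversion", {
  fit <- fit_intensity_response(sigmoid_table(18, -2.2, 0.9))
  v <- c(1, 3, 6, 9, 12, 15)
  s <- response_to_sensitivity(v, fit, normalize = FALSE)
  oracle <- vapply(v, oracle_invert_sigmoid, numeric(1),
                   V0 = fit$V0, logR = fit$logR, n = fit$n)
  expect_equal(s, oracle, tolerance = 1e-9)
})

test_that("reverse transformation honours its boundary behaviour", {
  fit <- fit_intensity_response(sigmoid_table(20, -2.5, 1))
  # half-maximal response maps to exactly the half-max intensity R
  expect_equal(response_to_sensitivity(10, fit, normalize = FALSE),
               10^-2.5, tolerance = 1e-9)
  # vanishing response maps to zero sensitivity
  expect_equal(response_to_sensitivity(0, fit, normalize = FALSE), 0)
  # saturated responses are excluded with a warning
  expect_warning(s <- response_to_sensitivity(c(10, 19.9), fit),
                 "saturation")
  expect_true(is.na(s[2]))
})

test_that("round trip response -> sensitivity recovers relative intensity", {
  fit <- fit_intensity_response(sigmoid_table(22, -2.8, 1.1))
  logI <- seq(-4, -1.5, by = 0.25)
  I <- 10^logI
  v <- 22 * I^1.1 / (I^1.1 + (10^-2.8)^1.1)
  s <- response_to_sensitivity(v, fit, normalize = TRUE)
  expect_equal(s, I / max(I), tolerance = 1e-9)
})

test_that("opponent decomposition isolates the two units", {
  cell <- opponent_cell_spec(g_lambda_max = 520, r_lambda_max = 620,
                             r_fwhm = 45, noise_sd = 0)
  mono <- monochromator_wavelengths()
  runs <- list(
    red = generate_run(cell, stimulus_protocol(
      "spectral_series", wavelengths = mono, adaptation = "red_650",
      log10_intensity = -1), 1),
    green = generate_run(cell, stimulus_protocol(
      "spectral_series", wavelengths = mono, adaptation = "green_500",
      log10_intensity = -1), 2),
    idark = generate_run(cell, stimulus_protocol(
      "intensity_series", wavelengths = 525), 3),
    ihyper = generate_run(cell, stimulus_protocol(
      "intensity_series", wavelengths = 625, adaptation = "green_500"), 4))
  depol <- fit_intensity_response(runs$idark, exclude = c(-1 + 1e-9, Inf))
  hyper <- fit_intensity_response(runs$ihyper)
  dec <- decompose_opponent(runs$red, runs$green, depol, hyper)
  expect_true(dec$R_minus_present)
  expect_equal(max(dec$G_plus, na.rm = TRUE), 1)
  expect_true(all(dec$R_minus <= 0))
  expect_equal(max(abs(dec$combined), na.rm = TRUE), 1)
  # component peaks recover the generative values within the grid
  gs <- spectrum_summary(mono, dec$G_plus)
  rs <- spectrum_summary(mono, dec$R_minus)
  expect_lt(abs(gs$lambda_max_nm - 520), 5)
  expect_lt(abs(rs$lambda_max_nm - 620), 5)
  # gain invariance: scaling amplitudes and V0 jointly changes nothing
  scale_run <- function(run, c) { run$response_mV <- run$response_mV * c; run }
  depol2 <- depol; depol2$V0 <- depol$V0 * 3
  hyper2 <- hyper; hyper2$V0 <- hyper$V0 * 3
  dec2 <- decompose_opponent(scale_run(runs$red, 3), scale_run(runs$green, 3),
                             depol2, hyper2)
  expect_equal(dec2$G_plus, dec$G_plus, tolerance = 1e-9)
  expect_equal(dec2$R_minus, dec$R_minus, tolerance = 1e-9)
})

test_that("a green-adapted run without hyperpolarization yields a null R-", {
  cell <- opponent_cell_spec(g_lambda_max = 530, r_lambda_max = NA,
                             r_fwhm = NA, noise_sd = 0)
  mono <- monochromator_wavelengths()
  red <- generate_run(cell, stimulus_protocol(
    "spectral_series", wavelengths = mono, adaptation = "red_650",
    log10_intensity = -1), 1)
  green <- generate_run(cell, stimulus_protocol(
    "spectral_series", wavelengths = mono, adaptation = "green_500",
    log10_intensity = -1), 2)
  depol <- fit_intensity_response(generate_run(cell, stimulus_protocol(
    "intensity_series", wavelengths = 525), 3), exclude = c(-1 + 1e-9, Inf))
  hyper <- fit_intensity_response(sigmoid_table(-10, -1.2, 1))
  dec <- decompose_opponent(red, green, depol, hyper)
  expect_false(dec$R_minus_present)
  expect_true(all(dec$R_minus == 0))
})

test_that("polarization fit recovers angle and ratio", {
  cell <- opponent_cell_spec(g_lambda_max = 520, r_lambda_max = 620,
                             r_fwhm = 45, noise_sd = 0,
                             ps_r = list(Phi = 96, Psi = 2.0))
  hyper <- fit_intensity_response(generate_run(cell, stimulus_protocol(
    "intensity_series", wavelengths = 625, adaptation = "green_500"), 1))
  run <- generate_run(cell, stimulus_protocol(
    "polarizer_rotation", wavelengths = 625, adaptation = "green_500",
    log10_intensity = -1), 2)
  ps <- fit_polarization(run, hyper)
  expect_false(ps$degenerate)
  expect_lt(abs(ps$Phi - 96), 3)
  expect_lt(abs(ps$Psi - 2.0), 0.1)
  # invariance to adding full turns and to reversing rotation direction
  run2 <- run; run2$polarizer_deg <- (run$polarizer_deg + 360) %% 360
  ps2 <- fit_polarization(run2, hyper)
  expect_equal(ps2$Phi, ps$Phi, tolerance = 1e-9)
  run3 <- run[rev(seq_len(nrow(run))), ]
  ps3 <- fit_polarization(run3, hyper)
  expect_equal(ps3$Phi, ps$Phi, tolerance = 1e-9)
  expect_error(fit_polarization(run[1:5, ], hyper), "rotation")
})

test_that("polarization angles are reported modulo 180 degrees", {
  cell <- opponent_cell_spec(g_lambda_max = 520, r_lambda_max = 620,
                             r_fwhm = 45, noise_sd = 0,
                             ps_r = list(Phi = 10, Psi = 2.0))
  hyper <- fit_intensity_response(generate_run(cell, stimulus_protocol(
    "intensity_series", wavelengths = 625, adaptation = "green_500"), 1))
  run <- generate_run(cell, stimulus_protocol(
    "polarizer_rotation", wavelengths = 625, adaptation = "green_500",
    log10_intensity = -1), 2)
  ps <- fit_polarization(run, hyper)
  expect_gte(ps$Phi, 0); expect_lt(ps$Phi, 180)
  expect_equal(ps$Phi, 10, tolerance = 1)
})

test_that("a flat polarization response is flagged degenerate, not fabricated", {
  cell <- opponent_cell_spec(g_lambda_max = 520, r_lambda_max = 620,
                             r_fwhm = 45, noise_sd = 0,
                             ps_g = list(Phi = 103, Psi = 1.0),
                             ps_r = list(Phi = 96, Psi = 1.0))
  hyper <- fit_intensity_response(generate_run(cell, stimulus_protocol(
    "intensity_series", wavelengths = 625, adaptation = "green_500"), 1))
  run <- generate_run(cell, stimulus_protocol(
    "polarizer_rotation", wavelengths = 625, adaptation = "green_500",
    log10_intensity = -1), 2)
  ps <- fit_polarization(run, hyper)
  expect_true(ps$degenerate)
  expect_equal(ps$Psi, 1)
  expect_true(is.na(ps$Phi))
})

test_that("spectral summaries report peak, FWHM and dual peaks", {
  lam <- seq(400, 700, 5)
  # Gaussian with sigma chosen so FWHM = 50 nm
  g <- exp(-((lam - 620)^2) / (2 * 21.23^2))
  sm <- spectrum_summary(lam, g)
  expect_equal(sm$lambda_max_nm, 620, tolerance = 0.5)
  expect_equal(sm$fwhm_nm, 50, tolerance = 0.5)
  expect_true(is.na(sm$secondary_peak_nm))
  # dual-peaked spectrum: both maxima reported
  g2 <- exp(-((lam - 465)^2) / (2 * 18^2)) + 0.9 * exp(-((lam - 545)^2) / (2 * 18^2))
  sm2 <- spectrum_summary(lam, g2)
  expect_equal(sm2$lambda_max_nm, 465, tolerance = 2)
  expect_equal(sm2$secondary_peak_nm, 545, tolerance = 5)
  # opponent (negative) spectra are summarized on their magnitude
  sm3 <- spectrum_summary(lam, -g)
  expect_equal(sm3$fwhm_nm, 50, tolerance = 0.5)
  # monotone spectrum: edge warning (plus the one-sided FWHM warning)
  w <- capture_warnings(spectrum_summary(lam, lam / 700))
  expect_true(any(grepl("edge", w)))
  expect_true(any(grepl("one-sided", w)))
})

test_that("cells are summarized as mean and standard error", {
  fits <- list(list(Phi = 100), list(Phi = 104), list(Phi = 96))
  s <- summarize_cells(fits, "Phi")
  expect_equal(s$mean, 100)
  expect_equal(s$se, stats::sd(c(100, 104, 96)) / sqrt(3))
  expect_equal(s$n, 3)
})
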