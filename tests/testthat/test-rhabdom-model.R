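test_that("absorption coefficients follow kappa = alpha * rho * f", {
  cfg <- coarse_config()
  nz <- length(cfg$z)
  # dark-adapted, full cross-section receptor: kappa_R = alpha_R, kappa_M = 0
  rho1 <- matrix(0, nz, 9); rho1[, 3] <- 1
  cfg1 <- coarse_config(rho = rho1)
  kap <- absorption_coefficients(matrix(1, nz, 9), cfg1)
  expect_equal(unique(kap$kappa_R[, 3]), 6)
  expect_true(all(kap$kappa_M == 0))
  # zero cross-section receptors have zero kappa
  expect_true(all(kap$kappa_R[, -3] == 0))
  # f_R + f_M = 1 implies kappa_R/alpha_R + kappa_M/alpha_M = rho
  f <- matrix(stats::runif(nz * 9), nz, 9)
  kap2 <- absorption_coefficients(f, cfg)
  expect_equal(kap2$kappa_R / 6 + kap2$kappa_M / 7.5, cfg$rho,
               tolerance = 1e-12)
  expect_error(absorption_coefficients(matrix(1, 3, 9), cfg), "dimension")
})

test_that("a lossless cavity transmits and reflects the full source", {
  nz <- 45
  rho0 <- matrix(0, nz, 9)
  cfg <- coarse_config(rho = rho0,
                       screening = list(lambda_half = 600, steepness = 0.05,
                                        alpha_S = 0, z_range = c(230, 420)))
  flux <- propagate_flux(matrix(1, nz, 9), cfg)
  expect_equal(flux$I_down[nz, ], cfg$source, tolerance = 1e-12)
  expect_equal(flux$I_up[1, ], cfg$source, tolerance = 1e-12)
  expect_equal(flux$I_exit, cfg$source, tolerance = 1e-12)
})

test_that("uniform absorber reproduces the Beer-Lambert closed form", {
  nz <- 90
  rho1 <- matrix(0, nz, 9); rho1[, 3] <- 1
  cfg <- rhabdom_config(rho = rho1,
                        screening = list(lambda_half = 600, steepness = 0.05,
                                         alpha_S = 0, z_range = c(230, 420)))
  flux <- propagate_flux(matrix(1, nz, 9), cfg)
  c_lambda <- 6 * cfg$gamma_R[, 3]          # 1/mm, constant over depth
  expect_equal(flux$I_tapetum, cfg$source * exp(-c_lambda * 0.450),
               tolerance = 1e-12)
})

test_that("photons are conserved: absorbed + exiting = source", {
  eq <- solve_equilibrium_fixed_point(rhabdom_config())
  rel <- abs(eq$flux$absorbed + eq$flux$I_exit - eq$config$source) /
    eq$config$source
  expect_lt(max(rel), 1e-6)
})

test_that("negative source flux is rejected", {
  src <- rep(1, length(wavelength_grid(300, 700, 2)$lambda))
  src[5] <- -1
  expect_error(coarse_config(source = src), "non-negative")
})

test_that("photochemical rates match a fine-grid quadrature", {
  cfg <- rhabdom_config()
  f <- matrix(0.6, length(cfg$z), 9)
  flux <- propagate_flux(f, cfg)
  kap <- absorption_coefficients(f, cfg)
  k <- photochemical_rates(kap, flux, cfg)
  for (idx in list(c(1, 3), c(40, 5), c(85, 9))) {
    z <- idx[1]; r <- idx[2]
    ref <- oracle_quadrature(cfg$grid$lambda,
                             kap$kappa_R[z, r] * cfg$gamma_R[, r] *
                               flux$I_actinic[z, ])
    if (ref > 0) expect_equal(unname(k$k_R[z, r]), ref, tolerance = 1e-3)
    else expect_equal(unname(k$k_R[z, r]), 0)
  }
  # no light, no conversion
  dark <- flux; dark$I_actinic[] <- 0
  k0 <- photochemical_rates(kap, dark, cfg)
  expect_true(all(k0$k_R == 0) && all(k0$k_M == 0))
})

test_that("monochromatic rates are proportional to kappa * Gamma at the line", {
  g <- wavelength_grid(500, 530, 1)
  src <- rep(0, length(g$lambda)); src[g$lambda == 515] <- 1
  cfg <- rhabdom_config(grid = g, source = src,
                        screening = list(lambda_half = 520, steepness = 0.05,
                                         alpha_S = 0, z_range = c(230, 420)))
  nz <- length(cfg$z)
  f <- matrix(1, nz, 9)
  flux <- propagate_flux(f, cfg)
  kap <- absorption_coefficients(f, cfg)
  k <- photochemical_rates(kap, flux, cfg)
  line <- g$lambda == 515
  expected <- kap$kappa_R[1, ] * cfg$gamma_R[line, ] * flux$I_actinic[1, line]
  expect_equal(k$k_R[1, ], expected, tolerance = 1e-12)
})

test_that("single-slab monochromatic equilibrium matches the closed form", {
  g <- wavelength_grid(500, 530, 1)
  src <- rep(0, length(g$lambda)); src[g$lambda == 515] <- 1
  rho1 <- matrix(0, 1, 9); rho1[1, 3] <- 1
  cfg <- rhabdom_config(grid = g, length_um = 5, dz_um = 5, rho = rho1,
                        screening = list(lambda_half = 520, steepness = 0.05,
                                         alpha_S = 0, z_range = c(0, 5)),
                        source = src)
  eq <- solve_equilibrium_fixed_point(cfg, tol = 1e-10)
  gr <- cfg$gamma_R[g$lambda == 515, 3]
  gm <- cfg$gamma_M[g$lambda == 515, 3]
  expect_equal(eq$f_R[1, 3], 7.5 * gm / (6 * gr + 7.5 * gm),
               tolerance = 1e-9)
  # and it is independent of source intensity
  cfg10 <- rhabdom_config(grid = g, length_um = 5, dz_um = 5, rho = rho1,
                          screening = cfg$screening, source = src * 10)
  eq10 <- solve_equilibrium_fixed_point(cfg10, tol = 1e-10)
  expect_equal(eq10$f_R[1, 3], eq$f_R[1, 3], tolerance = 1e-9)
})

test_that("equilibrium state is a valid pigment fraction field", {
  eq <- solve_equilibrium_fixed_point(rhabdom_config())
  expect_true(all(eq$f_R >= 0 & eq$f_R <= 1))
  expect_lte(eq$iterations, 10)
  expect_error(solve_equilibrium_fixed_point(rhabdom_config(), tol = -1),
               "tol")
})

test_that("equilibrium is invariant to source intensity scaling", {
  cfg1 <- coarse_config()
  s <- cfg1$screening
  cfg2 <- coarse_config(source = rep(37, length(cfg1$grid$lambda)),
                        screening = s)
  e1 <- solve_equilibrium_fixed_point(cfg1)
  e2 <- solve_equilibrium_fixed_point(cfg2)
  expect_equal(e1$f_R, e2$f_R, tolerance = 1e-9)
})

test_that("receptor permutation does not change per-receptor outputs", {
  cfg <- coarse_config()
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 8)
  cfgp <- coarse_config(rho = cfg$rho[, perm],
                        pigments = {
                          p <- default_pigments()[perm, ]
                          p$receptor <- paste0("R", 1:9); p
                        })
  e <- solve_equilibrium_fixed_point(cfg)
  ep <- solve_equilibrium_fixed_point(cfgp)
  expect_equal(ep$f_R, e$f_R[, perm], tolerance = 1e-9)
  s <- effective_sensitivity(e); sp <- effective_sensitivity(ep)
  expect_equal(unname(sp$Q), unname(s$Q[perm, ]), tolerance = 1e-9)
})

test_that("halving the slab thickness changes sensitivities by < 1%", {
  e5 <- solve_equilibrium_fixed_point(rhabdom_config(dz_um = 5))
  e25 <- solve_equilibrium_fixed_point(rhabdom_config(dz_um = 2.5))
  s5 <- effective_sensitivity(e5)
  s25 <- effective_sensitivity(e25)
  expect_lt(max(abs(s5$Q_norm - s25$Q_norm)), 0.01)
})

test_that("ODE path: dark state without light, dark start, fixed-point agreement", {
  # no light: state stays dark-adapted
  g <- wavelength_grid(300, 700, 2)
  dark_cfg <- coarse_config(source = rep(0, length(g$lambda)))
  od0 <- solve_equilibrium_ode(dark_cfg, duration = 10, n_times = 5)
  expect_true(all(od0$f_R == 1))
  # trajectory starts from f_R = 1 everywhere
  expect_true(all(od0$trajectory[1, ] == 1))
  # long-time ODE state matches the fixed point on the default config
  cfg <- rhabdom_config()
  fp <- solve_equilibrium_fixed_point(cfg)
  od <- solve_equilibrium_ode(cfg, duration = 400, n_times = 9)
  expect_lt(max(abs(od$f_R - fp$f_R)[cfg$rho > 0]), 0.01)
  expect_error(solve_equilibrium_ode(cfg, duration = -1), "duration")
})

test_that("effective sensitivity is an absorbed-photon spectrum", {
  eq <- solve_equilibrium_fixed_point(rhabdom_config())
  sens <- effective_sensitivity(eq)
  expect_true(all(sens$Q >= 0))
  expect_equal(unname(apply(sens$Q_norm, 1, max)), rep(1, 9))
  # receptors with zero cross-section catch nothing
  nz <- length(eq$config$z)
  rho0 <- eq$config$rho; rho0[, 1] <- 0
  cfg0 <- rhabdom_config(rho = rho0)
  eq0 <- solve_equilibrium_fixed_point(cfg0)
  expect_true(all(effective_sensitivity(eq0)$Q["R1", ] == 0))
})

test_that("distal and basal partial catches show the red shift of R3-8", {
  eq <- solve_equilibrium_fixed_point(rhabdom_config())
  lam <- eq$config$grid$lambda
  distal <- effective_sensitivity(eq, c(0, 230))
  basal <- effective_sensitivity(eq, c(350, 450))
  peak_d <- lam[which.max(distal$Q["R3", ])]
  peak_b <- lam[which.max(basal$Q["R3", ])]
  expect_gt(peak_b, 600)
  expect_gt(peak_b, peak_d)
  # the local catch spectrum at the very top of the rhabdom peaks at the
  # unfiltered template maximum
  expect_equal(depth_resolved_peak(eq, "R3")$peak_nm[1], 545, tolerance = 3)
})

test_that("screening pigment red-shifts R9 and deepens its sensitivity deficit", {
  cfg_red <- rhabdom_config()
  s <- cfg_red$screening; s$alpha_S <- 0
  cfg_nored <- rhabdom_config(screening = s)
  eq_red <- solve_equilibrium_fixed_point(cfg_red)
  eq_nored <- solve_equilibrium_fixed_point(cfg_nored)
  lam <- cfg_red$grid$lambda
  sens_red <- effective_sensitivity(eq_red)
  sens_nored <- effective_sensitivity(eq_nored)
  expect_gt(lam[which.max(sens_red$Q["R9", ])],
            lam[which.max(sens_nored$Q["R9", ])])
  expect_gt(abs(sensitivity_log_ratio(sens_red, "R1", "R9")),
            abs(sensitivity_log_ratio(sens_nored, "R1", "R9")))
})

test_that("sensitivity log ratio behaves as a log ratio", {
  eq <- solve_equilibrium_fixed_point(coarse_config())
  sens <- effective_sensitivity(eq)
  expect_equal(sensitivity_log_ratio(sens, "R3", "R3"), 0)
  expect_equal(sensitivity_log_ratio(sens, "R1", "R9"),
               -sensitivity_log_ratio(sens, "R9", "R1"))
  expect_error(sensitivity_log_ratio(sens, "R1", "R17"), "receptor")
})

test_that("eyeshine spectrum reflects the red ommatidium", {
  cfg <- rhabdom_config()
  eq <- solve_equilibrium_fixed_point(cfg)
  es <- eyeshine_spectrum(eq$flux, cfg$grid)
  expect_true(all(es$reflectance >= 0 & es$reflectance <= 1))
  expect_gt(es$reflectance[es$wavelength_nm == 650],
            es$reflectance[es$wavelength_nm == 500])
  # eyeshine in the green decreases monotonically with screening density
  r500 <- sapply(c(0, 10, 30), function(aS) {
    s <- cfg$screening; s$alpha_S <- aS
    e <- solve_equilibrium_fixed_point(rhabdom_config(screening = s))
    eyeshine_spectrum(e$flux, cfg$grid)$reflectance[cfg$grid$lambda == 500]
  })
  expect_true(all(diff(r500) <= 0))
})

test_that("configs round-trip through the structured-text format", {
  cfg <- rhabdom_config()
  path <- withr::local_tempfile(fileext = ".cfg")
  write_rhabdom_config(cfg, path)
  back <- read_rhabdom_config(path)
  expect_equal(back$rho, cfg$rho)
  expect_equal(back$screening, cfg$screening)
  expect_equal(back$pigments$lmax_R, cfg$pigments$lmax_R)
  # shipped reference configs load and differ only in alpha_S
  red <- read_rhabdom_config(default_config_path("red"))
  nored <- read_rhabdom_config(default_config_path("nored"))
  expect_equal(red$screening$alpha_S, 35)
  expect_equal(nored$screening$alpha_S, 0)
})
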