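# Independent oracles, written directly from first principles and kept
# separate from the package implementation.

# Visual pigment A1 nomogram, transcribed independently: absorbance as a
# function of x = lambda_max / lambda for the alpha band, plus the
# Gaussian beta band whose position/width scale linearly with lambda_max.
oracle_a1_nomogram <- function(lambda, lmax, beta = TRUE) {
  x <- lmax / lambda
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  S <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  if (beta) {
    A_beta <- 0.26
    lmb <- 189 + 0.315 * lmax
    bb <- -40.5 + 0.195 * lmax
    S <- S + A_beta * exp(-((lambda - lmb) / bb)^2)
  }
  S
}

# Invert a sigmoid V = V0 I^n / (I^n + R^n) for I by bisection on log10 I.
oracle_invert_sigmoid <- function(v, V0, logR, n, lo = -12, hi = 8,
                                  tol = 1e-12) {
  f <- function(logI) {
    I <- 10^logI
    V0 * I^n / (I^n + (10^logR)^n) - v
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  10^((lo + hi) / 2)
}

# Fine-grid trapezoid quadrature of kappa * Gamma * I over wavelength,
# with linear interpolation onto a 0.1 nm grid.
oracle_quadrature <- function(lambda, integrand, step = 0.1) {
  fine <- seq(min(lambda), max(lambda), by = step)
  y <- stats::approx(lambda, integrand, xout = fine)$y
  sum((y[-1] + y[-length(y)]) / 2) * step
}

# Shared small fixtures -------------------------------------------------

# A fast reduced-resolution model configuration (2 nm / 10 um) for tests
# that only need qualitative structure.
coarse_config <- function(...) {
  rhabdom_config(grid = wavelength_grid(300, 700, 2), dz_um = 10, ...)
}

# Noiseless sigmoid intensity-response table.
sigmoid_table <- function(V0, logR, n, logI = seq(-4.5, -1, by = 0.5)) {
  I <- 10^logI
  data.frame(log10_intensity = logI,
             response_mV = V0 * I^n / (I^n + (10^logR)^n))
}
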