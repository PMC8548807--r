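#' Default rhabdom cross-section profile
#'
#' Area fraction rho of each photoreceptor R1-R9 per depth slab. The shipped
#' profile is a documented stand-in for nymphalid morphology: R1&2 each
#' occupy 15% of the cross-section distally and vacate at 250 um; R3&4 each
#' hold 20% distally, rising to 25% where R1&2 vacate; R5-8 share the
#' remainder equally; the basal R9 fills the whole cross-section in its
#' 400-450 um window, where all others are absent.
#'
#' @param z Slab center depths, um.
#' @param r12_frac,r12_zmax R1/R2 fraction and the depth where they vacate.
#' @param r34_frac_distal,r34_frac_mid R3/R4 fractions before/after `r12_zmax`.
#' @param r9_window Depth window (um) of the basal R9.
#' @return Matrix `length(z)` x 9, columns `R1`..`R9`; rows sum to <= 1.
#' @export
default_rho_profile <- function(z,
                                r12_frac = 0.15, r12_zmax = 250,
                                r34_frac_distal = 0.20, r34_frac_mid = 0.25,
                                r9_window = c(400, 450)) {
  nz <- length(z)
  rho <- matrix(0, nz, 9, dimnames = list(NULL, paste0("R", 1:9)))
  distal <- z < r12_zmax
  mid <- !distal & z < r9_window[1]
  basal <- z >= r9_window[1] & z <= r9_window[2]
  rho[distal, 1:2] <- r12_frac
  rho[distal, 3:4] <- r34_frac_distal
  rho[mid, 3:4] <- r34_frac_mid
  # R5-8 share whatever R1-4 leave free
  rho[!basal, 5:8] <- (1 - rowSums(rho[, 1:4, drop = FALSE]))[!basal] / 4
  rho[basal, ] <- 0
  rho[basal, 9] <- 1
  rho
}

#' Perturb a cross-section profile
#'
#' Multiplies each receptor column by an independent factor drawn uniformly
#' from `[1 - delta, 1 + delta]`, then rescales any slab whose total would
#' exceed 1. Used to check robustness of model outputs to the uncertainty in
#' the morphological profile.
#'
#' @param rho Profile matrix (slabs x receptors).
#' @param delta Relative perturbation magnitude (default 0.1).
#' @param seed Integer seed.
#' @return Perturbed profile matrix.
#' @export
perturb_rho_profile <- function(rho, delta = 0.1, seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  fac <- withr_seed(stats::runif(ncol(rho), 1 - delta, 1 + delta))
  out <- sweep(rho, 2, fac, `*`)
  tot <- rowSums(out)
  over <- tot > 1
  if (any(over)) out[over, ] <- out[over, ] / tot[over]
  out
}

#' Rhabdom model configuration
#'
#' Full parametrization of the longitudinal light-transport model: a 450 um
#' rhabdom discretized into 5 um slabs, nine photoreceptors with assigned
#' rhodopsin/metarhodopsin isoform pairs, a non-bleaching red screening
#' pigment apposed to the rhabdom between 230 and 420 um, a fully reflecting
#' tapetum at the base, and an isoquantal white source at the cornea.
#' R1 and R2 carry the R515/M495 isoform pair; R3-R9 carry the main
#' R545/M505 pair. Peak absorption coefficients are 6 (rhodopsin) and
#' 7.5 (metarhodopsin) per mm.
#'
#' @param grid A [wavelength_grid()].
#' @param length_um Rhabdom length, um.
#' @param dz_um Slab thickness, um; must divide `length_um`.
#' @param pigments Data frame with one row per receptor: `lmax_R`, `lmax_M`
#'   (nm), `alpha_R`, `alpha_M` (1/mm). Default: R515/M495 for R1/2,
#'   R545/M505 for R3-9, alpha_R = 6, alpha_M = 7.5.
#' @param rho Cross-section profile matrix (slabs x 9); default
#'   [default_rho_profile()].
#' @param screening List: `lambda_half` (nm), `steepness` (1/nm), `alpha_S`
#'   (1/mm, peak absorption of the screening pigment; 0 disables it),
#'   `z_range` (um). The default `alpha_S` is calibrated so the modelled
#'   eyeshine half-rise sits near 600 nm.
#' @param tapetum_reflectance Scalar reflectance at the rhabdom base
#'   (default 1, full reflection).
#' @param source Corneal downwelling photon flux per wavelength; default
#'   isoquantal (1 at every wavelength). The stimulator's absolute cap,
#'   1.5e15 photons/cm^2/s, is kept as metadata only.
#' @param beta_band Include the UV beta band in visual pigment templates.
#' @return Object of class `rhabdom_config`.
#' @export
rhabdom_config <- function(grid = wavelength_grid(),
                           length_um = 450, dz_um = 5,
                           pigments = default_pigments(),
                           rho = NULL,
                           screening = list(lambda_half = 600,
                                            steepness = 0.05,
                                            alpha_S = 35,
                                            z_range = c(230, 420)),
                           tapetum_reflectance = 1,
                           source = NULL,
                           beta_band = TRUE) {
  if (dz_um <= 0 || abs(length_um / dz_um - round(length_um / dz_um)) > 1e-9)
    stop("dz_um must be positive and divide length_um")
  z <- seq(dz_um / 2, length_um - dz_um / 2, by = dz_um)
  if (is.null(rho)) rho <- default_rho_profile(z)
  if (nrow(rho) != length(z) || ncol(rho) != 9)
    stop("rho must be a (slabs x 9) matrix matching the depth grid")
  if (any(rho < 0)) stop("rho must be non-negative")
  if (any(rowSums(rho) > 1 + 1e-9)) stop("rho rows must sum to <= 1")
  if (is.null(source)) source <- rep(1, length(grid$lambda))
  if (length(source) != length(grid$lambda))
    stop("source must be sampled on the wavelength grid")
  if (any(source < 0)) stop("source flux must be non-negative")
  nl <- length(grid$lambda)
  gam_R <- gam_M <- matrix(0, nl, 9)
  for (r in 1:9) {
    gam_R[, r] <- rhodopsin_template(pigments$lmax_R[r], grid, beta_band)$values
    gam_M[, r] <- rhodopsin_template(pigments$lmax_M[r], grid, beta_band)$values
  }
  screen_tpl <- screening_template(screening$lambda_half, screening$steepness, grid)
  structure(
    list(grid = grid, length_um = length_um, dz_um = dz_um, z = z,
         pigments = pigments, rho = rho, screening = screening,
         tapetum_reflectance = tapetum_reflectance, source = source,
         beta_band = beta_band,
         gamma_R = gam_R, gamma_M = gam_M,
         kappa_S = screening$alpha_S * screen_tpl$values,
         screen_gate = as.numeric(z >= screening$z_range[1] &
                                    z <= screening$z_range[2]),
         source_cap_photons_cm2_s = 1.5e15),
    class = "rhabdom_config"
  )
}

#' @rdname rhabdom_config
#' @export
default_pigments <- function() {
  data.frame(
    receptor = paste0("R", 1:9),
    lmax_R = c(515, 515, rep(545, 7)),
    lmax_M = c(495, 495, rep(505, 7)),
    alpha_R = 6, alpha_M = 7.5
  )
}

#' @export
print.rhabdom_config <- function(x, ...) {
  cat(sprintf("rhabdom config: %g um / %g um slabs, lambda %g-%g nm\n",
              x$length_um, x$dz_um, x$grid$start, x$grid$stop))
  cat(sprintf("  screening pigment alpha_S = %g /mm over %g-%g um\n",
              x$screening$alpha_S, x$screening$z_range[1], x$screening$z_range[2]))
  invisible(x)
}

#' Effective absorption coefficients
#'
#' kappa_zrp = alpha_p * rho_zr * f_zp for both isoforms of every receptor
#' in every slab, in 1/mm. The red screening pigment enters light transport
#' as a separate depth-gated, non-bleaching term (see
#' [propagate_flux()]); its state never changes.
#'
#' @param f_R Rhodopsin fraction matrix (slabs x 9); the metarhodopsin
#'   fraction is `1 - f_R`.
#' @param config A [rhabdom_config()].
#' @return List with matrices `kappa_R` and `kappa_M` (slabs x 9), 1/mm.
#' @export
absorption_coefficients <- function(f_R, config) {
  if (!all(dim(f_R) == dim(config$rho)))
    stop("f_R and rho must share the (slab x receptor) dimensions")
  if (any(f_R < -1e-12 | f_R > 1 + 1e-12))
    stop("f_R must lie in [0, 1]")
  aR <- matrix(config$pigments$alpha_R, nrow(f_R), 9, byrow = TRUE)
  aM <- matrix(config$pigments$alpha_M, nrow(f_R), 9, byrow = TRUE)
  list(kappa_R = aR * config$rho * f_R,
       kappa_M = aM * config$rho * (1 - f_R))
}

#' Propagate light through the rhabdom
#'
#' Beer-Lambert transport slab by slab: the downwelling flux is attenuated
#' by all visual pigments plus the screening pigment, reflected at the
#' tapetum, and attenuated again on the way up. The bidirectional (actinic)
#' flux per slab is the sum of the mid-slab downwelling and upwelling
#' fluxes. Photons are conserved exactly: per-slab absorbed amounts are
#' computed as entering minus exiting flux for both passes.
#'
#' @param f_R Rhodopsin fraction matrix (slabs x 9).
#' @param config A [rhabdom_config()].
#' @return Object of class `flux_field`: list with matrices (slabs x
#'   wavelengths) `I_down` (flux entering each slab from above), `I_up`
#'   (entering from below), `I_actinic`, the attenuation `c_total` (1/mm),
#'   vectors `I_tapetum`, `I_exit` (eyeshine flux leaving the distal face),
#'   `absorbed` (total absorbed per wavelength), and the config's `source`.
#' @export
propagate_flux <- function(f_R, config) {
  kap <- absorption_coefficients(f_R, config)
  nz <- length(config$z); nl <- length(config$grid$lambda)
  # total attenuation per slab and wavelength, 1/mm
  c_total <- kap$kappa_R %*% t(config$gamma_R) +
    kap$kappa_M %*% t(config$gamma_M) +
    config$screen_gate %o% config$kappa_S
  dz_mm <- config$dz_um / 1000
  Tr <- exp(-dz_mm * c_total)          # slab transmittance
  sq <- sqrt(Tr)                       # half-slab transmittance
  I_down <- matrix(0, nz, nl)
  I_down[1, ] <- config$source
  for (i in seq_len(nz - 1)) I_down[i + 1, ] <- I_down[i, ] * Tr[i, ]
  I_tapetum <- I_down[nz, ] * Tr[nz, ]
  I_up <- matrix(0, nz, nl)
  I_up[nz, ] <- config$tapetum_reflectance * I_tapetum
  if (nz > 1)
    for (i in seq(nz - 1, 1)) I_up[i, ] <- I_up[i + 1, ] * Tr[i + 1, ]
  I_exit <- I_up[1, ] * Tr[1, ]
  absorbed <- colSums(I_down * (1 - Tr)) + colSums(I_up * (1 - Tr))
  structure(
    list(I_down = I_down, I_up = I_up,
         I_actinic = I_down * sq + I_up * sq,
         c_total = c_total, Tr = Tr,
         I_tapetum = I_tapetum, I_exit = I_exit,
         absorbed = absorbed, source = config$source),
    class = "flux_field"
  )
}

#' Photochemical conversion rates
#'
#' Absorbed-photon rates per slab, receptor and isoform:
#' k_zrp = integral over wavelength of kappa_zrp * Gamma_rp * I_z, by the
#' trapezoid rule on the wavelength grid.
#'
#' @param kappa Output of [absorption_coefficients()].
#' @param flux A `flux_field` from [propagate_flux()].
#' @param config A [rhabdom_config()].
#' @return List with matrices `k_R`, `k_M` (slabs x 9), non-negative.
#' @export
photochemical_rates <- function(kappa, flux, config) {
  lam <- config$grid$lambda
  # trapezoid weights on the (regular) grid
  w <- rep(config$grid$step, length(lam))
  w[c(1, length(lam))] <- config$grid$step / 2
  IW <- flux$I_actinic * matrix(w, nrow(flux$I_actinic), length(lam), byrow = TRUE)
  list(k_R = kappa$kappa_R * (IW %*% config$gamma_R),
       k_M = kappa$kappa_M * (IW %*% config$gamma_M))
}

# Per-molecule conversion rates (f and rho divided out): the quantities
# entering the photoequilibrium f_inf = k_M / (k_R + k_M) and the master
# equation df_R = k_M (1 - f_R) - k_R f_R.
molecular_rates <- function(flux, config) {
  unit <- list(kappa_R = matrix(rep(config$pigments$alpha_R, each = length(config$z)),
                                length(config$z), 9),
               kappa_M = matrix(rep(config$pigments$alpha_M, each = length(config$z)),
                                length(config$z), 9))
  photochemical_rates(unit, flux, config)
}

#' Photoequilibrium by fixed-point iteration
#'
#' Iterates flux propagation, per-molecule conversion rates and the
#' equilibrium condition f_R = k_M / (k_R + k_M) from the dark-adapted
#' state (f_R = 1) until the largest change in f_R falls below `tol`.
#' Because the rhodopsin/metarhodopsin ratio in each slab filters the light
#' reaching deeper slabs, the equilibrium is self-consistent and typically
#' settles within 5-10 iterations.
#'
#' @param config A [rhabdom_config()].
#' @param tol Convergence tolerance on max |delta f_R| (default 1e-3).
#' @param max_iter Iteration cap (default 100).
#' @return Object of class `rhabdom_equilibrium`: list with `f_R` (slabs x
#'   9), the converged `flux`, `iterations`, `delta` (last change) and the
#'   `config`.
#' @export
solve_equilibrium_fixed_point <- function(config, tol = 1e-3, max_iter = 100) {
  if (tol <= 0) stop("tol must be > 0")
  nz <- length(config$z)
  f <- matrix(1, nz, 9)
  active <- config$rho > 0
  delta <- Inf
  for (it in seq_len(max_iter)) {
    flux <- propagate_flux(f, config)
    k <- molecular_rates(flux, config)
    tot <- k$k_R + k$k_M
    f_new <- f
    upd <- active & tot > 0
    f_new[upd] <- (k$k_M / tot)[upd]
    delta <- max(abs(f_new - f)[active])
    f <- f_new
    if (delta < tol) {
      return(structure(
        list(f_R = f, flux = propagate_flux(f, config),
             iterations = it, delta = delta, config = config),
        class = "rhabdom_equilibrium"))
    }
  }
  stop(sprintf("photoequilibrium did not converge in %d iterations (last delta = %g)",
               max_iter, delta))
}

#' @export
print.rhabdom_equilibrium <- function(x, ...) {
  z <- x$config$z
  cat(sprintf("rhabdom photoequilibrium: converged in %d iterations (last delta %.2g)\n",
              x$iterations, x$delta))
  lw <- 3:8
  cat(sprintf("  f_R (R545 receptors): %.3f distal (<230 um), %.3f basal (350-400 um)\n",
              mean(x$f_R[z < 230, lw]), mean(x$f_R[z > 350 & z < 400, lw])))
  invisible(x)
}

#' Photoequilibrium as an ODE problem
#'
#' Integrates the coupled pigment-state / light-flux system
#' df_R/dt = k_M (1 - f_R) - k_R f_R from the dark-adapted state, with the
#' flux recomputed as the state evolves. Time is in normalized units: rates
#' are scaled so the largest initial per-molecule rate equals 1 per time
#' unit (no absolute photon-to-rate constant is defined).
#'
#' @param config A [rhabdom_config()].
#' @param duration Integration end time in normalized units (default 400;
#'   basal slabs relax much more slowly than distal ones because little
#'   light reaches them).
#' @param n_times Number of saved time points.
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return Object of class `rhabdom_ode`: list with the final `f_R`, its
#'   `flux`, the `times` and a (times x states) `trajectory` matrix of
#'   f_R values for the pigment-bearing cells, plus the `config`.
#' @export
solve_equilibrium_ode <- function(config, duration = 400, n_times = 41, ...) {
  if (duration <= 0) stop("duration must be > 0")
  nz <- length(config$z)
  active <- which(config$rho > 0)
  f0 <- rep(1, length(active))
  flux0 <- propagate_flux(matrix(1, nz, 9), config)
  k0 <- molecular_rates(flux0, config)
  K0 <- max(k0$k_R[active], k0$k_M[active])
  if (K0 <= 0) K0 <- 1   # no light: state stays dark-adapted
  deriv <- function(t, y, parms) {
    f <- matrix(1, nz, 9)
    f[active] <- y
    flux <- propagate_flux(f, config)
    k <- molecular_rates(flux, config)
    df <- (k$k_M[active] * (1 - y) - k$k_R[active] * y) / K0
    list(df)
  }
  times <- seq(0, duration, length.out = n_times)
  sol <- deSolve::ode(y = f0, times = times, func = deriv, parms = NULL, ...)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (step-size failure)")
  f_end <- matrix(1, nz, 9)
  f_end[active] <- sol[nrow(sol), -1]
  structure(
    list(f_R = f_end, flux = propagate_flux(f_end, config),
         times = times, trajectory = sol[, -1, drop = FALSE],
         active = active, config = config),
    class = "rhabdom_ode"
  )
}

#' Effective spectral sensitivity
#'
#' Rhodopsin quantum catch of each receptor per unit corneal flux:
#' Q_r(lambda) = sum over slabs of I_z(lambda) * kappa_zrR *
#' Gamma_rR(lambda) * dz, i.e. the photons absorbed by the rhodopsin
#' isoform. Both raw and peak-normalized spectra are returned; a depth
#' window restricts the sum to part of the rhabdom (distal/basal partial
#' catches).
#'
#' @param eq A `rhabdom_equilibrium` or `rhabdom_ode` result (or any list
#'   with `f_R`, `flux`, `config`).
#' @param z_window Optional depth window in um, e.g. `c(0, 230)`; `NULL`
#'   uses the whole rhabdom.
#' @return Object of class `sensitivity_result`: list with `lambda`, the
#'   raw catch matrix `Q` (9 x wavelengths), peak-normalized `Q_norm`,
#'   per-receptor `peak` values and `receptor` names.
#' @export
effective_sensitivity <- function(eq, z_window = NULL) {
  config <- eq$config
  kap <- absorption_coefficients(eq$f_R, config)
  keep <- if (is.null(z_window)) rep(TRUE, length(config$z)) else
    config$z >= z_window[1] & config$z <= z_window[2]
  dz_mm <- config$dz_um / 1000
  nl <- length(config$grid$lambda)
  Q <- matrix(0, 9, nl, dimnames = list(paste0("R", 1:9), NULL))
  for (r in 1:9) {
    Q[r, ] <- colSums(eq$flux$I_actinic[keep, , drop = FALSE] *
                        kap$kappa_R[keep, r]) * config$gamma_R[, r] * dz_mm
  }
  peak <- apply(Q, 1, max)
  Q_norm <- Q / ifelse(peak > 0, peak, 1)
  structure(
    list(lambda = config$grid$lambda, Q = Q, Q_norm = Q_norm, peak = peak,
         receptor = paste0("R", 1:9), z_window = z_window),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  peaks <- x$lambda[apply(x$Q_norm, 1, which.max)]
  win <- if (is.null(x$z_window)) "whole rhabdom" else
    sprintf("%g-%g um", x$z_window[1], x$z_window[2])
  cat(sprintf("effective sensitivities (%s):\n", win))
  print(data.frame(receptor = x$receptor, peak_nm = peaks,
                   log10_rel_peak = round(log10(x$peak / max(x$peak)), 2)),
        row.names = FALSE)
  invisible(x)
}

#' Depth-resolved local catch peak
#'
#' Peak wavelength of the local rhodopsin catch spectrum
#' I_z(lambda) * Gamma_rR(lambda) in each slab where the receptor is
#' present. Complements the depth-partial sums of
#' [effective_sensitivity()]: at the very top of the rhabdom the local
#' spectrum peaks at the pigment template peak, and it shifts continuously
#' redward with depth as green light is consumed by self-screening and the
#' screening pigment.
#'
#' @param eq A `rhabdom_equilibrium` (or compatible) result.
#' @param receptor Receptor name, default `"R3"`.
#' @return Data frame with `z_um` and `peak_nm` for slabs where the
#'   receptor has nonzero cross-section.
#' @export
depth_resolved_peak <- function(eq, receptor = "R3") {
  config <- eq$config
  r <- match(receptor, paste0("R", 1:9))
  if (is.na(r)) stop("unknown receptor name")
  keep <- which(config$rho[, r] > 0)
  local <- eq$flux$I_actinic[keep, , drop = FALSE] *
    matrix(config$gamma_R[, r], length(keep), length(config$grid$lambda),
           byrow = TRUE)
  data.frame(z_um = config$z[keep],
             peak_nm = config$grid$lambda[apply(local, 1, which.max)])
}

#' Eyeshine spectrum
#'
#' Upwelling flux exiting the distal face of the rhabdom relative to the
#' corneal source: the model's prediction of the ommatidial reflectance
#' spectrum seen as eyeshine.
#'
#' @param flux A `flux_field`.
#' @param grid The matching [wavelength_grid()].
#' @return Data frame with `wavelength_nm` and `reflectance` in \[0, 1\].
#' @export
eyeshine_spectrum <- function(flux, grid) {
  data.frame(wavelength_nm = grid$lambda,
             reflectance = flux$I_exit / flux$source)
}

#' Log10 peak-sensitivity ratio between receptors
#'
#' log10 of the ratio of unnormalized peak quantum catches, the model's
#' measure of the absolute sensitivity difference between receptors (e.g.
#' the ~2 log-unit deficit of the basal R9 relative to R1).
#'
#' @param sens A `sensitivity_result`.
#' @param receptor_a,receptor_b Receptor names (`"R1"`..`"R9"`).
#' @return log10(peak_a / peak_b), a scalar.
#' @export
sensitivity_log_ratio <- function(sens, receptor_a, receptor_b) {
  pa <- sens$peak[receptor_a]; pb <- sens$peak[receptor_b]
  if (is.na(pa) || is.na(pb)) stop("unknown receptor name")
  if (pa <= 0 || pb <= 0) stop("log ratio undefined: zero peak sensitivity")
  unname(log10(pa / pb))
}
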