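#' Fit a sigmoid intensity-response function
#'
#' Least-squares fit of the hyperbolic (Naka-Rushton type) sigmoid
#' V = V0 * I^n / (I^n + R^n) to measured response amplitudes, on the
#' linear intensity scale I = 10^log10_intensity. Fitting is on voltage,
#' not log voltage, matching the additive-noise convention of intracellular
#' recording. The branch (depolarizing / hyperpolarizing) is set by the
#' response sign; hyperpolarizing series are fitted on their magnitude and
#' reported with negative V0.
#'
#' @param run An `ephys_run` (see [generate_run()]) or a data frame with
#'   columns `log10_intensity` and `response_mV`.
#' @param exclude Optional log10-intensity window `c(lo, hi)` to exclude
#'   from the fit (e.g. the brightest flashes).
#' @return Object of class `sigmoid_fit`: list with `V0` (mV, signed),
#'   `logR` (log10 intensity at half-maximal response), `n` (slope),
#'   `rmse` (mV), `branch`, and the fitted model.
#' @export
fit_intensity_response <- function(run, exclude = NULL) {
  df <- as.data.frame(run)
  if (!all(c("log10_intensity", "response_mV") %in% names(df)))
    stop("need columns 'log10_intensity' and 'response_mV'")
  if (!is.null(exclude))
    df <- df[df$log10_intensity < exclude[1] | df$log10_intensity > exclude[2], ]
  if (nrow(df) < 4)
    stop("need at least 4 intensity levels to fit the sigmoid")
  if (stats::sd(df$response_mV) == 0)
    stop("degenerate input: all responses equal, no curvature to fit")
  branch <- if (mean(df$response_mV) >= 0) "depolarizing" else "hyperpolarizing"
  sgn <- if (branch == "depolarizing") 1 else -1
  v <- sgn * df$response_mV
  I <- 10^df$log10_intensity
  # starting values: saturation from the largest response, logR from the
  # intensity nearest half of it
  v0_start <- max(v) * 1.05
  logR_start <- df$log10_intensity[which.min(abs(v - v0_start / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ V0 * I^n / (I^n + 10^(logR * n)),
      data = data.frame(v = v, I = I),
      start = list(V0 = v0_start, logR = logR_start, n = 1),
      lower = c(V0 = 1e-6, logR = -Inf, n = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("sigmoid fit did not converge: ", conditionMessage(e))
  )
  p <- stats::coef(fit)
  structure(
    list(V0 = sgn * unname(p["V0"]), logR = unname(p["logR"]),
         n = unname(p["n"]),
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         branch = branch, model = fit),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid fit (%s): V0 = %.2f mV, logR = %.3f, n = %.3f, rmse = %.3f mV\n",
              x$branch, x$V0, x$logR, x$n, x$rmse))
  invisible(x)
}

# Evaluate the fitted sigmoid at log10 intensity values.
predict_sigmoid <- function(fit, log10_intensity) {
  I <- 10^log10_intensity
  R <- 10^fit$logR
  fit$V0 * I^fit$n / (I^fit$n + R^fit$n)
}

#' Reverse-transform response amplitudes to sensitivities
#'
#' Inverts the fitted sigmoid: each response amplitude V to an isoquantal
#' flash maps to the equivalent intensity I_eq = R * (V / (V0 - V))^(1/n)
#' that would evoke it; sensitivity is proportional to 1 / I_eq at the
#' common flash intensity. Responses at or beyond 98% of saturation are
#' excluded (set to NA) with a warning, as the inversion diverges there;
#' responses of the wrong sign map to zero sensitivity.
#'
#' @param amplitudes Response amplitudes, mV, one per stimulus.
#' @param fit A `sigmoid_fit`.
#' @param normalize Scale so the largest magnitude is 1 (default `TRUE`).
#' @param signed Report hyperpolarizing sensitivities as negative
#'   (default `FALSE`: plain relative sensitivities).
#' @return Numeric vector of sensitivities (same sign convention as the
#'   branch: hyperpolarizing branches give negative values when
#'   `signed = TRUE`).
#' @export
response_to_sensitivity <- function(amplitudes, fit, normalize = TRUE,
                                    signed = FALSE) {
  sgn <- if (fit$branch == "depolarizing") 1 else -1
  v <- sgn * amplitudes
  V0 <- abs(fit$V0)
  sat <- v >= 0.98 * V0
  if (any(sat)) {
    warning(sprintf("%d response(s) at >= 98%% of saturation excluded from reverse transformation",
                    sum(sat)))
    v[sat] <- NA_real_
  }
  s <- numeric(length(v))
  pos <- !is.na(v) & v > 0
  s[is.na(v)] <- NA_real_
  # the equivalent intensity I_eq = R * (V/(V0-V))^(1/n) that the flash
  # delivered through the cell's quantum catch; with all flashes at the
  # same quantal flux the relative sensitivity is proportional to I_eq
  # (a response of V0/2 maps to exactly R; V -> 0 maps to 0)
  s[pos] <- 10^(fit$logR) * (v[pos] / (V0 - v[pos]))^(1 / fit$n)
  s[!is.finite(s)] <- NA_real_
  if (normalize) {
    m <- max(abs(s), na.rm = TRUE)
    if (m > 0) s <- s / m
  }
  if (signed && fit$branch == "hyperpolarizing") s <- -s
  s
}

#' Decompose an opponent cell into G+ and R- component spectra
#'
#' Isolates the two units of a green-depolarizing / red-hyperpolarizing
#' (G+R-) photoreceptor from selectively adapted spectral runs: the G+
#' spectrum is the depolarizing sensitivity measured under red (650 nm)
#' adaptation, which silences the opponent input; the R- spectrum is the
#' hyperpolarizing response under green (500 nm) adaptation, reverse
#' transformed through the second (hyperpolarizing) intensity-response
#' function and reported as negative values. The combined spectrum is
#' normalized so the larger-magnitude peak equals +1.
#'
#' @param red_adapted,green_adapted `ephys_run` spectral series recorded
#'   under red and green adaptation.
#' @param depol_fit `sigmoid_fit` of the depolarizing (dark-adapted, green
#'   flash) intensity-response function.
#' @param hyperpol_fit `sigmoid_fit` of the hyperpolarizing function (red
#'   flashes over a green adapting background); must have
#'   `branch == "hyperpolarizing"`.
#' @param presence_threshold Minimum peak magnitude of the R- component
#'   (relative to the G+ peak) for the opponent unit to be called present
#'   (default 0.1); below it the R- spectrum is reported as absent (all
#'   zero). Guards against reading noise as an opponent unit in cells
#'   without one.
#' @return Object of class `opponent_decomposition`: list with
#'   `wavelength_nm`, `G_plus` (peak +1), `R_minus` (<= 0), the jointly
#'   normalized `combined` matrix, and `R_minus_present`.
#' @export
decompose_opponent <- function(red_adapted, green_adapted,
                               depol_fit, hyperpol_fit,
                               presence_threshold = 0.1) {
  ra <- as.data.frame(red_adapted); ga <- as.data.frame(green_adapted)
  if (!all(c("wavelength_nm", "response_mV") %in% names(ra)) ||
      !all(c("wavelength_nm", "response_mV") %in% names(ga)))
    stop("adapted runs must be spectral series with 'wavelength_nm' and 'response_mV'")
  if (!identical(ra$wavelength_nm, ga$wavelength_nm))
    stop("adapted runs must share a common wavelength grid")
  if (!is.null(hyperpol_fit) && hyperpol_fit$branch != "hyperpolarizing")
    stop("hyperpol_fit must be fitted to a hyperpolarizing branch (or NULL for cells without one)")
  g_plus <- response_to_sensitivity(pmax(ra$response_mV, 0), depol_fit,
                                    normalize = TRUE)
  if (is.null(hyperpol_fit)) {
    # no hyperpolarizing intensity-response function: no opponent unit
    zero <- rep(0, length(g_plus))
    comb <- cbind(G_plus = g_plus, R_minus = zero)
    return(structure(
      list(wavelength_nm = ra$wavelength_nm, G_plus = g_plus,
           R_minus = zero, combined = comb / max(abs(comb)),
           R_minus_present = FALSE),
      class = "opponent_decomposition"))
  }
  # hyperpolarizing amplitudes: negative responses under green adaptation
  # (positive excursions there are residual G+ and carry no R- signal)
  r_raw <- response_to_sensitivity(pmin(ga$response_mV, 0), hyperpol_fit,
                                   normalize = FALSE)
  r_raw[is.na(r_raw)] <- 0
  # scale R- relative to G+ through the two fitted half-max intensities so
  # the decomposition is invariant to overall recording gain
  r_minus <- if (max(r_raw) > 0) r_raw / max(r_raw) else r_raw
  present <- {
    # opponent unit called present only if the hyperpolarizing responses
    # rise clearly above the noise floor of the recording
    amp <- -min(ga$response_mV)
    amp > presence_threshold * abs(hyperpol_fit$V0) && max(r_raw) > 0
  }
  if (!present) r_minus <- rep(0, length(r_minus))
  comb <- cbind(G_plus = g_plus, R_minus = -r_minus)
  m <- max(abs(comb), na.rm = TRUE)
  if (m > 0) comb <- comb / m
  structure(
    list(wavelength_nm = ra$wavelength_nm,
         G_plus = g_plus, R_minus = -r_minus, combined = comb,
         R_minus_present = present),
    class = "opponent_decomposition"
  )
}

#' Fit polarization sensitivity
#'
#' Transforms responses to a rotating linear polarizer into sensitivities
#' (via the fitted intensity-response function) and fits the squared-cosine
#' modulation S(theta) = S_min + (S_max - S_min) * cos^2(theta - Phi).
#' Because cos^2 is a pure second harmonic, the fit is an exact linear
#' harmonic regression on cos(2 theta) and sin(2 theta). Parametrized as
#' the angle of maximal sensitivity Phi (mod 180 deg) and the polarization
#' sensitivity ratio Psi = S_max / S_min.
#'
#' @param run An `ephys_run` (or data frame) with columns `polarizer_deg`
#'   and `response_mV`, covering at least one full rotation.
#' @param fit `sigmoid_fit` used for the reverse transformation.
#' @return Object of class `ps_fit`: list with `Phi` (deg in \[0, 180), NA
#'   if degenerate), `Psi` (>= 1), `S_max`, `S_min`, `rmse` and
#'   `degenerate` flag.
#' @export
fit_polarization <- function(run, fit) {
  df <- as.data.frame(run)
  if (!all(c("polarizer_deg", "response_mV") %in% names(df)))
    stop("need columns 'polarizer_deg' and 'response_mV'")
  if (diff(range(df$polarizer_deg)) < 342)  # 360 - one 18 deg step
    stop("polarization fit needs at least one full polarizer rotation")
  s <- response_to_sensitivity(df$response_mV, fit, normalize = FALSE)
  ok <- !is.na(s)
  th <- df$polarizer_deg[ok] * pi / 180
  s <- s[ok]
  X <- cbind(1, cos(2 * th), sin(2 * th))
  cf <- stats::coef(stats::lm.fit(X, s))
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  resid <- s - X %*% cf
  rmse <- sqrt(mean(resid^2))
  if (amp < 1e-9 * max(abs(s), 1e-12) || amp < 1e-12) {
    return(structure(
      list(Phi = NA_real_, Psi = 1, S_max = cf[1], S_min = cf[1],
           rmse = rmse, degenerate = TRUE),
      class = "ps_fit"))
  }
  S_max <- cf[1] + amp
  S_min <- cf[1] - amp
  if (S_min <= 0) S_min <- max(S_min, 1e-12 * S_max)
  phi <- (atan2(cf[3], cf[2]) / 2 * 180 / pi) %% 180
  structure(
    list(Phi = unname(phi), Psi = unname(S_max / S_min),
         S_max = unname(S_max), S_min = unname(S_min),
         rmse = rmse, degenerate = FALSE),
    class = "ps_fit"
  )
}

#' @export
print.ps_fit <- function(x, ...) {
  if (x$degenerate)
    cat("polarization fit: degenerate (flat response), Psi = 1, Phi undefined\n")
  else
    cat(sprintf("polarization fit: Phi = %.1f deg, Psi = %.2f (rmse %.3g)\n",
                x$Phi, x$Psi, x$rmse))
  invisible(x)
}

#' Summarize a sensitivity spectrum
#'
#' Peak wavelength by parabolic interpolation around the grid maximum and
#' full width at half maximum (bandwidth at 50% sensitivity) by linear
#' interpolation of the two half-peak crossings flanking the main peak.
#' Opponent spectra are summarized on their magnitude. A secondary peak is
#' reported when a second local maximum exceeds 50% of the main one (the
#' dual-peaked blue+green cells).
#'
#' @param wavelength_nm Wavelength grid of the spectrum.
#' @param sensitivity Spectrum values (may be negative for opponent
#'   components; the magnitude is summarized).
#' @param apex_band Fraction of the maximum above which grid points enter
#'   the parabolic apex fit (default 0.75). The contiguous points around
#'   the grid maximum exceeding this level are fitted; with fewer than
#'   three such points the immediate neighbours are used. A wider band
#'   averages noise on broad peaks; 1.0 reproduces the plain three-point
#'   interpolation.
#' @return Object of class `spectral_summary`: list with `lambda_max_nm`,
#'   `fwhm_nm`, `secondary_peak_nm` (NA if none), and flags `edge_peak`,
#'   `one_sided_fwhm`. Warnings are raised when the peak sits at a grid
#'   edge or a 50% crossing is missing on one side.
#' @export
spectrum_summary <- function(wavelength_nm, sensitivity, apex_band = 0.75) {
  stopifnot(length(wavelength_nm) == length(sensitivity))
  keep <- !is.na(sensitivity)
  wavelength_nm <- wavelength_nm[keep]
  v <- abs(sensitivity[keep])
  n <- length(v)
  if (n < 3) stop("spectrum too short to summarize")
  i <- which.max(v)
  edge <- i == 1 || i == n
  if (edge) warning("spectrum peak lies at the grid edge")
  # parabolic interpolation around the grid maximum: least-squares
  # parabola through the contiguous points above apex_band of the maximum
  # (at least the immediate neighbours)
  lmax <- if (!edge) {
    lo <- i; while (lo > 1 && v[lo - 1] >= apex_band * v[i]) lo <- lo - 1
    hi <- i; while (hi < n && v[hi + 1] >= apex_band * v[i]) hi <- hi + 1
    if (hi - lo < 2) { lo <- i - 1; hi <- i + 1 }
    x <- wavelength_nm[lo:hi] - wavelength_nm[i]; y <- v[lo:hi]
    cf <- unname(stats::coef(stats::lm.fit(cbind(1, x, x^2), y)))
    if (is.finite(cf[3]) && cf[3] < 0) {
      apex <- wavelength_nm[i] - cf[2] / (2 * cf[3])
      # keep the apex inside the fitted band; otherwise distrust the fit
      if (apex >= wavelength_nm[lo] && apex <= wavelength_nm[hi]) apex
      else wavelength_nm[i]
    } else wavelength_nm[i]
  } else wavelength_nm[i]
  half <- v[i] / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(i - 1)) else seq(i + 1, n, length.out = max(0, n - i))
    prev <- i
    for (j in idx) {
      if (v[j] <= half) {
        x1 <- wavelength_nm[j]; x2 <- wavelength_nm[prev]
        y1 <- v[j]; y2 <- v[prev]
        return(x1 + (half - y1) * (x2 - x1) / (y2 - y1))
      }
      prev <- j
    }
    NA_real_
  }
  left <- if (i > 1) cross("left") else NA_real_
  right <- if (i < n) cross("right") else NA_real_
  one_sided <- is.na(left) || is.na(right)
  if (one_sided) warning("no 50% crossing on one side; FWHM is one-sided")
  fwhm <- if (!one_sided) right - left else
    if (!is.na(right)) 2 * (right - lmax) else if (!is.na(left)) 2 * (lmax - left) else NA_real_
  # secondary local maximum above 50% of the main peak, separated from it
  # by a dip below 50%
  sec <- NA_real_
  locmax <- which(diff(sign(diff(v))) == -2) + 1
  locmax <- setdiff(locmax, i)
  locmax <- locmax[v[locmax] >= half]
  if (length(locmax)) {
    dips <- vapply(locmax, function(j) {
      rng <- if (j < i) j:i else i:j
      min(v[rng]) < half
    }, logical(1))
    locmax <- locmax[dips]
    if (length(locmax)) sec <- wavelength_nm[locmax[which.max(v[locmax])]]
  }
  structure(
    list(lambda_max_nm = lmax, fwhm_nm = fwhm, secondary_peak_nm = sec,
         edge_peak = edge, one_sided_fwhm = one_sided),
    class = "spectral_summary"
  )
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("lambda_max = %.1f nm, FWHM = %.1f nm%s\n",
              x$lambda_max_nm, x$fwhm_nm,
              if (!is.na(x$secondary_peak_nm))
                sprintf(", secondary peak at %.0f nm", x$secondary_peak_nm) else ""))
  invisible(x)
}

#' Summarize fits across cells
#'
#' Mean and standard error of a named parameter over a list of fits: cells
#' are summarized after per-cell fitting, never pooled before.
#'
#' @param fits List of fit objects (e.g. `sigmoid_fit`, `ps_fit`).
#' @param field Parameter name to extract.
#' @return Named list with `mean`, `se`, `n`.
#' @export
summarize_cells <- function(fits, field) {
  x <- vapply(fits, function(f) as.numeric(f[[field]]), numeric(1))
  x <- x[!is.na(x)]
  list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
}
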