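#' Opponent-cell specification
#'
#' Generative description of a G+R- photoreceptor: a depolarizing green
#' unit with a sigmoid intensity-response function, and a delayed
#' hyperpolarizing opponent input driven by a red-sensitive unit acting
#' through a synapse with a ~-70 mV reversal potential. The G+ spectral
#' sensitivity is a visual-pigment template (or a co-expression-weighted
#' sum of two); the R- spectrum is a Gaussian parametrized directly by its
#' peak and FWHM (the screening-pigment-sharpened shape of the measured
#' opponent spectra), with a small UV sideband.
#'
#' @param g_lambda_max Peak wavelength(s) of the G+ unit, nm; two values
#'   generate a dual-peaked (opsin co-expressing) cell.
#' @param g_weights Mixture weights for dual-peaked cells.
#' @param r_lambda_max,r_fwhm Peak and FWHM of the R- unit spectrum, nm;
#'   `NA` for cells without an opponent unit.
#' @param r_uv_sideband Relative amplitude of the R- UV sideband (Gaussian
#'   at 380 nm, FWHM 60 nm).
#' @param sigmoid_g,sigmoid_h Sigmoid parameters `list(V0, logR, n)` for
#'   the depolarizing G+ pathway and the hyperpolarizing opponent pathway
#'   (V0 in mV, magnitudes). Defaults use the measured estimates
#'   logR = -2.51, n = 0.86 (G+) and logR = -1.21, n = 1.05 (R-).
#' @param V_rest Resting potential, mV.
#' @param E_rev Reversal potential of the opponent synaptic current, mV;
#'   must be below `V_rest`.
#' @param delay_ms Synaptic + propagation delay of the opponent component.
#' @param input_resistance_Mohm Converts injected current (nA) to a holding
#'   potential shift (mV).
#' @param ps_g,ps_r Polarization sensitivity `list(Phi, Psi)` per unit
#'   (degrees; Psi >= 1).
#' @param noise_sd Additive Gaussian response noise, mV.
#' @param adapt_strength Divisive adaptation strength: the unit's catch is
#'   divided by `1 + adapt_strength * S_unit(lambda_adapt)`.
#' @param species Optional label carried into generated runs.
#' @return Object of class `opponent_cell_spec`.
#' @export
opponent_cell_spec <- function(g_lambda_max = 520, g_weights = NULL,
                               r_lambda_max = 620, r_fwhm = 45,
                               r_uv_sideband = 0.1,
                               sigmoid_g = list(V0 = 25, logR = -2.51, n = 0.86),
                               sigmoid_h = list(V0 = 10, logR = -1.21, n = 1.05),
                               V_rest = -60, E_rev = -70, delay_ms = 20,
                               input_resistance_Mohm = 20,
                               ps_g = list(Phi = 103, Psi = 1.2),
                               ps_r = list(Phi = 96, Psi = 2.0),
                               noise_sd = 0.5,
                               adapt_strength = 5000,
                               species = "synthetic") {
  if (!is.na(E_rev) && E_rev >= V_rest)
    stop("E_rev must be below the resting potential")
  if (ps_g$Psi < 1 || ps_r$Psi < 1) stop("Psi must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(g_weights)) g_weights <- rep(1, length(g_lambda_max))
  g_weights <- g_weights / max(g_weights)
  # peak of the unnormalized template mixture, cached for fast evaluation
  fine <- seq(330, 700, 0.5)
  g_norm <- max(rowSums(vapply(seq_along(g_lambda_max), function(i) {
    g_weights[i] * (govardovskii_alpha(fine, g_lambda_max[i]) +
                      govardovskii_beta(fine, g_lambda_max[i]))
  }, numeric(length(fine)))))
  structure(
    list(g_lambda_max = g_lambda_max,
         g_weights = g_weights, g_norm = g_norm,
         r_lambda_max = r_lambda_max, r_fwhm = r_fwhm,
         r_uv_sideband = r_uv_sideband,
         sigmoid_g = sigmoid_g, sigmoid_h = sigmoid_h,
         V_rest = V_rest, E_rev = E_rev, delay_ms = delay_ms,
         input_resistance_Mohm = input_resistance_Mohm,
         ps_g = ps_g, ps_r = ps_r, noise_sd = noise_sd,
         adapt_strength = adapt_strength, species = species,
         has_r_minus = !is.na(r_lambda_max)),
    class = "opponent_cell_spec"
  )
}

# Generative G+ spectral sensitivity, peak-normalized (mixture of
# templates for co-expressing cells).
cell_g_sensitivity <- function(cell, lambda) {
  m <- vapply(seq_along(cell$g_lambda_max), function(i) {
    cell$g_weights[i] * (govardovskii_alpha(lambda, cell$g_lambda_max[i]) +
                           govardovskii_beta(lambda, cell$g_lambda_max[i]))
  }, numeric(length(lambda)))
  rowSums(matrix(m, nrow = length(lambda))) / cell$g_norm
}

# Generative R- spectral sensitivity (magnitude), peak-normalized Gaussian
# plus UV sideband.
cell_r_sensitivity <- function(cell, lambda) {
  if (!cell$has_r_minus) return(rep(0, length(lambda)))
  sig <- cell$r_fwhm / (2 * sqrt(2 * log(2)))
  main <- exp(-((lambda - cell$r_lambda_max)^2) / (2 * sig^2))
  uv <- cell$r_uv_sideband * exp(-((lambda - 380)^2) / (2 * (60 / 2.3548)^2))
  main + uv
}

# cos^2 polarization modulation factor: 1 at Phi, 1/Psi at Phi + 90 deg.
ps_factor <- function(angle_deg, Phi, Psi) {
  if (is.na(angle_deg)) return(1)
  1 / Psi + (1 - 1 / Psi) * cos((angle_deg - Phi) * pi / 180)^2
}

# Divisive adaptation gain of one unit for an adaptation label like
# "green_500" or "red_650"; "dark" leaves the unit unadapted.
adapt_gain <- function(cell, unit_sens_at, adaptation) {
  if (identical(adaptation, "dark")) return(1)
  lam_ad <- suppressWarnings(as.numeric(sub("^[a-z]+_", "", adaptation)))
  if (is.na(lam_ad)) stop("unrecognized adaptation label: ", adaptation)
  1 / (1 + cell$adapt_strength * unit_sens_at(lam_ad))
}

sigmoid_response <- function(catch_times_I, V0, logR, n) {
  x <- catch_times_I^n
  V0 * x / (x + 10^(logR * n))
}

#' Simulate a single flash response
#'
#' Steady-state response amplitude of an opponent cell to an isoquantal
#' monochromatic flash: depolarizing component from the G+ sigmoid driven
#' by the unit's quantum catch, minus a delayed opponent component whose
#' amplitude scales with the driving force (V_hold - E_rev) and therefore
#' reverses sign when injected hyperpolarizing current pulls the holding
#' potential below the reversal potential.
#'
#' @param cell An [opponent_cell_spec()].
#' @param wavelength_nm Flash wavelength.
#' @param log10_intensity Flash intensity, log10 relative to the isoquantal
#'   reference flux.
#' @param adaptation `"dark"` or a label like `"green_500"`, `"red_650"`.
#' @param polarizer_deg Polarizer angle (NA = unpolarized).
#' @param injected_current_nA Holding current.
#' @param noise Add Gaussian noise (uses the current RNG state).
#' @param time_course If `TRUE`, also return the two-component step
#'   waveform showing the opponent delay.
#' @return Amplitude in mV (difference from rest), or a list with
#'   `amplitude_mV` and a `time_course` data frame.
#' @export
simulate_flash_response <- function(cell, wavelength_nm, log10_intensity,
                                    adaptation = "dark",
                                    polarizer_deg = NA,
                                    injected_current_nA = 0,
                                    noise = TRUE, time_course = FALSE) {
  I <- 10^log10_intensity
  sG <- function(l) cell_g_sensitivity(cell, l)
  sR <- function(l) cell_r_sensitivity(cell, l)
  gain_g <- adapt_gain(cell, sG, adaptation)
  gain_r <- adapt_gain(cell, sR, adaptation)
  catch_g <- sG(wavelength_nm) * gain_g *
    ps_factor(polarizer_deg, cell$ps_g$Phi, cell$ps_g$Psi)
  v_dep <- sigmoid_response(catch_g * I, cell$sigmoid_g$V0,
                            cell$sigmoid_g$logR, cell$sigmoid_g$n)
  v_opp <- 0
  if (cell$has_r_minus) {
    catch_r <- sR(wavelength_nm) * gain_r *
      ps_factor(polarizer_deg, cell$ps_r$Phi, cell$ps_r$Psi)
    v_hold <- cell$V_rest + injected_current_nA * cell$input_resistance_Mohm
    driving <- (v_hold - cell$E_rev) / (cell$V_rest - cell$E_rev)
    v_opp <- -sigmoid_response(catch_r * I, cell$sigmoid_h$V0,
                               cell$sigmoid_h$logR, cell$sigmoid_h$n) * driving
  }
  amp <- v_dep + v_opp
  if (noise && cell$noise_sd > 0) amp <- amp + stats::rnorm(1, 0, cell$noise_sd)
  if (!time_course) return(amp)
  t <- seq(0, 200, by = 1)
  v <- ifelse(t >= 1, v_dep, 0) + ifelse(t >= 1 + cell$delay_ms, v_opp, 0)
  list(amplitude_mV = amp,
       time_course = data.frame(t_ms = t, V_mV = cell$V_rest + v))
}

#' Default LED stimulus wavelengths
#'
#' The 21 peak wavelengths of the LED-based spectral stimulator, nm.
#' @export
led_wavelengths <- function() {
  c(365, 375, 390, 402, 423, 437, 452, 470, 495, 512, 525, 543,
    560, 576, 592, 600, 619, 630, 660, 672, 685)
}

#' Monochromator scan wavelengths
#'
#' 10 nm steps across 360-700 nm: the xenon-arc/monochromator source used
#' for spectral scans while the LED source delivers the adapting light.
#' @export
monochromator_wavelengths <- function() seq(360, 700, by = 10)

#' Stimulus protocol
#'
#' Describes one run: a spectral series (isoquantal flashes across the LED
#' set), an intensity series at a fixed wavelength, or a polarizer
#' rotation.
#'
#' @param kind `"spectral_series"`, `"intensity_series"` or
#'   `"polarizer_rotation"`.
#' @param wavelengths Flash wavelengths (nm); default the LED set for
#'   spectral series.
#' @param log10_intensity Flash intensity for spectral/polarization runs.
#' @param log10_range,log10_step Intensity series range and step.
#' @param angles Polarizer angles, deg; default 18 deg steps over 3 full
#'   rotations.
#' @param adaptation Adaptation label (`"dark"`, `"green_500"`, ...).
#' @param injected_current_nA Holding current.
#' @param n_repeats Flash repetitions averaged per stimulus (default 3).
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(kind = c("spectral_series", "intensity_series",
                                       "polarizer_rotation"),
                              wavelengths = led_wavelengths(),
                              log10_intensity = -2,
                              log10_range = c(-4.5, 0), log10_step = 0.5,
                              angles = seq(0, 3 * 360 - 18, by = 18),
                              adaptation = "dark",
                              injected_current_nA = 0,
                              n_repeats = 3) {
  kind <- match.arg(kind)
  if (kind == "spectral_series" && length(wavelengths) == 0)
    stop("spectral series needs a non-empty wavelength list")
  structure(
    list(kind = kind, wavelengths = wavelengths,
         log10_intensity = log10_intensity,
         log10_range = log10_range, log10_step = log10_step,
         angles = angles, adaptation = adaptation,
         injected_current_nA = injected_current_nA,
         n_repeats = n_repeats),
    class = "stimulus_protocol"
  )
}

#' Generate a synthetic recording run
#'
#' Batches [simulate_flash_response()] over a [stimulus_protocol()] into a
#' tidy run table. Deterministic given `(cell, protocol, seed)`.
#'
#' @param cell An [opponent_cell_spec()].
#' @param protocol A [stimulus_protocol()].
#' @param seed Integer seed for the response noise.
#' @return Object of class `ephys_run`: a data frame with columns
#'   `wavelength_nm`, `polarizer_deg`, `log10_intensity`,
#'   `adaptation_label`, `injected_current_nA`, `response_mV`, plus
#'   attributes `species`, `seed`, `kind`.
#' @export
generate_run <- function(cell, protocol, seed = 1) {
  stim <- switch(
    protocol$kind,
    spectral_series = data.frame(
      wavelength_nm = protocol$wavelengths,
      polarizer_deg = NA_real_,
      log10_intensity = protocol$log10_intensity),
    intensity_series = data.frame(
      wavelength_nm = protocol$wavelengths[1],
      polarizer_deg = NA_real_,
      log10_intensity = seq(protocol$log10_range[1], protocol$log10_range[2],
                            by = protocol$log10_step)),
    polarizer_rotation = data.frame(
      wavelength_nm = protocol$wavelengths[1],
      polarizer_deg = protocol$angles %% 360,
      log10_intensity = protocol$log10_intensity)
  )
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  angles_raw <- if (protocol$kind == "polarizer_rotation") protocol$angles else
    stim$polarizer_deg
  resp <- vapply(seq_len(nrow(stim)), function(i) {
    mean(vapply(seq_len(protocol$n_repeats), function(rep) {
      simulate_flash_response(
        cell, stim$wavelength_nm[i], stim$log10_intensity[i],
        adaptation = protocol$adaptation,
        polarizer_deg = if (is.na(stim$polarizer_deg[i])) NA else angles_raw[i],
        injected_current_nA = protocol$injected_current_nA,
        noise = TRUE)
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(
    wavelength_nm = stim$wavelength_nm,
    polarizer_deg = stim$polarizer_deg,
    log10_intensity = stim$log10_intensity,
    adaptation_label = protocol$adaptation,
    injected_current_nA = protocol$injected_current_nA,
    response_mV = resp
  )
  attr(out, "species") <- cell$species
  attr(out, "seed") <- seed
  attr(out, "kind") <- protocol$kind
  class(out) <- c("ephys_run", "data.frame")
  out
}

#' Titrate the flash intensity for a spectral scan
#'
#' Mimics the experimenter's staircase: a dim scan locates the
#' response-maximal wavelength, a bright probe estimates the response
#' ceiling there, then the intensity is stepped up to the largest value
#' whose response stays below `target` of the ceiling, keeping the whole
#' scan in the invertible range of the sigmoid. Uses observable responses
#' only.
#'
#' @param cell An [opponent_cell_spec()].
#' @param wavelengths Scan wavelengths, nm.
#' @param adaptation Adaptation label of the planned scan.
#' @param seed Integer seed for the probe flashes.
#' @param target Fraction of the ceiling response to stay below
#'   (default 0.6).
#' @return A log10 intensity.
#' @export
tune_flash_intensity <- function(cell, wavelengths, adaptation = "dark",
                                 seed = 1, target = 0.6) {
  scan <- generate_run(cell, stimulus_protocol(
    "spectral_series", wavelengths = wavelengths, adaptation = adaptation,
    log10_intensity = -2, n_repeats = 1), seed)
  lam_star <- scan$wavelength_nm[which.max(scan$response_mV)]
  probe <- function(logI, s) mean(generate_run(cell, stimulus_protocol(
    "intensity_series", wavelengths = lam_star, adaptation = adaptation,
    log10_range = c(logI, logI), n_repeats = 3), s)$response_mV)
  ceiling_resp <- probe(0, seed + 1)
  if (ceiling_resp <= 0) return(-1)   # no depolarizing response to titrate
  steps <- seq(-3, -0.5, by = 0.5)
  resp <- vapply(seq_along(steps), function(i) probe(steps[i], seed + 1 + i),
                 numeric(1))
  ok <- which(resp <= target * ceiling_resp)
  if (length(ok)) steps[max(ok)] else -3
}

#' Species presets
#'
#' Generative parameters of the G+R- cells of the eight species with red
#' ommatidia, plus the two negative-control species without an opponent
#' unit. R- peak/FWHM and G+ peak(s) follow the measured per-species
#' summary; dual-peaked G+ cells (opsin co-expression) carry two peaks.
#'
#' @return Data frame with one row per species.
#' @export
species_presets <- function() {
  data.frame(
    species = c("Archaeoprepona demophon", "Argynnis paphia",
                "Charaxes jasius", "Danaus plexippus", "Heliconius erato",
                "Melitaea athalia", "Morpho peleides", "Speyeria aglaja",
                "Apatura ilia", "Vanessa atalanta"),
    r_lambda_max = c(620, 620, 620, 610, 620, 610, 610, 620, NA, NA),
    r_fwhm = c(47, 45, 40, 45, 50, 40, 60, 50, NA, NA),
    g_lambda_max1 = c(530, 535, 535, 440, 465, 450, 500, 530, 530, 530),
    g_lambda_max2 = c(NA, NA, NA, 510, 545, NA, NA, NA, NA, NA),
    g_weight2 = c(NA, NA, NA, 0.9, 0.9, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Build a benchmark suite of synthetic cells
#'
#' Fixture factory for parameter-recovery benchmarks: `n_cells` cells per
#' species preset, each with dark / green-adapted / red-adapted spectral
#' runs, depolarizing and hyperpolarizing intensity runs, and polarization
#' runs, plus a manifest of the generative truth.
#'
#' @param n_cells Cells per species (>= 1).
#' @param species Character vector of preset names (default: all).
#' @param noise_sd Response noise, mV.
#' @param seed Master seed; every run seed is derived from it.
#' @return Object of class `benchmark_suite`: list with `cells` (each a
#'   list of `spec` and named `runs`) and the `manifest` data frame.
#' @export
make_benchmark_suite <- function(n_cells = 1, species = NULL,
                                 noise_sd = 0.5, seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  presets <- species_presets()
  if (!is.null(species)) {
    missing <- setdiff(species, presets$species)
    if (length(missing)) stop("unknown preset(s): ", paste(missing, collapse = ", "))
    presets <- presets[presets$species %in% species, ]
  }
  cells <- list()
  manifest <- list()
  idx <- 0
  for (i in seq_len(nrow(presets))) {
    p <- presets[i, ]
    for (j in seq_len(n_cells)) {
      idx <- idx + 1
      cell_seed <- seed * 10000 + idx
      g_lmax <- c(p$g_lambda_max1, if (!is.na(p$g_lambda_max2)) p$g_lambda_max2)
      g_w <- if (is.na(p$g_lambda_max2)) NULL else c(1, p$g_weight2)
      cell <- opponent_cell_spec(
        g_lambda_max = g_lmax, g_weights = g_w,
        r_lambda_max = p$r_lambda_max, r_fwhm = p$r_fwhm,
        noise_sd = noise_sd, species = p$species)
      # spectral scans use the monochromator grid (10 nm steps) while the
      # second source provides the adapting light; the LED set remains the
      # default for generic protocols
      mono <- monochromator_wavelengths()
      red_logI <- tune_flash_intensity(cell, mono, "red_650",
                                       seed = cell_seed + 90)
      runs <- list(
        dark_spectral = generate_run(
          cell, stimulus_protocol("spectral_series", wavelengths = mono,
                                  n_repeats = 5), cell_seed + 1),
        green_spectral = generate_run(
          cell, stimulus_protocol("spectral_series", wavelengths = mono,
                                  adaptation = "green_500",
                                  log10_intensity = -1, n_repeats = 10),
          cell_seed + 2),
        red_spectral = generate_run(
          cell, stimulus_protocol("spectral_series", wavelengths = mono,
                                  adaptation = "red_650",
                                  log10_intensity = red_logI, n_repeats = 5),
          cell_seed + 3),
        intensity_dark = generate_run(
          cell, stimulus_protocol("intensity_series", wavelengths = 525),
          cell_seed + 4),
        intensity_hyper = generate_run(
          cell, stimulus_protocol("intensity_series", wavelengths = 625,
                                  adaptation = "green_500"), cell_seed + 5),
        ps_dark = generate_run(
          cell, stimulus_protocol("polarizer_rotation", wavelengths = 525,
                                  log10_intensity = -2), cell_seed + 6),
        ps_green = generate_run(
          cell, stimulus_protocol("polarizer_rotation", wavelengths = 625,
                                  adaptation = "green_500",
                                  log10_intensity = -1), cell_seed + 7)
      )
      cells[[idx]] <- list(spec = cell, runs = runs, cell_id = idx)
      manifest[[idx]] <- data.frame(
        cell_id = idx, species = p$species, seed = cell_seed,
        r_lambda_max = p$r_lambda_max, r_fwhm = p$r_fwhm,
        g_lambda_max1 = p$g_lambda_max1, g_lambda_max2 = p$g_lambda_max2,
        V0_g = cell$sigmoid_g$V0, logR_g = cell$sigmoid_g$logR,
        n_g = cell$sigmoid_g$n,
        V0_h = cell$sigmoid_h$V0, logR_h = cell$sigmoid_h$logR,
        n_h = cell$sigmoid_h$n,
        Phi_g = cell$ps_g$Phi, Psi_g = cell$ps_g$Psi,
        Phi_r = cell$ps_r$Phi, Psi_r = cell$ps_r$Psi,
        noise_sd = noise_sd)
    }
  }
  structure(list(cells = cells, manifest = do.call(rbind, manifest)),
            class = "benchmark_suite")
}
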