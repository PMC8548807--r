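#' Wavelength grid
#'
#' Regular wavelength grid (nm) on which all spectra in the package are
#' sampled. The model default spans 300-700 nm at 1 nm steps, covering the
#' emission range of the spectral stimulator and the absorbance of all
#' pigments involved.
#'
#' @param start,stop Grid limits in nm. Must satisfy 250 <= start < stop <= 800.
#' @param step Grid step in nm, > 0.
#' @return Object of class `wavelength_grid`: a list with `start`, `stop`,
#'   `step` and the sampled wavelengths `lambda`.
#' @export
wavelength_grid <- function(start = 300, stop = 700, step = 1) {
  if (step <= 0) stop("wavelength grid step must be > 0")
  if (start >= stop) stop("wavelength grid must be strictly increasing")
  if (start < 250 || stop > 800)
    stop("wavelength grid must lie within [250, 800] nm")
  structure(
    list(start = start, stop = stop, step = step,
         lambda = seq(start, stop, by = step)),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("wavelength grid: %g-%g nm, step %g nm (%d points)\n",
              x$start, x$stop, x$step, length(x$lambda)))
  invisible(x)
}

# Govardovskii A1 alpha-band: x = lambda_max / lambda.
# Constants of the vertebrate/invertebrate A1 nomogram; the position
# parameter a depends weakly on lambda_max.
govardovskii_alpha <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
}

# A1 beta-band: Gaussian in lambda whose position and width scale with the
# alpha-band peak.
govardovskii_beta <- function(lambda, lambda_max) {
  lambda_mb <- 189 + 0.315 * lambda_max
  b <- -40.5 + 0.195 * lambda_max
  0.26 * exp(-((lambda - lambda_mb) / b)^2)
}

#' Visual pigment absorbance template
#'
#' Peak-normalized absorbance spectrum of a rhodopsin or metarhodopsin
#' isoform from the A1 nomogram (Govardovskii template): an alpha band
#' parametrized by its peak wavelength plus, optionally, the UV beta band.
#' The same template family is used for both isoforms; they differ only in
#' peak wavelength and peak absorption coefficient.
#'
#' @param lambda_max Peak wavelength of the alpha band, nm; supported range
#'   330-700 nm.
#' @param grid A [wavelength_grid()].
#' @param beta_band Include the UV beta band (default `TRUE`).
#' @return Object of class `absorbance_template`: list with `grid`,
#'   `lambda_max`, `beta_band` and peak-normalized `values` in \[0, 1\].
#' @export
rhodopsin_template <- function(lambda_max, grid = wavelength_grid(),
                               beta_band = TRUE) {
  if (lambda_max < 330 || lambda_max > 700)
    stop("lambda_max must be within [330, 700] nm")
  v <- govardovskii_alpha(grid$lambda, lambda_max)
  # normalize analytically at lambda_max so values are independent of the
  # sampling grid (the nomogram's true apex exceeds S(lambda_max) by < 5e-6)
  peak <- govardovskii_alpha(lambda_max, lambda_max)
  if (beta_band) {
    v <- v + govardovskii_beta(grid$lambda, lambda_max)
    peak <- peak + govardovskii_beta(lambda_max, lambda_max)
  }
  structure(
    list(grid = grid, lambda_max = lambda_max, beta_band = beta_band,
         values = v / peak),
    class = "absorbance_template"
  )
}

#' Surrogate red screening pigment absorbance
#'
#' Logistic long-pass-blocking absorbance standing in for the measured
#' perirhabdomal red pigment spectrum: ~1 well below the half-fall
#' wavelength (the pigment absorbs green), 0.5 at `lambda_half`, and ~0 in
#' the red, which it transmits.
#'
#' @param lambda_half Half-fall wavelength, nm (default 600).
#' @param steepness Logistic steepness, 1/nm (default 0.05).
#' @param grid A [wavelength_grid()].
#' @return An `absorbance_template` (not re-normalized: values already in
#'   \[0, 1\] and non-increasing).
#' @export
screening_template <- function(lambda_half = 600, steepness = 0.05,
                               grid = wavelength_grid()) {
  if (lambda_half < grid$start || lambda_half > grid$stop)
    stop("lambda_half must lie within the wavelength grid")
  v <- 1 / (1 + exp(steepness * (grid$lambda - lambda_half)))
  structure(
    list(grid = grid, lambda_half = lambda_half, steepness = steepness,
         values = v),
    class = "absorbance_template"
  )
}

#' Write / read a spectrum table
#'
#' Two-column delimited text (`wavelength_nm`, `value`) with a header line;
#' the exchange format for all spectra produced by the package.
#'
#' @param lambda Wavelengths, nm.
#' @param values Spectrum values.
#' @param path Output file.
#' @param digits Significant digits written (default 6).
#' @return `write_spectrum`: `path`, invisibly. `read_spectrum`: a
#'   data.frame with columns `wavelength_nm` and `value`.
#' @export
write_spectrum <- function(lambda, values, path, digits = 6) {
  stopifnot(length(lambda) == length(values))
  df <- data.frame(wavelength_nm = lambda, value = signif(values, digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum file must have columns 'wavelength_nm' and 'value'")
  df[c("wavelength_nm", "value")]
}
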