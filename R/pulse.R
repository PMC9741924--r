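# Gabor pulse model: independent acquisition parameters -> derived beam/speckle
# parameters, the spatial sensitivity function (SSF), and its power spectrum.

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # FWHM of a Gaussian = 2*sqrt(2 ln 2) * sigma

#' Derive a Gabor pulse specification
#'
#' Builds the full set of pulse/beam parameters from the independent
#' acquisition parameters: center frequency, fractional bandwidth, sound
#' speed and f-numbers. Dependent quantities follow the closed forms
#' `u0 = 2 f0 / c`, `FWHM_uz = u0 * frac_bw`, `FWHM_x = 2 fnum_x / u0`,
#' `sigma_x = FWHM_x / (2 sqrt(2 ln 2))`, `sigma_y = FWHM_x / sqrt(2 ln 2)`,
#' `sigma_z = sqrt(2 ln 2) / (pi FWHM_uz)`, `A_2D = 4 sigma_x * 4 sigma_z`
#' and `A_3D = A_2D * 4 (2 sigma_x)`.
#'
#' @param f0 center frequency (MHz)
#' @param frac_bw fractional bandwidth (dimensionless, in (0, 2))
#' @param c sound speed (mm/us); 1.54 by default
#' @param fnum_x in-plane f-number (focal length / lateral aperture)
#' @param fnum_y elevational f-number; defaults to `2 * fnum_x`
#' @param phi Gabor carrier phase (rad)
#' @return an object of class `pulse_spec`: a list with the independent
#'   parameters plus `u0` (mm^-1), `fwhm_uz` (mm^-1), `fwhm_x` (mm),
#'   `sigma_x`, `sigma_y`, `sigma_z` (mm), `sigma_y_amp` (mm, elevational
#'   amplitude width of the SSF envelope, `sigma_x * sqrt(2)`), `a2d` (mm^2)
#'   and `a3d` (mm^3).
#' @examples
#' p <- pulse_spec(5, 0.75)
#' c(p$sigma_x, p$sigma_y, p$sigma_z)
#' @export
pulse_spec <- function(f0, frac_bw, c = 1.54, fnum_x = 2,
                       fnum_y = 2 * fnum_x, phi = 0) {
  vals <- c(f0 = f0, frac_bw = frac_bw, c = c, fnum_x = fnum_x, fnum_y = fnum_y)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("pulse parameters must be finite and positive")
  if (frac_bw >= 2) stop("fractional bandwidth must be < 2")
  if (!is.finite(phi)) stop("phi must be finite")

  u0      <- 2 * f0 / c
  fwhm_uz <- u0 * frac_bw
  fwhm_x  <- 2 * fnum_x / u0
  sigma_x <- fwhm_x / FWHM_SIGMA
  sigma_y <- fwhm_x / sqrt(2 * log(2))       # = 2 sigma_x for fnum_y = 2 fnum_x
  sigma_z <- sqrt(2 * log(2)) / (pi * fwhm_uz)
  a2d     <- (4 * sigma_x) * (4 * sigma_z)
  a3d     <- a2d * 4 * (2 * sigma_x)

  structure(list(
    f0 = f0, frac_bw = frac_bw, c = c, fnum_x = fnum_x, fnum_y = fnum_y,
    phi = phi, u0 = u0, fwhm_uz = fwhm_uz, fwhm_x = fwhm_x,
    sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
    # Elevational width of the SSF *amplitude* envelope, chosen so that the
    # echo interframe correlation under an elevational shift dy is
    # exp(-dy^2 / (2 sigma_y^2)) with sigma_y as above.
    sigma_y_amp = sigma_x * sqrt(2),
    a2d = a2d, a3d = a3d
  ), class = "pulse_spec")
}

#' Build a pulse specification directly from measured Gaussian widths
#'
#' Used for acquisition modes whose pulse widths were measured rather than
#' derived from f-numbers (e.g. narrowband color-mode pulses with
#' `sigma_x = 0.251`, `sigma_y = 0.743`, `sigma_z = 0.163` mm).
#'
#' @param f0 center frequency (MHz)
#' @param sigma_x,sigma_y,sigma_z Gaussian envelope widths (mm)
#' @param c sound speed (mm/us)
#' @param phi carrier phase (rad)
#' @return a `pulse_spec` object
#' @export
pulse_spec_widths <- function(f0, sigma_x, sigma_y, sigma_z, c = 1.54, phi = 0) {
  vals <- c(f0, sigma_x, sigma_y, sigma_z, c)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("pulse parameters must be finite and positive")
  u0 <- 2 * f0 / c
  fwhm_x <- sigma_x * FWHM_SIGMA
  fwhm_uz <- sqrt(2 * log(2)) / (pi * sigma_z)
  a2d <- (4 * sigma_x) * (4 * sigma_z)
  structure(list(
    f0 = f0, frac_bw = fwhm_uz / u0, c = c,
    fnum_x = fwhm_x * u0 / 2, fnum_y = NA_real_,
    phi = phi, u0 = u0, fwhm_uz = fwhm_uz, fwhm_x = fwhm_x,
    sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z,
    sigma_y_amp = sigma_y / sqrt(2),
    a2d = a2d, a3d = a2d * 4 * (2 * sigma_x)
  ), class = "pulse_spec")
}

#' @export
print.pulse_spec <- function(x, ...) {
  cat(sprintf("Gabor pulse: f0 = %g MHz, frac BW = %.3g, c = %g mm/us\n",
              x$f0, x$frac_bw, x$c))
  cat(sprintf("  u0 = %.4g mm^-1, FWHM_uz = %.4g mm^-1, FWHM_x = %.4g mm\n",
              x$u0, x$fwhm_uz, x$fwhm_x))
  cat(sprintf("  sigma (x, y, z) = (%.4g, %.4g, %.4g) mm\n",
              x$sigma_x, x$sigma_y, x$sigma_z))
  cat(sprintf("  A_2D = %.4g mm^2, A_3D = %.4g mm^3\n", x$a2d, x$a3d))
  invisible(x)
}

#' Gabor spatial sensitivity function
#'
#' Evaluates the Gabor approximation to the pulse-echo spatial sensitivity
#' function at positions relative to the beam axis:
#' `sin(2 pi u0 z + phi) * [(2 pi)^{3/2} (2 sigma_x^2) sigma_z]^{-1} *
#' exp(-0.5 ((x/sigma_x)^2 + (y/sigma_y_amp)^2 + (z/sigma_z)^2))`.
#' The function is separable in x, y and z.
#'
#' @param spec a `pulse_spec`
#' @param x,y,z positions (mm); recycled to a common length
#' @return SSF amplitude (dimensionless), vectorized
#' @export
gabor_ssf <- function(spec, x, y = 0, z = 0) {
  stopifnot(inherits(spec, "pulse_spec"))
  norm <- 1 / ((2 * pi)^1.5 * (2 * spec$sigma_x^2) * spec$sigma_z)
  sin(2 * pi * spec$u0 * z + spec$phi) * norm *
    exp(-0.5 * ((x / spec$sigma_x)^2 +
                (y / spec$sigma_y_amp)^2 +
                (z / spec$sigma_z)^2))
}

#' Analytic pulse power spectrum |H(u)|^2 in the scan plane
#'
#' Squared magnitude of the 2-D Fourier transform of the Gabor SSF restricted
#' to the y = 0 plane. The amplitude spectrum is Gaussian in `ux` (std
#' `1/(2 pi sigma_x)`) times a Gaussian pair in `uz` centered at `+/- u0`
#' (std `1/(2 pi sigma_z)`). With `one_sided = TRUE` only the `+u0` lobe is
#' returned, which is the convention used in the one-sided CRLB integrals.
#'
#' @param spec a `pulse_spec`
#' @param ux,uz spatial frequencies (mm^-1); recycled to a common length
#' @param one_sided keep only the `+u0` axial lobe
#' @return power spectral weight (arbitrary absolute scale fixed by the SSF
#'   normalization), vectorized
#' @export
pulse_spectrum <- function(spec, ux, uz, one_sided = FALSE) {
  stopifnot(inherits(spec, "pulse_spec"))
  norm <- 1 / ((2 * pi)^1.5 * (2 * spec$sigma_x^2) * spec$sigma_z)
  # FT of the y=0 profile: C * 2 pi sx sz * Gx(ux) * (1/2)[Gz(uz-u0) +/- Gz(uz+u0)]
  amp0 <- norm * 2 * pi * spec$sigma_x * spec$sigma_z / 2
  gx <- exp(-2 * pi^2 * spec$sigma_x^2 * ux^2)
  gzp <- exp(-2 * pi^2 * spec$sigma_z^2 * (uz - spec$u0)^2)
  h <- if (one_sided) amp0 * gx * gzp else {
    gzm <- exp(-2 * pi^2 * spec$sigma_z^2 * (uz + spec$u0)^2)
    amp0 * gx * (gzp + gzm)  # phase cross-term dropped (lobes well separated)
  }
  h^2
}

#' Load a named acquisition preset
#'
#' Presets mirror the independent-parameter columns of the standard
#' simulation table: "5MHz" (broadband RF processing path) and "20MHz"
#' (broadband IQ path with decimation by 5). Returns the pulse spec plus the
#' acquisition-sampling defaults needed to build grids and calibrate noise.
#'
#' @param name "5MHz" or "20MHz" (case-insensitive), or the path of a JSON
#'   file with the same fields
#' @return a list with elements `name`, `pulse` (a [pulse_spec()]),
#'   `tau_beta` (tissue/blood reflectivity ratio), `snr_db`, `fs_mhz`
#'   (fast-time sampling rate), `lateral_interval_mm`, `frame_rate_hz`,
#'   `modality` ("RF" or "IQ") and `iq_decimation`
#' @export
pd_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets.json", package = "pdus", mustWork = TRUE)
  all <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (file.exists(name)) {
    p <- all
  } else {
    key <- toupper(gsub("\\s", "", name))
    if (!key %in% names(all)) stop("unknown preset: ", name)
    p <- all[[key]]
  }
  p$pulse <- pulse_spec(f0 = p$f0_mhz, frac_bw = p$frac_bw, c = p$c_mm_us,
                        fnum_x = p$fnum_x, fnum_y = p$fnum_y)
  p$name <- name
  p
}
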