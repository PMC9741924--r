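# Echo-frame ensemble simulator: render RF frames from a scatterer trajectory
# by coherent SSF summation, add calibrated acquisition noise, optionally
# demodulate to IQ.

#' Simulate an RF echo-frame ensemble
#'
#' Renders `grid$M` frames `g[k, l, m]` as the weighted coherent sum of Gabor
#' SSF values at the scatterer positions of each frame, with scatterers
#' frozen during frame acquisition. Acquisition noise is i.i.d. zero-mean
#' Gaussian, calibrated so that the mean noise-free signal power over the
#' ensemble divided by the noise variance equals the requested echo SNR.
#'
#' @param field a [scatterer_field()]
#' @param motion a [motion_model()]; blood velocities are realized internally
#'   from `seed` if not already materialized
#' @param pulse a [pulse_spec()]
#' @param grid an [acq_grid()]
#' @param snr_db echo SNR in dB; `Inf` for noise-free
#' @param seed RNG seed for blood directions and the noise draw
#' @param trunc_sd per-axis truncation of the Gaussian footprint (standard
#'   deviations)
#' @return object of class `echo_ensemble`: list with `samples`
#'   (K x L x M array), `grid`, `pulse`, `snr_db`, `sigma_eps2` (noise
#'   variance actually added), `signal_power` (mean noise-free sample power),
#'   `modality` ("RF"), `roi` (the field's perfusion roi), `seed`
#' @export
simulate_ensemble <- function(field, motion, pulse, grid, snr_db = Inf,
                              seed = 1, trunc_sd = 3.5) {
  stopifnot(inherits(field, "scatterer_field"), inherits(motion, "motion_model"),
            inherits(pulse, "pulse_spec"), inherits(grid, "acq_grid"))
  if (nrow(field$positions) == 0) stop("empty scatterer field")
  half <- field$volume_dims / 2
  if (min(grid$x) < -half[1] || max(grid$x) > half[1] ||
      min(grid$z) < -half[3] || max(grid$z) > half[3])
    stop("acquisition frame extends outside the scattering volume")
  if (any(field$labels == "blood") && is.null(motion$blood_velocities))
    motion <- realize_motion(field, motion, seed = seed)

  g <- render_frames(field, motion, pulse, grid, trunc_sd)
  p_sig <- mean(g^2)
  sigma_eps2 <- 0
  if (is.finite(snr_db)) {
    sigma_eps2 <- calibrate_noise(g, snr_db)
    set.seed(seed + 10000L)
    g <- g + array(rnorm(length(g), sd = sqrt(sigma_eps2)), dim = dim(g))
  }
  structure(list(samples = g, grid = grid, pulse = pulse, snr_db = snr_db,
                 sigma_eps2 = sigma_eps2, signal_power = p_sig,
                 modality = "RF", roi = field$roi, seed = seed),
            class = "echo_ensemble")
}

# Noise-free rendering of all frames (internal; also used to build
# component-wise superposition states that share one noise draw).
render_frames <- function(field, motion, pulse, grid, trunc_sd = 3.5) {
  g <- array(0, dim = c(grid$K, grid$L, grid$M))
  for (m in seq_len(grid$M)) {
    pos <- advance(field, motion, m, grid$Tm)
    g[, , m] <- .render_frame(pos, field$amplitudes,
                              grid$K, grid$L, grid$z[1], grid$dz,
                              grid$x[1], grid$X,
                              pulse$u0, pulse$phi,
                              pulse$sigma_x, pulse$sigma_y_amp, pulse$sigma_z,
                              trunc_sd)
  }
  g
}

# Wrap a plain array (e.g. a superposition of rendered components) as an
# echo_ensemble sharing grid/pulse metadata.
as_ensemble <- function(samples, grid, pulse, snr_db = Inf, sigma_eps2 = 0,
                        modality = "RF", roi = NULL, seed = NA_integer_) {
  structure(list(samples = samples, grid = grid, pulse = pulse,
                 snr_db = snr_db, sigma_eps2 = sigma_eps2,
                 signal_power = mean(abs(samples)^2), modality = modality,
                 roi = roi, seed = seed),
            class = "echo_ensemble")
}

#' @export
print.echo_ensemble <- function(x, ...) {
  cat(sprintf("%s echo ensemble: %d x %d x %d frames, SNR %s dB\n",
              x$modality, dim(x$samples)[1], dim(x$samples)[2],
              dim(x$samples)[3],
              if (is.finite(x$snr_db)) format(x$snr_db) else "Inf"))
  invisible(x)
}

#' Calibrate acquisition-noise variance from noise-free frames
#'
#' `sigma_eps2 = mean signal power / 10^(snr_db / 10)`.
#'
#' @param signal_frames noise-free sample array (any shape)
#' @param snr_db target echo SNR (dB)
#' @return the noise variance to draw i.i.d. Gaussian samples from
#' @export
calibrate_noise <- function(signal_frames, snr_db) {
  p <- mean(abs(signal_frames)^2)
  if (p <= 0) stop("zero signal power: cannot calibrate noise")
  p / 10^(snr_db / 10)
}

#' Demodulate an RF ensemble to complex baseband (IQ)
#'
#' Mixes each fast-time line down by the carrier, low-pass filters with a
#' linear-phase FIR (cutoff 0.8x the post-decimation Nyquist), and
#' downsamples the fast-time axis by `decimation`. The `x sqrt(2)` scaling
#' preserves total in-band power.
#'
#' @param ensemble an RF `echo_ensemble`
#' @param decimation integer decimation factor (default 5)
#' @param n_taps FIR length
#' @return an IQ `echo_ensemble` (complex samples, K reduced by the
#'   decimation factor, grid updated: `Tk`, `dz`, `Bz` scale accordingly)
#' @export
to_iq <- function(ensemble, decimation = 5, n_taps = 63) {
  stopifnot(inherits(ensemble, "echo_ensemble"))
  if (ensemble$modality != "RF") stop("input must be an RF ensemble")
  g <- ensemble$samples
  grid <- ensemble$grid
  pulse <- ensemble$pulse
  # band edge of the RF signal vs post-decimation Nyquist (cycles/sample)
  f0_cps <- pulse$u0 * grid$dz            # carrier, cycles per axial sample
  bw_cps <- pulse$fwhm_uz * grid$dz       # FWHM band, cycles per sample
  nyq_post <- 0.5 / decimation
  if (bw_cps / 2 > 0.8 * nyq_post)
    stop("decimation would alias the signal band")
  mix <- exp(-2i * pi * f0_cps * (seq_len(grid$K) - 1))
  h <- as.numeric(signal::fir1(n_taps - 1, 2 * 0.8 * nyq_post))  # linear phase
  gd <- (n_taps - 1) / 2
  K2 <- length(seq(1, grid$K, by = decimation))
  keep <- gd + seq(1, grid$K, by = decimation)  # remove the FIR group delay
  out <- array(0i, dim = c(K2, grid$L, grid$M))
  for (m in seq_len(grid$M)) for (l in seq_len(grid$L)) {
    bb <- g[, l, m] * mix
    # full linear convolution (real and imaginary parts separately)
    yr <- stats::convolve(Re(bb), rev(h), type = "open")
    yi <- stats::convolve(Im(bb), rev(h), type = "open")
    out[, l, m] <- sqrt(2) * complex(real = yr[keep], imaginary = yi[keep])
  }
  grid2 <- acq_grid(Tk = grid$Tk * decimation, X = grid$X, Tm = grid$Tm,
                    K = K2, L = grid$L, M = grid$M, c = grid$c,
                    origin = grid$origin)
  structure(list(samples = out, grid = grid2, pulse = pulse,
                 snr_db = ensemble$snr_db, sigma_eps2 = ensemble$sigma_eps2,
                 signal_power = mean(abs(out)^2), modality = "IQ",
                 roi = ensemble$roi, seed = ensemble$seed),
            class = "echo_ensemble")
}

#' Logical ROI mask on the acquisition grid
#'
#' @param grid an [acq_grid()]
#' @param roi `NULL` for the whole frame, or a list with `x = c(lo, hi)`,
#'   `z = c(lo, hi)` (mm)
#' @param guard_mm strip excluded along every frame edge (alignment edge
#'   effects)
#' @return K x L logical matrix
#' @export
roi_mask <- function(grid, roi = NULL, guard_mm = 0) {
  inx <- rep(TRUE, grid$L); inz <- rep(TRUE, grid$K)
  if (!is.null(roi) && length(roi)) {
    inx <- grid$x >= roi$x[1] & grid$x <= roi$x[2]
    inz <- grid$z >= roi$z[1] & grid$z <= roi$z[2]
  }
  if (guard_mm > 0) {
    inx <- inx & grid$x >= min(grid$x) + guard_mm & grid$x <= max(grid$x) - guard_mm
    inz <- inz & grid$z >= min(grid$z) + guard_mm & grid$z <= max(grid$z) - guard_mm
  }
  outer(inz, inx, "&")
}

#' Save / load an echo ensemble container
#'
#' Serializes the sample array together with its grid metadata, pulse, SNR
#' calibration and seed.
#'
#' @param ensemble an `echo_ensemble`
#' @param path file path (.rds)
#' @return `load_ensemble` returns the `echo_ensemble`
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "echo_ensemble"))
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "echo_ensemble"))
  x
}
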