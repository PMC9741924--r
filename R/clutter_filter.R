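# Eigen-based (SVD/PCA) clutter filtering of echo ensembles in Casorati form,
# Doppler spectra, and net-power accounting for the component power states.

#' Eigen-decompose an echo ensemble over a region of interest
#'
#' Assembles the Casorati matrix (ROI pixels as rows, frames as columns) and
#' takes its thin singular value decomposition. The squared singular values
#' partition the total ensemble energy over the ROI.
#'
#' @param ensemble an `echo_ensemble` (RF or IQ)
#' @param roi region of interest (see [roi_mask()]); `NULL` = full frame
#' @param guard_mm frame-edge strip excluded from the ROI (mm); alignment
#'   resampling is extrapolated there, so power analyses exclude it
#' @return object of class `eigen_spectrum`: `singular_values`
#'   (nonincreasing, length M), `energy_fractions`, and the factors `u`, `v`
#'   plus the pixel mask, retained for reconstruction
#' @export
eigen_decompose <- function(ensemble, roi = NULL, guard_mm = 0) {
  stopifnot(inherits(ensemble, "echo_ensemble"))
  g <- ensemble$samples
  M <- dim(g)[3]
  if (M < 2) stop("need at least 2 frames")
  mask <- roi_mask(ensemble$grid, roi, guard_mm)
  C <- matrix(g, ncol = M)[as.vector(mask), , drop = FALSE]
  s <- svd(C)
  structure(list(singular_values = s$d,
                 energy_fractions = s$d^2 / sum(s$d^2),
                 u = s$u, v = s$v, mask = mask, roi = roi,
                 dims = dim(g)),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat("eigen spectrum (energy fractions):\n")
  print(signif(x$energy_fractions, 3))
  invisible(x)
}

#' Eigenindex band retained by the clutter filter
#'
#' @param lo,hi first and last retained eigenindex (1-based, inclusive)
#' @return list of class `filter_band`
#' @export
filter_band <- function(lo, hi) {
  stopifnot(lo >= 1, hi >= lo)
  structure(list(lo = as.integer(lo), hi = as.integer(hi)),
            class = "filter_band")
}

#' Apply an eigenindex band-pass filter to an ensemble
#'
#' Reconstructs the Casorati matrix from the singular components `lo..hi`
#' only; components outside the band are set to zero. Pixels outside the ROI
#' are either left untouched or zeroed.
#'
#' @param ensemble the `echo_ensemble` that was decomposed
#' @param decomposition an [eigen_decompose()] result for this ensemble
#' @param band a [filter_band()]
#' @param zero_outside zero the pixels outside the ROI (default TRUE so net
#'   power over the ROI is unambiguous)
#' @return filtered `echo_ensemble`
#' @export
apply_filter <- function(ensemble, decomposition, band, zero_outside = TRUE) {
  stopifnot(inherits(decomposition, "eigen_spectrum"),
            inherits(band, "filter_band"))
  M <- length(decomposition$singular_values)
  if (band$hi > M) stop("band exceeds the number of frames")
  idx <- band$lo:band$hi
  d <- decomposition$singular_values[idx]
  rec <- decomposition$u[, idx, drop = FALSE] %*%
         (d * Conj(t(decomposition$v[, idx, drop = FALSE])))
  g <- ensemble$samples
  out <- if (zero_outside) array(if (is.complex(g)) 0i else 0, dim = dim(g)) else g
  sel <- as.vector(decomposition$mask)
  flat <- matrix(out, ncol = dim(g)[3])
  flat[sel, ] <- rec
  ensemble$samples <- array(flat, dim = dim(g))
  ensemble
}

#' Slow-time Doppler power spectrum over a region of interest
#'
#' Per-pixel periodogram along the frame axis (optionally tapered), averaged
#' over the ROI pixels. The two-sided frequency axis spans
#' `+/- 1/(2 Tm)`; the velocity axis applies `v = (c/2) f_D / f0`, i.e.
#' `v [mm/s] = f_D [Hz] / u0 [mm^-1]`.
#'
#' @param ensemble an `echo_ensemble`
#' @param roi region of interest
#' @param guard_mm frame-edge strip excluded (mm)
#' @param window slow-time taper: "boxcar" (default) or "hann"
#' @return object of class `doppler_spectrum`: data.frame-like list with
#'   `frequency` (Hz), `velocity` (mm/s), `power` (mean power per frequency
#'   bin; sums to the ROI mean sample power), `Tm`
#' @export
doppler_spectrum <- function(ensemble, roi = NULL, guard_mm = 0,
                             window = c("boxcar", "hann")) {
  stopifnot(inherits(ensemble, "echo_ensemble"))
  window <- match.arg(window)
  g <- ensemble$samples
  M <- dim(g)[3]
  if (M < 4) stop("need at least 4 frames for a Doppler spectrum")
  mask <- roi_mask(ensemble$grid, roi, guard_mm)
  C <- matrix(g, ncol = M)[as.vector(mask), , drop = FALSE]
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(M - 1)) / M) else rep(1, M)
  w <- w / sqrt(mean(w^2))          # power-preserving taper normalization
  Cw <- sweep(C, 2, w, "*")
  P <- Mod(mvfft(t(Cw)))^2 / M^2    # frequency x pixel; sums (over freq) to mean power
  p <- rowMeans(P)
  k <- 0:(M - 1); k[k > M / 2] <- k[k > M / 2] - M
  ord <- order(k)
  fd <- k[ord] / (M * ensemble$grid$Tm)
  structure(list(frequency = fd, velocity = fd / ensemble$pulse$u0,
                 power = p[ord], Tm = ensemble$grid$Tm),
            class = "doppler_spectrum")
}

#' Net signal power over a region of interest
#'
#' The integral of the Doppler power spectrum over the full measurement
#' bandwidth, equal (Parseval) to the mean sample power over the ROI.
#'
#' @param ensemble an `echo_ensemble`
#' @param roi region of interest
#' @param guard_mm frame-edge strip excluded (mm)
#' @return mean power (signal units squared)
#' @export
net_power <- function(ensemble, roi = NULL, guard_mm = 0) {
  mask <- roi_mask(ensemble$grid, roi, guard_mm)
  mean(abs(matrix(ensemble$samples, ncol = dim(ensemble$samples)[3])[as.vector(mask), ])^2)
}

#' Power report across component measurement states
#'
#' Builds the standard measurement states from separately rendered noise-free
#' clutter and blood components plus one shared noise draw (superposition of
#' the linear echo model), and reports net power over the perfused ROI in dB
#' relative to the unfiltered, unregistered blood-only state:
#' unregistered/unfiltered `c`, `n`, `b`, `c+b+n`; registered+filtered
#' `fr c+n`, `fr b+n`, `fr b`, `fr c+b+n`; and unregistered+filtered
#' `fur c+n+b`. Registered states are aligned with [register_ensemble()]
#' using each state's own displacement estimates; filtered states retain the
#' eigenindex band.
#'
#' @param clutter_nf,blood_nf noise-free `echo_ensemble`s rendered from the
#'   same seed/grid (tissue-only and blood-only components)
#' @param noise K x L x M array of acquisition noise (one shared draw)
#' @param band a [filter_band()]
#' @param roi perfused ROI over which net power is integrated; defaults to
#'   the blood component's ROI
#' @param guard_mm frame-edge strip excluded from power integrals (mm)
#' @param config a [reg_config()] for the registered states
#' @param states character vector of states to compute (default all nine)
#' @param alignment "shared" (default): displacement estimated once from the
#'   combined c+b+n signal and applied to every registered state, because
#'   registration tracks the motion of the echogenic clutter; "self": each
#'   state is registered with its own displacement estimates (note that
#'   self-registration of blood-only directed flow removes the blood's own
#'   coherent motion)
#' @return data.frame with columns `state`, `power_db_rel_blood`
#' @export
net_power_report <- function(clutter_nf, blood_nf, noise, band,
                             roi = NULL, guard_mm = 0.5, config = reg_config(),
                             states = c("c", "n", "b", "c+b+n",
                                        "fr c+n", "fr b+n", "fr b",
                                        "fr c+b+n", "fur c+n+b"),
                             alignment = c("shared", "self")) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(clutter_nf, "echo_ensemble"), inherits(blood_nf, "echo_ensemble"))
  if (is.null(roi)) roi <- blood_nf$roi
  grid <- clutter_nf$grid; pulse <- clutter_nf$pulse
  comp <- function(samples) as_ensemble(samples, grid, pulse, roi = roi)
  p_blood <- net_power(blood_nf, roi, guard_mm)
  if (p_blood <= 0) stop("blood-only reference power is zero")

  gC <- clutter_nf$samples; gB <- blood_nf$samples
  # one displacement trace, estimated from the combined signal (registration
  # tracks the echogenic clutter), shared by all registered states
  disp <- NULL
  if (alignment == "shared" && any(grepl("^fr ", states)))
    disp <- register_ensemble(comp(gC + gB + noise), config)$displacement
  one <- function(state) {
    reg <- startsWith(state, "fr ")
    filt <- startsWith(state, "fr") || startsWith(state, "fur")
    spec <- sub("^(fr|fur) ", "", state)
    parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
    s <- array(0, dim = dim(gC))
    if ("c" %in% parts) s <- s + gC
    if ("b" %in% parts) s <- s + gB
    if ("n" %in% parts) s <- s + noise
    ens <- comp(s)
    if (reg) {
      ens <- if (alignment == "shared") apply_displacement(ens, disp)
             else register_ensemble(ens, config)$ensemble
    }
    if (filt) {
      dec <- eigen_decompose(ens, roi, guard_mm)
      ens <- apply_filter(ens, dec, band)
    }
    10 * log10(net_power(ens, roi, guard_mm) / p_blood)
  }
  data.frame(state = states,
             power_db_rel_blood = vapply(states, one, numeric(1)),
             row.names = NULL)
}
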