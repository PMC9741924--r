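# Acquisition grids: discrete fast-time/lateral/slow-time sampling of echo
# frames, plus the effective noise bandwidths they imply.

#' Define an echo acquisition grid
#'
#' @param Tk fast-time sampling interval (us); axial sample spacing is
#'   `c * Tk / 2`
#' @param X lateral sampling interval (mm)
#' @param Tm frame (slow-time) interval (s)
#' @param K,L,M axial, lateral and frame counts
#' @param c sound speed (mm/us)
#' @param origin (x, z) position of the first sample (mm); default centers
#'   the frame on the beam axis / focal depth (0, 0)
#' @return object of class `acq_grid` with sample axes `x` (lateral, mm),
#'   `z` (axial, mm), `t` (slow time, s) and noise bandwidths
#'   `Bx = 1/(2X)`, `Bz = 1/(c Tk)` (mm^-1)
#' @export
acq_grid <- function(Tk, X, Tm, K, L, M, c = 1.54, origin = NULL) {
  stopifnot(Tk > 0, X > 0, Tm > 0, K >= 1, L >= 1, M >= 1)
  dz <- c * Tk / 2
  if (is.null(origin))
    origin <- c(-(L - 1) * X / 2, -(K - 1) * dz / 2)
  structure(list(
    Tk = Tk, X = X, Tm = Tm, K = K, L = L, M = M, c = c,
    dz = dz, origin = origin,
    x = origin[1] + (seq_len(L) - 1) * X,
    z = origin[2] + (seq_len(K) - 1) * dz,
    t = (seq_len(M) - 1) * Tm,
    Bx = 1 / (2 * X), Bz = 1 / (c * Tk)
  ), class = "acq_grid")
}

#' Default grid for a preset
#'
#' Builds the sampling grid implied by a preset's independent parameters,
#' covering a `frame_mm[1] x frame_mm[2]` (lateral x axial) scan frame.
#'
#' @param preset a list from [pd_preset()]
#' @param frame_mm lateral and axial frame extents (mm); default 10 x 10
#' @param M number of frames in the Doppler ensemble
#' @return an [acq_grid()]
#' @export
preset_grid <- function(preset, frame_mm = c(10, 10), M = 21) {
  Tk <- 1 / preset$fs_mhz
  dz <- preset$c_mm_us * Tk / 2
  X <- preset$lateral_interval_mm
  acq_grid(Tk = Tk, X = X, Tm = 1 / preset$frame_rate_hz,
           K = floor(frame_mm[2] / dz) + 1,
           L = floor(frame_mm[1] / X) + 1,
           M = M, c = preset$c_mm_us)
}

#' @export
print.acq_grid <- function(x, ...) {
  cat(sprintf("acquisition grid: %d x %d samples x %d frames\n", x$K, x$L, x$M))
  cat(sprintf("  axial %.4g mm @ %.4g mm, lateral %.4g mm @ %.3g mm, frame rate %.3g Hz\n",
              (x$K - 1) * x$dz, x$dz, (x$L - 1) * x$X, x$X, 1 / x$Tm))
  cat(sprintf("  noise bandwidths Bx = %.4g, Bz = %.4g mm^-1\n", x$Bx, x$Bz))
  invisible(x)
}
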