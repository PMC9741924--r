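# Interframe correlation coefficients and Gaussian fits to decorrelation
# curves.

#' Interframe correlation coefficient
#'
#' Zero-lag, mean-removed (Pearson) correlation between two frames over a
#' region of interest. For complex (IQ) frames the magnitude of the complex
#' correlation coefficient is returned.
#'
#' @param frame_a,frame_b matrices of the same shape
#' @param mask optional logical matrix selecting the samples used; default
#'   all
#' @return correlation coefficient in `[-1, 1]` (or `[0, 1]` for IQ)
#' @export
interframe_rho <- function(frame_a, frame_b, mask = NULL) {
  stopifnot(all(dim(frame_a) == dim(frame_b)))
  a <- if (is.null(mask)) as.vector(frame_a) else frame_a[mask]
  b <- if (is.null(mask)) as.vector(frame_b) else frame_b[mask]
  if (length(a) < 2) stop("empty roi")
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(Mod(a)^2); vb <- sum(Mod(b)^2)
  if (va == 0 || vb == 0) stop("zero-variance frame")
  r <- sum(Conj(a) * b) / sqrt(va * vb)
  if (is.complex(frame_a) || is.complex(frame_b)) Mod(r) else Re(r)
}

#' Correlation of each ensemble frame against frame 1
#'
#' @param ensemble an `echo_ensemble`
#' @param guard_mm edge strip excluded from the correlation (mm)
#' @return numeric vector of length M, first element 1
#' @export
ensemble_rho <- function(ensemble, guard_mm = 0.5) {
  g <- ensemble$samples
  mask <- roi_mask(ensemble$grid, NULL, guard_mm)
  vapply(seq_len(dim(g)[3]), function(m)
    interframe_rho(g[, , 1], g[, , m], mask), numeric(1))
}

#' Fit a Gaussian to a decorrelation curve
#'
#' Unweighted least squares of `log(rho)` against `d^2` using points with
#' `rho > floor` only (tail bins are noise-dominated); returns the fitted
#' standard deviation and FWHM.
#'
#' @param d displacement values (mm)
#' @param rho correlation coefficients
#' @param floor smallest rho used in the fit
#' @return list with `sigma` (mm), `fwhm` (mm), `amplitude`
#' @export
fit_gaussian_rho <- function(d, rho, floor = 0.05) {
  keep <- is.finite(rho) & rho > floor
  if (sum(keep) < 3) stop("too few points above the fit floor")
  fit <- lm(log(rho[keep]) ~ I(d[keep]^2))
  s2 <- -1 / (2 * coef(fit)[[2]])
  if (s2 <= 0) stop("decorrelation curve is not Gaussian-decaying")
  sigma <- sqrt(s2)
  list(sigma = sigma, fwhm = 2 * sqrt(2 * log(2)) * sigma,
       amplitude = exp(coef(fit)[[1]]))
}

#' Locate the displacement at which a correlation curve crosses a level
#'
#' Linear interpolation between the bracketing samples of the first
#' downward crossing.
#'
#' @param d displacement values (monotone increasing, mm)
#' @param rho correlation values
#' @param level crossing level (default 0.5)
#' @return displacement (mm) of the crossing, or NA if none
#' @export
rho_crossing <- function(d, rho, level = 0.5) {
  below <- which(rho < level)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(d[1])
  d[i - 1] + (level - rho[i - 1]) * (d[i] - d[i - 1]) / (rho[i] - rho[i - 1])
}
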