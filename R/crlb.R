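# Coherence-based Cramer-Rao lower bounds on lateral/axial displacement
# estimation variance for correlated echo-frame pairs in noise.
#
# The bounds are one-sided spatial-frequency integrals of the marginal
# signal-to-noise spectra S(ux), S(uz), where the signal spectrum is the
# Gabor pulse power spectrum and the noise is band-limited white with
# bandwidths set by the sampling rates.

#' Spectral model for the displacement variance bounds
#'
#' @param pulse a [pulse_spec()]
#' @param Bx,Bz effective noise bandwidths (mm^-1); from an [acq_grid()]
#'   these are `1/(2X)` and `1/(c Tk)`
#' @param snr_db echo SNR (dB); fixes the signal-to-noise scale
#'   `sigma_f^2/sigma_eps^2` through the one-sided spectral integral
#' @param X0,Z0 lateral and axial correlation-window dimensions (mm)
#' @return list of class `spectral_model`
#' @export
spectral_model <- function(pulse, Bx, Bz, snr_db, X0 = 1, Z0 = 1) {
  stopifnot(inherits(pulse, "pulse_spec"), Bx > 0, Bz > 0, X0 > 0, Z0 > 0)
  # frequency stds of the power spectrum |H(u)|^2 (amplitude std / sqrt(2))
  sux <- 1 / (2 * pi * pulse$sigma_x) / sqrt(2)
  suz <- 1 / (2 * pi * pulse$sigma_z) / sqrt(2)
  # one-sided integral of |H|^2 (unit peak): ratio sigma_f^2/sigma_eps^2
  # follows from SNR = (sigma_f^2/sigma_eps^2) * int_0^inf du |H(u)|^2
  i_h2 <- (sux * sqrt(2 * pi) / 2) * (suz * sqrt(2 * pi) * pnorm(pulse$u0 / suz))
  structure(list(pulse = pulse, Bx = Bx, Bz = Bz, snr_db = snr_db,
                 X0 = X0, Z0 = Z0, sux = sux, suz = suz,
                 ratio = 10^(snr_db / 10) / i_h2),
            class = "spectral_model")
}

#' Magnitude-squared coherence from a signal-to-noise spectral ratio
#'
#' Pointwise `C = S / (1 + S)`; 0 for independent data (S = 0), -> 1 as
#' S -> Inf.
#'
#' @param S nonnegative spectral ratio value(s) or a function of frequency
#' @return coherence value(s), or a function if `S` is a function
#' @export
coherence_from_snr <- function(S) {
  if (is.function(S)) return(function(u) { s <- S(u); s / (1 + s) })
  stopifnot(all(S >= 0))
  S / (1 + S)
}

#' Marginal signal-to-noise spectra S(ux), S(uz)
#'
#' `S(ux) = Bx (sigma_f^2/sigma_eps^2) int_0^inf duz |H(u)|^2` and the axial
#' analog, using the one-sided (+u0 lobe) Gabor power spectrum. Closed-form
#' Gaussian integrals are used; set `method = "quadrature"` for an adaptive
#' quadrature cross-check.
#'
#' @param model a [spectral_model()]
#' @param method "closed" (default) or "quadrature"
#' @return list of vectorized functions `S_ux(ux)` and `S_uz(uz)`
#' @export
marginal_snr_spectra <- function(model, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  sux <- model$sux; suz <- model$suz; u0 <- model$pulse$u0
  gx <- function(ux) exp(-ux^2 / (2 * sux^2))
  gz <- function(uz) exp(-(uz - u0)^2 / (2 * suz^2))
  if (method == "closed") {
    Jz <- suz * sqrt(2 * pi) * pnorm(u0 / suz)   # int_0^inf gz
    Jx <- sux * sqrt(2 * pi) / 2                 # int_0^inf gx
  } else {
    Jz <- integrate(gz, 0, Inf, rel.tol = 1e-10)$value
    Jx <- integrate(gx, 0, Inf, rel.tol = 1e-10)$value
  }
  list(S_ux = function(ux) model$Bx * model$ratio * Jz * gx(ux),
       S_uz = function(uz) model$Bz * model$ratio * Jx * gz(uz))
}

#' Displacement variance lower bounds
#'
#' `var(xi) >= [8 pi^2 X0 int_0^inf ux^2 S(ux) dux]^-1` for the lateral
#' estimate, and the axial analog with `Z0` and `S(uz)`. The bounds are
#' independent of the true displacement.
#'
#' @param model a [spectral_model()]
#' @param method passed to [marginal_snr_spectra()]; "quadrature" also
#'   evaluates the outer integrals by adaptive quadrature
#' @return list of class `variance_bound`: `var_lateral`, `var_axial` (mm^2)
#' @export
variance_bounds <- function(model, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  S <- marginal_snr_spectra(model, method)
  sux <- model$sux; suz <- model$suz; u0 <- model$pulse$u0
  if (method == "closed") {
    # S_ux(0) and S_uz(u0) carry the Bx/Bz * ratio * J scales; the remaining
    # factors are Gaussian (partial) second moments.
    # int_0^inf ux^2 exp(-ux^2/(2 sux^2)) dux = sux^3 sqrt(2 pi) / 2
    ix <- S$S_ux(0) * sux^3 * sqrt(2 * pi) / 2
    # int_0^inf uz^2 exp(-(uz-u0)^2/(2 suz^2)) duz, clipped at 0:
    # with T = (uz - u0)/suz and a = -u0/suz,
    # = suz sqrt(2 pi) [u0^2 Q(a) + 2 u0 suz phi(a) + suz^2 (Q(a) + a phi(a))]
    a <- -u0 / suz
    phi_a <- exp(-a^2 / 2) / sqrt(2 * pi)
    Qa <- pnorm(a, lower.tail = FALSE)
    m2 <- suz * sqrt(2 * pi) *
      (u0^2 * Qa + 2 * u0 * suz * phi_a + suz^2 * (Qa + a * phi_a))
    iz <- S$S_uz(u0) * m2
  } else {
    ix <- integrate(function(u) u^2 * S$S_ux(u), 0, Inf, rel.tol = 1e-8)$value
    iz <- integrate(function(u) u^2 * S$S_uz(u), 0, Inf, rel.tol = 1e-8)$value
  }
  if (ix <= 0 || iz <= 0) stop("degenerate spectral integrals")
  structure(list(var_lateral = 1 / (8 * pi^2 * model$X0 * ix),
                 var_axial   = 1 / (8 * pi^2 * model$Z0 * iz)),
            class = "variance_bound")
}
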