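# Rigid in-plane interframe displacement estimation and ensemble alignment.
#
# Two-stage speckle tracking: (1) coarse integer-lag estimate from the peak of
# the FFT-computed 2-D cross correlation of zero-padded windows; (2) subsample
# refinement maximizing the continuously interpolated correlation surface with
# a derivative-free simplex search. Estimated displacements (averaged over a
# 3 x 3 window plan) are removed by resampling each frame onto the frame-1
# grid.

#' Registration configuration
#'
#' @param window_mm side of each square analysis window (mm); the literature
#'   default here is 2 mm with 1 mm available
#' @param layout windows are placed centered in an `nr x nc` grid of equal
#'   frame blocks (non-overlapping by construction)
#' @param tol convergence criterion of the simplex search, in samples
#' @param max_refine clamp on the subsample remainder per axis (samples)
#' @param margin extra samples of frame-m context kept around the window so
#'   the fine correlation is full-overlap (no shrinking-window bias)
#' @param zero_pad_factor minimum zero padding of the coarse correlation
#' @return a list of class `reg_config`
#' @export
reg_config <- function(window_mm = 2, layout = c(3, 3), tol = 1e-4,
                       max_refine = 1.5, margin = 6, zero_pad_factor = 2) {
  stopifnot(window_mm > 0, tol > 0, max_refine > 0, margin >= 2)
  structure(list(window_mm = window_mm, layout = layout, tol = tol,
                 max_refine = max_refine, margin = margin,
                 zero_pad_factor = zero_pad_factor),
            class = "reg_config")
}

#' Window plan: index ranges of the analysis windows
#'
#' @param grid an [acq_grid()]
#' @param config a [reg_config()]
#' @return list of windows, each `list(k = rows, l = cols)`
#' @export
window_plan <- function(grid, config = reg_config()) {
  nk <- max(2, round(config$window_mm / grid$dz))
  nl <- max(2, round(config$window_mm / grid$X))
  nr <- config$layout[1]; nc <- config$layout[2]
  R <- config$margin
  if (nr * nk > grid$K - 2 * R || nc * nl > grid$L - 2 * R)
    stop("window plan does not fit inside the frame (with the search margin)")
  wins <- vector("list", nr * nc)
  i <- 1
  for (r in seq_len(nr)) for (s in seq_len(nc)) {
    ck <- round((r - 0.5) * grid$K / nr)
    cl <- round((s - 0.5) * grid$L / nc)
    # keep the fine-search patch (window +/- margin) inside the frame
    k1 <- min(max(ck - floor(nk / 2), 1 + R), grid$K - nk + 1 - R)
    l1 <- min(max(cl - floor(nl / 2), 1 + R), grid$L - nl + 1 - R)
    wins[[i]] <- list(k = k1:(k1 + nk - 1), l = l1:(l1 + nl - 1))
    i <- i + 1
  }
  wins
}

# cross correlation over integer lags via zero-padded FFTs:
# corr[dk, dl] = sum_i ref[i] * Conj? -- for real RF this is plain product;
# for complex IQ we correlate conj(ref) with the patch.
# Returns list(S = cross spectrum, N = fft dims) for reuse by the fine stage.
cross_spectrum <- function(ref, patch, N1, N2) {
  A <- matrix(0, N1, N2); B <- matrix(0, N1, N2)
  if (is.complex(ref) || is.complex(patch)) { A <- A + 0i; B <- B + 0i }
  A[seq_len(nrow(ref)), seq_len(ncol(ref))] <- ref
  B[seq_len(nrow(patch)), seq_len(ncol(patch))] <- patch
  Conj(fft(A)) * fft(B)
}

# inverse transform back to the lag domain; complex_data selects the
# magnitude (IQ) vs real-part (RF) correlation criterion
corr_surface <- function(S, complex_data) {
  C <- fft(S, inverse = TRUE) / length(S)
  if (complex_data) Mod(C) else Re(C)
}

#' Coarse integer-lag displacement between two equal windows
#'
#' Argmax of the zero-padded FFT cross-correlation surface. Lags are
#' `(dk, dl)` such that the content of `window_m` is the content of
#' `window_ref` translated by `+dk` axial and `+dl` lateral samples. Ties are
#' broken toward the smaller Euclidean lag norm, then lexicographically.
#'
#' @param window_ref,window_m equal-size matrices (axial x lateral)
#' @param config a [reg_config()]
#' @return integer vector `c(dk, dl)`
#' @export
coarse_shift <- function(window_ref, window_m, config = reg_config()) {
  stopifnot(all(dim(window_ref) == dim(window_m)))
  if (all(window_ref == 0) || all(window_m == 0))
    stop("all-zero window: correlation peak undefined")
  nk <- nrow(window_ref); nl <- ncol(window_ref)
  N1 <- stats::nextn(config$zero_pad_factor * nk, 2)
  N2 <- stats::nextn(config$zero_pad_factor * nl, 2)
  mag <- corr_surface(cross_spectrum(window_ref, window_m, N1, N2),
                      is.complex(window_ref) || is.complex(window_m))
  # wrapped lag axes
  lag1 <- ifelse(seq_len(N1) - 1 <= N1 / 2, seq_len(N1) - 1, seq_len(N1) - 1 - N1)
  lag2 <- ifelse(seq_len(N2) - 1 <= N2 / 2, seq_len(N2) - 1, seq_len(N2) - 1 - N2)
  keep1 <- abs(lag1) <= nk - 1; keep2 <- abs(lag2) <= nl - 1
  mag <- mag[keep1, keep2, drop = FALSE]
  l1 <- lag1[keep1]; l2 <- lag2[keep2]
  best <- max(mag)
  idx <- which(mag >= best - 1e-12 * abs(best), arr.ind = TRUE)
  cand <- cbind(l1[idx[, 1]], l2[idx[, 2]])
  ord <- order(cand[, 1]^2 + cand[, 2]^2, cand[, 1], cand[, 2])
  as.integer(cand[ord[1], ])
}

# Tukey (tapered-cosine) window, flat over 1 - a of the length
tukey_win <- function(n, a = 0.4) {
  if (n < 4) return(rep(1, n))
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- x < a / 2
  hi <- x > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / a + 1)))
  w
}

# Continuous evaluation of the cross-correlation surface at fractional lags
# by direct trigonometric (band-limited) interpolation from the cross
# spectrum: corr(d) = (1/N) sum_j S[j] exp(+2 pi i f_j . d).
corr_at_cplx <- function(S, dk, dl) {
  N1 <- nrow(S); N2 <- ncol(S)
  f1 <- (seq_len(N1) - 1); f1[f1 > N1 / 2] <- f1[f1 > N1 / 2] - N1
  f2 <- (seq_len(N2) - 1); f2[f2 > N2 / 2] <- f2[f2 > N2 / 2] - N2
  e1 <- exp(2i * pi * f1 * dk / N1)
  e2 <- exp(2i * pi * f2 * dl / N2)
  as.vector(crossprod(e1, S %*% e2)) / length(S)
}

#' Subsample displacement refinement
#'
#' Starting at the coarse integer lags, maximizes the continuously
#' interpolated cross correlation between the reference window of frame 1
#' and the surrounding context of frame m with a Nelder-Mead simplex search
#' (derivative-free), terminating at the `tol` criterion. The correlation is
#' evaluated at fractional lags by exact band-limited (trigonometric)
#' interpolation of the full-overlap correlation surface. The remainder is
#' clamped to `max_refine` samples per axis.
#'
#' @param frame_ref,frame_m full frames (axial x lateral matrices)
#' @param window `list(k = rows, l = cols)` index ranges of the analysis
#'   window inside `frame_ref`
#' @param coarse integer lags `c(dk, dl)` from [coarse_shift()]
#' @param config a [reg_config()]
#' @return list with `remainder` (fractional samples, `c(dk, dl)`),
#'   `converged` flag, `value` (correlation at the optimum)
#' @export
fine_shift <- function(frame_ref, frame_m, window, coarse = c(0L, 0L),
                       config = reg_config()) {
  R <- config$margin
  kr <- window$k; lr <- window$l
  pk <- (min(kr) - R):(max(kr) + R) + coarse[1]
  pl <- (min(lr) - R):(max(lr) + R) + coarse[2]
  if (min(pk) < 1 || max(pk) > nrow(frame_m) ||
      min(pl) < 1 || max(pl) > ncol(frame_m))
    stop("window too close to the frame edge for the search radius")
  ref <- frame_ref[kr, lr, drop = FALSE]
  patch <- frame_m[pk, pl, drop = FALSE]
  nk <- length(kr); nl <- length(lr)
  # pad to hold the full linear correlation without wrap
  N1 <- stats::nextn(nrow(patch) + nk, 2)
  N2 <- stats::nextn(ncol(patch) + nl, 2)
  # the reference window is tapered (Tukey) so that both the correlation and
  # the sliding-energy sequences decay smoothly at their support edges --
  # band-limited (trigonometric) interpolation between integer lags is then
  # accurate, where a hard-edged window would ring
  W2 <- outer(tukey_win(nk), tukey_win(nl))^2
  S <- cross_spectrum(W2 * ref, patch, N1, N2)
  SE <- cross_spectrum(W2, Mod(patch)^2, N1, N2)
  cplx <- is.complex(ref) || is.complex(patch)
  # relative lag r: ref aligned with patch center when corr lag = R
  obj <- function(r) {
    if (any(abs(r) > config$max_refine)) return(1e300)
    e <- Re(corr_at_cplx(SE, R + r[1], R + r[2]))
    if (e <= 0) return(1e300)
    v <- corr_at_cplx(S, R + r[1], R + r[2])
    -(if (cplx) Mod(v) else Re(v)) / sqrt(e)
  }
  fit <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = config$tol^2, maxit = 400))
  list(remainder = fit$par, converged = fit$convergence == 0,
       value = -fit$value)
}

# One window, both stages; returns displacement in samples c(dk, dl).
estimate_window_shift <- function(frame_ref, frame_m, window, config) {
  ref <- frame_ref[window$k, window$l, drop = FALSE]
  win_m <- frame_m[window$k, window$l, drop = FALSE]
  co <- coarse_shift(ref, win_m, config)
  # keep the fine-stage patch inside the frame
  co[1] <- max(min(co[1], nrow(frame_m) - max(window$k) - config$margin),
               1 - min(window$k) + config$margin)
  co[2] <- max(min(co[2], ncol(frame_m) - max(window$l) - config$margin),
               1 - min(window$l) + config$margin)
  fs <- fine_shift(frame_ref, frame_m, window, co, config)
  co + fs$remainder
}

#' Register an echo ensemble to its first frame
#'
#' Estimates the rigid in-plane displacement of every frame relative to
#' frame 1 as the mean over the window plan of coarse + fine window
#' estimates, then resamples each frame at grid points offset by the
#' estimated displacement so that all frames align with frame 1 (frame 1 is
#' untouched). Resampling uses separable band-limited interpolation with
#' mirror extension at the frame edges.
#'
#' @param ensemble an `echo_ensemble`
#' @param config a [reg_config()]
#' @param cumulative estimate frame-to-frame displacements and accumulate
#'   them instead of correlating every frame directly against frame 1; use
#'   when the total travel exceeds a window size (window overlap with frame 1
#'   would otherwise vanish). Alignment is still to frame 1.
#' @return list: `ensemble` (aligned copy), `displacement` (data.frame with
#'   columns frame, xi_mm (lateral), zeta_mm (axial), spread_x, spread_z)
#' @export
register_ensemble <- function(ensemble, config = reg_config(),
                              cumulative = FALSE) {
  stopifnot(inherits(ensemble, "echo_ensemble"))
  g <- ensemble$samples
  grid <- ensemble$grid
  M <- dim(g)[3]
  if (M < 2) stop("need at least 2 frames to register")
  wins <- window_plan(grid, config)
  out <- g
  disp <- data.frame(frame = seq_len(M), xi_mm = 0, zeta_mm = 0,
                     spread_x = 0, spread_z = 0)
  f1 <- g[, , 1]
  for (m in 2:M) {
    fref <- if (cumulative) g[, , m - 1] else f1
    fm <- g[, , m]
    est <- vapply(wins, function(w)
      estimate_window_shift(fref, fm, w, config), numeric(2))
    dz_mm <- est[1, ] * grid$dz
    dx_mm <- est[2, ] * grid$X
    base <- if (cumulative) c(disp$xi_mm[m - 1], disp$zeta_mm[m - 1]) else c(0, 0)
    disp$xi_mm[m] <- base[1] + mean(dx_mm)
    disp$zeta_mm[m] <- base[2] + mean(dz_mm)
    disp$spread_x[m] <- sd(dx_mm); disp$spread_z[m] <- sd(dz_mm)
    out[, , m] <- shift_frame(fm, disp$xi_mm[m] / grid$X,
                              disp$zeta_mm[m] / grid$dz)
  }
  ens2 <- ensemble
  ens2$samples <- out
  list(ensemble = ens2, displacement = disp)
}

#' Resample a frame at grid points offset by a rigid shift
#'
#' Returns `out[k, l] = f(z_k + dk, x_l + dl)` (sample units), i.e. content
#' that moved by `+d` between the reference and this frame is moved back.
#' Implemented as a separable Fourier phase shift with mirror extension so
#' the wrap-around seam is continuous; interpolation is band-limited.
#'
#' @param frame matrix (axial x lateral), real or complex
#' @param dl,dk lateral and axial shifts in samples
#' @return matrix of the same shape
#' @export
shift_frame <- function(frame, dl, dk) {
  f <- frame
  if (dk != 0) f <- fourier_shift_cols(f, dk)
  if (dl != 0) f <- t(fourier_shift_cols(t(f), dl))
  f
}

# shift every column by +d samples (out[i] = col(i + d)), mirror-padded
fourier_shift_cols <- function(f, d) {
  K <- nrow(f)
  P <- min(K, 32L)
  fp <- rbind(f[P:1, , drop = FALSE], f, f[K:(K - P + 1), , drop = FALSE])
  N <- nrow(fp)
  fr <- (seq_len(N) - 1); fr[fr > N / 2] <- fr[fr > N / 2] - N
  ph <- exp(2i * pi * fr * d / N)
  out <- mvfft(mvfft(fp) * ph, inverse = TRUE) / N
  out <- out[(P + 1):(P + K), , drop = FALSE]
  if (is.complex(f)) out else Re(out)
}

#' Align an ensemble with a given displacement trace
#'
#' Applies the alignment stage of [register_ensemble()] using displacements
#' estimated elsewhere — typically from the clutter-bearing combined signal,
#' since registration tracks the motion of the echogenic clutter and the
#' same alignment must be applied to every component state for a consistent
#' power decomposition.
#'
#' @param ensemble an `echo_ensemble`
#' @param displacement data.frame with `xi_mm`, `zeta_mm` per frame (as
#'   returned by [register_ensemble()])
#' @return the aligned `echo_ensemble`
#' @export
apply_displacement <- function(ensemble, displacement) {
  g <- ensemble$samples
  grid <- ensemble$grid
  stopifnot(nrow(displacement) == dim(g)[3])
  for (m in seq_len(dim(g)[3])) {
    if (displacement$xi_mm[m] == 0 && displacement$zeta_mm[m] == 0) next
    g[, , m] <- shift_frame(g[, , m], displacement$xi_mm[m] / grid$X,
                            displacement$zeta_mm[m] / grid$dz)
  }
  ensemble$samples <- g
  ensemble
}

#' Displacement errors against known truth
#'
#' Per-frame errors `estimate - truth` for each in-plane axis, linearly
#' detrended (least squares in frame index) before the variance is formed as
#' the mean squared detrended error.
#'
#' @param estimates data.frame from [register_ensemble()] (columns `xi_mm`,
#'   `zeta_mm`) or a matrix with lateral/axial columns
#' @param truth matrix/data.frame of true displacements, same layout (mm)
#' @return list with `e_x`, `e_z` (detrended errors, mm), `var_x`, `var_z`
#'   (mm^2)
#' @export
displacement_errors <- function(estimates, truth) {
  col2 <- function(obj, nm, j) {
    if (is.data.frame(obj) && !is.null(obj[[nm]])) obj[[nm]] else obj[, j]
  }
  ex <- as.numeric(col2(estimates, "xi_mm", 1)) - as.numeric(col2(truth, "xi_mm", 1))
  ez <- as.numeric(col2(estimates, "zeta_mm", 2)) - as.numeric(col2(truth, "zeta_mm", 2))
  if (length(ex) < 3) stop("need at least 3 frames for a detrended variance")
  detrend <- function(e) stats::residuals(lm(e ~ seq_along(e)))
  ex <- detrend(ex); ez <- detrend(ez)
  list(e_x = ex, e_z = ez, var_x = mean(ex^2), var_z = mean(ez^2))
}
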