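test_that("coarse stage recovers integer shifts exactly", {
  set.seed(1)
  w <- matrix(rnorm(64 * 32), 64, 32)
  expect_identical(coarse_shift(w, w), c(0L, 0L))
  shifted <- w[c(62:64, 1:61), c(3:32, 1:2)]   # +3 axial, -2 lateral (circular)
  expect_identical(coarse_shift(w, shifted), c(3L, -2L))
  expect_error(coarse_shift(matrix(0, 8, 8), matrix(0, 8, 8)))
})

test_that("coarse stage agrees with a brute-force spatial-domain oracle", {
  brute <- function(a, b, max_lag = 6) {
    best <- c(0, 0); bv <- -Inf
    for (dk in -max_lag:max_lag) for (dl in -max_lag:max_lag) {
      ka <- max(1, 1 - dk):min(nrow(a), nrow(a) - dk)
      la <- max(1, 1 - dl):min(ncol(a), ncol(a) - dl)
      v <- sum(a[ka, la] * b[ka + dk, la + dl])
      if (v > bv) { bv <- v; best <- c(dk, dl) }
    }
    best
  }
  for (s in 1:25) {
    set.seed(s)
    base <- matrix(rnorm(48 * 48), 48, 48)
    # smooth to give the field correlation structure, then shift circularly
    k <- outer(dnorm(-2:2), dnorm(-2:2)); a <- matrix(0, 32, 32)
    for (i in 1:5) for (j in 1:5)
      a <- a + k[i, j] * base[(8 + i):(39 + i), (8 + j):(39 + j)]
    dk <- sample(-4:4, 1); dl <- sample(-4:4, 1)
    b <- a[((seq_len(32) - 1 - dk) %% 32) + 1, ((seq_len(32) - 1 - dl) %% 32) + 1]
    expect_identical(coarse_shift(a, b), c(as.integer(dk), as.integer(dl)),
                     label = paste("seed", s))
  }
})

test_that("fine stage recovers known subsample shifts", {
  pr <- shifted_pair(c(0, 0, 0), seed = 21, frame_mm = c(4, 4))
  grid <- pr$grid
  cfg <- reg_config(window_mm = 2)
  win <- window_plan(grid, reg_config(window_mm = 2, layout = c(1, 1)))[[1]]
  # zero true shift, noise-free: remainder vanishes
  fs <- fine_shift(pr$f1, pr$f1, win, c(0L, 0L), cfg)
  expect_true(fs$converged)
  expect_lt(max(abs(fs$remainder)), 1e-3)
  # known +0.30-sample axial shift at 30 dB SNR recovered within 0.02 samples
  d <- c(0.2 * grid$X, 0, 0.3 * grid$dz)
  pr2 <- shifted_pair(d, seed = 21, frame_mm = c(4, 4))
  s2 <- mean(pr2$f1^2) / 1000
  set.seed(99)
  f1n <- pr2$f1 + rnorm(length(pr2$f1), sd = sqrt(s2))
  f2n <- pr2$f2 + rnorm(length(pr2$f2), sd = sqrt(s2))
  est <- pdus:::estimate_window_shift(f1n, f2n, win, cfg)
  expect_lt(abs(est[1] - 0.3), 0.02)
  expect_lt(abs(est[2] - 0.2), 0.1)    # lateral sampling is 5x coarser
})

test_that("shift_frame is exact for band-limited content and invertible", {
  z <- seq_len(256)
  f <- outer(sin(2 * pi * 0.13 * z) * exp(-((z - 128) / 60)^2), rep(1, 20))
  g <- shift_frame(f, 0, 0.37)
  h <- shift_frame(g, 0, -0.37)
  inner <- 40:216
  expect_lt(max(abs(h[inner, ] - f[inner, ])), 1e-4)
})

test_that("register_ensemble: static input is a fixed point; symmetry holds", {
  s <- small_setup(c(5, 5), seed = 22, M = 3)
  ens <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid, snr_db = Inf)
  reg <- register_ensemble(ens, reg_config(window_mm = 1.2))
  expect_lt(max(abs(reg$displacement$xi_mm)), 1e-3)
  expect_lt(max(abs(reg$displacement$zeta_mm)), 1e-3)
  expect_equal(reg$ensemble$samples, ens$samples, tolerance = 5e-3)
  # symmetry: swapping the frame roles negates the estimate
  d <- c(0.04, 0, 0.012)
  pr <- shifted_pair(d, seed = 23, frame_mm = c(5, 5))
  cfg <- reg_config(window_mm = 2)
  win <- window_plan(pr$grid, reg_config(window_mm = 2, layout = c(1, 1)))[[1]]
  fwd <- pdus:::estimate_window_shift(pr$f1, pr$f2, win, cfg)
  bwd <- pdus:::estimate_window_shift(pr$f2, pr$f1, win, cfg)
  expect_equal(fwd, -bwd, tolerance = 0.02)
})

test_that("programmed elliptical trajectory is recovered by registration", {
  pulse <- preset5$pulse
  grid <- preset_grid(preset5, c(6, 6), M = 8)
  field <- scatterer_field(pulse, volume_dims = c(9, 3, 9), roi = list(),
                           tau_beta = 16, seed = 24)
  motion <- motion_model(clutter_elliptical(1, 0.05, 0.025))
  ens <- simulate_ensemble(field, motion, pulse, grid, snr_db = 30, seed = 24)
  reg <- register_ensemble(ens, reg_config(window_mm = 1.5))
  truth <- t(vapply(seq_len(8), function(m)
    clutter_offset(motion$clutter, (m - 1) * grid$Tm), numeric(3)))
  err <- displacement_errors(reg$displacement,
                             data.frame(xi_mm = truth[, 1], zeta_mm = truth[, 3]))
  expect_lt(sqrt(err$var_x), 2e-3)
  expect_lt(sqrt(err$var_z), 4e-4)
  # and the estimator is unbiased: raw mean error small
  expect_lt(abs(mean(reg$displacement$xi_mm - truth[, 1])), 2e-3)
})

test_that("displacement_errors: detrending removes exactly the linear part", {
  est <- data.frame(xi_mm = c(0, 1, 2, 3, 4) * 0.1 + c(0, .01, -.01, .02, 0),
                    zeta_mm = rep(0, 5))
  tru <- data.frame(xi_mm = c(0, 1, 2, 3, 4) * 0.1, zeta_mm = rep(0, 5))
  e <- displacement_errors(est, tru)
  # adding a perfect ramp changes nothing after detrending
  est2 <- est; est2$xi_mm <- est2$xi_mm + 5 + 0.3 * (1:5)
  e2 <- displacement_errors(est2, tru)
  expect_equal(e$var_x, e2$var_x, tolerance = 1e-12)
  expect_equal(displacement_errors(tru, tru)$var_x, 0)
  expect_error(displacement_errors(tru[1:2, ], tru[1:2, ]))
  # for white errors the detrended variance is deflated by the 2-parameter fit
  set.seed(4)
  vs <- replicate(3000, {
    e <- rnorm(20, sd = 0.1)
    z <- data.frame(xi_mm = e, zeta_mm = e)
    displacement_errors(z, data.frame(xi_mm = rep(0, 20), zeta_mm = rep(0, 20)))$var_x
  })
  expect_equal(mean(vs), 0.01 * (1 - 2 / 20), tolerance = 0.02)
})
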