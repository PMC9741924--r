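make_moving_ensemble <- function(M = 8, seed = 31, blood = NULL, snr = Inf) {
  pulse <- preset5$pulse
  grid <- preset_grid(preset5, c(5, 5), M = M)
  roi <- if (is.null(blood)) list() else list(x = c(-1, 1), z = c(-1.5, 1.5))
  field <- scatterer_field(pulse, volume_dims = c(8, 3, 8), tau_beta = 16,
                           roi = roi, seed = seed)
  motion <- motion_model(clutter_elliptical(), blood %||% blood_none())
  simulate_ensemble(field, motion, pulse, grid, snr_db = snr, seed = seed)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("singular values match a dense frame-covariance oracle", {
  ens <- make_moving_ensemble(M = 6, snr = 30)
  dec <- eigen_decompose(ens)
  C <- matrix(ens$samples, ncol = 6)
  ev <- eigen(crossprod(C), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(dec$singular_values, sqrt(pmax(ev, 0)), tolerance = 1e-8)
  expect_true(all(diff(dec$singular_values) <= 1e-8))
  # Frobenius identity
  expect_equal(sum(dec$singular_values^2), sum(C^2), tolerance = 1e-10)
  expect_error(eigen_decompose(make_moving_ensemble(M = 1)))
})

test_that("band filtering: identity band, energy bookkeeping, roi masking", {
  ens <- make_moving_ensemble(M = 6, snr = 30)
  dec <- eigen_decompose(ens)
  full <- apply_filter(ens, dec, filter_band(1, 6))
  expect_equal(full$samples, ens$samples, tolerance = 1e-10)
  part <- apply_filter(ens, dec, filter_band(2, 4))
  expect_equal(sum(part$samples^2), sum(dec$singular_values[2:4]^2),
               tolerance = 1e-10)
  expect_error(apply_filter(ens, dec, filter_band(2, 7)))
  expect_error(filter_band(0, 3))
  # roi-restricted filtering zeroes the outside by default
  roi <- list(x = c(-1, 1), z = c(-1, 1))
  decr <- eigen_decompose(ens, roi)
  fr <- apply_filter(ens, decr, filter_band(1, 6))
  mask <- roi_mask(ens$grid, roi)
  expect_true(all(fr$samples[!mask] == 0))
  expect_equal(fr$samples[mask], ens$samples[mask], tolerance = 1e-10)
})

test_that("registration narrows the eigenspectrum of moving clutter", {
  ens <- make_moving_ensemble(M = 8, seed = 32, snr = 30)
  reg <- register_ensemble(ens, reg_config(window_mm = 1))$ensemble
  n99 <- function(e) {
    fr <- cumsum(eigen_decompose(e, guard_mm = 0.5)$energy_fractions)
    which(fr >= 0.99)[1]
  }
  expect_lt(n99(reg), n99(ens))
  expect_gt(eigen_decompose(reg, guard_mm = 0.5)$energy_fractions[1], 0.99)
})

test_that("doppler spectrum: DC for static data, Parseval, velocity axis", {
  s <- small_setup(c(3, 3), seed = 33, M = 8)
  ens <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid, snr_db = Inf)
  sp <- doppler_spectrum(ens)
  expect_equal(sum(sp$power[sp$frequency != 0]) / sum(sp$power), 0,
               tolerance = 1e-20)
  expect_equal(sp$velocity, sp$frequency / s$pulse$u0)
  expect_equal(max(abs(sp$frequency)), 1 / (2 * s$grid$Tm), tolerance = 0.1)
  # Parseval with the boxcar window
  ens2 <- make_moving_ensemble(M = 8, seed = 34, snr = 20)
  sp2 <- doppler_spectrum(ens2)
  expect_equal(sum(sp2$power), net_power(ens2), tolerance = 1e-6)
  expect_error(doppler_spectrum(make_moving_ensemble(M = 3)))
})

test_that("directed flow peaks at the programmed Doppler frequency", {
  pulse <- preset5$pulse
  grid <- preset_grid(preset5, c(3, 3), M = 21)
  field <- scatterer_field(pulse, volume_dims = c(6, 3, 6), tau_beta = 16,
                           roi = list(x = c(-1.2, 1.2), z = c(-1.2, 1.2)),
                           seed = 35)
  fb <- subset_field(field, "blood")
  motion <- realize_motion(fb, motion_model(
    blood = blood_directed(0.2, cone_half_angle = 0)), seed = 35)
  ens <- simulate_ensemble(fb, motion, pulse, grid, snr_db = Inf, seed = 35)
  sp <- doppler_spectrum(ens, roi = field$roi)
  fd <- sp$frequency[which.max(sp$power)]
  # f_D = u0 * v = 6.494 * 0.2 ~ 1.30 Hz, within one bin (1/(M Tm) ~ 0.48 Hz)
  expect_lt(abs(abs(fd) - pulse$u0 * 0.2), 1 / (21 * grid$Tm) + 1e-9)
})

test_that("net_power_report reproduces the component power bookkeeping", {
  pulse <- preset5$pulse
  grid <- preset_grid(preset5, c(6, 6), M = 8)
  field <- scatterer_field(pulse, volume_dims = c(10, 4, 10), tau_beta = 16,
                           roi = list(x = c(-1.5, 1.5), z = c(-3, 3)), seed = 36)
  ft <- subset_field(field, "tissue"); fb <- subset_field(field, "blood")
  mb <- realize_motion(fb, motion_model(clutter_elliptical(), blood_diffuse(0.2)),
                       seed = 36)
  gC <- pdus:::render_frames(ft, motion_model(clutter_elliptical()), pulse, grid)
  gB <- pdus:::render_frames(fb, mb, pulse, grid)
  s2 <- calibrate_noise(gC + gB, 30)
  set.seed(99); nz <- array(rnorm(length(gC), sd = sqrt(s2)), dim = dim(gC))
  rep <- net_power_report(pdus:::as_ensemble(gC, grid, pulse, roi = field$roi),
                          pdus:::as_ensemble(gB, grid, pulse, roi = field$roi),
                          nz, filter_band(2, 6), roi = field$roi,
                          config = reg_config(window_mm = 1.2))
  val <- function(st) rep$power_db_rel_blood[rep$state == st]
  expect_equal(val("b"), 0)
  # clutter/blood amplitude ratio 16 at equal density: ~ +24.1 dB
  # (single-seed speckle statistics leave ~0.5 dB standard error)
  expect_lt(abs(val("c") - 24.1), 2)
  expect_lt(abs(val("n") - (24.1 - 30)), 2)
  # unregistered filtering leaks far more clutter than registered filtering
  expect_gt(val("fur c+n+b"), val("fr c+b+n") + 6)
  expect_error(net_power_report(pdus:::as_ensemble(gC, grid, pulse),
                                pdus:::as_ensemble(gB * 0, grid, pulse),
                                nz, filter_band(2, 6), roi = field$roi))
})

test_that("registration separates clutter and blood subspaces (directed)", {
  pulse <- preset5$pulse
  grid <- preset_grid(preset5, c(6, 6), M = 10)
  field <- scatterer_field(pulse, volume_dims = c(10, 4, 10), tau_beta = 16,
                           roi = list(x = c(-1.5, 1.5), z = c(-3, 3)), seed = 37)
  ft <- subset_field(field, "tissue"); fb <- subset_field(field, "blood")
  mb <- realize_motion(fb, motion_model(clutter_elliptical(),
                                        blood_directed(0.2)), seed = 37)
  gC <- pdus:::render_frames(ft, motion_model(clutter_elliptical()), pulse, grid)
  gB <- pdus:::render_frames(fb, mb, pulse, grid)
  s2 <- calibrate_noise(gC + gB, 30)
  set.seed(98); nz <- array(rnorm(length(gC), sd = sqrt(s2)), dim = dim(gC))
  roi <- field$roi
  comb <- pdus:::as_ensemble(gC + gB + nz, grid, pulse, roi = roi)
  disp <- register_ensemble(comb, reg_config(window_mm = 1.2))$displacement
  # the clutter filter is the temporal projector of the registered combined
  # ensemble with eigenindex 1 removed; apply it to each aligned component
  dec <- eigen_decompose(apply_displacement(comb, disp), roi, 0.5)
  v1 <- dec$v[, 1]
  proj <- diag(10) - tcrossprod(v1)
  msk <- as.vector(roi_mask(grid, roi, 0.5))
  pw <- function(g) {
    ens <- apply_displacement(pdus:::as_ensemble(g, grid, pulse, roi = roi), disp)
    C <- matrix(ens$samples, ncol = 10)[msk, ]
    sum((C %*% proj)^2) / sum(C^2)
  }
  # removing only eigenindex 1 keeps > 90% of blood power and < 1% of clutter
  expect_gt(pw(gB), 0.9)
  expect_lt(pw(gC), 0.01)
  # spectral narrowing: clutter Doppler second moment shrinks on registration
  m2 <- function(ens) {
    sp <- doppler_spectrum(ens, guard_mm = 0.5)
    sum(sp$frequency^2 * sp$power) / sum(sp$power)
  }
  cens <- pdus:::as_ensemble(gC, grid, pulse, roi = roi)
  expect_lt(m2(apply_displacement(cens, disp)), m2(cens))
})
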