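test_that("a single scatterer renders the sampled SSF axial line", {
  pulse <- pulse_spec(5, 0.75, phi = pi / 2)
  grid <- acq_grid(Tk = 1 / 38.5, X = 0.1, Tm = 0.1, K = 101, L = 21, M = 1)
  f <- structure(list(
    positions = matrix(c(grid$x[11], 0, grid$z[51]), 1, 3),
    amplitudes = 16, labels = "tissue",
    volume_dims = c(4, 2, 4), roi = list(), density = 1, seed = 1
  ), class = "scatterer_field")
  ens <- simulate_ensemble(f, motion_model(), pulse, grid, snr_db = Inf,
                           trunc_sd = 12)
  line <- ens$samples[, 11, 1]
  oracle <- 16 * gabor_ssf(pulse, 0, 0, f$positions[3] - grid$z)
  expect_equal(line, oracle, tolerance = 1e-12)
  # off-axis column picks up the lateral Gaussian factor
  col9 <- ens$samples[, 9, 1]
  expect_equal(col9, oracle * exp(-0.5 * (2 * grid$X / pulse$sigma_x)^2),
               tolerance = 1e-12)
})

test_that("static noise-free ensembles repeat frame 1 exactly (and are rank 1)", {
  s <- small_setup(c(2, 2), seed = 5, M = 4)
  ens <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid, snr_db = Inf)
  for (m in 2:4)
    expect_identical(ens$samples[, , m], ens$samples[, , 1])
  dec <- eigen_decompose(ens)
  expect_gt(dec$energy_fractions[1], 0.999)
})

test_that("noise calibration matches the requested echo SNR", {
  sig <- array(rnorm(1000, sd = 3), dim = c(10, 10, 10))
  expect_equal(calibrate_noise(sig, 30), mean(sig^2) / 1000)
  expect_equal(calibrate_noise(sig, Inf), 0)
  expect_error(calibrate_noise(array(0, c(2, 2)), 30))
  # Monte-Carlo self-consistency on a rendered ensemble
  s <- small_setup(c(4, 4), seed = 6, M = 8)
  nf <- pdus:::render_frames(s$field, motion_model(), s$pulse, s$grid)
  ens <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid,
                           snr_db = 20, seed = 6)
  noise <- ens$samples - nf
  snr_hat <- 10 * log10(mean(nf^2) / mean(noise^2))
  expect_lt(abs(snr_hat - 20), 0.2)
})

test_that("superposition: component ensembles add sample-for-sample", {
  pulse <- preset5$pulse
  grid <- preset_grid(preset5, c(3, 3), M = 3)
  field <- scatterer_field(pulse, volume_dims = c(6, 2, 6),
                           roi = list(x = c(-1, 1), z = c(-1, 1)), seed = 7)
  motion <- motion_model(clutter_elliptical(), blood_diffuse(0.2))
  motion <- realize_motion(subset_field(field, "blood"), motion, seed = 7)
  gt <- pdus:::render_frames(subset_field(field, "tissue"), motion, pulse, grid)
  gb <- pdus:::render_frames(subset_field(field, "blood"), motion, pulse, grid)
  gall <- pdus:::render_frames(field, realize_motion(field, motion_model(
    clutter_elliptical(), blood_diffuse(0.2)), seed = 7), pulse, grid)
  # blood velocities drawn identically for the blood rows (same seed), so
  # tissue-only + blood-only equals the full render
  expect_equal(gt + gb, gall, tolerance = 1e-10)
})

test_that("ensemble-averaged periodogram follows the pulse power spectrum", {
  pulse <- preset5$pulse
  grid <- preset_grid(preset5, c(4, 4), M = 1)
  acc <- 0
  n_real <- 60
  for (s in seq_len(n_real)) {
    st <- small_setup(c(4, 4), seed = 400 + s)
    f1 <- pdus:::render_frames(st$field, motion_model(), pulse, grid)[, , 1]
    acc <- acc + Mod(fft(f1))^2
  }
  acc <- acc / n_real
  uz <- (seq_len(grid$K) - 1) / (grid$K * grid$dz)
  ux <- (seq_len(grid$L) - 1) / (grid$L * grid$X)
  uz[uz > 1 / (2 * grid$dz)] <- uz[uz > 1 / (2 * grid$dz)] - 1 / grid$dz
  ux[ux > 1 / (2 * grid$X)] <- ux[ux > 1 / (2 * grid$X)] - 1 / grid$X
  H2 <- outer(uz, ux, function(z, x) pulse_spectrum(pulse, x, z))
  # flat scatterer-field spectrum: the ratio is constant over the -10 dB
  # band up to Monte-Carlo noise, and the shapes agree down to -20 dB
  band10 <- H2 > max(H2) / 10
  ratio <- acc[band10] / H2[band10]
  expect_lt(sd(ratio) / mean(ratio), 0.2)
  band20 <- H2 > max(H2) / 100
  expect_gt(cor(log(acc[band20]), log(H2[band20])), 0.97)
})

test_that("footprint truncation error is small", {
  s <- small_setup(c(2, 2), seed = 8)
  g35 <- pdus:::render_frames(s$field, motion_model(), s$pulse, s$grid, 3.5)
  g50 <- pdus:::render_frames(s$field, motion_model(), s$pulse, s$grid, 5.0)
  expect_lt(max(abs(g35 - g50)) / sqrt(mean(g50^2)), 0.01)
})

test_that("simulated ensembles are seeded and bit-reproducible", {
  s <- small_setup(c(2, 2), seed = 9, M = 3)
  e1 <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid, 30, seed = 2)
  e2 <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid, 30, seed = 2)
  expect_identical(e1$samples, e2$samples)
  e3 <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid, 30, seed = 3)
  expect_false(identical(e1$samples, e3$samples))
})

test_that("IQ conversion preserves rate bookkeeping and in-band energy", {
  grid <- preset_grid(preset20, c(2, 2), M = 2)
  expect_equal(1 / grid$Tk, 128.3, tolerance = 1e-9)
  s <- small_setup(c(2, 2), seed = 10, preset = preset20, M = 2)
  ens <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid, snr_db = Inf)
  iq <- to_iq(ens, 5)
  expect_equal(1 / iq$grid$Tk, 128.3 / 5, tolerance = 1e-9)
  expect_equal(iq$grid$Bz, 1 / (1.54 * iq$grid$Tk), tolerance = 1e-9)
  expect_s3_class(iq, "echo_ensemble")
  expect_true(is.complex(iq$samples))
  # band energy preserved (narrowband signal fully inside the passband)
  expect_equal(mean(Mod(iq$samples)^2), mean(ens$samples^2), tolerance = 0.02)
  # a pure carrier demodulates to a constant envelope away from transients
  ens2 <- ens
  ens2$samples[] <- rep(sin(2 * pi * s$pulse$u0 * grid$z), grid$L * grid$M)
  iq2 <- to_iq(ens2, 5)
  env <- Mod(iq2$samples[10:(dim(iq2$samples)[1] - 10), 1, 1])
  expect_lt(diff(range(env)) / mean(env), 0.01)
  # decimating an RF band that would alias is refused
  expect_error(to_iq(ens, 50))
})

test_that("ensemble containers round-trip through save/load", {
  s <- small_setup(c(2, 2), seed = 11, M = 2)
  ens <- simulate_ensemble(s$field, motion_model(), s$pulse, s$grid, 30, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  expect_identical(back$samples, ens$samples)
  expect_identical(back$grid$K, ens$grid$K)
  unlink(path)
})
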