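# Simulation experiments: estimator efficiency against the variance bounds,
# component-wise power states, out-of-plane decorrelation sweeps and
# sample-size scaling.

# tissue-only field sized so the frame (plus footprint margins and motion)
# stays illuminated
clutter_field_for <- function(preset, frame_mm, extra_mm = c(0, 0), seed = 1,
                              elev_mm = 5) {
  p <- preset$pulse
  vol <- c(frame_mm[1] + 2 * (3.5 * p$sigma_x + 0.6) + extra_mm[1],
           elev_mm,
           frame_mm[2] + 2 * (3.5 * p$sigma_z + 0.6) + extra_mm[2])
  scatterer_field(p, volume_dims = vol, tau_beta = preset$tau_beta,
                  roi = list(), seed = seed)
}

#' Measure displacement-estimator efficiency against the variance bounds
#'
#' Monte-Carlo replication of the estimator-efficiency experiment: pairs of
#' clutter-only frames with a known subsample in-plane shift are simulated
#' at each echo SNR, the two-stage estimator is run on a single analysis
#' window, and the lateral/axial error variances are compared with the
#' Cramer-Rao bounds for the same window and SNR.
#'
#' @param preset a [pd_preset()] list (the 5-MHz preset is the validated
#'   configuration)
#' @param snr_db SNR values (dB)
#' @param n_trials trials per SNR point
#' @param window_mm analysis window side (mm); also the X0 = Z0 of the bound
#' @param frame_mm simulated frame extent
#' @param seed master seed
#' @return data.frame with one row per SNR: measured `var_x`, `var_z`
#'   (mm^2), mean errors `bias_x`, `bias_z`, bound values `crlb_x`,
#'   `crlb_z`, and `n`
#' @export
efficiency_experiment <- function(preset, snr_db = c(20, 25, 30),
                                  n_trials = 100, window_mm = 1,
                                  frame_mm = c(3, 3), seed = 1) {
  pulse <- preset$pulse
  grid <- preset_grid(preset, frame_mm, M = 1)
  cfg <- reg_config(window_mm = window_mm)
  wins <- window_plan(grid, reg_config(window_mm = window_mm, layout = c(1, 1)))
  win <- wins[[1]]
  err <- array(NA_real_, c(n_trials, length(snr_db), 2))
  for (t in seq_len(n_trials)) {
    fs <- seed * 10000L + t
    field <- clutter_field_for(preset, frame_mm, seed = fs, elev_mm = 3)
    set.seed(fs + 1L)
    d_true <- c(runif(1, -0.5, 0.5) * grid$X, runif(1, -0.5, 0.5) * grid$dz)
    f1 <- render_frames(field, motion_model(), pulse, grid)[, , 1]
    field2 <- field
    field2$positions <- sweep(field$positions, 2, c(d_true[1], 0, d_true[2]), "+")
    f2 <- render_frames(field2, motion_model(), pulse, grid)[, , 1]
    p_sig <- mean(c(f1^2, f2^2))
    for (j in seq_along(snr_db)) {
      s2 <- p_sig / 10^(snr_db[j] / 10)
      set.seed(fs + 100L * j)
      n1 <- matrix(rnorm(length(f1), sd = sqrt(s2)), nrow(f1))
      n2 <- matrix(rnorm(length(f2), sd = sqrt(s2)), nrow(f2))
      est <- estimate_window_shift(f1 + n1, f2 + n2, win, cfg)
      err[t, j, 1] <- est[2] * grid$X - d_true[1]   # lateral
      err[t, j, 2] <- est[1] * grid$dz - d_true[2]  # axial
    }
  }
  out <- data.frame(snr_db = snr_db)
  for (j in seq_along(snr_db)) {
    b <- variance_bounds(spectral_model(pulse, grid$Bx, grid$Bz, snr_db[j],
                                        X0 = window_mm, Z0 = window_mm))
    out$var_x[j] <- var(err[, j, 1]); out$var_z[j] <- var(err[, j, 2])
    out$bias_x[j] <- mean(err[, j, 1]); out$bias_z[j] <- mean(err[, j, 2])
    out$crlb_x[j] <- b$var_lateral; out$crlb_z[j] <- b$var_axial
  }
  out$n <- n_trials
  out
}

#' Component-wise power states for one seeded perfusion simulation
#'
#' Renders noise-free clutter and blood components on a shared grid, draws
#' one calibrated noise field, builds the registered + filtered states that
#' measure blood power (`fr b`, `fr b+n`, `fr c+b+n`), SVD-filters each with
#' every requested eigenindex band, and reports net power over the perfused
#' ROI relative to the unfiltered blood-only power. Use [net_power_report()]
#' for the full nine-state table of a single band.
#'
#' @param preset a [pd_preset()] list
#' @param blood "diffuse" or "directed" perfusion at `blood_speed` mm/s
#' @param bands list of `c(lo, hi)` eigenindex bands
#' @param seed seed for the field, blood directions and noise
#' @param M ensemble frames
#' @param frame_mm frame extent
#' @param blood_speed blood-cell speed (mm/s)
#' @param clutter clutter program (default 1-Hz elliptical oscillation,
#'   0.05 / 0.025 mm half-amplitudes)
#' @param guard_mm frame-edge strip excluded from power integrals (mm)
#' @param config registration configuration
#' @return data.frame with columns `state` (`fr b`, `fr b+n`, `fr c+b+n`),
#'   `band` and `power_db_rel_blood`, plus attribute `unfiltered` (the
#'   unregistered/unfiltered state powers c, n, b, c+b+n in dB relative to
#'   blood)
#' @export
power_state_experiment <- function(preset, blood = c("diffuse", "directed"),
                                   bands = list(c(2, 6), c(2, 11)), seed = 1,
                                   M = 21, frame_mm = c(10, 10),
                                   blood_speed = 0.2,
                                   clutter = clutter_elliptical(),
                                   guard_mm = 0.5, config = reg_config()) {
  blood <- match.arg(blood)
  pulse <- preset$pulse
  grid <- preset_grid(preset, frame_mm, M = M)
  field <- scatterer_field(pulse, tau_beta = preset$tau_beta, seed = seed)
  roi <- field$roi
  field_t <- subset_field(field, "tissue")
  field_b <- subset_field(field, "blood")
  bl <- if (blood == "diffuse") blood_diffuse(blood_speed)
        else blood_directed(blood_speed)
  motion_b <- realize_motion(field_b, motion_model(clutter, bl), seed = seed)
  gC <- render_frames(field_t, motion_model(clutter), pulse, grid)
  gB <- render_frames(field_b, motion_b, pulse, grid)
  s2 <- calibrate_noise(gC + gB, preset$snr_db)
  set.seed(seed + 20000L)
  nz <- array(rnorm(length(gC), sd = sqrt(s2)), dim = dim(gC))

  msk <- as.vector(roi_mask(grid, roi, guard_mm))
  p_b <- mean(matrix(gB, ncol = M)[msk, ]^2)
  # displacement is estimated once from the clutter-bearing combined signal
  # (registration tracks the echogenic clutter) and the same alignment is
  # applied to every component state so the power decomposition is consistent
  comb <- as_ensemble(gC + gB + nz, grid, pulse, roi = roi)
  disp <- register_ensemble(comb, config)$displacement
  comps <- list(`fr b` = gB, `fr b+n` = gB + nz, `fr c+b+n` = gC + gB + nz)
  rows <- list()
  for (st in names(comps)) {
    ens <- as_ensemble(comps[[st]], grid, pulse, roi = roi)
    reg <- apply_displacement(ens, disp)
    dec <- eigen_decompose(reg, roi, guard_mm)
    for (b in bands) {
      f <- apply_filter(reg, dec, filter_band(b[1], b[2]))
      rows[[length(rows) + 1]] <- data.frame(
        state = st, band = paste0(b[1], "-", b[2]),
        power_db_rel_blood = 10 * log10(net_power(f, roi, guard_mm) / p_b))
    }
  }
  out <- do.call(rbind, rows)
  unf <- c(c = mean(matrix(gC, ncol = M)[msk, ]^2),
           n = s2, b = p_b,
           `c+b+n` = mean(matrix(gC + gB + nz, ncol = M)[msk, ]^2))
  attr(out, "unfiltered") <- 10 * log10(unf / p_b)
  out
}

#' Mean blood-power underestimate across the filtered states
#'
#' Seed-averaged mean, over the registered + filtered states that contain a
#' blood component (`fr b`, `fr b+n`, `fr c+b+n`), of net power relative to
#' the unfiltered blood-only power. This is the summary the diffuse-perfusion
#' filter settings are judged by (about -3 dB with eigenindices 2-6 retained
#' and about -2 dB with 2-11 out of a 21-frame ensemble).
#'
#' @inheritParams power_state_experiment
#' @param seeds seeds to average over
#' @return data.frame with columns `band`, `mean_db` (average over states
#'   and seeds), `sd_db` (between-seed sd of the state-mean)
#' @export
blood_power_underestimate <- function(preset, blood = "diffuse",
                                      bands = list(c(2, 6), c(2, 11)),
                                      seeds = 1:10, ...) {
  per_seed <- lapply(seeds, function(s) {
    r <- power_state_experiment(preset, blood, bands, seed = s, ...)
    stats::aggregate(power_db_rel_blood ~ band, data = r, FUN = mean)
  })
  all <- do.call(rbind, per_seed)
  agg <- stats::aggregate(power_db_rel_blood ~ band, data = all,
                          FUN = function(v) c(mean(v), sd(v)))
  data.frame(band = agg$band,
             mean_db = agg$power_db_rel_blood[, 1],
             sd_db = agg$power_db_rel_blood[, 2])
}

#' Interframe correlation and in-plane bias under elevational motion
#'
#' The transducer translates purely along the elevational (y) axis in equal
#' steps while clutter-only frames are recorded; in-plane motion truth is
#' zero. Returns the interframe correlation rho(y) of each frame against the
#' first (averaged over seeds) and, optionally, the single-window in-plane
#' displacement estimates whose mean should stay at zero while rho > 0.5.
#'
#' @param preset a [pd_preset()] list; the 20-MHz preset runs through the IQ
#'   path (noise added on RF before demodulation)
#' @param y_max,n_steps elevational sweep extent (mm) and number of steps
#' @param seeds seeds to average over
#' @param frame_mm frame extent (kept small; rho is frame-size independent)
#' @param estimate_bias also run the displacement estimator at each y
#' @param window_mm estimator window for the bias check
#' @return data.frame with columns `y`, `rho` (+ `rho_sd`), and when
#'   requested `est_x`, `est_z` means and `sd_x`, `sd_z` over seeds;
#'   attribute `crossing` holds the rho = 0.5 crossing (mm)
#' @export
elevation_sweep <- function(preset, y_max, n_steps = 20, seeds = 1:3,
                            frame_mm = c(5, 5), estimate_bias = FALSE,
                            window_mm = 2) {
  pulse <- preset$pulse
  M <- n_steps + 1
  grid <- preset_grid(preset, frame_mm, M = M)
  y <- seq(0, y_max, length.out = M)
  vy <- y_max / ((M - 1) * grid$Tm)
  cfg <- reg_config(window_mm = window_mm, layout = c(1, 1))
  win <- NULL  # planned on the (possibly IQ-decimated) grid of the first run
  rho <- est_x <- est_z <- matrix(NA_real_, length(seeds), M)
  for (i in seq_along(seeds)) {
    field <- clutter_field_for(preset, frame_mm, seed = seeds[i],
                               elev_mm = 4 + 2 * y_max)
    motion <- motion_model(clutter_linear(c(0, vy, 0)))
    g <- render_frames(field, motion, pulse, grid)
    s2 <- calibrate_noise(g, preset$snr_db)
    set.seed(seeds[i] + 30000L)
    g <- g + array(rnorm(length(g), sd = sqrt(s2)), dim = dim(g))
    ens <- as_ensemble(g, grid, pulse)
    if (identical(preset$modality, "IQ")) ens <- to_iq(ens, preset$iq_decimation)
    gm <- ens$samples
    mask <- roi_mask(ens$grid, NULL, 0.25)
    rho[i, ] <- vapply(seq_len(M), function(m)
      interframe_rho(gm[, , 1], gm[, , m], mask), numeric(1))
    if (estimate_bias) {
      if (is.null(win)) win <- window_plan(ens$grid, cfg)[[1]]
      for (m in 2:M) {
        e <- estimate_window_shift(gm[, , 1], gm[, , m], win, cfg)
        est_z[i, m] <- e[1] * ens$grid$dz; est_x[i, m] <- e[2] * ens$grid$X
      }
      est_x[i, 1] <- est_z[i, 1] <- 0
    }
  }
  out <- data.frame(y = y, rho = colMeans(rho),
                    rho_sd = apply(rho, 2, sd))
  if (estimate_bias) {
    out$est_x <- colMeans(est_x); out$est_z <- colMeans(est_z)
    out$sd_x <- apply(est_x, 2, sd); out$sd_z <- apply(est_z, 2, sd)
  }
  attr(out, "crossing") <- rho_crossing(out$y, out$rho, 0.5)
  out
}

#' Post-registration lateral decorrelation curve rho(x)
#'
#' The transducer translates along the lateral axis (optionally with a
#' coupled elevational drift `y_drift_per_mm`); frames are registered to the
#' first frame by cumulative frame-to-frame tracking, and the interframe
#' correlation of the aligned frames against frame 1 is computed over the
#' region that stays inside the frame for the whole sweep.
#'
#' @param preset a [pd_preset()] list
#' @param x_max total lateral travel (mm)
#' @param n_steps frames after the first
#' @param y_drift_per_mm elevational drift per mm of lateral travel
#' @param seed RNG seed
#' @param frame_mm frame extent
#' @param config registration configuration
#' @return data.frame with columns `x`, `rho`; attribute `displacement`
#'   holds the registration trace
#' @export
lateral_decorrelation <- function(preset, x_max = 2, n_steps = 20,
                                  y_drift_per_mm = 0, seed = 1,
                                  frame_mm = c(10, 10),
                                  config = reg_config()) {
  pulse <- preset$pulse
  M <- n_steps + 1
  grid <- preset_grid(preset, frame_mm, M = M)
  vx <- x_max / ((M - 1) * grid$Tm)
  field <- clutter_field_for(preset, frame_mm, extra_mm = c(2 * x_max, 0),
                             seed = seed, elev_mm = 4 + 2 * y_drift_per_mm * x_max)
  motion <- motion_model(clutter_linear(c(vx, y_drift_per_mm * vx, 0)))
  g <- render_frames(field, motion, pulse, grid)
  s2 <- calibrate_noise(g, preset$snr_db)
  set.seed(seed + 40000L)
  g <- g + array(rnorm(length(g), sd = sqrt(s2)), dim = dim(g))
  ens <- as_ensemble(g, grid, pulse)
  reg <- register_ensemble(ens, config, cumulative = TRUE)
  ga <- reg$ensemble$samples
  # content moves +x and alignment samples from +x; the right-hand strip of
  # width x_max is extrapolated, so exclude it (plus an edge guard)
  mask <- roi_mask(grid, list(x = c(min(grid$x) + 0.5,
                                    max(grid$x) - x_max - 0.5),
                              z = c(min(grid$z) + 0.5, max(grid$z) - 0.5)))
  x <- (seq_len(M) - 1) * vx * grid$Tm
  rho <- vapply(seq_len(M), function(m)
    interframe_rho(ga[, , 1], ga[, , m], mask), numeric(1))
  out <- data.frame(x = x, rho = rho)
  attr(out, "displacement") <- reg$displacement
  out
}

#' Standard error of displacement estimates versus independent sample count
#'
#' Clutter-only frames decorrelate through a small elevational drift while
#' the in-plane truth stays zero; displacement is estimated with a single
#' centered window of each requested size, and the standard error of the
#' (detrended) estimates is related to the independent-sample count
#' `N = (X0 Z0) / A_2D` by a log-log regression.
#'
#' @param preset a [pd_preset()] list
#' @param window_sizes window sides (mm)
#' @param seeds seeds (one short sweep per seed)
#' @param y_max total elevational drift (mm)
#' @param n_steps frames after the first
#' @param frame_mm frame extent
#' @return list: `table` (window size, N, sigma_x, sigma_z), `slope_x`,
#'   `slope_z`, `slope` (mean of the two log-log slopes)
#' @export
sample_size_scaling <- function(preset,
                                window_sizes = c(0.5, 1, 1.5, 2, 2.5),
                                seeds = 1:12, y_max = 0.15, n_steps = 5,
                                frame_mm = c(4, 4)) {
  stopifnot(length(window_sizes) >= 3)
  pulse <- preset$pulse
  M <- n_steps + 1
  grid <- preset_grid(preset, frame_mm, M = M)
  vy <- y_max / ((M - 1) * grid$Tm)
  cfgs <- lapply(window_sizes, function(w)
    reg_config(window_mm = w, layout = c(1, 1)))
  wins <- lapply(cfgs, function(cf) window_plan(grid, cf)[[1]])
  ex <- ez <- array(NA_real_, c(length(seeds), length(window_sizes), M - 1))
  for (i in seq_along(seeds)) {
    field <- clutter_field_for(preset, frame_mm, seed = 100L + seeds[i],
                               elev_mm = 4 + 2 * y_max)
    motion <- motion_model(clutter_linear(c(0, vy, 0)))
    g <- render_frames(field, motion, pulse, grid)
    s2 <- calibrate_noise(g, preset$snr_db)
    set.seed(seeds[i] + 50000L)
    g <- g + array(rnorm(length(g), sd = sqrt(s2)), dim = dim(g))
    for (j in seq_along(window_sizes)) {
      for (m in 2:M) {
        e <- estimate_window_shift(g[, , 1], g[, , m], wins[[j]], cfgs[[j]])
        ez[i, j, m - 1] <- e[1] * grid$dz
        ex[i, j, m - 1] <- e[2] * grid$X
      }
    }
  }
  N <- pmax(1, window_sizes^2 / pulse$a2d)
  sig <- function(e) apply(e, 2, function(v) sd(as.vector(v)))
  sigma_x <- sig(ex); sigma_z <- sig(ez)
  if (length(unique(N)) < 3) stop("degenerate N range")
  slope_x <- coef(lm(log(sigma_x) ~ log(N)))[[2]]
  slope_z <- coef(lm(log(sigma_z) ~ log(N)))[[2]]
  list(table = data.frame(window_mm = window_sizes, N = N,
                          sigma_x = sigma_x, sigma_z = sigma_z),
       slope_x = slope_x, slope_z = slope_z,
       slope = mean(c(slope_x, slope_z)))
}
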