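# Random tissue/blood scatterer configurations and their motion programs.
#
# Coordinates: x lateral, y elevational, z axial (beam direction), all mm,
# origin at the center of the scattering volume.

#' Generate a random perfused-tissue scatterer field
#'
#' Tissue scatterers are drawn as a Poisson point process filling the volume;
#' blood scatterers are drawn with the same number density (tissue/blood
#' density ratio 1) but restricted to a perfusion region of interest. The
#' expected density is `scatterers_per_pulse / a3d`, so that every pulse
#' resolution cell holds at least `scatterers_per_pulse` scatterers on
#' average and the echoes are fully developed speckle.
#'
#' @param pulse a [pulse_spec()]; supplies the speckle correlation volume
#' @param volume_dims (Lx, Ly, Lz) extents of the scattering volume (mm);
#'   default 14 x 5 x 14 with the scan plane spanning x-z (the two 14-mm
#'   axes) and 5 mm of elevational thickness
#' @param scatterers_per_pulse target mean scatterers per resolution cell
#' @param tau_beta tissue-to-blood reflectivity ratio (tau/beta); blood
#'   reflectivity is fixed at 1
#' @param roi perfusion region: a list with elements `x = c(lo, hi)` and
#'   `z = c(lo, hi)` (mm); blood fills the full elevational thickness.
#'   `NULL` gives the default central band 4 mm wide in x spanning z;
#'   `list()` (empty) gives no perfusion.
#' @param seed RNG seed (integer); fields are bit-reproducible given the seed
#' @return an object of class `scatterer_field`: list with `positions`
#'   (n x 3 matrix, mm), `amplitudes` (tau or 1), `labels`
#'   ("tissue"/"blood"), `volume_dims`, `roi`, `density` (mm^-3), `seed`
#' @export
scatterer_field <- function(pulse, volume_dims = c(14, 5, 14),
                            scatterers_per_pulse = 20, tau_beta = 16,
                            roi = NULL, seed = 1) {
  stopifnot(inherits(pulse, "pulse_spec"))
  if (length(volume_dims) != 3 || any(volume_dims <= 0))
    stop("volume_dims must be three positive extents")
  if (scatterers_per_pulse < 1) stop("need at least 1 scatterer per pulse")
  half <- volume_dims / 2
  if (is.null(roi)) {
    # central 4-mm-wide perfusion band, spanning the default 10-mm frame axially
    roi <- list(x = c(-2, 2), z = c(-min(5, half[3]), min(5, half[3])))
  }
  if (length(roi)) {
    if (roi$x[1] < -half[1] || roi$x[2] > half[1] ||
        roi$z[1] < -half[3] || roi$z[2] > half[3])
      stop("perfusion roi extends outside the scattering volume")
  }

  density <- scatterers_per_pulse / pulse$a3d
  set.seed(seed)
  n_t <- rpois(1, density * prod(volume_dims))
  pos_t <- cbind(runif(n_t, -half[1], half[1]),
                 runif(n_t, -half[2], half[2]),
                 runif(n_t, -half[3], half[3]))

  if (length(roi) && diff(roi$x) > 0 && diff(roi$z) > 0) {
    v_roi <- diff(roi$x) * volume_dims[2] * diff(roi$z)
    n_b <- rpois(1, density * v_roi)
  } else n_b <- 0L
  pos_b <- if (n_b > 0) cbind(runif(n_b, roi$x[1], roi$x[2]),
                              runif(n_b, -half[2], half[2]),
                              runif(n_b, roi$z[1], roi$z[2]))
           else matrix(0, 0, 3)

  structure(list(
    positions = rbind(pos_t, pos_b),
    amplitudes = c(rep(tau_beta, n_t), rep(1, n_b)),
    labels = c(rep("tissue", n_t), rep("blood", n_b)),
    volume_dims = volume_dims, roi = roi,
    density = density, seed = seed
  ), class = "scatterer_field")
}

#' Keep only one scatterer component
#'
#' @param field a `scatterer_field`
#' @param label "tissue" or "blood"
#' @return the sub-field with only the requested component (same class)
#' @export
subset_field <- function(field, label) {
  stopifnot(inherits(field, "scatterer_field"))
  keep <- field$labels == match.arg(label, c("tissue", "blood"))
  field$positions <- field$positions[keep, , drop = FALSE]
  field$amplitudes <- field$amplitudes[keep]
  field$labels <- field$labels[keep]
  field
}

#' @export
print.scatterer_field <- function(x, ...) {
  cat(sprintf("scatterer field: %d tissue + %d blood in %g x %g x %g mm (seed %d)\n",
              sum(x$labels == "tissue"), sum(x$labels == "blood"),
              x$volume_dims[1], x$volume_dims[2], x$volume_dims[3], x$seed))
  invisible(x)
}

# ---- motion programs --------------------------------------------------------

#' Motion model for clutter (tissue) and blood scatterers
#'
#' Tissue scatterers translate rigidly (all share one velocity at any time).
#' Blood-cell velocities are superposed on the tissue velocity, so blood
#' perfuses the moving tissue.
#'
#' @param clutter one of [clutter_none()], [clutter_linear()],
#'   [clutter_elliptical()]
#' @param blood one of [blood_none()], [blood_directed()], [blood_diffuse()]
#' @return an object of class `motion_model`
#' @export
motion_model <- function(clutter = clutter_none(), blood = blood_none()) {
  structure(list(clutter = clutter, blood = blood, blood_velocities = NULL),
            class = "motion_model")
}

#' @rdname motion_model
#' @export
clutter_none <- function() list(type = "none")

#' @param v 3-vector velocity (mm/s)
#' @rdname motion_model
#' @export
clutter_linear <- function(v) {
  stopifnot(length(v) == 3, all(is.finite(v)))
  list(type = "linear", v = as.numeric(v))
}

#' @param freq oscillation frequency (Hz)
#' @param amp_x,amp_z in-plane half-amplitudes of the elliptical trace (mm)
#' @rdname motion_model
#' @export
clutter_elliptical <- function(freq = 1, amp_x = 0.05, amp_z = 0.025) {
  stopifnot(freq > 0, amp_x >= 0, amp_z >= 0)
  list(type = "elliptical", freq = freq, amp_x = amp_x, amp_z = amp_z)
}

#' @rdname motion_model
#' @export
blood_none <- function() list(type = "none")

#' @param speed blood-cell speed (mm/s); every cell moves at exactly this speed
#' @param cone_half_angle angular spread about `axis` (degrees)
#' @param axis mean flow direction (3-vector, need not be unit length)
#' @rdname motion_model
#' @export
blood_directed <- function(speed, cone_half_angle = 15, axis = c(0, 0, 1)) {
  stopifnot(speed >= 0, cone_half_angle >= 0, cone_half_angle <= 90)
  list(type = "directed", speed = speed,
       cone_half_angle = cone_half_angle, axis = axis / sqrt(sum(axis^2)))
}

#' @rdname motion_model
#' @export
blood_diffuse <- function(speed) {
  stopifnot(speed >= 0)
  list(type = "diffuse", speed = speed)
}

#' Rigid clutter offset from the frame-1 position at time t
#'
#' @param clutter a clutter program (see [motion_model()])
#' @param t time since frame 1 (s)
#' @return 3-vector displacement (mm)
#' @export
clutter_offset <- function(clutter, t) {
  switch(clutter$type,
    none = c(0, 0, 0),
    linear = clutter$v * t,
    elliptical = {
      p <- function(tt) c(clutter$amp_x * cos(2 * pi * clutter$freq * tt), 0,
                          clutter$amp_z * sin(2 * pi * clutter$freq * tt))
      p(t) - p(0)
    },
    stop("unknown clutter program"))
}

#' In-plane velocity of the elliptical clutter program
#'
#' Position trace `(amp_x cos 2 pi f t, 0, amp_z sin 2 pi f t)`; the velocity
#' is its time derivative. Period is `1/freq`.
#'
#' @param t time (s), vectorized
#' @param freq oscillation frequency (Hz)
#' @param amp_x,amp_z half-amplitudes (mm)
#' @return length(t) x 3 matrix of velocities (mm/s)
#' @export
elliptical_clutter_velocity <- function(t, freq = 1, amp_x = 0.05, amp_z = 0.025) {
  stopifnot(freq > 0)
  w <- 2 * pi * freq
  cbind(-amp_x * w * sin(w * t), 0, amp_z * w * cos(w * t))
}

#' Sample directed blood-cell velocities in a cone
#'
#' Each velocity has magnitude `speed`; the polar angle from the mean axis is
#' uniform in `[0, cone_half_angle]` and the azimuth uniform in `[0, 2 pi)`.
#'
#' @param n number of cells
#' @param speed cell speed (mm/s)
#' @param cone_half_angle degrees, in [0, 90]
#' @param axis mean direction
#' @param seed optional RNG seed
#' @return n x 3 matrix of velocities
#' @export
sample_directed_velocities <- function(n, speed, cone_half_angle = 15,
                                       axis = c(0, 0, 1), seed = NULL) {
  stopifnot(cone_half_angle >= 0, cone_half_angle <= 90)
  if (!is.null(seed)) set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  theta <- runif(n, 0, cone_half_angle * pi / 180)
  psi <- runif(n, 0, 2 * pi)
  # local frame around the axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  d <- outer(cos(theta), axis) +
       outer(sin(theta) * cos(psi), e1) +
       outer(sin(theta) * sin(psi), e2)
  speed * d
}

#' Sample diffuse blood-cell velocities (uniform directions on the sphere)
#'
#' @inheritParams sample_directed_velocities
#' @return n x 3 matrix of velocities; the ensemble-mean velocity converges
#'   to zero as n grows
#' @export
sample_diffuse_velocities <- function(n, speed, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n, -1, 1)          # cos(polar) uniform => uniform on sphere
  psi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  speed * cbind(s * cos(psi), s * sin(psi), u)
}

#' Materialize per-cell blood velocities for a field
#'
#' Blood directions are drawn once and frozen for the whole ensemble (cells
#' follow constant-velocity tracks between frames).
#'
#' @param field a `scatterer_field`
#' @param motion a `motion_model`
#' @param seed RNG seed for the direction draw
#' @return the motion model with `blood_velocities` filled (n_blood x 3)
#' @export
realize_motion <- function(field, motion, seed = 1) {
  stopifnot(inherits(field, "scatterer_field"), inherits(motion, "motion_model"))
  nb <- sum(field$labels == "blood")
  b <- motion$blood
  motion$blood_velocities <- switch(b$type,
    none = matrix(0, nb, 3),
    directed = sample_directed_velocities(nb, b$speed, b$cone_half_angle,
                                          b$axis, seed = seed),
    diffuse = sample_diffuse_velocities(nb, b$speed, seed = seed),
    stop("unknown blood program"))
  motion
}

#' Advance scatterer positions to frame m
#'
#' Tissue: `x_p(t_m) = x_p(t_1) + offset(t_m)` with the rigid clutter offset.
#' Blood: the per-cell velocity is superposed on the clutter motion,
#' `x_q(t_m) = x_q(t_1) + offset(t_m) + (m - 1) T_m v_q`.
#' Scatterers may leave the volume; they are neither wrapped nor respawned
#' (drift over a 2-s ensemble is far below the guard margin).
#'
#' @param field a `scatterer_field`
#' @param motion a `motion_model`, realized via [realize_motion()] if blood
#'   is present
#' @param m frame index (1-based)
#' @param Tm frame interval (s)
#' @return n x 3 matrix of positions at frame m
#' @export
advance <- function(field, motion, m, Tm) {
  stopifnot(m >= 1)
  t <- (m - 1) * Tm
  pos <- field$positions
  off <- clutter_offset(motion$clutter, t)
  pos <- sweep(pos, 2, off, "+")
  is_b <- field$labels == "blood"
  if (any(is_b)) {
    v <- motion$blood_velocities
    if (is.null(v)) stop("blood motion present: call realize_motion() first")
    pos[is_b, ] <- pos[is_b, , drop = FALSE] + t * v
  }
  pos
}
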