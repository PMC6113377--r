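# Closed-form magnetic field of a current dipole in a spherical conductor
# (the Sarvas solution). Only the tangential component of the primary
# current produces external field; a radial dipole is silent, and volume
# currents contribute no radial field component. Internally SI units
# (m, A m, T); the API takes cm and nA m.

# Vectorized Sarvas field. dip_pos: n x 3 dipole positions (m, sphere
# frame), moments: n x 3 (A m), sensors: m x 3 coil positions (m, sphere
# frame). Returns an n x m x 3 array of B (tesla) if n > 1, else m x 3.
sarvas_field <- function(dip_pos, moments, sensor) {
  r <- as.numeric(sensor)                 # one sensor at a time (length 3)
  rn <- vnorm(r)
  r0 <- dip_pos                           # n x 3
  a_vec <- matrix(r, nrow(r0), 3, byrow = TRUE) - r0
  a <- row_norms(a_vec)
  r0_dot_r <- drop(r0 %*% r)
  a_dot_r <- drop(a_vec %*% r)
  F_s <- a * (rn * a + rn^2 - r0_dot_r)
  cF1 <- a^2 / rn + a_dot_r / a + 2 * a + 2 * rn
  cF2 <- a + 2 * rn + a_dot_r / a
  gradF <- cF1 %o% r - cF2 * r0           # n x 3
  Qxr0 <- cross3_rows(moments, r0)        # n x 3
  Qxr0_dot_r <- drop(Qxr0 %*% r)
  (MU0_OVER_4PI / F_s^2) * (F_s * Qxr0 - Qxr0_dot_r * gradF)
}

#' Magnetic field of a current dipole at a set of coils
#'
#' Evaluates the spherical-conductor closed-form solution in
#' sphere-centred coordinates. The field is linear in the dipole moment;
#' a dipole oriented along the radial direction produces no external
#' field.
#'
#' @param position dipole position, cm head frame.
#' @param moment dipole moment vector, nA m.
#' @param sphere_origin conductor sphere origin, cm head frame.
#' @param coil_positions m x 3 coil positions, cm head frame.
#' @param sphere_radius optional radius, cm; when given, positions are
#'   validated (dipole strictly inside, coils outside).
#' @return m x 3 matrix of field vectors, tesla.
#' @export
dipole_field <- function(position, moment, sphere_origin, coil_positions,
                         sphere_radius = NULL) {
  r0 <- (as.numeric(position) - as.numeric(sphere_origin)) * CM_TO_M
  if (vnorm(r0) < 1e-9)
    stop("dipole at the sphere origin: radial direction undefined")
  coil_positions <- as.matrix(coil_positions)
  sens <- sweep(coil_positions, 2, as.numeric(sphere_origin)) * CM_TO_M
  if (!is.null(sphere_radius)) {
    rr <- sphere_radius * CM_TO_M
    if (vnorm(r0) >= rr) stop("dipole must lie strictly inside the sphere")
    if (any(row_norms(sens) <= rr)) stop("all coils must lie outside the sphere")
  }
  Q <- matrix(as.numeric(moment) * NAM_TO_AM, 1, 3)
  out <- t(vapply(seq_len(nrow(sens)), function(j)
    drop(sarvas_field(matrix(r0, 1, 3), Q, sens[j, ])), numeric(3)))
  out
}

#' Channel response from per-coil fields
#'
#' Projects coil field vectors onto the channel geometry: a magnetometer
#' reads its single coil's projection onto the coil orientation; an axial
#' gradiometer reads the difference of the two coil projections
#' (rejecting uniform fields).
#'
#' @param field_coil1,field_coil2 n x 3 field vectors at the first and
#'   (for gradiometers) second coil.
#' @param channels a [channel_info()] table (n rows).
#' @return Numeric vector of channel readings, tesla.
#' @export
channel_response <- function(field_coil1, field_coil2, channels) {
  field_coil1 <- as.matrix(field_coil1)
  proj1 <- rowSums(field_coil1 * channels$orientation)
  grad <- channels$kind == "meg_gradiometer"
  out <- proj1
  if (any(grad)) {
    field_coil2 <- as.matrix(field_coil2)
    proj2 <- rowSums(field_coil2 * channels$orientation)
    out[grad] <- proj1[grad] - proj2[grad]
  }
  out
}

# Forward field of one dipole across the full channel array (tesla).
forward_channels <- function(position, moment, model, channels) {
  use <- which(meg_channel_mask(channels))
  ch <- channels[use, , drop = FALSE]
  vals <- vapply(seq_len(nrow(ch)), function(i) {
    sph <- sphere_for_channel(model, ch$name[i])
    b1 <- dipole_field(position, moment, sph$origin,
                       ch$coil1[i, , drop = FALSE])
    v <- sum(b1 * ch$orientation[i, ])
    if (ch$kind[i] == "meg_gradiometer") {
      b2 <- dipole_field(position, moment, sph$origin,
                         ch$coil2[i, , drop = FALSE])
      v <- v - sum(b2 * ch$orientation[i, ])
    }
    v
  }, numeric(1))
  out <- numeric(nrow(channels))
  out[use] <- vals
  out
}

#' Lead field at a source point
#'
#' Field patterns (T per nA m) of two orthonormal tangential unit dipoles
#' at `point`. The tangential basis is taken with respect to the default
#' sphere; with a multi-sphere model each channel's field uses its own
#' local sphere. The radial orientation is silent by construction, so two
#' columns span all reachable source orientations.
#'
#' @param point source position, cm head frame.
#' @param model a [head_model()].
#' @param channels a [channel_info()] table.
#' @param active_rows optional channel row indices to include (default:
#'   all non-excluded MEG channels).
#' @return List of class `lead_field` with `L` (channels x 2, T/nA m),
#'   `basis` (2 x 3 tangential unit vectors), `radial` (unit vector).
#' @export
lead_field_at <- function(point, model, channels, active_rows = NULL) {
  if (is.null(active_rows)) active_rows <- active_meg_channels(channels)
  basis <- tangential_basis(point, model$origin)
  f1 <- forward_channels(point, basis$t1, model, channels)[active_rows]
  f2 <- forward_channels(point, basis$t2, model, channels)[active_rows]
  structure(list(L = cbind(f1, f2, deparse.level = 0),
                 basis = rbind(basis$t1, basis$t2, deparse.level = 0),
                 radial = basis$radial, point = as.numeric(point)),
            class = "lead_field")
}

# Lead fields for many points at once, vectorized over points per coil.
# points: V x 3 (cm head frame). Returns list(L1, L2): V x nchan matrices
# (T per nA m for the t1/t2 tangential unit moments), plus basis arrays.
lead_field_matrix <- function(points, model, channels, active_rows = NULL) {
  if (is.null(active_rows)) active_rows <- active_meg_channels(channels)
  ch <- channels[active_rows, , drop = FALSE]
  V <- nrow(points)
  # per-point tangential basis w.r.t. default sphere
  t1 <- matrix(0, V, 3); t2 <- matrix(0, V, 3)
  for (v in seq_len(V)) {
    b <- tangential_basis(points[v, ], model$origin)
    t1[v, ] <- b$t1; t2[v, ] <- b$t2
  }
  nch <- nrow(ch)
  L1 <- matrix(0, V, nch); L2 <- matrix(0, V, nch)
  multi <- !is.null(model$channel_spheres)
  for (i in seq_len(nch)) {
    sph <- if (multi) sphere_for_channel(model, ch$name[i])
           else list(origin = model$origin)
    r0 <- sweep(points, 2, sph$origin) * CM_TO_M
    o <- ch$orientation[i, ]
    c1 <- (ch$coil1[i, ] - sph$origin) * CM_TO_M
    b1_t1 <- sarvas_field(r0, t1 * NAM_TO_AM, c1)
    b1_t2 <- sarvas_field(r0, t2 * NAM_TO_AM, c1)
    v1 <- drop(b1_t1 %*% o); v2 <- drop(b1_t2 %*% o)
    if (ch$kind[i] == "meg_gradiometer") {
      c2 <- (ch$coil2[i, ] - sph$origin) * CM_TO_M
      v1 <- v1 - drop(sarvas_field(r0, t1 * NAM_TO_AM, c2) %*% o)
      v2 <- v2 - drop(sarvas_field(r0, t2 * NAM_TO_AM, c2) %*% o)
    }
    L1[, i] <- v1; L2[, i] <- v2
  }
  list(L1 = L1, L2 = L2, t1 = t1, t2 = t2)
}
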