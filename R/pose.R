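#' Eye pose
#'
#' An orthonormal frame anchored at the eye center: \code{forward} is the ray
#' pointing directly in front of the eye (polar angle \eqn{\theta} is measured
#' away from it), \code{temporal} points horizontally away from the nose and
#' defines \eqn{\phi = 0}, and \code{up} sits at \eqn{\phi = 90^\circ} under
#' the default counter-clockwise azimuth convention (as seen looking outward
#' along \code{forward}).
#'
#' @param origin eye center, length-3 numeric (mm).
#' @param forward,up unit vectors; must be orthonormal to within 1e-9.
#' @param temporal optional unit vector; defaults to \code{up x forward},
#'   which for a right eye with nose on its nasal side points away from the
#'   nose.
#' @param chirality +1 for the default counter-clockwise azimuth sense
#'   (temporal 0, superior 90, nasal 180, inferior 270 degrees), -1 to flip.
#' @return An object of class \code{"eye_pose"}.
#' @export
eye_pose <- function(origin, forward, up, temporal = NULL, chirality = 1L) {
  origin <- as.numeric(origin); forward <- as.numeric(forward)
  up <- as.numeric(up)
  if (length(origin) != 3L || length(forward) != 3L || length(up) != 3L)
    stop("origin, forward and up must be length-3 numerics")
  if (is.null(temporal)) temporal <- cross3(up, forward)
  temporal <- as.numeric(temporal)
  if (!chirality %in% c(-1L, 1L)) stop("chirality must be +1 or -1")
  tol <- 1e-9
  for (v in list(forward, up, temporal))
    if (abs(sqrt(sum(v^2)) - 1) > tol)
      stop("eye pose axes must be unit vectors (tolerance 1e-9)")
  if (abs(sum(forward * up)) > tol || abs(sum(forward * temporal)) > tol ||
      abs(sum(up * temporal)) > tol)
    stop("eye pose axes must be mutually orthogonal (tolerance 1e-9)")
  structure(list(origin = origin, forward = forward, up = up,
                 temporal = temporal, chirality = as.integer(chirality)),
            class = "eye_pose")
}

#' @export
print.eye_pose <- function(x, ...) {
  cat("Eye pose at (", paste(signif(x$origin, 5), collapse = ", "), ") mm\n",
      "  forward (", paste(signif(x$forward, 4), collapse = ", "), ")",
      "  temporal (", paste(signif(x$temporal, 4), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Convert directions to eye-centered polar coordinates
#'
#' \eqn{\theta} (degrees, 0..180) is the angle from the eye's forward ray;
#' \eqn{\phi} (degrees, in \[0, 360)) is measured around it, counter-clockwise
#' from the temporal direction with up at 90 degrees (flipped when the pose
#' chirality is -1). For directions along \code{forward}, \eqn{\phi} is 0 by
#' convention.
#'
#' @param eye an [eye_pose()].
#' @param dir a length-3 unit vector or an \code{n x 3} matrix of them.
#' @return An \code{n x 2} matrix with columns \code{theta}, \code{phi}.
#' @export
direction_to_polar <- function(eye, dir) {
  if (!inherits(eye, "eye_pose")) stop("eye must be an eye_pose")
  d <- if (is.matrix(dir)) dir else matrix(dir, nrow = 1L)
  if (ncol(d) != 3L) stop("dir must have 3 columns")
  n <- sqrt(rowSums(d^2))
  if (any(!is.finite(n)) || any(n == 0)) stop("zero or non-finite direction")
  d <- d / n
  f <- d %*% eye$forward
  t <- d %*% eye$temporal
  u <- d %*% eye$up
  theta <- rad2deg(acos(pmin(pmax(f, -1), 1)))
  phi <- rad2deg(atan2(eye$chirality * u, t)) %% 360
  phi[t == 0 & u == 0] <- 0  # along +/- forward: phi defined as 0
  cbind(theta = as.numeric(theta), phi = as.numeric(phi))
}

#' Convert eye-centered polar coordinates to directions
#'
#' Inverse of [direction_to_polar()].
#'
#' @param eye an [eye_pose()].
#' @param theta,phi angles in degrees (vectors of equal length).
#' @return An \code{n x 3} matrix of unit direction vectors.
#' @export
polar_to_direction <- function(eye, theta, phi) {
  if (!inherits(eye, "eye_pose")) stop("eye must be an eye_pose")
  th <- deg2rad(theta); ph <- deg2rad(phi)
  st <- sin(th)
  comp_f <- cos(th)
  comp_t <- st * cos(ph)
  comp_u <- eye$chirality * st * sin(ph)
  outer(comp_f, eye$forward) + outer(comp_t, eye$temporal) +
    outer(comp_u, eye$up)
}
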