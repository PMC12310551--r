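## Fixed face order of the cube rig (shared by tracing, IO and boundary code).
RIG_FACE_NAMES <- c("forward", "up", "down", "temporal", "nasal")

#' Build the eye-centered five-camera sensor rig
#'
#' Five square pinhole cameras with a 90-degree field of view share the eye as
#' their center of projection and point along the forward, up, down, temporal
#' and nasal axes of the pose: five faces of a cube whose union covers every
#' direction within 90 degrees of forward (the front hemisphere). Ray origins
#' are displaced from the eye by \code{eps_offset} along forward so that rays
#' never start exactly on the socket surface.
#'
#' @param eye an [eye_pose()].
#' @param fov field of view in degrees; must be 90 for hemisphere coverage.
#' @param res pixels per image side (default 1024).
#' @param eps_offset ray-origin offset along forward, mm (default 1e-4).
#' @return An object of class \code{"sensor_rig"}.
#' @export
build_rig <- function(eye, fov = 90, res = 1024L, eps_offset = 1e-4) {
  if (!inherits(eye, "eye_pose")) stop("eye must be an eye_pose")
  if (!isTRUE(all.equal(fov, 90))) stop("fov must be 90 degrees")
  res <- as.integer(res)
  if (is.na(res) || res < 2L) stop("res must be an integer >= 2")
  if (!is.finite(eps_offset) || eps_offset < 0) stop("invalid eps_offset")
  f <- eye$forward; u <- eye$up; t <- eye$temporal
  faces <- list(
    forward  = list(right = t,  up = u,  w = f),
    up       = list(right = t,  up = -f, w = u),
    down     = list(right = t,  up = f,  w = -u),
    temporal = list(right = -f, up = u,  w = t),
    nasal    = list(right = f,  up = u,  w = -t)
  )
  structure(list(eye = eye, fov = 90, res = res, eps_offset = eps_offset,
                 faces = faces),
            class = "sensor_rig")
}

#' @export
print.sensor_rig <- function(x, ...) {
  cat("Sensor rig: 5 faces x ", x$res, "x", x$res,
      " pixels, fov 90 deg, origin offset ", x$eps_offset, " mm\n", sep = "")
  invisible(x)
}

## Pixel-center tangent-plane coordinates, matching the C++ tracer exactly.
pixel_xy <- function(res, i, j) {
  list(x = (2 * j - 1) / res - 1, y = 1 - (2 * i - 1) / res)
}

#' Direction through a pixel center
#'
#' Standard pinhole geometry for a 90-degree square camera: the tangent-plane
#' half extent is tan(45 deg) = 1 and pixel centers sit at
#' \code{(2k-1)/res - 1}. Rows run top to bottom, columns left to right.
#'
#' @param rig a [build_rig()] rig.
#' @param face_id face index 1..5 (forward, up, down, temporal, nasal) or name.
#' @param i,j row and column indices (vectors of equal length), 1-based.
#' @return An \code{n x 3} matrix of unit direction vectors.
#' @export
pixel_to_direction <- function(rig, face_id, i, j) {
  if (!inherits(rig, "sensor_rig")) stop("rig must be a sensor_rig")
  if (is.character(face_id)) face_id <- match(face_id, RIG_FACE_NAMES)
  if (is.na(face_id) || face_id < 1L || face_id > 5L)
    stop("face_id must index one of the five rig faces")
  if (any(i < 1L) || any(i > rig$res) || any(j < 1L) || any(j > rig$res))
    stop("pixel indices out of range [1, ", rig$res, "]")
  fr <- rig$faces[[face_id]]
  xy <- pixel_xy(rig$res, i, j)
  d <- outer(rep(1, length(xy$x)), fr$w) + outer(xy$x, fr$right) +
    outer(xy$y, fr$up)
  d / sqrt(rowSums(d^2))
}

## Which rig face owns each direction (largest positive view-axis component
## whose frustum contains the direction); NA if none (rear directions outside
## all five frusta). dirs: n x 3.
direction_owner_face <- function(rig, dirs) {
  dirs <- if (is.matrix(dirs)) dirs else matrix(dirs, nrow = 1L)
  n <- nrow(dirs)
  best <- rep(NA_integer_, n)
  bestp <- rep(0, n)
  tol <- 1 + 1e-12
  for (k in seq_len(5L)) {
    fr <- rig$faces[[k]]
    p <- as.numeric(dirs %*% fr$w)
    a <- as.numeric(dirs %*% fr$right)
    b <- as.numeric(dirs %*% fr$up)
    inside <- p > 0 & abs(a) <= p * tol & abs(b) <= p * tol
    take <- inside & p > bestp
    best[take] <- k
    bestp[take] <- p[take]
  }
  best
}

## Inverse of pixel_to_direction: face + (i, j) of the pixel containing each
## direction. Returns a data.frame(face, i, j) with NA rows for uncovered
## directions.
direction_to_pixel <- function(rig, dirs) {
  dirs <- if (is.matrix(dirs)) dirs else matrix(dirs, nrow = 1L)
  face <- direction_owner_face(rig, dirs)
  res <- rig$res
  i <- j <- rep(NA_integer_, nrow(dirs))
  for (k in seq_len(5L)) {
    sel <- which(face == k)
    if (length(sel) == 0L) next
    fr <- rig$faces[[k]]
    p <- as.numeric(dirs[sel, , drop = FALSE] %*% fr$w)
    x <- as.numeric(dirs[sel, , drop = FALSE] %*% fr$right) / p
    y <- as.numeric(dirs[sel, , drop = FALSE] %*% fr$up) / p
    jj <- pmin(pmax(floor((x + 1) * res / 2) + 1, 1L), res)
    ii <- pmin(pmax(floor((1 - y) * res / 2) + 1, 1L), res)
    i[sel] <- as.integer(ii)
    j[sel] <- as.integer(jj)
  }
  data.frame(face = face, i = i, j = j)
}
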