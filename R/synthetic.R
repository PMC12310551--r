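## UV sphere of given radius around the origin, poles on the +/-y (up) axis.
## n_lat latitude bands, 2*n_lat longitude steps; returns a tri_mesh.
uv_sphere <- function(radius, n_lat) {
  n_lon <- 2L * n_lat
  lat <- seq(0, pi, length.out = n_lat + 1L)        # 0 = north pole (+y)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  ring_lat <- lat[2:n_lat]
  V <- matrix(0, 2L + length(ring_lat) * n_lon, 3L)
  V[1L, ] <- c(0, radius, 0)
  V[2L, ] <- c(0, -radius, 0)
  idx <- function(r, c) 2L + (r - 1L) * n_lon + ((c - 1L) %% n_lon) + 1L
  row_pos <- 3L
  for (th in ring_lat) {
    V[row_pos:(row_pos + n_lon - 1L), ] <-
      cbind(radius * sin(th) * sin(lon), radius * cos(th),
            radius * sin(th) * cos(lon))
    row_pos <- row_pos + n_lon
  }
  tris <- vector("list", n_lat)
  ## polar caps
  tris[[1L]] <- cbind(1L, idx(1L, seq_len(n_lon)), idx(1L, seq_len(n_lon) + 1L))
  tris[[2L]] <- cbind(2L, idx(n_lat - 1L, seq_len(n_lon) + 1L),
                      idx(n_lat - 1L, seq_len(n_lon)))
  ## quad bands
  for (r in seq_len(n_lat - 2L)) {
    a <- idx(r, seq_len(n_lon));      b <- idx(r, seq_len(n_lon) + 1L)
    c_ <- idx(r + 1L, seq_len(n_lon)); d <- idx(r + 1L, seq_len(n_lon) + 1L)
    tris[[2L + r]] <- rbind(cbind(a, c_, d), cbind(a, d, b))
  }
  tri_mesh(V, do.call(rbind, tris))
}

## Smooth, strictly local radial bump: cosine falloff of angular distance
## from `center` (unit vector), zero outside `radius_deg`.
feature_weights <- function(dirs, center, radius_deg) {
  ang <- rad2deg(acos(pmin(pmax(dirs %*% center, -1), 1)))
  w <- numeric(length(ang))
  inside <- ang < radius_deg
  w[inside] <- 0.5 * (1 + cos(pi * ang[inside] / radius_deg))
  w
}

## Anatomical layout of the synthetic head, in head coordinates:
## the head looks along +z, up is +y, the right eye sits at positive x.
synthetic_layout <- function() {
  sph_dir <- function(az_deg, el_deg) {
    az <- deg2rad(az_deg); el <- deg2rad(el_deg)
    unit3(c(sin(az) * cos(el), sin(el), cos(az) * cos(el)))
  }
  list(
    eye = sph_dir(20, 5),
    features = list(
      nose  = list(center = sph_dir(0, -8),   radius = 22),
      brow  = list(center = sph_dir(18, 28),  radius = 18),
      cheek = list(center = sph_dir(24, -24), radius = 18)
    )
  )
}

#' Generate a synthetic morphable head model
#'
#' Builds a fully synthetic stand-in for a scanned morphable head: a convex
#' spherical cranium with a protruding nose, brow ridge and cheek bulge,
#' realised as smooth cosine-falloff radial displacement fields. Each of the
#' \code{n_ids} morph targets displaces exactly one feature by its stated
#' range, so blendshape coefficients modulate one anatomical feature each and
#' the morphs are strictly local. The right-eye anchor is placed 1 mm proud
#' of the cranium surface, outside all displaced geometry, with forward along
#' the local outward radial, up toward the crown, and temporal away from the
#' nose. The generator is fully deterministic given \code{seed}.
#'
#' For \code{n_ids > 3} the three features are cycled and repeated targets
#' get a deterministic, seed-derived azimuth offset so that no two targets
#' share a support region center.
#'
#' @param n_ids number of morph targets (features cycled: nose, brow, cheek).
#' @param cranium_radius cranium radius, mm.
#' @param nose_length,brow_protrusion,cheek_height base feature amplitudes on
#'   the generic head, mm.
#' @param nose_range,brow_range,cheek_range per-target displacement ranges,
#'   mm (the amplitude change when the coefficient goes from 0 to +1).
#' @param mesh_resolution latitude bands of the cranium sphere.
#' @param seed integer seed controlling the (deterministic) layout jitter of
#'   repeated targets.
#' @return A [morphable_model()] with the eye pose attached; the feature
#'   assignment of each target (name, center, radius and the affected vertex
#'   indices) is stored in \code{attr(model, "target_features")}.
#' @export
make_synthetic_model <- function(n_ids = 3L, cranium_radius = 90,
                                 nose_length = 42, brow_protrusion = 30,
                                 cheek_height = 34,
                                 nose_range = 15, brow_range = 10,
                                 cheek_range = 11,
                                 mesh_resolution = 48L, seed = 1L) {
  n_ids <- as.integer(n_ids)
  if (is.na(n_ids) || n_ids < 1L) stop("n_ids must be >= 1")
  dims <- c(cranium_radius, nose_length, brow_protrusion, cheek_height,
            nose_range, brow_range, cheek_range)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all dimensions must be positive and finite")

  lay <- synthetic_layout()
  sphere <- uv_sphere(cranium_radius, as.integer(mesh_resolution))
  dirs <- sphere$vertices / cranium_radius  # unit outward normals

  base_amp <- c(nose = nose_length, brow = brow_protrusion,
                cheek = cheek_height)
  range_amp <- c(nose = nose_range, brow = brow_range, cheek = cheek_range)

  ## generic head: sphere plus base feature bumps
  Vg <- sphere$vertices
  for (nm in names(lay$features)) {
    ft <- lay$features[[nm]]
    w <- feature_weights(dirs, ft$center, ft$radius)
    Vg <- Vg + base_amp[[nm]] * w * dirs
  }
  if (any(!is.finite(Vg))) stop("synthetic mesh self-check failed: non-finite vertex")
  generic <- tri_mesh(Vg, sphere$faces)

  ## per-target displacement fields: one feature each; repeats of a feature
  ## get a deterministic azimuth offset derived from the seed
  rot_y <- function(v, ang_deg) {
    a <- deg2rad(ang_deg)
    c(cos(a) * v[1] + sin(a) * v[3], v[2], -sin(a) * v[1] + cos(a) * v[3])
  }
  jitter_step <- 5 + (as.integer(seed) %% 7L)  # degrees, deterministic in seed
  feat_names <- names(lay$features)
  targets <- vector("list", n_ids)
  target_features <- vector("list", n_ids)
  for (i in seq_len(n_ids)) {
    nm <- feat_names[((i - 1L) %% 3L) + 1L]
    rep_k <- (i - 1L) %/% 3L
    ft <- lay$features[[nm]]
    center <- if (rep_k == 0L) ft$center else
      unit3(rot_y(ft$center, jitter_step * rep_k * ifelse(rep_k %% 2L, 1, -1)))
    w <- feature_weights(dirs, center, ft$radius)
    Vt <- Vg + range_amp[[nm]] * w * dirs
    if (any(!is.finite(Vt)))
      stop("synthetic mesh self-check failed: non-finite vertex")
    targets[[i]] <- tri_mesh(Vt, sphere$faces)
    target_features[[i]] <- list(feature = nm, center = center,
                                 radius = ft$radius,
                                 support = which(w > 0))
  }

  ## eye pose: 1 mm proud of the cranium surface, radial forward
  fwd <- lay$eye
  anchor <- (cranium_radius + 1) * fwd
  up <- unit3(c(0, 1, 0) - sum(c(0, 1, 0) * fwd) * fwd)
  temporal <- unit3(cross3(up, fwd))
  eye <- eye_pose(origin = anchor, forward = fwd, up = up,
                  temporal = temporal)

  model <- morphable_model(generic, targets, eye_anchor = anchor, eye = eye)
  attr(model, "target_features") <- target_features
  model
}

#' Spherical-cap occluder fixture
#'
#' A triangulated zone of the sphere of given radius centered at the eye,
#' spanning polar angles \code{[theta0, 90 + margin]} for all azimuths. Seen
#' from the eye it occludes exactly the directions with \eqn{\theta >
#' \theta_0} (up to triangulation error), so the true boundary is
#' \eqn{\theta(\phi) \equiv \theta_0} and the projected solid angle is
#' \eqn{\pi \sin^2 \theta_0} in closed form.
#'
#' @param theta0 cap rim polar angle, degrees, in (0, 90).
#' @param radius sphere radius, mm.
#' @param margin how far past the 90-degree rim the zone extends, degrees.
#' @param res azimuthal segments of the triangulation (polar step matched).
#' @return A list with elements \code{mesh} ([tri_mesh()]) and \code{eye}
#'   ([eye_pose()] at the sphere center).
#' @export
make_cap_occluder <- function(theta0, radius = 100, margin = 30, res = 180L) {
  if (!is.finite(theta0) || theta0 <= 0 || theta0 >= 90)
    stop("theta0 must lie strictly between 0 and 90 degrees")
  res <- as.integer(res)
  theta_max <- 90 + margin
  n_rings <- max(2L, ceiling((theta_max - theta0) / (360 / res)))
  th <- deg2rad(seq(theta0, theta_max, length.out = n_rings + 1L))
  ph <- seq(0, 2 * pi, length.out = res + 1L)[-(res + 1L)]
  ## eye frame: forward +z, up +y, temporal +x; polar angle from +z
  V <- do.call(rbind, lapply(th, function(t)
    cbind(radius * sin(t) * cos(ph), radius * sin(t) * sin(ph),
          radius * cos(t))))
  idx <- function(r, c) (r - 1L) * res + ((c - 1L) %% res) + 1L
  tris <- vector("list", n_rings)
  for (r in seq_len(n_rings)) {
    a <- idx(r, seq_len(res));      b <- idx(r, seq_len(res) + 1L)
    c_ <- idx(r + 1L, seq_len(res)); d <- idx(r + 1L, seq_len(res) + 1L)
    tris[[r]] <- rbind(cbind(a, c_, d), cbind(a, d, b))
  }
  eye <- eye_pose(origin = c(0, 0, 0), forward = c(0, 0, 1),
                  up = c(0, 1, 0), temporal = c(1, 0, 0))
  list(mesh = tri_mesh(V, do.call(rbind, tris)), eye = eye)
}

#' Half-space occluder fixture
#'
#' A large horizontal quad (two triangles) at height \code{drop} below the
#' eye, spanning \code{[-extent, extent]} in both horizontal directions. In
#' the limit \code{drop/extent -> 0} it occludes exactly the lower direction
#' hemisphere, so the ideal boundary is \eqn{\theta = 90^\circ} for upward
#' azimuths, \eqn{\theta = 0} for downward ones, and the projected solid
#' angle is \eqn{\pi/2}.
#'
#' The default \code{drop/extent} ratio (about 0.2 degrees) keeps the open
#' sliver just below the horizon wider than a sensor pixel at resolutions of
#' 512 and above; a ratio far below the pixel scale degenerates the occlusion
#' boundary into the great circle through the forward pole, which a binned
#' boundary function cannot represent (see the package vignette).
#'
#' @param drop quad depth below the eye, mm.
#' @param extent quad half width, mm (must be much larger than \code{drop}).
#' @return A list with elements \code{mesh} and \code{eye} as in
#'   [make_cap_occluder()].
#' @export
make_halfspace_occluder <- function(drop = 30, extent = 8000) {
  if (!is.finite(drop) || drop < 0) stop("drop must be >= 0")
  if (!is.finite(extent) || extent <= 10 * drop)
    stop("extent must be much larger than drop")
  V <- rbind(c(-extent, -drop, -extent),
             c(extent, -drop, -extent),
             c(extent, -drop, extent),
             c(-extent, -drop, extent))
  F <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  eye <- eye_pose(origin = c(0, 0, 0), forward = c(0, 0, 1),
                  up = c(0, 1, 0), temporal = c(1, 0, 0))
  list(mesh = tri_mesh(V, F), eye = eye)
}
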