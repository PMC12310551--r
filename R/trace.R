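#' Intersect rays with a triangle mesh
#'
#' Returns the smallest positive intersection distance of each ray with the
#' mesh, or \code{NA} for a miss. The accelerated path traverses a bounding
#' volume hierarchy but applies the identical watertight ray-triangle test as
#' the brute-force path, so the two methods return exactly equal distances.
#'
#' @param mesh a [tri_mesh()].
#' @param origin length-3 numeric or \code{n x 3} matrix of ray origins (mm).
#' @param dir length-3 numeric or \code{n x 3} matrix of ray directions
#'   (need not be unit length; distances are in units of \code{|dir|}).
#' @param method \code{"bvh"} (default) or \code{"brute"}.
#' @return Numeric vector of hit distances, \code{NA} where the ray misses.
#' @export
intersect_ray <- function(mesh, origin, dir, method = c("bvh", "brute")) {
  method <- match.arg(method)
  if (!inherits(mesh, "tri_mesh")) stop("mesh must be a tri_mesh")
  O <- if (is.matrix(origin)) origin else matrix(origin, nrow = 1L)
  D <- if (is.matrix(dir)) dir else matrix(dir, nrow = 1L)
  if (nrow(O) == 1L && nrow(D) > 1L)
    O <- O[rep(1L, nrow(D)), , drop = FALSE]
  storage.mode(O) <- "double"; storage.mode(D) <- "double"
  t <- cpp_ray_trace(mesh$vertices, mesh$faces, O, D,
                     brute = (method == "brute"))
  t[!is.finite(t)] <- NA_real_
  t
}

#' Trace binary occlusion maps through the sensor rig
#'
#' Casts one primary ray per pixel center from the (offset) eye position and
#' marks the pixel OCCLUDED when the ray hits the mesh. For the scene the
#' pipeline models -- an entirely non-reflective head inside a constant
#' radiance light source -- the per-pixel radiance of a physically based
#' render is binary and equals one minus this occlusion value, so the binary
#' maps are exact, not an approximation.
#'
#' @param mesh occluding head mesh, a [tri_mesh()].
#' @param rig a [build_rig()] rig.
#' @return An object of class \code{"occlusion_maps"}: a list of five
#'   \code{res x res} logical matrices (TRUE = occluded) named
#'   forward, up, down, temporal, nasal, with the rig stored as an attribute.
#' @export
trace_occlusion <- function(mesh, rig) {
  if (!inherits(mesh, "tri_mesh")) stop("mesh must be a tri_mesh")
  if (!inherits(rig, "sensor_rig")) stop("rig must be a sensor_rig")
  eye <- rig$eye
  origin <- eye$origin + rig$eps_offset * eye$forward
  bases <- t(vapply(rig$faces, function(fr) c(fr$right, fr$up, fr$w),
                    numeric(9)))
  occ <- cpp_trace_rig(mesh$vertices, mesh$faces, origin, bases, rig$res)
  res <- rig$res
  maps <- vector("list", 5L)
  names(maps) <- RIG_FACE_NAMES
  for (k in seq_len(5L)) {
    block <- occ[((k - 1L) * res * res + 1L):(k * res * res)]
    maps[[k]] <- matrix(block, nrow = res, ncol = res)
  }
  structure(maps, class = "occlusion_maps", rig = rig)
}

#' @export
print.occlusion_maps <- function(x, ...) {
  rig <- attr(x, "rig")
  frac <- vapply(unclass(x)[RIG_FACE_NAMES], mean, numeric(1))
  cat("Occlusion maps (", rig$res, "x", rig$res, " x 5 faces)\n", sep = "")
  cat("  occluded fraction:",
      paste(sprintf("%s %.3f", RIG_FACE_NAMES, frac), collapse = ", "), "\n")
  invisible(x)
}

#' Write occlusion maps as PGM (P5) images
#'
#' One binary image per rig face, occluded pixels black, open pixels white,
#' written as \code{<prefix>_<face>.pgm} in the fixed face order.
#'
#' @param maps an \code{occlusion_maps} object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_occlusion_pgm <- function(maps, dir, prefix = "occlusion") {
  if (!inherits(maps, "occlusion_maps")) stop("maps must be occlusion_maps")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- nrow(maps[[1L]])
  paths <- character(5L)
  for (k in seq_len(5L)) {
    path <- file.path(dir, sprintf("%s_%s.pgm", prefix, RIG_FACE_NAMES[k]))
    con <- file(path, open = "wb")
    writeChar(sprintf("P5\n%d %d\n255\n", res, res), con, eos = NULL)
    ## PGM is row-major from the top row; our matrices are [row, col]
    px <- ifelse(t(maps[[k]]), 0L, 255L)
    writeBin(as.raw(as.integer(px)), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}
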