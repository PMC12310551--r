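#' Visual field boundary function
#'
#' The boundary \eqn{\theta(\phi)} of the visual field, sampled on
#' \code{n_bins} equally spaced azimuth bins with centers at
#' \eqn{(k - 0.5) \cdot 360 / n\_bins} degrees. All values lie in \[0, 90\]:
#' 90 means the field extends to the rim of the front hemisphere in that
#' azimuth, 0 means it is fully occluded.
#'
#' @param theta numeric vector of polar extents in degrees, one per bin.
#' @return An object of class \code{"vf_boundary"}.
#' @export
vf_boundary <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) < 1L) stop("boundary needs at least one bin")
  if (any(!is.finite(theta))) stop("boundary values must be finite")
  if (any(theta < -1e-9) || any(theta > 90 + 1e-9))
    stop("boundary values must lie in [0, 90] degrees")
  structure(pmin(pmax(theta, 0), 90), class = "vf_boundary",
            n_bins = length(theta))
}

#' @export
print.vf_boundary <- function(x, ...) {
  cat("VF boundary on ", length(x), " phi bins: theta range [",
      sprintf("%.2f", min(x)), ", ", sprintf("%.2f", max(x)),
      "] deg, projected solid angle ",
      sprintf("%.4f", projected_solid_angle(x)), " sr\n", sep = "")
  invisible(x)
}

#' Azimuth bin centers of a boundary function
#' @param b a [vf_boundary()] or a bin count.
#' @return Numeric vector of bin-center azimuths in degrees.
#' @export
phi_bin_centers <- function(b) {
  n <- if (inherits(b, "vf_boundary")) length(b) else as.integer(b)
  (seq_len(n) - 0.5) * 360 / n
}

## Pixel direction without range validation (used for virtual neighbours one
## step beyond a face edge).
pixel_dir_raw <- function(rig, face_id, i, j) {
  fr <- rig$faces[[face_id]]
  xy <- pixel_xy(rig$res, i, j)
  d <- outer(rep(1, length(xy$x)), fr$w) + outer(xy$x, fr$right) +
    outer(xy$y, fr$up)
  d / sqrt(rowSums(d^2))
}

## Enumerate adjacent OPEN/OCCLUDED pixel pairs, including pairs whose two
## pixels sit on different cube faces across a shared edge. Returns a list of
## two matrices (n x 3: face, i, j) aligned row by row.
boundary_pixel_pairs <- function(maps, rig) {
  res <- rig$res
  open_px <- occ_px <- vector("list", 0L)
  add <- function(of, oi, oj, cf, ci, cj) {
    if (length(oi) == 0L) return()
    open_px[[length(open_px) + 1L]] <<- cbind(of, oi, oj)
    occ_px[[length(occ_px) + 1L]] <<- cbind(cf, ci, cj)
  }
  for (k in seq_len(5L)) {
    O <- maps[[k]]
    open <- !O
    ## in-face 4-neighbours
    m <- open[2:res, , drop = FALSE] & O[1:(res - 1), , drop = FALSE]
    w <- which(m, arr.ind = TRUE)
    add(k, w[, 1] + 1L, w[, 2], k, w[, 1], w[, 2])
    m <- open[1:(res - 1), , drop = FALSE] & O[2:res, , drop = FALSE]
    w <- which(m, arr.ind = TRUE)
    add(k, w[, 1], w[, 2], k, w[, 1] + 1L, w[, 2])
    m <- open[, 2:res, drop = FALSE] & O[, 1:(res - 1), drop = FALSE]
    w <- which(m, arr.ind = TRUE)
    add(k, w[, 1], w[, 2] + 1L, k, w[, 1], w[, 2])
    m <- open[, 1:(res - 1), drop = FALSE] & O[, 2:res, drop = FALSE]
    w <- which(m, arr.ind = TRUE)
    add(k, w[, 1], w[, 2], k, w[, 1], w[, 2] + 1L)
    ## cross-edge neighbours: for open border pixels, look up the pixel one
    ## grid step beyond the edge on whichever face owns that direction
    edges <- list(list(i = rep(1L, res), j = seq_len(res), di = -1L, dj = 0L),
                  list(i = rep(res, res), j = seq_len(res), di = 1L, dj = 0L),
                  list(i = seq_len(res), j = rep(1L, res), di = 0L, dj = -1L),
                  list(i = seq_len(res), j = rep(res, res), di = 0L, dj = 1L))
    for (e in edges) {
      sel <- open[cbind(e$i, e$j)]
      if (!any(sel)) next
      bi <- e$i[sel]; bj <- e$j[sel]
      vdir <- pixel_dir_raw(rig, k, bi + e$di, bj + e$dj)
      px <- direction_to_pixel(rig, vdir)
      ok <- !is.na(px$face)
      if (!any(ok)) next
      ## look up occlusion on the owning faces
      occ_there <- logical(length(bi))
      for (f2 in unique(px$face[ok])) {
        s2 <- which(px$face == f2 & ok)
        occ_there[s2] <- maps[[f2]][cbind(px$i[s2], px$j[s2])]
      }
      keep <- ok & occ_there
      add(rep(k, sum(keep)), bi[keep], bj[keep],
          px$face[keep], px$i[keep], px$j[keep])
    }
  }
  list(open = do.call(rbind, open_px), occ = do.call(rbind, occ_px))
}

## Directions of pixel triples (face, i, j), vectorized per face.
pairs_to_dirs <- function(rig, px) {
  d <- matrix(NA_real_, nrow(px), 3L)
  for (k in unique(px[, 1])) {
    sel <- which(px[, 1] == k)
    d[sel, ] <- pixel_dir_raw(rig, k, px[sel, 2], px[sel, 3])
  }
  d
}

#' Extract the visual field boundary from occlusion maps
#'
#' Boundary samples are taken where an OPEN pixel has at least one OCCLUDED
#' 4-neighbour, with the neighbourhood resolved across shared cube-face
#' edges. By default each open/occluded pixel pair contributes the direction
#' midway between the two pixel centers, which is unbiased to first order in
#' the pixel size; \code{side = "open"} and \code{side = "occluded"} instead
#' contribute the pixel center on the chosen side (each boundary pixel once).
#' Samples with \eqn{\theta > 90^\circ} are discarded (the field is the front
#' hemisphere) and the remaining \eqn{\theta} values are averaged per azimuth
#' bin. A bin without any sample means no occlusion boundary crosses that
#' azimuth inside the hemisphere: the maps are probed at the hemisphere rim
#' (\eqn{\theta = 90} minus half a pixel) and the bin is set to 90 when the
#' rim is open there (azimuths whose physical boundary lies beyond 90
#' degrees); bins whose rim is occluded are filled by circular linear
#' interpolation from the surrounding bins. The result is clipped to
#' \[0, 90\]. A fully open (fully occluded) map set yields
#' \eqn{\theta \equiv 90} (\eqn{\theta \equiv 0}).
#'
#' @param maps an \code{occlusion_maps} object from [trace_occlusion()].
#' @param n_bins number of azimuth bins (default 36000).
#' @param side boundary sampling rule: \code{"midpoint"} (default),
#'   \code{"open"} or \code{"occluded"}.
#' @return A [vf_boundary()].
#' @export
extract_boundary <- function(maps, n_bins = 36000L,
                             side = c("midpoint", "open", "occluded")) {
  side <- match.arg(side)
  if (!inherits(maps, "occlusion_maps")) stop("maps must be occlusion_maps")
  rig <- attr(maps, "rig")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be a positive integer")
  for (k in seq_len(5L))
    if (!is.logical(maps[[k]])) stop("occlusion maps must be binary (logical)")

  pr <- boundary_pixel_pairs(maps, rig)
  out <- rep(NA_real_, n_bins)
  if (!is.null(pr$open) && nrow(pr$open) > 0L) {
    dirs <- switch(side,
      midpoint = {
        d <- pairs_to_dirs(rig, pr$open) + pairs_to_dirs(rig, pr$occ)
        d / sqrt(rowSums(d^2))
      },
      open = pairs_to_dirs(rig, unique(pr$open)),
      occluded = pairs_to_dirs(rig, unique(pr$occ))
    )
    pol <- direction_to_polar(rig$eye, dirs)
    keep <- pol[, "theta"] <= 90
    if (any(keep)) {
      theta <- pol[keep, "theta"]
      phi <- pol[keep, "phi"]
      bin <- pmin(floor(phi / (360 / n_bins)) + 1L, n_bins)
      cnt <- tabulate(bin, n_bins)
      rs <- rowsum(theta, bin)
      nz <- cnt > 0L
      out[nz] <- rs[, 1L] / cnt[nz]
    }
  }

  ## Bins without a boundary sample carry no crossing of the occlusion
  ## boundary inside the front hemisphere. Probe the maps at the hemisphere
  ## rim (theta = 90 minus half a pixel) at those azimuths: an open rim means
  ## the field reaches the full 90 degrees there (e.g. temporal azimuths
  ## whose physical boundary lies beyond 90); only rim-occluded gaps are
  ## filled by circular linear interpolation from the surrounding bins.
  empty <- which(is.na(out))
  if (length(empty) > 0L) {
    eps <- 45 / rig$res  # half of the coarsest pixel angular step
    centers <- phi_bin_centers(n_bins)
    probe <- polar_to_direction(rig$eye, rep(90 - eps, length(empty)),
                                centers[empty])
    px <- direction_to_pixel(rig, probe)
    rim_open <- logical(length(empty))
    ok <- !is.na(px$face)
    for (f2 in unique(px$face[ok])) {
      s2 <- which(px$face == f2 & ok)
      rim_open[s2] <- !maps[[f2]][cbind(px$i[s2], px$j[s2])]
    }
    out[empty[rim_open]] <- 90
  }
  empty <- which(is.na(out))
  if (length(empty) > 0L) {
    idx <- which(!is.na(out))
    if (length(idx) == 0L) {
      ## no anchors anywhere: fully open or fully occluded field
      ctr <- direction_to_pixel(rig, matrix(rig$eye$forward, 1L))
      fwd_occ <- maps[[ctr$face[1L]]][ctr$i[1L], ctr$j[1L]]
      out[] <- if (isTRUE(fwd_occ)) 0 else 90
    } else {
      xs <- c(idx - n_bins, idx, idx + n_bins)
      ys <- rep(out[idx], 3L)
      out[empty] <- approx(xs, ys, xout = empty, ties = "ordered")$y
    }
  }
  vf_boundary(pmin(pmax(out, 0), 90))
}

#' Projected solid angle of a visual field
#'
#' The cosine-weighted integral
#' \eqn{\Omega = \int\!\!\int \cos\theta \sin\theta \, d\theta \, d\phi}
#' over the field, evaluated per azimuth bin in closed form:
#' \eqn{\Omega = \sum_k \Delta\phi \, \sin^2(\theta_k) / 2} with
#' \eqn{\Delta\phi = 2\pi / n\_bins}. An unobstructed hemisphere gives
#' \eqn{\pi} sr.
#'
#' @param b a [vf_boundary()] (or numeric vector of per-bin theta, degrees).
#' @return Projected solid angle in steradians.
#' @export
projected_solid_angle <- function(b) {
  theta <- as.numeric(b)
  if (any(!is.finite(theta)) || any(theta < -1e-9) || any(theta > 90 + 1e-9))
    stop("boundary theta values must lie in [0, 90] degrees")
  dphi <- 2 * pi / length(theta)
  sum(dphi * sin(deg2rad(theta))^2 / 2)
}

#' Percent decrease of a projected solid angle below the hemisphere
#'
#' \eqn{100 (\pi - \Omega) / \pi}: 0 for an unobstructed hemisphere, 100 for
#' a fully occluded field.
#'
#' @param omega projected solid angle in steradians, in \eqn{[0, \pi]}.
#' @return Percentage decrease.
#' @export
percent_decrease <- function(omega) {
  if (any(!is.finite(omega)) || any(omega < -1e-9) || any(omega > pi + 1e-9))
    stop("omega must lie in [0, pi] steradians")
  100 * (pi - omega) / pi
}

#' Write a boundary function to CSV
#'
#' Two columns, \code{phi_deg} and \code{theta_deg}, one row per bin, with a
#' header row.
#'
#' @param b a [vf_boundary()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_boundary_csv <- function(b, path) {
  if (!inherits(b, "vf_boundary")) b <- vf_boundary(b)
  df <- data.frame(phi_deg = phi_bin_centers(b), theta_deg = as.numeric(b))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a boundary function from CSV
#' @param path a CSV written by [write_boundary_csv()].
#' @return A [vf_boundary()].
#' @export
read_boundary_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("phi_deg", "theta_deg") %in% names(df)))
    stop("boundary CSV must have columns phi_deg and theta_deg")
  vf_boundary(df$theta_deg)
}

#' Plot a visual field boundary
#'
#' Either \eqn{\theta} against \eqn{\phi} (\code{type = "profile"}) or a polar
#' view of the field with \eqn{\theta} in the radial direction
#' (\code{type = "polar"}).
#'
#' @param x a [vf_boundary()].
#' @param type \code{"profile"} or \code{"polar"}.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.vf_boundary <- function(x, type = c("profile", "polar"), ...) {
  type <- match.arg(type)
  phi <- phi_bin_centers(x)
  if (type == "profile") {
    plot(phi, as.numeric(x), type = "l", xlab = expression(phi ~ "(deg)"),
         ylab = expression(theta ~ "(deg)"), ylim = c(0, 90), ...)
  } else {
    r <- as.numeric(x)
    px <- r * cos(deg2rad(phi)); py <- r * sin(deg2rad(phi))
    plot(px, py, type = "l", asp = 1, xlab = "", ylab = "",
         xlim = c(-90, 90), ylim = c(-90, 90), ...)
    cc <- seq(0, 2 * pi, length.out = 361)
    lines(90 * cos(cc), 90 * sin(cc), lty = 3)
  }
  invisible(x)
}
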