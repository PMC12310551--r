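#' Triangle mesh
#'
#' A minimal triangle-mesh container: an \code{n x 3} numeric matrix of vertex
#' coordinates (millimetres) and an \code{m x 3} integer matrix of 1-based
#' vertex indices. Occluder meshes must have at least one face.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class \code{"tri_mesh"}.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) < 1L) stop("mesh must have at least one face")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (any(is.na(faces)) || any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range [1, ", nrow(vertices), "]")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("Triangle mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces\n")
  invisible(x)
}

#' Read a Wavefront OBJ mesh
#'
#' Parses \code{v} and \code{f} records only; normals, texture coordinates and
#' material statements are ignored. Faces with more than three vertices are
#' fan-triangulated from the first vertex. Face tokens of the form
#' \code{v/vt/vn} keep the leading vertex index.
#'
#' @param path path to an ASCII OBJ file.
#' @return A [tri_mesh()] with 1-based face indices.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("OBJ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  tag <- substr(lines, 1L, 2L)
  v_lines <- which(tag == "v ")
  f_lines <- which(tag == "f ")
  if (length(v_lines) == 0L) stop("no vertex records in ", path)

  vtok <- strsplit(trimws(lines[v_lines]), "[[:space:]]+")
  nv <- length(vtok)
  V <- matrix(NA_real_, nv, 3L)
  for (k in seq_len(nv)) {
    tk <- vtok[[k]]
    if (length(tk) < 4L)
      stop("malformed vertex at line ", v_lines[k], " of ", path)
    xyz <- suppressWarnings(as.numeric(tk[2:4]))
    if (anyNA(xyz))
      stop("non-numeric vertex coordinate at line ", v_lines[k], " of ", path)
    V[k, ] <- xyz
  }

  tris <- vector("list", length(f_lines))
  for (k in seq_along(f_lines)) {
    tk <- strsplit(trimws(lines[f_lines[k]]), "[[:space:]]+")[[1]][-1]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tk)))
    if (anyNA(idx) || length(idx) < 3L)
      stop("malformed face at line ", f_lines[k], " of ", path)
    if (any(idx < 1L) || any(idx > nv))
      stop("face index out of range at line ", f_lines[k], " of ", path)
    n <- length(idx)
    ## fan triangulation: (1, i, i+1)
    tris[[k]] <- cbind(idx[1L], idx[2:(n - 1L)], idx[3:n])
  }
  F <- do.call(rbind, tris)
  tri_mesh(V, F)
}

#' Write a Wavefront OBJ mesh
#'
#' Writes vertices then faces with 1-based indices, in deterministic order.
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param digits significant digits for vertex coordinates.
#' @return Invisibly, \code{path}.
#' @export
write_obj <- function(mesh, path, digits = 9L) {
  if (!inherits(mesh, "tri_mesh")) mesh <- tri_mesh(mesh$vertices, mesh$faces)
  fmt <- paste0("v %.", digits, "g %.", digits, "g %.", digits, "g")
  v <- sprintf(fmt, mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(v, f), con)
  invisible(path)
}
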