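#' Morphable head model
#'
#' A generic (neutral) mesh plus an ordered list of morph-target meshes of
#' identical topology. Novel head shapes are synthesized by [blend_face()] as
#' the generic mesh plus a linear combination of per-target vertex offsets.
#'
#' @param generic a [tri_mesh()], the neutral head.
#' @param targets list of [tri_mesh()] morph targets, identical topology.
#' @param eye_anchor optional length-3 numeric, right-eye center (mm).
#' @param eye optional [eye_pose()] for the right eye; experiments that trace
#'   visibility require it.
#' @return An object of class \code{"morphable_model"} with fields
#'   \code{generic}, \code{targets}, \code{n_ids}, \code{eye_anchor},
#'   \code{eye}.
#' @export
morphable_model <- function(generic, targets, eye_anchor = NULL, eye = NULL) {
  if (!inherits(generic, "tri_mesh")) stop("generic must be a tri_mesh")
  if (!is.list(targets) || length(targets) < 1L)
    stop("targets must be a non-empty list of tri_mesh objects")
  nv <- nrow(generic$vertices)
  for (i in seq_along(targets)) {
    t <- targets[[i]]
    if (!inherits(t, "tri_mesh"))
      stop("target ", i, " is not a tri_mesh")
    if (nrow(t$vertices) != nv || !identical(t$faces, generic$faces))
      stop("topology mismatch between generic mesh and target ", i)
  }
  if (!is.null(eye_anchor)) {
    eye_anchor <- as.numeric(eye_anchor)
    if (length(eye_anchor) != 3L || !all(is.finite(eye_anchor)))
      stop("eye_anchor must be a finite length-3 numeric")
  }
  if (!is.null(eye) && !inherits(eye, "eye_pose"))
    stop("eye must be an eye_pose")
  structure(list(generic = generic, targets = targets,
                 n_ids = length(targets), eye_anchor = eye_anchor, eye = eye),
            class = "morphable_model")
}

#' @export
print.morphable_model <- function(x, ...) {
  cat("Morphable head model: ", x$n_ids, " morph targets, ",
      nrow(x$generic$vertices), " vertices, ", nrow(x$generic$faces),
      " faces\n", sep = "")
  if (!is.null(x$eye_anchor))
    cat("  right-eye anchor at (", paste(signif(x$eye_anchor, 5),
                                         collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' Load a morphable model from a manifest
#'
#' The manifest is a JSON or YAML document with fields \code{generic} (path),
#' \code{targets} (ordered list of paths), optional \code{eye_anchor}
#' (length-3, mm) and optional \code{eye_forward}, \code{eye_up},
#' \code{eye_temporal} unit vectors defining the eye pose at the anchor.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param manifest path to the manifest file (.json, .yaml or .yml).
#' @return A [morphable_model()].
#' @export
load_morph_model <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  ext <- tolower(tools::file_ext(manifest))
  spec <- switch(ext,
    json = jsonlite::read_json(manifest, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(manifest),
    stop("unsupported manifest format: .", ext)
  )
  base <- dirname(manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  generic <- read_obj(resolve(spec$generic))
  targets <- lapply(as.character(spec$targets),
                    function(p) read_obj(resolve(p)))
  eye <- NULL
  if (!is.null(spec$eye_anchor) && !is.null(spec$eye_forward)) {
    eye <- eye_pose(origin = as.numeric(spec$eye_anchor),
                    forward = as.numeric(spec$eye_forward),
                    up = as.numeric(spec$eye_up),
                    temporal = if (is.null(spec$eye_temporal)) NULL
                               else as.numeric(spec$eye_temporal))
  }
  morphable_model(generic, targets,
                  eye_anchor = spec$eye_anchor, eye = eye)
}

#' Save a morphable model as OBJ files plus a manifest
#'
#' Writes \code{generic.obj}, \code{target_###.obj} and \code{manifest.json}
#' into \code{dir}, in the layout [load_morph_model()] reads back.
#'
#' @param model a [morphable_model()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
save_morph_model <- function(model, dir) {
  if (!inherits(model, "morphable_model")) stop("model must be a morphable_model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obj(model$generic, file.path(dir, "generic.obj"))
  tnames <- sprintf("target_%03d.obj", seq_len(model$n_ids))
  for (i in seq_len(model$n_ids))
    write_obj(model$targets[[i]], file.path(dir, tnames[i]))
  spec <- list(generic = "generic.obj", targets = as.list(tnames))
  if (!is.null(model$eye_anchor)) spec$eye_anchor <- model$eye_anchor
  if (!is.null(model$eye)) {
    spec$eye_anchor <- model$eye$origin
    spec$eye_forward <- model$eye$forward
    spec$eye_up <- model$eye$up
    spec$eye_temporal <- model$eye$temporal
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(spec, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Synthesize a head shape from blendshape coefficients
#'
#' Computes the blendshape combination
#' \deqn{M_{new} = M_g + \sum_i c_i (M_i - M_g),}
#' i.e. the generic mesh plus a linear combination of the per-target vertex
#' offsets. Face connectivity is that of the generic mesh. Coefficients are
#' unrestricted reals; random-face sampling elsewhere draws them from
#' \eqn{(-1, 1)}.
#'
#' @param model a [morphable_model()].
#' @param coeffs numeric vector of length \code{model$n_ids}.
#' @return A [tri_mesh()].
#' @export
blend_face <- function(model, coeffs) {
  if (!inherits(model, "morphable_model")) stop("model must be a morphable_model")
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != model$n_ids)
    stop("coefficient length ", length(coeffs), " does not match n_ids = ",
         model$n_ids)
  if (!all(is.finite(coeffs))) stop("coefficients must be finite")
  V <- model$generic$vertices
  for (i in which(coeffs != 0)) {
    V <- V + coeffs[i] * (model$targets[[i]]$vertices - model$generic$vertices)
  }
  tri_mesh(V, model$generic$faces)
}
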