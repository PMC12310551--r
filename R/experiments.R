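## Trace one head mesh through the rig and extract its boundary, optionally
## through a content-addressed CSV cache (key: mesh geometry + rig + binning).
trace_boundary_cached <- function(mesh, rig, n_bins, side, cache_dir = NULL,
                                  counter = NULL) {
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    key <- content_hash(mesh$vertices, mesh$faces, rig$eye$origin,
                        rig$eye$forward, rig$eye$up, rig$eye$temporal,
                        rig$eye$chirality, rig$res, rig$eps_offset,
                        n_bins, side)
    path <- file.path(cache_dir, paste0(key, ".csv"))
    if (file.exists(path)) {
      if (!is.null(counter)) counter$hits <- counter$hits + 1L
      return(read_boundary_csv(path))
    }
  }
  b <- extract_boundary(trace_occlusion(mesh, rig), n_bins = n_bins,
                        side = side)
  if (!is.null(cache_dir)) write_boundary_csv(b, path)
  if (!is.null(counter)) counter$misses <- counter$misses + 1L
  b
}

model_rig <- function(model, res, eps_offset = 1e-4) {
  if (is.null(model$eye))
    stop("model has no eye pose; attach one via morphable_model(eye = ...)")
  build_rig(model$eye, fov = 90, res = res, eps_offset = eps_offset)
}

#' Render the boundary template set of a morphable model
#'
#' Traces the generic head plus, for each of the \code{n_ids} shape
#' parameters, the heads with that parameter alone set to +1 and to -1 --
#' \code{2 n_ids + 1} head shapes in total -- and extracts their boundary
#' functions. With a cache directory, per-face boundaries are stored as CSVs
#' keyed by a content hash of the blended mesh and rig parameters, so re-runs
#' are read back instead of re-traced.
#'
#' @param model a [morphable_model()] with an eye pose.
#' @param res sensor resolution per face side (default 1024).
#' @param n_bins azimuth bins of the boundary functions (default 36000).
#' @param side boundary sampling rule (see [extract_boundary()]).
#' @param cache_dir optional cache directory.
#' @param verbose print per-face progress.
#' @return A [template_set()]; attributes \code{n_faces_rendered} (always
#'   \code{2 n_ids + 1}) and \code{cache} (hit/miss counts) record the run.
#' @export
render_template_set <- function(model, res = 1024L, n_bins = 36000L,
                                side = "midpoint", cache_dir = NULL,
                                verbose = FALSE) {
  rig <- model_rig(model, res)
  K <- model$n_ids
  counter <- new.env()
  counter$hits <- 0L; counter$misses <- 0L
  say <- function(...) if (verbose) message(sprintf(...))

  say("rendering generic head (1 of %d)", 2L * K + 1L)
  g <- trace_boundary_cached(blend_face(model, rep(0, K)), rig, n_bins, side,
                             cache_dir, counter)
  plus <- matrix(NA_real_, n_bins, K)
  minus <- matrix(NA_real_, n_bins, K)
  for (i in seq_len(K)) {
    e <- rep(0, K)
    e[i] <- 1
    say("rendering parameter %d = +1 (%d of %d)", i, 2L * i, 2L * K + 1L)
    plus[, i] <- as.numeric(trace_boundary_cached(blend_face(model, e), rig,
                                                  n_bins, side, cache_dir,
                                                  counter))
    e[i] <- -1
    say("rendering parameter %d = -1 (%d of %d)", i, 2L * i + 1L,
        2L * K + 1L)
    minus[, i] <- as.numeric(trace_boundary_cached(blend_face(model, e), rig,
                                                   n_bins, side, cache_dir,
                                                   counter))
  }
  out <- template_set(as.numeric(g), plus, minus)
  attr(out, "n_faces_rendered") <- 2L * K + 1L
  attr(out, "cache") <- c(hits = counter$hits, misses = counter$misses)
  attr(out, "run") <- list(res = rig$res, n_bins = n_bins, side = side)
  out
}

#' Visual field variability over random faces
#'
#' Samples \code{n_faces} coefficient vectors uniformly from \eqn{(-1, 1)},
#' synthesizes each head, traces its visibility, extracts the boundary and
#' records the percent decrease of the projected solid angle below the
#' hemisphere. Fully reproducible from \code{(model, config, seed)}.
#'
#' @param model a [morphable_model()] with an eye pose.
#' @param n_faces number of random faces.
#' @param res sensor resolution.
#' @param n_bins azimuth bins.
#' @param seed integer seed for the coefficient sample.
#' @param side boundary sampling rule.
#' @param out_dir optional directory for per-face CSV and summary JSON.
#' @param verbose print per-face progress.
#' @return A list: \code{percent_decrease} (per face), \code{omega_sr},
#'   \code{coefficients}, \code{summary} (min/mean/median/max) and
#'   \code{run} metadata.
#' @export
run_variability_experiment <- function(model, n_faces = 10000L, res = 1024L,
                                       n_bins = 36000L, seed = 1L,
                                       side = "midpoint", out_dir = NULL,
                                       verbose = FALSE) {
  rig <- model_rig(model, res)
  cc <- sample_coefficients(n_faces, model$n_ids, seed)
  pct <- omega <- numeric(n_faces)
  for (j in seq_len(n_faces)) {
    if (verbose && j %% 25L == 0L)
      message(sprintf("face %d of %d", j, n_faces))
    b <- extract_boundary(trace_occlusion(blend_face(model, cc[j, ]), rig),
                          n_bins = n_bins, side = side)
    omega[j] <- projected_solid_angle(b)
    pct[j] <- percent_decrease(omega[j])
  }
  run <- list(n_faces = n_faces, res = rig$res, n_bins = n_bins, seed = seed,
              side = side)
  out <- list(percent_decrease = pct, omega_sr = omega, coefficients = cc,
              summary = error_summary(pct), run = run)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(face = seq_len(n_faces), omega_sr = omega,
                         percent_decrease = pct),
              file.path(out_dir, "variability.csv"), row.names = FALSE)
    jsonlite::write_json(c(as.list(out$summary), run),
                         file.path(out_dir, "variability_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Prediction error of the linear boundary model over random faces
#'
#' For each sampled face, compares the boundary predicted from a template set
#' (signed predictor by default) against the boundary obtained by actually
#' tracing the blended head, accumulating the squared error per face. Also
#' identifies the best, median, 95th-percentile and worst faces by error
#' rank.
#'
#' @param model a [morphable_model()] with an eye pose.
#' @param templates a [template_set()] or [fit_templates()] result.
#' @param n_faces number of random faces.
#' @param res sensor resolution.
#' @param n_bins azimuth bins (must match the templates).
#' @param seed integer seed for the coefficient sample.
#' @param method predictor: \code{"signed"} or \code{"symmetric"}.
#' @param side boundary sampling rule for the traced reference.
#' @param out_dir optional output directory (per-face CSV + summary JSON).
#' @param verbose print per-face progress.
#' @return A list: \code{errors} (per face, degrees squared),
#'   \code{summary}, \code{faces} (indices \code{best}, \code{median},
#'   \code{p95}, \code{worst}), \code{coefficients}, \code{rendered} and
#'   \code{predicted} boundary matrices, and \code{run} metadata.
#' @export
run_prediction_experiment <- function(model, templates, n_faces = 10000L,
                                      res = 1024L, n_bins = 36000L,
                                      seed = 1L,
                                      method = c("signed", "symmetric"),
                                      side = "midpoint", out_dir = NULL,
                                      verbose = FALSE) {
  method <- match.arg(method)
  if (inherits(templates, "vf_fit")) templates <- templates$templates
  if (templates$n_bins != n_bins)
    stop("templates have ", templates$n_bins, " bins but n_bins = ", n_bins)
  rig <- model_rig(model, res)
  cc <- sample_coefficients(n_faces, model$n_ids, seed)
  rendered <- matrix(NA_real_, n_faces, n_bins)
  for (j in seq_len(n_faces)) {
    if (verbose && j %% 25L == 0L)
      message(sprintf("face %d of %d", j, n_faces))
    rendered[j, ] <- as.numeric(
      extract_boundary(trace_occlusion(blend_face(model, cc[j, ]), rig),
                       n_bins = n_bins, side = side))
  }
  predicted <- predict(templates, cc, method = method, clip = TRUE)
  errors <- rowSums((predicted - rendered)^2)
  ord <- order(errors)
  faces <- list(best = ord[1L],
                median = ord[floor((n_faces + 1L) / 2L)],
                p95 = ord[ceiling(0.95 * n_faces)],
                worst = ord[n_faces])
  run <- list(n_faces = n_faces, res = rig$res, n_bins = n_bins, seed = seed,
              method = method, side = side)
  out <- list(errors = errors, summary = error_summary(errors),
              faces = faces, coefficients = cc, rendered = rendered,
              predicted = predicted, run = run)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(face = seq_len(n_faces), sq_error = errors),
              file.path(out_dir, "prediction_errors.csv"), row.names = FALSE)
    jsonlite::write_json(c(as.list(out$summary), faces, run),
                         file.path(out_dir, "prediction_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
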