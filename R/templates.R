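#' Boundary template set
#'
#' The basis of the linear visual-field predictors: the boundary of the
#' generic (neutral) head \eqn{\theta_g(\phi)} and, for every shape parameter
#' \eqn{i}, the boundaries \eqn{\theta_{+i}(\phi)} and \eqn{\theta_{-i}(\phi)}
#' obtained with that parameter alone set to +1 or -1.
#'
#' @param theta_g numeric vector (or [vf_boundary()]) of length \code{n_bins}.
#' @param theta_plus,theta_minus \code{n_bins x n_ids} matrices whose columns
#'   are the +1 / -1 single-parameter boundaries.
#' @return An object of class \code{"vf_templates"} with fields
#'   \code{theta_g}, \code{theta_plus}, \code{theta_minus}, \code{n_ids},
#'   \code{n_bins}.
#' @export
template_set <- function(theta_g, theta_plus, theta_minus) {
  theta_g <- as.numeric(theta_g)
  theta_plus <- as.matrix(theta_plus)
  theta_minus <- as.matrix(theta_minus)
  n <- length(theta_g)
  if (nrow(theta_plus) != n || nrow(theta_minus) != n)
    stop("all boundary functions must share n_bins = ", n)
  if (ncol(theta_plus) != ncol(theta_minus))
    stop("theta_plus and theta_minus must have the same number of parameters")
  structure(list(theta_g = theta_g, theta_plus = theta_plus,
                 theta_minus = theta_minus, n_ids = ncol(theta_plus),
                 n_bins = n),
            class = "vf_templates")
}

#' @export
print.vf_templates <- function(x, ...) {
  cat("VF template set: generic + ", x$n_ids, " parameters x {+1, -1} (",
      2L * x$n_ids + 1L, " boundaries on ", x$n_bins, " bins)\n", sep = "")
  invisible(x)
}

check_coeffs <- function(t, coeffs) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != t$n_ids)
    stop("coefficient length ", length(coeffs),
         " does not match n_ids = ", t$n_ids)
  coeffs
}

#' Predict a boundary by symmetric linear combination
#'
#' \deqn{\theta(\phi) = \theta_g + \sum_i c_i (\theta_{+i} - \theta_g),}
#' the first linear approximation: only the +1 templates are used and the
#' deviation is assumed antisymmetric in each coefficient.
#'
#' @param t a [template_set()].
#' @param coeffs numeric coefficient vector of length \code{n_ids}.
#' @param clip clip the result to \[0, 90\] (default TRUE).
#' @return A [vf_boundary()] if clipped, otherwise a numeric vector.
#' @export
predict_symmetric <- function(t, coeffs, clip = TRUE) {
  coeffs <- check_coeffs(t, coeffs)
  theta <- t$theta_g * (1 - sum(coeffs)) +
    as.numeric(t$theta_plus %*% coeffs)
  if (clip) vf_boundary(pmin(pmax(theta, 0), 90)) else theta
}

#' Predict a boundary with signed single-parameter templates
#'
#' \deqn{\theta(\phi) = \theta_g + \sum_i |c_i| (\theta_{\mathrm{sign}(c_i), i}
#' - \theta_g),}
#' the refined approximation that treats the positive and negative directions
#' of each shape parameter as separate templates; a zero coefficient
#' contributes nothing.
#'
#' @inheritParams predict_symmetric
#' @return A [vf_boundary()] if clipped, otherwise a numeric vector.
#' @export
predict_signed <- function(t, coeffs, clip = TRUE) {
  coeffs <- check_coeffs(t, coeffs)
  cp <- pmax(coeffs, 0)
  cm <- pmax(-coeffs, 0)
  theta <- t$theta_g * (1 - sum(abs(coeffs))) +
    as.numeric(t$theta_plus %*% cp) + as.numeric(t$theta_minus %*% cm)
  if (clip) vf_boundary(pmin(pmax(theta, 0), 90)) else theta
}

#' Predict boundaries for one or many coefficient vectors
#'
#' @param object a [template_set()].
#' @param coefficients numeric vector (one face) or \code{n x n_ids} matrix
#'   (one face per row).
#' @param method \code{"signed"} (default) or \code{"symmetric"}.
#' @param clip clip predictions to \[0, 90\].
#' @param ... unused.
#' @return A [vf_boundary()] / numeric vector for a single face, or an
#'   \code{n x n_bins} matrix for several.
#' @export
predict.vf_templates <- function(object, coefficients,
                                 method = c("signed", "symmetric"),
                                 clip = TRUE, ...) {
  method <- match.arg(method)
  fun <- if (method == "signed") predict_signed else predict_symmetric
  if (is.matrix(coefficients)) {
    out <- t(apply(coefficients, 1L,
                   function(cc) as.numeric(fun(object, cc, clip = clip))))
    dimnames(out) <- NULL
    out
  } else {
    fun(object, coefficients, clip = clip)
  }
}

#' Sample random face coefficients
#'
#' Independent uniform(-1, 1) draws for every coefficient of every face,
#' reproducible from \code{seed} (R's default Mersenne-Twister stream; the
#' caller's RNG state is left untouched).
#'
#' @param n number of faces.
#' @param n_ids coefficients per face.
#' @param seed integer seed.
#' @return An \code{n x n_ids} numeric matrix, one face per row.
#' @export
sample_coefficients <- function(n, n_ids, seed) {
  if (n < 1L) stop("n must be >= 1")
  with_seed(seed, matrix(runif(n * n_ids, -1, 1), nrow = n, ncol = n_ids))
}

#' Squared error between two boundary functions
#'
#' \eqn{\sum_\phi (a_\phi - b_\phi)^2} in squared degrees, the per-face error
#' the prediction experiments and the validation loss accumulate.
#'
#' @param a,b boundary functions (or numeric vectors) with equal bin counts.
#' @return A single number (degrees squared).
#' @export
boundary_sq_error <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("boundary bin counts differ: ", length(a), " vs ", length(b))
  sum((a - b)^2)
}

#' Save a template set as boundary CSVs plus an index
#'
#' Writes \code{generic.csv}, \code{plus_###.csv}, \code{minus_###.csv} and
#' \code{index.json} into \code{dir}.
#'
#' @param t a [template_set()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the index path.
#' @export
save_templates <- function(t, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_boundary_csv(vf_boundary(t$theta_g), file.path(dir, "generic.csv"))
  pn <- sprintf("plus_%03d.csv", seq_len(t$n_ids))
  mn <- sprintf("minus_%03d.csv", seq_len(t$n_ids))
  for (i in seq_len(t$n_ids)) {
    write_boundary_csv(vf_boundary(t$theta_plus[, i]), file.path(dir, pn[i]))
    write_boundary_csv(vf_boundary(t$theta_minus[, i]), file.path(dir, mn[i]))
  }
  index <- file.path(dir, "index.json")
  jsonlite::write_json(list(n_ids = t$n_ids, n_bins = t$n_bins,
                            generic = "generic.csv", plus = as.list(pn),
                            minus = as.list(mn)),
                       index, auto_unbox = TRUE, digits = NA)
  invisible(index)
}

#' Load a template set saved by [save_templates()]
#' @param dir directory containing \code{index.json} and the boundary CSVs.
#' @return A [template_set()].
#' @export
load_templates <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"),
                               simplifyVector = TRUE)
  g <- as.numeric(read_boundary_csv(file.path(dir, index$generic)))
  plus <- vapply(index$plus, function(p)
    as.numeric(read_boundary_csv(file.path(dir, p))), numeric(index$n_bins))
  minus <- vapply(index$minus, function(p)
    as.numeric(read_boundary_csv(file.path(dir, p))), numeric(index$n_bins))
  template_set(g, plus, minus)
}
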