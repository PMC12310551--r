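## Design matrix of the signed linear predictor: one row per face, columns
## (generic, plus_1..K, minus_1..K). With V the (2K+1) x n_bins template
## value matrix, predictions for all faces are A %*% V, which makes the
## weighted loss an (unnormalized) convex quadratic in V.
design_matrix <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  cbind(1 - rowSums(abs(coefficients)),
        pmax(coefficients, 0),
        pmax(-coefficients, 0))
}

templates_to_matrix <- function(t) {
  rbind(t$theta_g, t(t$theta_plus), t(t$theta_minus))
}

matrix_to_templates <- function(V, n_ids) {
  template_set(V[1L, ],
               t(V[1L + seq_len(n_ids), , drop = FALSE]),
               t(V[1L + n_ids + seq_len(n_ids), , drop = FALSE]))
}

check_fit_inputs <- function(templates, coefficients, boundaries) {
  coefficients <- as.matrix(coefficients)
  boundaries <- as.matrix(boundaries)
  if (ncol(coefficients) != templates$n_ids)
    stop("coefficient columns (", ncol(coefficients),
         ") do not match n_ids = ", templates$n_ids)
  if (ncol(boundaries) != templates$n_bins)
    stop("boundary columns (", ncol(boundaries),
         ") do not match n_bins = ", templates$n_bins)
  if (nrow(coefficients) != nrow(boundaries))
    stop("coefficients and boundaries must have one row per face")
  list(coefficients = coefficients, boundaries = boundaries)
}

#' Weighted training loss of a candidate template set
#'
#' The optimization objective: an unnormalized weighted sum of squares
#' \deqn{L = w_{pred} \sum_\phi \sum_j (\theta^{j,pred} - \theta^{j,rend})^2
#'  + w_{anchor} \Big[ \sum_\phi (\theta_{g,opt} - \theta_{g,rend})^2 +
#'  \sum_i \sum_\pm \sum_\phi (\theta_{\pm i,opt} - \theta_{\pm i,rend})^2
#'  \Big],}
#' where predictions use the signed linear predictor evaluated unclipped
#' (clipping would break the quadratic structure; it is applied only when
#' boundaries are reported). The first term scores predictions for the
#' training faces, the anchor term keeps the optimized templates near their
#' rendered values.
#'
#' @param opt candidate [template_set()] being optimized.
#' @param rendered the rendered (anchor) [template_set()].
#' @param coefficients \code{n x n_ids} matrix of face coefficients.
#' @param boundaries \code{n x n_bins} matrix of rendered face boundaries.
#' @param w_pred,w_anchor loss weights (defaults 0.75 / 0.25; must sum to 1).
#' @return The loss value (degrees squared).
#' @export
training_loss <- function(opt, rendered, coefficients, boundaries,
                          w_pred = 0.75, w_anchor = 0.25) {
  dat <- check_fit_inputs(opt, coefficients, boundaries)
  if (opt$n_bins != rendered$n_bins || opt$n_ids != rendered$n_ids)
    stop("opt and rendered template sets have mismatched dimensions")
  A <- design_matrix(dat$coefficients)
  V <- templates_to_matrix(opt)
  V0 <- templates_to_matrix(rendered)
  w_pred * sum((A %*% V - dat$boundaries)^2) + w_anchor * sum((V - V0)^2)
}

#' Validation loss of a candidate template set
#'
#' \eqn{\sum_\phi \sum_j (\theta^{j,pred} - \theta^{j,rend})^2} over the
#' reserved validation faces (no anchor term), i.e. the sum of
#' [boundary_sq_error()] over those faces with unclipped predictions.
#'
#' @param opt candidate [template_set()].
#' @param coefficients \code{n x n_ids} matrix of validation coefficients.
#' @param boundaries \code{n x n_bins} matrix of their rendered boundaries.
#' @return The loss value (degrees squared).
#' @export
validation_loss <- function(opt, coefficients, boundaries) {
  dat <- check_fit_inputs(opt, coefficients, boundaries)
  A <- design_matrix(dat$coefficients)
  sum((A %*% templates_to_matrix(opt) - dat$boundaries)^2)
}

#' Closed-form minimizer of the template loss
#'
#' The training loss is a convex quadratic in the \eqn{(2 n_{ids} + 1)}
#' template values of each azimuth bin, and the bins are uncoupled, so the
#' exact minimizer solves one small normal-equation system shared by all
#' bins:
#' \deqn{(w_{pred} A^\top A + w_{anchor} I)\, V =
#'       w_{pred} A^\top R + w_{anchor} V_0.}
#' Used as the independent oracle for the gradient-descent fitter.
#'
#' @inheritParams training_loss
#' @param rendered rendered [template_set()] (anchor and initialization).
#' @return The minimizing [template_set()].
#' @export
closed_form_templates <- function(rendered, coefficients, boundaries,
                                  w_pred = 0.75, w_anchor = 0.25) {
  dat <- check_fit_inputs(rendered, coefficients, boundaries)
  A <- design_matrix(dat$coefficients)
  p <- 2L * rendered$n_ids + 1L
  M <- w_pred * crossprod(A) + w_anchor * diag(p)
  rhs <- w_pred * crossprod(A, dat$boundaries) +
    w_anchor * templates_to_matrix(rendered)
  V <- tryCatch(solve(M, rhs), error = function(e)
    stop("singular normal-equation system: ", conditionMessage(e),
         call. = FALSE))
  matrix_to_templates(V, rendered$n_ids)
}

#' Optimize boundary templates by gradient descent
#'
#' Full-batch gradient descent on the weighted quadratic loss
#' ([training_loss()]) over all template values, initialized at the rendered
#' templates. The first \code{n_validation} faces are reserved for
#' validation (they never enter the gradient); descent stops when the
#' validation loss ([validation_loss()]) has not improved for
#' \code{patience} consecutive epochs, or at \code{max_epochs}. The template
#' set with the best validation loss is returned.
#'
#' The gradient is analytic:
#' \eqn{\nabla_V L = 2 w_{pred} A^\top (A V - R) + 2 w_{anchor} (V - V_0)}.
#' With \code{lr = "auto"} the step size is set to \eqn{1/\lambda_{max}} of
#' the loss Hessian (estimated by power iteration), which guarantees
#' monotone descent; the numeric default 5e-8 is appropriate for
#' full-scale problems (thousands of faces, tens of thousands of bins) where
#' the unnormalized loss and its curvature are large.
#'
#' @param rendered rendered [template_set()] (initialization and anchor).
#' @param coefficients \code{n x n_ids} matrix of face coefficients; the
#'   first \code{n_validation} rows are the validation faces.
#' @param boundaries \code{n x n_bins} matrix of rendered face boundaries.
#' @param n_validation number of leading faces reserved for validation.
#' @param w_pred,w_anchor loss weights (must sum to 1).
#' @param lr learning rate: a positive number, or \code{"auto"}.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs hard epoch cap.
#' @param early_stopping if \code{TRUE} (default) stop on validation patience
#'   and return the best-validation iterate; if \code{FALSE} run the full
#'   \code{max_epochs} and return the final iterate (used when comparing the
#'   descent against the closed-form minimizer, which optimizes the training
#'   objective alone).
#' @param verbose print progress every 100 epochs.
#' @return An object of class \code{"vf_fit"}; see [coef.vf_fit()],
#'   [predict.vf_fit()] and the other standard modelling methods.
#' @export
fit_templates <- function(rendered, coefficients, boundaries,
                          n_validation = 100L, w_pred = 0.75,
                          w_anchor = 0.25, lr = 5e-8, patience = 10L,
                          max_epochs = 1e5, early_stopping = TRUE,
                          verbose = FALSE) {
  cl <- match.call()
  dat <- check_fit_inputs(rendered, coefficients, boundaries)
  n <- nrow(dat$coefficients)
  n_validation <- as.integer(n_validation)
  if (n_validation < 1L || n_validation >= n)
    stop("need 0 < n_validation < number of faces")
  if (abs(w_pred + w_anchor - 1) > 1e-12)
    stop("w_pred + w_anchor must equal 1")
  val_idx <- seq_len(n_validation)
  Av <- design_matrix(dat$coefficients[val_idx, , drop = FALSE])
  Rv <- dat$boundaries[val_idx, , drop = FALSE]
  A <- design_matrix(dat$coefficients[-val_idx, , drop = FALSE])
  R <- dat$boundaries[-val_idx, , drop = FALSE]
  V0 <- templates_to_matrix(rendered)

  AtA <- crossprod(A)
  AtR <- crossprod(A, R)
  p <- nrow(V0)

  if (identical(lr, "auto")) {
    ## power iteration for the largest Hessian eigenvalue
    ## H = 2 (w_pred AtA + w_anchor I)
    H <- 2 * (w_pred * AtA + w_anchor * diag(p))
    v <- rep(1 / sqrt(p), p)
    for (it in seq_len(60L)) v <- unit3_any(H %*% v)
    lam <- as.numeric(crossprod(v, H %*% v))
    lr <- 1 / lam
  }
  if (!is.numeric(lr) || length(lr) != 1L || !is.finite(lr) || lr <= 0)
    stop("lr must be a positive number or \"auto\"")

  loss_at <- function(V) {
    w_pred * sum((A %*% V - R)^2) + w_anchor * sum((V - V0)^2)
  }
  vloss_at <- function(V) sum((Av %*% V - Rv)^2)

  V <- V0
  best_V <- V0
  best_val <- vloss_at(V0)
  best_epoch <- 0L
  since_best <- 0L
  hist_epoch <- integer(0)
  hist_train <- hist_val <- numeric(0)
  tl <- loss_at(V0)
  hist_epoch[1L] <- 0L; hist_train[1L] <- tl; hist_val[1L] <- best_val

  epoch <- 0L
  increased <- FALSE
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    G <- 2 * (w_pred * (AtA %*% V - AtR) + w_anchor * (V - V0))
    V <- V - lr * G
    tl_new <- loss_at(V)
    vl <- vloss_at(V)
    if (!is.finite(tl_new) || !is.finite(vl))
      stop("optimization diverged (non-finite loss); try a smaller lr")
    if (tl_new - tl > 1e-9 * (hist_train[1L] + 1)) increased <- TRUE
    tl <- tl_new
    hist_epoch[epoch + 1L] <- epoch
    hist_train[epoch + 1L] <- tl
    hist_val[epoch + 1L] <- vl
    if (vl < best_val) {
      best_val <- vl
      best_V <- V
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (early_stopping && since_best >= patience) break
    }
    if (verbose && epoch %% 100L == 0L)
      message(sprintf("epoch %d: training %.6g, validation %.6g",
                      epoch, tl, vl))
  }
  if (increased)
    warning("training loss increased during descent; lr may be too large")

  keep_V <- if (early_stopping) best_V else V
  structure(list(
    templates = matrix_to_templates(keep_V, rendered$n_ids),
    rendered = rendered,
    history = data.frame(epoch = hist_epoch, training_loss = hist_train,
                         validation_loss = hist_val),
    best_epoch = best_epoch,
    config = list(n_validation = n_validation, w_pred = w_pred,
                  w_anchor = w_anchor, lr = lr, patience = patience,
                  max_epochs = max_epochs, early_stopping = early_stopping),
    coefficients = dat$coefficients,
    boundaries = dat$boundaries,
    call = cl
  ), class = "vf_fit")
}

unit3_any <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("power iteration collapsed to zero")
  as.numeric(v) / n
}

#' Summary statistics of per-face errors
#'
#' Minimum, mean, median and maximum of a vector of per-face squared
#' boundary errors (the median uses the midpoint rule for even counts).
#'
#' @param errors non-empty numeric vector.
#' @return Named numeric vector \code{min}, \code{mean}, \code{median},
#'   \code{max}.
#' @export
error_summary <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("errors must be non-empty")
  if (any(!is.finite(errors))) stop("errors must be finite")
  c(min = min(errors), mean = mean(errors), median = median(errors),
    max = max(errors))
}
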