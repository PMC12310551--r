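#' @export
print.vf_fit <- function(x, ...) {
  h <- x$history
  cat("Optimized VF template set (", x$templates$n_ids, " parameters, ",
      x$templates$n_bins, " bins)\n", sep = "")
  cat(sprintf("  %d training faces, %d validation faces\n",
              nrow(x$coefficients) - x$config$n_validation,
              x$config$n_validation))
  cat(sprintf("  epochs run: %d (best validation at epoch %d)\n",
              max(h$epoch), x$best_epoch))
  cat(sprintf("  training loss: %.6g -> %.6g\n",
              h$training_loss[1], tail(h$training_loss, 1)))
  cat(sprintf("  validation loss: %.6g -> %.6g\n",
              h$validation_loss[1], min(h$validation_loss)))
  invisible(x)
}

#' @export
summary.vf_fit <- function(object, ...) {
  h <- object$history
  val_idx <- seq_len(object$config$n_validation)
  pred <- predict(object$templates,
                  object$coefficients[val_idx, , drop = FALSE], clip = TRUE)
  errs <- rowSums((pred - object$boundaries[val_idx, , drop = FALSE])^2)
  out <- list(
    config = object$config,
    epochs = max(h$epoch),
    best_epoch = object$best_epoch,
    initial = h[1L, ],
    final = h[nrow(h), ],
    best_validation = min(h$validation_loss),
    validation_error_summary = error_summary(errs)
  )
  class(out) <- "summary.vf_fit"
  out
}

#' @export
print.summary.vf_fit <- function(x, ...) {
  cat("Template optimization summary\n")
  cat(sprintf("  weights: %.2f prediction + %.2f anchor, lr %.3g\n",
              x$config$w_pred, x$config$w_anchor, x$config$lr))
  cat(sprintf("  epochs: %d (best validation at %d, patience %d)\n",
              x$epochs, x$best_epoch, x$config$patience))
  cat(sprintf("  training loss %.6g -> %.6g\n",
              x$initial$training_loss, x$final$training_loss))
  cat(sprintf("  validation loss %.6g -> %.6g\n",
              x$initial$validation_loss, x$best_validation))
  cat("  per-validation-face squared error (clipped predictions):\n")
  print(signif(x$validation_error_summary, 5))
  invisible(x)
}

#' Extract optimized template values
#'
#' @param object a [fit_templates()] result.
#' @param ... unused.
#' @return The \code{(2 n_ids + 1) x n_bins} matrix of optimized template
#'   values, rows named \code{generic}, \code{plus_i}, \code{minus_i}.
#' @export
coef.vf_fit <- function(object, ...) {
  V <- templates_to_matrix(object$templates)
  rownames(V) <- c("generic",
                   sprintf("plus_%d", seq_len(object$templates$n_ids)),
                   sprintf("minus_%d", seq_len(object$templates$n_ids)))
  V
}

#' Predict boundaries from an optimized fit
#'
#' @param object a [fit_templates()] result.
#' @param coefficients coefficient vector or matrix (defaults to the
#'   training-set coefficients).
#' @param method \code{"signed"} or \code{"symmetric"}.
#' @param clip clip predictions to \[0, 90\].
#' @param ... unused.
#' @return As [predict.vf_templates()].
#' @export
predict.vf_fit <- function(object, coefficients = NULL,
                           method = c("signed", "symmetric"), clip = TRUE,
                           ...) {
  if (is.null(coefficients)) coefficients <- object$coefficients
  predict(object$templates, coefficients, method = match.arg(method),
          clip = clip)
}

#' @export
fitted.vf_fit <- function(object, ...) {
  predict(object, object$coefficients, clip = TRUE)
}

#' Per-face boundary residuals of a fit
#'
#' Rendered minus predicted boundary values on the stored faces.
#'
#' @param object a [fit_templates()] result.
#' @param ... unused.
#' @return An \code{n x n_bins} matrix of residuals (degrees).
#' @export
residuals.vf_fit <- function(object, ...) {
  object$boundaries - fitted(object)
}

#' Plot optimization progress or fitted boundaries
#'
#' @param x a [fit_templates()] result.
#' @param which \code{"history"} (training and validation loss per epoch) or
#'   \code{"templates"} (generic boundary before and after optimization).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.vf_fit <- function(x, which = c("history", "templates"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    plot(h$epoch, h$training_loss, type = "l", log = "y", xlab = "epoch",
         ylab = "loss (deg^2)", ...)
    lines(h$epoch, h$validation_loss, lty = 2)
    abline(v = x$best_epoch, lty = 3)
    legend("topright", c("training", "validation"), lty = c(1, 2),
           bty = "n")
  } else {
    phi <- phi_bin_centers(x$templates$n_bins)
    plot(phi, x$rendered$theta_g, type = "l",
         xlab = expression(phi ~ "(deg)"), ylab = expression(theta ~ "(deg)"),
         ylim = c(0, 90), ...)
    lines(phi, x$templates$theta_g, lty = 2)
    legend("bottomright", c("rendered generic", "optimized generic"),
           lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Simulate random faces and their predicted boundaries
#'
#' Draws \code{nsim} coefficient vectors uniformly from \eqn{(-1, 1)} and
#' predicts their boundaries from the optimized templates.
#'
#' @param object a [fit_templates()] result.
#' @param nsim number of faces.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list with \code{coefficients} (\code{nsim x n_ids}) and
#'   \code{boundaries} (\code{nsim x n_bins}, clipped predictions).
#' @export
simulate.vf_fit <- function(object, nsim = 1L, seed = 1L, ...) {
  cc <- sample_coefficients(nsim, object$templates$n_ids, seed)
  list(coefficients = cc,
       boundaries = predict(object, cc, clip = TRUE))
}
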