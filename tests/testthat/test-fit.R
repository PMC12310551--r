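# Small self-consistent instances: boundaries generated exactly by the signed
# linear predictor from known templates, so the loss landscape has a known
# minimum and the closed-form solver acts as the oracle for the descent path.

make_instance <- function(n_bins = 16L, n_ids = 2L, n = 50L, seed = 42L,
                          perturb = 0.3, noise = 0) {
  set.seed(seed)
  gen <- random_templates(n_bins, n_ids, seed = seed)
  cc <- sample_coefficients(n, n_ids, seed = seed + 1L)
  R <- predict(gen, cc, clip = FALSE)
  if (noise > 0) R <- R + matrix(rnorm(n * n_bins, 0, noise), n)
  anchor <- gen
  if (perturb > 0) {
    anchor$theta_g <- gen$theta_g + rnorm(n_bins, 0, perturb)
    anchor$theta_plus <- gen$theta_plus +
      matrix(rnorm(n_bins * n_ids, 0, perturb), n_bins)
    anchor$theta_minus <- gen$theta_minus +
      matrix(rnorm(n_bins * n_ids, 0, perturb), n_bins)
  }
  list(gen = gen, anchor = anchor, cc = cc, R = R)
}

test_that("training loss reproduces hand-evaluated cases", {
  ## one face, one bin, prediction off by one, opt == rendered templates
  t0 <- template_set(50, matrix(55, 1L), matrix(45, 1L))
  L <- training_loss(t0, t0, matrix(0, 1L, 1L), matrix(51, 1L, 1L))
  expect_equal(L, 0.75)
  ## rendered boundary at the rendered generic, opt generic one degree off:
  ## both the prediction and the anchor terms contribute
  t1 <- template_set(51, matrix(55, 1L), matrix(45, 1L))
  L2 <- training_loss(t1, t0, matrix(0, 1L, 1L), matrix(50, 1L, 1L))
  expect_equal(L2, 0.75 * 1 + 0.25 * 1)
  ## fully self-consistent data at the anchor: zero loss
  inst <- make_instance(perturb = 0)
  expect_equal(training_loss(inst$gen, inst$gen, inst$cc, inst$R), 0,
               tolerance = 1e-18)
})

test_that("validation loss is the summed squared boundary error", {
  inst <- make_instance(n = 10L, perturb = 0)
  expect_equal(validation_loss(inst$gen, inst$cc, inst$R), 0,
               tolerance = 1e-18)
  m <- 16L
  off <- inst$R + 1  # every bin of every face off by one degree
  expect_equal(validation_loss(inst$gen, inst$cc, off), 10 * m)
  ## cross-check against per-face boundary_sq_error
  pred <- predict(inst$gen, inst$cc, clip = FALSE)
  expect_equal(validation_loss(inst$gen, inst$cc, off),
               sum(vapply(1:10, function(j)
                 boundary_sq_error(pred[j, ], off[j, ]), numeric(1))))
})

test_that("with no training faces the anchor term fixes the optimum", {
  t0 <- random_templates(12L, 2L, seed = 3L)
  cf <- closed_form_templates(t0, matrix(numeric(0), 0L, 2L),
                              matrix(numeric(0), 0L, 12L))
  expect_equal(cf$theta_g, t0$theta_g, tolerance = 1e-12)
  expect_equal(cf$theta_plus, t0$theta_plus, tolerance = 1e-12)
})

test_that("anchor-only weights return the rendered templates exactly", {
  inst <- make_instance(noise = 1)
  cf <- closed_form_templates(inst$anchor, inst$cc, inst$R,
                              w_pred = 0, w_anchor = 1)
  expect_equal(cf$theta_g, inst$anchor$theta_g, tolerance = 1e-12)
  expect_equal(cf$theta_minus, inst$anchor$theta_minus, tolerance = 1e-12)
})

test_that("closed form recovers generating templates on sign-covered data", {
  inst <- make_instance(perturb = 0)
  expect_true(all(colSums(inst$cc > 0) > 0) &&
              all(colSums(inst$cc < 0) > 0))
  cf <- closed_form_templates(inst$gen, inst$cc, inst$R)
  expect_equal(cf$theta_g, inst$gen$theta_g, tolerance = 1e-9)
  expect_equal(cf$theta_plus, inst$gen$theta_plus, tolerance = 1e-9)
  expect_equal(cf$theta_minus, inst$gen$theta_minus, tolerance = 1e-9)
})

test_that("the closed-form solution beats random perturbations", {
  inst <- make_instance(noise = 0.5)
  cf <- closed_form_templates(inst$anchor, inst$cc, inst$R)
  L_cf <- training_loss(cf, inst$anchor, inst$cc, inst$R)
  set.seed(99)
  for (k in 1:100) {
    p <- cf
    p$theta_g <- p$theta_g + rnorm(16, 0, 0.05)
    p$theta_plus <- p$theta_plus + matrix(rnorm(32, 0, 0.05), 16L)
    expect_gte(training_loss(p, inst$anchor, inst$cc, inst$R), L_cf)
  }
})

test_that("the per-bin solves equal the joint solve", {
  inst <- make_instance(noise = 0.5)
  cf <- closed_form_templates(inst$anchor, inst$cc, inst$R)
  for (b in c(1L, 7L, 16L)) {
    one <- closed_form_templates(
      template_set(inst$anchor$theta_g[b],
                   inst$anchor$theta_plus[b, , drop = FALSE],
                   inst$anchor$theta_minus[b, , drop = FALSE]),
      inst$cc, inst$R[, b, drop = FALSE])
    expect_equal(one$theta_g, cf$theta_g[b], tolerance = 1e-10)
    expect_equal(as.numeric(one$theta_plus), cf$theta_plus[b, ],
                 tolerance = 1e-10)
  }
})

test_that("gradient descent converges to the closed-form minimizer", {
  inst <- make_instance()
  train <- 11:50
  cf <- closed_form_templates(inst$anchor, inst$cc[train, ], inst$R[train, ])
  fit <- fit_templates(inst$anchor, inst$cc, inst$R, n_validation = 10L,
                       lr = "auto", max_epochs = 20000L,
                       early_stopping = FALSE)
  L_cf <- training_loss(cf, inst$anchor, inst$cc[train, ], inst$R[train, ])
  L_gd <- training_loss(fit$templates, inst$anchor, inst$cc[train, ],
                        inst$R[train, ])
  expect_lt(abs(L_gd - L_cf) / L_cf, 1e-6)
  ## descent on a convex quadratic with auto step never increases the loss
  expect_true(all(diff(fit$history$training_loss) <= 1e-9))
})

test_that("validation-driven early stopping returns the best iterate", {
  inst <- make_instance(perturb = 0.5)
  fit <- fit_templates(inst$anchor, inst$cc, inst$R, n_validation = 10L,
                       lr = "auto", patience = 25L, max_epochs = 5000L)
  h <- fit$history
  expect_equal(fit$best_epoch, h$epoch[which.min(h$validation_loss)])
  expect_lte(max(h$epoch), fit$best_epoch + 25L)
  ## on self-consistent data (no anchor pull) validation collapses
  fit2 <- fit_templates(inst$anchor, inst$cc, inst$R, n_validation = 10L,
                        w_pred = 1, w_anchor = 0, lr = "auto",
                        patience = 50L, max_epochs = 20000L)
  h2 <- fit2$history
  expect_true(all(diff(h2$validation_loss) <= 1e-9))
  expect_lt(min(h2$validation_loss), 1e-6 * h2$validation_loss[1L])
})

test_that("divergent learning rates raise an informative error", {
  inst <- make_instance()
  expect_error(
    suppressWarnings(fit_templates(inst$anchor, inst$cc, inst$R,
                                   n_validation = 10L, lr = 10,
                                   max_epochs = 5000L,
                                   early_stopping = FALSE)),
    "smaller lr")
})

test_that("error summaries match an independently coded reference", {
  expect_equal(error_summary(c(1, 2, 3)),
               c(min = 1, mean = 2, median = 2, max = 3))
  expect_equal(error_summary(7), c(min = 7, mean = 7, median = 7, max = 7))
  set.seed(12)
  x <- rexp(1e4, 0.1)
  s <- sort(x)
  n <- length(x)
  ref <- c(min = s[1L], mean = sum(x) / n,
           median = (s[n / 2] + s[n / 2 + 1L]) / 2, max = s[n])
  expect_equal(error_summary(x), ref)
  expect_error(error_summary(numeric(0)), "non-empty")
})

test_that("fit objects expose the standard modelling methods", {
  inst <- make_instance(perturb = 0.4)
  fit <- fit_templates(inst$gen, inst$cc, inst$R, n_validation = 10L,
                       lr = "auto", patience = 20L, max_epochs = 2000L)
  V <- coef(fit)
  expect_equal(dim(V), c(5L, 16L))
  expect_equal(rownames(V)[1:2], c("generic", "plus_1"))
  pred <- predict(fit, inst$cc[1L, ])
  expect_s3_class(pred, "vf_boundary")
  expect_equal(dim(residuals(fit)), dim(inst$R))
  expect_equal(dim(fitted(fit)), dim(inst$R))
  sim <- simulate(fit, nsim = 4L, seed = 2L)
  expect_equal(dim(sim$boundaries), c(4L, 16L))
  expect_output(print(fit), "Optimized VF template set")
  expect_output(print(summary(fit)), "validation loss")
})
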