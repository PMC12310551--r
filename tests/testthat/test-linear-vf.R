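test_that("both predictors collapse to the templates at unit coefficients", {
  t <- random_templates(24L, 3L, seed = 1L)
  expect_equal(as.numeric(predict_symmetric(t, c(0, 0, 0))), t$theta_g)
  expect_equal(as.numeric(predict_signed(t, c(0, 0, 0))), t$theta_g)
  e2 <- c(0, 1, 0)
  expect_equal(as.numeric(predict_symmetric(t, e2, clip = FALSE)),
               t$theta_plus[, 2L])
  expect_equal(as.numeric(predict_signed(t, -e2, clip = FALSE)),
               t$theta_minus[, 2L])
  expect_error(predict_signed(t, c(1, 0)), "n_ids")
})

test_that("predictor arithmetic matches hand evaluation", {
  t <- random_templates(16L, 2L, seed = 2L)
  ## symmetric with c_k = -1: theta_g - (theta_plus - theta_g)
  got <- predict_symmetric(t, c(-1, 0), clip = FALSE)
  expect_equal(got, t$theta_g - (t$theta_plus[, 1L] - t$theta_g))
  ## signed with c_k = +0.5: halfway toward the +1 template
  got2 <- predict_signed(t, c(0, 0.5), clip = FALSE)
  expect_equal(got2, t$theta_g + 0.5 * (t$theta_plus[, 2L] - t$theta_g))
})

test_that("signed and symmetric predictors agree for antisymmetric templates", {
  set.seed(5)
  for (k in 1:5) {
    g <- runif(20, 30, 60)
    plus <- g + matrix(rnorm(40, 0, 4), 20L)
    minus <- 2 * g - plus  # theta_minus = 2 theta_g - theta_plus
    t <- template_set(g, plus, minus)
    cc <- runif(2, -1, 1)
    expect_equal(predict_signed(t, cc, clip = FALSE),
                 predict_symmetric(t, cc, clip = FALSE), tolerance = 1e-12)
  }
})

test_that("predictions are Lipschitz in each coefficient", {
  t <- random_templates(30L, 2L, seed = 6L)
  set.seed(7)
  for (i in 1:2) {
    lip <- max(abs(t$theta_plus[, i] - t$theta_g),
               abs(t$theta_minus[, i] - t$theta_g))
    cc <- runif(2, -1, 1)
    delta <- runif(1, -0.5, 0.5)
    cc2 <- cc; cc2[i] <- cc2[i] + delta
    dev <- max(abs(predict_signed(t, cc2, clip = FALSE) -
                   predict_signed(t, cc, clip = FALSE)))
    expect_lte(dev, abs(delta) * lip + 1e-9)
  }
})

test_that("coefficient sampling is seeded, bounded and unbiased", {
  s1 <- sample_coefficients(50L, 4L, seed = 42L)
  s2 <- sample_coefficients(50L, 4L, seed = 42L)
  expect_identical(s1, s2)
  expect_true(all(s1 > -1 & s1 < 1))
  big <- sample_coefficients(1e5, 1L, seed = 9L)
  sigma <- sqrt(1 / 3)
  expect_lt(abs(mean(big)), 3 * sigma / sqrt(1e5))
})

test_that("boundary squared error is the plain sum of squares", {
  b <- vf_boundary(rep(45, 100))
  expect_equal(boundary_sq_error(b, b), 0)
  expect_equal(boundary_sq_error(b, rep(46, 100)), 100)
  m <- 37; d <- 2.5
  expect_equal(boundary_sq_error(rep(10, m), rep(10 + d, m)), m * d^2)
  expect_error(boundary_sq_error(rep(1, 10), rep(1, 11)), "differ")
})

test_that("the signed predictor is exact on self-generated boundaries", {
  t <- random_templates(20L, 3L, seed = 8L)
  cc <- sample_coefficients(10L, 3L, seed = 8L)
  R <- predict(t, cc, clip = FALSE)
  for (j in 1:10)
    expect_lt(boundary_sq_error(predict_signed(t, cc[j, ], clip = FALSE),
                                R[j, ]), 1e-18)
})

test_that("template sets round-trip through their CSV directory layout", {
  t <- random_templates(18L, 2L, seed = 10L)
  ## keep values inside [0, 90] so the boundary CSVs validate
  t$theta_plus <- pmin(pmax(t$theta_plus, 0), 90)
  t$theta_minus <- pmin(pmax(t$theta_minus, 0), 90)
  dir <- withr::local_tempdir()
  save_templates(t, dir)
  t2 <- load_templates(dir)
  expect_equal(t2$theta_g, t$theta_g, tolerance = 1e-9)
  expect_equal(t2$theta_plus, t$theta_plus, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(t2$n_ids, 2L)
})
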