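test_that("fully open and fully occluded maps give constant boundaries", {
  rig <- build_rig(default_eye(), res = 32L)
  b_open <- extract_boundary(manual_maps(rig, FALSE), n_bins = 90)
  expect_equal(as.numeric(b_open), rep(90, 90))
  b_occ <- extract_boundary(manual_maps(rig, TRUE), n_bins = 90)
  expect_equal(as.numeric(b_occ), rep(0, 90))
  bad <- manual_maps(rig, FALSE)
  bad$forward <- matrix(0.5, 32L, 32L)
  expect_error(extract_boundary(bad, n_bins = 90), "binary")
})

test_that("cap boundaries reproduce the closed form per bin", {
  cap <- make_cap_occluder(45)
  rig <- build_rig(cap$eye, res = 256L)
  b <- extract_boundary(trace_occlusion(cap$mesh, rig), n_bins = 360)
  expect_true(all(abs(as.numeric(b) - 45) < 0.5))
})

test_that("half-space boundary is 90 upward and 0 downward", {
  hs <- make_halfspace_occluder()
  rig <- build_rig(hs$eye, res = 512L)
  b <- as.numeric(extract_boundary(trace_occlusion(hs$mesh, rig),
                                   n_bins = 360))
  phi <- phi_bin_centers(360)
  expect_true(all(b[phi > 20 & phi < 160] > 89))
  expect_true(all(b[phi > 200 & phi < 340] < 2))
})

test_that("projected solid angle matches closed forms", {
  expect_equal(projected_solid_angle(vf_boundary(rep(90, 360))), pi)
  expect_equal(projected_solid_angle(vf_boundary(rep(30, 360))), pi / 4)
  expect_equal(projected_solid_angle(vf_boundary(rep(0, 360))), 0)
  expect_error(projected_solid_angle(rep(91, 10)), "0, 90")
})

test_that("percent decrease is the hemisphere-relative complement", {
  expect_equal(percent_decrease(pi), 0)
  expect_equal(percent_decrease(0), 100)
  expect_equal(round(percent_decrease(2.8277)), 10)
  expect_error(percent_decrease(pi + 0.1), "pi")
  expect_error(percent_decrease(-0.1), "pi")
})

test_that("pointwise-larger boundaries never decrease the solid angle", {
  set.seed(4)
  for (k in 1:20) {
    b1 <- runif(180, 0, 90)
    b2 <- pmin(b1 + runif(180, 0, 20), 90)
    expect_gte(projected_solid_angle(b2), projected_solid_angle(b1))
  }
  expect_true(all(percent_decrease(runif(50, 0, pi)) >= 0))
  expect_true(all(percent_decrease(runif(50, 0, pi)) <= 100))
})

test_that("solid angle is stable across bin counts on smooth fields", {
  cap <- make_cap_occluder(50)
  rig <- build_rig(cap$eye, res = 256L)
  maps <- trace_occlusion(cap$mesh, rig)
  om_coarse <- projected_solid_angle(extract_boundary(maps, n_bins = 360))
  om_fine <- projected_solid_angle(extract_boundary(maps, n_bins = 36000))
  expect_lt(abs(om_coarse - om_fine) / om_fine, 0.001)
})

test_that("boundary CSV round-trips", {
  b <- vf_boundary(seq(10, 80, length.out = 120))
  f <- withr::local_tempfile(fileext = ".csv")
  write_boundary_csv(b, f)
  df <- read.csv(f)
  expect_named(df, c("phi_deg", "theta_deg"))
  expect_equal(nrow(df), 120L)
  b2 <- read_boundary_csv(f)
  expect_equal(as.numeric(b2), as.numeric(b), tolerance = 1e-9)
})
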