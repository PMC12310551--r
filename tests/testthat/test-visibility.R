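test_that("the default rig has five 90-degree faces at res 1024", {
  rig <- build_rig(default_eye())
  expect_equal(length(rig$faces), 5L)
  expect_named(rig$faces, c("forward", "up", "down", "temporal", "nasal"))
  expect_equal(rig$res, 1024L)
  expect_equal(rig$fov, 90)
  expect_equal(rig$eps_offset, 1e-4)  # below the 2e-4 mm placement bound
  expect_error(build_rig(default_eye(), fov = 60), "90")
  expect_error(eye_pose(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0.01)),
               "orthogonal|unit")
})

test_that("the five frusta cover the front hemisphere", {
  set.seed(1)
  n <- 1e5
  d <- matrix(rnorm(3 * n), ncol = 3L)
  d <- d / sqrt(rowSums(d^2))
  d[, 3] <- abs(d[, 3])  # forward component >= 0 => theta <= 90
  rig <- build_rig(default_eye(), res = 64L)
  owner <- vfsim:::direction_owner_face(rig, d)
  expect_false(anyNA(owner))
})

test_that("pixel directions follow pinhole geometry", {
  rig <- build_rig(default_eye(), res = 17L)
  ctr <- (17L + 1L) / 2L
  expect_equal(as.numeric(pixel_to_direction(rig, 1L, ctr, ctr)),
               c(0, 0, 1), tolerance = 1e-12)
  expect_equal(as.numeric(pixel_to_direction(rig, "up", ctr, ctr)),
               c(0, 1, 0), tolerance = 1e-12)
  ## a true face corner direction (+/-1, +/-1, 1)/sqrt(3) is 54.7356 deg off
  ## axis; the outermost pixel center sits half a pixel inside
  corner <- c(1, 1, 1) / sqrt(3)
  ang <- acos(sum(corner * c(0, 0, 1))) * 180 / pi
  expect_equal(ang, 54.7356, tolerance = 1e-4)
  px <- pixel_to_direction(rig, 1L, 1L, 17L)
  ang_px <- acos(px[1L, 3L]) * 180 / pi
  expect_lt(abs(ang_px - ang), 3)  # within the half-pixel offset at res 17
  expect_error(pixel_to_direction(rig, 1L, 0L, 1L), "out of range")
})

test_that("polar coordinates follow the temporal-origin convention", {
  eye <- default_eye()
  expect_equal(direction_to_polar(eye, c(0, 0, 1))[1L, ], c(theta = 0, phi = 0))
  expect_equal(direction_to_polar(eye, c(1, 0, 0))[1L, ],
               c(theta = 90, phi = 0))
  expect_equal(direction_to_polar(eye, c(0, 1, 0))[1L, ],
               c(theta = 90, phi = 90))
  expect_equal(unname(direction_to_polar(eye, c(0, -1, 0))[1L, "phi"]), 270)
  ## chirality flag flips the azimuth sense
  eye2 <- eye_pose(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
                   chirality = -1L)
  expect_equal(unname(direction_to_polar(eye2, c(0, 1, 0))[1L, "phi"]), 270)
  expect_error(direction_to_polar(eye, c(0, 0, 0)), "zero")
  ## round trip through polar_to_direction
  set.seed(2)
  d <- matrix(rnorm(300), ncol = 3L)
  d <- d / sqrt(rowSums(d^2))
  pol <- direction_to_polar(eye, d)
  d2 <- polar_to_direction(eye, pol[, "theta"], pol[, "phi"])
  expect_equal(d2, d, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ray-triangle intersection returns exact plane distances", {
  tri <- tri_mesh(rbind(c(2, -1, -1), c(2, 1, -1), c(2, 0, 1)),
                  matrix(1:3, 1L))
  expect_equal(intersect_ray(tri, c(0, 0, 0), c(1, 0, 0)), 2)
  expect_true(is.na(intersect_ray(tri, c(0, 0, 0), c(-1, 0, 0))))
  expect_error(intersect_ray(tri, c(0, 0, 0), c(0, 0, 0)), "degenerate")
})

test_that("BVH traversal is exactly equivalent to brute force", {
  mesh <- random_triangle_soup(200L, seed = 9L)
  set.seed(10)
  n <- 1000L
  O <- matrix(runif(3 * n, -0.5, 0.5), ncol = 3L)
  D <- matrix(rnorm(3 * n), ncol = 3L)
  D <- D / sqrt(rowSums(D^2))
  t_bvh <- intersect_ray(mesh, O, D, method = "bvh")
  t_brute <- intersect_ray(mesh, O, D, method = "brute")
  expect_identical(t_bvh, t_brute)
  expect_gt(sum(!is.na(t_bvh)), 0L)  # the fixture does produce hits
})

test_that("traced occlusion matches the analytic cap membership", {
  cap <- make_cap_occluder(45)
  rig <- build_rig(cap$eye, res = 128L)
  maps <- trace_occlusion(cap$mesh, rig)
  ## probe directions well away from the rim
  set.seed(3)
  pol <- cbind(theta = runif(400, 0, 90), phi = runif(400, 0, 360))
  away <- abs(pol[, "theta"] - 45) > 2
  pol <- pol[away, ]
  d <- polar_to_direction(rig$eye, pol[, "theta"], pol[, "phi"])
  px <- vfsim:::direction_to_pixel(rig, d)
  got <- mapply(function(f, i, j) maps[[f]][i, j], px$face, px$i, px$j)
  expect_equal(got, pol[, "theta"] > 45, ignore_attr = TRUE)

  ## doubling the resolution leaves interior classification unchanged
  rig2 <- build_rig(cap$eye, res = 256L)
  maps2 <- trace_occlusion(cap$mesh, rig2)
  px2 <- vfsim:::direction_to_pixel(rig2, d)
  got2 <- mapply(function(f, i, j) maps2[[f]][i, j], px2$face, px2$i, px2$j)
  expect_identical(got, got2)
})
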