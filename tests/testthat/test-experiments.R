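# Experiment drivers run here at deliberately small scale (coarse meshes,
# res 64, few faces); scaling only changes precision, not structure.

small_model <- function() make_synthetic_model(mesh_resolution = 20L)

test_that("template rendering produces 2K+1 boundaries", {
  m <- small_model()
  tpl <- render_template_set(m, res = 64L, n_bins = 90L)
  expect_s3_class(tpl, "vf_templates")
  expect_equal(tpl$n_ids, 3L)
  expect_equal(attr(tpl, "n_faces_rendered"), 7L)
  expect_equal(tpl$n_bins, 90L)
  expect_true(all(tpl$theta_g >= 0 & tpl$theta_g <= 90))
})

test_that("the render cache avoids recomputation and changes nothing", {
  m <- small_model()
  dir <- withr::local_tempdir()
  t1 <- render_template_set(m, res = 48L, n_bins = 60L, cache_dir = dir)
  expect_equal(unname(attr(t1, "cache")["misses"]), 7L)
  t2 <- render_template_set(m, res = 48L, n_bins = 60L, cache_dir = dir)
  expect_equal(unname(attr(t2, "cache")["hits"]), 7L)
  expect_equal(unname(attr(t2, "cache")["misses"]), 0L)
  expect_equal(t2$theta_g, t1$theta_g, tolerance = 1e-9)
  expect_equal(t2$theta_plus, t1$theta_plus, tolerance = 1e-9)
})

test_that("variability runs are reproducible and bounded", {
  m <- small_model()
  v1 <- run_variability_experiment(m, n_faces = 5L, res = 64L,
                                   n_bins = 90L, seed = 1L)
  v2 <- run_variability_experiment(m, n_faces = 5L, res = 64L,
                                   n_bins = 90L, seed = 1L)
  expect_identical(v1$percent_decrease, v2$percent_decrease)
  expect_true(all(v1$percent_decrease >= 0 & v1$percent_decrease <= 100))
  expect_equal(v1$summary,
               error_summary(v1$percent_decrease))
  ## output files
  dir <- withr::local_tempdir()
  run_variability_experiment(m, n_faces = 2L, res = 48L, n_bins = 60L,
                             seed = 2L, out_dir = dir)
  expect_true(file.exists(file.path(dir, "variability.csv")))
  expect_true(file.exists(file.path(dir, "variability_summary.json")))
})

test_that("prediction experiments score faces and rank them consistently", {
  m <- small_model()
  tpl <- render_template_set(m, res = 64L, n_bins = 90L)
  pe <- run_prediction_experiment(m, tpl, n_faces = 8L, res = 64L,
                                  n_bins = 90L, seed = 3L)
  expect_length(pe$errors, 8L)
  expect_equal(pe$summary, error_summary(pe$errors))
  expect_equal(pe$faces$best, which.min(pe$errors))
  expect_equal(pe$faces$worst, which.max(pe$errors))
  expect_true(pe$errors[pe$faces$p95] >= median(pe$errors))
  ## the linear prediction must beat the generic-only baseline
  base <- vapply(seq_len(8L), function(j)
    boundary_sq_error(tpl$theta_g, pe$rendered[j, ]), numeric(1))
  expect_lt(mean(pe$errors), mean(base))
})

test_that("self-generated boundaries are predicted with zero error", {
  ## when the "rendered" boundaries come from the signed predictor itself,
  ## the experiment's error pathway must report (numerically) zero
  t <- random_templates(30L, 2L, seed = 4L)
  cc <- sample_coefficients(6L, 2L, seed = 4L)
  R <- predict(t, cc, clip = FALSE)
  errs <- vapply(1:6, function(j)
    boundary_sq_error(predict_signed(t, cc[j, ], clip = FALSE), R[j, ]),
    numeric(1))
  expect_true(all(errs < 1e-18))
})

test_that("occlusion maps export as valid P5 images", {
  cap <- make_cap_occluder(40)
  rig <- build_rig(cap$eye, res = 16L)
  maps <- trace_occlusion(cap$mesh, rig)
  dir <- withr::local_tempdir()
  paths <- write_occlusion_pgm(maps, dir)
  expect_length(paths, 5L)
  hdr <- readBin(paths[1L], "raw", 2L)
  expect_equal(rawToChar(hdr), "P5")
  expect_equal(file.size(paths[1L]), nchar("P5\n16 16\n255\n") + 16 * 16)
})
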