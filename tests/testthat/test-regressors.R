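# Model schemas, the linear baseline and the DECT empirical conversions.

test_that("model schemas carry the documented channel sets", {
  expect_equal(model_schema("A")$channels, c("t1w", "t1f", "t2stir"))
  expect_equal(model_schema("B")$channels, c("t1w", "t1f", "t2stir", "zte"))
  expect_equal(model_schema("A")$targets, c("density", "rsp"))
  expect_equal(model_schema("C")$targets, "density")
  expect_equal(model_schema("D")$channels, c("t1w", "t2stir", "rho_e", "z_eff"))
  expect_equal(model_schema("C", channels = c("t1w", "t1f"))$channels,
               c("t1w", "t1f"))
})

test_that("linear baseline recovers an exact line and rejects degenerate input", {
  s <- runif(200)
  tab <- tibble::tibble(t1w = s, density = 2 * s + 0.5, rsp = 1,
                        phantom = "x", tissue = "x")
  fit <- linear_baseline(tab, "density")
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-9)
  expect_equal(predict(fit, tab), tab$density, tolerance = 1e-9)

  const <- tibble::tibble(t1w = s, density = 1.3)
  cf <- linear_baseline(const, "density")
  expect_equal(cf$slope, 0, tolerance = 1e-9)
  expect_equal(cf$intercept, 1.3, tolerance = 1e-9)

  flat <- tibble::tibble(t1w = rep(1, 10), density = runif(10))
  expect_error(linear_baseline(flat, "density"), "constant")
})

test_that("DECT empirical density is the printed affine law", {
  expect_equal(dect_empirical_density(1.0), 1.0014, tolerance = 1e-12)
  expect_equal(dect_empirical_density(0), -0.1746, tolerance = 1e-12)
  expect_equal(dect_empirical_density(2) - dect_empirical_density(1), 1.176,
               tolerance = 1e-12)
  arr <- array(runif(24), c(2, 3, 4))
  out <- dect_empirical_density(arr)
  expect_equal(dim(out), dim(arr))
  expect_equal(as.vector(out), -0.1746 + 1.176 * as.vector(arr))
  expect_error(dect_empirical_density(c(1, NA)), "finite")
})

test_that("DECT empirical RSP follows the half-open branch structure", {
  expect_equal(dect_empirical_rsp(1.0, 9.0), 0.9905, tolerance = 1e-12)
  expect_equal(dect_empirical_rsp(1.0, 0.2), 1.0, tolerance = 1e-12)
  expect_equal(dect_empirical_rsp(1.35, 12.0), 1.312875, tolerance = 1e-12)

  # boundary voxels take the right-hand branch (half-open intervals)
  expect_equal(dect_empirical_rsp(1, 0.5), 1.1114 - 0.0148 * 0.5)
  expect_equal(dect_empirical_rsp(1, 8.5), 0.9905)
  expect_equal(dect_empirical_rsp(1, 10), 1.1117 - 0.116)

  # homogeneous of degree 1 in rho_e within a branch
  set.seed(1)
  z <- runif(100, 0, 15)
  r <- runif(100, 0.1, 2)
  k <- runif(100, 0.5, 2)
  expect_equal(dect_empirical_rsp(k * r, z), k * dect_empirical_rsp(r, z),
               tolerance = 1e-12)

  expect_error(dect_empirical_rsp(1, -0.1), "non-negative")
  expect_error(dect_empirical_rsp(NaN, 1), "finite")
})

test_that("predict_map applies fits voxel-wise with sentinel and schema checks", {
  labels <- small_scene()
  wm <- water_mask(labels)
  st <- default_signal_table()
  images <- list()
  for (sq in c("t1w", "t2stir")) {
    images[[sq]] <- normalize_by_water(
      render_sequence(labels, st, sq, noisy = FALSE), wm
    )
  }
  tab <- extract_voi_voxels(images, labels, n_per_phantom = 200,
                            vois = voi_table(labels, radius_vox = 4), seed = 1)
  fit <- train_fcnn(tab, NULL, target = "density", config = tiny_fcnn_config(),
                    channels = c("t1w", "t2stir"))

  mask <- labels$grid > 1L
  m1 <- predict_map(fit, images, mask)
  m2 <- predict_map(fit, images, mask)
  expect_identical(unclass(m1), unclass(m2))
  expect_true(all(is.na(m1[!mask])))
  idx <- which(mask)[1:5]
  expect_equal(
    m1[idx],
    predict(fit, tibble::tibble(t1w = images$t1w[idx], t2stir = images$t2stir[idx])),
    tolerance = 1e-12
  )
  expect_error(predict_map(fit, images["t1w"], mask), "t2stir")
})

test_that("a trained bundle covers the schema's targets", {
  tab <- signature_table(n = 80, channels = c("t1w", "t2stir"),
                         tissues = c("muscle", "adipose", "skin"))
  parts <- split_train_val(tab, 0.75, seed = 2)
  bundle <- train_regressor_bundle(
    parts$train, parts$val,
    schema = model_schema("C"), config = tiny_fcnn_config()
  )
  expect_named(bundle$fits, "density")
  expect_equal(bundle$fits$density$channels, c("t1w", "t2stir"))
})
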