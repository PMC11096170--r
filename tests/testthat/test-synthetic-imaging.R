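# Phantom scene voxelization and rendering.

test_that("build_scene voxelizes geometry correctly", {
  labels <- small_scene()
  dims <- dim(labels$grid)
  expect_equal(dims[1], 40)

  # insert centers carry their tissue ids
  pl <- labels$placements
  for (i in seq_len(nrow(pl))) {
    expect_equal(
      labels$grid[
        round(pl$center_slice[i]) + 1, round(pl$center_row[i]) + 1,
        round(pl$center_col[i]) + 1
      ],
      pl$id[i]
    )
  }
  # a voxel well outside the cylinder radius is air
  expect_equal(labels$grid[1, 1, 1], 0L)

  # water volume matches the analytic cylinder minus inserts (3% at this
  # small radius; voxelization error shrinks with the cylinder size)
  vox_vol <- prod(labels$spacing)
  water_vol <- sum(labels$grid == 1L) * vox_vol
  analytic <- pi * 20^2 * 40 - 2 * (20 * 12 * 12)
  expect_lt(abs(water_vol - analytic) / analytic, 0.03)

  # at acquisition scale the voxelization error is within 2%
  full <- build_scene(phantom_scene())
  full_water <- sum(full$grid == 1L) * prod(full$spacing)
  full_analytic <- pi * 84.1^2 * 254 - 57 * 57 * 129
  expect_lt(abs(full_water - full_analytic) / full_analytic, 0.02)

  # labels partition the grid: air + water + inserts account for every voxel
  expect_equal(sum(labels$grid %in% labels$legend), length(labels$grid))

  # deterministic
  expect_identical(labels$grid, small_scene()$grid)
})

test_that("invalid insert geometry is rejected", {
  expect_error(
    build_scene(phantom_scene(
      placements = tibble::tibble(tissue = "muscle", offset_row = 30),
      container_radius_mm = 20, container_height_mm = 40,
      insert_dims_mm = c(20, 12, 12)
    )),
    "outside the container"
  )
  expect_error(
    build_scene(phantom_scene(
      placements = tibble::tibble(tissue = c("muscle", "skin"), offset_row = c(0, 2)),
      container_radius_mm = 20, container_height_mm = 40,
      insert_dims_mm = c(20, 12, 12)
    )),
    "overlap"
  )
})

test_that("render_sequence honors nominal signals, SNR and the seed", {
  labels <- small_scene()
  st <- default_signal_table()

  clean <- render_sequence(labels, st, "t1w", noisy = FALSE)
  sig <- tidyr::pivot_wider(st$signals, names_from = "sequence", values_from = "signal")
  expect_equal(unique(clean[labels$grid == 1L]), 1.0)
  expect_equal(
    unique(clean[labels$grid == labels$legend[["muscle"]]]),
    sig$t1w[sig$tissue == "muscle"]
  )
  expect_equal(unique(clean[labels$grid == 0L]), 0)

  noisy1 <- render_sequence(labels, st, "t1w", noisy = TRUE, seed = 9)
  noisy2 <- render_sequence(labels, st, "t1w", noisy = TRUE, seed = 9)
  expect_identical(unclass(noisy1), unclass(noisy2))

  wm <- water_mask(labels)
  expect_gt(sum(wm), 1e4)
  snr_emp <- mean(noisy1[wm]) / sd(noisy1[wm])
  expect_lt(abs(snr_emp - 30) / 30, 0.1)

  # noise never changes the label geometry
  expect_identical(labels$grid, small_scene()$grid)

  ric <- render_sequence(
    labels, default_signal_table(noise_model = "rician"), "t1w",
    noisy = TRUE, seed = 3
  )
  expect_true(all(ric >= 0))

  st_missing <- signal_table(
    st$signals[st$signals$tissue != "adipose", ]
  )
  expect_error(render_sequence(labels, st_missing, "t1w"), "adipose")
})

test_that("parametric maps carry the physics values per tissue", {
  labels <- small_scene()
  maps <- render_parametric_maps(labels, noise_frac = NULL)

  wm <- water_mask(labels)
  expect_equal(unique(maps$rho_e[wm]), 1, tolerance = 1e-12)
  expect_equal(unique(maps$z_eff[wm]), 7.45, tolerance = 1e-2)

  # noiseless maps are piecewise constant: one value per tissue id (+ air)
  expect_lte(length(unique(as.vector(maps$rho_e))), length(labels$legend))

  ha_scene <- build_scene(phantom_scene(
    placements = tibble::tibble(tissue = "ha_bone_45"),
    container_radius_mm = 20, container_height_mm = 40,
    insert_dims_mm = c(20, 12, 12)
  ))
  ha_maps <- render_parametric_maps(ha_scene, noise_frac = NULL)
  ha_vox <- ha_scene$grid == ha_scene$legend[["ha_bone_45"]]
  expect_equal(unique(ha_maps$rho_e[ha_vox]), 1.351, tolerance = 1e-3)

  noisy <- render_parametric_maps(labels, seed = 5)
  expect_equal(sd(noisy$rho_e[wm]), 0.008, tolerance = 0.1)
  expect_error(
    render_parametric_maps(labels, tissues = tissue_table()[1, ]),
    "no tissue specification"
  )
})

test_that("ground-truth maps look up the measured columns", {
  labels <- small_scene()
  truth <- ground_truth_maps(labels)
  mus <- labels$grid == labels$legend[["muscle"]]
  expect_equal(unique(truth$density[mus]), 1.064)
  expect_equal(unique(truth$rsp[mus]), 1.056)
  wm <- water_mask(labels)
  expect_equal(unique(truth$density[wm]), 1)
  expect_equal(unique(truth$rsp[wm]), 1)
})

test_that("volumes round-trip through NIfTI with spacing", {
  labels <- small_scene(spacing = c(1.5, 1, 1))
  img <- render_sequence(labels, default_signal_table(), "t2stir",
                         noisy = TRUE, seed = 2)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(img, path)
  back <- read_volume(path, channel = "t2stir")
  expect_equal(as.vector(back), as.vector(img), tolerance = 1e-12)
  expect_equal(attr(back, "spacing"), c(1.5, 1, 1))
})
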