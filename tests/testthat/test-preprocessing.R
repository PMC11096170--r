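# Water normalization, VOI extraction, splitting and slice bookkeeping.

test_that("water normalization fixes the water mean at 1 and is idempotent", {
  labels <- small_scene()
  wm <- water_mask(labels)

  uniform <- volume_image(array(200, dim(labels$grid)), labels$spacing, "t1w")
  norm <- normalize_by_water(uniform, wm)
  expect_equal(unique(as.vector(norm)), 1)

  img <- render_sequence(labels, default_signal_table(), "t1w",
                         noisy = TRUE, seed = 1)
  n1 <- normalize_by_water(img, wm)
  expect_lt(abs(mean(n1[wm]) - 1), 1e-9)
  n2 <- normalize_by_water(n1, wm)
  expect_equal(as.vector(n2), as.vector(n1), tolerance = 1e-9)

  # value 300 against water mean 200 -> 1.5
  two <- volume_image(array(200, dim(labels$grid)), labels$spacing, "x")
  two[!wm] <- 300
  expect_equal(unique(normalize_by_water(two, wm)[!wm]), 1.5)

  expect_error(normalize_by_water(img, array(FALSE, dim(img))), "empty")
  neg <- volume_image(array(-5, dim(labels$grid)), labels$spacing, "x")
  expect_error(normalize_by_water(neg, wm), "positive")
})

extract_small <- function(labels, n = 150, policy = "first_half", seed = 3,
                          noisy = TRUE) {
  wm <- water_mask(labels)
  images <- lapply(c("t1w", "t2stir"), function(sq) {
    normalize_by_water(
      render_sequence(labels, default_signal_table(), sq,
                      noisy = noisy, seed = seed + match(sq, c("t1w", "t2stir"))),
      wm
    )
  })
  names(images) <- c("t1w", "t2stir")
  extract_voi_voxels(images, labels,
    n_per_phantom = n, slice_policy = policy,
    vois = voi_table(labels, radius_vox = 4), seed = seed
  )
}

test_that("VOI extraction counts, targets and determinism", {
  labels <- small_scene()
  tab <- extract_small(labels)
  expect_equal(nrow(tab), 2 * 150)
  expect_equal(names(tab)[1:2], c("t1w", "t2stir"))
  expect_true(all(is.finite(as.matrix(tab[, 1:2]))))

  # targets come from the measured table
  expect_equal(unique(tab$density[tab$tissue == "muscle"]), 1.064)
  expect_equal(unique(tab$rsp[tab$tissue == "adipose"]), 0.979)

  # per-phantom row conservation
  expect_equal(as.integer(table(tab$phantom)), c(150L, 150L))

  # no duplicate voxels within a phantom (sampling without replacement)
  expect_false(any(duplicated(tab[, c("phantom", "voxel")])))

  expect_identical(extract_small(labels), tab)

  expect_error(extract_small(labels, n = 1e6), "short by")
  raw <- list(t1w = render_sequence(labels, default_signal_table(), "t1w",
                                    noisy = FALSE))
  expect_error(
    extract_voi_voxels(raw, labels, n_per_phantom = 10,
                       vois = voi_table(labels, radius_vox = 4)),
    "normalized"
  )
})

test_that("extracted channels are invariant to a global gain", {
  labels <- small_scene()
  wm <- water_mask(labels)
  img <- render_sequence(labels, default_signal_table(), "t1w",
                         noisy = TRUE, seed = 5)
  scaled <- volume_image(unclass(img) * 7.3, labels$spacing, "t1w")
  t1 <- extract_voi_voxels(
    list(t1w = normalize_by_water(img, wm)), labels,
    n_per_phantom = 100, vois = voi_table(labels, radius_vox = 4), seed = 2
  )
  t2 <- extract_voi_voxels(
    list(t1w = normalize_by_water(scaled, wm)), labels,
    n_per_phantom = 100, vois = voi_table(labels, radius_vox = 4), seed = 2
  )
  expect_equal(t1$t1w, t2$t1w, tolerance = 1e-12)
})

test_that("train/application voxel sets are disjoint and cover both halves", {
  labels <- small_scene()
  first <- extract_small(labels, policy = "first_half")
  second <- extract_small(labels, policy = "second_half", seed = 11)
  expect_length(intersect(first$voxel, second$voxel), 0)
  expect_true(all(first$slice < 20))
  expect_true(all(second$slice >= 20))

  app <- application_mask(labels)
  expect_equal(attr(app, "slices"), 20:39)
  expect_length(intersect(first$voxel, app), 0)
  expect_true(all(second$voxel %in% app))
})

test_that("slice halving conventions", {
  expect_equal(mrirsp:::first_half_slices(60), 0:29)
  expect_equal(mrirsp:::second_half_slices(60), 30:59)
  # odd S gives the extra slice to the application half
  expect_equal(mrirsp:::first_half_slices(5), 0:1)
  expect_equal(mrirsp:::second_half_slices(5), 2:4)
  expect_equal(mrirsp:::second_half_slices(2), 1)
  expect_error(mrirsp:::second_half_slices(1), "single-slice")
})

test_that("75/25 split partitions exactly and preserves phantom proportions", {
  tab <- signature_table(n = 100, tissues = c("muscle", "adipose"))
  parts <- split_train_val(tab, 0.75, seed = 4)
  expect_equal(nrow(parts$train), 150)
  expect_equal(nrow(parts$val), 50)
  expect_equal(as.integer(table(parts$train$phantom)), c(75L, 75L))

  # disjoint and exhaustive partition
  all_rows <- dplyr::bind_rows(parts$train, parts$val)
  expect_equal(nrow(all_rows), nrow(tab))
  expect_equal(
    dplyr::arrange(all_rows, dplyr::across(dplyr::everything())),
    dplyr::arrange(tab, dplyr::across(dplyr::everything()))
  )

  expect_identical(split_train_val(tab, 0.75, seed = 4), parts)

  all_train <- split_train_val(tab, 1.0, seed = 1)
  expect_equal(nrow(all_train$train), nrow(tab))
  expect_equal(nrow(all_train$val), 0)

  expect_error(split_train_val(tab[0, ], 0.75), "empty")
  expect_error(split_train_val(tab, 1.5), "train_fraction")
})

test_that("voxel tables round-trip through CSV", {
  tab <- signature_table(n = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_voxel_table(tab, path)
  back <- read_voxel_table(path)
  expect_equal(back$density, tab$density)
  expect_equal(back$t1w, tab$t1w)
})
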