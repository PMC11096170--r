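# Normalization, volume-of-interest voxel extraction, dataset splitting and
# training-matrix assembly: the bridge from image volumes to the N x k voxel
# tables the regressors consume.

#' Water mask of a scene
#'
#' @param labels A `label_map`.
#' @return Logical array marking water-labeled voxels.
#' @export
water_mask <- function(labels) {
  labels$grid == labels$legend[["water"]]
}

#' Normalize an image by its mean water signal
#'
#' Divides the whole volume by the mean intensity over the water mask, fixing
#' the water reference at 1.0 regardless of scanner gain. The operation is
#' idempotent (up to floating point) and makes downstream voxel tables
#' invariant to any global positive rescaling of the raw image.
#'
#' @param image A [volume_image()].
#' @param mask Logical array (same shape) marking pure-water voxels, e.g.
#'   [water_mask()].
#' @return The normalized [volume_image()] (`normalized` flag set).
#' @export
normalize_by_water <- function(image, mask) {
  if (!any(mask)) abort("water mask is empty")
  m <- mean(image[mask])
  if (!is.finite(m) || m <= 0) abort("mean water signal must be positive")
  volume_image(
    unclass(image) / m, attr(image, "spacing"),
    channel = attr(image, "channel"), normalized = TRUE
  )
}

first_half_slices <- function(n_slice) {
  if (n_slice < 2L) abort("cannot halve a single-slice volume")
  seq_len(n_slice %/% 2L) - 1L
}

second_half_slices <- function(n_slice) {
  if (n_slice < 2L) abort("cannot halve a single-slice volume")
  seq.int(n_slice %/% 2L, n_slice - 1L)
}

#' Per-insert volumes of interest
#'
#' One circular in-plane VOI per insert, centered on the insert centroid with
#' a default radius of 15 voxels, spanning the insert's slice extent. The VOI
#' radius must keep the disc inside the insert cross-section.
#'
#' @param labels A `label_map`.
#' @param radius_vox VOI radius in voxels.
#' @return Tibble with one row per insert: `tissue`, `id`, center
#'   coordinates, `radius_vox` and the insert slice extent (0-based).
#' @export
voi_table <- function(labels, radius_vox = 15) {
  pl <- labels$placements
  half_row <- (pl$row_hi - pl$row_lo) / 2
  half_col <- (pl$col_hi - pl$col_lo) / 2
  if (any(radius_vox > pmin(half_row, half_col))) {
    abort("VOI radius exceeds the insert cross-section")
  }
  tibble(
    tissue = pl$tissue, id = pl$id,
    center_row = (pl$row_lo + pl$row_hi) / 2,
    center_col = (pl$col_lo + pl$col_hi) / 2,
    radius_vox = radius_vox,
    slice_lo = pl$slice_lo, slice_hi = pl$slice_hi
  )
}

# 1-based (row, col) matrix of the disc of voxel centers within `radius` of
# (center_row, center_col), both 0-based.
disc_voxels <- function(center_row, center_col, radius) {
  r0 <- round(center_row)
  c0 <- round(center_col)
  d <- ceiling(radius)
  dr <- rep(-d:d, times = 2 * d + 1)
  dc <- rep(-d:d, each = 2 * d + 1)
  keep <- (r0 + dr - center_row)^2 + (c0 + dc - center_col)^2 <= radius^2
  cbind(row = r0 + dr[keep] + 1L, col = c0 + dc[keep] + 1L)
}

#' Extract a voxel table from channel volumes
#'
#' Samples `n_per_phantom` voxels uniformly without replacement from each
#' insert's VOI restricted to the allowed slices, and assembles the N x k
#' channel matrix together with per-voxel ground-truth targets, tissue label
#' and provenance. This is the training currency of the voxel-wise
#' regressors: with the study-scale per-phantom count of 24,000 voxels it
#' reproduces 168,000 x 3 (7 phantoms, 3 channels) and 120,000 x 4
#' (5 phantoms, 4 channels) matrices.
#'
#' @param images Named list of water-normalized [volume_image()] channels;
#'   the list order defines the column order.
#' @param labels A `label_map`.
#' @param tissues Tissue tibble supplying density/RSP targets.
#' @param n_per_phantom Voxels to sample per insert.
#' @param slice_policy `"first_half"` (training convention: slices
#'   `[0, floor(S/2))`), `"second_half"`, or `"all"`.
#' @param vois VOI definitions, see [voi_table()].
#' @param seed Integer seed controlling the sampling.
#' @return A tibble with one channel column per image, `density`, `rsp`,
#'   `tissue`, `phantom`, `slice` (0-based) and `voxel` (linear array index).
#' @export
extract_voi_voxels <- function(images, labels, tissues = tissue_table(),
                               n_per_phantom = 24000,
                               slice_policy = c("first_half", "all", "second_half"),
                               vois = voi_table(labels), seed = NULL) {
  slice_policy <- match.arg(slice_policy)
  if (length(images) == 0L) abort("at least one channel image is required")
  if (is.null(names(images)) || any(names(images) == "")) {
    abort("channel images must be named")
  }
  for (img in images) {
    if (!isTRUE(attr(img, "normalized"))) {
      abort("channel images must be water-normalized (see normalize_by_water())")
    }
    if (!identical(dim(img), dim(labels$grid))) {
      abort("channel image shape does not match the label map")
    }
  }
  truth <- ground_truth_maps(labels, tissues)
  dims <- dim(labels$grid)
  allowed <- switch(slice_policy,
    first_half = first_half_slices(dims[1]),
    second_half = second_half_slices(dims[1]),
    all = seq_len(dims[1]) - 1L
  )

  with_seed(seed, {
    out <- vector("list", nrow(vois))
    for (i in seq_len(nrow(vois))) {
      v <- vois[i, ]
      disc <- disc_voxels(v$center_row, v$center_col, v$radius_vox)
      slices <- intersect(allowed, seq.int(v$slice_lo, v$slice_hi))
      n_avail <- nrow(disc) * length(slices)
      if (n_avail < n_per_phantom) {
        abort(sprintf(
          "phantom '%s' has only %d VOI voxels in the allowed slices (%d requested, short by %d)",
          v$tissue, n_avail, n_per_phantom, n_per_phantom - n_avail
        ))
      }
      pick <- sort(sample.int(n_avail, n_per_phantom))
      slice_idx <- slices[(pick - 1L) %/% nrow(disc) + 1L]   # 0-based slice
      d_idx <- (pick - 1L) %% nrow(disc) + 1L
      lin <- (slice_idx + 1L) +
        (disc[d_idx, "row"] - 1L) * dims[1] +
        (disc[d_idx, "col"] - 1L) * dims[1] * dims[2]
      row <- tibble(
        tissue = v$tissue, phantom = v$tissue,
        slice = slice_idx, voxel = lin,
        density = truth$density[lin], rsp = truth$rsp[lin]
      )
      for (ch in names(images)) row[[ch]] <- images[[ch]][lin]
      out[[i]] <- row
    }
    tab <- dplyr::bind_rows(out)
    tab <- tab[, c(names(images), "density", "rsp", "tissue", "phantom", "slice", "voxel")]
    if (any(!is.finite(as.matrix(tab[names(images)])))) {
      abort("non-finite channel values in extracted voxel table")
    }
    tab
  })
}

#' Split a voxel table into training and validation parts
#'
#' Randomly partitions rows with the given training fraction, stratified by
#' phantom so per-phantom proportions are preserved within rounding. The two
#' parts are disjoint and exhaustive, and the partition is deterministic for
#' a given seed.
#'
#' @param table A voxel table from [extract_voi_voxels()].
#' @param train_fraction Fraction of rows assigned to training (default 0.75).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `val`.
#' @export
split_train_val <- function(table, train_fraction = 0.75, seed = NULL) {
  if (nrow(table) == 0L) abort("cannot split an empty voxel table")
  if (train_fraction <= 0 || train_fraction > 1) {
    abort("train_fraction must lie in (0, 1]")
  }
  with_seed(seed, {
    groups <- if ("phantom" %in% names(table)) table$phantom else rep(1L, nrow(table))
    take <- logical(nrow(table))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      n_train <- round(train_fraction * length(idx))
      take[sample(idx, n_train)] <- TRUE
    }
    list(train = table[take, ], val = table[!take, ])
  })
}

#' Application-slice voxel indices
#'
#' The evaluation convention: the first half of the slices is reserved for
#' training, the second half (`[floor(S/2), S)`, including the extra slice
#' when S is odd) is the application set. Returns the linear indices of all
#' voxels in the application slices; they are disjoint from any first-half
#' extraction by construction.
#'
#' @param labels A `label_map`.
#' @param slice_policy Currently only `"second_half"`.
#' @return Sorted integer vector of linear voxel indices with the 0-based
#'   slice ids in attribute `"slices"`.
#' @export
application_mask <- function(labels, slice_policy = "second_half") {
  stopifnot(identical(slice_policy, "second_half"))
  dims <- dim(labels$grid)
  slices <- second_half_slices(dims[1])
  per_slice <- as.vector(outer(
    slices + 1L,
    seq_len(dims[2] * dims[3]) - 1L,
    function(s, rc) s + rc * dims[1]
  ))
  structure(sort(per_slice), slices = slices)
}

#' Round-trip a voxel table to CSV
#'
#' @param table Voxel table tibble.
#' @param path CSV path.
#' @return `write_voxel_table()` returns `path` invisibly;
#'   `read_voxel_table()` the tibble.
#' @export
write_voxel_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_table
#' @export
read_voxel_table <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
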