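# Synthetic phantom scenes: a cylindrical water container holding rectangular
# tissue-substitute inserts, voxelized on a common grid, rendered into
# per-sequence MR volumes and DECT-style parametric maps with known truth.
#
# Coordinate convention: arrays are indexed (slice, row, column); voxel centers
# sit at integer 0-based coordinates scaled by the spacing (mm).

#' Run an expression with a temporarily fixed RNG state
#'
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Phantom scene configuration
#'
#' Geometry of the synthetic acquisition: a water-filled cylinder (default
#' 84.1 mm radius, 254 mm height, matching an adult head-and-neck surrogate)
#' holding one or more 57 x 57 x 129 mm^3 tissue-substitute inserts.
#'
#' @param placements Tibble or data frame with columns `tissue` and optional
#'   `offset_row`, `offset_col`, `offset_slice` (mm displacements of the insert
#'   center from the container center). Default: a single `muscle` insert at
#'   the center.
#' @param container_radius_mm,container_height_mm Cylinder dimensions, mm.
#' @param insert_dims_mm Insert edge lengths, mm, in (slice, row, column)
#'   order; the long axis runs along the slice direction.
#' @param voxel_spacing_mm Spacing per axis (slice, row, column), mm.
#' @param sequences Ordered character vector of channel names to render.
#' @param seed Scene-level default seed used by rendering helpers.
#' @return An object of class `phantom_scene_config`.
#' @export
phantom_scene <- function(placements = tibble(tissue = "muscle"),
                          container_radius_mm = 84.1,
                          container_height_mm = 254,
                          insert_dims_mm = c(129, 57, 57),
                          voxel_spacing_mm = c(1, 1, 1),
                          sequences = c("t1w", "t1f", "t2stir", "zte"),
                          seed = NULL) {
  placements <- as_tibble(placements)
  if (nrow(placements) < 1L) abort("at least one insert placement is required")
  for (col in c("offset_row", "offset_col", "offset_slice")) {
    if (!col %in% names(placements)) placements[[col]] <- 0
  }
  if (any(voxel_spacing_mm <= 0)) abort("voxel spacing must be positive")
  if (length(voxel_spacing_mm) == 1L) voxel_spacing_mm <- rep(voxel_spacing_mm, 3)
  if (length(insert_dims_mm) != 3L) abort("insert_dims_mm must have length 3")
  structure(
    list(
      placements = placements,
      container_radius_mm = container_radius_mm,
      container_height_mm = container_height_mm,
      insert_dims_mm = insert_dims_mm,
      voxel_spacing_mm = voxel_spacing_mm,
      sequences = sequences,
      seed = seed
    ),
    class = "phantom_scene_config"
  )
}

#' Voxelize a phantom scene into a label map
#'
#' Deterministically rasterizes the configured cylinder and inserts onto the
#' voxel grid: id 0 is air (outside the cylinder), id 1 water, and ids 2+ the
#' inserts in placement order. Inserts must fit inside the container and must
#' not overlap.
#'
#' @param config A [phantom_scene()] configuration.
#' @return A `label_map`: list with `grid` (3-D integer array indexed
#'   slice/row/column), `spacing` (mm per axis), `legend` (named integer
#'   vector id per tissue) and `placements` (insert centers in voxel
#'   coordinates).
#' @export
build_scene <- function(config) {
  sp <- config$voxel_spacing_mm
  radius <- config$container_radius_mm
  height <- config$container_height_mm
  n_slice <- max(1L, as.integer(round(height / sp[1])))
  half_vox <- as.integer(floor(radius / sp[2]))
  n_row <- 2L * half_vox + 3L
  half_vox_c <- as.integer(floor(radius / sp[3]))
  n_col <- 2L * half_vox_c + 3L
  ctr <- c((n_slice - 1) / 2 * sp[1], (n_row - 1) / 2 * sp[2], (n_col - 1) / 2 * sp[3])

  half <- config$insert_dims_mm / 2
  pl <- config$placements
  centers <- cbind(
    ctr[1] + pl$offset_slice, ctr[2] + pl$offset_row, ctr[3] + pl$offset_col
  )
  # Fit checks in physical coordinates: in-plane corners inside the circle,
  # slice extent inside the cylinder height.
  corner_r <- sqrt((abs(pl$offset_row) + half[2])^2 + (abs(pl$offset_col) + half[3])^2)
  if (any(corner_r > radius)) {
    abort(sprintf(
      "insert '%s' extends outside the container radius",
      pl$tissue[which(corner_r > radius)[1]]
    ))
  }
  lo_s <- centers[, 1] - half[1]
  hi_s <- centers[, 1] + half[1]
  if (any(lo_s < -sp[1] / 2) || any(hi_s > height + sp[1] / 2)) {
    abort("insert extends outside the container height")
  }
  if (nrow(pl) > 1L) {
    for (i in seq_len(nrow(pl) - 1L)) {
      for (j in (i + 1L):nrow(pl)) {
        if (all(abs(centers[i, ] - centers[j, ]) < 2 * half)) {
          abort(sprintf("inserts '%s' and '%s' overlap", pl$tissue[i], pl$tissue[j]))
        }
      }
    }
  }

  rr <- (seq_len(n_row) - 1) * sp[2] - ctr[2]
  cc <- (seq_len(n_col) - 1) * sp[3] - ctr[3]
  in_circle <- outer(rr^2, cc^2, "+") <= radius^2
  tmpl <- matrix(0L, n_row, n_col)
  tmpl[in_circle] <- 1L
  grid <- aperm(array(tmpl, c(n_row, n_col, n_slice)), c(3, 1, 2))

  vox_range <- function(center_mm, half_mm, spacing, n) {
    lo <- max(0L, as.integer(ceiling((center_mm - half_mm) / spacing - 0.5 + 1e-9)))
    hi <- min(n - 1L, as.integer(floor((center_mm + half_mm) / spacing + 0.5 - 1e-9)))
    if (hi < lo) abort("insert thinner than one voxel")
    (lo:hi) + 1L
  }
  extents <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    rs <- vox_range(centers[i, 1], half[1], sp[1], n_slice)
    rr_i <- vox_range(centers[i, 2], half[2], sp[2], n_row)
    cc_i <- vox_range(centers[i, 3], half[3], sp[3], n_col)
    grid[rs, rr_i, cc_i] <- i + 1L
    extents[[i]] <- c(
      slice_lo = rs[1] - 1L, slice_hi = rs[length(rs)] - 1L,
      row_lo = rr_i[1] - 1L, row_hi = rr_i[length(rr_i)] - 1L,
      col_lo = cc_i[1] - 1L, col_hi = cc_i[length(cc_i)] - 1L
    )
  }
  extents <- do.call(rbind, extents)

  legend <- c(air = 0L, water = 1L, setNames(seq_len(nrow(pl)) + 1L, pl$tissue))
  placements_vox <- tibble(
    tissue = pl$tissue,
    id = seq_len(nrow(pl)) + 1L,
    center_slice = centers[, 1] / sp[1],
    center_row = centers[, 2] / sp[2],
    center_col = centers[, 3] / sp[3],
    as_tibble(extents)
  )
  structure(
    list(grid = grid, spacing = sp, legend = legend, placements = placements_vox),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf(
    "<label_map> %s voxels @ %s mm; tissues: %s\n",
    paste(dim(x$grid), collapse = " x "),
    paste(signif(x$spacing, 3), collapse = " x "),
    paste(names(x$legend), collapse = ", ")
  ))
  invisible(x)
}

#' A single-channel image volume
#'
#' @param grid 3-D numeric array indexed (slice, row, column).
#' @param spacing Voxel spacing per axis, mm.
#' @param channel Channel/sequence name.
#' @param normalized Whether intensities are water-normalized.
#' @return A `volume_image` (numeric array with metadata attributes).
#' @export
volume_image <- function(grid, spacing, channel = NA_character_,
                         normalized = FALSE) {
  structure(
    grid,
    spacing = spacing, channel = channel, normalized = normalized,
    class = c("volume_image", "array")
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf(
    "<volume_image> channel '%s', %s voxels @ %s mm%s\n",
    attr(x, "channel"), paste(dim(x), collapse = " x "),
    paste(signif(attr(x, "spacing"), 3), collapse = " x "),
    if (isTRUE(attr(x, "normalized"))) ", water-normalized" else ""
  ))
  invisible(x)
}

#' Per-tissue nominal sequence signals
#'
#' Water-relative nominal intensities for each (tissue, sequence) pair plus a
#' per-sequence signal-to-noise ratio and noise model. Real per-tissue
#' intensities depend on scanner and protocol; the packaged defaults encode
#' the qualitative contrasts of the phantom acquisitions (adipose bright on
#' the Dixon fat channel and suppressed on T2-STIR; the 45% hydroxyapatite
#' phantom bright on T1-Dixon and ZTE but dark on T2-STIR; spongiosa and
#' mineral phantoms bright on ZTE) and are fully user-overridable. Water's
#' signal is 1.0 in every sequence by construction.
#'
#' @param signals Long tibble with columns `tissue`, `sequence`, `signal`
#'   (water-relative, non-negative). Default: [default_signal_table()]'s set.
#' @param snr Signal-to-noise ratio, either one number for all sequences or a
#'   named vector per sequence. Default 30, the floor observed on the real
#'   acquisitions.
#' @param noise_model `"gaussian"` (additive, sd = water signal / SNR) or
#'   `"rician"` (magnitude of a complex signal with that per-channel sd).
#' @return An object of class `signal_table`.
#' @export
signal_table <- function(signals, snr = 30,
                         noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  signals <- as_tibble(signals)
  stopifnot(all(c("tissue", "sequence", "signal") %in% names(signals)))
  if (any(signals$signal < 0)) abort("nominal signals must be non-negative")
  if (any(snr <= 0)) abort("SNR must be positive")
  w <- signals[signals$tissue == "water", ]
  if (nrow(w) > 0 && any(w$signal != 1)) {
    abort("water's nominal signal must be 1.0 in every sequence")
  }
  structure(
    list(signals = signals, snr = snr, noise_model = noise_model),
    class = "signal_table"
  )
}

#' @rdname signal_table
#' @export
default_signal_table <- function(snr = 30,
                                 noise_model = c("gaussian", "rician")) {
  base <- tibble::tribble(
    ~tissue,      ~t1w, ~t1f, ~t2stir, ~zte,
    "water",      1.00, 1.00, 1.00,    1.00,
    "skin",       1.35, 0.25, 0.55,    0.35,
    "muscle",     1.20, 0.30, 0.40,    0.30,
    "adipose",    0.15, 2.60, 0.12,    0.55,
    "spongiosa",  0.70, 1.60, 0.28,    1.40,
    "ha_bone_45", 1.80, 0.90, 0.08,    1.90,
    "brain",      1.10, 0.45, 0.75,    0.25,
    "liver",      1.25, 0.55, 0.33,    0.28
  )
  long <- tidyr::pivot_longer(base, -"tissue",
    names_to = "sequence", values_to = "signal"
  )
  signal_table(long, snr = snr, noise_model = noise_model)
}

signal_for <- function(table, sequence) {
  s <- table$signals[table$signals$sequence == sequence, ]
  if (nrow(s) == 0L) abort(sprintf("no signals configured for sequence '%s'", sequence))
  setNames(s$signal, s$tissue)
}

snr_for <- function(table, sequence) {
  snr <- table$snr
  if (!is.null(names(snr))) {
    if (!sequence %in% names(snr)) abort(sprintf("no SNR for sequence '%s'", sequence))
    snr <- snr[[sequence]]
  }
  snr
}

#' Render one MR sequence of a scene
#'
#' Maps tissue ids to the configured nominal signals and (optionally) adds
#' noise with per-voxel sd = water signal / SNR. Air renders as 0 signal.
#' Rendering is a pure function of (inputs, seed): identical calls give
#' bit-identical volumes.
#'
#' @param labels A `label_map` from [build_scene()].
#' @param table A [signal_table()].
#' @param sequence Sequence name to render.
#' @param noisy Add noise? `FALSE` returns exact nominal values.
#' @param seed Integer seed for the noise draw.
#' @return A [volume_image()].
#' @export
render_sequence <- function(labels, table, sequence, noisy = TRUE, seed = NULL) {
  sig <- signal_for(table, sequence)
  ids <- labels$legend
  present <- setdiff(names(ids), "air")
  missing <- setdiff(present, names(sig))
  if (length(missing) > 0L) {
    abort(sprintf(
      "no nominal signal for (%s, %s)", missing[1], sequence
    ))
  }
  lut <- numeric(max(ids) + 1L)            # air -> 0
  lut[ids[present] + 1L] <- sig[present]
  grid <- array(lut[labels$grid + 1L], dim(labels$grid))
  if (noisy) {
    sigma <- sig[["water"]] / snr_for(table, sequence)
    grid <- with_seed(seed, {
      if (table$noise_model == "rician") {
        re <- grid + rnorm(length(grid), sd = sigma)
        im <- rnorm(length(grid), sd = sigma)
        array(sqrt(re^2 + im^2), dim(grid))
      } else {
        grid + array(rnorm(length(grid), sd = sigma), dim(grid))
      }
    })
  }
  volume_image(grid, labels$spacing, channel = sequence, normalized = FALSE)
}

#' Render DECT-style parametric maps
#'
#' Produces per-voxel relative electron density and effective atomic number
#' maps from the tissue compositions — the quantities a dual-energy CT
#' material decomposition would report — with optional multiplicative
#' Gaussian noise at the decomposition's characteristic fractional errors
#' (defaults 0.8% for rho_e and 2.9% for Z_eff).
#'
#' @param labels A `label_map`.
#' @param tissues Tissue tibble covering every insert in the legend (water is
#'   supplied automatically).
#' @param elements Elemental constants table.
#' @param noise_frac Length-2 named vector `c(rho_e = , z_eff = )` of
#'   fractional noise sd; `NULL` for noiseless maps.
#' @param m Effective-atomic-number power-law exponent.
#' @param seed Integer seed for the noise draw.
#' @return A `parametric_maps` list with `rho_e` and `z_eff` volumes.
#' @export
render_parametric_maps <- function(labels, tissues = tissue_table(),
                                   elements = element_table(),
                                   noise_frac = c(rho_e = 0.008, z_eff = 0.029),
                                   m = 3.1, seed = NULL) {
  specs <- dplyr::bind_rows(water_spec(), tissues)
  specs <- relative_electron_density(specs, elements)
  specs <- effective_atomic_number(specs, elements, m = m)
  present <- setdiff(names(labels$legend), "air")
  missing <- setdiff(present, specs$tissue)
  if (length(missing) > 0L) {
    abort(sprintf("no tissue specification for '%s'", missing[1]))
  }
  lut_rho <- numeric(max(labels$legend) + 1L)
  lut_z <- numeric(max(labels$legend) + 1L)
  lut_rho[1] <- 0.001                      # air
  lut_z[1] <- 7.64
  idx <- match(present, specs$tissue)
  lut_rho[labels$legend[present] + 1L] <- specs$rho_e[idx]
  lut_z[labels$legend[present] + 1L] <- specs$z_eff[idx]
  rho <- array(lut_rho[labels$grid + 1L], dim(labels$grid))
  zef <- array(lut_z[labels$grid + 1L], dim(labels$grid))
  if (!is.null(noise_frac)) {
    with_seed(seed, {
      rho <- rho * (1 + array(rnorm(length(rho), sd = noise_frac[["rho_e"]]), dim(rho)))
      zef <- zef * (1 + array(rnorm(length(zef), sd = noise_frac[["z_eff"]]), dim(zef)))
    })
  }
  structure(
    list(
      rho_e = volume_image(rho, labels$spacing, channel = "rho_e"),
      z_eff = volume_image(zef, labels$spacing, channel = "z_eff")
    ),
    class = "parametric_maps"
  )
}

#' Ground-truth density and RSP maps
#'
#' Per-voxel lookup of measured mass density and RSP for every tissue in the
#' scene; water maps to (1.000, 1.000) and air to near-zero.
#'
#' @inheritParams render_parametric_maps
#' @return List with `density` (g/cm^3) and `rsp` volumes.
#' @export
ground_truth_maps <- function(labels, tissues = tissue_table()) {
  present <- setdiff(names(labels$legend), "air")
  specs <- dplyr::bind_rows(water_spec(), tissues)
  missing <- setdiff(present, specs$tissue)
  if (length(missing) > 0L) {
    abort(sprintf("no tissue specification for '%s'", missing[1]))
  }
  lut_d <- numeric(max(labels$legend) + 1L)
  lut_r <- numeric(max(labels$legend) + 1L)
  lut_d[1] <- 0.001205                     # air at STP
  lut_r[1] <- 0.001
  idx <- match(present, specs$tissue)
  lut_d[labels$legend[present] + 1L] <- specs$density[idx]
  lut_r[labels$legend[present] + 1L] <- specs$rsp[idx]
  list(
    density = volume_image(array(lut_d[labels$grid + 1L], dim(labels$grid)),
      labels$spacing,
      channel = "density"
    ),
    rsp = volume_image(array(lut_r[labels$grid + 1L], dim(labels$grid)),
      labels$spacing,
      channel = "rsp"
    )
  )
}

#' Read/write volumes as NIfTI-1
#'
#' Volumes are written with the voxel spacing in the NIfTI header so scenes
#' round-trip with their geometry.
#'
#' @param volume A [volume_image()] (or bare 3-D array with a `spacing`
#'   attribute).
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a [volume_image()].
#' @export
write_volume <- function(volume, path) {
  arr <- unclass(volume)
  attributes(arr) <- list(dim = dim(volume))
  img <- RNifti::asNifti(arr, reference = list(pixdim = c(1, attr(volume, "spacing"), 1, 1, 1, 1)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param channel Channel name to record on the volume read back.
#' @export
read_volume <- function(path, channel = NA_character_) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  volume_image(arr, spacing = spacing, channel = channel)
}
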