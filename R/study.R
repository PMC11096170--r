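# End-to-end phantom study: simulate per-phantom scenes, normalize, extract
# voxel tables, train the FCNN and baselines, and report per-phantom MAPE on
# the application (second) half of the slices.

#' Simulate and extract voxel tables for a set of phantoms
#'
#' For each phantom, builds its cylinder-plus-insert scene, renders the
#' requested MR sequences (and DECT-surrogate parametric maps), water-
#' normalizes every MR channel, and extracts a voxel table from the VOI in
#' the requested slice half. Each phantom's volumes exist only transiently,
#' so memory stays bounded at acquisition-scale grids.
#'
#' @param tissues Tissue tibble (rows define the phantom set).
#' @param sequences MR sequences to render.
#' @param n_per_phantom Voxels sampled per phantom.
#' @param slice_policy `"first_half"`, `"second_half"` or `"all"`.
#' @param noisy Render with noise? Noise-free channels carry each tissue's
#'   exact nominal signature.
#' @param table A [signal_table()]; its SNR and noise model apply.
#' @param parametric Include `rho_e`/`z_eff` DECT-surrogate channels
#'   (rendered with the decomposition's characteristic noise when `noisy`).
#' @param voxel_spacing_mm Grid spacing, mm.
#' @param radius_vox VOI radius in voxels.
#' @param seed Base seed; per-phantom rendering and sampling seeds are
#'   derived from it deterministically.
#' @return A voxel-table tibble covering all phantoms.
#' @export
phantom_voxel_data <- function(tissues = tissue_table(),
                               sequences = c("t1w", "t1f", "t2stir", "zte"),
                               n_per_phantom = 2400,
                               slice_policy = "first_half",
                               noisy = TRUE,
                               table = default_signal_table(),
                               parametric = TRUE,
                               voxel_spacing_mm = c(1, 1, 1),
                               radius_vox = 15,
                               seed = 1L) {
  phantom_voxel_data_multi(
    tissues, sequences, n_per_phantom, slice_policy, noisy, table,
    parametric, voxel_spacing_mm, radius_vox, seed
  )[[slice_policy[1]]]
}

# Simulate one phantom's scene and return its normalized channel stack.
simulate_phantom_channels <- function(tiss, tissues, sequences, noisy, table,
                                      parametric, voxel_spacing_mm, seed) {
  labels <- build_scene(phantom_scene(
    placements = tibble(tissue = tiss),
    voxel_spacing_mm = voxel_spacing_mm,
    sequences = sequences
  ))
  wm <- water_mask(labels)
  images <- list()
  for (k in seq_along(sequences)) {
    img <- render_sequence(labels, table, sequences[k],
      noisy = noisy, seed = seed + k
    )
    images[[sequences[k]]] <- normalize_by_water(img, wm)
  }
  if (parametric) {
    maps <- render_parametric_maps(
      labels, tissues,
      noise_frac = if (noisy) c(rho_e = 0.008, z_eff = 0.029) else NULL,
      seed = seed + 99L
    )
    # Parametric maps are absolute physical quantities; no water reference
    # is involved, so they enter the voxel table as-is.
    for (nm in c("rho_e", "z_eff")) {
      v <- maps[[nm]]
      attr(v, "normalized") <- TRUE
      images[[nm]] <- v
    }
  }
  list(labels = labels, images = images)
}

# One scene pass per phantom, extracting a voxel table per slice policy so
# training and application halves share the same simulated volumes.
phantom_voxel_data_multi <- function(tissues, sequences, n_per_phantom,
                                     slice_policies, noisy, table, parametric,
                                     voxel_spacing_mm, radius_vox, seed) {
  out <- lapply(slice_policies, function(p) vector("list", nrow(tissues)))
  names(out) <- slice_policies
  for (i in seq_len(nrow(tissues))) {
    sc <- simulate_phantom_channels(
      tissues$tissue[i], tissues, sequences, noisy, table, parametric,
      voxel_spacing_mm, seed + 1000L * i
    )
    vois <- voi_table(sc$labels, radius_vox = radius_vox)
    for (p in slice_policies) {
      policy_off <- 50000L * (match(p, slice_policies) - 1L)
      out[[p]][[i]] <- extract_voi_voxels(
        sc$images, sc$labels, tissues,
        n_per_phantom = n_per_phantom, slice_policy = p, vois = vois,
        seed = seed + 2000L + policy_off + i
      )
    }
  }
  lapply(out, dplyr::bind_rows)
}

#' Run the phantom study end to end
#'
#' Simulates the phantom set for a model schema, extracts disjoint training
#' (first slice half) and application (second half) voxel sets, splits
#' training 75/25 into train/validation, fits the schema's FCNN regressors,
#' the single-channel linear baseline, and the DECT empirical conversions on
#' the application voxels' parametric channels, and reports per-phantom MAPE
#' for every model and target quantity.
#'
#' Model B's phantom set excludes the animal-tissue phantoms (they have no
#' ZTE acquisition); A, C and D use all seven.
#'
#' @param schema A [model_schema()] or its name.
#' @param tissues Tissue tibble; defaults to the packaged set filtered per
#'   schema.
#' @param n_per_phantom Training voxels sampled per phantom (the application
#'   set uses the same count from the second half).
#' @param epochs Training epochs (checkpoint at the last epoch).
#' @param noisy Simulate with measurement noise (SNR per `table`, parametric
#'   noise 0.8%/2.9%); `FALSE` gives noise-free channels.
#' @param table A [signal_table()].
#' @param seed Base seed for scene noise, sampling, splitting and training.
#' @param config Optional [fcnn_config()] override (its seed is still taken
#'   from `seed`).
#' @param voxel_spacing_mm,radius_vox Geometry overrides.
#' @return An object of class `phantom_study`: list with the error `report`
#'   tibble (phantom x model x quantity MAPE), the fitted `bundle`,
#'   `baselines`, and the train/val/application tables.
#' @export
phantom_study <- function(schema = "A", tissues = NULL, n_per_phantom = 2400,
                          epochs = 100, noisy = TRUE,
                          table = default_signal_table(), seed = 1L,
                          config = NULL,
                          voxel_spacing_mm = c(1, 1, 1), radius_vox = 15) {
  if (!inherits(schema, "model_schema")) schema <- model_schema(schema)
  if (is.null(tissues)) {
    tissues <- tissue_table()
    if (schema$name == "B") {
      tissues <- tissues[!tissues$tissue %in% c("brain", "liver"), ]
    }
  }
  sequences <- setdiff(schema$channels, c("rho_e", "z_eff"))

  halves <- phantom_voxel_data_multi(
    tissues, sequences, n_per_phantom,
    slice_policies = c("first_half", "second_half"), noisy = noisy,
    table = table, parametric = TRUE, voxel_spacing_mm = voxel_spacing_mm,
    radius_vox = radius_vox, seed = seed
  )
  train_all <- halves$first_half
  application <- halves$second_half
  parts <- split_train_val(train_all, 0.75, seed = seed + 7L)

  if (is.null(config)) {
    config <- fcnn_config(max_epochs = epochs, epochs_used = epochs, seed = seed + 11L)
  }
  bundle <- train_regressor_bundle(parts$train, parts$val, schema, config)
  baselines <- lapply(schema$targets, function(tg) {
    linear_baseline(parts$train, target = tg, channel = "t1w")
  })
  names(baselines) <- schema$targets

  rows <- list()
  for (tg in schema$targets) {
    preds <- list(
      linear = predict(baselines[[tg]], application),
      fcnn = predict(bundle$fits[[tg]], application)
    )
    preds$dect_empirical <- if (tg == "density") {
      dect_empirical_density(application$rho_e)
    } else {
      dect_empirical_rsp(application$rho_e, application$z_eff)
    }
    for (model in names(preds)) {
      per <- dplyr::group_map(
        dplyr::group_by(
          tibble(
            phantom = application$phantom,
            pred = preds[[model]],
            ref = application[[tg]]
          ),
          .data$phantom
        ),
        function(df, key) {
          m <- mape(df$pred, df$ref)
          tibble(
            phantom = key$phantom, model = model, quantity = tg,
            mape = m[["mape"]], sd = m[["sd"]], n = nrow(df)
          )
        }
      )
      rows <- c(rows, per)
    }
  }
  report <- dplyr::arrange(
    dplyr::bind_rows(rows),
    .data$quantity, .data$phantom, .data$model
  )

  structure(
    list(
      report = report, schema = schema, bundle = bundle,
      baselines = baselines, train = parts$train, val = parts$val,
      application = application, noisy = noisy, seed = seed
    ),
    class = "phantom_study"
  )
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf(
    "<phantom_study> Model %s, %d phantoms, %s channels, %d train / %d val / %d application voxels\n\n",
    x$schema$name, length(unique(x$report$phantom)),
    paste(x$schema$channels, collapse = "+"),
    nrow(x$train), nrow(x$val), nrow(x$application)
  ))
  cat(format_error_report(x$report), sep = "\n")
  invisible(x)
}

#' @rdname tidy.fcnn_fit
#' @export
tidy.phantom_study <- function(x, ...) x$report

#' @rdname tidy.fcnn_fit
#' @export
glance.phantom_study <- function(x, ...) {
  fcnn <- x$report[x$report$model == "fcnn", ]
  tibble(
    schema = x$schema$name,
    noisy = x$noisy,
    n_train = nrow(x$train),
    n_application = nrow(x$application),
    fcnn_max_mape = max(fcnn$mape),
    fcnn_mean_mape = mean(fcnn$mape)
  )
}
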