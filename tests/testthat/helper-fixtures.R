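# Shared fixtures: a small-but-valid cylinder scene and signature-based voxel
# tables, all generated in code.

small_scene_config <- function(tissues = c("muscle", "adipose"),
                               spacing = c(1, 1, 1)) {
  offsets <- if (length(tissues) == 2L) c(-8, 8) else rep(0, length(tissues))
  phantom_scene(
    placements = tibble::tibble(tissue = tissues, offset_row = offsets),
    container_radius_mm = 20, container_height_mm = 40,
    insert_dims_mm = c(20, 12, 12),
    voxel_spacing_mm = spacing
  )
}

small_scene <- function(...) build_scene(small_scene_config(...))

# A voxel table built straight from the nominal signatures (no scene pass):
# n rows per tissue, optional additive channel noise.
signature_table <- function(n = 200, channels = c("t1w", "t1f", "t2stir"),
                            tissues = NULL, noise_sd = 0, seed = 1) {
  st <- default_signal_table()
  sig <- tidyr::pivot_wider(st$signals,
    names_from = "sequence", values_from = "signal"
  )
  tt <- tissue_table()
  d <- dplyr::inner_join(sig, tt[, c("tissue", "density", "rsp")], by = "tissue")
  if (!is.null(tissues)) d <- d[d$tissue %in% tissues, ]
  tab <- d[rep(seq_len(nrow(d)), each = n), c("tissue", channels, "density", "rsp")]
  tab$phantom <- tab$tissue
  if (noise_sd > 0) {
    set.seed(seed)
    for (ch in channels) tab[[ch]] <- tab[[ch]] + rnorm(nrow(tab), sd = noise_sd)
  }
  tibble::as_tibble(tab)
}

tiny_fcnn_config <- function(hidden_layers = 2, width = 8, max_epochs = 40,
                             epochs_used = NULL, batch_size = 200, seed = 7,
                             ...) {
  fcnn_config(
    hidden_layers = hidden_layers, width = width, max_epochs = max_epochs,
    epochs_used = epochs_used %||% max_epochs, batch_size = batch_size,
    seed = seed, ...
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a
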