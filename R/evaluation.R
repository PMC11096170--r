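# Absolute-percentage-error metrics, per-phantom error reports and line
# profiles: the evaluation surface mirroring the phantom-study result tables.

#' Absolute percentage error
#'
#' \eqn{APE_i = |x_i - x_{i,REF}| / |x_{i,REF}| \times 100}, element-wise.
#'
#' @param x Predicted value(s).
#' @param ref Reference value(s); must be nonzero.
#' @return APE in percent, same shape as `x`.
#' @export
#' @examples
#' ape(1.05, 1.00)
ape <- function(x, ref) {
  if (any(ref == 0)) abort("reference values must be nonzero")
  abs(x - ref) / abs(ref) * 100
}

#' Mean absolute percentage error
#'
#' \eqn{MAPE = \frac{1}{N}\sum_{i=1}^N APE_i}, with the population standard
#' deviation of the per-voxel APE as spread. Invariant under permutation of
#' paired entries and under joint positive rescaling of both vectors.
#'
#' @param pred,ref Equal-length nonempty numeric vectors; `ref` nonzero.
#' @return Named numeric vector `c(mape = , sd = )`, both in percent.
#' @export
#' @examples
#' mape(c(1.01, 0.99), c(1, 1))
mape <- function(pred, ref) {
  if (length(pred) == 0L) abort("empty input")
  if (length(pred) != length(ref)) abort("pred and ref must have equal length")
  a <- ape(pred, ref)
  c(mape = mean(a), sd = sqrt(mean((a - mean(a))^2)))
}

#' Per-phantom error report
#'
#' One row per phantom insert: the MAPE (and SD of APE) of a prediction map
#' against a ground-truth map over that phantom's VOI voxels restricted to
#' the application slices — the second, never-trained-on half of the volume.
#'
#' @param pred,truth [volume_image()]s sharing the label map's grid.
#' @param labels A `label_map`.
#' @param model Model name recorded in the report.
#' @param quantity `"density"` or `"rsp"`.
#' @param vois VOI definitions, see [voi_table()].
#' @param slices 0-based slice ids to evaluate over; defaults to the
#'   application (second) half. Use `NULL` for all slices.
#' @return Tibble with columns `phantom`, `model`, `quantity`, `mape`, `sd`,
#'   `n`.
#' @export
per_phantom_report <- function(pred, truth, labels, model = "model",
                               quantity = c("density", "rsp"),
                               vois = voi_table(labels),
                               slices = second_half_slices(dim(labels$grid)[1])) {
  quantity <- match.arg(quantity)
  if (!identical(dim(pred), dim(labels$grid)) ||
      !identical(dim(truth), dim(labels$grid))) {
    abort("prediction/truth maps must share the label map's grid")
  }
  dims <- dim(labels$grid)
  legend_ids <- labels$legend
  rows <- vector("list", nrow(vois))
  for (i in seq_len(nrow(vois))) {
    v <- vois[i, ]
    if (!v$tissue %in% names(legend_ids)) {
      warn(sprintf("phantom '%s' missing from the legend: row omitted", v$tissue))
      next
    }
    disc <- disc_voxels(v$center_row, v$center_col, v$radius_vox)
    sl <- seq.int(v$slice_lo, v$slice_hi)
    if (!is.null(slices)) sl <- intersect(sl, slices)
    if (length(sl) == 0L) {
      warn(sprintf("phantom '%s' has no evaluable voxels: row omitted", v$tissue))
      next
    }
    lin <- as.vector(outer(
      sl + 1L,
      (disc[, "row"] - 1L) * dims[1] + (disc[, "col"] - 1L) * dims[1] * dims[2],
      "+"
    ))
    p <- pred[lin]
    keep <- is.finite(p)
    if (!any(keep)) {
      warn(sprintf("phantom '%s' has no evaluable voxels: row omitted", v$tissue))
      next
    }
    m <- mape(p[keep], truth[lin][keep])
    rows[[i]] <- tibble(
      phantom = v$tissue, model = model, quantity = quantity,
      mape = m[["mape"]], sd = m[["sd"]], n = sum(keep)
    )
  }
  dplyr::bind_rows(rows)
}

#' Sample a line profile through a volume
#'
#' Values at `n_samples` equispaced points along the segment from `start` to
#' `end` (0-based voxel coordinates, order slice/row/column), using
#' nearest-voxel lookup — profiles are voxel-indexed, not interpolated.
#'
#' @param volume A [volume_image()].
#' @param start,end Numeric length-3 voxel coordinates.
#' @param n_samples Number of samples (>= 2).
#' @return Tibble with `position_mm` (distance along the segment) and
#'   `value`.
#' @export
line_profile <- function(volume, start, end, n_samples = 50) {
  if (n_samples < 2L) abort("n_samples must be >= 2")
  if (length(start) != 3L || length(end) != 3L) {
    abort("start and end must be length-3 voxel coordinates")
  }
  if (all(start == end)) abort("degenerate segment: start equals end")
  dims <- dim(volume)
  for (pt in list(start, end)) {
    if (any(pt < 0) || any(pt > dims - 1)) abort("segment endpoint out of bounds")
  }
  t_seq <- seq(0, 1, length.out = n_samples)
  coords <- outer(t_seq, end - start) + matrix(start, n_samples, 3, byrow = TRUE)
  nearest <- round(coords)
  lin <- nearest[, 1] + 1 + nearest[, 2] * dims[1] + nearest[, 3] * dims[1] * dims[2]
  spacing <- attr(volume, "spacing") %||% c(1, 1, 1)
  seg_mm <- sqrt(sum(((end - start) * spacing)^2))
  tibble(position_mm = t_seq * seg_mm, value = volume[lin])
}

#' Render an error report as a result-style text table
#'
#' Formats a long error report (from [per_phantom_report()] or
#' [phantom_study()]) as phantom rows x model columns of
#' `MAPE +/- SD` percent strings, one block per quantity.
#'
#' @param report Error-report tibble.
#' @return Character vector of table lines (invisibly printed with `cat`).
#' @export
format_error_report <- function(report) {
  out <- character()
  for (q in unique(report$quantity)) {
    sub <- report[report$quantity == q, ]
    wide <- tidyr::pivot_wider(
      dplyr::mutate(sub, cell = sprintf("%.2f +/- %.2f", .data$mape, .data$sd)),
      id_cols = "phantom", names_from = "model", values_from = "cell"
    )
    mat <- as.matrix(wide)
    widths <- pmax(nchar(colnames(mat)), apply(nchar(mat), 2, max))
    fmt_row <- function(r) paste(mapply(formatC, r, width = widths), collapse = "  ")
    out <- c(
      out,
      sprintf("MAPE (%%) - %s", q),
      fmt_row(colnames(mat)),
      apply(mat, 1, fmt_row),
      ""
    )
  }
  out
}
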