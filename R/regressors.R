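# Model schemas, the DECT empirical conversion models, the single-channel
# linear baseline, and on-disk serialization for trained regressors.

#' Input schemas of the study models
#'
#' * Model A — T1-Dixon water (`t1w`), T1-Dixon fat (`t1f`), T2-STIR
#'   (`t2stir`); density and RSP targets (phantom study, all 7 phantoms).
#' * Model B — A's channels plus ZTE (`zte`); density and RSP (the 5
#'   tissue-substitute phantoms only: animal phantoms have no ZTE scan).
#' * Model C — two MR channels (default `t1w`, `t2stir`); density only.
#' * Model D — C's MR channels plus the two DECT-surrogate parametric
#'   channels (`rho_e`, `z_eff`); density only.
#'
#' C's channel pair is explicit and overridable rather than hard-wired.
#'
#' @param name `"A"`, `"B"`, `"C"` or `"D"`.
#' @param channels Optional channel override (order matters).
#' @return An object of class `model_schema`.
#' @export
model_schema <- function(name = c("A", "B", "C", "D"), channels = NULL) {
  name <- match.arg(name)
  defaults <- list(
    A = list(channels = c("t1w", "t1f", "t2stir"), targets = c("density", "rsp")),
    B = list(channels = c("t1w", "t1f", "t2stir", "zte"), targets = c("density", "rsp")),
    C = list(channels = c("t1w", "t2stir"), targets = "density"),
    D = list(channels = c("t1w", "t2stir", "rho_e", "z_eff"), targets = "density")
  )[[name]]
  structure(
    list(name = name, channels = channels %||% defaults$channels,
         targets = defaults$targets),
    class = "model_schema"
  )
}

#' @export
print.model_schema <- function(x, ...) {
  cat(sprintf(
    "<model_schema %s> channels: %s -> targets: %s\n",
    x$name, paste(x$channels, collapse = ", "), paste(x$targets, collapse = ", ")
  ))
  invisible(x)
}

#' Train all regressors of a schema
#'
#' Fits one single-output FCNN per target (density, and RSP where the schema
#' includes it) on the schema's channels.
#'
#' @inheritParams train_fcnn
#' @param schema A [model_schema()].
#' @return A `regressor_bundle`: named list of `fcnn_fit`s plus the schema.
#' @export
train_regressor_bundle <- function(train, val = NULL, schema = model_schema("A"),
                                   config = fcnn_config()) {
  fits <- lapply(schema$targets, function(tg) {
    train_fcnn(train, val, target = tg, config = config, channels = schema$channels)
  })
  names(fits) <- schema$targets
  structure(list(fits = fits, schema = schema), class = "regressor_bundle")
}

#' @export
print.regressor_bundle <- function(x, ...) {
  print(x$schema)
  for (f in x$fits) print(f)
  invisible(x)
}

#' Single-channel linear-regression baseline
#'
#' Ordinary least squares of the target on one MR channel (by default the
#' T1-Dixon water channel), the comparison model used to show what a
#' non-hierarchical single-sequence mapping can and cannot resolve.
#'
#' @param train Voxel table.
#' @param target `"density"` or `"rsp"`.
#' @param channel The single input channel.
#' @return An object of class `linear_baseline` wrapping the [stats::lm()]
#'   fit, with `slope` and `intercept`.
#' @export
linear_baseline <- function(train, target = c("density", "rsp"),
                            channel = "t1w") {
  target <- match.arg(target)
  if (!channel %in% names(train)) {
    abort(sprintf("channel '%s' not present in the voxel table", channel))
  }
  s <- train[[channel]]
  if (length(unique(s)) < 2L) {
    abort(sprintf("channel '%s' is constant: cannot fit a line", channel))
  }
  df <- data.frame(y = train[[target]], s = s)
  fit <- lm(y ~ s, data = df)
  structure(
    list(
      model = fit,
      channel = channel,
      target = target,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1])
    ),
    channels = channel,
    class = "linear_baseline"
  )
}

#' @export
print.linear_baseline <- function(x, ...) {
  cat(sprintf(
    "<linear_baseline> %s = %.4g * %s + %.4g\n",
    x$target, x$slope, x$channel, x$intercept
  ))
  invisible(x)
}

#' @export
predict.linear_baseline <- function(object, newdata, ...) {
  s <- if (is.matrix(newdata)) newdata[, 1] else newdata[[object$channel]]
  if (is.null(s)) abort(sprintf("input lacks channel '%s'", object$channel))
  object$slope * s + object$intercept
}

#' DECT empirical mass density conversion
#'
#' The affine relative-electron-density calibration
#' \eqn{\rho = -0.1746 + 1.176\,\rho_e} (g/cm^3), applied element-wise; array
#' dimensions are preserved. Note the line itself can produce negative
#' density at very low \eqn{\rho_e}; outputs are not clipped.
#'
#' @param rho_e Relative electron density (scalar, vector or array).
#' @return Mass density in g/cm^3 with the shape of `rho_e`.
#' @export
#' @examples
#' dect_empirical_density(1.0)
dect_empirical_density <- function(rho_e) {
  if (any(!is.finite(rho_e))) abort("rho_e must be finite")
  -0.1746 + 1.176 * rho_e
}

#' DECT empirical RSP conversion
#'
#' The piecewise empirical stopping-power calibration in effective atomic
#' number, with half-open Z_eff intervals:
#' \deqn{RSP = \begin{cases}
#'   \rho_e & 0 \le Z_{eff} < 0.5\\
#'   (1.1114 - 0.0148\,Z_{eff})\,\rho_e & 0.5 \le Z_{eff} < 8.5\\
#'   0.9905\,\rho_e & 8.5 \le Z_{eff} < 10\\
#'   (1.1117 - 0.0116\,Z_{eff})\,\rho_e & Z_{eff} \ge 10
#' \end{cases}}
#' Vectorized element-wise over `rho_e` and `z_eff`; array dimensions are
#' preserved.
#'
#' @param rho_e Relative electron density.
#' @param z_eff Effective atomic number (non-negative).
#' @return Dimensionless RSP with the shape of `rho_e`.
#' @export
#' @examples
#' dect_empirical_rsp(1.0, 9.0)
dect_empirical_rsp <- function(rho_e, z_eff) {
  if (any(!is.finite(rho_e)) || any(!is.finite(z_eff))) {
    abort("rho_e and z_eff must be finite")
  }
  if (any(z_eff < 0)) abort("z_eff must be non-negative")
  factor <- ifelse(
    z_eff < 0.5, 1,
    ifelse(
      z_eff < 8.5, 1.1114 - 0.0148 * z_eff,
      ifelse(z_eff < 10, 0.9905, 1.1117 - 0.0116 * z_eff)
    )
  )
  out <- factor * rho_e
  if (!is.null(dim(rho_e))) dim(out) <- dim(rho_e)
  out
}

#' Save / load a fitted FCNN
#'
#' The on-disk format is plain text: `<prefix>_weights.json` holds the
#' flattened checkpoint and final weight vectors at full precision,
#' `<prefix>_meta.json` the configuration, channel order (the normalization
#' convention: channels are water-normalized intensities), target and
#' training size, and `<prefix>_history.csv` the loss history.
#'
#' @param fit An `fcnn_fit`.
#' @param prefix Path prefix for the three files.
#' @return `save_fcnn()` returns `prefix` invisibly; `load_fcnn()` the
#'   restored `fcnn_fit`.
#' @export
save_fcnn <- function(fit, prefix) {
  jsonlite::write_json(
    list(
      theta = fcnn_flatten(fit$params),
      final_theta = fcnn_flatten(fit$final_params)
    ),
    paste0(prefix, "_weights.json"),
    digits = NA
  )
  jsonlite::write_json(
    list(
      config = unclass(fit$config),
      channels = fit$channels,
      target = fit$target,
      n_train = fit$n_train,
      normalization = "water-normalized intensities (mean water signal = 1)"
    ),
    paste0(prefix, "_meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  write.csv(fit$history, paste0(prefix, "_history.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname save_fcnn
#' @export
load_fcnn <- function(prefix) {
  w <- jsonlite::read_json(paste0(prefix, "_weights.json"), simplifyVector = TRUE)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  config <- do.call(fcnn_config, as.list(meta$config))
  skeleton <- with_seed(0L, fcnn_init(length(meta$channels), config))
  structure(
    list(
      params = fcnn_unflatten(as.numeric(w$theta), skeleton),
      final_params = fcnn_unflatten(as.numeric(w$final_theta), skeleton),
      config = config,
      channels = meta$channels,
      target = meta$target,
      n_train = meta$n_train,
      history = read_voxel_table(paste0(prefix, "_history.csv"))
    ),
    class = "fcnn_fit"
  )
}
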