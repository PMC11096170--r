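# Voxel-wise fully connected neural-network regressor: k input channels ->
# 1 output (mass density or RSP), hidden blocks of linear -> layer
# normalization -> ReLU, trained by mini-batch Adam on mean squared error.
# Written directly on BLAS-backed matrix ops; no GPU or external framework.

LN_EPS <- 1e-5

#' FCNN training configuration
#'
#' Defaults follow the architecture search result for this task: 9 fully
#' connected layers of 80 nodes (searched range 5-11), ReLU activations with
#' layer normalization, Adam at learning rate 1e-3, batch size 1000, 500
#' epochs trained with the 300-epoch checkpoint used for prediction to avoid
#' overfitting.
#'
#' @param hidden_layers Number of hidden fully connected blocks.
#' @param width Nodes per hidden layer.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epochs to train.
#' @param epochs_used Epoch whose weights are used for prediction
#'   (`<= max_epochs`).
#' @param seed Integer seed covering initialization and batch shuffling.
#' @return An object of class `fcnn_config`.
#' @export
fcnn_config <- function(hidden_layers = 9, width = 80, learning_rate = 1e-3,
                        batch_size = 1000, max_epochs = 500,
                        epochs_used = 300, seed = 1L) {
  if (hidden_layers < 1 || width < 1 || batch_size < 1) {
    abort("hidden_layers, width and batch_size must be >= 1")
  }
  if (epochs_used > max_epochs) {
    abort("epochs_used must not exceed max_epochs")
  }
  structure(
    list(
      hidden_layers = as.integer(hidden_layers), width = as.integer(width),
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), epochs_used = as.integer(epochs_used),
      seed = as.integer(seed)
    ),
    class = "fcnn_config"
  )
}

# Parameters live in a flat named list of arrays (W1, b1, g1, be1, ...,
# Wo, bo) so the Adam update is a short loop of vectorized ops. Uniform
# fan-in initialization (PyTorch-style) for all linear layers; layer-norm
# gains start at 1, offsets at 0.
fcnn_init <- function(n_in, config) {
  params <- list()
  fan_in <- n_in
  for (l in seq_len(config$hidden_layers)) {
    bound <- 1 / sqrt(fan_in)
    params[[paste0("W", l)]] <-
      matrix(runif(fan_in * config$width, -bound, bound), fan_in, config$width)
    params[[paste0("b", l)]] <- runif(config$width, -bound, bound)
    params[[paste0("g", l)]] <- rep(1, config$width)
    params[[paste0("be", l)]] <- rep(0, config$width)
    fan_in <- config$width
  }
  bound <- 1 / sqrt(config$width)
  params$Wo <- matrix(runif(config$width, -bound, bound), config$width, 1)
  params$bo <- runif(1, -bound, bound)
  params
}

fcnn_n_layers <- function(params) (length(params) - 2L) %/% 4L

# Forward pass. X is n x k. Returns predictions and, if keep_cache, the
# per-layer intermediates needed for backprop.
fcnn_forward <- function(params, X, keep_cache = FALSE) {
  n_layers <- fcnn_n_layers(params)
  n <- nrow(X)
  A <- X
  cache <- if (keep_cache) vector("list", n_layers) else NULL
  for (l in seq_len(n_layers)) {
    Z <- A %*% params[[paste0("W", l)]]
    Z <- Z + rep(params[[paste0("b", l)]], each = n)
    cen <- Z - rowMeans(Z)
    inv_sd <- 1 / sqrt(rowMeans(cen^2) + LN_EPS)
    xhat <- cen * inv_sd
    H <- xhat * rep(params[[paste0("g", l)]], each = n) +
      rep(params[[paste0("be", l)]], each = n)
    if (keep_cache) {
      cache[[l]] <- list(A_in = A, xhat = xhat, inv_sd = inv_sd, H = H)
    }
    A <- H * (H > 0)
  }
  pred <- as.vector(A %*% params$Wo) + as.vector(params$bo)
  list(pred = pred, A_last = A, cache = cache)
}

# Backward pass of the MSE loss; returns gradients with the same names and
# shapes as `params`. d_pred is dL/d(pred), an n x 1 matrix.
fcnn_backward <- function(params, fw, X, d_pred) {
  n_layers <- fcnn_n_layers(params)
  grads <- list(Wo = crossprod(fw$A_last, d_pred), bo = sum(d_pred))
  dA <- tcrossprod(d_pred, params$Wo)
  n <- nrow(X)
  for (l in rev(seq_len(n_layers))) {
    cc <- fw$cache[[l]]
    dH <- dA * (cc$H > 0)
    grads[[paste0("g", l)]] <- colSums(dH * cc$xhat)
    grads[[paste0("be", l)]] <- colSums(dH)
    dxhat <- dH * rep(params[[paste0("g", l)]], each = n)
    # Layer-norm backward (per row): project out mean and xhat components.
    dZ <- (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat)) * cc$inv_sd
    grads[[paste0("W", l)]] <- crossprod(cc$A_in, dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) dA <- tcrossprod(dZ, params[[paste0("W", l)]])
  }
  grads
}

# Flatten/unflatten used only for serialization.
fcnn_flatten <- function(params) {
  unlist(params, use.names = FALSE)
}

fcnn_unflatten <- function(flat, skeleton) {
  out <- skeleton
  pos <- 1L
  for (nm in names(skeleton)) {
    n <- length(skeleton[[nm]])
    val <- flat[pos:(pos + n - 1L)]
    dim(val) <- dim(skeleton[[nm]])
    out[[nm]] <- val
    pos <- pos + n
  }
  out
}

.fcnn_reserved <- c("density", "rsp", "tissue", "phantom", "slice", "voxel")

voxel_channels <- function(table) {
  setdiff(names(table), .fcnn_reserved)
}

#' Train a voxel-wise FCNN regressor
#'
#' Minimizes the mean squared error
#' \eqn{L = \frac{1}{N}\sum_i (y_{i,pred} - y_{i,truth})^2} over the training
#' partition by mini-batch Adam, recording training and validation loss every
#' epoch. Training is fully reproducible: identical seed and data give an
#' identical loss history and identical predictions.
#'
#' @param train,val Voxel tables (see [extract_voi_voxels()]); `val` may be
#'   `NULL`. Only the training partition influences the weights; validation
#'   loss is monitoring only.
#' @param target `"density"` or `"rsp"` — the column regressed on.
#' @param config An [fcnn_config()].
#' @param channels Channel columns used as inputs; defaults to every
#'   non-metadata column of `train`.
#' @return An object of class `fcnn_fit` with the checkpoint weights, config,
#'   channel schema and per-epoch loss `history`.
#' @export
train_fcnn <- function(train, val = NULL, target = c("density", "rsp"),
                       config = fcnn_config(), channels = NULL) {
  target <- match.arg(target)
  channels <- channels %||% voxel_channels(train)
  if (nrow(train) == 0L) abort("training table is empty")
  missing <- setdiff(c(channels, target), names(train))
  if (length(missing) > 0L) {
    abort(sprintf("training table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(train[channels])
  y <- train[[target]]
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    abort("training inputs and targets must be finite")
  }
  Xv <- NULL
  yv <- NULL
  if (!is.null(val) && nrow(val) > 0L) {
    Xv <- as.matrix(val[channels])
    yv <- val[[target]]
  }
  n <- nrow(X)

  # Initialization and the per-epoch shuffles come from R's RNG under the
  # configured seed; the compiled core is deterministic given them.
  seeded <- with_seed(config$seed, {
    params0 <- fcnn_init(ncol(X), config)
    perms <- vapply(
      seq_len(config$max_epochs), function(e) sample.int(n), integer(n)
    )
    list(params0 = params0, perms = perms)
  })
  res <- .cpp_fcnn_train(
    seeded$params0, X, y, Xv, yv, seeded$perms,
    config$batch_size, config$learning_rate, config$epochs_used
  )

  structure(
    list(
      params = res$params,
      final_params = res$final_params,
      config = config,
      channels = channels,
      target = target,
      n_train = n,
      history = tibble(
        epoch = seq_len(config$max_epochs),
        train_loss = as.vector(res$train_loss),
        val_loss = as.vector(res$val_loss)
      )
    ),
    class = "fcnn_fit"
  )
}

#' @export
print.fcnn_fit <- function(x, ...) {
  cat(sprintf(
    "<fcnn_fit> %s ~ %s | %d x %d hidden, %d epochs (checkpoint %d), final train MSE %.3g\n",
    x$target, paste(x$channels, collapse = " + "),
    x$config$hidden_layers, x$config$width,
    x$config$max_epochs, x$config$epochs_used,
    x$history$train_loss[x$config$max_epochs]
  ))
  invisible(x)
}

#' Predict from a fitted FCNN
#'
#' @param object An `fcnn_fit`.
#' @param newdata Data frame containing the fit's channel columns, or a
#'   numeric matrix with matching column count and order.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fcnn_fit <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != length(object$channels)) {
      abort(sprintf(
        "input has %d channels but the model expects %d (%s)",
        ncol(newdata), length(object$channels),
        paste(object$channels, collapse = ", ")
      ))
    }
    X <- newdata
  } else {
    missing <- setdiff(object$channels, names(newdata))
    if (length(missing) > 0L) {
      abort(sprintf(
        "input lacks channel(s) %s; the model expects (%s)",
        paste(missing, collapse = ", "), paste(object$channels, collapse = ", ")
      ))
    }
    X <- as.matrix(newdata[object$channels])
  }
  # Chunked so whole-volume prediction stays within modest memory.
  n <- nrow(X)
  chunk <- 100000L
  if (n <= chunk) return(as.vector(.cpp_fcnn_predict(object$params, X)))
  out <- numeric(n)
  for (start in seq.int(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- as.vector(.cpp_fcnn_predict(object$params, X[idx, , drop = FALSE]))
  }
  out
}

#' Apply a voxel-wise model to image volumes
#'
#' Runs a fitted regressor over every masked voxel of a normalized channel
#' stack, producing a parameter map. Voxels outside the mask are set to the
#' sentinel value. Predictions are deterministic and are not clipped;
#' negative outputs, if any, are the model's own and are surfaced by the
#' error reports rather than silently truncated.
#'
#' @param fit An `fcnn_fit` (or any object with a `predict` method over the
#'   named channels, e.g. the linear baseline).
#' @param images Named list of water-normalized [volume_image()] channels
#'   covering the fit's schema.
#' @param mask Logical array or integer index vector of voxels to predict.
#' @param sentinel Value for voxels outside the mask.
#' @return A [volume_image()] of predictions.
#' @export
predict_map <- function(fit, images, mask, sentinel = NA_real_) {
  channels <- if (inherits(fit, "fcnn_fit")) fit$channels else attr(fit, "channels")
  missing <- setdiff(channels, names(images))
  if (length(missing) > 0L) {
    abort(sprintf(
      "channel stack lacks %s; the model expects (%s)",
      paste(missing, collapse = ", "), paste(channels, collapse = ", ")
    ))
  }
  ref <- images[[channels[1]]]
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  X <- vapply(channels, function(ch) images[[ch]][idx], numeric(length(idx)))
  if (length(idx) == 1L) X <- matrix(X, nrow = 1)
  newdata <- as_tibble(as.data.frame(X))
  names(newdata) <- channels
  pred <- predict(fit, newdata)
  grid <- array(sentinel, dim(ref))
  grid[idx] <- pred
  volume_image(grid, attr(ref, "spacing"),
    channel = if (inherits(fit, "fcnn_fit")) fit$target else "prediction"
  )
}

#' Broom-style tidiers for FCNN fits
#'
#' `tidy()` returns the per-epoch loss history in long form; `glance()` a
#' one-row model summary.
#'
#' @param x An `fcnn_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fcnn_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
    names_to = "partition", values_to = "mse"
  ) |>
    dplyr::mutate(partition = sub("_loss$", "", .data$partition))
}

#' @rdname tidy.fcnn_fit
#' @export
glance.fcnn_fit <- function(x, ...) {
  tibble(
    target = x$target,
    channels = paste(x$channels, collapse = "+"),
    hidden_layers = x$config$hidden_layers,
    width = x$config$width,
    epochs = x$config$max_epochs,
    epochs_used = x$config$epochs_used,
    n_train = x$n_train,
    final_train_mse = x$history$train_loss[x$config$max_epochs],
    final_val_mse = x$history$val_loss[x$config$max_epochs]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
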