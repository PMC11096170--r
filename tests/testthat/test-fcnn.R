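# The FCNN regressor: gradients, convergence, determinism, serialization.

test_that("backpropagation matches numerical gradients (R and compiled paths)", {
  fi <- mrirsp:::fcnn_init
  fwR <- mrirsp:::fcnn_forward
  bwR <- mrirsp:::fcnn_backward
  fl <- mrirsp:::fcnn_flatten
  uf <- mrirsp:::fcnn_unflatten

  set.seed(42)
  cfg <- fcnn_config(hidden_layers = 2, width = 5, seed = 1)
  p <- fi(3, cfg)
  X <- matrix(rnorm(12), 4, 3)
  y <- rnorm(4)

  f <- fwR(p, X, keep_cache = TRUE)
  gR <- fl(bwR(p, f, X, matrix(2 * (f$pred - y) / 4, ncol = 1))[names(p)])
  gC <- fl(mrirsp:::.cpp_fcnn_grad(p, X, y)[names(p)])

  theta <- fl(p)
  lossfun <- function(th) mean((fwR(uf(th, p), X)$pred - y)^2)
  num <- vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + 1e-6
    dn <- theta; dn[i] <- dn[i] - 1e-6
    (lossfun(up) - lossfun(dn)) / 2e-6
  }, numeric(1))

  expect_lt(max(abs(gR - num)), 1e-7)
  expect_lt(max(abs(gC - num)), 1e-7)
  # compiled forward agrees with the R reference
  expect_equal(as.vector(mrirsp:::.cpp_fcnn_predict(p, X)), f$pred,
               tolerance = 1e-12)
})

test_that("a constant target is fit to near-zero loss", {
  tab <- tibble::tibble(
    t1w = runif(400), t1f = runif(400),
    density = 1.05, rsp = 1.0,
    tissue = "x", phantom = "x", slice = 0L, voxel = seq_len(400)
  )
  fit <- train_fcnn(tab, NULL, target = "density",
                    config = fcnn_config(hidden_layers = 3, width = 16,
                                         learning_rate = 1e-2,
                                         max_epochs = 1000, epochs_used = 1000,
                                         batch_size = 400, seed = 2))
  expect_lt(fit$history$train_loss[1000], 1e-6)
  expect_equal(mean(predict(fit, tab)), 1.05, tolerance = 1e-3)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(fit$history$train_loss >= 0))
})

test_that("training is reproducible per seed and uses only the training part", {
  tab <- signature_table(n = 120, noise_sd = 0.02)
  parts <- split_train_val(tab, 0.75, seed = 3)
  cfg <- tiny_fcnn_config()
  f1 <- train_fcnn(parts$train, parts$val, target = "density", config = cfg)
  f2 <- train_fcnn(parts$train, parts$val, target = "density", config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, tab), predict(f2, tab))
  expect_true(all(is.finite(f1$history$val_loss)))

  f3 <- train_fcnn(parts$train, parts$val, target = "density",
                   config = tiny_fcnn_config(seed = 8))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))

  # validation rows do not influence the weights
  f4 <- train_fcnn(parts$train, NULL, target = "density", config = cfg)
  expect_identical(f1$params, f4$params)
})

test_that("the epochs_used checkpoint differs from the final weights", {
  tab <- signature_table(n = 60, noise_sd = 0.02)
  fit <- train_fcnn(tab, NULL, target = "rsp",
                    config = tiny_fcnn_config(max_epochs = 10, epochs_used = 4))
  expect_false(identical(fit$params, fit$final_params))
  expect_error(fcnn_config(max_epochs = 5, epochs_used = 6), "epochs_used")
})

test_that("channel schema mismatches are rejected with the expected schema named", {
  tab <- signature_table(n = 50)
  fit <- train_fcnn(tab, NULL, target = "density", config = tiny_fcnn_config(),
                    channels = c("t1w", "t1f", "t2stir"))
  expect_error(predict(fit, matrix(0, 2, 4)), "expects 3")
  expect_error(predict(fit, tab[, c("t1w", "density")]), "t1f")
})

test_that("fits serialize to text files and back", {
  tab <- signature_table(n = 50, noise_sd = 0.01)
  fit <- train_fcnn(tab, NULL, target = "density", config = tiny_fcnn_config())
  prefix <- file.path(withr::local_tempdir(), "density")
  save_fcnn(fit, prefix)
  back <- load_fcnn(prefix)
  expect_equal(predict(back, tab), predict(fit, tab), tolerance = 1e-12)
  expect_equal(back$channels, fit$channels)
  expect_equal(back$config$width, fit$config$width)
})

test_that("tidy and glance summarize the fit", {
  tab <- signature_table(n = 40)
  fit <- train_fcnn(tab, NULL, target = "density",
                    config = tiny_fcnn_config(max_epochs = 5, epochs_used = 5))
  td <- tidy(fit)
  expect_equal(nrow(td), 10)  # 5 epochs x train/val
  expect_named(td, c("epoch", "partition", "mse"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs, 5)
  expect_s3_class(autoplot(fit), "ggplot")
})
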