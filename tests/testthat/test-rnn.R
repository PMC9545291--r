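test_that("the built architecture matches its configuration", {
  m <- build_model(model_config(seed = 3))
  expect_identical(dim(m$params$W[[1]]), c(64L, 101L))
  for (l in 2:4) expect_identical(dim(m$params$W[[l]]), c(64L, 64L))
  expect_identical(dim(m$params$W[[5]]), c(1L, 64L))
  n_hidden <- sum(vapply(m$params$U[1:4], nrow, 0L))
  expect_identical(n_hidden, 256L)
  # recurrent weights are orthogonal
  for (l in 1:4)
    expect_equal(crossprod(m$params$U[[l]]), diag(64), tolerance = 1e-10)
  expect_true(abs(abs(m$params$U[[5]][1, 1]) - 1) < 1e-12)
  # same seed, same parameters; different seed differs
  expect_identical(build_model(model_config(seed = 3))$params, m$params)
  expect_false(identical(build_model(model_config(seed = 4))$params,
                         m$params))
})

test_that("zero input with zero biases produces identically zero activity", {
  m <- build_model(model_config(seed = 5))
  rec <- forward_with_activations(m, matrix(0, 101, 111))
  expect_true(all(rec$activations == 0))
  expect_true(all(rec$output == 0))
})

test_that("activation records have the 4 x 64 x 111 layout and rectified range", {
  m <- build_model(model_config(seed = 6))
  cg <- condition_cochleagrams()[["S"]]
  rec <- forward_with_activations(m, cg)
  expect_identical(dim(rec$activations), c(4L, 64L, 111L))
  expect_true(all(rec$activations >= 0))
  expect_length(rec$output, 111L)
  expect_equal(rec$output, predict_waveform(m, cg))
  # five conditions flatten to the 5 x 28416 layout
  recs <- record_condition_activations(m)
  flat <- t(sapply(recs, function(r) as.vector(r$activations)))
  expect_identical(dim(flat), c(5L, 28416L))
})

test_that("the untrained zero-bias network is positively homogeneous, the trained one is not", {
  m <- build_model(model_config(seed = 8))
  cg <- unclass(condition_cochleagrams()[["S"]])
  y1 <- predict_waveform(m, cg)
  y2 <- predict_waveform(m, 2 * cg)
  expect_equal(y2, 2 * y1, tolerance = 1e-9)      # ReLU + linear, zero bias
  toy <- make_toy_dataset()
  mt <- train_model(m, toy, epochs = 30)
  z1 <- predict_waveform(mt, cg)
  z2 <- predict_waveform(mt, 2 * cg)
  expect_gt(max(abs(z2 - 2 * z1)), 1e-6)          # biases break homogeneity
})

test_that("training reduces the loss and is bit-deterministic", {
  toy <- make_toy_dataset()
  m <- build_model(model_config(seed = 12, batch_size = 16))
  m <- train_model(m, toy, epochs = 50)
  expect_lt(m$history[50], m$history[1])
  m2 <- train_model(build_model(model_config(seed = 12, batch_size = 16)),
                    toy, epochs = 50)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)
})

test_that("constant-zero targets collapse the output power", {
  # loss here is mean squared output; with raw (unnormalised) cochleagram
  # magnitudes driving the network, the degenerate fit suppresses it by
  # orders of magnitude relative to the untrained model
  toy <- make_toy_dataset(targets = "zero")
  m <- build_model(model_config(seed = 13, batch_size = 16))
  m <- train_model(m, toy, epochs = 100)
  expect_lt(min(m$history) / m$history[1], 1e-2)
})

test_that("compiled gradients match finite differences on a tiny network", {
  cfg <- model_config(n_input = 3, n_layers = 2, units_per_layer = 4,
                      seed = 21, batch_size = 4, learning_rate = 0.05,
                      beta1 = 0, beta2 = 0.999)
  m <- build_model(cfg)
  set.seed(1)
  X <- matrix(abs(rnorm(3 * 6)), 3, 6)
  targets <- matrix(rnorm(4 * 6), 4, 6)
  ds <- structure(list(targets = targets,
                       labels = data.frame(condition = rep("S", 4)),
                       inputs = list(S = X), times = 1:6, rate = 1),
                  class = "idealized_dataset")
  loss_of <- function(params) {
    mm <- m; mm$params <- params
    y <- predict_waveform(mm, X)
    mean(sweep(targets, 2, y)^2)
  }
  # with beta1 = 0 and one epoch/batch, the first Adam step moves each
  # parameter by -lr * sign(gradient) (bias-corrected); check directions
  m1 <- train_model(m, ds, epochs = 1)
  for (l in c(1, 3)) {
    w0 <- m$params$W[[l]]
    moved <- m1$params$W[[l]] - w0
    # numerical gradient for a few entries
    for (k in sample(length(w0), 4)) {
      eps <- 1e-6
      pp <- m$params; pp$W[[l]][k] <- pp$W[[l]][k] + eps
      up <- loss_of(pp)
      pp$W[[l]][k] <- pp$W[[l]][k] - 2 * eps
      dn <- loss_of(pp)
      num_grad <- (up - dn) / (2 * eps)
      if (abs(num_grad) > 1e-8)
        expect_lt(moved[k] * sign(num_grad), 0)   # moved against gradient
    }
  }
})

test_that("cross-validation folds partition the trials stratified by condition", {
  toy <- make_toy_dataset(n_per_cond = 10)
  cv <- crossvalidate_model(model_config(seed = 31, batch_size = 16),
                            toy, k = 5, epochs = 2)
  expect_identical(nrow(cv), 5L)
  folds <- attr(cv, "folds")
  expect_identical(sort(unique(folds)), 1:5)
  expect_length(folds, 50L)
  tab <- table(toy$labels$condition, folds)
  expect_true(all(tab == 2))                  # 10 per condition over 5 folds
  expect_error(crossvalidate_model(model_config(seed = 1), toy, k = 1),
               "k >= 2")
})

test_that("validation error stays comparable to training error on noise-free targets", {
  toy <- make_toy_dataset(n_per_cond = 10)
  cv <- crossvalidate_model(model_config(seed = 32, batch_size = 16),
                            toy, k = 3, epochs = 60)
  expect_lte(attr(cv, "mean_val"), 2 * attr(cv, "mean_train") + 1e-6)
})

test_that("ensemble selection picks the highest mean r-squared", {
  toy <- make_toy_dataset(n_per_cond = 6)
  ens <- train_ensemble_and_select(model_config(seed = 41, batch_size = 16),
                                   toy, n_models = 2, epochs = 15)
  expect_identical(nrow(ens$metrics), 2L)
  expect_identical(ens$best_index,
                   order(-ens$metrics$mean_r2, ens$metrics$mean_mse)[1])
  one <- train_ensemble_and_select(model_config(seed = 41, batch_size = 16),
                                   toy, n_models = 1, epochs = 5)
  expect_identical(one$best_index, 1L)
})

test_that("model archives round-trip through save and load", {
  m <- build_model(model_config(seed = 51))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
})
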