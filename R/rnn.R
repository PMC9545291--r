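#' Hierarchical recurrent network configuration
#'
#' Architecture and optimiser settings of the evoked-potential model:
#' 101 input units (one per STFT frequency bin), four hidden layers of 64
#' rectified recurrent units, and a single linear recurrent output unit.
#' Optimised with Adam (learning rate 0.001, beta1 0.9, beta2 0.99) on
#' mean-squared-error loss.
#'
#' @param n_input,n_layers,units_per_layer,n_output architecture sizes.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param epochs training epochs for the full protocol.
#' @param batch_size minibatch size (shuffled each epoch with a seeded
#'   generator).
#' @param seed integer seed for initialisation and batch shuffling.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_input = 101, n_layers = 4, units_per_layer = 64,
                         n_output = 1, learning_rate = 0.001, beta1 = 0.9,
                         beta2 = 0.99, epsilon = 1e-8, epochs = 500,
                         batch_size = 32, seed = 1) {
  stopifnot(n_input > 0, n_layers > 0, units_per_layer > 0, n_output == 1,
            epochs > 0, batch_size > 0)
  structure(list(n_input = n_input, n_layers = n_layers,
                 units_per_layer = units_per_layer, n_output = n_output,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = epochs, batch_size = batch_size,
                 seed = seed),
            class = "model_config")
}

glorot_uniform <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

# Orthogonal matrix from the QR decomposition of a standard-normal matrix,
# sign-fixed so the decomposition is unique.
orthogonal_init <- function(n) {
  qrd <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qrd)
  q * rep(sign(diag(qr.R(qrd))), each = n)
}

#' Build an (untrained) hierarchical recurrent network
#'
#' Hidden unit update h_t = relu(W x_t + U h_(t-1) + b); the output unit
#' is linear with a scalar recurrent weight. Inter-layer weights are
#' initialised Glorot-uniform, recurrent weights as orthogonal matrices
#' from a normal distribution, biases at zero, initial states at zero.
#' Initialisation is bit-reproducible given the config seed.
#'
#' @param config a [model_config()].
#' @return object of class `hierarchical_rnn`: list with `params`
#'   (`W`, `U`, `b` per layer, output layer last), `config`, `trained`,
#'   `history`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  nl <- config$n_layers
  nu <- config$units_per_layer
  params <- with_seed(derive_seed(config$seed, 101), {
    W <- vector("list", nl + 1)
    U <- vector("list", nl + 1)
    b <- vector("list", nl + 1)
    for (l in seq_len(nl)) {
      n_in <- if (l == 1) config$n_input else nu
      W[[l]] <- glorot_uniform(nu, n_in)
      U[[l]] <- orthogonal_init(nu)
      b[[l]] <- numeric(nu)
    }
    W[[nl + 1]] <- glorot_uniform(1, nu)
    U[[nl + 1]] <- orthogonal_init(1)
    b[[nl + 1]] <- 0
    list(W = W, U = U, b = b)
  })
  structure(list(params = params, config = config, trained = FALSE,
                 history = NULL),
            class = "hierarchical_rnn")
}

#' @export
print.hierarchical_rnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<hierarchical_rnn> %d -> %s -> %d (%strained)\n",
              cfg$n_input,
              paste(rep(cfg$units_per_layer, cfg$n_layers), collapse = " -> "),
              cfg$n_output, if (x$trained) "" else "un"))
  if (!is.null(x$history))
    cat(sprintf("  final training loss %.6g after %d epochs\n",
                utils::tail(x$history, 1), length(x$history)))
  invisible(x)
}

# Dataset pieces in the layout the compiled trainer expects.
dataset_for_training <- function(dataset, trial_subset = NULL) {
  stopifnot(inherits(dataset, "idealized_dataset"))
  conds <- names(dataset$inputs)
  inputs <- lapply(dataset$inputs, function(m) unclass(m)[, , drop = FALSE])
  cond_idx <- match(dataset$labels$condition, conds)
  targets <- dataset$targets
  if (!is.null(trial_subset)) {
    targets <- targets[trial_subset, , drop = FALSE]
    cond_idx <- cond_idx[trial_subset]
  }
  if (anyNA(cond_idx)) stop("dataset labels contain unknown conditions")
  list(inputs = inputs, targets = targets, cond = cond_idx)
}

#' Train the network on an idealised dataset
#'
#' Minimises mean-squared error between model outputs and the per-trial
#' target evoked responses using Adam with the configured
#' hyperparameters. Trials are shuffled into minibatches each epoch with
#' a generator seeded from the model seed, so training is deterministic
#' end to end.
#'
#' @param model a `hierarchical_rnn`.
#' @param dataset an `idealized_dataset` from [build_idealized_dataset()].
#' @param epochs number of epochs (defaults to the config value).
#' @param trial_subset optional integer vector of trials to train on
#'   (used by cross-validation).
#' @return the trained model, with per-epoch training loss in `$history`.
#' @export
train_model <- function(model, dataset, epochs = model$config$epochs,
                        trial_subset = NULL) {
  stopifnot(inherits(model, "hierarchical_rnn"))
  d <- dataset_for_training(dataset, trial_subset)
  n <- nrow(d$targets)
  ord <- with_seed(derive_seed(model$config$seed, 311),
                   t(replicate(epochs, sample.int(n))))
  if (epochs == 1) ord <- matrix(ord, nrow = 1)
  fit <- cpp_rnn_train(model$params, d$inputs, d$targets, d$cond, ord,
                       model$config$batch_size, model$config$learning_rate,
                       model$config$beta1, model$config$beta2,
                       model$config$epsilon)
  model$params <- fit$params
  model$history <- c(model$history, as.numeric(fit$history))
  model$trained <- TRUE
  model
}

#' Forward pass on one cochleagram
#'
#' @param model a `hierarchical_rnn`.
#' @param input a [cochleagram()] or a numeric n_input x time matrix.
#' @return numeric output waveform (one sample per input frame).
#' @export
predict_waveform <- function(model, input) {
  rec <- forward_with_activations(model, input)
  rec$output
}

#' Forward pass recording all hidden activations
#'
#' @param model a `hierarchical_rnn`.
#' @param input a [cochleagram()] or numeric n_input x time matrix.
#' @return object of class `activation_record`: list with `activations`
#'   (layers x units x time array, nonnegative) and `output` (time
#'   vector).
#' @export
forward_with_activations <- function(model, input) {
  stopifnot(inherits(model, "hierarchical_rnn"))
  x <- unclass(input)
  if (!is.matrix(x) || nrow(x) != model$config$n_input)
    stop("input must be a ", model$config$n_input, " x time matrix")
  res <- cpp_rnn_forward(model$params, x)
  nl <- model$config$n_layers
  nu <- model$config$units_per_layer
  act <- array(NA_real_, c(nl, nu, ncol(x)))
  for (l in seq_len(nl)) act[l, , ] <- res$activations[[l]]
  structure(list(activations = act, output = as.numeric(res$output)),
            class = "activation_record")
}

#' Activation records for all stimulus conditions
#'
#' @param model a trained `hierarchical_rnn`.
#' @param inputs named list of per-condition cochleagrams (defaults to
#'   the five training stimuli).
#' @return named list of `activation_record`s.
#' @export
record_condition_activations <- function(model,
                                         inputs = condition_cochleagrams()) {
  lapply(inputs, function(cg) forward_with_activations(model, cg))
}

#' Fit quality of model outputs against grand-average waveforms
#'
#' Per condition, the squared Pearson correlation (r^2) and mean-squared
#' error between the model output and the condition's grand-average
#' evoked response; plus their mean and SD across conditions.
#'
#' @param model a trained `hierarchical_rnn`.
#' @param grand_avg conditions x time matrix from [grand_average()].
#' @param inputs named list of per-condition cochleagrams.
#' @return data.frame (condition, r_squared, mse) with attributes
#'   `mean_r2`, `sd_r2`, `mean_mse`, `sd_mse`.
#' @export
fit_metrics <- function(model, grand_avg,
                        inputs = condition_cochleagrams()) {
  conds <- rownames(grand_avg)
  r2 <- mse <- numeric(length(conds))
  for (i in seq_along(conds)) {
    y <- predict_waveform(model, inputs[[conds[i]]])
    g <- grand_avg[conds[i], ]
    r2[i] <- stats::cor(y, g)^2
    mse[i] <- mean((y - g)^2)
  }
  out <- data.frame(condition = conds, r_squared = r2, mse = mse,
                    stringsAsFactors = FALSE)
  attr(out, "mean_r2") <- mean(r2)
  attr(out, "sd_r2") <- stats::sd(r2)
  attr(out, "mean_mse") <- mean(mse)
  attr(out, "sd_mse") <- stats::sd(mse)
  out
}

#' Stratified k-fold cross-validation of the architecture
#'
#' Folds are stratified by stimulus condition (each fold holds back ~10%
#' of the trials of each stimulus type with default k); per fold a fresh
#' model is trained on the remaining trials and evaluated on both sets.
#'
#' @param config a [model_config()].
#' @param dataset an `idealized_dataset`.
#' @param k number of folds (>= 2).
#' @param epochs training epochs per fold (defaults to config).
#' @return data.frame (fold, train_mse, val_mse) with attributes
#'   `mean_train`, `sd_train`, `mean_val`, `sd_val` and `folds` (the
#'   fold assignment vector).
#' @export
crossvalidate_model <- function(config, dataset, k = 10,
                                epochs = config$epochs) {
  stopifnot(inherits(config, "model_config"))
  if (k < 2) stop("cross-validation needs k >= 2")
  cond <- dataset$labels$condition
  if (any(table(cond) < k))
    stop("every condition needs at least k trials")
  fold <- integer(length(cond))
  fold_assign <- with_seed(derive_seed(config$seed, 421), {
    for (cc in unique(cond)) {
      idx <- which(cond == cc)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
    fold
  })
  trial_mse <- function(model, d, subset) {
    outs <- lapply(d$inputs, function(m) predict_waveform(model, m))
    mean(vapply(subset, function(i)
      mean((outs[[d$cond[i]]] - d$targets[i, ])^2), 0.0))
  }
  d <- dataset_for_training(dataset)
  res <- lapply(seq_len(k), function(f) {
    tr_idx <- which(fold_assign != f)
    m <- build_model(model_config(
      n_input = config$n_input, n_layers = config$n_layers,
      units_per_layer = config$units_per_layer,
      learning_rate = config$learning_rate, beta1 = config$beta1,
      beta2 = config$beta2, epsilon = config$epsilon,
      epochs = epochs, batch_size = config$batch_size,
      seed = derive_seed(config$seed, 600, f)))
    m <- train_model(m, dataset, epochs = epochs, trial_subset = tr_idx)
    data.frame(fold = f,
               train_mse = trial_mse(m, d, tr_idx),
               val_mse = trial_mse(m, d, which(fold_assign == f)))
  })
  out <- do.call(rbind, res)
  attr(out, "mean_train") <- mean(out$train_mse)
  attr(out, "sd_train") <- stats::sd(out$train_mse)
  attr(out, "mean_val") <- mean(out$val_mse)
  attr(out, "sd_val") <- stats::sd(out$val_mse)
  attr(out, "folds") <- fold_assign
  out
}

#' Train an ensemble and select the best model
#'
#' Trains `n_models` identically configured models from distinct seeds,
#' scores each against the grand-average waveforms with [fit_metrics()],
#' and returns the model with the highest mean r^2 (ties broken by lower
#' mean MSE; selection is independent of training order).
#'
#' @param config a [model_config()].
#' @param dataset an `idealized_dataset`.
#' @param n_models ensemble size (5 in the full protocol).
#' @param epochs training epochs per model.
#' @return list with `best_model`, `best_index`, `metrics` (per-model
#'   summary data.frame) and `per_condition` (list of [fit_metrics()]
#'   tables).
#' @export
train_ensemble_and_select <- function(config, dataset, n_models = 5,
                                      epochs = config$epochs) {
  ga <- grand_average(dataset)
  models <- vector("list", n_models)
  tabs <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 500, m)
    mod <- build_model(cfg)
    mod <- train_model(mod, dataset, epochs = epochs)
    models[[m]] <- mod
    tabs[[m]] <- fit_metrics(mod, ga, dataset$inputs)
  }
  mean_r2 <- vapply(tabs, attr, 0.0, "mean_r2")
  mean_mse <- vapply(tabs, attr, 0.0, "mean_mse")
  best <- order(-mean_r2, mean_mse)[1]
  list(best_model = models[[best]], best_index = best, models = models,
       metrics = data.frame(model = seq_len(n_models), mean_r2 = mean_r2,
                            mean_mse = mean_mse),
       per_condition = tabs)
}

#' Save / load a trained model archive
#'
#' @param model a `hierarchical_rnn`.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hierarchical_rnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "hierarchical_rnn"))
  model
}
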