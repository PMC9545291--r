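# Shared fixtures, built once per test run and cached. Heavier objects
# (the study-scale cohort and the trained ensemble) are only constructed
# by the tests that need them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small cohort for module-level decoding/preprocessing tests
fixture_cohort_small <- function() {
  fixture("cohort_small", function()
    build_synthetic_dataset(cohort_config(n_animals = 3, seed = 101)))
}

# study-scale cohort: 14 animals, both paradigms, default noise
fixture_cohort_full <- function() {
  fixture("cohort_full", function()
    build_synthetic_dataset(cohort_config(seed = 20)))
}

fixture_dataset <- function() {
  fixture("dataset", function() build_idealized_dataset(fixture_cohort_full()))
}

# 5-model ensemble at the scaled training protocol (150 epochs)
fixture_ensemble <- function() {
  fixture("ensemble", function()
    train_ensemble_and_select(model_config(seed = 7), fixture_dataset(),
                              n_models = 5, epochs = 150))
}

fixture_records <- function() {
  fixture("records", function()
    record_condition_activations(fixture_ensemble()$best_model,
                                 fixture_dataset()$inputs))
}

# tiny idealized-style dataset for fast model tests
make_toy_dataset <- function(n_per_cond = 8, targets = "template",
                             seed = 5) {
  inputs <- condition_cochleagrams()
  conds <- names(inputs)
  labels <- data.frame(
    paradigm = "frequency",
    label = "S",
    condition = rep(conds, each = n_per_cond),
    stringsAsFactors = FALSE)
  tm <- oddballerp:::trial_times(100)
  tg <- matrix(0, nrow(labels), length(tm))
  if (identical(targets, "template")) {
    for (i in seq_len(nrow(labels)))
      tg[i, ] <- erp_template(labels$condition[i], rate = 100)
  }
  structure(list(targets = tg, labels = labels, inputs = inputs,
                 times = tm, rate = 100),
            class = "idealized_dataset")
}

# independent brute-force sample-entropy oracle (double loop over all
# ordered template pairs, Chebyshev distance)
sample_entropy_oracle <- function(x, m = 2, r = 0.15) {
  n <- length(x)
  s <- sd(x)
  if (s == 0) return(0)
  tol <- r * s
  count <- function(len) {
    n_tpl <- n - m
    tot <- 0L
    for (i in seq_len(n_tpl)) for (j in seq_len(n_tpl)) {
      if (i == j) next
      if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= tol)
        tot <- tot + 1L
    }
    tot
  }
  B <- count(m)
  A <- count(m + 1)
  if (B == 0) return(0)
  if (A == 0) return(-log(1 / B))
  -log(A / B)
}

# epoched_trials with two linearly separable conditions at one time point
make_separable_trials <- function(n_per_class = 30, sep_at = 6,
                                  n_time = 11, seed = 3) {
  set.seed(seed)
  data <- array(rnorm(2 * n_per_class * 2 * n_time, sd = 0.2),
                dim = c(2 * n_per_class, 2, n_time))
  data[seq_len(n_per_class), , sep_at] <-
    abs(data[seq_len(n_per_class), , sep_at]) + 1
  data[-seq_len(n_per_class), , sep_at] <-
    -abs(data[-seq_len(n_per_class), , sep_at]) - 1
  labels <- data.frame(animal = 1, paradigm = "frequency",
                       label = rep(c("S", "D1"), each = n_per_class),
                       condition = rep(c("S", "fD1"), each = n_per_class),
                       seq_index = seq_len(2 * n_per_class))
  epoched_trials(data, rate = 100, times = seq(0, by = 0.01,
                                               length.out = n_time),
                 labels = labels)
}
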