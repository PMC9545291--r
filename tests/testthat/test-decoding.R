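test_that("exactly the eight pairwise contrasts are constructible", {
  names8 <- c("fSD", "fSD1", "fSD2", "fD1D2", "iSD", "iSD1", "iSD2", "iD1D2")
  for (nm in names8) {
    ct <- contrast_spec(nm)
    expect_identical(ct$name, nm)
    expect_length(intersect(ct$class_a, ct$class_b), 0L)
  }
  expect_error(contrast_spec("fSS"))
})

test_that("linearly separated classes decode perfectly at the separating sample", {
  tr <- make_separable_trials(n_per_class = 30, sep_at = 6)
  acc <- timewise_decode(tr, "fSD1", folds = 5, repeats = 1, seed = 1)
  expect_equal(unname(acc[6]), 1.0)
  expect_true(all(acc >= 0 & acc <= 1))
  # chance everywhere else (no structure)
  expect_lt(mean(acc[-6]), 0.65)
})

test_that("decoding accuracy is invariant to common amplitude rescaling", {
  tr <- make_separable_trials(n_per_class = 20, sep_at = 4)
  acc1 <- timewise_decode(tr, "fSD1", folds = 5, repeats = 1, seed = 2)
  tr$data <- tr$data * 37.5
  acc2 <- timewise_decode(tr, "fSD1", folds = 5, repeats = 1, seed = 2)
  expect_equal(unname(acc1), unname(acc2), tolerance = 1e-12)
})

test_that("swapping the two class definitions leaves accuracy unchanged", {
  tr <- make_separable_trials(n_per_class = 20, sep_at = 4)
  ct <- contrast_spec("fSD1")
  swapped <- ct
  swapped$class_a <- ct$class_b
  swapped$class_b <- ct$class_a
  a1 <- timewise_decode(tr, ct, folds = 5, repeats = 1, seed = 6)
  a2 <- timewise_decode(tr, swapped, folds = 5, repeats = 1, seed = 6)
  expect_equal(unname(a1), unname(a2), tolerance = 1e-12)
})

test_that("under-sampling handles unbalanced classes and small classes error", {
  tr <- make_separable_trials(n_per_class = 30, sep_at = 6)
  keep <- c(1:30, 31:45)                      # 30 vs 15 trials
  tr$data <- tr$data[keep, , , drop = FALSE]
  tr$labels <- tr$labels[keep, ]
  acc <- timewise_decode(tr, "fSD1", folds = 5, repeats = 2, seed = 3)
  expect_equal(unname(acc[6]), 1.0)
  tr2 <- tr
  tr2$data <- tr2$data[c(1:30, 31:33), , , drop = FALSE]
  tr2$labels <- tr2$labels[c(1:30, 31:33), ]
  expect_error(timewise_decode(tr2, "fSD1", folds = 5, repeats = 1, seed = 1),
               "folds")
})

test_that("temporal generalisation is square and its diagonal matches time-wise decoding", {
  cohort <- fixture_cohort_small()
  tr <- oddballerp:::merge_paradigm_trials(cohort, 1)
  tg <- temporal_generalization(tr, "fSD1", folds = 10, repeats = 1, seed = 4)
  expect_identical(dim(unclass(tg)), c(111L, 111L))
  expect_true(all(tg >= 0 & tg <= 1))
  tw <- timewise_decode(tr, "fSD1", folds = 10, repeats = 1, seed = 4)
  expect_lt(mean(abs(diag(tg) - tw)), 0.02)
})

test_that("an isolated condition effect confines generalisation to its window", {
  # two classes differing only by a bump over 0.3-0.5 s
  set.seed(8)
  tm <- oddballerp:::trial_times(100)
  bump <- exp(-0.5 * ((tm - 0.4) / 0.05)^2)
  n <- 40
  data <- array(rnorm(2 * n * 2 * 111, sd = 0.4), c(2 * n, 2, 111))
  for (i in seq_len(n))
    for (ch in 1:2) data[i, ch, ] <- data[i, ch, ] + bump
  labels <- data.frame(animal = 1, paradigm = "frequency",
                       label = rep(c("D1", "S"), each = n),
                       condition = rep(c("fD1", "S"), each = n),
                       seq_index = seq_len(2 * n))
  tr <- epoched_trials(data, 100, tm, labels)
  tg <- temporal_generalization(tr, "fSD1", folds = 5, repeats = 1, seed = 9)
  inside <- tm >= 0.3 & tm <= 0.5
  expect_gt(mean(tg[inside, inside]), 0.7)            # well above chance
  expect_lt(mean(tg[!inside, !inside]), 0.6)          # chance elsewhere
  expect_gt(mean(tg[inside, inside]) - mean(tg[!inside, !inside]), 0.15)
})

test_that("group-mean accuracy falls to chance as the condition effect vanishes", {
  specs <- default_component_specs()
  gains <- c(1, 0.4, 0)
  window_acc <- numeric(3)
  for (g in seq_along(gains)) {
    sp <- specs
    i <- which(vapply(sp, `[[`, "", "name") == "long_latency_positive")
    sp[[i]]$base_amplitude <- sp[[i]]$base_amplitude * gains[g]
    cfg <- cohort_config(n_animals = 2, n_s = 100, n_d1 = 25, n_d2 = 25,
                         component_specs = sp, seed = 71)
    cohort <- build_synthetic_dataset(cfg)
    acc <- group_decode(cohort, "fSD1", folds = 5, repeats = 1, seed = 5)
    tm <- attr(acc, "times")
    window_acc[g] <- mean(acc[, tm >= 0.3 & tm <= 0.5])
  }
  expect_true(all(diff(window_acc) < 0))      # monotone decay toward chance
  expect_lt(abs(window_acc[3] - 0.5), 0.06)
})
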