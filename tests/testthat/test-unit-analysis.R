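tm100 <- seq(-0.1, 1, by = 0.01)
bump_at <- function(mu, sd = 0.02) exp(-0.5 * ((tm100 - mu) / sd)^2)

test_that("the temporal-response-field cascade assigns the documented categories", {
  expect_identical(categorize_unit(rep(0, 111), tm100), "zero")
  expect_identical(categorize_unit(bump_at(0.05), tm100), "onset")
  expect_identical(categorize_unit(bump_at(0.60), tm100), "onset")
  expect_identical(categorize_unit(bump_at(0.12), tm100), "offset")
  expect_identical(categorize_unit(bump_at(0.68), tm100), "offset")
  expect_identical(categorize_unit(bump_at(0.20), tm100), "safety")
  expect_identical(categorize_unit(bump_at(0.75), tm100), "safety")
  expect_identical(categorize_unit(bump_at(0.38), tm100), "danger")
  expect_identical(categorize_unit(bump_at(0.50), tm100), "danger")
  # 10 Hz rhythm peaking before stimulus onset
  alpha_trace <- pmax(sin(2 * pi * 10 * tm100 + 2.51), 0) *
    c(rep(1, 10), rep(0.2, 101))
  expect_identical(categorize_unit(alpha_trace, tm100), "alpha")
  # window boundaries belong to the earlier category
  expect_identical(categorize_unit(bump_at(0.10), tm100), "onset")
  expect_identical(categorize_unit(bump_at(0.15), tm100), "offset")
  expect_identical(categorize_unit(bump_at(0.25), tm100), "safety")
  expect_identical(categorize_unit(bump_at(0.55), tm100), "onset")
  # a late peak outside all windows
  expect_identical(categorize_unit(bump_at(0.9), tm100), "other")
})

test_that("modal category takes the mode with cascade-order tie-breaking", {
  expect_identical(modal_category(rep("onset", 5)), "onset")
  expect_identical(modal_category(c("onset", "onset", "onset", "danger",
                                    "danger")), "onset")
  expect_identical(modal_category(c("onset", "onset", "danger", "danger",
                                    "zero")), "onset")
  expect_identical(modal_category(c("danger", "danger", "safety", "safety",
                                    "zero")), "safety")
})

test_that("sample entropy follows the Richman-Moorman conventions", {
  expect_identical(sample_entropy(rep(2.5, 111)), 0)
  expect_error(sample_entropy(c(1, 2, 3)), "short")
  # affine invariance: tolerance scales with the series SD
  set.seed(31)
  x <- rnorm(111)
  expect_equal(sample_entropy(x), sample_entropy(5 * x - 2),
               tolerance = 1e-12)
  # noise is less regular than a sampled rhythm
  set.seed(32)
  noise <- runif(111)
  rhythm <- sin(2 * pi * 10 * tm100)
  expect_gt(sample_entropy(noise), sample_entropy(rhythm))
  expect_equal(sample_entropy(rhythm), sample_entropy_oracle(rhythm),
               tolerance = 1e-12)
})

test_that("entropy summaries reproduce a hand-computed toy catalogue", {
  catalog <- data.frame(
    layer = c(1, 1, 2, 2), unit = c(1, 2, 1, 2),
    category_S = c("zero", "onset", "alpha", "danger"),
    entropy_S = c(0, 0.2, 0.1, 0.4),
    category_fD1 = c("zero", "onset", "alpha", "danger"),
    entropy_fD1 = c(0, 0.4, 0.3, 0.2),
    modal = c("zero", "onset", "alpha", "danger"),
    stringsAsFactors = FALSE)
  class(catalog) <- c("unit_catalog", "data.frame")
  es <- summarize_entropy(catalog)
  expect_equal(unname(es$zero_counts[, "S"]), c(1, 0))
  expect_equal(unname(es$nonzero_mean["layer1", "S"]), 0.2)
  expect_equal(unname(es$nonzero_mean["layer2", "fD1"]), 0.25)
  expect_equal(unname(es$median_by_layer[["layer1"]]),
               median(c(0, 0.2, 0, 0.4)))
  expect_equal(unname(es$median_by_condition[["fD1"]]),
               median(c(0, 0.4, 0.3, 0.2)))
  by_cat <- es$by_category
  expect_equal(by_cat$mean[by_cat$category == "onset"], mean(c(0.2, 0.4)))
  expect_equal(by_cat$n[by_cat$category == "zero"], 1L)
  expect_true(is.na(by_cat$mean[by_cat$category == "offset"]))
})

test_that("unit catalogues partition all hidden units of an untrained model", {
  m <- build_model(model_config(seed = 61))
  recs <- record_condition_activations(m)
  catalog <- build_unit_catalog(recs)
  expect_identical(nrow(catalog), 256L)
  counts <- category_counts(catalog)
  expect_equal(unname(colSums(counts[, 1:4])), rep(64, 4))
  expect_equal(unname(sum(counts[, "Total"])), 256)
  expect_true(all(catalog$modal %in% c("zero", "alpha", "onset", "offset",
                                       "safety", "danger", "other")))
})

test_that("PCA views expose the documented matrix layouts", {
  m <- build_model(model_config(seed = 62))
  recs <- record_condition_activations(m)
  pv <- pca_views(recs)
  expect_identical(pv$conditions$input_dim, c(5L, 28416L))
  expect_identical(pv$layers$input_dim, c(4L, 35520L))
  for (l in 1:4)
    expect_identical(pv$units_by_layer[[l]]$input_dim, c(64L, 555L))
  for (view in c(list(pv$conditions, pv$layers), pv$units_by_layer)) {
    ev <- view$explained
    expect_true(ev[1] >= ev[2] && ev[2] >= 0 && sum(ev) <= 1 + 1e-12)
  }
})
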