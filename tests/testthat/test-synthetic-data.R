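test_that("oddball sequences satisfy the paradigm constraints", {
  sq <- generate_oddball_sequence(seed = 11)
  expect_length(sq, 1000)
  expect_equal(as.vector(table(factor(as.character(sq),
                                      c("S", "D1", "D2")))),
               c(800, 100, 100))
  lab <- as.character(sq)
  expect_identical(lab[1], "S")
  dev <- lab != "S"
  expect_false(any(dev[-1] & dev[-length(dev)]))       # no adjacent deviants
  expect_length(standards_before_deviants(sq), 200)
  # reproducibility
  expect_identical(as.character(generate_oddball_sequence(seed = 11)), lab)
  expect_false(identical(as.character(generate_oddball_sequence(seed = 12)), lab))
  expect_error(generate_oddball_sequence(2, 2, 1), "infeasible")
})

test_that("the tiny 2-standard, 1-deviant sequence has exactly two layouts", {
  seen <- vapply(1:40, function(s)
    paste(generate_oddball_sequence(2, 1, 0, seed = s), collapse = " "), "")
  expect_true(all(seen %in% c("S D1 S", "S S D1")))
  expect_length(unique(seen), 2L)
})

test_that("response templates encode the condition-specific morphology", {
  tm <- oddballerp:::trial_times(1000)
  zero_ll <- c(long_latency_positive = 0, long_latency_positive_late = 0,
               long_latency_negative = 0)
  s_obl <- erp_template("S", component_gains = zero_ll)
  expect_equal(s_obl, erp_template("S"))   # S carries no long-latency bumps
  # salient first tones add a positive 0.3-0.5 s feature
  for (cc in c("fD1", "fD2", "iD1")) {
    d <- erp_template(cc) - erp_template("S")
    expect_gt(mean(d[tm >= 0.3 & tm <= 0.5]), 0.1)
  }
  # falling transition on iD2 adds a late positive feature
  d2 <- erp_template("iD2") - erp_template("S")
  expect_gt(mean(d2[tm >= 0.79 & tm <= 1.0]), 0.05)
  expect_lt(mean(d2[tm >= 0.3 & tm <= 0.5]), 0.05)
  # additivity: doubling a component's base amplitude doubles its share
  spec2 <- default_component_specs()
  i <- which(vapply(spec2, `[[`, "", "name") == "long_latency_positive")
  spec2[[i]]$base_amplitude <- 2 * spec2[[i]]$base_amplitude
  d_once <- erp_template("fD1") - s_obl
  d_twice <- erp_template("fD1", spec2) - s_obl
  ll_once <- erp_template("fD1") -
    erp_template("fD1", component_gains = c(long_latency_positive = 0))
  expect_equal(d_twice - d_once, ll_once, tolerance = 1e-12)
})

test_that("the noise-free cohort limit reproduces the templates exactly", {
  cfg <- cohort_config(n_animals = 2, trial_noise_sd = 0,
                       animal_effect_sd = 0, alpha_amplitude = 0,
                       n_s = 8, n_d1 = 2, n_d2 = 2, seed = 9)
  sim <- simulate_animal_paradigm(cfg, 1, "intensity")
  for (i in c(1, 5, 12)) {
    cond <- sim$trials$labels$condition[i]
    expect_equal(sim$trials$data[i, 1, ], erp_template(cond),
                 tolerance = 1e-12)
    expect_equal(sim$trials$data[i, 2, ], 0.95 * erp_template(cond),
                 tolerance = 1e-12)
  }
})

test_that("cohort simulation is bit-reproducible and balances to 400 trials", {
  cfg <- cohort_config(n_animals = 2, n_s = 16, n_d1 = 4, n_d2 = 4, seed = 33)
  a <- simulate_animal_paradigm(cfg, 1, "frequency")
  b <- simulate_animal_paradigm(cfg, 1, "frequency")
  expect_identical(a$trials$data, b$trials$data)
  c2 <- simulate_animal_paradigm(cfg, 2, "frequency")
  expect_false(identical(a$trials$data, c2$trials$data))
  # full default counts balance to 200 + 100 + 100 per paradigm
  full <- fixture_cohort_small()
  for (p in c("frequency", "intensity")) {
    tab <- table(full$animals[[1]][[p]]$trials$labels$label)
    expect_equal(as.vector(tab[c("S", "D1", "D2")]), c(200, 100, 100))
  }
})

test_that("grand averages track the generating templates at study scale", {
  ga <- grand_average(fixture_dataset())
  for (cc in rownames(ga)) {
    templ <- erp_template(cc, rate = 100)
    expect_gt(cor(ga[cc, ], templ), 0.95)
  }
})
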