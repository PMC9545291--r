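make_signal_trials <- function(f_hz, rate = 1000, amp = 1) {
  tm <- oddballerp:::trial_times(rate)
  sig <- amp * sin(2 * pi * f_hz * tm)
  data <- array(0, c(1, 1, length(tm)))
  data[1, 1, ] <- sig
  epoched_trials(data, rate, tm,
                 data.frame(animal = 1, paradigm = "frequency", label = "S",
                            condition = "S", seq_index = 1))
}

test_that("band-pass keeps 10 Hz and rejects 100 Hz", {
  mid <- function(tr) {
    keep <- tr$times > 0 & tr$times < 0.9     # avoid filter edge transients
    max(abs(tr$data[1, 1, keep]))
  }
  in10 <- make_signal_trials(10)
  expect_equal(mid(bandpass_filter(in10)), 1, tolerance = 0.1)
  in100 <- make_signal_trials(100)
  expect_lt(mid(bandpass_filter(in100)), 0.1)
  z <- make_signal_trials(10, amp = 0)
  expect_equal(bandpass_filter(z)$data, z$data)
  slow <- make_signal_trials(5, rate = 50)
  expect_error(bandpass_filter(slow), "rate")
})

test_that("baseline correction zeroes the pre-stimulus mean and is shift-invariant", {
  set.seed(4)
  tm <- oddballerp:::trial_times(1000)
  data <- array(rnorm(5 * 2 * length(tm)), c(5, 2, length(tm)))
  tr <- epoched_trials(data, 1000, tm,
                       data.frame(animal = 1, paradigm = "frequency",
                                  label = rep("S", 5), condition = "S",
                                  seq_index = 1:5))
  bc <- baseline_correct(tr)
  expect_lt(max(abs(apply(bc$data[, , tm < 0], c(1, 2), mean))), 1e-10)
  # adding a constant changes nothing after correction
  tr2 <- tr
  tr2$data <- tr$data + 3.7
  expect_equal(baseline_correct(tr2)$data, bc$data, tolerance = 1e-12)
  # idempotence
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
})

test_that("resampling to 100 Hz yields the 111-sample inclusive grid", {
  tr <- make_signal_trials(5)
  rs <- resample_to(tr)
  expect_identical(dim(rs$data)[3], 111L)
  expect_equal(rs$times, seq(-0.1, 1, by = 0.01))
  # pure subsampling: the 5 Hz sine is preserved exactly on shared samples
  expect_equal(rs$data[1, 1, ], sin(2 * pi * 5 * rs$times), tolerance = 1e-9)
  const <- make_signal_trials(5, amp = 0)
  const$data[] <- 2.5
  expect_true(all(resample_to(const)$data == 2.5))
  expect_error(resample_to(make_signal_trials(5), rate = 300), "integer")
})

test_that("balancing keeps exactly the standards that precede deviants", {
  lab <- c("S", "D1", "S", "S", "D2")
  tm <- oddballerp:::trial_times(100)
  data <- array(seq_len(5 * 1 * 111), c(5, 1, 111))
  tr <- epoched_trials(data, 100, tm,
                       data.frame(animal = 1, paradigm = "frequency",
                                  label = lab,
                                  condition = oddballerp:::paradigm_condition(lab, "frequency"),
                                  seq_index = 1:5))
  sq <- structure(lab, class = "oddball_sequence")
  bal <- select_balanced_standards(sq, tr)
  expect_identical(bal$labels$seq_index, c(1L, 2L, 4L, 5L))
  # deviant trials are untouched
  expect_equal(bal$data[bal$labels$label != "S", , ],
               data[c(2, 5), 1, ])
  # retained standards = total deviants whenever none are adjacent
  sq2 <- generate_oddball_sequence(40, 10, 5, seed = 2)
  expect_length(standards_before_deviants(sq2), 15)
  # misalignment is rejected
  tr$labels$label[1] <- "D1"
  expect_error(select_balanced_standards(sq, tr), "misaligned")
})

test_that("the idealised dataset is the cross-animal, cross-channel trial average", {
  cohort <- fixture_cohort_small()
  ds <- build_idealized_dataset(cohort)
  expect_identical(nrow(ds$targets), 800L)
  expect_identical(ncol(ds$targets), 111L)
  expect_equal(as.vector(table(ds$labels$condition)[c("S", "fD1", "fD2",
                                                      "iD1", "iD2")]),
               c(400, 100, 100, 100, 100))
  # spot-check one trial: first fD1 occurrence = mean over animals/channels
  i <- which(ds$labels$condition == "fD1")[1]
  manual <- rowMeans(sapply(cohort$animals, function(an) {
    tr <- an$frequency$trials
    j <- which(tr$labels$condition == "fD1")[1]
    colMeans(tr$data[j, , ])
  }))
  expect_equal(ds$targets[i, ], manual, tolerance = 1e-12)
})

test_that("a single-animal cohort passes through the idealised average unchanged", {
  small <- fixture_cohort_small()
  solo <- small
  solo$animals <- solo$animals[1]
  ds <- build_idealized_dataset(solo)
  tr <- solo$animals[[1]]$frequency$trials
  i <- which(ds$labels$condition == "fD2")[3]
  j <- which(tr$labels$condition == "fD2")[3]
  expect_equal(ds$targets[i, ], colMeans(tr$data[j, , ]), tolerance = 1e-12)
})

test_that("idealised-trial noise shrinks as 1/sqrt(channels x animals)", {
  # noise-only cohort: no components, no background rhythm
  cfg <- cohort_config(n_animals = 4, trial_noise_sd = 1, animal_effect_sd = 0,
                       alpha_amplitude = 0, n_s = 20, n_d1 = 5, n_d2 = 5,
                       channel_gains = c(1, 1),
                       component_specs = list(), seed = 61)
  cohort <- build_synthetic_dataset(cfg)
  ds <- build_idealized_dataset(cohort)
  sd_ideal <- sd(ds$targets)
  one <- cohort$animals[[1]]$frequency$trials
  sd_single <- sd(one$data[, 1, ])
  ratio <- sd_ideal / sd_single
  expect_equal(ratio, 1 / sqrt(2 * 4), tolerance = 0.2)
})

test_that("grand averages are per-condition means with standards pooled", {
  ds <- build_idealized_dataset(fixture_cohort_small())
  ga <- grand_average(ds)
  expect_identical(dim(ga), c(5L, 111L))
  expect_identical(rownames(ga), c("S", "fD1", "fD2", "iD1", "iD2"))
  # weighted recombination equals the overall mean trial
  w <- table(ds$labels$condition)[rownames(ga)]
  expect_equal(colSums(ga * as.vector(w)) / sum(w), colMeans(ds$targets),
               tolerance = 1e-12)
  expect_equal(ga["S", ],
               colMeans(ds$targets[ds$labels$condition == "S", ]),
               tolerance = 1e-12)
})

test_that("swapping baseline correction and resampling is inert for in-band signals", {
  tm <- oddballerp:::trial_times(1000)
  sig <- 0.8 + sin(2 * pi * 10 * tm + 0.4)    # 10 Hz + offset
  data <- array(0, c(1, 1, length(tm)))
  data[1, 1, ] <- sig
  tr <- epoched_trials(data, 1000, tm,
                       data.frame(animal = 1, paradigm = "frequency",
                                  label = "S", condition = "S", seq_index = 1))
  a <- resample_to(baseline_correct(tr))
  b <- baseline_correct(resample_to(tr))
  expect_lt(max(abs(a$data - b$data)), 1e-6)
})
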