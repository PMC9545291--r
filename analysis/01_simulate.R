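# Simulate the synthetic cohort: 14 animals x 2 oddball paradigms
# (frequency 10 +/- 2.5 kHz, intensity 80 +/- 10 dB), 800/100/100
# sequences realised as two-response epochs, balanced to 400 trials per
# animal-paradigm and preprocessed (0.1-30 Hz, baseline, 100 Hz).

source(file.path("analysis", "00_common.R"))

cc <- config$cohort
cohort <- cached("cohort", function()
  build_synthetic_dataset(cohort_config(
    n_animals = cc$n_animals, trial_noise_sd = cc$trial_noise_sd,
    animal_effect_sd = cc$animal_effect_sd,
    alpha_amplitude = cc$alpha_amplitude,
    n_s = cc$n_s, n_d1 = cc$n_d1, n_d2 = cc$n_d2, seed = config$seed)))

counts <- table(cohort$animals[[1]]$frequency$trials$labels$label)
message("animal 1, frequency paradigm after balancing: ",
        paste(names(counts), counts, sep = "=", collapse = ", "))

# per-animal condition means, long format, for plotting elsewhere
rows <- list()
for (a in seq_along(cohort$animals)) {
  for (p in c("frequency", "intensity")) {
    tr <- cohort$animals[[a]][[p]]$trials
    for (cc2 in unique(tr$labels$condition)) {
      m <- colMeans(tr$data[tr$labels$condition == cc2, , , drop = FALSE],
                    dims = 2)
      rows[[length(rows) + 1]] <-
        data.frame(animal = a, paradigm = p, condition = cc2,
                   time = tr$times, amplitude = m)
    }
  }
}
write.csv(do.call(rbind, rows),
          file.path(out_dir, "animal_condition_means.csv"),
          row.names = FALSE)
message("wrote ", file.path(out_dir, "animal_condition_means.csv"))
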