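# Time-wise decoding of all eight pairwise contrasts, per animal, with
# linear SVMs (10-fold CV x 5 repeats, undersampling to equal classes),
# plus temporal generalisation for the standard-vs-deviant contrasts.

source(file.path("analysis", "00_common.R"))
if (!file.exists(cache_path("cohort"))) source(file.path("analysis", "01_simulate.R"))
cohort <- readRDS(cache_path("cohort"))

maps <- cached("decoding_maps", function() {
  out <- lapply(config$decoding$contrasts, function(cn) {
    message("decoding ", cn, " ...")
    group_decode(cohort, cn, folds = config$decoding$folds,
                 repeats = config$decoding$repeats, seed = config$seed)
  })
  names(out) <- config$decoding$contrasts
  out
})

times <- attr(maps[[1]], "times")
acc <- data.frame(time = times, sapply(maps, function(m) colMeans(unclass(m))))
write.csv(acc, file.path(out_dir, "decoding_group_accuracy.csv"),
          row.names = FALSE)
for (cn in names(maps)) {
  peak <- max(colMeans(unclass(maps[[cn]])))
  message(sprintf("%-6s peak group accuracy %.3f at %.2f s", cn, peak,
                  times[which.max(colMeans(unclass(maps[[cn]])))]))
}

tg <- cached("tg_maps", function() {
  out <- lapply(c("fSD1", "iSD2"), function(cn) {
    message("temporal generalisation ", cn, " ...")
    group_decode(cohort, cn, folds = config$decoding$folds,
                 repeats = 1, seed = config$seed, generalize = TRUE)
  })
  names(out) <- c("fSD1", "iSD2")
  out
})
message("wrote decoding_group_accuracy.csv; cached decoding + TG maps")
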