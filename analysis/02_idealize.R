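# Assemble the "idealised experiment": average corresponding balanced
# trials across animals and channels (800 trials), attach per-condition
# cochleagram inputs, and write the grand-average waveforms.

source(file.path("analysis", "00_common.R"))
if (!file.exists(cache_path("cohort"))) source(file.path("analysis", "01_simulate.R"))
cohort <- readRDS(cache_path("cohort"))

dataset <- cached("dataset", function() build_idealized_dataset(cohort))
ga <- grand_average(dataset)

message(nrow(dataset$targets), " idealised trials (",
        paste(names(table(dataset$labels$condition)),
              table(dataset$labels$condition), sep = "=", collapse = ", "), ")")

write.csv(data.frame(time = dataset$times, t(ga)),
          file.path(out_dir, "grand_average.csv"), row.names = FALSE)
write.csv(dataset$labels, file.path(out_dir, "idealized_labels.csv"),
          row.names = FALSE)
message("wrote grand_average.csv and idealized_labels.csv")
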