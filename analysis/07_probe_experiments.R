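# Simulated probe experiments on the trained model: sweeps over tone
# duration (100-500 ms), frequency (5-15 kHz) and intensity (60-100 dB),
# with the qualitative expectations on offset latency and onset
# amplitude scaling.

source(file.path("analysis", "00_common.R"))
if (!file.exists(cache_path("ensemble"))) source(file.path("analysis", "05_fit_rnn.R"))
ens <- readRDS(cache_path("ensemble"))
model <- ens$best_model

reports <- lapply(c("duration", "frequency", "intensity"), function(k)
  run_probe_sweep(model, probe_sweep(k)))
names(reports) <- c("duration", "frequency", "intensity")

for (k in names(reports)) {
  write.csv(as.data.frame(reports[[k]]),
            file.path(out_dir, paste0("probe_", k, ".csv")), row.names = FALSE)
  wv <- attr(reports[[k]], "waveforms")
  write.csv(data.frame(value = reports[[k]]$value, wv),
            file.path(out_dir, paste0("probe_waveforms_", k, ".csv")),
            row.names = FALSE)
}

checks <- qualitative_checks(reports$duration, reports$intensity)
for (nm in names(checks))
  message(nm, ": ", if (checks[[nm]]) "pass" else "fail")
write.csv(data.frame(check = names(checks), passed = checks),
          file.path(out_dir, "probe_checks.csv"), row.names = FALSE)
message("wrote probe reports and checks")
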