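# Fit the hierarchical recurrent network: 10-fold cross-validation of
# the architecture, then five identically configured models trained for
# the full protocol; the best (highest mean r^2, lowest MSE) is kept for
# unit analysis and probe experiments.

source(file.path("analysis", "00_common.R"))
if (!file.exists(cache_path("dataset"))) source(file.path("analysis", "02_idealize.R"))
dataset <- readRDS(cache_path("dataset"))

mc <- model_config(epochs = config$model$epochs,
                   batch_size = config$model$batch_size, seed = config$seed)

cv <- cached("cv", function()
  crossvalidate_model(mc, dataset, k = 10, epochs = config$model$epochs))
message(sprintf("CV terminal MSE: train %.4g (SD %.2g), validation %.4g (SD %.2g)",
                attr(cv, "mean_train"), attr(cv, "sd_train"),
                attr(cv, "mean_val"), attr(cv, "sd_val")))
write.csv(cv, file.path(out_dir, "crossvalidation.csv"), row.names = FALSE)

ens <- cached("ensemble", function()
  train_ensemble_and_select(mc, dataset, n_models = config$model$n_models))
print(ens$metrics)
message(sprintf("selected model %d: mean r^2 = %.3f, mean MSE = %.4g",
                ens$best_index,
                ens$metrics$mean_r2[ens$best_index],
                ens$metrics$mean_mse[ens$best_index]))
write.csv(ens$metrics, file.path(out_dir, "model_metrics.csv"),
          row.names = FALSE)
write.csv(data.frame(epoch = seq_along(ens$best_model$history),
                     loss = ens$best_model$history),
          file.path(out_dir, "training_history.csv"), row.names = FALSE)
save_model(ens$best_model, file.path(out_dir, "best_model.rds"))
message("wrote crossvalidation.csv, model_metrics.csv, training_history.csv, best_model.rds")
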