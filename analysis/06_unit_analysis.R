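# Characterise the trained hidden units: temporal-response-field
# taxonomy (zero/alpha/onset/offset/safety/danger/other), the three PCA
# views, and sample-entropy summaries.

source(file.path("analysis", "00_common.R"))
if (!file.exists(cache_path("ensemble"))) source(file.path("analysis", "05_fit_rnn.R"))
ens <- readRDS(cache_path("ensemble"))
dataset <- readRDS(cache_path("dataset"))

recs <- record_condition_activations(ens$best_model, dataset$inputs)
catalog <- build_unit_catalog(recs, dataset$times)

counts <- category_counts(catalog)
print(counts)
write.csv(data.frame(category = rownames(counts), counts),
          file.path(out_dir, "category_counts.csv"), row.names = FALSE)
write.csv(as.data.frame(catalog), file.path(out_dir, "unit_catalog.csv"),
          row.names = FALSE)

es <- summarize_entropy(catalog)
message("median entropy by layer: ",
        paste(sprintf("%.3f", es$median_by_layer), collapse = ", "))
message("median entropy by condition: ",
        paste(names(es$median_by_condition),
              sprintf("%.3f", es$median_by_condition), collapse = ", "))
write.csv(data.frame(layer = rownames(es$zero_counts), es$zero_counts),
          file.path(out_dir, "entropy_zero_counts.csv"), row.names = FALSE)
write.csv(data.frame(layer = rownames(es$nonzero_mean), es$nonzero_mean),
          file.path(out_dir, "entropy_nonzero_mean.csv"), row.names = FALSE)
write.csv(es$by_category, file.path(out_dir, "entropy_by_category.csv"),
          row.names = FALSE)

pv <- pca_views(recs)
message(sprintf("PCA explained variance: conditions %.0f%%, layers %.0f%%, units/layer %s",
                100 * sum(pv$conditions$explained),
                100 * sum(pv$layers$explained),
                paste(sprintf("%.0f%%", 100 * vapply(pv$units_by_layer,
                                                     function(v) sum(v$explained), 0.0)),
                      collapse = " ")))
write.csv(data.frame(condition = rownames(pv$conditions$scores),
                     pv$conditions$scores),
          file.path(out_dir, "pca_conditions.csv"), row.names = FALSE)
unit_scores <- do.call(rbind, lapply(1:4, function(l)
  data.frame(layer = l, unit = 1:64, pv$units_by_layer[[l]]$scores,
             modal = catalog$modal[catalog$layer == l])))
write.csv(unit_scores, file.path(out_dir, "pca_units.csv"), row.names = FALSE)
message("wrote unit_catalog.csv, category_counts.csv, entropy tables, PCA scores")
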