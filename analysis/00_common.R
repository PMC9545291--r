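# Shared setup for the numbered analysis scripts: loads the package,
# reads analysis/config.yaml and fixes the output directory. Each script
# can be run on its own; intermediate objects are cached under results/
# so later stages reuse earlier ones.

library(oddballerp)

config <- load_pipeline_config(file.path("analysis", "config.yaml"))
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cache_path <- function(name) file.path(out_dir, paste0(name, ".rds"))

cached <- function(name, builder) {
  p <- cache_path(name)
  if (file.exists(p)) return(readRDS(p))
  obj <- builder()
  saveRDS(obj, p)
  obj
}
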