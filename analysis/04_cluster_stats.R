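# Group-level inference: one-sample cluster-based permutation tests of
# each decoding map against chance (alpha = .05, 1000 sign-flip
# permutations), in 1-D for the time-wise maps and 2-D (4-connectivity)
# for the temporal-generalisation maps.

source(file.path("analysis", "00_common.R"))
if (!file.exists(cache_path("decoding_maps"))) source(file.path("analysis", "03_decode.R"))
maps <- readRDS(cache_path("decoding_maps"))
tg <- readRDS(cache_path("tg_maps"))

times <- attr(maps[[1]], "times")
res_1d <- lapply(names(maps), function(cn) {
  res <- cluster_permutation(maps[[cn]], alpha = config$stats$alpha,
                             n_perm = config$stats$n_perm,
                             seed = derive_seed(config$seed, 7001,
                                                match(cn, names(maps))))
  sig <- Filter(function(cl) cl$significant, res$clusters)
  for (cl in sig)
    message(sprintf("%-6s significant cluster %.2f-%.2f s (mass %.1f, p = %.3f)",
                    cn, times[min(cl$members)], times[max(cl$members)],
                    cl$mass, cl$p))
  if (!length(sig)) message(cn, ": no significant clusters")
  list(contrast = cn,
       clusters = lapply(res$clusters, function(cl)
         list(start_s = times[min(cl$members)], end_s = times[max(cl$members)],
              mass = cl$mass, p = cl$p, significant = cl$significant)))
})
jsonlite::write_json(res_1d, file.path(out_dir, "cluster_stats_timewise.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

res_2d <- lapply(names(tg), function(cn) {
  res <- cluster_permutation(tg[[cn]], alpha = config$stats$alpha,
                             n_perm = config$stats$n_perm,
                             seed = derive_seed(config$seed, 7002,
                                                match(cn, names(tg))))
  n_sig <- sum(vapply(res$clusters, `[[`, TRUE, "significant"))
  message(cn, " temporal generalisation: ", n_sig, " significant cluster(s)")
  write.csv(data.frame(train = rep(times, times = length(times)),
                       test = rep(times, each = length(times)),
                       significant = as.vector(res$sig_mask)),
            file.path(out_dir, paste0("tg_sig_mask_", cn, ".csv")),
            row.names = FALSE)
  n_sig
})
message("wrote cluster_stats_timewise.json and TG significance masks")
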