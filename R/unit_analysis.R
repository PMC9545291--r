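.unit_categories <- c("zero", "alpha", "onset", "offset", "safety",
                      "danger", "other")

# Latency windows (seconds, relative to first-tone onset) used by the
# temporal-response-field taxonomy. Stimuli are on over [0, .1] and
# [.55, .65]; each later window follows both tones. Boundaries belong to
# the earlier category.
.category_windows <- list(
  onset  = rbind(c(0.00, 0.10), c(0.55, 0.65)),
  offset = rbind(c(0.10, 0.15), c(0.65, 0.70)),
  safety = rbind(c(0.15, 0.25), c(0.70, 0.80)),
  danger = rbind(c(0.25, 0.55))
)

in_windows <- function(t, win, closed_left) {
  hit <- FALSE
  for (r in seq_len(nrow(win))) {
    lo <- win[r, 1]; hi <- win[r, 2]
    hit <- hit || if (closed_left) (t >= lo && t <= hi) else (t > lo && t <= hi)
  }
  hit
}

#' Categorise a hidden unit by its temporal response field
#'
#' Decision cascade over the unit's 111-sample activation trace:
#' `zero` if the trace never departs from zero; `alpha` if the global
#' peak falls before stimulus onset, or pre-stimulus samples exceed the
#' trace mean by three trace SDs while the post-stimulus peak stays below
#' half the pre-stimulus peak; then by global peak latency: `onset`
#' during stimulus-on times (0-.1, .55-.65 s), `offset` up to 50 ms after
#' stimulus off, `safety` 50-150 ms after stimulus off, `danger` between
#' .25 and .55 s; `other` otherwise. The peak is the earliest global
#' argmax of the raw trace.
#'
#' @param trace numeric activation trace.
#' @param times sample times (defaults to the -0.1..1.0 s grid at 100 Hz).
#' @param zero_tol absolute tolerance for "never active".
#' @return a single category string.
#' @export
categorize_unit <- function(trace, times = trial_times(100),
                            zero_tol = 1e-12) {
  stopifnot(length(trace) == length(times))
  if (max(abs(trace)) <= zero_tol) return("zero")
  peak_i <- which.max(trace)          # earliest sample wins ties
  peak_t <- times[peak_i]
  pre <- times < 0
  m <- mean(trace); s <- stats::sd(trace)
  pre_peak <- max(trace[pre])
  post_peak <- max(trace[!pre])
  if (peak_t < 0 ||
      (pre_peak > m + 3 * s && post_peak < 0.5 * pre_peak))
    return("alpha")
  if (in_windows(peak_t, .category_windows$onset, closed_left = TRUE))
    return("onset")
  if (in_windows(peak_t, .category_windows$offset, closed_left = FALSE))
    return("offset")
  if (in_windows(peak_t, .category_windows$safety, closed_left = FALSE))
    return("safety")
  if (in_windows(peak_t, .category_windows$danger, closed_left = FALSE))
    return("danger")
  "other"
}

#' Most frequent category across stimulus conditions
#'
#' Ties are broken by the cascade order zero < alpha < onset < offset <
#' safety < danger < other, applied to the tied set.
#'
#' @param per_condition character vector of per-condition categories.
#' @return a single category string.
#' @export
modal_category <- function(per_condition) {
  tab <- table(factor(per_condition, levels = .unit_categories))
  names(tab)[which.max(tab)]       # which.max takes the first = cascade order
}

#' Sample entropy (Richman-Moorman)
#'
#' Negative log conditional probability that template subsequences of
#' length `m` matching within tolerance also match at length `m + 1`,
#' with Chebyshev distance and tolerance `r` times the series SD.
#' Self-matches are excluded. Conventions: a constant series (SD = 0)
#' has entropy 0; if no length-(m+1) matches exist the maximal defined
#' value -log(1/B) is returned (0 when B is also 0).
#'
#' @param x numeric series (length > m + 1).
#' @param m template length (2).
#' @param r tolerance as a fraction of the series SD (0.15).
#' @return nonnegative scalar entropy.
#' @export
sample_entropy <- function(x, m = 2, r = 0.15) {
  n <- length(x)
  if (n <= m + 1) stop("series too short for sample entropy")
  s <- stats::sd(x)
  if (s == 0) return(0)
  tol <- r * s
  # N - m templates of lengths m and m + 1 (the last length-m template
  # is dropped so both counts run over the same i); Chebyshev distance
  count_matches <- function(len) {
    n_tpl <- n - m
    # pairwise max over the template window via running maximum of
    # |x_i+k - x_j+k|
    d <- abs(outer(x[seq_len(n_tpl)], x[seq_len(n_tpl)], "-"))
    for (k in seq_len(len - 1)) {
      idx <- seq_len(n_tpl) + k
      d <- pmax(d, abs(outer(x[idx], x[idx], "-")))
    }
    sum(d <= tol) - n_tpl            # drop self-matches
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (B == 0) return(0)
  if (A == 0) return(-log(1 / B))
  -log(A / B)
}

#' Catalogue all hidden units of a trained model
#'
#' Applies [categorize_unit()] and [sample_entropy()] to every hidden
#' unit's activation trace under each stimulus condition, and derives
#' each unit's modal category.
#'
#' @param records named list of per-condition `activation_record`s from
#'   [record_condition_activations()].
#' @param times sample times of the traces.
#' @return object of class `unit_catalog`: data.frame with one row per
#'   (layer, unit), per-condition category and entropy columns, and
#'   `modal` category.
#' @export
build_unit_catalog <- function(records, times = trial_times(100)) {
  conds <- names(records)
  dims <- dim(records[[1]]$activations)   # layers x units x time
  rows <- expand.grid(unit = seq_len(dims[2]), layer = seq_len(dims[1]))
  cat_mat <- matrix(NA_character_, nrow(rows), length(conds),
                    dimnames = list(NULL, paste0("category_", conds)))
  ent_mat <- matrix(NA_real_, nrow(rows), length(conds),
                    dimnames = list(NULL, paste0("entropy_", conds)))
  for (ci in seq_along(conds)) {
    act <- records[[ci]]$activations
    for (k in seq_len(nrow(rows))) {
      tr <- act[rows$layer[k], rows$unit[k], ]
      cat_mat[k, ci] <- categorize_unit(tr, times)
      ent_mat[k, ci] <- sample_entropy(tr)
    }
  }
  modal <- apply(cat_mat, 1, modal_category)
  out <- data.frame(layer = rows$layer, unit = rows$unit,
                    cat_mat, ent_mat, modal = modal,
                    stringsAsFactors = FALSE)
  class(out) <- c("unit_catalog", "data.frame")
  out
}

#' Category counts per layer (taxonomy table)
#'
#' @param catalog a `unit_catalog`.
#' @return matrix categories x layers with a `Total` column.
#' @export
category_counts <- function(catalog) {
  tab <- table(factor(catalog$modal, levels = .unit_categories),
               factor(catalog$layer))
  cbind(tab, Total = rowSums(tab))
}

#' Summarise sample entropy across layers, conditions and categories
#'
#' @param catalog a `unit_catalog` from [build_unit_catalog()].
#' @return list with `zero_counts` (layers x conditions counts of
#'   zero-entropy units), `nonzero_mean` (layers x conditions mean
#'   entropy over nonzero-entropy units; NaN where a cell has none),
#'   `median_by_layer`, `median_by_condition`, and `by_category`
#'   (n / mean / sd of per-unit entropy, averaged over conditions first;
#'   NA mean for empty categories).
#' @export
summarize_entropy <- function(catalog) {
  ent_cols <- grep("^entropy_", names(catalog), value = TRUE)
  conds <- sub("^entropy_", "", ent_cols)
  layers <- sort(unique(catalog$layer))
  ent <- as.matrix(catalog[, ent_cols])
  zero_counts <- t(sapply(layers, function(l)
    colSums(ent[catalog$layer == l, , drop = FALSE] == 0)))
  nonzero_mean <- t(sapply(layers, function(l) {
    e <- ent[catalog$layer == l, , drop = FALSE]
    apply(e, 2, function(v) mean(v[v > 0]))
  }))
  dimnames(zero_counts) <- dimnames(nonzero_mean) <-
    list(paste0("layer", layers), conds)
  med_layer <- vapply(layers, function(l)
    stats::median(ent[catalog$layer == l, ]), 0.0)
  names(med_layer) <- paste0("layer", layers)
  med_cond <- apply(ent, 2, stats::median)
  names(med_cond) <- conds
  unit_ent <- rowMeans(ent)
  by_cat <- do.call(rbind, lapply(.unit_categories, function(cc) {
    v <- unit_ent[catalog$modal == cc]
    data.frame(category = cc, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else
                 if (length(v) == 1) 0 else NA_real_)
  }))
  list(zero_counts = zero_counts, nonzero_mean = nonzero_mean,
       median_by_layer = med_layer, median_by_condition = med_cond,
       by_category = by_cat)
}

#' Three principal-component views of hidden-unit activations
#'
#' (1) stimulus conditions x flattened (layer, unit, time) responses;
#' (2) layers x flattened (condition, unit, time) responses;
#' (3) per layer, units x flattened (condition, time) responses.
#' Each matrix is feature-mean-centred and projected onto its first two
#' principal components.
#'
#' @param records named list of per-condition `activation_record`s.
#' @return list with `conditions`, `layers` (each: list of `scores`,
#'   `explained` — fractions of variance of PC1 and PC2), and
#'   `units_by_layer` (one such list per layer).
#' @export
pca_views <- function(records) {
  conds <- names(records)
  dims <- dim(records[[1]]$activations)     # L x U x T
  L <- dims[1]; U <- dims[2]; Tn <- dims[3]
  acts <- lapply(records, `[[`, "activations")
  project <- function(M) {
    p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    ev <- p$sdev^2 / sum(p$sdev^2)
    k <- min(2, ncol(p$x))
    list(scores = p$x[, seq_len(k), drop = FALSE],
         explained = ev[seq_len(k)], input_dim = dim(M))
  }
  cond_mat <- t(sapply(acts, as.vector))                 # C x (L*U*T)
  layer_mat <- t(sapply(seq_len(L), function(l)
    as.vector(sapply(acts, function(a) a[l, , ]))))      # L x (C*U*T)
  unit_mats <- lapply(seq_len(L), function(l) {
    m <- sapply(acts, function(a) a[l, , ])              # (U*T) x C per cbind
    matrix(as.vector(m), nrow = U)                       # U x (T*C)
  })
  list(conditions = project(cond_mat),
       layers = project(layer_mat),
       units_by_layer = lapply(unit_mats, project))
}
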