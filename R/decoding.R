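#' Binary decoding contrasts of the oddball paradigms
#'
#' The eight pairwise classifications: within each paradigm (f = frequency,
#' i = intensity), standards vs. all deviants (SD), vs. increasing (SD1),
#' vs. decreasing deviants (SD2), and increasing vs. decreasing deviants
#' (D1D2).
#'
#' @param name one of `"fSD"`, `"fSD1"`, `"fSD2"`, `"fD1D2"`, `"iSD"`,
#'   `"iSD1"`, `"iSD2"`, `"iD1D2"`.
#' @return object of class `contrast`: list with `name`, `paradigm`,
#'   `class_a`, `class_b` (disjoint sets of condition labels).
#' @export
contrast_spec <- function(name) {
  all_names <- c("fSD", "fSD1", "fSD2", "fD1D2", "iSD", "iSD1", "iSD2", "iD1D2")
  name <- match.arg(name, all_names)
  pre <- substring(name, 1, 1)
  paradigm <- if (pre == "f") "frequency" else "intensity"
  body <- substring(name, 2)
  d1 <- paste0(pre, "D1"); d2 <- paste0(pre, "D2")
  sets <- switch(body,
                 SD    = list(a = "S", b = c(d1, d2)),
                 SD1   = list(a = "S", b = d1),
                 SD2   = list(a = "S", b = d2),
                 D1D2  = list(a = d1, b = d2))
  structure(list(name = name, paradigm = paradigm,
                 class_a = sets$a, class_b = sets$b),
            class = "contrast")
}

# Trials and class labels of one animal for one contrast.
contrast_trials <- function(trials, contrast) {
  stopifnot(inherits(trials, "epoched_trials"), inherits(contrast, "contrast"))
  keep_p <- trials$labels$paradigm == contrast$paradigm
  cond <- trials$labels$condition
  ia <- which(keep_p & cond %in% contrast$class_a)
  ib <- which(keep_p & cond %in% contrast$class_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both contrast classes must be non-empty")
  list(ia = ia, ib = ib)
}

# Stratified fold ids (1..folds) for a two-class index layout.
stratified_folds <- function(n_a, n_b, folds) {
  f_a <- rep_len(seq_len(folds), n_a)[sample.int(n_a)]
  f_b <- rep_len(seq_len(folds), n_b)[sample.int(n_b)]
  c(f_a, f_b)
}

# Fit a linear maximum-margin classifier and return a prediction closure.
# Features are standardised with training-fold statistics; prediction ties
# are broken toward class "a".
fit_linear_svm <- function(xtr, ytr) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(xs, ytr, kernel = "linear", cost = 1, scale = FALSE)
  function(xte) {
    xts <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    dv <- attr(stats::predict(fit, xts, decision.values = TRUE),
               "decision.values")
    sign_a <- if (colnames(dv) == "a/b") 1 else -1
    factor(ifelse(sign_a * dv[, 1] >= 0, "a", "b"), levels = c("a", "b"))
  }
}

# Core CV loop shared by time-wise and temporal-generalisation decoding.
# Returns accuracies averaged over folds x repeats: a vector over time, or
# a train-time x test-time matrix when `generalize = TRUE`.
decode_cv <- function(trials, contrast, folds, repeats, seed, generalize) {
  ct <- contrast_trials(trials, contrast)
  # canonical class order, so accuracy is invariant to swapping the two
  # class definitions (overall accuracy is label-symmetric; this also
  # aligns the RNG stream)
  if (paste(sort(contrast$class_b), collapse = "|") <
      paste(sort(contrast$class_a), collapse = "|"))
    ct <- list(ia = ct$ib, ib = ct$ia)
  n_t <- length(trials$times)
  acc <- if (generalize) matrix(0, n_t, n_t) else numeric(n_t)
  n_cell <- 0L
  for (rep_i in seq_len(repeats)) {
    rs <- derive_seed(seed, rep_i)
    sel <- with_seed(rs, {
      n <- min(length(ct$ia), length(ct$ib))
      ia <- if (length(ct$ia) > n) sample(ct$ia, n) else ct$ia
      ib <- if (length(ct$ib) > n) sample(ct$ib, n) else ct$ib
      if (n < folds) stop("each class needs at least `folds` trials")
      list(ia = ia, ib = ib, fold = stratified_folds(n, n, folds))
    })
    idx <- c(sel$ia, sel$ib)
    y <- factor(rep(c("a", "b"), c(length(sel$ia), length(sel$ib))),
                levels = c("a", "b"))
    for (k in seq_len(folds)) {
      tr <- sel$fold != k
      te <- !tr
      for (t_i in seq_len(n_t)) {
        xtr <- trials$data[idx[tr], , t_i, drop = TRUE]
        if (is.null(dim(xtr))) xtr <- matrix(xtr, ncol = 1)
        pred <- fit_linear_svm(xtr, y[tr])
        if (generalize) {
          nte <- sum(te)
          xte_all <- matrix(aperm(trials$data[idx[te], , , drop = FALSE],
                                  c(1, 3, 2)), ncol = dim(trials$data)[2])
          p <- pred(xte_all)
          hits <- matrix(p == rep(y[te], n_t), nte, n_t)
          acc[t_i, ] <- acc[t_i, ] + colMeans(hits)
        } else {
          xte <- trials$data[idx[te], , t_i, drop = TRUE]
          if (is.null(dim(xte))) xte <- matrix(xte, ncol = 1)
          acc[t_i] <- acc[t_i] + mean(pred(xte) == y[te])
        }
      }
    }
    n_cell <- n_cell + folds
  }
  acc / n_cell
}

#' Time-wise decoding for one animal
#'
#' Linear support-vector classification of stimulus condition from the
#' channel amplitudes at each time point. Per repeat, the larger class is
#' randomly under-sampled to equality and stratified k-fold
#' cross-validation is run; features are standardised per fold with
#' training statistics; reported accuracy is the mean over all folds and
#' repeats.
#'
#' @param trials preprocessed [epoched_trials()] of one animal.
#' @param contrast a [contrast_spec()] (or contrast name).
#' @param folds,repeats cross-validation folds (10) and repeats (5).
#' @param seed integer seed controlling under-sampling and fold
#'   allocation.
#' @return numeric accuracy vector over time (attributes `times`,
#'   `contrast`).
#' @export
timewise_decode <- function(trials, contrast, folds = 10, repeats = 5,
                            seed = 1) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  acc <- decode_cv(trials, contrast, folds, repeats, seed, generalize = FALSE)
  structure(acc, times = trials$times, contrast = contrast$name)
}

#' Temporal-generalisation decoding for one animal
#'
#' Same cross-validation structure as [timewise_decode()], but each
#' classifier trained at time t is evaluated on the held-out trials at
#' every time t', yielding a train-time x test-time accuracy matrix whose
#' diagonal approximates the time-wise map.
#'
#' @inheritParams timewise_decode
#' @return accuracy matrix (train time x test time) with attributes
#'   `times` and `contrast`.
#' @export
temporal_generalization <- function(trials, contrast, folds = 10,
                                    repeats = 5, seed = 1) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  acc <- decode_cv(trials, contrast, folds, repeats, seed, generalize = TRUE)
  structure(acc, times = trials$times, contrast = contrast$name)
}

#' Group decoding map over a cohort
#'
#' Runs per-animal decoding with independent, reproducible child seeds
#' and stacks the results into an animals x time matrix (or animals x
#' train x test array for temporal generalisation).
#'
#' @param cohort a balanced, preprocessed `synthetic_cohort`.
#' @param contrast a [contrast_spec()] or contrast name.
#' @param folds,repeats cross-validation settings.
#' @param seed master seed; animal a, repeat r uses a child seed derived
#'   from (seed, contrast, a, r).
#' @param generalize logical; temporal-generalisation instead of
#'   time-wise decoding.
#' @param permute_labels logical; randomly permute class labels within
#'   each animal before decoding (chance-level calibration).
#' @return matrix animals x time in \[0, 1\] (class `decoding_map`), or an
#'   animals x train x test array when `generalize = TRUE`.
#' @export
group_decode <- function(cohort, contrast, folds = 10, repeats = 5,
                         seed = 1, generalize = FALSE,
                         permute_labels = FALSE) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  c_idx <- match(contrast$name,
                 c("fSD", "fSD1", "fSD2", "fD1D2", "iSD", "iSD1", "iSD2", "iD1D2"))
  maps <- lapply(seq_along(cohort$animals), function(a) {
    tr <- merge_paradigm_trials(cohort, a)
    if (permute_labels) {
      tr$labels$condition <- with_seed(derive_seed(seed, 999, c_idx, a),
                                       sample(tr$labels$condition))
    }
    s <- derive_seed(seed, c_idx, a)
    if (generalize) temporal_generalization(tr, contrast, folds, repeats, s)
    else timewise_decode(tr, contrast, folds, repeats, s)
  })
  if (generalize) {
    out <- array(NA_real_, c(length(maps), dim(maps[[1]])))
    for (a in seq_along(maps)) out[a, , ] <- maps[[a]]
  } else {
    out <- do.call(rbind, maps)
  }
  structure(out, times = cohort$animals[[1]][[1]]$trials$times,
            contrast = contrast$name, class = c("decoding_map", class(out)))
}

# Concatenate one animal's two paradigm trial sets into one container.
merge_paradigm_trials <- function(cohort, animal) {
  an <- cohort$animals[[animal]]
  t1 <- an[[1]]$trials; t2 <- an[[2]]$trials
  d <- array(NA_real_, c(dim(t1$data)[1] + dim(t2$data)[1],
                         dim(t1$data)[2], dim(t1$data)[3]))
  d[seq_len(dim(t1$data)[1]), , ] <- t1$data
  d[-seq_len(dim(t1$data)[1]), , ] <- t2$data
  epoched_trials(d, t1$rate, t1$times, rbind(t1$labels, t2$labels))
}
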