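#' Band-pass filter epoched trials
#'
#' Zero-phase forward-backward (filtfilt) 4th-order Butterworth band-pass,
#' applied per trial and channel at the trials' own sampling rate.
#'
#' @param trials an [epoched_trials()] object.
#' @param low,high band edges in Hz (defaults 0.1 and 30).
#' @return filtered `epoched_trials`.
#' @export
bandpass_filter <- function(trials, low = 0.1, high = 30) {
  stopifnot(inherits(trials, "epoched_trials"))
  if (trials$rate <= 2 * high)
    stop("sampling rate must exceed twice the upper band edge")
  bf <- signal::butter(4, c(low, high) / (trials$rate / 2), type = "pass")
  d <- trials$data
  dm <- dim(d)
  for (i in seq_len(dm[1]))
    for (ch in seq_len(dm[2]))
      d[i, ch, ] <- signal::filtfilt(bf, d[i, ch, ])
  trials$data <- d
  trials
}

#' Baseline-correct epoched trials
#'
#' Subtracts, per trial and channel, the mean amplitude over the 0.1 s
#' pre-first-stimulus window (samples with t < 0) from the whole trial.
#'
#' @param trials an [epoched_trials()] object whose window includes
#'   \[-0.1, 0).
#' @return baseline-corrected `epoched_trials`.
#' @export
baseline_correct <- function(trials) {
  stopifnot(inherits(trials, "epoched_trials"))
  pre <- trials$times < 0
  if (!any(pre)) stop("window must include the pre-stimulus period")
  d <- trials$data
  base <- apply(d[, , pre, drop = FALSE], c(1, 2), mean)
  trials$data <- d - as.vector(base)   # recycles over the time dimension
  trials
}

#' Resample epoched trials to a lower rate
#'
#' Maps the output grid t = -0.1 + k/rate (k = 0..) onto the native grid
#' by index, taking every (native/target)-th sample. For the standard
#' -0.1..1.0 s window at 100 Hz this yields 111 samples; a native trial
#' missing the final endpoint sample reuses its last sample (off-by-one
#' tolerance of the window convention).
#'
#' @param trials an [epoched_trials()] object.
#' @param rate target rate in Hz; the native rate must be an integer
#'   multiple of it.
#' @return resampled `epoched_trials`.
#' @export
resample_to <- function(trials, rate = 100) {
  stopifnot(inherits(trials, "epoched_trials"))
  ratio <- trials$rate / rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("native rate must be an integer multiple of the target rate")
  ratio <- round(ratio)
  n <- dim(trials$data)[3]
  out_times <- trial_times(rate, trials$times[1],
                           trials$times[length(trials$times)])
  idx <- pmin(1 + round((out_times - trials$times[1]) * trials$rate), n)
  trials$data <- trials$data[, , idx, drop = FALSE]
  trials$times <- out_times
  trials$rate <- rate
  trials
}

#' Keep only standards that immediately precede a deviant
#'
#' Balances the trial counts of one animal-paradigm recording: of the 800
#' standards only the 200 that directly precede a deviant are retained;
#' deviant trials are untouched.
#'
#' @param sequence the [generate_oddball_sequence()] the trials realise.
#' @param trials the matching [epoched_trials()] (one trial per stimulus,
#'   in sequence order).
#' @return `epoched_trials` restricted to retained standards + deviants.
#' @export
select_balanced_standards <- function(sequence, trials) {
  stopifnot(inherits(trials, "epoched_trials"))
  lab <- as.character(sequence)
  if (length(lab) != dim(trials$data)[1] ||
      !identical(lab, trials$labels$label))
    stop("sequence and trial labels are misaligned")
  keep <- sort(c(standards_before_deviants(sequence), which(lab != "S")))
  trials$data <- trials$data[keep, , , drop = FALSE]
  trials$labels <- trials$labels[keep, , drop = FALSE]
  rownames(trials$labels) <- NULL
  trials
}

#' Standard preprocessing chain for one recording
#'
#' Filter (0.1-30 Hz) -> baseline-correct -> resample to 100 Hz, in the
#' order the epoched signals are treated throughout the pipeline.
#'
#' @param trials an [epoched_trials()] object at the native rate.
#' @param rate target rate in Hz.
#' @param low,high band-pass edges in Hz.
#' @return preprocessed `epoched_trials`.
#' @export
preprocess_trials <- function(trials, rate = 100, low = 0.1, high = 30) {
  resample_to(baseline_correct(bandpass_filter(trials, low, high)), rate)
}

#' Simulate, balance and preprocess a synthetic cohort
#'
#' The main entry point for downstream analyses: for every animal and
#' paradigm it simulates the full oddball sequence, retains the balanced
#' trial set (200 standards preceding deviants + 100 D1 + 100 D2) and
#' applies the preprocessing chain, keeping memory bounded by processing
#' one animal-paradigm at a time.
#'
#' @param config a [cohort_config()].
#' @param rate target rate in Hz after preprocessing.
#' @return object of class `synthetic_cohort` whose per-animal entries
#'   hold balanced, preprocessed [epoched_trials()] and the realised
#'   sequences.
#' @export
build_synthetic_dataset <- function(config = cohort_config(), rate = 100) {
  animals <- lapply(seq_len(config$n_animals), function(a) {
    out <- lapply(.paradigms, function(p) {
      sim <- simulate_animal_paradigm(config, a, p)
      bal <- select_balanced_standards(sim$sequence, sim$trials)
      list(trials = preprocess_trials(bal, rate), sequence = sim$sequence)
    })
    names(out) <- .paradigms
    out
  })
  structure(list(animals = animals, config = config),
            class = "synthetic_cohort")
}

#' Assemble the idealised-experiment training set
#'
#' Averages corresponding trials across animals (pairing by
#' within-condition occurrence order) and across channels, producing the
#' low-noise trial set used to train the recurrent network: per paradigm
#' 200 standards + 100 increasing + 100 decreasing deviants, 800 trials
#' in total with default counts. Inputs are attached per condition as
#' cochleagrams of the condition's two-tone stimulus.
#'
#' @param cohort a balanced, preprocessed `synthetic_cohort` from
#'   [build_synthetic_dataset()].
#' @param inputs named list of per-condition [cochleagram()]s (computed
#'   if omitted).
#' @return object of class `idealized_dataset`: list with `targets`
#'   (trials x time matrix), `labels` (condition/paradigm/label per
#'   trial), `inputs` (5 cochleagrams), `times`, `rate`.
#' @export
build_idealized_dataset <- function(cohort, inputs = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  first <- cohort$animals[[1]]
  targets <- NULL
  labels <- NULL
  for (p in .paradigms) {
    conds <- unique(paradigm_condition(c("S", "D1", "D2"), p))
    for (cc in conds) {
      # pair across animals by within-condition occurrence order
      per_animal <- lapply(cohort$animals, function(an) {
        tr <- an[[p]]$trials
        idx <- which(tr$labels$condition == cc)
        apply(tr$data[idx, , , drop = FALSE], c(1, 3), mean)  # channel mean
      })
      n_occ <- unique(vapply(per_animal, nrow, 0L))
      if (length(n_occ) != 1L)
        stop("animals contribute unequal balanced trial structures")
      avg <- Reduce(`+`, per_animal) / length(per_animal)
      targets <- rbind(targets, avg)
      labels <- rbind(labels,
                      data.frame(paradigm = p,
                                 label = if (cc == "S") "S"
                                         else substring(cc, 2),
                                 condition = cc,
                                 occurrence = seq_len(n_occ),
                                 stringsAsFactors = FALSE))
    }
  }
  rownames(labels) <- NULL
  if (is.null(inputs)) inputs <- condition_cochleagrams()
  structure(list(targets = unname(targets), labels = labels, inputs = inputs,
                 times = first[[1]]$trials$times, rate = first[[1]]$trials$rate),
            class = "idealized_dataset")
}

#' @export
print.idealized_dataset <- function(x, ...) {
  cat(sprintf("<idealized_dataset> %d trials x %d samples at %g Hz\n",
              nrow(x$targets), ncol(x$targets), x$rate))
  print(table(x$labels$condition))
  invisible(x)
}

#' Grand-average waveforms per stimulus condition
#'
#' Per-condition mean over trials; standards are pooled across the two
#' paradigms, giving one S waveform and five waveforms in total.
#'
#' @param dataset an `idealized_dataset`.
#' @return matrix 5 x time with rownames S, fD1, fD2, iD1, iD2.
#' @export
grand_average <- function(dataset) {
  stopifnot(inherits(dataset, "idealized_dataset"))
  conds <- .condition_levels
  ga <- t(sapply(conds, function(cc)
    colMeans(dataset$targets[dataset$labels$condition == cc, , drop = FALSE])))
  rownames(ga) <- conds
  ga
}
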