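#' Epoched trial container
#'
#' @param data numeric array, trials x channels x time.
#' @param rate sampling rate in Hz.
#' @param times sample times in seconds, one per time sample of `data`.
#' @param labels data frame with one row per trial; must contain columns
#'   `animal`, `paradigm`, `label` (S/D1/D2), `condition` (S/fD1/fD2/iD1/iD2)
#'   and `seq_index`.
#' @return an object of class `epoched_trials`.
#' @export
epoched_trials <- function(data, rate, times = trial_times(rate), labels) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[3] != length(times))
    stop("time axis length mismatch")
  if (nrow(labels) != dim(data)[1])
    stop("labels must have one row per trial")
  need <- c("animal", "paradigm", "label", "condition", "seq_index")
  if (!all(need %in% names(labels)))
    stop("labels must contain columns: ", paste(need, collapse = ", "))
  structure(list(data = data, rate = rate, times = times,
                 labels = as.data.frame(labels)),
            class = "epoched_trials")
}

#' @export
print.epoched_trials <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_trials> %d trials x %d channels x %d samples at %g Hz\n",
              d[1], d[2], d[3], x$rate))
  print(table(x$labels$condition))
  invisible(x)
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions: 14 animals, 2 epidural
#' channels over left/right auditory cortex, signals at 1000 Hz native
#' rate, oddball sequences of 800 standards + 100 increasing + 100
#' decreasing deviants per paradigm.
#'
#' @param n_animals number of animals (>= 2).
#' @param n_channels number of recording channels.
#' @param native_rate recording rate in Hz.
#' @param trial_noise_sd SD of white trial noise at the native rate
#'   (amplitude units; band-limited later by the 0.1-30 Hz filter).
#' @param animal_effect_sd SD of the per-animal multiplicative gain
#'   applied to each response component (mean 1).
#' @param alpha_amplitude amplitude of the ~10 Hz background rhythm
#'   (0.2 of the onset-component peak by default); phase is randomised
#'   per trial.
#' @param alpha_freq background rhythm frequency in Hz.
#' @param channel_gains per-channel signal gain.
#' @param n_s,n_d1,n_d2 per-paradigm stimulus counts.
#' @param component_specs component list, see [default_component_specs()].
#' @param seed master integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_animals = 14, n_channels = 2, native_rate = 1000,
                          trial_noise_sd = 1.0, animal_effect_sd = 0.1,
                          alpha_amplitude = 0.2, alpha_freq = 10,
                          channel_gains = c(1, 0.95),
                          n_s = 800, n_d1 = 100, n_d2 = 100,
                          component_specs = default_component_specs(),
                          seed = 1) {
  if (n_animals < 2) stop("group statistics need at least 2 animals")
  if (trial_noise_sd < 0 || animal_effect_sd < 0 || alpha_amplitude < 0)
    stop("noise parameters must be nonnegative")
  if (length(channel_gains) != n_channels)
    stop("`channel_gains` must have one entry per channel")
  structure(list(n_animals = n_animals, n_channels = n_channels,
                 native_rate = native_rate, trial_noise_sd = trial_noise_sd,
                 animal_effect_sd = animal_effect_sd,
                 alpha_amplitude = alpha_amplitude, alpha_freq = alpha_freq,
                 channel_gains = channel_gains,
                 n_s = n_s, n_d1 = n_d1, n_d2 = n_d2,
                 component_specs = component_specs, seed = seed),
            class = "cohort_config")
}

.paradigms <- c("frequency", "intensity")

# Map within-paradigm labels (S/D1/D2) to global stimulus conditions.
paradigm_condition <- function(label, paradigm) {
  pre <- if (paradigm == "frequency") "f" else "i"
  ifelse(label == "S", "S", paste0(pre, label))
}

# Per-animal multiplicative gain for each response component.
animal_component_gains <- function(config, animal) {
  specs <- config$component_specs
  g <- with_seed(derive_seed(config$seed, 77, animal),
                 stats::rnorm(length(specs), 1, config$animal_effect_sd))
  names(g) <- vapply(specs, `[[`, "", "name")
  g
}

#' Simulate one animal's epoched trials for one paradigm
#'
#' Each stimulus of the oddball sequence is realised as a two-response
#' epoch (-0.1..1.0 s at the native rate): the condition's noise-free
#' template scaled by the animal's per-component gains, plus a shared
#' ~10 Hz background oscillation with per-trial random phase, plus white
#' channel noise. Everything is deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @param animal animal index (1-based).
#' @param paradigm `"frequency"` or `"intensity"`.
#' @return list with elements `trials` (an [epoched_trials()] object) and
#'   `sequence` (the realised [generate_oddball_sequence()]).
#' @export
simulate_animal_paradigm <- function(config, animal,
                                     paradigm = c("frequency", "intensity")) {
  paradigm <- match.arg(paradigm)
  p_idx <- match(paradigm, .paradigms)
  sq <- generate_oddball_sequence(config$n_s, config$n_d1, config$n_d2,
                                  paradigm = paradigm,
                                  seed = derive_seed(config$seed, 11, animal, p_idx))
  lab <- as.character(sq)
  cond <- paradigm_condition(lab, paradigm)
  times <- trial_times(config$native_rate)
  nt <- length(times)
  n_trial <- length(lab)
  gains <- animal_component_gains(config, animal)
  templ <- sapply(unique(cond), function(cc)
    erp_template(cc, config$component_specs, config$native_rate,
                 component_gains = gains))
  data <- with_seed(derive_seed(config$seed, 23, animal, p_idx), {
    phases <- stats::runif(n_trial, 0, 2 * pi)
    arr <- array(stats::rnorm(n_trial * config$n_channels * nt,
                              sd = config$trial_noise_sd),
                 dim = c(n_trial, config$n_channels, nt))
    for (i in seq_len(n_trial)) {
      sig <- templ[, cond[i]] +
        config$alpha_amplitude * sin(2 * pi * config$alpha_freq * times + phases[i])
      for (ch in seq_len(config$n_channels))
        arr[i, ch, ] <- arr[i, ch, ] + config$channel_gains[ch] * sig
    }
    arr
  })
  labels <- data.frame(animal = animal, paradigm = paradigm, label = lab,
                       condition = cond, seq_index = seq_len(n_trial),
                       stringsAsFactors = FALSE)
  list(trials = epoched_trials(data, config$native_rate, times, labels),
       sequence = sq)
}

#' Simulate a full synthetic cohort
#'
#' Runs [simulate_animal_paradigm()] for every animal and both oddball
#' paradigms. With default counts this realises 1000 stimuli per
#' animal-paradigm; the result is large, so downstream drivers usually
#' prefer [build_synthetic_dataset()], which balances and preprocesses
#' animal by animal.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `animals` (per
#'   animal, per paradigm, the result of [simulate_animal_paradigm()])
#'   and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  animals <- lapply(seq_len(config$n_animals), function(a) {
    out <- lapply(.paradigms, function(p) simulate_animal_paradigm(config, a, p))
    names(out) <- .paradigms
    out
  })
  structure(list(animals = animals, config = config),
            class = "synthetic_cohort")
}
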