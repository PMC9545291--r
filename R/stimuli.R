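#' Pure-tone stimulus specification
#'
#' Describes one monophonic pure tone of the oddball paradigms. The
#' standard stimulus of both paradigms is 10 kHz, 80 dB SPL, 100 ms;
#' frequency deviants move +/-2.5 kHz and intensity deviants +/-10 dB
#' around it.
#'
#' @param frequency_khz tone frequency in kHz; must lie in (0, 50].
#' @param level_db sound level in dB SPL (finite).
#' @param duration_ms tone duration in ms (> 0).
#' @param onset_s tone onset in seconds relative to trial zero.
#' @return an object of class `tone_spec`.
#' @examples
#' tone_spec()                      # the standard tone
#' tone_spec(frequency_khz = 12.5)  # ascending frequency deviant
#' @export
tone_spec <- function(frequency_khz = 10, level_db = 80, duration_ms = 100,
                      onset_s = 0) {
  stopifnot(is.numeric(frequency_khz), length(frequency_khz) == 1L,
            is.numeric(level_db), length(level_db) == 1L,
            is.numeric(duration_ms), length(duration_ms) == 1L,
            is.numeric(onset_s), length(onset_s) == 1L)
  if (!is.finite(frequency_khz) || frequency_khz <= 0 || frequency_khz > 50)
    stop("`frequency_khz` must lie in (0, 50]")
  if (!is.finite(level_db)) stop("`level_db` must be finite")
  if (!is.finite(duration_ms) || duration_ms <= 0)
    stop("`duration_ms` must be > 0")
  structure(list(frequency_khz = frequency_khz, level_db = level_db,
                 duration_ms = duration_ms, onset_s = onset_s),
            class = "tone_spec")
}

#' @export
print.tone_spec <- function(x, ...) {
  cat(sprintf("<tone_spec> %.4g kHz, %g dB SPL, %g ms, onset %g s\n",
              x$frequency_khz, x$level_db, x$duration_ms, x$onset_s))
  invisible(x)
}

#' Convert a sound level to linear peak amplitude
#'
#' Amplitudes are normalised so that an 80 dB SPL tone has peak amplitude
#' 1; every 20 dB changes amplitude by a factor of 10.
#'
#' @param level_db sound level(s) in dB SPL.
#' @return linear peak amplitude(s), strictly increasing in `level_db`.
#' @examples
#' amplitude_from_level(c(60, 80, 100))  # 0.1, 1, 10
#' @export
amplitude_from_level <- function(level_db) {
  if (!is.numeric(level_db) || any(!is.finite(level_db)))
    stop("`level_db` must be finite")
  10^((level_db - 80) / 20)
}

#' Synthesise a pure tone on a fixed time axis
#'
#' Zero-phase sine at the specified frequency, scaled by
#' [amplitude_from_level()], placed at its onset within the supplied time
#' axis; zero elsewhere. No onset/offset ramps are applied.
#'
#' @param spec a [tone_spec()].
#' @param fs sampling frequency in Hz; must exceed twice the tone frequency.
#' @param times sample times in seconds (defaults to the standard trial
#'   window -0.1..1.0 s, inclusive).
#' @return numeric waveform, one sample per entry of `times`.
#' @export
synthesize_tone <- function(spec, fs = 100000,
                            times = trial_times(fs)) {
  stopifnot(inherits(spec, "tone_spec"))
  f_hz <- spec$frequency_khz * 1000
  if (fs < 2 * f_hz)
    stop("aliasing: tone frequency must be below fs/2")
  amp <- amplitude_from_level(spec$level_db)
  t0 <- spec$onset_s
  t1 <- spec$onset_s + spec$duration_ms / 1000
  w <- numeric(length(times))
  on <- times >= round_t(t0) & times < round_t(t1)
  w[on] <- amp * sin(2 * pi * f_hz * (times[on] - t0))
  w
}

.condition_levels <- c("S", "fD1", "fD2", "iD1", "iD2")

# First-tone specification per stimulus condition; the second tone of
# every trial is the standard.
condition_first_tone <- function(condition) {
  switch(condition,
         S   = tone_spec(),
         fD1 = tone_spec(frequency_khz = 12.5),
         fD2 = tone_spec(frequency_khz = 7.5),
         iD1 = tone_spec(level_db = 90),
         iD2 = tone_spec(level_db = 70),
         stop("unknown condition: ", condition))
}

#' Build one two-tone trial waveform
#'
#' Every trial of the oddball paradigms contains the condition's first
#' tone at 0 s followed, after a 450 ms offset-to-onset gap, by the
#' standard tone (10 kHz, 80 dB, 100 ms) at 0.55 s. The window spans
#' -0.1 to 1.0 s at 100 kHz (110 001 samples, endpoints included).
#'
#' @param condition one of `"S"`, `"fD1"`, `"fD2"`, `"iD1"`, `"iD2"`, or a
#'   [tone_spec()] to use as the first tone.
#' @param fs sampling frequency in Hz.
#' @param second_tone logical; include the trailing standard tone
#'   (disable for single-tone probe stimuli).
#' @return an object of class `trial_audio` with fields `waveform`,
#'   `times`, `fs` and `condition`.
#' @export
build_trial_audio <- function(condition = "S", fs = 100000,
                              second_tone = TRUE) {
  if (inherits(condition, "tone_spec")) {
    first <- condition
    cond_name <- "custom"
  } else {
    condition <- match.arg(condition, .condition_levels)
    first <- condition_first_tone(condition)
    cond_name <- condition
  }
  if (first$onset_s != 0) stop("first tone onset must be 0 s")
  times <- trial_times(fs)
  w <- synthesize_tone(first, fs, times)
  if (second_tone) {
    std2 <- tone_spec(onset_s = first$onset_s + first$duration_ms / 1000 + 0.45)
    w <- w + synthesize_tone(std2, fs, times)
  }
  structure(list(waveform = w, times = times, fs = fs,
                 condition = cond_name),
            class = "trial_audio")
}

#' @export
print.trial_audio <- function(x, ...) {
  cat(sprintf("<trial_audio> condition %s, %d samples at %g kHz, %g..%g s\n",
              x$condition, length(x$waveform), x$fs / 1000,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Cochleagram: STFT magnitude representation of a trial
#'
#' Short-time Fourier transform on Hann-windowed segments of 200 samples
#' with 100-sample overlap at 100 kHz, giving 101 one-sided frequency
#' bins from 0 to 50 kHz with 0.5 kHz spacing. The resulting 1000 Hz
#' frame sequence is down-sampled to 100 Hz by subsampling every 10th
#' frame, with frame centres aligned to the trial grid -0.1, -0.09, ...,
#' 1.0 s, yielding 111 frames for the standard window. Segments
#' overrunning the waveform are zero-padded. Magnitudes carry no
#' normalisation constant.
#'
#' @param audio a `trial_audio` object sampled at 100 kHz.
#' @param window_len,hop STFT segment length and hop in samples at the
#'   audio rate.
#' @param frame_rate output frame rate in Hz.
#' @return an object of class `cochleagram`: a nonnegative 101 x 111
#'   matrix with attributes `bin_khz` and `frame_times`.
#' @export
cochleagram <- function(audio, window_len = 200, hop = 100,
                        frame_rate = 100) {
  stopifnot(inherits(audio, "trial_audio"))
  if (audio$fs != 100000)
    stop("cochleagram requires audio sampled at 100 kHz")
  w <- audio$waveform
  n <- length(w)
  n_bins <- window_len / 2 + 1
  frame_times <- trial_times(frame_rate)
  # centre sample (1-based) of each output frame on the audio grid
  centres <- 1 + round((frame_times - audio$times[1]) * audio$fs)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(window_len - 1)) / window_len)
  seg <- matrix(0, window_len, length(centres))
  offs <- -(window_len / 2):(window_len / 2 - 1)
  for (j in seq_along(centres)) {
    idx <- centres[j] + offs
    ok <- idx >= 1 & idx <= n
    seg[ok, j] <- w[idx[ok]]
  }
  spec <- Mod(stats::mvfft(seg * hann))[seq_len(n_bins), , drop = FALSE]
  structure(spec,
            bin_khz = (seq_len(n_bins) - 1) * (audio$fs / window_len) / 1000,
            frame_times = frame_times,
            class = c("cochleagram", "matrix"))
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("<cochleagram> %d bins x %d frames, bins 0..%g kHz\n",
              nrow(x), ncol(x), max(attr(x, "bin_khz"))))
  invisible(x)
}

#' Cochleagrams for the five stimulus conditions
#'
#' @param fs audio sampling frequency in Hz.
#' @return named list of `cochleagram` objects for S, fD1, fD2, iD1, iD2.
#' @export
condition_cochleagrams <- function(fs = 100000) {
  out <- lapply(.condition_levels,
                function(cc) cochleagram(build_trial_audio(cc, fs = fs)))
  names(out) <- .condition_levels
  out
}
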