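#' Default evoked-response component specifications
#'
#' The synthetic evoked response is a sum of Gaussian bumps (latency =
#' mean, width = SD) plus a 10 Hz background rhythm added at simulation
#' time. Components and default morphology:
#'
#' * onset negativity 30 ms after each tone onset, gain increasing with
#'   tone level and modulated by tone frequency;
#' * offset positivity 30 ms after each tone offset, same modulation;
#' * long-latency positive ("danger") bump at 0.38 s for the salient
#'   first-tone changes fD1, fD2 and iD1;
#' * late positive bump at 0.88 s on iD2 trials, where the 80 dB standard
#'   after a 70 dB deviant is a rising sound-level transition;
#' * subtle negative ("safety") deflection centred at 0.70 s following
#'   the falling-salience return to standard on fD2 and iD1 trials.
#'
#' Gains are unitless multiples of `base_amplitude` (arbitrary amplitude
#' units); each spec carries a gain for all five conditions.
#'
#' @return list of component specs (class `erp_component_spec` each).
#' @export
default_component_specs <- function() {
  lv <- function(db) 1 + 0.05 * (db - 80)          # level modulation, monotone
  fq <- function(khz) 1 + 0.12 * (khz - 10)        # frequency modulation
  g1 <- c(S = 1, fD1 = fq(12.5), fD2 = fq(7.5), iD1 = lv(90), iD2 = lv(70))
  g2 <- c(S = 1, fD1 = 1, fD2 = 1, iD1 = 1, iD2 = 1)  # second tone = standard
  comp <- function(name, latency, width, base, gains) {
    structure(list(name = name, latency = latency, width = width,
                   base_amplitude = base, modulation = gains),
              class = "erp_component_spec")
  }
  list(
    comp("onset1",  0.03, 0.012, -1.0, g1),
    comp("offset1", 0.13, 0.012,  0.8, g1),
    comp("onset2",  0.58, 0.012, -1.0, g2),
    comp("offset2", 0.68, 0.012,  0.8, g2),
    comp("long_latency_positive", 0.38, 0.070, 0.6,
         c(S = 0, fD1 = 1, fD2 = 1, iD1 = 1, iD2 = 0)),
    comp("long_latency_positive_late", 0.88, 0.070, 0.5,
         c(S = 0, fD1 = 0, fD2 = 0, iD1 = 0, iD2 = 1)),
    comp("long_latency_negative", 0.70, 0.060, -0.25,
         c(S = 0, fD1 = 0, fD2 = 1, iD1 = 1, iD2 = 0))
  )
}

#' Noise-free evoked-response template for one condition
#'
#' @param condition one of `"S"`, `"fD1"`, `"fD2"`, `"iD1"`, `"iD2"`.
#' @param specs component list as from [default_component_specs()].
#' @param rate sampling rate in Hz.
#' @param component_gains optional named numeric vector of per-component
#'   multipliers (by component name), e.g. to scale or silence a
#'   component.
#' @return numeric waveform over -0.1..1.0 s (inclusive endpoints).
#' @export
erp_template <- function(condition, specs = default_component_specs(),
                         rate = 1000, component_gains = NULL) {
  condition <- match.arg(condition, .condition_levels)
  times <- trial_times(rate)
  w <- numeric(length(times))
  for (sp in specs) {
    g <- sp$modulation[[condition]]
    if (!is.null(component_gains) && sp$name %in% names(component_gains))
      g <- g * component_gains[[sp$name]]
    if (g == 0) next
    w <- w + sp$base_amplitude * g *
      exp(-0.5 * ((times - sp$latency) / sp$width)^2)
  }
  w
}
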