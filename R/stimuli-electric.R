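#' Biphasic electric pulse train
#'
#' Timed biphasic (cathodic-first) pulses with per-pulse current amplitudes,
#' as delivered by a single cochlear-implant electrode. Only the first-phase
#' onset times and amplitudes matter to the fiber model; the pulse shape
#' enters through the 100-us phase duration.
#'
#' @param pulse_times First-phase onset times (s), strictly increasing.
#' @param amplitudes Per-pulse current amplitudes (uA), non-negative.
#' @param phase_duration Phase duration (us).
#' @param carrier_rate Carrier pulse rate (pps).
#' @param f_m Modulation frequency (Hz) or `NA` for unmodulated trains.
#' @param level Level in dB re the reference threshold current.
#' @param duration Train duration (s).
#' @return An `electric_pulse_train` object.
#' @export
electric_pulse_train <- function(pulse_times, amplitudes, phase_duration = 100,
                                 carrier_rate, f_m = NA_real_, level = 0,
                                 duration) {
  stopifnot(
    length(pulse_times) == length(amplitudes),
    all(diff(pulse_times) > 0), all(amplitudes >= 0)
  )
  structure(
    list(
      pulse_times = pulse_times, amplitudes = amplitudes,
      phase_duration = phase_duration, polarity = "cathodic_first",
      carrier_rate = carrier_rate, f_m = f_m, level = level,
      duration = duration
    ),
    class = "electric_pulse_train"
  )
}

#' @export
print.electric_pulse_train <- function(x, ...) {
  cat(sprintf(
    "<electric_pulse_train: %g pps%s, %g dB thr, %d pulses, %.3g s>\n",
    x$carrier_rate,
    if (is.na(x$f_m)) " (unmodulated)" else sprintf(" SAM %g Hz", x$f_m),
    x$level, length(x$pulse_times), x$duration
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.electric_pulse_train <- function(x, ...) {
  tibble(pulse_time = x$pulse_times, amplitude = x$amplitudes)
}

#' Generate an electric pulse train
#'
#' Unmodulated or sinusoidally amplitude-modulated (SAM) biphasic pulse
#' trains. Pulses occur at `(k + 1/2) / carrier_rate` (so a 40-pps, 600-ms
#' train has 24 pulses, all clear of the gating ramps). For SAM trains the raised-
#' cosine envelope `(1 - cos(2 pi f_m t)) / 2` is sampled at each pulse time;
#' `f_m` may not exceed 40 % of the carrier rate. Amplitudes are
#' `reference_current * 10^(level/20)` times the envelope, with a 10-ms sin^2
#' amplitude gate at onset and offset (the gate scales pulse amplitudes; the
#' pulse shape itself is not windowed).
#'
#' @param carrier_rate Pulse rate (pps).
#' @param duration Duration (s); 600 ms by default.
#' @param level Level in dB re the reference threshold current.
#' @param f_m Modulation frequency (Hz), or `NA` for unmodulated trains.
#' @param reference_current Reference threshold current (uA); see
#'   [find_reference_threshold()].
#' @param ramp sin^2 amplitude-gating ramp (s).
#' @return An [electric_pulse_train()].
#' @export
#' @examples
#' gen_electric_train(40, level = 5)
gen_electric_train <- function(carrier_rate, duration = 0.6, level = 0,
                               f_m = NA_real_, reference_current = 240,
                               ramp = 0.010) {
  stopifnot(carrier_rate > 0, duration > 0)
  if (!is.na(f_m) && f_m > 0.4 * carrier_rate) {
    abort("`f_m` may not exceed 40% of the carrier rate.")
  }
  times <- (seq_len(floor(carrier_rate * duration)) - 0.5) / carrier_rate
  amp <- rep(reference_current * db_to_ratio(level), length(times))
  if (!is.na(f_m)) amp <- amp * (1 - cos(2 * pi * f_m * times)) / 2
  # sin^2 amplitude gating sampled at the pulse times
  g <- rep(1, length(times))
  on <- times < ramp
  off <- times > duration - ramp
  g[on] <- sin(pi / 2 * times[on] / ramp)^2
  g[off] <- sin(pi / 2 * (duration - times[off]) / ramp)^2
  electric_pulse_train(times, amp * g,
    carrier_rate = carrier_rate, f_m = f_m, level = level, duration = duration
  )
}
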