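#' Acoustic stimulus container
#'
#' A sampled pressure waveform (Pa) with its synthesis metadata. The four
#' generators ([gen_sam_tone()], [gen_transposed_tone()], [gen_ge_train()],
#' [gen_filtered_clicks()]) return this class with sin^2 gating applied and
#' the steady-state RMS scaled to the requested sound pressure level.
#'
#' @param samples Numeric waveform in Pa.
#' @param sample_rate Sampling rate in Hz.
#' @param kind One of `"sam"`, `"transposed"`, `"ge"`, `"clicks"`.
#' @param f_c Carrier frequency (Hz).
#' @param f_m Modulation frequency or pulse rate (1/s).
#' @param level Level in dB SPL (re 20 uPa RMS of the steady state).
#' @param ramp Gating ramp duration (s); `NA` for an ungated waveform.
#' @return An `acoustic_stimulus` object.
#' @export
acoustic_stimulus <- function(samples, sample_rate, kind, f_c, f_m, level,
                              ramp = NA_real_) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sample_rate > 0)
  structure(
    list(
      samples = samples, sample_rate = sample_rate,
      kind = match.arg(kind, c("sam", "transposed", "ge", "clicks")),
      f_c = f_c, f_m = f_m, level = level, ramp = ramp,
      duration = length(samples) / sample_rate
    ),
    class = "acoustic_stimulus"
  )
}

#' @export
print.acoustic_stimulus <- function(x, ...) {
  cat(sprintf(
    "<acoustic_stimulus: %s, f_c = %g Hz, f_m = %g /s, %g dB SPL, %.3g s @ %g kHz>\n",
    x$kind, x$f_c, x$f_m, x$level, x$duration, x$sample_rate / 1000
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.acoustic_stimulus <- function(x, ...) {
  tibble(
    time = (seq_along(x$samples) - 1) / x$sample_rate,
    value = x$samples
  )
}

sample_times <- function(duration, sample_rate) {
  seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
}

check_carrier <- function(f_c, f_m, sample_rate) {
  if (f_m >= f_c / 2) abort("`f_m` must be below `f_c`/2.")
  if (sample_rate <= 4 * f_c) {
    abort("`sample_rate` must exceed 4 * `f_c` to avoid aliasing.")
  }
}

#' Sinusoidally amplitude-modulated (SAM) tone
#'
#' Generates `a * sin(2 pi f_c t) * (1 - cos(2 pi f_m t))`: a three-component
#' stimulus with spectral lines at `f_c` and `f_c +/- f_m` in amplitude ratio
#' 1:1/2:1/2, then applies sin^2 gating and scales the steady-state RMS to
#' `level` dB SPL.
#'
#' @inheritParams acoustic_stimulus
#' @param duration Duration (s).
#' @param ramp sin^2 onset/offset ramp (s).
#' @param raw If `TRUE`, skip gating and level scaling (unit-amplitude
#'   waveform, for inspection).
#' @return An [acoustic_stimulus()].
#' @export
#' @examples
#' s <- gen_sam_tone(8000, 100, duration = 0.05, sample_rate = 100e3, level = 30)
gen_sam_tone <- function(f_c, f_m, duration = 1, sample_rate = 100e3,
                         level = 30, ramp = 0.010, raw = FALSE) {
  check_carrier(f_c, f_m, sample_rate)
  t <- sample_times(duration, sample_rate)
  x <- sin(2 * pi * f_c * t) * (1 - cos(2 * pi * f_m * t))
  out <- acoustic_stimulus(x, sample_rate, "sam", f_c, f_m, level)
  if (raw) out else apply_gating_and_level(out, ramp = ramp, level = level)
}

#' Transposed tone
#'
#' The low-frequency modulator `sin(2 pi f_m t)` is half-wave rectified and
#' low-pass filtered (4th-order Butterworth, 2-kHz cutoff, zero phase), peak
#' normalized, and multiplied onto the high-frequency carrier. Compared to a
#' SAM tone the envelope is "off" for half of each modulation cycle, giving a
#' higher AC/DC ratio.
#'
#' @inheritParams gen_sam_tone
#' @param lp_cutoff Low-pass cutoff applied to the rectified modulator (Hz).
#' @export
gen_transposed_tone <- function(f_c, f_m, duration = 1, sample_rate = 100e3,
                                level = 30, ramp = 0.010, lp_cutoff = 2000,
                                raw = FALSE) {
  check_carrier(f_c, f_m, sample_rate)
  if (f_m >= lp_cutoff) abort("`f_m` must lie below the low-pass cutoff.")
  t <- sample_times(duration, sample_rate)
  mod <- pmax(sin(2 * pi * f_m * t), 0)
  bf <- signal::butter(4, lp_cutoff / (sample_rate / 2), type = "low")
  mod <- signal::filtfilt(bf, mod)
  mod <- pmax(mod, 0) / max(mod)
  x <- mod * sin(2 * pi * f_c * t)
  out <- acoustic_stimulus(x, sample_rate, "transposed", f_c, f_m, level)
  if (raw) out else apply_gating_and_level(out, ramp = ramp, level = level)
}

#' Gaussian-envelope (GE) tone train
#'
#' A constant-amplitude train of Gaussian-windowed tone bursts. The Gaussian
#' width is set so that the equivalent rectangular bandwidth (amplitude-
#' spectrum convention) of a single pulse equals the frequency extent of
#' `band_mm` millimetres of cochlea at the carrier place ([greenwood_erb()]).
#' For a Gaussian, ERB * ERD = 1, so the equivalent rectangular duration of
#' the pulse envelope is `1/ERB` (about 0.6 ms for 1.5 mm at 8 kHz). The
#' carrier phase is locked to each pulse centre.
#'
#' @inheritParams gen_sam_tone
#' @param rate Pulse rate (pps); pulse centres at `(k + 1/2)/rate`.
#' @param band_mm Cochlear span defining the pulse bandwidth (mm).
#' @param map A [greenwood_map()].
#' @export
gen_ge_train <- function(f_c, rate, duration = 1, sample_rate = 100e3,
                         level = 30, ramp = 0.010, band_mm = 1.5,
                         map = greenwood_map(), raw = FALSE) {
  stopifnot(rate > 0)
  if (sample_rate <= 4 * f_c) abort("`sample_rate` must exceed 4 * `f_c`.")
  erb <- greenwood_erb(f_c, band_mm, map)
  sigma_t <- 1 / (erb * sqrt(2 * pi)) # ERD = sqrt(2 pi) sigma_t = 1/ERB
  # adjacent-pulse overlap at the midpoint between centres
  mid_db <- ratio_to_db(exp(-(1 / (2 * rate))^2 / (2 * sigma_t^2)))
  if (mid_db > -40) {
    warn(sprintf(
      "GE pulses overlap at -%.1f dB at the midpoint (rate too high for the bandwidth).",
      -mid_db
    ))
  }
  t <- sample_times(duration, sample_rate)
  x <- numeric(length(t))
  centers <- (seq_len(floor(rate * duration)) - 0.5) / rate
  half <- 5 * sigma_t
  for (tc in centers) {
    i <- which(t >= tc - half & t <= tc + half)
    dt <- t[i] - tc
    x[i] <- x[i] + exp(-dt^2 / (2 * sigma_t^2)) * cos(2 * pi * f_c * dt)
  }
  out <- acoustic_stimulus(x, sample_rate, "ge", f_c, rate, level)
  if (raw) out else apply_gating_and_level(out, ramp = ramp, level = level)
}

#' Bandpass-filtered click train
#'
#' Rectangular unipolar (condensation) pulses of 10-us width at the given
#' rate, band-pass filtered with a 2nd-order Butterworth of constant
#' Q = 0.5 centred on `f_c`. Corner frequencies follow the constant-Q
#' relations `f_lo * f_hi = f_c^2`, `f_hi - f_lo = f_c / Q`.
#'
#' @inheritParams gen_sam_tone
#' @param rate Click rate (pps); clicks at `k/rate`, `k = 0, 1, ...`.
#' @param q Filter quality factor.
#' @param click_width Click width (s).
#' @export
gen_filtered_clicks <- function(f_c, rate, duration = 1, sample_rate = 200e3,
                                level = 30, ramp = 0.010, q = 0.5,
                                click_width = 10e-6, raw = FALSE) {
  stopifnot(rate > 0)
  if (sample_rate < 2 / click_width) {
    abort("`sample_rate` must be at least 200 kHz so the 10-us click spans >= 2 samples.")
  }
  n <- round(duration * sample_rate)
  x <- numeric(n)
  onset_idx <- floor(seq(0, duration - 1 / rate, by = 1 / rate) * sample_rate) + 1
  w <- round(click_width * sample_rate)
  for (i in onset_idx) x[i:min(i + w - 1, n)] <- 1
  f_lo <- f_c * (sqrt(1 + 1 / (4 * q^2)) - 1 / (2 * q))
  f_hi <- f_lo + f_c / q
  bf <- signal::butter(1, c(f_lo, f_hi) / (sample_rate / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, x))
  out <- acoustic_stimulus(x, sample_rate, "clicks", f_c, rate, level)
  if (raw) out else apply_gating_and_level(out, ramp = ramp, level = level)
}

#' Apply sin^2 gating and level scaling
#'
#' Multiplies sin^2 onset/offset ramps of length `ramp` onto the waveform and
#' scales it so that the steady-state segment (between the ramps) has an RMS
#' of `level` dB SPL re 20 uPa. Re-application with the same level is
#' idempotent up to numerical precision.
#'
#' @param stimulus An [acoustic_stimulus()].
#' @param ramp Ramp duration (s).
#' @param level Target level, dB SPL.
#' @return The gated, scaled [acoustic_stimulus()].
#' @export
apply_gating_and_level <- function(stimulus, ramp = 0.010,
                                   level = stimulus$level) {
  stopifnot(inherits(stimulus, "acoustic_stimulus"))
  n <- length(stimulus$samples)
  fs <- stimulus$sample_rate
  nr <- round(ramp * fs)
  if (2 * ramp >= stimulus$duration) {
    abort("`ramp` must be shorter than half the stimulus duration.")
  }
  x <- stimulus$samples
  if (nr > 0) {
    g <- sin(pi / 2 * seq(0, 1, length.out = nr))^2
    x[seq_len(nr)] <- x[seq_len(nr)] * g
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(g)
  }
  ss <- x[(nr + 1):(n - nr)]
  rms <- sqrt(mean(ss^2))
  if (rms <= 0) abort("Cannot scale a silent stimulus to a target level.")
  x <- x * (P_REF * db_to_ratio(level) / rms)
  out <- stimulus
  out$samples <- x
  out$level <- level
  out$ramp <- ramp
  out
}

#' Steady-state RMS level of a gated stimulus
#'
#' @param stimulus An [acoustic_stimulus()].
#' @return Level in dB SPL re 20 uPa.
#' @export
stimulus_level <- function(stimulus) {
  n <- length(stimulus$samples)
  nr <- if (is.na(stimulus$ramp)) 0 else round(stimulus$ramp * stimulus$sample_rate)
  ss <- stimulus$samples[(nr + 1):(n - nr)]
  ratio_to_db(sqrt(mean(ss^2)) / P_REF)
}

#' AC/DC ratio of a rectified stimulus
#'
#' Half-wave rectifies the steady-state waveform and computes
#' `sqrt(sum A(f)^2, f != 0) / A(0)` from its FFT amplitudes: the ratio of
#' non-DC RMS content to the DC component. Sharper envelopes give larger
#' ratios; the ratio predicts the strength of envelope phase locking in the
#' auditory nerve. A half-wave-rectified pure sine gives
#' `sqrt(pi^2/4 - 1) ~= 1.211`.
#'
#' @param stimulus An [acoustic_stimulus()], or a numeric waveform.
#' @return Dimensionless ratio.
#' @export
ac_dc_ratio <- function(stimulus) {
  x <- if (inherits(stimulus, "acoustic_stimulus")) {
    n <- length(stimulus$samples)
    nr <- if (is.na(stimulus$ramp)) 0 else round(stimulus$ramp * stimulus$sample_rate)
    stimulus$samples[(nr + 1):(n - nr)]
  } else {
    as.numeric(stimulus)
  }
  x <- pmax(x, 0)
  a <- Mod(fft(x)) / length(x)
  if (a[1] <= 0) abort("Degenerate input: rectified waveform has zero mean.")
  sqrt(sum(a[-1]^2)) / a[1]
}

#' Equivalent rectangular duration of a stimulus envelope
#'
#' Computes the amplitude envelope by the analytic-signal (Hilbert) method
#' and returns its equivalent rectangular duration, the envelope integral
#' divided by its peak. For a single Gaussian-envelope tone pulse this
#' equals `sqrt(2 pi) sigma_t = 1/ERB` (about 0.6 ms for the 1.5-mm
#' bandwidth at 8 kHz).
#'
#' @param stimulus An [acoustic_stimulus()].
#' @return Duration in seconds.
#' @export
erd_of_envelope <- function(stimulus) {
  x <- stimulus$samples
  n <- length(x)
  h <- numeric(n)
  half <- floor(n / 2)
  h[1] <- 1
  h[2:(half + 1)] <- 2
  if (n %% 2 == 0) h[half + 1] <- 1
  env <- Mod(fft(fft(x) * h, inverse = TRUE) / n)
  sum(env) / stimulus$sample_rate / max(env)
}
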