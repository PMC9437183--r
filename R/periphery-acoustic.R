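#' Parameters of the simplified acoustic auditory-nerve fiber model
#'
#' A deliberately simple stand-in for a full auditory-periphery model,
#' targeting the properties that matter for envelope ITD coding: band-pass
#' filtering at the characteristic frequency (CF), inner-hair-cell envelope
#' extraction, a saturating rate-level nonlinearity, short-term adaptation,
#' and an inhomogeneous-Poisson spike generator with dead time. All fibers
#' are medium-spontaneous-rate (0.5-18 sp/s) with CF equal to the stimulus
#' carrier frequency. The module interface (stimulus in, spike ensemble out)
#' is narrow so a full published periphery can be substituted.
#'
#' @param cf Characteristic frequency (Hz).
#' @param spont_rate Spontaneous rate (sp/s), within the MSR class 0.5-18.
#' @param filter_order Gammatone filter order.
#' @param filter_bandwidth Filter bandwidth in Hz; default is the standard
#'   ERB scale `24.7 (4.37 cf/1000 + 1)`.
#' @param ihc_cutoff Inner-hair-cell low-pass cutoff (Hz).
#' @param rate_max Saturation rate (sp/s).
#' @param rate_slope Slope of the logarithmic level-to-rate compression
#'   (1/dB); the drive saturates `1/rate_slope` dB above the fiber's
#'   threshold.
#' @param adaptation_tau Short-term adaptation time constant (s).
#' @param adaptation_strength Fraction of the low-passed drive subtracted
#'   (0 = none; 0.5 halves the sustained response relative to the onset).
#' @param t_abs Absolute dead time of the spike generator (ms).
#' @param spike_fs Sampling rate (Hz) of the instantaneous-rate function
#'   used by the spike generator.
#' @return An `acoustic_fiber_params` object.
#' @export
acoustic_fiber_params <- function(cf = 8000, spont_rate = 5, filter_order = 4,
                                  filter_bandwidth = NULL, ihc_cutoff = 1000,
                                  rate_max = 250, rate_slope = 0.03,
                                  adaptation_tau = 0.06,
                                  adaptation_strength = 0.5,
                                  t_abs = 0.75, spike_fs = 20e3) {
  stopifnot(
    cf > 0, spont_rate >= 0.5, spont_rate <= 18, filter_order >= 1,
    ihc_cutoff > 0, rate_max > spont_rate, rate_slope > 0,
    adaptation_tau > 0, adaptation_strength >= 0, adaptation_strength < 1,
    t_abs >= 0, spike_fs > 0
  )
  if (is.null(filter_bandwidth)) {
    filter_bandwidth <- 24.7 * (4.37 * cf / 1000 + 1)
  }
  structure(
    list(
      cf = cf, spont_rate = spont_rate, filter_order = filter_order,
      filter_bandwidth = filter_bandwidth, ihc_cutoff = ihc_cutoff,
      rate_max = rate_max, rate_slope = rate_slope,
      adaptation_tau = adaptation_tau,
      adaptation_strength = adaptation_strength,
      t_abs = t_abs, spike_fs = spike_fs
    ),
    class = "acoustic_fiber_params"
  )
}

# Gammatone impulse response t^(n-1) exp(-2 pi b t) cos(2 pi cf t),
# normalized to unity gain at cf. b = 1.019 * bandwidth for order 4.
gammatone_filter <- function(x, fs, params) {
  b <- 1.019 * params$filter_bandwidth
  n_ord <- params$filter_order
  t_peak <- (n_ord - 1) / (2 * pi * b)
  t_end <- min(t_peak + 8 / (2 * pi * b) * n_ord, 0.03)
  t_ir <- seq(0, t_end, by = 1 / fs)
  ir <- t_ir^(n_ord - 1) * exp(-2 * pi * b * t_ir) * cos(2 * pi * params$cf * t_ir)
  h_cf <- sum(ir * exp(-2i * pi * params$cf * t_ir))
  ir <- ir / Mod(h_cf)
  # FFT convolution at a highly composite padded length
  nfft <- stats::nextn(length(x) + length(ir) - 1, c(2, 3, 5))
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
    fft(c(ir, numeric(nfft - length(ir)))), inverse = TRUE)) / nfft
  y[seq_along(x)]
}

#' Instantaneous firing-rate drive of the acoustic fiber model
#'
#' The deterministic part of the fiber chain: gammatone band-pass at CF,
#' half-wave rectification plus first-order low-pass (IHC stage),
#' logarithmic level-to-rate compression into `[spont_rate, rate_max]`, and
#' subtractive single-exponential adaptation. All fibers of a population
#' share this drive; only the Poisson draws differ, so it is computed once
#' and reused.
#'
#' @param stimulus An [acoustic_stimulus()].
#' @param params An [acoustic_fiber_params()].
#' @return A list with `rate` (sp/s, sampled at `fs`) and `fs`.
#' @export
acoustic_drive <- function(stimulus, params = acoustic_fiber_params()) {
  stopifnot(inherits(stimulus, "acoustic_stimulus"))
  fs <- stimulus$sample_rate
  if (fs <= 4 * params$cf) abort("Stimulus sample rate must exceed 4 * cf.")
  y <- gammatone_filter(stimulus$samples, fs, params)
  y <- pmax(y, 0)
  lp <- signal::butter(1, params$ihc_cutoff / (fs / 2), type = "low")
  y <- as.numeric(signal::filter(lp, y))
  # decimate to the spike-generator rate (envelope content is < ihc_cutoff)
  dec <- max(1L, round(fs / params$spike_fs))
  y <- y[seq(1, length(y), by = dec)]
  fs_r <- fs / dec
  # logarithmic compression re the drive of a CF tone at 0 dB SPL
  y_ref <- P_REF * sqrt(2) / pi
  level_db <- ifelse(y > y_ref, 20 * log10(y / y_ref), 0)
  g <- clamp(params$rate_slope * level_db, 0, 1)
  r <- params$spont_rate + (params$rate_max - params$spont_rate) * g
  # subtractive short-term adaptation on the driven component
  driven <- r - params$spont_rate
  alpha <- 1 / (params$adaptation_tau * fs_r)
  s <- as.numeric(stats::filter(alpha * driven, 1 - alpha,
    method = "recursive"
  ))
  r_out <- params$spont_rate + pmax(driven - params$adaptation_strength * s, 0)
  list(rate = r_out, fs = fs_r)
}

# Inhomogeneous-Poisson draw with dead time from a sampled rate function.
draw_poisson_spikes <- function(drive, t_abs_s, seed, duration) {
  dt <- 1 / drive$fs
  tt <- with_seed(seed, {
    cand <- which(runif(length(drive$rate)) < drive$rate * dt)
    # place spikes uniformly within their bin
    (cand - 1 + runif(length(cand))) * dt
  })
  if (length(tt) == 0) {
    return(numeric(0))
  }
  # enforce the absolute dead time
  keep <- numeric(length(tt))
  m <- 0L
  last <- -Inf
  for (t in tt) {
    if (t >= last + t_abs_s) {
      m <- m + 1L
      keep[m] <- t
      last <- t
    }
  }
  tt <- keep[seq_len(m)]
  tt[tt <= duration]
}

#' Simulate one acoustically stimulated auditory-nerve fiber
#'
#' Draws an inhomogeneous-Poisson spike train (with absolute dead time) from
#' the deterministic rate drive of [acoustic_drive()]. Reproducible given
#' the seed.
#'
#' @inheritParams acoustic_drive
#' @param seed Integer seed.
#' @param fiber_id Fiber label.
#' @param drive Optional precomputed [acoustic_drive()] result.
#' @return A single-fiber [spike_ensemble()].
#' @export
simulate_acoustic_fiber <- function(stimulus, params = acoustic_fiber_params(),
                                    seed = 1L, fiber_id = 1L, drive = NULL) {
  if (is.null(drive)) drive <- acoustic_drive(stimulus, params)
  times <- draw_poisson_spikes(drive, params$t_abs * 1e-3, seed, stimulus$duration)
  spike_train(times, stimulus$duration, fiber_id = fiber_id)
}

#' Simulate a population of identical acoustic fibers
#'
#' Independent fibers sharing one rate drive; fiber `i` uses the child seed
#' `derive_seed(seed, i)` as in [simulate_electric_population()].
#'
#' @inheritParams simulate_acoustic_fiber
#' @param n_fibers Number of fibers.
#' @return A [spike_ensemble()].
#' @export
simulate_acoustic_population <- function(stimulus, n_fibers,
                                         params = acoustic_fiber_params(),
                                         seed = 1L, drive = NULL) {
  stopifnot(n_fibers >= 1)
  if (is.null(drive)) drive <- acoustic_drive(stimulus, params)
  out <- map(seq_len(n_fibers), function(i) {
    simulate_acoustic_fiber(stimulus, params,
      seed = derive_seed(seed, i),
      fiber_id = i, drive = drive
    )
  })
  spike_ensemble(bind_rows(out), stimulus$duration)
}
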