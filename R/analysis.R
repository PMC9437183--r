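#' Mean firing rate in a window
#'
#' Spike count inside `[window[1], window[2]]` divided by the window length.
#' Acoustic analyses conventionally discard the first 200 ms of the response
#' ([acoustic_window()]); electric analyses use the full 600 ms minus the
#' 10-ms onset ramp ([electric_window()]).
#'
#' @param spikes A [spike_ensemble()] (pooled) or numeric spike times.
#' @param window Length-2 numeric `[t0, t1]`, seconds, `t1 > t0`.
#' @return Rate in sp/s.
#' @export
#' @examples
#' firing_rate(spike_train(seq(0.05, 0.5, by = 0.05), 0.5), c(0, 0.5))
firing_rate <- function(spikes, window) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) abort("`window` must have positive length.")
  t <- if (is.data.frame(spikes)) spikes$time else as.numeric(spikes)
  sum(t >= window[1] & t <= window[2]) / (window[2] - window[1])
}

#' @rdname firing_rate
#' @param duration Stimulus duration (s).
#' @param discard Initial segment to discard (s).
#' @export
acoustic_window <- function(duration = 1, discard = 0.2) c(discard, duration)

#' @rdname firing_rate
#' @param ramp Onset ramp excluded from analysis (s).
#' @export
electric_window <- function(duration = 0.6, ramp = 0.01) c(ramp, duration)

#' Peristimulus time histogram
#'
#' Histogram of pooled spike times in bins of width `bin` (1 ms by default).
#' Bin counts sum to the total number of spikes.
#'
#' @param ensemble A [spike_ensemble()] or numeric spike times.
#' @param bin Bin width (s).
#' @param duration Histogram extent (s); defaults to the ensemble duration.
#' @return A tibble with columns `time` (bin left edge) and `count`.
#' @export
psth <- function(ensemble, bin = 0.001, duration = NULL) {
  stopifnot(bin > 0)
  t <- if (is.data.frame(ensemble)) ensemble$time else as.numeric(ensemble)
  duration <- duration %||% attr(ensemble, "duration") %||%
    (if (length(t)) max(t) else bin)
  edges <- seq(0, duration + bin, by = bin)
  idx <- findInterval(t, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  tibble(time = edges[-length(edges)], count = counts)
}

#' Period histogram
#'
#' Histogram of spike phases relative to a reference frequency: phase
#' `phi_k` is the fractional part of `t_k * frequency`, mapped to `[0, 1)`
#' cycles and binned into `n_bins` equal bins. Counts sum to the number of
#' spikes.
#'
#' @inheritParams psth
#' @param frequency Reference frequency (Hz).
#' @param n_bins Number of phase bins.
#' @return A tibble with columns `phase` (bin left edge, cycles) and `count`.
#' @export
period_histogram <- function(ensemble, frequency, n_bins = 50) {
  stopifnot(frequency > 0, n_bins >= 1)
  t <- if (is.data.frame(ensemble)) ensemble$time else as.numeric(ensemble)
  phase <- (t * frequency) %% 1
  idx <- pmin(floor(phase * n_bins), n_bins - 1) + 1
  counts <- tabulate(idx, nbins = n_bins)
  tibble(phase = (seq_len(n_bins) - 1) / n_bins, count = counts)
}

#' Vector strength
#'
#' Modulus of the mean unit phasor of the spike phases at the reference
#' frequency: `vs = |1/N sum_k exp(i phi_k)|`, with `phi_k = 2 pi f t_k`.
#' Equal to 1 iff all spikes fall at a single stimulus phase, and 0 for
#' phases that cancel symmetrically.
#'
#' @inheritParams period_histogram
#' @return Vector strength in `[0, 1]`.
#' @export
#' @examples
#' vector_strength(c(0.01, 0.02, 0.03), 100) # all at phase 0 -> 1
vector_strength <- function(ensemble, frequency) {
  stopifnot(frequency > 0)
  t <- if (is.data.frame(ensemble)) ensemble$time else as.numeric(ensemble)
  if (length(t) == 0) abort("Vector strength is undefined for an empty spike train.")
  Mod(mean(exp(2i * pi * frequency * t)))
}

#' Rate tuning curve over an ITD or IPD grid
#'
#' Runs `runner(axis_value, rep)` for every grid point and repetition and
#' records the firing rate inside `window`. The result is a tibble of class
#' `tuning_curve` in long format (`axis_value`, `rep`, `rate`);
#' [tidy.tuning_curve()] returns per-point means and [glance.tuning_curve()]
#' the summary metrics.
#'
#' @param runner A function `(axis_value, rep) -> spike train` (a
#'   [spike_ensemble()] or numeric times).
#' @param grid Sorted abscissa values: ITDs in seconds or IPDs in radians.
#' @param n_reps Number of repetitions per grid point.
#' @param window Analysis window passed to [firing_rate()].
#' @param axis_kind `"itd_ms"` or `"ipd_rad"` (metadata; ITD grids are in
#'   seconds internally and reported in ms).
#' @return A `tuning_curve` tibble.
#' @export
tuning_curve <- function(runner, grid, n_reps = 1, window,
                         axis_kind = c("itd_ms", "ipd_rad")) {
  axis_kind <- match.arg(axis_kind)
  stopifnot(n_reps >= 1, !is.unsorted(grid))
  rows <- list_rbind(map(seq_len(n_reps), function(r) {
    rates <- map_dbl(grid, function(v) firing_rate(runner(v, r), window))
    tibble(axis_value = grid, rep = r, rate = rates)
  }))
  new_tuning_curve(rows, axis_kind = axis_kind, window = window)
}

new_tuning_curve <- function(df, axis_kind, window) {
  new_tibble(as_tibble(df),
    axis_kind = axis_kind, window = window,
    class = "tuning_curve"
  )
}

#' @exportS3Method generics::tidy
tidy.tuning_curve <- function(x, ...) {
  out <- x |>
    as_tibble() |>
    group_by(.data$axis_value) |>
    summarise(mean_rate = mean(.data$rate), n_reps = dplyr::n(), .groups = "drop")
  out
}

#' @exportS3Method generics::glance
glance.tuning_curve <- function(x, ...) {
  m <- tidy(x)
  tibble(
    r_max = max(m$mean_rate),
    r_min = min(m$mean_rate),
    best = m$axis_value[which.max(m$mean_rate)],
    worst = m$axis_value[which.min(m$mean_rate)],
    sqrt_contrast = sqrt(max(m$mean_rate)) - sqrt(min(m$mean_rate)),
    n_points = nrow(m),
    n_reps = max(x$rep)
  )
}

#' Best-worst rate contrast of a tuning curve
#'
#' `sqrt(r_max) - sqrt(r_min)` over the per-point mean rates: under a
#' Poisson-noise assumption the square-root transform stabilizes variance,
#' so this contrast is proportional to the best-case discriminability of the
#' best versus worst ITD/IPD.
#'
#' @param curve A [tuning_curve()].
#' @return Contrast in sqrt(sp/s), >= 0; 0 iff the mean curve is flat.
#' @export
sqrt_contrast <- function(curve) {
  m <- tidy(curve)
  if (nrow(m) == 0) abort("Empty tuning curve.")
  sqrt(max(m$mean_rate)) - sqrt(min(m$mean_rate))
}

#' Similarity of two tuning curves
#'
#' Squared Pearson correlation between the per-point mean rates of two
#' curves on identical grids. Symmetric, and invariant to affine rescaling
#' of either curve; undefined (error) if either mean curve is constant.
#'
#' @param a,b [tuning_curve()] objects on identical grids.
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(a, b) {
  ma <- tidy(a)
  mb <- tidy(b)
  if (nrow(ma) != nrow(mb) || max(abs(ma$axis_value - mb$axis_value)) > 1e-9) {
    abort("Tuning curves must share an identical grid.")
  }
  if (sd(ma$mean_rate) == 0 || sd(mb$mean_rate) == 0) {
    abort("R^2 is undefined for a constant tuning curve.")
  }
  stats::cor(ma$mean_rate, mb$mean_rate)^2
}

#' Width of the rate-ITD trough
#'
#' The contiguous span of grid points around the worst (minimum-rate) ITD
#' whose mean rate lies below `frac` of the curve maximum. For unmodulated
#' low-rate electric trains the trough width is set by the difference
#' between the inhibitory and excitatory windows (about 2 ms at the
#' defaults). Returns 0 if the rate at the worst ITD is not below the
#' threshold.
#'
#' @param curve A [tuning_curve()] on an ITD grid (seconds).
#' @param frac Fraction of the curve maximum defining "suppressed".
#' @return Span in seconds.
#' @export
trough_span <- function(curve, frac = 0.2) {
  m <- tidy(curve)
  thr <- frac * max(m$mean_rate)
  i0 <- which.min(m$mean_rate)
  if (m$mean_rate[i0] >= thr) {
    return(0)
  }
  lo <- i0
  while (lo > 1 && m$mean_rate[lo - 1] < thr) lo <- lo - 1
  hi <- i0
  while (hi < nrow(m) && m$mean_rate[hi + 1] < thr) hi <- hi + 1
  m$axis_value[hi] - m$axis_value[lo]
}

#' Onset offset of the doubled-rate plateau
#'
#' At high stimulation levels a second response per modulation cycle arises
#' once the excitation precedes the inhibition by more than the refractory
#' period, producing an upper plateau at twice the modulation frequency
#' whose onset sits a fixed ITD offset below the worst ITD. This measures
#' that offset: the distance from the worst ITD to the nearest grid point
#' whose mean rate reaches `2 * f_m`. If the curve never reaches `2 * f_m`
#' (a periphery with briefer high-level volleys than the full model shows a
#' lower upper plateau), the plateau onset is instead detected at
#' `frac_fallback` of the curve maximum, i.e., at the upper plateau's own
#' level.
#'
#' @param curve A [tuning_curve()] on an ITD grid (seconds).
#' @param f_m Modulation frequency / pulse rate (1/s).
#' @param frac_fallback Fraction of the curve maximum used when `2 * f_m`
#'   is not reached.
#' @return Offset in seconds (positive: the plateau begins below the worst
#'   ITD).
#' @export
second_plateau_offset <- function(curve, f_m, frac_fallback = 0.95) {
  m <- tidy(curve)
  worst <- m$axis_value[which.min(m$mean_rate)]
  cand <- m$axis_value[m$mean_rate >= 2 * f_m]
  if (length(cand) == 0) {
    cand <- m$axis_value[m$mean_rate >= frac_fallback * max(m$mean_rate)]
  }
  onset <- cand[which.min(abs(cand - worst))]
  worst - onset
}
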