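#' Spike train and spike ensemble containers
#'
#' Spike data are tibbles with a `fiber_id` column and a `time` column
#' (seconds, sorted within fiber), carrying the stimulus `duration` as an
#' attribute. A single-fiber train is simply an ensemble with one fiber.
#'
#' @param times Numeric spike times (s).
#' @param duration Stimulus/observation duration (s).
#' @param fiber_id Integer fiber label.
#' @return A tibble of class `spike_ensemble` with columns `fiber_id`, `time`.
#' @export
#' @examples
#' spike_train(c(0.01, 0.02), duration = 0.1)
spike_train <- function(times, duration, fiber_id = 1L) {
  spike_ensemble(
    tibble(fiber_id = as.integer(fiber_id), time = as.numeric(times)),
    duration
  )
}

#' @rdname spike_train
#' @param df A data frame with columns `fiber_id` and `time`.
#' @export
spike_ensemble <- function(df, duration) {
  df <- as_tibble(df)[, c("fiber_id", "time")]
  df <- df[order(df$fiber_id, df$time), ]
  stopifnot(all(df$time >= 0), all(df$time <= duration + 1e-12))
  out <- new_tibble(df, duration = duration, class = "spike_ensemble")
  out
}

#' @rdname spike_train
#' @param x A `spike_ensemble`.
#' @export
ens_duration <- function(x) {
  d <- attr(x, "duration")
  if (is.null(d)) abort("Object carries no `duration` attribute.")
  d
}

#' @export
print.spike_ensemble <- function(x, ...) {
  cat(sprintf(
    "<spike_ensemble: %d spikes, %d fiber(s), %.3g s>\n",
    nrow(x), length(unique(x$fiber_id)), ens_duration(x)
  ))
  NextMethod()
}

#' Apply an interaural time difference to the contralateral spike trains
#'
#' Positive ITDs represent contralateral-leading stimulation: all
#' contralateral spike times are shifted *earlier* by `itd` (the contralateral
#' stimulus leads, so relative to the ipsilateral clock its spikes arrive
#' earlier). Negative ITDs shift them later. Spikes shifted outside
#' `[0, duration]` are dropped.
#'
#' @param ensemble A [spike_ensemble()] of contralateral fibers.
#' @param itd Interaural time difference (s), positive = contralateral-leading.
#' @param side Which side the ensemble belongs to; only `"contralateral"`
#'   ensembles are shifted.
#' @return The shifted [spike_ensemble()].
#' @export
#' @examples
#' ens <- spike_train(0.010, duration = 0.1)
#' apply_itd(ens, 0.002)$time  # 0.008
apply_itd <- function(ensemble, itd, side = c("contralateral")) {
  side <- match.arg(side)
  dur <- ens_duration(ensemble)
  if (abs(itd) > dur) abort("|itd| exceeds the stimulus duration.")
  shifted <- ensemble$time - itd
  keep <- shifted >= 0 & shifted <= dur
  spike_ensemble(
    tibble(fiber_id = ensemble$fiber_id[keep], time = shifted[keep]),
    dur
  )
}
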