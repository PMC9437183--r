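#' Parameters of the excitatory-inhibitory coincidence-counting neuron
#'
#' The binaural neuron counts excitatory spikes inside a trailing rectangular
#' window of length `w_exc` and inhibitory spikes (weighted by `inh_gain`)
#' inside a longer trailing window `w_inh`; it fires whenever the net count
#' reaches `threshold`, subject to an absolute refractory period `t_ref`.
#' Defaults: 1.1-ms excitatory and 3.1-ms inhibitory windows, threshold 3,
#' inhibitory gain 2, 1.6-ms refractory period, 20 excitatory (ipsilateral)
#' and 8 inhibitory (contralateral) input fibers. With all inputs entrained,
#' 20 excitatory minus 8 double-weighted inhibitory inputs leave a net count
#' of +4, just above threshold.
#'
#' @param w_exc Excitatory coincidence window (s).
#' @param w_inh Inhibitory window (s); must be >= `w_exc`.
#' @param threshold Integer response threshold (net count).
#' @param inh_gain Weight applied to each inhibitory spike.
#' @param t_ref Absolute refractory period of the output (s).
#' @param n_exc,n_inh Number of excitatory / inhibitory input fibers.
#' @return An `ei_params` object.
#' @export
ei_params <- function(w_exc = 1.1e-3, w_inh = 3.1e-3, threshold = 3,
                      inh_gain = 2, t_ref = 1.6e-3, n_exc = 20, n_inh = 8) {
  stopifnot(
    w_exc > 0, w_inh >= w_exc, threshold >= 1, inh_gain >= 0, t_ref > 0,
    n_exc >= 1, n_inh >= 0
  )
  structure(
    list(
      w_exc = w_exc, w_inh = w_inh, threshold = threshold,
      inh_gain = inh_gain, t_ref = t_ref, n_exc = n_exc, n_inh = n_inh
    ),
    class = "ei_params"
  )
}

#' @export
print.ei_params <- function(x, ...) {
  cat(sprintf(
    "<ei_params: w_exc %.2g ms, w_inh %.2g ms, threshold %d, inh gain %g, t_ref %.2g ms, %d exc + %d inh>\n",
    x$w_exc * 1e3, x$w_inh * 1e3, x$threshold, x$inh_gain, x$t_ref * 1e3,
    x$n_exc, x$n_inh
  ))
  invisible(x)
}

#' Net coincidence count of the EI neuron
#'
#' Evaluates, at each time in `t`, the number of excitatory spikes in the
#' half-open trailing window `(t - w_exc, t]` minus `inh_gain` times the
#' number of inhibitory spikes in `(t - w_inh, t]`. The current spike counts
#' toward its own evaluation.
#'
#' @param t Evaluation time(s), seconds.
#' @param exc_spikes,inh_spikes Sorted numeric spike times (s), or
#'   [spike_ensemble()] objects (pooled across fibers).
#' @param params An [ei_params()].
#' @return Signed net count(s), same length as `t`.
#' @export
#' @examples
#' ei_count(0.01, rep(0.01, 20), rep(0.0095, 8), ei_params())  # +4
ei_count <- function(t, exc_spikes, inh_spikes, params = ei_params()) {
  exc <- pooled_times(exc_spikes)
  inh <- pooled_times(inh_spikes)
  n_e <- findInterval(t, exc) - findInterval(t - params$w_exc, exc)
  n_i <- findInterval(t, inh) - findInterval(t - params$w_inh, inh)
  n_e - params$inh_gain * n_i
}

pooled_times <- function(x) {
  t <- if (is.data.frame(x)) x$time else as.numeric(x)
  sort(t)
}

#' Simulate the EI neuron on excitatory and inhibitory spike ensembles
#'
#' Event-driven evaluation of the coincidence-counting rule: the net count
#' ([ei_count()]) is evaluated at each pooled excitatory spike time in
#' ascending order (simultaneous spikes form one evaluation), and an output
#' spike is emitted whenever the count reaches the threshold and the neuron
#' is outside its absolute refractory period. The neuron is fully
#' deterministic: all stochasticity lives in the periphery.
#'
#' @param exc Excitatory (ipsilateral) [spike_ensemble()].
#' @param inh Inhibitory (contralateral) [spike_ensemble()].
#' @param params An [ei_params()].
#' @return A single-fiber [spike_ensemble()] of output spike times
#'   (`fiber_id` 0).
#' @export
simulate_ei <- function(exc, inh, params = ei_params()) {
  dur <- ens_duration(exc)
  dur_i <- attr(inh, "duration") %||% dur
  if (abs(dur_i - dur) > 1e-9) {
    abort("Excitatory and inhibitory ensembles must share a duration.")
  }
  exc_t <- pooled_times(exc)
  inh_t <- pooled_times(inh)
  if (length(exc_t) == 0) {
    return(spike_train(numeric(0), dur, fiber_id = 0L))
  }
  eval_t <- unique(exc_t)
  count <- {
    n_e <- findInterval(eval_t, exc_t) - findInterval(eval_t - params$w_exc, exc_t)
    n_i <- findInterval(eval_t, inh_t) - findInterval(eval_t - params$w_inh, inh_t)
    n_e - params$inh_gain * n_i
  }
  cand <- eval_t[count >= params$threshold]
  out <- numeric(0)
  i <- 1L
  n <- length(cand)
  while (i <= n) {
    out <- c(out, cand[i])
    # jump to the first candidate at or beyond the end of the refractory period
    i <- findInterval(cand[i] + params$t_ref, cand, left.open = TRUE) + 1L
  }
  spike_train(out, dur, fiber_id = 0L)
}

#' Brute-force reference implementation of the EI neuron
#'
#' Evaluates the same counting rule as [simulate_ei()] by direct, quadratic
#' window-membership tests (an `outer()` comparison of every evaluation time
#' against every spike) and a step-by-step refractory walk, rather than the
#' sorted-search evaluation of the fast path. Intended solely as an
#' independent cross-check in tests; instances with more than 1000 spikes
#' are rejected.
#'
#' @inheritParams simulate_ei
#' @return A single-fiber [spike_ensemble()].
#' @export
ei_oracle <- function(exc, inh, params = ei_params()) {
  dur <- ens_duration(exc)
  exc_t <- pooled_times(exc)
  inh_t <- pooled_times(inh)
  if (length(exc_t) + length(inh_t) > 1000) {
    abort("ei_oracle is restricted to <= 1000 total spikes.")
  }
  if (length(exc_t) == 0) {
    return(spike_train(numeric(0), dur, fiber_id = 0L))
  }
  in_window <- function(t0, spikes, w) {
    if (length(spikes) == 0) {
      return(numeric(length(t0)))
    }
    rowSums(outer(t0, spikes, function(g, s) s <= g & s > g - w))
  }
  eval_t <- sort(unique(exc_t))
  count <- in_window(eval_t, exc_t, params$w_exc) -
    params$inh_gain * in_window(eval_t, inh_t, params$w_inh)
  out <- numeric(0)
  last <- -Inf
  for (k in seq_along(eval_t)) {
    if (count[k] >= params$threshold && eval_t[k] >= last + params$t_ref) {
      out <- c(out, eval_t[k])
      last <- eval_t[k]
    }
  }
  spike_train(out, dur, fiber_id = 0L)
}
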