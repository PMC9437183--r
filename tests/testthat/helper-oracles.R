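# Brute-force discrete-time oracle for the electric fiber model: walks a
# 1-us time grid carrying the refractory state explicitly, evaluating the
# same membrane/threshold equations as the event-driven implementation.
# Deterministic limit only (no noise, no latency spread, no jitter).
electric_fiber_oracle_det <- function(train, params) {
  dt <- 1e-6
  n_steps <- ceiling(train$duration / dt)
  pulse_idx <- round(train$pulse_times / dt)
  amp <- numeric(n_steps + 1)
  amp[pulse_idx + 1] <- train$amplitudes
  is_pulse <- logical(n_steps + 1)
  is_pulse[pulse_idx + 1] <- TRUE
  t_abs_s <- params$t_abs * 1e-3
  tau_rel_s <- params$tau_rel * 1e-3
  disch <- params$discharge_time * 1e-3
  t_last <- -Inf
  spikes <- numeric(0)
  for (k in which(is_pulse)) {
    t_now <- (k - 1) * dt
    u <- amp[k] * params$gain * (1 - exp(-train$phase_duration / params$tau_m))
    dt_last <- t_now - t_last
    if (dt_last < t_abs_s) next
    r <- if (is.finite(t_last)) {
      1 / (1 - exp(-(dt_last - t_abs_s) / tau_rel_s))
    } else {
      1
    }
    if (u >= params$v_threshold * r) {
      t_last <- t_now + disch
      spikes <- c(spikes, t_now + disch + params$latency_mean * 1e-3)
    }
  }
  spikes[spikes <= train$duration]
}
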