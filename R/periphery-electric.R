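#' Parameters of the electrically stimulated auditory-nerve fiber model
#'
#' A stochastic single-fiber model with four stages: leaky membrane
#' integration of the first pulse phase, additive zero-mean Gaussian membrane
#' noise, absolute-plus-relative refractoriness, and latency/jitter of the
#' recorded spike time. The per-pulse firing decision depends only on the
#' post-first-phase membrane voltage and on the time since the last action
#' potential; there is no adaptation across pulses.
#'
#' `relative_spread` (noise SD over threshold voltage) sets the slope of the
#' single-pulse firing-probability sigmoid. The jitter SD depends on the
#' *effective* firing efficiency of the pulse that triggered the spike (the
#' Gaussian tail of the margin to the refractoriness-elevated threshold):
#' it shrinks from `jitter_sd_max` for spikes fired at vanishing margin to
#' `jitter_sd_min` at full efficiency, `sd = min + (max - min) * (1 - FE)`,
#' following the efficiency dependence reported for electrically stimulated
#' cat fibers. Spikes triggered under partial refractory recovery (high-rate
#' stimulation) therefore carry large jitter, which smears the volley
#' structure once the stimulation period falls below the recovery time.
#'
#' @param tau_m Membrane time constant (us).
#' @param v_threshold Threshold potential (arbitrary voltage units).
#' @param relative_spread Noise SD / threshold (dimensionless, < 0.2).
#' @param gain Voltage per uA of stimulation current (lumped input
#'   resistance). The default is a calibration constant chosen so that
#'   [find_reference_threshold()] on the 40-pps standard returns
#'   approximately 240 uA.
#' @param t_abs Absolute refractory period (ms).
#' @param tau_rel Relative-refractory recovery time constant (ms).
#' @param latency_mean,latency_sd Spike latency mean and SD (ms).
#' @param jitter_sd_min,jitter_sd_max Jitter SD at full / zero firing
#'   efficiency (ms).
#' @param discharge_time Membrane discharge time on firing (ms).
#' @return An `electric_fiber_params` object.
#' @export
electric_fiber_params <- function(tau_m = 100, v_threshold = 1,
                                  relative_spread = 0.19, gain = 4.28e-3,
                                  t_abs = 0.7, tau_rel = 1.32,
                                  latency_mean = 0.685, latency_sd = 0.1,
                                  jitter_sd_min = 0.06, jitter_sd_max = 0.35,
                                  discharge_time = 0.01) {
  stopifnot(
    tau_m > 0, v_threshold > 0, relative_spread > 0, relative_spread < 0.2,
    gain > 0, t_abs > 0, tau_rel > 0, latency_mean > 0, latency_sd >= 0,
    jitter_sd_min >= 0, jitter_sd_max >= jitter_sd_min, discharge_time >= 0
  )
  structure(
    list(
      tau_m = tau_m, v_threshold = v_threshold,
      relative_spread = relative_spread, gain = gain, t_abs = t_abs,
      tau_rel = tau_rel, latency_mean = latency_mean, latency_sd = latency_sd,
      jitter_sd_min = jitter_sd_min, jitter_sd_max = jitter_sd_max,
      discharge_time = discharge_time
    ),
    class = "electric_fiber_params"
  )
}

#' Membrane voltage after the first pulse phase
#'
#' Leaky integrate-and-fire charging of the membrane by a rectangular
#' current phase: `u = current * gain * (1 - exp(-phase_duration / tau_m))`.
#' Deterministic; the membrane noise is added at the firing decision.
#'
#' @param current Stimulation current (uA), non-negative.
#' @param phase_duration First-phase duration (us).
#' @param params An [electric_fiber_params()].
#' @return Membrane voltage (arbitrary units), vectorized over `current`.
#' @export
#' @examples
#' membrane_first_phase(240, 100, electric_fiber_params())
membrane_first_phase <- function(current, phase_duration = 100,
                                 params = electric_fiber_params()) {
  stopifnot(all(current >= 0))
  current * params$gain * (1 - exp(-phase_duration / params$tau_m))
}

#' Per-pulse firing decision
#'
#' The fiber fires iff `u + noise >= v_threshold * R(dt_last)`, where the
#' refractory factor is infinite within the absolute refractory period and
#' recovers as `R = 1 / (1 - exp(-(dt_last - t_abs) / tau_rel))` afterwards
#' (`R = 1` with no prior spike). Averaged over the Gaussian membrane noise,
#' the single-pulse firing probability is `pnorm((u - v_thr * R) / sigma)`.
#'
#' @param u Membrane voltage after the first phase.
#' @param dt_last Time since the last action potential (s), or `NA`/`Inf` if
#'   none.
#' @param params An [electric_fiber_params()].
#' @param noise_draw Gaussian membrane-noise draw (voltage units).
#' @return Logical: did the fiber fire?
#' @export
spike_decision <- function(u, dt_last, params = electric_fiber_params(),
                           noise_draw = 0) {
  r <- refractory_factor(dt_last, params)
  u + noise_draw >= params$v_threshold * r
}

refractory_factor <- function(dt_last, params) {
  dt_ms <- dt_last * 1e3
  r <- rep(1, length(dt_ms))
  prior <- !is.na(dt_ms) & is.finite(dt_ms)
  abs_ref <- prior & dt_ms < params$t_abs
  rel <- prior & !abs_ref
  r[abs_ref] <- Inf
  r[rel] <- 1 / (1 - exp(-(dt_ms[rel] - params$t_abs) / params$tau_rel))
  r
}

#' Single-pulse firing efficiency
#'
#' Probability that an unrefractory fiber fires on one pulse of the given
#' current: the Gaussian tail `pnorm((u - v_threshold) / sigma_noise)`.
#'
#' @inheritParams membrane_first_phase
#' @return Probability in `[0, 1]`, vectorized over `current`.
#' @export
firing_efficiency <- function(current, phase_duration = 100,
                              params = electric_fiber_params()) {
  u <- membrane_first_phase(current, phase_duration, params)
  stats::pnorm(
    (u - params$v_threshold) / (params$relative_spread * params$v_threshold)
  )
}

#' Simulate one electrically stimulated auditory-nerve fiber
#'
#' For each pulse the firing decision ([spike_decision()]) is evaluated with
#' a fresh membrane-noise draw. On firing, the action potential is generated
#' `discharge_time` after the pulse onset (this time governs refractoriness),
#' and the recorded spike time additionally receives a latency draw
#' (`latency_mean` +/- `latency_sd`) and a level-dependent jitter draw.
#' Recorded times are kept non-decreasing and at least `t_abs` apart.
#'
#' @param train An [electric_pulse_train()].
#' @param params An [electric_fiber_params()].
#' @param seed Integer seed; the simulation is exactly reproducible.
#' @param fiber_id Fiber label for the output.
#' @return A single-fiber [spike_ensemble()].
#' @export
#' @examples
#' tr <- gen_electric_train(40, level = 6)
#' simulate_electric_fiber(tr, seed = 1)
simulate_electric_fiber <- function(train, params = electric_fiber_params(),
                                    seed = 1L, fiber_id = 1L) {
  stopifnot(inherits(train, "electric_pulse_train"))
  n <- length(train$pulse_times)
  u <- membrane_first_phase(train$amplitudes, train$phase_duration, params)
  sigma <- params$relative_spread * params$v_threshold
  draws <- with_seed(seed, {
    list(
      noise = rnorm(n, 0, sigma),
      latency = rnorm(n, params$latency_mean, params$latency_sd) * 1e-3,
      jitter_z = rnorm(n, 0, 1)
    )
  })
  t_abs_s <- params$t_abs * 1e-3
  tau_rel_ms <- params$tau_rel
  thr <- params$v_threshold
  disch <- params$discharge_time * 1e-3
  pt <- train$pulse_times
  uplus <- u + draws$noise
  fired <- logical(n)
  fe_eff <- numeric(n)
  t_last <- -Inf
  for (k in seq_len(n)) {
    dt_ms <- (pt[k] - t_last) * 1e3
    if (dt_ms < params$t_abs) next
    r <- if (is.finite(t_last)) {
      1 / (1 - exp(-(dt_ms - params$t_abs) / tau_rel_ms))
    } else {
      1
    }
    if (uplus[k] >= thr * r) {
      fired[k] <- TRUE
      # effective (refractoriness-included) firing efficiency of this pulse,
      # which sets the jitter of the recorded spike time
      fe_eff[k] <- stats::pnorm((u[k] - thr * r) / sigma)
      t_last <- pt[k] + disch
    }
  }
  jit_sd_ms <- params$jitter_sd_min +
    (params$jitter_sd_max - params$jitter_sd_min) * (1 - fe_eff)
  times <- pt[fired] + disch + draws$latency[fired] +
    (draws$jitter_z * jit_sd_ms * 1e-3)[fired]
  times <- cummax(times)
  if (length(times) > 1) {
    for (k in 2:length(times)) {
      if (times[k] < times[k - 1] + t_abs_s) times[k] <- times[k - 1] + t_abs_s
    }
  }
  times <- times[times >= 0 & times <= train$duration]
  spike_train(times, train$duration, fiber_id = fiber_id)
}

#' Simulate a population of identical electric fibers
#'
#' `n_fibers` statistically independent fibers with identical parameters;
#' fiber `i` uses the child seed `derive_seed(seed, i)`, so the population is
#' exactly reproducible and fiber 1 of a population equals a single-fiber
#' simulation with that derived seed.
#'
#' @inheritParams simulate_electric_fiber
#' @param n_fibers Number of fibers.
#' @return A [spike_ensemble()] with `fiber_id` 1..n_fibers.
#' @export
simulate_electric_population <- function(train, n_fibers,
                                         params = electric_fiber_params(),
                                         seed = 1L) {
  stopifnot(n_fibers >= 1)
  out <- map(seq_len(n_fibers), function(i) {
    simulate_electric_fiber(train, params, seed = derive_seed(seed, i), fiber_id = i)
  })
  spike_ensemble(bind_rows(out), train$duration)
}

#' Reference threshold current of the electric pathway
#'
#' Levels of electric stimuli are expressed in dB re a reference threshold:
#' the smallest current of a "standard" stimulus (40-pps unmodulated train,
#' or a 40-Hz SAM 1000-pps train for the SAM reference) at which
#' ipsilateral-only stimulation of the EI neuron (its `n_exc` excitatory
#' fibers, no inhibition) evokes at least 1 spike/s. Found by bisection to
#' 1-uA resolution, averaging the EI rate over `n_reps` repetitions.
#'
#' @param standard `"unmodulated"` (40 pps) or `"sam"` (40-Hz SAM, 1000 pps).
#' @param ei An [ei_params()].
#' @param params An [electric_fiber_params()].
#' @param seed Integer seed.
#' @param n_reps Repetitions averaged per probe current.
#' @param search Current bracket (uA).
#' @param window Analysis window (s) for the EI rate.
#' @return Threshold current in uA.
#' @export
find_reference_threshold <- function(standard = c("unmodulated", "sam"),
                                     ei = ei_params(),
                                     params = electric_fiber_params(),
                                     seed = 1L, n_reps = 10,
                                     search = c(10, 2000),
                                     window = c(0.01, 0.6)) {
  standard <- match.arg(standard)
  make_train <- function(current) {
    if (standard == "unmodulated") {
      gen_electric_train(40, duration = 0.6, level = 0, reference_current = current)
    } else {
      gen_electric_train(1000,
        duration = 0.6, level = 0, f_m = 40,
        reference_current = current
      )
    }
  }
  rate_at <- function(current) {
    tr <- make_train(current)
    rates <- map_dbl(seq_len(n_reps), function(rep) {
      ens <- simulate_electric_population(tr, ei$n_exc, params,
        seed = derive_seed(seed, rep)
      )
      out <- simulate_ei(ens, spike_train(numeric(0), tr$duration), ei)
      firing_rate(out, window)
    })
    mean(rates)
  }
  lo <- search[1]
  hi <- search[2]
  if (rate_at(lo) >= 1) abort("Lower search bound already above threshold.")
  if (rate_at(hi) < 1) abort("Upper search bound below threshold.")
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) >= 1) hi <- mid else lo <- mid
  }
  hi
}
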