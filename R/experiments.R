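#' Simulate the binaural input ensembles for one stimulus
#'
#' Generates the ipsilateral (excitatory, `n_exc` fibers) and contralateral
#' (inhibitory, `n_inh` fibers) auditory-nerve ensembles for each
#' repetition. The two sides receive the same (diotic) stimulus; the ITD is
#' applied afterwards to the contralateral spike trains ([apply_itd()]),
#' which avoids re-simulating the periphery for every grid point.
#'
#' @param stimulus An [acoustic_stimulus()] or [electric_pulse_train()].
#' @param n_reps Number of repetitions.
#' @param ei An [ei_params()] (supplies the fiber counts).
#' @param periphery Fiber parameters matching the stimulus class
#'   ([acoustic_fiber_params()] or [electric_fiber_params()]).
#' @param seed Master seed; side- and repetition-specific seeds are derived.
#' @return A list of length `n_reps`; each element has `$exc` and `$inh`
#'   [spike_ensemble()]s.
#' @export
binaural_ensembles <- function(stimulus, n_reps = 1, ei = ei_params(),
                               periphery = NULL, seed = 1L) {
  electric <- inherits(stimulus, "electric_pulse_train")
  if (is.null(periphery)) {
    periphery <- if (electric) {
      electric_fiber_params()
    } else {
      acoustic_fiber_params(cf = stimulus$f_c)
    }
  }
  drive <- if (!electric) acoustic_drive(stimulus, periphery)
  map(seq_len(n_reps), function(rep) {
    sim <- function(n, side_idx) {
      s <- derive_seed(seed, rep, side_idx)
      if (electric) {
        simulate_electric_population(stimulus, n, periphery, seed = s)
      } else {
        simulate_acoustic_population(stimulus, n, periphery, seed = s, drive = drive)
      }
    }
    list(exc = sim(ei$n_exc, 1L), inh = sim(ei$n_inh, 2L))
  })
}

stimulus_mod_frequency <- function(stimulus) {
  if (inherits(stimulus, "electric_pulse_train")) {
    if (is.na(stimulus$f_m)) stimulus$carrier_rate else stimulus$f_m
  } else {
    stimulus$f_m
  }
}

#' Rate-ITD / rate-IPD tuning curve of the EI neuron
#'
#' Full pipeline for one stimulus condition: simulate the binaural
#' periphery once per repetition, then for every grid point shift the
#' contralateral trains by the corresponding ITD, run the deterministic EI
#' neuron, and record its firing rate. IPD grids are converted to ITDs via
#' the stimulus modulation frequency (or pulse rate for unmodulated
#' trains); positive values are contralateral-leading.
#'
#' @inheritParams binaural_ensembles
#' @param axis `"itd"` (grid in seconds) or `"ipd"` (grid in radians).
#' @param grid Sorted grid; defaults to [-4, 4] ms in 0.1-ms steps for ITD
#'   and [-pi, pi] in 0.05*pi steps for IPD.
#' @param window Analysis window; defaults to [electric_window()] or
#'   [acoustic_window()] as appropriate.
#' @param ensembles Optional precomputed [binaural_ensembles()] result
#'   (reused, e.g., across inhibitory-window settings).
#' @return A [tuning_curve()] tibble.
#' @export
#' @examples
#' tr <- gen_electric_train(100, level = 5)
#' tc <- ei_tuning_curve(tr, axis = "itd", grid = seq(-2e-3, 2e-3, 5e-4), n_reps = 2)
ei_tuning_curve <- function(stimulus, axis = c("itd", "ipd"), grid = NULL,
                            n_reps = 10, ei = ei_params(), periphery = NULL,
                            seed = 1L, window = NULL, ensembles = NULL) {
  axis <- match.arg(axis)
  if (is.null(grid)) {
    grid <- if (axis == "itd") {
      seq(-4e-3, 4e-3, by = 0.1e-3)
    } else {
      seq(-pi, pi, by = 0.05 * pi)
    }
  }
  if (is.null(window)) {
    window <- if (inherits(stimulus, "electric_pulse_train")) {
      electric_window(stimulus$duration)
    } else {
      acoustic_window(stimulus$duration)
    }
  }
  if (is.null(ensembles)) {
    ensembles <- binaural_ensembles(stimulus, n_reps, ei, periphery, seed)
  }
  f_ref <- stimulus_mod_frequency(stimulus)
  to_itd <- if (axis == "itd") identity else function(v) v / (2 * pi * f_ref)
  runner <- function(v, rep) {
    e <- ensembles[[rep]]
    simulate_ei(e$exc, apply_itd(e$inh, to_itd(v)), ei)
  }
  tuning_curve(runner, grid, n_reps, window,
    axis_kind = if (axis == "itd") "itd_ms" else "ipd_rad"
  )
}

#' Experiment specification
#'
#' Declarative description of a sweep over stimulation levels, pulse rates /
#' modulation frequencies, and inhibitory window lengths, as used for the
#' figure-level protocols: rate-ITD/IPD tuning curves and their
#' `sqrt(r_max) - sqrt(r_min)` contrasts per condition.
#'
#' @param pathway `"electric"` or `"acoustic"`.
#' @param kind Stimulus kind: `"unmodulated"`, `"sam_electric"` for the
#'   electric pathway (with `carrier_rate`); `"sam"`, `"transposed"`,
#'   `"ge"`, `"clicks"` for the acoustic pathway.
#' @param f_c Acoustic carrier frequency (Hz); ignored for electric.
#' @param carrier_rate Electric carrier rate (pps) for SAM electric trains.
#' @param levels Stimulation levels (dB thr for electric, dB SPL for
#'   acoustic).
#' @param rates Pulse rates or modulation frequencies (1/s); default is the
#'   standard sweep `[25 50 100 200 250 320 400 500 800]`.
#' @param axis `"itd"` or `"ipd"`.
#' @param grid_step Grid step: seconds for ITD, radians for IPD.
#' @param n_reps Repetitions (10 for acoustic rate-ITD protocols, 20 for
#'   electric and comparison protocols).
#' @param w_inh Inhibitory window lengths to test (s).
#' @param reference_current Electric reference threshold (uA).
#' @param seed Master seed.
#' @param duration Stimulus duration (s); defaults to 0.6 (electric) or
#'   1 (acoustic).
#' @return An `experiment_spec` object.
#' @export
experiment_spec <- function(pathway = c("electric", "acoustic"),
                            kind = "unmodulated", f_c = 8000,
                            carrier_rate = 1000,
                            levels = 5,
                            rates = c(25, 50, 100, 200, 250, 320, 400, 500, 800),
                            axis = c("ipd", "itd"),
                            grid_step = NULL,
                            n_reps = NULL,
                            w_inh = 3.1e-3,
                            reference_current = 240,
                            seed = 1L,
                            duration = NULL) {
  pathway <- match.arg(pathway)
  axis <- match.arg(axis)
  valid_kinds <- if (pathway == "electric") {
    c("unmodulated", "sam_electric")
  } else {
    c("sam", "transposed", "ge", "clicks")
  }
  if (!kind %in% valid_kinds) {
    abort(sprintf(
      "Invalid `kind` '%s' for the %s pathway (expected one of: %s).",
      kind, pathway, paste(valid_kinds, collapse = ", ")
    ))
  }
  if (length(levels) == 0 || length(rates) == 0 || length(w_inh) == 0) {
    abort("`levels`, `rates` and `w_inh` must be non-empty.")
  }
  if (pathway == "electric" && any(levels < 0 | levels > 14)) {
    abort("Electric `levels` must lie within [0, 14] dB thr.")
  }
  if (pathway == "acoustic" && any(levels < 0 | levels > 70)) {
    abort("Acoustic `levels` must lie within [0, 70] dB SPL.")
  }
  structure(
    list(
      pathway = pathway, kind = kind, f_c = f_c, carrier_rate = carrier_rate,
      levels = levels, rates = rates, axis = axis,
      grid_step = grid_step %||% (if (axis == "itd") 0.1e-3 else 0.05 * pi),
      n_reps = n_reps %||% (if (pathway == "electric") 20L else 10L),
      w_inh = w_inh, reference_current = reference_current, seed = seed,
      duration = duration %||% (if (pathway == "electric") 0.6 else 1)
    ),
    class = "experiment_spec"
  )
}

make_stimulus <- function(spec, rate, level) {
  switch(spec$kind,
    unmodulated = gen_electric_train(rate,
      duration = spec$duration, level = level,
      reference_current = spec$reference_current
    ),
    sam_electric = gen_electric_train(spec$carrier_rate,
      duration = spec$duration, level = level, f_m = rate,
      reference_current = spec$reference_current
    ),
    sam = gen_sam_tone(spec$f_c, rate, spec$duration, level = level),
    transposed = gen_transposed_tone(spec$f_c, rate, spec$duration, level = level),
    ge = gen_ge_train(spec$f_c, rate, spec$duration, level = level),
    clicks = gen_filtered_clicks(spec$f_c, rate, spec$duration, level = level)
  )
}

#' Run a full sweep experiment
#'
#' Executes the protocol described by an [experiment_spec()]: for every
#' (level, rate, inhibitory-window) combination, synthesize the stimulus,
#' simulate the binaural periphery (`n_reps` repetitions, reused across
#' `w_inh` values), compute the rate-ITD/IPD tuning curve, and summarise it.
#' Fully deterministic given `spec$seed`: re-running an identical spec
#' reproduces identical tables.
#'
#' @param spec An [experiment_spec()].
#' @param out_dir Optional output directory; when given, tuning-curve and
#'   metrics CSVs plus a provenance JSON (the effective spec and seeds) are
#'   written there.
#' @param periphery Optional fiber parameter override.
#' @return A list with `curves` (long tibble over all conditions) and
#'   `metrics` (one row per condition: `sqrt_contrast`, `r_max`, `r_min`,
#'   `best`, `worst`).
#' @export
run_experiment <- function(spec, out_dir = NULL, periphery = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  grid <- if (spec$axis == "itd") {
    seq(-4e-3, 4e-3, by = spec$grid_step)
  } else {
    seq(-pi, pi, by = spec$grid_step)
  }
  curves <- list()
  metrics <- list()
  for (level in spec$levels) {
    for (rate in spec$rates) {
      stim <- make_stimulus(spec, rate, level)
      cond_seed <- derive_seed(spec$seed, round(level * 10), round(rate))
      ens <- binaural_ensembles(stim, spec$n_reps,
        ei = ei_params(),
        periphery = periphery, seed = cond_seed
      )
      for (w in spec$w_inh) {
        ei <- ei_params(w_inh = w)
        tc <- ei_tuning_curve(stim,
          axis = spec$axis, grid = grid, n_reps = spec$n_reps,
          ei = ei, periphery = periphery, seed = cond_seed, ensembles = ens
        )
        key <- tibble(
          level = level, rate = rate, w_inh = w,
          pathway = spec$pathway, kind = spec$kind
        )
        curve_tab <- as_tibble(tc)
        names(curve_tab) <- c("axis_value", "rep", "rate_sps")
        curves[[length(curves) + 1]] <-
          dplyr::bind_cols(key[rep(1, nrow(curve_tab)), ], curve_tab)
        metrics[[length(metrics) + 1]] <- dplyr::bind_cols(key, glance(tc))
      }
    }
  }
  res <- list(
    curves = list_rbind(curves), metrics = list_rbind(metrics),
    spec = spec, grid = grid
  )
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

#' Operationalized cutoff rate of ITD/IPD sensitivity
#'
#' The highest tested pulse rate or modulation frequency at which the
#' tuning-curve contrast `sqrt(r_max) - sqrt(r_min)` still reaches at least
#' half of its maximum over the tested rates. The inhibitory window sets
#' this limit: sensitivity collapses once the stimulation period falls
#' below about `w_inh`, so the cutoff scales as `1 / w_inh`.
#'
#' @param metrics A metrics tibble from [run_experiment()] (one `w_inh` and
#'   `level` at a time), with columns `rate` and `sqrt_contrast`.
#' @param frac Fraction of the maximum contrast defining the cutoff.
#' @return The cutoff rate (1/s).
#' @export
cutoff_rate <- function(metrics, frac = 0.5) {
  stopifnot(all(c("rate", "sqrt_contrast") %in% names(metrics)))
  thr <- frac * max(metrics$sqrt_contrast)
  max(metrics$rate[metrics$sqrt_contrast >= thr])
}

#' Hand-built spike-ensemble fixtures
#'
#' Deterministic fixture pairs for tests and worked examples:
#' `"full_volley"` (all 20 excitatory and 8 inhibitory spikes coincident
#' within their windows: net count +4), `"double_volley"` (two full
#' excitatory volleys `delta` apart, no inhibition), and `"poisson_pair"`
#' (seeded homogeneous-Poisson ensembles).
#'
#' @param name Fixture name.
#' @param delta Volley separation (s) for `"double_volley"`.
#' @param seed Seed for `"poisson_pair"`.
#' @param ei An [ei_params()] (fiber counts).
#' @param duration Fixture duration (s).
#' @return A list with `$exc` and `$inh` [spike_ensemble()]s.
#' @export
#' @examples
#' fx <- make_fixture_spikes("full_volley")
#' nrow(simulate_ei(fx$exc, fx$inh)) # 1
make_fixture_spikes <- function(name = c("full_volley", "double_volley", "poisson_pair"),
                                delta = 1e-3, seed = 1L, ei = ei_params(),
                                duration = 0.05) {
  name <- match.arg(name)
  t0 <- 0.010
  switch(name,
    full_volley = list(
      exc = spike_ensemble(
        tibble(fiber_id = seq_len(ei$n_exc), time = t0), duration
      ),
      inh = spike_ensemble(
        tibble(fiber_id = seq_len(ei$n_inh), time = t0 - 0.5e-3), duration
      )
    ),
    double_volley = list(
      exc = spike_ensemble(
        tibble(
          fiber_id = rep(seq_len(ei$n_exc), 2),
          time = rep(c(t0, t0 + delta), each = ei$n_exc)
        ),
        duration
      ),
      inh = spike_train(numeric(0), duration)
    ),
    poisson_pair = {
      hom <- function(n_fib, rate, s) {
        tt <- with_seed(s, {
          n <- stats::rpois(n_fib, rate * duration)
          tibble(
            fiber_id = rep(seq_len(n_fib), n),
            time = runif(sum(n), 0, duration)
          )
        })
        spike_ensemble(tt, duration)
      }
      list(
        exc = hom(ei$n_exc, 60, derive_seed(seed, 1)),
        inh = hom(ei$n_inh, 60, derive_seed(seed, 2))
      )
    }
  )
}
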