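#' Export stimuli, spikes and tuning curves as CSV with JSON sidecars
#'
#' Acoustic stimuli export as two-column CSV (`time_s`, `value`), electric
#' trains as (`pulse_time_s`, `amplitude_uA`); spike ensembles as
#' (`fiber_id`, `spike_time_s`); tuning curves as a long CSV
#' (`axis_value`, `rep`, `rate_sps`) plus a summary CSV
#' (`axis_value`, `mean_rate`). Each writer places a `.json` sidecar with
#' the metadata next to the CSV.
#'
#' @param x Object to export.
#' @param path Output CSV path.
#' @param meta Extra metadata recorded in the JSON sidecar.
#' @return The CSV path, invisibly.
#' @export
write_stimulus_csv <- function(x, path, meta = list()) {
  if (inherits(x, "acoustic_stimulus")) {
    df <- tidy(x)
    names(df) <- c("time_s", "value")
    side <- c(x[c("sample_rate", "kind", "f_c", "f_m", "level", "ramp", "duration")], meta)
  } else if (inherits(x, "electric_pulse_train")) {
    df <- tidy(x)
    names(df) <- c("pulse_time_s", "amplitude_uA")
    side <- c(
      x[c(
        "phase_duration", "polarity", "carrier_rate", "f_m", "level",
        "duration"
      )],
      meta
    )
  } else {
    abort("Unsupported stimulus class.")
  }
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_stimulus_csv
#' @export
write_spikes_csv <- function(x, path, meta = list()) {
  stopifnot(inherits(x, "spike_ensemble"))
  df <- as_tibble(x)
  names(df) <- c("fiber_id", "spike_time_s")
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(list(duration = ens_duration(x)), meta),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
write_tuning_csv <- function(x, path, meta = list()) {
  stopifnot(inherits(x, "tuning_curve"))
  df <- as_tibble(x)
  names(df) <- c("axis_value", "rep", "rate_sps")
  write.csv(df, path, row.names = FALSE)
  s <- tidy(x)
  write.csv(
    data.frame(axis_value = s$axis_value, mean_rate = s$mean_rate),
    sub("\\.csv$", "_summary.csv", path),
    row.names = FALSE
  )
  jsonlite::write_json(
    c(
      list(
        axis_kind = attr(x, "axis_kind"), window = attr(x, "window"),
        n_reps = max(x$rep)
      ),
      meta
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$curves, file.path(out_dir, "tuning_curves.csv"), row.names = FALSE)
  write.csv(res$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  spec <- res$spec
  prov <- c(
    unclass(spec),
    list(grid = res$grid, package_version = as.character(utils::packageVersion("itdsim")))
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Read an experiment specification from a YAML config file
#'
#' Recognized keys mirror the arguments of [experiment_spec()] (top level or
#' under `stimulus:`/`ei:`): `pathway`, `kind`, `f_c`, `f_m`/`rates`,
#' `carrier_rate`, `levels`/`level`, `axis`, `grid_step`, `n_reps`, `w_inh`
#' (seconds), `reference_current`, `seed`, `duration`. Unknown keys are
#' rejected with the offending name.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file (e.g. CLI
#'   flags).
#' @return An [experiment_spec()].
#' @export
read_experiment_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  flat <- c(cfg$stimulus, cfg$ei, cfg[setdiff(names(cfg), c("stimulus", "ei"))])
  if (!is.null(flat$level) && is.null(flat$levels)) flat$levels <- flat$level
  if (!is.null(flat$f_m) && is.null(flat$rates)) flat$rates <- flat$f_m
  flat$level <- NULL
  flat$f_m <- NULL
  flat[names(overrides)] <- overrides
  known <- names(formals(experiment_spec))
  bad <- setdiff(names(flat), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(experiment_spec, flat)
}
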