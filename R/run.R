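# Entry points behind the command-line interface: each reads inputs, runs
# one pipeline, and writes machine-readable reports. The JSON reports carry
# the full effective configuration (after defaults) and any clamp /
# immediate-failure warnings as data, so runs are reproducible from the
# report alone. Two runs with identical inputs and seed produce byte-identical
# reports.

.write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

.load_history <- function(history_csv = NULL, template = NULL,
                          n_cycles_gen = 5L, samples_per_cycle = 200L,
                          bpm = 70, period = NULL) {
  if (!is.null(history_csv) && !is.null(template)) {
    stop("give either `history_csv` or `template`, not both", call. = FALSE)
  }
  if (!is.null(history_csv)) {
    if (is.null(period)) period <- 60 / bpm
    read_history_csv(history_csv, period = period)
  } else if (!is.null(template)) {
    generate_cardiac_spectrum(template, n_cycles = n_cycles_gen,
                              samples_per_cycle = samples_per_cycle)
  } else {
    stop("one of `history_csv` or `template` is required", call. = FALSE)
  }
}

#' Run the fatigue-life pipeline and write reports
#'
#' Reads a stress history (CSV) or generates one from a template, runs
#' [fatigue_life_pipeline()] with the material config, and writes
#' `life_report.json` plus the per-sub-cycle breakdown
#' `life_breakdown.csv` into `out_dir`. Immediate-failure findings (clamped
#' sub-cycles) are reported in the JSON, not treated as errors.
#'
#' @param material_config Path to a YAML/JSON material config
#'   (see [read_material_config()]).
#' @param history_csv Path to a `time_s, stress_MPa` CSV, or `NULL`.
#' @param template A [spectrum_template()] used when `history_csv` is `NULL`.
#' @param out_dir Output directory, created if needed.
#' @param bpm Heart rate (default 70).
#' @param rel_tolerance Peak-similarity tolerance (default 0.05).
#' @param n_cycles Cardiac cycles in the history; `NULL` to infer.
#' @param clamp_negative_mean,endurance_limit See [spectrum_damage()].
#' @param n_cycles_gen,samples_per_cycle Generation size when a template is
#'   used.
#' @return The `fatigue_life_result`, invisibly.
#' @export
run_life <- function(material_config, history_csv = NULL, template = NULL,
                     out_dir = ".", bpm = 70, rel_tolerance = 0.05,
                     n_cycles = NULL, clamp_negative_mean = FALSE,
                     endurance_limit = NULL,
                     n_cycles_gen = 5L, samples_per_cycle = 200L) {
  cfg <- read_material_config(material_config)
  history <- .load_history(history_csv, template, n_cycles_gen,
                           samples_per_cycle, bpm)
  res <- fatigue_life_pipeline(history, cfg$material, bpm = bpm,
                               rel_tolerance = rel_tolerance,
                               n_cycles = n_cycles,
                               clamp_negative_mean = clamp_negative_mean,
                               endurance_limit = endurance_limit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$breakdown, file.path(out_dir, "life_breakdown.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  report <- list(
    label = res$label,
    damage_per_spectrum = res$damage_per_spectrum,
    total_life_cycles = if (res$infinite_life) "Inf" else res$total_life_cycles,
    duration_days = if (res$infinite_life) "Inf" else res$duration_days,
    duration_years = if (res$infinite_life) "Inf" else res$duration_years,
    infinite_life = res$infinite_life,
    warnings = list(
      clamped_subcycles = sum(res$breakdown$clamped)
    ),
    effective_config = list(
      material_config = material_config,
      history_csv = history_csv,
      template = if (is.null(template)) NULL else unclass(template),
      bpm = bpm, rel_tolerance = rel_tolerance,
      n_cycles = res$n_cycles,
      clamp_negative_mean = clamp_negative_mean,
      endurance_limit = endurance_limit
    ),
    breakdown = res$breakdown
  )
  .write_report_json(report, file.path(out_dir, "life_report.json"))
  invisible(res)
}

#' Run the tear-propagation pipeline and write reports
#'
#' Counts the per-cardiac-cycle spectrum of the input history, then grows an
#' elliptical tear with [propagate_crack()] and writes `crack_trajectory.csv`
#' plus `crack_report.json` (final axis lengths and stop status) into
#' `out_dir`.
#'
#' @inheritParams run_life
#' @param a0,b0 Initial semi-axes, mm (`a0 >= b0 > 0`).
#' @param cycles Number of cardiac cycles to simulate.
#' @param block_size Cardiac cycles per geometry refresh (default 1).
#' @param kt_convention `"paper-form"` or `"classical"`; see
#'   [stress_concentration_factor()].
#' @param max_axis_mm Tear-through threshold, mm (default `Inf`).
#' @return The `crack_growth_trajectory`, invisibly.
#' @export
run_crack <- function(material_config, history_csv = NULL, template = NULL,
                      a0 = 1, b0 = 0.5, cycles = 1000L, block_size = 1L,
                      kt_convention = "paper-form", max_axis_mm = Inf,
                      out_dir = ".", bpm = 70, rel_tolerance = 0.05,
                      n_cycles = NULL, n_cycles_gen = 5L,
                      samples_per_cycle = 200L) {
  cfg <- read_material_config(material_config)
  history <- .load_history(history_csv, template, n_cycles_gen,
                           samples_per_cycle, bpm)
  k <- if (is.null(n_cycles)) history_n_cycles(history) else n_cycles
  tp <- simplify_peaks(extract_turning_points(history),
                       rel_tolerance = rel_tolerance)
  sc <- per_cardiac_cycle(rainflow_count(tp), k)
  traj <- propagate_crack(elliptical_crack(a0, b0), sc, cfg$material,
                          n_cardiac_cycles = cycles, block_size = block_size,
                          kt_convention = kt_convention,
                          max_axis_mm = max_axis_mm)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory_csv(traj, file.path(out_dir, "crack_trajectory.csv"))
  report <- list(
    status = traj$status,
    cycles_run = traj$cycles_run,
    final_a_mm = traj$final$a,
    final_b_mm = traj$final$b,
    growth_a_mm = traj$final$a - a0,
    growth_b_mm = traj$final$b - b0,
    effective_config = list(
      material_config = material_config,
      history_csv = history_csv,
      template = if (is.null(template)) NULL else unclass(template),
      a0 = a0, b0 = b0, cycles = cycles, block_size = block_size,
      kt_convention = kt_convention, max_axis_mm = max_axis_mm,
      bpm = bpm, rel_tolerance = rel_tolerance, n_cycles = k
    )
  )
  .write_report_json(report, file.path(out_dir, "crack_report.json"))
  invisible(traj)
}

#' Generate a synthetic cardiac spectrum and write it as CSV
#'
#' @param template A [spectrum_template()].
#' @param out_csv Output CSV path (`time_s, stress_MPa`).
#' @param n_cycles,samples_per_cycle Generation size.
#' @return The generated [stress_history()], invisibly.
#' @export
run_simulate <- function(template, out_csv, n_cycles = 5L,
                         samples_per_cycle = 200L) {
  history <- generate_cardiac_spectrum(template, n_cycles = n_cycles,
                                       samples_per_cycle = samples_per_cycle)
  dir.create(dirname(out_csv), showWarnings = FALSE, recursive = TRUE)
  write_history_csv(history, out_csv)
  invisible(history)
}
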