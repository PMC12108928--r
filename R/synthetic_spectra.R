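# Seeded generator of cardiac-cycle-shaped stress histories. Stands in for
# fluid-structure-interaction output so every pipeline stage is testable:
# one dominant systolic extremum per cycle, a secondary diastolic feature of
# opposite sign, period set by heart rate, identical across cycles unless
# noise is added.

#' Cardiac load-spectrum template
#'
#' Describes the per-cardiac-cycle stress waveform at a leaflet integration
#' point: a dominant systolic peak of magnitude `peak_stress`, a secondary
#' diastolic feature of magnitude `diastolic_stress` with the opposite sign,
#' and the sign profile of the surface. On a compression-dominant surface
#' (outer leaflet surface during systolic root bending) the systolic peak is
#' compressive (negative) and the diastolic feature tensile; on a
#' tension-dominant surface the signs are reversed.
#'
#' @param peak_stress Systolic peak magnitude, MPa, positive.
#' @param diastolic_stress Diastolic feature magnitude, MPa, non-negative.
#' @param sign_profile `"compression-dominant"` or `"tension-dominant"`.
#' @param systole_fraction Fraction of the cardiac period in systole,
#'   in (0, 1); default 0.35 (physiological convention).
#' @param bpm Heart rate, beats per minute; default 70.
#' @param n_harmonics Integer smoothness control for the bump shape
#'   (exponent of the half-sine window); default 2.
#' @param noise_sd Additive Gaussian noise standard deviation, MPa;
#'   default 0.
#' @param seed Integer seed for the noise; default 1.
#' @param label Identifier carried into generated histories.
#' @return An object of class `spectrum_template`.
#' @export
spectrum_template <- function(peak_stress, diastolic_stress = 0,
                              sign_profile = c("compression-dominant",
                                               "tension-dominant"),
                              systole_fraction = 0.35, bpm = 70,
                              n_harmonics = 2L, noise_sd = 0, seed = 1L,
                              label = "template") {
  sign_profile <- match.arg(sign_profile)
  if (peak_stress <= 0) stop("`peak_stress` must be positive", call. = FALSE)
  if (diastolic_stress < 0) stop("`diastolic_stress` must be non-negative",
                                 call. = FALSE)
  if (systole_fraction <= 0 || systole_fraction >= 1) {
    stop("`systole_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (bpm <= 0) stop("`bpm` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(
    list(peak_stress = peak_stress, diastolic_stress = diastolic_stress,
         sign_profile = sign_profile, systole_fraction = systole_fraction,
         bpm = bpm, n_harmonics = as.integer(n_harmonics),
         noise_sd = noise_sd, seed = as.integer(seed),
         label = as.character(label)[1L]),
    class = "spectrum_template"
  )
}

#' Templates emulating the three virtual patients
#'
#' Encodes the printed systolic peak magnitudes of the three virtual-patient
#' load spectra (0.659, 0.632 and 1.676 MPa) together with their qualitative
#' surface descriptions: patients A and B are compression-dominant at the
#' failing (outer-surface) integration point, patient C tension-dominant at
#' the sharply folded cusp base with sustained dual-surface loading. The
#' diastolic load shares (0.15, 0.30 and 0.90 of the peak) encode the
#' reported relative severity of the three configurations: the smoothed
#' post-dilatation cusp fold of patient B sustains more of its load through
#' diastole than patient A's side fold, and patient C's non-recoverable fold
#' stays loaded throughout the cycle. These defaults are an emulation of the
#' published spectra's structure, not a reconstruction of their waveforms.
#'
#' @param patient `"A"`, `"B"` or `"C"`.
#' @param ... Overrides passed to [spectrum_template()].
#' @return A [spectrum_template()].
#' @export
#' @examples
#' patient_template("C")
patient_template <- function(patient = c("A", "B", "C"), ...) {
  patient <- match.arg(patient)
  base <- switch(patient,
    A = list(peak_stress = 0.659, diastolic_stress = 0.15 * 0.659,
             sign_profile = "compression-dominant"),
    B = list(peak_stress = 0.632, diastolic_stress = 0.30 * 0.632,
             sign_profile = "compression-dominant"),
    C = list(peak_stress = 1.676, diastolic_stress = 0.90 * 1.676,
             sign_profile = "tension-dominant")
  )
  base$label <- paste0("patient-", patient)
  args <- utils::modifyList(base, list(...))
  do.call(spectrum_template, args)
}

#' Generate a cardiac-cycle-shaped stress history from a template
#'
#' The per-cycle waveform is built from two smooth half-sine-power bumps:
#' the systolic bump spans the systolic window and reaches exactly
#' `peak_stress` (up to sample-grid discretisation) with the sign set by the
#' profile, and the diastolic bump spans the remainder of the period with
#' magnitude `diastolic_stress` and opposite sign. With `noise_sd = 0` every
#' cardiac cycle is bitwise identical (the stationarity assumption of the
#' fatigue model); noise is seeded Gaussian, so the history is deterministic
#' for a fixed template and seed. The caller's random number generator state
#' is left untouched.
#'
#' @param template A [spectrum_template()].
#' @param n_cycles Number of cardiac cycles, `>= 1`.
#' @param samples_per_cycle Samples per cardiac cycle, `>= 16`; default 200.
#' @return A [stress_history()] with `period = 60 / bpm` and `n_cycles` set.
#' @export
generate_cardiac_spectrum <- function(template, n_cycles = 1L,
                                      samples_per_cycle = 200L) {
  stopifnot(inherits(template, "spectrum_template"))
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (samples_per_cycle < 16) stop("`samples_per_cycle` must be >= 16",
                                   call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  samples_per_cycle <- as.integer(samples_per_cycle)
  period <- 60 / template$bpm
  f <- template$systole_fraction
  p <- max(1L, template$n_harmonics)
  u <- (seq_len(samples_per_cycle) - 1L) / samples_per_cycle  # phase in [0, 1)
  sys_w <- ifelse(u < f, sin(pi * u / f)^p, 0)
  dia_w <- ifelse(u >= f, sin(pi * (u - f) / (1 - f))^p, 0)
  s_sys <- if (template$sign_profile == "compression-dominant") -1 else 1
  cycle <- s_sys * template$peak_stress * sys_w -
    s_sys * template$diastolic_stress * dia_w
  stress <- rep(cycle, n_cycles)
  n <- length(stress)
  if (template$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(template$seed)
    stress <- stress + stats::rnorm(n, sd = template$noise_sd)
  }
  dt <- period / samples_per_cycle
  stress_history(time = (seq_len(n) - 1L) * dt, stress = stress,
                 label = template$label, period = period,
                 n_cycles = n_cycles)
}

#' Constant-amplitude (sinusoidal) stress history
#'
#' Oscillates between `s_min` and `s_max` once per cardiac cycle, starting
#' and ending each period at `s_min`; rainflow counting of one period yields
#' exactly one full cycle `(s_max, s_min)`. Used as the input for
#' closed-form checks of the fatigue and crack-growth predictions.
#'
#' @param s_max,s_min Cycle extremes, MPa, `s_max > s_min`.
#' @param n_cycles Number of cardiac cycles, `>= 1`.
#' @param samples_per_cycle Samples per cycle, `>= 16`; default 64.
#' @param bpm Heart rate, beats per minute; default 70.
#' @param label Identifier.
#' @return A [stress_history()].
#' @export
constant_amplitude_spectrum <- function(s_max, s_min, n_cycles = 1L,
                                        samples_per_cycle = 64L, bpm = 70,
                                        label = "constant-amplitude") {
  if (!(s_max > s_min)) stop("require `s_max` > `s_min`", call. = FALSE)
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (samples_per_cycle < 16) stop("`samples_per_cycle` must be >= 16",
                                   call. = FALSE)
  if (samples_per_cycle %% 2L != 0L) {
    stop("`samples_per_cycle` must be even so the peak lies on the grid",
         call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  samples_per_cycle <- as.integer(samples_per_cycle)
  period <- 60 / bpm
  u <- (seq_len(samples_per_cycle) - 1L) / samples_per_cycle
  mid <- (s_max + s_min) / 2
  amp <- (s_max - s_min) / 2
  cycle <- mid - amp * cos(2 * pi * u)
  # close the final period at s_min so its two residual half-cycles merge
  # into one full (s_max, s_min) cycle
  stress <- c(rep(cycle, n_cycles), s_min)
  dt <- period / samples_per_cycle
  stress_history(time = (seq_along(stress) - 1L) * dt, stress = stress,
                 label = label, period = period, n_cycles = n_cycles)
}
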