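# Fatigue life: Gerber pulsatile-equivalent correction, Basquin S-N life,
# Miner linear damage accumulation, and the end-to-end pipeline.

#' Material fatigue and fracture properties
#'
#' Collects the constants of the leaflet material used across the fatigue
#' and tear-growth calculations:
#' \describe{
#'   \item{su}{MPa, nominal ultimate tensile strength (Gerber denominator).}
#'   \item{sigma_f}{MPa, single-cycle fatigue strength limit of the Basquin
#'     curve, calibrated on pulsatile (R = 0) tests.}
#'   \item{beta}{dimensionless fatigue life exponent, negative; the slope of
#'     the high-cycle segment of the S-N curve in log-log coordinates.}
#'   \item{e_modulus}{MPa, elastic modulus (strain-energy-density notch solve).}
#'   \item{hardening_exp}{dimensionless work-hardening exponent of the cyclic
#'     Ramberg-Osgood law, in (0, 1].}
#'   \item{strength_coeff}{MPa, cyclic strength coefficient of the same law.}
#'   \item{paris_c}{Paris-law growth coefficient, in mm/cycle per
#'     (MPa*sqrt(mm))^m; units must match lengths in mm and stresses in MPa.}
#'   \item{paris_m}{dimensionless Paris-law growth exponent.}
#' }
#'
#' @param su,sigma_f,beta,e_modulus,hardening_exp,strength_coeff,paris_c,paris_m
#'   See description; invariants are validated.
#' @return An object of class `leaflet_material`.
#' @export
material_properties <- function(su, sigma_f, beta, e_modulus,
                                hardening_exp, strength_coeff,
                                paris_c, paris_m) {
  vals <- list(su = su, sigma_f = sigma_f, beta = beta,
               e_modulus = e_modulus, hardening_exp = hardening_exp,
               strength_coeff = strength_coeff,
               paris_c = paris_c, paris_m = paris_m)
  if (anyNA(unlist(vals))) stop("material properties must not be NA", call. = FALSE)
  if (su <= 0) stop("`su` must be positive", call. = FALSE)
  if (sigma_f <= 0) stop("`sigma_f` must be positive", call. = FALSE)
  if (beta >= 0) stop("`beta` (fatigue life exponent) must be negative", call. = FALSE)
  if (e_modulus <= 0) stop("`e_modulus` must be positive", call. = FALSE)
  if (hardening_exp <= 0 || hardening_exp > 1) {
    stop("`hardening_exp` must lie in (0, 1]", call. = FALSE)
  }
  if (strength_coeff <= 0) stop("`strength_coeff` must be positive", call. = FALSE)
  if (paris_c <= 0) stop("`paris_c` must be positive", call. = FALSE)
  if (paris_m <= 0) stop("`paris_m` must be positive", call. = FALSE)
  structure(vals, class = "leaflet_material")
}

#' @export
print.leaflet_material <- function(x, ...) {
  cat("<leaflet_material>\n")
  cat(sprintf("  S-N:    Su = %g MPa, sigma_f = %g MPa, beta = %g\n",
              x$su, x$sigma_f, x$beta))
  cat(sprintf("  cyclic: E = %g MPa, e = %g, K = %g MPa\n",
              x$e_modulus, x$hardening_exp, x$strength_coeff))
  cat(sprintf("  Paris:  C = %g mm/cycle/(MPa*sqrt(mm))^m, m = %g\n",
              x$paris_c, x$paris_m))
  invisible(x)
}

#' Gerber mean-stress correction to a pulsatile-equivalent amplitude
#'
#' Converts a cycle with alternating stress `s_a` and mean stress `s_m` to
#' the equivalent fatigue strength under fully pulsatile cycling via the
#' parabolic relation `s_a / SNf + (s_m / su)^2 = 1`, i.e.
#' `SNf = s_a / (1 - (s_m / su)^2)`. The squared term is sign-symmetric, so
#' compressive (negative) mean stress raises the equivalent amplitude exactly
#' as tensile mean stress does; set `clamp_negative_mean = TRUE` to zero out
#' negative means for sensitivity studies.
#'
#' A mean stress at or beyond the ultimate strength (`|s_m| >= su`) signals
#' immediate failure: `Inf` is returned with a warning and downstream life is
#' clamped to half a cycle.
#'
#' @param s_a Alternating stress amplitude, MPa, non-negative (vectorised).
#' @param s_m Mean stress, MPa, signed (vectorised).
#' @param su Nominal ultimate tensile strength, MPa.
#' @param clamp_negative_mean If `TRUE`, negative `s_m` is treated as zero.
#' @return Equivalent pulsatile amplitude `SNf` in MPa; `Inf` flags
#'   immediate failure.
#' @export
gerber_equivalent_stress <- function(s_a, s_m, su, clamp_negative_mean = FALSE) {
  if (any(s_a < 0)) stop("`s_a` must be non-negative", call. = FALSE)
  if (su <= 0) stop("`su` must be positive", call. = FALSE)
  if (clamp_negative_mean) s_m <- pmax(s_m, 0)
  fail <- abs(s_m) >= su
  if (any(fail)) {
    warning("mean stress at or beyond ultimate strength: immediate failure",
            call. = FALSE)
  }
  out <- s_a / (1 - (s_m / su)^2)
  out[fail] <- Inf
  out
}

#' Basquin S-N life
#'
#' Inverts the Basquin relation `SNf = sigma_f * (2 * Nf)^beta` to the number
#' of pulsatile cycles to failure, `Nf = 0.5 * (SNf / sigma_f)^(1 / beta)`.
#' Since `beta < 0`, life decreases monotonically with stress. Equivalent
#' stresses at or above `sigma_f` (including the `Inf` immediate-failure
#' signal) are clamped to half a cycle, the shortest physically countable
#' life, with a warning.
#'
#' @param snf Pulsatile-equivalent stress amplitude, MPa, positive
#'   (vectorised).
#' @param material A [material_properties()] object.
#' @return Cycles to failure `Nf >= 0.5`.
#' @export
basquin_life <- function(snf, material) {
  stopifnot(inherits(material, "leaflet_material"))
  if (any(snf <= 0)) stop("`snf` must be positive", call. = FALSE)
  clamp <- snf >= material$sigma_f
  if (any(clamp)) {
    warning("equivalent stress at or above sigma_f: life clamped to 0.5 cycles",
            call. = FALSE)
  }
  nf <- 0.5 * (snf / material$sigma_f)^(1 / material$beta)
  nf[clamp] <- 0.5
  nf
}

#' Miner damage of one load spectrum
#'
#' Linear damage accumulation over the counted sub-cycles of one cardiac
#' cycle: `D = sum(count / Nf)` with `Nf` from the Gerber-corrected Basquin
#' life of each sub-cycle. Zero-amplitude sub-cycles contribute no damage.
#'
#' @param subcycles A `subcycles` data frame from [rainflow_count()]
#'   (per-cardiac-cycle counts).
#' @param material A [material_properties()] object.
#' @param clamp_negative_mean Passed to [gerber_equivalent_stress()].
#' @param endurance_limit Optional amplitude threshold (MPa): sub-cycles with
#'   `s_a` at or below it are assigned zero damage. Default `NULL` (no
#'   threshold; damage accrues at all stress levels).
#' @return A list with `damage` (dimensionless, per spectrum) and `breakdown`,
#'   a data frame with one row per sub-cycle: `s_max`, `s_min`, `s_a`, `s_m`,
#'   `count`, `snf`, `nf`, `damage`, `clamped`.
#' @export
spectrum_damage <- function(subcycles, material, clamp_negative_mean = FALSE,
                            endurance_limit = NULL) {
  stopifnot(inherits(material, "leaflet_material"))
  n <- nrow(subcycles)
  if (n == 0L) {
    br <- data.frame(s_max = numeric(0), s_min = numeric(0), s_a = numeric(0),
                     s_m = numeric(0), count = numeric(0), snf = numeric(0),
                     nf = numeric(0), damage = numeric(0), clamped = logical(0))
    return(list(damage = 0, breakdown = br))
  }
  active <- subcycles$s_a > 0
  if (!is.null(endurance_limit)) {
    active <- active & subcycles$s_a > endurance_limit
  }
  snf <- rep(NA_real_, n)
  nf <- rep(Inf, n)
  dmg <- rep(0, n)
  clamped <- rep(FALSE, n)
  if (any(active)) {
    snf[active] <- gerber_equivalent_stress(
      subcycles$s_a[active], subcycles$s_m[active], material$su,
      clamp_negative_mean = clamp_negative_mean
    )
    nf[active] <- basquin_life(pmin(snf[active], Inf), material)
    clamped[active] <- snf[active] >= material$sigma_f
    dmg[active] <- subcycles$count[active] / nf[active]
  }
  breakdown <- data.frame(
    s_max = subcycles$s_max, s_min = subcycles$s_min,
    s_a = subcycles$s_a, s_m = subcycles$s_m, count = subcycles$count,
    snf = snf, nf = nf, damage = dmg, clamped = clamped
  )
  list(damage = sum(dmg), breakdown = breakdown)
}

#' Total expected life from per-spectrum damage
#'
#' Failure is declared when cumulative Miner damage reaches 1, so the total
#' expected life in cardiac cycles is the reciprocal of the damage accrued
#' per cardiac-cycle spectrum. Zero damage yields an infinite-life flag.
#'
#' @param damage_per_spectrum Non-negative dimensionless damage per spectrum.
#' @return Life in cycles (`Inf` when damage is zero).
#' @export
total_life <- function(damage_per_spectrum) {
  if (damage_per_spectrum < 0) {
    stop("damage must be non-negative", call. = FALSE)
  }
  if (damage_per_spectrum == 0) Inf else 1 / damage_per_spectrum
}

#' Convert a life in cardiac cycles to calendar time
#'
#' One cardiac cycle is one heart beat; at `bpm` beats per minute,
#' `days = L / (bpm * 60 * 24)` and `years = days / 365`.
#'
#' @param cycles Life in cardiac cycles, non-negative (vectorised).
#' @param bpm Heart rate in beats per minute (default 70).
#' @return A list with numeric `days` and `years`.
#' @export
#' @examples
#' cycles_to_duration(4.58e8, bpm = 70)  # about 12.4 years
cycles_to_duration <- function(cycles, bpm = 70) {
  if (any(cycles < 0)) stop("`cycles` must be non-negative", call. = FALSE)
  if (bpm <= 0) stop("`bpm` must be positive", call. = FALSE)
  days <- cycles / (bpm * 60 * 24)
  list(days = days, years = days / 365)
}

#' End-to-end fatigue life evaluation of a stress history
#'
#' Runs the full per-integration-point pipeline: turning-point extraction,
#' similar-peak averaging, rainflow counting (counts scaled to one cardiac
#' cycle), Gerber correction, Basquin life, Miner damage and total expected
#' life, reported in cycles and in calendar time at the given heart rate.
#' Deterministic for fixed input and settings.
#'
#' @param history A [stress_history()].
#' @param material A [material_properties()] object.
#' @param bpm Heart rate in beats per minute (default 70).
#' @param rel_tolerance Peak-similarity tolerance for [simplify_peaks()].
#' @param n_cycles Cardiac cycles spanned by the history; default inferred
#'   via [history_n_cycles()].
#' @param clamp_negative_mean,endurance_limit Passed to [spectrum_damage()].
#' @return An object of class `fatigue_life_result`: a list with
#'   `damage_per_spectrum`, `total_life_cycles`, `duration_days`,
#'   `duration_years`, `bpm`, `n_cycles`, `subcycles`, `breakdown`,
#'   `infinite_life` and `any_clamped`.
#' @export
fatigue_life_pipeline <- function(history, material, bpm = 70,
                                  rel_tolerance = 0.05, n_cycles = NULL,
                                  clamp_negative_mean = FALSE,
                                  endurance_limit = NULL) {
  stopifnot(inherits(history, "stress_history"),
            inherits(material, "leaflet_material"))
  if (is.null(n_cycles)) n_cycles <- history_n_cycles(history)
  tp <- extract_turning_points(history)
  tp <- simplify_peaks(tp, rel_tolerance = rel_tolerance)
  sc <- rainflow_count(tp)
  sc <- per_cardiac_cycle(sc, n_cycles)
  dm <- spectrum_damage(sc, material,
                        clamp_negative_mean = clamp_negative_mean,
                        endurance_limit = endurance_limit)
  life <- total_life(dm$damage)
  dur <- cycles_to_duration(if (is.finite(life)) life else 0, bpm = bpm)
  structure(
    list(
      label = history$label,
      damage_per_spectrum = dm$damage,
      total_life_cycles = life,
      duration_days = if (is.finite(life)) dur$days else Inf,
      duration_years = if (is.finite(life)) dur$years else Inf,
      bpm = bpm,
      n_cycles = n_cycles,
      subcycles = sc,
      breakdown = dm$breakdown,
      infinite_life = !is.finite(life),
      any_clamped = any(dm$breakdown$clamped)
    ),
    class = "fatigue_life_result"
  )
}

#' @export
print.fatigue_life_result <- function(x, ...) {
  cat(sprintf("<fatigue_life_result> %s\n", x$label))
  cat(sprintf("  damage per cardiac cycle: %.4g\n", x$damage_per_spectrum))
  if (x$infinite_life) {
    cat("  total expected life: infinite (zero damage per spectrum)\n")
  } else {
    cat(sprintf("  total expected life: %.4g cycles = %.4g days = %.4g years at %g bpm\n",
                x$total_life_cycles, x$duration_days, x$duration_years, x$bpm))
  }
  cat(sprintf("  %d counted sub-cycle(s); counts per cardiac cycle (k = %d)\n",
              nrow(x$subcycles), x$n_cycles))
  if (x$any_clamped) {
    cat("  warning: sub-cycle(s) at or above sigma_f clamped to 0.5 cycles\n")
  }
  invisible(x)
}
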