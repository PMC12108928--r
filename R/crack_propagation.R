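# Elliptical tear growth at the maximum-stress site: stress concentration,
# strain-energy-density (Glinka) notch stress, and Paris-law superposition.

#' Construct an elliptical crack
#'
#' The hypothesised initial tear at the maximum-stress concentration is
#' modelled as an ellipse with semi-major axis `a` and semi-minor axis `b`,
#' both in mm, with `a >= b > 0`.
#'
#' @param a Semi-major axis, mm.
#' @param b Semi-minor axis, mm.
#' @return An object of class `elliptical_crack`.
#' @export
elliptical_crack <- function(a, b) {
  if (!(b > 0) || !(a >= b)) {
    stop("require a >= b > 0 for an elliptical crack", call. = FALSE)
  }
  structure(list(a = a, b = b), class = "elliptical_crack")
}

#' @export
print.elliptical_crack <- function(x, ...) {
  cat(sprintf("<elliptical_crack> a = %g mm, b = %g mm (Kt = %g)\n",
              x$a, x$b, stress_concentration_factor(x)))
  invisible(x)
}

#' Stress concentration factor of an elliptical crack
#'
#' Default convention is `Kt = 1 + 2 b / a`, which lies in (1, 3] for
#' `a >= b` and reaches 3 at the circular limit. The classical
#' elliptical-hole factor under remote tension normal to the major axis is
#' `Kt = 1 + 2 a / b`; select it with `convention = "classical"` to probe the
#' sensitivity of the growth prediction to this choice.
#'
#' @param crack An [elliptical_crack()], or a semi-major axis if `b` given.
#' @param b Semi-minor axis when `crack` is numeric.
#' @param convention `"paper-form"` (default, `1 + 2b/a`) or `"classical"`
#'   (`1 + 2a/b`). `"paper"` is accepted as an alias of `"paper-form"`.
#' @return Dimensionless `Kt`.
#' @export
stress_concentration_factor <- function(crack, b = NULL,
                                        convention = c("paper-form", "classical",
                                                       "paper")) {
  convention <- match.arg(convention)
  if (inherits(crack, "elliptical_crack")) {
    a <- crack$a; b <- crack$b
  } else {
    a <- crack
    if (is.null(b)) stop("supply `b` when `crack` is a bare axis", call. = FALSE)
  }
  if (a <= 0 || b <= 0) stop("axes must be positive", call. = FALSE)
  if (convention == "classical") 1 + 2 * a / b else 1 + 2 * b / a
}

#' Local stress at the crack by the strain-energy-density (Glinka) criterion
#'
#' Equates the strain energy density of the linear-elastic concentrated
#' stress `Kt * S` with that of the elastic-plastic (Ramberg-Osgood) response
#' at the crack, and solves
#' `sigma^2 / E + (2 sigma / (e + 1)) * (sigma / K)^(1/e) = (Kt * S)^2 / E`
#' for the local stress `sigma`. The left side is strictly increasing in
#' `sigma > 0`, so the root in `(0, Kt * S]` is unique; it is bracketed and
#' refined by bisection until the residual is below `1e-10` times the right
#' side. Negative applied stress is solved on the magnitude and the sign
#' restored; `S = 0` returns 0.
#'
#' @param s Applied (nominal) stress `S`, MPa, signed (vectorised).
#' @param kt Stress concentration factor, `>= 1`.
#' @param material A [material_properties()] (uses `e_modulus`,
#'   `hardening_exp`, `strength_coeff`).
#' @param rel_residual Convergence criterion relative to the elastic energy
#'   term (default `1e-10`).
#' @param max_iter Bisection iteration budget (default 200).
#' @return Local stress `sigma` in MPa, `|sigma| <= Kt * |S|`.
#' @export
glinka_notch_stress <- function(s, kt, material, rel_residual = 1e-10,
                                max_iter = 200L) {
  stopifnot(inherits(material, "leaflet_material"))
  if (kt < 1) stop("`kt` must be >= 1", call. = FALSE)
  E <- material$e_modulus
  e <- material$hardening_exp
  K <- material$strength_coeff
  solve_one <- function(s_i) {
    if (s_i == 0) return(0)
    sgn <- sign(s_i)
    rhs <- (kt * abs(s_i))^2 / E
    lhs <- function(x) x^2 / E + (2 * x / (e + 1)) * (x / K)^(1 / e)
    upper <- kt * abs(s_i)   # lhs(upper) >= rhs since the plastic term is >= 0
    lo <- 0; hi <- upper
    it <- 0L
    repeat {
      mid <- (lo + hi) / 2
      r <- lhs(mid) - rhs
      if (abs(r) <= rel_residual * rhs || (hi - lo) < .Machine$double.eps * upper) {
        return(sgn * mid)
      }
      if (r > 0) hi <- mid else lo <- mid
      it <- it + 1L
      if (it > max_iter) {
        stop(sprintf(
          "Glinka solve did not converge: S = %g, Kt = %g, residual = %g",
          s_i, kt, r), call. = FALSE)
      }
    }
  }
  vapply(s, solve_one, numeric(1))
}

#' Stress intensity factor range
#'
#' `dK = (sigma_max - sigma_min) * sqrt(pi * alpha)` with the crack length
#' parameter `alpha` in mm and stresses in MPa, giving `dK` in MPa*sqrt(mm).
#' No geometry shape factor is applied (Y = 1).
#'
#' @param sigma_max,sigma_min Local stress extremes at the crack, MPa;
#'   `sigma_max >= sigma_min` (vectorised).
#' @param axis_length Crack length parameter, mm, positive.
#' @return `dK` in MPa*sqrt(mm).
#' @export
stress_intensity_range <- function(sigma_max, sigma_min, axis_length) {
  if (any(sigma_max < sigma_min)) {
    stop("`sigma_max` must be >= `sigma_min`", call. = FALSE)
  }
  if (any(axis_length <= 0)) stop("`axis_length` must be positive", call. = FALSE)
  (sigma_max - sigma_min) * sqrt(pi * axis_length)
}

#' Paris-law growth increment per cycle
#'
#' `d_alpha = C * dK^m` mm per cycle; zero range gives zero growth.
#'
#' @param delta_k Stress intensity factor range, MPa*sqrt(mm), non-negative
#'   (vectorised).
#' @param material A [material_properties()] (uses `paris_c`, `paris_m`).
#' @return Growth increment in mm per cycle.
#' @export
paris_increment <- function(delta_k, material) {
  stopifnot(inherits(material, "leaflet_material"))
  if (any(delta_k < 0)) stop("`delta_k` must be non-negative", call. = FALSE)
  ifelse(delta_k == 0, 0, material$paris_c * delta_k^material$paris_m)
}

#' Propagate an elliptical tear under a repeated cardiac load spectrum
#'
#' For every cardiac cycle, each counted sub-cycle loads the crack once
#' (weighted by its fractional count; half-cycles contribute 0.5 by default).
#' Per sub-cycle the current geometry gives `Kt`; the sub-cycle's stress
#' extremes are mapped to local stresses at the crack by
#' [glinka_notch_stress()]; the stress intensity range along each axis uses
#' the axis-swap rule (growth of the tear along the major axis uses the
#' semi-minor axis `b` as length parameter, and vice versa); and the Paris
#' increments, summed over the sub-cycles, extend both semi-axes. Geometry
#' (and hence `Kt` and `dK`) is refreshed after each block of `block_size`
#' cardiac cycles; `block_size = 1` refreshes every cycle and is the limit
#' the superposition of per-cycle increments approximates.
#'
#' @param crack0 Initial [elliptical_crack()].
#' @param subcycles A per-cardiac-cycle `subcycles` table from
#'   [rainflow_count()] / [per_cardiac_cycle()].
#' @param material A [material_properties()] object.
#' @param n_cardiac_cycles Total cardiac cycles to simulate, `>= 1`.
#' @param block_size Cardiac cycles per geometry refresh (default 1).
#' @param kt_convention Passed to [stress_concentration_factor()].
#' @param half_cycle_weight Weight applied to fractional counts; the default
#'   `TRUE` keeps the 0.5 weighting of residual half-cycles, `FALSE` drops
#'   sub-cycles with fractional count below 1 (full cycles only).
#' @param max_axis_mm Early-stop threshold: if either semi-axis exceeds this
#'   length (e.g. a leaflet dimension) the run stops with status
#'   `"tear-through"`. Default `Inf`.
#' @return An object of class `crack_growth_trajectory`: a list with
#'   `trajectory` (data frame `cycle, a_mm, b_mm, kt, dK_major, dK_minor`
#'   recorded at block boundaries, row 1 at cycle 0), `final` (crack after
#'   the last completed block), `status` (`"completed"` or `"tear-through"`),
#'   and `cycles_run`.
#' @export
propagate_crack <- function(crack0, subcycles, material, n_cardiac_cycles,
                            block_size = 1L,
                            kt_convention = c("paper-form", "classical", "paper"),
                            half_cycle_weight = TRUE,
                            max_axis_mm = Inf) {
  stopifnot(inherits(crack0, "elliptical_crack"),
            inherits(material, "leaflet_material"))
  kt_convention <- match.arg(kt_convention)
  if (n_cardiac_cycles < 1) stop("`n_cardiac_cycles` must be >= 1", call. = FALSE)
  block_size <- max(1L, as.integer(block_size))
  sc <- subcycles[subcycles$s_a > 0, , drop = FALSE]
  if (!half_cycle_weight) sc <- sc[sc$count >= 1, , drop = FALSE]
  a <- crack0$a; b <- crack0$b
  n_blocks <- ceiling(n_cardiac_cycles / block_size)
  rec_cycle <- numeric(n_blocks + 1L)
  rec_a <- numeric(n_blocks + 1L); rec_b <- numeric(n_blocks + 1L)
  rec_kt <- numeric(n_blocks + 1L)
  rec_dkM <- numeric(n_blocks + 1L); rec_dkm <- numeric(n_blocks + 1L)
  status <- "completed"
  cycles_done <- 0
  i <- 1L
  rec_cycle[1L] <- 0; rec_a[1L] <- a; rec_b[1L] <- b
  kt0 <- stress_concentration_factor(a, b, convention = kt_convention)
  rec_kt[1L] <- kt0; rec_dkM[1L] <- NA_real_; rec_dkm[1L] <- NA_real_
  while (cycles_done < n_cardiac_cycles) {
    nb <- min(block_size, n_cardiac_cycles - cycles_done)
    kt <- stress_concentration_factor(a, b, convention = kt_convention)
    da <- 0; db <- 0; dkM <- 0; dkm <- 0
    if (nrow(sc) > 0L) {
      sig_max <- glinka_notch_stress(sc$s_max, kt, material)
      sig_min <- glinka_notch_stress(sc$s_min, kt, material)
      rng <- sig_max - sig_min
      # axis-swap rule: major-axis tear length uses b, minor-axis uses a
      dk_major <- rng * sqrt(pi * b)
      dk_minor <- rng * sqrt(pi * a)
      da <- sum(sc$count * paris_increment(dk_major, material)) * nb
      db <- sum(sc$count * paris_increment(dk_minor, material)) * nb
      dkM <- max(dk_major); dkm <- max(dk_minor)
    }
    a <- a + da
    b <- b + db
    cycles_done <- cycles_done + nb
    i <- i + 1L
    rec_cycle[i] <- cycles_done
    rec_a[i] <- a; rec_b[i] <- b; rec_kt[i] <- kt
    rec_dkM[i] <- dkM; rec_dkm[i] <- dkm
    if (max(a, b) > max_axis_mm) {
      status <- "tear-through"
      break
    }
  }
  keep <- seq_len(i)
  traj <- data.frame(cycle = rec_cycle[keep], a_mm = rec_a[keep],
                     b_mm = rec_b[keep], kt = rec_kt[keep],
                     dK_major = rec_dkM[keep], dK_minor = rec_dkm[keep])
  structure(
    list(trajectory = traj,
         final = list(a = a, b = b),
         status = status,
         cycles_run = cycles_done),
    class = "crack_growth_trajectory"
  )
}

#' @export
print.crack_growth_trajectory <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat("<crack_growth_trajectory>\n")
  cat(sprintf("  %g cardiac cycles, status: %s\n", x$cycles_run, x$status))
  cat(sprintf("  a: %g -> %g mm; b: %g -> %g mm\n",
              x$trajectory$a_mm[1L], x$final$a,
              x$trajectory$b_mm[1L], x$final$b))
  invisible(x)
}

#' Write a crack growth trajectory as CSV
#'
#' Columns `cycle, a_mm, b_mm, kt, dK_major, dK_minor`.
#'
#' @param trajectory A `crack_growth_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory$trajectory, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
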