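material_with <- function(...) {
  args <- utils::modifyList(
    list(su = 10, sigma_f = 7, beta = -0.09, e_modulus = 2,
         hardening_exp = 0.3, strength_coeff = 15,
         paris_c = 1e-7, paris_m = 3),
    list(...)
  )
  do.call(material_properties, args)
}

test_that("material property invariants are validated", {
  expect_s3_class(material_with(), "leaflet_material")
  expect_error(material_with(beta = 0.1), "beta")
  expect_error(material_with(su = -1), "su")
  expect_error(material_with(hardening_exp = 1.5), "hardening_exp")
  expect_error(material_with(paris_c = 0), "paris_c")
})

test_that("Gerber correction maps cycles to pulsatile-equivalent amplitudes", {
  expect_equal(gerber_equivalent_stress(0.3, 0, 10), 0.3)
  expect_equal(gerber_equivalent_stress(0.3, 5, 10), 0.4)
  # the squared mean-stress term is sign-symmetric
  expect_equal(gerber_equivalent_stress(0.3, -5, 10), 0.4)
  # optional zero-clamp of compressive means for sensitivity studies
  expect_equal(gerber_equivalent_stress(0.3, -5, 10, clamp_negative_mean = TRUE),
               0.3)
  # mean stress at the ultimate strength signals immediate failure
  expect_warning(out <- gerber_equivalent_stress(0.3, 10, 10), "immediate")
  expect_identical(out, Inf)
  expect_error(gerber_equivalent_stress(-0.1, 0, 10), "non-negative")
})

test_that("Gerber equivalent stress grows with |mean| and tends to s_a at zero mean", {
  sm <- seq(0, 9, by = 0.5)
  snf <- gerber_equivalent_stress(rep(0.3, length(sm)), sm, 10)
  expect_true(all(diff(snf) > 0))
  expect_equal(snf[1], 0.3)
  expect_equal(gerber_equivalent_stress(0.3, 1e-8, 10), 0.3, tolerance = 1e-10)
  # symmetric in the sign of the mean
  expect_equal(gerber_equivalent_stress(0.3, -sm, 10), snf)
})

test_that("Basquin life inverts the S-N relation and clamps at sigma_f", {
  m <- material_with(sigma_f = 10, beta = -0.1)
  # the single-cycle strength boundary clamps (with a warning) to half a cycle
  expect_warning(nf <- basquin_life(10, m), "clamped")
  expect_equal(nf, 0.5)
  expect_equal(basquin_life(5, m), 512)    # 0.5 * (0.5)^(-10)
  # algebraic round trip over a range of lives (n = 0.5 sits on the boundary)
  for (n in c(0.5, 1, 10, 1e3, 1e7)) {
    snf <- m$sigma_f * (2 * n)^m$beta
    expect_equal(suppressWarnings(basquin_life(snf, m)), n, tolerance = 1e-10)
  }
  # monotone decreasing in stress
  lives <- basquin_life(c(1, 2, 4, 8), m)
  expect_true(all(diff(lives) < 0))
  expect_warning(out <- basquin_life(11, m), "clamped")
  expect_equal(out, 0.5)
  expect_error(basquin_life(0, m), "positive")
})

test_that("Miner damage sums count-weighted reciprocal lives", {
  m <- material_with()
  # one full cycle whose equivalent stress gives a known life
  sc <- data.frame(s_max = 1, s_min = 0, s_a = 0.5, s_m = 0.5, count = 1)
  nf <- basquin_life(gerber_equivalent_stress(0.5, 0.5, m$su), m)
  expect_equal(spectrum_damage(sc, m)$damage, 1 / nf)
  # half-cycle weighting
  sc$count <- 0.5
  expect_equal(spectrum_damage(sc, m)$damage, 0.5 / nf)
  # empty spectrum and zero-amplitude cycles contribute nothing
  expect_equal(spectrum_damage(sc[0, ], m)$damage, 0)
  sc0 <- data.frame(s_max = 0.5, s_min = 0.5, s_a = 0, s_m = 0.5, count = 2)
  expect_equal(spectrum_damage(sc0, m)$damage, 0)
  # immediate failure propagates as a half-cycle life
  schot <- data.frame(s_max = 21, s_min = 1, s_a = 10, s_m = 11, count = 1)
  # both the Gerber stage (|s_m| >= su) and the Basquin clamp warn
  ws <- capture_warnings(d <- spectrum_damage(schot, m)$damage)
  expect_match(ws, "immediate|clamped", all = TRUE)
  expect_gte(length(ws), 1)
  expect_equal(d, 1 / 0.5)
})

test_that("total life is the reciprocal of per-spectrum damage", {
  expect_equal(total_life(2.183e-9), 1 / 2.183e-9)
  expect_identical(total_life(0), Inf)
  expect_equal(total_life(1), 1)
  expect_error(total_life(-1), "non-negative")
})

test_that("cycle counts convert to calendar durations at a heart rate", {
  d <- cycles_to_duration(4.40e5, bpm = 70)
  expect_equal(d$days, 4.365079, tolerance = 1e-6)
  d <- cycles_to_duration(4.58e8, bpm = 70)
  expect_equal(d$years, 12.44836, tolerance = 1e-6)
  expect_equal(cycles_to_duration(0)$days, 0)
  # one day of beats at 1 bpm
  expect_equal(cycles_to_duration(60 * 24, bpm = 1)$days, 1)
})

test_that("Miner linearity: scaling counts scales damage and inverts life", {
  m <- material_with()
  set.seed(5)
  sc <- rainflow_count(random_alternating(11) / 3)
  d1 <- spectrum_damage(sc, m)$damage
  for (c_fac in c(0.5, 2, 10)) {
    sc2 <- sc
    sc2$count <- sc$count * c_fac
    expect_equal(spectrum_damage(sc2, m)$damage, c_fac * d1, tolerance = 1e-12)
    expect_equal(total_life(spectrum_damage(sc2, m)$damage),
                 total_life(d1) / c_fac, tolerance = 1e-12)
  }
})

test_that("life never increases with amplitude or |mean stress|", {
  m <- material_with()
  base <- data.frame(s_max = 1, s_min = -0.2, s_a = 0.6, s_m = 0.4, count = 1)
  life_of <- function(sc) total_life(spectrum_damage(sc, m)$damage)
  l0 <- life_of(base)
  for (ds in c(0.05, 0.2, 0.5)) {
    up_a <- base
    up_a$s_a <- base$s_a + ds
    up_a$s_max <- up_a$s_m + up_a$s_a
    up_a$s_min <- up_a$s_m - up_a$s_a
    expect_lte(life_of(up_a), l0)
    for (sgn in c(-1, 1)) {
      up_m <- base
      up_m$s_m <- sgn * (abs(base$s_m) + ds)
      up_m$s_max <- up_m$s_m + up_m$s_a
      up_m$s_min <- up_m$s_m - up_m$s_a
      expect_lte(life_of(up_m), l0)
    }
  }
})

test_that("constant-amplitude pipeline reproduces the single-cycle life", {
  m <- material_with()
  s_peak <- 1.2
  h <- constant_amplitude_spectrum(s_peak, 0, n_cycles = 6)
  res <- fatigue_life_pipeline(h, m)
  snf <- gerber_equivalent_stress(s_peak / 2, s_peak / 2, m$su)
  expect_equal(res$total_life_cycles, basquin_life(snf, m), tolerance = 1e-9)
  expect_equal(sum(res$subcycles$count), 1)  # one full cycle per cardiac cycle
})

test_that("zero-stress history yields the infinite-life flag", {
  h <- stress_history(0:9 / 10, rep(0, 10))
  res <- fatigue_life_pipeline(h, material_with())
  expect_true(res$infinite_life)
  expect_identical(res$total_life_cycles, Inf)
  expect_equal(res$damage_per_spectrum, 0)
})

test_that("S-N parameters are recovered from pipeline lives at five stress levels", {
  m <- material_with()
  levels <- c(0.5, 1, 1.5, 2, 2.5)
  lives <- vapply(levels, function(s) {
    fatigue_life_pipeline(
      constant_amplitude_spectrum(s, 0, n_cycles = 3), m
    )$total_life_cycles
  }, numeric(1))
  snf <- gerber_equivalent_stress(levels / 2, levels / 2, m$su)
  fit <- lm(log(snf) ~ log(2 * lives))
  beta_hat <- unname(coef(fit)[2])
  sigma_f_hat <- exp(unname(coef(fit)[1]))
  expect_lt(abs(beta_hat - m$beta) / abs(m$beta), 0.01)
  expect_lt(abs(sigma_f_hat - m$sigma_f) / m$sigma_f, 0.01)
})

test_that("pipeline results are deterministic and internally consistent", {
  m <- material_with()
  h <- generate_cardiac_spectrum(patient_template("B"), n_cycles = 5)
  r1 <- fatigue_life_pipeline(h, m)
  r2 <- fatigue_life_pipeline(h, m)
  expect_identical(r1$total_life_cycles, r2$total_life_cycles)
  expect_equal(r1$damage_per_spectrum, sum(r1$breakdown$damage))
  expect_equal(r1$total_life_cycles, 1 / r1$damage_per_spectrum)
  expect_false(r1$infinite_life)
})
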