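crack_material <- function(...) {
  args <- utils::modifyList(
    list(su = 10, sigma_f = 7, beta = -0.09, e_modulus = 2,
         hardening_exp = 0.3, strength_coeff = 15,
         paris_c = 1e-7, paris_m = 3),
    list(...)
  )
  do.call(material_properties, args)
}

test_that("elliptical stress concentration follows the configured convention", {
  expect_equal(stress_concentration_factor(elliptical_crack(1, 1)), 3)
  expect_equal(stress_concentration_factor(elliptical_crack(2, 1)), 2)
  # slit limit of the default form
  expect_equal(stress_concentration_factor(5, 1e-9), 1, tolerance = 1e-8)
  # classical elliptical-hole factor as the alternative convention
  expect_equal(stress_concentration_factor(2, 1, convention = "classical"), 5)
  expect_error(elliptical_crack(0, 0), "a >= b > 0")
  expect_error(elliptical_crack(1, 2), "a >= b > 0")
  expect_error(stress_concentration_factor(0, 1), "positive")
})

test_that("strain-energy-density notch stress solves the energy balance", {
  m <- crack_material(e_modulus = 1000, hardening_exp = 0.2,
                      strength_coeff = 50)
  # zero load
  expect_identical(glinka_notch_stress(0, 3, m), 0)
  # frozen value from the independent bisection oracle (E=1000, e=0.2, K=50)
  expect_equal(glinka_notch_stress(5, 3, m), 13.74757, tolerance = 1e-6)
  # linear-elastic limit: huge strength coefficient kills the plastic term
  m_lin <- crack_material(e_modulus = 1000, strength_coeff = 1e9)
  expect_equal(glinka_notch_stress(5, 3, m_lin), 15, tolerance = 1e-6)
  # negative load is solved on the magnitude with the sign restored
  expect_equal(glinka_notch_stress(-5, 3, m), -glinka_notch_stress(5, 3, m))
})

test_that("notch stress matches dense bisection across a parameter grid", {
  grid <- expand.grid(E = c(2, 1000), e = c(0.2, 0.3, 0.5),
                      K = c(15, 50), kt = c(1.5, 3), s = c(0.5, 5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- crack_material(e_modulus = g$E, hardening_exp = g$e,
                        strength_coeff = g$K)
    sig <- glinka_notch_stress(g$s, g$kt, m)
    ref <- oracle_glinka_bisection(g$s, g$kt, g$E, g$e, g$K)
    expect_equal(sig, ref, tolerance = 1e-7,
                 info = paste(unlist(g), collapse = " "))
    # residual of the returned root against the elastic energy term
    rhs <- (g$kt * g$s)^2 / g$E
    lhs <- sig^2 / g$E + (2 * sig / (g$e + 1)) * (sig / g$K)^(1 / g$e)
    expect_lte(abs(lhs - rhs), 1e-10 * rhs)
    # uniqueness bracket: the balance changes sign across (0, Kt*S]
    expect_lt(0 - rhs, 0)
    upper <- g$kt * g$s
    expect_gte(upper^2 / g$E + (2 * upper / (g$e + 1)) * (upper / g$K)^(1 / g$e),
               rhs)
  }
})

test_that("stress intensity range and Paris increment evaluate as written", {
  expect_equal(stress_intensity_range(2, 2, 1), 0)
  expect_equal(stress_intensity_range(2, 0, 1 / pi), 2)
  expect_equal(stress_intensity_range(3, 1, 4), 7.089815, tolerance = 1e-6)
  expect_error(stress_intensity_range(0, 1, 1), "sigma_max")

  m <- crack_material(paris_c = 1e-8, paris_m = 3)
  expect_identical(paris_increment(0, m), 0)
  expect_equal(paris_increment(10, m), 1e-5)
  expect_equal(paris_increment(8, m) / paris_increment(4, m), 2^3)
})

test_that("a constant-increment block reproduces plain superposition", {
  m <- crack_material()
  sc <- data.frame(s_max = 1, s_min = 0, s_a = 0.5, s_m = 0.5, count = 1)
  crack <- elliptical_crack(2, 1)
  n <- 500
  # one block: geometry (and dK) frozen at the initial crack
  traj <- propagate_crack(crack, sc, m, n_cardiac_cycles = n, block_size = n)
  kt <- stress_concentration_factor(crack)
  rng <- glinka_notch_stress(1, kt, m) - glinka_notch_stress(0, kt, m)
  dk_major <- rng * sqrt(pi * crack$b)   # major-axis tear length uses b
  dk_minor <- rng * sqrt(pi * crack$a)
  expect_equal(traj$final$a, crack$a + n * m$paris_c * dk_major^m$paris_m,
               tolerance = 1e-12)
  expect_equal(traj$final$b, crack$b + n * m$paris_c * dk_minor^m$paris_m,
               tolerance = 1e-12)
  expect_equal(traj$status, "completed")
})

test_that("circular-crack growth matches the closed-form Paris integral", {
  for (m_exp in c(2.5, 3, 4)) {
    mat <- crack_material(paris_c = 1e-7, paris_m = m_exp)
    sc <- data.frame(s_max = 1, s_min = 0, s_a = 0.5, s_m = 0.5, count = 1)
    a0 <- 0.5
    n <- 2000
    traj <- propagate_crack(elliptical_crack(a0, a0), sc, mat,
                            n_cardiac_cycles = n, block_size = 1)
    # a = b throughout, so Kt = 3 and the local stress range is constant
    rng <- glinka_notch_stress(1, 3, mat) - glinka_notch_stress(0, 3, mat)
    ref <- oracle_paris_closed_form(a0, rng, mat$paris_c, m_exp, n)
    expect_gt(ref, a0)  # the oracle itself must predict growth
    expect_equal(traj$final$a, ref, tolerance = 0.01)
    expect_equal(traj$final$b, traj$final$a, tolerance = 1e-12)
  }
})

test_that("tear growth is monotone and zero-amplitude spectra leave the crack unchanged", {
  m <- crack_material()
  set.seed(9)
  sc <- per_cardiac_cycle(rainflow_count(random_alternating(9) / 4), 1)
  traj <- propagate_crack(elliptical_crack(1.5, 0.8), sc, m,
                          n_cardiac_cycles = 200, block_size = 10)
  expect_true(all(diff(traj$trajectory$a_mm) >= 0))
  expect_true(all(diff(traj$trajectory$b_mm) >= 0))

  sc0 <- data.frame(s_max = 0.4, s_min = 0.4, s_a = 0, s_m = 0.4, count = 1)
  traj0 <- propagate_crack(elliptical_crack(1, 0.5), sc0, m,
                           n_cardiac_cycles = 100)
  expect_equal(traj0$final$a, 1)
  expect_equal(traj0$final$b, 0.5)
})

test_that("halving the geometry-refresh block barely changes the outcome", {
  m <- crack_material()
  sc <- data.frame(s_max = 1.676, s_min = -0.5, s_a = 1.088, s_m = 0.588,
                   count = 1)
  run <- function(bs) {
    propagate_crack(elliptical_crack(1, 0.5), sc, m,
                    n_cardiac_cycles = 400, block_size = bs)$final
  }
  f1 <- run(1); f2 <- run(2); f4 <- run(4)
  d21 <- abs(f2$a - f1$a)
  d42 <- abs(f4$a - f2$a)
  expect_lt(d21 / f1$a, 1e-4)
  expect_lte(d21, d42 + 1e-15)  # Richardson-style: refinement shrinks the change
})

test_that("a crack exceeding the leaflet dimension stops with tear-through", {
  m <- crack_material(paris_c = 1e-2)
  sc <- data.frame(s_max = 2, s_min = 0, s_a = 1, s_m = 1, count = 1)
  traj <- propagate_crack(elliptical_crack(1, 0.5), sc, m,
                          n_cardiac_cycles = 10000, block_size = 1,
                          max_axis_mm = 1.5)
  expect_equal(traj$status, "tear-through")
  expect_lt(traj$cycles_run, 10000)
  expect_gt(max(traj$final$a, traj$final$b), 1.5)
})

test_that("trajectory CSV export carries the documented columns", {
  m <- crack_material()
  sc <- data.frame(s_max = 1, s_min = 0, s_a = 0.5, s_m = 0.5, count = 1)
  traj <- propagate_crack(elliptical_crack(1, 0.5), sc, m,
                          n_cardiac_cycles = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  df <- read.csv(path)
  expect_named(df, c("cycle", "a_mm", "b_mm", "kt", "dK_major", "dK_minor"))
  expect_equal(df$cycle[1], 0)
  expect_equal(df$a_mm[1], 1)
})
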