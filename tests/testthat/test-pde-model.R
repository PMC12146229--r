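test_that("phase schedule follows from the progression velocities", {
  sch <- phase_schedule(pde_params(v = 1 / 16, u = 1 / 28))
  expect_equal(c(sch$L1, sch$L2, sch$eta1), c(8, 14, 22))
  sch <- phase_schedule(pde_params(v = 1 / 22, u = 1 / 22))
  expect_equal(c(sch$L1, sch$L2, sch$eta1), c(11, 11, 22))
  sch <- phase_schedule(pde_params(v = 0.04, u = 0.2))
  expect_equal(c(sch$L1, sch$L2, sch$eta1), c(12.5, 2.5, 15))
  expect_equal(sch$k_of_t(c(7, 15, 31)), c(0, 1, 2))
  expect_equal(sch$tau_of_t(c(7, 15, 31)), c(7, 0, 1))
  expect_error(pde_params(v = 0, u = 0.1), "positive")
  expect_error(pde_params(v = 0.1, u = -1), "positive")
  expect_error(pde_params(v = 0.1, u = 0.1, p0 = 0, q0 = 0), "positive")
})

test_that("density profile reproduces the characteristics solution", {
  pars <- pde_params(v = 1 / 16, u = 1 / 28, p0 = 1, q0 = 3)
  # initial condition: two uniform pieces
  d0 <- density(pars, t = 0)
  expect_equal(d0$breakpoints, c(0, 0.5, 1))
  expect_equal(d0$values, c(1, 3))
  # first-cycle profile at t = 6 h: four pieces by direct substitution
  d6 <- density(pars, t = 6)
  expect_equal(d6$breakpoints, c(0, 0.375, 0.5, 0.5 + 6 / 28, 1))
  expect_equal(d6$values, c(2 * 3 * (16 / 28), 1, 28 / 16, 3),
               tolerance = 1e-12)
})

test_that("division doubles the profile once per cycle and conserves flux", {
  for (pars in random_pde_params(8, seed = 11)) {
    eta1 <- phase_schedule(pars)$eta1
    for (t in c(0, 0.3 * eta1, 0.62 * eta1, 0.97 * eta1)) {
      a <- density(pars, t)
      b <- density(pars, t + eta1)
      expect_equal(b$breakpoints, a$breakpoints, tolerance = 1e-9)
      expect_equal(b$values, 2 * a$values, tolerance = 1e-9)
      # mitosis boundary condition v p(0+, t) = 2 u p(1-, t): holds for
      # every t > 0 once the influx is set by the outflux (the prescribed
      # uniform initial profile itself need not satisfy it at tau = 0)
      if (t > 0)
        expect_equal(pars$v * a$values[1],
                     2 * pars$u * a$values[length(a$values)],
                     tolerance = 1e-12)
    }
  }
})

test_that("closed-form phase counts equal integrals of the density", {
  for (pars in random_pde_params(12, seed = 2)) {
    eta1 <- phase_schedule(pars)$eta1
    set.seed(pars$v * 1e6)
    for (t in runif(4, 0, 3 * eta1)) {
      prof <- density(pars, t)
      st <- phase_counts(pars, t)
      expect_equal(st$N, profile_mass(prof), tolerance = 1e-10)
      expect_equal(st$pG2, profile_mass(prof, 0.5, 1), tolerance = 1e-10)
      expect_equal(st$pG1 + st$pG2, st$N)
      expect_equal(st$pi1 + st$pi2, 1)
    }
  }
})

test_that("population starts at (p0+q0)/2 and doubles every cycle", {
  pars <- pde_params(v = 1 / 16, u = 1 / 28, s = 2.7, p0 = 1.4)
  expect_equal(total_population(pars, 0), (pars$p0 + pars$q0) / 2)
  expect_equal(phase_counts(pars, 0)$pi2, pars$s / (1 + pars$s))
  expect_equal(total_population(pars, 22), 2 * total_population(pars, 0))
  m <- 1:5
  expect_equal(total_population(pars, m * 22),
               2^m * total_population(pars, 0))
  # same eta1, swapped velocities: identical N at multiples of the period
  a <- pde_params(v = 0.04, u = 0.2, s = 1)
  b <- pde_params(v = 0.2, u = 0.04, s = 1)
  expect_equal(total_population(a, 15 * (1:4)),
               total_population(b, 15 * (1:4)))
  # log_N stays finite long after N overflows
  far <- phase_counts(pars, 22 * 5000)
  expect_true(is.infinite(far$N) && is.finite(far$log_N))
  expect_equal(far$log_N, 5000 * log(2) + log(total_population(pars, 0)))
})

test_that("growth rate is periodic and averages to log(2)/eta1", {
  for (pars in random_pde_params(6, seed = 3)) {
    eta1 <- phase_schedule(pars)$eta1
    tt <- c(0.1, 0.45, 0.8) * eta1
    expect_equal(growth_rate(pars, tt + eta1), growth_rate(pars, tt),
                 tolerance = 1e-10)
    expect_equal(mean_beta_quadrature(pars), log(2) / eta1,
                 tolerance = 1e-9)
    expect_equal(mean_growth_rate(pars), log(2) / eta1)
  }
})

test_that("within-cycle growth segments order according to s vs L2/L1", {
  # the first segment rate is s*u*p0, the second v*p0
  pars <- pde_params(v = 1 / 16, u = 1 / 28, s = 10^2.645)
  expect_true(initial_growth_ordering(pars))
  expect_gt(growth_rate(pars, 0), growth_rate(pars, 20))
  pars <- pde_params(v = 1 / 16, u = 1 / 28, s = 14 / 8)  # boundary: strict
  expect_false(initial_growth_ordering(pars))
  expect_false(initial_growth_ordering(pde_params(1 / 22, 1 / 22, s = 1)))
})

test_that("mean growth rate is independent of s and of the phase split", {
  e1 <- mean_growth_rate(pde_params(1 / 16, 1 / 28, s = 0.01))
  e2 <- mean_growth_rate(pde_params(1 / 16, 1 / 28, s = 100))
  e3 <- mean_growth_rate(pde_params(1 / 28, 1 / 16, s = 1))
  expect_equal(e1, log(2) / 22)
  expect_equal(e2, e1)
  expect_equal(e3, e1)
  expect_equal(mean_growth_rate(pde_params(0.04, 0.2)), log(2) / 15)
})

test_that("closed-form cycle-averaged G2 proportion matches quadrature", {
  for (pars in random_pde_params(100, seed = 4)) {
    cf <- mean_g2_closed_form(pars)
    expect_equal(cf, mean_g2_quadrature(pars), tolerance = 1e-8)
    expect_true(cf > 0 && cf < 1)
  }
  # equal-velocity case (empty middle region) and extreme ratios
  for (s in c(1e-8, 1e-3, 1, 1e3, 1e8)) {
    pars <- pde_params(1 / 22, 1 / 22, s = s)
    expect_equal(mean_g2_closed_form(pars), mean_g2_quadrature(pars),
                 tolerance = 1e-10)
  }
  expect_error(mean_g2_closed_form(pde_params(0.1, 0.1, s = 0)), "s > 0")
})

test_that("phase proportions do not depend on the scale p0", {
  a <- pde_params(1 / 16, 1 / 28, s = 0.3, p0 = 1)
  b <- pde_params(1 / 16, 1 / 28, s = 0.3, p0 = 57.5)
  tt <- seq(0, 44, by = 1.7)
  expect_equal(phase_counts(a, tt)$pi2, phase_counts(b, tt)$pi2)
  expect_equal(mean_g2_closed_form(a), mean_g2_closed_form(b))
})

test_that("oscillation extrema sit at the kink times of the proportion", {
  for (pars in random_pde_params(10, seed = 5)) {
    eta1 <- phase_schedule(pars)$eta1
    ext <- oscillation_extrema(pars)
    # dense grid; the proportion has sharp kinks, so refine near them too
    grid <- sort(c(seq(0, eta1, by = 0.001 * eta1),
                   1 / (2 * pars$v), 1 / (2 * pars$u)))
    grid <- grid[grid < eta1]
    pg <- phase_counts(pars, grid)$pi2
    expect_equal(ext$pi2_max, max(pg), tolerance = 1e-9)
    expect_equal(ext$pi2_min, min(pg), tolerance = 1e-9)
    expect_equal(ext$amplitude, max(pg) - min(pg), tolerance = 1e-9)
    expect_true(ext$amplitude >= 0 && ext$amplitude <= 1)
    expect_true(all(c(ext$t_max, ext$t_min) %in%
                      c(0, 1 / (2 * pars$v), 1 / (2 * pars$u))))
  }
})

test_that("the realistic 22-hour cycle has out-of-phase extremes", {
  # G1 8 h / G2 14 h; the two matched initial ratios oscillate out of phase
  lo <- oscillation_extrema(pde_params(1 / 16, 1 / 28, s = 10^-0.605))
  hi <- oscillation_extrema(pde_params(1 / 16, 1 / 28, s = 10^2.645))
  expect_equal(lo$t_max, 14)   # 1/(2u): G2 about to empty through division
  expect_equal(lo$t_min, 0)
  expect_equal(hi$t_max, 0)
  expect_equal(hi$t_min, 8)    # 1/(2v): the initial G2 bulk has divided
  expect_equal(lo$pi2_min, 10^-0.605 / (1 + 10^-0.605))
  # frozen exact values (independently confirmed by the dense-grid check
  # above and by direct integration of the density pieces)
  expect_equal(lo$amplitude, 0.61147, tolerance = 1e-4)
  expect_equal(hi$amplitude, 0.72397, tolerance = 1e-4)
})

test_that("profiles export to data frames with half-open phi intervals", {
  prof <- density(pde_params(1 / 16, 1 / 28, p0 = 1, q0 = 3), t = 6)
  df <- as.data.frame(prof)
  expect_named(df, c("phi_lo", "phi_hi", "density"))
  expect_equal(df$phi_lo[1], 0)
  expect_equal(df$phi_hi[nrow(df)], 1)
  expect_equal(sum((df$phi_hi - df$phi_lo) * df$density),
               total_population(pde_params(1 / 16, 1 / 28, p0 = 1, q0 = 3), 6))
})
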