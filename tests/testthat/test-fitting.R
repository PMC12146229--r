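test_that("log loss vanishes on self-generated data and is scale free", {
  pars <- ode_params(0.11455, 0.05541)
  tr <- ode_solve(pars, init = c(0.8, 0.2), times = seq(0, 60, by = 4))
  ds <- as_dataset(tr)
  expect_lt(log_loss(ds, pars), 1e-18)
  expect_gt(log_loss(ds, ode_params(0.2, 0.1)), 0)
  # rescaling the counts rescales the fitted initial condition too, so the
  # loss is unchanged (residuals are log ratios)
  other <- ode_params(0.3, 0.08)
  ds2 <- ds
  ds2$N <- 2 * ds2$N
  expect_equal(log_loss(ds2, other), log_loss(ds, other), tolerance = 1e-10)
})

test_that("fitting recovers generating rates from noiseless ODE data", {
  set.seed(31)
  cfg <- fit_config(multistart = 4, seed = 5)
  for (i in 1:50) {
    k <- ode_params(10^runif(1, -2, 0), 10^runif(1, -2, 0))
    g0 <- runif(1, 0.05, 0.95)
    tr <- ode_solve(k, init = c(1 - g0, g0), times = seq(0, 48, by = 1))
    fit <- fit_ode(as_dataset(tr), cfg)
    expect_equal(fit$k1_hat, k$k1, tolerance = 1e-4)
    expect_equal(fit$k2_hat, k$k2, tolerance = 1e-4)
    expect_lt(fit$loss, 1e-12)
  }
})

test_that("fit results are deterministic under a fixed seed", {
  pars <- pde_params(1 / 16, 1 / 28, s = 10, p0 = 2 / 11)
  ds <- sample_trajectory(pars, sampling_schedule(interval = 7,
                                                  horizon = 120))
  a <- fit_ode(ds, fit_config(seed = 3))
  b <- fit_ode(ds, fit_config(seed = 3))
  expect_identical(c(a$k1_hat, a$k2_hat, a$loss),
                   c(b$k1_hat, b$k2_hat, b$loss))
  expect_true(a$converged)
  expect_error(fit_ode(ds[1:2, ], fit_config()), "three")
})

test_that("adding exactly-reproduced points never raises the optimum loss", {
  pars <- pde_params(1 / 16, 1 / 28, s = 10^3, p0 = 2 / (1 + 10^3))
  ds <- sample_trajectory(pars, sampling_schedule(interval = 30,
                                                  horizon = 120))
  fit1 <- fit_ode(ds, fit_config(seed = 2))
  khat <- ode_params(fit1$k1_hat, fit1$k2_hat)
  # augment with points the fitted ODE reproduces exactly
  extra_t <- setdiff(seq(0, 120, by = 15), ds$t)
  tr <- ode_solve(khat, init = c((1 - ds$pi2[1]) * ds$N[1],
                                 ds$pi2[1] * ds$N[1]),
                  times = sort(c(ds$t, extra_t)))
  aug <- as_dataset(tr)
  keep <- aug$t %in% ds$t
  aug$N[keep] <- ds$N
  aug$pi2[keep] <- ds$pi2
  fit2 <- fit_ode(aug, fit_config(seed = 2))
  expect_lte(fit2$loss, fit1$loss + 1e-8)
})

test_that("sampling frequency controls closeness to the matched ODE", {
  s <- 1e3
  pars <- pde_params(1 / 16, 1 / 28, s = s, p0 = 2 / (1 + s))
  m <- match_forward(1 / 16, 1 / 28, s)
  matched <- ode_params(m$k1, m$k2)
  init <- c(1 / (1 + s), s / (1 + s))
  dist_for <- function(interval) {
    ds <- sample_trajectory(pars, sampling_schedule(interval = interval,
                                                    horizon = 120))
    fit <- fit_ode(ds, fit_config(seed = 1), reference = matched)
    list(fit = fit,
         d = trajectory_distance(ode_params(fit$k1_hat, fit$k2_hat),
                                 matched, init = init))
  }
  r1 <- dist_for(1)
  r7 <- dist_for(7)
  r22 <- dist_for(22)
  r30 <- dist_for(30)
  # 7 h sampling tracks the matched ODE more closely than 22 h sampling,
  # which only ever sees the oscillation maximum, in both observables
  expect_lt(r7$d["log_N"], r22$d["log_N"])
  expect_lt(r7$d["pi2"], r22$d["pi2"])
  # full ordering in the proportion observable: 7 < 30 < 22
  expect_lt(r7$d["pi2"], r30$d["pi2"])
  expect_lt(r30$d["pi2"], r22$d["pi2"])
  # hourly and 7-hourly sampling give nearly identical fits
  expect_equal(r1$fit$k1_hat, r7$fit$k1_hat, tolerance = 0.05)
  expect_equal(r1$fit$k2_hat, r7$fit$k2_hat, tolerance = 0.05)
  # discrepancy slot reports distance to the matched reference
  expect_equal(unname(r7$fit$discrepancy["k1"]),
               abs(r7$fit$k1_hat - m$k1))
})
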