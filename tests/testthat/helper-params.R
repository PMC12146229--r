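# random but biologically plausible parameter draws: phase lengths between
# 1 and 22 hours, initial ratios spanning 10^-3 .. 10^3
random_pde_params <- function(n, seed = 1, s_range = c(-3, 3)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pde_params(v = 1 / (2 * runif(1, 1, 22)),
               u = 1 / (2 * runif(1, 1, 22)),
               s = 10^runif(1, s_range[1], s_range[2]),
               p0 = runif(1, 0.5, 2))
  })
}

# quadrature of the instantaneous growth rate over one period, split at the
# kink so each sub-integrand is smooth
mean_beta_quadrature <- function(params) {
  sch <- phase_schedule(params)
  bp <- sort(unique(c(0, sch$L2, sch$eta1)))
  tot <- 0
  for (j in seq_len(length(bp) - 1))
    tot <- tot + integrate(function(t) growth_rate(params, t),
                           bp[j], bp[j + 1], rel.tol = 1e-11)$value
  tot / sch$eta1
}

# mass of a density profile over [from, to) by direct summation
profile_mass <- function(profile, from = 0, to = 1) {
  bp <- profile$breakpoints
  lo <- pmax(bp[-length(bp)], from)
  hi <- pmin(bp[-1], to)
  sum(pmax(hi - lo, 0) * profile$values)
}

# dataset wrapper for a data frame of exact ODE output
as_dataset <- function(df) {
  out <- data.frame(t = df$t, N = df$N, pi2 = df$g2)
  class(out) <- c("trajectory_dataset", "data.frame")
  attr(out, "starts_at_zero") <- out$t[1] == 0
  out
}
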