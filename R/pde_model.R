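## Exact solution of the structured transport PDE and derived observables.
##
## Throughout, tau = t - k(t) * eta1 is the within-cycle time, and the
## "bracket" is N(t) / (2^k(t) p0): the population rescaled by the doubling
## factor accumulated over completed cycles.  All piecewise formulas below
## are expressed in the bracket to avoid overflow at large t; logarithmic
## population sizes are exposed alongside raw counts.

## bracket of N(t): two linear pieces, switching at tau = L2 for every
## ordering of (v, u)
.n_bracket <- function(v, u, s, tau) {
  L2 <- 1 / (2 * u)
  ifelse(tau < L2,
         (1 + s) / 2 + s * u * tau,
         s + 1 / 2 - v / (2 * u) + v * tau)
}

## G2 proportion at within-cycle time tau (scalar v, u, s; vector tau).
## Three regions: before min(L1, L2), the middle region (whose form depends
## on which phase is longer; empty when v == u), and after max(L1, L2).
.pi2_tau <- function(v, u, s, tau) {
  L1 <- 1 / (2 * v)
  L2 <- 1 / (2 * u)
  num <- numeric(length(tau))
  r1 <- tau < min(L1, L2)
  r3 <- tau >= max(L1, L2)
  r2 <- !(r1 | r3)
  num[r1] <- s / 2 + (v - s * u) * tau[r1]
  num[r3] <- (v / (2 * u) + 1 / 2) - (u / v) * s + (2 * u * s - v) * tau[r3]
  if (any(r2))
    num[r2] <- if (v > u) (1 + s) / 2 - (u / v) * s + s * u * tau[r2]
               else rep(v / (2 * u), sum(r2))
  num / .n_bracket(v, u, s, tau)
}

## integral of (a + b*tau) / (c + d*tau) over [t1, t2] (vectorised).
## The textbook antiderivative (b/d)*tau + ((a*d - b*c)/d^2) * log(c + d*tau)
## suffers catastrophic cancellation when d*(t2 - t1) << c (e.g. extreme s),
## so a series expansion in x = d*(t2 - t1)/(c + d*t1) is used there.
.piece_int <- function(a, b, c, d, t1, t2) {
  n <- max(length(a), length(b), length(c), length(d), length(t1), length(t2))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  d <- rep_len(d, n); t1 <- rep_len(t1, n); t2 <- rep_len(t2, n)
  dt <- t2 - t1
  a1 <- a + b * t1          # numerator value at t1
  c1 <- c + d * t1          # denominator value at t1 (positive)
  x <- d * dt / c1
  out <- numeric(n)
  big <- abs(x) > 0.1
  if (any(big))
    out[big] <- (b[big] / d[big]) * dt[big] +
      ((a1[big] * d[big] - b[big] * c1[big]) / d[big]^2) * log1p(x[big])
  if (any(!big)) {
    i <- which(!big)
    xi <- x[i]
    bi <- (b * dt)[i]
    ai <- a1[i]
    term <- rep(1, length(i))
    S <- ai + bi / 2
    k <- 1L
    repeat {
      term <- term * (-xi)
      add <- term * (ai / (k + 1) + bi / (k + 2))
      S <- S + add
      k <- k + 1L
      if (all(abs(add) <= 1e-17 * abs(S)) || k > 60L) break
    }
    out[i] <- (dt[i] / c1[i]) * S
  }
  out
}

## cycle-averaged G2 proportion, vectorised over (v, u, s): exact region-wise
## integration of the piecewise-rational pi2(tau) over one period
.mean_g2 <- function(v, u, s) {
  n <- max(length(v), length(u), length(s))
  v <- rep_len(v, n); u <- rep_len(u, n); s <- rep_len(s, n)
  L1 <- 1 / (2 * v); L2 <- 1 / (2 * u); eta1 <- L1 + L2
  mn <- pmin(L1, L2); mx <- pmax(L1, L2)
  I1 <- .piece_int(s / 2, v - s * u, (1 + s) / 2, s * u, 0, mn)
  gtr <- v > u
  a2 <- ifelse(gtr, (1 + s) / 2 - (u / v) * s, v / (2 * u))
  b2 <- ifelse(gtr, s * u, 0)
  c2 <- ifelse(gtr, (1 + s) / 2, s + 1 / 2 - v / (2 * u))
  d2 <- ifelse(gtr, s * u, v)
  I2 <- .piece_int(a2, b2, c2, d2, mn, mx)
  I3 <- .piece_int((v / (2 * u) + 1 / 2) - (u / v) * s, 2 * u * s - v,
                   s + 1 / 2 - v / (2 * u), v, mx, eta1)
  (I1 + I2 + I3) / eta1
}

#' Exact cell-density profile of the structured PDE
#'
#' Returns the method-of-characteristics solution \eqn{p(\phi, t)} of the
#' transport PDE at a fixed time: a piecewise-constant profile over
#' \eqn{\phi \in [0,1]} with at most four non-empty pieces.  Which case
#' applies is decided by the within-cycle time \eqn{\tau} relative to the
#' phase lengths and by the sign of \eqn{v - u}; zero-width pieces are
#' dropped.  Intervals are half-open `[phi_lo, phi_hi)`, with the value at a
#' jump point taken from the right.
#'
#' @param x a [pde_params()] object.
#' @param t time in hours (single non-negative number).
#' @param ... unused.
#' @return An object of class `"density_profile"`: a list with
#'   `breakpoints` (ascending, from 0 to 1), `values` (density on each
#'   interval), `t`, and the completed-cycle count `k`.
#' @export
#' @examples
#' pars <- pde_params(v = 1 / 16, u = 1 / 28, p0 = 1, q0 = 3)
#' density(pars, t = 6)
density.pde_params <- function(x, t = 0, ...) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t), t >= 0)
  v <- x$v; u <- x$u; p0 <- x$p0; q0 <- x$q0
  L1 <- 1 / (2 * v); L2 <- 1 / (2 * u); eta1 <- L1 + L2
  k <- floor(t / eta1)
  tau <- t - k * eta1
  m <- 2^k
  if (tau < min(L1, L2)) {
    bp <- c(0, v * tau, 1 / 2, u * tau + 1 / 2, 1)
    vals <- c(2 * m * q0 * u / v, m * p0, m * p0 * v / u, m * q0)
  } else if (tau < max(L1, L2) && v > u) {
    bp <- c(0, 1 / 2, u * tau + 1 / 2 - u / (2 * v), u * tau + 1 / 2, 1)
    vals <- c(2 * m * q0 * u / v, 2 * m * q0, m * p0 * v / u, m * q0)
  } else if (tau < max(L1, L2)) {      # u > v
    bp <- c(0, v * tau - v / (2 * u), v * tau, 1 / 2, 1)
    vals <- c(2 * m * p0, 2 * m * q0 * u / v, m * p0, m * p0 * v / u)
  } else {
    bp <- c(0, v * tau - v / (2 * u), 1 / 2, u * tau + 1 / 2 - u / (2 * v), 1)
    vals <- c(2 * m * p0, 2 * m * q0 * u / v, 2 * m * q0, m * p0 * v / u)
  }
  keep <- diff(bp) > 0
  structure(list(breakpoints = c(bp[-length(bp)][keep], 1),
                 values = vals[keep], t = t, k = k),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Cell-density profile at t = %g h (%d completed cycles)\n",
              x$t, x$k))
  bp <- x$breakpoints
  for (i in seq_along(x$values))
    cat(sprintf("  [%.6g, %.6g): %.6g\n", bp[i], bp[i + 1], x$values[i]))
  invisible(x)
}

#' @describeIn density.pde_params coerce a profile to a data frame with
#'   columns `phi_lo`, `phi_hi`, `density`.
#' @param row.names,optional passed on conventions of [as.data.frame()];
#'   unused.
#' @export
as.data.frame.density_profile <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  bp <- x$breakpoints
  data.frame(phi_lo = bp[-length(bp)], phi_hi = bp[-1], density = x$values)
}

## integral of a density profile over [from, to]
.profile_mass <- function(profile, from = 0, to = 1) {
  bp <- profile$breakpoints
  lo <- pmax(bp[-length(bp)], from)
  hi <- pmin(bp[-1], to)
  sum(pmax(hi - lo, 0) * profile$values)
}

#' Phase counts and proportions of the structured PDE
#'
#' Evaluates the closed-form phase occupancies of the PDE model: the number
#' of cells in G1 and G2 (the integrals of the density over
#' \eqn{[0, 1/2)} and \eqn{[1/2, 1)}), the total \eqn{N(t)}, and the phase
#' proportions \eqn{\pi_1, \pi_2}.  The proportions are periodic with the
#' cycle length \eqn{\eta_1} and independent of the scale `p0`; the counts
#' double every cycle.  `log_N` is computed in log space and remains finite
#' when `N` itself overflows at very large `t`.
#'
#' @param params a [pde_params()] object.
#' @param t vector of times in hours (non-negative).
#' @return A data frame of class `"phase_state"` with columns
#'   `t`, `pG1`, `pG2`, `N`, `log_N`, `pi1`, `pi2`.
#' @export
#' @examples
#' pars <- pde_params(v = 1 / 16, u = 1 / 28, s = 3)
#' phase_counts(pars, t = c(0, 11, 22))
phase_counts <- function(params, t) {
  stopifnot(inherits(params, "pde_params"),
            is.numeric(t), all(is.finite(t)), all(t >= 0))
  v <- params$v; u <- params$u; s <- params$s; p0 <- params$p0
  eta1 <- 1 / (2 * v) + 1 / (2 * u)
  k <- floor(t / eta1)
  tau <- t - k * eta1
  nb <- .n_bracket(v, u, s, tau)
  pi2 <- .pi2_tau(v, u, s, tau)
  N <- 2^k * nb * p0
  out <- data.frame(t = t,
                    pG1 = (1 - pi2) * N,
                    pG2 = pi2 * N,
                    N = N,
                    log_N = k * log(2) + log(nb * p0),
                    pi1 = 1 - pi2,
                    pi2 = pi2)
  class(out) <- c("phase_state", "data.frame")
  out
}

#' Total population of the structured PDE
#'
#' Convenience accessor returning only \eqn{N(t)} from [phase_counts()].
#'
#' @inheritParams phase_counts
#' @return Numeric vector of total cell counts.
#' @export
#' @examples
#' total_population(pde_params(1 / 16, 1 / 28), t = c(0, 22, 44))
total_population <- function(params, t) {
  phase_counts(params, t)$N
}

#' Instantaneous population growth rate of the structured PDE
#'
#' \eqn{\beta(t) = N'(t)/N(t)}.  Within each cycle \eqn{N'(t)} takes exactly
#' two constant values: the G2 outflux-driven rate \eqn{s u p_0 2^k} for
#' \eqn{\tau < 1/(2u)} and \eqn{v p_0 2^k} after, so \eqn{\beta} is periodic
#' with period \eqn{\eta_1}.  At the switch times the right-sided value is
#' returned.
#'
#' @inheritParams phase_counts
#' @return Numeric vector of per-hour growth rates.
#' @seealso [mean_growth_rate()] for the cycle average \eqn{\log(2)/\eta_1}.
#' @export
growth_rate <- function(params, t) {
  stopifnot(inherits(params, "pde_params"),
            is.numeric(t), all(is.finite(t)), all(t >= 0))
  v <- params$v; u <- params$u; s <- params$s
  L2 <- 1 / (2 * u)
  eta1 <- 1 / (2 * v) + L2
  tau <- t - floor(t / eta1) * eta1
  dN <- ifelse(tau < L2, s * u, v)
  dN / .n_bracket(v, u, s, tau)
}

#' Cycle-averaged population growth rate
#'
#' The average of \eqn{\beta(t)} over one period is exactly
#' \eqn{\log(2)/\eta_1}: the population doubles once per cycle regardless of
#' how the cycle splits into phases or of the initial ratio `s`.
#'
#' @param params a [pde_params()] object.
#' @return A single per-hour rate.
#' @export
#' @examples
#' mean_growth_rate(pde_params(1 / 16, 1 / 28))  # log(2) / 22
mean_growth_rate <- function(params) {
  stopifnot(inherits(params, "pde_params"))
  log(2) / (1 / (2 * params$v) + 1 / (2 * params$u))
}

#' Cycle-averaged G2 proportion (closed form)
#'
#' The mean of \eqn{\pi_2(t)} over one period, obtained by exact region-wise
#' integration of the piecewise-rational proportion.  Each region contributes
#' an elementary \eqn{(a+b\tau)/(c+d\tau)} integral; a series branch keeps
#' the evaluation accurate to machine precision for extreme `s` (tested to
#' \eqn{10^{\pm 12}}), including the equal-velocity case \eqn{v = u} where
#' the middle region is empty.
#'
#' @param params a [pde_params()] object with `p0 > 0` and `s > 0`.
#' @return The mean G2 proportion, in (0, 1).
#' @seealso [mean_g2_quadrature()] for the adaptive-quadrature oracle.
#' @export
#' @examples
#' mean_g2_closed_form(pde_params(1 / 16, 1 / 28, s = 10^-0.605))
mean_g2_closed_form <- function(params) {
  stopifnot(inherits(params, "pde_params"))
  if (!is.finite(params$s) || params$s <= 0)
    stop("mean G2 proportion requires p0 > 0 and s > 0", call. = FALSE)
  .mean_g2(params$v, params$u, params$s)
}

#' Cycle-averaged G2 proportion (adaptive quadrature)
#'
#' Numerically averages [phase_counts()]'s \eqn{\pi_2(t)} over one period
#' with [stats::integrate()], splitting the period at the kink times
#' \eqn{\min(L_1, L_2)} and \eqn{\max(L_1, L_2)} so each sub-integrand is
#' smooth.  Serves as an independent check on [mean_g2_closed_form()].
#'
#' @inheritParams mean_g2_closed_form
#' @param rel_tol relative tolerance passed to [stats::integrate()].
#' @return The mean G2 proportion, in (0, 1).
#' @export
mean_g2_quadrature <- function(params, rel_tol = 1e-10) {
  stopifnot(inherits(params, "pde_params"))
  if (!is.finite(params$s) || params$s <= 0)
    stop("mean G2 proportion requires p0 > 0 and s > 0", call. = FALSE)
  v <- params$v; u <- params$u; s <- params$s
  L1 <- 1 / (2 * v); L2 <- 1 / (2 * u); eta1 <- L1 + L2
  bp <- unique(c(0, min(L1, L2), max(L1, L2), eta1))
  tot <- 0
  for (j in seq_len(length(bp) - 1L))
    tot <- tot + integrate(function(tt) .pi2_tau(v, u, s, tt),
                           bp[j], bp[j + 1], rel.tol = rel_tol,
                           subdivisions = 1000L)$value
  tot / eta1
}

#' Oscillation extrema of the G2 proportion over one cycle
#'
#' \eqn{\pi_2(t)} is continuous, periodic, and monotone between its kink
#' times, so its extrema over a period lie in the candidate set
#' \eqn{\{0,\; 1/(2v),\; 1/(2u)\}} (times within \eqn{[0, \eta_1)}).  The
#' peak-to-peak amplitude \eqn{A = \max - \min} measures how poorly a
#' constant (steady-state ODE) proportion represents the PDE dynamics.
#' Ties are resolved towards the smallest attaining time.
#'
#' @param params a [pde_params()] object.
#' @return An object of class `"cycle_summary"`: a list with `mean_beta`,
#'   `mean_pi2`, `pi2_max`, `pi2_min`, `amplitude`, `t_max`, `t_min`
#'   (times in hours within one period).
#' @export
#' @examples
#' oscillation_extrema(pde_params(1 / 16, 1 / 28, s = 10^2.645))
oscillation_extrema <- function(params) {
  stopifnot(inherits(params, "pde_params"))
  v <- params$v; u <- params$u; s <- params$s
  eta1 <- 1 / (2 * v) + 1 / (2 * u)
  cand <- sort(unique(c(0, 1 / (2 * v), 1 / (2 * u))))
  cand <- cand[cand < eta1]
  vals <- .pi2_tau(v, u, s, cand)
  i_max <- which(vals >= max(vals) - 0)[1L]   # smallest attaining time
  i_min <- which(vals <= min(vals) + 0)[1L]
  structure(list(mean_beta = mean_growth_rate(params),
                 mean_pi2 = if (is.finite(s) && s > 0)
                   .mean_g2(v, u, s) else NA_real_,
                 pi2_max = vals[i_max], pi2_min = vals[i_min],
                 amplitude = vals[i_max] - vals[i_min],
                 t_max = cand[i_max], t_min = cand[i_min]),
            class = "cycle_summary")
}

#' @export
print.cycle_summary <- function(x, ...) {
  cat("One-cycle summary of the structured PDE\n")
  cat(sprintf("  mean growth rate : %.6g / h\n", x$mean_beta))
  cat(sprintf("  mean G2 fraction : %.6g\n", x$mean_pi2))
  cat(sprintf("  pi2 max %.4f at t = %g h; min %.4f at t = %g h\n",
              x$pi2_max, x$t_max, x$pi2_min, x$t_min))
  cat(sprintf("  peak-to-peak amplitude A = %.4f\n", x$amplitude))
  invisible(x)
}

#' Is the first within-cycle growth segment the faster one?
#'
#' Within each cycle \eqn{N'(t)} takes two values; the first (before
#' \eqn{\tau = 1/(2u)}) exceeds the second exactly when
#' \eqn{p_0 / L_1 < s p_0 / L_2}, i.e. `s > L2 / L1` (strict).  Observing
#' which growth segment is faster therefore constrains the phase lengths
#' relative to the initial distribution.
#'
#' @param params a [pde_params()] object with `p0 > 0`.
#' @return `TRUE` if the initial growth segment is the larger one.
#' @export
initial_growth_ordering <- function(params) {
  stopifnot(inherits(params, "pde_params"))
  if (params$p0 <= 0)
    stop("requires p0 > 0", call. = FALSE)
  L1 <- 1 / (2 * params$v)
  L2 <- 1 / (2 * params$u)
  params$p0 / L1 < params$s * params$p0 / L2
}

#' Plot a piecewise-constant density profile
#'
#' @param x a `"density_profile"` object.
#' @param ... further arguments passed to [plot()].
#' @export
plot.density_profile <- function(x, ...) {
  bp <- x$breakpoints
  plot(NA, xlim = c(0, 1), ylim = c(0, max(x$values) * 1.05),
       xlab = expression(phi), ylab = expression(p(phi, t)),
       main = sprintf("t = %g h", x$t), ...)
  segments(bp[-length(bp)], x$values, bp[-1], x$values, lwd = 2)
  abline(v = 0.5, lty = 3)
  invisible(x)
}
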