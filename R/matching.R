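## The PDE <-> ODE correspondence.  The forward map equates the PDE's
## cycle-averaged growth rate beta_bar(v, u) = 2 u v log(2) / (u + v) and
## cycle-averaged G2 proportion pi2_bar(v, u, s) with the ODE's long-term
## growth rate lambda^+ and steady proportion g2~, then inverts the ODE
## relations.  Because beta_bar does not involve s, a fixed (k1, k2) pins
## (v, u) to a one-parameter curve, and the remaining proportion equation in
## s can have zero, one or two solutions: the map is multi-valued in s.

#' Match ODE rates to a PDE parameter set
#'
#' Computes the cycle-averaged growth rate and G2 proportion of the
#' structured PDE with parameters `(v, u, s)` and returns the unique ODE
#' rate pair whose long-term growth rate and steady G2 proportion equal
#' them.
#'
#' @param v,u G1 and G2 progression velocities (per hour, > 0).
#' @param s initial G2:G1 density ratio (> 0).
#' @return An object of class `"match_result"`: a list with `k1`, `k2`, the
#'   matched averages `mean_beta` and `mean_pi2`, the inputs, and
#'   `residuals` (absolute defects of the two matching identities at the
#'   returned rates).
#' @export
#' @examples
#' match_forward(1 / 16, 1 / 28, 10^-0.605)
match_forward <- function(v, u, s) {
  pars <- pde_params(v = v, u = u, s = s)
  if (s <= 0) stop("'s' must be positive", call. = FALSE)
  mean_beta <- mean_growth_rate(pars)
  mean_pi2 <- mean_g2_closed_form(pars)
  k <- invert_long_term(mean_beta, mean_pi2)
  structure(list(k1 = k$k1, k2 = k$k2,
                 mean_beta = mean_beta, mean_pi2 = mean_pi2,
                 v = v, u = u, s = s,
                 residuals = c(growth = abs(long_term_growth(k) - mean_beta),
                               proportion = abs(steady_g2(k) - mean_pi2))),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("PDE -> ODE parameter matching\n")
  cat(sprintf("  PDE: v = %g, u = %g, s = %g\n", x$v, x$u, x$s))
  cat(sprintf("  averages: beta_bar = %.6g / h, pi2_bar = %.6g\n",
              x$mean_beta, x$mean_pi2))
  cat(sprintf("  matched ODE rates: k1 = %.6g, k2 = %.6g (per h)\n",
              x$k1, x$k2))
  cat(sprintf("  matching residuals: %.2e (growth), %.2e (proportion)\n",
              x$residuals[1], x$residuals[2]))
  invisible(x)
}

#' Iso-growth curve: the G2 velocity matching a growth rate at given v
#'
#' Fixing \eqn{(k_1, k_2)} fixes the growth rate
#' \eqn{\lambda^+ = 2uv\log 2/(u+v)}, i.e. \eqn{1/v + 1/u = 2\log 2/\lambda^+},
#' constraining \eqn{(v, u)} to a curve.  Solving for `u`:
#' \deqn{u(v) = \frac{\lambda^+ v}{2 v \log 2 - \lambda^+},}
#' which requires \eqn{v > \lambda^+ / (2\log 2)}.
#'
#' @param k1,k2 ODE transition rates (per hour, > 0).
#' @param v G1 progression velocity (per hour).
#' @return The matching G2 velocity `u` (per hour).
#' @export
#' @examples
#' iso_growth_u(0.11455, 0.05541, v = 1 / 16)  # close to 1/28
iso_growth_u <- function(k1, k2, v) {
  lam <- long_term_growth(ode_params(k1, k2))
  stopifnot(is.numeric(v), all(is.finite(v)))
  if (any(v <= lam / (2 * log(2))))
    stop(sprintf(paste0("no positive 'u' exists: 'v' must exceed the ",
                        "asymptote lambda+/(2 log 2) = %.6g"),
                 lam / (2 * log(2))), call. = FALSE)
  lam * v / (2 * log(2) * v - lam)
}

#' All initial ratios s matching a target ODE rate pair
#'
#' Given `(v, u)` on the iso-growth curve of `(k1, k2)`, finds every
#' \eqn{s} with cycle-averaged G2 proportion equal to the ODE steady
#' proportion \eqn{\tilde g_2(k_1, k_2)}, by sign-change bracketing of
#' \eqn{\bar\pi_2(v,u,10^x) - \tilde g_2} on a uniform grid in
#' \eqn{x = \log_{10} s} followed by root refinement.  The proportion curve
#' is non-monotone in \eqn{s}, so two distinct ratios can reproduce the
#' same ODE model; near its flat asymptotes the root location is highly
#' sensitive to the precision of the supplied rates.
#'
#' @param v,u progression velocities (per hour).
#' @param k1,k2 target ODE rates (per hour).
#' @param bracket search interval in \eqn{\log_{10} s}.
#' @param n_grid number of grid points used for bracketing.
#' @param growth_tol maximum relative mismatch tolerated between
#'   \eqn{\lambda^+(k_1,k_2)} and \eqn{\bar\beta(v,u)} (no `s` can repair a
#'   growth-rate mismatch; the default accommodates targets printed to a few
#'   significant figures).
#' @param tol root tolerance in \eqn{\log_{10} s}.
#' @return An object of class `"s_root_set"`: a list with `roots`
#'   (ascending `s` values; length 0, 1 or 2 in all regimes observed),
#'   `log10_roots`, `bracket`, and `target_g2`.
#' @export
#' @examples
#' solve_s_roots(1 / 16, 1 / 28, 0.11455, 0.05541)
solve_s_roots <- function(v, u, k1, k2, bracket = c(-10, 10),
                          n_grid = 2001L, growth_tol = 1e-3,
                          tol = 1e-12) {
  pars <- pde_params(v = v, u = u)
  k <- ode_params(k1, k2)
  lam <- long_term_growth(k)
  beta_bar <- mean_growth_rate(pars)
  if (abs(lam - beta_bar) > growth_tol * beta_bar)
    stop(sprintf(paste0("inconsistent target: lambda+(k1,k2) = %.6g but ",
                        "beta_bar(v,u) = %.6g; no 's' can match the growth ",
                        "rates"), lam, beta_bar), call. = FALSE)
  target <- steady_g2(k)
  f <- function(x) .mean_g2(v, u, 10^x) - target
  xs <- seq(bracket[1], bracket[2], length.out = n_grid)
  fs <- f(xs)
  roots <- xs[fs == 0]
  idx <- which(fs[-1] * fs[-n_grid] < 0)
  for (i in idx)
    roots <- c(roots, uniroot(f, c(xs[i], xs[i + 1]), tol = tol)$root)
  roots <- sort(roots)
  if (length(roots) > 1L)                       # merge near-duplicates
    roots <- roots[c(TRUE, diff(roots) > 1e-9)]
  structure(list(roots = 10^roots, log10_roots = roots,
                 bracket = bracket, target_g2 = target),
            class = "s_root_set")
}

#' @export
print.s_root_set <- function(x, ...) {
  cat(sprintf("Initial-ratio roots matching g2~ = %.6g ", x$target_g2))
  cat(sprintf("(searched log10(s) in [%g, %g])\n", x$bracket[1], x$bracket[2]))
  if (length(x$roots) == 0L) cat("  no roots found\n")
  else cat(sprintf("  s = %s  (log10: %s)\n",
                   paste(signif(x$roots, 6), collapse = ", "),
                   paste(sprintf("%.4f", x$log10_roots), collapse = ", ")))
  invisible(x)
}

#' Check the shared-rate property of multi-valued matches
#'
#' If two distinct initial ratios give the same matched \eqn{k_1} at fixed
#' `(v, u)`, they necessarily give the same \eqn{k_2} as well, because the
#' growth rate (hence \eqn{\lambda^+}) is independent of `s` and \eqn{k_2}
#' is a function of \eqn{(k_1, \lambda^+)} alone.  This verifies the
#' implication numerically for a pair of ratios.
#'
#' @param v,u progression velocities (per hour).
#' @param s1,s2 two positive initial ratios.
#' @param tol equality tolerance on the rates.
#' @return `TRUE` if equal `k1` implies equal `k2` for this pair (vacuously
#'   `TRUE` when the `k1` values differ).
#' @export
verify_theorem1 <- function(v, u, s1, s2, tol = 1e-9) {
  stopifnot(s1 > 0, s2 > 0)
  m1 <- match_forward(v, u, s1)
  m2 <- match_forward(v, u, s2)
  if (abs(m1$k1 - m2$k1) > tol) TRUE else abs(m1$k2 - m2$k2) <= tol
}
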