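## Linear two-compartment ODE model of the cell cycle:
##   dG1/dt = 2 k2 G2 - k1 G1,   dG2/dt = k1 G1 - k2 G2.
## The factor 2 implements division: each cell leaving G2 returns two
## daughters to G1.  The system is solved exactly by eigen-decomposition of
## the 2x2 rate matrix; the dominant eigenvalue gives the long-term growth
## rate and the associated eigenvector the steady phase proportions
## (asynchronous exponential growth).

#' Parameters of the two-compartment ODE model
#'
#' @param k1 G1-to-G2 transition rate (per hour, > 0).
#' @param k2 G2-to-division transition rate (per hour, > 0).
#' @return An object of class `"ode_params"`.
#' @export
#' @examples
#' ode_params(k1 = 0.11455, k2 = 0.05541)
ode_params <- function(k1, k2) {
  stopifnot(is.numeric(k1), length(k1) == 1L, is.finite(k1),
            is.numeric(k2), length(k2) == 1L, is.finite(k2))
  if (k1 <= 0 || k2 <= 0)
    stop("transition rates 'k1' and 'k2' must be positive", call. = FALSE)
  structure(list(k1 = k1, k2 = k2), class = "ode_params")
}

#' @export
print.ode_params <- function(x, ...) {
  cat(sprintf("Two-compartment ODE rates: k1 = %g, k2 = %g (per h)\n",
              x$k1, x$k2))
  cat(sprintf("  steady G2 proportion %.6g, long-term growth %.6g / h\n",
              steady_g2(x), long_term_growth(x)))
  invisible(x)
}

## dominant / subdominant eigenvalues of [[-k1, 2 k2], [k1, -k2]]
.ode_eigen <- function(k1, k2) {
  disc <- sqrt(k1^2 + 6 * k1 * k2 + k2^2)
  list(lp = (-(k1 + k2) + disc) / 2, lm = (-(k1 + k2) - disc) / 2)
}

#' Solve the two-compartment ODE exactly
#'
#' Closed-form solution by eigen-decomposition of the rate matrix
#' \eqn{[[-k_1, 2k_2], [k_1, -k_2]]}; eigenvectors are
#' \eqn{(2k_2,\, k_1+\lambda)} for each eigenvalue \eqn{\lambda}.  No
#' time-stepping error is incurred.
#'
#' @param params an [ode_params()] object.
#' @param init numeric length-2 vector `c(G1, G2)` of non-negative initial
#'   compartment counts with positive sum.
#' @param times vector of times in hours.
#' @return A data frame of class `"ode_trajectory"` with columns
#'   `t`, `G1`, `G2`, `N`, `g1`, `g2`.
#' @export
#' @examples
#' tr <- ode_solve(ode_params(0.5, 0.5), init = c(1, 0), times = 0:10)
#' tail(tr$g2, 1)  # approaching sqrt(2) - 1
ode_solve <- function(params, init, times) {
  stopifnot(inherits(params, "ode_params"),
            is.numeric(init), length(init) == 2L, all(is.finite(init)),
            is.numeric(times), all(is.finite(times)))
  if (any(init < 0) || sum(init) <= 0)
    stop("initial counts must be non-negative with positive total",
         call. = FALSE)
  k1 <- params$k1; k2 <- params$k2
  ev <- .ode_eigen(k1, k2)
  E <- cbind(c(2 * k2, k1 + ev$lp), c(2 * k2, k1 + ev$lm))
  cc <- solve(E, init)
  G1 <- cc[1] * E[1, 1] * exp(ev$lp * times) +
        cc[2] * E[1, 2] * exp(ev$lm * times)
  G2 <- cc[1] * E[2, 1] * exp(ev$lp * times) +
        cc[2] * E[2, 2] * exp(ev$lm * times)
  N <- G1 + G2
  out <- data.frame(t = times, G1 = G1, G2 = G2, N = N,
                    g1 = G1 / N, g2 = G2 / N)
  class(out) <- c("ode_trajectory", "data.frame")
  out
}

#' Steady-state G2 proportion of the ODE model
#'
#' The stable root of \eqn{k_1 - (k_1+k_2)g - k_2 g^2 = 0}:
#' \deqn{\tilde g_2 = \frac{-k_1 - k_2 + \sqrt{k_1^2 + 6k_1k_2 + k_2^2}}{2k_2}.}
#'
#' @param params an [ode_params()] object.
#' @return The steady G2 proportion, in (0, 1).
#' @export
steady_g2 <- function(params) {
  stopifnot(inherits(params, "ode_params"))
  k1 <- params$k1; k2 <- params$k2
  (-(k1 + k2) + sqrt(k1^2 + 6 * k1 * k2 + k2^2)) / (2 * k2)
}

#' Long-term growth rate of the ODE model
#'
#' The dominant eigenvalue of the rate matrix,
#' \deqn{\lambda^+ = \frac{-(k_1 + k_2) + \sqrt{k_1^2 + 6k_1k_2 + k_2^2}}{2},}
#' which equals \eqn{k_2 \tilde g_2}.
#'
#' @param params an [ode_params()] object.
#' @return Positive per-hour rate.
#' @export
long_term_growth <- function(params) {
  stopifnot(inherits(params, "ode_params"))
  .ode_eigen(params$k1, params$k2)$lp
}

#' Recover ODE rates from the long-term observables
#'
#' Inverts \eqn{(\lambda^+, \tilde g_2) \mapsto (k_1, k_2)}:
#' \eqn{k_2 = \lambda^+/\tilde g_2} and, from the steady state of the
#' proportion equation, \eqn{k_1 = \lambda^+ (1+\tilde g_2)/(1-\tilde g_2)}.
#' Composed with [long_term_growth()] and [steady_g2()] this is the identity
#' on the positive quadrant.
#'
#' @param lambda_plus long-term growth rate (per hour, > 0).
#' @param g2_star steady G2 proportion, strictly inside (0, 1).
#' @return An [ode_params()] object.
#' @export
#' @examples
#' invert_long_term(log(2) / 22, (log(2) / 22) / 0.05541)
invert_long_term <- function(lambda_plus, g2_star) {
  stopifnot(is.numeric(lambda_plus), length(lambda_plus) == 1L,
            is.numeric(g2_star), length(g2_star) == 1L)
  if (!is.finite(lambda_plus) || lambda_plus <= 0)
    stop("'lambda_plus' must be positive", call. = FALSE)
  if (!is.finite(g2_star) || g2_star <= 0 || g2_star >= 1)
    stop("'g2_star' must lie strictly inside (0, 1)", call. = FALSE)
  ode_params(k1 = lambda_plus * (1 + g2_star) / (1 - g2_star),
             k2 = lambda_plus / g2_star)
}
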