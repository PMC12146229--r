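#' Parameters of the structured PDE model
#'
#' Bundles the progression velocities and the uniform-per-phase initial
#' condition of the maturity-structured cell-cycle model.  The cycle position
#' \eqn{\phi} runs over \eqn{[0,1]} with the G1/G2 boundary fixed at
#' \eqn{\phi = 1/2}; cells advance at velocity `v` (per hour) in G1 and `u`
#' in G2, and the initial density is `p0` cells per \eqn{\phi}-unit on G1 and
#' `q0 = s * p0` on G2.
#'
#' Phase proportions depend on the initial condition only through the ratio
#' `s = q0 / p0`; `p0` sets the overall population scale.
#'
#' @param v G1 progression velocity (\eqn{\phi}-units per hour, > 0).
#' @param u G2 progression velocity (\eqn{\phi}-units per hour, > 0).
#' @param s initial G2:G1 density ratio `q0 / p0` (dimensionless, >= 0).
#'   Ignored (and recomputed) when `q0` is supplied.
#' @param p0 initial G1 density (cells per \eqn{\phi}-unit, >= 0).
#' @param q0 initial G2 density; defaults to `s * p0`.
#'
#' @return An object of class `"pde_params"`: a list with elements
#'   `v`, `u`, `p0`, `q0`, `s`.
#' @seealso [phase_schedule()], [phase_counts()], [density.pde_params()]
#' @export
#' @examples
#' pde_params(v = 1 / 16, u = 1 / 28, s = 10^-0.605)
pde_params <- function(v, u, s = 1, p0 = 1, q0 = s * p0) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v),
            is.numeric(u), length(u) == 1L, is.finite(u),
            is.numeric(p0), length(p0) == 1L, is.finite(p0),
            is.numeric(q0), length(q0) == 1L, is.finite(q0))
  if (v <= 0 || u <= 0)
    stop("progression velocities 'v' and 'u' must be positive", call. = FALSE)
  if (p0 < 0 || q0 < 0)
    stop("initial densities 'p0' and 'q0' must be non-negative", call. = FALSE)
  if (p0 + q0 <= 0)
    stop("initial population must be positive (p0 + q0 > 0)", call. = FALSE)
  s <- if (p0 > 0) q0 / p0 else Inf
  structure(list(v = v, u = u, p0 = p0, q0 = q0, s = s),
            class = "pde_params")
}

#' @export
print.pde_params <- function(x, ...) {
  sch <- phase_schedule(x)
  cat("Structured cell-cycle PDE parameters\n")
  cat(sprintf("  velocities : v = %g, u = %g  (phi-units / h)\n", x$v, x$u))
  cat(sprintf("  initial    : p0 = %g, q0 = %g  (s = q0/p0 = %g)\n",
              x$p0, x$q0, x$s))
  cat(sprintf("  schedule   : G1 %g h, G2 %g h, cycle %g h\n",
              sch$L1, sch$L2, sch$eta1))
  invisible(x)
}

#' Phase schedule implied by the progression velocities
#'
#' The structured model has a deterministic inter-mitotic time: every cell
#' spends \eqn{L_1 = 1/(2v)} hours in G1 and \eqn{L_2 = 1/(2u)} hours in G2,
#' so the cycle length is \eqn{\eta_1 = L_1 + L_2}.  The schedule also carries
#' the completed-cycle count \eqn{k(t) = \lfloor t/\eta_1 \rfloor} and the
#' within-cycle time \eqn{\tau(t) = t - k(t)\eta_1 \in [0, \eta_1)}.
#'
#' @param params a [pde_params()] object.
#' @return An object of class `"phase_schedule"`: a list with numeric
#'   `L1`, `L2`, `eta1` (hours) and functions `k_of_t`, `tau_of_t`.
#' @export
#' @examples
#' phase_schedule(pde_params(v = 1 / 16, u = 1 / 28))  # 8 h + 14 h = 22 h
phase_schedule <- function(params) {
  stopifnot(inherits(params, "pde_params"))
  L1 <- 1 / (2 * params$v)
  L2 <- 1 / (2 * params$u)
  eta1 <- L1 + L2
  structure(list(
    L1 = L1, L2 = L2, eta1 = eta1,
    k_of_t = function(t) floor(t / eta1),
    tau_of_t = function(t) t - floor(t / eta1) * eta1
  ), class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf("Phase schedule: L1 = %g h, L2 = %g h, eta1 = %g h\n",
              x$L1, x$L2, x$eta1))
  invisible(x)
}
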