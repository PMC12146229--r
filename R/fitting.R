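## Calibration of the two-compartment ODE to discretely sampled trajectory
## data.  The loss is least squares on the log scale for both series -- the
## total count spans orders of magnitude while the proportion lives in
## (0, 1], and logging puts them on comparable scales:
##   S = sum_k (ln z_k - ln N(t_k))^2 + sum_k (ln y_k - ln pi2(t_k))^2,
## with the ODE initial condition taken from the first sample:
## G1(0) = (1 - y_1) z_1, G2(0) = y_1 z_1.

#' Configuration of the ODE fit
#'
#' @param bounds length-2 positive vector of box bounds on both rates
#'   (per hour).
#' @param multistart number of local optimisations started from a Latin
#'   hypercube in log-rate space (>= 1).
#' @param seed integer seed for the multistart design.
#' @param ftol relative convergence tolerance of the least-squares
#'   optimiser.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(bounds = c(1e-4, 10), multistart = 16L, seed = 1L,
                       ftol = 1e-13) {
  stopifnot(is.numeric(bounds), length(bounds) == 2L, all(bounds > 0),
            bounds[1] < bounds[2], multistart >= 1L)
  structure(list(bounds = bounds, multistart = as.integer(multistart),
                 seed = as.integer(seed), ftol = ftol),
            class = "fit_config")
}

## log residual vector of the ODE prediction against a dataset
.fit_residuals <- function(log_k, dataset) {
  k1 <- exp(log_k[1])
  k2 <- exp(log_k[2])
  z1 <- dataset$N[1]
  y1 <- dataset$pi2[1]
  tr <- ode_solve(ode_params(k1, k2),
                  init = c((1 - y1) * z1, y1 * z1),
                  times = dataset$t)
  if (any(!is.finite(tr$N)) || any(tr$N <= 0) || any(tr$g2 <= 0))
    return(rep(1e6, 2L * nrow(dataset)))
  c(log(dataset$N) - log(tr$N), log(dataset$pi2) - log(tr$g2))
}

#' Log least-squares loss of an ODE parameter pair on a dataset
#'
#' @param dataset a `"trajectory_dataset"` (see [sample_trajectory()]).
#' @param params an [ode_params()] object.
#' @return The non-negative sum of squared log residuals over both the
#'   count and the proportion series; zero exactly when the ODE reproduces
#'   every sample.
#' @export
log_loss <- function(dataset, params) {
  stopifnot(inherits(params, "ode_params"))
  .validate_dataset(dataset)
  sum(.fit_residuals(log(c(params$k1, params$k2)), dataset)^2)
}

#' Fit the two-compartment ODE to a sampled trajectory
#'
#' Minimises [log_loss()] over `(k1, k2)` by bounded Levenberg-Marquardt
#' least squares ([minpack.lm::nls.lm()]) in log-rate space, restarted from
#' `multistart` Latin-hypercube points; the best local optimum is returned.
#' Results are deterministic for a fixed `config` seed.
#'
#' @param dataset a `"trajectory_dataset"` with at least three time points,
#'   the first at `t = 0`.
#' @param config a [fit_config()] object.
#' @param reference optional [ode_params()] (e.g. the analytically matched
#'   rates) against which the absolute discrepancy of the fitted rates is
#'   reported.
#' @return An object of class `"fit_result"`: a list with `k1_hat`,
#'   `k2_hat`, `loss`, `converged`, `n_evals`, `n_starts_converged`, and
#'   (when `reference` is given) `discrepancy = c(k1, k2)`.
#' @export
#' @examples
#' pars <- ode_params(0.11455, 0.05541)
#' tr <- ode_solve(pars, c(0.9, 0.1), times = seq(0, 48, by = 2))
#' ds <- structure(data.frame(t = tr$t, N = tr$N, pi2 = tr$g2),
#'                 class = c("trajectory_dataset", "data.frame"))
#' fit_ode(ds, fit_config(multistart = 4))
fit_ode <- function(dataset, config = fit_config(), reference = NULL) {
  stopifnot(inherits(config, "fit_config"))
  .validate_dataset(dataset)
  if (nrow(dataset) < 3L)
    stop("fitting requires at least three time points", call. = FALSE)
  if (dataset$t[1] != 0)
    stop("fitting requires the first sample at t = 0 ",
         "(the initial phase split is read from it)", call. = FALSE)
  lb <- log(config$bounds[1])
  ub <- log(config$bounds[2])
  set.seed(config$seed)
  starts <- lb + (ub - lb) * lhs::randomLHS(config$multistart, 2L)
  best <- NULL
  n_evals <- 0L
  n_conv <- 0L
  for (i in seq_len(config$multistart)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = c(lb, lb), upper = c(ub, ub),
        fn = .fit_residuals, dataset = dataset,
        control = minpack.lm::nls.lm.control(
          ftol = config$ftol, ptol = 1e-12, maxiter = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_evals <- n_evals + fit$niter
    conv <- fit$info %in% 1:4
    n_conv <- n_conv + conv
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best) || n_conv == 0L) {
    msg <- "no optimisation start converged"
    if (!is.null(best))
      msg <- paste0(msg, sprintf(" (best incumbent: k1 = %.6g, k2 = %.6g, ",
                                 exp(best$par[1]), exp(best$par[2])),
                    sprintf("loss = %.6g)", best$deviance))
    stop(msg, call. = FALSE)
  }
  k_hat <- exp(best$par)
  out <- list(k1_hat = k_hat[1], k2_hat = k_hat[2], loss = best$deviance,
              converged = TRUE, n_evals = n_evals,
              n_starts_converged = n_conv)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "ode_params"))
    out$discrepancy <- c(k1 = abs(k_hat[1] - reference$k1),
                         k2 = abs(k_hat[2] - reference$k2))
  }
  structure(out, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("ODE fit by multistart log least squares\n")
  cat(sprintf("  k1_hat = %.6g, k2_hat = %.6g (per h)\n", x$k1_hat, x$k2_hat))
  cat(sprintf("  loss = %.6g; %d/%s starts converged; %d LM iterations\n",
              x$loss, x$n_starts_converged, "multistart", x$n_evals))
  if (!is.null(x$discrepancy))
    cat(sprintf("  |k - k_matched| = (%.3g, %.3g)\n",
                x$discrepancy[1], x$discrepancy[2]))
  invisible(x)
}

#' Sup-norm distance between two ODE trajectories
#'
#' Compares the trajectories of two rate pairs started from the same
#' initial condition over a dense time grid, in the two observables used
#' for fitting: the largest absolute deviation of `log N` and of the G2
#' proportion.  Used to judge how close a fitted ODE is to the analytically
#' matched one.
#'
#' @param params_a,params_b [ode_params()] objects.
#' @param init length-2 initial condition `c(G1, G2)`.
#' @param horizon comparison horizon in hours.
#' @param step grid step in hours.
#' @return Named numeric vector `c(log_N = ..., pi2 = ...)`.
#' @export
trajectory_distance <- function(params_a, params_b, init, horizon = 120,
                                step = 0.1) {
  tt <- seq(0, horizon, by = step)
  a <- ode_solve(params_a, init, tt)
  b <- ode_solve(params_b, init, tt)
  c(log_N = max(abs(log(a$N) - log(b$N))),
    pi2 = max(abs(a$g2 - b$g2)))
}
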