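## Synthetic "experimental" data: the structured PDE observed only through
## discrete snapshots of total cell number N(t) and G2 proportion pi2(t).
## Because the PDE proportions are eta1-periodic, the sampling interval
## interacts with the cycle length: sampling every eta1 hours sees only one
## phase of the oscillation.

#' Sampling schedule for synthetic trajectories
#'
#' Either a regular grid (`start`, `interval`, `horizon`) or an explicit
#' ascending vector of `times`.  Calibration with [fit_ode()] assumes the
#' first sample is at `t = 0` (the initial phase split is read off the first
#' data point); schedules violating this are flagged, not rejected.
#'
#' @param interval sampling interval in hours (> 0), ignored when `times`
#'   is given.
#' @param horizon last sampling time in hours.
#' @param times explicit sampling times (non-negative, strictly ascending).
#' @param start first sampling time for the regular grid.
#' @return An object of class `"sampling_schedule"`: a list with `times`
#'   and the logical `starts_at_zero`.
#' @export
#' @examples
#' sampling_schedule(interval = 7, horizon = 120)
sampling_schedule <- function(interval = NULL, horizon = NULL, times = NULL,
                              start = 0) {
  if (is.null(times)) {
    stopifnot(is.numeric(interval), length(interval) == 1L, interval > 0,
              is.numeric(horizon), length(horizon) == 1L, horizon >= start)
    times <- seq(start, horizon, by = interval)
  }
  stopifnot(is.numeric(times), length(times) >= 1L, all(is.finite(times)))
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("sampling times must be non-negative and strictly ascending",
         call. = FALSE)
  starts_at_zero <- times[1] == 0
  if (!starts_at_zero)
    warning("schedule does not start at t = 0; ",
            "fitting assumes the initial phase split is observed",
            call. = FALSE)
  structure(list(times = times, starts_at_zero = starts_at_zero),
            class = "sampling_schedule")
}

#' Sample a synthetic PDE trajectory
#'
#' Evaluates the exact closed-form observables of the structured PDE at the
#' schedule's times.  By default the samples are noiseless; optionally,
#' independent multiplicative log-normal noise (standard deviation
#' `noise_sd` on the log scale) is applied to both series, with sampled
#' proportions clipped to `(0, 1]`.
#'
#' @param params a [pde_params()] object.
#' @param schedule a [sampling_schedule()] object.
#' @param noise_sd log-scale standard deviation of the multiplicative noise
#'   (default 0: noiseless).
#' @param seed integer seed for the noise (ignored when `noise_sd = 0`).
#' @return An object of class `"trajectory_dataset"`: a data frame with
#'   columns `t`, `N`, `pi2` and attribute `starts_at_zero`.
#' @export
#' @examples
#' pars <- pde_params(1 / 16, 1 / 28, s = 1000, p0 = 2 / 1001)
#' sample_trajectory(pars, sampling_schedule(interval = 22, horizon = 110))
sample_trajectory <- function(params, schedule, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "pde_params"),
            inherits(schedule, "sampling_schedule"),
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  st <- phase_counts(params, schedule$times)
  N <- st$N
  pi2 <- st$pi2
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    n <- length(N)
    N <- N * exp(stats::rnorm(n, sd = noise_sd))
    pi2 <- pmin(pi2 * exp(stats::rnorm(n, sd = noise_sd)), 1)
  }
  out <- data.frame(t = schedule$times, N = N, pi2 = pi2)
  class(out) <- c("trajectory_dataset", "data.frame")
  attr(out, "starts_at_zero") <- schedule$starts_at_zero
  out
}

.validate_dataset <- function(df, where = "dataset") {
  if (nrow(df) == 0L)
    stop(sprintf("%s is empty", where), call. = FALSE)
  bad <- which(!is.finite(df$N) | df$N <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive or non-finite N at line %d",
                 where, bad[1]), call. = FALSE)
  bad <- which(!is.finite(df$pi2) | df$pi2 <= 0 | df$pi2 > 1)
  if (length(bad))
    stop(sprintf("%s: pi2 outside (0, 1] at line %d", where, bad[1]),
         call. = FALSE)
  if (is.unsorted(df$t, strictly = TRUE) || any(df$t < 0))
    stop(sprintf("%s: times must be non-negative and strictly ascending",
                 where), call. = FALSE)
  invisible(df)
}

#' Write / read a trajectory dataset as CSV
#'
#' Plain CSV with header `t,N,pi2`; values are written with 17 significant
#' digits so that a write/read round trip reproduces the doubles exactly.
#'
#' @param dataset a `"trajectory_dataset"` (or compatible data frame with
#'   columns `t`, `N`, `pi2`).
#' @param path file path.
#' @return `read_dataset()` returns a `"trajectory_dataset"`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(is.data.frame(dataset),
            all(c("t", "N", "pi2") %in% names(dataset)))
  lines <- c("t,N,pi2",
             sprintf("%.17g,%.17g,%.17g", dataset$t, dataset$N,
                     dataset$pi2))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- tryCatch(
    read.csv(path, colClasses = "numeric"),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (!identical(names(raw), c("t", "N", "pi2")))
    stop(sprintf("'%s': expected header t,N,pi2", path), call. = FALSE)
  .validate_dataset(raw, where = path)
  out <- raw
  class(out) <- c("trajectory_dataset", "data.frame")
  attr(out, "starts_at_zero") <- out$t[1] == 0
  out
}

#' Plot a sampled trajectory
#'
#' @param x a `"trajectory_dataset"`.
#' @param ... passed to [plot()].
#' @export
plot.trajectory_dataset <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(x$t, log(x$N), xlab = "t (h)", ylab = "log N", type = "b", ...)
  plot(x$t, x$pi2, xlab = "t (h)", ylab = expression(pi[2]), ylim = c(0, 1),
       type = "b", ...)
  invisible(x)
}

#' @importFrom graphics par plot
NULL
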