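# Ensemble statistics, stationarity/histogram diagnostics, ergodicity
# checks, positivity audit and convergence-order estimation.

.COMPARTMENTS <- c("Sf", "Mb", "Mg", "U")

#' Run an ensemble of piecewise solves
#'
#' Performs `n_paths` independent [piecewise_solve()] runs.  The classical
#' and fractional regimes are deterministic, so they are computed once and
#' shared; each path then receives an independent Brownian substream for the
#' stochastic regime, with per-path seeds drawn reproducibly from the root
#' `seed`.  Per-time moments are accumulated with Welford's streaming
#' algorithm; the full per-time value array is retained for quantiles and
#' histogramming.
#'
#' @param scenario a [malnut_scenario()].
#' @param schedule a [piecewise_schedule()].
#' @param order fractional order for the middle regime.
#' @param kernel kernel choice, as in [piecewise_solve()].
#' @param n_paths number of ensemble members (>= 1).
#' @param seed root integer seed.
#' @param ... passed to [piecewise_solve()].
#' @return An object of class `ensemble_summary`: list with `times`,
#'   `regime`, per-time `mean`, `var` and quantile matrices `q025`, `q50`,
#'   `q975` (times x compartments), the `values` array
#'   (times x compartments x paths), `n_paths`, `seeds`.
#' @export
run_ensemble <- function(scenario, schedule, order = 1,
                         kernel = "power_law", n_paths, seed = NULL, ...) {
  stopifnot(inherits(scenario, "malnut_scenario"),
            inherits(schedule, "piecewise_schedule"))
  if (n_paths < 1 || n_paths != round(n_paths)) stop("'n_paths' must be >= 1")
  path_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, n_paths))
  n3 <- if (schedule$T > schedule$T2)
    as.integer(round((schedule$T - schedule$T2) / schedule$dz)) else 0L

  run_one <- function(ps) {
    pth <- if (n3 > 0) brownian_increments(n3, schedule$dz, 4, ps) else NULL
    piecewise_solve(scenario$params, scenario$noise, scenario$y0, schedule,
                    order = order, kernel = kernel, seed = ps, paths = pth,
                    ...)
  }
  first <- run_one(path_seeds[1])
  nt <- nrow(first)
  vals <- array(NA_real_, dim = c(nt, 4L, n_paths),
                dimnames = list(NULL, .COMPARTMENTS, NULL))
  mean_ <- as.matrix(first[, .COMPARTMENTS])
  M2 <- matrix(0, nt, 4L)
  vals[, , 1] <- mean_
  if (n_paths > 1) for (i in 2:n_paths) {
    tr <- run_one(path_seeds[i])
    x <- as.matrix(tr[, .COMPARTMENTS])
    vals[, , i] <- x
    delta <- x - mean_
    mean_ <- mean_ + delta / i
    M2 <- M2 + delta * (x - mean_)
  }
  var_ <- if (n_paths > 1) M2 / (n_paths - 1) else M2
  qs <- apply(vals, c(1, 2), stats::quantile,
              probs = c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  dimnames(mean_) <- dimnames(var_) <- list(NULL, .COMPARTMENTS)
  structure(list(times = first$time, regime = first$regime,
                 mean = mean_, var = var_,
                 q025 = qs[1, , ], q50 = qs[2, , ], q975 = qs[3, , ],
                 values = vals, n_paths = as.integer(n_paths),
                 seeds = path_seeds, schedule = schedule,
                 order = order, kernel = kernel),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble summary:", x$n_paths, "paths,", length(x$times),
      "grid points,", x$kernel, "kernel, order", x$order, "\n")
  i <- length(x$times)
  cat("terminal mean:", paste(sprintf("%s=%.4g", .COMPARTMENTS, x$mean[i, ]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Terminal-time histogram with moment-fitted normal
#'
#' Histogram of one compartment's ensemble values at a requested grid time,
#' with equal-width bins over the observed range, plus the moment-fitted
#' normal parameters (mean, variance) used for the stationary-distribution
#' frequency plots.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param compartment one of `"Sf"`, `"Mb"`, `"Mg"`, `"U"`.
#' @param time a time on the ensemble grid (error if off-grid).
#' @param n_bins number of bins (>= 2).
#' @return An object of class `histogram_report`: list with `compartment`,
#'   `time`, `edges`, `counts`, `fitted_mean`, `fitted_var`, `n_paths`.
#' @export
terminal_histogram <- function(ensemble, compartment, time, n_bins = 20L) {
  stopifnot(inherits(ensemble, "ensemble_summary"))
  compartment <- match.arg(compartment, .COMPARTMENTS)
  if (n_bins < 2) stop("'n_bins' must be >= 2")
  i <- which(abs(ensemble$times - time) <= 1e-9 * max(1, abs(time)))
  if (length(i) != 1L) stop("requested time ", time, " is not on the grid")
  x <- ensemble$values[i, compartment, ]
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)   # degenerate: one point mass
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, edges, all.inside = TRUE), 1L),
                          n_bins), nbins = n_bins)
  structure(list(compartment = compartment, time = ensemble$times[i],
                 edges = edges, counts = counts,
                 fitted_mean = mean(x),
                 fitted_var = if (length(x) > 1) stats::var(x) else 0,
                 n_paths = ensemble$n_paths),
            class = "histogram_report")
}

#' Time average of a statistic along a trajectory segment
#'
#' Grid-point average of `statistic` applied to each state, optionally
#' restricted to times `>= from`.  This is the empirical left side of the
#' ergodic-average property (time average = stationary ensemble average).
#'
#' @param trajectory a `malnut_trajectory` or `pw_segment`.
#' @param statistic function mapping a state vector to a scalar.
#' @param from lower time cutoff (default: include everything).
#' @return A scalar.
#' @export
time_average <- function(trajectory, statistic, from = -Inf) {
  if (inherits(trajectory, "malnut_trajectory")) {
    keep <- trajectory$time >= from
    states <- as.matrix(trajectory[keep, .COMPARTMENTS])
  } else if (inherits(trajectory, "pw_segment")) {
    keep <- trajectory$times >= from
    states <- trajectory$states[keep, , drop = FALSE]
  } else stop("unsupported trajectory object")
  mean(apply(states, 1, statistic))
}

#' Ergodic-average diagnostic
#'
#' Compares the time average of a statistic along one long stochastic-regime
#' path against the ensemble average of the same statistic at terminal time
#' over `n_paths` independent paths.  Under a unique ergodic stationary
#' distribution the two coincide; the comparison is reported with
#' Monte-Carlo error bars as a diagnostic (it is asserted only for analytic
#' oracle processes in the test suite).
#'
#' @param scenario a [malnut_scenario()].
#' @param schedule a [piecewise_schedule()]; its horizon `T` is replaced by
#'   `T_long` for the single long path.
#' @param order,kernel passed to the solver.
#' @param statistic function mapping a state vector to a scalar.
#' @param T_long horizon of the long path; must be `>= 10 * T2`.
#' @param seed root integer seed.
#' @param n_paths ensemble size for the terminal average (default 500).
#' @return An object of class `ergodic_report`: list with `time_average`,
#'   `time_average_se` (batch-means), `ensemble_average`, `ensemble_se`,
#'   `n_paths`, `T_long`.
#' @export
ergodic_average_check <- function(scenario, schedule, order = 1,
                                  kernel = "power_law", statistic,
                                  T_long, seed = NULL, n_paths = 500L) {
  stopifnot(inherits(schedule, "piecewise_schedule"))
  if (T_long < 10 * schedule$T2)
    stop("'T_long' must be at least 10 * T2 for the time average to settle")
  long_sched <- piecewise_schedule(schedule$dz, schedule$T1, schedule$T2,
                                   T_long)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, 2))
  long <- piecewise_solve(scenario$params, scenario$noise, scenario$y0,
                          long_sched, order = order, kernel = kernel,
                          seed = seeds[1])
  keep <- long$time >= schedule$T2
  f_along <- apply(as.matrix(long[keep, .COMPARTMENTS]), 1, statistic)
  tavg <- mean(f_along)
  nb <- 20L                                      # batch means for the SE
  batch <- tapply(f_along, cut(seq_along(f_along), nb), mean)
  tavg_se <- stats::sd(batch) / sqrt(nb)
  ens <- run_ensemble(scenario, schedule, order = order, kernel = kernel,
                      n_paths = n_paths, seed = seeds[2])
  i <- length(ens$times)
  f_end <- apply(ens$values[i, , ], 2, statistic)
  structure(list(time_average = tavg, time_average_se = tavg_se,
                 ensemble_average = mean(f_end),
                 ensemble_se = stats::sd(f_end) / sqrt(n_paths),
                 n_paths = as.integer(n_paths), T_long = T_long),
            class = "ergodic_report")
}

#' @export
print.ergodic_report <- function(x, ...) {
  cat(sprintf("Ergodic diagnostic: time average %.6g (SE %.2g) vs ensemble average %.6g (SE %.2g), %d paths, T_long = %g\n",
              x$time_average, x$time_average_se, x$ensemble_average,
              x$ensemble_se, x$n_paths, x$T_long))
  invisible(x)
}

#' Positivity audit of a trajectory
#'
#' The schemes are not positivity-preserving and never clip; this scan
#' reports the minimum value per compartment and the first negative entry,
#' if any, so that the theoretical positivity property can be audited rather
#' than enforced.  The trajectory is never mutated.
#'
#' @param trajectory a `malnut_trajectory` or `pw_segment`.
#' @return List with `clean` (logical), `min_values`, and `first_violation`
#'   (`NULL`, or list with `time`, `component`, `value`).
#' @export
positivity_check <- function(trajectory) {
  if (inherits(trajectory, "malnut_trajectory")) {
    times <- trajectory$time
    states <- as.matrix(trajectory[, .COMPARTMENTS])
  } else if (inherits(trajectory, "pw_segment")) {
    times <- trajectory$times
    states <- trajectory$states
    colnames(states) <- paste0("y", seq_len(ncol(states)))
  } else stop("unsupported trajectory object")
  mins <- apply(states, 2, min)
  neg <- which(states < 0, arr.ind = TRUE)
  first <- NULL
  if (nrow(neg) > 0) {
    j <- neg[which.min(times[neg[, 1]]), , drop = FALSE]
    first <- list(time = times[j[1, 1]],
                  component = colnames(states)[j[1, 2]],
                  value = states[j[1, 1], j[1, 2]])
  }
  list(clean = is.null(first), min_values = mins, first_violation = first)
}

#' Empirical convergence order on a step ladder
#'
#' Integrates a test problem with a deterministic solver over a ladder of
#' halved step sizes and estimates the convergence order as the mean
#' \eqn{\log_2} ratio of successive maximum errors against the analytic
#' solution.  Errors that are identically zero are reported as `exact`
#' (order undefined); non-monotone errors are reported raw with a warning
#' flag and no order.
#'
#' @param solver a segment integrator with signature
#'   `function(field, y0, t_start, t_end, dz, ...)`, e.g. [ab3_integrate()].
#' @param problem list with `field`, `y0`, `t_start`, `t_end` and `exact`
#'   (a vectorized function of time returning the solution).
#' @param dz_ladder decreasing step sizes, each half the previous, length
#'   >= 3.
#' @param ... passed to the solver (e.g. `order` for fractional solvers).
#' @return List with `dz`, `errors`, `order` (NA if not estimable), `exact`,
#'   `monotone`.
#' @export
convergence_order <- function(solver, problem, dz_ladder, ...) {
  if (length(dz_ladder) < 3) stop("need at least 3 ladder steps")
  if (any(abs(dz_ladder[-1] * 2 - dz_ladder[-length(dz_ladder)]) >
          1e-9 * dz_ladder[-1]))
    stop("'dz_ladder' must halve at each step")
  errs <- vapply(dz_ladder, function(h) {
    seg <- solver(problem$field, problem$y0, problem$t_start, problem$t_end,
                  h, ...)
    ex <- problem$exact(seg$times)
    if (is.null(dim(ex))) ex <- matrix(ex, ncol = ncol(seg$states))
    max(abs(seg$states - ex))
  }, numeric(1))
  if (all(errs <= 1e-12))   # at roundoff level: the scheme is exact here
    return(list(dz = dz_ladder, errors = errs, order = NA_real_,
                exact = TRUE, monotone = TRUE))
  if (any(diff(errs) >= 0))
    return(list(dz = dz_ladder, errors = errs, order = NA_real_,
                exact = FALSE, monotone = FALSE))
  list(dz = dz_ladder, errors = errs,
       order = mean(log2(errs[-length(errs)] / errs[-1])),
       exact = FALSE, monotone = TRUE)
}

#' Strong convergence order of Euler-Maruyama on geometric Brownian motion
#'
#' Drives scalar geometric Brownian motion \eqn{dy = \sigma y\, dW}
#' (zero drift) with one shared fine Brownian path per ensemble member,
#' coarsened across the step ladder, and estimates the strong order from the
#' mean absolute terminal error against the closed form
#' \eqn{y_0\exp(-\sigma^2 t/2 + \sigma W_t)}.
#'
#' @param sigma noise intensity.
#' @param y0 initial value.
#' @param t_end horizon.
#' @param dz_ladder decreasing, halving step sizes; the finest must divide
#'   `t_end`.
#' @param n_paths Monte-Carlo sample size.
#' @param seed root integer seed.
#' @return List with `dz`, `strong_errors`, `order`.
#' @export
em_strong_order_gbm <- function(sigma, y0 = 1, t_end = 1,
                                dz_ladder = c(0.02, 0.01, 0.005, 0.0025),
                                n_paths = 200L, seed = 1L) {
  if (any(abs(dz_ladder[-1] * 2 - dz_ladder[-length(dz_ladder)]) >
          1e-9 * dz_ladder[-1]))
    stop("'dz_ladder' must halve at each step")
  h_fine <- dz_ladder[length(dz_ladder)]
  n_fine <- round(t_end / h_fine)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, n_paths))
  field <- function(t, y) 0 * y
  diff_fn <- function(t, y) sigma * y
  abs_err <- matrix(NA_real_, n_paths, length(dz_ladder))
  for (i in seq_len(n_paths)) {
    fine <- brownian_increments(n_fine, h_fine, dims = 1, seed = seeds[i])
    WT <- sum(fine$increments)
    exact <- y0 * exp(-sigma^2 * t_end / 2 + sigma * WT)
    for (j in seq_along(dz_ladder)) {
      pth <- coarsen_paths(fine, round(dz_ladder[j] / h_fine))
      seg <- euler_maruyama_integrate(field, diff_fn, y0, 0, t_end,
                                      dz_ladder[j], pth)
      abs_err[i, j] <- abs(seg$states[nrow(seg$states), 1] - exact)
    }
  }
  errs <- colMeans(abs_err)
  list(dz = dz_ladder, strong_errors = errs,
       order = mean(log2(errs[-length(errs)] / errs[-1])))
}
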