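# Three-regime piecewise integrators: classical three-step Adams-Bashforth,
# the Newton-polynomial fractional multistep schemes (power-law,
# exponential-decay and Mittag-Leffler kernels), the stochastic multistep,
# and an Euler-Maruyama reference solver.
#
# Conventions shared by all multistep schemes:
#  * the value at grid point m+1 is computed from field values at grid
#    points <= m (fully explicit reading of the printed sums);
#  * the first two steps of each regime are bootstrapped with classical
#    4th-order Runge-Kutta substeps at dz/10, which preserves the schemes'
#    order without inventing history;
#  * fractional branches retain the full history (O(n^2) work; desk-scale
#    horizons make this acceptable) and add the kernel quadrature over the
#    first two grid cells (exact kernel moments against the Lagrange
#    polynomial through Phi^0, Phi^1, Phi^2; Simpson's rule at order 1),
#    which the printed sums, starting at index 2, leave uncovered;
#  * schemes never clip negative states; use positivity_check() to audit.

#' Piecewise schedule
#'
#' Grid and regime-switch times for the three-regime solve: classical
#' dynamics on `[0, T1]`, fractional-memory dynamics on `[T1, T2]`,
#' stochastic dynamics on `[T2, T]`.
#'
#' @param dz step size (days), positive.
#' @param T1,T2,T regime switch times and final horizon,
#'   `0 <= T1 <= T2 <= T`; each must be an integer multiple of `dz` within
#'   1e-9 relative (values are snapped to the grid).
#' @return An object of class `piecewise_schedule`.
#' @export
piecewise_schedule <- function(dz, T1, T2, T) {
  if (!is.numeric(dz) || length(dz) != 1L || !is.finite(dz) || dz <= 0)
    stop("'dz' must be a single positive number")
  snap <- function(x, nm) {
    k <- x / dz
    if (abs(k - round(k)) > 1e-9 * max(1, abs(k)))
      stop("'", nm, "' is not an integer multiple of dz (relative mismatch ",
           signif(abs(k - round(k)) / max(1, abs(k)), 3), ")")
    round(k) * dz
  }
  T1 <- snap(T1, "T1"); T2 <- snap(T2, "T2"); T <- snap(T, "T")
  if (T1 < 0 || T1 > T2 || T2 > T)
    stop("schedule must satisfy 0 <= T1 <= T2 <= T")
  structure(list(dz = dz, T1 = T1, T2 = T2, T = T),
            class = "piecewise_schedule")
}

#' @export
print.piecewise_schedule <- function(x, ...) {
  cat(sprintf("Piecewise schedule: dz = %g, classical [0, %g], fractional [%g, %g], stochastic [%g, %g]\n",
              x$dz, x$T1, x$T1, x$T2, x$T2, x$T))
  invisible(x)
}

.grid_n <- function(t_start, t_end, dz) {
  n <- (t_end - t_start) / dz
  if (n < 1 - 1e-9 || abs(n - round(n)) > 1e-9 * max(1, n))
    stop("(t_end - t_start)/dz must be a positive integer")
  as.integer(round(n))
}

.segment <- function(times, states) {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  structure(list(times = times, states = states), class = "pw_segment")
}

.check_field_value <- function(phi, t) {
  if (!all(is.finite(phi)))
    stop("non-finite field value at t = ", signif(t, 10))
  phi
}

# classical RK4 over one grid step, nsub substeps of h/nsub
.rk4_bootstrap <- function(field, t0, y, h, nsub = 10L) {
  hs <- h / nsub
  for (i in seq_len(nsub)) {
    t <- t0 + (i - 1) * hs
    k1 <- field(t, y)
    k2 <- field(t + hs / 2, y + hs / 2 * k1)
    k3 <- field(t + hs / 2, y + hs / 2 * k2)
    k4 <- field(t + hs, y + hs * k3)
    y <- y + hs / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

#' Classical three-step Adams-Bashforth integrator
#'
#' Explicit AB3: the step to grid point \eqn{m+1} uses field values at the
#' three most recent computed points with weights
#' \eqn{(23/12, -16/12, 5/12)\,\Delta\zeta}.  The first two steps are
#' bootstrapped with RK4 substeps at \eqn{\Delta\zeta/10}.
#'
#' @param field function `f(t, y)` returning the rate vector.
#' @param y0 initial state (numeric vector, any dimension).
#' @param t_start,t_end integration window; `(t_end - t_start)/dz` must be a
#'   positive integer.
#' @param dz step size.
#' @return A `pw_segment`: list with `times` (length n+1) and `states`
#'   ((n+1) x d matrix).
#' @export
#' @examples
#' seg <- ab3_integrate(function(t, y) -y, 1, 0, 2, 0.01)
#' max(abs(seg$states[, 1] - exp(-seg$times)))
ab3_integrate <- function(field, y0, t_start, t_end, dz) {
  n <- .grid_n(t_start, t_end, dz)
  d <- length(y0)
  times <- t_start + dz * (0:n)
  Y <- matrix(NA_real_, n + 1, d)
  Phi <- matrix(NA_real_, n + 1, d)
  Y[1, ] <- y0
  Phi[1, ] <- .check_field_value(field(t_start, y0), t_start)
  for (m in seq_len(min(2L, n))) {
    Y[m + 1, ] <- .rk4_bootstrap(field, times[m], Y[m, ], dz)
    Phi[m + 1, ] <- .check_field_value(field(times[m + 1], Y[m + 1, ]),
                                       times[m + 1])
  }
  if (n >= 3) for (m in 3:n) {
    Y[m + 1, ] <- Y[m, ] + dz * (23 / 12 * Phi[m, ] - 4 / 3 * Phi[m - 1, ] +
                                   5 / 12 * Phi[m - 2, ])
    Phi[m + 1, ] <- .check_field_value(field(times[m + 1], Y[m + 1, ]),
                                       times[m + 1])
  }
  .segment(times, Y)
}

# Kernel quadrature over the first two grid cells [t0, t0 + 2h] against the
# Lagrange polynomial through (t0, Phi0), (t1, Phi1), (t2, Phi2), for target
# time t_{m+1} = t0 + (m+1) h.  Returns weights (w0, w1, w2) such that the
# contribution to the history integral is (w0*Phi0 + w1*Phi1 + w2*Phi2)
# (the 1/Gamma(lam) prefactor is NOT included).  At lam = 1 this is
# Simpson's rule.
.startup_weights <- function(lam, h, m) {
  b <- (m + 1) * h          # t_{m+1} - t0
  a <- (m - 1) * h          # t_{m+1} - t2
  mu <- function(j) (b^(lam + j) - a^(lam + j)) / (lam + j)
  m0 <- mu(0); m1 <- mu(1); m2 <- mu(2)
  # in u = t_{m+1} - s:  s - t0 = b - u,  s - t1 = (b - h) - u,  s - t2 = a - u
  w0 <- ((b - h) * a * m0 - (a + b - h) * m1 + m2) / (2 * h^2)
  w1 <- -(b * a * m0 - (a + b) * m1 + m2) / h^2
  w2 <- (b * (b - h) * m0 - (2 * b - h) * m1 + m2) / (2 * h^2)
  c(w0, w1, w2)
}

# Shared engine for the power-law and Mittag-Leffler history branches.
# history_scale multiplies the whole memory integral (1 for Caputo,
# lam/ABC(lam) for ABC); local_coef multiplies the non-local pointwise term
# ((1-lam)/ABC or lam/ABC for ABC, 0 for Caputo).
.frac_newton_integrate <- function(field, y0, lam, t_start, t_end, dz,
                                   history_scale = 1, local_coef = 0,
                                   weights_as_printed = FALSE) {
  n <- .grid_n(t_start, t_end, dz)
  d <- length(y0)
  times <- t_start + dz * (0:n)
  Y <- matrix(NA_real_, n + 1, d)
  Phi <- matrix(NA_real_, n + 1, d)
  Y[1, ] <- y0
  Phi[1, ] <- .check_field_value(field(t_start, y0), t_start)
  for (m in seq_len(min(2L, n))) {
    Y[m + 1, ] <- .rk4_bootstrap(field, times[m], Y[m, ], dz)
    Phi[m + 1, ] <- .check_field_value(field(times[m + 1], Y[m + 1, ]),
                                       times[m + 1])
  }
  if (n >= 3) {
    W <- .newton_weights(0:(n - 2), lam, as_printed = weights_as_printed)
    if (any(!is.finite(W$I1)))
      stop("as-printed weight I1 is complex on this index range")
    c1 <- dz^lam / gamma(lam + 1)
    c2 <- dz^lam / gamma(lam + 2)
    c3 <- lam * dz^lam / (2 * gamma(lam + 3))
    glam <- gamma(lam)
    for (m in 2:(n - 1)) {
      sg <- 2:m                       # summation index
      lag <- m - sg + 1L              # index into lag-ordered weight vectors
      A <- Phi[sg - 1, , drop = FALSE]      # Phi^{s-2}
      Bm <- Phi[sg, , drop = FALSE]         # Phi^{s-1}
      Cm <- Phi[sg + 1, , drop = FALSE]     # Phi^{s}
      S <- c1 * colSums(A * W$I1[lag]) +
        c2 * colSums((Bm - A) * W$I2[lag]) +
        c3 * colSums((Cm - 2 * Bm + A) * W$I3[lag])
      sw <- .startup_weights(lam, dz, m)
      S <- S + (sw[1] * Phi[1, ] + sw[2] * Phi[2, ] + sw[3] * Phi[3, ]) / glam
      Y[m + 2, ] <- Y[1, ] + local_coef * Phi[m + 1, ] + history_scale * S
      Phi[m + 2, ] <- .check_field_value(field(times[m + 2], Y[m + 2, ]),
                                         times[m + 2])
    }
  }
  .segment(times, Y)
}

#' Power-law (Caputo) kernel multistep integrator
#'
#' Solves the fractional initial-value problem with power-law memory kernel,
#' \eqn{D^\Lambda y = \Phi(t, y)}, \eqn{y(t_{start}) = y_0}, by the
#' Newton-polynomial multistep scheme: the value at grid point \eqn{m+1} is
#' the initial state plus three \eqn{\Im}-weighted history sums over the full
#' past, with prefactors \eqn{\Delta\zeta^\Lambda/\Gamma(\Lambda+1)},
#' \eqn{\Delta\zeta^\Lambda/\Gamma(\Lambda+2)} and
#' \eqn{\Lambda\Delta\zeta^\Lambda/(2\Gamma(\Lambda+3))}.  At
#' \eqn{\Lambda = 1} the scheme collapses to [ab3_integrate()].
#'
#' @inheritParams ab3_integrate
#' @param order fractional order \eqn{\Lambda \in (0, 1]}.
#' @param weights_as_printed use the literal published \eqn{\Im_1}/\eqn{\Im_3}
#'   forms (diagnostic; see [caputo_weights()]).
#' @return A `pw_segment`.
#' @export
#' @examples
#' seg <- caputo_integrate(function(t, y) -y, 1, 0.7, 0, 1, 0.01)
#' exact <- mittag_leffler(-seg$times^0.7, 0.7)
#' max(abs(seg$states[, 1] - exact) / exact)
caputo_integrate <- function(field, y0, order, t_start, t_end, dz,
                             weights_as_printed = FALSE) {
  lam <- .check_order(order)
  .frac_newton_integrate(field, y0, lam, t_start, t_end, dz,
                         history_scale = 1, local_coef = 0,
                         weights_as_printed = weights_as_printed)
}

#' Exponential-decay (Caputo-Fabrizio) kernel multistep integrator
#'
#' The value at grid point \eqn{m+1} combines a pointwise (non-local) term
#' \eqn{(1-\Lambda)/\bar M(\Lambda)\,\Phi} with a
#' \eqn{\Lambda/\bar M(\Lambda)}-weighted AB3 cumulative sum, with
#' \eqn{\bar M(\Lambda) = 2/(2-\Lambda)} from [cf_normalization()].  At
#' \eqn{\Lambda = 1} the pointwise term vanishes and the scheme equals AB3
#' applied to the half-field \eqn{\Phi/\bar M(1) = \Phi/2}, exactly as the
#' printed coefficients collapse.
#'
#' @inheritParams caputo_integrate
#' @return A `pw_segment`.
#' @export
cf_integrate <- function(field, y0, order, t_start, t_end, dz) {
  lam <- .check_order(order)
  Mbar <- cf_normalization(lam)
  loc <- (1 - lam) / Mbar
  eff <- function(t, y) (lam / Mbar) * field(t, y)
  n <- .grid_n(t_start, t_end, dz)
  d <- length(y0)
  times <- t_start + dz * (0:n)
  Y <- matrix(NA_real_, n + 1, d)
  Phi <- matrix(NA_real_, n + 1, d)   # raw field values
  Y[1, ] <- y0
  Phi[1, ] <- .check_field_value(field(t_start, y0), t_start)
  for (m in seq_len(min(2L, n))) {
    # pointwise term enters as its increment between consecutive grid points
    Y[m + 1, ] <- .rk4_bootstrap(eff, times[m], Y[m, ], dz) +
      loc * (Phi[m, ] - if (m == 1) Phi[1, ] else Phi[m - 1, ])
    Phi[m + 1, ] <- .check_field_value(field(times[m + 1], Y[m + 1, ]),
                                       times[m + 1])
  }
  if (n >= 3) for (m in 3:n) {
    Y[m + 1, ] <- Y[m, ] + loc * (Phi[m, ] - Phi[m - 1, ]) +
      (lam / Mbar) * dz * (23 / 12 * Phi[m, ] - 4 / 3 * Phi[m - 1, ] +
                             5 / 12 * Phi[m - 2, ])
    Phi[m + 1, ] <- .check_field_value(field(times[m + 1], Y[m + 1, ]),
                                       times[m + 1])
  }
  .segment(times, Y)
}

#' Mittag-Leffler (Atangana-Baleanu-Caputo) kernel multistep integrator
#'
#' Same history machinery as [caputo_integrate()] but with every history sum
#' scaled by \eqn{\Lambda/ABC(\Lambda)} and a pointwise (non-local) term
#' added.  `local_term = "standard"` (default) uses the coefficient
#' \eqn{(1-\Lambda)/ABC(\Lambda)} carried by the operator's integral, which
#' vanishes at \eqn{\Lambda = 1} so that the scheme then agrees with the
#' power-law branch exactly.  `local_term = "as_printed"` uses the published
#' coefficient \eqn{\Lambda/ABC(\Lambda)} instead; the two outputs differ by
#' exactly \eqn{(2\Lambda-1)/ABC(\Lambda)\,\Phi} in each step's pointwise
#' term.
#'
#' @inheritParams caputo_integrate
#' @param local_term `"standard"` or `"as_printed"` (see Description).
#' @return A `pw_segment`.
#' @export
abc_integrate <- function(field, y0, order, t_start, t_end, dz,
                          local_term = c("standard", "as_printed"),
                          weights_as_printed = FALSE) {
  lam <- .check_order(order)
  local_term <- match.arg(local_term)
  abc <- abc_normalization(lam)
  loc <- if (local_term == "standard") (1 - lam) / abc else lam / abc
  .frac_newton_integrate(field, y0, lam, t_start, t_end, dz,
                         history_scale = lam / abc, local_coef = loc,
                         weights_as_printed = weights_as_printed)
}

.check_paths_cover <- function(paths, n, dz, d) {
  if (!inherits(paths, "brownian_paths"))
    stop("'paths' must be a brownian_paths object")
  if (abs(paths$dz - dz) > 1e-12 * max(1, dz))
    stop("path increment spacing does not match the integration grid")
  if (ncol(paths$increments) < d)
    stop("paths have fewer dimensions than the state")
  if (nrow(paths$increments) < n)
    stop("paths cover ", nrow(paths$increments), " steps; segment needs ", n)
  paths$increments[seq_len(n), seq_len(d), drop = FALSE]
}

#' Stochastic three-step Adams-Bashforth integrator
#'
#' The deterministic AB3 update plus noise terms pairing the Brownian
#' increments at lags \eqn{(\varsigma, \varsigma-1, \varsigma-2)} with the
#' multiplicative amplitudes \eqn{\sigma_k y_k} at the same lags and the AB3
#' weights \eqn{(23/12, -4/3, 5/12)}:
#' \deqn{y^{\varsigma+1} = y^\varsigma + \Delta\zeta\,(\ldots) +
#'  \tfrac{23}{12}\Delta W_\varsigma\,\sigma y^\varsigma -
#'  \tfrac{4}{3}\Delta W_{\varsigma-1}\,\sigma y^{\varsigma-1} +
#'  \tfrac{5}{12}\Delta W_{\varsigma-2}\,\sigma y^{\varsigma-2}.}
#' The printed backward summation is re-indexed as this forward cumulative
#' recursion from the regime start.  The two bootstrap steps use the RK4
#' deterministic bootstrap plus a plain Euler-Maruyama noise term (the lagged
#' increments do not exist yet).  With all noise intensities (or all
#' increments) zero the output is bit-identical to [ab3_integrate()].
#'
#' @inheritParams ab3_integrate
#' @param noise numeric length-d multiplicative noise intensities.
#' @param paths a [brownian_increments()] object covering at least
#'   `(t_end - t_start)/dz` steps at spacing `dz`.
#' @return A `pw_segment`.
#' @export
stochastic_ab3_integrate <- function(field, noise, y0, t_start, t_end, dz,
                                     paths) {
  n <- .grid_n(t_start, t_end, dz)
  d <- length(y0)
  if (length(noise) != d) stop("'noise' must have one intensity per component")
  sig <- as.numeric(noise)
  dW <- .check_paths_cover(paths, n, dz, d)
  times <- t_start + dz * (0:n)
  Y <- matrix(NA_real_, n + 1, d)
  Phi <- matrix(NA_real_, n + 1, d)
  Y[1, ] <- y0
  Phi[1, ] <- .check_field_value(field(t_start, y0), t_start)
  for (m in seq_len(min(2L, n))) {
    Y[m + 1, ] <- .rk4_bootstrap(field, times[m], Y[m, ], dz) +
      sig * Y[m, ] * dW[m, ]
    Phi[m + 1, ] <- .check_field_value(field(times[m + 1], Y[m + 1, ]),
                                       times[m + 1])
  }
  if (n >= 3) for (m in 3:n) {
    Y[m + 1, ] <- Y[m, ] + dz * (23 / 12 * Phi[m, ] - 4 / 3 * Phi[m - 1, ] +
                                   5 / 12 * Phi[m - 2, ]) +
      23 / 12 * dW[m, ] * sig * Y[m, ] -
      4 / 3 * dW[m - 1, ] * sig * Y[m - 1, ] +
      5 / 12 * dW[m - 2, ] * sig * Y[m - 2, ]
    Phi[m + 1, ] <- .check_field_value(field(times[m + 1], Y[m + 1, ]),
                                       times[m + 1])
  }
  .segment(times, Y)
}

#' Euler-Maruyama reference integrator
#'
#' First-order (strong 0.5) discretization
#' \eqn{y_{n+1} = y_n + \Phi(t_n, y_n)\Delta\zeta + g(t_n, y_n)\circ\Delta W_n},
#' used as the cross-validation oracle for the stochastic multistep.
#'
#' @inheritParams ab3_integrate
#' @param diffusion function `g(t, y)` returning the length-d amplitude
#'   vector multiplying the Brownian increments (elementwise).
#' @param paths a [brownian_increments()] object.
#' @return A `pw_segment`.
#' @export
euler_maruyama_integrate <- function(field, diffusion, y0, t_start, t_end,
                                     dz, paths) {
  n <- .grid_n(t_start, t_end, dz)
  d <- length(y0)
  dW <- .check_paths_cover(paths, n, dz, d)
  times <- t_start + dz * (0:n)
  Y <- matrix(NA_real_, n + 1, d)
  Y[1, ] <- y0
  for (m in seq_len(n)) {
    y <- Y[m, ]
    Y[m + 1, ] <- y + .check_field_value(field(times[m], y), times[m]) * dz +
      diffusion(times[m], y) * dW[m, ]
  }
  .segment(times, Y)
}

#' Three-regime piecewise solve of the malnutrition model
#'
#' Integrates the model through its three consecutive regimes: classical AB3
#' on `[0, T1]`, the kernel-selected fractional multistep on `[T1, T2]`
#' initialized at the classical terminal state, and the stochastic multistep
#' on `[T2, T]` initialized at the fractional terminal state with seeded
#' Brownian paths.  The state at each regime boundary is shared exactly by
#' both adjacent regimes.
#'
#' @param params a [malnut_params()] object.
#' @param noise numeric length-4 noise intensities.
#' @param y0 numeric length-4 initial state.
#' @param schedule a [piecewise_schedule()].
#' @param order fractional order \eqn{\Lambda \in (0, 1]} for the middle
#'   regime.
#' @param kernel `"power_law"`, `"exponential_decay"` or `"mittag_leffler"`.
#' @param seed integer seed for the Brownian paths of the stochastic regime
#'   (ignored when `T2 == T`).
#' @param paths optional pre-generated [brownian_increments()] overriding
#'   `seed`.
#' @param ... further arguments passed to the fractional integrator
#'   (e.g. `local_term` for the Mittag-Leffler kernel).
#' @return An object of class `malnut_trajectory`: a data frame with columns
#'   `time`, `regime`, `Sf`, `Mb`, `Mg`, `U` and attributes `seed`, `kernel`,
#'   `order`, `schedule`, `params`, `noise`.
#' @export
#' @examples
#' sc <- baseline_scenario()
#' tr <- piecewise_solve(sc$params, sc$noise, sc$y0,
#'                       piecewise_schedule(0.05, 10, 20, 30),
#'                       order = 0.95, kernel = "power_law", seed = 1)
#' head(tr)
piecewise_solve <- function(params, noise, y0, schedule, order = 1,
                            kernel = c("power_law", "exponential_decay",
                                       "mittag_leffler"),
                            seed = NULL, paths = NULL, ...) {
  stopifnot(inherits(params, "malnut_params"),
            inherits(schedule, "piecewise_schedule"))
  kernel <- match.arg(kernel)
  y0 <- .as_state(y0)
  sig <- .as_sigma(noise)
  field <- malnut_field(params)
  dz <- schedule$dz
  frac_fun <- switch(kernel,
                     power_law = caputo_integrate,
                     exponential_decay = cf_integrate,
                     mittag_leffler = abc_integrate)

  times <- NULL; states <- NULL; regime <- NULL
  append_seg <- function(seg, label, drop_first) {
    k <- if (drop_first) -1L else TRUE
    times <<- c(times, seg$times[k])
    states <<- rbind(states, seg$states[k, , drop = FALSE])
    regime <<- c(regime, rep(label, length(seg$times[k])))
  }

  y <- y0
  if (schedule$T1 > 0) {
    seg1 <- ab3_integrate(field, y, 0, schedule$T1, dz)
    append_seg(seg1, "classical", drop_first = FALSE)
    y <- seg1$states[nrow(seg1$states), ]
  } else {
    times <- 0; states <- matrix(y, 1); regime <- "classical"
  }
  if (schedule$T2 > schedule$T1) {
    seg2 <- frac_fun(field, y, order, schedule$T1, schedule$T2, dz, ...)
    append_seg(seg2, "fractional", drop_first = TRUE)
    y <- seg2$states[nrow(seg2$states), ]
  }
  if (schedule$T > schedule$T2) {
    n3 <- .grid_n(schedule$T2, schedule$T, dz)
    if (is.null(paths))
      paths <- brownian_increments(n3, dz, dims = 4, seed = seed)
    seg3 <- stochastic_ab3_integrate(field, sig, y, schedule$T2, schedule$T,
                                     dz, paths)
    append_seg(seg3, "stochastic", drop_first = TRUE)
  }

  out <- data.frame(time = times, regime = regime,
                    Sf = states[, 1], Mb = states[, 2],
                    Mg = states[, 3], U = states[, 4])
  rownames(out) <- NULL
  structure(out, class = c("malnut_trajectory", "data.frame"),
            seed = seed, kernel = kernel, order = order,
            schedule = schedule, params = params, noise = sig)
}

#' Write a trajectory as CSV plus a JSON metadata sidecar
#'
#' Writes `<prefix>.csv` with header `time,regime,Sf,Mb,Mg,U` (one row per
#' grid point, full precision) and `<prefix>.json` recording seed, kernel,
#' order, schedule and a parameter echo.
#'
#' @param trajectory a [piecewise_solve()] result.
#' @param prefix output path prefix.
#' @return The CSV path, invisibly.
#' @export
write_trajectory <- function(trajectory, prefix) {
  stopifnot(inherits(trajectory, "malnut_trajectory"))
  csv <- paste0(prefix, ".csv")
  df <- as.data.frame(trajectory)
  for (cn in c("time", "Sf", "Mb", "Mg", "U"))
    df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  sched <- attr(trajectory, "schedule")
  meta <- list(seed = attr(trajectory, "seed"),
               kernel = attr(trajectory, "kernel"),
               order = attr(trajectory, "order"),
               schedule = unclass(sched),
               params = unclass(attr(trajectory, "params")),
               noise = as.numeric(attr(trajectory, "noise")),
               n_points = nrow(trajectory))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(csv)
}
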