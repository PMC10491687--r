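# Drift and diffusion fields, equilibria and threshold quantities of the
# four-compartment malnutrition model.
#
# Compartments: Sf (susceptible females), Mb (malnourished boys),
# Mg (malnourished girls), U (underweight individuals).  The deterministic
# field is
#   dSf/dt = (B + eps) - (lam_b*Mb + lam_g*Mg + theta)*Sf + del_g*Mg
#   dMb/dt = lam_b*Sf*Mb - (theta_b + gam_b + theta)*Mb + chi_b*U
#   dMg/dt = lam_g*Sf*Mg - (gam_g + del_g + theta)*Mg + chi_g*U
#   dU/dt  = gam_b*Mb + gam_g*Mg - (chi_b + chi_g + theta)*U
# and the stochastic version perturbs each compartment multiplicatively with
# intensity sigma_k.

#' Deterministic drift field
#'
#' Right-hand side of the malnutrition ODE system, evaluated exactly as
#' written (no clipping; negative inputs are allowed so that root-finders and
#' integrators can probe the field).
#'
#' @param state numeric length-4 state `(Sf, Mb, Mg, U)`.
#' @param params a [malnut_params()] object.
#' @return Numeric length-4 rate vector (persons/day).
#' @export
#' @examples
#' p <- baseline_scenario()$params
#' drift(c(30, 2, 4, 1), p)
drift <- function(state, params) {
  stopifnot(inherits(params, "malnut_params"))
  x <- .as_state(state)
  Sf <- x[1]; Mb <- x[2]; Mg <- x[3]; U <- x[4]
  with(params, c(
    (B + eps) - (lam_b * Mb + lam_g * Mg + theta) * Sf + del_g * Mg,
    lam_b * Sf * Mb - (theta_b + gam_b + theta) * Mb + chi_b * U,
    lam_g * Sf * Mg - (gam_g + del_g + theta) * Mg + chi_g * U,
    gam_b * Mb + gam_g * Mg - (chi_b + chi_g + theta) * U))
}

#' Multiplicative diffusion amplitudes
#'
#' The multipliers of the four independent Brownian motions in the stochastic
#' model: \eqn{(\sigma_1 S_f, \sigma_2 M_b, \sigma_3 M_g, \sigma_4 U)}.
#'
#' @param state numeric length-4 state.
#' @param noise numeric length-4 noise intensities.
#' @return Numeric length-4 amplitude vector.
#' @export
diffusion <- function(state, noise) {
  .as_sigma(noise) * .as_state(state)
}

#' Drift of the total population
#'
#' The generator applied to \eqn{N = S_f + M_b + M_g + U} gives
#' \eqn{(B+\epsilon) - \theta N - \theta_b M_b}; this equals the sum of the
#' four components of [drift()] identically.
#'
#' @inheritParams drift
#' @return A single rate (persons/day).
#' @export
total_population_drift <- function(state, params) {
  stopifnot(inherits(params, "malnut_params"))
  x <- .as_state(state)
  with(params, (B + eps) - theta * sum(x) - theta_b * x[2])
}

#' Disease-free equilibrium
#'
#' The state with only susceptible females present,
#' \eqn{E_0 = ((B+\epsilon)/\theta, 0, 0, 0)}; [drift()] vanishes there.
#'
#' @param params a [malnut_params()] object.
#' @return Named numeric length-4 state.
#' @export
disease_free_equilibrium <- function(params) {
  stopifnot(inherits(params, "malnut_params"))
  if (params$theta == 0) stop("equilibrium undefined: theta = 0")
  c(Sf = (params$B + params$eps) / params$theta, Mb = 0, Mg = 0, U = 0)
}

#' Endemic (positive) equilibrium by damped Newton iteration
#'
#' Searches for a strictly positive root of the drift field.  The start point
#' is the long-run state of a coarse classical integration from `y0`; a damped
#' Newton iteration with a numerical Jacobian then refines it to residual
#' `tol`.  A root is reported only if all of its components exceed
#' `positive_tol`; otherwise (or on non-convergence) `NULL` is returned,
#' never a spurious state.
#'
#' @param params a [malnut_params()] object.
#' @param y0 start state for the preliminary integration (default `(1,1,1,1)`).
#' @param t_relax horizon of the preliminary coarse integration (days).
#' @param tol residual tolerance on \eqn{\|drift\|_\infty}.
#' @param positive_tol positivity threshold for accepting a root.
#' @param max_iter Newton iteration cap.
#' @return Named numeric length-4 state with `attr(, "residual")`, or `NULL`.
#' @export
endemic_equilibrium <- function(params, y0 = c(1, 1, 1, 1), t_relax = 2000,
                                tol = 1e-12, positive_tol = 1e-8,
                                max_iter = 200L) {
  stopifnot(inherits(params, "malnut_params"))
  field <- malnut_field(params)
  seg <- ab3_integrate(field, .as_state(y0), 0, t_relax, 0.05)
  x <- seg$states[nrow(seg$states), ]
  f <- drift(x, params)
  jac <- function(x) {
    h <- pmax(abs(x), 1) * 1e-7
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      e <- numeric(4); e[j] <- h[j]
      J[, j] <- (drift(x + e, params) - drift(x - e, params)) / (2 * h[j])
    }
    J
  }
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    step <- tryCatch(solve(jac(x), -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- drift(xn, params)
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(f))) break
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) >= 1e-10) return(NULL)
  if (any(x <= positive_tol)) return(NULL)
  structure(stats::setNames(x, c("Sf", "Mb", "Mg", "U")),
            residual = max(abs(f)))
}

#' Basic reproduction number (closed form)
#'
#' Evaluates the printed closed form
#' \deqn{R_0 = \frac{\lambda_g (B+\epsilon)\,[(\theta+\theta_b)(\theta+\chi_b+\chi_g)
#'   + \gamma_b(\theta+\chi_g)]}{\theta(\theta+\theta_b)\,[\theta(\theta+\gamma_g+
#'   \delta_g+\chi_b+\chi_g) + \chi_b(\gamma_g+\delta_g) + \chi_g\delta_g]}.}
#' This closed form is the canonical threshold; the next-generation-matrix
#' route is exposed separately as [ngm_spectral_radius()] and the two are not
#' asserted equal (the two printed objects are mutually inconsistent, so both
#' are reproduced faithfully).
#'
#' @param params a [malnut_params()] object.
#' @return The scalar \eqn{R_0}.
#' @export
basic_reproduction_number <- function(params) {
  stopifnot(inherits(params, "malnut_params"))
  with(params, {
    num <- lam_g * (B + eps) *
      ((theta + theta_b) * (theta + chi_b + chi_g) + gam_b * (theta + chi_g))
    den <- theta * (theta + theta_b) *
      (theta * (theta + gam_g + del_g + chi_b + chi_g) +
         chi_b * (gam_g + del_g) + chi_g * del_g)
    if (den == 0) stop("R0 undefined: zero denominator")
    num / den
  })
}

#' Spectral radius of the next-generation matrix
#'
#' Builds the 4x4 new-infection matrix \eqn{F} and transition matrix \eqn{V}
#' exactly as printed (rows in compartment order Mb, Mg, U, Sf at the
#' disease-free state) and returns \eqn{\rho(F V^{-1})}.
#'
#' @param params a [malnut_params()] object.
#' @return The spectral radius (a non-negative scalar).
#' @export
ngm_spectral_radius <- function(params) {
  stopifnot(inherits(params, "malnut_params"))
  with(params, {
    k <- (B + eps) / theta
    F_ <- matrix(0, 4, 4)
    F_[1, 1] <- lam_b * k
    F_[2, 2] <- lam_g * k
    V_ <- rbind(
      c(gam_b + theta_b + theta, 0,                      -chi_b,                0),
      c(0,                       gam_g + theta + del_g,  -chi_g,                0),
      c(-gam_b,                  -gam_g,                 chi_b + chi_g + theta, 0),
      c(lam_b * k,               lam_g * k - del_g,      0,                     theta))
    Vi <- tryCatch(solve(V_), error = function(e)
      stop("next-generation matrix V is singular"))
    max(Mod(eigen(F_ %*% Vi, only.values = TRUE)$values))
  })
}

.r0s_factors <- function(params, noise) {
  s <- .as_sigma(noise)
  with(params, c(lam_b + theta - s[1]^2 / 2,
                 theta_b + gam_b - s[2]^2 / 2,
                 gam_g + del_g + theta - s[3]^2 / 2))
}

#' Stochastic persistence threshold
#'
#' The noise-adjusted threshold
#' \deqn{R_0^s = \frac{\lambda_g \lambda_b}{(\lambda_b+\theta-\sigma_1^2/2)
#'  (\theta_b+\gamma_b-\sigma_2^2/2)(\gamma_g+\delta_g+\theta-\sigma_3^2/2)}.}
#' \eqn{R_0^s > 1} is the sufficient condition for the stochastic system to
#' admit a unique ergodic stationary distribution (persistence).
#'
#' @param params a [malnut_params()] object.
#' @param noise numeric length-4 noise intensities.
#' @return The scalar \eqn{R_0^s}.
#' @export
stochastic_threshold <- function(params, noise) {
  stopifnot(inherits(params, "malnut_params"))
  fac <- .r0s_factors(params, noise)
  if (any(fac <= 0))
    stop("out-of-regime noise: a denominator factor of R0^s is <= 0")
  params$lam_g * params$lam_b / prod(fac)
}

#' Lyapunov constants of the persistence analysis
#'
#' The constants \eqn{\psi_1, \psi_2, \psi_3} are \eqn{(B+\epsilon)} divided
#' by the respective denominator factors of [stochastic_threshold()], and
#' \eqn{\psi_5 = 4(B+\epsilon)[(R_0^s)^{1/4} - 1]}, which is positive exactly
#' when \eqn{R_0^s > 1}.  Diagnostic quantities only.
#'
#' @inheritParams stochastic_threshold
#' @return Named numeric vector `c(psi1, psi2, psi3, psi5)`.
#' @export
lyapunov_constants <- function(params, noise) {
  stopifnot(inherits(params, "malnut_params"))
  fac <- .r0s_factors(params, noise)
  if (any(fac <= 0))
    stop("out-of-regime noise: a denominator factor of R0^s is <= 0")
  be <- params$B + params$eps
  r0s <- params$lam_g * params$lam_b / prod(fac)
  c(psi1 = be / fac[1], psi2 = be / fac[2], psi3 = be / fac[3],
    psi5 = 4 * be * (r0s^(1 / 4) - 1))
}

#' Closure returning the model's deterministic field
#'
#' @param params a [malnut_params()] object.
#' @return A function `f(t, y)` returning the drift at state `y` (autonomous;
#'   `t` is ignored), suitable for the integrators.
#' @export
malnut_field <- function(params) {
  stopifnot(inherits(params, "malnut_params"))
  function(t, y) drift(y, params)
}

#' Threshold report for a scenario
#'
#' Computes the deterministic threshold \eqn{R_0} (closed form), the
#' next-generation-matrix spectral radius, the stochastic threshold
#' \eqn{R_0^s}, the Lyapunov constants and the persistence classification
#' (`"persists"` iff \eqn{R_0^s > 1}; the theory provides a sufficient
#' condition only, so the alternative is `"inconclusive"`, not extinction).
#'
#' @param scenario a [malnut_scenario()] object.
#' @return An object of class `threshold_report` (a named list).
#' @export
#' @examples
#' threshold_report(baseline_scenario())
threshold_report <- function(scenario) {
  stopifnot(inherits(scenario, "malnut_scenario"))
  psi <- lyapunov_constants(scenario$params, scenario$noise)
  r0s <- stochastic_threshold(scenario$params, scenario$noise)
  structure(list(
    label = scenario$label,
    R0 = basic_reproduction_number(scenario$params),
    ngm_spectral_radius = ngm_spectral_radius(scenario$params),
    R0_s = r0s,
    psi1 = unname(psi["psi1"]), psi2 = unname(psi["psi2"]),
    psi3 = unname(psi["psi3"]), psi5 = unname(psi["psi5"]),
    classification = if (r0s > 1) "persists" else "inconclusive"),
    class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Threshold report:", x$label, "\n")
  cat(sprintf("  R0 (closed form)      = %.10g\n", x$R0))
  cat(sprintf("  NGM spectral radius   = %.10g\n", x$ngm_spectral_radius))
  cat(sprintf("  R0^s                  = %.10g\n", x$R0_s))
  cat(sprintf("  psi1, psi2, psi3      = %.6g, %.6g, %.6g\n",
              x$psi1, x$psi2, x$psi3))
  cat(sprintf("  psi5                  = %.6g\n", x$psi5))
  cat("  classification        =", x$classification, "\n")
  invisible(x)
}

#' Write a threshold report as JSON
#'
#' @param report a [threshold_report()] object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(report, path) {
  stopifnot(inherits(report, "threshold_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
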