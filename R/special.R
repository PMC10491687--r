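# Kernel machinery: the one-parameter Mittag-Leffler function, the
# normalization constants of the exponential-decay and Mittag-Leffler
# fractional operators, and the Newton-polynomial multistep weights.

.check_order <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) ||
      lam <= 0 || lam > 1)
    stop("fractional order must be a single value in (0, 1]")
  lam
}

#' One-parameter Mittag-Leffler function
#'
#' Evaluates \eqn{E_\Lambda(z) = \sum_{k\ge 0} z^k / \Gamma(\Lambda k + 1)}
#' for \eqn{\Lambda \in (0, 1]} and real \eqn{z}.
#'
#' Three evaluation routes are combined so that the result is accurate to
#' better than 1e-10 everywhere it is defined:
#' \itemize{
#' \item \eqn{\Lambda = 1}: `exp(z)` exactly.
#' \item \eqn{z \ge -1} (and up to \eqn{z = 15}): direct series summation with
#'   term-ratio stopping at 1e-16; cancellation is mild on this range.
#' \item \eqn{z < -1}: the series suffers catastrophic cancellation in double
#'   precision (at \eqn{z=-10}, \eqn{\Lambda=0.3} intermediate terms exceed
#'   \eqn{10^{40}}), so the complete-monotonicity (spectral) representation
#'   \deqn{E_\Lambda(-x) = \frac{\sin(\Lambda\pi)}{\Lambda\pi}\int_0^\infty
#'     \frac{e^{-x^{1/\Lambda} u^{1/\Lambda}}}{u^2 + 2u\cos(\Lambda\pi) + 1}\,du}
#'   is integrated adaptively instead (split at the possible near-pole
#'   \eqn{u = 1}).
#' }
#' Arguments \eqn{z > 15} signal an error rather than silently losing
#' accuracy; the model never needs larger arguments at desk scale.
#'
#' @param z real argument(s); vectorized.
#' @param order fractional order \eqn{\Lambda \in (0, 1]}.
#' @return \eqn{E_\Lambda(z)}, same length as `z`.
#' @export
#' @examples
#' mittag_leffler(-1, 1)        # exp(-1)
#' mittag_leffler(-2, 0.7)
mittag_leffler <- function(z, order) {
  lam <- .check_order(order)
  if (!is.numeric(z) || !all(is.finite(z))) stop("'z' must be finite numeric")
  vapply(z, function(zz) .ml_scalar(zz, lam), numeric(1))
}

.ml_scalar <- function(z, lam) {
  if (lam == 1) return(exp(z))
  if (z > 15)
    stop("mittag_leffler: series route not reliable for z > 15 ",
         "(achieved accuracy would be worse than requested)")
  if (z >= -1) .ml_series(z, lam) else .ml_spectral(-z, lam)
}

.ml_series <- function(z, lam) {
  if (z == 0) return(1)
  s <- 1
  for (k in 1:2000) {
    term <- (if (z < 0 && k %% 2 == 1) -1 else 1) *
      exp(k * log(abs(z)) - lgamma(lam * k + 1))
    s <- s + term
    if (abs(term) <= 1e-16 * max(1, abs(s)) && k > 3) return(s)
  }
  stop("mittag_leffler: series did not converge to 1e-16 term ratio ",
       "(last term ", signif(term, 3), ")")
}

# E_lam(-x) for x > 0, 0 < lam < 1, via the Gorenflo-Mainardi spectral
# density: exact, positive, completely monotone integrand.
.ml_spectral <- function(x, lam) {
  t <- x^(1 / lam)
  cl <- cos(lam * pi)
  f <- function(u) exp(-t * u^(1 / lam)) / (u^2 + 2 * u * cl + 1)
  q <- function(lo, hi) stats::integrate(f, lo, hi, rel.tol = 1e-13,
                                         abs.tol = 1e-16,
                                         subdivisions = 1000L)$value
  sin(lam * pi) / (lam * pi) * (q(0, 1) + q(1, 2) + q(2, Inf))
}

#' Normalization constant of the exponential-decay kernel operator
#'
#' Returns \eqn{\bar M(\Lambda) = 2/(2-\Lambda)} exactly as printed.  Note
#' that this formula gives \eqn{\bar M(1) = 2}, not 1; the printed formula is
#' used everywhere, including inside the exponential-decay integrator.
#'
#' @param order fractional order \eqn{\Lambda < 2}.
#' @return The scalar \eqn{\bar M(\Lambda)}.
#' @export
cf_normalization <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order))
    stop("order must be a single finite numeric value")
  if (order == 2) stop("cf_normalization undefined at order 2")
  2 / (2 - order)
}

#' Normalization constant of the Mittag-Leffler kernel operator
#'
#' Returns \eqn{ABC(\Lambda) = 1 - \Lambda + \Lambda/\Gamma(\Lambda)}, which
#' satisfies \eqn{ABC(0^+) = ABC(1) = 1}.
#'
#' @param order fractional order \eqn{\Lambda \in (0, 1]}.
#' @return The scalar \eqn{ABC(\Lambda)}.
#' @export
abc_normalization <- function(order) {
  lam <- .check_order(order)
  1 - lam + lam / gamma(lam)
}

# Newton-polynomial weights by lag d = w - s >= 0 (vectorized over d).
# I3 default uses the "-" join between its two terms: the "+" printed form
# grows like d^(lam+2) and makes the history sum divergent; at lam = 1 the
# "-" form equals 23 and reproduces the 23/12 Adams-Bashforth weight.
.newton_weights <- function(d, lam, as_printed = FALSE) {
  I1 <- if (as_printed) (d - 1)^lam - d^lam else (d + 1)^lam - d^lam
  I2 <- (d + 1)^lam * (d + 2 * lam + 3) - d^lam * (d + 3 * lam + 3)
  t1 <- (d + 1)^lam * (2 * d^2 + (3 * lam + 10) * d + 2 * lam^2 + 9 * lam + 12)
  t2 <- d^lam * (2 * d^2 + (5 * lam + 10) * d + 6 * lam^2 + 18 * lam + 12)
  I3 <- if (as_printed) t1 + t2 else t1 - t2
  list(I1 = I1, I2 = I2, I3 = I3)
}

#' Fractional multistep weights
#'
#' The three Newton-polynomial quadrature weights of the fractional
#' Adams-Bashforth scheme, at step index `w` and summation index `s`
#' (\eqn{2 \le s \le w}):
#' \deqn{\Im_1 = (w-s+1)^\Lambda - (w-s)^\Lambda}
#' \deqn{\Im_2 = (w-s+1)^\Lambda(w-s+2\Lambda+3) - (w-s)^\Lambda(w-s+3\Lambda+3)}
#' and \eqn{\Im_3} with the matching sign pattern (see Details).
#'
#' @details With `as_printed = TRUE` the literal published forms are used
#' instead: \eqn{\Im_1 = (w-s-1)^\Lambda - (w-s)^\Lambda}, which raises a
#' negative base to a fractional power when \eqn{s = w} (a complex number; an
#' error is signalled rather than returning one), and \eqn{\Im_3} with its
#' two bracketed terms joined by `+`, which grows like \eqn{(w-s)^{\Lambda+2}}
#' and makes the history sum diverge.  The default sign pattern is the only
#' real-valued, convergent reading on the stated index range, and at
#' \eqn{\Lambda = 1} it collapses to the classical three-step
#' Adams-Bashforth weights.
#'
#' @param w step index (scalar integer).
#' @param s summation index (vectorized), `2 <= s <= w`.
#' @param order fractional order \eqn{\Lambda \in (0, 1]}.
#' @param as_printed use the literal published forms (see Details).
#' @return A list with numeric components `I1`, `I2`, `I3` (same length
#'   as `s`).
#' @export
caputo_weights <- function(w, s, order, as_printed = FALSE) {
  lam <- .check_order(order)
  if (any(s > w)) stop("summation index s must not exceed step index w")
  if (any(s < 2)) stop("summation index s must be >= 2")
  ww <- .newton_weights(w - s, lam, as_printed = as_printed)
  if (as_printed && any(w - s - 1 < 0) && lam != 1 &&
      any(!is.finite(ww$I1)))
    stop("as-printed weight I1 is complex at s = w ",
         "(negative base to fractional power)")
  ww
}
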