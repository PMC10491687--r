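# Domain types: model parameters, noise intensities, state vectors,
# and the flat key=value scenario configuration format.

.RATE_KEYS <- c("B", "eps", "lam_b", "lam_g", "theta", "theta_b",
                "gam_b", "gam_g", "chi_b", "chi_g", "del_g")
.PLACEHOLDER_KEYS <- c("theta1", "theta2")
.SIGMA_KEYS <- c("sigma1", "sigma2", "sigma3", "sigma4")
.STATE_KEYS <- c("Sf", "Mb", "Mg", "U")

#' Model parameters for the malnutrition compartmental model
#'
#' Bundles the rate constants of the four-compartment malnutrition model:
#' susceptible females \eqn{S_f}, malnourished boys \eqn{M_b}, malnourished
#' girls \eqn{M_g} and underweight individuals \eqn{U}.  All rates are per
#' day; states are continuous person-counts.
#'
#' @param B recruitment rate of new females (day\eqn{^{-1}}).
#' @param eps vertical-spread rate to the newborn community (day\eqn{^{-1}}).
#' @param lam_b,lam_g transfer rates from the susceptible female cohort into
#'   the malnourished boy/girl compartments (day\eqn{^{-1}} person\eqn{^{-1}}).
#' @param theta baseline death rate (day\eqn{^{-1}}); must be positive so that
#'   the disease-free total \eqn{(B+\epsilon)/\theta} is defined.
#' @param theta_b natural restoration rate of malnourished boys
#'   (day\eqn{^{-1}}).
#' @param gam_b,gam_g progression rates from malnourished to underweight for
#'   boys and girls (day\eqn{^{-1}}).
#' @param chi_b,chi_g return rates from underweight to the malnourished
#'   boy/girl compartments (day\eqn{^{-1}}).
#' @param del_g recovery rate of malnourished girls (day\eqn{^{-1}}).
#' @param theta1,theta2 treatment-rate placeholders in \eqn{[0,1]}.  They are
#'   recorded on the object but enter no equation of the model; they are kept
#'   so that a parameter table can be round-tripped verbatim.
#'
#' @return An object of class `malnut_params`: a named list of validated
#'   numeric rates.
#' @seealso [baseline_scenario()] for the study configuration,
#'   [read_scenario_config()] for file input.
#' @export
#' @examples
#' p <- malnut_params(B = 0.01, eps = 0.001, lam_b = 0.1, lam_g = 0.2,
#'                    theta = 0.1, theta_b = 0.3, gam_b = 0.01, gam_g = 0.1,
#'                    chi_b = 0.014, chi_g = 0.01, del_g = 0.1)
#' basic_reproduction_number(p)
malnut_params <- function(B, eps, lam_b, lam_g, theta, theta_b,
                          gam_b, gam_g, chi_b, chi_g, del_g,
                          theta1 = 0, theta2 = 0) {
  p <- list(B = B, eps = eps, lam_b = lam_b, lam_g = lam_g, theta = theta,
            theta_b = theta_b, gam_b = gam_b, gam_g = gam_g, chi_b = chi_b,
            chi_g = chi_g, del_g = del_g, theta1 = theta1, theta2 = theta2)
  for (k in names(p)) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", k, "' must be a single finite numeric value")
    if (v < 0) stop("parameter '", k, "' must be non-negative")
  }
  if (theta <= 0) stop("'theta' must be strictly positive")
  if (theta1 > 1 || theta2 > 1)
    stop("'theta1' and 'theta2' must lie in [0, 1]")
  structure(p, class = "malnut_params")
}

#' @export
print.malnut_params <- function(x, ...) {
  cat("Malnutrition model parameters (day^-1):\n")
  print(unlist(x[.RATE_KEYS]))
  cat("placeholders (recorded, unused): theta1 =", x$theta1,
      ", theta2 =", x$theta2, "\n")
  invisible(x)
}

#' White-noise intensities
#'
#' The multipliers \eqn{\sigma_k} of the multiplicative Brownian perturbations
#' \eqn{\sigma_k X_k \,dW_k} acting on the four compartments.
#'
#' @param sigma1,sigma2,sigma3,sigma4 non-negative noise intensities for the
#'   susceptible-female, malnourished-boy, malnourished-girl and underweight
#'   compartments.
#' @return A named numeric vector of class `noise_intensities`.
#' @export
noise_intensities <- function(sigma1, sigma2, sigma3, sigma4) {
  s <- c(sigma1 = sigma1, sigma2 = sigma2, sigma3 = sigma3, sigma4 = sigma4)
  if (!all(is.finite(s)) || any(s < 0))
    stop("noise intensities must be finite and non-negative")
  structure(s, class = "noise_intensities")
}

#' State vector of the four compartments
#'
#' @param Sf,Mb,Mg,U non-negative person-counts of susceptible females,
#'   malnourished boys, malnourished girls and underweight individuals.
#' @return A named numeric vector `c(Sf, Mb, Mg, U)`.
#' @export
state_vector <- function(Sf, Mb, Mg, U) {
  x <- c(Sf = Sf, Mb = Mb, Mg = Mg, U = U)
  if (!all(is.finite(x))) stop("state components must be finite")
  if (any(x < 0)) stop("state components must be non-negative")
  x
}

.as_state <- function(state) {
  if (!is.numeric(state) || length(state) != 4L)
    stop("'state' must be a numeric vector of length 4 (Sf, Mb, Mg, U)")
  if (!all(is.finite(state))) stop("invalid state: non-finite component")
  unname(state)
}

.as_sigma <- function(noise) {
  if (!is.numeric(noise) || length(noise) != 4L)
    stop("'noise' must be a numeric vector of length 4 (sigma1..sigma4)")
  if (!all(is.finite(noise)) || any(noise < 0))
    stop("invalid noise intensities")
  unname(noise)
}

#' Bundle parameters, noise and initial state into a scenario
#'
#' @param params a [malnut_params()] object.
#' @param noise a [noise_intensities()] vector.
#' @param y0 a [state_vector()] initial state.
#' @param label optional character tag.
#' @return An object of class `malnut_scenario`.
#' @export
malnut_scenario <- function(params, noise, y0, label = "scenario") {
  stopifnot(inherits(params, "malnut_params"))
  noise <- .as_sigma(noise)
  y0 <- .as_state(y0)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  structure(list(params = params,
                 noise = noise_intensities(noise[1], noise[2], noise[3], noise[4]),
                 y0 = state_vector(y0[1], y0[2], y0[3], y0[4]),
                 label = label),
            class = "malnut_scenario")
}

#' @export
print.malnut_scenario <- function(x, ...) {
  cat("Malnutrition scenario:", x$label, "\n")
  cat("  y0    =", paste(names(x$y0), unname(x$y0), sep = "=", collapse = ", "), "\n")
  cat("  sigma =", paste(unname(x$noise), collapse = ", "), "\n")
  cat("  rates :", paste(.RATE_KEYS, unlist(x$params[.RATE_KEYS]),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a scenario from a flat key=value configuration file
#'
#' The format is one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored.  Recognised keys are the model rates
#' (`B`, `eps`, `lam_b`, `lam_g`, `theta`, `theta_b`, `gam_b`, `gam_g`,
#' `chi_b`, `chi_g`, `del_g`, `theta1`, `theta2`), the noise intensities
#' (`sigma1`..`sigma4`) and the initial state (`Sf0`, `Mb0`, `Mg0`, `U0`).
#'
#' @param path file to read.
#' @return A [malnut_scenario()] object.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric value for key '", keys[is.na(vals)][1], "'")
  cfg <- stats::setNames(vals, keys)
  need <- c(.RATE_KEYS, .SIGMA_KEYS, paste0(.STATE_KEYS, "0"))
  miss <- setdiff(need, keys)
  if (length(miss)) stop("missing config keys: ", paste(miss, collapse = ", "))
  params <- do.call(malnut_params, as.list(cfg[c(.RATE_KEYS,
                                                 intersect(.PLACEHOLDER_KEYS, keys))]))
  malnut_scenario(params,
                  noise_intensities(cfg[["sigma1"]], cfg[["sigma2"]],
                                    cfg[["sigma3"]], cfg[["sigma4"]]),
                  state_vector(cfg[["Sf0"]], cfg[["Mb0"]], cfg[["Mg0"]], cfg[["U0"]]),
                  label = basename(path))
}

#' Write a scenario to the flat key=value configuration format
#'
#' @param scenario a [malnut_scenario()] object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "malnut_scenario"))
  p <- scenario$params
  lines <- c(
    paste0("# malnutrition model scenario: ", scenario$label),
    sprintf("%s = %.17g", c(.RATE_KEYS, .PLACEHOLDER_KEYS),
            unlist(p[c(.RATE_KEYS, .PLACEHOLDER_KEYS)])),
    sprintf("%s = %.17g", .SIGMA_KEYS, unname(scenario$noise)),
    sprintf("%s0 = %.17g", .STATE_KEYS, unname(scenario$y0)))
  writeLines(lines, path)
  invisible(path)
}
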