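# Synthetic-data stage: seeded Brownian drivers and parameter scenario
# generation around the study's printed design point.

# Evaluate expr under a given seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Seeded independent Brownian increment paths
#'
#' Generates `dims` mutually independent sequences of `n_steps` increments
#' drawn from Normal(0, `dz`); their cumulative sums form discrete Brownian
#' paths on a grid of spacing `dz`.  Fully reproducible from `seed`.
#'
#' @param n_steps number of increments per dimension (>= 1).
#' @param dz increment spacing (days), positive; the increment variance.
#' @param dims number of independent dimensions (default 4, one per
#'   compartment).
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return An object of class `brownian_paths`: list with `increments`
#'   (`n_steps` x `dims` matrix), `dz`, `dims`, `seed`.
#' @export
#' @examples
#' p <- brownian_increments(1000, 0.01, seed = 42)
#' colMeans(p$increments)
brownian_increments <- function(n_steps, dz, dims = 4L, seed = NULL) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != round(n_steps))
    stop("'n_steps' must be a positive integer")
  if (!is.numeric(dz) || length(dz) != 1L || dz <= 0)
    stop("'dz' must be positive")
  if (!is.numeric(dims) || dims < 1 || dims != round(dims))
    stop("'dims' must be a positive integer")
  inc <- .with_seed(seed,
    matrix(stats::rnorm(n_steps * dims, mean = 0, sd = sqrt(dz)),
           nrow = n_steps, ncol = dims))
  structure(list(increments = inc, dz = dz, dims = as.integer(dims),
                 seed = seed),
            class = "brownian_paths")
}

#' Coarsen Brownian paths to a multiple of their spacing
#'
#' Sums blocks of `factor` consecutive increments, producing the same
#' Brownian motion sampled on a grid `factor` times coarser.  Used for
#' strong-convergence studies that must share one underlying path across a
#' ladder of step sizes.
#'
#' @param paths a [brownian_increments()] object.
#' @param factor positive integer; `n_steps` must be divisible by it.
#' @return A new `brownian_paths` object with spacing `dz * factor`.
#' @export
coarsen_paths <- function(paths, factor) {
  stopifnot(inherits(paths, "brownian_paths"))
  n <- nrow(paths$increments)
  if (factor < 1 || factor != round(factor) || n %% factor != 0)
    stop("'factor' must divide the number of increments")
  if (factor == 1) return(paths)
  grp <- rep(seq_len(n / factor), each = factor)
  inc <- apply(paths$increments, 2, function(col) tapply(col, grp, sum))
  structure(list(increments = matrix(inc, ncol = paths$dims),
                 dz = paths$dz * factor, dims = paths$dims,
                 seed = paths$seed),
            class = "brownian_paths")
}

#' The study's baseline configuration
#'
#' The exact printed design point: rates B = 0.01, eps = 0.001, lam_b = 0.1,
#' lam_g = 0.2, theta = 0.1, theta_b = 0.3, gam_b = 0.01, gam_g = 0.1,
#' chi_b = 0.014, chi_g = 0.01, del_g = 0.1 (all per day); initial state
#' (Sf, Mb, Mg, U) = (30, 2, 4, 1); noise intensities
#' sigma = (0.08, 0.09, 0.1, 0.12).  The treatment-rate placeholders theta1,
#' theta2 enter no equation and are stored as 0.
#'
#' @return A [malnut_scenario()] object labelled `"baseline"`.
#' @export
baseline_scenario <- function() {
  malnut_scenario(
    malnut_params(B = 0.01, eps = 0.001, lam_b = 0.1, lam_g = 0.2,
                  theta = 0.1, theta_b = 0.3, gam_b = 0.01, gam_g = 0.1,
                  chi_b = 0.014, chi_g = 0.01, del_g = 0.1,
                  theta1 = 0, theta2 = 0),
    noise_intensities(0.08, 0.09, 0.1, 0.12),
    state_vector(30, 2, 4, 1),
    label = "baseline")
}

#' Perturbed scenarios around the baseline design point
#'
#' Each of the eleven model rates is multiplied by an independent log-normal
#' factor with median 1 and relative standard deviation `relative_sd`
#' (sdlog = sqrt(log(1 + relative_sd^2))), so positivity is preserved by
#' construction and the per-parameter sample median converges to the baseline
#' value.  The placeholders theta1, theta2, the noise intensities and the
#' initial state are left untouched.
#'
#' @param n number of scenarios (>= 1).
#' @param relative_sd relative standard deviation of the factors, in
#'   `[0, 1)`; 0 returns `n` copies of the baseline.
#' @param seed integer seed.
#' @return A list of `n` [malnut_scenario()] objects.
#' @export
perturbed_scenarios <- function(n, relative_sd, seed = NULL) {
  if (!is.numeric(n) || n < 1 || n != round(n)) stop("'n' must be >= 1")
  if (!is.numeric(relative_sd) || relative_sd < 0 || relative_sd >= 1)
    stop("'relative_sd' must lie in [0, 1)")
  base <- baseline_scenario()
  sdlog <- sqrt(log(1 + relative_sd^2))
  # row-major fill: scenario i consumes draws (i-1)*11+1 .. i*11, so the
  # first scenarios are identical whatever n is requested
  fac <- .with_seed(seed,
    matrix(stats::rlnorm(n * length(.RATE_KEYS), meanlog = 0, sdlog = sdlog),
           nrow = n, byrow = TRUE))
  lapply(seq_len(n), function(i) {
    p <- unlist(base$params[.RATE_KEYS]) * fac[i, ]
    params <- do.call(malnut_params,
                      c(as.list(p), list(theta1 = base$params$theta1,
                                         theta2 = base$params$theta2)))
    malnut_scenario(params, base$noise, base$y0,
                    label = sprintf("perturbed-%03d", i))
  })
}
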