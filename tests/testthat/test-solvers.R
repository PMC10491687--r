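decay <- function(t, y) -y
zero_field <- function(t, y) 0 * y

test_that("classical AB3 is exact on constants and third order on linear decay", {
  # zero field: constant trajectory
  seg <- ab3_integrate(zero_field, c(2, 3), 0, 1, 0.1)
  expect_true(all(seg$states[, 1] == 2) && all(seg$states[, 2] == 3))
  # constant field: every step adds exactly c*dz (the weights sum to 1)
  cfield <- function(t, y) c(1.5, -0.25)
  seg <- ab3_integrate(cfield, c(0, 0), 0, 1, 0.125)
  expect_equal(seg$states[, 1], 1.5 * seg$times, tolerance = 1e-14)
  expect_equal(seg$states[, 2], -0.25 * seg$times, tolerance = 1e-14)
  # exponential decay accuracy and empirical order
  seg <- ab3_integrate(decay, 1, 0, 2, 0.01)
  expect_lt(max(abs(seg$states[, 1] - exp(-seg$times))), 1e-6)
  co <- convergence_order(ab3_integrate,
                          list(field = decay, y0 = 1, t_start = 0,
                               t_end = 2, exact = function(t) exp(-t)),
                          c(0.04, 0.02, 0.01))
  expect_true(co$monotone)
  expect_gt(co$order, 2.7); expect_lt(co$order, 3.3)
  expect_error(ab3_integrate(function(t, y) NaN * y, 1, 0, 1, 0.1),
               "non-finite")
})

test_that("classical regime agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  p <- baseline_scenario()$params
  ref <- deSolve::lsoda(y = c(30, 2, 4, 1), times = seq(0, 10, by = 0.1),
                        func = function(t, y, parms) list(drift(y, p)),
                        parms = NULL, rtol = 1e-11, atol = 1e-12)
  seg <- ab3_integrate(malnut_field(p), c(30, 2, 4, 1), 0, 10, 0.002)
  idx <- match(round(ref[, 1], 9), round(seg$times, 9))
  expect_lt(max(abs(seg$states[idx, ] - ref[, 2:5])), 1e-4)
})

test_that("power-law branch solves the fractional relaxation test to the Mittag-Leffler oracle", {
  errs <- vapply(c(4e-3, 2e-3, 1e-3), function(h) {
    seg <- caputo_integrate(decay, 1, 0.7, 0, 2, h)
    ex <- mittag_leffler(-seg$times^0.7, 0.7)
    max(abs(seg$states[, 1] - ex) / ex)
  }, numeric(1))
  expect_lt(errs[3], 0.02)          # within 2% at the finest step
  expect_true(all(diff(errs) < 0))  # error decreases under halving
  # zero field: constant at the regime's initial state
  seg <- caputo_integrate(zero_field, c(5, 7), 0.6, 1, 3, 0.1)
  expect_true(all(seg$states[, 1] == 5) && all(seg$states[, 2] == 7))
})

test_that("power-law branch at order 1 collapses to the classical scheme", {
  seg <- caputo_integrate(decay, 1, 1, 0, 2, 1e-3)
  expect_lt(max(abs(seg$states[, 1] - exp(-seg$times))), 1e-3)
  segc <- ab3_integrate(decay, 1, 0, 2, 1e-2)
  segf <- caputo_integrate(decay, 1, 1, 0, 2, 1e-2)
  expect_lt(max(abs(segc$states - segf$states)), 1e-9)
})

test_that("exponential-decay branch collapses as printed at order 1 and is self-convergent", {
  # order 1: pointwise term vanishes and the scheme is AB3 on the half-field
  half <- function(t, y) decay(t, y) / 2
  sc <- ab3_integrate(half, 1, 0, 2, 0.01)
  sf <- cf_integrate(decay, 1, 1, 0, 2, 0.01)
  expect_lt(max(abs(sc$states - sf$states)), 1e-12)
  # zero field: constant
  seg <- cf_integrate(zero_field, c(1, 2), 0.9, 0, 1, 0.05)
  expect_true(all(seg$states[, 1] == 1) && all(seg$states[, 2] == 2))
  # order 0.9: fine-grid self-convergence against a first-order reference
  # discretization of the integral form
  # y_{n+1} = y_n + (1-lam)/M (phi_n - phi_{n-1}) + lam/M * h * phi_n
  lam <- 0.9; M <- cf_normalization(lam)
  h <- 1e-4; n <- round(2 / h)
  y <- 1; phi_prev <- -1
  for (i in 1:n) {
    phi <- -y
    y <- y + (1 - lam) / M * (phi - phi_prev) + lam / M * h * phi
    phi_prev <- phi
  }
  seg <- cf_integrate(decay, 1, lam, 0, 2, 1e-3)
  expect_lt(abs(seg$states[nrow(seg$states), 1] - y), 5e-4)
})

test_that("Mittag-Leffler branch matches the power-law branch at order 1 and exposes the printed local term", {
  s_abc <- abc_integrate(decay, 1, 1, 0, 2, 0.01)
  s_cap <- caputo_integrate(decay, 1, 1, 0, 2, 0.01)
  expect_lt(max(abs(s_abc$states - s_cap$states)), 1e-10)
  # zero field: constant
  seg <- abc_integrate(zero_field, c(4, 2), 0.8, 0, 1, 0.05)
  expect_true(all(seg$states[, 1] == 4))
  # default and as-printed local terms differ by exactly (2*lam-1)/ABC * Phi
  lam <- 0.8; abc <- abc_normalization(lam)
  s_std <- abc_integrate(decay, 1, lam, 0, 0.5, 0.01)
  s_prt <- abc_integrate(decay, 1, lam, 0, 0.5, 0.01,
                         local_term = "as_printed")
  # compare at the first multistep point, where the shared history is still
  # identical: the difference is the local-coefficient difference times Phi
  n0 <- 4  # first point produced by the multistep formula (index m+2, m=2)
  phi_m <- -s_std$states[3, 1]  # newest field value entering both
  expect_equal(s_prt$states[n0, 1] - s_std$states[n0, 1],
               (2 * lam - 1) / abc * phi_m, tolerance = 1e-12)
})

test_that("stochastic multistep reduces bit-exactly to the classical scheme without noise", {
  p <- baseline_scenario()
  n <- 200; dz <- 0.01
  paths <- brownian_increments(n, dz, 4, seed = 5)
  f <- malnut_field(p$params)
  det <- ab3_integrate(f, unname(p$y0), 0, n * dz, dz)
  s0 <- stochastic_ab3_integrate(f, c(0, 0, 0, 0), unname(p$y0), 0, n * dz,
                                 dz, paths)
  expect_identical(det$states, s0$states)
  # all increments forced to zero behaves the same with sigma > 0
  paths0 <- paths; paths0$increments[] <- 0
  sz <- stochastic_ab3_integrate(f, unname(p$noise), unname(p$y0), 0,
                                 n * dz, dz, paths0)
  expect_identical(det$states, sz$states)
  # path/grid mismatch errors
  expect_error(stochastic_ab3_integrate(f, unname(p$noise), unname(p$y0),
                                        0, 10, dz, paths), "cover")
  bad <- brownian_increments(n, 0.02, 4, seed = 5)
  expect_error(stochastic_ab3_integrate(f, unname(p$noise), unname(p$y0),
                                        0, n * dz, dz, bad), "spacing")
})

test_that("stochastic multistep steps match hand arithmetic on a scalar model", {
  sig <- 0.3; h <- 0.1
  paths <- brownian_increments(5, h, dims = 1, seed = 99)
  dW <- paths$increments[, 1]
  seg <- stochastic_ab3_integrate(decay, sig, 1, 0, 0.5, h, paths)
  # hand evaluation: RK4 substep factor for y' = -y over h/10, 10 substeps
  r <- local({hs <- h / 10; (1 - hs + hs^2 / 2 - hs^3 / 6 + hs^4 / 24)^10})
  y0 <- 1
  y1 <- y0 * r + sig * y0 * dW[1]
  y2 <- y1 * r + sig * y1 * dW[2]
  y3 <- y2 + h * (23 / 12 * (-y2) - 4 / 3 * (-y1) + 5 / 12 * (-y0)) +
    23 / 12 * dW[3] * sig * y2 - 4 / 3 * dW[2] * sig * y1 +
    5 / 12 * dW[1] * sig * y0
  y4 <- y3 + h * (23 / 12 * (-y3) - 4 / 3 * (-y2) + 5 / 12 * (-y1)) +
    23 / 12 * dW[4] * sig * y3 - 4 / 3 * dW[3] * sig * y2 +
    5 / 12 * dW[2] * sig * y1
  expect_equal(seg$states[2:5, 1], c(y1, y2, y3, y4), tolerance = 1e-13)
})

test_that("Euler-Maruyama matches hand arithmetic and explicit Euler decay", {
  h <- 0.05
  paths <- brownian_increments(3, h, dims = 1, seed = 3)
  dW <- paths$increments[, 1]
  seg <- euler_maruyama_integrate(decay, function(t, y) 0.4 * y, 2, 0,
                                  3 * h, h, paths)
  y1 <- 2 + (-2) * h + 0.4 * 2 * dW[1]
  expect_equal(seg$states[2, 1], y1, tolerance = 1e-14)
  # sigma = 0: explicit Euler decay (1 - dz)^n
  paths <- brownian_increments(50, 0.02, dims = 1, seed = 4)
  seg <- euler_maruyama_integrate(decay, function(t, y) 0 * y, 1, 0, 1,
                                  0.02, paths)
  expect_equal(seg$states[, 1], (1 - 0.02)^(0:50), tolerance = 1e-13)
})

test_that("piecewise solve is continuous across regimes and degenerate schedules work", {
  sc <- baseline_scenario()
  sched <- piecewise_schedule(0.05, 10, 20, 30)
  tr <- piecewise_solve(sc$params, sc$noise, sc$y0, sched, order = 0.95,
                        kernel = "power_law", seed = 2)
  expect_true(all(is.finite(as.matrix(tr[, c("Sf", "Mb", "Mg", "U")]))))
  expect_equal(nrow(tr), 30 / 0.05 + 1)
  expect_equal(diff(tr$time), rep(0.05, 600), tolerance = 1e-9)
  expect_setequal(unique(tr$regime), c("classical", "fractional", "stochastic"))
  # boundary states shared exactly: regime labels switch exactly at T1, T2
  expect_identical(tr$regime[tr$time <= 10 + 1e-9][201], "classical")
  expect_identical(tr$regime[202], "fractional")
  # deterministic prefix nonnegative with Sf decaying from 30
  pre <- tr[tr$time <= 20, ]
  expect_true(all(as.matrix(pre[, c("Sf", "Mb", "Mg", "U")]) >= 0))
  expect_lt(pre$Sf[nrow(pre)], 30)
  # T1 = T2 = T: purely classical
  trc <- piecewise_solve(sc$params, sc$noise, sc$y0,
                         piecewise_schedule(0.05, 30, 30, 30), seed = 2)
  expect_true(all(trc$regime == "classical"))
  ref <- ab3_integrate(malnut_field(sc$params), unname(sc$y0), 0, 30, 0.05)
  expect_equal(trc$Sf, ref$states[, 1], tolerance = 1e-14)
  # T2 = T: no stochastic regime; output is seed independent
  tra <- piecewise_solve(sc$params, sc$noise, sc$y0,
                         piecewise_schedule(0.05, 10, 30, 30), order = 0.95,
                         seed = 1)
  trb <- piecewise_solve(sc$params, sc$noise, sc$y0,
                         piecewise_schedule(0.05, 10, 30, 30), order = 0.95,
                         seed = 999)
  expect_identical(tra$Sf, trb$Sf)
  # off-grid switch times are refused
  expect_error(piecewise_schedule(0.05, 10.013, 20, 30), "multiple")
})

test_that("piecewise solve is bit-reproducible from its seed", {
  sc <- baseline_scenario()
  sched <- piecewise_schedule(0.05, 5, 10, 20)
  a <- piecewise_solve(sc$params, sc$noise, sc$y0, sched, order = 0.95,
                       kernel = "mittag_leffler", seed = 31)
  b <- piecewise_solve(sc$params, sc$noise, sc$y0, sched, order = 0.95,
                       kernel = "mittag_leffler", seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # the disease-free state with zero noise is invariant under every scheme
  p <- sc$params
  e0 <- unname(disease_free_equilibrium(p))
  for (k in c("power_law", "exponential_decay", "mittag_leffler")) {
    tr <- piecewise_solve(p, c(0, 0, 0, 0), e0,
                          piecewise_schedule(0.1, 2, 4, 6), order = 0.9,
                          kernel = k, seed = 1)
    expect_equal(max(abs(as.matrix(tr[, c("Sf", "Mb", "Mg", "U")]) -
                           matrix(e0, nrow(tr), 4, byrow = TRUE))), 0,
                 tolerance = 1e-13)
  }
})

test_that("trajectory writer produces the documented CSV and JSON sidecar", {
  sc <- baseline_scenario()
  tr <- piecewise_solve(sc$params, sc$noise, sc$y0,
                        piecewise_schedule(0.1, 1, 2, 3), order = 0.95,
                        seed = 8)
  pref <- tempfile()
  write_trajectory(tr, pref)
  back <- utils::read.csv(paste0(pref, ".csv"))
  expect_identical(names(back), c("time", "regime", "Sf", "Mb", "Mg", "U"))
  expect_equal(back$Sf, tr$Sf, tolerance = 1e-15)
  meta <- jsonlite::read_json(paste0(pref, ".json"))
  expect_equal(meta$seed, 8)
  expect_identical(meta$kernel, "power_law")
  expect_equal(meta$schedule$T, 3)
})
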