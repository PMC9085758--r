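# Embedded Euler/midpoint pair, error metrics, adaptive controller.

decay_rhs <- function(k) {
  function(state) {
    d <- list(grid = list(A = -k * state$grid$A), comp = list())
    d
  }
}

decay_state <- function(a0 = 1) list(grid = list(A = matrix(a0, 1, 1)),
                                     comp = list())

test_that("midpoint step reproduces the hand-evaluated pair for dc/dt = -kc", {
  st <- decay_state(1)
  res <- midpoint_step(st, decay_rhs(1), dt = 0.1)
  expect_equal(as.numeric(res$d1$grid$A), -0.1)
  expect_equal(as.numeric(res$d2$grid$A), -0.095)
})

test_that("a constant derivative gives identical deltas and -Inf local error", {
  st <- decay_state(1)
  rhs <- function(state) list(grid = list(A = matrix(0.7, 1, 1)), comp = list())
  res <- midpoint_step(st, rhs, dt = 0.25)
  expect_equal(res$d1, res$d2)
  expect_identical(local_error(res$d1, res$d2), -Inf)
})

test_that("successive step halving shows convergence order 2", {
  k <- 1; t_end <- 1
  integrate_fixed <- function(dt) {
    st <- decay_state(1)
    for (i in seq_len(round(t_end / dt))) {
      st <- state_apply(st, midpoint_step(st, decay_rhs(k), dt)$d2)
    }
    st$grid$A[1]
  }
  exact <- exp(-k * t_end)
  dts <- 0.1 / 2^(0:3)
  errs <- abs(vapply(dts, integrate_fixed, numeric(1)) - exact)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 1.9 & orders < 2.1))
})

test_that("local error values match the printed threshold arithmetic", {
  # 5% relative deviation sits exactly at log10(0.05)
  expect_equal(local_error(1.05, 1), log10(0.05))
  expect_identical(local_error(1, 1), -Inf)
  expect_identical(local_error(0.1, 0), Inf)
  # module error is the max over entities and grid points
  d1 <- list(grid = list(A = matrix(c(1, 2), 1, 2), B = matrix(1, 1, 2)),
             comp = list())
  d2 <- list(grid = list(A = matrix(c(1.01, 2), 1, 2), B = matrix(c(1, 1.2), 1, 2)),
             comp = list())
  set.seed(1)
  # brute-force scan oracle over every entry
  worst <- 0
  for (e in c("A", "B")) for (j in 1:2) {
    num <- abs(d1$grid[[e]][1, j] - d2$grid[[e]][1, j])
    den <- abs(d2$grid[[e]][1, j])
    if (num > 0) worst <- max(worst, num / den)
  }
  expect_equal(10^local_error(d1, d2), worst)
})

test_that("controller decisions: retry above threshold, increase below bound", {
  ctl <- error_controller(tau_local = log10(0.05), theta_local = 0.5)
  # the step-increase bound is exactly 2.5% in linear space
  expect_equal(ctl$theta_local * 10^ctl$tau_local, 0.025)
  expect_equal(adapt_timestep(c(-3, log10(0.10)), ctl), "retry")
  expect_equal(adapt_timestep(c(-3, -2.7), ctl), "accept_and_increase")
  expect_equal(adapt_timestep(c(-3, log10(0.03)), ctl), "accept")
  expect_equal(adapt_timestep(c(-Inf, -Inf), ctl), "accept_and_increase")
})

test_that("no accepted step exceeds the 5% local error cap on a stiff pair", {
  sim <- cell_sim(list(A = 1, B = 0),
                  list(mod_reaction_grid("stiff", c(A = 1), c(B = 1),
                                         k = 1000, k_rev = 1000)),
                  controller = error_controller(dt_init = 1e-2))
  run_simulation(sim, 0.05)
  dg <- diagnostics(sim)
  expect_gt(nrow(dg), 10)
  expect_lte(max(10^dg$eps_local), 0.05 + 1e-12)
})

test_that("the accepted stiff trajectory matches a high-accuracy reference", {
  skip_if_not_installed("deSolve")
  k1 <- 1000; k2 <- 1000
  sim <- cell_sim(list(A = 1, B = 0),
                  list(mod_reaction_grid("f", c(A = 1), c(B = 1), k = k1),
                       mod_reaction_grid("b", c(B = 1), c(A = 1), k = k2)),
                  controller = error_controller(dt_init = 1e-5))
  ts <- c(2e-4, 1e-3, 5e-3, 2e-2)
  got <- numeric(0)
  t_prev <- 0
  for (tt in ts) {
    run_simulation(sim, tt - t_prev)
    got <- c(got, sim$state$grid$A[1])
    t_prev <- tt
  }
  ref <- deSolve::ode(c(A = 1, B = 0), c(0, ts),
                      function(t, y, p) list(c(-k1 * y[1] + k2 * y[2],
                                               k1 * y[1] - k2 * y[2])),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(got, unname(ref[-1, "A"]), tolerance = 0.05)
})

test_that("the controller is deterministic: identical runs give identical steps", {
  mk <- function() {
    sim <- cell_sim(list(A = 2, B = 0),
                    list(mod_reaction_grid("r", c(A = 1), c(B = 1),
                                           k = 5, k_rev = 1)))
    run_simulation(sim, 2)
    diagnostics(sim)
  }
  expect_identical(mk(), mk())
})

test_that("total-error skipping engages and re-arms after a step increase", {
  # a linear constant-source system: total error is negligible immediately
  sim <- cell_sim(list(A = 1),
                  list(mod_influx("A", 0.5)),
                  controller = error_controller(dt_init = 1e-3, dt_max = 0.2))
  run_simulation(sim, 2)
  dg <- diagnostics(sim)
  # skipping engaged: most steps have no total-error evaluation (NA)
  expect_lt(mean(!is.na(dg$eps_total)), 0.9)
  # but the step after an increase re-evaluates
  dts <- dg$dt
  incs <- which(diff(dts) > 0) + 1L
  expect_gt(length(incs), 0L)
  expect_true(all(!is.na(dg$eps_total[incs])))
})

test_that("negative concentrations reject the step instead of clamping", {
  # an uncompensated sink on a nearly empty pool must not go negative
  sim <- cell_sim(list(A = 1e-3),
                  list(mod_reaction_grid("sink", c(A = 1), c(B = 1), k = 50),
                       mod_influx("B", 0)),
                  controller = error_controller(dt_init = 0.5))
  sim$state$grid$B <- matrix(0, 1, 1)
  run_simulation(sim, 0.5)
  expect_gte(min(sim$state$grid$A), 0 - 1e-12)
})

test_that("time-step underflow aborts with a diagnostic", {
  bad <- conc_module("explode", function(sim, state) {
    d <- delta_zero()
    d$grid$A <- matrix(NaN, 1, 1)
    d
  })
  sim <- cell_sim(list(A = 1), list(bad),
                  controller = error_controller(dt_min = 1e-6))
  expect_error(run_simulation(sim, 1), "underflow")
})
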