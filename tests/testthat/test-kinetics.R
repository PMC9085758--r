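# Rate laws and the restricted diffusion stencil.

test_that("two-cell diffusion reproduces the stencil by hand", {
  sp <- simulation_space(matrix("c", 1, 2), ds = 1)
  d <- diffusion_delta(matrix(c(1, 0), 1, 2), D = 1, dt = 0.1, sp)
  expect_equal(as.vector(d), c(-0.1, 0.1))
})

test_that("a uniform field has zero diffusion delta", {
  sp <- simulation_space(matrix("c", 8, 8), ds = 0.5)
  d <- diffusion_delta(matrix(2.5, 8, 8), D = 10, dt = 0.01, sp)
  expect_true(all(d == 0))
})

test_that("zero-flux boundaries conserve total amount to 1e-12 relative", {
  sp <- simulation_space(matrix("c", 15, 15), ds = 1)
  set.seed(2)
  f <- matrix(runif(225), 15, 15)
  tot0 <- sum(f)
  for (i in 1:50) f <- f + diffusion_delta(f, D = 5, dt = 0.02, sp)
  expect_lt(abs(sum(f) - tot0) / tot0, 1e-12)
})

test_that("a fully restricted region exchanges nothing", {
  layout <- matrix("a", 6, 6); layout[3:4, 3:4] <- "b"
  # restriction zero on the region, no membranes: the neighbour-r stencil
  # must keep the region total constant
  sp <- simulation_space(layout, ds = 1, restriction = c(a = 1, b = 0),
                         auto_membranes = FALSE)
  f <- matrix(1, 6, 6); f[layout == "b"] <- 5
  inside0 <- sum(f[layout == "b"])
  for (i in 1:40) f <- f + diffusion_delta(f, D = 2, dt = 0.05, sp)
  expect_equal(sum(f[layout == "b"]), inside0)
})

test_that("membrane faces block diffusion", {
  layout <- matrix("a", 4, 4); layout[, 3:4] <- "b"
  sp <- simulation_space(layout, ds = 1, auto_membranes = TRUE)
  f <- matrix(0, 4, 4); f[, 1:2] <- 1
  for (i in 1:30) f <- f + diffusion_delta(f, D = 1, dt = 0.1, sp)
  expect_true(all(f[, 3:4] == 0))
})

test_that("mass-action rates follow the law of mass action", {
  d <- mass_action_delta(c(A = 1), c(P = 1), c(A = 10, P = 0), k = 0.1, dt = 1)
  expect_equal(d[["A"]], -1)
  expect_equal(d[["P"]], 1)
  d0 <- mass_action_delta(c(A = 1), c(P = 1), c(A = 0, P = 3), k = 0.1, dt = 1)
  expect_equal(d0[["A"]], 0)
  # reversible: v(A) = -v(B) exactly
  dr <- mass_action_delta(c(A = 1), c(B = 1), c(A = 0.4, B = 1.1), k = 2,
                          k_rev = 1, dt = 0.2)
  expect_equal(dr[["A"]], -dr[["B"]])
  expect_error(mass_action_delta(c(Z = 1), c(P = 1), c(A = 1), k = 1),
               "missing")
})

test_that("a reversible pair relaxes to the detailed-balance ratio", {
  sim <- cell_sim(list(A = 1, B = 0),
                  list(mod_reaction_grid("rev", c(A = 1), c(B = 1),
                                         k = 2, k_rev = 1)))
  run_simulation(sim, 20)
  expect_equal(sim$state$grid$A[1] / sim$state$grid$B[1], 0.5, tolerance = 1e-3)
})

test_that("Michaelis-Menten identities and validity flag", {
  # half-saturation: c(A) = k_m -> v = k_cat * c(E) / 2
  r <- michaelis_menten_delta(cE = 2, cA = 1.5, k_cat = 4, k_m = 1.5)
  expect_equal(r$rate, 4 * 2 / 2)
  # saturation limit
  r2 <- michaelis_menten_delta(cE = 2, cA = 1e9, k_cat = 4, k_m = 1.5)
  expect_equal(r2$rate, 8, tolerance = 1e-6)
  # rate is monotone in c(A) and bounded by k_cat * c(E)
  cas <- seq(0, 50, by = 0.5)
  vs <- vapply(cas, function(ca) michaelis_menten_delta(1, ca, 3, 1.8)$rate,
               numeric(1))
  expect_true(all(diff(vs) >= 0))
  expect_true(all(vs <= 3))
  # validity flag per the quasi-steady-state caveat
  r3 <- michaelis_menten_delta(cE = 1, cA = 0.2, k_cat = 1, k_m = 1.8)
  expect_equal(r3$validity_ratio, 0.5)
  expect_false(r3$valid)
  expect_true(michaelis_menten_delta(cE = 0.01, cA = 0.2, 1, 1.8)$valid)
})

test_that("net_delta sums module deltas and cancels exactly", {
  d1 <- list(grid = list(A = matrix(0.3, 1, 1)), comp = list())
  d2 <- list(grid = list(A = matrix(-0.3, 1, 1)), comp = list())
  net <- net_delta(list(d1, d2))
  expect_equal(net$grid$A[1], 0)
  expect_equal(net_delta(list(d1))$grid$A[1], 0.3)
})

test_that("net deltas on the signalosome network equal the dense RHS oracle", {
  net <- cached_phospho_network()
  nm <- species_names(net)
  sto <- network_stoichiometry(net)
  S <- sto$S; rownames(S) <- unname(nm[rownames(S)])
  ordl <- lapply(sto$order, function(o) {
    names(o) <- unname(nm[names(o)]); o
  })
  set.seed(11)
  for (rep in 1:3) {
    init <- stats::setNames(as.list(runif(length(nm), 0, 0.6)), unname(nm))
    sim <- cell_sim(init, list(mod_network_cell(net)))
    d <- sim$modules[[1]]$rate(sim, sim$state)
    y <- unlist(init)
    v <- vapply(seq_along(ordl), function(j)
      sto$k[j] * prod(y[names(ordl[[j]])]^ordl[[j]]), numeric(1))
    dy <- stats::setNames(as.vector(S %*% v), rownames(S))
    for (e in names(dy)) {
      got <- if (is.null(d$grid[[e]])) 0 else as.numeric(d$grid[[e]])
      expect_equal(got, dy[[e]], tolerance = 1e-12)
    }
  }
})

test_that("reaction-bundle modules are equivalent to per-reaction modules", {
  m <- toy_model(2L)
  net <- generate_network(m, toy_rules(2L, k_on = 0.8, k_off = 0.3),
                          list(complex_entity(m, "X")))
  nm <- species_names(net)
  set.seed(5)
  init <- stats::setNames(as.list(runif(length(nm), 0.1, 2)), unname(nm))
  simA <- cell_sim(init, mod_network_grid(net))
  simB <- cell_sim(init, list(mod_network_cell(net)))
  dt <- 0.05
  ev <- getFromNamespace("eval_one_module", "vesiflow")
  resA <- lapply(simA$modules, ev, sim = simA, state = simA$state, dt = dt)
  d2A <- net_delta(lapply(resA, `[[`, "d2"))
  relA <- max(vapply(resA, `[[`, numeric(1), "rel"))
  fb <- ev(simB$modules[[1]], simB, simB$state, dt)
  for (e in names(d2A$grid)) {
    expect_equal(as.numeric(fb$d2$grid[[e]]), as.numeric(d2A$grid[[e]]),
                 tolerance = 1e-12)
  }
  expect_equal(fb$rel, relA, tolerance = 1e-10)
})
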