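# Brownian motion, filament transport, state changes, endocytosis, fusion.

test_that("Brownian MSD recovers the vesicle diffusivity within 3 SE", {
  sp <- simulation_space(matrix("c", 10, 10), ds = 1)
  sim <- simulation(sp, seed = 11)
  D_v <- 0.13; dt <- 0.1; n <- 10000L
  msd <- numeric(n)
  vesiflow:::with_rng(sim, "brownian", {
    for (i in seq_len(n)) msd[i] <- sum(brownian_displacement(D_v, dt)^2)
  })
  D_hat <- mean(msd) / (4 * dt)
  se <- stats::sd(msd) / (4 * dt) / sqrt(n)
  expect_lt(abs(D_hat - D_v), 3 * se)
  expect_equal(brownian_displacement(0, 0.1), c(0, 0))
})

test_that("fixed seeds give bit-identical agent trajectories", {
  mk <- function() {
    sp <- simulation_space(matrix("c", 8, 8), ds = 1)
    sim <- simulation(sp, disp_modules = list(mod_brownian(0.2)), seed = 99)
    add_vesicle(sim, 4, 4, 0.2)
    add_vesicle(sim, 6, 6, 0.2)
    run_simulation(sim, 5)
    vapply(sim$ves, function(v) c(v$x, v$y), numeric(2))
  }
  expect_identical(mk(), mk())
})

test_that("filament transport advances v_m * dt, rolls over vertices, detaches", {
  fl <- filament(rbind(c(0, 0), c(1, 0), c(1, 1)), type = "actin")
  r <- filament_displacement(fl, arc = 0, v_m = 0.8, direction = "plus", dt = 0.1)
  expect_equal(r$dp, c(0.08, 0)); expect_false(r$at_end)
  # rollover at the vertex
  r2 <- filament_displacement(fl, arc = 0.95, v_m = 1, direction = "plus", dt = 0.1)
  expect_equal(r2$dp, c(0.05, 0.05), tolerance = 1e-12)
  # at the designated end: no displacement, end flag set
  r3 <- filament_displacement(fl, arc = 2, v_m = 1, direction = "plus", dt = 0.1)
  expect_equal(r3$dp, c(0, 0)); expect_true(r3$at_end)
})

test_that("the actin boost scales with the clathrin coat concentration", {
  sp <- simulation_space(matrix("c", 6, 6), ds = 1)
  sim <- simulation(sp, disp_modules = list(mod_actin_boost(0.5)))
  id <- add_vesicle(sim, 3, 3, 0.2, state = "scissioned",
                    membrane = c(clathrin = 2))
  sim$ves[[as.character(id)]]$boost_dir <- c(0, -1)
  prop <- sim$disp_modules[[1]]$fn(sim, dt = 0.1)
  expect_equal(prop[[as.character(id)]], c(0, -0.1))
  # zero clathrin -> zero boost
  sim$state$comp[[paste0("ves:", id, ":membrane")]]["clathrin"] <- 0
  prop2 <- sim$disp_modules[[1]]$fn(sim, dt = 0.1)
  expect_equal(prop2[[as.character(id)]], c(0, 0))
})

test_that("state-change conditions fire as declared", {
  layout <- matrix("c", 6, 6)
  sp <- simulation_space(layout, ds = 1)
  mem <- surface_agent(sp, data.frame(type = "h", i = 1L, j = 1:6), "apical")
  rg <- volume_region(rbind(c(0, 3), c(6, 3), c(6, 6), c(0, 6)), name = "lower")
  fl <- filament(rbind(c(3, 1), c(3, 5)), name = "f1", type = "actin")
  sim <- simulation(sp, membranes = list(mem), regions = list(rg),
                    filaments = list(f1 = fl), seed = 5)
  id <- add_vesicle(sim, 3.04, 3.0, 0.02, state = "wandering",
                    cargo = c(X = 2))
  ves <- sim$ves[[as.character(id)]]
  # near filament (distance 0.04 - r <= 0.05) fires and attaches
  hit <- evaluate_state_changes(sim, ves, list(
    state_change("attach", "wandering", "attached", "near_filament",
                 filament_type = "actin", distance = 0.05)), dt = 0.1)
  expect_equal(hit$state, "attached")
  expect_equal(hit$filament, "f1")
  # containment: centroid exactly on the region edge counts as inside
  hit2 <- evaluate_state_changes(sim, ves, list(
    state_change("enter", "wandering", "inside", "in_region",
                 region = "lower", inside = TRUE)), dt = 0.1)
  expect_equal(hit2$state, "inside")
  # concentration threshold on the cargo compartment
  hit3 <- evaluate_state_changes(sim, ves, list(
    state_change("load", "wandering", "loaded", "conc_threshold",
                 compartment = "cargo", entity = "X", threshold = 1.5)), dt = 0.1)
  expect_equal(hit3$state, "loaded")
  # proximity to the membrane (far -> NULL)
  hit4 <- evaluate_state_changes(sim, ves, list(
    state_change("dock", "wandering", "docked", "near_surface",
                 descriptor = "apical", distance = 0.5)), dt = 0.1)
  expect_null(hit4)
})

test_that("chance state changes fire at frequency f within 3 SE", {
  sp <- simulation_space(matrix("c", 4, 4), ds = 1)
  sim <- simulation(sp, seed = 21)
  id <- add_vesicle(sim, 2, 2, 0.1, state = "on")
  ves <- sim$ves[[as.character(id)]]
  spec <- list(state_change("drop", "on", "off", "chance", f = 0.5))
  n <- 1e5L; dt <- 0.1
  fired <- 0L
  for (i in seq_len(n)) {
    if (!is.null(evaluate_state_changes(sim, ves, spec, dt))) fired <- fired + 1L
  }
  p_hat <- fired / n
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(p_hat - 0.05), 3 * se)
})

test_that("the cargo addition rate follows the catalysis/inhibition ratio", {
  expect_equal(cargo_rate(c_cat = 1, c_inh = 0, k_b = 0.4), 0.4)
  expect_equal(cargo_rate(c_cat = 1, c_inh = 1, k_b = 0.4), 0.2)
  expect_equal(cargo_rate(c_cat = 0, c_inh = 1, k_b = 0.4), 0)
  expect_equal(cargo_rate(0, 0, 0.4), 0)
  # monotone in c_cat, anti-monotone in c_inh, bounded by k_b
  cc <- seq(0, 2, by = 0.1)
  up <- vapply(cc, function(x) cargo_rate(x, 0.5, 1), numeric(1))
  dn <- vapply(cc, function(x) cargo_rate(0.5, x, 1), numeric(1))
  expect_true(all(diff(up) >= 0) && all(diff(dn) <= 0))
  expect_true(all(up <= 1) && all(dn <= 1))
})

test_that("pit lifecycle conserves cargo and aborts return it", {
  sp <- simulation_space(rbind(matrix("lumen", 1, 4), matrix("cyt", 1, 4)),
                         ds = 0.5, auto_membranes = FALSE)
  faces <- data.frame(type = "h", i = 1L, j = 1:4)
  mem <- surface_agent(sp, faces, "apical", conc = c(AQP2 = 3))
  ep <- endocytosis_params(k_p = 0.5, k_b = 0.6, t_cp = 5, c_cp = 1e6, t_m = 2,
                           cargo = "AQP2", capture_area = 0.05)
  sim <- simulation(sp, grid_init = list(), membranes = list(mem),
                    qual_modules = list(mod_endocytosis("apical", ep)),
                    seed = 3)
  tot0 <- sim_total_amount(sim, "AQP2")
  run_simulation(sim, 20)
  # impossible checkpoint: every pit aborts and returns its cargo
  ev <- events_tbl(sim)
  expect_gt(sum(ev$type == "pit_spawn"), 0)
  expect_equal(sum(ev$type == "pit_scission"), 0)
  expect_gt(sum(ev$type == "pit_abort"), 0)
  # aborted cargo is back on the membrane; open pits hold the rest
  open_cargo <- sum(vapply(sim$pits, function(p) sum(p$cargo), numeric(1)))
  expect_equal(sim_total_amount(sim, "AQP2") + open_cargo, tot0,
               tolerance = 1e-12)
  # abortive lifetimes sit at the checkpoint deadline
  lt <- unlist(ev$lifetime[ev$type == "pit_abort"])
  expect_true(all(abs(lt - 5) < 0.5))
})

test_that("scission produces a coated vesicle that conserves cargo", {
  sp <- simulation_space(rbind(matrix("lumen", 1, 4), matrix("cyt", 1, 4)),
                         ds = 0.5, auto_membranes = FALSE)
  faces <- data.frame(type = "h", i = 1L, j = 1:4)
  mem <- surface_agent(sp, faces, "apical", conc = c(AQP2 = 3))
  ep <- endocytosis_params(k_p = 0.5, k_b = 0.8, t_cp = 10, c_cp = 2, t_m = 3,
                           cargo = "AQP2", capture_area = 0.05)
  sim <- simulation(sp, membranes = list(mem),
                    qual_modules = list(mod_endocytosis("apical", ep)),
                    seed = 7)
  tot0 <- sim_total_amount(sim, "AQP2")
  run_simulation(sim, 30)
  ev <- events_tbl(sim)
  expect_gt(sum(ev$type == "pit_scission"), 0)
  expect_gt(length(sim$ves), 0)
  open_cargo <- sum(vapply(sim$pits, function(p) sum(p$cargo), numeric(1)))
  expect_equal(sim_total_amount(sim, "AQP2") + open_cargo, tot0,
               tolerance = 1e-12)
  # productive lifetimes = time-to-checkpoint + maturation > t_m
  lt <- unlist(ev$lifetime[ev$type == "pit_scission"])
  expect_true(all(lt >= 3))
})

test_that("fusion is SNARE-gated and conserves every species", {
  sp <- simulation_space(rbind(matrix("lumen", 1, 6), matrix("cyt", 2, 6)[1:2, ]),
                         ds = 1, auto_membranes = FALSE)
  faces <- data.frame(type = "h", i = 1L, j = 1:6)
  mem <- surface_agent(sp, faces, "apical", conc = c(QSNARE = 0.5, AQP2 = 0))
  fp <- fusion_params(t_f = 2, d_a = 0.3, n_p = 3L)
  mk <- function(rsnare) {
    sim <- simulation(sp, grid_init = list(lumenal = 0),
                      membranes = list(mem),
                      qual_modules = list(mod_fusion("apical", fp,
                                                     states = "tethered")),
                      seed = 2)
    add_vesicle(sim, 3, 1.3, 0.1, state = "tethered",
                membrane = c(RSNARE = rsnare, AQP2 = 4),
                cargo = c(lumenal = 10))
    sim
  }
  # 2 R-SNARE molecules on the vesicle: below n_p, no fusion
  low <- mk(2 / (4 * pi * 0.1^2) / vesiflow:::MOLECULES_PER_AMOUNT)
  run_simulation(low, 5)
  expect_equal(length(low$ves), 1L)
  expect_false(any(events_tbl(low)$type == "fusion_start"))
  # ample R-SNAREs: fusion completes after t_f and transfers everything
  sim <- mk(0.5)
  aqp0 <- sim_total_amount(sim, "AQP2")
  lum0 <- sim_total_amount(sim, "lumenal")
  run_simulation(sim, 5)
  ev <- events_tbl(sim)
  expect_true(any(ev$type == "fusion_complete"))
  expect_equal(length(sim$ves), 0L)
  expect_equal(sim_total_amount(sim, "AQP2"), aqp0, tolerance = 1e-12)
  expect_equal(sim_total_amount(sim, "lumenal"), lum0, tolerance = 1e-12)
  # the delivered AQP2 appears as a discrete membrane increase
  expect_gt(sim$state$comp[["mem:apical"]][["AQP2"]], 0)
})
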