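# Bundled model behaviours at reduced scale (the quantitative operating
# points live in test-acceptance.R).

test_that("zero influx and zero initial cAMP keep the basal fixed point", {
  res <- run_phospho_model(influx = 0, duration = 20, record_every = 10,
                           net = cached_phospho_network())
  tr <- res$trace
  expect_true(all(tr$cAMP == 0))
  expect_true(all(tr$pka_activity < 1e-6))
  expect_true(all(tr$aqp2_s256_ratio < 1e-4))
})

test_that("phospho trace reports ratios in [0, 1] and conserves scaffolds", {
  res <- run_phospho_model(influx = 0.2, duration = 20, record_every = 5,
                           net = cached_phospho_network())
  tr <- res$trace
  rat <- unlist(tr[, c("aqp2_s256_ratio", "pka_activity", "pde4_ratio",
                       "pkar_ratio")])
  expect_true(all(rat >= 0 & rat <= 1))
  # total AQP2 and PKAC are conserved by the pure reaction network
  net <- res$network
  for (part in c("AQP2", "PKAC", "PKAR", "PDE4", "PP2B")) {
    sp <- entities_matching(net, part)
    tot <- sum(vapply(sp, function(s) res$sim$state$grid[[s]][1], numeric(1)))
    want <- switch(part, AQP2 = 2, PKAC = 0.4, PKAR = 0.8, PDE4 = 0.4,
                   PP2B = 0.3)
    expect_equal(tot, want, tolerance = 1e-6)
  }
})

test_that("model results carry tidy/glance/autoplot interfaces", {
  res <- run_phospho_model(influx = 0.1, duration = 5, record_every = 5,
                           net = cached_phospho_network())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("time", "observable", "value") %in% names(td)))
  g <- glance(res)
  expect_equal(nrow(g), 1L)
  expect_true(g$max_local_rel_err <= 0.05 + 1e-12)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("compartment model: zero influx and zero initial cAMP stay at zero", {
  res <- run_compartment_model(permeability = 0.01, influx = 0, camp_init = 0,
                               duration = 5, record_every = 5)
  expect_true(all(res$trace$cAMP_cytosol == 0))
  expect_true(all(res$trace$cAMP_storage == 0))
})

test_that("the compartment model keeps its immobile species in the region", {
  res <- run_compartment_model(permeability = 0.01, duration = 5,
                               record_every = 5)
  lay <- storage_layout(30, 30, 8)
  pde <- res$sim$state$grid$PDE4
  expect_true(all(pde[lay != "storage"] == 0))
})

test_that("endocytosis model: zero base cargo rate gives zero productive pits", {
  p <- endo_params()
  p$pit$k_b <- 0
  res <- run_endocytosis_model(influx = 0.05, params = p, duration = 60,
                               seed = 2, net = cached_endo_network())
  expect_equal(res$n_productive, 0L)
  expect_gt(res$n_abortive + length(res$sim$pits), 0)
})

test_that("full model without vesicles keeps permeability at its basal level", {
  p <- full_params("activation", n_vesicles = 0)
  res <- run_full_model("activation", duration = 5, nrow = 10, ncol = 10,
                        params = p, seed = 3, net = cached_endo_network())
  expect_true(all(res$trace$permeability == res$trace$permeability[1]))
})

test_that("a tethered vesicle above threshold fuses and jumps permeability", {
  p <- full_params("activation", n_vesicles = 1, storage_permeability = 1)
  res <- run_full_model("activation", duration = 8, nrow = 10, ncol = 10,
                        record_every = 1, params = p, seed = 5,
                        net = cached_endo_network(),
                        vesicle_init = function(k, n)
                          list(state = "tethered", aqp2_ratio = 0.9,
                               position = c(5, 1.12)))
  ev <- res$events
  expect_true(any(ev$type == "fusion_complete"))
  perm <- res$trace$permeability
  jumps <- diff(perm)
  # one discrete delivery: a single large jump, permeability stays elevated
  expect_equal(sum(jumps > 1e-4), 1L)
  expect_gt(perm[length(perm)], 0)
})

test_that("total AQP2 is conserved across transport, endocytosis and fusion", {
  p <- full_params("recycling", n_vesicles = 2, storage_permeability = 1,
                   apical_aqp2 = 3)
  net <- cached_endo_network()
  res <- run_full_model("recycling", duration = 10, nrow = 10, ncol = 10,
                        record_every = 5, params = p, seed = 8, net = net,
                        vesicle_init = function(k, n)
                          list(state = "tethered", aqp2_ratio = 0.9,
                               position = c(2 + 4 * k, 1.12)))
  sim <- res$sim
  # every AQP2-containing species (free, phosphorylated, kinase/phosphatase
  # bound) in every pool, plus cargo held by open pits
  aqp2_sp <- entities_matching(net, "AQP2")
  tot <- sum(vapply(aqp2_sp, function(s) sim_total_amount(sim, s), numeric(1)))
  open_cargo <- sum(vapply(sim$pits, function(pp)
    sum(pp$cargo[c("AQP2", "AQP2.P")], na.rm = TRUE), numeric(1)))
  # initial: apical AQP2 * area + 2 vesicles * vesicle AQP2 * vesicle area
  area_ap <- sim$membranes$apical$area
  ves_area <- 4 * pi * 0.05^2
  want <- p$apical_aqp2 * area_ap + 2 * p$surface[["AQP2"]] * ves_area
  expect_equal(tot + open_cargo, want, tolerance = 1e-9)
})

test_that("the recycling variant dephosphorylates SRC faster than activation", {
  pa <- full_params("activation")
  pr <- full_params("recycling")
  expect_gt(pr$k_dp_src, pa$k_dp_src)
  expect_gt(pr$k_dp_csk, pa$k_dp_csk)
  # cargo collection scales with the active/inhibited SRC balance
  expect_lt(cargo_rate(0.1, 0.9, 0.4), cargo_rate(0.9, 0.1, 0.4))
})
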