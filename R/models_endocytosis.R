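# Clathrin-mediated endocytosis on a 1 um^2 apical membrane patch. The
# signalosome network runs on the membrane (PKA activation by cytosolic
# cAMP), PKAC phosphorylates CSK (S364), active CSK phosphorylates SRC
# (Y527), and the active/inhibited SRC ratio scales the cargo addition rate
# of endocytotic pits (active SRC catalyses, phospho-SRC inhibits).

#' Additional rules of the PKA/CSK/SRC endocytosis cascade
#'
#' @param p Parameters from [endo_params()].
#' @return List of [reaction_rule()]s (appended to [phospho_rules()]).
#' @export
src_cascade_rules <- function(p) {
  free_pkac <- list(cond_lacks_part("PKAR", "a"), cond_lacks_part("AQP2", "a"),
                    cond_lacks_part("PDE4", "a"), cond_lacks_part("CSK", "a"))
  list(
    reaction_rule("csk_bind", rx_bind("PKAC", "CSK", "cat_csk"),
                  c(free_pkac, list(cond_site_free("csk_p", "b"))),
                  k = p$k_sub_on),
    reaction_rule("csk_unbind", rx_release("PKAC", "CSK", "cat_csk"),
                  list(cond_site_free("csk_p")), k = p$k_sub_off),
    reaction_rule("csk_phos",
                  list(rx_add("P", to = "CSK", site = "csk_p"),
                       rx_release("PKAC", "CSK", "cat_csk")),
                  list(cond_has_part("PKAC")), k = p$k_cat),
    reaction_rule("csk_dephos", rx_remove("P", from = "CSK", site = "csk_p"),
                  list(cond_lacks_part("SRC")), k = p$k_dp_csk),
    reaction_rule("src_bind", rx_bind("CSK", "SRC", "cat_src"),
                  list(cond_site_occupied("csk_p", "a"), cond_lacks_part("PKAC", "a"),
                       cond_site_free("src_p", "b")),
                  k = p$k_sub_on),
    reaction_rule("src_unbind", rx_release("CSK", "SRC", "cat_src"),
                  list(cond_site_free("src_p")), k = p$k_sub_off),
    reaction_rule("src_phos",
                  list(rx_add("P", to = "SRC", site = "src_p"),
                       rx_release("CSK", "SRC", "cat_src")),
                  list(cond_has_part("CSK")), k = p$k_cat),
    reaction_rule("src_dephos", rx_remove("P", from = "SRC", site = "src_p"),
                  list(cond_lacks_part("CSK")), k = p$k_dp_src))
}

#' Parameters of the endocytosis patch model
#'
#' Extends [phospho_params()] with the SRC/CSK dephosphorylation rates (the
#' recycling variant of the full model raises these), the pit lifecycle
#' parameters, and membrane surface densities. All placeholder-provenance.
#'
#' @param k_dp_csk,k_dp_src CSK / SRC dephosphorylation (s^-1; implicit
#'   phosphatase).
#' @param k_p Pit formation rate (pits / (um^2 s)).
#' @param k_b Base cargo addition rate (s^-1).
#' @param t_cp Checkpoint deadline (s).
#' @param c_cp Required pit cargo density (uM um).
#' @param t_m Maturation time (s).
#' @return Parameter list.
#' @export
endo_params <- function(k_dp_csk = 0.05, k_dp_src = 0.05, k_p = 0.1,
                        k_b = 0.4, t_cp = 20, c_cp = 15, t_m = 15) {
  p <- phospho_params()
  p$k_dp_csk <- k_dp_csk
  p$k_dp_src <- k_dp_src
  p$pit <- list(k_p = k_p, k_b = k_b, t_cp = t_cp, c_cp = c_cp, t_m = t_m)
  p$surface <- c(holo = 0.4, pkar_free = 0.4, AQP2 = 5, PDE4 = 0.4,
                 PP2B = 0.3, SRC = 1, CSK = 1)
  p
}

#' Generate the endocytosis-model reaction network
#'
#' @param p Parameters from [endo_params()].
#' @param model Entity model.
#' @return A `reaction_network`.
#' @export
endo_network <- function(p = endo_params(), model = signalosome_entities()) {
  seeds <- c(phospho_seeds(model),
             list(SRC = complex_entity(model, "SRC"),
                  CSK = complex_entity(model, "CSK")))
  generate_network(model, c(phospho_rules(p), src_cascade_rules(p)), seeds,
                   max_complex_size = 16L)
}

#' Run the clathrin-mediated endocytosis patch model
#'
#' A 1 um^2 apical membrane patch (four unit faces at ds = 0.5 um) above a
#' thin cytosol strip. The signalosome and the SRC/CSK cascade run as
#' interface reactions on the membrane; cAMP enters the cytosol as a
#' zeroth-order influx. Pits spawn as a Poisson process, absorb AQP2 at the
#' SRC-scaled rate, abort at the checkpoint deadline or mature into coated
#' vesicles.
#'
#' @param influx cAMP influx per cytosol cell (uM/s).
#' @param params Parameters from [endo_params()].
#' @param duration Simulated time (s), typically 300.
#' @param seed Run seed (pit spawning and positions).
#' @param record_every Observer interval (s).
#' @param net Optionally a pre-generated [endo_network()].
#' @return An `endocytosis_result` with the trace, the event log, pit
#'   statistics (`n_productive`, `n_abortive`, `lifetimes`) and the mean SRC
#'   phospho-ratio.
#' @export
run_endocytosis_model <- function(influx = 0.1, params = endo_params(),
                                  duration = 300, seed = 1L,
                                  record_every = 10, net = NULL) {
  if (is.null(net)) net <- endo_network(params)
  nm <- species_names(net)
  nrow_g <- 2L; ncol_g <- 4L; ds <- 0.5
  layout <- rbind(matrix("lumen", 1L, ncol_g), matrix("cytosol", 1L, ncol_g))
  sp <- simulation_space(layout, ds = ds, auto_membranes = FALSE)
  faces <- data.frame(type = "h", i = 1L, j = seq_len(ncol_g))
  surf <- stats::setNames(rep(0, length(nm)), unname(nm))
  sconc <- params$surface
  seeds <- phospho_seeds(net$model)
  surf[[nm[[entity_label(seeds$holo)]]]] <- sconc[["holo"]]
  surf[[nm[[entity_label(seeds$pkar_free)]]]] <- sconc[["pkar_free"]]
  surf[["AQP2"]] <- sconc[["AQP2"]]
  surf[["PDE4"]] <- sconc[["PDE4"]]
  surf[["PP2B"]] <- sconc[["PP2B"]]
  surf[["SRC"]] <- sconc[["SRC"]]
  surf[["CSK"]] <- sconc[["CSK"]]
  apical <- surface_agent(sp, faces, "apical", conc = surf)
  cyto_cells <- cbind(2L, seq_len(ncol_g))
  # soluble species live in the cytosol strip
  grid_init <- list(cAMP = 0, AMP = 0, PKAC = 0)
  ep <- endocytosis_params(k_p = params$pit$k_p, k_b = params$pit$k_b,
                           t_cp = params$pit$t_cp, c_cp = params$pit$c_cp,
                           t_m = params$pit$t_m,
                           cargo = c("AQP2", "AQP2.P"),
                           cat_entity = "SRC", inh_entity = "P.SRC",
                           capture_area = 0.05, vesicle_radius = 0.04)
  sim <- simulation(sp, grid_init = grid_init, membranes = list(apical),
                    modules = list(
                      mod_diffusion(c(cAMP = 32, PKAC = 10)),
                      mod_network_interface_fast(net, "mem:apical",
                                                 cells = cyto_cells, area = apical$area),
                      mod_influx("cAMP", influx, cells = cyto_cells)),
                    qual_modules = list(mod_endocytosis("apical", ep,
                                                        interior_side = "down")),
                    controller = error_controller(dt_init = 1e-3, dt_max = 0.5,
                                                  nu = 1e-3),
                    seed = seed)
  src_ratio <- phospho_ratio_fn(net, "SRC", "src_p")
  aqp2_ratio <- phospho_ratio_fn(net, "AQP2", "aqp2_p")
  obs <- function(sim) {
    sigma <- sim$state$comp[["mem:apical"]]
    c(src_phospho_ratio = src_ratio(sigma),
      aqp2_membrane = sum(sigma[c("AQP2", "AQP2.P")], na.rm = TRUE),
      aqp2_s256_ratio = aqp2_ratio(sigma),
      cAMP = mean(sim$state$grid$cAMP[cyto_cells]),
      n_pits_open = length(sim$pits))
  }
  run_simulation(sim, duration, record_every = record_every, observer = obs)
  ev <- events_tbl(sim)
  lifetimes <- if (nrow(ev) && "lifetime" %in% names(ev))
    ev$lifetime[ev$type %in% c("pit_abort", "pit_scission")] else list()
  lifetimes <- unlist(lifetimes)
  lifetimes <- lifetimes[!is.na(lifetimes)]
  tr <- trace_tbl(sim)
  structure(list(kind = "endocytosis", trace = tr, events = ev,
                 n_productive = sum(ev$type == "pit_scission"),
                 n_abortive = sum(ev$type == "pit_abort"),
                 lifetimes = unlist(lifetimes),
                 mean_src_ratio = mean(tr$src_phospho_ratio),
                 influx = influx, params = params, sim = sim, network = net),
            class = c("endocytosis_result", "vesiflow_result"))
}
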