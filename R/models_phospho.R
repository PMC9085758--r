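# The allosteric PKA phosphorylation model: AKAP-scaffolded PKARII with two
# cAMP sites (A and B), PKAC release gated on double occupancy, PKAC
# autophosphorylation of PKAR (reduced rebinding), substrate phosphorylation
# of AQP2 / PDE4 via explicit binding + catalysis, PP2B dephosphorylation,
# and PDE4-mediated cAMP hydrolysis with a phospho-enhanced rate (negative
# feedback). Everything is generated from reactor-chain rules.

#' Entity model of the PKA/AQP2 signalosome
#'
#' Declares the simple entities and binding sites shared by the bundled
#' models, including the SRC/CSK endocytosis cascade. Membrane-bound flags
#' mark the AKAP scaffold and the membrane proteins (AQP2, SRC, CSK, and the
#' AKAP-anchored PDE4/PP2B); complexes containing them are treated as
#' surface species wherever a spatial context distinguishes membrane from
#' solution.
#'
#' @return An [entity_model()].
#' @export
signalosome_entities <- function() {
  entity_model(
    entities = list(
      simple_entity("AKAP", membrane_bound = TRUE),
      simple_entity("PKAR"),
      simple_entity("PKAC"),
      simple_entity("cAMP", small_molecule = TRUE),
      simple_entity("AMP", small_molecule = TRUE),
      simple_entity("P", small_molecule = TRUE),
      simple_entity("AQP2", membrane_bound = TRUE),
      simple_entity("PDE4", membrane_bound = TRUE),
      simple_entity("PP2B", membrane_bound = TRUE),
      simple_entity("SRC", membrane_bound = TRUE),
      simple_entity("CSK", membrane_bound = TRUE)),
    sites = list(
      binding_site("ra", "AKAP", "PKAR"),
      binding_site("siteA", "PKAR", "cAMP"),
      binding_site("siteB", "PKAR", "cAMP"),
      binding_site("rc", "PKAR", "PKAC"),
      binding_site("pkar_p", "PKAR", "P"),
      binding_site("aqp2_p", "AQP2", "P"),
      binding_site("pde4_p", "PDE4", "P"),
      binding_site("csk_p", "CSK", "P"),
      binding_site("src_p", "SRC", "P"),
      binding_site("cat_aqp2", "PKAC", "AQP2"),
      binding_site("cat_pde4", "PKAC", "PDE4"),
      binding_site("cat_csk", "PKAC", "CSK"),
      binding_site("cat_src", "CSK", "SRC"),
      binding_site("pp_aqp2", "PP2B", "AQP2"),
      binding_site("pp_pkar", "PP2B", "PKAR"),
      binding_site("pp_pde4", "PP2B", "PDE4"),
      binding_site("pde_camp", "PDE4", "cAMP"),
      binding_site("pde_amp", "PDE4", "AMP")))
}

#' Default kinetic parameters of the phosphorylation model
#'
#' Literature-anchored constants are hard defaults (cAMP-PKAR binding
#' 0.07 uM^-1 s^-1; influx levels in nM/s). The remaining
#' constants are physiological placeholders (`provenance = "placeholder"`),
#' chosen once so that the model reproduces the stated basal operating point
#' (S256 phospho-ratio 0.46 under basal 0.05 uM/s influx) and kept fixed; see
#' the methods vignette.
#'
#' @return Named list of rate constants (uM, s units) with a `provenance`
#'   attribute.
#' @export
phospho_params <- function() {
  p <- list(
    k_camp_on = 0.07,   # cAMP-PKAR binding, uM^-1 s^-1 (both sites)
    k_camp_off = 0.08,  # cAMP unbinding, s^-1
    k_rel = 4,          # PKAC release from double-occupied PKAR, s^-1
    k_rc_on = 0.35,     # PKAC-PKAR rebinding (unphosphorylated R), uM^-1 s^-1
    k_rc_on_p = 0.04,   # reduced rebinding to phospho-PKAR, uM^-1 s^-1
    k_phos_r = 0.5,     # PKAR autophosphorylation inside the holoenzyme, s^-1
    k_sub_on = 1,       # PKAC-substrate binding (AQP2/PDE4/CSK), uM^-1 s^-1
    k_sub_off = 0.5,    # unproductive dissociation, s^-1
    k_cat = 2,          # phosphoryl transfer + release, s^-1
    k_pp_on = 0.115,    # PP2B-substrate binding, uM^-1 s^-1
    k_pp_off = 0.5,     # PP2B dissociation, s^-1
    k_pp_cat = 1,       # dephosphorylation + release, s^-1
    k_pde_on = 1,       # cAMP-PDE4 binding, uM^-1 s^-1
    k_pde_off = 1,      # cAMP release from PDE4, s^-1
    k_hyd = 0.3,        # basal hydrolysis, s^-1
    k_hyd_p = 4,        # hydrolysis of phospho-PDE4, s^-1
    conc = c(holo = 0.4,    # AKAP.PKAR.PKAC holoenzyme, uM
             pkar_free = 0.4,  # surplus AKAP.PKAR without PKAC, uM
             AQP2 = 2, PDE4 = 0.4, PP2B = 0.3))
  attr(p, "provenance") <- c(k_camp_on = "literature", .default = "placeholder")
  p
}

#' Reaction rules of the phosphorylation model
#'
#' @param p Parameter list from [phospho_params()].
#' @return List of [reaction_rule()]s.
#' @export
phospho_rules <- function(p = phospho_params()) {
  free_pkac <- list(cond_lacks_part("PKAR", "a"), cond_lacks_part("AQP2", "a"),
                    cond_lacks_part("PDE4", "a"), cond_lacks_part("CSK", "a"))
  free_pp2b <- list(cond_lacks_part("PKAR", "a"), cond_lacks_part("AQP2", "a"),
                    cond_lacks_part("PDE4", "a"))
  # note: role "a" of a BIND is the complex containing the first operand
  list(
    reaction_rule("camp_on_A", rx_bind("PKAR", "cAMP", "siteA"), k = p$k_camp_on),
    reaction_rule("camp_off_A", rx_release("PKAR", "cAMP", "siteA"), k = p$k_camp_off),
    reaction_rule("camp_on_B", rx_bind("PKAR", "cAMP", "siteB"), k = p$k_camp_on),
    reaction_rule("camp_off_B", rx_release("PKAR", "cAMP", "siteB"), k = p$k_camp_off),
    # PKAC is only released once both cAMP sites are occupied
    reaction_rule("pkac_release", rx_release("PKAR", "PKAC", "rc"),
                  list(cond_site_occupied("siteA"), cond_site_occupied("siteB")),
                  k = p$k_rel),
    reaction_rule("pkac_rebind", rx_bind("PKAR", "PKAC", "rc"),
                  list(cond_site_free("pkar_p", "a"), cond_site_free("siteB", "a"),
                       cond_lacks_part("AQP2", "b"), cond_lacks_part("PDE4", "b"),
                       cond_lacks_part("CSK", "b")),
                  k = p$k_rc_on),
    reaction_rule("pkac_rebind_slow", rx_bind("PKAR", "PKAC", "rc"),
                  list(cond_site_occupied("pkar_p", "a"), cond_site_free("siteB", "a"),
                       cond_lacks_part("AQP2", "b"), cond_lacks_part("PDE4", "b"),
                       cond_lacks_part("CSK", "b")),
                  k = p$k_rc_on_p),
    # autophosphorylation of PKAR by its bound PKAC
    reaction_rule("pkar_phos", rx_add("P", to = "PKAR", site = "pkar_p"),
                  list(cond_has_part("PKAC", "a")), k = p$k_phos_r),
    # substrate phosphorylation: explicit binding, catalysis, dissociation
    reaction_rule("aqp2_bind", rx_bind("PKAC", "AQP2", "cat_aqp2"),
                  c(free_pkac, list(cond_site_free("aqp2_p", "b"))),
                  k = p$k_sub_on),
    reaction_rule("aqp2_unbind", rx_release("PKAC", "AQP2", "cat_aqp2"),
                  list(cond_site_free("aqp2_p")), k = p$k_sub_off),
    reaction_rule("aqp2_phos",
                  list(rx_add("P", to = "AQP2", site = "aqp2_p"),
                       rx_release("PKAC", "AQP2", "cat_aqp2")),
                  list(cond_has_part("PKAC")), k = p$k_cat),
    reaction_rule("pde4_bind", rx_bind("PKAC", "PDE4", "cat_pde4"),
                  c(free_pkac, list(cond_site_free("pde4_p", "b"))),
                  k = p$k_sub_on),
    reaction_rule("pde4_unbind", rx_release("PKAC", "PDE4", "cat_pde4"),
                  list(cond_site_free("pde4_p")), k = p$k_sub_off),
    reaction_rule("pde4_phos",
                  list(rx_add("P", to = "PDE4", site = "pde4_p"),
                       rx_release("PKAC", "PDE4", "cat_pde4")),
                  list(cond_has_part("PKAC")), k = p$k_cat),
    # PP2B reverses the phosphorylations
    reaction_rule("pp_aqp2_bind", rx_bind("PP2B", "AQP2", "pp_aqp2"),
                  c(free_pp2b, list(cond_site_occupied("aqp2_p", "b"))),
                  k = p$k_pp_on),
    reaction_rule("pp_aqp2_unbind", rx_release("PP2B", "AQP2", "pp_aqp2"),
                  list(cond_site_occupied("aqp2_p")), k = p$k_pp_off),
    reaction_rule("aqp2_dephos",
                  list(rx_remove("P", from = "AQP2", site = "aqp2_p"),
                       rx_release("PP2B", "AQP2", "pp_aqp2")),
                  list(cond_has_part("PP2B")), k = p$k_pp_cat),
    reaction_rule("pp_pkar_bind", rx_bind("PP2B", "PKAR", "pp_pkar"),
                  c(free_pp2b, list(cond_site_occupied("pkar_p", "b"))),
                  k = p$k_pp_on),
    reaction_rule("pp_pkar_unbind", rx_release("PP2B", "PKAR", "pp_pkar"),
                  list(cond_site_occupied("pkar_p")), k = p$k_pp_off),
    reaction_rule("pkar_dephos",
                  list(rx_remove("P", from = "PKAR", site = "pkar_p"),
                       rx_release("PP2B", "PKAR", "pp_pkar")),
                  list(cond_has_part("PP2B")), k = p$k_pp_cat),
    reaction_rule("pp_pde4_bind", rx_bind("PP2B", "PDE4", "pp_pde4"),
                  c(free_pp2b, list(cond_site_occupied("pde4_p", "b"))),
                  k = p$k_pp_on),
    reaction_rule("pp_pde4_unbind", rx_release("PP2B", "PDE4", "pp_pde4"),
                  list(cond_site_occupied("pde4_p")), k = p$k_pp_off),
    reaction_rule("pde4_dephos",
                  list(rx_remove("P", from = "PDE4", site = "pde4_p"),
                       rx_release("PP2B", "PDE4", "pp_pde4")),
                  list(cond_has_part("PP2B")), k = p$k_pp_cat),
    # cAMP hydrolysis by PDE4; phospho-PDE4 hydrolyses faster (feedback)
    reaction_rule("pde_camp_on", rx_bind("PDE4", "cAMP", "pde_camp"),
                  list(cond_lacks_part("PP2B", "a")), k = p$k_pde_on),
    reaction_rule("pde_camp_off", rx_release("PDE4", "cAMP", "pde_camp"),
                  k = p$k_pde_off),
    reaction_rule("hydrolysis",
                  list(rx_remove("cAMP", from = "PDE4", site = "pde_camp"),
                       rx_add("AMP", to = "PDE4", site = "pde_amp"),
                       rx_release("PDE4", "AMP", "pde_amp")),
                  list(cond_site_free("pde4_p")), k = p$k_hyd),
    reaction_rule("hydrolysis_p",
                  list(rx_remove("cAMP", from = "PDE4", site = "pde_camp"),
                       rx_add("AMP", to = "PDE4", site = "pde_amp"),
                       rx_release("PDE4", "AMP", "pde_amp")),
                  list(cond_site_occupied("pde4_p")), k = p$k_hyd_p))
}

#' Seed entities of the phosphorylation model
#'
#' @param model The [signalosome_entities()] model.
#' @return Named list of `complex_entity` seeds (`holo` is the
#'   AKAP-scaffolded PKAR-PKAC holoenzyme).
#' @export
phospho_seeds <- function(model = signalosome_entities()) {
  list(
    holo = complex_entity(model, c("AKAP", "PKAR", "PKAC"),
                          data.frame(from = c(1L, 2L), to = c(2L, 3L),
                                     site = c("ra", "rc"))),
    pkar_free = complex_entity(model, c("AKAP", "PKAR"),
                               data.frame(from = 1L, to = 2L, site = "ra")),
    AQP2 = complex_entity(model, "AQP2"),
    PDE4 = complex_entity(model, "PDE4"),
    PP2B = complex_entity(model, "PP2B"),
    cAMP = complex_entity(model, "cAMP"),
    AMP = complex_entity(model, "AMP"),
    PKAC = complex_entity(model, "PKAC"))
}

#' Generate the phosphorylation reaction network
#'
#' @param p Parameters from [phospho_params()].
#' @param model Entity model.
#' @return A `reaction_network`.
#' @export
phospho_network <- function(p = phospho_params(), model = signalosome_entities()) {
  generate_network(model, phospho_rules(p), phospho_seeds(model),
                   max_complex_size = 16L)
}

#' Species names of entities matching structural filters
#'
#' Returns the unique species names (see [species_names()]) of the network
#' entities that contain `part`, optionally restricted to those with a given
#' site occupied or free, or lacking other parts. The building block for
#' observables such as phosphorylation ratios.
#'
#' @param net A `reaction_network`.
#' @param part Simple entity name that must occur in the complex.
#' @param site_occupied,site_free Site name filters.
#' @param lacks Simple entity names that must not occur.
#' @return Character vector of species names.
#' @export
entities_matching <- function(net, part, site_occupied = NULL, site_free = NULL,
                              lacks = NULL) {
  hits <- character()
  for (lab in names(net$entities)) {
    x <- net$entities[[lab]]
    if (!(part %in% x$nodes)) next
    if (!is.null(site_occupied) && !any(x$edges$site == site_occupied)) next
    if (!is.null(site_free) && any(x$edges$site == site_free)) next
    if (!is.null(lacks) && any(lacks %in% x$nodes)) next
    hits <- c(hits, lab)
  }
  unname(species_names(net)[unique(hits)])
}

# observable closure: fraction of `part` carrying `site` over total `part`
phospho_ratio_fn <- function(net, part, site) {
  phos <- entities_matching(net, part, site_occupied = site)
  all_sp <- entities_matching(net, part)
  function(conc) {
    tot <- sum(conc[all_sp], na.rm = TRUE)
    if (tot <= 0) return(0)
    sum(conc[phos], na.rm = TRUE) / tot
  }
}

# observable closure: fraction of `part` in complexes lacking `partner`
free_fraction_fn <- function(net, part, partner) {
  free_sp <- entities_matching(net, part, lacks = partner)
  all_sp <- entities_matching(net, part)
  function(conc) {
    tot <- sum(conc[all_sp], na.rm = TRUE)
    if (tot <= 0) return(0)
    sum(conc[free_sp], na.rm = TRUE) / tot
  }
}

#' Run the well-mixed PKA/AQP2 phosphorylation model
#'
#' Single grid point, mass-action network generated from the rules, constant
#' zeroth-order cAMP influx emulating adenylyl cyclase activity. Returns the
#' time courses of the S256 phospho-ratio of AQP2, the PDE4 and PKAR
#' phospho-ratios, PKA activity (free-PKAC fraction) and cAMP.
#'
#' @param influx cAMP influx in uM/s (e.g. 0.05 basal, 0.2 stimulating).
#' @param camp_binding cAMP-PKAR binding rate constant (uM^-1 s^-1).
#' @param params Parameter list from [phospho_params()].
#' @param duration Simulated time (s), typically 300.
#' @param record_every Observer interval (s).
#' @param controller An [error_controller()].
#' @param net Optionally a pre-generated network (must match `params`).
#' @return A `phospho_result` with the trace tibble, final observables and
#'   the generated network.
#' @export
run_phospho_model <- function(influx = 0.05, camp_binding = NULL,
                              params = phospho_params(), duration = 300,
                              record_every = 5,
                              controller = error_controller(dt_init = 1e-3,
                                                            dt_max = 1),
                              net = NULL) {
  if (!is.null(camp_binding)) params$k_camp_on <- camp_binding
  if (is.null(net)) net <- phospho_network(params)
  nm <- species_names(net)
  init <- stats::setNames(as.list(rep(0, length(nm))), unname(nm))
  cn <- params$conc
  seeds <- phospho_seeds(net$model)
  init[[nm[[entity_label(seeds$holo)]]]] <- cn[["holo"]]
  init[[nm[[entity_label(seeds$pkar_free)]]]] <- cn[["pkar_free"]]
  init[["AQP2"]] <- cn[["AQP2"]]
  init[["PDE4"]] <- cn[["PDE4"]]
  init[["PP2B"]] <- cn[["PP2B"]]
  sp <- simulation_space(matrix("cytosol", 1, 1), ds = 1)
  sim <- simulation(sp, grid_init = init,
                    modules = list(mod_network_cell(
                      net, influx = list(list(entity = "cAMP", rate = influx)))),
                    controller = controller)
  aqp2_ratio <- phospho_ratio_fn(net, "AQP2", "aqp2_p")
  pde4_ratio <- phospho_ratio_fn(net, "PDE4", "pde4_p")
  pkar_ratio <- phospho_ratio_fn(net, "PKAR", "pkar_p")
  pka_act <- free_fraction_fn(net, "PKAC", "PKAR")
  obs <- function(sim) {
    conc <- vapply(sim$state$grid, function(m) m[1, 1], numeric(1))
    c(aqp2_s256_ratio = aqp2_ratio(conc), pka_activity = pka_act(conc),
      pde4_ratio = pde4_ratio(conc), pkar_ratio = pkar_ratio(conc),
      cAMP = unname(conc["cAMP"]), AMP = unname(conc["AMP"]))
  }
  run_simulation(sim, duration, record_every = record_every, observer = obs)
  tr <- trace_tbl(sim)
  structure(list(kind = "phospho", trace = tr,
                 final = tr[nrow(tr), , drop = FALSE],
                 influx = influx, params = params, network = net, sim = sim),
            class = c("phospho_result", "vesiflow_result"))
}
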