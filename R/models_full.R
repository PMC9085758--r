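# Full AQP2 recycling model (scaled down): a 2D cell section with an apical
# membrane, a reduced-permeability perinuclear storage region holding
# AQP2-positive vesicles carrying the PKA signalosome, actin tracks from
# storage to the apical membrane, a microtubule for retrograde transport,
# cAMP influx at four basolateral grid points following the stepped
# schedule, SNARE-gated fusion and clathrin-mediated endocytosis. The
# recycling variant accelerates SRC/CSK dephosphorylation so productive
# endocytosis resumes after activation.

#' The cAMP influx schedule of the full model
#'
#' 400 nM/s per influx grid point for the first 5 minutes, 200 nM/s until
#' 15 minutes, and a basal 50 nM/s afterwards.
#'
#' @return `function(t)` giving uM/s.
#' @export
full_influx_schedule <- function() {
  function(t) if (t < 300) 0.4 else if (t < 900) 0.2 else 0.05
}

#' Parameters of the full recycling model
#'
#' @param variant `"activation"` (slow SRC/CSK dephosphorylation: endocytosis
#'   stays unproductive, permeability stays high) or `"recycling"` (raised
#'   dephosphorylation rates recover productive pits).
#' @param departure_threshold S256 phospho-ratio that triggers vesicle
#'   departure (0.75).
#' @param permeability_factor Conversion from apical AQP2 density (uM um) to
#'   the reported membrane permeability (arbitrary units).
#' @param n_vesicles Number of storage vesicles.
#' @param storage_permeability Diffusive restriction of the storage region.
#' @param apical_aqp2 Initial AQP2 density already in the apical membrane
#'   (uM um); staged scenarios use this to study endocytosis without waiting
#'   for exocytic delivery.
#' @param influx cAMP influx per node (uM/s or `function(t)`); defaults to
#'   the stepped schedule.
#' @return Parameter list extending [endo_params()].
#' @export
full_params <- function(variant = c("activation", "recycling"),
                        departure_threshold = 0.75,
                        permeability_factor = 1,
                        n_vesicles = 5,
                        storage_permeability = 0.05,
                        apical_aqp2 = 0,
                        influx = full_influx_schedule()) {
  variant <- match.arg(variant)
  dp <- if (variant == "recycling") 0.5 else 0.05
  p <- endo_params(k_dp_csk = dp, k_dp_src = dp)
  p$variant <- variant
  p$departure_threshold <- departure_threshold
  p$permeability_factor <- permeability_factor
  p$n_vesicles <- n_vesicles
  p$storage_permeability <- storage_permeability
  p$apical_aqp2 <- apical_aqp2
  p$influx <- influx
  p$v_actin <- 0.8        # myosin transport velocity, um/s
  p$v_mt <- 0.8           # retrograde microtubule transport velocity, um/s
  p$v_boost <- 0.5        # actin boost base velocity, um/s per uM um clathrin
  p$D_v <- 0.13           # vesicle diffusivity, um^2/s
  p$fusion <- fusion_params(t_f = 5, d_a = 0.1, n_p = 3L)
  p$snare_q <- 0.05       # apical Q-SNARE density, uM um
  p$snare_r <- 0.3        # vesicle R-SNARE density, uM um (>= n_p molecules on a 50 nm sphere)
  p
}

#' Run the full AQP2 recycling model (scaled down)
#'
#' @param variant `"activation"` or `"recycling"`.
#' @param duration Simulated time (s). A full-scale run covers 40 minutes;
#'   the scaled default covers the activation phase.
#' @param nrow,ncol,ds Grid geometry (um).
#' @param params Parameters from [full_params()].
#' @param seed Run seed.
#' @param record_every Observer interval (s).
#' @param net Optionally a pre-generated [endo_network()].
#' @param vesicle_init Optional function `(k, n)` returning a list with
#'   `state`, `aqp2_ratio` and optionally `position` (um) for vesicle `k` of
#'   `n` (used to stage scaled-down scenarios); default: all `in_storage`
#'   with ratio 0, placed in the storage region.
#' @return A `full_result` with trace, events and the permeability trace.
#' @export
run_full_model <- function(variant = c("activation", "recycling"),
                           duration = 120, nrow = 20, ncol = 20, ds = 1,
                           params = NULL, seed = 1L, record_every = 5,
                           net = NULL, vesicle_init = NULL) {
  variant <- match.arg(variant)
  if (is.null(params)) params <- full_params(variant)
  if (is.null(net)) net <- endo_network(params)
  nm <- species_names(net)
  # layout: top row lumen, storage block low centre, cytosol elsewhere
  layout <- matrix("cytosol", nrow, ncol)
  layout[1, ] <- "lumen"
  sr <- max(4L, nrow - 8L):(nrow - 3L)
  sc_ <- (ncol %/% 2 - 2L):(ncol %/% 2 + 3L)
  layout[sr, sc_] <- "storage"
  sp <- simulation_space(layout, ds = ds,
                         restriction = c(cytosol = 1, lumen = 1,
                                         storage = params$storage_permeability),
                         auto_membranes = FALSE)
  apical_faces <- data.frame(type = "h", i = 1L, j = seq_len(ncol))
  surf0 <- stats::setNames(rep(0, length(nm)), unname(nm))
  ap <- surf0
  ap[["SRC"]] <- params$surface[["SRC"]]
  ap[["CSK"]] <- params$surface[["CSK"]]
  ap[["AQP2"]] <- params$apical_aqp2
  ap[["QSNARE"]] <- params$snare_q
  apical <- surface_agent(sp, apical_faces, "apical", conc = ap)
  storage_poly <- volume_region(rbind(
    c((min(sc_) - 1) * ds, (min(sr) - 1) * ds),
    c(max(sc_) * ds, (min(sr) - 1) * ds),
    c(max(sc_) * ds, max(sr) * ds),
    c((min(sc_) - 1) * ds, max(sr) * ds)), name = "storage")
  # filaments: actin tracks from storage to the apical membrane (plus end
  # apical), one microtubule for retrograde transport (minus end at storage)
  cx <- (min(sc_) + max(sc_)) / 2 * ds
  cy <- (min(sr) + max(sr)) / 2 * ds
  fl <- list(
    actin1 = filament(rbind(c(cx - 1.5, cy), c(cx - 1.5, 1.5 * ds)),
                      name = "actin1", type = "actin"),
    actin2 = filament(rbind(c(cx + 1.5, cy), c(cx + 1.5, 1.5 * ds)),
                      name = "actin2", type = "actin"),
    mt1 = filament(rbind(c(cx, cy), c(cx, 1.5 * ds)),
                   name = "mt1", type = "microtubule"))
  grid_init <- list(cAMP = 0.01, AMP = 0, PKAC = 0)
  influx_cols <- unique(round(seq(2, ncol - 1, length.out = 4)))
  influx_cells <- cbind(nrow, influx_cols)
  ep <- endocytosis_params(k_p = params$pit$k_p, k_b = params$pit$k_b,
                           t_cp = params$pit$t_cp, c_cp = params$pit$c_cp,
                           t_m = params$pit$t_m,
                           cargo = c("AQP2", "AQP2.P"),
                           cat_entity = "SRC", inh_entity = "P.SRC",
                           capture_area = 0.05, vesicle_radius = 0.04,
                           coat = c(clathrin = 1, RSNARE = params$snare_r))
  dep <- params$departure_threshold
  phos_sp <- entities_matching(net, "AQP2", site_occupied = "aqp2_p")
  all_aqp2 <- entities_matching(net, "AQP2")
  specs <- list(
    state_change("departure", "in_storage", "departing", "ratio_threshold",
                 compartment = "membrane", num = phos_sp, den = all_aqp2,
                 threshold = dep),
    state_change("actin_attach", "departing", "actin_attached",
                 "near_filament", filament_type = "actin", distance = 0.5),
    state_change("tether", "actin_attached", "tethered", "near_surface",
                 descriptor = "apical", distance = 0.3),
    state_change("mt_attach", "scissioned", "microtubule_attached",
                 "near_filament", filament_type = "microtubule", distance = 0.5),
    state_change("arrive_storage", "microtubule_attached", "in_storage",
                 "in_region", region = "storage", inside = TRUE))
  ctl <- error_controller(dt_init = 1e-3, dt_max = 0.25, nu = 1e-3)
  sim <- simulation(sp, grid_init = grid_init, membranes = list(apical),
                    modules = list(
                      mod_diffusion(c(cAMP = 32, PKAC = 10)),
                      mod_network_interface_fast(net, "mem:apical",
                                                 cells = cbind(2L, seq_len(ncol)),
                                                 area = apical$area),
                      mod_network_vesicle_fast(net),
                      mod_influx("cAMP", params$influx, cells = influx_cells)),
                    disp_modules = list(
                      mod_brownian(params$D_v, states = c("in_storage", "departing")),
                      mod_filament_transport(params$v_actin, type = "actin",
                                             direction = "plus",
                                             states = "actin_attached"),
                      mod_filament_transport(params$v_mt, type = "microtubule",
                                             direction = "minus",
                                             states = "microtubule_attached"),
                      mod_actin_boost(params$v_boost)),
                    qual_modules = list(
                      mod_state_changes(specs),
                      mod_endocytosis("apical", ep, interior_side = "down"),
                      mod_fusion("apical", params$fusion,
                                 states = "tethered")),
                    regions = list(storage_poly),
                    filaments = fl,
                    controller = ctl, seed = seed)
  # storage vesicles carrying the signalosome and AQP2 in their membrane
  seeds <- phospho_seeds(net$model)
  vm <- surf0
  vm[[nm[[entity_label(seeds$holo)]]]] <- params$surface[["holo"]]
  vm[[nm[[entity_label(seeds$pkar_free)]]]] <- params$surface[["pkar_free"]]
  vm[["PDE4"]] <- params$surface[["PDE4"]]
  vm[["PP2B"]] <- params$surface[["PP2B"]]
  vm[["RSNARE"]] <- params$snare_r
  n <- params$n_vesicles
  with_rng(sim, "placement", {
    for (k in seq_len(n)) {
      pos <- c(stats::runif(1, (min(sc_) - 0.7) * ds, (max(sc_) - 0.3) * ds),
               stats::runif(1, (min(sr) - 0.7) * ds, (max(sr) - 0.3) * ds))
      vi <- if (is.null(vesicle_init)) list(state = "in_storage", aqp2_ratio = 0)
            else vesicle_init(k, n)
      if (!is.null(vi$position)) pos <- vi$position
      m <- vm
      m[["AQP2"]] <- params$surface[["AQP2"]] * (1 - vi$aqp2_ratio)
      m[["AQP2.P"]] <- params$surface[["AQP2"]] * vi$aqp2_ratio
      add_vesicle(sim, pos[1], pos[2], 0.05, state = vi$state, membrane = m)
    }
  })
  aqp2_sp <- c("AQP2", "AQP2.P")
  storage_mask <- layout == "storage"
  src_ratio <- phospho_ratio_fn(net, "SRC", "src_p")
  obs <- function(sim) {
    sigma <- sim$state$comp[["mem:apical"]]
    perm <- params$permeability_factor * sum(sigma[aqp2_sp], na.rm = TRUE)
    ca <- sim$state$grid$cAMP
    rt <- vapply(sim$ves, function(v) {
      m <- sim$state$comp[[paste0("ves:", v$id, ":membrane")]]
      num <- sum(m[phos_sp], na.rm = TRUE); den <- sum(m[all_aqp2], na.rm = TRUE)
      if (den > 0) num / den else NA_real_
    }, numeric(1))
    c(permeability = perm,
      cAMP_cytosol = mean(ca[!storage_mask & sim$space$layout != "lumen"]),
      cAMP_storage = mean(ca[storage_mask]),
      src_phospho_ratio = src_ratio(sigma),
      n_vesicles = length(sim$ves),
      mean_vesicle_aqp2_ratio = if (length(rt)) mean(rt, na.rm = TRUE) else NA_real_)
  }
  run_simulation(sim, duration, record_every = record_every, observer = obs)
  tr <- trace_tbl(sim)
  structure(list(kind = "full", variant = variant, trace = tr,
                 events = events_tbl(sim),
                 permeability = tr$permeability,
                 final = tr[nrow(tr), , drop = FALSE],
                 params = params, sim = sim, network = net),
            class = c("full_result", "vesiflow_result"))
}
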