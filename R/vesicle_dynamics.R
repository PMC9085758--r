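# Displacement and qualitative modules for vesicles: Brownian diffusion,
# filament-guided and boost transport, state changes, the endocytotic pit
# lifecycle, and SNARE-gated fusion.

# molecules per amount unit (1 uM * um^3 = 1e-21 mol)
MOLECULES_PER_AMOUNT <- 602.214076

#' Brownian displacement of a sphere-like agent
#'
#' `dp = sqrt(2 * D_v * dt) * xi` per coordinate with `xi` standard Gaussian,
#' so the ensemble mean squared displacement per step is `4 * D_v * dt` in
#' 2D. Draws from the current RNG; modules route this through the run's
#' `"brownian"` substream.
#'
#' @param D_v Vesicle diffusivity (um^2/s), `>= 0`.
#' @param dt Time step (s).
#' @return Numeric `(dx, dy)` in um.
#' @export
brownian_displacement <- function(D_v, dt) {
  stopifnot(D_v >= 0)
  sqrt(2 * D_v * dt) * stats::rnorm(2L)
}

#' Brownian-motion displacement module
#'
#' @param D_v Vesicle diffusivity (um^2/s).
#' @param states Vesicle states the module applies to.
#' @return A `disp_module`.
#' @export
mod_brownian <- function(D_v, states = c("unattached", "in_storage")) {
  disp_module("brownian", function(sim, dt) {
    out <- list()
    with_rng(sim, "brownian", {
      for (key in names(sim$ves)) {
        v <- sim$ves[[key]]
        if (!(v$state %in% states)) next
        out[[key]] <- brownian_displacement(D_v, dt)
      }
    })
    out
  })
}

#' Filament-guided displacement of an attached vesicle
#'
#' Advances the vesicle `v_m * dt` along the filament toward the designated
#' end, rolling over polyline vertices; the proposal is the difference between
#' the new and current on-filament points. At the filament end the proposal is
#' zero (detachment is a state change).
#'
#' @param fl A [filament()].
#' @param arc Current arc-length coordinate (um).
#' @param v_m Motor velocity (um/s).
#' @param direction `"plus"` or `"minus"` end.
#' @param dt Time step (s).
#' @return List with `dp` (c(dx, dy)), `arc` (new coordinate) and `at_end`.
#' @export
filament_displacement <- function(fl, arc, v_m, direction = "plus", dt) {
  s1 <- arc + (if (direction == "plus") 1 else -1) * v_m * dt
  s1 <- min(max(s1, 0), fl$total_len)
  p0 <- filament_point(fl, arc)
  p1 <- filament_point(fl, s1)
  list(dp = p1 - p0, arc = s1,
       at_end = (direction == "plus" && s1 >= fl$total_len - 1e-12) ||
         (direction == "minus" && s1 <= 1e-12))
}

#' Filament transport module
#'
#' @param v_m Motor velocity (um/s).
#' @param type Filament type the motor walks on.
#' @param direction `"plus"` or `"minus"`.
#' @param states Vesicle states the module applies to.
#' @return A `disp_module`.
#' @export
mod_filament_transport <- function(v_m, type = "actin", direction = "plus",
                                   states = "actin_attached") {
  disp_module(paste0("transport:", type), function(sim, dt) {
    out <- list()
    for (key in names(sim$ves)) {
      v <- sim$ves[[key]]
      if (!(v$state %in% states) || is.null(v$filament)) next
      fl <- sim$filaments[[v$filament]]
      if (is.null(fl)) stop("vesicle ", v$id, " attached to unknown filament '",
                            v$filament, "'")
      res <- filament_displacement(fl, v$arc %||% 0, v_m, direction, dt)
      out[[key]] <- res$dp
    }
    out
  })
}

#' Actin-boost displacement module
#'
#' Directed, unguided transport applied to freshly scissioned vesicles: the
#' unit vector points orthogonal to the membrane segment the vesicle spawned
#' from and the velocity scales with the concentration of the scaling entity
#' (clathrin) in the vesicle coat, `v = v_b * c_s`.
#'
#' @param v_b Base velocity per concentration (um/s per uM um).
#' @param entity Scaling entity in the vesicle membrane compartment.
#' @param states Applicable states.
#' @return A `disp_module`.
#' @export
mod_actin_boost <- function(v_b, entity = "clathrin", states = "scissioned") {
  disp_module("actin-boost", function(sim, dt) {
    out <- list()
    for (key in names(sim$ves)) {
      v <- sim$ves[[key]]
      if (!(v$state %in% states) || is.null(v$boost_dir)) next
      cs <- sim$state$comp[[paste0("ves:", v$id, ":membrane")]]
      c_s <- if (entity %in% names(cs)) cs[[entity]] else 0
      out[[key]] <- v_b * c_s * dt * v$boost_dir
    }
    out
  })
}

# --- state changes ----------------------------------------------------------

#' Declare a vesicle state change
#'
#' Five condition types mirror the qualitative module cases: proximity to a
#' surface agent or filament (nearest-segment distance to the vesicle
#' surface), containment in a volume region (even-odd rule on the centroid;
#' on-boundary counts as inside), a compartment concentration threshold, and
#' chance (probability `f * dt` per step; if `f * dt > 1` the controller
#' decreases the step instead of clamping). A sixth, `at_filament_end`,
#' detaches vesicles that ran off their track.
#'
#' @param name Spec name (logged with each fired event).
#' @param states Applicable states.
#' @param to_state New state.
#' @param type One of `"near_surface"`, `"near_filament"`, `"in_region"`,
#'   `"conc_threshold"`, `"chance"`, `"at_filament_end"`, or
#'   `"ratio_threshold"` (fraction `sum(num)/sum(den)` of compartment
#'   species against a threshold, e.g. the 0.75 S256 phospho-ratio that
#'   triggers vesicle departure).
#' @param ... Type parameters: `descriptor`/`distance` (near_surface),
#'   `filament_type`/`distance` (near_filament; also attaches the vesicle),
#'   `region`/`inside` (in_region), `compartment`/`entity`/`threshold`/`above`
#'   (conc_threshold), `f` (chance).
#' @return A `state_change` spec.
#' @export
state_change <- function(name, states, to_state, type, ...) {
  # formals chosen so that `...` parameters (f, filament_type, distance, ...)
  # can never partially match them
  structure(list(name = name, from = states, to = to_state, type = type,
                 params = list(...)),
            class = "state_change")
}

ves_surface_distance <- function(sim, ves, faces) {
  segs <- faces_to_segments(sim$space, faces)
  p <- c(ves$x, ves$y)
  d <- Inf
  for (k in seq_len(nrow(segs))) {
    a <- segs[k, 1:2]; b <- segs[k, 3:4]
    ab <- b - a
    tt <- min(max(sum((p - a) * ab) / sum(ab^2), 0), 1)
    d <- min(d, sqrt(sum((p - (a + tt * ab))^2)))
  }
  d - ves$r
}

faces_to_segments <- function(space, faces) {
  ds <- space$ds
  out <- matrix(numeric(), nrow(faces), 4L)
  for (k in seq_len(nrow(faces))) {
    if (faces$type[k] == "v") {
      out[k, ] <- c(faces$j[k] * ds, (faces$i[k] - 1) * ds,
                    faces$j[k] * ds, faces$i[k] * ds)
    } else {
      out[k, ] <- c((faces$j[k] - 1) * ds, faces$i[k] * ds,
                    faces$j[k] * ds, faces$i[k] * ds)
    }
  }
  out
}

#' Evaluate state-change specs for one vesicle
#'
#' Specs are evaluated in order; the first satisfied condition fires and its
#' side effects (state, filament attachment) are returned.
#'
#' @param sim A [simulation()].
#' @param ves Vesicle record.
#' @param specs List of [state_change()] specs.
#' @param dt Time step (s).
#' @return `NULL` if nothing fired, else a list with `spec`, `state` and
#'   optional `filament`/`arc`.
#' @export
evaluate_state_changes <- function(sim, ves, specs, dt) {
  for (sc in specs) {
    if (!(ves$state %in% sc$from)) next
    p <- sc$params
    fired <- switch(sc$type,
      near_surface = {
        mb <- sim$membranes[[p$descriptor]]
        !is.null(mb) && ves_surface_distance(sim, ves, mb$faces) <= p$distance
      },
      near_filament = {
        hit <- NULL
        for (fn in names(sim$filaments)) {
          fl <- sim$filaments[[fn]]
          if (!is.null(p$filament_type) && fl$type != p$filament_type) next
          near <- filament_nearest(fl, c(ves$x, ves$y))
          if (near$dist - ves$r <= p$distance) { hit <- list(fn = fn, s = near$s); break }
        }
        if (!is.null(hit)) {
          return(list(spec = sc$name, state = sc$to,
                      filament = hit$fn, arc = hit$s))
        }
        FALSE
      },
      in_region = {
        rg <- Filter(function(r) r$name == p$region, sim$regions)
        length(rg) && region_contains(rg[[1L]], c(ves$x, ves$y)) == (p$inside %||% TRUE)
      },
      conc_threshold = {
        v <- sim$state$comp[[paste0("ves:", ves$id, ":", p$compartment)]]
        x <- if (p$entity %in% names(v)) v[[p$entity]] else 0
        if (isTRUE(p$above %||% TRUE)) x >= p$threshold else x <= p$threshold
      },
      chance = {
        with_rng(sim, "state-chance", stats::runif(1L) < p$f * dt)
      },
      at_filament_end = {
        !is.null(ves$filament) &&
          (ves$arc %||% 0) >= sim$filaments[[ves$filament]]$total_len - 1e-9
      },
      ratio_threshold = {
        v <- sim$state$comp[[paste0("ves:", ves$id, ":", p$compartment)]]
        num <- sum(v[p$num], na.rm = TRUE)
        den <- sum(v[p$den], na.rm = TRUE)
        ratio <- if (den > 0) num / den else 0
        if (isTRUE(p$above %||% TRUE)) ratio >= p$threshold else ratio <= p$threshold
      },
      stop("unknown state-change condition type '", sc$type, "'"))
    if (isTRUE(fired)) return(list(spec = sc$name, state = sc$to))
  }
  NULL
}

#' State-change qualitative module
#'
#' @param specs List of [state_change()] specs.
#' @return A `qual_module`.
#' @export
mod_state_changes <- function(specs) {
  fmax <- max(c(0, vapply(Filter(function(s) s$type == "chance", specs),
                          function(s) s$params$f, numeric(1))))
  qual_module("state-changes", function(sim, dt) {
    for (key in names(sim$ves)) {
      ves <- sim$ves[[key]]
      # keep the arc coordinate in sync with the applied position
      if (!is.null(ves$filament)) {
        near <- filament_nearest(sim$filaments[[ves$filament]], c(ves$x, ves$y))
        sim$ves[[key]]$arc <- near$s
        ves <- sim$ves[[key]]
      }
      hit <- evaluate_state_changes(sim, ves, specs, dt)
      if (is.null(hit)) next
      sim$ves[[key]]$state <- hit$state
      if (!is.null(hit$filament)) {
        sim$ves[[key]]$filament <- hit$filament
        sim$ves[[key]]$arc <- hit$arc
      }
      log_event(sim, "state_change", id = ves$id, spec = hit$spec,
                from = ves$state, to = hit$state, x = ves$x, y = ves$y)
    }
  }, f_max = function(sim) fmax)
}

log_event <- function(sim, type, ...) {
  sim$events[[length(sim$events) + 1L]] <- c(list(type = type, t = sim$t), list(...))
  invisible(sim)
}

#' Event log as a tibble
#'
#' @param sim A run [simulation()].
#' @return Tibble of logged events (pit lifecycle, state changes, fusion).
#' @export
events_tbl <- function(sim) {
  if (!length(sim$events)) {
    return(tibble::tibble(type = character(), t = numeric()))
  }
  cols <- unique(unlist(lapply(sim$events, names)))
  rows <- lapply(sim$events, function(e) {
    e <- c(e, stats::setNames(rep(list(NA), length(setdiff(cols, names(e)))),
                              setdiff(cols, names(e))))
    tibble::as_tibble(e[cols])
  })
  do.call(rbind, rows)
}

# --- endocytosis ------------------------------------------------------------

#' Effective cargo addition rate of an endocytotic pit
#'
#' `k_c = c_cat / (c_cat + c_inh) * k_b`: the catalysing entity (active SRC)
#' scales the base rate up to `k_b`, the inhibiting entity (phospho-SRC)
#' scales it down; both zero gives 0.
#'
#' @param c_cat,c_inh Catalysing and inhibiting concentrations (same units).
#' @param k_b Base cargo addition rate (1/s).
#' @return Effective rate in `[0, k_b]`.
#' @export
cargo_rate <- function(c_cat, c_inh, k_b) {
  stopifnot(c_cat >= 0, c_inh >= 0, k_b >= 0)
  if (c_cat + c_inh == 0) return(0)
  c_cat / (c_cat + c_inh) * k_b
}

#' Endocytosis parameters
#'
#' @param k_p Pit formation rate (pits / (um^2 s)).
#' @param k_b Base cargo addition rate (1/s).
#' @param t_cp Checkpoint deadline (s): a pit that has not collected `c_cp`
#'   by this age is aborted and returns its cargo to the membrane.
#' @param c_cp Required cargo density at the checkpoint (uM um).
#' @param t_m Maturation time (s) from checkpoint to scission.
#' @param cargo Cargo entity names collected from the membrane.
#' @param cat_entity,inh_entity Catalysing / inhibiting entities for
#'   [cargo_rate()] (membrane densities); `NULL` means `k_c = k_b`.
#' @param capture_area Pit footprint area (um^2) through which cargo is
#'   absorbed.
#' @param vesicle_radius Radius of the scissioned vesicle (um).
#' @param coat Named densities (uM um) added to the new vesicle's membrane at
#'   scission (the clathrin coat).
#' @return Parameter list.
#' @export
endocytosis_params <- function(k_p, k_b, t_cp, c_cp, t_m, cargo,
                               cat_entity = NULL, inh_entity = NULL,
                               capture_area = 0.03, vesicle_radius = 0.04,
                               coat = c(clathrin = 1)) {
  list(k_p = k_p, k_b = k_b, t_cp = t_cp, c_cp = c_cp, t_m = t_m,
       cargo = cargo, cat_entity = cat_entity, inh_entity = inh_entity,
       capture_area = capture_area, vesicle_radius = vesicle_radius,
       coat = coat)
}

# inward normal of a face: from the face into the second adjacent cell is
# ambiguous; use the supplied interior side ("down" rows increase / "up")
face_inward <- function(face, side = "down") {
  if (face$type == "h") c(0, if (side == "down") 1 else -1)
  else c(if (side == "down") 1 else -1, 0)
}

#' Endocytosis qualitative module
#'
#' Manages the pit lifecycle on one membrane agent: Poisson spawning at rate
#' `k_p * area`, per-step cargo absorption at the effective rate of
#' [cargo_rate()] through the pit footprint (never more than the membrane
#' holds), abortion at the checkpoint deadline (cargo returned), maturation,
#' and scission into a coated vesicle that receives the actin boost.
#'
#' @param descriptor Membrane agent descriptor.
#' @param params An [endocytosis_params()] list.
#' @param interior_side Which side of the membrane faces is intracellular
#'   (`"down"` = increasing row/column index).
#' @return A `qual_module`.
#' @export
mod_endocytosis <- function(descriptor, params, interior_side = "down") {
  qual_module("endocytosis", function(sim, dt) {
    mb <- sim$membranes[[descriptor]]
    cid <- paste0("mem:", descriptor)
    sigma <- sim$state$comp[[cid]]
    # spawn
    n_new <- with_rng(sim, "pits", stats::rpois(1L, params$k_p * mb$area * dt))
    if (n_new > 0) {
      picks <- with_rng(sim, "pits", {
        fi <- sample.int(nrow(mb$faces), n_new, replace = TRUE)
        list(fi = fi, u = stats::runif(n_new))
      })
      segs <- faces_to_segments(sim$space, mb$faces)
      for (k in seq_len(n_new)) {
        a <- segs[picks$fi[k], 1:2]; b <- segs[picks$fi[k], 3:4]
        pos <- a + picks$u[k] * (b - a)
        id <- sim$next_pit_id; sim$next_pit_id <- id + 1L
        sim$pits[[as.character(id)]] <- list(
          id = id, x = pos[1], y = pos[2],
          face = mb$faces[picks$fi[k], ], birth = sim$t, t_reach = NA_real_,
          phase = "collecting",
          cargo = stats::setNames(numeric(length(params$cargo)), params$cargo))
        log_event(sim, "pit_spawn", id = id, x = pos[1], y = pos[2])
      }
    }
    # collect / checkpoint / mature
    c_cat <- if (is.null(params$cat_entity)) 1 else
      (if (params$cat_entity %in% names(sigma)) sigma[[params$cat_entity]] else 0)
    c_inh <- if (is.null(params$inh_entity)) 0 else
      (if (params$inh_entity %in% names(sigma)) sigma[[params$inh_entity]] else 0)
    k_c <- cargo_rate(c_cat, c_inh, params$k_b)
    for (key in names(sim$pits)) {
      pit <- sim$pits[[key]]
      age <- sim$t - pit$birth
      if (pit$phase == "collecting") {
        sigma <- sim$state$comp[[cid]]
        for (e in params$cargo) {
          avail <- (if (e %in% names(sigma)) sigma[[e]] else 0) * mb$area
          demand <- k_c * (if (e %in% names(sigma)) sigma[[e]] else 0) *
            params$capture_area * dt
          take <- min(avail, demand)
          if (take <= 0) next
          sigma[e] <- sigma[[e]] - take / mb$area
          pit$cargo[e] <- pit$cargo[[e]] + take
        }
        sim$state$comp[[cid]] <- sigma
        if (sum(pit$cargo) / params$capture_area >= params$c_cp) {
          pit$phase <- "maturing"
          pit$t_reach <- sim$t
          log_event(sim, "pit_checkpoint", id = pit$id)
        } else if (age >= params$t_cp) {
          # aborted: all collected cargo returns to the source membrane
          sigma <- sim$state$comp[[cid]]
          for (e in names(pit$cargo)) {
            sigma[e] <- (if (e %in% names(sigma)) sigma[[e]] else 0) +
              pit$cargo[[e]] / mb$area
          }
          sim$state$comp[[cid]] <- sigma
          log_event(sim, "pit_abort", id = pit$id, lifetime = age)
          sim$pits[[key]] <- NULL
          next
        }
        sim$pits[[key]] <- pit
      } else if (pit$phase == "maturing" && sim$t - pit$t_reach >= params$t_m) {
        # scission: pit becomes a coated vesicle carrying its cargo
        dir <- face_inward(pit$face, interior_side)
        r <- params$vesicle_radius
        pos <- c(pit$x, pit$y) + dir * (r + 1e-3)
        vid <- add_vesicle(sim, pos[1], pos[2], r, state = "scissioned")
        varea <- sim$ves[[as.character(vid)]]$area
        memb <- pit$cargo / varea
        for (e in names(params$coat)) {
          memb[e] <- (if (e %in% names(memb)) memb[[e]] else 0) + params$coat[[e]]
        }
        sim$state$comp[[paste0("ves:", vid, ":membrane")]] <- memb
        sim$ves[[as.character(vid)]]$boost_dir <- dir
        log_event(sim, "pit_scission", id = pit$id, vesicle = vid,
                  lifetime = sim$t - pit$birth)
        sim$pits[[key]] <- NULL
      }
    }
  })
}

# --- fusion -----------------------------------------------------------------

#' Fusion parameters
#'
#' @param t_f Fusion duration (s).
#' @param d_a Attachment distance (um) between vesicle surface and membrane.
#' @param S_Q,S_R Q-SNARE (target membrane) and R-SNARE (vesicle membrane)
#'   entity names.
#' @param n_p Minimal number of SNARE pairs to initiate fusion.
#' @return Parameter list.
#' @export
fusion_params <- function(t_f, d_a, S_Q = "QSNARE", S_R = "RSNARE", n_p = 3L) {
  list(t_f = t_f, d_a = d_a, S_Q = S_Q, S_R = S_R, n_p = as.integer(n_p))
}

snare_count <- function(density, area) {
  floor(max(density, 0) * area * MOLECULES_PER_AMOUNT)
}

#' SNARE-gated fusion qualitative module
#'
#' When an eligible vesicle's surface comes within `d_a` of the target
#' membrane and at least `n_p` Q/R-SNARE pairs can be formed (counts obtained
#' from the area densities, rounded down), the vesicle enters the `fusing`
#' state for `t_f`; on completion its membrane species merge into the target
#' membrane compartment (area-scaled), its lumenal cargo merges into the grid
#' compartment under the vesicle, and the vesicle is removed.
#'
#' @param descriptor Target membrane agent descriptor.
#' @param params A [fusion_params()] list.
#' @param states Vesicle states eligible to initiate fusion.
#' @return A `qual_module`.
#' @export
mod_fusion <- function(descriptor, params, states = c("tethered", "unattached",
                                                      "actin_attached")) {
  qual_module("fusion", function(sim, dt) {
    mb <- sim$membranes[[descriptor]]
    cid <- paste0("mem:", descriptor)
    for (key in names(sim$ves)) {
      ves <- sim$ves[[key]]
      vmid <- paste0("ves:", ves$id, ":membrane")
      if (ves$state %in% states) {
        if (ves_surface_distance(sim, ves, mb$faces) > params$d_a) next
        sigma_t <- sim$state$comp[[cid]]
        sigma_v <- sim$state$comp[[vmid]]
        nQ <- snare_count(if (params$S_Q %in% names(sigma_t)) sigma_t[[params$S_Q]] else 0, mb$area)
        nR <- snare_count(if (params$S_R %in% names(sigma_v)) sigma_v[[params$S_R]] else 0, ves$area)
        if (min(nQ, nR) < params$n_p) next
        sim$ves[[key]]$state <- "fusing"
        sim$ves[[key]]$fusion_start <- sim$t
        sim$ves[[key]]$fusion_target <- descriptor
        log_event(sim, "fusion_start", id = ves$id, target = descriptor,
                  pairs = min(nQ, nR))
      } else if (ves$state == "fusing" &&
                 identical(ves$fusion_target, descriptor) &&
                 sim$t - ves$fusion_start >= params$t_f) {
        sigma_t <- sim$state$comp[[cid]]
        sigma_v <- sim$state$comp[[vmid]]
        for (e in names(sigma_v)) {
          sigma_t[e] <- (if (e %in% names(sigma_t)) sigma_t[[e]] else 0) +
            sigma_v[[e]] * ves$area / mb$area
        }
        sim$state$comp[[cid]] <- sigma_t
        cargo <- sim$state$comp[[paste0("ves:", ves$id, ":cargo")]]
        if (length(cargo)) {
          cell <- index_vesicle(sim$space, ves$x, ves$y, 0)$cells[1, ]
          vol <- point_volume(sim$space)
          for (e in names(cargo)) {
            g <- sim$state$grid[[e]]
            if (is.null(g)) stop("fusion cargo entity '", e, "' has no grid field")
            g[cell[1], cell[2]] <- g[cell[1], cell[2]] +
              cargo[[e]] * ves$cargo_volume / vol
            sim$state$grid[[e]] <- g
          }
        }
        log_event(sim, "fusion_complete", id = ves$id, target = descriptor)
        remove_vesicle(sim, ves$id)
      }
    }
  })
}
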