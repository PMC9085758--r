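# Concentration-based update modules.
#
# A concentration module is a named object whose `rate(sim, state)` returns a
# sparse delta per unit time (see state.R). The integrator turns rates into
# the embedded Euler/midpoint pair: d1 = dt * rate(state),
# d2 = dt * rate(state + d1/2), and computes the module's local error from
# the two.

#' Create a concentration module
#'
#' Low-level constructor; most users build modules through the `mod_*`
#' helpers or through model configurations.
#'
#' @param name Module name (used in controller diagnostics).
#' @param rate Function `(sim, state) -> delta` per unit time.
#' @param embedded Optional function `(sim, state, dt) -> list(d1, d2, rel)`
#'   supplying the embedded Euler/midpoint pair directly (used by vectorised
#'   reaction-bundle modules that evaluate the pair per reaction internally).
#' @return A `conc_module`.
#' @export
conc_module <- function(name, rate, embedded = NULL) {
  structure(list(name = name, rate = rate, embedded = embedded),
            class = "conc_module")
}

#' Diffusion module
#'
#' One concentration module covering every diffusing grid entity; the
#' module's local error is the maximum over its entities and grid points.
#'
#' @param entity Grid entity name, or a named numeric vector of diffusion
#'   coefficients (`c(cAMP = 32, PKAC = 10)`), in which case `D` is ignored.
#' @param D Diffusion coefficient (um^2/s) when `entity` is a single name.
#' @return A `conc_module`.
#' @export
mod_diffusion <- function(entity, D = NULL) {
  Ds <- if (is.numeric(entity)) entity else stats::setNames(D, entity)
  rate_fn <- function(sim, state) {
    d <- delta_zero()
    for (e in names(Ds)) {
      d$grid[[e]] <- diffusion_delta(state$grid[[e]], Ds[[e]], 1, sim$space)
    }
    d
  }
  # diffusion is linear: d2 = d1 + (dt/2) L d1, so the embedded pair costs
  # one operator application on the field and one on the delta
  embedded_fn <- function(sim, state, dt) {
    d1 <- delta_zero(); d2 <- delta_zero()
    relmax <- 0
    ctl <- sim$controller
    for (e in names(Ds)) {
      a <- diffusion_delta(state$grid[[e]], Ds[[e]], dt, sim$space)
      b <- a + diffusion_delta(a, Ds[[e]], dt, sim$space) / 2
      num <- abs(a - b)
      den <- pmax(abs(b), ctl$eta * abs(state$grid[[e]]), ctl$atol)
      nz <- num > 0
      if (any(nz)) relmax <- max(relmax, max(num[nz] / den[nz]))
      d1$grid[[e]] <- a
      d2$grid[[e]] <- b
    }
    list(d1 = d1, d2 = d2, rel = relmax)
  }
  conc_module(paste0("diffusion:", paste(names(Ds), collapse = "+")),
              rate_fn, embedded = embedded_fn)
}

#' Zeroth-order influx module
#'
#' Adds `rate` uM/s of `entity` at the listed grid cells (or everywhere).
#' `rate` may be a function of simulation time to express influx schedules.
#'
#' @param entity Grid entity name.
#' @param rate Influx in uM/s per target cell, or `function(t)` returning it.
#' @param cells Two-column matrix of 1-based `(i, j)` targets, or `NULL` for
#'   all cells.
#' @return A `conc_module`.
#' @export
mod_influx <- function(entity, rate, cells = NULL) {
  force(entity); force(rate); force(cells)
  conc_module(paste0("influx:", entity), function(sim, state) {
    rt <- if (is.function(rate)) rate(sim$t) else rate
    g <- state$grid[[entity]] * 0
    if (is.null(cells)) g[] <- rt else g[cells] <- rt
    d <- delta_zero()
    d$grid[[entity]] <- g
    d
  })
}

# elementwise mass-action rate over grid fields
grid_rate_matrix <- function(state, order, k) {
  v <- NULL
  for (e in names(order)) {
    f <- state$grid[[e]]
    if (is.null(f)) stop("grid field missing for entity '", e, "'")
    term <- if (order[[e]] == 1) f else f^order[[e]]
    v <- if (is.null(v)) term else v * term
  }
  if (is.null(v)) stop("grid reaction with no substrates")
  v * k
}

#' Grid-wide mass-action reaction module
#'
#' Applies one elementary reaction at every grid point, `v = k * prod(c^nu)`
#' (optionally minus a reverse term). Species names index grid fields.
#'
#' @param name Module name.
#' @param substrates,products Named stoichiometry vectors.
#' @param k Forward rate constant.
#' @param k_rev Reverse rate constant or `NULL`.
#' @return A `conc_module`.
#' @export
mod_reaction_grid <- function(name, substrates, products, k, k_rev = NULL) {
  force(substrates); force(products); force(k); force(k_rev)
  conc_module(name, function(sim, state) {
    v <- grid_rate_matrix(state, substrates, k)
    if (!is.null(k_rev)) v <- v - grid_rate_matrix(state, products, k_rev)
    d <- delta_zero()
    for (e in names(substrates)) {
      d$grid[[e]] <- (if (is.null(d$grid[[e]])) 0 else d$grid[[e]]) - substrates[[e]] * v
    }
    for (e in names(products)) {
      d$grid[[e]] <- (if (is.null(d$grid[[e]])) 0 else d$grid[[e]]) + products[[e]] * v
    }
    d
  })
}

#' Grid-wide Michaelis-Menten module
#'
#' Used only where a model configuration requests it; raises the
#' quasi-steady-state validity flag in the run diagnostics when
#' `c(E)/(c(A)+k_m)` reaches the threshold.
#'
#' @param name Module name.
#' @param enzyme,substrate,product Grid entity names.
#' @param k_cat Turnover (1/s).
#' @param k_m Michaelis constant (uM).
#' @param validity_threshold See [michaelis_menten_delta()].
#' @return A `conc_module`.
#' @export
mod_mm_grid <- function(name, enzyme, substrate, product, k_cat, k_m,
                        validity_threshold = 0.1) {
  conc_module(name, function(sim, state) {
    cE <- state$grid[[enzyme]]; cA <- state$grid[[substrate]]
    v <- k_cat * cE * cA / (k_m + cA)
    ratio <- max(cE / (cA + k_m))
    if (ratio >= validity_threshold) sim$mm_warnings[[name]] <- ratio
    d <- delta_zero()
    d$grid[[substrate]] <- -v
    d$grid[[product]] <- v
    d
  })
}

#' Grid modules for every reaction of a generated network
#'
#' One mass-action module per elementary reaction, each evaluated at every
#' grid point; species are keyed by the network's human-readable formulas.
#'
#' @param net A `reaction_network`.
#' @return List of `conc_module`s.
#' @export
mod_network_grid <- function(net) {
  labs <- names(net$entities)
  fml <- species_names(net)
  lapply(seq_along(net$reactions), function(j) {
    r <- net$reactions[[j]]
    st <- table(r$substrates); pt <- table(r$products)
    sub <- as.numeric(st); names(sub) <- fml[names(st)]
    prd <- as.numeric(pt); names(prd) <- fml[names(pt)]
    mod_reaction_grid(sprintf("rxn%02d:%s", j, r$rule), sub, prd, r$law$k)
  })
}

# --- interface (surface / vesicle) reactions -------------------------------
#
# Unit conventions (see the methods vignette): volume species carry uM, a
# surface compartment carries per-area density sigma (uM um). A reaction with
# at least one surface substrate runs at a per-area rate
#   v_A [uM um / s] = k * prod(sigma_surface) * prod(c_volume_local)
# surface products gain v_A directly; volume products receive the amount
# v_A * A spread over the coupled grid cells by weight.

interface_rate <- function(state, sim, comp_id, cells, weights,
                           surf_sub, vol_sub, k) {
  v <- k
  sc <- state$comp[[comp_id]]
  for (e in names(surf_sub)) {
    x <- if (e %in% names(sc)) sc[[e]] else 0
    v <- v * x^surf_sub[[e]]
  }
  for (e in names(vol_sub)) {
    f <- state$grid[[e]]
    cl <- sum(f[cells] * weights)
    v <- v * cl^vol_sub[[e]]
  }
  v
}

#' Interface reaction module between a surface compartment and the grid
#'
#' Species are partitioned by `surface_species`: those live in the compartment
#' `comp_id` as per-area densities, the rest are grid fields sampled and
#' updated at the coupled `cells` with the given `weights` (summing to 1).
#'
#' @param name Module name.
#' @param comp_id Compartment id, e.g. `"mem:apical"`.
#' @param substrates,products Named stoichiometry vectors.
#' @param surface_species Character vector naming the membrane-bound species.
#' @param cells Two-column matrix of coupled grid cells (1-based `(i, j)`).
#' @param weights Numeric weights per cell (default uniform).
#' @param area Interface area (um^2).
#' @param k Rate constant.
#' @return A `conc_module`.
#' @export
mod_reaction_interface <- function(name, comp_id, substrates, products,
                                   surface_species, cells, weights = NULL,
                                   area, k) {
  cells <- as.matrix(cells)
  if (is.null(weights)) weights <- rep(1 / nrow(cells), nrow(cells))
  weights <- weights / sum(weights)
  split_sp <- function(x) {
    s <- x[names(x) %in% surface_species]
    v <- x[!names(x) %in% surface_species]
    list(s = s, v = v)
  }
  sub <- split_sp(substrates); prd <- split_sp(products)
  conc_module(name, function(sim, state) {
    vol_cell <- point_volume(sim$space)
    vA <- interface_rate(state, sim, comp_id, cells, weights, sub$s, sub$v, k)
    d <- delta_zero()
    cv <- numeric(0)
    for (e in names(sub$s)) cv[e] <- -sub$s[[e]] * vA
    for (e in names(prd$s)) cv[e] <- (if (e %in% names(cv)) cv[[e]] else 0) + prd$s[[e]] * vA
    if (length(cv)) d$comp[[comp_id]] <- cv
    gtouch <- union(names(sub$v), names(prd$v))
    for (e in gtouch) {
      nu <- (if (e %in% names(prd$v)) prd$v[[e]] else 0) -
        (if (e %in% names(sub$v)) sub$v[[e]] else 0)
      g <- state$grid[[e]] * 0
      g[cells] <- nu * vA * area * weights / vol_cell
      d$grid[[e]] <- (if (is.null(d$grid[[e]])) 0 else d$grid[[e]]) + g
    }
    d
  })
}

#' Interface modules for a generated network on a surface compartment
#'
#' Membrane-bound entities (per their complex flag) live on the surface; the
#' others are grid species exchanged with the coupled cells.
#'
#' @param net A `reaction_network`.
#' @param comp_id Surface compartment id.
#' @param cells,weights,area See [mod_reaction_interface()].
#' @return List of `conc_module`s.
#' @export
mod_network_interface <- function(net, comp_id, cells, weights = NULL, area) {
  labs <- names(net$entities)
  fml <- species_names(net)
  memb <- vapply(labs, function(l) isTRUE(net$entities[[l]]$membrane_bound), logical(1))
  surface_species <- unname(fml[memb])
  lapply(seq_along(net$reactions), function(j) {
    r <- net$reactions[[j]]
    st <- table(r$substrates); pt <- table(r$products)
    sub <- as.numeric(st); names(sub) <- fml[names(st)]
    prd <- as.numeric(pt); names(prd) <- fml[names(pt)]
    mod_reaction_interface(sprintf("%s:rxn%02d:%s", comp_id, j, r$rule),
                           comp_id, sub, prd, surface_species,
                           cells, weights, area, r$law$k)
  })
}

#' Vesicle-compartment reaction module (vectorised over vesicles)
#'
#' Runs one elementary reaction in the membrane compartment of every vesicle
#' (in the applicable states). Membrane-bound species live on the vesicle
#' membrane; volume species are sampled from / deposited into the grid cells
#' the vesicle is associated with, weighted by its surface-area fractions.
#'
#' @param name Module name.
#' @param substrates,products Named stoichiometry vectors.
#' @param surface_species Membrane-bound species names.
#' @param k Rate constant.
#' @param states Vesicle states the reaction applies in (`NULL` = all).
#' @return A `conc_module`.
#' @export
mod_reaction_vesicle <- function(name, substrates, products, surface_species,
                                 k, states = NULL) {
  split_sp <- function(x) list(s = x[names(x) %in% surface_species],
                               v = x[!names(x) %in% surface_species])
  sub <- split_sp(substrates); prd <- split_sp(products)
  conc_module(name, function(sim, state) {
    d <- delta_zero()
    vol_cell <- point_volume(sim$space)
    for (ves in sim$ves) {
      if (!is.null(states) && !(ves$state %in% states)) next
      cid <- paste0("ves:", ves$id, ":membrane")
      if (is.null(state$comp[[cid]])) next
      cells <- ves$assoc$cells; w <- ves$assoc$fractions
      vA <- interface_rate(state, sim, cid, cells, w, sub$s, sub$v, k)
      if (vA == 0) next
      cv <- numeric(0)
      for (e in names(sub$s)) cv[e] <- -sub$s[[e]] * vA
      for (e in names(prd$s)) cv[e] <- (if (e %in% names(cv)) cv[[e]] else 0) + prd$s[[e]] * vA
      if (length(cv)) d$comp[[cid]] <- if (is.null(d$comp[[cid]])) cv else {
        merged <- d$comp[[cid]]
        for (e in names(cv)) merged[e] <- (if (e %in% names(merged)) merged[[e]] else 0) + cv[[e]]
        merged
      }
      gtouch <- union(names(sub$v), names(prd$v))
      for (e in gtouch) {
        nu <- (if (e %in% names(prd$v)) prd$v[[e]] else 0) -
          (if (e %in% names(sub$v)) sub$v[[e]] else 0)
        g <- if (is.null(d$grid[[e]])) state$grid[[e]] * 0 else d$grid[[e]]
        g[cells] <- g[cells] + nu * vA * ves$area * w / vol_cell
        d$grid[[e]] <- g
      }
    }
    d
  })
}

#' Vesicle-compartment modules for a generated network
#'
#' @param net A `reaction_network`.
#' @param states Vesicle states the network applies in (`NULL` = all).
#' @return List of `conc_module`s.
#' @export
mod_network_vesicle <- function(net, states = NULL) {
  labs <- names(net$entities)
  fml <- species_names(net)
  memb <- vapply(labs, function(l) isTRUE(net$entities[[l]]$membrane_bound), logical(1))
  surface_species <- unname(fml[memb])
  lapply(seq_along(net$reactions), function(j) {
    r <- net$reactions[[j]]
    st <- table(r$substrates); pt <- table(r$products)
    sub <- as.numeric(st); names(sub) <- fml[names(st)]
    prd <- as.numeric(pt); names(prd) <- fml[names(pt)]
    mod_reaction_vesicle(sprintf("ves:rxn%02d:%s", j, r$rule), sub, prd,
                         surface_species, r$law$k, states)
  })
}

# --- vectorised reaction-bundle modules -------------------------------------
#
# These bundle every reaction of a generated network into one module while
# preserving the per-reaction semantics exactly: the embedded Euler/midpoint
# pair is evaluated reaction by reaction (each reaction's half-step predictor
# perturbs the state by its own first-order delta only, as per-reaction
# modules would), and the reported local error is the maximum over reactions
# and grid points. They exist purely for speed.

compile_network <- function(net) {
  labs <- names(net$entities)
  fml <- species_names(net)
  memb <- vapply(labs, function(l) isTRUE(net$entities[[l]]$membrane_bound), logical(1))
  rx <- lapply(net$reactions, function(r) {
    st <- table(r$substrates); pt <- table(r$products)
    sub <- as.numeric(st); names(sub) <- fml[names(st)]
    if (any(sub > 2) || length(sub) > 2)
      stop("reaction-bundle modules support at most two substrate slots")
    slots <- rep(names(sub), sub)
    net_st <- stats::setNames(-sub, names(sub))
    for (e in names(pt)) {
      nm <- fml[[e]]
      net_st[nm] <- (if (nm %in% names(net_st)) net_st[[nm]] else 0) + as.numeric(pt[[e]])
    }
    net_st <- net_st[net_st != 0]
    list(k = r$law$k, slots = slots, net = net_st,
         numax = max(abs(net_st)))
  })
  list(species = unname(fml), surface = unname(fml[memb]), rx = rx)
}

# worst |d1 - d2| / max(|d2|, atol) for one reaction, computed on the delta
# scale of its largest stoichiometric coefficient
ratio_max <- function(v1, v2, atol = 0) {
  num <- abs(v1 - v2); den <- pmax(abs(v2), atol)
  max(ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den)), 0)
}

#' Bundled grid network module (vectorised per-reaction midpoint)
#'
#' Equivalent to the list of per-reaction [mod_reaction_grid()] modules for
#' the same network, evaluated in one pass: identical deltas and identical
#' worst-case local error, reported as a single module. An optional `mask`
#' restricts evaluation to the grid cells where the network's immobile
#' species live (reactions elsewhere have zero rate).
#'
#' @param net A `reaction_network`.
#' @param mask Logical matrix of active cells, or `NULL` for all cells.
#' @param influx Optional list of `list(entity =, rate =, cells =)`
#'   zeroth-order sources folded into the bundle; `rate` is uM/s per cell or
#'   a `function(t)`, `cells` a two-column `(i, j)` matrix.
#' @param name Module name.
#' @return A `conc_module`.
#' @export
mod_network_fast <- function(net, mask = NULL, influx = list(),
                             name = "reactions") {
  cmp <- compile_network(net)
  idx <- if (is.null(mask)) NULL else which(mask)
  inf_rate <- lapply(influx, `[[`, "rate")
  inf_entity <- vapply(influx, `[[`, character(1), "entity")
  inf_cells <- lapply(influx, `[[`, "cells")
  rate_at <- function(r, t) if (is.function(r)) r(t) else r
  add_influx <- function(d, state, t, dt) {
    for (q in seq_along(influx)) {
      e <- inf_entity[q]
      g <- d$grid[[e]]
      if (is.null(g)) g <- state$grid[[e]] * 0
      g[inf_cells[[q]]] <- g[inf_cells[[q]]] + rate_at(inf_rate[[q]], t) * dt
      d$grid[[e]] <- g
    }
    d
  }
  getf <- function(state, s) {
    f <- state$grid[[s]]
    if (is.null(f)) stop("grid field missing for entity '", s, "'")
    if (is.null(idx)) as.vector(f) else f[idx]
  }
  # accumulate masked per-species vectors; materialise matrices once
  acc_new <- function() new.env(parent = emptyenv())
  acc_add <- function(acc, e, vals) {
    cur <- acc[[e]]
    acc[[e]] <- if (is.null(cur)) vals else cur + vals
  }
  acc_delta <- function(acc, state) {
    d <- delta_zero()
    for (e in ls(acc)) {
      g <- state$grid[[e]] * 0
      if (is.null(idx)) g[] <- acc[[e]] else g[idx] <- acc[[e]]
      d$grid[[e]] <- g
    }
    d
  }
  rate_fn <- function(sim, state) {
    acc <- acc_new()
    for (r in cmp$rx) {
      v <- r$k
      for (s in r$slots) v <- v * getf(state, s)
      for (e in names(r$net)) acc_add(acc, e, r$net[[e]] * v)
    }
    add_influx(acc_delta(acc, state), state, sim$t, 1)
  }
  embedded_fn <- function(sim, state, dt) {
    a1 <- acc_new(); a2 <- acc_new()
    relmax <- 0
    atol <- sim$controller$atol
    for (r in cmp$rx) {
      v1 <- r$k
      for (s in r$slots) v1 <- v1 * getf(state, s)
      v2 <- r$k
      for (s in r$slots) {
        nu <- if (s %in% names(r$net)) r$net[[s]] else 0
        v2 <- v2 * (getf(state, s) + (dt / 2) * nu * v1)
      }
      num <- abs(v1 - v2) * (dt * r$numax)
      den <- pmax(abs(v2) * (dt * r$numax), atol)
      nz <- num > 0
      if (any(nz)) relmax <- max(relmax, num[nz] / den[nz])
      for (e in names(r$net)) {
        acc_add(a1, e, r$net[[e]] * v1 * dt)
        acc_add(a2, e, r$net[[e]] * v2 * dt)
      }
    }
    d1 <- add_influx(acc_delta(a1, state), state, sim$t, dt)
    d2 <- add_influx(acc_delta(a2, state), state, sim$t + dt / 2, dt)
    for (q in seq_along(influx)) {
      f1 <- rate_at(inf_rate[[q]], sim$t) * dt
      f2 <- rate_at(inf_rate[[q]], sim$t + dt / 2) * dt
      if (f1 != f2) relmax <- max(relmax, abs(f1 - f2) / max(abs(f2), atol))
    }
    list(d1 = d1, d2 = d2, rel = relmax)
  }
  conc_module(name, rate_fn, embedded = embedded_fn)
}

#' Bundled single-cell network module (fully vectorised)
#'
#' Per-reaction embedded pairs for a network running in one grid cell of a
#' 1x1 (well-mixed) space, computed with indexed vector arithmetic and a
#' stoichiometry-matrix multiply. Semantically identical to the per-reaction
#' module list. Zeroth-order influx terms (possibly time-scheduled) may be
#' folded into the bundle; their first-order delta evaluates the schedule at
#' t and the midpoint delta at t + dt/2.
#'
#' @param net A `reaction_network`.
#' @param influx Optional list of `list(entity =, rate =)` zeroth-order
#'   sources; `rate` is uM/s or a `function(t)`.
#' @param name Module name.
#' @return A `conc_module`.
#' @export
mod_network_cell <- function(net, influx = list(), name = "reactions") {
  cmp <- compile_network(net)
  species <- cmp$species
  nr <- length(cmp$rx)
  k <- vapply(cmp$rx, `[[`, numeric(1), "k")
  i1 <- integer(nr); i2 <- integer(nr)
  nu1 <- numeric(nr); nu2 <- numeric(nr)
  numax <- vapply(cmp$rx, `[[`, numeric(1), "numax")
  for (j in seq_len(nr)) {
    sl <- cmp$rx[[j]]$slots
    i1[j] <- match(sl[1L], species)
    nu <- cmp$rx[[j]]$net
    nu1[j] <- if (sl[1L] %in% names(nu)) nu[[sl[1L]]] else 0
    if (length(sl) > 1L) {
      i2[j] <- match(sl[2L], species)
      nu2[j] <- if (sl[2L] %in% names(nu)) nu[[sl[2L]]] else 0
    }
  }
  has2 <- i2 > 0L
  S <- matrix(0, length(species), nr, dimnames = list(species, NULL))
  for (j in seq_len(nr)) S[names(cmp$rx[[j]]$net), j] <- cmp$rx[[j]]$net
  inf_idx <- vapply(influx, function(x) match(x$entity, species), integer(1))
  if (anyNA(inf_idx)) stop("influx entity not part of the network")
  inf_rate <- lapply(influx, `[[`, "rate")
  inf_at <- function(t) {
    vapply(inf_rate, function(r) if (is.function(r)) r(t) else r, numeric(1))
  }
  touched <- rowSums(S != 0) > 0
  touched[inf_idx] <- TRUE
  tsp <- species[touched]
  St <- S[touched, , drop = FALSE]
  ti <- match(species[inf_idx], tsp)
  getc <- function(state) unlist(state$grid[species], use.names = FALSE)
  as_delta <- function(vals) {
    d <- delta_zero()
    d$grid <- stats::setNames(as.list(vals), tsp)
    d
  }
  rate_fn <- function(sim, state) {
    cc <- getc(state)
    x2 <- rep(1, nr); x2[has2] <- cc[i2[has2]]
    tot <- as.vector(St %*% (k * cc[i1] * x2))
    if (length(ti)) tot[ti] <- tot[ti] + inf_at(sim$t)
    as_delta(tot)
  }
  embedded_fn <- function(sim, state, dt) {
    cc <- getc(state)
    x2 <- rep(1, nr); x2[has2] <- cc[i2[has2]]
    v1 <- k * cc[i1] * x2
    h1 <- cc[i1] + (dt / 2) * nu1 * v1
    h2 <- rep(1, nr); h2[has2] <- cc[i2[has2]] + (dt / 2) * nu2[has2] * v1[has2]
    v2 <- k * h1 * h2
    num <- abs(v1 - v2) * dt * numax
    den <- pmax(abs(v2) * dt * numax, sim$controller$atol)
    rel <- max(c(0, ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))))
    t1 <- as.vector(St %*% (v1 * dt))
    t2 <- as.vector(St %*% (v2 * dt))
    if (length(ti)) {
      f1 <- inf_at(sim$t) * dt
      f2 <- inf_at(sim$t + dt / 2) * dt
      t1[ti] <- t1[ti] + f1
      t2[ti] <- t2[ti] + f2
      rel <- max(rel, ifelse(f2 == 0 & f1 == 0, 0,
                             abs(f1 - f2) / pmax(abs(f2), sim$controller$atol)))
    }
    list(d1 = as_delta(t1), d2 = as_delta(t2), rel = rel)
  }
  conc_module(name, rate_fn, embedded = embedded_fn)
}

#' Bundled interface network module (vectorised)
#'
#' Vectorised equivalent of [mod_network_interface()]: membrane-bound species
#' live as densities on the surface compartment, soluble species are sampled
#' from and deposited into the coupled grid cells. Per-reaction embedded
#' pairs and worst-case error as with individual modules.
#'
#' @param net A `reaction_network`.
#' @param comp_id Surface compartment id (e.g. `"mem:apical"`).
#' @param cells,weights Coupled grid cells and weights.
#' @param area Interface area (um^2).
#' @param name Module name.
#' @return A `conc_module`.
#' @export
mod_network_interface_fast <- function(net, comp_id, cells, weights = NULL,
                                       area, name = NULL) {
  cmp <- compile_network(net)
  cells <- as.matrix(cells)
  if (is.null(weights)) weights <- rep(1 / nrow(cells), nrow(cells))
  weights <- weights / sum(weights)
  if (is.null(name)) name <- paste0("reactions:", comp_id)
  species <- cmp$species
  surf <- species %in% cmp$surface
  nr <- length(cmp$rx)
  k <- vapply(cmp$rx, `[[`, numeric(1), "k")
  i1 <- integer(nr); i2 <- integer(nr); nu1 <- numeric(nr); nu2 <- numeric(nr)
  numax <- vapply(cmp$rx, `[[`, numeric(1), "numax")
  for (j in seq_len(nr)) {
    sl <- cmp$rx[[j]]$slots
    i1[j] <- match(sl[1L], species)
    nu <- cmp$rx[[j]]$net
    nu1[j] <- if (sl[1L] %in% names(nu)) nu[[sl[1L]]] else 0
    if (length(sl) > 1L) {
      i2[j] <- match(sl[2L], species)
      nu2[j] <- if (sl[2L] %in% names(nu)) nu[[sl[2L]]] else 0
    }
  }
  has2 <- i2 > 0L
  S <- matrix(0, length(species), nr, dimnames = list(species, NULL))
  for (j in seq_len(nr)) S[names(cmp$rx[[j]]$net), j] <- cmp$rx[[j]]$net
  surf_names <- species[surf]
  vol_names <- species[!surf]
  getz <- function(state) {
    z <- numeric(length(species))
    sc <- state$comp[[comp_id]]
    sv <- sc[surf_names]
    sv[is.na(sv)] <- 0
    z[surf] <- sv
    for (e in vol_names) {
      z[match(e, species)] <- sum(state$grid[[e]][cells] * weights)
    }
    z
  }
  to_delta <- function(state, tot, vol_cell) {
    d <- delta_zero()
    sv <- tot[surf]
    if (any(sv != 0)) d$comp[[comp_id]] <- stats::setNames(sv, surf_names)[sv != 0]
    for (e in vol_names[tot[!surf] != 0]) {
      g <- state$grid[[e]] * 0
      g[cells] <- tot[match(e, species)] * area * weights / vol_cell
      d$grid[[e]] <- g
    }
    d
  }
  rate_fn <- function(sim, state) {
    vol_cell <- point_volume(sim$space)
    z <- getz(state)
    x2 <- rep(1, nr); x2[has2] <- z[i2[has2]]
    to_delta(state, as.vector(S %*% (k * z[i1] * x2)), vol_cell)
  }
  embedded_fn <- function(sim, state, dt) {
    vol_cell <- point_volume(sim$space)
    fac <- ifelse(surf, 1, area * sum(weights^2) / vol_cell)
    z <- getz(state)
    x2 <- rep(1, nr); x2[has2] <- z[i2[has2]]
    v1 <- k * z[i1] * x2
    h1 <- z[i1] + (dt / 2) * nu1 * v1 * fac[i1]
    h2 <- rep(1, nr); h2[has2] <- z[i2[has2]] + (dt / 2) * nu2[has2] * v1[has2] * fac[i2[has2]]
    v2 <- k * h1 * h2
    num <- abs(v1 - v2) * dt * numax
    den <- pmax(abs(v2) * dt * numax, sim$controller$atol)
    rel <- max(c(0, ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))))
    list(d1 = to_delta(state, as.vector(S %*% (v1 * dt)), vol_cell),
         d2 = to_delta(state, as.vector(S %*% (v2 * dt)), vol_cell),
         rel = rel)
  }
  conc_module(name, rate_fn, embedded = embedded_fn)
}

#' Bundled vesicle network module (vectorised)
#'
#' Runs a generated network in the membrane compartment of every vesicle in
#' the applicable states. Membrane-bound species live on the vesicle
#' membrane as per-area densities; soluble species are sampled from and
#' deposited into the grid cells the vesicle is associated with, weighted by
#' its surface-area fractions. Per-reaction embedded pairs as elsewhere; the
#' reported error is the maximum over vesicles and reactions.
#'
#' @param net A `reaction_network`.
#' @param states Vesicle states the network applies in (`NULL` = all).
#' @param name Module name.
#' @return A `conc_module`.
#' @export
mod_network_vesicle_fast <- function(net, states = NULL, name = "ves-reactions") {
  cmp <- compile_network(net)
  species <- cmp$species
  surf <- species %in% cmp$surface
  nr <- length(cmp$rx)
  k <- vapply(cmp$rx, `[[`, numeric(1), "k")
  i1 <- integer(nr); i2 <- integer(nr); nu1 <- numeric(nr); nu2 <- numeric(nr)
  numax <- vapply(cmp$rx, `[[`, numeric(1), "numax")
  for (j in seq_len(nr)) {
    sl <- cmp$rx[[j]]$slots
    i1[j] <- match(sl[1L], species)
    nu <- cmp$rx[[j]]$net
    nu1[j] <- if (sl[1L] %in% names(nu)) nu[[sl[1L]]] else 0
    if (length(sl) > 1L) {
      i2[j] <- match(sl[2L], species)
      nu2[j] <- if (sl[2L] %in% names(nu)) nu[[sl[2L]]] else 0
    }
  }
  has2 <- i2 > 0L
  S <- matrix(0, length(species), nr, dimnames = list(species, NULL))
  for (j in seq_len(nr)) S[names(cmp$rx[[j]]$net), j] <- cmp$rx[[j]]$net
  surf_names <- species[surf]
  vol_names <- species[!surf]
  eval_ves <- function(sim, state, dt, want_err) {
    vol_cell <- point_volume(sim$space)
    d <- delta_zero()
    relmax <- 0
    for (ves in sim$ves) {
      if (!is.null(states) && !(ves$state %in% states)) next
      cid <- paste0("ves:", ves$id, ":membrane")
      sc <- state$comp[[cid]]
      if (is.null(sc)) next
      cells <- ves$assoc$cells; w <- ves$assoc$fractions
      z <- numeric(length(species))
      sv <- sc[surf_names]; sv[is.na(sv)] <- 0
      z[surf] <- sv
      for (e in vol_names) z[match(e, species)] <- sum(state$grid[[e]][cells] * w)
      x2 <- rep(1, nr); x2[has2] <- z[i2[has2]]
      v1 <- k * z[i1] * x2
      v <- v1
      if (want_err) {
        fac <- ifelse(surf, 1, ves$area * sum(w^2) / vol_cell)
        h1 <- z[i1] + (dt / 2) * nu1 * v1 * fac[i1]
        h2 <- rep(1, nr)
        h2[has2] <- z[i2[has2]] + (dt / 2) * nu2[has2] * v1[has2] * fac[i2[has2]]
        v2 <- k * h1 * h2
        num <- abs(v1 - v2) * (dt * numax)
        den <- pmax(abs(v2) * (dt * numax), sim$controller$atol)
        nz <- num > 0
        if (any(nz)) relmax <- max(relmax, num[nz] / den[nz])
        v <- v2  # the midpoint rate produces d2; d1 handled by caller
      }
      tot <- as.vector(S %*% v)
      sv2 <- tot[surf]
      if (any(sv2 != 0)) {
        cv <- d$comp[[cid]]
        if (is.null(cv)) cv <- numeric(0)
        add <- stats::setNames(sv2, surf_names)[sv2 != 0]
        for (e in names(add)) cv[e] <- (if (e %in% names(cv)) cv[[e]] else 0) + add[[e]]
        d$comp[[cid]] <- cv
      }
      vt <- tot[!surf]
      for (q in which(vt != 0)) {
        e <- vol_names[q]
        g <- d$grid[[e]]
        if (is.null(g)) g <- state$grid[[e]] * 0
        g[cells] <- g[cells] + vt[q] * ves$area * w / vol_cell
        d$grid[[e]] <- g
      }
    }
    list(d = d, rel = relmax)
  }
  rate_fn <- function(sim, state) eval_ves(sim, state, 1, FALSE)$d
  embedded_fn <- function(sim, state, dt) {
    r1 <- eval_ves(sim, state, dt, FALSE)
    r2 <- eval_ves(sim, state, dt, TRUE)
    list(d1 = d_scale(r1$d, dt), d2 = d_scale(r2$d, dt), rel = r2$rel)
  }
  conc_module(name, rate_fn, embedded = embedded_fn)
}
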