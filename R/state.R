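# Concentration state and delta algebra.
#
# A state holds every concentration pool of the simulation:
#   grid : named list entity -> (n_rows x n_cols) matrix of uM concentrations
#   comp : named list compartment-id -> named numeric vector; surface
#          compartments ("mem:<id>") store per-area densities (uM um),
#          vesicle/pit compartments ("ves:<id>:membrane", "ves:<id>:cargo",
#          "pit:<id>:cargo") store densities (uM um) or concentrations (uM).
# Deltas have the same shape but may be sparse (only touched pools present).

new_state <- function(grid = list(), comp = list()) {
  list(grid = grid, comp = comp)
}

delta_zero <- function() list(grid = list(), comp = list())

d_is_empty <- function(d) !length(d$grid) && !length(d$comp)

d_add <- function(a, b) {
  for (e in names(b$grid)) {
    a$grid[[e]] <- if (is.null(a$grid[[e]])) b$grid[[e]] else a$grid[[e]] + b$grid[[e]]
  }
  for (id in names(b$comp)) {
    if (is.null(a$comp[[id]])) { a$comp[[id]] <- b$comp[[id]]; next }
    v <- a$comp[[id]]
    for (e in names(b$comp[[id]])) {
      v[e] <- (if (e %in% names(v)) v[[e]] else 0) + b$comp[[id]][[e]]
    }
    a$comp[[id]] <- v
  }
  a
}

d_scale <- function(d, s) {
  d$grid <- lapply(d$grid, `*`, s)
  d$comp <- lapply(d$comp, `*`, s)
  d
}

state_apply <- function(state, d) {
  for (e in names(d$grid)) {
    if (is.null(state$grid[[e]]))
      stop("delta references unknown grid entity '", e, "'")
    state$grid[[e]] <- state$grid[[e]] + d$grid[[e]]
  }
  for (id in names(d$comp)) {
    if (is.null(state$comp[[id]]))
      stop("delta references unknown compartment '", id, "'")
    v <- state$comp[[id]]
    for (e in names(d$comp[[id]])) {
      v[e] <- (if (e %in% names(v)) v[[e]] else 0) + d$comp[[id]][[e]]
    }
    state$comp[[id]] <- v
  }
  state
}

# smallest value that applying d to state would produce (negativity check)
state_min_after <- function(state, d) {
  lo <- Inf
  for (e in names(d$grid)) lo <- min(lo, min(state$grid[[e]] + d$grid[[e]]))
  for (id in names(d$comp)) {
    v <- state$comp[[id]]
    for (e in names(d$comp[[id]])) {
      cur <- if (e %in% names(v)) v[[e]] else 0
      lo <- min(lo, cur + d$comp[[id]][[e]])
    }
  }
  lo
}

# zero out negative numerical dust (values in (-tol, 0)) left by accepted
# midpoint updates; genuine negativity is rejected before application.
state_clamp_dust <- function(state, tol) {
  for (e in names(state$grid)) {
    g <- state$grid[[e]]
    bad <- g < 0 & g > -tol
    if (any(bad)) { g[bad] <- 0; state$grid[[e]] <- g }
  }
  for (id in names(state$comp)) {
    v <- state$comp[[id]]
    bad <- v < 0 & v > -tol
    if (any(bad)) { v[bad] <- 0; state$comp[[id]] <- v }
  }
  state
}

# maximum linear relative deviation |d1 - d2| / max(|d2|, atol) over all
# pools. Both zero -> 0 (perfect agreement); d2 zero with d1 nonzero -> Inf
# unless the deviation is below the absolute floor atol (per-step deltas
# smaller than atol are numerically negligible; without the floor a pool
# sitting exactly at zero pins the relative error at order one for every dt).
rel_err_vals <- function(x1, x2, atol = 0) {
  num <- abs(x1 - x2)
  den <- pmax(abs(x2), atol)
  out <- ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den))
  max(out, 0)
}

d_rel_err <- function(d1, d2, atol = 0) {
  worst <- 0
  for (e in union(names(d1$grid), names(d2$grid))) {
    a <- d1$grid[[e]]; b <- d2$grid[[e]]
    if (is.null(a)) a <- 0 * b
    if (is.null(b)) b <- 0 * a
    worst <- max(worst, rel_err_vals(a, b, atol))
  }
  for (id in union(names(d1$comp), names(d2$comp))) {
    a <- d1$comp[[id]]; b <- d2$comp[[id]]
    es <- union(names(a), names(b))
    av <- ifelse(es %in% names(a), a[es], 0)
    bv <- ifelse(es %in% names(b), b[es], 0)
    if (length(es)) worst <- max(worst, rel_err_vals(av, bv, atol))
  }
  worst
}

# maximum deviation |d1 - d2| normalised by the pool's (scaffold)
# concentration, floored by atol: the entity-level total error compares the
# full-step and scaffold-based results relative to the concentration scale,
# so pools whose net delta nearly cancels are not pinned at order-one error.
d_rel_err_state <- function(d1, d2, state, atol = 0) {
  worst <- 0
  for (e in union(names(d1$grid), names(d2$grid))) {
    a <- d1$grid[[e]]; b <- d2$grid[[e]]
    if (is.null(a)) a <- 0 * b
    if (is.null(b)) b <- 0 * a
    den <- pmax(abs(state$grid[[e]]), atol)
    worst <- max(worst, abs(a - b) / den)
  }
  for (id in union(names(d1$comp), names(d2$comp))) {
    a <- d1$comp[[id]]; b <- d2$comp[[id]]
    es <- union(names(a), names(b))
    if (!length(es)) next
    av <- ifelse(es %in% names(a), a[es], 0)
    bv <- ifelse(es %in% names(b), b[es], 0)
    sv <- state$comp[[id]]
    dv <- pmax(abs(ifelse(es %in% names(sv), sv[es], 0)), atol)
    worst <- max(worst, abs(av - bv) / dv)
  }
  worst
}

# per-module local error with a mixed denominator: |d1 - d2| relative to
# max(|d2|, eta * |c|, atol). At grid points where a transport operator's
# net flux nearly cancels (e.g. a symmetric diffusion stencil), |d2| tends to
# zero while the curvature term does not, and a purely delta-relative error
# would pin the time step; deltas below the fraction eta of the local
# concentration are therefore controlled in absolute terms instead.
d_rel_err_mixed <- function(d1, d2, state, eta = 0, atol = 0) {
  worst <- 0
  for (e in union(names(d1$grid), names(d2$grid))) {
    a <- d1$grid[[e]]; b <- d2$grid[[e]]
    if (is.null(a)) a <- 0 * b
    if (is.null(b)) b <- 0 * a
    den <- pmax(abs(b), eta * abs(state$grid[[e]]), atol)
    num <- abs(a - b)
    worst <- max(worst, ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den)), 0)
  }
  for (id in union(names(d1$comp), names(d2$comp))) {
    a <- d1$comp[[id]]; b <- d2$comp[[id]]
    es <- union(names(a), names(b))
    if (!length(es)) next
    av <- ifelse(es %in% names(a), a[es], 0)
    bv <- ifelse(es %in% names(b), b[es], 0)
    sv <- state$comp[[id]]
    cv <- abs(ifelse(es %in% names(sv), sv[es], 0))
    den <- pmax(abs(bv), eta * cv, atol)
    num <- abs(av - bv)
    worst <- max(worst, ifelse(num == 0, 0, ifelse(den == 0, Inf, num / den)), 0)
  }
  worst
}

# total amount of an entity over every pool it occurs in (uM um^3);
# grid pools convert concentration via the per-point volume, surface and
# vesicle/pit pools are stored per compartment with their own capacity kept in
# sim (areas/volumes), so callers pass a capacity lookup.
state_total_amount <- function(state, entity, grid_volume, comp_capacity) {
  tot <- 0
  g <- state$grid[[entity]]
  if (!is.null(g)) tot <- tot + sum(g) * grid_volume
  for (id in names(state$comp)) {
    v <- state$comp[[id]]
    if (entity %in% names(v)) tot <- tot + v[[entity]] * comp_capacity(id)
  }
  tot
}
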