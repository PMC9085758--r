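# Sphere-like (vesicle), line-like (filament) agents, spatial indexing and
# collision handling.

#' Add a vesicle to a simulation
#'
#' A vesicle is a sphere-like agent with a continuous position (um), a radius
#' `r < ds` (required by the grid indexing), a state symbol, and two
#' compartments: `membrane` (per-area densities, uM um, capacity = sphere
#' surface area) and `cargo` (concentrations, uM, capacity = sphere volume).
#'
#' @param sim A [simulation()].
#' @param x,y Position (um); x runs along columns, y along rows (top-left
#'   origin).
#' @param radius Radius (um), must be `< ds`.
#' @param state State symbol (e.g. `"unattached"`, `"actin_attached"`,
#'   `"tethered"`, `"in_storage"`).
#' @param membrane,cargo Named numeric initial contents.
#' @param id Integer id; auto-assigned when `NULL`.
#' @return The vesicle id, invisibly.
#' @export
add_vesicle <- function(sim, x, y, radius, state = "unattached",
                        membrane = numeric(), cargo = numeric(), id = NULL) {
  if (radius >= sim$space$ds)
    stop("vesicle radius (", radius, ") must be smaller than the grid spacing ds (",
         sim$space$ds, ")")
  if (is.null(id)) { id <- sim$next_ves_id; sim$next_ves_id <- id + 1L }
  area <- 4 * pi * radius^2
  vol <- 4 / 3 * pi * radius^3
  ves <- list(id = id, x = x, y = y, r = radius, state = state,
              area = area, cargo_volume = vol,
              assoc = index_vesicle(sim$space, x, y, radius),
              filament = NULL, arc = NULL, boost_dir = NULL)
  sim$ves[[as.character(id)]] <- ves
  sim$state$comp[[paste0("ves:", id, ":membrane")]] <- membrane
  sim$state$comp[[paste0("ves:", id, ":cargo")]] <- cargo
  sim$comp_meta[[paste0("ves:", id, ":membrane")]] <- list(kind = "vesicle_membrane", capacity = area)
  sim$comp_meta[[paste0("ves:", id, ":cargo")]] <- list(kind = "vesicle_cargo", capacity = vol)
  invisible(id)
}

remove_vesicle <- function(sim, id) {
  key <- as.character(id)
  sim$ves[[key]] <- NULL
  sim$state$comp[[paste0("ves:", id, ":membrane")]] <- NULL
  sim$state$comp[[paste0("ves:", id, ":cargo")]] <- NULL
  sim$comp_meta[[paste0("ves:", id, ":membrane")]] <- NULL
  sim$comp_meta[[paste0("ves:", id, ":cargo")]] <- NULL
  invisible(sim)
}

#' Associate a vesicle with grid cells by perimeter overlap
#'
#' The fraction of the vesicle's membrane assigned to each grid cell is
#' proportional to the arc length of its circumference lying in that cell:
#' the circle is cut at its intersections with the grid lines within reach
#' (at most two vertical and two horizontal for `r < ds`), and each arc is
#' assigned to the cell containing its midpoint. Fractions sum to 1.
#'
#' @param space A [simulation_space()].
#' @param x,y Centre position (um).
#' @param r Radius (um), `< ds`.
#' @return List with `cells` (k x 2 matrix of 1-based `(i, j)`) and
#'   `fractions` (numeric, sums to 1).
#' @export
index_vesicle <- function(space, x, y, r) {
  ds <- space$ds
  cuts <- numeric()
  for (k in seq_len(space$n_cols - 1L)) {
    dx <- k * ds - x
    if (abs(dx) < r) {
      a <- acos(dx / r)
      cuts <- c(cuts, a, 2 * pi - a)
    }
  }
  for (k in seq_len(space$n_rows - 1L)) {
    dy <- k * ds - y
    if (abs(dy) < r) {
      a <- asin(dy / r)
      cuts <- c(cuts, a %% (2 * pi), (pi - a) %% (2 * pi))
    }
  }
  cell_of <- function(px, py) {
    c(min(max(floor(py / ds) + 1, 1), space$n_rows),
      min(max(floor(px / ds) + 1, 1), space$n_cols))
  }
  if (!length(cuts)) {
    return(list(cells = matrix(cell_of(x, y), 1L), fractions = 1))
  }
  cuts <- sort(unique(cuts))
  acc <- list()
  nseg <- length(cuts)
  for (s in seq_len(nseg)) {
    a0 <- cuts[s]
    a1 <- if (s < nseg) cuts[s + 1L] else cuts[1L] + 2 * pi
    mid <- (a0 + a1) / 2
    frac <- (a1 - a0) / (2 * pi)
    cl <- cell_of(x + r * cos(mid), y + r * sin(mid))
    key <- paste(cl, collapse = ",")
    acc[[key]] <- list(cell = cl, frac = (acc[[key]]$frac %||% 0) + frac)
  }
  list(cells = do.call(rbind, lapply(acc, `[[`, "cell")),
       fractions = vapply(acc, `[[`, numeric(1), "frac"))
}

reindex_vesicles <- function(sim) {
  for (key in names(sim$ves)) {
    v <- sim$ves[[key]]
    sim$ves[[key]]$assoc <- index_vesicle(sim$space, v$x, v$y, v$r)
  }
  invisible(sim)
}

# blocked membrane faces as line segments (x1, y1, x2, y2), cached on sim
face_segments <- function(space) {
  ds <- space$ds
  segs <- matrix(numeric(), 0L, 4L)
  vv <- which(space$vblock, arr.ind = TRUE)
  if (nrow(vv)) segs <- rbind(segs, cbind(vv[, 2L] * ds, (vv[, 1L] - 1) * ds,
                                          vv[, 2L] * ds, vv[, 1L] * ds))
  hh <- which(space$hblock, arr.ind = TRUE)
  if (nrow(hh)) segs <- rbind(segs, cbind((hh[, 2L] - 1) * ds, hh[, 1L] * ds,
                                          hh[, 2L] * ds, hh[, 1L] * ds))
  segs
}

# does segment p -> q cross any of the segments (vectorised orientation test)?
crosses_any <- function(p, q, segs) {
  if (!nrow(segs)) return(FALSE)
  o <- function(ax, ay, bx, by, cx, cy) sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- o(p[1], p[2], q[1], q[2], segs[, 1], segs[, 2])
  d2 <- o(p[1], p[2], q[1], q[2], segs[, 3], segs[, 4])
  d3 <- o(segs[, 1], segs[, 2], segs[, 3], segs[, 4], p[1], p[2])
  d4 <- o(segs[, 1], segs[, 2], segs[, 3], segs[, 4], q[1], q[2])
  # a face endpoint lying exactly on the path still blocks it (membrane
  # faces join end-to-end; paths through the joints must not slip through)
  any(d1 * d2 <= 0 & d3 * d4 < 0)
}

#' Resolve a proposed vesicle displacement (discard policy)
#'
#' The proposal is discarded — the vesicle keeps its old position — if the
#' move would overlap another vesicle (centre distance below the radius sum),
#' if the centre path crosses a membrane face, or if it crosses the boundary
#' of a barrier [volume_region()]. Otherwise the proposal is accepted.
#'
#' @param sim A [simulation()].
#' @param ves A vesicle record from `sim$ves`.
#' @param proposal Numeric `(x, y)` proposed position.
#' @param positions Optional matrix of other vesicles' current positions and
#'   radii (columns `x`, `y`, `r`); defaults to all other vesicles.
#' @return Accepted `(x, y)` position.
#' @export
resolve_displacement <- function(sim, ves, proposal, positions = NULL) {
  if (is.null(positions)) {
    others <- Filter(function(v) v$id != ves$id, sim$ves)
    positions <- if (length(others))
      cbind(x = vapply(others, `[[`, numeric(1), "x"),
            y = vapply(others, `[[`, numeric(1), "y"),
            r = vapply(others, `[[`, numeric(1), "r"))
    else matrix(numeric(), 0L, 3L)
  }
  old <- c(ves$x, ves$y)
  if (nrow(positions)) {
    dd <- sqrt((positions[, 1] - proposal[1])^2 + (positions[, 2] - proposal[2])^2)
    if (any(dd < positions[, 3] + ves$r)) return(old)
  }
  if (is.null(sim$face_seg_step) || sim$face_seg_step != sim$step) {
    sim$face_seg <- face_segments(sim$space)
    sim$face_seg_step <- sim$step
  }
  if (crosses_any(old, proposal, sim$face_seg)) return(old)
  for (rg in sim$regions) {
    if (isTRUE(rg$barrier %||% FALSE) &&
        region_contains(rg, old) != region_contains(rg, proposal)) return(old)
  }
  # domain boundary: discard moves leaving the simulated area
  ds <- sim$space$ds
  if (proposal[1] < ves$r || proposal[1] > sim$space$n_cols * ds - ves$r ||
      proposal[2] < ves$r || proposal[2] > sim$space$n_rows * ds - ves$r) return(old)
  proposal
}

#' Displacement-based time-step control
#'
#' `D(a) = log10(||dp_total|| / d_ref)` per agent; request a decrease when any
#' `D(a) > theta_plus`, an increase when all `D(a) < theta_minus`, otherwise
#' stay neutral. Stationary agents (`D = -Inf`) vote for an increase.
#'
#' @param norms Euclidean norms of the per-agent total displacements (um).
#' @param d_ref Reference distance (um, `> 0`).
#' @param theta_plus,theta_minus Log10 thresholds.
#' @return `"decrease"`, `"increase"` or `"neutral"`.
#' @export
displacement_control <- function(norms, d_ref, theta_plus = 0, theta_minus = -1) {
  stopifnot(d_ref > 0)
  if (!length(norms)) return("increase")
  D <- log10(norms / d_ref)
  if (any(D > theta_plus)) return("decrease")
  if (all(D < theta_minus)) return("increase")
  "neutral"
}

# gather proposals from all displacement modules; returns per-vesicle sums
compute_displacements <- function(sim, dt) {
  ids <- names(sim$ves)
  dx <- stats::setNames(numeric(length(ids)), ids)
  dy <- dx
  for (m in sim$disp_modules) {
    prop <- m$fn(sim, dt)
    for (id in names(prop)) {
      dx[id] <- dx[id] + prop[[id]][1]
      dy[id] <- dy[id] + prop[[id]][2]
    }
  }
  list(ids = ids, dx = dx, dy = dy, norms = sqrt(dx^2 + dy^2))
}

# apply summed displacements in deterministic id order with discard policy
apply_displacements <- function(sim, props) {
  if (!length(props$ids)) return(invisible(sim))
  ord <- props$ids[order(as.integer(props$ids))]
  for (id in ord) {
    if (props$norms[[id]] == 0) next
    ves <- sim$ves[[id]]
    prop <- c(ves$x + props$dx[[id]], ves$y + props$dy[[id]])
    acc <- resolve_displacement(sim, ves, prop)
    sim$ves[[id]]$x <- acc[1]
    sim$ves[[id]]$y <- acc[2]
  }
  invisible(sim)
}

#' Create a displacement module
#'
#' @param name Module name.
#' @param fn Function `(sim, dt) -> named list id -> c(dx, dy)` of proposed
#'   displacements (um).
#' @return A `disp_module`.
#' @export
disp_module <- function(name, fn) {
  structure(list(name = name, fn = fn), class = "disp_module")
}

#' Create a qualitative module
#'
#' Qualitative modules run after a step is accepted and may change agent
#' states, spawn or retire agents, and log events. A module may supply
#' `f_max(sim)`, the largest event frequency it uses, so the controller can
#' keep `f * dt <= 1`.
#'
#' @param name Module name.
#' @param apply Function `(sim, dt)` run after each accepted step.
#' @param f_max Optional function `(sim) -> numeric(1)`.
#' @return A `qual_module`.
#' @export
qual_module <- function(name, apply, f_max = NULL) {
  structure(list(name = name, apply = apply, f_max = f_max),
            class = "qual_module")
}

#' Declare a cytoskeletal filament
#'
#' Line-like agent: an ordered polyline with a minus end (first vertex) and a
#' plus end (last vertex) indicating direction for motor transport.
#'
#' @param positions Two-column matrix of vertices (um).
#' @param name Filament name.
#' @param type Filament type, e.g. `"actin"` or `"microtubule"`.
#' @return A `filament` object.
#' @export
filament <- function(positions, name = "filament", type = "actin") {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2L, nrow(positions) >= 2L)
  seg <- diff(positions)
  len <- sqrt(rowSums(seg^2))
  if (any(len <= 0)) stop("filament has zero-length segments")
  structure(list(name = name, type = type, positions = positions,
                 seg_len = len, cum_len = c(0, cumsum(len)),
                 total_len = sum(len)),
            class = "filament")
}

# point on the filament at arc-length s (clamped)
filament_point <- function(fl, s) {
  s <- min(max(s, 0), fl$total_len)
  k <- findInterval(s, fl$cum_len, rightmost.closed = TRUE)
  k <- min(k, length(fl$seg_len))
  frac <- (s - fl$cum_len[k]) / fl$seg_len[k]
  fl$positions[k, ] + frac * (fl$positions[k + 1L, ] - fl$positions[k, ])
}

# nearest point on the filament to p: returns list(dist, s)
filament_nearest <- function(fl, p) {
  best <- list(dist = Inf, s = 0)
  for (k in seq_along(fl$seg_len)) {
    a <- fl$positions[k, ]; b <- fl$positions[k + 1L, ]
    ab <- b - a
    tt <- min(max(sum((p - a) * ab) / sum(ab^2), 0), 1)
    q <- a + tt * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best$dist) best <- list(dist = d, s = fl$cum_len[k] + tt * fl$seg_len[k])
  }
  best
}

#' Generate a filament by persistent random-walk growth
#'
#' Simplified growth model used to initialise cytoskeletal tracks: starting
#' from a nucleation point, segments of length `step` grow with direction
#' persistence `kappa` biased toward `target`, stopping after `n_steps` or on
#' reaching the target's vicinity.
#'
#' @param from Nucleation point (um).
#' @param target Target point (um); the plus end grows toward it.
#' @param step Segment length (um).
#' @param n_steps Maximum number of segments.
#' @param wobble Standard deviation of the per-segment heading noise (rad).
#' @param name,type See [filament()].
#' @return A `filament`.
#' @export
grow_filament <- function(from, target, step = 0.25, n_steps = 200L,
                          wobble = 0.15, name = "filament", type = "actin") {
  pos <- matrix(from, 1L)
  p <- from
  heading <- atan2(target[2] - from[2], target[1] - from[1])
  for (k in seq_len(n_steps)) {
    goal <- atan2(target[2] - p[2], target[1] - p[1])
    heading <- heading + 0.5 * (goal - heading) + stats::rnorm(1L, 0, wobble)
    p <- p + step * c(cos(heading), sin(heading))
    pos <- rbind(pos, p)
    if (sqrt(sum((p - target)^2)) < step) break
  }
  filament(pos, name = name, type = type)
}
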