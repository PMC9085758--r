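#' Error-controller parameters
#'
#' Thresholds are `log10` of relative errors: `tau_local = log10(0.05)` caps
#' the accepted per-step local truncation error of every module at 5%. With
#' tolerance `theta_local` the time step is increased when every module's
#' relative error is below `theta_local * 10^tau_local` (0.5 * 5% = 2.5%).
#' The total (entity-level) error uses `tau_total`/`theta_total` analogously.
#' `nu` is the negligibility threshold on the *linear* relative total error
#' below which total-error evaluation is skipped (default `10^tau_total /
#' 10000`), re-armed after any step increase or after `total_backup_every`
#' steps. Displacement control uses `d_ref` (default `ds/4`, set at
#' simulation build time) with log10 thresholds `theta_disp_plus` /
#' `theta_disp_minus`.
#'
#' @param tau_local,theta_local Local error threshold (log10) and tolerance.
#' @param tau_total,theta_total Total error threshold (log10) and tolerance.
#' @param nu Linear negligibility threshold for total-error skipping.
#' @param atol Absolute per-step delta floor: deltas smaller than this (uM,
#'   or uM um on surfaces) never register as relative error, which keeps
#'   pools sitting at exactly zero from pinning the error at order one.
#' @param eta Delta significance fraction: per-step deltas smaller than
#'   `eta` times the local concentration are error-controlled in absolute
#'   rather than relative terms (rescues transport stencils at points where
#'   the net flux cancels).
#' @param dt_init,dt_min,dt_max Initial/minimum/maximum time step (s).
#' @param increase,decrease Step scaling factors.
#' @param total_backup_every Backup total-error re-evaluation period (steps).
#' @param d_ref Displacement reference distance (um); `NULL` = `ds/4`.
#' @param theta_disp_plus,theta_disp_minus Displacement thresholds (log10).
#' @return An `error_controller` object.
#' @export
error_controller <- function(tau_local = log10(0.05), theta_local = 0.5,
                             tau_total = log10(0.05), theta_total = 0.5,
                             nu = NULL, atol = 1e-9, eta = 0.01,
                             dt_init = 1e-3, dt_min = 1e-12, dt_max = Inf,
                             increase = 1.4, decrease = 0.5,
                             total_backup_every = 100L,
                             d_ref = NULL,
                             theta_disp_plus = 0, theta_disp_minus = -1) {
  if (is.null(nu)) nu <- 10^tau_total / 1e4
  stopifnot(theta_local > 0, theta_local < 1, dt_init > 0, nu < 10^tau_total)
  structure(list(tau_local = tau_local, theta_local = theta_local,
                 tau_total = tau_total, theta_total = theta_total, nu = nu,
                 atol = atol, eta = eta,
                 dt_init = dt_init, dt_min = dt_min, dt_max = dt_max,
                 increase = increase, decrease = decrease,
                 total_backup_every = as.integer(total_backup_every),
                 d_ref = d_ref,
                 theta_disp_plus = theta_disp_plus,
                 theta_disp_minus = theta_disp_minus),
            class = "error_controller")
}

#' Embedded Euler/midpoint step
#'
#' The first-order delta is the Euler step `d1 = dt * f(c)`; the second-order
#' delta evaluates the rate at the half-step predictor,
#' `d2 = dt * f(c + d1/2)`. The accepted update uses `d2`; `d1` exists to
#' estimate the local truncation error at no extra function evaluation.
#'
#' @param state A concentration state (see the methods vignette) or any
#'   object `rhs` accepts.
#' @param rhs Function `(state) -> delta` per unit time.
#' @param dt Time step (s).
#' @param apply Function `(state, delta) -> state` (defaults to the internal
#'   state algebra).
#' @param scale Function `(delta, s) -> delta`.
#' @return List with elements `d1` and `d2`.
#' @export
midpoint_step <- function(state, rhs, dt, apply = state_apply, scale = d_scale) {
  d1 <- scale(rhs(state), dt)
  half <- apply(state, scale(d1, 0.5))
  d2 <- scale(rhs(half), dt)
  list(d1 = d1, d2 = d2)
}

#' Local truncation error of an embedded step
#'
#' `eps = log10(|d1 - d2| / |d2|)`, maximised over every entity and grid
#' point the module touches. Both deltas zero gives `-Inf` (perfect);
#' `d2 = 0` with `d1 != 0` gives `+Inf`, forcing a step decrease.
#'
#' @param d1,d2 First-order and midpoint delta sets (or plain numerics).
#' @return Scalar log10 relative error.
#' @export
local_error <- function(d1, d2) {
  if (is.numeric(d1) && is.numeric(d2)) {
    return(log10(rel_err_vals(d1, d2)))
  }
  log10(d_rel_err(d1, d2))
}

#' Build a simulation
#'
#' Assembles the space, initial concentration fields, agents and update
#' modules into a mutable simulation object (an environment). Membrane agents
#' block diffusion across their faces. All randomness is drawn from named
#' substreams derived from `seed`.
#'
#' @param space A [simulation_space()].
#' @param grid_init Named list entity -> initial concentration (scalar uM or
#'   full matrix).
#' @param membranes List of [surface_agent()]s; each may carry `cells`
#'   (coupled interior cells) used by interface reactions.
#' @param modules List of `conc_module`s.
#' @param disp_modules List of displacement modules.
#' @param qual_modules List of qualitative modules.
#' @param regions List of [volume_region()]s.
#' @param filaments List of [filament()]s.
#' @param controller An [error_controller()].
#' @param seed Integer run seed (mandatory once any stochastic module is
#'   present).
#' @return A `simulation` environment.
#' @export
simulation <- function(space, grid_init = list(), membranes = list(),
                       modules = list(), disp_modules = list(),
                       qual_modules = list(), regions = list(),
                       filaments = list(),
                       controller = error_controller(), seed = 1L) {
  sim <- new.env(parent = emptyenv())
  sim$space <- space
  for (mb in membranes) sim$space <- block_faces(sim$space, mb$faces)
  grid <- lapply(grid_init, function(v) {
    if (is.matrix(v)) v else matrix(v, space$n_rows, space$n_cols)
  })
  comp <- list()
  meta <- list()
  sim$membranes <- list()
  for (mb in membranes) {
    id <- paste0("mem:", mb$descriptor)
    comp[[id]] <- mb$conc
    meta[[id]] <- list(kind = "surface", capacity = mb$area)
    sim$membranes[[mb$descriptor]] <- mb
  }
  sim$state <- new_state(grid, comp)
  sim$comp_meta <- meta
  sim$modules <- modules
  sim$disp_modules <- disp_modules
  sim$qual_modules <- qual_modules
  sim$regions <- regions
  sim$filaments <- filaments
  sim$ves <- list()
  sim$pits <- list()
  sim$controller <- controller
  if (is.null(controller$d_ref)) sim$controller$d_ref <- space$ds / 4
  sim$t <- 0
  sim$dt <- controller$dt_init
  sim$step <- 0L
  sim$next_ves_id <- 1L
  sim$next_pit_id <- 1L
  sim$mm_warnings <- list()
  sim$events <- list()
  sim$diag_n <- 0L
  sim$diag_cap <- 1024L
  sim$diag_step <- integer(1024L)
  sim$diag_t <- numeric(1024L)
  sim$diag_dt <- numeric(1024L)
  sim$diag_eps_local <- numeric(1024L)
  sim$diag_worst <- character(1024L)
  sim$diag_eps_total <- numeric(1024L)
  sim$rng <- list()
  sim$seed <- as.integer(seed)
  class(sim) <- c("simulation", "environment")
  sim
}

#' @export
print.simulation <- function(x, ...) {
  cat("<simulation> t = ", signif(x$t, 6), " s, dt = ", signif(x$dt, 4),
      ", ", length(x$modules), " conc / ", length(x$disp_modules), " disp / ",
      length(x$qual_modules), " qual modules, ", length(x$ves),
      " vesicles\n", sep = "")
  invisible(x)
}

# --- named RNG substreams ---------------------------------------------------
# Each named stream owns an independent .Random.seed, derived once from the
# run seed and the stream name, so modules can be toggled without perturbing
# each other's draws.
with_rng <- function(sim, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  if (is.null(sim$rng[[name]])) {
    offset <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
    set.seed((sim$seed + offset * 1009L) %% .Machine$integer.max)
    sim$rng[[name]] <- get(".Random.seed", globalenv())
  }
  assign(".Random.seed", sim$rng[[name]], globalenv())
  on.exit({
    sim$rng[[name]] <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  eval.parent(substitute(expr))
}

# --- module evaluation ------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# embedded Euler/midpoint pair for one module
eval_one_module <- function(m, sim, state, dt) {
  if (!is.null(m$embedded)) return(m$embedded(sim, state, dt))
  d1 <- d_scale(m$rate(sim, state), dt)
  half <- state_apply(state, d_scale(d1, 0.5))
  d2 <- d_scale(m$rate(sim, half), dt)
  list(d1 = d1, d2 = d2,
       rel = d_rel_err_mixed(d1, d2, state, sim$controller$eta,
                             sim$controller$atol))
}

# evaluate all concentration modules at dt; returns deltas and errors
eval_all_modules <- function(sim, state, dt) {
  res <- lapply(sim$modules, eval_one_module, sim = sim, state = state, dt = dt)
  names(res) <- vapply(sim$modules, `[[`, character(1), "name")
  res
}

#' Adapt the time step from module errors
#'
#' Pure decision rule: reject (retry at a decreased step) when any module's
#' local error exceeds `tau_local`; accept-and-increase when every module's
#' *linear* relative error is below `theta_local * 10^tau_local`; plain
#' accept otherwise.
#'
#' @param module_errors Numeric vector of per-module log10 local errors.
#' @param controller An [error_controller()].
#' @return One of `"retry"`, `"accept_and_increase"`, `"accept"`.
#' @export
adapt_timestep <- function(module_errors, controller) {
  if (length(module_errors) && any(module_errors > controller$tau_local))
    return("retry")
  if (!length(module_errors) ||
      all(10^module_errors < controller$theta_local * 10^controller$tau_local))
    return("accept_and_increase")
  "accept"
}

#' Run a simulation for a duration under the adaptive controller
#'
#' Executes the accept/retry/increase loop: per-module local errors first
#' (the interrupting module drives step decreases on its own until it
#' passes, then all modules rerun), then the negativity check on the summed
#' update, then the entity-level total error with negligibility skipping,
#' then displacement control, collision resolution (discard policy) and the
#' qualitative modules.
#'
#' @param sim A [simulation()].
#' @param duration Simulated time to advance (s).
#' @param record_every Observer recording interval (s); `NULL` records only
#'   the initial and final states.
#' @param observer Function `(sim) -> named numeric` of observables.
#' @return `sim`, invisibly (the trace is in `sim$trace`, diagnostics in
#'   `sim$diag`).
#' @export
run_simulation <- function(sim, duration, record_every = NULL, observer = NULL) {
  ctl <- sim$controller
  t_end <- sim$t + duration
  if (is.null(sim$trace)) sim$trace <- list()
  record <- function() {
    if (is.null(observer)) return(invisible())
    sim$trace[[length(sim$trace) + 1L]] <- c(time = sim$t, observer(sim))
  }
  if (sim$step == 0L) record()
  if (is.null(sim$rej)) sim$rej <- c(local = 0L, negativity = 0L,
                                     total = 0L, displacement = 0L)
  next_rec <- if (is.null(record_every)) Inf else sim$t + record_every
  total_due <- TRUE
  steps_since_total <- 0L
  while (sim$t < t_end - 1e-12) {
    dt <- min(sim$dt, t_end - sim$t, next_rec - sim$t + 1e-15, ctl$dt_max)
    # chance-frequency cap: p = f*dt must stay <= 1
    fmax <- 0
    for (q in sim$qual_modules) if (!is.null(q$f_max)) fmax <- max(fmax, q$f_max(sim))
    while (fmax * dt > 1) dt <- dt * ctl$decrease
    increase_vote <- FALSE
    repeat {
      if (dt < ctl$dt_min)
        stop("time step underflow (dt = ", dt, ") at t = ", sim$t,
             "; critical module: ", sim$last_critical %||% "unknown")
      res <- eval_all_modules(sim, sim$state, dt)
      rels <- vapply(res, `[[`, numeric(1), "rel")
      rels[is.na(rels)] <- Inf  # non-finite deltas force a step decrease
      eps <- log10(rels)
      if (length(eps) && any(eps > ctl$tau_local)) {
        sim$rej[["local"]] <- sim$rej[["local"]] + 1L
        # the interrupting module keeps requesting decreases until it passes
        worst <- which.max(eps)
        sim$last_critical <- names(res)[worst]
        mod <- sim$modules[[worst]]
        repeat {
          dt <- dt * ctl$decrease
          if (dt < ctl$dt_min)
            stop("time step underflow while optimising module '",
                 names(res)[worst], "' at t = ", sim$t)
          one <- eval_one_module(mod, sim, sim$state, dt)
          if (!is.na(one$rel) && log10(one$rel) <= ctl$tau_local) break
        }
        next  # rerun all modules at the new dt
      }
      dtotal <- net_delta(lapply(res, `[[`, "d2"))
      if (!d_is_empty(dtotal) && state_min_after(sim$state, dtotal) < -ctl$atol) {
        sim$last_critical <- "negativity"
        sim$rej[["negativity"]] <- sim$rej[["negativity"]] + 1L
        dt <- dt * ctl$decrease
        next
      }
      # entity-level total error with negligibility skipping. The scaffold
      # state c + Dtotal/2 is used to recompute the total delta (a midpoint
      # of the whole coupled system); that recomputed delta produces the
      # accepted step, and its deviation from the summed per-module deltas
      # is the total error, measured on the concentration scale.
      eps_total <- NA_real_
      if (length(res) && (total_due || steps_since_total >= ctl$total_backup_every)) {
        scaffold <- state_apply(sim$state, d_scale(dtotal, 0.5))
        dmid <- delta_zero()
        for (m in sim$modules) dmid <- d_add(dmid, d_scale(m$rate(sim, scaffold), dt))
        rel_tot <- d_rel_err_state(dtotal, dmid, scaffold, ctl$atol)
        eps_total <- log10(rel_tot)
        if (eps_total > ctl$tau_total) {
          sim$last_critical <- "total_error"
          sim$rej[["total"]] <- sim$rej[["total"]] + 1L
          dt <- dt * ctl$decrease
          next
        }
        if (state_min_after(sim$state, dmid) < -ctl$atol) {
          sim$last_critical <- "negativity"
          dt <- dt * ctl$decrease
          next
        }
        dtotal <- dmid
        total_due <- rel_tot >= ctl$nu
        steps_since_total <- 0L
      } else steps_since_total <- steps_since_total + 1L
      # displacement proposals under the same candidate dt
      props <- compute_displacements(sim, dt)
      if (length(props$norms)) {
        Dv <- log10(props$norms / ctl$d_ref)
        if (any(Dv > ctl$theta_disp_plus)) {
          sim$last_critical <- "displacement"
          sim$rej[["displacement"]] <- sim$rej[["displacement"]] + 1L
          dt <- dt * ctl$decrease
          next
        }
        disp_increase <- all(Dv < ctl$theta_disp_minus)
      } else disp_increase <- TRUE
      increase_vote <- adapt_timestep(eps, ctl) == "accept_and_increase" && disp_increase
      break
    }
    # ---- accept ----
    if (!d_is_empty(dtotal)) {
      sim$state <- state_clamp_dust(state_apply(sim$state, dtotal), ctl$atol)
    }
    apply_displacements(sim, props)
    if (length(sim$ves)) reindex_vesicles(sim)
    for (q in sim$qual_modules) q$apply(sim, dt)
    if (length(sim$ves)) reindex_vesicles(sim)
    sim$t <- sim$t + dt
    sim$step <- sim$step + 1L
    if (sim$diag_n >= sim$diag_cap) {
      sim$diag_cap <- sim$diag_cap * 2L
      length(sim$diag_step) <- sim$diag_cap
      length(sim$diag_t) <- sim$diag_cap
      length(sim$diag_dt) <- sim$diag_cap
      length(sim$diag_eps_local) <- sim$diag_cap
      length(sim$diag_worst) <- sim$diag_cap
      length(sim$diag_eps_total) <- sim$diag_cap
    }
    i <- sim$diag_n + 1L
    sim$diag_step[i] <- sim$step
    sim$diag_t[i] <- sim$t
    sim$diag_dt[i] <- dt
    if (length(res)) {
      rv <- vapply(res, `[[`, numeric(1), "rel")
      sim$diag_eps_local[i] <- log10(max(rv))
      sim$diag_worst[i] <- names(res)[which.max(rv)]
    } else {
      sim$diag_eps_local[i] <- -Inf
      sim$diag_worst[i] <- ""
    }
    sim$diag_eps_total[i] <- eps_total
    sim$diag_n <- i
    if (sim$t >= next_rec - 1e-12) {
      record()
      next_rec <- next_rec + record_every
    }
    sim$dt <- dt
    if (increase_vote) {
      newdt <- min(dt * ctl$increase, ctl$dt_max)
      if (newdt > dt) total_due <- TRUE  # skip re-arms after a step increase
      sim$dt <- newdt
    }
  }
  if (is.null(record_every)) record()
  invisible(sim)
}

#' Per-step controller diagnostics as a tibble
#'
#' @param sim A run [simulation()].
#' @return Tibble with step, time, dt, worst module and log10 errors.
#' @export
diagnostics <- function(sim) {
  n <- sim$diag_n %||% 0L
  ix <- seq_len(n)
  tibble::tibble(step = sim$diag_step[ix], t = sim$diag_t[ix],
                 dt = sim$diag_dt[ix], eps_local = sim$diag_eps_local[ix],
                 worst_module = sim$diag_worst[ix],
                 eps_total = sim$diag_eps_total[ix])
}

#' Recorded observable trace as a tibble
#'
#' @param sim A run [simulation()].
#' @return Tibble with a `time` column plus one column per observable.
#' @export
trace_tbl <- function(sim) {
  if (!length(sim$trace)) return(tibble::tibble(time = numeric()))
  tibble::as_tibble(do.call(rbind, sim$trace))
}

#' Total amount of an entity across every pool of a simulation
#'
#' Grid fields contribute concentration times per-point volume; surface,
#' vesicle and pit compartments contribute their density times capacity
#' (area or volume). Used by the conservation property tests.
#'
#' @param sim A [simulation()].
#' @param entity Entity (formula) name.
#' @return Amount in uM um^3.
#' @export
sim_total_amount <- function(sim, entity) {
  cap <- function(id) {
    mt <- sim$comp_meta[[id]]
    if (is.null(mt)) stop("unknown compartment ", id)
    mt$capacity
  }
  state_total_amount(sim$state, entity, point_volume(sim$space), cap)
}
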