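#' Diffusion delta on a restricted grid
#'
#' Explicit five-point stencil for Fick's second law with per-point
#' restriction coefficients and zero-flux boundaries:
#' `dc_ij = (D dt / ds^2) * sum_nb r_nb * (c_nb - c_ij)` over the four
#' neighbours, where each neighbour term uses the *neighbour* cell's
#' restriction coefficient, exactly as the discretisation is defined (not a
#' symmetric face mean — with spatially varying `r` the exchange is
#' asymmetric; see the methods vignette). Points with `r = 0` form the
#' non-diffusible set: their flux is zero in both directions, so a fully
#' restricted region exchanges nothing. Neighbour terms are dropped across
#' membrane faces and across the domain boundary (zero flux everywhere on
#' the boundary).
#'
#' @param field Concentration matrix (uM).
#' @param D Diffusion coefficient (um^2/s), `>= 0`.
#' @param dt Time step (s).
#' @param space A [simulation_space()] (supplies `ds`, restriction
#'   coefficients and membrane faces).
#' @return Delta matrix, same shape as `field`.
#' @export
diffusion_delta <- function(field, D, dt, space) {
  stopifnot(D >= 0, all(dim(field) == c(space$n_rows, space$n_cols)))
  r <- space$r
  n <- space$n_rows; m <- space$n_cols
  out <- matrix(0, n, m)
  if (m > 1L) {
    open <- !space$vblock
    # exchange across vertical faces between (i,j) and (i,j+1)
    dR <- r[, -1L, drop = FALSE] * (field[, -1L, drop = FALSE] - field[, -m, drop = FALSE]) * open
    dL <- r[, -m, drop = FALSE] * (field[, -m, drop = FALSE] - field[, -1L, drop = FALSE]) * open
    out[, -m] <- out[, -m] + dR
    out[, -1L] <- out[, -1L] + dL
  }
  if (n > 1L) {
    open <- !space$hblock
    dD <- r[-1L, , drop = FALSE] * (field[-1L, , drop = FALSE] - field[-n, , drop = FALSE]) * open
    dU <- r[-n, , drop = FALSE] * (field[-n, , drop = FALSE] - field[-1L, , drop = FALSE]) * open
    out[-n, ] <- out[-n, ] + dD
    out[-1L, ] <- out[-1L, ] + dU
  }
  out[r == 0] <- 0  # non-diffusible points: zero flux in both directions
  out * (D * dt / space$ds^2)
}

#' Mass-action delta for a single well-mixed compartment
#'
#' Irreversible: `v = k * prod(c(substrates)^order)`. Reversible:
#' `v = k1 * prod(c(substrates)) - k_rev * prod(c(products))`, so that
#' `v(A) = -v(B)` holds exactly for an A <-> B pair. Deltas are scaled by
#' stoichiometry and `dt`.
#'
#' @param substrates,products Named integer vectors of stoichiometric
#'   coefficients.
#' @param conc Named numeric vector of concentrations (uM).
#' @param k Forward rate constant (units set by the reaction order).
#' @param k_rev Backward rate constant, or `NULL` for an irreversible
#'   reaction.
#' @param dt Time step (s).
#' @return Named numeric vector of concentration deltas (uM).
#' @export
mass_action_delta <- function(substrates, products, conc, k, k_rev = NULL,
                              dt = 1) {
  miss <- setdiff(c(names(substrates), names(products)), names(conc))
  if (length(miss)) stop("concentrations missing for: ", paste(miss, collapse = ", "))
  v <- k * prod(conc[names(substrates)]^substrates)
  if (!is.null(k_rev)) v <- v - k_rev * prod(conc[names(products)]^products)
  d <- numeric(0)
  for (e in names(substrates)) d[e] <- -substrates[[e]] * v * dt
  for (e in names(products)) d[e] <- (if (e %in% names(d)) d[[e]] else 0) +
      products[[e]] * v * dt
  d
}

#' Michaelis-Menten rate with validity diagnostic
#'
#' `v = k_cat * c(E) * c(A) / (k_m + c(A))`. The quasi-steady-state treatment
#' is only valid when `c(E)0 / (c(A)0 + k_m) << 1`; a warning flag is raised
#' when the ratio reaches `validity_threshold` (default 0.1).
#'
#' @param cE,cA Enzyme and substrate concentrations (uM).
#' @param k_cat Turnover number (1/s).
#' @param k_m Saturation (Michaelis) constant (uM), `> 0`.
#' @param dt Time step (s).
#' @param validity_threshold Ratio above which the validity flag is raised.
#' @return List with `rate` (uM/s), `delta` (uM, product formed over `dt`),
#'   `validity_ratio` and logical `valid`.
#' @export
michaelis_menten_delta <- function(cE, cA, k_cat, k_m, dt = 1,
                                   validity_threshold = 0.1) {
  stopifnot(k_m > 0)
  v <- k_cat * cE * cA / (k_m + cA)
  ratio <- cE / (cA + k_m)
  list(rate = v, delta = v * dt, validity_ratio = ratio,
       valid = ratio < validity_threshold)
}

#' Net concentration delta across modules
#'
#' Sums the per-module deltas per (compartment, entity). No clamping is
#' applied: if the summed update would drive any concentration negative the
#' integrator rejects the step instead.
#'
#' @param deltas List of delta sets (as produced by module evaluation).
#' @return A single merged delta set.
#' @export
net_delta <- function(deltas) {
  out <- delta_zero()
  for (d in deltas) out <- d_add(out, d)
  out
}
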