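#' Reactor constructors
#'
#' Reaction rules are chains of basic reactors. Four reactors exist:
#' \describe{
#'   \item{BIND}{joins two available complexes A and B with a new bond.}
#'   \item{ADD}{attaches a component B to A; only A is consumed as a
#'     reactant (B is drawn from an implicit pool, e.g. phosphate from ATP).}
#'   \item{REMOVE}{deletes a leaf component B from A-B; B is not a product.}
#'   \item{RELEASE}{splits A-B at a bond into the two products A and B.
#'     RELEASE terminates a chain.}
#' }
#'
#' The binding site may be named explicitly; if `site = NULL` it is
#' auto-assigned when exactly one declared site matches the operand entity
#' pair, and ambiguity is an error.
#'
#' @param a,b Simple entity names anchoring the bond (the node in the
#'   candidate complex, and the partner node or added/removed component).
#' @param site Binding site name, or `NULL` for auto-assignment.
#' @return A `reactor` object.
#' @name reactors
NULL

new_reactor <- function(kind, a, b, site) {
  structure(list(kind = kind, a = a, b = b, site = site), class = "reactor")
}

#' @rdname reactors
#' @export
rx_bind <- function(a, b, site = NULL) new_reactor("bind", a, b, site)

#' @rdname reactors
#' @export
rx_add <- function(b, to, site = NULL) new_reactor("add", to, b, site)

#' @rdname reactors
#' @export
rx_remove <- function(b, from, site = NULL) new_reactor("remove", from, b, site)

#' @rdname reactors
#' @export
rx_release <- function(a, b, site = NULL) new_reactor("release", a, b, site)

#' @export
print.reactor <- function(x, ...) {
  cat("<reactor> ", toupper(x$kind), " ", x$b, " ~ ", x$a,
      if (!is.null(x$site)) paste0(" @", x$site), "\n", sep = "")
  invisible(x)
}

# resolve the binding site for a reactor against the model; auto-assignment
# uses the unique declared site matching the unordered operand pair
resolve_site <- function(model, reactor) {
  if (!is.null(reactor$site)) {
    s <- model$sites[[reactor$site]]
    if (is.null(s)) stop("rule references undeclared site '", reactor$site, "'")
    ok <- (s$from == reactor$a && s$to == reactor$b) ||
      (s$from == reactor$b && s$to == reactor$a)
    if (!ok) stop("site '", reactor$site, "' does not join (",
                  reactor$a, ", ", reactor$b, ")")
    return(s$name)
  }
  hits <- Filter(function(s) (s$from == reactor$a && s$to == reactor$b) ||
                   (s$from == reactor$b && s$to == reactor$a), model$sites)
  if (length(hits) == 0L)
    stop("no declared binding site for pair (", reactor$a, ", ", reactor$b, ")")
  if (length(hits) > 1L)
    stop("ambiguous binding site for pair (", reactor$a, ", ", reactor$b,
         "); declare the site explicitly")
  hits[[1L]]$name
}

#' Rule condition predicates
#'
#' Conditions restrict which candidate complexes a reactor may act on. The
#' closed predicate set covers presence/absence of a component, occupancy of a
#' site, and component counts; new predicate types can be registered with
#' [register_condition_type()].
#'
#' @param part Simple entity name.
#' @param site Binding site name.
#' @param n Required occurrence count.
#' @param role Which operand the condition applies to: `"a"` (first/primary
#'   candidate), `"b"` (the BIND partner), or `"any"`.
#' @return A `rule_condition` object.
#' @name conditions
NULL

new_condition <- function(type, role, ...) {
  structure(list(type = type, role = role, params = list(...)),
            class = "rule_condition")
}

#' @rdname conditions
#' @export
cond_has_part <- function(part, role = "a") new_condition("has_part", role, part = part)

#' @rdname conditions
#' @export
cond_lacks_part <- function(part, role = "a") new_condition("lacks_part", role, part = part)

#' @rdname conditions
#' @export
cond_site_free <- function(site, role = "a") new_condition("site_free", role, site = site)

#' @rdname conditions
#' @export
cond_site_occupied <- function(site, role = "a") new_condition("site_occupied", role, site = site)

#' @rdname conditions
#' @export
cond_count_part <- function(part, n, role = "a") new_condition("count_part", role, part = part, n = n)

condition_registry <- new.env(parent = emptyenv())

#' Register a new condition type
#'
#' @param type Type name used by the condition object.
#' @param fn Function `(complex, model, params) -> logical(1)`.
#' @export
register_condition_type <- function(type, fn) {
  stopifnot(is.character(type), is.function(fn))
  assign(type, fn, envir = condition_registry)
  invisible(type)
}

register_condition_type("has_part", function(x, model, p) p$part %in% x$nodes)
register_condition_type("lacks_part", function(x, model, p) !(p$part %in% x$nodes))
register_condition_type("site_free", function(x, model, p) {
  !any(x$edges$site == p$site)
})
register_condition_type("site_occupied", function(x, model, p) {
  any(x$edges$site == p$site)
})
register_condition_type("count_part", function(x, model, p) {
  sum(x$nodes == p$part) == p$n
})

check_conditions <- function(conditions, role, x, model) {
  for (cnd in conditions) {
    if (!(cnd$role == role || cnd$role == "any")) next
    fn <- get0(cnd$type, envir = condition_registry)
    if (is.null(fn)) stop("unknown condition type '", cnd$type, "'")
    if (!isTRUE(fn(x, model, cnd$params))) return(FALSE)
  }
  TRUE
}

#' Define a reaction rule
#'
#' A rule is an ordered chain of reactors plus conditions restricting the
#' candidate reactants, and the rate parameters assigned to every elementary
#' reaction the rule generates. RELEASE, if present, must terminate the chain.
#'
#' @param name Rule name (used in provenance tracks and diagnostics).
#' @param reactors A single reactor or list of reactors (see [reactors]).
#' @param conditions List of [conditions] predicates.
#' @param k Rate constant for generated reactions. Units depend on the order
#'   of the generated reaction (s^-1 first order, uM^-1 s^-1 second order).
#' @return A `reaction_rule` object.
#' @export
reaction_rule <- function(name, reactors, conditions = list(), k) {
  if (inherits(reactors, "reactor")) reactors <- list(reactors)
  stopifnot(length(reactors) >= 1L, is.numeric(k), k >= 0)
  kinds <- vapply(reactors, `[[`, character(1), "kind")
  rel <- which(kinds == "release")
  if (length(rel) && max(rel) != length(reactors))
    stop("RELEASE terminates a chain; rule '", name, "' continues after it")
  if (inherits(conditions, "rule_condition")) conditions <- list(conditions)
  structure(list(name = name, reactors = reactors, conditions = conditions,
                 k = k),
            class = "reaction_rule")
}

#' Apply a single reactor to candidate complexes
#'
#' Enumerates every distinct application of `reactor` to the candidates,
#' honouring implicit filters (site availability, small-molecule valence) and
#' the explicit rule `conditions`. Distinctness is up to graph isomorphism of
#' the products.
#'
#' @param model An [entity_model()].
#' @param reactor A reactor (see [reactors]).
#' @param candidates List of `complex_entity` candidates. BIND draws its two
#'   reactants from this pool; ADD/REMOVE/RELEASE act on each candidate.
#' @param conditions List of [conditions] predicates (roles `"a"`/`"b"`).
#' @return List of matches; each match is a list with elements `substrates`
#'   (list of complexes consumed), `products` (list of complexes produced) and
#'   `track` (lineage of canonical labels, substrates first).
#' @export
apply_reactor <- function(model, reactor, candidates, conditions = list()) {
  site <- resolve_site(model, reactor)
  out <- list()
  seen <- character()
  push <- function(substrates, products, track) {
    key <- paste(c(sort(vapply(substrates, entity_label, character(1))), "->",
                   sort(vapply(products, entity_label, character(1)))),
                 collapse = " ")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- list(substrates = substrates,
                                     products = products, track = track)
  }
  if (reactor$kind == "bind") {
    as <- Filter(function(x) length(free_nodes(model, x, reactor$a, site)) > 0 &&
                   check_conditions(conditions, "a", x, model), candidates)
    bs <- Filter(function(x) length(free_nodes(model, x, reactor$b, site)) > 0 &&
                   check_conditions(conditions, "b", x, model), candidates)
    for (A in as) for (B in bs) {
      for (ia in free_nodes(model, A, reactor$a, site)) {
        for (ib in free_nodes(model, B, reactor$b, site)) {
          nodes <- c(A$nodes, B$nodes)
          edges <- rbind(A$edges,
                         within(B$edges, { from <- from + length(A$nodes)
                                           to <- to + length(A$nodes) }),
                         data.frame(from = ia, to = ib + length(A$nodes),
                                    site = site, stringsAsFactors = FALSE))
          prod <- try(complex_entity(model, nodes, edges), silent = TRUE)
          if (inherits(prod, "try-error")) next
          push(list(A, B), list(prod),
               c(entity_label(A), entity_label(B), entity_label(prod)))
        }
      }
    }
  } else if (reactor$kind == "add") {
    for (A in candidates) {
      if (!check_conditions(conditions, "a", A, model)) next
      for (ia in free_nodes(model, A, reactor$a, site)) {
        nodes <- c(A$nodes, reactor$b)
        edges <- rbind(A$edges,
                       data.frame(from = ia, to = length(nodes),
                                  site = site, stringsAsFactors = FALSE))
        prod <- try(complex_entity(model, nodes, edges), silent = TRUE)
        if (inherits(prod, "try-error")) next
        push(list(A), list(prod), c(entity_label(A), entity_label(prod)))
      }
    }
  } else if (reactor$kind == "remove") {
    for (A in candidates) {
      if (!check_conditions(conditions, "a", A, model)) next
      deg <- tabulate(c(A$edges$from, A$edges$to), nbins = length(A$nodes))
      es <- which(A$edges$site == site)
      for (ei in es) {
        ends <- c(A$edges$from[ei], A$edges$to[ei])
        bn <- ends[A$nodes[ends] == reactor$b & deg[ends] == 1L]
        for (ib in bn) {
          keep <- setdiff(seq_along(A$nodes), ib)
          remap <- integer(length(A$nodes)); remap[keep] <- seq_along(keep)
          e2 <- A$edges[-ei, , drop = FALSE]
          e2$from <- remap[e2$from]; e2$to <- remap[e2$to]
          prod <- try(complex_entity(model, A$nodes[keep], e2), silent = TRUE)
          if (inherits(prod, "try-error")) next
          push(list(A), list(prod), c(entity_label(A), entity_label(prod)))
        }
      }
    }
  } else if (reactor$kind == "release") {
    for (A in candidates) {
      if (!check_conditions(conditions, "a", A, model)) next
      es <- which(A$edges$site == site)
      for (ei in es) {
        e2 <- A$edges[-ei, , drop = FALSE]
        comp <- split_components(length(A$nodes), e2)
        if (max(comp) != 2L) next  # bond is not a bridge
        halves <- lapply(1:2, function(ci) {
          keep <- which(comp == ci)
          remap <- integer(length(A$nodes)); remap[keep] <- seq_along(keep)
          e3 <- e2[comp[e2$from] == ci, , drop = FALSE]
          e3$from <- remap[e3$from]; e3$to <- remap[e3$to]
          complex_entity(model, A$nodes[keep], e3)
        })
        push(list(A), halves,
             c(entity_label(A), vapply(halves, entity_label, character(1))))
      }
    }
  } else stop("unknown reactor kind: ", reactor$kind)
  out
}

# connected components of nodes 1..n given an edge data frame
split_components <- function(n, edges) {
  comp <- integer(n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cid <- cid + 1L
    frontier <- start; comp[start] <- cid
    while (length(frontier)) {
      nb <- c(edges$to[edges$from %in% frontier], edges$from[edges$to %in% frontier])
      nb <- unique(nb[comp[nb] == 0L])
      comp[nb] <- cid
      frontier <- nb
    }
  }
  comp
}

# apply a full reactor chain; returns list of complete reactions
apply_rule <- function(model, rule, candidates) {
  first <- rule$reactors[[1L]]
  matches <- apply_reactor(model, first, candidates, rule$conditions)
  for (j in seq_along(rule$reactors)[-1L]) {
    rxr <- rule$reactors[[j]]
    nxt <- list()
    for (m in matches) {
      # subsequent reactors act on the single current intermediate product
      if (length(m$products) != 1L)
        stop("rule '", rule$name, "': reactor follows a RELEASE")
      sub <- apply_reactor(model, rxr, m$products, rule$conditions)
      for (s in sub) {
        nxt[[length(nxt) + 1L]] <- list(
          substrates = m$substrates,
          products = s$products,
          track = c(m$track, s$track[-1L]))
      }
    }
    matches <- nxt
  }
  matches
}
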