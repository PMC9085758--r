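#' Generate the reaction network implied by a set of rules
#'
#' Iterates rule application over a growing pool of candidate entities until a
#' fixpoint is reached: the products of each generated reaction are added to
#' the candidate pool for the next pass. Entities are deduplicated by their
#' canonical graph label and reactions by their (substrates, products, rate
#' law) signature. Products larger than `max_complex_size` simple-entity
#' occurrences are discarded, which keeps unbounded polymerisation out of the
#' network; if the pool still grows after `max_iter` passes the generation
#' aborts naming the offending rule.
#'
#' @param model An [entity_model()].
#' @param rules List of [reaction_rule()] objects.
#' @param seeds List of `complex_entity` seed entities.
#' @param max_complex_size Cap on product size (simple-entity occurrences).
#' @param max_iter Fixpoint iteration cap.
#' @return An object of class `reaction_network` with elements `model`,
#'   `entities` (named by canonical label), `reactions` and `rules`.
#' @export
generate_network <- function(model, rules, seeds, max_complex_size = 16L,
                             max_iter = 50L) {
  if (inherits(rules, "reaction_rule")) rules <- list(rules)
  if (inherits(seeds, "complex_entity")) seeds <- list(seeds)
  stopifnot(length(seeds) >= 1L)
  if (max_complex_size < max(vapply(seeds, complex_size, integer(1))))
    stop("max_complex_size is smaller than the largest seed complex")
  pool <- list()
  for (s in seeds) pool[[entity_label(s)]] <- s
  reactions <- list()
  rkeys <- character()
  iter <- 0L
  last_rule <- NULL
  repeat {
    iter <- iter + 1L
    grew <- FALSE
    for (rule in rules) {
      matches <- apply_rule(model, rule, unname(pool))
      for (m in matches) {
        if (any(vapply(m$products, complex_size, integer(1)) > max_complex_size))
          next
        slab <- sort(vapply(m$substrates, entity_label, character(1)))
        plab <- sort(vapply(m$products, entity_label, character(1)))
        key <- paste(paste(slab, collapse = "+"), "->",
                     paste(plab, collapse = "+"), "|k=", rule$k)
        if (key %in% rkeys) next
        rkeys <- c(rkeys, key)
        reactions[[length(reactions) + 1L]] <- structure(
          list(rule = rule$name,
               substrates = vapply(m$substrates, entity_label, character(1)),
               products = vapply(m$products, entity_label, character(1)),
               law = list(kind = "mass_action", k = rule$k),
               track = m$track),
          class = "network_reaction")
        for (p in m$products) {
          lab <- entity_label(p)
          if (is.null(pool[[lab]])) { pool[[lab]] <- p; grew <- TRUE; last_rule <- rule$name }
        }
      }
    }
    if (!grew) break
    if (iter >= max_iter)
      stop("network generation did not reach a fixpoint within ", max_iter,
           " iterations; last growing rule: '", last_rule,
           "' (unbounded polymerisation?)")
  }
  structure(list(model = model, entities = pool, reactions = reactions,
                 rules = rules),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$entities), " entities, ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Unique species names of a network
#'
#' Human-readable formulas, uniquified where distinct binding topologies
#' share a formula (isomers get `#1`, `#2`, ... suffixes). These names key
#' the concentration fields and observables everywhere.
#'
#' @param net A `reaction_network`.
#' @return Character vector named by canonical entity label.
#' @export
species_names <- function(net) {
  fml <- vapply(net$entities, entity_formula, character(1))
  stats::setNames(make.unique(unname(fml), sep = "#"), names(net$entities))
}

#' Tidy a reaction network into a flat reaction table
#'
#' One row per elementary reaction with human-readable substrate and product
#' formulas, the rate law, constants, and the generating rule — the flat
#' export format for inspection and CSV round-tripping.
#'
#' @param x A `reaction_network`.
#' @param ... Unused.
#' @return A tibble with columns `reaction`, `substrates`, `products`, `law`,
#'   `k`, `rule`.
#' @exportS3Method generics::tidy
#' @export
tidy.reaction_network <- function(x, ...) {
  nm <- species_names(x)
  fml <- function(labs) paste(nm[labs], collapse = " + ")
  tibble::tibble(
    reaction = seq_along(x$reactions),
    substrates = vapply(x$reactions, function(r) fml(r$substrates), character(1)),
    products = vapply(x$reactions, function(r) fml(r$products), character(1)),
    law = vapply(x$reactions, function(r) r$law$kind, character(1)),
    k = vapply(x$reactions, function(r) r$law$k, numeric(1)),
    rule = vapply(x$reactions, function(r) r$rule, character(1)))
}

#' @exportS3Method generics::glance
#' @export
glance.reaction_network <- function(x, ...) {
  tibble::tibble(n_entities = length(x$entities),
                 n_reactions = length(x$reactions),
                 n_rules = length(x$rules),
                 max_complex_size = max(vapply(x$entities, complex_size, integer(1))))
}

#' Export a reaction network as a flat CSV reaction list
#'
#' @param x A `reaction_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(x, path) {
  utils::write.csv(as.data.frame(tidy.reaction_network(x)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Stoichiometry of a reaction network
#'
#' Compiles the network into the dense entity-by-reaction stoichiometry matrix
#' and per-reaction substrate order vectors used by the kinetics layer.
#'
#' @param net A `reaction_network`.
#' @return List with `S` (entities x reactions stoichiometry matrix, row names
#'   are canonical labels), `order` (list of named substrate-order vectors)
#'   and `k` (rate constants).
#' @export
network_stoichiometry <- function(net) {
  labs <- names(net$entities)
  nr <- length(net$reactions)
  S <- matrix(0, nrow = length(labs), ncol = nr, dimnames = list(labs, NULL))
  ord <- vector("list", nr)
  k <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    st <- table(r$substrates)
    pt <- table(r$products)
    S[names(st), j] <- S[names(st), j] - as.numeric(st)
    S[names(pt), j] <- S[names(pt), j] + as.numeric(pt)
    ord[[j]] <- as.numeric(st); names(ord[[j]]) <- names(st)
    k[j] <- r$law$k
  }
  list(S = S, order = ord, k = k)
}

#' Replay a reaction's provenance track
#'
#' Every generated reaction records the lineage of canonical labels from its
#' substrates through each reactor application to its products. `replay_track`
#' re-applies the generating rule's reactor chain to the recorded substrate
#' entities and checks that one application reproduces the reaction's products
#' (the track replays to its product).
#'
#' @param net A `reaction_network`.
#' @param reaction A `network_reaction` from `net$reactions`.
#' @return `TRUE` if the replay reproduces the products.
#' @export
replay_track <- function(net, reaction) {
  rule <- Filter(function(r) r$name == reaction$rule, net$rules)[[1L]]
  nsub <- length(reaction$substrates)
  subs <- net$entities[reaction$track[seq_len(nsub)]]
  if (any(vapply(subs, is.null, logical(1)))) return(FALSE)
  matches <- apply_rule(net$model, rule, unname(subs))
  for (m in matches) {
    plab <- sort(vapply(m$products, entity_label, character(1)))
    slab <- sort(vapply(m$substrates, entity_label, character(1)))
    if (identical(plab, sort(reaction$products)) &&
        identical(slab, sort(reaction$substrates))) return(TRUE)
  }
  FALSE
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
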