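#' Declare a simple chemical entity
#'
#' Simple entities are the indivisible building blocks of the chemistry layer:
#' a protein, a second messenger, a phosphate group. Complexes are connected
#' graphs of simple entities joined at declared binding sites.
#'
#' @param name Unique identifier within a model.
#' @param small_molecule If `TRUE` the entity has a single effective binding
#'   site and can be bound to at most one partner at a time (e.g. cAMP, ATP).
#' @param membrane_bound If `TRUE`, any complex containing this entity is
#'   membrane-bound unless explicitly overridden.
#' @return An object of class `simple_entity`.
#' @export
simple_entity <- function(name, small_molecule = FALSE, membrane_bound = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name,
                 small_molecule = isTRUE(small_molecule),
                 membrane_bound = isTRUE(membrane_bound)),
            class = "simple_entity")
}

#' Declare a binding site
#'
#' A binding site is a named, ordered pair of simple entity names. An edge
#' between two nodes of a complex may only exist if a site for that pair of
#' entity names has been declared.
#'
#' @param name Site identifier (unique within a model).
#' @param from,to Names of the two simple entities the site connects.
#' @return An object of class `binding_site`.
#' @export
binding_site <- function(name, from, to) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(from), length(from) == 1L,
            is.character(to), length(to) == 1L)
  structure(list(name = name, from = from, to = to), class = "binding_site")
}

#' Assemble an entity model
#'
#' Collects simple entities and binding sites into the registry against which
#' complexes, reaction rules and networks are validated.
#'
#' @param entities List of [simple_entity()] objects.
#' @param sites List of [binding_site()] objects.
#' @return An object of class `entity_model`.
#' @export
entity_model <- function(entities = list(), sites = list()) {
  if (inherits(entities, "simple_entity")) entities <- list(entities)
  if (inherits(sites, "binding_site")) sites <- list(sites)
  enames <- vapply(entities, `[[`, character(1), "name")
  snames <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(enames)) stop("duplicate entity names: ",
                                  paste(enames[duplicated(enames)], collapse = ", "))
  if (anyDuplicated(snames)) stop("duplicate site names: ",
                                  paste(snames[duplicated(snames)], collapse = ", "))
  names(entities) <- enames
  names(sites) <- snames
  for (s in sites) {
    if (!s$from %in% enames || !s$to %in% enames)
      stop("site '", s$name, "' references undeclared entities")
  }
  structure(list(entities = entities, sites = sites,
                 entity_names = enames, site_names = snames),
            class = "entity_model")
}

#' @export
print.entity_model <- function(x, ...) {
  cat("<entity_model> ", length(x$entities), " entities, ",
      length(x$sites), " binding sites\n", sep = "")
  invisible(x)
}

empty_edges <- function() {
  data.frame(from = integer(), to = integer(), site = character(),
             stringsAsFactors = FALSE)
}

#' Construct a complex chemical entity
#'
#' A complex is a connected graph whose nodes are occurrences of simple
#' entities and whose edges are bonds labelled by a declared binding site.
#' Isomorphic complexes (respecting node names and edge site labels) compare
#' equal through their canonical form.
#'
#' @param model An [entity_model()].
#' @param nodes Character vector of simple entity names (occurrences).
#' @param edges Data frame with columns `from`, `to` (node indices) and
#'   `site` (site name), or `NULL` for a single-node complex.
#' @param membrane_bound Override the derived membrane flag (default: complex
#'   is membrane-bound if any node is).
#' @return An object of class `complex_entity` with its canonical label
#'   attached as attribute `"label"`.
#' @export
complex_entity <- function(model, nodes, edges = NULL, membrane_bound = NULL) {
  stopifnot(inherits(model, "entity_model"), is.character(nodes), length(nodes) >= 1L)
  unknown <- setdiff(nodes, model$entity_names)
  if (length(unknown)) stop("undeclared entities: ", paste(unknown, collapse = ", "))
  if (is.null(edges)) edges <- empty_edges()
  edges$from <- as.integer(edges$from); edges$to <- as.integer(edges$to)
  validate_complex(model, nodes, edges)
  if (is.null(membrane_bound)) {
    membrane_bound <- any(vapply(model$entities[nodes], `[[`, logical(1),
                                 "membrane_bound"))
  }
  x <- structure(list(nodes = nodes, edges = edges,
                      membrane_bound = isTRUE(membrane_bound)),
                 class = "complex_entity")
  attr(x, "label") <- canonical_form(x, model)
  x
}

validate_complex <- function(model, nodes, edges) {
  n <- length(nodes)
  if (nrow(edges)) {
    if (any(edges$from < 1L | edges$from > n | edges$to < 1L | edges$to > n))
      stop("edge endpoints out of range")
    for (i in seq_len(nrow(edges))) {
      s <- model$sites[[edges$site[i]]]
      if (is.null(s)) stop("undeclared binding site: ", edges$site[i])
      a <- nodes[edges$from[i]]; b <- nodes[edges$to[i]]
      ok <- (a == s$from && b == s$to) || (a == s$to && b == s$from)
      if (!ok) stop("edge endpoints (", a, ", ", b,
                    ") do not match site '", s$name, "' pair (",
                    s$from, ", ", s$to, ")")
    }
  }
  # connectivity
  if (n > 1L) {
    seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nb <- c(edges$to[edges$from %in% frontier], edges$from[edges$to %in% frontier])
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      frontier <- unique(nb)
    }
    if (!all(seen)) stop("complex graph is not connected")
  }
  # small-molecule valence
  deg <- tabulate(c(edges$from, edges$to), nbins = n)
  small <- vapply(model$entities[nodes], `[[`, logical(1), "small_molecule")
  if (any(small & deg > 1L))
    stop("small molecule '", nodes[which(small & deg > 1L)[1]],
         "' participates in more than one bond")
  invisible(TRUE)
}

#' Canonical label of a complex
#'
#' Computes a canonical string label such that two complexes receive the same
#' label if and only if their graphs are isomorphic respecting node entity
#' names and edge site labels. Bonds are subdivided into site-coloured nodes
#' and the canonical vertex order is obtained by refinement-based canonical
#' labelling, so the label is stable under any node reordering.
#'
#' @param x A `complex_entity` (or the bare list structure thereof).
#' @param model The [entity_model()] the complex belongs to.
#' @return A character scalar.
#' @export
canonical_form <- function(x, model) {
  n <- length(x$nodes)
  m <- nrow(x$edges)
  if (m == 0L) {
    lab <- paste(sort(x$nodes), collapse = "+")
    return(paste0(lab, if (isTRUE(x$membrane_bound)) "@m" else ""))
  }
  # subdivide each bond into a node coloured by its site name
  bond_ids <- n + seq_len(m)
  el <- rbind(cbind(x$edges$from, bond_ids), cbind(x$edges$to, bond_ids))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  ne <- length(model$entity_names)
  cols <- c(match(x$nodes, model$entity_names),
            ne + match(x$edges$site, model$site_names))
  perm <- igraph::canonical_permutation(g, colors = as.integer(cols))$labeling
  # serialize: colours in canonical vertex order + canonically indexed edges
  ord <- order(perm)
  col_str <- paste(cols[ord], collapse = ",")
  em <- igraph::as_edgelist(g, names = FALSE)
  a <- pmin(perm[em[, 1]], perm[em[, 2]])
  b <- pmax(perm[em[, 1]], perm[em[, 2]])
  eo <- order(a, b)
  edge_str <- paste(a[eo], b[eo], sep = "-", collapse = ";")
  paste0("{", col_str, "|", edge_str, "}",
         if (isTRUE(x$membrane_bound)) "@m" else "")
}

#' @export
print.complex_entity <- function(x, ...) {
  cat("<complex_entity> ", entity_formula(x),
      if (x$membrane_bound) " [membrane]", "\n", sep = "")
  invisible(x)
}

#' Human-readable formula of a complex
#'
#' @param x A `complex_entity`.
#' @return Character scalar such as `"AQP2.P"` or `"PKAR.2cAMP.PKAC"`.
#' @export
entity_formula <- function(x) {
  u <- sort(unique(x$nodes), method = "radix")  # locale-independent order
  n <- vapply(u, function(e) sum(x$nodes == e), integer(1))
  paste(ifelse(n > 1L, paste0(n, u), u), collapse = ".")
}

entity_label <- function(x) attr(x, "label")

#' Number of simple-entity occurrences in a complex
#' @param x A `complex_entity`.
#' @return Integer scalar.
#' @export
complex_size <- function(x) length(x$nodes)

# degree of each node restricted to a given site name
site_degree <- function(x, site) {
  n <- length(x$nodes)
  e <- x$edges[x$edges$site == site, , drop = FALSE]
  tabulate(c(e$from, e$to), nbins = n)
}

# nodes (indices) named `name` whose `site` slot is unoccupied and whose
# small-molecule valence permits a further bond
free_nodes <- function(model, x, name, site) {
  idx <- which(x$nodes == name)
  if (!length(idx)) return(integer())
  sdeg <- site_degree(x, site)
  deg <- tabulate(c(x$edges$from, x$edges$to), nbins = length(x$nodes))
  keep <- sdeg[idx] == 0L
  if (model$entities[[name]]$small_molecule) keep <- keep & deg[idx] == 0L
  idx[keep]
}
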