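# Shared fixtures built in code.

# toy entity model: one protein X with up to four independent phosphosites
toy_model <- function(k_sites = 3L) {
  sites <- lapply(seq_len(k_sites), function(i)
    binding_site(paste0("s", i), "X", "P"))
  entity_model(
    entities = list(simple_entity("X"), simple_entity("P", small_molecule = TRUE)),
    sites = sites)
}

toy_rules <- function(k_sites = 3L, k_on = 1, k_off = 1) {
  c(lapply(seq_len(k_sites), function(i)
    reaction_rule(paste0("p", i), rx_add("P", to = "X", site = paste0("s", i)),
                  k = k_on)),
    lapply(seq_len(k_sites), function(i)
      reaction_rule(paste0("d", i), rx_remove("P", from = "X", site = paste0("s", i)),
                    k = k_off)))
}

# minimal PKA-like model for reactor semantics tests
pka_toy <- function() {
  entity_model(
    entities = list(simple_entity("PKAR"), simple_entity("PKAC"),
                    simple_entity("cAMP", small_molecule = TRUE)),
    sites = list(binding_site("siteA", "PKAR", "cAMP"),
                 binding_site("siteB", "PKAR", "cAMP"),
                 binding_site("rc", "PKAR", "PKAC")))
}

# single-cell space + simulation around a module list
cell_sim <- function(init, modules, controller = error_controller(), seed = 1L) {
  sp <- simulation_space(matrix("c", 1, 1), ds = 1)
  simulation(sp, grid_init = init, modules = modules,
             controller = controller, seed = seed)
}

# brute-force isomorphism check (exhaustive permutation oracle, <= 6 nodes)
iso_oracle <- function(a, b) {
  if (length(a$nodes) != length(b$nodes)) return(FALSE)
  if (nrow(a$edges) != nrow(b$edges)) return(FALSE)
  n <- length(a$nodes)
  eset <- function(x, perm) {
    if (!nrow(x$edges)) return(character())
    sort(paste(pmin(perm[x$edges$from], perm[x$edges$to]),
               pmax(perm[x$edges$from], perm[x$edges$to]), x$edges$site))
  }
  target <- eset(b, seq_len(n))
  perms <- if (n == 1) matrix(1L, 1) else
    as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  for (r in seq_len(nrow(perms))) {
    perm <- as.integer(perms[r, ])
    if (anyDuplicated(perm)) next
    if (!all(b$nodes[perm] == a$nodes)) next
    if (identical(eset(a, perm), target)) return(TRUE)
  }
  FALSE
}

# cache the generated model networks across test files (generation ~ seconds)
net_cache <- new.env(parent = emptyenv())
cached_phospho_network <- function() {
  if (is.null(net_cache$phospho)) net_cache$phospho <- phospho_network()
  net_cache$phospho
}
cached_endo_network <- function() {
  if (is.null(net_cache$endo)) net_cache$endo <- endo_network()
  net_cache$endo
}
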