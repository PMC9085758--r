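# Rule-based network generation: state-space counts, fixpoint behaviour,
# conservation, provenance.

test_that("k independent binary modification sites generate 2^k entities", {
  for (k in 1:4) {
    m <- toy_model(k)
    net <- generate_network(m, toy_rules(k), list(complex_entity(m, "X")))
    expect_length(net$entities, 2^k)
    # each state has k outgoing transitions (toggle each site)
    expect_length(net$reactions, k * 2^k)
  }
})

test_that("an empty rule set returns the seeds and no reactions", {
  m <- pka_toy()
  net <- generate_network(m, list(), list(complex_entity(m, "PKAR"),
                                          complex_entity(m, "PKAC")))
  expect_length(net$entities, 2L)
  expect_length(net$reactions, 0L)
})

test_that("generation is idempotent: rerunning on its own output adds nothing", {
  m <- toy_model(3L)
  rules <- toy_rules(3L)
  net1 <- generate_network(m, rules, list(complex_entity(m, "X")))
  net2 <- generate_network(m, rules, unname(net1$entities))
  expect_setequal(names(net2$entities), names(net1$entities))
  expect_length(net2$reactions, length(net1$reactions))
})

test_that("BIND/RELEASE conserve simple-entity occurrences; ADD/REMOVE change by one", {
  m <- pka_toy()
  holo <- complex_entity(m, c("PKAR", "PKAC"),
                         data.frame(from = 1L, to = 2L, site = "rc"))
  camp <- complex_entity(m, "cAMP")
  multiset <- function(entities) sort(unlist(lapply(entities, `[[`, "nodes")))
  b <- apply_reactor(m, rx_bind("PKAR", "cAMP", "siteA"), list(holo, camp))[[1]]
  expect_identical(multiset(b$substrates), multiset(b$products))
  r <- apply_reactor(m, rx_release("PKAR", "PKAC", "rc"), list(holo))[[1]]
  expect_identical(multiset(r$substrates), multiset(r$products))
  m2 <- toy_model(1L)
  x <- complex_entity(m2, "X")
  a <- apply_reactor(m2, rx_add("P", to = "X", site = "s1"), list(x))[[1]]
  expect_identical(multiset(a$products), sort(c(multiset(a$substrates), "P")))
  d <- apply_reactor(m2, rx_remove("P", from = "X", site = "s1"),
                     a$products)[[1]]
  expect_identical(sort(c(multiset(d$products), "P")), multiset(d$substrates))
})

test_that("every generated reaction's provenance track replays to its product", {
  m <- toy_model(2L)
  net <- generate_network(m, toy_rules(2L), list(complex_entity(m, "X")))
  expect_true(all(vapply(net$reactions, function(r) replay_track(net, r),
                         logical(1))))
  # also for a chain rule (bind + add + release)
  netp <- cached_phospho_network()
  idx <- which(vapply(netp$reactions, function(r) r$rule == "aqp2_phos", logical(1)))
  expect_gt(length(idx), 0L)
  for (j in idx) expect_true(replay_track(netp, netp$reactions[[j]]))
})

test_that("unbounded polymerisation aborts naming the offending rule", {
  # two alternating head/tail sites let chains grow without bound
  m <- entity_model(list(simple_entity("A")),
                    list(binding_site("s1", "A", "A"),
                         binding_site("s2", "A", "A")))
  rules <- list(reaction_rule("grow1", rx_bind("A", "A", "s1"), k = 1),
                reaction_rule("grow2", rx_bind("A", "A", "s2"), k = 1))
  expect_error(generate_network(m, rules, list(complex_entity(m, "A")),
                                max_complex_size = 1000L, max_iter = 3L),
               "grow")
})

test_that("products above the complex-size cap are not added to the pool", {
  m <- entity_model(list(simple_entity("A")),
                    list(binding_site("s1", "A", "A"),
                         binding_site("s2", "A", "A")))
  rules <- list(reaction_rule("grow1", rx_bind("A", "A", "s1"), k = 1),
                reaction_rule("grow2", rx_bind("A", "A", "s2"), k = 1))
  net <- generate_network(m, rules, list(complex_entity(m, "A")),
                          max_complex_size = 4L)
  expect_true(all(vapply(net$entities, complex_size, integer(1)) <= 4L))
})

test_that("network export produces a readable flat reaction list", {
  m <- toy_model(2L)
  net <- generate_network(m, toy_rules(2L), list(complex_entity(m, "X")))
  tt <- tidy(net)
  expect_s3_class(tt, "tbl_df")
  expect_named(tt, c("reaction", "substrates", "products", "law", "k", "rule"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), length(net$reactions))
  g <- glance(net)
  expect_equal(g$n_entities, 4L)
})

test_that("the generated signalosome network encodes the gating rules", {
  net <- cached_phospho_network()
  tt <- tidy(net)
  # PKAC release only from the double-cAMP holoenzyme
  rel <- tt[tt$rule == "pkac_release", ]
  expect_gt(nrow(rel), 0L)
  expect_true(all(grepl("2cAMP", rel$substrates)))
  # phospho-PDE4 hydrolyses cAMP with the enhanced rate constant
  hyd <- tt[tt$rule == "hydrolysis_p", ]
  expect_true(all(hyd$k > unique(tt$k[tt$rule == "hydrolysis"])))
})
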