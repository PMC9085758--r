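# Chemical entity graphs, reactor semantics and canonical labelling.

test_that("reactor semantics: BIND, ADD with condition, RELEASE", {
  m <- pka_toy()
  holo <- complex_entity(m, c("PKAR", "PKAC"),
                         data.frame(from = 1L, to = 2L, site = "rc"))
  camp <- complex_entity(m, "cAMP")
  # BIND with a single free site gives exactly one product
  r <- apply_reactor(m, rx_bind("PKAR", "cAMP", "siteA"), list(holo, camp))
  expect_length(r, 1L)
  expect_equal(entity_formula(r[[1]]$products[[1]]), "PKAC.PKAR.cAMP")
  # condition filter: occupied site yields an empty result
  occ <- r[[1]]$products[[1]]
  r2 <- apply_reactor(m, rx_bind("PKAR", "cAMP", "siteA"), list(occ, camp))
  expect_length(r2, 0L)
  # RELEASE PKAC from the double-occupied holoenzyme splits into two products
  rB <- apply_reactor(m, rx_bind("PKAR", "cAMP", "siteB"), list(occ, camp))
  full <- rB[[1]]$products[[1]]
  rel <- apply_reactor(m, rx_release("PKAR", "PKAC", "rc"), list(full),
                       list(cond_site_occupied("siteA"),
                            cond_site_occupied("siteB")))
  expect_length(rel, 1L)
  fml <- sort(vapply(rel[[1]]$products, entity_formula, character(1)))
  expect_equal(fml, c("PKAC", "PKAR.2cAMP"))
})

test_that("RELEASE on an unbonded pair is a no-match, undeclared sites error", {
  m <- pka_toy()
  pkar <- complex_entity(m, "PKAR")
  expect_length(apply_reactor(m, rx_release("PKAR", "PKAC", "rc"), list(pkar)), 0L)
  expect_error(apply_reactor(m, rx_bind("PKAC", "cAMP"), list(pkar)),
               "no declared binding site")
})

test_that("auto-assignment uses the unique matching site; ambiguity errors", {
  m <- pka_toy()
  pkar <- complex_entity(m, "PKAR")
  pkac <- complex_entity(m, "PKAC")
  # (PKAR, PKAC) has exactly one site -> auto-assigned
  r <- apply_reactor(m, rx_bind("PKAR", "PKAC"), list(pkar, pkac))
  expect_length(r, 1L)
  # (PKAR, cAMP) has two sites -> error
  camp <- complex_entity(m, "cAMP")
  expect_error(apply_reactor(m, rx_bind("PKAR", "cAMP"), list(pkar, camp)),
               "ambiguous")
})

test_that("small molecules bind at most one partner, graphs must be connected", {
  m <- pka_toy()
  expect_error(complex_entity(m, c("PKAR", "PKAR", "cAMP"),
                              data.frame(from = c(1L, 2L), to = c(3L, 3L),
                                         site = c("siteA", "siteA"))),
               "small molecule")
  expect_error(complex_entity(m, c("PKAR", "PKAC")), "not connected")
})

test_that("canonical labels are invariant under node reordering", {
  m <- pka_toy()
  ab1 <- complex_entity(m, c("PKAR", "cAMP"),
                        data.frame(from = 1L, to = 2L, site = "siteA"))
  ab2 <- complex_entity(m, c("cAMP", "PKAR"),
                        data.frame(from = 2L, to = 1L, site = "siteA"))
  expect_identical(canonical_form(ab1, m), canonical_form(ab2, m))
  # different site label -> different label
  ab3 <- complex_entity(m, c("PKAR", "cAMP"),
                        data.frame(from = 1L, to = 2L, site = "siteB"))
  expect_false(identical(canonical_form(ab1, m), canonical_form(ab3, m)))
})

test_that("canonical label equality matches the exhaustive isomorphism oracle", {
  m <- toy_model(4L)
  set.seed(7)
  rand_complex <- function() {
    k <- sample(2:4, 1)
    nodes <- c("X", rep("P", k))
    edges <- data.frame(from = 1L, to = seq_len(k) + 1L,
                        site = sample(paste0("s", 1:4), k))
    complex_entity(m, nodes, edges)
  }
  for (rep in 1:25) {
    a <- rand_complex(); b <- rand_complex()
    expect_identical(identical(canonical_form(a, m), canonical_form(b, m)),
                     iso_oracle(a, b),
                     info = paste("rep", rep))
  }
  # permuted copies of the same complex always agree
  for (rep in 1:10) {
    a <- rand_complex()
    perm <- sample(length(a$nodes))
    inv <- order(perm)
    b <- complex_entity(m, a$nodes[perm],
                        data.frame(from = inv[a$edges$from],
                                   to = inv[a$edges$to], site = a$edges$site))
    expect_identical(canonical_form(a, m), canonical_form(b, m))
    expect_true(iso_oracle(a, b))
  }
})
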