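# Vesicle indexing, collision handling, displacement control, filaments.

test_that("a vesicle wholly inside one cell has a single full association", {
  sp <- simulation_space(matrix("c", 10, 10), ds = 1)
  idx <- index_vesicle(sp, 2.5, 2.5, 0.3)
  expect_equal(nrow(idx$cells), 1L)
  expect_equal(idx$fractions, 1)
  expect_equal(unname(idx$cells[1, ]), c(3, 3))
})

test_that("a vesicle centred on a four-cell corner splits 4 x 0.25", {
  sp <- simulation_space(matrix("c", 10, 10), ds = 1)
  idx <- index_vesicle(sp, 5, 5, 0.3)
  expect_equal(nrow(idx$cells), 4L)
  expect_equal(sort(unname(idx$fractions)), rep(0.25, 4), tolerance = 1e-12)
})

test_that("association fractions match a perimeter-sampling oracle and sum to 1", {
  sp <- simulation_space(matrix("c", 10, 10), ds = 1)
  set.seed(42)
  for (k in 1:15) {
    x <- runif(1, 1, 9); y <- runif(1, 1, 9); r <- runif(1, 0.05, 0.49)
    idx <- index_vesicle(sp, x, y, r)
    expect_equal(sum(idx$fractions), 1, tolerance = 1e-12)
    expect_lte(nrow(idx$cells), 4L)
    th <- seq_len(20000) / 20000 * 2 * pi
    ci <- floor((y + r * sin(th))) + 1L
    cj <- floor((x + r * cos(th))) + 1L
    tab <- table(paste(ci, cj)) / length(th)
    keys <- paste(idx$cells[, 1], idx$cells[, 2])
    for (q in seq_along(keys)) {
      expect_equal(unname(idx$fractions[q]), unname(tab[[keys[q]]]),
                   tolerance = 2e-3)
    }
  }
})

test_that("vesicle radius must stay below the grid spacing", {
  sp <- simulation_space(matrix("c", 4, 4), ds = 0.5)
  sim <- simulation(sp)
  expect_error(add_vesicle(sim, 1, 1, radius = 0.6), "smaller than the grid")
})

test_that("displacement proposals are discarded on overlap and membrane crossing", {
  layout <- matrix("a", 6, 6); layout[, 4:6] <- "b"
  sp <- simulation_space(layout, ds = 1, auto_membranes = TRUE)
  sim <- simulation(sp)
  id1 <- add_vesicle(sim, 2.0, 2.0, 0.2)
  id2 <- add_vesicle(sim, 2.6, 2.0, 0.2)
  v1 <- sim$ves[[as.character(id1)]]
  # free move accepted
  expect_equal(resolve_displacement(sim, v1, c(2.0, 2.5)), c(2.0, 2.5))
  # overlapping move discarded (distance < r1 + r2)
  expect_equal(resolve_displacement(sim, v1, c(2.35, 2.0)), c(2.0, 2.0))
  # crossing the membrane between columns 3 and 4 (x = 3) discarded
  expect_equal(resolve_displacement(sim, v1, c(3.4, 2.0)), c(2.0, 2.0))
  # barrier region: moves inside are fine, crossing its boundary is discarded
  rg <- volume_region(rbind(c(0, 0), c(2.5, 0), c(2.5, 6), c(0, 6)), name = "box")
  rg$barrier <- TRUE
  sim$regions <- list(rg)
  expect_equal(resolve_displacement(sim, v1, c(2.0, 2.8)), c(2.0, 2.8))
  expect_equal(resolve_displacement(sim, v1, c(2.8, 3.5)), c(2.0, 2.0))
})

test_that("crossing proposals match a segment-intersection oracle", {
  layout <- matrix("a", 5, 5); layout[3, 3] <- "b"
  sp <- simulation_space(layout, ds = 1, auto_membranes = TRUE)
  sim <- simulation(sp)
  id <- add_vesicle(sim, 1.2, 1.2, 0.1)
  v <- sim$ves[[as.character(id)]]
  segs <- vesiflow:::face_segments(sp)
  seg_cross <- function(p, q, a, b) {
    o <- function(p1, p2, p3) sign((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                                     (p2[2] - p1[2]) * (p3[1] - p1[1]))
    o(p, q, a) * o(p, q, b) < 0 && o(a, b, p) * o(a, b, q) < 0
  }
  set.seed(9)
  for (k in 1:200) {
    tgt <- c(runif(1, 0.3, 4.7), runif(1, 0.3, 4.7))
    hit <- any(apply(segs, 1, function(s)
      seg_cross(c(v$x, v$y), tgt, s[1:2], s[3:4])))
    got <- resolve_displacement(sim, v, tgt)
    if (hit) expect_equal(got, c(v$x, v$y)) else expect_equal(got, tgt)
  }
})

test_that("displacement control follows the log-ratio rules", {
  expect_equal(displacement_control(numeric(), d_ref = 0.25), "increase")
  # ||dp|| = d_ref -> D = 0, above the increase band, below decrease
  expect_equal(displacement_control(0.25, 0.25), "neutral")
  expect_equal(displacement_control(c(0, 0), 0.25), "increase")
  expect_equal(displacement_control(c(0.5, 0.01), 0.25), "decrease")
  # brute-force evaluation of both threshold rules on random magnitudes
  set.seed(3)
  for (k in 1:50) {
    norms <- runif(4, 0, 0.6)
    D <- log10(norms / 0.25)
    want <- if (any(D > 0)) "decrease" else if (all(D < -1)) "increase" else "neutral"
    expect_equal(displacement_control(norms, 0.25), want)
  }
})

test_that("no vesicle overlaps or membrane crossings survive random stepping", {
  layout <- matrix("a", 8, 8); layout[4:5, 4:5] <- "b"
  sp <- simulation_space(layout, ds = 1, auto_membranes = TRUE)
  sim <- simulation(sp, disp_modules = list(mod_brownian(0.5, states = "unattached")),
                    seed = 42)
  set.seed(1)
  placed <- 0L
  while (placed < 6L) {
    x <- runif(1, 0.5, 7.5); y <- runif(1, 0.5, 7.5)
    cellsides <- floor(c(x, y)) + 1
    if (sp$layout[cellsides[2], cellsides[1]] == "b") next
    ok <- all(vapply(sim$ves, function(v)
      sqrt((v$x - x)^2 + (v$y - y)^2) >= 0.5, logical(1)))
    if (!ok) next
    add_vesicle(sim, x, y, 0.2)
    placed <- placed + 1L
  }
  start_side <- vapply(sim$ves, function(v) sp$layout[floor(v$y) + 1, floor(v$x) + 1],
                       character(1))
  run_simulation(sim, 10)
  ids <- names(sim$ves)
  for (a in seq_along(ids)) {
    va <- sim$ves[[ids[a]]]
    # never inside the membrane-enclosed block
    expect_false(sp$layout[floor(va$y) + 1, floor(va$x) + 1] == "b")
    for (b in seq_len(a - 1L)) {
      vb <- sim$ves[[ids[b]]]
      expect_gte(sqrt((va$x - vb$x)^2 + (va$y - vb$y)^2), va$r + vb$r - 1e-9)
    }
    # association stays normalised after every re-indexing
    expect_equal(sum(va$assoc$fractions), 1, tolerance = 1e-12)
  }
})

test_that("filament geometry: points, nearest distance, end handling", {
  fl <- filament(rbind(c(0, 0), c(2, 0), c(2, 2)), type = "actin")
  expect_equal(fl$total_len, 4)
  expect_equal(vesiflow:::filament_point(fl, 1), c(1, 0))
  expect_equal(vesiflow:::filament_point(fl, 3), c(2, 1))
  near <- vesiflow:::filament_nearest(fl, c(1, 1))
  expect_equal(near$dist, 1)
  expect_error(filament(rbind(c(0, 0), c(0, 0))), "zero-length")
})
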