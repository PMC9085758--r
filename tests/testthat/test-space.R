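# Simulation space: raster construction, membranes, areas, round-trips.

test_that("uniform single-colour raster gives one compartment and no membranes", {
  img <- array(1, c(10, 10, 3))
  sp <- from_raster(img, ds = 0.1,
                    color_map = data.frame(color = "#FFFFFF",
                                           descriptor = "cytosol"))
  expect_equal(sp$n_rows * sp$n_cols, 100L)
  expect_equal(n_membrane_faces(sp), 0L)
  expect_equal(unique(as.vector(sp$layout)), "cytosol")
})

test_that("an inner block is surrounded by a membrane ring of 16 faces", {
  img <- array(1, c(10, 10, 3))
  img[4:7, 4:7, ] <- 0   # 4x4 black block
  sp <- from_raster(img, ds = 1,
                    color_map = data.frame(color = c("#FFFFFF", "#000000"),
                                           descriptor = c("cytosol", "storage")))
  expect_equal(n_membrane_faces(sp), 16L)
  ring <- region_boundary_faces(sp, "storage")
  expect_equal(nrow(ring), 16L)
  expect_equal(segment_area(sp, ring), 16 * 1^2)
})

test_that("unmapped pixel colours raise a config error naming pixels", {
  img <- array(1, c(3, 3, 3))
  img[2, 2, ] <- c(1, 0, 0)
  expect_error(from_raster(img, 1, data.frame(color = "#FFFFFF",
                                              descriptor = "c")),
               "unmapped pixel")
})

test_that("per-region restriction coefficients are applied", {
  img <- array(1, c(6, 6, 3))
  img[2:4, 2:4, ] <- 0
  sp <- from_raster(img, ds = 1,
                    color_map = data.frame(color = c("#FFFFFF", "#000000"),
                                           descriptor = c("cytosol", "storage"),
                                           restriction = c(1, 0.01)))
  expect_true(all(sp$r[sp$layout == "storage"] == 0.01))
  expect_true(all(sp$r[sp$layout == "cytosol"] == 1))
})

test_that("segment areas follow the pseudo-3D convention", {
  sp <- simulation_space(matrix("c", 4, 4), ds = 0.1)
  one <- data.frame(type = "v", i = 1L, j = 1L)
  expect_equal(segment_area(sp, one), 0.01)
  ten <- data.frame(type = "h", i = rep(1L, 4), j = 1:4)
  expect_equal(segment_area(sp, ten), 4 * 0.1^2)
  # a 1 um^2 apical patch at ds = 0.1 um needs 100 unit faces
  sp2 <- simulation_space(matrix("c", 2, 100), ds = 0.1)
  patch <- data.frame(type = "h", i = 1L, j = 1:100)
  expect_equal(segment_area(sp2, patch), 1)
  expect_error(segment_area(sp, data.frame(type = "v", i = 1L, j = 9L)),
               "neighbouring")
})

test_that("compartment volumes partition the total simulated volume", {
  sp <- simulation_space(storage_layout(10, 10, 4), ds = 2, height = 1)
  v_storage <- sum(sp$layout == "storage") * point_volume(sp)
  v_cyt <- sum(sp$layout == "cytosol") * point_volume(sp)
  expect_equal(v_storage + v_cyt, 10 * 10 * 2^2 * 1)
})

test_that("raster export and re-import round-trips the space", {
  layout <- storage_layout(12, 12, 4)
  cmap <- data.frame(color = c("#FFFFFF", "#4040C0"),
                     descriptor = c("cytosol", "storage"),
                     restriction = c(1, 0.01))
  sp <- simulation_space(layout, ds = 1,
                         restriction = c(cytosol = 1, storage = 0.01))
  png_path <- withr::local_tempfile(fileext = ".png")
  write_space_png(sp, png_path, cmap)
  sp2 <- from_raster(png_path, ds = 1, color_map = cmap)
  expect_identical(sp2$layout, sp$layout)
  expect_equal(sp2$r, sp$r)
  expect_equal(sp2$vblock, sp$vblock)
  expect_equal(sp2$hblock, sp$hblock)
  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_space_csv(sp, csv_path)
  back <- utils::read.csv(csv_path)
  expect_equal(nrow(back), 144L)
  expect_setequal(unique(back$descriptor), c("cytosol", "storage"))
})

test_that("open_passages removes exactly the requested number of ring faces", {
  sp <- simulation_space(storage_layout(30, 30, 8), ds = 1)
  ring <- region_boundary_faces(sp, "storage")
  n0 <- n_membrane_faces(sp)
  sp2 <- open_passages(sp, ring, 2L)
  expect_equal(n_membrane_faces(sp2), n0 - 2L)
  expect_error(open_passages(sp, ring, nrow(ring) + 1L), "passages")
})

test_that("volume regions use the even-odd rule with on-boundary inside", {
  rg <- volume_region(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_true(region_contains(rg, c(1, 1)))
  expect_false(region_contains(rg, c(3, 1)))
  expect_true(region_contains(rg, c(0, 0)))   # vertex counts as inside
  expect_true(region_contains(rg, c(1, 0)))   # edge counts as inside
})
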