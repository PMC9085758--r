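#' Build a compartmentalised simulation space
#'
#' The simulation space is a pseudo-3D slice: a regular 2D grid of spacing
#' `ds` (um) and fixed slice `height` (um). Each grid point belongs to one
#' compartment class (its descriptor); boundaries between differently
#' labelled areas are membrane faces that block diffusion. Grid indices are
#' 0-based `(row, col)` with pixel (0,0) at top-left in all exports; inside R,
#' matrices use the usual 1-based indexing.
#'
#' @param layout Character (or factor/integer) matrix of compartment
#'   descriptors, one per grid point.
#' @param ds Grid spacing in um (> 0).
#' @param height Slice depth in um used to convert areas to volumes.
#' @param restriction Named numeric vector mapping descriptors to diffusive
#'   restriction coefficients in `[0, 1]` (default 1 everywhere), or a full
#'   numeric matrix of per-point coefficients.
#' @param auto_membranes If `TRUE`, areas of different descriptors are
#'   separated by membrane faces (each region is surrounded by a membrane).
#' @return An object of class `simulation_space`.
#' @export
simulation_space <- function(layout, ds, height = 1, restriction = NULL,
                             auto_membranes = TRUE) {
  stopifnot(is.matrix(layout), ds > 0, height > 0)
  layout <- matrix(as.character(layout), nrow(layout), ncol(layout))
  n <- nrow(layout); m <- ncol(layout)
  if (is.matrix(restriction)) {
    stopifnot(all(dim(restriction) == dim(layout)))
    r <- restriction
  } else {
    r <- matrix(1, n, m)
    if (!is.null(restriction)) {
      for (d in names(restriction)) r[layout == d] <- restriction[[d]]
    }
  }
  if (any(r < 0 | r > 1)) stop("restriction coefficients must lie in [0, 1]")
  vblock <- matrix(FALSE, n, max(m - 1L, 0L))
  hblock <- matrix(FALSE, max(n - 1L, 0L), m)
  if (auto_membranes) {
    if (m > 1L) vblock <- layout[, -m, drop = FALSE] != layout[, -1L, drop = FALSE]
    if (n > 1L) hblock <- layout[-n, , drop = FALSE] != layout[-1L, , drop = FALSE]
  }
  structure(list(layout = layout, ds = ds, height = height, r = r,
                 vblock = vblock, hblock = hblock,
                 n_rows = n, n_cols = m),
            class = "simulation_space")
}

#' @export
print.simulation_space <- function(x, ...) {
  cat("<simulation_space> ", x$n_rows, "x", x$n_cols, " grid, ds = ", x$ds,
      " um, height = ", x$height, " um\n  compartments: ",
      paste(unique(as.vector(x$layout)), collapse = ", "),
      "\n  membrane faces: ", n_membrane_faces(x), "\n", sep = "")
  invisible(x)
}

#' Count membrane faces in a space
#' @param space A `simulation_space`.
#' @return Integer number of blocked faces.
#' @export
n_membrane_faces <- function(space) sum(space$vblock) + sum(space$hblock)

#' Interior volume of one grid point
#'
#' The pseudo-3D convention: each grid point represents a box of volume
#' `ds^2 * height` (um^3).
#'
#' @param space A `simulation_space`.
#' @return Volume in um^3.
#' @export
point_volume <- function(space) space$ds^2 * space$height

#' Enumerate the faces on the boundary of a compartment region
#'
#' A face is identified by `type` (`"v"`: between `(i, j)` and `(i, j+1)`;
#' `"h"`: between `(i, j)` and `(i+1, j)`) and the 1-based indices `(i, j)` of
#' its first cell. Only interior faces (between two grid points) qualify;
#' membranes never lie on the domain boundary.
#'
#' @param space A `simulation_space`.
#' @param descriptor Compartment descriptor whose boundary ring is requested.
#' @return Data frame with columns `type`, `i`, `j`.
#' @export
region_boundary_faces <- function(space, descriptor) {
  inside <- space$layout == descriptor
  n <- space$n_rows; m <- space$n_cols
  out <- list()
  if (m > 1L) {
    vv <- which(inside[, -m, drop = FALSE] != inside[, -1L, drop = FALSE], arr.ind = TRUE)
    if (nrow(vv)) out[[1L]] <- data.frame(type = "v", i = vv[, 1L], j = vv[, 2L])
  }
  if (n > 1L) {
    hh <- which(inside[-n, , drop = FALSE] != inside[-1L, , drop = FALSE], arr.ind = TRUE)
    if (nrow(hh)) out[[2L]] <- data.frame(type = "h", i = hh[, 1L], j = hh[, 2L])
  }
  if (!length(out)) return(data.frame(type = character(), i = integer(), j = integer()))
  do.call(rbind, out)
}

validate_faces <- function(space, faces) {
  stopifnot(is.data.frame(faces), all(c("type", "i", "j") %in% names(faces)))
  okv <- faces$type == "v" & faces$i >= 1 & faces$i <= space$n_rows &
    faces$j >= 1 & faces$j <= space$n_cols - 1L
  okh <- faces$type == "h" & faces$i >= 1 & faces$i <= space$n_rows - 1L &
    faces$j >= 1 & faces$j <= space$n_cols
  if (!all(okv | okh))
    stop("faces must lie between two neighbouring grid points")
  invisible(TRUE)
}

#' Open passages in a membrane ring
#'
#' Removes `n` membrane faces (evenly spread along the listed faces) so that
#' diffusing species can pass through the gaps.
#'
#' @param space A `simulation_space`.
#' @param faces Face table as returned by [region_boundary_faces()].
#' @param n Number of passages to open.
#' @return The modified space.
#' @export
open_passages <- function(space, faces, n) {
  validate_faces(space, faces)
  if (n > nrow(faces)) stop("requested ", n, " passages but the ring has only ",
                            nrow(faces), " faces")
  if (n == 0L) return(space)
  pick <- unique(round(seq(1L, nrow(faces), length.out = n)))
  for (k in pick) {
    f <- faces[k, ]
    if (f$type == "v") space$vblock[f$i, f$j] <- FALSE
    else space$hblock[f$i, f$j] <- FALSE
  }
  space
}

#' Area of a membrane segment
#'
#' In the pseudo-3D convention a surface segment's area is its in-plane
#' length multiplied by the spatial step width `ds` — each unit face between
#' two neighbouring grid points contributes `ds^2`.
#'
#' @param space A `simulation_space`.
#' @param faces Face table (see [region_boundary_faces()]); each row is one
#'   unit face of length `ds`.
#' @return Total area in um^2.
#' @export
segment_area <- function(space, faces) {
  validate_faces(space, faces)
  nrow(faces) * space$ds^2
}

#' Build a space from a raster image
#'
#' Each pixel maps to one grid point; pixel colours map to compartment
#' descriptors via `color_map`. Areas of the same colour are automatically
#' surrounded by a membrane (unless `auto_membranes = FALSE`).
#'
#' @param image Path to a PNG file, or an `nrow x ncol x 3` numeric array of
#'   RGB values in `[0, 1]`.
#' @param ds Grid spacing in um.
#' @param color_map Data frame with columns `color` (hex, e.g. `"#FFFFFF"`),
#'   `descriptor`, and optionally `restriction`.
#' @param height Slice depth in um.
#' @param auto_membranes Surround differently coloured areas with membranes.
#' @return A `simulation_space`.
#' @export
from_raster <- function(image, ds, color_map, height = 1, auto_membranes = TRUE) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) == 2L) image <- array(rep(image, 3L), c(dim(image), 3L))
  image <- image[, , 1:3, drop = FALSE]
  hex <- matrix(grDevices::rgb(image[, , 1L], image[, , 2L], image[, , 3L]),
                dim(image)[1L], dim(image)[2L])
  cmap <- toupper(color_map$color)
  miss <- matrix(!(toupper(hex) %in% cmap), nrow(hex), ncol(hex))
  if (any(miss)) {
    px <- which(miss, arr.ind = TRUE)[1:min(5L, sum(miss)), , drop = FALSE]
    stop("unmapped pixel colours ", paste(unique(toupper(hex)[miss]), collapse = ", "),
         " at (row, col) [0-based]: ",
         paste(apply(px - 1L, 1L, paste, collapse = ","), collapse = "; "))
  }
  idx <- match(toupper(hex), cmap)
  layout <- matrix(color_map$descriptor[idx], nrow(hex), ncol(hex))
  restriction <- NULL
  if (!is.null(color_map$restriction)) {
    restriction <- matrix(color_map$restriction[idx], nrow(hex), ncol(hex))
  }
  simulation_space(layout, ds = ds, height = height, restriction = restriction,
                   auto_membranes = auto_membranes)
}

#' Export the compartment map of a space
#'
#' `write_space_csv` writes one row per grid point (0-based `i`, `j`,
#' descriptor, restriction). `write_space_png` writes the compartment raster
#' using the supplied colour map; re-importing it with [from_raster()] yields
#' an identical space.
#'
#' @param space A `simulation_space`.
#' @param path Output file path.
#' @param color_map As in [from_raster()].
#' @return `path`, invisibly.
#' @export
write_space_csv <- function(space, path) {
  idx <- expand.grid(i = seq_len(space$n_rows), j = seq_len(space$n_cols))
  df <- data.frame(i = idx$i - 1L, j = idx$j - 1L,
                   descriptor = space$layout[cbind(idx$i, idx$j)],
                   r = space$r[cbind(idx$i, idx$j)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_space_csv
#' @export
write_space_png <- function(space, path, color_map) {
  idx <- match(as.vector(space$layout), color_map$descriptor)
  if (anyNA(idx)) stop("color_map lacks descriptors: ",
                       paste(setdiff(unique(as.vector(space$layout)),
                                     color_map$descriptor), collapse = ", "))
  col <- grDevices::col2rgb(color_map$color[idx]) / 255
  img <- array(0, c(space$n_rows, space$n_cols, 3L))
  img[, , 1L] <- matrix(col[1L, ], space$n_rows)
  img[, , 2L] <- matrix(col[2L, ], space$n_rows)
  img[, , 3L] <- matrix(col[3L, ], space$n_rows)
  png::writePNG(img, path)
  invisible(path)
}

#' Declare a surface (membrane) agent
#'
#' A surface agent is a set of unit membrane faces with one topological
#' descriptor and a compartment holding per-area concentrations (uM um, i.e.
#' amount per um^2 with amounts measured in uM um^3). Its faces block
#' diffusion across them.
#'
#' @param space A `simulation_space`.
#' @param faces Face table (`type`, `i`, `j`).
#' @param descriptor Topological descriptor, e.g. `"apical-membrane"`.
#' @param conc Named numeric vector of initial surface densities (uM um).
#' @return An object of class `surface_agent`.
#' @export
surface_agent <- function(space, faces, descriptor, conc = numeric()) {
  validate_faces(space, faces)
  structure(list(descriptor = descriptor, faces = faces,
                 area = segment_area(space, faces), conc = conc),
            class = "surface_agent")
}

# apply a surface agent's faces as diffusion blocks
block_faces <- function(space, faces) {
  validate_faces(space, faces)
  for (k in seq_len(nrow(faces))) {
    if (faces$type[k] == "v") space$vblock[faces$i[k], faces$j[k]] <- TRUE
    else space$hblock[faces$i[k], faces$j[k]] <- TRUE
  }
  space
}

#' Declare a volume region agent
#'
#' Volume-like agents are simple polygons marking areas where distinct
#' behaviour applies (diffusive restriction, cortex entry actions, forbidden
#' zones for vesicles). Containment uses the even-odd rule; points on the
#' boundary count as inside.
#'
#' @param vertices Two-column matrix of polygon vertices (um), in order.
#' @param name Region name.
#' @return An object of class `volume_region`.
#' @export
volume_region <- function(vertices, name = "region") {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  structure(list(name = name, vertices = vertices), class = "volume_region")
}

#' Test point containment in a volume region (even-odd rule)
#'
#' @param region A [volume_region()].
#' @param p Numeric length-2 point (um).
#' @return Logical.
#' @export
region_contains <- function(region, p) {
  v <- region$vertices
  n <- nrow(v)
  x <- p[1]; y <- p[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # boundary counts as inside
    if (on_segment(x, y, xi, yi, xj, yj)) return(TRUE)
    if ((yi > y) != (yj > y)) {
      xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

on_segment <- function(x, y, x1, y1, x2, y2, tol = 1e-12) {
  cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
  if (abs(cross) > tol * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  x >= min(x1, x2) - tol && x <= max(x1, x2) + tol &&
    y >= min(y1, y2) - tol && y <= max(y1, y2) + tol
}
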