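# Configuration loading and validation, unit normalisation, deterministic
# run orchestration, trajectory/event output and synthetic fixtures. The
# internal unit system is um / s / uM; config values carry explicit units
# that are converted at load.

unit_scale <- local({
  tab <- c("uM" = 1, "nM" = 1e-3, "mM" = 1e3,
           "uM/s" = 1, "nM/s" = 1e-3, "mM/s" = 1e3,
           "1/s" = 1, "s^-1" = 1, "1/min" = 1 / 60,
           "uM^-1 s^-1" = 1, "nM^-1 s^-1" = 1e3, "mM^-1 s^-1" = 1e-3,
           "um^2/s" = 1, "s" = 1, "min" = 60, "ms" = 1e-3,
           "um" = 1, "nm" = 1e-3,
           "uM um" = 1, "pits/(um^2 s)" = 1, "um/s" = 1)
  function(unit) {
    if (is.null(unit) || !nzchar(unit)) return(1)
    if (!unit %in% names(tab))
      stop("unsupported unit '", unit, "'")
    tab[[unit]]
  }
})

#' Normalise a config value to internal units
#'
#' Internal units are um, s, uM (so e.g. `200 nM/s` becomes `0.2`).
#'
#' @param x A number, or a list with `value` and `unit`.
#' @param name Parameter name for error messages.
#' @return Numeric scalar in internal units.
#' @export
normalize_value <- function(x, name = "parameter") {
  if (is.numeric(x)) return(x)
  if (is.list(x) && !is.null(x$value)) {
    sc <- tryCatch(unit_scale(x$unit),
                   error = function(e) stop("parameter '", name, "': ",
                                            conditionMessage(e)))
    return(x$value * sc)
  }
  stop("parameter '", name, "' must be a number or {value, unit}")
}

MODEL_KINDS <- c("phospho", "compartment", "endocytosis", "full")
STOCHASTIC_MODELS <- c("endocytosis", "full")

#' Load and validate a model run configuration
#'
#' The YAML schema has top-level fields `model` (one of `phospho`,
#' `compartment`, `endocytosis`, `full`), `duration` (s), optional `seed`
#' (mandatory for models with stochastic modules), and `params`, a mapping
#' of run-function arguments; values may be plain numbers (internal units)
#' or `{value, unit}` pairs that are normalised at load. Placeholder
#' provenance may be flagged per parameter with `provenance: placeholder`
#' and is reported at load.
#'
#' @param path Path to a YAML config file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  errs <- character()
  if (is.null(raw$model) || !raw$model %in% MODEL_KINDS)
    errs <- c(errs, paste0("model: must be one of ",
                           paste(MODEL_KINDS, collapse = ", ")))
  if (is.null(raw$duration)) errs <- c(errs, "duration: missing")
  if (!is.null(raw$model) && raw$model %in% STOCHASTIC_MODELS &&
      is.null(raw$seed))
    errs <- c(errs, paste0("seed: mandatory for the stochastic '", raw$model,
                           "' model"))
  params <- list()
  placeholders <- character()
  for (nmp in names(raw$params %||% list())) {
    x <- raw$params[[nmp]]
    if (is.character(x)) { params[[nmp]] <- x; next }
    val <- tryCatch(normalize_value(x, nmp), error = function(e) {
      errs <<- c(errs, conditionMessage(e)); NULL
    })
    if (!is.null(val)) params[[nmp]] <- val
    if (is.list(x) && identical(x$provenance, "placeholder"))
      placeholders <- c(placeholders, nmp)
  }
  if (length(errs))
    stop("invalid config '", path, "':\n  ", paste(errs, collapse = "\n  "))
  if (length(placeholders))
    message("placeholder-provenance parameters: ",
            paste(placeholders, collapse = ", "))
  structure(list(model = raw$model, duration = normalize_value(raw$duration),
                 seed = raw$seed, params = params, path = path),
            class = "run_config")
}

#' Execute a run configuration
#'
#' Dispatches to the bundled model runner, then writes the trajectory
#' (`trajectory.csv`), the event log (`events.jsonl`) and a run manifest
#' (`manifest.json` with the config hash, package version and time-step
#' statistics) into `out_dir`. Deterministic for a fixed seed: the same
#' config and seed produce byte-identical trajectory files.
#'
#' @param config A `run_config` from [load_config()], or a path to one.
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return The model result object, invisibly.
#' @export
run_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  args <- config$params
  args$duration <- config$duration
  if (!is.null(config$seed) && config$model %in% STOCHASTIC_MODELS)
    args$seed <- config$seed
  runner <- switch(config$model,
                   phospho = run_phospho_model,
                   compartment = run_compartment_model,
                   endocytosis = run_endocytosis_model,
                   full = run_full_model)
  bad <- setdiff(names(args), names(formals(runner)))
  if (length(bad)) stop("unknown parameters for model '", config$model,
                        "': ", paste(bad, collapse = ", "))
  res <- do.call(runner, args)
  if (!is.null(out_dir)) write_outputs(res, config, out_dir)
  invisible(res)
}

write_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(res$trace),
                   file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  ev <- if (!is.null(res$events)) res$events else events_tbl(res$sim)
  con <- file(file.path(out_dir, "events.jsonl"), "w")
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      row <- as.list(ev[i, ])
      row <- row[!vapply(row, function(v) all(is.na(unlist(v))), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  close(con)
  dg <- diagnostics(res$sim)
  manifest <- list(
    model = config$model,
    config_hash = unname(tools::md5sum(config$path)),
    package_version = as.character(utils::packageVersion("vesiflow")),
    seed = config$seed,
    duration = config$duration,
    n_steps = res$sim$step,
    dt = list(min = min(dg$dt), median = stats::median(dg$dt), max = max(dg$dt)),
    max_local_rel_err = max(10^dg$eps_local))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Generate a synthetic raster + config fixture
#'
#' Emits a PNG layout and a matching YAML config reproducing the schematic
#' geometry of the bundled model setups at a configurable grid size.
#'
#' @param kind One of `"well_mixed"`, `"storage_region"`, `"apical_patch"`,
#'   `"full_cell"`.
#' @param dir Output directory.
#' @param nrow,ncol Grid size (ignored for `well_mixed`).
#' @param passages,permeability Storage-region ring gaps and restriction.
#' @param seed Seed recorded in the config.
#' @return Invisibly, a list with `png`, `config` paths and the layout.
#' @export
generate_fixture <- function(kind = c("well_mixed", "storage_region",
                                      "apical_patch", "full_cell"),
                             dir = ".", nrow = 30, ncol = 30,
                             passages = 2, permeability = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cmap <- data.frame(
    descriptor = c("cytosol", "storage", "lumen"),
    color = c("#FFFFFF", "#4040C0", "#C0C0C0"),
    restriction = c(1, permeability, 1))
  layout <- switch(kind,
    well_mixed = matrix("cytosol", 1, 1),
    storage_region = storage_layout(nrow, ncol),
    apical_patch = rbind(matrix("lumen", 1, ncol), matrix("cytosol", 1, ncol)),
    full_cell = {
      l <- matrix("cytosol", nrow, ncol)
      l[1, ] <- "lumen"
      l[max(4L, nrow - 8L):(nrow - 3L),
        (ncol %/% 2 - 2L):(ncol %/% 2 + 3L)] <- "storage"
      l
    })
  sp <- simulation_space(layout, ds = 1,
                         restriction = stats::setNames(cmap$restriction,
                                                       cmap$descriptor))
  if (kind == "storage_region" && passages > 0) {
    ring <- region_boundary_faces(sp, "storage")
    if (passages > nrow(ring))
      stop("requested ", passages, " passages but the ring has ", nrow(ring),
           " faces")
  }
  png_path <- file.path(dir, paste0(kind, ".png"))
  write_space_png(sp, png_path, cmap)
  model <- switch(kind, well_mixed = "phospho", storage_region = "compartment",
                  apical_patch = "endocytosis", full_cell = "full")
  cfg <- list(model = model, duration = 300, seed = seed,
              params = switch(kind,
                well_mixed = list(influx = list(value = 50, unit = "nM/s")),
                storage_region = list(permeability = permeability,
                                      passages = passages,
                                      nrow = nrow, ncol = ncol),
                apical_patch = list(influx = list(value = 100, unit = "nM/s")),
                full_cell = list(variant = "activation")))
  cfg_path <- file.path(dir, paste0(kind, ".yaml"))
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(png = png_path, config = cfg_path, layout = layout))
}
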