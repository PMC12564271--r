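# Run configuration, reports and field export.
#
# Configs are written in the device's units (mm, Pa, s); all internal
# computation is SI, with conversion at this boundary only.

config_blocks <- c("geometry", "fluid", "waveform", "solver", "sweep",
                   "observation", "grid", "output_dir")

default_run_config <- function() {
  list(
    geometry = unclass(channel_geometry())[
      c("b1", "h3", "b2", "h2", "L1", "L2", "L_trans", "R", "x_step")],
    fluid = unclass(fluid_props()),
    waveform = list(
      pwss = list(period = 0.8, mean_wss = 0.5, pulse_amplitude = 1.0,
                  peak_time = 0.11, n_harmonics = 8L, dt = 0.01,
                  concentration = 10),
      owss = list(period = 0.8, mean_wss = -0.02,
                  oscillation_amplitude = 0.1, n_harmonics = 8L, dt = 0.01,
                  peak_time = 0.11, concentration = 3)
    ),
    solver = unclass(solver_config()),
    sweep = unclass(sweep_spec()),
    observation = unclass(observation_set()),
    grid = list(base_dx = 2.5e-4, base_dy = 5e-6, refine_factor = 100,
                refine_window = c(13.5, 14.5), growth = 1.3),
    output_dir = "."
  )
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop(sprintf("config block '%s' must be a mapping",
                                   block))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in config block '%s': %s", block,
                 paste(unknown, collapse = ", ")))
  }
  defaults[names(user)] <- user
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration, validates every key, fills all
#' defaults in explicitly, and computes a content hash.  Recognized blocks:
#' `geometry`, `fluid`, `waveform` (`pwss`/`owss` sub-blocks), `solver`,
#' `sweep`, `observation`, `grid`, `output_dir`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Object of class `run_config`: fully explicit nested list plus
#'   `hash` (md5 of the canonical content).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_run_config(raw)
}

#' @rdname load_config
#' @param x Named list with any subset of the configuration blocks.
#' @export
as_run_config <- function(x) {
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop("config must be a mapping")
  unknown <- setdiff(names(x), config_blocks)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  d <- default_run_config()
  cfg <- list(
    geometry = merge_block(d$geometry, x$geometry, "geometry"),
    fluid = merge_block(d$fluid, x$fluid, "fluid"),
    waveform = list(
      pwss = merge_block(d$waveform$pwss,
                         if (is.null(x$waveform)) NULL else x$waveform$pwss,
                         "waveform/pwss"),
      owss = merge_block(d$waveform$owss,
                         if (is.null(x$waveform)) NULL else x$waveform$owss,
                         "waveform/owss")
    ),
    solver = merge_block(d$solver, x$solver, "solver"),
    sweep = merge_block(d$sweep, x$sweep, "sweep"),
    observation = merge_block(d$observation, x$observation, "observation"),
    grid = merge_block(d$grid, x$grid, "grid"),
    output_dir = if (is.null(x$output_dir)) d$output_dir else
      as.character(x$output_dir)
  )
  if (!is.null(x$waveform)) {
    unknown <- setdiff(names(x$waveform), c("pwss", "owss"))
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in config block 'waveform': %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  # validate by constructing the domain objects (errors name the key)
  do.call(channel_geometry, cfg$geometry)
  do.call(fluid_props, cfg$fluid)
  do.call(sweep_spec, cfg$sweep)
  do.call(observation_set, cfg$observation)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' Content hash of a run configuration
#'
#' md5 over the canonical (name-sorted, full-precision JSON) serialization
#' of the configuration, excluding the hash field itself.  The hash changes
#' iff any configuration value changes.
#'
#' @param cfg A `run_config` (or plain config list).
#' @return Character md5 digest.
#' @export
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$hash <- NULL
  canonical <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(canonical(cfg), auto_unbox = TRUE,
                              digits = I(17)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run configuration
#'
#' @param cfg A `run_config`.
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$hash <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE), path)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

design_result_to_list <- function(r) {
  vm <- function(v) {
    list(exists = v$exists, area_mm2 = v$area_mm2,
         center_mm = if (is.null(v$center_mm)) NULL else
           as.list(v$center_mm),
         reattachment_mm = v$reattachment_mm, time = v$time)
  }
  list(
    geometry = unclass(r$geometry),
    rmse_per_point = as.list(r$rmse_per_point),
    rmse_avg = r$rmse_avg,
    partII_rmse = r$partII_rmse,
    partII_nrmse = r$partII_nrmse,
    vortex = list(t_p = vm(r$vortex$t_p), t_m = vm(r$vortex$t_m)),
    vortex_wss_min = r$vortex_wss_min,
    criterion_met = r$criterion_met,
    threshold = r$threshold
  )
}

#' Write a machine- and human-readable design report
#'
#' Writes `report.json` (full per-candidate records at full numeric
#' precision) and `report.csv` (summary table) for the results of a sweep or
#' a list of [evaluate_design()] results.
#'
#' @param results A `design_sweep` or non-empty list of `design_result`s.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` whose hash is embedded in the report.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(results, dir, config = NULL) {
  if (inherits(results, "design_sweep")) results <- results$results
  if (inherits(results, "design_result")) results <- list(results)
  if (!length(results)) stop("empty results: nothing to report")
  if (!all(vapply(results, inherits, logical(1), "design_result"))) {
    stop("results must be design_result objects")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    config_hash = if (is.null(config)) NA_character_ else config$hash,
    n_candidates = length(results),
    candidates = lapply(results, design_result_to_list)
  )
  json_path <- file.path(dir, "report.json")
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, null = "null"), json_path)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(b1 = r$geometry$b1, h3 = r$geometry$h3, b2 = r$geometry$b2,
               rmse_avg = r$rmse_avg, partII_rmse = r$partII_rmse,
               vortex_area_tp_mm2 = r$vortex$t_p$area_mm2,
               vortex_area_tm_mm2 = r$vortex$t_m$area_mm2,
               criterion_met = r$criterion_met,
               config_hash = payload$config_hash)
  }))
  csv_path <- file.path(dir, "report.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' @rdname write_report
#' @param path Path to a previously written `report.json`.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Export a flow field as a legacy-VTK rectilinear grid
#'
#' ASCII legacy VTK (version 3.0) `RECTILINEAR_GRID` file with the
#' streamfunction as point data and pressure, cell-centered velocity and
#' the solid mask as cell data, for inspection in ParaView and similar
#' viewers.
#'
#' @param field A `flow_field` (or NULL for a grid/mask-only export).
#' @param grid A [build_grid()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(field, grid, path) {
  nx <- grid$nx; ny <- grid$ny
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(v) paste(formatC(v, format = "g", digits = 9),
                           collapse = " ")
  w("# vtk DataFile Version 3.0")
  w("stepwss mid-plane field")
  w("ASCII")
  w("DATASET RECTILINEAR_GRID")
  w("DIMENSIONS %d %d 1", nx + 1L, ny + 1L)
  w("X_COORDINATES %d double", nx + 1L); w("%s", num(grid$xf))
  w("Y_COORDINATES %d double", ny + 1L); w("%s", num(grid$yf))
  w("Z_COORDINATES 1 double"); w("0")
  if (!is.null(field)) {
    psi <- streamfunction(field, grid, div_tol = Inf)
    w("POINT_DATA %d", (nx + 1L) * (ny + 1L))
    w("SCALARS streamfunction double 1")
    w("LOOKUP_TABLE default")
    w("%s", num(as.numeric(psi)))   # column-major: x varies fastest, as VTK expects
  }
  w("CELL_DATA %d", nx * ny)
  w("SCALARS solid_mask int 1")
  w("LOOKUP_TABLE default")
  w("%s", paste(as.integer(grid$solid), collapse = " "))
  if (!is.null(field)) {
    uc <- 0.5 * (field$u[1:nx, , drop = FALSE] +
                   field$u[2:(nx + 1L), , drop = FALSE])
    vc <- 0.5 * (field$v[, 1:ny, drop = FALSE] +
                   field$v[, 2:(ny + 1L), drop = FALSE])
    w("SCALARS pressure double 1"); w("LOOKUP_TABLE default")
    w("%s", num(as.numeric(field$p)))
    w("VECTORS velocity double")
    w("%s", paste(apply(cbind(as.numeric(uc), as.numeric(vc), 0), 1L,
                        function(r) num(r)), collapse = "\n"))
  }
  invisible(path)
}
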