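#' Write the recorded time series to CSV
#'
#' Column names carry the units (`t_day`, `thickness_center_cm`, ...).
#'
#' @param sim a `scar_sim` result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(sim, path) {
  utils::write.csv(sim$series, path, row.names = FALSE)
  invisible(path)
}

#' Write outcome metrics to JSON
#'
#' @param metrics one-row data frame from [extract_metrics()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(as.list(metrics[1, , drop = TRUE]), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' JSON document with optional blocks `parameters` (flat overrides of the
#' shipped defaults), `geometry` (`length_x`, `height_y`, `W`, `s`),
#' `solver` (any [solver_config()] argument), and `scenario`
#' (`"wound"`, `"intact"`, or a numeric `collagen_fraction` in (0, 1]).
#'
#' @param path JSON file path.
#' @return list with `params`, `spec`, `cfg`, `collagen_fraction`,
#'   `fibroblast_fraction`.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(scar_params, as.list(doc$parameters))
  geo <- as.list(doc$geometry)
  if (identical(doc$scenario, "intact")) geo$W <- 0
  spec <- do.call(domain_spec, geo)
  cfg <- do.call(solver_config, as.list(doc$solver))
  cf <- if (!is.null(doc$collagen_fraction)) doc$collagen_fraction else 0.2
  ff <- if (!is.null(doc$fibroblast_fraction)) doc$fibroblast_fraction else 0.2
  list(params = params, spec = spec, cfg = cfg,
       collagen_fraction = cf, fibroblast_fraction = ff)
}

#' Execute a configured run and write its outputs
#'
#' Runs the simulation described by a configuration file (or the list
#' returned by [read_run_config()]) and writes `timeseries.csv`,
#' `metrics.json`, and a copy of the configuration into `out_dir`.
#'
#' @param config path to a JSON run configuration, or the parsed list.
#' @param out_dir output directory (created if missing).
#' @param snapshot_days days at which to write VTK mesh+field snapshots.
#' @return the `scar_sim` result, invisibly.
#' @export
run_from_config <- function(config, out_dir, snapshot_days = numeric(0)) {
  rc <- if (is.character(config)) read_run_config(config) else config
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  st <- check_stability(rc$params)
  writeLines(sprintf("stability margin: ratio %.6g (%s)", st$ratio,
                     if (st$pass) "pass" else "FAIL"),
             file.path(out_dir, "run.log"))
  sim <- run_simulation(rc$params, rc$spec, rc$cfg,
                        fibroblast_fraction = rc$fibroblast_fraction,
                        collagen_fraction = rc$collagen_fraction)
  write_timeseries(sim, file.path(out_dir, "timeseries.csv"))
  met <- extract_metrics(sim, rc$spec, t_end = rc$cfg$t_end)
  write_metrics_json(met, file.path(out_dir, "metrics.json"))
  cfg_copy <- list(parameters = rc$params[.param_names_all],
                   geometry = unclass(rc$spec),
                   collagen_fraction = rc$collagen_fraction,
                   fibroblast_fraction = rc$fibroblast_fraction)
  jsonlite::write_json(cfg_copy, file.path(out_dir, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(snapshot_days) > 0)
    write_vtk(sim$mesh, sim$state,
              file.path(out_dir, sprintf("snapshot_day%.0f.vtk", max(snapshot_days))))
  invisible(sim)
}

#' Write a mesh with nodal fields as a legacy ASCII VTK file
#'
#' @param mesh a `scar_mesh`.
#' @param state nodal state matrix (columns written as point data).
#' @param path output `.vtk` path.
#' @return the path, invisibly.
#' @export
write_vtk <- function(mesh, state, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "scarfem snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  # boundary membership as a bit mask (1 = B.I, 2 = B.II, 4 = B.III, 8 = B.IV)
  tag <- integer(n)
  tag[mesh$bnd$BI] <- bitwOr(tag[mesh$bnd$BI], 1L)
  tag[mesh$bnd$BII] <- bitwOr(tag[mesh$bnd$BII], 2L)
  tag[mesh$bnd$BIII] <- bitwOr(tag[mesh$bnd$BIII], 4L)
  tag[mesh$bnd$BIV] <- bitwOr(tag[mesh$bnd$BIV], 8L)
  writeLines(c("SCALARS boundary_tag int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", tag), con)
  for (cn in colnames(state)) {
    writeLines(c(sprintf("SCALARS %s float 1", cn), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", state[, cn]), con)
  }
  invisible(path)
}

#' Deterministic small fixtures for verification
#'
#' @param kind one of `"tiny-mesh"` (two-element unit square),
#'   `"quasi-1d"` (one-element-tall strip), `"sheared-mesh"` (structured mesh
#'   with area-ratio quality 0.3), `"equilibrium-state"` (mesh plus state at
#'   the intact-skin equilibrium).
#' @param params a [scar_params()] list (used by `"equilibrium-state"`).
#' @return the fixture object (a `scar_mesh`, or a list for
#'   `"equilibrium-state"`).
#' @export
make_fixtures <- function(kind = c("tiny-mesh", "quasi-1d", "sheared-mesh",
                                   "equilibrium-state"),
                          params = scar_params()) {
  kind <- match.arg(kind)
  tg <- .default_mesh_target()
  if (kind == "tiny-mesh") {
    tg$ny <- 1L
    return(.structured_mesh(c(0, 1), c(1, 1), tg,
                            gen = list(target = tg, focus = 0.5)))
  }
  if (kind == "quasi-1d") {
    tg$ny <- 1L
    xg <- seq(0, 10, by = 0.25)
    return(.structured_mesh(xg, rep(0.15, length(xg)), tg,
                            gen = list(target = tg, focus = 4)))
  }
  if (kind == "sheared-mesh") {
    tg$ny <- 1L
    return(.structured_mesh(c(0, 0.15, 0.65, 1), rep(0.3, 4), tg,
                            gen = list(target = tg, focus = 0.5)))
  }
  spec <- domain_spec(W = 0)
  mesh <- build_mesh(spec)
  state <- initial_state(mesh, params, spec)
  list(mesh = mesh, state = state, spec = spec)
}
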