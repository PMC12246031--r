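#' Outcome metrics of a simulation
#'
#' Extracts the hypertrophy and contraction outcomes from a recorded time
#' series: maximum central tissue thickness within the simulated year
#' (`TH_max`), its day (`TH_day`, earliest in case of ties), the thickness on
#' the final day (`TH_end`), the minimum wound-boundary position (`WB_min`,
#' maximal contraction) with its day (`WB_day`), the final-day boundary
#' (`WB_end`), and the maximal contraction percentage
#' `100 (W - WB_min) / W`. Also records the cross terms used by the
#' contraction-hypertrophy report: thickness on the day of maximal
#' contraction and boundary on the day of maximal thickness.
#'
#' @param sim a `scar_sim` result or its `series` data frame.
#' @param spec the [domain_spec()] of the run (for the initial wound
#'   half-width `W`).
#' @param t_end required final day of the series (default 365).
#' @return one-row data frame of metrics.
#' @export
extract_metrics <- function(sim, spec, t_end = 365) {
  s <- if (inherits(sim, "scar_sim")) sim$series else sim
  if (max(s$t_day) < t_end - 1e-6)
    stop("incomplete series: ends at day ", max(s$t_day), " < ", t_end)
  th <- s$thickness_center_cm; wb <- s$wound_boundary_cm; tt <- s$t_day
  i_th <- which.max(th); i_wb <- which.min(wb)
  at <- function(y, day) stats::approx(tt, y, xout = day, rule = 2,
                                       ties = "ordered")$y
  W <- spec$W
  data.frame(
    TH_max = th[i_th], TH_day = tt[i_th], TH_end = at(th, t_end),
    WB_min = wb[i_wb], WB_day = tt[i_wb], WB_end = at(wb, t_end),
    contraction_max = if (W > 0) 100 * (W - wb[i_wb]) / W else NA_real_,
    TH_at_WB_day = th[i_wb], WB_at_TH_day = wb[i_th],
    day_gap = abs(tt[i_th] - tt[i_wb]),
    TH_peak_diff = abs(th[i_th] - th[i_wb]))
}

#' Standardize sweep outcomes into z-scores
#'
#' For each outcome `r` and signed variation fraction `j`, standardizes the
#' outcome values across the varied parameters:
#' `z = (x - mean(x)) / sd(x)` with the sample standard deviation. The
#' control run (fraction 0) is excluded from the groups.
#'
#' @param metrics data frame with columns `parameter`, `fraction`, and one
#'   column per outcome.
#' @param outcomes outcome column names to standardize.
#' @return long data frame with columns `parameter`, `fraction`, `outcome`,
#'   `value`, `z`.
#' @export
compute_z_scores <- function(metrics,
                             outcomes = c("TH_max", "TH_day", "TH_end")) {
  m <- metrics[metrics$fraction != 0, , drop = FALSE]
  out <- list()
  for (r in outcomes) {
    for (j in sort(unique(m$fraction))) {
      g <- m[m$fraction == j, , drop = FALSE]
      if (nrow(g) < 2L)
        stop("need at least 2 varied parameters per variation group")
      x <- g[[r]]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) {
        warning("zero sample SD in group (", r, ", ", j, "); z set to 0")
        z <- rep(0, length(x))
      } else {
        z <- (x - mean(x)) / s
      }
      out[[length(out) + 1L]] <- data.frame(
        parameter = g$parameter, fraction = j, outcome = r, value = x, z = z)
    }
  }
  do.call(rbind, out)
}

#' Aggregate z-scores into sensitivity scores
#'
#' `S_i^r = sum_j |z_ij^r|` over the signed variations, and
#' `S_i^total = sum_r S_i^r` over the thickness outcomes; also reports each
#' parameter's share of the total.
#'
#' @param zscores output of [compute_z_scores()].
#' @return data frame with one row per parameter: one `S_<outcome>` column
#'   per outcome, `S_total`, and `share` (fraction of the summed totals),
#'   sorted by decreasing `S_total`.
#' @export
sensitivity_scores <- function(zscores) {
  pars <- unique(zscores$parameter)
  outs <- unique(zscores$outcome)
  res <- data.frame(parameter = pars)
  for (r in outs) {
    zr <- zscores[zscores$outcome == r, , drop = FALSE]
    agg <- tapply(abs(zr$z), zr$parameter, sum)
    res[[paste0("S_", r)]] <- as.numeric(agg[pars])
  }
  res$S_total <- rowSums(res[, paste0("S_", outs), drop = FALSE])
  res$share <- res$S_total / sum(res$S_total)
  res[order(-res$S_total), ]
}

.run_key <- function(name, fraction, delta_m) {
  sprintf("%s_%+.4f_dm%.4f", name, fraction, delta_m)
}

#' Run the one-at-a-time sensitivity sweep
#'
#' Executes one simulation per (parameter, variation) of the plan, at each
#' myofibroblast-apoptosis level, extracts the outcome metrics, and builds
#' the z-score and sensitivity tables per level. Runs are cached as small
#' CSV files keyed by (parameter, fraction, level), so an interrupted sweep
#' resumes without recomputation. Individual run failures are recorded and
#' excluded from the group statistics, not fatal.
#'
#' @param base a [scar_params()] list (its `delta_m` is overridden by each
#'   level of the plan).
#' @param plan a [variation_plan()].
#' @param spec a [domain_spec()].
#' @param cfg a [solver_config()].
#' @param out_dir directory for cache and result tables; `NULL` disables
#'   caching.
#' @param resume reuse cached runs if present.
#' @param runner function `(params, spec, cfg)` returning a `scar_sim` (or a
#'   series data frame); defaults to [run_simulation()]. Injectable so the
#'   pipeline can be exercised with inexpensive surrogates.
#' @return list with one entry per apoptosis level, each holding `metrics`,
#'   `zscores`, `scores`, `fig3`, and `failures`.
#' @export
run_sweep <- function(base, plan, spec, cfg = solver_config(),
                      out_dir = NULL, resume = TRUE,
                      runner = NULL) {
  if (is.null(runner))
    runner <- function(params, spec, cfg) run_simulation(params, spec, cfg)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  levels_out <- list()
  for (dm in plan$apoptosis_levels) {
    pl <- base; pl$delta_m <- dm
    pl <- update_dependent_params(pl); class(pl) <- "scar_params"
    vars <- generate_variations(pl, plan)
    rows <- list(); failures <- character(0)
    for (v in vars) {
      key <- .run_key(v$name, v$fraction, dm)
      cache_file <- if (!is.null(out_dir))
        file.path(out_dir, paste0("cache_", key, ".csv")) else NULL
      met <- NULL
      if (resume && !is.null(cache_file) && file.exists(cache_file)) {
        met <- utils::read.csv(cache_file)
      } else {
        met <- tryCatch({
          sim <- runner(v$params, spec, cfg)
          extract_metrics(sim, spec, t_end = cfg$t_end)
        }, error = function(e) {
          warning("run ", key, " failed: ", conditionMessage(e))
          NULL
        })
        if (!is.null(met) && !is.null(cache_file))
          utils::write.csv(met, cache_file, row.names = FALSE)
      }
      if (is.null(met)) {
        failures <- c(failures, key)
        next
      }
      met$parameter <- v$name; met$fraction <- v$fraction
      met$delta_m <- dm; met$stable <- v$stable
      rows[[length(rows) + 1L]] <- met
    }
    metrics <- do.call(rbind, rows)
    zs <- compute_z_scores(metrics)
    sc <- sensitivity_scores(zs)
    fig3 <- contraction_hypertrophy_report(metrics)
    if (!is.null(out_dir)) {
      tag <- sprintf("dm%.4f", dm)
      utils::write.csv(metrics, file.path(out_dir, paste0("metrics_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(zs, file.path(out_dir, paste0("zscores_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(sc, file.path(out_dir, paste0("scores_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(fig3, file.path(out_dir, paste0("fig3_points_", tag, ".csv")),
                       row.names = FALSE)
    }
    levels_out[[sprintf("dm_%g", dm)]] <-
      list(metrics = metrics, zscores = zs, scores = sc, fig3 = fig3,
           failures = failures)
  }
  levels_out
}

#' Contraction-hypertrophy relationship data
#'
#' Emits, per run, the three scatter points relating wound-boundary position
#' and central thickness: (boundary at maximal contraction, thickness then),
#' (boundary at maximal thickness, maximal thickness), and the day-365 pair;
#' plus the day gap between the two maxima and the thickness difference
#' between them.
#'
#' @param metrics metrics data frame from [run_sweep()] or a row-bound set of
#'   [extract_metrics()] outputs (needs a `parameter` column or rownames).
#' @return data frame with one row per run and columns for the three point
#'   pairs, `day_gap` and `TH_peak_diff`.
#' @export
contraction_hypertrophy_report <- function(metrics) {
  if (nrow(metrics) < 1L) stop("no runs supplied")
  data.frame(
    parameter = if (!is.null(metrics$parameter)) metrics$parameter
                else rownames(metrics),
    fraction = if (!is.null(metrics$fraction)) metrics$fraction else NA,
    wb_at_max_contraction = metrics$WB_min,
    th_at_max_contraction = metrics$TH_at_WB_day,
    wb_at_max_thickness = metrics$WB_at_TH_day,
    th_max = metrics$TH_max,
    wb_end = metrics$WB_end,
    th_end = metrics$TH_end,
    day_gap = metrics$day_gap,
    TH_peak_diff = metrics$TH_peak_diff)
}
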