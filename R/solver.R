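#' Solver configuration
#'
#' Settings of the adaptive backward-Euler/Picard time integrator. The
#' defaults implement the reference stepping policy: initial step 0.05 day,
#' maximal step 0.05 day for the first half day and 0.5 day after; growth by
#' 1.1 per converged step; shrink to 80% on Picard non-convergence; after a
#' remesh, non-convergence rewinds one accepted step at half the step, and a
#' second consecutive failure rewinds five accepted steps and halves again.
#' When the domain height at the center is past its maximum and decreasing
#' and the last step converged within two Picard iterations, the maximal
#' step is boosted by 10% (compounding, capped at twice the phase-2 value).
#'
#' @param dt_init initial time step (day).
#' @param dt_max_phase1,phase1_end,dt_max_phase2 maximal step (day) before /
#'   after `phase1_end` (day).
#' @param growth_factor step growth per converged step.
#' @param shrink_factor_picard step shrink on Picard non-convergence.
#' @param shrink_factor_remesh step shrink on post-remesh non-convergence.
#' @param max_picard_iters Picard iteration cap per step.
#' @param fast_converge_iters iteration count counted as fast convergence.
#' @param dt_max_boost boost factor for the maximal step past the thickness
#'   peak; compounds, capped at `dt_max_boost_cap` times `dt_max_phase2`.
#' @param dt_max_boost_cap cap multiplier for the boost.
#' @param rollback_depth accepted states retained for rollback.
#' @param quality_threshold mesh area-ratio quality below which remeshing is
#'   triggered.
#' @param quality_birth_factor the effective trigger is
#'   `min(quality_threshold, quality_birth_factor * birth quality)` of the
#'   current mesh, so geometries that cannot reach the nominal quality do
#'   not remesh on every step.
#' @param picard_tolerance relative L2 update norm for Picard convergence.
#' @param t_end final time (day).
#' @param dt_min abort threshold for the time step (day).
#' @param mesh list of mesh targets passed to [build_mesh()].
#' @param include_mechanics,include_reactions,include_chemotaxis physics
#'   switches (all `TRUE` for the full model; used for verification).
#' @param dirichlet_species impose the intact-skin equilibrium on boundary
#'   B.II for N, M, c (`TRUE` for the full model).
#' @param surface_load keep the active-potential flux on the free top
#'   surface (see the methods vignette for the discretization discussion).
#' @param negative_tolerance abort when a density drops below minus this
#'   fraction of its characteristic scale (scheme-induced negativity is a
#'   diagnostic error, not something to clamp).
#' @param max_attempts_per_step guard against remesh/shrink livelock.
#' @param verbose print one line per accepted step.
#' @param test_fail_hook internal testing hook: function(t, just_remeshed)
#'   returning TRUE forces a Picard failure.
#' @return object of class `scar_solver_config`.
#' @export
solver_config <- function(dt_init = 0.05,
                          dt_max_phase1 = 0.05, phase1_end = 0.5,
                          dt_max_phase2 = 0.5,
                          growth_factor = 1.1,
                          shrink_factor_picard = 0.8,
                          shrink_factor_remesh = 0.5,
                          max_picard_iters = 6L,
                          fast_converge_iters = 2L,
                          dt_max_boost = 1.1,
                          dt_max_boost_cap = 2,
                          rollback_depth = 5L,
                          quality_threshold = 0.5,
                          quality_birth_factor = 0.7,
                          picard_tolerance = 1e-6,
                          t_end = 365,
                          dt_min = 1e-6,
                          mesh = list(),
                          include_mechanics = TRUE,
                          include_reactions = TRUE,
                          include_chemotaxis = TRUE,
                          dirichlet_species = TRUE,
                          surface_load = TRUE,
                          negative_tolerance = 5e-2,
                          max_attempts_per_step = 200L,
                          verbose = FALSE,
                          test_fail_hook = NULL) {
  stopifnot(shrink_factor_picard > 0, shrink_factor_picard < 1,
            shrink_factor_remesh > 0, shrink_factor_remesh < 1,
            growth_factor > 1, rollback_depth >= 1L)
  structure(as.list(environment()), class = "scar_solver_config")
}

# Picard fixed-point loop over the monolithic system on a fixed mesh
.picard <- function(fem, state_prev, dt, params, cfg) {
  iter <- state_prev
  n <- fem$n
  scales <- .field_scales(params)
  floors <- 1e-3 * scales * sqrt(n)
  for (k in seq_len(cfg$max_picard_iters)) {
    tr <- .assemble_core(fem, state_prev, iter, dt, params, cfg)
    U <- .solve_step(tr, params)
    if (is.null(U) || anyNA(U) || any(!is.finite(U)))
      return(list(converged = FALSE, iters = k, state = NULL))
    newst <- iter
    newst[, .FIELDS] <- matrix(U, n, 9L)
    rel <- 0
    for (f in seq_len(9L)) {
      du <- newst[, f] - iter[, f]
      rel <- max(rel, sqrt(sum(du^2)) / (sqrt(sum(newst[, f]^2)) + floors[f]))
    }
    iter <- newst
    if (rel < cfg$picard_tolerance)
      return(list(converged = TRUE, iters = k, state = iter))
  }
  list(converged = FALSE, iters = cfg$max_picard_iters, state = iter)
}

#' One implicit step by Picard iteration
#'
#' Iterates assemble-and-solve on the current mesh until the relative L2
#' update norm of every field drops below the tolerance. Non-convergence
#' within the iteration cap is returned as a failure flag, not an error.
#'
#' @param mesh a `scar_mesh`.
#' @param state_prev state matrix at the previous time.
#' @param dt time step (day).
#' @param cfg a [solver_config()].
#' @param params a [scar_params()] list.
#' @return list with `converged`, `iters`, and `state` (the new state matrix,
#'   `NULL` if the solve broke down).
#' @export
picard_step <- function(mesh, state_prev, dt, cfg, params) {
  stopifnot(dt > 0)
  .picard(.fem_precompute(mesh), state_prev, dt, params, cfg)
}

#' Advance the Lagrangian mesh with the velocity field
#'
#' Moves every node by `v * dt` and accumulates the displacement, keeping the
#' essential constraints exact (B.IV at x = 0, B.II at x = length_x, B.I at
#' y = 0).
#'
#' @param mesh a `scar_mesh`.
#' @param v nodal velocities, n x 2 (cm/day).
#' @param dt time step (day).
#' @return the moved `scar_mesh`.
#' @export
advance_mesh <- function(mesh, v, dt) {
  L <- max(mesh$nodes[, 1])
  mesh$nodes <- mesh$nodes + dt * v
  mesh$nodes[mesh$bnd$BIV, 1] <- 0
  mesh$nodes[mesh$bnd$BII, 1] <- L
  mesh$nodes[mesh$bnd$BI, 2] <- 0
  mesh
}

#' Adaptive timestep controller
#'
#' Returns the next step and maximal step given the outcome of the last
#' attempted step. On success the step grows by `growth_factor` up to the
#' phase-dependent maximum; past the thickness peak, fast Picard convergence
#' compounds a 10% boost of the maximum (capped).
#'
#' @param t current time (day).
#' @param dt step just taken (day).
#' @param iters Picard iterations of the last step.
#' @param converged logical, last step converged.
#' @param past_peak_decreasing logical: center thickness has passed its
#'   maximum and is decreasing.
#' @param boost current boost multiplier (start at 1).
#' @param cfg a [solver_config()].
#' @return list with `dt` (next step), `dt_max`, `boost`.
#' @export
timestep_controller <- function(t, dt, iters, converged, past_peak_decreasing,
                                boost = 1, cfg = solver_config()) {
  if (!converged)
    return(list(dt = dt * cfg$shrink_factor_picard,
                dt_max = NA_real_, boost = boost))
  in_phase2 <- t >= cfg$phase1_end
  if (in_phase2 && past_peak_decreasing && iters <= cfg$fast_converge_iters)
    boost <- min(boost * cfg$dt_max_boost, cfg$dt_max_boost_cap)
  dt_max <- if (in_phase2) cfg$dt_max_phase2 * boost else cfg$dt_max_phase1
  list(dt = min(dt * cfg$growth_factor, dt_max), dt_max = dt_max,
       boost = boost)
}

# remesh the current configuration and transfer all nodal data onto it
.remesh_state <- function(mesh, state, xw) {
  newmesh <- remesh(mesh, focus = xw)
  # barycentric tolerance is generous here: near-degenerate source elements
  # at a sharp ridge make barycentric units much stricter than physical
  # distance, and clamped coordinates keep the transfer a convex combination
  newstate <- interpolate_fields(mesh, state, newmesh, tol = 0.05,
                                 fallback = "nearest")
  list(mesh = newmesh, state = newstate)
}

#' Run the full biomorphoelastic simulation
#'
#' Integrates the coupled model from t = 0 to `cfg$t_end` days on a moving
#' Lagrangian mesh: monolithic backward-Euler/Picard stepping, mesh motion by
#' the converged velocity, quality-driven remeshing with field transfer, and
#' rollback on persistent post-remesh failures. Deterministic for a given
#' configuration.
#'
#' @param params a [scar_params()] list.
#' @param spec a [domain_spec()].
#' @param cfg a [solver_config()].
#' @param fibroblast_fraction,collagen_fraction initial wound densities as
#'   fractions of the equilibria (see [initial_state()]).
#' @return object of class `scar_sim`: list with `series` (one row per
#'   accepted step: `t_day, dt_day, thickness_center_cm, wound_boundary_cm,
#'   mesh_quality, picard_iters, remeshed`), `diagnostics` (one row per
#'   attempted step), `state`, `mesh`, and the inputs.
#' @export
run_simulation <- function(params, spec, cfg = solver_config(),
                           fibroblast_fraction = 0.2,
                           collagen_fraction = 0.2) {
  st_check <- check_stability(params)
  if (!st_check$pass)
    warning("stability constraint k_c <= delta_c*a_c_II*rho_bar violated (ratio ",
            signif(st_check$ratio, 4), "); the equilibrium may destabilize")
  mesh <- build_mesh(spec, cfg$mesh)
  fem <- .fem_precompute(mesh)
  state <- initial_state(mesh, params, spec,
                         fibroblast_fraction = fibroblast_fraction,
                         collagen_fraction = collagen_fraction)
  t <- 0; dt <- cfg$dt_init; xw <- spec$W
  boost <- 1; th_max_seen <- thickness_at_center(mesh)
  just_remeshed <- FALSE; remesh_failures <- 0L
  birth_q <- mesh_quality(mesh)
  scales <- .field_scales(params)
  hist <- list(list(mesh = mesh, state = state, t = t, xw = xw, dt = dt))
  series <- list(); diags <- list()
  rec_series <- function(t, dt, q, iters, remeshed) {
    series[[length(series) + 1L]] <<- data.frame(
      t_day = t, dt_day = dt,
      thickness_center_cm = thickness_at_center(mesh),
      wound_boundary_cm = xw, mesh_quality = q,
      picard_iters = iters, remeshed = remeshed)
  }
  rec_diag <- function(t, dt, iters, converged, q_before, q_after, remeshed,
                       rollback, minvals) {
    diags[[length(diags) + 1L]] <<- data.frame(
      t_day = t, dt_day = dt, picard_iters = iters, converged = converged,
      quality_before = q_before, quality_after = q_after,
      remeshed = remeshed, rollback = rollback,
      min_N = minvals[1], min_M = minvals[2], min_c = minvals[3],
      min_rho = minvals[4])
  }
  q0 <- mesh_quality(mesh)
  rec_series(0, 0, q0, 0L, FALSE)
  attempts <- 0L
  step_remeshed <- FALSE

  rollback_to <- function(k) {
    keep <- max(1L, length(hist) - k)
    snap <- hist[[keep]]
    hist <<- hist[seq_len(keep)]
    mesh <<- snap$mesh; state <<- snap$state; t <<- snap$t; xw <<- snap$xw
    fem <<- .fem_precompute(mesh)
    birth_q <<- mesh_quality(mesh)
  }

  while (t < cfg$t_end - 1e-9) {
    attempts <- attempts + 1L
    if (attempts > cfg$max_attempts_per_step)
      stop("step at t = ", signif(t, 6), " did not succeed after ",
           cfg$max_attempts_per_step, " attempts (dt = ", signif(dt, 4), ")")
    dt_eff <- min(dt, cfg$t_end - t)
    if (t < cfg$phase1_end - 1e-9 && t + dt_eff > cfg$phase1_end)
      dt_eff <- cfg$phase1_end - t
    q_before <- mesh_quality(mesh)
    res <- .picard(fem, state, dt_eff, params, cfg)
    if (!is.null(cfg$test_fail_hook) &&
        isTRUE(cfg$test_fail_hook(t, just_remeshed)))
      res$converged <- FALSE
    if (!res$converged) {
      rec_diag(t, dt_eff, res$iters, FALSE, q_before, NA, step_remeshed,
               FALSE, rep(NA_real_, 4))
      if (just_remeshed) {
        remesh_failures <- remesh_failures + 1L
        if (remesh_failures >= 2L) {
          rollback_to(cfg$rollback_depth)
          dt <- dt * 0.5
        } else {
          rollback_to(1L)
          dt <- dt * cfg$shrink_factor_remesh
        }
        just_remeshed <- FALSE
        step_remeshed <- FALSE
        diags[[length(diags)]]$rollback <- TRUE
      } else {
        dt <- dt * cfg$shrink_factor_picard
      }
      if (dt < cfg$dt_min)
        stop("timestep underflow at t = ", signif(t, 6),
             " day; aborting with diagnostics")
      next
    }
    newstate <- res$state
    minvals <- c(min(newstate[, "N"]), min(newstate[, "M"]),
                 min(newstate[, "c"]), min(newstate[, "rho"]))
    if (minvals[1] < -cfg$negative_tolerance * scales["N"] ||
        minvals[2] < -cfg$negative_tolerance * scales["M"] ||
        minvals[4] < -cfg$negative_tolerance * scales["rho"])
      stop("negative density beyond tolerance at t = ", signif(t, 6),
           " day (min N/M/rho = ", paste(signif(minvals[c(1, 2, 4)], 3),
                                         collapse = ", "),
           "); refine the mesh or timestep")
    v <- newstate[, c("v1", "v2")]
    moved <- advance_mesh(mesh, v, dt_eff)
    dJ <- .mesh_detJ(moved)
    q_after <- if (any(dJ <= 0)) 0 else min(dJ) / max(dJ)
    if (q_after < min(cfg$quality_threshold,
                      cfg$quality_birth_factor * birth_q)) {
      rec_diag(t, dt_eff, res$iters, TRUE, q_before, q_after, step_remeshed,
               FALSE, minvals)
      if (!step_remeshed) {
        rs <- .remesh_state(mesh, state, xw)
        mesh <- rs$mesh; state <- rs$state
        fem <- .fem_precompute(mesh)
        # a sharply ridged surface may cap the achievable quality below the
        # nominal threshold; the trigger is then relative to this birth value
        birth_q <- mesh_quality(mesh)
        just_remeshed <- TRUE; step_remeshed <- TRUE
        next
      } else {
        # remeshed already and still degenerate: treat as a failed step
        remesh_failures <- remesh_failures + 1L
        if (remesh_failures >= 2L) {
          rollback_to(cfg$rollback_depth)
          dt <- dt * 0.5
        } else {
          rollback_to(1L)
          dt <- dt * cfg$shrink_factor_remesh
        }
        just_remeshed <- FALSE; step_remeshed <- FALSE
        if (dt < cfg$dt_min) stop("timestep underflow after remeshing")
        next
      }
    }
    # accept
    newstate[, "u1"] <- newstate[, "u1"] + dt_eff * v[, 1]
    newstate[, "u2"] <- newstate[, "u2"] + dt_eff * v[, 2]
    xw <- .advect_wound_point(xw, mesh, v[, 1], dt_eff)
    mesh <- moved
    fem <- .fem_precompute(mesh)
    state <- newstate
    t <- t + dt_eff
    rec_diag(t, dt_eff, res$iters, TRUE, q_before, q_after, step_remeshed,
             FALSE, minvals)
    rec_series(t, dt_eff, q_after, res$iters, step_remeshed)
    hist[[length(hist) + 1L]] <- list(mesh = mesh, state = state, t = t,
                                      xw = xw, dt = dt)
    if (length(hist) > cfg$rollback_depth + 1L)
      hist <- hist[-1L]
    th <- thickness_at_center(mesh)
    past_peak <- th < th_max_seen - 1e-12
    th_max_seen <- max(th_max_seen, th)
    ctrl <- timestep_controller(t, dt_eff, res$iters, TRUE, past_peak,
                                boost, cfg)
    dt <- ctrl$dt; boost <- ctrl$boost
    just_remeshed <- FALSE; step_remeshed <- FALSE
    remesh_failures <- 0L
    attempts <- 0L
    if (isTRUE(cfg$verbose))
      message(sprintf("t=%8.3f dt=%6.4f iters=%d q=%.3f th=%.4f xw=%.4f",
                      t, dt_eff, res$iters, q_after, th, xw))
  }
  out <- list(series = do.call(rbind, series),
              diagnostics = do.call(rbind, diags),
              state = state, mesh = mesh, xw = xw,
              params = params, spec = spec, cfg = cfg,
              fibroblast_fraction = fibroblast_fraction,
              collagen_fraction = collagen_fraction)
  class(out) <- "scar_sim"
  out
}

#' @export
print.scar_sim <- function(x, ...) {
  s <- x$series
  cat(sprintf("<scar_sim> %d accepted steps to day %.1f\n", nrow(s) - 1L,
              max(s$t_day)))
  cat(sprintf("  thickness: start %.4f, max %.4f (day %.1f), end %.4f cm\n",
              s$thickness_center_cm[1], max(s$thickness_center_cm),
              s$t_day[which.max(s$thickness_center_cm)],
              s$thickness_center_cm[nrow(s)]))
  cat(sprintf("  wound boundary: start %.4f, min %.4f (day %.1f), end %.4f cm\n",
              s$wound_boundary_cm[1], min(s$wound_boundary_cm),
              s$t_day[which.min(s$wound_boundary_cm)],
              s$wound_boundary_cm[nrow(s)]))
  invisible(x)
}

#' Wound-boundary position of a finished simulation
#'
#' The x-coordinate of the material point initially at the wound edge on the
#' bottom boundary, advected with the velocity field.
#'
#' @param sim a `scar_sim` result.
#' @param day day at which to evaluate (linear interpolation in the recorded
#'   series); `NULL` returns the whole series.
#' @return position (cm) or the series data frame.
#' @export
wound_boundary_position <- function(sim, day = NULL) {
  s <- sim$series
  if (is.null(day)) return(s[, c("t_day", "wound_boundary_cm")])
  stats::approx(s$t_day, s$wound_boundary_cm, xout = day, rule = 2,
                ties = "ordered")$y
}
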