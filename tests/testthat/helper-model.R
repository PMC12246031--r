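# shared fixtures: a low-apoptosis parameter set and small meshes
params_low <- scar_params(delta_m = 0.02)
spec_default <- domain_spec()

# coarse settings for whole-pipeline tests that must stay fast
coarse_cfg <- function(...) {
  solver_config(mesh = list(dx_fine = 0.7, dx_coarse = 0.7, ny = 2L), ...)
}

# implicit-Euler integration of the strain ODE using only strain_rhs as a
# black box (fixed-point solve per step); used against the closed form
integrate_strain_decay <- function(eps0, N, M, c, params, t_end, dt) {
  eps <- eps0
  gv <- matrix(0, 2, 2)
  nstep <- round(t_end / dt)
  for (k in seq_len(nstep)) {
    enew <- eps
    for (it in 1:60) {
      enew <- eps + dt * strain_rhs(enew, gv, N, M, c, params)
    }
    eps <- enew
  }
  eps
}
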