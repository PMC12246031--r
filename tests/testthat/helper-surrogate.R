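# inexpensive deterministic surrogate runner: returns a synthetic series
# whose metrics respond smoothly to the parameters, so the sweep pipeline can
# be exercised without PDE solves
surrogate_runner <- function(params, spec, cfg) {
  tt <- seq(0, cfg$t_end, by = 0.05)
  a <- params$xi * 1e3 + params$k_c * 1e13 + 10 * params$rho_bar
  peak_day <- 40 + 3 * a
  th <- 0.15 + 0.001 * a + 0.05 * a * exp(-((tt - peak_day) / 30)^2)
  wb <- spec$W - 0.3 * a * exp(-((tt - peak_day - 2) / 35)^2)
  data.frame(t_day = tt, dt_day = 1, thickness_center_cm = th,
             wound_boundary_cm = wb, mesh_quality = 1,
             picard_iters = 2L, remeshed = FALSE)
}

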