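test_that("metrics are extracted from a recorded series as defined", {
  tt <- seq(0, 365, by = 1)
  th <- 0.15 + 0.1 * sin(pi * pmin(tt, 120) / 120)
  wb <- 4 - 2 * sin(pi * pmin(tt, 130) / 130)
  s <- data.frame(t_day = tt, thickness_center_cm = th,
                  wound_boundary_cm = wb)
  m <- extract_metrics(s, domain_spec())
  expect_equal(m$TH_max, max(th))
  expect_equal(m$TH_day, 60)
  expect_equal(m$TH_end, th[366])
  expect_equal(m$WB_min, min(wb))
  expect_equal(m$contraction_max, 100 * (4 - min(wb)) / 4)
  expect_error(extract_metrics(s[s$t_day < 300, ], domain_spec()),
               "incomplete")
  # constant thickness: the maximum is the first sample
  s2 <- s; s2$thickness_center_cm <- 0.15
  m2 <- extract_metrics(s2, domain_spec())
  expect_equal(m2$TH_day, 0)
  expect_equal(m2$TH_max, m2$TH_end)
})

test_that("z-scores standardize each variation group to mean 0, sd 1", {
  df <- data.frame(parameter = rep(c("a", "b", "c"), 2),
                   fraction = rep(c(-0.05, 0.05), each = 3),
                   TH_max = c(1, 2, 3, 5, 5, 5),
                   TH_day = c(10, 20, 30, 40, 50, 60),
                   TH_end = c(0.1, 0.2, 0.3, 0.1, 0.4, 0.7))
  expect_warning(z <- compute_z_scores(df), "zero sample SD")
  g <- z[z$outcome == "TH_max" & z$fraction == -0.05, ]
  expect_equal(g$z, c(-1, 0, 1))
  flat <- z[z$outcome == "TH_max" & z$fraction == 0.05, ]
  expect_equal(flat$z, c(0, 0, 0))
  for (r in unique(z$outcome)) for (j in unique(z$fraction)) {
    zz <- z$z[z$outcome == r & z$fraction == j]
    expect_lt(abs(sum(zz)), 1e-12)
    if (stats::sd(zz) > 0) expect_equal(stats::sd(zz), 1, tolerance = 1e-10)
  }
})

test_that("sensitivity scores sum absolute z-scores across variations", {
  z <- data.frame(parameter = c("a", "b", "a", "b"),
                  fraction = c(-0.05, -0.05, 0.05, 0.05),
                  outcome = "TH_max", value = 1:4,
                  z = c(-2, 2, 0, 0))
  s <- sensitivity_scores(z)
  expect_equal(s$S_TH_max[s$parameter == "a"], 2)
  expect_equal(s$S_total[s$parameter == "a"], 2)
  expect_equal(sum(s$share), 1)
  z0 <- z; z0$z <- 0
  s0 <- sensitivity_scores(z0)
  expect_true(all(s0$S_total == 0))
})

test_that("a reduced sweep produces internally consistent tables", {
  plan <- variation_plan(varied = c("xi", "k_c", "rho_bar", "delta_n",
                                    "E_mod", "mu_1", "chi", "zeta"),
                         fractions = c(-0.15, -0.05, 0.05, 0.15),
                         apoptosis_levels = 0.02)
  cfg <- solver_config(t_end = 365)
  out <- run_sweep(params_low, plan, domain_spec(), cfg,
                   runner = surrogate_runner)
  lev <- out$dm_0.02
  expect_equal(nrow(lev$metrics), 8 * 4 + 1)
  z <- lev$zscores
  for (r in unique(z$outcome)) for (j in unique(z$fraction)) {
    zz <- z$z[z$outcome == r & z$fraction == j]
    expect_lt(abs(mean(zz)), 1e-10)
    expect_equal(stats::sd(zz), 1, tolerance = 1e-10)
  }
  expect_equal(nrow(lev$scores), 8)
  expect_equal(nrow(lev$fig3), 33)
  expect_length(lev$failures, 0)
})

test_that("sweep caching resumes without rerunning and is deterministic", {
  plan <- variation_plan(varied = c("xi", "k_c"), fractions = c(-0.15, 0.15),
                         apoptosis_levels = 0.02)
  cfg <- solver_config(t_end = 365)
  dir <- tempfile("sweep")
  calls <- new.env(); calls$n <- 0L
  counting_runner <- function(params, spec, cfg) {
    calls$n <- calls$n + 1L
    surrogate_runner(params, spec, cfg)
  }
  out1 <- run_sweep(params_low, plan, domain_spec(), cfg, out_dir = dir,
                    runner = counting_runner)
  n1 <- calls$n
  out2 <- run_sweep(params_low, plan, domain_spec(), cfg, out_dir = dir,
                    runner = counting_runner)
  expect_equal(calls$n, n1)   # all runs served from cache
  expect_equal(out1$dm_0.02$metrics, out2$dm_0.02$metrics)
  expect_true(file.exists(file.path(dir, "metrics_dm0.0200.csv")))
  expect_true(file.exists(file.path(dir, "scores_dm0.0200.csv")))
})

test_that("failed runs are excluded and reported, not fatal", {
  plan <- variation_plan(varied = c("xi", "k_c", "chi"),
                         fractions = c(-0.05, 0.05),
                         apoptosis_levels = 0.02, control_included = FALSE)
  failing_runner <- function(params, spec, cfg) {
    if (params$chi != params_low$chi) stop("synthetic failure")
    surrogate_runner(params, spec, cfg)
  }
  cfg <- solver_config(t_end = 365)
  w <- capture_warnings(out <- run_sweep(params_low, plan, domain_spec(), cfg,
                                         runner = failing_runner))
  expect_true(any(grepl("failed", w)))
  lev <- out$dm_0.02
  expect_length(lev$failures, 2)
  expect_equal(nrow(lev$metrics), 4)
})

test_that("contraction-hypertrophy report emits in-range point pairs", {
  sims <- lapply(1:3, function(k) {
    p <- params_low; p$xi <- p$xi * (1 + 0.05 * k)
    surrogate_runner(p, domain_spec(), solver_config(t_end = 365))
  })
  mets <- do.call(rbind, lapply(sims, extract_metrics, spec = domain_spec()))
  mets$parameter <- paste0("run", 1:3); mets$fraction <- 0
  rep <- contraction_hypertrophy_report(mets)
  expect_equal(nrow(rep), 3)
  for (k in 1:3) {
    rng <- range(sims[[k]]$thickness_center_cm)
    expect_gte(rep$th_at_max_contraction[k], rng[1])
    expect_lte(rep$th_at_max_contraction[k], rng[2])
    expect_gte(rep$th_max[k], rep$th_end[k])
  }
  expect_true(all(rep$day_gap >= 0))
})
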