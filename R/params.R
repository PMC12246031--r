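#' Model parameters for the biomorphoelastic scar model
#'
#' Constructs a validated parameter set. Defaults are the mean values of the
#' wound-healing model (units: cm, g, cells, day), shipped with the package in
#' `inst/extdata/table1_defaults.json`. The equilibrium exponent `q` and the
#' collagen secretion rate `k_rho` are *dependent* parameters: they are always
#' (re)computed from the intact-skin equilibrium (N = N_bar, M = 0, c = 0,
#' rho = rho_bar) so that the fibroblast and collagen kinetics vanish there.
#'
#' @param ... named overrides of individual parameters, e.g. `delta_m = 0.02`.
#'   Unknown names are an error.
#' @param file optional path to a JSON parameter file with a flat
#'   `parameters` object (same schema as the shipped defaults file).
#' @param validate logical; check invariants (positivity, `nu` in (0, 0.5),
#'   `kappa * N_bar < 1`). Default `TRUE`.
#'
#' @return An object of class `scar_params`: a named list of parameters
#'   including the derived `q` and `k_rho`.
#' @export
#' @examples
#' p <- scar_params(delta_m = 0.02)
#' p$q            # equilibrium exponent, about -0.42
#' p$k_rho        # delta_rho * rho_bar^2
scar_params <- function(..., file = NULL, validate = TRUE) {
  base <- .table1_defaults()
  if (!is.null(file)) {
    doc <- jsonlite::read_json(file, simplifyVector = TRUE)
    vals <- if (!is.null(doc$parameters)) doc$parameters else doc
    base <- .apply_overrides(base, as.list(vals))
  }
  base <- .apply_overrides(base, list(...))
  base <- update_dependent_params(base)
  class(base) <- "scar_params"
  if (validate) validate_params(base)
  base
}

.param_names_independent <- c(
  "D_n", "chi", "D_c", "r_n", "r_m", "r_max", "a_c_I", "kappa", "k_1",
  "delta_n", "delta_m", "k_c", "a_c_II", "delta_c", "eta_I", "eta_II",
  "a_c_III", "k_rho_max", "a_c_IV", "delta_rho", "rho_t", "mu_1", "mu_2",
  "xi", "R_force", "E_mod", "nu", "zeta", "N_bar", "M_bar", "c_bar",
  "rho_bar", "c_tilde")

.param_names_all <- c(.param_names_independent, "q", "k_rho")

.defaults_cache <- new.env(parent = emptyenv())

.table1_defaults <- function() {
  if (is.null(.defaults_cache$p)) {
    path <- system.file("extdata", "table1_defaults.json", package = "scarfem")
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    .defaults_cache$p <- as.list(doc$parameters)
  }
  .defaults_cache$p
}

.apply_overrides <- function(base, over) {
  if (length(over) == 0L) return(base)
  nm <- names(over)
  if (is.null(nm) || any(nm == "")) stop("all parameter overrides must be named")
  unknown <- setdiff(nm, .param_names_all)
  if (length(unknown) > 0L)
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  for (k in nm) base[[k]] <- as.numeric(over[[k]])
  base
}

#' Recompute the dependent parameters q and k_rho
#'
#' @param params a `scar_params` object or plain named list.
#' @return the same list with `q` and `k_rho` set from the equilibrium
#'   equations.
#' @export
update_dependent_params <- function(params) {
  params$q <- solve_q(params)
  params$k_rho <- solve_k_rho(params)
  params
}

#' Equilibrium exponent of the cell proliferation terms
#'
#' Solves R_N(N_bar, M = 0, c = 0) = 0 for the exponent `q` in the
#' proliferation term `r_n [1 - kappa N] N^(1+q)`, giving
#' `q = ln(delta_n / (r_n (1 - kappa N_bar))) / ln(N_bar)`.
#'
#' @param params parameter list (needs `r_n`, `kappa`, `N_bar`, `delta_n`).
#' @return the exponent `q` (dimensionless).
#' @export
solve_q <- function(params) {
  num <- params$delta_n
  den <- params$r_n * (1 - params$kappa * params$N_bar)
  if (!is.finite(num) || num <= 0)
    stop("invalid equilibrium: delta_n must be positive (delta_n = ", num, ")")
  if (!is.finite(den) || den <= 0)
    stop("invalid equilibrium: r_n * (1 - kappa * N_bar) must be positive ",
         "(r_n = ", params$r_n, ", kappa = ", params$kappa,
         ", N_bar = ", params$N_bar, ")")
  if (params$N_bar <= 0)
    stop("invalid equilibrium: N_bar must be positive")
  if (params$N_bar == 1)
    stop("invalid equilibrium: N_bar = 1 makes the exponent indeterminate")
  log(num / den) / log(params$N_bar)
}

#' Equilibrium collagen secretion rate
#'
#' Solves R_rho(N_bar, 0, 0, rho_bar) = 0 for `k_rho`; the fibroblast density
#' cancels, leaving `k_rho = delta_rho * rho_bar^2`.
#'
#' @param params parameter list (needs `delta_rho`, `rho_bar`).
#' @return the secretion rate `k_rho` (g^2 / (cells cm^3 day)).
#' @export
solve_k_rho <- function(params) {
  if (params$rho_bar < 0) stop("rho_bar must be nonnegative")
  params$delta_rho * params$rho_bar^2
}

#' Linear-stability constraint of the intact-skin equilibrium
#'
#' The homogeneous equilibrium is stable against signaling-molecule
#' autocatalysis only if `k_c <= delta_c * a_c_II * rho_bar`. Returns the
#' pass/fail flag and the ratio of the two sides.
#'
#' @param params parameter list.
#' @return list with elements `pass` (logical), `ratio`
#'   (`k_c / (delta_c a_c_II rho_bar)`), and `margin` (right side minus left).
#' @export
check_stability <- function(params) {
  rhs <- params$delta_c * params$a_c_II * params$rho_bar
  ratio <- if (rhs > 0) params$k_c / rhs else Inf
  list(pass = params$k_c <= rhs, ratio = ratio, margin = rhs - params$k_c)
}

#' Validate a parameter set
#'
#' Checks strict positivity of rates, diffusivities and densities,
#' `nu` in (0, 0.5), `kappa * N_bar < 1`, and consistency of the dependent
#' parameters with the equilibrium equations.
#'
#' @param params a `scar_params` object.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_params <- function(params) {
  pos <- c("D_n", "chi", "D_c", "r_n", "r_m", "r_max", "a_c_I", "kappa",
           "k_1", "delta_n", "delta_m", "k_c", "a_c_II", "delta_c", "eta_I",
           "eta_II", "a_c_III", "k_rho_max", "a_c_IV", "delta_rho", "rho_t",
           "mu_1", "mu_2", "xi", "R_force", "E_mod", "zeta", "N_bar",
           "rho_bar", "c_tilde")
  for (k in pos) {
    v <- params[[k]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      stop("parameter ", k, " must be a finite positive number (got ",
           if (is.null(v)) "NULL" else v, ")")
  }
  for (k in c("M_bar", "c_bar")) {
    if (!isTRUE(params[[k]] == 0))
      stop("parameter ", k, " must be 0 (intact-skin equilibrium)")
  }
  if (!(params$nu > 0 && params$nu < 0.5))
    stop("nu must lie in (0, 0.5), got ", params$nu)
  if (!(params$kappa * params$N_bar < 1))
    stop("kappa * N_bar must be < 1, got ", params$kappa * params$N_bar)
  if (abs(params$q - solve_q(params)) > 1e-12 * max(1, abs(params$q)))
    stop("q is inconsistent with the equilibrium equations; ",
         "call update_dependent_params()")
  if (abs(params$k_rho - solve_k_rho(params)) >
      1e-12 * max(params$k_rho, .Machine$double.xmin))
    stop("k_rho is inconsistent with the equilibrium equations; ",
         "call update_dependent_params()")
  if (1 + params$q <= 0)
    stop("1 + q must be positive for the proliferation terms, got ",
         1 + params$q)
  invisible(TRUE)
}

#' @export
print.scar_params <- function(x, ...) {
  cat("<scar_params> biomorphoelastic model parameters (cm/g/cells/day)\n")
  st <- check_stability(x)
  cat(sprintf("  q = %.6g (dependent), k_rho = %.6g (dependent)\n", x$q, x$k_rho))
  cat(sprintf("  stability k_c <= delta_c*a_c_II*rho_bar: %s (ratio %.3g)\n",
              if (st$pass) "satisfied" else "VIOLATED", st$ratio))
  nm <- setdiff(.param_names_all, c("q", "k_rho"))
  vals <- vapply(nm, function(k) x[[k]], numeric(1))
  print(vals)
  invisible(x)
}

#' Names of the independently varied parameters
#'
#' The 30 model parameters varied in the one-at-a-time sensitivity sweep.
#' Excluded are the dependent `q` and `k_rho`, the Poisson ratio `nu`, and the
#' initial fibroblast/collagen densities (tied to the equilibria), leaving 30
#' of the 35 model parameters.
#'
#' @return character vector of length 30.
#' @export
varied_parameter_names <- function() {
  setdiff(.param_names_independent, c("nu", "M_bar", "c_bar"))
}

#' One-at-a-time variation plan for the sensitivity sweep
#'
#' @param varied character vector of parameter names to vary; defaults to the
#'   full 30-parameter set of [varied_parameter_names()].
#' @param fractions signed relative variations; default
#'   `c(-0.15, -0.10, -0.05, 0.05, 0.10, 0.15)`.
#' @param apoptosis_levels myofibroblast apoptosis rates at which the whole
#'   sweep is repeated; default `c(0.02, 0.06)` per day.
#' @param control_included include an unvaried control run per level.
#' @return object of class `scar_variation_plan`.
#' @export
variation_plan <- function(varied = varied_parameter_names(),
                           fractions = c(-0.15, -0.10, -0.05, 0.05, 0.10, 0.15),
                           apoptosis_levels = c(0.02, 0.06),
                           control_included = TRUE) {
  unknown <- setdiff(varied, .param_names_independent)
  if (length(unknown) > 0L)
    stop("unknown parameter name(s) in plan: ", paste(unknown, collapse = ", "))
  bad <- intersect(varied, c("nu", "M_bar", "c_bar"))
  if (length(bad) > 0L)
    stop("parameters held fixed by design cannot be varied: ",
         paste(bad, collapse = ", "))
  if (any(fractions <= -1))
    stop("variation fractions must be > -1")
  structure(list(varied = varied, fractions = fractions,
                 apoptosis_levels = apoptosis_levels,
                 control_included = isTRUE(control_included)),
            class = "scar_variation_plan")
}

#' @export
print.scar_variation_plan <- function(x, ...) {
  n_runs <- length(x$varied) * length(x$fractions) + as.integer(x$control_included)
  cat(sprintf("<scar_variation_plan> %d parameters x %d fractions%s = %d runs per apoptosis level (%s)\n",
              length(x$varied), length(x$fractions),
              if (x$control_included) " + control" else "",
              n_runs, paste(x$apoptosis_levels, collapse = ", ")))
  invisible(x)
}

#' Generate the varied parameter sets of a sweep plan
#'
#' Each returned entry scales exactly one parameter of `base` by
#' `(1 + fraction)`; the dependent `q` and `k_rho` are re-solved for every
#' set, and sets violating the stability constraint are flagged (not
#' dropped). The sequence is deterministic and order-stable: parameters in
#' plan order, fractions in plan order, control (if any) first.
#'
#' @param base a `scar_params` object (its `delta_m` is the level the plan is
#'   generated at).
#' @param plan a `scar_variation_plan`.
#' @return list of records with elements `name`, `fraction`, `params`,
#'   `stable`; the control record has `name = "control"`, `fraction = 0`.
#' @export
generate_variations <- function(base, plan) {
  stopifnot(inherits(plan, "scar_variation_plan"))
  out <- list()
  if (plan$control_included) {
    out[[length(out) + 1L]] <- list(name = "control", fraction = 0,
                                    params = base,
                                    stable = check_stability(base)$pass)
  }
  for (nm in plan$varied) {
    for (f in plan$fractions) {
      p <- base
      p[[nm]] <- p[[nm]] * (1 + f)
      p <- update_dependent_params(p)
      class(p) <- "scar_params"
      out[[length(out) + 1L]] <- list(name = nm, fraction = f, params = p,
                                      stable = check_stability(p)$pass)
    }
  }
  out
}
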