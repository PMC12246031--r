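#' Biochemical kinetics and fluxes
#'
#' Pointwise, stateless evaluation of the reaction terms and fluxes of the
#' four transported species: fibroblasts N, myofibroblasts M, signaling
#' molecules c and collagen rho. All functions are vectorised over nodes.
#'
#' @name kinetics
NULL

# z^(1+q) with 0^(1+q) := 0 (valid since 1+q > 0 for the default values);
# evaluated via exp((1+q) log z) to avoid NaN from negative fractional powers.
.pow1q <- function(z, q) {
  out <- numeric(length(z))
  pos <- z > 0
  out[pos] <- exp((1 + q) * log(z[pos]))
  out
}

#' Fibroblast reaction kinetics
#'
#' `R_N = r_n [1 + r_max c/(a_c_I + c)] [1 - kappa (N+M)] N^(1+q)
#'        - k_1 c N - delta_n N`.
#'
#' @param N,M,c,rho nodal densities (vectors of equal length).
#' @param params a [scar_params()] list.
#' @return reaction rate, same shape as `N`.
#' @export
reaction_N <- function(N, M, c, rho, params) {
  if (any(N < 0)) stop("reaction_N: negative fibroblast density")
  prolif <- params$r_n * (1 + params$r_max * c / (params$a_c_I + c)) *
    (1 - params$kappa * (N + M)) * .pow1q(N, params$q)
  prolif - params$k_1 * c * N - params$delta_n * N
}

#' Myofibroblast reaction kinetics
#'
#' `R_M = r_m [(1 + r_max) c/(a_c_I + c)] [1 - kappa (N+M)] M^(1+q)
#'        + k_1 c N - delta_m M`.
#'
#' @inheritParams reaction_N
#' @return reaction rate.
#' @export
reaction_M <- function(N, M, c, rho, params) {
  if (any(M < 0)) stop("reaction_M: negative myofibroblast density")
  prolif <- params$r_m * ((1 + params$r_max) * c / (params$a_c_I + c)) *
    (1 - params$kappa * (N + M)) * .pow1q(M, params$q)
  prolif + params$k_1 * c * N - params$delta_m * M
}

#' Signaling-molecule reaction kinetics
#'
#' `R_c = k_c [c/(a_c_II + c)] [N + eta_I M]
#'        - delta_c [N + eta_II M] rho c / (1 + a_c_III c)`.
#'
#' @inheritParams reaction_N
#' @return reaction rate.
#' @export
reaction_c <- function(N, M, c, rho, params) {
  params$k_c * (c / (params$a_c_II + c)) * (N + params$eta_I * M) -
    params$delta_c * (N + params$eta_II * M) * rho * c / (1 + params$a_c_III * c)
}

#' Collagen reaction kinetics
#'
#' `R_rho = k_rho [1 + k_rho_max c/(a_c_IV + c)] [N + eta_I M]
#'          - delta_rho [N + eta_II M] rho^2 / (1 + a_c_III c)`.
#'
#' @inheritParams reaction_N
#' @return reaction rate.
#' @export
reaction_rho <- function(N, M, c, rho, params) {
  params$k_rho * (1 + params$k_rho_max * c / (params$a_c_IV + c)) *
    (N + params$eta_I * M) -
    params$delta_rho * (N + params$eta_II * M) * rho^2 / (1 + params$a_c_III * c)
}

#' Cell flux (density-dependent diffusion plus chemotaxis)
#'
#' `J_z = -D_n (N + M) grad z + chi z grad c` for `z` the chosen cell species
#' (fibroblasts or myofibroblasts).
#'
#' @param species `"N"` or `"M"`.
#' @param N,M nodal cell densities.
#' @param grad_z gradient of the chosen species, n x 2 matrix.
#' @param grad_c gradient of the signaling concentration, n x 2 matrix.
#' @param params a [scar_params()] list.
#' @return n x 2 matrix of flux vectors.
#' @export
flux_cells <- function(species, N, M, grad_z, grad_c, params) {
  species <- match.arg(species, c("N", "M"))
  z <- if (species == "N") N else M
  -params$D_n * (N + M) * grad_z + params$chi * z * grad_c
}

#' Signaling-molecule flux (Fickian); collagen has zero flux
#'
#' `J_c = -D_c grad c`. Collagen molecules are not transported
#' (`J_rho = 0`); pass `species = "rho"` to get the zero vector.
#'
#' @param grad_c gradient of c, n x 2 matrix.
#' @param params a [scar_params()] list.
#' @param species `"c"` (default) or `"rho"`.
#' @return n x 2 matrix of flux vectors.
#' @export
flux_signal <- function(grad_c, params, species = c("c", "rho")) {
  species <- match.arg(species)
  if (species == "rho") return(matrix(0, nrow(grad_c), 2))
  -params$D_c * grad_c
}
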