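#' Visco-elastic Cauchy stress
#'
#' `sigma = mu_1 sym(grad v) + mu_2 tr(sym(grad v)) I
#'          + E sqrt(rho)/(1+nu) [eps + tr(eps) nu/(1-2 nu) I]`.
#' The stiffness prefactor `E sqrt(rho)` makes the Young's modulus depend on
#' the local collagen density.
#'
#' @param grad_v 2x2 velocity gradient, entries `(k, l) = d v_k / d x_l`.
#' @param eps 2x2 symmetric effective Eulerian strain.
#' @param rho collagen density (scalar, g/cm^3).
#' @param params a [scar_params()] list.
#' @return 2x2 symmetric stress tensor (N/cm^2).
#' @export
cauchy_stress <- function(grad_v, eps, rho, params) {
  if (rho < 0) stop("cauchy_stress: negative collagen density")
  if (params$nu == 0.5) stop("cauchy_stress: nu = 0.5 (incompressible limit)")
  symv <- (grad_v + t(grad_v)) / 2
  kE <- params$E_mod * sqrt(rho) / (1 + params$nu)
  nt <- params$nu / (1 - 2 * params$nu)
  params$mu_1 * symv + params$mu_2 * sum(diag(symv)) * diag(2) +
    kE * (eps + sum(diag(eps)) * nt * diag(2))
}

#' Myofibroblast body-force potential
#'
#' `psi = xi M rho / (R^2 + rho^2)`; the traction exerted by myofibroblasts
#' pulling on the collagen matrix enters the momentum balance as
#' `div(psi I)`. Vectorised over nodes. `psi` vanishes without myofibroblasts
#' and is maximal (at fixed M) at `rho = R`.
#'
#' @param M myofibroblast density (cells/cm^3).
#' @param rho collagen density (g/cm^3).
#' @param params a [scar_params()] list.
#' @return force potential (N/cm^2), same shape as `M`.
#' @export
body_force_potential <- function(M, rho, params) {
  params$xi * M * rho / (params$R_force^2 + rho^2)
}

#' Morphoelastic strain-evolution right-hand side
#'
#' Material rate of the effective Eulerian strain:
#' `D eps / D t = skw(grad v) eps - eps skw(grad v)
#'                - (tr(eps) - 1) sym(grad v) - zeta G eps`
#' with `G = (N + eta_II M) c / (1 + a_c_III c)`. The co-rotational terms keep
#' the output symmetric exactly; the `zeta G` term converts elastic strain
#' into permanent deformation.
#'
#' @param eps 2x2 symmetric strain.
#' @param grad_v 2x2 velocity gradient.
#' @param N,M,c local densities (scalars).
#' @param params a [scar_params()] list.
#' @return 2x2 symmetric tensor `D eps / D t` (1/day).
#' @export
strain_rhs <- function(eps, grad_v, N, M, c, params) {
  if (max(abs(eps - t(eps))) > 1e-12 * max(1, max(abs(eps))))
    stop("strain_rhs: eps must be symmetric")
  symv <- (grad_v + t(grad_v)) / 2
  skwv <- (grad_v - t(grad_v)) / 2
  G <- (N + params$eta_II * M) * c / (1 + params$a_c_III * c)
  out <- skwv %*% eps - eps %*% skwv - (sum(diag(eps)) - 1) * symv -
    params$zeta * G * eps
  (out + t(out)) / 2  # kill roundoff asymmetry only
}
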