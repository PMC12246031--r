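#' Domain specification for the dermal slab
#'
#' The computational domain is half of a symmetric slab of skin: x runs from
#' the wound center (symmetry axis, boundary B.IV) to intact tissue at
#' `length_x` (essential boundary B.II), y from the slab bottom (B.I) to the
#' free top surface (B.III). The wound occupies `x < W` with a sine-shaped
#' transition band of width `s` just inside the wound edge.
#'
#' @param length_x slab length (cm); B.II sits at `x = length_x`.
#' @param height_y initial dermal thickness (cm).
#' @param W wound half-width (cm).
#' @param s wound-boundary steepness size (cm).
#' @return object of class `scar_domain`.
#' @export
domain_spec <- function(length_x = 10, height_y = 0.15, W = 4, s = 0.5) {
  if (!(height_y > 0)) stop("height_y must be positive")
  if (W < 0) stop("W must be nonnegative")
  if (!(W + s <= length_x)) stop("W + s must not exceed length_x")
  structure(list(length_x = length_x, height_y = height_y, W = W, s = s),
            class = "scar_domain")
}

#' @export
print.scar_domain <- function(x, ...) {
  cat(sprintf("<scar_domain> %.3g x %.3g cm slab, wound half-width %.3g cm, slope %.3g cm\n",
              x$length_x, x$height_y, x$W, x$s))
  invisible(x)
}

#' Wound profile weight
#'
#' Smooth indicator of the wounded region: 1 deep inside the wound
#' (`x <= W - s`), 0 in intact skin (`x >= W`), and a C1-continuous
#' `sin^2(pi (W - x) / (2 s))` ramp across the transition band.
#'
#' @param x x-coordinates (cm), vectorised.
#' @param spec a [domain_spec()].
#' @return weights in `[0, 1]`.
#' @export
wound_profile <- function(x, spec) {
  W <- spec$W; s <- spec$s
  w <- numeric(length(x))
  w[x <= W - s] <- 1
  band <- x > W - s & x < W
  w[band] <- sin(pi * (W - x[band]) / (2 * s))^2
  w
}

# graded x-grid on [0, L]: spacing dx_fine within band_halfwidth of `focus`,
# ramping to dx_coarse outside, modulated by min(h)/h(x) so that element
# areas stay near-uniform when the top surface h(x) is nonuniform.
.grade_xgrid <- function(L, focus, target, hfun = NULL) {
  xs <- seq(0, L, length.out = 2001)
  dist <- abs(xs - focus)
  ramp <- target$ramp
  frac <- pmin(1, pmax(0, (dist - target$band_halfwidth) / ramp))
  dxt <- target$dx_fine + (target$dx_coarse - target$dx_fine) * frac
  if (!is.null(hfun)) {
    h <- hfun(xs)
    dxt <- dxt * min(h) / h
    # shape guard: keep the per-column thickness jump bounded where the top
    # surface is steep (sharp hypertrophic ridges), at some cost in area
    # uniformity
    dh <- abs(c(diff(h) / diff(xs), 0))
    dxt <- pmin(dxt, 0.35 * h / pmax(dh, 1e-12))
    dxt <- pmax(dxt, target$dx_fine / 4)
  }
  dens <- 1 / dxt
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs)))
  n_cells <- max(4L, round(cdf[length(cdf)]))
  targets <- seq(0, cdf[length(cdf)], length.out = n_cells + 1L)
  x <- stats::approx(cdf, xs, xout = targets, ties = "ordered")$y
  x[1] <- 0; x[length(x)] <- L
  x
}

.default_mesh_target <- function() {
  # a refinement band follows the wound edge (steep fronts and the strongest
  # deformation live there); spacing is further modulated by 1/h(x) so that
  # element areas track the thickened profile
  list(dx_fine = 0.15, dx_coarse = 0.30, band_halfwidth = 2.0, ramp = 1.0,
       ny = 3L)
}

# assemble a structured triangulation from an x-grid and a top-surface height
# per x-column; ny layers of quads, each split into two CCW triangles.
.structured_mesh <- function(xg, htop, target, gen) {
  nx <- length(xg); ny <- target$ny
  if (any(htop <= 0)) stop("degenerate spec: nonpositive thickness")
  nodes <- matrix(0, nx * (ny + 1L), 2L)
  for (j in 0:ny) {
    idx <- j * nx + seq_len(nx)
    nodes[idx, 1] <- xg
    nodes[idx, 2] <- htop * j / ny
  }
  tri <- matrix(0L, 2L * (nx - 1L) * ny, 3L)
  k <- 0L
  for (j in 0:(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      a <- j * nx + i; b <- a + 1L; cc <- b + nx; d <- a + nx
      tri[k + 1L, ] <- c(a, b, cc)
      tri[k + 2L, ] <- c(a, cc, d)
      k <- k + 2L
    }
  }
  bnd <- list(
    BI  = seq_len(nx),                       # y = 0, ordered by x
    BII = (0:ny) * nx + nx,                  # x = L, ordered by y
    BIII = ny * nx + seq_len(nx),            # top, ordered by x
    BIV = (0:ny) * nx + 1L                   # x = 0, ordered by y
  )
  m <- list(nodes = nodes, tri = tri, bnd = bnd, nx = nx, ny = ny, gen = gen)
  class(m) <- "scar_mesh"
  m
}

#' Build the initial triangulation of the slab
#'
#' Structured graded triangulation of the rectangle
#' `[0, length_x] x [0, height_y]` with a refinement band that straddles the
#' wound edge. The grading is mild (coarse/fine spacing ratio 1.5 by default)
#' so that the fresh-mesh area-ratio quality stays well above the remeshing
#' threshold.
#'
#' @param spec a [domain_spec()].
#' @param target list of mesh targets: `dx_fine`, `dx_coarse` (cm),
#'   `band_halfwidth`, `ramp` (cm), `ny` (number of element layers through
#'   the thickness). Missing entries take the package defaults.
#' @return object of class `scar_mesh` with fields `nodes` (n x 2 cm),
#'   `tri` (m x 3, counter-clockwise), and `bnd` (ordered node indices of
#'   boundaries `BI`, `BII`, `BIII`, `BIV`).
#' @export
build_mesh <- function(spec, target = list()) {
  tg <- utils::modifyList(.default_mesh_target(), target)
  if (tg$dx_fine <= 0 || tg$dx_coarse <= 0 || tg$ny < 2L)
    stop("degenerate spec: positive edge targets and ny >= 2 required")
  focus <- spec$W
  xg <- .grade_xgrid(spec$length_x, focus, tg)
  .structured_mesh(xg, rep(spec$height_y, length(xg)), tg,
                   gen = list(target = tg, focus = focus))
}

#' @export
print.scar_mesh <- function(x, ...) {
  cat(sprintf("<scar_mesh> %d nodes, %d triangles (%d x %d grid), quality %.3f\n",
              nrow(x$nodes), nrow(x$tri), x$nx, x$ny + 1L, mesh_quality(x)))
  invisible(x)
}

# signed Jacobian determinants (2 x element area for CCW elements)
.mesh_detJ <- function(mesh) {
  p <- mesh$nodes; t1 <- mesh$tri[, 1]; t2 <- mesh$tri[, 2]; t3 <- mesh$tri[, 3]
  (p[t2, 1] - p[t1, 1]) * (p[t3, 2] - p[t1, 2]) -
    (p[t3, 1] - p[t1, 1]) * (p[t2, 2] - p[t1, 2])
}

#' Mesh quality ratio
#'
#' Ratio of the smallest to the largest element Jacobian determinant
#' (equivalently, triangle area); in `(0, 1]`. A value below 0.5 flags the
#' mesh for remeshing.
#'
#' @param mesh a `scar_mesh`.
#' @return quality ratio.
#' @export
mesh_quality <- function(mesh) {
  dJ <- .mesh_detJ(mesh)
  if (any(dJ <= 0)) stop("mesh tangling: inverted element (|J| <= 0)")
  min(dJ) / max(dJ)
}

#' Initial nodal state
#'
#' Fibroblasts and collagen start at a fraction (default 20%) of their
#' equilibria inside the wound, signaling molecules at `c_tilde` inside the
#' wound, all ramped by the sine-slope [wound_profile()]. Myofibroblasts,
#' velocity, effective strain and accumulated displacement start at zero.
#'
#' @param mesh a `scar_mesh`.
#' @param params a [scar_params()] list.
#' @param spec a [domain_spec()].
#' @param fibroblast_fraction initial wound fibroblast density as a fraction
#'   of `N_bar` (default 0.2).
#' @param collagen_fraction initial wound collagen density as a fraction of
#'   `rho_bar` (default 0.2; 1.0 models a collagen-rich graft).
#' @return n x 11 state matrix with columns
#'   `N, M, c, rho, v1, v2, exx, eyy, exy, u1, u2`.
#' @export
initial_state <- function(mesh, params, spec,
                          fibroblast_fraction = 0.2,
                          collagen_fraction = 0.2) {
  if (!(collagen_fraction > 0 && collagen_fraction <= 1))
    stop("collagen_fraction must be in (0, 1]")
  if (!(fibroblast_fraction > 0 && fibroblast_fraction <= 1))
    stop("fibroblast_fraction must be in (0, 1]")
  n <- nrow(mesh$nodes)
  w <- wound_profile(mesh$nodes[, 1], spec)
  st <- matrix(0, n, 11L,
               dimnames = list(NULL, c("N", "M", "c", "rho", "v1", "v2",
                                       "exx", "eyy", "exy", "u1", "u2")))
  st[, "N"] <- params$N_bar * (1 - (1 - fibroblast_fraction) * w)
  st[, "rho"] <- params$rho_bar * (1 - (1 - collagen_fraction) * w)
  st[, "c"] <- params$c_tilde * w
  st
}

#' Thickness of the tissue at the wound center
#'
#' The y-coordinate of the top boundary B.III at the symmetry axis `x = 0`
#' (the B.III/B.IV corner node).
#'
#' @param mesh a `scar_mesh`.
#' @return thickness (cm).
#' @export
thickness_at_center <- function(mesh) {
  corner <- intersect(mesh$bnd$BIII, mesh$bnd$BIV)
  if (length(corner) != 1L) stop("mesh has no unique B.III/B.IV corner")
  mesh$nodes[corner, 2]
}

# linear interpolation of a nodal field along the bottom boundary B.I
.interp_BI <- function(mesh, values, x) {
  idx <- mesh$bnd$BI
  xs <- mesh$nodes[idx, 1]
  o <- order(xs)
  stats::approx(xs[o], values[idx][o], xout = x, rule = 2, ties = "ordered")$y
}

# advect the tracked wound-boundary material point (on B.I, y = 0) with the
# nodal velocity field over one time step
.advect_wound_point <- function(xw, mesh, v1, dt) {
  xw_new <- xw + dt * .interp_BI(mesh, v1, xw)
  L <- max(mesh$nodes[, 1])
  if (xw_new < -1e-9 || xw_new > L + 1e-9)
    stop("wound-boundary tracking: point left the domain")
  min(max(xw_new, 0), L)
}

#' Remesh the deformed domain
#'
#' Builds a fresh structured graded triangulation of the current deformed
#' slab `{0 <= x <= length_x, 0 <= y <= h(x)}`, where the top curve `h(x)` is
#' taken from the current B.III boundary. Boundary corners are fixed; the
#' x-grid is re-graded around `focus` (by default the focus stored at mesh
#' generation) with spacing modulated by `1/h(x)` to keep element areas
#' near-uniform.
#'
#' @param mesh a (possibly distorted) `scar_mesh`.
#' @param focus x-position to refine around (cm); defaults to the stored one.
#' @return a new `scar_mesh` covering the same polygonal domain.
#' @export
remesh <- function(mesh, focus = NULL) {
  tg <- mesh$gen$target
  if (is.null(focus)) focus <- mesh$gen$focus
  top_idx <- mesh$bnd$BIII
  tx <- mesh$nodes[top_idx, 1]
  ty <- mesh$nodes[top_idx, 2]
  o <- order(tx)
  tx <- tx[o]; ty <- ty[o]
  if (any(diff(tx) <= 0))
    stop("unrecoverable geometry: top boundary folds over in x")
  # light tangential smoothing of the resampled top curve: damps
  # single-column ridges that the unregularized free surface can develop,
  # while leaving multi-column features essentially untouched
  if (length(ty) > 4L) {
    yin <- ty
    sm <- 0.25 * yin[-((length(ty) - 1L):length(ty))] +
      0.5 * yin[-c(1L, length(ty))] + 0.25 * yin[-(1:2)]
    # clip-only: peaks are shaved, valleys never raised, so the remeshed
    # domain stays inside the old one and field transfer remains well posed
    ty[-c(1L, length(ty))] <- pmin(yin[-c(1L, length(ty))], sm)
  }
  L <- max(mesh$nodes[, 1])
  hfun <- function(x) stats::approx(tx, ty, xout = x, rule = 2,
                                    ties = "ordered")$y
  xg <- .grade_xgrid(L, focus, tg, hfun = hfun)
  .structured_mesh(xg, hfun(xg), tg, gen = list(target = tg, focus = focus))
}

#' Transfer nodal fields between meshes
#'
#' Piecewise-linear interpolation: each new node is located in the old
#' triangulation and its value is the barycentric combination of the old
#' vertex values. New nodes that fall outside the old mesh by less than
#' `tol` (boundary roundoff) are clamped to the nearest element; farther
#' outside is an error.
#'
#' @param old_mesh,new_mesh `scar_mesh` objects over the same domain.
#' @param fields numeric matrix (n_old x k) of nodal values.
#' @param tol barycentric tolerance for points marginally outside.
#' @param fallback `"error"` (default) rejects nodes outside beyond `tol`;
#'   `"nearest"` assigns them the value of the nearest source node (used for
#'   transfers from locally sheared meshes whose triangles no longer tile
#'   the nominal region).
#' @return matrix (n_new x k) of interpolated values.
#' @export
interpolate_fields <- function(old_mesh, fields, new_mesh, tol = 1e-6,
                               fallback = c("error", "nearest")) {
  fallback <- match.arg(fallback)
  fields <- as.matrix(fields)
  px <- new_mesh$nodes[, 1]; py <- new_mesh$nodes[, 2]
  p <- old_mesh$nodes; tri <- old_mesh$tri
  np <- length(px)
  best <- rep(-Inf, np)
  bl1 <- bl2 <- bl3 <- numeric(np)
  btri <- integer(np)
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  dJ <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  for (e in seq_len(nrow(tri))) {
    l1 <- ((x2[e] - px) * (y3[e] - py) - (x3[e] - px) * (y2[e] - py)) / dJ[e]
    l2 <- ((x3[e] - px) * (y1[e] - py) - (x1[e] - px) * (y3[e] - py)) / dJ[e]
    l3 <- 1 - l1 - l2
    m <- pmin(l1, l2, l3)
    upd <- m > best
    if (any(upd)) {
      best[upd] <- m[upd]
      bl1[upd] <- l1[upd]; bl2[upd] <- l2[upd]; bl3[upd] <- l3[upd]
      btri[upd] <- e
    }
  }
  outside <- best < -tol
  if (any(outside) && fallback == "error")
    stop("interpolation error: ", sum(outside),
         " node(s) outside the source mesh beyond tolerance")
  # clamp marginally-outside points onto their closest element
  l1 <- pmax(bl1, 0); l2 <- pmax(bl2, 0); l3 <- pmax(bl3, 0)
  s <- l1 + l2 + l3
  l1 <- l1 / s; l2 <- l2 / s; l3 <- l3 / s
  i1 <- tri[btri, 1]; i2 <- tri[btri, 2]; i3 <- tri[btri, 3]
  out <- l1 * fields[i1, , drop = FALSE] + l2 * fields[i2, , drop = FALSE] +
    l3 * fields[i3, , drop = FALSE]
  if (any(outside)) {
    for (k in which(outside)) {
      d2 <- (p[, 1] - px[k])^2 + (p[, 2] - py[k])^2
      out[k, ] <- fields[which.min(d2), ]
    }
  }
  dimnames(out) <- list(NULL, colnames(fields))
  out
}
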