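# Regular hexagon of area a0 in the lattice orientation used throughout
# (two vertical junctions; junction vectors ~ (0,1), (+-sqrt(3)/2, 1/2)).
hex_cell_polygon <- function(a0 = 1) {
  s <- sqrt(2 * a0 / (3 * sqrt(3)))
  w <- sqrt(3) * s
  cbind(c(w / 2, w / 2, 0, -w / 2, -w / 2, 0),
        c(-s / 2, s / 2, s, s / 2, -s / 2, -s))
}

poly_area <- function(p) {
  n <- nrow(p)
  k1 <- c(2:n, 1)
  sum(p[, 1] * p[k1, 2] - p[k1, 1] * p[, 2]) / 2
}

poly_perimeter <- function(p) {
  n <- nrow(p)
  k1 <- c(2:n, 1)
  sum(sqrt((p[k1, 1] - p[, 1])^2 + (p[k1, 2] - p[, 2])^2))
}

cell_energy_poly <- function(p, params) {
  A <- poly_area(p)
  P <- poly_perimeter(p)
  0.5 * params$k * (A - params$a0)^2 + 0.5 * params$gamma_p * (P - params$P0)^2
}

#' Quasistatic shear modulus of the hexagonal solid
#'
#' In the slow-driving limit the tissue relaxes internally and the storage
#' shear modulus is `E2 = K A0 (1 - alpha^2)`, where `alpha` is the isotropic
#' box rescaling that makes the residual hydrostatic stress of the hexagonal
#' tiling vanish. `alpha` is found by root bracketing on the hydrostatic
#' stress of a uniformly rescaled lattice. (The exact quasistatic modulus,
#' obtainable by eliminating the internal modes against the Hessian, agrees
#' with this expression to better than 1% throughout the solid phase and
#' exactly at the transition, where both vanish.)
#'
#' @param params a [model_params()]; meaningful in the solid phase
#'   (`p0 < 3.7224`).
#' @param bracket search interval for `alpha`.
#' @return Modulus in units `K*A0`.
#' @export
analytic_shear_quasistatic <- function(params, bracket = c(0.5, 1.5)) {
  if (params$gamma_p == 0) return(0) # area term alone sets A = A0, alpha = 1
  base <- hex_tiling(2, a0 = params$a0)
  f <- function(alpha) {
    m <- apply_affine(base, diag(c(alpha, alpha)))
    hydrostatic(tissue_stress(m, params))
  }
  alpha <- stats::uniroot(f, bracket, tol = 1e-12)$root
  params$k * params$a0 * (1 - alpha^2)
}

#' High-frequency (affine) shear modulus of the hexagonal solid
#'
#' In the fast-driving limit vertices follow the imposed affine deformation
#' with no internal relaxation. For the undeformed lattice (`a = 1`) the
#' modulus has the closed form `3*sqrt(3)*Gamma*(1 - p0/p_c)`. For a
#' uniaxially pre-deformed lattice (deformation gradient `diag(a, 1)`) it is
#' computed as the second strain derivative of the single-cell energy density
#' of the affinely sheared, pre-deformed hexagon (central differences,
#' `h = 1e-5`), which reduces to the closed form at `a = 1`.
#'
#' @param params a [model_params()].
#' @param a uniaxial pre-deformation factor (> 0).
#' @param h strain step of the numeric second derivative.
#' @return Modulus in units `K*A0`.
#' @export
analytic_shear_affine <- function(params, a = 1, h = 1e-5) {
  stopifnot(a > 0)
  if (a == 1) {
    return(3 * sqrt(3) * params$gamma_p * (1 - params$p0 / p_c_hex()))
  }
  pg <- hex_cell_polygon(params$a0) %*% t(diag(c(a, 1)))
  e <- function(eps) {
    sh <- matrix(c(1, 0, eps, 1), 2, 2)
    cell_energy_poly(pg %*% t(sh), params) / (a * params$a0)
  }
  (e(h) - 2 * e(0) + e(-h)) / h^2
}

#' Affine bulk modulus of the hexagonal solid
#'
#' Closed form `B = 2 K A0 + 12^(1/4) * Gamma * p0` for the storage bulk
#' modulus of the hexagonal tiling under affine biaxial deformation. The
#' coefficient `12^(1/4)` equals `p_c/2` with `p_c = sqrt(8*sqrt(3))`, the
#' value obtained by differentiating the hydrostatic stress
#' `K(A - A0) + Gamma (P - P0) P / (2A)` of a regular hexagon under affine
#' dilation (`P = p_c sqrt(A)`); the test suite checks the coefficient
#' against that independent construction.
#'
#' @param params a [model_params()].
#' @return Modulus in units `K*A0`.
#' @export
analytic_bulk <- function(params) {
  2 * params$k * params$a0 + 12^0.25 * params$gamma_p * params$p0
}

#' Solid-fluid boundary under uniaxial pre-deformation
#'
#' Critical shape parameter of the hexagonal tiling pre-deformed by
#' `diag(a, 1)`: the zero of the affine shear modulus,
#' `p_c(a) = sqrt(8*sqrt(3)) * (1 + sqrt(1 + 3 a^2)) / 3`.
#' Compression (`a < 1`) lowers the transition, stretching raises it;
#' `p_c(1) = 3.7224`.
#'
#' @param a pre-deformation factor (> 0), vectorized.
#' @return Critical shape parameter(s).
#' @export
critical_p0_predeformed <- function(a) {
  stopifnot(all(a > 0))
  sqrt(8 * sqrt(3)) * (1 + sqrt(1 + 3 * a^2)) / 3
}
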