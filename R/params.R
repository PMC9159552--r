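#' Vertex-model parameters
#'
#' Bundles the mechanical constants of the tissue energy
#' `E = sum_C [ K/2 (A_C - A0)^2 + Gamma/2 (P_C - P0)^2 ]`
#' and the substrate friction `gamma` of the overdamped vertex dynamics
#' `gamma dr/dt = F`. The single control parameter of the solid-fluid
#' transition is the dimensionless shape parameter `p0 = P0/sqrt(A0)`; the
#' perimeter-to-area stiffness ratio defaults to `Gamma/(K*A0) = 0.289`, the
#' value used throughout the study. The friction sets the unit of time
#' `t* = gamma/(K*A0)`.
#'
#' @param p0 target shape parameter `P0/sqrt(A0)` (dimensionless).
#' @param k area stiffness `K` (> 0).
#' @param gamma_p perimeter stiffness `Gamma` (>= 0), in the same units as
#'   `K*A0` when `a0 = 1`.
#' @param a0 preferred cell area (> 0).
#' @param gamma substrate friction coefficient (> 0).
#' @return An object of class `model_params` with derived fields `P0`
#'   (preferred perimeter) and `t_star` (unit of time).
#' @export
model_params <- function(p0, k = 1, gamma_p = 0.289 * k * a0, a0 = 1,
                         gamma = 1) {
  stopifnot(k > 0, a0 > 0, gamma > 0, gamma_p >= 0, p0 >= 0)
  structure(
    list(k = k, gamma_p = gamma_p, a0 = a0, p0 = p0,
         P0 = p0 * sqrt(a0), gamma = gamma, t_star = gamma / (k * a0)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> K = %g, Gamma = %g (Gamma/KA0 = %.4g), A0 = %g, p0 = %.4f, gamma = %g (t* = %g)\n",
    x$k, x$gamma_p, x$gamma_p / (x$k * x$a0), x$a0, x$p0, x$gamma, x$t_star))
  invisible(x)
}

#' Critical shape parameter of the regular hexagonal tiling
#'
#' `p_hex = 6 / sqrt(3*sqrt(3)/2) = sqrt(8*sqrt(3)) ~ 3.7224`, the shape index
#' of a regular hexagon and the solid-fluid transition point of the honeycomb
#' lattice.
#'
#' @return The critical shape parameter (scalar).
#' @export
p_c_hex <- function() sqrt(8 * sqrt(3))
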