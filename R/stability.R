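#' Hessian spectrum report
#'
#' Full symmetric eigendecomposition of the energy Hessian. Eigenvalues are
#' classified against a zero tolerance (default `1e-10 * K * A0`): two
#' trivial zero modes are the rigid translations of any periodic mesh;
#' additional zero modes are the floppy (soft) modes that signal fluidity;
#' negative modes mark an unstable stationary point.
#'
#' @param mesh a [tissue_mesh()] at (or near) a stationary point.
#' @param params a [model_params()].
#' @param zero_tol zero-mode tolerance in units `K*A0`.
#' @param force_warn_tol warn if the residual force exceeds this.
#' @return An object of class `spectrum_report`: sorted eigenvalues, counts
#'   of trivial zero, nontrivial zero and negative modes, the lowest
#'   nontranslational eigenvalue, and a phase label in
#'   `{"solid", "fluid", "unstable"}`.
#' @export
hessian_spectrum <- function(mesh, params, zero_tol = 1e-10,
                             force_warn_tol = 1e-8) {
  H <- vm_hessian(mesh, params)
  fmax <- max(sqrt(rowSums(tissue_forces(mesh, params)^2)))
  warn <- NULL
  if (fmax > force_warn_tol * params$k * params$a0^1.5) {
    warn <- sprintf("mesh is not stationary (max force %.3g)", fmax)
    warning(warn)
  }
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  tol <- zero_tol * params$k * params$a0
  n_zero <- sum(abs(ev) < tol)
  n_neg <- sum(ev < -tol)
  trivial <- min(2L, n_zero)
  nontrivial <- max(0L, n_zero - 2L)
  phase <- if (n_neg > 0) "unstable" else if (nontrivial > 0) "fluid" else "solid"
  # lowest eigenvalue outside the two-dimensional translation null space
  lam_min <- lowest_nontranslational(H, params)
  structure(
    list(eigenvalues = ev, n_trivial_zero = trivial,
         n_nontrivial_zero = nontrivial, n_negative = n_neg,
         lowest_nontrivial = lam_min, zero_tol = tol, fmax = fmax,
         phase = phase, warning = warn),
    class = "spectrum_report"
  )
}

# Smallest eigenvalue orthogonal to rigid translations: shift the (exact)
# translation null vectors up by a large multiple of K*A0 and take the
# minimum of the shifted spectrum.
lowest_nontranslational <- function(H, params) {
  n <- nrow(H)
  nv <- n / 2
  t1 <- rep(c(1, 0), nv) / sqrt(nv)
  t2 <- rep(c(0, 1), nv) / sqrt(nv)
  mu <- 100 * params$k * params$a0 + max(abs(diag(H)))
  Hs <- H + mu * (tcrossprod(t1) + tcrossprod(t2))
  min(eigen(Hs, symmetric = TRUE, only.values = TRUE)$values)
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf(
    "<spectrum_report> %d modes: %d trivial zero, %d nontrivial zero, %d negative\n",
    length(x$eigenvalues), x$n_trivial_zero, x$n_nontrivial_zero, x$n_negative))
  cat(sprintf("  lowest nontranslational eigenvalue: %.6g\n", x$lowest_nontrivial))
  cat(sprintf("  phase: %s\n", x$phase))
  invisible(x)
}

#' Classify the mechanical phase
#'
#' Fluid if and only if the relaxed configuration has nontrivial zero modes;
#' configurations with negative modes are labelled `"unstable"` (saddle
#' points, not valid solid/fluid states).
#'
#' @param report a `spectrum_report` from [hessian_spectrum()].
#' @return `"solid"`, `"fluid"` or `"unstable"`.
#' @export
classify_phase <- function(report) {
  stopifnot(inherits(report, "spectrum_report"))
  report$phase
}

#' Locate the hexagonal critical point by bisection
#'
#' Bisects the sign change of the lowest nontranslational Hessian eigenvalue
#' of the (optionally uniaxially pre-deformed) hexagonal lattice as a
#' function of the shape parameter `p0`. For `a = 1` the transition is at
#' `p0 = sqrt(8*sqrt(3)) ~ 3.7224`; compression shifts it down.
#'
#' @param a uniaxial pre-deformation factor.
#' @param bracket `p0` interval straddling the sign change.
#' @param nx lattice size (columns of cells).
#' @param tol bisection tolerance in `p0`.
#' @param gamma_p_ratio perimeter-to-area stiffness ratio `Gamma/(K*A0)`.
#' @return The critical shape parameter estimate.
#' @export
find_critical_p0 <- function(a = 1, bracket = c(3.6, 3.8), nx = 15,
                             tol = 1e-3, gamma_p_ratio = 0.289) {
  base <- hex_tiling(nx)
  if (a != 1) base <- apply_predeformation(base, a)
  g <- function(p0) {
    params <- model_params(p0 = p0, gamma_p = gamma_p_ratio)
    H <- vm_hessian(base, params)
    lowest_nontranslational(H, params)
  }
  glo <- g(bracket[1])
  ghi <- g(bracket[2])
  if (sign(glo) == sign(ghi)) {
    stop("bracket does not straddle the stability sign change")
  }
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(glo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Ensemble onset of zero modes in disordered tilings
#'
#' For each seed, builds the random-sequential-addition Voronoi tiling,
#' relaxes it with FIRE at each shape parameter of `p0_grid` (ascending) and
#' records the smallest `p0` whose relaxed state carries nontrivial zero
#' modes; returns the per-seed onsets and their median, the operational
#' estimate of the disordered critical point.
#'
#' @param seeds integer vector of tiling seeds.
#' @param p0_grid ascending grid of shape parameters (step 0.01 by default).
#' @param n,L tiling size parameters.
#' @param gamma_p_ratio stiffness ratio `Gamma/(K*A0)`.
#' @param sigma,kick_seed_offset perturbation applied before relaxation.
#' @param bisect assume zero-mode presence is monotone in `p0` and locate
#'   the onset by bisection on the grid (default); set `FALSE` for a full
#'   ascending scan.
#' @param rel_tol,f_tol FIRE energy and residual-force tolerances. The tight
#'   force tolerance pushes the eigenvalue noise on the flat (zero-mode)
#'   directions below ~1e-8, which sets the `zero_tol` default here: relaxed
#'   fluid states reach E ~ 0 only to machine precision, so their flat
#'   directions carry curvature noise of order 1e-9, well above the 1e-10
#'   used for exact lattice states but far below the smallest genuine solid
#'   eigenvalue (~1e-6) near the onset.
#' @param zero_tol zero-mode tolerance (units `K*A0`).
#' @param verbose print per-seed progress.
#' @return List: `onset` (per-seed vector, NA if no onset in the grid),
#'   `median`, `spread` (median absolute deviation), and a data frame `scan`
#'   of evaluated points.
#' @export
disordered_critical_p0 <- function(seeds = 1:10,
                                   p0_grid = seq(3.85, 4.01, by = 0.01),
                                   n = 200, L = 15, gamma_p_ratio = 0.289,
                                   sigma = NULL, kick_seed_offset = 1000L,
                                   bisect = TRUE, rel_tol = 1e-12,
                                   f_tol = 1e-10, zero_tol = 1e-8,
                                   verbose = FALSE) {
  scan <- NULL
  onset <- rep(NA_real_, length(seeds))
  for (si in seq_along(seeds)) {
    mesh0 <- disordered_tiling(n = n, L = L, seed = seeds[si])
    a0 <- mesh0$meta$a0
    if (is.null(sigma)) sigma <- 1.5e-4 * sqrt(a0)
    has_zero <- function(p0) {
      params <- model_params(p0 = p0, a0 = a0,
                             gamma_p = gamma_p_ratio * a0)
      m <- perturb_vertices(mesh0, sigma, seed = seeds[si] + kick_seed_offset)
      rel <- fire_minimize(m, params, rel_tol = rel_tol, f_tol = f_tol,
                           l_t1 = 0.002 * sqrt(a0))
      rep <- suppressWarnings(hessian_spectrum(rel$mesh, params,
                                               zero_tol = zero_tol))
      scan <<- rbind(scan, data.frame(seed = seeds[si], p0 = p0,
                                      n_zero = rep$n_nontrivial_zero,
                                      lowest = rep$lowest_nontrivial,
                                      phase = rep$phase))
      if (verbose) {
        message(sprintf("seed %d p0 = %.2f: %d nontrivial zero modes",
                        seeds[si], p0, rep$n_nontrivial_zero))
      }
      rep$n_nontrivial_zero > 0
    }
    if (bisect) {
      lo <- 1L; hi <- length(p0_grid)
      if (!has_zero(p0_grid[hi])) next       # no onset inside the grid
      if (has_zero(p0_grid[lo])) {
        onset[si] <- p0_grid[lo]
        next
      }
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (has_zero(p0_grid[mid])) hi <- mid else lo <- mid
      }
      onset[si] <- p0_grid[hi]
    } else {
      for (p0 in p0_grid) {
        if (has_zero(p0)) {
          onset[si] <- p0
          break
        }
      }
    }
  }
  list(onset = onset, median = stats::median(onset, na.rm = TRUE),
       spread = stats::mad(onset, na.rm = TRUE), scan = scan)
}
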