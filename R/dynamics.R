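#' One forward-Euler step of the overdamped dynamics
#'
#' Advances the vertex positions by `r_i <- r_i + (dt/gamma) F_i`, the
#' first-order discretization of the force balance `gamma dr/dt = F` between
#' substrate friction and cell-shape elasticity. The box is unchanged.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [model_params()].
#' @param dt time step (> 0), in the same units as `t* = gamma/(K*A0)`.
#' @return The updated [tissue_mesh()].
#' @export
euler_step <- function(mesh, params, dt) {
  stopifnot(dt > 0)
  F <- tissue_forces(mesh, params)
  mesh$x <- mesh$x + (dt / params$gamma) * F
  mesh
}

#' FIRE energy minimization
#'
#' Relaxes the mesh to a local energy minimum with the fast inertial
#' relaxation engine. Convergence is declared when the relative energy change
#' per iteration stays below `rel_tol` (default 1e-12). T1 junction flips are
#' allowed between relaxation rounds when a junction collapses below `l_t1`.
#'
#' @inheritParams euler_step
#' @param rel_tol relative energy-change tolerance.
#' @param f_tol residual-force tolerance (units `K*A0^{3/2}` per length);
#'   convergence requires both the energy plateau and `fmax <= f_tol`.
#' @param maxit iteration cap; exceeding it returns `converged = FALSE`
#'   rather than an error.
#' @param l_t1,l_new T1 thresholds, see [detect_and_apply_t1()]; set
#'   `l_t1 = 0` to forbid topology changes.
#' @param dt_start,dt_max,alpha_start,f_inc,f_dec,f_alpha,n_min FIRE
#'   hyperparameters (units of `t*` for the time steps).
#' @return A list: `mesh`, `converged`, `iterations`, `energy`, `fmax`
#'   (residual force), `t1_events`.
#' @export
fire_minimize <- function(mesh, params, rel_tol = 1e-12, f_tol = 1e-8,
                          maxit = 1e6,
                          l_t1 = 0.01 * sqrt(params$a0), l_new = 1.5 * l_t1,
                          dt_start = 0.01 * params$t_star,
                          dt_max = 0.1 * params$t_star,
                          alpha_start = 0.1, f_inc = 1.1, f_dec = 0.5,
                          f_alpha = 0.99, n_min = 5) {
  stopifnot(rel_tol > 0)
  fl <- mesh_flat(mesh)
  n_flips <- 0L
  iters <- 0L
  e_floor <- 1e-12 * n_cells(mesh) * params$k * params$a0^2
  # per-junction flip budget: a junction that keeps re-collapsing after two
  # flips is oscillating about a near-fourfold vertex; freeze it and let the
  # minimizer proceed with a lowered bail-out threshold instead of thrashing
  flip_count <- new.env(parent = emptyenv())
  l_bail <- l_t1
  for (round in 1:500) {
    res <- cpp_fire(mesh$x, fl$ptr, fl$cv, mesh$box,
                    params$k, params$gamma_p, params$a0, params$P0,
                    rel_tol, e_floor, f_tol, as.integer(maxit), dt_start,
                    dt_max, alpha_start, f_inc, f_dec, f_alpha,
                    as.integer(n_min), l_bail)
    mesh$x <- res$x
    iters <- iters + res$iterations
    if (l_t1 <= 0 || !isTRUE(res$needs_t1)) break
    et <- edge_table(mesh)
    lens <- edge_lengths(mesh, et)
    short <- unique(et$key[lens < max(l_t1, l_bail)])
    cand <- NULL
    for (key in short[order(lens[match(short, et$key)])]) {
      rows <- et[et$key == key, ]
      pk <- paste(min(rows$v1[1], rows$v2[1]), max(rows$v1[1], rows$v2[1]))
      cnt <- flip_count[[pk]] %||% 0L
      klen <- lens[match(key, et$key)]
      if (cnt < 2L || klen < 1e-6 * sqrt(params$a0)) {
        # frozen junctions are still flipped if they collapse to (numerical)
        # zero, to keep the geometry non-degenerate
        if (klen < 1e-6 * sqrt(params$a0)) flip_count[[pk]] <- 0L
        cand <- list(rows = rows, pk = pk)
        break
      }
    }
    if (is.null(cand)) {
      # all short junctions are frozen: allow them to shrink further
      l_bail <- max(0.45 * min(lens), 0.5e-6 * sqrt(params$a0))
      next
    }
    flipped <- try(t1_flip(mesh, cand$rows, l_new), silent = TRUE)
    flip_count[[cand$pk]] <- (flip_count[[cand$pk]] %||% 0L) + 1L
    if (inherits(flipped, "try-error")) next
    mesh <- flipped
    n_flips <- n_flips + 1L
    fl <- mesh_flat(mesh)
  }
  list(mesh = mesh, converged = res$converged, iterations = iters,
       energy = res$energy, fmax = res$fmax, t1_events = n_flips)
}

#' Prepare a relaxed (fluid-phase) state
#'
#' Applies a small Gaussian kick to every vertex (default standard deviation
#' `1.5e-4 * sqrt(A0)`) and relaxes with FIRE. Above the transition the
#' lattice is a saddle point, so the kick selects one of many local minima;
#' below it the mesh relaxes back to the lattice.
#'
#' @inheritParams fire_minimize
#' @param sigma kick standard deviation.
#' @param seed RNG seed for the kick.
#' @param quiet suppress the note emitted when `p0` is below the lattice
#'   transition (where the kick just relaxes back).
#' @param ... forwarded to [fire_minimize()].
#' @return As [fire_minimize()].
#' @export
prepare_fluid_state <- function(mesh, params, sigma = 1.5e-4 * sqrt(params$a0),
                                seed = 1L, quiet = FALSE, ...) {
  if (!quiet && params$p0 <= p_c_hex() && identical(mesh$meta$kind, "hexagonal")) {
    # below the lattice transition the kick simply relaxes back
    message("p0 <= 3.7224: the hexagonal solid will relax back to the lattice")
  }
  mesh <- perturb_vertices(mesh, sigma, seed = seed)
  fire_minimize(mesh, params, ...)
}

#' Uniaxial pre-deformation
#'
#' Applies the deformation gradient `diag(a, 1)` (pre-compression for
#' `a < 1`, pre-stretch for `a > 1`) to vertices and box, and resets the
#' reference box so that subsequent oscillatory strain is measured about the
#' pre-deformed state (tangent moduli).
#'
#' @param mesh a [tissue_mesh()].
#' @param a stretch factor (> 0) along x.
#' @return The pre-deformed [tissue_mesh()].
#' @export
apply_predeformation <- function(mesh, a) {
  stopifnot(a > 0)
  apply_affine(mesh, diag(c(a, 1)), update_ref = TRUE)
}

#' Oscillatory deformation protocol
#'
#' Settings of the small-amplitude oscillatory probe
#' `eps(t) = eps0 sin(omega0 t)` applied as simple shear
#' (`F = [[1, eps], [0, 1]]`) or biaxially (`F = (1+eps) I`). The time step
#' follows the two-tier rule `dt = 0.00866 t*` for `omega0 t* < 29.02` and
#' `dt = 0.000866 t*` above, shrunk where needed so that the
#' `samples_per_cycle` sampling points land on integer steps.
#'
#' @param mode `"shear"` or `"biaxial"`.
#' @param omega0 angular driving frequency (units `1/t*`).
#' @param eps0 strain amplitude (default 1e-7, deep in the linear regime).
#' @param samples_per_cycle stress samples per driving period (>= 25).
#' @param cycles_per_block cycles per Fourier block (default 3).
#' @param max_blocks cap on the number of blocks.
#' @param steady_rel_tol relative tolerance of the steady-state criterion.
#' @return An object of class `deformation_protocol`.
#' @export
deformation_protocol <- function(mode = c("shear", "biaxial"), omega0,
                                 eps0 = 1e-7, samples_per_cycle = 25,
                                 cycles_per_block = 3, max_blocks = 40,
                                 steady_rel_tol = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(eps0 > 0, omega0 > 0, samples_per_cycle >= 25)
  structure(list(mode = mode, omega0 = omega0, eps0 = eps0,
                 samples_per_cycle = as.integer(samples_per_cycle),
                 cycles_per_block = as.integer(cycles_per_block),
                 max_blocks = as.integer(max_blocks),
                 steady_rel_tol = steady_rel_tol),
            class = "deformation_protocol")
}

# Resolve the time-step rule for a protocol.
protocol_steps <- function(protocol, params) {
  dt_base <- if (protocol$omega0 * params$t_star < 29.02) {
    0.00866 * params$t_star
  } else {
    0.000866 * params$t_star
  }
  T0 <- 2 * pi / protocol$omega0
  spc <- protocol$samples_per_cycle
  steps_per_cycle <- spc * max(1L, as.integer(ceiling(T0 / (spc * dt_base))))
  list(dt = T0 / steps_per_cycle,
       steps_per_cycle = steps_per_cycle,
       sample_every = steps_per_cycle %/% spc,
       T0 = T0)
}

#' Run the oscillatory deformation protocol
#'
#' At every time step the incremental affine map `F(t+dt) F(t)^-1` is applied
#' to all vertices and the box, followed by one overdamped Euler step, so
#' accumulated non-affine relaxation is preserved. The tissue stress tensor
#' is sampled `samples_per_cycle` times per cycle; the run stops once the
#' block Fourier amplitude of the stress channel is steady (see
#' [steady_amplitude()]) or after `max_blocks` blocks.
#'
#' @param mesh a relaxed (or deliberately pre-deformed) [tissue_mesh()].
#' @param params a [model_params()].
#' @param protocol a [deformation_protocol()].
#' @param l_t1 T1 threshold during driving (0 disables checks).
#' @return An object of class `stress_series`: data frame columns `time`,
#'   `strain`, `sxx`, `sxy`, `syy`, with the protocol, convergence flag,
#'   number of blocks and T1 count as attributes.
#' @export
run_oscillatory <- function(mesh, params, protocol,
                            l_t1 = 0.01 * sqrt(params$a0)) {
  st <- protocol_steps(protocol, params)
  fl <- mesh_flat(mesh)
  mode_i <- if (protocol$mode == "shear") 0L else 1L
  steps_per_block <- protocol$cycles_per_block * st$steps_per_cycle
  x <- mesh$x
  box <- mesh$box
  samp <- vector("list", protocol$max_blocks)
  amps <- complex(0)
  converged <- FALSE
  nb <- 0L
  t1_count <- 0L
  for (b in seq_len(protocol$max_blocks)) {
    res <- cpp_osc_block(x, box, fl$ptr, fl$cv, fl$enb,
                         params$k, params$gamma_p, params$a0, params$P0,
                         params$gamma, mode_i, protocol$eps0, protocol$omega0,
                         st$dt, steps_per_block, st$sample_every,
                         (b - 1) * steps_per_block)
    x <- res$x
    box <- res$box
    samp[[b]] <- res$samples
    nb <- b
    if (l_t1 > 0 && res$min_edge < l_t1) {
      mtmp <- mesh; mtmp$x <- x; mtmp$box <- box
      t1 <- detect_and_apply_t1(mtmp, l_t1 = l_t1)
      if (any(t1$events$applied)) {
        t1_count <- t1_count + sum(t1$events$applied)
        x <- t1$mesh$x
        mesh$cells <- t1$mesh$cells
        fl <- mesh_flat(t1$mesh)
      }
    }
    sig <- stress_channel(res$samples, protocol$mode)
    amps <- c(amps, block_amplitude(sig, res$samples[, 1], protocol$omega0))
    sa <- steady_check(amps, protocol$steady_rel_tol)
    if (sa) {
      converged <- TRUE
      break
    }
  }
  s <- do.call(rbind, samp[seq_len(nb)])
  out <- data.frame(time = s[, 1], strain = s[, 2], sxx = s[, 3],
                    sxy = s[, 4], syy = s[, 5])
  structure(out, class = c("stress_series", "data.frame"),
            protocol = protocol, params = params, dt = st$dt,
            converged = converged, blocks = nb, t1_events = t1_count)
}

stress_channel <- function(samples, mode) {
  if (mode == "shear") samples[, 4] else (samples[, 3] + samples[, 5]) / 2
}

# two-consecutive-pass steady-state rule on a vector of block amplitudes
steady_check <- function(amps, rel_tol) {
  n <- length(amps)
  if (n < 3) return(FALSE)
  rel <- function(k) Mod(amps[k] - amps[k - 1]) / Mod(amps[k])
  rel(n) < rel_tol && rel(n - 1) < rel_tol
}
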