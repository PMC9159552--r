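# Rectangle-rule Fourier amplitude of one block of uniformly sampled data:
# (1/T) sum x_k e^{-i w t_k} dt. The conjugate kernel makes the loss modulus
# the positive imaginary part of stress/strain for a dissipative material.
block_amplitude <- function(x, t, omega) {
  dt <- t[2] - t[1]
  T <- length(x) * dt
  sum(x * exp(-1i * omega * t)) * dt / T
}

#' Block Fourier amplitude
#'
#' Amplitude of a sampled signal at frequency `omega` over block `n` of
#' length `block_len` samples, computed with the rectangle rule on the
#' uniformly spaced samples (the same discretization is applied to stress
#' and strain, so quadrature bias cancels in their ratio).
#'
#' @param x sampled signal.
#' @param t sample times (uniform spacing).
#' @param omega analysis frequency.
#' @param n block index (1-based).
#' @param block_len samples per block.
#' @return Complex amplitude; a pure sine of amplitude `A` at `omega` gives
#'   modulus `A/2`.
#' @export
block_fourier <- function(x, t, omega, n, block_len) {
  i0 <- (n - 1) * block_len
  if (i0 + block_len > length(x)) stop("insufficient data: incomplete block")
  idx <- i0 + seq_len(block_len)
  block_amplitude(x[idx], t[idx], omega)
}

#' Steady-state amplitude
#'
#' Scans a sequence of per-block complex amplitudes and returns the first
#' amplitude whose relative change from the previous block is below
#' `rel_tol` for two consecutive comparisons (so the earliest convergence is
#' at block 3). Monotone drifts never satisfy the rule and come back flagged.
#'
#' @param amps complex vector of block amplitudes (>= 2).
#' @param rel_tol relative tolerance (default 1e-3).
#' @return List: `value` (complex), `converged`, `blocks` (blocks consumed).
#' @export
steady_amplitude <- function(amps, rel_tol = 1e-3) {
  stopifnot(length(amps) >= 2)
  npass <- 0L
  for (n in 2:length(amps)) {
    rel <- Mod(amps[n] - amps[n - 1]) / Mod(amps[n])
    npass <- if (is.finite(rel) && rel < rel_tol) npass + 1L else 0L
    if (npass >= 2L) {
      return(list(value = amps[n], converged = TRUE, blocks = n))
    }
  }
  list(value = amps[length(amps)], converged = FALSE, blocks = length(amps))
}

#' Complex dynamic modulus from a stress time series
#'
#' Splits the stress and strain channels of a [run_oscillatory()] series into
#' blocks of `cycles_per_block` driving cycles, Fourier-transforms each block
#' at the driving frequency with an identical discrete rule, finds the steady
#' amplitude of both channels, and returns their ratio
#' `G*(omega0) = stress_amp / strain_amp` (shear mode) or the bulk analogue
#' built from the hydrostatic stress (biaxial mode).
#'
#' @param series a `stress_series` from [run_oscillatory()].
#' @param rel_tol steady-state tolerance (defaults to the protocol's).
#' @return Complex modulus with attributes `converged` and `blocks`.
#' @export
dynamic_modulus <- function(series, rel_tol = NULL) {
  protocol <- attr(series, "protocol")
  if (is.null(rel_tol)) rel_tol <- protocol$steady_rel_tol
  blen <- protocol$samples_per_cycle * protocol$cycles_per_block
  nb <- nrow(series) %/% blen
  if (nb < 2) stop("insufficient data: need at least two full blocks")
  sig <- stress_channel(as.matrix(series[, c("time", "strain", "sxx", "sxy",
                                             "syy")]), protocol$mode)
  samps <- vapply(seq_len(nb), function(n) {
    block_fourier(sig, series$time, protocol$omega0, n, blen)
  }, complex(1))
  eamps <- vapply(seq_len(nb), function(n) {
    block_fourier(series$strain, series$time, protocol$omega0, n, blen)
  }, complex(1))
  ss <- steady_amplitude(samps, rel_tol)
  se <- steady_amplitude(eamps, rel_tol)
  if (Mod(se$value) < .Machine$double.eps * 10) {
    stop("strain amplitude is numerically zero")
  }
  G <- ss$value / se$value
  attr(G, "converged") <- ss$converged && se$converged
  attr(G, "blocks") <- max(ss$blocks, se$blocks)
  G
}

#' Modulus curve container
#'
#' @param omega frequencies (strictly increasing).
#' @param modulus complex moduli at each frequency.
#' @param converged logical per-point convergence flags.
#' @param blocks integer blocks used per point.
#' @param mode deformation mode.
#' @param meta metadata list (p0, tiling kind, seed, pre-deformation a, ...).
#' @return A data frame of class `modulus_curve` with columns `omega`,
#'   `storage`, `loss`, `converged`, `blocks`.
#' @export
modulus_curve <- function(omega, modulus, converged = TRUE,
                          blocks = NA_integer_, mode = "shear",
                          meta = list()) {
  ord <- order(omega)
  structure(
    data.frame(omega = omega[ord], storage = Re(modulus)[ord],
               loss = Im(modulus)[ord],
               converged = rep_len(converged, length(omega))[ord],
               blocks = rep_len(blocks, length(omega))[ord]),
    class = c("modulus_curve", "data.frame"),
    mode = mode, meta = meta
  )
}

#' Frequency sweep
#'
#' Runs one oscillatory simulation per frequency, always starting from a
#' fresh copy of the same initial state, and assembles the measured complex
#' moduli into a [modulus_curve()]. Per-point failures are recorded (NA
#' moduli, `converged = FALSE`) and the sweep continues.
#'
#' @param mesh relaxed initial [tissue_mesh()] (reused for every frequency).
#' @param params a [model_params()].
#' @param mode `"shear"` or `"biaxial"`.
#' @param omega frequencies to probe (units `1/t*`).
#' @param ... protocol settings forwarded to [deformation_protocol()].
#' @param verbose print per-point progress.
#' @return A [modulus_curve()].
#' @export
frequency_sweep <- function(mesh, params, mode = "shear", omega, ...,
                            verbose = FALSE) {
  res <- lapply(omega, function(w) {
    out <- try({
      pr <- deformation_protocol(mode = mode, omega0 = w, ...)
      series <- run_oscillatory(mesh, params, pr)
      dynamic_modulus(series)
    }, silent = TRUE)
    if (inherits(out, "try-error")) {
      if (verbose) message(sprintf("omega = %g failed: %s", w, out))
      out <- structure(NA_complex_, converged = FALSE, blocks = NA_integer_)
    } else if (verbose) {
      message(sprintf("omega = %.3g: G' = %.4g  G'' = %.4g (%d blocks)",
                      w, Re(out), Im(out), attr(out, "blocks")))
    }
    out
  })
  modulus_curve(
    omega = omega,
    modulus = vapply(res, function(z) as.complex(z), complex(1)),
    converged = vapply(res, function(z) isTRUE(attr(z, "converged")), logical(1)),
    blocks = vapply(res, function(z) as.integer(attr(z, "blocks") %||% NA), integer(1)),
    mode = mode,
    meta = list(p0 = params$p0, kind = mesh$meta$kind %||% "unknown",
                seed = mesh$meta$seed %||% NA)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Power-law exponent of the loss modulus
#'
#' Log-log slope of the loss modulus over a frequency window, the estimator
#' used to quantify the intermediate-frequency crossover scaling of
#' disordered ensembles (a long-run analysis: large ensembles and wide
#' frequency windows are needed for a converged exponent).
#'
#' @param curve a [modulus_curve()].
#' @param window frequency interval `c(lo, hi)` (inclusive).
#' @return The fitted exponent.
#' @export
loss_exponent <- function(curve, window = range(curve$omega)) {
  d <- as.data.frame(curve)
  d <- d[d$omega >= window[1] & d$omega <= window[2] & d$loss > 0, ]
  if (nrow(d) < 3) stop("need at least 3 points in the window")
  unname(stats::coef(stats::lm(log(loss) ~ log(omega), d))[2])
}

#' Average an ensemble of modulus curves
#'
#' Per-frequency mean and standard error of the mean of storage and loss
#' moduli over configurations (all curves must share the frequency grid).
#'
#' @param curves list of [modulus_curve()]s on a common grid.
#' @return A data frame with means and standard errors.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  om <- curves[[1]]$omega
  for (cu in curves) stopifnot(isTRUE(all.equal(cu$omega, om)))
  gs <- sapply(curves, function(cu) cu$storage)
  gl <- sapply(curves, function(cu) cu$loss)
  n <- length(curves)
  data.frame(
    omega = om,
    storage = rowMeans(gs), loss = rowMeans(gl),
    storage_se = apply(gs, 1, stats::sd) / sqrt(n),
    loss_se = apply(gl, 1, stats::sd) / sqrt(n),
    n = n
  )
}

#' @export
plot.modulus_curve <- function(x, ..., main = "dynamic modulus") {
  ok <- x$converged & x$storage > 0 & x$loss > 0
  graphics::plot(x$omega[ok], x$storage[ok], log = "xy", type = "b", pch = 16,
                 xlab = expression(omega[0] * t^"*"),
                 ylab = expression(G * "'" ~ "," ~ G * "''" ~ (K * A[0])),
                 main = main, ...)
  graphics::lines(x$omega[ok], x$loss[ok], type = "b", pch = 1, lty = 2)
  graphics::legend("bottomright", legend = c("storage", "loss"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
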