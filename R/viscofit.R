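#' Standard Linear Solid moduli
#'
#' Storage and loss shear moduli of the SLS model (a spring `E2` in parallel
#' with a Maxwell element `E1`--`eta1`):
#' `G'(w) = E2 + (eta1/E1)^2 w^2 (E1+E2) / (1 + (eta1/E1)^2 w^2)` and
#' `G''(w) = w eta1 / (1 + (eta1/E1)^2 w^2)`. The single loss peak sits at
#' `w = E1/eta1` with height `E1/2`.
#'
#' @param omega frequencies.
#' @param e1,e2 spring constants (moduli).
#' @param eta1 dashpot viscosity.
#' @return List with `storage` and `loss` vectors.
#' @export
sls_moduli <- function(omega, e1, e2, eta1) {
  t2 <- (eta1 / e1)^2 * omega^2
  list(storage = (e2 + t2 * (e1 + e2)) / (1 + t2),
       loss = omega * eta1 / (1 + t2))
}

#' Burgers model moduli
#'
#' Storage and loss moduli of the Burgers model (two Maxwell elements in
#' parallel), in the rational form
#' `G'(w) = (p1 q1 w^2 - q2 w^2 (1 - p2 w^2)) / (p1^2 w^2 + (1 - p2 w^2)^2)`,
#' `G''(w) = (p1 q2 w^3 + q1 w (1 - p2 w^2)) / (p1^2 w^2 + (1 - p2 w^2)^2)`,
#' with `p1 = eta1/E1 + eta2/E2`, `p2 = eta1 eta2/(E1 E2)`,
#' `q1 = eta1 + eta2`, `q2 = eta1 eta2 (E1+E2)/(E1 E2)`. Algebraically equal
#' to the sum of the two Maxwell arms' moduli.
#'
#' @param omega frequencies.
#' @param e1,e2 spring constants of the two arms.
#' @param eta1,eta2 dashpot viscosities of the two arms.
#' @return List with `storage` and `loss` vectors.
#' @export
burgers_moduli <- function(omega, e1, e2, eta1, eta2) {
  p1 <- eta1 / e1 + eta2 / e2
  p2 <- eta1 * eta2 / (e1 * e2)
  q1 <- eta1 + eta2
  q2 <- eta1 * eta2 * (e1 + e2) / (e1 * e2)
  den <- p1^2 * omega^2 + (1 - p2 * omega^2)^2
  list(storage = (p1 * q1 * omega^2 - q2 * omega^2 * (1 - p2 * omega^2)) / den,
       loss = (p1 * q2 * omega^3 + q1 * omega * (1 - p2 * omega^2)) / den)
}

# generalized Maxwell: optional parallel spring e_inf plus n Maxwell arms
# (e_k, tau_k); complex modulus sum_k e_k i w tau_k / (1 + i w tau_k) + e_inf
gm_complex <- function(omega, e_inf, e, tau) {
  z <- rep(e_inf + 0i, length(omega))
  for (k in seq_along(e)) {
    iwt <- 1i * omega * tau[k]
    z <- z + e[k] * iwt / (1 + iwt)
  }
  z
}

#' Generalized Maxwell moduli
#'
#' `n` Maxwell arms in parallel, optionally with a parallel spring. One arm
#' plus a spring is the SLS model; two arms without a spring is the Burgers
#' model.
#'
#' @param omega frequencies.
#' @param e_inf parallel spring constant (0 for none).
#' @param e,tau vectors of arm spring constants and relaxation times.
#' @return List with `storage` and `loss` vectors.
#' @export
gm_moduli <- function(omega, e_inf, e, tau) {
  z <- gm_complex(omega, e_inf, e, tau)
  list(storage = Re(z), loss = Im(z))
}

#' Fit a spring-dashpot constitutive model to a modulus curve
#'
#' Fits the Standard Linear Solid, Burgers, or a generalized Maxwell model to
#' a measured [modulus_curve()] by nonlinear least squares on the joint
#' log-residuals of the storage and loss channels (equal weight, points below
#' `floor` excluded); positivity is enforced by optimizing in log-parameter
#' space, with Levenberg-Marquardt steps and multistart from perturbed
#' asymptote-based initial values. Maxwell arms are reported in decreasing
#' order of relaxation time, so for Burgers `t1 = eta1/E1 >= t2 = eta2/E2`.
#'
#' @param curve a [modulus_curve()] (or data frame with `omega`, `storage`,
#'   `loss`; a `converged` column, when present, filters the points used).
#' @param model `"sls"`, `"burgers"` or `"maxwell"`.
#' @param n_arms number of Maxwell arms (only for `model = "maxwell"`).
#' @param spring include a parallel spring (only for `model = "maxwell"`;
#'   `TRUE` for solid-like curves).
#' @param floor moduli below this magnitude are excluded from the objective.
#' @param n_starts multistart count (first start is the asymptote-based
#'   initialization, the rest are seeded log-normal perturbations of it).
#' @param seed seed of the multistart perturbations.
#' @return An object of class `viscofit`: coefficients, timescales, residual
#'   sum of squared log-deviations, per-point residuals and convergence
#'   diagnostics. Methods: [print()], [summary()], [coef()], [predict()],
#'   [plot()], [residuals()].
#' @export
fit_viscoelastic <- function(curve, model = c("sls", "burgers", "maxwell"),
                             n_arms = 2, spring = FALSE, floor = 1e-12,
                             n_starts = 5, seed = 1L) {
  model <- match.arg(model)
  if (model == "sls") {
    n_arms <- 1L
    spring <- TRUE
  } else if (model == "burgers") {
    n_arms <- 2L
    spring <- FALSE
  }
  n_arms <- as.integer(n_arms)
  stopifnot(n_arms >= 1)

  d <- as.data.frame(curve)
  if ("converged" %in% names(d)) d <- d[d$converged & is.finite(d$storage), ]
  d <- d[is.finite(d$storage) & is.finite(d$loss), ]
  npar <- n_arms * 2L + as.integer(spring)
  min_pts <- max(npar + 2L, if (model == "sls") 6L else 8L)
  if (nrow(d) < min_pts) {
    stop(sprintf("need at least %d converged points to fit a %s model",
                 min_pts, model))
  }
  om <- d$omega

  resid_fn <- function(logp) {
    pr <- exp(logp)
    e_inf <- if (spring) pr[1] else 0
    e <- pr[(1 + spring):(spring + n_arms)]
    tau <- pr[(spring + n_arms + 1):(spring + 2 * n_arms)]
    mod <- gm_moduli(om, e_inf, e, tau)
    r <- c(ifelse(d$storage > floor & mod$storage > 0,
                  log(mod$storage) - log(d$storage), 0),
           ifelse(d$loss > floor & mod$loss > 0,
                  log(mod$loss) - log(d$loss), 0))
    r[!is.finite(r)] <- 1e3
    r
  }

  start0 <- gm_start(d, n_arms, spring)
  starts <- list(log(start0))
  if (n_starts > 1) {
    perts <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i) {
      log(start0) + stats::rnorm(length(start0), sd = 0.5)
    }))
    starts <- c(starts, perts)
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(par = s, fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500, ftol = 1e-14,
                                    ptol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("all optimization starts failed")
  fit <- best$fit
  pr <- exp(fit$par)
  e_inf <- if (spring) pr[1] else 0
  e <- pr[(1 + spring):(spring + n_arms)]
  tau <- pr[(spring + n_arms + 1):(spring + 2 * n_arms)]
  ord <- order(tau, decreasing = TRUE) # arm 1 = slowest
  e <- e[ord]
  tau <- tau[ord]
  eta <- e * tau

  coefs <- stats::setNames(
    c(if (spring) e_inf, rbind(e, eta)),
    c(if (spring) if (model == "sls") "E2" else "E_inf",
      as.vector(rbind(paste0("E", seq_len(n_arms)),
                      paste0("eta", seq_len(n_arms)))))
  )
  structure(
    list(model = model, n_arms = n_arms, spring = spring,
         coefficients = coefs, e_inf = e_inf, e = e, eta = eta,
         timescales = tau, ssr = best$ssr,
         residuals = fit$fvec, data = d,
         converged = fit$info %in% 1:4, info = fit$info,
         message = fit$message),
    class = "viscofit"
  )
}

# asymptote-based starting values (E2 ~ low-w storage, sum E ~ high-w
# storage, slowest time from the loss maximum)
gm_start <- function(d, n_arms, spring) {
  d <- d[order(d$omega), ]
  g_lo <- max(d$storage[1], 1e-8)
  g_hi <- max(d$storage[nrow(d)], 2e-8)
  w_pk <- d$omega[which.max(d$loss)]
  e_tot <- max(g_hi - if (spring) g_lo else 0, 1e-8)
  e <- rep(e_tot / n_arms, n_arms)
  tau <- 1 / w_pk * 4^(seq_len(n_arms) - (n_arms + 1) / 2)
  c(if (spring) g_lo, e, rev(tau))
}

#' @export
print.viscofit <- function(x, ...) {
  cat(sprintf("<viscofit: %s model, %d arm(s)%s>\n", x$model, x$n_arms,
              if (x$spring) " + parallel spring" else ""))
  print(signif(x$coefficients, 6))
  cat(sprintf("timescales: %s\n",
              paste(signif(x$timescales, 4), collapse = ", ")))
  cat(sprintf("residual (sum sq log): %.3e; %s\n", x$ssr,
              if (x$converged) "converged" else
                sprintf("NOT converged (info %d: %s)", x$info, x$message)))
  invisible(x)
}

#' @export
summary.viscofit <- function(object, ...) {
  print(object)
  d <- object$data
  cat(sprintf("fitted on %d points, omega in [%.3g, %.3g]\n",
              nrow(d), min(d$omega), max(d$omega)))
  invisible(object)
}

#' @export
coef.viscofit <- function(object, ...) object$coefficients

#' Predicted moduli of a fitted constitutive model
#' @param object a `viscofit`.
#' @param omega frequencies (defaults to the fitted grid).
#' @param ... unused.
#' @return Data frame with `omega`, `storage`, `loss`.
#' @export
predict.viscofit <- function(object, omega = NULL, ...) {
  if (is.null(omega)) omega <- object$data$omega
  m <- gm_moduli(omega, object$e_inf, object$e, object$timescales)
  data.frame(omega = omega, storage = m$storage, loss = m$loss)
}

#' @export
residuals.viscofit <- function(object, ...) object$residuals

#' @export
plot.viscofit <- function(x, ...) {
  d <- x$data
  ok <- d$storage > 0 & d$loss > 0
  grid <- exp(seq(log(min(d$omega)), log(max(d$omega)), length.out = 200))
  p <- predict(x, grid)
  graphics::plot(d$omega[ok], d$storage[ok], log = "xy", pch = 16,
                 xlab = expression(omega[0] * t^"*"),
                 ylab = "modulus", main = sprintf("%s fit", x$model), ...)
  graphics::points(d$omega[ok], d$loss[ok], pch = 1)
  graphics::lines(p$omega, pmax(p$storage, 1e-300), lty = 2)
  graphics::lines(p$omega, pmax(p$loss, 1e-300), lty = 3)
  graphics::legend("bottomright",
                   legend = c("G' data", "G'' data", "G' fit", "G'' fit"),
                   pch = c(16, 1, NA, NA), lty = c(NA, NA, 2, 3), bty = "n")
  invisible(x)
}

#' @rdname fit_viscoelastic
#' @export
fit_sls <- function(curve, ...) fit_viscoelastic(curve, model = "sls", ...)

#' @rdname fit_viscoelastic
#' @export
fit_burgers <- function(curve, ...) fit_viscoelastic(curve, model = "burgers", ...)

#' @rdname fit_viscoelastic
#' @export
fit_generalized_maxwell <- function(curve, n_arms = 2, spring = FALSE, ...) {
  fit_viscoelastic(curve, model = "maxwell", n_arms = n_arms,
                   spring = spring, ...)
}

#' Synthetic modulus curve
#'
#' Closed-form SLS or Burgers moduli on a frequency grid with multiplicative
#' log-normal noise, used as a fixture for fit-recovery checks.
#'
#' @param model `"sls"` or `"burgers"`.
#' @param pars named list of model constants: `e1`, `e2`, `eta1`, and for
#'   Burgers also `eta2`.
#' @param omega frequency grid.
#' @param noise log-normal noise level (0 for exact values).
#' @param seed RNG seed.
#' @return A [modulus_curve()].
#' @export
synthetic_modulus_curve <- function(model = c("sls", "burgers"), pars, omega,
                                    noise = 0, seed = 1L) {
  model <- match.arg(model)
  m <- if (model == "sls") {
    sls_moduli(omega, pars$e1, pars$e2, pars$eta1)
  } else {
    burgers_moduli(omega, pars$e1, pars$e2, pars$eta1, pars$eta2)
  }
  if (noise > 0) {
    f <- with_seed(seed, exp(noise * stats::rnorm(2 * length(omega))))
    m$storage <- m$storage * f[seq_along(omega)]
    m$loss <- m$loss * f[length(omega) + seq_along(omega)]
  }
  modulus_curve(omega, complex(real = m$storage, imaginary = m$loss),
                converged = TRUE, mode = "synthetic",
                meta = c(list(model = model, noise = noise, seed = seed), pars))
}

#' Scaling collapse of modulus curves
#'
#' Rescales frequencies by each curve's fitted slowest relaxation time and
#' the moduli by its fitted arm modulus (`branch = "low"` uses the slow arm,
#' `"high"` the fast arm; the fluid phase needs both because it carries two
#' independent timescales). Returns the collapsed coordinates and a collapse
#' quality metric: the maximum pairwise relative deviation of log-moduli
#' interpolated on the common overlap grid.
#'
#' @param curves list of [modulus_curve()]s.
#' @param fits list of `viscofit` objects (same length and model kind).
#' @param branch `"low"` or `"high"` frequency branch.
#' @return List: `data` (collapsed points with curve index), `deviation`.
#' @export
scaling_collapse <- function(curves, fits, branch = c("low", "high")) {
  branch <- match.arg(branch)
  stopifnot(length(curves) == length(fits), length(curves) >= 2)
  kinds <- vapply(fits, function(f) f$model, character(1))
  if (length(unique(kinds)) != 1) stop("invalid argument: mixed model kinds")
  arm <- if (branch == "low") 1L else
    vapply(fits, function(f) f$n_arms, integer(1))
  rows <- lapply(seq_along(curves), function(i) {
    f <- fits[[i]]
    k <- if (length(arm) > 1) arm[i] else arm
    escale <- f$e[k] + if (f$spring) f$e_inf else 0
    tscale <- f$timescales[k]
    d <- as.data.frame(curves[[i]])
    data.frame(curve = i, x = d$omega * tscale,
               storage = d$storage / escale, loss = d$loss / escale)
  })
  dat <- do.call(rbind, rows)
  # overlap grid in x across curves
  xr <- range(do.call(rbind, lapply(rows, function(r) range(r$x))))
  lo <- max(vapply(rows, function(r) min(r$x), numeric(1)))
  hi <- min(vapply(rows, function(r) max(r$x), numeric(1)))
  dev <- NA_real_
  if (hi > lo) {
    grid <- exp(seq(log(lo), log(hi), length.out = 20))
    interp <- function(r, what) {
      stats::approx(log(r$x), log(pmax(r[[what]], 1e-300)), xout = log(grid),
                    rule = 2)$y
    }
    devs <- c()
    for (what in c("storage", "loss")) {
      ys <- sapply(rows, interp, what = what)
      devs <- c(devs, max(apply(ys, 1, function(v) diff(range(v)))))
    }
    dev <- max(devs) # max |delta log| ~ max relative deviation
  }
  list(data = dat, deviation = dev)
}
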