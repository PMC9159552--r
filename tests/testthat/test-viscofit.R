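test_that("SLS moduli have the textbook limits and loss peak", {
  e1 <- 0.4; e2 <- 0.15; eta1 <- 2
  lo <- sls_moduli(1e-9, e1, e2, eta1)
  expect_equal(lo$storage, e2, tolerance = 1e-12)
  expect_lt(lo$loss, 1e-8)
  hi <- sls_moduli(1e9, e1, e2, eta1)
  expect_equal(hi$storage, e1 + e2, tolerance = 1e-12)
  expect_lt(hi$loss, 1e-6)
  pk <- sls_moduli(e1 / eta1, e1, e2, eta1)
  expect_equal(pk$loss, e1 / 2, tolerance = 1e-12)
  grid <- 10^seq(-3, 3, length.out = 50)
  expect_equal(which.max(sls_moduli(grid, e1, e2, eta1)$loss),
               which.min(abs(grid - e1 / eta1)))
})

test_that("Burgers rational form equals the sum of two Maxwell arms", {
  with_seed(21, {
    for (rep in 1:20) {
      p <- exp(rnorm(4))
      om <- 10^seq(-3, 3, length.out = 17)
      rational <- burgers_moduli(om, p[1], p[2], p[3], p[4])
      arms <- gm_moduli(om, 0, c(p[1], p[2]), c(p[3] / p[1], p[4] / p[2]))
      expect_equal(rational$storage, arms$storage, tolerance = 1e-9)
      expect_equal(rational$loss, arms$loss, tolerance = 1e-9)
    }
  })
  # fluid limits: storage ~ w^2, loss ~ w at low frequency; plateau at high
  b <- burgers_moduli(c(1e-4, 2e-4), 0.2, 0.8, 2, 0.1)
  expect_equal(b$storage[2] / b$storage[1], 4, tolerance = 1e-4)
  expect_equal(b$loss[2] / b$loss[1], 2, tolerance = 1e-4)
  hi <- burgers_moduli(1e6, 0.2, 0.8, 2, 0.1)
  expect_equal(hi$storage, 1.0, tolerance = 1e-6)
})

test_that("fits recover synthetic constants exactly at zero noise", {
  om <- 10^seq(-2.5, 2.5, length.out = 30)
  cv <- synthetic_modulus_curve("sls", list(e1 = 0.1, e2 = 0.05, eta1 = 1), om)
  f <- fit_sls(cv)
  expect_true(f$converged)
  expect_equal(unname(coef(f)[c("E1", "E2", "eta1")]), c(0.1, 0.05, 1),
               tolerance = 1e-6)
  cb <- synthetic_modulus_curve("burgers",
                                list(e1 = 0.2, e2 = 0.8, eta1 = 2, eta2 = 0.1),
                                om)
  fb <- fit_burgers(cb)
  expect_gte(fb$timescales[1], fb$timescales[2]) # arm ordering
  expect_equal(unname(coef(fb)[c("E1", "eta1", "E2", "eta2")]),
               c(0.2, 2, 0.8, 0.1), tolerance = 1e-6)
})

test_that("Burgers recovery stays within 5% median error at 1% noise", {
  om <- 10^seq(-2.5, 2.5, length.out = 30)
  truth <- c(E1 = 0.2, eta1 = 2, E2 = 0.8, eta2 = 0.1)
  errs <- vapply(1:50, function(s) {
    cv <- synthetic_modulus_curve("burgers",
      list(e1 = 0.2, e2 = 0.8, eta1 = 2, eta2 = 0.1), om,
      noise = 0.01, seed = s)
    f <- fit_burgers(cv, n_starts = 2)
    max(abs(coef(f)[names(truth)] - truth) / truth)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("generalized Maxwell nests the SLS and Burgers models", {
  om <- 10^seq(-2, 2, length.out = 25)
  cv <- synthetic_modulus_curve("sls", list(e1 = 0.1, e2 = 0.05, eta1 = 1),
                                om, noise = 0.02, seed = 3)
  f_sls <- fit_sls(cv)
  f_gm1 <- fit_generalized_maxwell(cv, n_arms = 1, spring = TRUE)
  expect_equal(unname(coef(f_gm1)), unname(coef(f_sls)), tolerance = 1e-10)
  cb <- synthetic_modulus_curve("burgers",
                                list(e1 = 0.2, e2 = 0.8, eta1 = 2, eta2 = 0.1),
                                om, noise = 0.02, seed = 4)
  f_b <- fit_burgers(cb)
  f_gm2 <- fit_generalized_maxwell(cb, n_arms = 2, spring = FALSE)
  expect_equal(unname(coef(f_gm2)), unname(coef(f_b)), tolerance = 1e-10)
})

test_that("fitted SLS storage is monotone and its loss has a single peak", {
  om <- 10^seq(-2, 2, length.out = 25)
  cv <- synthetic_modulus_curve("sls", list(e1 = 0.3, e2 = 0.1, eta1 = 0.5),
                                om, noise = 0.05, seed = 8)
  f <- fit_sls(cv)
  p <- predict(f, 10^seq(-3, 3, length.out = 200))
  expect_true(all(diff(p$storage) >= -1e-12))
  peaks <- sum(diff(sign(diff(p$loss))) < 0)
  expect_identical(peaks, 1L)
})

test_that("viscofit objects expose the standard modelling methods", {
  om <- 10^seq(-2, 2, length.out = 20)
  cv <- synthetic_modulus_curve("sls", list(e1 = 0.1, e2 = 0.05, eta1 = 1), om)
  f <- fit_sls(cv)
  expect_s3_class(f, "viscofit")
  expect_named(coef(f), c("E2", "E1", "eta1"))
  expect_identical(nrow(predict(f)), length(om))
  expect_identical(length(residuals(f)), 2L * length(om))
  expect_output(print(f), "sls model")
  expect_output(summary(f), "fitted on 20 points")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})

test_that("fitting refuses curves with too few converged points", {
  om <- 10^seq(-1, 1, length.out = 4)
  cv <- synthetic_modulus_curve("sls", list(e1 = 0.1, e2 = 0.05, eta1 = 1), om)
  expect_error(fit_sls(cv), "at least")
})

test_that("scaling collapse is exact for rescaled copies of one shape", {
  shapes <- list(c(E = 0.1, t = 1), c(E = 0.02, t = 12), c(E = 1.5, t = 0.2))
  curves <- lapply(shapes, function(s) {
    om <- 10^seq(-2, 2, length.out = 20) / s["t"]
    synthetic_modulus_curve("sls",
      list(e1 = 2 * s[["E"]], e2 = s[["E"]], eta1 = 2 * s[["E"]] * s[["t"]]), om)
  })
  fits <- lapply(curves, fit_sls)
  col <- scaling_collapse(curves, fits)
  expect_lt(col$deviation, 1e-8)
  badfits <- list(fits[[1]], fit_generalized_maxwell(curves[[2]], 2))
  expect_error(scaling_collapse(curves[1:2], badfits), "mixed model kinds")
})

test_that("analytic limits agree with their independent constructions", {
  pr <- model_params(p0 = 3.60)
  # direct arithmetic of the affine form
  expect_equal(analytic_shear_affine(pr),
               3 * sqrt(3) * 0.289 * (1 - 3.60 / p_hex), tolerance = 1e-12)
  expect_equal(analytic_shear_affine(model_params(p0 = p_hex)), 0,
               tolerance = 1e-12)
  # numeric single-cell path reduces to the closed form at a = 1
  expect_equal(analytic_shear_affine(pr, a = 1 + 1e-12), analytic_shear_affine(pr),
               tolerance = 1e-4)
  # quasistatic limits: marginal state and Gamma = 0 give zero
  expect_equal(analytic_shear_quasistatic(model_params(p0 = p_hex)), 0,
               tolerance = 1e-9)
  expect_equal(analytic_shear_quasistatic(model_params(p0 = 3.6, gamma_p = 0)),
               0)
  expect_gt(analytic_shear_affine(pr), analytic_shear_quasistatic(pr))
  # bulk: Gamma = 0 leaves the area term; coefficient equals the
  # hexagon-dilation oracle d sigma_h / d eps with P = p_c sqrt(A)
  expect_equal(analytic_bulk(model_params(p0 = 3.65, gamma_p = 0)), 2)
  pg <- vertexrheo:::hex_cell_polygon(1)
  prm <- model_params(p0 = 3.65)
  hyd <- function(e) {
    p <- pg * (1 + e)
    A <- vertexrheo:::poly_area(p)
    P <- vertexrheo:::poly_perimeter(p)
    prm$k * (A - 1) + prm$gamma_p * (P - prm$P0) * P / (2 * A)
  }
  h <- 1e-6
  oracle <- (hyd(h) - hyd(-h)) / (2 * h)
  expect_equal(analytic_bulk(prm), oracle, tolerance = 1e-10)
})

test_that("the pre-deformed phase boundary matches the affine modulus zero", {
  expect_equal(critical_p0_predeformed(1), p_hex, tolerance = 1e-12)
  expect_lt(critical_p0_predeformed(0.95), p_hex)
  expect_gt(critical_p0_predeformed(1.05), p_hex)
  for (a in c(0.9, 0.95, 1.05, 1.15)) {
    z <- uniroot(function(p0) analytic_shear_affine(model_params(p0 = p0), a = a),
                 c(3.3, 4.2), tol = 1e-10)$root
    expect_equal(z, critical_p0_predeformed(a), tolerance = 1e-6)
  }
})
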