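test_that("block Fourier amplitudes match closed forms", {
  omega <- 0.7
  T0 <- 2 * pi / omega
  t <- seq_len(75) * (T0 / 25) # 3 cycles, 25 samples/cycle
  # pure sine: modulus A/2, phase +-pi/2
  x <- 0.3 * sin(omega * t)
  amp <- block_fourier(x, t, omega, 1, 75)
  expect_equal(Mod(amp), 0.15, tolerance = 1e-12)
  expect_equal(abs(Arg(amp)), pi / 2, tolerance = 1e-10)
  # constant signal: orthogonal to the probe frequency
  expect_lt(Mod(block_fourier(rep(2, 75), t, omega, 1, 75)), 1e-12)
  # harmonic rejection: content at 2*omega does not leak into omega
  y <- 0.3 * sin(omega * t) + 5 * sin(2 * omega * t)
  expect_equal(block_fourier(y, t, omega, 1, 75), amp, tolerance = 1e-9)
  expect_error(block_fourier(x, t, omega, 2, 75), "insufficient")
})

test_that("steady-state detection follows the two-consecutive-pass rule", {
  a <- rep(1 + 2i, 6)
  s <- steady_amplitude(a)
  expect_true(s$converged)
  expect_identical(s$blocks, 3L) # earliest possible convergence
  # geometric transient toward a limit
  tr <- (1 + 2i) + 0.5 * 0.1^(0:9)
  s2 <- steady_amplitude(tr, rel_tol = 1e-3)
  expect_true(s2$converged)
  expect_lt(Mod(s2$value - (1 + 2i)) / Mod(1 + 2i), 1e-3)
  # monotone drift never converges
  s3 <- steady_amplitude(complex(real = 1:10), rel_tol = 1e-3)
  expect_false(s3$converged)
})

test_that("dynamic modulus recovers elastic and viscous fixtures", {
  omega <- 0.9
  G0 <- 2.5
  s <- make_series(omega, stress_fun = function(t) G0 * 1e-7 * sin(omega * t))
  g <- as.complex(dynamic_modulus(s))
  expect_equal(Re(g), G0, tolerance = 1e-10)
  expect_lt(abs(Im(g)), 1e-10)
  # dashpot: stress = eta * d(strain)/dt -> G* ~ i eta omega
  eta <- 0.8
  s2 <- make_series(omega, stress_fun = function(t) {
    eta * 1e-7 * omega * cos(omega * t)
  })
  g2 <- as.complex(dynamic_modulus(s2))
  expect_equal(Im(g2), eta * omega, tolerance = 1e-3)
  expect_lt(abs(Re(g2)) / (eta * omega), 1e-6)
})

test_that("modulus curves keep ordered frequencies and survive CSV round trips", {
  cv <- modulus_curve(c(1, 0.1, 10), c(1 + 1i, 0.5 + 0.2i, 2 + 0.1i),
                      mode = "shear", meta = list(p0 = 3.6))
  expect_identical(cv$omega, c(0.1, 1, 10))
  f <- tempfile(fileext = ".csv")
  write_modulus_curve(cv, f)
  cv2 <- read_modulus_curve(f)
  expect_equal(as.data.frame(cv2), as.data.frame(cv))
  expect_identical(attr(cv2, "meta")$p0, 3.6)
})

test_that("ensemble averaging reports the standard error of the mean", {
  om <- c(0.1, 1)
  curves <- lapply(1:4, function(i) {
    modulus_curve(om, complex(real = c(1, 2) + i * 0.1, imaginary = c(0.1, 0.2)))
  })
  av <- average_curves(curves)
  expect_equal(av$storage, c(1, 2) + 0.25)
  expect_equal(av$storage_se,
               rep(sd(0.1 * (1:4)) / 2, 2), tolerance = 1e-12)
})

test_that("moduli are insensitive to sampling density", {
  m <- hex_tiling(6)
  pr <- model_params(p0 = 3.6)
  g25 <- dynamic_modulus(run_oscillatory(m, pr,
    deformation_protocol("shear", omega0 = 1, samples_per_cycle = 25)))
  g50 <- dynamic_modulus(run_oscillatory(m, pr,
    deformation_protocol("shear", omega0 = 1, samples_per_cycle = 50)))
  expect_lt(Mod(as.complex(g50) - as.complex(g25)) / Mod(as.complex(g25)), 1e-3)
})
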