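test_that("profile construction validates its grid and uncertainties", {
  expect_error(saxs_profile(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(saxs_profile(c(0.1, 0.2), c(1, 1), c(1, -1)))
  p <- saxs_profile(c(0, 0.1, 0.2), c(3, 2, 1))
  expect_s3_class(p, "saxs_profile")
})

test_that("scattering files round-trip through the 3-column text dialect", {
  q <- default_q_grid(n = 50)
  p <- saxs_profile(q, 100 * exp(-q^2 * 20^2 / 3), sigma = rep(0.5, 50))
  f <- withr::local_tempfile(fileext = ".dat")
  write_saxs(p, f, header = c("synthetic curve", "units 1/A"))
  p2 <- read_saxs(f)
  expect_equal(p2$q, p$q, tolerance = 1e-6)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-6)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-6)
})

test_that("the Debye sum obeys its closed forms and rigid-motion invariance", {
  q <- default_q_grid(n = 60)
  one <- matrix(c(0, 0, 0), 1)
  expect_equal(debye_profile(one, q)$intensity, rep(1, 60))

  d <- 12
  two <- rbind(c(0, 0, 0), c(d, 0, 0))
  I2 <- debye_profile(two, q)$intensity
  expect_equal(I2, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  # the oscillatory term vanishes where qd is a multiple of pi
  qz <- pi * (1:2) / d
  Iz <- debye_profile(two, qz)$intensity
  expect_equal(Iz, rep(2, 2), tolerance = 1e-12)

  set.seed(6)
  X <- matrix(rnorm(60, sd = 8), ncol = 3)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  expect_equal(debye_profile(X %*% t(R) + 5, q)$intensity,
               debye_profile(X, q)$intensity, tolerance = 1e-9)
  expect_error(debye_profile(X[0, , drop = FALSE], q), "empty")
})

test_that("a lattice-filled sphere matches the analytic form factor within 3% to qR = 4", {
  R <- 25
  prof <- sphere_profile(R)
  n <- NULL # normalization from forward limit
  sel <- prof$q * R <= 4
  ratio <- prof$intensity[sel] / prof$intensity[1] /
    (sphere_ff(prof$q[sel], R) / sphere_ff(prof$q[1], R))
  expect_lt(max(abs(ratio - 1)), 0.03)
})

test_that("Guinier analysis is exact on Gaussian input and accurate on spheres", {
  q <- default_q_grid()
  gf <- guinier_fit(saxs_profile(q, 100 * exp(-q^2 * 27.4^2 / 3)))
  expect_equal(gf$rg, 27.4, tolerance = 1e-4)
  expect_equal(gf$i0, 100, tolerance = 1e-4)
  expect_lte(gf$qmax_rg, 1.3 + 1e-9)

  R <- 25
  gf2 <- guinier_fit(sphere_profile(R))
  expect_equal(gf2$rg, R * sqrt(3 / 5), tolerance = 0.02)

  expect_error(guinier_fit(saxs_profile(q, exp(q^2 * 50))), "no-guinier-region")
})

test_that("the indirect transform recovers sphere and two-point distance structure", {
  R <- 25
  prof <- sphere_profile(R)
  pd <- pddf(prof, dmax = 2 * R)
  expect_equal(pd$pr[1], 0)
  expect_equal(pd$pr[length(pd$pr)], 0)
  expect_true(all(pd$pr >= 0))
  expect_equal(pd$rg_from_pr, R * sqrt(3 / 5), tolerance = 0.03)
  expect_equal(pd$r[which.max(pd$pr)], 1.05 * R, tolerance = 0.1)

  # two-point scatterer: the self term sits at r = 0 (anchored away), so the
  # transform's dominant interparticle peak must sit at the pair distance
  d <- 30
  q <- seq(0.01, 0.6, length.out = 300)
  p2 <- saxs_profile(q, 2 * (1 + sin(q * d) / (q * d)))
  pd2 <- pddf(p2, dmax = 45, alpha = 1e-6)
  peak_r <- pd2$r[pd2$r > 10][which.max(pd2$pr[pd2$r > 10])]
  expect_equal(peak_r, d, tolerance = 0.1)
})

test_that("indirect-transform and Guinier radii agree for globular scatterers", {
  g <- make_toy_globule(rg = 27.4, n_atoms = 1200, seed = 2)
  prof <- debye_profile(g)
  gf <- guinier_fit(prof)
  pd <- pddf(prof, dmax = as.numeric(estimate_dmax(prof, n_scan = 15)))
  expect_equal(pd$rg_from_pr / gf$rg, 1, tolerance = 0.05)
})

test_that("Dmax estimation lands near truth for spheres and two-point scatterers", {
  R <- 25
  dm <- estimate_dmax(sphere_profile(R))
  expect_equal(as.numeric(dm), 2 * R, tolerance = 0.05)

  d <- 30
  q <- seq(0.01, 0.6, length.out = 300)
  dm2 <- estimate_dmax(saxs_profile(q, 2 * (1 + sin(q * d) / (q * d))))
  expect_equal(as.numeric(dm2), d, tolerance = 0.15)
})

test_that("the volume of correlation is scale-invariant, convergent and size-monotone", {
  q <- seq(0.004, 0.5, length.out = 500)
  R <- 25
  prof <- debye_profile(initialize_beads(2 * R, 1.8, "full_sphere"), q)
  vc1 <- as.numeric(volume_of_correlation(prof))
  scaled <- saxs_profile(prof$q, prof$intensity * 37)
  expect_equal(as.numeric(volume_of_correlation(scaled)), vc1, tolerance = 1e-6)

  vc_03 <- as.numeric(volume_of_correlation(prof, qmax = 0.3))
  vc_05 <- as.numeric(volume_of_correlation(prof, qmax = 0.5))
  expect_lt(abs(vc_05 - vc_03) / vc_03, 0.02)

  big <- debye_profile(make_toy_globule(35, 800, seed = 3), q)
  small <- debye_profile(make_toy_globule(20, 800, seed = 4), q)
  expect_gt(as.numeric(volume_of_correlation(big)),
            as.numeric(volume_of_correlation(small)))
})

test_that("dimensionless Kratky plots separate globular from chain-like scatterers", {
  q <- default_q_grid()
  rg <- 27.4
  gau <- saxs_profile(q, 100 * exp(-q^2 * rg^2 / 3))
  kr <- dimensionless_kratky(gau)
  expect_equal(kr$x[which.max(kr$y)], sqrt(3), tolerance = 0.02)
  expect_equal(max(kr$y), 3 / exp(1), tolerance = 0.005)

  # ideal-chain (Debye chain) intensity: monotone plateau, no return to baseline
  x2 <- (q * rg)^2
  chain <- saxs_profile(q, 100 * 2 * (exp(-x2) + x2 - 1) / x2^2)
  krc <- dimensionless_kratky(chain, rg = rg, i0 = 100)
  tail_y <- krc$y[krc$x > 2]
  expect_true(all(diff(tail_y) > -1e-4))       # no decay back towards zero
  expect_gt(krc$y[length(krc$y)], max(krc$y) * 0.95)

  # Vc-based scaling stays finite and peaked
  krv <- dimensionless_kratky(sphere_profile(25), scaling = "vc")
  expect_true(all(is.finite(krv$y)))
})

test_that("profile fitting recovers scales and calibrated noise gives chi2 near 1", {
  q <- default_q_grid()
  p <- saxs_profile(q, 50 * exp(-q^2 * 25^2 / 3), sigma = rep(1, length(q)))
  self <- fit_profile(p, p)
  expect_equal(self$chi2, 0, tolerance = 1e-12)
  expect_equal(self$scale, 1, tolerance = 1e-12)

  doubled <- saxs_profile(q, 2 * p$intensity)
  expect_equal(fit_profile(p, doubled)$scale, 0.5, tolerance = 1e-12)

  q5 <- seq(0.005, 0.3, length.out = 500)
  base <- 80 * exp(-q5^2 * 22^2 / 3)
  sig <- 0.02 * base
  chis <- vapply(1:50, function(k) {
    set.seed(k)
    noisy <- saxs_profile(q5, base + rnorm(500, 0, sig), sigma = sig)
    fit_profile(noisy, saxs_profile(q5, base))$chi2
  }, numeric(1))
  expect_gt(chis[1], 0.7); expect_lt(chis[1], 1.3)
  expect_gt(mean(chis), 0.9); expect_lt(mean(chis), 1.1)

  expect_error(fit_profile(saxs_profile(1:5 / 10, rep(1, 5)),
                           saxs_profile(6:9 / 10, rep(1, 4))), "disjoint")
})

test_that("two-state mixture deconvolution recovers planted fractions", {
  q <- default_q_grid()
  a <- debye_profile(make_toy_globule(27.4, 1200, seed = 3), q)
  b <- debye_profile(make_toy_globule(22, 1200, seed = 4), q)

  pure <- mixture_fit(make_mixture(a, b, 1), a, b)
  expect_equal(pure$fraction_a, 1, tolerance = 1e-3)

  m0 <- mixture_fit(make_mixture(a, b, 0, noise_model(level = 0.01, seed = 2)), a, b)
  expect_lte(m0$fraction_a, 0.05)

  # planted-fraction recovery across the unit interval at 1% noise
  for (f in seq(0.1, 0.9, by = 0.2)) {
    for (seed in 1:4) {
      mx <- make_mixture(a, b, f, noise_model(level = 0.01, seed = seed * 100 + round(10 * f)))
      got <- mixture_fit(mx, a, b)$fraction_a
      expect_lt(abs(got - f), 0.05)
    }
  }

  expect_warning(mixture_fit(make_mixture(a, a, 0.5, noise_model(seed = 3)), a, a),
                 "degenerate-components")
})
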