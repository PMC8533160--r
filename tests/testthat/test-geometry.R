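test_that("atom distances follow plane geometry, identity and the triangle inequality", {
  res <- list(
    list(resno = 1, resid = "GLY", atoms = list(CA = c(0, 0, 0))),
    list(resno = 2, resid = "GLY", atoms = list(CA = c(3, 4, 0))))
  s <- mini_structure(res)
  expect_equal(atom_distance(s, c(1, "CA"), c(2, "CA")), 5.0)
  expect_equal(atom_distance(s, c(1, "CA"), c(1, "CA")), 0)
  expect_error(atom_distance(s, c(1, "CA"), c(9, "CA")), "named-atom-not-found")

  set.seed(42)
  for (k in 1:20) {
    pts <- matrix(rnorm(9, sd = 10), 3)
    s3 <- mini_structure(lapply(1:3, function(i)
      list(resno = i, resid = "GLY", atoms = list(CA = pts[i, ]))))
    dab <- atom_distance(s3, c(1, "CA"), c(2, "CA"))
    dbc <- atom_distance(s3, c(2, "CA"), c(3, "CA"))
    dac <- atom_distance(s3, c(1, "CA"), c(3, "CA"))
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("centre of mass handles weighting, symmetry and rotational equivariance", {
  res <- list(
    list(resno = 1, resid = "GLY", atoms = list(CA = c(0, 0, 0))),
    list(resno = 2, resid = "GLY", atoms = list(CA = c(2, 0, 0))))
  s <- mini_structure(res)
  expect_equal(center_of_mass(s, 1), c(0, 0, 0))
  expect_equal(center_of_mass(s, 1:2), c(1, 0, 0))
  expect_equal(center_of_mass(s, 1:2, weighting = "unit"), c(1, 0, 0))
  expect_error(center_of_mass(s, 99), "empty-selection")

  toy <- toy_closed()
  com0 <- center_of_mass(toy$structure, 77:404)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  s2 <- toy$structure
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms$x <- xyz[, 1]; s2$atoms$y <- xyz[, 2]; s2$atoms$z <- xyz[, 3]
  expect_equal(center_of_mass(s2, 77:404), as.numeric(R %*% com0), tolerance = 1e-10)
})

test_that("superposition is exact for rigid motions and symmetric under swapping", {
  toy <- toy_closed()
  s <- toy$structure
  expect_equal(superpose(s, s)$rmsd, 0, tolerance = 1e-9)

  th <- 0.6
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, byrow = TRUE)
  s2 <- s
  xyz <- sweep(as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R), 2, c(7, -2, 4), "+")
  s2$atoms$x <- xyz[, 1]; s2$atoms$y <- xyz[, 2]; s2$atoms$z <- xyz[, 3]
  fit <- superpose(s2, s)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-6)
  expect_identical(nrow(fit$per_residue), fit$pair_count)

  s3 <- s
  set.seed(11)
  s3$atoms$x <- s3$atoms$x + rnorm(nrow(s3$atoms), 0, 0.4)
  expect_equal(superpose(s3, s)$rmsd, superpose(s, s3)$rmsd, tolerance = 1e-6)
})

test_that("Kabsch agrees with bio3d and with a brute-force rotation search", {
  toy <- toy_closed()
  s <- toy$structure
  s2 <- s
  set.seed(23)
  s2$atoms$x <- s2$atoms$x + rnorm(nrow(s2$atoms), 0, 0.5)
  s2$atoms$y <- s2$atoms$y + rnorm(nrow(s2$atoms), 0, 0.5)
  ours <- superpose(s2, s)
  ca2 <- s2$atoms[s2$atoms$elety == "CA" & !s2$atoms$het, ]
  ca1 <- s$atoms[s$atoms$elety == "CA" & !s$atoms$het, ]
  ca2 <- ca2[order(ca2$resno), ]; ca1 <- ca1[order(ca1$resno), ]
  fx <- as.numeric(t(as.matrix(ca1[, c("x", "y", "z")])))
  mb <- as.numeric(t(as.matrix(ca2[, c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = fx, mobile = mb))
  expect_equal(ours$rmsd, as.numeric(bio3d::rmsd(fx, fitted)), tolerance = 1e-3)

  # brute force on a tiny instance: optimize a quaternion + translation
  set.seed(5)
  X <- matrix(rnorm(24, sd = 5), ncol = 3)
  Y <- matrix(rnorm(24, sd = 5), ncol = 3)
  sx <- mini_structure(lapply(1:8, function(i)
    list(resno = i, resid = "GLY", atoms = list(CA = X[i, ]))))
  sy <- mini_structure(lapply(1:8, function(i)
    list(resno = i, resid = "GLY", atoms = list(CA = Y[i, ]))))
  kab <- superpose(sx, sy)$rmsd
  quat_rmsd <- function(par) {
    q <- par[1:4] / sqrt(sum(par[1:4]^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, byrow = TRUE)
    Xc <- sweep(X, 2, colMeans(X))
    Yc <- sweep(Y, 2, colMeans(Y))
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  best <- min(vapply(1:40, function(k) {
    stats::optim(rnorm(4), quat_rmsd, method = "BFGS")$value
  }, numeric(1)))
  expect_equal(kab, best, tolerance = 1e-3)
})

test_that("superposition refuses underdetermined pairings", {
  s <- mini_structure(list(
    list(resno = 1, resid = "GLY", atoms = list(CA = c(0, 0, 0))),
    list(resno = 2, resid = "GLY", atoms = list(CA = c(1, 0, 0)))))
  expect_error(superpose(s, s), "insufficient-pairs")
})

test_that("B-factor profiles report per-residue means and match planted tables", {
  res <- lapply(1:5, function(i)
    list(resno = i, resid = "GLY", atoms = list(CA = c(i, 0, 0), CB = c(i, 1, 0))))
  s <- mini_structure(res)
  s$atoms$b <- 10
  prof <- bfactor_profile(s)
  expect_true(all(prof$b == 10))
  expect_error(bfactor_profile(s, region = 99), "empty-selection")

  toy <- toy_closed(seed = 13)
  prof2 <- bfactor_profile(toy$structure, region = 77:404)
  planted <- toy$meta$b_table
  expect_equal(prof2$b, planted$b[match(prof2$resno, planted$resno)], tolerance = 1e-9)
})
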