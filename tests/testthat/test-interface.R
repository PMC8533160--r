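test_that("Shrake-Rupley areas match isolated- and two-sphere closed forms", {
  one <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                    element = "C", x = 0, y = 0, z = 0, het = FALSE)
  r <- 1.70 + 1.4
  s1 <- sasa(one)
  expect_equal(s1$total, 4 * pi * r^2, tolerance = 0.01)
  expect_error(sasa(one, probe = -1), "invalid-parameter")

  # two identical spheres beyond contact: no occlusion
  two_far <- rbind(one, transform(one, resno = 2, x = 2 * r + 0.5))
  expect_equal(sasa(two_far)$total, 2 * 4 * pi * r^2, tolerance = 0.01)

  # intersecting spheres: each loses a cap of height R - d/2
  d <- 2.0
  two <- rbind(one, transform(one, resno = 2, x = d))
  exact <- 2 * (4 * pi * r^2 - 2 * pi * r * (r - d / 2))
  expect_equal(sasa(two)$total, exact, tolerance = 0.02)
})

test_that("SASA converges in point density and totals equal per-atom sums", {
  toy <- toy_closed()
  at <- toy$structure$atoms[toy$structure$atoms$resno %in% 1:100 &
                              !toy$structure$atoms$het, ]
  s_lo <- sasa(at, n_points = 480)
  s_hi <- sasa(at, n_points = 960)
  expect_lt(abs(s_hi$total - s_lo$total) / s_hi$total, 0.005)
  expect_equal(s_hi$total, sum(s_hi$per_atom), tolerance = 1e-6)
  expect_true(all(s_hi$per_atom >= 0))
})

test_that("buried fraction vanishes for separated domains and shrinks as the hinge opens", {
  # two far-apart pseudo-domains under the standard numbering
  set.seed(2)
  res <- c(lapply(1:40, function(i)
    list(resno = i, resid = "ALA", atoms = list(CA = c(runif(1, 0, 10), runif(1, 0, 10), runif(1, 0, 10))))),
    lapply(77:116, function(i)
      list(resno = i, resid = "ALA", atoms = list(CA = c(runif(1, 200, 210), runif(1, 0, 10), runif(1, 0, 10))))))
  s_far <- mini_structure(res)
  p_far <- partition_domains(s_far)
  bf_far <- buried_fraction(s_far, p_far, n_points = 240)
  expect_equal(unname(bf_far), c(0, 0), tolerance = 1e-9)

  angles <- c(0, 15, 30)
  bur <- vapply(angles, function(a) {
    toy <- make_toy_two_domain(toy_spec(hinge_angle = a, seed = 7))
    p <- partition_domains(toy$structure)
    buried_fraction(toy$structure, p, n_points = 240)[["catalytic"]]
  }, numeric(1))
  expect_true(all(diff(bur) < 0))
  expect_true(all(bur >= 0 & bur <= 100))
})

test_that("interface residues follow the SASA-loss threshold monotonically", {
  toy <- toy_closed()
  p <- partition_domains(toy$structure)
  ir_small <- interface_residues(toy$structure, p, dsasa_min = 0.1, n_points = 240)
  ir_big <- interface_residues(toy$structure, p, dsasa_min = 5, n_points = 240)
  for (nm in c("catalytic", "propeller")) {
    expect_true(all(ir_big$residues[[nm]] %in% ir_small$residues[[nm]]))
    expect_gte(ir_small$pct[[nm]], ir_big$pct[[nm]])
  }
  expect_gt(length(ir_small$residues$catalytic), 0)
})

test_that("salt bridges are detected from constructed geometry within the cutoff only", {
  arg_asp <- function(gap) mini_structure(list(
    list(resno = 151, resid = "ARG", atoms = list(CA = c(0, 0, 0), NH2 = c(1.5, 0, 0))),
    list(resno = 617, resid = "ASP", atoms = list(CA = c(gap + 3, 0, 0),
                                                  OD1 = c(1.5 + gap, 0, 0)))))
  hit <- find_salt_bridges(arg_asp(3.0), 151, 617)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$distance, 3.0, tolerance = 1e-9)
  expect_identical(hit$basic_atom, "NH2")
  expect_identical(nrow(find_salt_bridges(arg_asp(4.5), 151, 617)), 0L)

  gly <- mini_structure(list(
    list(resno = 1, resid = "GLY", atoms = list(CA = c(0, 0, 0), N = c(1, 0, 0))),
    list(resno = 2, resid = "ALA", atoms = list(CA = c(3, 0, 0), CB = c(4, 0, 0)))))
  expect_identical(nrow(find_salt_bridges(gly, 1, 2)), 0L)
})

test_that("hydrogen bonds use the heavy-atom distance criterion", {
  pair <- mini_structure(list(
    list(resno = 1, resid = "ALA", atoms = list(CA = c(0, 0, 0), O = c(1.2, 0, 0))),
    list(resno = 2, resid = "ALA", atoms = list(CA = c(5.5, 0, 0), N = c(4.1, 0, 0)))))
  hb <- find_hbonds(pair, 1, 2)
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)

  apart <- mini_structure(list(
    list(resno = 1, resid = "ALA", atoms = list(O = c(0, 0, 0))),
    list(resno = 2, resid = "ALA", atoms = list(N = c(50, 0, 0)))))
  expect_identical(nrow(find_hbonds(apart, 1, 2)), 0L)
})

test_that("contact lists are order-invariant and symmetric between regions", {
  toy <- toy_closed()
  s <- toy$structure
  p <- partition_domains(s)
  cat_res <- region_residues(p, "catalytic")
  prop_res <- region_residues(p, "propeller")
  hb1 <- find_hbonds(s, cat_res, prop_res)
  s_shuf <- s
  set.seed(4)
  s_shuf$atoms <- s_shuf$atoms[sample(nrow(s_shuf$atoms)), ]
  hb2 <- find_hbonds(s_shuf, cat_res, prop_res)
  expect_identical(nrow(hb1), nrow(hb2))
  expect_setequal(paste(hb1$donor_resno, hb1$acceptor_resno),
                  paste(hb2$donor_resno, hb2$acceptor_resno))

  # polar contacts mirror when querying from the partner side
  rc1 <- residue_contacts(s, 71:76, polar_cutoff = 8)
  partners <- unique(rc1$partner_resno)
  if (length(partners)) {
    rc2 <- residue_contacts(s, partners, polar_cutoff = 8)
    back <- rc2[rc2$partner_resno %in% 71:76, ]
    expect_setequal(paste(rc1$region_resno, rc1$partner_resno),
                    paste(back$partner_resno, back$region_resno))
  }
  expect_identical(nrow(residue_contacts(mini_structure(list(
    list(resno = 1, resid = "ALA", atoms = list(N = c(0, 0, 0))),
    list(resno = 50, resid = "ALA", atoms = list(N = c(99, 0, 0))))), 1)), 0L)
})
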