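test_that("writing then re-reading a structure preserves atoms, numbering and coordinates", {
  toy <- make_toy_two_domain(toy_spec(seed = 3, ligands = list(
    list(resname = "SPM", offset = c(3, 0, 2)))))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$structure, f)
  s2 <- read_structure(f)
  expect_identical(nrow(s2$atoms), nrow(toy$structure$atoms))
  a1 <- toy$structure$atoms[order(toy$structure$atoms$serial), ]
  a2 <- s2$atoms[order(s2$atoms$serial), ]
  expect_equal(a2$x, a1$x, tolerance = 1e-3)
  expect_equal(a2$y, a1$y, tolerance = 1e-3)
  expect_equal(a2$z, a1$z, tolerance = 1e-3)
  expect_identical(a2$resno, a1$resno)
  expect_identical(sum(a2$het), sum(a1$het))
})

test_that("unreadable and empty coordinate files raise informative errors", {
  expect_error(read_structure(file.path(tempdir(), "absent.pdb")), "no such file")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f)
  expect_error(read_structure(f), "")
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA ASER A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BSER A   1       5.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB ASER A   1       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BSER A   1       6.000   0.000   0.000  0.50 10.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_identical(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$elety == "CA"], 5.0)  # occupancy 0.6 wins
  expect_equal(s$atoms$x[s$atoms$elety == "CB"], 1.0)  # tie broken towards A
})

test_that("default domain partition covers 1-676 disjointly and places marker residues", {
  toy <- toy_closed()
  p <- partition_domains(toy$structure)
  core <- p$regions[c("n_loop", "hinge1", "propeller", "hinge2", "hydrolase")]
  all_res <- sort(unlist(core, use.names = FALSE))
  expect_identical(all_res, 1:676)
  expect_identical(anyDuplicated(all_res), 0L)
  expect_true(151 %in% p$regions$propeller)
  expect_true(all(c(532, 617, 652) %in% p$regions$hydrolase))
  expect_setequal(region_residues(p, "catalytic"),
                  c(p$regions$n_loop, p$regions$hydrolase))
})

test_that("residues outside every range go to the unassigned bucket, not an error", {
  res <- list(
    list(resno = 1, resid = "ALA", atoms = list(CA = c(0, 0, 0))),
    list(resno = 100, resid = "GLY", atoms = list(CA = c(5, 0, 0))),
    list(resno = 700, resid = "HIS", atoms = list(CA = c(10, 0, 0))))  # tag residue
  s <- mini_structure(res)
  p <- partition_domains(s)
  expect_identical(p$regions$unassigned, 700L)
})

test_that("overlapping custom ranges are rejected", {
  toy <- toy_closed()
  expect_error(partition_domains(toy$structure, scheme = "custom",
                                 ranges = list(a = c(1, 100), b = c(90, 200))),
               "invalid-scheme")
})

test_that("the generator-declared partition is returned unchanged for toy structures", {
  toy <- toy_closed()
  p <- partition_domains(toy$structure)
  for (nm in names(toy$meta$ranges))
    expect_identical(p$regions[[nm]], as.integer(toy$meta$ranges[[nm]]))
})

test_that("het residue counting is name-specific and chain-order invariant", {
  toy <- make_toy_two_domain(toy_spec(seed = 5, ligands = list(
    list(resname = "SPM", offset = c(3, 0, 2)),
    list(resname = "SPM", offset = c(-4, 1, 0)),
    list(resname = "GOL", offset = c(0, 6, 0)))))
  s <- toy$structure
  expect_identical(count_het_residues(s, "SPM"), 2L)
  expect_identical(count_het_residues(s, "GOL"), 1L)
  expect_identical(count_het_residues(s, "XYZ"), 0L)
  s_rev <- s
  s_rev$atoms <- s_rev$atoms[rev(seq_len(nrow(s_rev$atoms))), ]
  expect_identical(count_het_residues(s_rev, "SPM"), 2L)
})

test_that("structure census separates protein, water and ligand atoms", {
  res <- list(
    list(resno = 1, resid = "ALA", atoms = list(CA = c(0, 0, 0), N = c(1, 0, 0))),
    list(resno = 501, resid = "HOH", atoms = list(O = c(9, 0, 0)), het = TRUE),
    list(resno = 701, resid = "SPM", atoms = list(C1 = c(12, 0, 0)), het = TRUE))
  cen <- structure_census(mini_structure(res))
  expect_identical(unname(cen), c(2L, 1L, 1L))
})
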