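# shared fixtures, all generated in code

# analytic sphere form factor (normalized to 1 at q = 0)
sphere_ff <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# lattice-filled sphere profile: deterministic near-continuum Debye curve
sphere_profile <- function(R, q = default_q_grid(), bead_radius = 1.6) {
  m <- initialize_beads(dmax = 2 * R, bead_radius = bead_radius, fill = "full_sphere")
  debye_profile(m, q)
}

# minimal hand-built structure from a residue table:
# list(resno =, resid =, atoms = list(name = c(x, y, z)))
mini_structure <- function(residues, id = "mini") {
  rows <- lapply(residues, function(r) {
    do.call(rbind, lapply(names(r$atoms), function(nm) {
      p <- r$atoms[[nm]]
      data.frame(chain = "A", resno = r$resno, resid = r$resid, elety = nm,
                 element = toupper(substr(nm, 1, 1)), x = p[1], y = p[2], z = p[3],
                 het = isTRUE(r$het))
    }))
  })
  new_structure(do.call(rbind, rows), id = id)
}

toy_closed <- function(seed = 7, ...) make_toy_two_domain(toy_spec(hinge_angle = 0, seed = seed, ...))
toy_open <- function(seed = 7, ...) make_toy_two_domain(toy_spec(hinge_angle = 35, triad_gap = 15, seed = seed, ...))
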