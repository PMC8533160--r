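#' Noise model for simulated measurements
#'
#' @param kind `"gaussian_relative"` (sd = level x signal) or
#'   `"poisson_like"` (counting statistics scaled so the relative error at
#'   the curve maximum equals `level`).
#' @param level Relative noise level (> 0), e.g. 0.01 for 1%.
#' @param seed RNG seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(kind = c("gaussian_relative", "poisson_like"),
                        level = 0.01, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(level > 0)
  structure(list(kind = kind, level = level, seed = seed), class = "noise_model")
}

# uniform points inside a sphere
.runif_sphere <- function(n, radius, centre = c(0, 0, 0)) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n)^(1 / 3)
  sweep(u * r, 2, centre, "+")
}

#' Specification for a synthetic two-domain structure
#'
#' Defaults emulate the two-domain geometry of a POP-family peptidase: a
#' catalytic pseudo-domain (sphere radius 17 A housing the N-terminal-loop
#' and hydrolase residue ranges) and a beta-propeller pseudo-domain (radius
#' 21 A), joined by two 6-residue linkers, with domain centres 32 A apart in
#' the fully closed pose. The hinge angle swings the propeller away about a
#' spine below the interface, so the centre-of-mass separation grows and the
#' interface shrinks as the angle opens.
#'
#' @param radius_catalytic,radius_propeller Domain sphere radii (A).
#' @param hinge_angle Opening angle in degrees, in [0, 60].
#' @param triad_gap Planted Ser OG - His NE2 distance (A).
#' @param asp_gap Planted Asp OD - His ND1 distance (default: `triad_gap`).
#' @param overlap Domain-sphere interpenetration at angle 0 (A); must not
#'   exceed the smaller radius.
#' @param ligands List of `list(resname =, offset =)` plants; each becomes a
#'   single-atom het residue at the planted offset from the serine OG.
#' @param b_table Optional data frame (resno, b) of per-residue B-factors;
#'   generated (and recorded) when NULL.
#' @param seed RNG seed.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(radius_catalytic = 17, radius_propeller = 21, hinge_angle = 0,
                     triad_gap = 3.3, asp_gap = NULL, overlap = 6, ligands = list(),
                     b_table = NULL, seed = 1) {
  if (hinge_angle < 0 || hinge_angle > 60) stop("hinge angle must be in [0, 60] degrees")
  if (overlap > min(radius_catalytic, radius_propeller))
    stop("invalid-spec: domains overlap beyond tolerance at angle 0")
  structure(list(radius_catalytic = radius_catalytic,
                 radius_propeller = radius_propeller,
                 hinge_angle = hinge_angle, triad_gap = triad_gap,
                 asp_gap = asp_gap %||% triad_gap, overlap = overlap,
                 ligands = ligands, b_table = b_table, seed = seed),
            class = "toy_spec")
}

# residue ranges shared with the real partition scheme
.TOY_RANGES <- list(n_loop = 1:70, hinge1 = 71:76, propeller = 77:404,
                    hinge2 = 405:410, hydrolase = 411:676)

#' Generate a synthetic two-domain structure with known ground truth
#'
#' Pseudo-residues (one C-alpha each) are numbered to mimic the real domain
#' scheme so partitioning, geometry, interface and state-calling code paths
#' are shared with deposited structures. Catalytic-triad marker atoms
#' (Ser532 OG, His652 NE2/ND1, Asp617 OD1/OD2) realize the requested gaps
#' exactly; ligand plants sit at their exact offsets from the serine OG.
#' Deterministic under the spec seed.
#'
#' @param spec A [toy_spec()].
#' @return List with `structure` (a `pop_structure`) and `meta` (spec,
#'   partition ranges, domain centres and centre-of-mass distance, planted
#'   gaps, B-factor table, ligand positions).
#' @export
make_toy_two_domain <- function(spec = toy_spec()) {
  rA <- spec$radius_catalytic; rB <- spec$radius_propeller
  d0 <- rA + rB - spec$overlap
  theta <- spec$hinge_angle * pi / 180
  cA <- c(0, 0, 0)
  pivot <- c(d0 / 2, 0, -15)       # spine below the interface midpoint
  rot <- function(p) {             # rotate about the y axis through the pivot
    v <- p - pivot
    pivot + c(v[1L] * cos(theta) + v[3L] * sin(theta), v[2L],
              -v[1L] * sin(theta) + v[3L] * cos(theta))
  }
  cB <- rot(c(d0, 0, 0))
  out <- with_seed(spec$seed, {
    res_cat <- c(.TOY_RANGES$n_loop, .TOY_RANGES$hydrolase)
    res_prop <- .TOY_RANGES$propeller
    xyz_cat <- .runif_sphere(length(res_cat), rA, cA)
    xyz_prop_base <- .runif_sphere(length(res_prop), rB, c(d0, 0, 0))
    xyz_prop <- t(apply(xyz_prop_base, 1, rot))
    # linkers interpolate between facing surface points of the two domains
    anchor_a <- cA + 0.9 * rA * (cB - cA) / sqrt(sum((cB - cA)^2))
    anchor_b <- cB + 0.9 * rB * (cA - cB) / sqrt(sum((cB - cA)^2))
    link_pos <- function(k, n) anchor_a + (k / (n + 1)) * (anchor_b - anchor_a)
    xyz_h1 <- t(vapply(seq_along(.TOY_RANGES$hinge1), link_pos,
                       numeric(3), n = length(.TOY_RANGES$hinge1)))
    xyz_h2 <- t(vapply(seq_along(.TOY_RANGES$hinge2), function(k, n)
      link_pos(k, n) + c(0, 3, 0), numeric(3), n = length(.TOY_RANGES$hinge2)))
    resno <- c(res_cat, res_prop, .TOY_RANGES$hinge1, .TOY_RANGES$hinge2)
    xyz <- rbind(xyz_cat, xyz_prop, xyz_h1, xyz_h2)
    b_table <- spec$b_table %||%
      data.frame(resno = sort(resno), b = round(stats::runif(length(resno), 10, 40), 2))
    atoms <- data.frame(chain = "A", resno = resno, resid = "ALA", elety = "CA",
                        element = "C", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                        b = b_table$b[match(resno, b_table$resno)], het = FALSE)
    # planted catalytic-triad marker atoms inside the catalytic domain
    pT <- cA + c(rA - 3, 0, 0)
    og <- pT
    ne2 <- og + c(0, 0, spec$triad_gap)
    nd1 <- ne2 + c(1.36, 0, 0)
    od1 <- nd1 + c(0, 0, spec$asp_gap)
    od2 <- od1 + c(1.0, 0, 0)
    plant <- function(resno, resid, elety, element, p)
      data.frame(chain = "A", resno = resno, resid = resid, elety = elety,
                 element = element, x = p[1L], y = p[2L], z = p[3L],
                 b = 20, het = FALSE)
    triad <- rbind(
      plant(532, "SER", "OG", "O", og), plant(532, "SER", "CA", "C", og + c(0, -1.5, 0)),
      plant(652, "HIS", "NE2", "N", ne2), plant(652, "HIS", "ND1", "N", nd1),
      plant(652, "HIS", "CA", "C", ne2 + c(0, 1.5, 0)),
      plant(617, "ASP", "OD1", "O", od1), plant(617, "ASP", "OD2", "O", od2),
      plant(617, "ASP", "CA", "C", od1 + c(0, 1.5, 0)))
    atoms <- atoms[!(atoms$resno %in% c(532, 617, 652)), , drop = FALSE]
    atoms <- rbind(atoms, triad)
    lig_meta <- list()
    if (length(spec$ligands)) {
      for (k in seq_along(spec$ligands)) {
        lg <- spec$ligands[[k]]
        p <- og + lg$offset
        la <- plant(700 + k, lg$resname, "C11", "C", p)
        la$het <- TRUE
        atoms <- rbind(atoms, la)
        lig_meta[[k]] <- list(resname = lg$resname, resno = 700 + k,
                              position = p, distance_to_og = sqrt(sum(lg$offset^2)))
      }
    }
    atoms <- atoms[order(atoms$het, atoms$resno), , drop = FALSE]
    atoms$serial <- seq_len(nrow(atoms))
    list(atoms = atoms, b_table = b_table, lig_meta = lig_meta)
  })
  s <- new_structure(out$atoms, id = sprintf("toy_angle%02d", round(spec$hinge_angle)))
  prot <- out$atoms[!out$atoms$het, , drop = FALSE]
  com_of <- function(res) colMeans(as.matrix(
    prot[prot$resno %in% res, c("x", "y", "z")]))
  com_cat <- com_of(c(.TOY_RANGES$n_loop, .TOY_RANGES$hydrolase))
  com_prop <- com_of(.TOY_RANGES$propeller)
  list(structure = s,
       meta = list(spec = spec, ranges = .TOY_RANGES,
                   com_catalytic = com_cat, com_propeller = com_prop,
                   com_distance = sqrt(sum((com_cat - com_prop)^2)),
                   triad_gap = spec$triad_gap, asp_gap = spec$asp_gap,
                   b_table = out$b_table, ligands = out$lig_meta,
                   domain_centres = list(catalytic = cA, propeller = cB),
                   seed = spec$seed))
}

#' Generate a globular pseudo-particle with an exact radius of gyration
#'
#' Uniformly fills a sphere and rescales the coordinates so the unit-weight
#' Rg equals `rg` exactly; a convenient ground-truth scatterer for
#' solution-scattering validation at the size scale of a ~76 kDa two-domain
#' peptidase (Rg 26-28 A).
#'
#' @param rg Target radius of gyration (A).
#' @param n_atoms Number of pseudo-atoms.
#' @param seed RNG seed.
#' @return A `pop_structure` of carbon pseudo-atoms.
#' @export
make_toy_globule <- function(rg = 27.4, n_atoms = 2000, seed = 1) {
  xyz <- with_seed(seed, .runif_sphere(n_atoms, rg * sqrt(5 / 3)))
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- xyz * rg / radius_of_gyration(xyz)
  new_structure(data.frame(chain = "A", resno = seq_len(n_atoms), resid = "ALA",
                           elety = "CA", element = "C",
                           x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], het = FALSE),
                id = sprintf("globule_rg%.1f", rg))
}

.apply_noise <- function(I, noise, n_frames = 1) {
  if (noise$kind == "gaussian_relative") {
    sigma <- noise$level * abs(I) / sqrt(n_frames)
    frames <- vapply(seq_len(n_frames), function(f)
      I * (1 + noise$level * stats::rnorm(length(I))), numeric(length(I)))
    list(I = rowMeans(matrix(frames, ncol = n_frames)), sigma = sigma)
  } else {
    cc <- 1 / (noise$level^2 * max(I))
    frames <- vapply(seq_len(n_frames), function(f)
      stats::rpois(length(I), cc * I) / cc, numeric(length(I)))
    list(I = rowMeans(matrix(frames, ncol = n_frames)),
         sigma = sqrt(I / cc) / sqrt(n_frames))
  }
}

#' Simulate a SAXS measurement of a structure
#'
#' Debye forward scattering plus per-point noise; optional frame averaging
#' (n frames averaged, uncertainties scaled by 1/sqrt(n)), mimicking
#' multi-frame synchrotron acquisition.
#'
#' @param model A `pop_structure` (or coordinate matrix).
#' @param noise A [noise_model()], or NULL for a noise-free curve.
#' @param q q grid.
#' @param n_frames Frames averaged.
#' @param form_factor Passed to [debye_profile()].
#' @return A `saxs_profile` with `sigma` set (when noise is present) and the
#'   seed recorded in attribute `seed`.
#' @export
simulate_saxs <- function(model, noise = noise_model(), q = default_q_grid(),
                          n_frames = 1, form_factor = "uniform") {
  base <- debye_profile(model, q = q, form_factor = form_factor)
  if (is.null(noise)) return(base)
  ns <- with_seed(noise$seed, .apply_noise(base$intensity, noise, n_frames))
  p <- saxs_profile(q, ns$I, pmax(ns$sigma, 1e-12 * max(base$intensity)))
  attr(p, "seed") <- noise$seed
  p
}

#' Mix two scattering profiles at a planted volume fraction
#'
#' `f I_a + (1-f) I_b` plus optional noise; the planted fraction is recorded
#' in the `planted_fraction` attribute.
#'
#' @param profile_a,profile_b `saxs_profile` objects on identical q grids.
#' @param f Fraction of component a, in [0, 1].
#' @param noise Optional [noise_model()].
#' @return A `saxs_profile`.
#' @export
make_mixture <- function(profile_a, profile_b, f, noise = NULL) {
  stopifnot(f >= 0, f <= 1)
  if (length(profile_a$q) != length(profile_b$q) ||
      max(abs(profile_a$q - profile_b$q)) > 1e-9)
    stop("incompatible q grids")
  I <- f * profile_a$intensity + (1 - f) * profile_b$intensity
  if (is.null(noise)) {
    p <- saxs_profile(profile_a$q, I)
  } else {
    ns <- with_seed(noise$seed, .apply_noise(I, noise))
    p <- saxs_profile(profile_a$q, ns$I, pmax(ns$sigma, 1e-12 * max(I)))
  }
  attr(p, "planted_fraction") <- f
  p
}

#' Simulate Michaelis-Menten rate data
#'
#' @param kcat,km Planted parameters (km in the unit of `s_grid`).
#' @param s_grid Substrate concentrations; default 10 points log-spaced on
#'   0.2-5 Km.
#' @param noise A [noise_model()] applied multiplicatively, or NULL.
#' @return A [kinetics_dataset()] with attribute `planted = c(kcat, km)`.
#' @export
simulate_mm <- function(kcat, km, s_grid = NULL, noise = noise_model(level = 0.02)) {
  stopifnot(kcat > 0, km > 0)
  if (is.null(s_grid)) s_grid <- exp(seq(log(0.2 * km), log(5 * km), length.out = 10))
  v <- kcat * s_grid / (km + s_grid)
  if (!is.null(noise))
    v <- with_seed(noise$seed, v * (1 + noise$level * stats::rnorm(length(v))))
  d <- kinetics_dataset(s_grid, v)
  attr(d, "planted") <- c(kcat = kcat, km = km)
  d
}
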