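# van der Waals radii (A) used for accessible-surface calculations
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
               H = 1.20, FE = 1.40, ZN = 1.39, MG = 1.73)

.vdw_of <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over element-typed van der Waals spheres, counting
#' quasi-uniform test points on each expanded sphere that are not occluded by
#' any neighbouring sphere.
#'
#' @param x A `pop_structure` or an atom data frame (columns x, y, z, element,
#'   and optionally chain/resno for per-residue totals).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @param resnos,chain Optional residue/chain selection when `x` is a
#'   structure (waters and ligands are excluded there).
#' @return A `pop_sasa`: list with `per_atom` (A^2, one per atom row),
#'   `per_residue` (named by resno when available), `total`, `probe_radius`,
#'   `n_points`.
#' @export
sasa <- function(x, probe = 1.4, n_points = 960, resnos = NULL, chain = NULL) {
  if (probe <= 0) stop("invalid-parameter: probe radius must be positive")
  atoms <- if (inherits(x, "pop_structure")) .select_atoms(x, resnos = resnos, chain = chain) else x
  n <- nrow(atoms)
  if (is.null(n) || n == 0L) stop("sasa: empty atom set")
  xyz <- .xyz_of(atoms)
  rad <- .vdw_of(atoms$element) + probe
  pts <- .sphere_points(n_points)
  # coarse neighbour search on a grid keyed by max expanded radius
  cut <- 2 * max(rad)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cut)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cellmap <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb_keys <- paste(cell[i, 1] + offsets[, 1], cell[i, 2] + offsets[, 2],
                     cell[i, 3] + offsets[, 3])
    cand <- unlist(cellmap[nb_keys], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      dv <- sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])
      d2 <- rowSums(dv^2)
      cand <- cand[d2 < (rad[i] + rad[cand])^2]
    }
    if (!length(cand)) { area[i] <- 4 * pi * rad[i]^2; next }
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in cand) {
      if (!any(acc)) break
      dv <- sweep(p[acc, , drop = FALSE], 2, xyz[j, ])
      acc[acc] <- rowSums(dv^2) > rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  per_res <- NULL
  if (!is.null(atoms$resno)) {
    pr <- tapply(area, atoms$resno, sum)
    per_res <- setNames(as.numeric(pr), names(pr))
  }
  structure(list(per_atom = area, per_residue = per_res, total = sum(area),
                 probe_radius = probe, n_points = n_points), class = "pop_sasa")
}

# SASA bookkeeping shared by buried_fraction / interface_residues: for each of
# the two domains, per-residue areas in isolation and in the full (two-domain)
# context. Hinge strands are covalent connectors, not interface, and are
# excluded from both domain definitions; waters/ligands are excluded from the
# context by default.
.domain_sasa <- function(s, p, probe = 1.4, n_points = 960) {
  doms <- list(catalytic = region_residues(p, "catalytic"),
               propeller = region_residues(p, "propeller"))
  full_res <- sort(unique(c(doms$catalytic, doms$propeller)))
  full <- sasa(s, probe = probe, n_points = n_points, resnos = full_res, chain = p$chain)
  out <- list()
  for (nm in names(doms)) {
    if (length(doms[[nm]]) == 0L) stop("degenerate domain: ", nm)
    alone <- sasa(s, probe = probe, n_points = n_points, resnos = doms[[nm]], chain = p$chain)
    keys <- names(alone$per_residue)
    out[[nm]] <- list(
      alone = alone$per_residue,
      in_full = full$per_residue[keys],
      total_alone = alone$total,
      total_in_full = sum(full$per_residue[keys], na.rm = TRUE)
    )
  }
  out
}

#' Buried fraction of each domain surface at the interdomain interface
#'
#' For the catalytic and propeller domains: 100 x (SASA(domain alone) -
#' SASA(domain in the two-domain context)) / SASA(domain alone). Hinge
#' strands are excluded from both domains.
#'
#' @param s A `pop_structure`.
#' @param p A `pop_partition` (see [partition_domains()]).
#' @param probe,n_points Passed to [sasa()].
#' @return Named numeric vector of percentages (`catalytic`, `propeller`).
#' @export
buried_fraction <- function(s, p, probe = 1.4, n_points = 960) {
  ds <- .domain_sasa(s, p, probe, n_points)
  vapply(ds, function(d) {
    if (sum(d$alone > 0) < 10) stop("degenerate domain: fewer than 10 surface atoms")
    100 * (d$total_alone - d$total_in_full) / d$total_alone
  }, numeric(1))
}

#' Interface residues by SASA loss
#'
#' A residue is interfacial when its accessible area drops by more than
#' `dsasa_min` between the isolated-domain and two-domain contexts.
#'
#' @inheritParams buried_fraction
#' @param dsasa_min Area-loss threshold in A^2 (default 0.1).
#' @return List with `residues` (per-domain residue-number vectors) and `pct`
#'   (per-domain percentage of domain residues that are interfacial).
#' @export
interface_residues <- function(s, p, dsasa_min = 0.1, probe = 1.4, n_points = 960) {
  ds <- .domain_sasa(s, p, probe, n_points)
  res <- lapply(ds, function(d) {
    drop <- d$alone - d$in_full
    as.integer(names(drop)[drop > dsasa_min])
  })
  pct <- vapply(names(ds), function(nm)
    100 * length(res[[nm]]) / length(ds[[nm]]$alone), numeric(1))
  list(residues = res, pct = pct)
}

# formally charged side-chain atoms
BASIC_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
BASIC_ATOMS_HIS <- c(BASIC_ATOMS, list(HIS = c("ND1", "NE2")))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.charged_atoms <- function(atoms, table) {
  keep <- rep(FALSE, nrow(atoms))
  for (res in names(table))
    keep <- keep | (atoms$resid == res & atoms$elety %in% table[[res]])
  atoms[keep, , drop = FALSE]
}

#' Salt bridges between two residue selections
#'
#' Pairs formally charged basic (Arg NH1/NH2/NE, Lys NZ, optionally His
#' ND1/NE2) and acidic (Asp OD1/OD2, Glu OE1/OE2) side-chain atoms across the
#' two selections; one bridge per residue pair, at the minimum atom distance.
#'
#' @param s A `pop_structure`.
#' @param sel_a,sel_b Residue-number vectors.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @param include_his Count histidine as basic (default FALSE).
#' @param chain Optional chain id.
#' @return Data frame: basic_resno, basic_resid, basic_atom, acidic_resno,
#'   acidic_resid, acidic_atom, distance.
#' @export
find_salt_bridges <- function(s, sel_a, sel_b, cutoff = 4.0, include_his = FALSE,
                              chain = NULL) {
  btab <- if (include_his) BASIC_ATOMS_HIS else BASIC_ATOMS
  a <- .select_atoms(s, resnos = sel_a, chain = chain)
  b <- .select_atoms(s, resnos = sel_b, chain = chain)
  hits <- rbind(.pair_min(.charged_atoms(a, btab), .charged_atoms(b, ACIDIC_ATOMS), cutoff),
                .pair_min(.charged_atoms(b, btab), .charged_atoms(a, ACIDIC_ATOMS), cutoff))
  names(hits) <- c("basic_resno", "basic_resid", "basic_atom",
                   "acidic_resno", "acidic_resid", "acidic_atom", "distance")
  hits[order(hits$distance), , drop = FALSE]
}

# minimum-distance contact per residue pair between two atom sets
.pair_min <- function(A, B, cutoff) {
  empty <- data.frame(resno_a = integer(), resid_a = character(), atom_a = character(),
                      resno_b = integer(), resid_b = character(), atom_b = character(),
                      distance = numeric())
  if (nrow(A) == 0L || nrow(B) == 0L) return(empty)
  D <- .cross_dist(.xyz_of(A), .xyz_of(B))
  idx <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  out <- data.frame(resno_a = A$resno[idx[, 1]], resid_a = A$resid[idx[, 1]],
                    atom_a = A$elety[idx[, 1]], resno_b = B$resno[idx[, 2]],
                    resid_b = B$resid[idx[, 2]], atom_b = B$elety[idx[, 2]],
                    distance = D[idx], stringsAsFactors = FALSE)
  key <- paste(out$resno_a, out$resno_b)
  out <- out[order(out$distance), ]
  out[!duplicated(paste(out$resno_a, out$resno_b)), , drop = FALSE]
}

.cross_dist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  sqrt(pmax(d2, 0))
}

# hydrogen-bond capable heavy atoms, by atom name (models carry no hydrogens,
# so the criterion is purely distance-based)
HB_DONOR_NAMES <- c("N", "NE", "NH1", "NH2", "NZ", "ND1", "NE2", "ND2", "NE1",
                    "OG", "OG1", "OH", "SG", "O")
HB_ACCEPTOR_NAMES <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
                       "OH", "ND1", "NE2", "SD")

#' Hydrogen bonds between two residue selections (geometric criterion)
#'
#' Donor-capable and acceptor-capable N/O heavy atoms within `d_max`; no
#' angular term and no hydrogen placement, so counts are comparable between
#' structures but not identical to PISA's.
#'
#' @inheritParams find_salt_bridges
#' @param d_max Heavy-atom donor-acceptor cutoff (default 3.5 A).
#' @return Data frame of donor/acceptor atoms and distances (one per
#'   donor-acceptor residue pair, minimum distance).
#' @export
find_hbonds <- function(s, sel_a, sel_b, d_max = 3.5, chain = NULL) {
  a <- .select_atoms(s, resnos = sel_a, chain = chain)
  b <- .select_atoms(s, resnos = sel_b, chain = chain)
  don_a <- a[a$elety %in% HB_DONOR_NAMES, , drop = FALSE]
  acc_a <- a[a$elety %in% HB_ACCEPTOR_NAMES, , drop = FALSE]
  don_b <- b[b$elety %in% HB_DONOR_NAMES, , drop = FALSE]
  acc_b <- b[b$elety %in% HB_ACCEPTOR_NAMES, , drop = FALSE]
  hits <- rbind(.pair_min(don_a, acc_b, d_max), .pair_min(don_b, acc_a, d_max))
  names(hits) <- c("donor_resno", "donor_resid", "donor_atom",
                   "acceptor_resno", "acceptor_resid", "acceptor_atom", "distance")
  # one bond per unordered residue pair
  key <- paste(pmin(hits$donor_resno, hits$acceptor_resno),
               pmax(hits$donor_resno, hits$acceptor_resno))
  hits <- hits[order(hits$distance), ]
  hits[!duplicated(paste(pmin(hits$donor_resno, hits$acceptor_resno),
                         pmax(hits$donor_resno, hits$acceptor_resno))), , drop = FALSE]
}

#' Polar contacts of a region with the rest of the chain
#'
#' All N/O-N/O atom pairs within `polar_cutoff` between the region and every
#' other residue of the same chain.
#'
#' @param s A `pop_structure`.
#' @param region Residue numbers of the query region.
#' @param polar_cutoff Distance cutoff (default 3.6 A).
#' @param chain Optional chain id.
#' @return Data frame: region_resno, region_atom, partner_resno,
#'   partner_resid, partner_atom, distance (all qualifying atom pairs).
#' @export
residue_contacts <- function(s, region, polar_cutoff = 3.6, chain = NULL) {
  if (length(region) == 0L) stop("empty-selection: region is empty")
  prot <- .protein_atoms(s, chain)
  a <- prot[prot$resno %in% region & prot$element %in% c("N", "O"), , drop = FALSE]
  b <- prot[!(prot$resno %in% region) & prot$element %in% c("N", "O"), , drop = FALSE]
  empty <- data.frame(region_resno = integer(), region_atom = character(),
                      partner_resno = integer(), partner_resid = character(),
                      partner_atom = character(), distance = numeric())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  D <- .cross_dist(.xyz_of(a), .xyz_of(b))
  idx <- which(D <= polar_cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  out <- data.frame(region_resno = a$resno[idx[, 1]], region_atom = a$elety[idx[, 1]],
                    partner_resno = b$resno[idx[, 2]], partner_resid = b$resid[idx[, 2]],
                    partner_atom = b$elety[idx[, 2]], distance = D[idx],
                    stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}
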