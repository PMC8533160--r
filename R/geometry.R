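# standard atomic masses (heavy atoms; unknown elements fall back to carbon)
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
                 MN = 54.938, "NA" = 22.990, CL = 35.45, CA = 40.078, K = 39.098)
ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34, FE = 26,
                   ZN = 30, MG = 12, MN = 25, "NA" = 11, CL = 17, CA = 20, K = 19)

.mass_of <- function(element) {
  m <- ATOMIC_MASS[element]
  m[is.na(m)] <- ATOMIC_MASS[["C"]]
  unname(m)
}

.xyz_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Coordinates of a single named atom
#' @noRd
.atom_xyz <- function(s, resno, atom_name, chain = NULL, het = FALSE) {
  a <- .select_atoms(s, resnos = resno, atom_names = atom_name, chain = chain, het = het)
  if (nrow(a) == 0L && !het) # allow het residues (e.g. ligand targets) too
    a <- .select_atoms(s, resnos = resno, atom_names = atom_name, chain = chain, het = TRUE)
  if (nrow(a) == 0L)
    stop("named-atom-not-found: residue ", resno, " atom ", atom_name)
  as.numeric(a[1L, c("x", "y", "z")])
}

#' Euclidean distance between two named atoms
#'
#' @param s A `pop_structure`.
#' @param a,b Length-2 specifiers `c(resno, atom_name)` or `list(resno, name)`,
#'   e.g. `c(532, "CA")`.
#' @param chain Optional chain id (default: first protein chain).
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(s, a, b, chain = NULL) {
  pa <- .atom_xyz(s, as.integer(a[[1L]]), as.character(a[[2L]]), chain)
  pb <- .atom_xyz(s, as.integer(b[[1L]]), as.character(b[[2L]]), chain)
  sqrt(sum((pa - pb)^2))
}

#' Centre of mass of a residue selection
#'
#' Heavy atoms only; weighting is by standard atomic mass by default, or
#' unit weights on request (the two differ by well under an Angstrom for
#' globular domains, and both are reported in the state-profile output).
#'
#' @param s A `pop_structure`.
#' @param region Integer vector of residue numbers.
#' @param weighting `"atomic_mass"` or `"unit"`.
#' @param chain Optional chain id.
#' @return Numeric length-3 coordinate (Angstrom).
#' @export
center_of_mass <- function(s, region, weighting = c("atomic_mass", "unit"), chain = NULL) {
  weighting <- match.arg(weighting)
  a <- .select_atoms(s, resnos = region, chain = chain)
  if (nrow(a) == 0L) stop("empty-selection: no atoms in region")
  w <- if (weighting == "atomic_mass") .mass_of(a$element) else rep(1, nrow(a))
  unname(colSums(.xyz_of(a) * w) / sum(w))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Pairs C-alpha atoms by residue number (residues present in both structures
#' only; unpaired residues are excluded and counted) or accepts explicit index
#' pairs, then solves the least-squares rotation/translation via SVD.
#'
#' @param mobile,reference `pop_structure` objects.
#' @param pairing `"ca_by_resnum"` or `"custom"`.
#' @param pairs For custom pairing: two-column matrix of residue numbers
#'   (mobile, reference); C-alpha atoms are still used.
#' @param chain Optional chain id applied to both structures.
#' @return A `pop_superposition`: rotation (3x3, det +1), translation, rmsd,
#'   pair_count, n_unpaired and `per_residue` data frame of displacements
#'   after fitting.
#' @export
superpose <- function(mobile, reference, pairing = c("ca_by_resnum", "custom"),
                      pairs = NULL, chain = NULL) {
  pairing <- match.arg(pairing)
  ca_m <- .select_atoms(mobile, atom_names = "CA", chain = chain)
  ca_r <- .select_atoms(reference, atom_names = "CA", chain = chain)
  if (pairing == "ca_by_resnum") {
    common <- intersect(ca_m$resno, ca_r$resno)
    pairs <- cbind(common, common)
  } else if (is.null(pairs)) stop("custom pairing requires 'pairs'")
  if (nrow(pairs) < 3L) stop("insufficient-pairs: need at least 3 paired atoms")
  im <- match(pairs[, 1L], ca_m$resno)
  ir <- match(pairs[, 2L], ca_r$resno)
  ok <- !is.na(im) & !is.na(ir)
  if (sum(ok) < 3L) stop("insufficient-pairs: need at least 3 paired atoms")
  X <- .xyz_of(ca_m[im[ok], ])  # mobile
  Y <- .xyz_of(ca_r[ir[ok], ])  # reference
  fit <- .kabsch(X, Y)
  Xf <- sweep(X, 2, fit$cx) %*% fit$rotation
  Xf <- sweep(Xf, 2, fit$cy, "+")
  d <- sqrt(rowSums((Xf - Y)^2))
  structure(list(
    rotation = fit$rotation,
    translation = as.numeric(fit$cy - fit$cx %*% fit$rotation),
    rmsd = sqrt(mean(d^2)),
    pair_count = sum(ok),
    n_unpaired = (nrow(ca_m) - sum(ok)) + (nrow(ca_r) - sum(ok)),
    per_residue = data.frame(resno = pairs[ok, 1L], displacement = d)
  ), class = "pop_superposition")
}

# least-squares rotation: rows of sweep(X,2,cx) %*% R approximate rows of
# sweep(Y,2,cy); reflection guarded so det(R) = +1
.kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, cx = cx, cy = cy)
}

#' Apply a superposition to a structure's coordinates
#'
#' @param s A `pop_structure`.
#' @param fit A `pop_superposition` from [superpose()].
#' @return The structure with transformed coordinates.
#' @export
apply_superposition <- function(s, fit) {
  xyz <- .xyz_of(s$atoms) %*% fit$rotation
  xyz <- sweep(xyz, 2, fit$translation, "+")
  s$atoms$x <- xyz[, 1L]; s$atoms$y <- xyz[, 2L]; s$atoms$z <- xyz[, 3L]
  s
}

#' Per-residue mean heavy-atom B-factor profile
#'
#' @param s A `pop_structure`.
#' @param region Residue numbers (default: all protein residues of the first
#'   chain).
#' @param chain Optional chain id.
#' @return Data frame with `resno` and `b` (Angstrom^2), ordered by residue.
#' @export
bfactor_profile <- function(s, region = NULL, chain = NULL) {
  a <- .select_atoms(s, resnos = region, chain = chain)
  if (nrow(a) == 0L) stop("empty-selection: no atoms in region")
  b <- tapply(a$b, a$resno, mean)
  data.frame(resno = as.integer(names(b)), b = as.numeric(b), row.names = NULL)
}

#' Radius of gyration of a coordinate set
#'
#' @param xyz Nx3 coordinate matrix.
#' @param w Optional weights (default unit).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(xyz, w = NULL) {
  xyz <- as.matrix(xyz)
  if (is.null(w)) w <- rep(1, nrow(xyz))
  com <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)) / sum(w))
}
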