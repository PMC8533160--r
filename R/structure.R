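#' @importFrom stats approx coef dist lm median nls optimize quantile sd setNames var
#' @importFrom utils head read.table tail write.table
NULL

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read an atomic structure from a PDB or mmCIF file
#'
#' Parses coordinates into the package's structure container. Alternate
#' locations are collapsed to a single conformer (highest occupancy, ties
#' broken towards altloc "A"), hydrogens are dropped, and waters and other
#' heteroatoms are retained with their `het` flag set. Author residue
#' numbering is used throughout, because that is how POP-family catalytic
#' residues (e.g. Ser532/Asp617/His652 in PSP) are conventionally labelled.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (from the file extension), `"pdb"` or `"mmcif"`.
#' @param chain Optional chain identifier; by default all chains are kept and
#'   downstream single-chain analyses use the first protein chain.
#' @return An object of class `pop_structure`: a list with `id`, an `atoms`
#'   data frame (serial, chain, resno, insert, resid, elety, element, x, y, z,
#'   b, occ, het) and `source_format`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), chain = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("parse error reading '", path, "': ", conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty-structure: no ATOM/HETATM records in ", path)
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = .element_of(at),
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  atoms <- .resolve_altloc(atoms)
  atoms$alt <- NULL
  if (nrow(atoms) == 0L) stop("empty-structure: no heavy atoms left after filtering")
  new_structure(atoms, id = sub("\\.(pdb|cif|ent)$", "", basename(path), ignore.case = TRUE),
                source_format = format)
}

.element_of <- function(at) {
  el <- if (!is.null(at$elesy)) toupper(trimws(at$elesy)) else rep("", nrow(at))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the first alphabetic character of the atom name
    guess <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", at$elety[miss])), 1, 1))
    two <- toupper(substr(at$elety[miss], 1, 2))
    guess[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "CA") & at$type[miss] == "HETATM"] <-
      two[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "CA") & at$type[miss] == "HETATM"]
    el[miss] <- guess
  }
  el
}

.resolve_altloc <- function(atoms) {
  has_alt <- atoms$alt != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$elety, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    best <- idx[order(-atoms$occ[idx], atoms$alt[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Construct a structure object from an atom table
#'
#' @param atoms Data frame with at least chain, resno, resid, elety, element,
#'   x, y, z columns; `serial`, `b`, `occ`, `insert`, `het` are filled with
#'   defaults when absent.
#' @param id Structure identifier string.
#' @param source_format Provenance tag (`"pdb"`, `"mmcif"` or `"memory"`).
#' @return A `pop_structure` object.
#' @export
new_structure <- function(atoms, id = "structure", source_format = "memory") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  defaults <- list(serial = seq_len(nrow(atoms)), insert = "", b = 0, occ = 1, het = FALSE)
  for (nm in names(defaults)) if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  atoms$resno <- as.integer(atoms$resno)
  atoms$serial <- as.integer(atoms$serial)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  stopifnot(all(atoms$occ >= 0 & atoms$occ <= 1), all(nzchar(atoms$element)))
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "pop_structure")
}

#' @export
print.pop_structure <- function(x, ...) {
  cen <- structure_census(x)
  cat(sprintf("<pop_structure> %s [%s]: %d atoms (%d protein, %d water, %d ligand), chains: %s\n",
              x$id, x$source_format, nrow(x$atoms), cen["protein"], cen["water"],
              cen["ligand"], paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Count protein, water and ligand atoms
#'
#' @param s A `pop_structure`.
#' @return Named integer vector with elements `protein`, `water`, `ligand`.
#' @export
structure_census <- function(s) {
  a <- s$atoms
  water <- a$het & a$resid %in% WATER_RESNAMES
  ligand <- a$het & !water
  c(protein = sum(!a$het), water = sum(water), ligand = sum(ligand))
}

#' Atoms of the first protein chain
#' @noRd
.protein_atoms <- function(s, chain = NULL) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  if (nrow(a) == 0L) stop("structure has no protein atoms")
  if (is.null(chain)) chain <- a$chain[1L]
  a[a$chain == chain, , drop = FALSE]
}

#' Partition a POP-family chain into its domain regions
#'
#' The default scheme (`psp_default`) follows the PSP two-domain architecture:
#' N-terminal loop 1-70, first hinge strand 71-76, seven-bladed beta-propeller
#' 77-404, second hinge strand 405-410, and alpha/beta-hydrolase fold 411-676.
#' The catalytic domain is the union of the N-terminal loop and the hydrolase
#' fold. Residues outside every declared range (expression-tag residues,
#' waters, ligands) land in the `unassigned` bucket.
#'
#' @param s A `pop_structure`.
#' @param scheme `"psp_default"` or `"custom"` with explicit `ranges`.
#' @param ranges Named list of `c(first, last)` residue-number ranges
#'   (required when `scheme = "custom"`); ranges must not overlap.
#' @param chain Chain to partition (default: first protein chain).
#' @return A `pop_partition`: list with `regions` (named list of residue
#'   numbers), `scheme_id` and `chain`.
#' @export
partition_domains <- function(s, scheme = c("psp_default", "custom"), ranges = NULL,
                              chain = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "psp_default") {
    ranges <- list(n_loop = c(1, 70), hinge1 = c(71, 76), propeller = c(77, 404),
                   hinge2 = c(405, 410), hydrolase = c(411, 676))
  } else if (is.null(ranges)) {
    stop("custom scheme requires 'ranges'")
  }
  rngm <- do.call(rbind, ranges)
  ord <- order(rngm[, 1L])
  if (any(rngm[ord, 1L][-1L] <= rngm[ord, 2L][-length(ranges)]))
    stop("invalid-scheme: custom ranges overlap")
  prot <- .protein_atoms(s, chain)
  resnos <- sort(unique(prot$resno))
  regions <- lapply(ranges, function(r) resnos[resnos >= r[1L] & resnos <= r[2L]])
  assigned <- unlist(regions, use.names = FALSE)
  if (length(assigned) == 0L)
    stop("structure has no protein residues inside any declared range")
  regions$unassigned <- setdiff(resnos, assigned)
  structure(list(regions = regions, scheme_id = scheme, chain = prot$chain[1L]),
            class = "pop_partition")
}

#' Residue numbers of a (possibly composite) partition region
#'
#' `"catalytic"` is understood as the union of `n_loop` and `hydrolase`.
#'
#' @param p A `pop_partition`.
#' @param name Region name, one of the partition's regions, or `"catalytic"`.
#' @return Integer vector of residue numbers.
#' @export
region_residues <- function(p, name) {
  if (name == "catalytic") return(sort(c(p$regions$n_loop, p$regions$hydrolase)))
  r <- p$regions[[name]]
  if (is.null(r)) stop("unknown region: ", name)
  r
}

#' Count het residues with a given residue name
#'
#' Counts distinct HETATM residues (e.g. `"SPM"` for spermine) across all
#' chains; absent names give zero.
#'
#' @param s A `pop_structure`.
#' @param resname Three-letter residue name.
#' @return Integer count.
#' @export
count_het_residues <- function(s, resname) {
  a <- s$atoms[s$atoms$het & s$atoms$resid == resname, , drop = FALSE]
  if (nrow(a) == 0L) return(0L)
  length(unique(paste(a$chain, a$resno, a$insert)))
}

#' Write a structure as a fixed-column PDB file
#'
#' Intended for toy/synthetic structures and bead models; coordinates are
#' written at the standard 0.001 A precision.
#'
#' @param s A `pop_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  # atom-name column convention: 1-3 character names start in column 14
  name <- ifelse(nchar(a$elety) >= 4L, substr(a$elety, 1, 4), sprintf(" %-3s", a$elety))
  lines <- sprintf("%s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000L, name, substr(a$resid, 1, 3),
                   substr(a$chain, 1, 1), a$resno %% 10000L, substr(a$insert, 1, 1),
                   a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms by residue number (first protein chain by default)
#' @noRd
.select_atoms <- function(s, resnos = NULL, atom_names = NULL, chain = NULL, het = FALSE) {
  a <- if (het) s$atoms else s$atoms[!s$atoms$het, , drop = FALSE]
  if (is.null(chain)) chain <- .protein_atoms(s)$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  if (!is.null(resnos)) a <- a[a$resno %in% resnos, , drop = FALSE]
  if (!is.null(atom_names)) a <- a[a$elety %in% atom_names, , drop = FALSE]
  a
}
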