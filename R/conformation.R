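#' Catalytic-triad specification
#'
#' Defaults to the PSP triad Ser532/His652/Asp617.
#'
#' @param ser,his,asp Residue numbers of the triad serine, histidine and
#'   aspartate.
#' @return A `triad_spec` list.
#' @export
triad_spec <- function(ser = 532, his = 652, asp = 617) {
  stopifnot(length(unique(c(ser, his, asp))) == 3L)
  structure(list(ser = ser, his = his, asp = asp), class = "triad_spec")
}

.try_dist <- function(s, a, b, chain) {
  tryCatch(atom_distance(s, a, b, chain = chain), error = function(e) NA_real_)
}

#' Catalytic-triad geometry
#'
#' The four distances characterizing triad integrity: Ser-His and His-Asp
#' C-alpha separations, the Ser OG - His NE2 nucleophile gap, and the His
#' ND1 - Asp OD gap (minimum over OD1/OD2, since which carboxylate oxygen
#' engages the histidine is structure-dependent). Side-chain atoms absent
#' from the model (disordered His-loops are common in open-state POP
#' structures) are flagged in `missing_atoms`, never silently zeroed.
#'
#' @param s A `pop_structure`.
#' @param spec A [triad_spec()].
#' @param chain Optional chain id.
#' @return A `triad_geometry` list: `d_ca_ser_his`, `d_ca_his_asp`,
#'   `d_og_ne2`, `d_od_nd1` (NA when atoms are missing), `missing_atoms`.
#' @export
triad_geometry <- function(s, spec = triad_spec(), chain = NULL) {
  d_ca_sh <- .try_dist(s, c(spec$ser, "CA"), c(spec$his, "CA"), chain)
  d_ca_ha <- .try_dist(s, c(spec$his, "CA"), c(spec$asp, "CA"), chain)
  if (is.na(d_ca_sh) || is.na(d_ca_ha))
    stop("triad residue C-alpha missing; check residue numbers/chain")
  d_og_ne2 <- .try_dist(s, c(spec$ser, "OG"), c(spec$his, "NE2"), chain)
  d_od_nd1 <- suppressWarnings(min(
    .try_dist(s, c(spec$asp, "OD1"), c(spec$his, "ND1"), chain),
    .try_dist(s, c(spec$asp, "OD2"), c(spec$his, "ND1"), chain), na.rm = TRUE))
  if (!is.finite(d_od_nd1)) d_od_nd1 <- NA_real_
  missing <- c(if (is.na(d_og_ne2)) "Ser OG / His NE2",
               if (is.na(d_od_nd1)) "Asp OD / His ND1")
  structure(list(d_ca_ser_his = d_ca_sh, d_ca_his_asp = d_ca_ha,
                 d_og_ne2 = d_og_ne2, d_od_nd1 = d_od_nd1,
                 missing_atoms = missing %||% character(0)),
            class = "triad_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default classification thresholds
#'
#' Derived from the spread of triad and domain-positioning metrics across
#' open, closed and intermediate POP-family crystal structures: intact-triad
#' gaps sit at hydrogen-bond distance (2.9-3.5 A) versus >= 7 A when
#' disrupted; open-state centre-of-mass separations are 6-8 A larger than
#' closed/intermediate ones.
#'
#' @param t_triad Maximum Ser OG-His NE2 and His ND1-Asp OD distance (A) for
#'   an intact triad (default 4.0).
#' @param t_com Centre-of-mass separation (A) below which domains count as
#'   close (default 34.5, midpoint of the observed closed/open clusters).
#' @param t_buried Buried-surface percentage at/above which the catalytic
#'   domain counts as close (default 10).
#' @param com_margin Half-width (A) of the near-threshold band in which the
#'   buried-surface vote breaks the centre-of-mass call (default 1.0).
#' @return Named list of thresholds.
#' @export
state_thresholds <- function(t_triad = 4.0, t_com = 34.5, t_buried = 10,
                             com_margin = 1.0) {
  list(t_triad = t_triad, t_com = t_com, t_buried = t_buried, com_margin = com_margin)
}

#' Call the conformational state from triad and domain metrics
#'
#' The two-axis rule of POP-family conformational analysis: the triad is
#' intact when both side-chain gaps are at hydrogen-bond distance; the
#' domains are close when the interdomain centre-of-mass separation is below
#' threshold (with the buried-surface fraction breaking near-threshold
#' cases). Closed = intact + close; intermediate = disrupted + close; open =
#' disrupted + apart; intact + apart is geometrically odd and returned as
#' indeterminate. Missing side-chain gaps (disordered His-loop, mutated
#' serine) count as a disrupted triad, with the reason recorded.
#'
#' @param tg A `triad_geometry`, or a list with `d_og_ne2`/`d_od_nd1`
#'   (NA allowed).
#' @param com_distance Interdomain centre-of-mass separation (A).
#' @param buried_pct Optional buried-surface percentages as from
#'   [buried_fraction()] (the `catalytic` entry is used).
#' @param thresholds See [state_thresholds()].
#' @return A `pop_state_call`: `label` ("open", "intermediate", "closed",
#'   "indeterminate"), `triad_intact`, `domains_close`, `evidence`,
#'   `thresholds_used`, `notes`.
#' @export
classify_state <- function(tg, com_distance, buried_pct = NULL,
                           thresholds = state_thresholds()) {
  if (is.na(com_distance) && is.null(buried_pct))
    return(structure(list(label = "indeterminate", triad_intact = NA,
                          domains_close = NA, evidence = list(),
                          thresholds_used = thresholds,
                          notes = "all domain metrics missing"),
                     class = "pop_state_call"))
  gaps <- c(tg$d_og_ne2, tg$d_od_nd1)
  notes <- character(0)
  if (anyNA(gaps)) {
    triad_intact <- FALSE
    notes <- c(notes, "triad side-chain atoms missing (disordered His-loop or substitution); triad counted as disrupted")
  } else {
    triad_intact <- all(gaps <= thresholds$t_triad)
  }
  bur <- if (!is.null(buried_pct)) unname(buried_pct[["catalytic"]] %||% buried_pct[[1L]]) else NA_real_
  if (is.na(com_distance)) {
    domains_close <- bur >= thresholds$t_buried
  } else {
    domains_close <- com_distance <= thresholds$t_com
    if (!is.na(bur) && abs(com_distance - thresholds$t_com) < thresholds$com_margin) {
      domains_close <- bur >= thresholds$t_buried
      notes <- c(notes, "centre-of-mass separation near threshold; buried-surface vote applied")
    }
  }
  label <- if (triad_intact && domains_close) "closed"
           else if (!triad_intact && domains_close) "intermediate"
           else if (!triad_intact && !domains_close) "open"
           else "indeterminate"
  structure(list(label = label, triad_intact = triad_intact,
                 domains_close = domains_close,
                 evidence = list(d_og_ne2 = tg$d_og_ne2, d_od_nd1 = tg$d_od_nd1,
                                 com_distance = com_distance, buried_catalytic = bur),
                 thresholds_used = thresholds, notes = notes),
            class = "pop_state_call")
}

#' @export
print.pop_state_call <- function(x, ...) {
  cat(sprintf("<state call> %s (triad %s, domains %s)\n", x$label,
              if (isTRUE(x$triad_intact)) "intact" else "disrupted",
              if (isTRUE(x$domains_close)) "close" else "apart"))
  invisible(x)
}

#' Channel / opening aperture distances
#'
#' C-alpha separations for residue pairs spanning the propeller channel or
#' the interdomain opening.
#'
#' @param s A `pop_structure`.
#' @param pairs List of length-2 residue-number vectors, or a two-column
#'   matrix.
#' @param chain Optional chain id.
#' @return Data frame: res_a, res_b, distance (NA with an `error` message for
#'   pairs whose residues are missing; other pairs still computed).
#' @export
aperture_distances <- function(s, pairs, chain = NULL) {
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  out <- lapply(pairs, function(p) {
    d <- tryCatch(atom_distance(s, c(p[1L], "CA"), c(p[2L], "CA"), chain = chain),
                  error = function(e) NA_real_)
    data.frame(res_a = p[1L], res_b = p[2L], distance = d,
               error = if (is.na(d)) "residue or CA missing" else "")
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Minimum distance from each copy of a ligand to a target atom
#'
#' @param s A `pop_structure`.
#' @param resname Ligand residue name (e.g. `"SPM"` for spermine).
#' @param target Length-2 specifier `c(resno, atom_name)` of the target
#'   protein atom (e.g. the catalytic serine OG).
#' @param chain Optional chain id for the target atom.
#' @return Data frame: ligand_resno, atom (closest ligand atom), distance;
#'   empty when the ligand is absent.
#' @export
ligand_proximity <- function(s, resname, target, chain = NULL) {
  t_xyz <- .atom_xyz(s, as.integer(target[[1L]]), as.character(target[[2L]]), chain)
  lig <- s$atoms[s$atoms$het & s$atoms$resid == resname, , drop = FALSE]
  if (nrow(lig) == 0L)
    return(data.frame(ligand_resno = integer(), atom = character(), distance = numeric()))
  d <- sqrt(rowSums(sweep(.xyz_of(lig), 2, t_xyz)^2))
  by_copy <- split(seq_len(nrow(lig)), paste(lig$chain, lig$resno))
  out <- lapply(by_copy, function(i) {
    k <- i[which.min(d[i])]
    data.frame(ligand_resno = lig$resno[k], atom = lig$elety[k], distance = d[k])
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$distance), , drop = FALSE]
}
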