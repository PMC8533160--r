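#' Crystal-structure state-profiling workflow
#'
#' For each input structure: domain partition, catalytic-triad geometry,
#' interdomain centre-of-mass separation (both mass and unit weighting),
#' buried-surface and interface-residue percentages, interdomain
#' hydrogen-bond and salt-bridge counts, and the conformational-state call.
#' Structures that fail to parse are reported in the `errors` attribute;
#' the others are still processed.
#'
#' @param structures List of `pop_structure` objects and/or file paths.
#' @param scheme,ranges Passed to [partition_domains()].
#' @param triad A [triad_spec()].
#' @param thresholds A [state_thresholds()].
#' @param n_points Surface-point density for the SASA terms (reduced from
#'   the single-structure default to keep multi-structure profiling fast).
#' @param out_dir Optional directory; when given, the table is written to
#'   `state_profile.tsv` there.
#' @return Data frame with one row per successfully processed structure.
#' @export
run_state_profile <- function(structures, scheme = "psp_default", ranges = NULL,
                              triad = triad_spec(), thresholds = state_thresholds(),
                              n_points = 240, out_dir = NULL) {
  if (length(structures) == 0L) stop("usage: at least one input structure is required")
  errors <- character(0)
  rows <- list()
  for (k in seq_along(structures)) {
    item <- structures[[k]]
    row <- tryCatch({
      s <- if (inherits(item, "pop_structure")) item else read_structure(item)
      p <- partition_domains(s, scheme = scheme, ranges = ranges)
      tg <- triad_geometry(s, triad)
      com_m <- sqrt(sum((center_of_mass(s, region_residues(p, "catalytic")) -
                           center_of_mass(s, region_residues(p, "propeller")))^2))
      com_u <- sqrt(sum((center_of_mass(s, region_residues(p, "catalytic"), "unit") -
                           center_of_mass(s, region_residues(p, "propeller"), "unit"))^2))
      bur <- buried_fraction(s, p, n_points = n_points)
      ir <- interface_residues(s, p, n_points = n_points)
      cat_res <- region_residues(p, "catalytic")
      prop_res <- region_residues(p, "propeller")
      hb <- find_hbonds(s, cat_res, prop_res)
      sb <- find_salt_bridges(s, cat_res, prop_res)
      call <- classify_state(tg, com_distance = com_m, buried_pct = bur,
                             thresholds = thresholds)
      data.frame(id = s$id,
                 d_ca_ser_his = round(tg$d_ca_ser_his, 1),
                 d_og_ne2 = round(tg$d_og_ne2, 1),
                 d_ca_his_asp = round(tg$d_ca_his_asp, 1),
                 d_od_nd1 = round(tg$d_od_nd1, 1),
                 com_distance = round(com_m, 1),
                 com_distance_unit_weight = round(com_u, 1),
                 buried_catalytic = round(bur[["catalytic"]], 1),
                 buried_propeller = round(bur[["propeller"]], 1),
                 interface_res_catalytic = round(ir$pct[["catalytic"]], 1),
                 interface_res_propeller = round(ir$pct[["propeller"]], 1),
                 hbonds = nrow(hb), salt_bridges = nrow(sb),
                 conformation = call$label)
    }, error = function(e) {
      errors <<- c(errors, sprintf("input %d: %s", k, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows) %||% data.frame()
  attr(out, "errors") <- errors
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(out_dir, "state_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Classify conformational states from a table of precomputed metrics
#'
#' Applies [classify_state()] row-wise to a metrics table (as produced by
#' [run_state_profile()], or curated from published comparative analyses),
#' so the state call can be audited independently of the geometry
#' extraction.
#'
#' @param metrics Data frame with columns `d_og_ne2`, `d_od_nd1`,
#'   `com_distance` and optionally `buried_catalytic` (NA allowed where a
#'   structure's side chains are unmodelled).
#' @param thresholds A [state_thresholds()].
#' @return The table with a `label` column appended.
#' @export
state_call_table <- function(metrics, thresholds = state_thresholds()) {
  metrics$label <- vapply(seq_len(nrow(metrics)), function(i) {
    tg <- list(d_og_ne2 = metrics$d_og_ne2[i], d_od_nd1 = metrics$d_od_nd1[i])
    bur <- if (!is.null(metrics$buried_catalytic))
      c(catalytic = metrics$buried_catalytic[i]) else NULL
    classify_state(tg, com_distance = metrics$com_distance[i],
                   buried_pct = bur, thresholds = thresholds)$label
  }, character(1))
  metrics
}

#' Curated domain-positioning metrics for POP-family crystal structures
#'
#' Published catalytic-triad and domain-positioning measurements for the
#' PSPmod structure and eight comparator POP-family entries crystallized in
#' open, closed and intermediate states (triad side-chain gaps, centre-of-
#' mass separations, buried-surface and interface-residue percentages,
#' interdomain hydrogen-bond and salt-bridge counts), together with each
#' structure's reported conformation. Gaps are NA where His-loop electron
#' density was too poor or the catalytic serine was substituted.
#'
#' @return Data frame, one row per structure.
#' @export
pop_reference_metrics <- function() {
  path <- system.file("extdata", "pop_family_domain_metrics.tsv", package = "popstate")
  read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
             stringsAsFactors = FALSE)
}

#' Curated solution-scattering reference parameters for the PSP series
#'
#' Published Guinier radii of gyration, maximum dimensions and volumes of
#' correlation for wild-type PSP, PSP with spermine, and two hinge-modified
#' variants; used to calibrate the synthetic scatterer generators.
#'
#' @return Data frame: protein, rg, dmax, vc.
#' @export
pop_reference_saxs <- function() {
  path <- system.file("extdata", "psp_saxs_reference.tsv", package = "popstate")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Solution-state SAXS analysis workflow
#'
#' Per profile: Guinier Rg and I(0), estimated Dmax, volume of correlation;
#' optionally a chi^2 against a model curve and a two-component mixture
#' fit. Profiles without a Guinier region are flagged and the run
#' continues.
#'
#' @param profiles Named list of `saxs_profile` objects and/or .dat paths.
#' @param model Optional `saxs_profile` to scale onto each input.
#' @param components Optional `list(a =, b =)` of component profiles for
#'   mixture deconvolution.
#' @param out_dir Optional output directory (`saxs_analysis.tsv`).
#' @return Data frame with one row per profile (`flag` holds error notes).
#' @export
run_saxs_analysis <- function(profiles, model = NULL, components = NULL,
                              out_dir = NULL) {
  if (length(profiles) == 0L) stop("usage: at least one input profile is required")
  nms <- names(profiles) %||% paste0("profile", seq_along(profiles))
  rows <- lapply(seq_along(profiles), function(k) {
    item <- profiles[[k]]
    tryCatch({
      p <- if (inherits(item, "saxs_profile")) item else read_saxs(item)
      gf <- guinier_fit(p)
      dmax <- as.numeric(estimate_dmax(p))
      vc <- as.numeric(volume_of_correlation(p, i0 = gf$i0, rg = gf$rg))
      chi2 <- if (!is.null(model)) fit_profile(p, model)$chi2 else NA_real_
      frac <- if (!is.null(components))
        mixture_fit(p, components$a, components$b)$fraction_a else NA_real_
      data.frame(name = nms[k], rg = gf$rg, i0 = gf$i0, dmax = dmax, vc = vc,
                 model_chi2 = chi2, fraction_a = frac, flag = "")
    }, error = function(e)
      data.frame(name = nms[k], rg = NA, i0 = NA, dmax = NA, vc = NA,
                 model_chi2 = NA, fraction_a = NA, flag = conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(out_dir, "saxs_analysis.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
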