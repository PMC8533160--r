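#' Construct a kinetics dataset
#'
#' Initial-rate observations normalized by enzyme concentration, as used for
#' Michaelis-Menten fitting. Replicated substrate concentrations are allowed.
#'
#' @param S Substrate concentrations (must be positive; any single
#'   concentration unit, consistently).
#' @param v Normalized initial rates v/[E] (1/min).
#' @param substrate,enzyme Optional labels.
#' @return A `kinetics_dataset` data-frame-like list.
#' @export
kinetics_dataset <- function(S, v, substrate = "substrate", enzyme = "enzyme") {
  stopifnot(length(S) == length(v), all(is.finite(S)), all(is.finite(v)))
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  structure(list(S = as.numeric(S), v = as.numeric(v),
                 substrate = substrate, enzyme = enzyme),
            class = "kinetics_dataset")
}

#' Fit the Michaelis-Menten equation by nonlinear least squares
#'
#' `v/E = kcat S / (Km + S)`, unweighted by default (optional 1/v^2
#' weighting). Starting values come from the Lineweaver-Burk linearization
#' unless supplied. Data with no saturation curvature (all S far below Km)
#' converge but carry an ill-conditioning warning flag.
#'
#' @param d A [kinetics_dataset()] with at least 6 distinct substrate
#'   concentrations.
#' @param init `"auto"` or `"explicit"` (then give `start`).
#' @param start Named list `list(kcat =, km =)` for explicit initialization.
#' @param weighting `"none"` (default) or `"inv_v2"`.
#' @return An `mm_fit`: `kcat` (1/min), `km` (units of `S`),
#'   `kcat_over_km`, standard errors, `converged`, `ill_conditioned`.
#' @export
fit_michaelis_menten <- function(d, init = c("auto", "explicit"), start = NULL,
                                 weighting = c("none", "inv_v2")) {
  init <- match.arg(init)
  weighting <- match.arg(weighting)
  if (length(unique(d$S)) < 6L)
    stop("need at least 6 distinct substrate concentrations")
  if (init == "auto") {
    lb <- lm(I(1 / d$v) ~ I(1 / d$S), subset = d$v > 0)
    kcat0 <- 1 / coef(lb)[[1L]]
    km0 <- coef(lb)[[2L]] * kcat0
    if (!is.finite(kcat0) || kcat0 <= 0) kcat0 <- max(d$v) * 1.2
    if (!is.finite(km0) || km0 <= 0) km0 <- median(d$S)
    start <- list(kcat = kcat0, km = km0)
  } else if (is.null(start)) stop("explicit init requires 'start'")
  w <- if (weighting == "inv_v2") 1 / pmax(d$v, 1e-12)^2 else rep(1, length(d$v))
  fit <- minpack.lm::nlsLM(v ~ kcat * S / (km + S),
                           data = data.frame(S = d$S, v = d$v),
                           start = start, weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, km = NA_real_))
  ill <- est[["km"]] > 5 * max(d$S) || est[["km"]] < min(d$S) / 50
  if (ill)
    warning("ill-conditioned fit: Km lies far outside the sampled substrate range")
  structure(list(kcat = est[["kcat"]], km = est[["km"]],
                 kcat_over_km = est[["kcat"]] / est[["km"]],
                 se_kcat = unname(se[1L]), se_km = unname(se[2L]),
                 converged = fit$convInfo$isConv %||% TRUE,
                 ill_conditioned = ill,
                 substrate = d$substrate, enzyme = d$enzyme),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %s / %s: kcat = %.4g 1/min, Km = %.4g, kcat/Km = %.4g\n",
              x$enzyme, x$substrate, x$kcat, x$km, x$kcat_over_km))
  invisible(x)
}

#' Catalytic efficiency on the conventional 1e7 1/(M min) scale
#'
#' `kcat/Km` with kcat in 1/min and Km in micromolar, reported in units of
#' 1e7 per molar per minute (so 1 1/min per 1 uM prints as 0.1).
#'
#' @param kcat Turnover number, 1/min.
#' @param km_uM Michaelis constant, micromolar.
#' @return Efficiency in 1e7 1/(M min).
#' @export
catalytic_efficiency <- function(kcat, km_uM) {
  stopifnot(all(kcat > 0), all(km_uM > 0))
  (kcat / (km_uM * 1e-6)) / 1e7
}

#' Reference kinetic panel for the PSP enzyme series
#'
#' Curated published kinetic parameters (kcat in 1/min, Km in uM, efficiency
#' as printed, on the 1e7 1/(M min) scale) for wild-type PSP, the
#' hinge-modified PSPmod and its Glu75-reinstalled and Glu125Ala derivatives
#' against three p-nitroanilide substrates.
#'
#' @return Data frame: enzyme, substrate, kcat, km_uM, printed_eff
#'   (character, preserving the printed precision).
#' @export
opb_kinetic_panel <- function() {
  path <- system.file("extdata", "opb_variant_kinetics.tsv", package = "popstate")
  read.table(path, header = TRUE, sep = "\t", colClasses = c(
    enzyme = "character", substrate = "character", kcat = "numeric",
    km_uM = "numeric", printed_eff = "character"))
}

# significant figures of a printed decimal string
.printed_sigfig <- function(s) {
  digits <- gsub("[^0-9]", "", sub("^[-+]?0*\\.?0*", "", s))
  nchar(digits)
}

#' Recompute a panel's efficiency column and compare at printed precision
#'
#' For each panel row, recomputes kcat/Km from the kcat and Km columns,
#' rounds to the number of significant figures of the printed efficiency and
#' flags disagreements rather than reconciling them.
#'
#' @param panel Data frame as from [opb_kinetic_panel()].
#' @return The panel with `computed_eff`, `computed_rounded` and `match`
#'   columns.
#' @export
recompute_efficiency_panel <- function(panel = opb_kinetic_panel()) {
  panel$computed_eff <- catalytic_efficiency(panel$kcat, panel$km_uM)
  sf <- vapply(panel$printed_eff, .printed_sigfig, integer(1))
  panel$computed_rounded <- signif(panel$computed_eff, sf)
  panel$match <- panel$computed_rounded == as.numeric(panel$printed_eff)
  panel
}

#' Efficiencies relative to a reference enzyme
#'
#' Per (enzyme, substrate) cell: efficiency divided by the reference
#' enzyme's efficiency for the same substrate, as percent and fold. Missing
#' cells yield NA rather than failure. Unit changes that rescale every
#' efficiency equally cancel.
#'
#' @param panel Data frame with enzyme, substrate and either an `efficiency`
#'   column or kcat / km_uM columns.
#' @param reference Reference enzyme name (must be present for every
#'   substrate).
#' @return Data frame: enzyme, substrate, efficiency, ref_efficiency,
#'   pct_of_ref, fold.
#' @export
relative_efficiency_table <- function(panel, reference) {
  if (is.null(panel$efficiency))
    panel$efficiency <- catalytic_efficiency(panel$kcat, panel$km_uM)
  refs <- panel[panel$enzyme == reference, c("substrate", "efficiency")]
  if (nrow(refs) == 0L) stop("reference enzyme not present in panel: ", reference)
  out <- panel[, c("enzyme", "substrate", "efficiency")]
  out$ref_efficiency <- refs$efficiency[match(out$substrate, refs$substrate)]
  if (anyNA(out$ref_efficiency))
    stop("reference enzyme missing for some substrates")
  out$pct_of_ref <- 100 * out$efficiency / out$ref_efficiency
  out$fold <- out$efficiency / out$ref_efficiency
  out
}

#' Percent inhibition relative to the uninhibited rate
#'
#' @param conc Inhibitor concentrations, including 0 (the reference).
#' @param rate Initial rates at those concentrations.
#' @return Data frame: conc, rate, inhibition_pct = 100 (1 - v(c)/v(0)).
#' @export
inhibition_profile <- function(conc, rate) {
  stopifnot(length(conc) == length(rate))
  v0 <- mean(rate[conc == 0])
  if (!is.finite(v0) || v0 <= 0)
    stop("reference (zero-concentration) rate missing or non-positive")
  data.frame(conc = conc, rate = rate, inhibition_pct = 100 * (1 - rate / v0))
}
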