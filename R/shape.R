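# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Initialize a dummy-atom bead model on a lattice
#'
#' Lattice sites fill a search sphere of diameter `dmax`; occupancy is either
#' every site (`full_sphere`) or an independent Bernoulli draw per site
#' (`random`), deterministic under `seed`.
#'
#' @param dmax Search-sphere diameter in Angstrom (must exceed the target
#'   particle's maximum dimension).
#' @param bead_radius Bead radius in A; lattice spacing is twice this.
#' @param fill `"full_sphere"` or `"random"`.
#' @param fill_fraction Occupancy probability for random fill.
#' @param lattice `"sc"` (simple cubic, default) or `"hcp"`.
#' @param seed RNG seed for random fill.
#' @return A `bead_model`: `sites` (Nx3), `occupied` (logical), `bead_radius`.
#' @export
initialize_beads <- function(dmax, bead_radius = 3.0, fill = c("full_sphere", "random"),
                             fill_fraction = 0.5, lattice = c("sc", "hcp"), seed = 1) {
  fill <- match.arg(fill)
  lattice <- match.arg(lattice)
  if (dmax <= 2 * bead_radius) stop("dmax must exceed the bead diameter")
  a <- 2 * bead_radius
  rmax <- dmax / 2
  k <- ceiling(rmax / a)
  if (lattice == "sc") {
    g <- expand.grid(x = -k:k, y = -k:k, z = -k:k)
    sites <- as.matrix(g) * a
  } else {
    # hcp as stacked hexagonal layers
    layers <- -k:k
    sites <- do.call(rbind, lapply(seq_along(layers), function(li) {
      lz <- layers[li] * a * sqrt(2 / 3) * 1.5  # layer spacing ~ close packing
      off <- if (li %% 2 == 0) c(a / 2, a * sqrt(3) / 6) else c(0, 0)
      g <- expand.grid(x = -k:k, y = -k:k)
      cbind(g$x * a + off[1L] + (g$y %% 2) * 0, g$y * a * sqrt(3) / 2 + off[2L], lz)
    }))
  }
  keep <- sqrt(rowSums(sites^2)) <= rmax
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) < 20L) stop("too-coarse: lattice has fewer than 20 sites")
  occupied <- if (fill == "full_sphere") rep(TRUE, nrow(sites))
              else with_seed(seed, stats::runif(nrow(sites)) < fill_fraction)
  structure(list(sites = sites, occupied = occupied, bead_radius = bead_radius,
                 lattice = lattice), class = "bead_model")
}

#' Radius of gyration of the occupied beads (unit weights)
#'
#' @param m A `bead_model`.
#' @return Rg in Angstrom.
#' @export
bead_rg <- function(m) {
  occ <- m$sites[m$occupied, , drop = FALSE]
  if (nrow(occ) == 0L) stop("empty bead model")
  radius_of_gyration(occ)
}

#' Export a bead model as a PDB of pseudo-atoms
#'
#' One carbon pseudo-atom per occupied bead, viewable in any molecular
#' viewer.
#'
#' @param m A `bead_model`.
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
bead_to_pdb <- function(m, path) {
  occ <- m$sites[m$occupied, , drop = FALSE]
  atoms <- data.frame(chain = "A", resno = seq_len(nrow(occ)), resid = "DUM",
                      elety = "CA", element = "C",
                      x = occ[, 1L], y = occ[, 2L], z = occ[, 3L], het = TRUE)
  write_structure(new_structure(atoms, id = "beads"), path)
}

#' Annealing configuration
#'
#' @param seed RNG seed (all stochastic moves flow from it).
#' @param t0 Initial temperature; `NULL` calibrates it so that roughly half
#'   of the initial moves are accepted.
#' @param cooling Multiplicative cooling factor per stage, in (0,1).
#' @param moves_per_stage Metropolis proposals per temperature stage;
#'   `NULL` uses 5x the number of lattice sites.
#' @param w_conn Weight of the connectivity penalty (fraction of occupied
#'   beads with no occupied neighbour).
#' @param w_comp Weight of the compactness penalty (relative excess of the
#'   bead Rg over the target's Guinier Rg).
#' @param stop_stages Consecutive stages with < `stop_tol` relative
#'   improvement of the best energy before stopping.
#' @param stop_tol Relative best-energy improvement threshold.
#' @param max_stages Hard stage cap.
#' @param n_q Coarse q-grid size used for the chi^2 term.
#' @return Config list.
#' @export
anneal_config <- function(seed = 1, t0 = NULL, cooling = 0.9, moves_per_stage = NULL,
                          w_conn = 1, w_comp = 1, stop_stages = 3, stop_tol = 0.001,
                          max_stages = 60, n_q = 50) {
  stopifnot(cooling > 0, cooling < 1, w_conn >= 0, w_comp >= 0)
  list(seed = seed, t0 = t0, cooling = cooling, moves_per_stage = moves_per_stage,
       w_conn = w_conn, w_comp = w_comp, stop_stages = stop_stages,
       stop_tol = stop_tol, max_stages = max_stages, n_q = n_q)
}

#' Ab initio shape reconstruction by simulated annealing
#'
#' A deliberately simplified dummy-atom annealer: single-bead occupancy flips
#' under a Metropolis criterion on
#' `E = chi2(model profile, target) + w_conn * loose_fraction + w_comp *
#' rg_excess`, where the model profile is the unit-weight Debye curve of the
#' occupied beads (pair-distance histogram, coarse q grid), `loose_fraction`
#' is the fraction of occupied beads without an occupied lattice neighbour,
#' and `rg_excess` is the relative excess of the bead Rg over the target's
#' Guinier Rg. No hydration shell and no bead form factor are modelled.
#'
#' @param m A `bead_model` starting configuration.
#' @param target A `saxs_profile` with a valid Guinier region.
#' @param cfg An [anneal_config()].
#' @return List with `model` (best-seen `bead_model`), `energy` (best E),
#'   `chi2` (its chi^2 term), and `trace` (per-stage data frame of
#'   temperature, best/current energy and acceptance rate).
#' @export
anneal <- function(m, target, cfg = anneal_config()) {
  gf <- guinier_fit(target)      # errors out when no Guinier region exists
  rg_target <- gf$rg
  sites <- m$sites
  n_sites <- nrow(sites)
  moves <- cfg$moves_per_stage %||% (5L * n_sites)
  # coarse target grid
  idx <- unique(round(seq(1, length(target$q), length.out = cfg$n_q)))
  qy <- target$q[idx]; ty <- target$intensity[idx]
  tw <- if (is.null(target$sigma)) rep(1 / mean(ty)^2, length(idx)) else 1 / target$sigma[idx]^2
  # pair-distance histogram machinery
  bw <- max(1, m$bead_radius / 2)
  dmax_lat <- 2 * max(sqrt(rowSums(sites^2))) + bw
  edges <- seq(0, dmax_lat + bw, by = bw)
  centres <- edges[-1L] - bw / 2
  nb_bins <- length(centres)
  S <- outer(qy, centres, function(qq, rr) .sinc(qq * rr))   # n_q x n_bins
  # neighbour lists (within 1.05 lattice spacings)
  a <- 2 * m$bead_radius
  nb <- lapply(seq_len(n_sites), function(i) {
    d2 <- rowSums(sweep(sites, 2, sites[i, ])^2)
    which(d2 > 1e-9 & d2 <= (1.05 * a)^2)
  })

  state <- new.env(parent = emptyenv())
  state$occ <- m$occupied
  .init_state <- function() {
    occ_idx <- which(state$occ)
    state$n <- length(occ_idx)
    h <- numeric(nb_bins)
    if (state$n > 1L) {
      d <- as.numeric(dist(sites[occ_idx, , drop = FALSE]))
      tb <- tabulate(findInterval(d, edges, rightmost.closed = TRUE), nbins = nb_bins)
      h <- as.numeric(tb)
    }
    state$hist <- h
    state$I <- state$n + 2 * as.numeric(S %*% h)
    state$sx <- colSums(sites[occ_idx, , drop = FALSE])
    state$sxx <- sum(sites[occ_idx, , drop = FALSE]^2)
    state$nbocc <- vapply(seq_len(n_sites), function(i) sum(state$occ[nb[[i]]]), integer(1))
  }
  .energy_of <- function(I, n, sx, sxx, loose_frac) {
    cc <- sum(tw * ty * I) / sum(tw * I^2)
    chi2 <- sum(tw * (ty - cc * I)^2) / (length(ty) - 1L)
    rg2 <- max(0, sxx / n - sum((sx / n)^2))
    rg_excess <- max(0, sqrt(rg2) / rg_target - 1)
    c(E = chi2 + cfg$w_conn * loose_frac + cfg$w_comp * rg_excess, chi2 = chi2)
  }
  .loose_frac <- function() {
    occ_idx <- which(state$occ)
    if (!length(occ_idx)) return(1)
    mean(state$nbocc[occ_idx] == 0L)
  }
  .move_delta <- function(i) {
    # histogram contribution of site i against currently occupied sites
    occ_idx <- which(state$occ)
    occ_idx <- occ_idx[occ_idx != i]
    if (!length(occ_idx)) return(numeric(nb_bins))
    d <- sqrt(rowSums(sweep(sites[occ_idx, , drop = FALSE], 2, sites[i, ])^2))
    as.numeric(tabulate(findInterval(d, edges, rightmost.closed = TRUE), nbins = nb_bins))
  }

  run <- function() {
    .init_state()
    e0 <- .energy_of(state$I, state$n, state$sx, state$sxx, .loose_frac())
    cur_E <- e0[["E"]]
    best_E <- cur_E; best_chi2 <- e0[["chi2"]]; best_occ <- state$occ
    # temperature calibration: median uphill step of sampled proposals
    t0 <- cfg$t0
    if (is.null(t0)) {
      dEs <- replicate(100, {
        i <- sample.int(n_sites, 1L)
        cnt <- .move_delta(i)
        sgn <- if (state$occ[i]) -1 else 1
        Inew <- state$I + sgn * (1 + 2 * as.numeric(S %*% cnt))
        nn <- state$n + sgn
        if (nn < 2L) return(NA_real_)
        en <- .energy_of(Inew, nn, state$sx + sgn * sites[i, ],
                         state$sxx + sgn * sum(sites[i, ]^2), .loose_frac())
        en[["E"]] - cur_E
      })
      up <- dEs[is.finite(dEs) & dEs > 0]
      t0 <- if (length(up)) median(up) / log(2) else 1e-3
    }
    Tcur <- t0
    trace <- list()
    stall <- 0L
    for (stage in seq_len(cfg$max_stages)) {
      acc <- 0L
      stage_best_in <- best_E
      for (mv in seq_len(moves)) {
        i <- sample.int(n_sites, 1L)
        sgn <- if (state$occ[i]) -1L else 1L
        nn <- state$n + sgn
        if (nn < 2L) next
        cnt <- .move_delta(i)
        Inew <- state$I + sgn * (1 + 2 * as.numeric(S %*% cnt))
        sx_new <- state$sx + sgn * sites[i, ]
        sxx_new <- state$sxx + sgn * sum(sites[i, ]^2)
        # connectivity after the flip
        occ_cnt <- sum(state$occ) + sgn
        nbocc_new_i <- state$nbocc[i]
        loose_new <- {
          occ_idx <- which(state$occ)
          nbo <- state$nbocc
          if (sgn > 0) { occ_set <- c(occ_idx, i); nbo[nb[[i]]] <- nbo[nb[[i]]] + 1L }
          else { occ_set <- occ_idx[occ_idx != i]; nbo[nb[[i]]] <- nbo[nb[[i]]] - 1L }
          mean(nbo[occ_set] == 0L)
        }
        en <- .energy_of(Inew, nn, sx_new, sxx_new, loose_new)
        dE <- en[["E"]] - cur_E
        if (dE <= 0 || stats::runif(1) < exp(-dE / Tcur)) {
          acc <- acc + 1L
          state$occ[i] <- !state$occ[i]
          state$n <- nn
          state$hist <- state$hist + sgn * cnt
          state$I <- Inew
          state$sx <- sx_new
          state$sxx <- sxx_new
          state$nbocc[nb[[i]]] <- state$nbocc[nb[[i]]] + sgn
          cur_E <- en[["E"]]
          if (cur_E < best_E) { best_E <- cur_E; best_chi2 <- en[["chi2"]]; best_occ <- state$occ }
        }
      }
      if (stage == 1L && acc == 0L)
        stop("badly-scaled-config: no accepted moves in the first temperature stage")
      trace[[stage]] <- data.frame(stage = stage, temperature = Tcur,
                                   best_energy = best_E, current_energy = cur_E,
                                   acceptance = acc / moves)
      improved <- (stage_best_in - best_E) > cfg$stop_tol * max(stage_best_in, 1e-12)
      stall <- if (improved) 0L else stall + 1L
      if (stall >= cfg$stop_stages) break
      Tcur <- Tcur * cfg$cooling
    }
    best <- m
    best$occupied <- best_occ
    list(model = best, energy = best_E, chi2 = best_chi2,
         trace = do.call(rbind, trace))
  }
  with_seed(cfg$seed, run())
}
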