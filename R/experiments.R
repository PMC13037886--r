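#' Short-term contraction losses across a structure-by-loss grid
#'
#' Runs the moment engine over a grid of migration rates (structure levels)
#' and edge-contraction loss fractions, reporting the realized average
#' pairwise F_ST of each equilibrium and the species-wide pi loss one
#' generation after loss. This is the experiment behind the GDAR power-law
#' fit: diversity loss against area loss, stratified by population
#' structure.
#'
#' @param m_values migration rates defining the structure levels.
#' @param loss_fractions edge-contraction fractions in `(0, 1)`.
#' @param habitat model habitat (default 10 x 10, 50 diploids per deme).
#' @param u mutation rate.
#' @param edge contraction edge.
#' @return data frame with columns `m`, `fst`, `a_lost`, `loss_short`.
#' @export
contraction_loss_grid <- function(m_values, loss_fractions, habitat = NULL,
                                  u = 1e-6, edge = "north") {
  if (is.null(habitat)) habitat <- grid_habitat(10, 10, 50, 0.01)
  rows <- list()
  for (m in m_values) {
    hab <- habitat; hab$migration_rate <- m
    eq <- wf_equilibrium(hab, u)
    fst <- pairwise_fst(eq)$average
    pi0 <- pi_species(eq)
    for (f in loss_fractions) {
      hab2 <- edge_contraction(hab, f, edge)
      st <- wf_step(apply_loss(eq, live_demes(hab2)), hab2)
      rows[[length(rows) + 1L]] <- data.frame(
        m = m, fst = fst, a_lost = attr(hab2, "realized_fraction"),
        loss_short = 1 - pi_species(st) / pi0)
    }
  }
  do.call(rbind, rows)
}

#' Random-fragmentation ensemble of the moment engine
#'
#' Draws seeded random fragmentation maps across a range of loss fractions
#' on a calibrated habitat, and for each map records species-wide and mean
#' local pi loss at the short, mid and long horizons together with
#' landscape fragmentation metrics of the surviving mask. The long horizon
#' is `long_generations` of propagation (see [wf_forecast()] for why
#' fragmented landscapes use a time horizon rather than the equilibrium
#' solve).
#'
#' @param n_maps number of random maps.
#' @param loss_range range of loss fractions; maps are spread evenly over
#'   it (a single value repeats the same fraction with different maps).
#' @param migration_rate migration rate; `NULL` uses the weakly structured
#'   limit (the largest rate the grid admits).
#' @param seed base seed; map `i` uses a seed derived from it.
#' @param habitat model habitat (default 10 x 10, 50 diploids per deme).
#' @param u mutation rate.
#' @param horizons subset of `c("short", "mid", "long")`.
#' @param long_generations long-term horizon in generations.
#' @param n_ref census defining the mid-term horizon (default: pre-loss
#'   total).
#' @return data frame with one row per map: `map_seed`, `a_lost`,
#'   `loss_species_*`, `loss_local_*` per horizon, and landscape metrics
#'   `n_patches`, `edge_density`, `cohesion`, `core`, `perimeter`.
#' @export
fragmentation_ensemble <- function(n_maps = 50, loss_range = c(0.06, 0.93),
                                   migration_rate = NULL, seed = 1L,
                                   habitat = NULL, u = 1e-6,
                                   horizons = c("short", "mid", "long"),
                                   long_generations = 20000L, n_ref = NULL) {
  if (is.null(habitat)) habitat <- grid_habitat(10, 10, 50, 0.01)
  if (is.null(migration_rate))
    migration_rate <- 0.9999 / max_degree(habitat$rows, habitat$cols)
  habitat$migration_rate <- migration_rate
  eq0 <- wf_equilibrium(habitat, u)
  pi0_sp <- pi_species(eq0)
  pi0_loc <- pi_local(eq0)
  if (is.null(n_ref)) n_ref <- sum(habitat_sizes(habitat))
  t_mid <- as.integer(ceiling(n_ref / 2))
  fracs <- if (length(loss_range) == 1 || loss_range[1] == loss_range[2]) {
    rep(loss_range[1], n_maps)
  } else seq(loss_range[1], loss_range[2], length.out = n_maps)
  rows <- lapply(seq_len(n_maps), function(i) {
    ms <- child_seed(seed, i)
    hab2 <- random_fragmentation(habitat, fracs[i], ms)
    if (length(live_demes(hab2)) < 1) return(NULL)
    st <- apply_loss(eq0, live_demes(hab2))
    out <- list(map_seed = ms, a_lost = attr(hab2, "realized_fraction"))
    if ("short" %in% horizons) {
      s1 <- wf_step(st, hab2)
      out$loss_species_short <- 1 - pi_species(s1) / pi0_sp
      out$loss_local_short <- 1 - pi_local(s1) / pi0_loc
    }
    B <- migration_matrix(hab2)
    F <- st$F
    gens <- sort(unique(c(if ("mid" %in% horizons) t_mid,
                          if ("long" %in% horizons) as.integer(long_generations))))
    g_done <- 0L
    for (g_target in gens) {
      steps <- g_target - g_done
      for (s in seq_len(steps)) F <- step_F(F, B, st$sizes, u)
      g_done <- g_target
      stx <- new_wf_state((F + t(F)) / 2, st$demes, st$sizes, u, g_target)
      hz <- if (g_target == t_mid && "mid" %in% horizons) "mid" else "long"
      out[[paste0("loss_species_", hz)]] <- 1 - pi_species(stx) / pi0_sp
      out[[paste0("loss_local_", hz)]] <- 1 - pi_local(stx) / pi0_loc
    }
    ls <- landscape_summary(habitat_mask(hab2))
    out$n_patches <- ls$n_patches
    out$edge_density <- ls$edge_density
    out$cohesion <- ls$cohesion
    out$core <- ls$total_core_area
    out$perimeter <- ls$total_perimeter
    as.data.frame(out)
  })
  out <- do.call(rbind, rows)
  attr(out, "migration_rate") <- migration_rate
  attr(out, "pi0_species") <- pi0_sp
  attr(out, "pi0_local") <- pi0_loc
  out
}

#' Pooled R-squared of per-series GDAR fits
#'
#' Fits the power law separately within each structure level and reports
#' the pooled coefficient of determination of all fitted points on the
#' untransformed loss scale (1 - SS_res / SS_tot about the global mean).
#'
#' @param grid output of [contraction_loss_grid()].
#' @return list with `r_squared`, `fits` (per-level `gdar_fit`s) and `n`.
#' @export
gdar_pooled_r2 <- function(grid) {
  fits <- lapply(split(grid, grid$m), function(g)
    fit_power_law(g$a_lost, g$loss_short))
  pts <- do.call(rbind, lapply(fits, function(f) f$points))
  ss_res <- sum((pts$loss - pts$fitted)^2)
  ss_tot <- sum((pts$loss - mean(pts$loss))^2)
  list(r_squared = 1 - ss_res / ss_tot, fits = fits, n = nrow(pts))
}
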