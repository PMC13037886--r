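#' Forecast pi loss for a habitat-loss scenario
#'
#' Builds the default deme-grid model (10 x 10, 50 diploids per deme,
#' `u = 1e-6`), calibrates migration to the requested average pairwise
#' F_ST, solves the pre-loss equilibrium, applies the habitat-loss scenario,
#' and reports species-wide and mean local pi loss at the requested horizons:
#'
#' * `short`: one generation after loss;
#' * `mid`: `ceiling(n_ref / 2)` generations after loss, `n_ref` defaulting
#'   to the pre-loss total census size;
#' * `long`: the new equilibrium (direct solve) for edge contraction; for
#'   fragmentation, `long_generations` (default 20,000) generations after
#'   loss, since disconnected fragments re-equilibrate only on the much
#'   slower mutation timescale.
#'
#' @param loss_fraction proportion of habitat lost, in `[0, 1)`.
#' @param fst target average pairwise F_ST in `[0, 1)` (ignored if
#'   `migration_rate` is given).
#' @param horizon one or more of `"short"`, `"mid"`, `"long"`.
#' @param scenario `"contraction"` (edge removal, connected remainder) or
#'   `"fragmentation"` (seeded random map).
#' @param seed seed for the fragmentation map draw.
#' @param habitat model habitat; default `grid_habitat(10, 10, 50, ...)`.
#' @param u mutation rate per lineage per generation.
#' @param migration_rate bypass calibration with a known `m`.
#' @param n_ref census size defining the mid-term horizon.
#' @param long_generations long-term horizon (generations) for fragmentation.
#' @param edge contraction edge.
#' @param mode destroyed-deme migration handling (see [apply_loss()]).
#' @return a data frame of class `wf_forecast` with one row per horizon and
#'   columns `horizon`, `loss_species`, `loss_local` (proportions of the
#'   pre-loss values lost; negative = gain), plus attributes
#'   `migration_rate`, `realized_fst`, `realized_fraction` and `seed`.
#' @examples
#' \donttest{
#' wf_forecast(0.5, fst = 0.3, horizon = "short", scenario = "contraction")
#' }
#' @export
wf_forecast <- function(loss_fraction, fst, horizon = c("short", "mid", "long"),
                        scenario = c("contraction", "fragmentation"),
                        seed = 1L, habitat = NULL, u = 1e-6,
                        migration_rate = NULL, n_ref = NULL,
                        long_generations = 20000L, edge = "north",
                        mode = "renormalize") {
  scenario <- match.arg(scenario)
  horizon <- match.arg(horizon, several.ok = TRUE)
  if (loss_fraction < 0 || loss_fraction >= 1)
    stopf("loss_fraction must be in [0, 1)")
  if (is.null(habitat)) habitat <- grid_habitat(10, 10, 50, 0.01)
  realized_fst <- NA_real_
  if (is.null(migration_rate)) {
    migration_rate <- calibrate_migration(habitat, u, fst)
    realized_fst <- attr(migration_rate, "realized_fst")
  }
  habitat$migration_rate <- as.numeric(migration_rate)
  res <- scenario_losses(habitat, u, loss_fraction, scenario, seed,
                         horizon, n_ref, long_generations, edge, mode)
  out <- res$losses
  class(out) <- c("wf_forecast", "data.frame")
  attr(out, "migration_rate") <- as.numeric(migration_rate)
  attr(out, "realized_fst") <- realized_fst
  attr(out, "realized_fraction") <- res$realized_fraction
  attr(out, "seed") <- if (scenario == "fragmentation") seed else NA_integer_
  out
}

#' @export
print.wf_forecast <- function(x, ...) {
  cat("pi-loss forecast (proportion of pre-loss diversity lost):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("  m = %.4g, realized loss = %.3g\n",
              attr(x, "migration_rate"), attr(x, "realized_fraction")))
  invisible(x)
}

# All-horizon losses for one scenario on a calibrated habitat.
scenario_losses <- function(habitat, u, loss_fraction, scenario, seed,
                            horizons, n_ref, long_generations, edge, mode) {
  eq0 <- wf_equilibrium(habitat, u)
  pi0_sp <- pi_species(eq0)
  pi0_loc <- pi_local(eq0)
  if (loss_fraction == 0) {
    losses <- data.frame(horizon = horizons,
                         loss_species = 0, loss_local = 0)
    return(list(losses = losses, realized_fraction = 0))
  }
  hab2 <- if (scenario == "contraction") {
    edge_contraction(habitat, loss_fraction, edge)
  } else {
    random_fragmentation(habitat, loss_fraction, seed)
  }
  if (is.null(n_ref)) n_ref <- sum(habitat_sizes(habitat))
  st <- apply_loss(eq0, live_demes(hab2), mode)
  vals <- list()
  if ("short" %in% horizons) {
    s1 <- wf_step(st, hab2)
    vals$short <- c(1 - pi_species(s1) / pi0_sp, 1 - pi_local(s1) / pi0_loc)
  }
  t_mid <- as.integer(ceiling(n_ref / 2))
  if ("mid" %in% horizons || ("long" %in% horizons && scenario == "fragmentation")) {
    pr <- wf_propagate(st, hab2, t_mid, record_every = t_mid, keep_state = TRUE)
    if ("mid" %in% horizons)
      vals$mid <- c(1 - pi_species(pr$state) / pi0_sp,
                    1 - pi_local(pr$state) / pi0_loc)
    if ("long" %in% horizons && scenario == "fragmentation") {
      rest <- max(0L, as.integer(long_generations) - t_mid)
      pl <- wf_propagate(pr$state, hab2, rest, record_every = max(rest, 1),
                         keep_state = TRUE)
      vals$long <- c(1 - pi_species(pl$state) / pi0_sp,
                     1 - pi_local(pl$state) / pi0_loc)
    }
  }
  if ("long" %in% horizons && scenario == "contraction") {
    eq2 <- wf_equilibrium(hab2, u)
    vals$long <- c(1 - pi_species(eq2) / pi0_sp, 1 - pi_local(eq2) / pi0_loc)
  }
  vals <- vals[intersect(c("short", "mid", "long"), names(vals))]
  losses <- data.frame(horizon = names(vals),
                       loss_species = vapply(vals, `[`, 0, 1),
                       loss_local = vapply(vals, `[`, 0, 2),
                       row.names = NULL)
  list(losses = losses, realized_fraction = attr(hab2, "realized_fraction"))
}

#' Precompute a lookup table of pi-loss forecasts
#'
#' Tabulates [wf_forecast()] over a grid of F_ST and habitat-loss values for
#' the requested horizons and scenarios. Contraction cells are deterministic
#' (one evaluation); fragmentation cells average over `reps_per_cell` random
#' maps and also report the inter-quartile range of the species-wide loss.
#'
#' @param fst_grid,loss_grid numeric grids of F_ST and loss values.
#' @param horizons,scenarios subsets of the forecast horizons/scenarios.
#' @param reps_per_cell random maps per fragmentation cell.
#' @param seed base seed; map seeds derive deterministically from it.
#' @inheritParams wf_forecast
#' @return a data frame of class `forecast_table` with columns `fst`,
#'   `loss`, `horizon`, `scenario`, `mean_loss_species`, `iqr_lo`, `iqr_hi`,
#'   `mean_loss_local`, `reps`, `seed`.
#' @export
build_lookup_table <- function(fst_grid, loss_grid,
                               horizons = c("short", "mid", "long"),
                               scenarios = c("contraction", "fragmentation"),
                               reps_per_cell = 5L, seed = 1L,
                               habitat = NULL, u = 1e-6, n_ref = NULL,
                               long_generations = 20000L) {
  if (!length(fst_grid) || !length(loss_grid)) stopf("grids must be non-empty")
  if (is.null(habitat)) habitat <- grid_habitat(10, 10, 50, 0.01)
  rows <- list()
  cell <- 0L
  for (fst in fst_grid) {
    m <- calibrate_migration(habitat, u, fst)
    hab <- habitat; hab$migration_rate <- as.numeric(m)
    for (loss in loss_grid) for (sc in scenarios) {
      cell <- cell + 1L
      reps <- if (sc == "fragmentation" && loss > 0) reps_per_cell else 1L
      sp <- matrix(NA_real_, reps, length(horizons))
      lc <- matrix(NA_real_, reps, length(horizons))
      for (r in seq_len(reps)) {
        res <- scenario_losses(hab, u, loss, sc, child_seed(seed, cell * 131L + r),
                               horizons, n_ref, long_generations, "north",
                               "renormalize")
        idx <- match(res$losses$horizon, horizons)
        sp[r, idx] <- res$losses$loss_species
        lc[r, idx] <- res$losses$loss_local
      }
      for (j in seq_along(horizons)) {
        q <- quantile(sp[, j], c(0.25, 0.75), names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          fst = fst, loss = loss, horizon = horizons[j], scenario = sc,
          mean_loss_species = mean(sp[, j]), iqr_lo = q[1], iqr_hi = q[2],
          mean_loss_local = mean(lc[, j]), reps = reps, seed = seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("forecast_table", "data.frame")
  out
}

#' Nearest-bin lookup in a forecast table
#'
#' @param table a [build_lookup_table()] result (or one read back from CSV).
#' @param fst,loss query values; the nearest tabulated bin is used.
#' @param horizon,scenario exact levels present in the table.
#' @param value which loss to return: species-wide or mean local.
#' @return the tabulated mean loss (proportion).
#' @export
lookup_forecast <- function(table, fst, loss, horizon, scenario,
                            value = c("species", "local")) {
  value <- match.arg(value)
  sub <- table[table$horizon == horizon & table$scenario == scenario, ]
  if (!nrow(sub)) stopf("no table rows for horizon '%s' / scenario '%s'",
                        horizon, scenario)
  fst_bins <- sort(unique(sub$fst))
  loss_bins <- sort(unique(sub$loss))
  fq <- fst_bins[which.min(abs(fst_bins - fst))]
  lq <- loss_bins[which.min(abs(loss_bins - loss))]
  row <- sub[sub$fst == fq & sub$loss == lq, ][1, ]
  if (value == "species") row$mean_loss_species else row$mean_loss_local
}

#' Read/write forecast tables as CSV
#'
#' @param table a `forecast_table`.
#' @param path CSV path.
#' @export
write_forecast_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forecast_table
#' @export
read_forecast_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("forecast_table", "data.frame")
  out
}
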