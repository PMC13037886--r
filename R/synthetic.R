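#' Synthetic spatially structured genotype matrices
#'
#' Generates an isolation-by-distance-structured biallelic SNP matrix with a
#' tunable average pairwise F_ST: migration is calibrated on a small deme
#' grid with the moment engine, a forward Wright-Fisher simulation is burnt
#' in to diversity equilibrium, and diploid genotypes are sampled per deme
#' with planar coordinates. Defaults are desk-scale (a 6 x 6 grid of 20
#' diploids, `u = 1e-3`) so that burn-in takes seconds while still producing
#' realistic spatial structure.
#'
#' @param target_fst average pairwise F_ST to calibrate to, in `[0, 0.95]`.
#' @param n_per_deme diploids sampled per deme. Small per-deme samples bias
#'   the realized Hudson F_ST downward (the pi estimator's n/(n-1)
#'   correction is individual-level, not copy-level), so keep this at 10 or
#'   more when the realized F_ST matters.
#' @param L number of SNP sites.
#' @param rows,cols deme grid dimensions.
#' @param seed integer seed (mandatory: the spec of every synthetic dataset
#'   is reproducible).
#' @param deme_size diploids per deme in the simulation.
#' @param u per-site mutation rate.
#' @return a [genotype_matrix()] with attributes `realized_fst` (Hudson
#'   F_ST between deme samples), `target_fst`, `migration_rate` and `spec`
#'   (the full generating parameter list).
#' @export
make_structured_genotypes <- function(target_fst, n_per_deme = 15, L = 400,
                                      rows = 6, cols = 6, seed = 1L,
                                      deme_size = 20, u = 1e-3) {
  if (target_fst < 0 || target_fst > 0.95)
    stopf("target_fst must be in [0, 0.95]")
  hab <- grid_habitat(rows, cols, deme_size, 0.01)
  # calibrate under the biallelic model: that is what the SNP data realize
  m <- calibrate_migration(hab, u, target_fst, mutation_model = "biallelic")
  hab$migration_rate <- as.numeric(m)
  sim <- wf_burn_in(hab, u, L, seed = child_seed(seed, 1L),
                    stability_window = 4 * sum(habitat_sizes(hab)) %/% 10,
                    tol = 0.02)
  gm <- sample_genotypes(sim, hab, n_per_deme, seed = child_seed(seed, 2L))
  fst <- tryCatch(hudson_fst(gm)$average, error = function(e) NA_real_)
  attr(gm, "realized_fst") <- fst
  attr(gm, "target_fst") <- target_fst
  attr(gm, "migration_rate") <- as.numeric(m)
  attr(gm, "spec") <- list(kind = "genotypes", target_fst = target_fst,
                           n_per_deme = n_per_deme, L = L, rows = rows,
                           cols = cols, deme_size = deme_size, u = u,
                           seed = seed)
  gm
}

#' Synthetic Living Planet Index table
#'
#' Per-species remaining fractions are drawn from a Beta distribution
#' moment-matched to the reported across-species summary (mean 64%
#' population loss, IQR of loss 40-93%): `remaining ~ Beta(0.528, 0.938)`.
#' Each species gets `n_populations` two-point census series consistent
#' with its draw (baseline abundances large enough that the `+1` guard in
#' [lpi_decline()] is negligible).
#'
#' @param n_species number of species.
#' @param seed integer seed.
#' @param remaining_dist list with `shape1`, `shape2` of the Beta on the
#'   remaining fraction.
#' @param n_populations populations per species.
#' @param years census years of the two-point series.
#' @return data frame with columns `species`, `population_id`, `year`,
#'   `abundance`, plus attribute `spec`.
#' @export
make_lpi_table <- function(n_species, seed = 1L,
                           remaining_dist = list(shape1 = 0.528, shape2 = 0.938),
                           n_populations = 3, years = c(1970, 2020)) {
  if (n_species < 0) stopf("n_species must be non-negative")
  if (!all(c("shape1", "shape2") %in% names(remaining_dist)) ||
      remaining_dist$shape1 <= 0 || remaining_dist$shape2 <= 0)
    stopf("invalid remaining-fraction distribution spec")
  rows <- with_seed(seed, {
    lapply(seq_len(n_species), function(i) {
      rem <- rbeta(1, remaining_dist$shape1, remaining_dist$shape2)
      n_past <- round(runif(n_populations, 500, 5000))
      n_present <- round(n_past * rem)
      data.frame(species = sprintf("lpi_sp%04d", i),
                 population_id = sprintf("pop%d", seq_len(n_populations)),
                 year = rep(years[1], n_populations),
                 abundance = n_past) |>
        rbind(data.frame(species = sprintf("lpi_sp%04d", i),
                         population_id = sprintf("pop%d", seq_len(n_populations)),
                         year = rep(years[2], n_populations),
                         abundance = n_present))
    })
  })
  out <- if (n_species > 0) do.call(rbind, rows) else
    data.frame(species = character(), population_id = character(),
               year = numeric(), abundance = numeric())
  attr(out, "spec") <- list(kind = "lpi", n_species = n_species,
                            remaining_dist = remaining_dist,
                            n_populations = n_populations, seed = seed)
  out
}

#' Synthetic Red List table
#'
#' @param category_counts named integer vector, e.g.
#'   `c(CR = 10, EN = 20, VU = 30)`; categories must exist in the range
#'   table used downstream.
#' @param seed integer seed (species order is shuffled).
#' @return data frame with columns `species`, `category`, `criteria`.
#' @export
make_redlist_table <- function(category_counts, seed = 1L) {
  if (any(category_counts < 0)) stopf("category counts must be non-negative")
  cats <- rep(names(category_counts), times = category_counts)
  out <- with_seed(seed, {
    cats <- if (length(cats)) sample(cats) else character()
    data.frame(species = sprintf("rl_sp%04d", seq_along(cats)),
               category = cats,
               criteria = if (length(cats)) "A2" else character(),
               stringsAsFactors = FALSE)
  })
  attr(out, "spec") <- list(kind = "redlist",
                            category_counts = as.list(category_counts),
                            seed = seed)
  out
}

#' Synthetic GBF Indicator-2 table
#'
#' Fractions of populations lost are drawn from a Beta moment-matched to
#' the reported summary (mean 18.6% lost, IQR 0-35%):
#' `loss ~ Beta(0.323, 1.416)`; past population counts are uniform on
#' 5..20 and present counts follow from the loss draw.
#'
#' @param n_species number of species.
#' @param seed integer seed.
#' @param loss_dist list with `shape1`, `shape2` of the Beta on the lost
#'   fraction.
#' @return data frame with columns `species`, `populations_past`,
#'   `populations_present`.
#' @export
make_gbf_table <- function(n_species, seed = 1L,
                           loss_dist = list(shape1 = 0.323, shape2 = 1.416)) {
  if (n_species < 0) stopf("n_species must be non-negative")
  if (loss_dist$shape1 <= 0 || loss_dist$shape2 <= 0)
    stopf("invalid loss distribution spec")
  out <- with_seed(seed, {
    loss <- rbeta(n_species, loss_dist$shape1, loss_dist$shape2)
    past <- if (n_species > 0) sample(5:20, n_species, replace = TRUE) else integer()
    data.frame(species = sprintf("gbf_sp%04d", seq_len(n_species)),
               populations_past = past,
               populations_present = round(past * (1 - loss)),
               stringsAsFactors = FALSE)
  })
  attr(out, "spec") <- list(kind = "gbf", n_species = n_species,
                            loss_dist = loss_dist, seed = seed)
  out
}

#' Write a synthetic table with its generating spec alongside
#'
#' @param table a synthetic table carrying a `spec` attribute.
#' @param path CSV path; the spec is written to `<path>.spec.json`.
#' @export
write_synthetic <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  spec <- attr(table, "spec")
  if (!is.null(spec))
    jsonlite::write_json(spec, paste0(path, ".spec.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
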