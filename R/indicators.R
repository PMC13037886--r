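#' Default Red List category-to-loss table
#'
#' Population/area loss ranges (percent) per IUCN Red List category,
#' following the A-criterion thresholds: Vulnerable 30-50, Endangered
#' 50-80, Critically Endangered 80-95 (mean 87.5), with Extinct fixed at
#' 100, "Likely Extinct" 95-100, Near Threatened 0-30 and Least Concern 0.
#' The table is configuration: override any range via a CSV or data frame
#' with columns `category`, `min`, `max`.
#'
#' @return data frame with columns `category`, `min`, `max`.
#' @export
default_redlist_table <- function() {
  data.frame(
    category = c("EX", "LE", "CR", "EN", "VU", "NT", "LC"),
    min = c(100, 95, 80, 50, 30, 0, 0),
    max = c(100, 100, 95, 80, 50, 30, 0),
    stringsAsFactors = FALSE)
}

#' Translate a Red List category into an area-loss proxy
#'
#' The proxy is the arithmetic mean of the category's loss range (so
#' Critically Endangered, 80-95%, maps to 87.5%), returned as a proportion.
#' Population loss is used as a proxy for habitat area loss, assuming the
#' two are proportional.
#'
#' @param category character vector of categories present in the table.
#' @param criteria_table range table (defaults to
#'   [default_redlist_table()]).
#' @return area-loss proportions in `[0, 1]`.
#' @export
redlist_to_area_loss <- function(category, criteria_table = default_redlist_table()) {
  idx <- match(category, criteria_table$category)
  if (anyNA(idx))
    stopf("unknown Red List category: %s",
          paste(unique(category[is.na(idx)]), collapse = ", "))
  (criteria_table$min[idx] + criteria_table$max[idx]) / 2 / 100
}

#' Species-level decline from Living Planet Index population series
#'
#' For each population the remaining fraction is
#' `N_present / (N_past + 1)` -- earliest vs latest census, with the `+ 1`
#' guarding against zero baselines; the species remaining fraction is the
#' arithmetic mean across populations, clipped to `[0, 1]`; the reported
#' loss is its complement. Species with no decline (loss <= 0) are flagged
#' so callers can exclude them.
#'
#' @param series data frame with columns `population_id`, `year`,
#'   `abundance` for one species (each population needs >= 2 censuses).
#' @param guard additive denominator guard (default 1; set 0 for the raw
#'   ratio).
#' @return loss proportion with attribute `"declining"` (logical).
#' @export
lpi_decline <- function(series, guard = 1) {
  if (!nrow(series)) stopf("empty abundance series")
  rem <- vapply(split(series, series$population_id), function(p) {
    if (nrow(p) < 2) stopf("population %s has fewer than 2 censuses",
                           p$population_id[1])
    p <- p[order(p$year), ]
    n_past <- p$abundance[1]
    n_present <- p$abundance[nrow(p)]
    n_present / (n_past + guard)
  }, 0)
  remaining <- min(max(mean(rem), 0), 1)
  loss <- 1 - remaining
  attr(loss, "declining") <- loss > 0
  loss
}

#' Fraction of populations lost (GBF complementary Indicator 2)
#'
#' @param n_past,n_present population counts (`past >= present >= 0`,
#'   `past > 0`).
#' @return `(past - present) / past`, vectorized.
#' @export
gbf_population_loss <- function(n_past, n_present) {
  if (any(n_past <= 0)) stopf("past population count must be positive")
  if (any(n_present > n_past) || any(n_present < 0))
    stopf("need past >= present >= 0")
  (n_past - n_present) / n_past
}

#' Sample species F_ST values
#'
#' Draws from a truncated normal on `[0, 1)` with the across-species mean
#' 0.270 and SD 0.211, or resamples (with replacement) from a supplied
#' empirical table of F_ST values.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @param mean,sd parameters of the untruncated normal.
#' @param empirical optional numeric vector to resample from instead.
#' @return `n` values in `[0, 1)`.
#' @export
sample_fst <- function(n, seed = NULL, mean = 0.270, sd = 0.211,
                       empirical = NULL) {
  with_seed(seed, {
    if (!is.null(empirical)) {
      if (any(empirical < 0 | empirical >= 1)) stopf("empirical F_ST must lie in [0, 1)")
      return(sample(empirical, n, replace = TRUE))
    }
    plo <- pnorm(0, mean, sd)
    phi <- pnorm(1, mean, sd)
    qnorm(runif(n, plo, phi), mean, sd)
  })
}

#' Sample GDAR exponents
#'
#' Resamples with replacement from an empirical table of fitted `z` values;
#' without a table, draws from an exponential with mean 0.03 truncated to
#' `[0, 0.45]` (matching the across-species mean and range of fitted
#' exponents).
#'
#' @inheritParams sample_fst
#' @param empirical optional numeric vector of non-negative exponents.
#' @return `n` non-negative exponents.
#' @export
sample_z <- function(n, seed = NULL, empirical = NULL) {
  with_seed(seed, {
    if (!is.null(empirical)) {
      if (any(empirical < 0)) stopf("z values must be non-negative")
      return(sample(empirical, n, replace = TRUE))
    }
    p_max <- 1 - exp(-0.45 / 0.03)
    -0.03 * log(1 - runif(n, 0, p_max))
  })
}

#' Per-species pi-loss predictions from indicator records
#'
#' Each record carries an area-loss proxy plus the species' GDAR exponent
#' and F_ST (measured or sampled). Short-term contraction losses come from
#' the GDAR power law, [predict_loss()]; every other horizon/scenario comes
#' from a nearest-bin lookup in a precomputed [build_lookup_table()].
#' Fragmentation horizons report the mean local pi loss (the species-wide
#' value is attached alongside), since pooled diversity is misleading in
#' shattered landscapes.
#'
#' @param records data frame with columns `species`, `source`,
#'   `area_loss_proxy`, `f_st`, `z_gdar` (see [make_species_records()]).
#' @param table a `forecast_table` covering the queried horizons/scenarios.
#' @param horizons horizons to predict.
#' @param scenario habitat-loss scenario.
#' @return data frame with one row per record x horizon: `species`,
#'   `source`, `horizon`, `scenario`, `loss` (proportion), `loss_species`,
#'   `method`.
#' @export
predict_species <- function(records, table,
                            horizons = c("short", "mid"),
                            scenario = c("contraction", "fragmentation")) {
  scenario <- match.arg(scenario)
  need <- c("species", "source", "area_loss_proxy", "f_st", "z_gdar")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  if (any(records$area_loss_proxy < 0 | records$area_loss_proxy > 1))
    stopf("area_loss_proxy must be in [0, 1]")
  out <- list()
  for (hz in horizons) {
    if (hz == "short" && scenario == "contraction") {
      loss <- predict_loss(records$z_gdar, pmin(records$area_loss_proxy, 1))
      loss_sp <- loss
      method <- "gdar"
    } else {
      # no habitat lost, nothing to look up: the loss is identically zero
      look <- function(f, a, what) {
        if (a == 0) return(0)
        lookup_forecast(table, f, a, hz, scenario, what)
      }
      loss_sp <- mapply(look, records$f_st, records$area_loss_proxy,
                        MoreArgs = list(what = "species"))
      loss <- if (scenario == "fragmentation") {
        mapply(look, records$f_st, records$area_loss_proxy,
               MoreArgs = list(what = "local"))
      } else loss_sp
      method <- "wfmoments_table"
    }
    out[[hz]] <- data.frame(species = records$species,
                            source = records$source, horizon = hz,
                            scenario = scenario, loss = pmax(loss, 0),
                            loss_species = loss_sp, method = method,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build species records from raw indicator tables
#'
#' Converts Red List, LPI or GBF input tables into the record format
#' consumed by [predict_species()], sampling F_ST and GDAR exponents where
#' the species has no measured value. Sampling provenance is recorded per
#' record.
#'
#' @param redlist data frame (`species`, `category`) or `NULL`.
#' @param lpi data frame (`species`, `population_id`, `year`, `abundance`)
#'   or `NULL`; non-declining species are dropped.
#' @param gbf data frame (`species`, `populations_past`,
#'   `populations_present`) or `NULL`.
#' @param seed seed for parameter sampling.
#' @param fst_values,z_values optional empirical pools passed to
#'   [sample_fst()] / [sample_z()].
#' @param criteria_table Red List range table.
#' @return a records data frame with provenance columns `f_st_source`,
#'   `z_source`.
#' @export
make_species_records <- function(redlist = NULL, lpi = NULL, gbf = NULL,
                                 seed = 1L, fst_values = NULL,
                                 z_values = NULL,
                                 criteria_table = default_redlist_table()) {
  recs <- list()
  if (!is.null(redlist) && nrow(redlist)) {
    recs$redlist <- data.frame(
      species = redlist$species, source = "redlist",
      area_loss_proxy = redlist_to_area_loss(redlist$category, criteria_table),
      stringsAsFactors = FALSE)
  }
  if (!is.null(lpi) && nrow(lpi)) {
    sp <- split(lpi, lpi$species)
    losses <- vapply(sp, function(s)
      as.numeric(lpi_decline(s[, c("population_id", "year", "abundance")])), 0)
    keep <- losses > 0
    recs$lpi <- data.frame(species = names(sp)[keep], source = "lpi",
                           area_loss_proxy = unname(losses[keep]),
                           stringsAsFactors = FALSE)
  }
  if (!is.null(gbf) && nrow(gbf)) {
    recs$gbf <- data.frame(
      species = gbf$species, source = "gbf",
      area_loss_proxy = gbf_population_loss(gbf$populations_past,
                                            gbf$populations_present),
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) stopf("no indicator tables supplied")
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$f_st <- sample_fst(nrow(out), seed = child_seed(seed, 1L),
                         empirical = fst_values)
  out$z_gdar <- sample_z(nrow(out), seed = child_seed(seed, 2L),
                         empirical = z_values)
  out$f_st_source <- if (is.null(fst_values)) "sampled_normal" else "sampled_empirical"
  out$z_source <- if (is.null(z_values)) "sampled_default" else "sampled_empirical"
  out$seed <- seed
  out
}

#' Aggregate per-species predictions
#'
#' Arithmetic mean and inter-quartile range of the predicted loss per
#' `source` x `horizon` x `scenario` stratum.
#'
#' @param predictions output of [predict_species()].
#' @return data frame with `source`, `horizon`, `scenario`, `n`,
#'   `mean_loss`, `iqr_lo`, `iqr_hi`.
#' @export
aggregate_predictions <- function(predictions) {
  if (!nrow(predictions)) stopf("no predictions to aggregate")
  key <- interaction(predictions$source, predictions$horizon,
                     predictions$scenario, drop = TRUE)
  rows <- lapply(split(predictions, key), function(g) {
    q <- quantile(g$loss, c(0.25, 0.75), names = FALSE)
    data.frame(source = g$source[1], horizon = g$horizon[1],
               scenario = g$scenario[1], n = nrow(g),
               mean_loss = mean(g$loss), iqr_lo = q[1], iqr_hi = q[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
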