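# Conservation-indicator translation pipeline.

test_that("Red List categories map to midpoint losses", {
  expect_equal(redlist_to_area_loss("CR"), 0.875)
  expect_equal(redlist_to_area_loss("EN"), 0.65)
  expect_equal(redlist_to_area_loss("VU"), 0.40)
  expect_equal(redlist_to_area_loss("LC"), 0)
  custom <- data.frame(category = "X", min = 50, max = 80)
  expect_equal(redlist_to_area_loss("X", custom), 0.65)
  expect_error(redlist_to_area_loss("??"), "unknown")
})

test_that("LPI declines average populations with the +1 guard", {
  s <- data.frame(population_id = c("a", "a", "b", "b"),
                  year = c(1970, 2020, 1970, 2020),
                  abundance = c(100, 30, 200, 100))
  loss <- lpi_decline(s)
  expect_equal(as.numeric(loss), 1 - mean(c(30 / 101, 100 / 201)))
  expect_true(attr(loss, "declining"))

  const <- data.frame(population_id = "a", year = c(2000, 2010),
                      abundance = c(500, 500))
  l0 <- lpi_decline(const)
  expect_lt(as.numeric(l0), 0.01)     # only the +1 guard remains
  # a zero baseline is handled finitely
  z <- data.frame(population_id = "a", year = c(2000, 2010),
                  abundance = c(0, 5))
  expect_true(is.finite(as.numeric(lpi_decline(z))))
  expect_error(lpi_decline(s[0, ]), "empty")
})

test_that("GBF population loss is the straightforward fraction", {
  expect_equal(gbf_population_loss(10, 10), 0)
  expect_equal(gbf_population_loss(10, 0), 1)
  expect_equal(gbf_population_loss(8, 6), 0.25)
  expect_error(gbf_population_loss(0, 0), "positive")
  expect_error(gbf_population_loss(5, 6), "past >= present")
})

test_that("F_ST sampling is truncated, seeded, and matches its mean", {
  x <- sample_fst(10000, seed = 4)
  expect_true(all(x >= 0 & x < 1))
  expect_identical(sample_fst(50, seed = 4), sample_fst(50, seed = 4))
  # mean of the truncated normal: compare against a numeric integral
  f <- function(v) v * dnorm(v, 0.270, 0.211) /
    (pnorm(1, 0.270, 0.211) - pnorm(0, 0.270, 0.211))
  mu <- integrate(f, 0, 1)$value
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(10000))
  # empirical resampling reproduces the pool
  pool <- c(0.1, 0.2, 0.5)
  expect_true(all(sample_fst(100, seed = 1, empirical = pool) %in% pool))
})

test_that("z sampling resamples tables and respects its default range", {
  expect_equal(sample_z(20, seed = 1, empirical = 0.07), rep(0.07, 20))
  expect_identical(sample_z(30, seed = 2), sample_z(30, seed = 2))
  z <- sample_z(10000, seed = 3)
  expect_true(all(z >= 0 & z <= 0.45))
  expect_lt(abs(mean(z) - 0.03), 0.01)
  pool <- c(0.01, 0.05, 0.4)
  zs <- sample_z(5000, seed = 4, empirical = pool)
  expect_lt(abs(mean(zs) - mean(pool)), 3 * sd(pool) / sqrt(5000))
  expect_error(sample_z(5, empirical = c(-0.1)), "non-negative")
})

small_table <- function() {
  cached("indicator_table",
         build_lookup_table(c(0.05, 0.3), c(0.3, 0.65, 0.875),
                            horizons = c("short", "mid"),
                            scenarios = "contraction",
                            habitat = grid_habitat(4, 4, 25, 0.01),
                            u = 1e-4, n_ref = 400, seed = 9))
}

test_that("per-species predictions follow GDAR short-term and table lookups", {
  tb <- small_table()
  recs <- data.frame(species = c("sp1", "sp2"), source = "redlist",
                     area_loss_proxy = c(0.8, 0), f_st = c(0.05, 0.3),
                     z_gdar = c(0.02809, 0.1))
  preds <- predict_species(recs, tb, horizons = c("short", "mid"),
                           scenario = "contraction")
  short1 <- preds$loss[preds$species == "sp1" & preds$horizon == "short"]
  expect_equal(round(100 * short1, 1), 4.4)   # the worked example
  expect_true(all(preds$loss[preds$species == "sp2"] == 0))
  mid1 <- preds$loss[preds$species == "sp1" & preds$horizon == "mid"]
  expect_equal(mid1, lookup_forecast(tb, 0.05, 0.8, "mid", "contraction"))
  # mid-term contraction loss never falls below short-term
  expect_gte(mid1, short1 - 1e-9)
})

test_that("records assembly samples parameters deterministically and filters LPI", {
  lpi <- rbind(
    data.frame(species = "down", population_id = "p1", year = c(1980, 2020),
               abundance = c(1000, 200)),
    data.frame(species = "up", population_id = "p1", year = c(1980, 2020),
               abundance = c(200, 1000)))
  rl <- data.frame(species = "r1", category = "CR")
  gbf <- data.frame(species = "g1", populations_past = 8,
                    populations_present = 6)
  r1 <- make_species_records(rl, lpi, gbf, seed = 5)
  r2 <- make_species_records(rl, lpi, gbf, seed = 5)
  expect_identical(r1, r2)
  expect_false("up" %in% r1$species)  # non-declining excluded
  expect_equal(r1$area_loss_proxy[r1$species == "r1"], 0.875)
  expect_equal(r1$area_loss_proxy[r1$species == "g1"], 0.25)
  expect_true(all(r1$f_st >= 0 & r1$f_st < 1))
})

test_that("aggregation reports means and hand-computed quartiles", {
  p <- data.frame(species = letters[1:8], source = "lpi", horizon = "short",
                  scenario = "contraction",
                  loss = c(0.02, 0.04, 0.05, 0.07, 0.10, 0.12, 0.2, 0.4),
                  loss_species = 0, method = "gdar")
  agg <- aggregate_predictions(p)
  expect_equal(agg$mean_loss, mean(p$loss))
  expect_equal(agg$iqr_lo, quantile(p$loss, 0.25, names = FALSE))
  expect_equal(agg$iqr_hi, quantile(p$loss, 0.75, names = FALSE))
  # identical predictions give a zero-width IQR; order never matters
  p2 <- p; p2$loss <- 0.1
  agg2 <- aggregate_predictions(p2)
  expect_equal(agg2$iqr_lo, agg2$iqr_hi)
  expect_equal(aggregate_predictions(p[sample(8), ])$mean_loss, agg$mean_loss)
})

test_that("global means respond monotonically to threat-category shifts", {
  tb <- small_table()
  mk <- function(counts) {
    rl <- make_redlist_table(counts, seed = 3)
    recs <- make_species_records(redlist = rl, seed = 3)
    agg <- aggregate_predictions(
      predict_species(recs, tb, horizons = "short", scenario = "contraction"))
    agg$mean_loss
  }
  lo <- mk(c(VU = 30, CR = 0))
  mid <- mk(c(VU = 15, CR = 15))
  hi <- mk(c(VU = 0, CR = 30))
  expect_true(lo < mid && mid < hi)
})
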