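# Forecasting interface, lookup tables, and the trajectory fit.

test_that("zero loss forecasts zero at every horizon", {
  fc <- wf_forecast(0, fst = 0.2, habitat = grid_habitat(3, 3, 20, 0.01),
                    u = 1e-4, n_ref = 180)
  expect_true(all(fc$loss_species == 0))
  expect_true(all(fc$loss_local == 0))
})

test_that("contraction losses are ordered short <= mid <= long", {
  fc <- wf_forecast(0.5, fst = 0.3, habitat = grid_habitat(4, 4, 25, 0.01),
                    u = 1e-4, n_ref = 400, seed = 2)
  v <- setNames(fc$loss_species, fc$horizon)
  expect_lte(v["short"], v["mid"] + 1e-12)
  expect_lte(v["mid"], v["long"] + 1e-12)
})

test_that("fragmentation inflates species pi while local pi falls", {
  # high loss, weakly structured small model, long horizon on the mutation
  # timescale so isolated fragments diverge visibly
  fc <- suppressWarnings(   # target F_ST 0 resolves to the boundary m
    wf_forecast(0.8, fst = 0, scenario = "fragmentation", seed = 4,
                habitat = grid_habitat(5, 5, 20, 0.01), u = 1e-4,
                n_ref = 500, long_generations = 4000))
  long <- fc[fc$horizon == "long", ]
  expect_lt(long$loss_species, 0)   # inflation (negative loss)
  expect_gt(long$loss_local, 0.3)   # local collapse
})

test_that("lookup tables cover their grid and behave monotonically", {
  tb <- build_lookup_table(c(0.05, 0.4), c(0, 0.3, 0.6),
                           horizons = c("short", "mid"),
                           scenarios = "contraction",
                           habitat = grid_habitat(4, 4, 25, 0.01),
                           u = 1e-4, n_ref = 400, seed = 1)
  expect_equal(nrow(tb), 2 * 3 * 2)
  zero <- tb[tb$loss == 0, ]
  expect_true(all(abs(zero$mean_loss_species) < 1e-12))
  for (f in c(0.05, 0.4)) {
    s <- tb[tb$fst == f & tb$horizon == "short", ]
    expect_true(all(diff(s$mean_loss_species[order(s$loss)]) >= -1e-12))
  }
  # nearest-bin lookup picks the right cells
  expect_equal(lookup_forecast(tb, 0.06, 0.29, "short", "contraction"),
               tb$mean_loss_species[tb$fst == 0.05 & tb$loss == 0.3 &
                                      tb$horizon == "short"])
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_forecast_table(tb, f)
  tb2 <- read_forecast_table(f)
  expect_equal(tb2$mean_loss_species, tb$mean_loss_species)
})

test_that("fragmentation table cells report replicate IQRs deterministically", {
  tb1 <- build_lookup_table(0.1, 0.6, horizons = "short",
                            scenarios = "fragmentation", reps_per_cell = 4,
                            habitat = grid_habitat(4, 4, 25, 0.01),
                            u = 1e-4, n_ref = 400, seed = 7)
  tb2 <- build_lookup_table(0.1, 0.6, horizons = "short",
                            scenarios = "fragmentation", reps_per_cell = 4,
                            habitat = grid_habitat(4, 4, 25, 0.01),
                            u = 1e-4, n_ref = 400, seed = 7)
  expect_identical(tb1, tb2)
  expect_equal(tb1$reps, 4)
  expect_lte(tb1$iqr_lo, tb1$iqr_hi)
})

test_that("the trajectory fit recovers the engine's own parameters", {
  h <- grid_habitat(3, 3, 30, 0.04)
  u_true <- 2e-4
  eq <- wf_equilibrium(h, u_true)
  h2 <- edge_contraction(h, 0.4, "north")
  st <- apply_loss(eq, live_demes(h2))
  obs <- wf_propagate(st, h2, 400, record_every = 25)
  fit <- fit_to_trajectory(obs, h, survivors = live_demes(h2),
                           start = c(u = 1e-4, m = 0.02, time_scale = 1))
  expect_lt(abs(fit$u - u_true) / u_true, 0.05)
  expect_lt(abs(fit$m - 0.04) / 0.04, 0.05)
  expect_lt(abs(fit$time_scale - 1), 0.05)
  expect_lt(fit$residual, 1e-10)

  # a flat trajectory at equilibrium fits with ~zero residual
  flat <- wf_propagate(eq, h, 100, record_every = 20)
  fit0 <- fit_to_trajectory(flat, h, survivors = NULL,
                            start = c(u = u_true, m = 0.04, time_scale = 1))
  expect_lt(fit0$residual, 1e-8)
  expect_error(fit_to_trajectory(obs[1:2, ], h), "at least 3")
})

test_that("fitting the noisy forward simulation stays near the truth", {
  h <- grid_habitat(3, 3, 30, 0.04)
  u_true <- 2e-4
  eq <- wf_equilibrium(h, u_true)
  h2 <- edge_contraction(h, 0.4, "north")
  sims <- lapply(1:6, function(s) {
    b <- wf_simulate(h, u_true, 800, 1200, seed = 50 + s, record_every = 1200)
    wf_continue(list(state = b$state), h2, 400, seed = 70 + s,
                record_every = 25)$trajectory
  })
  avg <- sims[[1]]
  avg$pi_species <- rowMeans(sapply(sims, function(tr) tr$pi_species))
  ctrl <- list(maxit = 250)   # noise floors quickly; no need to polish
  fit <- suppressWarnings(
    fit_to_trajectory(avg, h, survivors = live_demes(h2),
                      start = c(u = 1e-4, m = 0.02, time_scale = 1),
                      mutation_model = "biallelic", control = ctrl))
  # the level of pi pins u to its order of magnitude; tighter recovery needs
  # more replicates than a unit test should spend
  expect_lt(abs(log(fit$u / u_true)), log(3))
  # residual shrinks as replicates accumulate
  one <- sims[[1]]
  fit1 <- suppressWarnings(
    fit_to_trajectory(one, h, survivors = live_demes(h2),
                      start = c(u = 1e-4, m = 0.02, time_scale = 1),
                      mutation_model = "biallelic", control = ctrl))
  expect_lt(fit$residual, fit1$residual)
})
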