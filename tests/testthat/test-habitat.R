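test_that("grid construction gives the expected topology and census", {
  h <- grid_habitat(10, 10, 50, 0.01)
  expect_equal(sum(h$live), 100)
  expect_equal(sum(habitat_sizes(h)), 5000)
  A <- divloss:::grid_adjacency(h)
  deg <- rowSums(A)
  co <- deme_coords(h)
  interior <- co$row > 1 & co$row < 10 & co$col > 1 & co$col < 10
  expect_true(all(deg[interior] == 4))
  expect_true(all(deg[!interior] %in% c(2, 3)))

  chain <- grid_habitat(1, 20, 50, 0.01)
  degc <- rowSums(divloss:::grid_adjacency(chain))
  expect_equal(sum(degc == 1), 2)   # the two ends
  expect_true(all(degc <= 2))

  sq <- grid_habitat(2, 2, 10, 0.1)
  expect_equal(sum(sq$live), 4)
  expect_true(all(rowSums(divloss:::grid_adjacency(sq)) == 2))
})

test_that("invalid grids and migration rates are refused", {
  expect_error(grid_habitat(0, 5), "positive")
  expect_error(grid_habitat(10, 10, 50, 0.25), "migration")
  expect_error(grid_habitat(10, 10, 50, -0.1), "migration")
  # 1-D chain allows larger m (max degree 2)
  expect_silent(grid_habitat(1, 10, 50, 0.4))
})

test_that("migration matrix is row-stochastic and symmetric on uniform grids", {
  h <- grid_habitat(5, 7, 30, 0.08)
  B <- migration_matrix(h)
  expect_equal(unname(rowSums(B)), rep(1, 35), tolerance = 1e-12)
  expect_true(isSymmetric(B))
  expect_true(all(B[divloss:::grid_adjacency(h) == 1] == 0.08))
})

test_that("edge contraction removes the right demes and stays connected", {
  h <- grid_habitat(10, 10, 50, 0.01)
  h2 <- edge_contraction(h, 0.5, "north")
  expect_equal(sum(h2$live), 50)
  expect_equal(attr(h2, "realized_fraction"), 0.5)
  # top five rows gone
  expect_true(all(deme_coords(h2)$row >= 6))
  expect_true(is_connected(h2))

  expect_identical(edge_contraction(h, 0, "north")$live, h$live)

  h3 <- edge_contraction(h, 0.9, "south")
  expect_equal(sum(h3$live), 10)
  expect_true(all(deme_coords(h3)$row == 1))
  expect_true(is_connected(h3))
  expect_error(edge_contraction(h, 1), "destroy")

  # partial rows keep the remainder connected, for every fraction and edge
  for (f in seq(0.05, 0.95, by = 0.07)) {
    for (e in c("north", "south", "east", "west")) {
      hf <- edge_contraction(h, min(f, 0.99), e)
      expect_equal(sum(hf$live), 100 - floor(min(f, 0.99) * 100))
      expect_true(is_connected(hf))
    }
  }
})

test_that("random fragmentation is seed-deterministic with exact counts", {
  h <- grid_habitat(10, 10, 50, 0.01)
  a <- random_fragmentation(h, 0.5, seed = 1)
  b <- random_fragmentation(h, 0.5, seed = 1)
  expect_identical(a$live, b$live)
  expect_equal(sum(a$live), 50)
  c1 <- random_fragmentation(h, 0.5, seed = 2)
  expect_false(identical(a$live, c1$live))

  h20 <- grid_habitat(20, 20, 50, 0.01)
  m20 <- random_fragmentation(h20, 0.5, seed = 7)
  expect_equal(sum(m20$live), 200)

  # 121 seeded draws over the studied loss range give 121 distinct maps
  fr <- seq(0.06, 0.93, length.out = 121)
  maps <- vapply(seq_along(fr), function(i)
    paste(which(random_fragmentation(h, fr[i], seed = i)$live), collapse = ","),
    "")
  expect_equal(length(unique(maps)), 121)
})

test_that("gradual schedules compose to the one-shot contraction", {
  h <- grid_habitat(10, 10, 50, 0.01)
  sch <- gradual_schedule(h, 0.5, 0.01, 11)
  expect_equal(nrow(sch$events), 50)
  expect_true(all(lengths(sch$events$demes) == 1))
  expect_equal(diff(sch$events$offset), rep(11, 49))
  final <- apply_schedule(h, sch)
  expect_identical(final$live, edge_contraction(h, 0.5, "north")$live)

  one <- gradual_schedule(h, 0.5, 0.5, 1)
  expect_equal(nrow(one$events), 1)
  expect_equal(length(one$events$demes[[1]]), 50)

  two <- gradual_schedule(h, 0.1, 0.05, 100)
  expect_equal(nrow(two$events), 2)
  expect_equal(lengths(two$events$demes), c(5L, 5L))

  expect_error(gradual_schedule(h, 0.5, 0, 11), "invalid schedule")
})

test_that("restore is the inverse of removal on the topology", {
  h <- grid_habitat(6, 6, 40, 0.02)
  h2 <- random_fragmentation(h, 0.5, seed = 3)
  gone <- setdiff(which(h$live), which(h2$live))
  h3 <- restore(h2, gone)
  expect_identical(h3$live, h$live)
  expect_identical(h3$sizes, h$sizes)

  expect_identical(restore(h2, integer(0))$live, h2$live)
  expect_warning(restore(h2, live_demes(h2)[1]), "already live")

  h50 <- edge_contraction(grid_habitat(10, 10), 0.5)
  back <- restore(h50, setdiff(1:100, live_demes(h50))[1:25])
  expect_equal(sum(back$live), 75)
})

test_that("habitat masks round-trip through CSV and schedules through JSON", {
  h <- random_fragmentation(grid_habitat(8, 12, 25, 0.03), 0.4, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_habitat_csv(h, f)
  h2 <- read_habitat_csv(f, deme_size = 25, migration_rate = 0.03)
  expect_identical(h2$live, h$live)
  expect_equal(h2$rows, 8); expect_equal(h2$cols, 12)

  sch <- gradual_schedule(grid_habitat(10, 10), 0.3, 0.1, 5)
  j <- tempfile(fileext = ".json")
  write_schedule_json(sch, j)
  sch2 <- read_schedule_json(j)
  expect_equal(sch2$events$offset, sch$events$offset)
  expect_identical(sch2$events$demes, sch$events$demes)
  expect_equal(sch2$total_fraction, sch$total_fraction)
})
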