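# The identity-recursion engine: closed forms, oracles, and invariants.

test_that("one step reproduces first-generation coalescence probabilities", {
  h1 <- grid_habitat(1, 1, 100)
  st <- wf_state(h1, u = 0)
  s1 <- wf_step(st, h1)
  expect_equal(s1$F[1, 1], 1 / 200)   # two lineages coalesce w.p. 1/(2N)

  # two isolated demes started fully identical: between-deme identity decays
  # by mutation alone, (1-u)^(2t)
  h2 <- grid_habitat(1, 2, 50, migration_rate = 0)
  u <- 1e-3
  st <- wf_state(h2, u = u, F = matrix(1, 2, 2))
  for (t in 1:25) st <- wf_step(st, h2)
  expect_equal(st$F[1, 2], (1 - u)^(2 * 25), tolerance = 1e-12)
})

test_that("single-deme equilibrium matches the scalar fixed point and 4Nu/(1+4Nu)", {
  N <- 5000
  h <- grid_habitat(1, 1, N)
  # exact scalar fixed point solved independently: F = a(1/(2N) + (1-1/(2N)) F)
  for (u in c(1e-8, 1e-6, 1e-4)) {
    a <- (1 - u)^2
    f_star <- uniroot(function(f) a * (1 / (2 * N) + (1 - 1 / (2 * N)) * f) - f,
                      c(0, 1), tol = 1e-15)$root
    eq <- wf_equilibrium(h, u)
    expect_equal(eq$F[1, 1], f_star, tolerance = 1e-10)
  }
  # the classic approximation H = theta/(1+theta) holds to o(u); at u = 1e-8
  # the discretization error is far below 1e-8
  eq <- wf_equilibrium(h, 1e-8)
  theta <- 4 * N * 1e-8
  expect_lt(abs((1 - eq$F[1, 1]) - theta / (1 + theta)), 1e-8)
  # and at the default model scale: N = 5000, u = 1e-6 -> H ~ 0.0196
  eq <- wf_equilibrium(h, 1e-6)
  expect_lt(abs((1 - eq$F[1, 1]) - 0.0196), 1e-4)
})

test_that("two-deme equilibrium matches an independently derived island model solve", {
  # symmetric 2-deme island model: hand-derived linear system in (Fw, Fb):
  #   Fw' = a [ ((1-m)^2 + m^2) g + 2 m (1-m) Fb ],  g = 1/(2N) + (1-1/(2N)) Fw
  #   Fb' = a [ 2 m (1-m) g + ((1-m)^2 + m^2) Fb ]
  N <- 40; m <- 0.03; u <- 5e-4
  a <- (1 - u)^2
  c1 <- (1 - m)^2 + m^2; c2 <- 2 * m * (1 - m)
  # linear system M x = b for x = (Fw, Fb)
  k <- 1 / (2 * N); r <- 1 - k
  M <- rbind(c(1 - a * c1 * r, -a * c2),
             c(-a * c2 * r, 1 - a * c1))
  b <- c(a * c1 * k, a * c2 * k)
  x <- solve(M, b)
  h <- grid_habitat(1, 2, N, m)
  eq <- wf_equilibrium(h, u)
  expect_equal(eq$F[1, 1], x[1], tolerance = 1e-12)
  expect_equal(eq$F[1, 2], x[2], tolerance = 1e-12)
})

test_that("equilibrium is an exact fixed point and matches long iteration", {
  h <- grid_habitat(3, 3, 50, 0.05)
  eq <- wf_equilibrium(h, 1e-4)
  s1 <- wf_step(eq, h)
  expect_lt(max(abs(s1$F - eq$F)), 1e-10)

  # iterate the recursion from scratch as an independent convergence oracle
  st <- wf_state(h, u = 1e-3)
  B <- migration_matrix(h)
  F <- st$F
  for (t in 1:30000) F <- divloss:::step_F(F, B, st$sizes, 1e-3)
  eq2 <- wf_equilibrium(h, 1e-3)
  expect_lt(max(abs(F - eq2$F)), 1e-8)
})

test_that("well-mixed limit equalizes identities across demes", {
  # at m near 1/2 on a 2-deme chain a lineage's deme is randomized every
  # generation, so within- and between-deme identities coincide
  h <- grid_habitat(1, 2, 50, migration_rate = 0.4999)
  eq <- wf_equilibrium(h, 1e-6)
  expect_lt(diff(range(eq$F)), 1e-6)
  expect_lt(pairwise_fst(eq)$average, 1e-3)
})

test_that("pi summaries implement the stated weighting", {
  h <- grid_habitat(1, 2, 50, 0.01)
  st <- wf_state(h, 1e-6)
  # all H equal h0 -> pi_species = pi_local = h0
  st$F <- matrix(0.8, 2, 2)
  expect_equal(pi_species(st), 0.2)
  expect_equal(pi_local(st), 0.2)
  # H = [[0,1],[1,0]] with equal sizes -> ordered-pair weighted mean 0.5
  st$F <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(pi_species(st), 0.5)
  expect_equal(pi_local(st), 0)
  # weight collapse: sizes (N, 0) -> pi_species = H[1,1]
  st$F <- matrix(c(0.3, 0.9, 0.9, 0.4), 2, 2)
  expect_equal(pi_species(st, sizes = c(50, 0)), 1 - 0.3)
  expect_equal(pi_local(st, sizes = c(50, 0)), 0.7)
})

test_that("model F_ST behaves at the fixed points and decreases with migration", {
  h <- grid_habitat(1, 2, 50, 0.01)
  st <- wf_state(h, 1e-6)
  st$F <- matrix(0.5, 2, 2)           # no differentiation
  expect_equal(pairwise_fst(st)$average, 0)
  st$F <- matrix(c(1, 0.4, 0.4, 1), 2, 2)  # zero within, positive between
  expect_equal(pairwise_fst(st)$average, 1)

  h10 <- grid_habitat(10, 10, 50, 0.01)
  fsts <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(m) {
    h10$migration_rate <- m
    pairwise_fst(wf_equilibrium(h10, 1e-6))$average
  }, 0)
  expect_true(all(diff(fsts) < 0))
})

test_that("apply_loss restricts the state and reweights pi", {
  h <- grid_habitat(2, 2, 50, 0.05)
  eq <- wf_equilibrium(h, 1e-4)
  same <- apply_loss(eq, eq$demes)
  expect_equal(same$F, eq$F)
  one <- apply_loss(eq, eq$demes[2])
  expect_equal(dim(one$F), c(1, 1))
  expect_equal(pi_species(one), 1 - eq$F[2, 2])
  expect_error(apply_loss(eq, integer(0)), "empty")
  expect_error(apply_loss(eq, 99L), "subset")
})

test_that("restoration founds new demes as specified", {
  h <- grid_habitat(1, 3, 50, 0.05)
  eq <- wf_equilibrium(h, 1e-4)
  h2 <- divloss:::remove_demes(h, 3L)
  st <- apply_loss(eq, c(1L, 2L))
  # translocation into a homogeneous landscape leaves F unchanged
  hom <- st; hom$F <- matrix(0.6, 2, 2)
  h3 <- restore(h2, 3L)
  tr <- apply_restore(hom, h3, "translocation")
  expect_equal(max(abs(tr$F - 0.6)), 0, tolerance = 1e-12)

  # from-neighbours founding copies the neighbour block
  fn <- apply_restore(st, h3, "from_neighbors")
  expect_equal(fn$F[3, 1], st$F[2, 1])   # deme 3's only live neighbour is 2
  expect_equal(fn$F[3, 3], st$F[2, 2])

  # restoring immediately after removal keeps pi_species within a few percent
  pi_before <- pi_species(eq)
  expect_lt(abs(pi_species(fn) - pi_before) / pi_before, 0.05)

  # long-run after restoration returns to the original equilibrium
  pr <- wf_propagate(fn, h3, 2000, record_every = 2000, keep_state = TRUE)
  expect_lt(max(abs(pr$state$F - eq$F)), 1e-6)

  # no live neighbour falls back to translocation with a warning
  h1d <- grid_habitat(1, 3, 50, 0.05)
  hgap <- divloss:::remove_demes(h1d, 2:3)
  stg <- apply_loss(eq, 1L)
  expect_warning(apply_restore(stg, restore(hgap, 3L), "from_neighbors"),
                 "translocation")
})

test_that("propagation records trajectories and converges to the solved equilibrium", {
  h <- grid_habitat(2, 3, 30, 0.05)
  eq <- wf_equilibrium(h, 1e-4)
  tr0 <- wf_propagate(eq, h, 0)
  expect_equal(nrow(tr0), 1)

  flat <- wf_propagate(eq, h, 50, record_every = 10)
  expect_lt(diff(range(flat$pi_species)), 1e-9)

  st <- wf_state(h, 1e-4)   # start far from equilibrium
  pr <- wf_propagate(st, h, 12000, record_every = 12000, keep_state = TRUE)
  expect_lt(max(abs(pr$state$F - eq$F)), 1e-8)
})

test_that("identity matrices stay within [0,1] and symmetric along any trajectory", {
  set.seed(42)
  for (rep in 1:5) {
    rows <- sample(1:3, 1); cols <- sample(2:4, 1)
    h <- grid_habitat(rows, cols, sample(c(10, 40, 200), 1),
                      runif(1, 0, 0.9999 / max(4, 1)) * 0.2)
    st <- wf_state(h, 10^runif(1, -6, -2),
                   F = matrix(runif(sum(h$live)^2, 0, 1), sum(h$live)) |>
                     (\(M) (M + t(M)) / 2)())
    for (t in 1:30) {
      st <- wf_step(st, h)
      expect_true(all(st$F >= 0 & st$F <= 1))
      expect_true(isSymmetric(st$F))
    }
  }
})

test_that("migration calibration reaches targets and is monotone", {
  h <- grid_habitat(10, 10, 50, 0.01)
  m9 <- calibrate_migration(h, 1e-6, 0.9)
  expect_equal(attr(m9, "realized_fst"), 0.9, tolerance = 1e-3)
  m3 <- calibrate_migration(h, 1e-6, 0.3)
  m6 <- calibrate_migration(h, 1e-6, 0.6)
  expect_true(m3 > m6 && m6 > m9)
  # unreachable target returns the boundary with a warning
  expect_warning(m0 <- calibrate_migration(h, 1e-6, 0), "boundary")
  expect_equal(as.numeric(m0), 0.9999 / 4, tolerance = 1e-12)
})

test_that("u = 0 equilibrium is refused with guidance", {
  expect_error(wf_equilibrium(grid_habitat(2, 2, 10, 0.1), 0), "transient")
})

test_that("loss ordering across structure: short-term rises, long-term falls with F_ST", {
  short <- long <- numeric(0)
  for (fst in c(0, 0.3, 0.6, 0.9)) {
    v <- contraction_losses_at(calib_m(fst), 0.5)
    short <- c(short, v["short"]); long <- c(long, v["long"])
  }
  expect_true(all(diff(short) > 0))
  expect_true(all(diff(long) < 0))
})
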