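#' Forward multideme Wright-Fisher simulator
#'
#' Stochastic counterpart of the moment engine, tracking allele frequencies
#' at `L` unlinked biallelic sites across demes. Each generation applies, per
#' site: deterministic migration mixing `x <- B x`, symmetric mutation
#' `x <- u + (1 - 2u) x`, then binomial resampling
#' `x' ~ Binom(2 N_k, x) / (2 N_k)` in every deme. Diversity summaries use
#' the distinct-lineage (without replacement) convention so they estimate the
#' same quantities as the moment engine: within a deme the per-site
#' heterozygosity is `2 x (1 - x) * 2N/(2N - 1)`.
#'
#' @param habitat a [grid_habitat()] object (live demes simulate).
#' @param u per-site per-generation mutation rate.
#' @param L number of unlinked sites.
#' @param generations generations to simulate (>= 0).
#' @param seed integer seed; the same seed reproduces the trajectory exactly.
#' @param record_every record diversity every this many generations.
#' @param init initial frequencies: `"beta"` draws each site's frequency from
#'   the single-population stationary Beta(theta, theta) with
#'   `theta = 4 sum(N) u` (shared across demes), `"zero"` starts all sites
#'   absent, or supply a `D x L` matrix.
#' @return a list of class `wf_sim` with elements `state` (list: `x`
#'   frequencies, `demes`, `sizes`, `u`, `generation`, `seed`) and
#'   `trajectory` (a `wf_trajectory` data frame).
#' @export
wf_simulate <- function(habitat, u, L, generations, seed = NULL,
                        record_every = Inf, init = "beta") {
  demes <- live_demes(habitat)
  sizes <- habitat_sizes(habitat)
  if (any(sizes <= 0)) stopf("live demes must have positive size")
  D <- length(demes)
  B <- migration_matrix(habitat)
  with_seed(seed, {
    x <- init_frequencies(init, D, L, sum(sizes), u)
    sim_core(x, B, sizes, u, generations, record_every, demes, seed)
  })
}

init_frequencies <- function(init, D, L, N_tot, u) {
  if (is.matrix(init)) {
    stopifnot(nrow(init) == D, ncol(init) == L)
    return(init)
  }
  switch(init,
    zero = matrix(0, D, L),
    beta = {
      theta <- max(4 * N_tot * u, 1e-8)
      matrix(rep(rbeta(L, theta, theta), each = D), D, L)
    },
    stopf("unknown init '%s'", init))
}

sim_core <- function(x, B, sizes, u, generations, record_every, demes, seed) {
  D <- nrow(x); L <- ncol(x)
  two_n <- 2 * sizes
  rec <- list()
  record <- function(g) {
    s <- sim_diversity(x, sizes)
    rec[[length(rec) + 1L]] <<- c(g, s["pi_species"], s["pi_local"])
  }
  record(0)
  if (generations > 0) {
    for (g in seq_len(generations)) {
      x <- B %*% x
      if (u > 0) x <- u + (1 - 2 * u) * x
      x[] <- rbinom(D * L, rep(two_n, L), pmin(pmax(x, 0), 1)) / rep(two_n, L)
      if (g %% record_every == 0 || g == generations) record(g)
    }
  }
  traj <- as.data.frame(do.call(rbind, rec))
  names(traj) <- c("generation", "pi_species", "pi_local")
  class(traj) <- c("wf_trajectory", "data.frame")
  structure(list(state = list(x = x, demes = demes, sizes = sizes, u = u,
                              generation = generations, seed = seed),
                 trajectory = traj),
            class = "wf_sim")
}

#' @export
print.wf_sim <- function(x, ...) {
  s <- sim_diversity(x$state$x, x$state$sizes)
  cat(sprintf(
    "forward WF simulation: %d demes x %d sites, generation %d\n  pi_species = %.6g, mean pi_local = %.6g\n",
    nrow(x$state$x), ncol(x$state$x), x$state$generation,
    s["pi_species"], s["pi_local"]))
  invisible(x)
}

# pi summaries from a D x L frequency matrix (distinct-lineage convention)
sim_diversity <- function(x, sizes) {
  w <- sizes / sum(sizes)
  two_n <- 2 * sizes
  pbar <- as.vector(t(w) %*% x)              # per-site pooled frequency
  het_pool <- 2 * pbar * (1 - pbar)          # with-replacement pooled pi
  within <- 2 * x * (1 - x)                  # per-deme, with replacement
  corr <- within * (1 / (two_n - 1))         # without-replacement correction
  pi_sp <- mean(het_pool + as.vector(t(w^2) %*% corr))
  pi_loc <- mean(rowMeans(within * (two_n / (two_n - 1))))
  c(pi_species = pi_sp, pi_local = pi_loc)
}

#' Burn a forward simulation in to diversity equilibrium
#'
#' Runs [wf_simulate()] in windows until the window mean of species-wide pi
#' is stable: the relative change between consecutive window means falls
#' below `tol`, or `max_generations` is hit (the returned object is then
#' flagged unstable).
#'
#' @inheritParams wf_simulate
#' @param stability_window generations per stability window.
#' @param tol relative tolerance on consecutive window means.
#' @param max_generations hard cap.
#' @return a `wf_sim` whose `state` carries attributes `stable` (logical)
#'   and `burnin_generations`.
#' @export
wf_burn_in <- function(habitat, u, L, seed = NULL, stability_window = 200L,
                       tol = 0.02, max_generations = 20000L, init = "beta") {
  demes <- live_demes(habitat)
  sizes <- habitat_sizes(habitat)
  B <- migration_matrix(habitat)
  D <- length(demes)
  with_seed(seed, {
    x <- init_frequencies(init, D, L, sum(sizes), u)
    two_n <- 2 * sizes
    prev_mean <- NA_real_
    gen <- 0L
    stable <- FALSE
    while (gen < max_generations) {
      acc <- 0
      for (g in seq_len(stability_window)) {
        x <- B %*% x
        if (u > 0) x <- u + (1 - 2 * u) * x
        x[] <- rbinom(D * L, rep(two_n, L), pmin(pmax(x, 0), 1)) / rep(two_n, L)
        acc <- acc + sim_diversity(x, sizes)["pi_species"]
      }
      gen <- gen + stability_window
      cur_mean <- acc / stability_window
      if (!is.na(prev_mean) &&
          abs(cur_mean - prev_mean) <= tol * max(prev_mean, 1e-12)) {
        stable <- TRUE
        break
      }
      prev_mean <- cur_mean
    }
    out <- sim_core(x, B, sizes, u, 0L, Inf, demes, seed)
    out$state$generation <- gen
    attr(out$state, "stable") <- stable
    attr(out$state, "burnin_generations") <- gen
    if (!stable)
      warnf("burn-in hit the %d-generation cap before stabilising", max_generations)
    out
  })
}

#' Continue a forward simulation, optionally on a reduced habitat
#'
#' @param sim a `wf_sim`.
#' @param habitat habitat for the continuation; its live demes must be a
#'   subset of the simulation's demes (surviving demes keep their current
#'   allele frequencies).
#' @inheritParams wf_simulate
#' @return a `wf_sim`.
#' @export
wf_continue <- function(sim, habitat, generations, seed = NULL,
                        record_every = Inf) {
  demes <- live_demes(habitat)
  idx <- match(demes, sim$state$demes)
  if (anyNA(idx)) stopf("habitat demes must be a subset of the simulation's")
  x <- sim$state$x[idx, , drop = FALSE]
  B <- migration_matrix(habitat)
  with_seed(seed,
    sim_core(x, B, habitat_sizes(habitat), sim$state$u, generations,
             record_every, demes, seed))
}

#' Sample diploid genotypes from a forward simulation
#'
#' Draws `n_per_deme` diploid individuals per live deme; each genotype at
#' each site is Binomial(2, x) in that deme's current frequency. Samples get
#' planar coordinates at their deme's grid centre plus a small seeded jitter
#' (x = column, y = `rows - row + 1`, so north = larger y). Monomorphic
#' sites are retained (unfiltered data avoid ascertainment bias).
#'
#' @param sim a `wf_sim`.
#' @param habitat the habitat the simulation ran on (for coordinates).
#' @param n_per_deme diploids sampled per deme (must not exceed deme size).
#' @param seed sampling seed.
#' @return a [genotype_matrix()] with per-sample deme labels and coordinates.
#' @export
sample_genotypes <- function(sim, habitat, n_per_deme, seed = NULL) {
  x <- sim$state$x
  demes <- sim$state$demes
  if (any(n_per_deme > sim$state$sizes))
    stopf("cannot sample more individuals than a deme holds")
  D <- nrow(x); L <- ncol(x)
  co <- deme_coords(habitat, demes)
  with_seed(seed, {
    G <- matrix(0L, 0, L)
    samples <- list()
    for (i in seq_len(D)) {
      gi <- matrix(rbinom(n_per_deme * L, 2, rep(x[i, ], each = n_per_deme)),
                   n_per_deme, L)
      G <- rbind(G, gi)
      samples[[i]] <- data.frame(
        deme = demes[i],
        x = co$col[i] + runif(n_per_deme, -0.3, 0.3),
        y = (habitat$rows - co$row[i] + 1) + runif(n_per_deme, -0.3, 0.3))
    }
    samp <- do.call(rbind, samples)
    samp$sample_id <- sprintf("d%03d_i%02d", samp$deme,
                              unlist(lapply(seq_len(D), function(i)
                                seq_len(n_per_deme))))
    genotype_matrix(G, coords = samp[, c("sample_id", "x", "y")],
                    groups = samp$deme)
  })
}
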