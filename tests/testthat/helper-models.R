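# shared small models and lazily cached expensive objects

default_grid <- function() grid_habitat(10, 10, 50, 0.01)

# Independent brute-force pi oracle: per site, loop over all ordered
# individual pairs (self-pairs included) and count, at the allele-copy level,
# the fraction of differing copy comparisons (with replacement within an
# individual); normalize by the n(n-1) ordered distinct pairs. This is the
# exact pairwise convention of the dosage estimator: individuals are pools of
# two copies and within-individual comparisons enter the numerator.
brute_pi <- function(G) {
  G <- if (inherits(G, "genotype_matrix")) G$G else G
  n <- nrow(G)
  per_site <- apply(G, 2, function(g) {
    acc <- 0
    for (i in 1:n) for (j in 1:n) {
      ci <- c(g[i] >= 1, g[i] == 2)  # the two copies of i as logicals
      cj <- c(g[j] >= 1, g[j] == 2)
      diffs <- 0
      for (a in 1:2) for (b in 1:2) diffs <- diffs + (ci[a] != cj[b])
      acc <- acc + diffs / 4
    }
    acc / (n * (n - 1))
  })
  mean(per_site)
}

# cache for expensive fixtures, shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small spatially structured genotype dataset used by several files
structured_gm <- function() {
  cached("structured_gm",
         suppressWarnings(make_structured_genotypes(0.3, n_per_deme = 4,
                                                    L = 400, seed = 11)))
}
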