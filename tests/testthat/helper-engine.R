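# Cached default-scale engine objects shared by the heavier tests.
# Default study conditions: 10 x 10 deme grid, 50 diploids per deme
# (total census 5000), u = 1e-6 per lineage per generation.

U_DEFAULT <- 1e-6

default_10x10 <- function() grid_habitat(10, 10, 50, 0.01)

# migration rate calibrated to an average pairwise F_ST on the default grid;
# target 0 returns the weakly structured boundary (largest admissible m)
calib_m <- function(fst) {
  cached(paste0("calib_m_", fst), {
    m <- suppressWarnings(
      calibrate_migration(default_10x10(), U_DEFAULT, fst))
    as.numeric(m)
  })
}

# equilibrium of the default grid at migration rate m
eq_default <- function(m) {
  cached(paste0("eq_default_", signif(m, 10)), {
    h <- default_10x10(); h$migration_rate <- m
    wf_equilibrium(h, U_DEFAULT)
  })
}

# short / long losses after edge contraction at fraction f, migration m
contraction_losses_at <- function(m, f, horizons = c("short", "long")) {
  h <- default_10x10(); h$migration_rate <- m
  res <- divloss:::scenario_losses(h, U_DEFAULT, f, "contraction", 1L,
                                   horizons, NULL, 20000L, "north",
                                   "renormalize")
  setNames(res$losses$loss_species, res$losses$horizon)
}

# random fragmentation ensembles on the weakly structured default model
frag_ensemble_90 <- function() {
  cached("frag_ensemble_90",
         fragmentation_ensemble(n_maps = 50, loss_range = c(0.9, 0.9),
                                seed = 301, horizons = c("short", "long")))
}

frag_ensemble_full <- function() {
  cached("frag_ensemble_full",
         fragmentation_ensemble(n_maps = 40, loss_range = c(0.06, 0.93),
                                seed = 302,
                                horizons = c("short", "mid", "long")))
}
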