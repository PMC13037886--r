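#' The pairwise-identity moment engine for the multideme Wright-Fisher model
#'
#' The engine tracks `F[i, j]`, the probability that two distinct lineages,
#' one sampled from deme `i` and one from deme `j`, are identical in state
#' under an infinite-alleles mutation model. `H = 1 - F` is the expected
#' heterozygosity, the model's per-site nucleotide diversity between demes
#' (`pi_ij`). One generation applies backward migration, within-deme
#' coalescence, and mutation:
#'
#'   `F' = (1 - u)^2 * B G t(B)`,  `G[k, k] = 1/(2 N_k) + (1 - 1/(2 N_k)) F[k, k]`,
#'   `G[k, l] = F[k, l]` for `k != l`,
#'
#' where `B` is the backward migration matrix and `N_k` the diploid deme
#' sizes. Because the recursion is linear in `F`, the equilibrium solves
#' directly and transient dynamics iterate exactly (no Monte Carlo error).
#'
#' @name moments-engine
NULL

new_wf_state <- function(F, demes, sizes, u, generation = 0L,
                         mutation_model = "infinite_alleles") {
  dimnames(F) <- list(demes, demes)
  structure(list(F = F, demes = as.integer(demes),
                 sizes = as.numeric(sizes), u = u,
                 generation = generation,
                 mutation_model = mutation_model),
            class = "wf_state")
}

#' @export
print.wf_state <- function(x, ...) {
  cat(sprintf(
    "wf_state: %d demes, u = %g, generation %d\n  pi_species = %.6g, mean pi_local = %.6g, avg F_ST = %.4g\n",
    length(x$demes), x$u, x$generation, pi_species(x), pi_local(x),
    if (length(x$demes) > 1) pairwise_fst(x)$average else NA_real_))
  invisible(x)
}

#' @export
summary.wf_state <- function(object, ...) {
  H <- 1 - object$F
  out <- list(n_demes = length(object$demes), u = object$u,
              generation = object$generation,
              pi_species = pi_species(object), pi_local = pi_local(object),
              fst = if (length(object$demes) > 1) pairwise_fst(object)$average else NA_real_,
              H_range = range(H))
  class(out) <- "summary.wf_state"
  out
}

#' @export
print.summary.wf_state <- function(x, ...) {
  cat(sprintf(
    "multideme identity state: %d demes, u = %g, generation %d\n", x$n_demes,
    x$u, x$generation))
  cat(sprintf("  pi_species %.6g | mean pi_local %.6g | avg pairwise F_ST %.4g\n",
              x$pi_species, x$pi_local, x$fst))
  cat(sprintf("  H range [%.3g, %.3g]\n", x$H_range[1], x$H_range[2]))
  invisible(x)
}

#' Fresh (all-identical or custom) pair-identity state for a habitat
#'
#' @param habitat a [grid_habitat()] object.
#' @param u per-lineage per-generation mutation rate.
#' @param F optional initial identity matrix over live demes (defaults to
#'   all-zero, i.e. maximal diversity).
#' @param mutation_model `"infinite_alleles"` (identity decays by (1-u)^2
#'   per generation; the default, matching the classic theta/(1+theta)
#'   equilibrium) or `"biallelic"` (two-allele symmetric mutation, exactly
#'   matching the forward simulator's SNP frequencies).
#' @return a `wf_state`.
#' @export
wf_state <- function(habitat, u, F = NULL,
                     mutation_model = c("infinite_alleles", "biallelic")) {
  mutation_model <- match.arg(mutation_model)
  demes <- live_demes(habitat)
  D <- length(demes)
  if (is.null(F)) F <- matrix(0, D, D)
  stopifnot(nrow(F) == D, ncol(F) == D)
  new_wf_state(F, demes, habitat_sizes(habitat), u,
               mutation_model = mutation_model)
}

# One-generation update of the raw identity matrix. B G t(B) is symmetric
# whenever G is, so no per-step symmetrization is needed.
#
# Mutation models: "infinite_alleles" decays identity as (1-u)^2 per pair of
# lineages; "biallelic" is the two-allele symmetric model matching the
# forward simulator, where a pair identical before mutation stays identical
# w.p. (1-u)^2 + u^2 and a discordant pair becomes identical w.p. 2u(1-u),
# giving the affine update F' = 2u(1-u) + (1-2u)^2 * (B G t(B)). The two
# agree to O(theta); the biallelic variant is exact for SNP frequencies.
step_F <- function(F, B, sizes, u, model = "infinite_alleles") {
  G <- F
  diag(G) <- 1 / (2 * sizes) + (1 - 1 / (2 * sizes)) * diag(F)
  if (model == "biallelic") {
    2 * u * (1 - u) + (1 - 2 * u)^2 * (B %*% G %*% t(B))
  } else {
    (1 - u)^2 * (B %*% G %*% t(B))
  }
}

#' Advance the pair-identity state one generation
#'
#' @param state a `wf_state`.
#' @param habitat the habitat providing topology and sizes; its live demes
#'   must match `state$demes` (demes of size 0 must be removed with
#'   [apply_loss()] first).
#' @return the updated `wf_state`.
#' @export
wf_step <- function(state, habitat) {
  check_state_habitat(state, habitat)
  B <- migration_matrix_mode(habitat, attr(state, "migration_mode") %||% "renormalize")
  Fn <- step_F(state$F, B, state$sizes, state$u,
               state$mutation_model %||% "infinite_alleles")
  state$F <- (Fn + t(Fn)) / 2
  state$generation <- state$generation + 1L
  state
}

check_state_habitat <- function(state, habitat) {
  demes <- live_demes(habitat)
  if (!identical(state$demes, demes))
    stopf("state demes do not match the habitat's live demes")
  if (any(habitat_sizes(habitat) <= 0))
    stopf("live demes with size 0 must be removed via apply_loss() first")
  invisible(TRUE)
}

# Direct equilibrium of F = c0 + a B (F + diag((1-diag F)/(2N))) B', with
# (c0, a) = (0, (1-u)^2) for infinite alleles and (2u(1-u), (1-2u)^2) for the
# biallelic model. Unrolling gives
#   F = c0/(1-a) + sum_t a^t B^t D_v B'^t,  D_v = diag((1-v)/(2N)), v = diag(F)
# (the constant term sums exactly because B is row-stochastic, so
# B^t 1 B'^t = 1). In the eigenbasis of B the geometric series sums in
# closed form, leaving a small linear system in v only.
solve_equilibrium_F <- function(B, sizes, u, model = "infinite_alleles") {
  if (model == "biallelic") {
    a <- (1 - 2 * u)^2
    c0 <- 2 * u * (1 - u)
  } else {
    a <- (1 - u)^2
    c0 <- 0
  }
  base <- if (c0 > 0) c0 / (1 - a) else 0
  D <- nrow(B)
  sym <- isSymmetric.matrix(B, tol = 1e-12)
  e <- eigen(B, symmetric = sym)
  lam <- e$values
  Q <- e$vectors
  Qi <- if (sym) t(Q) else solve(Q)
  K <- a * outer(lam, lam)
  if (any(Mod(1 - K) < 1e-14))
    stopf("singular identity system (u = 0?): use the transient mode instead")
  K <- K / (1 - K)
  # T[i, k] = d F[i,i] / d d_k where d_k = (1 - v_k)/(2 N_k)
  Tm <- matrix(0, D, D)
  for (k in 1:D) {
    ck <- Qi[, k]                       # column k of Q^-1
    Y <- Q * rep(ck, each = D)          # Y[i, a] = Q[i, a] * ck[a]
    Tm[, k] <- Re(rowSums((Y %*% K) * Conj(Y)))
  }
  rhs <- base + Tm %*% (1 / (2 * sizes))
  v <- solve(diag(D) + Tm %*% diag(1 / (2 * sizes), D), rhs)
  d <- as.vector((1 - v) / (2 * sizes))
  C <- Qi %*% (d * t(Conj(Qi)))
  F <- base + Re(Q %*% (C * K) %*% t(Conj(Q)))
  (F + t(F)) / 2
}

#' Equilibrium pair-identity state
#'
#' Solves the linear fixed point of the identity recursion directly (no
#' iteration). Requires `u > 0`; with `u = 0` only the degenerate fixed
#' point `F = 1` exists and an error points to the transient mode.
#'
#' @inheritParams wf_state
#' @param mutation_model see [wf_state()].
#' @return a `wf_state` at equilibrium (one further [wf_step()] reproduces it
#'   to numerical tolerance).
#' @export
wf_equilibrium <- function(habitat, u,
                           mutation_model = c("infinite_alleles", "biallelic")) {
  mutation_model <- match.arg(mutation_model)
  if (u <= 0)
    stopf("equilibrium requires u > 0; with u = 0 only F = 1 is stationary: use the transient mode (wf_propagate)")
  if (any(habitat_sizes(habitat) <= 0))
    stopf("live demes must have positive size")
  B <- migration_matrix(habitat)
  F <- solve_equilibrium_F(B, habitat_sizes(habitat), u, mutation_model)
  new_wf_state(F, live_demes(habitat), habitat_sizes(habitat), u,
               mutation_model = mutation_model)
}

#' Diversity summaries of a pair-identity state
#'
#' `pi_species()` is the census-size-weighted average heterozygosity over all
#' ordered deme pairs (within-deme pairs included):
#' `sum_ij w_i w_j H[i, j]` with `w_i = N_i / sum(N)`. `pi_local()` is the
#' unweighted mean of the within-deme heterozygosities `H[i, i]`.
#'
#' @param state a `wf_state`.
#' @param sizes optional per-deme sizes overriding those stored in the state.
#' @return a proportion in `[0, 1]`.
#' @export
pi_species <- function(state, sizes = NULL) {
  N <- sizes %||% state$sizes
  if (sum(N) <= 0) stopf("total census size must be positive")
  w <- N / sum(N)
  as.numeric(t(w) %*% (1 - state$F) %*% w)
}

#' @rdname pi_species
#' @export
pi_local <- function(state, sizes = NULL) {
  N <- sizes %||% state$sizes
  keep <- N > 0
  if (!any(keep)) stopf("no live demes")
  mean(1 - diag(state$F)[keep])
}

#' Hudson-style pairwise F_ST between demes of the model
#'
#' For each unordered deme pair, `F_ST(i, j) = 1 - ((H[i,i] + H[j,j])/2) /
#' H[i,j]` where `H = 1 - F`; pairs with `H[i, j] = 0` but positive
#' within-deme diversity are skipped with a warning.
#'
#' @param state a `wf_state` with at least two demes.
#' @return a list with the pairwise `matrix` and the `average` over pairs.
#' @export
pairwise_fst <- function(state) {
  H <- 1 - state$F
  D <- nrow(H)
  if (D < 2) stopf("pairwise F_ST needs at least two demes")
  Hw <- outer(diag(H), diag(H), "+") / 2
  M <- matrix(NA_real_, D, D, dimnames = dimnames(state$F))
  ok <- H > 0
  M[ok] <- 1 - Hw[ok] / H[ok]
  zero_between <- !ok & Hw > 0
  if (any(zero_between[upper.tri(zero_between)]))
    warnf("deme pairs with zero between-deme diversity skipped in F_ST")
  M[!ok & Hw == 0] <- 0
  diag(M) <- 0
  vals <- M[upper.tri(M)]
  list(matrix = M, average = mean(vals, na.rm = TRUE))
}

#' Restrict the state to surviving demes after habitat loss
#'
#' The surviving submatrix of `F` becomes the initial condition of the
#' reduced system. The caller rebuilds migration from the reduced habitat;
#' under the default `"renormalize"` mode ([migration_matrix()]) migration
#' mass pointing at destroyed demes returns to the source deme. Mode
#' `"absorb"` instead redistributes each row proportionally over survivors.
#'
#' @param state a `wf_state`.
#' @param survivors deme ids to keep (non-empty subset of `state$demes`).
#' @param mode how destroyed-deme migration mass is handled when the engine
#'   later rebuilds `B`; stored as an attribute consumed by
#'   [wf_propagate()] and [wf_forecast()].
#' @return the restricted `wf_state`.
#' @export
apply_loss <- function(state, survivors, mode = c("renormalize", "absorb")) {
  mode <- match.arg(mode)
  if (length(survivors) == 0) stopf("survivor set is empty")
  idx <- match(survivors, state$demes)
  if (anyNA(idx)) stopf("survivors must be a subset of the state's demes")
  idx <- sort(idx)
  out <- new_wf_state(state$F[idx, idx, drop = FALSE], state$demes[idx],
                      state$sizes[idx], state$u, state$generation,
                      state$mutation_model %||% "infinite_alleles")
  attr(out, "migration_mode") <- mode
  out
}

# Backward migration under the requested destroyed-mass handling.
migration_matrix_mode <- function(habitat, mode = "renormalize") {
  if (identical(mode, "absorb")) {
    ids <- live_demes(habitat)
    co <- deme_coords(habitat, ids)
    m <- habitat$migration_rate
    # degree each live deme had on the full grid
    full_deg <- (co$row > 1) + (co$row < habitat$rows) +
      (co$col > 1) + (co$col < habitat$cols)
    A <- grid_adjacency(habitat, ids)
    B <- m * A
    diag(B) <- 1 - m * full_deg
    B / rowSums(B)
  } else {
    migration_matrix(habitat)
  }
}

#' Re-found restored demes in the pair-identity state
#'
#' `"from_neighbors"` founds each restored deme from its live neighbours:
#' its identity rows (and its own within-deme identity) are the
#' neighbour-average, i.e. founders are a random sample of neighbour
#' lineages. `"translocation"` founds it from the whole landscape, using the
#' census-size-weighted average instead. Restored demes with no live
#' neighbour fall back to translocation with a warning.
#'
#' @param state a `wf_state` (post-loss).
#' @param habitat the habitat after [restore()]: its live demes are the
#'   union of the state's demes and the restored demes.
#' @param founding founding mode.
#' @return a `wf_state` over all live demes of `habitat`.
#' @export
apply_restore <- function(state, habitat,
                          founding = c("from_neighbors", "translocation")) {
  founding <- match.arg(founding)
  all_demes <- live_demes(habitat)
  new_idx <- which(!(all_demes %in% state$demes))
  if (length(new_idx) == 0) return(state)
  if (any(!(state$demes %in% all_demes)))
    stopf("habitat is missing demes present in the state")
  D_old <- length(state$demes)
  W <- matrix(0, length(all_demes), D_old)
  old_pos <- match(state$demes, all_demes)
  W[cbind(old_pos, seq_len(D_old))] <- 1
  w_land <- state$sizes / sum(state$sizes)
  A <- grid_adjacency(habitat, all_demes)
  for (r in new_idx) {
    if (founding == "from_neighbors") {
      nb <- which(A[r, ] == 1 & all_demes %in% state$demes)
      if (length(nb)) {
        W[r, match(all_demes[nb], state$demes)] <- 1 / length(nb)
        next
      }
      warnf("restored deme %d has no live neighbour: using translocation",
            all_demes[r])
    }
    W[r, ] <- w_land
  }
  F_new <- W %*% state$F %*% t(W)
  new_wf_state((F_new + t(F_new)) / 2, all_demes,
               habitat$sizes[all_demes], state$u, state$generation,
               state$mutation_model %||% "infinite_alleles")
}

#' Propagate the state forward and record a diversity trajectory
#'
#' Iterates [wf_step()] for `generations` generations, recording
#' `pi_species` and mean `pi_local` every `record_every` generations
#' (generation 0 is always recorded).
#'
#' @inheritParams wf_step
#' @param generations number of generations (>= 0).
#' @param record_every recording interval.
#' @param keep_state return the final state as well.
#' @return a data frame of class `wf_trajectory` with columns `generation`,
#'   `pi_species`, `pi_local`; if `keep_state`, a list with elements
#'   `trajectory` and `state`.
#' @export
wf_propagate <- function(state, habitat, generations, record_every = 1,
                         keep_state = FALSE) {
  check_state_habitat(state, habitat)
  mode <- attr(state, "migration_mode") %||% "renormalize"
  B <- migration_matrix_mode(habitat, mode)
  sizes <- state$sizes
  u <- state$u
  model <- state$mutation_model %||% "infinite_alleles"
  F <- state$F
  gen0 <- state$generation
  rec_gens <- unique(c(0, if (generations >= record_every)
    seq(record_every, generations, by = record_every), generations))
  rec_gens <- rec_gens[rec_gens <= generations]
  out <- matrix(NA_real_, length(rec_gens), 3)
  w <- sizes / sum(sizes)
  r <- 1L
  for (g in 0:generations) {
    if (g == rec_gens[r]) {
      out[r, ] <- c(gen0 + g,
                    as.numeric(t(w) %*% (1 - F) %*% w),
                    mean(1 - diag(F)))
      if (r < length(rec_gens)) r <- r + 1L
    }
    if (g < generations) F <- step_F(F, B, sizes, u, model)
  }
  F <- (F + t(F)) / 2
  traj <- data.frame(generation = out[, 1], pi_species = out[, 2],
                     pi_local = out[, 3])
  class(traj) <- c("wf_trajectory", "data.frame")
  if (!keep_state) return(traj)
  st <- new_wf_state(F, state$demes, sizes, u, gen0 + generations, model)
  attr(st, "migration_mode") <- mode
  list(trajectory = traj, state = st)
}

#' @export
plot.wf_trajectory <- function(x, which = c("pi_species", "pi_local"), ...) {
  which <- match.arg(which)
  graphics::plot(x$generation, x[[which]], type = "l", xlab = "generation",
                 ylab = which, ...)
  invisible(x)
}

#' Calibrate the migration rate to a target average pairwise F_ST
#'
#' Bisection on `log(m)` using the equilibrium state's [pairwise_fst()];
#' average F_ST is monotone decreasing in `m`. If the target lies outside
#' what the topology allows (the maximum `m` keeps `m * degree < 1`), the
#' boundary value is returned with a warning.
#'
#' @inheritParams wf_equilibrium
#' @param target_fst desired average pairwise F_ST in `[0, 1)`.
#' @param tol calibration tolerance on F_ST.
#' @param m_range search interval for `m` (upper end defaults to just below
#'   the topology's limit).
#' @param mutation_model mutation model for the equilibrium solves (see
#'   [wf_state()]); calibrate under `"biallelic"` when the target is to be
#'   realized by SNP data from the forward simulator.
#' @return the calibrated migration rate, with attribute `"realized_fst"`.
#' @export
calibrate_migration <- function(habitat, u, target_fst, tol = 1e-3,
                                m_range = NULL,
                                mutation_model = "infinite_alleles") {
  if (target_fst < 0 || target_fst >= 1) stopf("target_fst must be in [0, 1)")
  deg <- max_degree(habitat$rows, habitat$cols)
  if (is.null(m_range)) m_range <- c(1e-10, 0.9999 / deg)
  fst_at <- function(m) {
    h <- habitat; h$migration_rate <- m
    pairwise_fst(wf_equilibrium(h, u, mutation_model))$average
  }
  lo <- log(m_range[1]); hi <- log(m_range[2])
  f_hi <- fst_at(exp(hi))
  if (f_hi >= target_fst - tol) {
    if (f_hi > target_fst + tol)
      warnf("target F_ST %.3g below the minimum %.3g reachable at m = %.4g; returning boundary",
            target_fst, f_hi, exp(hi))
    out <- exp(hi)
    attr(out, "realized_fst") <- f_hi
    return(out)
  }
  f_lo <- fst_at(exp(lo))
  if (f_lo < target_fst - tol) {
    warnf("target F_ST %.3g above the maximum %.3g reachable at m = %.4g; returning boundary",
          target_fst, f_lo, exp(lo))
    out <- exp(lo)
    attr(out, "realized_fst") <- f_lo
    return(out)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f_mid <- fst_at(exp(mid))
    if (abs(f_mid - target_fst) <= tol) break
    if (f_mid > target_fst) lo <- mid else hi <- mid
  }
  out <- exp(mid)
  attr(out, "realized_fst") <- f_mid
  out
}
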