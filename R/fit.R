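#' Fit the moment engine to an observed diversity trajectory
#'
#' Least-squares fit of the engine's species-wide pi trajectory to observed
#' values, over three free parameters: the mutation rate `u`, the migration
#' rate `m` between adjacent demes, and a time scaling converting observed
#' time units into model generations. Deme sizes (the effective population
#' size) are held fixed at the habitat's sizes. The model trajectory starts
#' at the pre-loss equilibrium; if `survivors` is given, the corresponding
#' habitat loss is applied at time 0 and the transient compared to the
#' observations. Optimization is derivative-free (Nelder-Mead on the log
#' parameters).
#'
#' @param observed data frame with columns `generation` and `pi_species`
#'   (at least 3 timepoints), e.g. a `wf_trajectory` from [wf_simulate()].
#' @param habitat the pre-loss model habitat (sizes = fixed N_e per deme).
#' @param survivors live deme ids after loss; `NULL` fits an undisturbed
#'   (equilibrium) trajectory.
#' @param start named starting values for `u`, `m`, `time_scale`.
#' @param mutation_model engine mutation model (see [wf_state()]); use
#'   `"biallelic"` when the observations are SNP-frequency diversities such
#'   as [wf_simulate()] output.
#' @param control passed to [stats::optim()].
#' @return an object of class `wf_fit`: fitted `u`, `m`, `time_scale`,
#'   residual sum of squares, and a convergence flag (non-convergence
#'   returns the best point found, flagged).
#' @export
fit_to_trajectory <- function(observed, habitat, survivors = NULL,
                              start = c(u = 1e-5, m = 0.05, time_scale = 1),
                              mutation_model = c("infinite_alleles", "biallelic"),
                              control = list(maxit = 400)) {
  mutation_model <- match.arg(mutation_model)
  if (!all(c("generation", "pi_species") %in% names(observed)))
    stopf("observed needs columns 'generation' and 'pi_species'")
  observed <- observed[is.finite(observed$pi_species), ]
  if (nrow(observed) < 3) stopf("need at least 3 observed timepoints")
  gens <- observed$generation - min(observed$generation)
  target <- observed$pi_species
  model_pi <- function(u, m, ts) {
    h <- habitat; h$migration_rate <- m
    eq <- tryCatch(wf_equilibrium(h, u, mutation_model),
                   error = function(e) NULL)
    if (is.null(eq)) return(rep(NA_real_, length(gens)))
    if (is.null(survivors)) {
      return(rep(pi_species(eq), length(gens)))
    }
    tg <- gens * ts
    h2 <- h; h2$live[] <- FALSE; h2$live[survivors] <- TRUE
    h2$sizes[!h2$live] <- 0
    st <- apply_loss(eq, survivors)
    tr <- wf_propagate(st, h2, ceiling(max(tg)) + 1L, record_every = 1)
    # linear interpolation keeps the objective smooth in the time scaling
    stats::approx(tr$generation, tr$pi_species, xout = tg, rule = 2)$y
  }
  obj <- function(p) {
    u <- exp(p[1]); m <- exp(p[2]); ts <- exp(p[3])
    deg <- max_degree(habitat$rows, habitat$cols)
    if (m * deg >= 1) return(1e6)
    # keep the propagation horizon bounded while the simplex explores
    if (ts > 20 || ts < 0.05) return(1e6)
    pred <- model_pi(u, m, ts)
    if (anyNA(pred)) return(1e6)
    sum((pred - target)^2)
  }
  ctrl <- utils::modifyList(list(maxit = 400, reltol = 1e-12), control)
  p0 <- log(unname(start[c("u", "m", "time_scale")]))
  # restart the simplex until it reports convergence: a fresh simplex
  # escapes the narrow valley left by the weakly identified migration rate
  opt <- optim(p0, obj, method = "Nelder-Mead", control = ctrl)
  restarts <- 0L
  while (opt$convergence != 0 && restarts < 4L) {
    opt <- optim(opt$par, obj, method = "Nelder-Mead", control = ctrl)
    restarts <- restarts + 1L
  }
  out <- list(u = exp(opt$par[1]), m = exp(opt$par[2]),
              time_scale = exp(opt$par[3]), residual = opt$value,
              converged = opt$convergence == 0, n_obs = nrow(observed))
  if (!out$converged)
    warnf("trajectory fit did not converge; returning best point found")
  class(out) <- "wf_fit"
  out
}

#' @export
print.wf_fit <- function(x, ...) {
  cat(sprintf(
    "moment-engine trajectory fit (%d points)%s\n  u = %.4g, m = %.4g, time_scale = %.4g, RSS = %.4g\n",
    x$n_obs, if (x$converged) "" else " [not converged]",
    x$u, x$m, x$time_scale, x$residual))
  invisible(x)
}

#' @export
coef.wf_fit <- function(object, ...) {
  c(u = object$u, m = object$m, time_scale = object$time_scale)
}
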