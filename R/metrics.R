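#' Genotype matrices with sample coordinates
#'
#' Container for an `n x L` biallelic diploid dosage matrix (entries 0/1/2 =
#' copies of the alternate allele) with per-sample planar coordinates and
#' optional group (deme/population) labels. Missing genotypes are refused:
#' filtering or imputation is a documented pre-processing step so the
#' estimators stay exact.
#'
#' @param G integer matrix, entries in `{0, 1, 2}`, no missing values.
#' @param coords data frame with columns `sample_id`, `x`, `y` (one row per
#'   sample) or `NULL`.
#' @param groups optional per-sample group labels.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, coords = NULL, groups = NULL) {
  G <- as.matrix(G)
  if (anyNA(G)) stopf("genotype matrix contains missing values; filter or impute first")
  if (!all(G %in% 0:2)) stopf("genotypes must be dosages in {0, 1, 2}")
  if (ncol(G) < 1) stopf("need at least one site")
  storage.mode(G) <- "integer"
  if (!is.null(coords)) {
    stopifnot(all(c("sample_id", "x", "y") %in% names(coords)),
              nrow(coords) == nrow(G))
    if (any(!is.finite(coords$x)) || any(!is.finite(coords$y)))
      stopf("sample coordinates must be finite")
    rownames(G) <- coords$sample_id
  }
  if (!is.null(groups)) stopifnot(length(groups) == nrow(G))
  structure(list(G = G, coords = coords, groups = groups),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites, %d segregating, pi = %.5g\n",
              nrow(x$G), ncol(x$G), segregating_sites(x),
              if (nrow(x$G) >= 2) nucleotide_diversity(x) else NA_real_))
  invisible(x)
}

as_dosage <- function(G) {
  if (inherits(G, "genotype_matrix")) G$G else as.matrix(G)
}

#' Nucleotide diversity of a genotype matrix
#'
#' The estimator `pi = (n/(n - 1)) (1/L) sum_i 2 p_i (1 - p_i)`, where `n`
#' is the number of individuals, `L` the number of sites and `p_i` the
#' alternate-allele frequency (mean dosage / 2) at site `i`. Individuals are
#' treated as pools of two allele copies; the `n/(n-1)` factor makes the
#' estimator the expected difference probability between two allele copies
#' drawn without replacement (up to the within-individual pairing
#' convention, which the brute-force oracle in the tests pins down).
#'
#' @param G a [genotype_matrix()] or a plain dosage matrix.
#' @return pi per site (unitless proportion).
#' @export
nucleotide_diversity <- function(G) {
  G <- as_dosage(G)
  n <- nrow(G)
  if (n < 2) stopf("nucleotide diversity is undefined for fewer than 2 individuals")
  p <- colMeans(G) / 2
  (n / (n - 1)) * mean(2 * p * (1 - p))
}

#' Number of segregating sites
#'
#' @inheritParams nucleotide_diversity
#' @return count of sites with allele frequency strictly between 0 and 1.
#' @export
segregating_sites <- function(G) {
  G <- as_dosage(G)
  p <- colMeans(G) / 2
  sum(p > 0 & p < 1)
}

#' Grid-local nucleotide diversity
#'
#' Overlays an equal-cell grid on the samples' coordinate bounding box and
#' computes [nucleotide_diversity()] within each cell holding at least two
#' individuals; cells with fewer are excluded. The summary is the unweighted
#' mean over included cells.
#'
#' @inheritParams nucleotide_diversity
#' @param coords data frame (`sample_id`, `x`, `y`); defaults to the
#'   object's coordinates.
#' @param rows,cols grid dimensions.
#' @return a list: `mean` (mean pi_local), `cells` (data frame of per-cell
#'   pi and sample counts).
#' @export
pi_local_grid <- function(G, coords = NULL, rows = 10, cols = 10) {
  gm <- if (inherits(G, "genotype_matrix")) G else genotype_matrix(G, coords)
  coords <- coords %||% gm$coords
  if (is.null(coords)) stopf("sample coordinates are required")
  cells <- assign_grid(coords, rows, cols)
  G <- as_dosage(gm)
  per_cell <- lapply(split(seq_len(nrow(G)), cells$cell), function(idx) {
    if (length(idx) < 2) return(NULL)
    data.frame(cell = cells$cell[idx[1]], n = length(idx),
               pi = nucleotide_diversity(G[idx, , drop = FALSE]))
  })
  per_cell <- do.call(rbind, per_cell)
  if (is.null(per_cell) || !nrow(per_cell))
    stopf("no grid cell holds at least two individuals")
  list(mean = mean(per_cell$pi), cells = per_cell)
}

#' Hudson-style F_ST between groups of a genotype matrix
#'
#' For each group pair, `F_ST = 1 - mean(pi_1, pi_2) / pi_between`, where the
#' within-group `pi` values come from [nucleotide_diversity()] and
#' `pi_between` is the mean per-site difference probability between one
#' allele copy from each group, `p_1 (1 - p_2) + p_2 (1 - p_1)` averaged over
#' sites. Negative values are clipped at 0.
#'
#' @inheritParams nucleotide_diversity
#' @param groups per-sample group labels (>= 2 groups with >= 2 samples each);
#'   defaults to the object's labels.
#' @return list with the pairwise `matrix` and the `average` over pairs.
#' @export
hudson_fst <- function(G, groups = NULL) {
  gm_groups <- if (inherits(G, "genotype_matrix")) G$groups else NULL
  groups <- groups %||% gm_groups
  G <- as_dosage(G)
  if (is.null(groups)) stopf("group labels are required")
  tab <- table(groups)
  keep <- names(tab)[tab >= 2]
  if (length(keep) < 2) stopf("need at least two groups with two or more samples")
  gl <- keep
  p <- sapply(gl, function(g) colMeans(G[groups == g, , drop = FALSE]) / 2)
  pw <- sapply(gl, function(g)
    nucleotide_diversity(G[groups == g, , drop = FALSE]))
  K <- length(gl)
  M <- matrix(NA_real_, K, K, dimnames = list(gl, gl))
  diag(M) <- 0
  for (i in 1:(K - 1)) for (j in (i + 1):K) {
    between <- mean(p[, i] * (1 - p[, j]) + p[, j] * (1 - p[, i]))
    fst <- if (between > 0) 1 - mean(c(pw[i], pw[j])) / between else 0
    M[i, j] <- M[j, i] <- max(0, fst)
  }
  list(matrix = M, average = mean(M[upper.tri(M)]))
}
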