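#' Label habitat patches in a binary grid
#'
#' Connected components of habitat cells under rook (4-neighbour) adjacency,
#' labelled deterministically in row-major scan order (the patch containing
#' the first habitat cell encountered is patch 1, and so on).
#'
#' @param grid binary matrix (1 = habitat, 0 = lost); an all-zero grid has
#'   zero patches.
#' @return integer matrix of patch labels (0 for non-habitat).
#' @export
label_patches <- function(grid) {
  grid <- as.matrix(grid)
  R <- nrow(grid); C <- ncol(grid)
  lab <- matrix(0L, R, C)
  next_lab <- 0L
  for (r in seq_len(R)) for (c in seq_len(C)) {
    if (grid[r, c] != 0 && lab[r, c] == 0L) {
      next_lab <- next_lab + 1L
      # flood fill
      stack <- matrix(c(r, c), 1)
      lab[r, c] <- next_lab
      while (nrow(stack)) {
        cur <- stack[nrow(stack), ]
        stack <- stack[-nrow(stack), , drop = FALSE]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- cur[1] + d[1]; cc <- cur[2] + d[2]
          if (rr >= 1 && rr <= R && cc >= 1 && cc <= C &&
              grid[rr, cc] != 0 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- next_lab
            stack <- rbind(stack, c(rr, cc))
          }
        }
      }
    }
  }
  lab
}

#' Fragmentation metrics of a binary habitat grid
#'
#' FRAGSTATS-style summaries: number of patches and patch density (patches
#' per grid cell); total perimeter, counting every cell face between habitat
#' and non-habitat or the map boundary, and edge density (perimeter per
#' cell); total core area (habitat cells whose four neighbours are all
#' habitat); and patch cohesion,
#' `100 * (1 - sum(p_i) / sum(p_i sqrt(a_i))) / (1 - 1/sqrt(Z))`, with
#' `p_i`/`a_i` the per-patch perimeter and cell count and `Z` the landscape
#' cell count -- the "spatial connectedness" metric. A CONNECT-style
#' alternative (percentage of habitat-cell pairs within a threshold
#' centre-to-centre distance) is available via [connectedness()].
#'
#' @inheritParams label_patches
#' @return a list of class `landscape_summary`: `n_patches`,
#'   `patch_density`, `total_perimeter`, `edge_density`, `total_core_area`,
#'   `cohesion`.
#' @export
landscape_summary <- function(grid) {
  grid <- as.matrix(grid)
  if (sum(grid) == 0) stopf("empty grid: no habitat cells")
  R <- nrow(grid); C <- ncol(grid)
  lab <- label_patches(grid)
  n_patches <- max(lab)
  pad <- matrix(0L, R + 2, C + 2)
  pad[2:(R + 1), 2:(C + 1)] <- grid
  core <- pad[2:(R + 1), 2:(C + 1)] == 1 &
    pad[1:R, 2:(C + 1)] == 1 & pad[3:(R + 2), 2:(C + 1)] == 1 &
    pad[2:(R + 1), 1:C] == 1 & pad[2:(R + 1), 3:(C + 2)] == 1
  per_cell_perim <- function(mask) {
    p <- matrix(0L, R + 2, C + 2)
    p[2:(R + 1), 2:(C + 1)] <- mask
    (p[2:(R + 1), 2:(C + 1)] == 1) *
      ((p[1:R, 2:(C + 1)] == 0) + (p[3:(R + 2), 2:(C + 1)] == 0) +
       (p[2:(R + 1), 1:C] == 0) + (p[2:(R + 1), 3:(C + 2)] == 0))
  }
  perim_all <- per_cell_perim(grid)
  total_perimeter <- sum(perim_all)
  # per-patch perimeter and area for cohesion
  pi_perim <- vapply(seq_len(n_patches), function(k) sum(perim_all[lab == k]), 0)
  ai <- vapply(seq_len(n_patches), function(k) sum(lab == k), 0)
  Z <- R * C
  cohesion <- if (Z > 1) {
    100 * (1 - sum(pi_perim) / sum(pi_perim * sqrt(ai))) / (1 - 1 / sqrt(Z))
  } else 0
  structure(list(n_patches = n_patches,
                 patch_density = n_patches / Z,
                 total_perimeter = total_perimeter,
                 edge_density = total_perimeter / Z,
                 total_core_area = sum(core),
                 cohesion = cohesion),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf(
    "landscape: %d patches (density %.3g), perimeter %d (edge density %.3g), core %d, cohesion %.2f\n",
    x$n_patches, x$patch_density, x$total_perimeter, x$edge_density,
    x$total_core_area, x$cohesion))
  invisible(x)
}

#' CONNECT-style connectedness
#'
#' Percentage of all habitat-cell pairs whose centre-to-centre distance is
#' within `threshold` cells.
#'
#' @inheritParams label_patches
#' @param threshold joining distance in cell units.
#' @return percentage in `[0, 100]`.
#' @export
connectedness <- function(grid, threshold = 2) {
  grid <- as.matrix(grid)
  idx <- which(grid == 1, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2) return(0)
  d <- as.matrix(dist(idx))
  100 * mean(d[upper.tri(d)] <= threshold)
}

#' Ordinary least-squares regression of a response on one landscape metric
#'
#' @param metric_values numeric predictor (>= 3 values, non-constant).
#' @param responses numeric response of equal length.
#' @return a list: `slope`, `intercept`, `r_squared`, `p_value` (t-test on
#'   the slope).
#' @export
metric_regression <- function(metric_values, responses) {
  ok <- is.finite(metric_values) & is.finite(responses)
  x <- metric_values[ok]; y <- responses[ok]
  if (length(x) < 3) stopf("need at least 3 paired observations")
  if (var(x) == 0) stopf("zero-variance predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]))
}

#' The live-cell mask of a habitat as a binary matrix
#'
#' @inheritParams live_demes
#' @return a `rows x cols` 0/1 matrix (row 1 = north).
#' @export
habitat_mask <- function(habitat) {
  matrix(as.integer(habitat$live), nrow = habitat$rows, ncol = habitat$cols,
         byrow = TRUE)
}
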