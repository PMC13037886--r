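#' Assign geo-referenced samples to an equal-cell grid
#'
#' Cells tile the coordinate bounding box; intervals are half-open
#' `[lo, hi)` with the maximum edge closed, so every sample falls in exactly
#' one cell. Habitat cells are the cells containing at least one sample.
#' Cell rows follow decreasing `y` (row 1 is the northernmost band).
#'
#' @param coords data frame with columns `x`, `y`.
#' @param rows,cols grid dimensions.
#' @return a list: `cell` (per-sample cell id string "r_c"), `habitat`
#'   (data frame of occupied cells with centre coordinates and counts).
#' @export
assign_grid <- function(coords, rows = 10, cols = 10) {
  if (!nrow(coords)) stopf("need at least one sample")
  rx <- range(coords$x); ry <- range(coords$y)
  if (diff(rx) == 0 && diff(ry) == 0 && nrow(coords) > 1)
    warnf("all samples share one location: a single habitat cell")
  bin <- function(v, lo, hi, k) {
    if (hi == lo) return(rep(1L, length(v)))
    i <- floor((v - lo) / (hi - lo) * k) + 1L
    pmin(i, k)  # close the max edge
  }
  cx <- bin(coords$x, rx[1], rx[2], cols)
  iy <- bin(coords$y, ry[1], ry[2], rows)
  cr <- rows - iy + 1L   # row 1 = largest y (north)
  cell <- sprintf("%d_%d", cr, cx)
  wx <- if (diff(rx) > 0) diff(rx) / cols else 1
  wy <- if (diff(ry) > 0) diff(ry) / rows else 1
  occ <- unique(data.frame(row = cr, col = cx))
  occ <- occ[order(occ$row, occ$col), , drop = FALSE]
  occ$cell <- sprintf("%d_%d", occ$row, occ$col)
  occ$cx <- rx[1] + (occ$col - 0.5) * wx
  occ$cy <- ry[1] + (rows - occ$row + 0.5) * wy
  occ$n <- as.integer(table(cell)[occ$cell])
  list(cell = cell, habitat = occ)
}

#' In-silico extinction on a geo-referenced genotype matrix
#'
#' Overlays a grid on the sample map, then removes occupied (habitat) cells
#' one at a time -- individuals in removed cells go extinct -- recomputing
#' nucleotide diversity and segregating sites on the survivors after each
#' removal, until fewer than two individuals remain. Area loss is the number
#' of removed habitat cells over the total number of habitat cells.
#'
#' Schemes: `"random"` removes cells in a seeded random order (one
#' permutation per replicate); `"south_north"` removes cells north to south
#' -- decreasing centre `y`, ties west to east -- mimicking a climate-driven
#' extinction front (deterministic, so replicates differ only through SNP
#' subsampling).
#'
#' @param G a [genotype_matrix()] (or dosage matrix plus `coords`).
#' @param coords data frame (`sample_id`, `x`, `y`); defaults to the
#'   object's coordinates.
#' @param scheme extinction scheme.
#' @param rows,cols map grid dimensions.
#' @param replicates number of replicates.
#' @param max_snps subsample at most this many sites (seeded) per replicate.
#' @param seed base seed.
#' @return a list of `loss_curve` data frames, one per replicate, with
#'   columns `step`, `a_lost`, `pi`, `s`, `n` and attributes `scheme`,
#'   `seed`; `a_lost = 0` rows hold the full-sample statistics.
#' @export
run_extinction <- function(G, coords = NULL,
                           scheme = c("random", "south_north"),
                           rows = 10, cols = 10, replicates = 20,
                           max_snps = 10000, seed = 1L) {
  scheme <- match.arg(scheme)
  gm <- if (inherits(G, "genotype_matrix")) G else genotype_matrix(G, coords)
  coords <- coords %||% gm$coords
  if (is.null(coords)) stopf("coordinates are required")
  Gd <- as_dosage(gm)
  grid <- assign_grid(coords, rows, cols)
  occ <- grid$habitat
  n_cells <- nrow(occ)
  if (n_cells < 2) warnf("fewer than 2 habitat cells: loss curve is trivial")
  lapply(seq_len(replicates), function(r) {
    rs <- child_seed(seed, r)
    with_seed(rs, {
      sites <- if (ncol(Gd) > max_snps) sort(sample(ncol(Gd), max_snps))
               else seq_len(ncol(Gd))
      Gs <- Gd[, sites, drop = FALSE]
      order_idx <- switch(scheme,
        random = sample(n_cells),
        south_north = order(-occ$cy, occ$cx))
      alive <- rep(TRUE, nrow(Gs))
      out <- list(curve_point(0L, 0, Gs, alive))
      for (k in seq_len(n_cells)) {
        gone_cell <- occ$cell[order_idx[k]]
        alive[grid$cell == gone_cell] <- FALSE
        if (sum(alive) < 2) break
        out[[length(out) + 1L]] <- curve_point(k, k / n_cells, Gs, alive)
      }
      cur <- do.call(rbind, out)
      attr(cur, "scheme") <- scheme
      attr(cur, "seed") <- rs
      class(cur) <- c("loss_curve", "data.frame")
      cur
    })
  })
}

curve_point <- function(step, a_lost, G, alive) {
  sub <- G[alive, , drop = FALSE]
  data.frame(step = step, a_lost = a_lost,
             pi = nucleotide_diversity(sub),
             s = segregating_sites(sub),
             n = nrow(sub))
}

#' Write extinction loss curves to CSV
#'
#' One row per curve point with the scheme and replicate seed attached.
#' @param curves list of `loss_curve` data frames from [run_extinction()].
#' @param path CSV path.
#' @export
write_loss_curves <- function(curves, path) {
  rows <- lapply(seq_along(curves), function(i) {
    cu <- curves[[i]]
    data.frame(replicate = i, scheme = attr(cu, "scheme"),
               seed = attr(cu, "seed"), as.data.frame(cu))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
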