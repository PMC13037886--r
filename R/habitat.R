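#' Deme-grid habitats and habitat-change scenarios
#'
#' A `habitat` represents a species range as a rectangular grid of demes
#' (locally panmictic subpopulations) with rook (4-neighbour) adjacency and a
#' single per-edge migration rate. Habitat loss removes demes; restoration
#' re-adds them. Demes are indexed row-major, row 1 being the northern edge,
#' so deme `(r, c)` has id `(r - 1) * cols + c`.
#'
#' @param rows,cols grid dimensions (at least 1; `rows = 1` gives a 1-D chain).
#' @param deme_size diploid census size per deme (individuals).
#' @param migration_rate per-generation probability `m` that a lineage's
#'   parent came from one given adjacent deme. The total emigration
#'   probability `m * degree` must stay below 1, so `m < 1/4` on a 2-D grid.
#'
#' @return An object of class `habitat`: grid dimensions, the logical vector
#'   of live demes, per-deme census sizes, and the migration rate.
#' @examples
#' h <- grid_habitat(10, 10, deme_size = 50, migration_rate = 0.01)
#' sum(habitat_sizes(h))      # total census 5000
#' h2 <- edge_contraction(h, 0.5, edge = "north")
#' @export
grid_habitat <- function(rows, cols, deme_size = 50, migration_rate = 0.01) {
  if (length(rows) != 1 || length(cols) != 1 || rows < 1 || cols < 1)
    stopf("grid dimensions must be positive integers")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (deme_size < 0) stopf("deme_size must be non-negative")
  max_deg <- max_degree(rows, cols)
  if (migration_rate < 0 || migration_rate * max_deg >= 1)
    stopf("invalid migration rate: need 0 <= m and m * %d < 1", max_deg)
  D <- rows * cols
  structure(list(
    rows = rows, cols = cols,
    live = rep(TRUE, D),
    sizes = rep(as.numeric(deme_size), D),
    base_sizes = rep(as.numeric(deme_size), D),
    migration_rate = migration_rate
  ), class = "habitat")
}

max_degree <- function(rows, cols) {
  if (rows == 1 && cols == 1) return(1L)
  if (rows == 1 || cols == 1) return(2L)
  4L
}

#' @export
print.habitat <- function(x, ...) {
  cat(sprintf("habitat: %d x %d grid, %d/%d live demes, N total = %g, m = %g\n",
              x$rows, x$cols, sum(x$live), length(x$live),
              sum(x$sizes[x$live]), x$migration_rate))
  invisible(x)
}

#' @export
plot.habitat <- function(x, ...) {
  z <- matrix(as.numeric(x$live), nrow = x$rows, ncol = x$cols, byrow = TRUE)
  image(seq_len(x$cols), seq_len(x$rows), t(z[x$rows:1, , drop = FALSE]),
        col = c("grey90", "darkgreen"), xlab = "col", ylab = "row (south up)",
        main = "habitat (live demes)", ...)
  invisible(x)
}

#' Live deme ids, sizes and coordinates
#'
#' @param habitat a [grid_habitat()] object.
#' @return `live_demes()` returns the integer ids of live demes;
#'   `habitat_sizes()` their census sizes (aligned with the ids);
#'   `deme_coords()` a data frame of `deme`, `row`, `col` for the requested
#'   demes (row 1 = north).
#' @export
live_demes <- function(habitat) which(habitat$live)

#' @rdname live_demes
#' @export
habitat_sizes <- function(habitat) habitat$sizes[habitat$live]

#' @rdname live_demes
#' @param demes deme ids; defaults to the live demes.
#' @export
deme_coords <- function(habitat, demes = live_demes(habitat)) {
  data.frame(deme = demes,
             row = (demes - 1L) %/% habitat$cols + 1L,
             col = (demes - 1L) %% habitat$cols + 1L)
}

# adjacency between two deme ids under rook moves
grid_adjacency <- function(habitat, demes = live_demes(habitat)) {
  co <- deme_coords(habitat, demes)
  D <- length(demes)
  A <- matrix(0L, D, D)
  if (D > 1) {
    dr <- abs(outer(co$row, co$row, "-"))
    dc <- abs(outer(co$col, co$col, "-"))
    A[dr + dc == 1L] <- 1L
  }
  dimnames(A) <- list(demes, demes)
  A
}

#' Backward migration matrix of a habitat
#'
#' Row-stochastic matrix `B` over live demes: `B[i, k]` is the probability
#' that a lineage now in deme `i` had its parent in deme `k`. Off-diagonal
#' entries equal the migration rate for adjacent live demes; the diagonal
#' holds the remainder, so migration mass pointing at destroyed demes is
#' returned to the source deme (reflecting boundary).
#'
#' @inheritParams live_demes
#' @return a `D x D` numeric matrix with rows summing to 1.
#' @export
migration_matrix <- function(habitat) {
  A <- grid_adjacency(habitat)
  m <- habitat$migration_rate
  B <- m * A
  diag(B) <- 1 - m * rowSums(A)
  if (any(diag(B) < 0))
    stopf("migration rate too large for this topology (m * degree >= 1)")
  B
}

remove_demes <- function(habitat, demes) {
  if (any(!habitat$live[demes]))
    stopf("attempt to remove a deme that is not live")
  habitat$live[demes] <- FALSE
  habitat$sizes[demes] <- 0
  habitat
}

#' Edge contraction: remove demes from one edge of the range
#'
#' Removes `floor(fraction * D)` live demes in whole rows (or columns)
#' starting from the named edge; a partial final row is removed in reading
#' order (west to east for north/south edges, north to south for east/west
#' edges). The remaining habitat is always connected.
#'
#' @inheritParams live_demes
#' @param fraction proportion of live demes to remove, in `[0, 1)`.
#' @param edge which edge contracts: `"north"` (row 1) by default.
#' @return the contracted `habitat`; attribute `"realized_fraction"` records
#'   the realized loss `floor(fraction * D) / D`.
#' @export
edge_contraction <- function(habitat, fraction,
                             edge = c("north", "south", "east", "west")) {
  edge <- match.arg(edge)
  if (fraction < 0) stopf("fraction must be non-negative")
  if (fraction >= 1) stopf("fraction >= 1 would destroy all habitat")
  ids <- live_demes(habitat)
  n_remove <- floor(fraction * length(ids) + 1e-9)
  if (n_remove == 0) {
    attr(habitat, "realized_fraction") <- 0
    return(habitat)
  }
  co <- deme_coords(habitat, ids)
  ord <- switch(edge,
    north = order(co$row, co$col),
    south = order(-co$row, co$col),
    west  = order(co$col, co$row),
    east  = order(-co$col, co$row))
  out <- remove_demes(habitat, ids[ord[seq_len(n_remove)]])
  attr(out, "realized_fraction") <- n_remove / length(ids)
  out
}

#' Random fragmentation: remove a random subset of demes
#'
#' Removes `round(fraction * D)` live demes chosen uniformly at random. The
#' surviving habitat may be disconnected; the seed fully determines the map.
#'
#' @inheritParams edge_contraction
#' @param seed integer seed for the map draw.
#' @return the fragmented `habitat`, with attributes `"realized_fraction"`
#'   and `"seed"`.
#' @export
random_fragmentation <- function(habitat, fraction, seed) {
  if (fraction < 0 || fraction >= 1) stopf("fraction must be in [0, 1)")
  ids <- live_demes(habitat)
  n_remove <- round(fraction * length(ids))
  drop <- with_seed(seed, sample(ids, n_remove))
  out <- if (n_remove > 0) remove_demes(habitat, drop) else habitat
  attr(out, "realized_fraction") <- n_remove / length(ids)
  attr(out, "seed") <- seed
  out
}

#' Gradual habitat-loss schedule
#'
#' Builds an ordered schedule of removal events implementing a gradual
#' decline: every `interval` generations a further `step_fraction` of the
#' initial habitat is removed from the contraction edge until
#' `total_fraction` is reached. Cumulative targets use `floor`, so applying
#' all events reproduces exactly the deme set of a single
#' [edge_contraction()] at `total_fraction`.
#'
#' @inheritParams edge_contraction
#' @param total_fraction total proportion of demes to remove.
#' @param step_fraction proportion removed per event.
#' @param interval generations between events (>= 1).
#' @return an object of class `scenario_schedule`: a data frame of events
#'   (`offset`, `action`) with a list column `demes`.
#' @export
gradual_schedule <- function(habitat, total_fraction, step_fraction,
                             interval,
                             edge = c("north", "south", "east", "west")) {
  edge <- match.arg(edge)
  if (step_fraction <= 0 && total_fraction > 0)
    stopf("invalid schedule: step_fraction = 0 with positive total")
  if (step_fraction > total_fraction) stopf("step must not exceed total")
  if (interval < 1) stopf("interval must be >= 1")
  ids <- live_demes(habitat)
  D <- length(ids)
  co <- deme_coords(habitat, ids)
  ord <- switch(edge,
    north = order(co$row, co$col),
    south = order(-co$row, co$col),
    west  = order(co$col, co$row),
    east  = order(-co$col, co$row))
  removal_order <- ids[ord]
  n_events <- ceiling(total_fraction / step_fraction)
  # the 1e-9 nudge keeps floor() stable against floating-point round-off
  cum <- floor(pmin(seq_len(n_events) * step_fraction, total_fraction) * D + 1e-9)
  prev <- c(0, cum[-n_events])
  events <- data.frame(offset = (seq_len(n_events) - 1L) * interval,
                       action = "remove", stringsAsFactors = FALSE)
  events$demes <- lapply(seq_len(n_events), function(j)
    if (cum[j] > prev[j]) removal_order[(prev[j] + 1):cum[j]] else integer(0))
  structure(list(events = events,
                 total_fraction = max(cum) / D,
                 interval = interval, edge = edge),
            class = "scenario_schedule")
}

#' @export
print.scenario_schedule <- function(x, ...) {
  cat(sprintf("scenario schedule: %d events, realized total loss %.4g\n",
              nrow(x$events), x$total_fraction))
  invisible(x)
}

#' Apply the removal/restoration events of a schedule to a habitat
#'
#' Topology only; the moments engine applies the same events to its state via
#' [apply_loss()] / [apply_restore()].
#'
#' @inheritParams live_demes
#' @param schedule a [gradual_schedule()] (or hand-built) `scenario_schedule`.
#' @return the habitat after all events.
#' @export
apply_schedule <- function(habitat, schedule) {
  for (j in seq_len(nrow(schedule$events))) {
    d <- schedule$events$demes[[j]]
    habitat <- switch(schedule$events$action[j],
      remove  = if (length(d)) remove_demes(habitat, d) else habitat,
      restore = restore(habitat, d),
      stopf("unknown schedule action '%s'", schedule$events$action[j]))
  }
  habitat
}

#' Restore previously removed demes
#'
#' Re-adds demes with their original census sizes and grid edges. How the
#' restored demes are genetically founded is decided in the moments engine
#' ([apply_restore()]).
#'
#' @inheritParams live_demes
#' @param demes ids of demes to restore.
#' @return the habitat with the demes live again.
#' @export
restore <- function(habitat, demes) {
  if (length(demes) == 0) return(habitat)
  if (any(habitat$live[demes])) {
    warnf("restoring demes that are already live: no-op for those demes")
    demes <- demes[!habitat$live[demes]]
  }
  habitat$live[demes] <- TRUE
  habitat$sizes[demes] <- habitat$base_sizes[demes]
  habitat
}

#' Is the live habitat connected under rook adjacency?
#'
#' Flood fill from the first live deme.
#' @inheritParams live_demes
#' @return logical.
#' @export
is_connected <- function(habitat) {
  ids <- live_demes(habitat)
  if (length(ids) <= 1) return(TRUE)
  A <- grid_adjacency(habitat, ids)
  seen <- logical(length(ids)); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Read and write habitat masks as 0/1 CSV grids
#'
#' The mask is written as a headerless `rows x cols` grid of 0/1 (row 1 =
#' north). Reading builds a habitat with the given deme size and migration
#' rate, dead cells having size 0.
#'
#' @inheritParams live_demes
#' @param path CSV file path.
#' @export
write_habitat_csv <- function(habitat, path) {
  z <- matrix(as.integer(habitat$live), nrow = habitat$rows,
              ncol = habitat$cols, byrow = TRUE)
  write.table(z, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_habitat_csv
#' @inheritParams grid_habitat
#' @export
read_habitat_csv <- function(path, deme_size = 50, migration_rate = 0.01) {
  z <- as.matrix(read.csv(path, header = FALSE))
  h <- grid_habitat(nrow(z), ncol(z), deme_size, migration_rate)
  dead <- which(t(z) == 0)  # row-major ids
  if (length(dead)) h <- remove_demes(h, dead)
  h
}

#' Serialize a scenario schedule to JSON (and back)
#'
#' @param schedule a `scenario_schedule`.
#' @param path JSON file path.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(
    total_fraction = schedule$total_fraction,
    interval = schedule$interval,
    edge = schedule$edge,
    events = lapply(seq_len(nrow(schedule$events)), function(j) list(
      offset = schedule$events$offset[j],
      action = schedule$events$action[j],
      demes = schedule$events$demes[[j]]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  events <- data.frame(
    offset = vapply(x$events, function(e) as.numeric(e$offset), 0),
    action = vapply(x$events, function(e) as.character(e$action), ""),
    stringsAsFactors = FALSE)
  events$demes <- lapply(x$events, function(e) as.integer(unlist(e$demes)))
  structure(list(events = events, total_fraction = x$total_fraction,
                 interval = x$interval, edge = x$edge),
            class = "scenario_schedule")
}
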