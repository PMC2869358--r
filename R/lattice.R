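#' Neighborhood offsets on the 3-D lattice
#'
#' Enumerates every nonzero integer offset `(dx, dy, dz)` within `radius` of
#' the origin.  Distances are Chebyshev by default, so `radius = 1` yields the
#' full 26-neighborhood and a radius-`r` ball is the `(2r+1)^3` cube minus the
#' origin.  Radii are in cellular space units: one unit is one lattice site.
#'
#' @param radius Non-negative integer radius.
#' @param metric `"chebyshev"` (default, cube-shaped balls) or `"euclidean"`.
#' @return Integer matrix with columns `dx`, `dy`, `dz`, one row per offset,
#'   in lexicographic order.
#' @examples
#' nrow(ball_offsets(1))  # 26
#' nrow(ball_offsets(2))  # 124
#' @export
ball_offsets <- function(radius, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  if (length(radius) != 1L || is.na(radius) || radius < 0 ||
      radius != floor(radius)) {
    stop("`radius` must be a single non-negative integer")
  }
  radius <- as.integer(radius)
  if (radius == 0L) {
    m <- matrix(integer(0), ncol = 3L)
    colnames(m) <- c("dx", "dy", "dz")
    return(m)
  }
  g <- expand.grid(dz = -radius:radius, dy = -radius:radius,
                   dx = -radius:radius, KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g[, c("dx", "dy", "dz")])
  keep <- rowSums(m != 0L) > 0L
  if (metric == "euclidean") {
    keep <- keep & sqrt(rowSums(m^2)) <= radius + 1e-9
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' @rdname sim_state
#' @export
site_index <- function(state, pos) {
  e <- state$extents
  if (length(pos) != 3L) stop("`pos` must be an (x, y, z) triple")
  if (any(pos < 0L) || any(pos >= e)) stop("`pos` is outside the grid")
  as.integer(pos[1L] + e[1L] * (pos[2L] + e[2L] * pos[3L]) + 1L)
}

#' @rdname sim_state
#' @export
site_position <- function(state, index) {
  e <- state$extents
  i <- as.integer(index) - 1L
  cbind(x = i %% e[1L],
        y = (i %/% e[1L]) %% e[2L],
        z = i %/% (e[1L] * e[2L]))
}

#' Free neighboring sites of a position
#'
#' In-bounds, unoccupied sites in the 26-neighborhood of `pos`, the space a
#' normal cell is allowed to divide into (contact inhibition confines normal
#' daughters to free adjacent sites).  Returned in lexicographic order so
#' trajectories are reproducible.
#'
#' @param state A [sim_state] object.
#' @param pos Integer `(x, y, z)` position, 0-based.
#' @return Integer matrix of free positions (columns `x`, `y`, `z`).
#' @export
free_neighbors <- function(state, pos) {
  i <- site_index(state, pos)  # validates bounds
  off <- ball_offsets(1L)
  cand <- sweep(off, 2L, as.integer(pos), "+")
  colnames(cand) <- c("x", "y", "z")
  e <- state$extents
  inb <- cand[, 1L] >= 0L & cand[, 1L] < e[1L] &
         cand[, 2L] >= 0L & cand[, 2L] < e[2L] &
         cand[, 3L] >= 0L & cand[, 3L] < e[3L]
  cand <- cand[inb, , drop = FALSE]
  idx <- cand[, 1L] + e[1L] * (cand[, 2L] + e[2L] * cand[, 3L]) + 1L
  free <- state$phen[idx] == 0L
  cand <- cand[free, , drop = FALSE]
  cand[order(cand[, 1L], cand[, 2L], cand[, 3L]), , drop = FALSE]
}

#' Occupancy fraction of the lattice
#'
#' Fraction of all lattice sites holding a cell of the requested phenotype.
#'
#' @param state A [sim_state] object.
#' @param phenotype `"any"`, `"normal"` or `"tumor"`.
#' @return Fraction in `[0, 1]`.
#' @export
occupancy <- function(state, phenotype = c("any", "normal", "tumor")) {
  phenotype <- match.arg(phenotype)
  ns <- prod(state$extents)
  code <- switch(phenotype, any = 1:2, normal = 1L, tumor = 2L)
  sum(state$phen %in% code) / ns
}

#' Simulation state on a bounded 3-D lattice
#'
#' A `sim_state` holds the full state of the cell society: a fixed
#' rectangular box of `extents[1] * extents[2] * extents[3]` sites (hard
#' walls, no wraparound) with at most one cell per site, plus per-cell
#' phenotype parameters, signal accumulators and bookkeeping.  Sites are
#' addressed by 0-based `(x, y, z)` positions; cells never move, so the site
#' index identifies a cell together with its `id`.
#'
#' All fields are flat site-indexed vectors: `phen` (0 free, 1 normal,
#' 2 tumor), `prolif`/`death` (per-step probabilities), `genpot` (remaining
#' divisions, -1 unlimited), `age`, `gen` (divisions completed), `flags`
#' (protocol-integrity bitmask: repair 1, apoptosis 2,
#' proliferation-suppression 4, distance-regulation 8; 15 = fully intact
#' normal, 0 = tumor), `acc_a`/`acc_r` (apoptotic and repopulation signal
#' accumulators), `reqs` (distinct apoptotic requests received), `accel`
#' (remaining accelerated steps), `primed` (early please-die emitter), `id`.
#'
#' @param extents Three positive integers.
#' @return An empty `sim_state` (all sites free).
#' @export
sim_state <- function(extents) {
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(is.na(extents)) || any(extents < 1L)) {
    stop("`extents` must be three positive integers")
  }
  ns <- prod(extents)
  structure(list(
    extents = extents, clock = 0L, next_id = 1L,
    phen = integer(ns), genpot = integer(ns), age = integer(ns),
    gen = integer(ns), flags = integer(ns), accel = integer(ns),
    primed = integer(ns), reqs = integer(ns), id = integer(ns),
    prolif = numeric(ns), death = numeric(ns),
    acc_a = numeric(ns), acc_r = numeric(ns)
  ), class = "sim_state")
}

#' @rdname sim_state
#' @param state,field For `state_array`: the state and the site-indexed field
#'   to reshape into a 3-D array indexed `[x+1, y+1, z+1]`.
#' @export
state_array <- function(state, field = "phen") {
  array(state[[field]], dim = state$extents)
}

#' @rdname sim_state
#' @export
state_counts <- function(state) {
  c(normal = sum(state$phen == 1L), tumor = sum(state$phen == 2L),
    free = sum(state$phen == 0L))
}

#' Place a cell into a state (fixture construction)
#'
#' Low-level helper used to build deterministic grid states in tests and
#' examples.  Overwrites whatever occupies `pos`.
#'
#' @param state A [sim_state].
#' @param pos 0-based `(x, y, z)` position.
#' @param phenotype `"normal"` or `"tumor"`.
#' @param prolif,death Per-step probabilities.
#' @param genpot Remaining divisions (-1 unlimited).
#' @return The modified state.
#' @export
place_cell <- function(state, pos, phenotype = c("normal", "tumor"),
                       prolif = 0, death = 0, genpot = -1L) {
  phenotype <- match.arg(phenotype)
  i <- site_index(state, pos)
  state$phen[i] <- if (phenotype == "tumor") 2L else 1L
  state$prolif[i] <- prolif
  state$death[i] <- death
  state$genpot[i] <- as.integer(genpot)
  state$flags[i] <- if (phenotype == "tumor") 0L else 15L
  state$age[i] <- 0L
  state$gen[i] <- 0L
  state$acc_a[i] <- 0
  state$acc_r[i] <- 0
  state$reqs[i] <- 0L
  state$accel[i] <- 0L
  state$primed[i] <- 0L
  state$id[i] <- state$next_id
  state$next_id <- state$next_id + 1L
  state
}

#' @export
print.sim_state <- function(x, ...) {
  n <- state_counts(x)
  cat(sprintf("<sim_state %dx%dx%d  step %d  normal %d  tumor %d  free %d>\n",
              x$extents[1L], x$extents[2L], x$extents[3L], x$clock,
              n["normal"], n["tumor"], n["free"]))
  invisible(x)
}
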