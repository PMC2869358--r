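# shared fixtures: small deterministic grid states built in code

# a compact configuration for fast engine tests
test_config <- function(extents = c(10L, 10L, 10L), ...) {
  sim_config(extents = extents, ...)
}

# fully occupied state with an optional centered cubic tumor blob of the
# given Chebyshev radius; per-cell probabilities are fixed, not sampled
full_state <- function(extents, tumor_radius = NULL, prolif_n = 0,
                       death_n = 0, prolif_t = 0, death_t = 0) {
  st <- sim_state(extents)
  ctr <- extents %/% 2L
  for (z in seq_len(extents[3L]) - 1L) {
    for (y in seq_len(extents[2L]) - 1L) {
      for (x in seq_len(extents[1L]) - 1L) {
        tum <- !is.null(tumor_radius) &&
          max(abs(c(x, y, z) - ctr)) <= tumor_radius
        st <- place_cell(st, c(x, y, z),
                         if (tum) "tumor" else "normal",
                         prolif = if (tum) prolif_t else prolif_n,
                         death = if (tum) death_t else death_n)
      }
    }
  }
  st
}

# brute-force offset enumeration used as the oracle for ball_offsets
brute_offsets <- function(radius, metric = "chebyshev") {
  out <- NULL
  for (dx in -radius:radius) for (dy in -radius:radius) {
    for (dz in -radius:radius) {
      if (dx == 0 && dy == 0 && dz == 0) next
      d <- if (metric == "euclidean") sqrt(dx^2 + dy^2 + dz^2) else
        max(abs(dx), abs(dy), abs(dz))
      if (d <= radius + 1e-9) out <- rbind(out, c(dx, dy, dz))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 3L) else out
}

# Chebyshev distance from each occupied site of one phenotype to the nearest
# cell of another phenotype
min_cheb_dist <- function(state, from_code, to_code) {
  from <- which(state$phen == from_code)
  to <- which(state$phen == to_code)
  pf <- site_position(state, from)
  pt <- site_position(state, to)
  vapply(seq_along(from), function(i) {
    min(pmax(abs(pt[, 1L] - pf[i, 1L]),
             pmax(abs(pt[, 2L] - pf[i, 2L]), abs(pt[, 3L] - pf[i, 3L]))))
  }, numeric(1L))
}
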