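#' Signal strength received at a distance
#'
#' A signal of strength `s` and radius `r` is observed at full strength by
#' the emitter's immediate position and decays with distance: linearly,
#' `s * (1 - d / (r + 1))`, reaching zero one unit beyond the radius; or
#' exponentially (halving per unit), truncated to zero beyond the radius.
#' The strength is strictly decreasing on `[0, r]` and exactly zero for
#' `d > r`.
#'
#' @param s Strength at the emitter (signal units), `> 0`.
#' @param r Propagation radius (cellular space units), `>= 0`.
#' @param d Distance from the emitter (Chebyshev by default in the engine).
#' @param decay `"linear"` or `"exponential"`.
#' @return Received strength in signal units (vectorized over `d`).
#' @export
received_strength <- function(s, r, d, decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (any(d < 0)) stop("`d` must be non-negative")
  out <- if (decay == "linear") s * (1 - d / (r + 1)) else s * 0.5^d
  out[d > r + 1e-9] <- 0
  pmax(out, 0)
}

#' Detect spatial violation of a normal cell
#'
#' A normal cell is spatially violated when at least one tumor cell lies
#' within the violation radius (default 1, the 26-neighborhood).  Violation
#' is what licenses please-die emission; only normal cells emit it, so tumor
#' positions are rejected.
#'
#' @param state A [sim_state].
#' @param pos Position of a normal cell.
#' @param radius Violation radius.
#' @return Logical.
#' @export
detect_spatial_violation <- function(state, pos, radius = 1L) {
  i <- site_index(state, pos)
  if (state$phen[i] != 1L) {
    stop("`pos` must hold a normal cell (only normal cells emit please-die)")
  }
  off <- ball_offsets(radius)
  if (nrow(off) == 0L) return(FALSE)
  cand <- sweep(off, 2L, as.integer(pos), "+")
  e <- state$extents
  inb <- cand[, 1L] >= 0L & cand[, 1L] < e[1L] &
         cand[, 2L] >= 0L & cand[, 2L] < e[2L] &
         cand[, 3L] >= 0L & cand[, 3L] < e[3L]
  cand <- cand[inb, , drop = FALSE]
  idx <- cand[, 1L] + e[1L] * (cand[, 2L] + e[2L] * cand[, 3L]) + 1L
  any(state$phen[idx] == 2L)
}

# deposits of one emission: occupied in-bounds sites within radius, decayed
deposit_map <- function(state, pos, radius, strength, decay, metric) {
  off <- ball_offsets(radius, metric)
  empty <- data.frame(x = integer(0), y = integer(0), z = integer(0),
                      site = integer(0), amount = numeric(0))
  if (nrow(off) == 0L) return(empty)
  cand <- sweep(off, 2L, as.integer(pos), "+")
  e <- state$extents
  inb <- cand[, 1L] >= 0L & cand[, 1L] < e[1L] &
         cand[, 2L] >= 0L & cand[, 2L] < e[2L] &
         cand[, 3L] >= 0L & cand[, 3L] < e[3L]
  cand <- cand[inb, , drop = FALSE]
  off <- off[inb, , drop = FALSE]
  idx <- cand[, 1L] + e[1L] * (cand[, 2L] + e[2L] * cand[, 3L]) + 1L
  occ <- state$phen[idx] != 0L
  cand <- cand[occ, , drop = FALSE]
  off <- off[occ, , drop = FALSE]
  idx <- idx[occ]
  if (length(idx) == 0L) return(empty)
  d <- if (metric == "euclidean") sqrt(rowSums(off^2)) else
    pmax(abs(off[, 1L]), pmax(abs(off[, 2L]), abs(off[, 3L])))
  amt <- received_strength(strength, radius, d, decay)
  keep <- amt > 0
  data.frame(x = cand[keep, 1L], y = cand[keep, 2L], z = cand[keep, 3L],
             site = idx[keep], amount = amt[keep])
}

#' Emit a please-die signal
#'
#' A spatially violated (or low-threshold-primed) normal cell deposits the
#' decayed please-die signal at every occupied site within the signal
#' radius, emitter excluded.  Free sites carry no field: signals only exist
#' on cells.
#'
#' @param state A [sim_state].
#' @param pos Position of the emitting normal cell.
#' @param config A [sim_config] (signal parameters and decay law).
#' @return Data frame of deposits with columns `x`, `y`, `z`, `site`,
#'   `amount` (all amounts `> 0`).
#' @export
emit_please_die <- function(state, pos, config) {
  i <- site_index(state, pos)
  if (state$phen[i] != 1L) stop("only normal cells emit please-die")
  p <- config$signals$normal_please_die
  deposit_map(state, pos, p[1L], p[2L], config$decay, config$metric)
}

#' Emit a death report ("I'm dying")
#'
#' A cell dying through a rescue protocol reports its death over the
#' phenotype-specific radius.  Normal cells always report; a dying tumor
#' cell fails to report with probability `fail_emit_prob` (stochastic
#' resistance at the emission side), in which case the deposit map is empty.
#'
#' @param state A [sim_state].
#' @param pos Position of the dying cell.
#' @param config A [sim_config].
#' @return Data frame of deposits (possibly empty).
#' @export
emit_im_dying <- function(state, pos, config) {
  i <- site_index(state, pos)
  if (state$phen[i] == 0L) stop("no cell at `pos`")
  tumor <- state$phen[i] == 2L
  if (tumor && stats::runif(1L) < config$fail_emit_prob) {
    return(deposit_map(state, pos, 0L, 1, config$decay, config$metric))
  }
  p <- if (tumor) config$signals$tumor_im_dying else config$signals$normal_im_dying
  deposit_map(state, pos, p[1L], p[2L], config$decay, config$metric)
}

#' Fold deposits into an accumulator
#'
#' Receiving cells consider the total strength of signals received over
#' time: each step the accumulator is carried over with retention `rho` and
#' the step's deposits are added, `acc' = rho * acc + sum(deposits)`.
#' `rho = 1` is a pure sum over time; `rho = 0` is memoryless.
#'
#' @param acc Current accumulator value (`>= 0`).
#' @param deposits Numeric vector of deposits addressed to the cell.
#' @param rho Retention factor in `[0, 1]`.
#' @return Updated accumulator.
#' @export
apply_deposits <- function(acc, deposits, rho = 1) {
  if (rho < 0 || rho > 1) stop("`rho` must be in [0, 1]")
  rho * acc + sum(deposits)
}

#' Two-threshold response of a cell
#'
#' Decides the single highest-priority action from the accumulated signal.
#' A tumor cell apoptoses once its apoptotic accumulator reaches the tumor
#' high threshold *and* it has collected at least `det_counts["tumor"]`
#' distinct requests (deterministic resistance).  A normal cell apoptoses at
#' its high threshold; below that, the repopulation accumulator reaching
#' `low_repop` accelerates replication, and otherwise the apoptotic
#' accumulator reaching `low_please_die` primes early please-die emission.
#'
#' @param phenotype `"normal"` or `"tumor"`.
#' @param acc_apoptotic Apoptotic accumulator (signal units).
#' @param acc_repop Repopulation accumulator (normal cells).
#' @param requests Distinct above-half-strength apoptotic requests received.
#' @param config A [sim_config] (thresholds and deterministic counts).
#' @return One of `"none"`, `"apoptose"`, `"accelerate"`, `"emit_early"`.
#' @export
respond <- function(phenotype, acc_apoptotic, acc_repop = 0, requests = 0L,
                    config = sim_config()) {
  th <- config$thresholds
  if (phenotype == "tumor") {
    if (acc_apoptotic >= th$high_tumor &&
        requests >= config$det_counts[["tumor"]]) {
      return("apoptose")
    }
    return("none")
  }
  if (acc_apoptotic >= th$high_normal &&
      requests >= config$det_counts[["normal"]]) {
    return("apoptose")
  }
  if (acc_repop >= th$low_repop) return("accelerate")
  if (acc_apoptotic >= th$low_please_die) return("emit_early")
  "none"
}
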