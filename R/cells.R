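#' Draw phenotype parameters from the population ranges
#'
#' Population heterogeneity: each cell's proliferation and death
#' probabilities are drawn uniformly from its phenotype's range, so no two
#' cells need behave identically even under the same configuration.
#'
#' @param ranges Population ranges as from [population_ranges()].
#' @param phenotype `"normal"` or `"tumor"`.
#' @param generation_potential Divisions granted to a new normal lineage
#'   (tumor lineages are unlimited).
#' @return List with `prolif_prob`, `death_prob`, `generation_potential`,
#'   `protocols_intact` (named logical vector), `phenotype`.
#' @export
sample_population_params <- function(ranges, phenotype = c("normal", "tumor"),
                                     generation_potential = 50L) {
  phenotype <- match.arg(phenotype)
  if (phenotype == "normal") {
    pr <- ranges$normal_prolif
    dr <- ranges$normal_death
    gp <- as.integer(generation_potential)
    intact <- c(repair = TRUE, apoptosis = TRUE,
                proliferation_suppression = TRUE, distance_regulation = TRUE)
  } else {
    pr <- ranges$tumor_prolif
    dr <- ranges$tumor_death
    gp <- -1L
    intact <- c(repair = FALSE, apoptosis = FALSE,
                proliferation_suppression = FALSE, distance_regulation = FALSE)
  }
  list(prolif_prob = stats::runif(1L, pr[1L], pr[2L]),
       death_prob = stats::runif(1L, dr[1L], dr[2L]),
       generation_potential = gp,
       protocols_intact = intact,
       phenotype = phenotype)
}

#' Inherit phenotype parameters with random skewing
#'
#' A daughter's probabilities are the parent's multiplied by
#' `uniform(1 - skew_frac, 1 + skew_frac)` and clipped back into the
#' population range; her generation potential is the parent's minus one.
#'
#' @param parent Parameter list as from [sample_population_params()].
#' @param ranges Population ranges for the clipping bounds.
#' @param skew_frac Non-negative skew fraction (0 copies the parent exactly).
#' @return Daughter parameter list.
#' @export
inherit_params <- function(parent, ranges, skew_frac = 0.1) {
  if (skew_frac < 0) stop("`skew_frac` must be >= 0")
  tumor <- identical(parent$phenotype, "tumor")
  pr <- if (tumor) ranges$tumor_prolif else ranges$normal_prolif
  dr <- if (tumor) ranges$tumor_death else ranges$normal_death
  d <- parent
  d$prolif_prob <- min(pr[2L], max(pr[1L],
    parent$prolif_prob * stats::runif(1L, 1 - skew_frac, 1 + skew_frac)))
  d$death_prob <- min(dr[2L], max(dr[1L],
    parent$death_prob * stats::runif(1L, 1 - skew_frac, 1 + skew_frac)))
  if (parent$generation_potential > 0L) {
    d$generation_potential <- parent$generation_potential - 1L
  }
  d
}

#' Intrinsic death decision
#'
#' Apoptosis as a random per-step process, plus deterministic senescence once
#' the generation potential is exhausted and age exceeds the configured
#' horizon.  A `TRUE` return marks the cell as dying this step.
#'
#' @param params Parameter list with `death_prob` and
#'   `generation_potential`.
#' @param age Cell age in steps.
#' @param senescence_age Horizon (steps); `NA` disables senescence.
#' @return Logical.
#' @export
intrinsic_death <- function(params, age = 0L, senescence_age = NA) {
  if (stats::runif(1L) < params$death_prob) return(TRUE)
  if (!is.na(senescence_age) && params$generation_potential == 0L &&
      age > senescence_age) {
    return(TRUE)
  }
  FALSE
}

#' Mutation step at the division checkpoint
#'
#' Tumorigenesis requires a particular ordering of mutations: each intact
#' guarding protocol (repair, apoptosis, proliferation-suppression, distance
#' regulation) is lost independently with the given probability, but while
#' repair is still intact it restores any other protocol lost in the same
#' checkpoint -- so repair must fall first.  When all four guards are lost
#' the cell becomes a tumor cell and resamples its parameters from the tumor
#' ranges; the transition is irreversible.
#'
#' @param params Parameter list of a normal cell (tumor input is rejected:
#'   tumor cells cannot back-mutate and do not run this protocol).
#' @param mutation_prob Per-protocol loss probability.
#' @param ranges Population ranges used to resample on transformation.
#' @return Updated parameter list (possibly with `phenotype = "tumor"`).
#' @export
mutate_step <- function(params, mutation_prob, ranges) {
  if (identical(params$phenotype, "tumor")) {
    stop("tumor cells do not run the mutation protocol (no back-mutation)")
  }
  intact <- params$protocols_intact
  if (mutation_prob > 0) {
    lost_now <- intact & (stats::runif(4L) < mutation_prob)
    intact[lost_now] <- FALSE
    if (intact[["repair"]]) {
      restore <- lost_now
      restore[["repair"]] <- FALSE
      intact[restore] <- TRUE
    }
  }
  params$protocols_intact <- intact
  if (!any(intact)) {
    pr <- ranges$tumor_prolif
    dr <- ranges$tumor_death
    params$phenotype <- "tumor"
    params$prolif_prob <- stats::runif(1L, pr[1L], pr[2L])
    params$death_prob <- stats::runif(1L, dr[1L], dr[2L])
    params$generation_potential <- -1L
  }
  params
}

#' Attempt one cell division on a state
#'
#' With probability `prolif_prob` the cell at `pos` divides.  A normal cell
#' may only place its daughter on a free site of its 26-neighborhood
#' (contact inhibition); a tumor cell whose radius-1 neighborhood is full
#' falls back to a free site on the radius-2 shell (local pressure).  The
#' daughter inherits the parent's parameters with skew.  No-op when no
#' admissible site exists or the generation potential is exhausted.
#'
#' @param state A [sim_state].
#' @param pos Position of a living cell.
#' @param config A [sim_config] (ranges and skew are taken from it).
#' @return List with the updated `state` and `daughter` (position or `NULL`).
#' @export
attempt_division <- function(state, pos, config) {
  i <- site_index(state, pos)
  if (state$phen[i] == 0L) stop("no cell at `pos`")
  tumor <- state$phen[i] == 2L
  if (!tumor && state$genpot[i] == 0L) {
    return(list(state = state, daughter = NULL))
  }
  if (stats::runif(1L) >= state$prolif[i]) {
    return(list(state = state, daughter = NULL))
  }
  sites <- free_neighbors(state, pos)
  if (nrow(sites) == 0L && tumor) {
    off <- ball_offsets(2L)
    off <- off[pmax(abs(off[, 1L]), pmax(abs(off[, 2L]), abs(off[, 3L]))) == 2L,
               , drop = FALSE]
    cand <- sweep(off, 2L, as.integer(pos), "+")
    e <- state$extents
    inb <- cand[, 1L] >= 0L & cand[, 1L] < e[1L] &
           cand[, 2L] >= 0L & cand[, 2L] < e[2L] &
           cand[, 3L] >= 0L & cand[, 3L] < e[3L]
    cand <- cand[inb, , drop = FALSE]
    idx <- cand[, 1L] + e[1L] * (cand[, 2L] + e[2L] * cand[, 3L]) + 1L
    sites <- cand[state$phen[idx] == 0L, , drop = FALSE]
  }
  if (nrow(sites) == 0L) return(list(state = state, daughter = NULL))
  pick <- sites[sample.int(nrow(sites), 1L), ]
  r <- config$ranges
  pr <- if (tumor) r$tumor_prolif else r$normal_prolif
  dr <- if (tumor) r$tumor_death else r$normal_death
  sk <- config$skew_frac
  dp <- min(pr[2L], max(pr[1L],
    state$prolif[i] * stats::runif(1L, 1 - sk, 1 + sk)))
  dd <- min(dr[2L], max(dr[1L],
    state$death[i] * stats::runif(1L, 1 - sk, 1 + sk)))
  if (state$genpot[i] > 0L) state$genpot[i] <- state$genpot[i] - 1L
  state$gen[i] <- state$gen[i] + 1L
  state <- place_cell(state, pick, if (tumor) "tumor" else "normal",
                      prolif = dp, death = dd, genpot = state$genpot[i])
  list(state = state, daughter = as.integer(pick))
}

#' Plant a single tumor cell
#'
#' Replaces one occupied site (grid center by default, or a uniformly random
#' occupied site) with a tumor cell whose parameters are sampled from the
#' tumor ranges, leaving the membrane as full as it was.  This is the
#' standard entry point of the anti-cancer experiments: it starts every
#' tumor from a single cell at a set time.
#'
#' @param state A confluent [sim_state] with at least one normal cell.
#' @param config A [sim_config].
#' @return The state with exactly one more tumor cell.
#' @export
plant_tumor <- function(state, config) {
  if (sum(state$phen == 1L) == 0L) stop("cannot plant into an empty system")
  if (config$plant_site == "center") {
    pos <- state$extents %/% 2L
    i <- site_index(state, pos)
    if (state$phen[i] == 0L) {  # transient hole at the center: use nearest cell
      occ <- which(state$phen != 0L)
      pp <- site_position(state, occ)
      d2 <- (pp[, 1L] - pos[1L])^2 + (pp[, 2L] - pos[2L])^2 +
        (pp[, 3L] - pos[3L])^2
      i <- occ[which.min(d2)]
      pos <- site_position(state, i)[1L, ]
    }
  } else {
    occ <- which(state$phen != 0L)
    i <- occ[sample.int(length(occ), 1L)]
    pos <- site_position(state, i)[1L, ]
  }
  r <- config$ranges
  place_cell(state, as.integer(pos), "tumor",
             prolif = stats::runif(1L, r$tumor_prolif[1L], r$tumor_prolif[2L]),
             death = stats::runif(1L, r$tumor_death[1L], r$tumor_death[2L]),
             genpot = -1L)
}
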