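#' Population parameter ranges by proliferation ratio
#'
#' Per-step proliferation and death probability ranges for normal and tumor
#' cells.  The proliferation ratio is the quotient of the tumor and normal
#' proliferation ranges: tumor cells always draw from `[0.3, 0.9]` while the
#' normal range shrinks with the ratio (`[0.05, 0.15]` for 6, `[0.03, 0.09]`
#' for 10, `[0.015, 0.045]` for 20).  Death ranges are `[0.0024, 0.0048]` for
#' normal and `[0.0001, 0.0002]` for tumor cells at every ratio, so the
#' tumor's advantage is both faster birth and slower intrinsic death.
#'
#' @param ratio One of 6, 10, 20.
#' @return List with elements `normal_prolif`, `tumor_prolif`,
#'   `normal_death`, `tumor_death` (each `c(lo, hi)`) and `ratio_label`.
#' @export
population_ranges <- function(ratio) {
  np <- switch(as.character(ratio),
               "6" = c(0.05, 0.15),
               "10" = c(0.03, 0.09),
               "20" = c(0.015, 0.045),
               stop("`ratio` must be one of 6, 10, 20 ",
                    "(custom populations require explicit `ranges`)"))
  list(normal_prolif = np,
       tumor_prolif = c(0.3, 0.9),
       normal_death = c(0.0024, 0.0048),
       tumor_death = c(0.0001, 0.0002),
       ratio_label = as.integer(ratio))
}

#' Rescue-signal parameter presets
#'
#' The five labelled radius/strength combinations for the three signal
#' classes (tumor death report, normal death report, please-die request).
#' Radius is how far the signal propagates in cellular space units; strength
#' is its value at the emitter, decaying with distance (see
#' [received_strength()]).
#'
#' @param label Integer preset label, 1 to 5.
#' @return List with elements `tumor_im_dying`, `normal_im_dying`,
#'   `normal_please_die`, each `c(radius, strength)`, plus `label`.
#' @export
signal_preset <- function(label) {
  presets <- list(
    list(tumor_im_dying = c(1, 1), normal_im_dying = c(1, 1),
         normal_please_die = c(1, 1)),
    list(tumor_im_dying = c(1, 2), normal_im_dying = c(1, 2),
         normal_please_die = c(1, 1)),
    list(tumor_im_dying = c(1, 2), normal_im_dying = c(1, 2),
         normal_please_die = c(1, 2)),
    list(tumor_im_dying = c(1, 3), normal_im_dying = c(1, 3),
         normal_please_die = c(1, 3)),
    list(tumor_im_dying = c(2, 3), normal_im_dying = c(1, 2),
         normal_please_die = c(1, 2)))
  if (!(length(label) == 1L && label %in% 1:5)) {
    stop("`label` must be an integer in 1..5")
  }
  p <- presets[[as.integer(label)]]
  p$label <- as.integer(label)
  p
}

check_range <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 2L || any(is.na(x)) || x[1L] > x[2L] ||
      x[1L] < lo || x[2L] > hi) {
    stop(sprintf("`%s` must be an ordered pair within [%g, %g]", name, lo, hi))
  }
  as.numeric(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  as.numeric(x)
}

#' Simulation configuration
#'
#' Assembles and validates every tunable of the simulator.  Defaults are the
#' study conditions used throughout the package: a 20 x 20 x 20 membrane,
#' ratio-6 populations, signal preset 2, a unit tumor apoptosis threshold
#' with a four-fold higher normal threshold (normal cells retain regulated
#' resistance to external kill commands; the tested threshold pairs are
#' asymmetric in the same direction), low thresholds at half a unit, no
#' resistance, and immediate rescue activation at tumor planting.
#'
#' @param extents Lattice extents (three positive integers).
#' @param ratio Proliferation ratio preset (6, 10 or 20); ignored when
#'   `ranges` is supplied.
#' @param ranges Explicit population ranges as from [population_ranges()].
#' @param skew_frac Daughter cells inherit parental probabilities multiplied
#'   by `uniform(1 - skew_frac, 1 + skew_frac)`, clipped to the population
#'   range.
#' @param generation_potential Maximum divisions for a normal lineage
#'   (tumor cells are unlimited); -1 disables the limit.
#' @param senescence_age Once a normal cell's generation potential is
#'   exhausted it dies deterministically past this age; `NA` disables.
#' @param suppression_factor Proliferation multiplier for normal cells with a
#'   tumor cell within `violation_radius` (contact pressure).
#' @param mutation_prob Per-protocol loss probability at the division
#'   checkpoint (spontaneous tumorigenesis; 0 disables, planting is the
#'   standard entry point).
#' @param signal_set Signal preset label (1-5); ignored when `signals` given.
#' @param signals Explicit signal parameters as from [signal_preset()].
#' @param decay `"linear"` (strength `s * (1 - d/(r+1))`) or `"exponential"`
#'   (halving per unit distance, truncated at the radius).
#' @param metric Distance metric for neighborhoods and signal propagation.
#' @param thresholds Named list: `high_tumor`, `high_normal` (apoptosis),
#'   `low_please_die` (early emission priming), `low_repop` (replication
#'   acceleration), all in signal units.
#' @param det_counts Deterministic resistance: distinct above-half-strength
#'   requests required before apoptosis, `c(tumor =, normal =)`.
#' @param ignore_prob Tumor cells discard each received deposit with this
#'   probability (stochastic resistance, cell level).
#' @param fail_emit_prob Dying tumor cells fail to emit their death report
#'   with this probability.
#' @param rho Accumulator retention per step (1 = pure sum over time).
#' @param accel_factor,accel_duration Replication acceleration triggered in
#'   normal cells by the low repopulation threshold: multiplier and duration
#'   in steps (re-triggered while the threshold holds).
#' @param violation_radius Tumor within this radius spatially violates a
#'   normal cell (it emits please-die and is growth-suppressed).
#' @param early_radius Primed normal cells emit please-die already when a
#'   tumor is within this radius ("emit sooner").
#' @param please_die,im_dying Protocol switches.
#' @param im_dying_kills_normals If `TRUE`, death reports also feed normal
#'   cells' apoptotic accumulator (symmetric apoptosis); by default they only
#'   drive repopulation acceleration in normals.
#' @param emit_on_intrinsic_death If `TRUE`, cells dying intrinsically also
#'   emit death reports; by default only protocol-induced deaths report.
#' @param plant Plant a single tumor cell at confluence.
#' @param plant_site `"center"` or `"random"` (an occupied site is replaced).
#' @param activation_volume_frac Rescue protocols stay inactive until tumor
#'   occupancy reaches this fraction of the lattice (0 = active from
#'   planting).
#' @param confluence_frac Occupancy fraction treated as confluent (birth/
#'   death turnover keeps a handful of transient holes open in large grids).
#' @param max_steps Step budget for the rescue phase of a run.
#' @param growth_cap,wait_cap Step caps for the initial growth phase and the
#'   delayed-activation waiting phase.
#' @param integrity_frac A run is only a success if the final normal count is
#'   at least this fraction of the normal count at rescue activation.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(extents = c(20L, 20L, 20L),
                       ratio = 6,
                       ranges = NULL,
                       skew_frac = 0.1,
                       generation_potential = 50L,
                       senescence_age = NA,
                       suppression_factor = 0.5,
                       mutation_prob = 0,
                       signal_set = 2L,
                       signals = NULL,
                       decay = c("linear", "exponential"),
                       metric = c("chebyshev", "euclidean"),
                       thresholds = list(high_tumor = 1, high_normal = 4,
                                         low_please_die = 0.5,
                                         low_repop = 0.5),
                       det_counts = c(tumor = 1L, normal = 1L),
                       ignore_prob = 0,
                       fail_emit_prob = 0,
                       rho = 1,
                       accel_factor = 2,
                       accel_duration = 5L,
                       violation_radius = 1L,
                       early_radius = 2L,
                       please_die = TRUE,
                       im_dying = TRUE,
                       im_dying_kills_normals = FALSE,
                       emit_on_intrinsic_death = FALSE,
                       plant = TRUE,
                       plant_site = c("center", "random"),
                       activation_volume_frac = 0,
                       confluence_frac = 0.995,
                       max_steps = 500L,
                       growth_cap = 5000L,
                       wait_cap = 20000L,
                       integrity_frac = 0.5) {
  decay <- match.arg(decay)
  metric <- match.arg(metric)
  plant_site <- match.arg(plant_site)
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(is.na(extents)) || any(extents < 2L)) {
    stop("`extents` must be three integers >= 2")
  }
  if (is.null(ranges)) ranges <- population_ranges(ratio)
  ranges$normal_prolif <- check_range(ranges$normal_prolif, "normal_prolif")
  ranges$tumor_prolif <- check_range(ranges$tumor_prolif, "tumor_prolif")
  ranges$normal_death <- check_range(ranges$normal_death, "normal_death")
  ranges$tumor_death <- check_range(ranges$tumor_death, "tumor_death")
  if (is.null(signals)) signals <- signal_preset(signal_set)
  for (nm in c("tumor_im_dying", "normal_im_dying", "normal_please_die")) {
    v <- signals[[nm]]
    if (length(v) != 2L || v[1L] < 0 || v[2L] <= 0) {
      stop(sprintf("`signals$%s` must be c(radius >= 0, strength > 0)", nm))
    }
  }
  th <- thresholds
  for (nm in c("high_tumor", "high_normal", "low_please_die", "low_repop")) {
    if (is.null(th[[nm]]) || th[[nm]] <= 0) {
      stop(sprintf("threshold `%s` must be positive", nm))
    }
  }
  if (th$low_please_die >= th$high_normal) {
    stop("`low_please_die` must be below `high_normal`")
  }
  ignore_prob <- check_prob(ignore_prob, "ignore_prob")
  fail_emit_prob <- check_prob(fail_emit_prob, "fail_emit_prob")
  rho <- check_prob(rho, "rho")
  mutation_prob <- check_prob(mutation_prob, "mutation_prob")
  suppression_factor <- check_prob(suppression_factor, "suppression_factor")
  if (skew_frac < 0) stop("`skew_frac` must be >= 0")
  if (activation_volume_frac < 0 || activation_volume_frac >= 1) {
    stop("`activation_volume_frac` must be in [0, 1)")
  }
  if (integrity_frac < 0 || integrity_frac > 1) {
    stop("`integrity_frac` must be in [0, 1]")
  }
  if (max_steps < 1) stop("`max_steps` must be positive")
  cfg <- list(
    extents = extents, ranges = ranges, skew_frac = as.numeric(skew_frac),
    generation_potential = as.integer(generation_potential),
    senescence_age = if (is.na(senescence_age)) -1L else
      as.integer(senescence_age),
    suppression_factor = suppression_factor, mutation_prob = mutation_prob,
    signals = signals, decay = decay, metric = metric, thresholds = th,
    det_counts = c(tumor = as.integer(det_counts[["tumor"]]),
                   normal = as.integer(det_counts[["normal"]])),
    ignore_prob = ignore_prob, fail_emit_prob = fail_emit_prob, rho = rho,
    accel_factor = as.numeric(accel_factor),
    accel_duration = as.integer(accel_duration),
    violation_radius = as.integer(violation_radius),
    early_radius = as.integer(early_radius),
    please_die = isTRUE(please_die), im_dying = isTRUE(im_dying),
    im_dying_kills_normals = isTRUE(im_dying_kills_normals),
    emit_on_intrinsic_death = isTRUE(emit_on_intrinsic_death),
    plant = isTRUE(plant), plant_site = plant_site,
    activation_volume_frac = as.numeric(activation_volume_frac),
    confluence_frac = as.numeric(confluence_frac),
    max_steps = as.integer(max_steps), growth_cap = as.integer(growth_cap),
    wait_cap = as.integer(wait_cap),
    integrity_frac = as.numeric(integrity_frac))
  class(cfg) <- "sim_config"
  cfg
}

# flatten a sim_config into the named list the C++ engine reads
cfg_for_engine <- function(config) {
  r <- config$ranges
  s <- config$signals
  th <- config$thresholds
  list(
    normal_prolif = r$normal_prolif, tumor_prolif = r$tumor_prolif,
    normal_death = r$normal_death, tumor_death = r$tumor_death,
    skew_frac = config$skew_frac,
    generation_potential = config$generation_potential,
    senescence_age = config$senescence_age,
    suppression_factor = config$suppression_factor,
    mutation_prob = config$mutation_prob,
    signal_radius = as.integer(c(s$tumor_im_dying[1L], s$normal_im_dying[1L],
                                 s$normal_please_die[1L])),
    signal_strength = as.numeric(c(s$tumor_im_dying[2L], s$normal_im_dying[2L],
                                   s$normal_please_die[2L])),
    decay_exponential = as.integer(config$decay == "exponential"),
    metric_euclidean = as.integer(config$metric == "euclidean"),
    violation_radius = config$violation_radius,
    early_radius = config$early_radius,
    high_tumor = th$high_tumor, high_normal = th$high_normal,
    low_please_die = th$low_please_die, low_repop = th$low_repop,
    det_count_tumor = config$det_counts[["tumor"]],
    det_count_normal = config$det_counts[["normal"]],
    ignore_prob = config$ignore_prob, fail_emit_prob = config$fail_emit_prob,
    rho = config$rho, accel_factor = config$accel_factor,
    accel_duration = config$accel_duration,
    please_die = as.integer(config$please_die),
    im_dying = as.integer(config$im_dying),
    im_dying_kills_normals = as.integer(config$im_dying_kills_normals),
    emit_on_intrinsic_death = as.integer(config$emit_on_intrinsic_death))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config %dx%dx%d  ratio %s  signal set %s  q=%g f=%g  V*=%g>\n",
    x$extents[1L], x$extents[2L], x$extents[3L],
    x$ranges$ratio_label %||% "custom", x$signals$label %||% "custom",
    x$ignore_prob, x$fail_emit_prob, x$activation_volume_frac))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
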