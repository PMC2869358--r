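#' Advance a simulation state
#'
#' Runs the synchronous step loop of the engine on an explicit state.  Each
#' step executes, in fixed order: intrinsic deaths; emissions (please-die
#' from violated or primed normals, buffered death reports from the previous
#' step's protocol deaths); accumulation with stochastic ignoring; threshold
#' responses (apoptosis marks, accelerations, priming); simultaneous removal
#' of all dead cells; divisions in randomized order; clock increment.
#' Within-step cell orders are drawn from R's RNG, so `set.seed()` makes
#' trajectories bit-identical.
#'
#' @param state A [sim_state].
#' @param config A [sim_config].
#' @param steps Number of steps to run.
#' @param rescue Are the rescue protocols active?
#' @param record Record the per-step count series?
#' @return List with `state`, `series` (matrix of per-step counts),
#'   `reason`, `steps`, `n_normal`, `n_tumor`.
#' @export
sim_step <- function(state, config, steps = 1L, rescue = TRUE,
                     record = TRUE) {
  stopifnot(inherits(state, "sim_state"), inherits(config, "sim_config"))
  out <- .cpp_simulate(unclass(state), cfg_for_engine(config),
                       as.integer(steps), 0L, 0, rescue, record)
  out$state <- structure(out$state, class = "sim_state")
  out
}

run_phase <- function(state, config, max_steps, stop_mode, stop_value,
                      rescue, record) {
  out <- .cpp_simulate(unclass(state), cfg_for_engine(config),
                       as.integer(max_steps), as.integer(stop_mode),
                       as.numeric(stop_value), rescue, record)
  out$state <- structure(out$state, class = "sim_state")
  out
}

#' Grow a confluent system from a single cell
#'
#' Starts one normal cell at the grid center and runs homeostatic division
#' steps (rescue protocols off, no tumor) until the membrane is confluent --
#' occupancy at least `confluence_frac`, which at the default 0.995 means
#' exactly full on small grids and full up to the transient birth/death
#' holes on large ones -- or until `growth_cap` steps have elapsed, in which
#' case a degenerate-configuration warning is attached to the result.
#'
#' @param config A [sim_config].
#' @param seed Integer seed; the full trajectory is a deterministic function
#'   of `(config, seed)`.
#' @param record Record the growth count series?
#' @return List with `state`, `series`, `confluent` (logical), `steps`.
#' @export
grow_to_confluence <- function(config, seed = NULL, record = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  center <- config$extents %/% 2L
  budget <- config$growth_cap
  repeat {
    state <- sim_state(config$extents)
    p <- sample_population_params(config$ranges, "normal",
                                  config$generation_potential)
    state <- place_cell(state, center, "normal", prolif = p$prolif_prob,
                        death = p$death_prob,
                        genpot = p$generation_potential)
    out <- run_phase(state, config, budget, 1L, config$confluence_frac,
                     rescue = FALSE, record = record)
    budget <- budget - out$steps
    # a founder lineage can stochastically die out before the tissue takes
    # hold; re-seed a fresh founder from the same stream within the budget
    if (!identical(out$reason, "extinct") || budget <= 0L) break
  }
  confluent <- identical(out$reason, "confluent")
  if (!confluent) {
    warning("growth step cap reached before confluence; ",
            "configuration may be degenerate")
  }
  list(state = out$state, series = out$series, confluent = confluent,
       steps = out$steps)
}

# outcome classification on a terminal state; success means every tumor cell
# is gone and the healthy system was not irreversibly wiped out (final normal
# count at least integrity_frac of the at-activation baseline)
classify_outcome <- function(n_tumor, n_normal, baseline, integrity_frac,
                             timed_out) {
  if (n_tumor == 0L && n_normal >= integrity_frac * baseline) return("success")
  if (n_tumor > 0L && timed_out && n_normal > 0L) return("timeout")
  "collapse"
}

#' Run one full anti-cancer experiment
#'
#' Grows the system to confluence, plants a single tumor cell, waits (with
#' protocols inactive) until tumor occupancy reaches
#' `activation_volume_frac` if a delayed activation is configured, then
#' battles with the rescue protocols active for up to `max_steps` steps.
#'
#' The run stops early once the tumor is extinct *and* the normal population
#' holds at least `integrity_frac` of its baseline -- the normal count at
#' rescue activation -- since neither condition can subsequently fail (a
#' tumor cannot re-appear without back-mutation, and with no tumor present
#' no apoptotic signals flow).  If the tumor dies while the tissue is below
#' the baseline fraction, stepping continues so the tissue can repopulate
#' the evacuated space; classification happens on the final state:
#' `"success"` (tumor extinct, tissue intact), `"collapse"` (tissue
#' irreversibly lost), or `"timeout"` (tumor cells alive at the step cap,
#' counted as failure).
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @param record Record per-step count series for all phases?
#' @return A `sim_run` object: `outcome`, `success` (logical),
#'   `steps_elapsed` (battle steps), `final_normal_frac`,
#'   `final_tumor_frac`, `baseline_normal` (at activation),
#'   `planting_normal` (at planting), `series` (when recorded), `seed`,
#'   `confluent`, and the final `state`.
#' @export
sim_run <- function(config, seed, record = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  grown <- grow_to_confluence(config, seed = NULL, record = record)
  state <- grown$state
  series <- list(growth = grown$series)
  planting_normal <- sum(state$phen == 1L)
  if (planting_normal == 0L) {  # degenerate growth: nothing to defend
    ns <- prod(config$extents)
    return(structure(list(
      outcome = "collapse", success = FALSE, steps_elapsed = 0L,
      final_normal_frac = 0, final_tumor_frac = 0, baseline_normal = 0L,
      planting_normal = 0L, series = if (record) series else NULL,
      seed = seed, confluent = grown$confluent, state = state
    ), class = "sim_run"))
  }

  if (config$plant) state <- plant_tumor(state, config)

  # delayed activation: protocols stay off until the tumor volume threshold
  if (config$plant && config$activation_volume_frac > 0) {
    wait <- run_phase(state, config, config$wait_cap, 2L,
                      config$activation_volume_frac, rescue = FALSE,
                      record = record)
    state <- wait$state
    series$wait <- wait$series
  }
  baseline <- sum(state$phen == 1L)

  floor_n <- config$integrity_frac * baseline
  battle <- run_phase(state, config, config$max_steps, 3L, floor_n,
                      rescue = TRUE, record = record)
  state <- battle$state
  series$battle <- battle$series

  timed_out <- identical(battle$reason, "cap")
  outcome <- classify_outcome(battle$n_tumor, battle$n_normal, baseline,
                              config$integrity_frac, timed_out)
  ns <- prod(config$extents)
  structure(list(
    outcome = outcome, success = outcome == "success",
    steps_elapsed = battle$steps,
    final_normal_frac = battle$n_normal / ns,
    final_tumor_frac = battle$n_tumor / ns,
    baseline_normal = baseline, planting_normal = planting_normal,
    series = if (record) series else NULL,
    seed = seed, confluent = grown$confluent, state = state
  ), class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "<sim_run seed %d  outcome %s  battle steps %d  normal %.3f  tumor %.3f>\n",
    x$seed, x$outcome, x$steps_elapsed, x$final_normal_frac,
    x$final_tumor_frac))
  invisible(x)
}
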