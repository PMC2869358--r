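#' Wilson score interval for a binomial success rate
#'
#' @param k Number of successes.
#' @param n Number of runs (`>= 1`).
#' @param level Confidence level.
#' @return Named vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n < 1L) stop("`n` must be >= 1")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

# deterministic 31-bit hash of a condition label, used to give every sweep
# condition its own seed stream independent of condition order
hash_seed <- function(master_seed, label) {
  h <- 17
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((master_seed + h) %% 2147483629 + 1)
}

#' Run independent replicates of one configuration
#'
#' Because the life protocols are stochastic, a fixed parameter set is
#' tested multiple times; per-run seeds are derived deterministically from
#' `master_seed`, so the same `(config, n, master_seed)` always reproduces
#' the same counts.
#'
#' @param config A [sim_config].
#' @param n Number of replicates (`>= 1`).
#' @param master_seed Integer master seed.
#' @return List with `n_runs`, `n_success`, `success_rate`, `outcomes`,
#'   `seeds`.
#' @export
run_replicates <- function(config, n, master_seed) {
  stopifnot(n >= 1L)
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, n)
  outcomes <- character(n)
  for (i in seq_len(n)) {
    outcomes[i] <- sim_run(config, seed = seeds[i])$outcome
  }
  k <- sum(outcomes == "success")
  list(n_runs = n, n_success = k, success_rate = k / n, outcomes = outcomes,
       seeds = seeds)
}

sweep_row <- function(labels, rep) {
  ci <- wilson_ci(rep$n_success, rep$n_runs)
  cbind(as.data.frame(labels),
        data.frame(n_runs = rep$n_runs, n_success = rep$n_success,
                   success_rate = rep$success_rate,
                   ci_lower = ci[["lower"]], ci_upper = ci[["upper"]]))
}

#' Sweep the rescue-protocol parameter grid
#'
#' Full factorial over proliferation ratios, signal presets and response
#' threshold/deterministic-count pairs, with `replicates` independent runs
#' per condition.  This is the protocol-robustness experiment: the tumor is
#' planted at confluence and the protocols are active from planting.
#'
#' @param ratios Proliferation ratios to test.
#' @param signal_sets Signal preset labels to test.
#' @param det_pairs List of `c(tumor, normal)` deterministic request counts.
#' @param replicates Runs per condition.
#' @param master_seed Master seed; each condition derives its own stream.
#' @param base Base configuration whose other settings are held fixed.
#' @return Data frame with one row per condition: `ratio`, `signal_set`,
#'   `det_tumor`, `det_normal`, `n_runs`, `n_success`, `success_rate` and
#'   Wilson 95% CI bounds, sorted by condition.
#' @export
sweep_protocol_grid <- function(ratios = c(6, 10, 20), signal_sets = 1:5,
                                det_pairs = list(c(1L, 1L)),
                                replicates = 30L, master_seed = 1L,
                                base = sim_config()) {
  rows <- list()
  for (ratio in ratios) {
    for (set in signal_sets) {
      for (dp in det_pairs) {
        cfg <- base
        cfg$ranges <- population_ranges(ratio)
        cfg$signals <- signal_preset(set)
        cfg$det_counts <- c(tumor = as.integer(dp[1L]),
                            normal = as.integer(dp[2L]))
        label <- sprintf("ratio=%s set=%s det=%s/%s", ratio, set, dp[1L],
                         dp[2L])
        rep <- run_replicates(cfg, replicates, hash_seed(master_seed, label))
        rows[[label]] <- sweep_row(
          list(ratio = ratio, signal_set = set, det_tumor = dp[1L],
               det_normal = dp[2L]), rep)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ratio, out$signal_set, out$det_tumor,
                   out$det_normal), ]
  rownames(out) <- NULL
  out
}

#' Sweep stochastic resistance levels
#'
#' Success rate as a function of the tumor cells' per-signal ignore
#' probability `q` (with emission failure off) and, separately, of the
#' death-report emission failure probability `f` (with ignoring off).
#'
#' @param q_grid,f_grid Probability grids (either may be empty).
#' @param replicates Runs per condition.
#' @param master_seed Master seed.
#' @param base Base configuration.
#' @return Data frame with columns `param` (`"q"` or `"f"`), `value`,
#'   `n_runs`, `n_success`, `success_rate`, CI bounds.
#' @export
sweep_resistance <- function(q_grid = numeric(0), f_grid = numeric(0),
                             replicates = 30L, master_seed = 1L,
                             base = sim_config()) {
  if (length(q_grid) == 0L && length(f_grid) == 0L) {
    stop("at least one of `q_grid`, `f_grid` must be nonempty")
  }
  rows <- list()
  for (q in q_grid) {
    cfg <- base
    cfg$ignore_prob <- check_prob(q, "ignore_prob")
    cfg$fail_emit_prob <- 0
    label <- sprintf("q=%.6f", q)
    rep <- run_replicates(cfg, replicates, hash_seed(master_seed, label))
    rows[[label]] <- sweep_row(list(param = "q", value = q), rep)
  }
  for (f in f_grid) {
    cfg <- base
    cfg$fail_emit_prob <- check_prob(f, "fail_emit_prob")
    cfg$ignore_prob <- 0
    label <- sprintf("f=%.6f", f)
    rep <- run_replicates(cfg, replicates, hash_seed(master_seed, label))
    rows[[label]] <- sweep_row(list(param = "f", value = f), rep)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$param, out$value), ]
  rownames(out) <- NULL
  out
}

#' Sweep delayed activation volumes
#'
#' Holds the rescue protocols inactive until the tumor occupies a fraction
#' `V` of the system, for each `V` in the grid, and measures how late an
#' activation can still eradicate the tumor.
#'
#' @param volumes Activation volume fractions in `(0, 1)`.
#' @param replicates Runs per condition.
#' @param master_seed Master seed.
#' @param base Base configuration.
#' @return Data frame with one row per volume.
#' @export
sweep_activation_volume <- function(volumes = seq(0.1, 0.9, by = 0.1),
                                    replicates = 30L, master_seed = 1L,
                                    base = sim_config()) {
  if (any(volumes <= 0 | volumes >= 1)) stop("`volumes` must lie in (0, 1)")
  rows <- list()
  for (v in volumes) {
    cfg <- base
    cfg$activation_volume_frac <- v
    label <- sprintf("V=%.6f", v)
    rep <- run_replicates(cfg, replicates, hash_seed(master_seed, label))
    rows[[label]] <- sweep_row(list(activation_volume = v), rep)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$activation_volume), ]
  rownames(out) <- NULL
  out
}

#' Summarize raw success counts
#'
#' Adds `success_rate` and Wilson 95% binomial confidence bounds to a table
#' of per-condition counts.
#'
#' @param results Data frame with columns `n_success` and `n_runs`.
#' @return The table with `success_rate`, `ci_lower`, `ci_upper`
#'   (re)computed.
#' @export
summarize_sweep <- function(results) {
  stopifnot(all(c("n_success", "n_runs") %in% names(results)),
            nrow(results) >= 1L, all(results$n_runs >= 1L),
            all(results$n_success <= results$n_runs))
  ci <- t(mapply(wilson_ci, results$n_success, results$n_runs))
  results$success_rate <- results$n_success / results$n_runs
  results$ci_lower <- ci[, "lower"]
  results$ci_upper <- ci[, "upper"]
  results
}

#' Largest resistance level still tolerated by the protocols
#'
#' From a resistance sweep, the largest parameter value whose success rate
#' is at least `min_rate` -- an estimate of the protocol-break point.
#'
#' @param sweep Result of [sweep_resistance()] filtered to one `param`.
#' @param min_rate Required success rate.
#' @return One row of `sweep` (or zero rows if none qualifies).
#' @export
critical_resistance <- function(sweep, min_rate = 0.95) {
  ok <- sweep[sweep$success_rate >= min_rate, , drop = FALSE]
  if (nrow(ok) == 0L) return(ok)
  ok[which.max(ok$value), , drop = FALSE]
}
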