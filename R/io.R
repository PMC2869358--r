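config_keys <- function() {
  names(formals(sim_config))
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) file of configuration keys, validates every value
#' against its domain, fills defaults for everything unstated, and rejects
#' unknown keys by name.  `ratio` and `signal_set` select the documented
#' presets; custom populations or signals require explicit `ranges` /
#' `signals` blocks.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param quiet Suppress the effective-configuration echo.
#' @return A validated [sim_config].
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- config_keys()
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in c("ranges", "signals", "thresholds")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.list(raw[[nm]])
  }
  if (!is.null(raw$det_counts)) {
    raw$det_counts <- c(tumor = as.integer(raw$det_counts[["tumor"]]),
                        normal = as.integer(raw$det_counts[["normal"]]))
  }
  cfg <- do.call(sim_config, raw)
  if (!quiet) {
    message("effective configuration:\n",
            paste(" ", utils::capture.output(utils::str(
              unclass(cfg), give.attr = FALSE)), collapse = "\n"))
  }
  cfg
}

#' Write a configuration file
#'
#' Serializes a [sim_config] to YAML such that [load_config()] returns an
#' identical configuration (load -> dump -> load is a fixed point).
#'
#' @param config A [sim_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$senescence_age <- if (out$senescence_age < 0L) NULL else
    out$senescence_age
  out$ranges$ratio_label <- NULL
  out$signals$label <- NULL
  out$det_counts <- as.list(out$det_counts)
  yaml::write_yaml(out, path)
  invisible(path)
}

config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2147480009
  sprintf("%08x", as.integer(h))
}

#' Write a results table to CSV
#'
#' Writes one row per condition or run, with a stable column order, floats
#' at fixed precision, and comment headers recording the seed and the hash
#' of the configuration that produced the table.
#'
#' @param table Nonempty data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param config Configuration recorded (as a hash) in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, seed = NA, config = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("`table` must be a nonempty data frame")
  }
  num <- vapply(table, is.double, logical(1L))
  table[num] <- lapply(table[num], function(x) round(x, 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %s", seed),
               sprintf("# config_hash: %s",
                       if (is.null(config)) "none" else config_hash(config))),
             con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#' @param path Path to the CSV.
#' @return Data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Export a grid snapshot
#'
#' One CSV row per occupied site (`x`, `y`, `z`, `phenotype`, `cell_id`,
#' `age`, `generation`) plus a JSON sidecar (`<path>.json`) holding the
#' extents and the time step.
#'
#' @param state A [sim_state].
#' @param path Output CSV path.
#' @param seed Seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path, seed = NA) {
  stopifnot(inherits(state, "sim_state"))
  occ <- which(state$phen != 0L)
  pos <- site_position(state, occ)
  df <- data.frame(x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
                   phenotype = c("free", "normal", "tumor")[state$phen[occ] + 1L],
                   cell_id = state$id[occ], age = state$age[occ],
                   generation = state$gen[occ])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(extents = state$extents, step = state$clock, seed = seed,
         n_normal = sum(state$phen == 1L), n_tumor = sum(state$phen == 2L)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a snapshot back into a data frame
#' @param path CSV path written by [write_snapshot()].
#' @return List with `cells` (data frame) and `meta` (sidecar list).
#' @export
read_snapshot <- function(path) {
  list(cells = utils::read.csv(path),
       meta = jsonlite::read_json(paste0(path, ".json"),
                                  simplifyVector = TRUE))
}
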