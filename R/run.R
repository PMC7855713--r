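# ---------------------------------------------------------------------------
# Run orchestration: execute ticks, snapshot tables, write artifacts.
# ---------------------------------------------------------------------------

#' Run a simulation
#'
#' Builds the initial state from a configuration and advances it either for
#' a fixed number of ticks or until the cell population is quiescent. When
#' `out_dir` is given, the event log, cell/synapse/axon tables, metrics and
#' a run manifest are written there.
#'
#' @param config an `organoid_config` (see [load_config()]).
#' @param seed optional PRNG seed overriding the configuration's.
#' @param ticks optional tick budget overriding the configuration's.
#' @param out_dir optional output directory.
#' @param quiescence if `TRUE`, stop early once the census (live counts,
#'   births, deaths) has not changed for `quiescence_window` ticks.
#' @param quiescence_window plateau length, in ticks, that counts as
#'   quiescent.
#' @return the final `organoid_sim` state, invisibly.
#' @export
run_simulation <- function(config, seed = NULL, ticks = NULL, out_dir = NULL,
                           quiescence = FALSE, quiescence_window = 80L) {
  sim <- build_initial_state(config, seed = seed)
  budget <- as.integer(ticks %||% config$model$ticks)
  if (quiescence) {
    run_until_quiescent(sim, max_ticks = budget, window = quiescence_window)
  } else {
    for (i in seq_len(budget)) step(sim)
  }
  if (!is.null(out_dir)) write_run_outputs(sim, out_dir)
  invisible(sim)
}

#' Run until the population is quiescent
#'
#' Steps the state until live counts, cumulative births and cumulative
#' deaths have all been unchanged for `window` consecutive ticks, or until
#' `max_ticks` is reached. Connectivity events (axon growth, synapses) do
#' not reset the plateau; quiescence is a population-level notion.
#'
#' @param sim an `organoid_sim`.
#' @param max_ticks hard tick cap.
#' @param window plateau length in ticks.
#' @return the state, invisibly.
#' @export
run_until_quiescent <- function(sim, max_ticks, window = 80L) {
  fingerprint <- function() c(sim$census, sim$births, sim$deaths)
  last <- fingerprint()
  last_change <- sim$tick
  while (sim$tick < max_ticks) {
    step(sim)
    now <- fingerprint()
    if (!identical(now, last)) {
      last <- now
      last_change <- sim$tick
    } else if (sim$tick - last_change >= window) {
      break
    }
  }
  invisible(sim)
}

# ---------------------------------------------------------------------------
# Snapshot tables.
# ---------------------------------------------------------------------------

#' Cell snapshot table
#'
#' @param sim an `organoid_sim`.
#' @param include_removed include removed cells (with their last position).
#' @return a data.frame with one row per object: id, type, 0-based x/y/z,
#'   status, birth/removal ticks, compartment flags, axon length (in unit
#'   displacements), terminal count and growth-cone state.
#' @export
cells_snapshot <- function(sim, include_removed = FALSE) {
  ids <- sort(as.integer(ls(sim$cells)))
  rows <- lapply(ids, function(id) {
    cl <- sim$cells[[as.character(id)]]
    if (!include_removed && cl$status == "removed") return(NULL)
    cc <- index_to_coord(cl$pos, sim$edge)[1L, ]
    list(id = cl$id, type = cl$type, x = cc[1L], y = cc[2L], z = cc[3L],
         status = cl$status, born = cl$born, removed_tick = cl$removed_tick,
         has_axon = !is.null(cl$axon),
         has_dendrite = "dendrite_formed" %in% cl$flags,
         spine_ready = "spine_ready" %in% cl$flags,
         axon_length = if (is.null(cl$axon)) 0L else cl$axon$n - 1L,
         terminal_count = if (is.null(cl$axon)) 0L else length(cl$axon$terminals),
         cone_state = if (is.null(cl$axon)) "" else cl$axon$state)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(id = integer(0), type = character(0), x = integer(0),
                      y = integer(0), z = integer(0), status = character(0),
                      born = integer(0), removed_tick = integer(0),
                      has_axon = logical(0), has_dendrite = logical(0),
                      spine_ready = logical(0), axon_length = integer(0),
                      terminal_count = integer(0), cone_state = character(0)))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Synapse table
#'
#' @param sim an `organoid_sim`.
#' @return a data.frame (formed_tick, pre_id, pre_type, post_id, post_type,
#'   category), one row per formed synapse in formation order.
#' @export
connections_table <- function(sim) {
  n <- sim$conn_n
  type_of <- function(ids) vapply(ids, function(id) sim$cells[[as.character(id)]]$type,
                                  character(1))
  if (n == 0L) {
    return(data.frame(formed_tick = integer(0), pre_id = integer(0),
                      pre_type = character(0), post_id = integer(0),
                      post_type = character(0), category = character(0)))
  }
  data.frame(formed_tick = sim$conn_tick[seq_len(n)],
             pre_id = sim$conn_pre[seq_len(n)],
             pre_type = type_of(sim$conn_pre[seq_len(n)]),
             post_id = sim$conn_post[seq_len(n)],
             post_type = type_of(sim$conn_post[seq_len(n)]),
             category = sim$conn_cat[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Axon table
#'
#' @param sim an `organoid_sim`.
#' @return a data.frame (cell_id, cell_type, path_length, terminal_count,
#'   cone_state) over live cells that sprouted an axon.
#' @export
axon_table <- function(sim) {
  snap <- cells_snapshot(sim)
  snap <- snap[snap$has_axon, c("id", "type", "axon_length", "terminal_count",
                                "cone_state")]
  names(snap) <- c("cell_id", "cell_type", "path_length", "terminal_count",
                   "cone_state")
  rownames(snap) <- NULL
  snap
}

#' Factor field dump
#'
#' @param sim an `organoid_sim`.
#' @param factors factor ids to dump (default all).
#' @return a data.frame (tick, factor, x, y, z, concentration) over nonzero
#'   entries.
#' @export
fields_table <- function(sim, factors = names(sim$fields)) {
  out <- lapply(factors, function(fn) {
    f <- sim$fields[[fn]]
    nz <- which(f$values > 0)
    if (length(nz) == 0L) return(NULL)
    cc <- index_to_coord(nz, sim$edge)
    data.frame(tick = sim$tick, factor = fn, x = cc[, 1L], y = cc[, 2L],
               z = cc[, 3L], concentration = f$values[nz],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(tick = integer(0), factor = character(0), x = integer(0),
                      y = integer(0), z = integer(0), concentration = numeric(0)))
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# Artifact writers.
# ---------------------------------------------------------------------------

#' Write run artifacts
#'
#' Writes events.jsonl (one JSON record per logged event), cells.csv,
#' synapses.csv, axons.csv, metrics.json, resolved_config.yaml and
#' manifest.json into `out_dir`.
#'
#' @param sim an `organoid_sim`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- events_log(sim)
  con <- file(file.path(out_dir, "events.jsonl"), "w")
  if (nrow(log)) {
    for (i in seq_len(nrow(log))) {
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE), con)
    }
  }
  close(con)
  utils::write.csv(cells_snapshot(sim), file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(connections_table(sim), file.path(out_dir, "synapses.csv"),
                   row.names = FALSE)
  utils::write.csv(axon_table(sim), file.path(out_dir, "axons.csv"),
                   row.names = FALSE)
  write_config(sim$cfg, file.path(out_dir, "resolved_config.yaml"))
  m <- run_metrics(sim)
  jsonlite::write_json(as.list(m), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_md5 = unname(tools::md5sum(file.path(out_dir, "resolved_config.yaml"))),
    seed = sim$seed,
    ticks_run = sim$tick,
    lattice_edge = sim$edge,
    artifacts = c("events.jsonl", "cells.csv", "synapses.csv", "axons.csv",
                  "metrics.json", "resolved_config.yaml"),
    package_version = as.character(utils::packageVersion("organoidsim"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run replicates over several seeds
#'
#' Runs the same configuration once per seed and aggregates the per-run
#' metrics as mean and standard deviation (reported as 0 with an `n = 1`
#' flag for a single replicate).
#'
#' @param config an `organoid_config`.
#' @param seeds integer vector of PRNG seeds.
#' @param ticks optional tick budget override.
#' @param quiescence stop each run at population quiescence.
#' @return a list with `per_seed` (metric matrix, one row per seed),
#'   `mean`, `sd` and `n`.
#' @export
run_replicates <- function(config, seeds, ticks = NULL, quiescence = FALSE) {
  stopifnot(length(seeds) >= 1L)
  per <- lapply(seeds, function(s) {
    sim <- run_simulation(config, seed = s, ticks = ticks,
                          quiescence = quiescence)
    run_metrics(sim)
  })
  keys <- unique(unlist(lapply(per, names)))
  mat <- do.call(rbind, lapply(per, function(m) m[keys]))
  colnames(mat) <- keys
  rownames(mat) <- as.character(seeds)
  mat[is.na(mat)] <- 0
  list(per_seed = mat,
       mean = colMeans(mat),
       sd = if (nrow(mat) > 1L) apply(mat, 2L, stats::sd) else
         stats::setNames(rep(0, ncol(mat)), colnames(mat)),
       n = nrow(mat))
}
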