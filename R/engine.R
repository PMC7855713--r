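# ---------------------------------------------------------------------------
# Discrete-event core.
#
# The model advances in integer ticks. All pending work lives in a queue of
# owner-bound events; one transition (`step`) drains the events due at the
# current tick, applies the mechanisms they trigger, runs the per-tick field
# dynamics, and increments the tick. Events due at the same tick execute in
# (priority, insertion) order, with lower priority values first, so
# destructive mechanisms resolve before constructive ones; independent
# events commute, and conflicts between interdependent events (e.g. two
# movers claiming one coordinate) are resolved by that deterministic order,
# the loser re-evaluating next tick. All stochastic choices draw from R's
# RNG in this canonical order, so a fixed (configuration, seed) pair replays
# to an identical event log.
# ---------------------------------------------------------------------------

#' Construct an event
#'
#' Events are owner-bound, prioritized units of work. User-facing events
#' reference a signaling pathway declared in the biological configuration;
#' the pathway's guard and stochastic gate are (re-)evaluated when the
#' event executes.
#'
#' @param owner_id id of a live logical object.
#' @param pathway_id a pathway declared in the biological configuration.
#' @param due_tick tick at which the event becomes due (>= current tick).
#' @param priority integer; lower values execute earlier within a tick.
#'   Defaults to the pathway's priority.
#' @return a list of class `sim_event`.
#' @export
sim_event <- function(owner_id, pathway_id, due_tick, priority = NULL) {
  structure(list(owner = owner_id, pw = pathway_id,
                 due = as.integer(due_tick), prio = priority,
                 seq = NA_integer_, epoch = NA_integer_, internal = NULL),
            class = "sim_event")
}

#' Schedule an event
#'
#' Inserts an event into the queue. Events are dequeued in
#' (due tick, priority, insertion order).
#'
#' @param state a simulation state.
#' @param event a [sim_event()].
#' @return the state, invisibly.
#' @export
schedule <- function(state, event) {
  if (event$due < state$tick)
    stop("event due_tick ", event$due, " precedes current tick ", state$tick)
  cl <- state$cells[[as.character(event$owner)]]
  if (is.null(cl) || cl$status == "removed")
    stop("unknown or removed event owner: ", event$owner)
  if (is.null(event$prio)) {
    pw <- state$bio$pathways[[event$pw]]
    event$prio <- if (is.null(pw)) 50L else pw$priority
  }
  event$epoch <- cl$epoch
  push_event(state, event)
  invisible(state)
}

# Internal enqueue; assigns the insertion sequence number unless the event
# already carries one (deferred events keep theirs so relative order among
# them is preserved).
push_event <- function(sim, ev) {
  if (isTRUE(sim$in_step) && ev$due <= sim$tick) ev$due <- sim$tick + 1L
  if (is.na(ev$seq)) {
    sim$seq <- sim$seq + 1L
    ev$seq <- sim$seq
  }
  k <- as.character(ev$due)
  b <- sim$queue[[k]]
  if (is.null(b)) {
    b <- new.env(parent = emptyenv())
    b$items <- vector("list", 64L)
    b$n <- 0L
    sim$queue[[k]] <- b
  }
  n <- b$n + 1L
  if (n > length(b$items)) b$items <- c(b$items, vector("list", length(b$items)))
  b$items[[n]] <- ev
  b$n <- n
  invisible(sim)
}

schedule_pathway_event <- function(sim, cl, pwid, due, epoch = cl$epoch) {
  pw <- sim$bio$pathways[[pwid]]
  if (is.null(pw)) stop("unknown pathway: ", pwid)
  push_event(sim, list(owner = cl$id, pw = pwid, due = as.integer(due),
                       prio = pw$priority, seq = NA_integer_, epoch = epoch,
                       internal = NULL))
}

schedule_internal <- function(sim, cl, fn, due, params = list(),
                              priority = 5L, epoch = cl$epoch) {
  push_event(sim, list(owner = cl$id, pw = NA_character_,
                       due = as.integer(due), prio = priority,
                       seq = NA_integer_, epoch = epoch,
                       internal = list(fn = fn, params = params)))
}

#' Advance the simulation by one tick
#'
#' Processes every event due at the current tick in (priority, insertion)
#' order, applies one diffusion and one degradation step to every active
#' factor field, records the census, and increments the tick.
#'
#' @param state a simulation state.
#' @return the state, invisibly.
#' @export
step <- function(state) {
  t <- state$tick
  k <- as.character(t)
  b <- state$queue[[k]]
  if (!is.null(b)) {
    rm(list = k, envir = state$queue)
    bucket <- b$items[seq_len(b$n)]
    prios <- vapply(bucket, function(e) as.integer(e$prio), integer(1))
    seqs <- vapply(bucket, function(e) e$seq, integer(1))
    state$in_step <- TRUE
    for (j in order(prios, seqs)) exec_event(state, bucket[[j]])
    state$in_step <- FALSE
  }
  for (f in state$fields) {
    diffuse_step(f)
    degrade_step(f)
  }
  record_census(state)
  state$tick <- t + 1L
  invisible(state)
}

exec_event <- function(sim, ev) {
  cl <- sim$cells[[as.character(ev$owner)]]
  if (is.null(cl) || cl$status == "removed" || ev$epoch != cl$epoch) {
    log_event(sim, 1L, ev$owner, "?", ev$pw, "dropped", NA_integer_,
              "stale or ownerless event")
    return(invisible(NULL))
  }
  if (cl$status == "paused" && is.null(ev$internal)) {
    ev$due <- sim$tick + 1L
    push_event(sim, ev) # frozen: retained with original insertion order
    return(invisible(NULL))
  }
  if (!is.null(ev$internal)) {
    fn <- internal_ops[[ev$internal$fn]]
    if (is.null(fn)) stop("unknown internal op: ", ev$internal$fn)
    fn(sim, cl, ev)
  } else {
    run_pathway(sim, cl, ev)
  }
  invisible(NULL)
}

run_pathway <- function(sim, cl, ev) {
  pwid <- ev$pw
  pw <- sim$bio$pathways[[pwid]]
  if (is.null(pw)) stop("event references unknown pathway: ", pwid)
  if (pwid %in% cl$stopped) return(invisible(NULL))
  ok <- is.null(pw$guard) || eval_pred_idx(sim, pw$guard, cl$pos)
  fired <- FALSE
  if (ok) {
    p <- gate_prob(sim, pw, cl)
    pass <- if (p >= 1) TRUE else if (p <= 0) FALSE else stats::runif(1L) < p
    if (pass) {
      fired <- TRUE
      mech <- mechanisms_registry[[pw$mechanism]]
      if (is.null(mech)) stop("unknown mechanism: ", pw$mechanism)
      mech(sim, cl, pw, ev)
    } else {
      log_event(sim, 1L, cl$id, cl$type, pwid, "gate_failed", cl$pos)
    }
  } else {
    log_event(sim, 1L, cl$id, cl$type, pwid, "guard_failed", cl$pos)
  }
  # Rescheduling. Cyclic pathways restart themselves regardless of outcome;
  # conditional pathways retry on guard/gate failure when their policy says
  # so. A mechanism that bumped the owner's epoch (differentiation, death)
  # implicitly cancels the cycle because the stale epoch drops the event.
  if (pw$trigger$kind == "cyclic") {
    if (cl$status != "removed" && !(pwid %in% cl$stopped) && ev$epoch == cl$epoch)
      schedule_pathway_event(sim, cl, pwid, sim$tick + pw$trigger$period,
                             epoch = ev$epoch)
  } else if (!fired && identical(pw$policy, "retry")) {
    if (cl$status != "removed" && !(pwid %in% cl$stopped) && ev$epoch == cl$epoch)
      schedule_pathway_event(sim, cl, pwid, sim$tick + pw$retry_delay,
                             epoch = ev$epoch)
  }
  invisible(NULL)
}

gate_prob <- function(sim, pw, cl) {
  g <- pw$gate
  if (is.null(g)) return(1)
  if (is.numeric(g)) return(g)
  conc <- sensed_conc(sim, g$factor, cl$pos, g$radius %||% 0L)
  switch(g$kind,
         linear = min(1, conc / g$scale),
         hill = {
           n <- g$n %||% 2
           conc^n / (conc^n + g$k^n)
         },
         stop("unknown gate kind: ", g$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Predicate trees.
#
# Guards are nested AND/OR lists over leaf conditions on factor
# concentrations. A leaf is list(factor=, op = "ge"|"le"|"between",
# threshold = <1 or 2 values>, radius = <0 for own coordinate, r for the
# total over the Chebyshev ball of radius r>). Lower bounds use >= and
# upper bounds <=; an empty tree is vacuously true.
# ---------------------------------------------------------------------------

#' Evaluate a predicate tree
#'
#' @param tree a nested guard (see Details in [load_config()]); `NULL` or an
#'   empty list is vacuously true.
#' @param state a simulation state.
#' @param at integer coordinate of length 3 at which leaf conditions are
#'   evaluated.
#' @return logical scalar; evaluation never mutates the state.
#' @export
evaluate_predicate <- function(tree, state, at) {
  eval_pred_idx(state, tree, coord_to_index(at, state$edge))
}

eval_pred_idx <- function(sim, tree, idx) {
  if (is.null(tree) || length(tree) == 0L) return(TRUE)
  if (!is.null(tree$all)) {
    for (child in tree$all) if (!eval_pred_idx(sim, child, idx)) return(FALSE)
    return(TRUE)
  }
  if (!is.null(tree$any)) {
    for (child in tree$any) if (eval_pred_idx(sim, child, idx)) return(TRUE)
    return(FALSE)
  }
  # leaf
  if (is.null(tree$factor)) stop("malformed predicate node")
  if (is.null(sim$fields[[tree$factor]]))
    stop("predicate references undeclared factor: ", tree$factor)
  v <- sensed_conc(sim, tree$factor, idx, tree$radius %||% 0L)
  th <- tree$threshold
  switch(tree$op,
         ge = v >= th[1L],
         le = v <= th[1L],
         between = v >= th[1L] && v <= th[2L],
         stop("unknown predicate op: ", tree$op))
}

# ---------------------------------------------------------------------------
# Pathway interruption semantics.
# ---------------------------------------------------------------------------

#' Interrupt an object's signaling pathways
#'
#' `pause` freezes the owner's queued events (they are retained and deferred
#' tick by tick, preserving their relative order) until `release`.
#' `disrupt` discards all queued events; the owner's pathway set is expected
#' to be re-launched by the mechanism that disrupted it (differentiation
#' re-launches the new type's pathways). `terminate` discards all queued
#' events permanently and bars the owner from any future pathway execution;
#' it is the event-side half of cell removal and is irreversible.
#'
#' @param state a simulation state.
#' @param owner_id a live object id.
#' @param mode one of `"pause"`, `"release"`, `"disrupt"`, `"terminate"`.
#' @return the state, invisibly.
#' @export
interrupt_pathways <- function(state, owner_id,
                               mode = c("pause", "release", "disrupt", "terminate")) {
  mode <- match.arg(mode)
  cl <- state$cells[[as.character(owner_id)]]
  if (is.null(cl)) stop("unknown owner: ", owner_id)
  switch(mode,
         pause = {
           cl$status <- "paused"
         },
         release = {
           if (cl$status == "paused") cl$status <- "active"
         },
         disrupt = {
           cl$epoch <- cl$epoch + 1L
         },
         terminate = {
           cl$epoch <- cl$epoch + 1L
           cl$stopped <- names(state$bio$pathways)
         })
  invisible(state)
}

# ---------------------------------------------------------------------------
# Cells, census and the event log.
# ---------------------------------------------------------------------------

new_cell <- function(sim, type, idx, kind = "cell", initial = FALSE) {
  sim$next_id <- sim$next_id + 1L
  id <- sim$next_id
  cl <- new.env(parent = emptyenv())
  cl$id <- id
  cl$type <- type
  cl$pos <- idx
  cl$kind <- kind
  cl$status <- "active"
  cl$epoch <- 0L
  cl$stopped <- character(0)
  cl$flags <- character(0)
  cl$axon <- NULL
  cl$born <- sim$tick
  cl$removed_tick <- NA_integer_
  sim$cells[[as.character(id)]] <- cl
  if (kind == "cell") {
    if (sim$lat$occ[idx] != 0L)
      stop("coordinate already occupied by cell ", sim$lat$occ[idx])
    sim$lat$occ[idx] <- id
  } else {
    pass_add(sim$lat, idx, paste0("mark:", id))
  }
  sim$census[type] <- sim$census[type] + 1L
  if (is.null(sim$first_seen[[type]])) sim$first_seen[[type]] <- sim$tick
  if (!initial) sim$births <- sim$births + 1L
  cl
}

remove_cell <- function(sim, cl, outcome) {
  if (cl$status == "removed") return(invisible(NULL))
  cl$epoch <- cl$epoch + 1L
  cl$status <- "removed"
  cl$removed_tick <- sim$tick
  if (cl$kind == "cell") sim$lat$occ[cl$pos] <- 0L
  if (!is.null(cl$axon) && cl$axon$n > 1L) {
    lab <- paste0("axon:", cl$id)
    for (i in cl$axon$path[seq_len(cl$axon$n)][-1L]) pass_remove(sim$lat, i, lab)
  }
  sim$census[cl$type] <- sim$census[cl$type] - 1L
  sim$deaths <- sim$deaths + 1L
  log_event(sim, 0L, cl$id, cl$type, NA_character_, outcome, cl$pos)
  invisible(NULL)
}

record_census <- function(sim) {
  n <- sim$hist_n + 1L
  if (n > length(sim$hist)) sim$hist <- c(sim$hist, vector("list", length(sim$hist)))
  sim$hist[[n]] <- c(tick = sim$tick, sim$census,
                     .births = sim$births, .deaths = sim$deaths)
  sim$hist_n <- n
  invisible(NULL)
}

log_event <- function(sim, level, owner, otype, pathway, outcome, idx,
                      details = "") {
  if (level > sim$log_level) return(invisible(NULL))
  if (is.null(idx) || is.na(idx)) {
    x <- y <- z <- NA_integer_
  } else {
    cc <- index_to_coord(idx, sim$edge)[1L, ]
    x <- cc[1L]; y <- cc[2L]; z <- cc[3L]
  }
  n <- sim$log_n + 1L
  if (n > length(sim$log)) sim$log <- c(sim$log, vector("list", max(64L, length(sim$log))))
  sim$log[[n]] <- list(tick = sim$tick, owner_id = owner, owner_type = otype,
                       pathway = if (is.null(pathway) || is.na(pathway)) "" else pathway,
                       outcome = outcome, x = x, y = y, z = z,
                       details = details)
  sim$log_n <- n
  invisible(NULL)
}

#' Extract the event log
#'
#' One row per logged event: tick, owner id and type, pathway, outcome,
#' coordinate and free-text details. At the default log level only
#' state-changing outcomes (divisions, differentiations, deaths, sproutings,
#' terminals, spines, synapses) are recorded; level 1 also records guard and
#' gate failures and dropped stale events.
#'
#' @param state a simulation state.
#' @return a data.frame.
#' @export
events_log <- function(state) {
  n <- state$log_n
  if (n == 0L) {
    return(data.frame(tick = integer(0), owner_id = integer(0),
                      owner_type = character(0), pathway = character(0),
                      outcome = character(0), x = integer(0), y = integer(0),
                      z = integer(0), details = character(0)))
  }
  rows <- state$log[seq_len(n)]
  data.frame(
    tick = vapply(rows, `[[`, integer(1), "tick"),
    owner_id = vapply(rows, `[[`, integer(1), "owner_id"),
    owner_type = vapply(rows, `[[`, character(1), "owner_type"),
    pathway = vapply(rows, `[[`, character(1), "pathway"),
    outcome = vapply(rows, `[[`, character(1), "outcome"),
    x = vapply(rows, `[[`, integer(1), "x"),
    y = vapply(rows, `[[`, integer(1), "y"),
    z = vapply(rows, `[[`, integer(1), "z"),
    details = vapply(rows, `[[`, character(1), "details"),
    stringsAsFactors = FALSE
  )
}

launch_initial_pathways <- function(sim, cl, delay = 1L) {
  ty <- sim$bio$types[[cl$type]]
  cl$stopped <- character(0)
  for (pwid in ty$pathways) {
    pw <- sim$bio$pathways[[pwid]]
    d <- pw$trigger$start_delay %||% delay
    schedule_pathway_event(sim, cl, pwid, sim$tick + d)
  }
  invisible(NULL)
}
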