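# ---------------------------------------------------------------------------
# Built-in mechanisms.
#
# Mechanisms are the fixed behavioral vocabulary of the simulator; a
# signaling pathway is a mechanism plus parameters, a trigger (cyclic or
# conditional), a guard predicate and an optional stochastic gate. Cells
# can only do what a pathway attached to their type lets them do.
#
# Default priorities (lower executes earlier within a tick) are chosen so
# destructive events resolve before constructive ones:
#   death 0 < internal completions 5 < division 10 < differentiation 20
#   < locomotion 30 < axon growth 40..43 < transduction 45 < secretion 50.
# ---------------------------------------------------------------------------

mechanism_priorities <- c(
  apoptose = 0L, necrose = 0L,
  divide_symmetric = 10L, divide_asymmetric = 10L,
  differentiate = 20L,
  move = 30L,
  grow_axon = 40L, form_terminal = 41L, form_spine = 42L, form_synapse = 43L,
  transduce = 45L,
  secrete_factor = 50L
)

#' Names of the built-in mechanisms
#' @return character vector.
#' @export
mechanism_names <- function() names(mechanism_priorities)

# --- secretion --------------------------------------------------------------

mech_secrete <- function(sim, cl, pw, ev) {
  f <- sim$fields[[pw$params$factor]]
  secrete(f, index_to_coord(cl$pos, sim$edge)[1L, ],
          amount = pw$params$amount %||% NULL)
  log_event(sim, 1L, cl$id, cl$type, pw$id, "secreted", cl$pos, pw$params$factor)
}

# --- transduction -----------------------------------------------------------
# The configurable glue: when guard and gate pass, perform the configured
# actions: launch pathways, stop pathways, set flags, sprout compartments.

mech_transduce <- function(sim, cl, pw, ev) {
  a <- pw$params
  if (!is.null(a$sprout)) {
    for (what in a$sprout) {
      if (what == "axon" && is.null(cl$axon)) {
        ax <- new.env(parent = emptyenv())
        ax$path <- cl$pos
        ax$n <- 1L
        ax$state <- "searching"
        ax$terminals <- integer(0)
        ax$wait <- 0L
        cl$axon <- ax
        cl$flags <- union(cl$flags, "axon_formed")
        log_event(sim, 0L, cl$id, cl$type, pw$id, "sprouted_axon", cl$pos)
      } else if (what == "dendrite" && !("dendrite_formed" %in% cl$flags)) {
        cl$flags <- union(cl$flags, "dendrite_formed")
        log_event(sim, 0L, cl$id, cl$type, pw$id, "sprouted_dendrite", cl$pos)
      }
    }
  }
  if (!is.null(a$set_flags)) cl$flags <- union(cl$flags, a$set_flags)
  if (!is.null(a$stop)) cl$stopped <- union(cl$stopped, a$stop)
  if (!is.null(a$launch)) {
    for (pwid in a$launch) {
      lpw <- sim$bio$pathways[[pwid]]
      schedule_pathway_event(sim, cl, pwid,
                             sim$tick + (lpw$trigger$start_delay %||% 1L))
    }
  }
  if (isTRUE(a$once)) cl$stopped <- union(cl$stopped, pw$id)
  if (is.null(a$sprout)) # sprouting already logged
    log_event(sim, 1L, cl$id, cl$type, pw$id, "transduced", cl$pos)
}

# --- locomotion -------------------------------------------------------------
# Single-step gradient following, or targeted long-range movement along an
# A* route (recomputed when blocked), one unit displacement per event.

mech_move <- function(sim, cl, pw, ev) {
  p <- pw$params
  from <- index_to_coord(cl$pos, sim$edge)[1L, ]
  if (!is.null(p$goal)) {
    goal <- as.integer(p$goal)
    if (all(from == goal)) return(invisible(NULL))
    if (is.null(cl$route) || cl$route$n > length(cl$route$idx) ||
        sim$lat$occ[cl$route$idx[cl$route$n]] != 0L) {
      pm <- astar_path(sim$lat, from, goal)
      if (is.null(pm)) {
        cl$route <- NULL
        log_event(sim, 1L, cl$id, cl$type, pw$id, "move_blocked", cl$pos)
        return(invisible(NULL))
      }
      cl$route <- list(idx = coord_to_index(pm, sim$edge), n = 2L)
    }
    to_idx <- cl$route$idx[cl$route$n]
    if (sim$lat$occ[to_idx] != 0L) return(invisible(NULL)) # re-plan next event
    to <- index_to_coord(to_idx, sim$edge)[1L, ]
    res <- displace(sim$lat, cl$id, from, to, eject = FALSE)
    if (res$ok) {
      cl$pos <- to_idx
      cl$route$n <- cl$route$n + 1L
      log_event(sim, 1L, cl$id, cl$type, pw$id, "moved", cl$pos)
    }
    return(invisible(NULL))
  }
  rule <- gradient_rule(p$factor, p$direction %||% "gradient",
                        min_conc = p$min_conc, max_conc = p$max_conc)
  to_idx <- pick_gradient_index(sim, cl$pos, rule)
  if (is.null(to_idx)) return(invisible(NULL))
  to <- index_to_coord(to_idx, sim$edge)[1L, ]
  res <- displace(sim$lat, cl$id, from, to, eject = FALSE)
  if (res$ok) {
    cl$pos <- to_idx
    log_event(sim, 1L, cl$id, cl$type, pw$id, "moved", cl$pos)
  }
}

# --- proliferation ----------------------------------------------------------
# Division pauses every other pathway of the parent until completion; the
# daughter is placed at a uniformly chosen vacant unit-displacement
# neighbor. When the parent is fully enclosed at initiation the division is
# deferred to the next cycle; when enclosure happens during completion the
# completion retries a bounded number of times and then aborts.

mech_divide <- function(sim, cl, pw, ev) {
  max_rounds <- pw$params$max_rounds
  if (!is.null(max_rounds) && (cl$rounds %||% 0L) >= max_rounds) {
    # proliferative capacity exhausted; retire the division pathway
    cl$stopped <- union(cl$stopped, pw$id)
    return(invisible(NULL))
  }
  if (length(vacant_nbr_indices(sim$lat, cl$pos)) == 0L) {
    log_event(sim, 1L, cl$id, cl$type, pw$id, "division_deferred", cl$pos)
    return(invisible(NULL))
  }
  daughter <- if (pw$mechanism == "divide_symmetric") cl$type else pw$params$daughter
  check_potency(sim, cl$type, daughter, pw)
  cl$status <- "paused"
  schedule_internal(sim, cl, "div_complete",
                    sim$tick + (pw$params$duration %||% 1L),
                    params = list(daughter = daughter, attempts = 0L,
                                  pw = pw$id))
}

check_potency <- function(sim, parent, daughter, pw) {
  if (pw$mechanism == "divide_asymmetric") {
    pr <- sim$bio$types[[parent]]$potency
    dr <- sim$bio$types[[daughter]]$potency
    if (dr >= pr)
      stop("asymmetric division requires strictly lower daughter potency: ",
           parent, " -> ", daughter)
  }
}

int_div_complete <- function(sim, cl, ev) {
  p <- ev$internal$params
  vac <- vacant_nbr_indices(sim$lat, cl$pos)
  if (length(vac) == 0L) {
    if (p$attempts < 10L) {
      schedule_internal(sim, cl, "div_complete", sim$tick + 1L,
                        params = list(daughter = p$daughter,
                                      attempts = p$attempts + 1L, pw = p$pw))
    } else {
      cl$status <- "active"
      log_event(sim, 0L, cl$id, cl$type, p$pw, "division_aborted", cl$pos)
    }
    return(invisible(NULL))
  }
  slot <- resample1(vac)
  d <- new_cell(sim, p$daughter, slot)
  cl$rounds <- (cl$rounds %||% 0L) + 1L
  cl$status <- "active"
  cl$epoch <- cl$epoch + 1L # both daughters relaunch their initial pathways
  launch_initial_pathways(sim, cl)
  launch_initial_pathways(sim, d)
  log_event(sim, 0L, cl$id, cl$type, p$pw, "divided", cl$pos,
            paste0("daughter=", d$id, ":", p$daughter))
}

# --- differentiation --------------------------------------------------------
# Eligible targets are those lineage-allowed transitions whose guards hold
# at the cell's coordinate; when several intervals intersect, one target is
# drawn with the configured weights. All other pathways are disrupted and
# the new type's initial pathways are launched on completion.

mech_differentiate <- function(sim, cl, pw, ev) {
  tg <- pw$params$targets
  ok <- vapply(tg, function(t) {
    is.null(t$guard) || eval_pred_idx(sim, t$guard, cl$pos)
  }, logical(1))
  if (!any(ok)) {
    log_event(sim, 1L, cl$id, cl$type, pw$id, "no_eligible_target", cl$pos)
    return(invisible(NULL))
  }
  tg <- tg[ok]
  w <- vapply(tg, function(t) t$weight %||% 1, numeric(1))
  pick <- if (length(tg) == 1L) 1L else sample.int(length(tg), 1L, prob = w)
  to <- tg[[pick]]$to
  cl$epoch <- cl$epoch + 1L # disrupt: queued events are discarded
  cl$status <- "paused"
  schedule_internal(sim, cl, "diff_complete",
                    sim$tick + (pw$params$duration %||% 1L),
                    params = list(to = to, pw = pw$id))
}

int_diff_complete <- function(sim, cl, ev) {
  p <- ev$internal$params
  from <- cl$type
  sim$census[from] <- sim$census[from] - 1L
  cl$type <- p$to
  sim$census[p$to] <- sim$census[p$to] + 1L
  if (is.null(sim$first_seen[[p$to]])) sim$first_seen[[p$to]] <- sim$tick
  cl$status <- "active"
  cl$flags <- character(0)
  launch_initial_pathways(sim, cl)
  log_event(sim, 0L, cl$id, p$to, p$pw, "differentiated", cl$pos,
            paste0("from=", from))
}

# --- cell death -------------------------------------------------------------
# Apoptosis removes the cell without touching the extracellular fields;
# necrosis additionally deposits the configured factor amounts at the death
# coordinate. Removal is irreversible and terminates all pathways.

mech_apoptose <- function(sim, cl, pw, ev) {
  remove_cell(sim, cl, "apoptosis")
}

mech_necrose <- function(sim, cl, pw, ev) {
  rel <- pw$params$release
  if (!is.null(rel) && cl$status != "removed") {
    cc <- index_to_coord(cl$pos, sim$edge)[1L, ]
    for (fname in names(rel)) secrete(sim$fields[[fname]], cc, amount = rel[[fname]])
  }
  remove_cell(sim, cl, "necrosis")
}

# --- axon growth and synaptogenesis ----------------------------------------
# The growth cone follows the target-layer guidance factor gradient one
# unit displacement per event through vacant coordinates. When the local
# arrest factor (emitted by target dendrites) exceeds its threshold, growth
# is arrested and a terminal forms; the terminal emits the
# terminal-formed factor, target dendrites respond by forming a spine and
# emitting the spine-formed factor, and the synapse is recorded when that
# handshake completes. After a synapse the cone reverses along the
# anti-gradient until the guidance factor is lost, then re-enters search.

mech_grow_axon <- function(sim, cl, pw, ev) {
  ax <- cl$axon
  if (is.null(ax)) return(invisible(NULL))
  p <- pw$params
  cone <- ax$path[ax$n]
  if (ax$state %in% c("terminal_pending", "synapse_wait")) return(invisible(NULL))
  if (ax$state == "exhausted") {
    cl$stopped <- union(cl$stopped, pw$id)
    return(invisible(NULL))
  }
  presence <- sensed_conc(sim, p$agf, cone, p$presence_radius %||% 1L)
  if (ax$state == "reversing") {
    if (presence < p$presence_threshold) {
      ax$state <- "searching"
      return(invisible(NULL))
    }
    nxt <- pick_gradient_index(sim, cone,
                               gradient_rule(p$agf, "anti-gradient"))
    if (!is.null(nxt)) extend_axon(sim, cl, ax, nxt)
    if (ax$n >= p$max_len) ax$state <- "exhausted"
    return(invisible(NULL))
  }
  # searching / growing
  if (presence < p$presence_threshold) {
    ax$state <- "searching"
    return(invisible(NULL)) # not growing: no consensus on direction
  }
  acf_here <- sensed_conc(sim, p$acf, cone, p$acf_radius %||% 0L)
  if (acf_here >= p$acf_threshold) {
    ax$state <- "terminal_pending"
    schedule_internal(sim, cl, "terminal_complete",
                      sim$tick + (p$terminal_duration %||% 2L),
                      params = list(pw = pw$id))
    log_event(sim, 0L, cl$id, cl$type, pw$id, "growth_arrested", cone)
    return(invisible(NULL))
  }
  nxt <- pick_gradient_index(sim, cone, gradient_rule(p$agf, "gradient"))
  if (is.null(nxt)) return(invisible(NULL))
  ax$state <- "growing"
  extend_axon(sim, cl, ax, nxt)
  if (ax$n >= p$max_len) ax$state <- "exhausted"
}

extend_axon <- function(sim, cl, ax, nxt) {
  ax$n <- ax$n + 1L
  if (ax$n > length(ax$path)) ax$path <- c(ax$path, integer(max(16L, length(ax$path))))
  ax$path[ax$n] <- nxt
  pass_add(sim$lat, nxt, paste0("axon:", cl$id))
}

int_terminal_complete <- function(sim, cl, ev) {
  ax <- cl$axon
  pwid <- ev$internal$params$pw
  pw <- sim$bio$pathways[[pwid]]
  p <- pw$params
  cone <- ax$path[ax$n]
  ax$terminals <- c(ax$terminals, cone)
  secrete(sim$fields[[p$tff]], index_to_coord(cone, sim$edge)[1L, ])
  ax$state <- "synapse_wait"
  ax$wait <- 0L
  schedule_internal(sim, cl, "synapse_try", sim$tick + 1L,
                    params = list(pw = pwid), priority = 43L)
  log_event(sim, 0L, cl$id, cl$type, pwid, "terminal_formed", cone)
}

int_synapse_try <- function(sim, cl, ev) {
  ax <- cl$axon
  pwid <- ev$internal$params$pw
  pw <- sim$bio$pathways[[pwid]]
  p <- pw$params
  cone <- ax$path[ax$n]
  dsff <- sensed_conc(sim, p$dsff, cone, p$handshake_radius %||% 2L)
  if (dsff >= p$dsff_threshold) {
    post <- find_spine_partner(sim, cone, p$target_type,
                               p$handshake_radius %||% 2L)
    if (!is.null(post)) {
      record_connection(sim, cl, post)
      if (!is.null(p$dscf))
        secrete(sim$fields[[p$dscf]], index_to_coord(post$pos, sim$edge)[1L, ])
      ax$state <- "reversing"
      return(invisible(NULL))
    }
  }
  ax$wait <- ax$wait + 1L
  if (ax$wait > (p$handshake_patience %||% 20L)) {
    ax$state <- "reversing" # handshake failed; resume along the anti-gradient
    log_event(sim, 1L, cl$id, cl$type, pwid, "handshake_timeout", cone)
  } else {
    schedule_internal(sim, cl, "synapse_try", sim$tick + 1L,
                      params = list(pw = pwid), priority = 43L)
  }
}

find_spine_partner <- function(sim, cone, target_type, radius) {
  ids <- sim$lat$occ[ball_indices(cone, sim$edge, radius)]
  ids <- ids[ids != 0L]
  if (length(ids) == 0L) return(NULL)
  hits <- integer(0)
  for (id in ids) {
    c2 <- sim$cells[[as.character(id)]]
    if (!is.null(c2) && c2$status != "removed" && c2$type == target_type &&
        ("spine_ready" %in% c2$flags))
      hits <- c(hits, id)
  }
  if (length(hits) == 0L) return(NULL)
  sim$cells[[as.character(resample1(hits))]]
}

mech_form_spine <- function(sim, cl, pw, ev) {
  if (!("dendrite_formed" %in% cl$flags)) return(invisible(NULL))
  first <- !("spine_ready" %in% cl$flags)
  cl$flags <- union(cl$flags, "spine_ready")
  secrete(sim$fields[[pw$params$dsff]], index_to_coord(cl$pos, sim$edge)[1L, ])
  if (first) log_event(sim, 0L, cl$id, cl$type, pw$id, "spine_formed", cl$pos)
}

# Standalone pathway-facing wrappers for terminal/synapse formation so the
# full mechanism vocabulary is configurable, not only reachable through the
# growth automaton.
mech_form_terminal <- function(sim, cl, pw, ev) {
  if (is.null(cl$axon)) return(invisible(NULL))
  ev$internal <- list(fn = "terminal_complete", params = list(pw = pw$id))
  int_terminal_complete(sim, cl, ev)
}

mech_form_synapse <- function(sim, cl, pw, ev) {
  if (is.null(cl$axon)) return(invisible(NULL))
  ev$internal <- list(fn = "synapse_try", params = list(pw = pw$id))
  int_synapse_try(sim, cl, ev)
}

# --- connection bookkeeping -------------------------------------------------
# Each presynaptic cell keeps its ordered outgoing history; a new
# connection to the same partner as the immediately previous one is
# sequentially repeated, to a partner seen earlier (but not immediately
# previous) non-sequentially repeated, otherwise single.

record_connection <- function(sim, pre, post) {
  key <- as.character(pre$id)
  last <- sim$conn_last[[key]]
  partners <- sim$conn_partners[[key]]
  cat <- if (!is.null(last) && last == post$id) {
    "sequentially-repeated"
  } else if (!is.null(partners) && post$id %in% partners) {
    "non-sequentially-repeated"
  } else {
    "single"
  }
  sim$conn_last[[key]] <- post$id
  sim$conn_partners[[key]] <- union(partners, post$id)
  n <- sim$conn_n + 1L
  if (n > length(sim$conn_pre)) {
    grow <- max(64L, length(sim$conn_pre))
    sim$conn_pre <- c(sim$conn_pre, integer(grow))
    sim$conn_post <- c(sim$conn_post, integer(grow))
    sim$conn_tick <- c(sim$conn_tick, integer(grow))
    sim$conn_cat <- c(sim$conn_cat, character(grow))
  }
  sim$conn_pre[n] <- pre$id
  sim$conn_post[n] <- post$id
  sim$conn_tick[n] <- sim$tick
  sim$conn_cat[n] <- cat
  sim$conn_n <- n
  log_event(sim, 0L, pre$id, pre$type, NA_character_, "synapse", pre$pos,
            paste0("post=", post$id, ":", post$type, " cat=", cat))
  invisible(NULL)
}

# --- registries -------------------------------------------------------------

mechanisms_registry <- list(
  secrete_factor = mech_secrete,
  transduce = mech_transduce,
  move = mech_move,
  divide_symmetric = mech_divide,
  divide_asymmetric = mech_divide,
  differentiate = mech_differentiate,
  apoptose = mech_apoptose,
  necrose = mech_necrose,
  grow_axon = mech_grow_axon,
  form_terminal = mech_form_terminal,
  form_spine = mech_form_spine,
  form_synapse = mech_form_synapse
)

internal_ops <- list(
  div_complete = int_div_complete,
  diff_complete = int_diff_complete,
  terminal_complete = int_terminal_complete,
  synapse_try = int_synapse_try
)
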