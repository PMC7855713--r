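# ---------------------------------------------------------------------------
# Declarative configuration.
#
# A run is specified by three documents: the model configuration (lattice
# edge, tick budget, PRNG seed, logging), the spatial configuration (the
# initial objects and their coordinates) and the biological configuration
# (factors, cell types, signaling pathways, lineage). The model and
# biological configurations are immutable during a run; only the spatial
# arrangement evolves. Configurations are plain nested lists and round-trip
# through YAML.
# ---------------------------------------------------------------------------

#' Load and validate a configuration
#'
#' Reads a YAML (or JSON, a YAML subset) configuration document and
#' validates it: every referenced factor, cell type and pathway must be
#' declared; the lineage must be acyclic with strictly decreasing potency;
#' asymmetric divisions must produce strictly lower-potency daughters;
#' differentiation targets must be lineage edges of the hosting type.
#'
#' Guards are nested AND/OR lists over leaves
#' `list(factor =, op = "ge"|"le"|"between", threshold =, radius =)`:
#' `list(all = list(...))`, `list(any = list(...))`. Lower bounds use `>=`
#' and upper bounds `<=`; `radius = 0` senses the object's own coordinate,
#' `radius = r` the total over the Chebyshev ball of radius r.
#'
#' @param x path to a configuration file, a YAML string, or a nested list.
#' @return a validated list of class `organoid_config` with elements
#'   `model`, `spatial`, `biology`.
#' @export
load_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    doc <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  } else if (is.list(x)) {
    doc <- x
  } else {
    stop("expected a file path, a YAML string, or a list")
  }
  validate_config(doc)
}

#' Write a configuration to YAML
#' @param config an `organoid_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(doc) {
  fail <- function(...) stop("configuration error: ", ..., call. = FALSE)
  model <- doc$model
  if (is.null(model$edge) || model$edge < 3L) fail("model.edge must be >= 3")
  if (is.null(model$ticks) || model$ticks < 1L) fail("model.ticks must be >= 1")
  model$edge <- as.integer(model$edge)
  model$ticks <- as.integer(model$ticks)
  model$seed <- as.integer(model$seed %||% 1L)
  model$log_level <- as.integer(model$log_level %||% 0L)

  bio <- doc$biology
  factors <- bio$factors %||% list()
  fnames <- names(factors)
  for (fn in fnames) {
    fd <- factors[[fn]]
    factors[[fn]] <- factor_def(fn,
                                emission_radius = fd$emission_radius,
                                signal_power = fd$signal_power,
                                propagation_rate = fd$propagation_rate %||% 0.5,
                                degradation_rate = fd$degradation_rate %||% 0.05,
                                floor = fd$floor %||% 1e-12)
  }
  check_factor <- function(f, where) {
    if (!(f %in% fnames)) fail("undeclared factor \"", f, "\" referenced by ", where)
  }
  walk_guard <- function(tree, where) {
    if (is.null(tree) || length(tree) == 0L) return(invisible(NULL))
    if (!is.null(tree$all)) {
      for (ch in tree$all) walk_guard(ch, where)
    } else if (!is.null(tree$any)) {
      for (ch in tree$any) walk_guard(ch, where)
    } else {
      if (is.null(tree$factor)) fail("malformed guard leaf in ", where)
      check_factor(tree$factor, where)
      if (is.null(tree$op) || !(tree$op %in% c("ge", "le", "between")))
        fail("guard op must be ge/le/between in ", where)
      need <- if (tree$op == "between") 2L else 1L
      if (length(tree$threshold) != need) fail("guard threshold arity in ", where)
    }
    invisible(NULL)
  }

  pathways <- bio$pathways %||% list()
  for (pid in names(pathways)) {
    pw <- pathways[[pid]]
    where <- paste0("pathway \"", pid, "\"")
    if (is.null(pw$mechanism) || !(pw$mechanism %in% mechanism_names()))
      fail("unknown mechanism in ", where)
    # trigger normalization
    tr <- pw$trigger
    if (is.null(tr)) tr <- list(conditional = TRUE)
    if (!is.null(tr$kind)) { # already normalized (idempotent revalidation)
      pw$trigger <- tr
    } else if (!is.null(tr$cyclic)) {
      if (tr$cyclic < 1L) fail("cyclic period must be >= 1 in ", where)
      pw$trigger <- list(kind = "cyclic", period = as.integer(tr$cyclic),
                         start_delay = tr$start_delay %||% NULL)
    } else {
      pw$trigger <- list(kind = "conditional",
                         start_delay = tr$start_delay %||% NULL)
    }
    pw$priority <- as.integer(pw$priority %||% mechanism_priorities[[pw$mechanism]])
    pw$policy <- pw$policy %||% "retry"
    if (!(pw$policy %in% c("retry", "drop"))) fail("policy must be retry/drop in ", where)
    pw$retry_delay <- as.integer(pw$retry_delay %||% 1L)
    walk_guard(pw$guard, where)
    g <- pw$gate
    if (!is.null(g) && !is.numeric(g)) {
      check_factor(g$factor, where)
      if (!(g$kind %in% c("linear", "hill"))) fail("gate kind in ", where)
    }
    if (is.numeric(g) && (g < 0 || g > 1)) fail("gate probability outside [0,1] in ", where)
    # mechanism-specific factor references
    p <- pw$params %||% list()
    for (key in c("factor", "agf", "acf", "tff", "dsff", "dscf"))
      if (!is.null(p[[key]])) check_factor(p[[key]], where)
    if (!is.null(p$release)) for (fn in names(p$release)) check_factor(fn, where)
    if (pw$mechanism == "differentiate") {
      if (is.null(p$targets) || length(p$targets) == 0L)
        fail("differentiate needs targets in ", where)
      for (t in p$targets) walk_guard(t$guard, where)
    }
    pw$id <- pid
    pathways[[pid]] <- pw
  }
  # transduction action references must resolve to declared pathways
  for (pid in names(pathways)) {
    p <- pathways[[pid]]$params %||% list()
    for (ref in c(p$launch, p$stop))
      if (is.null(pathways[[ref]]))
        fail("pathway \"", pid, "\" references undeclared pathway \"", ref, "\"")
  }

  types <- bio$cell_types %||% list()
  tnames <- names(types)
  for (tn in tnames) {
    ty <- types[[tn]]
    where <- paste0("cell type \"", tn, "\"")
    ty$kind <- ty$kind %||% "cell"
    ty$potency <- as.integer(ty$potency %||% 1L)
    for (f in ty$emits %||% character(0)) check_factor(f, where)
    for (f in ty$receives %||% character(0)) check_factor(f, where)
    for (pid in ty$pathways %||% character(0))
      if (is.null(pathways[[pid]]))
        fail("undeclared pathway \"", pid, "\" referenced by ", where)
    types[[tn]] <- ty
  }

  # lineage: declared types, acyclic, strictly decreasing potency
  lineage <- bio$lineage %||% list()
  for (ed in lineage) {
    if (!(ed$from %in% tnames)) fail("lineage references undeclared type \"", ed$from, "\"")
    if (!(ed$to %in% tnames)) fail("lineage references undeclared type \"", ed$to, "\"")
    if (types[[ed$to]]$potency >= types[[ed$from]]$potency)
      fail("lineage edge ", ed$from, " -> ", ed$to,
           " does not strictly decrease potency")
  }
  # acyclicity check (potency decrease already implies it, but check anyway
  # to report the offending cycle when potencies are misdeclared)
  if (length(lineage)) {
    adj <- split(vapply(lineage, `[[`, character(1), "to"),
                 vapply(lineage, `[[`, character(1), "from"))
    state <- new.env(parent = emptyenv())
    visit <- function(v, stack) {
      if (v %in% stack) fail("lineage contains a cycle through \"", v, "\"")
      if (isTRUE(state[[v]])) return(invisible(NULL))
      for (w in adj[[v]] %||% character(0)) visit(w, c(stack, v))
      state[[v]] <- TRUE
      invisible(NULL)
    }
    for (v in names(adj)) visit(v, character(0))
  }
  edge_set <- vapply(lineage, function(e) paste0(e$from, ">", e$to), character(1))

  # per-host checks: differentiation targets are lineage edges; asymmetric
  # daughters have strictly lower potency
  for (tn in tnames) {
    for (pid in types[[tn]]$pathways %||% character(0)) {
      pw <- pathways[[pid]]
      if (pw$mechanism == "differentiate") {
        for (t in pw$params$targets) {
          if (!(paste0(tn, ">", t$to) %in% edge_set))
            fail("differentiation ", tn, " -> ", t$to,
                 " (pathway \"", pid, "\") is not a lineage edge")
        }
      }
      if (pw$mechanism == "divide_asymmetric") {
        d <- pw$params$daughter
        if (is.null(d) || !(d %in% tnames))
          fail("asymmetric division daughter undeclared in pathway \"", pid, "\"")
        if (types[[d]]$potency >= types[[tn]]$potency)
          fail("asymmetric division ", tn, " -> ", d,
               " requires strictly lower daughter potency")
      }
    }
  }

  # spatial
  spatial <- doc$spatial %||% list(objects = list())
  seen <- character(0)
  for (ob in spatial$objects %||% list()) {
    if (!(ob$type %in% tnames)) fail("initial object of undeclared type \"", ob$type, "\"")
    at <- as.integer(ob$at)
    if (length(at) != 3L || !in_bounds(at, model$edge))
      fail("initial coordinate out of bounds for type \"", ob$type, "\"")
    if ((types[[ob$type]]$kind %||% "cell") == "cell") {
      key <- paste(at, collapse = ",")
      if (key %in% seen) fail("two cell bodies declared at coordinate (", key, ")")
      seen <- c(seen, key)
    }
  }

  structure(list(model = model,
                 spatial = spatial,
                 biology = list(factors = factors, cell_types = types,
                                pathways = pathways, lineage = lineage)),
            class = "organoid_config")
}

#' Build the initial simulation state
#'
#' Creates the lattice and factor fields, seeds the PRNG, places the
#' initial objects and schedules each object's initial pathways at tick 0.
#'
#' @param config an `organoid_config` from [load_config()].
#' @param seed optional PRNG seed overriding the one in the configuration.
#' @return an environment of class `organoid_sim`.
#' @export
build_initial_state <- function(config, seed = NULL) {
  stopifnot(inherits(config, "organoid_config"))
  edge <- config$model$edge
  sim <- new.env(parent = emptyenv())
  sim$cfg <- config
  sim$edge <- edge
  sim$lat <- new_lattice(edge)
  sim$fields <- lapply(config$biology$factors, new_factor_field, edge = edge)
  sim$bio <- list(types = config$biology$cell_types,
                  pathways = config$biology$pathways,
                  factors = config$biology$factors,
                  lineage = config$biology$lineage)
  sim$cells <- new.env(parent = emptyenv())
  tnames <- names(config$biology$cell_types)
  sim$census <- stats::setNames(integer(length(tnames)), tnames)
  sim$first_seen <- new.env(parent = emptyenv())
  sim$queue <- new.env(parent = emptyenv())
  sim$tick <- 0L
  sim$seq <- 0L
  sim$next_id <- 0L
  sim$in_step <- FALSE
  sim$births <- 0L
  sim$deaths <- 0L
  sim$log <- vector("list", 256L)
  sim$log_n <- 0L
  sim$log_level <- config$model$log_level %||% 0L
  sim$hist <- vector("list", 1024L)
  sim$hist_n <- 0L
  sim$conn_pre <- integer(64L)
  sim$conn_post <- integer(64L)
  sim$conn_tick <- integer(64L)
  sim$conn_cat <- character(64L)
  sim$conn_n <- 0L
  sim$conn_last <- new.env(parent = emptyenv())
  sim$conn_partners <- new.env(parent = emptyenv())
  sim$seed <- as.integer(seed %||% config$model$seed)
  set.seed(sim$seed)
  class(sim) <- "organoid_sim"
  for (ob in config$spatial$objects %||% list()) {
    ty <- config$biology$cell_types[[ob$type]]
    idx <- coord_to_index(as.integer(ob$at), edge)
    cl <- new_cell(sim, ob$type, idx, kind = ty$kind %||% "cell", initial = TRUE)
    launch_initial_pathways(sim, cl, delay = 0L)
  }
  sim$initial_count <- sum(sim$census)
  sim
}

#' @export
print.organoid_sim <- function(x, ...) {
  live <- sum(x$census)
  cat("<organoid_sim> tick", x$tick, "| edge", x$edge,
      "| live objects", live, "| synapses", x$conn_n, "\n")
  nz <- x$census[x$census > 0L]
  if (length(nz)) {
    cat("  census:", paste(names(nz), nz, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
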