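# ---------------------------------------------------------------------------
# Analysis of simulation outputs: census dynamics, radial layer structure,
# connectivity statistics, axon lengths and glia/neuron ratios.
# ---------------------------------------------------------------------------

# Cell-type clusters used for census grouping: multipotent progenitors,
# neuron progenitors, glial progenitors, neuron cells, glial cells.
cluster_map <- c(
  NSC = "MP", NPC = "MP",
  BPC = "NP", NRPC = "NP",
  RGC = "GP", GRPC = "GP", OT2APC = "GP",
  L1N = "NC", L2N = "NC", L3N = "NC", L4N = "NC",
  T1A = "GC", ODC = "GC", T2A = "GC"
)

#' Cluster of a cell type
#' @param type character vector of cell type names.
#' @return character vector of cluster codes (`"other"` when unmapped).
#' @export
cluster_of <- function(type) {
  out <- unname(cluster_map[type])
  out[is.na(out)] <- "other"
  out
}

#' Per-tick census of live cells
#'
#' Reconstructs the per-tick live count of every declared cell type from
#' the recorded census history, together with per-tick cumulative births
#' and deaths, which reconcile exactly with the live total at every tick
#' (initial count + births - deaths = live count).
#'
#' @param sim an `organoid_sim` that has been stepped at least once.
#' @return a data.frame (tick, type, cluster, count); the per-tick totals
#'   are attached as `attr(, "totals")`, a data.frame
#'   (tick, live, births, deaths).
#' @export
census <- function(sim) {
  n <- sim$hist_n
  if (n == 0L) stop("no census history: step the simulation first")
  rows <- sim$hist[seq_len(n)]
  tnames <- names(sim$census)
  ticks <- vapply(rows, `[[`, numeric(1), "tick")
  mat <- do.call(rbind, lapply(rows, function(r) r[tnames]))
  long <- data.frame(
    tick = rep(as.integer(ticks), times = length(tnames)),
    type = rep(tnames, each = n),
    count = as.integer(as.vector(mat)),
    stringsAsFactors = FALSE
  )
  long$cluster <- cluster_of(long$type)
  totals <- data.frame(
    tick = as.integer(ticks),
    live = as.integer(rowSums(mat)),
    births = as.integer(vapply(rows, `[[`, numeric(1), ".births")),
    deaths = as.integer(vapply(rows, `[[`, numeric(1), ".deaths"))
  )
  attr(long, "totals") <- totals
  attr(long, "initial") <- sim$initial_count
  long
}

#' Stem-to-progenitor ratio over time
#'
#' Ratio of the multipotent-progenitor pool (cluster MP) to the committed
#' progenitor pools (clusters NP and GP) at the queried ticks. Undefined
#' ratios (zero denominator) are flagged with `NA` rather than infinity.
#'
#' @param census_df output of [census()].
#' @param at_ticks integer ticks to evaluate.
#' @return a data.frame (tick, stem, progenitor, ratio).
#' @export
stem_progenitor_ratio <- function(census_df, at_ticks) {
  out <- lapply(as.integer(at_ticks), function(t) {
    sub <- census_df[census_df$tick == t, ]
    if (nrow(sub) == 0L) stop("tick ", t, " not present in census")
    stem <- sum(sub$count[sub$cluster == "MP"])
    prog <- sum(sub$count[sub$cluster %in% c("NP", "GP")])
    data.frame(tick = t, stem = stem, progenitor = prog,
               ratio = if (prog == 0L) NA_real_ else stem / prog)
  })
  do.call(rbind, out)
}

#' Radial distribution of a cell type
#'
#' Euclidean distances of the type's cells from the structure center,
#' normalized by the maximum distance over all neuron-cluster cells (so
#' the outermost neuron maps to 1), binned into `bins` equal-width bins on
#' `[0, 1]`. Values above 1 (possible for non-neuron types) are clipped
#' into the last bin.
#'
#' @param cells a cell snapshot ([cells_snapshot()]).
#' @param type cell type name.
#' @param center numeric length-3 coordinate of the structure center
#'   (by convention the initial stem cell's coordinate).
#' @param bins number of histogram bins.
#' @return a list of class `radial_distribution`: type, normalized
#'   distances, bin `breaks`, `counts` and probabilities `p`, and the
#'   median normalized distance.
#' @export
radial_distribution <- function(cells, type, center, bins = 20L) {
  sel <- cells[cells$type == type, ]
  if (nrow(sel) == 0L) stop("no cells of type ", type)
  dist_of <- function(df) sqrt((df$x - center[1L])^2 + (df$y - center[2L])^2 +
                                 (df$z - center[3L])^2)
  neurons <- cells[cluster_of(cells$type) == "NC", ]
  dmax <- if (nrow(neurons)) max(dist_of(neurons)) else max(dist_of(cells))
  if (dmax <= 0) dmax <- 1
  d <- pmin(dist_of(sel) / dmax, 1)
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(d, breaks, rightmost.closed = TRUE),
                          bins), nbins = bins)
  structure(list(type = type, distances = d, breaks = breaks,
                 counts = counts, p = counts / sum(counts),
                 median = stats::median(d)),
            class = "radial_distribution")
}

#' Shannon entropy of a binned distribution
#'
#' Natural-log Shannon entropy of the histogram probabilities; 0 for a
#' point mass, `log(bins)` for the uniform distribution.
#'
#' @param dist a `radial_distribution` (or any list with element `p`
#'   summing to 1).
#' @return non-negative numeric.
#' @export
distribution_entropy <- function(dist) {
  p <- dist$p
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Connectivity summary
#'
#' Per-layer connection rates following the compartment-based denominators:
#' the axon connection rate is the share of neurons with at least one
#' outgoing connection among neurons that formed an axon; the dendrite
#' rate likewise over formed dendrites; the interneuron rate is the share
#' of neurons with both incoming and outgoing connections among neurons
#' that formed both compartments. Also returns in/out degree tables,
#' repeated-connection fractions per layer and the (pre, post) pair census.
#'
#' @param synapses a synapse table ([connections_table()]).
#' @param cells a cell snapshot ([cells_snapshot()]).
#' @return a list with elements `rates`, `repeated`, `pairs`, `out_degree`,
#'   `in_degree`.
#' @export
connectivity_summary <- function(synapses, cells) {
  dangling <- setdiff(unique(c(synapses$pre_id, synapses$post_id)), cells$id)
  if (length(dangling))
    stop("synapse table references unknown cell ids: ",
         paste(dangling, collapse = ", "))
  neurons <- cells[cluster_of(cells$type) == "NC", ]
  out_deg <- table(factor(synapses$pre_id, levels = neurons$id))
  in_deg <- table(factor(synapses$post_id, levels = neurons$id))
  layers <- sort(unique(neurons$type))
  rate_rows <- lapply(layers, function(ly) {
    sub <- neurons[neurons$type == ly, ]
    has_out <- out_deg[as.character(sub$id)] > 0
    has_in <- in_deg[as.character(sub$id)] > 0
    n_ax <- sum(sub$has_axon)
    n_de <- sum(sub$has_dendrite)
    n_both <- sum(sub$has_axon & sub$has_dendrite)
    data.frame(
      layer = ly,
      n_neurons = nrow(sub),
      axon_connection_rate = if (n_ax) sum(has_out & sub$has_axon) / n_ax else NA_real_,
      dendrite_connection_rate = if (n_de) sum(has_in & sub$has_dendrite) / n_de else NA_real_,
      interneuron_rate = if (n_both) sum(has_out & has_in & sub$has_axon &
                                           sub$has_dendrite) / n_both else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  rep_rows <- lapply(layers, function(ly) {
    sub <- synapses[synapses$pre_type == ly, ]
    n <- nrow(sub)
    data.frame(
      layer = ly,
      n_connections = n,
      seq_repeated_frac = if (n) mean(sub$category == "sequentially-repeated") else NA_real_,
      nonseq_repeated_frac = if (n) mean(sub$category == "non-sequentially-repeated") else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  list(rates = do.call(rbind, rate_rows),
       repeated = do.call(rbind, rep_rows),
       pairs = table(pre = synapses$pre_type, post = synapses$post_type),
       out_degree = out_deg,
       in_degree = in_deg)
}

#' Axon length statistics
#'
#' Per-layer axon length totals and the length-to-count ratio
#' (total axon length divided by the number of axons).
#'
#' @param axons an axon table ([axon_table()]).
#' @return a data.frame (layer, n_axons, total_length,
#'   length_to_count_ratio, mean_terminals); per-layer length vectors are
#'   attached as `attr(, "lengths")`.
#' @export
axon_length_stats <- function(axons) {
  layers <- sort(unique(axons$cell_type))
  rows <- lapply(layers, function(ly) {
    sub <- axons[axons$cell_type == ly, ]
    data.frame(layer = ly, n_axons = nrow(sub),
               total_length = sum(sub$path_length),
               length_to_count_ratio = sum(sub$path_length) / nrow(sub),
               mean_terminals = mean(sub$terminal_count),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(layer = character(0), n_axons = integer(0),
               total_length = numeric(0), length_to_count_ratio = numeric(0),
               mean_terminals = numeric(0))
  attr(out, "lengths") <- lapply(stats::setNames(layers, layers), function(ly)
    axons$path_length[axons$cell_type == ly])
  out
}

#' Glia-to-neuron ratio per layer band
#'
#' Assigns each neuron layer a radial band (by default the 10th-90th
#' percentile of the layer's Euclidean distances from the center) and
#' reports the ratio of glial cells falling inside the band to the layer's
#' neurons inside the band. Empty layers are flagged with `NA`.
#'
#' @param cells a cell snapshot.
#' @param center numeric length-3 structure center.
#' @param band quantile pair defining the layer band.
#' @return a data.frame (layer, n_neurons, n_glia, ratio).
#' @export
glia_neuron_ratio <- function(cells, center, band = c(0.1, 0.9)) {
  dist_of <- function(df) sqrt((df$x - center[1L])^2 + (df$y - center[2L])^2 +
                                 (df$z - center[3L])^2)
  neurons <- cells[cluster_of(cells$type) == "NC", ]
  glia <- cells[cluster_of(cells$type) == "GC", ]
  gd <- dist_of(glia)
  layers <- sort(unique(neurons$type))
  rows <- lapply(layers, function(ly) {
    sub <- neurons[neurons$type == ly, ]
    nd <- dist_of(sub)
    if (length(nd) == 0L)
      return(data.frame(layer = ly, n_neurons = 0L, n_glia = 0L,
                        ratio = NA_real_))
    q <- stats::quantile(nd, band, names = FALSE)
    n_in <- sum(nd >= q[1L] & nd <= q[2L])
    g_in <- sum(gd >= q[1L] & gd <= q[2L])
    data.frame(layer = ly, n_neurons = n_in, n_glia = g_in,
               ratio = if (n_in) g_in / n_in else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Headline metrics of a run
#'
#' A flat named numeric vector of the run's main quantities: live counts
#' per type, totals, synapse counts, per-layer connection rates and axon
#' length ratios. Used by [run_replicates()] and written to metrics.json.
#'
#' @param sim an `organoid_sim`.
#' @return a named numeric vector.
#' @export
run_metrics <- function(sim) {
  m <- c(stats::setNames(as.numeric(sim$census),
                         paste0("count_", names(sim$census))),
         total_live = sum(sim$census),
         births = sim$births,
         deaths = sim$deaths,
         synapses = sim$conn_n,
         ticks = sim$tick)
  cells <- cells_snapshot(sim)
  syn <- connections_table(sim)
  if (nrow(cells) && any(cluster_of(cells$type) == "NC")) {
    cs <- connectivity_summary(syn, cells)
    for (i in seq_len(nrow(cs$rates))) {
      ly <- cs$rates$layer[i]
      m[paste0("axon_rate_", ly)] <- cs$rates$axon_connection_rate[i]
      m[paste0("dendrite_rate_", ly)] <- cs$rates$dendrite_connection_rate[i]
      m[paste0("interneuron_rate_", ly)] <- cs$rates$interneuron_rate[i]
      m[paste0("seq_repeated_frac_", ly)] <- cs$repeated$seq_repeated_frac[i]
    }
    ax <- axon_length_stats(axon_table(sim))
    for (i in seq_len(nrow(ax))) {
      m[paste0("axon_length_ratio_", ax$layer[i])] <- ax$length_to_count_ratio[i]
    }
  }
  m
}
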