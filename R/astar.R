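# ---------------------------------------------------------------------------
# A* pathfinding on the lattice under the Chebyshev metric.
#
# Moves are unit displacements through vacant coordinates (cell bodies
# block; axon segments and marks do not). The Chebyshev distance to the
# goal is an admissible, consistent heuristic here because one step changes
# it by at most 1, so A* returns a shortest path.
# ---------------------------------------------------------------------------

#' Shortest path between two lattice coordinates
#'
#' A* search over vacant coordinates with the Chebyshev-distance heuristic.
#' The start may be occupied (by the mover itself); the goal must be vacant
#' or equal to the start.
#'
#' @param lattice an `organoid_lattice`.
#' @param from,to integer coordinates of length 3.
#' @return an integer matrix of coordinates (one row per step, first row
#'   `from`, last row `to`), or `NULL` when no path exists. The path length
#'   in steps is `nrow(path) - 1`.
#' @export
astar_path <- function(lattice, from, to) {
  e <- lattice$edge
  s <- coord_to_index(from, e)
  g <- coord_to_index(to, e)
  blocked <- lattice$occ != 0L
  blocked[s] <- FALSE
  idx <- astar_idx(blocked, e, s, g)
  if (is.null(idx)) NULL else index_to_coord(idx, e)
}

astar_idx <- function(blocked, edge, s, g) {
  if (s == g) return(s)
  if (blocked[g]) return(NULL)
  n3 <- edge^3
  gs <- rep.int(NA_integer_, n3)   # best known cost from start
  came <- integer(n3)
  closed <- logical(n3)
  cg <- index_to_coord(g, edge)[1L, ]
  h <- function(i) {
    cc <- index_to_coord(i, edge)
    pmax(abs(cc[, 1L] - cg[1L]), pmax(abs(cc[, 2L] - cg[2L]), abs(cc[, 3L] - cg[3L])))
  }
  gs[s] <- 0L
  # bucket queue over f = g + h (grown on demand for winding paths)
  buckets <- vector("list", 3L * edge + 2L)
  f0 <- 1L + h(s)
  buckets[[f0]] <- s
  fmin <- f0
  while (fmin <= length(buckets)) {
    b <- buckets[[fmin]]
    if (length(b) == 0L) {
      fmin <- fmin + 1L
      next
    }
    cur <- b[1L]
    buckets[[fmin]] <- b[-1L]
    if (closed[cur]) next
    closed[cur] <- TRUE
    if (cur == g) {
      # reconstruct
      path <- cur
      while (cur != s) {
        cur <- came[cur]
        path <- c(cur, path)
      }
      return(path)
    }
    nb <- nbr_indices(cur, edge)
    nb <- nb[!blocked[nb] & !closed[nb]]
    if (length(nb)) {
      gn <- gs[cur] + 1L
      better <- is.na(gs[nb]) | gn < gs[nb]
      for (v in nb[better]) {
        gs[v] <- gn
        came[v] <- cur
        fv <- 1L + gn + h(v)
        if (fv > length(buckets)) buckets <- c(buckets, vector("list", fv))
        buckets[[fv]] <- c(buckets[[fv]], v)
        if (fv < fmin) fmin <- fv
      }
    }
  }
  NULL
}
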