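# ---------------------------------------------------------------------------
# Lattice geometry.
#
# The model space is a finite 3D integer grid with equal edge length `edge`.
# Coordinates are 0-based integer triples (x, y, z), each axis in [0, edge-1].
# The metric is the Chebyshev distance, so a unit displacement moves to any of
# the up-to-26 surrounding coordinates. Internally coordinates are carried as
# 1-based linear indices into vectors of length edge^3; the public API uses
# (x, y, z) triples.
# ---------------------------------------------------------------------------

#' Convert between coordinate triples and linear indices
#'
#' @param coord integer vector of length 3 (0-based), or an n x 3 matrix.
#' @param edge lattice edge length.
#' @return `coord_to_index` returns 1-based linear indices;
#'   `index_to_coord` returns an n x 3 integer matrix of 0-based coordinates.
#' @keywords internal
coord_to_index <- function(coord, edge) {
  if (is.matrix(coord)) {
    1L + coord[, 1L] + edge * (coord[, 2L] + edge * coord[, 3L])
  } else {
    1L + coord[1L] + edge * (coord[2L] + edge * coord[3L])
  }
}

#' @rdname coord_to_index
#' @param idx 1-based linear index vector.
#' @keywords internal
index_to_coord <- function(idx, edge) {
  i <- idx - 1L
  x <- i %% edge
  i <- i %/% edge
  y <- i %% edge
  z <- i %/% edge
  cbind(x = as.integer(x), y = as.integer(y), z = as.integer(z))
}

in_bounds <- function(coord, edge) {
  all(coord >= 0L & coord <= edge - 1L)
}

#' Chebyshev distance between two lattice coordinates
#'
#' The distance used throughout the model: the maximum of per-axis absolute
#' differences. A unit displacement is any move with Chebyshev distance 1,
#' so an interior coordinate has 26 unit-displacement neighbors.
#'
#' @param a,b integer vectors of length 3 (0-based coordinates).
#' @return non-negative integer.
#' @examples
#' chebyshev_distance(c(0, 0, 0), c(1, 1, 1)) # 1
#' chebyshev_distance(c(2, 5, 1), c(7, 5, 3)) # 5
#' @export
chebyshev_distance <- function(a, b) {
  max(abs(as.integer(a) - as.integer(b)))
}

#' Chebyshev neighborhood of a coordinate
#'
#' All in-bounds coordinates at Chebyshev distance 1..`radius` from `coord`
#' (the coordinate itself is excluded). For an interior coordinate and
#' radius 1 this is the full 26-coordinate neighborhood; at lattice corners
#' and faces the set is clipped to the grid.
#'
#' @param coord integer vector of length 3 (0-based).
#' @param radius positive integer radius.
#' @param edge lattice edge length.
#' @return integer matrix with columns x, y, z (possibly 0 rows).
#' @export
neighborhood <- function(coord, radius = 1L, edge) {
  coord <- as.integer(coord)
  r <- as.integer(radius)
  xs <- max(0L, coord[1L] - r):min(edge - 1L, coord[1L] + r)
  ys <- max(0L, coord[2L] - r):min(edge - 1L, coord[2L] + r)
  zs <- max(0L, coord[3L] - r):min(edge - 1L, coord[3L] + r)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  keep <- !(g[, 1L] == coord[1L] & g[, 2L] == coord[2L] & g[, 3L] == coord[3L])
  g[keep, , drop = FALSE]
}

# Cached cube offsets for the hot-path neighborhood lookups.
.geom_cache <- new.env(parent = emptyenv())
cube_offsets <- function(radius) {
  key <- paste0("c", radius)
  got <- .geom_cache[[key]]
  if (is.null(got)) {
    r <- as.integer(radius)
    g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r, KEEP.OUT.ATTRS = FALSE)
    off <- cbind(g$dx, g$dy, g$dz)
    got <- list(off = off, center = off[, 1L] == 0L & off[, 2L] == 0L &
                  off[, 3L] == 0L)
    .geom_cache[[key]] <- got
  }
  got
}

# Linear-index neighborhood (center excluded), used on hot paths.
nbr_indices <- function(idx, edge, radius = 1L) {
  cube <- cube_offsets(radius)
  i <- idx - 1L
  x <- i %% edge; i <- i %/% edge
  y <- i %% edge; z <- i %/% edge
  xs <- x + cube$off[, 1L]
  ys <- y + cube$off[, 2L]
  zs <- z + cube$off[, 3L]
  keep <- !cube$center & xs >= 0L & xs < edge & ys >= 0L & ys < edge &
    zs >= 0L & zs < edge
  (1L + xs + edge * (ys + edge * zs))[keep]
}

# Ball of indices within Chebyshev radius r, *including* the center.
ball_indices <- function(idx, edge, radius) {
  if (radius <= 0L) return(idx)
  cube <- cube_offsets(radius)
  i <- idx - 1L
  x <- i %% edge; i <- i %/% edge
  y <- i %% edge; z <- i %/% edge
  xs <- x + cube$off[, 1L]
  ys <- y + cube$off[, 2L]
  zs <- z + cube$off[, 3L]
  keep <- xs >= 0L & xs < edge & ys >= 0L & ys < edge & zs >= 0L & zs < edge
  (1L + xs + edge * (ys + edge * zs))[keep]
}

#' Create an empty lattice
#'
#' The lattice tracks exclusive cell-body occupancy (at most one cell body
#' per coordinate) and non-exclusive pass-through occupancy used by axon
#' segments and spatial marks, which never block movement.
#'
#' @param edge positive integer edge length (>= 3).
#' @return an environment of class `organoid_lattice`.
#' @export
new_lattice <- function(edge) {
  edge <- as.integer(edge)
  stopifnot(edge >= 3L)
  lat <- new.env(parent = emptyenv())
  lat$edge <- edge
  lat$occ <- integer(edge^3)      # 0 = empty, else owning cell id
  lat$pass <- new.env(parent = emptyenv()) # idx (chr) -> character ids
  class(lat) <- "organoid_lattice"
  lat
}

#' Vacancy test
#'
#' A coordinate is vacant unless a cell body occupies it. Coordinates holding
#' only axon segments or spatial marks count as vacant.
#'
#' @param lattice an `organoid_lattice`.
#' @param coord integer vector of length 3.
#' @return logical scalar.
#' @export
is_vacant <- function(lattice, coord) {
  stopifnot(in_bounds(coord, lattice$edge))
  lattice$occ[coord_to_index(coord, lattice$edge)] == 0L
}

vacant_nbr_indices <- function(lattice, idx, radius = 1L) {
  nb <- nbr_indices(idx, lattice$edge, radius)
  nb[lattice$occ[nb] == 0L]
}

pass_add <- function(lattice, idx, label) {
  k <- as.character(idx)
  lattice$pass[[k]] <- c(lattice$pass[[k]], label)
  invisible(lattice)
}

pass_remove <- function(lattice, idx, label) {
  k <- as.character(idx)
  cur <- lattice$pass[[k]]
  cur <- cur[cur != label]
  if (length(cur)) lattice$pass[[k]] <- cur else if (!is.null(lattice$pass[[k]])) rm(list = k, envir = lattice$pass)
  invisible(lattice)
}

#' Move a cell body by one unit displacement
#'
#' Attempts to move the object `mover_id` from `from` to the adjacent
#' coordinate `to`. If `to` is vacant the occupancy is transferred. If `to`
#' holds another cell body that is ejectable, the occupant is pushed to a
#' uniformly chosen vacant neighbor of `to` (a single-level push; push
#' chains do not cascade) and the mover takes its place. If the occupant
#' cannot be displaced the move fails and the lattice is unchanged.
#'
#' @param lattice an `organoid_lattice`.
#' @param mover_id integer id currently occupying `from`.
#' @param from,to integer coordinates at Chebyshev distance 1.
#' @param eject if `TRUE`, an occupant of `to` may be pushed aside.
#' @return list with `ok` (logical), and for a successful push `ejected_to`
#'   (the linear index the occupant was pushed to) and `ejected_id`.
#' @export
displace <- function(lattice, mover_id, from, to, eject = TRUE) {
  edge <- lattice$edge
  if (!in_bounds(to, edge)) return(list(ok = FALSE, reason = "out-of-bounds"))
  stopifnot(chebyshev_distance(from, to) == 1L)
  i_from <- coord_to_index(from, edge)
  i_to <- coord_to_index(to, edge)
  if (lattice$occ[i_from] != mover_id) stop("mover does not occupy `from`")
  occ_to <- lattice$occ[i_to]
  ejected_to <- NULL
  ejected_id <- NULL
  if (occ_to != 0L) {
    if (!eject) return(list(ok = FALSE, reason = "occupied"))
    slots <- vacant_nbr_indices(lattice, i_to)
    slots <- slots[slots != i_from]
    if (length(slots) == 0L) return(list(ok = FALSE, reason = "blocked"))
    ejected_to <- resample1(slots)
    ejected_id <- occ_to
    lattice$occ[ejected_to] <- occ_to
  }
  lattice$occ[i_to] <- mover_id
  lattice$occ[i_from] <- 0L
  list(ok = TRUE, ejected_to = ejected_to, ejected_id = ejected_id)
}

# sample() misbehaves for length-1 integer vectors; this never does.
resample1 <- function(x) {
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}
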