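# Small configurations built in code for unit tests.

# One cell type with a cyclic symmetric-division pathway and one factor.
toy_division_config <- function(edge = 11L, ticks = 20L, seed = 1L,
                                period = 3L, gate = NULL) {
  load_config(list(
    model = list(edge = edge, ticks = ticks, seed = seed),
    spatial = list(objects = list(list(type = "A", at = rep((edge - 1L) %/% 2L, 3L)))),
    biology = list(
      factors = list(F1 = list(emission_radius = 3, signal_power = 1)),
      cell_types = list(A = list(potency = 2, pathways = "div")),
      pathways = list(div = list(mechanism = "divide_symmetric",
                                 trigger = list(cyclic = period),
                                 gate = gate)),
      lineage = list()
    )
  ))
}

# A single stationary secreting cell; useful for field and predicate tests.
toy_secretion_config <- function(edge = 15L, ticks = 10L, seed = 1L,
                                 emission_radius = 5, signal_power = 4,
                                 propagation_rate = 0.5, degradation_rate = 0) {
  load_config(list(
    model = list(edge = edge, ticks = ticks, seed = seed),
    spatial = list(objects = list(list(type = "S", at = rep((edge - 1L) %/% 2L, 3L)))),
    biology = list(
      factors = list(FX = list(emission_radius = emission_radius,
                               signal_power = signal_power,
                               propagation_rate = propagation_rate,
                               degradation_rate = degradation_rate)),
      cell_types = list(S = list(potency = 1, emits = "FX", pathways = "sec")),
      pathways = list(sec = list(mechanism = "secrete_factor",
                                 trigger = list(cyclic = 1),
                                 params = list(factor = "FX"))),
      lineage = list()
    )
  ))
}

# A bare state with declared factors but no pathways: a scaffold on which
# tests can secrete and probe by hand.
bare_state <- function(edge = 11L, factors = list(), cells = list(), seed = 1L) {
  ctypes <- list(P = list(potency = 1, pathways = character(0)))
  objs <- lapply(cells, function(at) list(type = "P", at = at))
  cfg <- load_config(list(
    model = list(edge = edge, ticks = 1L, seed = seed),
    spatial = list(objects = objs),
    biology = list(factors = factors, cell_types = ctypes,
                   pathways = list(), lineage = list())
  ))
  build_initial_state(cfg)
}

# Dense 3x3x3 discrete-Gaussian convolution oracle with reflecting walls,
# written as a direct triple loop over the product kernel - independent of
# the separable implementation it checks.
dense_conv_oracle <- function(a, s2) {
  e <- dim(a)[1L]
  w1 <- exp(-1 / (2 * s2))
  k <- c(w1, 1, w1) / (1 + 2 * w1)
  out <- array(0, dim = dim(a))
  refl <- function(i) ifelse(i < 1L, 1L, ifelse(i > e, e, i))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    w <- k[dx + 2L] * k[dy + 2L] * k[dz + 2L]
    src <- a[refl(seq_len(e) + dx), refl(seq_len(e) + dy), refl(seq_len(e) + dz)]
    out <- out + w * src
  }
  out
}

# Breadth-first-search shortest path length oracle on a blocked grid.
bfs_path_length <- function(blocked, edge, s, g) {
  if (s == g) return(0L)
  dist <- rep(NA_integer_, edge^3)
  dist[s] <- 0L
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (cur in frontier) {
      nb <- organoidsim:::nbr_indices(cur, edge)
      nb <- nb[!blocked[nb] & is.na(dist[nb])]
      dist[nb] <- dist[cur] + 1L
      if (g %in% nb) return(dist[g])
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  NA_integer_
}
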