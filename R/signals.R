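# ---------------------------------------------------------------------------
# Extracellular factor fields.
#
# Each factor is described by a concentration map over lattice coordinates.
# Secretion deposits `signal_power` units at the source; diffusion is a
# truncated discrete-Gaussian convolution (separable 3x3x3 kernel with
# per-step variance `propagation_rate`, reflecting walls so that mass is
# conserved inside the grid); degradation is multiplicative exponential
# decay. Concentrations are ignored outside the union of Chebyshev balls of
# radius `emission_radius` around past sources (the truncated support),
# and entries below a pruning floor are dropped.
# ---------------------------------------------------------------------------

#' Define a diffusible factor
#'
#' @param id factor name.
#' @param emission_radius significant action radius in lattice units
#'   (Chebyshev); concentrations are truncated to the union of balls of
#'   this radius around sources.
#' @param signal_power concentration deposited per secretion event.
#' @param propagation_rate per-step variance of the discrete-Gaussian
#'   diffusion kernel, in `[0, 1]`; 0 disables spreading.
#' @param degradation_rate per-step fractional decay in `[0, 1]`.
#' @param floor concentrations below this value are pruned to zero.
#' @return a list of class `factor_def`.
#' @export
factor_def <- function(id, emission_radius, signal_power,
                       propagation_rate = 0.5, degradation_rate = 0.05,
                       floor = 1e-12) {
  stopifnot(emission_radius >= 1,
            signal_power >= 0,
            propagation_rate >= 0, propagation_rate <= 1,
            degradation_rate >= 0, degradation_rate <= 1)
  structure(list(id = id,
                 emission_radius = as.integer(emission_radius),
                 signal_power = signal_power,
                 propagation_rate = propagation_rate,
                 degradation_rate = degradation_rate,
                 floor = floor),
            class = "factor_def")
}

#' Create an empty factor field over a lattice
#'
#' @param def a [factor_def()].
#' @param edge lattice edge length.
#' @return an environment of class `factor_field`.
#' @export
new_factor_field <- function(def, edge) {
  stopifnot(inherits(def, "factor_def"))
  f <- new.env(parent = emptyenv())
  f$def <- def
  f$edge <- as.integer(edge)
  f$values <- array(0, dim = rep(f$edge, 3L))
  f$support <- array(FALSE, dim = rep(f$edge, 3L))
  f$stamped <- new.env(parent = emptyenv()) # source idx -> TRUE, memoized
  f$active <- FALSE
  class(f) <- "factor_field"
  f
}

# Stamp the truncation support: the Chebyshev ball (a cube, clipped to the
# grid) of radius emission_radius around a source coordinate.
stamp_support <- function(field, idx) {
  k <- as.character(idx)
  if (!is.null(field$stamped[[k]])) return(invisible(field))
  e <- field$edge
  r <- field$def$emission_radius
  c0 <- index_to_coord(idx, e)[1L, ]
  xr <- (max(0L, c0[1L] - r):min(e - 1L, c0[1L] + r)) + 1L
  yr <- (max(0L, c0[2L] - r):min(e - 1L, c0[2L] + r)) + 1L
  zr <- (max(0L, c0[3L] - r):min(e - 1L, c0[3L] + r)) + 1L
  field$support[xr, yr, zr] <- TRUE
  field$stamped[[k]] <- TRUE
  invisible(field)
}

#' Secrete a factor at a source coordinate
#'
#' Adds `signal_power` (or `amount`, if given) to the concentration at
#' `source` and extends the field's truncated support by the emission ball
#' around the source. Spreading is performed separately by [diffuse_step()].
#'
#' @param field a `factor_field`.
#' @param source integer coordinate of length 3 (0-based).
#' @param amount optional override of the deposited amount.
#' @return the field, invisibly.
#' @export
secrete <- function(field, source, amount = NULL) {
  stopifnot(in_bounds(source, field$edge))
  idx <- coord_to_index(source, field$edge)
  amt <- if (is.null(amount)) field$def$signal_power else amount
  field$values[idx] <- field$values[idx] + amt
  stamp_support(field, idx)
  field$active <- TRUE
  invisible(field)
}

# One separable pass of the 3x3x3 discrete-Gaussian kernel with reflecting
# walls (out-of-grid flux returns to the boundary cell, conserving mass and
# leaving constant fields unchanged).
conv_gauss3 <- function(a, w1) {
  e <- dim(a)[1L]
  s <- 1 + 2 * w1
  k0 <- 1 / s
  k1 <- w1 / s
  # x axis
  out <- k0 * a
  out[2:e, , ] <- out[2:e, , ] + k1 * a[1:(e - 1L), , ]
  out[1:(e - 1L), , ] <- out[1:(e - 1L), , ] + k1 * a[2:e, , ]
  out[1L, , ] <- out[1L, , ] + k1 * a[1L, , ]
  out[e, , ] <- out[e, , ] + k1 * a[e, , ]
  a <- out
  # y axis
  out <- k0 * a
  out[, 2:e, ] <- out[, 2:e, ] + k1 * a[, 1:(e - 1L), ]
  out[, 1:(e - 1L), ] <- out[, 1:(e - 1L), ] + k1 * a[, 2:e, ]
  out[, 1L, ] <- out[, 1L, ] + k1 * a[, 1L, ]
  out[, e, ] <- out[, e, ] + k1 * a[, e, ]
  a <- out
  # z axis
  out <- k0 * a
  out[, , 2:e] <- out[, , 2:e] + k1 * a[, , 1:(e - 1L)]
  out[, , 1:(e - 1L)] <- out[, , 1:(e - 1L)] + k1 * a[, , 2:e]
  out[, , 1L] <- out[, , 1L] + k1 * a[, , 1L]
  out[, , e] <- out[, , e] + k1 * a[, , e]
  out
}

#' One diffusion step
#'
#' Replaces the field by its convolution with the separable 3x3x3 discrete
#' Gaussian (per-step variance `propagation_rate`), then clips to the
#' truncated support and prunes sub-floor entries. Within the support and
#' away from support edges the step conserves total mass to rounding error.
#'
#' @param field a `factor_field`.
#' @return the field, invisibly.
#' @export
diffuse_step <- function(field) {
  if (!field$active) return(invisible(field))
  s2 <- field$def$propagation_rate
  if (s2 > 0) {
    w1 <- exp(-1 / (2 * s2))
    v <- conv_gauss3(field$values, w1)
    v[!field$support] <- 0
    v[v < field$def$floor] <- 0
    field$values <- v
    if (!any(v > 0)) field$active <- FALSE
  }
  invisible(field)
}

#' One degradation step
#'
#' Multiplies every concentration by `1 - degradation_rate` and prunes
#' entries below the floor.
#'
#' @param field a `factor_field`.
#' @return the field, invisibly.
#' @export
degrade_step <- function(field) {
  if (!field$active) return(invisible(field))
  d <- field$def$degradation_rate
  if (d > 0) {
    v <- field$values * (1 - d)
    v[v < field$def$floor] <- 0
    field$values <- v
    if (!any(v > 0)) field$active <- FALSE
  }
  invisible(field)
}

#' Concentration at a coordinate
#'
#' @param field a `factor_field`.
#' @param coord integer coordinate of length 3.
#' @return non-negative concentration (0 for unset or pruned entries).
#' @export
concentration_at <- function(field, coord) {
  stopifnot(in_bounds(coord, field$edge))
  field$values[coord_to_index(coord, field$edge)]
}

#' Total mass of a field
#' @param field a `factor_field`.
#' @return sum of all concentrations.
#' @export
field_mass <- function(field) sum(field$values)

# Sensed amount of a factor at position `idx`: the concentration at the
# coordinate itself (radius 0) or the sum over the Chebyshev ball of the
# given radius including the coordinate.
sensed_conc <- function(sim, factor, idx, radius = 0L) {
  f <- sim$fields[[factor]]
  if (is.null(f)) stop("unknown factor: ", factor)
  if (radius <= 0L) return(f$values[idx])
  sum(f$values[ball_indices(idx, sim$edge, radius)])
}

#' Define a gradient-following rule
#'
#' @param factor factor id whose field guides the choice.
#' @param direction `"gradient"` (toward higher concentration) or
#'   `"anti-gradient"`.
#' @param min_conc,max_conc optional bounds a candidate coordinate's
#'   concentration must satisfy.
#' @return a list of class `gradient_rule`.
#' @export
gradient_rule <- function(factor, direction = c("gradient", "anti-gradient"),
                          min_conc = NULL, max_conc = NULL) {
  direction <- match.arg(direction)
  structure(list(factor = factor, direction = direction,
                 min_conc = min_conc, max_conc = max_conc),
            class = "gradient_rule")
}

#' Pick a gradient-satisfying neighbor coordinate
#'
#' Among vacant unit-displacement neighbors of `from`, keeps those whose
#' concentration satisfies the rule's bounds; candidates that strictly
#' improve along the rule's direction are preferred, and when none improves
#' strictly the candidates at equal concentration are kept (plateau drift).
#' One of the kept coordinates is returned uniformly at random.
#'
#' @param sim a simulation state (see [build_initial_state()]).
#' @param from integer coordinate of length 3.
#' @param rule a [gradient_rule()].
#' @return an integer coordinate of length 3, or `NULL` when no candidate
#'   satisfies the rule.
#' @export
pick_gradient_coordinate <- function(sim, from, rule) {
  idx <- coord_to_index(from, sim$edge)
  i <- pick_gradient_index(sim, idx, rule)
  if (is.null(i)) NULL else as.integer(index_to_coord(i, sim$edge)[1L, ])
}

pick_gradient_index <- function(sim, idx, rule) {
  cand <- vacant_nbr_indices(sim$lat, idx)
  if (length(cand) == 0L) return(NULL)
  f <- sim$fields[[rule$factor]]
  if (is.null(f)) stop("unknown factor: ", rule$factor)
  cc <- f$values[cand]
  keep <- rep(TRUE, length(cand))
  if (!is.null(rule$min_conc)) keep <- keep & cc >= rule$min_conc
  if (!is.null(rule$max_conc)) keep <- keep & cc <= rule$max_conc
  cand <- cand[keep]
  cc <- cc[keep]
  if (length(cand) == 0L) return(NULL)
  c0 <- f$values[idx]
  if (rule$direction == "gradient") {
    strict <- cc > c0
    level <- cc == c0
  } else {
    strict <- cc < c0
    level <- cc == c0
  }
  pool <- if (any(strict)) cand[strict] else cand[level]
  if (length(pool) == 0L) return(NULL)
  resample1(pool)
}
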