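# ---------------------------------------------------------------------------
# Organoid configurations.
#
# Ready-made, scale-parameterized configurations that grow a layered,
# synaptically wired structure from a single neural stem cell, in four
# conceptual stages that run concurrently in one event stream:
#
#   Stage 1  proliferation. The NSC sits at the lattice center, secretes
#            the stem-cell factor NSCF every tick (its quasi-steady radial
#            profile bounds the structure) and divides asymmetrically into
#            neural progenitors (NPC) once the profile has built up. NPCs
#            divide symmetrically while NSCF is above the boundary value;
#            NPCs reaching the low-NSCF boundary secrete the progenitor
#            factor NPCF, neighboring NPCs join in (a chain reaction that
#            sweeps inward), high NPCF halts divisions and triggers
#            probabilistic NPC differentiation; NPCs pushed below the
#            apoptosis bound die.
#   Stage 2  differentiation. Pass-through progenitors (BPC -> NRPC,
#            RGC -> GRPC) commit the pools; neuron-restricted progenitors
#            differentiate into L1-L4 neurons according to intersecting
#            NSCF intervals (outermost layer first, since the NPCF wave
#            arrives there first), glial-restricted progenitors amplify by
#            symmetric division and split probabilistically into
#            astrocytes and oligodendrocyte-lineage cells with an
#            NSCF-dependent bias (type-1 astrocytes central, type-2
#            peripheral, oligodendrocytes even).
#   Stage 3  compartments. Neurons secrete NF until nearby glia answer
#            with GNF (negative feedback); sufficient GNF triggers axon
#            and/or dendrite sprouting.
#   Stage 4  wiring. Dendrites emit per-target guidance (AGF) and arrest
#            (ACF) factors; growth cones follow the AGF gradient of their
#            configured target layer (L1 -> L3, L3 -> L2, L2 -> L4),
#            arrest on ACF, and complete the TFF/DSFF/DSCF handshake that
#            records a synapse, then reverse along the anti-gradient.
#
# All numeric thresholds are derived at configuration time from the
# quasi-steady NSCF profile, computed by relaxing an isolated field with
# the same secretion/diffusion/degradation rules the run itself uses, so
# layer bands scale consistently with the target radius.
# ---------------------------------------------------------------------------

# Quasi-steady radial concentration profile of a factor secreted every
# tick from a fixed source, after `ticks` relaxation steps. Returns an
# interpolating function of (possibly fractional) radius plus the tick at
# which the concentration at `watch_radius` first reached 90% of its final
# value (used to delay proliferation onset until the gradient that bounds
# the structure has actually built up).
steady_profile <- function(def, edge, center, ticks = 400L,
                           watch_radius = NULL) {
  f <- new_factor_field(def, edge)
  watch <- NULL
  trace <- numeric(ticks)
  if (!is.null(watch_radius))
    watch <- center + c(min(as.integer(round(watch_radius)),
                            edge - 1L - center[1L]), 0L, 0L)
  for (i in seq_len(ticks)) {
    secrete(f, center)
    diffuse_step(f)
    degrade_step(f)
    if (!is.null(watch)) trace[i] <- concentration_at(f, watch)
  }
  rmax <- def$emission_radius
  rs <- 0:min(rmax, edge - 1L - center[1L])
  vals <- vapply(rs, function(r) concentration_at(f, center + c(r, 0L, 0L)),
                 numeric(1))
  keep <- vals > 0
  fn <- stats::approxfun(rs[keep], log(vals[keep]), rule = 2L)
  t90 <- if (is.null(watch)) NA_integer_ else
    which(trace >= 0.9 * trace[ticks])[1L]
  list(prof = function(r) exp(fn(r)), t90 = as.integer(t90))
}

#' Build an organoid configuration
#'
#' Generates a complete, validated configuration that grows a layered
#' organoid-like structure from a single stem cell at the lattice center.
#' `scale = 1` targets a structure radius of 7 lattice units (on the order
#' of a thousand cells); radii, lattice edge and all NSCF-derived
#' thresholds scale with `scale^(1/3)`.
#'
#' The two variants differ only in the NSCF differentiation intervals for
#' L3/L4 neurons (variant II trades L3 thickness for a larger, more
#' peripheral L4) and in the guidance-factor radii: the L2-neuron AGF
#' radius in variant I is 1.5 times variant II's, the L4-neuron AGF radius
#' 1.4 times, and the L3-neuron AGF radius differs by one lattice unit.
#'
#' @param scale positive size knob; `scale = 1` is the desk-scale default.
#' @param variant `"I"` or `"II"`.
#' @param seed PRNG seed stored in the model configuration.
#' @param ticks tick budget stored in the model configuration.
#' @return an `organoid_config`.
#' @export
make_organoid_config <- function(scale = 1, variant = c("I", "II"), seed = 1L,
                                 ticks = NULL) {
  variant <- match.arg(variant)
  stopifnot(scale >= 1)
  build_organoid_config(scale, variant, seed, stages = 4L, ticks = ticks)
}

#' Build a single-stage sub-experiment configuration
#'
#' Stages 1-3 are cumulative from a single stem cell (stage 2 embeds stage
#' 1's rules, stage 3 embeds both). Stage 4 is the wiring sub-experiment
#' in isolation: pre-placed L1/L3 neuron slabs with interspersed glia, so
#' compartment formation and the synaptogenesis handshake can be exercised
#' without growing the full structure.
#'
#' @param stage 1, 2, 3 or 4.
#' @param scale size knob (stages 1-3).
#' @param seed PRNG seed.
#' @param ticks tick budget override.
#' @return an `organoid_config`.
#' @export
make_stage_config <- function(stage, scale = 1, seed = 1L, ticks = NULL) {
  stage <- as.integer(stage)
  stopifnot(stage %in% 1:4)
  if (stage == 4L) return(make_wiring_config(seed = seed, ticks = ticks))
  build_organoid_config(scale, "I", seed, stages = stage, ticks = ticks)
}

build_organoid_config <- function(scale, variant, seed, stages, ticks = NULL) {
  s3 <- scale^(1 / 3)
  R <- 7 * s3                        # target structure radius
  edge <- 2L * as.integer(ceiling(1.45 * R)) + 3L
  ctr <- rep((edge - 1L) %/% 2L, 3L)

  nscf_def <- factor_def("NSCF", emission_radius = as.integer(ceiling(R + 5)),
                         signal_power = 8, propagation_rate = 0.5,
                         degradation_rate = 0.05)
  sp <- steady_profile(nscf_def, edge, ctr, watch_radius = R)
  prof <- sp$prof
  p0 <- prof(0)

  # the NSC stays quiescent until the boundary gradient has built up:
  # without this, daughters born early see a still-growing NSCF tail and
  # read it as the structure boundary
  nsc_onset <- sp$t90 + 10L
  th_div <- prof(R)                  # NPC divides while NSCF >= this
  th_bnd <- prof(R - 0.8)            # boundary: NSCF <= this starts NPCF
  th_apop <- prof(R + 1)             # beyond the structure: apoptosis
  # Chain-reaction pacing. Both thresholds sense the cell's own
  # coordinate; with the one-unit NPCF emission radius this makes the
  # secretion relay strictly nearest-neighbor, so the wave crawls inward a
  # shell at a time. Joining the chain (th_chain) only needs a neighbor's
  # halo; differentiating (th_npcf) effectively requires the cell's own
  # secretion on top of it, so commitment trails the relay instead of
  # starving it.
  th_chain <- 0.7                    # NPCF (own coordinate) joining the chain
  th_npcf <- 1.3                     # NPCF (own coordinate) to differentiate
  th_stop <- 0.5                     # NPCF halting NSC/NPC divisions

  # Layer bands in units of radius (outer to inner), overlapping by design;
  # variant II moves the L3/L4 boundary outward.
  bands <- list(
    L1N = c(5.4, 7.6), L2N = c(4.2, 5.8),
    L3N = if (variant == "I") c(3.0, 4.6) else c(3.4, 4.6),
    L4N = if (variant == "I") c(1.8, 3.4) else c(1.8, 3.8)
  )
  interval_guard <- function(b) {
    lo <- prof(b[2L] * s3) # outer radius -> lower NSCF bound
    hi <- prof(b[1L] * s3)
    list(factor = "NSCF", op = "between", threshold = c(lo, hi), radius = 0L)
  }

  # Guidance/arrest factor radii per target layer (paper-style variant
  # contrast: I/II differ by factors 1.5, 1.4 and by one unit).
  agf_r <- if (variant == "I") {
    c(L2 = 6L, L3 = 5L, L4 = 7L)
  } else {
    c(L2 = 4L, L3 = 6L, L4 = 5L)
  }

  th_gnf <- 2.0; th_nf <- 1.5; th_gnf_cap <- 6
  th_acf <- 2.0; th_tff <- 0.3; th_dsff <- 0.3; th_agf <- 0.05

  factors <- list(
    NSCF = list(emission_radius = nscf_def$emission_radius, signal_power = 8,
                propagation_rate = 0.5, degradation_rate = 0.05),
    # the short emission radius makes the secretion chain advance one
    # lattice unit per activation cycle, so differentiation sweeps inward
    # as an orderly wave (outer layers first)
    NPCF = list(emission_radius = 1, signal_power = 2,
                propagation_rate = 0.3, degradation_rate = 0.2)
  )
  if (stages >= 3L) {
    factors$NF <- list(emission_radius = 2, signal_power = 2,
                       propagation_rate = 0.3, degradation_rate = 0.1)
    factors$GNF <- list(emission_radius = 2, signal_power = 2,
                        propagation_rate = 0.3, degradation_rate = 0.1)
  }
  if (stages >= 4L) {
    for (ly in c("L2", "L3", "L4")) {
      factors[[paste0(ly, "NeuronAGF")]] <-
        list(emission_radius = agf_r[[ly]], signal_power = 4,
             propagation_rate = 0.5, degradation_rate = 0.05)
      factors[[paste0(ly, "NeuronACF")]] <-
        list(emission_radius = 2, signal_power = 3,
             propagation_rate = 0.25, degradation_rate = 0.2)
    }
    factors$TFF <- list(emission_radius = 2, signal_power = 3,
                        propagation_rate = 0.3, degradation_rate = 0.25)
    factors$DSFF <- list(emission_radius = 2, signal_power = 3,
                         propagation_rate = 0.3, degradation_rate = 0.25)
    factors$DSCF <- list(emission_radius = 1, signal_power = 1,
                         propagation_rate = 0.2, degradation_rate = 0.3)
  }

  leaf <- function(factor, op, threshold, radius = 0L)
    list(factor = factor, op = op, threshold = threshold, radius = radius)

  pathways <- list(
    nsc_secrete = list(mechanism = "secrete_factor", trigger = list(cyclic = 1),
                       params = list(factor = "NSCF")),
    nsc_divide = list(mechanism = "divide_asymmetric",
                      trigger = list(cyclic = 6, start_delay = nsc_onset),
                      guard = list(all = list(leaf("NPCF", "le", th_stop))),
                      params = list(daughter = "NPC", duration = 2)),
    npc_divide = list(mechanism = "divide_symmetric", trigger = list(cyclic = 5),
                      gate = 0.9,
                      guard = list(all = list(leaf("NSCF", "ge", th_div),
                                              leaf("NPCF", "le", th_stop))),
                      # the finite per-cell budget lets the boundary churn
                      # (apoptosis opening slots that neighbors refill)
                      # drain instead of cycling forever
                      params = list(duration = 2, max_rounds = 6)),
    npc_secrete_npcf = list(mechanism = "secrete_factor",
                            trigger = list(cyclic = 3),
                            guard = list(any = list(
                              leaf("NSCF", "le", th_bnd),
                              leaf("NPCF", "ge", th_chain))),
                            params = list(factor = "NPCF")),
    npc_apop_out = list(mechanism = "apoptose", trigger = list(cyclic = 3),
                        guard = list(all = list(leaf("NSCF", "le", th_apop))))
  )
  types <- list(
    NSC = list(potency = 10, emits = "NSCF",
               pathways = c("nsc_secrete", "nsc_divide")),
    NPC = list(potency = 8, emits = "NPCF", receives = c("NSCF", "NPCF"),
               pathways = c("npc_divide", "npc_secrete_npcf", "npc_apop_out"))
  )
  lineage <- list()

  if (stages >= 2L) {
    pathways$npc_diff <- list(
      mechanism = "differentiate", trigger = list(cyclic = 4), gate = 0.35,
      guard = list(all = list(leaf("NPCF", "ge", th_npcf))),
      params = list(duration = 1, targets = list(
        list(to = "BPC", weight = 0.32),
        list(to = "RGC", weight = 0.68))))
    pathways$npc_apop_crowd <- list(
      mechanism = "apoptose", trigger = list(cyclic = 4), gate = 0.10,
      guard = list(all = list(leaf("NPCF", "ge", th_npcf))))
    types$NPC$pathways <- c(types$NPC$pathways, "npc_diff", "npc_apop_crowd")

    pathways$bpc_diff <- list(
      mechanism = "differentiate", trigger = list(cyclic = 3),
      params = list(duration = 1, targets = list(list(to = "NRPC"))))
    pathways$rgc_diff <- list(
      mechanism = "differentiate", trigger = list(cyclic = 3),
      params = list(duration = 1, targets = list(list(to = "GRPC"))))
    pathways$nrpc_diff <- list(
      mechanism = "differentiate", trigger = list(cyclic = 3), gate = 0.5,
      params = list(duration = 1, targets = lapply(names(bands), function(ly)
        list(to = ly, guard = list(all = list(interval_guard(bands[[ly]])))))))
    # glial amplification is kept subcritical (division rate below the
    # differentiation rate), so the pool self-extinguishes after roughly a
    # 2.4-fold expansion instead of filling the lattice
    pathways$grpc_divide <- list(
      mechanism = "divide_symmetric", trigger = list(cyclic = 4), gate = 0.42,
      guard = list(all = list(leaf("NSCF", "ge", th_div))),
      params = list(duration = 2, max_rounds = 3))
    pathways$grpc_diff <- list(
      mechanism = "differentiate", trigger = list(cyclic = 4), gate = 0.6,
      params = list(duration = 1, targets = list(
        list(to = "T1A", weight = 3,
             guard = list(all = list(leaf("NSCF", "ge", prof(5.8 * s3))))),
        list(to = "OT2APC", weight = 1))))
    pathways$ot2a_diff <- list(
      mechanism = "differentiate", trigger = list(cyclic = 3),
      params = list(duration = 1, targets = list(
        list(to = "ODC", weight = 1),
        list(to = "T2A", weight = 1.5,
             guard = list(all = list(leaf("NSCF", "le", prof(4.0 * s3))))))))

    types$BPC <- list(potency = 6, pathways = "bpc_diff")
    types$RGC <- list(potency = 6, pathways = "rgc_diff")
    types$NRPC <- list(potency = 4, receives = "NSCF", pathways = "nrpc_diff")
    types$GRPC <- list(potency = 4, receives = "NSCF",
                       pathways = c("grpc_divide", "grpc_diff"))
    types$OT2APC <- list(potency = 3, receives = "NSCF", pathways = "ot2a_diff")
    for (ly in names(bands)) types[[ly]] <- list(potency = 1, pathways = character(0))
    for (g in c("T1A", "ODC", "T2A")) types[[g]] <- list(potency = 1,
                                                         pathways = character(0))
    lineage <- c(
      list(list(from = "NPC", to = "BPC"), list(from = "NPC", to = "RGC"),
           list(from = "BPC", to = "NRPC"), list(from = "RGC", to = "GRPC"),
           list(from = "GRPC", to = "T1A"), list(from = "GRPC", to = "OT2APC"),
           list(from = "OT2APC", to = "ODC"), list(from = "OT2APC", to = "T2A")),
      lapply(names(bands), function(ly) list(from = "NRPC", to = ly))
    )
  }

  if (stages >= 3L) {
    # glia answer neuronal NF with GNF unless GNF is already abundant
    pathways$glia_gnf <- list(
      mechanism = "secrete_factor", trigger = list(cyclic = 2),
      guard = list(all = list(leaf("NF", "ge", th_nf, radius = 2L),
                              leaf("GNF", "le", th_gnf_cap, radius = 2L))),
      params = list(factor = "GNF"))
    for (g in c("T1A", "ODC", "T2A")) {
      types[[g]]$pathways <- "glia_gnf"
      types[[g]]$emits <- "GNF"
      types[[g]]$receives <- "NF"
    }
    # per-layer neuron pathways: NF call, GNF-triggered sprouting
    wiring <- list(L1N = list(axon = "L3", dendrite = NULL),
                   L2N = list(axon = "L4", dendrite = "L2"),
                   L3N = list(axon = "L2", dendrite = "L3"),
                   L4N = list(axon = NULL, dendrite = "L4"))
    for (ly in names(wiring)) {
      w <- wiring[[ly]]
      pre <- tolower(sub("N$", "", ly))
      nf_id <- paste0(pre, "_nf")
      sp_id <- paste0(pre, "_sprout")
      pathways[[nf_id]] <- list(
        mechanism = "secrete_factor", trigger = list(cyclic = 2),
        guard = list(all = list(leaf("GNF", "le", th_gnf, radius = 2L))),
        params = list(factor = "NF"))
      sprout <- c(if (!is.null(w$axon)) "axon",
                  if (!is.null(w$dendrite)) "dendrite")
      launch <- character(0)
      if (stages >= 4L) {
        if (!is.null(w$axon)) launch <- c(launch, paste0(pre, "_grow"))
        if (!is.null(w$dendrite))
          launch <- c(launch, paste0(pre, "_agf"), paste0(pre, "_acf"),
                      paste0(pre, "_spine"))
      }
      pathways[[sp_id]] <- list(
        mechanism = "transduce", trigger = list(cyclic = 2),
        guard = list(all = list(leaf("GNF", "ge", th_gnf, radius = 2L))),
        params = list(sprout = sprout, stop = nf_id,
                      launch = if (length(launch)) launch else NULL,
                      once = TRUE))
      types[[ly]]$pathways <- c(nf_id, sp_id)
      types[[ly]]$emits <- "NF"
      types[[ly]]$receives <- c("GNF")
    }
  }

  if (stages >= 4L) {
    wiring <- list(L1N = "L3", L2N = "L4", L3N = "L2") # axon target layers
    for (ly in names(wiring)) {
      pre <- tolower(sub("N$", "", ly))
      tgt <- wiring[[ly]]
      pathways[[paste0(pre, "_grow")]] <- list(
        mechanism = "grow_axon", trigger = list(cyclic = 1),
        params = list(agf = paste0(tgt, "NeuronAGF"),
                      acf = paste0(tgt, "NeuronACF"),
                      target_type = paste0(tgt, "N"),
                      presence_threshold = th_agf, presence_radius = 1,
                      acf_threshold = th_acf, acf_radius = 1,
                      tff = "TFF", dsff = "DSFF", dscf = "DSCF",
                      dsff_threshold = th_dsff, handshake_radius = 2,
                      handshake_patience = 25,
                      max_len = as.integer(ceiling(6 * R)),
                      terminal_duration = 2))
    }
    for (ly in c("L2N", "L3N", "L4N")) { # dendrite-side emissions
      pre <- tolower(sub("N$", "", ly))
      own <- sub("N$", "", ly)
      pathways[[paste0(pre, "_agf")]] <- list(
        mechanism = "secrete_factor", trigger = list(cyclic = 2),
        params = list(factor = paste0(own, "NeuronAGF")))
      pathways[[paste0(pre, "_acf")]] <- list(
        mechanism = "secrete_factor", trigger = list(cyclic = 2),
        params = list(factor = paste0(own, "NeuronACF")))
      pathways[[paste0(pre, "_spine")]] <- list(
        mechanism = "form_spine", trigger = list(cyclic = 2),
        guard = list(all = list(leaf("TFF", "ge", th_tff, radius = 2L))),
        params = list(dsff = "DSFF"))
    }
  }

  default_ticks <- as.integer(ceiling(900 * s3))
  cfg <- list(
    model = list(edge = edge, ticks = as.integer(ticks %||% default_ticks),
                 seed = as.integer(seed), log_level = 0L),
    spatial = list(objects = list(list(type = "NSC", at = ctr))),
    biology = list(factors = factors, cell_types = types,
                   pathways = pathways, lineage = lineage)
  )
  out <- validate_config(cfg)
  attr(out, "meta") <- list(scale = scale, variant = variant, radius = R,
                            center = ctr, stages = stages,
                            thresholds = list(div = th_div, boundary = th_bnd,
                                              apoptosis = th_apop,
                                              npcf = th_npcf))
  out
}

# Stage-4 wiring sub-experiment: pre-placed L1/L3 slabs with glia.
make_wiring_config <- function(seed = 1L, ticks = NULL) {
  edge <- 16L
  grid <- as.matrix(expand.grid(y = c(4L, 6L, 8L, 10L), z = c(4L, 6L, 8L, 10L)))
  objects <- list()
  for (i in seq_len(nrow(grid))) {
    objects[[length(objects) + 1L]] <-
      list(type = "L3N", at = c(5L, grid[i, 1L], grid[i, 2L]))
    objects[[length(objects) + 1L]] <-
      list(type = "L1N", at = c(10L, grid[i, 1L], grid[i, 2L]))
  }
  ggrid <- as.matrix(expand.grid(x = c(6L, 9L), y = c(5L, 7L, 9L),
                                 z = c(5L, 7L, 9L)))
  for (i in seq_len(nrow(ggrid))) {
    objects[[length(objects) + 1L]] <-
      list(type = "T1A", at = as.integer(ggrid[i, ]))
  }
  th_gnf <- 2.0; th_nf <- 1.5
  leaf <- function(factor, op, threshold, radius = 0L)
    list(factor = factor, op = op, threshold = threshold, radius = radius)
  factors <- list(
    NF = list(emission_radius = 2, signal_power = 2, propagation_rate = 0.3,
              degradation_rate = 0.1),
    GNF = list(emission_radius = 2, signal_power = 2, propagation_rate = 0.3,
               degradation_rate = 0.1),
    L3NeuronAGF = list(emission_radius = 7, signal_power = 4,
                       propagation_rate = 0.5, degradation_rate = 0.05),
    L3NeuronACF = list(emission_radius = 2, signal_power = 3,
                       propagation_rate = 0.25, degradation_rate = 0.2),
    TFF = list(emission_radius = 2, signal_power = 3, propagation_rate = 0.3,
               degradation_rate = 0.25),
    DSFF = list(emission_radius = 2, signal_power = 3, propagation_rate = 0.3,
                degradation_rate = 0.25),
    DSCF = list(emission_radius = 1, signal_power = 1, propagation_rate = 0.2,
                degradation_rate = 0.3)
  )
  pathways <- list(
    glia_gnf = list(mechanism = "secrete_factor", trigger = list(cyclic = 2),
                    guard = list(all = list(leaf("NF", "ge", th_nf, radius = 2L))),
                    params = list(factor = "GNF")),
    l1_nf = list(mechanism = "secrete_factor", trigger = list(cyclic = 2),
                 guard = list(all = list(leaf("GNF", "le", th_gnf, radius = 2L))),
                 params = list(factor = "NF")),
    l1_sprout = list(mechanism = "transduce", trigger = list(cyclic = 2),
                     guard = list(all = list(leaf("GNF", "ge", th_gnf, radius = 2L))),
                     params = list(sprout = "axon", stop = "l1_nf",
                                   launch = "l1_grow", once = TRUE)),
    l1_grow = list(mechanism = "grow_axon", trigger = list(cyclic = 1),
                   params = list(agf = "L3NeuronAGF", acf = "L3NeuronACF",
                                 target_type = "L3N",
                                 presence_threshold = 0.05, presence_radius = 1,
                                 acf_threshold = 2.0, acf_radius = 1,
                                 tff = "TFF", dsff = "DSFF", dscf = "DSCF",
                                 dsff_threshold = 0.3, handshake_radius = 2,
                                 handshake_patience = 25, max_len = 30,
                                 terminal_duration = 2)),
    l3_nf = list(mechanism = "secrete_factor", trigger = list(cyclic = 2),
                 guard = list(all = list(leaf("GNF", "le", th_gnf, radius = 2L))),
                 params = list(factor = "NF")),
    l3_sprout = list(mechanism = "transduce", trigger = list(cyclic = 2),
                     guard = list(all = list(leaf("GNF", "ge", th_gnf, radius = 2L))),
                     params = list(sprout = "dendrite", stop = "l3_nf",
                                   launch = c("l3_agf", "l3_acf", "l3_spine"),
                                   once = TRUE)),
    l3_agf = list(mechanism = "secrete_factor", trigger = list(cyclic = 2),
                  params = list(factor = "L3NeuronAGF")),
    l3_acf = list(mechanism = "secrete_factor", trigger = list(cyclic = 2),
                  params = list(factor = "L3NeuronACF")),
    l3_spine = list(mechanism = "form_spine", trigger = list(cyclic = 2),
                    guard = list(all = list(leaf("TFF", "ge", 0.3, radius = 2L))),
                    params = list(dsff = "DSFF"))
  )
  types <- list(
    L1N = list(potency = 1, emits = "NF", receives = "GNF",
               pathways = c("l1_nf", "l1_sprout")),
    L3N = list(potency = 1, emits = "NF", receives = "GNF",
               pathways = c("l3_nf", "l3_sprout")),
    T1A = list(potency = 1, emits = "GNF", receives = "NF",
               pathways = "glia_gnf")
  )
  cfg <- list(model = list(edge = edge, ticks = as.integer(ticks %||% 120L),
                           seed = as.integer(seed), log_level = 0L),
              spatial = list(objects = objects),
              biology = list(factors = factors, cell_types = types,
                             pathways = pathways, lineage = list()))
  out <- validate_config(cfg)
  attr(out, "meta") <- list(stages = 4L, wiring_demo = TRUE)
  out
}
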