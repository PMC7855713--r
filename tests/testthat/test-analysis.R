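# Hand-built snapshot/synapse tables for analysis-layer tests.
fake_cells <- function(types, xs, has_axon = rep(TRUE, length(types)),
                       has_dendrite = rep(TRUE, length(types))) {
  n <- length(types)
  data.frame(id = seq_len(n), type = types, x = xs, y = 0, z = 0,
             status = "active", born = 0L, removed_tick = NA_integer_,
             has_axon = has_axon, has_dendrite = has_dendrite,
             spine_ready = FALSE, axon_length = 0L, terminal_count = 0L,
             cone_state = "", stringsAsFactors = FALSE)
}

test_that("census reconstructs per-tick counts and clusters reconcile", {
  cfg <- toy_division_config(ticks = 20L, gate = 0.8, seed = 5L)
  sim <- run_simulation(cfg)
  cen <- census(sim)
  tot <- attr(cen, "totals")
  # cluster sums equal member sums at every tick
  for (t in unique(cen$tick)[c(1, 10, 20)]) {
    sub <- cen[cen$tick == t, ]
    expect_identical(sum(sub$count), tot$live[tot$tick == t])
  }
  # conservation at every tick
  expect_true(all(attr(cen, "initial") + tot$births - tot$deaths == tot$live))
})

test_that("stem-to-progenitor ratios divide cluster counts and flag 0/0", {
  df <- data.frame(tick = rep(c(1L, 2L), each = 4),
                   type = rep(c("NSC", "NPC", "BPC", "GRPC"), 2),
                   count = c(3L, 1L, 2L, 0L, 0L, 0L, 5L, 5L))
  df$cluster <- cluster_of(df$type)
  out <- stem_progenitor_ratio(df, c(1L, 2L))
  expect_equal(out$ratio[1], (3 + 1) / 2)
  expect_equal(out$stem[2], 0)
  expect_equal(out$ratio[2], 0)
  # undefined when the progenitor pool is empty
  df0 <- df[df$tick == 1L, ]
  df0$count <- c(4L, 2L, 0L, 0L)
  out0 <- stem_progenitor_ratio(df0, 1L)
  expect_true(is.na(out0$ratio))
  # a shrinking stem pool against growing progenitors decreases strictly
  ticks <- 1:5
  dfm <- do.call(rbind, lapply(ticks, function(t)
    data.frame(tick = t, type = c("NSC", "NRPC"), count = c(12L - 2L * t, 3L * t),
               cluster = c("MP", "NP"))))
  r <- stem_progenitor_ratio(dfm, ticks)$ratio
  expect_true(all(diff(r) < 0))
})

test_that("radial distributions bin normalized distances correctly", {
  # all cells at the center: point mass in the first bin, entropy 0
  cells <- fake_cells(rep("L1N", 10), xs = rep(0, 10))
  rd <- radial_distribution(cells, "L1N", center = c(0, 0, 0))
  expect_identical(rd$counts[1], 10L)
  expect_equal(distribution_entropy(rd), 0)
  # a shell plus one cell at the max distance: direct binning oracle
  xs <- c(rep(5, 30), 10)
  cells2 <- fake_cells(rep("L2N", 31), xs = xs)
  rd2 <- radial_distribution(cells2, "L2N", center = c(0, 0, 0), bins = 20L)
  # left-closed binning convention, matched by hist(right = FALSE)
  oracle <- hist(pmin(xs / 10, 1), breaks = seq(0, 1, 0.05), right = FALSE,
                 plot = FALSE)$counts
  expect_identical(rd2$counts, as.integer(oracle))
  expect_identical(sum(rd2$counts), 31L)
})

test_that("entropy matches the direct sum and its analytic bounds", {
  # uniform over k occupied bins -> log k
  cells <- fake_cells(rep("L3N", 20), xs = seq(0.5, 10, length.out = 20))
  rd <- radial_distribution(cells, "L3N", center = c(0, 0, 0), bins = 20L)
  p <- rd$counts / sum(rd$counts)
  oracle <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(distribution_entropy(rd), oracle)
  expect_gte(distribution_entropy(rd), 0)
  expect_lte(distribution_entropy(rd), log(20))
  unif <- list(p = rep(1 / 20, 20))
  expect_equal(distribution_entropy(unif), log(20))
})

test_that("connectivity rates use compartment-formed denominators", {
  # 10 L1 neurons with axons, 9 connected: axon rate 0.9
  cells <- rbind(
    fake_cells(rep("L1N", 10), xs = 1:10, has_axon = TRUE,
               has_dendrite = FALSE),
    fake_cells(rep("L3N", 5), xs = 11:15, has_axon = FALSE,
               has_dendrite = TRUE))
  cells$id <- 1:15
  syn <- data.frame(formed_tick = 1:9, pre_id = 1:9,
                    pre_type = "L1N", post_id = rep(11:13, 3),
                    post_type = "L3N",
                    category = rep("single", 9), stringsAsFactors = FALSE)
  cs <- connectivity_summary(syn, cells)
  r1 <- cs$rates[cs$rates$layer == "L1N", ]
  expect_equal(r1$axon_connection_rate, 0.9)
  r3 <- cs$rates[cs$rates$layer == "L3N", ]
  expect_equal(r3$dendrite_connection_rate, 3 / 5)
  # degree totals: out of L1 equals in at L3
  expect_identical(sum(cs$out_degree), sum(cs$in_degree))
  # dangling ids error and name the culprit
  syn_bad <- syn
  syn_bad$post_id[1] <- 99L
  expect_error(connectivity_summary(syn_bad, cells), "99")
})

test_that("repeated-connection fractions follow the category labels", {
  cells <- fake_cells(c("L1N", "L3N", "L3N"), xs = 1:3)
  syn <- data.frame(formed_tick = 1:4, pre_id = 1L, pre_type = "L1N",
                    post_id = c(2L, 2L, 3L, 2L), post_type = "L3N",
                    category = c("single", "sequentially-repeated", "single",
                                 "non-sequentially-repeated"),
                    stringsAsFactors = FALSE)
  cs <- connectivity_summary(syn, cells)
  rep1 <- cs$repeated[cs$repeated$layer == "L1N", ]
  expect_equal(rep1$seq_repeated_frac, 0.25)
  expect_equal(rep1$nonseq_repeated_frac, 0.25)
})

test_that("axon length ratios are total length over axon count", {
  ax <- data.frame(cell_id = 1:2, cell_type = "L1N", path_length = c(3L, 5L),
                   terminal_count = c(1L, 1L), cone_state = "reversing",
                   stringsAsFactors = FALSE)
  out <- axon_length_stats(ax)
  expect_equal(out$length_to_count_ratio, 4)
  # all-equal lengths give a point-mass distribution
  ax2 <- data.frame(cell_id = 1:5, cell_type = "L2N", path_length = 7L,
                    terminal_count = 0L, cone_state = "growing",
                    stringsAsFactors = FALSE)
  out2 <- axon_length_stats(ax2)
  expect_equal(out2$length_to_count_ratio, 7)
  expect_identical(unique(attr(out2, "lengths")$L2N), 7L)
})

test_that("glia-to-neuron band ratios count glia inside the layer band", {
  cells <- rbind(fake_cells(rep("L1N", 1), xs = 5),
                 fake_cells(rep("T1A", 6), xs = rep(5, 6)),
                 fake_cells(rep("ODC", 2), xs = rep(50, 2)))
  cells$id <- seq_len(nrow(cells))
  out <- glia_neuron_ratio(cells, center = c(0, 0, 0))
  expect_equal(out$ratio[out$layer == "L1N"], 6)
  # no glia in band -> 0
  cells2 <- rbind(fake_cells(rep("L2N", 5), xs = rep(5, 5)))
  out2 <- glia_neuron_ratio(cells2, center = c(0, 0, 0))
  expect_equal(out2$ratio[out2$layer == "L2N"], 0)
})
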