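test_that("extract_window reproduces the worked-example geometry and wraps circularly", {
  g <- rand_genome(16569, seed = 1)
  win <- extract_window(g, 6329, 13993, W = 100)
  expect_equal(win$L_interval, c(6229L, 6429L))
  expect_equal(win$H_interval, c(13893L, 14093L))
  expect_equal(nchar(win$L_window), 201L)
  expect_equal(nchar(win$H_window), 201L)
  expect_equal(win$H_window,
               reverse_complement(circular_slice(g, 13893, 14093)))
  # center offset maps to the breakpoint
  expect_equal(substr(win$L_window, 101, 101), circular_slice(g, 6329, 6329))

  # window wrapping the origin keeps its length
  wo <- extract_window(g, 50, 8000, W = 100)
  expect_equal(nchar(wo$L_window), 201L)
  expect_equal(wo$L_interval, c(16519L, 150L))

  w1 <- extract_window(g, 500, 900, W = 1)
  expect_equal(nchar(w1$L_window), 3L)
  expect_error(extract_window(mt_genome("ACGTACGT"), 1, 5, W = 10), "exceeds")
})

test_that("position-pair propensity sums the l x l overlapping duplex partition functions", {
  g <- rand_genome(1200, seed = 6)
  win <- extract_window(g, 400, 900, W = 10)
  d5 <- direct_pair_propensity(g, 400, 900, 5)
  expect_equal(d5$n_duplexes, 25L)
  expect_equal(position_pair_propensity(win, 0, 0, 5, nn_par), d5$value,
               tolerance = 1e-9)
  # off-center pair
  d3 <- direct_pair_propensity(g, 397, 904, 3)
  expect_equal(d3$n_duplexes, 9L)
  expect_equal(position_pair_propensity(win, -3, 4, 3, nn_par), d3$value,
               tolerance = 1e-9)
  # l = 1: a lone pair has no stack, so every duplex has Z = 0
  expect_equal(position_pair_propensity(win, 0, 0, 1, nn_par), 0)
  expect_error(position_pair_propensity(win, 0, 0, 0, nn_par), "l = 0")
})

test_that("l = 3 propensity equals the hand-summed enumeration oracle", {
  g <- rand_genome(600, seed = 8)
  win <- extract_window(g, 200, 450, W = 5)
  tot <- 0
  for (a in 198:200) {
    segA <- circular_slice(g, a, a + 2)
    for (u in 448:450) {
      segB <- reverse_complement(circular_slice(g, u, u + 2))
      tot <- tot + enumeration_Z(enumerate_configurations(segA, segB, nn_par),
                                 nn_par)
    }
  }
  expect_equal(position_pair_propensity(win, 0, 0, 3, nn_par), tot,
               tolerance = 1e-9)
})

test_that("propensity maps are deterministic, conserve mass under binning and normalize", {
  g <- rand_genome(2000, seed = 12)
  win <- extract_window(g, 600, 1400, W = 20)
  pm <- propensity_map(win, 5, nn_par)
  expect_true(all(pm$values >= 0), all(is.finite(pm$values)))
  pm2 <- propensity_map(win, 5, nn_par)       # recomputation is identical
  expect_identical(pm$values, pm2$values)
  bm <- bin_map(pm, 5)
  expect_equal(sum(bm$bins), sum(pm$values[1:40, 1:40]), tolerance = 1e-9)
  expect_equal(sum(bm$relative_bins), 1, tolerance = 1e-12)
  expect_equal(bm$breakpoint_bin, c(5L, 5L))
})

test_that("degenerate maps: uniform map gives equal bins, single spike owns its bin, all-N falls back", {
  mk_map <- function(vals, W) structure(list(l = 5L, W = W, p5 = 1L, p3 = 1L,
                                             values = vals),
                                        class = "PropensityMap")
  W <- 20L
  uni <- bin_map(mk_map(matrix(1, 2 * W + 1, 2 * W + 1), W), 5L)
  expect_true(all(abs(uni$relative_bins - 1 / 64) < 1e-12))
  spike <- matrix(0, 2 * W + 1, 2 * W + 1); spike[22, 22] <- 3.7
  bs <- bin_map(mk_map(spike, W), 5L)
  expect_equal(bs$relative_bins[bs$breakpoint_bin[1], bs$breakpoint_bin[2]], 1)
  # all-N window: every duplex has Z = 0
  gN <- mt_genome(strrep("N", 800))
  winN <- extract_window(gN, 200, 600, W = 10)
  pmN <- propensity_map(winN, 5, nn_par)
  expect_true(all(pmN$values == 0))
  expect_warning(bN <- bin_map(pmN, 5), "uniform")
  expect_equal(sum(bN$relative_bins), 1, tolerance = 1e-12)
})

test_that("breakpoint profile has the exact uniform l = 0 component", {
  g <- rand_genome(2000, seed = 2)
  prof <- breakpoint_profile(g, 500, 1500, grid = c(0L, 5L), params = nn_par,
                             W = 20L, b = 5L)
  expect_identical(prof[["0"]], 1 / 64)
  expect_true(prof[["5"]] > 0 && prof[["5"]] <= 1)
})

test_that("planted perfect repeats are recovered at their length", {
  # 10-mer and 25-mer at W = 50, b = 10
  grid <- c(0L, 5L, 10L, 15L, 25L, 50L)
  spec10 <- simulation_spec(genome_length = 4000L, theta_true = c(`0` = 1),
                            n = 1L, region5 = c(1001L, 1001L),
                            region3 = c(2501L, 2501L), grid = c(0L, 10L),
                            seed = 13L,
                            planted_repeats = data.frame(length = 10L,
                                                         pos5 = 1001L,
                                                         pos3 = 2501L))
  g10 <- synthetic_genome(spec10)
  p10 <- breakpoint_profile(g10, 1001L, 2501L, grid = grid, params = nn_par,
                            W = 50L, b = 10L)
  expect_equal(grid[which.max(p10)], 10L)
  expect_gt(p10[["10"]], 10 / 100)      # >> uniform 1/100

  spec25 <- simulation_spec(genome_length = 4000L, theta_true = c(`0` = 1),
                            n = 1L, region5 = c(1001L, 1001L),
                            region3 = c(2501L, 2501L), grid = c(0L, 25L),
                            seed = 28L,
                            planted_repeats = data.frame(length = 25L,
                                                         pos5 = 1001L,
                                                         pos3 = 2501L))
  g25 <- synthetic_genome(spec25)
  p25 <- breakpoint_profile(g25, 1001L, 2501L, grid = grid, params = nn_par,
                            W = 50L, b = 10L)
  # a perfect repeat much longer than the bin spreads its duplex mass over
  # neighboring bins, capping the breakpoint-bin share near (b/(2l-b))-type
  # geometry; assert strong elevation and dominance over the longer lengths
  expect_gt(p25[["25"]], 10 / 100)
  expect_gt(p25[["25"]], p25[["50"]])
  expect_gt(p25[["25"]], p25[["15"]])

  # 5-mer: only detectable above chance in a small window (short perfect
  # duplexes are marginal against background, as expected thermodynamically)
  spec5 <- simulation_spec(genome_length = 3000L, theta_true = c(`0` = 1),
                           n = 1L, region5 = c(1001L, 1001L),
                           region3 = c(2001L, 2001L), grid = c(0L, 5L),
                           seed = 9L,
                           planted_repeats = data.frame(length = 5L,
                                                        pos5 = 1001L,
                                                        pos3 = 2001L))
  g5 <- synthetic_genome(spec5)
  p5 <- breakpoint_profile(g5, 1001L, 2001L, grid = c(0L, 5L, 10L, 15L),
                           params = nn_par, W = 20L, b = 5L)
  expect_equal(c(0, 5, 10, 15)[which.max(p5)], 5)
})

test_that("translating the planted repeat by one bin moves the maximal bin by one index", {
  spec <- simulation_spec(genome_length = 4000L, theta_true = c(`0` = 1),
                          n = 1L, region5 = c(1001L, 1001L),
                          region3 = c(2501L, 2501L), grid = c(0L, 10L),
                          seed = 13L,
                          planted_repeats = data.frame(length = 10L,
                                                       pos5 = 1001L,
                                                       pos3 = 2501L))
  g <- synthetic_genome(spec)
  b1 <- bin_map(propensity_map(extract_window(g, 1001L, 2501L, 50L), 10L, nn_par), 10L)
  b2 <- bin_map(propensity_map(extract_window(g, 1011L, 2511L, 50L), 10L, nn_par), 10L)
  am1 <- which(b1$relative_bins == max(b1$relative_bins), arr.ind = TRUE)
  am2 <- which(b2$relative_bins == max(b2$relative_bins), arr.ind = TRUE)
  expect_equal(as.integer(am1), as.integer(am2) + c(1L, 1L))
})

test_that("the shared-grid engine agrees with direct window computation", {
  g <- rand_genome(4000, seed = 21)
  eng <- propensity_engine(g, nn_par, c(0L, 5L, 10L), W = 20L, b = 5L)
  pairs <- data.frame(p5 = c(1000L, 1040L, 1000L), p3 = c(2500L, 2560L, 2500L))
  pr <- engine_profiles(eng, pairs)
  expect_equal(pr$P[1, ], pr$P[3, ])          # duplicate pairs share profiles
  for (k in 1:2) {
    win <- extract_window(g, pairs$p5[k], pairs$p3[k], 20L)
    for (l in c(5L, 10L)) {
      bm <- bin_map(propensity_map(win, l, nn_par), 5L)
      expect_equal(unname(pr$P[k, as.character(l)]),
                   bm$relative_bins[bm$breakpoint_bin[1], bm$breakpoint_bin[2]],
                   tolerance = 1e-9)
    }
  }
  # engine pair propensity equals the direct double loop
  v <- mtMisalign:::.engine_pair_propensity(eng, 5L, 1000L, 2500L)
  expect_equal(v, direct_pair_propensity(g, 1000L, 2500L, 5)$value,
               tolerance = 1e-9)
})
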