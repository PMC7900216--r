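test_that("component matrix has the uniform l = 0 column and row independence", {
  g <- rand_genome(3000, seed = 31)
  ds <- breakpoint_dataset(c(800L, 850L, 800L), c(2200L, 2300L, 2200L), g, "toy")
  cm <- component_matrix(ds, grid = c(0L, 5L, 10L), params = nn_par,
                         W = 20L, b = 5L)
  expect_equal(dim(cm$P), c(3L, 3L))
  expect_true(all(cm$P[, "0"] == 1 / 64))
  expect_true(all(cm$P > 0 & cm$P <= 1))
  # permuting dataset rows permutes matrix rows only
  dsp <- breakpoint_dataset(c(850L, 800L, 800L), c(2300L, 2200L, 2200L), g, "toy")
  cmp <- component_matrix(dsp, grid = c(0L, 5L, 10L), params = nn_par,
                          W = 20L, b = 5L)
  expect_equal(cmp$P[c(2L, 1L, 3L), ], cm$P, ignore_attr = TRUE)

  # single-deletion dataset
  ds1 <- breakpoint_dataset(800L, 2200L, g, "one")
  cm1 <- component_matrix(ds1, grid = c(0L, 5L), params = nn_par, W = 20L, b = 5L)
  expect_equal(dim(cm1$P), c(1L, 2L))
  expect_equal(unname(cm1$P[1, "0"]), 1 / 64)
})

test_that("planted-repeat datasets give dominant columns at the planted length", {
  spec <- simulation_spec(genome_length = 4000L, theta_true = c(`0` = 1), n = 1L,
                          region5 = c(1001L, 1001L), region3 = c(2501L, 2501L),
                          grid = c(0L, 10L), seed = 13L,
                          planted_repeats = data.frame(length = 10L,
                                                       pos5 = 1001L, pos3 = 2501L))
  g <- synthetic_genome(spec)
  ds <- breakpoint_dataset(rep(1001L, 3), rep(2501L, 3), g, "planted")
  cm <- component_matrix(ds, grid = c(0L, 5L, 10L, 15L), params = nn_par,
                         W = 50L, b = 10L)
  expect_true(all(cm$P[, "10"] == apply(cm$P, 1, max)))
})

test_that("EM maximizes the simplex likelihood (grid-search oracle) with monotone trace", {
  set.seed(77)
  n <- 50L
  theta_star <- c(0.6, 0.3, 0.1)
  # component likelihoods: rows drawn from one of three distinct profiles
  prof <- rbind(c(0.02, 0.001, 0.004),
                c(0.002, 0.03, 0.001),
                c(0.003, 0.002, 0.05))
  z <- sample.int(3, n, replace = TRUE, prob = theta_star)
  P <- prof[z, ] * exp(stats::rnorm(n, 0, 0.1))   # row scale jitter
  fit <- fit_mixture(P)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))      # EM monotonicity
  expect_equal(sum(fit$theta), 1, tolerance = 1e-10)
  expect_true(all(fit$theta >= 0))
  expect_true(fit$converged)
  # dense simplex grid-search oracle
  step <- 0.01
  best <- -Inf
  for (a in seq(0, 1, step)) for (bq in seq(0, 1 - a, step)) {
    ll <- sum(log(P %*% c(a, bq, 1 - a - bq)))
    if (ll > best) best <- ll
  }
  expect_lt(abs(fit$loglik - best), 1e-3 + 1e-6 * abs(best))
  expect_gte(fit$loglik, best - 1e-9)   # EM at least matches the grid

  # multi-start agreement
  fit2 <- fit_mixture(P, n_starts = 5L, seed = 1L)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("EM degenerate cases: one component, flat likelihood, row-scaling invariance", {
  expect_equal(as.numeric(fit_mixture(matrix(0.3, 10, 1))$theta), 1)
  # all rows identical and uniform across l: uniform start is a fixed point
  flat <- fit_mixture(matrix(0.02, 20, 4))
  expect_equal(as.numeric(flat$theta), rep(0.25, 4), tolerance = 1e-12)
  expect_false(flat$identifiable)
  # scaling single rows leaves the optimum unchanged
  set.seed(5)
  P <- matrix(stats::runif(60, 0.001, 0.05), 20, 3)
  f1 <- fit_mixture(P)
  P2 <- P * stats::runif(20, 0.5, 2)   # per-row constants
  f2 <- fit_mixture(P2)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
  expect_error(fit_mixture(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("group_weights partitions the grid into short/medium/long", {
  th <- setNames(rep(1 / 9, 9), default_length_grid())
  expect_equal(group_weights(th), c(short = 2 / 9, medium = 4 / 9, long = 3 / 9))
  th5 <- setNames(c(0, 1, rep(0, 7)), default_length_grid())
  expect_equal(group_weights(th5), c(short = 1, medium = 0, long = 0))
  set.seed(6)
  for (i in 1:10) {
    x <- stats::runif(9); x <- x / sum(x)
    expect_equal(sum(group_weights(setNames(x, default_length_grid()))), 1)
  }
})

test_that("bootstrap SDs are reproducible, shrink with n, and vanish for separated fits", {
  g <- rand_genome(6000, seed = 41)
  grid <- c(0L, 5L, 10L)
  eng <- propensity_engine(g, nn_par, grid, W = 10L, b = 5L)
  mk <- function(n, seed) {
    set.seed(seed)
    p5 <- sample(seq(1001L, 1301L, by = 10L), n, replace = TRUE)
    p3 <- sample(seq(4001L, 4301L, by = 10L), n, replace = TRUE)
    breakpoint_dataset(p5, p3, g, "bs")
  }
  run_bs <- function(n, B, seed) {
    ds <- mk(n, seed)
    cm <- component_matrix(ds, grid, nn_par, W = 10L, b = 5L, engine = eng,
                           want_bins = TRUE, margin = 10L)
    fit <- fit_mixture(cm)
    bootstrap_sd(fit, cm, B = B, seed = 100L + seed)
  }
  b1 <- run_bs(40L, 10L, 1L)
  b1b <- run_bs(40L, 10L, 1L)
  expect_identical(b1$sd_grouped, b1b$sd_grouped)   # determinism given seed
  expect_equal(dim(b1$replicates), c(10L, 3L))
  b2 <- run_bs(640L, 10L, 1L)
  # SDs scale roughly as 1/sqrt(n): 16x the data should clearly shrink them
  expect_lt(max(b2$sd_grouped), max(b1$sd_grouped))

  # strongly separated component matrix pinned at one component: SDs near 0
  Psep <- cbind(`0` = rep(1 / 64, 30), `5` = 0.9, `10` = 1e-6)
  cm_f <- structure(list(P = Psep, grid = grid, nbins = 4L,
                         pairs = mk(30L, 3L)$breakpoints[, c("p5", "p3")],
                         bins = list(`0` = matrix(1 / 16, 30, 16),
                                     `5` = matrix(c(1, rep(0, 15)), 30, 16,
                                                  byrow = TRUE),
                                     `10` = matrix(1 / 16, 30, 16)),
                         engine = eng, name = "sep"),
                    class = "ComponentMatrix")
  fit_sep <- fit_mixture(cm_f)
  expect_gt(fit_sep$theta[["5"]], 0.95)
})
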