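#' Specification for a synthetic validation study
#'
#' Defines the conditions under which in-silico breakpoint catalogs with a
#' known mixture of misalignment lengths are generated: a random circular
#' genome, two candidate arcs (one for 5' and one for 3' breakpoints) with a
#' regular lattice of candidate positions, and the true simplex weights over
#' the length grid.
#'
#' @param genome_length Genome size in nt (>= 1000).
#' @param gc_content GC fraction of the random genome.
#' @param theta_true Simplex weights, named by grid length or matching
#'   \code{grid}.
#' @param n Number of deletions to draw.
#' @param region5,region3 \code{c(start, end)} candidate arcs for the 5' and
#'   3' breakpoints.  A single shared interval may be given as
#'   \code{region5 = c(start, end), region3 = NULL}; it is split at its
#'   midpoint.
#' @param stride Lattice stride in nt (default 10, the bin size, so sampling
#'   resolution equals analysis resolution).
#' @param grid Length grid.
#' @param sampling How breakpoints are placed given a drawn length l.
#'   \code{"bin"} (default): a candidate pair is drawn from the lattice with
#'   probability proportional to the relative breakpoint-bin propensity of
#'   its own window at length l - i.e. the data are drawn from the mixture
#'   model the analysis fits, which is what a parameter-recovery validation
#'   requires.  \code{"lattice"}: the pair is drawn with probability
#'   proportional to its raw position-pair propensity at l (no within-window
#'   normalization).
#' @param seed Integer seed; all outputs are pure functions of (spec, seed).
#' @param planted_repeats Optional data frame with columns \code{length},
#'   \code{pos5}, \code{pos3}: perfect direct repeats to embed.
#' @return A \code{SimulationSpec}.
#' @export
simulation_spec <- function(genome_length = 16000L, gc_content = 0.44,
                            theta_true = c(`0` = 0.2, `5` = 0.5, `20` = 0.3),
                            n = 2000L,
                            region5 = c(3001L, 3200L), region3 = c(9001L, 9200L),
                            stride = 10L, grid = default_length_grid(),
                            sampling = c("bin", "lattice"),
                            seed = 1L, planted_repeats = NULL) {
  stopifnot(genome_length >= 1000L, gc_content > 0, gc_content < 1, n >= 1L,
            stride >= 1L)
  sampling <- match.arg(sampling)
  if (is.null(region3)) {
    mid <- floor((region5[1] + region5[2]) / 2)
    region3 <- c(mid + 1L, region5[2]); region5 <- c(region5[1], mid)
  }
  grid <- as.integer(grid)
  th <- rep(0, length(grid)); names(th) <- grid
  if (is.null(names(theta_true))) {
    stopifnot(length(theta_true) == length(grid))
    th[] <- theta_true
  } else {
    miss <- setdiff(names(theta_true), as.character(grid))
    if (length(miss)) stop("theta_true names not in grid: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    th[names(theta_true)] <- theta_true
  }
  if (any(th < 0) || abs(sum(th) - 1) > 1e-8)
    stop("theta_true must be non-negative and sum to 1", call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, theta_true = th, n = as.integer(n),
                 region5 = as.integer(region5), region3 = as.integer(region3),
                 stride = as.integer(stride), grid = grid, sampling = sampling,
                 seed = as.integer(seed), planted_repeats = planted_repeats),
            class = "SimulationSpec")
}

#' Generate a random circular genome, optionally with planted repeats
#'
#' Bases are i.i.d. at the requested GC content.  Each planted repeat copies
#' the segment at \code{pos5} to \code{pos3}, creating a perfect direct
#' repeat; overlapping plants are an error.
#'
#' @param spec A \code{SimulationSpec}.
#' @return An \code{MtGenome} with attribute \code{"planted"}.
#' @export
synthetic_genome <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  p <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
         spec$gc_content / 2, (1 - spec$gc_content) / 2)
  bases <- sample(c("A", "C", "G", "T"), spec$genome_length, replace = TRUE,
                  prob = p)
  pr <- spec$planted_repeats
  if (!is.null(pr)) {
    iv <- cbind(c(pr$pos5, pr$pos3), c(pr$pos5 + pr$length - 1L,
                                       pr$pos3 + pr$length - 1L))
    if (any(iv > spec$genome_length) || any(iv < 1))
      stop("planted repeat extends outside the genome", call. = FALSE)
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)]))
      stop("planted repeats overlap", call. = FALSE)
    for (r in seq_len(nrow(pr))) {
      seg <- bases[pr$pos5[r]:(pr$pos5[r] + pr$length[r] - 1L)]
      bases[pr$pos3[r]:(pr$pos3[r] + pr$length[r] - 1L)] <- seg
    }
  }
  g <- mt_genome(paste(bases, collapse = ""),
                 id = sprintf("synthetic_L%d_gc%.2f_seed%d", spec$genome_length,
                              spec$gc_content, spec$seed))
  attr(g, "planted") <- pr
  g
}

# Maximum-entropy base measure over the candidate lattice.
#
# The mixture likelihood normalizes propensities within each deletion's own
# window, so it is a pseudo-likelihood over breakpoint positions: its MLE is
# consistent only when every length component q_l assigns the same total
# mass over the sampling space.  On small candidate arcs the analysis
# windows see sequence the lattice does not cover, so no raw
# propensity-proportional sampling satisfies that.  We therefore choose the
# base measure h maximizing entropy subject to
#     sum_x h(x) (q_l(x) - 1/nbins^2) = 0   for simulated lengths l,
#     sum_x h(x) (q_l(x) - 1/nbins^2) <= 0  for the other grid lengths,
# i.e. h(x) = exp(-sum_l nu_l d_l(x)) with free duals on the simulated
# support and non-negative duals elsewhere - a smooth convex dual solved by
# L-BFGS-B.  Sampling x | l ~ h q_l then makes theta* the exact population
# optimum of the fitted mixture.
.calibrate_base_measure <- function(Q, support) {
  q0 <- Q[1, "0"]
  D <- sweep(Q[, colnames(Q) != "0", drop = FALSE], 2, q0, `-`) / q0
  free <- colnames(D) %in% as.character(support)
  phi <- function(nu) {
    e <- as.numeric(D %*% nu); m <- min(e)
    log(sum(exp(-(e - m)))) - m
  }
  gr <- function(nu) {
    e <- as.numeric(D %*% nu); w <- exp(-(e - min(e))); w <- w / sum(w)
    -as.numeric(crossprod(D, w))
  }
  opt <- stats::optim(rep(0, ncol(D)), phi, gr, method = "L-BFGS-B",
                      lower = ifelse(free, -Inf, 0),
                      control = list(maxit = 1000))
  e <- as.numeric(D %*% opt$par)
  h <- exp(-(e - mean(e)))
  cl <- colSums(Q * h) / (sum(h) * q0)   # component integrals, uniform = 1
  if (opt$convergence != 0 || any(abs(cl[as.character(support)] - 1) > 0.02))
    warning("base-measure calibration is approximate (component integrals ",
            paste(sprintf("%s: %.3f", names(cl), cl), collapse = ", "), ")")
  h
}

#' Draw an in-silico breakpoint catalog with known mixture structure
#'
#' For each deletion a misalignment length l is drawn from
#' \code{theta_true}, then a breakpoint pair is placed according to
#' \code{spec$sampling}: in \code{"bin"} mode (default) a candidate pair is
#' drawn from the lattice with probability proportional to the relative
#' breakpoint-bin propensity of its own window at l (uniform for l = 0), so
#' catalogs follow the fitted mixture family; in \code{"lattice"} mode the
#' pair is drawn with probability proportional to its raw position-pair
#' propensity at l (uniformly for l = 0).  True lengths are recorded in the
#' \code{true_l} column so evaluation never re-infers them.
#'
#' @param genome The \code{MtGenome} to simulate on (normally
#'   \code{synthetic_genome(spec)}).
#' @param spec A \code{SimulationSpec}.
#' @param params An \code{NNParameterSet}.
#' @param W Window half-width used by the downstream analysis.
#' @param b Bin size.
#' @param engine Optional shared \code{PropensityEngine}.
#' @return A \code{BreakpointDataset} with a \code{true_l} column and the
#'   spec attached as attribute \code{"spec"}.
#' @export
simulate_breakpoints <- function(genome, spec, params = load_nn_parameters(),
                                 W = 100L, b = 10L, engine = NULL) {
  stopifnot(inherits(genome, "MtGenome"), inherits(spec, "SimulationSpec"))
  p5s <- seq.int(spec$region5[1], spec$region5[2], by = spec$stride)
  p3s <- seq.int(spec$region3[1], spec$region3[2], by = spec$stride)
  cand <- expand.grid(p5 = p5s, p3 = p3s)
  if (is.null(engine))
    engine <- propensity_engine(genome, params, spec$grid, W = W, b = b)
  set.seed(spec$seed + 1L)
  li <- sample.int(length(spec$grid), spec$n, replace = TRUE,
                   prob = spec$theta_true)
  if (spec$sampling == "bin") {
    # Draw pairs from the generative model for which the per-window mixture
    # likelihood is a consistent maximum-likelihood estimator: p(x | l)
    # proportional to h(x) q_l(x), where q_l(x) is the relative
    # breakpoint-bin propensity of x's own window and h is a shared base
    # measure calibrated on the candidate lattice (see
    # .calibrate_base_measure) so every simulated component integrates the
    # fitted likelihood identically and no other grid length integrates it
    # more.  theta* is then the population optimum of the fit.
    pr <- engine_profiles(engine, cand)        # rows align with cand
    support <- spec$grid[spec$theta_true > 0]
    h <- .calibrate_base_measure(pr$P, support[support > 0L])
    pick <- integer(spec$n)
    for (ki in sort(unique(li))) {
      rows <- which(li == ki)
      l <- spec$grid[ki]
      wts <- if (l == 0L) h else h * pr$P[, as.character(l)]
      if (sum(wts) <= 0)
        stop("zero total propensity over candidate pairs at l = ", l,
             call. = FALSE)
      pick[rows] <- sample.int(nrow(cand), length(rows), replace = TRUE,
                               prob = as.numeric(wts))
    }
    ds <- breakpoint_dataset(cand$p5[pick], cand$p3[pick], genome,
                             name = "simulated", species = "synthetic",
                             true_l = spec$grid[li])
  } else {
    pick <- integer(spec$n)
    for (ki in sort(unique(li))) {
      rows <- which(li == ki)
      l <- spec$grid[ki]
      if (l == 0L) {
        pick[rows] <- sample.int(nrow(cand), length(rows), replace = TRUE)
      } else {
        wts <- .engine_pair_propensity(engine, l, cand$p5, cand$p3)
        if (sum(wts) <= 0)
          stop("zero total propensity over candidate pairs at l = ", l,
               call. = FALSE)
        pick[rows] <- sample.int(nrow(cand), length(rows), replace = TRUE,
                                 prob = wts)
      }
    }
    ds <- breakpoint_dataset(cand$p5[pick], cand$p3[pick], genome,
                             name = "simulated", species = "synthetic",
                             true_l = spec$grid[li])
  }
  attr(ds, "spec") <- spec
  attr(ds, "engine") <- engine
  ds
}
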