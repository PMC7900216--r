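#' Default grid of misalignment lengths
#'
#' Nine lengths from 0 to 100 nt; 0 is the hybridization-independent
#' (uniform) component.
#' @return Integer vector \code{c(0, 5, 10, 15, 20, 25, 50, 75, 100)}.
#' @export
default_length_grid <- function() c(0L, 5L, 10L, 15L, 20L, 25L, 50L, 75L, 100L)

.check_grid <- function(grid, W) {
  grid <- as.integer(grid)
  stopifnot(length(grid) >= 1L, !is.unsorted(grid, strictly = TRUE),
            0L %in% grid, all(grid <= 2L * W + 1L))
  grid
}

#' Extract the two-strand window of analysis around a breakpoint
#'
#' The L-strand window is the circular reference slice \code{p5 - W ..
#' p5 + W} (reference orientation, 5' to 3'); the H-strand window is the
#' reverse complement of the slice \code{p3 - W .. p3 + W}.
#'
#' @param genome An \code{MtGenome}.
#' @param p5,p3 Breakpoint positions.
#' @param W Window half-width in nt (default 100, i.e. 201-nt windows).
#' @return An \code{AnalysisWindow}: list with \code{L_window},
#'   \code{H_window}, the reference-coordinate intervals \code{L_interval}
#'   and \code{H_interval} (wrapped to \code{[1, length]}), \code{W} and the
#'   breakpoint.
#' @export
extract_window <- function(genome, p5, p3, W = 100L) {
  stopifnot(inherits(genome, "MtGenome"), W >= 1L)
  L <- genome$length
  if (2L * W + 1L > L) stop("window (2W+1 = ", 2 * W + 1,
                            " nt) exceeds genome length ", L, call. = FALSE)
  if (p5 < 1 || p5 > L || p3 < 1 || p3 > L)
    stop("breakpoint positions outside [1, ", L, "]", call. = FALSE)
  Lwin <- .circular_slice_any(genome, p5 - W, p5 + W)
  Hsl <- .circular_slice_any(genome, p3 - W, p3 + W)
  structure(list(
    genome = genome, p5 = as.integer(p5), p3 = as.integer(p3), W = as.integer(W),
    L_window = Lwin,
    H_window = reverse_complement(Hsl),
    L_interval = as.integer(c(.wrap_pos(p5 - W, L), .wrap_pos(p5 + W, L))),
    H_interval = as.integer(c(.wrap_pos(p3 - W, L), .wrap_pos(p3 + W, L)))
  ), class = "AnalysisWindow")
}

#' @export
print.AnalysisWindow <- function(x, ...) {
  cat("AnalysisWindow (", 2 * x$W + 1, " x ", 2 * x$W + 1, " nt) at (",
      x$p5, ":", x$p3, "); L ", x$L_interval[1], "..", x$L_interval[2],
      ", H ", x$H_interval[1], "..", x$H_interval[2], "\n", sep = "")
  invisible(x)
}

# --- duplex partition-function grid over genome coordinates ---------------
#
# .zgrid(): matrix Z[a, u] with a = a_lo..a_hi, u = u_lo..u_hi, where entry
# (a, u) is the partition function of the duplex between the L-strand l-mer
# starting at reference position a and the H-strand l-mer whose reference
# footprint starts at u.  Both extended slices are read circularly; in the
# kernel's bottom-strand orientation the H l-mer is simply the complement of
# the reference slice, so the grid is computed without any per-duplex
# reversal.
.zgrid <- function(genome, a_lo, a_hi, u_lo, u_hi, l, params) {
  Aext <- .encode_seq(.circular_slice_any(genome, a_lo, a_hi + l - 1L))
  Cext <- .encode_seq(.complement_chr(
    .circular_slice_any(genome, u_lo, u_hi + l - 1L)))
  .pf_grid_cpp(Aext, Cext, as.integer(l), .par_for_cpp(params))
}

# summed-area table with zero padding row/col
.sat <- function(M) {
  S <- matrix(0, nrow(M) + 1L, ncol(M) + 1L)
  S[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  S
}

# sum b x b patches of a (nb*b) x (nb*b) matrix; rows of the result follow
# rows of V (L axis), columns follow columns (H axis)
.bin_sums <- function(V, nb, b) {
  g <- rep(seq_len(nb), each = b)
  t(rowsum(t(rowsum(V, g)), g))
}

# box sums over a SAT: rows r1..r2, cols c1..c2 (vectors give a matrix)
.boxsum <- function(S, r1, r2, c1, c2) {
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

#' Misalignment propensity of one position pair
#'
#' Sum of duplex partition functions over the \code{l * l} pairs of l-nt
#' segments - one from the L-strand containing position \code{p5 + i}, one
#' from the H-strand containing position \code{p3 + j} - that overlap the
#' position pair.  Segments may extend past the window edge; they are read
#' from the circular genome.
#'
#' @param window An \code{AnalysisWindow}.
#' @param i,j Offsets from the window centers, in \code{-W..W}.
#' @param l Misalignment length (>= 1; the l = 0 component is uniform and
#'   handled at the bin level).
#' @param params An \code{NNParameterSet}.
#' @return Non-negative propensity value.
#' @export
position_pair_propensity <- function(window, i, j, l, params = load_nn_parameters()) {
  stopifnot(inherits(window, "AnalysisWindow"))
  if (l < 1) stop("l must be >= 1 (the l = 0 component is handled at bin level)",
                  call. = FALSE)
  stopifnot(abs(i) <= window$W, abs(j) <= window$W)
  x <- window$p5 + i; y <- window$p3 + j
  Z <- .zgrid(window$genome, x - l + 1L, x, y - l + 1L, y, l, params)
  sum(Z)
}

#' Full propensity map of a window at one length
#'
#' @param window An \code{AnalysisWindow}.
#' @param l Misalignment length (>= 1).
#' @param params An \code{NNParameterSet}.
#' @return A \code{PropensityMap}: list with \code{values} (a
#'   \code{(2W+1) x (2W+1)} matrix, rows = L offsets \code{-W..W}, cols = H
#'   offsets), \code{l}, \code{W} and the breakpoint.
#' @export
propensity_map <- function(window, l, params = load_nn_parameters()) {
  stopifnot(inherits(window, "AnalysisWindow"))
  if (l < 1) stop("l must be >= 1", call. = FALSE)
  W <- window$W
  Z <- .zgrid(window$genome, window$p5 - W - l + 1L, window$p5 + W,
              window$p3 - W - l + 1L, window$p3 + W, l, params)
  S <- .sat(Z)
  idx <- seq_len(2L * W + 1L)      # position index within the window
  vals <- .boxsum(S, idx, idx + l - 1L, idx, idx + l - 1L)
  vals[vals < 0] <- 0              # guard against summed-area cancellation
  dimnames(vals) <- list(L_offset = -W:W, H_offset = -W:W)
  structure(list(l = as.integer(l), W = W, p5 = window$p5, p3 = window$p3,
                 values = vals), class = "PropensityMap")
}

#' Bin a propensity map into b x b-nt bins
#'
#' The window axes are tiled with \code{2W / b} bins covering offsets
#' \code{-W .. W-1} (the single offset \code{+W} is dropped, giving the
#' default 20 x 20 = 400-bin geometry for W = 100, b = 10).  An all-zero map
#' falls back to the uniform distribution with a warning so downstream
#' likelihoods stay finite.
#'
#' @param map A \code{PropensityMap}.
#' @param b Bin size in nt; must divide \code{2W}.
#' @return A \code{BinnedPropensityMap}: list with \code{bins},
#'   \code{relative_bins} (normalized to sum 1), \code{breakpoint_bin}
#'   (row/col of the bin containing offset 0), \code{l} and \code{b}.
#' @export
bin_map <- function(map, b = 10L) {
  stopifnot(inherits(map, "PropensityMap"))
  W <- map$W
  if ((2L * W) %% b != 0L) stop("bin size b must divide 2W", call. = FALSE)
  nb <- (2L * W) %/% b
  V <- map$values[seq_len(2L * W), seq_len(2L * W)]
  bins <- .bin_sums(V, nb, b)             # nb x nb
  tot <- sum(bins)
  if (tot <= 0) {
    warning("all-zero propensity map; falling back to the uniform bin distribution")
    rel <- matrix(1 / (nb * nb), nb, nb)
  } else {
    rel <- bins / tot
  }
  bb <- W %/% b + 1L                       # bin containing offset 0
  structure(list(l = map$l, b = as.integer(b), bins = bins,
                 relative_bins = rel, breakpoint_bin = c(bb, bb)),
            class = "BinnedPropensityMap")
}

#' Per-length relative breakpoint-bin propensity profile
#'
#' For each length l in the grid, the relative propensity of the bin
#' containing the breakpoint: exactly \code{1 / nbins^2} for l = 0 (the
#' uniform component), and the breakpoint bin of the binned propensity map
#' for l >= 1.
#'
#' @param genome An \code{MtGenome}.
#' @param p5,p3 Breakpoint positions.
#' @param grid Length grid (must contain 0, strictly increasing).
#' @param params An \code{NNParameterSet}.
#' @param W Window half-width (default 100).
#' @param b Bin size (default 10).
#' @return Named numeric vector, one entry per grid length.
#' @export
breakpoint_profile <- function(genome, p5, p3, grid = default_length_grid(),
                               params = load_nn_parameters(), W = 100L, b = 10L) {
  eng <- propensity_engine(genome, params, grid, W = W, b = b)
  drop(engine_profiles(eng, data.frame(p5 = p5, p3 = p3))$P)
}

# --- shared-grid engine ----------------------------------------------------
#
# For a set of breakpoints, duplex partition functions are computed once per
# length over the union bounding box of all windows (plus an optional margin)
# and turned into a summed-area table; window maps, bin sums and pair
# propensities are then O(1) lookups.  This mirrors pre-computing partition
# functions over the analyzed arc.  If the union box exceeds max_cells, each
# breakpoint gets its own grid instead (slower, unbounded geometry).

#' Create a propensity engine over a genome
#'
#' @param genome An \code{MtGenome}.
#' @param params An \code{NNParameterSet}.
#' @param grid Length grid.
#' @param W Window half-width.
#' @param b Bin size.
#' @param max_cells Largest per-length duplex grid held in memory before
#'   falling back to per-breakpoint computation.
#' @return An environment of class \code{PropensityEngine}.
#' @export
propensity_engine <- function(genome, params = load_nn_parameters(),
                              grid = default_length_grid(), W = 100L, b = 10L,
                              max_cells = 4e6) {
  grid <- .check_grid(grid, W)
  if ((2L * W) %% b != 0L) stop("bin size b must divide 2W", call. = FALSE)
  eng <- new.env(parent = emptyenv())
  eng$genome <- genome; eng$params <- params; eng$grid <- grid
  eng$W <- as.integer(W); eng$b <- as.integer(b); eng$max_cells <- max_cells
  eng$sats <- list()   # per length: list(a_lo, u_lo, S)
  class(eng) <- "PropensityEngine"
  eng
}

#' @export
print.PropensityEngine <- function(x, ...) {
  cat("PropensityEngine on <", x$genome$id, ">, W = ", x$W, ", b = ", x$b,
      ", grid {", paste(x$grid, collapse = ", "), "}, ",
      length(x$sats), " cached length grid(s)\n", sep = "")
  invisible(x)
}

# ensure the cached SAT for length l covers a-range/u-range needed for pairs
.engine_ensure <- function(eng, l, p5, p3, margin = 0L) {
  key <- as.character(l)
  a_lo <- min(p5) - eng$W - l + 1L - margin; a_hi <- max(p5) + eng$W + margin
  u_lo <- min(p3) - eng$W - l + 1L - margin; u_hi <- max(p3) + eng$W + margin
  cur <- eng$sats[[key]]
  if (!is.null(cur) && cur$a_lo <= a_lo && cur$u_lo <= u_lo &&
      cur$a_hi >= a_hi && cur$u_hi >= u_hi) return(cur)
  if (!is.null(cur)) { # grow to the union
    a_lo <- min(a_lo, cur$a_lo); a_hi <- max(a_hi, cur$a_hi)
    u_lo <- min(u_lo, cur$u_lo); u_hi <- max(u_hi, cur$u_hi)
  }
  cells <- as.numeric(a_hi - a_lo + 1L) * as.numeric(u_hi - u_lo + 1L)
  if (cells > eng$max_cells) return(NULL)   # caller falls back per-breakpoint
  Z <- .zgrid(eng$genome, a_lo, a_hi, u_lo, u_hi, l, eng$params)
  cur <- list(a_lo = a_lo, a_hi = a_hi, u_lo = u_lo, u_hi = u_hi, S = .sat(Z))
  eng$sats[[key]] <- cur
  cur
}

# propensity values at position pairs (x, y) for one length, via the engine
.engine_pair_propensity <- function(eng, l, x, y) {
  g <- .engine_ensure(eng, l, x, y)
  if (is.null(g)) {
    return(vapply(seq_along(x), function(k)
      sum(.zgrid(eng$genome, x[k] - l + 1L, x[k], y[k] - l + 1L, y[k],
                 l, eng$params)), numeric(1)))
  }
  r <- x - g$a_lo + 1L; cc <- y - g$u_lo + 1L
  v <- vapply(seq_along(x), function(k)
    .boxsum(g$S, r[k] - l + 1L, r[k], cc[k] - l + 1L, cc[k])[1L], numeric(1))
  pmax(v, 0)   # guard against summed-area cancellation
}

#' Relative breakpoint-bin propensities for a set of breakpoint pairs
#'
#' Computes, through a shared-grid engine, the per-length relative
#' breakpoint-bin propensity of every (p5, p3) pair and (optionally) the full
#' relative-bin matrices needed for within-window resampling.
#'
#' @param eng A \code{PropensityEngine}.
#' @param pairs Data frame with columns \code{p5}, \code{p3}.
#' @param want_bins If \code{TRUE}, also return per-length \code{n x nbins^2}
#'   relative-bin matrices (column-major flattening of the bin grid).
#' @param margin Extra genome margin (nt) to cover when building the shared
#'   duplex grids, e.g. \code{W} when bootstrap resamples will shift pairs.
#' @param lengths Optional subset of the engine's grid to evaluate (default:
#'   the whole grid).
#' @return List with \code{P} (n x K matrix of relative breakpoint-bin
#'   propensities), \code{bins}, \code{uniform_fallback},
#'   \code{breakpoint_bin_flat} and \code{nbins}.
#' @export
engine_profiles <- function(eng, pairs, want_bins = FALSE, margin = 0L,
                            lengths = NULL) {
  stopifnot(inherits(eng, "PropensityEngine"))
  if (is.null(lengths)) lengths <- eng$grid
  stopifnot(all(lengths %in% eng$grid))
  W <- eng$W; b <- eng$b; nb <- (2L * W) %/% b
  key <- paste(pairs$p5, pairs$p3)
  upairs <- pairs[!duplicated(key), , drop = FALSE]
  ukey <- paste(upairs$p5, upairs$p3)
  row_of <- match(key, ukey)
  nu <- nrow(upairs)
  K <- length(lengths)
  P <- matrix(NA_real_, nu, K, dimnames = list(NULL, lengths))
  bins <- if (want_bins) vector("list", K) else NULL
  fallback <- rep(FALSE, nu)
  bb <- W %/% b + 1L
  bbflat <- (bb - 1L) * nb + bb
  for (ki in seq_len(K)) {
    l <- lengths[ki]
    if (l == 0L) {
      P[, ki] <- 1 / (nb * nb)
      if (want_bins) bins[[ki]] <- matrix(1 / (nb * nb), nu, nb * nb)
      next
    }
    g <- .engine_ensure(eng, l, upairs$p5, upairs$p3, margin = margin)
    relmat <- if (want_bins) matrix(NA_real_, nu, nb * nb) else NULL
    for (k in seq_len(nu)) {
      if (is.null(g)) {
        win <- extract_window(eng$genome, upairs$p5[k], upairs$p3[k], W)
        bm <- suppressWarnings(bin_map(propensity_map(win, l, eng$params), b))
        rel <- bm$relative_bins
        if (sum(bm$bins) <= 0) fallback[k] <- TRUE
      } else {
        r0 <- upairs$p5[k] - g$a_lo + 1L   # grid row of L position offset 0... start
        c0 <- upairs$p3[k] - g$u_lo + 1L
        # propensity over window offsets -W..W-1 (the +W offset is outside
        # the binned tiling): rows (rel. position) i -> box over Z rows
        io <- seq.int(r0 - l + 1L - W, by = 1L, length.out = 2L * W)
        jo <- seq.int(c0 - l + 1L - W, by = 1L, length.out = 2L * W)
        Pw <- .boxsum(g$S, io, io + l - 1L, jo, jo + l - 1L)
        Pw[Pw < 0] <- 0                    # guard against SAT cancellation
        bsum <- .bin_sums(Pw, nb, b)
        tot <- sum(bsum)
        if (tot <= 0) {
          fallback[k] <- TRUE
          rel <- matrix(1 / (nb * nb), nb, nb)
        } else rel <- bsum / tot
      }
      P[k, ki] <- rel[bb, bb]
      if (want_bins) relmat[k, ] <- as.numeric(rel)
    }
    if (want_bins) bins[[ki]] <- relmat
  }
  if (any(fallback))
    warning(sum(fallback), " breakpoint window(s) had zero total propensity; ",
            "uniform fallback used")
  if (want_bins) {
    bins <- lapply(bins, function(M) M[row_of, , drop = FALSE])
    names(bins) <- lengths
  }
  list(P = P[row_of, , drop = FALSE], bins = bins,
       uniform_fallback = fallback[row_of],
       breakpoint_bin_flat = bbflat, nbins = nb)
}
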