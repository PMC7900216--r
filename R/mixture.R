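#' Component matrix of a breakpoint dataset
#'
#' Row i holds the relative breakpoint-bin propensities of deletion i across
#' the length grid; the l = 0 column is the uniform value \code{1/nbins^2}.
#' Rows whose windows carry no thermodynamic signal use the uniform fallback
#' and are flagged.
#'
#' @param dataset A \code{BreakpointDataset}.
#' @param grid Length grid.
#' @param params An \code{NNParameterSet}.
#' @param W Window half-width.
#' @param b Bin size.
#' @param engine Optional pre-built \code{PropensityEngine} (reused across
#'   fits and bootstrap replicates).
#' @param want_bins Keep the full relative-bin matrices (needed for
#'   \code{bootstrap_sd}).
#' @param margin Extra grid margin in nt (use \code{W} if bootstrap
#'   resampling will follow).
#' @return A \code{ComponentMatrix}: list with \code{P} (n x K), \code{grid},
#'   \code{pairs}, \code{uniform_fallback} and (optionally) \code{bins}.
#' @export
component_matrix <- function(dataset, grid = default_length_grid(),
                             params = load_nn_parameters(), W = 100L, b = 10L,
                             engine = NULL, want_bins = FALSE, margin = 0L) {
  stopifnot(inherits(dataset, "BreakpointDataset"))
  if (is.null(engine))
    engine <- propensity_engine(dataset$genome, params, grid, W = W, b = b)
  pr <- engine_profiles(engine, dataset$breakpoints, want_bins = want_bins,
                        margin = margin)
  structure(list(P = pr$P, grid = engine$grid,
                 pairs = dataset$breakpoints[, c("p5", "p3")],
                 uniform_fallback = pr$uniform_fallback,
                 bins = pr$bins, nbins = pr$nbins,
                 breakpoint_bin_flat = pr$breakpoint_bin_flat,
                 engine = engine, name = dataset$name),
            class = "ComponentMatrix")
}

#' @export
print.ComponentMatrix <- function(x, ...) {
  cat("ComponentMatrix '", x$name, "': ", nrow(x$P), " deletions x ",
      ncol(x$P), " lengths {", paste(x$grid, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

.loglik <- function(theta, P) sum(log(as.numeric(P %*% theta)))

#' Maximum-likelihood mixture weights over misalignment lengths
#'
#' Maximizes \code{sum_i log(sum_l theta_l P[i, l])} over the probability
#' simplex by expectation-maximization with closed-form updates
#' (responsibilities \code{r_il = theta_l P_il / sum_l' theta_l' P_il'};
#' \code{theta_l <- mean_i r_il}).  The objective is concave in theta, the
#' log-likelihood is non-decreasing across iterations, and the uniform start
#' makes ties reproducible.  Optional random restarts (Dirichlet(1) starts)
#' guard against flat ridges; all starts must agree within tolerance.
#'
#' @param P A \code{ComponentMatrix} or a plain n x K matrix of positive
#'   finite component likelihoods.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param n_starts Number of starts (1 = uniform start only; extra starts are
#'   random Dirichlet draws).
#' @param seed Optional seed for the random starts.
#' @return A \code{MixtureFit}: \code{theta} (named by grid length),
#'   \code{loglik}, \code{loglik_trace}, \code{n_iter}, \code{converged},
#'   \code{grouped} (short/medium/long sums), \code{identifiable}.
#' @export
fit_mixture <- function(P, tol = 1e-9, max_iter = 10000L, n_starts = 1L,
                        seed = NULL) {
  grid <- NULL
  if (inherits(P, "ComponentMatrix")) { grid <- P$grid; P <- P$P }
  P <- as.matrix(P)
  if (!all(is.finite(P)) || any(P < 0))
    stop("component matrix must be finite and non-negative", call. = FALSE)
  if (any(rowSums(P) <= 0))
    stop("component matrix has all-zero rows", call. = FALSE)
  n <- nrow(P); K <- ncol(P)
  if (is.null(grid)) {
    grid <- suppressWarnings(as.numeric(colnames(P)))
    if (length(grid) != K || anyNA(grid)) grid <- seq_len(K) - 1
  }
  em <- function(theta) {
    trace <- numeric(0)
    ll <- .loglik(theta, P)
    it <- 0L; conv <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      denom <- as.numeric(P %*% theta)
      r <- sweep(P, 2L, theta, `*`) / denom
      theta <- colMeans(r)
      theta[theta < 0] <- 0
      theta <- theta / sum(theta)
      ll_new <- .loglik(theta, P)
      trace[it] <- ll_new
      if (is.finite(ll) && abs(ll_new - ll) <= tol * (abs(ll) + 1e-12)) {
        conv <- TRUE; ll <- ll_new; break
      }
      ll <- ll_new
    }
    list(theta = theta, loglik = ll, n_iter = it, converged = conv, trace = trace)
  }
  starts <- list(rep(1 / K, K))
  if (n_starts > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (s in seq_len(n_starts - 1L)) {
      g <- -log(runif(K)); starts[[s + 1L]] <- g / sum(g)
    }
  }
  fits <- lapply(starts, em)
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  if (n_starts > 1L && diff(range(lls)) > 1e-6 * (abs(max(lls)) + 1))
    warning("multi-start optima disagree by ", format(diff(range(lls))),
            " in log-likelihood")
  best <- fits[[1L]]   # uniform start is the documented tie-break
  theta <- stats::setNames(best$theta, grid)
  # near-singularity of the observed information on the simplex tangent space
  if (K > 1L) {
    denom <- as.numeric(P %*% theta)
    G <- crossprod(P / denom) / n
    Tb <- diff(diag(K))             # (K-1) x K tangent basis
    H <- Tb %*% G %*% t(Tb)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    identifiable <- (min(ev) > 1e-8 * max(ev))
  } else identifiable <- TRUE
  structure(list(theta = theta, loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = best$n_iter,
                 converged = best$converged, grid = grid,
                 grouped = group_weights(theta, grid),
                 identifiable = identifiable, n = n),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat("MixtureFit: n =", x$n, ", loglik =", format(x$loglik),
      if (!x$converged) "(not converged)" else "", "\n")
  print(round(x$theta, 4))
  cat("grouped: short", round(x$grouped["short"], 3),
      "medium", round(x$grouped["medium"], 3),
      "long", round(x$grouped["long"], 3), "\n")
  invisible(x)
}

#' Group mixture weights into short / medium / long misalignment classes
#'
#' short = lengths 0-5 nt, medium = 10-25 nt, long = >= 50 nt.
#'
#' @param theta Simplex weights (named by length, or supply \code{grid}).
#' @param grid Numeric lengths matching \code{theta}.
#' @return Named numeric vector \code{c(short, medium, long)}; sums to 1 when
#'   the grid partitions into the three classes.
#' @export
group_weights <- function(theta, grid = as.numeric(names(theta))) {
  if (anyNA(grid) || length(grid) != length(theta))
    stop("grid lengths matching theta are required", call. = FALSE)
  c(short = sum(theta[grid <= 5]),
    medium = sum(theta[grid >= 10 & grid <= 25]),
    long = sum(theta[grid >= 50]))
}

#' Parametric bootstrap standard deviations of grouped mixture weights
#'
#' Generates \code{B} in-silico datasets of the original size from the fitted
#' mixture: for each original deletion a length l is drawn from theta-hat,
#' then a bin within that deletion's own window with probability equal to the
#' relative bin propensity at l (uniform for l = 0), and the breakpoint is
#' placed at the bin's first offset (so the resampled pair's own breakpoint
#' bin is exactly the drawn patch).  Each replicate is refit and the sample
#' standard deviation of the grouped weights is returned.  Shared duplex
#' grids are reused across replicates.
#'
#' @param fit A \code{MixtureFit}.
#' @param cm The \code{ComponentMatrix} the fit was computed from, built with
#'   \code{want_bins = TRUE} and \code{margin = W}.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Seed for reproducibility.
#' @return List with \code{sd_grouped}, \code{sd_theta}, \code{replicates}
#'   (B x 3 grouped weights) and \code{B}.
#' @export
bootstrap_sd <- function(fit, cm, B = 100L, seed = NULL) {
  stopifnot(inherits(fit, "MixtureFit"), inherits(cm, "ComponentMatrix"),
            B >= 2L)
  if (is.null(cm$bins))
    stop("component matrix must be built with want_bins = TRUE", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eng <- cm$engine
  W <- eng$W; b <- eng$b; nb <- cm$nbins
  n <- nrow(cm$P); K <- length(cm$grid)
  starts <- -W + (seq_len(nb) - 1L) * b   # first offset of each bin
  reps_group <- matrix(NA_real_, B, 3L,
                       dimnames = list(NULL, c("short", "medium", "long")))
  reps_theta <- matrix(NA_real_, B, K)
  for (bi in seq_len(B)) {
    li <- sample.int(K, n, replace = TRUE, prob = fit$theta)
    off5 <- integer(n); off3 <- integer(n)
    for (ki in unique(li)) {
      rows <- which(li == ki)
      Bm <- cm$bins[[ki]]
      for (r in rows) {
        flat <- sample.int(nb * nb, 1L, prob = Bm[r, ])
        off5[r] <- starts[(flat - 1L) %% nb + 1L]
        off3[r] <- starts[(flat - 1L) %/% nb + 1L]
      }
    }
    L <- eng$genome$length
    sim <- data.frame(p5 = .wrap_pos(cm$pairs$p5 + off5, L),
                      p3 = .wrap_pos(cm$pairs$p3 + off3, L))
    pr <- engine_profiles(eng, sim, want_bins = FALSE)
    f <- fit_mixture(structure(list(P = pr$P, grid = cm$grid),
                               class = "ComponentMatrix"))
    reps_theta[bi, ] <- f$theta
    reps_group[bi, ] <- f$grouped
  }
  list(sd_grouped = apply(reps_group, 2L, stats::sd),
       sd_theta = stats::setNames(apply(reps_theta, 2L, stats::sd), cm$grid),
       replicates = reps_group, B = B)
}
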