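#' Load a packaged nearest-neighbor thermodynamic parameter set
#'
#' The default set \code{"unified_37C"} combines the unified Watson-Crick
#' DNA/DNA free energies at 37 C and 1 M NaCl with published internal
#' single-mismatch nearest-neighbor parameters, a duplex initiation penalty,
#' a terminal A.T penalty per A.T-closing end, and a Jacobson-Stockmayer
#' internal-loop/bulge penalty \code{loop_a + loop_b * log(size)} capped at
#' \code{maxloop} unpaired nucleotides.  No salt correction is applied.
#'
#' @param name Parameter-set label; see \code{nn_parameter_sets()}.
#' @return An object of class \code{NNParameterSet}.
#' @export
load_nn_parameters <- function(name = "unified_37C") {
  sets <- nn_parameter_sets()
  if (!name %in% sets)
    stop("unknown parameter set '", name, "'; available: ",
         paste(sets, collapse = ", "), call. = FALSE)
  path <- system.file("extdata", "nn_unified_dna37.tsv", package = "mtMisalign",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  stack_dG <- rep(NA_real_, 256)
  code <- function(ch) match(ch, c("A", "C", "G", "T")) - 1L
  for (r in seq_len(nrow(tab))) {
    ctx <- tab$context[r]
    x <- code(substr(ctx, 1, 1)); y <- code(substr(ctx, 2, 2))
    w <- code(substr(ctx, 4, 4)); z <- code(substr(ctx, 5, 5))
    stack_dG[((x * 4 + y) * 4 + w) * 4 + z + 1] <- tab$dG37[r]
  }
  structure(list(
    name = name,
    stack_table = tab,
    stack_dG = stack_dG,          # 256-entry dG37 lookup, NA = inadmissible
    init_dG = 1.93684,            # two G.C-closing ends
    terminal_AT_dG = 0.05997,     # extra per A.T-closing end
    loop_a = 2.4, loop_b = 1.3,   # kcal/mol; dG_loop(s) = a + b log s
    maxloop = 30L,
    temperature = 310.15,         # K
    R = 0.0019872                 # kcal/mol/K
  ), class = "NNParameterSet")
}

#' Available nearest-neighbor parameter sets
#' @return Character vector of labels accepted by \code{load_nn_parameters}.
#' @export
nn_parameter_sets <- function() "unified_37C"

#' @export
print.NNParameterSet <- function(x, ...) {
  cat("NNParameterSet '", x$name, "': ",
      sum(x$stack_table$kind == "wc"), " WC stacks, ",
      sum(x$stack_table$kind == "mm"), " internal-mismatch contexts, T = ",
      x$temperature, " K\n", sep = "")
  invisible(x)
}

#' Loop/bulge free-energy penalty
#' @param params An \code{NNParameterSet}.
#' @param size Total number of unpaired nucleotides in the loop (>= 1).
#' @return Penalty in kcal/mol (non-decreasing in \code{size}).
#' @export
loop_penalty <- function(params, size) {
  stopifnot(all(size >= 1))
  params$loop_a + params$loop_b * log(size)
}

# parameter list handed to the C++ kernels
.par_for_cpp <- function(params) {
  list(stack_dG = params$stack_dG, init_dG = params$init_dG,
       terminal_AT_dG = params$terminal_AT_dG,
       loop_a = params$loop_a, loop_b = params$loop_b,
       maxloop = as.integer(params$maxloop),
       temperature = params$temperature, R = params$R)
}

#' Partition function of hybridization between two short DNA strands
#'
#' Sums \code{exp(-dG/RT)} over all admissible antiparallel intermolecular
#' duplex configurations of \code{seqA} (an L-strand fragment, 5' to 3') and
#' \code{seqB} (an H-strand fragment, 5' to 3').  A configuration is a
#' non-crossing set of base pairs organized into helices of stacked pairs
#' (Watson-Crick stacks or tabulated isolated internal mismatches, at least
#' one stack per helix), separated by internal loops/bulges; its free energy
#' is initiation + stack terms + loop penalties + terminal A.T penalties.
#' The unhybridized state is excluded, so Z = 0 when no configuration exists.
#' Positions pairing with N are unpairable.
#'
#' @param seqA,seqB DNA strings over A, C, G, T, N; 1-200 nt each.
#' @param params An \code{NNParameterSet}.
#' @return A \code{PartitionFunctionValue}: list with \code{Z} (dimensionless
#'   Boltzmann sum) and \code{mfe_dG} (minimum configuration free energy in
#'   kcal/mol, \code{Inf} when no configuration exists).
#' @export
duplex_partition_function <- function(seqA, seqB, params = load_nn_parameters()) {
  stopifnot(inherits(params, "NNParameterSet"))
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence", call. = FALSE)
  if (nchar(seqA) > 200 || nchar(seqB) > 200)
    stop("duplex_partition_function is limited to strands of <= 200 nt", call. = FALSE)
  A <- .encode_seq(seqA)
  Bb <- rev(.encode_seq(seqB))  # bottom strand, 3'->5' left to right
  res <- .pf_single_cpp(A, Bb, .par_for_cpp(params))
  structure(list(Z = res$Z, mfe_dG = res$mfe_dG), class = "PartitionFunctionValue")
}

#' @export
print.PartitionFunctionValue <- function(x, ...) {
  cat("Z =", format(x$Z), " (MFE", format(x$mfe_dG), "kcal/mol)\n")
  invisible(x)
}

#' Exhaustively enumerate admissible duplex configurations (validation oracle)
#'
#' Lists every admissible configuration of the duplex grammar together with
#' its free energy, by depth-first search over chains of base pairs.  The sum
#' of \code{exp(-dG/RT)} over the returned configurations equals
#' \code{duplex_partition_function} up to floating-point error; the oracle is
#' deliberately independent of the dynamic-programming implementation.
#'
#' @param seqA,seqB DNA strings; \code{nchar(seqA) * nchar(seqB)} must be
#'   at most 64.
#' @param params An \code{NNParameterSet}.
#' @return List of configurations, each a list with \code{pairs} (two-column
#'   matrix of 1-based indices into \code{seqA} and into the reversed
#'   \code{seqB}) and \code{dG}.
#' @export
enumerate_configurations <- function(seqA, seqB, params = load_nn_parameters()) {
  A <- .encode_seq(seqA)
  Bb <- rev(.encode_seq(seqB))
  n <- length(A); m <- length(Bb)
  if (n * m > 64) stop("enumeration oracle limited to |seqA| * |seqB| <= 64", call. = FALSE)
  sdg <- params$stack_dG
  wc <- function(x, w) (x == 0L && w == 3L) || (x == 3L && w == 0L) ||
    (x == 1L && w == 2L) || (x == 2L && w == 1L)
  at <- function(x, w) (x == 0L && w == 3L) || (x == 3L && w == 0L)
  stack_dg <- function(i, k) {
    if (A[i] > 3L || A[i + 1] > 3L || Bb[k] > 3L || Bb[k + 1] > 3L) return(NA_real_)
    sdg[((A[i] * 4L + A[i + 1]) * 4L + Bb[k]) * 4L + Bb[k + 1] + 1L]
  }
  term <- function(i, k) if (at(A[i], Bb[k])) params$terminal_AT_dG else 0
  res <- list()
  dfs <- function(pairs, i, k, helixlen, dG) {
    curWC <- wc(A[i], Bb[k])
    if (curWC && helixlen >= 2L)
      res[[length(res) + 1L]] <<- list(pairs = pairs, dG = dG + term(i, k))
    if (i < n && k < m) {                      # stack extension
      sg <- stack_dg(i, k)
      nxtWC <- wc(A[i + 1], Bb[k + 1])
      nxt_ok <- nxtWC || (A[i + 1] < 4L && Bb[k + 1] < 4L)
      if (!is.na(sg) && nxt_ok)
        dfs(rbind(pairs, c(i + 1L, k + 1L)), i + 1L, k + 1L, helixlen + 1L, dG + sg)
    }
    if (curWC && helixlen >= 2L) {             # close a loop, start a new helix
      d1max <- min(params$maxloop, n - i - 2L)
      if (d1max >= 0L) for (d1 in 0:d1max) {
        d2max <- min(params$maxloop - d1, m - k - 2L)
        if (d2max < 0) next
        for (d2 in 0:d2max) {
          s <- d1 + d2
          if (s < 1L) next
          ii <- i + d1 + 1L; kk <- k + d2 + 1L
          if (wc(A[ii], Bb[kk]))
            dfs(rbind(pairs, c(ii, kk)), ii, kk, 1L, dG + loop_penalty(params, s))
        }
      }
    }
  }
  for (i in seq_len(n)) for (k in seq_len(m)) {
    if (wc(A[i], Bb[k]))
      dfs(matrix(c(i, k), 1L), i, k, 1L, params$init_dG + term(i, k))
  }
  res
}

#' Partition function from an enumeration (helper for oracle comparisons)
#' @param configs Result of \code{enumerate_configurations}.
#' @param params The matching \code{NNParameterSet}.
#' @return Sum of Boltzmann weights (0 for an empty list).
#' @export
enumeration_Z <- function(configs, params = load_nn_parameters()) {
  if (!length(configs)) return(0)
  RT <- params$R * params$temperature
  sum(exp(-vapply(configs, `[[`, numeric(1), "dG") / RT))
}
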