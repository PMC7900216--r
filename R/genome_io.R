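#' Construct a circular mitochondrial genome object
#'
#' @param seq Single character string over the alphabet A, C, G, T, N,
#'   giving the reference (L-strand) sequence read 5' to 3'.
#' @param id Free-text identifier.
#' @return An object of class \code{MtGenome} with fields \code{id},
#'   \code{seq}, \code{length} and \code{circular} (always \code{TRUE}).
#' @export
mt_genome <- function(seq, id = "genome") {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  .check_alphabet(seq, "genome sequence")
  structure(list(id = id, seq = seq, length = nchar(seq), circular = TRUE),
            class = "MtGenome")
}

#' @export
print.MtGenome <- function(x, ...) {
  cat("MtGenome <", x$id, ">: ", x$length, " nt, circular\n", sep = "")
  invisible(x)
}

#' Read a circular reference genome from a FASTA file
#'
#' The reference sequence is taken to be the L-strand read 5' to 3'; the
#' H-strand is its reverse complement.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param record_id Optional record identifier; by default the first record
#'   is used.  Matching is on the first whitespace-delimited token of the
#'   header.
#' @return An \code{MtGenome}.
#' @export
read_genome <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
  if (is.null(record_id)) {
    k <- 1L
  } else {
    k <- match(record_id, ids)
    if (is.na(k)) stop("record '", record_id, "' not found in ", path,
                       "; available: ", paste(ids, collapse = ", "), call. = FALSE)
  }
  s <- toupper(as.character(recs[[k]]))
  if (!nzchar(s)) stop("record '", ids[k], "' is empty", call. = FALSE)
  .check_alphabet(s, paste0("record '", ids[k], "'"))
  mt_genome(s, id = ids[k])
}

#' Reverse complement of a DNA string
#'
#' N is its own complement.  Used to realize the H-strand from the deposited
#' L-strand reference.
#'
#' @param seq Character string over A, C, G, T, N.
#' @return The reverse complement, same alphabet.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .check_alphabet(seq)
  comp <- .complement_chr(toupper(seq))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Inclusive slice of a circular genome
#'
#' Positions are 1-based on the reference; when \code{start > end} the slice
#' wraps through the origin, so the result length is
#' \code{(end - start) \%\% length + 1}.
#'
#' @param genome An \code{MtGenome}.
#' @param start,end 1-based positions in \code{[1, genome$length]}.
#' @return A character string.
#' @export
circular_slice <- function(genome, start, end) {
  stopifnot(inherits(genome, "MtGenome"))
  L <- genome$length
  if (start < 1 || start > L || end < 1 || end > L)
    stop("slice positions must lie in [1, ", L, "]", call. = FALSE)
  if (start <= end) {
    substr(genome$seq, start, end)
  } else {
    paste0(substr(genome$seq, start, L), substr(genome$seq, 1, end))
  }
}

# slice allowing out-of-range endpoints (internal: windows wrap freely)
.circular_slice_any <- function(genome, start, end) {
  L <- genome$length
  n <- end - start + 1L
  stopifnot(n >= 1L, n <= L)
  circular_slice(genome, .wrap_pos(start, L),
                 .wrap_pos(start + n - 1L, L))
}

#' Construct a breakpoint dataset
#'
#' @param p5,p3 Integer vectors of 1-based 5' and 3' breakpoint positions on
#'   the reference.
#' @param genome The \code{MtGenome} the positions refer to.
#' @param name Dataset label.
#' @param species Species label (recycled).
#' @param true_l Optional integer vector of true misalignment lengths (used
#'   by the simulator's evaluation side-channel).
#' @return A \code{BreakpointDataset}: list with \code{name}, \code{genome}
#'   and a data frame \code{breakpoints}.
#' @export
breakpoint_dataset <- function(p5, p3, genome, name = "dataset",
                               species = NA_character_, true_l = NULL) {
  stopifnot(inherits(genome, "MtGenome"), length(p5) == length(p3))
  if (length(p5) == 0L) stop("breakpoint dataset '", name, "' is empty", call. = FALSE)
  p5 <- as.integer(p5); p3 <- as.integer(p3)
  L <- genome$length
  if (any(p5 < 1L | p5 > L | p3 < 1L | p3 > L))
    stop("breakpoint positions outside [1, ", L, "]", call. = FALSE)
  if (any(p5 == p3)) stop("breakpoints with p5 == p3 are not allowed", call. = FALSE)
  bp <- data.frame(p5 = p5, p3 = p3,
                   dataset = name,
                   species = rep_len(species, length(p5)),
                   stringsAsFactors = FALSE)
  if (!is.null(true_l)) bp$true_l <- as.integer(rep_len(true_l, length(p5)))
  structure(list(name = name, genome = genome, breakpoints = bp),
            class = "BreakpointDataset")
}

#' @export
print.BreakpointDataset <- function(x, ...) {
  cat("BreakpointDataset '", x$name, "': ", nrow(x$breakpoints),
      " deletions on <", x$genome$id, ">\n", sep = "")
  invisible(x)
}

#' Load breakpoint catalogs from a delimited table
#'
#' Reads a TSV or CSV table (delimiter auto-detected from the header line)
#' with one row per deletion, validates positions against the genome, and
#' groups rows by dataset label.  Malformed or out-of-range rows are rejected
#' with a message naming the row numbers; per-dataset counts are logged to
#' stderr.
#'
#' @param path Path to the table.
#' @param genome \code{MtGenome} the positions refer to.
#' @param col_dataset,col_species,col_p5,col_p3 Header names of the four
#'   required columns.
#' @return A named list of \code{BreakpointDataset}, one per dataset label,
#'   with attributes \code{n_accepted} and \code{n_rejected}.
#' @export
load_breakpoints <- function(path, genome,
                             col_dataset = "dataset", col_species = "species",
                             col_p5 = "p5", col_p3 = "p3") {
  stopifnot(inherits(genome, "MtGenome"))
  if (!file.exists(path)) stop("breakpoint table not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  need <- c(col_dataset, col_species, col_p5, col_p3)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("breakpoint table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  p5 <- suppressWarnings(as.integer(tab[[col_p5]]))
  p3 <- suppressWarnings(as.integer(tab[[col_p3]]))
  L <- genome$length
  ok <- !is.na(p5) & !is.na(p3) & p5 >= 1L & p5 <= L & p3 >= 1L & p3 <= L &
    p5 != p3 & !is.na(tab[[col_dataset]]) & nzchar(tab[[col_dataset]])
  if (any(!ok))
    message("load_breakpoints: rejected ", sum(!ok), " malformed/out-of-range row(s): ",
            paste(utils::head(which(!ok), 20L), collapse = ", "))
  if (!any(ok)) stop("no valid breakpoint rows in ", path, call. = FALSE)
  acc <- data.frame(dataset = as.character(tab[[col_dataset]])[ok],
                    species = as.character(tab[[col_species]])[ok],
                    p5 = p5[ok], p3 = p3[ok], stringsAsFactors = FALSE)
  out <- lapply(split(acc, acc$dataset), function(d)
    breakpoint_dataset(d$p5, d$p3, genome, name = d$dataset[1], species = d$species))
  for (nm in names(out))
    message("load_breakpoints: dataset '", nm, "': ",
            nrow(out[[nm]]$breakpoints), " records")
  message("load_breakpoints: total ", nrow(acc), " records in ",
          length(out), " dataset(s)")
  attr(out, "n_accepted") <- nrow(acc)
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Length of the longest perfect direct repeat flanking a breakpoint
#'
#' Compares the reference sequence read 5' to 3' starting at \code{p5} with
#' the one starting at \code{p3} (convention \code{"start"}), the sequences
#' ending at \code{p5 - 1} and \code{p3 - 1} (\code{"end"}), or both
#' (\code{"both"}, the default, reporting the maximum).
#'
#' @param genome An \code{MtGenome}.
#' @param p5,p3 Breakpoint positions (1-based).
#' @param max_len Longest repeat length searched.
#' @param convention Flank convention; see Details.
#' @return Integer repeat length, 0 when the flanks share no identity.
#' @export
flanking_repeat_length <- function(genome, p5, p3, max_len = 25L,
                                   convention = c("both", "start", "end")) {
  stopifnot(inherits(genome, "MtGenome"), max_len >= 1L)
  convention <- match.arg(convention)
  L <- genome$length
  if (p5 < 1 || p5 > L || p3 < 1 || p3 > L)
    stop("breakpoint positions outside [1, ", L, "]", call. = FALSE)
  run_from <- function(a, b) {
    sa <- .encode_seq(.circular_slice_any(genome, a, a + max_len - 1L))
    sb <- .encode_seq(.circular_slice_any(genome, b, b + max_len - 1L))
    same <- sa == sb & sa != 4L & sb != 4L   # N never matches
    if (!same[1]) 0L else {
      w <- which(!same)
      if (length(w)) w[1] - 1L else max_len
    }
  }
  run_to <- function(a, b) {
    sa <- rev(.encode_seq(.circular_slice_any(genome, a - max_len, a - 1L)))
    sb <- rev(.encode_seq(.circular_slice_any(genome, b - max_len, b - 1L)))
    same <- sa == sb & sa != 4L & sb != 4L
    if (!same[1]) 0L else {
      w <- which(!same)
      if (length(w)) w[1] - 1L else max_len
    }
  }
  as.integer(switch(convention,
    start = run_from(p5, p3),
    end   = run_to(p5, p3),
    both  = max(run_from(p5, p3), run_to(p5, p3))))
}
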