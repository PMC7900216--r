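# shared fixtures: parameter set, random sequences, small synthetic genomes

nn_par <- load_nn_parameters()

rand_dna <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

rand_genome <- function(n = 4000L, seed = 1L, gc = 0.44) {
  set.seed(seed)
  mt_genome(rand_dna(n, prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            id = paste0("toy", seed))
}

# genome with a perfect direct repeat of `len` planted at (p5, p3): the
# L-strand l-mer starting at p5 equals the one starting at p3, so the
# corresponding L/H window centers are perfect duplex partners
planted_genome <- function(len, p5, p3, n = 4000L, seed = 1L) {
  spec <- simulation_spec(genome_length = n, gc_content = 0.44,
                          theta_true = c(`0` = 1), n = 1L,
                          region5 = c(p5, p5), region3 = c(p3, p3),
                          grid = c(0L, as.integer(len)), seed = seed,
                          planted_repeats = data.frame(length = len,
                                                       pos5 = p5, pos3 = p3))
  synthetic_genome(spec)
}

# brute-force propensity of one position pair: explicit double loop over the
# l x l overlapping duplexes, each scored with duplex_partition_function
direct_pair_propensity <- function(genome, p5, p3, l, params = nn_par) {
  tot <- 0
  nterms <- 0L
  for (a in (p5 - l + 1):p5) {
    segA <- mtMisalign:::.circular_slice_any(genome, a, a + l - 1L)
    for (u in (p3 - l + 1):p3) {
      segB <- reverse_complement(
        mtMisalign:::.circular_slice_any(genome, u, u + l - 1L))
      tot <- tot + duplex_partition_function(segA, segB, params)$Z
      nterms <- nterms + 1L
    }
  }
  list(value = tot, n_duplexes = nterms)
}
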