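# Small in-code fixtures shared across test files.

# A toy alignment: `haps` is a character vector of equal-length sequences,
# two per individual (ind1_1, ind1_2, ind2_1, ...).
toy_alignment <- function(haps, gene = NULL) {
  n_ind <- length(haps) / 2
  names(haps) <- as.vector(t(outer(paste0("ind", seq_len(n_ind)), 1:2,
                                   paste, sep = "_")))
  hap_alignment(haps, gene)
}

# Replicate a set of haplotype strings with given copy numbers.
rep_haps <- function(seqs, times) rep(seqs, times = times)

# A pileup from explicit reads: list of c(start, bases).
toy_pileup <- function(reads, L, gene_id = "g", sample_id = "s") {
  df <- data.frame(read_id = sprintf("r%02d", seq_along(reads)),
                   start = vapply(reads, function(r) as.integer(r[[1L]]),
                                  integer(1L)),
                   bases = vapply(reads, function(r) as.character(r[[2L]]),
                                  character(1L)))
  read_pileup(gene_id, sample_id, df, L)
}

# Exact two-sided Fisher P for a 2x2 table by hypergeometric enumeration
# (independent oracle for mk_test).
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force per-site mean pairwise difference over all haplotype pairs.
pi_bruteforce <- function(aln, sites) {
  n <- aln$n
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(aln$mat[i, sites] != aln$mat[j, sites])
  tot / choose(n, 2) / length(sites)
}

# A small two-class sample table for structure tests.
toy_samples <- function(n_pop = 6, per_pop = 4) {
  pops <- sprintf("p%02d", seq_len(n_pop))
  data.frame(
    sample_id = as.vector(t(outer(pops, seq_len(per_pop), paste, sep = "_"))),
    population_id = rep(pops, each = per_pop),
    altitude_class = rep(rep(c("H", "L"), n_pop / 2), each = per_pop),
    latitude = rep(46 + seq_len(n_pop) * 0.1, each = per_pop),
    longitude = rep(10 + seq_len(n_pop) * 0.2, each = per_pop),
    elevation = rep(ifelse(rep(c(TRUE, FALSE), n_pop / 2), 2300, 1400),
                    each = per_pop))
}
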