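# Polymorphism detection from amplicon read pileups: binomial false-allele
# model, site calling, minimal-haplotype reconstruction, read-backed phasing
# with seeded phase-gap resolution, and consensus building.

#' Sequencing error model for site calling
#'
#' @param f_M Per-base error probability (study estimate 0.024, from haploid
#'   plastid reads of the same run).
#' @param min_depth Minimum read depth at a callable site (default 5).
#' @param minor_fraction Minimum minor-allele read fraction, exclusive
#'   (default 0.3: the minor allele must be present in more than 30% of
#'   reads).
#' @return Object of class `error_model`.
#' @export
error_model <- function(f_M = 0.024, min_depth = 5L, minor_fraction = 0.3) {
  stopifnot(f_M >= 0, f_M < 0.5, min_depth >= 1,
            minor_fraction > 0, minor_fraction < 0.5)
  structure(list(f_M = f_M, min_depth = as.integer(min_depth),
                 minor_fraction = minor_fraction), class = "error_model")
}

#' Read pileup for one individual x gene assembly
#'
#' @param gene_id,sample_id Identifiers.
#' @param reads Data frame with columns `read_id`, `start` (1-based) and
#'   `bases` (aligned bases over `{A,C,G,T,-}`; a `-` means the read spans a
#'   deletion at that position).
#' @param gene_length Total length of the assembled region.
#' @return Object of class `read_pileup` with a reads-by-positions character
#'   matrix `mat` (`NA` where a read does not cover).
#' @export
read_pileup <- function(gene_id, sample_id, reads, gene_length) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "start", "bases") %in% names(reads)))
  gene_length <- as.integer(gene_length)
  ends <- reads$start + nchar(reads$bases) - 1L
  if (any(reads$start < 1L) || any(ends > gene_length))
    stop("read(s) outside [1, ", gene_length, "]: ",
         paste(reads$read_id[reads$start < 1L | ends > gene_length],
               collapse = ", "))
  mat <- matrix(NA_character_, nrow(reads), gene_length,
                dimnames = list(reads$read_id, NULL))
  for (i in seq_len(nrow(reads))) {
    b <- strsplit(toupper(reads$bases[i]), "")[[1L]]
    mat[i, reads$start[i]:ends[i]] <- b
  }
  structure(list(gene_id = gene_id, sample_id = sample_id,
                 reads = reads, mat = mat, length = gene_length),
            class = "read_pileup")
}

#' Per-position read depth
#'
#' @param pileup A [read_pileup()].
#' @return Integer vector of read counts covering each position.
#' @export
pileup_depth <- function(pileup) colSums(!is.na(pileup$mat))

#' Probability of a false polymorphism call
#'
#' The binomial point mass `C(n,k) * f_M^k * (1-f_M)^(n-k)`: the probability
#' that exactly `k` of `n` reads carry the same erroneous base at a site.
#'
#' @param n Read depth.
#' @param k Minor-allele read count.
#' @param f_M Per-base error rate.
#' @return Probability.
#' @export
p_false <- function(n, k, f_M) {
  if (any(k > n) || any(k < 0) || any(n < 0)) stop("need 0 <= k <= n")
  stopifnot(all(f_M >= 0), all(f_M <= 1))
  choose(n, k) * f_M^k * (1 - f_M)^(n - k)
}

#' False-call probability profile over read depths
#'
#' For each depth `n` in `1..n_max`, sets `k` to the smallest integer
#' strictly greater than `minor_fraction * n` (the minimal minor-allele
#' count that would pass the frequency filter) and evaluates [p_false()].
#'
#' @param f_M Per-base error rate.
#' @param minor_fraction Minor-allele fraction threshold.
#' @param n_max Largest depth to tabulate.
#' @return Data frame with columns `n`, `k`, `p_false`.
#' @export
p_false_profile <- function(f_M = 0.024, minor_fraction = 0.3, n_max = 20L) {
  stopifnot(n_max >= 1)
  n <- seq_len(n_max)
  k <- floor(minor_fraction * n) + 1L
  data.frame(n = n, k = k, p_false = p_false(n, k, f_M))
}

#' Call polymorphic sites in a pileup
#'
#' A site is called when it is covered by at least `min_depth` reads and the
#' minor allele is present in strictly more than `minor_fraction` of them.
#' Insertion/deletion alleles (`-` vs a base) are eligible.  Sites where
#' more than two alleles pass the frequency filter are rejected with an
#' error (only biallelic handling is defined).
#'
#' @param pileup A [read_pileup()].
#' @param model An [error_model()].
#' @return Data frame with columns `position`, `major`, `minor`, `depth`,
#'   `minor_count`, `is_indel` (zero rows when nothing is called).
#' @export
call_sites <- function(pileup, model = error_model()) {
  levels <- c("A", "C", "G", "T", "-")
  out <- NULL
  for (pos in seq_len(pileup$length)) {
    col <- pileup$mat[, pos]
    col <- col[!is.na(col)]
    depth <- length(col)
    if (depth < model$min_depth) next
    cnt <- sort(tabulate(match(col, levels), nbins = 5L),
                decreasing = TRUE, index.return = TRUE)
    counts <- cnt$x
    if (counts[2L] / depth <= model$minor_fraction) next
    if (counts[3L] / depth > model$minor_fraction)
      stop("more than two alleles pass filters at position ", pos)
    al <- levels[cnt$ix[1:2]]
    # deterministic major/minor on count ties: alphabetical, gap last
    if (counts[1L] == counts[2L]) al <- sort(al)
    out <- rbind(out, data.frame(position = pos, major = al[1L],
                                 minor = al[2L], depth = depth,
                                 minor_count = counts[2L],
                                 is_indel = "-" %in% al))
  }
  if (is.null(out))
    out <- data.frame(position = integer(), major = character(),
                      minor = character(), depth = integer(),
                      minor_count = integer(), is_indel = logical())
  out
}

#' Minimal haplotypes per read
#'
#' The ordered alleles each read carries at the called sites it covers;
#' reads covering no called site are omitted.  Only bases matching one of
#' the two called alleles are recorded (others are sequencing errors and are
#' dropped from the haplotype).
#'
#' @param pileup A [read_pileup()].
#' @param sites Output of [call_sites()].
#' @return Named list (by read id) of data frames `position`, `allele`.
#' @export
minimal_haplotypes <- function(pileup, sites) {
  if (nrow(sites) == 0L) return(list())
  out <- list()
  for (i in seq_len(nrow(pileup$mat))) {
    b <- pileup$mat[i, sites$position]
    ok <- !is.na(b) & (b == sites$major | b == sites$minor)
    if (!any(ok)) next
    out[[rownames(pileup$mat)[i]]] <-
      data.frame(position = sites$position[ok], allele = b[ok])
  }
  out
}

#' Phase called heterozygous sites by chaining minimal haplotypes
#'
#' Greedy left-to-right chaining: for each pair of consecutive called sites,
#' reads covering both vote for the parallel or crossed pairing of alleles;
#' the majority wins.  When no read covers both sites (a phase gap) the two
#' partial haplotype blocks are joined by a seeded random pairing and the
#' `phase_gap_resolved` flag is set.  A junction whose votes support both
#' pairings equally is reported as an ambiguity error.
#'
#' @param minimal Output of [minimal_haplotypes()].
#' @param sites Output of [call_sites()].
#' @param seed Integer seed for phase-gap resolution.
#' @return List with `alleles` (2 x n_sites character matrix: the allele each
#'   phase carries at each called site) and `phase_gap_resolved` flag.
#' @export
phase_haplotypes <- function(minimal, sites, seed = 1L) {
  m <- nrow(sites)
  if (m == 0L) return(list(alleles = matrix(character(), 2L, 0L),
                           phase_gap_resolved = FALSE))
  set.seed(seed)
  hap <- matrix(NA_character_, 2L, m)
  hap[, 1L] <- c(sites$major[1L], sites$minor[1L])
  gap <- FALSE
  if (m >= 2L) for (j in 2:m) {
    p_prev <- sites$position[j - 1L]; p_cur <- sites$position[j]
    votes <- matrix(0L, 2L, 2L,
                    dimnames = list(c(sites$major[j - 1L], sites$minor[j - 1L]),
                                    c(sites$major[j], sites$minor[j])))
    for (mh in minimal) {
      a <- mh$allele[match(c(p_prev, p_cur), mh$position)]
      if (anyNA(a)) next
      votes[a[1L], a[2L]] <- votes[a[1L], a[2L]] + 1L
    }
    parallel <- votes[hap[1L, j - 1L], sites$major[j]] +
      votes[hap[2L, j - 1L], sites$minor[j]]
    crossed <- votes[hap[1L, j - 1L], sites$minor[j]] +
      votes[hap[2L, j - 1L], sites$major[j]]
    if (parallel + crossed == 0L) {
      gap <- TRUE
      flip <- stats::runif(1L) < 0.5
      hap[, j] <- if (flip) c(sites$minor[j], sites$major[j]) else
        c(sites$major[j], sites$minor[j])
    } else if (parallel == crossed) {
      stop("ambiguous phasing at junction between positions ",
           p_prev, " and ", p_cur)
    } else {
      hap[, j] <- if (parallel > crossed) c(sites$major[j], sites$minor[j]) else
        c(sites$minor[j], sites$major[j])
    }
  }
  list(alleles = hap, phase_gap_resolved = gap)
}

#' Build the phased consensus pair
#'
#' The backbone is the per-position majority base across reads (ties broken
#' alphabetically with the gap character last, `A < C < G < T < -`); the
#' two output sequences equal the backbone everywhere except at called
#' heterozygous sites, where each carries its phased allele.
#'
#' @param pileup A [read_pileup()].
#' @param sites Output of [call_sites()].
#' @param phased Output of [phase_haplotypes()].
#' @return List of class `phased_pair`: `seq1`, `seq2` (strings),
#'   `phase_gap_resolved`, `sites`.
#' @export
build_consensus <- function(pileup, sites, phased) {
  levels <- c("A", "C", "G", "T", "-")
  depth <- pileup_depth(pileup)
  if (any(depth == 0L))
    stop("position(s) not covered by any read: ",
         paste(utils::head(which(depth == 0L), 5L), collapse = ", "))
  cons <- vapply(seq_len(pileup$length), function(pos) {
    col <- pileup$mat[, pos]
    cnt <- tabulate(match(col[!is.na(col)], levels), nbins = 5L)
    levels[which.max(cnt)]                       # ties: first in A,C,G,T,-
  }, character(1L))
  s1 <- s2 <- cons
  if (nrow(sites) > 0L) {
    s1[sites$position] <- phased$alleles[1L, ]
    s2[sites$position] <- phased$alleles[2L, ]
  }
  structure(list(seq1 = paste(s1, collapse = ""),
                 seq2 = paste(s2, collapse = ""),
                 phase_gap_resolved = phased$phase_gap_resolved,
                 sites = sites),
            class = "phased_pair")
}

#' Call, phase and build the consensus pair for one assembly
#'
#' Convenience wrapper running [call_sites()], [minimal_haplotypes()],
#' [phase_haplotypes()] and [build_consensus()].
#'
#' @param pileup A [read_pileup()].
#' @param model An [error_model()].
#' @param seed Integer seed (used only at phase gaps).
#' @return A `phased_pair`.
#' @export
call_genotype <- function(pileup, model = error_model(), seed = 1L) {
  sites <- call_sites(pileup, model)
  minimal <- minimal_haplotypes(pileup, sites)
  phased <- phase_haplotypes(minimal, sites, seed = seed)
  build_consensus(pileup, sites, phased)
}
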