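#' Effective sites of a given segment kind
#'
#' Counts alignment columns of the requested kind at which no haplotype
#' carries missing data (`N`) or an alignment gap (`-`).  Diversity and
#' divergence statistics are computed on these columns only.
#'
#' @param aln A [hap_alignment()].
#' @param kind `"intron"`, `"exon"` or `"all"`.
#' @param outgroup Optional outgroup sequence (single string or character
#'   vector of bases) aligned to the same coordinates; when supplied, columns
#'   where the outgroup has `N`/`-` are excluded too.
#' @return Integer vector of effective column indices (use `length()` for
#'   `L_eff`).
#' @export
effective_sites <- function(aln, kind = "intron", outgroup = NULL) {
  mask <- segment_mask(aln$gene, kind)
  clean <- colSums(aln$mat == "N" | aln$mat == "-") == 0L
  if (!is.null(outgroup)) {
    og <- outgroup_chars(outgroup, aln$gene$length)
    clean <- clean & og != "N" & og != "-"
  }
  which(mask & clean)
}

outgroup_chars <- function(outgroup, L) {
  og <- if (length(outgroup) == 1L && nchar(outgroup[1L]) > 1L)
    strsplit(toupper(outgroup), "")[[1L]] else toupper(outgroup)
  if (length(og) != L)
    stop("outgroup length ", length(og), " does not match alignment L = ", L)
  og
}

# Per-column allele counts (A/C/G/T) over a set of columns.
.col_counts <- function(mat, cols) {
  vapply(cols, function(j) tabulate(match(mat[, j], c("A", "C", "G", "T")),
                                    nbins = 4L),
         integer(4L))
}

#' Segregating sites
#'
#' A site is segregating if at least two distinct states are present among
#' haplotypes at an effective (fully observed) site; singletons count.
#'
#' @param aln A [hap_alignment()].
#' @param sites Integer vector of effective column indices
#'   (from [effective_sites()]).
#' @return Integer vector of segregating column indices.
#' @export
segregating_sites <- function(aln, sites) {
  if (length(sites) == 0L) return(integer(0))
  cc <- .col_counts(aln$mat, sites)
  sites[colSums(cc > 0L) >= 2L]
}

#' Nucleotide diversity (pi) per site
#'
#' Average number of pairwise differences between haplotypes per effective
#' site.
#'
#' @inheritParams segregating_sites
#' @return Per-site pi (numeric scalar).
#' @export
nucleotide_diversity <- function(aln, sites) {
  n <- aln$n
  if (n < 2L) stop("nucleotide diversity needs n >= 2 haplotypes")
  if (length(sites) == 0L) return(NA_real_)
  cc <- .col_counts(aln$mat, sites)
  npairs <- n * (n - 1) / 2
  diff_pairs <- npairs - colSums(cc * (cc - 1) / 2)
  sum(diff_pairs) / npairs / length(sites)
}

#' Watterson's theta per site
#'
#' `S / (a1 * L_eff)` with `a1` the (n-1)-th harmonic number.
#'
#' @param S Number of segregating sites.
#' @param n Number of haplotypes.
#' @param L_eff Number of effective sites.
#' @return Per-site theta_W.
#' @export
watterson_theta <- function(S, n, L_eff) {
  stopifnot(n >= 2, L_eff >= 1)
  S / (sum(1 / seq_len(n - 1)) * L_eff)
}

# Tajima (1989) normalizing constants, computed exactly from n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Scaled difference between the pairwise-difference and segregating-sites
#' estimators of the population mutation rate.  Undefined (returns `NA`) when
#' `S = 0`.
#'
#' @param n Number of haplotypes (>= 4).
#' @param S Number of segregating sites.
#' @param mean_pairwise Mean number of pairwise differences across the region
#'   (absolute, i.e. per-site pi times `L_eff`).
#' @return Tajima's D, or `NA_real_` when `S = 0`.
#' @export
tajimas_d <- function(n, S, mean_pairwise) {
  stopifnot(n >= 4)
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (mean_pairwise - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Haplotype diversity
#'
#' `(n/(n-1)) * (1 - sum p_i^2)` over distinct haplotype frequencies, using
#' the full sequences (missing data included in the identity comparison).
#'
#' @param aln A [hap_alignment()].
#' @return H in `[0, 1]`.
#' @export
haplotype_diversity <- function(aln) {
  n <- aln$n
  stopifnot(n >= 2)
  key <- apply(aln$mat, 1L, paste, collapse = "")
  p <- as.numeric(table(key)) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Pairwise linkage disequilibrium and the ZZ statistic
#'
#' Computes `r^2` for every pair of biallelic segregating sites, the ZZ
#' statistic `Z_a - Z_nS` (mean adjacent-pair `r^2` minus mean all-pair
#' `r^2`), and a per-pair permutation P value from seeded shuffles of one
#' site's alleles.
#'
#' @inheritParams segregating_sites
#' @param permutations Number of allele shuffles per pair (default 10,000).
#' @param seed Integer seed for the permutation null.
#' @return List with `zz`, `z_a`, `z_ns`, `r2` (matrix with site positions as
#'   dimnames), `p` (matrix of permutation P values), or `NULL` when fewer
#'   than two biallelic segregating sites exist.
#' @export
linkage_stats <- function(aln, sites, permutations = 10000, seed = 1L) {
  seg <- segregating_sites(aln, sites)
  if (length(seg) < 2L) return(NULL)
  cc <- .col_counts(aln$mat, seg)
  seg <- seg[colSums(cc > 0L) == 2L]            # biallelic only
  if (length(seg) < 2L) return(NULL)
  # minor-allele indicator coding
  X <- vapply(seg, function(j) {
    col <- aln$mat[, j]
    tab <- sort(table(col), decreasing = TRUE)
    as.numeric(col == names(tab)[2L])
  }, numeric(aln$n))
  r2 <- suppressWarnings(stats::cor(X))^2
  dimnames(r2) <- list(seg, seg)
  m <- length(seg)
  pairs <- which(upper.tri(r2), arr.ind = TRUE)
  z_ns <- mean(r2[upper.tri(r2)])
  z_a <- mean(r2[cbind(seq_len(m - 1L), 2:m)])
  set.seed(seed)
  p <- matrix(NA_real_, m, m, dimnames = dimnames(r2))
  for (idx in seq_len(nrow(pairs))) {
    i <- pairs[idx, 1L]; j <- pairs[idx, 2L]
    obs <- r2[i, j]
    null <- vapply(seq_len(permutations), function(b)
      suppressWarnings(stats::cor(X[, i], sample(X[, j]))^2), numeric(1L))
    null[is.na(null)] <- 0
    p[i, j] <- p[j, i] <- (sum(null >= obs - 1e-12) + 1) / (permutations + 1)
  }
  list(zz = z_a - z_ns, z_a = z_a, z_ns = z_ns, r2 = r2, p = p)
}

#' Divergence from the outgroup per site
#'
#' Mean over haplotypes of the per-effective-site difference from the aligned
#' outgroup sequence.
#'
#' @inheritParams segregating_sites
#' @param outgroup Outgroup sequence aligned to the same coordinates.
#' @return Per-site divergence.
#' @export
divergence <- function(aln, outgroup, sites) {
  og <- outgroup_chars(outgroup, aln$gene$length)
  if (length(sites) == 0L) return(NA_real_)
  diffs <- sweep(aln$mat[, sites, drop = FALSE], 2L, og[sites], FUN = "!=")
  mean(rowSums(diffs)) / length(sites)
}
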