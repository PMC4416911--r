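# SNP-climate association with ancestry (Q-matrix) structure covariates and
# population-block permutation inference.

#' Minor-allele dosage matrix from phased alignments
#'
#' Extracts every biallelic segregating site from each gene alignment and
#' codes each individual by its minor-allele dosage (0/1/2; `NA` when either
#' haplotype is missing or gapped at the site).
#'
#' @param alns List of [hap_alignment()]s (same individuals in each).
#' @return List with `dosage` (individuals x SNPs matrix), `meta` (data
#'   frame `gene`, `position`, `type`), `sample_id`.
#' @export
genotype_matrix <- function(alns) {
  if (inherits(alns, "hap_alignment")) alns <- list(alns)
  ids <- unique(alns[[1L]]$sample_id)
  cols <- list(); meta <- NULL
  for (aln in alns) {
    stopifnot(identical(unique(aln$sample_id), ids))
    # biallelic SNPs: exactly two distinct bases observed (N/- ignored)
    seg <- which(vapply(seq_len(ncol(aln$mat)), function(j) {
      b <- aln$mat[, j]
      length(unique(b[b %in% c("A", "C", "G", "T")])) == 2L
    }, logical(1L)))
    if (length(seg) == 0L) next
    cls <- annotate_sites(aln, seg)
    for (si in seq_along(seg)) {
      j <- seg[si]
      b <- aln$mat[, j]
      tab <- sort(table(b[b %in% c("A", "C", "G", "T")]), decreasing = TRUE)
      minor <- names(tab)[2L]
      dos <- vapply(ids, function(id) {
        h <- b[aln$sample_id == id]
        if (any(!h %in% c("A", "C", "G", "T"))) NA_real_ else sum(h == minor)
      }, numeric(1L))
      cols[[length(cols) + 1L]] <- dos
      meta <- rbind(meta, data.frame(gene = aln$gene$gene_id, position = j,
                                     type = cls[si]))
    }
  }
  dosage <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(), length(ids), 0L)
  rownames(dosage) <- ids
  list(dosage = dosage, meta = meta, sample_id = ids)
}

# t statistic of the first non-intercept column in a least-squares fit.
.clim_t <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    if (!(2L %in% keep)) return(NA_real_)
    X <- X[, sort(keep), drop = FALSE]
    qrx <- qr(X)
  }
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  if (df <= 0) return(NA_real_)
  s2 <- sum(res^2) / df
  xtxi <- chol2inv(qrx$qr[seq_len(ncol(X)), , drop = FALSE])
  beta[2L] / sqrt(s2 * xtxi[2L, 2L])
}

#' SNP-climate association with structure covariates
#'
#' Per SNP, fits `dosage ~ climate + Q` by least squares (one Q column is
#' dropped for identifiability) and tests the climate coefficient with a
#' permutation null: climate values are permuted across populations as
#' blocks (climate is a population-level predictor), and
#' `p = (count(|t*| >= |t|) + 1) / (permutations + 1)`.
#'
#' @param dosage Individuals x SNPs matrix (from [genotype_matrix()]).
#' @param climate Numeric climate value per individual.
#' @param q Q-matrix (individuals x K ancestry proportions).
#' @param populations Population id per individual (permutation blocks).
#' @param permutations Number of block permutations (study preset 100,000;
#'   default 10,000).
#' @param seed Integer seed.
#' @param n_tests Number of climate variables tested, for the multiple-test
#'   correction (study value 4).
#' @return Data frame per SNP: `beta`, `t`, `p`, `p_corrected`,
#'   `significant`; skipped (monomorphic in complete cases) SNPs carry `NA`.
#' @export
associate <- function(dosage, climate, q, populations,
                      permutations = 10000L, seed = 1L, n_tests = 4L) {
  n <- nrow(dosage)
  stopifnot(length(climate) == n, nrow(q) == n, length(populations) == n,
            permutations >= 100L)
  q <- as.matrix(q)
  if (ncol(q) > 1L) q <- q[, -ncol(q), drop = FALSE]  # drop one for identifiability
  pops <- unique(populations)
  pop_clim <- vapply(pops, function(p) climate[populations == p][1L],
                     numeric(1L))
  set.seed(seed)
  perm_clim <- vapply(seq_len(permutations), function(b)
    pop_clim[sample.int(length(pops))][match(populations, pops)],
    numeric(n))
  S <- ncol(dosage)
  beta <- t_obs <- p <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    y <- dosage[, s]
    cc <- !is.na(y)
    if (length(unique(y[cc])) < 2L) next
    X <- cbind(1, climate[cc], q[cc, , drop = FALSE])
    tt <- .clim_t(X, y[cc])
    if (is.na(tt)) next
    null <- vapply(seq_len(permutations), function(b) {
      Xb <- X; Xb[, 2L] <- perm_clim[cc, b]
      .clim_t(Xb, y[cc])
    }, numeric(1L))
    null <- null[!is.na(null)]
    fit <- stats::lm.fit(X, y[cc])
    beta[s] <- fit$coefficients[2L]
    t_obs[s] <- tt
    p[s] <- (sum(abs(null) >= abs(tt) - 1e-12) + 1) / (length(null) + 1)
  }
  pc <- correct_multiple(p, n_tests)
  data.frame(beta = beta, t = t_obs, p = p, p_corrected = pc,
             significant = !is.na(pc) & pc < 0.05)
}

#' Bonferroni-style correction over climate variables
#'
#' `min(1, p * n_tests)`; the study tests four climate variables (spring and
#' summer temperature and precipitation) per SNP.
#'
#' @param p P value(s) in `[0, 1]`.
#' @param n_tests Number of tests (default 4).
#' @return Corrected p value(s).
#' @export
correct_multiple <- function(p, n_tests = 4L) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Per-population minor-allele frequency table
#'
#' Frequencies in `[0, 1]` per SNP and population, with populations sorted
#' along the longitudinal gradient.
#'
#' @param dosage Individuals x SNPs dosage matrix.
#' @param populations Population id per individual.
#' @param longitude Named vector of population longitudes (for ordering).
#' @return Matrix SNPs x populations of minor-allele frequencies.
#' @export
snp_frequency_table <- function(dosage, populations, longitude = NULL) {
  pops <- unique(populations)
  if (!is.null(longitude)) pops <- pops[order(longitude[pops])]
  freq <- vapply(pops, function(p) {
    d <- dosage[populations == p, , drop = FALSE]
    colMeans(d, na.rm = TRUE) / 2
  }, numeric(ncol(dosage)))
  freq <- matrix(freq, ncol = length(pops),
                 dimnames = list(colnames(dosage), pops))
  freq[is.nan(freq)] <- 0
  freq
}
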