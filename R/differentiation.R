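# Population differentiation: Hudson F_ST, Jost D_est, and the H-vs-L
# rank-sum contrast.

# Pairwise difference counts between all haplotype rows over `sites`.
.pair_diffs <- function(mat, sites) {
  sub <- mat[, sites, drop = FALSE]
  m <- nrow(sub)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    di <- colSums(t(sub[(i + 1L):m, , drop = FALSE]) != sub[i, ])
    d[i, (i + 1L):m] <- d[(i + 1L):m, i] <- di
  }
  d
}

#' Hudson-type F_ST between populations
#'
#' `1 - H_w / H_b`, where `H_w` is the mean within-population pairwise
#' difference and `H_b` the mean between-population pairwise difference, for
#' every population pair and overall.  Negative estimates are reported as
#' computed.
#'
#' @param aln A [hap_alignment()].
#' @param populations Character/factor vector assigning each haplotype row to
#'   a population.
#' @param sites Effective column indices (default: all effective sites of the
#'   whole region).
#' @return List with `pairwise` (data frame `pop_a`, `pop_b`, `f_st`),
#'   `overall`, and `matrix` (symmetric pairwise matrix).  `NA` where the
#'   total sample is monomorphic.
#' @export
fst <- function(aln, populations, sites = effective_sites(aln, "all")) {
  populations <- as.character(populations)
  stopifnot(length(populations) == aln$n)
  pops <- sort(unique(populations))
  if (length(pops) < 2L) stop("need >= 2 populations")
  d <- .pair_diffs(aln$mat, sites)
  same <- outer(populations, populations, "==")
  up <- upper.tri(d)
  hb_all <- mean(d[up & !same])
  hw_all <- mean(d[up & same])
  overall <- if (!is.finite(hb_all) || hb_all == 0) NA_real_ else 1 - hw_all / hb_all
  k <- length(pops)
  mat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pw <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sel <- populations %in% c(pops[i], pops[j])
    dd <- d[sel, sel]; ps <- populations[sel]
    sm <- outer(ps, ps, "==")
    u <- upper.tri(dd)
    hb <- mean(dd[u & !sm]); hw <- mean(dd[u & sm])
    f <- if (!is.finite(hb) || hb == 0) NA_real_ else 1 - hw / hb
    mat[i, j] <- mat[j, i] <- f
    pw <- rbind(pw, data.frame(pop_a = pops[i], pop_b = pops[j], f_st = f))
  }
  list(pairwise = pw, overall = overall, matrix = mat)
}

# Jost D for one gene and one set of populations, from haplotype-frequency
# heterozygosities with Nei-Chesser sample-size corrections.
.jost_d_gene <- function(keys, populations) {
  pops <- sort(unique(populations))
  k <- length(pops)
  alleles <- unique(keys)
  freq <- vapply(pops, function(p) {
    tab <- table(factor(keys[populations == p], levels = alleles))
    as.numeric(tab) / sum(tab)
  }, numeric(length(alleles)))
  freq <- matrix(freq, nrow = length(alleles))
  nj <- vapply(pops, function(p) sum(populations == p), numeric(1L))
  ntilde <- k / sum(1 / nj)                      # harmonic mean sample size
  hs_unc <- mean(1 - colSums(freq^2))
  hs <- ntilde / (ntilde - 1) * hs_unc
  pbar <- rowMeans(freq)
  ht <- (1 - sum(pbar^2)) + hs / (k * ntilde)
  if (1 - hs <= 0) return(0)
  max(0, min(1, (ht - hs) / (1 - hs) * k / (k - 1)))
}

#' Jost's actual differentiation index D_est
#'
#' Per-gene Jost D from sample-size-corrected within- and total-population
#' heterozygosities of haplotype (allele) frequencies; multiple genes are
#' combined by the arithmetic mean of per-gene values.  Monomorphic genes
#' contribute `D = 0`.
#'
#' @param alns A single [hap_alignment()] or list of them (one per gene).
#' @param populations Population assignment per haplotype row (same order in
#'   every gene).
#' @return List with `pairwise` (data frame), `overall`, `matrix`,
#'   `per_gene` (overall D per gene).
#' @export
d_est <- function(alns, populations) {
  if (inherits(alns, "hap_alignment")) alns <- list(alns)
  populations <- as.character(populations)
  pops <- sort(unique(populations))
  k <- length(pops)
  if (k < 2L) stop("need >= 2 populations")
  keys <- lapply(alns, function(a) apply(a$mat, 1L, paste, collapse = ""))
  per_gene <- vapply(keys, .jost_d_gene, numeric(1L), populations = populations)
  mat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pw <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sel <- populations %in% c(pops[i], pops[j])
    dg <- vapply(keys, function(kk) .jost_d_gene(kk[sel], populations[sel]),
                 numeric(1L))
    dd <- mean(dg)
    mat[i, j] <- mat[j, i] <- dd
    pw <- rbind(pw, data.frame(pop_a = pops[i], pop_b = pops[j], d_est = dd))
  }
  list(pairwise = pw, overall = mean(per_gene), matrix = mat,
       per_gene = per_gene)
}

#' Compare differentiation between altitude classes
#'
#' Two-sided Wilcoxon rank-sum test (exact for small samples without ties)
#' contrasting, e.g., pairwise F_ST values among H-populations against those
#' among L-populations.
#'
#' @param values_H,values_L Numeric vectors of within-class pairwise values.
#' @return List with `W`, `p_value`, `mean_H`, `mean_L`.
#' @export
compare_groups <- function(values_H, values_L) {
  stopifnot(length(values_H) > 0L, length(values_L) > 0L)
  wt <- suppressWarnings(stats::wilcox.test(values_H, values_L))
  list(W = unname(wt$statistic), p_value = wt$p.value,
       mean_H = mean(values_H), mean_L = mean(values_L))
}

#' Within-class pairwise values from a differentiation matrix
#'
#' Extracts the pairwise entries whose two populations both belong to the
#' requested altitude class.
#'
#' @param mat Symmetric pairwise matrix with population dimnames.
#' @param class_of Named vector mapping population id to `"H"`/`"L"`.
#' @param class `"H"` or `"L"`.
#' @return Numeric vector of within-class pairwise values.
#' @export
class_pairs <- function(mat, class_of, class) {
  pops <- rownames(mat)[class_of[rownames(mat)] == class]
  m <- mat[pops, pops, drop = FALSE]
  m[upper.tri(m)]
}
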