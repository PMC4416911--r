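# Per-gene summary rows (diversity, neutrality, linkage, divergence,
# selection) and the combined table with the across-genes "All genes" row.

#' Per-gene population-genetics summary
#'
#' Computes the standard per-gene row: haplotype count `n`, region length
#' `L`, the linkage statistic `ZZ` and haplotype diversity `H` over the
#' whole region; effective intronic sites `L_eff`, segregating sites `S`,
#' `pi`, Watterson's `theta_W`, Tajima's `D` and outgroup divergence `Div`
#' over introns; and the McDonald-Kreitman counts with the DoS index over
#' the coding sequence.  Intronless genes report the intron block as `NA`.
#'
#' @param aln A [hap_alignment()].
#' @param outgroup Aligned outgroup sequence.
#' @param zz_permutations Permutations for the per-pair r2 P values
#'   (0 skips them).
#' @param seed Seed for the r2 permutations.
#' @return List of class `gene_summary`.
#' @export
gene_summary <- function(aln, outgroup, zz_permutations = 0L, seed = 1L) {
  n_introns <- sum(aln$gene$segments$kind == "intron")
  eff_all <- effective_sites(aln, "all")
  ls <- linkage_stats(aln, eff_all, permutations = max(1L, zz_permutations),
                      seed = seed)
  out <- list(gene_id = aln$gene$gene_id, n = aln$n, L = aln$gene$length,
              zz = if (is.null(ls)) NA_real_ else ls$zz,
              hap_div = haplotype_diversity(aln),
              n_introns = n_introns,
              L_eff = NA_integer_, S = NA_integer_, pi = NA_real_,
              theta_w = NA_real_, tajima_d = NA_real_, div = NA_real_)
  if (n_introns > 0L) {
    eff <- effective_sites(aln, "intron")
    out$L_eff <- length(eff)
    if (out$L_eff > 0L) {
      seg <- segregating_sites(aln, eff)
      out$S <- length(seg)
      out$pi <- nucleotide_diversity(aln, eff)
      out$theta_w <- watterson_theta(out$S, aln$n, out$L_eff)
      out$tajima_d <- tajimas_d(aln$n, out$S, out$pi * out$L_eff)
      eff_og <- effective_sites(aln, "intron", outgroup = outgroup)
      out$div <- divergence(aln, outgroup, eff_og)
    }
  }
  mk <- mk_test(aln, outgroup)
  out$mk <- mk
  out$dos <- dos(mk$Dn, mk$Ds, mk$Pn, mk$Ps)
  structure(out, class = "gene_summary")
}

.fmt <- function(x, digits) ifelse(is.na(x), "NA", formatC(x, digits = digits,
                                                           format = "f"))
.mean_sd <- function(x, digits) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return("NA")
  sprintf("%s (%s)", .fmt(mean(x), digits), .fmt(stats::sd(x), digits))
}

#' Gene-summary rows as a data frame
#'
#' @param summaries List of [gene_summary()] objects.
#' @return Data frame, one row per gene.
#' @export
gene_summary_frame <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(gene_id = s$gene_id, n = s$n, L = s$L, zz = s$zz,
               hap_div = s$hap_div, n_introns = s$n_introns, L_eff = s$L_eff,
               S = s$S, pi = s$pi, theta_w = s$theta_w,
               tajima_d = s$tajima_d, div = s$div,
               mk_p = s$mk$p_value, dos = s$dos)))
}

#' Write the per-gene summary table with the "All genes" row
#'
#' One row per gene plus a final row of across-genes means (SD) and column
#' totals for `L`, intron count, `L_eff` and `S`.  Diversity and divergence
#' columns print with 5 decimals, test statistics with 3.
#'
#' @param summaries Nonempty list of [gene_summary()] objects.
#' @param path Output path.
#' @return Invisibly, the formatted data frame that was written.
#' @export
write_gene_summary_table <- function(summaries, path) {
  stopifnot(length(summaries) > 0L)
  df <- gene_summary_frame(summaries)
  fmt <- data.frame(
    gene_id = df$gene_id, n = as.character(df$n), L = as.character(df$L),
    zz = .fmt(df$zz, 3L), hap_div = .fmt(df$hap_div, 3L),
    n_introns = as.character(df$n_introns),
    L_eff = ifelse(is.na(df$L_eff), "NA", as.character(df$L_eff)),
    S = ifelse(is.na(df$S), "NA", as.character(df$S)),
    pi = .fmt(df$pi, 5L), theta_w = .fmt(df$theta_w, 5L),
    tajima_d = .fmt(df$tajima_d, 3L), div = .fmt(df$div, 5L),
    mk_p = .fmt(df$mk_p, 4L), dos = .fmt(df$dos, 3L))
  total <- data.frame(
    gene_id = "All genes", n = .mean_sd(df$n, 1L),
    L = format(sum(df$L), big.mark = ","),
    zz = .mean_sd(df$zz, 3L), hap_div = .mean_sd(df$hap_div, 3L),
    n_introns = as.character(sum(df$n_introns)),
    L_eff = as.character(sum(df$L_eff, na.rm = TRUE)),
    S = as.character(sum(df$S, na.rm = TRUE)),
    pi = .mean_sd(df$pi, 5L), theta_w = .mean_sd(df$theta_w, 5L),
    tajima_d = .mean_sd(df$tajima_d, 3L), div = .mean_sd(df$div, 5L),
    mk_p = "NA", dos = .mean_sd(df$dos, 3L))
  out <- rbind(fmt, total)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
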