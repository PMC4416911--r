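# Coding-site classification, the McDonald-Kreitman test and the DoS index.

# Concatenated exon coordinates: alignment positions (in order) that make up
# the coding sequence, trimmed to whole codons.
cds_positions <- function(gene) {
  pos <- which(segment_mask(gene, "exon"))
  pos[seq_len(length(pos) %/% 3L * 3L)]
}

# Majority-rule consensus base per alignment column (A/C/G/T only; ties
# resolved alphabetically for determinism).
consensus_base <- function(mat, cols) {
  vapply(cols, function(j) {
    cnt <- tabulate(match(mat[, j], c("A", "C", "G", "T")), nbins = 4L)
    c("A", "C", "G", "T")[which.max(cnt)]
  }, character(1L))
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify sites as noncod / syn / nonsyn
#'
#' Intronic positions are `noncod`.  For exonic positions each alternative
#' allele is substituted into the consensus codon background (reading frame
#' anchored on the annotated exons); the variant is `syn` iff every observed
#' allele preserves the amino acid.  Positions in a trailing incomplete codon
#' are classified `noncod`.
#'
#' @param aln A [hap_alignment()].
#' @param positions Alignment positions (1-based) to classify.
#' @param alleles Optional list (parallel to `positions`) of the alleles to
#'   compare at each site; by default the observed sample alleles.
#' @return Character vector in `{noncod, syn, nonsyn}`.
#' @export
annotate_sites <- function(aln, positions, alleles = NULL) {
  cds <- cds_positions(aln$gene)
  cons <- consensus_base(aln$mat, cds)
  vapply(seq_along(positions), function(i) {
    pos <- positions[i]
    ci <- match(pos, cds)
    if (is.na(ci)) return("noncod")
    al <- if (is.null(alleles)) {
      a <- unique(aln$mat[, pos])
      a[a %in% c("A", "C", "G", "T")]
    } else alleles[[i]]
    if (length(al) < 2L) return("syn")
    codon_idx <- (ci - 1L) %/% 3L
    slot <- (ci - 1L) %% 3L + 1L
    codon <- cons[codon_idx * 3L + 1:3]
    aas <- vapply(al, function(b) {
      codon[slot] <- b
      translate_codon(paste(codon, collapse = ""))
    }, character(1L))
    if (length(unique(aas)) == 1L) "syn" else "nonsyn"
  }, character(1L))
}

#' McDonald-Kreitman test
#'
#' Counts synonymous and non-synonymous intraspecific polymorphisms (`Ps`,
#' `Pn`) and fixed differences from the outgroup (`Ds`, `Dn`) over effective
#' coding sites, and tests the 2x2 contingency table with a two-sided Fisher
#' exact test.
#'
#' @param aln A [hap_alignment()].
#' @param outgroup Aligned outgroup sequence.
#' @return List with `Pn`, `Ps`, `Dn`, `Ds`, `p_value`, `degenerate` (flag:
#'   an empty table margin, `p_value` reported as 1).
#' @export
mk_test <- function(aln, outgroup) {
  og <- outgroup_chars(outgroup, aln$gene$length)
  eff <- effective_sites(aln, "exon", outgroup = og)
  eff <- intersect(eff, cds_positions(aln$gene))
  seg <- segregating_sites(aln, eff)
  cls_p <- annotate_sites(aln, seg)
  Pn <- sum(cls_p == "nonsyn"); Ps <- sum(cls_p == "syn")
  mono <- setdiff(eff, seg)
  fixed <- mono[aln$mat[1L, mono] != og[mono]]
  cls_d <- annotate_sites(aln, fixed,
                          alleles = lapply(fixed, function(p)
                            c(aln$mat[1L, p], og[p])))
  Dn <- sum(cls_d == "nonsyn"); Ds <- sum(cls_d == "syn")
  degenerate <- (Pn + Ps) == 0L || (Dn + Ds) == 0L ||
    (Pn + Dn) == 0L || (Ps + Ds) == 0L
  p <- if (degenerate) 1 else
    stats::fisher.test(matrix(c(Pn, Ps, Dn, Ds), nrow = 2L))$p.value
  list(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds, p_value = p,
       degenerate = degenerate)
}

#' Direction of selection index (DoS)
#'
#' `Dn/(Dn+Ds) - Pn/(Pn+Ps)`; positive under adaptive divergence, negative
#' under segregating slightly deleterious variation, 0 at neutrality.
#'
#' @param Dn,Ds Fixed non-synonymous / synonymous differences.
#' @param Pn,Ps Non-synonymous / synonymous polymorphisms.
#' @return DoS in `[-1, 1]`, or `NA_real_` when either margin is empty.
#' @export
dos <- function(Dn, Ds, Pn, Ps) {
  if (Dn + Ds == 0 || Pn + Ps == 0) return(NA_real_)
  Dn / (Dn + Ds) - Pn / (Pn + Ps)
}
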