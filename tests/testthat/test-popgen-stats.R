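# Diversity, neutrality, linkage, divergence and selection statistics.

test_that("effective sites exclude columns with missing data or gaps", {
  gene <- gene_region("g", 10, data.frame(kind = c("exon", "intron"),
                                          start = c(1, 5), end = c(4, 10)))
  aln <- toy_alignment(c("ACGTACGTAC", "ACGTACGTAC",
                         "ACGTACGTAC", "ACGTACGTAC"), gene)
  expect_length(effective_sites(aln, "intron"), 6)
  expect_length(effective_sites(aln, "exon"), 4)
  # one gap column inside the intron drops L_eff by 1
  aln2 <- toy_alignment(c("ACGTAC-TAC", "ACGTACGTAC",
                          "ACGTACGTAC", "ACGTACGTAC"), gene)
  expect_length(effective_sites(aln2, "intron"), 5)
  # all-exon gene has zero intronic sites
  gene3 <- gene_region("g3", 6, data.frame(kind = "exon", start = 1, end = 6))
  aln3 <- toy_alignment(c("ACGTAC", "ACGTAC"), gene3)
  expect_length(effective_sites(aln3, "intron"), 0)
})

test_that("nucleotide diversity matches the brute-force pair enumeration", {
  aln <- toy_alignment(c("AAAAAAAAAA", "AAAAAAAAAA",
                         "AAAAAAAAAA", "AAAAAAAAAA"))
  sites <- effective_sites(aln, "all")
  expect_equal(nucleotide_diversity(aln, sites), 0)
  # 2 haplotypes differing at 1 of 100 sites
  s <- paste(rep("A", 100), collapse = "")
  s2 <- paste0(substr(s, 1, 99), "G")
  aln2 <- toy_alignment(c(s, s2))
  expect_equal(nucleotide_diversity(aln2, effective_sites(aln2, "all")), 0.01)
  # 4-haplotype toy equals exhaustive enumeration over the 6 pairs
  aln4 <- toy_alignment(c("ACGTACGTAC", "ACGTTCGTAC",
                          "AGGTACGAAC", "ACGTACGTCC"))
  s4 <- effective_sites(aln4, "all")
  expect_equal(nucleotide_diversity(aln4, s4), pi_bruteforce(aln4, s4))
})

test_that("Watterson's theta reproduces the published worked rows", {
  expect_equal(round(watterson_theta(10, 120, 289), 5), 0.00645)
  expect_equal(round(watterson_theta(12, 116, 458), 5), 0.00492)
  expect_equal(watterson_theta(0, 50, 300), 0)
})

test_that("Tajima's D reproduces the published worked rows", {
  expect_equal(tajimas_d(120, 10, 0.01621 * 289), 3.763, tolerance = 0.01)
  expect_equal(tajimas_d(120, 4, 0.00954 * 146), 1.667, tolerance = 0.01)
  # numerator identity: mean pairwise = S / a1 -> D = 0
  a1 <- sum(1 / (1:19))
  expect_equal(tajimas_d(20, 7, 7 / a1), 0)
  expect_true(is.na(tajimas_d(20, 0, 0)))
})

test_that("haplotype diversity follows the unbiased frequency formula", {
  expect_equal(haplotype_diversity(toy_alignment(rep("ACGT", 6))), 0)
  distinct <- toy_alignment(c("AAAA", "CCCC", "GGGG", "TTTT"))
  expect_equal(haplotype_diversity(distinct), 1)
  half <- toy_alignment(c("AAAA", "AAAA", "CCCC", "CCCC"))
  expect_equal(haplotype_diversity(half), (4 / 3) * (1 - 0.5), tolerance = 1e-6)
})

test_that("linkage statistics match hand-computed r2 and are invariant", {
  # exactly 2 segregating sites -> zz = 0
  aln2 <- toy_alignment(c("AATA", "AATA", "CAGA", "CAGA"))
  s2 <- effective_sites(aln2, "all")
  ls2 <- linkage_stats(aln2, s2, permutations = 100, seed = 1)
  expect_equal(ls2$zz, 0)
  # all pairs in perfect association -> both means 1, zz = 0
  aln_p <- toy_alignment(c("ACA", "ACA", "GTG", "GTG", "ACA", "GTG"))
  lsp <- linkage_stats(aln_p, effective_sites(aln_p, "all"),
                       permutations = 100, seed = 1)
  expect_equal(lsp$z_a, 1)
  expect_equal(lsp$z_ns, 1)
  # toy with one decayed pair: hand-computed r2 from haplotype counts
  haps <- c("AA", "AA", "AA", "AC", "GA", "GC", "GC", "GC")
  aln_d <- toy_alignment(haps)
  lsd <- linkage_stats(aln_d, effective_sites(aln_d, "all"),
                       permutations = 100, seed = 1)
  x <- as.numeric(substr(haps, 1, 1) == "G")
  y <- as.numeric(substr(haps, 2, 2) == "C")
  expect_equal(lsd$r2[1, 2], cor(x, y)^2)
  # invariance to row order and allele label swap
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  aln_perm <- toy_alignment(haps[perm])
  lsd2 <- linkage_stats(aln_perm, effective_sites(aln_perm, "all"),
                        permutations = 100, seed = 1)
  expect_equal(lsd2$zz, lsd$zz)
  swapped <- chartr("AG", "GA", haps)
  aln_sw <- toy_alignment(swapped)
  lsd3 <- linkage_stats(aln_sw, effective_sites(aln_sw, "all"),
                        permutations = 100, seed = 1)
  expect_equal(lsd3$zz, lsd$zz)
})

test_that("divergence equals the mean per-haplotype outgroup distance", {
  aln <- toy_alignment(c("ACGTACGTAC", "ACGTACGTAC"))
  sites <- effective_sites(aln, "all")
  expect_equal(divergence(aln, "ACGTACGTAC", sites), 0)
  og <- "GCGTACGTAC"  # differs at 1 of 10 sites from a monomorphic sample
  expect_equal(divergence(aln, og, sites), 0.10)
  # with segregating sites: mean of per-haplotype distances
  aln2 <- toy_alignment(c("AAAA", "AACA", "AAAT", "AAAA"))
  s2 <- effective_sites(aln2, "all")
  dists <- apply(aln2$mat, 1, function(h) sum(h != c("G", "A", "A", "A")))
  expect_equal(divergence(aln2, "GAAA", s2), mean(dists) / 4)
})

test_that("McDonald-Kreitman counts and Fisher P match the oracle", {
  expect_equal(fisher_enum(5, 5, 5, 5), 1)
  expect_equal(stats::fisher.test(matrix(c(8, 2, 1, 9), 2))$p.value,
               fisher_enum(8, 2, 1, 9))
  for (tab in list(c(3, 7, 11, 2), c(1, 1, 20, 5), c(0, 4, 6, 6),
                   c(12, 9, 30, 25))) {
    expect_equal(stats::fisher.test(matrix(tab, 2))$p.value,
                 fisher_enum(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
  # counts on a constructed coding alignment: CCT->CCC is synonymous (P/P),
  # AAA->GAA is non-synonymous (K/E)
  gene <- gene_region("g", 6, data.frame(kind = "exon", start = 1, end = 6))
  aln <- toy_alignment(c("CCTAAA", "CCCAAA", "CCTGAA", "CCTAAA"), gene)
  mk <- mk_test(aln, "CCTAAA")
  expect_equal(mk$Ps, 1)
  expect_equal(mk$Pn, 1)
  expect_equal(mk$Dn + mk$Ds, 0)
  expect_true(mk$degenerate)
  expect_equal(mk$p_value, 1)
  # fixed difference against the outgroup: sample CCT vs outgroup CCA (syn)
  aln2 <- toy_alignment(c("CCTAAA", "CCTAAA", "CCTAAA", "CCTAAA"), gene)
  mk2 <- mk_test(aln2, "CCAGAA")
  expect_equal(mk2$Ds, 1)   # CCT vs CCA: both Pro
  expect_equal(mk2$Dn, 1)   # AAA vs GAA: Lys vs Glu
})

test_that("DoS contrasts divergence and polymorphism fractions", {
  expect_equal(dos(5, 5, 3, 3), 0)
  expect_equal(dos(10, 10, 1, 3), 0.25)
  expect_equal(dos(0, 5, 5, 0), -1)
  expect_true(is.na(dos(0, 0, 2, 2)))
})

test_that("site annotation distinguishes noncod, syn and nonsyn", {
  gene <- gene_region("g", 9, data.frame(kind = c("exon", "intron"),
                                         start = c(1, 7), end = c(6, 9)))
  # codon 2 position 6 is third position of codon AAA/AAG (both Lys) -> syn
  aln <- toy_alignment(c("CCTAAAGGG", "CCTAAGGGG",
                         "CCAAAAGGG", "CCTAAAGGG"), gene)
  cls <- annotate_sites(aln, c(3, 6, 8))
  expect_equal(unname(cls), c("syn", "syn", "noncod"))
  # first codon position change CCT -> ACT is nonsyn (Pro -> Thr)
  aln2 <- toy_alignment(c("CCTAAAGGG", "ACTAAAGGG",
                          "CCTAAAGGG", "CCTAAAGGG"), gene)
  expect_equal(unname(annotate_sites(aln2, 1)), "nonsyn")
})
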