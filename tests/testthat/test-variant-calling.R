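# Binomial error model, site calling, minimal haplotypes, phasing and
# consensus building.

test_that("p_false is the binomial point mass", {
  expect_equal(p_false(5, 2, 0.024), choose(5, 2) * 0.024^2 * 0.976^3)
  expect_equal(p_false(5, 2, 0.024), 0.005355, tolerance = 1e-4)
  expect_equal(p_false(1, 1, 0.37), 0.37)      # single-read identity
  expect_equal(p_false(5, 0, 0), 1)
  expect_error(p_false(3, 4, 0.1), "k <= n")
})

test_that("p_false sums to one over k and matches outcome enumeration", {
  for (f in c(0.01, 0.024, 0.1))
    for (n in 1:12)
      expect_equal(sum(p_false(n, 0:n, f)), 1)
  # oracle: enumerate all error/no-error outcomes of n reads
  enum_pmf <- function(n, k, f) {
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    probs <- apply(grid, 1, function(g) prod(ifelse(g == 1, f, 1 - f)))
    sum(probs[rowSums(grid) == k])
  }
  for (n in c(2, 5, 8)) for (k in c(0, 1, n %/% 2, n))
    expect_equal(p_false(n, k, 0.024), enum_pmf(n, k, 0.024))
})

test_that("p_false_profile uses the smallest integer above 0.3 n", {
  prof <- p_false_profile(0.024, 0.3, 12)
  expect_equal(prof$k[prof$n == 5], 2)
  expect_equal(prof$k[prof$n == 10], 4)
  expect_equal(prof$p_false[prof$n == 5], 0.005355, tolerance = 1e-4)
  expect_lte(prof$p_false[prof$n == 5], 0.0055)
  expect_equal(prof$k[prof$n == 1], 1)
  expect_equal(prof$p_false[prof$n == 1], 0.024)
  prof0 <- p_false_profile(0, 0.3, 6)
  expect_true(all(prof0$p_false == 0))
})

test_that("call_sites applies the depth and minor-fraction filters", {
  # depth 10, minor count 4 at position 3 -> called
  pu <- toy_pileup(c(lapply(1:6, function(i) c(1, "ACGTA")),
                     lapply(1:4, function(i) c(1, "ACTTA"))), 5)
  sites <- call_sites(pu)
  expect_equal(sites$position, 3)
  expect_equal(sites$major, "G")
  expect_equal(sites$minor, "T")
  expect_false(sites$is_indel)
  # depth 4 -> not called
  pu4 <- toy_pileup(c(lapply(1:2, function(i) c(1, "AC")),
                      lapply(1:2, function(i) c(1, "AT"))), 2)
  expect_equal(nrow(call_sites(pu4)), 0)
  # minor exactly 30% is not "more than 30%"
  pu30 <- toy_pileup(c(lapply(1:7, function(i) c(1, "AC")),
                       lapply(1:3, function(i) c(1, "AT"))), 2)
  expect_equal(nrow(call_sites(pu30)), 0)
  # indel allele eligible
  puind <- toy_pileup(c(lapply(1:5, function(i) c(1, "ACG")),
                        lapply(1:5, function(i) c(1, "A-G"))), 3)
  expect_true(call_sites(puind)$is_indel)
  # three alleles each above threshold -> ambiguity error
  pu3 <- toy_pileup(c(lapply(1:4, function(i) c(1, "AA")),
                      lapply(1:4, function(i) c(1, "AC")),
                      lapply(1:4, function(i) c(1, "AG"))), 2)
  expect_error(call_sites(pu3), "more than two alleles")
})

test_that("minimal haplotypes chain across overlapping reads", {
  reads <- list(c(1, "AaaaaaaaaG"),   # sites 1 and 10 (case-insensitive)
                c(8, "aaGaaaaaaa"),   # sites 10 and 15 (as positions 8..17)
                c(13, "aaTaaaaa"))    # site 15
  # build a pileup with called sites at 1, 10, 15
  pu <- toy_pileup(c(lapply(1:5, function(i) c(1, "AAAAAAAAAGAAAATAAAAA")),
                     lapply(1:5, function(i) c(1, "GAAAAAAAATAAAACAAAAA"))), 20)
  sites <- call_sites(pu)
  expect_equal(sites$position, c(1, 10, 15))
  mh <- minimal_haplotypes(pu, sites)
  expect_length(mh, 10)
  expect_equal(mh[[1]]$position, c(1, 10, 15))
  # a read covering no called site is omitted
  pu2 <- toy_pileup(c(lapply(1:5, function(i) c(1, "AC")),
                      lapply(1:5, function(i) c(1, "GC")),
                      list(c(2, "C"))), 2)
  s2 <- call_sites(pu2)
  expect_equal(s2$position, 1)
  expect_length(minimal_haplotypes(pu2, s2), 10)
})

test_that("phasing chains consistent alleles and flags phase gaps", {
  pu <- toy_pileup(c(lapply(1:5, function(i) c(1, "AAAAAAAAAGAAAATAAAAA")),
                     lapply(1:5, function(i) c(1, "GAAAAAAAATAAAACAAAAA"))), 20)
  sites <- call_sites(pu)
  ph <- phase_haplotypes(minimal_haplotypes(pu, sites), sites, seed = 1)
  expect_false(ph$phase_gap_resolved)
  haps <- apply(ph$alleles, 1, paste, collapse = "")
  expect_setequal(haps, c("AGT", "GTC"))
  # phase gap: no read covers both site blocks
  pug <- toy_pileup(c(lapply(1:5, function(i) c(1, "AC")),
                      lapply(1:5, function(i) c(1, "GC")),
                      lapply(1:5, function(i) c(9, "TA")),
                      lapply(1:5, function(i) c(9, "CA"))), 10)
  sg <- call_sites(pug)
  expect_equal(sg$position, c(1, 9))
  mg <- minimal_haplotypes(pug, sg)
  pg <- phase_haplotypes(mg, sg, seed = 42)
  expect_true(pg$phase_gap_resolved)
  expect_identical(pg$alleles, phase_haplotypes(mg, sg, seed = 42)$alleles)
})

test_that("consensus carries the majority backbone and phased alleles", {
  pu <- toy_pileup(c(lapply(1:4, function(i) c(1, "ACGTT")),
                     lapply(1:4, function(i) c(1, "ACGTT"))), 5)
  pair <- call_genotype(pu)
  expect_equal(pair$seq1, "ACGTT")
  expect_equal(pair$seq2, "ACGTT")
  # one het site -> sequences differ only there
  pu1 <- toy_pileup(c(lapply(1:5, function(i) c(1, "ACGTT")),
                      lapply(1:5, function(i) c(1, "ACATT"))), 5)
  pair1 <- call_genotype(pu1)
  d <- which(strsplit(pair1$seq1, "")[[1]] != strsplit(pair1$seq2, "")[[1]])
  expect_equal(d, 3)
  # majority tie at a non-called position resolved alphabetically
  put <- toy_pileup(list(c(1, "AC"), c(1, "AC"), c(1, "AC"), c(1, "AC"),
                         c(2, "G"), c(2, "G"), c(2, "G"), c(2, "G")), 2)
  # position 2: C x4 vs G x4, tie -> C (alphabetical)
  ct <- call_genotype(put)
  expect_equal(substr(ct$seq1, 2, 2), "C")
  # uncovered position is an error
  pue <- toy_pileup(list(c(1, "ACG"), c(1, "ACG"), c(1, "ACG"),
                         c(1, "ACG"), c(1, "ACG")), 5)
  expect_error(call_genotype(pue), "not covered")
})

test_that("false-positive call rate on homozygous pileups is bounded", {
  # 10,000 simulated depth-5 sites with error rate f_M = 0.024
  set.seed(71)
  n_sites <- 10000
  calls <- 0
  bases <- c("A", "C", "G", "T")
  for (b in seq_len(n_sites)) {
    col <- rep("A", 5)
    err <- runif(5) < 0.024
    col[err] <- sample(bases[-1], sum(err), replace = TRUE)
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) >= 2 && tab[2] / 5 > 0.3) calls <- calls + 1
  }
  expect_lte(calls / n_sites, 0.01)
})

test_that("error-free tiled diploids are rephased exactly", {
  # het sites spaced closer than the read length, so consecutive called
  # sites always share reads (no phase gaps)
  set.seed(5)
  n_rep <- 1000
  ok <- 0
  for (b in seq_len(n_rep)) {
    L <- 120
    h1 <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    h2 <- h1
    het <- sort(sample(30:90, 3))
    for (p in het) h2[p] <- sample(setdiff(c("A", "C", "G", "T"), h1[p]), 1)
    s1 <- paste(h1, collapse = ""); s2 <- paste(h2, collapse = "")
    # deterministic tiling: both haplotypes read 3x from every start, so
    # every position has depth >= 6 split exactly 50/50
    rl <- 80
    reads <- list()
    for (st in seq(1, L - rl + 1, by = 20)) for (rep3 in 1:3) {
      reads <- c(reads, list(c(st, substr(s1, st, st + rl - 1)),
                             c(st, substr(s2, st, st + rl - 1))))
    }
    pu <- toy_pileup(reads, L)
    pair <- call_genotype(pu, seed = b)
    if ((pair$seq1 == s1 && pair$seq2 == s2) ||
        (pair$seq1 == s2 && pair$seq2 == s1)) ok <- ok + 1
  }
  expect_equal(ok, n_rep)
})
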