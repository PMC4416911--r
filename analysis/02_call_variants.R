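#!/usr/bin/env Rscript
# Stage 2: sequence every individual x gene assembly (coverage 20, 250 bp
# reads, per-base error 0.024), call polymorphic sites under the binomial
# error model (depth >= 5, minor allele > 30%), phase by minimal-haplotype
# chaining, and write the called phased alignments plus a SNP report under
# results/called/.  Reports concordance with the simulated truth.

suppressPackageStartupMessages(library(altipop))

src <- "results/study"
out <- "results/called"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240915
set.seed(seed + 2)

samples <- read_samples(file.path(src, "samples.tsv"))
genes <- sub("_segments\\.tsv$", "",
             basename(list.files(src, pattern = "_segments\\.tsv$")))
emodel <- error_model(f_M = 0.024, min_depth = 5, minor_fraction = 0.3)
ids <- unique(samples$sample_id)

n_poly <- 0L; n_gap <- 0L; n_exact <- 0L; n_tot <- 0L
snp_report <- NULL
for (g in sort(genes)) {
  truth <- read_alignment(file.path(src, paste0(g, ".fasta")),
                          annotation = file.path(src,
                                                 paste0(g, "_segments.tsv")),
                          gene_id = g, outgroup_id = "outgroup")
  sub_seed <- sample.int(.Machine$integer.max - 1L, length(ids))
  called <- matrix(NA_character_, 0, truth$gene$length)
  for (i in seq_along(ids)) {
    rows <- which(truth$sample_id == ids[i])
    h1 <- paste(truth$mat[rows[1], ], collapse = "")
    h2 <- paste(truth$mat[rows[2], ], collapse = "")
    pu <- simulate_reads(h1, h2, coverage = 20, read_length = 250,
                         f_M = 0.024, seed = sub_seed[i],
                         gene_id = g, sample_id = ids[i])
    pair <- tryCatch(call_genotype(pu, emodel, seed = sub_seed[i]),
                     error = function(e) e)
    if (inherits(pair, "error")) {
      pair <- build_consensus(pu, call_sites(pu, emodel)[0, ],
                              list(alleles = matrix(character(), 2, 0),
                                   phase_gap_resolved = FALSE))
    }
    n_tot <- n_tot + 1L
    if (nrow(pair$sites) > 0) n_poly <- n_poly + 1L
    if (pair$phase_gap_resolved) n_gap <- n_gap + 1L
    if ((pair$seq1 == h1 && pair$seq2 == h2) ||
        (pair$seq1 == h2 && pair$seq2 == h1)) n_exact <- n_exact + 1L
    if (nrow(pair$sites) > 0)
      snp_report <- rbind(snp_report,
                          cbind(gene = g, sample = ids[i], pair$sites))
    called <- rbind(called, strsplit(pair$seq1, "")[[1]],
                    strsplit(pair$seq2, "")[[1]])
  }
  rownames(called) <- as.vector(t(outer(ids, 1:2, function(s, p)
    sprintf("%s_%d", s, p))))
  aln <- hap_alignment(called, truth$gene,
                       sample_id = rep(ids, each = 2),
                       phase_index = rep(1:2, length(ids)))
  write_alignment(aln, file.path(out, paste0(g, ".fasta")))
}
utils::write.table(snp_report, file.path(out, "snp_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("assemblies:", n_tot, "| polymorphic:", n_poly,
    sprintf("(%.1f%%)", 100 * n_poly / n_tot),
    "| phase gaps randomly resolved:", n_gap,
    "| exact haplotype recovery:", n_exact,
    sprintf("(%.1f%%)\n", 100 * n_exact / n_tot))
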