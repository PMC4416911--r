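#!/usr/bin/env Rscript
# Stage 6: SNP-climate association on the called genotypes with ancestry
# covariates (K = 2..5), block-permutation P values and the x4 correction,
# plus the per-population minor-allele frequency table sorted along the
# longitudinal gradient.  Permutations are scaled down from the 100,000
# production setting.

suppressPackageStartupMessages(library(altipop))

src <- "results/study"
out <- "results/association"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240915
perms <- 2000L

samples <- read_samples(file.path(src, "samples.tsv"))
genes <- sort(sub("_segments\\.tsv$", "",
                  basename(list.files(src, pattern = "_segments\\.tsv$"))))
alns <- lapply(genes, function(g)
  read_alignment(file.path("results/called", paste0(g, ".fasta")),
                 annotation = file.path(src, paste0(g, "_segments.tsv")),
                 gene_id = g))
gm <- genotype_matrix(alns)
popv <- samples$population_id[match(gm$sample_id, samples$sample_id)]
lon <- stats::setNames(samples$longitude[!duplicated(samples$population_id)],
                       samples$population_id[!duplicated(samples$population_id)])
freq <- snp_frequency_table(gm$dosage, popv, lon)

clim_vars <- c("temp_spring", "temp_summer", "prec_spring", "prec_summer")
sig_k <- matrix("", nrow(gm$meta), length(clim_vars),
                dimnames = list(NULL, clim_vars))
for (K in 2:5) {
  q <- simulate_qmatrix(popv, K = K, admixture = 0.3, seed = seed + K)
  for (v in clim_vars) {
    clim <- samples[[v]][match(gm$sample_id, samples$sample_id)]
    res <- associate(gm$dosage, clim, q, popv, permutations = perms,
                     seed = seed + K, n_tests = length(clim_vars))
    hit <- which(res$significant)
    if (length(hit))
      sig_k[hit, v] <- ifelse(sig_k[hit, v] == "", K,
                              paste(sig_k[hit, v], K, sep = ","))
  }
}
report <- cbind(gm$meta, round(freq, 2), sig_k)
utils::write.table(report, file.path(out, "association.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

n_sig <- sum(apply(sig_k != "", 1, any))
cat("SNPs tested:", nrow(gm$meta), "| significant for any variable/K:",
    n_sig, "\n")
if (n_sig > 0) {
  cat("significant SNPs (gene, position, variable, K):\n")
  idx <- which(apply(sig_k != "", 1, any))
  print(cbind(gm$meta[idx, c("gene", "position", "type")],
              sig_k[idx, , drop = FALSE]))
}
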