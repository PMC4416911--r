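#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study -- 10 populations (5 H + 5 L) of 6
# diploid individuals along a west-east transect, 19 gene regions (15 with
# an intron), under a constant-size island model with less gene flow into
# H-populations.  Writes the true phased alignments, outgroups and sample
# metadata under results/study/.

suppressPackageStartupMessages(library(altipop))

out <- "results/study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240915

study <- simulate_study(study_design(), demographic_model("CON", N_C = 5000),
                        mu = 2e-7, migration = list(H = NULL, L = NULL),
                        seed = seed)
# plant one intermediate-frequency SNP-climate association so stage 6 has a
# positive control
gm <- genotype_matrix(study$alignments[[1]])
maf <- colMeans(gm$dosage, na.rm = TRUE) / 2
pos <- gm$meta$position[which(maf > 0.1 & maf < 0.9)[1]]
study <- plant_association(study, names(study$alignments)[1],
                           pos, climate_var = "prec_spring",
                           beta = 0.8, seed = seed + 1)

write_samples(study$samples, file.path(out, "samples.tsv"))
for (g in names(study$alignments)) {
  write_alignment(study$alignments[[g]],
                  file.path(out, paste0(g, ".fasta")),
                  outgroup = study$outgroups[[g]])
  utils::write.table(study$alignments[[g]]$gene$segments,
                     file.path(out, paste0(g, "_segments.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
n_seg <- sum(vapply(study$alignments, function(a)
  length(segregating_sites(a, effective_sites(a, "all"))), numeric(1)))
cat("simulated", length(study$alignments), "gene alignments,",
    nrow(study$samples), "individuals;", n_seg, "segregating sites\n")
cat("planted association:", study$truth$planted$gene,
    "position", study$truth$planted$position, "\n")
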