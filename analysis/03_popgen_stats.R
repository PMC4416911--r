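#!/usr/bin/env Rscript
# Stage 3: per-gene diversity/selection statistics from the called phased
# alignments (whole-region ZZ and haplotype diversity; intronic L_eff, S,
# pi, theta_W, Tajima's D, divergence; MK and DoS on the coding sequence),
# plus Hudson F_ST and Jost D_est matrices and the H-vs-L contrasts.

suppressPackageStartupMessages(library(altipop))

src <- "results/study"
called_dir <- "results/called"
out <- "results/popgen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

samples <- read_samples(file.path(src, "samples.tsv"))
genes <- sort(sub("_segments\\.tsv$", "",
                  basename(list.files(src, pattern = "_segments\\.tsv$"))))
alns <- list(); outgroups <- character()
for (g in genes) {
  alns[[g]] <- read_alignment(file.path(called_dir, paste0(g, ".fasta")),
                              annotation = file.path(src,
                                                     paste0(g,
                                                            "_segments.tsv")),
                              gene_id = g)
  og <- read_alignment(file.path(src, paste0(g, ".fasta")),
                       gene_id = g, outgroup_id = "outgroup")
  outgroups[g] <- attr(og, "outgroup")
}

summaries <- lapply(genes, function(g) gene_summary(alns[[g]], outgroups[g]))
tab <- write_gene_summary_table(summaries, file.path(out, "gene_summary.tsv"))
cat("per-gene summary ('All genes' row):\n")
print(tab[nrow(tab), c("n", "L", "L_eff", "S", "pi", "theta_w", "tajima_d")])

pops <- samples$population_id[match(alns[[1]]$sample_id, samples$sample_id)]
fst_res <- altipop:::.combined_fst(alns, pops)
dest_res <- d_est(alns, pops)
write_matrix_tsv(round(fst_res$matrix, 5), file.path(out, "fst.tsv"))
write_matrix_tsv(round(dest_res$matrix, 5), file.path(out, "dest.tsv"))

cls <- stats::setNames(samples$altitude_class[!duplicated(samples$population_id)],
                       samples$population_id[!duplicated(samples$population_id)])
for (nm in c("fst", "dest")) {
  m <- if (nm == "fst") fst_res$matrix else dest_res$matrix
  hl <- compare_groups(class_pairs(m, cls, "H"), class_pairs(m, cls, "L"))
  cat(sprintf("%s: overall %.3f | H-pairs %.3f vs L-pairs %.3f (W = %s, P = %.4f)\n",
              toupper(nm),
              if (nm == "fst") fst_res$overall else dest_res$overall,
              hl$mean_H, hl$mean_L, format(hl$W), hl$p_value))
}
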