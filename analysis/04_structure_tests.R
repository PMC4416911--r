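#!/usr/bin/env Rscript
# Stage 4: structure hypothesis tests -- Mantel isolation-by-distance (raw
# and ln), the ancestry-asymmetry randomization test on a synthetic
# ancestry matrix, the Evanno delta-K utility on a synthetic likelihood
# trace, and diversity-longitude rank correlations within the H class.

suppressPackageStartupMessages(library(altipop))

src <- "results/study"
out <- "results/structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240915

samples <- read_samples(file.path(src, "samples.tsv"))
pops <- samples[!duplicated(samples$population_id),
                c("population_id", "altitude_class", "latitude", "longitude",
                  "elevation")]
fst_m <- as.matrix(utils::read.delim("results/popgen/fst.tsv",
                                     row.names = 1, check.names = FALSE))
geo <- geo_distance_matrix(pops)

rows <- NULL
for (tr in c("raw", "ln")) {
  mt <- mantel_ibd(fst_m, geo, permutations = 10000, transform = tr,
                   seed = seed + 3)
  rows <- rbind(rows, data.frame(test = paste0("mantel_", tr),
                                 statistic = round(mt$r, 4),
                                 p_value = signif(mt$p_value, 4)))
}

# ancestry stand-in for an external clustering run (K = 2)
q <- simulate_qmatrix(samples$population_id, K = 2, admixture = 0.3,
                      seed = seed + 4)
rownames(q) <- samples$sample_id
write_qmatrix(round(q, 8), file.path(out, "qmatrix_K2.tsv"))
asym <- ancestry_asymmetry_test(q[, 1], samples$altitude_class,
                                n_randomizations = 10000, seed = seed + 5)
rows <- rbind(rows, data.frame(test = "ancestry_asymmetry",
                               statistic = round(asym$observed_difference, 4),
                               p_value = signif(asym$p_value, 4)))

# synthetic likelihood trace with a plateau at K = 2
set.seed(seed + 6)
trace <- do.call(rbind, lapply(1:6, function(k)
  data.frame(K = k, logL = c(-5000, -4200, -4150, -4140, -4135, -4133)[k] +
               stats::rnorm(10, 0, 15))))
dk <- evanno_delta_k(trace)
rows <- rbind(rows, data.frame(test = "evanno_best_K",
                               statistic = dk$K[which.max(dk$delta_k)],
                               p_value = NA))

# per-population Watterson theta vs longitude among H populations
genes <- sort(sub("_segments\\.tsv$", "",
                  basename(list.files(src, pattern = "_segments\\.tsv$"))))
h_pops <- pops$population_id[pops$altitude_class == "H"]
theta_pop <- vapply(h_pops, function(p) {
  ids <- samples$sample_id[samples$population_id == p]
  mean(vapply(genes[1:5], function(g) {
    a <- read_alignment(file.path("results/called", paste0(g, ".fasta")),
                        annotation = file.path(src, paste0(g, "_segments.tsv")),
                        gene_id = g)
    keep <- a$sample_id %in% ids
    sub <- hap_alignment(a$mat[keep, , drop = FALSE], a$gene,
                         sample_id = a$sample_id[keep],
                         phase_index = a$phase_index[keep])
    eff <- effective_sites(sub, "all")
    S <- length(segregating_sites(sub, eff))
    watterson_theta(S, sub$n, max(1, length(eff)))
  }, numeric(1)))
}, numeric(1))
ct <- rank_correlations(theta_pop,
                        pops$longitude[match(h_pops, pops$population_id)],
                        z = pops$elevation[match(h_pops, pops$population_id)])
rows <- rbind(rows,
              data.frame(test = "spearman_thetaW_longitude_H",
                         statistic = round(ct$rho, 4),
                         p_value = signif(ct$p_value, 4)),
              data.frame(test = "partial_thetaW_longitude_H",
                         statistic = round(ct$partial_rho, 4),
                         p_value = signif(ct$partial_p, 4)))

utils::write.table(rows, file.path(out, "structure_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(rows)
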