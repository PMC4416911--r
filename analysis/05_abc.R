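#!/usr/bin/env Rscript
# Stage 5: ABC demographic inference on the called intronic data --
# reference tables under the four demographic models, rejection at 0.5%,
# regression-adjusted posteriors for the winning model, model-choice power
# from PODs, and kernel-corrected posterior probabilities (bandwidth 0.1).
# Table sizes here are scaled down from the million-row production setting;
# raise n_sims/n_pods for production runs.

suppressPackageStartupMessages(library(altipop))

src <- "results/study"
out <- "results/abc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240915
n_sims <- 5000L
retention <- 0.02
n_pods <- 100L

genes <- sort(sub("_segments\\.tsv$", "",
                  basename(list.files(src, pattern = "_segments\\.tsv$"))))
alns <- lapply(genes, function(g)
  read_alignment(file.path("results/called", paste0(g, ".fasta")),
                 annotation = file.path(src, paste0(g, "_segments.tsv")),
                 gene_id = g))
names(alns) <- genes
intronic <- Filter(function(g)
  sum(alns[[g]]$gene$segments$kind == "intron") > 0, genes)
obs <- altipop:::.observed_summary(alns[intronic])
cat(sprintf("observed intronic summaries over %d loci: mean S = %.2f, mean pi = %.5f\n",
            length(intronic), obs$summary["mean_S"], obs$summary["mean_pi"]))

priors <- prior_spec()
models <- c("CON", "BOT", "EXP", "RED")
tables <- lapply(models, function(kind)
  build_reference_table(kind, priors, obs$loci, n_sims,
                        seed = seed + 10 + match(kind, models)))
names(tables) <- models

mc <- model_choice(obs$summary, tables, retention)
pw <- power_analysis(tables, priors, obs$loci, n_pods = n_pods,
                     retention_fraction = retention, seed = seed + 20)
cc <- kernel_corrected_pp(mc$pp, pw$pod_pp, bandwidth = 0.1)
mc$power <- pw$power[mc$model]
mc$pp_corrected <- cc[mc$model]
utils::write.table(transform(mc, md = signif(md, 5), pp = signif(pp, 5),
                             pp_corrected = signif(pp_corrected, 5)),
                   file.path(out, "model_choice.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(mc[, c("model", "fit_p", "pp", "power", "pp_corrected")])

best <- mc$model[which.max(mc$pp)]
ret <- abc_reject(obs$summary, tables[[best]], retention)
post <- regression_adjust(tables[[best]], ret, obs$summary)
post_sum <- do.call(rbind, lapply(names(post), function(p) {
  ps <- posterior_summary(post[[p]], log_scale = all(post[[p]] > 0))
  data.frame(parameter = p, mode = signif(ps$mode, 5),
             hpd_low = signif(ps$hpd[1], 5), hpd_high = signif(ps$hpd[2], 5))
}))
utils::write.table(post_sum, file.path(out, "posterior.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("best model:", best, "\n")
print(post_sum)
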