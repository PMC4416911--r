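# End-to-end driver: simulate a study, sequence and re-call it, compute the
# per-gene statistics, differentiation and structure tests, run ABC model
# choice, and test SNP-climate associations -- all from one config and seed,
# with byte-identical outputs on rerun.

#' Default pipeline configuration
#'
#' Study-scale defaults (10 populations x 6 diploids, 19 genes).  Every
#' entry can be overridden by the `config` argument of [run_pipeline()] or
#' by a YAML file read with [read_config()].
#'
#' @return Nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    design = list(n_populations = 10L, individuals_per_population = 6L,
                  n_genes = 19L, n_intron_genes = 15L, gene_length = 780L),
    demography = list(kind = "CON", N_C = 5000),
    mu = 2e-7,
    migration = list(H = NULL, L = NULL),
    reads = list(coverage = 20, read_length = 250L, f_M = 0.024),
    calling = list(min_depth = 5L, minor_fraction = 0.3),
    plant = list(enabled = TRUE, beta = 0.8, climate_var = "prec_spring"),
    abc = list(n_sims = 2000L, retention = 0.05,
               models = c("CON", "BOT", "EXP", "RED")),
    association = list(permutations = 10000L, K = 2L,
                       climate_var = "prec_spring", n_tests = 4L),
    mantel_permutations = 10000L
  )
}

#' Read a YAML pipeline configuration
#'
#' Values present in the file override [default_config()].
#'
#' @param path YAML file.
#' @return Merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulation -> read generation -> variant calling/phasing -> per-gene
#' statistics -> differentiation and structure tests -> ABC model choice ->
#' SNP-climate association.  All outputs are plain-text TSV/FASTA under
#' `out_dir`; a fixed seed makes the whole run reproducible byte for byte.
#'
#' @param config Configuration list (see [default_config()]); partial lists
#'   are merged over the defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("pipeline seed:", cfg$seed, "\n", file = log_path)
  logmsg <- function(...) cat(..., "\n", file = log_path, append = TRUE)

  design <- do.call(study_design, cfg$design)
  model <- do.call(demographic_model, cfg$demography)
  study <- simulate_study(design, model, mu = cfg$mu,
                          migration = cfg$migration, seed = cfg$seed)

  if (isTRUE(cfg$plant$enabled)) {
    g1 <- names(study$alignments)[1L]
    cand <- genotype_matrix(study$alignments[[g1]])
    if (!is.null(cand$meta) && nrow(cand$meta) > 0L) {
      maf <- colMeans(cand$dosage, na.rm = TRUE) / 2
      mid <- which(maf > 0.1 & maf < 0.9)
      pos <- cand$meta$position[if (length(mid)) mid[1L] else 1L]
      study <- plant_association(study, g1, pos,
                                 climate_var = cfg$plant$climate_var,
                                 beta = cfg$plant$beta, seed = cfg$seed + 1L)
      logmsg("planted association at", g1, "position", pos)
    } else logmsg("no segregating SNP available to plant")
  }

  write_samples(study$samples, file.path(out_dir, "samples.tsv"))
  for (g in names(study$alignments))
    write_alignment(study$alignments[[g]],
                    file.path(out_dir, paste0("truth_", g, ".fasta")),
                    outgroup = study$outgroups[[g]])

  # --- sequencing + variant calling -------------------------------------
  set.seed(cfg$seed + 2L)
  emodel <- error_model(cfg$reads$f_M, cfg$calling$min_depth,
                        cfg$calling$minor_fraction)
  ids <- unique(study$samples$sample_id)
  called <- list()
  n_fail <- 0L
  for (g in names(study$alignments)) {
    aln <- study$alignments[[g]]
    mat <- aln$mat
    out_mat <- matrix(NA_character_, 0L, aln$gene$length)
    sub_seed <- sample.int(.Machine$integer.max - 1L, length(ids))
    for (i in seq_along(ids)) {
      rows <- which(aln$sample_id == ids[i])
      h1 <- paste(mat[rows[1L], ], collapse = "")
      h2 <- paste(mat[rows[2L], ], collapse = "")
      pu <- simulate_reads(h1, h2, cfg$reads$coverage, cfg$reads$read_length,
                           cfg$reads$f_M, seed = sub_seed[i],
                           gene_id = g, sample_id = ids[i])
      pair <- tryCatch(call_genotype(pu, emodel, seed = sub_seed[i]),
                       error = function(e) e)
      if (inherits(pair, "error")) {
        # unresolvable assembly: fall back to its majority consensus
        n_fail <- n_fail + 1L
        logmsg("assembly", g, ids[i], "failed:", conditionMessage(pair))
        cons <- build_consensus(pu, call_sites(pu, emodel)[0, ],
                                list(alleles = matrix(character(), 2L, 0L),
                                     phase_gap_resolved = FALSE))
        pair <- cons
      }
      out_mat <- rbind(out_mat, strsplit(pair$seq1, "")[[1L]],
                       strsplit(pair$seq2, "")[[1L]])
    }
    rownames(out_mat) <- as.vector(t(outer(ids, 1:2, function(s, p)
      sprintf("%s_%d", s, p))))
    called[[g]] <- hap_alignment(out_mat, study$alignments[[g]]$gene,
                                 sample_id = rep(ids, each = 2L),
                                 phase_index = rep(1:2, length(ids)))
    write_alignment(called[[g]],
                    file.path(out_dir, paste0("called_", g, ".fasta")))
  }
  logmsg("assemblies failing phasing:", n_fail)

  # --- per-gene statistics ----------------------------------------------
  summaries <- lapply(names(called), function(g)
    gene_summary(called[[g]], study$outgroups[[g]], seed = cfg$seed))
  write_gene_summary_table(summaries, file.path(out_dir, "gene_summary.tsv"))

  pop_of_hap <- study$samples$population_id[
    match(called[[1L]]$sample_id, study$samples$sample_id)]
  fst_res <- .combined_fst(called, pop_of_hap)
  write_matrix_tsv(round(fst_res$matrix, 5L), file.path(out_dir, "fst.tsv"))
  dest_res <- d_est(called, pop_of_hap)
  write_matrix_tsv(round(dest_res$matrix, 5L), file.path(out_dir, "dest.tsv"))

  # --- structure tests ---------------------------------------------------
  geo <- geo_distance_matrix(study$populations)
  mant <- mantel_ibd(fst_res$matrix, geo,
                     permutations = cfg$mantel_permutations,
                     seed = cfg$seed + 3L)
  q <- simulate_qmatrix(study$samples$population_id, K = cfg$association$K,
                        seed = cfg$seed + 4L)
  asym <- ancestry_asymmetry_test(q[, 1L], study$samples$altitude_class,
                                  seed = cfg$seed + 5L)
  class_of <- stats::setNames(study$populations$altitude_class,
                              study$populations$population_id)
  hl <- compare_groups(class_pairs(fst_res$matrix, class_of, "H"),
                       class_pairs(fst_res$matrix, class_of, "L"))
  struct <- data.frame(
    test = c("mantel_fst_geo", "ancestry_asymmetry", "fst_H_vs_L"),
    statistic = round(c(mant$r, asym$observed_difference, hl$W), 5L),
    p_value = signif(c(mant$p_value, asym$p_value, hl$p_value), 5L))
  utils::write.table(struct, file.path(out_dir, "structure_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- ABC model choice --------------------------------------------------
  intronic <- Filter(function(g) sum(called[[g]]$gene$segments$kind ==
                                       "intron") > 0, names(called))
  obs <- .observed_summary(called[intronic])
  loci <- obs$loci
  priors <- prior_spec()
  tables <- lapply(cfg$abc$models, function(kind)
    build_reference_table(kind, priors, loci, cfg$abc$n_sims,
                          seed = cfg$seed + 10L + match(kind, cfg$abc$models)))
  names(tables) <- cfg$abc$models
  mc <- model_choice(obs$summary, tables, cfg$abc$retention)
  utils::write.table(transform(mc, md = signif(md, 5L), pp = signif(pp, 5L)),
                     file.path(out_dir, "abc_model_choice.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  best <- mc$model[which.max(mc$pp)]
  ret <- abc_reject(obs$summary, tables[[best]], cfg$abc$retention)
  post <- regression_adjust(tables[[best]], ret, obs$summary)
  if (nrow(post) >= 100L) {
    post_sum <- do.call(rbind, lapply(names(post), function(p) {
      ps <- posterior_summary(post[[p]], log_scale = all(post[[p]] > 0))
      data.frame(parameter = p, mode = signif(ps$mode, 5L),
                 hpd_low = signif(ps$hpd[1L], 5L),
                 hpd_high = signif(ps$hpd[2L], 5L))
    }))
    utils::write.table(post_sum, file.path(out_dir, "abc_posterior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else logmsg("retained sample too small for posterior summaries")

  # --- association -------------------------------------------------------
  gm <- genotype_matrix(called)
  clim <- study$samples[[cfg$association$climate_var]][
    match(gm$sample_id, study$samples$sample_id)]
  pop_of_ind <- study$samples$population_id[
    match(gm$sample_id, study$samples$sample_id)]
  assoc <- associate(gm$dosage, clim, q, pop_of_ind,
                     permutations = cfg$association$permutations,
                     seed = cfg$seed + 6L,
                     n_tests = cfg$association$n_tests)
  freq <- snp_frequency_table(gm$dosage, pop_of_ind,
                              stats::setNames(study$populations$longitude,
                                              study$populations$population_id))
  assoc_out <- cbind(gm$meta, round(freq, 2L),
                     transform(assoc, beta = round(beta, 4L),
                               t = round(t, 4L)))
  utils::write.table(assoc_out, file.path(out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(study = study, called = called, summaries = summaries,
                 fst = fst_res, d_est = dest_res, structure = struct,
                 model_choice = mc, posterior = post, association = assoc_out))
}

# Multi-gene F_ST: per-gene Hudson estimates averaged over genes
# (pairwise and overall).
.combined_fst <- function(alns, populations) {
  per <- lapply(alns, function(a) fst(a, populations))
  mats <- lapply(per, `[[`, "matrix")
  mat <- Reduce(`+`, lapply(mats, function(m) {
    m[is.na(m)] <- 0; m
  })) / Reduce(`+`, lapply(mats, function(m) (!is.na(m)) * 1))
  ov <- mean(vapply(per, `[[`, numeric(1L), "overall"), na.rm = TRUE)
  list(matrix = mat, overall = ov, per_gene = per)
}

# Observed across-loci summary vector (intronic S and pi) plus the matching
# locus configuration.
.observed_summary <- function(alns) {
  S <- pi <- n <- L <- numeric(length(alns))
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    eff <- effective_sites(a, "intron")
    S[i] <- length(segregating_sites(a, eff))
    p <- nucleotide_diversity(a, eff)
    pi[i] <- if (is.na(p)) 0 else p
    n[i] <- a$n; L[i] <- max(1L, length(eff))
  }
  list(summary = summary_vector(S, pi), loci = locus_config(n, L),
       S = S, pi = pi)
}
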