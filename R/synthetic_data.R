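# Synthetic-data generators that stand in for the field data: a structured
# (finite-island) coalescent producing phased multi-population alignments, a
# read simulator for the variant caller, climate covariates along a
# west-east transect, ancestry matrices, and planted SNP-climate effects.
# Every generator records its truth so recovery can be tested.

#' Study design description
#'
#' Defaults mirror a two-altitude-class transect survey: 10 populations
#' (5 H + 5 L, interleaved west to east) of 6 diploid individuals, 19 gene
#' regions of which 15 contain an intron.
#'
#' @param n_populations Number of populations (even: alternating H/L pairs).
#' @param individuals_per_population Diploid individuals per population.
#' @param n_genes Total gene regions.
#' @param n_intron_genes How many carry an intron.
#' @param gene_length Alignment length per gene (bp; divisible by 3).
#' @param elevation_H,elevation_L Mean elevations (m) of the two classes.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_populations = 10L, individuals_per_population = 6L,
                         n_genes = 19L, n_intron_genes = 15L,
                         gene_length = 780L,
                         elevation_H = 2300, elevation_L = 1400) {
  stopifnot(n_populations %% 2L == 0L, n_intron_genes <= n_genes,
            gene_length %% 3L == 0L)
  structure(list(n_populations = n_populations,
                 individuals_per_population = individuals_per_population,
                 n_genes = n_genes, n_intron_genes = n_intron_genes,
                 gene_length = gene_length,
                 elevation_H = elevation_H, elevation_L = elevation_L),
            class = "study_design")
}

# Structured (finite-island) coalescent for one locus: returns per-edge
# durations and descendant leaf sets.  `deme_of` assigns each of the n
# lineages to a deme; `mig` is the per-lineage per-generation migration rate
# by deme; sizes follow the (shared) trajectory `traj` per deme.
.sim_structured_tree <- function(deme_of, mig_of_deme, traj) {
  n <- length(deme_of)
  leaves <- lapply(seq_len(n), function(i) i)
  deme <- deme_of
  birth <- numeric(n)
  t <- 0
  edges <- list()
  while (length(leaves) > 1L) {
    kd <- table(deme)
    pairs <- sum(kd * (kd - 1) / 2)
    mig_rates <- mig_of_deme[deme]
    ev <- .next_event(t, pairs, traj, extra = sum(mig_rates))
    t <- ev$t
    if (ev$coal && pairs > 0) {
      dsel <- sample(names(kd), 1L, prob = kd * (kd - 1) / 2)
      cand <- which(deme == dsel)
      pick <- cand[sample.int(length(cand), 2L)]
      for (i in pick)
        edges[[length(edges) + 1L]] <- list(dur = t - birth[i],
                                            leaves = leaves[[i]])
      merged <- c(leaves[[pick[1L]]], leaves[[pick[2L]]])
      leaves[pick] <- NULL
      deme <- deme[-pick]; birth <- birth[-pick]
      leaves[[length(leaves) + 1L]] <- merged
      deme <- c(deme, dsel); birth <- c(birth, t)
    } else {
      li <- sample.int(length(deme), 1L, prob = mig_rates)
      demes <- unique(names(mig_of_deme))
      deme[li] <- sample(setdiff(demes, deme[li]), 1L)
    }
  }
  edges
}

# Place infinite-sites mutations on edges over L discrete positions (distinct
# positions per mutation) and build the haplotype matrix from a random
# ancestral sequence.
.edges_to_alignment <- function(edges, n, L, mu, divergence = 0.27) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  counts <- stats::rpois(length(edges),
                         mu * L * vapply(edges, `[[`, numeric(1L), "dur"))
  total <- sum(counts)
  if (total > L) stop("mutation count exceeds locus length; lower mu or L")
  pos <- sample.int(L, total)
  mat <- matrix(rep(anc, each = n), nrow = n)
  p <- 0L
  for (i in seq_along(edges)) {
    if (counts[i] == 0L) next
    for (j in seq_len(counts[i])) {
      p <- p + 1L
      at <- pos[p]
      derived <- sample(setdiff(bases, anc[at]), 1L)
      mat[edges[[i]]$leaves, at] <- derived
    }
  }
  flip <- stats::runif(L) < divergence
  og <- anc
  og[flip] <- vapply(which(flip), function(i)
    sample(setdiff(bases, anc[i]), 1L), character(1L))
  list(mat = mat, outgroup = paste(og, collapse = ""), ancestral = anc)
}

.gene_annotation <- function(design, g) {
  L <- design$gene_length
  if (g <= design$n_intron_genes) {
    third <- L %/% 3L
    segs <- data.frame(kind = c("exon", "intron", "exon"),
                       start = c(1L, third + 1L, 2L * third + 1L),
                       end = c(third, 2L * third, L))
  } else {
    segs <- data.frame(kind = "exon", start = 1L, end = L)
  }
  gene_region(sprintf("gene%02d", g), L, segs, outgroup_id = "outgroup")
}

#' Simulate a full multi-population study
#'
#' Per gene, a finite-island structured coalescent (shared size trajectory,
#' class-specific migration so H-populations can receive less gene flow)
#' generates two haplotypes per individual in every population; sample
#' metadata places populations on a synthetic west-east transect with
#' seasonal climate means: temperature decreases linearly with elevation
#' (plus noise), precipitation is independent of elevation.
#'
#' @param design A [study_design()].
#' @param model A [demographic_model()] describing the metapopulation; each
#'   deme follows the model's size trajectory divided by the number of
#'   populations, so the total size (and hence the diversity scale) matches
#'   the model.
#' @param mu Mutation rate per site per generation.
#' @param migration Named list `H`, `L`: per-lineage per-generation
#'   migration rates for demes of each class (lower `H` mimics restricted
#'   gene flow at the upper range margin).  Defaults give `4 N_deme m` of 2
#'   for H and 8 for L demes.
#' @param seed Integer seed.
#' @param divergence Expected per-site outgroup divergence (default 0.27).
#' @return List with `alignments` (per gene [hap_alignment()]s),
#'   `outgroups`, `samples` (metadata data frame), `truth`.
#' @export
simulate_study <- function(design = study_design(),
                           model = demographic_model("CON", N_C = 5000),
                           mu = 2e-7,
                           migration = list(H = NULL, L = NULL),
                           seed = 1L, divergence = 0.27) {
  set.seed(seed)
  P <- design$n_populations
  I <- design$individuals_per_population
  n <- 2L * P * I
  traj <- size_trajectory(model)
  traj$N <- traj$N / P                       # per-deme share of the total
  # default scaled migration: 4 N_deme m = 2 (H) and 8 (L)
  N0 <- traj$N[1L]
  if (is.null(migration$H)) migration$H <- 2 / (4 * N0)
  if (is.null(migration$L)) migration$L <- 8 / (4 * N0)
  pops <- sprintf("pop%02d", seq_len(P))
  class_of <- stats::setNames(rep(c("H", "L"), P / 2L), pops)
  mig_of_deme <- stats::setNames(
    ifelse(class_of == "H", migration$H, migration$L), pops)
  sample_ids <- as.vector(t(outer(pops, seq_len(I),
                                  function(p, i) sprintf("%s_ind%d", p, i))))
  pop_of_ind <- rep(pops, each = I)
  deme_of <- rep(pop_of_ind, each = 2L)
  alignments <- list(); outgroups <- character(design$n_genes)
  truth_haps <- list()
  for (g in seq_len(design$n_genes)) {
    gene <- .gene_annotation(design, g)
    edges <- .sim_structured_tree(deme_of, mig_of_deme, traj)
    sim <- .edges_to_alignment(edges, n, gene$length, mu, divergence)
    rn <- as.vector(t(outer(sample_ids, 1:2,
                            function(s, p) sprintf("%s_%d", s, p))))
    rownames(sim$mat) <- rn
    alignments[[gene$gene_id]] <- hap_alignment(sim$mat, gene,
      sample_id = rep(sample_ids, each = 2L),
      phase_index = rep(1:2, times = length(sample_ids)))
    outgroups[g] <- sim$outgroup
    truth_haps[[gene$gene_id]] <- sim$mat
  }
  names(outgroups) <- names(alignments)
  # transect metadata: longitude increases west to east, one pair per step
  lon <- 10.5 + (rep(seq_len(P / 2L), each = 2L) - 1L) * 0.25 +
    stats::runif(P, 0, 0.08)
  lat <- 46.2 + stats::rnorm(P, 0, 0.05)
  elev <- ifelse(class_of == "H", design$elevation_H, design$elevation_L) +
    stats::rnorm(P, 0, 120)
  temp_spring <- 14 - 5 * elev / 1000 + stats::rnorm(P, 0, 0.4)
  temp_summer <- 22 - 6 * elev / 1000 + stats::rnorm(P, 0, 0.4)
  prec_spring <- stats::runif(P, 210, 280)
  prec_summer <- stats::runif(P, 225, 350)
  pop_meta <- data.frame(population_id = pops, altitude_class = class_of,
                         latitude = lat, longitude = lon, elevation = elev,
                         temp_spring = temp_spring, temp_summer = temp_summer,
                         prec_spring = prec_spring, prec_summer = prec_summer,
                         row.names = NULL)
  samples <- cbind(data.frame(sample_id = sample_ids),
                   pop_meta[match(pop_of_ind, pops), , drop = FALSE])
  rownames(samples) <- NULL
  list(alignments = alignments, outgroups = outgroups, samples = samples,
       populations = pop_meta,
       truth = list(haplotypes = truth_haps, model = model, mu = mu,
                    migration = migration, seed = seed))
}

#' Simulate an amplicon read pileup from a phased pair
#'
#' Reads are drawn from the two haplotypes with equal probability, start
#' uniformly, and carry independent per-base substitution errors at rate
#' `f_M`.  The read count is chosen so the mean per-site depth equals
#' `coverage`.
#'
#' @param seq1,seq2 The individual's two haplotype sequences (strings).
#' @param coverage Target mean per-site depth.
#' @param read_length Read length in bp.
#' @param f_M Per-base substitution error rate.
#' @param seed Integer seed.
#' @param gene_id,sample_id Identifiers for the pileup.
#' @param balanced Assign reads to the two haplotypes alternately along the
#'   start-sorted order instead of at random, so local depth is split almost
#'   exactly 50/50 (used for noiseless round-trip checks; real amplicon
#'   sampling is the random default).
#' @return A [read_pileup()].
#' @export
simulate_reads <- function(seq1, seq2, coverage = 20, read_length = 250L,
                           f_M = 0.024, seed = 1L,
                           gene_id = "gene", sample_id = "ind",
                           balanced = FALSE) {
  set.seed(seed)
  stopifnot(coverage >= 1)
  h <- rbind(strsplit(toupper(seq1), "")[[1L]], strsplit(toupper(seq2), "")[[1L]])
  L <- ncol(h)
  read_length <- min(read_length, L)
  # reads may overhang either end (and are clipped), so every position has
  # the same expected depth = coverage
  n_span <- L + read_length - 1L
  n_reads <- max(1L, round(coverage * n_span / read_length))
  starts <- sample.int(n_span, n_reads, replace = TRUE) - read_length + 1L
  hap <- if (balanced) rep(1:2, length.out = n_reads)[order(order(starts))] else
    sample.int(2L, n_reads, replace = TRUE)
  bases <- character(n_reads)
  for (i in seq_len(n_reads)) {
    from <- max(1L, starts[i])
    to <- min(L, starts[i] + read_length - 1L)
    starts[i] <- from
    b <- h[hap[i], from:to]
    err <- stats::runif(length(b)) < f_M & b %in% c("A", "C", "G", "T")
    if (any(err))
      b[err] <- vapply(b[err], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
    bases[i] <- paste(b, collapse = "")
  }
  read_pileup(gene_id, sample_id,
              data.frame(read_id = sprintf("read%04d", seq_len(n_reads)),
                         start = starts, bases = bases),
              gene_length = L)
}

#' Synthetic ancestry (Q) matrix reflecting population structure
#'
#' Populations are split into `K` contiguous cluster groups along their
#' order; each individual's ancestry vector is its population's cluster
#' profile perturbed by gamma noise and renormalized.
#'
#' @param populations Population id per individual.
#' @param K Number of clusters.
#' @param admixture Noise level in `[0, 1)` (0 = crisp assignment).
#' @param seed Integer seed.
#' @return Individuals x K matrix of ancestry proportions (rows sum to 1).
#' @export
simulate_qmatrix <- function(populations, K = 2L, admixture = 0.2, seed = 1L) {
  set.seed(seed)
  pops <- unique(populations)
  grp <- ceiling(seq_along(pops) / (length(pops) / K))
  base <- matrix(admixture / K, length(pops), K)
  base[cbind(seq_along(pops), grp)] <- 1 - admixture + admixture / K
  q <- t(vapply(seq_along(populations), function(i) {
    b <- base[match(populations[i], pops), ]
    g <- stats::rgamma(K, shape = b * 20)
    g / sum(g)
  }, numeric(K)))
  rownames(q) <- names(populations)
  colnames(q) <- sprintf("Q%d", seq_len(K))
  q
}

#' Plant a SNP-climate association into a simulated study
#'
#' Reassigns the alleles at one chosen segregating site so the individual
#' minor-allele dosage correlates with a population-level climate variable
#' at effect size `beta` (the fraction of dosage variance explained by the
#' latent climate score), while preserving the overall minor-allele count
#' exactly.
#'
#' @param study Output of [simulate_study()].
#' @param gene Gene id of the target SNP.
#' @param position Alignment position of the target SNP (must be biallelic
#'   segregating).
#' @param climate_var Column of `study$samples` to associate with.
#' @param beta Effect size in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified study; `truth$planted` lists the planted SNPs.
#' @export
plant_association <- function(study, gene, position,
                              climate_var = "prec_spring", beta = 0.8,
                              seed = 1L) {
  set.seed(seed)
  aln <- study$alignments[[gene]]
  if (is.null(aln)) stop("unknown gene ", gene)
  col <- aln$mat[, position]
  ok <- col %in% c("A", "C", "G", "T")
  tab <- sort(table(col[ok]), decreasing = TRUE)
  if (length(tab) != 2L)
    stop("position ", position, " is not a biallelic segregating site")
  major <- names(tab)[1L]; minor <- names(tab)[2L]
  M <- as.integer(tab[2L])
  if (beta > 0) {
    ids <- unique(aln$sample_id)
    clim <- study$samples[[climate_var]][match(ids, study$samples$sample_id)]
    z <- scale(clim)[, 1L]
    latent <- sqrt(beta) * z + sqrt(1 - beta) * stats::rnorm(length(ids))
    slot_latent <- rep(latent, each = 2L) + stats::rnorm(2L * length(ids), 0, 1e-3)
    slot_rows <- unlist(lapply(ids, function(id) which(aln$sample_id == id)))
    new_col <- rep(major, aln$n)
    carriers <- slot_rows[order(slot_latent, decreasing = TRUE)][seq_len(M)]
    new_col[carriers] <- minor
    new_col[!ok] <- col[!ok]                    # keep missing/gap states
    if (abs(sum(new_col == minor) - M) / M > 0.05)
      stop("requested effect infeasible at this frequency")
    aln$mat[, position] <- new_col
    study$alignments[[gene]] <- aln
    study$truth$haplotypes[[gene]][, position] <- new_col
  }
  study$truth$planted <- rbind(study$truth$planted,
                               data.frame(gene = gene, position = position,
                                          climate_var = climate_var,
                                          beta = beta))
  study
}
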