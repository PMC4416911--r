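# Generators: structured study simulation, read simulation, ancestry
# matrices, planted associations.

small_design <- function() study_design(n_populations = 4L,
                                        individuals_per_population = 3L,
                                        n_genes = 3L, n_intron_genes = 2L,
                                        gene_length = 300L)

test_that("study simulation is deterministic and well-formed", {
  s1 <- simulate_study(small_design(), demographic_model("CON", N_C = 2000),
                       seed = 21)
  s2 <- simulate_study(small_design(), demographic_model("CON", N_C = 2000),
                       seed = 21)
  expect_identical(s1$alignments[[1]]$mat, s2$alignments[[1]]$mat)
  expect_identical(s1$samples, s2$samples)
  expect_equal(nrow(s1$samples), 12)
  expect_equal(s1$alignments[[1]]$n, 24)
  expect_setequal(unique(s1$samples$altitude_class), c("H", "L"))
  # every alignment passes the container validators on write/read round trip
  path <- tempfile(fileext = ".fasta")
  write_alignment(s1$alignments[[2]], path, outgroup = s1$outgroups[[2]])
  back <- read_alignment(path, annotation = s1$alignments[[2]]$gene$segments,
                         gene_id = "gene02", outgroup_id = "outgroup")
  expect_identical(back$mat, s1$alignments[[2]]$mat)
  expect_identical(attr(back, "outgroup"), unname(s1$outgroups[[2]]))
  # climate: temperature decreases with elevation
  expect_lt(cor(s1$populations$elevation, s1$populations$temp_spring), 0)
})

test_that("migration limits drive differentiation as expected", {
  set.seed(22)
  mean_fst <- function(mig, reps = 30) {
    vals <- replicate(reps, {
      s <- simulate_study(study_design(n_populations = 4L,
                                       individuals_per_population = 3L,
                                       n_genes = 1L, n_intron_genes = 1L,
                                       gene_length = 402L),
                          demographic_model("CON", N_C = 1000),
                          mu = 5e-7, migration = mig,
                          seed = sample.int(1e6, 1))
      a <- s$alignments[[1]]
      pops <- s$samples$population_id[match(a$sample_id, s$samples$sample_id)]
      fst(a, pops)$overall
    })
    mean(vals, na.rm = TRUE)
  }
  high <- mean_fst(list(H = 0.05, L = 0.05))      # 4Nm = 200: panmixia
  low <- mean_fst(list(H = 2.5e-5, L = 2.5e-5))   # 4Nm = 0.1: strong drift
  expect_lt(abs(high), 0.08)
  expect_gt(low, 0.4)
})

test_that("lower H-class migration raises F_ST among H populations", {
  set.seed(23)
  diffs <- replicate(60, {
    s <- simulate_study(study_design(n_populations = 4L,
                                     individuals_per_population = 3L,
                                     n_genes = 2L, n_intron_genes = 1L,
                                     gene_length = 402L),
                        demographic_model("CON", N_C = 1000),
                        mu = 5e-7,
                        migration = list(H = 2.5e-4, L = 5e-3),
                        seed = sample.int(1e6, 1))
    pops <- s$samples$population_id[match(s$alignments[[1]]$sample_id,
                                          s$samples$sample_id)]
    m <- altipop:::.combined_fst(s$alignments, pops)$matrix
    cls <- stats::setNames(s$populations$altitude_class,
                           s$populations$population_id)
    mean(class_pairs(m, cls, "H")) - mean(class_pairs(m, cls, "L"))
  })
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})

test_that("read simulation hits the target coverage and is seeded", {
  s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  pu <- simulate_reads(s, s, coverage = 20, read_length = 200, f_M = 0.024,
                       seed = 31)
  expect_equal(mean(pileup_depth(pu)), 20, tolerance = 0.1)
  pu2 <- simulate_reads(s, s, coverage = 20, read_length = 200, f_M = 0.024,
                        seed = 31)
  expect_identical(pu$mat, pu2$mat)
  # error rate realized near f_M
  truth <- strsplit(s, "")[[1]]
  mism <- mean(sweep(pu$mat, 2, truth, "!=")[!is.na(pu$mat)])
  expect_equal(mism, 0.024, tolerance = 0.3)
})

test_that("single-deme structured simulation matches the plain coalescent", {
  # same sample size, size trajectory, and mutation rate: the island model
  # with one deme must reproduce the unstructured S distribution
  set.seed(24)
  traj <- altipop:::size_trajectory(demographic_model("CON", N_C = 1500))
  mu <- 5e-7; L <- 400; n <- 12
  S_struct <- replicate(400, {
    edges <- altipop:::.sim_structured_tree(rep("d1", n), c(d1 = 0), traj)
    sum(stats::rpois(length(edges),
                     mu * L * vapply(edges, `[[`, numeric(1), "dur")))
  })
  S_plain <- replicate(400, simulate_locus(demographic_model("CON",
    N_C = 1500), mu, 0, n, L)$S)
  expect_equal(mean(S_struct), mean(S_plain), tolerance = 0.12)
  expect_equal(sd(S_struct), sd(S_plain), tolerance = 0.25)
})

test_that("ancestry matrices are valid and reflect grouping", {
  pops <- rep(sprintf("p%d", 1:4), each = 5)
  q <- simulate_qmatrix(pops, K = 2, admixture = 0.1, seed = 41)
  expect_equal(rowSums(q), rep(1, 20))
  expect_true(all(q >= 0 & q <= 1))
  # first two populations load on cluster 1
  expect_gt(mean(q[pops %in% c("p1", "p2"), 1]), 0.8)
  expect_lt(mean(q[pops %in% c("p3", "p4"), 1]), 0.2)
})

test_that("planting an association preserves frequency and records truth", {
  s <- simulate_study(small_design(), demographic_model("CON", N_C = 3000),
                      mu = 5e-7, seed = 42)
  gm <- genotype_matrix(s$alignments[[1]])
  maf <- colMeans(gm$dosage, na.rm = TRUE) / 2
  pos <- gm$meta$position[which(maf > 0.1 & maf < 0.9)[1]]
  before <- table(s$alignments[[1]]$mat[, pos])
  planted <- plant_association(s, names(s$alignments)[1], pos,
                               beta = 0.9, seed = 43)
  after <- table(planted$alignments[[1]]$mat[, pos])
  expect_identical(before, after)       # allele counts preserved exactly
  expect_equal(planted$truth$planted$position, pos)
  # beta = 0 leaves the data unchanged
  un <- plant_association(s, names(s$alignments)[1], pos, beta = 0, seed = 43)
  expect_identical(un$alignments[[1]]$mat, s$alignments[[1]]$mat)
  # planted dosage correlates with the climate variable
  gm2 <- genotype_matrix(planted$alignments[[1]])
  j <- which(gm2$meta$position == pos)
  clim <- planted$samples$prec_spring[match(gm2$sample_id,
                                            planted$samples$sample_id)]
  expect_gt(abs(cor(gm2$dosage[, j], clim, use = "complete.obs")), 0.5)
})
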