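# Ancestry asymmetry, Evanno delta-K, Mantel IBD, distances, correlations.

test_that("ancestry asymmetry uses the add-one randomization estimator", {
  cls <- rep(c("H", "L"), each = 30)
  anc <- c(rep(1, 30), rep(0, 30))
  res <- ancestry_asymmetry_test(anc, cls, n_randomizations = 10000, seed = 2)
  expect_equal(res$observed_difference, 1)
  expect_equal(res$p_value, 1 / 10001)
  # identical ancestry everywhere -> difference 0, p = 1
  res0 <- ancestry_asymmetry_test(rep(0.4, 60), cls,
                                  n_randomizations = 500, seed = 2)
  expect_equal(res0$observed_difference, 0)
  expect_equal(res0$p_value, 1)
  expect_error(ancestry_asymmetry_test(anc, rep("H", 60), 100),
               "both H and L")
})

test_that("ancestry asymmetry is calibrated and deterministic", {
  cls <- rep(c("H", "L"), each = 30)
  set.seed(11)
  ps <- replicate(500, {
    anc <- runif(60)
    ancestry_asymmetry_test(anc, cls, n_randomizations = 199,
                            seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(mean(ps <= 0.05), 0.06 + 0.02)  # null rejection near nominal
  expect_gt(mean(ps <= 0.5), 0.42)
  anc <- runif(60)
  expect_identical(ancestry_asymmetry_test(anc, cls, 500, seed = 7),
                   ancestry_asymmetry_test(anc, cls, 500, seed = 7))
})

test_that("Evanno delta-K finds the elbow and ignores likelihood shifts", {
  # exactly linear likelihoods -> second difference 0 at interior K
  set.seed(4)
  lin <- do.call(rbind, lapply(1:5, function(k)
    data.frame(K = k, logL = -1000 + 50 * k + rnorm(3, 0, 1e-9))))
  # add tiny replicate spread so sd > 0 but keep means exactly linear
  lin$logL <- ave(lin$logL, lin$K, FUN = function(x) x - mean(x) + 0) +
    rep(-1000 + 50 * (1:5), each = 3)
  dk <- evanno_delta_k(lin)
  expect_true(all(abs(dk$delta_k) < 1e-3))
  # sharp elbow at K = 3
  mean_l <- c(-2000, -1500, -1000, -990, -980)
  tr <- do.call(rbind, lapply(1:5, function(k)
    data.frame(K = k, logL = mean_l[k] + rnorm(4, 0, 5))))
  dk2 <- evanno_delta_k(tr)
  expect_equal(dk2$K[which.max(dk2$delta_k)], 3)
  # invariant to adding a constant to all likelihoods
  tr2 <- transform(tr, logL = logL + 12345)
  expect_equal(evanno_delta_k(tr2)$delta_k, dk2$delta_k)
  # single replicate per K -> unavailable
  single <- data.frame(K = 1:3, logL = c(-3, -2, -1))
  expect_true(all(is.na(evanno_delta_k(single)$delta_k)))
})

test_that("Mantel test recovers exact structure and calibrates", {
  set.seed(8)
  n <- 8
  geo <- as.matrix(dist(cbind(runif(n), runif(n))))
  gen <- 0.1 + 2 * geo          # affine function of distance
  dimnames(gen) <- dimnames(geo) <- list(letters[1:n], letters[1:n])
  res <- mantel_ibd(gen, geo, permutations = 499, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 500)
  # joint relabeling leaves r unchanged
  p <- sample(n)
  res2 <- mantel_ibd(gen[p, p], geo[p, p], permutations = 99, seed = 1)
  expect_equal(res2$r, 1)
  # ln transform handles non-positive genetic entries
  gen0 <- gen; gen0[1, 2] <- gen0[2, 1] <- 0
  resln <- mantel_ibd(gen0, geo, permutations = 99, transform = "ln", seed = 1)
  expect_true(is.finite(resln$r))
  # agreement with the vegan implementation on the statistic
  gen_r <- as.matrix(dist(cbind(runif(n), runif(n))))
  dimnames(gen_r) <- dimnames(geo)
  vg <- vegan::mantel(as.dist(gen_r), as.dist(geo), permutations = 99)
  expect_equal(mantel_ibd(gen_r, geo, permutations = 99, seed = 1)$r,
               unname(vg$statistic))
})

test_that("Mantel p-values are calibrated under independence", {
  set.seed(12)
  ps <- replicate(400, {
    n <- 7
    a <- as.matrix(dist(runif(n))); b <- as.matrix(dist(runif(n)))
    mantel_ibd(a, b, permutations = 99, seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(mean(ps <= 0.05), 0.09)
  expect_gte(mean(ps <= 0.5), 0.40)
})

test_that("great-circle distances use the 6371 km sphere", {
  expect_equal(geo_distance(46, 11, 46, 11), 0)
  expect_equal(geo_distance(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_equal(geo_distance(46.2, 10.8, 45.9, 11.5),
               geo_distance(45.9, 11.5, 46.2, 10.8))
  expect_error(geo_distance(100, 0, 0, 0))
  m <- geo_distance_matrix(data.frame(population_id = c("a", "b"),
                                      latitude = c(46, 46.5),
                                      longitude = c(11, 11.2)))
  expect_equal(m["a", "b"], m["b", "a"])
  expect_equal(diag(m), c(a = 0, b = 0))
})

test_that("Spearman and partial rank correlations behave", {
  # perfectly decreasing, n = 5: rho = -1, exact P = 2/120
  res <- rank_correlations(1:5, c(10, 8, 6, 4, 2))
  expect_equal(res$rho, -1)
  expect_equal(res$p_value, 2 / 120, tolerance = 1e-9)
  expect_equal(rank_correlations(1:6, 1:6)$rho, 1)
  # control variable removal: y depends only on z
  set.seed(6)
  z <- rnorm(30); y <- 2 * z + rnorm(30, 0, 0.1); x <- z + rnorm(30, 0, 0.1)
  pc <- rank_correlations(x, y, z)
  expect_lt(abs(pc$partial_rho), abs(pc$rho))
  expect_error(rank_correlations(rep(1, 5), 1:5), "constant")
})
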