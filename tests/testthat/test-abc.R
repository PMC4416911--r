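# Coalescent simulator and ABC machinery.

test_that("prior draws respect model structure and bounds", {
  set.seed(2)
  pr <- prior_spec()
  d <- sample_prior("CON", pr)
  expect_setequal(names(d$params), c("N_C", "mu", "rho"))
  draws <- replicate(2000, sample_prior("CON", pr)$params["N_C"])
  expect_gte(min(draws), pr$N_range[1])
  expect_lte(max(draws), pr$N_range[2])
  for (b in 1:50) {
    e <- sample_prior("EXP", pr)
    expect_equal(e$model$N_C, e$model$N_A * exp(e$model$r * e$model$T_E),
                 tolerance = 1e-8)
    r <- sample_prior("RED", pr)
    expect_lt(r$model$N_C, r$model$N_A)
    bo <- sample_prior("BOT", pr)
    expect_lt(bo$model$T_B_end, bo$model$T_B_start)
    expect_lt(bo$model$N_B, min(bo$model$N_C, bo$model$N_A))
  }
})

test_that("model specifications validate their constraints", {
  expect_error(demographic_model("RED", N_C = 100, N_A = 50, T_R = 10),
               "N_C < N_A")
  expect_error(demographic_model("CON", N_C = -5), "positive")
  expect_error(demographic_model("BOT", N_C = 100, N_A = 100, N_B = 10,
                                 T_B_start = 5, T_B_end = 10),
               "T_B_end < T_B_start")
  m <- demographic_model("EXP", N_C = 1000, N_A = 100, T_E = 500)
  expect_equal(m$N_C, m$N_A * exp(m$r * m$T_E))
})

test_that("pair-sample coalescent matches the analytic identity", {
  # n = 2 under CON: T_MRCA ~ Exp(mean 2N); E[S] = 2 mu L * 2N
  set.seed(9)
  m <- demographic_model("CON", N_C = 2000)
  res <- replicate(4000, simulate_locus(m, 1e-6, 0, 2, 100)$S)
  expect_equal(mean(res), 2 * 1e-6 * 100 * 2 * 2000, tolerance = 0.1)
  one <- simulate_locus(m, 1e-6, 0, 2, 100, seed = 4)
  expect_equal(one$pi, one$S / 100)
})

test_that("growth and reduction skew Tajima's D in opposite directions", {
  set.seed(10)
  dvals <- function(model, reps = 400) {
    mean(replicate(reps, {
      r <- simulate_locus(model, 5e-7, 0, 25, 400)
      if (r$S == 0) 0 else tajimas_d(25, r$S, r$pi * 400)
    }))
  }
  d_exp <- dvals(demographic_model("EXP", N_C = 20000, N_A = 200, T_E = 8000))
  d_red <- dvals(demographic_model("RED", N_C = 200, N_A = 20000, T_R = 400))
  expect_lt(d_exp, -0.2)
  expect_gt(d_red, 0.2)
})

test_that("compiled simulator matches the reference R implementation", {
  set.seed(15)
  m <- demographic_model("CON", N_C = 2000)
  cpp <- replicate(800, unlist(simulate_locus(m, 3e-7, 4e-9, 25, 400)))
  ref <- replicate(800, unlist(altipop:::.r_simulate_locus(m, 3e-7, 4e-9,
                                                           25, 400)))
  expect_equal(mean(cpp["S", ]), mean(ref["S", ]), tolerance = 0.1)
  expect_equal(sd(cpp["S", ]), sd(ref["S", ]), tolerance = 0.2)
  expect_equal(mean(cpp["pi", ]), mean(ref["pi", ]), tolerance = 0.1)
})

test_that("reference tables have the documented shape and determinism", {
  loci <- locus_config(n = c(8, 8, 8), L_eff = c(200, 300, 250))
  pr <- prior_spec(N_range = c(500, 2000), mu_range = c(1e-7, 5e-7))
  tab <- build_reference_table("CON", pr, loci, 100, seed = 3)
  expect_equal(nrow(tab$summaries), 100)
  expect_equal(colnames(tab$summaries),
               c("mean_S", "sd_S", "mean_pi", "sd_pi"))
  tab2 <- build_reference_table("CON", pr, loci, 100, seed = 3)
  expect_identical(tab$summaries, tab2$summaries)
  # single-locus configuration: sd summaries are 0 by convention
  tab1 <- build_reference_table("CON", pr, locus_config(8, 300), 20, seed = 1)
  expect_true(all(tab1$summaries[, "sd_S"] == 0))
  expect_true(all(tab1$summaries[, "sd_pi"] == 0))
  expect_equal(unname(summary_vector(5, 0.01)[c("sd_S", "sd_pi")]), c(0, 0))
})

test_that("rejection retains the closest rows", {
  loci <- locus_config(n = c(8, 8), L_eff = c(200, 300))
  pr <- prior_spec(N_range = c(500, 5000), mu_range = c(1e-7, 5e-7))
  tab <- build_reference_table("CON", pr, loci, 200, seed = 5)
  obs <- tab$summaries[37, ]
  ret <- abc_reject(obs, tab, 0.05)
  expect_equal(length(ret$index), 10)    # ceiling(0.05 * 200)
  expect_true(37 %in% ret$index)         # the zero-distance row is retained
  expect_equal(ret$distance[1], 0)
  all_ret <- abc_reject(obs, tab, 1)
  expect_equal(length(all_ret$index), 200)
})

test_that("regression adjustment concentrates on noiseless linear maps", {
  # construct a table whose summaries are a noiseless function of log N_C
  set.seed(6)
  n_rows <- 400
  N <- exp(runif(n_rows, log(100), log(10000)))
  tab <- structure(list(
    kind = "CON",
    params = data.frame(N_C = N),
    summaries = cbind(mean_S = 2 * log(N) + 1, sd_S = rep(0, n_rows),
                      mean_pi = rep(0, n_rows), sd_pi = rep(0, n_rows))),
    class = "abc_table")
  true_N <- 1500
  obs <- c(mean_S = 2 * log(true_N) + 1, sd_S = 0, mean_pi = 0, sd_pi = 0)
  ret <- abc_reject(obs, tab, 0.2)
  adj <- regression_adjust(tab, ret, obs)
  expect_lt(stats::sd(log(adj$N_C)), 0.01)
  expect_equal(stats::median(adj$N_C), true_N, tolerance = 0.02)
  # adjusted values never leave the retained support
  expect_gte(min(adj$N_C), min(tab$params$N_C[ret$index]))
  expect_lte(max(adj$N_C), max(tab$params$N_C[ret$index]))
  # summaries carrying no information leave the sample nearly unadjusted
  tab_null <- tab
  set.seed(7)
  tab_null$summaries <- cbind(mean_S = rnorm(n_rows), sd_S = rnorm(n_rows),
                              mean_pi = rnorm(n_rows), sd_pi = rnorm(n_rows))
  ret0 <- abc_reject(obs * 0, tab_null, 0.2)
  adj0 <- regression_adjust(tab_null, ret0, obs * 0)
  raw <- tab_null$params$N_C[ret0$index]
  expect_gt(stats::cor(log(adj0$N_C), log(raw)), 0.95)
})

test_that("model choice normalizes and respects symmetry", {
  loci <- locus_config(n = c(8, 8), L_eff = c(200, 300))
  pr <- prior_spec(N_range = c(500, 5000), mu_range = c(1e-7, 5e-7))
  tab_a <- build_reference_table("CON", pr, loci, 300, seed = 8)
  tab_b <- build_reference_table("CON", pr, loci, 300, seed = 8)
  obs <- tab_a$summaries[10, ]
  mc <- model_choice(obs, list(m1 = tab_a, m2 = tab_b), 0.1)
  expect_equal(sum(mc$pp), 1)
  expect_equal(mc$pp[1], mc$pp[2])       # identical tables -> equal pP
  expect_true(all(mc$fit_p >= 0 & mc$fit_p <= 1))
})

test_that("kernel-corrected probabilities normalize and separate", {
  set.seed(13)
  # degenerate: observed sits on one model's POD cloud, far from the other
  pods <- list(a = matrix(rep(c(0.9, 0.1), each = 200), 200),
               b = matrix(rep(c(0.1, 0.9), each = 200), 200))
  cc <- kernel_corrected_pp(c(0.9, 0.1), pods, bandwidth = 0.05 + 0.05)
  expect_equal(sum(cc), 1)
  expect_gt(cc[["a"]], 0.99)
  # identical POD clouds -> uniform
  pods_same <- list(a = pods$a, b = pods$a, c = pods$a, d = pods$a)
  cc2 <- kernel_corrected_pp(c(0.9, 0.1), pods_same, bandwidth = 0.1)
  expect_equal(unname(cc2), rep(0.25, 4))
  expect_error(kernel_corrected_pp(c(0.5, 0.5), pods, bandwidth = 0.5),
               "bandwidth")
})

test_that("posterior summaries report modes and shortest intervals", {
  set.seed(14)
  u <- runif(100000)
  ps <- posterior_summary(u)
  expect_equal(diff(ps$hpd), 0.95, tolerance = 0.02)
  pt <- posterior_summary(rep(3.5, 200))
  expect_equal(pt$mode, 3.5, tolerance = 1e-6)
  expect_equal(diff(pt$hpd), 0)
  x <- rlnorm(5000, 5, 1)
  px <- posterior_summary(x, log_scale = TRUE)
  expect_gte(px$hpd[1], min(x))
  expect_lte(px$hpd[2], max(x))
})
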