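# Approximate Bayesian Computation: priors, reference tables, rejection,
# regression adjustment, model choice, POD power analysis, kernel-corrected
# posterior probabilities, posterior summaries.

#' Prior specification for ABC
#'
#' Per-parameter sampling distributions.  Mutation and recombination rate
#' ranges default to 1e-9..5e-7 and 0..1e-8 per site per generation.  Size
#' and time priors are log-uniform over supports wide enough to contain the
#' posterior mass typically reported for alpine herb populations
#' (hundreds to about a million individuals; 1e2 to 1e5 generations).
#'
#' @param N_range,T_range Log-uniform supports for diploid sizes and times.
#' @param mu_range Log-uniform support for the mutation rate.
#' @param rho_range Uniform support for the recombination rate.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(N_range = c(1e2, 1e6), T_range = c(1e2, 1e5),
                       mu_range = c(1e-9, 5e-7), rho_range = c(0, 1e-8)) {
  chk <- function(r, nm) if (length(r) != 2L || r[1L] > r[2L])
    stop("invalid range for ", nm)
  chk(N_range, "N"); chk(T_range, "T"); chk(mu_range, "mu")
  chk(rho_range, "rho")
  structure(list(N_range = N_range, T_range = T_range,
                 mu_range = mu_range, rho_range = rho_range),
            class = "prior_spec")
}

.runif_log <- function(range) exp(stats::runif(1L, log(range[1L]), log(range[2L])))

#' Draw one parameter set from the prior
#'
#' Independent draws per the configured distributions.  For `EXP`, `r` is
#' uniform on `[0, log(N_max / N_A) / T_E]` so the constraint
#' `N_C = N_A * exp(r * T_E)` is always satisfiable within the size prior;
#' `RED` redraws until `N_C < N_A`; `BOT` orders its two times and redraws
#' until `N_B < min(N_C, N_A)`.
#'
#' @param kind Model kind (`"CON"`, `"BOT"`, `"EXP"`, `"RED"`).
#' @param priors A [prior_spec()].
#' @return List with `model` (a [demographic_model()]), `mu`, `rho`, and
#'   `params` (named numeric vector of the kind-relevant parameters).
#' @export
sample_prior <- function(kind, priors = prior_spec()) {
  kind <- match.arg(kind, c("CON", "BOT", "EXP", "RED"))
  mu <- .runif_log(priors$mu_range)
  rho <- stats::runif(1L, priors$rho_range[1L], priors$rho_range[2L])
  Nr <- priors$N_range; Tr <- priors$T_range
  if (kind == "CON") {
    m <- demographic_model("CON", N_C = .runif_log(Nr))
    par <- c(N_C = m$N_C)
  } else if (kind == "RED") {
    repeat {
      N_C <- .runif_log(Nr); N_A <- .runif_log(Nr)
      if (N_C < N_A) break
    }
    m <- demographic_model("RED", N_C = N_C, N_A = N_A, T_R = .runif_log(Tr))
    par <- c(N_C = m$N_C, N_A = m$N_A, T_R = m$T_R)
  } else if (kind == "EXP") {
    N_A <- .runif_log(c(Nr[1L], Nr[2L] / 1.001))
    T_E <- .runif_log(Tr)
    r <- stats::runif(1L, 0, log(Nr[2L] / N_A) / T_E)
    r <- max(r, 1e-12 / T_E)                  # keep N_C strictly above N_A
    m <- demographic_model("EXP", N_C = N_A * exp(r * T_E), N_A = N_A,
                           T_E = T_E, r = r)
    par <- c(N_C = m$N_C, N_A = m$N_A, T_E = m$T_E, r = m$r)
  } else {
    repeat {
      N_C <- .runif_log(Nr); N_A <- .runif_log(Nr); N_B <- .runif_log(Nr)
      if (N_B < min(N_C, N_A)) break
    }
    tt <- sort(c(.runif_log(Tr), .runif_log(Tr)))
    m <- demographic_model("BOT", N_C = N_C, N_A = N_A, N_B = N_B,
                           T_B_start = tt[2L], T_B_end = tt[1L])
    par <- c(N_C = N_C, N_A = N_A, N_B = N_B,
             T_B_start = tt[2L], T_B_end = tt[1L])
  }
  list(model = m, mu = mu, rho = rho, params = c(par, mu = mu, rho = rho))
}

#' Locus configuration for multi-locus simulation
#'
#' @param n Integer vector of haplotype counts per locus.
#' @param L_eff Integer vector of effective site counts per locus.
#' @return Data frame with columns `n`, `L_eff`.
#' @export
locus_config <- function(n, L_eff) {
  stopifnot(length(n) == length(L_eff), all(n >= 4), all(L_eff >= 1))
  data.frame(n = as.integer(n), L_eff = as.integer(L_eff))
}

#' Summary vector across loci
#'
#' Mean and standard deviation across loci of the number of segregating
#' sites `S` and the per-site pairwise diversity `pi`.  With a single locus
#' the SDs are defined as 0.
#'
#' @param S,pi Numeric vectors of per-locus values.
#' @return Named numeric vector `mean_S`, `sd_S`, `mean_pi`, `sd_pi`.
#' @export
summary_vector <- function(S, pi) {
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  c(mean_S = mean(S), sd_S = sd0(S), mean_pi = mean(pi), sd_pi = sd0(pi))
}

# Simulate all loci under one parameter draw; returns the summary vector.
.sim_summary <- function(draw, loci) {
  S <- numeric(nrow(loci)); pi <- numeric(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    res <- simulate_locus(draw$model, draw$mu, draw$rho,
                          loci$n[i], loci$L_eff[i])
    S[i] <- res$S; pi[i] <- res$pi
  }
  summary_vector(S, pi)
}

#' Build an ABC reference table
#'
#' Draws `n_sims` parameter sets from the prior; each draw is applied
#' identically to all loci, and the across-locus summary vector is stored.
#'
#' @param kind Model kind.
#' @param priors A [prior_spec()].
#' @param loci A [locus_config()].
#' @param n_sims Number of simulated parameter sets.
#' @param seed Integer seed.
#' @return List of class `abc_table` with `kind`, `params` (data frame),
#'   `summaries` (matrix with columns mean_S, sd_S, mean_pi, sd_pi).
#' @export
build_reference_table <- function(kind, priors, loci, n_sims, seed = 1L) {
  set.seed(seed)
  stopifnot(n_sims >= 1L)
  params <- vector("list", n_sims)
  summ <- matrix(NA_real_, n_sims, 4L,
                 dimnames = list(NULL, c("mean_S", "sd_S", "mean_pi", "sd_pi")))
  for (b in seq_len(n_sims)) {
    draw <- sample_prior(kind, priors)
    summ[b, ] <- .sim_summary(draw, loci)
    params[[b]] <- draw$params
  }
  structure(list(kind = kind,
                 params = as.data.frame(do.call(rbind, params)),
                 summaries = summ),
            class = "abc_table")
}

# Standardize summary columns by the table's per-summary SD (zero SD columns
# are dropped from the distance).
.std_dist <- function(observed, summaries) {
  sds <- apply(summaries, 2L, stats::sd)
  use <- sds > 0
  if (!any(use)) stop("all summary columns are constant in the table")
  z <- sweep(summaries[, use, drop = FALSE], 2L, sds[use], "/")
  zo <- observed[use] / sds[use]
  sqrt(colSums((t(z) - zo)^2))
}

#' ABC rejection step
#'
#' Retains the `ceiling(retention_fraction * n)` rows of the reference table
#' closest to the observed summary vector in Euclidean distance on
#' SD-standardized summaries.
#'
#' @param observed Named summary vector (as from [summary_vector()]).
#' @param table An `abc_table`.
#' @param retention_fraction Fraction of rows to retain (production setting 0.005).
#' @return List with `index`, `distance` (both ordered by distance).
#' @export
abc_reject <- function(observed, table, retention_fraction = 0.005) {
  stopifnot(retention_fraction > 0, retention_fraction <= 1)
  d <- .std_dist(observed[colnames(table$summaries)], table$summaries)
  keep <- ceiling(retention_fraction * length(d))
  ord <- order(d)[seq_len(keep)]
  list(index = ord, distance = d[ord])
}

#' Local-linear regression adjustment of the retained sample
#'
#' Regresses each parameter (log scale for strictly positive parameters) on
#' the standardized summaries with Epanechnikov weights in the rejection
#' distance, and translates the retained draws to the observed point:
#' `adjusted = fitted(observed) + residual`.  Values are clipped to the
#' retained sample's support (and hence the prior's).  A singular design
#' falls back to the unadjusted sample with a warning.
#'
#' @param table An `abc_table`.
#' @param retained Result of [abc_reject()].
#' @param observed Observed summary vector.
#' @return Data frame of adjusted parameter draws (same columns as
#'   `table$params`).
#' @export
regression_adjust <- function(table, retained, observed) {
  idx <- retained$index
  if (length(idx) < 20L) stop("need >= 20 retained rows")
  summ <- table$summaries[idx, , drop = FALSE]
  sds <- apply(table$summaries, 2L, stats::sd)
  # only summaries that vary both overall and within the retained set can
  # enter the local regression
  use <- sds > 0 & apply(summ, 2L, stats::sd) > 0
  if (!any(use)) return(table$params[idx, , drop = FALSE])
  X <- sweep(summ[, use, drop = FALSE], 2L, sds[use], "/")
  x0 <- observed[colnames(table$summaries)][use] / sds[use]
  dmax <- max(retained$distance)
  w <- if (dmax == 0) rep(1, length(idx)) else
    pmax(0, 1 - (retained$distance / (dmax * 1.0001))^2)
  out <- table$params[idx, , drop = FALSE]
  for (p in names(out)) {
    y <- out[[p]]
    pos <- all(y > 0)
    ty <- if (pos) log(y) else y
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), ty, w),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("singular regression design for ", p,
              "; returning unadjusted sample")
      next
    }
    co <- fit$coefficients
    co[is.na(co)] <- 0          # aliased (collinear) columns carry no slope
    adj <- drop(c(1, x0) %*% co) + fit$residuals
    if (pos) adj <- exp(adj)
    out[[p]] <- pmin(max(y), pmax(min(y), adj))
  }
  out
}

# Product-Gaussian kernel density of point(s) x0 given sample rows Z.
.gauss_kde <- function(x0, Z, bw) {
  if (is.null(dim(x0))) x0 <- matrix(x0, nrow = 1L)
  apply(x0, 1L, function(p) {
    lk <- -0.5 * colSums(((t(Z) - p) / bw)^2) -
      sum(log(bw)) - ncol(Z) / 2 * log(2 * pi)
    mean(exp(lk))
  })
}

#' ABC model choice by marginal densities
#'
#' For each candidate model the marginal density (MD) of the observed
#' summary vector is estimated by a multivariate Gaussian kernel over the
#' model's retained summaries (standardized per summary; Silverman
#' bandwidths).  Posterior probabilities are the MDs normalized across
#' models; the model-fit P is the fraction of retained simulations whose own
#' estimated density is smaller than or equal to that of the observed data.
#'
#' @param observed Observed summary vector.
#' @param tables Named list of `abc_table`s (one per model, equal `n_sims`).
#' @param retention_fraction Rejection retention fraction.
#' @return Data frame with one row per model: `model`, `md`, `fit_p`, `pp`.
#' @export
model_choice <- function(observed, tables, retention_fraction = 0.005) {
  stopifnot(length(tables) >= 2L)
  res <- lapply(tables, function(tab) {
    ret <- abc_reject(observed, tab, retention_fraction)
    summ <- tab$summaries[ret$index, , drop = FALSE]
    sds <- apply(tab$summaries, 2L, stats::sd)
    use <- sds > 0
    Z <- sweep(summ[, use, drop = FALSE], 2L, sds[use], "/")
    zo <- observed[colnames(tab$summaries)][use] / sds[use]
    m <- nrow(Z); d <- ncol(Z)
    bw <- apply(Z, 2L, stats::sd) * (4 / ((d + 2) * m))^(1 / (d + 4))
    bw[bw <= 0] <- 1e-6
    md <- .gauss_kde(zo, Z, bw)
    dens_ret <- .gauss_kde(Z, Z, bw)
    c(md = md, fit_p = mean(dens_ret <= md + 1e-300))
  })
  md <- vapply(res, `[[`, numeric(1L), "md")
  if (all(md == 0)) stop("zero marginal density under every model")
  data.frame(model = names(tables), md = md,
             fit_p = vapply(res, `[[`, numeric(1L), "fit_p"),
             pp = md / sum(md), row.names = NULL)
}

#' Model-choice power analysis with pseudo-observed datasets
#'
#' Generates `n_pods` pseudo-observed datasets (PODs) under each model's
#' prior predictive, runs [model_choice()] for each against the shared
#' reference tables, and reports the fraction of PODs whose generating model
#' attains the maximum posterior probability (random expectation 1/#models).
#'
#' @param tables Named list of `abc_table`s.
#' @param priors A [prior_spec()], or a named list of them (one per model)
#'   for experiments with model-specific priors.
#' @param loci A [locus_config()].
#' @param n_pods PODs per model.
#' @param retention_fraction Rejection retention fraction.
#' @param seed Integer seed.
#' @return List with `power` (named vector) and `pod_pp` (named list of
#'   n_pods x n_models matrices of posterior probabilities).
#' @export
power_analysis <- function(tables, priors, loci, n_pods = 100L,
                           retention_fraction = 0.005, seed = 1L) {
  set.seed(seed)
  kinds <- names(tables)
  prior_for <- function(kind)
    if (inherits(priors, "prior_spec")) priors else priors[[kind]]
  pod_pp <- stats::setNames(vector("list", length(kinds)), kinds)
  for (kind in kinds) {
    pp <- matrix(NA_real_, n_pods, length(kinds),
                 dimnames = list(NULL, kinds))
    for (b in seq_len(n_pods)) {
      obs <- .sim_summary(sample_prior(kind, prior_for(kind)), loci)
      pp[b, ] <- model_choice(obs, tables, retention_fraction)$pp
    }
    pod_pp[[kind]] <- pp
  }
  power <- vapply(kinds, function(kind) {
    mean(apply(pod_pp[[kind]], 1L, which.max) == match(kind, kinds))
  }, numeric(1L))
  list(power = power, pod_pp = pod_pp)
}

#' Kernel-corrected posterior model probabilities
#'
#' Conditions the observed vector of posterior probabilities on the
#' distribution of such vectors among PODs of each model, using a
#' product-Gaussian kernel with a common bandwidth in all four dimensions.
#'
#' @param observed_pp Numeric vector of posterior probabilities (one per
#'   model, summing to 1).
#' @param pod_pp Named list of POD posterior-probability matrices (as from
#'   [power_analysis()]).
#' @param bandwidth Common kernel bandwidth in `[0.01, 0.2]` (default 0.1).
#' @return Named vector of corrected probabilities summing to 1.
#' @export
kernel_corrected_pp <- function(observed_pp, pod_pp, bandwidth = 0.1) {
  stopifnot(bandwidth >= 0.01, bandwidth <= 0.2)
  d <- vapply(pod_pp, function(Z)
    .gauss_kde(observed_pp, Z, rep(bandwidth, ncol(Z))), numeric(1L))
  if (sum(d) == 0) {
    warning("zero kernel density under every model; uniform fallback")
    return(stats::setNames(rep(1 / length(d), length(d)), names(pod_pp)))
  }
  d / sum(d)
}

#' Posterior mode and 95% HPD interval
#'
#' Mode from a 1-D Gaussian kernel density (Silverman bandwidth); the
#' highest-posterior-density interval is the shortest interval containing
#' the requested mass of the sample.
#'
#' @param sample Numeric posterior sample (>= 100 draws).
#' @param mass HPD mass (default 0.95).
#' @param log_scale Estimate the mode on the log scale (for size/time
#'   parameters spanning orders of magnitude).
#' @return List with `mode`, `hpd` (length-2 vector).
#' @export
posterior_summary <- function(sample, mass = 0.95, log_scale = FALSE) {
  stopifnot(length(sample) >= 100L)
  x <- if (log_scale) log(sample) else sample
  if (stats::sd(x) == 0) {
    mode <- x[1L]
  } else {
    dd <- stats::density(x)
    mode <- dd$x[which.max(dd$y)]
  }
  if (log_scale) mode <- exp(mode)
  s <- sort(sample)
  m <- length(s)
  k <- max(1L, ceiling(mass * m))
  starts <- seq_len(m - k + 1L)
  widths <- s[starts + k - 1L] - s[starts]
  i <- starts[which.min(widths)]
  list(mode = mode, hpd = c(s[i], s[i + k - 1L]))
}
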