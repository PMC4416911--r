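# Structure-related hypothesis tests: ancestry-asymmetry randomization,
# Evanno delta-K, Mantel isolation-by-distance, great-circle distances, and
# Spearman / partial rank correlations.

#' Ancestry asymmetry randomization test
#'
#' Tests whether mean ancestry in the first cluster differs between H- and
#' L-class individuals.  The observed statistic is the absolute difference
#' of class means; the null reassigns the individual ancestry values to
#' classes at random preserving class sizes.  P uses the add-one estimator
#' `(count(null >= observed) + 1) / (n_randomizations + 1)`.
#'
#' @param ancestry Numeric vector of cluster-1 ancestry proportions.
#' @param altitude_class Character vector (`"H"`/`"L"`), same length.
#' @param n_randomizations Number of random reassignments (study value
#'   10,000).
#' @param seed Integer seed.
#' @return List with `observed_difference`, `p_value`, `mean_H`, `mean_L`.
#' @export
ancestry_asymmetry_test <- function(ancestry, altitude_class,
                                    n_randomizations = 10000L, seed = 1L) {
  stopifnot(length(ancestry) == length(altitude_class))
  is_h <- altitude_class == "H"
  if (!any(is_h) || all(is_h)) stop("both H and L classes must be represented")
  obs <- abs(mean(ancestry[is_h]) - mean(ancestry[!is_h]))
  set.seed(seed)
  nh <- sum(is_h); ntot <- length(ancestry)
  null <- vapply(seq_len(n_randomizations), function(b) {
    idx <- sample.int(ntot, nh)
    abs(mean(ancestry[idx]) - mean(ancestry[-idx]))
  }, numeric(1L))
  list(observed_difference = obs,
       p_value = (sum(null >= obs - 1e-12) + 1) / (n_randomizations + 1),
       mean_H = mean(ancestry[is_h]), mean_L = mean(ancestry[!is_h]))
}

#' Evanno delta-K from likelihood traces
#'
#' `deltaK(K) = mean_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| / sd_r(L_r(K))`,
#' defined for interior K with at least two replicates.  A K with zero
#' replicate spread is reported as `NA`.
#'
#' @param trace Data frame with columns `K` and `logL` (one row per
#'   replicate run).
#' @return Data frame `K`, `delta_k` for interior K values.
#' @export
evanno_delta_k <- function(trace) {
  stopifnot(all(c("K", "logL") %in% names(trace)))
  ks <- sort(unique(trace$K))
  if (length(ks) < 3L) stop("need >= 3 consecutive K values")
  means <- tapply(trace$logL, trace$K, mean)
  sds <- tapply(trace$logL, trace$K, stats::sd)
  nrep <- tapply(trace$logL, trace$K, length)
  interior <- ks[-c(1L, length(ks))]
  dk <- vapply(interior, function(k) {
    if (nrep[[as.character(k)]] < 2L) return(NA_real_)
    s <- sds[[as.character(k)]]
    if (is.na(s) || s == 0) return(NA_real_)
    abs(means[[as.character(k + 1L)]] - 2 * means[[as.character(k)]] +
        means[[as.character(k - 1L)]]) / s
  }, numeric(1L))
  data.frame(K = interior, delta_k = dk)
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation of the lower triangles of a genetic and a geographic
#' distance matrix; significance by seeded permutations of one matrix's
#' row/column labels.  With `transform = "ln"` both matrices are
#' log-transformed; non-positive genetic entries are first offset by half
#' the smallest positive observed value.
#'
#' @param genetic,geographic Square symmetric matrices with matching labels.
#' @param permutations Number of label permutations.
#' @param transform `"raw"` or `"ln"`.
#' @param seed Integer seed.
#' @return List with `r`, `p_value`, `permutations`.
#' @export
mantel_ibd <- function(genetic, geographic, permutations = 10000L,
                       transform = c("raw", "ln"), seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(nrow(genetic) == ncol(genetic),
            all(dim(genetic) == dim(geographic)))
  if (!is.null(rownames(genetic)) && !is.null(rownames(geographic)))
    geographic <- geographic[rownames(genetic), rownames(genetic)]
  if (nrow(genetic) < 4L)
    warning("fewer than 4 populations: the Mantel test has little power")
  if (transform == "ln") {
    gpos <- genetic[upper.tri(genetic)]
    eps <- min(gpos[gpos > 0]) / 2
    genetic[genetic <= 0] <- eps
    genetic <- log(genetic)
    dpos <- geographic[upper.tri(geographic)]
    epsd <- if (any(dpos <= 0)) min(dpos[dpos > 0]) / 2 else 0
    geographic[geographic <= 0] <- max(epsd, .Machine$double.xmin)
    geographic <- log(geographic)
  }
  lt <- lower.tri(genetic)
  obs <- stats::cor(genetic[lt], geographic[lt])
  set.seed(seed)
  n <- nrow(genetic)
  null <- vapply(seq_len(permutations), function(b) {
    p <- sample.int(n)
    stats::cor(genetic[p, p][lt], geographic[lt])
  }, numeric(1L))
  list(r = obs,
       p_value = (sum(null >= obs - 1e-12) + 1) / (permutations + 1),
       permutations = permutations)
}

#' Great-circle distance in kilometers
#'
#' Spherical earth, radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance in km.
#' @export
geo_distance <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  geosphere::distCosine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Pairwise great-circle distance matrix for populations
#'
#' @param coords Data frame with columns `population_id`, `latitude`,
#'   `longitude` (one row per population).
#' @return Symmetric matrix of distances in km.
#' @export
geo_distance_matrix <- function(coords) {
  k <- nrow(coords)
  m <- matrix(0, k, k, dimnames = list(coords$population_id,
                                       coords$population_id))
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- geo_distance(coords$latitude[i], coords$longitude[i],
                            coords$latitude[j], coords$longitude[j])
  m
}

#' Spearman and partial rank correlations
#'
#' Spearman rank correlation with exact small-sample P (via
#' [stats::cor.test()]); when a control variable is supplied, the partial
#' rank correlation is computed by correlating the residuals of the ranks of
#' `x` and `y` after linear removal of the ranks of `z`, with its P from the
#' t approximation on `n - 3` degrees of freedom.
#'
#' @param x,y Numeric vectors (length >= 4).
#' @param z Optional control variable.
#' @return List with `rho`, `p_value` and, when `z` is given, `partial_rho`,
#'   `partial_p`.
#' @export
rank_correlations <- function(x, y, z = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation unavailable")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  out <- list(rho = unname(ct$estimate), p_value = ct$p.value)
  if (!is.null(z)) {
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    ex <- stats::resid(stats::lm(rx ~ rz))
    ey <- stats::resid(stats::lm(ry ~ rz))
    pr <- stats::cor(ex, ey)
    n <- length(x)
    tt <- pr * sqrt((n - 3) / (1 - pr^2))
    out$partial_rho <- pr
    out$partial_p <- 2 * stats::pt(-abs(tt), df = n - 3)
  }
  out
}
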