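# Single-population coalescent simulator with piecewise population-size
# trajectories, infinite-sites mutation, and (optional) recombination via the
# ancestral recombination graph.  Times are in generations looking backwards
# from the present; sizes are diploid individuals.

#' Demographic model specification
#'
#' One of four single-population histories: constant size (`CON`), bottleneck
#' (`BOT`), exponential expansion (`EXP`, with `N_C = N_A * exp(r * T_E)`),
#' and stepwise size reduction (`RED`, `N_C < N_A`).
#'
#' @param kind `"CON"`, `"BOT"`, `"EXP"` or `"RED"`.
#' @param N_C Current effective population size (diploid individuals).
#' @param N_A Ancestral size (all kinds but `CON`).
#' @param T_R Generations since the size reduction (`RED`).
#' @param T_E Generations since expansion onset (`EXP`).
#' @param r Exponential growth parameter (`EXP`); `N_C = N_A * exp(r * T_E)`
#'   must hold (supply any two of `N_C`, `N_A`, `r` plus `T_E`).
#' @param N_B,T_B_start,T_B_end Bottleneck size and its start/end times ago
#'   (`BOT`; `T_B_end < T_B_start`, `N_B < min(N_C, N_A)`).
#' @return Object of class `demographic_model`.
#' @export
demographic_model <- function(kind, N_C = NULL, N_A = NULL, T_R = NULL,
                              T_E = NULL, r = NULL, N_B = NULL,
                              T_B_start = NULL, T_B_end = NULL) {
  kind <- match.arg(kind, c("CON", "BOT", "EXP", "RED"))
  chk <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0)
      stop("model ", kind, " requires positive ", nm)
    x
  }
  m <- list(kind = kind)
  m$N_C <- chk(N_C, "N_C")
  if (kind == "RED") {
    m$N_A <- chk(N_A, "N_A"); m$T_R <- chk(T_R, "T_R")
    if (m$N_C >= m$N_A) stop("RED requires N_C < N_A")
  } else if (kind == "EXP") {
    m$T_E <- chk(T_E, "T_E")
    if (is.null(r)) {
      m$N_A <- chk(N_A, "N_A")
      if (m$N_C <= m$N_A) stop("EXP requires N_C > N_A")
      m$r <- log(m$N_C / m$N_A) / m$T_E
    } else {
      m$r <- chk(r, "r")
      m$N_A <- if (is.null(N_A)) m$N_C / exp(m$r * m$T_E) else N_A
      if (abs(log(m$N_C / (m$N_A * exp(m$r * m$T_E)))) > 1e-8)
        stop("EXP constraint N_C = N_A * exp(r * T_E) violated")
    }
  } else if (kind == "BOT") {
    m$N_A <- chk(N_A, "N_A"); m$N_B <- chk(N_B, "N_B")
    m$T_B_start <- chk(T_B_start, "T_B_start")
    m$T_B_end <- chk(T_B_end, "T_B_end")
    if (m$T_B_end >= m$T_B_start) stop("BOT requires T_B_end < T_B_start")
    if (m$N_B >= min(m$N_C, m$N_A)) stop("BOT requires N_B < min(N_C, N_A)")
  }
  structure(m, class = "demographic_model")
}

# Piecewise-constant size trajectory backwards in time: boundaries (starting
# at 0, last epoch unbounded) and the diploid size within each epoch.
# Exponential growth phases are discretized into `steps` equal time slices.
size_trajectory <- function(model, steps = 64L) {
  with(model, switch(model$kind,
    CON = list(bounds = 0, N = N_C),
    RED = list(bounds = c(0, T_R), N = c(N_C, N_A)),
    BOT = list(bounds = c(0, T_B_end, T_B_start), N = c(N_C, N_B, N_A)),
    EXP = {
      b <- seq(0, T_E, length.out = steps + 1L)[-(steps + 1L)]
      mid <- b + T_E / steps / 2
      list(bounds = c(b, T_E), N = c(N_C * exp(-r * mid), N_A))
    }))
}

# Waiting time to the next event from time `t`, under coalescent hazard
# pairs/(2 N(t)) plus a constant competing rate `extra`.  Returns the event
# time and whether the event is a coalescence.
.next_event <- function(t, pairs, traj, extra = 0) {
  target <- stats::rexp(1L)
  nb <- length(traj$bounds)
  ep <- findInterval(t, traj$bounds)
  repeat {
    coal <- pairs / (2 * traj$N[ep])
    rate <- coal + extra
    upper <- if (ep < nb) traj$bounds[ep + 1L] else Inf
    span <- upper - t
    if (rate * span >= target) {
      t <- t + target / rate
      return(list(t = t, coal = stats::runif(1L) < coal / rate))
    }
    target <- target - rate * span
    t <- upper
    ep <- ep + 1L
  }
}

# Fast path (rho = 0): simulate the genealogy of n lineages, returning the
# per-edge durations and descendant-leaf counts.
.sim_tree_edges <- function(n, traj) {
  birth <- numeric(2L * n - 1L)
  count <- c(rep(1L, n), integer(n - 1L))
  dur <- numeric(2L * n - 2L)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    ev <- .next_event(t, k * (k - 1) / 2, traj)
    t <- ev$t
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    dur[a] <- t - birth[a]; dur[b] <- t - birth[b]
    birth[nxt] <- t
    count[nxt] <- count[a] + count[b]
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(dur = dur, count = count[seq_len(2L * n - 2L)])
}

# Merge two ARG segment matrices (columns s, e, count), adding carrier counts
# on overlap and dropping intervals whose count reaches n (local MRCA).
.merge_segs <- function(a, b, n) {
  if (nrow(a) == 1L && nrow(b) == 1L &&
      a[1L, 1L] == b[1L, 1L] && a[1L, 2L] == b[1L, 2L]) {
    cnt <- a[1L, 3L] + b[1L, 3L]           # fully overlapping single segments
    if (cnt >= n) return(NULL)
    a[1L, 3L] <- cnt
    return(a)
  }
  pts <- sort(unique(c(a[, 1L], a[, 2L], b[, 1L], b[, 2L])))
  s <- pts[-length(pts)]; e <- pts[-1L]
  mid <- (s + e) / 2
  cnt <- numeric(length(mid))
  for (m in list(a, b))
    for (i in seq_len(nrow(m))) {
      in_seg <- mid >= m[i, 1L] & mid < m[i, 2L]
      cnt[in_seg] <- cnt[in_seg] + m[i, 3L]
    }
  keep <- cnt > 0 & cnt < n
  if (!any(keep)) return(NULL)
  s <- s[keep]; e <- e[keep]; cnt <- cnt[keep]
  # coalesce adjacent runs with equal count
  brk <- c(TRUE, s[-1L] != e[-length(e)] | cnt[-1L] != cnt[-length(cnt)])
  idx <- which(brk)
  last <- c(idx[-1L] - 1L, length(s))
  cbind(s = s[idx], e = e[last], count = cnt[idx])
}

#' Simulate one locus under a demographic model
#'
#' Draws a neutral coalescent genealogy of `n` lineages under the model's
#' size trajectory, places infinite-sites mutations as a Poisson process with
#' rate `mu` per site per generation along branches, and (when `rho > 0`)
#' threads recombination through the ancestral recombination graph.  Returns
#' the realized number of segregating sites and per-site mean pairwise
#' difference.
#'
#' @param model A [demographic_model()].
#' @param mu Mutation rate per site per generation.
#' @param rho Recombination rate per site per generation.
#' @param n Number of sampled haplotypes.
#' @param L Number of sites.
#' @param seed Optional integer seed.
#' @return List with `S` (integer) and `pi` (per-site).
#' @export
simulate_locus <- function(model, mu, rho, n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 2, L >= 1, mu >= 0, rho >= 0)
  traj <- size_trajectory(model)
  npair <- n * (n - 1) / 2
  # The ARG is bypassed when the expected number of recombination events on
  # the genealogy (~ rho * L * 4 * N_max * H_{n-1}) is below 0.01: the
  # marginal effect on the summaries is then far below Monte Carlo noise.
  exp_rec <- rho * L * 4 * max(traj$N) * sum(1 / seq_len(n - 1))
  # In the high-recombination regime adjacent blocks are nearly independent;
  # the locus is split so each block carries a bounded expected number of
  # recombination events and blocks are simulated as independent ARGs.
  if (exp_rec > 10) {
    m <- ceiling(exp_rec / 5)
    sizes <- diff(round(seq(0, L, length.out = m + 1L)))
    sizes <- sizes[sizes > 0]
    S <- 0L; pi_sum <- 0
    for (Lb in sizes) {
      r <- simulate_locus(model, mu, rho, n, Lb)
      S <- S + r$S
      pi_sum <- pi_sum + r$pi * Lb
    }
    return(list(S = S, pi = pi_sum / sum(sizes)))
  }
  if (rho == 0 || exp_rec < 0.01) {
    res <- .cpp_sim_tree(n, mu, L, traj$bounds, traj$N)
    return(list(S = as.integer(res$S), pi = res$pi))
  }
  res <- .cpp_sim_arg(n, mu, rho, L, traj$bounds, traj$N)
  list(S = as.integer(res$S), pi = res$pi)
}

# Reference R implementation of the locus simulator (used as an independent
# cross-check of the compiled core in the tests).
.r_simulate_locus <- function(model, mu, rho, n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traj <- size_trajectory(model)
  npair <- n * (n - 1) / 2
  if (rho == 0) {
    tr <- .sim_tree_edges(n, traj)
    cnt <- stats::rpois(length(tr$dur), mu * L * tr$dur)
    S <- sum(cnt)
    pi <- sum(cnt * tr$count * (n - tr$count)) / npair / L
    return(list(S = as.integer(S), pi = pi))
  }
  # ARG path: mutations are drawn per lineage at its death (its segments are
  # constant over its lifetime), so per-event work stays O(1)-ish.
  lineages <- lapply(seq_len(n), function(i) cbind(s = 0, e = L, count = 1))
  births <- numeric(n)
  spans <- rep.int(as.numeric(L), n)
  t <- 0
  S <- 0L; pi_num <- 0
  kill <- function(idx, at) {
    m <- lineages[[idx]]
    lens <- m[, 2L] - m[, 1L]
    cnt <- stats::rpois(length(lens), mu * (at - births[idx]) * lens)
    S <<- S + sum(cnt)
    pi_num <<- pi_num + sum(cnt * m[, 3L] * (n - m[, 3L]))
  }
  while (length(lineages) >= 2L) {
    k <- length(lineages)
    ev <- .next_event(t, k * (k - 1) / 2, traj, extra = rho * sum(spans))
    t <- ev$t
    if (ev$coal) {
      pick <- sample.int(k, 2L)
      kill(pick[1L], t); kill(pick[2L], t)
      merged <- .merge_segs(lineages[[pick[1L]]], lineages[[pick[2L]]], n)
      lineages <- lineages[-pick]
      births <- births[-pick]; spans <- spans[-pick]
      if (!is.null(merged)) {
        lineages <- c(lineages, list(merged))
        births <- c(births, t)
        spans <- c(spans, max(merged[, 2L]) - min(merged[, 1L]))
      }
    } else {
      li <- sample.int(k, 1L, prob = spans)
      kill(li, t)
      m <- lineages[[li]]
      x <- stats::runif(1L, min(m[, 1L]), max(m[, 2L]))
      left <- m[m[, 1L] < x, , drop = FALSE]
      left[left[, 2L] > x, 2L] <- x
      right <- m[m[, 2L] > x, , drop = FALSE]
      right[right[, 1L] < x, 1L] <- x
      lineages[[li]] <- NULL
      births <- births[-li]; spans <- spans[-li]
      for (part in list(left, right)) if (nrow(part) > 0L) {
        lineages <- c(lineages, list(part))
        births <- c(births, t)
        spans <- c(spans, max(part[, 2L]) - min(part[, 1L]))
      }
    }
  }
  # material still carried by a surviving lineage cannot exist: every
  # non-MRCA site is ancestral to >= 2 lineages, so the loop exits clean.
  list(S = as.integer(S), pi = pi_num / npair / L)
}
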