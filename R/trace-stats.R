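# Empirical stationary moment estimation from event-driven voltage traces,
# using the closed-form inter-event integrals of the piecewise-exponential
# trace, with block-bootstrap standard errors.

# Voltage state of every neuron at an arbitrary time t (exact relaxation
# from the last stored post-event voltage; resting level before the first
# event). Uncoupled traces only.
state_at <- function(trace, t) {
  k <- findInterval(t, trace$times)
  n <- ncol(trace$V)
  v <- numeric(n)
  for (a in seq_len(n)) {
    p <- trace$params[[a]]
    v0 <- if (k == 0) p$Irest else trace$V[k, a]
    t0 <- if (k == 0) 0 else trace$times[k]
    v[a] <- p$Irest + (v0 - p$Irest) * exp(-(t - t0) / p$tau)
  }
  v
}

#' Empirical shifted stationary moment of a voltage trace
#'
#' Estimates `mu_A = (1/T) integral prod_{a in A} (V_a(t) - I_a/G_a) dt`
#' over `[t_start, t_end]` using the exact closed form of the
#' piecewise-exponential trace: on each inter-event interval the product
#' decays as `exp(-lambda (t - Tn))` with `lambda = sum_{a in A} 1/tau_a`
#' (repeats counted), so
#' `mu = (1/(lambda T)) sum_n P_n (1 - exp(-lambda dT_n))` with
#' `P_n = prod_a (V_{a,n} - I_a/G_a)` and the final partial interval
#' included (convention `T_{N+1} = t_end`). No quadrature error beyond
#' floating point. Gap-junction-coupled traces (whose products are not
#' single exponentials) fall back to dense trapezoid quadrature.
#'
#' @param trace A `voltage_trace`.
#' @param labels Multiset of neuron indices/labels (repeats allowed).
#' @param t_start Start of the averaging window; defaults to a burn-in of
#'   `20 * tau`.
#' @param t_end End of the window (default: trace duration).
#' @return The shifted moment estimate (mV^order).
#' @export
empirical_shifted_moment <- function(trace, labels,
                                     t_start = 20 * trace$params[[1]]$tau,
                                     t_end = trace$T) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (t_end <= t_start) {
    stop("trace shorter than the burn-in: nothing to average")
  }
  idx <- label_index(trace, labels)
  if (trace$coupling > 0) {
    return(quadrature_moment(trace, idx, t_start, t_end))
  }
  taus <- vapply(trace$params, function(p) p$tau, numeric(1))
  irest <- vapply(trace$params, function(p) p$Irest, numeric(1))
  lambda <- sum(1 / taus[idx])
  inwin <- which(trace$times > t_start & trace$times <= t_end)
  starts <- c(t_start, trace$times[inwin])
  ends <- c(trace$times[inwin], t_end)
  P <- rep(1, length(starts))
  v_start <- state_at(trace, t_start)
  for (a in idx) {
    col <- c(v_start[a], trace$V[inwin, a]) - irest[a]
    P <- P * col
  }
  sum(P * (1 - exp(-lambda * (ends - starts)))) /
    (lambda * (t_end - t_start))
}

label_index <- function(trace, labels) {
  n <- ncol(trace$V)
  if (is.character(labels)) {
    stop("voltage traces index neurons by position; pass integer indices")
  }
  idx <- as.integer(labels)
  if (any(idx < 1 | idx > n)) stop("neuron index out of range")
  idx
}

quadrature_moment <- function(trace, idx, t_start, t_end, per_tau = 200) {
  tau <- min(vapply(trace$params, function(p) p$tau, numeric(1)))
  tg <- seq(t_start, t_end, by = tau / per_tau)
  V <- trace_at_times(trace, tg)
  irest <- vapply(trace$params, function(p) p$Irest, numeric(1))
  f <- rep(1, length(tg))
  for (a in idx) f <- f * (V[, a] - irest[a])
  # trapezoid; jumps inside grid cells contribute O(dt) which the fine grid
  # controls
  sum((f[-1] + f[-length(f)]) / 2 * diff(tg)) / (t_end - t_start)
}

# All shifted moments needed by the summary (per neuron m1, m2, m3; per
# pair m11), evaluated per block in one vectorized pass over the trace.
# Returns a (n_blocks x n_moments) matrix with named columns.
block_moment_matrix <- function(trace, edges) {
  if (trace$coupling > 0) {
    return(block_moment_matrix_grid(trace, edges))
  }
  n <- ncol(trace$V)
  taus <- vapply(trace$params, function(p) p$tau, numeric(1))
  irest <- vapply(trace$params, function(p) p$Irest, numeric(1))
  nb <- length(edges) - 1
  lo <- edges[1]
  hi <- edges[nb + 1]
  sel <- which(trace$times > lo & trace$times <= hi)
  t_ev <- trace$times[sel]
  U_ev <- sweep(trace$V[sel, , drop = FALSE], 2, irest)
  # shifted state at every block edge (exact relaxation from the previous
  # stored post-event voltage)
  U_edge <- do.call(rbind, lapply(edges[-(nb + 1)], function(e) {
    state_at(trace, e) - irest
  }))
  t_seg <- c(edges[-(nb + 1)], t_ev)
  U_seg <- rbind(U_edge, U_ev)
  ord <- order(t_seg)
  t_seg <- t_seg[ord]
  U_seg <- U_seg[ord, , drop = FALSE]
  dt <- c(t_seg[-1], hi) - t_seg
  block <- findInterval(t_seg, edges)
  block[block > nb] <- nb
  blen <- diff(edges)
  multisets <- list()
  for (a in seq_len(n)) {
    multisets[[paste0("m1_", a)]] <- a
    multisets[[paste0("m2_", a)]] <- c(a, a)
    multisets[[paste0("m3_", a)]] <- c(a, a, a)
  }
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        multisets[[paste0("m11_", a, "_", b)]] <- c(a, b)
      }
    }
  }
  out <- matrix(0, nb, length(multisets),
                dimnames = list(NULL, names(multisets)))
  for (j in seq_along(multisets)) {
    ms <- multisets[[j]]
    lambda <- sum(1 / taus[ms])
    P <- rep(1, nrow(U_seg))
    for (a in ms) P <- P * U_seg[, a]
    contrib <- P * (1 - exp(-lambda * dt)) / lambda
    sums <- rowsum(contrib, block)
    out[as.integer(rownames(sums)), j] <- sums[, 1]
    out[, j] <- out[, j] / blen
  }
  out
}

stats_from_moments <- function(mom, n, irest) {
  means <- vars <- skews <- numeric(n)
  for (a in seq_len(n)) {
    m1 <- mom[[paste0("m1_", a)]]
    m2 <- mom[[paste0("m2_", a)]]
    m3 <- mom[[paste0("m3_", a)]]
    means[a] <- m1 + irest[a]
    vars[a] <- m2 - m1^2
    third <- m3 - 3 * m2 * m1 + 2 * m1^3
    skews[a] <- if (vars[a] > 0) third / vars[a]^1.5 else NA_real_
  }
  covm <- diag(vars, n)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        cv <- mom[[paste0("m11_", a, "_", b)]] -
          mom[[paste0("m1_", a)]] * mom[[paste0("m1_", b)]]
        covm[a, b] <- covm[b, a] <- cv
      }
    }
  }
  corm <- stats::cov2cor(covm)
  list(mean = means, variance = vars, covariance = covm,
       correlation = corm, skewness = skews)
}

# Vectorized exact evaluation of a coupled pair trace on a time grid.
sample_pair_grid <- function(trace, tg) {
  k <- findInterval(tg, trace$times)
  pl <- trace$params
  tau <- pl[[1]]$tau
  g <- trace$coupling
  i1 <- pl[[1]]$Irest
  i2 <- pl[[2]]$Irest
  v01 <- ifelse(k == 0, i1, trace$V[pmax(k, 1), 1])
  v02 <- ifelse(k == 0, i2, trace$V[pmax(k, 1), 2])
  t0 <- ifelse(k == 0, 0, trace$times[pmax(k, 1)])
  dt <- tg - t0
  s_star <- (i1 + i2) / 2
  d_star <- (i1 - i2) / (2 * (1 + 2 * g))
  s <- s_star + ((v01 + v02) / 2 - s_star) * exp(-dt / tau)
  d <- d_star + ((v01 - v02) / 2 - d_star) * exp(-dt * (1 + 2 * g) / tau)
  cbind(s + d, s - d)
}

# Grid-based per-block moments for gap-junction-coupled traces, whose
# inter-event relaxation mixes two exponentials (the closed-form single
# exponential integral does not apply). Midpoint rule at tau/100.
block_moment_matrix_grid <- function(trace, edges) {
  n <- ncol(trace$V)
  stopifnot(n == 2)
  irest <- vapply(trace$params, function(p) p$Irest, numeric(1))
  nb <- length(edges) - 1
  blen <- diff(edges)
  dt_g <- trace$params[[1]]$tau / 100
  tg <- seq(edges[1] + dt_g / 2, edges[nb + 1], by = dt_g)
  Vg <- sample_pair_grid(trace, tg)
  U <- sweep(Vg, 2, irest)
  block <- pmin(findInterval(tg, edges), nb)
  cols <- list(m1_1 = U[, 1], m2_1 = U[, 1]^2, m3_1 = U[, 1]^3,
               m1_2 = U[, 2], m2_2 = U[, 2]^2, m3_2 = U[, 2]^3,
               m11_1_2 = U[, 1] * U[, 2])
  out <- matrix(0, nb, length(cols), dimnames = list(NULL, names(cols)))
  cnt <- tabulate(block, nbins = nb)
  for (j in seq_along(cols)) {
    out[, j] <- rowsum(cols[[j]], block)[, 1] / cnt
  }
  out
}

#' Empirical summary statistics of a voltage trace
#'
#' Means, variances, covariance and correlation matrices, and skewness per
#' neuron, estimated from the exact inter-event integrals after burn-in,
#' with block-bootstrap standard errors (the window is cut into contiguous
#' blocks whose per-block moment estimates are resampled with replacement).
#'
#' @param trace A `voltage_trace`.
#' @param burn_in Discarded initial stretch (seconds, default `20 * tau`).
#' @param block_len Bootstrap block length (seconds, default `100 * tau`).
#' @param n_boot Bootstrap replicates (default 200; 0 skips the bootstrap).
#' @param seed Seed for the bootstrap resampling.
#' @return A list with `estimate` (list: mean, variance, covariance,
#'   correlation, skewness), `se` (same shapes, bootstrap SEs), `n_events`,
#'   `T_effective`, `n_blocks`.
#' @export
empirical_summary <- function(trace,
                              burn_in = 20 * trace$params[[1]]$tau,
                              block_len = 100 * trace$params[[1]]$tau,
                              n_boot = 200, seed = 1) {
  stopifnot(inherits(trace, "voltage_trace"))
  n <- ncol(trace$V)
  irest <- vapply(trace$params, function(p) p$Irest, numeric(1))
  if (trace$T - burn_in < 2 * block_len) {
    stop("trace too short for the requested burn-in and block length")
  }
  nb <- floor((trace$T - burn_in) / block_len)
  edges <- burn_in + block_len * (0:nb)
  block_mom <- block_moment_matrix(trace, edges)
  overall <- colMeans(block_mom)
  est <- stats_from_moments(as.list(overall), n, irest)
  se <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    draws <- vapply(seq_len(n_boot), function(bb) {
      pick <- sample.int(nb, nb, replace = TRUE)
      st <- stats_from_moments(as.list(colMeans(block_mom[pick, ,
                                                          drop = FALSE])),
                               n, irest)
      c(st$mean, st$variance, st$skewness,
        st$covariance[upper.tri(st$covariance)],
        st$correlation[upper.tri(st$correlation)])
    }, numeric(3 * n + 2 * n * (n - 1) / 2))
    sds <- apply(draws, 1, stats::sd)
    npair <- n * (n - 1) / 2
    se <- list(
      mean = sds[seq_len(n)],
      variance = sds[n + seq_len(n)],
      skewness = sds[2 * n + seq_len(n)],
      covariance = if (npair) sds[3 * n + seq_len(npair)] else numeric(0),
      correlation = if (npair) {
        sds[3 * n + npair + seq_len(npair)]
      } else {
        numeric(0)
      }
    )
  }
  list(estimate = est, se = se, n_events = sum(trace$times > burn_in),
       T_effective = nb * block_len, n_blocks = nb)
}
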