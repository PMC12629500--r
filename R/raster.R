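# Correlated spike-raster generation via beta-marginal / Gaussian-copula
# mixing, spike-time jittering, and conversion to synaptic event trains.

#' Beta-marginal parameters for the copula raster generator
#'
#' Within a homogeneous block, per-bin activation probabilities `theta` are
#' drawn from a beta distribution whose mean is exactly `r * dt` and whose
#' overdispersion realizes the within-block spiking correlation `rho`:
#' `alpha = r*dt*(1/rho - 1)`, `beta = (1 - r*dt)*(1/rho - 1)`.
#'
#' @param r Per-input rate (Hz).
#' @param rho Within-block spiking correlation, strictly inside `(0, 1)`
#'   (the limits are handled by dedicated thinning/Bernoulli branches of the
#'   sampler, not by beta parameters).
#' @param dt Bin width (seconds), with `r * dt < 1`.
#' @return A list with `alpha` and `beta`.
#' @examples
#' beta_marginal_params(10, 0.5, 1e-4) # alpha = 1e-3, beta = 0.999
#' @export
beta_marginal_params <- function(r, rho, dt) {
  stopifnot(r > 0, dt > 0, r * dt < 1)
  if (rho <= 0 || rho >= 1) {
    stop("rho must lie strictly in (0, 1); the limits are special-cased")
  }
  s <- 1 / rho - 1
  list(alpha = r * dt * s, beta = (1 - r * dt) * s)
}

# quantile function of the per-block mixing variable theta given uniform u
theta_quantile <- function(u, r, rho, dt) {
  if (rho == 0) {
    rep(r * dt, length(u))
  } else if (rho >= 1) {
    as.numeric(u < r * dt) # Bernoulli mixing limit
  } else {
    bp <- beta_marginal_params(r, rho, dt)
    stats::qbeta(u, bp$alpha, bp$beta)
  }
}

# E[theta_i theta_j] under a bivariate Gaussian copula with correlation sig,
# by Gauss-Legendre quadrature on the Gaussian scale.
copula_cross_moment <- function(sig, r1, rho1, r2, rho2, dt, n_nodes = 64) {
  gl <- pracma::gaussLegendre(n_nodes, -8, 8)
  f1 <- theta_quantile(stats::pnorm(gl$x), r1, rho1, dt)
  f2 <- theta_quantile(stats::pnorm(gl$x), r2, rho2, dt)
  if (abs(sig) < 1e-14) {
    return(sum(gl$w * f1 * stats::dnorm(gl$x)) *
             sum(gl$w * f2 * stats::dnorm(gl$x)))
  }
  # density of (z1, z2) with correlation sig
  z1 <- matrix(gl$x, n_nodes, n_nodes)
  z2 <- t(z1)
  det <- 1 - sig^2
  dens <- exp(-(z1^2 - 2 * sig * z1 * z2 + z2^2) / (2 * det)) /
    (2 * pi * sqrt(det))
  w2 <- gl$w %o% gl$w
  sum(w2 * (f1 %o% f2) * dens)
}

#' Calibrate the Gaussian-copula correlation matrix
#'
#' Finds the unit-diagonal matrix `Sigma` of Gaussian-copula correlations
#' such that the per-bin mixing variables satisfy
#' `E[theta_i theta_j] = r_i * r_j * rho_ij * dt` for every cross-block pair,
#' by one-dimensional root finding on the bivariate copula moment (evaluated
#' by two-dimensional Gauss-Legendre quadrature).
#'
#' @param corr A [correlation_spec()] across `L` blocks.
#' @param rates Per-block per-input rates (Hz), length `L`.
#' @param dt Bin width (seconds).
#' @return `L x L` copula correlation matrix.
#' @export
calibrate_copula_sigma <- function(corr, rates, dt) {
  stopifnot(inherits(corr, "correlation_spec"))
  L <- corr$L
  rates <- rep_len(rates, L)
  rho <- corr$block_rho
  Sigma <- diag(L)
  if (L < 2) return(Sigma)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (rho[i, j] == 0) next
      # consistency with the within-block marginals (E[theta_i^2] ~
      # rho_ii * r_i * dt) requires the sqrt-rate normalization
      target <- sqrt(rates[i] * rates[j]) * rho[i, j] * dt
      mom <- function(s) {
        copula_cross_moment(s, rates[i], rho[i, i], rates[j], rho[j, j], dt) -
          target
      }
      hi <- 1 - 1e-9
      if (mom(hi) < 0) {
        stop(sprintf(
          "cross-block correlation [%d,%d] infeasible: requires sigma > 1",
          i, j
        ))
      }
      root <- stats::uniroot(mom, c(0, hi), tol = 1e-10)$root
      Sigma[i, j] <- Sigma[j, i] <- root
    }
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("calibrated copula matrix is not positive semidefinite; ",
         "reduce the cross-block correlations toward sqrt(rho_ii * rho_jj)")
  }
  Sigma
}

#' Sample a correlated spike raster
#'
#' Per time bin of width `dt`, draws a Gaussian vector with the calibrated
#' copula correlation, maps it through the normal CDF and the per-block
#' inverse beta CDFs to mixing probabilities `theta_i`, and draws binomial
#' counts `(K_i, theta_i)`. Bins are i.i.d., so per-bin mean counts are
#' exactly `K_i r_i dt` and within-block pairwise spiking correlations are
#' `rho_ii + o(dt)`.
#'
#' @param corr A [correlation_spec()] (one block per pool).
#' @param pools List of [input_pool()]s, uniform within each block.
#' @param dt Bin width (seconds); default 1e-4.
#' @param T Duration (seconds).
#' @param seed Integer seed (required for reproducibility).
#' @return An object of class `spike_raster`: list with `counts`
#'   (`L x Nbins` integer matrix), `dt`, `T`, `pools`, `corr`.
#' @export
sample_raster <- function(corr, pools, dt = 1e-4, T, seed) {
  stopifnot(inherits(corr, "correlation_spec"), T > 0, dt > 0)
  L <- length(pools)
  stopifnot(L == corr$L)
  for (pl in pools) {
    if (!pool_is_uniform(pl)) {
      stop("raster blocks must be uniform pools (single w, r per block)")
    }
  }
  set.seed(seed)
  nbins <- floor(T / dt)
  rates <- vapply(pools, function(p) p$r[1], numeric(1))
  Ks <- vapply(pools, function(p) p$K, integer(1))
  rho <- corr$block_rho
  need_copula <- L > 1 && any(rho[upper.tri(rho)] > 0)
  counts <- matrix(0L, L, nbins)
  if (need_copula) {
    Sigma <- calibrate_copula_sigma(corr, rates, dt)
    Cchol <- chol(Sigma + diag(1e-12, L))
    Z <- matrix(stats::rnorm(L * nbins), nbins, L) %*% Cchol
    U <- stats::pnorm(Z)
    for (i in seq_len(L)) {
      theta <- theta_quantile(U[, i], rates[i], rho[i, i], dt)
      counts[i, ] <- stats::rbinom(nbins, Ks[i], theta)
    }
  } else {
    for (i in seq_len(L)) {
      theta <- theta_quantile(stats::runif(nbins), rates[i], rho[i, i], dt)
      counts[i, ] <- stats::rbinom(nbins, Ks[i], theta)
    }
  }
  structure(
    list(counts = counts, dt = dt, T = nbins * dt, pools = pools,
         corr = corr),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "spike_raster: %d block(s), %d bins of %g s (T = %g s), %d spikes\n",
    nrow(x$counts), ncol(x$counts), x$dt, x$T, sum(x$counts)
  ))
  invisible(x)
}

#' Disaggregate raster counts into per-input spike trains
#'
#' Within each block, per-bin counts `k` are assigned to `k` inputs chosen
#' uniformly at random (the exchangeable allocation consistent with the
#' beta-binomial mixing). Spike times are the bin right edges.
#'
#' @param raster A [sample_raster()] output.
#' @param block Block index.
#' @param seed Integer seed for the random allocation.
#' @return A list of `K` numeric vectors of spike times (seconds).
#' @export
raster_to_trains <- function(raster, block = 1L, seed) {
  stopifnot(inherits(raster, "spike_raster"))
  set.seed(seed)
  K <- raster$pools[[block]]$K
  cnt <- raster$counts[block, ]
  trains <- vector("list", K)
  active <- which(cnt > 0)
  picks <- lapply(active, function(j) sample.int(K, cnt[j]))
  tms <- active * raster$dt
  for (idx in seq_along(active)) {
    for (k in picks[[idx]]) {
      trains[[k]] <- c(trains[[k]], tms[idx])
    }
  }
  lapply(trains, function(v) if (is.null(v)) numeric(0) else v)
}

#' Jitter spike times by independent Gaussian shifts
#'
#' Adds i.i.d. `N(0, sigmaJ^2)` offsets to every spike time. Spikes shifted
#' outside `[0, T)` are wrapped periodically, preserving the total count and
#' the stationary rate.
#'
#' @param spikes Numeric vector of spike times, or a list of such vectors.
#' @param sigmaJ Jitter standard deviation (seconds); 0 is the identity.
#' @param T Recording duration for the periodic wrap (seconds).
#' @param seed Integer seed.
#' @return Jittered spikes, same shape as the input, each train sorted.
#' @export
jitter_spikes <- function(spikes, sigmaJ, T, seed) {
  stopifnot(sigmaJ >= 0, T > 0)
  set.seed(seed)
  one <- function(v) {
    if (length(v) == 0 || sigmaJ == 0) return(sort(v))
    sort((v + stats::rnorm(length(v), 0, sigmaJ)) %% T)
  }
  if (is.list(spikes)) lapply(spikes, one) else one(spikes)
}

#' Empirical spike-count correlation at a timescale
#'
#' Pearson correlation of the spike counts of two trains in disjoint windows
#' of the given width, the timescale-dependent spiking correlation measured
#' from data.
#'
#' @param spikes_i,spikes_j Spike-time vectors (seconds).
#' @param window Window width (seconds).
#' @param T Recording duration (seconds); needs `T >= 100 * window`.
#' @return Pearson correlation coefficient.
#' @export
empirical_count_correlation <- function(spikes_i, spikes_j, window, T) {
  stopifnot(window > 0, T > 0)
  nwin <- floor(T / window)
  if (nwin < 100) stop("recording too short: need at least 100 windows")
  breaks <- seq(0, nwin * window, by = window)
  ci <- graphics::hist(spikes_i[spikes_i < nwin * window], breaks = breaks,
                       plot = FALSE)$counts
  cj <- graphics::hist(spikes_j[spikes_j < nwin * window], breaks = breaks,
                       plot = FALSE)$counts
  if (stats::sd(ci) == 0 || stats::sd(cj) == 0) {
    stop("undefined correlation: zero-variance counts")
  }
  stats::cor(ci, cj)
}

#' Convert a spike raster to a synaptic event train
#'
#' Every bin with at least one spike among the blocks driving the neuron set
#' becomes ONE synaptic event at the bin's right edge (simultaneous spikes in
#' one bin form a single event); jump components are the count-weighted sums
#' `We_a = sum_i k_i * w_{i,a}` over excitatory blocks (likewise inhibitory).
#'
#' @param raster A [sample_raster()] output.
#' @param weight_map List (one entry per block) of lists
#'   `list(kind = "e"|"i", w = per-neuron weight vector)`; defaults to each
#'   block driving a single neuron with its pool kind and weight.
#' @return An [event_train()].
#' @export
raster_to_events <- function(raster, weight_map = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  L <- nrow(raster$counts)
  if (is.null(weight_map)) {
    weight_map <- lapply(raster$pools, function(p) {
      list(kind = p$kind, w = p$w[1])
    })
  }
  stopifnot(length(weight_map) == L)
  n <- length(weight_map[[1]]$w)
  for (wm in weight_map) {
    if (length(wm$w) != n) stop("weight vectors must share one neuron count")
    if (!wm$kind %in% c("e", "i")) {
      stop("each block must map to a single sign per neuron ('e' or 'i')")
    }
  }
  tot <- colSums(raster$counts)
  act <- which(tot > 0)
  times <- act * raster$dt
  We <- matrix(0, length(act), n)
  Wi <- matrix(0, length(act), n)
  for (i in seq_len(L)) {
    k <- raster$counts[i, act]
    contrib <- k %o% weight_map[[i]]$w
    if (weight_map[[i]]$kind == "e") We <- We + contrib else Wi <- Wi + contrib
  }
  event_train(times, We, Wi, T = raster$T)
}

#' Synaptic event train
#'
#' Ordered synaptic-event times with per-event, per-neuron dimensionless
#' jump components. The native drive representation of the event-driven
#' simulator.
#'
#' @param times Strictly increasing event times (seconds).
#' @param We,Wi Jump matrices (events x neurons); vectors are single-neuron.
#' @param T Nominal duration covered (defaults to the last event time).
#' @return An object of class `event_train`.
#' @export
event_train <- function(times, We, Wi = NULL, T = NULL) {
  We <- as_jump_matrix(We)
  if (is.null(Wi)) Wi <- matrix(0, nrow(We), ncol(We))
  Wi <- as_jump_matrix(Wi)
  stopifnot(all(dim(We) == dim(Wi)), length(times) == nrow(We))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("event times must be strictly increasing")
  }
  if (length(times) > 0 && (any(We < 0) || any(Wi < 0))) {
    stop("jump components must be >= 0")
  }
  if (length(times) > 0 && any(rowSums(We) + rowSums(Wi) <= 0)) {
    stop("every event must carry a positive jump for at least one neuron")
  }
  if (is.null(T)) T <- if (length(times)) max(times) else 0
  structure(list(times = as.numeric(times), We = We, Wi = Wi, T = T),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("event_train: %d events over %g s, %d neuron(s)\n",
              length(x$times), x$T, ncol(x$We)))
  invisible(x)
}
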