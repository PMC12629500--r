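# Exact stationary mixed voltage moments of AONCB neurons driven by a
# compound Poisson synaptic drive (PASTA-based recursion), plus the
# closed-form special cases and small-weight approximations.

# Per-atom auxiliary variables of neuron a: the post-jump contraction
# Y = exp(-(We + Wi)) and the shifted mixed reversal
# R' = (We*Ve + Wi*Vi)/(We + Wi) - I/G (set to 0 for empty jumps, where it
# is multiplied by 1 - Y = 0 anyway).
atom_aux <- function(jm, a, p) {
  We <- jm$We[, a]
  Wi <- jm$Wi[, a]
  Wtot <- We + Wi
  Y <- exp(-Wtot)
  Vmix <- ifelse(Wtot > 0, (We * p$Ve + Wi * p$Vi) / pmax(Wtot, 1e-300), 0)
  Rp <- ifelse(Wtot > 0, Vmix - p$Irest, 0)
  list(Y = Y, Rp = Rp, Vmix = Vmix)
}

# Reduce a sampler-backed model to an equal-weight atom model by seeded
# Monte Carlo (flagged via the "approx" attribute).
as_atom_model <- function(jm, n_draws = 1e5, seed = NULL) {
  if (jm$backend == "atoms") return(jm)
  if (is.null(seed)) stop("sampler-backed models require an explicit seed")
  draws <- jm$sampler(n_draws, seed)
  out <- jump_model(jm$b, draws$We, draws$Wi,
                    prob = rep(1 / n_draws, n_draws), labels = jm$labels)
  attr(out, "approx") <- TRUE
  out
}

#' Rate coefficients of the stationary mean
#'
#' The excitatory and inhibitory rate coefficients
#' `c_alpha = b * E[W_alpha/(We + Wi) * (1 - exp(-(We + Wi)))]` entering the
#' stationary-mean formula. Their sum is `b * E[1 - Y]`, the effective
#' synaptic relaxation rate.
#'
#' @param jm Single-neuron [jump_model()].
#' @param params A [neuron_params()].
#' @param ... Passed to [as_atom_model()] reduction for sampler backends
#'   (`n_draws`, `seed`).
#' @return List with `ce` and `ci` (Hz).
#' @export
rate_coefficients <- function(jm, params, ...) {
  jm <- as_atom_model(jm, ...)
  We <- jm$We[, 1]
  Wi <- jm$Wi[, 1]
  Wtot <- We + Wi
  fac <- ifelse(Wtot > 0, (1 - exp(-Wtot)) / pmax(Wtot, 1e-300), 0)
  list(ce = jm$b * sum(jm$prob * We * fac),
       ci = jm$b * sum(jm$prob * Wi * fac))
}

#' Exact stationary mean voltage
#'
#' `m = (I/(G*tau) + ce*Ve + ci*Vi) / (1/tau + ce + ci)` with the rate
#' coefficients of [rate_coefficients()]; a drive-rate-weighted average of
#' the resting level and the reversal potentials, always inside `(Vi, Ve)`
#' for `I = 0`.
#'
#' @inheritParams rate_coefficients
#' @return Mean voltage (mV).
#' @export
stationary_mean <- function(jm, params, ...) {
  rc <- rate_coefficients(jm, params, ...)
  (params$Irest / params$tau + rc$ce * params$Ve + rc$ci * params$Vi) /
    (1 / params$tau + rc$ce + rc$ci)
}

# ---- general moment engine ---------------------------------------------

#' Exact stationary shifted mixed moment of arbitrary order
#'
#' Solves the triangular fixed-point system implied by the PASTA principle
#' for the shifted moments `mu_A = E[prod_{a in A} (V_a - I_a/G_a)]` of a
#' multiset `A` of neuron labels:
#' `mu_A * (sum_a 1/tau_a + b * E[1 - prod_a Y_a]) =
#'  b * sum_{B proper subset of A} mu_B *
#'  E[prod_{a in B} Y_a * prod_{a not in B} R'_a (1 - Y_a)]`,
#' with `mu_{} = 1`, iterating bottom-up over sub-multisets. Order 1
#' reproduces the stationary mean; order 2 the covariance; order 3 the
#' compact third-moment form.
#'
#' @param jm A [jump_model()] over the neuron set.
#' @param params One [neuron_params()] or a list, one per neuron of `jm`.
#' @param labels Multiset of neuron labels (repeats allowed), e.g.
#'   `c("1", "1", "2")` for `E[U1^2 U2]`.
#' @param max_order Guard on the moment order (default 6; the sub-multiset
#'   lattice grows combinatorially).
#' @param ... Sampler-backend reduction options (`n_draws`, `seed`).
#' @return The shifted moment (mV^order).
#' @export
general_mixed_moment <- function(jm, params, labels, max_order = 6, ...) {
  jm <- as_atom_model(jm, ...)
  n <- length(labels)
  if (n < 1) stop("need at least one label")
  if (n > max_order) {
    stop(sprintf("order %d exceeds max_order = %d", n, max_order))
  }
  idx <- match(as.character(labels), jm$labels)
  if (anyNA(idx)) stop("unknown neuron label")
  engine <- moment_engine(jm, as_params_list(params, length(jm$labels)))
  counts <- tabulate(idx, nbins = length(jm$labels))
  engine$mu(counts)
}

# Closure holding the memoized recursion over label-count vectors.
moment_engine <- function(jm, params_list) {
  nlab <- length(jm$labels)
  aux <- lapply(seq_len(nlab), function(a) atom_aux(jm, a, params_list[[a]]))
  taus <- vapply(params_list, function(p) p$tau, numeric(1))
  b <- jm$b
  prob <- jm$prob
  memo <- new.env(parent = emptyenv())

  # E[prod_a Y_a^{k_a} * (R'_a (1 - Y_a))^{c_a - k_a}] over atoms
  eprod <- function(k, cvec) {
    v <- prob
    for (a in seq_len(nlab)) {
      if (k[a] > 0) v <- v * aux[[a]]$Y^k[a]
      d <- cvec[a] - k[a]
      if (d > 0) v <- v * (aux[[a]]$Rp * (1 - aux[[a]]$Y))^d
    }
    sum(v)
  }

  mu <- function(cvec) {
    if (sum(cvec) == 0) return(1)
    key <- paste(cvec, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    denom <- sum(cvec / taus) + b * (1 - eprod(cvec, cvec))
    grids <- lapply(cvec, function(ci) 0:ci)
    kk <- as.matrix(expand.grid(grids))
    num <- 0
    for (rrow in seq_len(nrow(kk))) {
      k <- kk[rrow, ]
      if (all(k == cvec)) next # proper sub-multisets only
      mult <- prod(choose(cvec, k))
      num <- num + mult * mu(k) * eprod(k, cvec)
    }
    out <- b * num / denom
    memo[[key]] <- out
    out
  }

  list(mu = mu, nlab = nlab)
}

#' Centered stationary mixed moment
#'
#' `M_A = E[prod_{a in A} (V_a - m_a)]`, obtained from the shifted moments
#' of [general_mixed_moment()] by binomial expansion (exactly, reusing the
#' memoized recursion). Singletons give 0 by construction.
#'
#' @inheritParams general_mixed_moment
#' @return The centered moment (mV^order).
#' @export
centered_mixed_moment <- function(jm, params, labels, max_order = 6, ...) {
  jm <- as_atom_model(jm, ...)
  nlab <- length(jm$labels)
  pl <- as_params_list(params, nlab)
  idx <- match(as.character(labels), jm$labels)
  if (anyNA(idx)) stop("unknown neuron label")
  cvec <- tabulate(idx, nbins = nlab)
  if (sum(cvec) > max_order) stop("order exceeds max_order")
  engine <- moment_engine(jm, pl)
  mu1 <- vapply(seq_len(nlab), function(a) {
    e <- rep(0, nlab)
    e[a] <- 1
    engine$mu(e)
  }, numeric(1))
  grids <- lapply(cvec, function(ci) 0:ci)
  kk <- as.matrix(expand.grid(grids))
  total <- 0
  for (rrow in seq_len(nrow(kk))) {
    k <- kk[rrow, ]
    mult <- prod(choose(cvec, k)) * prod((-mu1)^(cvec - k))
    total <- total + mult * engine$mu(k)
  }
  total
}

#' Table of stationary moments up to a given order
#'
#' Enumerates every multiset of neuron labels up to `order` and tabulates
#' the exact shifted and centered stationary moments.
#'
#' @inheritParams general_mixed_moment
#' @param order Maximum total order (default 3).
#' @return A data frame with columns `labels` (comma-joined, sorted),
#'   `order`, `shifted`, `centered`.
#' @export
moment_table <- function(jm, params, order = 3, ...) {
  jm <- as_atom_model(jm, ...)
  labs <- jm$labels
  rows <- list()
  for (n in seq_len(order)) {
    combos <- utils::combn(length(labs) + n - 1, n)
    # multisets via stars-and-bars over label indices
    for (cidx in seq_len(ncol(combos))) {
      sel <- combos[, cidx] - seq_len(n) + 1
      ms <- labs[sel]
      rows[[length(rows) + 1]] <- data.frame(
        labels = paste(sort(ms), collapse = ","),
        order = n,
        shifted = general_mixed_moment(jm, params, ms),
        centered = centered_mixed_moment(jm, params, ms),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Exact stationary voltage variance
#'
#' @inheritParams general_mixed_moment
#' @param neuron Neuron label (default: first).
#' @return Variance (mV^2).
#' @export
stationary_variance <- function(jm, params, neuron = jm$labels[1], ...) {
  centered_mixed_moment(jm, params, c(neuron, neuron), ...)
}

#' Exact stationary voltage covariance of a neuron pair
#'
#' Evaluates the centered order-2 cross moment from the exact engine; it is
#' symmetric in the two labels and reduces to the variance when both labels
#' coincide.
#'
#' @inheritParams general_mixed_moment
#' @param neurons Two neuron labels (default: first two).
#' @return Covariance (mV^2).
#' @export
stationary_covariance <- function(jm, params, neurons = jm$labels[1:2], ...) {
  stopifnot(length(neurons) == 2)
  centered_mixed_moment(jm, params, neurons, ...)
}

#' Exact third centered moment and skewness (compact form)
#'
#' Evaluates the compact third-moment expression
#' `M3 = (E[R^3 (1-Y)^3] + 3 M2 E[R (Y^2 - 1)(1 - Y)]) /
#'       (3/(b*tau) + E[1 - Y^3])`
#' with `Y = exp(-(We+Wi))` and the centered mixed reversal
#' `R = (We*Ve + Wi*Vi)/(We+Wi) - m`, together with the skewness
#' `S = M3 / M2^(3/2)`. Agrees with the order-3 engine value exactly.
#'
#' @inheritParams rate_coefficients
#' @return List with `mean`, `variance`, `third`, `skewness`.
#' @export
third_moment <- function(jm, params, ...) {
  jm <- as_atom_model(jm, ...)
  m <- stationary_mean(jm, params)
  a <- atom_aux(jm, 1, params)
  Y <- a$Y
  R <- ifelse(a$Y < 1, a$Vmix - m, 0)
  b <- jm$b
  tau <- params$tau
  E <- function(v) sum(jm$prob * v)
  M2 <- b * E(R^2 * (1 - Y)^2) / (2 / tau + b * E(1 - Y^2))
  M3 <- (E(R^3 * (1 - Y)^3) + 3 * M2 * E(R * (Y^2 - 1) * (1 - Y))) /
    (3 / (b * tau) + E(1 - Y^3))
  if (M2 <= 0) stop("undefined skewness: zero variance")
  list(mean = m, variance = M2, third = M3, skewness = M3 / M2^1.5)
}

# ---- closed forms and small-weight approximations ------------------------

total_pool_sums <- function(pools) {
  rw <- 0
  for (pl in pools) rw <- rw + sum(pl$r * pl$w)
  rw
}

#' Small-weight stationary mean
#'
#' Leading-order mean under `w << 1`:
#' `m = (I/(G*tau) + sum_alpha K_alpha r_alpha w_alpha V_alpha) /
#'      (1/tau + sum_alpha K_alpha r_alpha w_alpha)`.
#'
#' @param pools List of [input_pool()]s.
#' @param params A [neuron_params()].
#' @return Mean voltage (mV).
#' @export
small_weight_mean <- function(pools, params) {
  num <- params$Irest / params$tau
  den <- 1 / params$tau
  for (pl in pools) {
    V <- if (pl$kind == "e") params$Ve else params$Vi
    num <- num + sum(pl$r * pl$w) * V
    den <- den + sum(pl$r * pl$w)
  }
  num / den
}

#' Exact stationary variance under fully asynchronous inputs
#'
#' Closed form for independent inputs (each synapse its own Poisson
#' process):
#' `M = [sum_k r_k (1-e^{-w_k})^2 (V_k - m)^2] /
#'      [2/tau + sum_k r_k (1 - e^{-2 w_k})]`,
#' the effective-time-constant expression. Matches the general engine on
#' the equivalent monosynaptic atom model exactly.
#'
#' @param pools List of [input_pool()]s.
#' @param params A [neuron_params()].
#' @return Variance (mV^2).
#' @export
variance_asynchronous <- function(pools, params) {
  jm <- jump_model_asynchronous(pools)
  m <- stationary_mean(jm, params)
  num <- 0
  den <- 2 / params$tau
  for (pl in pools) {
    V <- if (pl$kind == "e") params$Ve else params$Vi
    num <- num + sum(pl$r * (1 - exp(-pl$w))^2) * (V - m)^2
    den <- den + sum(pl$r * (1 - exp(-2 * pl$w)))
  }
  num / den
}

#' Asynchronous monosynaptic jump model from input pools
#'
#' The discrete-atom jump model equivalent to fully independent inputs: one
#' atom per input with probability `r_k / b`, `b = sum r_k` (over inputs
#' with positive weight).
#'
#' @param pools List of [input_pool()]s.
#' @param label Neuron label.
#' @return A [jump_model()].
#' @export
jump_model_asynchronous <- function(pools, label = "1") {
  Wes <- numeric(0)
  Wis <- numeric(0)
  rs <- numeric(0)
  for (pl in pools) {
    keep <- pl$w > 0 & pl$r > 0
    if (!any(keep)) next
    w <- pl$w[keep]
    r <- pl$r[keep]
    if (pl$kind == "e") {
      Wes <- c(Wes, w)
      Wis <- c(Wis, rep(0, length(w)))
    } else {
      Wes <- c(Wes, rep(0, length(w)))
      Wis <- c(Wis, w)
    }
    rs <- c(rs, r)
  }
  b <- sum(rs)
  if (b <= 0) stop("no active inputs")
  jump_model(b, matrix(Wes, ncol = 1), matrix(Wis, ncol = 1),
             prob = rs / b, labels = label)
}

#' Single-neuron jump model for independent e and i beta-binomial pools
#'
#' Superposes an excitatory and an inhibitory beta-binomial drive with no
#' cross-type synchrony (`rho_ei = 0`): the event processes are independent,
#' so the atoms are the union of the per-type count atoms with rates mixed
#' in proportion.
#'
#' @param bb_e,bb_i [beta_binomial_model()]s (either may be `NULL`).
#' @param we,wi Uniform weights.
#' @param label Neuron label.
#' @return A [jump_model()].
#' @export
jump_model_ei <- function(bb_e = NULL, we = NULL, bb_i = NULL, wi = NULL,
                          label = "1") {
  parts <- list()
  if (!is.null(bb_e)) parts$e <- as_jump_model(bb_e, we, "e", label)
  if (!is.null(bb_i)) parts$i <- as_jump_model(bb_i, wi, "i", label)
  if (length(parts) == 0) stop("need at least one pool")
  if (length(parts) == 1) return(parts[[1]])
  b <- parts$e$b + parts$i$b
  jump_model(
    b,
    rbind(parts$e$We, parts$i$We),
    rbind(parts$e$Wi, parts$i$Wi),
    prob = c(parts$e$prob * parts$e$b, parts$i$prob * parts$i$b) / b,
    labels = label
  )
}

# within-block quadratic sum sum_{k,l} rho_kl sqrt(r_k r_l) w_k w_l with
# uniform off-diagonal correlation rho (diagonal 1)
block_quadratic <- function(w, r, rho) {
  s1 <- sum(sqrt(r) * w)
  s2 <- sum(r * w^2)
  s2 + rho * (s1^2 - s2)
}

#' Small-weight stationary variance with block-structured synchrony
#'
#' Leading-order variance under `w << 1`:
#' `M = sum_{a,b} (V_a - m)(V_b - m) S_ab / (2 (1/tau + sum_k r_k w_k))`
#' where `S_ab = sum_{k in a, l in b} rho_ab,kl sqrt(r_k r_l) w_k w_l`.
#' For uniform pools the within-block sums expose the synchrony
#' amplification factor `1 + (K - 1) rho`; positive e-i synchrony strictly
#' decreases the result (the e and i driving forces have opposite signs).
#'
#' @param pools List of [input_pool()]s, one per correlation block.
#' @param corr A [correlation_spec()] over the blocks.
#' @param params A [neuron_params()].
#' @return Variance (mV^2), with the small-weight mean in attribute
#'   `"mean"`.
#' @export
variance_small_weight <- function(pools, corr, params) {
  stopifnot(length(pools) == corr$L)
  m <- small_weight_mean(pools, params)
  rho <- corr$block_rho
  V <- vapply(pools, function(pl) {
    if (pl$kind == "e") params$Ve else params$Vi
  }, numeric(1))
  num <- 0
  for (a in seq_along(pools)) {
    for (bk in seq_along(pools)) {
      if (a == bk) {
        S <- block_quadratic(pools[[a]]$w, pools[[a]]$r, rho[a, a])
      } else {
        S <- rho[a, bk] *
          sum(sqrt(pools[[a]]$r) * pools[[a]]$w) *
          sum(sqrt(pools[[bk]]$r) * pools[[bk]]$w)
      }
      num <- num + (V[a] - m) * (V[bk] - m) * S
    }
  }
  out <- num / (2 * (1 / params$tau + total_pool_sums(pools)))
  attr(out, "mean") <- m
  out
}

#' Small-weight voltage covariance of a neuron pair
#'
#' Generic small-weight covariance:
#' `M12 = sum_{a,b} (V_a - m1)(V_b - m2) *
#'        sum_{k in pools1[a], l in pools2[b]} rho_cross[a,b]
#'        sqrt(r_k r_l) w_{1,k} w_{2,l} /
#'        (1/tau1 + 1/tau2 + sum_k r_k (w_{1,k} + w_{2,k}))`.
#' It is linear in every cross-neuron spiking correlation and can be
#' negative when only e-i cross correlations are present.
#'
#' @param pools1,pools2 Uniform pools of neurons 1 and 2.
#' @param rho_cross Matrix (`length(pools1) x length(pools2)`) of uniform
#'   cross-neuron spiking correlations between the pools.
#' @param params1,params2 [neuron_params()] of the two neurons.
#' @return Covariance (mV^2).
#' @export
covariance_small_weight <- function(pools1, pools2, rho_cross,
                                    params1, params2 = params1) {
  rho_cross <- as.matrix(rho_cross)
  stopifnot(nrow(rho_cross) == length(pools1),
            ncol(rho_cross) == length(pools2))
  m1 <- small_weight_mean(pools1, params1)
  m2 <- small_weight_mean(pools2, params2)
  num <- 0
  for (a in seq_along(pools1)) {
    Va <- if (pools1[[a]]$kind == "e") params1$Ve else params1$Vi
    for (bk in seq_along(pools2)) {
      Vb <- if (pools2[[bk]]$kind == "e") params2$Ve else params2$Vi
      S <- rho_cross[a, bk] *
        sum(sqrt(pools1[[a]]$r) * pools1[[a]]$w) *
        sum(sqrt(pools2[[bk]]$r) * pools2[[bk]]$w)
      num <- num + (Va - m1) * (Vb - m2) * S
    }
  }
  den <- 1 / params1$tau + 1 / params2$tau +
    total_pool_sums(pools1) + total_pool_sums(pools2)
  num / den
}

#' Excitatory share of the small-weight voltage variance
#'
#' `q = Ke re we^2 (Ve - m)^2 / sum_alpha K_alpha r_alpha w_alpha^2
#'      (V_alpha - m)^2`, the fraction of variance attributable to
#' excitation; decreasing in the mean depolarization `m` when `Ve > |Vi|`.
#'
#' @param pools Uniform [input_pool()]s (e and optionally i).
#' @param m Mean voltage (mV) at which to evaluate the driving forces.
#' @param params A [neuron_params()].
#' @return `q` in `[0, 1]`.
#' @export
excitatory_variability_share <- function(pools, m, params) {
  num <- 0
  den <- 0
  for (pl in pools) {
    V <- if (pl$kind == "e") params$Ve else params$Vi
    term <- sum(pl$r * pl$w^2) * (V - m)^2
    den <- den + term
    if (pl$kind == "e") num <- num + term
  }
  if (den <= 0) stop("no variability: all weights zero")
  num / den
}

#' Voltage correlation from shared asynchronous inputs
#'
#' `rho_V = fe * q + fi * (1 - q)` where `fe`, `fi` are the shared fractions
#' of the excitatory and inhibitory pools and `q` the excitatory
#' variability share.
#'
#' @param fe,fi Shared input fractions in `[0, 1]`.
#' @param q Excitatory variability share.
#' @return Correlation in `[0, 1]`.
#' @export
correlation_shared_inputs <- function(fe, fi, q) {
  stopifnot(fe >= 0, fe <= 1, fi >= 0, fi <= 1, q >= 0, q <= 1)
  fe * q + fi * (1 - q)
}

#' Synchrony strength ratio kappa
#'
#' The dimensionless ratio of the fully synchronous variance to the
#' asynchronous variance entering the synchrony correlation formula:
#' case (i), separately synchronous e and i pools (`rho_ei = 0`):
#' `kappa = Ke*q + Ki*(1-q)`; case (ii), uniformly cross-correlated e and i:
#' `kappa = (sqrt(Ke*q) - sqrt(Ki*(1-q)))^2` (the e and i contributions to
#' the fully synchronous jump interfere destructively).
#'
#' @param Ke,Ki Pool sizes.
#' @param q Excitatory variability share.
#' @param cross_correlated Case (ii)?
#' @return `kappa > 0`.
#' @export
kappa_synchrony <- function(Ke, Ki, q, cross_correlated = FALSE) {
  stopifnot(Ke >= 0, Ki >= 0, q >= 0, q <= 1)
  if (cross_correlated) {
    (sqrt(Ke * q) - sqrt(Ki * (1 - q)))^2
  } else {
    Ke * q + Ki * (1 - q)
  }
}

#' Voltage correlation under synchronous inputs across neurons
#'
#' `rho_V = rho' / ((1 - rho)/kappa + rho)` for within-neuron spiking
#' correlation `rho`, cross-neuron spiking correlation `rho' <= rho`, and
#' synchrony ratio `kappa`; always strictly below the admissibility bound
#' `rho'/rho`.
#'
#' @param rho_within Within-neuron spiking correlation, `0 < rho <= 1`.
#' @param rho_cross Cross-neuron spiking correlation, `0 <= rho' <= rho`.
#' @param kappa Synchrony ratio from [kappa_synchrony()].
#' @return Correlation in `[0, 1)`.
#' @export
correlation_synchrony <- function(rho_within, rho_cross, kappa) {
  stopifnot(rho_within > 0, rho_within <= 1, kappa > 0)
  if (rho_cross < 0 || rho_cross > rho_within + 1e-12) {
    stop("need 0 <= rho_cross <= rho_within (admissibility)")
  }
  rho_cross / ((1 - rho_within) / kappa + rho_within)
}

#' Approximate skewness for excitation-only synchronous drive
#'
#' Small-weight beta-binomial approximation (for `Ke * we ~ 1`):
#' `S[V] = s[V] * (1 - 2 re tau)/(1 + re tau) * sqrt(1 + rho_e * Ke)` with
#' the asynchronous current-based baseline
#' `s[V] = 2 sqrt(2) / (3 sqrt(Ke re tau))`. The drive factor changes sign
#' at `re = 1/(2 tau)` (about 33 Hz for `tau` = 15 ms).
#'
#' @param Ke Pool size.
#' @param re Per-input rate (Hz).
#' @param params A [neuron_params()] (only `tau` enters).
#' @param rho_e Beta-binomial spiking correlation (default 0).
#' @param we Uniform weight; the approximation assumes `Ke * we` of order
#'   one (informational, does not enter the formula).
#' @return List with `skewness`, `baseline` (current-based `s[V]`),
#'   `drive_factor`, `synchrony_factor`.
#' @export
skewness_excitation_approx <- function(Ke, re, params, rho_e = 0,
                                       we = 1 / Ke) {
  stopifnot(Ke > 0, re > 0, rho_e >= 0)
  tau <- params$tau
  baseline <- 2 * sqrt(2) / (3 * sqrt(Ke * re * tau))
  drive <- (1 - 2 * re * tau) / (1 + re * tau)
  sync <- sqrt(1 + rho_e * Ke)
  list(skewness = baseline * drive * sync, baseline = baseline,
       drive_factor = drive, synchrony_factor = sync)
}

#' Sign-change rate of the approximate skewness
#'
#' The drive rate at which the skewness drive factor `(1 - 2 re tau)`
#' vanishes: `re = 1/(2 tau)`.
#'
#' @param params A [neuron_params()].
#' @return Rate in Hz.
#' @export
skewness_sign_change_rate <- function(params) {
  1 / (2 * params$tau)
}

#' Small-weight third moment, excitation only, uniform beta-binomial pool
#'
#' Leading-order Taylor expansion of the compact third-moment form for a
#' uniform excitatory pool with pairwise correlation `rho_e` and third-order
#' coefficient `rho_e3`:
#' `M3/(Ve-m)^3 = Ke re we^3 (1 + 3 rho_e (Ke-1) + rho_e3 (Ke-1)(Ke-2)) /
#'               (3 (1/tau + Ke re we))
#'             - (Ke re we^2 (1 + rho_e (Ke-1)))^2 / (1/tau + Ke re we)^2`.
#'
#' @param Ke,we,re Pool size, weight, rate.
#' @param rho_e Pairwise correlation; `rho_e3` defaults to the
#'   beta-binomial value `2 rho^2/(1+rho)`.
#' @param params A [neuron_params()].
#' @return List with `third` (mV^3), `variance` (mV^2), `skewness`, `mean`.
#' @export
third_moment_small_weight_excitation <- function(Ke, we, re, rho_e, params,
                                                 rho_e3 = 2 * rho_e^2 /
                                                   (1 + rho_e)) {
  m <- small_weight_mean(list(input_pool("e", Ke, we, re)), params)
  eff <- 1 / params$tau + Ke * re * we
  F2 <- Ke * re * we^2 * (1 + rho_e * (Ke - 1))
  F3 <- Ke * re * we^3 *
    (1 + 3 * rho_e * (Ke - 1) + rho_e3 * (Ke - 1) * (Ke - 2))
  M2 <- (params$Ve - m)^2 * F2 / (2 * eff)
  M3 <- (params$Ve - m)^3 * (F3 / (3 * eff) - F2^2 / eff^2)
  list(mean = m, variance = M2, third = M3, skewness = M3 / M2^1.5)
}

#' Stationary means of a gap-junction-coupled pair
#'
#' Solves the exact stationary mean balance of two electrically coupled
#' AONCB neurons: `m_a (1/tau + c_a + g/tau) - (g/tau) m_b = (1/tau + c_a)
#' m_a|0` where `c_a = ce,a + ci,a` are the uncoupled rate coefficients and
#' `m_a|0` the uncoupled means — weighted averages of the uncoupled means.
#' `g = 0` returns the uncoupled means; `g -> Inf` equalizes them.
#'
#' @param jm [jump_model()] over the pair.
#' @param params One [neuron_params()] or a list of two (shared `tau`).
#' @param g Dimensionless coupling `G12/G >= 0`.
#' @return Numeric vector `c(m1, m2)` (mV).
#' @export
gap_junction_means <- function(jm, params, g, ...) {
  jm <- as_atom_model(jm, ...)
  stopifnot(length(jm$labels) == 2, g >= 0)
  pl <- as_params_list(params, 2L)
  tau <- pl[[1]]$tau
  stopifnot(abs(pl[[2]]$tau - tau) < 1e-12)
  # per-neuron rate coefficients and uncoupled means, computed directly on
  # the pair model's marginals (atoms may be empty for one neuron)
  rc <- lapply(1:2, function(a) {
    We <- jm$We[, a]
    Wi <- jm$Wi[, a]
    Wtot <- We + Wi
    fac <- ifelse(Wtot > 0, (1 - exp(-Wtot)) / pmax(Wtot, 1e-300), 0)
    list(ce = jm$b * sum(jm$prob * We * fac),
         ci = jm$b * sum(jm$prob * Wi * fac))
  })
  den <- vapply(1:2, function(a) 1 / tau + rc[[a]]$ce + rc[[a]]$ci,
                numeric(1))
  m0 <- vapply(1:2, function(a) {
    (pl[[a]]$Irest / tau + rc[[a]]$ce * pl[[a]]$Ve +
       rc[[a]]$ci * pl[[a]]$Vi) / den[a]
  }, numeric(1))
  A <- rbind(c(den[1] + g / tau, -g / tau),
             c(-g / tau, den[2] + g / tau))
  as.numeric(solve(A, den * m0))
}

#' Heterogeneous-weight variance and its CV decomposition
#'
#' For an asynchronous excitatory pool with heterogeneous weights, the
#' small-weight variance numerator factors as
#' `K <w>^2 (1 + CV^2[w])`; weight heterogeneity multiplies the
#' homogeneous-pool variance by `1 + CV^2[w]` (at most doubling it for
#' `CV[w] <= 1`).
#'
#' @param weights Per-input weights.
#' @param r Common rate (Hz).
#' @param params A [neuron_params()].
#' @return List with `variance` (mV^2, small-weight), `CV2`,
#'   `factor = 1 + CV2`, `mean_w`.
#' @export
heterogeneity_equivalent_variance <- function(weights, r, params) {
  stopifnot(all(weights >= 0), r > 0)
  K <- length(weights)
  wbar <- mean(weights)
  CV2 <- if (wbar > 0) stats::var(weights) * (K - 1) / K / wbar^2 else 0
  pool <- input_pool("e", K, weights, r)
  v <- variance_small_weight(list(pool), correlation_spec(matrix(0, 1, 1)),
                             params)
  list(variance = as.numeric(v), CV2 = CV2, factor = 1 + CV2, mean_w = wbar)
}
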