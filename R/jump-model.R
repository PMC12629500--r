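#' Jump model of a synchronous synaptic drive
#'
#' The drive to a set of neurons is a compound Poisson process: synaptic
#' events arrive at rate `b` (Hz) and at each event every neuron `a`
#' receives a dimensionless conductance jump `(We_a, Wi_a)`. The joint jump
#' distribution encodes all input synchrony. This constructor builds the
#' discrete-atom representation: a finite list of jump vectors with
#' probabilities.
#'
#' @param b Synaptic-event rate in Hz (`b > 0`).
#' @param We,Wi Numeric matrices (atoms x neurons) of excitatory and
#'   inhibitory jump components; vectors are treated as single-neuron
#'   columns.
#' @param prob Atom probabilities (non-negative, summing to 1).
#' @param labels Neuron labels; default `"1"`, `"2"`, ...
#' @param X Optional per-event input-activation description used by the
#'   spiking-correlation operations: either a 0/1 matrix (atoms x inputs) or
#'   `exchangeable_inputs(K, counts)` for exchangeable pools.
#'
#' @return An object of class `jump_model`.
#' @examples
#' # two neurons, disjointly driven
#' jm <- jump_model(
#'   b = 10,
#'   We = rbind(c(0.1, 0), c(0, 0.1)),
#'   Wi = rbind(c(0, 0), c(0, 0)),
#'   prob = c(0.5, 0.5)
#' )
#' subsample_rate(jm, "1") # 5 Hz
#' @export
jump_model <- function(b, We, Wi = NULL, prob, labels = NULL, X = NULL) {
  We <- as_jump_matrix(We)
  if (is.null(Wi)) Wi <- matrix(0, nrow(We), ncol(We))
  Wi <- as_jump_matrix(Wi)
  stopifnot(all(dim(We) == dim(Wi)))
  n <- ncol(We)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  stopifnot(length(labels) == n)
  prob <- as.numeric(prob)
  stopifnot(length(prob) == nrow(We), all(prob >= 0))
  s <- sum(prob)
  if (abs(s - 1) > 1e-8) stop("atom probabilities must sum to 1")
  prob <- prob / s
  if (any(We < 0) || any(Wi < 0)) stop("jump components must be >= 0")
  if (any(rowSums(We) + rowSums(Wi) <= 0)) {
    stop("every synaptic event must carry a positive jump for some neuron")
  }
  stopifnot(is.numeric(b), length(b) == 1L, b > 0)
  colnames(We) <- colnames(Wi) <- labels
  structure(
    list(labels = labels, b = b, backend = "atoms",
         We = We, Wi = Wi, prob = prob, X = X),
    class = "jump_model"
  )
}

as_jump_matrix <- function(W) {
  if (is.null(dim(W))) W <- matrix(as.numeric(W), ncol = 1L)
  storage.mode(W) <- "double"
  W
}

#' @export
print.jump_model <- function(x, ...) {
  cat(sprintf(
    "jump_model (%s): %d neuron(s) [%s], event rate b = %g Hz, %s\n",
    x$backend, length(x$labels), paste(x$labels, collapse = ", "), x$b,
    if (x$backend == "atoms") sprintf("%d atoms", length(x$prob))
    else "sampler backend"
  ))
  invisible(x)
}

#' Jump model with a Monte Carlo sampler backend
#'
#' For jump distributions without a tractable finite-atom representation
#' (e.g. multi-pool copula models), the jump model may carry a sampler:
#' a function `sampler(n, rng_seed)` returning `list(We = , Wi = )`
#' matrices with `n` rows. Expectations over such models are evaluated by
#' seeded Monte Carlo with a reported standard error.
#'
#' @param b Event rate (Hz).
#' @param sampler Function `(n, seed)` returning `list(We, Wi)` matrices.
#' @param labels Neuron labels.
#' @return An object of class `jump_model`.
#' @export
jump_model_sampler <- function(b, sampler, labels = "1") {
  stopifnot(is.function(sampler), b > 0)
  structure(
    list(labels = labels, b = b, backend = "sampler",
         sampler = sampler, X = NULL),
    class = "jump_model"
  )
}

#' Exchangeable input-activation descriptor
#'
#' Marks the per-event input activations of a jump model as exchangeable
#' over a pool of `K` inputs, with the number of coactive inputs per atom
#' given by `counts`. Coactivation moments are then computed from falling
#' factorial moments of the count.
#'
#' @param K Pool size.
#' @param counts Integer vector, one count per atom.
#' @export
exchangeable_inputs <- function(K, counts) {
  stopifnot(K >= 1, all(counts >= 0), all(counts <= K))
  structure(list(K = as.integer(K), counts = as.integer(counts)),
            class = "exchangeable_inputs")
}

#' Beta-binomial model of homogeneous input synchrony
#'
#' Exchangeable pool of `K` inputs with per-input rate `r` whose per-event
#' activation probability is beta-distributed, giving uniform pairwise
#' spiking correlation `rho = 1/(1 + beta)`. `rho = 0` denotes the
#' asynchronous limit (independent inputs).
#'
#' @param K Number of inputs.
#' @param rho Pairwise spiking correlation in `[0, 1)`.
#' @param r Per-input spike rate (Hz).
#' @return An object of class `beta_binomial_model`.
#' @examples
#' bb <- beta_binomial_model(K = 100, rho = 0.03, r = 10)
#' collective_event_rate(bb)          # < K * r
#' @export
beta_binomial_model <- function(K, rho, r) {
  stopifnot(K >= 1, K == round(K), rho >= 0, rho < 1, r > 0)
  beta <- if (rho > 0) 1 / rho - 1 else Inf
  structure(list(K = as.integer(K), rho = rho, r = r, beta = beta),
            class = "beta_binomial_model")
}

#' Per-event coactivation count distribution of a beta-binomial pool
#'
#' Probability mass function of the number `k >= 1` of inputs coactivating
#' at a synaptic event, obtained as the vanishing-bin-width limit of
#' beta-mixed binomial counts conditioned on at least one spike.
#'
#' @param bb A [beta_binomial_model()].
#' @return A list with `k` (1..K) and `prob`.
#' @export
bb_count_pmf <- function(bb) {
  stopifnot(inherits(bb, "beta_binomial_model"))
  K <- bb$K
  if (bb$rho == 0) {
    return(list(k = 1L, prob = 1))
  }
  beta <- bb$beta
  k <- seq_len(K)
  logp <- lchoose(K, k) + lgamma(k) + lgamma(beta + K - k) - lgamma(beta + K)
  p <- exp(logp - max(logp))
  list(k = k, prob = p / sum(p))
}

#' Collective synaptic-event rate of a beta-binomial pool
#'
#' Rate at which at least one of `K_subset` inputs of a homogeneous
#' beta-binomial pool fires: `r * beta * (digamma(K + beta) - digamma(beta))`
#' with `beta = 1/rho - 1`. Equals `r` at `K_subset = 1`, grows
#' logarithmically (`~ beta * r * log K`) for large pools, and reduces to
#' `K * r` in the asynchronous limit `rho = 0`.
#'
#' @param bb A [beta_binomial_model()].
#' @param K_subset Number of inputs pooled (default: the whole pool).
#' @return Event rate in Hz.
#' @examples
#' bb <- beta_binomial_model(K = 2, rho = 0.5, r = 1)
#' collective_event_rate(bb) # 1 * (psi(3) - psi(1)) = 1.5 Hz
#' @export
collective_event_rate <- function(bb, K_subset = bb$K) {
  stopifnot(inherits(bb, "beta_binomial_model"))
  if (K_subset < 1 || K_subset > bb$K) stop("K_subset must be in [1, K]")
  if (bb$rho == 0) {
    return(bb$r * K_subset)
  }
  beta <- bb$beta
  bb$r * beta * (digamma(K_subset + beta) - digamma(beta))
}

#' Convert a beta-binomial pool to a single-neuron jump model
#'
#' Enumerates the per-event coactivation counts `k = 1..K` exactly, giving
#' a discrete-atom jump model with jumps `k * w` of the requested type.
#'
#' @param bb A [beta_binomial_model()].
#' @param w Uniform dimensionless synaptic weight.
#' @param kind `"e"` or `"i"`.
#' @param label Neuron label.
#' @return A [jump_model()].
#' @export
as_jump_model <- function(bb, w, kind = c("e", "i"), label = "1") {
  stopifnot(inherits(bb, "beta_binomial_model"), w > 0)
  kind <- match.arg(kind)
  pmf <- bb_count_pmf(bb)
  b <- collective_event_rate(bb)
  W <- matrix(pmf$k * w, ncol = 1L)
  Z <- matrix(0, length(pmf$k), 1L)
  jump_model(
    b = b,
    We = if (kind == "e") W else Z,
    Wi = if (kind == "i") W else Z,
    prob = pmf$prob, labels = label,
    X = exchangeable_inputs(bb$K, pmf$k)
  )
}

# ---- expectation machinery -------------------------------------------------

#' Expectation of a functional of the jump vector
#'
#' Evaluates `E[f(We, Wi)]` with respect to the per-event jump distribution.
#' Discrete-atom models are summed exactly (standard error 0); sampler
#' models use seeded Monte Carlo and report the standard error of the
#' estimate.
#'
#' @param jm A [jump_model()].
#' @param f Function of two matrices (atoms/draws x neurons) returning one
#'   value per row.
#' @param n_draws Monte Carlo sample size for sampler backends.
#' @param seed Seed for sampler backends (required there).
#' @return A list with `value` and `se`.
#' @examples
#' jm <- jump_model(b = 10, We = c(0.2, 0), Wi = c(0, 0.1), prob = c(.5, .5))
#' jump_expectation(jm, function(We, Wi) We[, 1])$value # 0.1
#' @export
jump_expectation <- function(jm, f, n_draws = 1e6, seed = NULL) {
  stopifnot(inherits(jm, "jump_model"))
  if (jm$backend == "atoms") {
    v <- f(jm$We, jm$Wi)
    stopifnot(length(v) == length(jm$prob))
    return(list(value = sum(v * jm$prob), se = 0))
  }
  if (is.null(seed)) {
    stop("sampler-backed jump expectations require an explicit seed")
  }
  draws <- jm$sampler(n_draws, seed)
  v <- f(draws$We, draws$Wi)
  list(value = mean(v), se = stats::sd(v) / sqrt(length(v)))
}

# ---- spiking correlations --------------------------------------------------

# raw coactivation moment E[X_{k1} ... X_{kn}] over synaptic events,
# for distinct input indices
event_coactivation <- function(jm, idx) {
  X <- jm$X
  if (is.null(X)) {
    stop("jump model carries no input-activation description")
  }
  if (inherits(X, "exchangeable_inputs")) {
    n <- length(idx)
    if (length(unique(idx)) != n) stop("input indices must be distinct")
    if (any(idx < 1 | idx > X$K)) stop("input index out of range")
    k <- X$counts
    K <- X$K
    # falling factorial ratio k(k-1)...(k-n+1) / (K(K-1)...(K-n+1))
    num <- rep(1, length(k))
    den <- 1
    for (j in 0:(n - 1)) {
      num <- num * pmax(k - j, 0)
      den <- den * (K - j)
    }
    sum(num / den * jm$prob)
  } else {
    Xm <- as.matrix(X)
    if (any(idx < 1 | idx > ncol(Xm))) stop("input index out of range")
    v <- rep(1, nrow(Xm))
    for (i in idx) v <- v * Xm[, i]
    sum(v * jm$prob)
  }
}

event_activation_prob <- function(jm, i) event_coactivation(jm, i)

#' Raw coactivation moment of a set of inputs
#'
#' `E[X_{k1} ... X_{kn}]` over synaptic events, where `X_k` is the 0/1
#' activation indicator of input `k`.
#'
#' @param jm A [jump_model()] carrying an input-activation description.
#' @param inputs Distinct input indices.
#' @return Probability in `[0, 1]`.
#' @export
coactivation_moment <- function(jm, inputs) {
  event_coactivation(jm, inputs)
}

#' Pairwise spiking correlation between two inputs
#'
#' The spiking correlation of inputs `k` and `l` in the jump-process
#' framework: `E[X_k X_l] / sqrt(E[X_k] E[X_l])` over synaptic events.
#' Equals 0 for inputs that never coactivate, 1 for fully synchronous
#' inputs, and `rho` for a beta-binomial pool with `beta = 1/rho - 1`.
#'
#' @param jm A [jump_model()] carrying an input-activation description.
#' @param input_a,input_b Input indices.
#' @return Correlation coefficient in `[0, 1]`.
#' @export
pairwise_correlation <- function(jm, input_a, input_b) {
  higher_order_correlation(jm, c(input_a, input_b))
}

#' Higher-order spiking correlation of n inputs
#'
#' Order-n generalization of the pairwise spiking correlation:
#' `rho_{k1..kn} = E[X_{k1}...X_{kn}] / (E[X_{k1}]...E[X_{kn}])^(1/n)`.
#' Reduces to [pairwise_correlation()] at n = 2; for a beta-binomial pool it
#' equals `prod_{j=1}^{n-1} j / (beta + j)`.
#'
#' @param jm A [jump_model()].
#' @param inputs Distinct input indices (length >= 2).
#' @return Coefficient in `[0, 1]`.
#' @export
higher_order_correlation <- function(jm, inputs) {
  if (length(inputs) < 2) stop("need at least two inputs")
  p <- vapply(inputs, function(i) event_activation_prob(jm, i), numeric(1))
  if (any(p <= 0) || any(p >= 1 + 1e-12)) {
    if (any(p <= 0)) {
      stop("undefined correlation: input never activates over events")
    }
  }
  joint <- event_coactivation(jm, inputs)
  joint / exp(mean(log(p)))
}

# ---- rates -----------------------------------------------------------------

#' Event rate of the drive restricted to a neuron subset
#'
#' The rate at which at least one neuron in `subset` receives a positive
#' jump: `b * P[sum_{a in subset} (We_a + Wi_a) > 0]`. Monotone in the
#' subset and equal to `b` for the full neuron set.
#'
#' @param jm A discrete-atom [jump_model()].
#' @param subset Neuron labels (or indices) to keep.
#' @return Rate in Hz.
#' @export
subsample_rate <- function(jm, subset) {
  stopifnot(inherits(jm, "jump_model"), jm$backend == "atoms")
  if (length(subset) == 0) stop("subset must be nonempty")
  cols <- if (is.character(subset)) {
    match(subset, jm$labels)
  } else {
    as.integer(subset)
  }
  if (anyNA(cols) || any(cols < 1 | cols > length(jm$labels))) {
    stop("unknown neuron label in subset")
  }
  tot <- rowSums(jm$We[, cols, drop = FALSE]) +
    rowSums(jm$Wi[, cols, drop = FALSE])
  jm$b * sum(jm$prob[tot > 0])
}

#' Pair event rate from individual rates and the synchrony overlap
#'
#' For two neurons with individual drive rates `b1`, `b2`, and overlap
#' `q12 = P[both receive input | at least one receives input]`, the rate of
#' events seen by the pair is `b12 = (b1 + b2) / (1 + q12)`. Independent
#' drives give `b1 + b2`; optimally synchronous drives
#' (`q12 = min(b1,b2)/max(b1,b2)`) give `max(b1, b2)`.
#'
#' @param b1,b2 Individual event rates (Hz).
#' @param q12 Overlap probability.
#' @return The pair event rate `b12` in Hz.
#' @examples
#' pair_event_rate(10, 10, 0.25) # 16 Hz
#' @export
pair_event_rate <- function(b1, b2, q12) {
  stopifnot(b1 > 0, b2 > 0)
  qmax <- min(b1, b2) / max(b1, b2)
  if (q12 < 0 || q12 > qmax + 1e-12) {
    stop(sprintf("q12 must lie in [0, %g]", qmax))
  }
  (b1 + b2) / (1 + q12)
}

# ---- faulty transmission ---------------------------------------------------

#' Effective input statistics under faulty synaptic transmission
#'
#' Models stochastic transmission failure: each spike of input `k` is
#' transmitted independently with probability `p_k`. Effective rates scale
#' as `r' = p * r` and effective spiking correlations as
#' `rho'_{kl} = rho_{kl} * sqrt(p_k * p_l)`. With `compensate = TRUE`, pool
#' sizes are scaled to `K' = K / p` (weights unchanged), which restores the
#' mean drive exactly and the second/third-order voltage statistics to
#' leading order in the small-weight approximation.
#'
#' @param pools List of [input_pool()] objects (assumed homogeneous per
#'   pool).
#' @param corr A [correlation_spec()] across the pools (one block per pool).
#' @param p Release probabilities, length 1 or one per pool, in `(0, 1]`.
#' @param compensate Scale pool sizes by `1/p`?
#' @return A list with transformed `pools` and `corr`.
#' @export
faulty_transmission_transform <- function(pools, corr, p, compensate = FALSE) {
  L <- length(pools)
  p <- rep_len(as.numeric(p), L)
  if (any(p <= 0) || any(p > 1)) stop("release probabilities must be in (0, 1]")
  rho <- corr$block_rho
  sp <- sqrt(p)
  rho_new <- rho * (sp %o% sp)
  diag(rho_new) <- diag(rho) * p # within-pool off-diagonal correlation
  pools_new <- vector("list", L)
  for (i in seq_len(L)) {
    pl <- pools[[i]]
    Knew <- if (compensate) as.integer(round(pl$K / p[i])) else pl$K
    pools_new[[i]] <- input_pool(pl$kind, Knew, pl$w[1], p[i] * pl$r[1])
  }
  list(pools = pools_new, corr = correlation_spec(rho_new))
}
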