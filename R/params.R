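#' Passive membrane parameters of an AONCB neuron
#'
#' Bundles the passive membrane constants of a single
#' all-or-none-conductance-based (AONCB) neuron. Voltages are measured
#' relative to the leak reversal potential, which is fixed at 0 mV, so the
#' excitatory and inhibitory reversal potentials must bracket it:
#' `Vi < 0 < Ve`.
#'
#' @param tau Passive membrane time constant `C/G` in seconds.
#' @param Ve Excitatory reversal potential in mV.
#' @param Vi Inhibitory reversal potential in mV.
#' @param Irest Constant-current resting level `I/G` in mV (the voltage the
#'   neuron relaxes to between synaptic events). Defaults to 0.
#'
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params()                     # tau = 15 ms, Ve = 60, Vi = -10
#' neuron_params(tau = 0.02, Ve = 70)
#' @export
neuron_params <- function(tau = 0.015, Ve = 60, Vi = -10, Irest = 0) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  stopifnot(is.numeric(Ve), length(Ve) == 1L, is.numeric(Vi), length(Vi) == 1L)
  if (!(Vi < 0 && 0 < Ve)) {
    stop("reversal potentials must satisfy Vi < VL = 0 < Ve", call. = FALSE)
  }
  structure(
    list(tau = tau, Ve = Ve, Vi = Vi, VL = 0, Irest = Irest),
    class = "neuron_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "AONCB neuron: tau = %g ms, Ve = %g mV, Vi = %g mV, I/G = %g mV\n",
    1000 * x$tau, x$Ve, x$Vi, x$Irest
  ))
  invisible(x)
}

# Recycle a single neuron_params into a list of n, or validate a list of n.
as_params_list <- function(params, n) {
  if (inherits(params, "neuron_params")) {
    return(rep(list(params), n))
  }
  stopifnot(is.list(params), length(params) == n)
  lapply(params, function(p) {
    if (!inherits(p, "neuron_params")) stop("expected neuron_params objects")
    p
  })
}

#' Homogeneous pool of synaptic inputs
#'
#' A pool of `K` synaptic inputs of one type (excitatory or inhibitory) with
#' per-input dimensionless weights `w = g * tau_s / C` and per-input spike
#' rates `r` (Hz). Scalars are recycled to length `K`.
#'
#' @param kind `"e"` or `"i"`.
#' @param K Number of inputs (non-negative integer).
#' @param w Dimensionless synaptic weight(s), length 1 or `K`.
#' @param r Per-input spike rate(s) in Hz, length 1 or `K`.
#'
#' @return An object of class `input_pool`.
#' @examples
#' input_pool("e", K = 100, w = 0.01, r = 10)
#' @export
input_pool <- function(kind = c("e", "i"), K, w, r) {
  kind <- match.arg(kind)
  stopifnot(length(K) == 1L, K >= 0, K == round(K))
  K <- as.integer(K)
  w <- rep_len(as.numeric(w), max(K, 1L))
  r <- rep_len(as.numeric(r), max(K, 1L))
  if (K == 0L) {
    w <- numeric(0)
    r <- numeric(0)
  }
  if (any(w < 0) || any(r < 0)) stop("weights and rates must be >= 0")
  structure(list(kind = kind, K = K, w = w, r = r), class = "input_pool")
}

pool_is_uniform <- function(pool) {
  pool$K == 0L ||
    (length(unique(pool$w)) == 1L && length(unique(pool$r)) == 1L)
}

#' Block-structured spiking-correlation specification
#'
#' Pairwise spiking correlations across `L` homogeneous input subpopulations
#' arranged as an `L x L` block matrix. Entry `[i, j]` is the spiking
#' correlation between any input of block `i` and any input of block `j`;
#' diagonal entries are within-block correlations.
#'
#' @param block_rho Symmetric `L x L` matrix with entries in `[0, 1]`;
#'   diagonal entries in `(0, 1]` are within-block correlations (a diagonal
#'   value of 0 marks an asynchronous block).
#' @param names Optional block names.
#'
#' @return An object of class `correlation_spec`.
#' @export
correlation_spec <- function(block_rho, names = NULL) {
  block_rho <- as.matrix(block_rho)
  if (nrow(block_rho) != ncol(block_rho)) stop("block_rho must be square")
  if (max(abs(block_rho - t(block_rho))) > 1e-12) {
    stop("block_rho must be symmetric")
  }
  if (any(block_rho < 0) || any(block_rho > 1)) {
    stop("spiking correlations must lie in [0, 1]")
  }
  if (!is.null(names)) {
    dimnames(block_rho) <- list(names, names)
  }
  # Admissibility of cross-block entries: rho_ij <= sqrt(rho_ii * rho_jj)
  L <- nrow(block_rho)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i != j) {
        bound <- sqrt(block_rho[i, i] * block_rho[j, j])
        if (block_rho[i, j] > bound + 1e-12) {
          stop(sprintf(
            "cross-block correlation [%d,%d] = %g exceeds sqrt(rho_ii*rho_jj) = %g",
            i, j, block_rho[i, j], bound
          ))
        }
      }
    }
  }
  structure(list(block_rho = block_rho, L = L), class = "correlation_spec")
}
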