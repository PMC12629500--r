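# Event-driven simulation of AONCB neurons in the instantaneous-synapse
# limit (Marcus dynamics), finite synaptic time-constant Euler reference,
# and gap-junction-coupled pairs.

#' Marcus jump of the membrane voltage
#'
#' Exact voltage increment produced by an instantaneous conductance jump
#' `(We, Wi)`: `J = (Vmix - V_pre) * (1 - exp(-(We + Wi)))` with the mixed
#' reversal `Vmix = (We*Ve + Wi*Vi) / (We + Wi)`. The post-jump voltage
#' `V_pre + J` always stays strictly inside `(Vi, Ve)` when `V_pre` does.
#'
#' @param V_pre Pre-event voltage (mV), strictly inside `(Vi, Ve)`.
#' @param We,Wi Non-negative dimensionless jump components with
#'   `We + Wi > 0`.
#' @param params A [neuron_params()].
#' @return The jump `J` in mV (vectorized over the inputs).
#' @examples
#' marcus_jump(0, We = 0.01, Wi = 0, neuron_params()) # ~ 0.597 mV
#' @export
marcus_jump <- function(V_pre, We, Wi, params) {
  stopifnot(inherits(params, "neuron_params"))
  n <- max(length(V_pre), length(We), length(Wi))
  V_pre <- rep_len(V_pre, n)
  We <- rep_len(We, n)
  Wi <- rep_len(Wi, n)
  if (any(We < 0) || any(Wi < 0)) stop("jump components must be >= 0")
  if (any(We + Wi <= 0)) {
    stop("no event: We + Wi must be > 0 (empty jumps are filtered upstream)")
  }
  if (any(V_pre <= params$Vi) || any(V_pre >= params$Ve)) {
    stop("V_pre must lie strictly inside (Vi, Ve)")
  }
  Vmix <- (We * params$Ve + Wi * params$Vi) / (We + Wi)
  (Vmix - V_pre) * (1 - exp(-(We + Wi)))
}

#' Sample a synaptic event train from a jump model
#'
#' Poisson event times at rate `b` on `[0, T]` with i.i.d. per-event jumps
#' drawn from the jump distribution.
#'
#' @param jm A [jump_model()].
#' @param T Duration (seconds).
#' @param seed Integer seed.
#' @return An [event_train()].
#' @export
sample_event_train <- function(jm, T, seed) {
  stopifnot(inherits(jm, "jump_model"), T > 0)
  set.seed(seed)
  # exponential inter-event gaps (guarantees strictly increasing times)
  times <- numeric(0)
  t_last <- 0
  repeat {
    chunk <- ceiling(jm$b * (T - t_last) + 10 * sqrt(jm$b * T) + 100)
    gaps <- stats::rexp(chunk, jm$b)
    times <- c(times, t_last + cumsum(gaps))
    t_last <- times[length(times)]
    if (t_last > T) break
  }
  times <- times[times <= T]
  N <- length(times)
  if (jm$backend == "atoms") {
    idx <- sample.int(length(jm$prob), N, replace = TRUE, prob = jm$prob)
    We <- jm$We[idx, , drop = FALSE]
    Wi <- jm$Wi[idx, , drop = FALSE]
  } else {
    draws <- jm$sampler(N, seed + 1L)
    We <- as_jump_matrix(draws$We)
    Wi <- as_jump_matrix(draws$Wi)
  }
  event_train(times, We, Wi, T = T)
}

new_voltage_trace <- function(times, V, params_list, T, coupling = 0) {
  structure(
    list(times = times, V = V, params = params_list, T = T,
         coupling = coupling),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage_trace: %d neuron(s), %d events over %g s\n",
              ncol(x$V), length(x$times), x$T))
  invisible(x)
}

#' Event-driven Marcus simulation of a feedforward population
#'
#' Between synaptic events each neuron relaxes exponentially toward its
#' resting level `I/G` with its own time constant; at events the per-neuron
#' Marcus updates apply. The scheme is exact given the event train: stored
#' post-event voltages carry no discretization error, and the trace between
#' events is the known piecewise exponential.
#'
#' @param events An [event_train()].
#' @param params One [neuron_params()] (recycled) or a list, one per neuron.
#' @param V0 Initial voltages at time 0 (default: resting levels).
#' @param T Duration; defaults to the train's.
#' @return A `voltage_trace` with event times, the post-event voltage
#'   matrix, and the per-neuron parameters.
#' @export
simulate_population <- function(events, params, V0 = NULL, T = events$T) {
  stopifnot(inherits(events, "event_train"))
  n <- ncol(events$We)
  pl <- as_params_list(params, n)
  if (is.null(V0)) V0 <- vapply(pl, function(p) p$Irest, numeric(1))
  V0 <- rep_len(V0, n)
  for (a in seq_len(n)) {
    if (pl[[a]]$Irest == 0 && (V0[a] <= pl[[a]]$Vi || V0[a] >= pl[[a]]$Ve)) {
      stop("V0 must lie strictly inside (Vi, Ve)")
    }
  }
  if (length(events$times) && max(events$times) > T + 1e-12) {
    stop("event times exceed the requested duration")
  }
  V <- marcus_simulate_cpp(
    events$times, events$We, events$Wi,
    vapply(pl, function(p) p$tau, numeric(1)),
    vapply(pl, function(p) p$Ve, numeric(1)),
    vapply(pl, function(p) p$Vi, numeric(1)),
    vapply(pl, function(p) p$Irest, numeric(1)),
    V0
  )
  new_voltage_trace(events$times, V, pl, T)
}

#' Gap-junction-coupled pair simulation
#'
#' Two AONCB neurons with identical membrane time constant coupled by a
#' dimensionless electrical conductance `g = G12/G`. Between events the
#' linear two-dimensional relaxation is propagated exactly in the
#' symmetric/antisymmetric eigenbasis (decay rates `1/tau` and
#' `(1 + 2g)/tau`); at events the per-neuron Marcus updates apply unchanged.
#' `g = 0` reproduces [simulate_population()].
#'
#' @param events An [event_train()] over two neurons.
#' @param params One [neuron_params()] or a list of two sharing `tau`.
#' @param g Coupling strength `G12/G >= 0`.
#' @param V0 Initial voltages (length 2).
#' @param T Duration.
#' @return A `voltage_trace`.
#' @export
simulate_gap_junction_pair <- function(events, params, g, V0 = NULL,
                                       T = events$T) {
  stopifnot(inherits(events, "event_train"), ncol(events$We) == 2, g >= 0)
  pl <- as_params_list(params, 2L)
  if (abs(pl[[1]]$tau - pl[[2]]$tau) > 1e-12) {
    stop("the gap-junction propagator assumes identical time constants")
  }
  if (is.null(V0)) V0 <- vapply(pl, function(p) p$Irest, numeric(1))
  V0 <- rep_len(V0, 2L)
  V <- gap_pair_simulate_cpp(
    events$times, events$We, events$Wi, pl[[1]]$tau,
    vapply(pl, function(p) p$Ve, numeric(1)),
    vapply(pl, function(p) p$Vi, numeric(1)),
    vapply(pl, function(p) p$Irest, numeric(1)),
    g, V0
  )
  new_voltage_trace(events$times, V, pl, T, coupling = g)
}

#' Finite synaptic time-constant Euler reference integrator
#'
#' Integrates the single-neuron conductance-based dynamics with box-car
#' synaptic conductances of duration `tau_s = epsilon * tau` (conductance
#' amplitude `W/epsilon` relative to leak, so the integrated weight matches
#' the dimensionless jump), by forward Euler with step `dt_euler`. As
#' `epsilon -> 0` its stationary statistics converge to the Marcus
#' simulator's; it exists for that validation, not for production runs.
#'
#' @param events Single-neuron [event_train()].
#' @param params A [neuron_params()].
#' @param epsilon Ratio `tau_s / tau` (> 0).
#' @param dt_euler Euler step (seconds), must be `< tau_s`.
#' @param T Duration (seconds).
#' @param burn_in Discarded initial stretch (seconds); default `20 * tau`.
#' @param V0 Initial voltage.
#' @param thin Keep every `thin`-th post-burn-in sample (0 = none).
#' @return List with `mean`, `variance`, `third_central`, `n`, `samples`.
#' @export
simulate_finite_synapse <- function(events, params, epsilon, dt_euler,
                                    T = events$T,
                                    burn_in = 20 * params$tau,
                                    V0 = params$Irest, thin = 0L) {
  stopifnot(inherits(events, "event_train"), ncol(events$We) == 1,
            inherits(params, "neuron_params"), epsilon > 0)
  if (dt_euler >= epsilon * params$tau) {
    stop("dt_euler must be smaller than tau_s = epsilon * tau")
  }
  euler_finite_synapse_cpp(
    events$times, events$We[, 1], events$Wi[, 1],
    params$tau, params$Ve, params$Vi, params$Irest,
    epsilon, dt_euler, T, burn_in, V0, as.integer(thin)
  )
}

#' Evaluate a voltage trace on a time grid
#'
#' Reconstructs the piecewise-exponential trace between stored post-event
#' voltages (exact for uncoupled populations; for gap-junction pairs the
#' coupled two-dimensional relaxation is used).
#'
#' @param trace A `voltage_trace`.
#' @param t_grid Times (seconds), within `[0, T]`.
#' @param V0 Voltage at time 0 (default: resting levels).
#' @return Matrix (length(t_grid) x neurons).
#' @export
trace_at_times <- function(trace, t_grid, V0 = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  n <- ncol(trace$V)
  pl <- trace$params
  if (is.null(V0)) V0 <- vapply(pl, function(p) p$Irest, numeric(1))
  g <- trace$coupling
  out <- matrix(NA_real_, length(t_grid), n)
  idx <- findInterval(t_grid, trace$times)
  for (r in seq_along(t_grid)) {
    k <- idx[r]
    t0 <- if (k == 0) 0 else trace$times[k]
    v0 <- if (k == 0) V0 else trace$V[k, ]
    dt <- t_grid[r] - t0
    if (g == 0) {
      for (a in seq_len(n)) {
        out[r, a] <- pl[[a]]$Irest +
          (v0[a] - pl[[a]]$Irest) * exp(-dt / pl[[a]]$tau)
      }
    } else {
      tau <- pl[[1]]$tau
      s_star <- mean(c(pl[[1]]$Irest, pl[[2]]$Irest))
      d_star <- (pl[[1]]$Irest - pl[[2]]$Irest) / (2 * (1 + 2 * g))
      s <- s_star + (mean(v0) - s_star) * exp(-dt / tau)
      d <- d_star + ((v0[1] - v0[2]) / 2 - d_star) *
        exp(-dt * (1 + 2 * g) / tau)
      out[r, ] <- c(s + d, s - d)
    }
  }
  out
}
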