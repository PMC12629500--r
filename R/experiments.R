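# Config-driven experiment runners sweeping the study's parameter regimes
# and emitting tidy result tables. All runners are deterministic under the
# supplied seed; simulation durations default to scaled-down values (tens to
# hundreds of seconds per grid point) and can be raised via the config.

#' Run a named experiment
#'
#' Available experiments:
#' * `worked_numbers` — the analytic spot checks (variability share `q`,
#'   synchrony ratio `kappa`, example voltage correlations, skewness values
#'   and the skewness sign-change rate).
#' * `variance_vs_rate` — exact theory and simulated variance vs drive rate
#'   under asynchronous and synchronous conditions.
#' * `shared_inputs` — voltage correlation vs shared input fractions.
#' * `synchrony_correlation` — voltage correlation vs cross-neuron spiking
#'   correlation, both `kappa` cases.
#' * `skewness_vs_drive` — exact and approximate skewness vs drive rate.
#' * `jitter_consistency` — stationary statistics of matched instantaneous
#'   vs jittered synchronous drives, plus measured count correlations.
#' * `decorrelating_drive` — pair correlation and variance vs the rate of
#'   an added uncorrelated excitatory pool.
#'
#' @param name Experiment name.
#' @param cfg Named list of overrides (experiment-specific; see each
#'   runner's defaults in the source).
#' @param seed Integer seed controlling all randomness.
#' @return A data frame, one row per grid point/quantity.
#' @export
run_experiment <- function(name, cfg = list(), seed = 1) {
  runners <- list(
    worked_numbers = exp_worked_numbers,
    variance_vs_rate = exp_variance_vs_rate,
    shared_inputs = exp_shared_inputs,
    synchrony_correlation = exp_synchrony_correlation,
    skewness_vs_drive = exp_skewness_vs_drive,
    jitter_consistency = exp_jitter_consistency,
    decorrelating_drive = exp_decorrelating_drive
  )
  if (!name %in% names(runners)) {
    stop(sprintf("unknown experiment '%s'; available: %s", name,
                 paste(names(runners), collapse = ", ")))
  }
  runners[[name]](cfg, seed)
}

merge_cfg <- function(defaults, cfg) {
  defaults[names(cfg)] <- cfg
  defaults
}

exp_worked_numbers <- function(cfg, seed) {
  d <- merge_cfg(list(
    Ke = 1e4, Ki = 2500, we = 1e-4, re = 10, ri = 10,
    m_values = c(0, 15), rho = 0.03, rho_cross = 0.013,
    skew_Ke = 1e3, skew_re = c(1, 25), skew_rho = c(0, 0.03)
  ), cfg)
  params <- neuron_params()
  wi <- 4 * d$we
  pools <- list(input_pool("e", d$Ke, d$we, d$re),
                input_pool("i", d$Ki, wi, d$ri))
  rows <- list()
  add <- function(quantity, value, ...) {
    rows[[length(rows) + 1]] <<- data.frame(quantity = quantity,
                                            value = value, ...)
  }
  for (m in d$m_values) {
    q <- excitatory_variability_share(pools, m, params)
    add(sprintf("q_percent_m%g", m), 100 * q)
    kap <- kappa_synchrony(d$Ke, d$Ki, q, cross_correlated = TRUE)
    add(sprintf("kappa_percent_of_Ke_m%g", m), 100 * kap / d$Ke)
    add(sprintf("rhoV_synchrony_m%g", m),
        correlation_synchrony(d$rho, d$rho_cross, kap))
  }
  for (re in d$skew_re) {
    base <- skewness_excitation_approx(d$skew_Ke, re, params)$baseline
    add(sprintf("current_based_skewness_re%g", re), base)
  }
  for (rho in d$skew_rho) {
    sk <- skewness_excitation_approx(d$skew_Ke, 1, params, rho_e = rho)
    add(sprintf("skewness_re1_rho%g", rho), sk$skewness)
  }
  add("skewness_sign_change_Hz", skewness_sign_change_rate(params))
  do.call(rbind, rows)
}

exp_variance_vs_rate <- function(cfg, seed) {
  d <- merge_cfg(list(
    Ke = 1000, we = 1e-3, Ki = 250, wi = 4e-3,
    rates = c(1, 5, 10), rho_sync = 0.03, T = 100, simulate = TRUE
  ), cfg)
  params <- neuron_params()
  rows <- list()
  i <- 0
  for (r in d$rates) {
    for (cond in c("asynchronous", "synchronous")) {
      rho <- if (cond == "synchronous") d$rho_sync else 0
      jm <- jump_model_ei(beta_binomial_model(d$Ke, rho, r), d$we,
                          beta_binomial_model(d$Ki, rho, r), d$wi)
      v_exact <- stationary_variance(jm, params)
      m_exact <- stationary_mean(jm, params)
      sim_var <- sim_var_se <- NA_real_
      if (isTRUE(d$simulate)) {
        i <- i + 1
        ev <- sample_event_train(jm, d$T, seed + i)
        tr <- simulate_population(ev, params)
        s <- empirical_summary(tr, n_boot = 100, seed = seed + 1000 + i)
        sim_var <- s$estimate$variance[1]
        sim_var_se <- s$se$variance[1]
      }
      rows[[length(rows) + 1]] <- data.frame(
        rate = r, condition = cond, mean_theory = m_exact,
        variance_theory = v_exact, variance_sim = sim_var,
        variance_sim_se = sim_var_se
      )
    }
  }
  do.call(rbind, rows)
}

exp_shared_inputs <- function(cfg, seed) {
  d <- merge_cfg(list(
    Ke = 1e4, we = 1e-4, Ki = 2500, re = 10, ri = 10,
    fe = seq(0, 1, by = 0.25), fi = c(0, 0.5, 1), m_values = c(0, 15)
  ), cfg)
  params <- neuron_params()
  wi <- 4 * d$we
  pools <- list(input_pool("e", d$Ke, d$we, d$re),
                input_pool("i", d$Ki, wi, d$ri))
  grid <- expand.grid(fe = d$fe, fi = d$fi, m = d$m_values)
  grid$q <- vapply(grid$m, function(m) {
    excitatory_variability_share(pools, m, params)
  }, numeric(1))
  grid$rho_V <- correlation_shared_inputs(grid$fe, grid$fi, grid$q)
  grid
}

exp_synchrony_correlation <- function(cfg, seed) {
  d <- merge_cfg(list(
    Ke = 1e4, Ki = 2500, rho = 0.03, rho_cross = seq(0, 0.03, by = 0.005),
    m_values = c(0, 15)
  ), cfg)
  params <- neuron_params()
  we <- 1 / d$Ke
  pools <- list(input_pool("e", d$Ke, we, 10),
                input_pool("i", d$Ki, 4 * we, 10))
  rows <- list()
  for (m in d$m_values) {
    q <- excitatory_variability_share(pools, m, params)
    for (case in c("separate", "cross_correlated")) {
      kap <- kappa_synchrony(d$Ke, d$Ki, q, case == "cross_correlated")
      for (rp in d$rho_cross) {
        rows[[length(rows) + 1]] <- data.frame(
          m = m, case = case, rho_cross = rp, kappa = kap,
          rho_V = correlation_synchrony(d$rho, rp, kap),
          bound = rp / d$rho
        )
      }
    }
  }
  do.call(rbind, rows)
}

exp_skewness_vs_drive <- function(cfg, seed) {
  d <- merge_cfg(list(
    Ke = 1000, we = 1e-3, rho = 0.03, rates = c(1, 5, 10, 25, 40),
    T = 100, simulate = FALSE
  ), cfg)
  params <- neuron_params()
  rows <- list()
  i <- 0
  for (r in d$rates) {
    jm <- jump_model_ei(beta_binomial_model(d$Ke, d$rho, r), d$we)
    th <- third_moment(jm, params)
    approx <- skewness_excitation_approx(d$Ke, r, params, rho_e = d$rho,
                                         we = d$we)
    sim_skew <- sim_skew_se <- NA_real_
    if (isTRUE(d$simulate)) {
      i <- i + 1
      ev <- sample_event_train(jm, d$T, seed + i)
      tr <- simulate_population(ev, params)
      s <- empirical_summary(tr, n_boot = 100, seed = seed + 1000 + i)
      sim_skew <- s$estimate$skewness[1]
      sim_skew_se <- s$se$skewness[1]
    }
    rows[[length(rows) + 1]] <- data.frame(
      rate = r, skewness_exact = th$skewness,
      skewness_approx = approx$skewness, variance_exact = th$variance,
      skewness_sim = sim_skew, skewness_sim_se = sim_skew_se
    )
  }
  do.call(rbind, rows)
}

exp_jitter_consistency <- function(cfg, seed) {
  d <- merge_cfg(list(
    K = 100, w = 0.01, r = 10, rho_inst = 0.25, sigmaJ = 0.05,
    window = 0.025, T = 200, dt = 1e-4
  ), cfg)
  params <- neuron_params()
  pool <- input_pool("e", d$K, d$w, d$r)
  corr <- correlation_spec(matrix(d$rho_inst, 1, 1))
  raster <- sample_raster(corr, list(pool), dt = d$dt, T = d$T, seed = seed)
  ev <- raster_to_events(raster)
  tr <- simulate_population(ev, params)
  s0 <- empirical_summary(tr, n_boot = 100, seed = seed + 1)
  # jitter each input's spikes, re-bin, and rebuild the event train
  trains <- raster_to_trains(raster, 1L, seed = seed + 2)
  jit <- jitter_spikes(trains, d$sigmaJ, d$T, seed = seed + 3)
  nb <- ncol(raster$counts)
  cnt <- integer(nb)
  for (v in jit) {
    bins <- pmin(pmax(ceiling(v / d$dt), 1L), nb)
    tb <- tabulate(bins, nbins = nb)
    cnt <- cnt + tb
  }
  raster_j <- raster
  raster_j$counts <- matrix(cnt, 1, nb)
  ev_j <- raster_to_events(raster_j)
  tr_j <- simulate_population(ev_j, params)
  s1 <- empirical_summary(tr_j, n_boot = 100, seed = seed + 4)
  cc <- mean_pairwise_count_correlation(jit, d$window, d$T,
                                        max_pairs = 20, seed = seed + 5)
  data.frame(
    condition = c("instantaneous", "jittered"),
    mean = c(s0$estimate$mean[1], s1$estimate$mean[1]),
    variance = c(s0$estimate$variance[1], s1$estimate$variance[1]),
    skewness = c(s0$estimate$skewness[1], s1$estimate$skewness[1]),
    skewness_se = c(s0$se$skewness[1], s1$se$skewness[1]),
    count_correlation_25ms = c(NA_real_, cc)
  )
}

#' Mean pairwise count correlation across input trains
#'
#' Average of [empirical_count_correlation()] over (a sample of) input
#' pairs.
#'
#' @param trains List of spike-time vectors.
#' @param window Window width (seconds).
#' @param T Recording duration (seconds).
#' @param max_pairs Cap on the number of sampled pairs.
#' @param seed Seed used when sampling pairs.
#' @return Mean Pearson correlation.
#' @export
mean_pairwise_count_correlation <- function(trains, window, T,
                                            max_pairs = 50, seed = 1) {
  K <- length(trains)
  stopifnot(K >= 2)
  pairs <- utils::combn(K, 2)
  if (ncol(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  vals <- apply(pairs, 2, function(pr) {
    empirical_count_correlation(trains[[pr[1]]], trains[[pr[2]]], window, T)
  })
  mean(vals)
}

exp_decorrelating_drive <- function(cfg, seed) {
  d <- merge_cfg(list(
    Ke = 1e4, we = 1e-3, Ki = 250, wi = 4e-3, re = 5, ri = 10,
    rho = 0.03, rho_cross = 0.025,
    Kx = 250, wx = 0.01, drive_rates = c(0, 5, 10, 20, 40)
  ), cfg)
  params <- neuron_params()
  rows <- list()
  for (rx in d$drive_rates) {
    pools <- list(input_pool("e", d$Ke, d$we, d$re),
                  input_pool("i", d$Ki, d$wi, d$ri))
    rho_m <- diag(c(d$rho, d$rho))
    if (rx > 0) {
      pools <- c(pools, list(input_pool("e", d$Kx, d$wx, rx)))
      rho_m <- diag(c(d$rho, d$rho, 0))
    }
    corr <- correlation_spec(rho_m)
    v <- variance_small_weight(pools, corr, params)
    cross <- matrix(0, length(pools), length(pools))
    cross[1, 1] <- cross[2, 2] <- d$rho_cross # correlated shared-pool drive
    cv <- covariance_small_weight(pools, pools, cross, params)
    rows[[length(rows) + 1]] <- data.frame(
      drive_rate = rx, variance = as.numeric(v), covariance = cv,
      rho_V = cv / as.numeric(v)
    )
  }
  do.call(rbind, rows)
}
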