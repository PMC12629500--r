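test_that("beta marginals carry the exact rate and intraclass correlation", {
  r <- 10
  rho <- 0.2
  dt <- 1e-4
  bp <- beta_marginal_params(r, rho, dt)
  mean_theta <- bp$alpha / (bp$alpha + bp$beta)
  var_theta <- bp$alpha * bp$beta /
    ((bp$alpha + bp$beta)^2 * (bp$alpha + bp$beta + 1))
  expect_equal(mean_theta, r * dt, tolerance = 1e-12)
  # within-block spiking correlation of conditionally independent
  # Bernoulli(theta) indicators equals Var(theta) / (E[theta](1 - E[theta]))
  expect_equal(var_theta / (mean_theta * (1 - mean_theta)), rho,
               tolerance = 1e-12)
  expect_error(beta_marginal_params(10, 0, dt), "strictly")
})

test_that("copula calibration hits the cross-block moment target", {
  corr <- correlation_spec(matrix(c(0.25, 0.1, 0.1, 0.25), 2))
  rates <- c(10, 20)
  dt <- 1e-4
  Sigma <- calibrate_copula_sigma(corr, rates, dt)
  expect_equal(diag(Sigma), c(1, 1))
  expect_true(Sigma[1, 2] > 0 && Sigma[1, 2] < 1)
  mom <- aoncb:::copula_cross_moment(Sigma[1, 2], rates[1], 0.25,
                                     rates[2], 0.25, dt)
  target <- sqrt(rates[1] * rates[2]) * 0.1 * dt
  expect_equal(mom, target, tolerance = 1e-6)
  # independence at zero copula correlation: the moment factorizes (up to
  # the quadrature error on the spiky beta quantile)
  m0 <- aoncb:::copula_cross_moment(0, rates[1], 0.25, rates[2], 0.25, dt)
  expect_lt(abs(m0 - rates[1] * dt * rates[2] * dt) /
              (rates[1] * dt * rates[2] * dt), 0.05)
  # infeasible cross-block correlations are rejected at construction
  expect_error(correlation_spec(matrix(c(0.01, 0.5, 0.5, 0.01), 2)),
               "exceeds")
})

test_that("sampled rasters are seed-reproducible with the nominal rates", {
  pool <- input_pool("e", 50, 0.01, 10)
  corr <- correlation_spec(matrix(0.2, 1, 1))
  r1 <- sample_raster(corr, list(pool), dt = 1e-4, T = 50, seed = 11)
  r2 <- sample_raster(corr, list(pool), dt = 1e-4, T = 50, seed = 11)
  expect_identical(r1$counts, r2$counts)
  # mean spike count per input ~ r * T (relative SE ~ sqrt((1+rho K)/ (K r T)))
  rate_hat <- sum(r1$counts) / (pool$K * r1$T)
  expect_lt(abs(rate_hat - 10) / 10, 0.2)
  # measured within-pool correlation at the bin scale matches the target
  trains <- raster_to_trains(r1, 1L, seed = 12)
  cc <- mean_pairwise_count_correlation(trains, window = 1e-4, T = r1$T,
                                        max_pairs = 30, seed = 13)
  expect_lt(abs(cc - 0.2), 0.05)
})

test_that("jitter preserves spike counts and stays inside the recording", {
  set.seed(5)
  spikes <- list(sort(runif(200, 0, 100)), sort(runif(150, 0, 100)))
  jit <- jitter_spikes(spikes, sigmaJ = 0.05, T = 100, seed = 3)
  expect_identical(lengths(jit), lengths(spikes))
  for (v in jit) {
    expect_true(all(v >= 0 & v < 100))
    expect_false(is.unsorted(v))
  }
  expect_identical(jitter_spikes(spikes, 0, 100, seed = 3),
                   lapply(spikes, sort))
})

test_that("independent trains show near-zero measured count correlation", {
  set.seed(21)
  a <- cumsum(rexp(2000, 10))
  b <- cumsum(rexp(2000, 10))
  T <- min(max(a), max(b))
  cc <- empirical_count_correlation(a, b, window = 0.025, T = T)
  expect_lt(abs(cc), 0.03)
  expect_error(empirical_count_correlation(a, b, window = 10, T = T),
               "100 windows")
})

test_that("raster-to-event conversion conserves the total synaptic weight", {
  pools <- list(input_pool("e", 30, 2e-3, 10), input_pool("i", 20, 5e-3, 5))
  corr <- correlation_spec(diag(c(0.1, 0.05)))
  ras <- sample_raster(corr, pools, dt = 1e-4, T = 20, seed = 9)
  ev <- raster_to_events(ras)
  expect_s3_class(ev, "event_train")
  expect_false(is.unsorted(ev$times, strictly = TRUE))
  expect_equal(sum(ev$We), sum(ras$counts[1, ]) * 2e-3, tolerance = 1e-12)
  expect_equal(sum(ev$Wi), sum(ras$counts[2, ]) * 5e-3, tolerance = 1e-12)
})
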