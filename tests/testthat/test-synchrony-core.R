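test_that("beta-binomial pools reproduce the prescribed spiking correlations", {
  rho <- 0.05
  bb <- beta_binomial_model(K = 100, rho = rho, r = 10)
  jm <- as_jump_model(bb, w = 0.01, "e")
  expect_equal(pairwise_correlation(jm, 1, 2), rho, tolerance = 1e-10)
  beta <- 1 / rho - 1
  expect_equal(higher_order_correlation(jm, 1:3),
               prod(1:2 / (beta + 1:2)), tolerance = 1e-10)
  expect_equal(higher_order_correlation(jm, 1:4),
               prod(1:3 / (beta + 1:3)), tolerance = 1e-10)
})

test_that("third-order synchrony decays as 2 rho^2 / (1 + rho)", {
  for (rho in c(0.01, 0.03, 0.1)) {
    jm <- as_jump_model(beta_binomial_model(500, rho, 5), 1e-3, "e")
    expect_equal(higher_order_correlation(jm, 1:3),
                 2 * rho^2 / (1 + rho), tolerance = 1e-9)
  }
})

test_that("collective event rate conserves the total spike rate", {
  bb <- beta_binomial_model(K = 200, rho = 0.04, r = 7)
  pmf <- bb_count_pmf(bb)
  b <- collective_event_rate(bb)
  expect_equal(b * sum(pmf$k * pmf$prob), bb$K * bb$r, tolerance = 1e-9)
  # digamma closed form: K = 2, rho = 0.5 gives psi(3) - psi(1) = 1.5 Hz
  expect_equal(collective_event_rate(beta_binomial_model(2, 0.5, 1)), 1.5,
               tolerance = 1e-12)
  # asynchronous limit: independent inputs superpose
  expect_equal(collective_event_rate(beta_binomial_model(50, 0, 3)), 150)
  # monotone in the subset size, equal to r at a single input
  expect_equal(collective_event_rate(bb, 1), bb$r, tolerance = 1e-12)
  expect_lt(collective_event_rate(bb, 100), b)
})

test_that("subsampled drives satisfy the pair event-rate overlap identity", {
  jm <- jump_model(
    b = 10,
    We = rbind(c(0.1, 0), c(0, 0.1), c(0.1, 0.1)),
    prob = c(0.3, 0.3, 0.4)
  )
  b1 <- subsample_rate(jm, "1")
  b2 <- subsample_rate(jm, "2")
  expect_equal(b1, 7)
  expect_equal(b2, 7)
  q12 <- 0.4 # P[both driven | at least one driven]
  expect_equal(pair_event_rate(b1, b2, q12), jm$b)
  expect_equal(pair_event_rate(5, 10, 0), 15)
  expect_equal(pair_event_rate(5, 10, 0.5), 10)
  expect_error(pair_event_rate(5, 10, 0.8), "q12")
})

test_that("Monte Carlo jump expectations agree with exact atom sums", {
  jm <- as_jump_model(beta_binomial_model(50, 0.1, 5), 0.01, "e")
  f <- function(We, Wi) 1 - exp(-We[, 1])
  exact <- jump_expectation(jm, f)
  sampler <- jump_model_sampler(jm$b, function(n, seed) {
    set.seed(seed)
    k <- sample(length(jm$prob), n, TRUE, jm$prob)
    list(We = jm$We[k, , drop = FALSE], Wi = jm$Wi[k, , drop = FALSE])
  })
  mc <- jump_expectation(sampler, f, n_draws = 2e5, seed = 7)
  expect_identical(exact$se, 0)
  expect_gt(mc$se, 0)
  expect_lt(abs(mc$value - exact$value), 4 * mc$se)
  expect_error(jump_expectation(sampler, f), "seed")
})

test_that("transmission failure scales rates by p and correlations by sqrt(p)", {
  pools <- list(input_pool("e", 100, 1e-3, 10), input_pool("i", 50, 4e-3, 8))
  corr <- correlation_spec(matrix(c(0.04, 0.01, 0.01, 0.02), 2))
  ft <- faulty_transmission_transform(pools, corr, p = c(0.5, 0.8))
  expect_equal(ft$pools[[1]]$r[1], 5)
  expect_equal(ft$pools[[2]]$r[1], 6.4)
  expect_equal(ft$corr$block_rho[1, 2], 0.01 * sqrt(0.5 * 0.8))
  expect_equal(ft$corr$block_rho[1, 1], 0.04 * 0.5)
  expect_identical(ft$pools[[1]]$K, 100L)
  ftc <- faulty_transmission_transform(pools, corr, p = 0.5,
                                       compensate = TRUE)
  expect_identical(ftc$pools[[1]]$K, 200L)
  expect_identical(ftc$pools[[2]]$K, 100L)
  expect_error(faulty_transmission_transform(pools, corr, p = 0), "release")
})

test_that("degenerate jump models are rejected with informative errors", {
  expect_error(jump_model(10, We = c(0.1, 0), prob = c(0.5, 0.5)),
               "positive jump")
  expect_error(jump_model(10, We = c(0.1, 0.2), prob = c(0.7, 0.7)),
               "sum to 1")
  expect_error(beta_binomial_model(10, 1, 5))
  expect_error(beta_binomial_model(10, -0.1, 5))
  jm <- as_jump_model(beta_binomial_model(10, 0.1, 5), 0.01, "e")
  expect_error(coactivation_moment(jm, c(1, 1)), "distinct")
  expect_error(coactivation_moment(jm, c(1, 11)), "range")
})
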