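test_that("the moment recursion reproduces the closed-form stationary mean", {
  p <- neuron_params(Irest = 2)
  for (s in 1:5) {
    jm <- random_ei_model(100 + s)
    ce <- jump_expectation(jm, function(We, Wi) {
      tot <- We[, 1] + Wi[, 1]
      ifelse(tot > 0, We[, 1] / tot * (1 - exp(-tot)), 0)
    })$value * jm$b
    ci <- jump_expectation(jm, function(We, Wi) {
      tot <- We[, 1] + Wi[, 1]
      ifelse(tot > 0, Wi[, 1] / tot * (1 - exp(-tot)), 0)
    })$value * jm$b
    m_closed <- (p$Irest / p$tau + ce * p$Ve + ci * p$Vi) /
      (1 / p$tau + ce + ci)
    expect_equal(stationary_mean(jm, p), m_closed, tolerance = 1e-12)
    # the engine's order-1 shifted moment is E[V - Irest]
    expect_equal(general_mixed_moment(jm, p, jm$labels[1]),
                 m_closed - p$Irest, tolerance = 1e-12)
  }
})

test_that("the recursion agrees with the compact variance and third-moment forms", {
  p <- neuron_params()
  for (s in 1:5) {
    jm <- random_ei_model(200 + s)
    m <- stationary_mean(jm, p)
    # independent oracle for the variance: with R = Vmix - m and Y = e^-W,
    # M2 = b E[R^2 (1-Y)^2] / (2/tau + b E[1 - Y^2])
    EY <- function(f) jump_expectation(jm, f)$value
    R <- function(We, Wi) {
      tot <- We[, 1] + Wi[, 1]
      (We[, 1] * p$Ve + Wi[, 1] * p$Vi) / tot - m
    }
    M2 <- jm$b * EY(function(We, Wi) {
      R(We, Wi)^2 * (1 - exp(-(We[, 1] + Wi[, 1])))^2
    }) / (2 / p$tau + jm$b * EY(function(We, Wi) {
      1 - exp(-2 * (We[, 1] + Wi[, 1]))
    }))
    expect_equal(stationary_variance(jm, p), M2, tolerance = 1e-10)
    expect_equal(centered_mixed_moment(jm, p, rep(jm$labels[1], 2)), M2,
                 tolerance = 1e-10)
    th <- third_moment(jm, p)
    expect_equal(th$variance, M2, tolerance = 1e-10)
    expect_equal(centered_mixed_moment(jm, p, rep(jm$labels[1], 3)),
                 th$third, tolerance = 1e-10)
  }
})

test_that("mixed moments are symmetric and covariances vanish for disjoint drives", {
  p <- neuron_params()
  jm <- jump_model(
    b = 60,
    We = rbind(c(0.02, 0), c(0, 0.03), c(0.01, 0.01)),
    Wi = rbind(c(0.005, 0), c(0, 0), c(0, 0.004)),
    prob = c(0.4, 0.4, 0.2),
    labels = c("a", "b")
  )
  expect_equal(centered_mixed_moment(jm, p, c("a", "b")),
               centered_mixed_moment(jm, p, c("b", "a")), tolerance = 1e-13)
  expect_equal(stationary_covariance(jm, p, c("a", "b")),
               centered_mixed_moment(jm, p, c("a", "b")), tolerance = 1e-13)
  # disjointly driven neurons are uncorrelated
  jm0 <- jump_model(
    b = 40,
    We = rbind(c(0.05, 0), c(0, 0.05)),
    prob = c(0.5, 0.5),
    labels = c("a", "b")
  )
  expect_equal(stationary_covariance(jm0, p, c("a", "b")), 0,
               tolerance = 1e-12)
  tab <- moment_table(jm, p, order = 3)
  expect_true(all(c("labels", "order", "shifted", "centered") %in%
                    names(tab)))
  expect_true(any(tab$order == 3))
  # centered singletons vanish by construction
  expect_equal(tab$centered[tab$order == 1], c(0, 0), tolerance = 1e-12)
})

test_that("small-weight formulas approach the exact engine as weights shrink", {
  p <- neuron_params()
  K <- 200
  r <- 10
  rho <- 0.05
  err_at <- function(w) {
    jm <- as_jump_model(beta_binomial_model(K, rho, r), w, "e")
    pools <- list(input_pool("e", K, w, r))
    v_sw <- variance_small_weight(pools, correlation_spec(matrix(rho, 1, 1)),
                                  p)
    abs(as.numeric(v_sw) - stationary_variance(jm, p)) /
      stationary_variance(jm, p)
  }
  e1 <- err_at(4e-3)
  e2 <- err_at(2e-3)
  e3 <- err_at(1e-3)
  expect_lt(e2, e1)
  expect_lt(e3, e2)
  expect_lt(e1 / e2, 2.6) # first-order convergence: halving w halves the error
  expect_gt(e1 / e2, 1.5)
})

test_that("synchrony strictly amplifies variance while preserving the mean", {
  p <- neuron_params()
  K <- 300
  w <- 1e-3
  r <- 10
  vs <- vapply(c(0, 0.01, 0.03, 0.1), function(rho) {
    stationary_variance(as_jump_model(beta_binomial_model(K, rho, r), w, "e"),
                        p)
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
  ms <- vapply(c(0, 0.03, 0.1), function(rho) {
    stationary_mean(as_jump_model(beta_binomial_model(K, rho, r), w, "e"), p)
  }, numeric(1))
  # the mean is synchrony-invariant at leading order in the weights; jump
  # saturation can only lower it, slightly
  expect_true(all(diff(ms) <= 1e-12))
  expect_lt(max(abs(ms - ms[1])), 0.03 * abs(ms[1]))
})

test_that("shared-input and synchrony correlation formulas obey their bounds", {
  expect_equal(correlation_shared_inputs(1, 1, 0.7), 1)
  expect_equal(correlation_shared_inputs(0, 0, 0.7), 0)
  q <- 0.9
  expect_equal(correlation_shared_inputs(0.5, 0.25, q),
               0.5 * q + 0.25 * (1 - q), tolerance = 1e-12)
  # kappa closed form, case (ii): (sqrt(Ke q) - sqrt(Ki (1 - q)))^2
  Ke <- 1e4
  Ki <- 2500
  kap <- kappa_synchrony(Ke, Ki, q, cross_correlated = TRUE)
  expect_equal(kap, (sqrt(Ke * q) - sqrt(Ki * (1 - q)))^2, tolerance = 1e-12)
  rho <- 0.03
  for (rp in c(0, 0.01, 0.03)) {
    rv <- correlation_synchrony(rho, rp, kap)
    expect_lte(rv, rp / rho + 1e-12)
    expect_gte(rv, 0)
  }
  # monotone in the cross-neuron correlation
  rvs <- vapply(c(0, 0.005, 0.01, 0.02, 0.03), function(rp) {
    correlation_synchrony(rho, rp, kap)
  }, numeric(1))
  expect_true(all(diff(rvs) > 0))
})

test_that("electrical coupling pulls stationary means together", {
  p <- neuron_params()
  # asymmetric drive: neuron 1 strongly excited, neuron 2 weakly
  jm <- jump_model(
    b = 150,
    We = rbind(c(0.02, 0), c(0, 0.004)),
    prob = c(0.5, 0.5),
    labels = c("1", "2")
  )
  m0 <- gap_junction_means(jm, p, g = 0)
  expect_equal(m0[1], stationary_mean(jm, p), tolerance = 1e-10)
  jm_swap <- jump_model(jm$b, jm$We[, 2:1], jm$Wi[, 2:1], prob = jm$prob,
                        labels = c("2", "1"))
  expect_equal(m0[2], stationary_mean(jm_swap, p), tolerance = 1e-10)
  gaps <- vapply(c(0, 0.5, 2, 10, 100), function(g) {
    m <- gap_junction_means(jm, p, g)
    abs(m[1] - m[2])
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  m_inf <- gap_junction_means(jm, p, 1e6)
  expect_lt(abs(m_inf[1] - m_inf[2]), 1e-4)
})

test_that("weight heterogeneity amplifies variance by exactly 1 + CV^2", {
  p <- neuron_params()
  r <- 10
  set.seed(3)
  w_het <- 2e-3 * exp(rnorm(100, 0, 0.5))
  het <- heterogeneity_equivalent_variance(w_het, r, p)
  hom <- heterogeneity_equivalent_variance(rep(mean(w_het), 100), r, p)
  expect_equal(hom$CV2, 0, tolerance = 1e-12)
  expect_equal(het$variance, hom$variance * het$factor, tolerance = 1e-10)
  expect_gt(het$CV2, 0)
})
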