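test_that("jumps move the voltage toward the mixed reversal and stay bounded", {
  p <- neuron_params()
  # small excitatory weight: J ~ w (Ve - V)
  expect_equal(marcus_jump(0, 0.01, 0, p), (1 - exp(-0.01)) * 60,
               tolerance = 1e-12)
  set.seed(2)
  V <- runif(100, p$Vi + 1e-6, p$Ve - 1e-6)
  We <- runif(100, 0, 3)
  Wi <- runif(100, 0, 3)
  keep <- We + Wi > 0
  J <- marcus_jump(V[keep], We[keep], Wi[keep], p)
  Vmix <- (We[keep] * p$Ve + Wi[keep] * p$Vi) / (We[keep] + Wi[keep])
  post <- V[keep] + J
  expect_true(all(post > p$Vi & post < p$Ve))
  expect_true(all(sign(J) == sign(Vmix - V[keep]) | J == 0))
  expect_true(all(abs(post - Vmix) <= abs(V[keep] - Vmix) + 1e-12))
  expect_error(marcus_jump(0, 0, 0, p), "We \\+ Wi")
  expect_error(marcus_jump(70, 0.1, 0, p), "strictly inside")
})

test_that("the event-driven integrator matches a plain R reference exactly", {
  p <- neuron_params(tau = 0.02, Irest = 3)
  set.seed(4)
  times <- sort(runif(10, 0, 1))
  We <- matrix(runif(10, 0, 0.5), ncol = 1)
  Wi <- matrix(runif(10, 0, 0.5), ncol = 1)
  ev <- event_train(times, We, Wi, T = 1)
  tr <- simulate_population(ev, p)
  # reference: exponential relaxation toward Irest between events, Marcus
  # update at events
  V <- p$Irest
  t0 <- 0
  ref <- numeric(10)
  for (k in 1:10) {
    V <- p$Irest + (V - p$Irest) * exp(-(times[k] - t0) / p$tau)
    V <- V + marcus_jump(V, We[k, 1], Wi[k, 1], p)
    ref[k] <- V
    t0 <- times[k]
  }
  expect_equal(tr$V[, 1], ref, tolerance = 1e-13)
  # trace reconstruction at the event times reproduces the relaxation
  tg <- times[5] + 0.005
  expect_equal(
    trace_at_times(tr, tg)[1, 1],
    p$Irest + (ref[5] - p$Irest) * exp(-0.005 / p$tau),
    tolerance = 1e-12
  )
})

test_that("sampled event trains are Poisson with reproducible seeding", {
  jm <- as_jump_model(beta_binomial_model(100, 0.05, 10), 1e-3, "e")
  ev1 <- sample_event_train(jm, T = 50, seed = 8)
  ev2 <- sample_event_train(jm, T = 50, seed = 8)
  expect_identical(ev1$times, ev2$times)
  expect_identical(ev1$We, ev2$We)
  expect_false(is.unsorted(ev1$times, strictly = TRUE))
  expect_true(all(ev1$times > 0 & ev1$times <= 50))
  n <- length(ev1$times)
  expect_lt(abs(n - jm$b * 50) / sqrt(jm$b * 50), 5)
})

test_that("simulated voltages never leave the reversal-potential interval", {
  p <- neuron_params()
  jm <- jump_model_ei(beta_binomial_model(100, 0.2, 20), 5e-2,
                      beta_binomial_model(100, 0.2, 20), 5e-2)
  ev <- sample_event_train(jm, T = 20, seed = 14)
  tr <- simulate_population(ev, p)
  expect_true(all(tr$V > p$Vi & tr$V < p$Ve))
})

test_that("gap junctions reduce to the uncoupled model at g = 0 and pull voltages together", {
  p <- neuron_params()
  jm2 <- jump_model(
    b = 200,
    We = rbind(c(0.05, 0), c(0, 0.05)),
    prob = c(0.5, 0.5),
    labels = c("1", "2")
  )
  ev <- sample_event_train(jm2, T = 30, seed = 6)
  tr0 <- simulate_population(ev, p)
  trg0 <- simulate_gap_junction_pair(ev, p, g = 0)
  expect_equal(trg0$V, tr0$V, tolerance = 1e-12)
  d_abs <- function(tr) mean(abs(tr$V[, 1] - tr$V[, 2]))
  tr1 <- simulate_gap_junction_pair(ev, p, g = 1)
  tr5 <- simulate_gap_junction_pair(ev, p, g = 5)
  expect_lt(d_abs(tr1), d_abs(trg0))
  expect_lt(d_abs(tr5), d_abs(tr1))
  expect_true(all(tr5$V > p$Vi & tr5$V < p$Ve))
})

test_that("the finite synaptic time-constant reference is deterministic and consistent", {
  p <- neuron_params()
  jm <- as_jump_model(beta_binomial_model(200, 0.03, 10), 2e-3, "e")
  ev <- sample_event_train(jm, T = 60, seed = 31)
  a <- simulate_finite_synapse(ev, p, epsilon = 0.01, dt_euler = 1e-5)
  b <- simulate_finite_synapse(ev, p, epsilon = 0.01, dt_euler = 1e-5)
  expect_identical(a$mean, b$mean)
  expect_gt(a$n, 0)
  expect_gt(a$variance, 0)
  # matches the exact event-driven statistics loosely even at coarse epsilon
  tr <- simulate_population(ev, p)
  s <- empirical_summary(tr, n_boot = 50, seed = 32)
  expect_lt(abs(a$mean - s$estimate$mean[1]), 0.1 * abs(s$estimate$mean[1]))
  expect_error(simulate_finite_synapse(ev, p, epsilon = 0.01, dt_euler = 1e-3),
               "dt_euler")
})
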