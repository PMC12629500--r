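test_that("unknown experiments fail with the list of available runners", {
  expect_error(run_experiment("nope"), "worked_numbers")
  expect_error(run_experiment("nope"), "decorrelating_drive")
})

test_that("the worked-number runner reproduces the analytic spot checks", {
  tab <- run_experiment("worked_numbers")
  val <- function(q) tab$value[tab$quantity == q]
  expect_equal(val("q_percent_m0"), 90, tolerance = 1e-10)
  expect_equal(val("kappa_percent_of_Ke_m0"), 62.5, tolerance = 1e-10)
  expect_equal(val("skewness_sign_change_Hz"), 1 / (2 * 0.015),
               tolerance = 1e-12)
  expect_lt(val("q_percent_m15"), val("q_percent_m0"))
  expect_lt(val("kappa_percent_of_Ke_m15"), val("kappa_percent_of_Ke_m0"))
  # synchrony-based voltage correlations exceed the cross/within ratio bound
  # only never: rho_V < rho' / rho = 0.013 / 0.03
  expect_lt(val("rhoV_synchrony_m0"), 0.013 / 0.03)
  expect_lt(val("rhoV_synchrony_m15"), val("rhoV_synchrony_m0"))
})

test_that("experiment tables are bit-identical under a fixed seed", {
  a <- run_experiment("variance_vs_rate",
                      cfg = list(rates = c(2, 8), T = 30), seed = 7)
  b <- run_experiment("variance_vs_rate",
                      cfg = list(rates = c(2, 8), T = 30), seed = 7)
  expect_identical(a, b)
  # simulation estimates agree with the exact theory within 4 SE
  expect_true(all(abs(a$variance_sim - a$variance_theory) <
                    4 * a$variance_sim_se))
  # synchrony amplifies the variance at every rate
  sync <- a$variance_theory[a$condition == "synchronous"]
  asyn <- a$variance_theory[a$condition == "asynchronous"]
  expect_true(all(sync > asyn))
})

test_that("shared-input correlations interpolate between fi-only and fe-only", {
  tab <- run_experiment("shared_inputs")
  expect_true(all(tab$rho_V >= -1e-12 & tab$rho_V <= 1 + 1e-12))
  full <- tab[tab$fe == 1 & tab$fi == 1, ]
  expect_equal(full$rho_V, rep(1, nrow(full)), tolerance = 1e-12)
  none <- tab[tab$fe == 0 & tab$fi == 0, ]
  expect_equal(none$rho_V, rep(0, nrow(none)), tolerance = 1e-12)
  # at spontaneous q ~ 0.9, excitatory sharing dominates
  sp <- tab[tab$m == 0, ]
  expect_true(all(sp$rho_V[sp$fe == 1 & sp$fi == 0] >
                    sp$rho_V[sp$fe == 0 & sp$fi == 1]))
})

test_that("synchrony-induced correlations stay below the cross/within bound", {
  tab <- run_experiment("synchrony_correlation")
  expect_true(all(tab$rho_V <= tab$bound + 1e-12))
  expect_true(all(tab$rho_V[tab$rho_cross == 0] == 0))
  for (case in unique(tab$case)) {
    for (m in unique(tab$m)) {
      sub <- tab[tab$case == case & tab$m == m, ]
      expect_true(all(diff(sub$rho_V[order(sub$rho_cross)]) > 0))
    }
  }
})

test_that("skewness decays with drive and is amplified by synchrony", {
  tab <- run_experiment("skewness_vs_drive")
  expect_true(all(diff(tab$skewness_exact) < 0))
  low <- run_experiment("skewness_vs_drive", cfg = list(rates = 1))
  none <- run_experiment("skewness_vs_drive",
                         cfg = list(rates = 1, rho = 0))
  expect_gt(low$skewness_exact, none$skewness_exact)
  # the sign change of the approximate form sits at 1/(2 tau) ~ 33 Hz
  hi <- run_experiment("skewness_vs_drive", cfg = list(rates = c(30, 40)))
  expect_gt(hi$skewness_approx[1], 0)
  expect_lt(hi$skewness_approx[2], 0)
})

test_that("uncorrelated external drive decorrelates the pair", {
  tab <- run_experiment("decorrelating_drive")
  expect_true(all(diff(tab$rho_V) < 0))
  expect_true(all(tab$variance > 0))
  expect_true(all(tab$covariance > 0))
  expect_true(all(tab$rho_V > 0 & tab$rho_V < 1))
})

test_that("model configurations round-trip through YAML and JSON", {
  cfg_text <- paste(
    "neuron:",
    "  tau: 0.02",
    "  Ve: 55",
    "pools:",
    "  - {kind: e, K: 100, w: 0.001, r: 10}",
    "  - {kind: i, K: 25, w: 0.004, r: 5}",
    "correlation:",
    "  rho: [[0.03, 0.0], [0.0, 0.02]]",
    sep = "\n"
  )
  path <- tempfile(fileext = ".yaml")
  writeLines(cfg_text, path)
  cfg <- read_model_config(path)
  expect_s3_class(cfg$params, "neuron_params")
  expect_equal(cfg$params$tau, 0.02)
  expect_equal(cfg$params$Ve, 55)
  expect_length(cfg$pools, 2)
  expect_equal(cfg$corr$block_rho[1, 1], 0.03)
  jm <- as_jump_model(beta_binomial_model(50, 0.05, 10), 2e-3, "e")
  jpath <- tempfile(fileext = ".json")
  jump_model_to_json(jm, jpath)
  jm2 <- jump_model_from_json(jpath)
  expect_equal(jm2$b, jm$b, tolerance = 1e-12)
  expect_equal(jm2$We, jm$We, tolerance = 1e-12)
  expect_equal(jm2$prob, jm$prob, tolerance = 1e-12)
  p <- neuron_params()
  expect_equal(stationary_variance(jm2, p), stationary_variance(jm, p),
               tolerance = 1e-10)
})
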