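# Randomized excitation-inhibition jump models used by the property tests.
random_ei_model <- function(seed, K_max = 400) {
  set.seed(seed)
  Ke <- sample(50:K_max, 1)
  Ki <- sample(20:(K_max %/% 2), 1)
  we <- stats::runif(1, 5e-4, 5e-3)
  wi <- stats::runif(1, 5e-4, 5e-3)
  re <- stats::runif(1, 2, 20)
  ri <- stats::runif(1, 2, 20)
  rho_e <- stats::runif(1, 0, 0.08)
  rho_i <- stats::runif(1, 0, 0.08)
  jump_model_ei(beta_binomial_model(Ke, rho_e, re), we,
                beta_binomial_model(Ki, rho_i, ri), wi)
}
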