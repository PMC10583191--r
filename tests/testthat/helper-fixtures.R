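# Shared fixtures for the test suite; everything is generated in code.

# one-row species truth with chosen parameters
make_truth <- function(a = 120, b = 0.12, K = 20, m = 260, s = 0.08,
                       theta = 1, species_id = "spX") {
  data.frame(species_id = species_id, a_true = a, b_true = b, K_true = K,
             m_true = m, s_true = s, theta_true = theta,
             stringsAsFactors = FALSE)
}

# config whose species are exact copies of the baseline (no structural
# variation); measurement noise as requested
exact_config <- function(...) {
  generation_config(structural_noise = 0,
                    niche_to_traits = matrix(0, 4, 7),
                    to_phenology = matrix(0, 6, 11), ...)
}

# linear decline profile on a daily grid: fraction 1 at day `from`, 0 at `to`
linear_profile <- function(from = 200, to = 300, species_id = "lin") {
  grid <- seq(from, to, 1)
  senescence_profile(grid, (to - grid) / (to - from),
                     species_id = species_id)
}

# growth-phase measurement table for nlme fitting tests: logistic shoots
# with lognormal K_i spread and multiplicative size noise
logistic_shoots <- function(n_shoots = 7, a = 120, b = 0.12, K = 20,
                            k_cv = 0, noise_cv = 0,
                            days = seq(7, 180, 14)) {
  rows <- lapply(seq_len(n_shoots), function(i) {
    K_i <- if (k_cv > 0) {
      sdlog <- sqrt(log(1 + k_cv^2))
      K * rlnorm(1, -sdlog^2 / 2, sdlog)
    } else K
    size <- K_i * plogis(b * (days - a))
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      size <- size * rlnorm(length(days), -sdlog^2 / 2, sdlog)
    }
    data.frame(shoot_id = sprintf("sh%02d", i), day = days, size = size,
               K_i = K_i, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# small chain SEM (one d-sep claim) used across the SEM tests
chain_spec <- function() {
  sem_spec(data.frame(node = c("X", "M", "Y"),
                      layer = c("niche", "trait", "phenology")),
           data.frame(from = c("X", "M"), to = c("M", "Y")))
}

chain_coefs <- function(beta = 0.6) {
  data.frame(from = c("X", "M"), to = c("M", "Y"), beta = beta)
}
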