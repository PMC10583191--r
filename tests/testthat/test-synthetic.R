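# Synthetic trajectory generator: determinism, linear-map structure,
# closed-form decline crossings, measurement round-trips.

test_that("identical seeds give byte-identical datasets", {
  cfg <- generation_config(n_species = 3, rng_seed = 42)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("zero path matrices and zero structural noise collapse all species onto the baseline", {
  cfg <- exact_config(n_species = 5, rng_seed = 3)
  tr <- generate_species(cfg)
  expect_equal(tr$a_true, rep(120, 5))
  expect_equal(tr$b_true, rep(0.12, 5))
  expect_equal(tr$K_true, rep(20, 5))
  expect_equal(tr$m_true, rep(260, 5))
  expect_equal(tr$theta_true, rep(1, 5))
})

test_that("a single niche-to-phenology path reproduces the exact linear map", {
  Bp <- matrix(0, 6, 11,
               dimnames = list(c("a", "log_b", "m", "log_s", "log_theta",
                                 "log_K"),
                               c("moisture", "light", "reaction", "nutrients",
                                 "temperature", "dist_frequency",
                                 "dist_severity", "log_height",
                                 "log_lateral_spread", "sla", "ldmc")))
  Bp["m", "light"] <- 0.5
  cfg <- generation_config(n_species = 400, structural_noise = 0,
                           niche_to_traits = matrix(0, 4, 7),
                           to_phenology = Bp, rng_seed = 9)
  tr <- generate_species(cfg)
  # independent re-derivation of the map from the stored niche scores
  m_expected <- 260 + 18 * 0.5 * (tr$light - 5) / 2
  expect_equal(tr$m_true, m_expected, tolerance = 1e-12)
  expect_gt(cor(tr$light, tr$m_true), 0.999)
})

test_that("species truth satisfies its invariants", {
  tr <- generate_species(generation_config(n_species = 50, rng_seed = 8))
  expect_true(all(tr$b_true > 0))
  expect_true(all(tr$s_true > 0))
  expect_true(all(tr$theta_true > 0 & tr$K_true > 0))
  expect_true(all(tr$a_true < tr$m_true))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generation_config(n_species = 0), "configuration error")
  expect_error(generation_config(noise_cv = -0.1), "configuration error")
  expect_error(generation_config(cadence_days = 0), "configuration error")
})

test_that("true trajectory hits the logistic midpoint at the inflection", {
  tr <- make_truth()
  expect_equal(true_size(tr, tr$a_true), tr$K_true / 2, tolerance = 1e-9)
})

test_that("decline crossings match their closed form and a root-finding oracle", {
  tr <- make_truth(m = 250, s = 0.1, theta = 1)
  # symmetric logistic: the 50% crossing is the midpoint m
  expect_equal(true_crossing(tr, 0.5), 250, tolerance = 1e-12)
  t95 <- true_crossing(tr, 0.95)
  t05 <- true_crossing(tr, 0.05)
  expect_equal(t95, 250 + 10 * log(1 / 0.95 - 1), tolerance = 1e-12)
  expect_equal(t95, 220.5556, tolerance = 1e-4)
  expect_equal(t05, 279.4444, tolerance = 1e-4)
  # numeric oracle: root of the decline fraction minus q
  for (q in c(0.95, 0.5, 0.25, 0.05)) {
    root <- uniroot(function(t)
      (1 + exp(tr$s_true * (t - tr$m_true)))^(-tr$theta_true) - q,
      c(100, 400), tol = 1e-10)$root
    expect_equal(true_crossing(tr, q), root, tolerance = 1e-6)
  }
  # asymmetric case stays ordered
  tr3 <- make_truth(theta = 3)
  expect_true(true_crossing(tr3, 0.95) < true_crossing(tr3, 0.5))
  expect_true(true_crossing(tr3, 0.5) < true_crossing(tr3, 0.05))
})

test_that("true trajectories are unimodal", {
  tr <- generate_species(generation_config(n_species = 5, rng_seed = 21))
  for (i in seq_len(nrow(tr))) {
    sizes <- true_size(tr[i, ], seq(5, 360, 1))
    peak <- which.max(sizes)
    expect_true(all(diff(sizes[1:peak]) >= 0))
    expect_true(all(diff(sizes[peak:length(sizes)]) <= 0))
  }
})

test_that("noiseless measurements invert exactly to the true size", {
  cfg <- exact_config(n_species = 2, noise_cv = 0, shoot_k_cv = 0,
                      rng_seed = 4)
  ds <- simulate_dataset(cfg)
  sizes <- compute_size(ds$measurements$upper_width_cm,
                        ds$measurements$lower_width_cm,
                        ds$measurements$length_cm)
  truth_sizes <- unlist(lapply(unique(ds$measurements$shoot_id), function(sh) {
    d <- ds$measurements[ds$measurements$shoot_id == sh, ]
    true_size(ds$truth[ds$truth$species_id == d$species_id[1], ],
              d$day_of_year)
  }))
  expect_equal(sizes, truth_sizes, tolerance = 1e-9)
})

test_that("measurement table has one row per species x shoot x date", {
  cfg <- generation_config(n_species = 3, shoots_per_species = 7,
                           cadence_days = 14, rng_seed = 2)
  ds <- simulate_dataset(cfg)
  expect_identical(nrow(ds$measurements), 3L * 7L * 26L)
})

test_that("recomputed-size CV matches its delta-method prediction", {
  set.seed(77)
  cv <- 0.05
  s0 <- 10
  const <- c(upper = 0.5, lower = 1, length = 3)
  const[c("upper", "lower")] <- const[c("upper", "lower")] *
    sqrt(12 / (pi * 3 * (0.25 + 0.5 + 1)))
  base <- const * s0
  sdlog <- sqrt(log(1 + cv^2))
  n <- 10000
  noisy <- sapply(1:3, function(j)
    base[j] * rlnorm(n, -sdlog^2 / 2, sdlog))
  sizes <- compute_size(noisy[, 1], noisy[, 2], noisy[, 3])
  emp_cv <- sd(sizes) / mean(sizes)
  # delta method: numeric log-log gradient of the size formula
  grad <- sapply(1:3, function(j) {
    h <- 1e-6
    args_hi <- args_lo <- as.list(base)
    args_hi[[j]] <- base[j] * exp(h)
    args_lo[[j]] <- base[j] * exp(-h)
    (log(do.call(compute_size, args_hi)) -
       log(do.call(compute_size, args_lo))) / (2 * h)
  })
  pred_cv <- cv * sqrt(sum(grad^2))
  expect_lt(abs(emp_cv / pred_cv - 1), 0.2)
})
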