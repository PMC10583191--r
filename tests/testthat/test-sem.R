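# Piecewise SEM: specification, basis sets, Fisher's C, local fits and
# refinement.

test_that("invalid specifications are rejected", {
  nodes <- data.frame(node = c("n1", "t1", "p1"),
                      layer = c("niche", "trait", "phenology"))
  expect_error(sem_spec(nodes, data.frame(from = "t1", to = "n1")),
               "later to an earlier layer")
  expect_error(sem_spec(nodes, data.frame(from = "n1", to = "n1")),
               "self-loop")
  expect_error(sem_spec(nodes, correlated_errors = data.frame(a = "n1",
                                                              b = "t1")),
               "same-layer")
  expect_error(sem_spec(nodes, data.frame(from = "n1", to = "t1"),
                        data.frame(a = c("n1"), b = c("n1"))),
               "specification error")
})

test_that("a pair cannot be both an edge and a correlated error", {
  nodes <- data.frame(node = c("p1", "p2"), layer = c("phenology",
                                                      "phenology"))
  expect_error(sem_spec(nodes, data.frame(from = "p1", to = "p2"),
                        data.frame(a = "p1", b = "p2")),
               "both as edge and correlated error")
})

test_that("basis sets follow the textbook cases", {
  # chain X -> M -> Y: single claim (X, Y | M)
  bs <- sem_basis_set(chain_spec())
  expect_identical(nrow(bs), 1L)
  expect_identical(bs$upstream, "X")
  expect_identical(bs$downstream, "Y")
  expect_identical(bs$conditioning, "M")
  # fully connected layered DAG: empty basis set
  nodes <- data.frame(node = c("a", "b", "c"),
                      layer = c("niche", "trait", "phenology"))
  full <- sem_spec(nodes, data.frame(from = c("a", "a", "b"),
                                     to = c("b", "c", "c")))
  expect_identical(nrow(sem_basis_set(full)), 0L)
})

test_that("a correlated error removes exactly its claim from the basis set", {
  nodes <- data.frame(node = c("n1", "p1", "p2"),
                      layer = c("niche", "phenology", "phenology"))
  edges <- data.frame(from = c("n1", "n1"), to = c("p1", "p2"))
  s0 <- sem_spec(nodes, edges)
  s1 <- sem_spec(nodes, edges, data.frame(a = "p1", b = "p2"))
  b0 <- sem_basis_set(s0)
  b1 <- sem_basis_set(s1)
  key0 <- paste(b0$upstream, b0$downstream)
  key1 <- paste(b1$upstream, b1$downstream)
  expect_identical(setdiff(key0, key1), "p1 p2")
  expect_identical(setdiff(key1, key0), character(0))
})

test_that("edges, correlated errors and claims partition all node pairs", {
  spec <- default_sem_spec()
  spec2 <- sem_spec(spec$nodes, spec$edges,
                    data.frame(a = c("sen_date", "sla"),
                               b = c("sen_pace", "ldmc")))
  for (s in list(spec, spec2)) {
    n_pairs <- choose(nrow(s$nodes), 2)
    expect_identical(nrow(s$edges) + nrow(s$correlated_errors) +
                       nrow(sem_basis_set(s)), as.integer(n_pairs))
  }
})

test_that("Fisher's C matches its closed form and boundaries", {
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * 2 * log(0.5), tolerance = 1e-12)
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  expect_identical(fc$df, 4L)
  fc1 <- fishers_c(c(1, 1, 1))
  expect_equal(fc1$C, 0)
  expect_equal(fc1$p_global, 1)
  expect_equal(fishers_c(numeric(0))$p_global, 1)
  expect_error(fishers_c(c(0.5, 0)), "p = 0")
})

test_that("a chain fit recovers standardized paths and the single-parent identity", {
  set.seed(71)
  d <- simulate_sem_data(chain_spec(), chain_coefs(0.6), 1e4)
  fit <- sem_fit_local(chain_spec(), d)
  expect_equal(nrow(fit$paths), 2L)
  expect_true(all(abs(fit$paths$estimate - 0.6) < 0.05))
  # single-parent path equals the simple correlation
  xm <- fit$paths$estimate[fit$paths$from == "X" & fit$paths$to == "M"]
  expect_equal(xm, cor(d$X, d$M), tolerance = 1e-10)
})

test_that("an empty edge set yields no paths and all-exogenous claims", {
  nodes <- data.frame(node = c("u", "v"), layer = c("niche", "niche"))
  spec <- sem_spec(nodes)
  set.seed(2)
  d <- data.frame(u = rnorm(50), v = rnorm(50))
  fit <- sem_fit_local(spec, d)
  expect_identical(nrow(fit$paths), 0L)
  expect_identical(nrow(fit$claims), 1L)
  # with no parents the claim test is the plain correlation test
  expect_equal(fit$claims$p_value, cor.test(d$u, d$v)$p.value,
               tolerance = 1e-10)
})

test_that("path coefficients are invariant to affine rescaling of variables", {
  set.seed(15)
  d <- simulate_sem_data(chain_spec(), chain_coefs(0.5), 300)
  d2 <- d
  d2$M <- 10 * d2$M + 5
  f1 <- sem_fit_local(chain_spec(), d)
  f2 <- sem_fit_local(chain_spec(), d2)
  expect_equal(f1$paths$estimate, f2$paths$estimate, tolerance = 1e-10)
  expect_equal(f1$fisher_C, f2$fisher_C, tolerance = 1e-10)
})

test_that("refinement leaves the spec unchanged when additions are disabled", {
  set.seed(19)
  d <- simulate_sem_data(chain_spec(), chain_coefs(0.6), 300)
  rr <- sem_refine(chain_spec(), d, alpha_add = 0)
  expect_identical(rr$spec$edges, chain_spec()$edges)
  expect_false(any(rr$trail$action %in% c("add_edge",
                                          "add_correlated_error")))
})

test_that("an omitted strong cross-layer path is the first addition", {
  set.seed(23)
  nodes <- data.frame(node = c("X", "M", "Y"),
                      layer = c("niche", "trait", "phenology"))
  full <- sem_spec(nodes, data.frame(from = c("X", "M", "X"),
                                     to = c("M", "Y", "Y")))
  coefs <- data.frame(from = c("X", "M", "X"), to = c("M", "Y", "Y"),
                      beta = c(0.6, 0.6, 0.5))
  d <- simulate_sem_data(full, coefs, 500)
  rr <- sem_refine(chain_spec(), d)
  adds <- rr$trail[rr$trail$action == "add_edge", ]
  expect_gte(nrow(adds), 1L)
  expect_identical(adds$from[1], "X")
  expect_identical(adds$to[1], "Y")
  expect_true(rr$converged)
})

test_that("an omitted same-layer dependence is added as a correlated error", {
  set.seed(29)
  n <- 400
  X <- rnorm(n)
  e <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.6, 0.6, 1), 2))
  d <- data.frame(X = X, P = 0.5 * X + e[, 1], Q = 0.5 * X + e[, 2])
  nodes <- data.frame(node = c("X", "P", "Q"),
                      layer = c("niche", "phenology", "phenology"))
  spec <- sem_spec(nodes, data.frame(from = c("X", "X"), to = c("P", "Q")))
  rr <- sem_refine(spec, d)
  expect_true(any(rr$trail$action == "add_correlated_error"))
  expect_identical(sort(unlist(rr$spec$correlated_errors[1, c("a", "b")],
                               use.names = FALSE)), c("P", "Q"))
})

test_that("refined fits report both whole-model AIC variants", {
  set.seed(37)
  d <- simulate_sem_data(chain_spec(), chain_coefs(0.6), 200)
  fit <- sem_fit_local(chain_spec(), d)
  expect_true(is.finite(fit$aic_sum))
  expect_equal(fit$aic_c,
               fit$fisher_C + 2 * sum(vapply(fit$fits, function(f)
                 attr(logLik(f), "df"), numeric(1))), tolerance = 1e-12)
})
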