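make_2x2 <- function(a, b, c, d) {
  # exposure x outcome cell counts (a = exposed cases)
  data.frame(
    x = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
    y = rep(c(1, 0, 1, 0), times = c(a, b, c, d))
  )
}

test_that("logistic OR on a 2x2 equals the cross-product ratio exactly", {
  d <- make_2x2(20, 80, 10, 90)
  fr <- fit_logistic(cbind(1, asthma = d$x), d$y)
  expect_equal(unname(exp(fr$coefficients["asthma"])), 2.25,
               tolerance = 1e-10)
  # sandwich with singleton clusters equals the HC0 form
  hc0 <- sandwich::vcovHC(fr$fit, type = "HC0")
  expect_equal(unname(fr$vcov_sandwich), unname(hc0), tolerance = 1e-10)
})

test_that("coefficients match an independent likelihood maximizer", {
  set.seed(12)
  n <- 200
  X <- cbind(1, matrix(rnorm(n * 3), ncol = 3,
                       dimnames = list(NULL, c("a", "b", "c"))))
  y <- rbinom(n, 1, plogis(0.2 + X[, 2] - 0.5 * X[, 3]))
  fr <- fit_logistic(X, y)
  ref <- oracle_logistic(X, y)
  expect_lt(max(abs(fr$coefficients - ref)), 1e-6)
  # invariance to row order and cluster relabeling
  perm <- sample(n)
  fr2 <- fit_logistic(X[perm, ], y[perm],
                      clusters = paste0("c", perm %% 10))
  fr3 <- fit_logistic(X, y, clusters = (seq_len(n) %% 10) + 100)
  expect_equal(unname(fr$coefficients), unname(fr2$coefficients),
               tolerance = 1e-8)
  expect_equal(unname(fit_logistic(X, y, clusters = seq_len(n) %% 10)$vcov_sandwich),
               unname(fr3$vcov_sandwich), tolerance = 1e-10)
})

test_that("clustered sandwich equals the hand-computed score sandwich", {
  set.seed(13)
  n <- 120
  cl <- rep(1:30, each = 4)
  X <- cbind(1, x = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 * X[, 2] + 0.4 * rep(rnorm(30), each = 4)))
  fr <- fit_logistic(X, y, clusters = cl)
  mu <- fitted(fr$fit)
  sc <- X * (y - mu)                       # score contributions
  meat <- crossprod(rowsum(sc, cl))        # summed within cluster
  bread <- solve(t(X) %*% (X * (mu * (1 - mu))))
  expect_equal(unname(fr$vcov_sandwich), unname(bread %*% meat %*% bread),
               tolerance = 1e-5)
})

test_that("degenerate designs fail loudly", {
  d <- make_2x2(20, 80, 10, 90)
  X <- cbind(1, x = d$x, x2 = 2 * d$x)
  expect_error(fit_logistic(X, d$y), "rank deficient.*x2")
  expect_error(fit_logistic(cbind(1, d$x), rep(0, nrow(d))), "degenerate")
  # complete separation
  xs <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(cbind(1, x = xs), xs), "separation")
})

test_that("pair datasets are double-entered with validation", {
  pars <- acde_params(A = c(0.5, 0.5), r_A = 0.3)
  sim <- simulate_registry(registry_config(n_nuclear = 40, sibship_size = 3),
                           pars, threshold_spec(c(0.3, 0.3)), seed = 14)
  pd <- build_pair_dataset(sim$registry, sim$pairs, "full_sibling")
  expect_equal(nrow(pd), 2 * nrow(sim$pairs))   # sibship of 3: 6 rows/family
  expect_equal(attr(pd, "n_pairs"), nrow(sim$pairs))
  # single pair gives two rows in the same cluster
  one <- sim$pairs[1, , drop = FALSE]
  pd1 <- build_pair_dataset(sim$registry, one, "full_sibling")
  expect_equal(nrow(pd1), 2)
  expect_equal(length(unique(pd1$cluster)), 1)
  expect_error(build_pair_dataset(sim$registry, one, "nephew"),
               "unknown pair kind")
  # pairs referencing phenotype-free ids are rejected with the ids listed
  reg_broken <- sim$registry
  reg_broken$asd[match(one$id_1, reg_broken$id)] <- NA
  expect_error(build_pair_dataset(reg_broken, one, "full_sibling"),
               as.character(one$id_1))
})

test_that("null architectures give null odds ratios", {
  pars0 <- acde_params(A = c(0.3, 0.3))  # no cross-trait paths at all
  sim <- simulate_registry(registry_config(n_nuclear = 15000),
                           pars0, threshold_spec(c(0.2, 0.1)), seed = 15)
  wi <- within_individual_or(sim$registry)
  expect_true(wi$ci_low <= 1 && 1 <= wi$ci_high)
  co <- coaggregation_or(build_pair_dataset(sim$registry, sim$pairs,
                                            "full_sibling"), "crude")
  expect_true(co$ci_low <= 1 && 1 <= co$ci_high)
  # Wald CI symmetric about log OR
  expect_equal(log(co$ci_high) - log(co$OR), log(co$OR) - log(co$ci_low),
               tolerance = 1e-10)
})

test_that("within-person correlation drives the within-individual OR", {
  pars <- acde_params(A = c(0.2, 0.2), r_E = 0.4)
  sim <- simulate_registry(registry_config(n_nuclear = 40000),
                           pars, threshold_spec(c(0.15, 0.05)), seed = 16)
  wi <- within_individual_or(sim$registry, "adj_covariates")
  expect_gt(wi$ci_low, 1)
})

test_that("excluded individuals are removed before estimation", {
  pars <- acde_params(A = c(0.3, 0.3), r_E = 0.2)
  sim <- simulate_registry(registry_config(n_nuclear = 3000,
                                           exclusion_prob = 0.3),
                           pars, threshold_spec(c(0.2, 0.1)), seed = 17)
  wi <- within_individual_or(sim$registry)
  n_kept <- sum(sim$registry$role == "child" & !sim$registry$excluded)
  expect_equal(wi$n, n_kept)
})

test_that("confounding adjustment moves the estimate toward the truth", {
  thr <- threshold_spec(c(0.2, 0.1))
  pars0 <- acde_params(A = c(0.3, 0.3))    # no true cross-trait effect
  cfg_conf <- registry_config(n_nuclear = 40000,
                              confounding = c(birth_year = 0.45,
                                              parental_age = 0))
  sim <- simulate_registry(cfg_conf, pars0, thr, seed = 18)
  crude <- within_individual_or(sim$registry, "crude")
  adj <- within_individual_or(sim$registry, "adj_covariates")
  # the shared birth-year effect inflates the crude OR; adjustment removes it
  expect_gt(crude$OR, adj$OR)
  expect_true(adj$ci_low <= 1 && 1 <= adj$ci_high)
  expect_gt(crude$ci_low, 1)
})
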