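rand_params <- function(seed, r_scale = 0.5) {
  set.seed(seed)
  frac <- function() {
    w <- rexp(4) * c(1, 0.5, 0.5, 1)
    w <- w / sum(w)
    w[4] <- max(w[4], 0.1)             # keep E well away from zero
    w / sum(w)
  }
  f1 <- frac(); f2 <- frac()
  acde_params(A = c(f1[1], f2[1]), C = c(f1[2], f2[2]),
              D = c(f1[3], f2[3]), E = c(f1[4], f2[4]),
              r_A = runif(1, -r_scale, r_scale),
              r_C = runif(1, -r_scale, r_scale),
              r_D = runif(1, -r_scale, r_scale),
              r_E = runif(1, -r_scale, r_scale))
}

test_that("implied pair covariance reproduces the sharing algebra", {
  ade <- acde_params(A = c(0.67, 0.29), D = c(0.22, 0.43),
                     r_A = 0.31, r_D = -0.13, r_E = 0.03)
  S <- implied_pair_covariance(ade, "MZ_twin")
  # MZ within-trait cross-person correlation is exactly A + D
  expect_equal(S[1, 3], 0.67 + 0.22, tolerance = 1e-12)
  expect_equal(S[2, 4], 0.29 + 0.43, tolerance = 1e-12)
  ace <- acde_params(A = c(0.6, 0.5), C = c(0.2, 0.3), r_A = 0.2, r_C = 0.1)
  Sp <- implied_pair_covariance(ace, "paternal_half_sibling")
  # paternal half-siblings share a quarter of A and none of C
  expect_equal(Sp[1, 3], 0.25 * 0.6, tolerance = 1e-12)
  expect_equal(Sp[2, 4], 0.25 * 0.5, tolerance = 1e-12)
  expect_true(all(diag(S) == 1))
  # member exchangeability of the 4x4 structure
  perm <- c(3, 4, 1, 2)
  expect_equal(S[perm, perm], S, tolerance = 1e-12)
})

test_that("implied covariance agrees with the simulator", {
  pars <- rand_params(31, r_scale = 0.4)
  cfg <- registry_config(n_maternal_half = 60000)
  reg <- draw_liabilities(build_pedigrees(cfg, seed = 32), pars, seed = 33)
  pp <- enumerate_pairs(reg)
  i1 <- match(pp$id_1, reg$id); i2 <- match(pp$id_2, reg$id)
  emp <- cor(cbind(reg$liab_asthma[i1], reg$liab_asd[i1],
                   reg$liab_asthma[i2], reg$liab_asd[i2]))
  S <- implied_pair_covariance(pars, "maternal_half_sibling")
  expect_lt(max(abs(emp - S)), 4 / sqrt(nrow(pp)))
})

test_that("binary pattern probabilities are a distribution matching the
           independent orthant oracle", {
  for (seed in c(34, 35)) {
    pars <- rand_params(seed)
    tau <- c(0.9, 1.6)
    for (kind in c("full_sibling", "MZ_twin", "full_cousin")) {
      tab <- pattern_probs_binary(pars, tau, kind)
      expect_equal(sum(tab$p), 1, tolerance = 1e-6)
      # independent oracle: adaptive 4-d rectangle integration (Genz-Bretz)
      S <- implied_pair_covariance(pars, kind)
      tv <- c(tau[1], tau[2], tau[1], tau[2])
      for (r in c(1, 6, 16)) {
        y <- as.numeric(tab[r, c("y1_1", "y2_1", "y1_2", "y2_2")])
        set.seed(1)  # Genz-Bretz quasi-MC uses the R stream
        ref <- mvtnorm::pmvnorm(
          lower = ifelse(y == 1, tv, -Inf), upper = ifelse(y == 1, Inf, tv),
          corr = S, algorithm = mvtnorm::GenzBretz(abseps = 1e-8,
                                                   maxpts = 1e6))[1]
        expect_lt(abs(tab$p[r] - ref), 1e-6)
      }
    }
  }
  # zero correlations: orthant probability factorizes exactly
  ind <- acde_params(A = c(0.4, 0.3))
  tab <- pattern_probs_binary(ind, c(0.5, 1.0), "paternal_half_sibling")
  # paternal half sibs share 0.25 A, so switch everything off instead
  ind0 <- acde_params(A = c(0, 0))
  tab0 <- pattern_probs_binary(ind0, c(0.5, 1.0), "full_sibling")
  p1 <- pnorm(0.5, lower.tail = FALSE); p2 <- pnorm(1.0, lower.tail = FALSE)
  row <- tab0[tab0$y1_1 == 1 & tab0$y2_1 == 0 & tab0$y1_2 == 1 &
                tab0$y2_2 == 1, ]
  expect_equal(row$p, p1 * (1 - p2) * p1 * p2, tolerance = 1e-10)
})

test_that("pair log-likelihood is invariant to member ordering", {
  pars <- rand_params(36)
  pat <- data.frame(y1_1 = c(1, 0), y2_1 = c(0, 1), y1_2 = c(0, 1),
                    y2_2 = c(1, 1), count = c(3, 5))
  swapped <- data.frame(y1_1 = pat$y1_2, y2_1 = pat$y2_2,
                        y1_2 = pat$y1_1, y2_2 = pat$y2_1, count = pat$count)
  expect_equal(pair_loglik_binary(pars, c(0.8, 1.2), pat, "full_sibling"),
               pair_loglik_binary(pars, c(0.8, 1.2), swapped, "full_sibling"),
               tolerance = 1e-10)
})

test_that("mixed twin likelihood obeys probability laws", {
  pars <- rand_params(37)
  m <- 8; s <- 2.5; tau1 <- 1.0
  d0 <- data.frame(s_1 = 9.1, s_2 = 6.7)
  # summing over the 4 binary patterns recovers the marginal score density
  tot <- 0
  for (y1 in 0:1) for (y2 in 0:1) {
    d <- cbind(d0, y1_1 = y1, y1_2 = y2)
    tot <- tot + exp(pair_loglik_mixed(pars, tau1, m, s, d, "DZ_twin"))
  }
  S <- implied_pair_covariance(pars, "DZ_twin")
  c2 <- S[2, 4]
  z <- (c(9.1, 6.7) - m) / s
  dens <- exp(-log(2 * pi) - 2 * log(s) - 0.5 * log(1 - c2^2) -
                (z[1]^2 - 2 * c2 * z[1] * z[2] + z[2]^2) / (2 * (1 - c2^2)))
  expect_equal(tot, dens, tolerance = 1e-9)
  # independent oracle: conditional orthant via mvtnorm on the 4x4 matrix
  d <- cbind(d0, y1_1 = 1, y1_2 = 0)
  Scc <- S[c(2, 4), c(2, 4)]; Sbc <- S[c(1, 3), c(2, 4)]
  mu <- Sbc %*% solve(Scc, z)
  V <- S[c(1, 3), c(1, 3)] - Sbc %*% solve(Scc, t(Sbc))
  p_ref <- mvtnorm::pmvnorm(lower = c(tau1, -Inf), upper = c(Inf, tau1),
                            mean = as.vector(mu), sigma = V,
                            algorithm = mvtnorm::Miwa(steps = 512))[1]
  expect_equal(exp(pair_loglik_mixed(pars, tau1, m, s, d, "DZ_twin")),
               dens * p_ref, tolerance = 1e-8)
  # no cross paths and no twin sharing: factorizes into marginals
  ind <- acde_params(A = c(0, 0))
  di <- data.frame(s_1 = 0.3, s_2 = -0.8, y1_1 = 1, y1_2 = 0)
  ll <- pair_loglik_mixed(ind, 0.5, 0, 1, di, "MZ_twin")
  ref <- dnorm(0.3, log = TRUE) + dnorm(-0.8, log = TRUE) +
    pnorm(0.5, lower.tail = FALSE, log.p = TRUE) + pnorm(0.5, log.p = TRUE)
  expect_equal(ll, ref, tolerance = 1e-9)
})

test_that("univariate fits recover simulated truths", {
  # binary twin design under AE truth
  pars <- acde_params(A = c(0.6, 0.6))
  thr <- threshold_spec(c(0.2, 0.2))
  sim <- cached_sim("twin20k", function() {
    simulate_registry(registry_config(n_twin = 20000), pars, thr, seed = 38,
                      score_mean = 10, score_sd = 3)
  })
  tw <- prepare_twin_pairs(sim$registry, sim$pairs)
  f <- fit_model(tw, model_spec("AE", "twin_mixed", 1), n_starts = 2)
  A_hat <- f$estimates$estimate[f$estimates$parameter == "A1"]
  expect_lt(abs(A_hat - 0.6), 0.05)
  expect_equal(f$aic, 2 * f$n_free - 2 * f$loglik, tolerance = 1e-9)
  # continuous twin trait: ADE point estimates match the classical
  # moment solutions A = 4 r_DZ - r_MZ, D = 2 r_MZ - 4 r_DZ
  fc <- fit_model(tw, model_spec("ADE", "twin_mixed", 2), n_starts = 2)
  r_of <- function(kind) {
    q <- sim$pairs[sim$pairs$kind == kind, ]
    s1 <- sim$registry$asd_score[match(q$id_1, sim$registry$id)]
    s2 <- sim$registry$asd_score[match(q$id_2, sim$registry$id)]
    cor(c(s1, s2), c(s2, s1))
  }
  r_mz <- r_of("MZ_twin"); r_dz <- r_of("DZ_twin")
  A_m <- 4 * r_dz - r_mz; D_m <- 2 * r_mz - 4 * r_dz
  if (A_m > 0 && D_m > 0) {   # interior case only
    expect_lt(abs(fc$estimates$estimate[fc$estimates$parameter == "A2"] - A_m),
              0.02)
    expect_lt(abs(fc$estimates$estimate[fc$estimates$parameter == "D2"] - D_m),
              0.02)
    # broad-sense H = A + D equals the MZ correlation in moment terms
    expect_lt(abs(fc$estimates$estimate[fc$estimates$parameter == "H2"] -
                    r_mz), 0.02)
  }
})

test_that("permuted pairs destroy the familial signal", {
  pars <- acde_params(A = c(0.6, 0.6))
  sim <- cached_sim("twin20k", function() {
    simulate_registry(registry_config(n_twin = 20000), pars,
                      threshold_spec(c(0.2, 0.2)), seed = 38,
                      score_mean = 10, score_sd = 3)
  })
  tw <- prepare_twin_pairs(sim$registry, sim$pairs)
  set.seed(39)
  tw$y1_2 <- sample(tw$y1_2)   # relatives shuffled across families
  f <- fit_model(tw, model_spec("AE", "twin_mixed", 1), n_starts = 2)
  row <- f$estimates[f$estimates$parameter == "A1", ]
  expect_true(f$boundary || (!is.na(row$se) && row$ci_low <= 0.05))
})

test_that("model selection ranks nested families sensibly", {
  pars <- acde_params(A = c(0.3, 0.3), C = c(0.35, 0.35))  # strong C
  thr <- threshold_spec(c(0.25, 0.25))
  sim <- simulate_registry(registry_config(n_twin = 12000), pars, thr,
                           seed = 40, score_mean = 0, score_sd = 1)
  tw <- prepare_twin_pairs(sim$registry, sim$pairs)
  f_ace <- fit_model(tw, model_spec("ACE", "twin_mixed", 1), n_starts = 2)
  f_ae <- fit_model(tw, model_spec("AE", "twin_mixed", 1), n_starts = 2)
  sel <- select_model(list(f_ace, f_ae))
  expect_equal(sel$best$spec$family, "ACE")
  lrt <- sel$table[sel$table$family == "ACE", ]
  expect_gt(lrt$lrt_stat, 0)
  expect_lt(lrt$lrt_p, 0.01)
  # two AE fits: no nested comparison is attempted
  sel2 <- select_model(list(f_ae, f_ae))
  expect_true(all(is.na(sel2$table$lrt_stat)))
  # identical log-likelihoods across nesting: statistic 0, p = 1
  f_ae2 <- f_ae; f_ae2$spec$family <- "ACE"
  sel3 <- select_model(list(f_ae2, f_ae))
  expect_equal(sel3$table$lrt_stat[sel3$table$family == "ACE"], 0)
  expect_equal(sel3$table$lrt_p[sel3$table$family == "ACE"], 1)
})

test_that("derived broad-sense quantities are internally consistent", {
  pars <- acde_params(A = c(0.67, 0.29), D = c(0.22, 0.43),
                      r_A = 0.31, r_D = -0.13, r_E = 0.03)
  h <- derived_H(pars)
  expect_equal(h$H[1], 0.89)
  # r_H equals the implied within-person cross-trait genetic covariance
  # normalized by sqrt(H1 H2), computed from the covariance construction
  gen_cov <- pars$r_A * sqrt(pars$A[1] * pars$A[2]) +
    pars$r_D * sqrt(pars$D[1] * pars$D[2])
  expect_equal(h$r_H, gen_cov / sqrt(h$H[1] * h$H[2]), tolerance = 1e-12)
  # and the MZ cross-person cross-trait implied entry equals that covariance
  S <- implied_pair_covariance(pars, "MZ_twin")
  expect_equal(S[1, 4], gen_cov, tolerance = 1e-12)
})

test_that("bivariate twin fit recovers broad-sense structure", {
  pars <- acde_params(A = c(0.67, 0.29), D = c(0.22, 0.43),
                      r_A = 0.31, r_D = -0.13, r_E = 0.03)
  thr <- threshold_spec(c(0.15, 0.5))
  sim <- simulate_registry(registry_config(n_twin = 4000), pars, thr,
                           seed = 42, score_mean = 10, score_sd = 3)
  tw <- prepare_twin_pairs(sim$registry, sim$pairs)
  f <- fit_model(tw, model_spec("ADE", "twin_mixed", "both"), n_starts = 2)
  est <- function(p) f$estimates$estimate[f$estimates$parameter == p]
  expect_lt(abs(est("H1") - 0.89), 0.08)
  expect_lt(abs(est("H2") - 0.72), 0.05)
  truth_rH <- derived_H(pars)$r_H
  expect_lt(abs(est("r_H") - truth_rH), 0.1)
  dg <- derived_genetics(f)
  expect_setequal(dg$parameter, c("H1", "H2", "r_H"))
  expect_error(derived_genetics(fit_model(tw, model_spec("ACE", "twin_mixed",
                                                         1), n_starts = 1)),
               "ADE/AE")
})
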