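test_that("degenerate configurations behave predictably", {
  empty <- build_pedigrees(registry_config(), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(enumerate_pairs(empty)), 0)
  # one nuclear family of three children: 3 choose 2 sibling pairs
  reg <- build_pedigrees(registry_config(n_nuclear = 1, sibship_size = 3),
                         seed = 1)
  pp <- enumerate_pairs(reg)
  expect_equal(nrow(pp), 3)
  expect_true(all(pp$kind == "full_sibling"))
  expect_error(registry_config(n_nuclear = -1), "non-negative")
})

test_that("pedigree generation is deterministic given the seed", {
  cfg <- registry_config(n_nuclear = 50, n_maternal_half = 100, n_twin = 30)
  a <- build_pedigrees(cfg, seed = 77)
  b <- build_pedigrees(cfg, seed = 77)
  expect_identical(a, b)
  c <- build_pedigrees(cfg, seed = 78)
  expect_false(identical(a$sex, c$sex))
})

test_that("pedigree structure is internally consistent", {
  cfg <- registry_config(n_nuclear = 200, sibship_size = 3,
                         n_maternal_half = 150, n_paternal_half = 150,
                         n_cousin = 150, n_twin = 200)
  reg <- build_pedigrees(cfg, seed = 3)
  expect_false(any(duplicated(reg$id)))
  ch <- reg[reg$role == "child", ]
  expect_true(all(ch$mother %in% reg$id) && all(ch$father %in% reg$id))
  # MZ pairs share sex and birth year
  pp <- enumerate_pairs(reg)
  mz <- pp[pp$kind == "MZ_twin", ]
  expect_gt(nrow(mz), 0)
  i1 <- match(mz$id_1, reg$id); i2 <- match(mz$id_2, reg$id)
  expect_true(all(reg$sex[i1] == reg$sex[i2]))
  expect_true(all(reg$birth_year[i1] == reg$birth_year[i2]))
  # pair classification matches parent pointers
  for (r in sample(nrow(pp), 50)) {
    a <- reg[match(pp$id_1[r], reg$id), ]
    b <- reg[match(pp$id_2[r], reg$id), ]
    same_m <- a$mother == b$mother
    same_f <- a$father == b$father
    expected <- if (same_m && same_f) {
      if (!is.na(a$zygosity)) paste0(a$zygosity, "_twin") else "full_sibling"
    } else if (same_m) "maternal_half_sibling"
    else if (same_f) "paternal_half_sibling"
    else "full_cousin"
    expect_equal(pp$kind[r], expected)
  }
  # kind-specific pair counts implied by the configuration
  expect_equal(sum(pp$kind == "full_sibling"), 200 * 3)
  expect_equal(sum(pp$kind == "maternal_half_sibling"), 150)
  expect_equal(sum(pp$kind == "full_cousin"), 150)
})

test_that("liability correlations match the closed-form implied values", {
  # one family type per kind, many pairs; empirical pair correlation must
  # sit within 4 Monte-Carlo SEs of k_A A + k_D D + k_C C per trait
  pars <- acde_params(A = c(0.5, 0.6), C = c(0.2, 0.1), D = c(0, 0.1),
                      r_A = 0.3, r_C = 0.1, r_D = 0.2, r_E = -0.1)
  cfg <- registry_config(n_nuclear = 15000, n_maternal_half = 15000,
                         n_paternal_half = 15000, n_cousin = 15000,
                         n_twin = 30000)
  reg <- build_pedigrees(cfg, seed = 10)
  reg <- draw_liabilities(reg, pars, seed = 11)
  pp <- enumerate_pairs(reg)
  kinds <- pair_kinds()
  for (k in kinds$kind) {
    sel <- pp[pp$kind == k, ]
    i1 <- match(sel$id_1, reg$id); i2 <- match(sel$id_2, reg$id)
    kk <- pair_kind(k)
    n <- nrow(sel)
    for (t in 1:2) {
      implied <- kk$k_A * pars$A[t] + kk$k_D * pars$D[t] + kk$k_C * pars$C[t]
      v <- if (t == 1) reg$liab_asthma else reg$liab_asd
      emp <- cor(v[i1], v[i2])
      expect_lt(abs(emp - implied), 4 * (1 - implied^2) / sqrt(n))
    }
    # cross-trait covariance weakens with genetic distance
    implied_ct <- kk$k_A * pars$r_A * sqrt(pars$A[1] * pars$A[2]) +
      kk$k_D * pars$r_D * sqrt(pars$D[1] * pars$D[2]) +
      kk$k_C * pars$r_C * sqrt(pars$C[1] * pars$C[2])
    emp_ct <- (cor(reg$liab_asthma[i1], reg$liab_asd[i2]) +
                 cor(reg$liab_asthma[i2], reg$liab_asd[i1])) / 2
    expect_lt(abs(emp_ct - implied_ct), 4 / sqrt(n))
  }
  # independence architecture: all pair correlations near zero
  pars0 <- acde_params(A = c(0, 0), E = c(1, 1))
  reg0 <- draw_liabilities(build_pedigrees(
    registry_config(n_nuclear = 8000), seed = 1), pars0, seed = 2)
  pp0 <- enumerate_pairs(reg0)
  i1 <- match(pp0$id_1, reg0$id); i2 <- match(pp0$id_2, reg0$id)
  expect_lt(abs(cor(reg0$liab_asthma[i1], reg0$liab_asthma[i2])),
            3 / sqrt(nrow(pp0)))
})

test_that("degenerate covariance structures are rejected loudly", {
  # perfectly correlated unique environments make the MZ joint liability
  # singular; the simulator must refuse rather than silently repair
  bad <- acde_params(A = c(0.5, 0.5), r_E = 1)
  reg <- build_pedigrees(registry_config(n_twin = 5, mz_ratio = 1), seed = 1)
  expect_error(draw_liabilities(reg, bad, seed = 1), "positive definite")
})

test_that("thresholding hits target prevalence and handles extremes", {
  pars <- acde_params(A = c(0.5, 0.5))
  reg <- build_pedigrees(registry_config(n_nuclear = 50000), seed = 4)
  reg <- draw_liabilities(reg, pars, seed = 5)
  reg5 <- apply_thresholds(reg, threshold_spec(c(0.5, 0.5)))
  ch <- reg5[reg5$role == "child", ]
  expect_lt(abs(mean(ch$asthma) - 0.5), 0.01)
  # male-specific target inside the register range
  regs <- apply_thresholds(reg, threshold_spec(rbind(c(0.5, 0.17),
                                                     c(0.5, 0.17))))
  m <- regs[regs$role == "child" & regs$sex == "male", ]
  expect_gt(mean(m$asthma), 0.16)
  expect_lt(mean(m$asthma), 0.18)
  # vanishing prevalence: all-zero column survives the pipeline step
  tiny <- apply_thresholds(reg, threshold_spec(c(1e-9, 0.5)))
  expect_true(all(tiny$asthma[tiny$role == "child"] == 0))
})

test_that("twin trait scores are affine transforms of the liability", {
  cfg <- registry_config(n_twin = 2000)
  pars <- acde_params(A = c(0.5, 0.5))
  reg <- draw_liabilities(build_pedigrees(cfg, seed = 6), pars, seed = 7)
  id <- make_trait_score(reg, mean = 0, sd = 1)
  tw <- !is.na(id$zygosity) & id$role == "child"
  expect_equal(id$asd_score[tw], id$liab_asd[tw])
  sc <- make_trait_score(reg, mean = 5, sd = 3)
  expect_lt(abs(mean(sc$asd_score[tw]) - 5), 3 * 3 / sqrt(sum(tw)) + 0.05)
  expect_lt(abs(sd(sc$asd_score[tw]) - 3), 0.15)
  gr <- make_trait_score(reg, mean = 8, sd = 4, grid = TRUE)
  expect_true(all(gr$asd_score[tw] %in% 0:17))
  expect_error(make_trait_score(reg, sd = -1), "non-negative")
})

test_that("registry and pair tables round-trip through TSV", {
  cfg <- registry_config(n_nuclear = 30, n_twin = 20, exclusion_prob = 0.1)
  pars <- acde_params(A = c(0.4, 0.4))
  sim <- simulate_registry(cfg, pars, threshold_spec(c(0.2, 0.05)), seed = 8)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_registry(sim$registry, f1)
  write_pairs(sim$pairs, f2)
  back <- read_registry(f1)
  expect_equal(back$id, sim$registry$id)
  expect_equal(back$asthma, sim$registry$asthma)
  expect_equal(back$excluded, sim$registry$excluded)
  expect_equal(read_pairs(f2)$kind, sim$pairs$kind)
  expect_error(read_registry(f2), "version")
})

test_that("the confounding knob injects covariate effects on liability", {
  cfg0 <- registry_config(n_nuclear = 20000)
  cfg1 <- registry_config(n_nuclear = 20000,
                          confounding = c(birth_year = 0.4,
                                          parental_age = 0.2))
  pars <- acde_params(A = c(0.5, 0.5))
  r0 <- draw_liabilities(build_pedigrees(cfg0, seed = 9), pars, seed = 10)
  r1 <- draw_liabilities(build_pedigrees(cfg1, seed = 9), pars, seed = 10)
  ch0 <- r0[r0$role == "child", ]; ch1 <- r1[r1$role == "child", ]
  expect_lt(abs(cor(ch0$birth_year, ch0$liab_asthma)), 0.02)
  expect_gt(cor(ch1$birth_year, ch1$liab_asthma), 0.3)
  # total liability variance stays one under confounding
  expect_lt(abs(var(ch1$liab_asthma) - 1), 0.03)
})
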