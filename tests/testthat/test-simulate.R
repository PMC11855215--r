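test_that("genotype simulation is deterministic under a fixed seed", {
  model <- flat_model(m = 8)
  p1 <- simulate_genotypes(model, 500, seed = 42)
  p2 <- simulate_genotypes(model, 500, seed = 42)
  expect_identical(p1$G, p2$G)
  p3 <- simulate_genotypes(model, 500, seed = 43)
  expect_false(identical(p1$G, p3$G))
})

test_that("sample allele frequencies match the model MAF (binomial bound)", {
  model <- flat_model(m = 4, maf = 0.3)
  panel <- simulate_genotypes(model, 50000, seed = 7)
  freq <- colMeans(panel$G) / 2
  bound <- 3 * sqrt(0.3 * 0.7 / (2 * 50000))
  expect_true(all(abs(freq - 0.3) < pmax(bound, 0.01)))
})

test_that("rho = 0 gives independent variants; rho > 0 the designed LD decay", {
  model0 <- flat_model(m = 20, maf = 0.25)
  panel0 <- simulate_genotypes(model0, 5000, seed = 3)
  r2 <- cor(panel0$G)^2
  off <- r2[upper.tri(r2)]
  expect_lt(mean(off), 0.01)

  model_ld <- true_model(maf = rep(0.3, 10), rho = 0.4, block_size = 10)
  panel_ld <- simulate_genotypes(model_ld, 20000, seed = 5)
  r <- cor(panel_ld$G)
  # adjacent correlation ~ rho, lag-2 ~ rho^2 (3 sigma ~ 1/sqrt(n) scale)
  expect_true(all(abs(diag(r[-10, -1]) - 0.4) < 0.03))
  expect_true(all(abs(diag(r[-(9:10), -(1:2)]) - 0.16) < 0.03))
})

test_that("Hardy-Weinberg genotype proportions hold at each variant", {
  model <- flat_model(m = 3, maf = 0.2)
  panel <- simulate_genotypes(model, 50000, seed = 9)
  tab <- table(panel$G[, 2])
  expected <- 50000 * c(0.64, 0.32, 0.04)
  expect_true(all(abs(tab - expected) / expected < 0.05))
})

test_that("phenotype moments match the closed-form model covariances", {
  # non-trivial structure: causal lambda, confounder, direct effects
  model <- flat_model(m = 6, a_std = c(0.2, 0.2, 0, 0, 0, 0),
                      b_std = c(0, 0, 0.25, 0.25, 0, 0),
                      lambda = 0.5, delta_T = 0.4, delta_C = 0.3,
                      theta_H = 0.2, theta_T = 0.3)
  mom <- implied_moments(model)
  panel <- simulate_genotypes(model, 50000, seed = 21)
  ph <- simulate_phenotypes(panel, model, seed = 22)
  expect_lt(abs(var(ph$H) - mom$var_H), 0.03)
  expect_lt(abs(var(ph$T) - mom$var_T), 0.03)
  expect_lt(abs(cor(ph$H, ph$T) - mom$cov_HT / sqrt(mom$var_H * mom$var_T)), 0.02)
})

test_that("with no genetics and lambda = 0 the H-T and C-H correlations vanish", {
  model <- flat_model(m = 4, lambda = 0, delta_T = 0.5, delta_C = 0.5)
  panel <- simulate_genotypes(model, 50000, seed = 31)
  ph <- simulate_phenotypes(panel, model, seed = 32)
  mc_se <- 1 / sqrt(50000)
  expect_lt(abs(cor(ph$H, ph$T)), pmax(3 * mc_se, 0.02))
  expect_lt(abs(cor(ph$C, ph$H)), pmax(3 * mc_se, 0.02))
})

test_that("liability intercept controls the case fraction", {
  model <- flat_model(m = 4, alpha = -2)
  panel <- simulate_genotypes(model, 50000, seed = 41)
  ph <- simulate_phenotypes(panel, model, seed = 42)
  p <- plogis(-2)
  expect_lt(abs(mean(ph$AD) - p), 3 * sqrt(p * (1 - p) / 50000))
})

test_that("per-variant test size under the null is ~5% (200 seeds)", {
  model <- flat_model(m = 5)
  hits <- vapply(1:200, function(s) {
    panel <- simulate_genotypes(model, 400, seed = 5000 + s)
    ph <- simulate_phenotypes(panel, model, seed = 6000 + s)
    scan <- association_scan(panel, ph$C, "continuous", trait_name = "c",
                             variant_ids = "rs1")
    abs(scan$records$beta / scan$records$se) > 1.96
  }, logical(1))
  band <- 2.58 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(hits) - 0.05), band)
})

test_that("the scan recovers a known standardized effect within 3 SEs", {
  model <- flat_model(m = 10, b_std = c(0.05, rep(0, 9)), maf = 0.3)
  panel <- simulate_genotypes(model, 20000, seed = 51)
  ph <- simulate_phenotypes(panel, model, seed = 52)
  scan <- association_scan(panel, ph$T, "continuous", standardize = TRUE,
                           trait_name = "t")
  sdz <- sqrt(2 * 0.3 * 0.7)
  expected <- 0.05 / sdz  # per-allele beta on the unit-variance trait
  expect_lt(abs(scan$records$beta[1] - expected), 3 * scan$records$se[1])
})

test_that("an irrelevant covariate leaves the scan essentially unchanged", {
  model <- flat_model(m = 100)
  panel <- simulate_genotypes(model, 4000, seed = 61)
  ph <- simulate_phenotypes(panel, model, seed = 62)
  irrelevant <- run_seeded(63, rnorm(4000))
  plain <- association_scan(panel, ph$C, "continuous", trait_name = "c")
  adj <- association_scan(panel, ph$C, "continuous", adjustment = "covariate",
                          adjust_on = irrelevant, trait_name = "c")
  expect_lt(mean(abs(adj$records$beta - plain$records$beta)), 0.005)
})

test_that("binary scans equal per-variant logistic ML (glm oracle)", {
  model <- flat_model(m = 6, a_std = c(0.3, rep(0, 5)), phi_H = 0.5, alpha = -1)
  panel <- simulate_genotypes(model, 3000, seed = 71)
  ph <- simulate_phenotypes(panel, model, seed = 72)
  scan <- association_scan(panel, ph$AD, "binary", trait_name = "ad")
  for (j in c(1, 4)) {
    fit <- glm(ph$AD ~ panel$G[, j], family = binomial())
    expect_equal(scan$records$beta[j], unname(coef(fit)[2]), tolerance = 1e-6)
    expect_equal(scan$records$se[j], sqrt(vcov(fit)[2, 2]), tolerance = 1e-6)
  }
  expect_identical(scan$records$n_cases[1], as.integer(sum(ph$AD)))
})

test_that("scan betas are unbiased for the LD-aware marginal effects (full model)", {
  model <- model_confounded()
  mom <- implied_moments(model)
  panel <- simulate_genotypes(model, 20000, seed = 81)
  ph <- simulate_phenotypes(panel, model, seed = 82)
  sdz <- sqrt(2 * model$maf * (1 - model$maf))
  for (trait in c("H", "T")) {
    scan <- association_scan(panel, ph[[trait]], "continuous",
                             standardize = TRUE, trait_name = trait)
    expected <- (if (trait == "H") mom$marg_H else mom$marg_T) /
      sdz / sqrt(if (trait == "H") mom$var_H else mom$var_T)
    z_dev <- (scan$records$beta - expected) / scan$records$se
    # mean standardized deviation over 600 variants ~ N(0, 1/sqrt(600))
    expect_lt(abs(mean(z_dev)), 0.1)
  }
})

test_that("reported SEs are calibrated against the sampling SD of beta-hat", {
  model <- flat_model(m = 3, b_std = c(0.1, 0, 0))
  reps <- t(vapply(1:100, function(s) {
    panel <- simulate_genotypes(model, 1500, seed = 7000 + s)
    ph <- simulate_phenotypes(panel, model, seed = 8000 + s)
    scan <- association_scan(panel, ph$T, "continuous", trait_name = "t",
                             variant_ids = "rs1")
    c(scan$records$beta, scan$records$se)
  }, numeric(2)))
  expect_lt(abs(sd(reps[, 1]) / mean(reps[, 2]) - 1), 0.15)
})

test_that("residual and covariate adjustment agree for exogenous covariates but diverge for heritable ones", {
  # exogenous covariate: the two modes estimate the same partial coefficient
  model <- flat_model(m = 20, b_std = c(rep(0.1, 5), rep(0, 15)))
  panel <- simulate_genotypes(model, 10000, seed = 91)
  ph <- simulate_phenotypes(panel, model, seed = 92)
  exo <- run_seeded(93, rnorm(10000))
  covm <- association_scan(panel, ph$T, "continuous", adjustment = "covariate",
                           adjust_on = exo, trait_name = "t")
  resm <- association_scan(panel, ph$T, "continuous", adjustment = "residual",
                           adjust_on = exo, trait_name = "t")
  expect_lt(mean(abs(covm$records$beta - resm$records$beta)), 0.005)

  # heritable covariate (height): a pure-height variant acquires the
  # collider-induced negative coefficient predicted in closed form
  # variants 1-4 affect height only; 5-8 affect both (the rho_s source)
  model2 <- flat_model(m = 20, maf = 0.3,
                       a_std = c(rep(0.25, 4), rep(0.15, 4), rep(0, 12)),
                       b_std = c(rep(0, 4), rep(0.15, 4), rep(0.1, 12)),
                       lambda = 0.4, delta_T = 0.3)
  mom2 <- implied_moments(model2)
  expect_lt(mom2$marg_T_resid[1], 0)  # over-correction: rho_s > 0
  panel2 <- simulate_genotypes(model2, 15000, seed = 94)
  ph2 <- simulate_phenotypes(panel2, model2, seed = 95)
  resm2 <- association_scan(panel2, ph2$T, "continuous", adjustment = "residual",
                            adjust_on = ph2$H, trait_name = "t")
  sdz <- sqrt(2 * 0.3 * 0.7)
  expected <- mom2$marg_T_resid[1] / sdz
  expect_lt(abs(resm2$records$beta[1] - expected), 3 * resm2$records$se[1])
  # unadjusted beta for the same variant is positive: the sign flips
  plain2 <- association_scan(panel2, ph2$T, "continuous", trait_name = "t")
  expect_gt(plain2$records$beta[1], 0)
  expect_lt(resm2$records$beta[1], 0)
})

test_that("make_study_set is deterministic and honours the overlap plan", {
  model <- flat_model(m = 12, a_std = c(0.3, rep(0, 11)))
  cfg <- sim_config(n_exposure = 600, n_height_extra = 600, n_outcome = 500,
                    n_adjusted = 400, n_ref = 200)
  s1 <- make_study_set(model, cfg, seed = 5)
  s2 <- make_study_set(model, cfg, seed = 5)
  expect_equal(s1$tables, s2$tables)
  expect_identical(s1$panel$G, s2$panel$G)
  # larger height GWAS has smaller SEs
  expect_lt(median(s1$tables$height_15m$records$se),
            median(s1$tables$height_05m$records$se))
  expect_identical(s1$tables$height_15m$records$n[1], 1200L)
  # adjusted scans use the subset sample size
  expect_identical(s1$tables$tlm_residual$records$n[1], 400L)
  expect_error(sim_config(n_exposure = 500, n_adjusted = 600), "overlap plan")
})

test_that("model construction rejects invalid configurations", {
  expect_error(true_model(maf = rep(0.3, 4), a_std = 0.9, rho = 0),
               "genetic variance")
  expect_error(true_model(maf = c(0.1, 0.4), rho = 0.4, block_size = 2),
               "constant within an LD block")
  expect_error(true_model(maf = rep(0.3, 2), alpha = 50, rho = 0),
               "case fraction")
  expect_error(sim_config(n_exposure = 50), "n_exposure")
})
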