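# builds a minimal harmonized data.frame for estimator tests
mk_hd <- function(g, G, se_G, se_g = rep(0.01, length(g)), outcome_type = "continuous") {
  structure(data.frame(variant_id = paste0("rs", seq_along(g)), chrom = "1",
                       pos = seq_along(g) * 1000L, effect_allele = "A",
                       other_allele = "G", eaf_exposure = 0.3,
                       beta_exposure = g, se_exposure = se_g,
                       beta_outcome = G, se_outcome = se_G,
                       action = "kept", stringsAsFactors = FALSE),
            class = c("mr_harmonized", "data.frame"),
            exposure = "x", outcome = "y", outcome_type = outcome_type)
}

mk_hd2 <- function(g1, g2, G, se_G, se1 = rep(0.01, length(g1)),
                   se2 = rep(0.01, length(g1)), outcome_type = "continuous") {
  structure(data.frame(variant_id = paste0("rs", seq_along(g1)), chrom = "1",
                       pos = seq_along(g1) * 1000L, effect_allele = "A",
                       other_allele = "G", eaf_exposure = 0.3,
                       beta_exposure1 = g1, se_exposure1 = se1,
                       beta_exposure2 = g2, se_exposure2 = se2,
                       beta_outcome = G, se_outcome = se_G,
                       action = "kept", stringsAsFactors = FALSE),
            class = c("mr_harmonized", "data.frame"),
            exposures = c("x1", "x2"), outcome = "y",
            outcome_type = outcome_type)
}

test_that("wald_ratio arithmetic and error handling", {
  est <- wald_ratio(0.2, 0.01, 0.1, 0.05)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.25)
  expect_equal(est$ci_lower, 0.5 - qnorm(0.975) * 0.25)
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.05)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "undefined")
})

test_that("second-order Wald SE stays within 10% of first order for strong instruments", {
  first <- wald_ratio(0.2, 0.015, 0.1, 0.05)$se           # se_g/|g| = 0.075
  second <- wald_ratio(0.2, 0.015, 0.1, 0.05, second_order = TRUE)$se
  expect_gt(second, first)
  expect_lt(second / first, 1.1)
  # exact second-order delta formula, evaluated independently
  expect_equal(second, sqrt(0.05^2 / 0.2^2 + 0.1^2 * 0.015^2 / 0.2^4),
               tolerance = 1e-12)
})

test_that("IVW reproduces the weighted normal-equations oracle to 1e-10", {
  g <- c(0.10, 0.20, 0.30); G <- c(0.06, 0.09, 0.16); se <- rep(0.02, 3)
  est <- mr_ivw(mk_hd(g, G, se))
  w <- 1 / se^2
  beta_o <- sum(w * g * G) / sum(w * g^2)
  Q_o <- sum(w * (G - beta_o * g)^2)
  se_o <- max(1, sqrt(Q_o / 2)) / sqrt(sum(w * g^2))
  expect_equal(est$beta, beta_o, tolerance = 1e-10)
  expect_equal(est$se, se_o, tolerance = 1e-10)
  expect_equal(est$Q, Q_o, tolerance = 1e-10)
  # and against lm() as an independent solver for the slope
  fit <- lm(G ~ 0 + g, weights = w)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
})

test_that("IVW exact-fit, J = 1 error, dispersion floor, and sign-flip invariance", {
  g <- c(0.1, 0.2, 0.4)
  est <- mr_ivw(mk_hd(g, 0.5 * g, rep(0.02, 3)))
  expect_equal(est$beta, 0.5)
  expect_equal(est$Q, 0)
  expect_equal(est$sigma, 1)    # under-dispersion floored at 1
  expect_error(mr_ivw(mk_hd(0.1, 0.05, 0.02)), "wald_ratio")

  # joint sign flips of (gamma, Gamma) leave the estimate unchanged
  set.seed(2)
  g <- rnorm(8, 0.2, 0.05); G <- 0.3 * g + rnorm(8, 0, 0.02)
  hd <- mk_hd(g, G, rep(0.02, 8))
  flip <- rep(c(1, -1), 4)
  hd_f <- mk_hd(g * flip, G * flip, rep(0.02, 8))
  expect_equal(mr_ivw(hd_f)$beta, mr_ivw(hd)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(hd_f)$se, mr_ivw(hd)$se, tolerance = 1e-12)
})

test_that("IVW with a duplicated single instrument equals its Wald ratio", {
  est <- mr_ivw(mk_hd(c(0.2, 0.2), c(0.1, 0.1), c(0.05, 0.05)))
  wr <- wald_ratio(0.2, 0.01, 0.1, 0.05)
  expect_equal(est$beta, wr$beta, tolerance = 1e-12)
})

test_that("MR-Egger matches the weighted regression oracle and is orientation invariant", {
  g <- c(0.12, 0.22, 0.31, 0.08, 0.27)
  G <- 0.1 + 0.3 * g + c(0.01, -0.02, 0.005, 0.015, -0.01)
  se <- c(0.02, 0.03, 0.02, 0.04, 0.025)
  est <- mr_egger(mk_hd(g, G, se))
  fit <- lm(G ~ g, weights = 1 / se^2)
  expect_equal(est$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(est$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  # SEs: weighted normal equations with the multiplicative dispersion floor
  w <- 1 / se^2
  Q <- sum(w * resid(fit)^2)
  sigma <- max(1, sqrt(Q / 3))
  det <- sum(w) * sum(w * g^2) - sum(w * g)^2
  expect_equal(est$se, sigma * sqrt(sum(w) / det), tolerance = 1e-10)
  expect_equal(est$intercept_se, sigma * sqrt(sum(w * g^2) / det), tolerance = 1e-10)

  # exact fit
  ex <- mr_egger(mk_hd(g, 0.1 + 0.3 * g, se))
  expect_equal(ex$intercept, 0.1, tolerance = 1e-12)
  expect_equal(ex$beta, 0.3, tolerance = 1e-12)
  expect_equal(ex$Q, 0, tolerance = 1e-20)

  # orienting all exposure associations negative changes nothing
  neg <- mr_egger(mk_hd(-g, -G, se))
  expect_equal(neg$beta, est$beta, tolerance = 1e-12)
  expect_equal(neg$intercept, est$intercept, tolerance = 1e-12)
  expect_error(mr_egger(mk_hd(g[1:2], G[1:2], se[1:2])), "at least 3")
})

test_that("weighted median interpolates the cumulative weights correctly", {
  # symmetric equal weights -> middle ratio
  est <- mr_weighted_median(mk_hd(c(1, 1, 1), c(0.2, 0.5, 0.9), rep(0.1, 3)),
                            n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)

  # identical ratios -> that ratio, with a tight bootstrap SE
  est2 <- mr_weighted_median(mk_hd(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12),
                                   rep(0.002, 3), se_g = rep(1e-4, 3)),
                             n_boot = 200, seed = 1)
  expect_equal(est2$beta, 0.3, tolerance = 1e-10)
  expect_lt(est2$se, 0.05)

  # hand-stepped interpolation oracle with unequal weights:
  # ratios .1/.2/.3/.4, weights 1/7,4/7,1/7,1/7 -> midpoints 1/14, 3/7, 11/14;
  # 0.5 sits between ratio 2 and 3: 0.2 + (0.5 - 3/7)/(11/14 - 3/7) * 0.1 = 0.22
  est3 <- mr_weighted_median(mk_hd(rep(1, 4), c(0.1, 0.2, 0.3, 0.4),
                                   c(0.1, 0.05, 0.1, 0.1)),
                             n_boot = 200, seed = 1)
  expect_equal(est3$beta, 0.22, tolerance = 1e-12)
  expect_error(mr_weighted_median(mk_hd(c(1, 1), c(0.1, 0.2), c(0.1, 0.1))),
               "at least 3")
})

test_that("weighted median bootstrap SE is reproducible under a seed", {
  hd <- mk_hd(c(0.1, 0.2, 0.3, 0.15), c(0.03, 0.05, 0.1, 0.05),
              rep(0.02, 4), se_g = rep(0.01, 4))
  e1 <- mr_weighted_median(hd, n_boot = 300, seed = 9)
  e2 <- mr_weighted_median(hd, n_boot = 300, seed = 9)
  expect_identical(e1$se, e2$se)
})

test_that("MVMR matches the matrix-algebra oracle, detects collinearity, exact fit", {
  set.seed(3)
  g1 <- rnorm(8, 0.2, 0.08); g2 <- rnorm(8, 0.15, 0.1)
  G <- 0.25 * g1 - 0.1 * g2 + rnorm(8, 0, 0.01)
  se <- runif(8, 0.015, 0.04)
  est <- mvmr_regression(mk_hd2(g1, g2, G, se))
  # independent oracle: weighted normal equations via solve()
  X <- cbind(g1, g2); W <- diag(1 / se^2)
  beta_o <- solve(t(X) %*% W %*% X, t(X) %*% W %*% G)[, 1]
  Q_o <- sum((G - X %*% beta_o)^2 / se^2)
  sigma_o <- max(1, sqrt(Q_o / 6))
  se_o <- sigma_o * sqrt(diag(solve(t(X) %*% W %*% X)))
  expect_equal(unname(est$beta), unname(beta_o), tolerance = 1e-10)
  expect_equal(unname(est$se), unname(se_o), tolerance = 1e-10)
  expect_equal(est$Q, Q_o, tolerance = 1e-10)

  ex <- mvmr_regression(mk_hd2(g1, g2, 0.3 * g1, se))
  expect_equal(unname(ex$beta), c(0.3, 0), tolerance = 1e-10)
  expect_equal(ex$Q, 0, tolerance = 1e-16)

  expect_error(mvmr_regression(mk_hd2(g1, 2 * g1, G, se)), "collinearity")
  expect_error(mvmr_regression(mk_hd2(g1[1:2], g2[1:2], G[1:2], se[1:2])),
               "at least K")
})

test_that("conditional F: collinear exposures drive it to ~0, orthogonal ones to the mean marginal F", {
  g1 <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  hd_col <- mk_hd2(g1, 3 * g1, 0.2 * g1, rep(0.02, 5))
  expect_lt(max(conditional_f(hd_col)), 1e-16)

  # orthogonal association vectors: each variant instruments one exposure
  se1 <- rep(0.02, 8)
  g1 <- c(0.2, 0.2, 0.2, 0.2, 0, 0, 0, 0)
  g2 <- c(0, 0, 0, 0, 0.2, 0.2, 0.2, 0.2)
  hd <- mk_hd2(g1, g2, rep(0.05, 8), rep(0.02, 8), se1 = se1, se2 = se1)
  cf <- conditional_f(hd)
  marginal_F <- colMeans(cbind(g1^2 / se1^2, g2^2 / se1^2))
  expect_lt(abs(cf[1] / marginal_F[1] - 1), 0.2)
  expect_lt(abs(cf[2] / marginal_F[2] - 1), 0.2)
})

test_that("odds-scale conversion matches closed forms and symmetry", {
  est <- mr_ivw(mk_hd(c(0.2, 0.2), c(0, 0), c(0.05, 0.05), outcome_type = "binary"))
  est$beta <- 0; est$se <- 0.1
  est$ci_lower <- -qnorm(0.975) * 0.1; est$ci_upper <- qnorm(0.975) * 0.1
  or <- to_odds_scale(est)
  expect_equal(or$or, 1)
  expect_equal(or$or_ci_lower, exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(or$or_ci_upper, exp(qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(round(or$or_ci_lower, 3), 0.822)
  expect_equal(round(or$or_ci_upper, 3), 1.217)

  est$beta <- -0.21; est$se <- 0.06
  est$ci_lower <- est$beta - qnorm(0.975) * 0.06
  est$ci_upper <- est$beta + qnorm(0.975) * 0.06
  or <- to_odds_scale(est)
  expect_equal(round(or$or, 2), 0.81)
  expect_equal(round(or$or_ci_lower, 2), 0.72)
  expect_equal(round(or$or_ci_upper, 2), 0.91)

  # negation gives the reciprocal OR
  est_neg <- est
  est_neg$beta <- -est$beta
  est_neg$ci_lower <- -est$ci_upper; est_neg$ci_upper <- -est$ci_lower
  or_neg <- to_odds_scale(est_neg)
  expect_equal(or_neg$or, 1 / or$or, tolerance = 1e-12)

  cont <- mr_ivw(mk_hd(c(0.2, 0.2), c(0.1, 0.1), c(0.05, 0.05)))
  expect_error(to_odds_scale(cont), "binary")
})

test_that("estimate invariants: CI construction and p-values", {
  set.seed(4)
  g <- rnorm(6, 0.2, 0.05); G <- 0.2 * g + rnorm(6, 0, 0.03)
  for (est in list(mr_ivw(mk_hd(g, G, rep(0.03, 6))),
                   mr_egger(mk_hd(g, G, rep(0.03, 6))))) {
    expect_equal(est$ci_lower, est$beta - qnorm(0.975) * est$se)
    expect_equal(est$ci_upper, est$beta + qnorm(0.975) * est$se)
    expect_equal(est$pval, 2 * pnorm(-abs(est$beta / est$se)))
  }
})
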