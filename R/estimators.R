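# Summary-data MR estimators. Notation: per variant j, gamma_j (beta_exposure)
# is the instrument-exposure association and Gamma_j (beta_outcome) the
# instrument-outcome association, with standard errors se_gamma, se_Gamma.
# All regressions are inverse-variance weighted by 1/se_Gamma^2, with a
# multiplicative random-effects dispersion sigma = max(1, sqrt(Q/df))
# (under-dispersion floored at 1), the standard behaviour of the
# "random-effects IVW" family.

CI_Z <- qnorm(0.975)

new_mr_estimate <- function(method, exposure, outcome, outcome_type,
                            beta, se, n_snps, Q = NA_real_, Q_df = NA_real_,
                            sigma = NA_real_, intercept = NULL) {
  est <- list(method = method, exposure = exposure, outcome = outcome,
              outcome_type = outcome_type, beta = beta, se = se,
              ci_lower = beta - CI_Z * se, ci_upper = beta + CI_Z * se,
              pval = 2 * pnorm(-abs(beta / se)), n_snps = n_snps,
              Q = Q, Q_df = Q_df, sigma = sigma)
  if (!is.null(intercept)) est <- c(est, intercept)
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: %s -> %s (%d SNPs)\n", x$method, x$exposure, x$outcome, x$n_snps))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_lower, x$ci_upper, x$pval))
  if (!is.null(x$or)) {
    cat(sprintf("  OR = %.3f, 95%% CI [%.3f, %.3f]\n", x$or, x$or_ci_lower, x$or_ci_upper))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  if (is.finite(x$Q)) cat(sprintf("  Q = %.2f on %d df (sigma = %.2f)\n",
                                  x$Q, x$Q_df, x$sigma))
  invisible(x)
}

hdat_meta <- function(data) {
  expo <- attr(data, "exposure")
  if (is.null(expo)) expo <- paste(attr(data, "exposures"), collapse = "+")
  list(exposure = expo,
       outcome = attr(data, "outcome") %||% "outcome",
       outcome_type = attr(data, "outcome_type") %||% "continuous")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald ratio estimate from a single instrument
#'
#' beta = Gamma / gamma with, by default, the first-order delta-method
#' standard error se(Gamma)/|gamma|; the second-order form adds the
#' contribution of the instrument-exposure uncertainty.
#'
#' @param gamma,se_gamma instrument-exposure association and SE.
#' @param Gamma,se_Gamma instrument-outcome association and SE.
#' @param second_order use the second-order delta SE.
#' @param exposure,outcome,outcome_type metadata labels.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma, second_order = FALSE,
                       exposure = "exposure", outcome = "outcome",
                       outcome_type = "continuous") {
  if (gamma == 0) stop("undefined Wald ratio: instrument-exposure association is zero",
                       call. = FALSE)
  beta <- Gamma / gamma
  se <- if (second_order) {
    sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  } else {
    se_Gamma / abs(gamma)
  }
  new_mr_estimate("wald_ratio", exposure, outcome, outcome_type, beta, se,
                  n_snps = 1L)
}

#' Random-effects inverse-variance weighted estimator
#'
#' Weighted regression of the outcome associations on the exposure
#' associations through the origin, weights 1/se(Gamma)^2. Heterogeneity is
#' summarized by Cochran's Q on J - 1 df and absorbed multiplicatively:
#' se(beta) = sigma / sqrt(sum w gamma^2) with sigma = max(1, sqrt(Q/df)).
#'
#' @param data an `mr_harmonized` data.frame (univariable).
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(data) {
  J <- nrow(data)
  if (J < 2) stop("IVW needs at least 2 variants; use wald_ratio() for a single instrument",
                  call. = FALSE)
  g <- data$beta_exposure; G <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  swg2 <- sum(w * g^2)
  beta <- sum(w * g * G) / swg2
  Q <- sum(w * (G - beta * g)^2)
  df <- J - 1
  sigma <- max(1, sqrt(Q / df))
  se <- sigma / sqrt(swg2)
  meta <- hdat_meta(data)
  new_mr_estimate("ivw", meta$exposure, meta$outcome, meta$outcome_type,
                  beta, se, n_snps = J, Q = Q, Q_df = df, sigma = sigma)
}

#' MR-Egger regression
#'
#' Variants are oriented so every instrument-exposure association is
#' positive, then the outcome associations are regressed on the exposure
#' associations with a free intercept (weights 1/se(Gamma)^2). The slope
#' estimates the causal effect under the InSIDE assumption; the intercept
#' estimates average directional pleiotropy. Both SEs carry the
#' multiplicative dispersion floor.
#'
#' @param data an `mr_harmonized` data.frame (univariable).
#' @return An `mr_estimate` with intercept fields.
#' @export
mr_egger <- function(data) {
  J <- nrow(data)
  if (J < 3) stop("MR-Egger needs at least 3 variants", call. = FALSE)
  flip <- sign(data$beta_exposure)
  flip[flip == 0] <- 1
  g <- data$beta_exposure * flip
  G <- data$beta_outcome * flip
  w <- 1 / data$se_outcome^2
  sw <- sum(w); swg <- sum(w * g); swg2 <- sum(w * g^2)
  swG <- sum(w * G); swgG <- sum(w * g * G)
  det <- sw * swg2 - swg^2
  slope <- (sw * swgG - swg * swG) / det
  inter <- (swg2 * swG - swg * swgG) / det
  Q <- sum(w * (G - inter - slope * g)^2)
  df <- J - 2
  sigma <- max(1, sqrt(Q / df))
  se_slope <- sigma * sqrt(sw / det)
  se_inter <- sigma * sqrt(swg2 / det)
  meta <- hdat_meta(data)
  new_mr_estimate("mr_egger", meta$exposure, meta$outcome, meta$outcome_type,
                  slope, se_slope, n_snps = J, Q = Q, Q_df = df, sigma = sigma,
                  intercept = list(intercept = inter, intercept_se = se_inter,
                                   intercept_pval = 2 * pnorm(-abs(inter / se_inter))))
}

#' Weighted median estimator
#'
#' Orders the per-variant Wald ratios and takes the weight-interpolated
#' median, with weights proportional to the inverse variance of each ratio
#' (first-order delta method). The SE is the standard deviation of the
#' estimator over parametric-bootstrap replicates of the summary data.
#'
#' @param data an `mr_harmonized` data.frame (univariable).
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1) {
  J <- nrow(data)
  if (J < 3) stop("weighted median needs at least 3 variants", call. = FALSE)
  stopifnot(n_boot >= 100)
  point <- weighted_median_point(data$beta_exposure, data$beta_outcome,
                                 data$se_outcome)
  boot <- run_seeded(seed, {
    g_star <- matrix(rnorm(J * n_boot, data$beta_exposure, data$se_exposure), J)
    G_star <- matrix(rnorm(J * n_boot, data$beta_outcome, data$se_outcome), J)
    vapply(seq_len(n_boot), function(k) {
      weighted_median_point(g_star[, k], G_star[, k], data$se_outcome)
    }, numeric(1))
  })
  se <- sd(boot)
  meta <- hdat_meta(data)
  new_mr_estimate("weighted_median", meta$exposure, meta$outcome,
                  meta$outcome_type, point, se, n_snps = J)
}

# weight-interpolated median of ratio estimates; weights are inverse
# first-order variances of the ratios, normalized to sum to 1
weighted_median_point <- function(g, G, se_G) {
  ratio <- G / g
  w <- 1 / (se_G / abs(g))^2
  w <- w / sum(w)
  ord <- order(ratio)
  ratio <- ratio[ord]; w <- w[ord]
  S <- cumsum(w)
  p <- S - w / 2
  if (p[1] >= 0.5) return(ratio[1])
  if (p[length(p)] <= 0.5) return(ratio[length(p)])
  stats::approx(p, ratio, xout = 0.5, ties = "ordered")$y
}

#' Regression-based multivariable MR
#'
#' Weighted multiple regression of the outcome associations on both
#' exposures' associations with no intercept (weights 1/se(Gamma)^2),
#' estimating each exposure's direct effect. Residual heterogeneity uses
#' Q on J - K df with the same multiplicative dispersion floor as IVW.
#' Conditional F-statistics (see [conditional_f()]) are attached per
#' exposure.
#'
#' @param data an `mr_harmonized` data.frame from
#'   [harmonize_multivariable()].
#' @return An object of class `mvmr_estimate` with per-exposure estimates
#'   and conditional F-statistics.
#' @export
mvmr_regression <- function(data) {
  X <- cbind(data$beta_exposure1, data$beta_exposure2)
  K <- ncol(X); J <- nrow(X)
  if (J < K + 1) stop("MVMR needs at least K + 1 variants", call. = FALSE)
  G <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  XtWX <- crossprod(X * sqrt(w))
  qrd <- qr(XtWX)
  if (qrd$rank < K) {
    stop("collinearity error: the exposures' genetic associations are linearly dependent; multivariable estimation cannot separate their direct effects",
         call. = FALSE)
  }
  XtWG <- crossprod(X, w * G)
  beta <- solve(XtWX, XtWG)[, 1]
  resid <- G - X %*% beta
  Q <- sum(w * resid^2)
  df <- J - K
  sigma <- max(1, sqrt(Q / df))
  se <- sigma * sqrt(diag(solve(XtWX)))
  cf <- conditional_f(data)
  meta <- hdat_meta(data)
  exposures <- attr(data, "exposures") %||% c("exposure1", "exposure2")
  structure(list(method = "mvmr", exposures = exposures, outcome = meta$outcome,
                 outcome_type = meta$outcome_type,
                 beta = setNames(beta, exposures), se = setNames(se, exposures),
                 ci_lower = setNames(beta - CI_Z * se, exposures),
                 ci_upper = setNames(beta + CI_Z * se, exposures),
                 pval = setNames(2 * pnorm(-abs(beta / se)), exposures),
                 n_snps = J, Q = Q, Q_df = df, sigma = sigma,
                 conditional_F = setNames(cf, exposures),
                 f_formula = "Q_k / (J - K + 1), summary-data construction ignoring cross-exposure sampling covariance"),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("MVMR: %s -> %s (%d SNPs)\n", paste(x$exposures, collapse = " + "),
              x$outcome, x$n_snps))
  for (k in seq_along(x$exposures)) {
    flag <- if (x$conditional_F[k] < 10) "  [conditional F < 10: potential weak-instrument bias]" else ""
    cat(sprintf("  %-12s beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, cond. F = %.1f%s\n",
                x$exposures[k], x$beta[k], x$se[k], x$ci_lower[k], x$ci_upper[k],
                x$pval[k], x$conditional_F[k], flag))
  }
  cat(sprintf("  residual Q = %.2f on %d df\n", x$Q, x$Q_df))
  invisible(x)
}

#' Conditional F-statistics for multivariable MR instrument strength
#'
#' For each exposure k, the other exposures' associations are regressed out
#' of gamma_k (weighted by 1/se(gamma_k)^2, no intercept); the weighted
#' residual sum of squares Q_k, scaled by J - K + 1, measures the
#' instrument signal in exposure k conditional on the others. Values below
#' 10 conventionally flag weak-instrument bias. This summary-data
#' construction ignores cross-exposure sampling covariance, which is
#' reported in the output metadata of [mvmr_regression()].
#'
#' @param data an `mr_harmonized` data.frame with two exposures.
#' @return Numeric vector of per-exposure conditional F-statistics.
#' @export
conditional_f <- function(data) {
  X <- cbind(data$beta_exposure1, data$beta_exposure2)
  SE <- cbind(data$se_exposure1, data$se_exposure2)
  K <- ncol(X); J <- nrow(X)
  if (J < K + 1) stop("conditional F needs at least K + 1 variants", call. = FALSE)
  vapply(seq_len(K), function(k) {
    y <- X[, k]
    Z <- X[, -k, drop = FALSE]
    w <- 1 / SE[, k]^2
    ZtWZ <- crossprod(Z * sqrt(w))
    coefs <- tryCatch(solve(ZtWZ, crossprod(Z, w * y)),
                      error = function(e) matrix(0, ncol(Z), 1))
    resid <- y - Z %*% coefs
    Qk <- sum(w * resid^2)
    Qk / (J - K + 1)
  }, numeric(1))
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' OR = exp(beta) with CI exp(beta +/- 1.96 se); p-values are unchanged.
#' Only valid for binary-outcome estimates (log-odds betas).
#'
#' @param est an `mr_estimate` or `mvmr_estimate` from a binary outcome.
#' @return The estimate with `or`, `or_ci_lower`, `or_ci_upper` fields added.
#' @export
to_odds_scale <- function(est) {
  stopifnot(inherits(est, c("mr_estimate", "mvmr_estimate")))
  if (!identical(est$outcome_type, "binary")) {
    stop("odds-scale conversion requires a binary outcome (log-odds betas)",
         call. = FALSE)
  }
  est$or <- exp(est$beta)
  est$or_ci_lower <- exp(est$ci_lower)
  est$or_ci_upper <- exp(est$ci_upper)
  est
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, exposure = x$exposure, outcome = x$outcome,
             n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper, pval = x$pval,
             or = x$or %||% NA_real_, or_ci_lower = x$or_ci_lower %||% NA_real_,
             or_ci_upper = x$or_ci_upper %||% NA_real_,
             intercept = x$intercept %||% NA_real_,
             intercept_se = x$intercept_se %||% NA_real_,
             intercept_pval = x$intercept_pval %||% NA_real_,
             Q = x$Q, Q_df = x$Q_df,
             conditional_F = NA_real_,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.mvmr_estimate <- function(x, ...) {
  data.frame(method = "mvmr", exposure = x$exposures, outcome = x$outcome,
             n_snps = x$n_snps, beta = unname(x$beta), se = unname(x$se),
             ci_lower = unname(x$ci_lower), ci_upper = unname(x$ci_upper),
             pval = unname(x$pval),
             or = if (is.null(x$or)) NA_real_ else unname(x$or),
             or_ci_lower = if (is.null(x$or_ci_lower)) NA_real_ else unname(x$or_ci_lower),
             or_ci_upper = if (is.null(x$or_ci_upper)) NA_real_ else unname(x$or_ci_upper),
             intercept = NA_real_, intercept_se = NA_real_, intercept_pval = NA_real_,
             Q = x$Q, Q_df = x$Q_df,
             conditional_F = unname(x$conditional_F),
             stringsAsFactors = FALSE)
}
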