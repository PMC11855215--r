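# Synthetic GWAS generator.
#
# Generative structure (per sample, genotypes X_j in {0,1,2}, Z_j the
# standardized dosage):
#   H  = sum_j a_j Z_j + e_H                        (height)
#   U  ~ N(0,1)                                     (non-genetic confounder)
#   T  = lambda * H + sum_j b_j Z_j + delta_T U + e_T   (total lean mass)
#   C  = theta_H H + theta_T T + sum_j c_j Z_j + delta_C U + e_C  (cognition)
#   AD ~ Bernoulli(plogis(alpha + phi_H H + phi_T T + sum_j d_j Z_j + delta_AD U))
# with all noise independent. c_j / d_j are optional direct (pleiotropic)
# variant effects on the outcomes, zero by default.

run_seeded <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

ALLELE_PAIRS <- list(c("A", "G"), c("C", "T"), c("T", "C"), c("G", "A"),
                     c("A", "C"), c("A", "T"), c("G", "T"), c("C", "G"))

# deterministic variant metadata: blocks laid out >= 30 Mb apart on a chromosome
# (outside any +/-10 Mb clumping window), variants 5 kb apart within a block
make_variant_metadata <- function(m, block_size) {
  block <- (seq_len(m) - 1L) %/% block_size
  within <- (seq_len(m) - 1L) %% block_size
  chrom <- as.character((block %% 20L) + 1L)
  pos <- 1000000L + (block %/% 20L) * 30000000L + within * 5000L
  pair <- ALLELE_PAIRS[(seq_len(m) - 1L) %% length(ALLELE_PAIRS) + 1L]
  data.frame(variant_id = paste0("rs", seq_len(m)),
             chrom = chrom, pos = pos,
             effect_allele = vapply(pair, `[`, "", 1L),
             other_allele = vapply(pair, `[`, "", 2L),
             block = block,
             stringsAsFactors = FALSE)
}

# Exact correlation matrix of dosages under the haplotype-copy mosaic with
# block-constant allele frequencies: corr(X_j, X_k) = rho^|k-j| within a
# block, blocks independent.
dosage_cor_matrix <- function(maf, block, rho) {
  m <- length(maf)
  R <- diag(m)
  if (rho > 0) {
    for (j in seq_len(m - 1)) {
      for (k in (j + 1):m) {
        if (block[k] != block[j]) break
        R[j, k] <- R[k, j] <- rho^(k - j)
      }
    }
  }
  R
}

#' Specify the generative causal model for the synthetic GWAS study
#'
#' Effect sizes are supplied on the standardized-genotype scale (trait SD per
#' SD of dosage) and converted internally to per-allele effects. Residual SDs
#' left `NULL` are solved so that H, T and C each have unit variance; an error
#' is raised if the requested effects already exceed unit variance.
#'
#' @param maf per-variant minor (effect) allele frequencies, in (0, 0.5].
#' @param a_std per-variant standardized effects on height.
#' @param b_std per-variant standardized direct effects on lean mass.
#' @param lambda causal effect of height on lean mass (SD/SD).
#' @param delta_T,delta_C,delta_AD loadings of the shared non-genetic
#'   confounder on lean mass, cognition, and AD liability.
#' @param theta_H,theta_T direct effects of height and lean mass on the
#'   continuous cognition outcome.
#' @param phi_H,phi_T direct log-odds effects of height and lean mass on AD
#'   liability.
#' @param alpha liability intercept (controls the case fraction).
#' @param sigma_H,sigma_T,sigma_C residual SDs; `NULL` to normalize the trait
#'   variance to 1.
#' @param pleio_C_std,pleio_AD_std optional per-variant direct (pleiotropic)
#'   standardized effects on cognition / AD liability.
#' @param block_size,rho LD block size and within-block adjacent-variant
#'   dosage correlation of the haplotype-copy mosaic.
#' @param variants optional variant metadata data.frame (defaults generated).
#'
#' @return An object of class `true_model`.
#' @export
true_model <- function(maf, a_std = 0, b_std = 0, lambda = 0,
                       delta_T = 0, delta_C = 0, delta_AD = 0,
                       theta_H = 0, theta_T = 0, phi_H = 0, phi_T = 0,
                       alpha = 0, sigma_H = NULL, sigma_T = NULL, sigma_C = NULL,
                       pleio_C_std = 0, pleio_AD_std = 0,
                       block_size = 10, rho = 0.4, variants = NULL) {
  m <- length(maf)
  stopifnot(m >= 1, all(maf > 0 & maf < 1), rho >= 0, rho < 1, block_size >= 1)
  if (is.null(variants) && rho > 0) {
    blk <- (seq_len(m) - 1L) %/% block_size
    if (any(tapply(maf, blk, function(x) diff(range(x))) > 0)) {
      stop("with rho > 0, allele frequencies must be constant within an LD block (the mosaic copies alleles between adjacent variants)",
           call. = FALSE)
    }
  }
  expand <- function(x) if (length(x) == 1) rep(x, m) else {
    stopifnot(length(x) == m); x
  }
  a_std <- expand(a_std); b_std <- expand(b_std)
  pleio_C_std <- expand(pleio_C_std); pleio_AD_std <- expand(pleio_AD_std)
  if (is.null(variants)) variants <- make_variant_metadata(m, block_size)
  stopifnot(nrow(variants) == m)
  if (!"block" %in% names(variants)) variants$block <- seq_len(m) - 1L
  model <- structure(list(m = m, maf = maf, a_std = a_std, b_std = b_std,
                          lambda = lambda, delta_T = delta_T, delta_C = delta_C,
                          delta_AD = delta_AD, theta_H = theta_H, theta_T = theta_T,
                          phi_H = phi_H, phi_T = phi_T, alpha = alpha,
                          sigma_H = sigma_H, sigma_T = sigma_T, sigma_C = sigma_C,
                          pleio_C_std = pleio_C_std, pleio_AD_std = pleio_AD_std,
                          block_size = block_size, rho = rho, variants = variants),
                     class = "true_model")
  mom <- implied_moments(model, partial = TRUE)
  if (is.null(sigma_H)) {
    if (mom$V_gH >= 1) stop("genetic variance of H exceeds 1; supply sigma_H", call. = FALSE)
    model$sigma_H <- sqrt(1 - mom$V_gH)
  }
  mom <- implied_moments(model, partial = TRUE)
  if (is.null(sigma_T)) {
    vt <- mom$var_T_nores
    if (vt >= 1) stop("non-residual variance of T exceeds 1; supply sigma_T", call. = FALSE)
    model$sigma_T <- sqrt(1 - vt)
  }
  mom <- implied_moments(model, partial = TRUE)
  if (is.null(sigma_C)) {
    vc <- mom$var_C_nores
    if (vc >= 1) stop("non-residual variance of C exceeds 1; supply sigma_C", call. = FALSE)
    model$sigma_C <- sqrt(1 - vc)
  }
  fr <- case_fraction(model)
  if (fr <= 0 || fr >= 1) stop("implied case fraction outside (0,1)", call. = FALSE)
  model
}

# approximate implied case fraction (logistic-normal integral via quadrature)
case_fraction <- function(model) {
  mom <- implied_moments(model)
  v <- model$phi_H^2 * mom$var_H + model$phi_T^2 * mom$var_T +
    2 * model$phi_H * model$phi_T * mom$cov_HT + model$delta_AD^2 +
    sum((model$pleio_AD_std %*% mom$R) * model$pleio_AD_std)
  gh <- seq(-6, 6, length.out = 201)
  w <- stats::dnorm(gh); w <- w / sum(w)
  sum(w * plogis(model$alpha + gh * sqrt(v)))
}

#' Closed-form moments implied by a `true_model`
#'
#' Returns the exact population variances, covariances, and per-variant
#' marginal (LD-aware) standardized association effects implied by the
#' generative model. Used throughout the test suite as the analytic oracle for
#' parameter-recovery checks.
#'
#' @param model a [true_model()].
#' @param partial internal; skip quantities needing residual SDs.
#' @return A list with (among others) `var_H`, `var_T`, `cov_HT`, `rho_s`
#'   (genetic covariance between the height score and the direct lean-mass
#'   score), `lambda_pop` (population regression of T on H), and marginal
#'   standardized effect vectors `marg_H`, `marg_T`, `marg_C`, `marg_T_resid`,
#'   `marg_T_covadj`, `marg_AD_liability`.
#' @export
implied_moments <- function(model, partial = FALSE) {
  R <- dosage_cor_matrix(model$maf, model$variants$block, model$rho)
  a <- model$a_std; b <- model$b_std
  Ra <- as.vector(R %*% a); Rb <- as.vector(R %*% b)
  V_gH <- sum(a * Ra); V_gT <- sum(b * Rb); rho_s <- sum(a * Rb)
  out <- list(R = R, V_gH = V_gH, V_gT = V_gT, rho_s = rho_s)
  out$var_T_nores <- NA_real_
  if (!is.null(model$sigma_H)) {
    var_H <- V_gH + model$sigma_H^2
    out$var_H <- var_H
    out$var_T_nores <- model$lambda^2 * var_H + V_gT + 2 * model$lambda * rho_s +
      model$delta_T^2
    if (!is.null(model$sigma_T)) {
      var_T <- out$var_T_nores + model$sigma_T^2
      cov_HT <- model$lambda * var_H + rho_s
      out$var_T <- var_T
      out$cov_HT <- cov_HT
      out$lambda_pop <- cov_HT / var_H
      pc <- model$pleio_C_std
      Rpc <- as.vector(R %*% pc)
      cov_H_gc <- sum(a * Rpc)
      cov_T_gc <- model$lambda * cov_H_gc + sum(b * Rpc)
      out$var_C_nores <- model$theta_H^2 * var_H + model$theta_T^2 * var_T +
        2 * model$theta_H * model$theta_T * cov_HT + sum(pc * Rpc) +
        2 * (model$theta_H * cov_H_gc + model$theta_T * cov_T_gc) +
        model$delta_C^2 + 2 * model$theta_T * model$delta_T * model$delta_C
      if (!partial) {
        marg_H <- Ra
        marg_T <- model$lambda * Ra + Rb
        out$marg_H <- marg_H
        out$marg_T <- marg_T
        out$marg_C <- model$theta_H * marg_H + model$theta_T * marg_T + Rpc
        out$marg_AD_liability <- model$phi_H * marg_H + model$phi_T * marg_T +
          as.vector(R %*% model$pleio_AD_std)
        out$marg_T_resid <- marg_T - out$lambda_pop * marg_H
        # per-variant covariate-adjusted coefficient (T ~ Z_j + H), std scale
        out$marg_T_covadj <- (marg_T - cov_HT / var_H * marg_H) /
          (1 - marg_H^2 / var_H)
        out$var_T_resid <- var_T - out$lambda_pop^2 * var_H
      }
    }
  }
  out
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf("true_model: %d variants (%d blocks of %d, rho = %.2f)\n",
              x$m, length(unique(x$variants$block)), x$block_size, x$rho))
  cat(sprintf("  lambda = %.2f, theta = (H %.3f, T %.3f), phi = (H %.3f, T %.3f)\n",
              x$lambda, x$theta_H, x$theta_T, x$phi_H, x$phi_T))
  invisible(x)
}

#' Cohort-level simulation settings
#'
#' Defaults define the desk-scale study: 20,000 samples per cohort, 600
#' variants in LD blocks of 10 with adjacent-variant correlation 0.4. The two
#' height GWASs share the lean-mass cohort (the larger one adds extra
#' samples); outcome cohorts never overlap the exposure cohorts; the
#' covariate-adjusted scans use a subset of the exposure cohort.
#'
#' @param n_exposure samples in the lean-mass/height exposure cohort.
#' @param n_height_extra additional samples for the large height GWAS
#'   (total `n_exposure + n_height_extra`).
#' @param n_outcome samples in each (non-overlapping) outcome cohort.
#' @param n_adjusted samples used for the covariate-adjusted / residualized
#'   lean-mass scans (must not exceed `n_exposure`).
#' @param n_ref samples in the LD reference panel.
#' @param standardize divide scan betas/SEs by the sample SD of the
#'   (possibly residualized) phenotype.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_exposure = 20000, n_height_extra = 20000,
                       n_outcome = 20000, n_adjusted = 15000, n_ref = 1000,
                       standardize = TRUE) {
  stopifnot(n_exposure >= 100, n_outcome >= 100, n_ref >= 100,
            n_height_extra >= 0, n_adjusted >= 100)
  if (n_adjusted > n_exposure) {
    stop("overlap plan error: n_adjusted exceeds n_exposure", call. = FALSE)
  }
  structure(list(n_exposure = n_exposure, n_height_extra = n_height_extra,
                 n_outcome = n_outcome, n_adjusted = n_adjusted, n_ref = n_ref,
                 standardize = standardize),
            class = "sim_config")
}

#' Simulate a hard-call genotype panel under the model's LD structure
#'
#' Two independent haplotypes per sample; each haplotype is a first-order
#' mosaic: the allele at a variant copies the previous variant's allele with
#' probability `rho` (within a block) or is drawn fresh at that variant's
#' allele frequency, so Hardy-Weinberg marginals hold at each variant and the
#' adjacent-variant dosage correlation is `rho` (exactly, for equal allele
#' frequencies, which the model enforces within blocks). Blocks are\n#' mutually independent.
#'
#' @param model a [true_model()].
#' @param n number of samples.
#' @param seed RNG seed.
#' @return A [geno_panel()] object.
#' @export
simulate_genotypes <- function(model, n, seed) {
  stopifnot(inherits(model, "true_model"), n >= 1)
  run_seeded(seed, {
    G <- sim_haplotypes_dosage(n, model)
    v <- model$variants
    geno_panel(G, v$variant_id, v$chrom, v$pos, v$effect_allele, v$other_allele,
               validate = FALSE)
  })
}

sim_haplotypes_dosage <- function(n, model) {
  .sim_mosaic_dosage(as.integer(n), model$maf,
                     as.integer(model$variants$block), model$rho)
}

#' Simulate phenotypes for a genotype panel
#'
#' Draws height, lean mass, cognition, and AD case status per the model's
#' structural equations. Genetic scores use population-centered dosages
#' (X - 2 * maf), so the liability intercept maps onto the case fraction
#' directly.
#'
#' @param panel a [geno_panel()] whose variants match the model.
#' @param model a [true_model()].
#' @param seed RNG seed.
#' @return data.frame with columns `H`, `T`, `C`, `AD` (and `U`, the latent
#'   confounder, for diagnostics).
#' @export
simulate_phenotypes <- function(panel, model, seed) {
  stopifnot(inherits(panel, "geno_panel"), inherits(model, "true_model"),
            ncol(panel$G) == model$m)
  run_seeded(seed, {
    n <- nrow(panel$G)
    sdz <- sqrt(2 * model$maf * (1 - model$maf))
    score <- function(std_eff) {
      use <- std_eff != 0
      if (!any(use)) return(numeric(n))
      w <- std_eff[use] / sdz[use]
      as.vector(panel$G[, use, drop = FALSE] %*% w) - sum(2 * model$maf[use] * w)
    }
    gH <- score(model$a_std)
    gT <- score(model$b_std)
    gC <- score(model$pleio_C_std)
    gAD <- score(model$pleio_AD_std)
    U <- rnorm(n)
    H <- gH + rnorm(n, sd = model$sigma_H)
    T_ <- model$lambda * H + gT + model$delta_T * U + rnorm(n, sd = model$sigma_T)
    C_ <- model$theta_H * H + model$theta_T * T_ + gC + model$delta_C * U +
      rnorm(n, sd = model$sigma_C)
    liab <- model$alpha + model$phi_H * H + model$phi_T * T_ + gAD +
      model$delta_AD * U
    AD <- rbinom(n, 1L, plogis(liab))
    data.frame(H = H, T = T_, C = C_, AD = AD, U = U)
  })
}

#' Per-variant genome-wide association scan
#'
#' Continuous traits: per-variant least-squares regression of the phenotype on
#' dosage (optionally including a covariate, or scanning the phenotype
#' residualized on the covariate over the full sample). Binary traits:
#' per-variant logistic regression by maximum likelihood with Wald standard
#' errors. Perfectly separated variants are dropped with a warning.
#'
#' @param panel a [geno_panel()].
#' @param phenotype numeric vector (0/1 for binary traits), one value per
#'   panel sample.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param adjustment `"none"`, `"covariate"` (covariate enters each
#'   per-variant model) or `"residual"` (phenotype residualized on the
#'   covariate once, then scanned unadjusted).
#' @param adjust_on covariate vector, required unless `adjustment = "none"`.
#' @param standardize divide beta and SE by the sample SD of the (possibly
#'   residualized) phenotype. Continuous traits only.
#' @param trait_name,sd_unit metadata for the returned table.
#' @param variant_ids optional subset of variants to scan.
#' @return A [sumstats()] object.
#' @export
association_scan <- function(panel, phenotype,
                             trait_type = c("continuous", "binary"),
                             adjustment = c("none", "covariate", "residual"),
                             adjust_on = NULL, standardize = FALSE,
                             trait_name = "trait", sd_unit = NA_real_,
                             variant_ids = NULL) {
  trait_type <- match.arg(trait_type)
  adjustment <- match.arg(adjustment)
  stopifnot(length(phenotype) == nrow(panel$G))
  if (adjustment != "none" && is.null(adjust_on)) {
    stop("adjust_on is required when adjustment != 'none'", call. = FALSE)
  }
  if (adjustment == "none" && !is.null(adjust_on)) adjust_on <- NULL
  meta <- panel$variants
  if (!is.null(variant_ids)) {
    keep <- match(variant_ids, meta$variant_id)
    if (anyNA(keep)) stop("variant_ids not in panel", call. = FALSE)
    meta <- meta[keep, , drop = FALSE]
    X <- panel$G[, keep, drop = FALSE]
  } else {
    X <- panel$G
  }
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (trait_type == "continuous") {
    res <- scan_continuous(X, phenotype, adjustment, adjust_on, standardize)
  } else {
    if (!all(phenotype %in% c(0, 1))) stop("binary trait must be coded 0/1", call. = FALSE)
    res <- scan_binary(X, phenotype, adjustment, adjust_on)
  }
  keep <- is.finite(res$beta) & is.finite(res$se) & res$se > 0
  if (!all(keep)) {
    warning(sprintf("dropped %d variant(s) with unstable fits (monomorphic or separated)",
                    sum(!keep)), call. = FALSE)
  }
  z <- res$beta[keep] / res$se[keep]
  pval <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  rec <- data.frame(variant_id = meta$variant_id[keep], chrom = meta$chrom[keep],
                    pos = meta$pos[keep], effect_allele = meta$effect_allele[keep],
                    other_allele = meta$other_allele[keep],
                    eaf = colMeans(X[, keep, drop = FALSE]) / 2,
                    beta = res$beta[keep], se = res$se[keep], pval = pval,
                    n = n, stringsAsFactors = FALSE)
  if (trait_type == "binary") {
    rec$n_cases <- as.integer(sum(phenotype == 1))
    rec$n_controls <- as.integer(sum(phenotype == 0))
  }
  sumstats(rec, trait_name = trait_name, trait_type = trait_type,
           sd_unit = sd_unit, validate = FALSE)
}

scan_continuous <- function(X, y, adjustment, adjust_on, standardize) {
  n <- nrow(X)
  if (adjustment == "residual") {
    cc <- adjust_on - mean(adjust_on)
    y <- y - mean(y) - cc * sum(cc * (y - mean(y))) / sum(cc^2)
    adjust_on <- NULL
  }
  s_y <- sd(y)
  yc <- y - mean(y)
  Sxy <- as.vector(crossprod(X, yc))
  xm <- colMeans(X)
  Sxx <- colSums(X^2) - n * xm^2
  Syy <- sum(yc^2)
  df <- n - 2
  if (adjustment == "covariate") {
    cc <- adjust_on - mean(adjust_on)
    Scc <- sum(cc^2)
    Sxc <- as.vector(crossprod(X, cc))
    Scy <- sum(cc * yc)
    Sxy <- Sxy - Sxc * Scy / Scc
    Sxx <- Sxx - Sxc^2 / Scc
    Syy <- Syy - Scy^2 / Scc
    df <- n - 3
  }
  beta <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  sse <- pmax(Syy - beta^2 * Sxx, 0)
  se <- sqrt(sse / df / Sxx)
  if (standardize) {
    beta <- beta / s_y
    se <- se / s_y
  }
  list(beta = beta, se = se)
}

# Vectorized per-variant logistic ML (intercept + dosage) via Newton scoring;
# with a covariate, falls back to per-variant glm fits.
scan_binary <- function(X, y, adjustment, adjust_on) {
  if (adjustment == "residual") {
    stop("residual adjustment is undefined for binary traits", call. = FALSE)
  }
  if (adjustment == "covariate") {
    m <- ncol(X)
    beta <- se <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      fit <- try(suppressWarnings(
        stats::glm.fit(cbind(1, X[, j], adjust_on), y,
                       family = stats::binomial())), silent = TRUE)
      if (!inherits(fit, "try-error") && fit$converged) {
        cf <- fit$coefficients[2]
        vc <- tryCatch(chol2inv(chol(crossprod(
          cbind(1, X[, j], adjust_on) * sqrt(fit$weights))))[2, 2],
          error = function(e) NA_real_)
        if (is.finite(cf) && abs(cf) < 15 && is.finite(vc)) {
          beta[j] <- cf; se[j] <- sqrt(vc)
        }
      }
    }
    return(list(beta = beta, se = se))
  }
  m <- ncol(X)
  # dosage takes values {0,1,2}: collapse to per-genotype case/total counts,
  # on which per-variant logistic ML is exact and vectorizes across variants
  N <- Y <- matrix(0, m, 3)
  for (g in 0:2) {
    Ig <- X == g
    N[, g + 1] <- colSums(Ig, na.rm = TRUE)
    Y[, g + 1] <- colSums(Ig * y, na.rm = TRUE)
  }
  gval <- c(0, 1, 2)
  b0 <- rep(stats::qlogis(mean(y)), m)
  b1 <- rep(0, m)
  for (iter in 1:40) {
    U0 <- U1 <- S0 <- S1 <- S2 <- 0
    for (k in 1:3) {
      mu <- 1 / (1 + exp(-(b0 + b1 * gval[k])))
      w <- N[, k] * mu * (1 - mu)
      r <- Y[, k] - N[, k] * mu
      U0 <- U0 + r; U1 <- U1 + gval[k] * r
      S0 <- S0 + w; S1 <- S1 + gval[k] * w; S2 <- S2 + gval[k]^2 * w
    }
    det <- S0 * S2 - S1^2
    db0 <- (S2 * U0 - S1 * U1) / det
    db1 <- (S0 * U1 - S1 * U0) / det
    bad <- !is.finite(db0) | !is.finite(db1) | abs(b1 + db1) > 20
    db0[bad] <- 0; db1[bad] <- 0
    b0 <- b0 + db0; b1 <- b1 + db1
    if (max(abs(db0), abs(db1)) < 1e-10) break
  }
  S0 <- S1 <- S2 <- 0
  for (k in 1:3) {
    mu <- 1 / (1 + exp(-(b0 + b1 * gval[k])))
    w <- N[, k] * mu * (1 - mu)
    S0 <- S0 + w; S1 <- S1 + gval[k] * w; S2 <- S2 + gval[k]^2 * w
  }
  det <- S0 * S2 - S1^2
  se <- sqrt(S0 / det)
  sep <- !is.finite(b1) | abs(b1) > 15 | !is.finite(se) | se > 100
  b1[sep] <- NA_real_; se[sep] <- NA_real_
  list(beta = b1, se = se)
}

#' Generate the full synthetic study set
#'
#' Emits the seven summary-statistics tables of the study design -- lean mass
#' (TLM), two height GWASs of different sample size, AD, cognitive
#' performance, and the covariate-adjusted and residualized TLM scans --
#' plus an independent LD reference panel. Exposure GWASs share samples (the
#' larger height GWAS is the exposure cohort plus extra samples; the adjusted
#' scans use a subset); each outcome GWAS uses a fresh cohort.
#'
#' @param model a [true_model()].
#' @param config a [sim_config()].
#' @param seed integer seed; the whole collection is deterministic given it.
#' @return An object of class `mr_study_set`: list with `tables` (named list
#'   of [sumstats()]), `panel` (LD reference [geno_panel()]), `model`,
#'   `config`, `seed`.
#' @export
make_study_set <- function(model, config = sim_config(), seed = 1) {
  stopifnot(inherits(model, "true_model"), inherits(config, "sim_config"))
  std <- config$standardize
  cohA <- simulate_genotypes(model, config$n_exposure, seed = seed * 10L + 1L)
  phenA <- simulate_phenotypes(cohA, model, seed = seed * 10L + 2L)
  tlm <- association_scan(cohA, phenA$T, "continuous", standardize = std,
                          trait_name = "tlm", sd_unit = 11.5)
  height_05 <- association_scan(cohA, phenA$H, "continuous", standardize = std,
                                trait_name = "height_05m")
  idx <- seq_len(config$n_adjusted)
  subA <- cohA
  subA$G <- cohA$G[idx, , drop = FALSE]
  subA$variants$call_rate <- colMeans(!is.na(subA$G))
  tlm_cov <- association_scan(subA, phenA$T[idx], "continuous",
                              adjustment = "covariate", adjust_on = phenA$H[idx],
                              standardize = std, trait_name = "tlm_covariate",
                              sd_unit = 11.5)
  tlm_res <- association_scan(subA, phenA$T[idx], "continuous",
                              adjustment = "residual", adjust_on = phenA$H[idx],
                              standardize = std, trait_name = "tlm_residual",
                              sd_unit = 11.5)
  rm(subA)
  if (config$n_height_extra > 0) {
    cohB <- simulate_genotypes(model, config$n_height_extra, seed = seed * 10L + 3L)
    phenB <- simulate_phenotypes(cohB, model, seed = seed * 10L + 4L)
    pooled <- cohA
    pooled$G <- rbind(cohA$G, cohB$G)
    pooled$variants$call_rate <- colMeans(!is.na(pooled$G))
    height_15 <- association_scan(pooled, c(phenA$H, phenB$H), "continuous",
                                  standardize = std, trait_name = "height_15m")
    rm(cohB, pooled)
  } else {
    height_15 <- height_05
    height_15$trait_name <- "height_15m"
  }
  rm(cohA)
  cohC <- simulate_genotypes(model, config$n_outcome, seed = seed * 10L + 5L)
  phenC <- simulate_phenotypes(cohC, model, seed = seed * 10L + 6L)
  ad <- association_scan(cohC, phenC$AD, "binary", trait_name = "ad")
  rm(cohC)
  cohD <- simulate_genotypes(model, config$n_outcome, seed = seed * 10L + 7L)
  phenD <- simulate_phenotypes(cohD, model, seed = seed * 10L + 8L)
  cognition <- association_scan(cohD, phenD$C, "continuous", standardize = std,
                                trait_name = "cognition")
  rm(cohD)
  panel <- simulate_genotypes(model, config$n_ref, seed = seed * 10L + 9L)
  structure(list(tables = list(tlm = tlm, height_05m = height_05,
                               height_15m = height_15, ad = ad,
                               cognition = cognition, tlm_covariate = tlm_cov,
                               tlm_residual = tlm_res),
                 panel = panel, model = model, config = config, seed = seed),
            class = "mr_study_set")
}

#' @export
print.mr_study_set <- function(x, ...) {
  cat("Synthetic MR study set\n")
  for (nm in names(x$tables)) {
    tb <- x$tables[[nm]]
    cat(sprintf("  %-14s %s, n = %d, %d variants\n", nm, tb$trait_type,
                tb$records$n[1], nrow(tb$records)))
  }
  cat(sprintf("  LD reference panel: %d samples\n", nrow(x$panel$G)))
  invisible(x)
}
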