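# Canned generative scenarios at desk scale.
#
# The default architecture concentrates heritability into block-level loci so
# that instrument selection at p < 5e-8 behaves, at n = 20,000 per cohort,
# like selection in a biobank-scale GWAS: 12 large-effect "tall stature"
# loci, 18 "muscle mass" loci, and 24 pleiotropic background blocks whose
# variants affect both traits (the source of the genetic covariance rho_s
# between height and the direct lean-mass component, and hence of the
# collider bias under height adjustment). See the methods vignette for the
# power algebra behind each constant.

default_architecture <- function(m = 600, block_size = 10) {
  n_blocks <- m %/% block_size
  stopifnot(n_blocks >= 60)
  center <- function(blocks) (blocks) * block_size + block_size %/% 2
  blk <- (seq_len(m) - 1L) %/% block_size
  maf <- 0.1 + 0.4 * (((blk * 7L) %% 60L) / 59)
  a_std <- b_std <- numeric(m)
  tall <- center(0:11)
  muscle <- center(12:29)
  bg <- as.vector(outer(seq_len(block_size), 30:53 * block_size, `+`))
  a_std[tall] <- 0.19
  b_std[muscle] <- 0.11
  a_std[bg] <- 0.0314
  b_std[bg] <- 0.66 * 0.0314
  list(maf = maf, a_std = a_std, b_std = b_std, tall = tall, muscle = muscle,
       bg = bg, block_size = block_size)
}

#' Default synthetic scenario: height confounds the lean-mass associations
#'
#' Lean mass has no direct effect on either outcome (`theta_T = phi_T = 0`);
#' height protects against AD (`phi_H = -0.6` log-odds per SD) and improves
#' cognition (`theta_H = 0.15` SD per SD). Height and lean mass are linked
#' both causally (`lambda = 0.35`) and through pleiotropic background
#' variants (genetic covariance `rho_s` of about 0.25), so univariable
#' lean-mass MR is confounded, MVMR recovers the null direct effect, and
#' height-adjusted lean-mass GWASs exhibit collider-induced sign reversal.
#'
#' @param m number of variants (default 600 in blocks of 10).
#' @param ... overrides passed on to [true_model()].
#' @return A [true_model()].
#' @export
model_confounded <- function(m = 600, ...) {
  arch <- default_architecture(m)
  args <- modifyList(
    list(maf = arch$maf, a_std = arch$a_std, b_std = arch$b_std,
         lambda = 0.35, delta_T = 0.3, delta_C = 0.15, delta_AD = 0.1,
         theta_H = 0.15, theta_T = 0, phi_H = -0.6, phi_T = 0,
         alpha = -0.65, block_size = arch$block_size, rho = 0.4),
    list(...))
  do.call(true_model, args)
}

#' Parameter-recovery scenario: known causal effect of lean mass on cognition
#'
#' Same genetic architecture as [model_confounded()], but lean mass carries
#' the entire outcome effect (`theta_T = effect`, `theta_H = 0`), so every
#' valid-instrument estimator should recover `effect` exactly.
#'
#' @param effect true causal effect of lean mass on cognition (SD per SD).
#' @param ... overrides passed on to [true_model()].
#' @return A [true_model()].
#' @export
model_recovery <- function(effect = 0.10, ...) {
  model_confounded(theta_H = 0, theta_T = effect, ...)
}

#' Global-null scenario: no causal effects on either outcome
#'
#' The exposures keep their genetic architecture and mutual structure
#' (so instruments exist), but neither trait affects the outcomes; the
#' non-genetic confounder still links the traits observationally.
#'
#' @param ... overrides passed on to [true_model()].
#' @return A [true_model()].
#' @export
model_null <- function(...) {
  model_confounded(theta_H = 0, theta_T = 0, phi_H = 0, phi_T = 0, ...)
}

#' Directional-pleiotropy scenario
#'
#' [model_recovery()] plus a common direct outcome effect on 22 of the ~54
#' instrument-bearing loci (about 40% of instruments): 5 tall-stature loci,
#' 7 muscle loci, and the lead variants of 10 background blocks acquire a
#' direct effect `pleio` on cognition, violating the exclusion restriction
#' in one direction.
#'
#' @param effect true causal effect of lean mass on cognition.
#' @param pleio common directional pleiotropic effect (standardized).
#' @param ... overrides passed on to [true_model()].
#' @return A [true_model()].
#' @export
model_pleiotropy <- function(effect = 0.10, pleio = 0.08, ...) {
  arch <- default_architecture(600)
  pc <- numeric(600)
  loci <- c(arch$tall[1:5], arch$muscle[1:7],
            (30:39) * arch$block_size + arch$block_size %/% 2)
  pc[loci] <- pleio
  model_recovery(effect = effect, pleio_C_std = pc, ...)
}

#' Shared-instrument scenario for conditional instrument strength
#'
#' Thirty instrument loci; a fraction `shared` affect both height and lean
#' mass with proportional effects, the remainder split into height-only and
#' lean-mass-only loci. As `shared` approaches 1 the two exposures' genetic
#' association vectors become collinear and the conditional F-statistic of
#' each exposure collapses toward zero.
#'
#' @param shared fraction of the 30 loci affecting both exposures, in [0, 1).
#' @param ... overrides passed on to [true_model()].
#' @return A [true_model()].
#' @export
model_shared <- function(shared = 0, ...) {
  stopifnot(shared >= 0, shared < 1)
  m <- 600; block_size <- 10
  maf <- default_architecture(m, block_size)$maf
  centers <- (0:29) * block_size + block_size %/% 2
  n_sh <- round(30 * shared)
  n_tall <- max(1L, ceiling((30 - n_sh) * 0.4))
  a_std <- b_std <- numeric(m)
  sh <- centers[seq_len(n_sh)]
  tall <- centers[n_sh + seq_len(n_tall)]
  muscle <- centers[setdiff(seq_len(30), seq_len(n_sh + n_tall))]
  a_std[sh] <- 0.15; b_std[sh] <- 0.10
  a_std[tall] <- 0.18
  b_std[muscle] <- 0.12
  args <- modifyList(
    list(maf = maf, a_std = a_std, b_std = b_std, lambda = 0.35,
         delta_T = 0.3, delta_C = 0.15, delta_AD = 0.1,
         theta_H = 0, theta_T = 0.1, phi_H = 0, phi_T = 0, alpha = -0.65,
         block_size = block_size, rho = 0.4),
    list(...))
  do.call(true_model, args)
}
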