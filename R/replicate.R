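# Efficient single-replicate driver for Monte-Carlo evaluation of the MR
# pipeline: one exposure cohort, one (non-overlapping) outcome cohort, one
# fixed LD reference panel, with the outcome scan restricted to the selected
# instruments (the only variants whose outcome associations the estimators
# consume).

#' Run one synthetic two-sample MR replicate
#'
#' Simulates an exposure cohort and an independent outcome cohort under
#' `model`, performs instrument selection against the supplied reference
#' panel, harmonizes, and returns the harmonized dataset(s) for the
#' requested analysis arms. Used by the package's Monte-Carlo calibration
#' studies; the outcome association scan is restricted to the selected
#' instruments, which leaves every estimate identical while avoiding
#' needless per-variant fits.
#'
#' @param model a [true_model()].
#' @param seed replicate seed (cohort draws are derived from it).
#' @param panel a fixed LD reference [geno_panel()] for clumping (generate
#'   once with [simulate_genotypes()]; a reference panel is a fixed resource,
#'   not part of the replicate).
#' @param params a [clump_params()].
#' @param outcome `"cognition"` (continuous) or `"ad"` (binary).
#' @param arms subset of `c("uni", "covariate", "residual", "mvmr")`:
#'   unadjusted univariable lean-mass MR, the two adjusted-GWAS modes, and
#'   multivariable lean mass + height.
#' @param n_exposure,n_outcome,n_adjusted cohort sizes (the adjusted scans
#'   use the first `n_adjusted` exposure-cohort samples).
#' @param standardize divide betas by the sample phenotype SD.
#' @return Named list of `mr_harmonized` objects, one per requested arm.
#' @export
simulate_replicate <- function(model, seed, panel, params = clump_params(),
                               outcome = c("cognition", "ad"),
                               arms = "uni",
                               n_exposure = 20000, n_outcome = 20000,
                               n_adjusted = 15000, standardize = TRUE) {
  outcome <- match.arg(outcome)
  arms <- match.arg(arms, c("uni", "covariate", "residual", "mvmr"),
                    several.ok = TRUE)
  cohA <- simulate_genotypes(model, n_exposure, seed = seed * 10L + 1L)
  phA <- simulate_phenotypes(cohA, model, seed = seed * 10L + 2L)
  tlm <- association_scan(cohA, phA$T, "continuous", standardize = standardize,
                          trait_name = "tlm")
  exposures <- list()
  insts <- list()
  if ("uni" %in% arms) {
    exposures$uni <- tlm
    insts$uni <- greedy_clump(filter_candidates(tlm, params), panel, params)
  }
  if ("mvmr" %in% arms) {
    height <- association_scan(cohA, phA$H, "continuous",
                               standardize = standardize, trait_name = "height")
    exposures$mvmr <- list(tlm, height)
    insts$mvmr <- select_mvmr_instruments(tlm, height, panel, params)
  }
  if (any(c("covariate", "residual") %in% arms)) {
    idx <- seq_len(min(n_adjusted, n_exposure))
    sub <- cohA
    sub$G <- cohA$G[idx, , drop = FALSE]
    for (adj in intersect(arms, c("covariate", "residual"))) {
      tab <- association_scan(sub, phA$T[idx], "continuous", adjustment = adj,
                              adjust_on = phA$H[idx], standardize = standardize,
                              trait_name = paste0("tlm_", adj))
      exposures[[adj]] <- tab
      insts[[adj]] <- greedy_clump(filter_candidates(tab, params), panel, params)
    }
  }
  rm(cohA)
  cohB <- simulate_genotypes(model, n_outcome, seed = seed * 10L + 5L)
  phB <- simulate_phenotypes(cohB, model, seed = seed * 10L + 6L)
  needed <- unique(unlist(lapply(insts, `[[`, "ids")))
  out_tab <- if (outcome == "cognition") {
    association_scan(cohB, phB$C, "continuous", standardize = standardize,
                     trait_name = "cognition", variant_ids = needed)
  } else {
    association_scan(cohB, phB$AD, "binary", trait_name = "ad",
                     variant_ids = needed)
  }
  out <- list()
  for (arm in arms) {
    out[[arm]] <- if (arm == "mvmr") {
      harmonize_multivariable(exposures$mvmr[[1]], exposures$mvmr[[2]],
                              out_tab, insts$mvmr)
    } else {
      harmonize_univariable(exposures[[arm]], out_tab, insts[[arm]])
    }
  }
  out
}
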