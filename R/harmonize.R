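COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) COMPLEMENT[[a1]] == a2

#' Align one association record to an exposure record's effect allele
#'
#' Resolves effect/other allele swaps, strand flips (allele complements), and
#' palindromic (A/T, C/G) ambiguity. Palindromic variants are resolved by
#' allele-frequency concordance only when both records' minor allele
#' frequencies are below the ambiguity threshold (default 0.42, applied to
#' both sides); otherwise they are dropped. Records whose alleles cannot be
#' reconciled, that carry non-ACGT alleles, or whose chrom/pos disagree at a
#' matched id, are dropped as mismatches.
#'
#' @param exposure_rec,other_rec single-row data.frames in the canonical
#'   record schema, sharing `variant_id`.
#' @param maf_ambiguous palindromic ambiguity threshold on the minor allele
#'   frequency.
#' @param both_sides apply the ambiguity threshold to both records' MAFs
#'   (`TRUE`, conservative) or to the exposure side only.
#' @return list with `record` (the aligned `other_rec`, or `NULL` when
#'   dropped) and `action`, one of `kept`, `flipped`, `strand_corrected`,
#'   `strand_corrected_flipped`, `dropped_palindromic`, `dropped_mismatch`.
#' @export
align_alleles <- function(exposure_rec, other_rec, maf_ambiguous = 0.42,
                          both_sides = TRUE) {
  stopifnot(exposure_rec$variant_id == other_rec$variant_id)
  drop <- function(action) list(record = NULL, action = action)
  ea_x <- exposure_rec$effect_allele; oa_x <- exposure_rec$other_allele
  ea_y <- other_rec$effect_allele;    oa_y <- other_rec$other_allele
  if (!all(c(ea_x, oa_x, ea_y, oa_y) %in% VALID_ALLELES)) {
    return(drop("dropped_mismatch"))
  }
  if (!is.na(exposure_rec$pos) && !is.na(other_rec$pos) &&
      (exposure_rec$chrom != other_rec$chrom || exposure_rec$pos != other_rec$pos)) {
    return(drop("dropped_mismatch"))
  }
  flip_rec <- function(rec) {
    tmp <- rec$effect_allele; rec$effect_allele <- rec$other_allele; rec$other_allele <- tmp
    rec$beta <- -rec$beta
    if (!is.na(rec$eaf)) rec$eaf <- 1 - rec$eaf
    rec
  }
  if (is_palindromic(ea_x, oa_x)) {
    # complement equals swap here: strand cannot be read off the alleles
    if (!((ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x))) {
      return(drop("dropped_mismatch"))
    }
    maf_x <- min(exposure_rec$eaf, 1 - exposure_rec$eaf)
    if (is.na(other_rec$eaf)) return(drop("dropped_palindromic"))
    maf_y <- min(other_rec$eaf, 1 - other_rec$eaf)
    ambiguous <- if (both_sides) {
      is.na(maf_x) || maf_x >= maf_ambiguous || maf_y >= maf_ambiguous
    } else {
      is.na(maf_x) || maf_x >= maf_ambiguous
    }
    if (ambiguous) return(drop("dropped_palindromic"))
    # frequency concordance: opposite sides of 0.5 means the reported effect
    # alleles are opposite strands/orientations of the same allele
    if ((exposure_rec$eaf < 0.5) != (other_rec$eaf < 0.5)) {
      rec <- flip_rec(other_rec)
      rec$effect_allele <- ea_x; rec$other_allele <- oa_x
      return(list(record = rec, action = "flipped"))
    }
    rec <- other_rec
    rec$effect_allele <- ea_x; rec$other_allele <- oa_x
    return(list(record = rec, action = "kept"))
  }
  if (ea_y == ea_x && oa_y == oa_x) {
    return(list(record = other_rec, action = "kept"))
  }
  if (ea_y == oa_x && oa_y == ea_x) {
    return(list(record = flip_rec(other_rec), action = "flipped"))
  }
  cea <- COMPLEMENT[[ea_y]]; coa <- COMPLEMENT[[oa_y]]
  if (cea == ea_x && coa == oa_x) {
    rec <- other_rec
    rec$effect_allele <- cea; rec$other_allele <- coa
    return(list(record = rec, action = "strand_corrected"))
  }
  if (cea == oa_x && coa == ea_x) {
    rec <- other_rec
    rec$effect_allele <- cea; rec$other_allele <- coa
    return(list(record = flip_rec(rec), action = "strand_corrected"))
  }
  drop("dropped_mismatch")
}

# vectorized harmonization of a full table against exposure records;
# returns aligned records plus per-variant action
align_table <- function(exp_rec, other_rec, maf_ambiguous = 0.42,
                        both_sides = TRUE) {
  n <- nrow(exp_rec)
  actions <- character(n)
  out <- other_rec
  for (i in seq_len(n)) {
    al <- align_alleles(exp_rec[i, , drop = FALSE], other_rec[i, , drop = FALSE],
                        maf_ambiguous = maf_ambiguous, both_sides = both_sides)
    actions[i] <- al$action
    if (!is.null(al$record)) out[i, ] <- al$record
  }
  list(records = out, actions = actions)
}

#' Harmonize exposure and outcome associations over an instrument set
#'
#' Aligns each instrument's outcome record to the exposure's effect allele
#' and assembles the per-variant association matrix used by the estimators.
#' Instruments missing from the outcome dataset are logged as mismatches.
#'
#' @param exposure,outcome [sumstats()] objects.
#' @param instruments an `instrument_set` (or character vector of ids), all
#'   present in the exposure dataset.
#' @param maf_ambiguous,both_sides palindromic handling, see [align_alleles()].
#' @return An object of class `mr_harmonized`: a data.frame with one row per
#'   retained variant (columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf_exposure`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `action`), sorted by
#'   (chrom, pos), with attributes `exposure`, `outcome`, `outcome_type`,
#'   and `action_log` (a table over all instruments, drops included).
#' @export
harmonize_univariable <- function(exposure, outcome, instruments,
                                  maf_ambiguous = 0.42, both_sides = TRUE) {
  ids <- if (inherits(instruments, "instrument_set")) instruments$ids else
    as.character(instruments)
  exp_rec <- exposure$records[match(ids, exposure$records$variant_id), , drop = FALSE]
  if (anyNA(exp_rec$variant_id)) {
    stop("instruments must be a subset of the exposure dataset", call. = FALSE)
  }
  out_idx <- match(ids, outcome$records$variant_id)
  actions <- rep("dropped_mismatch", length(ids))
  present <- !is.na(out_idx)
  aligned <- NULL
  if (any(present)) {
    al <- align_table(exp_rec[present, , drop = FALSE],
                      outcome$records[out_idx[present], , drop = FALSE],
                      maf_ambiguous = maf_ambiguous, both_sides = both_sides)
    actions[present] <- al$actions
    aligned <- al$records
  }
  retained <- !startsWith(actions, "dropped")
  if (!any(retained)) stop("no variants retained after harmonization", call. = FALSE)
  keep_in_present <- which(retained[present])
  dat <- data.frame(
    variant_id = exp_rec$variant_id[retained],
    chrom = exp_rec$chrom[retained],
    pos = exp_rec$pos[retained],
    effect_allele = exp_rec$effect_allele[retained],
    other_allele = exp_rec$other_allele[retained],
    eaf_exposure = exp_rec$eaf[retained],
    beta_exposure = exp_rec$beta[retained],
    se_exposure = exp_rec$se[retained],
    beta_outcome = aligned$beta[keep_in_present],
    se_outcome = aligned$se[keep_in_present],
    action = actions[retained],
    stringsAsFactors = FALSE)
  ord <- order(suppressWarnings(as.integer(dat$chrom)), dat$chrom, dat$pos,
               method = "radix")
  dat <- dat[ord, , drop = FALSE]
  rownames(dat) <- NULL
  structure(dat, class = c("mr_harmonized", "data.frame"),
            exposure = exposure$trait_name, outcome = outcome$trait_name,
            outcome_type = outcome$trait_type,
            action_log = table(factor(actions, levels = c(
              "kept", "flipped", "strand_corrected",
              "dropped_palindromic", "dropped_mismatch"))))
}

#' Harmonize two exposures and an outcome for multivariable MR
#'
#' Orientation is anchored to the first exposure's effect allele; a variant is
#' retained only if it aligns across all three datasets.
#'
#' @param exposure1,exposure2,outcome [sumstats()] objects.
#' @param instruments instrument set (typically [select_mvmr_instruments()]
#'   output), all present in `exposure1`.
#' @param maf_ambiguous,both_sides palindromic handling, see [align_alleles()].
#' @return An `mr_harmonized` data.frame with columns `beta_exposure1`,
#'   `se_exposure1`, `beta_exposure2`, `se_exposure2`, `beta_outcome`,
#'   `se_outcome`, `action`; attribute `exposures` holds both trait names.
#' @export
harmonize_multivariable <- function(exposure1, exposure2, outcome, instruments,
                                    maf_ambiguous = 0.42, both_sides = TRUE) {
  ids <- if (inherits(instruments, "instrument_set")) instruments$ids else
    as.character(instruments)
  exp_rec <- exposure1$records[match(ids, exposure1$records$variant_id), , drop = FALSE]
  if (anyNA(exp_rec$variant_id)) {
    stop("instruments must be a subset of the first exposure dataset", call. = FALSE)
  }
  align_one <- function(tab) {
    idx <- match(ids, tab$records$variant_id)
    actions <- rep("dropped_mismatch", length(ids))
    beta <- se <- rep(NA_real_, length(ids))
    present <- !is.na(idx)
    if (any(present)) {
      al <- align_table(exp_rec[present, , drop = FALSE],
                        tab$records[idx[present], , drop = FALSE],
                        maf_ambiguous = maf_ambiguous, both_sides = both_sides)
      actions[present] <- al$actions
      beta[present] <- al$records$beta
      se[present] <- al$records$se
    }
    list(beta = beta, se = se, actions = actions)
  }
  al2 <- align_one(exposure2)
  alo <- align_one(outcome)
  comb <- ifelse(startsWith(al2$actions, "dropped"), al2$actions,
                 ifelse(startsWith(alo$actions, "dropped"), alo$actions,
                        ifelse(alo$actions != "kept", alo$actions, al2$actions)))
  retained <- !startsWith(comb, "dropped")
  if (!any(retained)) stop("no variants retained after harmonization", call. = FALSE)
  dat <- data.frame(
    variant_id = exp_rec$variant_id[retained],
    chrom = exp_rec$chrom[retained],
    pos = exp_rec$pos[retained],
    effect_allele = exp_rec$effect_allele[retained],
    other_allele = exp_rec$other_allele[retained],
    eaf_exposure = exp_rec$eaf[retained],
    beta_exposure1 = exp_rec$beta[retained],
    se_exposure1 = exp_rec$se[retained],
    beta_exposure2 = al2$beta[retained],
    se_exposure2 = al2$se[retained],
    beta_outcome = alo$beta[retained],
    se_outcome = alo$se[retained],
    action = comb[retained],
    stringsAsFactors = FALSE)
  ord <- order(suppressWarnings(as.integer(dat$chrom)), dat$chrom, dat$pos,
               method = "radix")
  dat <- dat[ord, , drop = FALSE]
  rownames(dat) <- NULL
  structure(dat, class = c("mr_harmonized", "data.frame"),
            exposures = c(exposure1$trait_name, exposure2$trait_name),
            outcome = outcome$trait_name, outcome_type = outcome$trait_type,
            action_log = table(factor(comb, levels = c(
              "kept", "flipped", "strand_corrected",
              "dropped_palindromic", "dropped_mismatch"))))
}

#' @export
print.mr_harmonized <- function(x, ...) {
  expo <- attr(x, "exposures")
  if (is.null(expo)) expo <- attr(x, "exposure")
  cat(sprintf("Harmonized data: %s -> %s (%s outcome), %d variants\n",
              paste(expo, collapse = " + "), attr(x, "outcome"),
              attr(x, "outcome_type"), nrow(x)))
  log <- attr(x, "action_log")
  cat("  actions:", paste(sprintf("%s=%d", names(log), log), collapse = ", "), "\n")
  invisible(x)
}
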