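#' Instrument-selection thresholds
#'
#' Defaults follow the conventional genome-wide pipeline: significance
#' p < 5e-8, minor allele frequency > 0.01, clumping within a +/-10 Mb window
#' at r-squared < 0.001. All comparisons are strict inequalities.
#'
#' @param p_threshold genome-wide significance cutoff.
#' @param maf_min minimum minor allele frequency.
#' @param window_bp physical clumping window, interpreted as +/- `window_bp`
#'   around the index variant.
#' @param r2_max LD cutoff; variants with r-squared at or above this against a
#'   retained index variant (within the window, same chromosome) are removed.
#' @return An object of class `clump_params`.
#' @export
clump_params <- function(p_threshold = 5e-8, maf_min = 0.01,
                         window_bp = 1e7, r2_max = 0.001) {
  stopifnot(p_threshold > 0, p_threshold <= 1, maf_min >= 0, maf_min < 0.5,
            window_bp >= 0, r2_max >= 0, r2_max <= 1)
  structure(list(p_threshold = p_threshold, maf_min = maf_min,
                 window_bp = window_bp, r2_max = r2_max),
            class = "clump_params")
}

#' Filter candidate instruments on significance, frequency and availability
#'
#' Retains records with `pval < p_threshold`, minor allele frequency strictly
#' above `maf_min`, and variant id present in the outcome dataset. Row order
#' is preserved.
#'
#' @param table a [sumstats()] object for the exposure.
#' @param params a [clump_params()].
#' @param outcome_ids character vector of variant ids available in the
#'   outcome dataset (`NULL` to skip the availability filter).
#' @return A [sumstats()] object containing the survivors.
#' @export
filter_candidates <- function(table, params = clump_params(), outcome_ids = NULL) {
  stopifnot(inherits(table, "gwas_sumstats"))
  rec <- table$records
  pass_p <- rec$pval < params$p_threshold
  pass_maf <- pmin(rec$eaf, 1 - rec$eaf) > params$maf_min
  pass_avail <- if (is.null(outcome_ids)) rep(TRUE, nrow(rec)) else
    rec$variant_id %in% outcome_ids
  keep <- pass_p & pass_maf & pass_avail
  if (!any(keep)) {
    stop(sprintf(paste0("no instruments for '%s': %d/%d pass p < %g, %d/%d pass ",
                        "MAF > %g, %d/%d available in outcome"),
                 table$trait_name, sum(pass_p), nrow(rec), params$p_threshold,
                 sum(pass_maf), nrow(rec), params$maf_min, sum(pass_avail),
                 nrow(rec)), call. = FALSE)
  }
  out <- table
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Iteratively selects the unclaimed variant with the lowest ranking p-value
#' as an index variant, then removes all unclaimed variants on the same
#' chromosome within the physical window whose panel r-squared with the index
#' is at or above the cutoff. Ties in p are broken by (chrom, pos,
#' variant_id). Candidates missing from the LD panel are dropped with a
#' warning (they cannot be shown independent).
#'
#' @param candidates a [sumstats()] object (typically [filter_candidates()]
#'   output).
#' @param panel a [geno_panel()] LD reference.
#' @param params a [clump_params()].
#' @param rank_pvals optional named numeric vector of p-values (id -> p) that
#'   overrides the candidates' own p-values for ranking (used for the pooled
#'   multivariable selection).
#' @return An object of class `instrument_set`: list with `exposures`, `ids`
#'   (index variants, in selection order), and `provenance` (one row per
#'   candidate: id, role `"index"` or `"removed"`, and the claiming index).
#' @export
greedy_clump <- function(candidates, panel, params = clump_params(),
                         rank_pvals = NULL) {
  stopifnot(inherits(candidates, "gwas_sumstats"), inherits(panel, "geno_panel"))
  rec <- candidates$records
  in_panel <- rec$variant_id %in% panel$variants$variant_id
  if (!all(in_panel)) {
    warning(sprintf("dropped %d candidate(s) missing from the LD panel",
                    sum(!in_panel)), call. = FALSE)
    rec <- rec[in_panel, , drop = FALSE]
  }
  if (nrow(rec) == 0) stop("no clumpable candidates (none present in panel)", call. = FALSE)
  p_rank <- rec$pval
  if (!is.null(rank_pvals)) {
    stopifnot(!is.null(names(rank_pvals)))
    p_rank <- unname(rank_pvals[rec$variant_id])
    if (anyNA(p_rank)) {
      warning(sprintf("dropped %d candidate(s) without a ranking p-value",
                      sum(is.na(p_rank))), call. = FALSE)
      rec <- rec[!is.na(p_rank), , drop = FALSE]
      p_rank <- p_rank[!is.na(p_rank)]
      if (nrow(rec) == 0) stop("no clumpable candidates remain", call. = FALSE)
    }
  }
  chrom_num <- suppressWarnings(as.integer(rec$chrom))
  ord <- order(p_rank, chrom_num, rec$chrom, rec$pos, rec$variant_id,
               method = "radix")
  rec <- rec[ord, , drop = FALSE]
  p_rank <- p_rank[ord]
  n_cand <- nrow(rec)
  status <- rep(NA_character_, n_cand)   # "index" / "removed"
  claimed_by <- rep(NA_character_, n_cand)
  G <- panel$G[, rec$variant_id, drop = FALSE]
  storage.mode(G) <- "double"
  for (i in seq_len(n_cand)) {
    if (!is.na(status[i])) next
    status[i] <- "index"
    near <- which(is.na(status) & rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= params$window_bp)
    if (length(near) > 0) {
      r <- suppressWarnings(
        cor(G[, i], G[, near, drop = FALSE], use = "pairwise.complete.obs"))
      r2 <- as.vector(r)^2
      hit <- near[!is.na(r2) & r2 >= params$r2_max]
      status[hit] <- "removed"
      claimed_by[hit] <- rec$variant_id[i]
    }
  }
  keep <- status == "index"
  structure(list(exposures = candidates$trait_name,
                 ids = rec$variant_id[keep],
                 provenance = data.frame(variant_id = rec$variant_id,
                                         chrom = rec$chrom, pos = rec$pos,
                                         rank_pval = p_rank, role = status,
                                         claimed_by = claimed_by,
                                         stringsAsFactors = FALSE)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d index variants (%d candidates clumped away)\n",
              paste(x$exposures, collapse = " + "), length(x$ids),
              sum(x$provenance$role == "removed")))
  invisible(x)
}

#' Pooled instrument selection for multivariable MR
#'
#' Pools variants reaching genome-wide significance for either exposure
#' (each also passing the MAF and outcome-availability filters and present in
#' both exposure datasets), then clumps the pooled list ranked by the p-values
#' of the designated ranking exposure -- the convention used when one
#' exposure's GWAS is disproportionately large. Pool variants lacking a
#' ranking p-value are dropped and counted.
#'
#' @param exposure1,exposure2 [sumstats()] objects; `exposure1` is the
#'   orientation anchor downstream.
#' @param panel a [geno_panel()] LD reference.
#' @param params a [clump_params()].
#' @param outcome_ids variant ids available in the outcome dataset.
#' @param ranking_exposure trait name of the exposure whose p-values rank the
#'   pooled clumping (default: exposure1's).
#' @return An `instrument_set` whose provenance records which exposure(s)
#'   qualified each pooled variant.
#' @export
select_mvmr_instruments <- function(exposure1, exposure2, panel,
                                    params = clump_params(), outcome_ids = NULL,
                                    ranking_exposure = exposure1$trait_name) {
  stopifnot(inherits(exposure1, "gwas_sumstats"), inherits(exposure2, "gwas_sumstats"))
  traits <- c(exposure1$trait_name, exposure2$trait_name)
  if (!ranking_exposure %in% traits) {
    stop("ranking_exposure must name one of the two exposures", call. = FALSE)
  }
  sig <- lapply(list(exposure1, exposure2), function(tb) {
    tryCatch(filter_candidates(tb, params, outcome_ids)$records$variant_id,
             error = function(e) character(0))
  })
  pooled <- union(sig[[1]], sig[[2]])
  if (length(pooled) == 0) {
    stop("no instruments: no variant reaches significance for either exposure",
         call. = FALSE)
  }
  in_both <- pooled %in% exposure1$records$variant_id &
    pooled %in% exposure2$records$variant_id
  if (!all(in_both)) {
    warning(sprintf("dropped %d pooled variant(s) absent from one exposure dataset",
                    sum(!in_both)), call. = FALSE)
    pooled <- pooled[in_both]
  }
  ranking_tab <- if (ranking_exposure == exposure1$trait_name) exposure1 else exposure2
  rank_pvals <- setNames(ranking_tab$records$pval, ranking_tab$records$variant_id)
  cand <- exposure1
  cand$records <- exposure1$records[match(pooled, exposure1$records$variant_id), ,
                                    drop = FALSE]
  cand$trait_name <- paste(traits, collapse = "+")
  inst <- greedy_clump(cand, panel, params, rank_pvals = rank_pvals)
  inst$exposures <- traits
  inst$provenance$qualified_exposure1 <- inst$provenance$variant_id %in% sig[[1]]
  inst$provenance$qualified_exposure2 <- inst$provenance$variant_id %in% sig[[2]]
  inst
}
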