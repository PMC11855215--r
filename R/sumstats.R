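#' @importFrom stats cor pnorm qnorm rbinom rnorm runif sd setNames var complete.cases plogis
#' @importFrom utils head modifyList
NULL

# canonical column order for summary-statistics tables
SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n", "n_cases", "n_controls")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics table
#'
#' Bundles per-variant association records with trait metadata. Records are
#' validated against the invariants of the internal schema; offending rows are
#' dropped with a warning rather than raising an error, mirroring how
#' practitioners treat malformed rows in published summary files.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, and
#'   optionally `n_cases`, `n_controls`.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`. Binary traits carry
#'   log-odds betas.
#' @param sd_unit optional trait standard deviation in natural units (e.g. kg),
#'   recorded as metadata only.
#' @param validate logical; run row validation (default `TRUE`).
#'
#' @return An object of class `gwas_sumstats`: a list with elements
#'   `trait_name`, `trait_type`, `sd_unit` and `records`.
#' @export
sumstats <- function(records, trait_name, trait_type = c("continuous", "binary"),
                     sd_unit = NA_real_, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("n_cases", "n_controls")) {
    if (!col %in% names(records)) records[[col]] <- rep(NA_integer_, nrow(records))
  }
  mandatory <- setdiff(SUMSTATS_COLS, c("n_cases", "n_controls"))
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols) > 0) {
    stop("summary-statistics table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, SUMSTATS_COLS]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) records[[col]] <- as.numeric(records[[col]])
  for (col in c("n", "n_cases", "n_controls")) records[[col]] <- as.integer(records[[col]])
  if (validate) records <- validate_sumstats_records(records)
  if (anyDuplicated(records$variant_id)) {
    stop("duplicate variant_id in summary-statistics table", call. = FALSE)
  }
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 sd_unit = sd_unit, records = records),
            class = "gwas_sumstats")
}

# Drop rows violating record invariants; warn with counts. A beta/se vs pval
# inconsistency (two-sided normal approximation, off by more than a factor of
# 2) only triggers a warning: published files routinely carry more precise
# p-values than beta/se imply.
validate_sumstats_records <- function(records) {
  bad <- rep(FALSE, nrow(records))
  reasons <- character(0)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    if (any(cond & !bad)) reasons <<- c(reasons, sprintf("%s (%d)", why, sum(cond & !bad)))
    bad <<- bad | cond
  }
  flag(!(records$se > 0), "se <= 0")
  flag(!(records$eaf > 0 & records$eaf < 1), "eaf outside (0,1)")
  flag(!(records$pval > 0 & records$pval <= 1), "pval outside (0,1]")
  flag(records$effect_allele == records$other_allele, "identical alleles")
  flag(!(records$effect_allele %in% VALID_ALLELES &
           records$other_allele %in% VALID_ALLELES), "non-ACGT allele")
  flag(!is.finite(records$beta), "non-finite beta")
  if (any(bad)) {
    warning(sprintf("dropped %d invalid record(s): %s", sum(bad),
                    paste(reasons, collapse = "; ")), call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no valid records remain after validation", call. = FALSE)
  ok <- records$pval > 0 & records$pval < 1 & records$se > 0
  z_p <- abs(records$beta[ok] / records$se[ok])
  z_q <- qnorm(pmax(records$pval[ok] / 2, .Machine$double.xmin), lower.tail = FALSE)
  inconsistent <- is.finite(z_q) & z_q > 0 & (z_p / z_q > 2 | z_q / z_p > 2)
  if (any(inconsistent, na.rm = TRUE)) {
    warning(sprintf("%d record(s) have p-values inconsistent with |beta/se| beyond a factor of 2 (kept as given)",
                    sum(inconsistent, na.rm = TRUE)), call. = FALSE)
  }
  rownames(records) <- NULL
  records
}

#' @export
print.gwas_sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s)\n", x$trait_name, x$trait_type))
  if (!is.na(x$sd_unit)) cat(sprintf("  trait SD: %g natural units\n", x$sd_unit))
  cat(sprintf("  %d variants\n", nrow(x$records)))
  invisible(x)
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' @param path file path to a tab-delimited file with a header row.
#' @param trait_name,trait_type,sd_unit trait metadata, as in [sumstats()].
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(variant_id = "SNP", pval = "P")`.
#'   Unmapped canonical names are looked up verbatim.
#' @return A [sumstats()] object. Rows failing validation are dropped with a
#'   warning giving counts per reason.
#' @export
read_sumstats <- function(path, trait_name = basename(path),
                          trait_type = c("continuous", "binary"),
                          sd_unit = NA_real_, dialect = NULL) {
  trait_type <- match.arg(trait_type)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(dt)) {
        stop(sprintf("format error: mapped column '%s' (for '%s') not found in %s",
                     src, canon, path), call. = FALSE)
      }
      names(dt)[names(dt) == src] <- canon
    }
  }
  mandatory <- setdiff(SUMSTATS_COLS, c("n_cases", "n_controls"))
  missing_cols <- setdiff(mandatory, names(dt))
  if (length(missing_cols) > 0) {
    stop(sprintf("format error: missing mandatory column(s) %s in %s",
                 paste(missing_cols, collapse = ", "), path), call. = FALSE)
  }
  sumstats(dt, trait_name = trait_name, trait_type = trait_type, sd_unit = sd_unit)
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Output uses the canonical column order and a deterministic row order
#' (chrom, pos, variant_id), so two writes of the same table are
#' byte-identical. Missing optional fields are written as `NA`.
#'
#' @param x a [sumstats()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "gwas_sumstats"))
  rec <- x$records
  ord <- order(suppressWarnings(as.integer(rec$chrom)), rec$chrom, rec$pos, rec$variant_id,
               method = "radix")
  rec <- rec[ord, SUMSTATS_COLS]
  data.table::fwrite(rec, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Construct a hard-call genotype reference panel
#'
#' @param G integer matrix of allele dosages in \{0, 1, 2\} (`NA` for missing
#'   calls), samples in rows, variants in columns.
#' @param variant_id,chrom,pos,effect_allele,other_allele per-variant metadata;
#'   `effect_allele` is the counted allele of the dosage.
#' @param validate check that dosages lie in \{0,1,2\} (skipped by the
#'   internal simulator, which guarantees it by construction).
#' @return An object of class `geno_panel`.
#' @export
geno_panel <- function(G, variant_id, chrom, pos, effect_allele, other_allele,
                       validate = TRUE) {
  G <- as.matrix(G)
  m <- ncol(G)
  stopifnot(length(variant_id) == m, length(chrom) == m, length(pos) == m,
            length(effect_allele) == m, length(other_allele) == m)
  if (anyDuplicated(variant_id)) stop("duplicate variant_id in panel", call. = FALSE)
  if (validate) {
    rng <- range(G, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("genotype dosages must lie in {0,1,2}", call. = FALSE)
  }
  colnames(G) <- variant_id
  structure(list(G = G,
                 variants = data.frame(variant_id = as.character(variant_id),
                                       chrom = as.character(chrom),
                                       pos = as.integer(pos),
                                       effect_allele = toupper(effect_allele),
                                       other_allele = toupper(other_allele),
                                       call_rate = colMeans(!is.na(G)),
                                       stringsAsFactors = FALSE)),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d samples x %d variants (mean call rate %.3f)\n",
              nrow(x$G), ncol(x$G), mean(x$variants$call_rate)))
  invisible(x)
}

#' Read a genotype panel from a tab-delimited matrix file
#'
#' Expects metadata columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele` followed by one column per sample holding \{0, 1, 2, NA\};
#' variants in rows.
#'
#' @param path file path.
#' @return A [geno_panel()] object.
#' @export
read_panel <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  meta_cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  missing_cols <- setdiff(meta_cols, names(dt))
  if (length(missing_cols) > 0) {
    stop("format error: panel file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  G <- t(as.matrix(dt[, setdiff(names(dt), meta_cols), drop = FALSE]))
  storage.mode(G) <- "integer"
  geno_panel(G, dt$variant_id, dt$chrom, dt$pos, dt$effect_allele, dt$other_allele)
}

#' Write a genotype panel to a tab-delimited matrix file
#'
#' @param panel a [geno_panel()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "geno_panel"))
  out <- cbind(panel$variants[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele")],
               as.data.frame(t(panel$G)))
  names(out) <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                  paste0("S", seq_len(nrow(panel$G))))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Pairwise linkage disequilibrium (r-squared) from a genotype panel
#'
#' Squared Pearson correlation between allele dosages, computed over samples
#' complete for each variant pair (no imputation).
#'
#' @param panel a [geno_panel()] object.
#' @param ids variant ids to include; all must be present in the panel.
#' @return An object of class `ld_matrix`: list with `ids` and the symmetric
#'   unit-diagonal matrix `r2`.
#' @export
ld_r2 <- function(panel, ids) {
  stopifnot(inherits(panel, "geno_panel"))
  missing_ids <- setdiff(ids, panel$variants$variant_id)
  if (length(missing_ids) > 0) {
    stop("variant(s) not in panel: ", paste(head(missing_ids, 5), collapse = ", "),
         call. = FALSE)
  }
  G <- panel$G[, ids, drop = FALSE]
  v <- apply(G, 2, stats::var, na.rm = TRUE)
  if (any(!is.finite(v) | v == 0)) {
    stop("monomorphic variant(s) in LD computation: ",
         paste(ids[!is.finite(v) | v == 0], collapse = ", "), call. = FALSE)
  }
  r2 <- suppressWarnings(cor(G, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)
  structure(list(ids = ids, r2 = r2), class = "ld_matrix")
}

#' Write / read an LD matrix cache
#'
#' Tab-delimited square matrix with an id header column.
#' @param ld an `ld_matrix` object.
#' @param path file path.
#' @return `path` (write) or an `ld_matrix` (read).
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  out <- data.frame(variant_id = ld$ids, ld$r2, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(dt$variant_id)
  r2 <- as.matrix(dt[, -1, drop = FALSE])
  dimnames(r2) <- list(ids, ids)
  structure(list(ids = ids, r2 = r2), class = "ld_matrix")
}
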