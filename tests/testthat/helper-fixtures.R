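# Shared fixtures: toy summary-statistics builders, small deterministic
# genotype panels, and compact generative models for fast simulation tests.

toy_records <- function(n = 3, variant_id = paste0("rs", seq_len(n)),
                        chrom = "1", pos = seq_len(n) * 1000L,
                        effect_allele = "A", other_allele = "G",
                        eaf = 0.3, beta = 0.1, se = 0.02, pval = NULL,
                        n_samples = 10000) {
  rec <- data.frame(variant_id = variant_id, chrom = rep_len(chrom, n),
                    pos = rep_len(pos, n),
                    effect_allele = rep_len(effect_allele, n),
                    other_allele = rep_len(other_allele, n),
                    eaf = rep_len(eaf, n), beta = rep_len(beta, n),
                    se = rep_len(se, n), pval = rep_len(NA_real_, n),
                    n = rep_len(n_samples, n), stringsAsFactors = FALSE)
  rec$pval <- if (is.null(pval)) 2 * pnorm(-abs(rec$beta / rec$se)) else pval
  rec
}

toy_sumstats <- function(..., trait_name = "toy", trait_type = "continuous") {
  # toy p-values are set freely, so silence the beta/se consistency warning
  suppressWarnings(sumstats(toy_records(...), trait_name = trait_name,
                            trait_type = trait_type))
}

# panel whose dosage columns are supplied explicitly
manual_panel <- function(G, chrom = "1", pos = seq_len(ncol(G)) * 1000L,
                         effect_allele = "A", other_allele = "G") {
  m <- ncol(G)
  geno_panel(G, variant_id = paste0("rs", seq_len(m)),
             chrom = rep_len(chrom, m), pos = pos,
             effect_allele = rep_len(effect_allele, m),
             other_allele = rep_len(other_allele, m))
}

# eight-sample panel with mutually uncorrelated (exactly orthogonal) dosages
orthogonal_panel <- function() {
  G <- cbind(rep(c(0L, 2L), 4),
             rep(c(0L, 0L, 2L, 2L), 2),
             c(rep(0L, 4), rep(2L, 4)),
             c(0L, 2L, 2L, 0L, 2L, 0L, 0L, 2L))
  manual_panel(G)
}

# small unlinked model for fast phenotype/scan tests
flat_model <- function(m = 10, maf = 0.3, ...) {
  true_model(maf = rep(maf, m), rho = 0, block_size = 1, ...)
}

# reference LD panel shared by simulation-heavy tests (fixed resource)
ref_panel_cache <- new.env(parent = emptyenv())
ref_panel <- function(model, n = 1000, key = "default") {
  if (is.null(ref_panel_cache[[key]])) {
    ref_panel_cache[[key]] <- simulate_genotypes(model, n, seed = 990001)
  }
  ref_panel_cache[[key]]
}

expect_row_equal <- function(rec, expected, fields = names(expected)) {
  for (f in fields) expect_equal(rec[[f]], expected[[f]], tolerance = 1e-12)
}
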