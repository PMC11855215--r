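# End-to-end orchestration of the four analysis arms over a synthetic (or
# user-supplied) study set: univariable MR per exposure-outcome pair, MVMR of
# lean mass + each height dataset, and the covariate-adjustment comparison.

#' Declare an end-to-end analysis plan
#'
#' A plan either references a synthetic scenario (a [true_model()] plus
#' [sim_config()]) or a roster of user-supplied summary-statistics files for
#' the study roles (`tlm`, `height_05m`, `height_15m`, `ad`, `cognition`,
#' `tlm_covariate`, `tlm_residual`) plus a genotype panel file.
#'
#' @param model,config synthetic scenario (ignored when `files` given).
#' @param files optional named list of file paths for the study roles; must
#'   include `panel`.
#' @param arms subset of `c("univariable", "mvmr", "adjusted_gwas")`.
#' @param params a [clump_params()].
#' @param n_boot,second_order estimator settings (weighted-median bootstrap
#'   replicates; second-order Wald SEs).
#' @param seed integer seed governing simulation and bootstrap.
#' @param out_dir optional output directory; when set, [run_analysis()]
#'   writes `results.tsv`, `results.md`, `run.log` and an effective-config
#'   echo there.
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(model = model_confounded(), config = sim_config(),
                          files = NULL,
                          arms = c("univariable", "mvmr", "adjusted_gwas"),
                          params = clump_params(), n_boot = 1000,
                          second_order = FALSE, seed = 1, out_dir = NULL) {
  if (length(arms) == 0) stop("plan must name at least one arm", call. = FALSE)
  arms <- match.arg(arms, several.ok = TRUE)
  if (!is.null(files)) {
    if (!"panel" %in% names(files)) stop("file roster must include 'panel'", call. = FALSE)
    missing_files <- unlist(files)[!file.exists(unlist(files))]
    if (length(missing_files) > 0) {
      stop("file(s) not found: ", paste(missing_files, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(model = model, config = config, files = files, arms = arms,
                 params = params, n_boot = n_boot, second_order = second_order,
                 seed = seed, out_dir = out_dir),
            class = "analysis_plan")
}

load_study_set <- function(plan) {
  if (is.null(plan$files)) {
    return(make_study_set(plan$model, plan$config, seed = plan$seed))
  }
  f <- plan$files
  binary_roles <- "ad"
  tables <- list()
  for (role in setdiff(names(f), "panel")) {
    tables[[role]] <- read_sumstats(f[[role]], trait_name = role,
                                    trait_type = if (role %in% binary_roles) "binary" else "continuous")
  }
  structure(list(tables = tables, panel = read_panel(f$panel),
                 model = NULL, config = NULL, seed = plan$seed),
            class = "mr_study_set")
}

estimate_all <- function(hd, arm, adjustment, n_boot, seed, log) {
  ests <- list(mr_ivw(hd), mr_egger(hd), mr_weighted_median(hd, n_boot = n_boot, seed = seed))
  rows <- lapply(ests, function(e) {
    if (identical(e$outcome_type, "binary")) e <- to_odds_scale(e)
    as.data.frame(e)
  })
  out <- do.call(rbind, rows)
  out <- cbind(arm = arm, adjustment = adjustment, out)
  log(sprintf("[%s] %s -> %s (%s): %d instruments harmonized (%s)",
              arm, out$exposure[1], out$outcome[1], adjustment, nrow(hd),
              paste(sprintf("%s=%d", names(attr(hd, "action_log")),
                            attr(hd, "action_log")), collapse = ", ")))
  out
}

#' Run the univariable MR arm
#'
#' For each exposure-outcome pair: significance/MAF/availability filter, LD
#' clumping, harmonization, then IVW, MR-Egger and weighted-median
#' estimation (with odds-ratio conversion for binary outcomes).
#'
#' @param study an `mr_study_set`.
#' @param params a [clump_params()].
#' @param exposures,outcomes role names within `study$tables`.
#' @param n_boot,seed weighted-median bootstrap settings.
#' @param log logging callback (`function(msg)`).
#' @return A `data.frame` of class `mr_results`.
#' @export
run_univariable_analysis <- function(study, params = clump_params(),
                                     exposures = c("tlm", "height_05m", "height_15m"),
                                     outcomes = c("ad", "cognition"),
                                     n_boot = 1000, seed = 1,
                                     log = function(msg) message(msg)) {
  res <- list()
  for (ex in exposures) {
    for (ou in outcomes) {
      rows <- with_stage(sprintf("univariable %s->%s", ex, ou), {
        cand <- filter_candidates(study$tables[[ex]], params,
                                  outcome_ids = study$tables[[ou]]$records$variant_id)
        inst <- greedy_clump(cand, study$panel, params)
        hd <- harmonize_univariable(study$tables[[ex]], study$tables[[ou]], inst)
        estimate_all(hd, "univariable", "none", n_boot, seed, log)
      })
      res[[paste(ex, ou)]] <- rows
    }
  }
  finish_results(do.call(rbind, res))
}

#' Run the multivariable MR arm
#'
#' Pools genome-wide significant variants for lean mass and each height
#' dataset, clumps ranked by the lean-mass p-values, harmonizes all three
#' datasets, and fits the regression-based MVMR model with conditional
#' F-statistics (flagged when below 10).
#'
#' @inheritParams run_univariable_analysis
#' @param exposure1 primary exposure role (orientation anchor and ranking
#'   exposure).
#' @param exposure2s height dataset roles to adjust for, one MVMR fit each.
#' @return A `data.frame` of class `mr_results`.
#' @export
run_mvmr_analysis <- function(study, params = clump_params(),
                              exposure1 = "tlm",
                              exposure2s = c("height_05m", "height_15m"),
                              outcomes = c("ad", "cognition"),
                              log = function(msg) message(msg)) {
  res <- list()
  for (ex2 in exposure2s) {
    for (ou in outcomes) {
      rows <- with_stage(sprintf("mvmr %s+%s->%s", exposure1, ex2, ou), {
        inst <- select_mvmr_instruments(
          study$tables[[exposure1]], study$tables[[ex2]], study$panel, params,
          outcome_ids = study$tables[[ou]]$records$variant_id,
          ranking_exposure = study$tables[[exposure1]]$trait_name)
        hd <- harmonize_multivariable(study$tables[[exposure1]],
                                      study$tables[[ex2]],
                                      study$tables[[ou]], inst)
        est <- mvmr_regression(hd)
        if (identical(est$outcome_type, "binary")) est <- to_odds_scale(est)
        weak <- est$conditional_F < 10
        if (any(weak)) {
          log(sprintf("[mvmr] WARNING: conditional F < 10 for %s (%s): potential weak-instrument bias",
                      paste(est$exposures[weak], collapse = ", "),
                      paste(sprintf("%.1f", est$conditional_F[weak]), collapse = ", ")))
        }
        out <- cbind(arm = "mvmr", adjustment = paste0("mvmr_", ex2),
                     as.data.frame(est))
        log(sprintf("[mvmr] %s + %s -> %s: %d instruments, conditional F = %s",
                    exposure1, ex2, ou, est$n_snps,
                    paste(sprintf("%.1f", est$conditional_F), collapse = "/")))
        out
      })
      res[[paste(ex2, ou)]] <- rows
    }
  }
  finish_results(do.call(rbind, res))
}

#' Run the covariate-adjustment comparison arm
#'
#' Runs univariable MR for the lean-mass exposure three ways -- unadjusted,
#' height-as-covariate, and residualized-on-height -- against each outcome,
#' each with its own instrument selection, producing the side-by-side
#' comparison that exposes collider bias from heritable-covariate
#' adjustment.
#'
#' @inheritParams run_univariable_analysis
#' @param roles named character vector mapping adjustment labels to table
#'   roles.
#' @return A `data.frame` of class `mr_results`.
#' @export
run_adjustment_comparison <- function(study, params = clump_params(),
                                      roles = c(none = "tlm",
                                                covariate = "tlm_covariate",
                                                residual = "tlm_residual"),
                                      outcomes = c("ad", "cognition"),
                                      n_boot = 1000, seed = 1,
                                      log = function(msg) message(msg)) {
  res <- list()
  for (adj in names(roles)) {
    for (ou in outcomes) {
      rows <- with_stage(sprintf("adjusted_gwas %s->%s", roles[[adj]], ou), {
        cand <- filter_candidates(study$tables[[roles[[adj]]]], params,
                                  outcome_ids = study$tables[[ou]]$records$variant_id)
        inst <- greedy_clump(cand, study$panel, params)
        hd <- harmonize_univariable(study$tables[[roles[[adj]]]],
                                    study$tables[[ou]], inst)
        estimate_all(hd, "adjusted_gwas", adj, n_boot, seed, log)
      })
      res[[paste(adj, ou)]] <- rows
    }
  }
  finish_results(do.call(rbind, res))
}

with_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

finish_results <- function(df) {
  ord <- order(df$arm, df$exposure, df$outcome, df$adjustment, df$method,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mr_results", "data.frame")
  df
}

#' Run a full analysis plan
#'
#' Simulates (or loads) the study set, runs the requested arms, and
#' optionally writes `results.tsv`, `results.md`, `run.log`, and an echo of
#' the effective configuration to `plan$out_dir`. Reruns with an identical
#' plan and seed produce identical results.
#'
#' @param plan an [analysis_plan()].
#' @return A `data.frame` of class `mr_results` with attribute `log`.
#' @export
run_analysis <- function(plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(sprintf("seed = %d; arms = %s", plan$seed, paste(plan$arms, collapse = ", ")))
  log(sprintf("clump: p < %g, MAF > %g, window +/-%g bp, r2 < %g",
              plan$params$p_threshold, plan$params$maf_min,
              plan$params$window_bp, plan$params$r2_max))
  study <- load_study_set(plan)
  res <- list()
  if ("univariable" %in% plan$arms) {
    res$univariable <- run_univariable_analysis(study, plan$params,
                                                n_boot = plan$n_boot,
                                                seed = plan$seed, log = log)
  }
  if ("mvmr" %in% plan$arms) {
    res$mvmr <- run_mvmr_analysis(study, plan$params, log = log)
  }
  if ("adjusted_gwas" %in% plan$arms) {
    res$adjusted <- run_adjustment_comparison(study, plan$params,
                                              n_boot = plan$n_boot,
                                              seed = plan$seed, log = log)
  }
  out <- finish_results(do.call(rbind, res))
  attr(out, "log") <- log_lines
  if (!is.null(plan$out_dir)) {
    dir.create(plan$out_dir, showWarnings = FALSE, recursive = TRUE)
    render_results_table(out, file.path(plan$out_dir, "results.tsv"), "tsv")
    render_results_table(out, file.path(plan$out_dir, "results.md"), "markdown")
    writeLines(log_lines, file.path(plan$out_dir, "run.log"))
    echo_config(plan, file.path(plan$out_dir, "config.txt"))
  }
  out
}

echo_config <- function(plan, path) {
  cfg <- c(sprintf("seed: %d", plan$seed),
           sprintf("arms: %s", paste(plan$arms, collapse = ", ")),
           sprintf("p_threshold: %g", plan$params$p_threshold),
           sprintf("maf_min: %g", plan$params$maf_min),
           sprintf("window_bp: %g", plan$params$window_bp),
           sprintf("r2_max: %g", plan$params$r2_max),
           sprintf("n_boot: %d", plan$n_boot))
  if (is.null(plan$files)) {
    cfg <- c(cfg,
             sprintf("n_exposure: %d", plan$config$n_exposure),
             sprintf("n_height_extra: %d", plan$config$n_height_extra),
             sprintf("n_outcome: %d", plan$config$n_outcome),
             sprintf("n_adjusted: %d", plan$config$n_adjusted),
             sprintf("n_ref: %d", plan$config$n_ref),
             sprintf("standardize: %s", plan$config$standardize),
             sprintf("m_variants: %d", plan$model$m))
  } else {
    cfg <- c(cfg, paste0(names(plan$files), ": ", unlist(plan$files)))
  }
  writeLines(cfg, path)
}

#' Render a results table to TSV or markdown
#'
#' The TSV retains full numeric precision; the markdown rendering formats to
#' three significant figures. Rows are ordered deterministically by (arm,
#' exposure, outcome, adjustment, method).
#'
#' @param results an `mr_results` data.frame.
#' @param path output file path.
#' @param fmt `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_results_table <- function(results, path, fmt = c("tsv", "markdown")) {
  fmt <- match.arg(fmt)
  if (nrow(results) == 0) stop("empty results table", call. = FALSE)
  results <- finish_results(as.data.frame(results))
  if (fmt == "tsv") {
    data.table::fwrite(results, path, sep = "\t", quote = FALSE, na = "NA")
  } else {
    num <- vapply(results, is.numeric, logical(1))
    disp <- results
    disp[num] <- lapply(results[num], function(x) ifelse(is.na(x), "", signif(x, 3)))
    header <- paste0("| ", paste(names(disp), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(disp)), collapse = "|"), "|")
    body <- apply(disp, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  invisible(path)
}
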