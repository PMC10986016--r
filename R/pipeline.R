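# Orchestration of the full two-step study workflow:
# total effect -> mediator effects -> MVMR -> mediation -> diagnostics -> BH.

#' Study configuration
#'
#' Tables may be given as [summary_stat_table()] objects or file paths
#' (read with [read_summary_stats()]).
#'
#' @param exposure Exposure summary statistics (table or path).
#' @param outcomes Named list of outcome tables/paths (primary outcome
#'   first; secondary outcomes after).
#' @param mediators Named list of mediator tables/paths (may be empty).
#' @param ld Optional [ld_matrix()] shared by all traits.
#' @param p_threshold Instrument significance threshold (default 5e-8).
#' @param clump_r2,clump_window_kb LD-clumping parameters (defaults 0.001
#'   and 10000).
#' @param f_min Weak-instrument flag threshold (default 10).
#' @param palindromic_eaf_limit Harmonization frequency limit (default 0.42).
#' @param ivw_model `"random"` or `"fixed"`.
#' @param methods Univariable estimator subset (see [mr_all()]).
#' @param n_boot,bandwidth_factor Bootstrap/mode settings.
#' @param presso_n_sim,presso_sig MR-PRESSO settings.
#' @param loo_flag_multiplier Leave-one-out influence threshold.
#' @param outlier_removal `"auto"` (re-estimate after PRESSO removal only
#'   when the Egger intercept is significant at 0.05, the default),
#'   `"always"`, or `"never"`.
#' @param bh_scope `"per-outcome"` (default) or `"joint"` adjustment of
#'   mediation p-values.
#' @param seed RNG seed recorded in every output.
#' @return A `study_config`.
#' @export
study_config <- function(exposure, outcomes, mediators = list(), ld = NULL,
                         p_threshold = 5e-8, clump_r2 = 0.001,
                         clump_window_kb = 10000, f_min = 10,
                         palindromic_eaf_limit = 0.42,
                         ivw_model = "random",
                         methods = c("IVW", "Egger", "weighted-median",
                                     "simple-mode", "weighted-mode", "RAPS"),
                         n_boot = 1000, bandwidth_factor = 1,
                         presso_n_sim = 1000, presso_sig = 0.05,
                         loo_flag_multiplier = 2,
                         outlier_removal = c("auto", "always", "never"),
                         bh_scope = c("per-outcome", "joint"),
                         seed = 42) {
  outlier_removal <- match.arg(outlier_removal)
  bh_scope <- match.arg(bh_scope)
  if (inherits(outcomes, "summary_stat_table") || is.character(outcomes)) {
    outcomes <- list(outcome = outcomes)
  }
  if (inherits(mediators, "summary_stat_table") || is.character(mediators)) {
    mediators <- list(mediator = mediators)
  }
  if (length(outcomes) > 0 && is.null(names(outcomes))) {
    names(outcomes) <- paste0("outcome", seq_along(outcomes))
  }
  if (length(mediators) > 0 && is.null(names(mediators))) {
    names(mediators) <- paste0("mediator", seq_along(mediators))
  }
  structure(as.list(environment()), class = "study_config")
}

load_table <- function(x, label) {
  if (inherits(x, "summary_stat_table")) return(x)
  if (is.character(x)) return(read_summary_stats(x, trait_label = label))
  ts_error("twostepmr_parameter_error",
           sprintf("%s must be a summary_stat_table or a file path", label))
}

relabel <- function(tab, label) {
  attr(tab, "trait_label") <- label
  tab
}

# Select genome-wide significant, LD-independent instruments for a trait.
select_instruments <- function(tab, cfg) {
  sel <- select_by_pvalue(tab, cfg$p_threshold)
  ld_clump(sel, cfg$ld, cfg$clump_r2, cfg$clump_window_kb)
}

stage <- function(report, name, pair, expr) {
  tryCatch(expr, error = function(e) {
    ts_error("twostepmr_stage_error",
             sprintf("stage '%s' failed for %s: %s", name, pair,
                     conditionMessage(e)),
             stage = name, pair = pair, parent = e)
  })
}

# One exposure -> outcome univariable analysis with diagnostics and the
# optional automatic PRESSO outlier-removal pass.
analyze_pair <- function(exposure_inst, outcome_tab, cfg, pair_label) {
  h <- stage(NULL, "harmonize", pair_label,
             harmonize(exposure_inst, outcome_tab,
                       cfg$palindromic_eaf_limit))
  k <- n_snps(h)
  if (k < 2) {
    ts_error("twostepmr_data_error",
             sprintf("%s: only %d SNP(s) after harmonization", pair_label, k))
  }
  estimates <- stage(NULL, "estimators", pair_label,
                     mr_all(h, methods = cfg$methods,
                            ivw_model = cfg$ivw_model, n_boot = cfg$n_boot,
                            bandwidth_factor = cfg$bandwidth_factor,
                            seed = cfg$seed))
  diagnostics <- stage(NULL, "sensitivity", pair_label, {
    dg <- list(cochran_q = cochran_q(h))
    if (k >= 3) {
      dg$rucker_q <- rucker_q(h)
      dg$egger_intercept <- egger_intercept_test(h)
      dg$leave_one_out <- leave_one_out(h, cfg$loo_flag_multiplier,
                                        cfg$ivw_model)
    }
    if (k >= 4) {
      dg$presso <- mr_presso(h, cfg$presso_n_sim, cfg$presso_sig, cfg$seed)
    }
    dg
  })
  ivw_before <- mr_ivw(h, model = cfg$ivw_model)
  removed <- character(0)
  egger_sig <- !is.null(diagnostics$egger_intercept) &&
    diagnostics$egger_intercept$pvalue < 0.05
  do_removal <- cfg$outlier_removal == "always" ||
    (cfg$outlier_removal == "auto" && egger_sig)
  h_final <- h
  post <- NULL
  if (do_removal && !is.null(diagnostics$presso) &&
      nrow(diagnostics$presso$outlier_snps) > 0) {
    removed <- diagnostics$presso$outlier_snps$SNP
    keep <- !(h$snp_id %in% removed)
    h_final <- harmonized_set(
      h$snp_id[keep], h$traits,
      h$beta[keep, , drop = FALSE], h$se[keep, , drop = FALSE],
      eaf = h$eaf[keep, , drop = FALSE], p = h$p[keep, , drop = FALSE],
      n = h$n[keep, , drop = FALSE],
      chrom = h$chrom[keep], pos = h$pos[keep])
    post <- list(ivw = mr_ivw(h_final, model = cfg$ivw_model),
                 egger_intercept = if (n_snps(h_final) >= 3)
                   egger_intercept_test(h_final) else NULL)
  }
  list(harmonized = h, harmonized_final = h_final,
       estimates = estimates, diagnostics = diagnostics,
       ivw_before = ivw_before,
       ivw_final = if (is.null(post)) ivw_before else post$ivw,
       post_removal = post, removed_snps = removed,
       snp_counts = c(harmonized = k, final = n_snps(h_final)))
}

#' Run the full two-step MR mediation workflow
#'
#' Per outcome: (1) instrument selection (significance filter, LD clump,
#' strength metrics), harmonization, total-effect estimation (`beta0`)
#' with the full estimator suite and all diagnostics; when the Egger
#' intercept signals pleiotropy (and `outlier_removal = "auto"`), an
#' MR-PRESSO outlier-removal pass re-estimates the total effect and
#' re-tests the intercept. (2) Per mediator: exposure -> mediator
#' estimation (`beta1`), multivariable MR on the union of exposure and
#' mediator instruments for the mediator's direct effect (`beta2`), and
#' the product-of-coefficients mediation decomposition. (3)
#' Benjamini-Hochberg adjustment of the mediation p-values.
#'
#' @param cfg [study_config()].
#' @return A `study_report`: per-outcome results (instrument summary,
#'   estimates, diagnostics, before/after-removal totals, per-mediator
#'   MVMR and mediation rows with `pvalue_bh`) plus a provenance block
#'   (seed, parameters, package version).
#' @export
run_two_step <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  exposure <- load_table(cfg$exposure, "exposure")
  outcome_tabs <- lapply(names(cfg$outcomes) %||% seq_along(cfg$outcomes),
                         function(nm) relabel(load_table(cfg$outcomes[[nm]], nm), nm))
  names(outcome_tabs) <- names(cfg$outcomes)
  mediator_tabs <- lapply(names(cfg$mediators) %||% character(0),
                          function(nm) relabel(load_table(cfg$mediators[[nm]], nm), nm))
  names(mediator_tabs) <- names(cfg$mediators)

  exposure_inst <- select_instruments(exposure, cfg)
  inst_summary <- instrument_strength(exposure_inst, cfg$f_min)
  mediator_inst <- lapply(mediator_tabs, select_instruments, cfg = cfg)

  outcomes <- list()
  for (out_nm in names(outcome_tabs)) {
    out_tab <- outcome_tabs[[out_nm]]
    total <- analyze_pair(exposure_inst, out_tab, cfg,
                          paste("exposure ->", out_nm))
    beta0 <- total$ivw_final
    mediation_rows <- NULL
    mvmr_fits <- list()
    for (med_nm in names(mediator_tabs)) {
      med_tab <- mediator_tabs[[med_nm]]
      pair <- sprintf("exposure -> %s -> %s", med_nm, out_nm)
      h1 <- stage(NULL, "beta1-harmonize", pair,
                  harmonize(exposure_inst, med_tab,
                            cfg$palindromic_eaf_limit))
      beta1 <- stage(NULL, "beta1-ivw", pair,
                     mr_ivw(h1, model = cfg$ivw_model))
      union_ids <- union(exposure_inst$SNP, mediator_inst[[med_nm]]$SNP)
      sub <- function(tab) {
        s <- tab[tab$SNP %in% union_ids, , drop = FALSE]
        rownames(s) <- NULL
        structure(s, trait_label = trait_label(tab), class = class(tab))
      }
      h2 <- stage(NULL, "mvmr-harmonize", pair,
                  harmonize(sub(exposure), list(sub(med_tab), sub(out_tab)),
                            cfg$palindromic_eaf_limit))
      fit <- stage(NULL, "mvmr", pair, mvmr_ivw(h2, model = cfg$ivw_model))
      mvmr_fits[[med_nm]] <- fit
      b2 <- fit[fit$exposure == med_nm, ]
      med_row <- mediate(beta1$beta, beta1$se, b2$beta, b2$se,
                         beta0$beta, beta0$se,
                         label = paste(med_nm, "->", out_nm))
      med_row$mediator <- med_nm
      med_row$outcome <- out_nm
      med_row$n_snp_beta1 <- beta1$n_snp
      med_row$n_snp_mvmr <- attr(fit, "n_snp")
      mediation_rows <- rbind(mediation_rows, med_row)
    }
    if (!is.null(mediation_rows) && cfg$bh_scope == "per-outcome") {
      mediation_rows$pvalue_bh <- bh_adjust(mediation_rows$pvalue)
    }
    outcomes[[out_nm]] <- list(
      total = total, beta0 = beta0,
      mvmr = mvmr_fits, mediation = mediation_rows)
  }
  all_med <- do.call(rbind, lapply(outcomes, `[[`, "mediation"))
  if (!is.null(all_med) && cfg$bh_scope == "joint") {
    all_med$pvalue_bh <- bh_adjust(all_med$pvalue)
    i <- 1
    for (out_nm in names(outcomes)) {
      n_i <- nrow(outcomes[[out_nm]]$mediation)
      if (n_i > 0) {
        outcomes[[out_nm]]$mediation$pvalue_bh <-
          all_med$pvalue_bh[i:(i + n_i - 1)]
        i <- i + n_i
      }
    }
  }
  structure(list(
    instruments = inst_summary,
    exposure_instruments = exposure_inst$SNP,
    outcomes = outcomes,
    provenance = list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("twostepmr")),
      parameters = cfg[!(names(cfg) %in%
                           c("exposure", "outcomes", "mediators", "ld"))])),
    class = "study_report")
}

#' Reverse-direction MR screen
#'
#' Swaps roles: each mediator becomes the exposure and the original
#' exposure the outcome, running univariable estimation only (a check
#' that the mediators do not causally affect the exposure).
#'
#' @param cfg [study_config()].
#' @return A `study_report` with one entry per mediator under `outcomes`
#'   (same schema as [run_two_step()], univariable parts only) and
#'   `reverse = TRUE` in provenance.
#' @export
run_reverse_mr <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  exposure <- load_table(cfg$exposure, "exposure")
  mediator_tabs <- lapply(names(cfg$mediators) %||% character(0),
                          function(nm) relabel(load_table(cfg$mediators[[nm]], nm), nm))
  names(mediator_tabs) <- names(cfg$mediators)
  outcomes <- list()
  for (med_nm in names(mediator_tabs)) {
    inst <- select_instruments(mediator_tabs[[med_nm]], cfg)
    res <- analyze_pair(inst, exposure, cfg,
                        paste(med_nm, "-> exposure (reverse)"))
    outcomes[[med_nm]] <- list(total = res, beta0 = res$ivw_final,
                               mvmr = list(), mediation = NULL)
  }
  structure(list(
    instruments = NULL, exposure_instruments = NULL, outcomes = outcomes,
    provenance = list(
      seed = cfg$seed, reverse = TRUE,
      package_version = as.character(utils::packageVersion("twostepmr")),
      parameters = cfg[!(names(cfg) %in%
                           c("exposure", "outcomes", "mediators", "ld"))])),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Two-step MR study report\n")
  if (!is.null(x$instruments)) {
    cat(sprintf("  exposure instruments: K=%d, F=%.1f\n",
                x$instruments$k, x$instruments$f_stat))
  }
  for (nm in names(x$outcomes)) {
    o <- x$outcomes[[nm]]
    cat(sprintf("  [%s] IVW total beta=%.4g (SE %.4g), p=%.3g, %d SNPs\n",
                nm, o$beta0$beta, o$beta0$se, o$beta0$pvalue, o$beta0$n_snp))
    if (!is.null(o$mediation)) {
      for (i in seq_len(nrow(o$mediation))) {
        r <- o$mediation[i, ]
        cat(sprintf("    %s: proportion mediated %.1f%% (%.1f%%, %.1f%%)\n",
                    r$label, 100 * r$proportion, 100 * r$ci_low,
                    100 * r$ci_high))
      }
    }
  }
  invisible(x)
}

#' Write a study report as TSV files plus JSON
#'
#' Emits `estimates.tsv` (all univariable estimates per pair),
#' `diagnostics.tsv` (Q statistics, Egger intercept, PRESSO summary),
#' `mvmr.tsv`, `mediation.tsv` and `report.json` (the full report).
#'
#' @param report `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est <- do.call(rbind, lapply(names(report$outcomes), function(nm) {
    cbind(outcome = nm, report$outcomes[[nm]]$total$estimates)
  }))
  utils::write.table(est, file.path(dir, "estimates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  diag_rows <- do.call(rbind, lapply(names(report$outcomes), function(nm) {
    dg <- report$outcomes[[nm]]$total$diagnostics
    data.frame(
      outcome = nm,
      cochran_q = dg$cochran_q$statistic, cochran_p = dg$cochran_q$pvalue,
      rucker_q = dg$rucker_q$statistic %||% NA_real_,
      rucker_p = dg$rucker_q$pvalue %||% NA_real_,
      egger_intercept = dg$egger_intercept$intercept %||% NA_real_,
      egger_intercept_p = dg$egger_intercept$pvalue %||% NA_real_,
      presso_global_p = dg$presso$global_pvalue %||% NA_real_,
      presso_outliers = if (is.null(dg$presso)) NA_character_
        else paste(dg$presso$outlier_snps$SNP, collapse = ","),
      stringsAsFactors = FALSE)
  }))
  utils::write.table(diag_rows, file.path(dir, "diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mvmr <- do.call(rbind, lapply(names(report$outcomes), function(nm) {
    fits <- report$outcomes[[nm]]$mvmr
    do.call(rbind, lapply(names(fits), function(med) {
      cbind(outcome = nm, mediator = med, as.data.frame(fits[[med]]))
    }))
  }))
  if (!is.null(mvmr)) {
    utils::write.table(mvmr, file.path(dir, "mvmr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  med <- do.call(rbind, lapply(report$outcomes, `[[`, "mediation"))
  if (!is.null(med)) {
    utils::write.table(med, file.path(dir, "mediation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report_to_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

# Plain-list view of a report for JSON serialization (drops the bulky
# harmonized sets; everything else is numbers/tables).
report_to_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "harmonized_set")) return(NULL)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
      return(x[!vapply(x, is.null, TRUE)])
    }
    x
  }
  strip(unclass(report))
}
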