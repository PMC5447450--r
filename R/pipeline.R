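#' End-to-end pipeline orchestration
#'
#' Runs the staged workflow over a cohort: small-variant prioritisation per
#' case, CNV/SV parsing + classification + microarray concordance, the
#' secondary-findings screen, and cohort statistics. Per-stage record counts
#' are logged to standard error so filter behaviour is auditable.
#'
#' @name pipeline
NULL

stage_log <- function(stage, ...) {
  message(sprintf("[wgsdx:%s] %s", stage, sprintf(...)))
}

#' Run the pipeline over an in-memory cohort
#'
#' @param cohort a \code{wgsdx_cohort} (or the list returned by
#'   \code{\link{read_cohort_dir}}).
#' @param cfg a \code{\link{threshold_config}}.
#' @param stages subset of c("prioritize", "cnv", "secondary", "stats");
#'   "stats" requires "prioritize".
#' @return list of class \code{wgsdx_run}: \code{candidates},
#'   \code{rare_damaging} (per-case counts), \code{cnv_classified},
#'   \code{concordance}, \code{breakpoints}, \code{secondary_findings},
#'   \code{diagnoses}, \code{summary}.
#' @export
run_cohort_pipeline <- function(cohort, cfg = threshold_config(),
                                stages = c("prioritize", "cnv", "secondary", "stats")) {
  cfg <- as_thresholds(cfg)
  res <- cohort$resources
  out <- list(stages = stages)
  cases <- cohort$cases

  if ("prioritize" %in% stages) {
    cand_list <- list(); nrd <- integer(nrow(cases))
    for (i in seq_len(nrow(cases))) {
      id <- cases$case_id[i]
      v <- cohort$variants[cohort$variants$case_id == id, , drop = FALSE]
      terms <- strsplit(cases$hpo_terms[i], ",", fixed = TRUE)[[1]]
      pr <- prioritize_case(v, res, case_sex = cases$sex[i],
                            case_terms = terms[nzchar(terms)], cfg = cfg)
      cand_list[[id]] <- pr$candidates
      nrd[i] <- pr$n_rare_damaging
    }
    out$candidates <- do.call(rbind, cand_list)
    rownames(out$candidates) <- NULL
    out$rare_damaging <- data.frame(case_id = cases$case_id, n = nrd,
                                    stringsAsFactors = FALSE)
    stage_log("prioritize", "%d cases, %d variants in, %d candidates out",
              nrow(cases), nrow(cohort$variants), nrow(out$candidates))
  }

  if ("cnv" %in% stages) {
    seg <- parse_read_depth_segments(cohort$cnv_segments, cfg)
    seg <- merge_fragmented_segments(seg, cfg = cfg)
    sv <- parse_sv_events(cohort$sv_events, cfg)
    annotate_all <- function(r) {
      r <- annotate_cnv_frequency(r, res$control_cnvs, res$common_cnv_loci,
                                  cfg = cfg)
      r <- annotate_gene_exon_overlap(r, res$gene_models)
      classify_cnv(r, res$syndromic_regions, res$disease_genes, cfg)
    }
    seg <- annotate_all(seg)
    sv <- annotate_all(sv)
    out$cnv_classified <- seg
    out$sv_classified <- sv
    stage_log("cnv", "%d segment rows -> %d CNVs; %d SV rows -> %d events",
              nrow(cohort$cnv_segments), nrow(seg),
              nrow(cohort$sv_events), nrow(sv))
    if (!is.null(cohort$cma_calls) && nrow(cohort$cma_calls) > 0) {
      cma <- read_cma_calls(cohort$cma_calls)
      n_wgs_samples <- length(unique(seg$case_id))
      n_cma_samples <- length(unique(cma$case_id))
      cma_f <- filter_for_concordance(cma, res$segdup,
                                      datasets = list(seg, cma), cfg = cfg)
      wgs_f <- filter_for_concordance(seg, res$segdup,
                                      datasets = list(seg, cma), cfg = cfg)
      out$concordance <- match_cma_wgs(cma_f, wgs_f, cfg)
      out$breakpoints <- breakpoint_concordance(out$concordance, cfg)
      stage_log("cnv", "concordance: %d/%d CMA calls detected",
                out$concordance$n_detected, out$concordance$n_cma)
    }
  }

  if ("secondary" %in% stages) {
    consent <- stats::setNames(cases$consent_secondary, cases$case_id)
    out$secondary_findings <- screen_secondary(cohort$variants, res$panel,
                                               consent, cfg)
    stage_log("secondary", "%d findings (%d returnable)",
              nrow(out$secondary_findings), sum(out$secondary_findings$returnable))
  }

  if ("stats" %in% stages) {
    if (is.null(out$candidates)) stop("stats stage requires prioritize stage")
    diag_snv <- out$candidates[out$candidates$acmg_class %in%
                                 c("pathogenic", "likely_pathogenic"), , drop = FALSE]
    diagnoses <- if (nrow(diag_snv)) data.frame(
      case_id = diag_snv$case_id, locus_id = diag_snv$gene,
      variant_type = "SNV", moi = diag_snv$moi_model,
      origin = NA_character_, category = NA_integer_,
      stringsAsFactors = FALSE) else
      data.frame(case_id = character(), locus_id = character(),
                 variant_type = character(), moi = character(),
                 origin = character(), category = integer(),
                 stringsAsFactors = FALSE)
    if (!is.null(out$cnv_classified)) {
      pc <- out$cnv_classified[out$cnv_classified$classification %in%
                                 c("pathogenic", "likely_pathogenic"), , drop = FALSE]
      if (nrow(pc))
        diagnoses <- rbind(diagnoses, data.frame(
          case_id = pc$case_id,
          locus_id = sprintf("%s:%d-%d", pc$chrom, pc$start, pc$end),
          variant_type = "CNV", moi = "AD", origin = NA_character_,
          category = NA_integer_, stringsAsFactors = FALSE))
    }
    out$diagnoses <- diagnoses
    n <- nrow(cases)
    yield <- diagnostic_yield(diagnoses, n)
    ci <- binomial_ci(yield$n_diagnosed, n)
    cma_only <- unique(diagnoses$case_id[diagnoses$variant_type == "CNV"])
    cmp <- two_proportion_chisq(yield$n_diagnosed, n, length(cma_only), n)
    sec_ids <- if (is.null(out$secondary_findings)) character() else
      out$secondary_findings$case_id
    comb <- combined_actionable_fraction(diagnoses,
                                         data.frame(case_id = sec_ids),
                                         n)
    out$summary <- list(
      cohort_n = n,
      yield = yield, yield_ci95 = as.list(ci),
      wgs_vs_cma = cmp,
      multi_locus = multi_diagnosis_count(diagnoses, n),
      combined_actionable = comb,
      subgroup = subgroup_yield(cases, diagnoses, res$ontology),
      mean_rare_damaging = if (!is.null(out$rare_damaging))
        mean(out$rare_damaging$n) else NA_real_)
    stage_log("stats", "yield %d/%d (%.1f%%)", yield$n_diagnosed, n,
              100 * yield$proportion)
  }
  structure(out, class = "wgsdx_run")
}

#' Run the pipeline from a configuration (directory in, reports out)
#'
#' Reads the cohort directory named by the config, executes the requested
#' stages, and writes the candidate table (TSV), classified CNVs (TSV),
#' secondary findings (TSV), concordance report (JSON) and cohort summary
#' (JSON) into \code{out_dir}. Identical inputs produce identical outputs.
#'
#' @param config path to a JSON/YAML run config, or an equivalent named list
#'   (see \code{\link{read_run_config}}).
#' @return the \code{wgsdx_run}, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg_in <- if (is.character(config)) read_run_config(config) else config
  cohort <- read_cohort_dir(cfg_in$input_dir)
  thr <- if (is.null(cfg_in$thresholds)) threshold_config() else
    do.call(threshold_config, cfg_in$thresholds)
  run <- run_cohort_pipeline(cohort, thr,
                             stages = cfg_in$stages %||%
                               c("prioritize", "cnv", "secondary", "stats"))
  dir.create(cfg_in$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$candidates))
    write_tsv(run$candidates, file.path(cfg_in$out_dir, "candidates.tsv"))
  if (!is.null(run$cnv_classified))
    write_tsv(run$cnv_classified, file.path(cfg_in$out_dir, "cnv_classified.tsv"))
  if (!is.null(run$secondary_findings))
    write_tsv(run$secondary_findings,
              file.path(cfg_in$out_dir, "secondary_findings.tsv"))
  if (!is.null(run$concordance))
    jsonlite::write_json(
      list(n_cma = run$concordance$n_cma,
           n_detected = run$concordance$n_detected,
           detection_rate = run$concordance$detection_rate,
           breakpoints = run$breakpoints),
      file.path(cfg_in$out_dir, "concordance.json"), auto_unbox = TRUE,
      digits = NA)
  if (!is.null(run$summary))
    jsonlite::write_json(run$summary,
                         file.path(cfg_in$out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(run)
}
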