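#' Small-variant prioritisation
#'
#' Variants are plain data.frames, one row per call, carrying the VCF-derived
#' call fields (\code{case_id, chrom, pos, ref, alt, zygosity, read_depth,
#' genotype_quality, allele_fraction}) plus an annotation bundle: \code{gene},
#' \code{effect_class}, population frequencies in columns prefixed
#' \code{freq_} (NA = absent from that database), conservation scores in
#' columns prefixed \code{cons_}, \code{damaging_predictor_count},
#' \code{predictor_total}, \code{splice_delta} (NA when no prediction),
#' \code{assertion_clinvar}, \code{assertion_hgmd} and
#' \code{mouse_phenotype_flag}.
#'
#' @name prioritize
NULL

ANNOT_REQUIRED <- c("gene", "effect_class", "damaging_predictor_count",
                    "predictor_total", "splice_delta",
                    "assertion_clinvar", "assertion_hgmd", "mouse_phenotype_flag")

variant_id <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

freq_columns <- function(v) grep("^freq_", names(v), value = TRUE)

#' Maximum population allele frequency across all configured databases
#'
#' The rarity rule aggregates by the maximum across databases (the most
#' conservative retention rule). NA everywhere means the allele is absent
#' from every database and is treated as frequency 0 for thresholding but
#' flagged as "absent" for frequency tiering.
#'
#' @param variants annotated variant data.frame.
#' @return numeric vector; NA where absent from all databases.
#' @export
max_pop_freq <- function(variants) {
  fc <- freq_columns(variants)
  if (length(fc) == 0L) return(rep(NA_real_, nrow(variants)))
  m <- as.matrix(variants[fc])
  mode(m) <- "numeric"
  out <- apply(m, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  as.numeric(out)
}

check_annotated <- function(variants) {
  missing_cols <- setdiff(ANNOT_REQUIRED, names(variants))
  if (length(missing_cols))
    stop("variants lack annotation column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(is.na(variants$effect_class))
  if (length(bad))
    stop("variant(s) without annotation bundle: ",
         paste(variant_id(variants[head(bad, 5L), ]), collapse = ", "))
  if (!all(variants$effect_class %in% EFFECT_CLASSES))
    stop("unknown effect_class value(s): ",
         paste(setdiff(unique(variants$effect_class), EFFECT_CLASSES), collapse = ", "))
  invisible(TRUE)
}

#' Join call-level variants with a site annotation table
#'
#' @param variants data.frame with the call fields.
#' @param annotations data.frame keyed by \code{chrom, pos, ref, alt} carrying
#'   the annotation bundle columns.
#' @return annotated variant data.frame (left join; unannotated rows keep NA
#'   and are rejected downstream).
#' @export
annotate_variants <- function(variants, annotations) {
  key_v <- variant_id(variants)
  key_a <- variant_id(annotations)
  if (anyDuplicated(key_a))
    stop("annotation table has duplicated variant keys")
  idx <- match(key_v, key_a)
  ann_cols <- setdiff(names(annotations), c("chrom", "pos", "ref", "alt"))
  cbind(variants, annotations[idx, ann_cols, drop = FALSE], row.names = NULL)
}

#' Filter to high-quality rare functional variants
#'
#' Retains variants that are rare (maximum population frequency below
#' \code{rare_freq_max}; absent counts as rare) and either exonic with
#' potential functional impact (nonsense, frameshift, canonical splice,
#' in-frame indel, missense, ncRNA exonic) or predicted to impact splicing
#' (\code{|splice_delta| >= splice_delta_min}), regardless of region class.
#' Row order is preserved; the input is not modified; idempotent.
#'
#' @param variants annotated variant data.frame.
#' @param cfg a \code{\link{threshold_config}}.
#' @return the retained subset, with helper column \code{max_freq} attached.
#' @export
filter_rare_functional <- function(variants, cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  check_annotated(variants)
  mf <- max_pop_freq(variants)
  rare <- is.na(mf) | mf < cfg$rare_freq_max
  exonic_like <- variants$effect_class %in%
    c("nonsense", "frameshift", "canonical_splice", "inframe_indel",
      "missense", "ncRNA_exonic")
  splice_hit <- !is.na(variants$splice_delta) &
    abs(variants$splice_delta) >= cfg$splice_delta_min
  keep <- rare & (exonic_like | splice_hit)
  out <- variants[keep, , drop = FALSE]
  out$max_freq <- mf[keep]
  rownames(out) <- NULL
  out
}

#' Assign ordered prioritisation tiers
#'
#' Adds four ordinal tier columns (1 = strongest support):
#' \describe{
#'   \item{quality_tier}{1: depth >= 20, GQ >= 30 and allele fraction in the
#'     expected window (0.3-0.7 het, >= 0.85 hom/hemizygous); 2: depth >= 10;
#'     3: otherwise.}
#'   \item{frequency_tier}{1: absent from every database; 2: < 0.1\%;
#'     3: < 1\%; 4: < 5\%; 5: common.}
#'   \item{impact_tier}{1: loss of function (nonsense/frameshift/canonical
#'     splice); 2: missense with a damaging majority of available predictors
#'     or high conservation, or any variant with a damaging splice
#'     prediction; 3: otherwise.}
#'   \item{disease_tier}{1: gene in the disease-gene table; 2: abnormal mouse
#'     phenotype only; 3: otherwise.}
#' }
#' Pure function of (variants, cfg, disease table).
#'
#' @param variants annotated variant data.frame (typically post
#'   \code{\link{filter_rare_functional}}).
#' @param cfg a \code{\link{threshold_config}}.
#' @param disease_genes disease-gene table with a \code{gene} column, or NULL.
#' @return input with tier columns appended.
#' @export
assign_tiers <- function(variants, cfg = threshold_config(), disease_genes = NULL) {
  cfg <- as_thresholds(cfg)
  check_annotated(variants)
  n <- nrow(variants)
  af <- variants$allele_fraction
  het <- variants$zygosity == "het"
  af_ok <- ifelse(het,
                  af >= cfg$het_af_range[1] & af <= cfg$het_af_range[2],
                  af >= cfg$hom_af_min)
  qt <- ifelse(variants$read_depth >= cfg$quality_min_depth &
                 variants$genotype_quality >= cfg$quality_min_gq & af_ok, 1L,
               ifelse(variants$read_depth >= cfg$quality_tier2_depth, 2L, 3L))

  mf <- if ("max_freq" %in% names(variants)) variants$max_freq else max_pop_freq(variants)
  ft <- ifelse(is.na(mf), 1L,
        ifelse(mf < 0.001, 2L,
        ifelse(mf < 0.01, 3L,
        ifelse(mf < cfg$rare_freq_max, 4L, 5L))))

  lof <- variants$effect_class %in% LOF_CLASSES
  avail <- pmax(variants$predictor_total, 0L)
  damaging_majority <- avail > 0L &
    variants$damaging_predictor_count >= ceiling(avail / 2)
  cons_cols <- grep("^cons_", names(variants), value = TRUE)
  high_cons <- rep(FALSE, n)
  if (length(cons_cols)) {
    cm <- as.matrix(variants[cons_cols])
    mode(cm) <- "numeric"
    high_cons <- apply(cm, 1L, function(r) any(!is.na(r) & r >= cfg$conservation_high))
  }
  splice_hit <- !is.na(variants$splice_delta) &
    abs(variants$splice_delta) >= cfg$splice_delta_min
  it <- ifelse(lof, 1L,
        ifelse((variants$effect_class == "missense" & (damaging_majority | high_cons)) |
                 (!lof & splice_hit), 2L, 3L))

  in_disease <- if (is.null(disease_genes)) rep(FALSE, n) else
    !is.na(variants$gene) & variants$gene %in% disease_genes$gene
  dt <- ifelse(in_disease, 1L,
        ifelse(!is.na(variants$mouse_phenotype_flag) & variants$mouse_phenotype_flag, 2L, 3L))

  variants$quality_tier <- as.integer(qt)
  variants$frequency_tier <- as.integer(ft)
  variants$impact_tier <- as.integer(it)
  variants$disease_tier <- as.integer(dt)
  variants
}

#' Assign inheritance category per variant within one case
#'
#' Variants are grouped by gene and interpreted against the gene's modes of
#' inheritance: dominant gene + het (or hom) -> \code{AD_het}; recessive gene
#' + hom -> \code{AR_hom}; recessive gene + >= 2 distinct het positions ->
#' \code{AR_compound_het_candidate} (phase unknown in a proband-only design);
#' X-linked gene + hemizygous male -> \code{XL_hemizygous}; recessive gene +
#' lone het -> \code{carrier_only}; otherwise \code{incompatible}. Genes
#' absent from the disease table are flagged \code{novel_gene} and mapped by
#' zygosity with no mode restriction.
#'
#' @param case_variants annotated variants of a single case.
#' @param disease_genes disease-gene table (\code{gene},
#'   \code{inheritance_modes} comma-separated subset of AD/AR/XL,
#'   \code{lof_mechanism}, \code{phenotype_terms}, \code{condition}).
#' @param case_sex "M" or "F".
#' @return input with \code{inheritance_category} and \code{novel_gene}
#'   columns appended.
#' @export
assign_inheritance_category <- function(case_variants, disease_genes, case_sex) {
  stopifnot(case_sex %in% c("M", "F"))
  n <- nrow(case_variants)
  cat_out <- rep("incompatible", n)
  novel <- rep(FALSE, n)
  if (n == 0L) {
    case_variants$inheritance_category <- character()
    case_variants$novel_gene <- logical()
    return(case_variants)
  }
  gene <- ifelse(is.na(case_variants$gene), "", case_variants$gene)
  for (g in unique(gene)) {
    idx <- which(gene == g)
    entry <- if (nzchar(g)) disease_genes[disease_genes$gene == g, , drop = FALSE] else
      disease_genes[0, , drop = FALSE]
    is_novel <- nrow(entry) == 0L
    modes <- if (is_novel) c("AD", "AR", "XL") else
      strsplit(entry$inheritance_modes[1], ",", fixed = TRUE)[[1]]
    novel[idx] <- is_novel
    zyg <- case_variants$zygosity[idx]
    het_pos <- unique(case_variants$pos[idx][zyg == "het"])
    n_het_distinct <- length(het_pos)
    for (k in seq_along(idx)) {
      z <- zyg[k]
      cat_out[idx[k]] <-
        if ("AR" %in% modes && z == "hom") "AR_hom"
        else if ("AD" %in% modes && z %in% c("het", "hom")) "AD_het"
        else if ("AR" %in% modes && z == "het" && n_het_distinct >= 2L)
          "AR_compound_het_candidate"
        else if ("XL" %in% modes && z == "hemizygous" && case_sex == "M") "XL_hemizygous"
        else if ("AR" %in% modes && z == "het") "carrier_only"
        else if ("XL" %in% modes && z == "het" && case_sex == "F") "carrier_only"
        else "incompatible"
    }
  }
  case_variants$inheritance_category <- cat_out
  case_variants$novel_gene <- novel
  case_variants
}

#' Classify reported pathogenicity from assertion databases
#'
#' Combines the two assertion sources: a pathogenic (or likely-pathogenic)
#' assertion from either source gives \code{asserted_pathogenic}
#' (\code{asserted_likely}); a pathogenic/likely call in one source against a
#' benign call in the other gives \code{conflicting}; no assertion (and
#' benign/VUS-only assertions, which the category set cannot express) gives
#' \code{novel}.
#'
#' @param variants annotated variant data.frame.
#' @return input with \code{pathogenicity_category} appended.
#' @export
classify_reported_pathogenicity <- function(variants) {
  a <- as.character(variants$assertion_clinvar)
  b <- as.character(variants$assertion_hgmd)
  a[is.na(a)] <- "none"; b[is.na(b)] <- "none"
  bad <- setdiff(unique(c(a, b)), ASSERTION_LEVELS)
  if (length(bad)) stop("unknown assertion level(s): ", paste(bad, collapse = ", "))
  path_any <- a == "pathogenic" | b == "pathogenic"
  likely_any <- a == "likely_pathogenic" | b == "likely_pathogenic"
  benign_any <- a == "benign" | b == "benign"
  cat <- ifelse((path_any | likely_any) & benign_any, "conflicting",
         ifelse(path_any, "asserted_pathogenic",
         ifelse(likely_any, "asserted_likely", "novel")))
  variants$pathogenicity_category <- cat
  variants
}

pathogenicity_rank <- function(category) {
  match(category, c("asserted_pathogenic", "asserted_likely", "novel", "conflicting"))
}

# Deterministic simplified ACMG rule table (a deliberate reduction of the full
# 28-criterion framework; see the methods vignette). Inputs are per-candidate
# booleans; first matching rule wins:
#   1. LoF in a gene with an established LoF mechanism, absent from every
#      population database                                  -> pathogenic
#   2. asserted pathogenic (either source, no conflict) and
#      MOI-compatible                                       -> pathogenic
#   3. LoF in a known disease gene, MOI-compatible          -> likely_pathogenic
#   4. asserted likely-pathogenic, MOI-compatible           -> likely_pathogenic
#   5. novel missense with a damaging predictor majority,
#      MOI-compatible, phenotype overlap                    -> likely_pathogenic
#   6. otherwise                                            -> VUS
acmg_rule_table <- function(is_lof, lof_mechanism, freq_absent, is_missense,
                            pathogenicity_category, moi_compatible,
                            phenotype_overlap, in_disease_gene,
                            damaging_majority = TRUE) {
  ifelse(is_lof & lof_mechanism & freq_absent, "pathogenic",
  ifelse(pathogenicity_category == "asserted_pathogenic" & moi_compatible, "pathogenic",
  ifelse(is_lof & in_disease_gene & moi_compatible, "likely_pathogenic",
  ifelse(pathogenicity_category == "asserted_likely" & moi_compatible, "likely_pathogenic",
  ifelse(is_missense & pathogenicity_category == "novel" & moi_compatible &
           phenotype_overlap & damaging_majority, "likely_pathogenic", "VUS")))))
}

#' Simplified ACMG classification of a candidate variant
#'
#' Applies the deterministic rule table documented in the package source (see
#' \code{acmg_rule_table}): loss-of-function variants in LoF-mechanism genes
#' absent from population databases are pathogenic; asserted-pathogenic,
#' mode-compatible variants are pathogenic; mode-compatible LoF in a disease
#' gene, asserted-likely variants, and novel mode-compatible missense with
#' phenotype overlap are likely pathogenic; everything else is a VUS.
#'
#' @param variants data.frame with tiers, \code{inheritance_category},
#'   \code{pathogenicity_category} and \code{novel_gene} assigned.
#' @param disease_genes disease-gene table.
#' @param phenotype_match numeric vector of phenotype match scores (recycled).
#' @return character vector of classes.
#' @export
acmg_classify_simplified <- function(variants, disease_genes,
                                     phenotype_match = 0) {
  lofm <- rep(FALSE, nrow(variants))
  hit <- match(variants$gene, disease_genes$gene)
  ok <- !is.na(hit)
  lofm[ok] <- as.logical(disease_genes$lof_mechanism[hit[ok]])
  mf <- if ("max_freq" %in% names(variants)) variants$max_freq else max_pop_freq(variants)
  moi_ok <- variants$inheritance_category %in%
    c("AD_het", "AR_hom", "AR_compound_het_candidate", "XL_hemizygous") &
    !variants$novel_gene
  avail <- pmax(variants$predictor_total, 0L)
  dmg <- avail > 0L & variants$damaging_predictor_count >= ceiling(avail / 2)
  acmg_rule_table(is_lof = variants$effect_class %in% LOF_CLASSES,
                  lof_mechanism = lofm,
                  freq_absent = is.na(mf) | mf == 0,
                  is_missense = variants$effect_class == "missense",
                  pathogenicity_category = variants$pathogenicity_category,
                  moi_compatible = moi_ok,
                  phenotype_overlap = rep_len(phenotype_match, nrow(variants)) > 0,
                  in_disease_gene = ok,
                  damaging_majority = dmg)
}

#' Rank candidate diagnoses for one case
#'
#' Builds one candidate per diagnostic-compatible variant (dominant het,
#' recessive hom, X-linked hemizygous) and one per recessive
#' compound-heterozygote gene (the two strongest distinct het variants,
#' phase unknown). Carrier-only and incompatible variants never form
#' candidates. Candidates are totally ordered by (pathogenicity category,
#' impact tier, disease tier, mode compatibility, phenotype match, frequency
#' tier), ties broken by genomic coordinate.
#'
#' @param tiered annotated variants of one case after filtering, tiering,
#'   inheritance and pathogenicity classification.
#' @param disease_genes disease-gene table.
#' @param case_terms HPO term identifiers of the case.
#' @param ontology a \code{wgsdx_ontology} (NULL disables phenotype matching).
#' @param cfg a \code{\link{threshold_config}}.
#' @return data.frame of ranked candidates (one row each) with columns
#'   \code{case_id, gene, variant_ids, n_variants, moi_model, acmg_class,
#'   phenotype_match, phase_unknown, rank} plus ordering keys.
#' @export
rank_candidates <- function(tiered, disease_genes, case_terms = character(),
                            ontology = NULL, cfg = threshold_config()) {
  cols <- c("inheritance_category", "pathogenicity_category", "impact_tier")
  if (!all(cols %in% names(tiered)))
    stop("rank_candidates requires tiered, categorised variants")
  empty <- data.frame(case_id = character(), gene = character(),
                      variant_ids = character(), n_variants = integer(),
                      moi_model = character(), acmg_class = character(),
                      phenotype_match = numeric(), phase_unknown = logical(),
                      path_rank = integer(), impact_tier = integer(),
                      disease_tier = integer(), moi_compatible = logical(),
                      frequency_tier = integer(), chrom = character(),
                      pos = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(tiered) == 0L) return(empty)

  gene_pheno <- function(g) {
    if (is.null(ontology) || length(case_terms) == 0L) return(0)
    hit <- match(g, disease_genes$gene)
    if (is.na(hit)) return(0)
    terms <- strsplit(disease_genes$phenotype_terms[hit], ",", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L) return(0)
    phenotype_match_score(case_terms, terms, ontology)
  }

  rows <- list()
  singles <- tiered[tiered$inheritance_category %in%
                      c("AD_het", "AR_hom", "XL_hemizygous"), , drop = FALSE]
  if (nrow(singles)) {
    pm <- vapply(singles$gene, gene_pheno, numeric(1))
    cls <- acmg_classify_simplified(singles, disease_genes, pm)
    rows[[length(rows) + 1L]] <- data.frame(
      case_id = singles$case_id, gene = singles$gene,
      variant_ids = variant_id(singles), n_variants = 1L,
      moi_model = c(AD_het = "AD", AR_hom = "AR_hom",
                    XL_hemizygous = "XL")[singles$inheritance_category],
      acmg_class = cls, phenotype_match = pm, phase_unknown = FALSE,
      path_rank = pathogenicity_rank(singles$pathogenicity_category),
      impact_tier = singles$impact_tier, disease_tier = singles$disease_tier,
      moi_compatible = !singles$novel_gene,
      frequency_tier = singles$frequency_tier,
      chrom = singles$chrom, pos = singles$pos, stringsAsFactors = FALSE)
  }

  ch <- tiered[tiered$inheritance_category == "AR_compound_het_candidate", , drop = FALSE]
  if (nrow(ch)) {
    for (g in unique(ch$gene)) {
      gv <- ch[ch$gene == g, , drop = FALSE]
      gv <- gv[!duplicated(gv$pos), , drop = FALSE]
      if (nrow(gv) < 2L) next
      ord <- order(gv$impact_tier, pathogenicity_rank(gv$pathogenicity_category),
                   gv$frequency_tier, gv$pos)
      pair <- gv[ord[1:2], , drop = FALSE]
      pm <- gene_pheno(g)
      cls <- acmg_classify_simplified(pair, disease_genes, pm)
      # both alleles must qualify: the pair takes the weaker class
      cls_rank <- match(cls, c("pathogenic", "likely_pathogenic", "VUS"))
      pair_class <- c("pathogenic", "likely_pathogenic", "VUS")[max(cls_rank)]
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = pair$case_id[1], gene = g,
        variant_ids = paste(variant_id(pair), collapse = ","), n_variants = 2L,
        moi_model = "AR_compound_het", acmg_class = pair_class,
        phenotype_match = pm, phase_unknown = TRUE,
        path_rank = min(pathogenicity_rank(pair$pathogenicity_category)),
        impact_tier = min(pair$impact_tier), disease_tier = min(pair$disease_tier),
        moi_compatible = !pair$novel_gene[1],
        frequency_tier = min(pair$frequency_tier),
        chrom = pair$chrom[1], pos = min(pair$pos), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  cand <- do.call(rbind, rows)
  ord <- order(cand$path_rank, cand$impact_tier, cand$disease_tier,
               !cand$moi_compatible, -cand$phenotype_match,
               cand$frequency_tier, cand$chrom, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}

#' Count rare damaging events for one case
#'
#' Number of variants surviving the rare-functional filter with impact tier
#' at most 2 (loss of function, damaging missense, or splice-damaging) -- the
#' per-genome workload the analyst interrogates.
#'
#' @param tiered variants after \code{\link{filter_rare_functional}} and
#'   \code{\link{assign_tiers}}.
#' @return integer count.
#' @export
count_rare_damaging <- function(tiered) {
  if (!"impact_tier" %in% names(tiered)) stop("tiers not assigned")
  sum(tiered$impact_tier <= 2L)
}

#' Run the full small-variant prioritisation for one case
#'
#' Applies, in order: annotation validation, rare-functional filtering, tier
#' assignment, per-gene inheritance categorisation, assertion classification
#' and candidate ranking.
#'
#' @param variants annotated variants of one case.
#' @param resources a resource bundle (list with \code{disease_genes} and
#'   optionally \code{ontology}), e.g. from \code{\link{generate_resources}}.
#' @param case_sex "M" or "F".
#' @param case_terms case HPO terms.
#' @param cfg a \code{\link{threshold_config}}.
#' @return list with \code{candidates} (ranked data.frame), \code{tiered}
#'   (surviving variants with all columns), and \code{n_rare_damaging}.
#' @export
prioritize_case <- function(variants, resources, case_sex = "F",
                            case_terms = character(), cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  dg <- resources$disease_genes
  flt <- filter_rare_functional(variants, cfg)
  flt <- assign_tiers(flt, cfg, dg)
  flt <- assign_inheritance_category(flt, dg, case_sex)
  flt <- classify_reported_pathogenicity(flt)
  cand <- rank_candidates(flt, dg, case_terms, resources$ontology, cfg)
  list(candidates = cand, tiered = flt, n_rare_damaging = count_rare_damaging(flt))
}
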