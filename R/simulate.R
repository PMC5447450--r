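#' Synthetic cohort generation
#'
#' Generates a fully self-contained synthetic cohort on a reduced coordinate
#' space (ten 30-Mb chromosomes including X and Y; all coordinates
#' synthetic): resources (gene models, disease genes, segmental-duplication
#' and hypervariable tracks, syndromic regions, control CNVs, phenotype
#' ontology), per-case annotated small-variant sets, read-depth CNV segment
#' files, junction SV event files and microarray calls, with planted causal
#' scenarios recorded in a ground-truth manifest. Calibrated to the
#' per-genome workload of the clinical platform modelled: about 20,014
#' exonic/splicing variants, 248 read-depth CNVs (median 10 kb, ~28\% exonic),
#' 1,604 junction SVs (median 495 bp, ~2\% exonic) and ~498 rare damaging
#' events at full scale. Fully deterministic under (config, seed).
#'
#' @name simulate
NULL

SIM_CHROMS <- c(paste0("chr", 1:8), "chrX", "chrY")
SIM_CHROM_LEN <- 30e6

#' Simulation configuration
#'
#' @param cohort_n number of cases.
#' @param seed integer seed (mandatory; identical config + seed gives
#'   identical cohorts).
#' @param scale fraction in (0, 1] downscaling all per-genome counts.
#' @param exonic_mean mean exonic/splicing variants per genome at scale 1.
#' @param nonexonic_mean mean intronic/UTR/intergenic decoy variants.
#' @param cnv_count_mean,sv_count_mean mean read-depth CNVs / junction SVs.
#' @param cnv_median_size,sv_median_size median event sizes (bp).
#' @param cnv_exonic_frac,sv_exonic_frac target exon-overlap fractions.
#' @param rare_damaging_target calibration target for rare damaging events
#'   per genome at scale 1; the rare-variant rate is solved from the class
#'   mixture so that the expectation hits this value.
#' @param p_lof,p_missense,p_damaging_missense class mixture parameters.
#' @param diagnosed_frac fraction of cases given a planted primary scenario.
#' @param secondary_rate probability a case carries a plantable secondary
#'   (ACMG-panel) variant.
#' @param opt_out_rate probability a case opts out of secondary findings.
#' @param cma_probe_jitter maximum probe offset (bp) for microarray inner and
#'   outer boundaries.
#' @param fragment_frac fraction of planted CNVs emitted as two fragments
#'   (exercises segment merging).
#' @param control_cohort_n number of CNV control samples.
#' @return object of class \code{wgsdx_simconfig}.
#' @export
simulation_config <- function(cohort_n = 100L, seed = 1L, scale = 1,
                              exonic_mean = 20014, nonexonic_mean = 2000,
                              cnv_count_mean = 248, sv_count_mean = 1604,
                              cnv_median_size = 10000, sv_median_size = 495,
                              cnv_exonic_frac = 0.28, sv_exonic_frac = 0.02,
                              rare_damaging_target = 498,
                              p_lof = 0.01, p_missense = 0.45,
                              p_damaging_missense = 0.25,
                              diagnosed_frac = 0.34, secondary_rate = 0.07,
                              opt_out_rate = 0.26,
                              cma_probe_jitter = 5000,
                              fragment_frac = 0.25,
                              control_cohort_n = 100L) {
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  # class mixture: missense, synonymous, LoF split, in-frame indel, ncRNA,
  # splice region, UTR; solve the rare-variant rate so that
  # E[rare & damaging] = rare_damaging_target at scale 1
  p_syn <- 1 - p_missense - p_lof - 0.01 - 0.03 - 0.05 - 0.05
  p_sr_delta <- 0.10   # splice-region variants with a damaging splice delta
  p_syn_delta <- 0.005
  p_cons_tail <- stats::pnorm(2, mean = 0, sd = 0.8, lower.tail = FALSE)
  p_damaging <- p_lof +
    p_missense * (p_damaging_missense + (1 - p_damaging_missense) * p_cons_tail) +
    0.05 * p_sr_delta + p_syn * p_syn_delta
  p_rare <- (rare_damaging_target / exonic_mean) / p_damaging
  structure(list(cohort_n = as.integer(cohort_n), seed = as.integer(seed),
                 scale = scale, exonic_mean = exonic_mean,
                 nonexonic_mean = nonexonic_mean,
                 cnv_count_mean = cnv_count_mean, sv_count_mean = sv_count_mean,
                 cnv_median_size = cnv_median_size, sv_median_size = sv_median_size,
                 cnv_exonic_frac = cnv_exonic_frac, sv_exonic_frac = sv_exonic_frac,
                 rare_damaging_target = rare_damaging_target,
                 p_lof = p_lof, p_missense = p_missense, p_syn = p_syn,
                 p_damaging_missense = p_damaging_missense,
                 p_sr_delta = p_sr_delta, p_syn_delta = p_syn_delta,
                 p_rare = p_rare,
                 diagnosed_frac = diagnosed_frac, secondary_rate = secondary_rate,
                 opt_out_rate = opt_out_rate,
                 cma_probe_jitter = cma_probe_jitter,
                 fragment_frac = fragment_frac,
                 control_cohort_n = as.integer(control_cohort_n)),
            class = "wgsdx_simconfig")
}

#' Generate the shared resource bundle
#'
#' Deterministic under the seed: 600 gene models (5 x 300 bp exons each) on
#' chr1-chr8 and chrX, 120 disease genes with inheritance modes and
#' LoF-mechanism flags, segmental-duplication and hypervariable tracks,
#' syndromic regions, 30 polymorphic control-CNV loci realised over the
#' control cohort, the ACMG-56 panel and the phenotype ontology.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param seed overrides \code{cfg$seed} when given.
#' @return list of class \code{wgsdx_resources}.
#' @export
generate_resources <- function(cfg = simulation_config(), seed = NULL) {
  set.seed(seed %||% cfg$seed)
  gene_chroms <- setdiff(SIM_CHROMS, "chrY")
  slots <- seq(2e5, by = 4e5, length.out = 67)
  tx <- do.call(rbind, lapply(gene_chroms, function(ch)
    data.frame(chrom = ch, start = slots, end = slots + 1e4,
               stringsAsFactors = FALSE)))
  tx <- tx[seq_len(600L), ]
  tx$gene <- sprintf("GENE%03d", seq_len(nrow(tx)))
  exon_off <- seq(0, 8000, by = 2000)
  exons <- do.call(rbind, lapply(exon_off, function(o)
    data.frame(gene = tx$gene, chrom = tx$chrom, start = tx$start + o,
               end = tx$start + o + 300L, stringsAsFactors = FALSE)))
  exons <- exons[order(exons$chrom, exons$start), ]
  gene_models <- list(transcripts = tx[c("gene", "chrom", "start", "end")],
                      exons = exons)

  ontology <- fixture_ontology()
  leaf_terms <- ontology$edges$child[!ontology$edges$child %in% ontology$edges$parent]
  cat_of_leaf <- stats::setNames(ontology$edges$parent[match(leaf_terms, ontology$edges$child)],
                                 leaf_terms)

  dg_idx <- seq(1, 600, by = 5)
  dg <- tx[dg_idx, c("gene", "chrom")]
  modes <- ifelse(dg$chrom == "chrX", "XL", rep_len(c("AD", "AR"), nrow(dg)))
  # a few dual-mode genes
  modes[seq(4, length(modes), by = 10)] <- "AD,AR"
  lofm <- rep_len(c(TRUE, TRUE, TRUE, FALSE), nrow(dg))
  leaf_pairs <- matrix(rep_len(leaf_terms, 2 * nrow(dg)), ncol = 2, byrow = TRUE)
  disease_genes <- data.frame(
    gene = dg$gene, inheritance_modes = modes,
    condition = paste0("synthetic disorder ", seq_len(nrow(dg))),
    phenotype_terms = paste(leaf_pairs[, 1], leaf_pairs[, 2], sep = ","),
    lof_mechanism = lofm, stringsAsFactors = FALSE)

  segdup <- do.call(rbind, lapply(SIM_CHROMS, function(ch) {
    st <- seq(5e5, SIM_CHROM_LEN - 1e6, by = 2e6)
    data.frame(chrom = ch, start = st, end = st + 1e5, stringsAsFactors = FALSE)
  }))
  # kept clear of the syndromic zone (< 5 Mb) so planted pathogenic CNVs are
  # never masked by the hypervariable exclusion
  hyperv <- do.call(rbind, lapply(SIM_CHROMS, function(ch) {
    st <- seq(5.2e6, SIM_CHROM_LEN - 1e6, by = 5e6)
    data.frame(chrom = ch, start = st, end = st + 5e4, stringsAsFactors = FALSE)
  }))

  syndromic <- data.frame(
    chrom = c("chr2", "chr3", "chr4", "chr5", "chr6", "chr7", "chr1", "chr8"),
    start = c(1e6, 2e6, 1.5e6, 3e6, 2.5e6, 1e6, 4e6, 2e6),
    end = c(3.4e6, 2.8e6, 2.9e6, 4.1e6, 3.2e6, 1.6e6, 4.8e6, 3.5e6),
    state = c(rep("loss", 6), "gain", "gain"),
    name = paste0("SYNDROME_", 1:8), stringsAsFactors = FALSE)

  loci_chrom <- rep_len(setdiff(SIM_CHROMS, "chrY"), 30L)
  loci <- data.frame(chrom = loci_chrom,
                     start = 8e6 + (seq_len(30L) - 1) * 6e5,
                     stringsAsFactors = FALSE)
  loci$end <- loci$start + 2e4
  loci$state <- rep_len(c("loss", "gain"), 30L)
  loci$pop_freq <- seq(0.01, 0.30, length.out = 30L)

  ctrl <- do.call(rbind, lapply(seq_len(cfg$control_cohort_n), function(s) {
    present <- stats::runif(nrow(loci)) < loci$pop_freq
    if (!any(present)) return(NULL)
    data.frame(sample_id = sprintf("CTRL%03d", s),
               chrom = loci$chrom[present], start = loci$start[present],
               end = loci$end[present], state = loci$state[present],
               stringsAsFactors = FALSE)
  }))

  structure(list(gene_models = gene_models, disease_genes = disease_genes,
                 segdup = segdup, hypervariable = hyperv,
                 syndromic_regions = syndromic, common_cnv_loci = loci,
                 control_cnvs = ctrl, panel = acmg_panel(),
                 ontology = ontology),
            class = "wgsdx_resources")
}

rand_base <- function(n, not = NULL) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (!is.null(not)) {
    clash <- b == not
    while (any(clash)) {
      b[clash] <- sample(c("A", "C", "G", "T"), sum(clash), replace = TRUE)
      clash <- b == not
    }
  }
  b
}

# Draw background exonic/splicing + non-exonic variants for one case.
draw_background_variants <- function(cfg, resources, case_id, sex) {
  n_ex <- stats::rpois(1, cfg$scale * cfg$exonic_mean)
  n_nx <- stats::rpois(1, cfg$scale * cfg$nonexonic_mean)
  n <- n_ex + n_nx
  if (n == 0L) n <- 1L
  ex_classes <- c("missense", "synonymous", "nonsense", "frameshift",
                  "canonical_splice", "inframe_indel", "ncRNA_exonic",
                  "splice_region", "UTR")
  ex_probs <- c(cfg$p_missense, cfg$p_syn, cfg$p_lof * 0.4, cfg$p_lof * 0.4,
                cfg$p_lof * 0.2, 0.01, 0.03, 0.05, 0.05)
  cls <- c(sample(ex_classes, n_ex, replace = TRUE, prob = ex_probs),
           sample(c("intronic", "intergenic"), n_nx, replace = TRUE))
  n <- length(cls)

  tx <- resources$gene_models$transcripts
  gi <- sample.int(nrow(tx), n, replace = TRUE)
  exonic_like <- cls %in% c("missense", "synonymous", "nonsense", "frameshift",
                            "inframe_indel", "ncRNA_exonic")
  off <- ifelse(exonic_like,
                sample(seq(0, 8000, by = 2000), n, replace = TRUE) +
                  sample.int(300L, n, replace = TRUE) - 1L,
                sample.int(10000L, n, replace = TRUE) - 1L)
  chrom <- tx$chrom[gi]
  pos <- tx$start[gi] + off + 1L   # 1-based
  gene <- tx$gene[gi]
  gene[cls == "intergenic"] <- NA_character_
  intergenic <- cls == "intergenic"
  pos[intergenic] <- pos[intergenic] + 200000L

  rare <- stats::runif(n) < cfg$p_rare
  absent <- rare & stats::runif(n) < 0.3
  f1 <- ifelse(rare, stats::runif(n, 0, 0.049), stats::runif(n, 0.05, 0.5))
  f1[absent] <- NA_real_
  f2 <- ifelse(is.na(f1), NA_real_, pmin(pmax(f1 * stats::runif(n, 0.5, 1.5), 0), 1))
  f2[rare & !absent] <- pmin(f2[rare & !absent], 0.049)

  dmg <- cls == "missense" & stats::runif(n) < cfg$p_damaging_missense
  pred_total <- rep(4L, n)
  pred_dmg <- ifelse(cls == "missense",
                     ifelse(dmg, sample(2:4, n, replace = TRUE),
                            sample(0:1, n, replace = TRUE)), 0L)
  cons <- ifelse(dmg, stats::rnorm(n, 3, 1), stats::rnorm(n, 0, 0.8))
  sd_raw <- stats::runif(n)
  splice_delta <- rep(NA_real_, n)
  splice_delta[cls == "canonical_splice"] <- 0.8
  sr <- cls == "splice_region" & sd_raw < cfg$p_sr_delta
  splice_delta[sr] <- stats::runif(sum(sr), 0.3, 0.9)
  syn <- cls == "synonymous" & sd_raw < cfg$p_syn_delta
  splice_delta[syn] <- stats::runif(sum(syn), 0.3, 0.9)

  hemi <- chrom == "chrX" & sex == "M"
  zyg <- ifelse(hemi, "hemizygous",
                ifelse(stats::runif(n) < 0.07, "hom", "het"))
  af <- ifelse(zyg == "het", pmin(pmax(stats::rnorm(n, 0.5, 0.05), 0.05), 0.95),
               pmin(stats::rnorm(n, 0.97, 0.02), 1))
  depth <- stats::rpois(n, 50)
  gq <- sample(30:99, n, replace = TRUE)

  is_indel <- cls %in% c("frameshift", "inframe_indel")
  ref <- rand_base(n)
  alt <- rand_base(n, not = NULL)
  clash <- alt == ref & !is_indel
  alt[clash] <- rand_base(sum(clash), not = NULL)
  alt[alt == ref & !is_indel] <- "T"; ref[alt == ref & !is_indel] <- "A"
  ref[is_indel] <- paste0(ref[is_indel], "ACG")
  asrt <- sample(c("none", "benign", "VUS"), n, replace = TRUE,
                 prob = c(0.98, 0.01, 0.01))

  data.frame(case_id = case_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
             zygosity = zyg, read_depth = depth, genotype_quality = gq,
             allele_fraction = af, gene = gene, effect_class = cls,
             freq_1kg = f1, freq_exac = f2,
             cons_phylop = cons,
             damaging_predictor_count = pred_dmg, predictor_total = pred_total,
             splice_delta = splice_delta,
             assertion_clinvar = asrt, assertion_hgmd = "none",
             mouse_phenotype_flag = stats::runif(n) < 0.15,
             stringsAsFactors = FALSE)
}

planted_variant_row <- function(case_id, gene_row, exon_slot, zygosity,
                                effect_class, asserted = FALSE) {
  pos <- gene_row$start + (exon_slot - 1L) * 2000L + 50L + 1L
  data.frame(case_id = case_id, chrom = gene_row$chrom, pos = pos,
             ref = if (effect_class == "frameshift") "GACT" else "G",
             alt = "A", zygosity = zygosity,
             read_depth = 45L, genotype_quality = 70L,
             allele_fraction = if (zygosity == "het") 0.5 else 0.99,
             gene = gene_row$gene, effect_class = effect_class,
             freq_1kg = NA_real_, freq_exac = NA_real_,
             cons_phylop = 4.5,
             damaging_predictor_count = if (effect_class == "missense") 4L else 0L,
             predictor_total = 4L,
             splice_delta = if (effect_class == "canonical_splice") 0.9 else NA_real_,
             assertion_clinvar = if (asserted) "pathogenic" else "none",
             assertion_hgmd = "none",
             mouse_phenotype_flag = TRUE,
             stringsAsFactors = FALSE)
}

# Random interval placement: exonic with the target probability, otherwise
# rejection-sampled away from exons.
place_intervals <- function(n, size, exonic_frac, resources, chroms = NULL) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  ex <- resources$gene_models$exons
  exonic <- stats::runif(n) < exonic_frac
  chrom <- character(n); start <- numeric(n)
  pick_ex <- sample.int(nrow(ex), n, replace = TRUE)
  chrom[exonic] <- ex$chrom[pick_ex[exonic]]
  start[exonic] <- pmax(0, ex$start[pick_ex[exonic]] - round(size[exonic] / 2))
  ne <- which(!exonic)
  pool <- chroms %||% setdiff(SIM_CHROMS, "chrY")
  if (length(ne)) {
    chrom[ne] <- sample(pool, length(ne), replace = TRUE)
    start[ne] <- stats::runif(length(ne), 0, SIM_CHROM_LEN - size[ne] - 1)
    # keep clear of exons (gene bodies occupy ~2.5% of the genome)
    gr_ex <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
    for (iter in 1:8) {
      gr <- GenomicRanges::GRanges(chrom[ne], IRanges::IRanges(start[ne] + 1, start[ne] + size[ne]))
      bad <- unique(S4Vectors::queryHits(quiet_overlaps(gr, gr_ex)))
      if (!length(bad)) break
      chrom[ne[bad]] <- sample(pool, length(bad), replace = TRUE)
      start[ne[bad]] <- stats::runif(length(bad), 0, SIM_CHROM_LEN - size[ne[bad]] - 1)
    }
  }
  data.frame(chrom = chrom, start = round(start), end = round(start) + round(size),
             stringsAsFactors = FALSE)
}

overlaps_track <- function(df, track) {
  if (nrow(df) == 0L || nrow(track) == 0L) return(rep(FALSE, nrow(df)))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
  tr <- GenomicRanges::GRanges(track$chrom, IRanges::IRanges(track$start + 1, track$end))
  out <- rep(FALSE, nrow(df))
  out[unique(S4Vectors::queryHits(quiet_overlaps(gr, tr)))] <- TRUE
  out
}

#' Generate one synthetic case
#'
#' Draws background small variants, read-depth CNV segments (including
#' diploid, hypervariable and chromosome-Y decoy rows), junction SV events
#' (including under-supported and non-deletion/duplication decoys) and
#' microarray calls; injects the requested planted scenario with annotations
#' guaranteeing pipeline eligibility; emits the ground-truth manifest rows.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @param resources from \code{\link{generate_resources}}.
#' @param scenario one of "none", "AD_het_lof", "AR_hom", "AR_compound_het",
#'   "AD_het_missense_asserted", "XL_hemizygous", "CNV_pathogenic".
#' @param case_id case identifier.
#' @param sex "M" or "F" (XL scenarios require "M").
#' @param plant_secondary also plant an ACMG-panel asserted-pathogenic variant.
#' @return list with \code{variants}, \code{cnv_segments} (raw file rows),
#'   \code{sv_events}, \code{cma_calls}, \code{case} (phenotype/consent row)
#'   and \code{manifest} (zero or more ground-truth rows).
#' @export
generate_case <- function(cfg, resources, scenario = "none", case_id = "S001",
                          sex = c("F", "M"), plant_secondary = FALSE) {
  sex <- match.arg(sex)
  if (scenario == "XL_hemizygous" && sex != "M")
    stop("XL scenario requires a male case")
  dg <- resources$disease_genes
  tx <- resources$gene_models$transcripts
  ontology <- resources$ontology

  variants <- draw_background_variants(cfg, resources, case_id, sex)
  manifest <- list()
  leaf_terms <- ontology$edges$child[!ontology$edges$child %in% ontology$edges$parent]
  case_terms <- sample(leaf_terms, 2L)

  pick_gene <- function(modes_needed, need_lof = TRUE, on_x = FALSE) {
    ok <- grepl(modes_needed, dg$inheritance_modes) &
      (!need_lof | dg$lof_mechanism)
    ok <- ok & (if (on_x) tx$chrom[match(dg$gene, tx$gene)] == "chrX"
                else tx$chrom[match(dg$gene, tx$gene)] != "chrX")
    idx <- which(ok)
    if (!length(idx)) stop("no eligible disease gene for scenario")
    dg[sample(idx, 1L), , drop = FALSE]
  }
  add_manifest <- function(type, gene, vids, category, class, origin,
                           chrom = NA, start = NA, end = NA, detectable = TRUE) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      case_id = case_id, scenario = type, gene = gene,
      variant_ids = vids, expected_category = category,
      expected_class = class, origin = origin,
      chrom = chrom, start = start, end = end,
      detectable = detectable,
      phenotype_categories = paste(case_categories(case_terms, ontology),
                                   collapse = ","),
      stringsAsFactors = FALSE)
  }
  use_gene_terms <- function(g) {
    terms <- strsplit(dg$phenotype_terms[dg$gene == g], ",")[[1]]
    case_terms <<- unique(c(terms, case_terms[1]))
  }
  origins <- c("de_novo", "maternal", "paternal")

  planted_cnv <- NULL
  if (scenario %in% c("AD_het_lof", "AD_het_missense_asserted")) {
    g <- pick_gene("AD", need_lof = scenario == "AD_het_lof")
    grow <- tx[tx$gene == g$gene, ]
    v <- planted_variant_row(case_id, grow, sample(1:5, 1), "het",
                             if (scenario == "AD_het_lof") "frameshift" else "missense",
                             asserted = scenario == "AD_het_missense_asserted")
    variants <- rbind(variants, v)
    use_gene_terms(g$gene)
    add_manifest(scenario, g$gene, variant_id(v), "AD_het", "pathogenic",
                 sample(origins, 1, prob = c(0.6, 0.2, 0.2)))
  } else if (scenario == "AR_hom") {
    g <- pick_gene("AR")
    grow <- tx[tx$gene == g$gene, ]
    v <- planted_variant_row(case_id, grow, 2L, "hom", "frameshift")
    variants <- rbind(variants, v)
    use_gene_terms(g$gene)
    add_manifest(scenario, g$gene, variant_id(v), "AR_hom", "pathogenic",
                 "maternal+paternal")
  } else if (scenario == "AR_compound_het") {
    g <- pick_gene("AR")
    grow <- tx[tx$gene == g$gene, ]
    v1 <- planted_variant_row(case_id, grow, 1L, "het", "nonsense")
    v2 <- planted_variant_row(case_id, grow, 4L, "het", "missense", asserted = TRUE)
    variants <- rbind(variants, v1, v2)
    use_gene_terms(g$gene)
    add_manifest(scenario, g$gene,
                 paste(variant_id(v1), variant_id(v2), sep = ","),
                 "AR_compound_het_candidate", "pathogenic", "maternal+paternal")
  } else if (scenario == "XL_hemizygous") {
    g <- pick_gene("XL", on_x = TRUE)
    grow <- tx[tx$gene == g$gene, ]
    v <- planted_variant_row(case_id, grow, 3L, "hemizygous", "nonsense")
    variants <- rbind(variants, v)
    use_gene_terms(g$gene)
    add_manifest(scenario, g$gene, variant_id(v), "XL_hemizygous", "pathogenic",
                 "maternal")
  } else if (scenario == "CNV_pathogenic") {
    reg <- resources$syndromic_regions[
      sample.int(nrow(resources$syndromic_regions), 1L), ]
    planted_cnv <- reg
    add_manifest(scenario, reg$name, NA_character_, "CNV", "pathogenic",
                 "de_novo", chrom = reg$chrom, start = reg$start, end = reg$end)
  }

  sec <- NULL
  if (plant_secondary) {
    panel_gene <- sample(resources$panel$gene, 1L)
    sec <- data.frame(case_id = case_id, chrom = "chr1",
                      pos = 29e6 + sample.int(5e5, 1L), ref = "C", alt = "T",
                      zygosity = "het", read_depth = 50L, genotype_quality = 80L,
                      allele_fraction = 0.5, gene = panel_gene,
                      effect_class = "missense", freq_1kg = NA_real_,
                      freq_exac = NA_real_, cons_phylop = 3,
                      damaging_predictor_count = 4L, predictor_total = 4L,
                      splice_delta = NA_real_, assertion_clinvar = "pathogenic",
                      assertion_hgmd = "none", mouse_phenotype_flag = FALSE,
                      stringsAsFactors = FALSE)
    variants <- rbind(variants, sec)
    add_manifest("secondary", panel_gene, variant_id(sec), "secondary",
                 "secondary_finding", NA_character_)
  }

  # ---- read-depth CNV segments -------------------------------------------
  n_cnv <- stats::rpois(1, cfg$scale * cfg$cnv_count_mean)
  sizes <- pmax(2000, round(stats::rlnorm(n_cnv, log(cfg$cnv_median_size), 0.8)))
  cnv <- place_intervals(n_cnv, sizes, cfg$cnv_exonic_frac, resources)
  # route ~1/3 of background CNVs through the polymorphic loci
  loci <- resources$common_cnv_loci
  n_common <- stats::rbinom(1, n_cnv, 0.30)
  if (n_common > 0 && n_cnv > 0) {
    pick <- sample.int(nrow(loci), n_common, replace = TRUE,
                       prob = loci$pop_freq)
    rows <- sample.int(n_cnv, n_common)
    cnv$chrom[rows] <- loci$chrom[pick]
    cnv$start[rows] <- loci$start[pick]
    cnv$end[rows] <- loci$end[pick]
  }
  cnv$copy_state <- sample(c(0L, 1L, 3L, 4L), max(n_cnv, 0), replace = TRUE,
                           prob = c(0.05, 0.55, 0.35, 0.05))
  if (n_common > 0 && n_cnv > 0)
    cnv$copy_state[rows] <- ifelse(loci$state[pick] == "gain", 3L, 1L)

  seg_rows <- cnv
  # decoys: diploid rows, hypervariable rows, chrY rows
  n_dip <- stats::rpois(1, cfg$scale * 40)
  if (n_dip > 0) {
    dip <- place_intervals(n_dip, rep(5000, n_dip), 0, resources)
    dip$copy_state <- 2L
    seg_rows <- rbind(seg_rows, dip)
  }
  hv <- resources$hypervariable[sample.int(nrow(resources$hypervariable),
                                           max(1, round(cfg$scale * 10))), ]
  hv_rows <- data.frame(chrom = hv$chrom, start = hv$start, end = hv$end,
                        copy_state = 1L, stringsAsFactors = FALSE)
  y_rows <- data.frame(chrom = "chrY", start = c(1e6, 5e6), end = c(1.2e6, 5.4e6),
                       copy_state = c(1L, 3L), stringsAsFactors = FALSE)
  seg_rows <- rbind(seg_rows, hv_rows, if (sex == "M") y_rows)

  cma <- NULL
  if (!is.null(planted_cnv)) {
    st <- 2000 * floor(planted_cnv$start / 2000)
    en <- 2000 * ceiling(planted_cnv$end / 2000)
    if (stats::runif(1) < cfg$fragment_frac) {
      mid <- 2000 * floor((st + en) / 2 / 2000)
      frag <- data.frame(chrom = planted_cnv$chrom,
                         start = c(st, mid + 2000), end = c(mid, en),
                         copy_state = if (planted_cnv$state == "gain") 3L else 1L,
                         stringsAsFactors = FALSE)
    } else {
      frag <- data.frame(chrom = planted_cnv$chrom, start = st, end = en,
                         copy_state = if (planted_cnv$state == "gain") 3L else 1L,
                         stringsAsFactors = FALSE)
    }
    seg_rows <- rbind(seg_rows, frag)
    j_in <- stats::runif(2, 0, cfg$cma_probe_jitter)
    j_out <- stats::runif(2, 0, cfg$cma_probe_jitter)
    cma <- data.frame(case_id = case_id, chrom = planted_cnv$chrom,
                      outer_start = max(0, planted_cnv$start - j_out[1]),
                      inner_start = planted_cnv$start + j_in[1],
                      inner_end = planted_cnv$end - j_in[2],
                      outer_end = planted_cnv$end + j_out[2],
                      state = planted_cnv$state,
                      classification = "pathogenic", stringsAsFactors = FALSE)
  }
  # background CMA calls at common loci (~6 per patient)
  n_cma_bg <- stats::rpois(1, 6)
  if (n_cma_bg > 0) {
    pick <- sample.int(nrow(loci), n_cma_bg, replace = TRUE, prob = loci$pop_freq)
    j <- stats::runif(n_cma_bg, 0, cfg$cma_probe_jitter)
    bg <- data.frame(case_id = case_id, chrom = loci$chrom[pick],
                     outer_start = pmax(0, loci$start[pick] - j),
                     inner_start = loci$start[pick] + 500,
                     inner_end = loci$end[pick] - 500,
                     outer_end = loci$end[pick] + j,
                     state = loci$state[pick], classification = "benign",
                     stringsAsFactors = FALSE)
    cma <- rbind(cma, bg)
  }

  seg_rows$hypervariable <- overlaps_track(seg_rows, resources$hypervariable)
  seg_rows <- data.frame(case_id = case_id, seg_rows, stringsAsFactors = FALSE)
  seg_rows <- seg_rows[order(seg_rows$chrom, seg_rows$start), ]
  rownames(seg_rows) <- NULL

  # ---- junction SV events -------------------------------------------------
  n_sv <- stats::rpois(1, cfg$scale * cfg$sv_count_mean)
  sv_sizes <- pmin(pmax(50, round(stats::rlnorm(n_sv, log(cfg$sv_median_size), 1.1))),
                   75000)
  sv <- place_intervals(n_sv, sv_sizes, cfg$sv_exonic_frac, resources)
  sv$type <- sample(c("deletion", "tandem_duplication", "inversion"),
                    max(n_sv, 0), replace = TRUE, prob = c(0.60, 0.35, 0.05))
  low_support <- stats::runif(max(n_sv, 0)) < 0.2
  sv$support <- ifelse(low_support, sample(5:19, max(n_sv, 0), replace = TRUE),
                       stats::rpois(max(n_sv, 0), 45))
  sv <- data.frame(case_id = case_id, sv, stringsAsFactors = FALSE)

  case_row <- data.frame(case_id = case_id, sex = sex,
                         age = round(stats::runif(1, 0.5, 17.5), 1),
                         hpo_terms = paste(case_terms, collapse = ","),
                         consent_secondary = stats::runif(1) >= cfg$opt_out_rate,
                         consanguinity = stats::runif(1) < 0.08,
                         stringsAsFactors = FALSE)

  list(variants = variants, cnv_segments = seg_rows, sv_events = sv,
       cma_calls = cma, case = case_row,
       manifest = if (length(manifest)) do.call(rbind, manifest) else NULL)
}

#' Simulate a full cohort with ground-truth manifest
#'
#' Assigns planted scenarios to \code{diagnosed_frac} of cases (cycling
#' through the dominant, recessive homozygous, compound-heterozygous,
#' asserted-missense, X-linked and pathogenic-CNV classes), plants secondary
#' panel variants at \code{secondary_rate}, and concatenates all per-case
#' outputs.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return list of class \code{wgsdx_cohort} with \code{cases}, \code{variants},
#'   \code{cnv_segments}, \code{sv_events}, \code{cma_calls}, \code{manifest},
#'   \code{resources} and \code{cfg}.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  resources <- generate_resources(cfg, seed = cfg$seed)
  n <- cfg$cohort_n
  types <- c("AD_het_lof", "AR_hom", "AR_compound_het",
             "AD_het_missense_asserted", "XL_hemizygous", "CNV_pathogenic")
  n_planted <- round(cfg$diagnosed_frac * n)
  scen <- rep("none", n)
  if (n_planted > 0) scen[seq_len(n_planted)] <- rep_len(types, n_planted)
  scen <- sample(scen)   # shuffle which cases carry scenarios
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.57, 0.43))
  sex[scen == "XL_hemizygous"] <- "M"
  plant_sec <- stats::runif(n) < cfg$secondary_rate
  ids <- sprintf("S%04d", seq_len(n))

  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((cfg$seed * 10007L + i) %% .Machine$integer.max)
    out[[i]] <- generate_case(cfg, resources, scen[i], ids[i], sex[i],
                              plant_secondary = plant_sec[i])
  }
  bind <- function(f) do.call(rbind, lapply(out, function(x) x[[f]]))
  structure(list(cases = bind("case"), variants = bind("variants"),
                 cnv_segments = bind("cnv_segments"), sv_events = bind("sv_events"),
                 cma_calls = bind("cma_calls"), manifest = bind("manifest"),
                 resources = resources, cfg = cfg),
            class = "wgsdx_cohort")
}

#' @export
print.wgsdx_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d cases, %d variants, %d CNV rows, %d SV rows, %d planted scenarios\n",
              nrow(x$cases), nrow(x$variants), nrow(x$cnv_segments),
              nrow(x$sv_events),
              if (is.null(x$manifest)) 0L else nrow(x$manifest)))
  invisible(x)
}
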