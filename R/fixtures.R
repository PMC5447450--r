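#' Packaged worked-example fixtures
#'
#' Machine-readable encodings of the published diagnosis and
#' secondary-finding tables of the 100-patient paediatric WGS cohort this
#' package models, plus a synthetic stand-in cohort table consistent with the
#' published marginal counts (the per-case phenotype profiles were never
#' printed). Printed 1-based inclusive coordinates are converted to the
#' package-internal 0-based half-open convention at the accessor boundary.
#'
#' @name fixtures
NULL

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "wgsdx")
  if (!nzchar(p)) stop("missing packaged fixture: ", name)
  p
}

#' @rdname fixtures
#' @return \code{paper_table2()}: CNV diagnoses (9 rows, 8 cases) with both
#'   microarray and read-depth coordinates.
#' @export
paper_table2 <- function() {
  df <- utils::read.delim(fixture_path("table2_cnv_diagnoses.tsv"),
                          stringsAsFactors = FALSE)
  df$case_id <- as.character(df$case_id)
  df
}

#' @rdname fixtures
#' @return \code{paper_table3()}: sequence-level diagnoses (30 rows, 28 cases).
#' @export
paper_table3 <- function() {
  df <- utils::read.delim(fixture_path("table3_snv_diagnoses.tsv"),
                          stringsAsFactors = FALSE)
  df$case_id <- as.character(df$case_id)
  df
}

#' @rdname fixtures
#' @return \code{paper_table4()}: secondary findings (7 rows).
#' @export
paper_table4 <- function() {
  df <- utils::read.delim(fixture_path("table4_secondary_findings.tsv"),
                          stringsAsFactors = FALSE)
  df$case_id <- as.character(df$case_id)
  df
}

map_origin <- function(x) {
  m <- c(DN = "de_novo", MA = "maternal", P = "paternal",
         `MA/P` = "maternal+paternal", `N/A` = NA_character_)
  unname(m[x])
}

#' Diagnosis records derived from the printed tables
#'
#' One row per accepted molecular diagnosis: CNV diagnoses keyed by their
#' microarray region label, sequence-level diagnoses by gene symbol.
#'
#' @return data.frame with \code{case_id, locus_id, variant_type, moi,
#'   origin, category}.
#' @export
paper_diagnoses <- function() {
  t2 <- paper_table2()
  t3 <- paper_table3()
  cnv <- data.frame(case_id = t2$case_id,
                    locus_id = t2$locus,
                    variant_type = "CNV",
                    moi = "AD",
                    origin = map_origin(t2$origin),
                    category = t2$category,
                    stringsAsFactors = FALSE)
  snv <- data.frame(case_id = t3$case_id,
                    locus_id = t3$gene,
                    variant_type = "SNV",
                    moi = t3$moi,
                    origin = map_origin(t3$origin),
                    category = t3$category,
                    stringsAsFactors = FALSE)
  rbind(cnv, snv)
}

#' CMA calls and WGS records encoding the printed pathogenic CNVs
#'
#' The printed table gives one coordinate pair per platform, so the probe
#' uncertainty windows collapse (outer = inner).
#'
#' @return list with \code{cma_calls} and \code{wgs_records} data.frames in
#'   0-based half-open coordinates.
#' @export
paper_table2_concordance <- function() {
  t2 <- paper_table2()
  cma <- data.frame(case_id = t2$case_id, chrom = t2$chrom,
                    outer_start = t2$cma_start - 1L, inner_start = t2$cma_start - 1L,
                    inner_end = t2$cma_end, outer_end = t2$cma_end,
                    state = t2$state, classification = "pathogenic",
                    stringsAsFactors = FALSE)
  cma$start <- cma$outer_start; cma$end <- cma$outer_end
  cma$source <- "microarray"
  wgs <- data.frame(case_id = t2$case_id, chrom = t2$chrom,
                    start = t2$wgs_start - 1L, end = t2$wgs_end,
                    copy_state = ifelse(t2$state == "gain", 3L, 1L),
                    state = t2$state, source = "read_depth",
                    stringsAsFactors = FALSE)
  list(cma_calls = cma, wgs_records = wgs)
}

#' Annotated variant records for the secondary-findings screen
#'
#' Encodes the seven printed actionable variants (panel genes, asserted
#' pathogenic, rare) together with \code{n_decoys} variants that each fail at
#' least one screen criterion: non-panel genes with pathogenic assertions,
#' unasserted non-LoF variants in panel genes, benign-asserted panel-gene
#' variants, and common asserted panel-gene variants. Positions are synthetic
#' placeholders (the screen never uses coordinates).
#'
#' @param n_decoys number of decoy variants (default 24, minimum 20).
#' @return annotated variant data.frame; the true findings carry
#'   \code{is_true_finding = TRUE}.
#' @export
secondary_screen_fixture <- function(n_decoys = 24L) {
  if (n_decoys < 20L) stop("need at least 20 decoys")
  t4 <- paper_table4()
  base <- function(case_id, gene, effect, clinvar, hgmd, freq, truth) {
    n <- length(case_id)
    data.frame(case_id = case_id, chrom = "chr1",
               pos = seq_len(n) * 1000L,
               ref = "A", alt = "G", zygosity = "het",
               read_depth = 40L, genotype_quality = 60L, allele_fraction = 0.5,
               gene = gene, effect_class = effect,
               freq_db = freq,
               damaging_predictor_count = 3L, predictor_total = 4L,
               splice_delta = NA_real_,
               assertion_clinvar = clinvar, assertion_hgmd = hgmd,
               mouse_phenotype_flag = FALSE,
               is_true_finding = truth, stringsAsFactors = FALSE)
  }
  truth <- base(t4$case_id, t4$gene, "missense", "pathogenic", "none",
                NA_real_, TRUE)
  truth$pos <- 10000L + seq_len(nrow(truth))
  k <- ceiling(n_decoys / 4)
  decoy_genes_off_panel <- paste0("DECOY", seq_len(k))
  d1 <- base(sprintf("2%03d", seq_len(k)), decoy_genes_off_panel,
             "missense", "pathogenic", "none", NA_real_, FALSE)   # wrong gene
  d2 <- base(sprintf("3%03d", seq_len(k)), rep_len(c("BRCA1", "MYH7", "TP53"), k),
             "missense", "none", "none", 0.001, FALSE)            # non-LoF, unasserted
  d3 <- base(sprintf("4%03d", seq_len(k)), rep_len(c("LDLR", "PKP2"), k),
             "missense", "benign", "none", 0.002, FALSE)          # benign assertion
  d4 <- base(sprintf("5%03d", seq_len(n_decoys - 3L * k)),
             rep_len(c("KCNQ1", "APC"), n_decoys - 3L * k),
             "missense", "pathogenic", "none", 0.12, FALSE)       # common allele
  out <- rbind(truth, d1, d2, d3, d4)
  out$pos <- seq_len(nrow(out)) * 137L
  rownames(out) <- NULL
  out
}

#' Minimal fixed phenotype ontology for the worked-example cohort
#'
#' A single root, top-level system categories mirroring the published cohort
#' description, and a few leaf terms per category.
#'
#' @return a \code{wgsdx_ontology}.
#' @export
fixture_ontology <- function() {
  root <- "HP:0000118"
  cats <- c(developmental_delay = "HP:0012758",
            nervous_system = "HP:0000707",
            skeletal = "HP:0000924",
            growth = "HP:0001507",
            eye = "HP:0000478",
            cardiovascular = "HP:0001626",
            musculature = "HP:0003011",
            connective_tissue = "HP:0003549")
  leaves <- list(`HP:0012758` = c("HP:0001263", "HP:0000750"),
                 `HP:0000707` = c("HP:0001250", "HP:0001252"),
                 `HP:0000924` = c("HP:0002652", "HP:0002650"),
                 `HP:0001507` = c("HP:0004322", "HP:0001508"),
                 `HP:0000478` = c("HP:0000545", "HP:0000505"),
                 `HP:0001626` = c("HP:0001631", "HP:0001635"),
                 `HP:0003011` = c("HP:0003560", "HP:0003198"),
                 `HP:0003549` = c("HP:0000974", "HP:0001382"))
  edges <- data.frame(child = unname(cats), parent = root,
                      stringsAsFactors = FALSE)
  # developmental delay nests inside the nervous-system branch as in HPO
  edges$parent[edges$child == "HP:0012758"] <- "HP:0000707"
  for (p in names(leaves))
    edges <- rbind(edges, data.frame(child = leaves[[p]], parent = p,
                                     stringsAsFactors = FALSE))
  ontology_graph(edges, cats)
}

#' Synthetic 100-case cohort table (stand-in)
#'
#' The published study never prints per-case phenotype profiles, so this
#' cohort table is a SYNTHETIC reconstruction consistent with the printed
#' marginals: the 34 diagnosed case IDs are the printed ones, exactly 57
#' cases carry a developmental-delay term with exactly 22 of them diagnosed
#' (yield 38.6\%), 26 cases opt out of secondary findings and 8 report
#' consanguinity. Membership is chosen deterministically in sorted case-ID
#' order. Not real patient data.
#'
#' @return data.frame with \code{case_id, sex, hpo_terms, consent_secondary,
#'   consanguinity}.
#' @export
synthetic_cohort_fixture <- function() {
  t2 <- paper_table2(); t3 <- paper_table3(); t4 <- paper_table4()
  diagnosed <- sort(unique(c(t2$case_id, t3$case_id)))
  secondary_only <- sort(setdiff(t4$case_id, diagnosed))
  known_sex <- c(stats::setNames(t2$sex, t2$case_id),
                 stats::setNames(t3$sex, t3$case_id),
                 stats::setNames(t4$sex, t4$case_id))
  used <- c(diagnosed, secondary_only)
  fillers <- setdiff(sprintf("1%03d", 1:150), used)[seq_len(100L - length(used))]
  ids <- sort(c(used, fillers))
  sex <- ifelse(ids %in% names(known_sex), known_sex[ids],
                rep_len(c("M", "F"), length(ids)))
  dd_diag <- sort(diagnosed)[1:22]
  undiag <- sort(setdiff(ids, diagnosed))
  dd_undiag <- undiag[1:35]
  dd <- ids %in% c(dd_diag, dd_undiag)
  hpo <- ifelse(dd, "HP:0001263,HP:0002652", "HP:0000545,HP:0002652")
  opt_out <- rev(sort(setdiff(ids, c(diagnosed, secondary_only))))[1:26]
  consang <- sort(ids[grepl("^1", ids)])[seq(5, by = 12, length.out = 8)]
  data.frame(case_id = ids, sex = unname(sex), hpo_terms = hpo,
             consent_secondary = !(ids %in% opt_out),
             consanguinity = ids %in% consang,
             stringsAsFactors = FALSE)
}
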