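#' Readers and writers for interchange formats
#'
#' VCF 4.2 for per-case small-variant calls (read through Bioconductor's
#' VariantAnnotation, multiallelic records split per alternate allele);
#' headered TSVs for segments, SV events, CMA calls, annotations and tables;
#' 3-column BED for genomic tracks. All genomic intervals are 0-based
#' half-open internally; VCF positions are 1-based and converted at the
#' boundary. Readers reject malformed input rather than coercing silently.
#'
#' @name io
NULL

#' Write per-case variant calls as single-sample VCF 4.2
#'
#' @param variants variant data.frame (call fields; annotation columns are
#'   ignored -- annotations travel in a sidecar TSV).
#' @param path output file.
#' @param sample_name sample column name (defaults to the case id).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(variants, path, sample_name = NULL) {
  sample_name <- sample_name %||% as.character(variants$case_id[1] %||% "SAMPLE")
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  gt <- c(het = "0/1", hom = "1/1", hemizygous = "1")[v$zygosity]
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", unique(v$chrom), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
              '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
              '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Allele fraction">',
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample_name, sep = "\t"))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                "GT:DP:GQ:AF",
                paste(gt, v$read_depth, v$genotype_quality,
                      sprintf("%.6g", v$allele_fraction), sep = ":"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a single-sample VCF into the variant data.frame layout
#'
#' Multiallelic records are split into one row per alternate allele. Genotype
#' to zygosity: 0/1 (or 0|1) het, 1/1 hom, haploid 1 hemizygous.
#'
#' @param path VCF file.
#' @param case_id case identifier to stamp on the rows (defaults to the VCF
#'   sample name).
#' @return data.frame with the call fields.
#' @export
read_vcf <- function(path, case_id = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT[, 1]
  if (any(is.na(gt) | gt %in% c(".", "./.")))
    stop("read_vcf: missing genotype at ",
         paste(head(names(gt)[is.na(gt) | gt %in% c(".", "./.")], 3L), collapse = ", "))
  zyg_map <- c("0/1" = "het", "0|1" = "het", "1/0" = "het", "1|0" = "het",
               "1/1" = "hom", "1|1" = "hom", "1" = "hemizygous")
  zyg <- zyg_map[gt]
  if (any(is.na(zyg)))
    stop("read_vcf: unsupported genotype(s): ",
         paste(unique(gt[is.na(zyg)]), collapse = ", "))
  sample_name <- colnames(vcf)[1]
  af <- VariantAnnotation::geno(vcf)$AF
  data.frame(case_id = case_id %||% sample_name,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(rr$REF),
             alt = as.character(rr$ALT),
             zygosity = unname(zyg),
             read_depth = as.integer(VariantAnnotation::geno(vcf)$DP[, 1]),
             genotype_quality = as.integer(VariantAnnotation::geno(vcf)$GQ[, 1]),
             allele_fraction = as.numeric(af[, 1]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read genomic intervals of a given kind
#'
#' \code{kind = "bed"}: 3+ column BED, no header, 0-based half-open.
#' \code{"segments"}, \code{"sv"}, \code{"cma"}: the headered TSVs consumed
#' by \code{\link{parse_read_depth_segments}}, \code{\link{parse_sv_events}}
#' and \code{\link{read_cma_calls}} (validated, unfiltered for bed; the
#' typed kinds delegate to their parsers, which filter).
#'
#' @param path input file.
#' @param kind one of "bed", "segments", "sv", "cma".
#' @param cfg thresholds for the typed parsers.
#' @return data.frame.
#' @export
read_intervals <- function(path, kind = c("bed", "segments", "sv", "cma"),
                           cfg = threshold_config()) {
  kind <- match.arg(kind)
  switch(kind,
    bed = {
      df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(df) < 3L) stop("BED: need at least 3 columns")
      names(df)[1:3] <- c("chrom", "start", "end")
      bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
      if (length(bad)) stop("BED: malformed interval at line(s) ",
                            paste(head(bad, 5L), collapse = ", "))
      check_chroms(df$chrom, "BED")
      df[1:3]
    },
    segments = parse_read_depth_segments(path, cfg),
    sv = parse_sv_events(path, cfg),
    cma = read_cma_calls(path))
}

write_bed <- function(df, path) {
  utils::write.table(df[c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory tree
#'
#' Lays out resources (TSV/BED), one VCF plus annotation sidecar TSV per
#' case, per-case CNV segment and SV event TSVs, pooled CMA calls, the
#' cohort table and the ground-truth manifest -- exactly the formats the
#' pipeline readers consume.
#'
#' @param cohort a \code{wgsdx_cohort} from \code{\link{simulate_cohort}}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_cohort_files <- function(cohort, dir) {
  rdir <- file.path(dir, "resources"); cdir <- file.path(dir, "cases")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  res <- cohort$resources
  write_tsv(res$disease_genes, file.path(rdir, "disease_genes.tsv"))
  write_tsv(res$gene_models$transcripts, file.path(rdir, "transcripts.tsv"))
  write_tsv(res$gene_models$exons, file.path(rdir, "exons.tsv"))
  write_bed(res$segdup, file.path(rdir, "segdup.bed"))
  write_bed(res$hypervariable, file.path(rdir, "hypervariable.bed"))
  write_tsv(res$syndromic_regions, file.path(rdir, "syndromic_regions.tsv"))
  write_tsv(res$control_cnvs, file.path(rdir, "control_cnvs.tsv"))
  write_tsv(res$ontology$edges, file.path(rdir, "ontology_edges.tsv"))
  write_tsv(data.frame(label = names(res$ontology$categories),
                       term = unname(res$ontology$categories)),
            file.path(rdir, "ontology_categories.tsv"))
  write_tsv(res$panel, file.path(rdir, "panel.tsv"))
  write_tsv(cohort$cases, file.path(dir, "cases.tsv"))
  if (!is.null(cohort$cma_calls))
    write_tsv(cohort$cma_calls, file.path(dir, "cma_calls.tsv"))
  if (!is.null(cohort$manifest))
    write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"))
  ann_cols <- c("chrom", "pos", "ref", "alt", "gene", "effect_class",
                grep("^freq_|^cons_", names(cohort$variants), value = TRUE),
                "damaging_predictor_count", "predictor_total", "splice_delta",
                "assertion_clinvar", "assertion_hgmd", "mouse_phenotype_flag")
  for (id in cohort$cases$case_id) {
    v <- cohort$variants[cohort$variants$case_id == id, , drop = FALSE]
    write_vcf(v, file.path(cdir, paste0(id, ".vcf")), sample_name = id)
    write_tsv(v[ann_cols], file.path(cdir, paste0(id, "_annotations.tsv")))
    write_tsv(cohort$cnv_segments[cohort$cnv_segments$case_id == id, , drop = FALSE],
              file.path(cdir, paste0(id, "_cnv.tsv")))
    write_tsv(cohort$sv_events[cohort$sv_events$case_id == id, , drop = FALSE],
              file.path(cdir, paste0(id, "_sv.tsv")))
  }
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' Inverse of \code{\link{write_cohort_files}}; per-case variants are
#' rebuilt by joining each VCF with its annotation sidecar.
#'
#' @param dir cohort directory.
#' @return list shaped like a \code{wgsdx_cohort} (without \code{cfg}).
#' @export
read_cohort_dir <- function(dir) {
  rdir <- file.path(dir, "resources"); cdir <- file.path(dir, "cases")
  edges <- utils::read.delim(file.path(rdir, "ontology_edges.tsv"),
                             stringsAsFactors = FALSE)
  cats <- utils::read.delim(file.path(rdir, "ontology_categories.tsv"),
                            stringsAsFactors = FALSE)
  resources <- structure(list(
    gene_models = list(
      transcripts = utils::read.delim(file.path(rdir, "transcripts.tsv"),
                                      stringsAsFactors = FALSE),
      exons = utils::read.delim(file.path(rdir, "exons.tsv"),
                                stringsAsFactors = FALSE)),
    disease_genes = utils::read.delim(file.path(rdir, "disease_genes.tsv"),
                                      stringsAsFactors = FALSE),
    segdup = read_intervals(file.path(rdir, "segdup.bed"), "bed"),
    hypervariable = read_intervals(file.path(rdir, "hypervariable.bed"), "bed"),
    syndromic_regions = utils::read.delim(file.path(rdir, "syndromic_regions.tsv"),
                                          stringsAsFactors = FALSE),
    control_cnvs = utils::read.delim(file.path(rdir, "control_cnvs.tsv"),
                                     stringsAsFactors = FALSE),
    panel = read_tsv_checked(file.path(rdir, "panel.tsv"),
                             c("gene", "inheritance", "condition"), "panel"),
    ontology = ontology_graph(edges, stats::setNames(cats$term, cats$label))),
    class = "wgsdx_resources")
  cases <- utils::read.delim(file.path(dir, "cases.tsv"),
                             stringsAsFactors = FALSE)
  cases$case_id <- as.character(cases$case_id)
  variants <- list(); cnv <- list(); sv <- list()
  for (id in cases$case_id) {
    calls <- read_vcf(file.path(cdir, paste0(id, ".vcf")), case_id = id)
    ann <- utils::read.delim(file.path(cdir, paste0(id, "_annotations.tsv")),
                             stringsAsFactors = FALSE)
    variants[[id]] <- annotate_variants(calls, ann)
    cnv[[id]] <- utils::read.delim(file.path(cdir, paste0(id, "_cnv.tsv")),
                                   stringsAsFactors = FALSE)
    sv[[id]] <- utils::read.delim(file.path(cdir, paste0(id, "_sv.tsv")),
                                  stringsAsFactors = FALSE)
  }
  cma_path <- file.path(dir, "cma_calls.tsv")
  man_path <- file.path(dir, "manifest.tsv")
  fix_id <- function(df) { df$case_id <- as.character(df$case_id); df }
  list(cases = cases,
       variants = fix_id(do.call(rbind, variants)),
       cnv_segments = fix_id(do.call(rbind, cnv)),
       sv_events = fix_id(do.call(rbind, sv)),
       cma_calls = if (file.exists(cma_path))
         fix_id(utils::read.delim(cma_path, stringsAsFactors = FALSE)) else NULL,
       manifest = if (file.exists(man_path))
         fix_id(utils::read.delim(man_path, stringsAsFactors = FALSE)) else NULL,
       resources = resources)
}

#' Read a pipeline run configuration (JSON, or YAML when available)
#'
#' Unknown top-level keys are rejected.
#'
#' @param path config file (.json, .yml/.yaml).
#' @return named list with \code{input_dir}, \code{out_dir}, \code{thresholds},
#'   \code{stages}.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- c("input_dir", "out_dir", "thresholds", "stages", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$input_dir) || is.null(cfg$out_dir))
    stop("config must name input_dir and out_dir")
  cfg$stages <- cfg$stages %||% c("prioritize", "cnv", "secondary", "stats")
  cfg
}
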