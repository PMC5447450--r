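#' CNV and SV parsing, annotation and classification
#'
#' Unbalanced variants are plain data.frames (one row per record) with
#' 0-based half-open coordinates: \code{case_id, chrom, start, end, state}
#' ("gain"/"loss") and a \code{source} tag ("read_depth", "junction",
#' "microarray"). Read-depth records keep \code{copy_state}; junction records
#' keep \code{support}. Microarray calls additionally carry probe-bounded
#' breakpoints \code{outer_start <= inner_start < inner_end <= outer_end}.
#'
#' @name cnv
NULL

CHROM_RE <- "^(chr)?([0-9]+|X|Y|MT?)$"

check_chroms <- function(chrom, where = "input") {
  bad <- which(is.na(chrom) | !grepl(CHROM_RE, chrom))
  if (length(bad))
    stop(sprintf("%s: unknown chromosome at line(s) %s", where,
                 paste(head(bad, 5L), collapse = ", ")))
  invisible(TRUE)
}

is_chrY <- function(chrom) sub("^chr", "", chrom) == "Y"

read_tsv_checked <- function(file, required, where) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", where, paste(miss, collapse = ", ")))
  df
}

cnv_granges <- function(records) {
  GenomicRanges::GRanges(records$chrom,
                         IRanges::IRanges(start = records$start + 1L,
                                          end = records$end))
}

#' Parse and filter read-depth CNV segments
#'
#' Accepts a headered TSV (or equivalent data.frame) with columns
#' \code{case_id, chrom, start, end, copy_state, hypervariable}. Retains
#' segments with a non-diploid copy state, outside hypervariable regions and
#' off chromosome Y; gains are copy state > 2, losses < 2.
#'
#' @param file path or data.frame.
#' @param cfg a \code{\link{threshold_config}} (unused thresholds ignored).
#' @return CNV record data.frame with \code{source = "read_depth"}.
#' @export
parse_read_depth_segments <- function(file, cfg = threshold_config()) {
  df <- if (is.data.frame(file)) file else
    read_tsv_checked(file, c("case_id", "chrom", "start", "end",
                             "copy_state", "hypervariable"),
                     "read-depth segments")
  req <- c("case_id", "chrom", "start", "end", "copy_state", "hypervariable")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("read-depth segments: missing column(s) ",
                         paste(miss, collapse = ", "))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end |
                 is.na(df$copy_state) | df$copy_state < 0)
  if (length(bad))
    stop("read-depth segments: malformed row(s) at line(s) ",
         paste(head(bad, 5L), collapse = ", "))
  check_chroms(df$chrom, "read-depth segments")
  keep <- df$copy_state != 2L & !as.logical(df$hypervariable) & !is_chrY(df$chrom)
  out <- df[keep, req, drop = FALSE]
  out$state <- ifelse(out$copy_state > 2L, "gain", "loss")
  out$source <- "read_depth"
  out$hypervariable <- NULL
  rownames(out) <- NULL
  out
}

#' Merge fragmented read-depth segments
#'
#' The read-depth caller can split one event into fragments; adjacent records
#' of the same case, chromosome and state separated by at most \code{gap_max}
#' bp are merged into a single spanning record. Idempotent; covered bases only
#' change by gap filling.
#'
#' @param records CNV record data.frame.
#' @param gap_max maximum gap bridged (bp); default from \code{cfg}.
#' @param cfg a \code{\link{threshold_config}}.
#' @return merged record data.frame, sorted by (case, chrom, start).
#' @export
merge_fragmented_segments <- function(records, gap_max = NULL,
                                      cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  gap_max <- gap_max %||% cfg$merge_gap_max
  if (nrow(records) == 0L) return(records)
  ord <- order(records$case_id, records$chrom, records$state, records$start)
  r <- records[ord, , drop = FALSE]
  key <- paste(r$case_id, r$chrom, r$state, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    g <- r[key == k, , drop = FALSE]
    cur <- g[1, , drop = FALSE]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] - cur$end <= gap_max) {
        cur$end <- max(cur$end, g$end[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- g[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  merged <- do.call(rbind, out)
  merged <- merged[order(merged$case_id, merged$chrom, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Parse and filter junction-based SV events
#'
#' Accepts a headered TSV (or data.frame) with columns \code{case_id, chrom,
#' start, end, type, support}. Retains deletions and tandem duplications with
#' mate-pair support of at least \code{sv_support_min}, off chromosome Y.
#'
#' @param file path or data.frame.
#' @param cfg a \code{\link{threshold_config}}.
#' @return CNV record data.frame with \code{source = "junction"} (deletions as
#'   losses, tandem duplications as gains).
#' @export
parse_sv_events <- function(file, cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  req <- c("case_id", "chrom", "start", "end", "type", "support")
  df <- if (is.data.frame(file)) file else read_tsv_checked(file, req, "SV events")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("SV events: missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end |
                 is.na(df$support) | df$support < 0)
  if (length(bad))
    stop("SV events: malformed row(s) at line(s) ",
         paste(head(bad, 5L), collapse = ", "))
  check_chroms(df$chrom, "SV events")
  keep <- df$type %in% c("deletion", "tandem_duplication") &
    df$support >= cfg$sv_support_min & !is_chrY(df$chrom)
  out <- df[keep, req, drop = FALSE]
  out$state <- ifelse(out$type == "deletion", "loss", "gain")
  out$source <- "junction"
  rownames(out) <- NULL
  out
}

#' Reciprocal overlap between two intervals
#'
#' min(|a intersect b| / |a|, |a intersect b| / |b|) on 0-based half-open
#' intervals; 0 when disjoint or on different chromosomes; symmetric;
#' vectorised over all arguments.
#'
#' @param a_start,a_end,b_start,b_end interval bounds (half-open).
#' @param same_chrom logical; FALSE forces 0 (recycled).
#' @return numeric fraction(s) in \[0, 1\].
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end, same_chrom = TRUE) {
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  ro <- pmin(inter / (a_end - a_start), inter / (b_end - b_start))
  ifelse(rep_len(same_chrom, length(ro)), ro, 0)
}

# For each query record, the fraction of distinct samples in `dataset` that
# carry a same-state record with reciprocal overlap >= ro_min. The query's own
# case never counts towards its own frequency (a variant unique to one sample
# must have frequency 0, whatever the cohort size).
cnv_frequency_against <- function(records, dataset, n_samples, cfg) {
  freq <- numeric(nrow(records))
  if (nrow(records) == 0L || is.null(dataset) || nrow(dataset) == 0L) return(freq)
  if (n_samples <= 0L) {
    warning("empty control/comparison set; frequencies set to 0")
    return(freq)
  }
  hits <- quiet_overlaps(cnv_granges(records), cnv_granges(dataset))
  if (length(hits) == 0L) return(freq)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ro <- reciprocal_overlap(records$start[q], records$end[q],
                           dataset$start[s], dataset$end[s])
  ok <- ro >= cfg$reciprocal_overlap_min & records$state[q] == dataset$state[s]
  if ("case_id" %in% names(dataset) && "case_id" %in% names(records))
    ok <- ok & dataset$case_id[s] != records$case_id[q]
  if (!any(ok)) return(freq)
  sample_col <- if ("sample_id" %in% names(dataset)) "sample_id" else "case_id"
  counts <- tapply(dataset[[sample_col]][s[ok]], q[ok],
                   function(x) length(unique(x)))
  freq[as.integer(names(counts))] <- as.numeric(counts) / n_samples
  freq
}

#' Annotate CNV records with control frequency and DGV-style overlap
#'
#' \code{control_freq} is the fraction of control samples carrying a
#' same-state CNV at reciprocal overlap of at least
#' \code{reciprocal_overlap_min}; \code{dgv_overlap} is TRUE when any
#' qualifying same-state overlap exists with the population-variant set.
#'
#' @param records CNV record data.frame.
#' @param control_set control CNVs (\code{sample_id, chrom, start, end, state}).
#' @param dgv_like_set population CNVs (\code{chrom, start, end, state}), or NULL.
#' @param n_control number of control samples (defaults to distinct sample ids
#'   in \code{control_set}).
#' @param cfg a \code{\link{threshold_config}}.
#' @return records with \code{control_freq} and \code{dgv_overlap} appended.
#' @export
annotate_cnv_frequency <- function(records, control_set, dgv_like_set = NULL,
                                   n_control = NULL, cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  if (is.null(control_set) || nrow(control_set) == 0L) {
    warning("empty control set; control_freq set to 0")
    records$control_freq <- 0
  } else {
    n_control <- n_control %||% length(unique(control_set$sample_id))
    records$control_freq <-
      cnv_frequency_against(records, control_set, n_control, cfg)
  }
  records$dgv_overlap <- FALSE
  if (!is.null(dgv_like_set) && nrow(dgv_like_set) > 0L && nrow(records) > 0L) {
    hits <- quiet_overlaps(cnv_granges(records), cnv_granges(dgv_like_set))
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      ro <- reciprocal_overlap(records$start[q], records$end[q],
                               dgv_like_set$start[s], dgv_like_set$end[s])
      ok <- ro >= cfg$reciprocal_overlap_min &
        records$state[q] == dgv_like_set$state[s]
      records$dgv_overlap[unique(q[ok])] <- TRUE
    }
  }
  records
}

#' Annotate CNV records with overlapping genes and exons
#'
#' @param records CNV record data.frame.
#' @param gene_models list with \code{transcripts} (\code{gene, chrom, start,
#'   end}) and \code{exons} (\code{gene, chrom, start, end}), half-open.
#' @return records with \code{genes_hit} (comma-joined symbols, "" if none)
#'   and \code{exons_hit} (logical) appended.
#' @export
annotate_gene_exon_overlap <- function(records, gene_models) {
  records$genes_hit <- ""
  records$exons_hit <- FALSE
  if (nrow(records) == 0L) return(records)
  gr <- cnv_granges(records)
  tx <- gene_models$transcripts
  if (!is.null(tx) && nrow(tx) > 0L) {
    hits <- quiet_overlaps(gr, cnv_granges(tx))
    if (length(hits)) {
      sym <- tapply(tx$gene[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(x) paste(sort(unique(x)), collapse = ","))
      records$genes_hit[as.integer(names(sym))] <- as.character(sym)
    }
  }
  ex <- gene_models$exons
  if (!is.null(ex) && nrow(ex) > 0L) {
    hits <- quiet_overlaps(gr, cnv_granges(ex))
    records$exons_hit[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  records
}

#' Classify a CNV record
#'
#' Deterministic rule table, first match wins:
#' \enumerate{
#'   \item same-state reciprocal overlap >= \code{reciprocal_overlap_min}
#'     with a known syndromic region -> pathogenic;
#'   \item control frequency >= \code{cnv_freq_exclude} or population-variant
#'     overlap -> benign;
#'   \item exonic hit of a dominant disease gene (a loss, or a gain of a
#'     dosage-sensitive/LoF-mechanism gene), rare and not in the population
#'     set -> likely_pathogenic;
#'   \item otherwise VUS.
#' }
#'
#' @param records annotated CNV record data.frame (frequency and gene
#'   annotation applied).
#' @param syndromic_regions data.frame (\code{chrom, start, end, state, name}).
#' @param disease_genes disease-gene table.
#' @param cfg a \code{\link{threshold_config}}.
#' @return records with \code{classification} appended.
#' @export
classify_cnv <- function(records, syndromic_regions, disease_genes,
                         cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  n <- nrow(records)
  if (n == 0L) { records$classification <- character(); return(records) }
  if (!all(c("control_freq", "dgv_overlap", "genes_hit", "exons_hit") %in% names(records)))
    stop("classify_cnv requires frequency and gene annotations")
  syndromic <- rep(FALSE, n)
  if (!is.null(syndromic_regions) && nrow(syndromic_regions) > 0L) {
    hits <- quiet_overlaps(cnv_granges(records),
                                        cnv_granges(syndromic_regions))
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      ro <- reciprocal_overlap(records$start[q], records$end[q],
                               syndromic_regions$start[s], syndromic_regions$end[s])
      ok <- ro >= cfg$reciprocal_overlap_min &
        records$state[q] == syndromic_regions$state[s]
      syndromic[unique(q[ok])] <- TRUE
    }
  }
  common <- records$control_freq >= cfg$cnv_freq_exclude | records$dgv_overlap
  ad_genes <- disease_genes$gene[grepl("AD", disease_genes$inheritance_modes)]
  dosage <- disease_genes$gene[as.logical(disease_genes$lof_mechanism)]
  hit_list <- strsplit(records$genes_hit, ",", fixed = TRUE)
  gene_risk <- vapply(seq_len(n), function(i) {
    g <- hit_list[[i]]
    records$exons_hit[i] && length(g) > 0L &&
      any(g %in% ad_genes & (records$state[i] == "loss" | g %in% dosage))
  }, logical(1))
  records$classification <- ifelse(syndromic, "pathogenic",
                            ifelse(common, "benign",
                            ifelse(gene_risk, "likely_pathogenic", "VUS")))
  records
}

#' Segmental-duplication coverage of CNV records
#'
#' Fraction of each CNV covered by the union of segmental-duplication
#' intervals (coverage of the CNV, not reciprocal, since segdups are small
#' and numerous).
#'
#' @param records CNV record data.frame.
#' @param segdup_track data.frame (\code{chrom, start, end}), half-open.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
segdup_coverage <- function(records, segdup_track) {
  n <- nrow(records)
  cov <- numeric(n)
  if (n == 0L || is.null(segdup_track) || nrow(segdup_track) == 0L) return(cov)
  sd_red <- IRanges::reduce(cnv_granges(segdup_track))
  gr <- cnv_granges(records)
  hits <- quiet_overlaps(gr, sd_red)
  if (length(hits) == 0L) return(cov)
  q <- S4Vectors::queryHits(hits)
  pint <- GenomicRanges::pintersect(gr[q], sd_red[S4Vectors::subjectHits(hits)])
  covered <- tapply(IRanges::width(pint), q, sum)
  cov[as.integer(names(covered))] <-
    as.numeric(covered) / (records$end - records$start)[as.integer(names(covered))]
  pmin(cov, 1)
}
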