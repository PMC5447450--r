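#' Microarray vs sequencing CNV concordance
#'
#' Implements the comparison between clinical microarray (CMA) CNV calls and
#' WGS read-depth CNVs: both sets are pruned of segmental-duplication-ridden
#' and common calls, CMA calls are matched to read-depth records by same-state
#' reciprocal overlap against the CMA outer (maximum) interval, and breakpoint
#' agreement is scored against the probe-bounded boundary windows.
#'
#' @name concordance
NULL

#' Parse CMA calls
#'
#' Headered TSV (or data.frame) with columns \code{case_id, chrom,
#' outer_start, inner_start, inner_end, outer_end, state, classification}.
#' Boundary ordering \code{outer_start <= inner_start < inner_end <=
#' outer_end} is enforced; chromosome-Y calls are dropped.
#'
#' @param file path or data.frame.
#' @return CMA call data.frame with \code{source = "microarray"} and
#'   convenience columns \code{start}/\code{end} set to the outer interval.
#' @export
read_cma_calls <- function(file) {
  req <- c("case_id", "chrom", "outer_start", "inner_start",
           "inner_end", "outer_end", "state", "classification")
  df <- if (is.data.frame(file)) file else read_tsv_checked(file, req, "CMA calls")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("CMA calls: missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(!(df$outer_start <= df$inner_start &
                   df$inner_start < df$inner_end &
                   df$inner_end <= df$outer_end))
  if (length(bad))
    stop("CMA calls: boundary-order violation at line(s) ",
         paste(head(bad, 5L), collapse = ", "))
  check_chroms(df$chrom, "CMA calls")
  df <- df[!is_chrY(df$chrom), , drop = FALSE]
  df$start <- df$outer_start
  df$end <- df$outer_end
  df$source <- "microarray"
  rownames(df) <- NULL
  df
}

#' Exclude unreliable CNVs before concordance
#'
#' Drops records covered at least \code{segdup_cover_exclude} by segmental
#' duplications or at frequency of at least \code{cnv_freq_exclude} in either
#' data set. Idempotent.
#'
#' @param records CNV or CMA record data.frame (uses \code{start}/\code{end}).
#' @param segdup_track segmental-duplication intervals.
#' @param freq_either per-record frequency: a numeric vector, or NULL to
#'   compute via \code{\link{cnv_frequency_against}} from \code{datasets}.
#' @param datasets optional list of record data.frames (each one platform,
#'   with per-sample calls) against which frequency in "either data set" is
#'   computed by same-state reciprocal-overlap cluster counting.
#' @param cfg a \code{\link{threshold_config}}.
#' @return the retained subset, with \code{segdup_cover} and
#'   \code{freq_either} columns attached.
#' @export
filter_for_concordance <- function(records, segdup_track, freq_either = NULL,
                                   datasets = NULL, cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  records$segdup_cover <- segdup_coverage(records, segdup_track)
  if (is.null(freq_either)) {
    freq_either <- numeric(nrow(records))
    for (ds in datasets %||% list()) {
      ns <- length(unique(ds$case_id))
      freq_either <- pmax(freq_either,
                          cnv_frequency_against(records, ds, ns, cfg))
    }
  }
  records$freq_either <- freq_either
  keep <- records$segdup_cover < cfg$segdup_cover_exclude &
    records$freq_either < cfg$cnv_freq_exclude
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match CMA calls to WGS read-depth records
#'
#' A CMA call is "detected by WGS" when a same-case, same-state read-depth
#' record has reciprocal overlap of at least \code{reciprocal_overlap_min}
#' against the CMA outer interval. Each CMA call is matched to at most one
#' WGS record: greatest overlap wins, ties broken by genomic coordinate.
#'
#' @param cma_calls CMA call data.frame (post filtering).
#' @param wgs_records read-depth CNV record data.frame (post filtering,
#'   fragments merged).
#' @param cfg a \code{\link{threshold_config}}.
#' @return object of class \code{wgsdx_concordance}: list with
#'   \code{matched_pairs} (CMA columns prefixed \code{cma_}, WGS columns
#'   \code{wgs_}, plus \code{ro}), \code{unmatched_cma}, \code{n_cma},
#'   \code{n_detected} and \code{detection_rate}.
#' @export
match_cma_wgs <- function(cma_calls, wgs_records, cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  n_cma <- nrow(cma_calls)
  matched <- integer(n_cma)   # 0 = unmatched, else row index into wgs_records
  ro_best <- numeric(n_cma)
  for (i in seq_len(n_cma)) {
    cand <- which(wgs_records$case_id == cma_calls$case_id[i] &
                    wgs_records$chrom == cma_calls$chrom[i] &
                    wgs_records$state == cma_calls$state[i])
    if (length(cand) == 0L) next
    ro <- reciprocal_overlap(cma_calls$outer_start[i], cma_calls$outer_end[i],
                             wgs_records$start[cand], wgs_records$end[cand])
    ok <- ro >= cfg$reciprocal_overlap_min
    if (!any(ok)) next
    cand <- cand[ok]; ro <- ro[ok]
    pick <- cand[order(-ro, wgs_records$start[cand])][1]
    matched[i] <- pick
    ro_best[i] <- ro[order(-ro, wgs_records$start[cand])][1]
  }
  hit <- matched > 0L
  pairs <- if (any(hit)) {
    cma <- cma_calls[hit, , drop = FALSE]
    wgs <- wgs_records[matched[hit], , drop = FALSE]
    names(cma) <- paste0("cma_", names(cma))
    names(wgs) <- paste0("wgs_", names(wgs))
    cbind(cma, wgs, ro = ro_best[hit], row.names = NULL)
  } else data.frame()
  structure(list(matched_pairs = pairs,
                 unmatched_cma = cma_calls[!hit, , drop = FALSE],
                 n_cma = n_cma,
                 n_detected = sum(hit),
                 detection_rate = if (n_cma) sum(hit) / n_cma else NA_real_),
            class = "wgsdx_concordance")
}

#' @export
print.wgsdx_concordance <- function(x, ...) {
  cat(sprintf("CMA vs WGS concordance: %d/%d detected (%.1f%%)\n",
              x$n_detected, x$n_cma, 100 * x$detection_rate))
  invisible(x)
}

#' Breakpoint concordance of matched CMA/WGS pairs
#'
#' For each matched pair, the WGS call is \emph{within boundary} when its
#' start lies in \code{[outer_start, inner_start]} and its end in
#' \code{[inner_end, outer_end]} (the probe-bounded uncertainty windows), and
#' \emph{within window} when both WGS breakpoints are within
#' \code{breakpoint_window} bp of the corresponding boundary interval
#' (within-boundary implies within-window).
#'
#' @param result a \code{wgsdx_concordance} from \code{\link{match_cma_wgs}}.
#' @param cfg a \code{\link{threshold_config}}.
#' @return list with \code{within_boundary_count}, \code{within_window_count},
#'   \code{n_pairs}, \code{within_boundary_rate}, \code{within_window_rate}.
#' @export
breakpoint_concordance <- function(result, cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  p <- result$matched_pairs
  n <- nrow(p)
  if (n == 0L)
    return(list(within_boundary_count = 0L, within_window_count = 0L,
                n_pairs = 0L, within_boundary_rate = NA_real_,
                within_window_rate = NA_real_))
  wb <- p$wgs_start >= p$cma_outer_start & p$wgs_start <= p$cma_inner_start &
    p$wgs_end >= p$cma_inner_end & p$wgs_end <= p$cma_outer_end
  dist_to <- function(x, lo, hi) pmax(0, pmax(lo - x, x - hi))
  w <- cfg$breakpoint_window
  ww <- dist_to(p$wgs_start, p$cma_outer_start, p$cma_inner_start) <= w &
    dist_to(p$wgs_end, p$cma_inner_end, p$cma_outer_end) <= w
  list(within_boundary_count = sum(wb),
       within_window_count = sum(ww),
       n_pairs = n,
       within_boundary_rate = sum(wb) / n,
       within_window_rate = sum(ww) / n)
}
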