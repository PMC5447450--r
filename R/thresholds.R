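#' Pipeline threshold configuration
#'
#' Collects every numeric threshold used by the filtering, tiering and
#' concordance stages. Defaults follow the clinical pipeline this package
#' models: rare means <5\% population allele frequency; junction SVs need at
#' least 20 supporting mate pairs; CNV equivalence is 50\% reciprocal overlap;
#' CNVs covered >=70\% by segmental duplications or at >=3\% frequency in
#' either platform are excluded from concordance; breakpoints within 10 kb of
#' the array boundaries count as near-concordant.
#'
#' @param rare_freq_max maximum population allele frequency for a "rare"
#'   variant (fraction, default 0.05).
#' @param sv_support_min minimum mate-pair support for junction SVs (default 20).
#' @param reciprocal_overlap_min reciprocal-overlap fraction defining CNV
#'   equivalence (default 0.50).
#' @param segdup_cover_exclude segmental-duplication coverage fraction at or
#'   above which a CNV is excluded from concordance (default 0.70).
#' @param cnv_freq_exclude CNV frequency in either data set at or above which
#'   it is excluded (default 0.03).
#' @param breakpoint_window distance in bp within which a WGS breakpoint is
#'   considered near an array boundary (default 10000).
#' @param quality_min_depth,quality_min_gq read depth and genotype quality for
#'   quality tier 1 (defaults 20 and 30).
#' @param quality_tier2_depth read depth for quality tier 2 (default 10).
#' @param het_af_range,hom_af_min allele-fraction windows for tier-1 het and
#'   hom calls.
#' @param splice_delta_min minimum absolute splice-prediction delta treated as
#'   "predicted to impact splicing" (default 0.2).
#' @param conservation_high conservation score (phyloP-like) at or above which
#'   a missense variant is treated as highly conserved (default 2).
#' @param merge_gap_max maximum gap in bp bridged when merging fragmented
#'   read-depth segments (default 10000).
#' @return an object of class \code{wgsdx_thresholds} (a validated list).
#' @export
threshold_config <- function(rare_freq_max = 0.05,
                             sv_support_min = 20L,
                             reciprocal_overlap_min = 0.50,
                             segdup_cover_exclude = 0.70,
                             cnv_freq_exclude = 0.03,
                             breakpoint_window = 10000L,
                             quality_min_depth = 20L,
                             quality_min_gq = 30L,
                             quality_tier2_depth = 10L,
                             het_af_range = c(0.3, 0.7),
                             hom_af_min = 0.85,
                             splice_delta_min = 0.2,
                             conservation_high = 2,
                             merge_gap_max = 10000L) {
  cfg <- list(rare_freq_max = rare_freq_max,
              sv_support_min = as.integer(sv_support_min),
              reciprocal_overlap_min = reciprocal_overlap_min,
              segdup_cover_exclude = segdup_cover_exclude,
              cnv_freq_exclude = cnv_freq_exclude,
              breakpoint_window = as.integer(breakpoint_window),
              quality_min_depth = as.integer(quality_min_depth),
              quality_min_gq = as.integer(quality_min_gq),
              quality_tier2_depth = as.integer(quality_tier2_depth),
              het_af_range = het_af_range,
              hom_af_min = hom_af_min,
              splice_delta_min = splice_delta_min,
              conservation_high = conservation_high,
              merge_gap_max = as.integer(merge_gap_max))
  for (nm in c("rare_freq_max", "reciprocal_overlap_min", "segdup_cover_exclude",
               "cnv_freq_exclude")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(sprintf("threshold '%s' must be a fraction in [0,1]", nm))
  }
  if (cfg$sv_support_min < 0L || cfg$breakpoint_window < 0L)
    stop("count/distance thresholds must be non-negative")
  structure(cfg, class = "wgsdx_thresholds")
}

#' @export
print.wgsdx_thresholds <- function(x, ...) {
  cat("wgsdx threshold configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = "-")))
  invisible(x)
}

as_thresholds <- function(cfg) {
  if (inherits(cfg, "wgsdx_thresholds")) return(cfg)
  if (is.null(cfg)) return(threshold_config())
  if (is.list(cfg)) return(do.call(threshold_config, cfg))
  stop("cfg must be a wgsdx_thresholds object or a named list")
}
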