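#' Secondary (incidental) findings screen
#'
#' Screens annotated variants against a medically actionable gene panel. The
#' default is the 56-gene panel from the 2013 ACMG guidelines on return of
#' incidental findings, shipped as a replaceable TSV.
#'
#' @name secondary
NULL

#' The packaged ACMG-56 medically actionable gene panel
#'
#' @param file optional path to a replacement panel TSV with columns
#'   \code{gene, inheritance, condition}.
#' @return data.frame with 56 rows for the default panel.
#' @export
acmg_panel <- function(file = NULL) {
  file <- file %||% system.file("extdata", "acmg56_panel.tsv", package = "wgsdx")
  read_tsv_checked(file, c("gene", "inheritance", "condition"), "gene panel")
}

#' Screen variants for reportable secondary findings
#'
#' A variant is a finding when its gene is on the panel, it is rare (maximum
#' population frequency below \code{rare_freq_max}) and it either has the
#' highest predicted impact (loss of function: nonsense, frameshift,
#' canonical splice) or is asserted pathogenic/likely pathogenic by either
#' assertion source. Region class is not restricted: asserted-pathogenic UTR,
#' intronic and intergenic variants are eligible. Consent only controls the
#' \code{returnable} flag, never membership. Idempotent: re-screening the
#' returned findings yields the same set.
#'
#' @param case_variants annotated variant data.frame (one or more cases).
#' @param panel gene panel data.frame (see \code{\link{acmg_panel}}).
#' @param consent logical scalar, or named logical vector keyed by case_id.
#' @param cfg a \code{\link{threshold_config}}.
#' @return data.frame of findings: the qualifying variant rows plus
#'   \code{basis} ("LoF" or "asserted_pathogenic") and \code{returnable}.
#' @export
screen_secondary <- function(case_variants, panel = acmg_panel(),
                             consent = TRUE, cfg = threshold_config()) {
  cfg <- as_thresholds(cfg)
  if (is.null(panel) || nrow(panel) == 0L) stop("empty gene panel")
  check_annotated(case_variants)
  mf <- max_pop_freq(case_variants)
  rare <- is.na(mf) | mf < cfg$rare_freq_max
  in_panel <- !is.na(case_variants$gene) & case_variants$gene %in% panel$gene
  lof <- case_variants$effect_class %in% LOF_CLASSES
  asserted <- case_variants$assertion_clinvar %in% c("pathogenic", "likely_pathogenic") |
    case_variants$assertion_hgmd %in% c("pathogenic", "likely_pathogenic")
  keep <- in_panel & rare & (lof | asserted)
  out <- case_variants[keep, , drop = FALSE]
  out$basis <- ifelse(lof[keep], "LoF", "asserted_pathogenic")
  consent_for <- if (length(consent) == 1L && is.null(names(consent)))
    rep(as.logical(consent), nrow(out)) else {
      v <- as.logical(consent[as.character(out$case_id)])
      v[is.na(v)] <- FALSE
      v
    }
  out$returnable <- consent_for
  rownames(out) <- NULL
  out
}
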