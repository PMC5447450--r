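#' Cohort diagnostic-yield statistics
#'
#' Diagnoses are data.frames with one row per accepted molecular diagnosis:
#' \code{case_id}, \code{locus_id} (gene symbol or CNV region label),
#' \code{variant_type} ("SNV"/"CNV"), \code{moi}, \code{origin} (de_novo,
#' maternal, paternal, maternal+paternal, or NA) and management
#' \code{category} (1-3).
#'
#' @name cohort_stats
NULL

#' Diagnostic yield of a cohort
#'
#' Distinct diagnosed cases over cohort size; a case diagnosed by several
#' variants (or by both a CNV and an SNV) counts once.
#'
#' @param diagnoses diagnosis data.frame.
#' @param cohort_n cohort size (> 0).
#' @return list with \code{n_diagnosed}, \code{cohort_n}, \code{proportion}.
#' @export
diagnostic_yield <- function(diagnoses, cohort_n) {
  if (cohort_n <= 0) stop("cohort_n must be positive")
  n <- length(unique(diagnoses$case_id))
  list(n_diagnosed = n, cohort_n = cohort_n, proportion = n / cohort_n)
}

#' Two-proportion chi-squared test
#'
#' 2x2 chi-squared comparison of x1/n1 vs x2/n2 with Yates continuity
#' correction by default (the correction reproduces the published diagnostic
#' yield p-values; the uncorrected statistic equals the squared pooled
#' two-proportion z statistic). Implemented by explicit formula; symmetric in
#' its two samples; any zero margin gives p = 1 with a warning.
#'
#' @param x1,n1,x2,n2 successes and totals.
#' @param continuity apply Yates correction (default TRUE).
#' @return list with \code{chi2}, \code{p}, \code{df}, the inputs, and
#'   \code{continuity}.
#' @export
two_proportion_chisq <- function(x1, n1, x2, n2, continuity = TRUE) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  # 2x2 table: rows = groups, cols = success/failure
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  N <- n1 + n2
  margins <- c(a + c, b + d, n1, n2)
  if (any(margins == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(list(chi2 = 0, p = 1, df = 1L, x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                continuity = continuity))
  }
  delta <- abs(a * d - b * c)
  if (continuity) delta <- max(0, delta - N / 2)
  chi2 <- N * delta^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, x1 = x1, n1 = n1, x2 = x2, n2 = n2, continuity = continuity)
}

#' Wilson score binomial confidence interval
#'
#' @param x successes; @param n trials (> 0); @param level confidence level.
#' @return numeric vector \code{c(lower, upper)} in \[0, 1\].
#' @export
binomial_ci <- function(x, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(x >= 0, x <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- x / n
  den <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Diagnostic yield by phenotype category
#'
#' Cases are assigned to top-level system categories through ancestor closure
#' of their HPO terms; a case may contribute to several categories.
#' Categories with no cases are omitted.
#'
#' @param cases cohort data.frame (\code{case_id}, \code{hpo_terms}
#'   comma-joined).
#' @param diagnoses diagnosis data.frame.
#' @param ontology a \code{wgsdx_ontology} with categories.
#' @return data.frame (\code{category, n, diagnosed, rate}).
#' @export
subgroup_yield <- function(cases, diagnoses, ontology) {
  diagnosed <- unique(diagnoses$case_id)
  cat_list <- lapply(strsplit(cases$hpo_terms, ",", fixed = TRUE), function(t)
    case_categories(t[nzchar(t)], ontology))
  rows <- lapply(names(ontology$categories), function(cat) {
    in_cat <- vapply(cat_list, function(cc) cat %in% cc, logical(1))
    n <- sum(in_cat)
    if (n == 0L) return(NULL)
    d <- sum(cases$case_id[in_cat] %in% diagnosed)
    data.frame(category = cat, n = n, diagnosed = d, rate = d / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Cases with diagnoses at two or more distinct loci
#'
#' @param diagnoses diagnosis data.frame with \code{locus_id}.
#' @param cohort_n cohort size for the fraction (optional).
#' @return list with \code{n_multi}, \code{case_ids}, and \code{fraction}
#'   (NA when \code{cohort_n} missing).
#' @export
multi_diagnosis_count <- function(diagnoses, cohort_n = NA) {
  loci <- tapply(diagnoses$locus_id, diagnoses$case_id,
                 function(x) length(unique(x)))
  ids <- sort(names(loci)[loci >= 2])
  list(n_multi = length(ids), case_ids = ids,
       fraction = if (is.na(cohort_n)) NA_real_ else length(ids) / cohort_n)
}

#' Fraction of the cohort with any counselling-relevant finding
#'
#' Union of cases with a primary molecular diagnosis and cases with a
#' secondary finding, over the cohort size.
#'
#' @param diagnoses diagnosis data.frame.
#' @param secondary_findings findings data.frame with \code{case_id}.
#' @param cohort_n cohort size.
#' @return list with \code{n_cases} and \code{fraction}.
#' @export
combined_actionable_fraction <- function(diagnoses, secondary_findings, cohort_n) {
  if (cohort_n <= 0) stop("cohort_n must be positive")
  ids <- union(unique(diagnoses$case_id), unique(secondary_findings$case_id))
  list(n_cases = length(ids), fraction = length(ids) / cohort_n)
}

#' Tabulate variant origin across diagnosed cases
#'
#' Counts diagnosed cases by origin of transmission. Because origin is
#' unknown (NA) for a subset of diagnoses in a proband-only design, the
#' de novo fraction is a minimum estimate; the returned note says so.
#'
#' @param diagnoses diagnosis data.frame with \code{origin}.
#' @param cohort_n cohort size for the de novo fraction (optional).
#' @return list with \code{by_origin} (table over case-level origin),
#'   \code{n_de_novo} (cases with any de novo diagnosis),
#'   \code{de_novo_fraction} and \code{note}.
#' @export
origin_summary <- function(diagnoses, cohort_n = NA) {
  org <- as.character(diagnoses$origin)
  org[is.na(org) | org == ""] <- "NA"
  dn_cases <- unique(diagnoses$case_id[org == "de_novo"])
  case_org <- tapply(org, diagnoses$case_id, function(x)
    if ("de_novo" %in% x) "de_novo" else x[1])
  list(by_origin = table(unlist(case_org)),
       n_de_novo = length(dn_cases),
       de_novo_fraction = if (is.na(cohort_n)) NA_real_ else
         length(dn_cases) / cohort_n,
       note = paste("origins are unavailable (NA) for some diagnoses in a",
                    "proband-only design; the de novo fraction is a minimum"))
}
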