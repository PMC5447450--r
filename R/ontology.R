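#' Phenotype ontology helpers
#'
#' A minimal HPO-like directed acyclic graph is used for deterministic
#' phenotype matching: terms are identifiers, edges point child -> parent, and
#' matching is performed on ancestor closures. The packaged synthetic ontology
#' (see \code{\link{generate_resources}}) has a single root, a layer of
#' top-level system categories (nervous system, skeletal, growth, eye,
#' cardiovascular, musculature, connective tissue) and leaf phenotype terms;
#' real HPO graphs can be substituted as an edge table.
#'
#' @name ontology
NULL

#' Build an ontology object from an edge table
#'
#' @param edges data.frame with columns \code{child}, \code{parent} (term
#'   identifiers); the root is the unique term never appearing as a child.
#' @param categories named character vector mapping human-readable top-level
#'   category labels to term identifiers (optional).
#' @return an object of class \code{wgsdx_ontology}.
#' @export
ontology_graph <- function(edges, categories = character()) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  terms <- unique(c(edges$child, edges$parent))
  parent_map <- split(edges$parent, edges$child)
  structure(list(edges = edges, terms = terms, parent_map = parent_map,
                 categories = categories),
            class = "wgsdx_ontology")
}

#' Ancestor closure of a term set
#'
#' Returns the input terms together with every ancestor reachable through the
#' child -> parent edges (including the root).
#'
#' @param terms character vector of term identifiers.
#' @param ontology a \code{wgsdx_ontology}.
#' @return character vector (unique, unordered).
#' @export
hpo_closure <- function(terms, ontology) {
  stopifnot(inherits(ontology, "wgsdx_ontology"))
  terms <- unique(as.character(terms))
  terms <- terms[!is.na(terms) & nzchar(terms)]
  unknown <- setdiff(terms, ontology$terms)
  if (length(unknown))
    stop("unknown ontology term(s): ", paste(unknown, collapse = ", "))
  seen <- character()
  frontier <- terms
  while (length(frontier)) {
    seen <- union(seen, frontier)
    parents <- unique(unlist(ontology$parent_map[frontier], use.names = FALSE))
    frontier <- setdiff(parents, seen)
  }
  seen
}

#' Deterministic phenotype match score
#'
#' A stand-in for clinician adjudication of phenotype fit: the number of terms
#' shared by the ancestor closures of the case profile and the gene's disease
#' profile, normalised by the size of the case closure. The ontology root is
#' excluded from both closures (every term set trivially shares it, so sets
#' from disjoint branches score 0). Identical sets score 1; a child term
#' scores positively against its own ancestor.
#'
#' @param case_terms,gene_terms character vectors of term identifiers.
#' @param ontology a \code{wgsdx_ontology}.
#' @return a score in \[0, 1\].
#' @export
phenotype_match_score <- function(case_terms, gene_terms, ontology) {
  roots <- setdiff(ontology$terms, ontology$edges$child)
  cc <- setdiff(hpo_closure(case_terms, ontology), roots)
  if (length(cc) == 0L) return(0)
  gc <- setdiff(hpo_closure(gene_terms, ontology), roots)
  length(intersect(cc, gc)) / length(cc)
}

#' Map case HPO terms to top-level system categories
#'
#' A case belongs to a category when the ancestor closure of its terms
#' contains the category's term. Used for subgroup-yield tables.
#'
#' @param hpo_terms character vector of term identifiers for one case.
#' @param ontology a \code{wgsdx_ontology} with non-empty \code{categories}.
#' @return character vector of category labels (possibly several, possibly none).
#' @export
case_categories <- function(hpo_terms, ontology) {
  stopifnot(inherits(ontology, "wgsdx_ontology"))
  if (length(ontology$categories) == 0L) stop("ontology carries no categories")
  cl <- hpo_closure(hpo_terms, ontology)
  names(ontology$categories)[ontology$categories %in% cl]
}
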