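# Ontology coverage statistics: depth histograms, mean depth, normalized
# depth-distribution distance, and lineage counts.

#' Depth statistics of a set of ontology terms
#'
#' Histogram and mean of shortest-path is_a depths over the *unique* term ids
#' supplied ("number of terms present at each depth"); pass
#' `frequency_weighted = TRUE` to keep duplicates and weight by mention
#' frequency. Unresolvable or unreachable ids are excluded and counted.
#'
#' @param term_ids character vector of term ids.
#' @param ontology an [ontology()].
#' @param frequency_weighted keep duplicate ids (mention-weighted histogram).
#' @return object of class `depth_stats`: list with `histogram` (named count
#'   vector, names are depths), `mean_depth`, `n_terms`, `n_excluded`.
#' @export
depth_stats <- function(term_ids, ontology, frequency_weighted = FALSE) {
  if (!frequency_weighted) term_ids <- unique(term_ids)
  known <- term_ids %in% ontology$terms$id
  if (any(!known)) message(sum(!known), " unknown id(s) excluded from depth statistics")
  d <- term_depth(ontology, term_ids[known])
  excluded <- sum(!known) + sum(is.na(d))
  d <- d[!is.na(d)]
  if (!length(d)) {
    return(structure(list(histogram = stats::setNames(integer(), character()),
                          mean_depth = NaN, n_terms = 0L,
                          n_excluded = excluded), class = "depth_stats"))
  }
  h <- table(d)
  structure(list(histogram = stats::setNames(as.integer(h), names(h)),
                 mean_depth = mean(d), n_terms = length(d),
                 n_excluded = excluded), class = "depth_stats")
}

#' @export
print.depth_stats <- function(x, ...) {
  cat(sprintf("<depth_stats> %d terms, mean depth %.2f (%d excluded)\n",
              x$n_terms, x$mean_depth, x$n_excluded))
  invisible(x)
}

#' L1 distance between normalized depth distributions
#'
#' Sum over depths of the absolute difference between the two histograms
#' normalized to probability distributions; ranges from 0 (identical) to 2
#' (disjoint supports).
#'
#' @param stats_a,stats_b [depth_stats()] objects.
#' @return real in `[0, 2]`.
#' @export
depth_l1 <- function(stats_a, stats_b) {
  if (stats_a$n_terms == 0 || stats_b$n_terms == 0) stop("empty depth stats")
  depths <- union(names(stats_a$histogram), names(stats_b$histogram))
  pa <- pb <- stats::setNames(numeric(length(depths)), depths)
  pa[names(stats_a$histogram)] <- stats_a$histogram / stats_a$n_terms
  pb[names(stats_b$histogram)] <- stats_b$histogram / stats_b$n_terms
  sum(abs(pa - pb))
}

#' Count terms per major lineage
#'
#' A term counts toward lineage L iff L's root-term set intersects the term
#' itself or its ancestors; terms whose ancestors span multiple lineages are
#' counted in each.
#'
#' @param term_ids character vector (multiset) of term ids.
#' @param ontology an [ontology()].
#' @param lineage_map named list mapping lineage label to a character vector
#'   of lineage root term ids (a `lineage_roots` vector from
#'   [generate_ontology()] also works).
#' @param unique_terms count unique ids only (default TRUE).
#' @return named integer vector of counts per lineage.
#' @export
lineage_counts <- function(term_ids, ontology, lineage_map,
                           unique_terms = TRUE) {
  if (!is.list(lineage_map)) lineage_map <- as.list(lineage_map)
  bad <- setdiff(unlist(lineage_map, use.names = FALSE), ontology$terms$id)
  if (length(bad)) stop("lineage roots do not resolve: ", paste(bad, collapse = ", "))
  if (unique_terms) term_ids <- unique(term_ids)
  term_ids <- term_ids[term_ids %in% ontology$terms$id]
  counts <- stats::setNames(integer(length(lineage_map)), names(lineage_map))
  for (id in term_ids) {
    anc <- c(id, ancestors(ontology, id))
    for (lin in names(lineage_map)) {
      if (any(lineage_map[[lin]] %in% anc)) counts[[lin]] <- counts[[lin]] + 1L
    }
  }
  counts
}
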