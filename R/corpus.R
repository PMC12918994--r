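#' Construct an annotated corpus
#'
#' The corpus container pairs a passage table with a span-annotation table.
#' Character offsets are 0-based and half-open over the passage text, so an
#' annotation's `text` equals `substr(passage, start + 1, end)`; this matches
#' the BioC convention and makes slicing directly testable.
#'
#' Annotations carry an entity type (`cell_phenotype`, `heterogeneous`, or
#' `vague`), semicolon-joined ontology identifiers with a parallel
#' semicolon-joined qualifier channel (`exact`/`related`), and an annotator
#' id. Coordination ellipses ("CD4+ and CD8+ T cells") are one annotation
#' with several identifiers and `coordination = TRUE`.
#'
#' @param passages data.frame with columns `passage_id`, `doc_id`,
#'   `passage_type`, `text`, and optionally `year`, `journal`,
#'   `mesh_clusters` (semicolon-joined cluster labels).
#' @param annotations data.frame with columns `passage_id`, `ann_id`,
#'   `start`, `end`, `text`, `entity_type`, and optionally `identifiers`,
#'   `qualifiers` (semicolon-joined, parallel), `annotator`, `coordination`.
#' @param provenance free-text metadata.
#' @return object of class `annotated_corpus`.
#' @export
annotated_corpus <- function(passages, annotations = NULL, provenance = "") {
  passages <- as.data.frame(passages, stringsAsFactors = FALSE)
  need <- c("passage_id", "doc_id", "passage_type", "text")
  stopifnot(all(need %in% names(passages)))
  if (anyDuplicated(passages$passage_id)) stop("duplicate passage_id")
  if (is.null(passages$year)) passages$year <- NA_integer_
  if (is.null(passages$journal)) passages$journal <- NA_character_
  if (is.null(passages$mesh_clusters)) passages$mesh_clusters <- ""
  ok_types <- c("title", "abstract", "paragraph", "section_header", "caption",
                "table", "supplementary")
  bad <- setdiff(unique(passages$passage_type), ok_types)
  if (length(bad)) stop("unknown passage_type: ", paste(bad, collapse = ", "))

  if (is.null(annotations) || nrow(as.data.frame(annotations)) == 0) {
    annotations <- data.frame(passage_id = character(), ann_id = character(),
                              start = integer(), end = integer(), text = character(),
                              entity_type = character(), identifiers = character(),
                              qualifiers = character(), annotator = character(),
                              coordination = logical(), stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    need <- c("passage_id", "ann_id", "start", "end", "text", "entity_type")
    stopifnot(all(need %in% names(annotations)))
    if (is.null(annotations$identifiers)) annotations$identifiers <- ""
    if (is.null(annotations$qualifiers)) annotations$qualifiers <- ""
    if (is.null(annotations$annotator)) annotations$annotator <- "annotator1"
    if (is.null(annotations$coordination)) annotations$coordination <- FALSE
    annotations$identifiers[is.na(annotations$identifiers)] <- ""
    annotations$qualifiers[is.na(annotations$qualifiers)] <- ""
    annotations$start <- as.integer(annotations$start)
    annotations$end <- as.integer(annotations$end)
    if (anyDuplicated(annotations$ann_id)) stop("duplicate ann_id")
    bad <- setdiff(unique(annotations$entity_type),
                   c("cell_phenotype", "heterogeneous", "vague"))
    if (length(bad)) stop("unknown entity_type: ", paste(bad, collapse = ", "))
    orphan <- setdiff(annotations$passage_id, passages$passage_id)
    if (length(orphan)) stop("annotations reference unknown passages: ",
                             paste(orphan, collapse = ", "))
  }
  structure(list(passages = passages, annotations = annotations,
                 provenance = provenance), class = "annotated_corpus")
}

#' @export
print.annotated_corpus <- function(x, ...) {
  cat(sprintf("<annotated_corpus> %d passages (%d documents), %d annotations\n",
              nrow(x$passages), length(unique(x$passages$doc_id)),
              nrow(x$annotations)))
  invisible(x)
}

#' Long-format view of annotation-to-ontology links
#'
#' Splits the semicolon-joined identifier and qualifier channels into one row
#' per (annotation, identifier) pair.
#'
#' @param corpus an [annotated_corpus()].
#' @return data.frame with columns `ann_id`, `term_id`, `qualifier`.
#' @export
annotation_links <- function(corpus) {
  ann <- corpus$annotations
  linked <- ann[nzchar(ann$identifiers), , drop = FALSE]
  if (!nrow(linked)) {
    return(data.frame(ann_id = character(), term_id = character(),
                      qualifier = character(), stringsAsFactors = FALSE))
  }
  ids <- strsplit(linked$identifiers, ";", fixed = TRUE)
  quals <- strsplit(linked$qualifiers, ";", fixed = TRUE)
  n <- lengths(ids)
  quals <- mapply(function(q, k) {
    if (length(q) == k) q else rep_len(if (length(q)) q else "exact", k)
  }, quals, n, SIMPLIFY = FALSE)
  data.frame(ann_id = rep(linked$ann_id, n),
             term_id = unlist(ids, use.names = FALSE),
             qualifier = unlist(quals, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Validate a corpus against the annotation guidelines
#'
#' Violations are returned as data rather than raised as errors. Checked
#' rules: spans must lie inside the passage and match its text slice; vague
#' cell populations must not carry ontology links; overlapping annotations by
#' the same annotator are allowed only when a vague annotation strictly
#' contains a non-vague one; when an ontology is supplied, every linked
#' identifier must resolve (obsolete ids with a replacement resolve with a
#' notice).
#'
#' @param corpus an [annotated_corpus()].
#' @param ontology optional [ontology()] to resolve identifiers against.
#' @return data.frame with columns `kind`, `passage_id`, `ann_id`, `detail`;
#'   zero rows iff the corpus is guideline-conformant.
#' @export
validate_corpus <- function(corpus, ontology = NULL) {
  ann <- corpus$annotations
  pas <- corpus$passages
  out <- list()
  emit <- function(kind, passage_id, ann_id, detail) {
    out[[length(out) + 1L]] <<- data.frame(kind = kind, passage_id = passage_id,
                                           ann_id = ann_id, detail = detail,
                                           stringsAsFactors = FALSE)
  }
  plen <- stats::setNames(nchar(pas$text), pas$passage_id)
  ptext <- stats::setNames(pas$text, pas$passage_id)
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    L <- plen[[a$passage_id]]
    if (is.na(a$start) || is.na(a$end) || a$start < 0 || a$start >= a$end || a$end > L) {
      emit("span_out_of_bounds", a$passage_id, a$ann_id,
           sprintf("span [%s,%s) outside passage of length %d", a$start, a$end, L))
      next
    }
    slice <- substr(ptext[[a$passage_id]], a$start + 1L, a$end)
    if (!identical(slice, a$text)) {
      emit("span_text_mismatch", a$passage_id, a$ann_id,
           sprintf("annotation text %s != passage slice %s", dQuote(a$text), dQuote(slice)))
    }
    if (a$entity_type == "vague" && nzchar(a$identifiers)) {
      emit("vague_linked", a$passage_id, a$ann_id,
           paste("vague cell population linked to", a$identifiers))
    }
  }
  # pairwise overlap rule, per passage and annotator
  for (pid in unique(ann$passage_id)) {
    pa <- ann[ann$passage_id == pid, , drop = FALSE]
    for (who in unique(pa$annotator)) {
      aa <- pa[pa$annotator == who, , drop = FALSE]
      if (nrow(aa) < 2) next
      for (i in seq_len(nrow(aa) - 1L)) for (j in seq.int(i + 1L, nrow(aa))) {
        s1 <- aa$start[i]; e1 <- aa$end[i]; s2 <- aa$start[j]; e2 <- aa$end[j]
        if (max(s1, s2) >= min(e1, e2)) next  # disjoint
        vague_contains <- function(vi, vj) {
          aa$entity_type[vi] == "vague" && aa$entity_type[vj] != "vague" &&
            aa$start[vi] <= aa$start[vj] && aa$end[vi] >= aa$end[vj] &&
            (aa$start[vi] < aa$start[vj] || aa$end[vi] > aa$end[vj])
        }
        if (!vague_contains(i, j) && !vague_contains(j, i)) {
          emit("illegal_overlap", pid, aa$ann_id[i],
               sprintf("overlaps %s without vague-containment", aa$ann_id[j]))
        }
      }
    }
  }
  if (!is.null(ontology)) {
    links <- annotation_links(corpus)
    resolved <- resolve_term(ontology, links$term_id, quiet = TRUE)
    bad <- is.na(resolved)
    for (k in which(bad)) {
      pid <- ann$passage_id[match(links$ann_id[k], ann$ann_id)]
      emit("unresolved_id", pid, links$ann_id[k],
           paste("identifier does not resolve:", links$term_id[k]))
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), passage_id = character(),
                      ann_id = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Map obsolete identifiers in a corpus to their replacements
#'
#' Rewrites each linked identifier that is obsolete in `ontology` and carries
#' a `replaced_by` pointer; a notice reports how many were mapped.
#'
#' @inheritParams validate_corpus
#' @export
map_obsolete_links <- function(corpus, ontology) {
  ann <- corpus$annotations
  idx <- which(nzchar(ann$identifiers))
  n_mapped <- 0L
  for (i in idx) {
    ids <- strsplit(ann$identifiers[i], ";", fixed = TRUE)[[1]]
    new <- resolve_term(ontology, ids, quiet = TRUE)
    keep <- !is.na(new)
    changed <- keep & new != ids
    n_mapped <- n_mapped + sum(changed)
    ids[changed] <- new[changed]
    ann$identifiers[i] <- paste(ids, collapse = ";")
  }
  if (n_mapped) message("mapped ", n_mapped, " obsolete identifier(s) via replaced_by")
  corpus$annotations <- ann
  corpus
}
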