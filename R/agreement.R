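# Inter-annotator agreement (IAA) in four strictness regimes, plus the
# automated inconsistency flags used during consensus review.

.agreement_modes <- c("strict_span_id", "strict_span", "strict_id", "approx_span")

# exact-id key per annotation after the related-as-no-ID coercion: related
# qualifiers are treated as "no ID" because several combinations of related
# identifiers can be equally acceptable.
.exact_id_key <- function(identifiers, qualifiers) {
  mapply(function(ids, quals) {
    if (!nzchar(ids)) return("")
    id <- strsplit(ids, ";", fixed = TRUE)[[1]]
    ql <- strsplit(quals, ";", fixed = TRUE)[[1]]
    ql <- rep_len(if (length(ql)) ql else "exact", length(id))
    keep <- ql == "exact"
    if (!any(keep)) "" else paste(sort(id[keep]), collapse = ";")
  }, identifiers, qualifiers, USE.NAMES = FALSE)
}

# greedy one-to-one overlap matching; both sides ordered by start offset
.greedy_overlap_matches <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0L)
  a <- a[order(a$start, a$end), , drop = FALSE]
  used <- rep(FALSE, nrow(b))
  m <- 0L
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
    ov[used | b$key != a$key[i]] <- -1L
    j <- which.max(ov)
    if (length(j) && ov[j] > 0) {
      used[j] <- TRUE
      m <- m + 1L
    }
  }
  m
}

#' Inter-annotator agreement between two annotation sets
#'
#' Computes pooled micro precision/recall/F1 between two annotators over the
#' same passages, under one of four regimes:
#' \describe{
#'   \item{strict_span_id}{exact span, entity type, and exact-match
#'     identifier set (related identifiers coerced to "no ID" first).}
#'   \item{strict_span}{exact span and entity type; identifiers ignored.}
#'   \item{strict_id}{presence of the same exact-match identifiers anywhere
#'     within the passage (set comparison per passage).}
#'   \item{approx_span}{same entity type and any span overlap, greedy
#'     one-to-one matching by start offset.}
#' }
#' `merge_labels` collapses the three entity types into one. Annotator 1 is
#' the reference: precision is measured on annotator 2, recall on
#' annotator 1; swapping annotators swaps P and R and leaves F1 unchanged.
#'
#' @param ann1,ann2 [annotated_corpus()] objects over the same passages (or
#'   annotation data.frames with a `passage_id` column).
#' @param mode one of `strict_span_id`, `strict_span`, `strict_id`,
#'   `approx_span`.
#' @param merge_labels collapse entity types before matching.
#' @param by_passage_type also compute a per-passage-type breakdown
#'   (requires corpora, not bare annotation tables).
#' @return list with `mode`, `precision`, `recall`, `f1`, counts, and
#'   optionally `by_passage_type`.
#' @export
iaa <- function(ann1, ann2, mode = "strict_span_id", merge_labels = FALSE,
                by_passage_type = FALSE) {
  mode <- match.arg(mode, .agreement_modes)
  ptype <- NULL
  if (inherits(ann1, "annotated_corpus")) {
    if (!setequal(ann1$passages$passage_id, ann2$passages$passage_id))
      stop("annotators do not cover the same passages")
    ptype <- stats::setNames(ann1$passages$passage_type, ann1$passages$passage_id)
    a <- ann1$annotations
    b <- ann2$annotations
  } else {
    a <- ann1
    b <- ann2
  }
  score <- function(a, b) {
    if (mode == "strict_id") {
      pids <- union(a$passage_id, b$passage_id)
      tp <- n1 <- n2 <- 0L
      for (p in pids) {
        s1 <- .exact_id_key(a$identifiers[a$passage_id == p], a$qualifiers[a$passage_id == p])
        s2 <- .exact_id_key(b$identifiers[b$passage_id == p], b$qualifiers[b$passage_id == p])
        s1 <- unique(unlist(strsplit(s1[nzchar(s1)], ";", fixed = TRUE)))
        s2 <- unique(unlist(strsplit(s2[nzchar(s2)], ";", fixed = TRUE)))
        tp <- tp + length(intersect(s1, s2))
        n1 <- n1 + length(s1)
        n2 <- n2 + length(s2)
      }
      return(c(tp = tp, n1 = n1, n2 = n2))
    }
    type1 <- if (merge_labels) rep("mention", nrow(a)) else a$entity_type
    type2 <- if (merge_labels) rep("mention", nrow(b)) else b$entity_type
    if (mode == "approx_span") {
      tp <- 0L
      for (p in union(a$passage_id, b$passage_id)) {
        ai <- a$passage_id == p
        bi <- b$passage_id == p
        tp <- tp + .greedy_overlap_matches(
          data.frame(start = a$start[ai], end = a$end[ai], key = type1[ai]),
          data.frame(start = b$start[bi], end = b$end[bi], key = type2[bi]))
      }
      return(c(tp = tp, n1 = nrow(a), n2 = nrow(b)))
    }
    key1 <- paste(a$passage_id, a$start, a$end, type1)
    key2 <- paste(b$passage_id, b$start, b$end, type2)
    if (mode == "strict_span_id") {
      key1 <- paste(key1, .exact_id_key(a$identifiers, a$qualifiers))
      key2 <- paste(key2, .exact_id_key(b$identifiers, b$qualifiers))
    }
    # multiset intersection
    tp <- sum(pmin(table(key1)[intersect(key1, key2)],
                   table(key2)[intersect(key1, key2)]))
    c(tp = tp, n1 = length(key1), n2 = length(key2))
  }
  counts <- score(a, b)
  prf <- function(cn) {
    p <- if (cn[["n2"]] > 0) cn[["tp"]] / cn[["n2"]] else 0
    r <- if (cn[["n1"]] > 0) cn[["tp"]] / cn[["n1"]] else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    list(precision = p, recall = r, f1 = f)
  }
  out <- c(list(mode = mode, merge_labels = merge_labels), prf(counts),
           list(tp = counts[["tp"]], n1 = counts[["n1"]], n2 = counts[["n2"]]))
  if (by_passage_type) {
    if (is.null(ptype)) stop("by_passage_type requires annotated_corpus inputs")
    rows <- lapply(unique(ptype), function(pt) {
      pids <- names(ptype)[ptype == pt]
      cn <- score(a[a$passage_id %in% pids, , drop = FALSE],
                  b[b$passage_id %in% pids, , drop = FALSE])
      cbind(data.frame(passage_type = pt), as.data.frame(prf(cn)))
    })
    out$by_passage_type <- do.call(rbind, rows)
  }
  out
}

#' Flag mention-identifier pairs diverging from the predominant pattern
#'
#' For each case-folded mention string with at least `min_support` linked
#' occurrences, occurrences whose exact-match identifier set differs from the
#' modal one are flagged as potential inconsistencies. Ties for the mode flag
#' nothing.
#'
#' @param corpus an [annotated_corpus()].
#' @param min_support minimum occurrences for a mention to be examined.
#' @return data.frame with columns `ann_id`, `mention`, `identifier`,
#'   `modal_identifier`.
#' @export
flag_divergent_links <- function(corpus, min_support = 2L) {
  ann <- corpus$annotations
  key <- .exact_id_key(ann$identifiers, ann$qualifiers)
  linked <- nzchar(key)
  mention <- tolower(ann$text)
  out <- list()
  for (m in unique(mention[linked])) {
    idx <- which(linked & mention == m)
    if (length(idx) < min_support) next
    tab <- sort(table(key[idx]), decreasing = TRUE)
    if (length(tab) < 2) next
    if (tab[1] == tab[2]) next  # modal tie: flag nothing
    modal <- names(tab)[1]
    for (i in idx[key[idx] != modal]) {
      out[[length(out) + 1L]] <- data.frame(
        ann_id = ann$ann_id[i], mention = m, identifier = key[i],
        modal_identifier = modal, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(ann_id = character(), mention = character(),
                      identifier = character(), modal_identifier = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Flag annotated populations followed by a subset descriptor
#'
#' Flags each non-vague annotation whose span is immediately followed
#' (whitespace-tolerant) by a subset descriptor word ("epithelial cell
#' subsets"), unless a vague annotation already covers the extended phrase --
#' the guidelines require such phrases to be annotated as vague cell
#' populations.
#'
#' @param corpus an [annotated_corpus()].
#' @param subset_terms descriptor word list.
#' @return data.frame with columns `ann_id`, `passage_id`, `descriptor`.
#' @export
flag_subset_phrases <- function(corpus,
                                subset_terms = c("subset", "subsets", "subtype",
                                                 "subtypes", "subpopulation",
                                                 "subpopulations", "class",
                                                 "classes")) {
  stopifnot(length(subset_terms) > 0)
  ann <- corpus$annotations
  ptext <- stats::setNames(corpus$passages$text, corpus$passages$passage_id)
  pattern <- sprintf("^[[:space:]]*(%s)\\b", paste(subset_terms, collapse = "|"))
  out <- list()
  for (i in which(ann$entity_type != "vague")) {
    tail_text <- substr(ptext[[ann$passage_id[i]]], ann$end[i] + 1L, 1e6)
    m <- regmatches(tail_text, regexpr(pattern, tail_text, ignore.case = TRUE))
    if (!length(m)) next
    ext_end <- ann$end[i] + nchar(m)
    covered <- ann$entity_type == "vague" & ann$passage_id == ann$passage_id[i] &
      ann$start <= ann$start[i] & ann$end >= ext_end
    if (any(covered)) next
    out[[length(out) + 1L]] <- data.frame(
      ann_id = ann$ann_id[i], passage_id = ann$passage_id[i],
      descriptor = trimws(m), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(ann_id = character(), passage_id = character(),
                      descriptor = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
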