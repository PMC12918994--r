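#' Construct an ontology
#'
#' An ontology is a rooted directed acyclic graph of terms connected by
#' `is_a` edges, as used by the Cell Ontology: deeper terms denote more
#' specific cell types. Only `is_a` edges are represented; depth is the
#' shortest `is_a` path from the root.
#'
#' @param terms data.frame with columns `id`, `label`, and optionally
#'   `obsolete` (logical) and `replaced_by` (id of the official replacement
#'   for an obsolete term, `NA` otherwise).
#' @param edges data.frame with columns `child`, `parent`; each row is one
#'   `child is_a parent` assertion.
#' @param root_id identifier of the root term.
#' @param synonyms optional data.frame with columns `id`, `synonym`.
#' @return an object of class `ontology` with precomputed term depths.
#' @export
ontology <- function(terms, edges, root_id, synonyms = NULL) {
  stopifnot(is.data.frame(terms), all(c("id", "label") %in% names(terms)))
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (is.null(terms$obsolete)) terms$obsolete <- FALSE
  if (is.null(terms$replaced_by)) terms$replaced_by <- NA_character_
  if (anyDuplicated(terms$id)) stop("duplicate term ids")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) edges <- data.frame(child = character(), parent = character())
  stopifnot(all(c("child", "parent") %in% names(edges)))
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown)) stop("edges reference unknown terms: ", paste(unknown, collapse = ", "))
  if (!root_id %in% terms$id) stop("root_id not among terms: ", root_id)
  if (is.null(synonyms)) synonyms <- data.frame(id = character(), synonym = character())

  onto <- structure(list(terms = terms, edges = edges, root_id = root_id,
                         synonyms = synonyms), class = "ontology")
  if (.has_cycle(onto)) stop("edge graph is cyclic; is_a graph must be a DAG")
  onto$depth <- .compute_depths(onto)
  onto
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms (%d obsolete), %d is_a edges, root %s\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges), x$root_id))
  invisible(x)
}

# Kahn's algorithm on child->parent edges
.has_cycle <- function(onto) {
  ids <- onto$terms$id
  outdeg <- table(factor(onto$edges$child, levels = ids))
  preds <- split(onto$edges$child, factor(onto$edges$parent, levels = ids))
  queue <- ids[outdeg == 0]
  seen <- 0L
  outdeg <- as.integer(outdeg)
  names(outdeg) <- ids
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (u in preds[[v]]) {
      outdeg[[u]] <- outdeg[[u]] - 1L
      if (outdeg[[u]] == 0L) queue <- c(queue, u)
    }
  }
  seen < length(ids)
}

# BFS from the root over parent->child adjacency; is_a edges whose child is
# obsolete are not traversed, so obsolete terms (and anything reachable only
# through them) get NA depth.
.compute_depths <- function(onto) {
  ids <- onto$terms$id
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  live <- onto$edges[!onto$edges$child %in% onto$terms$id[onto$terms$obsolete], , drop = FALSE]
  children <- split(live$child, factor(live$parent, levels = ids))
  depth[[onto$root_id]] <- 0L
  frontier <- onto$root_id
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

#' Shortest-path depth of ontology terms
#'
#' Depth is the length of the shortest `is_a` path from the root to the term;
#' the root has depth 0. Terms unreachable from the root (including obsolete
#' terms) have depth `NA` and are excluded from depth statistics.
#'
#' @param ontology an [ontology()] object.
#' @param term_id character vector of term identifiers.
#' @return integer vector of depths (`NA` when unreachable).
#' @export
term_depth <- function(ontology, term_id) {
  bad <- setdiff(term_id, ontology$terms$id)
  if (length(bad)) stop("unknown term id(s): ", paste(bad, collapse = ", "))
  unname(ontology$depth[term_id])
}

#' Ancestors of a term
#'
#' Transitive closure over `is_a` edges, excluding the term itself and
#' including the root when reachable.
#'
#' @inheritParams term_depth
#' @param term_id a single term identifier.
#' @return character vector of ancestor ids.
#' @export
ancestors <- function(ontology, term_id) {
  if (!term_id %in% ontology$terms$id) stop("unknown term id: ", term_id)
  parents <- split(ontology$edges$parent, ontology$edges$child)
  out <- character()
  frontier <- term_id
  while (length(frontier)) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  setdiff(out, term_id)
}

#' Resolve a term id, mapping obsolete terms to their replacement
#'
#' Obsolete identifiers carrying a `replaced_by` pointer are mapped to their
#' official replacement with a message; unknown identifiers return `NA`.
#'
#' @inheritParams term_depth
#' @param quiet suppress the replacement notice.
#' @return character vector of resolved ids (`NA` where unresolvable).
#' @export
resolve_term <- function(ontology, term_id, quiet = FALSE) {
  idx <- match(term_id, ontology$terms$id)
  out <- ontology$terms$id[idx]
  obs <- !is.na(idx) & ontology$terms$obsolete[idx]
  repl <- ontology$terms$replaced_by[idx]
  mappable <- obs & !is.na(repl) & repl %in% ontology$terms$id
  if (any(mappable) && !quiet) {
    message("mapped ", sum(mappable), " obsolete id(s) to replacement(s)")
  }
  out[mappable] <- repl[mappable]
  out[obs & !mappable] <- NA_character_
  out
}

#' Read an ontology from an OBO-graph JSON subset
#'
#' Accepts the node/edge subset of the OBO-graph JSON exchange format:
#' `graphs[[1]]$nodes` with `id`, `lbl`, optional `meta$deprecated`,
#' `meta$synonyms[*]$val` and `meta$basicPropertyValues` carrying a
#' `term replaced by` property; `graphs[[1]]$edges` with `sub`, `pred`,
#' `obj`, of which only `is_a` predicates are used.
#'
#' @param path file path.
#' @param root_id root term id; when `NULL` the unique term with no parent
#'   is used.
#' @return an [ontology()].
#' @export
read_ontology_json <- function(path, root_id = NULL) {
  doc <- jsonlite::read_json(path)
  g <- if (!is.null(doc$graphs)) doc$graphs[[1]] else doc
  nodes <- g$nodes
  terms <- data.frame(
    id = vapply(nodes, function(n) n$id, ""),
    label = vapply(nodes, function(n) if (is.null(n$lbl)) "" else n$lbl, ""),
    obsolete = vapply(nodes, function(n) isTRUE(n$meta$deprecated), TRUE),
    replaced_by = vapply(nodes, function(n) {
      for (bp in n$meta$basicPropertyValues) {
        if (grepl("replaced", bp$pred, ignore.case = TRUE)) return(bp$val)
      }
      NA_character_
    }, ""),
    stringsAsFactors = FALSE
  )
  syn <- do.call(rbind, lapply(nodes, function(n) {
    vals <- vapply(n$meta$synonyms, function(s) s$val, "")
    if (!length(vals)) return(NULL)
    data.frame(id = n$id, synonym = vals, stringsAsFactors = FALSE)
  }))
  if (is.null(syn)) syn <- data.frame(id = character(), synonym = character())
  is_a <- vapply(g$edges, function(e) identical(e$pred, "is_a"), TRUE)
  edges <- data.frame(
    child = vapply(g$edges[is_a], function(e) e$sub, ""),
    parent = vapply(g$edges[is_a], function(e) e$obj, ""),
    stringsAsFactors = FALSE
  )
  if (is.null(root_id)) {
    cand <- setdiff(terms$id[!terms$obsolete], edges$child)
    if (length(cand) != 1) stop("cannot infer a unique root; pass root_id")
    root_id <- cand
  }
  ontology(terms, edges, root_id, synonyms = syn)
}

#' Read a toy ontology from a 3-column TSV edge list
#'
#' Columns: child id, parent id, child label. The root appears only in the
#' parent column; its label defaults to its id.
#'
#' @inheritParams read_ontology_json
#' @export
read_ontology_tsv <- function(path, root_id = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("child", "parent", "label"))
  ids <- unique(c(df$child, df$parent))
  labels <- stats::setNames(ids, ids)
  labels[df$child] <- df$label
  terms <- data.frame(id = ids, label = unname(labels[ids]), stringsAsFactors = FALSE)
  edges <- df[, c("child", "parent")]
  if (is.null(root_id)) {
    cand <- setdiff(ids, df$child)
    if (length(cand) != 1) stop("cannot infer a unique root; pass root_id")
    root_id <- cand
  }
  ontology(terms, edges, root_id)
}

#' Write an ontology as OBO-graph JSON
#'
#' @inheritParams term_depth
#' @param path output file path.
#' @export
write_ontology_json <- function(ontology, path) {
  nodes <- lapply(seq_len(nrow(ontology$terms)), function(i) {
    t <- ontology$terms[i, ]
    syn <- ontology$synonyms$synonym[ontology$synonyms$id == t$id]
    meta <- list()
    if (isTRUE(t$obsolete)) meta$deprecated <- TRUE
    if (!is.na(t$replaced_by)) {
      meta$basicPropertyValues <- list(list(pred = "term replaced by", val = t$replaced_by))
    }
    if (length(syn)) meta$synonyms <- lapply(syn, function(s) list(val = s))
    n <- list(id = t$id, lbl = t$label)
    if (length(meta)) n$meta <- meta
    n
  })
  edges <- lapply(seq_len(nrow(ontology$edges)), function(i) {
    list(sub = ontology$edges$child[i], pred = "is_a", obj = ontology$edges$parent[i])
  })
  jsonlite::write_json(list(graphs = list(list(nodes = nodes, edges = edges))),
                       path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
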