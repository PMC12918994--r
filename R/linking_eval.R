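# Embedding-based candidate retrieval against an ontology, single-link and
# top-k evaluation with exact/related gold semantics, and novelty-detection
# ROC analysis. The embedder is a plug-in contract: any function mapping a
# character vector to a matrix of unit-norm rows will do; the shipped default
# is a deterministic hashed character-trigram bag.

#' Deterministic toy text embedder (hashed character n-gram bag)
#'
#' Returns an embedding function mapping a character vector to a matrix with
#' one unit-L2-norm row per input. Texts are lowercased, padded with
#' boundary markers, decomposed into character n-grams, and each n-gram is
#' hashed into one of `dim` buckets; the bucket-count vector is normalized.
#' Identical inputs always give identical vectors, and string similarity is
#' reflected in cosine similarity, which is all the evaluation harness needs
#' (pretrained embedding models are out of scope and pluggable).
#'
#' @param dim embedding dimension (number of hash buckets).
#' @param n n-gram length.
#' @return function(texts) -> numeric matrix (length(texts) x dim).
#' @export
toy_embedder <- function(dim = 256L, n = 3L) {
  force(dim); force(n)
  function(texts) {
    out <- matrix(0, length(texts), dim)
    for (i in seq_along(texts)) {
      s <- paste0("#", tolower(texts[[i]]), "#")
      cp <- utf8ToInt(s)
      L <- length(cp) - n + 1L
      if (L < 1L) {
        cp <- c(cp, rep(35L, n))  # pad very short strings with '#'
        L <- length(cp) - n + 1L
      }
      # polynomial rolling hash of each n-gram
      h <- integer(L)
      for (k in seq_len(n)) h <- (h * 131L + cp[k:(k + L - 1L)]) %% dim
      v <- tabulate(h + 1L, nbins = dim)
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) out[i, ] <- v / nrm
    }
    out
  }
}

#' Build an embedding index over ontology labels and synonyms
#'
#' Every non-obsolete term contributes one vector per label and synonym.
#'
#' @param ontology an [ontology()].
#' @param embedder an embedding function as from [toy_embedder()].
#' @return object of class `ontology_index`: list with `vectors` (matrix,
#'   unit-norm rows), `term_id` (row -> term), `text` (row -> embedded
#'   string), and the `embedder`.
#' @export
ontology_index <- function(ontology, embedder = toy_embedder()) {
  live <- ontology$terms[!ontology$terms$obsolete, , drop = FALSE]
  if (!nrow(live)) stop("ontology has no non-obsolete terms to index")
  texts <- live$label
  ids <- live$id
  syn <- ontology$synonyms[ontology$synonyms$id %in% live$id, , drop = FALSE]
  if (nrow(syn)) {
    texts <- c(texts, syn$synonym)
    ids <- c(ids, syn$id)
  }
  structure(list(vectors = embedder(texts), term_id = ids, text = texts,
                 embedder = embedder), class = "ontology_index")
}

#' Conservative mention preprocessing: abbreviation expansion + plural strip
#'
#' Longest-match whole-word abbreviation expansion using the supplied map
#' (construction of the map is external), followed by a conservative plural
#' stemmer: a trailing "s" is removed from a word only when the stem has at
#' least 3 letters and the word does not end in ss/us/is/as. Idempotent.
#'
#' @param text character vector of mention strings.
#' @param abbreviation_map named character vector, abbreviation -> long form.
#' @param stem_plurals apply the plural stemmer.
#' @export
preprocess_mention <- function(text, abbreviation_map = NULL,
                               stem_plurals = TRUE) {
  if (!is.null(abbreviation_map) && length(abbreviation_map)) {
    keys <- names(abbreviation_map)[order(-nchar(names(abbreviation_map)))]
    for (k in keys) {
      text <- gsub(paste0("\\b", k, "\\b"), abbreviation_map[[k]], text,
                   fixed = FALSE)
    }
  }
  if (stem_plurals) {
    strip <- function(word) {
      if (grepl("s$", word) && nchar(word) >= 4 &&
          !grepl("(ss|us|is|as)$", word)) {
        sub("s$", "", word)
      } else word
    }
    text <- vapply(strsplit(text, " ", fixed = TRUE), function(ws) {
      paste(vapply(ws, strip, ""), collapse = " ")
    }, "")
  }
  text
}

#' Link mentions to the top-k ontology terms by cosine similarity
#'
#' Per term, the best score over its label and synonym vectors is used; the
#' top `k` distinct terms are returned in nonincreasing score order, cosine
#' ties broken by lexicographic term id.
#'
#' @param mention character vector of mention strings.
#' @param index an [ontology_index()].
#' @param k number of candidates per mention.
#' @return list of data.frames (one per mention) with columns `term_id`,
#'   `score`; the top-1 score is the linker confidence.
#' @export
link_topk <- function(mention, index, k = 10L) {
  stopifnot(k >= 1)
  if (!length(index$term_id)) stop("empty index")
  V <- index$embedder(mention)
  sims <- V %*% t(index$vectors)
  lapply(seq_along(mention), function(i) {
    best <- tapply(sims[i, ], index$term_id, max)
    ord <- order(-best, names(best))
    top <- ord[seq_len(min(k, length(ord)))]
    data.frame(term_id = names(best)[top], score = unname(best[top]),
               stringsAsFactors = FALSE)
  })
}

# gold id/qualifier sets per annotation as a list of data.frames
.gold_links <- function(gold) {
  if (inherits(gold, "annotated_corpus")) {
    links <- annotation_links(gold)
    ann_ids <- gold$annotations$ann_id
  } else {
    links <- gold
    ann_ids <- unique(gold$ann_id)
  }
  list(links = links, ann_ids = ann_ids)
}

#' Score single-link predictions against possibly multi-identifier gold
#'
#' Micro counts over (annotation, identifier) pairs: a prediction is a TP if
#' its identifier is in the annotation's gold id set and an FP otherwise;
#' each annotation contributes `|gold set| - TP` FNs. In `exact_only` mode,
#' annotations without an exact-match link are dropped and gold sets are
#' reduced to exact ids; in `all_ids` mode exact and related ids are pooled.
#' Unlinked gold annotations have empty gold sets, so any prediction on them
#' is an FP. Because each model links exactly one identifier per annotation,
#' F1 = 1 is unattainable in `all_ids` mode whenever any annotation carries
#' multiple gold identifiers.
#'
#' @param gold an [annotated_corpus()] or a long link table
#'   (`ann_id`, `term_id`, `qualifier`).
#' @param predictions data.frame with `ann_id` and `term_id`, exactly one row
#'   per predicted annotation.
#' @param mode `"exact_only"` or `"all_ids"`.
#' @return one-row data.frame: `mode`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
score_single_link <- function(gold, predictions, mode = c("all_ids", "exact_only")) {
  mode <- match.arg(mode)
  if (anyDuplicated(predictions$ann_id))
    stop("multi-id predictions violate the single-link contract")
  g <- .gold_links(gold)
  links <- g$links
  if (mode == "exact_only") {
    has_exact <- unique(links$ann_id[links$qualifier == "exact"])
    links <- links[links$qualifier == "exact", , drop = FALSE]
    ann_ids <- intersect(g$ann_ids, has_exact)
    predictions <- predictions[predictions$ann_id %in% ann_ids, , drop = FALSE]
  } else {
    ann_ids <- g$ann_ids
  }
  gold_sets <- split(links$term_id, links$ann_id)
  tp <- fp <- fn <- 0L
  for (a in ann_ids) {
    gs <- unique(gold_sets[[a]])
    pr <- predictions$term_id[predictions$ann_id == a]
    hit <- length(pr) == 1 && pr %in% gs
    tp <- tp + hit
    fp <- fp + (length(pr) == 1 && !hit)
    fn <- fn + length(gs) - hit
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  data.frame(mode = mode, tp = tp, fp = fp, fn = fn,
             precision = p, recall = r, f1 = f, stringsAsFactors = FALSE)
}

#' Top-k recall of ranked candidate lists
#'
#' Fraction of gold-linked annotations whose gold identifier set (exact and
#' related pooled, without differentiating) intersects the top `k` ranked
#' candidates. Annotation-level: one unit per annotation. Rankings shorter
#' than `k` are used as-is.
#'
#' @param gold an [annotated_corpus()] or long link table.
#' @param rankings named list: `ann_id` -> data.frame with ranked `term_id`
#'   (as returned by [link_topk()]).
#' @param k cutoff.
#' @return recall in `[0, 1]`.
#' @export
topk_recall <- function(gold, rankings, k) {
  g <- .gold_links(gold)
  gold_sets <- split(g$links$term_id, g$links$ann_id)
  linked <- names(gold_sets)
  if (!length(linked)) return(NA_real_)
  hits <- vapply(linked, function(a) {
    r <- rankings[[a]]
    if (is.null(r) || !nrow(r)) return(FALSE)
    any(utils::head(r$term_id, k) %in% gold_sets[[a]])
  }, TRUE)
  mean(hits)
}

#' ROC curve and AUROC for novelty detection from linker confidence
#'
#' Assesses how well a confidence score separates ontology-mapped mentions
#' (exact match available; positives) from novel ones. AUROC uses the rank
#' statistic (concordant pairs + half ties) / (n+ * n-); the curve lists
#' TPR/FPR at every distinct score threshold.
#'
#' @param score numeric confidence scores.
#' @param is_positive logical labels (both classes must be present).
#' @return list with `auroc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
novelty_roc <- function(score, is_positive) {
  stopifnot(length(score) == length(is_positive))
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(score)
  auroc <- (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(score), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) sum(score[!is_positive] >= t) / n_neg, 0)),
    tpr = c(0, vapply(thr, function(t) sum(score[is_positive] >= t) / n_pos, 0)))
  list(auroc = auroc, curve = curve)
}
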