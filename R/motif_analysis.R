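# Compositional naming-motif labeling, fractional lineage assignment, and
# prevalence testing with exact statistics under FDR control.

#' Extract candidate motif phrases from a tokenized name
#'
#' All contiguous token ranges of length one to three (overlaps permitted)
#' that do not intersect a manually labeled motif span and do not begin or
#' end with a stop word.
#'
#' @param tokens character vector of (lemmatized) tokens.
#' @param manual_spans data.frame with `token_start`, `token_end` (1-based
#'   inclusive) of already-placed manual motifs, or `NULL`.
#' @param stopwords character vector of stop words.
#' @return data.frame with `token_start`, `token_end`.
#' @export
extract_candidates <- function(tokens, manual_spans = NULL,
                               stopwords = character()) {
  n <- length(tokens)
  blocked <- rep(FALSE, n)
  if (!is.null(manual_spans) && nrow(manual_spans)) {
    stopifnot(all(manual_spans$token_start >= 1),
              all(manual_spans$token_end <= n))
    for (r in seq_len(nrow(manual_spans))) {
      blocked[manual_spans$token_start[r]:manual_spans$token_end[r]] <- TRUE
    }
  }
  is_stop <- tolower(tokens) %in% tolower(stopwords)
  out <- list()
  for (i in seq_len(n)) {
    for (len in 1:3) {
      j <- i + len - 1L
      if (j > n) break
      if (any(blocked[i:j])) next
      if (is_stop[i] || is_stop[j]) next
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) {
    return(data.frame(token_start = integer(), token_end = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(token_start = m[, 1], token_end = m[, 2])
}

#' Apply a manually curated lemma-sequence to motif-type map
#'
#' Greedy left-to-right longest non-overlapping matching: at each position the
#' longest mapped phrase (up to 3 tokens) wins, then scanning resumes after
#' it.
#'
#' @param tokens character vector of tokens.
#' @param manual_map named character vector mapping space-joined lemma
#'   sequences to motif types.
#' @return data.frame of motif spans (`motif_type`, `token_start`,
#'   `token_end`, `phrase`, `source = "manual"`).
#' @export
apply_manual_map <- function(tokens, manual_map) {
  out <- list()
  n <- length(tokens)
  max_len <- if (length(manual_map)) {
    max(lengths(strsplit(names(manual_map), " ", fixed = TRUE)))
  } else 0L
  i <- 1L
  while (i <= n) {
    placed <- FALSE
    for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
      if (len < 1L) break
      phrase <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      mt <- unname(manual_map[phrase])
      if (length(mt) == 1 && !is.na(mt)) {
        out[[length(out) + 1L]] <- data.frame(
          motif_type = mt, token_start = i, token_end = i + len - 1L,
          phrase = phrase, source = "manual", stringsAsFactors = FALSE)
        i <- i + len
        placed <- TRUE
        break
      }
    }
    if (!placed) i <- i + 1L
  }
  if (!length(out)) {
    return(data.frame(motif_type = character(), token_start = integer(),
                      token_end = integer(), phrase = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' The manual motif map shipped with the synthetic-data generator
#'
#' Maps every word in [motif_vocabulary()], the lineage adjectives, and the
#' root words to their motif type, so manual labeling alone recovers the
#' generator's ground-truth spans exactly.
#'
#' @param lineages lineage labels to map to the `lineage` motif type.
#' @return named character vector (phrase -> motif type).
#' @export
default_manual_map <- function(lineages = .default_lineages) {
  vocab <- motif_vocabulary()
  map <- unlist(lapply(names(vocab), function(mt) {
    stats::setNames(rep(mt, length(vocab[[mt]])), vocab[[mt]])
  }))
  map <- c(map, stats::setNames(rep("lineage", length(lineages)), lineages))
  map <- c(map, cell = "root", cells = "root")
  # also key by the plural-stemmed form so the default tokenizer still matches
  stemmed <- stats::setNames(map, preprocess_mention(names(map)))
  c(map, stemmed[!names(stemmed) %in% names(map)])
}

#' Train a multinomial logistic-regression motif classifier
#'
#' Embeds the labeled phrases and fits a (lightly ridge-regularized)
#' multinomial logistic regression; exposes per-class probabilities.
#' Deterministic given its inputs.
#'
#' @param texts character vector of labeled phrases.
#' @param labels motif-type labels (>= 2 distinct classes required).
#' @param embedder an embedding function as from [toy_embedder()].
#' @param lambda ridge penalty (small; a pure MLE is not identifiable for
#'   separable toy data).
#' @return object of class `motif_classifier`.
#' @export
train_motif_classifier <- function(texts, labels, embedder = toy_embedder(),
                                   lambda = 1e-3) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 motif classes to train")
  x <- embedder(texts)
  # glmnet needs a decreasing lambda path for a reliable fit at small lambda
  path <- lambda * c(1000, 100, 10, 1)
  fit <- suppressWarnings(
    glmnet::glmnet(x, factor(labels), family = "multinomial",
                   lambda = path, alpha = 0, standardize = FALSE))
  structure(list(fit = fit, classes = levels(factor(labels)),
                 embedder = embedder, lambda = lambda),
            class = "motif_classifier")
}

#' Predict motif-type probabilities for phrases
#'
#' @param object a [train_motif_classifier()] model.
#' @param texts character vector of phrases.
#' @param ... unused.
#' @return matrix of class probabilities (rows sum to 1), with attributes
#'   `label` (argmax class) and `margin` (difference between highest and
#'   second-highest probability).
#' @export
predict_motifs <- function(object, texts, ...) {
  x <- object$embedder(texts)
  probs <- stats::predict(object$fit, newx = x, type = "response",
                          s = object$lambda)[, , 1]
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, object$classes))
  top <- apply(probs, 1, function(p) {
    o <- order(-p)
    c(o[1], p[o[1]] - if (length(p) > 1) p[o[2]] else 0)
  })
  attr(probs, "label") <- colnames(probs)[top[1, ]]
  attr(probs, "margin") <- top[2, ]
  probs
}

#' Cross-validated accuracy of the motif classifier
#'
#' Stratified k-fold cross-validation repeated several times (the accuracy
#' estimation protocol: 10 folds, 5 repeats).
#'
#' @inheritParams train_motif_classifier
#' @param folds,repeats protocol parameters.
#' @param seed integer seed for fold assignment.
#' @return mean held-out accuracy.
#' @export
cv_motif_accuracy <- function(texts, labels, embedder = toy_embedder(),
                              folds = 10L, repeats = 5L, seed = 1L,
                              lambda = 1e-3) {
  labels <- as.character(labels)
  with_seed(seed, {
    accs <- numeric()
    for (r in seq_len(repeats)) {
      fold_of <- integer(length(labels))
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
      for (f in seq_len(folds)) {
        test <- fold_of == f
        if (!any(test) || length(unique(labels[!test])) < 2) next
        clf <- train_motif_classifier(texts[!test], labels[!test], embedder,
                                      lambda = lambda)
        pred <- attr(predict_motifs(clf, texts[test]), "label")
        accs <- c(accs, mean(pred == labels[test]))
      }
    }
    mean(accs)
  })
}

#' Assign motif spans to a tokenized name
#'
#' Manually mapped motifs are placed first (longest non-overlapping matches);
#' remaining candidate phrases are labeled by the classifier and added in
#' order of increasing margin (difference between the highest and
#' second-highest predicted probabilities), each added only if it does not
#' overlap an already-placed span. Set `margin_order = "decreasing"` to place
#' the most confident candidates first instead.
#'
#' @param tokens character vector of tokens.
#' @param manual_map named map as in [apply_manual_map()].
#' @param classifier optional [train_motif_classifier()] model; when `NULL`
#'   only manual spans are returned.
#' @param stopwords stop words for candidate extraction.
#' @param margin_order `"increasing"` (default) or `"decreasing"`.
#' @return data.frame of pairwise non-overlapping motif spans with `source`
#'   (`manual` or `classifier`) and `margin` (`NA` for manual).
#' @export
assign_motifs <- function(tokens, manual_map, classifier = NULL,
                          stopwords = c("and", "or", "of", "the"),
                          margin_order = c("increasing", "decreasing")) {
  margin_order <- match.arg(margin_order)
  manual <- apply_manual_map(tokens, manual_map)
  manual$margin <- rep(NA_real_, nrow(manual))
  if (is.null(classifier)) return(manual)
  cands <- extract_candidates(tokens, manual, stopwords)
  if (!nrow(cands)) return(manual)
  phrases <- vapply(seq_len(nrow(cands)), function(r) {
    paste(tokens[cands$token_start[r]:cands$token_end[r]], collapse = " ")
  }, "")
  probs <- predict_motifs(classifier, phrases)
  cands$motif_type <- attr(probs, "label")
  cands$margin <- attr(probs, "margin")
  cands$phrase <- phrases
  cands$source <- "classifier"
  ord <- order(if (margin_order == "increasing") cands$margin else -cands$margin,
               cands$token_start)
  occupied <- rep(FALSE, length(tokens))
  if (nrow(manual)) {
    for (r in seq_len(nrow(manual))) {
      occupied[manual$token_start[r]:manual$token_end[r]] <- TRUE
    }
  }
  placed <- list()
  for (r in ord) {
    span <- cands$token_start[r]:cands$token_end[r]
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    placed[[length(placed) + 1L]] <- cands[r, ]
  }
  cols <- c("motif_type", "token_start", "token_end", "phrase", "source", "margin")
  out <- rbind(manual[, cols, drop = FALSE],
               if (length(placed)) do.call(rbind, placed)[, cols, drop = FALSE])
  out[order(out$token_start), , drop = FALSE]
}

#' Default tokenizer for mention text
#'
#' Lowercases, splits on whitespace, and applies the conservative plural
#' stemmer (full lemmatizers are a pluggable alternative).
#'
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
tokenize_mention <- function(text) {
  toks <- strsplit(tolower(trimws(text)), "[[:space:]]+")[[1]]
  vapply(toks, function(w) preprocess_mention(w, stem_plurals = TRUE), "",
         USE.NAMES = FALSE)
}

#' Fractional lineage assignment of an annotation
#'
#' Each linked identifier carries weight `1/|links|`, split equally across
#' the lineages whose root set intersects the identifier or its ancestors;
#' weights are summed over links and renormalized over lineage-hitting links
#' so they sum to 1. Returns an empty vector when no link hits any lineage
#' (the annotation is excluded as lineage-less).
#'
#' @param term_ids character vector of linked identifiers.
#' @param ontology an [ontology()].
#' @param lineage_map named list lineage -> root term ids (or a named
#'   character vector).
#' @return named numeric weights summing to 1 (or empty).
#' @export
assign_lineages <- function(term_ids, ontology, lineage_map) {
  if (!is.list(lineage_map)) lineage_map <- as.list(lineage_map)
  w <- stats::setNames(numeric(length(lineage_map)), names(lineage_map))
  term_ids <- term_ids[nzchar(term_ids)]
  if (!length(term_ids)) return(w[0])
  for (id in term_ids) {
    anc <- c(id, ancestors(ontology, id))
    hit <- names(lineage_map)[vapply(lineage_map, function(r) any(r %in% anc), TRUE)]
    if (!length(hit)) next
    w[hit] <- w[hit] + (1 / length(term_ids)) / length(hit)
  }
  w <- w[w > 0]
  if (!length(w)) return(w)
  w / sum(w)
}

#' Scope filter preceding motif analysis
#'
#' Keeps annotations that name a single cell population with at least one
#' ontology link: vague, unlinked and coordination-ellipsis annotations are
#' removed, as are annotations whose text contains a keyword indicating
#' artificial or abnormal cells.
#'
#' @param corpus an [annotated_corpus()].
#' @param exclude_keywords case-insensitive keywords to drop.
#' @param qualifier optionally restrict to `"exact"`- or `"related"`-linked
#'   annotations (default keeps both).
#' @return the corpus with its annotation table filtered.
#' @export
motif_scope_filter <- function(corpus,
                               exclude_keywords = c("cultured", "ipsc-derived",
                                                    "abnormal", "infected"),
                               qualifier = NULL) {
  ann <- corpus$annotations
  keep <- ann$entity_type != "vague" & nzchar(ann$identifiers) & !ann$coordination
  if (length(exclude_keywords)) {
    pat <- paste(exclude_keywords, collapse = "|")
    keep <- keep & !grepl(pat, ann$text, ignore.case = TRUE)
  }
  if (!is.null(qualifier)) {
    has_q <- vapply(strsplit(ann$qualifiers, ";", fixed = TRUE),
                    function(q) qualifier %in% q, TRUE)
    keep <- keep & has_q
  }
  corpus$annotations <- ann[keep, , drop = FALSE]
  corpus
}

#' Weighted motif prevalence per lineage
#'
#' Prevalence is the proportion of mentions in which a motif type appears at
#' least once, with fractional lineage weights propagated to the counts: for
#' lineage L and motif m, numerator = sum over annotations of
#' `w_L(a) * 1[m in a]` and denominator = sum of `w_L(a)`. A pooled baseline
#' row (`lineage = "ALL"`) aggregates all lineages.
#'
#' @param motifs data.frame with `ann_id`, `motif_type` (one row per placed
#'   motif span).
#' @param weights data.frame with `ann_id`, `lineage`, `weight` (per-annotation
#'   weights summing to 1); annotations without weights are excluded.
#' @param motif_vocab motif vocabulary for the table rows.
#' @return data.frame with `lineage`, `motif_type`, `numerator`,
#'   `denominator`, `prevalence`.
#' @export
prevalence_table <- function(motifs, weights, motif_vocab = motif_types()) {
  lineages <- unique(weights$lineage)
  if (!length(lineages)) stop("no lineage weights supplied")
  has_motif <- unique(motifs[, c("ann_id", "motif_type")])
  rows <- list()
  for (lin in c(lineages, "ALL")) {
    wsub <- if (lin == "ALL") weights else weights[weights$lineage == lin, , drop = FALSE]
    denom <- sum(wsub$weight)
    if (denom <= 0) {
      message("lineage ", lin, " has zero total weight; omitted")
      next
    }
    wa <- tapply(wsub$weight, wsub$ann_id, sum)
    for (mt in motif_vocab) {
      with_m <- unique(has_motif$ann_id[has_motif$motif_type == mt])
      num <- sum(wa[names(wa) %in% with_m])
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = lin, motif_type = mt, numerator = num, denominator = denom,
        prevalence = num / denom, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Exact two-sided binomial test (minimum-likelihood method)
#'
#' p-value = sum of `Binom(i; n, p0)` over all outcomes `i` whose point
#' probability does not exceed that of the observed `k` (within a 1e-9
#' relative tolerance).
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials.
#' @param p0 null success probability in (0, 1).
#' @return p-value.
#' @export
binom_test_exact <- function(k, n, p0) {
  if (!(k >= 0 && k <= n && n >= 1)) stop("require 0 <= k <= n, n >= 1")
  if (!(p0 > 0 && p0 < 1)) stop("require 0 < p0 < 1")
  probs <- stats::dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-9)]))
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Sums hypergeometric point probabilities not exceeding that of the observed
#' table, over all tables with the same margins. Degenerate margins (an empty
#' row or column) give p = 1 with a notice.
#'
#' @param a,b,c,d nonnegative integer cell counts, table `rbind(c(a, b), c(c, d))`.
#' @return p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be nonnegative integers")
  m1 <- a + b
  m2 <- c + d
  c1 <- a + c
  if (m1 == 0 || m2 == 0 || c1 == 0 || (b + d) == 0) {
    message("degenerate margins: p = 1")
    return(1)
  }
  support <- max(0, c1 - m2):min(m1, c1)
  probs <- stats::dhyper(support, m1, m2, c1)
  obs <- stats::dhyper(a, m1, m2, c1)
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j` over the sorted p-values, clipped to
#' 1, returned in input order. `NA`s are preserved and excluded from `m`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(p_values))
  if (m) {
    o <- order(p)
    ranked <- p[o] * m / seq_len(m)
    ranked <- rev(cummin(rev(ranked)))
    qs <- numeric(m)
    qs[o] <- pmin(1, ranked)
    q[ok] <- qs
  }
  q
}

#' Test motif-prevalence differences per lineage under FDR control
#'
#' Each (lineage, motif) cell of `table` is compared to a reference
#' prevalence by an exact two-sided binomial test with fractional counts
#' rounded (round-half-to-even): `k = round(numerator)`,
#' `n = round(denominator)`, `p0` = the reference prevalence. With
#' `reference = NULL` the reference is the table's own pooled `ALL` row
#' (lineage under test included in the baseline); with a second prevalence
#' table as reference, the matching cell's prevalence is used and the pooled
#' `ALL` rows are compared by Fisher's exact test on the rounded with/without
#' counts. All p-values are Benjamini-Hochberg adjusted jointly; significance
#' is declared at `q < alpha_fdr` (default FDR < 0.01).
#'
#' @param table a [prevalence_table()].
#' @param reference `NULL` (pooled baseline) or another [prevalence_table()].
#' @param alpha_fdr FDR threshold.
#' @return data.frame with `lineage`, `motif_type`, `test`, `k`, `n`, `p0`,
#'   `p_value`, `q_value`, `significant`, `direction`.
#' @export
compare_prevalence <- function(table, reference = NULL, alpha_fdr = 0.01) {
  rows <- list()
  lin_rows <- table[table$lineage != "ALL", , drop = FALSE]
  if (is.null(reference)) {
    base <- table[table$lineage == "ALL", , drop = FALSE]
    p0_of <- stats::setNames(base$prevalence, base$motif_type)
    for (i in seq_len(nrow(lin_rows))) {
      r <- lin_rows[i, ]
      p0 <- p0_of[[r$motif_type]]
      k <- round(r$numerator)
      n <- round(r$denominator)
      if (is.null(p0) || is.na(p0) || p0 <= 0 || p0 >= 1 || n < 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = r$lineage, motif_type = r$motif_type, test = "binomial",
        k = k, n = n, p0 = p0, p_value = binom_test_exact(k, n, p0),
        direction = if (k / n >= p0) "higher" else "lower",
        stringsAsFactors = FALSE)
    }
  } else {
    if (!setequal(paste(table$lineage, table$motif_type),
                  paste(reference$lineage, reference$motif_type)))
      stop("table and reference must share lineages and motif types")
    key <- function(t) paste(t$lineage, t$motif_type)
    ref <- reference[match(key(lin_rows), key(reference)), , drop = FALSE]
    for (i in seq_len(nrow(lin_rows))) {
      r <- lin_rows[i, ]
      p0 <- ref$prevalence[i]
      k <- round(r$numerator)
      n <- round(r$denominator)
      if (is.na(p0) || p0 <= 0 || p0 >= 1 || n < 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = r$lineage, motif_type = r$motif_type, test = "binomial",
        k = k, n = n, p0 = p0, p_value = binom_test_exact(k, n, p0),
        direction = if (k / n >= p0) "higher" else "lower",
        stringsAsFactors = FALSE)
    }
    tab_all <- table[table$lineage == "ALL", , drop = FALSE]
    ref_all <- reference[reference$lineage == "ALL", , drop = FALSE]
    ref_all <- ref_all[match(tab_all$motif_type, ref_all$motif_type), , drop = FALSE]
    for (i in seq_len(nrow(tab_all))) {
      a <- round(tab_all$numerator[i])
      b <- round(tab_all$denominator[i]) - a
      cc <- round(ref_all$numerator[i])
      d <- round(ref_all$denominator[i]) - cc
      if (b < 0 || d < 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = "ALL", motif_type = tab_all$motif_type[i], test = "fisher",
        k = a, n = a + b, p0 = ref_all$prevalence[i],
        p_value = suppressMessages(fisher_exact(a, b, cc, d)),
        direction = if (tab_all$prevalence[i] >= ref_all$prevalence[i])
          "higher" else "lower",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(lineage = character(), motif_type = character(),
                      test = character(), k = numeric(), n = numeric(),
                      p0 = numeric(), p_value = numeric(), q_value = numeric(),
                      significant = logical(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha_fdr
  out[, c("lineage", "motif_type", "test", "k", "n", "p0", "p_value",
          "q_value", "significant", "direction")]
}

#' Label motifs for every in-scope annotation of a corpus
#'
#' Convenience wrapper: applies the scope filter, tokenizes each mention with
#' [tokenize_mention()] (optionally after abbreviation expansion), assigns
#' motif spans via [assign_motifs()], and computes fractional lineage weights
#' via [assign_lineages()].
#'
#' @param corpus an [annotated_corpus()].
#' @param ontology an [ontology()].
#' @param lineage_map named lineage -> root id map (defaults to the
#'   ontology's `lineage_roots` when present).
#' @param manual_map manual motif map (default [default_manual_map()]).
#' @param classifier optional motif classifier.
#' @param abbreviation_map optional abbreviation expansion map.
#' @param ... passed to [assign_motifs()].
#' @return list with `motifs` (`ann_id`, `motif_type`, `token_start`,
#'   `token_end`, `phrase`, `source`, `margin`) and `weights` (`ann_id`,
#'   `lineage`, `weight`).
#' @export
label_motifs <- function(corpus, ontology, lineage_map = ontology$lineage_roots,
                         manual_map = default_manual_map(names(lineage_map)),
                         classifier = NULL, abbreviation_map = NULL, ...) {
  if (is.null(lineage_map)) stop("lineage_map is required")
  scoped <- motif_scope_filter(corpus)
  ann <- scoped$annotations
  links <- annotation_links(scoped)
  link_sets <- split(links$term_id, links$ann_id)
  motif_rows <- list()
  weight_rows <- list()
  for (i in seq_len(nrow(ann))) {
    w <- assign_lineages(link_sets[[ann$ann_id[i]]], ontology, lineage_map)
    if (!length(w)) next
    weight_rows[[length(weight_rows) + 1L]] <- data.frame(
      ann_id = ann$ann_id[i], lineage = names(w), weight = unname(w),
      stringsAsFactors = FALSE)
    text <- ann$text[i]
    if (!is.null(abbreviation_map))
      text <- preprocess_mention(text, abbreviation_map, stem_plurals = FALSE)
    spans <- assign_motifs(tokenize_mention(text), manual_map, classifier, ...)
    if (nrow(spans)) {
      spans$ann_id <- ann$ann_id[i]
      motif_rows[[length(motif_rows) + 1L]] <- spans
    }
  }
  list(motifs = if (length(motif_rows)) do.call(rbind, motif_rows) else
         data.frame(ann_id = character(), motif_type = character()),
       weights = if (length(weight_rows)) do.call(rbind, weight_rows) else
         data.frame(ann_id = character(), lineage = character(),
                    weight = numeric()))
}
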