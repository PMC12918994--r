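# Scoring of span predictions against gold annotations: exact or approximate
# (overlap) span matching, typed or merged labels, micro-averaged P/R/F1.

#' Match predicted annotations to gold annotations
#'
#' One-to-one matching within a passage. Exact mode requires identical
#' `(start, end)` (and identical entity type when `label_mode = "typed"`);
#' approximate mode requires span overlap of at least one character (and the
#' same type when typed). Greedy resolution: gold annotations are processed
#' by start offset; each takes the unmatched qualifying prediction with the
#' largest overlap, ties broken by lowest prediction index. Each prediction
#' may match at most one gold annotation and vice versa.
#'
#' @param gold,pred annotation data.frames (`passage_id`, `start`, `end`,
#'   `entity_type`, `ann_id`).
#' @param span_mode `"exact"` or `"approx"`.
#' @param label_mode `"typed"` or `"merged"`.
#' @return data.frame of matched pairs (`gold_ann_id`, `pred_ann_id`).
#' @export
match_annotations <- function(gold, pred, span_mode = c("exact", "approx"),
                              label_mode = c("typed", "merged")) {
  span_mode <- match.arg(span_mode)
  label_mode <- match.arg(label_mode)
  out <- list()
  for (p in unique(gold$passage_id)) {
    g <- gold[gold$passage_id == p, , drop = FALSE]
    q <- pred[pred$passage_id == p, , drop = FALSE]
    if (!nrow(q)) next
    g <- g[order(g$start, g$end), , drop = FALSE]
    used <- rep(FALSE, nrow(q))
    for (i in seq_len(nrow(g))) {
      type_ok <- if (label_mode == "typed") q$entity_type == g$entity_type[i]
                 else rep(TRUE, nrow(q))
      if (span_mode == "exact") {
        cand <- which(!used & type_ok & q$start == g$start[i] & q$end == g$end[i])
        if (length(cand)) {
          j <- cand[1]
          used[j] <- TRUE
          out[[length(out) + 1L]] <- data.frame(gold_ann_id = g$ann_id[i],
                                                pred_ann_id = q$ann_id[j],
                                                stringsAsFactors = FALSE)
        }
      } else {
        ov <- pmin(g$end[i], q$end) - pmax(g$start[i], q$start)
        ov[used | !type_ok] <- 0L
        if (any(ov > 0)) {
          j <- which(ov == max(ov))[1]
          used[j] <- TRUE
          out[[length(out) + 1L]] <- data.frame(gold_ann_id = g$ann_id[i],
                                                pred_ann_id = q$ann_id[j],
                                                stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gold_ann_id = character(), pred_ann_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Score span predictions against gold annotations
#'
#' Micro-aggregated counts from [match_annotations()] across passages, with a
#' per-entity-type breakdown (FN typed by the gold annotation, FP by the
#' prediction) and an overall row. Undefined precision or recall is reported
#' as 0.
#'
#' @param gold,pred [annotated_corpus()] objects or annotation data.frames.
#' @inheritParams match_annotations
#' @return data.frame with one row per entity type plus `overall`:
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
score_ner <- function(gold, pred, span_mode = c("exact", "approx"),
                      label_mode = c("typed", "merged")) {
  span_mode <- match.arg(span_mode)
  label_mode <- match.arg(label_mode)
  if (inherits(gold, "annotated_corpus")) gold <- gold$annotations
  if (inherits(pred, "annotated_corpus")) pred <- pred$annotations
  matches <- match_annotations(gold, pred, span_mode, label_mode)
  gold_matched <- gold$ann_id %in% matches$gold_ann_id
  pred_matched <- pred$ann_id %in% matches$pred_ann_id
  types <- if (label_mode == "merged") character() else
    sort(unique(c(gold$entity_type, pred$entity_type)))
  row_for <- function(tp, fp, fn, label) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(entity_type = label, tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f1 = f, stringsAsFactors = FALSE)
  }
  rows <- lapply(types, function(ty) {
    # in typed mode a match's gold and pred types agree, so TP per type is
    # well-defined from the gold side
    tp <- sum(gold_matched & gold$entity_type == ty)
    fn <- sum(!gold_matched & gold$entity_type == ty)
    fp <- sum(!pred_matched & pred$entity_type == ty)
    row_for(tp, fp, fn, ty)
  })
  overall <- row_for(nrow(matches), sum(!pred_matched), sum(!gold_matched),
                     "overall")
  out <- do.call(rbind, c(rows, list(overall)))
  attr(out, "span_mode") <- span_mode
  attr(out, "label_mode") <- label_mode
  out
}
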