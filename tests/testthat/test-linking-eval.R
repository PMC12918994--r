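test_that("preprocess_mention expands abbreviations then strips plurals", {
  expect_identical(preprocess_mention("Tregs", c(Tregs = "regulatory T cells")),
                   "regulatory T cell")
  expect_identical(preprocess_mention("cells"), "cell")
  expect_identical(preprocess_mention("pancreas"), "pancreas")
  expect_identical(preprocess_mention("class"), "class")
  expect_identical(preprocess_mention("nucleus"), "nucleus")
  # idempotent
  once <- preprocess_mention("exhausted T cells")
  expect_identical(preprocess_mention(once), once)
})

test_that("the toy embedder is deterministic and unit-norm", {
  emb <- toy_embedder()
  v1 <- emb(c("endothelial cell", "endothelial cell", "neuron"))
  expect_equal(v1[1, ], v1[2, ])
  expect_false(isTRUE(all.equal(v1[1, ], v1[3, ])))
  expect_equal(sqrt(rowSums(v1^2)), rep(1, 3), tolerance = 1e-6)
})

test_that("link_topk ranks by cosine with deterministic tie-breaking", {
  onto <- chain_ontology()
  idx <- ontology_index(onto)
  # a mention identical to a unique label ranks that term first at score 1
  r <- link_topk("alpha sub cell", idx, k = 2)[[1]]
  expect_identical(r$term_id[1], "T:B")
  expect_equal(r$score[1], 1, tolerance = 1e-9)
  # k = |terms| yields a permutation of all terms
  r_all <- link_topk("alpha cell", idx, k = 10)[[1]]
  expect_setequal(r_all$term_id, onto$terms$id)
  expect_true(all(diff(r_all$score) <= 1e-12))
})

test_that("link_topk agrees with a brute-force cosine oracle", {
  onto <- generate_ontology(3, 3, 2, seed = 14)
  emb <- toy_embedder()
  idx <- ontology_index(onto, emb)
  mentions <- c("epithelial cell type 3", "neuronal cell", "cd8+ cell")
  ranks <- link_topk(mentions, idx, k = 5)
  for (i in seq_along(mentions)) {
    v <- emb(mentions[i])[1, ]
    sims <- as.numeric(idx$vectors %*% v)
    per_term <- tapply(sims, idx$term_id, max)
    oracle <- names(per_term)[order(-per_term, names(per_term))][1:5]
    expect_identical(ranks[[i]]$term_id, oracle)
  }
})

test_that("score_single_link implements pair counting per mode", {
  gold <- data.frame(ann_id = c("a1", "a2", "a2"),
                     term_id = c("T:A", "T:X", "T:Y"),
                     qualifier = c("exact", "related", "related"))
  # a1 predicted correctly, exact_only drops a2 entirely
  pred <- data.frame(ann_id = c("a1", "a2"), term_id = c("T:A", "T:X"))
  s_ex <- score_single_link(gold, pred, "exact_only")
  expect_equal(s_ex$f1, 1)
  expect_identical(s_ex$tp + s_ex$fp, 1L)
  # all_ids: a2 has 2 gold ids, one predicted -> P = 1, R = 2/3 over pairs
  s_all <- score_single_link(gold, pred, "all_ids")
  expect_equal(s_all$precision, 1)
  expect_equal(s_all$recall, 2 / 3)
  expect_equal(s_all$f1, 2 * (1 * 2 / 3) / (1 + 2 / 3))
  # the multi-id gold annotation caps all_ids F1 below 1 (single-link ceiling)
  expect_lt(s_all$f1, 1)
  # duplicate predictions violate the contract
  expect_error(score_single_link(gold, rbind(pred, pred), "all_ids"),
               "single-link")
  # gold {A, B} related, predicted A -> F1 = 2/3
  gold2 <- data.frame(ann_id = "a1", term_id = c("T:A", "T:B"),
                      qualifier = "related")
  s2 <- score_single_link(gold2, data.frame(ann_id = "a1", term_id = "T:A"),
                          "all_ids")
  expect_equal(s2$f1, 2 / 3)
})

test_that("predictions on unlinked gold annotations count as false positives", {
  corp <- mini_corpus(anns = list(list(start = 0, end = 11)))  # no links
  s <- score_single_link(corp, data.frame(ann_id = "a1", term_id = "T:A"),
                         "all_ids")
  expect_identical(s$fp, 1L)
  expect_identical(s$tp, 0L)
})

test_that("top-k recall is monotone in k and matches hand counts", {
  gold <- data.frame(ann_id = c("a1", "a2", "a3", "a4"),
                     term_id = c("T:1", "T:2", "T:3", "T:4"),
                     qualifier = c("exact", "related", "exact", "exact"))
  rk <- function(ids) data.frame(term_id = ids, score = seq(1, 0.1, length.out = length(ids)))
  rankings <- list(a1 = rk(c("T:1", "T:9")),      # hit at k = 1
                   a2 = rk(c("T:9", "T:2")),      # hit at k = 2
                   a3 = rk(c("T:9", "T:8", "T:3")),  # hit at k = 3
                   a4 = rk(c("T:9", "T:8")))      # never hit
  expect_equal(topk_recall(gold, rankings, 1), 1 / 4)
  expect_equal(topk_recall(gold, rankings, 2), 2 / 4)
  expect_equal(topk_recall(gold, rankings, 10), 3 / 4)
  ks <- vapply(1:10, topk_recall, 0, gold = gold, rankings = rankings)
  expect_true(all(diff(ks) >= 0))
})

test_that("novelty_roc matches the hand-computed rank statistic", {
  r <- novelty_roc(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auroc, 0.75)  # 3 of 4 concordant pairs
  expect_equal(novelty_roc(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE))$auroc, 0.5)
  expect_error(novelty_roc(c(0.2, 0.4), c(TRUE, TRUE)), "both classes")
})

test_that("rank-statistic AUROC equals the trapezoidal area under the curve", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    score <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # induce ties
    lab <- stats::runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    r <- novelty_roc(score, lab)
    trap <- sum(diff(r$curve$fpr) * (utils::head(r$curve$tpr, -1) +
                                       utils::tail(r$curve$tpr, -1)) / 2)
    expect_equal(r$auroc, trap, tolerance = 1e-9)
  }
})

test_that("verbatim-label linking achieves F1 = 1 in exact_only mode", {
  cfg <- generator_config(seed = 41, n_passages = 25, exact_link_fraction = 1,
                          multi_id_fraction = 0, vague_fraction = 0)
  gen <- generate_corpus(cfg)
  idx <- ontology_index(gen$ontology)
  ann <- gen$corpus$annotations
  # restrict to mentions whose label is unique in the ontology
  lab <- gen$ontology$terms$label
  unique_labels <- names(which(table(lab) == 1))
  ann <- ann[ann$text %in% unique_labels, ]
  expect_gt(nrow(ann), 20)
  ranks <- link_topk(ann$text, idx, k = 1)
  pred <- data.frame(ann_id = ann$ann_id,
                     term_id = vapply(ranks, function(r) r$term_id[1], ""))
  gold <- annotation_links(gen$corpus)
  gold <- gold[gold$ann_id %in% ann$ann_id, ]
  s <- score_single_link(gold, pred, "exact_only")
  expect_equal(s$f1, 1)
})
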