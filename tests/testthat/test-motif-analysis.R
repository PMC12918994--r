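test_that("the motif vocabulary is closed with exactly 14 types", {
  expect_identical(length(motif_types()), 14L)
  expect_setequal(motif_types(),
                  c("root", "anatomical_context", "lineage",
                    "molecular_signature", "appearance", "functional_role",
                    "developmental_stage", "state", "variant",
                    "molecular_signaling", "disease", "eponym", "stimulus",
                    "species_sex"))
  expect_true(all(names(motif_vocabulary()) %in% motif_types()))
})

test_that("candidate extraction enumerates 1-3 token ranges under both filters", {
  # 3 tokens, no constraints: 3 + 2 + 1 = 6 candidates
  c6 <- extract_candidates(c("exhausted", "cd8", "t"))
  expect_identical(nrow(c6), 6L)
  expect_true(all(c6$token_end - c6$token_start + 1 <= 3))
  # stopword endpoints are excluded but interior stopwords allowed
  c3 <- extract_candidates(c("t", "and", "nk"), stopwords = "and")
  expect_identical(nrow(c3), 3L)
  expect_setequal(paste(c3$token_start, c3$token_end),
                  c("1 1", "3 3", "1 3"))
  # a manual span covering everything blocks all candidates
  c0 <- extract_candidates(c("a", "b"), manual_spans = data.frame(
    token_start = 1L, token_end = 2L))
  expect_identical(nrow(c0), 0L)
})

test_that("manual map matching is greedy left-to-right, longest first", {
  m1 <- apply_manual_map(c("regulatory", "t", "cell"),
                         c(regulatory = "functional_role"))
  expect_identical(m1$motif_type, "functional_role")
  expect_identical(m1$source, "manual")
  # the 2-token entry beats its 1-token prefix
  map <- c("cardiac" = "anatomical_context",
           "cardiac muscle" = "anatomical_context")
  m2 <- apply_manual_map(c("cardiac", "muscle", "cell"), map)
  expect_identical(m2$token_end[1], 2L)
  expect_identical(nrow(apply_manual_map(c("a", "b"), character())), 0L)
})

test_that("classifier reaches perfect accuracy on separable vocabulary", {
  vocab <- motif_vocabulary()
  texts <- unlist(vocab, use.names = FALSE)
  labels <- rep(names(vocab), lengths(vocab))
  expect_error(train_motif_classifier(texts, rep("state", length(texts))),
               "2 motif classes")
  clf <- train_motif_classifier(texts, labels)
  probs <- predict_motifs(clf, texts)
  expect_equal(unname(rowSums(probs)), rep(1, length(texts)), tolerance = 1e-9)
  expect_identical(attr(probs, "label"), labels)
  expect_true(all(attr(probs, "margin") >= 0))
})

test_that("assign_motifs places manual spans first, then candidates by margin", {
  vocab <- motif_vocabulary()
  clf <- train_motif_classifier(unlist(vocab, use.names = FALSE),
                                rep(names(vocab), lengths(vocab)))
  tokens <- c("exhausted", "cd8+", "t", "cell")
  spans <- assign_motifs(tokens, default_manual_map(), clf)
  # pairwise disjoint, always
  cov <- unlist(lapply(seq_len(nrow(spans)),
                       function(i) spans$token_start[i]:spans$token_end[i]))
  expect_identical(anyDuplicated(cov), 0L)
  # manual placements win over the classifier on mapped words
  expect_identical(spans$source[spans$phrase == "exhausted"], "manual")

  # derived check of the margin ordering on unmapped tokens: compute the
  # expected placement independently from the classifier's margins
  tokens2 <- c("qq", "zz", "cell")
  cands <- extract_candidates(tokens2[1:2])
  phrases <- vapply(seq_len(nrow(cands)), function(r)
    paste(tokens2[cands$token_start[r]:cands$token_end[r]], collapse = " "), "")
  margins <- attr(predict_motifs(clf, phrases), "margin")
  expected_first <- cands[order(margins, cands$token_start)[1], ]
  spans2 <- assign_motifs(tokens2, c(cell = "root"), clf)
  got <- spans2[spans2$source == "classifier", ]
  expect_identical(got$token_start[1], expected_first$token_start)
  expect_identical(got$token_end[1], expected_first$token_end)
  # decreasing order places the most confident candidate first instead
  spans3 <- assign_motifs(tokens2, c(cell = "root"), clf,
                          margin_order = "decreasing")
  expected_last <- cands[order(-margins, cands$token_start)[1], ]
  got3 <- spans3[spans3$source == "classifier", ]
  expect_identical(got3$token_start[1], expected_last$token_start)
  # without a classifier only manual spans are returned
  expect_identical(nrow(assign_motifs(tokens2, c(cell = "root"))), 1L)
})

test_that("assign_lineages splits weight across links and lineages", {
  # root -> A -> t1; root -> A -> t2 <- B (t2 under both lineages)
  onto <- ontology(
    terms = data.frame(id = c("r", "A", "B", "t1", "t2"),
                       label = c("cell", "a", "b", "t1", "t2")),
    edges = data.frame(child = c("A", "B", "t1", "t2", "t2"),
                       parent = c("r", "r", "A", "A", "B")),
    root_id = "r")
  lm <- list(A = "A", B = "B")
  expect_equal(assign_lineages("t1", onto, lm), c(A = 1))
  expect_equal(assign_lineages("t2", onto, lm), c(A = 0.5, B = 0.5))
  expect_equal(assign_lineages(c("t1", "t2"), onto, lm),
               c(A = 0.75, B = 0.25))
  # no lineage hit -> excluded
  expect_identical(length(assign_lineages("r", onto, lm)), 0L)
  # weights always sum to 1 for included annotations
  expect_equal(sum(assign_lineages(c("t1", "t2", "t2"), onto, lm)), 1)
})

test_that("prevalence_table computes weighted proportions with an ALL row", {
  motifs <- data.frame(ann_id = c("a1", "a1"), motif_type = c("state", "root"))
  weights <- data.frame(ann_id = c("a1", "a2"), lineage = "L",
                        weight = c(1, 0.5))
  tab <- prevalence_table(motifs, weights)
  expect_equal(tab$prevalence[tab$lineage == "L" & tab$motif_type == "state"],
               1 / 1.5)
  expect_equal(tab$prevalence[tab$lineage == "ALL" & tab$motif_type == "state"],
               1 / 1.5)
  expect_true(all(tab$numerator <= tab$denominator + 1e-12))
  # a motif present in every mention has prevalence 1 in every lineage
  m2 <- data.frame(ann_id = c("a1", "a2"), motif_type = "root")
  t2 <- prevalence_table(m2, weights)
  expect_true(all(t2$prevalence[t2$motif_type == "root"] == 1))
})

test_that("binom_test_exact: examples and exhaustive oracle for n <= 12", {
  expect_equal(binom_test_exact(5, 10, 0.5), 1)
  expect_equal(binom_test_exact(0, 10, 0.5), 2 / 1024)
  expect_error(binom_test_exact(5, 4, 0.5), "k <= n")
  expect_error(binom_test_exact(1, 4, 0), "p0")
  for (n in c(1:6, 9, 12)) {
    for (p0 in c(0.1, 0.5, 0.9)) {
      for (k in 0:n) {
        expect_equal(binom_test_exact(k, n, p0), oracle_binom(k, n, p0),
                     tolerance = 1e-9,
                     info = sprintf("k=%d n=%d p0=%.1f", k, n, p0))
      }
    }
  }
  # cross-check against the stats implementation on a sample
  for (i in 1:20) {
    set.seed(i)
    n <- sample(1:40, 1)
    k <- sample(0:n, 1)
    p0 <- stats::runif(1, 0.05, 0.95)
    expect_equal(binom_test_exact(k, n, p0),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-6)
  }
})

test_that("fisher_exact: examples and exhaustive oracle for margins <= 10", {
  expect_equal(fisher_exact(5, 0, 0, 5), 2 / 252)
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_message(p <- fisher_exact(0, 0, 3, 4), "degenerate")
  expect_equal(p, 1)
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    if (a + b > 10 || cc + d > 10 || a + cc > 10 || b + d > 10) next
    expect_equal(fisher_exact(a, b, cc, d), oracle_fisher(a, b, cc, d),
                 tolerance = 1e-9, info = paste(a, b, cc, d))
  }
  # spot-check against stats::fisher.test
  for (i in 1:10) {
    set.seed(i + 40)
    t <- sample(0:15, 4, replace = TRUE) + 1L
    expect_equal(fisher_exact(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-6)
  }
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(9)
  for (i in 1:20) {
    p <- stats::runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    expect_equal(q, stats::p.adjust(p, "BH"))
  }
  expect_identical(bh_adjust(c(0.2, NA, 0.9))[2], NA_real_)
})

test_that("compare_prevalence: self-comparison yields nothing significant", {
  gen <- generate_corpus(generator_config(seed = 51, n_passages = 40))
  lab <- label_motifs(gen$corpus, gen$ontology)
  tab <- prevalence_table(lab$motifs, lab$weights)
  res <- compare_prevalence(tab, reference = tab)
  expect_true(all(!res$significant))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(res$test[res$lineage == "ALL"] == "fisher"))
})

test_that("an injected prevalence shift is detected at FDR < 0.01", {
  cfg <- generator_config(seed = 52, n_passages = 200)
  cfg$motif_prevalence[, "state"] <- 0.2
  cfg$motif_prevalence["hematopoietic", "state"] <- 0.6
  gen <- generate_corpus(cfg)
  lab <- label_motifs(gen$corpus, gen$ontology)
  tab <- prevalence_table(lab$motifs, lab$weights)
  res <- compare_prevalence(tab)
  hit <- res[res$lineage == "hematopoietic" & res$motif_type == "state", ]
  expect_true(hit$significant)
  expect_identical(hit$direction, "higher")
})

test_that("manual labeling recovers the generator's ground-truth motif spans", {
  gen <- generate_corpus(generator_config(seed = 53, n_passages = 30))
  lab <- label_motifs(gen$corpus, gen$ontology)
  truth <- gen$truth$motifs
  scoped <- intersect(unique(lab$motifs$ann_id), unique(truth$ann_id))
  expect_gt(length(scoped), 50)
  got <- lab$motifs[lab$motifs$ann_id %in% scoped,
                    c("ann_id", "motif_type", "token_start", "token_end")]
  want <- truth[truth$ann_id %in% scoped,
                c("ann_id", "motif_type", "token_start", "token_end")]
  key <- function(d) sort(paste(d$ann_id, d$motif_type, d$token_start, d$token_end))
  expect_identical(key(got), key(want))
})

test_that("the scope filter drops vague, unlinked, coordination and keyword hits", {
  gen <- generate_corpus(generator_config(seed = 54, n_passages = 40))
  ann <- motif_scope_filter(gen$corpus)$annotations
  expect_true(all(ann$entity_type != "vague"))
  expect_true(all(nzchar(ann$identifiers)))
  expect_true(all(!ann$coordination))
  corp <- mini_corpus(text = "cultured fibroblasts here",
                      anns = list(list(start = 0, end = 20, ids = "T:A",
                                       quals = "exact")))
  expect_identical(nrow(motif_scope_filter(corp)$annotations), 0L)
  # qualifier restriction
  ex_only <- motif_scope_filter(gen$corpus, qualifier = "exact")$annotations
  expect_true(all(grepl("exact", ex_only$qualifiers)))
})
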