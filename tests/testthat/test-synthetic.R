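test_that("generate_ontology matches closed-form sizes and is deterministic", {
  onto <- generate_ontology(2, 1, 1, seed = 4)
  expect_identical(nrow(onto$terms), 3L)  # root -> L1, root -> L2
  expect_identical(sort(term_depth(onto, onto$terms$id)), c(0L, 1L, 1L))

  onto2 <- generate_ontology(3, 3, 2, seed = 9)
  expect_identical(nrow(onto2$terms), as.integer(1 + 3 * (2^3 - 1)))
  expect_identical(nrow(onto2$edges), nrow(onto2$terms) - 1L)  # pure tree

  # diamonds add edges but not nodes
  onto3 <- generate_ontology(3, 3, 2, seed = 9, diamond_fraction = 0.2)
  expect_identical(nrow(onto3$terms), nrow(onto2$terms))
  expect_gt(nrow(onto3$edges), nrow(onto2$edges))

  expect_identical(generate_ontology(3, 3, 2, seed = 9)$terms,
                   generate_ontology(3, 3, 2, seed = 9)$terms)
})

test_that("generate_name honors prevalence extremes and records spans", {
  cfg <- generator_config(seed = 1)
  cfg$motif_prevalence[] <- 0
  set.seed(1)
  nm <- generate_name("epithelial", cfg)
  expect_identical(nm$name, "cell")
  expect_identical(nm$motifs$motif_type, "root")

  cfg$motif_prevalence["epithelial", "molecular_signature"] <- 1
  set.seed(1)
  nm <- generate_name("epithelial", cfg)
  expect_identical(nrow(nm$motifs), 2L)
  sig <- nm$motifs[nm$motifs$motif_type == "molecular_signature", ]
  expect_true(nm$tokens[sig$token_start] %in% motif_vocabulary()$molecular_signature)
  expect_error(generate_name("bogus", cfg), "unknown lineage")
})

test_that("motif inclusion rate concentrates at the configured prevalence", {
  cfg <- generator_config(seed = 1)
  cfg$motif_prevalence[] <- 0
  cfg$motif_prevalence["neuronal", "state"] <- 0.3
  set.seed(42)
  hits <- vapply(seq_len(10000), function(i) {
    "state" %in% generate_name("neuronal", cfg)$motifs$motif_type
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("generate_corpus respects the entity mix and link fractions", {
  cfg <- generator_config(seed = 21, n_passages = 150,
                          entity_type_mix = c(0.8, 0.1, 0.1))
  gen <- generate_corpus(cfg)
  ann <- gen$corpus$annotations
  n <- nrow(ann)
  props <- table(factor(ann$entity_type,
                        c("cell_phenotype", "heterogeneous", "vague"))) / n
  for (i in 1:3) {
    p <- c(0.8, 0.1, 0.1)[i]
    expect_lt(abs(props[[i]] - p), 3 * sqrt(p * (1 - p) / n))
  }
  # exact-linked mention text is the verbatim label of the linked term
  links <- annotation_links(gen$corpus)
  exact1 <- ann[ann$qualifiers == "exact" & !ann$coordination, ]
  lab <- stats::setNames(gen$ontology$terms$label, gen$ontology$terms$id)
  expect_true(all(exact1$text == lab[exact1$identifiers]))
  # determinism
  gen2 <- generate_corpus(cfg)
  expect_identical(gen$corpus$annotations, gen2$corpus$annotations)
})

test_that("vague_fraction = 1 produces only unlinked vague annotations", {
  gen <- generate_corpus(generator_config(seed = 2, n_passages = 10,
                                          vague_fraction = 1))
  expect_true(all(gen$corpus$annotations$entity_type == "vague"))
  expect_true(all(gen$corpus$annotations$identifiers == ""))
})

test_that("ground truth aligns one-to-one with generated annotations", {
  gen <- generate_corpus(generator_config(seed = 8, n_passages = 25))
  expect_identical(gen$truth$annotations$ann_id, gen$corpus$annotations$ann_id)
  # lineage weights sum to 1 per linked annotation
  sums <- tapply(gen$truth$lineage_weights$weight,
                 gen$truth$lineage_weights$ann_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("perturb_annotations identity, drop-all, and sibling relabel", {
  gen <- generate_corpus(generator_config(seed = 13, n_passages = 15))
  same <- perturb_annotations(gen$corpus, seed = 3)
  expect_identical(nrow(same$annotations), nrow(gen$corpus$annotations))
  expect_identical(same$annotations$start, gen$corpus$annotations$start)
  expect_identical(same$annotations$identifiers, gen$corpus$annotations$identifiers)

  none <- perturb_annotations(gen$corpus, drop_p = 1, seed = 3)
  expect_identical(nrow(none$annotations), 0L)

  expect_error(perturb_annotations(gen$corpus, relabel_id_p = 1, seed = 3),
               "ontology")
  rel <- perturb_annotations(gen$corpus, relabel_id_p = 1, seed = 3,
                             ontology = gen$ontology)
  # relabeled ids are siblings: same parent set intersects
  parents_of <- split(gen$ontology$edges$parent, gen$ontology$edges$child)
  single <- gen$corpus$annotations$ann_id[
    !grepl(";", gen$corpus$annotations$identifiers, fixed = TRUE)]
  before <- annotation_links(gen$corpus)
  before <- before[before$ann_id %in% single, ]
  after <- annotation_links(rel)
  after$ann_id <- sub("-b$", "", after$ann_id)
  after <- after[after$ann_id %in% single, ]
  merged <- merge(before, after, by = "ann_id")
  changed <- merged[merged$term_id.x != merged$term_id.y, ]
  expect_gt(nrow(changed), 0)
  ok <- mapply(function(a, b) length(intersect(parents_of[[a]], parents_of[[b]])) > 0,
               changed$term_id.x, changed$term_id.y)
  expect_true(all(ok))

  # boundary jitter keeps spans valid and text in sync
  jit <- perturb_annotations(gen$corpus, boundary_p = 1, seed = 4)
  expect_identical(nrow(validate_corpus(jit)[
    validate_corpus(jit)$kind %in% c("span_out_of_bounds", "span_text_mismatch"), ]), 0L)
})

test_that("confidence scores: determinism and separation extremes", {
  a <- generate_confidence_scores(50, 50, 0.3, seed = 7)
  b <- generate_confidence_scores(50, 50, 0.3, seed = 7)
  expect_identical(a, b)
  wide <- generate_confidence_scores(200, 200, 3, seed = 7)
  expect_identical(novelty_roc(wide$score, wide$is_exact)$auroc, 1)
  flat <- generate_confidence_scores(2000, 2000, 0, seed = 7)
  expect_lt(abs(novelty_roc(flat$score, flat$is_exact)$auroc - 0.5), 0.03)
})
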