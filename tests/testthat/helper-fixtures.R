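# Shared fixtures, built in code.

# chain: root -> A -> B, plus sibling A2 under root
chain_ontology <- function() {
  ontology(
    terms = data.frame(id = c("T:root", "T:A", "T:A2", "T:B"),
                       label = c("cell", "alpha cell", "beta cell", "alpha sub cell")),
    edges = data.frame(child = c("T:A", "T:A2", "T:B"),
                       parent = c("T:root", "T:root", "T:A")),
    root_id = "T:root")
}

# diamond: root -> A -> C, root -> B -> C, plus direct root -> C
diamond_ontology <- function() {
  ontology(
    terms = data.frame(id = c("T:root", "T:A", "T:B", "T:C"),
                       label = c("cell", "a cell", "b cell", "c cell")),
    edges = data.frame(child = c("T:A", "T:B", "T:C", "T:C", "T:C"),
                       parent = c("T:root", "T:root", "T:A", "T:B", "T:root")),
    root_id = "T:root")
}

# a single-passage corpus from explicit annotation specs
mini_corpus <- function(text = "fibroblasts and exhausted CD8+ T cells in lung",
                        anns = list()) {
  ann <- if (length(anns)) {
    do.call(rbind, lapply(seq_along(anns), function(i) {
      a <- anns[[i]]
      data.frame(passage_id = "p1", ann_id = paste0("a", i),
                 start = a$start, end = a$end,
                 text = substr(text, a$start + 1, a$end),
                 entity_type = if (is.null(a$type)) "cell_phenotype" else a$type,
                 identifiers = if (is.null(a$ids)) "" else a$ids,
                 qualifiers = if (is.null(a$quals)) "" else a$quals,
                 annotator = if (is.null(a$who)) "annotator1" else a$who,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  annotated_corpus(
    passages = data.frame(passage_id = "p1", doc_id = "d1",
                          passage_type = "paragraph", text = text,
                          stringsAsFactors = FALSE),
    annotations = ann)
}

# random rooted DAG for depth/ancestor oracle tests: each node gets >= 1
# parent among earlier nodes
random_dag_ontology <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- sprintf("T:%03d", seq_len(n_nodes))
  edges <- do.call(rbind, lapply(2:n_nodes, function(i) {
    k <- sample(1:min(2, i - 1), 1)
    data.frame(child = ids[i], parent = ids[sample(i - 1, k)])
  }))
  ontology(terms = data.frame(id = ids, label = ids), edges = edges,
           root_id = ids[1])
}

# annotation table shorthand for eval tests
ann_df <- function(...) {
  specs <- list(...)
  do.call(rbind, lapply(seq_along(specs), function(i) {
    a <- specs[[i]]
    data.frame(passage_id = if (is.null(a$p)) "p1" else a$p,
               ann_id = paste0("x", i),
               start = a$s, end = a$e,
               text = if (is.null(a$text)) "t" else a$text,
               entity_type = if (is.null(a$type)) "cell_phenotype" else a$type,
               identifiers = if (is.null(a$ids)) "" else a$ids,
               qualifiers = if (is.null(a$quals)) "" else a$quals,
               annotator = "a", coordination = FALSE,
               stringsAsFactors = FALSE)
  }))
}
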