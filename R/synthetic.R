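# Synthetic fixtures with known ground truth: toy ontologies, motif-structured
# cell population names, annotated corpora, dual-annotator variants, and linker
# confidence scores. Every generator is a pure function of (config, seed).

#' The closed vocabulary of naming-motif types
#'
#' The 14 compositional components of cell population names: the root word
#' plus 13 descriptor categories (anatomical context, lineage, molecular
#' signature, appearance, functional role, developmental stage, state,
#' variant, molecular signaling, disease, eponym, stimulus, species/sex).
#'
#' @return character vector of length 14.
#' @export
motif_types <- function() {
  c("root", "anatomical_context", "lineage", "molecular_signature",
    "appearance", "functional_role", "developmental_stage", "state",
    "variant", "molecular_signaling", "disease", "eponym", "stimulus",
    "species_sex")
}

# fixed assembly order for generated names (roughly head-final: descriptors
# precede the lineage word and root). Relative order of state < functional
# role < signature < anatomical < developmental < lineage < root is fixed so
# span ground truth is unambiguous.
.motif_order <- c("species_sex", "disease", "stimulus", "state", "appearance",
                  "eponym", "variant", "functional_role", "molecular_signaling",
                  "molecular_signature", "anatomical_context",
                  "developmental_stage", "lineage", "root")

#' Fixed per-motif word vocabularies used by the name generator
#'
#' Small fixed word lists per motif type (all lowercase, one whitespace token
#' each) so that classifier training data is separable by construction and the
#' shipped manual motif map covers the generator's output exactly.
#'
#' @return named list of character vectors, one per motif type except
#'   `root` and `lineage` (which are lineage-specific).
#' @export
motif_vocabulary <- function() {
  list(
    species_sex = c("human", "murine", "male", "female"),
    disease = c("diabetic", "asthmatic", "arthritic", "fibrotic"),
    stimulus = c("light-responsive", "odor-sensing", "heat-activated"),
    state = c("activated", "exhausted", "naive", "quiescent", "senescent",
              "proliferating"),
    appearance = c("pyramidal", "granular", "spindle", "stellate"),
    eponym = c("purkinje", "schwann", "kupffer", "langerhans"),
    variant = c("m1", "m2", "th1", "th2", "th17"),
    functional_role = c("regulatory", "cytotoxic", "helper", "suppressor",
                        "effector", "secretory"),
    molecular_signaling = c("gabaergic", "glutamatergic", "dopaminergic",
                            "cholinergic"),
    molecular_signature = c("cd4+", "cd8+", "foxp3+", "cd56-", "ly6c+",
                            "pdgfra+"),
    anatomical_context = c("hepatic", "pulmonary", "renal", "cardiac",
                           "dermal", "intestinal", "alveolar", "cortical"),
    developmental_stage = c("immature", "mature", "fetal", "adult",
                            "embryonic", "pluripotent")
  )
}

.default_lineages <- c("hematopoietic", "epithelial", "endothelial",
                       "neuronal", "mesenchymal")

#' Default per-lineage motif prevalences
#'
#' Rows are lineages, columns motif types (excluding `root`, which every name
#' carries). Values emulate the qualitative lineage signatures of real cell
#' nomenclature: hematopoietic names lean on molecular signatures, functional
#' roles, states and variants; structural lineages (epithelial, endothelial,
#' mesenchymal) lean on anatomical context and the lineage word itself;
#' neuronal names use signaling and appearance motifs.
#'
#' @param lineages lineage labels (rownames of the returned matrix).
#' @return numeric matrix of inclusion probabilities in `[0, 1]`.
#' @export
default_motif_prevalence <- function(lineages = .default_lineages) {
  cols <- setdiff(motif_types(), "root")
  base <- c(anatomical_context = 0.25, lineage = 0.35,
            molecular_signature = 0.15, appearance = 0.03,
            functional_role = 0.10, developmental_stage = 0.07, state = 0.10,
            variant = 0.05, molecular_signaling = 0.03, disease = 0.03,
            eponym = 0.02, stimulus = 0.01, species_sex = 0.03)
  m <- matrix(rep(base[cols], each = length(lineages)),
              nrow = length(lineages), dimnames = list(lineages, cols))
  tweak <- function(lin, ...) {
    if (!lin %in% lineages) return(invisible())
    v <- c(...)
    m[lin, names(v)] <<- v
  }
  tweak("hematopoietic", molecular_signature = 0.45, functional_role = 0.30,
        state = 0.25, variant = 0.15, anatomical_context = 0.10, lineage = 0.10)
  tweak("epithelial", anatomical_context = 0.45, lineage = 0.75,
        molecular_signature = 0.08)
  tweak("endothelial", anatomical_context = 0.45, lineage = 0.70,
        molecular_signature = 0.08)
  tweak("neuronal", molecular_signaling = 0.30, appearance = 0.20,
        lineage = 0.10, anatomical_context = 0.25)
  tweak("mesenchymal", anatomical_context = 0.40, lineage = 0.50)
  m
}

#' Configuration for the synthetic corpus generator
#'
#' @param seed integer seed; every generator is deterministic given the
#'   config.
#' @param n_passages number of passages to generate.
#' @param lineage_roots lineage labels; one ontology subtree per lineage.
#' @param motif_prevalence matrix of per-(lineage, motif) inclusion
#'   probabilities as from [default_motif_prevalence()].
#' @param entity_type_mix probabilities of (cell_phenotype, heterogeneous,
#'   vague); must sum to 1 within 1e-9. Defaults follow the observed corpus
#'   composition (82.8 / 7.2 / 10.0 percent).
#' @param vague_fraction convenience override of the vague share of
#'   `entity_type_mix`; the other two components are rescaled.
#' @param exact_link_fraction probability that a non-vague annotation is an
#'   exact match to one ontology term (default 0.65, the observed share of
#'   unique phenotype mentions with exact links).
#' @param related_link_fraction among non-exact, non-coordination
#'   annotations, the probability of carrying 1-2 related links (the rest are
#'   unlinked).
#' @param multi_id_fraction probability that a non-vague annotation is a
#'   coordination ellipsis carrying multiple identifiers.
#' @param annotations_per_passage fixed annotation count per passage
#'   (the observed corpus averages ~7.4).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_passages = 100L,
                             lineage_roots = .default_lineages,
                             motif_prevalence = default_motif_prevalence(lineage_roots),
                             entity_type_mix = c(cell_phenotype = 0.828,
                                                 heterogeneous = 0.072,
                                                 vague = 0.100),
                             vague_fraction = NULL,
                             exact_link_fraction = 0.65,
                             related_link_fraction = 0.8,
                             multi_id_fraction = 0.05,
                             annotations_per_passage = 7L) {
  if (!is.null(vague_fraction)) {
    stopifnot(vague_fraction >= 0, vague_fraction <= 1)
    nv <- entity_type_mix[c("cell_phenotype", "heterogeneous")]
    nv <- if (sum(nv) > 0) nv / sum(nv) else c(cell_phenotype = 1, heterogeneous = 0)
    entity_type_mix <- c(nv * (1 - vague_fraction), vague = vague_fraction)
  }
  stopifnot(length(entity_type_mix) == 3,
            abs(sum(entity_type_mix) - 1) < 1e-9,
            all(entity_type_mix >= 0),
            all(motif_prevalence >= 0), all(motif_prevalence <= 1),
            all(rownames(motif_prevalence) == lineage_roots))
  probs <- c(exact_link_fraction, related_link_fraction, multi_id_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1))
  structure(list(seed = as.integer(seed), n_passages = as.integer(n_passages),
                 lineage_roots = lineage_roots,
                 motif_prevalence = motif_prevalence,
                 entity_type_mix = stats::setNames(as.numeric(entity_type_mix),
                                                   c("cell_phenotype", "heterogeneous", "vague")),
                 vague_fraction = unname(entity_type_mix[3]),
                 exact_link_fraction = exact_link_fraction,
                 related_link_fraction = related_link_fraction,
                 multi_id_fraction = multi_id_fraction,
                 annotations_per_passage = as.integer(annotations_per_passage)),
            class = "generator_config")
}

# evaluate code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a toy rooted-DAG ontology
#'
#' One balanced `branching`-ary subtree of `depth` levels per lineage under a
#' single root term, plus (optionally) a fraction of cross-lineage
#' multi-parent "diamond" nodes: extra is_a edges from a node to a second
#' parent at a strictly smaller depth, which keeps the graph acyclic.
#' Deterministic given `seed`.
#'
#' @param n_lineages number of lineage subtrees.
#' @param depth levels per subtree (1 = the lineage root only).
#' @param branching children per internal node.
#' @param seed integer seed.
#' @param lineages optional lineage labels (default the first `n_lineages`
#'   built-in labels, recycled with suffixes if more are needed).
#' @param diamond_fraction fraction of non-root nodes receiving a second
#'   parent.
#' @return an [ontology()] with an extra `lineage_roots` element mapping
#'   lineage label to its root term id.
#' @export
generate_ontology <- function(n_lineages, depth, branching, seed = 1L,
                              lineages = NULL, diamond_fraction = 0) {
  stopifnot(n_lineages >= 1, depth >= 1, branching >= 1)
  if (is.null(lineages)) {
    lineages <- rep_len(.default_lineages, max(n_lineages, length(.default_lineages)))
    if (n_lineages > length(.default_lineages)) {
      extra <- seq_len(n_lineages - length(.default_lineages))
      lineages <- c(.default_lineages, paste0("lineage", extra))
    }
    lineages <- lineages[seq_len(n_lineages)]
  }
  stopifnot(length(lineages) == n_lineages)
  with_seed(seed, {
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("SYN:%07d", counter)
    }
    root <- new_id()
    ids <- root
    labels <- "cell"
    node_depth <- 0L
    edges_child <- character()
    edges_parent <- character()
    lineage_root_ids <- character(n_lineages)
    for (li in seq_len(n_lineages)) {
      lroot <- new_id()
      lineage_root_ids[li] <- lroot
      ids <- c(ids, lroot)
      labels <- c(labels, paste(lineages[li], "cell"))
      node_depth <- c(node_depth, 1L)
      edges_child <- c(edges_child, lroot)
      edges_parent <- c(edges_parent, root)
      level <- lroot
      k <- 0L
      for (d in seq_len(depth - 1L)) {
        nxt <- character()
        for (parent in level) {
          for (b in seq_len(branching)) {
            k <- k + 1L
            id <- new_id()
            nxt <- c(nxt, id)
            ids <- c(ids, id)
            labels <- c(labels, sprintf("%s cell type %d", lineages[li], k))
            node_depth <- c(node_depth, d + 1L)
            edges_child <- c(edges_child, id)
            edges_parent <- c(edges_parent, parent)
          }
        }
        level <- nxt
      }
    }
    if (diamond_fraction > 0 && length(ids) > 2) {
      eligible <- which(node_depth >= 1L)
      n_extra <- round(diamond_fraction * length(eligible))
      if (n_extra > 0) {
        picks <- sample(eligible, n_extra)
        for (i in picks) {
          shallower <- which(node_depth < node_depth[i] & ids != edges_parent[match(ids[i], edges_child)])
          if (!length(shallower)) next
          p <- ids[if (length(shallower) == 1) shallower else sample(shallower, 1)]
          edges_child <- c(edges_child, ids[i])
          edges_parent <- c(edges_parent, p)
        }
      }
    }
    onto <- ontology(terms = data.frame(id = ids, label = labels,
                                        stringsAsFactors = FALSE),
                     edges = data.frame(child = edges_child, parent = edges_parent,
                                        stringsAsFactors = FALSE),
                     root_id = root)
    onto$lineage_roots <- stats::setNames(lineage_root_ids, lineages)
    onto
  })
}

#' Generate one motif-structured cell population name
#'
#' Each motif type is included independently with its configured prevalence
#' for the lineage, with a word drawn from the fixed per-type vocabulary; the
#' lineage motif uses the lineage word itself and the root word is always
#' "cell". Words are assembled in a fixed order so motif span ground truth is
#' unambiguous. Uses the current RNG state (seed at the call site).
#'
#' @param lineage a lineage label present in `config$lineage_roots`.
#' @param config a [generator_config()].
#' @return list with `name` (string), `tokens` (character vector), and
#'   `motifs` (data.frame `motif_type`, `token_start`, `token_end`, `phrase`;
#'   token indices 1-based inclusive).
#' @export
generate_name <- function(lineage, config) {
  if (!lineage %in% config$lineage_roots) stop("unknown lineage: ", lineage)
  vocab <- motif_vocabulary()
  prev <- config$motif_prevalence[lineage, ]
  tokens <- character()
  rows <- list()
  for (mt in .motif_order) {
    word <- if (mt == "root") {
      "cell"
    } else if (mt == "lineage") {
      if (stats::runif(1) < prev[["lineage"]]) lineage else NA_character_
    } else {
      if (stats::runif(1) < prev[[mt]]) {
        w <- vocab[[mt]]
        w[[sample.int(length(w), 1)]]
      } else NA_character_
    }
    if (is.na(word)) next
    tokens <- c(tokens, word)
    rows[[length(rows) + 1L]] <- data.frame(motif_type = mt,
                                            token_start = length(tokens),
                                            token_end = length(tokens),
                                            phrase = word,
                                            stringsAsFactors = FALSE)
  }
  list(name = paste(tokens, collapse = " "), tokens = tokens,
       motifs = do.call(rbind, rows))
}

.passage_templates <- c("We examined %s in donor tissue.",
                        "Clusters enriched for %s were detected.",
                        "The abundance of %s increased with treatment.",
                        "Profiling revealed %s across samples.",
                        "Marker analysis confirmed %s in all cohorts.")
.journals <- c("J Cell Sci", "Cell Rep", "Nat Commun", "eLife",
               "Front Immunol", "Genome Biol")
.mesh_cluster_pool <- c("Immune-Anatomy", "Nervous-Anatomy", "Cardiovascular-Disease",
                        "Cancer-Disease", "Exocrine-Anatomy", "Musculoskeletal-Anatomy")
.passage_type_mix <- c(paragraph = 0.70, abstract = 0.10, title = 0.05,
                       caption = 0.08, table = 0.03, section_header = 0.02,
                       supplementary = 0.02)

#' Generate a synthetic annotated corpus with ground truth
#'
#' Produces passages of template sentences, each embedding motif-structured
#' cell population names annotated per the configured entity-type mix and
#' link fractions. Exact-match annotations use mention text identical to the
#' label of the linked ontology term (labels are assigned to ontology terms
#' as names are generated, so exact mentions are verbatim term labels).
#' Related-match annotations carry 1-2 related identifiers; coordination
#' ellipses ("x and y") carry one identifier per conjunct. Vague annotations
#' are never linked. The output always passes [validate_corpus()] with zero
#' violations.
#'
#' @param config a [generator_config()].
#' @param ontology optional pre-built ontology from [generate_ontology()]
#'   (with `lineage_roots`); when `NULL` one is generated large enough to
#'   label every exact mention with a fresh term.
#' @return list with elements `corpus` ([annotated_corpus()]), `ontology`,
#'   and `truth` (list of data.frames: `annotations` with true lineage,
#'   entity type and term ids; `motifs` with true token spans; and
#'   `lineage_weights` with the true fractional lineage assignment).
#' @export
generate_corpus <- function(config, ontology = NULL) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    lineages <- config$lineage_roots
    n_ann_total <- config$n_passages * config$annotations_per_passage
    if (is.null(ontology)) {
      need <- ceiling(1.5 * n_ann_total / length(lineages)) + 10
      b <- 3L
      depth <- 2L
      while ((b^depth - 1) / (b - 1) < need) depth <- depth + 1L
      ontology <- generate_ontology(length(lineages), depth, b,
                                    seed = config$seed + 1L,
                                    lineages = lineages,
                                    diamond_fraction = 0.05)
    }
    lroots <- ontology$lineage_roots
    # structural lineage membership: term -> lineages whose root is an ancestor
    parents_of <- split(ontology$edges$parent, ontology$edges$child)
    lineage_cache <- new.env(parent = emptyenv())
    term_lineages <- function(id) {
      if (!is.null(lineage_cache[[id]])) return(lineage_cache[[id]])
      anc <- id
      frontier <- id
      while (length(frontier)) {
        nxt <- setdiff(unique(unlist(parents_of[frontier], use.names = FALSE)), anc)
        anc <- c(anc, nxt)
        frontier <- nxt
      }
      out <- names(lroots)[lroots %in% anc]
      lineage_cache[[id]] <- out
      out
    }
    # per-lineage pools of relabelable terms (below the lineage root)
    pool <- lapply(names(lroots), function(lin) {
      sub <- ontology$terms$id[startsWith(ontology$terms$label, paste0(lin, " cell type"))]
      sub
    })
    names(pool) <- names(lroots)
    pool_pos <- stats::setNames(rep(1L, length(lroots)), names(lroots))
    label_env <- new.env(parent = emptyenv())
    term_label <- stats::setNames(ontology$terms$label, ontology$terms$id)
    # a generated name equal to a lineage-root label links to that root term
    for (lin in names(lroots)) {
      label_env[[paste0(lin, "\r", paste(lin, "cell"))]] <- lroots[[lin]]
    }
    register_exact <- function(lin, name) {
      key <- paste0(lin, "\r", name)
      if (!is.null(label_env[[key]])) return(label_env[[key]])
      p <- pool[[lin]]
      if (pool_pos[[lin]] <= length(p)) {
        id <- p[[pool_pos[[lin]]]]
        pool_pos[[lin]] <<- pool_pos[[lin]] + 1L
      } else {
        id <- p[[sample.int(length(p), 1)]]  # pool exhausted: reuse a term
      }
      term_label[[id]] <<- name
      label_env[[key]] <- id
      id
    }
    subtree_terms <- function(lin) pool[[lin]]

    pas_rows <- list(); ann_rows <- list()
    truth_ann <- list(); truth_motifs <- list(); truth_weights <- list()
    ann_counter <- 0L
    n_docs_two <- floor(config$n_passages / 5)  # ~20% of passages share a doc
    doc_of <- character(config$n_passages)
    doc_meta <- list()
    di <- 0L; i <- 1L
    while (i <= config$n_passages) {
      di <- di + 1L
      did <- sprintf("doc%04d", di)
      span <- if (di <= n_docs_two && i < config$n_passages) 2L else 1L
      doc_of[i:(i + span - 1L)] <- did
      # article-level metadata is shared by all passages of a document
      doc_meta[[did]] <- list(
        year = sample(2019:2024, 1),
        journal = .journals[[sample.int(length(.journals), 1)]],
        mesh = paste(sample(.mesh_cluster_pool, sample.int(3L, 1)), collapse = ";"))
      i <- i + span
    }
    for (pi in seq_len(config$n_passages)) {
      pid <- sprintf("p%05d", pi)
      text <- ""
      for (ai in seq_len(config$annotations_per_passage)) {
        ann_counter <- ann_counter + 1L
        aid <- sprintf("a%06d", ann_counter)
        lin <- names(lroots)[sample.int(length(lroots), 1)]
        etype <- sample(c("cell_phenotype", "heterogeneous", "vague"), 1,
                        prob = config$entity_type_mix)
        coord <- FALSE
        ids <- ""; quals <- ""; kind <- "unlinked"
        if (etype == "vague") {
          nm <- generate_name(lin, config)
          mention <- paste(nm$name, sample(c("populations", "clusters", "subsets"), 1))
          motifs <- nm$motifs
        } else if (stats::runif(1) < config$multi_id_fraction) {
          coord <- TRUE
          nm1 <- generate_name(lin, config)
          nm2 <- generate_name(lin, config)
          t1 <- register_exact(lin, nm1$name)
          t2 <- register_exact(lin, nm2$name)
          while (identical(t2, t1)) {
            nm2 <- generate_name(lin, config)
            t2 <- register_exact(lin, nm2$name)
            if (identical(nm1$name, nm2$name)) break
          }
          mention <- paste(nm1$name, "and", nm2$name)
          ids <- paste(unique(c(t1, t2)), collapse = ";")
          quals <- paste(rep("exact", length(unique(c(t1, t2)))), collapse = ";")
          kind <- "coordination"
          motifs <- NULL
        } else if (stats::runif(1) < config$exact_link_fraction) {
          nm <- generate_name(lin, config)
          mention <- nm$name
          ids <- register_exact(lin, nm$name)
          quals <- "exact"
          kind <- "exact"
          motifs <- nm$motifs
        } else {
          nm <- generate_name(lin, config)
          mention <- nm$name
          motifs <- nm$motifs
          if (stats::runif(1) < config$related_link_fraction) {
            k <- sample.int(2L, 1)
            terms <- subtree_terms(lin)
            pick <- terms[sample.int(length(terms), min(k, length(terms)))]
            ids <- paste(pick, collapse = ";")
            quals <- paste(rep("related", length(pick)), collapse = ";")
            kind <- "related"
          }
        }
        tmpl <- .passage_templates[[sample.int(length(.passage_templates), 1)]]
        parts <- strsplit(tmpl, "%s", fixed = TRUE)[[1]]
        base <- if (nzchar(text)) nchar(text) + 1L else 0L
        start <- base + nchar(parts[1])
        end <- start + nchar(mention)
        sentence <- paste0(parts[1], mention, parts[2])
        text <- if (nzchar(text)) paste(text, sentence) else sentence
        ann_rows[[ann_counter]] <- data.frame(
          passage_id = pid, ann_id = aid, start = start, end = end,
          text = mention, entity_type = etype, identifiers = ids,
          qualifiers = quals, annotator = "consensus", coordination = coord,
          stringsAsFactors = FALSE)
        truth_ann[[ann_counter]] <- data.frame(
          ann_id = aid, lineage = lin, entity_type = etype, link_kind = kind,
          term_ids = ids, stringsAsFactors = FALSE)
        if (!is.null(motifs) && nrow(motifs)) {
          motifs$ann_id <- aid
          truth_motifs[[length(truth_motifs) + 1L]] <-
            motifs[, c("ann_id", "motif_type", "token_start", "token_end", "phrase")]
        }
        if (nzchar(ids)) {
          link_ids <- strsplit(ids, ";", fixed = TRUE)[[1]]
          w <- list()
          for (tid in link_ids) {
            hit <- term_lineages(tid)
            if (!length(hit)) next
            for (h in hit) w[[h]] <- (if (is.null(w[[h]])) 0 else w[[h]]) +
                (1 / length(link_ids)) / length(hit)
          }
          if (length(w)) {
            wv <- unlist(w)
            wv <- wv / sum(wv)
            truth_weights[[length(truth_weights) + 1L]] <- data.frame(
              ann_id = aid, lineage = names(wv), weight = unname(wv),
              stringsAsFactors = FALSE)
          }
        }
      }
      meta <- doc_meta[[doc_of[pi]]]
      pas_rows[[pi]] <- data.frame(
        passage_id = pid, doc_id = doc_of[pi],
        passage_type = sample(names(.passage_type_mix), 1, prob = .passage_type_mix),
        text = text,
        year = meta$year, journal = meta$journal, mesh_clusters = meta$mesh,
        stringsAsFactors = FALSE)
    }
    ontology$terms$label <- unname(term_label[ontology$terms$id])
    corpus <- annotated_corpus(do.call(rbind, pas_rows), do.call(rbind, ann_rows),
                               provenance = "corpuscle synthetic corpus")
    list(corpus = corpus, ontology = ontology,
         truth = list(
           annotations = do.call(rbind, truth_ann),
           motifs = if (length(truth_motifs)) do.call(rbind, truth_motifs) else
             data.frame(ann_id = character(), motif_type = character(),
                        token_start = integer(), token_end = integer(),
                        phrase = character()),
           lineage_weights = if (length(truth_weights)) do.call(rbind, truth_weights) else
             data.frame(ann_id = character(), lineage = character(),
                        weight = numeric())))
  })
}

#' Create a perturbed second-annotator copy of a corpus
#'
#' Each annotation is independently dropped with probability `drop_p`, has a
#' span endpoint jittered with probability `boundary_p` (annotation text is
#' kept in sync with the new slice), and has each linked identifier replaced
#' by a uniformly chosen sibling term (sharing a parent) with probability
#' `relabel_id_p`. Used to emulate controlled inter-annotator disagreement.
#'
#' @param corpus an [annotated_corpus()].
#' @param drop_p,boundary_p,relabel_id_p probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @param ontology required when `relabel_id_p > 0` (sibling lookup).
#' @param annotator annotator id for the copy.
#' @return a new [annotated_corpus()] over the same passages.
#' @export
perturb_annotations <- function(corpus, drop_p = 0, boundary_p = 0,
                                relabel_id_p = 0, seed = 1L, ontology = NULL,
                                annotator = "annotator2") {
  stopifnot(all(c(drop_p, boundary_p, relabel_id_p) >= 0),
            all(c(drop_p, boundary_p, relabel_id_p) <= 1))
  if (relabel_id_p > 0 && is.null(ontology))
    stop("relabel_id_p > 0 requires an ontology for sibling lookup")
  with_seed(seed, {
    ann <- corpus$annotations
    keep <- stats::runif(nrow(ann)) >= drop_p
    ann <- ann[keep, , drop = FALSE]
    ptext <- stats::setNames(corpus$passages$text, corpus$passages$passage_id)
    if (nrow(ann)) {
      jitter <- stats::runif(nrow(ann)) < boundary_p
      for (i in which(jitter)) {
        L <- nchar(ptext[[ann$passage_id[i]]])
        delta <- sample(c(-2L, -1L, 1L, 2L), 1)
        if (stats::runif(1) < 0.5) {
          s <- max(0L, min(ann$end[i] - 1L, ann$start[i] + delta))
          ann$start[i] <- s
        } else {
          e <- min(L, max(ann$start[i] + 1L, ann$end[i] + delta))
          ann$end[i] <- e
        }
        ann$text[i] <- substr(ptext[[ann$passage_id[i]]], ann$start[i] + 1L, ann$end[i])
      }
      if (relabel_id_p > 0) {
        children_of <- split(ontology$edges$child, ontology$edges$parent)
        parents_of <- split(ontology$edges$parent, ontology$edges$child)
        for (i in which(nzchar(ann$identifiers))) {
          ids <- strsplit(ann$identifiers[i], ";", fixed = TRUE)[[1]]
          for (j in seq_along(ids)) {
            if (stats::runif(1) >= relabel_id_p) next
            sibs <- setdiff(unique(unlist(children_of[parents_of[[ids[j]]]],
                                          use.names = FALSE)), ids[j])
            if (length(sibs)) ids[j] <- sibs[[sample.int(length(sibs), 1)]]
          }
          ann$identifiers[i] <- paste(ids, collapse = ";")
        }
      }
      ann$annotator <- annotator
      ann$ann_id <- paste0(ann$ann_id, "-b")
    }
    annotated_corpus(corpus$passages, ann,
                     provenance = paste0(corpus$provenance, " [perturbed]"))
  })
}

#' Generate mention-level linker confidence scores with known labels
#'
#' Positive (exact-match) and negative (related/no-match) scores are drawn
#' from normal distributions centred `separation` apart and truncated to the
#' unit interval by clipping, emulating a linker that is confident on
#' ontology-mapped mentions and uncertain on novel ones.
#'
#' @param n_pos,n_neg class sizes (>= 1).
#' @param separation difference between class means.
#' @param seed integer seed.
#' @param sd common standard deviation before clipping.
#' @return data.frame with columns `score` and `is_exact` (logical).
#' @export
generate_confidence_scores <- function(n_pos, n_neg, separation, seed = 1L,
                                       sd = 0.12) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  with_seed(seed, {
    pos <- pmin(1, pmax(0, stats::rnorm(n_pos, 0.5 + separation / 2, sd)))
    neg <- pmin(1, pmax(0, stats::rnorm(n_neg, 0.5 - separation / 2, sd)))
    data.frame(score = c(pos, neg),
               is_exact = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
  })
}
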