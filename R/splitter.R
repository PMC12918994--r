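# Train/validation/test partitioning by iterative hill climbing: balance the
# annotation composition of the subsets while pushing mentions and
# identifiers to be unique to a single subset.

#' Splitting objective weights
#'
#' The split score (lower is better) is a weighted sum of L1 deviations of
#' each subset's normalized distribution from the global distribution
#' (entity-type composition, passage-length bins, MeSH-cluster frequencies),
#' minus uniqueness rewards: the fraction of identifiers, and of case-folded
#' mention strings, occurring in exactly one subset. Fractions (not raw
#' counts) keep the deviation and uniqueness terms commensurate under the
#' default weight 1; scale the weight to recover count behaviour.
#'
#' @param entity_type,length,clusters deviation weights (>= 0).
#' @param unique_ids,unique_mentions uniqueness reward weights (>= 0).
#' @param length_bins bin edges for the passage-length feature.
#' @export
split_objective <- function(entity_type = 1, length = 1, clusters = 1,
                            unique_ids = 1, unique_mentions = 1,
                            length_bins = c(100, 200, 400, 800)) {
  w <- c(entity_type, length, clusters, unique_ids, unique_mentions)
  stopifnot(all(w >= 0))
  structure(list(entity_type = entity_type, length = length,
                 clusters = clusters, unique_ids = unique_ids,
                 unique_mentions = unique_mentions, length_bins = length_bins),
            class = "split_objective")
}

# per-passage summaries reused across score evaluations
.split_features <- function(corpus, objective) {
  pas <- corpus$passages
  ann <- corpus$annotations
  n <- nrow(pas)
  pid <- pas$passage_id
  etypes <- c("cell_phenotype", "heterogeneous", "vague")
  et <- matrix(0, n, 3, dimnames = list(pid, etypes))
  if (nrow(ann)) {
    tab <- table(factor(ann$passage_id, levels = pid),
                 factor(ann$entity_type, levels = etypes))
    et[] <- as.numeric(tab)
  }
  bins <- objective$length_bins
  lb <- findInterval(nchar(pas$text), bins, left.open = TRUE) + 1L
  lbm <- matrix(0, n, length(bins) + 1L)
  lbm[cbind(seq_len(n), lb)] <- 1
  clusters <- strsplit(pas$mesh_clusters, ";", fixed = TRUE)
  cl_vocab <- unique(unlist(clusters, use.names = FALSE))
  clm <- matrix(0, n, max(1L, length(cl_vocab)),
                dimnames = list(NULL, if (length(cl_vocab)) cl_vocab else "none"))
  for (i in seq_len(n)) {
    cs <- clusters[[i]]
    cs <- cs[nzchar(cs)]
    if (length(cs)) clm[i, cs] <- 1 / length(cs)
  }
  links <- annotation_links(corpus)
  ann_passage <- stats::setNames(ann$passage_id, ann$ann_id)
  id_by_passage <- if (nrow(links)) {
    split(links$term_id, ann_passage[links$ann_id])
  } else list()
  mention_by_passage <- if (nrow(ann)) {
    split(tolower(ann$text), ann$passage_id)
  } else list()
  list(entity_type = et, length_bin = lbm, clusters = clm,
       ids = lapply(stats::setNames(pid, pid), function(p) unique(id_by_passage[[p]])),
       mentions = lapply(stats::setNames(pid, pid),
                         function(p) unique(mention_by_passage[[p]])))
}

.l1_deviation <- function(mat, assignment, subsets) {
  global <- colSums(mat)
  if (sum(global) == 0) return(0)
  global <- global / sum(global)
  dev <- 0
  for (s in subsets) {
    sub <- colSums(mat[assignment == s, , drop = FALSE])
    if (sum(sub) == 0) next
    dev <- dev + sum(abs(sub / sum(sub) - global))
  }
  dev
}

.unique_fraction <- function(sets_by_passage, assignment, subsets) {
  per_subset <- lapply(subsets, function(s) {
    unique(unlist(sets_by_passage[assignment == s], use.names = FALSE))
  })
  all_vals <- unique(unlist(per_subset, use.names = FALSE))
  if (!length(all_vals)) return(0)
  hits <- Reduce(`+`, lapply(per_subset, function(v) as.integer(all_vals %in% v)))
  sum(hits == 1) / length(all_vals)
}

#' Score a split (lower is better)
#'
#' @param corpus an [annotated_corpus()].
#' @param split a split object from [hill_climb_split()], or a named character
#'   vector mapping `passage_id` to one of `train`, `valid`, `test`.
#' @param objective a [split_objective()].
#' @export
score_split <- function(corpus, split, objective = split_objective()) {
  assignment <- if (is.list(split)) split$assignment else split
  feats <- .split_features(corpus, objective)
  .score_assignment(feats, assignment[corpus$passages$passage_id], objective)
}

.score_assignment <- function(feats, assignment, objective) {
  subsets <- c("train", "valid", "test")
  objective$entity_type * .l1_deviation(feats$entity_type, assignment, subsets) +
    objective$length * .l1_deviation(feats$length_bin, assignment, subsets) +
    objective$clusters * .l1_deviation(feats$clusters, assignment, subsets) -
    objective$unique_ids * .unique_fraction(feats$ids, assignment, subsets) -
    objective$unique_mentions * .unique_fraction(feats$mentions, assignment, subsets)
}

#' Hill-climbing train/validation/test split
#'
#' Starts from a seeded random partition at exact sizes `floor(ratio * N)`
#' (remainder assigned to train), then repeatedly proposes swapping two
#' passages between subsets (subsets drawn with probability proportional to
#' size, passages uniformly) and accepts a swap iff the [score_split()]
#' objective strictly decreases. Stops after `max_stale` consecutive
#' rejections. Subset sizes never change. Default ratios: 1/2 training, 1/6
#' validation, 1/3 testing.
#'
#' @param corpus an [annotated_corpus()].
#' @param ratios probability triple `(train, valid, test)`.
#' @param objective a [split_objective()].
#' @param seed integer seed.
#' @param max_stale consecutive rejected proposals before stopping.
#' @return object of class `corpus_split`: list with `assignment` (named
#'   subset vector over passage ids), `ratios`, `score`, and the
#'   accepted-score trajectory `trace` (strictly decreasing).
#' @export
hill_climb_split <- function(corpus, ratios = c(train = 1/2, valid = 1/6, test = 1/3),
                             objective = split_objective(), seed = 1L,
                             max_stale = 300L) {
  pid <- corpus$passages$passage_id
  N <- length(pid)
  stopifnot(N >= 3, length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9)
  sizes <- floor(ratios * N)
  sizes[1] <- sizes[1] + (N - sum(sizes))
  names(sizes) <- c("train", "valid", "test")
  feats <- .split_features(corpus, objective)
  with_seed(seed, {
    assignment <- stats::setNames(
      sample(rep(c("train", "valid", "test"), sizes)), pid)
    score <- .score_assignment(feats, assignment, objective)
    trace <- score
    stale <- 0L
    idx_by_subset <- split(seq_len(N), assignment[pid])
    while (stale < max_stale) {
      ss <- sample(c("train", "valid", "test"), 2, prob = sizes)
      if (ss[1] == ss[2]) {
        stale <- stale + 1L
        next
      }
      i <- idx_by_subset[[ss[1]]][sample.int(sizes[[ss[1]]], 1)]
      j <- idx_by_subset[[ss[2]]][sample.int(sizes[[ss[2]]], 1)]
      prop <- assignment
      prop[i] <- ss[2]
      prop[j] <- ss[1]
      new_score <- .score_assignment(feats, prop, objective)
      if (new_score < score - 1e-12) {
        assignment <- prop
        score <- new_score
        trace <- c(trace, score)
        idx_by_subset[[ss[1]]] <- c(setdiff(idx_by_subset[[ss[1]]], i), j)
        idx_by_subset[[ss[2]]] <- c(setdiff(idx_by_subset[[ss[2]]], j), i)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    structure(list(assignment = assignment, ratios = ratios, score = score,
                   trace = trace, sizes = sizes), class = "corpus_split")
  })
}

#' @export
print.corpus_split <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf("<corpus_split> train %d / valid %d / test %d (score %.4f)\n",
              tab[["train"]], tab[["valid"]], tab[["test"]], x$score))
  invisible(x)
}
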