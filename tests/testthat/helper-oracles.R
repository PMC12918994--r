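# Independent oracles used by both the unit and acceptance suites.

# exact two-sided binomial p-value by enumerating all 2^n outcome sequences
oracle_binom <- function(k, n, p0) {
  seqs <- as.matrix(expand.grid(rep(list(0:1), n)))
  counts <- rowSums(seqs)
  seq_prob <- p0^counts * (1 - p0)^(n - counts)
  point <- tapply(seq_prob, counts, sum)
  obs <- point[[as.character(k)]]
  sum(seq_prob[point[as.character(counts)] <= obs * (1 + 1e-9)])
}

# two-sided Fisher p-value from binomial coefficients over all same-margin tables
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - m1)):min(m1, c1)
  probs <- choose(m1, xs) * choose(n - m1, c1 - xs) / choose(n, c1)
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# brute-force maximum one-to-one matching TP count (recursion over gold rows)
optimal_tp <- function(gold, pred, span_mode, label_mode) {
  ok <- function(i, j) {
    type_ok <- label_mode == "merged" ||
      gold$entity_type[i] == pred$entity_type[j]
    span_ok <- if (span_mode == "exact") {
      gold$start[i] == pred$start[j] && gold$end[i] == pred$end[j]
    } else {
      min(gold$end[i], pred$end[j]) > max(gold$start[i], pred$start[j])
    }
    type_ok && span_ok
  }
  best <- 0L
  recurse <- function(i, used) {
    if (i > nrow(gold)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    recurse(i + 1L, used)
    for (j in seq_len(nrow(pred))) {
      if (!used[j] && ok(i, j)) {
        used[j] <- TRUE
        recurse(i + 1L, used)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nrow(pred)))
  best
}

# random small annotation sets for matching tests
random_annotation_set <- function(n) {
  if (n == 0) return(ann_df(list(s = 0, e = 1))[0, ])
  starts <- sample(0:12, n, replace = TRUE)
  do.call(ann_df, lapply(seq_len(n), function(i) {
    list(s = starts[i], e = starts[i] + sample(1:4, 1),
         type = sample(c("cell_phenotype", "vague"), 1))
  }))
}
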