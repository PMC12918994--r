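passage_row <- function(text, doc = "d1", year = 2020, journal = "J",
                        mesh = "", type = "paragraph") {
  data.frame(passage_id = paste0("p", substr(digest_text(text), 1, 6)),
             doc_id = doc, passage_type = type, text = text, year = year,
             journal = journal, mesh_clusters = mesh, stringsAsFactors = FALSE)
}
digest_text <- function(x) paste0(utf8ToInt(substr(x, 1, 4)), collapse = "")

test_that("feature extraction tokenizes and bins as specified", {
  p <- list(text = "CD8+ T cells", year = 2021, journal = "J",
            passage_type = "title", mesh_clusters = "A;B")
  fv <- extract_features(p, length_bins = c(100, 200, 300))
  expect_setequal(fv$tokens, c("cd8", "t", "cells"))
  expect_identical(fv$mesh_clusters, c("A", "B"))
  expect_identical(fv$length_bin, "<=100")

  long <- list(text = paste(rep("a", 250), collapse = ""), year = 2021,
               journal = "J", passage_type = "title", mesh_clusters = "")
  expect_identical(extract_features(long, c(100, 200, 300))$length_bin, "200-300")

  empty <- list(text = "", year = 2021, journal = "J", passage_type = "title",
                mesh_clusters = "")
  fv <- extract_features(empty, c(100, 200, 300))
  expect_identical(fv$tokens, character())
  expect_identical(fv$length_bin, "<=100")
})

test_that("empirical_distribution applies epsilon smoothing per vocabulary", {
  pool <- lapply(c("a", "a", "a", "b"), function(v) list(f = v))
  d0 <- empirical_distribution(pool, epsilon = 0)
  expect_equal(unname(d0$dist$f[c("a", "b")]), c(0.75, 0.25))
  # {a:3, b:1}, eps = 1, vocab {a, b} -> (4/6, 2/6)
  d1 <- empirical_distribution(pool, epsilon = 1, vocab = list(f = c("a", "b")))
  expect_equal(unname(d1$dist$f), c(4 / 6, 2 / 6))
  d2 <- empirical_distribution(lapply(c("a", "b"), function(v) list(f = v)),
                               epsilon = 0)
  expect_equal(unname(d2$dist$f[c("a", "b")]), c(0.5, 0.5))
  expect_error(empirical_distribution(list()), "empty")
})

test_that("temper: identity at T = 1, hand value at T = 1.6, flat limit, composition", {
  d <- empirical_distribution(list(list(f = "a")), epsilon = 0,
                              vocab = list(f = c("a", "b")))
  d$dist$f <- c(a = 0.8, b = 0.2)
  expect_equal(temper(d, 1)$dist$f, d$dist$f)
  t16 <- temper(d, 1.6)$dist$f
  expect_equal(unname(t16), c(0.704, 0.296), tolerance = 1e-3)
  expect_equal(unname(temper(d, 1e9)$dist$f), c(0.5, 0.5), tolerance = 1e-4)
  # exponent composition: temper(T1) then temper(T2) == temper(T1 * T2)
  expect_equal(temper(temper(d, 1.3), 2.1)$dist$f, temper(d, 1.3 * 2.1)$dist$f)
  expect_error(temper(d, 0), "> 0")
})

test_that("adjust_target multiplies then renormalizes in order", {
  d <- empirical_distribution(list(list(f = "a"), list(f = "b")), epsilon = 0)
  expect_equal(adjust_target(d, list())$dist$f, d$dist$f)
  half <- adjust_target(d, list(list(feature = "f", value = "a", multiplier = 0.5)))
  expect_equal(unname(half$dist$f[c("a", "b")]), c(1 / 3, 2 / 3))
  # x9 on a value holding 10% of the mass lands at 50%
  d2 <- d
  d2$dist$f <- c(a = 0.1, b = 0.9, OTHER = 0)
  nine <- adjust_target(d2, list(list(feature = "f", value = "a", multiplier = 9)))
  expect_equal(unname(nine$dist$f[["a"]]), 0.5)
  expect_error(adjust_target(d, list(list(feature = "f", value = "a", multiplier = 0))),
               "> 0")
  expect_message(adjust_target(d, list(list(feature = "f", value = "zz", multiplier = 2))),
                 "matched no values")
})

test_that("kl_divergence: zero at identity, closed form, nonnegative", {
  mk <- function(p) {
    d <- empirical_distribution(list(list(f = "a")), epsilon = 0)
    d$dist$f <- p
    d
  }
  p <- mk(c(a = 0.3, b = 0.7))
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(mk(c(a = 1, b = 0)), mk(c(a = 0.5, b = 0.5))), log(2))
  expect_identical(kl_divergence(mk(c(a = 1, b = 0)), mk(c(a = 0, b = 1))), Inf)
  set.seed(99)
  for (i in 1:1000) {
    x <- stats::runif(4)
    y <- stats::runif(4)
    kl <- kl_divergence(mk(stats::setNames(x / sum(x), letters[1:4])),
                        mk(stats::setNames(y / sum(y), letters[1:4])))
    expect_gte(kl, -1e-12)
  }
})

test_that("greedy_select balances a 90/10 pool toward a uniform target", {
  pool <- do.call(rbind, lapply(1:100, function(i) {
    data.frame(passage_id = paste0("p", i), doc_id = paste0("d", i),
               passage_type = "paragraph",
               text = if (i <= 90) "xx" else "yy",
               year = 2020, journal = "J", mesh_clusters = "",
               stringsAsFactors = FALSE)
  }))
  feats <- lapply(seq_len(nrow(pool)), function(i) {
    list(token = pool$text[i])  # single feature type, two values
  })
  # uniform target built from a balanced pseudo-pool (smoothed like real use)
  target <- empirical_distribution(
    lapply(rep(c("xx", "yy"), 50), function(v) list(token = v)))
  sel <- greedy_select(pool, feats, target,
                       sampler_config(n_select = 10, seed = 1))
  expect_identical(as.integer(table(pool$text[sel$selected])[c("xx", "yy")]),
                   c(5L, 5L))
})

test_that("per-article cap and full-selection edge cases hold", {
  # one article floods the pool with 50 passages bearing the favored token
  pool <- do.call(rbind, c(
    lapply(1:50, function(i) data.frame(
      passage_id = paste0("fav", i), doc_id = "bigdoc", passage_type = "paragraph",
      text = "favored topic", year = 2020, journal = "J", mesh_clusters = "",
      stringsAsFactors = FALSE)),
    lapply(1:30, function(i) data.frame(
      passage_id = paste0("oth", i), doc_id = paste0("d", i), passage_type = "paragraph",
      text = "other topic", year = 2020, journal = "J", mesh_clusters = "",
      stringsAsFactors = FALSE))))
  feats <- lapply(seq_len(nrow(pool)), function(i)
    extract_features(pool[i, ]))
  target <- empirical_distribution(feats)
  target$dist$tokens["favored"] <- 100 * target$dist$tokens["favored"]
  target$dist$tokens <- target$dist$tokens / sum(target$dist$tokens)
  sel <- greedy_select(pool, feats, target,
                       sampler_config(n_select = 12, max_per_article = 2, seed = 3))
  expect_lte(sum(pool$doc_id[sel$selected] == "bigdoc"), 2L)

  # infeasible cap errors before selection
  expect_error(greedy_select(pool[1:10, ], feats[1:10],
                             empirical_distribution(feats[1:10]),
                             sampler_config(n_select = 3, max_per_article = 2)),
               "infeasible")

  # n_select = pool size with no cap returns the whole pool
  sel_all <- greedy_select(pool[51:60, ], feats[51:60],
                           empirical_distribution(feats[51:60]),
                           sampler_config(n_select = 10, max_per_article = 10,
                                          seed = 2))
  expect_setequal(sel_all$selected, 1:10)
})

test_that("greedy selection dominates random selections in KL", {
  for (seed in 1:3) {
    gen <- generate_corpus(generator_config(seed = seed, n_passages = 60))
    pas <- gen$corpus$passages
    feats <- lapply(seq_len(nrow(pas)), function(i) extract_features(pas[i, ]))
    cfg <- sampler_config(n_select = 15, temperature = 1.6, seed = seed,
                          max_per_article = 15)
    target <- build_target(feats, cfg)
    sel <- greedy_select(pas, feats, target, cfg)
    greedy_kl <- kl_divergence(
      empirical_distribution(feats[sel$selected], vocab = lapply(target$dist, names)),
      target)
    set.seed(seed + 1000)
    random_kls <- replicate(100, kl_divergence(
      empirical_distribution(feats[sample(nrow(pas), 15)],
                             vocab = lapply(target$dist, names)),
      target))
    expect_lt(greedy_kl, mean(random_kls))
    # the greedy KL trajectory ends no higher than its first step
    expect_lte(utils::tail(sel$kl_trace, 1), sel$kl_trace[1])
  }
})

test_that("determinism: same seed gives the same selection", {
  gen <- generate_corpus(generator_config(seed = 2, n_passages = 40))
  pas <- gen$corpus$passages
  feats <- lapply(seq_len(nrow(pas)), function(i) extract_features(pas[i, ]))
  cfg <- sampler_config(n_select = 8, seed = 5, candidate_subsample = 20)
  target <- build_target(feats, cfg)
  expect_identical(greedy_select(pas, feats, target, cfg)$selected,
                   greedy_select(pas, feats, target, cfg)$selected)
})
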