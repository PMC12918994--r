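# Designed corpus sampling: greedy selection of passages minimizing the
# KL divergence between the selected set's feature distribution and an
# adjusted target distribution.

#' Extract the discrete feature vector of a passage
#'
#' Feature types: `year`, `journal`, `passage_type`, `length_bin` (character
#' length bucketed at `length_bins`), `tokens` (maximal runs of letters or
#' digits, case-folded), and `mesh_clusters`.
#'
#' @param passage one row of a corpus passage table (data.frame or list with
#'   `text`, `year`, `journal`, `passage_type`, `mesh_clusters`).
#' @param length_bins strictly increasing bin edges for passage length.
#' @return named list of character vectors (a feature vector).
#' @export
extract_features <- function(passage, length_bins = c(100, 200, 400, 800)) {
  stopifnot(!is.unsorted(length_bins, strictly = TRUE))
  len <- nchar(passage$text)
  idx <- findInterval(len, length_bins, left.open = TRUE)
  labels <- c(paste0("<=", length_bins[1]),
              if (length(length_bins) > 1)
                paste0(length_bins[-length(length_bins)], "-", length_bins[-1]),
              paste0(">", length_bins[length(length_bins)]))
  toks <- tokenize_text(passage$text)
  mesh <- passage$mesh_clusters
  mesh <- if (is.null(mesh) || is.na(mesh) || !nzchar(mesh)) character()
          else strsplit(mesh, ";", fixed = TRUE)[[1]]
  list(year = as.character(passage$year),
       journal = as.character(passage$journal),
       passage_type = as.character(passage$passage_type),
       length_bin = labels[idx + 1L],
       tokens = unique(toks),
       mesh_clusters = mesh)
}

#' Tokenize text into maximal runs of letters or digits, case-folded
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
tokenize_text <- function(text) {
  toks <- regmatches(text, gregexpr("[[:alnum:]]+", text))[[1]]
  tolower(toks)
}

#' Smoothed empirical feature distribution of a pool
#'
#' Multi-valued feature types (tokens, clusters) contribute fractional mass
#' `1/|values|` per passage so each passage carries total mass 1 per feature
#' type. Per feature type, `P(v) = (mass(v) + eps) / (total + eps * |vocab|)`.
#' An `OTHER` bucket is always part of each vocabulary so unseen values have
#' positive smoothed probability.
#'
#' @param pool nonempty list of feature vectors from [extract_features()].
#' @param epsilon smoothing constant (default 1e-6).
#' @param vocab optional named list fixing the per-feature-type vocabulary.
#' @return object of class `feature_distribution`: list with `dist` (named
#'   list of named probability vectors) and `epsilon`.
#' @export
empirical_distribution <- function(pool, epsilon = 1e-6, vocab = NULL) {
  if (!length(pool)) stop("empty pool")
  ftypes <- names(pool[[1]])
  masses <- feature_mass(pool, ftypes, vocab)
  dist <- lapply(masses, function(m) {
    (m + epsilon) / (sum(m) + epsilon * length(m))
  })
  structure(list(dist = dist, epsilon = epsilon), class = "feature_distribution")
}

# accumulate fractional mass per feature type over a pool; unseen values are
# folded into OTHER when a vocabulary is fixed
feature_mass <- function(pool, ftypes, vocab = NULL) {
  out <- list()
  for (ft in ftypes) {
    vals <- lapply(pool, `[[`, ft)
    w <- rep(1 / pmax(1L, lengths(vals)), lengths(vals))
    v <- unlist(vals, use.names = FALSE)
    if (!is.null(vocab)) {
      voc <- vocab[[ft]]
      v[!v %in% voc] <- "OTHER"
      m <- stats::setNames(numeric(length(voc)), voc)
    } else {
      voc <- unique(c(v, "OTHER"))
      m <- stats::setNames(numeric(length(voc)), voc)
    }
    if (length(v)) {
      agg <- tapply(w, v, sum)
      m[names(agg)] <- agg
    }
    out[[ft]] <- m
  }
  out
}

#' Temperature-scale a feature distribution
#'
#' Per value, `p <- p^(1/T)`, renormalized per feature type. `T = 1` is the
#' identity; `T > 1` flattens toward uniform, emphasizing long-tail values.
#'
#' @param dist a [empirical_distribution()] object.
#' @param T positive temperature (the designed-sampling default is 1.6).
#' @export
temper <- function(dist, T) {
  if (!is.numeric(T) || T <= 0) stop("temperature must be > 0")
  dist$dist <- lapply(dist$dist, function(p) {
    q <- p^(1 / T)
    q / sum(q)
  })
  dist
}

#' Apply multiplicative adjustments to a target distribution
#'
#' Each adjustment is a list `(feature, value, multiplier)` where `value` is
#' either a character vector of values or a predicate function over value
#' names; matched values are multiplied in listed order (an "800% increase"
#' is multiplier 9, a "50% reduction" multiplier 0.5), then each feature type
#' is renormalized. Unmatched predicates are reported via a message.
#'
#' @param dist a [empirical_distribution()] object.
#' @param adjustments list of adjustment specs.
#' @export
adjust_target <- function(dist, adjustments) {
  for (adj in adjustments) {
    if (is.null(adj$multiplier) || adj$multiplier <= 0) stop("multiplier must be > 0")
    p <- dist$dist[[adj$feature]]
    if (is.null(p)) stop("unknown feature type: ", adj$feature)
    hit <- if (is.function(adj$value)) {
      vapply(names(p), adj$value, TRUE)
    } else names(p) %in% adj$value
    if (!any(hit)) {
      message("adjustment matched no values for feature ", adj$feature)
      next
    }
    p[hit] <- p[hit] * adj$multiplier
    dist$dist[[adj$feature]] <- p
  }
  dist$dist <- lapply(dist$dist, function(p) p / sum(p))
  dist
}

#' Weighted KL divergence between two feature distributions
#'
#' Sum over shared feature types of `weight * sum_v p(v) log(p(v)/q(v))`,
#' with `0 log 0 = 0`. Values of `p` absent from `q` contribute `Inf` when
#' `p(v) > 0` (which cannot occur after smoothing).
#'
#' @param p,q [empirical_distribution()] objects over the same vocabularies.
#' @param weights optional named nonnegative weights per feature type
#'   (default 1).
#' @return nonnegative real (possibly `Inf`).
#' @export
kl_divergence <- function(p, q, weights = NULL) {
  total <- 0
  for (ft in names(p$dist)) {
    pv <- p$dist[[ft]]
    qv <- q$dist[[ft]]
    vals <- union(names(pv), names(qv))
    pa <- stats::setNames(numeric(length(vals)), vals)
    qa <- pa
    pa[names(pv)] <- pv
    qa[names(qv)] <- qv
    nz <- pa > 0
    term <- if (any(nz & qa == 0)) Inf else sum(pa[nz] * log(pa[nz] / qa[nz]))
    w <- if (is.null(weights) || is.null(weights[[ft]])) 1 else weights[[ft]]
    total <- total + w * term
  }
  total
}

#' Sampler configuration
#'
#' @param n_select number of passages to select.
#' @param max_per_article cap on passages selected per article (default 2).
#' @param temperature temperature for target scaling (default 1.6; applied by
#'   [build_target()], recorded here for provenance).
#' @param adjustments default adjustment list for [build_target()].
#' @param candidate_subsample per-step candidate pool size; `NULL` means full
#'   scan for pools up to 10,000 passages and 2,000 seeded candidates beyond.
#' @param epsilon smoothing constant shared by selected and target
#'   distributions.
#' @param weights optional per-feature-type KL weights.
#' @param seed integer seed for candidate subsampling.
#' @export
sampler_config <- function(n_select, max_per_article = 2L, temperature = 1.6,
                           adjustments = list(), candidate_subsample = NULL,
                           epsilon = 1e-6, weights = NULL, seed = 1L) {
  stopifnot(n_select >= 1, max_per_article >= 1, temperature > 0)
  structure(list(n_select = as.integer(n_select),
                 max_per_article = as.integer(max_per_article),
                 temperature = temperature, adjustments = adjustments,
                 candidate_subsample = candidate_subsample,
                 epsilon = epsilon, weights = weights, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Build the adjusted target distribution from a pool
#'
#' Estimates the empirical distribution of the pool, applies temperature
#' scaling, then the configured multiplicative adjustments, in that order.
#'
#' @param features list of feature vectors for the pool.
#' @param config a [sampler_config()].
#' @export
build_target <- function(features, config) {
  dist <- empirical_distribution(features, epsilon = config$epsilon)
  dist <- temper(dist, config$temperature)
  adjust_target(dist, config$adjustments)
}

#' Greedy KL-minimizing passage selection
#'
#' Iteratively adds the candidate passage whose addition minimizes the KL
#' divergence between the selected set's smoothed feature distribution and
#' the target. Candidates from articles that already contributed
#' `max_per_article` selections are skipped; each step scans a seeded random
#' subsample of the remaining candidates (`candidate_subsample`; full scan by
#' default for pools up to 10,000). Ties break toward the lowest pool index.
#'
#' @param pool data.frame of passages (needs `doc_id`) or an
#'   [annotated_corpus()].
#' @param features list of feature vectors aligned with the pool rows.
#' @param target a [empirical_distribution()] target.
#' @param config a [sampler_config()].
#' @return list with `selected` (integer pool indices in selection order) and
#'   `kl_trace` (KL divergence after each addition).
#' @export
greedy_select <- function(pool, features, target, config) {
  if (inherits(pool, "annotated_corpus")) pool <- pool$passages
  n <- nrow(pool)
  stopifnot(length(features) == n, config$n_select <= n)
  n_articles <- length(unique(pool$doc_id))
  if (config$n_select > n_articles * config$max_per_article) {
    stop(sprintf("infeasible: n_select = %d > %d articles x cap %d",
                 config$n_select, n_articles, config$max_per_article))
  }
  subsample <- config$candidate_subsample
  if (is.null(subsample)) subsample <- if (n <= 10000) n else 2000L
  eps <- config$epsilon
  ftypes <- names(target$dist)
  vocab <- lapply(target$dist, names)
  # per-passage fractional mass vectors aligned to the target vocabulary
  pmass <- lapply(seq_len(n), function(i) {
    feature_mass(features[i], ftypes, vocab = vocab)
  })
  sel_mass <- lapply(vocab, function(v) stats::setNames(numeric(length(v)), v))
  sel_tot <- stats::setNames(numeric(length(ftypes)), ftypes)
  doc_count <- new.env(parent = emptyenv())
  kl_of <- function(mass, tot) {
    total <- 0
    for (ft in ftypes) {
      pv <- (mass[[ft]] + eps) / (tot[[ft]] + eps * length(mass[[ft]]))
      qv <- target$dist[[ft]]
      nz <- pv > 0
      w <- if (is.null(config$weights) || is.null(config$weights[[ft]])) 1
           else config$weights[[ft]]
      total <- total + w * sum(pv[nz] * log(pv[nz] / qv[nz]))
    }
    total
  }
  selected <- integer()
  kl_trace <- numeric()
  available <- rep(TRUE, n)
  with_seed(config$seed, {
    for (step in seq_len(config$n_select)) {
      cand <- which(available)
      capped <- vapply(pool$doc_id[cand], function(d) {
        cnt <- doc_count[[d]]
        !is.null(cnt) && cnt >= config$max_per_article
      }, TRUE)
      cand <- cand[!capped]
      if (!length(cand)) stop("no eligible candidates remain at step ", step)
      if (length(cand) > subsample) cand <- sort(sample(cand, subsample))
      best <- NA_integer_
      best_kl <- Inf
      for (i in cand) {
        m <- sel_mass
        t <- sel_tot
        for (ft in ftypes) {
          m[[ft]] <- m[[ft]] + pmass[[i]][[ft]]
          t[[ft]] <- t[[ft]] + sum(pmass[[i]][[ft]])
        }
        kl <- kl_of(m, t)
        if (is.na(best) || kl < best_kl - 1e-12) {
          best_kl <- kl
          best <- i
        }
      }
      for (ft in ftypes) {
        sel_mass[[ft]] <- sel_mass[[ft]] + pmass[[best]][[ft]]
        sel_tot[[ft]] <- sel_tot[[ft]] + sum(pmass[[best]][[ft]])
      }
      d <- pool$doc_id[best]
      doc_count[[d]] <- if (is.null(doc_count[[d]])) 1L else doc_count[[d]] + 1L
      available[best] <- FALSE
      selected <- c(selected, best)
      kl_trace <- c(kl_trace, best_kl)
    }
  })
  list(selected = selected, kl_trace = kl_trace)
}
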