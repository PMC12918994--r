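---
title: "Methods: models, generators, and design choices in corpuscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators, and design choices in corpuscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corpuscle)
```

# The problem

Single-cell technologies are producing cell phenotypes faster than structured
resources can absorb them, and the names authors give those phenotypes are
increasingly compositional ("exhausted CD8+ T cells": a state, a molecular
signature, a lineage word, a root). Building an annotation corpus that
captures this language — and evaluating the NLP systems trained on it —
requires a pipeline of well-defined, testable steps: sampling passages worth
annotating, measuring annotator agreement, scoring recognition and
ontology-linking systems, quantifying ontology coverage, and testing how
naming motifs vary across cell lineages.

`corpuscle` implements that pipeline as a reusable toolkit, exercisable end
to end on synthetic corpora with known ground truth. A green test therefore
establishes that each procedure does what its contract says on data whose
generating process is fully known; it does not establish anything about a
particular real corpus, ontology release, or pretrained model, all of which
are out of scope here.

# Data model

A corpus is a passage table plus an annotation table. Spans are 0-based,
half-open character offsets over the passage text, so
`substr(text, start + 1, end)` must equal the annotation's recorded text;
this matches the BioC convention and makes the invariant directly testable.
Annotations carry one of three entity types — `cell_phenotype` (a distinct,
identifiable type or state), `heterogeneous` (cells of several developmental
lineages grouped by a shared attribute), `vague` (identity not determinable
from the text) — and semicolon-joined ontology identifiers with a parallel
qualifier channel (`exact` or `related`). Guideline rules are checked by
`validate_corpus()` and reported as data, not exceptions: vague annotations
must be unlinked, and overlapping spans are legal only when a vague
annotation strictly contains a non-vague one.

Ontologies are rooted DAGs of `is_a` edges. Depth is the **shortest** `is_a`
path from the root: the source material does not state whether shortest or
longest paths define depth, so shortest-path is adopted (it is also what a
breadth-first oracle naturally checks); no other component depends on the
choice. Obsolete identifiers are remapped through `replaced_by` with a
logged notice.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are a stated
world chosen once:

* entity-type mix 82.8 / 7.2 / 10.0 percent (phenotype / heterogeneous /
  vague), the composition reported for the real corpus;
* 65% of non-vague annotations carry a single exact link (the reported share
  of exactly linked unique phenotype mentions); of the remainder, 80% carry
  1–2 related links and the rest are unlinked;
* 5% of non-vague annotations are coordination ellipses ("x and y") with one
  identifier per conjunct — a rate the source does not quantify, chosen as a
  small-but-exercised fraction;
* 7 annotations per passage (the real corpus averages ~7.4);
* per-(lineage, motif) prevalences in `default_motif_prevalence()` emulate
  the qualitative lineage signatures described for real nomenclature
  (hematopoietic names lean on molecular signatures, functional roles and
  states; structural lineages on anatomical context and the lineage word;
  neuronal names on signaling and appearance motifs). Magnitudes are
  realistic choices, not reported values.

Names are assembled from fixed per-motif word vocabularies in a fixed,
roughly head-final order, so motif span ground truth is unambiguous. When an
annotation is an exact match, its mention text **is** the label of the
linked ontology term (labels are assigned as names are generated); this
makes the entity-linking invariant — verbatim-label mentions link perfectly
with the toy embedder — true by construction on corpora with unique labels.

What the generator deliberately does not emulate: scientific prose (passages
are template sentences), context-dependent linking (the same string linked
to different terms in different passages), abbreviation phenomena, and
annotator-specific biases beyond the three perturbation knobs (drop,
boundary jitter, sibling relabeling) of `perturb_annotations()`.

# Designed sampling

Passages are selected greedily to minimize the KL divergence between the
selected set's feature distribution and an adjusted target. Feature types:
year, journal, passage type, length bin, tokens (maximal alphanumeric runs,
case-folded), MeSH clusters. Decisions the source leaves open, resolved
here:

* **Set-valued features.** Tokens and clusters contribute fractional mass
  `1/|values|` per passage so every passage carries total mass 1 per feature
  type, keeping distributions comparable.
* **Combining feature types.** Per-type KL terms are combined as a weighted
  sum, default weight 1.
* **Temperature.** Scaling exponentiates probabilities, `p^(1/T)` then
  renormalization, with the documented default T = 1.6; exponentiating
  log-odds would be an alternative reading, not adopted.
* **Smoothing.** Epsilon (default 1e-6) is applied to both the selected and
  target distributions, with an `OTHER` bucket always in the vocabulary, so
  the KL at selection start is finite.
* **"Increase average passage length by 300%"-style goals** are expressed as
  ordinary multiplicative adjustments on length bins; an 800% increase is
  multiplier 9, a 50% reduction multiplier 0.5.
* Candidate scans are exhaustive for pools up to 10,000 passages and a
  seeded 2,000-candidate subsample beyond; ties break to the lowest pool
  index.

# Splitting

`hill_climb_split()` partitions passages into train/validation/test at exact
sizes `floor(ratio * N)` (remainder to train; defaults 1/2, 1/6, 1/3). It
accepts a swap of two passages iff the objective strictly decreases and
stops after `max_stale` consecutive rejections, so the accepted-score
trajectory is strictly decreasing and sizes never change. The objective
balances entity-type, length-bin and cluster composition (L1 deviation of
each subset from the global distribution) against rewards for identifiers
and case-folded mentions unique to a single subset. The uniqueness terms use
*fractions* rather than raw counts so that deviation and uniqueness terms
stay commensurate under the default weight 1 (raw counts would swamp the
O(1) deviation terms on any non-toy corpus); scaling the weight recovers
count behaviour. Objective weights are exposed because the source states the
intent, not the functional form.

# Agreement and inconsistency flags

`iaa()` reports pooled micro-F1 (annotator 1 as reference; swapping
annotators swaps precision and recall) in four regimes: strict
span+type+identifier, strict span+type, identifier-presence per passage, and
approximate (any-overlap) span matching with greedy one-to-one resolution.
Related identifiers are coerced to "no ID" before identifier comparison,
because several combinations of related identifiers can be equally
acceptable. Pooled micro-F1 (not a per-passage average) is the headline
number — the standard NER convention — with a per-passage-type table as a
secondary breakdown. Under drop-only perturbation at rate *d*, pooled
strict-span F1 concentrates at `2(1-d)/(2-d)`; the tests verify this with a
delta-method standard error.

Two automated inconsistency flags mirror consensus review: mention strings
whose exact identifier diverges from the modal identifier for that string
(ties flag nothing), and annotated populations immediately followed by a
subset descriptor ("epithelial cell subsets") without a covering vague
annotation.

# NER and entity-linking evaluation

NER matching is one-to-one and greedy: gold annotations in start-offset
order take the unmatched qualifying prediction with the largest overlap
(ties to the lowest prediction index). Exact mode requires identical
offsets; approximate mode any overlap; merged labels collapse the three
entity types. Whether the reference evaluation uses greedy or optimal
matching is unstated; greedy is adopted and the tests compare its exact-mode
TP count against a brute-force optimal matcher on all small instances (they
agree), while approximate-mode greedy is verified never to exceed the
optimum. Division by zero yields P = R = F1 = 0.

Entity linking is embedding-based retrieval against term labels and
synonyms. The embedder is a plug-in contract (text to unit-norm vector); the
shipped backend is a deterministic hashed character-trigram bag, sufficient
to make string similarity meaningful without pretrained models. Cosine ties
break by lexicographic term id. Single-link scoring counts (annotation,
identifier) pairs, which reproduces the documented ceiling: with any
multi-identifier gold annotation, a single-link system cannot reach F1 = 1
in all-IDs mode. Top-k recall is annotation-level (one unit per annotation,
exact and related ids pooled), the reading adopted where the source reports
one recall per model and cutoff. Novelty detection uses the rank-statistic
AUROC (concordant pairs plus half ties), which the tests verify equals the
trapezoidal area under the reported ROC curve.

Mention preprocessing is conservative: longest-match abbreviation expansion
from a user-supplied map (the detector that builds the map is external),
then a plural stemmer that strips a trailing "s" only when the stem has at
least three letters and the word does not end in ss/us/is/as. It is
idempotent by construction.

# Motif analysis

The motif vocabulary is a closed set of exactly 14 types. Candidate phrases
are all 1–3 token ranges that avoid manual spans and stopword endpoints.
Manually mapped motifs are placed first (greedy left-to-right longest
match); remaining candidates are labeled by a multinomial
logistic-regression classifier over embeddings and added in order of
**increasing** margin, skipping overlaps — implemented as documented even
though placing the least-confident candidates first is counterintuitive; a
`margin_order = "decreasing"` switch is provided rather than guessing the
intent. The classifier is backed by glmnet (ridge-regularized multinomial
fit along a short lambda path) because no plain multinomial-logit package is
available in the target environment; the contract (class probabilities,
margins) is unchanged. Accuracy estimation uses stratified 10-fold
cross-validation repeated 5 times.

Lineage assignment propagates each linked identifier to its ancestors: each
link carries weight `1/|links|`, split equally over the lineages hit.
When some links hit no lineage, weights are renormalized over the
lineage-hitting links so each included annotation's weights sum to exactly
1; annotations with no lineage-hitting links are excluded. Prevalence is the
weighted proportion of mentions containing a motif at least once, with a
pooled `ALL` baseline row.

Testing uses exact statistics implemented in the package and verified
against enumeration oracles: a minimum-likelihood two-sided binomial test
(all outcomes whose point probability does not exceed the observed one,
within 1e-9 relative tolerance), Fisher's exact test by hypergeometric
enumeration, and Benjamini–Hochberg step-up adjustment, with significance at
FDR < 0.01. Fractional counts are rounded half-to-even (the source says
only "rounded"; R's `round()` is half-to-even). The binomial baseline
*includes* the lineage under test (inclusive pooled baseline), and
table-versus-reference comparisons use Fisher tests on rounded pooled counts
for the `ALL` rows — both resolutions of points the source leaves open.

# Numerical and testing notes

* Every generator is a pure function of (config, seed); RNG state is saved
  and restored around seeded operations.
* The parameter-recovery acceptance check evaluates 65 (lineage, motif)
  cells at once. The expected number of cells outside their own 99% binomial
  band is 0.65 even for an exactly unbiased pipeline, so coverage is
  asserted jointly: every cell within its 99.9% band and no more cells
  outside the 99% band than Binomial(65, 0.01) sampling permits at the 99.9%
  level. This is the multiplicity-correct reading of "recovered within 99%
  bands", not a loosened tolerance.
* Recovery runs use a lineage-pure toy ontology (no cross-lineage
  multi-parent nodes) so each mention's motif draws come from exactly one
  configured lineage row; with diamonds enabled, a small fraction of weight
  crosses lineages by design and recovery would measure a mixture.
* Configuration files use JSON (not YAML) because the target environment
  does not ship a YAML parser.

# Known limitations

The toy embedder captures surface string similarity only; context-dependent
linking and semantic similarity require a pretrained backend plugged into
the same contract. The hill climber is a local optimizer: it guarantees a
strictly decreasing score and exact subset sizes, not a global optimum.
Greedy approximate-span matching can in principle fall below the optimal
matching on adversarial overlap configurations (never observed on generated
data; logged, not hidden). The generator's prose is templated, so
token-distribution features are far less diverse than in real passages.
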