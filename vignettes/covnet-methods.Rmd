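---
title: "Methods: categorical dataset similarity from coverage profiles and ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorical dataset similarity from coverage profiles and ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covnet)
library(dplyr)
```

`covnet` decides, for any two genomics datasets of the same assembly and
experiment type, whether they are *similar* — as a categorical verdict, not a
score — along two independent routes: what their annotations mean
(metadata), and what their genome-wide signal looks like (primary data).
This vignette describes the models behind both routes, the tunable
parameters and their defaults, what the synthetic generators do and do not
emulate, and the design choices made where more than one reasonable option
existed.

## Coverage profiles

A dataset enters the system as a coverage track (bigWig, or bedGraph as a
text fallback) summarized over a fixed, ordered feature set: promoters,
gene bodies, transcripts or enhancers supplied as BED (0-based, half-open;
file order defines the vector index). For feature $i$ with length $l_i$ and
per-base coverage sum $c_i$,

$$\mathrm{rate}_i = c_i / l_i, \qquad
  \mathrm{TPM}_i = 10^6 \,\mathrm{rate}_i \Big/ \sum_j \mathrm{rate}_j .$$

Only the TPM vector and the metadata are retained. Properties worth noting:
profiles are invariant to rescaling the track (sequencing depth), always sum
to $10^6$, and are *compositional* — mass gained by one feature is lost by
all others, which matters later for feature selection. Coverage is treated
as unstranded; features extending past the track's extent are clipped and
fully absent chromosomes contribute zero. A zero-signal track yields an
all-zero profile that is kept but flagged degenerate and excluded from
classifier training. Per-feature-class profiles (promoter vs transcript
models) are kept separate throughout; which model feeds the network is a
configuration choice (`transcript` for RNA-seq, `promoter` otherwise is the
convention used in examples), because nothing in the comparison rule itself
depends on combining them.

## Metadata similarity

Annotated terms are free text, so they are first fuzzy-matched into an
ontology: case-insensitive exact name/synonym matches score 100, otherwise
the normalized Levenshtein similarity $100(1 - d/\max(|a|,|b|))$ is computed
over the whole vocabulary and the best term at or above the threshold
(default 90, ties to the smallest term id) wins. Raising the threshold can
only shrink the set of matched terms; unmatched terms degrade to
"not similar" with a warning rather than an error, so one bad record cannot
block a batch comparison.

Similarity is then defined through **key parent classes**: manually
designated ontology classes (e.g. "cardiovascular system",
"neurological system" in a tissue ontology) whose descendants are considered
mutually similar. `key_parents()` intersects a term's ancestor closure —
*including the term itself*, so a term that is a key class counts as its own
key parent and identical annotations are always similar — with the
designated set. Two cell types are similar when their key-parent sets
intersect.

Targets need two extra rules. Histone marks are compared in a dedicated
ontology that groups modifications by genomic location of enrichment (e.g.
H3K4me3 under both "At active promoters" and "At poised promoters", making
prediction naturally multi-label). Protein targets matched into the GO-like
ontology whose key parents include a configured transcription-factor class
are treated as TFs, and a TF pair is similar only when it *also* shows
interaction evidence at score $\ge$ 0.4 (the usual medium-confidence
convention) in the supplied interaction table. Which classes define "TF" is
deliberately configuration, not code, as is the key-class list itself
(`inst/extdata/key_classes.tsv` shows the layout). Fuzzy matching is applied
to both cell-type and target terms. The overall verdict: cell types similar
AND (both targets absent OR targets similar); a pair where only one side
annotates a target is not similar.

## Primary-data similarity

The primary route predicts the *same* key classes from the TPM profile and
compares predictions. It is a two-stage model per (assembly, experiment
type, metadata field, feature class):

1. **Feature filtering.** A random forest (100 trees, Gini importance,
   fixed seed) is trained to predict the collapsed label set; the top 1,000
   features by importance are kept (all of them when fewer exist). This
   removes constitutively covered and low-signal features before the
   network sees them. Importance is estimated on the training split only.
2. **Multi-label MLP.** Profiles are transformed $\log_2(\mathrm{TPM}+1)$
   and standardized per feature with training-set statistics. The network
   has one ReLU hidden layer (default 128 units) and per-class sigmoid
   outputs trained with binary cross-entropy and full-batch Adam (learning
   rate 0.01, at most 200 epochs), early-stopped on validation loss with
   patience 10 and the best-epoch weights restored. A class is called when
   its score reaches 0.5.

Cohorts are split train/validation/test as round(0.8n)/round(0.1n)/remainder
— reproducing 80/10/10 at $n = 100$ and reserving 20% of any cohort —
stratified by label set when every stratum has at least 3 members, plain
random otherwise, always deterministic under the seed. Training **refuses**
(returns a refusal value, not an error) below 100 labelled datasets:
accuracy estimates from smaller cohorts are too unstable to gate similarity
decisions on. Held-out accuracy is recorded at train time as exact
label-set match — stricter than per-class accuracy, and the honest
summary when downstream logic intersects predicted sets; per-class
accuracies are additionally available via `tidy()`. Two datasets are
primary-similar when predicted cell-type sets intersect and, where the
assay has a target, predicted target sets intersect too.

The MLP is implemented in the package (plain matrix arithmetic with
analytic gradients, verified against finite differences in the test suite)
so that validation-based early stopping, multi-label sigmoid outputs and
seeded reproducibility behave exactly as specified.

## Network, views and recommendations

Within each (assembly, experiment type) group every unordered pair gets
independent `by_metadata` / `by_primary` flags; an edge exists when either
holds. Datasets sharing an annotated (cell type, target) pair collapse into
one node sized by member count; two nodes are connected when *any* member
pair is (a quorum rule was considered and rejected — with categorical
verdicts a single similar pair is already the event of interest). Layout is
Fruchterman–Reingold (200 iterations, seeded, coordinates centered so a
lone node sits at the origin). The dendrogram uses average linkage on
$1 - $ Pearson correlation over $\log_2(\mathrm{TPM}+1)$ profiles, and the
PCA view fixes centering and loadings on a reference cohort so new datasets
are projected without refitting. Adding one dataset only requires comparing
it against its own group (`compare_new()`), which the tests verify against
a full recompute.

Recommendations for a user are the union of datasets similar to what they
own, similar to what they favorited, and owned by users they follow, minus
what they already own or favorited, minus every private dataset they do not
own. A user's own private data still seeds similarity search, so private
work can be contextualized without being exposed; followed users' private
datasets are *not* recommended, since access rules would make them
unviewable anyway. The primary/metadata filter applies to similarity
reasons only — follow-based reasons are not similarity edges and pass
through. Ranking (reason count descending, then dataset id) is a
determinism device, not a relevance model.

## Synthetic generators

`simulate_cohort()` draws $\log_2$ signal as feature-specific baselines
$\mathcal N(4,1)$ plus $\mathcal N(0,\sigma^2)$ noise, adds a class shift of
`mean_shift` $\times\sigma$ on each class's disjoint signal-feature block,
exponentiates and renormalizes to TPM. Defaults (200 datasets, 2,000
features, 2 classes, 50 signal features each, 3-SD shift) describe a
cleanly separable cohort; mislabeling swaps an exact count of annotations
to the next class, creating pairs similar by coverage but not metadata.
`simulate_ontology()` builds balanced `is_a` trees with key classes at a
chosen level; `simulate_interactions()` realizes an exact
`round(density * n_pairs)` edge count with scores in $[0.4, 1]$ so density
0 and 1 are exactly empty and saturated. `simulate_timecourse()` mimics a
stem-to-cardiomyocyte differentiation course: four timepoints (days 0, 2,
4, 30) interpolate linearly (weight day/30) between the stem-like and
cardiac-like class centroids in log space, all annotated with the
uploader's original stem-cell label — so late timepoints can only reach
cardiac data through primary similarity, which is exactly what the
end-to-end tests check.

These generators emulate separable class structure, annotation noise and
compositional normalization. They do **not** emulate real coverage
autocorrelation along the genome, batch effects, library-preparation
biases, heavy-tailed expression, or the vocabulary breadth of real
ontologies — so a passing suite shows the machinery is correct and the
statistical workflow behaves as designed under its stated assumptions, not
that any particular accuracy will be attained on archive data.

## Numerical choices and scales

Zero-variance features are given unit scale at standardization (their
z-score is 0); correlation distances are clipped at 0 and NA correlations
(possible only for constant profiles) treated as distance 1; TPM of an
all-zero dataset is all-zero rather than NaN. Ties in RF importance resolve
by feature index, fuzzy ties by term id. All stochastic steps (generators,
splits, forests, MLP initialization, layout) consume explicit seeds.

Test and acceptance runs use deliberately modest sizes — cohorts of
100–200 datasets, 150–5,000 features, fuzz suites of 1,000 random
instances — chosen so each quantity is estimated stably while the whole
suite stays interactive. The TPM renormalization bleeds a little class
signal into non-planted features (they become anti-correlated with the
class), which is why planted-feature recovery is asserted on its mean over
seeds rather than demanding perfection from each.

## Limitations

- Comparisons are strictly categorical; no graded semantic similarity
  (Resnik/Lin) or continuous profile distance enters the verdicts.
- The fuzzy matcher is edit-distance-based and will not resolve synonyms
  that are lexically distant unless the ontology lists them.
- Classifier quality is bounded by annotation quality of the training
  cohort; systematically mislabeled cohorts shift what "similar" means.
- One model per metadata field and feature class is trained independently;
  no transfer across assemblies or assays.
- The recommender has no popularity or collaborative-filtering component;
  it is a deterministic function of the similarity graph and the social
  graph.
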