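# covnet

Similarity networks and recommendations for genomic coverage datasets.

High-throughput sequencing archives hold tens of thousands of RNA-seq,
ChIP-seq and ATAC-seq datasets whose free-text annotations are inconsistent
and whose raw signal is hard to compare directly. `covnet` implements, as a
plain R library, the engine behind data-driven dataset discovery: it turns
genome-wide read coverage into fixed-length profiles, decides *categorically*
whether two datasets are similar — by what their annotations mean, and by
what their signal looks like — and uses those verdicts to drive network
views and per-user recommendations. Everything runs offline on local files
and ships with seed-reproducible synthetic generators, so the full pipeline
is testable without any external download.

## What it computes

**Coverage featurization.** Each dataset is a coverage track (bigWig or
bedGraph) summarized over a fixed feature set (promoters, gene bodies,
transcripts or enhancers, as BED). Per-feature sums are converted to
transcripts per million: with count `c_i` over a feature of length `l_i`,

```
rate_i = c_i / l_i        TPM_i = 1e6 * rate_i / sum_j rate_j
```

so every profile sums to 10^6 and is invariant to sequencing depth. Raw
coverage is not retained.

**Metadata similarity.** Free-text cell-type and target terms are
fuzzy-matched (normalized Levenshtein, threshold 90) into ontologies in
which selected *key parent classes* (e.g. "cardiovascular system") mark
groups of mutually similar descendants. Two datasets are metadata-similar
when their cell types share a key parent and — where the assay has a target
— the targets do too, with histone marks compared in a
location-of-enrichment ontology and transcription-factor pairs additionally
required to show interaction evidence (score >= 0.4) in a STRING-like table.

**Primary-data similarity.** A random forest ranks features by importance
against the key-class labels and the top 1,000 are kept; a one-hidden-layer
multi-label MLP (ReLU, sigmoid outputs, Adam, early stopping) then predicts
key classes from `log2(TPM+1)` profiles. Cohorts are split 80/10/10 into
train/validation/test and training requires at least 100 labelled datasets.
Two datasets are primary-similar when their predicted class sets intersect
(cell type, and target where applicable).

**Network and recommendations.** Pairwise verdicts within each (assembly,
experiment type) group become a graph whose nodes collapse datasets sharing
an annotated (cell type, target) pair; views include a seeded
force-directed layout, an average-linkage dendrogram (Newick export) and a
fixed-reference PCA projection. A social graph (ownership, favorites,
follows) turns similarity edges into per-user recommendations that never
expose another user's private datasets.

## Worked example

```r
library(covnet)

# a synthetic two-class cohort: 200 RNA-seq datasets, 500 features,
# classes separated by 3 SD on 50 planted features
co <- simulate_cohort(cohort_spec(n_datasets = 200, n_features = 500,
                                  n_signal = 50, mean_shift = 3, seed = 1))
model <- train_classifier(co$matrix, co$annotated,
                          classifier_config(seed = 1))
glance(model)
#> # A tibble: 1 x 12
#>   field     assembly experiment_type feature_class     n n_train n_validation
#>   <chr>     <chr>    <chr>           <chr>         <int>   <int>        <int>
#> 1 cell_type NA       NA              NA              200     160           20
#> # i 5 more variables: n_test <int>, n_features <int>, n_classes <int>,
#> #   best_epoch <int>, test_accuracy <dbl>
```

The cohort of 200 splits 160/20/20; with well-separated classes the
held-out exact-set accuracy is 1.0. Comparing all datasets and building the
collapsed network:

```r
cfg   <- comparison_config(cell_type = co$ontology)
edges <- compare_all(co$records, cfg, mat = co$matrix, models = list(model))
net   <- layout_network(build_network(edges, co$records), seed = 1)
net
#> <dataset_network: 4 nodes (200 datasets), 2 edges, laid out>
autoplot(net)   # force-directed view, node size = dataset count
```

Each node is one annotated (cell type, target) group; edges carry
independent `by_primary` / `by_metadata` flags. `recommend()` then turns the
edges plus a `social_graph()` into a ranked recommendation table per user.

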