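# Shared fixtures and independent oracles used across test files.

suppressMessages({
  library(dplyr)
  library(purrr)
  library(tibble)
})

toy_config <- example_comparison_config()

# --- oracles -------------------------------------------------------------

# Per-base brute-force coverage sum: expand the track to one value per base.
brute_force_counts <- function(track, features) {
  map_dbl(seq_len(nrow(features)), function(i) {
    bases <- seq(features$start[i], features$end[i] - 1L)
    total <- 0
    rows <- which(track$chrom == features$chrom[i])
    for (r in rows) {
      hit <- bases >= track$start[r] & bases < track$end[r]
      total <- total + sum(hit) * track$value[r]
    }
    total
  })
}

# Reachability closure by boolean matrix powers (independent of the BFS in
# the package).
reachability_oracle <- function(terms, edges) {
  n <- length(terms)
  A <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  if (nrow(edges) > 0) {
    A[cbind(match(edges$child, terms), match(edges$parent, terms))] <- TRUE
  }
  R <- A
  for (k in seq_len(n)) R <- R | (R %*% A > 0)
  R
}

# Naive average-linkage agglomeration over a distance matrix; returns the
# sequence of merge heights.
avg_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# --- random fixture generators ------------------------------------------

# A random acyclic is_a edge set over n terms (edges only point to
# lower-numbered terms, so the graph is a DAG by construction).
random_dag <- function(n, p = 0.3) {
  terms <- sprintf("N:%03d", seq_len(n))
  edges <- list()
  for (i in 2:n) {
    parents <- which(runif(i - 1) < p)
    if (length(parents) == 0) parents <- sample.int(i - 1, 1)
    edges[[i]] <- tibble(child = terms[i], parent = terms[parents])
  }
  list(terms = tibble(id = terms, name = terms), edges = bind_rows(edges))
}

# Leaf terms that carry a key parent class (terms without one are correctly
# never similar, even to themselves, and are tested separately).
anatomy_terms <- function() {
  lv <- ontology_leaves(toy_config$cell_type)
  lv$name[!is.na(lv$key_class)]
}

# Random records drawn from the toy anatomy vocabulary (always matchable).
random_records <- function(n, assembly = "asm1",
                           experiment_type = "RNA-seq",
                           with_targets = FALSE, owners = "user1",
                           public = TRUE) {
  terms <- anatomy_terms()
  targets <- c("H3K4me3", "H3K27ac", "H3K27me3", "GATA4", "TBX5", "NANOG",
               "EZH2")
  bind_rows(map(seq_len(n), function(i) {
    dataset_record(
      dataset_id = sprintf("d%03d", i),
      assembly = assembly, experiment_type = experiment_type,
      cell_type = sample(terms, 1),
      target = if (with_targets) sample(targets, 1) else NA_character_,
      owner = sample(owners, 1),
      public = if (length(public) == 1) public else sample(public, 1)
    )
  }))
}

# A small well-separated cohort for classifier tests (cheap to train on).
small_cohort <- function(seed = 1, n = 120, n_features = 300,
                         mean_shift = 3, fraction_mislabeled = 0) {
  simulate_cohort(cohort_spec(
    n_datasets = n, n_features = n_features, n_signal = 30,
    mean_shift = mean_shift, fraction_mislabeled = fraction_mislabeled,
    seed = seed))
}

fast_config <- function(seed = 1, ...) {
  classifier_config(seed = seed, hidden = 32, ...)
}
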