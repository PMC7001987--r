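# Seed-reproducible synthetic fixtures: cohorts with planted class structure,
# toy ontologies, interaction tables and coverage tracks, so every stage of
# the pipeline is testable without external downloads.

#' Specify a synthetic cohort
#'
#' Datasets are drawn per class from a log-normal base signal; each class
#' gets an additive mean shift (in within-class-SD units) on its designated
#' signal features, and rows are renormalized to the TPM scale. A fixed
#' number of records can be deliberately mislabeled (annotated with a
#' cell-type term from another class) to create primary-only similarity
#' edges.
#'
#' @param n_datasets Cohort size (default 200).
#' @param n_features Profile length (default 2000).
#' @param n_classes Number of planted classes (default 2, equal membership).
#' @param n_signal Signal features per class, disjoint blocks (default 50).
#' @param mean_shift Class separation on signal features, in units of
#'   `noise_sd` (default 3).
#' @param noise_sd Within-class SD in log2 space (default 1).
#' @param fraction_mislabeled Fraction of records (exact count, rounded)
#'   whose annotation is swapped to the next class (default 0).
#' @param seed Integer seed.
#' @param classes Optional explicit class table (`n_members`,
#'   `signal_features` list-column) overriding the equal-membership default.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_datasets = 200, n_features = 2000, n_classes = 2,
                        n_signal = 50, mean_shift = 3, noise_sd = 1,
                        fraction_mislabeled = 0, seed = 1L, classes = NULL) {
  if (is.null(classes)) {
    base <- n_datasets %/% n_classes
    members <- rep(base, n_classes)
    members[seq_len(n_datasets - base * n_classes)] <-
      members[seq_len(n_datasets - base * n_classes)] + 1L
    classes <- tibble(
      class = seq_len(n_classes),
      n_members = members,
      signal_features = map(seq_len(n_classes),
                            ~ ((.x - 1) * n_signal + 1):(.x * n_signal))
    )
  }
  if (sum(classes$n_members) != n_datasets) {
    abort_validation("class memberships must sum to n_datasets")
  }
  if (max(unlist(classes$signal_features)) > n_features) {
    abort_validation("signal feature indices exceed n_features")
  }
  if (mean_shift < 0) abort_validation("mean_shift must be >= 0")
  if (fraction_mislabeled < 0 || fraction_mislabeled > 1) {
    abort_validation("fraction_mislabeled must lie in [0, 1]")
  }
  structure(list(n_datasets = n_datasets, n_features = n_features,
                 classes = classes, mean_shift = mean_shift,
                 noise_sd = noise_sd,
                 fraction_mislabeled = fraction_mislabeled,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a balanced toy ontology
#'
#' A balanced `is_a` tree of the given depth and branching factor, with the
#' nodes at `key_level` (root = level 0) designated as key parent classes.
#'
#' @param depth Number of levels including the root (>= 2).
#' @param branching Children per node.
#' @param key_level Level whose nodes become key classes (default 1).
#' @param prefix Term-id prefix (default `"SY"`).
#' @return An [ontology()].
#' @export
simulate_ontology <- function(depth = 3, branching = 2, key_level = 1,
                              prefix = "SY") {
  if (depth < 2) abort_validation("depth must be >= 2")
  terms <- list(); edges <- list(); key <- character()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("%s:%07d", prefix, counter)
  }
  level_nodes <- list()
  root <- new_id()
  terms[[1]] <- tibble(id = root, name = "root")
  level_nodes[[1]] <- root
  for (lev in seq_len(depth - 1)) {
    ids <- character()
    for (parent in level_nodes[[lev]]) {
      for (b in seq_len(branching)) {
        id <- new_id()
        nm <- sprintf("term_%d_%d", lev, length(ids) + 1L)
        terms[[length(terms) + 1L]] <- tibble(id = id, name = nm)
        edges[[length(edges) + 1L]] <- tibble(child = id, parent = parent)
        ids <- c(ids, id)
      }
    }
    level_nodes[[lev + 1L]] <- ids
    if (lev == key_level) key <- ids
  }
  ontology(bind_rows(terms), bind_rows(edges), key)
}

#' Leaf terms of an ontology, grouped by key parent class
#'
#' @param onto An [ontology()].
#' @return Tibble `id`, `name`, `key_class` (first key parent, `NA` if none).
#' @export
ontology_leaves <- function(onto) {
  has_child <- unique(onto$is_a$parent)
  leaves <- onto$terms[!onto$terms$id %in% has_child, c("id", "name")]
  leaves$key_class <- map_chr(leaves$id, function(id) {
    k <- key_parents(onto, id)
    if (length(k) == 0) NA_character_ else sort(k)[1]
  })
  leaves
}

#' Generate a synthetic cohort with planted class structure
#'
#' @param spec A [cohort_spec()].
#' @param onto Optional [ontology()] supplying cell-type annotations; by
#'   default a toy ontology with one key class per planted class is built.
#' @return A list: `matrix` (TPM, rows = features, columns = datasets),
#'   `records` ([dataset_record()] rows annotated with leaf terms),
#'   `labels` (true key-class id per dataset), `mislabeled` (dataset ids),
#'   `ontology`, `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), onto = NULL) {
  n_classes <- nrow(spec$classes)
  if (is.null(onto)) {
    onto <- simulate_ontology(depth = 3, branching = max(2L, n_classes))
  }
  key <- onto$key_classes
  if (length(key) < n_classes) {
    abort_validation("ontology has %d key classes but the spec plants %d",
                     length(key), n_classes)
  }
  leaves <- ontology_leaves(onto)
  class_terms <- map(key[seq_len(n_classes)], function(k) {
    lv <- leaves[!is.na(leaves$key_class) & leaves$key_class == k, ]
    if (nrow(lv) == 0) abort_validation("key class %s has no leaf terms", k)
    lv
  })
  set.seed(spec$seed)
  base <- rnorm(spec$n_features, mean = 4, sd = 1)
  class_of <- rep(seq_len(n_classes), times = spec$classes$n_members)
  logx <- matrix(rnorm(spec$n_features * spec$n_datasets,
                       mean = 0, sd = spec$noise_sd),
                 nrow = spec$n_features)
  logx <- logx + base
  for (k in seq_len(n_classes)) {
    idx <- which(class_of == k)
    sig <- spec$classes$signal_features[[k]]
    logx[sig, idx] <- logx[sig, idx] + spec$mean_shift * spec$noise_sd
  }
  tpm <- 2^logx
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  dimnames(tpm) <- list(sprintf("f%04d", seq_len(spec$n_features)),
                        sprintf("ds%03d", seq_len(spec$n_datasets)))
  n_mis <- round(spec$fraction_mislabeled * spec$n_datasets)
  mislabeled <- if (n_mis > 0) sort(sample.int(spec$n_datasets, n_mis))
  else integer()
  annotated_class <- class_of
  annotated_class[mislabeled] <- (class_of[mislabeled] %% n_classes) + 1L
  records <- bind_rows(map(seq_len(spec$n_datasets), function(i) {
    terms_i <- class_terms[[annotated_class[i]]]
    dataset_record(
      dataset_id = colnames(tpm)[i],
      assembly = "asm1", experiment_type = "RNA-seq",
      cell_type = terms_i$name[1 + (i - 1) %% nrow(terms_i)],
      owner = "user1", public = TRUE
    )
  }))
  list(matrix = tpm, records = records,
       labels = key[class_of], annotated = key[annotated_class],
       mislabeled = colnames(tpm)[mislabeled],
       ontology = onto, spec = spec)
}

#' Generate a random symmetric interaction table
#'
#' Exactly `round(density * n_pairs)` of all unordered term pairs receive an
#' edge, with confidence scores drawn uniformly from `[0.4, 1]` (so at the
#' default medium-confidence cutoff every generated edge counts as
#' evidence).
#'
#' @param terms Character vector of protein names.
#' @param density Fraction of pairs connected, in `[0, 1]`.
#' @param seed Integer seed.
#' @return An [interaction_table()].
#' @export
simulate_interactions <- function(terms, density = 0.5, seed = 1L) {
  if (length(terms) < 2 || density == 0) {
    return(interaction_table(tibble(protein_a = character(),
                                    protein_b = character(),
                                    score = numeric())))
  }
  cmb <- utils::combn(terms, 2)
  n_pairs <- ncol(cmb)
  m <- round(density * n_pairs)
  set.seed(seed)
  pick <- sort(sample.int(n_pairs, m))
  interaction_table(tibble(protein_a = cmb[1, pick],
                           protein_b = cmb[2, pick],
                           score = runif(m, 0.4, 1)))
}

#' Write a synthetic coverage track
#'
#' @param intervals Tibble `chrom`, `start`, `end` of non-overlapping
#'   intervals (0-based half-open).
#' @param values Coverage value per interval.
#' @param path Optional bedGraph output path.
#' @return The `coverage_track` tibble (written to `path` when given).
#' @export
simulate_track <- function(intervals, values, path = NULL) {
  intervals <- as_tibble(intervals)
  if (nrow(intervals) != length(values)) {
    abort_validation("one value per interval required")
  }
  ord <- order(intervals$chrom, intervals$start)
  iv <- intervals[ord, ]
  same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
  if (nrow(iv) > 1 && any(same & iv$start[-1] < iv$end[-nrow(iv)])) {
    abort_validation("intervals overlap")
  }
  track <- validate_track(tibble(chrom = intervals$chrom,
                                 start = intervals$start,
                                 end = intervals$end,
                                 value = values))
  if (!is.null(path)) write_bedgraph(track, path)
  track
}

#' Built-in example ontologies and comparison configuration
#'
#' Loads the toy anatomy ontology (organ-system-level key classes), the
#' GO-like target ontology (with a TF-defining key class), the
#' histone-modification ontology (marks grouped by genomic location of
#' enrichment) and a small interaction table shipped with the package, and
#' bundles them into a [comparison_config()].
#'
#' @return A `comparison_config`.
#' @export
example_comparison_config <- function() {
  ext <- function(f) system.file("extdata", f, package = "covnet",
                                 mustWork = TRUE)
  key <- readr::read_tsv(ext("key_classes.tsv"), show_col_types = FALSE)
  kc <- function(o) key$class_id[key$ontology == o]
  comparison_config(
    cell_type = read_obo(ext("toy_anatomy.obo"), kc("cell_type")),
    target_go = read_obo(ext("toy_go.obo"), kc("target_go")),
    target_histone = read_obo(ext("histone_ontology.obo"),
                              kc("target_histone")),
    tf_classes = kc("transcription_factor"),
    interactions = read_interactions(ext("toy_interactions.tsv"))
  )
}

timecourse_ontology <- function() {
  ext <- function(f) system.file("extdata", f, package = "covnet",
                                 mustWork = TRUE)
  key <- readr::read_tsv(ext("key_classes.tsv"), show_col_types = FALSE)
  read_obo(ext("toy_anatomy.obo"), key$class_id[key$ontology == "cell_type"])
}

#' Simulate a stem-to-cardiomyocyte differentiation timecourse
#'
#' A scaled-down analogue of an hESC-to-cardiomyocyte RNA-seq timecourse: a
#' reference cohort of stem-like and cardiac-like datasets (annotated with
#' embryonic-structure and cardiovascular-system leaf terms of the toy
#' anatomy ontology) plus four timepoint datasets (days 0, 2, 4 and 30)
#' whose log-profiles interpolate linearly between the two class centroids
#' (interpolation weight `day / 30`). All timepoints carry the uploader's
#' "embryonic stem cell" annotation, so late timepoints can only connect to
#' cardiac data through primary-data similarity.
#'
#' @param seed Integer seed.
#' @param n_per_class Reference datasets per class (default 100).
#' @param n_features Profile length (default 2000).
#' @param mean_shift Class separation in SD units (default 3).
#' @param days Timepoints in days (default `c(0, 2, 4, 30)`).
#' @param owner Uploading user id for the timecourse datasets.
#' @return A list: `matrix`/`records` (reference cohort), `tc_matrix`/
#'   `tc_records` (timepoints), `labels`, `days`, `ontology`, `spec`.
#' @export
simulate_timecourse <- function(seed = 1L, n_per_class = 100,
                                n_features = 2000, mean_shift = 3,
                                days = c(0, 2, 4, 30), owner = "uploader") {
  onto <- timecourse_ontology()
  # class 1 = stem-like (embryonic structure), class 2 = cardiac-like
  key_stem <- "TA:0000004"; key_cardiac <- "TA:0000002"
  spec <- cohort_spec(n_datasets = 2 * n_per_class, n_features = n_features,
                      n_classes = 2, mean_shift = mean_shift, seed = seed)
  set.seed(seed)
  base <- rnorm(n_features, mean = 4, sd = 1)
  class_of <- rep(1:2, each = n_per_class)
  logx <- base + matrix(rnorm(n_features * spec$n_datasets, sd = spec$noise_sd),
                        nrow = n_features)
  centroids <- cbind(base, base)
  centroids[spec$classes$signal_features[[1]], 1] <-
    centroids[spec$classes$signal_features[[1]], 1] +
    mean_shift * spec$noise_sd
  centroids[spec$classes$signal_features[[2]], 2] <-
    centroids[spec$classes$signal_features[[2]], 2] +
    mean_shift * spec$noise_sd
  for (k in 1:2) {
    idx <- which(class_of == k)
    sig <- spec$classes$signal_features[[k]]
    logx[sig, idx] <- logx[sig, idx] + mean_shift * spec$noise_sd
  }
  tpm <- 2^logx
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  dimnames(tpm) <- list(sprintf("f%04d", seq_len(n_features)),
                        sprintf("ds%03d", seq_len(spec$n_datasets)))
  stem_terms <- c("embryonic stem cell", "H1 cell line")
  cardiac_terms <- c("cardiomyocyte", "heart", "aorta")
  records <- bind_rows(map(seq_len(spec$n_datasets), function(i) {
    terms_i <- if (class_of[i] == 1) stem_terms else cardiac_terms
    dataset_record(colnames(tpm)[i], assembly = "asm1",
                   experiment_type = "RNA-seq",
                   cell_type = terms_i[1 + (i - 1) %% length(terms_i)],
                   owner = "archive", public = TRUE)
  }))
  alpha <- days / max(days)
  tc <- vapply(alpha, function(a) {
    lx <- (1 - a) * centroids[, 1] + a * centroids[, 2] +
      rnorm(n_features, sd = spec$noise_sd / 2)
    x <- 2^lx
    1e6 * x / sum(x)
  }, numeric(n_features))
  dimnames(tc) <- list(rownames(tpm), sprintf("tc_day%02d", days))
  tc_records <- bind_rows(map(seq_along(days), function(i) {
    dataset_record(colnames(tc)[i], assembly = "asm1",
                   experiment_type = "RNA-seq",
                   cell_type = "embryonic stem cell",
                   owner = owner, public = FALSE)
  }))
  list(matrix = tpm, records = records,
       labels = c(key_stem, key_cardiac)[class_of],
       key_stem = key_stem, key_cardiac = key_cardiac,
       tc_matrix = tc, tc_records = tc_records, days = days,
       ontology = onto, spec = spec)
}
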