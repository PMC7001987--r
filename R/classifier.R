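# Primary-data similarity: predict key ontology classes from TPM profiles
# (random-forest importance filter -> multi-label MLP), then compare the
# predicted class sets of two datasets categorically.

#' Classifier configuration
#'
#' @param top_k_features Number of features kept by the random-forest
#'   importance filter (default 1000).
#' @param split_fractions Train/validation/test fractions (must sum to 1;
#'   default 0.8/0.1/0.1).
#' @param min_training_cohort Minimum number of labelled datasets required to
#'   train at all (default 100); smaller cohorts yield a refusal, not a model.
#' @param seed Random seed controlling feature selection, the split and MLP
#'   initialization.
#' @param hidden Hidden-layer width of the MLP (default 128, ReLU).
#' @param max_epochs,patience Adam epoch cap (default 200) and early-stopping
#'   patience on validation loss (default 10).
#' @param learning_rate Adam step size (default 0.01, full-batch).
#' @param rf_trees Trees in the importance forest (default 100).
#' @param decision_threshold Per-class sigmoid score above which a class is
#'   called (default 0.5).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(top_k_features = 1000,
                              split_fractions = c(0.8, 0.1, 0.1),
                              min_training_cohort = 100,
                              seed = 1L,
                              hidden = 128,
                              max_epochs = 200,
                              patience = 10,
                              learning_rate = 0.01,
                              rf_trees = 100,
                              decision_threshold = 0.5) {
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    abort_validation("split fractions must sum to 1")
  }
  if (top_k_features < 1 || min_training_cohort < 1) {
    abort_validation("top_k_features and min_training_cohort must be >= 1")
  }
  structure(list(top_k_features = top_k_features,
                 split_fractions = split_fractions,
                 min_training_cohort = min_training_cohort,
                 seed = as.integer(seed), hidden = hidden,
                 max_epochs = max_epochs, patience = patience,
                 learning_rate = learning_rate, rf_trees = rf_trees,
                 decision_threshold = decision_threshold),
            class = "classifier_config")
}

label_key <- function(labels) {
  map_chr(labels, ~ paste(sort(.x), collapse = "|"))
}

#' Derive key-class label sets from annotated metadata
#'
#' Each record's cell-type (or target) term is fuzzy-matched into the
#' corresponding ontology and its key parent classes become the record's
#' multi-label target — the same classes used in annotated metadata
#' comparisons. Records whose term does not match, or has no key parent, are
#' excluded from training with a warning.
#'
#' @param records Tibble of [dataset_record()] rows.
#' @param config A [comparison_config()].
#' @param field `"cell_type"` or `"target"`.
#' @return Tibble `dataset_id`, `term`, `labels` (list-column of key-class
#'   ids), restricted to usable records.
#' @export
derive_labels <- function(records, config, field = c("cell_type", "target")) {
  field <- arg_match(field)
  terms <- records[[field]]
  labels <- map(terms, function(term) {
    if (is.na(term)) return(character())
    if (field == "cell_type") {
      m <- fuzzy_match(term, config$cell_type, config$fuzzy_threshold)
      if (!m$matched) return(character())
      key_parents(config$cell_type, m$term_id)
    } else {
      m <- match_target(term, config)
      if (is.null(m)) character() else m$key
    }
  })
  out <- tibble(dataset_id = records$dataset_id, term = terms,
                labels = labels)
  empty <- lengths(out$labels) == 0
  if (any(empty)) {
    warn(sprintf("%d record(s) excluded from training (unmatched term or no key parent): %s",
                 sum(empty),
                 paste(head(out$dataset_id[empty], 5), collapse = ", ")))
  }
  out[!empty, ]
}

#' Select discriminative features by random-forest importance
#'
#' A random forest is trained to predict the (collapsed) label set from the
#' profile matrix; features are ranked by mean decrease in Gini impurity and
#' the top `min(top_k_features, n_features)` are kept. This removes features
#' that are constitutively or lowly covered before MLP training.
#'
#' @param mat Numeric matrix, rows = features, columns = datasets.
#' @param labels List of key-class character vectors, one per column, or a
#'   `derive_labels()` tibble aligned to the columns.
#' @param config A [classifier_config()].
#' @return Integer vector of selected feature (row) indices.
#' @export
select_features <- function(mat, labels, config = classifier_config()) {
  labels <- as_label_list(labels, colnames(mat))
  y <- factor(label_key(labels))
  if (nlevels(y) < 2) {
    abort_validation("feature selection needs >= 2 distinct label sets")
  }
  if (nrow(mat) < 1) abort_validation("matrix has no features")
  x <- t(mat)
  colnames(x) <- paste0("f", seq_len(nrow(mat)))
  set.seed(config$seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = config$rf_trees)
  imp <- rf$importance[, "MeanDecreaseGini"]
  k <- min(config$top_k_features, nrow(mat))
  order(imp, decreasing = TRUE)[seq_len(k)]
}

as_label_list <- function(labels, ids) {
  if (is_tibble(labels) || is.data.frame(labels)) {
    labels <- setNames(labels$labels, labels$dataset_id)[ids]
  }
  if (length(labels) != length(ids)) {
    abort_validation("labels do not align with matrix columns")
  }
  labels
}

#' Split a cohort into train/validation/test sets
#'
#' Sizes follow the 80/10/10 convention: `round(0.8 n)` train,
#' `round(0.1 n)` validation, remainder test, so 20% of the cohort is
#' reserved. Cohorts below `min_training_cohort` (default 100) refuse
#' training: a `cohort_split` with `refused = TRUE` is returned, not an
#' error. Splitting is stratified by collapsed label set when every stratum
#' has at least 3 members, otherwise plain random; either way it is
#' deterministic for a fixed seed.
#'
#' @param labels Either an integer cohort size (plain random split) or a
#'   vector/list of labels, one per dataset (enables stratification).
#' @param config A [classifier_config()].
#' @return A `cohort_split` list: `train`, `validation`, `test` index
#'   vectors, `n`, `refused`.
#' @export
split_cohort <- function(labels, config = classifier_config()) {
  if (is.numeric(labels) && length(labels) == 1) {
    n <- as.integer(labels)
    keys <- rep("all", n)
  } else {
    if (is.list(labels) && !is.character(labels)) labels <- label_key(labels)
    keys <- as.character(labels)
    n <- length(keys)
  }
  if (n < config$min_training_cohort) {
    return(structure(list(train = integer(), validation = integer(),
                          test = integer(), n = n, refused = TRUE),
                     class = "cohort_split"))
  }
  fr <- config$split_fractions
  n_train <- round(fr[1] * n)
  n_val <- round(fr[2] * n)
  n_test <- n - n_train - n_val
  set.seed(config$seed)
  tab <- table(keys)
  if (length(tab) > 1 && all(tab >= 3)) {
    assignment <- stratified_assignment(keys, c(n_train, n_val, n_test))
  } else {
    perm <- sample.int(n)
    assignment <- integer(n)
    assignment[perm[seq_len(n_train)]] <- 1L
    assignment[perm[n_train + seq_len(n_val)]] <- 2L
    assignment[perm[n_train + n_val + seq_len(n_test)]] <- 3L
  }
  structure(list(train = which(assignment == 1L),
                 validation = which(assignment == 2L),
                 test = which(assignment == 3L),
                 n = n, refused = FALSE),
            class = "cohort_split")
}

# Largest-remainder allocation of split sizes across label strata, then a
# random within-stratum assignment. Guarantees the exact global sizes.
stratified_assignment <- function(keys, sizes) {
  strata <- split(seq_along(keys), keys)
  n_s <- lengths(strata)
  remaining <- n_s
  alloc <- matrix(0L, nrow = length(strata), ncol = 3)
  n <- length(keys)
  for (j in 1:2) {
    quota <- pmin(sizes[j] * n_s / n, remaining)
    base <- floor(quota)
    deficit <- sizes[j] - sum(base)
    if (deficit > 0) {
      room <- remaining - base
      pick <- order(quota - base, decreasing = TRUE)
      for (s in pick) {
        if (deficit == 0) break
        add <- min(deficit, room[s])
        base[s] <- base[s] + add
        deficit <- deficit - add
      }
    }
    alloc[, j] <- as.integer(base)
    remaining <- remaining - base
  }
  alloc[, 3] <- as.integer(remaining)
  assignment <- integer(length(keys))
  for (s in seq_along(strata)) {
    members <- sample(strata[[s]])
    lab <- rep(1:3, times = alloc[s, ])
    assignment[members] <- lab
  }
  assignment
}

#' @export
print.cohort_split <- function(x, ...) {
  if (x$refused) {
    cat(sprintf("<cohort_split: training refused (n = %d)>\n", x$n))
  } else {
    cat(sprintf("<cohort_split: n = %d, train/validation/test = %d/%d/%d>\n",
                x$n, length(x$train), length(x$validation), length(x$test)))
  }
  invisible(x)
}

#' Did a split or training attempt refuse to train?
#'
#' @param x A `cohort_split` or the result of [train_classifier()].
#' @return Logical flag.
#' @export
training_refused <- function(x) {
  isTRUE(x$refused) || inherits(x, "training_refusal")
}

# ---- multi-label MLP (one ReLU hidden layer, sigmoid outputs, Adam, ----
# ---- validation-based early stopping)                               ----

mlp_init <- function(p, h, L, seed) {
  set.seed(seed)
  list(W1 = matrix(rnorm(p * h, sd = sqrt(2 / p)), p, h),
       b1 = numeric(h),
       W2 = matrix(rnorm(h * L, sd = sqrt(2 / h)), h, L),
       b2 = numeric(L))
}

mlp_forward <- function(par, X) {
  Z1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% par$W2, 2, par$b2, "+")
  list(Z1 = Z1, A1 = A1, P = 1 / (1 + exp(-Z2)))
}

mlp_bce <- function(P, Y) {
  eps <- 1e-12
  -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
}

mlp_train <- function(X, Y, Xval, Yval, config) {
  p <- ncol(X); h <- config$hidden; L <- ncol(Y)
  par <- mlp_init(p, h, L, config$seed)
  adam <- list(m = lapply(par, function(w) w * 0),
               v = lapply(par, function(w) w * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  best <- list(par = par, loss = Inf, epoch = 0L)
  wait <- 0L
  n <- nrow(X)
  history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    fw <- mlp_forward(par, X)
    dZ2 <- (fw$P - Y) / n
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(fw$A1, dZ2),
      b2 = colSums(dZ2)
    )
    dA1 <- dZ2 %*% t(par$W2)
    dZ1 <- dA1 * (fw$Z1 > 0)
    grads$W1 <- crossprod(X, dZ1)
    grads$b1 <- colSums(dZ1)
    for (w in names(par)) {
      adam$m[[w]] <- b1 * adam$m[[w]] + (1 - b1) * grads[[w]]
      adam$v[[w]] <- b2 * adam$v[[w]] + (1 - b2) * grads[[w]]^2
      mhat <- adam$m[[w]] / (1 - b1^epoch)
      vhat <- adam$v[[w]] / (1 - b2^epoch)
      par[[w]] <- par[[w]] - lr * mhat / (sqrt(vhat) + eps)
    }
    val_loss <- mlp_bce(mlp_forward(par, Xval)$P, Yval)
    history <- c(history, val_loss)
    if (val_loss < best$loss - 1e-9) {
      best <- list(par = par, loss = val_loss, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }
  list(par = best$par, val_loss = best$loss, best_epoch = best$epoch,
       epochs_run = length(history), history = history)
}

transform_profiles <- function(mat_sel, center = NULL, scale = NULL) {
  X <- t(log2(mat_sel + 1))
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  X <- sweep(X, 2, center, "-")
  X <- sweep(X, 2, scale, "/")
  list(X = X, center = center, scale = scale)
}

#' Train a key-class classifier on TPM profiles
#'
#' The cohort is split 80/10/10 (refusing below `min_training_cohort`
#' labelled datasets), features are filtered by random-forest importance on
#' the training split, profiles are `log2(TPM + 1)`-transformed and
#' standardized with training-set statistics, and a one-hidden-layer
#' multi-label MLP is trained with Adam and early-stopped on validation
#' loss. Test accuracy (exact label-set match at the decision threshold) is
#' recorded at train time.
#'
#' @param mat Numeric TPM matrix, rows = features, columns = datasets.
#' @param labels A [derive_labels()] tibble or list of key-class vectors
#'   aligned to the columns.
#' @param config A [classifier_config()].
#' @param feature_indices Optional pre-selected feature rows; when `NULL`
#'   (default) [select_features()] is run on the training split.
#' @param field,assembly,experiment_type,feature_class Identity stamps stored
#'   on the model.
#' @return A `coverage_classifier` object, or a `training_refusal` when the
#'   cohort is too small.
#' @export
train_classifier <- function(mat, labels, config = classifier_config(),
                             feature_indices = NULL,
                             field = "cell_type", assembly = NA_character_,
                             experiment_type = NA_character_,
                             feature_class = NA_character_) {
  labels <- as_label_list(labels, colnames(mat))
  nonzero <- colSums(mat) > 0
  if (any(!nonzero)) {
    warn(sprintf("%d zero-signal dataset(s) excluded from training",
                 sum(!nonzero)))
    mat <- mat[, nonzero, drop = FALSE]
    labels <- labels[nonzero]
  }
  keys <- label_key(labels)
  split <- split_cohort(keys, config)
  if (split$refused) {
    return(structure(list(refused = TRUE, n = split$n,
                          reason = sprintf(
                            "cohort of %d labelled datasets is below the minimum of %d",
                            split$n, config$min_training_cohort)),
                     class = "training_refusal"))
  }
  if (length(unique(keys)) < 2) {
    abort_validation("all datasets carry the same label set; nothing to learn")
  }
  class_labels <- sort(unique(unlist(labels)))
  Y <- vapply(class_labels,
              function(cl) as.numeric(map_lgl(labels, ~ cl %in% .x)),
              numeric(length(labels)))
  if (is.null(feature_indices)) {
    feature_indices <- select_features(mat[, split$train, drop = FALSE],
                                       labels[split$train], config)
  }
  feature_indices <- sort(unique(as.integer(feature_indices)))
  mat_sel <- mat[feature_indices, , drop = FALSE]
  tr <- transform_profiles(mat_sel[, split$train, drop = FALSE])
  va <- transform_profiles(mat_sel[, split$validation, drop = FALSE],
                           tr$center, tr$scale)
  te <- transform_profiles(mat_sel[, split$test, drop = FALSE],
                           tr$center, tr$scale)
  fit <- mlp_train(tr$X, Y[split$train, , drop = FALSE],
                   va$X, Y[split$validation, , drop = FALSE], config)
  P_test <- mlp_forward(fit$par, te$X)$P
  pred <- P_test >= config$decision_threshold
  truth <- Y[split$test, , drop = FALSE] > 0
  exact <- rowSums(pred != truth) == 0
  model <- structure(
    list(field = field, assembly = assembly,
         experiment_type = experiment_type, feature_class = feature_class,
         selected_features = feature_indices,
         feature_names = rownames(mat)[feature_indices],
         class_labels = class_labels,
         center = tr$center, scale = tr$scale,
         weights = fit$par, config = config,
         test_accuracy = mean(exact),
         per_class_accuracy = colMeans(pred == truth),
         split_sizes = c(train = length(split$train),
                         validation = length(split$validation),
                         test = length(split$test)),
         n = split$n, best_epoch = fit$best_epoch,
         epochs_run = fit$epochs_run, val_loss = fit$val_loss),
    class = "coverage_classifier")
  model
}

#' @export
print.coverage_classifier <- function(x, ...) {
  cat(sprintf(
    "<coverage_classifier: %s, %d classes, %d features, test accuracy %.3f (n = %d)>\n",
    x$field, length(x$class_labels), length(x$selected_features),
    x$test_accuracy, x$n))
  invisible(x)
}

#' @export
print.training_refusal <- function(x, ...) {
  cat(sprintf("<training refused: %s>\n", x$reason))
  invisible(x)
}

#' Tidy a trained classifier: per-class held-out accuracy
#'
#' @param x A `coverage_classifier`.
#' @param ... Unused.
#' @return Tibble `class`, `test_accuracy`.
#' @export
tidy.coverage_classifier <- function(x, ...) {
  tibble(class = x$class_labels,
         test_accuracy = as.numeric(x$per_class_accuracy))
}

#' One-row model summary
#'
#' @param x A `coverage_classifier`.
#' @param ... Unused.
#' @return One-row tibble mirroring a per-model accuracy report: identity,
#'   cohort size, split sizes, exact-set test accuracy.
#' @export
glance.coverage_classifier <- function(x, ...) {
  tibble(field = x$field, assembly = x$assembly,
         experiment_type = x$experiment_type,
         feature_class = x$feature_class,
         n = x$n,
         n_train = unname(x$split_sizes["train"]),
         n_validation = unname(x$split_sizes["validation"]),
         n_test = unname(x$split_sizes["test"]),
         n_features = length(x$selected_features),
         n_classes = length(x$class_labels),
         best_epoch = x$best_epoch,
         test_accuracy = x$test_accuracy)
}

#' Predict key ontology classes for profiles
#'
#' Applies the stored feature selection, transform and MLP to each profile.
#' Deterministic for a fixed model. An all-zero profile is allowed; it may
#' yield an empty predicted set and is flagged degenerate.
#'
#' @param model A `coverage_classifier`.
#' @param mat TPM matrix (rows = features, columns = datasets) over the same
#'   feature set the model was trained on, or a single `dataset_profile`.
#' @return Tibble `dataset_id`, `class`, `score`, `predicted`, `degenerate`.
#' @export
predict_classes <- function(model, mat) {
  if (inherits(mat, "dataset_profile")) {
    m <- matrix(mat$tpm, ncol = 1,
                dimnames = list(mat$name, attr(mat, "dataset_id")))
    mat <- m
  }
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1,
                                       dimnames = list(NULL, "dataset"))
  if (max(model$selected_features) > nrow(mat)) {
    abort_validation("profile has %d features but the model expects >= %d",
                     nrow(mat), max(model$selected_features))
  }
  degenerate <- colSums(mat) == 0
  sel <- mat[model$selected_features, , drop = FALSE]
  X <- transform_profiles(sel, model$center, model$scale)$X
  P <- mlp_forward(model$weights, X)$P
  ids <- colnames(mat) %||% paste0("dataset_", seq_len(ncol(mat)))
  out <- tidyr::expand_grid(dataset_id = ids, class = model$class_labels)
  out$score <- as.vector(t(P))  # dataset-major, matching expand_grid order
  out$predicted <- out$score >= model$config$decision_threshold
  out$degenerate <- degenerate[match(out$dataset_id, ids)]
  out
}

#' Extract predicted class sets from a prediction table
#'
#' @param predictions Output of [predict_classes()].
#' @return Named list of predicted key-class vectors, one per dataset.
#' @export
predicted_sets <- function(predictions) {
  ids <- unique(predictions$dataset_id)
  sets <- map(ids, ~ predictions$class[predictions$dataset_id == .x &
                                         predictions$predicted])
  setNames(sets, ids)
}

#' Categorical primary-data similarity
#'
#' Two datasets are similar by primary data when their coverage-predicted
#' cell-type class sets intersect and, where the assay has a target, their
#' predicted target class sets intersect too.
#'
#' @param cell_a,cell_b Predicted cell-type class sets (character vectors) or
#'   single-dataset [predict_classes()] tibbles.
#' @param target_a,target_b Predicted target class sets, or `NULL` when the
#'   target field is not applicable (e.g. RNA-seq).
#' @return Logical flag.
#' @export
primary_similarity <- function(cell_a, cell_b,
                               target_a = NULL, target_b = NULL) {
  as_set <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) x$class[x$predicted] else as.character(x)
  }
  cell_a <- as_set(cell_a); cell_b <- as_set(cell_b)
  target_a <- as_set(target_a); target_b <- as_set(target_b)
  cell_ok <- length(intersect(cell_a, cell_b)) > 0
  target_ok <- if (is.null(target_a) && is.null(target_b)) TRUE
  else length(intersect(target_a, target_b)) > 0
  cell_ok && target_ok
}
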