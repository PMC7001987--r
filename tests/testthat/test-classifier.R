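# Label derivation, RF feature filtering, cohort splitting, MLP training and
# categorical primary-data similarity.

test_that("labels are the key parents of the annotated term, multi-label where needed", {
  cfg <- toy_config
  recs <- dplyr::bind_rows(
    dataset_record("a", "asm1", "RNA-seq", "cardiomyocyte"),
    dataset_record("b", "asm1", "RNA-seq", "not a real tissue"),
    dataset_record("c", "asm1", "RNA-seq", "neuron")
  )
  expect_warning(lab <- derive_labels(recs, cfg, "cell_type"), "excluded")
  expect_equal(lab$dataset_id, c("a", "c"))
  expect_equal(lab$labels[[1]], "TA:0000002")

  chip <- dplyr::bind_rows(
    dataset_record("d", "asm1", "ChIP-seq", "heart", target = "H3K4me3"),
    dataset_record("e", "asm1", "ChIP-seq", "heart", target = "H3K27me3")
  )
  tl <- derive_labels(chip, cfg, "target")
  expect_setequal(tl$labels[[1]], c("HM:0000002", "HM:0000003"))
  expect_equal(tl$labels[[2]], "HM:0000005")
})

test_that("the RF filter returns min(top_k, n_features) indices, deterministically", {
  co <- small_cohort(seed = 2, n = 60, n_features = 120)
  cfg <- fast_config(seed = 2, top_k_features = 40)
  idx <- select_features(co$matrix, co$annotated, cfg)
  expect_length(idx, 40)
  expect_true(all(idx >= 1 & idx <= 120))
  expect_false(anyDuplicated(idx) > 0)
  # deterministic under a fixed seed
  expect_identical(idx, select_features(co$matrix, co$annotated, cfg))
  # k larger than the number of features returns everything
  idx_all <- select_features(co$matrix, co$annotated,
                             fast_config(seed = 2, top_k_features = 500))
  expect_length(idx_all, 120)
  # single-class labels are rejected
  one <- rep(list("K"), 60)
  expect_error(select_features(co$matrix, one, cfg),
               class = "covnet_validation_error")
})

test_that("the RF filter recovers planted discriminative features", {
  # 50 strongly planted features among 2000; the TPM renormalization bleeds a
  # little class signal into every feature, so recovery is asserted on the
  # mean over seeds with a per-seed floor.
  hits <- sapply(1:10, function(seed) {
    co <- simulate_cohort(cohort_spec(n_datasets = 200, n_features = 2000,
                                      n_signal = 25, mean_shift = 5,
                                      seed = seed))
    planted <- unlist(co$spec$classes$signal_features)
    top <- select_features(co$matrix, co$annotated,
                           fast_config(seed = seed,
                                       top_k_features = length(planted)))
    mean(top %in% planted)
  })
  expect_gte(mean(hits), 0.9)
  expect_true(all(hits >= 0.8))
})

test_that("cohort splitting reproduces 80/10/10 and refuses small cohorts", {
  cfg <- classifier_config(seed = 3)
  s100 <- split_cohort(100, cfg)
  expect_equal(lengths(s100[c("train", "validation", "test")]),
               c(train = 80, validation = 10, test = 10))
  expect_true(training_refused(split_cohort(99, cfg)))
  s200 <- split_cohort(200, cfg)
  expect_equal(lengths(s200[c("train", "validation", "test")]),
               c(train = 160, validation = 20, test = 20))
})

test_that("splits partition the cohort for any n >= 100, stratified or not", {
  cfg <- classifier_config(seed = 9)
  set.seed(9)
  for (n in c(100, 101, sample(100:400, 8))) {
    keys <- sample(c("A", "B", "C"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
    s <- split_cohort(keys, cfg)
    expect_false(s$refused)
    all_idx <- c(s$train, s$validation, s$test)
    expect_equal(sort(all_idx), 1:n)               # complete and disjoint
    expect_equal(length(s$train), round(0.8 * n))
    expect_equal(length(s$validation), round(0.1 * n))
    # stratification keeps class proportions in the training split
    expect_true(all(abs(prop.table(table(keys[s$train])) -
                          prop.table(table(keys))) < 0.05))
  }
})

test_that("the training gate is monotone at the minimum cohort size", {
  cfg <- classifier_config()
  for (n in 90:99) expect_true(training_refused(split_cohort(n, cfg)))
  for (n in c(100, 150, 307)) {
    expect_false(training_refused(split_cohort(n, cfg)))
  }
})

test_that("MLP backpropagation matches finite-difference gradients", {
  set.seed(4)
  n <- 7; p <- 5; h <- 4; L <- 3
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rbinom(n * L, 1, 0.5), n, L)
  par <- covnet:::mlp_init(p, h, L, seed = 4)
  loss_at <- function(par) covnet:::mlp_bce(covnet:::mlp_forward(par, X)$P, Y)
  # analytic gradients (same computation as one training step)
  fw <- covnet:::mlp_forward(par, X)
  dZ2 <- (fw$P - Y) / (n * L)
  gW2 <- crossprod(fw$A1, dZ2)
  dZ1 <- (dZ2 %*% t(par$W2)) * (fw$Z1 > 0)
  gW1 <- crossprod(X, dZ1)
  eps <- 1e-6
  for (probe in 1:10) {
    i <- sample(p, 1); j <- sample(h, 1)
    pp <- par; pp$W1[i, j] <- pp$W1[i, j] + eps
    pm <- par; pm$W1[i, j] <- pm$W1[i, j] - eps
    expect_equal(gW1[i, j], (loss_at(pp) - loss_at(pm)) / (2 * eps),
                 tolerance = 1e-4)
    i2 <- sample(h, 1); j2 <- sample(L, 1)
    pp <- par; pp$W2[i2, j2] <- pp$W2[i2, j2] + eps
    pm <- par; pm$W2[i2, j2] <- pm$W2[i2, j2] - eps
    expect_equal(gW2[i2, j2], (loss_at(pp) - loss_at(pm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("training learns well-separated synthetic classes and records accuracy", {
  co <- small_cohort(seed = 5, n = 160, n_features = 300)
  model <- train_classifier(co$matrix, co$annotated, fast_config(seed = 5))
  expect_s3_class(model, "coverage_classifier")
  expect_gte(model$test_accuracy, 0.9)
  expect_equal(sum(model$split_sizes), 160)
  g <- glance(model)
  expect_equal(g$n_train, 128)
  expect_equal(g$test_accuracy, model$test_accuracy)
  td <- tidy(model)
  expect_equal(td$class, model$class_labels)
  expect_true(all(td$test_accuracy >= 0 & td$test_accuracy <= 1))
})

test_that("training is refused below 100 labelled datasets and on degenerate labels", {
  co <- small_cohort(seed = 6, n = 99, n_features = 100)
  res <- train_classifier(co$matrix, co$annotated, fast_config(seed = 6))
  expect_s3_class(res, "training_refusal")
  expect_true(training_refused(res))

  co2 <- small_cohort(seed = 6, n = 120, n_features = 100)
  same <- rep(list(co2$annotated[[1]]), 120)
  expect_error(train_classifier(co2$matrix, same, fast_config(seed = 6)),
               class = "covnet_validation_error")
})

test_that("zero-signal datasets are excluded from training with a warning", {
  co <- small_cohort(seed = 12, n = 110, n_features = 100)
  mat <- co$matrix
  mat[, 3] <- 0
  expect_warning(
    model <- train_classifier(mat, co$annotated, fast_config(seed = 12)),
    "zero-signal")
  expect_equal(model$n, 109)
})

test_that("a label-shuffled cohort trains to chance-level accuracy", {
  co <- small_cohort(seed = 7, n = 160, n_features = 300)
  accs <- sapply(1:5, function(s) {
    set.seed(s + 100)
    shuffled <- sample(co$annotated)
    m <- train_classifier(co$matrix, shuffled, fast_config(seed = s))
    m$test_accuracy
  })
  # exact-set chance for two balanced classes is ~0.5
  expect_lt(mean(accs), 0.75)
})

test_that("predictions are deterministic, dimension-checked and flag degenerate input", {
  co <- small_cohort(seed = 8, n = 120, n_features = 300)
  model <- train_classifier(co$matrix, co$annotated, fast_config(seed = 8))
  p1 <- predict_classes(model, co$matrix[, 1:4])
  p2 <- predict_classes(model, co$matrix[, 1:4])
  expect_identical(p1, p2)
  expect_setequal(unique(p1$dataset_id), colnames(co$matrix)[1:4])
  expect_true(all(p1$score >= 0 & p1$score <= 1))

  zero <- matrix(0, nrow(co$matrix), 1,
                 dimnames = list(rownames(co$matrix), "z"))
  pz <- predict_classes(model, zero)
  expect_true(all(pz$degenerate))

  expect_error(predict_classes(model, co$matrix[1:10, , drop = FALSE]),
               class = "covnet_validation_error")
})

test_that("training exemplars near their class centroid recover the planted class", {
  co <- small_cohort(seed = 10, n = 160, n_features = 300)
  model <- train_classifier(co$matrix, co$annotated, fast_config(seed = 10))
  sets <- predicted_sets(predict_classes(model, co$matrix))
  acc <- mean(purrr::map2_lgl(sets[co$records$dataset_id], co$annotated,
                              ~ setequal(.x, .y)))
  expect_gte(acc, 0.9)
})

test_that("primary similarity intersects predicted sets, honoring target applicability", {
  expect_true(primary_similarity(c("A", "B"), c("B", "C")))
  expect_false(primary_similarity(c("A"), c("B")))
  # reflexive and symmetric
  expect_true(primary_similarity("A", "A"))
  expect_identical(primary_similarity("A", c("A", "B")),
                   primary_similarity(c("A", "B"), "A"))
  # target check only when applicable
  expect_true(primary_similarity("A", "A"))                     # RNA-seq style
  expect_false(primary_similarity("A", "A", "T1", "T2"))
  expect_true(primary_similarity("A", "A", c("T1", "T2"), "T2"))
  # empty predicted sets never intersect
  expect_false(primary_similarity(character(), character()))
})

test_that("the hand-rolled MLP is competitive with an independent single-layer net", {
  skip_if_not_installed("nnet")
  co <- small_cohort(seed = 13, n = 140, n_features = 200)
  model <- train_classifier(co$matrix, co$annotated, fast_config(seed = 13))
  # nnet on the same transformed features and split as an independent check
  sel <- model$selected_features
  X <- t(log2(co$matrix[sel, ] + 1))
  y <- factor(covnet:::label_key(co$annotated))
  split <- split_cohort(covnet:::label_key(co$annotated),
                        fast_config(seed = 13))
  set.seed(13)
  fit <- nnet::nnet(x = X[split$train, ], y = nnet::class.ind(y[split$train]),
                    size = 8, softmax = TRUE, maxit = 200, trace = FALSE,
                    MaxNWts = 10000)
  pred <- factor(levels(y)[max.col(predict(fit, X[split$test, ]))],
                 levels = levels(y))
  nnet_acc <- mean(pred == y[split$test])
  expect_gte(model$test_accuracy, nnet_acc - 0.15)
})
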