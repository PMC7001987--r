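# Pairwise comparison, the collapsed network, layout, dendrogram and PCA.

test_that("identical-metadata datasets form a complete metadata edge set", {
  cfg <- toy_config
  recs <- dplyr::bind_rows(lapply(1:3, function(i) {
    dataset_record(sprintf("d%d", i), "asm1", "RNA-seq", "heart")
  }))
  edges <- compare_all(recs, cfg)
  expect_equal(nrow(edges), 3)
  expect_true(all(edges$by_metadata))
  expect_false(any(edges$by_primary))   # no profiles/models supplied
})

test_that("datasets from different experiment types or assemblies are never compared", {
  cfg <- toy_config
  recs <- dplyr::bind_rows(
    dataset_record("a", "asm1", "RNA-seq", "heart"),
    dataset_record("b", "asm1", "ChIP-seq", "heart", target = "H3K4me3"),
    dataset_record("c", "asm2", "RNA-seq", "heart")
  )
  expect_equal(nrow(compare_all(recs, cfg)), 0)
})

test_that("compare_all flags are invariant under record order", {
  cfg <- toy_config
  set.seed(21)
  recs <- random_records(15, with_targets = TRUE,
                         experiment_type = "ChIP-seq")
  e1 <- compare_all(recs, cfg)
  e2 <- compare_all(recs[sample(nrow(recs)), ], cfg)
  expect_equal(e1, e2)
})

test_that("compare_all metadata flags agree with pairwise metadata_similarity", {
  cfg <- toy_config
  set.seed(22)
  recs <- random_records(12, with_targets = TRUE,
                         experiment_type = "ChIP-seq")
  edges <- compare_all(recs, cfg)
  flagged <- paste(edges$dataset_id_a, edges$dataset_id_b)[edges$by_metadata]
  cmb <- combn(nrow(recs), 2)
  for (k in seq_len(ncol(cmb))) {
    a <- recs[cmb[1, k], ]; b <- recs[cmb[2, k], ]
    expected <- suppressWarnings(metadata_similarity(a, b, cfg)$similar)
    key <- paste(min(a$dataset_id, b$dataset_id),
                 max(a$dataset_id, b$dataset_id))
    expect_identical(key %in% flagged, expected,
                     label = sprintf("pair %s", key))
  }
})

test_that("a mislabeled dataset connects by primary data only", {
  co <- simulate_cohort(cohort_spec(n_datasets = 120, n_features = 300,
                                    n_signal = 30, mean_shift = 3,
                                    fraction_mislabeled = 0.05, seed = 31))
  model <- train_classifier(co$matrix, co$annotated, fast_config(seed = 31))
  cfg <- comparison_config(cell_type = co$ontology)
  sub <- co$records$dataset_id %in%
    c(co$mislabeled[1],
      setdiff(co$records$dataset_id, co$mislabeled)[1:20])
  edges <- compare_all(co$records[sub, ], cfg, mat = co$matrix[, sub],
                       models = list(model))
  mis <- co$mislabeled[1]
  inc <- edges[edges$dataset_id_a == mis | edges$dataset_id_b == mis, ]
  primary_only <- inc[inc$by_primary & !inc$by_metadata, ]
  expect_gt(nrow(primary_only), 0)
})

test_that("missing profiles degrade to metadata-only comparison with a warning", {
  cfg <- toy_config
  co <- small_cohort(seed = 32, n = 110, n_features = 100)
  model <- train_classifier(co$matrix, co$annotated, fast_config(seed = 32))
  recs <- dplyr::bind_rows(
    dataset_record("ds001", "asm1", "RNA-seq", "heart"),
    dataset_record("missing1", "asm1", "RNA-seq", "heart")
  )
  cfg2 <- comparison_config(cell_type = co$ontology)
  recs$cell_type <- co$records$cell_type[1:2]
  expect_warning(
    edges <- compare_all(recs, cfg2, mat = co$matrix[, 1, drop = FALSE],
                         models = list(model)),
    "metadata-only")
  expect_true(all(!edges$by_primary))
})

test_that("network collapsing groups by (cell type, target) and conserves sizes", {
  recs <- dplyr::bind_rows(
    dataset_record("a", "asm1", "RNA-seq", "heart"),
    dataset_record("b", "asm1", "RNA-seq", "heart"),
    dataset_record("c", "asm1", "RNA-seq", "heart"),
    dataset_record("d", "asm1", "RNA-seq", "brain")
  )
  edges <- compare_all(recs, toy_config)
  net <- build_network(edges, recs)
  expect_equal(nrow(net$nodes), 2)
  heart_node <- net$nodes[net$nodes$cell_type == "heart", ]
  expect_equal(heart_node$size, 3)
  expect_setequal(heart_node$members[[1]], c("a", "b", "c"))
  expect_equal(sum(net$nodes$size), nrow(recs))
  # no inter-group edge here (heart vs brain dissimilar)
  expect_equal(nrow(net$edges), 0)

  expect_error(build_network(edges, recs[1:2, ]),
               class = "covnet_validation_error")
})

test_that("collapsed node sizes sum to the dataset count on random fixtures", {
  set.seed(41)
  for (trial in 1:300) {
    n <- sample(2:12, 1)
    recs <- tibble(
      dataset_id = sprintf("d%02d", 1:n),
      experiment_id = sprintf("d%02d", 1:n),
      assembly = "asm1", experiment_type = "RNA-seq",
      cell_type = sample(c("heart", "brain", "neuron"), n, replace = TRUE),
      target = sample(c(NA, "H3K4me3"), n, replace = TRUE),
      owner = "u", public = TRUE)
    cmb <- combn(n, 2)
    keep <- runif(ncol(cmb)) < 0.3
    edges <- tibble(dataset_id_a = recs$dataset_id[cmb[1, keep]],
                    dataset_id_b = recs$dataset_id[cmb[2, keep]],
                    by_primary = runif(sum(keep)) < 0.5,
                    by_metadata = TRUE)
    net <- build_network(edges, recs)
    expect_equal(sum(net$nodes$size), n)
    expect_false(anyDuplicated(net$nodes$group) > 0)
  }
})

test_that("force-directed layout is seeded, centered and clusters cliques", {
  # single node sits at the origin
  one <- build_network(
    tibble(dataset_id_a = character(), dataset_id_b = character(),
           by_primary = logical(), by_metadata = logical()),
    dataset_record("a", "asm1", "RNA-seq", "heart"))
  l1 <- layout_network(one, seed = 1)
  expect_equal(c(l1$nodes$x, l1$nodes$y), c(0, 0))

  # two cliques of distinct (cell type, target) groups joined by one edge
  recs <- dplyr::bind_rows(lapply(1:10, function(i) {
    dataset_record(sprintf("d%02d", i), "asm1", "RNA-seq",
                   sprintf("ct%02d", i))
  }))
  ids <- recs$dataset_id
  clique <- function(members) {
    cmb <- combn(members, 2)
    tibble(dataset_id_a = cmb[1, ], dataset_id_b = cmb[2, ],
           by_primary = FALSE, by_metadata = TRUE)
  }
  edges <- dplyr::bind_rows(clique(ids[1:5]), clique(ids[6:10]),
                            tibble(dataset_id_a = ids[5],
                                   dataset_id_b = ids[6],
                                   by_primary = FALSE, by_metadata = TRUE))
  net <- build_network(edges, recs)
  la <- layout_network(net, seed = 7)
  lb <- layout_network(net, seed = 7)
  expect_equal(la$nodes$x, lb$nodes$x)   # deterministic under the seed
  expect_true(all(is.finite(c(la$nodes$x, la$nodes$y))))

  xy <- as.matrix(la$nodes[, c("x", "y")])
  grp <- ifelse(la$nodes$group %in% covnet:::group_key(
    recs$cell_type[1:5], recs$target[1:5]), 1, 2)
  D <- as.matrix(dist(xy))
  intra <- mean(D[grp == 1, grp == 1][upper.tri(D[grp == 1, grp == 1])])
  inter <- mean(D[grp == 1, grp == 2])
  expect_lt(intra, inter)
})

test_that("dendrograms merge identical profiles at height zero with one leaf per dataset", {
  set.seed(51)
  mat <- matrix(runif(60, 1, 100), nrow = 12,
                dimnames = list(sprintf("f%02d", 1:12),
                                sprintf("d%d", 1:5)))
  mat[, 5] <- mat[, 1]
  hc <- network_dendrogram(mat)
  expect_equal(length(hc$order), 5)
  expect_equal(min(hc$height), 0, tolerance = 1e-10)
  merged_first <- sort(-hc$merge[which.min(hc$height), ])
  expect_equal(merged_first, c(1, 5))
  expect_error(network_dendrogram(mat[, 1, drop = FALSE]),
               class = "covnet_validation_error")

  nw <- dendrogram_newick(hc)
  expect_match(nw, "^\\(.*\\);$")
  expect_true(all(grepl(paste(colnames(mat), collapse = "|"), nw)))
})

test_that("merge heights match a naive average-linkage oracle on 4 leaves", {
  set.seed(52)
  mat <- matrix(2^rnorm(40, 5, 2), nrow = 10,
                dimnames = list(sprintf("f%02d", 1:10),
                                c("w", "x", "y", "z")))
  hc <- network_dendrogram(mat)
  x <- log2(mat + 1)
  d <- 1 - cor(x)
  expect_equal(sort(hc$height), sort(avg_linkage_heights(as.dist(d))),
               tolerance = 1e-10)
})

test_that("dendrogram heights are non-decreasing along root paths (ultrametric order)", {
  co <- small_cohort(seed = 53, n = 30, n_features = 80)
  hc <- network_dendrogram(co$matrix)
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("PCA projection is consistent with the fit and centers the reference", {
  co <- small_cohort(seed = 61, n = 40, n_features = 100)
  fit <- fit_pca(co$matrix)
  proj <- project_pca(fit, co$matrix)
  expect_equal(proj$PC1, fit$scores$PC1, tolerance = 1e-8)
  expect_equal(proj$PC2, fit$scores$PC2, tolerance = 1e-8)
  # the mean reference profile projects to the origin
  mean_prof <- matrix(2^colMeans(t(log2(co$matrix + 1))) - 1, ncol = 1,
                      dimnames = list(rownames(co$matrix), "mean"))
  at0 <- project_pca(fit, mean_prof)
  expect_equal(unlist(at0[, c("PC1", "PC2")]), c(PC1 = 0, PC2 = 0),
               tolerance = 1e-6)
  expect_error(project_pca(fit, co$matrix[1:10, ]),
               class = "covnet_validation_error")
})

test_that("PC1 aligns with a planted dominant axis of variance", {
  set.seed(62)
  n <- 60; p <- 50
  axis_pos <- rnorm(n, sd = 40)               # dominant axis in log space
  loading <- rep(c(1, -1), length.out = p) / sqrt(p)
  logx <- 8 + outer(loading, axis_pos) + matrix(rnorm(p * n, sd = 0.3), p, n)
  mat <- 2^logx - 1
  mat[mat < 0] <- 0
  dimnames(mat) <- list(sprintf("f%02d", 1:p), sprintf("d%02d", 1:n))
  fit <- fit_pca(mat)
  expect_gte(abs(cor(fit$scores$PC1, axis_pos)), 0.99)
})

test_that("incremental comparison equals the full recompute restricted to the new dataset", {
  cfg <- toy_config
  set.seed(71)
  recs <- random_records(14, with_targets = TRUE,
                         experiment_type = "ChIP-seq")
  full <- compare_all(recs, cfg)
  for (id in sample(recs$dataset_id, 4)) {
    inc <- compare_new(id, recs, cfg)
    expected <- full[full$dataset_id_a == id | full$dataset_id_b == id, ]
    expect_equal(inc, expected, ignore_attr = TRUE)
  }
  expect_error(compare_new("nope", recs, cfg),
               class = "covnet_lookup_error")
})

test_that("network JSON export includes nodes, edges and coordinates", {
  recs <- dplyr::bind_rows(
    dataset_record("a", "asm1", "RNA-seq", "heart"),
    dataset_record("b", "asm1", "RNA-seq", "cardiomyocyte"))
  edges <- compare_all(recs, toy_config)
  net <- layout_network(build_network(edges, recs), seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(nrow(parsed$nodes), 2)
  expect_true(all(c("x", "y", "size") %in% names(parsed$nodes)))
  expect_equal(parsed$n_datasets, 2)
})

test_that("autoplot methods return ggplot objects", {
  co <- small_cohort(seed = 81, n = 20, n_features = 60)
  cfg <- comparison_config(cell_type = co$ontology)
  edges <- compare_all(co$records, cfg)
  net <- build_network(edges, co$records)
  expect_s3_class(autoplot(net), "ggplot")
  expect_s3_class(autoplot(fit_pca(co$matrix)), "ggplot")
})
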