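# The dataset similarity network: pairwise verdicts within each
# (assembly, experiment type) group, a collapsed force-directed graph, a
# hierarchical-clustering dendrogram and a fixed-reference PCA projection.

# Per-dataset metadata precomputation so pairwise comparison does not repeat
# fuzzy matching. The pair rule here must agree with metadata_similarity();
# an invariant test checks the two routes against each other.
precompute_metadata <- function(records, config) {
  map(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    cm <- fuzzy_match(rec$cell_type, config$cell_type, config$fuzzy_threshold)
    cell_key <- if (cm$matched) {
      key_parents(config$cell_type, cm$term_id)
    } else NULL
    tgt <- if (is.na(rec$target)) NULL else match_target(rec$target, config)
    is_tf <- !is.null(tgt) && tgt$ontology == "go" &&
      length(intersect(tgt$key, config$tf_classes)) > 0
    list(dataset_id = rec$dataset_id, has_target = !is.na(rec$target),
         cell_key = cell_key, target = tgt, is_tf = is_tf)
  })
}

pair_metadata_similar <- function(a, b, config) {
  if (is.null(a$cell_key) || is.null(b$cell_key)) return(FALSE)
  if (length(intersect(a$cell_key, b$cell_key)) == 0) return(FALSE)
  if (!a$has_target && !b$has_target) return(TRUE)
  if (xor(a$has_target, b$has_target)) return(FALSE)
  if (is.null(a$target) || is.null(b$target)) return(FALSE)
  shared <- intersect(a$target$key, b$target$key)
  if (length(shared) == 0) return(FALSE)
  if (a$is_tf && b$is_tf) {
    return(has_interaction(config$interactions, a$target$term_name,
                           b$target$term_name, config$interaction_cutoff))
  }
  TRUE
}

model_for <- function(models, assembly, experiment_type, field) {
  for (m in models) {
    if (!inherits(m, "coverage_classifier")) next
    if (!identical(m$field, field)) next
    if (!is.na(m$assembly) && !identical(m$assembly, assembly)) next
    if (!is.na(m$experiment_type) &&
        !identical(m$experiment_type, experiment_type)) next
    return(m)
  }
  NULL
}

# Predicted class sets per dataset for one group; NULL when no model applies.
group_predictions <- function(ids, mat, models, assembly, experiment_type,
                              field) {
  model <- model_for(models, assembly, experiment_type, field)
  if (is.null(model) || is.null(mat)) return(NULL)
  present <- intersect(ids, colnames(mat))
  if (length(present) == 0) return(NULL)
  preds <- predict_classes(model, mat[, present, drop = FALSE])
  predicted_sets(preds)
}

compare_pairs <- function(pairs, prep, cell_sets, target_sets, config,
                          target_applicable) {
  by_meta <- map_lgl(seq_len(nrow(pairs)), function(k) {
    pair_metadata_similar(prep[[pairs$ia[k]]], prep[[pairs$ib[k]]], config)
  })
  by_prim <- map_lgl(seq_len(nrow(pairs)), function(k) {
    a <- prep[[pairs$ia[k]]]$dataset_id
    b <- prep[[pairs$ib[k]]]$dataset_id
    if (is.null(cell_sets) || is.null(cell_sets[[a]]) ||
        is.null(cell_sets[[b]])) {
      return(FALSE)
    }
    if (target_applicable) {
      if (is.null(target_sets) || is.null(target_sets[[a]]) ||
          is.null(target_sets[[b]])) {
        return(FALSE)
      }
      primary_similarity(cell_sets[[a]], cell_sets[[b]],
                         target_sets[[a]], target_sets[[b]])
    } else {
      primary_similarity(cell_sets[[a]], cell_sets[[b]])
    }
  })
  tibble(
    dataset_id_a = map_chr(pairs$ia, ~ prep[[.x]]$dataset_id),
    dataset_id_b = map_chr(pairs$ib, ~ prep[[.x]]$dataset_id),
    by_primary = by_prim, by_metadata = by_meta
  )
}

empty_edges <- function() {
  tibble(dataset_id_a = character(), dataset_id_b = character(),
         by_primary = logical(), by_metadata = logical())
}

normalize_edges <- function(edges) {
  if (nrow(edges) == 0) return(empty_edges())
  edges |>
    mutate(a = pmin(.data$dataset_id_a, .data$dataset_id_b),
           b = pmax(.data$dataset_id_a, .data$dataset_id_b)) |>
    select(dataset_id_a = "a", dataset_id_b = "b",
           "by_primary", "by_metadata") |>
    filter(.data$dataset_id_a != .data$dataset_id_b,
           .data$by_primary | .data$by_metadata) |>
    arrange(.data$dataset_id_a, .data$dataset_id_b)
}

#' Pairwise dataset comparison
#'
#' Every unordered pair of datasets within the same (assembly, experiment
#' type) group is compared by annotated metadata and — where a profile matrix
#' and trained models are available — by primary data. An edge is emitted when
#' either comparison declares similarity; the two flags are set
#' independently. Pairs from different groups are never compared. The target
#' field participates only in groups where any record annotates a target.
#'
#' @param records Tibble of [dataset_record()] rows.
#' @param config A [comparison_config()].
#' @param mat Optional TPM matrix (rows = features, columns = dataset ids).
#' @param models Optional list of [train_classifier()] models (cell_type and,
#'   where applicable, target fields).
#' @return Tibble of similarity edges: `dataset_id_a` < `dataset_id_b`,
#'   `by_primary`, `by_metadata`.
#' @export
compare_all <- function(records, config, mat = NULL, models = NULL) {
  groups <- split(seq_len(nrow(records)),
                  paste(records$assembly, records$experiment_type, sep = "\r"))
  out <- map(groups, function(idx) {
    if (length(idx) < 2) return(NULL)
    grp <- records[idx, ]
    if (!is.null(mat)) {
      missing_prof <- setdiff(grp$dataset_id, colnames(mat))
      if (length(missing_prof) > 0) {
        warn(sprintf("no profile for dataset(s) %s; metadata-only comparison",
                     paste(head(missing_prof, 5), collapse = ", ")))
      }
    }
    prep <- precompute_metadata(grp, config)
    target_applicable <- any(!is.na(grp$target))
    cell_sets <- group_predictions(grp$dataset_id, mat, models,
                                   grp$assembly[1], grp$experiment_type[1],
                                   "cell_type")
    target_sets <- if (target_applicable) {
      group_predictions(grp$dataset_id, mat, models,
                        grp$assembly[1], grp$experiment_type[1], "target")
    } else NULL
    cmb <- utils::combn(length(idx), 2)
    pairs <- tibble(ia = cmb[1, ], ib = cmb[2, ])
    compare_pairs(pairs, prep, cell_sets, target_sets, config,
                  target_applicable)
  })
  normalize_edges(bind_rows(out))
}

#' Incrementally compare one new dataset
#'
#' Computes only the edges incident to `new_id` (against same-group
#' datasets), mirroring the fast integration path; the result is identical to
#' the corresponding rows of a full [compare_all()] recompute.
#'
#' @param new_id Dataset id present in `records`.
#' @inheritParams compare_all
#' @return Tibble of similarity edges incident to `new_id`.
#' @export
compare_new <- function(new_id, records, config, mat = NULL, models = NULL) {
  i <- which(records$dataset_id == new_id)
  if (length(i) != 1) abort_lookup("dataset '%s' not found in records", new_id)
  grp_idx <- which(records$assembly == records$assembly[i] &
                     records$experiment_type == records$experiment_type[i])
  grp <- records[grp_idx, ]
  prep <- precompute_metadata(grp, config)
  target_applicable <- any(!is.na(grp$target))
  cell_sets <- group_predictions(grp$dataset_id, mat, models,
                                 grp$assembly[1], grp$experiment_type[1],
                                 "cell_type")
  target_sets <- if (target_applicable) {
    group_predictions(grp$dataset_id, mat, models,
                      grp$assembly[1], grp$experiment_type[1], "target")
  } else NULL
  pos <- which(grp$dataset_id == new_id)
  others <- setdiff(seq_len(nrow(grp)), pos)
  if (length(others) == 0) return(empty_edges())
  pairs <- tibble(ia = rep(pos, length(others)), ib = others)
  normalize_edges(compare_pairs(pairs, prep, cell_sets, target_sets, config,
                                target_applicable))
}

group_key <- function(cell_type, target) {
  paste(cell_type, dplyr::coalesce(target, ""), sep = " | ")
}

#' Collapse similarity edges into the dataset network graph
#'
#' Datasets sharing the same annotated (cell type, target) pair collapse into
#' one node whose size is the member count; an edge links two nodes when any
#' member pair is similar, with the source flags aggregated by "any".
#'
#' @param edges Edge tibble from [compare_all()].
#' @param records Tibble of [dataset_record()] rows covering all edge
#'   endpoints.
#' @return A `dataset_network`: `nodes` (group, cell_type, target, size,
#'   members) and `edges` (group_a, group_b, by_primary, by_metadata).
#' @export
build_network <- function(edges, records) {
  missing_rec <- setdiff(c(edges$dataset_id_a, edges$dataset_id_b),
                         records$dataset_id)
  if (length(missing_rec) > 0) {
    abort_validation("edge endpoint '%s' has no record", missing_rec[1])
  }
  nodes <- records |>
    mutate(group = group_key(.data$cell_type, .data$target)) |>
    group_by(.data$group) |>
    summarise(cell_type = .data$cell_type[1],
              target = .data$target[1],
              size = dplyr::n(),
              members = list(.data$dataset_id),
              .groups = "drop")
  grp_of <- setNames(group_key(records$cell_type, records$target),
                     records$dataset_id)
  gedges <- edges |>
    mutate(group_a = pmin(grp_of[.data$dataset_id_a],
                          grp_of[.data$dataset_id_b]),
           group_b = pmax(grp_of[.data$dataset_id_a],
                          grp_of[.data$dataset_id_b])) |>
    filter(.data$group_a != .data$group_b) |>
    group_by(.data$group_a, .data$group_b) |>
    summarise(by_primary = any(.data$by_primary),
              by_metadata = any(.data$by_metadata),
              .groups = "drop")
  structure(list(nodes = nodes, edges = gedges,
                 n_datasets = nrow(records)),
            class = "dataset_network")
}

#' @export
print.dataset_network <- function(x, ...) {
  cat(sprintf("<dataset_network: %d nodes (%d datasets), %d edges%s>\n",
              nrow(x$nodes), x$n_datasets, nrow(x$edges),
              if ("x" %in% names(x$nodes)) ", laid out" else ""))
  invisible(x)
}

#' Force-directed layout of the collapsed network
#'
#' Fruchterman-Reingold layout (via igraph) so connected nodes are pulled
#' together; deterministic for a fixed seed. Coordinates are centered, so a
#' single isolated node sits at the origin.
#'
#' @param network A [build_network()] result.
#' @param seed Integer seed.
#' @param iterations Layout iterations (default 200).
#' @return The network with `x`, `y` columns added to `nodes`.
#' @export
layout_network <- function(network, seed = 1L, iterations = 200) {
  if (nrow(network$nodes) == 0) abort_validation("network has no nodes")
  g <- igraph::graph_from_data_frame(
    network$edges[, c("group_a", "group_b")],
    directed = FALSE,
    vertices = network$nodes["group"]
  )
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = iterations)
  xy <- sweep(xy, 2, colMeans(xy), "-")
  ord <- match(network$nodes$group, igraph::V(g)$name)
  network$nodes$x <- xy[ord, 1]
  network$nodes$y <- xy[ord, 2]
  network
}

#' Export the network as node-link JSON
#'
#' @param network A laid-out (or plain) `dataset_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(
    list(nodes = network$nodes, edges = network$edges,
         n_datasets = network$n_datasets),
    path, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot the collapsed dataset network
#'
#' @param object A `dataset_network` (laid out with [layout_network()];
#'   laid out on the fly otherwise).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dataset_network <- function(object, ...) {
  if (!"x" %in% names(object$nodes)) object <- layout_network(object)
  nd <- object$nodes
  eg <- object$edges |>
    left_join(nd[c("group", "x", "y")], by = c(group_a = "group")) |>
    rename(xa = "x", ya = "y") |>
    left_join(nd[c("group", "x", "y")], by = c(group_b = "group")) |>
    rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = eg,
      ggplot2::aes(x = .data$xa, y = .data$ya,
                   xend = .data$xb, yend = .data$yb),
      color = "grey70") +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                   color = .data$cell_type)) +
    ggplot2::labs(x = NULL, y = NULL, size = "datasets",
                  color = "cell type") +
    ggplot2::theme_minimal()
}

#' Hierarchical clustering of dataset profiles
#'
#' Average-linkage agglomeration on `1 - Pearson correlation` distances over
#' `log2(TPM + 1)` profiles (optionally restricted to a model's selected
#' features). Identical profiles merge at height 0.
#'
#' @param mat TPM matrix, rows = features, columns = datasets (>= 2).
#' @param feature_indices Optional feature rows to restrict to.
#' @return An [stats::hclust] tree over the datasets.
#' @export
network_dendrogram <- function(mat, feature_indices = NULL) {
  if (ncol(mat) < 2) abort_validation("dendrogram needs >= 2 datasets")
  if (!is.null(feature_indices)) mat <- mat[feature_indices, , drop = FALSE]
  x <- log2(mat + 1)
  keep <- apply(x, 1, stats::sd) > 0
  cc <- suppressWarnings(cor(x[keep, , drop = FALSE]))
  cc[is.na(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  d[d < 0] <- 0
  hclust(d, method = "average")
}

#' Export a dendrogram as a Newick string or file
#'
#' @param hc An [stats::hclust] tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the 'ape' package")
  }
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    readr::write_lines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Fit a PCA reference model on a dataset cohort
#'
#' The reference cohort (all same-assembly, same-experiment-type datasets)
#' fixes the centering and component loadings; new datasets are projected
#' into this fixed space and never trigger a refit.
#'
#' @param mat TPM matrix, rows = features, columns = datasets (>= 2 of each).
#' @param feature_indices Optional feature rows to restrict to.
#' @param n_components Components to retain (default 2).
#' @return A `coverage_pca` object with the reference scores in `$scores`.
#' @export
fit_pca <- function(mat, feature_indices = NULL, n_components = 2) {
  if (ncol(mat) < 2 || nrow(mat) < 2) {
    abort_validation("PCA needs >= 2 datasets and >= 2 features")
  }
  if (!is.null(feature_indices)) mat <- mat[feature_indices, , drop = FALSE]
  x <- t(log2(mat + 1))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores$dataset_id <- colnames(mat)
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev,
                 feature_indices = feature_indices,
                 scores = scores[, c("dataset_id",
                                     paste0("PC", seq_len(k)))]),
            class = "coverage_pca")
}

#' Project datasets into a fitted PCA space
#'
#' @param fit A [fit_pca()] model.
#' @param mat TPM matrix over the same feature set (rows = features).
#' @return Tibble `dataset_id`, `PC1`, `PC2`, ...
#' @export
project_pca <- function(fit, mat) {
  if (inherits(mat, "dataset_profile")) {
    mat <- matrix(mat$tpm, ncol = 1,
                  dimnames = list(mat$name, attr(mat, "dataset_id")))
  }
  if (!is.null(fit$feature_indices)) {
    mat <- mat[fit$feature_indices, , drop = FALSE]
  }
  x <- t(log2(mat + 1))
  if (ncol(x) != length(fit$center)) {
    abort_validation("profile has %d features but the PCA expects %d",
                     ncol(x), length(fit$center))
  }
  proj <- sweep(x, 2, fit$center, "-") %*% fit$rotation
  out <- as_tibble(proj)
  out$dataset_id <- colnames(mat) %||% paste0("dataset_", seq_len(nrow(proj)))
  out[, c("dataset_id", colnames(fit$rotation))]
}

#' @export
print.coverage_pca <- function(x, ...) {
  cat(sprintf("<coverage_pca: %d reference datasets, %d components>\n",
              nrow(x$scores), ncol(x$rotation)))
  invisible(x)
}

#' Plot a PCA projection with the reference cohort
#'
#' @param object A `coverage_pca`.
#' @param new_scores Optional [project_pca()] tibble drawn on top.
#' @param color_by Optional named vector dataset_id -> group used for color.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_pca <- function(object, new_scores = NULL, color_by = NULL,
                                  ...) {
  sc <- object$scores
  sc$group <- if (is.null(color_by)) "reference" else
    unname(color_by[sc$dataset_id])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                        color = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::theme_minimal() +
    ggplot2::labs(color = NULL)
  if (!is.null(new_scores)) {
    p <- p + ggplot2::geom_point(
      data = new_scores,
      ggplot2::aes(x = .data$PC1, y = .data$PC2),
      inherit.aes = FALSE, shape = 17, size = 3, color = "black")
  }
  p
}
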