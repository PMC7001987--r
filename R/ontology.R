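# Ontology handling and categorical metadata comparison.
#
# Terms are compared through designated "key parent classes": manually chosen
# ontology classes (e.g. organ-system-level anatomy classes) whose descendants
# are considered mutually similar. Transcription-factor target pairs must
# additionally show interaction evidence in a STRING-like table.

#' Construct an ontology
#'
#' @param terms Tibble with columns `id`, `name` and optionally a `synonyms`
#'   list-column.
#' @param is_a Tibble of directed edges `child`, `parent` (must be acyclic).
#' @param key_classes Character vector of term ids designated as key parent
#'   classes.
#' @return An `ontology` object.
#' @export
ontology <- function(terms, is_a, key_classes = character()) {
  terms <- as_tibble(terms)
  if (!"synonyms" %in% names(terms)) {
    terms$synonyms <- rep(list(character()), nrow(terms))
  }
  is_a <- as_tibble(is_a)
  if (anyDuplicated(terms$id)) abort_validation("duplicate term ids")
  unknown <- setdiff(c(is_a$child, is_a$parent), terms$id)
  if (length(unknown) > 0) {
    abort_validation("is_a edge references unknown term '%s'", unknown[1])
  }
  if (nrow(is_a) > 0) {
    g <- igraph::graph_from_data_frame(is_a[c("child", "parent")],
                                       vertices = terms["id"])
    if (!igraph::is_dag(g)) {
      abort_validation("is_a graph contains a cycle")
    }
  }
  missing_key <- setdiff(key_classes, terms$id)
  if (length(missing_key) > 0) {
    abort_validation("key class '%s' is not a term in the ontology",
                     missing_key[1])
  }
  parents <- split(is_a$parent, factor(is_a$child, levels = terms$id))
  out <- structure(
    list(terms = terms, is_a = is_a, parents = parents,
         key_classes = unique(key_classes)),
    class = "ontology"
  )
  out$vocab <- ontology_vocabulary(out)  # cached for fuzzy matching
  out
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d terms, %d is_a edges, %d key classes>\n",
              nrow(x$terms), nrow(x$is_a), length(x$key_classes)))
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas (id, name, synonym, is_a); other stanza types and
#' tags are ignored. The `is_a` graph must be acyclic and every requested key
#' class must exist.
#'
#' @param path Path to an `.obo` file.
#' @param key_classes Term ids to designate as key parent classes.
#' @return An [ontology()].
#' @export
read_obo <- function(path, key_classes = character()) {
  if (!file.exists(path)) abort_io("cannot read OBO file '%s'", path)
  lines <- readr::read_lines(path)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) abort_parse("no [Term] stanzas in '%s'", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  terms <- list(); edges <- list()
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    if (is.na(id)) abort_parse("[Term] stanza near line %d lacks an id", s)
    syn_lines <- grep("^synonym:", block, value = TRUE)
    syns <- sub('^synonym: *"([^"]*)".*$', "\\1", syn_lines)
    isa_lines <- grep("^is_a:", block, value = TRUE)
    pars <- sub("^is_a: *([^ !]+).*$", "\\1", isa_lines)
    terms[[length(terms) + 1L]] <- tibble(
      id = trimws(id), name = trimws(nm), synonyms = list(syns)
    )
    if (length(pars) > 0) {
      edges[[length(edges) + 1L]] <- tibble(child = trimws(id),
                                            parent = trimws(pars))
    }
  }
  ontology(bind_rows(terms),
           if (length(edges)) bind_rows(edges)
           else tibble(child = character(), parent = character()),
           key_classes)
}

#' Write an ontology as OBO 1.2
#'
#' @param onto An [ontology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(onto$terms))) {
    row <- onto$terms[i, ]
    out <- c(out, "[Term]", sprintf("id: %s", row$id),
             sprintf("name: %s", row$name))
    for (syn in row$synonyms[[1]]) {
      out <- c(out, sprintf('synonym: "%s" EXACT []', syn))
    }
    for (p in onto$parents[[row$id]]) {
      out <- c(out, sprintf("is_a: %s", p))
    }
    out <- c(out, "")
  }
  readr::write_lines(out, path)
  invisible(path)
}

check_term <- function(onto, term_id) {
  if (!term_id %in% onto$terms$id) {
    abort_lookup("term '%s' is not in the ontology", term_id)
  }
}

#' Transitive ancestors of a term
#'
#' Closure over `is_a` edges, excluding the term itself.
#'
#' @param onto An [ontology()].
#' @param term_id A term id present in the ontology.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ontology_ancestors <- function(onto, term_id) {
  check_term(onto, term_id)
  seen <- character()
  frontier <- onto$parents[[term_id]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(onto$parents[frontier], use.names = FALSE))
  }
  sort(unique(seen))
}

#' Key parent classes of a term
#'
#' The designated key classes among the term itself and its ancestors. A term
#' that is itself a key class reports itself, so identically annotated
#' datasets always share a key parent.
#'
#' @inheritParams ontology_ancestors
#' @return Character vector of key-class ids.
#' @export
key_parents <- function(onto, term_id) {
  check_term(onto, term_id)
  intersect(c(term_id, ontology_ancestors(onto, term_id)), onto$key_classes)
}

ontology_vocabulary <- function(onto) {
  syn <- tidyr::unnest(onto$terms[c("id", "synonyms")],
                       "synonyms", keep_empty = FALSE)
  bind_rows(
    tibble(id = onto$terms$id, label = onto$terms$name),
    tibble(id = syn$id, label = syn$synonyms)
  ) |> filter(!is.na(.data$label), nzchar(.data$label))
}

#' Fuzzy-match a free-text term into an ontology
#'
#' Case-insensitive exact matches against term names and synonyms
#' short-circuit at score 100. Otherwise the normalized Levenshtein
#' similarity `100 * (1 - d / max(nchar))` is computed against the whole
#' vocabulary and the best-scoring term at or above `threshold` wins; ties go
#' to the lexicographically smallest term id. This mitigates clerical errors
#' in user-annotated metadata.
#'
#' @param query Free-text term (non-empty).
#' @param onto An [ontology()].
#' @param threshold Minimum score in `[0, 100]` (default 90).
#' @return One-row tibble: `query`, `term_id`, `term_name`, `score`,
#'   `matched`. `term_id` is `NA` when nothing reaches the threshold.
#' @export
fuzzy_match <- function(query, onto, threshold = 90) {
  if (length(query) != 1 || is.na(query) || !nzchar(trimws(query))) {
    abort_validation("query must be a non-empty string")
  }
  vocab <- onto$vocab %||% ontology_vocabulary(onto)
  q <- tolower(trimws(query))
  lab <- tolower(vocab$label)
  no_match <- tibble(query = query, term_id = NA_character_,
                     term_name = NA_character_, score = NA_real_,
                     matched = FALSE)
  exact <- vocab$id[lab == q]
  if (length(exact) > 0) {
    id <- sort(exact)[1]
    return(tibble(query = query, term_id = id,
                  term_name = onto$terms$name[onto$terms$id == id],
                  score = 100, matched = TRUE))
  }
  d <- as.numeric(adist(q, lab))
  score <- 100 * (1 - d / pmax(nchar(q), nchar(lab)))
  ok <- score >= threshold
  if (!any(ok)) return(no_match)
  best <- max(score[ok])
  id <- sort(vocab$id[ok & score == best])[1]
  tibble(query = query, term_id = id,
         term_name = onto$terms$name[onto$terms$id == id],
         score = best, matched = TRUE)
}

#' Read a protein-protein interaction table
#'
#' Three-column TSV (`protein_a`, `protein_b`, `score` in `[0, 1]`), treated
#' as an undirected edge set.
#'
#' @param path Path to the TSV (header optional, detected from the first row).
#' @return An `interaction_table` tibble.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) abort_io("cannot read interaction table '%s'", path)
  tb <- readr::read_tsv(path, col_names = c("protein_a", "protein_b", "score"),
                        show_col_types = FALSE)
  if (nrow(tb) > 0 && is.na(suppressWarnings(as.numeric(tb$score[1])))) {
    tb <- tb[-1, ]  # header row
  }
  tb$score <- as.numeric(tb$score)
  interaction_table(tb)
}

#' @rdname read_interactions
#' @param edges Tibble with columns `protein_a`, `protein_b`, `score`.
#' @export
interaction_table <- function(edges) {
  edges <- as_tibble(edges)[c("protein_a", "protein_b", "score")]
  if (nrow(edges) > 0 && (any(edges$score < 0) || any(edges$score > 1))) {
    abort_validation("interaction scores must lie in [0, 1]")
  }
  structure(edges, class = c("interaction_table", class(edges)))
}

#' Look up interaction evidence between two proteins
#'
#' @param interactions An [interaction_table()].
#' @param a,b Protein names (case-insensitive, order-insensitive).
#' @param cutoff Minimum confidence score (default 0.4, the usual
#'   medium-confidence convention).
#' @return `TRUE` if an edge with `score >= cutoff` links `a` and `b`.
#' @export
has_interaction <- function(interactions, a, b, cutoff = 0.4) {
  pa <- tolower(interactions$protein_a)
  pb <- tolower(interactions$protein_b)
  a <- tolower(a); b <- tolower(b)
  hit <- (pa == a & pb == b) | (pa == b & pb == a)
  any(hit & interactions$score >= cutoff)
}

#' Bundle the ontologies and rules used for metadata comparison
#'
#' @param cell_type Anatomy-like [ontology()] for cell/tissue terms, with
#'   organ-system-level key classes.
#' @param target_go GO-like [ontology()] for protein targets, whose key
#'   classes include the transcription-factor-defining classes.
#' @param target_histone Histone-modification [ontology()] grouping marks by
#'   genomic location of enrichment.
#' @param tf_classes Key-class ids in `target_go` that define a transcription
#'   factor (defaults to all of `target_go`'s key classes).
#' @param interactions An [interaction_table()] (may be empty).
#' @param fuzzy_threshold Score threshold for [fuzzy_match()].
#' @param interaction_cutoff Minimum STRING-style confidence for TF pairs.
#' @return A `comparison_config` list.
#' @export
comparison_config <- function(cell_type, target_go = NULL,
                              target_histone = NULL,
                              tf_classes = NULL,
                              interactions = interaction_table(
                                tibble(protein_a = character(),
                                       protein_b = character(),
                                       score = numeric())),
                              fuzzy_threshold = 90,
                              interaction_cutoff = 0.4) {
  if (is.null(tf_classes) && !is.null(target_go)) {
    tf_classes <- target_go$key_classes
  }
  structure(list(cell_type = cell_type, target_go = target_go,
                 target_histone = target_histone,
                 tf_classes = tf_classes %||% character(),
                 interactions = interactions,
                 fuzzy_threshold = fuzzy_threshold,
                 interaction_cutoff = interaction_cutoff),
            class = "comparison_config")
}

# Match a target term against the histone and GO ontologies; returns a list
# with the matched ontology ("histone"/"go"), matched id and its key parents.
match_target <- function(term, config) {
  for (slot in c("target_histone", "target_go")) {
    onto <- config[[slot]]
    if (is.null(onto)) next
    m <- fuzzy_match(term, onto, config$fuzzy_threshold)
    if (m$matched) {
      return(list(ontology = if (slot == "target_histone") "histone" else "go",
                  term_id = m$term_id, term_name = m$term_name,
                  key = key_parents(onto, m$term_id)))
    }
  }
  NULL
}

#' Is a target term a transcription factor?
#'
#' A target counts as a transcription factor when it matches into the GO-like
#' ontology and one of its key parents is a configured TF-defining class.
#' Unmatched terms are treated as non-TF with a warning.
#'
#' @param term Free-text target term.
#' @param config A [comparison_config()].
#' @return Logical flag.
#' @export
is_transcription_factor <- function(term, config) {
  if (is.null(config$target_go) || length(config$tf_classes) == 0) {
    return(FALSE)
  }
  m <- fuzzy_match(term, config$target_go, config$fuzzy_threshold)
  if (!m$matched) {
    warn(sprintf("target '%s' not matched in the GO-like ontology; treated as non-TF",
                 term))
    return(FALSE)
  }
  length(intersect(key_parents(config$target_go, m$term_id),
                   config$tf_classes)) > 0
}

#' Are two protein targets similar?
#'
#' Non-TF pairs are similar when they share a key parent class in the histone
#' or GO-like ontology. Two transcription factors must additionally show
#' interaction evidence at or above the configured confidence cutoff.
#'
#' @param target_a,target_b Free-text target terms.
#' @param config A [comparison_config()].
#' @return A list: `similar`, `shared_classes`, `tf_checked`.
#' @export
targets_similar <- function(target_a, target_b, config) {
  ma <- match_target(target_a, config)
  mb <- match_target(target_b, config)
  if (is.null(ma) || is.null(mb)) {
    unmatched <- c(target_a, target_b)[c(is.null(ma), is.null(mb))]
    warn(sprintf("target term(s) not matched to any ontology: %s",
                 paste(unique(unmatched), collapse = ", ")))
    return(list(similar = FALSE, shared_classes = character(),
                tf_checked = FALSE))
  }
  shared <- intersect(ma$key, mb$key)
  both_tf <- ma$ontology == "go" && mb$ontology == "go" &&
    length(intersect(ma$key, config$tf_classes)) > 0 &&
    length(intersect(mb$key, config$tf_classes)) > 0
  if (both_tf) {
    ok <- length(shared) > 0 &&
      has_interaction(config$interactions, ma$term_name, mb$term_name,
                      config$interaction_cutoff)
    return(list(similar = ok, shared_classes = shared, tf_checked = TRUE))
  }
  list(similar = length(shared) > 0, shared_classes = shared,
       tf_checked = FALSE)
}

#' Categorical metadata similarity between two dataset records
#'
#' Two datasets (already scoped to the same assembly and experiment type) are
#' metadata-similar when their cell-type terms share an organ-system-level key
#' parent class and, where the assay has a target, the targets are similar
#' under [targets_similar()]. Unmatched terms degrade to "not similar" with a
#' warning so one bad record cannot block a batch comparison.
#'
#' @param rec_a,rec_b One-row tibbles from [dataset_record()].
#' @param config A [comparison_config()].
#' @return One-row tibble: `similar`, `cell_type_shared` (list-column of
#'   shared key-class ids), `target_shared` (list-column; `NA` when targets
#'   are not applicable), `tf_interaction_checked`.
#' @export
metadata_similarity <- function(rec_a, rec_b, config) {
  ma <- fuzzy_match(rec_a$cell_type, config$cell_type, config$fuzzy_threshold)
  mb <- fuzzy_match(rec_b$cell_type, config$cell_type, config$fuzzy_threshold)
  if (!ma$matched || !mb$matched) {
    unmatched <- c(rec_a$cell_type, rec_b$cell_type)[!c(ma$matched, mb$matched)]
    warn(sprintf("cell type(s) not matched to the ontology: %s",
                 paste(unique(unmatched), collapse = ", ")))
    cell_shared <- character()
  } else {
    cell_shared <- intersect(key_parents(config$cell_type, ma$term_id),
                             key_parents(config$cell_type, mb$term_id))
  }
  a_has <- !is.na(rec_a$target); b_has <- !is.na(rec_b$target)
  if (!a_has && !b_has) {
    tgt <- list(similar = TRUE, shared_classes = NA, tf_checked = FALSE)
    target_applicable <- FALSE
  } else if (xor(a_has, b_has)) {
    tgt <- list(similar = FALSE, shared_classes = character(),
                tf_checked = FALSE)
    target_applicable <- TRUE
  } else {
    tgt <- targets_similar(rec_a$target, rec_b$target, config)
    target_applicable <- TRUE
  }
  tibble(
    similar = length(cell_shared) > 0 && tgt$similar,
    cell_type_shared = list(cell_shared),
    target_shared = list(if (target_applicable) tgt$shared_classes else NA),
    tf_interaction_checked = tgt$tf_checked
  )
}
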