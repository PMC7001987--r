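# Social graph and dataset recommendations.
#
# Recommendations come from three sources: datasets similar to what the user
# owns, datasets similar to what the user favorited, and datasets owned by
# users the user follows. Private datasets of other users are never exposed,
# but a user's own private data still seeds similarity-based recommendations.

#' Construct a social graph
#'
#' @param users Tibble `user_id`, `public` (logical).
#' @param owns Tibble `user_id`, `dataset_id` (ownership; may be empty).
#' @param favorites Tibble `user_id`, `dataset_id`.
#' @param follows Tibble `user_id`, `follows` (followed user id). Only public
#'   users may be followed.
#' @return A `social_graph` object.
#' @export
social_graph <- function(users,
                         owns = tibble(user_id = character(),
                                       dataset_id = character()),
                         favorites = tibble(user_id = character(),
                                            dataset_id = character()),
                         follows = tibble(user_id = character(),
                                          follows = character())) {
  users <- as_tibble(users)
  if (anyDuplicated(users$user_id)) abort_validation("duplicate user ids")
  g <- structure(list(users = users,
                      owns = distinct(as_tibble(owns)),
                      favorites = distinct(as_tibble(favorites)),
                      follows = distinct(as_tibble(follows))),
                 class = "social_graph")
  bad <- setdiff(g$follows$follows, users$user_id[users$public])
  if (length(bad) > 0) {
    abort("only public users may be followed",
          class = "covnet_permission_error")
  }
  g
}

#' @export
print.social_graph <- function(x, ...) {
  cat(sprintf(
    "<social_graph: %d users, %d ownerships, %d favorites, %d follows>\n",
    nrow(x$users), nrow(x$owns), nrow(x$favorites), nrow(x$follows)))
  invisible(x)
}

check_user <- function(graph, user) {
  if (!user %in% graph$users$user_id) {
    abort_lookup("unknown user '%s'", user)
  }
}

dataset_visible <- function(records, dataset, user) {
  rec <- records[records$dataset_id == dataset, ]
  if (nrow(rec) == 0) abort_lookup("unknown dataset '%s'", dataset)
  rec$public[1] || identical(rec$owner[1], user)
}

#' Favorite a dataset
#'
#' Idempotent set insertion; a user may favorite any dataset visible to them
#' (public, or their own private data).
#'
#' @param graph A [social_graph()].
#' @param user Acting user id.
#' @param dataset Dataset id.
#' @param records Tibble of [dataset_record()] rows (for visibility checks).
#' @return The updated graph.
#' @export
add_favorite <- function(graph, user, dataset, records) {
  check_user(graph, user)
  if (!dataset_visible(records, dataset, user)) {
    abort(sprintf("dataset '%s' is private and not owned by '%s'",
                  dataset, user),
          class = "covnet_permission_error")
  }
  graph$favorites <- distinct(bind_rows(
    graph$favorites, tibble(user_id = user, dataset_id = dataset)))
  graph
}

#' Follow another user
#'
#' Idempotent; only public accounts may be followed.
#'
#' @param graph A [social_graph()].
#' @param user Acting user id.
#' @param target_user User id to follow.
#' @return The updated graph.
#' @export
add_follow <- function(graph, user, target_user) {
  check_user(graph, user)
  check_user(graph, target_user)
  pub <- graph$users$public[graph$users$user_id == target_user]
  if (!pub) {
    abort(sprintf("user '%s' is private and may not be followed", target_user),
          class = "covnet_permission_error")
  }
  graph$follows <- distinct(bind_rows(
    graph$follows, tibble(user_id = user, follows = target_user)))
  graph
}

edge_neighbors <- function(edges, dataset_ids, filter) {
  if (nrow(edges) == 0 || length(dataset_ids) == 0) {
    return(tibble(dataset_id = character(), by_primary = logical(),
                  by_metadata = logical()))
  }
  if (filter == "primary") edges <- filter(edges, .data$by_primary)
  if (filter == "metadata") edges <- filter(edges, .data$by_metadata)
  fwd <- edges |>
    filter(.data$dataset_id_a %in% dataset_ids) |>
    select(dataset_id = "dataset_id_b", "by_primary", "by_metadata")
  rev <- edges |>
    filter(.data$dataset_id_b %in% dataset_ids) |>
    select(dataset_id = "dataset_id_a", "by_primary", "by_metadata")
  bind_rows(fwd, rev) |>
    group_by(.data$dataset_id) |>
    summarise(by_primary = any(.data$by_primary),
              by_metadata = any(.data$by_metadata), .groups = "drop")
}

#' Recommend datasets to a user
#'
#' The union of (i) datasets similar to the user's own datasets, (ii)
#' datasets similar to the user's favorites, and (iii) datasets owned by
#' followed users. The user's own and already-favorited datasets are
#' excluded, as is every private dataset the user does not own (a followed
#' user's private data is not recommended either). `filter` restricts
#' similarity-based reasons to edges carrying the requested source flag;
#' follow-based reasons are not similarity edges and pass through any filter.
#' Output is ordered by reason count (descending), then dataset id.
#'
#' @param graph A [social_graph()].
#' @param edges Similarity edges from [compare_all()].
#' @param records Tibble of [dataset_record()] rows.
#' @param user User id to recommend for.
#' @param filter `"all"` (default), `"primary"` or `"metadata"`.
#' @return Tibble `dataset_id`, `reasons` (list-column), `n_reasons`,
#'   `by_primary`, `by_metadata`.
#' @export
recommend <- function(graph, edges, records, user,
                      filter = c("all", "primary", "metadata")) {
  filter <- arg_match(filter)
  check_user(graph, user)
  owned <- graph$owns$dataset_id[graph$owns$user_id == user]
  faved <- graph$favorites$dataset_id[graph$favorites$user_id == user]
  followed <- graph$follows$follows[graph$follows$user_id == user]

  from_owned <- edge_neighbors(edges, owned, filter) |>
    mutate(reason = "similar_to_owned")
  from_fav <- edge_neighbors(edges, faved, filter) |>
    mutate(reason = "similar_to_favorite")
  from_follow <- graph$owns |>
    filter(.data$user_id %in% followed) |>
    select(dataset_id = "dataset_id") |>
    distinct() |>
    mutate(by_primary = FALSE, by_metadata = FALSE,
           reason = "from_followed_user")

  cand <- bind_rows(from_owned, from_fav, from_follow) |>
    filter(!.data$dataset_id %in% c(owned, faved))
  if (nrow(cand) == 0) {
    return(tibble(dataset_id = character(), reasons = list(),
                  n_reasons = integer(), by_primary = logical(),
                  by_metadata = logical()))
  }
  visible <- records |>
    filter(.data$public | .data$owner %in% user) |>
    pull("dataset_id")
  cand |>
    filter(.data$dataset_id %in% visible) |>
    group_by(.data$dataset_id) |>
    summarise(reasons = list(sort(unique(.data$reason))),
              n_reasons = length(unique(.data$reason)),
              by_primary = any(.data$by_primary),
              by_metadata = any(.data$by_metadata), .groups = "drop") |>
    arrange(desc(.data$n_reasons), .data$dataset_id)
}

#' Persist / load a social graph as JSON
#'
#' @param graph A [social_graph()].
#' @param path JSON path.
#' @return `path` invisibly; `read_social_graph()` returns the graph.
#' @export
write_social_graph <- function(graph, path) {
  jsonlite::write_json(unclass(graph), path, dataframe = "rows",
                       na = "null", auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_social_graph
#' @export
read_social_graph <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  empty <- function(x, cols) {
    if (is.null(x) || length(x) == 0) {
      as_tibble(setNames(rep(list(character()), length(cols)), cols))
    } else as_tibble(x)
  }
  social_graph(users = as_tibble(raw$users),
               owns = empty(raw$owns, c("user_id", "dataset_id")),
               favorites = empty(raw$favorites, c("user_id", "dataset_id")),
               follows = empty(raw$follows, c("user_id", "follows")))
}
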