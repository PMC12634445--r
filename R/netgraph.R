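#' Build the reciprocal (mutual-nomination) friendship graph
#'
#' An undirected edge connects two people only if each nominated the other;
#' one-way nominations carry no edge. Participants with no mutual ties are
#' kept as isolates, which is why the full participant roster must be passed
#' alongside the nomination edge list.
#'
#' @param nominations Tibble/data frame of directed nominations with columns
#'   `src`, `dst` (one row per nomination).
#' @param participants Character vector of all participant ids (defines the
#'   vertex set, including isolates).
#' @return An [igraph::igraph] undirected simple graph whose vertex names are
#'   the participant ids.
#' @examples
#' g <- build_reciprocal_graph(
#'   tibble::tibble(src = c("a", "b", "a"), dst = c("b", "a", "c")),
#'   participants = c("a", "b", "c")
#' )
#' igraph::ecount(g)  # only the mutual a-b tie survives
#' @export
build_reciprocal_graph <- function(nominations, participants) {
  participants <- as.character(participants)
  if (anyDuplicated(participants) > 0) abort("Duplicate participant ids.")
  nm <- as_tibble(nominations)
  if (!all(c("src", "dst") %in% names(nm))) {
    abort("`nominations` needs columns `src` and `dst`.")
  }
  if (any(nm$src == nm$dst)) abort("Self-nominations are not allowed.")
  unknown <- setdiff(c(nm$src, nm$dst), participants)
  if (length(unknown)) {
    abort(paste0("Nominations mention ids outside the roster: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  nm <- distinct(nm, .data$src, .data$dst)
  key_fwd <- paste(nm$src, nm$dst, sep = "\r")
  key_rev <- paste(nm$dst, nm$src, sep = "\r")
  mutual <- nm[key_fwd %in% key_rev & nm$src < nm$dst, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    mutual, directed = FALSE,
    vertices = data.frame(name = participants)
  )
  igraph::simplify(g)
}

#' Geodesic social distances for a subset of participants
#'
#' Shortest-path hop counts are computed on the full cohort graph (so paths
#' may run through non-imaged cohort members) and read out for all pairs of
#' the requested subset. Unreachable pairs get `Inf`.
#'
#' @param graph Reciprocal graph from [build_reciprocal_graph()].
#' @param subset Character vector of participant ids to read distances for;
#'   defaults to all vertices.
#' @return A tibble `dyad_i`, `dyad_j`, `distance` over the canonical dyads
#'   of `subset` (in the order given).
#' @export
geodesic_distances <- function(graph, subset = NULL) {
  all_ids <- igraph::V(graph)$name
  subset <- if (is.null(subset)) all_ids else as.character(subset)
  unknown <- setdiff(subset, all_ids)
  if (length(unknown)) {
    abort(paste0("Unknown participant id(s) in subset: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  d <- igraph::distances(graph, v = subset, to = subset)
  pairs <- dyad_pairs(subset)
  mutate(pairs, distance = d[cbind(.data$dyad_i, .data$dyad_j)])
}

#' Cap (recode) large social distances
#'
#' Finite distances above `cap` are recoded to `cap` (the study recoded
#' distance-4 dyads to distance 3). Unreachable pairs follow `unreachable`:
#' `"cap"` assigns them the cap value with a warning, `"exclude"` drops the
#' dyads with a warning.
#'
#' @param distances Tibble from [geodesic_distances()].
#' @param cap Positive integer recoding cap (default 3).
#' @param unreachable Policy for infinite distances: `"cap"` or `"exclude"`.
#' @return The distance tibble with recoded `distance`; attribute
#'   `recode_cap` records the cap.
#' @examples
#' d <- tibble::tibble(dyad_i = "a", dyad_j = c("b", "c"), distance = c(4, 2))
#' recode_distances(d, cap = 3)$distance  # 3 2
#' @export
recode_distances <- function(distances, cap = 3L,
                             unreachable = c("cap", "exclude")) {
  unreachable <- match.arg(unreachable)
  if (!is.numeric(cap) || length(cap) != 1 || cap < 1) {
    abort("`cap` must be a positive integer.")
  }
  d <- as_tibble(distances)
  inf <- is.infinite(d$distance)
  if (any(inf)) {
    if (unreachable == "cap") {
      warn(sprintf("%d unreachable dyad(s) recoded to the cap value %d.",
                   sum(inf), as.integer(cap)))
      d$distance[inf] <- cap
    } else {
      warn(sprintf("%d unreachable dyad(s) excluded.", sum(inf)))
      d <- d[!inf, , drop = FALSE]
    }
  }
  d$distance <- pmin(d$distance, cap)
  attr(d, "recode_cap") <- as.integer(cap)
  d
}

#' Categorize the direction of change in social distance
#'
#' The change score is (later distance) minus (earlier distance); its sign
#' maps each dyad to `"closer"` (negative), `"same"` (zero) or `"apart"`
#' (positive).
#'
#' @param distances_t2,distances_t3 Distance tibbles over the same dyad set
#'   (finite values; apply [recode_distances()] first if needed).
#' @return Tibble `dyad_i`, `dyad_j`, `distance_t2`, `distance_t3`,
#'   `change_category` (factor closer/same/apart).
#' @export
change_categories <- function(distances_t2, distances_t3) {
  d2 <- as_tibble(distances_t2)
  d3 <- as_tibble(distances_t3)
  key2 <- paste(d2$dyad_i, d2$dyad_j)
  key3 <- paste(d3$dyad_i, d3$dyad_j)
  if (nrow(d2) != nrow(d3) || !setequal(key2, key3)) {
    abort("The two waves cover different dyad sets.")
  }
  d3 <- d3[match(key2, key3), , drop = FALSE]
  if (any(!is.finite(d2$distance)) || any(!is.finite(d3$distance))) {
    abort("Distances must be finite; resolve unreachable dyads first.")
  }
  delta <- d3$distance - d2$distance
  tibble(
    dyad_i = d2$dyad_i, dyad_j = d2$dyad_j,
    distance_t2 = d2$distance, distance_t3 = d3$distance,
    change_category = factor(
      dplyr::case_when(delta < 0 ~ "closer", delta > 0 ~ "apart",
                       TRUE ~ "same"),
      levels = c("closer", "same", "apart")
    )
  )
}

#' Descriptive statistics of a nomination roster
#'
#' Social ties per person are degree centrality on the directed nomination
#' graph with incoming and outgoing ties summed. Reciprocity is the
#' probability that i nominated j given that j nominated i, i.e. the number
#' of mutually nominated ordered pairs over the number of nominations.
#'
#' @param nominations Directed nomination tibble (`src`, `dst`).
#' @param participants Full roster of ids (isolates count toward the degree
#'   summaries with 0 ties).
#' @return One-row tibble: `n_participants`, `n_nominations`, `mean_ties`,
#'   `median_ties`, `reciprocity` (`NA` if there are no nominations),
#'   `n_mutual_edges`.
#' @examples
#' network_stats(tibble::tibble(src = c("a", "b", "a", "c", "a"),
#'                              dst = c("b", "a", "c", "a", "d")),
#'               participants = c("a", "b", "c", "d"))
#' @export
network_stats <- function(nominations, participants) {
  participants <- as.character(participants)
  nm <- distinct(as_tibble(nominations), .data$src, .data$dst)
  if (any(nm$src == nm$dst)) abort("Self-nominations are not allowed.")
  deg <- rep(0L, length(participants))
  names(deg) <- participants
  tab <- table(factor(c(nm$src, nm$dst), levels = participants))
  deg[names(tab)] <- as.integer(tab)
  key_fwd <- paste(nm$src, nm$dst, sep = "\r")
  key_rev <- paste(nm$dst, nm$src, sep = "\r")
  n_mutual_ordered <- sum(key_fwd %in% key_rev)
  reciprocity <- if (nrow(nm) == 0) {
    warn("No nominations: reciprocity is undefined.")
    NA_real_
  } else {
    n_mutual_ordered / nrow(nm)
  }
  tibble(
    n_participants = length(participants),
    n_nominations = nrow(nm),
    mean_ties = mean(deg),
    median_ties = median(deg),
    reciprocity = reciprocity,
    n_mutual_edges = n_mutual_ordered %/% 2L
  )
}
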