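#' Build the reaction-centric directed graph
#'
#' Nodes are reactions; a directed edge i -> j means some metabolite that i
#' can produce is consumed by j. Reversible reactions are treated as
#' bidirectionally capable: they count as producer and consumer of every
#' metabolite they touch, so they contribute edges for both orientations.
#' Multiple shared metabolites collapse to a single edge (the retroactive
#' distance is a hop count).
#'
#' @param model a `metabolic_model` (typically the ShReD variant).
#' @return a directed `igraph` with one named vertex per reaction.
#' @export
build_reaction_graph <- function(model) {
  st <- model$stoich |>
    left_join(select(model$reactions, "id", "reversible"),
              by = c(reaction_id = "id"))
  producers <- st |>
    filter(.data$num > 0 | .data$reversible) |>
    select("metabolite_id", from = "reaction_id")
  consumers <- st |>
    filter(.data$num < 0 | .data$reversible) |>
    select("metabolite_id", to = "reaction_id")
  edges <- inner_join(producers, consumers, by = "metabolite_id",
                      relationship = "many-to-many") |>
    filter(.data$from != .data$to) |>
    distinct(.data$from, .data$to) |>
    arrange(.data$from, .data$to)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = sort(model$reactions$id))
}

#' Export a reaction graph as an edge-list tibble
#'
#' @param graph a directed `igraph` from [build_reaction_graph()].
#' @return tibble with columns `from`, `to`.
#' @export
graph_edges <- function(graph) {
  e <- igraph::as_data_frame(graph, what = "edges")
  as_tibble(e[, c("from", "to")]) |> arrange(.data$from, .data$to)
}

#' Strongly connected components of a reaction graph
#'
#' @param graph a directed `igraph`.
#' @return list of character vectors (sorted members), ordered by smallest
#'   member id.
#' @export
reaction_sccs <- function(graph) {
  comp <- igraph::components(graph, mode = "strong")
  nm <- igraph::V(graph)$name
  groups <- split(nm, comp$membership)
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[[`, character(1), 1))] |> unname()
}

#' Shortest Retroactive Distance between two reactions
#'
#' The ShReD of a reaction pair is the edge length of the shortest directed
#' closed walk through both nodes, i.e. d(i -> j) + d(j -> i) in hops. It is
#' finite exactly when i and j lie in the same strongly connected component.
#'
#' @param graph a directed `igraph`.
#' @param i,j distinct reaction ids (vertex names).
#' @return positive integer, or `NA` when no directed cycle spans the pair.
#' @export
shred <- function(graph, i, j) {
  nm <- igraph::V(graph)$name
  if (!i %in% nm || !j %in% nm) abort("unknown reaction node id")
  if (i == j) abort("shred is defined for distinct reactions")
  dij <- igraph::distances(graph, v = i, to = j, mode = "out")[1, 1]
  dji <- igraph::distances(graph, v = j, to = i, mode = "out")[1, 1]
  val <- dij + dji
  if (!is.finite(val)) return(NA_integer_)
  as.integer(val)
}

#' All-pairs ShReD table
#'
#' Computed per strongly connected component (shortest paths between two
#' nodes of an SCC never leave it); pairs in different components are absent.
#'
#' @param graph a directed `igraph`.
#' @return tibble with columns `i`, `j` (unordered pair stored with `i < j`)
#'   and `shred` (integer >= 2).
#' @export
shred_table <- function(graph) {
  out <- list()
  for (members in reaction_sccs(graph)) {
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(graph, members)
    D <- igraph::distances(sub, mode = "out")
    D <- D[members, members, drop = FALSE]
    idx <- which(upper.tri(D), arr.ind = TRUE)
    out[[length(out) + 1]] <- tibble(
      i = members[idx[, 1]],
      j = members[idx[, 2]],
      shred = as.integer(D[idx] + t(D)[idx])
    )
  }
  if (length(out) == 0) {
    return(tibble(i = character(), j = character(), shred = integer()))
  }
  bind_rows(out) |>
    mutate(a = pmin(.data$i, .data$j), b = pmax(.data$i, .data$j)) |>
    select(i = "a", j = "b", "shred") |>
    arrange(.data$i, .data$j)
}
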