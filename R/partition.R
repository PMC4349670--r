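#' Weighted similarity graph
#'
#' Symmetric nonnegative pairwise weights over reaction nodes; the input to
#' modularity-based bisection. Built either from a ShReD table (retroactivity
#' metric) or from the plain reaction-graph adjacency (Newman connectivity
#' comparator).
#'
#' @param nodes character vector of node ids.
#' @param edges tibble with columns `i`, `j`, `w` (`w > 0`; pairs stored once).
#' @return an object of class `similarity_graph`.
#' @export
similarity_graph <- function(nodes, edges) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(edges$i %in% nodes), all(edges$j %in% nodes),
              all(edges$w > 0), all(edges$i != edges$j))
    edges <- edges |>
      mutate(a = pmin(.data$i, .data$j), b = pmax(.data$i, .data$j)) |>
      group_by(.data$a, .data$b) |>
      summarise(w = max(.data$w), .groups = "drop") |>
      select(i = "a", j = "b", "w") |>
      arrange(.data$i, .data$j)
  }
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' Similarity weights from a ShReD table
#'
#' Pairs spanned by short directed cycles should stay together, so the weight
#' is a strictly decreasing transform of the ShReD value: `1/d` (default) or
#' `exp(-d)`. Pairs with no common cycle get weight zero (no edge).
#'
#' @param table tibble from [shred_table()].
#' @param nodes all node ids (so acyclic reactions appear as isolated nodes).
#' @param transform `"inverse"` or `"exp"`.
#' @return a `similarity_graph`.
#' @export
similarity_from_shred <- function(table, nodes,
                                  transform = c("inverse", "exp")) {
  transform <- match.arg(transform)
  f <- switch(transform, inverse = function(d) 1 / d,
              exp = function(d) exp(-d))
  edges <- table |> mutate(w = f(.data$shred)) |> select("i", "j", "w")
  similarity_graph(nodes, edges)
}

#' Connectivity (Newman) similarity from a reaction graph
#'
#' Symmetrized, unweighted adjacency of the reaction-centric graph, used as
#' the connectivity-only comparator metric: the bisection machinery is shared
#' with the ShReD metric so the only varied factor is the weighting.
#'
#' @param graph a directed `igraph`.
#' @return a `similarity_graph`.
#' @export
similarity_newman <- function(graph) {
  e <- graph_edges(graph)
  edges <- e |>
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    distinct(.data$a, .data$b) |>
    select(i = "a", j = "b") |>
    mutate(w = 1)
  similarity_graph(igraph::V(graph)$name, edges)
}

# dense symmetric weight matrix over sorted nodes
weight_matrix <- function(sim) {
  n <- length(sim$nodes)
  W <- matrix(0, n, n, dimnames = list(sim$nodes, sim$nodes))
  if (nrow(sim$edges) > 0) {
    ii <- match(sim$edges$i, sim$nodes)
    jj <- match(sim$edges$j, sim$nodes)
    W[cbind(ii, jj)] <- sim$edges$w
    W[cbind(jj, ii)] <- sim$edges$w
  }
  W
}

#' Newman modularity of a partition of a similarity graph
#'
#' `Q = sum_c [ W_in(c)/W - (W_deg(c)/(2 W))^2 ]` with `W` the total edge
#' weight, `W_in(c)` the intra-community weight and `W_deg(c)` the summed
#' weighted degree of community `c`.
#'
#' @param sim a `similarity_graph` with positive total weight.
#' @param membership named vector (names = node ids) of community labels.
#' @return modularity score in `[-1/2, 1)`.
#' @export
modularity_score <- function(sim, membership) {
  W <- weight_matrix(sim)
  Wtot <- sum(W) / 2
  if (Wtot == 0) abort("unpartitionable: similarity graph has zero weight")
  memb <- membership[sim$nodes]
  k <- rowSums(W)
  q <- 0
  for (cc in unique(memb)) {
    idx <- which(memb == cc)
    q <- q + sum(W[idx, idx]) / (2 * Wtot) - (sum(k[idx]) / (2 * Wtot))^2
  }
  q
}

# modularity from a precomputed weight matrix (internal fast path)
.q_from_matrix <- function(W, memb) {
  Wtot <- sum(W) / 2
  k <- rowSums(W)
  q <- 0
  for (cc in unique(memb)) {
    idx <- which(memb == cc)
    q <- q + sum(W[idx, idx]) / (2 * Wtot) - (sum(k[idx]) / (2 * Wtot))^2
  }
  q
}

#' Bisect a similarity graph by modularity
#'
#' Spectral split on the leading eigenvector of the modularity matrix
#' `B = W - k k' / (2 W)`, refined by greedy single-node moves until no move
#' improves Q. Deterministic: nodes are processed in sorted id order and ties
#' go to the lowest id.
#'
#' @param sim a `similarity_graph` with at least 2 nodes and positive weight.
#' @return list with `membership` (named vector of 1/2) and `q` (the split's
#'   modularity). When the best achievable split is the trivial one-side
#'   assignment, `q <= 0` signals the module is indivisible.
#' @export
bisect_graph <- function(sim) {
  n <- length(sim$nodes)
  if (n < 2) abort("unpartitionable: fewer than 2 nodes")
  W <- weight_matrix(sim)
  Wtot <- sum(W) / 2
  if (Wtot == 0) abort("unpartitionable: similarity graph has zero weight")
  k <- rowSums(W)
  B <- W - outer(k, k) / (2 * Wtot)
  ev <- eigen(B, symmetric = TRUE)
  v <- ev$vectors[, 1]
  nz <- which(abs(v) > 1e-12)
  if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
  memb <- ifelse(v >= 0, 1L, 2L)
  if (length(unique(memb)) == 1) {
    # spectral step found no split; start from moving the top-scoring node
    memb[which.max(v)] <- 2L
  }
  # greedy refinement by single-node flips
  q <- .q_from_matrix(W, memb)
  repeat {
    best_gain <- 0
    best_i <- 0L
    for (i in seq_len(n)) {
      cand <- memb
      cand[i] <- 3L - cand[i]
      qq <- .q_from_matrix(W, cand)
      if (qq > q + 1e-12 && qq - q > best_gain + 1e-12) {
        best_gain <- qq - q
        best_i <- i
      }
    }
    if (best_i == 0L) break
    memb[best_i] <- 3L - memb[best_i]
    q <- q + best_gain
    q <- .q_from_matrix(W, memb)  # re-anchor to avoid drift
  }
  if (length(unique(memb)) == 1) {
    return(list(membership = setNames(memb, sim$nodes), q = 0))
  }
  list(membership = setNames(memb, sim$nodes), q = q)
}

# connected components of the positive-weight similarity graph,
# ordered by smallest member; isolated nodes form singleton components
.sim_components <- function(sim) {
  g <- igraph::graph_from_data_frame(
    sim$edges[, c("i", "j")], directed = FALSE, vertices = sim$nodes
  )
  comp <- igraph::components(g)
  groups <- split(sim$nodes, comp$membership[sim$nodes])
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[[`, character(1), 1))] |> unname()
}

#' Hierarchical ShReD / Newman partition of a metabolic network
#'
#' Recursively bisects the reaction set. At each module the reaction graph is
#' induced on the module's reactions and the metric recomputed within it
#' (cycles leaving the module no longer count); the module is split by
#' [bisect_graph()] and the recursion continues into each side only while the
#' split's modularity is positive. A module whose similarity graph is
#' disconnected is first split into its connected components. A module whose
#' similarity weight is all zero (no directed cycle at all under the shred
#' metric) is a leaf.
#'
#' @param model_shred the ShReD-variant `metabolic_model`.
#' @param metric `"shred"` (retroactivity) or `"newman"` (connectivity).
#' @param transform similarity transform for the shred metric, see
#'   [similarity_from_shred()].
#' @param min_module_size modules at or below this size are not split further.
#' @return a `partition_tree`: tibble with one row per module (`module_id`,
#'   `parent`, `height`, `q`, `n_reactions`, `reactions` list-column).
#' @export
hierarchical_partition <- function(model_shred,
                                   metric = c("shred", "newman"),
                                   transform = c("inverse", "exp"),
                                   min_module_size = 1L) {
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  rg <- build_reaction_graph(model_shred)
  rows <- list()
  counter <- 0L

  make_sim <- function(ids) {
    sub <- igraph::induced_subgraph(rg, ids)
    if (metric == "shred") {
      similarity_from_shred(shred_table(sub), ids, transform = transform)
    } else {
      similarity_newman(sub)
    }
  }

  recurse <- function(ids, parent) {
    ids <- sort(ids)
    counter <<- counter + 1L
    my_id <- counter
    rows[[my_id]] <<- list(module_id = my_id, parent = parent, q = NA_real_,
                           reactions = ids)
    if (length(ids) <= max(1L, min_module_size)) return(invisible(my_id))
    sim <- make_sim(ids)
    if (nrow(sim$edges) == 0) return(invisible(my_id))  # unpartitionable
    comps <- .sim_components(sim)
    if (length(comps) > 1) {
      for (cc in comps) recurse(cc, my_id)
      return(invisible(my_id))
    }
    bi <- bisect_graph(sim)
    if (bi$q <= 0) return(invisible(my_id))
    rows[[my_id]]$q <<- bi$q
    part1 <- names(bi$membership)[bi$membership == 1L]
    part2 <- names(bi$membership)[bi$membership == 2L]
    recurse(part1, my_id)
    recurse(part2, my_id)
    invisible(my_id)
  }

  recurse(model_shred$reactions$id, NA_integer_)

  tree <- tibble(
    module_id = vapply(rows, `[[`, integer(1), "module_id"),
    parent = vapply(rows, `[[`, integer(1), "parent"),
    q = vapply(rows, `[[`, numeric(1), "q"),
    reactions = lapply(rows, `[[`, "reactions")
  ) |>
    mutate(n_reactions = vapply(.data$reactions, length, integer(1)))
  # heights leaf-up: children always carry larger ids than their parent
  height <- integer(nrow(tree))
  for (m in rev(seq_len(nrow(tree)))) {
    kids <- which(tree$parent == tree$module_id[m])
    height[m] <- if (length(kids) == 0) 0L else 1L + max(height[kids])
  }
  tree$height <- height
  tree <- tree |>
    select("module_id", "parent", "height", "q", "n_reactions", "reactions")
  class(tree) <- c("partition_tree", class(tree))
  attr(tree, "metric") <- metric
  tree
}

#' @export
print.partition_tree <- function(x, ...) {
  cat("<partition_tree> metric:", attr(x, "metric") %||% "?",
      "| modules:", nrow(x),
      "| leaves:", sum(!x$module_id %in% x$parent),
      "| max height:", max(x$height), "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a partition tree into a flat module membership table
#'
#' @param x a `partition_tree`.
#' @param ... unused.
#' @return tibble with columns `module_id`, `reaction_id`.
#' @export
tidy.partition_tree <- function(x, ...) {
  tibble(module_id = rep(x$module_id, x$n_reactions),
         reaction_id = unlist(x$reactions))
}

#' @export
glance.partition_tree <- function(x, ...) {
  leaves <- !x$module_id %in% x$parent
  tibble(
    metric = attr(x, "metric") %||% NA_character_,
    n_modules = nrow(x),
    n_leaves = sum(leaves),
    max_height = max(x$height),
    n_root_reactions = x$n_reactions[is.na(x$parent)][1]
  )
}

#' Modules in enumeration order (leaves first)
#'
#' Module height is leaf-up: leaves have height 0 and a parent's height is one
#' more than its tallest child. Enumeration proceeds in increasing height so
#' small modules are exhausted before their (larger) ancestors; ties break by
#' module id.
#'
#' @param tree a `partition_tree`.
#' @return integer vector of module ids.
#' @export
module_height_order <- function(tree) {
  tree$module_id[order(tree$height, tree$module_id)]
}

#' Serialize a partition tree to JSON
#'
#' @param tree a `partition_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(tree, path) {
  obj <- lapply(seq_len(nrow(tree)), function(i) {
    list(
      module_id = tree$module_id[i],
      parent = if (is.na(tree$parent[i])) NULL else tree$parent[i],
      children = tree$module_id[which(tree$parent == tree$module_id[i])],
      height = tree$height[i],
      q = if (is.na(tree$q[i])) NULL else tree$q[i],
      reactions = tree$reactions[[i]]
    )
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
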