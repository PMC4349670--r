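# Shared toy networks and independent oracles used across the suite.

# two disjoint directed 3-cycles (all irreversible, cytosolic)
two_triangles_model <- function() {
  model_from_equations(c(
    A1 = "a1(c) --> a2(c)", A2 = "a2(c) --> a3(c)", A3 = "a3(c) --> a1(c)",
    B1 = "b1(c) --> b2(c)", B2 = "b2(c) --> b3(c)", B3 = "b3(c) --> b1(c)"
  ))
}

# directed 3-cycle as an igraph (reaction-centric toy)
ring_graph <- function(n, prefix = "R") {
  ids <- paste0(prefix, seq_len(n))
  igraph::graph_from_data_frame(
    data.frame(from = ids, to = ids[c(2:n, 1)]),
    directed = TRUE, vertices = sort(ids)
  )
}

# independent ShReD oracle: min over shortest directed i->j and j->i paths,
# found by exhaustive DFS simple-path enumeration (never uses igraph::distances)
shred_oracle <- function(graph, i, j) {
  adj <- igraph::as_adj_list(graph, mode = "out")
  nm <- igraph::V(graph)$name
  names(adj) <- nm
  shortest_path <- function(from, to) {
    best <- Inf
    walk <- function(node, seen, len) {
      if (len >= best) return(invisible())
      for (nb in nm[as.integer(adj[[node]])]) {
        if (nb == to) {
          best <<- min(best, len + 1)
        } else if (!nb %in% seen) {
          walk(nb, c(seen, nb), len + 1)
        }
      }
    }
    walk(from, from, 0)
    best
  }
  val <- shortest_path(i, j) + shortest_path(j, i)
  if (is.finite(val)) as.integer(val) else NA_integer_
}

# exhaustive modularity oracle: best 2-partition of a similarity graph
best_bisection_oracle <- function(sim) {
  n <- length(sim$nodes)
  best_q <- -Inf
  for (code in 1:(2^(n - 1) - 1)) {
    memb <- as.integer(bitwAnd(code, bitwShiftL(1, seq_len(n) - 1)) != 0) + 1L
    q <- modularity_score(sim, stats::setNames(memb, sim$nodes))
    best_q <- max(best_q, q)
  }
  best_q
}

# modes tibble -> canonical list of signed-support strings for set comparison
mode_signatures <- function(modes) {
  if (nrow(modes) == 0) return(character())
  sp <- split(modes, modes$efm_id)
  unname(sort(vapply(sp, function(m) {
    m <- m[order(m$reaction_id), ]
    paste(m$reaction_id, m$coef_int, sep = ":", collapse = ";")
  }, character(1))))
}

expect_same_modes <- function(a, b) {
  expect_identical(mode_signatures(a), mode_signatures(b))
}
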