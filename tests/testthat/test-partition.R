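test_that("modularity matches closed forms and the igraph implementation", {
  # two disconnected unit-weight triangles, split into the two triangles
  nodes <- c("a1", "a2", "a3", "b1", "b2", "b3")
  edges <- tibble::tibble(
    i = c("a1", "a1", "a2", "b1", "b1", "b2"),
    j = c("a2", "a3", "a3", "b2", "b3", "b3"),
    w = 1
  )
  sim <- similarity_graph(nodes, edges)
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 2), nodes)
  expect_equal(modularity_score(sim, memb), 0.5)
  # one community: Q = 0 by the normalization identity
  expect_equal(modularity_score(sim, stats::setNames(rep(1, 6), nodes)), 0)
  # agreement with igraph on an asymmetric weighted case
  sim2 <- similarity_graph(nodes, dplyr::mutate(edges, w = c(1, 2, 3, 1, 1, 5)))
  memb2 <- stats::setNames(c(1, 1, 2, 2, 1, 2), nodes)
  g <- igraph::graph_from_data_frame(sim2$edges[, c("i", "j")],
                                     directed = FALSE, vertices = nodes)
  expect_equal(
    modularity_score(sim2, memb2),
    igraph::modularity(g, membership = memb2[nodes],
                       weights = sim2$edges$w)
  )
  expect_error(modularity_score(similarity_graph("a", edges[0, ]),
                                c(a = 1)), "unpartitionable")
})

test_that("random splits of a complete graph rarely beat Q = 0", {
  nodes <- paste0("n", 1:8)
  pairs <- t(utils::combn(nodes, 2))
  sim <- similarity_graph(nodes, tibble::tibble(i = pairs[, 1],
                                                j = pairs[, 2], w = 1))
  qs <- withr::with_seed(99, replicate(50, {
    memb <- stats::setNames(sample(1:2, 8, replace = TRUE), nodes)
    modularity_score(sim, memb)
  }))
  expect_lte(mean(qs), 0)
})

test_that("bisection finds planted weak links and declares cliques indivisible", {
  # two triangles joined by one weak edge: exhaustive-search optimum
  nodes <- c("a1", "a2", "a3", "b1", "b2", "b3")
  edges <- tibble::tibble(
    i = c("a1", "a1", "a2", "b1", "b1", "b2", "a3"),
    j = c("a2", "a3", "a3", "b2", "b3", "b3", "b1"),
    w = c(1, 1, 1, 1, 1, 1, 0.01)
  )
  sim <- similarity_graph(nodes, edges)
  bi <- bisect_graph(sim)
  expect_gt(bi$q, 0)
  expect_equal(bi$q, best_bisection_oracle(sim), tolerance = 1e-12)
  expect_setequal(names(bi$membership)[bi$membership == bi$membership[["a1"]]],
                  c("a1", "a2", "a3"))
  # complete uniform K4: no split has positive modularity
  n4 <- paste0("k", 1:4)
  p4 <- t(utils::combn(n4, 2))
  sim4 <- similarity_graph(n4, tibble::tibble(i = p4[, 1], j = p4[, 2], w = 1))
  expect_lte(best_bisection_oracle(sim4), 0)
  expect_lte(bisect_graph(sim4)$q, 0)
  expect_error(bisect_graph(similarity_graph("a", edges[0, ])),
               "unpartitionable")
})

test_that("hierarchical partition splits disjoint cycles and stops on triangles", {
  tr <- hierarchical_partition(two_triangles_model(), metric = "shred")
  expect_equal(nrow(tr), 3)
  leaves <- tr[!tr$module_id %in% tr$parent, ]
  expect_equal(sort(vapply(leaves$reactions, length, integer(1))), c(3, 3))
  expect_setequal(unlist(leaves$reactions),
                  two_triangles_model()$reactions$id)
  # a single 3-cycle is indivisible
  tri <- model_from_equations(c(A1 = "a1(c) --> a2(c)",
                                A2 = "a2(c) --> a3(c)",
                                A3 = "a3(c) --> a1(c)"))
  expect_equal(nrow(hierarchical_partition(tri, metric = "shred")), 1)
  # a pure DAG has zero shred similarity: root stays a leaf
  dag <- model_from_equations(c(R1 = "A(c) --> B(c)", R2 = "B(c) --> C(c)"))
  expect_equal(nrow(hierarchical_partition(dag, metric = "shred")), 1)
})

test_that("partition trees satisfy the tree-partition invariants", {
  gen <- generate_planted(planted_spec(n_cycles = 3, cycle_lengths = c(3, 4, 5),
                                       n_bridge_edges = 2, seed = 11))
  shredm <- suppressWarnings(
    apply_cofactor_policy(gen$model, gen$policy, "shred"))
  for (metric in c("shred", "newman")) {
    tr <- hierarchical_partition(shredm, metric = metric)
    for (m in tr$module_id) {
      kids <- tr[which(tr$parent == m), ]
      if (nrow(kids) > 0) {
        expect_gte(nrow(kids), 2)
        expect_setequal(unlist(kids$reactions),
                        tr$reactions[[which(tr$module_id == m)]])
        expect_equal(sum(vapply(kids$reactions, length, integer(1))),
                     length(tr$reactions[[which(tr$module_id == m)]]))
        # monotone sizes
        expect_true(all(kids$n_reactions <
                          tr$n_reactions[tr$module_id == m]))
        # leaf-up heights
        expect_equal(tr$height[tr$module_id == m], 1L + max(kids$height))
      } else {
        expect_equal(tr$height[tr$module_id == m], 0L)
      }
    }
    # determinism
    tr2 <- hierarchical_partition(shredm, metric = metric)
    expect_identical(tibble::as_tibble(tr), tibble::as_tibble(tr2))
  }
})

test_that("height order lists leaves before ancestors", {
  tr <- hierarchical_partition(two_triangles_model(), metric = "shred")
  ord <- module_height_order(tr)
  h <- tr$height[match(ord, tr$module_id)]
  expect_true(all(diff(h) >= 0))
  expect_equal(ord[3], 1L)  # root last
  # root-only tree
  tri <- model_from_equations(c(A1 = "a1(c) --> a2(c)",
                                A2 = "a2(c) --> a3(c)",
                                A3 = "a3(c) --> a1(c)"))
  expect_equal(module_height_order(hierarchical_partition(tri)), 1L)
})

test_that("shred similarity weights decrease with distance", {
  tab <- tibble::tibble(i = c("a", "a"), j = c("b", "c"),
                        shred = c(4L, 8L))
  sim <- similarity_from_shred(tab, c("a", "b", "c"))
  w <- sim$edges
  expect_equal(w$w[w$j == "b"] / w$w[w$j == "c"], 2)
  simx <- similarity_from_shred(tab, c("a", "b", "c"), transform = "exp")
  expect_equal(simx$edges$w, exp(-c(4, 8)))
  # DAG: no entries, all-zero similarity
  empty <- similarity_from_shred(tab[0, ], c("a", "b"))
  expect_equal(nrow(empty$edges), 0)
})
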