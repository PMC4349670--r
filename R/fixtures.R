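#' The six-reaction worked-example network
#'
#' A small bipartite network with one linear pathway and one embedded cycle:
#' R1: M1 -> M2; R2: M2 -> M3; R3: M3 -> M4; R4: M3 -> M5; R5: M5 -> M6;
#' R6: M6 -> M2 (all irreversible, all cytosolic). M1 and M4 are dead ends;
#' after pruning, the network carries exactly two elementary modes,
#' \{R1,R2,R3\} (linear) and \{R2,R4,R5,R6\} (the only strongly connected
#' set, hence the only cycle).
#'
#' @return a `metabolic_model`.
#' @export
figure_network <- function() {
  model_from_equations(c(
    R1 = "M1(c) --> M2(c)",
    R2 = "M2(c) --> M3(c)",
    R3 = "M3(c) --> M4(c)",
    R4 = "M3(c) --> M5(c)",
    R5 = "M5(c) --> M6(c)",
    R6 = "M6(c) --> M2(c)"
  ))
}

#' Specification for a planted-cycle synthetic network
#'
#' @param n_cycles number of planted substrate cycles.
#' @param cycle_lengths integer vector (recycled to `n_cycles`), each >= 2.
#' @param n_linear_pathways number of linear decoy pathways (each gets a
#'   source and a sink reaction so it survives pruning as a non-cyclical
#'   mode).
#' @param pathway_lengths lengths of the decoy pathways (>= 1 internal
#'   conversion reactions).
#' @param cofactor_attach_prob probability that a cycle reaction carries a
#'   cofactor couple (X consumed, X* produced); every cycle is guaranteed at
#'   least one attachment so its designed cofactor net is nonzero.
#' @param n_bridge_edges number of acyclic bridge reactions between cycles
#'   (oriented from lower- to higher-numbered cycles, so no new directed
#'   cycle can arise).
#' @param seed integer seed; fully determines the generated network.
#' @return a `planted_spec` list.
#' @export
planted_spec <- function(n_cycles = 3, cycle_lengths = c(2, 3, 5),
                         n_linear_pathways = 2, pathway_lengths = 3,
                         cofactor_attach_prob = 0.5, n_bridge_edges = 0,
                         seed = 1) {
  cycle_lengths <- rep_len(cycle_lengths, n_cycles)
  pathway_lengths <- rep_len(pathway_lengths, max(n_linear_pathways, 1))
  if (n_cycles > 0 && any(cycle_lengths < 2)) abort("cycle lengths must be >= 2")
  if (any(pathway_lengths < 1)) abort("pathway lengths must be >= 1")
  if (n_bridge_edges > 0 && n_cycles < 2) {
    abort("bridges require at least two cycles")
  }
  structure(list(n_cycles = n_cycles, cycle_lengths = cycle_lengths,
                 n_linear_pathways = n_linear_pathways,
                 pathway_lengths = pathway_lengths,
                 cofactor_attach_prob = cofactor_attach_prob,
                 n_bridge_edges = n_bridge_edges, seed = seed),
            class = "planted_spec")
}

# cofactor couples available to the generator (consumed / produced form)
.planted_cofactor_pairs <- function() {
  list(c("CofA(c)", "CofA*(c)"),
       c("CofB(c)", "CofB*(c)"),
       c("CofC(c)", "CofC*(c)"))
}

#' Generate a planted-cycle network with known ground truth
#'
#' Each planted cycle is a closed chain of fresh metabolites joined by
#' irreversible reactions; cofactor couples are attached so the cycle has a
#' designed nonzero net cofactor turnover. Linear decoy pathways (with source
#' and sink reactions) survive pruning as non-cyclical modes, and optional
#' bridge reactions connect cycles acyclically. All generated cofactors are
#' listed in both policy sections, so the ShReD graph reflects the carbon
#' backbone only.
#'
#' @param spec a [planted_spec()].
#' @return list with `model` (a `metabolic_model`), `truth` (tibble
#'   `cycle_id`, `reactions` list-column, `length`, `net` list-column of the
#'   designed per-unit-flux cofactor net), and `policy` (a
#'   `cofactor_policy`).
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  withr::with_seed(spec$seed, {
    eqs <- character()
    pairs <- .planted_cofactor_pairs()
    truth_rows <- list()
    for (ci in seq_len(spec$n_cycles)) {
      L <- spec$cycle_lengths[ci]
      mets <- sprintf("C%d_%d(c)", ci, seq_len(L))
      rids <- sprintf("cyc%d_r%d", ci, seq_len(L))
      attach <- stats::runif(L) < spec$cofactor_attach_prob
      if (!any(attach)) attach[1] <- TRUE
      net <- list()
      for (k in seq_len(L)) {
        lhs <- mets[k]
        rhs <- mets[if (k == L) 1 else k + 1]
        if (attach[k]) {
          pair <- pairs[[sample.int(length(pairs), 1)]]
          lhs <- paste(lhs, pair[1], sep = " + ")
          rhs <- paste(rhs, pair[2], sep = " + ")
          net[[pair[1]]] <- (net[[pair[1]]] %||% 0) - 1
          net[[pair[2]]] <- (net[[pair[2]]] %||% 0) + 1
        }
        eqs[rids[k]] <- paste(lhs, "-->", rhs)
      }
      net <- net[vapply(net, function(x) x != 0, logical(1))]
      truth_rows[[ci]] <- tibble(cycle_id = ci, reactions = list(rids),
                                 length = L, net = list(net))
    }
    for (pi in seq_len(spec$n_linear_pathways)) {
      L <- spec$pathway_lengths[pi]
      mets <- sprintf("D%d_%d(c)", pi, seq_len(L + 1))
      eqs[sprintf("lin%d_src", pi)] <- paste(" -->", mets[1])
      for (k in seq_len(L)) {
        eqs[sprintf("lin%d_r%d", pi, k)] <- paste(mets[k], "-->", mets[k + 1])
      }
      eqs[sprintf("lin%d_snk", pi)] <- paste(mets[L + 1], "--> ")
    }
    if (spec$n_bridge_edges > 0) {
      for (bi in seq_len(spec$n_bridge_edges)) {
        ab <- sort(sample.int(spec$n_cycles, 2))
        from_m <- sprintf("C%d_%d(c)", ab[1],
                          sample.int(spec$cycle_lengths[ab[1]], 1))
        to_m <- sprintf("C%d_%d(c)", ab[2],
                        sample.int(spec$cycle_lengths[ab[2]], 1))
        eqs[sprintf("bridge%d", bi)] <- paste(from_m, "-->", to_m)
      }
    }
    cof_ids <- unlist(.planted_cofactor_pairs())
    policy <- cofactor_policy(efm_removed = cof_ids, shred_removed = cof_ids)
    list(model = model_from_equations(eqs),
         truth = bind_rows(truth_rows),
         policy = policy)
  })
}

#' Random sparse stoichiometric system
#'
#' Random integer stoichiometries (entries in -2..2) for oracle testing of
#' the mode enumeration; fully determined by the seed.
#'
#' @param n_metabolites,n_reactions matrix dimensions before dropping empty
#'   reaction columns.
#' @param density probability that an entry is nonzero.
#' @param rev_fraction probability that a reaction is reversible.
#' @param seed integer seed.
#' @return a `metabolic_model` (possibly with fewer than `n_reactions`
#'   reactions if some columns came out empty).
#' @export
random_cone <- function(n_metabolites, n_reactions, density = 0.3,
                        rev_fraction = 0.3, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(0, n_metabolites, n_reactions)
    nz <- matrix(stats::runif(n_metabolites * n_reactions) < density,
                 n_metabolites, n_reactions)
    M[nz] <- sample(c(-2, -1, 1, 2), sum(nz), replace = TRUE)
    keep <- colSums(M != 0) > 0
    M <- M[, keep, drop = FALSE]
    rev <- stats::runif(ncol(M)) < rev_fraction
    mets <- sprintf("X%d(c)", seq_len(n_metabolites))
    rxns <- sprintf("v%d", seq_len(ncol(M)))
    st <- which(M != 0, arr.ind = TRUE)
    stoich <- tibble(reaction_id = rxns[st[, 2]],
                     metabolite_id = mets[st[, 1]],
                     num = M[st], den = 1)
    metabolic_model(
      tibble(id = mets, name = sub("\\(c\\)$", "", mets),
             compartment = "c"),
      tibble(id = rxns, reversible = rev),
      stoich
    ) |> drop_orphan_metabolites() |> rebuild_model()
  })
}
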