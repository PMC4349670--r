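#' Directed bipartite graph of a flux mode
#'
#' Nodes are the mode's active reactions plus the submodel metabolites they
#' touch; edges are oriented by the direction each reaction is actually used
#' in (substrate -> reaction -> product under the signed coefficients, so a
#' reversible reaction run backwards has its edges flipped).
#'
#' @param mode tibble for one mode with columns `reaction_id`, `coefficient`
#'   (or `coef_int`); signs give the direction used.
#' @param submodel the `metabolic_model` the mode was computed on.
#' @return a directed `igraph`; metabolite vertices carry `type = "metabolite"`,
#'   reaction vertices `type = "reaction"`.
#' @export
mode_graph <- function(mode, submodel) {
  coef <- if ("coef_int" %in% names(mode)) mode$coef_int else mode$coefficient
  rids <- mode$reaction_id
  unknown <- setdiff(rids, submodel$reactions$id)
  if (length(unknown) > 0) {
    abort(paste("mode references reaction absent from submodel:",
                paste(unknown, collapse = ", ")))
  }
  st <- submodel$stoich |>
    filter(.data$reaction_id %in% rids) |>
    mutate(flux = coef[match(.data$reaction_id, rids)],
           oriented = sign(.data$num) * sign(.data$flux))
  from <- ifelse(st$oriented > 0, st$reaction_id, st$metabolite_id)
  to <- ifelse(st$oriented > 0, st$metabolite_id, st$reaction_id)
  mets <- unique(st$metabolite_id)
  verts <- tibble(name = c(sort(unique(rids)), sort(mets)),
                  type = c(rep("reaction", length(unique(rids))),
                           rep("metabolite", length(mets))))
  igraph::graph_from_data_frame(tibble(from = from, to = to),
                                directed = TRUE, vertices = verts)
}

# reaction-projected digraph of a mode: r -> r' iff r produces a submodel
# metabolite that r' consumes, under the orientations actually used
.mode_reaction_graph <- function(mode, submodel) {
  coef <- if ("coef_int" %in% names(mode)) mode$coef_int else mode$coefficient
  rids <- mode$reaction_id
  st <- submodel$stoich |>
    filter(.data$reaction_id %in% rids) |>
    mutate(flux = coef[match(.data$reaction_id, rids)],
           oriented = sign(.data$num) * sign(.data$flux))
  prod <- st |> filter(.data$oriented > 0) |>
    select("metabolite_id", from = "reaction_id")
  cons <- st |> filter(.data$oriented < 0) |>
    select("metabolite_id", to = "reaction_id")
  edges <- inner_join(prod, cons, by = "metabolite_id",
                      relationship = "many-to-many") |>
    filter(.data$from != .data$to) |>
    distinct(.data$from, .data$to)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = sort(unique(rids)))
}

#' Is a flux mode cyclical?
#'
#' A mode is cyclical when every vertex of its directed (bipartite) graph
#' lies in a single strongly connected component and the mode uses at least
#' two reactions — the closed-loop signature of a candidate substrate cycle.
#' The reaction-projected test (`method = "projected"`) is an equivalent
#' formulation kept as an internal cross-check.
#'
#' @param mode tibble for one mode (see [mode_graph()]). A mode flagged
#'   `isomerization` (single reversible reaction run both ways) is cyclical
#'   by definition.
#' @param submodel the `metabolic_model` the mode was computed on.
#' @param method `"bipartite"` (default) or `"projected"`.
#' @return logical.
#' @export
is_cyclical <- function(mode, submodel, method = c("bipartite", "projected")) {
  method <- match.arg(method)
  if (nrow(mode) == 0) abort("empty mode")
  if ("isomerization" %in% names(mode) && isTRUE(mode$isomerization[1])) {
    return(TRUE)
  }
  if (length(unique(mode$reaction_id)) < 2) return(FALSE)
  g <- if (method == "bipartite") mode_graph(mode, submodel) else
    .mode_reaction_graph(mode, submodel)
  comp <- igraph::components(g, mode = "strong")
  comp$no == 1
}

#' Keep only the cyclical modes
#'
#' @param modes tibble of modes (possibly several, keyed by `efm_id`).
#' @param submodel the `metabolic_model` the modes were computed on.
#' @return the subset of rows belonging to cyclical modes.
#' @export
filter_cyclical <- function(modes, submodel) {
  if (nrow(modes) == 0) return(modes)
  keep <- modes |>
    group_by(.data$efm_id) |>
    summarise(cyc = is_cyclical(dplyr::pick(dplyr::everything()), submodel),
              .groups = "drop")
  modes |> semi_join(filter(keep, .data$cyc), by = "efm_id")
}

#' Classify every enumerated mode as cyclical or not
#'
#' Re-extracts each module's submodel and applies the single-SCC test to each
#' of its modes.
#'
#' @param result a `module_efms` from [enumerate_tree()].
#' @param tree the `partition_tree` used for enumeration.
#' @param model_efm the EFM-variant model.
#' @return tibble with one row per mode: `module_id`, `efm_id`, `cyclical`,
#'   `length` (number of active reactions).
#' @export
classify_cycles <- function(result, tree, model_efm) {
  modes <- result$modes
  if (nrow(modes) == 0) {
    return(tibble(module_id = integer(), efm_id = integer(),
                  cyclical = logical(), length = integer()))
  }
  out <- list()
  for (mid in unique(modes$module_id)) {
    rids <- intersect(tree$reactions[[which(tree$module_id == mid)]],
                      model_efm$reactions$id)
    sub <- extract_module_submodel(model_efm, rids)
    mm <- modes[modes$module_id == mid, , drop = FALSE]
    out[[length(out) + 1]] <- mm |>
      group_by(.data$efm_id) |>
      summarise(
        cyclical = is_cyclical(dplyr::pick(dplyr::everything()), sub),
        length = dplyr::n_distinct(.data$reaction_id),
        .groups = "drop"
      ) |>
      mutate(module_id = mid)
  }
  bind_rows(out) |>
    select("module_id", "efm_id", "cyclical", "length") |>
    arrange(.data$module_id, .data$efm_id)
}
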