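#' Net species balance of a mode against the full base model
#'
#' Sums the full stoichiometry column of every active reaction weighted by
#' the mode's unit-flux coefficients (smallest absolute coefficient 1), in
#' exact rational arithmetic. Species balanced in the mode's submodel come
#' out exactly zero and are dropped; what remains is the net cofactor
#' turnover of the candidate substrate cycle, plus any other species left
#' unbalanced by dead-end pruning (reported separately, not merged with
#' cofactors). Reported magnitudes scale with the chosen normalization.
#'
#' @param mode tibble for one mode with `reaction_id` and `coef_int` (or
#'   `coefficient`).
#' @param base_model the full base `metabolic_model`.
#' @param policy a `cofactor_policy`; species in `efm_removed` are classed
#'   `"cofactor"`, all other unbalanced species `"other_unbalanced"`.
#' @return tibble with columns `species`, `num`, `den` (exact net rate),
#'   `net` (numeric value), `direction` (`"consumed"`/`"produced"`), `class`.
#' @export
net_balance <- function(mode, base_model, policy) {
  coef <- if ("coef_int" %in% names(mode)) mode$coef_int else mode$coefficient
  rids <- mode$reaction_id
  unknown <- setdiff(rids, base_model$reactions$id)
  if (length(unknown) > 0) {
    abort(paste("unknown reaction id(s):", paste(unknown, collapse = ", ")))
  }
  # unit-flux normalization: divide by the smallest absolute coefficient
  m <- min(abs(coef[coef != 0]))
  st <- base_model$stoich |>
    filter(.data$reaction_id %in% rids) |>
    mutate(fn = coef[match(.data$reaction_id, rids)], fd = m)
  if (nrow(st) == 0) {
    return(tibble(species = character(), num = numeric(), den = numeric(),
                  net = numeric(), direction = character(),
                  class = character()))
  }
  # per species: sum of (flux_r * stoich) as exact rationals
  contrib <- rat_mul(st$num, st$den, st$fn, st$fd)
  st$cn <- contrib$num
  st$cd <- contrib$den
  st |>
    group_by(species = .data$metabolite_id) |>
    summarise(res = list(Reduce(
      function(a, b) { s <- rat_add(a[1], a[2], b[1], b[2]); c(s$num, s$den) },
      purrr::map2(.data$cn, .data$cd, c)
    )), .groups = "drop") |>
    mutate(num = purrr::map_dbl(.data$res, 1),
           den = purrr::map_dbl(.data$res, 2)) |>
    filter(.data$num != 0) |>
    mutate(net = .data$num / .data$den,
           direction = ifelse(.data$num < 0, "consumed", "produced"),
           class = ifelse(.data$species %in% policy$efm_removed,
                          "cofactor", "other_unbalanced")) |>
    select("species", "num", "den", "net", "direction", "class") |>
    arrange(.data$species)
}

#' Net balances for every cyclical mode in a result set
#'
#' @param result a `module_efms` from [enumerate_tree()].
#' @param cycles classification tibble from [classify_cycles()].
#' @param base_model the full base model.
#' @param policy a `cofactor_policy`.
#' @return tibble: `module_id`, `efm_id`, plus the [net_balance()] columns.
#' @export
cycle_balances <- function(result, cycles, base_model, policy) {
  cyc <- cycles |> filter(.data$cyclical)
  out <- list()
  for (i in seq_len(nrow(cyc))) {
    mm <- result$modes |>
      filter(.data$module_id == cyc$module_id[i],
             .data$efm_id == cyc$efm_id[i])
    # drop reactions absent from the base model only if truly unknown: error
    nb <- net_balance(mm, base_model, policy)
    if (nrow(nb) > 0) {
      out[[length(out) + 1]] <- nb |>
        mutate(module_id = cyc$module_id[i], efm_id = cyc$efm_id[i])
    }
  }
  if (length(out) == 0) {
    return(tibble(module_id = integer(), efm_id = integer(),
                  species = character(), num = numeric(), den = numeric(),
                  net = numeric(), direction = character(),
                  class = character()))
  }
  bind_rows(out) |>
    select("module_id", "efm_id", "species", "num", "den", "net",
           "direction", "class")
}

#' Cofactor participation summary
#'
#' For each species, the number of cyclical modes that net-consume and
#' net-produce it (a mode counts once per species per direction regardless of
#' stoichiometric magnitude). Sorted by total participation descending, ties
#' by id.
#'
#' @param balances tibble from [cycle_balances()] (or any tibble with
#'   `module_id`, `efm_id`, `species`, `direction`).
#' @return tibble with columns `species`, `n_consumed`, `n_produced`.
#' @export
summarize_cofactors <- function(balances) {
  if (nrow(balances) == 0) {
    return(tibble(species = character(), n_consumed = integer(),
                  n_produced = integer()))
  }
  balances |>
    distinct(.data$module_id, .data$efm_id, .data$species,
             .data$direction) |>
    group_by(.data$species) |>
    summarise(n_consumed = sum(.data$direction == "consumed"),
              n_produced = sum(.data$direction == "produced"),
              .groups = "drop") |>
    arrange(desc(.data$n_consumed + .data$n_produced), .data$species)
}

#' Per-module cyclical-mode length statistics
#'
#' Length of a mode is its number of active reactions. Modules with no
#' cyclical modes are reported with `n_cyclical = 0` and `NA` statistics.
#'
#' @param tree a `partition_tree`.
#' @param cycles classification tibble from [classify_cycles()].
#' @return a `cycle_length_stats` tibble: `module_id`, `n_reactions`,
#'   `n_cyclical`, `median_length`, `min_length`, `max_length`, `histogram`
#'   (list-column of length counts).
#' @export
length_stats <- function(tree, cycles) {
  cyc <- cycles |> filter(.data$cyclical)
  stats <- if (nrow(cyc) == 0) {
    tibble(module_id = integer(), n_cyclical = integer(),
           median_length = numeric(), min_length = integer(),
           max_length = integer(), histogram = list())
  } else cyc |>
    group_by(.data$module_id) |>
    summarise(n_cyclical = n(),
              median_length = median(.data$length),
              min_length = min(.data$length),
              max_length = max(.data$length),
              histogram = list(table(.data$length)),
              .groups = "drop")
  out <- tibble(module_id = tree$module_id,
                n_reactions = tree$n_reactions) |>
    left_join(stats, by = "module_id") |>
    mutate(n_cyclical = ifelse(is.na(.data$n_cyclical), 0L,
                               .data$n_cyclical))
  class(out) <- c("cycle_length_stats", class(out))
  out
}

#' Plot median cyclical-mode length against module size
#'
#' @param object a `cycle_length_stats` tibble from [length_stats()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cycle_length_stats <- function(object, ...) {
  dat <- object |> filter(.data$n_cyclical > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_reactions,
                                    y = .data$median_length)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_cyclical),
                        alpha = 0.7) +
    ggplot2::labs(x = "reactions in module",
                  y = "median cyclical mode length",
                  size = "cyclical modes") +
    ggplot2::theme_minimal()
}
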