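#' Split reversible reactions into irreversible column pairs
#'
#' Builds the split system on which the flux cone is pointed: each reversible
#' reaction contributes a forward and a negated reverse column (adjacent,
#' forward first); irreversible reactions contribute one column. The matrix is
#' the exact integer stoichiometric matrix of the model.
#'
#' @param model a `metabolic_model` (usually a module submodel).
#' @return a `split_system`: list with `S` (metabolites x split columns,
#'   integer-valued) and `map` (tibble `col`, `reaction_id`, `dir`).
#' @export
split_reversibles <- function(model) {
  S0 <- smatrix(model)
  cols <- list()
  map <- list()
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    v <- S0[, rid]
    cols[[length(cols) + 1]] <- v
    map[[length(map) + 1]] <- tibble(reaction_id = rid, dir = "fwd")
    if (model$reactions$reversible[i]) {
      cols[[length(cols) + 1]] <- -v
      map[[length(map) + 1]] <- tibble(reaction_id = rid, dir = "rev")
    }
  }
  S <- if (length(cols) > 0) do.call(cbind, cols) else
    matrix(0, nrow = nrow(S0), ncol = 0)
  rownames(S) <- rownames(S0)
  map <- if (length(map) > 0) bind_rows(map) else
    tibble(reaction_id = character(), dir = character())
  map$col <- seq_len(nrow(map))
  structure(list(S = S, map = map[, c("col", "reaction_id", "dir")]),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat("<split_system>", nrow(x$S), "metabolites x", ncol(x$S),
      "split columns\n")
  invisible(x)
}

# map split-space rays (columns of R, n_split x k) back to signed modes on
# original reactions; applies the split-pair and both-direction exclusions
# and the support-size-1 default exclusion
.rays_to_modes <- function(R, system, include_isomerization = FALSE) {
  map <- system$map
  modes <- list()
  iso <- list()
  if (ncol(R) > 0) {
    for (k in seq_len(ncol(R))) {
      x <- R[, k]
      supp <- which(x != 0)
      rids <- map$reaction_id[supp]
      both <- unique(rids[duplicated(rids)])
      if (length(both) > 0) {
        # both directions of one reaction active: either the futile split
        # pair (an isomerization-style cycle) or a non-extreme candidate
        if (include_isomerization && length(supp) == 2 &&
            length(unique(rids)) == 1) {
          iso[[length(iso) + 1]] <- unique(rids)
        }
        next
      }
      coef <- ifelse(map$dir[supp] == "fwd", x[supp], -x[supp])
      names(coef) <- rids
      if (length(coef) <= 1) next  # single-reaction modes not reported
      modes[[length(modes) + 1]] <- coef
    }
  }
  .canonical_modes(modes, iso)
}

# order modes by (support size, lexicographic support) and build the tidy
# output tibble; integer coefficients are gcd-reduced, `coefficient` is the
# unit-flux normalization (smallest absolute coefficient 1). A fully
# reversible mode is a ray in both orientations; it is reported once, with
# positive flux through its smallest reaction id.
.canonical_modes <- function(modes, iso = list()) {
  modes <- lapply(modes, function(m) {
    m <- m[order(names(m))]
    int_reduce(m)
  })
  if (length(modes) > 1) {
    sig <- vapply(modes, function(m)
      paste(names(m), abs(m), sep = ":", collapse = ";"), character(1))
    keep <- rep(TRUE, length(modes))
    for (grp in split(seq_along(modes), sig)) {
      if (length(grp) < 2) next
      for (a in grp) {
        for (b in grp) {
          if (a < b && keep[a] && keep[b] &&
              all(modes[[a]] == -modes[[b]])) {
            drop_idx <- if (modes[[a]][1] > 0) b else a
            keep[drop_idx] <- FALSE
          }
        }
      }
    }
    modes <- modes[keep]
  }
  if (length(iso) > 0) {
    for (r in unique(unlist(iso))) {
      m <- setNames(1, r)
      attr(m, "isomerization") <- TRUE
      modes[[length(modes) + 1]] <- m
    }
  }
  if (length(modes) == 0) {
    return(tibble(efm_id = integer(), reaction_id = character(),
                  coef_int = numeric(), coefficient = numeric(),
                  isomerization = logical()))
  }
  key <- vapply(modes, function(m)
    sprintf("%04d|%s", length(m), paste(names(m), collapse = ",")),
    character(1))
  modes <- modes[order(key)]
  bind_rows(lapply(seq_along(modes), function(i) {
    m <- modes[[i]]
    tibble(
      efm_id = i,
      reaction_id = names(m),
      coef_int = unname(m),
      coefficient = unname(m) / min(abs(m)),
      isomerization = isTRUE(attr(m, "isomerization"))
    )
  }))
}

#' Enumerate elementary flux modes of a split system
#'
#' Double description of the flux cone `{x >= 0 : S x = 0}` in exact integer
#' arithmetic: rays start at the coordinate axes and each balance constraint
#' is imposed in turn, combining adjacent positive/negative ray pairs
#' (adjacency by the combinatorial support test) and reducing every new ray
#' by its gcd. The surviving extreme rays are the elementary modes of the
#' split network; split-pair futile modes and candidates activating both
#' directions of one reaction are excluded, and modes are mapped back to
#' signed coefficients on the original reactions. Modes supported on a single
#' original reaction (reversible isomerizations run in both directions) are
#' suppressed by default.
#'
#' The time budget is checked cooperatively between iterations; on timeout an
#' empty mode set with status `"timed_out"` is returned (all-or-nothing per
#' module).
#'
#' @param system a `split_system`.
#' @param time_budget wall-clock seconds allowed for the enumeration.
#' @param include_isomerization if `TRUE`, single-reaction cycles (both
#'   directions of one reversible reaction) are reported as modes of length 1.
#' @return list with `modes` (tibble `efm_id`, `reaction_id`, `coef_int`,
#'   `coefficient`, `isomerization`) and `status` (`"complete"` or
#'   `"timed_out"`).
#' @export
enumerate_efms <- function(system, time_budget = 3600,
                           include_isomerization = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  timed_out <- function() proc.time()[["elapsed"]] - t0 >= time_budget
  empty <- .canonical_modes(list())
  if (time_budget <= 0) {
    return(list(modes = empty, status = "timed_out"))
  }
  S <- system$S
  # zero columns only ever yield the excluded single-reaction modes
  nonzero <- which(colSums(S != 0) > 0)
  S <- S[, nonzero, drop = FALSE]
  n <- ncol(S)
  if (n == 0) return(list(modes = empty, status = "complete"))
  R <- diag(1, n)
  # impose denser rows last (standard double-description ordering heuristic)
  row_order <- order(rowSums(S != 0))
  for (ri in row_order) {
    a <- S[ri, ]
    v <- as.vector(a %*% R)
    check_exact(v)
    if (all(v == 0)) next
    zero <- which(v == 0)
    pos <- which(v > 0)
    neg <- which(v < 0)
    Supp <- R != 0
    new_rays <- list()
    for (p in pos) {
      if (timed_out()) return(list(modes = empty, status = "timed_out"))
      for (q in neg) {
        u <- Supp[, p] | Supp[, q]
        # adjacency: no third ray's support fits inside the union
        inside <- colSums(Supp & !u) == 0
        inside[c(p, q)] <- FALSE
        if (any(inside)) next
        r <- v[p] * R[, q] - v[q] * R[, p]
        check_exact(r)
        new_rays[[length(new_rays) + 1]] <- int_reduce(r)
      }
    }
    R <- cbind(R[, zero, drop = FALSE],
               if (length(new_rays) > 0) do.call(cbind, new_rays))
    if (is.null(R) || ncol(R) == 0) {
      return(list(modes = empty, status = "complete"))
    }
  }
  # lift rays back to the full split-column space
  full <- matrix(0, nrow = ncol(system$S), ncol = ncol(R))
  full[nonzero, ] <- R
  list(modes = .rays_to_modes(full, system, include_isomerization),
       status = "complete")
}

#' Brute-force elementary mode oracle
#'
#' Independent oracle for testing [enumerate_efms()]: every support subset
#' `T` of the split columns is examined; `T` carries a mode iff the exact
#' nullspace of `S[, T]` is one-dimensional and spanned by a vector strictly
#' positive on `T`. Candidate supports are then filtered to the minimal ones
#' and the same exclusions applied.
#'
#' @param system a `split_system`.
#' @param guard refuse systems with more than this many columns (subset
#'   enumeration is exponential).
#' @param include_isomerization as in [enumerate_efms()].
#' @return tibble in the same canonical form as `enumerate_efms()$modes`.
#' @export
brute_force_efms <- function(system, guard = 20,
                             include_isomerization = FALSE) {
  S <- system$S
  n <- ncol(S)
  if (n > guard) {
    abort(paste0("brute_force_efms: ", n, " columns exceeds guard ", guard))
  }
  supports <- list()
  vectors <- list()
  if (n > 0) {
    for (code in seq_len(2^n - 1)) {
      T_ <- which(bitwAnd(code, bitwShiftL(1, seq_len(n) - 1)) != 0)
      NS <- int_nullspace(S[, T_, drop = FALSE])
      if (ncol(NS) != 1) next
      vvec <- NS[, 1]
      if (any(vvec == 0)) next
      if (all(vvec < 0)) vvec <- -vvec
      if (any(vvec < 0)) next
      x <- numeric(n)
      x[T_] <- vvec
      supports[[length(supports) + 1]] <- T_
      vectors[[length(vectors) + 1]] <- x
    }
  }
  # support minimality
  keep <- rep(TRUE, length(supports))
  for (i in seq_along(supports)) {
    for (j in seq_along(supports)) {
      if (i != j && keep[i] &&
          length(supports[[j]]) < length(supports[[i]]) &&
          all(supports[[j]] %in% supports[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  R <- if (any(keep)) do.call(cbind, vectors[keep]) else
    matrix(0, nrow = n, ncol = 0)
  .rays_to_modes(R, system, include_isomerization)
}

#' Enumerate modes over a partition tree
#'
#' Visits modules in increasing height (leaves first); for each, the module
#' submodel is extracted from the EFM-variant model, reversibles are split and
#' modes enumerated under the per-module time budget. Modules that time out
#' are recorded as skipped; their ancestors are still attempted.
#'
#' @param tree a `partition_tree` (built on the ShReD variant).
#' @param model_efm the EFM-variant `metabolic_model`. Module reactions not
#'   present in it (e.g. pure cofactor-interconversion reactions stripped by
#'   the policy) are ignored.
#' @param time_budget seconds per module.
#' @param include_isomerization as in [enumerate_efms()].
#' @return a `module_efms` object: list with `modes` (tibble `module_id`,
#'   `efm_id`, `reaction_id`, `coef_int`, `coefficient`, `isomerization`) and
#'   `log` (tibble `module_id`, `n_reactions`, `n_modes`, `status`,
#'   `wall_seconds`).
#' @export
enumerate_tree <- function(tree, model_efm, time_budget = 3600,
                           include_isomerization = FALSE) {
  order_ids <- module_height_order(tree)
  modes_out <- list()
  log_out <- list()
  for (mid in order_ids) {
    rids <- intersect(tree$reactions[[which(tree$module_id == mid)]],
                      model_efm$reactions$id)
    t0 <- proc.time()[["elapsed"]]
    if (length(rids) == 0) {
      res <- list(modes = .canonical_modes(list()), status = "complete")
    } else {
      sub <- extract_module_submodel(model_efm, rids)
      res <- enumerate_efms(split_reversibles(sub),
                            time_budget = time_budget,
                            include_isomerization = include_isomerization)
    }
    wall <- proc.time()[["elapsed"]] - t0
    if (nrow(res$modes) > 0) {
      modes_out[[length(modes_out) + 1]] <-
        mutate(res$modes, module_id = mid)
    }
    log_out[[length(log_out) + 1]] <- tibble(
      module_id = mid, n_reactions = length(rids),
      n_modes = if (nrow(res$modes) > 0) max(res$modes$efm_id) else 0L,
      status = if (res$status == "timed_out") "skipped" else "complete",
      wall_seconds = wall
    )
  }
  modes <- if (length(modes_out) > 0) {
    bind_rows(modes_out) |>
      select("module_id", "efm_id", "reaction_id", "coef_int",
             "coefficient", "isomerization")
  } else {
    tibble(module_id = integer(), efm_id = integer(),
           reaction_id = character(), coef_int = numeric(),
           coefficient = numeric(), isomerization = logical())
  }
  structure(list(modes = modes, log = bind_rows(log_out)),
            class = "module_efms")
}

#' @export
print.module_efms <- function(x, ...) {
  cat("<module_efms>", sum(x$log$n_modes), "modes over", nrow(x$log),
      "modules (", sum(x$log$status == "skipped"), "skipped )\n")
  invisible(x)
}

#' @export
tidy.module_efms <- function(x, ...) x$modes

#' @export
glance.module_efms <- function(x, ...) {
  tibble(
    n_modules = nrow(x$log),
    n_complete = sum(x$log$status == "complete"),
    n_skipped = sum(x$log$status == "skipped"),
    n_modes = sum(x$log$n_modes),
    total_wall_seconds = sum(x$log$wall_seconds)
  )
}
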