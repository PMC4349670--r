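#' Construct a metabolic model
#'
#' A `metabolic_model` bundles compartment-tagged metabolites, reactions with
#' reversibility flags, and a sparse stoichiometry held as a long tibble with
#' exact rational coefficients (numerator/denominator columns). Negative
#' coefficients denote consumption, positive production.
#'
#' @param metabolites tibble with columns `id`, `name`, `compartment`.
#' @param reactions tibble with columns `id`, `reversible` (logical).
#' @param stoich tibble with columns `reaction_id`, `metabolite_id`,
#'   `num`, `den` (exact rational coefficient `num/den`, nonzero).
#' @param provenance one of `"base"`, `"efm_variant"`, `"shred_variant"`,
#'   `"module_submodel"`.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoich,
                            provenance = c("base", "efm_variant",
                                           "shred_variant",
                                           "module_submodel")) {
  provenance <- match.arg(provenance)
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stoich <- as_tibble(stoich)
  validate_model(metabolites, reactions, stoich)
  structure(
    list(metabolites = metabolites, reactions = reactions,
         stoich = stoich, provenance = provenance),
    class = "metabolic_model"
  )
}

validate_model <- function(metabolites, reactions, stoich) {
  if (anyDuplicated(metabolites$id)) {
    abort("duplicate metabolite id")
  }
  if (anyDuplicated(reactions$id)) {
    abort("duplicate reaction id")
  }
  if (nrow(stoich) > 0) {
    missing_m <- setdiff(stoich$metabolite_id, metabolites$id)
    if (length(missing_m) > 0) {
      abort(paste("reaction references undeclared metabolite:",
                  paste(missing_m, collapse = ", ")))
    }
    missing_r <- setdiff(stoich$reaction_id, reactions$id)
    if (length(missing_r) > 0) {
      abort(paste("stoichiometry references unknown reaction:",
                  paste(missing_r, collapse = ", ")))
    }
    if (any(stoich$num == 0)) abort("zero stoichiometric coefficient")
    if (anyDuplicated(stoich[, c("reaction_id", "metabolite_id")])) {
      abort("metabolite listed twice in one reaction")
    }
  }
  # compartment tag embedded in the id must match the compartment field
  tag <- compartment_of(metabolites$id)
  bad <- which(!is.na(tag) & tag != metabolites$compartment)
  if (length(bad) > 0) {
    abort(paste("id/compartment mismatch for:",
                paste(metabolites$id[bad], collapse = ", ")))
  }
  invisible(TRUE)
}

# compartment tag from an id of the form "Name(tag)"; NA when untagged
compartment_of <- function(id) {
  m <- regmatches(id, regexec("\\(([^()]+)\\)$", id))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> [", x$provenance, "]\n", sep = "")
  cat("  metabolites:", nrow(x$metabolites), "\n")
  cat("  reactions:  ", nrow(x$reactions),
      sprintf(" (%d reversible)", sum(x$reactions$reversible)), "\n")
  invisible(x)
}

#' Tidy a metabolic model into its long stoichiometry table
#'
#' @param x a `metabolic_model`.
#' @param ... unused.
#' @return tibble with one row per (reaction, metabolite) pair: `reaction_id`,
#'   `metabolite_id`, `coefficient` (numeric value of the exact rational),
#'   `num`, `den`, `reversible`, `compartment`.
#' @export
tidy.metabolic_model <- function(x, ...) {
  x$stoich |>
    mutate(coefficient = .data$num / .data$den) |>
    left_join(x$reactions, by = c(reaction_id = "id")) |>
    left_join(select(x$metabolites, "id", "compartment"),
              by = c(metabolite_id = "id")) |>
    select("reaction_id", "metabolite_id", "coefficient",
           "num", "den", "reversible", "compartment")
}

#' @export
glance.metabolic_model <- function(x, ...) {
  tibble(
    provenance = x$provenance,
    n_metabolites = nrow(x$metabolites),
    n_reactions = nrow(x$reactions),
    n_reversible = sum(x$reactions$reversible),
    n_entries = nrow(x$stoich)
  )
}

# drop metabolites no longer referenced by any reaction
drop_orphan_metabolites <- function(model) {
  keep <- model$metabolites$id %in% unique(model$stoich$metabolite_id)
  model$metabolites <- model$metabolites[keep, , drop = FALSE]
  model
}

# rebuild a model after subsetting, revalidating invariants
rebuild_model <- function(model, provenance = model$provenance) {
  metabolic_model(model$metabolites, model$reactions, model$stoich,
                  provenance = provenance)
}

#' Integer stoichiometric matrix of a model
#'
#' Rows are metabolites, columns reactions. Each row is scaled by the least
#' common multiple of its rational denominators, which leaves the nullspace
#' (and hence the flux modes) unchanged while making every entry an exact
#' integer.
#'
#' @param model a `metabolic_model`.
#' @return integer-valued numeric matrix with metabolite/reaction dimnames.
#' @export
smatrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  if (nrow(model$stoich) > 0) {
    st <- model$stoich
    S[cbind(match(st$metabolite_id, mets), match(st$reaction_id, rxns))] <-
      st$num / st$den
    # clear denominators row-wise
    for (i in seq_along(mets)) {
      dens <- st$den[st$metabolite_id == mets[i]]
      l <- lcm_all(dens)
      if (l != 1) S[i, ] <- S[i, ] * l
    }
  }
  check_exact(S)
  S
}
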