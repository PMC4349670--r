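#' Remove boundary (exchange) reactions
#'
#' Drops every reaction that produces or consumes a metabolite in a boundary
#' compartment (extracellular by default), focusing the analysis on flux
#' modes internal to the network. Metabolites left unreferenced are dropped.
#'
#' @param model a `metabolic_model`.
#' @param boundary_tags compartment tags considered extracellular.
#' @return a `metabolic_model`.
#' @export
remove_boundary_reactions <- function(model, boundary_tags = "x") {
  boundary_met <- model$metabolites$id[
    model$metabolites$compartment %in% boundary_tags
  ]
  touched <- unique(model$stoich$reaction_id[
    model$stoich$metabolite_id %in% boundary_met
  ])
  model$reactions <- model$reactions[!model$reactions$id %in% touched, ,
                                     drop = FALSE]
  model$stoich <- model$stoich[!model$stoich$reaction_id %in% touched, ,
                               drop = FALSE]
  model <- drop_orphan_metabolites(model)
  rebuild_model(model)
}

#' Apply a cofactor policy to derive a working model
#'
#' For `variant = "efm"` every metabolite in `policy$efm_removed` is deleted
#' from all stoichiometries (these species are deliberately left unbalanced so
#' that cyclical flux modes on the stripped network are candidate substrate
#' cycles); for `variant = "shred"` only `policy$shred_removed` is deleted, so
#' regulatory cofactors keep mediating retroactive couplings. Reactions left
#' with empty stoichiometry are dropped. Coefficients of retained metabolites
#' are never altered.
#'
#' @param model a `metabolic_model` (boundary reactions usually already
#'   removed).
#' @param policy a `cofactor_policy`.
#' @param variant `"efm"` or `"shred"`.
#' @return a `metabolic_model` with the matching provenance.
#' @export
apply_cofactor_policy <- function(model, policy, variant = c("efm", "shred")) {
  variant <- match.arg(variant)
  remove <- if (variant == "efm") policy$efm_removed else policy$shred_removed
  absent <- setdiff(remove, model$metabolites$id)
  if (length(absent) > 0) {
    warn(paste0("policy ids absent from model (ignored): ",
                paste(head(absent, 5), collapse = ", "),
                if (length(absent) > 5) ", ..." else ""))
  }
  model$stoich <- model$stoich[!model$stoich$metabolite_id %in% remove, ,
                               drop = FALSE]
  keep_rxn <- model$reactions$id %in% unique(model$stoich$reaction_id)
  model$reactions <- model$reactions[keep_rxn, , drop = FALSE]
  model$metabolites <- model$metabolites[
    !model$metabolites$id %in% remove, , drop = FALSE
  ]
  model <- drop_orphan_metabolites(model)
  rebuild_model(model, provenance = paste0(variant, "_variant"))
}

#' Prune dead-end metabolites to a fixed point
#'
#' Iteratively deletes every metabolite lacking either a producing or a
#' consuming reaction (a reversible reaction counts as both) from all
#' stoichiometries, until no such metabolite remains. Reactions are kept even
#' if their stoichiometry empties: they become net producers/consumers of
#' nothing at the deleted species, which is exactly what turns an open
#' pathway into a linear (non-cyclical) flux mode.
#'
#' @param model a `metabolic_model`.
#' @return a `metabolic_model` in which every surviving metabolite has at
#'   least one producer and one consumer.
#' @export
prune_dead_ends <- function(model) {
  repeat {
    if (nrow(model$stoich) == 0) break
    st <- model$stoich |>
      left_join(select(model$reactions, "id", "reversible"),
                by = c(reaction_id = "id"))
    status <- st |>
      group_by(.data$metabolite_id) |>
      summarise(
        has_producer = any(.data$num > 0 | .data$reversible),
        has_consumer = any(.data$num < 0 | .data$reversible),
        .groups = "drop"
      )
    dead <- status$metabolite_id[!(status$has_producer & status$has_consumer)]
    if (length(dead) == 0) break
    model$stoich <- model$stoich[!model$stoich$metabolite_id %in% dead, ,
                                 drop = FALSE]
    model$metabolites <- model$metabolites[
      !model$metabolites$id %in% dead, , drop = FALSE
    ]
  }
  model <- drop_orphan_metabolites(model)
  rebuild_model(model)
}

#' Extract a module submodel
#'
#' Takes the stoichiometry columns of the given reactions and prunes dead-end
#' metabolites within the submodel, yielding the system on which elementary
#' flux modes are enumerated for that module.
#'
#' @param model_efm the EFM-variant `metabolic_model`.
#' @param reaction_ids character vector of reaction ids in `model_efm`.
#' @return a `metabolic_model` with provenance `"module_submodel"`.
#' @export
extract_module_submodel <- function(model_efm, reaction_ids) {
  reaction_ids <- unique(as.character(reaction_ids))
  unknown <- setdiff(reaction_ids, model_efm$reactions$id)
  if (length(unknown) > 0) {
    abort(paste("unknown reaction id(s):", paste(unknown, collapse = ", ")))
  }
  model_efm$reactions <- model_efm$reactions[
    model_efm$reactions$id %in% reaction_ids, , drop = FALSE
  ]
  model_efm$stoich <- model_efm$stoich[
    model_efm$stoich$reaction_id %in% reaction_ids, , drop = FALSE
  ]
  model_efm <- drop_orphan_metabolites(model_efm)
  sub <- rebuild_model(model_efm, provenance = "module_submodel")
  sub <- prune_dead_ends(sub)
  sub$provenance <- "module_submodel"
  sub
}
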