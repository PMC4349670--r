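#' Read a metabolic model
#'
#' Supports two formats: the native tab-separated reaction-equation format
#' (`reaction_id<TAB>equation`, arrows `-->` irreversible and `<=>`
#' reversible, metabolite tokens `Name(compartment)`, optional leading
#' integer or rational coefficients such as `2 H2O(c)` or `1/2 O2(c)`) and
#' SBML Level 2/3 (read-only, species/reaction/stoichiometry/reversibility).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"native_tsv"`, or `"sbml"`.
#' @return a `metabolic_model` with provenance `"base"`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("R1\tA(c) --> B(c)", tf)
#' load_model(tf)
load_model <- function(path, format = c("auto", "native_tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("file not found:", path))
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else {
      "native_tsv"
    }
  }
  switch(format,
    native_tsv = read_native_model(path),
    sbml = read_sbml_model(path)
  )
}

#' Build a model from reaction equations
#'
#' @param equations named character vector: names are reaction ids, values
#'   equations in the native syntax (see [load_model()]).
#' @return a `metabolic_model`.
#' @export
#' @examples
#' model_from_equations(c(R1 = "A(c) --> B(c)", R2 = "B(c) <=> A(c)"))
model_from_equations <- function(equations) {
  ids <- names(equations)
  if (is.null(ids) || any(ids == "")) abort("equations must be named by reaction id")
  if (anyDuplicated(ids)) abort("duplicate reaction id")
  parsed <- lapply(seq_along(equations), function(i) {
    parse_equation(equations[[i]], ids[[i]])
  })
  reactions <- tibble(
    id = ids,
    reversible = vapply(parsed, `[[`, logical(1), "reversible")
  )
  stoich <- bind_rows(lapply(parsed, `[[`, "stoich"))
  met_ids <- unique(stoich$metabolite_id)
  metabolites <- tibble(
    id = met_ids,
    name = sub("\\([^()]+\\)$", "", met_ids),
    compartment = compartment_of(met_ids)
  )
  metabolic_model(metabolites, reactions, stoich, provenance = "base")
}

#' @rdname load_model
#' @export
read_native_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[lines != "" & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(metabolic_model(
      tibble(id = character(), name = character(), compartment = character()),
      tibble(id = character(), reversible = logical()),
      tibble(reaction_id = character(), metabolite_id = character(),
             num = numeric(), den = numeric())
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad) > 0) {
    abort(paste0("malformed line (expected 'id<TAB>equation'): '",
                 lines[bad[1]], "'"))
  }
  eqs <- vapply(parts, function(p) paste(p[-1], collapse = "\t"), character(1))
  names(eqs) <- vapply(parts, `[[`, character(1), 1)
  model_from_equations(eqs)
}

# parse one equation into reversible flag + long stoichiometry rows
parse_equation <- function(eq, reaction_id) {
  eq <- trimws(eq)
  reversible <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "-->"
  if (!reversible && !grepl("-->", eq, fixed = TRUE)) {
    abort(paste0("reaction '", reaction_id,
                 "': no arrow ('-->' or '<=>') in equation '", eq, "'"))
  }
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2) {
    abort(paste0("reaction '", reaction_id, "': multiple arrows"))
  }
  lhs <- if (length(sides) >= 1) sides[1] else ""
  rhs <- if (length(sides) == 2) sides[2] else ""
  rows <- bind_rows(
    parse_side(lhs, -1, reaction_id),
    parse_side(rhs, +1, reaction_id)
  )
  if (nrow(rows) == 0) {
    abort(paste0("reaction '", reaction_id, "': empty equation"))
  }
  # net out a species appearing on both sides
  rows <- rows |>
    group_by(.data$metabolite_id) |>
    summarise(res = list(Reduce(
      function(a, b) {
        s <- rat_add(a[1], a[2], b[1], b[2])
        c(s$num, s$den)
      },
      purrr::map2(.data$num, .data$den, c)
    )), .groups = "drop") |>
    mutate(num = purrr::map_dbl(.data$res, 1),
           den = purrr::map_dbl(.data$res, 2)) |>
    filter(.data$num != 0) |>
    mutate(reaction_id = reaction_id) |>
    select("reaction_id", "metabolite_id", "num", "den")
  list(reversible = reversible, stoich = rows)
}

parse_side <- function(side, sgn, reaction_id) {
  side <- trimws(side)
  if (side == "") {
    return(tibble(metabolite_id = character(), num = numeric(),
                  den = numeric()))
  }
  terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
  terms <- terms[terms != ""]
  out <- lapply(terms, function(tok) {
    m <- regmatches(tok, regexec("^([0-9]+(?:/[0-9]+)?)\\s+(.*)$", tok))[[1]]
    if (length(m) == 3) {
      coef <- rat_parse(m[2])
      tok <- m[3]
    } else {
      coef <- c(num = 1, den = 1)
    }
    tok <- trimws(tok)
    if (!grepl("^.*\\([^()]+\\)$", tok)) {
      abort(paste0("reaction '", reaction_id,
                   "': malformed metabolite token '", tok,
                   "' (expected 'Name(compartment)')"))
    }
    tibble(metabolite_id = tok, num = sgn * coef[["num"]],
           den = coef[["den"]])
  })
  bind_rows(out)
}

#' Write a model in the native reaction-equation format
#'
#' Inverse of [read_native_model()]: `read_native_model(write_native_model(m))`
#' reproduces `m` up to term ordering (substrates/products sorted by id).
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_native_model <- function(model, path) {
  lines <- vapply(seq_len(nrow(model$reactions)), function(i) {
    rid <- model$reactions$id[i]
    rev <- model$reactions$reversible[i]
    st <- model$stoich |>
      filter(.data$reaction_id == rid) |>
      arrange(.data$metabolite_id)
    fmt <- function(rows) {
      if (nrow(rows) == 0) return("")
      paste(vapply(seq_len(nrow(rows)), function(j) {
        cnum <- abs(rows$num[j])
        cden <- rows$den[j]
        coef <- if (cnum == 1 && cden == 1) {
          ""
        } else if (cden == 1) {
          paste0(cnum, " ")
        } else {
          paste0(cnum, "/", cden, " ")
        }
        paste0(coef, rows$metabolite_id[j])
      }, character(1)), collapse = " + ")
    }
    lhs <- fmt(st[st$num < 0, , drop = FALSE])
    rhs <- fmt(st[st$num > 0, , drop = FALSE])
    arrow <- if (rev) "<=>" else "-->"
    paste0(rid, "\t", lhs, " ", arrow, " ", rhs)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# --- SBML ------------------------------------------------------------------

#' @rdname load_model
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0) abort("no species found in SBML file")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  # normalize ids to Name(tag) so the compartment tag is part of the id
  tagged <- paste0(sp_id, "(", sp_comp, ")")
  metabolites <- tibble(id = tagged, name = sp_id, compartment = sp_comp)
  id_map <- setNames(tagged, sp_id)

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rx_id <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(rx_id)) abort("duplicate reaction id in SBML file")
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible")
  reversible <- !(tolower(rev_attr) %in% "false")  # SBML default is true
  side_rows <- function(node, xp, sgn) {
    refs <- xml2::xml_find_all(node, xp)
    if (length(refs) == 0) return(NULL)
    sref <- xml2::xml_attr(refs, "species")
    sval <- xml2::xml_attr(refs, "stoichiometry")
    sval[is.na(sval)] <- "1"
    tibble(metabolite_ref = sref, coef = sgn * as.numeric(sval))
  }
  stoich <- bind_rows(lapply(seq_along(rx_nodes), function(i) {
    rows <- bind_rows(
      side_rows(rx_nodes[[i]], "./listOfReactants/speciesReference", -1),
      side_rows(rx_nodes[[i]], "./listOfProducts/speciesReference", +1)
    )
    if (is.null(rows) || nrow(rows) == 0) return(NULL)
    rows |>
      group_by(.data$metabolite_ref) |>
      summarise(coef = sum(.data$coef), .groups = "drop") |>
      filter(.data$coef != 0) |>
      mutate(reaction_id = rx_id[i])
  }))
  unknown <- setdiff(stoich$metabolite_ref, sp_id)
  if (length(unknown) > 0) {
    abort(paste("SBML reaction references undeclared species:",
                paste(unknown, collapse = ", ")))
  }
  stoich <- stoich |>
    mutate(metabolite_id = unname(id_map[.data$metabolite_ref])) |>
    mutate(rat = purrr::map(.data$coef, ~ rat_reduce(round(.x * 10^6), 10^6))) |>
    mutate(num = purrr::map_dbl(.data$rat, "num"),
           den = purrr::map_dbl(.data$rat, "den")) |>
    select("reaction_id", "metabolite_id", "num", "den")
  metabolic_model(metabolites,
                  tibble(id = rx_id, reversible = reversible),
                  stoich, provenance = "base")
}

# --- cofactor policy -------------------------------------------------------

#' Cofactor policy
#'
#' Which metabolites to strip before elementary-flux-mode analysis
#' (`efm_removed`) versus before retroactivity (ShReD) analysis
#' (`shred_removed`). Regulatory cofactors such as ATP or NADH typically
#' appear only in `efm_removed` — they are retained for ShReD because they
#' mediate retroactive couplings — while inorganic species (water, protons,
#' phosphate, sulfate) appear in both. `shred_removed` must be a subset of
#' `efm_removed`.
#'
#' @param efm_removed character vector of metabolite ids.
#' @param shred_removed character vector of metabolite ids.
#' @return an object of class `cofactor_policy`.
#' @export
cofactor_policy <- function(efm_removed, shred_removed = character()) {
  efm_removed <- unique(as.character(efm_removed))
  shred_removed <- unique(as.character(shred_removed))
  extra <- setdiff(shred_removed, efm_removed)
  if (length(extra) > 0) {
    abort(paste("shred_removed must be a subset of efm_removed; offending:",
                paste(extra, collapse = ", ")))
  }
  structure(list(efm_removed = efm_removed, shred_removed = shred_removed),
            class = "cofactor_policy")
}

#' @export
print.cofactor_policy <- function(x, ...) {
  cat("<cofactor_policy> efm_removed:", length(x$efm_removed),
      "ids; shred_removed:", length(x$shred_removed), "ids\n")
  invisible(x)
}

#' Read a cofactor policy file
#'
#' Plain text, one metabolite id per line, under section headers
#' `[efm_removed]` and `[shred_removed]`; `#` starts a comment.
#'
#' @param path file path.
#' @return a `cofactor_policy`.
#' @export
read_cofactor_policy <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  section <- NA_character_
  efm <- character()
  shred <- character()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% c("efm_removed", "shred_removed")) {
        abort(paste0("unknown policy section [", section, "]"))
      }
    } else if (is.na(section)) {
      abort("policy entries before any section header")
    } else if (section == "efm_removed") {
      efm <- c(efm, ln)
    } else {
      shred <- c(shred, ln)
    }
  }
  cofactor_policy(efm, shred)
}

#' Write a cofactor policy file
#'
#' @param policy a `cofactor_policy`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cofactor_policy <- function(policy, path) {
  writeLines(c("[efm_removed]", policy$efm_removed,
               "[shred_removed]", policy$shred_removed), path)
  invisible(path)
}

#' Reconstructed default cofactor policy
#'
#' A synthetic reconstruction of a typical cofactor list for a
#' compartmentalized mammalian model: energy and redox carriers (ATP/ADP/AMP,
#' NAD(H), NADP(H), FAD(H2)) are stripped for EFM analysis but retained for
#' ShReD analysis; inorganic species (H2O, H+, Pi, PPi, sulfate, sulfite, O2,
#' CO2, HCO3) are stripped for both. This is the package's own reconstruction,
#' not any published model's curated list; real analyses should supply their
#' model's list via [read_cofactor_policy()].
#'
#' @param compartments compartment tags to instantiate the per-compartment
#'   species for.
#' @return a `cofactor_policy`.
#' @export
default_cofactor_policy <- function(compartments = c("c", "m", "r", "p",
                                                     "n", "x")) {
  regulatory <- c("ATP", "ADP", "AMP", "NADH", "NAD+", "NADPH", "NADP+",
                  "FADH2", "FAD")
  inorganic <- c("H2O", "H+", "Pi", "PPi", "Sulfate", "Sulfite", "O2",
                 "CO2", "HCO3-")
  tag <- function(x) as.vector(outer(x, compartments,
                                     function(a, b) paste0(a, "(", b, ")")))
  cofactor_policy(efm_removed = c(tag(regulatory), tag(inorganic)),
                  shred_removed = tag(inorganic))
}
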