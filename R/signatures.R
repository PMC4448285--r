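#' The thirteen built-in relation ids
#' @return character vector of relation ids.
#' @export
kb_relations <- function() {
  c("affects", "aggravates", "alleviates", "causes", "complicationOf",
    "contraindicates", "createsRisk", "diagnoses", "interacts", "isSymptom",
    "reducesRisk", "sideEffect", "treats")
}

#' Default relation type signatures
#'
#' Each relation constrains the semantic types of its left (domain) and
#' right (range) arguments: for instance `affects` holds between diseases
#' and organs, but not between diseases and drugs.  Type codes here are the
#' coarse built-in codes also used by [default_type_hierarchy()]; the
#' signature file format accepts arbitrary codes.
#'
#' @return data frame of class `type_signatures` with columns `relation`,
#'   `domain_types`, `range_types` (comma-separated codes).
#' @export
default_type_signatures <- function() {
  sig <- data.frame(
    relation = kb_relations(),
    domain_types = c("Disease", "Ecofactor", "Drug", "Disease", "Disease",
                     "Drug", "Ecofactor", "Device", "Drug", "Symptom,Disease",
                     "Drug,Behavior", "Symptom,Disease", "Drug"),
    range_types = c("Organ", "Disease", "Disease", "Disease", "Disease",
                    "Disease", "Disease", "Disease", "Drug", "Disease",
                    "Disease", "Drug", "Disease"),
    stringsAsFactors = FALSE)
  class(sig) <- c("type_signatures", "data.frame")
  sig
}

#' Default coarse semantic-type hierarchy
#'
#' A small forest matching the built-in signatures: seven coarse codes under
#' a single root plus one finer child per coarse code, so depth-based
#' overlap resolution and descendant-aware type checking are exercised.
#'
#' @return a [type_hierarchy()].
#' @export
default_type_hierarchy <- function() {
  coarse <- c("Disease", "Organ", "Ecofactor", "Drug", "Device", "Symptom",
              "Behavior")
  fine <- paste0(coarse, ".fine")
  type_hierarchy(c(
    stats::setNames("", "Entity"),
    stats::setNames(rep("Entity", length(coarse)), coarse),
    stats::setNames(coarse, fine)))
}

#' Read type signatures from TSV
#' @param path TSV with columns `relation`, `domain_types`, `range_types`
#'   (comma-separated type codes).
#' @return a `type_signatures` data frame.
#' @export
read_type_signatures <- function(path) {
  df <- read_tsv_file(path, colClasses = "character")
  need <- c("relation", "domain_types", "range_types")
  if (!all(need %in% names(df)))
    stopf("signature file %s: expected columns %s", path,
          paste(need, collapse = ", "))
  if (any(!nzchar(df$domain_types)) || any(!nzchar(df$range_types)))
    stopf("signature file %s: empty domain or range type set", path)
  class(df) <- c("type_signatures", "data.frame")
  df
}

#' Default mutual-exclusion constraints
#'
#' One documented constraint ships by default: a drug having a symptom as a
#' side effect cannot treat that symptom at the same time --
#' `sideEffect(x, y)` excludes `treats(y, x)` (swapped arguments).  Further
#' constraints can be supplied via [read_exclusions()].
#'
#' @return data frame with columns `relation_a`, `relation_b`,
#'   `argument_map` (`"same"` or `"swapped"`).
#' @export
default_exclusions <- function() {
  data.frame(relation_a = "sideEffect", relation_b = "treats",
             argument_map = "swapped", stringsAsFactors = FALSE)
}

#' Read mutual-exclusion constraints from TSV
#' @param path TSV with columns `relation_a`, `relation_b`, `argument_map`
#'   (`same` or `swapped`).
#' @return exclusion data frame.
#' @export
read_exclusions <- function(path) {
  df <- read_tsv_file(path, colClasses = "character")
  need <- c("relation_a", "relation_b", "argument_map")
  if (!all(need %in% names(df)))
    stopf("exclusion file %s: expected columns %s", path,
          paste(need, collapse = ", "))
  bad <- !df$argument_map %in% c("same", "swapped")
  if (any(bad)) stopf("exclusion file %s: argument_map must be same|swapped", path)
  same_rel <- df$relation_a == df$relation_b & df$argument_map == "same"
  if (any(same_rel))
    stopf("exclusion file %s: a relation cannot exclude itself in same order", path)
  df
}

#' Check a fact candidate against its relation's type signature
#'
#' Passes iff the left entity holds at least one domain type and the right
#' entity at least one range type, where "holds" accepts the signature code
#' itself or any descendant of it in the hierarchy.
#'
#' @param candidate one-row candidate (or list) with `relation`,
#'   `left_entity`, `right_entity`.
#' @param signatures a `type_signatures` data frame.
#' @param entity_types named list mapping entity id to its character vector
#'   of semantic-type codes (see [dictionary_entity_types()]).
#' @param hierarchy a [type_hierarchy()].
#' @return list with `pass` (logical) and `reason` (string, `""` on pass).
#' @export
check_type_signature <- function(candidate, signatures, entity_types,
                                 hierarchy) {
  row <- signatures[signatures$relation == candidate$relation, , drop = FALSE]
  if (nrow(row) == 0L) stopf("unknown relation '%s'", candidate$relation)
  holds <- function(entity, allowed) {
    types <- entity_types[[entity]]
    if (is.null(types)) return(FALSE)
    anc <- unique(unlist(lapply(types, type_ancestors, hierarchy = hierarchy)))
    any(allowed %in% anc)
  }
  dom <- entity_type_codes(row$domain_types)
  rng <- entity_type_codes(row$range_types)
  if (!holds(candidate$left_entity, dom))
    return(list(pass = FALSE,
                reason = sprintf("left entity %s lacks domain type {%s}",
                                 candidate$left_entity, row$domain_types)))
  if (!holds(candidate$right_entity, rng))
    return(list(pass = FALSE,
                reason = sprintf("right entity %s lacks range type {%s}",
                                 candidate$right_entity, row$range_types)))
  list(pass = TRUE, reason = "")
}

#' Entity-to-types lookup from a dictionary
#'
#' @param dict an entity dictionary ([read_dictionary()]).
#' @return named list: entity id -> character vector of type codes (union
#'   over the entity's dictionary rows).
#' @export
dictionary_entity_types <- function(dict) {
  lapply(split(dict$semantic_types, dict$entity_id), function(x)
    unique(unlist(lapply(x, entity_type_codes))))
}

#' Filter candidates by type signature
#'
#' The reasoner's pre-filter: mismatching candidates are pruned before
#' clause grounding, shrinking the hypothesis space of the NP-hard solving
#' step.
#'
#' @param candidates a [build_fact_candidates()] result.
#' @inheritParams check_type_signature
#' @return list with `kept` (candidates passing), `pruned` (failing rows
#'   plus a `reason` column).
#' @export
filter_by_type_signature <- function(candidates, signatures, entity_types,
                                     hierarchy) {
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, pruned = cbind(candidates[0, ], reason = character(0))))
  checks <- lapply(seq_len(nrow(candidates)), function(i)
    check_type_signature(candidates[i, ], signatures, entity_types, hierarchy))
  pass <- vapply(checks, `[[`, logical(1), "pass")
  pruned <- candidates[!pass, , drop = FALSE]
  pruned$reason <- vapply(checks[!pass], `[[`, character(1), "reason")
  kept <- candidates[pass, , drop = FALSE]
  rownames(kept) <- rownames(pruned) <- NULL
  list(kept = kept, pruned = pruned)
}
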