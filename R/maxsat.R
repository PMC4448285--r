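# Weighted Max-Sat reasoning over fact hypotheses.
#
# Clause representation: list(vars = integer vector of hypothesis ids,
# signs = logical vector (TRUE = positive literal), weight = numeric,
# hard = logical).  Hard clauses must be satisfied; soft clause weights are
# the candidate weights from pattern analysis.

new_clause <- function(vars, signs, weight, hard = FALSE) {
  if (anyDuplicated(vars)) {
    # merge duplicate literals; a literal and its negation in one clause is
    # invalid by construction
    if (any(tapply(signs, vars, function(s) length(unique(s)) > 1L)))
      stopf("clause contains a literal and its negation")
    keep <- !duplicated(vars)
    vars <- vars[keep]; signs <- signs[keep]
  }
  list(vars = as.integer(vars), signs = as.logical(signs),
       weight = weight, hard = isTRUE(hard))
}

#' Ground candidates and constraints into weighted clauses
#'
#' Three clause families: a soft unit clause per type-checked candidate,
#' weighted by the candidate weight; a hard binary clause
#' `(!f | !g)` per instantiated mutual exclusion between two candidates; and
#' a hard positive unit clause per seed fact that is itself present among
#' the candidates (seeds are not injected as facts otherwise).
#'
#' @param candidates type-filtered [build_fact_candidates()] rows; hypothesis
#'   id `i` refers to row `i`.
#' @param exclusions exclusion data frame ([default_exclusions()]).
#' @param seeds optional seed data frame; seed triples present among the
#'   candidates are pinned as hard positives.
#' @return list of class `weighted_clauses`: `clauses` (list), `n_vars`.
#'   Raises an infeasibility error when an exclusion instantiates against
#'   two seed-pinned candidates.
#' @export
ground_clauses <- function(candidates, exclusions = default_exclusions(),
                           seeds = NULL) {
  k <- nrow(candidates)
  clauses <- vector("list", 0L)
  for (i in seq_len(k))
    clauses[[length(clauses) + 1L]] <-
      new_clause(i, TRUE, candidates$weight[i], hard = FALSE)
  keys <- if (k > 0L)
    fact_key(candidates$relation, candidates$left_entity, candidates$right_entity)
  else character(0)
  pinned <- rep(FALSE, k)
  if (!is.null(seeds) && nrow(seeds) > 0L && k > 0L) {
    seed_keys <- fact_key(seeds$relation, seeds$left_entity, seeds$right_entity)
    pinned <- keys %in% seed_keys
    for (i in which(pinned))
      clauses[[length(clauses) + 1L]] <- new_clause(i, TRUE, Inf, hard = TRUE)
  }
  if (k > 0L && nrow(exclusions) > 0L) {
    idx <- stats::setNames(seq_len(k), keys)
    seen <- character(0)
    for (x in seq_len(nrow(exclusions))) {
      ra <- exclusions$relation_a[x]; rb <- exclusions$relation_b[x]
      swapped <- exclusions$argument_map[x] == "swapped"
      for (i in which(candidates$relation == ra)) {
        bl <- if (swapped) candidates$right_entity[i] else candidates$left_entity[i]
        br <- if (swapped) candidates$left_entity[i] else candidates$right_entity[i]
        j <- idx[fact_key(rb, bl, br)]
        if (is.na(j) || j == i) next
        pk <- paste(sort(c(i, j)), collapse = "-")
        if (pk %in% seen) next
        seen <- c(seen, pk)
        if (pinned[i] && pinned[j])
          stopf("infeasible: exclusion between seed-pinned facts %s and %s",
                keys[i], keys[j])
        clauses[[length(clauses) + 1L]] <-
          new_clause(c(i, j), c(FALSE, FALSE), Inf, hard = TRUE)
      }
    }
  }
  structure(list(clauses = clauses, n_vars = k), class = "weighted_clauses")
}

#' @export
print.weighted_clauses <- function(x, ...) {
  hard <- sum(vapply(x$clauses, `[[`, logical(1), "hard"))
  cat(sprintf("<weighted_clauses: %d clauses (%d hard) over %d hypotheses>\n",
              length(x$clauses), hard, x$n_vars))
  invisible(x)
}

#' Approximate weighted Max-Sat: dominating unit clauses + Johnson's greedy
#'
#' Two phases.  (1) Dominating-unit-clause preprocessing: any literal whose
#' total unit-clause weight (hard counted as infinite) strictly dominates
#' the total weight of clauses containing its negation is fixed, the clause
#' set simplified, and the pass repeated to a fixed point.  (2) Johnson's
#' heuristic: remaining variables are processed in a deterministic order
#' (descending total incident soft weight, then id); each is assigned the
#' sign maximizing the expected satisfied soft weight of the remaining
#' clauses under uniform random completion (a clause with `u` unassigned
#' literals and no satisfied literal is satisfied with probability
#' `1 - 2^-u`).  Hard clauses act as infinite weight: a sign that would
#' falsify a hard clause outright is never chosen.  The returned assignment
#' is total.
#'
#' @param clauses a [ground_clauses()] result.
#' @return list with `assignment` (logical vector over hypothesis ids) and
#'   `satisfied_weight` (total weight of satisfied soft clauses).  Raises an
#'   infeasibility error on mutually contradictory hard clauses.
#' @export
solve_weighted_maxsat <- function(clauses) {
  n <- clauses$n_vars
  cls <- clauses$clauses
  assign <- rep(NA, n)
  if (n == 0L)
    return(list(assignment = logical(0), satisfied_weight = 0))

  clause_state <- function(cl) {
    # returns "sat", "unsat", or number of unassigned literals
    unassigned <- 0L
    for (t in seq_along(cl$vars)) {
      v <- assign[cl$vars[t]]
      if (is.na(v)) unassigned <- unassigned + 1L
      else if (v == cl$signs[t]) return("sat")
    }
    if (unassigned == 0L) return("unsat")
    unassigned
  }

  # --- phase 0: propagate hard unit clauses --------------------------------
  # A hard clause reduced to a single open literal forces that literal (the
  # clause must be satisfied); propagation runs to a fixed point so a pinned
  # seed fact immediately falsifies its exclusion partners.
  repeat {
    forced <- FALSE
    for (cl in cls) {
      if (!cl$hard) next
      st <- clause_state(cl)
      if (identical(st, "unsat"))
        stopf("infeasible: contradictory hard clauses (hypothesis %s)",
              paste(cl$vars, collapse = ","))
      if (identical(st, 1L)) {
        open <- which(is.na(assign[cl$vars]))
        assign[cl$vars[open]] <- cl$signs[open]
        forced <- TRUE
      }
    }
    if (!forced) break
  }

  # --- phase 1: dominating unit clauses -----------------------------------
  repeat {
    fixed_any <- FALSE
    live <- Filter(function(cl) !identical(clause_state(cl), "sat"), cls)
    # accumulate unit weights and opposing weights per literal
    unit_w <- matrix(0, nrow = n, ncol = 2L)   # columns: sign FALSE, TRUE
    opp_w <- matrix(0, nrow = n, ncol = 2L)
    for (cl in live) {
      un <- which(is.na(assign[cl$vars]))
      w <- if (cl$hard) Inf else cl$weight
      if (length(un) == 1L && length(cl$vars) >= 1L) {
        # effectively-unit clause on the remaining literal
        v <- cl$vars[un]; s <- cl$signs[un]
        if (identical(clause_state(cl), 1L))
          unit_w[v, s + 1L] <- unit_w[v, s + 1L] + w
      }
      for (t in seq_along(cl$vars)) {
        v <- cl$vars[t]
        if (!is.na(assign[v])) next
        s <- cl$signs[t]
        # this clause opposes the literal (v, !s)
        opp_w[v, (!s) + 1L] <- opp_w[v, (!s) + 1L] + w
      }
    }
    for (v in seq_len(n)) {
      if (!is.na(assign[v])) next
      for (s in c(TRUE, FALSE)) {
        uw <- unit_w[v, s + 1L]
        ow <- opp_w[v, s + 1L]   # weight of clauses containing literal (v, !s)
        if (uw > ow) {           # Inf > Inf is FALSE: tied hard sides stay open
          assign[v] <- s
          fixed_any <- TRUE
          break
        }
      }
    }
    # detect contradictions among hard clauses
    for (cl in cls) {
      if (cl$hard && identical(clause_state(cl), "unsat"))
        stopf("infeasible: contradictory hard clauses (hypothesis %s)",
              paste(cl$vars, collapse = ","))
    }
    if (!fixed_any) break
  }

  # --- phase 2: Johnson's greedy heuristic --------------------------------
  soft_incident <- rep(0, n)
  for (cl in cls) {
    if (!cl$hard) soft_incident[cl$vars] <- soft_incident[cl$vars] + cl$weight
  }
  order_vars <- order(-soft_incident, seq_len(n))
  for (v in order_vars) {
    if (!is.na(assign[v])) next
    score <- c(`FALSE` = 0, `TRUE` = 0)
    feasible <- c(`FALSE` = TRUE, `TRUE` = TRUE)
    for (cl in cls) {
      st <- clause_state(cl)
      if (identical(st, "sat")) next
      t <- match(v, cl$vars)
      if (is.na(t)) next
      u <- st  # number of unassigned literals, >= 1 since v is unassigned
      for (s in c(FALSE, TRUE)) {
        nm <- as.character(s)
        if (cl$signs[t] == s) {
          p <- 1
        } else if (u == 1L) {
          p <- 0
          if (cl$hard) feasible[nm] <- FALSE
        } else {
          p <- 1 - 2^-(u - 1L)
        }
        if (!cl$hard) score[nm] <- score[nm] + cl$weight * p
      }
    }
    if (!any(feasible))
      stopf("infeasible: contradictory hard clauses at hypothesis %d", v)
    if (!feasible[["FALSE"]]) assign[v] <- TRUE
    else if (!feasible[["TRUE"]]) assign[v] <- FALSE
    else assign[v] <- score[["TRUE"]] >= score[["FALSE"]]
  }

  # final audit: every hard clause satisfied
  for (cl in cls) {
    if (cl$hard && !identical(clause_state(cl), "sat"))
      stopf("infeasible: hard clause violated (hypothesis %s)",
            paste(cl$vars, collapse = ","))
  }
  satisfied <- 0
  for (cl in cls) {
    if (cl$hard) next
    if (identical(clause_state(cl), "sat")) satisfied <- satisfied + cl$weight
  }
  list(assignment = as.logical(assign), satisfied_weight = satisfied)
}

#' Extract the accepted fact set from a solver assignment
#'
#' @param solution a [solve_weighted_maxsat()] result.
#' @param candidates the candidate rows the clauses were grounded over.
#' @return list of class `reasoner_result`: `accepted` and `rejected`
#'   (candidate data frames, provenance preserved), `satisfied_weight`.
#' @export
extract_accepted_facts <- function(solution, candidates) {
  acc <- candidates[solution$assignment, , drop = FALSE]
  rej <- candidates[!solution$assignment, , drop = FALSE]
  rownames(acc) <- rownames(rej) <- NULL
  structure(list(accepted = acc, rejected = rej,
                 satisfied_weight = solution$satisfied_weight),
            class = "reasoner_result")
}

#' @export
print.reasoner_result <- function(x, ...) {
  cat(sprintf("<reasoner_result: %d accepted, %d rejected, satisfied weight %.4f>\n",
              nrow(x$accepted), nrow(x$rejected), x$satisfied_weight))
  invisible(x)
}

#' Run the full consistency-reasoning stage
#'
#' Type-signature pre-filter, clause grounding, Max-Sat approximation, and
#' accepted-fact extraction in one call.
#'
#' @param candidates a [build_fact_candidates()] result.
#' @param signatures,entity_types,hierarchy see [check_type_signature()].
#' @param exclusions exclusion constraints.
#' @param seeds optional seed facts (hard positives when present among the
#'   candidates).
#' @return a `reasoner_result` with an extra `type_pruned` element (the
#'   candidates removed by the type filter, with reasons).
#' @export
reason_consistency <- function(candidates, signatures = default_type_signatures(),
                               entity_types = list(),
                               hierarchy = default_type_hierarchy(),
                               exclusions = default_exclusions(),
                               seeds = NULL) {
  flt <- filter_by_type_signature(candidates, signatures, entity_types, hierarchy)
  clauses <- ground_clauses(flt$kept, exclusions, seeds)
  sol <- solve_weighted_maxsat(clauses)
  res <- extract_accepted_facts(sol, flt$kept)
  res$type_pruned <- flt$pruned
  res
}
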