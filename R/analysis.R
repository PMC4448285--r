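#' Collect pattern occurrences from gathered patterns
#'
#' Normalizes sentence-level patterns and document-structure patterns into
#' one occurrence table: the unit that is mined, matched against seed
#' patterns, and aggregated into fact candidates.  A DOM pattern contributes
#' its tokenized heading sequence as the pattern tokens; DOM patterns with
#' no headings are dropped (nothing to match on).
#'
#' @param sentence_patterns list of `sentence_pattern` objects
#'   ([gather_sentence_patterns()]).
#' @param dom_patterns list of `dom_pattern` objects
#'   ([extract_dom_patterns()]).
#' @return data frame with columns `pattern` (space-joined lemma key),
#'   `left_entity`, `right_entity`, `doc_id`, `locator` (sentence id or DOM
#'   path), `kind` (`"sentence"` or `"dom"`).
#' @export
pattern_occurrences <- function(sentence_patterns = list(), dom_patterns = list()) {
  rows <- list()
  for (p in sentence_patterns) {
    rows[[length(rows) + 1L]] <- data.frame(
      pattern = pattern_key(p$tokens),
      left_entity = p$left_entity, right_entity = p$right_entity,
      doc_id = p$doc_id, locator = p$sent_id, kind = "sentence",
      stringsAsFactors = FALSE)
  }
  for (dp in dom_patterns) {
    toks <- dom_pattern_tokens(dp)
    if (length(toks) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      pattern = pattern_key(toks),
      left_entity = dp$title_entity$entity_id,
      right_entity = dp$item_entity$entity_id,
      doc_id = dp$doc_id, locator = dp$dom_path, kind = "dom",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(pattern = character(), left_entity = character(),
                      right_entity = character(), doc_id = character(),
                      locator = character(), kind = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Group occurrences by their sentence (or DOM locator): the counting unit of
# the confidence ratio.  Returns a list per group with `patterns` (list of
# token vectors) and `pairs` (ordered pair keys seen in the group).
group_occurrences <- function(occurrences) {
  key <- paste(occurrences$doc_id, occurrences$locator, sep = "\r")
  lapply(split(seq_len(nrow(occurrences)), key), function(rows) {
    list(patterns = lapply(occurrences$pattern[rows], pattern_tokens),
         pairs = unique(pair_key(occurrences$left_entity[rows],
                                 occurrences$right_entity[rows])))
  })
}

#' Mine frequent subsequences of gathered patterns
#'
#' Generalizes over-specific phrases by enumerating all order-preserving
#' (not necessarily contiguous) token subsequences of the gathered patterns
#' and keeping those that occur in at least `min_support` distinct
#' occurrences.  Containment is counted against every occurrence, including
#' those whose own patterns are too long for enumeration
#' (`max_enum_length`, default 12 tokens).
#'
#' @param occurrences occurrence data frame ([pattern_occurrences()]).
#' @param min_support minimum number of distinct supporting occurrences
#'   (default 2).
#' @param max_enum_length patterns longer than this contribute to support
#'   counting but not to candidate generation.
#' @return data frame with columns `pattern` (space-joined subsequence) and
#'   `support`, ordered by decreasing support then pattern.
#' @export
mine_frequent_subsequences <- function(occurrences, min_support = 2L,
                                       max_enum_length = 12L) {
  if (min_support < 1L) stopf("min_support must be >= 1")
  empty <- data.frame(pattern = character(), support = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(occurrences) == 0L) return(empty)
  pats <- lapply(occurrences$pattern, pattern_tokens)
  cand <- unique(unlist(lapply(pats, function(p) {
    if (length(p) > max_enum_length) return(character(0))
    all_subsequences(p)
  })))
  if (length(cand) == 0L) return(empty)
  cand_tok <- lapply(cand, pattern_tokens)
  support <- vapply(cand_tok, function(q)
    sum(vapply(pats, function(p) is_subsequence(q, p), logical(1))),
    integer(1))
  keep <- support >= min_support
  out <- data.frame(pattern = cand[keep], support = support[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All distinct non-empty order-preserving subsequences of a token vector,
# as space-joined keys.
all_subsequences <- function(tokens) {
  n <- length(tokens)
  out <- character(0)
  for (k in seq_len(n)) {
    idx <- utils::combn(n, k)
    out <- c(out, apply(idx, 2L, function(ii) pattern_key(tokens[ii])))
  }
  unique(out)
}

#' Distant-supervision confidence of a pattern for a relation
#'
#' The fraction of sentences containing the pattern together with a seed
#' entity pair in which that pair belongs to the relation's own seeds:
#' `|{s : q occurs in s and some (e1,e2) in sx(R) occurs in s}| /`
#' `|{s : q occurs in s and some (e1,e2) in sx(R) union cx(R) occurs in s}|`.
#' "q occurs in s" means q is an order-preserving subsequence of a pattern
#' gathered in s; counting is over distinct sentences.  A zero denominator
#' (the pattern never co-occurs with any seed pair) leaves the confidence
#' undefined (`NA`), excluding the pattern from seed-pattern candidacy.
#'
#' @param q pattern: token vector or space-joined key.
#' @param relation relation id.
#' @param groups sentence groups from occurrences (see
#'   [pattern_occurrences()]); internally any occurrence data frame is
#'   grouped automatically.
#' @param index a [build_seed_index()] result.
#' @return confidence in `[0, 1]`, or `NA_real_` when undefined.
#' @export
compute_confidence <- function(q, relation, groups, index) {
  if (is.data.frame(groups)) groups <- group_occurrences(groups)
  if (!relation %in% names(index$sx)) stopf("unknown relation '%s'", relation)
  if (length(q) == 1L) q <- pattern_tokens(q)
  sx <- index$sx[[relation]]
  all_pairs <- index$all_pairs
  num <- 0L; den <- 0L
  for (g in groups) {
    if (!any(vapply(g$patterns, function(p) is_subsequence(q, p), logical(1))))
      next
    if (any(g$pairs %in% all_pairs)) {
      den <- den + 1L
      if (any(g$pairs %in% sx)) num <- num + 1L
    }
  }
  if (den == 0L) return(NA_real_)
  num / den
}

#' Confidence table for all mined patterns and relations
#'
#' Convenience wrapper: mines frequent subsequences and computes every
#' defined (pattern, relation) confidence.
#'
#' @param occurrences occurrence data frame.
#' @param index a [build_seed_index()] result.
#' @param min_support passed to [mine_frequent_subsequences()].
#' @return data frame `pattern`, `relation`, `confidence` (only defined,
#'   non-`NA` rows).
#' @export
pattern_confidences <- function(occurrences, index, min_support = 2L) {
  mined <- mine_frequent_subsequences(occurrences, min_support)
  groups <- group_occurrences(occurrences)
  rows <- list()
  for (q in mined$pattern) {
    qt <- pattern_tokens(q)
    # sentence mask computed once per pattern
    has_q <- vapply(groups, function(g)
      any(vapply(g$patterns, function(p) is_subsequence(qt, p), logical(1))),
      logical(1))
    with_seed_pair <- vapply(groups, function(g)
      any(g$pairs %in% index$all_pairs), logical(1))
    den <- sum(has_q & with_seed_pair)
    if (den == 0L) next
    for (r in names(index$sx)) {
      num <- sum(vapply(groups[has_q & with_seed_pair], function(g)
        any(g$pairs %in% index$sx[[r]]), logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = q, relation = r, confidence = num / den,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pattern = character(), relation = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select seed patterns above the confidence threshold
#'
#' Keeps (pattern, relation) pairs whose confidence is strictly greater
#' than the threshold (default 0.3).  One pattern may seed several
#' relations when each confidence clears the threshold.
#'
#' @param confidences data frame from [pattern_confidences()].
#' @param threshold selection threshold in `[0, 1)`.
#' @return data frame of class `seed_patterns` (`pattern`, `relation`,
#'   `confidence`).
#' @export
select_seed_patterns <- function(confidences, threshold = 0.3) {
  if (threshold < 0 || threshold >= 1) stopf("threshold must be in [0, 1)")
  keep <- !is.na(confidences$confidence) & confidences$confidence > threshold
  out <- confidences[keep, c("pattern", "relation", "confidence"), drop = FALSE]
  out <- out[order(out$relation, -out$confidence, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seed_patterns", "data.frame")
  out
}

#' Score a pattern against the seed-pattern set
#'
#' Weight `w = max over q of Jaccard(tokens(p), tokens(q)) * confidence(q)`
#' with Jaccard over token *sets* (duplicates collapsed).  Ties are broken
#' by higher confidence, then lexicographic relation id.  A pattern sharing
#' no token with any seed pattern scores zero and yields no candidate.
#'
#' @param p pattern: token vector or space-joined key.
#' @param seed_patterns a [select_seed_patterns()] result.
#' @return list with `weight` and `relation`, or `NULL` when the weight is
#'   zero.
#' @export
score_pattern <- function(p, seed_patterns) {
  if (nrow(seed_patterns) == 0L) return(NULL)
  if (length(p) == 1L) p <- pattern_tokens(p)
  pset <- unique(p)
  jac <- vapply(seed_patterns$pattern, function(qk)
    jaccard_similarity(pset, unique(pattern_tokens(qk))), numeric(1),
    USE.NAMES = FALSE)
  w <- jac * seed_patterns$confidence
  if (max(w) <= 0) return(NULL)
  ord <- order(-w, -seed_patterns$confidence, seed_patterns$relation)
  best <- ord[1L]
  list(weight = w[best], relation = seed_patterns$relation[best])
}

#' Build fact candidates from scored occurrences
#'
#' Scores every occurrence against the seed patterns and merges occurrences
#' sharing the same (relation, left, right) triple into one candidate whose
#' weight aggregates the per-occurrence weights by noisy-or,
#' `w = 1 - prod(1 - w_i)`: bounded in (0, 1] and monotone in added
#' evidence.
#'
#' @param occurrences occurrence data frame ([pattern_occurrences()]).
#' @param seed_patterns a [select_seed_patterns()] result.
#' @return data frame of class `fact_candidates` with columns `relation`,
#'   `left_entity`, `right_entity`, `weight` and a list column `support`
#'   holding the supporting occurrence rows (data frames with the original
#'   occurrence columns plus `occ_weight`).
#' @export
build_fact_candidates <- function(occurrences, seed_patterns) {
  empty <- data.frame(relation = character(), left_entity = character(),
                      right_entity = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  empty$support <- list()
  class(empty) <- c("fact_candidates", "data.frame")
  if (nrow(occurrences) == 0L || nrow(seed_patterns) == 0L) return(empty)
  # score distinct pattern strings once
  pat_scores <- lapply(stats::setNames(nm = unique(occurrences$pattern)),
                       score_pattern, seed_patterns = seed_patterns)
  scored <- occurrences
  scored$occ_weight <- vapply(occurrences$pattern, function(pk)
    pat_scores[[pk]]$weight %||% 0, numeric(1), USE.NAMES = FALSE)
  scored$relation <- vapply(occurrences$pattern, function(pk)
    pat_scores[[pk]]$relation %||% NA_character_, character(1), USE.NAMES = FALSE)
  scored <- scored[scored$occ_weight > 0 & !is.na(scored$relation), , drop = FALSE]
  if (nrow(scored) == 0L) return(empty)
  key <- fact_key(scored$relation, scored$left_entity, scored$right_entity)
  parts <- split(seq_len(nrow(scored)), key)
  # deterministic candidate order: relation, left, right
  parts <- parts[order(names(parts))]
  out <- do.call(rbind, lapply(parts, function(rows) {
    data.frame(relation = scored$relation[rows[1L]],
               left_entity = scored$left_entity[rows[1L]],
               right_entity = scored$right_entity[rows[1L]],
               weight = 1 - prod(1 - scored$occ_weight[rows]),
               stringsAsFactors = FALSE)
  }))
  out$support <- lapply(parts, function(rows) {
    s <- scored[rows, c("pattern", "doc_id", "locator", "kind", "occ_weight"),
                drop = FALSE]
    rownames(s) <- NULL
    s
  })
  rownames(out) <- NULL
  class(out) <- c("fact_candidates", "data.frame")
  out
}
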