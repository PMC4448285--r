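#' Shortest dependency path between two mentions
#'
#' Breadth-first shortest path on the *undirected* dependency graph between
#' the head tokens of the two mentions.  The head of a mention is the token
#' in its span that has a governor outside the span (or no governor at all);
#' ties take the leftmost such token.  When several shortest paths exist,
#' the lexicographically smallest token-index sequence is returned, so the
#' output is deterministic.
#'
#' @param sentence a [parsed_sentence()].
#' @param m1,m2 one-row mention data frames (or lists) with `start`/`end`.
#' @return integer vector of 0-based token indices from the head of `m1` to
#'   the head of `m2` (endpoints included), or `NULL` when the heads lie in
#'   disconnected components ("no path"; the pattern is skipped upstream).
#' @export
shortest_dependency_path <- function(sentence, m1, m2) {
  if (max(m1$start, m2$start) < min(m1$end, m2$end))
    stopf("mention spans overlap: [%d,%d) and [%d,%d)",
          m1$start, m1$end, m2$start, m2$end)
  h1 <- mention_head(sentence, m1)
  h2 <- mention_head(sentence, m2)
  n <- nrow(sentence$tokens)
  adj <- adjacency_list(sentence$edges, n)
  # BFS distances from both endpoints
  d1 <- bfs_distances(adj, h1, n)
  d2 <- bfs_distances(adj, h2, n)
  if (is.na(d1[h2 + 1L])) return(NULL)
  total <- d1[h2 + 1L]
  # walk forward choosing the smallest-index neighbour that stays on a
  # shortest path: d1 = step and d2 = total - step
  path <- h1
  cur <- h1
  for (step in seq_len(total)) {
    nb <- adj[[cur + 1L]]
    ok <- nb[!is.na(d1[nb + 1L]) & d1[nb + 1L] == step &
             !is.na(d2[nb + 1L]) & d2[nb + 1L] == total - step]
    cur <- min(ok)
    path <- c(path, cur)
  }
  as.integer(path)
}

# Head token of a mention: governor outside the span, or no governor; ties
# (or no qualifying token) resolve to the leftmost token of the span.
mention_head <- function(sentence, m) {
  span <- m$start:(m$end - 1L)
  e <- sentence$edges
  cand <- integer(0)
  for (t in span) {
    govs <- e$gov[e$dep == t]
    if (length(govs) == 0L || any(!govs %in% span)) cand <- c(cand, t)
  }
  as.integer(if (length(cand) == 0L) m$start else min(cand))
}

adjacency_list <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      g <- edges$gov[i]; d <- edges$dep[i]
      adj[[g + 1L]] <- c(adj[[g + 1L]], d)
      adj[[d + 1L]] <- c(adj[[d + 1L]], g)
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

bfs_distances <- function(adj, from, n) {
  dist <- rep(NA_integer_, n)
  dist[from + 1L] <- 0L
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u + 1L]]) {
        if (is.na(dist[v + 1L])) {
          dist[v + 1L] <- dist[u + 1L] + 1L
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' Expand a dependency path with negation and modifier dependents
#'
#' The shortest path alone can drop essential context: negations,
#' adjectival and adverbial modifiers.  For every token in the set, the
#' dependents attached by the labels `neg`, `amod` and `advmod` are added,
#' repeatedly until a fixed point, so the operation is idempotent (a
#' modifier's own modifiers, e.g. "not very common", are also captured).
#'
#' @param path integer vector of 0-based token indices.
#' @param sentence a [parsed_sentence()].
#' @return sorted integer vector of token indices (a superset of `path`).
#' @export
expand_with_modifiers <- function(path, sentence) {
  e <- sentence$edges
  labels <- c("neg", "amod", "advmod")
  cur <- sort(unique(as.integer(path)))
  repeat {
    add <- as.integer(e$dep[e$gov %in% cur & e$label %in% labels])
    nxt <- sort(unique(c(cur, add)))
    if (length(nxt) == length(cur)) return(nxt)
    cur <- nxt
  }
}

#' Render a sentence-level pattern
#'
#' Emits the lemmas of the kept tokens in surface order, excluding every
#' token inside either mention span.  The mention starting earlier in the
#' sentence is recorded as the left argument.  An empty rendered sequence
#' (nothing outside the spans) discards the pattern.
#'
#' @param token_set expanded token indices from [expand_with_modifiers()].
#' @param sentence a [parsed_sentence()].
#' @param m1,m2 the two mentions (order irrelevant; surface order decides
#'   left/right).
#' @return a list of class `sentence_pattern` with `tokens` (lemma vector),
#'   `left_entity`, `right_entity`, `left_span`, `right_span`, `doc_id`,
#'   `sent_id` -- or `NULL` when the pattern renders empty.
#' @export
render_pattern <- function(token_set, sentence, m1, m2) {
  if (m1$start > m2$start) { tmp <- m1; m1 <- m2; m2 <- tmp }
  span_tokens <- c(m1$start:(m1$end - 1L), m2$start:(m2$end - 1L))
  kept <- sort(setdiff(as.integer(token_set), span_tokens))
  if (length(kept) == 0L) return(NULL)
  structure(list(
    tokens = sentence$tokens$lemma[kept + 1L],
    left_entity = m1$entity_id, right_entity = m2$entity_id,
    left_span = c(m1$start, m1$end), right_span = c(m2$start, m2$end),
    doc_id = sentence$doc_id, sent_id = sentence$sent_id),
    class = "sentence_pattern")
}

#' Gather sentence-level patterns for all mention pairs of a sentence
#'
#' For each pair of disjoint resolved mentions: shortest dependency path
#' between the mention heads, modifier expansion, and rendering.  Pairs in
#' disconnected parse components and patterns that render empty are skipped
#' and counted in the returned diagnostics.
#'
#' @param sentence a [parsed_sentence()].
#' @param mentions resolved mention data frame ([resolve_overlaps()]).
#' @return list with `patterns` (list of `sentence_pattern`) and
#'   `diagnostics` (`n_pairs`, `n_disconnected`, `n_empty`).
#' @export
gather_sentence_patterns <- function(sentence, mentions) {
  patterns <- list()
  diag <- c(n_pairs = 0L, n_disconnected = 0L, n_empty = 0L)
  k <- nrow(mentions)
  if (k >= 2L) {
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        m1 <- mentions[i, ]; m2 <- mentions[j, ]
        if (max(m1$start, m2$start) < min(m1$end, m2$end)) next  # overlap
        diag["n_pairs"] <- diag["n_pairs"] + 1L
        path <- shortest_dependency_path(sentence, m1, m2)
        if (is.null(path)) {
          diag["n_disconnected"] <- diag["n_disconnected"] + 1L
          next
        }
        expanded <- expand_with_modifiers(path, sentence)
        p <- render_pattern(expanded, sentence, m1, m2)
        if (is.null(p)) {
          diag["n_empty"] <- diag["n_empty"] + 1L
          next
        }
        patterns[[length(patterns) + 1L]] <- p
      }
    }
  }
  list(patterns = patterns, diagnostics = diag)
}
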