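#' Build a MinHash/LSH dictionary match index
#'
#' Every dictionary name is reduced to its character n-gram set, MinHash
#' signatures are banded into an LSH table for candidate retrieval, and the
#' exact n-gram sets are kept for verification.  Retrieval is a candidate
#' filter only: [recognize_mentions()] always verifies candidates by exact
#' Jaccard similarity, so a false LSH collision can never produce a mention
#' below the threshold, and an identical string always retrieves itself.
#'
#' @param entries an entity dictionary ([read_dictionary()]).
#' @param params a [match_index_params()].
#' @return an object of class `match_index`.
#' @export
build_match_index <- function(entries, params = match_index_params()) {
  if (nrow(entries) == 0L) stopf("cannot index an empty dictionary")
  coef <- minhash_coefficients(params)
  n <- nrow(entries)
  grams <- vector("list", n)
  buckets <- new.env(parent = emptyenv(), hash = TRUE)
  signatures <- matrix(0, nrow = params$signature_length, ncol = n)
  for (i in seq_len(n)) {
    g <- trigram_set(entries$name[i], params$ngram_size)
    grams[[i]] <- g
    sig <- minhash_signature(g, coef)
    signatures[, i] <- sig
    for (key in lsh_band_keys(sig, params)) {
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  structure(list(params = params, coef = coef, entries = entries,
                 grams = grams, signatures = signatures, buckets = buckets),
            class = "match_index")
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf("<match_index: %d names, %d-gram MinHash %d/%d bands, threshold %.2f>\n",
              nrow(x$entries), x$params$ngram_size, x$params$signature_length,
              x$params$band_count, x$params$threshold))
  invisible(x)
}

# LSH candidate entry rows for a query string.
lsh_candidates <- function(index, text) {
  g <- trigram_set(text, index$params$ngram_size)
  sig <- minhash_signature(g, index$coef)
  cand <- integer(0)
  for (key in lsh_band_keys(sig, index$params)) {
    hit <- index$buckets[[key]]
    if (!is.null(hit)) cand <- c(cand, hit)
  }
  list(grams = g, rows = sort(unique(cand)))
}

#' Match a free-text string against the dictionary
#'
#' Retrieves LSH candidates for the whole string and verifies them by exact
#' n-gram Jaccard similarity.  Used for token windows in
#' [recognize_mentions()] and for title/list-item texts of DOM documents.
#'
#' @param index a [build_match_index()] result.
#' @param text query string.
#' @return data frame with one row per matching entity: `entity_id`,
#'   `matched_name` (the best-scoring dictionary name), `semantic_types`,
#'   `similarity` (exact Jaccard, `>= threshold`).
#' @export
match_text <- function(index, text) {
  empty <- data.frame(entity_id = character(), matched_name = character(),
                      semantic_types = character(), similarity = numeric(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  cand <- lsh_candidates(index, text)
  if (length(cand$rows) == 0L) return(empty)
  sims <- vapply(cand$rows, function(i)
    jaccard_similarity(cand$grams, index$grams[[i]]), numeric(1))
  keep <- sims >= index$params$threshold
  if (!any(keep)) return(empty)
  rows <- cand$rows[keep]
  sims <- sims[keep]
  df <- data.frame(entity_id = index$entries$entity_id[rows],
                   matched_name = index$entries$name[rows],
                   semantic_types = index$entries$semantic_types[rows],
                   similarity = sims, stringsAsFactors = FALSE)
  # several names (synonyms) of one entity may match; keep the best name
  df <- df[order(df$entity_id, -df$similarity, df$matched_name), , drop = FALSE]
  df <- df[!duplicated(df$entity_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Recognize dictionary entities in a parsed sentence
#'
#' Scans every token window of length 1 to `max_window`, retrieves LSH
#' candidates for the window surface and keeps entities whose exact n-gram
#' Jaccard similarity reaches the threshold.  Spans are half-open 0-based
#' token ranges `[start, end)`.
#'
#' @param sentence a [parsed_sentence()].
#' @param index a [build_match_index()] result.
#' @return data frame of mentions: `doc_id`, `sent_id`, `start`, `end`,
#'   `entity_id`, `semantic_types`, `matched_name`, `similarity`.  May be
#'   empty.  Overlaps are *not* resolved here; see [resolve_overlaps()].
#' @export
recognize_mentions <- function(sentence, index) {
  tok <- sentence$tokens
  n <- nrow(tok)
  maxw <- index$params$max_window
  out <- list()
  for (start in 0:(n - 1L)) {
    for (len in 1:min(maxw, n - start)) {
      surface <- paste(tok$surface[(start + 1L):(start + len)], collapse = " ")
      hits <- match_text(index, surface)
      if (nrow(hits) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        doc_id = sentence$doc_id, sent_id = sentence$sent_id,
        start = start, end = start + len,
        entity_id = hits$entity_id, semantic_types = hits$semantic_types,
        matched_name = hits$matched_name, similarity = hits$similarity,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(doc_id = character(), sent_id = character(),
                      start = integer(), end = integer(),
                      entity_id = character(), semantic_types = character(),
                      matched_name = character(), similarity = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve overlapping mentions
#'
#' Two rules, applied in order, with no further entity disambiguation:
#' longer spans strictly containing a shorter span suppress the shorter
#' mention; then, among mentions sharing an identical span, only the most
#' specifically typed entities are kept -- those whose deepest semantic type
#' (path length to the hierarchy root) is maximal.  Ties keep all tied
#' mentions.  The operation is idempotent.
#'
#' @param mentions mention data frame from [recognize_mentions()] (one
#'   sentence).
#' @param hierarchy a [type_hierarchy()]; codes absent from it count as
#'   depth 0 (with a warning).
#' @return the filtered mention data frame.
#' @export
resolve_overlaps <- function(mentions, hierarchy) {
  if (nrow(mentions) <= 1L) return(mentions)
  m <- mentions
  # 1) subsumption: drop spans strictly contained in another mention's span
  spans <- unique(m[, c("start", "end")])
  contained <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    inside <- m$start >= s & m$end <= e & (m$end - m$start) < (e - s)
    contained <- contained | inside
  }
  m <- m[!contained, , drop = FALSE]
  # 2) same span: keep maximal type depth
  depth_of <- function(codes) {
    d <- vapply(entity_type_codes(codes), type_depth, integer(1),
                hierarchy = hierarchy)
    if (length(d) == 0L) 0L else max(d)
  }
  key <- paste(m$start, m$end)
  keep <- rep(TRUE, nrow(m))
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) <= 1L) next
    depths <- vapply(m$semantic_types[rows], depth_of, integer(1),
                     USE.NAMES = FALSE)
    keep[rows[depths < max(depths)]] <- FALSE
  }
  res <- m[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
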