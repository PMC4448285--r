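#' Construct a parsed sentence
#'
#' A parsed sentence carries the tokens (0-based indices, surfaces, lemmas,
#' part-of-speech tags) and the labelled dependency edges produced by an
#' external NLP pipeline.  Parsing itself is out of scope: the package
#' consumes already-parsed text through [read_parsed_corpus()].
#'
#' @param doc_id,sent_id document and sentence identifiers.
#' @param tokens data frame with columns `index` (0-based, contiguous),
#'   `surface`, `lemma`, `pos`.
#' @param edges data frame with columns `gov`, `dep` (token indices) and
#'   `label` (dependency relation name), or `NULL` for an edgeless sentence.
#' @param genre one of `"scientific"`, `"encyclopedic"`, `"social"`.
#' @param source free-text source name.
#' @return an object of class `parsed_sentence`.
#' @export
parsed_sentence <- function(doc_id, sent_id, tokens, edges = NULL,
                            genre = "scientific", source = "unknown") {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(gov = integer(), dep = integer(),
                        label = character(), stringsAsFactors = FALSE)
  }
  s <- structure(
    list(doc_id = as.character(doc_id), sent_id = as.character(sent_id),
         genre = genre, source = source,
         tokens = as.data.frame(tokens), edges = as.data.frame(edges)),
    class = "parsed_sentence")
  validate_sentence(s)
  s
}

validate_sentence <- function(s, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
  tok <- s$tokens
  n <- nrow(tok)
  if (n == 0L) stopf("sentence %s/%s has no tokens%s", s$doc_id, s$sent_id, ctx)
  if (!identical(as.integer(tok$index), 0:(n - 1L)))
    stopf("sentence %s/%s: token indices must be 0..%d contiguous%s",
          s$doc_id, s$sent_id, n - 1L, ctx)
  if (any(!nzchar(tok$lemma)))
    stopf("sentence %s/%s: empty lemma%s", s$doc_id, s$sent_id, ctx)
  e <- s$edges
  if (nrow(e) > 0L) {
    bad <- e$gov < 0L | e$gov >= n | e$dep < 0L | e$dep >= n
    if (any(bad))
      stopf("sentence %s/%s: edge references missing token (gov=%s dep=%s)%s",
            s$doc_id, s$sent_id, e$gov[bad][1], e$dep[bad][1], ctx)
    if (any(e$gov == e$dep))
      stopf("sentence %s/%s: self-loop edge%s", s$doc_id, s$sent_id, ctx)
  }
  if (!s$genre %in% c("scientific", "encyclopedic", "social"))
    stopf("sentence %s/%s: unknown genre '%s'%s", s$doc_id, s$sent_id, s$genre, ctx)
  invisible(s)
}

#' @export
print.parsed_sentence <- function(x, ...) {
  cat(sprintf("<parsed_sentence %s/%s: %d tokens, %d edges>\n",
              x$doc_id, x$sent_id, nrow(x$tokens), nrow(x$edges)))
  cat(" ", paste(x$tokens$surface, collapse = " "), "\n")
  invisible(x)
}

#' Read a parsed corpus from JSON Lines
#'
#' One sentence per line:
#' `{"doc_id":..,"sent_id":..,"genre":..,"source":..,
#'   "tokens":[{"i":..,"surface":..,"lemma":..,"pos":..},..],
#'   "edges":[{"gov":..,"dep":..,"label":..},..]}`.
#' Token indices are 0-based; records are validated as they are read and a
#' malformed record raises an error naming its line number.
#'
#' @param path path to a UTF-8 JSONL file.
#' @return an object of class `parsed_corpus`: a list with `sentences`
#'   (list of [parsed_sentence()]) and `meta` (one row per document:
#'   `doc_id`, `genre`, `source`).
#' @seealso [write_parsed_corpus()]
#' @export
read_parsed_corpus <- function(path) {
  if (!file.exists(path)) stopf("no such corpus file: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sentences <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyDataFrame = TRUE),
                    error = function(e) stopf("line %d: malformed record: %s",
                                              ln, conditionMessage(e)))
    for (f in c("doc_id", "sent_id", "tokens"))
      if (is.null(rec[[f]])) stopf("line %d: missing field '%s'", ln, f)
    tok <- as.data.frame(rec$tokens)
    names(tok)[names(tok) == "i"] <- "index"
    edges <- rec$edges
    if (is.null(edges) || length(edges) == 0L) edges <- NULL
    s <- tryCatch(
      parsed_sentence(rec$doc_id, rec$sent_id, tok, edges,
                      genre = rec$genre %||% "scientific",
                      source = rec$source %||% "unknown"),
      error = function(e) stopf("line %d: %s", ln, conditionMessage(e)))
    sentences[[ln]] <- s
  }
  new_parsed_corpus(sentences)
}

new_parsed_corpus <- function(sentences) {
  meta <- unique(do.call(rbind, lapply(sentences, function(s)
    data.frame(doc_id = s$doc_id, genre = s$genre, source = s$source,
               stringsAsFactors = FALSE))))
  if (is.null(meta))
    meta <- data.frame(doc_id = character(), genre = character(),
                       source = character(), stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  structure(list(sentences = sentences, meta = meta), class = "parsed_corpus")
}

#' @export
print.parsed_corpus <- function(x, ...) {
  cat(sprintf("<parsed_corpus: %d sentences in %d documents>\n",
              length(x$sentences), nrow(x$meta)))
  invisible(x)
}

#' Write a parsed corpus as JSON Lines
#'
#' Inverse of [read_parsed_corpus()]; used to materialize synthetic fixtures.
#'
#' @param corpus a `parsed_corpus` or a list of `parsed_sentence` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parsed_corpus <- function(corpus, path) {
  sentences <- if (inherits(corpus, "parsed_corpus")) corpus$sentences else corpus
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sentences) {
    tok <- s$tokens
    rec <- list(
      doc_id = s$doc_id, sent_id = s$sent_id,
      genre = s$genre, source = s$source,
      tokens = data.frame(i = as.integer(tok$index), surface = tok$surface,
                          lemma = tok$lemma, pos = tok$pos,
                          stringsAsFactors = FALSE),
      edges = if (nrow(s$edges) > 0L)
        data.frame(gov = as.integer(s$edges$gov), dep = as.integer(s$edges$dep),
                   label = s$edges$label, stringsAsFactors = FALSE)
      else list())
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read an entity dictionary
#'
#' Tab-separated file with columns `entity_id`, `name`,
#' `semantic_type_codes` (comma-separated) and `is_canonical` (0/1); rows
#' sharing an `entity_id` are synonyms of one canonical entity.  Rows with
#' an empty name are rejected with a warning.
#'
#' @param path path to the TSV file.
#' @return data frame of class `entity_dictionary` with columns `entity_id`,
#'   `name`, `semantic_types` (comma-separated string), `is_canonical`
#'   (logical).
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) stopf("no such dictionary file: %s", path)
  raw <- tryCatch(
    read_tsv_file(path, colClasses = "character"),
    error = function(e) {
      # empty file (header only is fine; fully empty is an empty dictionary)
      if (length(readLines(path, warn = FALSE)) == 0L) return(NULL)
      stop(e)
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    warnf("dictionary %s is empty", path)
    return(new_dictionary(data.frame(entity_id = character(),
                                     name = character(),
                                     semantic_types = character(),
                                     is_canonical = logical(),
                                     stringsAsFactors = FALSE)))
  }
  need <- c("entity_id", "name", "semantic_type_codes", "is_canonical")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stopf("dictionary %s: missing column(s) %s", path, paste(miss, collapse = ", "))
  empty <- !nzchar(trimws(raw$name))
  if (any(empty)) {
    warnf("dictionary %s: %d row(s) with empty name rejected", path, sum(empty))
    raw <- raw[!empty, , drop = FALSE]
  }
  new_dictionary(data.frame(
    entity_id = raw$entity_id,
    name = raw$name,
    semantic_types = raw$semantic_type_codes,
    is_canonical = raw$is_canonical %in% c("1", "TRUE", "true"),
    stringsAsFactors = FALSE))
}

new_dictionary <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("entity_dictionary", "data.frame")
  df
}

#' Construct an entity dictionary in memory
#'
#' @param entity_id,name character vectors (recycled to equal length); rows
#'   sharing an `entity_id` are synonyms.
#' @param semantic_types comma-separated type codes per row.
#' @param is_canonical logical flag per row.
#' @return an `entity_dictionary` data frame.
#' @export
entity_dictionary <- function(entity_id, name, semantic_types,
                              is_canonical = TRUE) {
  df <- data.frame(entity_id = entity_id, name = name,
                   semantic_types = semantic_types,
                   is_canonical = is_canonical, stringsAsFactors = FALSE)
  if (any(!nzchar(df$name))) stopf("entity names must be non-empty")
  new_dictionary(df)
}

#' Write an entity dictionary
#' @param dict a dictionary data frame as returned by [read_dictionary()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  write_tsv_file(data.frame(
    entity_id = dict$entity_id, name = dict$name,
    semantic_type_codes = dict$semantic_types,
    is_canonical = as.integer(dict$is_canonical),
    stringsAsFactors = FALSE), path)
}

# Split the comma-separated type codes of one dictionary row.
entity_type_codes <- function(codes) {
  strsplit(codes, ",", fixed = TRUE)[[1]]
}
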