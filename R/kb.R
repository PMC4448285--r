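#' Assemble a knowledge base from accepted facts
#'
#' One fact per accepted (relation, left, right) triple; provenance is the
#' union of supporting occurrences, joined with document genre/source
#' metadata when a corpus is supplied.  Fact count and occurrence count are
#' both reported: they differ whenever one fact is stated in several
#' sentences or documents.
#'
#' @param result a `reasoner_result` (or any data frame of accepted
#'   candidates with a `support` list column).
#' @param corpus optional `parsed_corpus`; its `meta` supplies `genre` and
#'   `source` per document.
#' @return object of class `knowledge_base`: list with `facts` (data frame
#'   `relation`, `left_entity`, `right_entity`, `weight`,
#'   `provenance_count`), `provenance` (data frame `relation`,
#'   `left_entity`, `right_entity`, `doc_id`, `locator`, `kind`, `pattern`,
#'   `genre`, `source`), `n_facts`, `n_occurrences`.
#' @export
assemble_kb <- function(result, corpus = NULL) {
  accepted <- if (inherits(result, "reasoner_result")) result$accepted else result
  meta <- if (!is.null(corpus)) corpus$meta else NULL
  if (nrow(accepted) == 0L) {
    facts <- data.frame(relation = character(), left_entity = character(),
                        right_entity = character(), weight = numeric(),
                        provenance_count = integer(), stringsAsFactors = FALSE)
    prov <- data.frame(relation = character(), left_entity = character(),
                       right_entity = character(), doc_id = character(),
                       locator = character(), kind = character(),
                       pattern = character(), genre = character(),
                       source = character(), stringsAsFactors = FALSE)
    return(structure(list(facts = facts, provenance = prov,
                          n_facts = 0L, n_occurrences = 0L),
                     class = "knowledge_base"))
  }
  ord <- order(accepted$relation, accepted$left_entity, accepted$right_entity)
  accepted <- accepted[ord, , drop = FALSE]
  prov_rows <- lapply(seq_len(nrow(accepted)), function(i) {
    s <- accepted$support[[i]]
    genre <- source <- rep(NA_character_, nrow(s))
    if (!is.null(meta) && nrow(meta) > 0L) {
      mi <- match(s$doc_id, meta$doc_id)
      genre <- meta$genre[mi]
      source <- meta$source[mi]
    }
    data.frame(relation = accepted$relation[i],
               left_entity = accepted$left_entity[i],
               right_entity = accepted$right_entity[i],
               doc_id = s$doc_id, locator = s$locator, kind = s$kind,
               pattern = s$pattern, genre = genre, source = source,
               stringsAsFactors = FALSE)
  })
  prov <- do.call(rbind, prov_rows)
  rownames(prov) <- NULL
  facts <- data.frame(relation = accepted$relation,
                      left_entity = accepted$left_entity,
                      right_entity = accepted$right_entity,
                      weight = accepted$weight,
                      provenance_count = vapply(accepted$support, nrow, integer(1)),
                      stringsAsFactors = FALSE)
  rownames(facts) <- NULL
  structure(list(facts = facts, provenance = prov,
                 n_facts = nrow(facts), n_occurrences = nrow(prov)),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base: %d facts from %d occurrences>\n",
              x$n_facts, x$n_occurrences))
  invisible(x)
}

KB_IRI_PREFIX <- "urn:kbharvest:"

kb_iri <- function(kind, id) {
  paste0("<", KB_IRI_PREFIX, kind, "/", utils::URLencode(id, reserved = TRUE), ">")
}

#' Export a knowledge base
#'
#' `tsv`: one data row per fact with columns `relation`, `left_entity`,
#' `right_entity`, `weight` (fixed 6 decimals), `provenance_count`,
#' `sources` (comma-joined distinct source names).  `ntriples`: one RDF
#' triple per fact under a deterministic IRI scheme (fixed namespace prefix
#' plus percent-encoded ids), with provenance written to a sidecar TSV
#' `<path>.provenance.tsv`.  Identical KBs produce byte-identical files.
#'
#' @param kb a [assemble_kb()] result.
#' @param path output file path.
#' @param format `"tsv"` or `"ntriples"`.
#' @return `path`, invisibly.
#' @export
export_kb <- function(kb, path, format = c("tsv", "ntriples")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stopf("unknown export format"))
  f <- kb$facts
  if (format == "tsv") {
    sources <- vapply(seq_len(nrow(f)), function(i) {
      p <- kb$provenance
      hit <- p$relation == f$relation[i] &
        p$left_entity == f$left_entity[i] & p$right_entity == f$right_entity[i]
      src <- sort(unique(stats::na.omit(p$source[hit])))
      paste(src, collapse = ",")
    }, character(1))
    out <- data.frame(relation = f$relation, left_entity = f$left_entity,
                      right_entity = f$right_entity,
                      weight = fmt_weight(f$weight),
                      provenance_count = f$provenance_count,
                      sources = sources, stringsAsFactors = FALSE)
    write_tsv_file(out, path)
  } else {
    lines <- sprintf("%s %s %s .",
                     kb_iri("entity", f$left_entity),
                     kb_iri("relation", f$relation),
                     kb_iri("entity", f$right_entity))
    writeLines(lines, path, useBytes = TRUE)
    write_tsv_file(kb$provenance, paste0(path, ".provenance.tsv"))
  }
  invisible(path)
}

#' Import a knowledge base from its TSV export
#'
#' Round-trips the fact table of [export_kb()]; provenance locators are not
#' portable across exports and are restored as an empty provenance table.
#'
#' @param path TSV file written by `export_kb(format = "tsv")`.
#' @return a `knowledge_base` whose `facts` equal the exported ones.
#' @export
import_kb_tsv <- function(path) {
  df <- read_tsv_file(path, colClasses = c(relation = "character",
                                           left_entity = "character",
                                           right_entity = "character",
                                           weight = "numeric",
                                           provenance_count = "integer",
                                           sources = "character"))
  facts <- df[, c("relation", "left_entity", "right_entity", "weight",
                  "provenance_count")]
  prov <- data.frame(relation = character(), left_entity = character(),
                     right_entity = character(), doc_id = character(),
                     locator = character(), kind = character(),
                     pattern = character(), genre = character(),
                     source = character(), stringsAsFactors = FALSE)
  structure(list(facts = facts, provenance = prov,
                 n_facts = nrow(facts),
                 n_occurrences = sum(facts$provenance_count)),
            class = "knowledge_base")
}

#' Query a knowledge base
#'
#' Facts matching all supplied filters, ordered by descending weight (ties
#' by relation, left, right).  `entity` matches either argument.
#'
#' @param kb a `knowledge_base`.
#' @param relation,left,right,entity optional filters.
#' @return data frame of matching fact rows.
#' @export
query_kb <- function(kb, relation = NULL, left = NULL, right = NULL,
                     entity = NULL) {
  f <- kb$facts
  keep <- rep(TRUE, nrow(f))
  if (!is.null(relation)) keep <- keep & f$relation %in% relation
  if (!is.null(left)) keep <- keep & f$left_entity %in% left
  if (!is.null(right)) keep <- keep & f$right_entity %in% right
  if (!is.null(entity))
    keep <- keep & (f$left_entity %in% entity | f$right_entity %in% entity)
  out <- f[keep, , drop = FALSE]
  out <- out[order(-out$weight, out$relation, out$left_entity, out$right_entity),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}
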