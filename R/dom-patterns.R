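#' Extract document-structure patterns from a reduced DOM tree
#'
#' Encyclopedic pages state facts through layout: the page title names an
#' entity, section headings carry the relation ("Side Effects"), and list
#' items name the other entity.  A pattern is emitted only when the `h1`
#' text resolves to exactly one dictionary entity and an `li` text resolves
#' to an entity; the pattern's headings are the `h2`-`h6` texts governing
#' that list item -- the stack of open section headings at the item's
#' position in document order (an `h3` under an `h2` contributes both, a
#' later heading of the same or higher level closes the previous one).
#'
#' @param tree a `dom_node` root from [parse_dom_document()].
#' @param index a [build_match_index()] result used to resolve title and
#'   item texts.
#' @return list of `dom_pattern` objects: `title_entity`, `item_entity`
#'   (one-row data frames as from [match_text()]), `headings` (character,
#'   possibly empty), `doc_id`, `dom_path` (index path to the `li`).
#' @export
extract_dom_patterns <- function(tree, index) {
  h1 <- find_first_tag(tree, "h1")
  if (is.null(h1)) return(list())
  title_hits <- match_text(index, h1$text)
  if (nrow(title_hits) != 1L) return(list())  # gate: single-entity title
  out <- list()
  stack <- character(0)       # open heading texts, outermost first
  levels <- integer(0)        # their numeric levels (2..6)
  walk <- function(node, path) {
    if (node$tag %in% paste0("h", 2:6)) {
      lev <- as.integer(substring(node$tag, 2L))
      keep <- levels < lev
      stack <<- c(stack[keep], node$text)
      levels <<- c(levels[keep], lev)
    } else if (node$tag == "li" && nzchar(node$text)) {
      hits <- match_text(index, node$text)
      if (nrow(hits) > 0L) {
        hits <- hits[order(-hits$similarity, hits$entity_id), , drop = FALSE]
        out[[length(out) + 1L]] <<- structure(list(
          title_entity = title_hits, item_entity = hits[1L, , drop = FALSE],
          headings = stack, doc_id = tree$doc_id,
          dom_path = paste(path, collapse = "/")), class = "dom_pattern")
      }
    }
    for (i in seq_along(node$children)) walk(node$children[[i]], c(path, i))
  }
  walk(tree, integer(0))
  out
}

find_first_tag <- function(node, tag) {
  if (identical(node$tag, tag)) return(node)
  for (ch in node$children) {
    hit <- find_first_tag(ch, tag)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' @export
print.dom_pattern <- function(x, ...) {
  cat(sprintf("<dom_pattern %s: %s -[%s]-> %s>\n", x$doc_id,
              x$title_entity$entity_id,
              paste(x$headings, collapse = " / "),
              x$item_entity$entity_id))
  invisible(x)
}

# Tokenized heading sequence of a DOM pattern, used as its pattern tokens
# when matched against seed patterns.
dom_pattern_tokens <- function(dp) {
  toks <- unlist(lapply(dp$headings, function(h)
    strsplit(squash_ws(tolower(h)), " ", fixed = TRUE)[[1]]))
  if (is.null(toks)) character(0) else toks
}
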