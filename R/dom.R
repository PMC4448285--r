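#' Parse an HTML document into a reduced DOM tree
#'
#' Web portals often state facts through document structure: the page title
#' (`<h1>`), section headings (`<h2>`-`<h6>`) and list items (`<li>`).  This
#' parser keeps exactly that skeleton: headings and list items in document
#' order, list nesting preserved through `li` children, and everything else
#' (divs, paragraphs, scripts, styles) stripped.  Tolerant parsing: any
#' input libxml2 can repair is accepted.
#'
#' A document may carry at most one `<h1>`; later ones are demoted to plain
#' containers (their structure is kept, their heading status dropped) with a
#' warning.
#'
#' @param html HTML source text.
#' @param doc_id identifier attached to the returned tree.
#' @return a `dom_node` of tag `"other"` (the document root) whose children
#'   are `h1`..`h6` and `li` nodes; each node is a list with `tag`, `text`
#'   (concatenated visible text; empty on the root) and `children` (ordered
#'   list of `dom_node`, non-empty only for `li` items holding nested
#'   lists).  The root additionally carries `doc_id`.
#' @export
parse_dom_document <- function(html, doc_id) {
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) stopf("document %s: unusable HTML", doc_id)
  body <- xml2::xml_find_first(doc, "//body")
  if (inherits(body, "xml_missing")) stopf("document %s: no extractable body", doc_id)
  for (bad in xml2::xml_find_all(body, ".//script | .//style"))
    xml2::xml_remove(bad)
  state <- new.env(parent = emptyenv())
  state$seen_h1 <- FALSE
  state$demoted <- 0L
  root <- dom_node("other", "", dom_collect(body, state))
  if (state$demoted > 0L)
    warnf("document %s: %d extra <h1> tag(s) demoted with their heading status dropped",
          doc_id, state$demoted)
  root$doc_id <- as.character(doc_id)
  root
}

dom_node <- function(tag, text, children = list()) {
  structure(list(tag = tag, text = text, children = children),
            class = "dom_node")
}

# Normalize whitespace in visible text.
squash_ws <- function(x) trimws(gsub("[[:space:]]+", " ", x))

# Flattened collection of retained nodes below `node`, in document order.
# Containers never become nodes themselves; their retained descendants are
# spliced in place, so "other" only ever appears at the document root.
dom_collect <- function(node, state) {
  out <- list()
  for (child in xml2::xml_children(node)) {
    tag <- xml2::xml_name(child)
    if (tag %in% paste0("h", 1:6)) {
      if (tag == "h1" && state$seen_h1) {
        state$demoted <- state$demoted + 1L
        next
      }
      if (tag == "h1") state$seen_h1 <- TRUE
      out <- c(out, list(dom_node(tag, squash_ws(xml2::xml_text(child)))))
    } else if (tag == "li") {
      kids <- dom_collect(child, state)
      own <- xml2::xml_find_all(
        child, "./text() | ./*[not(self::ul) and not(self::ol)]//text()")
      txt <- squash_ws(paste(vapply(own, xml2::xml_text, character(1)),
                             collapse = " "))
      out <- c(out, list(dom_node("li", txt, kids)))
    } else {
      out <- c(out, dom_collect(child, state))
    }
  }
  out
}

#' @export
print.dom_node <- function(x, ...) {
  cat(sprintf("<dom_node %s%s: %d children>%s\n", x$tag,
              if (!is.null(x$doc_id)) paste0(" doc=", x$doc_id) else "",
              length(x$children),
              if (nzchar(x$text)) paste0(" \"", x$text, "\"") else ""))
  invisible(x)
}

#' Serialize a reduced DOM tree back to HTML
#'
#' Inverse of [parse_dom_document()] on the retained structure: parsing the
#' output again yields an equal tree.  Runs of sibling list items are
#' emitted inside one `<ul>`.
#'
#' @param node a `dom_node` (normally the document root).
#' @return a single HTML string.
#' @export
serialize_dom <- function(node) {
  body <- if (node$tag == "other") serialize_dom_children(node$children)
          else serialize_dom_node(node)
  paste0("<html><body>", body, "</body></html>")
}

serialize_dom_children <- function(children) {
  parts <- character(0)
  in_list <- FALSE
  for (ch in children) {
    if (ch$tag == "li") {
      if (!in_list) { parts <- c(parts, "<ul>"); in_list <- TRUE }
      parts <- c(parts, serialize_dom_node(ch))
    } else {
      if (in_list) { parts <- c(parts, "</ul>"); in_list <- FALSE }
      parts <- c(parts, serialize_dom_node(ch))
    }
  }
  if (in_list) parts <- c(parts, "</ul>")
  paste(parts, collapse = "")
}

serialize_dom_node <- function(node) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  inner <- serialize_dom_children(node$children)
  paste0("<", node$tag, ">", esc(node$text), inner, "</", node$tag, ">")
}

# Count nodes with a given tag in a reduced DOM tree (test/diagnostic aid).
dom_count_tag <- function(node, tag) {
  n <- as.integer(identical(node$tag, tag))
  for (ch in node$children) n <- n + dom_count_tag(ch, tag)
  n
}
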