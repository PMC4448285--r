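#' Semantic-type hierarchy
#'
#' A rooted forest over semantic-type codes, given as a child-to-parent
#' mapping; roots have parent `""`/`NA`.  The hierarchy drives two decisions
#' downstream: mention overlap resolution keeps the most specifically typed
#' entity (deepest code), and type-signature checking accepts an entity whose
#' type is the signature code or any descendant of it.
#'
#' @param parent_of named character vector: `names()` are child codes,
#'   values are parent codes (`""` or `NA` for roots).
#' @return an object of class `type_hierarchy`.
#' @export
type_hierarchy <- function(parent_of) {
  parent_of <- vapply(parent_of, as.character, character(1))
  parent_of[is.na(parent_of)] <- ""
  h <- structure(list(parent_of = parent_of), class = "type_hierarchy")
  # reject cycles / unreachable codes by computing every depth eagerly
  for (code in names(parent_of)) type_depth(code, h)
  h
}

#' Read a semantic-type hierarchy from TSV
#'
#' Columns `child_code`, `parent_code`; roots are listed with an empty
#' parent.
#'
#' @param path TSV file path.
#' @return a [type_hierarchy()].
#' @export
read_type_hierarchy <- function(path) {
  df <- read_tsv_file(path, colClasses = "character")
  need <- c("child_code", "parent_code")
  if (!all(need %in% names(df)))
    stopf("hierarchy %s: expected columns child_code, parent_code", path)
  type_hierarchy(stats::setNames(df$parent_code, df$child_code))
}

#' Write a semantic-type hierarchy to TSV
#' @param hierarchy a [type_hierarchy()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_type_hierarchy <- function(hierarchy, path) {
  write_tsv_file(data.frame(child_code = names(hierarchy$parent_of),
                            parent_code = unname(hierarchy$parent_of),
                            stringsAsFactors = FALSE), path)
}

#' Depth of a type code
#'
#' Path length from the code to its root: roots have depth 0.  A code absent
#' from the hierarchy is treated as depth 0 with a warning.
#'
#' @param code semantic-type code.
#' @param hierarchy a [type_hierarchy()].
#' @return integer depth.
#' @export
type_depth <- function(code, hierarchy) {
  parent_of <- hierarchy$parent_of
  if (!code %in% names(parent_of)) {
    warnf("type code '%s' absent from hierarchy; treated as depth 0", code)
    return(0L)
  }
  depth <- 0L
  seen <- character()
  cur <- code
  while (cur %in% names(parent_of) && nzchar(parent_of[[cur]])) {
    if (cur %in% seen) stopf("type hierarchy has a cycle at '%s'", cur)
    seen <- c(seen, cur)
    cur <- parent_of[[cur]]
    depth <- depth + 1L
    if (depth > length(parent_of)) stopf("type hierarchy has a cycle at '%s'", code)
  }
  if (!cur %in% names(parent_of) && cur != code)
    stopf("type code '%s' is not reachable from a root (missing '%s')", code, cur)
  depth
}

#' Ancestors of a type code, including the code itself
#' @param code semantic-type code.
#' @param hierarchy a [type_hierarchy()].
#' @return character vector from the code up to its root; unknown codes
#'   return only themselves.
#' @export
type_ancestors <- function(code, hierarchy) {
  parent_of <- hierarchy$parent_of
  out <- code
  cur <- code
  while (cur %in% names(parent_of) && nzchar(parent_of[[cur]])) {
    cur <- parent_of[[cur]]
    out <- c(out, cur)
    if (length(out) > length(parent_of) + 1L)
      stopf("type hierarchy has a cycle at '%s'", code)
  }
  out
}

#' @export
print.type_hierarchy <- function(x, ...) {
  roots <- sum(!nzchar(x$parent_of))
  cat(sprintf("<type_hierarchy: %d codes, %d root(s)>\n",
              length(x$parent_of), roots))
  invisible(x)
}
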