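#' Read seed facts from TSV
#'
#' Seed facts are relation triples presumed true; they anchor the distant
#' supervision that scores mined patterns.  Columns: `relation`,
#' `left_entity_id`, `right_entity_id`.
#'
#' @param path TSV file path.
#' @param relations character vector of configured relation ids; a seed
#'   with an unknown relation is an error.
#' @return data frame with columns `relation`, `left_entity`, `right_entity`.
#' @export
read_seed_facts <- function(path, relations = kb_relations()) {
  df <- read_tsv_file(path, colClasses = "character")
  need <- c("relation", "left_entity_id", "right_entity_id")
  if (!all(need %in% names(df)))
    stopf("seed file %s: expected columns %s", path, paste(need, collapse = ", "))
  seeds <- data.frame(relation = df$relation, left_entity = df$left_entity_id,
                      right_entity = df$right_entity_id, stringsAsFactors = FALSE)
  bad <- setdiff(unique(seeds$relation), relations)
  if (length(bad) > 0L)
    stopf("seed file %s: unknown relation(s) %s", path, paste(bad, collapse = ", "))
  seeds
}

#' Write seed facts to TSV
#' @param seeds seed data frame (`relation`, `left_entity`, `right_entity`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_seed_facts <- function(seeds, path) {
  write_tsv_file(data.frame(relation = seeds$relation,
                            left_entity_id = seeds$left_entity,
                            right_entity_id = seeds$right_entity,
                            stringsAsFactors = FALSE), path)
}

#' Build the per-relation seed-pair index
#'
#' For each relation `R`, `sx(R)` is the set of ordered entity pairs
#' appearing in `R`'s seed facts and `cx(R)` the remaining seed pairs (those
#' appearing only in seeds of other relations).  For every relation the two
#' sets partition the full seed-pair set; they are the numerator and
#' complement sets of the pattern-confidence ratio.
#'
#' @param seeds seed data frame from [read_seed_facts()].
#' @param relations configured relation ids (defaults to the thirteen
#'   built-in relations, see [kb_relations()]).
#' @return an object of class `seed_index`: list with `sx` and `cx` (named
#'   lists of pair-key character vectors), `all_pairs`, and `seeds`.
#' @export
build_seed_index <- function(seeds, relations = kb_relations()) {
  if (nrow(seeds) == 0L) stopf("no seed facts supplied")
  bad <- setdiff(unique(seeds$relation), relations)
  if (length(bad) > 0L)
    stopf("unknown relation(s) in seeds: %s", paste(bad, collapse = ", "))
  keys <- pair_key(seeds$left_entity, seeds$right_entity)
  all_pairs <- unique(keys)
  sx <- lapply(stats::setNames(relations, relations), function(r)
    unique(keys[seeds$relation == r]))
  cx <- lapply(sx, function(own) setdiff(all_pairs, own))
  structure(list(sx = sx, cx = cx, all_pairs = all_pairs, seeds = seeds),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  nz <- sum(vapply(x$sx, length, integer(1)) > 0L)
  cat(sprintf("<seed_index: %d seed facts, %d distinct pairs, %d relation(s) with seeds>\n",
              nrow(x$seeds), length(x$all_pairs), nz))
  invisible(x)
}
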