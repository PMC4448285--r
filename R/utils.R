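# Internal helpers shared across modules.

# Run `expr` with a reproducible RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Collapse a token vector into the canonical space-joined pattern key.
pattern_key <- function(tokens) paste(tokens, collapse = " ")

pattern_tokens <- function(key) strsplit(key, " ", fixed = TRUE)[[1]]

# Ordered entity pair key;  never occurs in entity ids.
pair_key <- function(left, right) paste(left, right, sep = "")

fact_key <- function(relation, left, right) {
  paste(relation, left, right, sep = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# TRUE if `q` is an order-preserving (not necessarily contiguous)
# subsequence of `p`; both are character vectors of tokens.
is_subsequence <- function(q, p) {
  nq <- length(q)
  if (nq == 0L) return(TRUE)
  if (nq > length(p)) return(FALSE)
  i <- 1L
  for (tok in p) {
    if (tok == q[i]) {
      i <- i + 1L
      if (i > nq) return(TRUE)
    }
  }
  FALSE
}

# Fixed 6-decimal formatting used by all TSV exports.
fmt_weight <- function(x) sprintf("%.6f", x)

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = colClasses, fileEncoding = "UTF-8")
}
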