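#' Character n-gram set of a string
#'
#' Names and token spans are compared in the space of character-level
#' 3-grams.  Text is lowercased and whitespace-normalized first; strings
#' shorter than the n-gram size are padded with the boundary character `#`
#' on both sides until they are long enough, so 1-2 character names still
#' yield a non-empty set.
#'
#' @param text non-empty string.
#' @param n n-gram size in characters (default 3).
#' @return character vector of distinct n-grams.
#' @export
trigram_set <- function(text, n = 3L) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stopf("trigram_set: empty text")
  s <- squash_ws(tolower(text))
  while (nchar(s) < n) s <- paste0("#", s, "#")
  L <- nchar(s)
  unique(substring(s, 1:(L - n + 1L), n:L))
}

#' Exact Jaccard similarity between two n-gram sets
#' @param a,b character vectors (sets) of n-grams.
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Matching-index parameters
#'
#' @param ngram_size character n-gram size (default 3).
#' @param signature_length number of MinHash hash functions.
#' @param band_count number of LSH bands; must divide `signature_length`.
#' @param threshold minimum exact Jaccard similarity for a verified match.
#' @param max_window longest token window (in tokens) scanned for mentions.
#' @param hash_seed seed for the random hash coefficients; fixed by default
#'   so two builds produce identical signatures.
#' @return a list of class `match_index_params`.
#' @export
match_index_params <- function(ngram_size = 3L, signature_length = 128L,
                               band_count = 32L, threshold = 0.7,
                               max_window = 6L, hash_seed = 42L) {
  if (signature_length %% band_count != 0L)
    stopf("signature_length (%d) must be divisible by band_count (%d)",
          signature_length, band_count)
  if (threshold <= 0 || threshold > 1)
    stopf("threshold must be in (0, 1]")
  structure(list(ngram_size = as.integer(ngram_size),
                 signature_length = as.integer(signature_length),
                 band_count = as.integer(band_count),
                 threshold = threshold,
                 max_window = as.integer(max_window),
                 hash_seed = as.integer(hash_seed)),
            class = "match_index_params")
}

# --- MinHash machinery -----------------------------------------------------
#
# Each n-gram is first mapped to an integer key < 2^24; MinHash then applies
# `signature_length` universal hash functions h_i(x) = (a_i x + b_i) mod p
# with the Mersenne prime p = 2^31 - 1.  Keys stay < 2^24 and a_i < 2^28,
# so products stay below 2^52 and are exact in doubles.

MINHASH_PRIME <- 2147483647

ngram_keys <- function(ngrams) {
  vapply(ngrams, function(g) {
    cp <- utf8ToInt(g) %% 256
    # little-endian base-256; n-gram size beyond 3 is folded mod 2^24
    sum(cp * 256^(seq_along(cp) - 1L)) %% 16777216
  }, numeric(1), USE.NAMES = FALSE)
}

minhash_coefficients <- function(params) {
  with_seed(params$hash_seed, {
    L <- params$signature_length
    list(a = sample.int(2^28 - 1L, L, replace = TRUE),
         b = sample.int(MINHASH_PRIME - 1L, L, replace = TRUE))
  })
}

#' MinHash signature of an n-gram set
#'
#' @param ngrams character vector of n-grams (as from [trigram_set()]).
#' @param coef hash coefficients from the index (internally derived from
#'   `params$hash_seed`); exposed mainly for property testing.
#' @return numeric vector of length `signature_length`.
#' @keywords internal
minhash_signature <- function(ngrams, coef) {
  x <- ngram_keys(ngrams)
  # outer(): |a| x |x| products, min over columns per hash function
  hv <- (outer(coef$a, x) + coef$b) %% MINHASH_PRIME
  if (is.matrix(hv)) apply(hv, 1L, min) else hv
}

#' Estimate Jaccard similarity from two MinHash signatures
#' @param sig1,sig2 signatures of equal length.
#' @return fraction of agreeing components, an unbiased Jaccard estimate.
#' @export
minhash_estimate <- function(sig1, sig2) mean(sig1 == sig2)

lsh_band_keys <- function(signature, params) {
  rows <- params$signature_length %/% params$band_count
  vapply(seq_len(params$band_count), function(bi) {
    vals <- signature[((bi - 1L) * rows + 1L):(bi * rows)]
    paste0(bi, "|", paste(vals, collapse = ","))
  }, character(1))
}
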