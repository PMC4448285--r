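#' Wilson score confidence interval
#'
#' Two-sided interval for a binomial proportion at significance level
#' `alpha`, using the standard normal quantile `z = qnorm(1 - alpha/2)`.
#' The interval always contains `k/n` and lies within `[0, 1]`.
#'
#' @param k number of successes (e.g. facts judged true).
#' @param n number of trials (facts evaluated), `>= 1`.
#' @param alpha significance level in `(0, 1)` (default 0.05).
#' @return named numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(k, n, alpha = 0.05) {
  if (n < 1) stopf("wilson_interval: n must be >= 1")
  if (k < 0 || k > n) stopf("wilson_interval: k must be in [0, n]")
  if (alpha <= 0 || alpha >= 1) stopf("wilson_interval: alpha must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Sequential evaluation with a width-based stopping rule
#'
#' Consumes true/false judgments until the Wilson interval width drops
#' below `width_target` or the stream is exhausted.  An exhausted finite
#' stream means the whole population was evaluated; by the census
#' convention its reported width is 0.
#'
#' @param judgments logical vector (the judgment stream, in evaluation
#'   order) or a function `function(i)` returning a logical or `NULL` when
#'   exhausted.
#' @param alpha significance level (default 0.05).
#' @param width_target maximum interval width (default 0.05).
#' @param population_size optional total population; when supplied and the
#'   stream is a function, exhaustion is at `i > population_size`.
#' @return list of class `sample_state`: `n`, `k`, `alpha`, `width_target`,
#'   `low`, `high`, `width` (0 under census), `census` (logical).
#' @export
sample_until_width <- function(judgments, alpha = 0.05, width_target = 0.05,
                               population_size = NULL) {
  fetch <- if (is.function(judgments)) {
    function(i) {
      if (!is.null(population_size) && i > population_size) return(NULL)
      judgments(i)
    }
  } else {
    function(i) if (i > length(judgments)) NULL else judgments[i]
  }
  n <- 0L; k <- 0L
  low <- 0; high <- 1
  census <- FALSE
  repeat {
    j <- fetch(n + 1L)
    if (is.null(j)) { census <- TRUE; break }
    n <- n + 1L
    k <- k + as.integer(isTRUE(j))
    ci <- wilson_interval(k, n, alpha)
    low <- ci[["low"]]; high <- ci[["high"]]
    if (high - low < width_target) break
  }
  if (n == 0L) stopf("sample_until_width: empty judgment stream")
  structure(list(n = n, k = k, alpha = alpha, width_target = width_target,
                 low = low, high = high,
                 width = if (census) 0 else high - low,
                 census = census),
            class = "sample_state")
}

#' @export
print.sample_state <- function(x, ...) {
  cat(sprintf("<sample_state: n=%d k=%d precision=%.3f CI=[%.3f, %.3f] width=%s>\n",
              x$n, x$k, x$k / x$n, x$low, x$high,
              if (x$census) "0 (census)" else sprintf("%.3f", x$width)))
  invisible(x)
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Chance-corrected agreement for `N` items rated by a fixed number of
#' raters into mutually exclusive categories; the input matrix holds, per
#' item (row) and category (column), the number of raters choosing that
#' category.  Returns 1 under perfect agreement; errors when chance
#' agreement is degenerate (all ratings in one category).
#'
#' @param matrix integer matrix, rows = items, columns = categories; every
#'   row must sum to the same rater count `>= 2`.
#' @return kappa value.
#' @export
fleiss_kappa <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stopf("fleiss_kappa: need >= 2 items and >= 2 categories")
  raters <- unique(rowSums(m))
  if (length(raters) != 1L)
    stopf("fleiss_kappa: every item must have the same number of raters")
  r <- raters[[1]]
  if (r < 2L) stopf("fleiss_kappa: need >= 2 raters per item")
  N <- nrow(m)
  p_i <- (rowSums(m^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(m) / (N * r)
  p_e <- sum(p_j^2)
  if (isTRUE(all.equal(p_e, 1)))
    stopf("fleiss_kappa: chance agreement is 1; kappa undefined")
  (p_bar - p_e) / (1 - p_e)
}

#' Read annotator judgments from TSV
#'
#' Columns: `fact_key`, `judgment` (0/1), `annotator_id`.
#'
#' @param path TSV file path.
#' @return data frame with those columns, `judgment` as logical.
#' @export
read_judgments <- function(path) {
  df <- read_tsv_file(path, colClasses = "character")
  need <- c("fact_key", "judgment", "annotator_id")
  if (!all(need %in% names(df)))
    stopf("judgments %s: expected columns %s", path, paste(need, collapse = ", "))
  df$judgment <- df$judgment %in% c("1", "TRUE", "true")
  df
}

#' Precision and recall against a planted truth set
#'
#' Desk-scale analogue of a precision evaluation: compares the triples of a
#' harvested KB against the ground-truth ledger of the synthetic-corpus
#' generator.
#'
#' @param kb a `knowledge_base` (or a data frame with `relation`,
#'   `left_entity`, `right_entity`).
#' @param truth data frame of true triples (same three columns).
#' @return named numeric vector `c(precision, recall)`; errors on an empty
#'   KB (precision undefined).
#' @export
precision_recall_on_planted <- function(kb, truth) {
  facts <- if (inherits(kb, "knowledge_base")) kb$facts else kb
  if (nrow(facts) == 0L) stopf("empty KB: precision undefined")
  got <- unique(fact_key(facts$relation, facts$left_entity, facts$right_entity))
  want <- unique(fact_key(truth$relation, truth$left_entity, truth$right_entity))
  hit <- length(intersect(got, want))
  c(precision = hit / length(got),
    recall = if (length(want) == 0L) NA_real_ else hit / length(want))
}
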