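#' Pipeline configuration
#'
#' Paths to the five inputs, the matcher and analysis parameters, and the
#' ablation switches.  Flags: `no_dom` skips document-structure patterns,
#' `no_pattern_stats` promotes every mined pattern co-occurring with a
#' relation's seeds to a seed pattern with confidence 1 (disabling the
#' confidence statistics), `no_reasoning` accepts all candidates without
#' type filtering or Max-Sat reasoning.
#'
#' @param dictionary,hierarchy,seeds,corpus input file paths (TSV, TSV,
#'   TSV, JSONL).
#' @param out_dir output directory (created if missing).
#' @param html_dir optional directory of HTML documents.
#' @param signatures,exclusions optional config file paths; defaults are
#'   the built-in signature table and exclusion list.
#' @param matcher a [match_index_params()].
#' @param min_support subsequence-mining support threshold (default 2).
#' @param confidence_threshold seed-pattern selection threshold
#'   (default 0.3).
#' @param no_dom,no_pattern_stats,no_reasoning ablation switches.
#' @param resume reuse a cached `occurrences.tsv` from a previous run in
#'   `out_dir`, skipping recognition and gathering.
#' @param rng_seed seed recorded in the run report (the pipeline itself is
#'   deterministic).
#' @param verbose emit progress messages to stderr.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dictionary, hierarchy, seeds, corpus,
                            out_dir, html_dir = NULL,
                            signatures = NULL, exclusions = NULL,
                            matcher = match_index_params(),
                            min_support = 2L, confidence_threshold = 0.3,
                            no_dom = FALSE, no_pattern_stats = FALSE,
                            no_reasoning = FALSE, resume = FALSE,
                            rng_seed = 1L, verbose = FALSE) {
  if (confidence_threshold < 0 || confidence_threshold >= 1)
    stopf("confidence_threshold must be in [0, 1)")
  structure(list(dictionary = dictionary, hierarchy = hierarchy,
                 seeds = seeds, corpus = corpus, out_dir = out_dir,
                 html_dir = html_dir, signatures = signatures,
                 exclusions = exclusions, matcher = matcher,
                 min_support = as.integer(min_support),
                 confidence_threshold = confidence_threshold,
                 no_dom = isTRUE(no_dom),
                 no_pattern_stats = isTRUE(no_pattern_stats),
                 no_reasoning = isTRUE(no_reasoning),
                 resume = isTRUE(resume),
                 rng_seed = as.integer(rng_seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full harvesting pipeline
#'
#' recognize -> gather -> analyze -> reason -> assemble -> export.  All
#' stage outputs are pure functions of the inputs and the configuration;
#' two runs on the same config produce byte-identical files.  Intermediates
#' (`mentions.tsv`, `occurrences.tsv`, `seed_patterns.tsv`,
#' `candidates.tsv`), the KB exports (`kb.tsv`, `kb.nt`), `diagnostics.tsv`
#' and `report.tsv` are written to `out_dir`.  An empty corpus yields an
#' empty KB with a warning.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the stage objects: `corpus`, `mentions`,
#'   `occurrences`, `confidences`, `seed_patterns`, `candidates`, `result`
#'   (reasoner), `kb`, `report`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  say <- function(fmt, ...) if (cfg$verbose) message(sprintf(fmt, ...))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)

  say("reading inputs")
  dict <- read_dictionary(cfg$dictionary)
  hierarchy <- read_type_hierarchy(cfg$hierarchy)
  signatures <- if (is.null(cfg$signatures)) default_type_signatures()
                else read_type_signatures(cfg$signatures)
  exclusions <- if (is.null(cfg$exclusions)) default_exclusions()
                else read_exclusions(cfg$exclusions)
  seeds <- read_seed_facts(cfg$seeds, relations = signatures$relation)
  corpus <- read_parsed_corpus(cfg$corpus)

  occ_cache <- out("occurrences.tsv")
  diagnostics <- data.frame(metric = character(), value = numeric(),
                            stringsAsFactors = FALSE)
  mentions <- NULL
  if (cfg$resume && file.exists(occ_cache)) {
    say("resuming from cached occurrences")
    occurrences <- read_tsv_file(occ_cache, colClasses = "character")
  } else {
    say("recognizing mentions and gathering patterns (%d sentences)",
        length(corpus$sentences))
    index <- build_match_index(dict, cfg$matcher)
    sent_patterns <- list()
    mention_rows <- list()
    diag_totals <- c(n_pairs = 0L, n_disconnected = 0L, n_empty = 0L)
    for (s in corpus$sentences) {
      m <- recognize_mentions(s, index)
      m <- resolve_overlaps(m, hierarchy)
      if (nrow(m) > 0L) mention_rows[[length(mention_rows) + 1L]] <- m
      g <- gather_sentence_patterns(s, m)
      sent_patterns <- c(sent_patterns, g$patterns)
      diag_totals <- diag_totals + g$diagnostics
    }
    mentions <- if (length(mention_rows) > 0L) do.call(rbind, mention_rows)
                else NULL
    dom_patterns <- list()
    if (!cfg$no_dom && !is.null(cfg$html_dir) && dir.exists(cfg$html_dir)) {
      say("extracting document-structure patterns")
      files <- sort(list.files(cfg$html_dir, pattern = "\\.html?$",
                               full.names = TRUE))
      for (f in files) {
        tree <- parse_dom_document(paste(readLines(f, warn = FALSE),
                                         collapse = "\n"),
                                   doc_id = sub("\\.html?$", "", basename(f)))
        dom_patterns <- c(dom_patterns, extract_dom_patterns(tree, index))
      }
    }
    occurrences <- pattern_occurrences(sent_patterns, dom_patterns)
    diagnostics <- data.frame(
      metric = c("pairs_considered", "pairs_disconnected", "patterns_empty",
                 "dom_patterns"),
      value = c(diag_totals, length(dom_patterns)), stringsAsFactors = FALSE)
    if (!is.null(mentions)) write_tsv_file(mentions, out("mentions.tsv"))
    write_tsv_file(occurrences, occ_cache)
  }

  if (nrow(occurrences) == 0L) warnf("no pattern occurrences: the KB will be empty")

  say("analyzing patterns (distant supervision)")
  seed_index <- build_seed_index(seeds, relations = signatures$relation)
  confidences <- pattern_confidences(occurrences, seed_index,
                                     min_support = cfg$min_support)
  if (cfg$no_pattern_stats) {
    sp <- confidences[!is.na(confidences$confidence) & confidences$confidence > 0,
                      , drop = FALSE]
    sp$confidence <- 1
    seed_patterns <- select_seed_patterns(sp, threshold = 0)
  } else {
    seed_patterns <- select_seed_patterns(confidences,
                                          threshold = cfg$confidence_threshold)
  }
  sp_out <- seed_patterns
  sp_out$confidence <- fmt_weight(sp_out$confidence)
  write_tsv_file(sp_out, out("seed_patterns.tsv"))

  candidates <- build_fact_candidates(occurrences, seed_patterns)
  cand_out <- candidates[, c("relation", "left_entity", "right_entity", "weight")]
  cand_out$weight <- fmt_weight(cand_out$weight)
  cand_out$support <- vapply(candidates$support, nrow, integer(1))
  write_tsv_file(cand_out, out("candidates.tsv"))

  say("reasoning (%d candidates)", nrow(candidates))
  entity_types <- dictionary_entity_types(dict)
  if (cfg$no_reasoning) {
    result <- structure(list(accepted = candidates,
                             rejected = candidates[0, , drop = FALSE],
                             satisfied_weight = sum(candidates$weight),
                             type_pruned = candidates[0, , drop = FALSE]),
                        class = "reasoner_result")
  } else {
    result <- reason_consistency(candidates, signatures, entity_types,
                                 hierarchy, exclusions, seeds)
  }

  say("assembling and exporting the KB")
  kb <- assemble_kb(result, corpus)
  export_kb(kb, out("kb.tsv"), "tsv")
  export_kb(kb, out("kb.nt"), "ntriples")
  write_tsv_file(diagnostics, out("diagnostics.tsv"))

  report <- data.frame(
    stage = c("sentences", "mentions", "occurrences", "mined_seed_patterns",
              "candidates", "type_pruned", "accepted", "facts",
              "fact_occurrences"),
    count = c(length(corpus$sentences),
              if (is.null(mentions)) NA_integer_ else nrow(mentions),
              nrow(occurrences), nrow(seed_patterns), nrow(candidates),
              nrow(result$type_pruned %||% candidates[0, ]),
              nrow(result$accepted), kb$n_facts, kb$n_occurrences),
    stringsAsFactors = FALSE)
  write_tsv_file(report, out("report.tsv"))
  say("done: %d facts from %d occurrences", kb$n_facts, kb$n_occurrences)

  invisible(list(corpus = corpus, mentions = mentions,
                 occurrences = occurrences, confidences = confidences,
                 seed_patterns = seed_patterns, candidates = candidates,
                 result = result, kb = kb, report = report))
}
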