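# Shared fixture builders and independent oracles.

# --- tiny dictionaries -------------------------------------------------------

tiny_dictionary <- function() {
  entity_dictionary(
    entity_id = c("E1", "E1", "E2", "E3", "E4"),
    name = c("myocardial infarction", "heart attack", "asthma",
             "sarcoidosis", "anemia"),
    semantic_types = c("Disease", "Disease", "Disease", "Disease", "Symptom"),
    is_canonical = c(TRUE, FALSE, TRUE, TRUE, TRUE))
}

# The Table-3-style micro-corpora used by the confidence worked examples.
# Returns occurrences + seed index, built through the real pipeline stages
# (recognition, gathering) rather than by hand.
confidence_fixture <- function(which = c("risk_factor", "progress", "occur")) {
  which <- match.arg(which)
  if (which == "risk_factor") {
    dict <- entity_dictionary(
      entity_id = sprintf("E%d", 1:8),
      name = c("obesity", "diabetes", "asthma", "wood dust", "anemia",
               "sarcoidosis", "golf", "tendinitis"),
      semantic_types = c("Ecofactor", "Disease", "Disease", "Ecofactor",
                         "Symptom", "Disease", "Behavior", "Disease"))
    seeds <- data.frame(
      relation = c("createsRisk", "createsRisk", "createsRisk",
                   "isSymptom", "createsRisk"),
      left_entity = c("E1", "E1", "E4", "E5", "E7"),
      right_entity = c("E2", "E3", "E3", "E6", "E8"),
      stringsAsFactors = FALSE)
    phr <- list(surface = c("risk", "factor"), lemma = c("risk", "factor"))
    sents <- list(
      make_planted_sentence("d1", "s1", "obesity", "diabetes", phr),
      make_planted_sentence("d1", "s2", "obesity", "asthma", phr),
      make_planted_sentence("d2", "s1", "wood dust", "asthma", phr))
  } else if (which == "progress") {
    dict <- entity_dictionary(
      entity_id = sprintf("E%d", 1:3),
      name = c("pericarditis", "tamponade", "tuberculosis"),
      semantic_types = c("Disease", "Disease", "Disease"))
    seeds <- data.frame(
      relation = c("createsRisk", "causes"),
      left_entity = c("E1", "E3"), right_entity = c("E2", "E1"),
      stringsAsFactors = FALSE)
    sents <- list(
      make_planted_sentence("d1", "s1", "pericarditis", "tamponade",
                            list(surface = c("which", "progresses", "to"),
                                 lemma = c("which", "progress", "to"))),
      make_planted_sentence("d1", "s2", "tuberculosis", "pericarditis",
                            list(surface = c("still", "progressing", "to"),
                                 lemma = c("still", "progress", "to"))))
  } else {
    dict <- entity_dictionary(
      entity_id = sprintf("E%d", 1:6),
      name = c("hashimoto disease", "thyroid gland", "pericarditis",
               "heart", "anemia", "sarcoidosis"),
      semantic_types = c("Disease", "Organ", "Disease", "Organ",
                         "Symptom", "Disease"))
    seeds <- data.frame(
      relation = c("affects", "affects", "isSymptom"),
      left_entity = c("E1", "E3", "E5"),
      right_entity = c("E2", "E4", "E6"),
      stringsAsFactors = FALSE)
    sents <- list(
      make_planted_sentence("d1", "s1", "hashimoto disease", "thyroid gland",
                            list(surface = c("occurs", "anywhere"),
                                 lemma = c("occur", "anywhere"))),
      make_planted_sentence("d1", "s2", "pericarditis", "heart",
                            list(surface = c("occurs", "anywhere"),
                                 lemma = c("occur", "anywhere"))),
      make_planted_sentence("d1", "s3", "anemia", "sarcoidosis",
                            list(surface = c("occurs", "patients"),
                                 lemma = c("occur", "patients"))))
  }
  index <- build_match_index(dict)
  hierarchy <- default_type_hierarchy()
  pats <- list()
  for (s in sents) {
    m <- resolve_overlaps(recognize_mentions(s, index), hierarchy)
    pats <- c(pats, gather_sentence_patterns(s, m)$patterns)
  }
  list(dict = dict, seeds = seeds, sentences = sents,
       occurrences = pattern_occurrences(pats),
       seed_index = build_seed_index(seeds))
}

# The Figure-2a-style sentence: "anemia is a common symptom of sarcoidosis"
# with a Stanford-style dependency parse.
symptom_sentence <- function() {
  parsed_sentence(
    "doc", "s1",
    tokens = data.frame(
      index = 0:6,
      surface = c("anemia", "is", "a", "common", "symptom", "of", "sarcoidosis"),
      lemma = c("anemia", "be", "a", "common", "symptom", "of", "sarcoidosis"),
      pos = c("NN", "VBZ", "DT", "JJ", "NN", "IN", "NN"),
      stringsAsFactors = FALSE),
    edges = data.frame(
      gov = c(4, 4, 4, 4, 4, 5),
      dep = c(0, 1, 2, 3, 5, 6),
      label = c("nsubj", "cop", "det", "amod", "prep", "pobj"),
      stringsAsFactors = FALSE))
}

mention_at <- function(start, end, entity_id = "X") {
  list(start = start, end = end, entity_id = entity_id)
}

# --- independent oracles -----------------------------------------------------

# Exhaustive enumeration of all simple paths between two nodes on the
# undirected graph of `edges`; returns the shortest, lexicographically
# smallest index sequence, or NULL.
oracle_shortest_path <- function(edges, n, from, to) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    g <- edges$gov[i] + 1L; d <- edges$dep[i] + 1L
    adj[[g]] <- c(adj[[g]], d - 1L)
    adj[[d]] <- c(adj[[d]], g - 1L)
  }
  best <- NULL
  dfs <- function(node, visited, path) {
    if (node == to) {
      if (is.null(best) || length(path) < length(best) ||
          (length(path) == length(best) &&
           paste(sprintf("%04d", path), collapse = "") <
           paste(sprintf("%04d", best), collapse = ""))) best <<- path
      return(invisible())
    }
    for (nb in adj[[node + 1L]]) {
      if (!nb %in% visited) dfs(nb, c(visited, nb), c(path, nb))
    }
  }
  dfs(from, from, from)
  best
}

# Random dependency tree over n tokens (token i's parent drawn among 0..i-1).
random_tree_sentence <- function(n, doc = "rt", sid = "s") {
  parents <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L) - 1L,
                          integer(1)))
  edges <- data.frame(gov = parents[-1L], dep = 1:(n - 1L),
                      label = sample(c("dep", "nsubj", "obj", "amod"),
                                     n - 1L, replace = TRUE),
                      stringsAsFactors = FALSE)
  parsed_sentence(doc, sid,
                  tokens = data.frame(index = 0:(n - 1L),
                                      surface = paste0("w", 0:(n - 1L)),
                                      lemma = paste0("w", 0:(n - 1L)),
                                      pos = "NN", stringsAsFactors = FALSE),
                  edges = edges)
}

# Exhaustive weighted Max-Sat over <= ~14 variables.
oracle_maxsat <- function(clauses) {
  n <- clauses$n_vars
  best <- NA_real_
  for (mask in 0:(2^n - 1)) {
    a <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    w <- 0; ok <- TRUE
    for (cl in clauses$clauses) {
      sat <- any(a[cl$vars] == cl$signs)
      if (cl$hard && !sat) { ok <- FALSE; break }
      if (!cl$hard && sat) w <- w + cl$weight
    }
    if (ok && (is.na(best) || w > best)) best <- w
  }
  best
}

# Random candidate table + exclusion clauses for solver tests.
random_maxsat_instance <- function(n, n_exclusions) {
  cand <- data.frame(relation = rep("treats", n),
                     left_entity = sprintf("L%d", seq_len(n)),
                     right_entity = sprintf("R%d", seq_len(n)),
                     weight = round(stats::runif(n, 0.05, 1), 3),
                     stringsAsFactors = FALSE)
  cl <- ground_clauses(cand,
                       exclusions = data.frame(relation_a = character(),
                                               relation_b = character(),
                                               argument_map = character()),
                       seeds = NULL)
  if (n_exclusions > 0L) {
    for (k in seq_len(n_exclusions)) {
      pr <- sample(n, 2L)
      cl$clauses[[length(cl$clauses) + 1L]] <-
        kbharvest:::new_clause(pr, c(FALSE, FALSE), Inf, TRUE)
    }
  }
  cl
}

# Independent transcription of the Wilson score interval.
oracle_wilson <- function(k, n, alpha) {
  z <- qnorm(1 - alpha / 2)
  p <- k / n
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  c(max(0, lo), min(1, hi))
}

# Independent step-by-step transcription of Fleiss' kappa.
oracle_fleiss <- function(m) {
  N <- nrow(m); r <- sum(m[1, ])
  P_i <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(ncol(m))) s <- s + m[i, j] * (m[i, j] - 1)
    P_i[i] <- s / (r * (r - 1))
  }
  p_j <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) p_j[j] <- sum(m[, j]) / (N * r)
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# Write dictionary/hierarchy/seeds/corpus of a generated fixture to a temp
# dir and return the pipeline_config-ready paths.
write_fixture_inputs <- function(dict, seeds, gen, dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  write_dictionary(dict$dictionary, file.path(dir, "dictionary.tsv"))
  write_type_hierarchy(dict$hierarchy, file.path(dir, "hierarchy.tsv"))
  write_seed_facts(seeds, file.path(dir, "seeds.tsv"))
  write_parsed_corpus(gen$corpus, file.path(dir, "corpus.jsonl"))
  list(dictionary = file.path(dir, "dictionary.tsv"),
       hierarchy = file.path(dir, "hierarchy.tsv"),
       seeds = file.path(dir, "seeds.tsv"),
       corpus = file.path(dir, "corpus.jsonl"),
       dir = dir)
}
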