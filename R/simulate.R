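# Synthetic-corpus generator: dictionaries, seed facts, parsed sentences
# with planted pattern/seed co-occurrence structure, and DOM documents.
# Every stage of the pipeline is testable against the generator's ledger
# without any external data.

#' Default per-relation seed-fact counts
#'
#' The built-in seed inventory sizes for the thirteen relations (467 seed
#' facts in total).
#' @return named integer vector over [kb_relations()].
#' @export
default_seed_counts <- function() {
  stats::setNames(
    c(23L, 21L, 18L, 70L, 5L, 26L, 103L, 29L, 9L, 69L, 24L, 12L, 58L),
    kb_relations())
}

#' Built-in planted pattern phrases
#'
#' One connective phrase per relation, with surface and lemma forms.  The
#' phrases are token-disjoint across relations so that a planted occurrence
#' can only match seed patterns of its own relation.
#' @return named list: relation -> list(surface, lemma) of token vectors.
#' @export
relation_phrases <- function() {
  list(
    affects         = list(surface = "involves", lemma = "involve"),
    aggravates      = list(surface = "worsens", lemma = "worsen"),
    alleviates      = list(surface = "relieves", lemma = "relieve"),
    causes          = list(surface = c("results", "in"), lemma = c("result", "in")),
    complicationOf  = list(surface = "follows", lemma = "follow"),
    contraindicates = list(surface = c("contraindicated", "for"),
                           lemma = c("contraindicate", "for")),
    createsRisk     = list(surface = c("risk", "factor"), lemma = c("risk", "factor")),
    diagnoses       = list(surface = "detects", lemma = "detect"),
    interacts       = list(surface = c("interacts", "with"),
                           lemma = c("interact", "with")),
    isSymptom       = list(surface = "heralds", lemma = "herald"),
    reducesRisk     = list(surface = c("protects", "against"),
                           lemma = c("protect", "against")),
    sideEffect      = list(surface = "triggers", lemma = "trigger"),
    treats          = list(surface = "treats", lemma = "treat"))
}

# Relation-specific adverbs planted as advmod dependents; token-disjoint
# from every phrase and from each other.
relation_modifiers <- function() {
  stats::setNames(
    c("often", "severely", "partly", "directly", "rarely", "strictly",
      "strongly", "reliably", "adversely", "typically", "modestly",
      "occasionally", "effectively"),
    kb_relations())
}

#' Specification of a synthetic corpus
#'
#' Defines the statistical structure the pattern-confidence stage assumes:
#' which relations exist, how many seed pairs each has, how often each
#' planted phrase co-occurs with seed pairs of each relation, how many new
#' (harvest) facts are planted, and how much distractor noise surrounds
#' them.
#'
#' @param relations subset of [kb_relations()].
#' @param seed_pairs_per_relation named integer vector of seed-fact counts;
#'   defaults to the built-in inventory sizes ([default_seed_counts()]).
#' @param phrases named list of planted phrases (`relation ->
#'   list(surface, lemma)`); defaults to [relation_phrases()].
#' @param plan data frame (`phrase_id`, `relation`, `sentences`) stating how
#'   many sentences pair each phrase with seed pairs of each relation.
#'   `NULL` builds the default plan: each relation's own phrase with
#'   `seed_sentences_per_pattern` of its own seed pairs.
#' @param seed_sentences_per_pattern sentences pairing a phrase with its own
#'   relation's seed pairs in the default plan (default 3).
#' @param harvest_pairs_per_relation new non-seed, correctly-typed entity
#'   pairs planted with the relation's phrase: the facts the pipeline is
#'   expected to harvest (default 4).
#' @param noise_rate fraction of distractor sentences (junk connectives,
#'   non-seed entity pairs) in the final corpus, in `[0, 1]` (default 0).
#' @param type_violation_sentences sentences planting a relation's phrase
#'   between entities violating its type signature; they yield candidates
#'   that only the reasoner's type filter removes (default 0).
#' @param modifier_rate probability that a planted sentence carries the
#'   relation's adverb as an advmod dependent of the first phrase token
#'   (default 0.25).
#' @param synonym_rate fraction of entities receiving a synonym row
#'   (default 0.1).
#' @param near_miss_rate fraction of entities spawning a near-miss
#'   dictionary name (one character edit on a distractor entity, below the
#'   default match threshold) (default 0.05).
#' @param two_token_name_rate fraction of entities with two-token names
#'   (default 0.1).
#' @param edit_rate probability of perturbing a planted surface form by one
#'   character substitution, to exercise approximate matching (default 0).
#' @param dom_docs_per_relation HTML documents generated per drug-domain
#'   relation by [generate_dom_corpus()] (default 0).
#' @param dom_items_per_doc list items (facts) per DOM document (default 2).
#' @param rng_seed integer seed; all generation is deterministic given it.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(relations = kb_relations(),
                        seed_pairs_per_relation = default_seed_counts()[relations],
                        phrases = relation_phrases()[relations],
                        plan = NULL,
                        seed_sentences_per_pattern = 3L,
                        harvest_pairs_per_relation = 4L,
                        noise_rate = 0,
                        type_violation_sentences = 0L,
                        modifier_rate = 0.25,
                        synonym_rate = 0.1,
                        near_miss_rate = 0.05,
                        two_token_name_rate = 0.1,
                        edit_rate = 0,
                        dom_docs_per_relation = 0L,
                        dom_items_per_doc = 2L,
                        rng_seed = 1L) {
  stopifnot(all(relations %in% kb_relations()), length(relations) > 0L)
  if (noise_rate < 0 || noise_rate > 1) stopf("noise_rate must be in [0, 1]")
  seed_pairs_per_relation <- stats::setNames(
    as.integer(seed_pairs_per_relation), relations)
  if (any(seed_pairs_per_relation < 0L)) stopf("seed pair counts must be >= 0")
  if (is.null(plan)) {
    active <- relations[seed_pairs_per_relation[relations] > 0L]
    plan <- data.frame(phrase_id = active, relation = active,
                       sentences = pmin(seed_sentences_per_pattern,
                                        seed_pairs_per_relation[active]),
                       stringsAsFactors = FALSE)
  }
  if (!all(plan$phrase_id %in% names(phrases)))
    stopf("plan references unknown phrase id(s)")
  if (!all(plan$relation %in% relations))
    stopf("plan references unknown relation(s)")
  structure(list(
    relations = relations,
    seed_pairs_per_relation = seed_pairs_per_relation,
    phrases = phrases, plan = plan,
    harvest_pairs_per_relation = as.integer(harvest_pairs_per_relation),
    noise_rate = noise_rate,
    type_violation_sentences = as.integer(type_violation_sentences),
    modifier_rate = modifier_rate, synonym_rate = synonym_rate,
    near_miss_rate = near_miss_rate,
    two_token_name_rate = two_token_name_rate, edit_rate = edit_rate,
    dom_docs_per_relation = as.integer(dom_docs_per_relation),
    dom_items_per_doc = as.integer(dom_items_per_doc),
    rng_seed = as.integer(rng_seed)), class = "corpus_spec")
}

# --- name generation -------------------------------------------------------

CONSONANTS <- c("b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
                "t", "v", "z")
VOWELS <- c("a", "e", "i", "o", "u")

random_word <- function() {
  n_syll <- sample(3:4, 1L)
  paste0(paste0(sample(CONSONANTS, n_syll, replace = TRUE),
                sample(VOWELS, n_syll, replace = TRUE), collapse = ""))
}

# Generate `n` names mutually dissimilar in trigram space (Jaccard < 0.55),
# so synthetic names never cross-match at the default 0.7 threshold.
generate_names <- function(n, two_token_rate, existing = character(0)) {
  out <- character(0)
  grams <- lapply(existing, trigram_set)
  while (length(out) < n) {
    nm <- if (stats::runif(1) < two_token_rate)
      paste(random_word(), random_word()) else random_word()
    g <- trigram_set(nm)
    ok <- !nm %in% c(out, existing)
    if (ok && length(grams) > 0L) {
      sims <- vapply(grams, jaccard_similarity, numeric(1), b = g)
      ok <- max(sims) < 0.55
    }
    if (ok) {
      out <- c(out, nm)
      grams <- c(grams, list(g))
    }
  }
  out
}

perturb_name <- function(name) {
  chars <- strsplit(name, "")[[1]]
  letters_only <- which(chars %in% letters)
  i <- if (length(letters_only) > 0L) sample(letters_only, 1L)
       else sample(length(chars), 1L)
  repl <- sample(setdiff(letters, chars[i]), 1L)
  chars[i] <- repl
  paste(chars, collapse = "")
}

# --- dictionary ------------------------------------------------------------

# Pick a concrete type code for a signature position: one of the allowed
# coarse codes or (half the time) its finer descendant.
pick_type <- function(allowed_csv) {
  codes <- entity_type_codes(allowed_csv)
  code <- if (length(codes) == 1L) codes else sample(codes, 1L)
  if (stats::runif(1) < 0.5) paste0(code, ".fine") else code
}

#' Generate a synthetic entity dictionary with its type hierarchy
#'
#' Creates entities typed to satisfy the relation type signatures of the
#' chosen relations: one left and one right entity per seed pair, per
#' harvest pair, per type-violation pair (deliberately wrongly typed) and
#' per DOM fact, plus a pool of noise entities.  A fraction of entities get
#' synonym rows and a fraction spawn near-miss names (one-character edits
#' attached to separate distractor entities, dissimilar enough to stay
#' below the default match threshold).
#'
#' @param spec a [corpus_spec()].
#' @return list with `dictionary` (an `entity_dictionary`), `hierarchy`
#'   (a [type_hierarchy()]) and `registry` (internal bookkeeping: one row
#'   per entity with its generation role).
#' @export
generate_dictionary <- function(spec) {
  with_seed(spec$rng_seed, {
    sigs <- default_type_signatures()
    rows <- list()
    add_entity <- function(role, relation, slot, type) {
      rows[[length(rows) + 1L]] <<- data.frame(
        role = role, relation = relation, slot = slot, type = type,
        stringsAsFactors = FALSE)
    }
    for (r in spec$relations) {
      sig <- sigs[sigs$relation == r, ]
      n_seed <- spec$seed_pairs_per_relation[[r]]
      for (i in seq_len(n_seed)) {
        add_entity("seed_left", r, i, pick_type(sig$domain_types))
        add_entity("seed_right", r, i, pick_type(sig$range_types))
      }
      for (i in seq_len(spec$harvest_pairs_per_relation)) {
        add_entity("harvest_left", r, i, pick_type(sig$domain_types))
        add_entity("harvest_right", r, i, pick_type(sig$range_types))
      }
      if (spec$dom_docs_per_relation > 0L &&
          grepl("Drug", sig$domain_types, fixed = TRUE)) {
        for (d in seq_len(spec$dom_docs_per_relation)) {
          add_entity("dom_left", r, d, "Drug")
          for (i in seq_len(spec$dom_items_per_doc))
            add_entity("dom_right", r, (d - 1L) * spec$dom_items_per_doc + i,
                       pick_type(sig$range_types))
        }
      }
    }
    # wrongly-typed pairs for type-violation sentences: swap domain/range
    # sources so the left entity carries a type outside the signature
    if (spec$type_violation_sentences > 0L) {
      viol_rel <- rep(spec$relations, length.out = spec$type_violation_sentences)
      for (i in seq_len(spec$type_violation_sentences)) {
        sig <- sigs[sigs$relation == viol_rel[i], ]
        wrong <- setdiff(c("Disease", "Organ", "Ecofactor", "Drug", "Device",
                           "Symptom", "Behavior"),
                         entity_type_codes(sig$domain_types))
        add_entity("violation_left", viol_rel[i], i, sample(wrong, 1L))
        add_entity("violation_right", viol_rel[i], i, pick_type(sig$range_types))
      }
    }
    for (i in seq_len(8L)) add_entity("noise", NA_character_, i,
                                      sample(c("Disease", "Drug", "Symptom"), 1L))
    reg <- do.call(rbind, rows)
    reg$entity_id <- sprintf("E%05d", seq_len(nrow(reg)))
    reg$name <- generate_names(nrow(reg), spec$two_token_name_rate)
    # dictionary rows: canonical name per entity, synonyms, near misses
    dict_rows <- data.frame(entity_id = reg$entity_id, name = reg$name,
                            semantic_types = reg$type, is_canonical = TRUE,
                            stringsAsFactors = FALSE)
    n_syn <- round(spec$synonym_rate * nrow(reg))
    if (n_syn > 0L) {
      syn_of <- sample(nrow(reg), n_syn)
      syn_names <- generate_names(n_syn, 0, existing = reg$name)
      dict_rows <- rbind(dict_rows, data.frame(
        entity_id = reg$entity_id[syn_of], name = syn_names,
        semantic_types = reg$type[syn_of], is_canonical = FALSE,
        stringsAsFactors = FALSE))
    }
    n_miss <- round(spec$near_miss_rate * nrow(reg))
    if (n_miss > 0L) {
      miss_of <- sample(nrow(reg), n_miss)
      for (j in seq_len(n_miss)) {
        nm <- perturb_name(reg$name[miss_of[j]])
        if (nm %in% dict_rows$name) next
        dict_rows <- rbind(dict_rows, data.frame(
          entity_id = sprintf("EMISS%04d", j), name = nm,
          semantic_types = "Entity", is_canonical = TRUE,
          stringsAsFactors = FALSE))
      }
    }
    hierarchy <- default_type_hierarchy()
    list(dictionary = new_dictionary(dict_rows), hierarchy = hierarchy,
         registry = reg)
  })
}

#' Generate seed facts from a generated dictionary
#'
#' One seed fact per (relation, pair index) of the registry's seed
#' entities; pairs are ordered and type-consistent with the signatures by
#' construction.
#'
#' @param spec a [corpus_spec()].
#' @param dict result of [generate_dictionary()].
#' @return seed data frame (`relation`, `left_entity`, `right_entity`).
#' @export
generate_seed_facts <- function(spec, dict) {
  reg <- dict$registry
  rows <- list()
  for (r in spec$relations) {
    lefts <- reg[reg$role == "seed_left" & reg$relation == r, ]
    rights <- reg[reg$role == "seed_right" & reg$relation == r, ]
    lefts <- lefts[order(lefts$slot), ]
    rights <- rights[order(rights$slot), ]
    if (nrow(lefts) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        relation = r, left_entity = lefts$entity_id,
        right_entity = rights$entity_id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build one planted parsed sentence
#'
#' Lays out `left-entity tokens, phrase tokens, right-entity tokens` with a
#' right-branching dependency chain (each phrase token governs the next;
#' the left entity head governs the first phrase token, the last phrase
#' token governs the right entity head), so the shortest dependency path
#' between the entity heads is exactly the phrase.  An optional modifier
#' token is appended and attached by `advmod` to the first phrase token.
#'
#' @param doc_id,sent_id identifiers.
#' @param left_surface,right_surface entity surface strings (tokens split
#'   on spaces; multi-token names hang off their first token by `compound`
#'   edges).
#' @param phrase list with `surface` and `lemma` token vectors.
#' @param modifier optional single modifier word (surface = lemma), or
#'   `NULL`.
#' @param genre,source document metadata.
#' @return a [parsed_sentence()].
#' @export
make_planted_sentence <- function(doc_id, sent_id, left_surface, right_surface,
                                  phrase, modifier = NULL,
                                  genre = "scientific", source = "synthetic") {
  lt <- strsplit(left_surface, " ", fixed = TRUE)[[1]]
  rt <- strsplit(right_surface, " ", fixed = TRUE)[[1]]
  ps <- phrase$surface
  pl <- phrase$lemma
  if (length(ps) != length(pl)) stopf("phrase surface/lemma length mismatch")
  surfaces <- c(lt, ps, rt)
  lemmas <- c(lt, pl, rt)
  pos <- c(rep("NN", length(lt)), rep("XX", length(ps)), rep("NN", length(rt)))
  lh <- 0L                                  # left entity head
  p0 <- length(lt)                          # first phrase token
  pk <- length(lt) + length(ps) - 1L        # last phrase token
  rh <- length(lt) + length(ps)             # right entity head
  edges <- data.frame(gov = lh, dep = p0, label = "dep",
                      stringsAsFactors = FALSE)
  if (length(ps) > 1L)
    edges <- rbind(edges, data.frame(gov = p0:(pk - 1L), dep = (p0 + 1L):pk,
                                     label = "dep", stringsAsFactors = FALSE))
  edges <- rbind(edges, data.frame(gov = pk, dep = rh, label = "dep",
                                   stringsAsFactors = FALSE))
  if (length(lt) > 1L)
    edges <- rbind(edges, data.frame(gov = 0L, dep = 1:(length(lt) - 1L),
                                     label = "compound", stringsAsFactors = FALSE))
  if (length(rt) > 1L)
    edges <- rbind(edges, data.frame(gov = rh, dep = (rh + 1L):(rh + length(rt) - 1L),
                                     label = "compound", stringsAsFactors = FALSE))
  if (!is.null(modifier)) {
    mi <- length(surfaces)
    surfaces <- c(surfaces, modifier)
    lemmas <- c(lemmas, modifier)
    pos <- c(pos, "RB")
    edges <- rbind(edges, data.frame(gov = p0, dep = mi, label = "advmod",
                                     stringsAsFactors = FALSE))
  }
  parsed_sentence(doc_id, sent_id,
                  tokens = data.frame(index = seq_along(surfaces) - 1L,
                                      surface = surfaces, lemma = lemmas,
                                      pos = pos, stringsAsFactors = FALSE),
                  edges = edges, genre = genre, source = source)
}

GENRES <- data.frame(
  genre = c("scientific", "encyclopedic", "social"),
  source = c("synthetic-journal", "synthetic-portal", "synthetic-forum"),
  stringsAsFactors = FALSE)

#' Generate a planted parsed corpus with its ground-truth ledger
#'
#' Realizes the spec's co-occurrence plan exactly: for every plan row
#' `(phrase, relation, n)`, `n` sentences each embed the phrase between a
#' distinct seed pair of that relation (an error is raised when a plan row
#' asks for more sentences than the relation has seed pairs).  Harvest
#' sentences then plant each relation's phrase between fresh,
#' correctly-typed non-seed pairs -- the facts the pipeline should recover.
#' Optional noise sentences (junk connectives between noise entities) and
#' type-violation sentences are appended.  The ledger records every planted
#' mention, pattern occurrence and intended fact.
#'
#' @param spec a [corpus_spec()].
#' @param dict result of [generate_dictionary()].
#' @param seeds result of [generate_seed_facts()].
#' @param path optional file path; when given the corpus is also written as
#'   JSON Lines.
#' @return list with `corpus` (a `parsed_corpus`), `ledger` (list of data
#'   frames `mentions`, `patterns`, `facts`, and `counts`), and `path`.
#' @export
generate_parsed_corpus <- function(spec, dict, seeds, path = NULL) {
  reg <- dict$registry
  name_of <- stats::setNames(reg$name, reg$entity_id)
  mods <- relation_modifiers()
  with_seed(spec$rng_seed + 1L, {
    sentences <- list()
    mention_rows <- list()
    pattern_rows <- list()
    fact_rows <- list()
    sent_no <- 0L

    surface_of <- function(entity_id) {
      nm <- name_of[[entity_id]]
      if (stats::runif(1) < spec$edit_rate) perturb_name(nm) else nm
    }
    emit <- function(phrase_id, relation, left_id, right_id, kind) {
      sent_no <<- sent_no + 1L
      doc <- sprintf("D%04d", (sent_no - 1L) %/% 5L + 1L)
      sid <- sprintf("S%d", (sent_no - 1L) %% 5L + 1L)
      gi <- (((sent_no - 1L) %/% 5L) %% 3L) + 1L
      phrase <- spec$phrases[[phrase_id]]
      modifier <- if (!is.na(relation) && stats::runif(1) < spec$modifier_rate)
        mods[[relation]] else NULL
      ls <- surface_of(left_id)
      rs <- surface_of(right_id)
      s <- make_planted_sentence(doc, sid, ls, rs, phrase, modifier,
                                 genre = GENRES$genre[gi],
                                 source = GENRES$source[gi])
      sentences[[length(sentences) + 1L]] <<- s
      nl <- length(strsplit(ls, " ", fixed = TRUE)[[1]])
      np <- length(phrase$surface)
      nr <- length(strsplit(rs, " ", fixed = TRUE)[[1]])
      mention_rows[[length(mention_rows) + 1L]] <<- data.frame(
        doc_id = doc, sent_id = sid,
        start = c(0L, nl + np), end = c(nl, nl + np + nr),
        entity_id = c(left_id, right_id), surface = c(ls, rs),
        similarity = c(jaccard_similarity(trigram_set(ls),
                                          trigram_set(name_of[[left_id]])),
                       jaccard_similarity(trigram_set(rs),
                                          trigram_set(name_of[[right_id]]))),
        stringsAsFactors = FALSE)
      pattern_rows[[length(pattern_rows) + 1L]] <<- data.frame(
        doc_id = doc, sent_id = sid, phrase_id = phrase_id,
        pattern = pattern_key(phrase$lemma),
        relation = relation, left_entity = left_id, right_entity = right_id,
        kind = kind, stringsAsFactors = FALSE)
    }

    # 1) plan rows: phrase x seed pairs of the stated relation, exact counts
    for (i in seq_len(nrow(spec$plan))) {
      r <- spec$plan$relation[i]
      n <- spec$plan$sentences[i]
      pool <- seeds[seeds$relation == r, , drop = FALSE]
      if (n > nrow(pool))
        stopf("infeasible plan: %d sentence(s) requested for relation %s but only %d seed pair(s)",
              n, r, nrow(pool))
      use <- pool[seq_len(n), , drop = FALSE]
      for (j in seq_len(n)) {
        emit(spec$plan$phrase_id[i], r, use$left_entity[j], use$right_entity[j],
             kind = "seed")
        fact_rows[[length(fact_rows) + 1L]] <- data.frame(
          relation = r, left_entity = use$left_entity[j],
          right_entity = use$right_entity[j], truth = TRUE, kind = "seed",
          stringsAsFactors = FALSE)
      }
    }

    # 2) harvest sentences: each relation's own phrase between fresh pairs
    for (r in spec$relations) {
      if (!r %in% names(spec$phrases)) next
      lefts <- reg[reg$role == "harvest_left" & reg$relation == r, ]
      rights <- reg[reg$role == "harvest_right" & reg$relation == r, ]
      lefts <- lefts[order(lefts$slot), ]
      rights <- rights[order(rights$slot), ]
      for (j in seq_len(nrow(lefts))) {
        emit(r, r, lefts$entity_id[j], rights$entity_id[j], kind = "harvest")
        fact_rows[[length(fact_rows) + 1L]] <- data.frame(
          relation = r, left_entity = lefts$entity_id[j],
          right_entity = rights$entity_id[j], truth = TRUE, kind = "harvest",
          stringsAsFactors = FALSE)
      }
    }

    # 3) type-violation sentences: the phrase with a wrongly-typed pair
    if (spec$type_violation_sentences > 0L) {
      vl <- reg[reg$role == "violation_left", ]
      vr <- reg[reg$role == "violation_right", ]
      vl <- vl[order(vl$slot), ]; vr <- vr[order(vr$slot), ]
      for (j in seq_len(nrow(vl))) {
        r <- vl$relation[j]
        emit(r, r, vl$entity_id[j], vr$entity_id[j], kind = "violation")
        fact_rows[[length(fact_rows) + 1L]] <- data.frame(
          relation = r, left_entity = vl$entity_id[j],
          right_entity = vr$entity_id[j], truth = FALSE, kind = "violation",
          stringsAsFactors = FALSE)
      }
    }

    # 4) noise: junk connectives between noise entities; no seed pairs, so
    # these never enter a confidence ratio and never match a seed pattern
    n_planted <- sent_no
    n_noise <- if (spec$noise_rate >= 1) 0L else
      round(spec$noise_rate / (1 - spec$noise_rate) * n_planted)
    if (n_noise > 0L) {
      pool <- reg$entity_id[reg$role == "noise"]
      for (j in seq_len(n_noise)) {
        junk <- list(surface = c(random_word(), random_word()))
        junk$lemma <- junk$surface
        pair <- sample(pool, 2L)
        spec_local <- list(surface = junk$surface, lemma = junk$lemma)
        sent_no <- sent_no + 1L
        doc <- sprintf("D%04d", (sent_no - 1L) %/% 5L + 1L)
        sid <- sprintf("S%d", (sent_no - 1L) %% 5L + 1L)
        gi <- (((sent_no - 1L) %/% 5L) %% 3L) + 1L
        s <- make_planted_sentence(doc, sid, name_of[[pair[1L]]],
                                   name_of[[pair[2L]]], spec_local, NULL,
                                   genre = GENRES$genre[gi],
                                   source = GENRES$source[gi])
        sentences[[length(sentences) + 1L]] <- s
      }
    }

    corpus <- new_parsed_corpus(sentences)
    ledger <- list(
      mentions = do.call(rbind, mention_rows),
      patterns = do.call(rbind, pattern_rows),
      facts = do.call(rbind, fact_rows),
      counts = list(
        n_sentences = length(sentences),
        n_tokens = sum(vapply(sentences, function(s) nrow(s$tokens), integer(1))),
        n_edges = sum(vapply(sentences, function(s) nrow(s$edges), integer(1)))))
    rownames(ledger$mentions) <- rownames(ledger$patterns) <-
      rownames(ledger$facts) <- NULL
    if (!is.null(path)) write_parsed_corpus(corpus, path)
    list(corpus = corpus, ledger = ledger, path = path)
  })
}

#' Generate synthetic HTML documents with planted DOM patterns
#'
#' For each drug-domain relation (signature domain containing `Drug`),
#' documents with a single-entity `<h1>` title (a drug), one `<h2>` heading
#' carrying the relation's phrase lemmas, and `<li>` items naming
#' correctly-typed right-argument entities.  The ledger records the
#' intended (title, headings, item) triples and facts.
#'
#' @param spec a [corpus_spec()] with `dom_docs_per_relation > 0`.
#' @param dict result of [generate_dictionary()].
#' @param dir optional directory; when given each document is written as
#'   `<doc_id>.html`.
#' @return list with `documents` (named list of HTML strings), `ledger`
#'   (data frames `dom_patterns` and `facts`), and `dir`.
#' @export
generate_dom_corpus <- function(spec, dict, dir = NULL) {
  reg <- dict$registry
  name_of <- stats::setNames(reg$name, reg$entity_id)
  docs <- list()
  pat_rows <- list()
  fact_rows <- list()
  for (r in spec$relations) {
    lefts <- reg[reg$role == "dom_left" & reg$relation == r, ]
    if (nrow(lefts) == 0L) next
    rights <- reg[reg$role == "dom_right" & reg$relation == r, ]
    rights <- rights[order(rights$slot), ]
    heading <- pattern_key(spec$phrases[[r]]$lemma)
    for (d in seq_len(nrow(lefts))) {
      doc_id <- sprintf("H-%s-%d", r, d)
      items <- rights[((d - 1L) * spec$dom_items_per_doc + 1L):
                        (d * spec$dom_items_per_doc), , drop = FALSE]
      lis <- paste0("<li>", name_of[items$entity_id], "</li>", collapse = "")
      html <- paste0("<html><body><h1>", name_of[lefts$entity_id[d]],
                     "</h1><h2>", heading, "</h2><ul>", lis,
                     "</ul></body></html>")
      docs[[doc_id]] <- html
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        writeLines(html, file.path(dir, paste0(doc_id, ".html")))
      }
      for (i in seq_len(nrow(items))) {
        pat_rows[[length(pat_rows) + 1L]] <- data.frame(
          doc_id = doc_id, title_entity = lefts$entity_id[d],
          heading = heading, item_entity = items$entity_id[i],
          relation = r, stringsAsFactors = FALSE)
        fact_rows[[length(fact_rows) + 1L]] <- data.frame(
          relation = r, left_entity = lefts$entity_id[d],
          right_entity = items$entity_id[i], truth = TRUE, kind = "dom",
          stringsAsFactors = FALSE)
      }
    }
  }
  list(documents = docs,
       ledger = list(dom_patterns = do.call(rbind, pat_rows),
                     facts = do.call(rbind, fact_rows)),
       dir = dir)
}
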