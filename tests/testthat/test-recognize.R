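# Entity recognition: trigram sets, MinHash/LSH index, mention resolution.

test_that("trigram sets follow the lowercase/normalize/pad rules", {
  expect_identical(trigram_set("ab"), c("#ab", "ab#"))
  expect_identical(trigram_set("a"), c("#a#"))
  expect_identical(trigram_set("Heart  Attack"), trigram_set("heart attack"))
  expect_error(trigram_set("   "), "empty")
  # identical strings: identical sets, Jaccard 1
  expect_identical(jaccard_similarity(trigram_set("asthma"),
                                      trigram_set("asthma")), 1)
})

test_that("Jaccard matches a brute-force set enumeration", {
  # independent enumeration: sliding window by hand
  brute <- function(a, b, n = 3) {
    grams <- function(s) {
      s <- tolower(s)
      out <- character(0)
      for (i in 1:(nchar(s) - n + 1)) out <- c(out, substr(s, i, i + n - 1))
      unique(out)
    }
    ga <- grams(a); gb <- grams(b)
    both <- sum(ga %in% gb)
    both / (length(ga) + length(gb) - both)
  }
  pairs <- list(c("sarcoidosis", "sarcoidoses"),
                c("myocardial infarction", "myocardial infarctions"),
                c("asthma", "asthmatic"),
                c("heart attack", "heart attacks"))
  for (p in pairs)
    expect_equal(jaccard_similarity(trigram_set(p[1]), trigram_set(p[2])),
                 brute(p[1], p[2]))
})

test_that("index is deterministic and every name retrieves itself", {
  dict <- tiny_dictionary()
  i1 <- build_match_index(dict)
  i2 <- build_match_index(dict)
  expect_identical(i1$signatures, i2$signatures)
  # different hash seed: different signatures
  i3 <- build_match_index(dict, match_index_params(hash_seed = 7L))
  expect_false(identical(i1$signatures, i3$signatures))
  expect_error(match_index_params(signature_length = 100, band_count = 32),
               "divisible")

  # exhaustive self-query over a generated name inventory
  set.seed(301)
  nms <- kbharvest:::generate_names(1000, two_token_rate = 0.1)
  big <- entity_dictionary(sprintf("E%04d", seq_along(nms)), nms, "Disease")
  idx <- build_match_index(big)
  ok <- vapply(seq_along(nms), function(i) {
    hits <- match_text(idx, nms[i])
    any(hits$entity_id == big$entity_id[i] & hits$similarity == 1)
  }, logical(1))
  expect_true(all(ok))
})

test_that("mentions carry exact similarity and synonyms resolve to one entity", {
  dict <- tiny_dictionary()
  idx <- build_match_index(dict)
  s <- make_planted_sentence("d", "s", "heart attack", "asthma",
                             list(surface = c("leads", "to"),
                                  lemma = c("lead", "to")))
  m <- recognize_mentions(s, idx)
  ha <- m[m$start == 0 & m$end == 2, ]
  expect_identical(ha$entity_id, "E1")       # synonym -> canonical entity id
  expect_identical(ha$similarity, 1)
  expect_true(any(m$entity_id == "E2" & m$similarity == 1))
})

test_that("no emitted mention falls below the verification threshold", {
  spec <- corpus_spec(relations = c("treats", "affects"),
                      seed_pairs_per_relation = c(treats = 6, affects = 6),
                      harvest_pairs_per_relation = 2,
                      edit_rate = 0.5, near_miss_rate = 0.3, rng_seed = 5)
  dict <- generate_dictionary(spec)
  seeds <- generate_seed_facts(spec, dict)
  gen <- generate_parsed_corpus(spec, dict, seeds)
  for (thr in c(0.4, 0.7)) {
    idx <- build_match_index(dict$dictionary,
                             match_index_params(threshold = thr))
    sims <- unlist(lapply(gen$corpus$sentences, function(s)
      recognize_mentions(s, idx)$similarity))
    expect_true(all(sims >= thr))
  }
})

test_that("planted surface forms are recalled at matching thresholds", {
  spec <- corpus_spec(relations = c("treats", "causes"),
                      seed_pairs_per_relation = c(treats = 5, causes = 5),
                      harvest_pairs_per_relation = 2, rng_seed = 9)
  dict <- generate_dictionary(spec)
  seeds <- generate_seed_facts(spec, dict)
  gen <- generate_parsed_corpus(spec, dict, seeds)
  idx <- build_match_index(dict$dictionary)
  led <- gen$ledger$mentions
  sent_of <- stats::setNames(gen$corpus$sentences,
                             vapply(gen$corpus$sentences, function(s)
                               paste(s$doc_id, s$sent_id), character(1)))
  found <- vapply(seq_len(nrow(led)), function(i) {
    s <- sent_of[[paste(led$doc_id[i], led$sent_id[i])]]
    m <- recognize_mentions(s, idx)
    any(m$start == led$start[i] & m$end == led$end[i] &
          m$entity_id == led$entity_id[i])
  }, logical(1))
  expect_true(all(found[led$similarity >= 0.7]))
  expect_true(all(led$similarity == 1))  # edit_rate 0: exact surfaces
})

test_that("overlap resolution keeps deepest types and longest spans, idempotently", {
  h <- type_hierarchy(c(Entity = "", Disease = "Entity",
                        Neoplasm = "Disease", Carcinoma = "Neoplasm",
                        Finding = "Entity"))
  m <- data.frame(
    doc_id = "d", sent_id = "s",
    start = c(0L, 0L, 0L, 3L), end = c(2L, 2L, 3L, 4L),
    entity_id = c("A", "B", "C", "D"),
    semantic_types = c("Disease", "Carcinoma", "Finding", "Disease"),
    matched_name = "x", similarity = 1, stringsAsFactors = FALSE)
  out <- resolve_overlaps(m, h)
  # [0,3) subsumes both [0,2) mentions; [3,4) untouched
  expect_setequal(out$entity_id, c("C", "D"))
  # same-span depth contest once subsumer removed
  m2 <- m[m$start == 0 & m$end == 2, ]
  out2 <- resolve_overlaps(m2, h)
  expect_identical(out2$entity_id, "B")   # Carcinoma depth 3 > Disease depth 1
  # ties keep all
  m3 <- m2; m3$semantic_types <- c("Neoplasm", "Neoplasm")
  expect_identical(nrow(resolve_overlaps(m3, h)), 2L)
  # idempotence
  expect_identical(resolve_overlaps(out, h), out)
  # unknown code: depth 0 with warning
  m4 <- m2; m4$semantic_types <- c("Mystery", "Disease")
  expect_warning(out4 <- resolve_overlaps(m4, h), "absent")
  expect_identical(out4$entity_id, "B")
  # single mention unchanged
  expect_identical(resolve_overlaps(m[4, ], h)$entity_id, "D")
})

test_that("MinHash estimates track exact Jaccard (signature length 256)", {
  params <- match_index_params(signature_length = 256L, band_count = 32L)
  coef <- kbharvest:::minhash_coefficients(params)
  set.seed(77)
  devs <- replicate(400, {
    base <- paste(sample(letters, sample(8:16, 1), replace = TRUE),
                  collapse = "")
    other <- if (runif(1) < 0.5) {
      kbharvest:::perturb_name(base)
    } else {
      paste0(substr(base, 1, sample(3:nchar(base), 1)),
             paste(sample(letters, 4, replace = TRUE), collapse = ""))
    }
    g1 <- trigram_set(base); g2 <- trigram_set(other)
    abs(minhash_estimate(kbharvest:::minhash_signature(g1, coef),
                         kbharvest:::minhash_signature(g2, coef)) -
          jaccard_similarity(g1, g2))
  })
  expect_gte(mean(devs <= 0.1), 0.95)
})
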