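# Distant supervision: seed index, subsequence mining, confidence, scoring.

test_that("seed index partitions pairs into sx and cx", {
  seeds <- data.frame(
    relation = c("treats", "treats", "causes", "isSymptom"),
    left_entity = c("D1", "D2", "X1", "S1"),
    right_entity = c("I1", "I2", "X2", "X1"),
    stringsAsFactors = FALSE)
  idx <- build_seed_index(seeds)
  expect_length(idx$sx$treats, 2L)
  expect_length(idx$cx$treats, 2L)
  for (r in kb_relations()) {
    expect_length(intersect(idx$sx[[r]], idx$cx[[r]]), 0L)
    expect_setequal(c(idx$sx[[r]], idx$cx[[r]]), idx$all_pairs)
  }
  # single-relation seeds: empty cx
  idx1 <- build_seed_index(seeds[seeds$relation == "treats", ])
  expect_length(idx1$cx$treats, 0L)
  expect_error(build_seed_index(data.frame(relation = "foo",
                                           left_entity = "a",
                                           right_entity = "b")),
               "unknown relation")
})

test_that("the built-in seed inventory realizes the per-relation counts", {
  spec <- corpus_spec(rng_seed = 3)
  dict <- generate_dictionary(spec)
  seeds <- generate_seed_facts(spec, dict)
  expect_identical(nrow(seeds), 467L)
  counts <- table(seeds$relation)
  want <- default_seed_counts()
  expect_identical(as.integer(counts[names(want)]), unname(want))
})

test_that("frequent subsequences include generalizations like 'risk factor'", {
  occ <- data.frame(
    pattern = c("known risk factors", "have risk factors",
                "children risk factors"),
    left_entity = c("a", "b", "c"), right_entity = c("x", "y", "z"),
    doc_id = "d", locator = c("s1", "s2", "s3"), kind = "sentence",
    stringsAsFactors = FALSE)
  mined <- mine_frequent_subsequences(occ, min_support = 3)
  expect_true("risk factors" %in% mined$pattern)
  expect_true(all(mined$support >= 3))
  # min_support above the occurrence count: empty
  expect_identical(nrow(mine_frequent_subsequences(occ, min_support = 4)), 0L)
})

test_that("mining agrees with brute-force subsequence enumeration", {
  set.seed(55)
  vocab <- c("a", "b", "c", "d")
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    pats <- replicate(k, paste(sample(vocab, sample(1:4, 1), replace = TRUE),
                               collapse = " "))
    occ <- data.frame(pattern = pats, left_entity = "l", right_entity = "r",
                      doc_id = "d", locator = paste0("s", seq_len(k)),
                      kind = "sentence", stringsAsFactors = FALSE)
    # oracle: enumerate all subsequences of every pattern, count containment
    subseq_all <- function(tok) {
      out <- character(0)
      n <- length(tok)
      for (mask in 1:(2^n - 1)) {
        keep <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
        out <- c(out, paste(tok[keep], collapse = " "))
      }
      unique(out)
    }
    is_sub <- function(q, p) {
      qt <- strsplit(q, " ")[[1]]; pt <- strsplit(p, " ")[[1]]
      i <- 1
      for (t in pt) if (i <= length(qt) && t == qt[i]) i <- i + 1
      i > length(qt)
    }
    cand <- unique(unlist(lapply(pats, function(p)
      subseq_all(strsplit(p, " ")[[1]]))))
    support <- vapply(cand, function(q)
      sum(vapply(pats, function(p) is_sub(q, p), logical(1))), numeric(1))
    for (ms in 1:3) {
      want <- sort(cand[support >= ms])
      got <- sort(mine_frequent_subsequences(occ, min_support = ms)$pattern)
      expect_identical(got, want)
    }
  }
})

test_that("confidence reproduces the worked ratios 1.0, 2/3 and 1/3", {
  fx <- confidence_fixture("risk_factor")
  expect_identical(compute_confidence("risk factor", "createsRisk",
                                      fx$occurrences, fx$seed_index), 1)
  fx2 <- confidence_fixture("progress")
  mined <- mine_frequent_subsequences(fx2$occurrences, min_support = 2)
  expect_true("progress" %in% mined$pattern)
  expect_identical(compute_confidence("progress", "createsRisk",
                                      fx2$occurrences, fx2$seed_index), 0.5)
  expect_identical(compute_confidence("progress", "causes",
                                      fx2$occurrences, fx2$seed_index), 0.5)
  fx3 <- confidence_fixture("occur")
  expect_equal(compute_confidence("occur", "affects",
                                  fx3$occurrences, fx3$seed_index), 2 / 3)
  expect_equal(compute_confidence("occur", "isSymptom",
                                  fx3$occurrences, fx3$seed_index), 1 / 3)
  # a pattern never co-occurring with a seed pair is undefined
  expect_true(is.na(compute_confidence("nonexistent", "causes",
                                       fx3$occurrences, fx3$seed_index)))
})

test_that("confidences over relations sum to 1 when seed pairs are unambiguous", {
  fx <- confidence_fixture("occur")
  confs <- pattern_confidences(fx$occurrences, fx$seed_index)
  for (q in unique(confs$pattern)) {
    expect_equal(sum(confs$confidence[confs$pattern == q]), 1)
    expect_true(all(confs$confidence >= 0 & confs$confidence <= 1))
  }
})

test_that("seed-pattern selection is strictly greater-than the threshold", {
  confs <- data.frame(pattern = c("p1", "p2", "p3"),
                      relation = "treats",
                      confidence = c(0.31, 0.30, 0.29),
                      stringsAsFactors = FALSE)
  sel <- select_seed_patterns(confs, threshold = 0.3)
  expect_identical(sel$pattern, "p1")
  # the 2/3-1/3 fixture keeps the pattern under both relations
  fx <- confidence_fixture("occur")
  sel2 <- select_seed_patterns(pattern_confidences(fx$occurrences, fx$seed_index),
                               threshold = 0.3)
  occ_rows <- sel2[sel2$pattern == "occur", ]
  expect_setequal(occ_rows$relation, c("affects", "isSymptom"))
  # refilter oracle on random confidences
  set.seed(12)
  rnd <- data.frame(pattern = sprintf("q%d", 1:50),
                    relation = sample(kb_relations(), 50, replace = TRUE),
                    confidence = round(runif(50), 2), stringsAsFactors = FALSE)
  sel3 <- select_seed_patterns(rnd, threshold = 0.3)
  manual <- rnd[rnd$confidence > 0.3, ]
  expect_setequal(paste(sel3$pattern, sel3$relation),
                  paste(manual$pattern, manual$relation))
})

test_that("pattern scoring takes the exhaustive maximum of Jaccard x confidence", {
  Q <- select_seed_patterns(data.frame(
    pattern = c("risk factor", "progress", "treat", "protect against"),
    relation = c("createsRisk", "createsRisk", "treats", "reducesRisk"),
    confidence = c(1, 0.5, 0.9, 0.8), stringsAsFactors = FALSE), 0)
  # identity: p == q gives w = confidence(q)
  got <- score_pattern("risk factor", Q)
  expect_identical(got$weight, 1)
  expect_identical(got$relation, "createsRisk")
  # no shared token: no candidate
  expect_null(score_pattern("entirely unrelated", Q))
  # exhaustive evaluation over all pairs
  set.seed(31)
  vocab <- c("risk", "factor", "progress", "treat", "protect", "against", "zz")
  for (rep in 1:20) {
    p <- sample(vocab, sample(1:4, 1))
    w <- vapply(seq_len(nrow(Q)), function(i) {
      qt <- unique(strsplit(Q$pattern[i], " ")[[1]])
      ps <- unique(p)
      (length(intersect(ps, qt)) / length(union(ps, qt))) * Q$confidence[i]
    }, numeric(1))
    got <- score_pattern(p, Q)
    if (max(w) == 0) expect_null(got) else expect_equal(got$weight, max(w))
  }
})

test_that("candidates aggregate supporting occurrences by noisy-or", {
  Q <- select_seed_patterns(data.frame(
    pattern = c("alpha", "beta"), relation = c("treats", "treats"),
    confidence = c(0.6, 0.5), stringsAsFactors = FALSE), 0)
  occ <- data.frame(
    pattern = c("alpha", "alpha beta", "alpha", "gamma"),
    left_entity = c("D1", "D1", "D2", "D3"),
    right_entity = c("I1", "I1", "I2", "I3"),
    doc_id = "d", locator = c("s1", "s2", "s3", "s4"), kind = "sentence",
    stringsAsFactors = FALSE)
  cands <- build_fact_candidates(occ, Q)
  one <- cands[cands$left_entity == "D2", ]
  expect_identical(one$weight, 0.6)           # single support: identity
  two <- cands[cands$left_entity == "D1", ]
  # supports: w1 = 0.6 (identical to 'alpha'); w2 = max(J({alpha,beta},{alpha})
  # x 0.6, J x 0.5) = 0.3; noisy-or = 1 - 0.4 * 0.7
  expect_equal(two$weight, 1 - (1 - 0.6) * (1 - 0.3))
  expect_identical(nrow(two$support[[1]]), 2L)
  expect_false("D3" %in% cands$left_entity)   # zero-weight: no candidate
  # noisy-or closed form 1 - 0.5 * 0.5
  Q2 <- select_seed_patterns(data.frame(pattern = "alpha", relation = "treats",
                                        confidence = 0.5,
                                        stringsAsFactors = FALSE), 0)
  occ2 <- occ[c(1, 1), ]; occ2$locator <- c("s1", "s9")
  expect_equal(build_fact_candidates(occ2, Q2)$weight, 0.75)
  # monotonicity: adding support never decreases weight
  expect_gte(two$weight, 0.6)
})

test_that("the candidate table is a deterministic function of its inputs", {
  fx <- confidence_fixture("risk_factor")
  Q <- select_seed_patterns(pattern_confidences(fx$occurrences, fx$seed_index))
  c1 <- build_fact_candidates(fx$occurrences, Q)
  c2 <- build_fact_candidates(fx$occurrences, Q)
  expect_identical(c1, c2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write.table(c1[, 1:4], f1, sep = "\t"); write.table(c2[, 1:4], f2, sep = "\t")
  expect_identical(readLines(f1), readLines(f2))
})
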