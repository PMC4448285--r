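# Consistency reasoning: type signatures, grounding, DUC + Johnson Max-Sat.

cand_row <- function(relation, left, right, weight = 0.5) {
  out <- data.frame(relation = relation, left_entity = left,
                    right_entity = right, weight = weight,
                    stringsAsFactors = FALSE)
  out$support <- list(data.frame(pattern = "p", doc_id = "d", locator = "s",
                                 kind = "sentence", occ_weight = weight,
                                 stringsAsFactors = FALSE))
  out
}

test_that("type signatures accept matching and reject mismatching arguments", {
  sig <- default_type_signatures()
  h <- default_type_hierarchy()
  types <- list(dis = "Disease", org = "Organ", drg = "Drug",
                fine = "Disease.fine")
  expect_true(check_type_signature(
    list(relation = "affects", left_entity = "dis", right_entity = "org"),
    sig, types, h)$pass)
  bad <- check_type_signature(
    list(relation = "affects", left_entity = "dis", right_entity = "drg"),
    sig, types, h)
  expect_false(bad$pass)
  expect_match(bad$reason, "range")
  # descendant of a signature type passes (hierarchy-walk oracle)
  expect_true("Disease" %in% type_ancestors("Disease.fine", h))
  expect_true(check_type_signature(
    list(relation = "causes", left_entity = "fine", right_entity = "dis"),
    sig, types, h)$pass)
  expect_error(check_type_signature(
    list(relation = "unknownRel", left_entity = "dis", right_entity = "org"),
    sig, types, h), "unknown relation")
})

test_that("clause counts equal candidates + instantiated exclusions + seed units", {
  cands <- rbind(cand_row("sideEffect", "S1", "DR1", 0.9),
                 cand_row("treats", "DR1", "S1", 0.4),
                 cand_row("treats", "DR2", "D5", 0.7))
  cl <- ground_clauses(cands, default_exclusions(), seeds = NULL)
  expect_identical(length(cl$clauses), 3L + 1L)  # one instantiated exclusion
  hard <- Filter(function(c) c$hard, cl$clauses)
  expect_length(hard, 1L)
  expect_setequal(hard[[1]]$vars, c(1L, 2L))
  expect_identical(hard[[1]]$signs, c(FALSE, FALSE))
  # no exclusions: soft units only
  cl2 <- ground_clauses(cands[3, ], default_exclusions(), seeds = NULL)
  expect_length(cl2$clauses, 1L)
  # seeds present among candidates become hard positives
  seeds <- data.frame(relation = "treats", left_entity = "DR2",
                      right_entity = "D5", stringsAsFactors = FALSE)
  cl3 <- ground_clauses(cands, default_exclusions(), seeds = seeds)
  expect_identical(length(cl3$clauses), 3L + 1L + 1L)
  # exclusion between two seed-pinned facts is infeasible at grounding
  seeds2 <- rbind(seeds,
                  data.frame(relation = "sideEffect", left_entity = "S1",
                             right_entity = "DR1", stringsAsFactors = FALSE),
                  data.frame(relation = "treats", left_entity = "DR1",
                             right_entity = "S1", stringsAsFactors = FALSE))
  expect_error(ground_clauses(cands, default_exclusions(), seeds = seeds2),
               "infeasible")
})

test_that("weight dominance decides the documented side-effect/treats conflict", {
  cands <- rbind(cand_row("sideEffect", "S1", "DR1", 0.9),
                 cand_row("treats", "DR1", "S1", 0.4))
  cl <- ground_clauses(cands, default_exclusions())
  sol <- solve_weighted_maxsat(cl)
  expect_identical(sol$assignment, c(TRUE, FALSE))
  expect_equal(sol$satisfied_weight, 0.9)
  res <- extract_accepted_facts(sol, cands)
  expect_identical(res$accepted$relation, "sideEffect")
  expect_identical(res$rejected$relation, "treats")
})

test_that("conflict-free instances accept everything at full weight", {
  set.seed(2)
  cands <- do.call(rbind, lapply(1:8, function(i)
    cand_row("treats", sprintf("D%d", i), sprintf("I%d", i), runif(1))))
  cl <- ground_clauses(cands, default_exclusions())
  sol <- solve_weighted_maxsat(cl)
  expect_true(all(sol$assignment))
  expect_equal(sol$satisfied_weight, sum(cands$weight))
  res <- extract_accepted_facts(sol, cands)
  expect_identical(nrow(res$accepted), 8L)
})

test_that("a seed-pinned fact survives even against a heavier conflicting fact", {
  cands <- rbind(cand_row("sideEffect", "S1", "DR1", 0.9),
                 cand_row("treats", "DR1", "S1", 0.4))
  seeds <- data.frame(relation = "treats", left_entity = "DR1",
                      right_entity = "S1", stringsAsFactors = FALSE)
  cl <- ground_clauses(cands, default_exclusions(), seeds = seeds)
  sol <- solve_weighted_maxsat(cl)
  expect_identical(sol$assignment, c(FALSE, TRUE))
})

test_that("heuristic stays within the oracle bound and never violates hard clauses", {
  set.seed(7)
  worst <- 1
  for (i in 1:200) {
    n <- sample(2:12, 1)
    n_ex <- sample(0:min(4, n %/% 2), 1)
    cl <- random_maxsat_instance(n, n_ex)
    sol <- solve_weighted_maxsat(cl)
    opt <- oracle_maxsat(cl)
    for (c2 in cl$clauses) {
      if (c2$hard)
        expect_true(any(sol$assignment[c2$vars] == c2$signs))
    }
    if (opt > 0) worst <- min(worst, sol$satisfied_weight / opt)
    if (n_ex == 0) expect_equal(sol$satisfied_weight, opt)
  }
  expect_gte(worst, 0.5)
})

test_that("removing exclusions never shrinks the accepted set; output is deterministic", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    cl_free <- random_maxsat_instance(n, 0)
    seed_state <- .Random.seed
    cl_con <- cl_free
    n_ex <- sample(1:3, 1)
    for (k in seq_len(n_ex)) {
      pr <- sample(n, 2)
      cl_con$clauses[[length(cl_con$clauses) + 1L]] <-
        kbharvest:::new_clause(pr, c(FALSE, FALSE), Inf, TRUE)
    }
    a_free <- solve_weighted_maxsat(cl_free)$assignment
    a_con <- solve_weighted_maxsat(cl_con)$assignment
    expect_true(all(which(a_con) %in% which(a_free)))
    expect_identical(solve_weighted_maxsat(cl_con)$assignment, a_con)
  }
})

test_that("type filtering prunes before solving, with reasons", {
  sig <- default_type_signatures()
  h <- default_type_hierarchy()
  types <- list(D1 = "Disease", O1 = "Organ", DR1 = "Drug")
  cands <- rbind(cand_row("affects", "D1", "O1", 0.8),
                 cand_row("affects", "D1", "DR1", 0.8))
  res <- reason_consistency(cands, sig, types, h)
  expect_identical(nrow(res$accepted), 1L)
  expect_identical(res$accepted$right_entity, "O1")
  expect_identical(nrow(res$type_pruned), 1L)
  expect_match(res$type_pruned$reason, "range")
})
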