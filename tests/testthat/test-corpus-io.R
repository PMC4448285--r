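# Corpus data model: JSONL round-trips, validation, dictionary and DOM.

test_that("parsed corpus round-trips through JSONL identically", {
  s1 <- symptom_sentence()
  s2 <- make_planted_sentence("d2", "s1", "anemia", "sarcoidosis",
                              list(surface = "heralds", lemma = "herald"),
                              modifier = "often", genre = "social",
                              source = "forum")
  s3 <- make_planted_sentence("d3", "s1", "wood dust", "asthma",
                              list(surface = c("risk", "factor"),
                                   lemma = c("risk", "factor")),
                              genre = "encyclopedic", source = "portal")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_parsed_corpus(list(s1, s2, s3), path)
  back <- read_parsed_corpus(path)
  expect_length(back$sentences, 3L)
  for (i in 1:3) {
    orig <- list(s1, s2, s3)[[i]]
    got <- back$sentences[[i]]
    expect_identical(got$doc_id, orig$doc_id)
    expect_identical(got$tokens$surface, orig$tokens$surface)
    expect_identical(got$tokens$lemma, orig$tokens$lemma)
    expect_identical(as.integer(got$edges$gov), as.integer(orig$edges$gov))
    expect_identical(got$edges$label, orig$edges$label)
    expect_identical(got$genre, orig$genre)
  }
  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_parsed_corpus(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed corpus records raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- '{"doc_id":"d","sent_id":"s","genre":"scientific","source":"x","tokens":[{"i":0,"surface":"a","lemma":"a","pos":"NN"}],"edges":[]}'
  bad_edge <- '{"doc_id":"d","sent_id":"s2","genre":"scientific","source":"x","tokens":[{"i":0,"surface":"a","lemma":"a","pos":"NN"},{"i":1,"surface":"b","lemma":"b","pos":"NN"},{"i":2,"surface":"c","lemma":"c","pos":"NN"},{"i":3,"surface":"d","lemma":"d","pos":"NN"}],"edges":[{"gov":9,"dep":0,"label":"dep"}]}'
  writeLines(c(good, bad_edge), path)
  expect_error(read_parsed_corpus(path), "line 2.*missing token")
  writeLines(c(good, "{not json"), path)
  expect_error(read_parsed_corpus(path), "line 2.*malformed")
  writeLines('{"doc_id":"d","sent_id":"s"}', path)
  expect_error(read_parsed_corpus(path), "missing field 'tokens'")
})

test_that("token invariants are enforced", {
  tok <- data.frame(index = c(0, 2), surface = c("a", "b"),
                    lemma = c("a", "b"), pos = "NN")
  expect_error(parsed_sentence("d", "s", tok), "contiguous")
  tok2 <- data.frame(index = 0:1, surface = c("a", "b"),
                     lemma = c("a", ""), pos = "NN")
  expect_error(parsed_sentence("d", "s", tok2), "empty lemma")
  tok3 <- data.frame(index = 0:1, surface = c("a", "b"),
                     lemma = c("a", "b"), pos = "NN")
  expect_error(parsed_sentence("d", "s", tok3,
                               edges = data.frame(gov = 0, dep = 0,
                                                  label = "dep")),
               "self-loop")
})

test_that("generated corpus matches the generator's bookkeeping totals", {
  spec <- corpus_spec(relations = c("treats", "causes", "isSymptom"),
                      seed_pairs_per_relation = c(treats = 5, causes = 5,
                                                  isSymptom = 5),
                      harvest_pairs_per_relation = 2, rng_seed = 11)
  dict <- generate_dictionary(spec)
  seeds <- generate_seed_facts(spec, dict)
  path <- withr::local_tempfile(fileext = ".jsonl")
  gen <- generate_parsed_corpus(spec, dict, seeds, path = path)
  back <- read_parsed_corpus(path)
  expect_length(back$sentences, gen$ledger$counts$n_sentences)
  expect_identical(sum(vapply(back$sentences, function(s) nrow(s$tokens),
                              integer(1))),
                   gen$ledger$counts$n_tokens)
  expect_identical(sum(vapply(back$sentences, function(s) nrow(s$edges),
                              integer(1))),
                   gen$ledger$counts$n_edges)
})

test_that("dictionary reader handles synonyms, empty names, empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("entity_id\tname\tsemantic_type_codes\tis_canonical",
               "E1\tmyocardial infarction\tDisease\t1",
               "E1\theart attack\tDisease\t0",
               "E2\t\tDisease\t1"), path)
  expect_warning(d <- read_dictionary(path), "empty name")
  expect_identical(nrow(d), 2L)
  expect_identical(unique(d$entity_id), "E1")

  writeLines(c("entity_id\tname\tis_canonical", "E1\tx\t1"), path)
  expect_error(read_dictionary(path), "missing column")

  file.create(path2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_warning(d2 <- read_dictionary(path2), "empty")
  expect_identical(nrow(d2), 0L)

  # round trip preserves rows
  dict <- tiny_dictionary()
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(dict, path3)
  back <- read_dictionary(path3)
  expect_identical(nrow(back), nrow(dict))
  expect_identical(back$entity_id, dict$entity_id)
  expect_identical(back$is_canonical, dict$is_canonical)
})

test_that("DOM parsing keeps the heading/list skeleton", {
  tree <- parse_dom_document(
    "<h1>Diclofenac</h1><h2>Side Effects</h2><ul><li>Belching</li></ul>",
    "doc1")
  expect_identical(tree$tag, "other")
  tags <- vapply(tree$children, `[[`, character(1), "tag")
  expect_identical(tags, c("h1", "h2", "li"))
  expect_identical(tree$children[[1]]$text, "Diclofenac")
  expect_identical(tree$children[[3]]$text, "Belching")
})

test_that("a second h1 is demoted with a warning", {
  expect_warning(
    tree <- parse_dom_document("<h1>First</h1><h1>Second</h1><h2>S</h2>", "d"),
    "demoted")
  expect_identical(dom_count_tag(tree, "h1"), 1L)
  expect_identical(tree$children[[1]]$text, "First")
})

test_that("li count survives arbitrary nesting; serialization is idempotent", {
  set.seed(402)
  for (rep in 1:10) {
    n_items <- sample(1:6, 1)
    inner <- paste0("<li>item", seq_len(n_items), "</li>", collapse = "")
    depth <- sample(0:3, 1)
    html <- paste0("<h1>T</h1>",
                   strrep("<div><ul><li>outer<ul>", depth),
                   "<ul>", inner, "</ul>",
                   strrep("</ul></li></ul></div>", depth))
    tree <- parse_dom_document(html, "d")
    n_li_src <- lengths(regmatches(html, gregexpr("<li>", html)))
    expect_identical(dom_count_tag(tree, "li"), as.integer(n_li_src))
    # idempotence: parse(serialize(tree)) == tree
    tree2 <- parse_dom_document(serialize_dom(tree), "d")
    tree$doc_id <- NULL; tree2$doc_id <- NULL
    expect_identical(tree2, tree)
  }
})

test_that("unusable HTML is rejected", {
  expect_error(parse_dom_document("", "d"), "unusable|body")
})
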