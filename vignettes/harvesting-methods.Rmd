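---
title: "Methods: distant-supervision fact harvesting with consistency reasoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distant-supervision fact harvesting with consistency reasoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbharvest)
```

## The problem and the model

`kbharvest` extracts binary relational facts `R(e1, e2)` between dictionary
entities from three kinds of already-parsed text — scientific, encyclopedic
and social — plus the layout structure of HTML pages. The method is distant
supervision: instead of labelled training sentences, it starts from a small
inventory of *seed facts* per relation (a few dozen triples presumed true)
and lets their co-occurrence with textual patterns decide which patterns
express which relation. Extraction noise is then cut back by logical
consistency constraints — type signatures and mutual exclusions — solved as
a weighted Max-Sat problem.

Two assumptions carry the statistics. First, a sentence containing a
pattern together with a seed entity pair is evidence that the pattern
expresses the pair's relation; systematic violations (a pattern that
happens to connect seed pairs for accidental reasons) inflate confidences.
Second, occurrences of the same candidate triple in different sentences are
treated as independent evidence (noisy-or aggregation); correlated
restatements of one source weaken that reading.

## Stage by stage

### Entity recognition

Dictionary names and token windows are compared in character 3-gram space
(`trigram_set()`: lowercased, whitespace-normalized, strings shorter than
the n-gram size padded with `#` on both sides so 1–2 character names still
have a non-empty set). A MinHash/LSH index (`build_match_index()`) retrieves
candidate names quickly; the decision, however, is always made by the exact
trigram Jaccard similarity of the window against the candidate name
(`recognize_mentions()`). The index can therefore miss (LSH is
probabilistic) but never admit a sub-threshold mention: verification is
authoritative. MinHash uses universal hashing
`h_i(x) = (a_i x + b_i) mod (2^31 - 1)` over n-gram keys below `2^24`, so
every product stays below `2^53` and is exact in doubles.

Parameters (all in `match_index_params()`):

| parameter | default | rationale |
|---|---|---|
| `ngram_size` | 3 characters | standard for name matching; robust to inflection |
| `signature_length` | 128 hashes | estimator sd ≈ 0.044 at J = 0.7; tests also exercise 256 |
| `band_count` | 32 bands of 4 rows | candidate recall ≈ 0.9998 at J = 0.7 |
| `threshold` | 0.7 exact Jaccard | admits plural/inflection variants, rejects one-edit lookalikes of short names; configurable because no published value exists |
| `max_window` | 6 tokens | covers long entity names without quadratic window blowup |
| `hash_seed` | 42 | two builds of the same dictionary are bit-identical |

Overlap resolution (`resolve_overlaps()`) applies span subsumption (a
mention strictly inside a longer mention is dropped) and then, among
mentions with an identical span, keeps those whose deepest semantic type is
maximal in the hierarchy — "most specifically typed" — with ties keeping
all. There is no further entity disambiguation by design.

### Pattern gathering

For each pair of disjoint mentions, `shortest_dependency_path()` runs
breadth-first search on the *undirected* dependency graph between the
mention heads (the head is the span token governed from outside the span;
ties take the leftmost). Direction is ignored because informative paths
routinely cross edges against their orientation (a copular "X is a symptom
of Y" walks from the subject up into the predicate nominal and down into
the prepositional object). When several shortest paths exist, the
lexicographically smallest token-index sequence is returned, making output
deterministic. `expand_with_modifiers()` closes the path set under `neg`,
`amod` and `advmod` dependents — closure rather than one level, so the
operation is idempotent and chains like "not very common" are captured
whole. `render_pattern()` emits lemmas in surface order with all
mention-internal tokens removed; an empty rendering discards the pair, and
pairs in disconnected parse components are counted in the diagnostics
rather than fabricated.

Document-structure patterns (`extract_dom_patterns()`) require the page
`<h1>` to resolve to exactly one dictionary entity and a `<li>` text to
resolve to an entity; the pattern is the stack of open `<h2>`–`<h6>`
headings at the list item's position in document order (a later heading of
the same or higher level closes the previous one). The reduced DOM model
keeps only headings and list items; anonymous containers are flattened,
which is what makes `parse_dom_document()` and `serialize_dom()` mutually
idempotent. Extra `<h1>` tags are demoted with a warning; heading text is
treated as opaque pattern text.

### Pattern analysis

`mine_frequent_subsequences()` enumerates all order-preserving (not
necessarily contiguous) token subsequences of gathered patterns and keeps
those supported by at least `min_support` occurrences (default 2 — the
smallest value at which "frequent" means anything; there is no published
value). Support counting is by subsequence containment against *every*
occurrence, including those too long for enumeration (cap 12 tokens).
Generalization is realized purely by these subsequences; no wildcard or
part-of-speech masking variant is attempted because its construction is
not specified anywhere usable.

`compute_confidence()` implements the ratio

$$\mathrm{confidence}(q, R) = \frac{|\{s : q \text{ and some } (e_1,e_2) \in SX(R) \text{ occur in } s\}|}{|\{s : q \text{ and some } (e_1,e_2) \in SX(R) \cup CX(R) \text{ occur in } s\}|}$$

with "q occurs in s" meaning q is a subsequence of a pattern gathered in s
(that containment is what lets mined generalizations match their own
sources), counting distinct sentences, and a zero denominator leaving the
confidence undefined rather than zero. When every seed pair belongs to one
relation, denominators are shared across relations and confidences sum
to 1 per pattern — a property the tests assert. Selection keeps
`confidence > 0.3`, strictly greater, per the stated threshold semantics.

`score_pattern()` weights an occurrence by
`max_q Jaccard(tokens(p), tokens(q)) × confidence(q)` over token *sets*
(multiplicity is undefined for patterns, so duplicates collapse), breaking
ties by higher confidence then lexicographic relation id.
`build_fact_candidates()` merges occurrences of one triple by noisy-or,
`w = 1 - \prod_i (1 - w_i)`: bounded in (0, 1], monotone in added evidence,
and readable as "at least one occurrence is a true statement" under
independence. DOM patterns are scored with their heading token sequence as
the pattern.

### Consistency reasoning

Type checking (`check_type_signature()`) is a pre-filter, not a clause
family: a candidate whose left entity holds no domain type and no
descendant of one (similarly right/range) is pruned before solving, which
shrinks the NP-hard instance. The built-in signature table covers the
thirteen relations; both signatures and exclusions are plain config files,
because only one exclusion is documented (`sideEffect(x, y)` excludes
`treats(y, x)`) and real deployments will extend the list.

`ground_clauses()` emits one soft unit clause per surviving candidate
(weight = candidate weight), one hard binary clause `(¬f ∨ ¬g)` per
instantiated exclusion, and one hard positive unit per seed fact that is
itself among the candidates (seeds are never injected as free facts).
`solve_weighted_maxsat()` runs three phases:

1. **Hard unit propagation** to a fixed point: a hard clause reduced to one
   open literal forces it; contradictions raise an infeasibility error.
   This is what lets a seed-pinned fact immediately falsify its exclusion
   partner before any greedy choice is made.
2. **Dominating unit clauses**: a literal whose unit-clause weight (hard
   counted as infinite) strictly exceeds the total weight of clauses
   containing its negation is fixed; repeat to fixpoint. On conflict-free
   instances this alone solves exactly.
3. **Johnson's greedy heuristic** over the remaining variables in
   deterministic order (descending incident soft weight, then id): each
   variable takes the sign maximizing the expected satisfied soft weight
   under uniform random completion (an unsatisfied clause with `u` open
   literals contributes `w(1 - 2^{-u})`). Hard clauses act as infinite
   weight through a feasibility rule — a sign that would falsify a hard
   clause outright is never chosen. The naive alternative (a huge finite
   weight inside the expectation) is rejected deliberately: for a hard
   exclusion `(¬f ∨ ¬g)` it awards `w_hard/2` against `w_hard` and
   therefore rejects *both* facts regardless of their soft weights, the
   wrong outcome for weight dominance.

The test suite checks the heuristic against an exhaustive 2^n oracle on 200
random instances (≤ 12 hypotheses): satisfied soft weight at least half the
optimum (Johnson's classic bound), exact optimum whenever the instance is
conflict-free soft-unit-only, and zero hard-clause violations; removing
exclusions never shrinks the accepted set.

### KB assembly and evaluation

`assemble_kb()` emits one fact per accepted triple with the union of its
supporting occurrences as provenance; fact count and occurrence count are
reported separately since one fact can be stated in many places. Exports
are byte-deterministic (fixed 6-decimal weights, sorted rows, fixed IRI
scheme `urn:kbharvest:entity/<percent-encoded id>`).

`wilson_interval()` is the standard two-sided Wilson score interval
(`z = qnorm(1 - alpha/2)`); note that at `k = n` its upper bound is exactly
1 — only the lower bound stays below 1. `sample_until_width()` consumes
judgments until the width drops below the target (default 5% at alpha 5%);
an exhausted finite stream is a census and reports width 0 by convention.
`fleiss_kappa()` errors when chance agreement is degenerate (all ratings in
one category) rather than returning 0/0.

## What the synthetic generator emulates — and what it does not

`corpus_spec()` fixes the study conditions once: the thirteen relations
with their built-in seed inventory sizes (467 seed pairs in total), one
planted connective phrase per relation, three seed-co-occurrence sentences
and four harvest pairs per relation, no distractor noise, and optional
knobs (noise rate, surface-edit rate, near-miss dictionary names, two-token
names, type-violation sentences) that default to the clean condition.
Design choices worth stating:

- **Phrases are token-disjoint across relations**, so a planted occurrence
  can only match seed patterns of its own relation and the expected
  confidences are exact by construction. Real corpora share function words
  across relations; the worked `occur` example (2/3 vs 1/3) covers the
  ambiguous case at micro scale instead.
- **Names are random pronounceable strings kept mutually below 0.55
  trigram Jaccard**, so no two synthetic entities collide at the 0.7
  threshold. Near-miss names (one-character edits) are planted *below* the
  threshold deliberately: they exercise rejection, not confusion.
- **The dependency skeleton is a right-branching chain** through the phrase
  tokens, the simplest graph whose shortest path is exactly the planted
  phrase; per-relation adverbs attached by `advmod` (rate 0.25) exercise
  the modifier expansion without entangling relations.
- **DOM documents are generated only for drug-domain relations** (title =
  left argument = drug). Pages whose title would be the *right* argument —
  a drug page listing side effects — would be extracted with swapped
  arguments and correctly pruned by type checking; the generator does not
  plant facts the method is known to reverse. That swapped-argument blind
  spot is a genuine limitation of title-as-left-entity extraction, not of
  the generator.

Passing against this generator therefore shows that the machinery —
matching, path extraction, counting, solving, bookkeeping — is correct
under the model's own assumptions. It does not show robustness to real
clinical or forum language: lexical ambiguity, abbreviations, coreference,
negation scope beyond `neg` edges, parser errors and correlated
restatements are all absent from the fixtures by construction.

## Degenerate inputs and numerical conventions

Empty dictionaries warn and match nothing; empty corpora produce an empty
KB with a warning, not an error. Disconnected parses yield "no path" and a
diagnostics count. Undefined confidences (zero denominator) exclude a
pattern from candidacy instead of defaulting to zero. Zero-weight
occurrences yield no candidate. Unknown type codes count as depth 0 with a
warning. All orderings (candidate tables, variable order in the solver,
exports) are explicit, so identical inputs give byte-identical outputs.
Problem sizes in the tests — a ~100-sentence default corpus, 200-instance
oracle suites, 12-hypothesis exhaustive enumeration — were chosen as the
smallest sizes at which every claimed property is actually exercised.

## Ablations

The pipeline exposes the three ablation switches as configuration:
`no_dom` (drop document-structure patterns), `no_pattern_stats` (every
mined pattern that co-occurs with a relation's seeds becomes a seed pattern
at confidence 1 — the closest explicit reading of "keep all patterns"), and
`no_reasoning` (accept every candidate, skipping type checking and
Max-Sat). With type-violating distractors planted, the acceptance suite
verifies the qualitative direction: reasoning on, precision 1.0; reasoning
off, precision strictly lower.
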