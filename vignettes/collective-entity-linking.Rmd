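---
title: "Collective entity linking with relation-informed Personalized PageRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective entity linking with relation-informed Personalized PageRank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(relink)
library(dplyr)
```

## The problem

Biomedical named-entity linking (normalization) maps a textual mention — a
chemical or disease surface form recognised in an abstract — to the concept it
denotes in a curated vocabulary such as ChEBI or the CTD MEDIC/Chemicals
vocabularies. Lexical matching alone is often ambiguous: several concepts sit
within one or two edit operations of a mention, and the string-closest one is
frequently wrong. Collective (global) disambiguation resolves all mentions of
a document together, preferring the combination of candidates that forms a
coherent set.

`relink` implements that idea with a per-document *disambiguation graph* whose
nodes are mention/candidate pairs and whose edges carry evidence that two
candidates belong together. The distinguishing feature is where the edges come
from: besides the ontology's own is-a structure (`link_mode = "kb"`), edges
can be drawn from *relations extracted from the text itself* — gold
chemical-disease interaction annotations, or the output of any relation
extraction tool (`"corpus"`), or the union of both (`"kb_corpus"`). Ontology
structure is sparse exactly where documents are most informative: two concepts
interacting in a sentence are rarely ontology neighbours. Text-derived
relations fill in those missing edges.

## The model, step by step

**Candidate generation.** For a mention $e$ the candidate list $CL(e)$ is built
by string search over every concept name and synonym. Similarity between
folded strings $a, b$ is the normalised Levenshtein ratio
$1 - d(a,b)/\max(|a|,|b|)$. A mention identical (after case folding and
whitespace collapsing) to a knowledge-base name short-circuits: it is linked
immediately and enters the graph as a single *fixed* node — an anchor. All
other mentions receive the 10 best-scoring distinct concepts (configurable
`k`), plus entries for the remaining names and synonyms of those concepts.
Candidates whose identifier is missing or obsolete are discarded. There is no
similarity floor by default; an optional floor exists for noisy vocabularies.

**Graph construction.** One node per (mention, distinct candidate concept).
Edges never join two candidates of the same mention — only one of them can be
right, so such edges would be pure noise. Across mentions, `"kb"` adds an edge
when the concepts are ontology-adjacent (undirected shortest path of length
1), `"corpus"` when the unordered concept pair occurs in the pooled relation
set, `"kb_corpus"` when either holds. Relations are pooled corpus-wide by
default: an interaction stated in one abstract may legitimately support the
same concept pair elsewhere. Gold chemical-disease pairs can additionally be
expanded by the shared-entity rule (two diseases related to one chemical
become related, and vice versa) with `expand_shared_entity_relations()`.

**Scoring.** Relevance of node $n$ to a source node $s$ is the truncated
Personalized PageRank $PPR(s \to n)$: the probability that a walk of exactly
$T$ steps from $s$ — teleporting back to $s$ with probability $\epsilon$ at
each step, otherwise moving to a uniformly random neighbour — ends at $n$.
The node score is IC-weighted coherence,

$$\mathrm{Coherence}(n) \;=\; IC(c_n)\sum_{s\,:\,\mathrm{mention}(s)\neq\mathrm{mention}(n)} PPR(s\to n),$$

where competing candidates of $n$'s own mention (including $n$ itself) are
excluded from the sum. Fixed exact-match nodes do act as sources — that is
precisely how an unambiguous mention anchors its neighbours. Each mention is
resolved to its maximal-coherence candidate; the information content term
favours specific concepts over frequent, generic ones.

**Information content.** IC is extrinsic (corpus-frequency based) with
Resnik-style cumulative counts and add-one smoothing:
$n(c)$ = own frequency + frequencies of all is-a descendants, and
$IC(c) = -\ln\,\big((n(c)+1)/(N+|C|)\big)$. The smoothing keeps every value
finite and strictly positive and the cumulative counts make IC monotone along
is-a edges. Frequencies come from a two-column TSV
(`read_ic_frequencies()`); without one, `uniform_ic()` (IC $\equiv$ 1) gives
plain unweighted coherence. We chose the constant-one table, not all-ones
*counts*, as the degenerate default: cumulative all-ones counts are not
constant over a DAG, and the point of the fallback is exactly that weighting
disappears.

**The four models.** `string_matching` (top lexical candidate, no graph),
`ppr_ic` (coherence over `"kb"` edges), `reel_corpus` (over `"corpus"`
edges), `reel_kb_corpus` (over the union). All three graph models use the
same scoring; only the edge source differs, so comparisons between them
isolate the value of text-derived relations.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 10 | distinct concepts admitted per mention by the primary ranking |
| `min_score` | 0 | optional lexical-similarity floor (off) |
| `n_steps` | 5 | walk length $T$ of the truncated PPR |
| `teleport` | 0.2 | restart probability $\epsilon$ |
| `n_walks` | 2000 | walks per source for the Monte-Carlo engine |
| `engine` | `"exact"` | PPR computation: power iteration or end-point sampling |

The walk parameters (2000 walks, 5 steps, teleport 0.2) are the standard
values for this family of graph-based linkers and we keep them as defaults.

## Numerical choices

*Estimand.* "A number of random walks of fixed length" admits two readings:
end-point frequency or visit counts. We define the target quantity as the
$T$-step end-point distribution $p_T$ with
$p_{t+1} = \epsilon e_s + (1-\epsilon) p_t W$, and the sampler as unbiased
end-point sampling of exactly that chain. Sampler and oracle then estimate the
same quantity, which makes the Monte-Carlo engine *testable*: the suite
checks total-variation agreement on random graphs and an exactly
hand-iterated two-node value ($PPR(s\to n) = 0.59008$ at $\epsilon = 0.2$,
$T = 5$).

*Default engine.* Per-document graphs have tens of nodes, so the exact
power iteration is both faster and deterministic; it is the default, while
the sampler remains available (`engine = "monte_carlo"`) and is validated
against the exact engine. The sampler restores the R RNG state after use and
derives one sub-seed per document, so corpora of any size are reproducible
from a single seed.

*Dangling nodes* teleport to the source with probability 1, keeping the chain
stochastic and the personalization semantics intact: an isolated source keeps
all of its mass.

*Ties and degeneracy.* Candidate ordering breaks score ties by shorter
matched name, then concept id; coherence ties break by lexical score, then
concept id. When every candidate of a mention scores zero — an edgeless or
disconnected graph — the decision falls back to lexical order, which makes
the graph models degrade exactly to the string-matching baseline rather than
behave arbitrarily. Mentions with an empty candidate list stay unlinked (NIL)
and count as false negatives.

*Identifier hygiene.* Offsets are 0-based half-open over
`title + " " + abstract` and are validated against the annotated surface on
read — silent offset drift is the classic corpus-format bug. Bare MeSH
identifiers are normalised to `MESH:` CURIEs on read; alternative OBO ids
resolve to their canonical concept at a single point (`resolve_concept()`).
Composite annotations (one span, two gold ids) become two mentions sharing
offsets; at evaluation each gold id is its own unit, so at most one of the
two can be credited — the conservative reading.

## Evaluation

Micro-averaged precision, recall and F1 on a 0-100 scale, pooled over
documents. Within a document, repeated instances of the same case-folded
surface form collapse to one evaluation unit (scored by the first instance);
a correct link is a true positive, a wrong link a false positive, an
unlinked unit a false negative, so `tp + fp + fn` always equals the number
of unique units.

## What the synthetic generator emulates — and what it does not

`make_ontology()` + `make_corpus()` generate the full input regime without
downloads: a branching is-a tree with synonyms (the vocabulary), documents
whose mentions are lexically ambiguous, and a relation set covering
same-document gold pairs with probability `relation_coverage`. Ambiguity is
constructed, not accidental: every gold (leaf) concept receives `ambiguity`
decoy concepts whose names are single-character *deletions* of the gold name,
attached nowhere in the tree. Half of the mention surfaces (in expectation)
are verbatim gold names — exact-match anchors — and the rest substitute one
character at a position where a decoy dropped one. The perturbed surface then
ties the gold concept on normalised similarity, and the shorter decoy name
wins the deterministic tie-break: pure string matching errs on essentially
every perturbed mention, while the decoys' isolation means any coherence
signal at all identifies the gold concept. This isolates precisely the
mechanism under test — relations rescuing mentions the lexical ranker gets
wrong. Perturbations are rejected if they collide with any knowledge-base
name, so the exact-match short-circuit never fires on a decoy.

Defaults (`n_concepts = 5000`, `branching = 3`, `n_synonyms = 2`) keep the
vocabulary large relative to the candidate depth, as real vocabularies are
(tens of thousands of names against a top-10 cut): with a small toy ontology,
arbitrary concepts enter the top-10 lists and ontology-adjacent strays can
collect spurious coherence, which is an artefact of scale, not of the method.

What the generator does *not* model: natural language context (abstracts are
concatenated surface forms), relation-extraction errors beyond the coverage
parameter (no false-positive relations), abbreviations, nested or
discontinuous mentions, and the heavy-tailed name-length and frequency
distributions of real vocabularies. Passing the synthetic benchmark therefore
shows that the machinery — candidate ranking, graph assembly, PPR coherence,
fallback logic — behaves as designed; it does not certify performance on any
particular real corpus.

## Worked example

The package ships a compact fixture reproducing the canonical rescue
scenario: one exact-match anchor and two ambiguous chemical mentions whose
correct concepts are related to the anchor in text but not adjacent in the
ontology.

```{r}
fx <- make_anchor_fixture()
cands <- generate_candidate_table(fx$document, fx$kb, k = fx$k)

glance(build_graph(cands, fx$kb, fx$relations, "kb"))     # 0 edges
glance(build_graph(cands, fx$kb, fx$relations, "corpus")) # 2 edges

runs <- bind_rows(lapply(
  c("string_matching", "ppr_ic", "reel_corpus"),
  function(m) run_model(fx$document, fx$kb, fx$relations, model = m,
                        k = fx$k, candidates = cands)
))
runs |> select(model, surface, gold_id, predicted_id)
evaluate_linking(runs, fx$document)
```

String matching (and `ppr_ic`, whose ontology graph here has no edges and
falls back to lexical order) picks the decoys; `reel_corpus` recovers both
correct concepts through the anchored relations.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline on a
100-document, 4-mentions-per-document corpus over the default 5000-concept
ontology (about 11,700 concepts with decoys; roughly 35,000 searchable
names), verify the Monte-Carlo sampler against the exact engine on ten random
graphs of up to 12 nodes at 50,000 walks per source, and exercise the metric
layer on 200 randomized prediction sets against a brute-force counter. These
sizes were chosen to give clear statistical margins (binomial error well
below the asserted tolerances) while completing in a few minutes on one core.

## Known limitations

- Only `is_a` ontology relations are used for KB-link edges; ChEBI
  cross-products (e.g. `has_role`) would densify the graph and are ignored.
- PubTator is the only corpus dialect; Knowtator-XML and BioC are out of
  scope.
- Relation matching is by concept-id pair, so a relation can only help after
  the correct concepts appear somewhere in the candidate lists — candidate
  recall bounds everything downstream.
- Whether the original family of systems scored synonyms during the top-10
  search or expanded them afterwards is not documented; we score against all
  names and synonyms (the more recall-friendly reading) and note that the
  alternative would only shrink candidate lists.
- Shared-entity expansion defaults to corpus-wide pooling; a per-document
  variant is a one-line filter on the relation set before graph building.
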