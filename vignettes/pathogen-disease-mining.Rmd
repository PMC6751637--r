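---
title: "Mining pathogen–disease associations with ontology-propagated NPMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining pathogen–disease associations with ontology-propagated NPMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padminer)
```

## The problem and the model

Pathogen–disease relations ("*Borrelia burgdorferi* causes Lyme
disease") are mostly reported in free text. `padminer` extracts them in
three steps: dictionary-based recognition of ontology classes in
sentences, co-occurrence counting with subsumption propagation, and a
class-level collocation score with fixed acceptance thresholds.

The unit of evidence is the sentence. A sentence supports a
(pathogen class, disease class) pair when it contains a surface form
from each class's *term set*

$$Terms(C) = \{\, x \mid x \in Labels(S),\; S \sqsubseteq C \,\},$$

the labels and synonyms of the class and all its subclasses. In the
implementation this string-level definition is realized by *count
aggregation*: a mention of a subclass increments the counts of every
ancestor-or-self class. The two are equivalent by the definition of
$Terms(C)$, and aggregation costs $O(\text{mentions} \times
\text{depth})$ rather than $O(|Terms|)$.

With $n_{tot}$ the number of sentences containing at least one pathogen
and one disease mention, $n_C$ and $n_D$ the marginal sentence counts of
the two classes, and $n_{C,D}$ their joint count, each pair is scored
with normalized pointwise mutual information lifted to classes:

$$npmi(C,D) = \frac{\log \frac{n_{C,D}\, n_{tot}}{n_C\, n_D}}
                   {-\log \frac{n_{C,D}}{n_{tot}}} \in [-1, 1].$$

The logarithm base cancels. A pair is accepted when $npmi > 0.2$
(strict) and $n_{C,D} \ge 10$ (inclusive). An accepted pair is *direct*
if at least one evidence sentence mentions both classes' own labels;
otherwise it is *indirect*, i.e. inferred purely through the ontology.

### Assumptions

* Sentence-level co-occurrence is a (noisy) proxy for an asserted
  relation; the NPMI and count thresholds remove most coincidental
  co-mentions but encode no linguistic analysis of the relation itself.
* Subsumption (`is_a`) is the only relation with counting semantics;
  `part_of` and other relationships are ignored.
* The two ontologies occupy disjoint identifier spaces (colliding CURIE
  prefixes are rejected at counting time).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `npmi_threshold` | 0.2 | minimum collocation score, strict `>` |
| `count_threshold` | 10 | minimum joint sentence count, inclusive `>=` |
| `min_length` | 3 characters | shortest dictionary term kept |
| stoplist | packaged list | common/geographic words excluded from dictionaries |
| keywords | disease, disorder, syndrome, defect, infection, fever | long-form words that validate a disease abbreviation |
| `cap_roots` | branch roots | classes at which upward propagation stops |
| `whole_corpus_marginals` | off | count $n_C, n_D$ over all sentences instead of the co-occurrence space |

Two of these deserve comment.

**Event space.** $n_{tot}$ is defined over sentences with at least one
mention from each category. We count $n_C$ and $n_D$ in that same
restricted space, so every ratio in the NPMI formula is a valid
probability and the score stays inside $[-1,1]$ by construction. The
alternative — whole-corpus marginals — can push the score outside the
normalized range and is available behind a flag for comparison only.

**Propagation cap.** The pipeline stops propagation *below* the
configured branch roots. Associations at the level of "pathogen as
such" or "disease as such" are vacuous: the root's marginal equals
$n_{tot}$, so its pairs carry no information (the root–root pair
degenerates to the $n_{C,D}=n_{tot}$ limit of $+1$). The cap is
configurable, and `count_cooccurrences()` itself applies none.

## Tagging and the abbreviation filter

Dictionary keys are normalized (trimmed, whitespace-collapsed,
lowercased) **except** all-uppercase forms of five characters or fewer,
which are stored and matched case-sensitively: short all-caps strings
are nearly always abbreviations, and case-folding "ALS" onto the German
article "als" would manufacture false positives. Matching is
longest-match-wins with ties to the leftmost, and both match edges must
fall on alphanumeric/non-alphanumeric transitions ("rat" never fires
inside "strategy"). These conventions are fixed here because upstream
annotation services leave them implicit.

Disease abbreviations are additionally screened per document.
Parenthetical definitions "LONG FORM (SF)" are detected with
Schwartz–Hearst-style right-to-left letter alignment (short form 2–10
characters, at least half upper-case/digits, long-form window capped at
$\min(|SF|+5,\, 2|SF|)$ words). A disease mention that looks like an
abbreviation survives only if a dictionary long form for one of its
classes occurs elsewhere in the document, or a detected long form
contains a disease keyword. The filter never touches pathogen mentions.

The sentence splitter is rule-based: a break requires terminal
punctuation, following whitespace, and an upper-case/digit sentence
opener, with an exception list for scholarly abbreviations ("et al.",
"Fig.", "sp."). Single capital initials need no exception — "E. coli"
is protected because "coli" opens lower-case. The exception list is a
configurable argument, not a constant.

## The synthetic fixture generator

`synthetic_spec()` describes a complete miniature study and is the
package's test bed: two random `is_a` trees (20 pathogen and 15 disease
classes, depth ≤ 3) with unique pronounceable labels and 0–2 synonyms
per class, and a corpus (default 2000 sentences, 10 per document) drawn
sentence by sentence:

* with probability equal to its joint probability, a planted pair emits
  a carrier sentence ("X was isolated from patients with Y.") using a
  surface form of each class — through a proper subclass for
  `subclass_only` pairs, or with probability 0.5 per side for `mixed`
  pairs;
* otherwise the sentence independently mentions a uniformly random
  pathogen and/or disease with probability 0.1 each (background), or is
  pure filler.

The default planting — three pairs at joint probabilities 0.10, 0.07
and 0.05, the last reachable only through subclasses — gives expected
joint counts of 200/140/100 sentences against background pair counts
of order $2000 \times 0.01 / (19 \times 14) \approx 0.08$, i.e. a
planted-to-decoy margin of three orders of magnitude. These are the
study conditions for all recovery and rejection tests. The planted
pairs are placed on *disjoint subtrees*: if one planted class subsumed
another pair's class, the two signals would absorb each other's
marginal counts and the ground truth would be ill-posed.

Ground truth is recorded from the realized emissions, not the
configuration: the expected pair set is the ancestor closure of the
class combinations actually co-emitted (a subclass emission is a
genuine association at the subclass level too), and a pair's expected
direct flag is true iff some emitted sentence mentions both classes
themselves — a chance background co-mention can legitimately turn a
subclass-only planting direct.

What the generator does *not* emulate: linguistic variation (fixed
carrier frames), negation and speculation, nested or discontinuous
entities, cross-sentence coreference, and the heavy-tailed term
ambiguity of a real taxonomy. Passing tests therefore demonstrate the
statistical and structural correctness of the machinery, not
real-corpus precision/recall, which depend on dictionary quality and
corpus scale.

## Numerical and degenerate-case choices

* $n_{C,D}=0 \mapsto -1$ and $n_{C,D}=n_{tot} \mapsto +1$, the
  continuous limits of the formula, rather than errors; $n_{tot}=0$
  (an empty counting space) is an error.
* Counts are coerced to double before forming products ($n_{C,D} \cdot
  n_{tot}$ overflows 32-bit integers at corpus scale).
* Within one sentence a class counts once, however many of its terms
  occur (set semantics); the co-occurrence literature is split on this
  and the choice keeps $n_{C,D} \le \min(n_C, n_D) \le n_{tot}$ exact.
* Output ordering is NPMI descending, then pathogen id, then disease id
  — repeated runs are byte-identical.
* Overlapping matches resolve longest-first, ties leftmost; a form in
  both dictionaries yields one mention per category and no arbitration.
* Dangling `is_a` targets are dropped with a warning (real OBO exports
  contain them); cycles are a hard error naming one cycle.

## Verification

The test suite checks every component against an independent oracle:
closures against brute-force edge expansion on random DAGs, the tagger
against a quadratic all-substring matcher, propagated counts against
triple enumeration over 50 seeded corpora of 400 sentences, the NPMI
against its closed form (counts 20/50/40/1000 give
$\ln 10 / \ln 50$) and range/monotonicity over $10^4$ randomized count
tuples, and the full pipeline against planted ground truth across 10
seeds of 2000 sentences — sizes chosen so the whole suite runs on a
laptop in a few minutes. `scripts/acceptance.R` recomputes the headline
quantities from scratch on fresh fixtures.

## Known limitations

* Dictionary matching cannot resolve genuinely ambiguous surface forms
  (shared synonyms map to all owning classes; class-level counting
  dilutes, but does not remove, the ambiguity).
* The abbreviation filter covers diseases only; ambiguous pathogen
  names ("Katanga") are handled solely by the stoplist.
* Evaluation matches pairs at the exact class level — no credit for
  ancestor/descendant near-misses — which is stricter than crediting
  subsumption-compatible matches.
* Reference lists must already use the extraction's CURIE spaces;
  mapping from external databases is out of scope.
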