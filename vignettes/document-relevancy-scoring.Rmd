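---
title: "Rules-based document relevancy scoring for biocuration triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rules-based document relevancy scoring for biocuration triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litriage)
```

## The problem

Curated interaction databases extract chemical–gene, chemical–disease and
gene–disease interactions from the literature by expert reading. For a
well-studied chemical, a PubMed triage query returns far more candidate
articles than curators can review, and the default ordering — descending
PMID, roughly recency — carries no information about whether an article
contains curatable interactions. `litriage` implements a rules-based
*document relevancy score* (DRS): an integer computed from dictionary
recognition of chemicals, genes, diseases and molecular action terms in an
article's title and abstract. Ranking a triage corpus by descending DRS
concentrates curatable articles, and their novel interactions, at the top
of the review list.

## The scoring model

Recognition is purely dictionary-based. Candidate spans — token-boundary
anchored, longest-match, scanned left to right once per vocabulary
category — are normalized and looked up against controlled vocabularies;
spans that fail to resolve to a vocabulary accession are discarded. This
trades recall for precision and determinism: there is no statistical NER
and no randomness anywhere in recognition or scoring.

Thirteen additive rules turn the validated mentions of one document into
its DRS. With default weights:

| rule | points |
|---|---|
| abstract alludes to full-text content (trigger lexicon) | 50, flat |
| target chemical in title | 10 per occurrence |
| action term co-occurring with two entity categories in one sentence | 8 per sentence-pair |
| target chemical on the MeSH chemical list | 5, flat |
| target chemical in first abstract sentence | 5 per occurrence |
| action term in abstract, gene and chemical both present | 4 per occurrence |
| target chemical in second / second-to-last / last sentence | 3 per occurrence each |
| entity (chemical, gene, disease) in abstract, gene and chemical both present | 2 per occurrence |
| action term in abstract otherwise | 1 per occurrence |
| entity in abstract otherwise | 1 per occurrence |
| priority journal | 1, flat |

Key modelling choices, made where the rule statement alone does not fix
the arithmetic:

* **Independence and stacking.** Every rule is evaluated independently
  and the contributions summed. A target-chemical mention in the first
  sentence also counts toward the entity-occurrence rule; in a
  one-sentence abstract that sentence is simultaneously first and last,
  so a target mention there earns 5 + 3. There are no exclusion clauses;
  independence keeps the scorer compositional and each rule separately
  testable.
* **Field scope.** The occurrence and action rules read "appears in
  abstract", so title and chemical-list mentions never feed them; the
  title has no sentence index.
* **Flat versus per-occurrence.** Rules without a per-occurrence reading
  (full-text boost, chemical list, priority journal) fire at most once.
* **The gene-and-chemical switch.** Whether the abstract contains at
  least one gene and at least one chemical mention is evaluated once per
  document, on abstract mentions only, and selects the 4/2-point or
  1/1-point variants of the action and entity rules.
* **No base score.** Documents with no recognizable feature score 0.

All point values, the priority-journal list and the trigger lexicon live
in a `rule_config` object (serializable as JSON), so the algorithm can be
re-weighted without code change; re-optimizing the weights is out of
scope.

## Normalization choices

* **Gene symbols** are case-folded; whole-word Greek letter names map to
  single-letter romanizations (alpha→a … omega→w, with eta→h, theta→q,
  chi→c, psi→y as the conventional single letters); hyphens and internal
  spaces are removed. "TNF-alpha", "TNF alpha" and "tnfa" share one key.
  These rules are this package's own declared normalization.
* **Action terms** are lower-cased and Porter-stemmed to a fixed point,
  word by word, so "binds"/"binding" and
  "phosphorylates"/"phosphorylation" conflate. Iterating the stemmer to a
  fixed point makes the mapping idempotent by construction without
  affecting which inflections share a stem.
* **Chemicals and diseases** are case-folded with whitespace collapsed.
* **Short surfaces** (two characters or fewer after normalization, e.g.
  "Pb") additionally require an exact-case match, suppressing false hits
  on stopword-like symbols.
* **Collisions.** If two accessions of one category claim the same
  normalized surface, the lexicographically smallest accession wins and a
  warning is emitted — deterministic across runs and platforms.
* **Sentences** split at `.`, `!`, `?` followed by whitespace and an
  uppercase letter or digit, with a fixed abbreviation guard list (i.e.,
  e.g., et al., vs., cf., Fig(s)., ca., approx., No., St., Dr., sp(p).).
* **Structured abstracts**: labeled `AbstractText` sections are
  concatenated in document order with a single space — the order they are
  displayed in, which is our choice since upstream behavior is not
  prescribed.
* **Journal names** are compared case-insensitively after collapsing
  punctuation/whitespace and dropping a leading "The", since MEDLINE
  journal strings vary in exactly these respects.

## Ranking, bins and evaluation

Corpora are ranked by descending DRS with ties broken by descending PMID
(the tie-break is our declaration; it lets equal-DRS articles fall back to
the recency baseline and keeps runs deterministic), or by descending PMID
alone as the baseline. Scores are binned high (≥ 100), medium (21–99) and
low (≤ 20); DRS 0 is assigned to the low bin, a harmless extension since
any matched feature scores at least 1. Progressive quantile groups cut a
ranking into k contiguous groups whose sizes differ by at most one,
larger groups first, so 3,583 documents yield quartiles of 896, 896, 896
and 895.

Evaluation follows standard information-retrieval practice: average
precision per target chemical against curated/rejected labels, mean
average precision (MAP) as the unweighted mean over chemicals, and
macro-averaged recall of curated actors (distinct accessions found by any
synonym, divided by distinct curated accessions, averaged unweighted over
groups). Both reference-level and target-chemical-level groupings are
supported; the target-chemical grouping is the default headline number.
Precision of mined actors is deliberately not computed: curated actors
may live only in the full text, and cited-but-uncurated actors are
unknown, so no fair denominator exists. Per-bin curation tables report
counts, minutes, curation/rejection rates (minutes per curated/rejected
article; absent rather than zero over empty bins) and interactions;
percentages are rounded half-up, with one decimal below 1%. The
interaction yield rate is interactions (novel plus repeated) per minute.

## The synthetic-data generator

Real triage corpora and their curation labels cannot be redistributed, so
the package ships a seeded generator. Each document draws a latent
relevance and with it a number of planted features: target-chemical title
mentions, positional target sentences, co-occurrence sentences
(chemical + action term + gene, sometimes + disease), full-text trigger
phrases, a MeSH chemical-list entry, occasionally a priority journal.
Curation status is Bernoulli with probability `plogis(-2.2 + 0.55 × f)`
in the planted-feature count `f` — chosen once so that low-bin documents
curate at roughly 10–15% and high-bin documents at roughly 85%, the
curatability structure reported for heavy-metal triage corpora. Curated
documents receive `1 + Poisson(0.6 × f)` interactions, so interaction
density rises with the score; review times are truncated normals with
means 16.5 minutes (curated) and 1.6 minutes (rejected), the published
mean curation and rejection rates, with rejection time inflated 10% per
planted feature to mimic the observed slower rejection of dense
abstracts. A configurable fraction (default 15%) of interaction actors is
drawn from vocabulary entries absent from the abstract, emulating
full-text-only curation and capping attainable recall. PMIDs are a
uniform shuffle, independent of relevance, so the recency baseline is
uninformative by construction.

What the generator does **not** emulate: real linguistic variety,
abbreviations and acronym coinage, species ambiguity, gene complexes,
chemical classes, negation, or review articles — exactly the phenomena
reported to defeat rules-based scoring in practice. Passing tests on
synthetic corpora therefore demonstrate the internal consistency of the
pipeline and the direction of its effects, not field performance on real
abstracts.

## Test design and problem sizes

The suite checks every rule against hand-computed worked examples, and
checks the composed scorer against an independent naive scorer (plain
arithmetic over a known document recipe, sharing no code with the
pipeline) on 1,000 random documents. Average precision is verified
against an exhaustive oracle over all permutations of lists of up to six
items; the recognizer against a brute-force scan that enumerates every
token-boundary substring. The simulation-recovery checks use seven
target-chemical corpora of 300 documents each (2,100 documents pooled) —
sizes chosen to hold Monte-Carlo error well below the tested margins
(all monotonicity and MAP-gain assertions require > 3 standard errors)
while keeping the suite quick. The published per-bin curation table is
reproduced arithmetically by feeding `bin_metrics()` per-document logs
whose per-bin totals equal the printed inputs; standard deviations are
computed but not asserted, since only totals and means are published.

## Known limitations

* The trigger lexicon behind the 50-point full-text boost is a
  documented, configurable default; the original in-house lexicon is not
  public, and the boost dominates the score (half a bin width), so corpora
  heavy in high-throughput language are sensitive to it.
* Target-chemical matching uses the canonical name and all synonyms,
  although triage queries are typically synonym-free; recall of the
  target in text is correspondingly generous.
* Dictionary recognition cannot resolve abbreviations, acronyms, gene
  complexes or chemical classes, and scores species the database would
  not curate.
* Single-pass longest-match keeps at most one mention per category per
  span; nested or overlapping same-category mentions are not produced.
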