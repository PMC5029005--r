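---
title: "Rule-based plant–chemical relation extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based plant–chemical relation extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantchem)
```

## The task and its data model

`plantchem` extracts *containment* relationships between plants and
chemicals from sentence-level text. The unit of everything — annotation,
classification, evaluation — is the **corpus unit**: one (plant mention,
chemical mention) pair in one sentence, labeled `POS` when the sentence
asserts that the plant contains, produces or is the source of the
chemical, `NEG` otherwise. Working at the sentence level (rather than the
abstract level) increases the diversity of plant names per annotated item
and keeps the syntactic evidence for each decision local to one parse.

Two data contracts are enforced throughout:

* a `POS` unit must carry a *weak trigger* (a token sequence expressing
  the relationship, e.g. "were obtained from") and a *strong trigger*
  (exactly one word, e.g. "obtained"); a `NEG` unit must carry neither;
* plant identifiers are restricted to the Taxonomy and TCMID namespaces,
  chemical identifiers to MeSH, CHEMBL and CAS (or the literal `NA`).

Violations are rejected at construction time, at sheet import (with the
offending row number) and before BioC serialization, so no invalid corpus
can be round-tripped.

## The classifier

The model is rule-based on purpose: with a small development corpus, six
dependency-pattern families plus a trigger lexicon give a transparent
baseline whose errors can be read off the rules. A unit is `POS` iff at
least one family fires on the sentence's typed-dependency parse
(Stanford basic-dependency labels). The families are checked in a fixed
order — verbal, prepositional, relative, apposition, copula, compound
noun — but the order only determines which rule id is *reported*; the
label is order-independent, and `classify_unit()` returns all firing
matches.

Two containment notions are used deliberately:

* **Full subtree** (`descendants()`): whether an entity participates in a
  grammatical slot. "Entity inside the `nsubj` argument" means its head
  token is any descendant of the `nsubj` dependent, so "Pomegranate
  *derived from the tree Punica granatum*" places both plant mentions in
  the subject.
* **Noun phrase** (`np_subtree()`): the maximal *nominal* subtree,
  obtained by blocking traversal of clausal, coordinating, appositive,
  punctuation and clause-argument edges (`partmod`, `rcmod`, `ccomp`,
  `advcl`, `conj`, `appos`, `punct`, `nsubj`, `nsubjpass`, `cop`, `aux`,
  `mark`, `dep`, `cc`, ...) while keeping nominal modifiers and
  `prep`/`pobj` chains, so "the volatile oil (2-3 %) *of ginger*" keeps
  "ginger". Blocking `appos`, `punct` and the clause-argument labels is
  this package's operationalization: it is what makes an apposition's two
  phrases disjoint and a copular predicate's phrase exclude its subject,
  which the token-distance constraint requires (the phrases in "[soybean
  oil], [a source of unsaturated fatty acids]" are separated by exactly
  the comma, distance 1).

Family-specific notes:

* **Prepositional.** The rule fires when a `prep` edge attaches to a
  token *h* with one entity inside `np_subtree(h)` (minus the
  preposition's own subtree) and the other inside the `pobj` subtree.
  Attachment is NP-wide rather than head-only: in "dichloromethane
  extract of Feverfew" the chemical is an `nn` modifier of "extract",
  which carries the preposition — and the model is *supposed* to fire
  here; this is its canonical documented false positive. Subtracting the
  preposition's subtree from the left phrase prevents the same entity
  from counting on both sides (NPs include `prep` chains) and fixes the
  reported direction.
* **Relative.** The past-participle set is the same object as the passive
  verbal set — the trigger word lists coincide. The gerund "consisting"
  is intransitive, so its object must be reached through the preposition
  "of"; a bare `dobj` under "consisting" does not fire.
* **Apposition / copula.** Triggers are identified structurally (`appos`
  and `cop` edges), not lexically; any tense of "be" is accepted. Both
  carry a token-distance constraint, resolved as *strictly fewer than*
  `max_dist = 10` intervening tokens (the bound is exposed as an argument
  because "within ten" and "less than ten" read differently; strict
  inequality was fixed once and is configurable).
* **Compound noun.** The trigger is a single whitespace between the plant
  mention's end and the chemical mention's start, plant first only
  ("Aloe emodin" = emodin in aloe; "saponins panax" does not fire). The
  match therefore has an empty trigger-token list.

What the model does **not** do, by design: negation, hedging,
coordination scope and world knowledge. Solvent-extract and
treatment contexts ("ammonia treatment of rice straw") are syntactically
indistinguishable from containment and are predicted `POS`; relations
expressed through brackets ("3-(methylthio)propanal (cooked potato)") or
`-specific` compounds have no rule and are predicted `NEG`. The four
documented-error fixtures in `table1_fixtures()` pin this behavior so a
future "fix" cannot silently change the model's published error profile.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_dist` | 10 tokens | exclusive distance bound for apposition/copula |
| trigger lexicon | packaged lists (54 active, 29 passive/past-participle, 2 intransitive, 19 gerund surface forms) | lexical gate for verbal/relative families |
| `families` | all six | which rule families are evaluated |
| abbreviation guard | small built-in list | sentence-splitter period suppression |

Trigger matching is on lowercased *surface* tokens, not lemmas, because
the curated lists enumerate inflected forms explicitly; adding a word is
a one-line lexicon edit and, by the monotonicity property (tested),
removing words can only move predictions from `POS` to `NEG`.

## Conventions and numerical choices

* Character offsets are 0-based and half-open everywhere; sentence-
  relative in units and sheets, document-relative inside BioC locations
  (converters translate).
* Token indices are 1-based with head 0 for the root, following CoNLL
  usage; `read_conll()` rejects multi-headed tokens and cycles with row
  numbers.
* Unknown dependency labels never match any pattern and are reported once
  per label per session.
* Dictionary matching is case-insensitive, longest-match, left-to-right,
  token-boundary anchored; hyphens are boundaries, so "cinnamon-rat"
  still matches "cinnamon" (filtering contextual non-plants is an
  annotator guideline, not implemented). Cross-class overlaps keep the
  longer span, ties going to the plant; this resolution is a fixed
  package convention.
* A mention's syntactic head is the right-most mention token whose
  dependency head lies outside the mention.
* Percentages (P/R/F, agreement) are rounded half-up to one decimal,
  matching how such tables are conventionally printed; `prf_from_pr()`
  takes a `digits` argument where two decimals are wanted.
* The annotation sheet is UTF-8 TSV with a fixed 15-column header; the
  exact order of the bookkeeping columns is a convention of this package
  (the layout it mirrors is only partially specified), as are the BioC
  infon key names. The sheet has no field for the sentence's document
  offset, so import places sentences at offset 0; round-trips are
  lossless for all fifteen columns.
* `write_bioc()` orders documents by PMID and annotations by span start,
  making output deterministic: write → read → write is byte-identical.

## The synthetic generator

`generate_units(n, positive_fraction, confounder_fraction, seed)` builds
labeled corpus units from parameterized sentence templates — one template
per rule structure for positives, trigger-free templates for negatives,
and two confounder templates reproducing the documented false-positive
patterns (solvent extract, agronomic treatment; gold `NEG`, model `POS`).
Plant and chemical slots are filled from pools of surface forms taken
from the worked examples. Class counts are allocated deterministically
(`round(n * fraction)`) and shuffled by the seed; the corpus is a pure
function of its arguments.

Crucially, each template emits its own gold dependency parse, so
rule-engine tests need no statistical parser and cannot be confounded by
parser errors; an adapter contract (`dep_graph` in, Stanford labels,
`ud_to_stanford()` for UD parsers) is the integration point for real
parses. The generator emulates *structure*, not corpus statistics: it
makes no attempt to mimic real lexical distributions, sentence length
variety, parser noise, or any particular published class ratio. Passing
tests on generated data therefore demonstrate that the rule engine
implements its specification exactly — 100 % recovery of non-confounder
gold labels is by construction, since every positive template realizes
exactly one rule family — and say nothing about recall on real prose,
where grammar not covered by the six families dominates the error budget.

Default study conditions used by the test suite and the acceptance
script: 200 units, 50 % positives, 10 % confounders — large enough that
every template and pool entry is exercised, small enough that the whole
suite runs in seconds on one CPU.

## Known limitations

* Only the six families are modeled; passive-voice actives ("is contained
  by") fire only via the passive structure, and cross-sentence relations
  are out of scope.
* The dictionary NER has no abbreviation resolution and no contextual
  filtering; its recall is bounded by the lexicon.
* Corpus-level published scores (overall F on a ~1,000-unit
  manually-annotated corpus, annotator kappa) depend on data that must be
  obtained separately; the CLI supports re-running them (`classify`,
  `evaluate`, `agreement`) once such a corpus is available, but the
  package's own checks are the worked examples, the metric identities and
  the synthetic-corpus properties.
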