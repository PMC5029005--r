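# plantchem

Rule-based extraction of plant–chemical containment relationships from
biomedical text, together with the corpus-construction tooling such a
system presupposes.

## The problem

Plants are a major source of bioactive chemicals, and statements of the
form *"plant X contains chemical Y"* are scattered across millions of
PubMed abstracts. `plantchem` is for text-mining and NLP researchers who
want to build, exchange and evaluate corpora of such statements, and to
run a transparent, rule-based baseline extractor over them. The unit of
annotation and evaluation is the **corpus unit**: one (plant mention,
chemical mention) pair inside one sentence, labeled `POS` (the plant
contains / produces / is the source of the chemical) or `NEG` (no such
assertion). A sentence with several entity pairs yields several units.

The package covers the full pipeline:

* **Dictionary NER** — case-insensitive, longest-match, token-boundary
  anchored gazetteer matching for plant and chemical names, with a
  pluggable chemical-recognizer slot for external NER engines.
* **Preprocessing** — rule-based sentence splitting, co-occurrence
  filtering (keep sentences with ≥ 1 plant and ≥ 1 chemical mention), and
  Cartesian expansion of sentences into candidate corpus units.
* **Corpus I/O** — a BioC XML dialect and a 15-column tab-separated
  annotation-sheet layout, both with lossless round-trips, plus the
  data-contract validation behind them (`POS` units must carry a weak and
  a strong trigger; `NEG` units must not).
* **The rule-based classifier** — the core of the package, below.
* **Evaluation** — precision/recall/F1 against gold labels, simple percent
  agreement, and Cohen's kappa for annotator pairs.
* **Fixtures and synthesis** — packaged worked examples with hand-built
  gold dependency parses, and a seeded template generator that emits
  labeled sentences *with* gold parses so the whole pipeline is testable
  offline, without a statistical parser.

## The model

A unit is classified `POS` iff its sentence's typed-dependency parse
(Stanford basic-dependency label vocabulary) matches one of six rule
families and, for the lexically gated families, the matched word is in the
curated trigger lexicon. Writing NP₀ for the noun phrase containing the
plant and NP₁ for the one containing the chemical:

| Family | Structures | Trigger |
|---|---|---|
| Verbal | NP₀ V NP₁ (active, `nsubj`/`dobj`); NP₁ V PP NP₀ (passive, `nsubjpass` + `prep`/`pobj`); NP₀ V PP NP₁ (intransitive) | verb surface form ∈ active / passive / intransitive word set |
| Prepositional | NP₀ PP NP₁ and NP₁ PP NP₀ | any `prep` token attached inside one entity's NP |
| Relative | NP₁ R PP NP₀ (past participle); NP₀ R (PP) NP₁ (gerund; "consisting" requires "of") | participle/gerund surface form ∈ passive / gerund word set |
| Apposition | NP₀ , NP₁ and NP₁ , NP₀ | any `appos` edge; token distance < 10 |
| Copula | NP₀ be NP₁ and NP₁ be NP₀ | any `cop` edge; token distance < 10 |
| Compound noun | NP₀ ␣ NP₁ | a single whitespace ("Aloe emodin") |

The structural check runs first, then the trigger check; the family order
only decides which rule id is *reported*, never the label. The model is
deliberately syntactic: solvent-extract and treatment contexts
("dichloromethane extract of Feverfew") are known false positives, and
"plant-specific chemical" or bracketed relations are known false
negatives — the packaged error fixtures preserve exactly this behavior.

## Worked example

```r
library(plantchem)

fig3 <- table1_fixtures()[[2]]           # passive-clause worked example
print(fig3$unit)
#> <corpus_unit> [POS] "corn" -- "FB1" (PMID 23605447)
#>   weak trigger: "were obtained from"; strong trigger: "obtained"
#>   About 450 mg of FB1 were obtained from 800 g cultured corn.

cls <- classify_unit(fig3$graph, fig3$unit)
cls$label                                 # "POS"
cls$matches[[1]]$rule_id                  # "V2"  (passive verbal rule)
fig3$graph$tokens$text[cls$matches[[1]]$trigger_tokens]
#> [1] "obtained" "from"

# a synthetic 200-unit corpus: 50 % positives, 10 % confounders
syn <- generate_units(200, positive_fraction = 0.5,
                      confounder_fraction = 0.1, seed = 7)
res <- classify_fixtures(syn)
evaluate_labels(res$predicted, res$gold)
#> <eval_result> tp=100 fp=20 fn=0 tn=80  P=83.3% R=100.0% F=90.9%
```

The 20 false positives are exactly the 20 confounder units (solvent
extract / agronomic treatment sentences), which the syntactic model fires
on by design; every non-confounder label is recovered.

Evaluation helpers reproduce published-table arithmetic directly:

```r
prf_from_pr(73.5, 63.3)     # 68.0   F1 from a printed P/R pair
simple_agreement(2077, 9)   # 99.6   percent agreement from counts
```

A thin CLI wraps the same functions (`exec/plantchem`): `convert` between
BioC and sheet, `units` to run the candidate pipeline over raw abstracts,
`classify` against CoNLL-style parses, `evaluate`, `agreement` and
`generate`.

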