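---
title: "Extracting family history information from clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting family history information from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famhx)
```

## The task

Family history sections of electronic health records describe a patient's
relatives and their medical conditions in free text: *"His maternal cousin
was diagnosed with type 2 diabetes."* The extraction task that `famhx`
addresses turns each note into a deduplicated document-level list of

* **family members**, normalized to a closed vocabulary of 15 names
  (Father, Mother, Parent, Sister, Brother, Daughter, Son, Child;
  Grandmother, Grandfather, Grandparent, Cousin, Sibling, Aunt, Uncle),
  each with a **side-of-family** attribute (`NA`, `Maternal` or
  `Paternal`; first-degree relatives are always `NA`), and
* **clinical observations** — disease and health-behavior phrases of
  typically one to five tokens.

The package treats this as sentence-level sequence labeling followed by
rule-based property resolution and document-level aggregation.

## Tag schemes

All labelers use IOB2 tags. Observations are always `B/I-Ob`. For family
members three schemes trade training-data fragmentation against
post-processing burden:

* **standard** — members are plain `B/I-FM` (five labels in total). Both
  the normalized name and the side must be recovered by rules afterwards.
* **side** — the side is encoded in the tag: `B/I-FM_SIDE_Maternal`,
  `B/I-FM_SIDE_Paternal`, `B/I-FM_SIDE_NA`, and a dedicated `B/I-FM_NA`
  for member types never observed with any side in training. Only the
  name is recovered by rules.
* **relation-side** — both properties are in the tag
  (`B-FM_Cousin_Maternal`), over exactly the (name, side) pairs observed
  in training. No rules are needed at decode time, at the cost of many
  sparsely supported labels.

A mention of "cousin" annotated Maternal therefore encodes as `B-FM`,
`B-FM_SIDE_Maternal` or `B-FM_Cousin_Maternal` depending on the scheme.
Inventories for side eligibility and relation-side pairs are always built
from the training mentions (`build_side_scheme()`,
`build_relation_side_scheme()`), never hard-coded.

## Property-resolution rules

`normalize_fm()` maps a recognized mention to the 15-name vocabulary:
adjective/numeral tokens and a small modifier stop list (`older`, `twin`,
`step`, ...) are dropped, the remainder is lowercased, surface variants
(`mom`, `mommy`, `grandpa`, ...) are mapped and regular plurals reduced,
and the final head token is matched against the base names. The shipped
variant table is an editable TSV resource and is a reconstruction — the
underlying corpus documents only the `mom`/`mommy` style of variation, so
the analogous grandparent forms are included by design choice.

`resolve_sf()` sets the side attribute for schemes that do not encode it:
an explicit `maternal`/`paternal` term within a two-token lookbehind
window wins; otherwise the side most frequently observed for that member
type in training (`build_side_prior()`) is used. The window default of 2
covers "maternal half aunt" without leaking across clauses and is
configurable. Ties and all-zero priors resolve to the least committal
order `NA > Maternal > Paternal`, because a spurious side is punished
twice (one false positive plus one false negative) by the exact-match
scorer. Finally, first-degree relatives are forced to `NA`, mirroring the
annotation convention.

## The neural sequence labeler

The labeler follows the character-CNN + bidirectional LSTM + CRF family of
architectures. Per token, the input vector concatenates:

| channel            | default dim | notes                                   |
|--------------------|------------:|-----------------------------------------|
| word embedding     | 200         | looked up on the digit-normalized form  |
| char-CNN output    | 50          | 50 kernels of width 3, tanh + max-pool  |
| PoS embedding      | 20          | pluggable tagger backend                |
| family flag        | 1           | binary dictionary feature               |
| concept embedding  | 200         | CUI of the covering concept match       |

for a 471-dimensional input. Dropout (0.5) is applied to the character
embeddings before the CNN and to the concatenated vector before the LSTM.
Emission scores feed a linear-chain CRF whose Viterbi decoding can be
constrained so IOB2-invalid transitions are impossible; the no-CRF
ablation replaces the objective with per-token cross-entropy and decodes
by argmax plus `repair_iob2()`. Training is plain SGD (learning rate 0.01,
decayed as $\eta_t = \eta / (1 + 0.05\,(t-1))$ per epoch, batch size 10,
L2 penalty $10^{-8}$, default 1000 epochs) with gradient-norm clipping at
5.0 — clipping is a numerical safeguard the original description does not
discuss. The recurrent hidden size is likewise not published; the default
of 200 per direction follows the architecture this model family builds on.
Gradients for every layer, including fine-tuned embedding tables, are
computed in compiled code (`src/nn.cpp`); the mini-batch update uses the
summed batch gradient, which together with the clip gives well-scaled
steps.

Numeric normalization collapses every maximal digit run to `0`
("35-year-old" → "0-year-old"), and is idempotent. Because the underlying
description is ambiguous between run reduction and whole-token reduction,
both are implemented (`normalize_numeric(mode =)`); run reduction is the
default.

Desk-scale runs in the tests and scripts use reduced dimensions
(word 50, char 16, filters 20, PoS 10, CUI 16, hidden 50) and 30-150
epochs; the published values remain the `labeler_config()` defaults.

The classical baseline is a feature-based linear-chain CRF sharing the
same compiled forward-backward core, schemes, rules and evaluator. Its
feature templates (identity/lowercase/PoS/flag/CUI-presence, prefixes and
suffixes up to length 3, the same features at offsets −2..+2, label
bigrams) are a documented reconstruction, since the original templates are
unpublished.

## Evaluation protocol

Scoring is document-level. Family records match by exact `(fm, sf)`
equality. Observations use partial matching: a prediction matches a gold
phrase when one contains the other or when they share a contiguous token
run with at most four leftover tokens. Leftovers are counted on both
sides by default — the stricter of the two readings, since the official
script's internals are unpublished — with `count_sides = "gold"`
available. Matching is greedy one-to-one, predictions in document order,
largest token overlap first. The overall figure micro-averages the two
classes; undefined precision/recall is reported as 0.

## The synthetic corpus

The restricted challenge corpus cannot be redistributed, so
`generate_corpus()` emulates its statistical structure: templated
sentences ("His maternal aunt has heart disease.", "The patient's brother
died at age 62 of a stroke.") plus entity-free filler at rate 0.25;
first-degree-heavy member frequencies; first-degree members NA-only;
strongly modal sides for extended family with Maternal modal for Cousin;
60% of non-NA sides textually realized as a preceding side term, so the
resolver's prior fallback is genuinely exercised; surface variants,
plurals, modifiers and numeric tokens at configurable rates. Every
generated mention is emitted as a gold annotation with exact character
offsets.

What it does **not** emulate: coreference, cross-sentence side inference,
kin-of-kin constructions ("her father's brothers" meaning uncles —
available only in `hard_mode`, excluded from the standard conditions
because they are documented failure modes of this model family),
abbreviation-heavy clinical telegraphese, and annotation noise. Passing
results on this corpus therefore demonstrate that the machinery learns
and decodes the structures it models, not clinical-grade accuracy on real
notes.

The side distributions were chosen once: with 60% explicit side terms, a
side sampled but not textually realized is irreducible noise, so weakly
modal distributions would cap achievable held-out accuracy below any
useful recovery check; strongly modal distributions keep the qualitative
structure while leaving the recovery target attainable.

## Study sizes and reproducibility

The recovery study trains the side-scheme model on a 92-document corpus
(about 500 sentences) and evaluates on a held-out 25-document corpus;
the ablation compares CRF and softmax inference over 5 seeds on a
40-document corpus. All randomness — corpus generation, initialization,
shuffling, dropout — derives from explicit integer seeds, and identical
seeds give byte-identical corpora and loss curves. `scripts/acceptance.R`
re-runs both studies from scratch.

## Known limitations

* Properties requiring cross-sentence inference are out of scope by
  design; the decoder never looks beyond a sentence.
* Indirect kin descriptions are not resolved (see `hard_mode` above).
* The bundled concept recognizer is an exact-match toy dictionary behind
  the same interface a full recognizer adapter would implement; it exists
  so the CUI feature channel is functional and testable offline.
* The bundled PoS tagger is a deterministic rule lexicon with a closed
  inventory; any backend with a `tagset` and vectorized `tag()` can
  replace it.
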