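# famhx — family history information extraction from clinical notes

`famhx` extracts **family history information (FHI)** from free-text
patient notes: which relatives are mentioned, on which side of the family
they fall, and which clinical observations the note attributes to them.
It is written for clinical-NLP researchers and engineers who need a
complete, reproducible, offline implementation of the entity-recognition
subtask of document-level FHI extraction — from raw text to the scored
prediction list.

## What it implements

Each note is reduced to a deduplicated document-level list of

* family members, normalized to a 15-name vocabulary
  (Father ... Child for first degree; Grandmother ... Uncle for second
  degree) with a side-of-family attribute *sf* ∈ {NA, Maternal, Paternal},
  and
* observation phrases (diseases, health behaviors).

The pipeline is sentence-level IOB2 sequence labeling plus rule-based
property resolution:

* **Three tag schemes** — *standard* (`B/I-FM`), *side*
  (`B/I-FM_SIDE_Maternal`, ...), and *relation-side*
  (`B-FM_Cousin_Maternal`, ...) — encoding progressively more of the
  (fm, sf) properties inside the labels. Observations are always `B/I-Ob`.
* **A neural sequence labeler**: character-level CNN (max-pooled, width-3
  kernels) concatenated with word, PoS and concept (CUI) embeddings and a
  binary family-dictionary flag, fed through a bidirectional LSTM into a
  linear-chain CRF; trained by SGD with dropout, learning-rate decay and
  gradient clipping. Inference is Viterbi decoding

  $$\hat{y} = \arg\max_y \sum_t \big(\psi(x_t, y_t) + A_{y_{t-1}, y_t}\big)$$

  optionally constrained so IOB2-invalid transitions are impossible, or
  per-token softmax for the no-CRF ablation. The numerical core
  (forward-backward, Viterbi, full backpropagation) is compiled
  C++ (Rcpp/RcppArmadillo).
* **A classical feature-based CRF baseline** sharing the same schemes,
  decoding, rules and evaluator.
* **Rule-based normalization**: variant/plural/modifier-aware mapping of
  mentions to the 15 names, and side resolution by an explicit
  `maternal`/`paternal` lookbehind with a training-frequency fallback.
* **The document-level evaluation protocol**: exact (fm, sf) matching for
  members, partial matching for observations (at most four mismatched
  tokens), with micro-averaged precision P = TP/(TP+FP),
  recall R = TP/(TP+FN) and F1 = 2PR/(P+R).
* **A synthetic-corpus generator** that emulates the statistical structure
  of a family-history corpus (the real challenge corpus is restricted), so
  every stage is trainable and testable offline.

## Worked example

```r
library(famhx)

# 1. A reproducible synthetic corpus of annotated notes
corpus <- generate_corpus(default_generator_config(n_documents = 20, seed = 42))

# 2. Fit the side-scheme extractor (classical CRF baseline for speed)
extractor <- fit_extractor(corpus$documents, corpus$annotations,
                           scheme_name = "side", model_type = "crf_baseline",
                           config = list(epochs = 20, seed = 1))

# 3. Extract document-level lists from new notes
unseen <- generate_corpus(default_generator_config(n_documents = 8, seed = 43))
pred <- extract_fhi(extractor, unseen$documents)
head(pred, 4)
#>    doc_id         type     fm       sf     obs_text
#> 1 note001 FamilyMember   Aunt Paternal         <NA>
#> 2 note001  Observation   <NA>     <NA>       asthma
#> 3 note001 FamilyMember Father       NA         <NA>
#> 4 note001  Observation   <NA>     <NA> colon cancer

# 4. Score against the gold lists
score_predictions(pred, gold_document_list(unseen$annotations))
#> Document-level evaluation (partial matching for observations)
#>              tp fp fn precision recall     f1
#> FamilyMember 25  1  1    0.9615 0.9615 0.9615
#> Observation  20  0  0    1.0000 1.0000 1.0000
#> Overall      45  1  1    0.9783 0.9783 0.9783
```

The report reads: of 26 gold (name, side) pairs in the 8 held-out notes
the extractor recovered 25 exactly (one side attribute wrong, costing one
false positive and one false negative), and every observation phrase was
recovered under the four-token partial-match rule.

For the neural labeler, replace `model_type = "crf_baseline"` with
`"neural"` and pass a `labeler_config()`; `vignettes/` documents the
architecture, rules and design choices in full. A thin command-line
interface (`inst/cli/famhx`) wraps the same functions as `train`,
`predict`, `evaluate` and `generate-corpus` subcommands.

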