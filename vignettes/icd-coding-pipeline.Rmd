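---
title: "Embedding-based ICD-10 coding: method, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-based ICD-10 coding: method, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdvec)
```

## The method

`icdvec` assigns ICD-10 codes to free-text German diagnosis phrases by
nearest-centroid search in a word-embedding space. The pipeline has four
stages:

1. **Normalization** (`normalize_text()`). Clinical German is reduced to a
   lowercase alphanumeric token stream: umlauts and `ß` are transliterated
   (`ä→ae`, `ö→oe`, `ü→ue`, `ß→ss`), every non-alphanumeric character
   separates tokens, pure integers greater than 10 are dropped (visual
   acuity values, years and the like carry no diagnostic signal, while
   small grades and stages do), and compounds can optionally be split by a
   pluggable strategy. Multi-word diagnoses listed in a phrase lexicon are
   merged into single underscore-joined tokens (`apply_phrases()`), so
   that, say, a retinal detachment phrase receives one dedicated vector
   instead of dissolving into its parts.

2. **Embedding** (`train_embedding()`). A skip-gram model with negative
   sampling is trained on the normalized corpus. Each token $w$ gets a
   vector $v_w \in \mathbb{R}^d$ such that tokens appearing in similar
   contexts lie close in cosine similarity. A token sequence
   $t_1,\dots,t_k$ is represented by the unweighted column-wise mean of
   its in-vocabulary vectors.

3. **Annotation** (`build_centroids()`). A thesaurus maps natural-language
   annotations to ICD-10 codes. Every annotation is embedded through the
   same path as a query, and each code $c$ receives the centroid
   $\mu_c = \frac{1}{|A_c|}\sum_{a \in A_c} v_a$ of its embeddable
   annotation vectors. The centroids are the classification targets.

4. **Inference** (`infer_codes()`). A query $q$ is embedded to $v_q$ and
   assigned $\hat c = \arg\min_c \; d_{\cos}(v_q, \mu_c)$ with
   $d_{\cos}(u,v) = 1 - \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert}
   \in [0,2]$, scanning all centroids exhaustively. A prediction is
   accepted only if its distance does not exceed a threshold
   $\theta$, which allows rejecting queries with no sensible neighbor.

Evaluation (`score_predictions()`, `summarize_eval()`) grades a prediction
at two levels: **CC** ("completely correct", exact code string) and **C**
("correct", agreement of the 3-character superordinate group — H33.0 vs
H33.2 are both retinal detachments). `summarize_eval()` also emits a
per-group CC-accuracy table restricted to groups with more than
`min_group_n` gold occurrences (default 3).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `dim` | 300 | Embedding dimensionality. 300 is the standard operating point for skip-gram on large clinical corpora; the validation worlds use 50, which is ample for a 20-code vocabulary. |
| `window` | 5 | Context half-width in tokens; diagnosis phrases are short, so a 5-token window spans them comfortably. |
| `epochs` | 5 | Passes over the corpus. |
| `min_count` | 5 | Tokens rarer than this get no vector; below that frequency skip-gram estimates are mostly noise. |
| `negative` | 5 | Negative samples per positive pair, drawn from the unigram distribution raised to 0.75. |
| `learning_rate` | 0.025 | Initial SGD step, decayed linearly to 1e-4 of itself. |
| `phrase_mode` | `"augment"` | At query time a detected phrase's vector is *added* to the vector array alongside its constituent words before averaging. The alternative (`"replace"`, phrase vector only) is available; augmenting keeps single-word context when the phrase vector is poorly estimated. |
| `max_distance` ($\theta$) | 2 | Acceptance threshold. The default accepts everything; rejection is opt-in because a useful operating value depends on the corpus and must be chosen from a distance distribution (see `plot_distance_distribution()`). |
| `min_group_n` | 3 | Per-group table exclusion: a group needs more than 3 gold occurrences to be reported. |

The model variant (negative sampling, no subsampling) and `min_count` are
package choices exposed in the training interface; the downstream
centroid geometry does not depend on the variant.

## Determinism

Training is single-threaded and driven by a 64-bit linear congruential
generator; a fixed `seed` reproduces the embedding matrix bitwise, and the
test suite asserts this. All other randomness (world generation, OOV
injection) flows through R's RNG under `withr::with_seed()`, so every
artifact is a pure function of its configuration.

## The synthetic world

The generator (`world_config()`, `generate_world()`) builds a
self-contained world so the pipeline can be exercised without clinical
data:

* Each of `n_codes` ICD-like codes (spread over at least three 3-character
  groups) owns a disjoint **signature vocabulary** of CVCV pseudowords.
  Pseudowords avoid shipping any medical vocabulary and make disjointness
  provable.
* Every document is assigned a code and draws each token from that code's
  signature distribution (a fixed Dirichlet-tilted multinomial) with
  probability `alpha`, otherwise from a background distribution over the
  *whole* vocabulary (all signatures plus shared fillers). The background
  deliberately covers the full vocabulary rather than fillers alone: this
  keeps every word embeddable at any `alpha`, so `alpha` interpolates
  cleanly between perfectly separated sublanguages (`alpha = 1`) and a
  corpus with no code/token association at all (`alpha = 0`), where
  retrieval can only succeed at the $1/\text{n\_codes}$ chance rate.
* Each code's signature is split into an **annotation pool** and a
  held-out **query pool**. Thesaurus annotations sample the former; gold
  queries sample the latter. Gold queries are therefore true paraphrases:
  they share no words with any annotation, and success requires the
  embedding to have learned from co-occurrence that query-pool words
  belong with annotation-pool words. Without this split, nearest-centroid
  search succeeds through trivial lexical identity even on an
  uninformative corpus. Verbatim self-retrieval (querying an annotation
  itself) is exercised separately and must return the code at distance
  zero.
* `n_phrases` codes get a two-word collocation that is injected into their
  documents and annotations and listed in the phrase lexicon, exercising
  the phrase-merging path end to end.
* `inject_oov()` emulates the cross-site vocabulary mismatch that degrades
  accuracy when queries come from a hospital whose jargon the corpus never
  saw: it replaces a chosen fraction of query words with tokens that are
  out of vocabulary by construction.

**What passing tests show — and what they do not.** The synthetic world
has no grammar, no negation, no abbreviations, no misspellings, and its
"synonyms" are resampled word sets rather than true lexical variants.
Passing the validation suite demonstrates that the pipeline's mechanics
are correct (normalization rules, averaging, centroid geometry, nearest
search, thresholding, scoring) and that the method recovers structure
when the corpus contains it; it does not certify any accuracy level on
real clinical text, where vocabulary coverage and annotation quality
dominate.

## Validation conditions and problem sizes

The validation suite runs the full pipeline under fixed study conditions:
20 codes, 12 signature words per code (4 held out for queries), 2000
documents of 40 tokens, 5 annotations of 3 words per code, 100 paraphrase
queries, embeddings of dimension 50 trained with window 5 for 5 epochs.
These sizes give stable multi-seed statistics while a full end-to-end run
stays in the low seconds. The frozen expectations, derived from a 5-seed
pilot at those conditions and then fixed:

* separable world (`alpha = 1`): mean CC accuracy over seeds 1–5 of at
  least 95%;
* uninformative world (`alpha = 0`): pooled CC successes consistent with
  the 1/20 chance rate (two-sided binomial test at level 0.001);
* mean CC accuracy non-increasing along `alpha` ∈ {1, 0.8, 0.5, 0.2};
* the no-vector rate non-decreasing in the OOV-injection fraction and
  exactly 100% at full replacement.

## Numerical and design choices

* **Tie-breaking**: equidistant centroids resolve to the
  lexicographically smallest code; the index stores codes sorted, so the
  argmin is deterministic and auditable.
* **Distances** are clamped into $[0, 2]$ against floating-point
  excursions; a query whose mean vector has zero norm is treated as
  producing no vector (it cannot be compared under cosine) rather than
  raising.
* **Averaging** uses raw vector rows, not length-normalized ones; the
  sequence representation is the plain column-wise mean.
* **Number rule**: strictly greater than 10, on pure-integer tokens only;
  mixed tokens such as `h40` pass through whole.
* **Compound splitting** is off by default and pluggable
  (`compound_splitter()` implements a greedy binary split into two
  vocabulary words of at least 4 characters, applied only to
  out-of-vocabulary tokens); corpus-specific strategies can be swapped in
  without touching the pipeline.
* **Phrase matching** is greedy longest-match left-to-right,
  non-overlapping — the standard gazetteer-merging order, and
  deterministic.
* **Annotations are embedded through the query path** (including phrase
  augmentation) so index-side and query-side representations live in the
  same space; asymmetric conventions would shift every centroid relative
  to its own annotations.
* **Degenerate inputs** raise classed conditions
  (`icdvec_config_error`, `icdvec_format_error`,
  `icdvec_dimension_error`, ...) rather than generic errors, so callers
  can distinguish configuration mistakes from data problems.

## Known limitations

* The vocabulary is closed at training time: unseen words contribute
  nothing to a query vector, and fully unseen queries are unanswerable.
  This is the dominant failure mode across sites with different jargon;
  retraining on an extended corpus is the intended remedy.
* One code per query; multi-diagnosis lines must be segmented upstream.
* No negation or context handling ("kein Glaukom" embeds next to
  "Glaukom").
* Rejection thresholds are not auto-calibrated; choose them from the
  distance distribution on held-out data.

## A worked run

```{r, eval = FALSE}
library(icdvec)

world <- generate_world(world_config(alpha = 1, seed = 7))
report <- run_end_to_end(world, dim = 50, seed = 7)
report
glance(report)
tidy(report)          # per-group CC accuracy table
autoplot(report)      # bar chart of the table

preds <- attr(report, "predictions")
plot_distance_distribution(preds, max_distance = 0.6)
```
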