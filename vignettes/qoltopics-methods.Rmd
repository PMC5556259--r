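---
title: "Methods: topic modeling of patient-authored text and questionnaire alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic modeling of patient-authored text and questionnaire alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qoltopics)
```

## The problem

Breast-cancer patients discuss their disease on forums and social networks in
their own words. Standardized quality-of-life (QoL) instruments — the EORTC
QLQ-C30 (items 1–30) and its breast module QLQ-BR23 (items 31–53) — measure
the same experience through fixed items grouped into functional and
symptomatic scales. `qoltopics` implements a pipeline that (i) normalizes
noisy patient-authored text, (ii) infers latent topics with LDA, (iii) aligns
each questionnaire item to its most similar topic with a probability-weighted
Jaccard statistic, (iv) evaluates those proposed relationships against expert
annotations, and (v) flags *emerging topics*: patient concerns that align to
no item, i.e. candidate additions to the instruments.

The original communities (a French forum and public Facebook groups) cannot
be redistributed, so the package ships a synthetic-data module that generates
every input with known ground truth, plus the published aggregate tables
(`qlq_study_tables()`) from which the headline evaluation figures can be
recomputed exactly.

## Text normalization

`preprocess_document()` applies up to nine steps, always in this order:
user-tag removal; hyperlink/email replacement (tokens `link` / `mail`) and
emoticon coding (`:)` → `:smile:`); slang removal (*lol*, *mdr*, *xD*, matched
case-insensitively); lemmatization; lowercasing; stopword removal; lay-term
substitution (*crabe* → *cancer*, *onco* → *oncologue*); spelling correction;
pseudonym removal.

Design notes:

* **Links: replace or delete.** Replacement (`link_mode = "replace"`) is the
  default because the `link`/`mail` tokens carry signal about message type; a
  `"delete"` mode exists for applications that want no artifact tokens (the
  noisy-text round-trip property in the test suite uses it so that injected
  URLs vanish).
* **Order sensitivity.** Lowercasing precedes stopword removal, so
  capitalized stopwords are removed; slang is matched case-insensitively
  because it runs *before* lowercasing. Lay substitution precedes spelling
  correction, both on lowercase lemmas.
* **Pluggable morphology.** Lemmatization and spelling correction are
  function arguments with dictionary-lookup defaults
  (`dictionary_lemmatizer()`, `dictionary_speller()`; identity when a form is
  absent). Real French morphological analysis is out of scope; any external
  tagger can be wrapped as a function. POS tags (`NN`, `V`, `A`, `OTHER`)
  come from the lemmatizer dictionary.
* **Idempotence.** The pipeline is idempotent on its own output provided the
  substitution tables are *converged*: no lay variant or misspelling maps to
  another table's key. `lexicon_set()` rejects self-maps; converged tables
  are the user's contract.
* **Tokenization** uses unicode word characters, keeps coded emoticons
  (`:smile:`) intact, and splits French elision clitics (`l'`, `d'`, `j'`,
  one- or two-letter prefixes) so that articles become removable stopwords;
  longer apostrophe words (*aujourd'hui*) stay whole.

`build_vocabulary()` then restricts the token stream to a **scenario**:
`MED` keeps only terms of the medical lexicon (MeSH-style; multi-word terms
such as *cancer du sein* are merged longest-match-first, leftmost,
non-overlapping by `multiword_match()`), and `MED+NN`, `MED+NN+V`,
`MED+NN+V+A` progressively add nouns, verbs, adjectives. Two
strongly-represented words that drown topics (*femme*, *temps*) are excluded
by default via `noise_terms`, under every scenario.

## The topic model

LDA with `K` topics: each topic `t` is a distribution `phi[t, ]` over the `V`
vocabulary terms; each document `d` mixes topics with weights `theta[d, ]`;
every position `j` of document `d` carries a latent assignment `z[d, j]`.
Priors are symmetric Dirichlet: `theta_d ~ Dir(alpha)`, `phi_t ~ Dir(beta)`.

**Hyperparameter scheme.** `alpha = alpha0 / K`, which keeps the total prior
mass per document fixed as `K` changes. The classical recommendation
`alpha0 = 50` produces very flat document-topic posteriors on short
social-media messages, making per-message topic attribution useless, so the
default is `alpha0 = 10`; `beta = 0.1`; `K = 20` (the operating point chosen
for the breast-cancer corpora after expert inspection). `K = 1` is rejected
except under an explicit test override (`allow_single_topic`), where the
closed form is returned.

**Inference** (`fit_lda_gibbs()`) is the collapsed Gibbs sampler: with
`phi` and `theta` integrated out, each assignment is resampled from

    P(z = t | rest) ∝ (n_dt + alpha) * (n_tw + beta) / (n_t + V*beta)

with the current position excluded from all counts. After `burn_in` sweeps
(default 200) the count tables are averaged over the retained sweeps
(default 800) and the point estimates are the smoothed ratios
`phi_hat = (n_tw + beta)/(n_t + V*beta)`,
`theta_hat = (n_dt + alpha)/(l_d + K*alpha)`. Averaging over sweeps rather
than taking one final sweep reduces Monte-Carlo variance; no identifiability
correction is applied during sampling (single-chain averaged counts are the
standard practice; label switching is handled only at evaluation time by
`match_topics_greedy()`).

**Determinism.** The sampler uses R's RNG (so `set.seed()` governs it) and a
fixed scan order — documents in index order, positions left to right — making
runs bitwise reproducible from the seed.

**Validation against an exact oracle.** `enumerate_lda_posterior()`
enumerates all `K^N` assignments of a tiny corpus and computes the exact
posterior mean of `theta` from the collapsed joint via `lgamma`; it shares no
code with the sampler. The test suite compares the sampler's estimate
(averaged over 16 independent chains) to the exact value, using the
between-chain standard error as the Monte-Carlo SE; agreement is required
within 3 SEs. Note that for symmetric priors the exact posterior mean of
`theta` is `1/K` by label symmetry, so this check is precisely a test that
the chain mixes across the symmetric modes — a stringent requirement for a
Gibbs implementation.

**Diagnostics.** `perplexity()` computes
`exp(-sum log P(w|d) / total tokens)`; uniform topic rows give exactly `V`,
and the value never drops below 1. `theta_entropy()` exposes the flatness of
document-topic posteriors; its mean is non-decreasing in `alpha0` (tested on
a fixed corpus over `alpha0 ∈ {1, 10, 50}`), which is the quantitative form
of the "flat posterior" argument behind `alpha0 = 10`.

## Aligning topics to questionnaire items

Each topic is profiled by its top `n = 20` terms (the keyword-presentation
convention), renormalized to sum 1; each item by the *uniform* distribution
over its preprocessed tokens — items are very short (fewer than five words),
so uniform weights are the only defensible choice. Items run through the
*identical* normalization pipeline as messages, including lay-term
substitution, so both profiles share a vocabulary.

The similarity is the min/max weighted Jaccard

    s(x, y) = sum_w min(x_w, y_w) / sum_w max(x_w, y_w)

which is symmetric, lies in [0, 1], equals 1 iff the profiles coincide and 0
iff their supports are disjoint, and reduces to the plain Jaccard index of
the supports for equal-size uniform profiles. It is the standard
weight-aware generalization of the Jaccard coefficient; an alternative
reading — topic mass on the shared terms over the union size,
`sum_{w∈T∩Q} x_w / |T∪Q|` — is available as `variant = "overlap"`. The
min/max form is the package default.

`align_items()` keeps, for every item, the topic with the highest similarity
(ties toward the lowest topic id; the full score matrix is retained as an
attribute for audit). No similarity threshold is applied: every item gets a
best topic and rejection is left to the expert, matching how the published
evaluation was run. `evaluate_precision()` then scores the proposals against
the expert annotation table — precision is the percentage of validated
relationships, rounded to the nearest whole percent — and
`emerging_topics()` lists the topics that are the *validated* best topic of
no item, together with the number and share of documents they dominate.

`match_topics_across_corpora()` reuses the same similarity to pair topics of
two independently fitted models (greedy, highest similarity first, one-to-one,
pairs below `threshold = 0.3` dropped), the automation proposed for the
manual cross-corpus comparison.

Two percentage conventions coexist in the published tables and are kept
distinct on purpose: precision is *rounded* (39/53 → 74%), while
questionnaire-dimension coverage is *truncated* (22/23 → 95%, 20/23 → 86%;
`dimension_coverage()`).

## The synthetic-data generator

`generate_corpus()` draws `phi_t ~ Dir(beta_gen)`, `theta_d ~ Dir(alpha0/K)`,
then topics and words per position — exactly the generative model the fitter
assumes, which is the point: generator and fitter form a consistent pair, so
recovery failures indict the inference, not the data. Defaults:

* `beta_gen = 0.01` — well-separated, peaked topics. This is deliberately
  smaller than the fitting `beta = 0.1`: generation needs distinguishable
  topics, while fitting smooths.
* `alpha0 = 10`, matching the fitting scheme.
* Document lengths Poisson with mean 30, truncated at 1 (message lengths
  were never reported for the original corpora; 30 medical-term occurrences
  per message is a realistic post-filtering size for forum posts).
* Users and threads are assigned round-robin so `corpus_summary()` is
  testable against construction.

`generate_questionnaire()` writes items of 2–4 distinct terms sampled by
probability from a topic's top-20 pool (QoL items contain fewer than five
words), recording the generating topic as the ground-truth label;
`generate_noisy_text()` wraps clean tokens in user tags, URLs, slang,
pseudonyms, lay variants, misspellings and case noise such that the
normalization pipeline provably recovers the clean tokens.

What the generator does **not** emulate: French grammar and word order (LDA
ignores both), realistic spelling-error processes, thread structure and
discourse, narrator roles, or the heavy-tailed vocabulary of real text.
Passing recovery tests therefore demonstrates the correctness of the
inference and alignment machinery under the model's own assumptions — not
that K = 20 topics of real forum text are recoverable at any given accuracy.

## Reference experiment sizes and numerical choices

The test suite and the acceptance script use these problem sizes, chosen as
the smallest instances that still exercise every claim:

* Oracle comparison: 3 documents, 9 positions, `V = 3`, `K = 2` (512
  enumerable assignments); 16 chains × 3,000 retained sweeps.
* Parameter recovery: `K = 5`, `V = 200`, `D = 500`, ~60 tokens/document,
  `beta_gen = 0.01`, fit with `beta = 0.1`, 1,000 sweeps (200 burn-in);
  matched mean total-variation distance ≤ 0.15 and dominant-topic agreement
  ≥ 95% at the reference simulation seed, item→topic alignment recovery
  ≥ 90% with 4 items per topic.
* Properties (idempotence, closure, conservation): 1,000 randomized noisy
  fixtures.

Tie-breaks are uniformly "lowest index wins" (top words, dominant topic,
best topic). Model artifacts serialize matrices at full double precision
(`%.17g`), so `load_model(save_model(x))` is bit-identical.

## Known limitations

* **Dominant-topic agreement is intrinsically capped.** The generating
  dominant topic is the mode of a document's true assignments; documents
  whose top two topic counts are tied or nearly tied cannot be attributed
  reliably by *any* inference. With `alpha0 = 10` (so `alpha = 2` at
  `K = 5`) such near-ties are common, and agreement across generator
  realizations varies roughly between 0.90 and 0.97. Agreement against the
  argmax of the latent `theta_d` itself would be bounded far lower (~0.78
  even with perfect inference), which is why recovery is defined against the
  realized assignments.
* Very peaked generating topics (`Dir(0.01)` over 200 terms concentrates on
  a handful of words) occasionally collide on their dominant terms, which
  blurs attribution for the affected pair; this is a property of the study
  conditions, not of the sampler.
* The dictionary lemmatizer and speller are lookup tables; unknown forms
  pass through. Multi-word term matching is greedy (longest-first leftmost),
  not globally optimal.
* Precision and coverage on the real corpora are reproduced as *arithmetic*
  from the published validation counts and dimension map; the raw corpora
  are not available, so no claim is made about re-running the pipeline on
  them.
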