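---
title: "Auditing word embeddings for mental-health bias: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing word embeddings for mental-health bias: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embaudit)
```

## The problem

Clinical NLP systems for mental health are routinely built on pre-trained
word embeddings such as GloVe (trained on Wikipedia/Common Crawl) and
word2vec (trained on Google News). Embeddings place every vocabulary token
at a point in a d-dimensional real space where geometric proximity tracks
distributional similarity. Because the training corpora reflect how society
writes about demographic groups, the geometry can encode associations
between group labels (woman, irish, queer, teenager, ...) and psychiatric
vocabulary (alcoholism, perinatal_depression, substance_abuse, ...). A
model that consumes these vectors inherits those associations.

embaudit measures such associations three ways, each producing a
deterministic, serializable table:

1. **Analogy probes** (`analogy_query`): "w1 is to w2 as w3 is to ?",
   answered by the 3CosAdd rule — candidates ranked by cosine similarity to
   the renormalized query vector q = v(w2) − v(w1) + v(w3). A probe like
   (w1 = depression, w2 = british, w3 = irish) surfaces the diagnosis the
   space associates with the probe group relative to the reference pair.
2. **Nearest-diagnosis audits** (`nearest_in_lexicon`, `batch_audit`): for
   each demographic label, rank every entry of a diagnosis lexicon by
   cosine similarity to the label's vector. Restricting candidates to a
   curated lexicon asks "which *diagnosis* is closest", not "which word".
3. **Pole-axis placements** (`axis_coordinate`, `project_plane`,
   `gradient_rank`): a pair of opposing words (safe/dangerous, he/she,
   suicide/healthy) defines a semantic axis; each term receives the scalar
   coordinate cos(term, pole_high) − cos(term, pole_low). Crossing two axes
   gives a 2-D placement; a single axis gives a 1-D gradient ranking.

Cross-dimensional stability (`stability_compare`) then asks whether a
finding in one dimensionality of a model (say 50d) survives in its 200d and
300d siblings, using Kendall rank correlation computed by explicit pair
counting, top-1 agreement, and coordinate-sign agreement.

## Scoring and normalization choices

**All similarities are cosines on unit vectors.** Readers return vectors
as-is; every audit requires `unit_normalize()` first and fails with a clear
error otherwise. The cosine of a term with itself is 1, the anchor of the
similarity scale; scores live in [−1, 1].

**Case-variant combination.** Mixed-case vocabularies carry near-duplicate
tokens ("Teenager"/"teenager"). `resolve_term_vector` combines the variants
of one label as the arithmetic mean of their unit vectors, renormalized.
The mean is the symmetric, order-free choice; because other combination
rules exist, the rule is recorded in every audit's metadata so score
differences against other toolchains are explainable. Missing variants are
skipped and logged; only a label with no variant in the vocabulary at all
is an error. GloVe vocabularies are lowercase-only while word2vec is
mixed-case, so partial variant coverage is the normal case.

**Two readings of a printed similarity score.** For an analogy table there
are two defensible meanings of the score column: the 3CosAdd value (cosine
between candidate and the renormalized query q) and the pairwise cosine
between candidate and v(w3) alone. Published audit tables do not always say
which they print. embaudit retrieves by 3CosAdd always and exposes both
scores behind `score_rule = c("3cosadd", "pairwise")`; the rule in force is
stored in the table metadata. The default is 3CosAdd, the standard analogy
completion score.

**Candidate pools and exclusion.** `exclude_inputs` defaults on: an analogy
answered by one of its own query words is vacuous, and published analogy
tables never return a query word. With a restriction lexicon, each entry is
resolved to one pooled vector and the entry's canonical name is what the
ranking returns. Ties are broken lexicographically (C locale) so outputs
are identical across platforms and reruns.

**Axis coordinate rule.** Plotting conventions behind published embedding
"bias graphs" are rarely stated. The difference-of-cosines rule used here
is symmetric in the poles, scale-free, antisymmetric under pole swap, and
bounded in [−2, 2]; it reproduces "closer to safe than to dangerous"
semantics directly and is recorded in every coordinate table and manifest.
An axis whose two poles are the same concept pair (a suicide↔healthy axis
on both X and Y) is treated as a 1-D gradient, which is what
`gradient_rank` computes. Rendering (`plot_placements`) is presentation
only; the coordinate table is the canonical artifact.

**Kendall tau by pair counting.** `kendall_pair_tau` is tau-a from explicit
enumeration of concordant and discordant pairs, with no tie or continuity
correction — exact on the short term lists these audits compare (typically
6–12 terms). `stability_compare` reports tau, top-1 agreement and
sign agreement against the first (reference) result set and deliberately
does not declare a single "consistent / not consistent" threshold: the
three metrics answer different questions and are reported side by side.

## File dialects

Two embedding dialects are supported, matching the files the common
pre-trained models ship in:

* **GloVe text**: headerless, one token plus d numeric fields per line,
  whitespace-separated; dimension inferred from the first line and enforced
  thereafter (violations name the offending line).
* **word2vec binary**: ASCII header "vocab_size dim", then per record the
  token bytes, one space, and d little-endian 32-bit floats; the original C
  tool's trailing newline between records is tolerated.

Both readers preserve file order, replace undecodable bytes (UTF-8 with
substitution, logged), and treat a duplicate token as a hard error — a
silent last-wins overwrite could change an audit result without trace.
Writers refuse tokens containing whitespace, which neither dialect can
represent. Round-tripping is exact for the text dialect (17 significant
digits) and exact at 32-bit float precision for the binary one. Note that
some distribution channels pre-normalize vectors; the manifest records
which normalization embaudit applied so results can be compared across
toolchains.

## Shipped lexicons

`default_lexicon()` provides editable label sets for gender, race,
nationality/ethnicity, religion, age and sexuality in census-style
vocabulary, plus gendered family terms, the pole words used by the axis
examples, and a psychiatric diagnosis list. The diagnosis file
(`diagnoses_dsm5_reconstructed.txt`) is a **best-effort reconstruction**
of a DSM-5-derived term list assembled from commonly audited categories and
their vocabulary phrase forms; it is not an authoritative clinical
ontology, and any serious audit should substitute a curated list. Because
every result is lexicon-dependent, audits record the MD5 hash of each
lexicon file used. The shipped vocabulary is Standard-American-English
census terminology; idioms of distress from other cultures and communities
are absent, which bounds what any audit built on these defaults can see.

## The synthetic planted-bias generator

Real pre-trained embeddings are multi-gigabyte downloads, so the test
surface is built on `generate_planted_space()`: a synthetic embedding space
whose bias structure is known exactly.

Construction, given `plant_config(dim, n_groups, n_diagnoses, n_background,
bias_magnitude, noise_sd, case_variant_rate, seed)`:

1. One base direction per group, per diagnosis, and for the two gradient
   poles, drawn as standard normal vectors and **orthonormalized by QR**
   (hence `dim` must be at least `n_groups + n_diagnoses + 2`). With merely
   near-orthogonal random directions, a non-target diagnosis can outscore
   the planted one by chance even with zero noise (at 50 dimensions the
   residual cosines have standard deviation ≈ 1/√50 ≈ 0.14, comparable to
   the planted signal); exact orthogonality makes noise-free recovery a
   theorem rather than a probability, which is what a ground-truth fixture
   is for. Noise then perturbs the geometry realistically.
2. Each group is assigned a diagnosis cyclically; its vector is its own
   direction displaced by `bias_magnitude` along the assigned diagnosis
   direction. This emulates the asserted structure of biased spaces: each
   demographic label has a systematically nearest diagnosis.
3. Eight gradient terms are laid out at evenly spaced convex mixtures of
   the two pole directions, so the planted gradient ordering is known.
4. Isotropic Gaussian noise (`noise_sd`, per component) is added to every
   vector; `n_background` filler tokens are random unit vectors.
5. A fraction `case_variant_rate` of tokens gains a capitalized noisy
   duplicate, exercising case-variant resolution the way mixed-case
   vocabularies do.

All randomness comes from one stream seeded by `seed`; the global RNG state
is restored afterwards. Equal seeds give bit-identical spaces.

Defaults are dim 50 (the smallest common GloVe release), 6 groups and 12
diagnoses (the scale of one published audit table), bias 0.5 and noise 0.1
(signal comfortably above noise but not degenerate: nearest-diagnosis
recovery sits near 0.9, analogy recovery near 0.6), 100 background tokens
(filler dominates planted terms, as in real vocabularies) and case-variant
rate 0.3 (mixed- and single-case tokens coexist).

**What the generator does not emulate**: Zipfian frequencies, co-occurrence
training dynamics, polysemy, phrase segmentation artifacts, or the
correlated (non-isotropic) noise of real corpora. Passing recovery tests on
planted spaces validates the *measurement pipeline* — that the audit finds
structure that is present and finds nothing when none is planted — not any
claim about what real embeddings contain. Audits of real models remain
conditional on the released files and the lexicons supplied.

`recovery_metrics()` scores an audit against the planted truth with top-1
accuracy and mean reciprocal rank; a truth term missing from a ranking
contributes 0 to the MRR, so an MRR of 1 means every planted diagnosis was
ranked first.

## Numerical and degenerate-input choices

* Zero vectors cannot be normalized or compared; they raise a
  degenerate-vector error naming the term rather than propagating NaN.
* Cosines are clamped to [−1, 1] after computation to absorb float
  round-off at the boundaries.
* Rankings sort by score descending with lexicographic (C-locale radix)
  tie-break; reruns and platforms agree byte-for-byte.
* An analogy with w1 = w3 collapses algebraically to v(w2): with exclusion
  off it returns w2 at score 1, a useful self-check.
* Duplicate tokens in files and duplicate canonicals in lexicons are hard
  errors, not last-wins.

## Problem sizes in the test suite

The suite validates oracle equivalence (rankings equal exhaustive full-scan
sorts) on a ~9,900-term vocabulary at depth 50; noise-free recovery on 100
seeded planted spaces; monotone degradation on a 5-point noise grid
(0–0.4, 40 seeds per point); round-trip fidelity on 1,000-term sets in both
dialects; and pair-counting exactness on all 576 ordered pairs of 4-term
permutations. These sizes exercise every code path at comfortable margins
while keeping the default test run in the tens of seconds.

## Limitations

* The audits measure geometry, not statistical significance. Significance
  frameworks such as WEAT answer a different, narrower question and are out
  of scope here by design.
* Results are only as meaningful as the lexicons: the shipped diagnosis
  list is a reconstruction, and all shipped label sets are
  census-style English.
* Loading is whole-file and in-memory (a vocabulary filter on load is
  available); memory-mapped access to multi-gigabyte files is out of scope.
* The score-rule ambiguity above means numeric score columns from other
  tools are comparable only once their rule is known; rankings are robust
  to the choice.
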