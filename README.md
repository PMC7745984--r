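# embaudit

Bias audits of word embeddings for mental-health terminology.

Pre-trained word embeddings (GloVe, word2vec) underlie many clinical NLP
systems for mental health. Because embeddings are trained on web and news
text, they can encode associations between demographic labels (*woman*,
*irish*, *queer*, *teenager*) and psychiatric vocabulary (*alcoholism*,
*perinatal_depression*, *substance_abuse*). Any model consuming the vectors
inherits these associations. embaudit is a toolkit for clinicians and data
scientists to measure them, three ways:

* **Analogy probes** — "w1 is to w2 as w3 is to ?", completed by the
  3CosAdd rule: candidates ranked by cosine similarity to the renormalized
  query vector **q** = v(w2) − v(w1) + v(w3). Scores are cosines in
  [−1, 1]; a term scores 1 against itself.
* **Nearest-diagnosis audits** — for each demographic label, rank every
  entry of a DSM-5-derived diagnosis lexicon by cosine similarity to the
  label's vector (candidates restricted to the lexicon).
* **Pole-axis placements** — a pair of opposing words (*safe*/*dangerous*,
  *he*/*she*, *suicide*/*healthy*) defines a semantic axis; each term gets
  the coordinate cos(term, pole_high) − cos(term, pole_low). Two axes give
  a 2-D placement, one axis a 1-D gradient ranking. Cross-dimensional
  stability is scored by pair-counted Kendall rank correlation, top-1
  agreement and sign agreement.

Case variants of a label ("Teenager"/"teenager") are combined as the
renormalized mean of their unit vectors. Both common embedding file
dialects are read and written (GloVe plain text; word2vec binary with
little-endian 32-bit floats). A synthetic generator plants known
group-to-diagnosis bias into an embedding space so the whole pipeline is
testable against ground truth without multi-gigabyte downloads.

## Worked example

Generate a planted space (50 dimensions, 6 demographic groups, 12
diagnoses, bias magnitude 0.5, noise 0.1), audit it, and check recovery
against the planted truth:

```r
library(embaudit)

sp <- generate_planted_space(plant_config(noise_sd = 0.1, seed = 42))
es <- unit_normalize(sp$set)

aud <- batch_audit(es, sp$truth$groups, sp$truth$diagnoses, top_k = 3)
aud
#> <audit_table> nearest audit, 6 labels x top-3 (50d embedding)
#>    label rank         term      score
#>  group01    1 diagnosis_01 0.33876110
#>  group01    2 diagnosis_06 0.22756531
#>  group01    3 diagnosis_04 0.07363226
#>  group02    1 diagnosis_02 0.37509020
#>  ...

recovery_metrics(sp, aud)
#> $top1
#> [1] 0.8333333
#> $mrr
#> [1] 0.8888889
```

The generator planted `diagnosis_01` on `group01`, `diagnosis_02` on
`group02`, and so on; at this noise level 5 of the 6 labels still rank
their planted diagnosis first (top-1 accuracy 0.83), and the mean
reciprocal rank of the planted diagnosis is 0.89. An analogy probe on the
same space ("diagnosis_01 is to group01 as group02 is to ?", restricted to
the diagnosis lexicon):

```r
pr <- sp$truth$probes[1, ]
analogy_query(es, pr$w1, pr$w2, pr$w3, restrict = sp$truth$diagnoses, top_k = 3)
#>           term     score
#> 1 diagnosis_02 0.2989670
#> 2 diagnosis_09 0.2376162
#> 3 diagnosis_06 0.2078953
```

The planted completion `diagnosis_02` comes back first. A gradient ranking
along the planted pole axis orders terms from the low pole to the high
pole:

```r
gradient_rank(es, sp$truth$gradient_terms, axis_spec("pole_low", "pole_high"))
#>      term coordinate
#> 1 grad_01 -0.8351029
#> 2 grad_02 -0.3571689
#> 3 grad_04 -0.3077463
#> ...
```

Real embeddings are audited the same way: read the file with
`read_glove_text()` or `read_word2vec_binary()`, `unit_normalize()`, and
use the shipped label lexicons (`default_lexicon("gender")`,
`default_lexicon("diagnoses")`, ...). `run_audit()` drives a whole audit —
analogy tables, nearest-diagnosis tables, axis coordinate tables,
stability reports and a manifest with file hashes — from one declarative
YAML config, and `inst/scripts/embaudit.R` wraps it for the shell.

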