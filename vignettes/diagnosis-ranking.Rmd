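---
title: "Ranking diagnoses with likelihood-ratio Naive Bayes variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking diagnoses with likelihood-ratio Naive Bayes variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxbayes)
```

## The model

A diagnosis corpus is a table of single-disease cases, each carrying an
ordered list of canonical symptom terms. Writing $N$ for the number of
records, $N(d)$, $N(s)$ and $N(d,s)$ for the per-disease, per-symptom and
cooccurrence record counts, the package estimates everything at the record
level (a symptom counts once per record, however often it was typed):

$$\hat P(s\mid d) = \frac{N(d,s)}{N(d)},\qquad
  \hat P(s) = \frac{N(s)}{N},\qquad
  \hat P(d) = \frac{N(d)}{N}.$$

Under conditional independence of symptoms given the disease, the
posterior factorises into per-symptom **likelihood-ratio operators**
$\mathrm{op}(s,d) = \hat P(s\mid d)/\hat P(s)$ times the prior:

$$P(d \mid s_1,\dots,s_n) \;=\;
  \prod_{i} \frac{\hat P(s_i\mid d)}{\hat P(s_i)} \cdot \hat P(d).$$

This ratio form is algebraically identical to the joint form
$\prod_i \hat P(s_i\mid d)\,\hat P(d) / \prod_i \hat P(s_i)$ — a property
the test suite checks to $10^{-12}$ relative tolerance — but it makes each
(disease, symptom) pair an independent feature whose operator can be
patched individually when the pair was never observed.

### The eight variants

Four treatments of the score are crossed with main-symptom weighting:

* **Empirical prior** (`prior`): the product above, as written.
* **No prior** (`noprior`): the product of operators alone. Dividing both
  sides by $\hat P(d)$ reads the score as the *rate of change* from prior
  to posterior, which sidesteps the prior-imbalance problem at the cost of
  ignoring base rates entirely.
* **Log form** (`log`): $\sum_i \log \mathrm{op}(s_i,d) + \log\hat P(d)$.
  Monotone in the product score, so rankings agree wherever the product
  does not underflow; it exists because products of many small ratios do
  underflow on long symptom lists. The product branch is deliberately
  computed as a literal product — the log branch is the numerically safe
  one, and keeping the product literal preserves that distinction.
* **Equal probability** (`uniform`): every disease gets prior $1/|D|$,
  *and* the symptom marginal is recomputed as the uniform mixture
  $$\hat P_u(s) = \frac{1}{|D|}\sum_d \hat P(s\mid d),$$
  which is exactly the marginal a corpus oversampled to equal class sizes
  would induce. We compute this analytically rather than physically
  replicating records: the analytic form is the exact, deterministic limit
  of that oversampling, and `oversample_balanced()` (which replicates each
  class to the least common multiple of the class counts) exists precisely
  so a test can confirm the identity on small corpora. Note it is the
  changed *denominator*, not just the constant prior, that makes this
  variant rank differently from the no-prior variant.

**Smoothing.** When $N(d,s) = 0$ the operator is replaced by
$$\mathrm{op}_\alpha(s,d) = \frac{\alpha/(N(d)+\alpha|V|)}{\hat P(s)},$$
with $|V|$ the vocabulary size and $\alpha = 1$ by default: add-$\alpha$
on the conditional count, applied *only* to non-cooccurring pairs —
cooccurring pairs keep their unsmoothed maximum-likelihood estimate. The
smoothed value is strictly positive and, at realistic counts, far below
any cooccurring operator for the same symptom, so unseen pairs demote a
candidate without eliminating it. One consequence worth knowing: the
smoothed operator shrinks as the corpus grows (more data is stronger
evidence against the pair), so scores that involve smoothed pairs are not
invariant to duplicating the corpus, while every score built purely from
cooccurring pairs is exactly count-scale invariant. The tests assert both
halves of that statement.

**Main-symptom weighting.** Clinically, the first three symptoms entered
are the chief complaints. When weighting is on, the operator of each of
the first `n_main = 3` input symptoms is multiplied by a coefficient
`w` (> 1 to have an effect; default 2) *if* that symptom cooccurs with the
candidate disease — a candidate that has never been seen with the chief
complaint gets no bonus for it. In the log form the weight enters as
$\log(w\cdot\mathrm{op})$, i.e. multiplicatively before the log, matching
the product form; at $w = 1$ weighted and unweighted variants are
bitwise identical, and when every candidate cooccurs with all three main
symptoms the weighting rescales all scores by $w^3$ and cannot reorder
them. Both properties are tested. The coefficient itself is a judgement
call with no principled estimate here; it is exposed everywhere
(functions, CLI) rather than hidden.

**Candidates, ranking, ties.** Only diseases that cooccur with at least
one input symptom are scored; input terms never seen in training are
excluded from scoring and reported back (their marginal is zero, so their
operator is undefined — and in deployment unmatched entries are a known
accuracy risk). Ranking is by descending score with ties broken by
lexicographic disease label, so output is deterministic; the top
`top_k = 3` are recommended. Pairwise log-ratio comparisons between two
diseases are recovered as differences of per-disease log scores, so no
pairwise tournament is needed for $|D| > 2$.

## Corpus cleaning

Symptom strings are split on commas only — ASCII `,` and fullwidth `，` —
with tokens trimmed, empties dropped and duplicates removed keeping the
first occurrence (which preserves main-symptom positions). No dictionary
or statistical word segmentation and no fuzzy matching: term variants are
handled by an explicit synonym lexicon mapping surface forms to canonical
terms, looked up after case folding. Tokens absent from the lexicon are
kept as-is by default (`keep_raw`) because the system accepts
natural-language input; `drop_token` and `drop_record` policies are
available. Rows whose diagnosis field names more than one disease
(detected as a comma in that field) are excluded, as are records left
with no symptoms; every exclusion and unmapped token is tallied in the
ingest report rather than silently dropped.

## Evaluation protocol

`run_variant_grid()` evaluates all eight variants on the *same* stratified
k-fold split (default `k = 3`, covering the 2/3-train : 1/3-test ratio
each fold), so comparisons are paired. A test record is a hit when its
true disease appears anywhere in the top-3; records with an empty
candidate set count as misses and are reported separately. Pooled
(record-weighted) accuracy is the primary number, with per-fold values
alongside; pooling is chosen over fold-averaging so every record counts
equally, and with stratification plus shared folds the whole grid is
bit-for-bit reproducible from one seed. Stratification keeps rare classes
out of the zero-shot regime; it degrades to random assignment for classes
with fewer records than folds and can be disabled.

## The synthetic generator

Real corpora of this kind are private, so all empirical claims here rest
on generated ones. A generative spec fixes disease prevalences, a
per-disease Bernoulli emission profile, and up to three designated main
symptoms that are placed first in every record (the rest follow in random
order); records are redrawn if no symptom fires. Emissions are
independent per symptom — deliberately matching the classifier's own
assumption, so fitted conditionals have an exact target and parameter
recovery is a sharp test. A `coupling` knob mixes in record-level "flares"
that raise all of a disease's emissions together, inducing positive
pairwise correlation as a robustness probe; it defaults to off.

Two canned conditions cover the regimes that matter:

* `spec_separable()` — 20 equiprevalent diseases, each with two exclusive
  main symptoms at emission 0.9 plus three shared background symptoms at
  0.3. Every variant should essentially always rank the true disease in
  its top 3; the tests require ≥ 0.95 at n = 5000 under 3-fold CV.
* `spec_skewed()` — 20 diseases whose profiles are sliding windows (10
  symptoms, consecutive windows differing by one symptom) over a 30-term
  pool, with main emissions 0.6/0.5/0.4 and background 0.15; prevalence is
  a geometric ladder spanning 50:1, interleaved around the profile ring so
  every rare disease has common near-twins. This is the configuration in
  which the empirical prior visibly crowds rare diseases out of the top 3
  (rare-class hit accuracy drops from ~0.91 under the uniform prior to
  ~0.75 under the empirical prior at n = 5000) while the equal-probability
  treatment does not — and the tests assert exactly that ordering, along
  with the pooled ordering of the weighted equal-probability variant over
  the classic unweighted no-prior variant.

What passing these tests does *not* show: real symptom lists are not
conditionally independent given the disease, their length and noise
structure differ from Bernoulli profiles, and free-text entry introduces
unmatched terms the generator never produces. The synthetic results
validate the machinery and the direction of the prior/weighting effects,
not clinical accuracy levels.

## Numerical and design notes

* Problem sizes in the test suite — 200 random small models for the
  formula-equivalence sweep, exhaustive symptom subsets on models with up
  to 4 diseases and 6 symptoms against a literal brute-force scorer, and
  n = 5000, D = 20 corpora for the cross-validated properties — keep the
  whole suite in the low minutes while leaving each assertion several
  standard errors of headroom.
* Parameter-recovery is asserted on disjoint profiles with emissions at
  0.95, where the 0.05 absolute band is > 3.5 binomial standard errors at
  ~250 records per class; at mid-range emissions the same band would sit
  inside ordinary sampling noise and assert nothing.
* Scores from the vectorised kernel and from a literal re-derivation can
  differ in the last couple of ulps; ranking comparisons in the tests
  therefore treat scores equal within $10^{-9}$ relative as ties.
* The model serialises to JSON as integer counts only, so a round trip is
  exact and a served model reproduces training-time scores bitwise.
* Degenerate inputs: an empty corpus or an all-unknown symptom list fail
  loudly (error and `no_candidates` status respectively); duplicate
  symptoms in one record collapse to first occurrence by design, since the
  event model is presence/absence.

## A complete run

```{r example, eval = FALSE}
corpus <- sample_corpus(spec_skewed(), 5000, seed = 1)
grid <- run_variant_grid(corpus, nb_variants(), k = 3, seed = 1)
grid[, c("variant", "accuracy", "n_no_candidate")]
autoplot(grid)
```
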