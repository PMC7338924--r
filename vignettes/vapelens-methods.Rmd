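---
title: "Methods: from keyword taxonomies to co-mention GEEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from keyword taxonomies to co-mention GEEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vapelens studies how e-cigarette users talk about e-liquid flavors and
health symptoms in social-media posts. This vignette explains each stage's
model and assumptions, the parameters that matter, what the synthetic
corpus does and does not emulate, and the numerical choices behind the
implementation.

## Corpus construction

Posts (id, author, UTC timestamp, text) are filtered by a keyword taxonomy:
an e-cigarette term list (20 spelling variants such as "vape", "e-juice",
"juul"), 9 health-symptom categories (Respiratory, Cardiovascular,
Neurological, Psychological, Digestive, Mouth, Throat, Cancer, Other) and 7
flavor categories (Fruit, Menthol or Mint, Tobacco, Sweet, Beverage, Mixed,
Other). Matching is case-insensitive on token boundaries; multi-word
keywords match as contiguous token sequences, and at overlapping character
spans the longest keyword wins, so "sore throat" suppresses a separate
"throat" hit and nothing is double counted. Hyphens inside keywords are
literal: "e-juice" and "ejuice" are distinct list entries, mirroring how
such lists enumerate variants explicitly.

Sentences are split at ".", "!", "?" followed by whitespace, and at
newlines -- a deliberately simple rule, because the only sentence-level
operation is disambiguation. Ambiguous keywords carry sentence-scope
context rules: "tobacco" names both a flavor and the plant, so a tobacco
hit survives only when its sentence also contains a flavor-context word
("flavor", "e-liquid", ...). The context list is configuration, not code,
because it is corpus-dependent. URLs and e-mail addresses are stripped, and
a pluggable language filter (default: at least half of the tokens
ASCII-alphabetic) drops non-English posts. Titles and bodies are
concatenated before matching.

`audit_filter_precision()` reproduces the manual audit workflow: a seeded
sample of posts per keyword with the matching sentences highlighted, and
precision = true positives / sample size once labels are supplied.

## Frequent itemset mining

Keyword lists never start complete; `mine_frequent_itemsets()` proposes
conversational variants by mining token-set transactions (one per post,
deduplicated, stopword-free) with Apriori over a vertical transaction-id
layout. Candidate (k+1)-sets are joined from frequent k-sets sharing a
prefix and pruned by downward closure, so the output is exactly the set of
itemsets with support at or above the threshold -- a property the tests
verify against exhaustive enumeration on small corpora. `min_support` is an
absolute count (or a fraction), `max_size` defaults to 3: beyond trigrams
the combinations stop being reviewable. Candidates co-occurring with a seed
keyword are ranked by best co-itemset support for manual review;
the pipeline never auto-appends them to a taxonomy.

## Temporal trends

`monthly_counts()` counts each post once per mentioned category per UTC
calendar month (timestamps are UTC epoch seconds), with empty months kept
at zero so series are contiguous; `normalize_series()` divides by the total
e-cigarette post volume of the month, returning missing (never zero) for
empty months. `category_share()` turns counts into two-decimal
percentages. Published tables mix display conventions -- 0.9775% can be
printed as 0.97 (truncated) while 28.058% is printed as 28.06 (rounded) --
so both modes are supported; rounding is the default and truncation is one
flag away. Counting posts versus counting keyword mentions is a choice the
caller makes through the category-assignment table it passes in.

## Sentiment

Scoring is lexicon-based. Health keywords carry intrinsic negative valence
("headache", "cancer"), which would contaminate opinion measurement, so
every valenced health keyword is first replaced by the neutral placeholder
"X" (`neutralize_keywords()`, idempotent, multi-word keywords as units).
By default only keywords that actually carry valence in the scoring
lexicon are neutralized; a flag widens this to all health keywords. The
score of a text is the sum s of its lexicon hits -- a negator within the
three preceding tokens flips a hit's sign, and optional boosters add
ALL-CAPS and exclamation emphasis -- normalized to s / sqrt(s^2 + 15),
the standard compound-score squashing to (-1, 1). The scorer is a bundled,
hermetic implementation of that design; any drop-in `text -> score`
backend (e.g. a binding to the reference VADER implementation, whose
normalization constant and negation window it shares) can replace it.

Propensity discretizes the score: positive at or above +0.05, negative at
or below -0.05, neutral strictly between. Per health category the positive
and negative proportions are compared with a pooled two-proportion z-test
(no continuity correction; its square is the 1-df chi-square statistic),
Bonferroni-adjusted across the categories tested. The two proportions come
from the same post set, so the independent-samples test is an
approximation; it is used deliberately, for fidelity with common practice,
and flagged here. The Bonferroni multiplicity defaults to the number of
categories summarized (nine for the full taxonomy) and can be fixed
explicitly.

## Topic modeling

Preprocessing lowercases, tokenizes, lemmatizes (a pluggable token-to-stem
map; the bundled suffix stripper keeps tests dependency-free) and removes
stopwords. Frequent adjacent pairs are merged into single underscore terms
with the count-based phrase score
`(count(a,b) - min_count) * V / (count(a) * count(b)) > threshold`
(V = vocabulary size), greedily left-to-right; a second pass builds
trigrams from merged bigrams, so "throat hit" and "food drug
administration" become single model terms. Defaults `min_count = 20`,
`threshold = 10` suit corpora of tens of thousands of posts; small test
corpora need lower thresholds because V is small.

LDA is fit by collapsed Gibbs sampling, implemented in C++ for speed: each
token's topic is resampled from
`p(z = k) ~ (n_dk + alpha)(n_kw + beta) / (n_k + V beta)` with the token's
own counts removed. Draws use R's RNG, so a seed makes runs
bit-reproducible. Defaults are `alpha = 50/K`, `beta = 0.01` and 1000
sweeps, the common collapsed-Gibbs settings; K is corpus-dependent (the
desk-scale pipeline default is 10; a 100-topic fit matches a "top 100
topics" reading). Because the sampler scans tokens sequentially, permuting
document order changes which random numbers hit which tokens: seeded runs
are reproducible, but only for a fixed document order. Count conservation
and row-normalization of the derived theta and phi are tested invariants,
and a planted two-block corpus must be recovered with best-match cosine
above 0.9.

Topic labeling (flavor / health / other by keyword hits among the top
terms, flavor winning ties) is a reproducible proxy for what is inherently
a manual judgment, and is documented as such.

## Co-mention GEE

The association unit is the entry: a post with exactly one distinct flavor
keyword and at least one health keyword contributes one entry per distinct
health keyword, carrying its user id. For each modeled health category h,
the outcome is y = 1 if the entry's category equals h. The source study
never states the GEE response variable; this indicator construction is the
package's own definition, chosen because the per-flavor probabilities it
yields sum to one across exhaustive categories and match the magnitudes of
published heatmaps. It is the most consequential modeling decision in the
package and is therefore stated prominently here: the estimated
"co-mention probability" is P(health category = h | flavor, entry), not
P(flavor and h co-mentioned | post).

The design is a cell-means (no-intercept) indicator over flavor levels, so
the inverse-logit of each coefficient is directly that flavor's
probability. Coefficients solve the estimating equations
`sum_i D_i' V_i^-1 (y_i - mu_i) = 0` with logit link,
`V_i = phi A_i^{1/2} R(alpha) A_i^{1/2}` and exchangeable
(compound-symmetry) R; alpha and phi are moment estimates from Pearson
residuals, re-computed each Fisher-scoring step, with alpha truncated to
the feasibility bound `(-1/(max n_i - 1), 1)`. The exchangeable inverse is
applied in closed form (`R^-1 = (I - cJ)/(1 - alpha)` with
`c = alpha / (1 + (n_i - 1) alpha)`), so no per-cluster matrices are built
and a 6000-entry fit takes tens of milliseconds. Iterations start at the
independence solution (closed-form cell means) and stop when the largest
coefficient change drops below 1e-8 (cap 100). Inference uses the sandwich
covariance B^-1 M B^-1. Flavors whose outcome is constant (empirical cell
mean 0 or 1) have divergent coefficients; they are flagged as boundary,
reported as probability 0/1 without a standard error, and excluded from
the scoring iterations. Flavor levels below a configurable entry count
(default 10) are excluded entirely -- the small-sample exclusion that
leaves a reduced flavor-by-health heatmap.

Pairwise flavor contrasts within a health category use
z = (beta_a - beta_b)/se from the sandwich covariance and the single-step
Tukey adjustment `p_adj = P(Q_{k, Inf} >= |z| sqrt(2))`. The studentized
range is taken at infinite degrees of freedom because GEE inference is
asymptotic -- there is no natural finite error df -- and at k = 2 this
reproduces the unadjusted two-sided normal p-value exactly, a tested
identity.

## The synthetic corpus

The generator emulates the statistical structure the analysis assumes:
user-clustered posts (Poisson post counts), a monthly volume trend
(default: linear three-fold growth over a January 2013 to April 2019
window, echoing the steady growth of vaping discussions), configurable
flavor frequencies, a co-mention matrix P(health | flavor) whose row
remainder is the no-mention probability, per-category sentiment mixes
(positive-dominant everywhere except a Cancer-style negative-dominant
mix), and template text that embeds exactly one flavor keyword, an
e-cigarette term and the word "flavor" per post -- so the corpus filter
and the tobacco rule pass by construction, and a contamination option
injects second flavor keywords to exercise the one-flavor exclusion.

Within-user correlation comes from logit-normal user effects. Each user
draws an independent effect per health category; the conditional row is
perturbed on the logit scale and renormalized. A single shared effect
would largely cancel under renormalization (measured: correlation under
0.04 even at sd 1.5), so per-category effects are used, giving
within-user correlation around 0.13 at sd 1.5. Because the GEE estimates
population-averaged probabilities, the generator calibrates the per-row
intercepts by a fixed quasi-Monte-Carlo expectation and a fixed-point
update so that the marginal row equals the planted row for any effect sd.
That makes "the GEE recovers the planted matrix" a well-posed statement;
recovery bias stays under 0.02 at 2000 users over 50 replicates, and the
calibration itself is deterministic.

Default study conditions: six flavors with frequencies (Fruit .28,
Menthol or Mint .17, Tobacco .10, Sweet .22, Beverage .10, Mixed .13),
six health categories per flavor with Throat and Respiratory dominant
(magnitudes modeled on published flavor-health heatmaps), an overall
health-mention rate of 0.6 per flavor post (higher than a raw platform
rate, deliberately, so desk-scale corpora yield thousands of entries),
and user effect sd 0.5. All draws flow from one integer seed;
regeneration is byte-identical.

What the generator does not emulate: real linguistic variety (template
text), subreddit structure, topic drift, event-driven spikes beyond the
volume multiplier, typos, or the long-tailed flavor vocabulary of real
e-liquid markets. Passing tests therefore demonstrate that the pipeline's
statistics are implemented correctly under the assumed structure -- not
that the keyword lists or sentiment lexicon would be adequate for any
particular real corpus.

## Problem sizes and runtimes

The default test and acceptance runs use corpora of roughly 10,000 posts
(2500 users), GEE recovery at 2000 users times 3 entries over 50
replicates per effect-sd setting, and LDA recovery on 500 documents with a
40-term vocabulary -- sizes chosen so the whole suite runs in a few
minutes on one CPU while keeping Monte-Carlo error well inside the stated
tolerances.

## Known limitations

- The positive-vs-negative proportion test ignores the shared denominator
  (see above); a paired or multinomial test would be more exact.
- The bundled lexicon and taxonomies are miniatures for hermetic testing;
  real analyses should supply full keyword appendices and a full valence
  lexicon through the same readers.
- `label_topics()` is a keyword-count proxy for manual labeling.
- The GEE implementation supports independence and exchangeable working
  correlations only, matching the analysis design; no covariate
  adjustment is offered because post metadata (age, device, nicotine
  strength) is unavailable in this setting.
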