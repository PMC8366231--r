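---
title: "Modeling word durations with linear discriminative learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling word durations with linear discriminative learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

Linear discriminative learning (LDL) represents a speaker's lexicon as a
pair of linear mappings between word forms and word meanings. Forms live
in a binary cue space: each word's transcription is padded with a boundary
symbol and decomposed into overlapping triphones, and the cue matrix $C$
codes which triphones occur in which word. Meanings live in a real-valued
lexome space: each word (and each derivational function, such as NESS) is
a pointer to a semantic vector, and the semantic matrix $S$ stacks the
word vectors. Comprehension is the least-squares map $F$ with
$CF \approx S$; production is the map $G$ with $SG \approx C$. Both are
solved with the Moore–Penrose generalized inverse, so $\hat S = CF$ and
$\hat C = SG$ are the model's predicted meanings and forms.

A derived word's meaning can be composed in three ways, giving three
network architectures:

* **idiosyncratic** — the derivative's own vector, no category
  information;
* **morphology** — the derivative's vector plus the function vector of
  its category (idiosyncratic and shared meaning);
* **base** — the base word's vector plus the function vector (strictly
  compositional, no idiosyncrasy).

From a fitted network, five per-word measures serve as duration
predictors. A word's *articulatory path* is its own triphone sequence;
each node's *support* is its predicted cue activation (negatives clamped
to zero) normalized over all cues sharing its two-symbol left context, so
supports are selection probabilities bounded by 1. **Path sum** adds the
supports; **mean word support** divides by path length (a certainty
measure that does not grow with word length); **path entropies** is the
Shannon entropy, in bits, of the supports normalized to probabilities (an
uncertainty measure). **Semantic vector length** is the L1 norm of
$\hat s$ (activation diversity); **semantic density** is the mean
correlation of $\hat s$ with its top-8 neighbors (a transparency proxy);
**target correlation** is $\mathrm{cor}(\hat s, s)$.

The response is not raw duration: observed durations are regressed on
*baseline duration* (the sum of corpus-mean segment durations), and the
residual — the **duration difference** — is what the measures predict,
together with speech rate as the one non-network covariate. Models are
ordinary least squares and, restricted to word types observed more than
once, linear mixed models with a random intercept per type (REML,
Satterthwaite p-values). Observations with residuals beyond 2.5 SD are
removed once and the model refit; non-significant terms are then
eliminated stepwise at $\alpha = 0.05$, highest p first, with speech rate
never eligible. Explained variance is decomposed with the lmg metric
(incremental $R^2$ averaged over all orderings of predictor entry; for
mixed models, on the marginal $R^2$ of refitted submodels).

```{r pipeline}
library(ldldur)
study <- ldl_study(seed = 1)
glance(study$networks$morphology)
fit <- run_duration_analysis(study$tokens, kind = "standard")
tidy(fit)
lmg_importance(fit)
```

## What the generator emulates

Real inputs for this analysis (conversational speech recordings,
corpus-trained lexome vectors, dictionary transcriptions) are not
desk-scale, so the package ships a generator that emulates their
statistical structure with known ground truth. Its defaults are the
package's fixed study conditions:

* **Lexicon.** 60 monomorphemic bases (random consonant–vowel
  alternating strings of 3–6 phones over a DISC-like alphabet) plus five
  derivational categories of 40 types each — DIS as a prefix, NESS,
  LESS, ATION, IZE as suffixes — formed by concatenation. Bases are
  always simplex, so multi-affix derivatives never arise.
* **Semantic vectors.** 100 dimensions (a desk-scale stand-in for the
  several-thousand-dimensional corpus spaces). Content vectors are
  i.i.d. normal per dimension with sd $1/\sqrt{D}$, giving unit-order
  norms; this is a modeling choice, not a claim about empirical vector
  distributions, whose form corpus studies do not report. Each category
  has an independent shift vector; a derivative's vector is base +
  shift + idiosyncratic noise with per-dimension sd
  `transparency_sd` $\times 1/\sqrt D$ (default 0.5). Shift scales
  (LESS 2.1, DIS 1.7, NESS 1.3, IZE 0.9, ATION 0.5) are deliberately
  well separated, emulating the markedly different semantic-transparency
  profiles these affix classes show in corpus-trained spaces, where all
  pairwise per-category density contrasts separate sharply.
* **Durations.** Segment means are log-normal around 70 ms (a plausible
  spread for speech segments); baseline duration is their sum. Token
  counts per type are zero-truncated geometric with success probability
  0.3, reproducing a hapax share near 30% as in conversational corpus
  samples, so the mixed-model type filter has something to do. Observed
  duration is `intercept + baseline + 150 * mean_word_support -
  30 * path_entropies - 5 * semantic_vector_length - 20 * speech_rate`
  plus Gaussian noise (sd 20 ms), with speech rate drawn per token from
  N(5, 1) syllables/s. The coefficient signs follow the directional
  findings the measures were designed to test (certainty lengthens,
  uncertainty and activation diversity shorten); the magnitudes are set
  so that each effect is clearly detectable at the simulated size
  (roughly 900 tokens), as a parameter-recovery study requires.
  Non-positive durations are redrawn (durations are physical).

```{r generator}
lex <- generate_lexicon(60, default_affixes(40), seed = 1)
store <- generate_vector_store(lex, dimension = 100, seed = 2)
cue <- build_cue_matrix(lex)
net <- ldl_network(cue, build_semantic_matrix(lex, store, "morphology"))
measures <- ldl_measures(net, lexicon = lex)
```

## What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes —
overlapping cues, additive category semantics, category-graded
transparency, hapax-rich token counts, a known linear duration model —
but not everything corpus data does:

* At the default size (260 words, far fewer words than cues) the cue
  matrix generically has full row rank and the comprehension mapping
  interpolates exactly: accuracies are 1.0 and every target correlation
  is 1. Realistic lexicons (thousands of words, shared cue structure)
  sit in the over-determined regime where accuracies drop into the
  80–99% range; the package's accuracy machinery is exercised in that
  regime with over-determined random networks in the tests.
* Because the generator builds derivative vectors *additively*
  (base + shift + noise), the three architectures' matrices are all
  strongly correlated with one another: the idiosyncratic space cannot
  drift far from the morphology space when the idiosyncratic vector
  contains the composed meaning by construction. Corpus-trained
  derivative vectors are not additive compositions, which is why
  empirical studies find near-zero correlations between the
  idiosyncratic and category-aware predicted spaces. At
  `transparency_sd = 0` the idiosyncratic and base matrices coincide
  exactly — a useful algebraic check, but a regime where the contrast
  between those architectures vanishes.
* The Gaussian vector geometry has no "hub" words (words with
  degenerate norms or aligned neighborhoods), so the neighbor-collapse
  phenomenon reported for the base architecture on corpus vectors (the
  same few types appearing as everyone's nearest neighbors) has no
  analog here; what does carry over is that category-aware networks
  draw far more of a word's top-8 neighbors from its own category.
* Mean semantic density still orders idiosyncratic < morphology, and
  per-category density distributions separate sharply even in the
  idiosyncratic network — the category-emergence phenomenon — because
  category shifts leak into derivative vectors.

## Numerical and design choices

* **Pseudoinverse.** SVD with relative cutoff
  $\varepsilon \cdot \max(m, n) \cdot \sigma_{\max}$, machine precision
  $\varepsilon$ — the standard stable rank treatment.
* **Accuracy ties.** A word is correct only if its own target is the
  *unique* correlation argmax (tolerance $10^{-12}$); ties are counted
  and scored incorrect, keeping evaluation deterministic.
* **Negative activations.** Clamped to zero before support
  normalization, so supports are probabilities in $[0, 1]$; a
  competitor set with no positive activation yields support 0, and an
  all-zero path is flagged missing rather than given an entropy.
* **Path-length divisor.** Mean word support divides by the number of
  path *nodes* by default; the worked account of path sums counts
  *transitions*, so the divisor is switchable (`divisor =
  "transitions"`). For a word of $n$ phones these differ by
  $n/(n-1)$.
* **Entropy base.** Log base 2 (bits); any base only rescales
  regression coefficients.
* **Neighbors.** Semantic density and neighbor reports use the
  predicted matrix $\hat S$ by default (the measure is defined on
  $\hat s$), with the target matrix available via `density_space =
  "target"`.
* **Trimming.** One pass after the initial fit, not iterated; removal
  of more than 20% of observations is treated as an error (suspect
  data). Note that trimming truncates the residual distribution and so
  shrinks the refit's error estimate by a few percent; downstream tests
  become slightly anti-conservative, which is why the package's type-I
  calibration of stepwise elimination is assessed on untrimmed fits.
* **Stepwise order.** Aliased (perfectly collinear) terms are discarded
  first, then the highest-p non-forced term at or above $\alpha$ is
  dropped and the model refit, repeatedly. The elimination order is
  recorded on the fit object.
* **Random effects.** Random intercept per word type only; the type
  filter (types observed more than once) is applied before fitting and
  the number of excluded hapax types is recorded. Marginal and
  conditional $R^2$ use the variance-components formulas (fixed-effect
  variance share, and fixed-plus-random share).
* **Recovery design.** The duration-difference construction removes
  baseline duration's own linear contribution from the response but not
  from the predictors; path-based measures correlate with word length
  and hence with baseline, so regressing the residual response on raw
  measures estimates something other than the generating coefficients.
  Parameter-recovery analyses therefore keep `baseline_duration` as a
  forced covariate in the second stage — by Frisch–Waugh–Lovell this
  makes the measure coefficients estimate exactly the generating ones —
  while the default analysis keeps the study's final-model shape
  (measures plus speech rate only).

## Problem sizes

The shipped tests and the acceptance script run the default study (260
words, 100 dimensions, roughly 900 tokens), a 200-word interpolation
check, 50 replicate studies for coefficient recovery, and 200 token
redraws for the null-retention calibration — sizes chosen so the whole
simulation battery re-runs comfortably on a laptop while keeping every
check well-powered.

## Known limitations

Phonotactics are only superficially realistic (consonant–vowel
alternation, no stress or syllable structure); vectors are Gaussian with
additive composition, which understates the idiosyncrasy of corpus
semantics; no speaker variable exists, so the mixed models' only
grouping factor is word type; and production is evaluated on the word's
own path (the model's production accuracy is near ceiling in all regimes
studied), not by graph search over candidate paths.
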