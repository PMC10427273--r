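---
title: "Inferring cultural transmission biases from lyric sentiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cultural transmission biases from lyric sentiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Chart lyrics have become more negative and less positive over the last
fifty years. Cultural evolution offers competing explanations framed as
*transmission biases* — heuristics governing whom and what people copy:

* **Success bias** — songwriters copy the best-selling songs; the lagged
  mean emotional word count of recent top-10 chart songs predicts today's
  lyrics.
* **Prestige bias** — songwriters copy high-status artists, operationalised
  as artists with more than 10 chart appearances.
* **Content bias** — negative content is intrinsically preferred; chart
  rank (1 = best-selling) predicts a song's negativity. This applies to
  negative valence only: there is experimental evidence for a negativity
  preference but none for a positivity one.
* **Unbiased transmission (drift)** — songwriters copy any recent song at
  random, so a word class spreads in proportion to its recent frequency,
  captured by the lagged mean count over *all* recent songs.

Each word of each song is classified against positive/negative emotion
lexicons as positive, negative or neither. Writing $k_i$ for the number of
positive (or, in separate models, negative) words among the $W_i$ words of
song $i$, the aggregated binomial multilevel model is

$$k_i \sim \mathrm{Binomial}(W_i, p_i), \qquad
\mathrm{logit}(p_i) = \alpha + a_{artist[i]} + a_{genre[i]} + a_{year[i]}
 + \sum_j \beta_j x_{ij},$$

with adaptively regularising varying intercepts
$a_g \sim \mathrm{Normal}(0, \sigma_g)$, $\sigma_g \sim \mathrm{Exponential}(1)$.
Aggregating words within songs is exactly equivalent to a per-word
Bernoulli regression up to the binomial coefficient, and it removes any
need to average over songs of different lengths. Candidate models are the
null (varying intercepts only), single-bias models, the full model, and
the full model plus the drift covariate; models are screened by WAIC but
inference rests on the full models' coefficients, because WAIC ordering is
unstable for time-series-structured data (the comparison report carries a
permanent warning to that effect). A slope "has an effect" when its 89%
equal-tailed credible interval excludes zero; a log-odds slope $\beta$
reads as a $100(e^\beta - 1)$ percent change in the odds of a word carrying
that valence.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window` | 3 years | lag window, strictly before the focal year |
| `top_k` | 10 | chart depth defining "successful" songs |
| `min_appearances` | 10 | strict threshold for prestige (`> 10` entries) |
| priors | N(0, 1.5), N(0, 1), Exp(1) | intercept, slopes, group sds |
| `ci_mass` | 0.89 | credible mass used in all summaries |
| `chains`, `iter`, `warmup` | 4 / 1000 / 500 | sampler defaults |

Covariates are the *raw* lagged mean per-song word counts (the source
wording says "average number of … words"); a proportion mode (`k/W`) is
available as a sensitivity switch because song length varies. By default
the design matrix is z-scored before fitting — the source does not state
its scaling, and standardisation stabilises sampling; a `fixed` mode
reuses externally supplied constants so that simulation and inference can
share one scale, and `none` disables scaling for sensitivity checks.
Success and prestige are always computed from the *chart* corpus, even
when the modelled corpus is the larger bag-of-words collection: charts
define success and prestige. The drift covariate comes from the modelled
corpus itself; whether the original analysis used the chart-only or the
larger pool for it is not stated, so the same-corpus pool is the default
and the function accepts any corpus.

## Sampling

No probabilistic-programming backend is assumed: the posterior is explored
with a self-contained Hamiltonian Monte Carlo sampler (compiled gradient,
leapfrog integrator, jittered path lengths of 24–48 steps, dual-averaging
step-size adaptation targeting 0.8 acceptance, diagonal mass matrix
estimated from the middle half of warmup and shrunk toward its median).
The long default trajectories matter: the intercept trades off against
the group-intercept means along a narrow diagonal valley that a diagonal
mass matrix cannot rotate away, and short paths leave the intercept's
effective sample size in the single digits. Parameterisation of the
varying intercepts is mixed, which is the reparameterisation these models
need for convergence: sparse factors (artists, mostly a song or two each)
are non-centred ($a_g = \sigma_g z_g$, $z_g \sim \mathrm N(0,1)$, the cure
for funnel geometry), while data-rich factors (year, genre; chosen
automatically when a factor averages more than 20 songs per level) are
centred, which mixes better when the likelihood dominates the prior.
Group sds are sampled on the log scale with the Jacobian included. The
compiled log-posterior gradient is cross-checked in the tests against an
independent plain-R implementation and against finite differences.
Convergence is checked by split-chain $\hat R$ (warn above 1.01) and an
effective-sample-size estimate (warn below 400). Fits are exactly
reproducible given a seed. Stored pointwise log-likelihoods include the
binomial-coefficient term, which shifts absolute WAIC values but cancels
in model differences; WAIC uses a stable log-sum-exp throughout.

## What the simulator emulates

`simulate_corpus()` generates the world the model assumes, so that the
entire pipeline — I/O, sentiment coding, covariate construction, fitting,
comparison — can be validated by parameter recovery with no downloads:

* yearly cohorts of 100 songs (charts), ~300 words per song (Poisson),
  matching the roughly 30,000 words a chart year carries;
* baseline positive/negative word shares of 5% and 2.5% — typical lexicon
  hit rates for lyrics;
* a Zipf artist population (1000 artists, exponent 1) calibrated so that
  roughly 3–4% of artists clear the `> 10` appearances prestige bar, the
  share reported for the real chart population;
* true slopes defaulting to 0.02–0.12 in absolute value, bracketing the
  published chart estimates;
* group sds (0.3 artist, 0.2 genre, 0.1 year) giving mild overdispersion;
* lagged covariates computed *through the inference code path itself*
  (`success_covariate()` etc.), so the generative covariates equal the
  rebuilt design exactly;
* ranks drawn as an exogenous per-year permutation that feeds the negative
  linear predictor. The alternative — assigning ranks from realised
  negativity — would make rank endogenous and the content-bias slope
  unidentifiable in recovery, so the causal arrow is fixed rank-to-lyrics
  in the generator.

Artist identities, ranks and song lengths are drawn before any words so
that the prestige roster is a fixed function of the artist assignment and
identical between generation and re-analysis. Burn-in years (equal to the
lag window by default) are generated from the baseline intercepts alone
and are dropped from analysis, mirroring the real pipeline discarding its
first window years. `simulate_neutral()` is the pure drift regime: each
year's valence probabilities equal the realised word-class frequencies of
the preceding window pool. It has no mutation, so a class that reaches
zero stays at zero, and drift variance shrinks as cohorts grow.

The simulator deliberately omits several features of real corpora:
vocabulary growth and semantic change, genre emergence, non-stationary
artist careers, correlated song lengths within artists, and any acoustic
properties. A green recovery test therefore establishes that *the
inference machinery recovers the generative process it assumes*, not that
real lyric dynamics satisfy those assumptions.

### Identifiability in the stated world

The success, prestige and drift covariates are all window means over
overlapping song pools, and in a chart-sized world they are correlated
above 0.95 at the year level — in 20 analysis years there is limited
independent variation to separate them. This is a property of the study
design, not of the implementation: it is the same confounding that makes
the real success and prestige effects collapse once drift is controlled.
Consequences for validation: the song-level content-bias slope is
recovered tightly; the individual year-level slopes carry wide
posteriors, and their posterior means are subject to prior shrinkage and
rotation noise, so recovery bias for them is assessed across replicates
and interpreted against that Monte-Carlo error.

The drift slope is the extreme case. What identifies each slope
*individually* is its idiosyncratic variation around the shared drift
signal, and that variation is the sampling noise of a window mean: large
for success (a 30-song mean), intermediate for prestige, and an order of
magnitude smaller for the all-songs drift covariate (a ~300-song mean).
In a faithful chart world the drift slope is therefore close to
unidentified: its posterior collapses to the prior-shrunk neighbourhood
of zero whether the true value is 0 or 0.12, so its recovery "bias" is
roughly minus the truth, and no correctly specified estimator escapes
this — the posteriors themselves are verified against long gold-standard
runs, and a null world (all slopes zero) recovers zero without spurious
bias. Frequentist coverage of Bayesian intervals at a fixed truth is
correspondingly below nominal for the year-level slopes. The recovery
suite reports these numbers honestly rather than hiding them; readers
should carry the same caution to real-data claims that drift "explains"
valence trends inferred from ~50 chart years.

## Numerical and design choices

* **Stemmer.** A self-contained Porter (1980) implementation with the two
  conventional departures (`bli->ble`, `logi->log`), verified against an
  independent reference implementation. The default variant adds one rule:
  words ending `-ily` drop the `ly` so that adverbs stem with their
  adjectives ("happily"/"happy"/"happiness" all give "happi", the
  behaviour the pipeline's data dialect documents); `porter-classic`
  switches it off.
* **English filter.** A song counts as English iff the stem "the" occurs —
  the documented heuristic of the source corpus. "the" is stem-invariant,
  so running the check before or after stemming is immaterial.
* **Artist clustering.** Fingerprint key collision (lowercase, strip
  accents/punctuation, collapse whitespace, sort tokens); the canonical
  form is the most frequent raw variant, ties broken lexicographically.
  Collaboration strings split on the standard separators; if every part is
  a known solo artist the parts are occasional collaborators (the song is
  attributed to the lead, i.e. first-listed, artist), otherwise the whole
  string is one stable-collaboration unit.
* **Lexicon wildcards.** A trailing `*` is a prefix pattern matched
  against stems; any overlap between the positive and negative sides,
  including prefix cones, is a load-time error rather than a silent
  priority rule. Proprietary dictionaries are never shipped; a small open
  placeholder (20 positive / 24 negative patterns) supports the tests.
* **Degenerate inputs.** Songs stemming to zero words are excluded from
  modelling and logged; years lacking a complete lag window are dropped;
  a window with no prestigious songs yields a missing prestige covariate
  and the affected rows are dropped with a log entry; a constant covariate
  or a single-level grouping factor is a hard error naming the offender.
* **Tokens with digits** are kept verbatim and never stemmed.

## Known limitations

* The real-data headline numbers (the 86-artist roster, the 267/169
  lexicon stem counts, the published coefficient values) require the
  public chart download and the proprietary LIWC dictionaries, so the
  package validates against simulation and in-text arithmetic instead.
* WAIC on autocorrelated yearly cohorts can misrank models; the package
  surfaces this rather than fixing it.
* The HMC sampler is static (no tree-building); for very stiff posteriors
  more draws may be needed than a NUTS-based backend would require.
* Exact reproduction of third-party name-merging libraries is not
  attempted; the fingerprint scheme may split or merge a handful of artist
  names differently.
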