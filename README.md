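# lyricbias

Inference of cultural transmission biases from the emotional valence of
song lyrics.

Pop lyrics have grown measurably more negative and less positive over the
last half-century. `lyricbias` is for cultural-evolution researchers who
want to ask *why*: does the trend reflect **success bias** (copying
best-selling songs), **prestige bias** (copying high-status artists),
**content bias** (an intrinsic preference for negative content, visible as
chart rank predicting negativity), or **unbiased transmission** (random
copying — drift), where a word class spreads simply in proportion to its
recent frequency?

## The model

Every word of every song is classified against positive/negative emotion
lexicons. With $k_i$ emotional words out of $W_i$ total in song $i$, the
package fits the Bayesian aggregated binomial multilevel model

$$k_i \sim \mathrm{Binomial}(W_i,\ p_i),\qquad
\operatorname{logit}(p_i)=\alpha + a_{artist[i]} + a_{genre[i]} + a_{year[i]}
+ \beta_S S_i + \beta_P P_i + \beta_U U_i \;[+\, \beta_R \mathrm{rank}_i],$$

where $S$, $P$ and $U$ are the lagged mean emotional word counts of the
preceding three years' top-10 chart songs, prestigious artists' songs
(artists with >10 chart entries) and all songs respectively, rank enters
the negative-valence models only, and the varying intercepts get
adaptively regularising priors $a_g\sim\mathrm N(0,\sigma_g)$,
$\sigma_g\sim\mathrm{Exponential}(1)$. Posteriors come from a
self-contained Hamiltonian Monte Carlo sampler (non-centred, diagonal
mass adaptation); candidate models are screened with WAIC and interpreted
through the full models' 89% credible intervals. A coefficient $\beta$
reads as a $100(e^\beta-1)\%$ change in the odds that a word carries that
valence: `odds_interpretation(0.04)` is `4.08` (≈ +4%).

A generative simulator (`simulate_corpus()`, `simulate_neutral()`) emits
chart-style corpora from the same model with known coefficients — the
lagged covariates are computed through the inference code path itself — so
the whole pipeline is validated by parameter recovery with no downloads.

## Worked example

```r
library(lyricbias)

cfg <- sim_config(n_years = 10, songs_per_year = 60, mean_words = 200,
                  n_artists = 80, seed = 2024)
sim <- simulate_corpus(cfg)
sim$corpus
#> <lyric_corpus> 600 songs, years 2000-2009, provenance: synthetic

lex    <- synthetic_vocabulary(cfg)$lexicon
design <- build_design(sim$corpus, sim$corpus, lex, "negative")
spec   <- model_spec("negative",
                     effects = c("success", "prestige", "unbiased", "rank"),
                     chains = 2, iter = 400, warmup = 300)
fit <- fit_model(spec, design, seed = 7)
summarize_fit(fit)
#>      parameter        mean        lower       upper excludes_zero
#> 1        alpha -3.47177409 -3.712809857 -3.10214065          TRUE
#> 2    b_success  0.17284643 -0.420828175  0.85101632         FALSE
#> 3   b_prestige  0.09102310 -0.122787917  0.30763368         FALSE
#> 4   b_unbiased -0.22916522 -0.677154652  0.19693690         FALSE
#> 5       b_rank -0.01228177 -0.045870617  0.02048743         FALSE
#> 6 sigma_artist  0.32055648  0.256327610  0.39323338          TRUE
#> 7  sigma_genre  0.38494519  0.134547388  0.94156506          TRUE
#> 8   sigma_year  0.06111586  0.008555405  0.16651474          TRUE
```

`alpha` is the baseline log-odds of a word being negative
(`plogis(-3.47)` ≈ 3%, matching the simulated baseline), the `b_*` slopes
are the transmission-bias effects on the scaled covariates, and the
`sigma_*` rows are the between-artist/genre/year spreads. At this small
demonstration scale no bias excludes zero — the year-level covariates are
few and collinear, which is exactly the uncertainty the credible
intervals should report. Model comparison:

```r
null_fit <- fit_model(model_spec("negative", chains = 2, iter = 400,
                                 warmup = 300), design, seed = 7)
compare_waic(list(full_unbiased = waic(fit$loglik),
                  null = waic(null_fit$loglik)))
#>           model     waic       se   d_waic     d_se     weight
#> 1          null 1865.142 28.55191 0.000000 0.000000 0.97171162
#> 2 full_unbiased 1872.215 29.32206 7.073216 5.775968 0.02828838
#> Warning: WAIC comparison on time-series data is unstable; ...
```

The difference (7.1) is close to its own standard error (5.8): the data
cannot firmly rank the models, and the always-on warning reminds you that
WAIC is unstable for yearly time series — interpret the full model's
coefficients instead.

Real corpora enter through `read_chart_csv()` (rank/song/artist/year/
lyrics tables) or `read_bow_corpus()` (sparse `%`-vocabulary bag-of-words
files plus a metadata CSV), followed by `filter_english()`,
`filter_years()` and `resolve_artists()`; user-supplied lexicons load via
`load_lexicon()` (a small open placeholder ships in `inst/extdata/` for
tests). `run_pipeline()` drives the whole analysis from one JSON config,
and `inst/cli/lyricbias` exposes `simulate` / `run-all` / `recover`
subcommands.

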