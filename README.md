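# pluralinfo

Tools for asking a precise question about German morphology: **do
individual speakers use grammatical gender when they inflect novel
nouns?** In the German lexicon, gender (feminine/masculine/neuter) is a
strong statistical cue to a noun's plural class (the suffix classes
*-(e)n*, *-e*, ø, *-s*, *-er*, other) — about a third of plural-class
variation is explained by gender. Whether individual speakers deploy that
cue when generalizing to nonce nouns ("wug" tests) is an empirical
question about language production, and answering it per speaker needs
care: the natural measure, mutual information, is upward-biased on 24
trials, so "ignoring gender" does not look like zero.

The package implements the full analysis pipeline:

* **Plug-in information measures** over gender-by-class tables: entropy
  `H(C)`, conditional entropy `H(C|G)`, mutual information `MI(C;G)`, the
  normalized ratio `MI/H`, and KL divergence (`entropy()`,
  `info_summary()`, `kl_divergence()`), in bits.
* **Hypothesis simulators** (`hypothesis_spec()`, `simulate_cohort()`):
  multinomial production of 24 plural classes per participant under a
  gender-ignoring null (h0), lexicon-level gender conditioning (h1), or
  monosyllable-mediated conditioning (h2), with gender either presented
  (8 per gender) or self-assigned (sampled from a gender marginal).
* **A simulation-calibrated Bayesian Beta regression**
  (`fit_beta_regression()`) of `MI/H` on `H` with logit link and
  mean–precision parameterization, fitted by MCMC, plus per-participant
  log Bayes factors and best-fit classification (`classify_cohort()`,
  `aggregate_bayes_factor()`).
* **A synthetic behavioral-data generator** (`generate_cohort()`)
  emulating the elicitation designs with mixed latent strategies, since
  real participant data are not redistributable.
* **Orthographic neighborhoods** (`find_neighbors()`,
  `neighborhood_info()`): normalized-Levenshtein neighbor retrieval and
  neighborhood-level gender-conditioning statistics.
* **Orchestration** (`pipeline_config()`, `run_pipeline()`): one
  declarative config drives calibrate → generate/load → summarize →
  classify → report, deterministically.

The `analysis/` directory holds numbered drivers that run the whole
study at desk scale and write tables under `results/`.

## Worked example

Simulate 10,000 gender-ignoring participants under the fixed-gender
design and fit the calibration model:

```r
library(pluralinfo)

cohort <- simulate_cohort(hypothesis_spec("h0", "fixed"), 10000, seed = 42)
fit <- fit_beta_regression(cohort, seed = 7)
fit
#> Beta regression fit (10000 observations, 4 chains)
#>   parameter Estimate Est.Error l-95% CI u-95% CI
#> 1 Intercept    -2.33      0.04    -2.40    -2.25
#> 2      H(C)     0.33      0.02     0.29     0.37
#> 3       phi    32.15      0.45    31.27    33.06
#> split-Rhat: 1.000 1.000 1.000 (converged)
```

The *positive* entropy slope is the null's signature: plug-in MI noise
grows with class variation. A lexicon-conditioning cohort fits with a
*negative* slope, and the two fitted models then classify participants.
Even though every simulated participant here ignores gender, their mean
`MI/H` is about 0.15 — the plug-in noise floor, which is why the null is
simulated rather than assumed to be zero.

Score a cohort of synthetic speakers against both models:

```r
h1_fit <- fit_beta_regression(
  simulate_cohort(hypothesis_spec("h1", "fixed"), 10000, seed = 43),
  seed = 8
)
records <- generate_cohort(120, strategy_mixture(ignore = 0.9, lexicon = 0.1),
                           "exp1", seed = 1)
summaries <- summarize_productions(records)
cls <- classify_cohort(summaries, list(h0 = fit, h1 = h1_fit))
summary_report(cls, summaries)
#> Gender-conditioning report over 120 participants
#> Best-fit hypothesis counts:
#>  hypothesis count   percent
#>          h0   109 90.833333
#>          h1    11  9.166667
#> Normalized MI ratio: median 0.163 (quartiles 0.120 - 0.204)
#> Aggregate BF10: 0 (log BF10 = -1249.29)
```

The report reads like the behavioral result it emulates: a ~90%
gender-ignoring cohort is classified as such, the median speaker's
gender conditioning (≈ 0.16) sits below the monosyllable reference level
(0.17), and the aggregate Bayes factor shows decisive evidence for the
null.

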