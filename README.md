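# sjstar

Scoring and evaluation machinery for **STAR** (Sjögren's Tool for Assessing
Response), a composite responder index for randomised controlled trials in
primary Sjögren's syndrome (pSS).

pSS trials have repeatedly failed on single-domain primary endpoints even
when several secondary measures moved: systemic disease activity,
patient-reported symptoms, glandular function and biological markers
respond differently to different drugs. STAR declares a patient a
responder from improvement across five domains, each worth points when its
rule is met:

| Domain | Points | Response rule |
|---|---|---|
| Systemic activity | 3 | clinESSDAI decrease ≥ 3 |
| Patient-reported outcome | 3 | ESSPRI decrease ≥ 1 point or ≥ 15% |
| Lachrymal gland function | 1 | Schirmer (abnormal < 5 mm): +5 mm if abnormal at baseline, else stays normal; *or* OSS (abnormal ≥ 3): −2 points if abnormal, else stays normal |
| Salivary gland function | 1 | UWSF: +25% (any increase from 0); *or* Hocevar ultrasound score: −25% |
| Biological | 1 | serum IgG −10% *or* RF −25% |

**STAR responder: total ≥ 5 points** — which provably requires at least one
major domain (systemic or PRO), since the minors sum to 3.

Beyond the scorer, the package implements the full endpoint-evaluation
toolkit used to develop composites of this kind:

* `option_spec()` / `enumerate_options()` — candidate endpoint families
  (SRI-like with a no-worsening clause, ≥3-of-5 domain counts with and
  without a major-domain requirement, point sums at thresholds 4–9,
  ACR-like uniform percent improvement, CRESS-like);
* `cohens_d()` (pooled SD, noncentral-t CI), `hedges_g()`, `c_index()` —
  sensitivity-to-change metrics;
* `pool_binary()` / `pool_continuous()` — random-effects meta-analysis
  (Mantel–Haenszel fixed effect, Paule–Mandel τ², Q-profile CIs, 0.5
  zero-cell correction);
* `fit_twins()` / `grow_tree()` / `select_subsets()` — virtual-twins
  subgroup discovery with cross-fitted optimism correction;
* `simulate_trial()` / `simulate_suite()` — a synthetic two-visit pSS
  trial generator with configurable per-domain effects, a latent severity
  copula, missingness and planted subgroups;
* `evaluate_options()` / `rank_options()` — score every option on every
  trial and pool expected-positive and expected-null trials separately.

Everything takes a data frame first and returns a tibble; fitted objects
have `tidy()`, `glance()` and `autoplot()`/`plot_*()` methods.

## Worked example

```r
library(sjstar)
library(dplyr)

trial <- read_trial_csv(system.file("extdata", "example_trial.csv",
                                    package = "sjstar"),
                        trial_id = "example", expert_class = "positive")
score_trial(trial)
#> # A tibble: 2 × 5
#>   arm           n n_scored responders  rate
#>   <chr>     <int>    <int>      <int> <dbl>
#> 1 placebo       5        5          0   0
#> 2 treatment     5        5          3   0.6
```

Three of five treated patients reach ≥ 5 points (all three respond in both
major domains; the per-patient detail is in `score_star(trial)`), no
placebo patient does — patient p08 improves systemically (3 points) but
nowhere else.

Evaluating the candidate index across a simulated nine-trial development
suite (six trials with real effects, three null):

```r
trials <- simulate_suite(seed = 42)
ev <- evaluate_options(trials, candidate_star_spec())
ev$meta_positive[[1]]
#> <star_meta> 6 studies, OR
#>   random effects log OR = 1.7194 [0.6732, 2.7656]  (OR = 5.5813)
#>   fixed effect (MH) = 1.3289 [0.9094, 1.7485]
#>   tau^2 = 1.1676 [0.0000, 12.3054]  Q = 11.587 (df 5, p = 0.041)
ev$meta_negative[[1]]
#> <star_meta> 3 studies, OR
#>   random effects log OR = -0.5140 [-1.0722, 0.0442]  (OR = 0.5981)
#>   fixed effect (MH) = -0.5148 [-1.0719, 0.0422]
#>   tau^2 = 0.0000 [0.0000, 1.8435]  Q = 0.348 (df 2, p = 0.840)
```

The pattern a usable endpoint must show: pooled odds ratio far above 1
where trials are expected to be positive (here OR ≈ 5.6 with the CI
excluding 1), and a CI spanning 1 where no effect exists. `rank_options()`
orders candidate options by exactly this contrast, and
`plot_option_evaluation()` draws it.

A thin command-line wrapper ships in `inst/cli/star.R`
(`simulate`, `score`, `evaluate`, `rank` subcommands).

## Vignette

`vignettes/star-methods.Rmd` documents the scoring conventions the
published rules leave open (missing data, zero baselines, boundary
arithmetic), the estimators and their numerical choices, what the
simulator does and does not emulate, and known limitations.
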