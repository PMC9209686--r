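---
title: "Scoring and evaluating the STAR composite responder index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and evaluating the STAR composite responder index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sjstar)
library(dplyr)
```

## The index

Primary Sjögren's syndrome trials have repeatedly failed on single-domain
primary endpoints even when several secondary measures moved: systemic
activity, patient-reported symptoms, glandular function and biological
markers respond differently to different drugs. STAR (Sjögren's Tool for
Assessing Response) addresses this with a composite responder definition
over five domains, each contributing points when its response rule is met:

| Domain | Points | Rule |
|---|---|---|
| Systemic activity | 3 | clinESSDAI decrease ≥ 3 points |
| Patient-reported outcome | 3 | ESSPRI decrease ≥ 1 point or ≥ 15% |
| Lachrymal gland function | 1 | Schirmer: abnormal (< 5 mm) at baseline → increase ≥ 5 mm; normal → stays normal. *Or* OSS: abnormal (≥ 3) at baseline → decrease ≥ 2; normal → stays normal |
| Salivary gland function | 1 | UWSF: baseline > 0 → increase ≥ 25%; baseline 0 → any increase. *Or* ultrasound: Hocevar decrease ≥ 25% |
| Biological | 1 | IgG decrease ≥ 10% *or* RF decrease ≥ 25% |

A patient is a STAR responder at **≥ 5 points**, which forces at least one
major domain (systemic or PRO) to respond: the three minor domains together
are worth only 3 points. `score_star()` implements the rules; all
thresholds are inclusive.

```{r}
trial <- read_trial_csv(system.file("extdata", "example_trial.csv",
                                    package = "sjstar"),
                        trial_id = "example", expert_class = "positive")
score_star(trial) |> count(arm, responder)
```

### Conventions the published rules leave open

* **Missing data.** A rule with either visit missing is `undetermined`; a
  domain with no usable instrument pair is `undetermined` and earns 0
  points. This is conservative — it biases *against* response — and the
  per-patient `n_undetermined` count is surfaced so users can filter by
  completeness instead. Patients with no determinate domain at all are
  excluded from per-trial 2×2 tables by the evaluation pipeline.
* **"Or" between instruments** means any available instrument meeting its
  criterion triggers the domain; an available non-responding pair makes the
  domain "no", not "undetermined".
* **Zero baselines.** A Hocevar score of 0 cannot decrease by 25%, so it
  scores "no" (the rules state an explicit zero-baseline branch only for
  salivary flow). The ESSPRI percent branch requires baseline > 0.
* **Maintenance counts.** A glandular instrument that is normal at baseline
  scores a response by *staying* normal. In mild populations this inflates
  glandular response rates; it is the printed rule, applied as printed.
* **Numerics.** Relative-change thresholds are evaluated in product form
  (`followup >= baseline * (1 + threshold)`, and the decrease analogue)
  rather than as a ratio. The two are identical over the reals, but the
  ratio form can misclassify an exact boundary case in double precision
  (an exact +25% from baseline 0.2 evaluates to a ratio of
  0.24999999999999994). No rounding is applied before comparison.

## The option space

STAR's final form was chosen from families of candidate designs, all
expressible with `option_spec()`: SRI-like (major-domain improvement with a
no-worsening clause), domain counting with or without a major-domain
requirement (design 3A, CRESS-like), the point-sum design (3B, binary at
thresholds 4–9 or continuous), and ACR-like uniform percent improvement
(10–70%). `candidate_star_spec()` is the point-sum design at threshold 5
and classifies identically to `score_star()`. A weighted-score (DAS-28
style) family is deliberately absent: stable domain weights could not be
estimated during development, and the family was dropped.

Open parameters were fixed as follows:

* **Worsening** has no consensual published definition; SRI-like designs
  default to the mirror image of each improvement rule (e.g. clinESSDAI
  increase ≥ 3). Domains whose worsening status is undeterminable are
  treated as not worsened.
* **ACR-like zero baselines**: on increase-direction instruments a zero
  baseline responds to any increase (mirroring the salivary-flow rule); on
  decrease-direction instruments it cannot respond.
* The ACR-like percent grid defaults to steps of 10 over the stated 10–70%
  range.
* The historical option list was produced by expert voting and is not
  reconstructible; `enumerate_options()` generates systematic grids
  instead.

## Discrimination metrics

`cohens_d()` is the standardised mean difference with the pooled SD; its CI
uses the noncentrality-parameter approach — root-finding the noncentral-t
NCPs whose tail probabilities at the observed t statistic are α/2 and
1 − α/2, then rescaling by √(1/n₁ + 1/n₂). The root is bracketed within
±(|t| + 10) and solved to 1e-8. Effect sizes classify by magnitude as
small (< 0.5), moderate (0.5–0.8, with 0.8 itself moderate — the printed
cutpoints leave the boundary ambiguous) and large (> 0.8). `hedges_g()`
applies the small-sample factor J = 1 − 3/(4·df − 1); the exact
gamma-function J differs only in the sixth decimal at trial-sized df.

`c_index()` is the Mann–Whitney concordance — the probability a random
treated patient beats a random control, ties credited 0.5 — computed by the
midrank formula, which is algebraically identical to exhaustive pair
counting at any size. For a binary responder indicator it equals the AUC of
response against arm; both the binary-indicator and continuous-score routes
are available, since either reading of the development analysis is
possible.

## Meta-analysis

`pool_binary()` pools per-trial odds ratios: 0.5 is added to all four cells
of any study with a zero cell (other studies untouched); the fixed-effect
estimate is Mantel–Haenszel on uncorrected cells (the MH estimator
tolerates zeros; Robins–Breslow–Greenland variance) and the random-effects
estimate uses inverse-variance weights 1/(vᵢ + τ²) with the Paule–Mandel
τ². Pairing MH (fixed) with PM (random) follows mainstream meta-analysis
practice, and both estimates are reported. `pool_continuous()` pools
Hedges' g by inverse variance with the same τ² machinery. The pooled CI is
a normal approximation — no Knapp–Hartung adjustment, since none is part of
the method being reproduced.

`paule_mandel_tau2()` solves Σ wᵢ(τ²)(yᵢ − μ̂(τ²))² = k − 1 to 1e-10,
truncated at zero; `q_profile_ci()` profiles the generalised Q statistic
against χ²ₖ₋₁ quantiles, truncating empty intersections at zero, with the τ
interval the square root of the τ² interval. Both are authored here —
they are small, their defining equations are explicit, and the test suite
verifies them against an independent grid-search oracle *and* against
`metafor` — so the package's estimates never depend on the cross-check.

## Virtual twins

`fit_twins()` estimates each patient's response probability under both
arms with bagged classification trees (`randomForest` with `mtry` equal to
the number of predictors, i.e. pure bagging), the arm indicator included as
a feature; p₁ and p₀ come from predicting with the arm toggled, and
z = p₁ − p₀ is the individual treatment effect. Predictions are
out-of-fold (default K = 10 cross-fitting) to limit the optimism of the
subsequent search; defaults (500 bags, node size 5) are package choices —
the method's description names no hyperparameters — and all are
overridable. `grow_tree()` partitions z with an `rpart` regression tree
whose minimum leaf size defaults to 60, the sample-size criterion used for
subset selection. Every non-root branch is a candidate subset, reported
with its observed relative risk of response (treatment vs placebo), the
whole-population RR, and an optimism-corrected RR built from the
cross-fitted probabilities, mean(p₁)/mean(p₀) within the subset.

`select_subsets()` keeps branches whose corrected RR is at least
`rr_ratio_min` times the overall RR ("notably higher" — quantified here as
1.5× by default, since no published value exists) and whose size is ≥ 60.
When the overall RR is undefined (zero placebo responders) the ratio
criterion cannot apply; the result is flagged and nothing is selected on
that ground.

One caution from the package's own simulations: with a planted subgroup of
modest effect (+0.4 response probability), the *true* branch's RR ratio
over the whole population is about 1.4, below the 1.5 default, so selection
tends to fire on enhanced sub-branches of the true rule rather than the
rule itself. The multiplier is a sensitivity dial, not a sharp boundary.

## The trial simulator

The nine development RCTs' patient-level data are not redistributable, so
`simulate_suite()` stands in for them: nine trials of 80, 52, 120, 29, 27,
32, 133, 120 and 110 patients — three positive, three "in between", three
negative, evaluated at week 24 except two week-12 and one week-48 trial.
Baselines come from range-respecting marginals (truncated negative binomial
clinESSDAI around 10; truncated normal ESSPRI around 6 and Hocevar around
22; zero-inflated gamma Schirmer and salivary flow; binomial-type OSS;
lognormal IgG; zero-inflated lognormal RF) coupled through a single latent
severity factor via a Gaussian copula (default loading 0.5). Follow-up is
baseline plus an arm-dependent mean change plus Gaussian noise, truncated
to the instrument range and rounded to its granularity (ESSPRI 0.1, counts
to integers, flow to 0.001 mL/min). Missingness is independent per
instrument and visit, with ultrasound the most often absent (20%) since it
is not universally performed.

The effect profiles are the study conditions: the *positive* profile moves
every domain (clinESSDAI −4, ESSPRI −1.5, UWSF +35%, IgG −12%, ... against
a placebo drift of clinESSDAI −1, ESSPRI −0.5); the *in-between* profile
mimics trials that missed symptomatic endpoints but moved objective and
biological measures (IgG −10%, RF −25%, UWSF +20%, ESSPRI −0.8); the
*negative* profile sets treatment changes equal to placebo changes, which
the constructor enforces. None of these are calibrated to real covariance
structures — no such estimates are printed anywhere usable — so passing
calibration tests shows internal consistency of the machinery, not fidelity
to any particular drug's behaviour. Seeding is one master seed with a
deterministic per-trial derivation; a fixed seed reproduces a suite
byte-for-byte.

## The evaluation pipeline

`evaluate_options()` scores every option on every trial, forms per-trial
2×2 tables (binary designs) or per-arm summaries (continuous point sum),
computes C-indexes, and pools positive + in-between trials separately from
negative trials — the first meta-analysis measures sensitivity to a real
effect, the second specificity to its absence. `rank_options()` orders
options by |effect_pos| − λ·|effect_neg| on the analysis scale (λ = 1 by
default; λ = 0 ranks on sensitivity alone). The historical final selection
among well-ranked options was a consensus judgement of clinical relevance;
the ranking here is only the quantitative half.

```{r, fig.width = 6, fig.height = 3.5}
trials <- simulate_suite(seed = 7)
ev <- evaluate_options(trials, enumerate_options(
  list(design_3b_binary = list(thresholds = 5:6), cress_like = list())))
plot_option_evaluation(ev)
```

## Problem sizes used by the test suite

Monte-Carlo checks run at sizes chosen to give stable verdicts on a
laptop-class machine: CI coverage of the noncentral-t interval over 2,000
two-arm draws at n = 30/30; splitting-variable recovery over 100 planted
replications at n = 400 (100 bags, 5 cross-fitting folds); null-data
specificity over 50 replications at n = 200; pipeline calibration over 50
simulated nine-trial suites. Unit tests use smaller replicate counts of the
same generators.

## Limitations

* The simulator does not model dropout dynamics, dose groups, or real
  instrument covariance; correlations are driven by one latent factor.
* Subgroup discovery assumes binary response and numeric baseline
  covariates; censored outcomes are out of scope.
* The C-index is reported without a CI; between-arm inference is carried by
  the meta-analysis layer.
* Patients with partially undetermined domains still classify (conservative
  zero points); sensitivity of trial-level conclusions to that convention
  should be checked with the `n_undetermined` counts when missingness is
  heavy.
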