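---
title: "Linear models for guide RNA efficiency: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear models for guide RNA efficiency: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidelm)
```

## The problem and the modelling stance

SpCas9 cuts where its guide RNA matches a 20-nt protospacer next to an NGG
PAM, but observed editing efficiency varies over orders of magnitude between
guides targeting the same locus.  Efficiency is largely encoded in local
sequence, so it can be predicted; the question is with what kind of model.
`guidelm` deliberately uses linear-family models.  Deep and ensemble
predictors can be somewhat more accurate on in-distribution data, but a
linear model's prediction is a sum of named terms: the contribution of
"adenine at protospacer position 19" or "poly-T burden" is a number with a
confidence interval, and a surprising score can be traced to the features
that produced it.  For experiment planning — where a wrong guide costs weeks —
that auditability is worth more than a few points of rank correlation.

## Sequence layout and featurization

A scoring target is a 30-mer with fixed anatomy: positions 1–4 upstream
context, 5–24 protospacer (protospacer position $p$ sits at 30-mer position
$p+4$; position 20 is PAM-proximal), 25–27 the NGG PAM (so "GG" is invariant
at 26–27), 28–30 downstream.  This is the dominant 30-mer convention for NGG
guide design and makes position-named features such as `A_19` well defined.
RNA input (`U` bases) and lowercase are normalized; IUPAC ambiguity codes are
rejected because a scored sequence must describe a single molecule.  PAM
enforcement can be switched off for permissive scoring of non-canonical
sites.

The candidate feature set (`candidate_schema()`, 473 features) covers:

* **Position-specific indicators** — one-hot mononucleotides at protospacer
  positions 1–20 (80 features) and dinucleotides at starts 1–19 (304).
* **Global counts** — overlapping occurrences of every 1-, 2- and 3-mer in
  the protospacer.  Overlapping counting is chosen so a `TTTT` run registers
  an elevated `TTT` burden; poly-T matters biologically because TTTT
  terminates Pol III (U6) transcription.
* **GC content** — the G+C count of the protospacer plus extreme-content
  indicators (`GC low`: count < 4, `GC high`: count > 14 of 20).  The bounds
  are configuration values, defaults chosen where guide-activity work
  usually places "extreme"; `GC count` names the *base* count, the
  conventional reading in guide-design feature sets, while the dinucleotide
  `GC` occurrence count remains available under the distinct name
  `GC dinuc count`.
* **Structural proxies** — Wallace-rule melting temperatures,
  $2(A{+}T) + 4(G{+}C)$ °C, for the whole protospacer and segments 1–5,
  6–13, 14–20.  A closed-form rule keeps featurization deterministic and
  dependency-free; the descriptor parameters would admit a nearest-neighbor
  substitute without changing the schema format.
* **A middle-adenine count** over protospacer positions 6–13 — "middle" has
  no canonical definition, so the bounds are explicit parameters.

Schemas are ordered, named, and serialize to JSON; a reloaded schema induces
a bit-identical design matrix, which is what makes persisted models
portable.

## The four models

Guide efficiency is measured differently under different expression systems,
so one model per condition and task is fitted (`train_model_suite()`):

* **U6 regression** — the response is a fraction of efficient edits in
  $[0,1]$ with no trial counts, so a binomial likelihood is not literally
  available.  We fit a quasi-likelihood *fractional logit*:
  $\mathrm{E}[y\mid x] = \mathrm{logit}^{-1}(\beta_0 + \beta^\top x)$,
  estimated by IRLS and paired with a Pearson-dispersion-scaled covariance
  $\hat\phi\,(X^\top W X)^{-1}$, the standard quasi-binomial treatment.
* **T7 regression** — continuous in-vitro efficiency scores; ordinary least
  squares with the classical covariance $\hat\sigma^2 (X^\top X)^{-1}$.
* **U6 / T7 classification** — guides in the top 20% of observed efficiency
  are labeled efficient, the bottom 20% inefficient
  (`label_top_bottom()`, exactly $\lfloor 0.2 n \rfloor$ per class —
  flooring never labels more than the stated fraction), and a logistic model
  is fitted on the labeled subset *using the same selected features as that
  promoter's regression model*.  Boundary ties are resolved by stable input
  order: in the stable descending-score order the first $k$ guides are
  efficient and the last $k$ inefficient, a rule that is reproducible and
  well defined even when all scores tie.  A hard label at prediction time
  uses the 0.5 probability threshold.

### Numerical choices

IRLS iterates to a coefficient change below $10^{-8}$ in max norm (cap 100
iterations), with two principled early exits: a glm-style relative-deviance
plateau ($<10^{-10}$), and explicit detection of complete separation —
every response fitted to its boundary to within $10^{-4}$ with all fitted
probabilities pinned — which returns the current fit with a `separation`
warning rather than erroring, matching how practitioners treat
separated logistic fits.  Separation is not hypothetical here: top/bottom-20%
labels discard the middle of the response, so with enough selected features a
few hundred labeled guides can become linearly separable.  Rank-deficient
designs are rejected with the names of the redundant columns.  Confidence
intervals are Wald (normal-quantile) intervals; nothing in the model family
makes profile likelihood worth its cost at these sample sizes.

### Feature selection

Three sequential, individually switchable steps (`select_features()`):
(1) drop indicator features active in under 1% of guides — their weights are
unidentifiable; (2) rank features by absolute Spearman correlation with the
response and keep the top 100; (3) lasso with the penalty chosen by 5-fold
cross-validation (`glmnet`), keeping features nonzero at the
cross-validated optimum.  The fold assignment derives from a configuration
seed (default 17) so selection is reproducible.  The screen cap and
prevalence threshold are honest defaults, not tuned constants: the aim is a
compact interpretable model, and downstream weight CIs flag any survivor
that contributes nothing.

## Ranking evaluation

Spearman correlation (mid-rank ties) measures overall agreement;
nDCG measures what a designer actually consumes — the top of the list.  We
use linear gain $rel_i$ with discount $\log_2(i+1)$, normalized by the
ideal ordering's DCG, over the full list by default (`k` truncation
available).  Negative relevances are min-shifted to nonnegative, and the
shift is applied only when negatives are present — so a constant positive
relevance vector scores 1 for every ordering (order is irrelevant), while an
all-zero vector is signalled as undefined rather than silently scored.  An
exponential-gain variant ($2^{rel}-1$) sits behind a switch.

## Interpretation

For a linear model the *effect* of feature $j$ on a guide is exactly
$\beta_j x_j$.  `feature_effects()` reports each effect against the training
distribution of effects as Tukey boxplot statistics: type-7 (linear
interpolation) quantiles, whiskers clamped to the most extreme observation
within $1.5\,\mathrm{IQR}$ of the box, points beyond flagged as outliers.
`centered_attribution()` reports $\beta_j (x_j - \bar x_j)$ against a
background set; these sum *exactly* to the prediction's deviation from the
background-mean prediction on the linear-predictor scale.  The identity is
kept on the link scale deliberately — passing through the inverse logit
would break additivity — and the response-scale view is exposed as separate,
clearly labeled attributes.

## Synthetic data: what it does and does not show

`random_targets()` draws i.i.d. uniform bases with the PAM "GG" fixed;
`simulate_efficiencies()` adds Gaussian noise to a known linear predictor —
on the logit scale for fractional responses, which keeps them strictly
inside $(0,1)$ without clipping.  The default ground truth
(`default_truth()`) uses five recognizable features with effect sizes fixed
once at realistic magnitudes for guide-activity models (logit scale:
`A_19` +0.5, `G count` +0.08, `GC count` −0.06, `TTT count` −0.40,
`AG count` +0.15, intercept −0.5, noise SD 0.5; the continuous variant
scales these to roughly half, noise SD 0.3).

This generator emulates the *structure* of a guide-efficiency study — valid
sequence space, fractional vs continuous responses, a sparse linear signal —
and therefore supports closed-loop tests: parameter recovery to numerical
precision at noise 0, recovery within 3 standard errors under noise,
interval coverage calibration, and Spearman > 0.99 of predictions against
the noiseless truth.  It does **not** emulate real screens: real efficiency
distributions are not logit-Gaussian, real sequence composition is not
uniform, and real effects are neither exactly linear nor exactly sparse.
Passing these tests certifies the estimators and the pipeline, not
state-of-the-art accuracy on any particular published dataset; fitting to
real training tables is the supported path for that
(`read_csv_targets()` → `train_model_suite()`).

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical claims are crisp: suite training on
1000 guides per promoter, parameter recovery at $n = 2000$, and interval
calibration by 1000 replicate refits at $n = 500$ with 5 features (binomial
Monte-Carlo error on a 95% coverage estimate is then ±0.7%, so a ±3-SE
acceptance band is ±2.1%).

## Known limitations

* Feature effects beyond additivity (position×position interactions) are out
  of scope; the candidate schema could express products, but the selection
  and interpretation machinery assume main effects.
* The fractional-logit family specifies only a mean-variance relationship;
  it supports estimation and Wald inference but not simulation or
  likelihood-ratio tests (`simulate()` refuses, by design).
* Off-target propensity, chromatin context, and genome-wide candidate
  retrieval are outside the package: input is the 30-mer list, output is
  scores over it.
* Under complete separation the classification weights are reported at the
  detection point with a warning; their Wald intervals are then not
  meaningful, only the ranking of scores is.
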