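---
title: "Iterative thematic analysis of high-dimensional survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative thematic analysis of high-dimensional survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itasurvey)
```

## The problem

Large household surveys (DHS-style microdata in particular) ask thousands of
questions, and after one-hot encoding a respondent-level table easily exceeds
several thousand binary features. When the outcome of interest is rare — say,
current use of an intra-uterine device (IUD), reported by roughly 1–2% of
married respondents in national surveys — classical hypothesis-driven
regression is poorly suited to screening that feature space: power is low,
pre-registration of a handful of covariates discards most of the data, and
p-values from enormous samples are uninformative as a selection device.

`itasurvey` implements an exploratory, hypothesis-generating alternative:
penalized logistic regression combined with *iterative thematic analysis*
(ITA). Machine-selected features are grouped by a human-curated theme map,
the dominant theme is removed, and the models are rerun so that weaker—but
substantively distinct—signal can surface. The output is not a single fitted
model but a sequence of themes, in discovery order, each supported by a set
of named category-level features.

## The model stack

**Penalized logistic regression.** For outcome $y_i \in \{0,1\}$ and feature
row $X_i$, the package maximizes the Bernoulli log-likelihood under the
logistic link,
$$
\ell(\theta) = \sum_i -\log(1+e^{-\eta_i}) + \sum_{i:\,y_i=0} -\eta_i,
\qquad \eta_i = X_i\theta + b,
$$
minus a penalty: $\lambda\lVert\theta\rVert_1$ for the lasso,
$\lambda\lVert\theta\rVert_2^2$ for the ridge. Columns are standardized to
unit variance at fit time (penalties are scale-sensitive; coefficients are
reported back on the raw scale) and the intercept is unpenalized. At
$\lambda = 0$ the fit is the ordinary MLE. The convex optimization is
delegated to `glmnet`; $\lambda$ here is on the total-log-likelihood scale,
mapped internally to glmnet's per-observation parameterization
($\lambda/n$ for L1, $2\lambda/n$ for L2).

**Tuning.** $\lambda$ is chosen by 5-fold cross-validation maximizing the
mean held-out log-likelihood. Folds are stratified on the outcome — at 1.5%
prevalence an unstratified fold can lose the positive class entirely — and
fold sizes differ by at most one. The grid has 50 log-spaced points
descending from $\lambda_{\max}$ (the smallest $\lambda$ with an all-zero
lasso solution). The lasso grid spans two decades: in the regimes this
package targets the CV optimum sits comfortably inside that span, and the
nearly-unpenalized fits further down cost most of the path time without ever
being selected. The ridge grid starts at $100\,\lambda_{\max}$ and spans four
decades. Both are arguments (`lambda_grid()`) if your data disagree. Ties on
the CV criterion resolve to the larger, more parsimonious $\lambda$.

**Knee-point selection.** Instead of p-values, selection uses the knee
(maximum-curvature point) of the sorted coefficient curve: coefficients are
ranked from high to low, and features whose values lie *strictly above* the
knee value are selected. The detector is the Kneedle procedure for a
decreasing convex curve: min–max normalize both axes, form the difference
between the normalized curve and the diagonal, take the local maxima of that
difference as candidate knees, and confirm a candidate when the difference
subsequently dips below it by more than the sensitivity allowance
($S/(n-1)$, $S = 1$, no smoothing). Among confirmed candidates the knee is
the one with the largest difference value — the extremum of the difference
curve, which is what "point of maximum curvature" means operationally. (A
streaming variant that stops at the first confirmed candidate behaves
identically on pronounced elbows but degenerates on long noisy coefficient
curves, latching onto a micro-bend among the top few features; see the
design notes.) A perfectly linear curve has no knee; the selection then
refuses rather than guessing. Ranking defaults to absolute magnitude
(`ranking_mode = "absolute"`): one-hot dummies carry protective (negative)
effects whose strength matters as much as risk effects, and a literal
high-to-low sort would silently discard strong negative determinants. The
literal signed sort remains available and the choice is recorded on the
curve object.

**The ITA loop** (`run_ita()`). One stratified 80/20 train/test split is
drawn up front and reused by every iteration, so per-round AUC/BER values
are comparable. Each iteration then:

1. fits a CV-tuned lasso on the active features and keeps the nonzero
   support;
2. refits a CV-tuned ridge on that support ($\lambda$ is re-tuned for both
   stages in every iteration);
3. sorts the ridge coefficients, finds the knee, selects the features above
   it;
4. looks the selected features up in the theme map: a theme is *valid* when
   its selected membership reaches `max(2, ceiling(0.05 * n_selected))` —
   the 5%-of-selection rule with an absolute floor of two variables.
   Selected features in no theme are reported individually as unthemed;
5. evaluates the ridge fit on the held-out split (AUC; BER at a
   training-tuned threshold);
6. drops the top-scoring theme (default score: maximum coefficient magnitude
   among selected members; mean and variance modes exist). A variable leaves
   the active set only when *all* of its themes have been dropped, so
   multi-theme variables survive their first theme's removal. Once
   identified, a theme stays in the drop pool in later iterations even if
   the smaller later selections no longer re-validate it — dropping
   proceeds through the accumulated catalogue of themes, mirroring how an
   analyst would treat an established theme.

Stopping is checked *before* any drop: the loop ends when an iteration
selects nothing outside the union of all previously selected features
(`no_new_variables`), when three consecutive iterations add no new theme
(`no_new_themes_3x`), or when no identified theme with currently-selected
members remains to drop (`exhausted`). An iteration cap of
(number of distinct theme labels + 3) guarantees termination regardless.
If the lasso support falls below the four points a knee needs, the iteration
selects nothing and the loop stops; this is reported in the trace note.

**Evaluation.** AUC is computed in the Mann–Whitney form (probability that a
random positive outscores a random negative, ties counted ½) via mid-ranks,
which equals trapezoidal ROC integration exactly. The balanced error rate
BER $= \tfrac12\!\left(\mathrm{FN}/(\mathrm{TP{+}FN}) +
\mathrm{FP}/(\mathrm{TN{+}FP})\right)$ needs a decision threshold; a 0.5 cut
on an unweighted fit at 1–2% prevalence predicts "negative" for everyone and
pins BER at 0.5, so the default threshold maximizes balanced accuracy on the
*training* data (a fixed-threshold mode exists).

**Neural-network validator.** As a cross-check that linear selection is not
an artifact, `fit_feedforward()` trains a fully connected net — four hidden
layers by default, tapering 64-32-16-8, ReLU activations, sigmoid output —
on the round-1 lasso support, with mini-batch Adam, He initialization, an
output bias initialized at the base rate, and early stopping on a stratified
10% validation split. The network is written in plain R matrix algebra;
training is deterministic given the seed. Per-feature importance defaults to
permutation importance (mean held-out AUC drop over `R` seeded permutations,
with Monte-Carlo standard errors; negative means are clipped to zero for
ranking only), and the same knee detector then selects the important
features, making the NN and ridge selections directly comparable
(`compare_selections()` reports the overlap and Jaccard index). One property
of permutation importance worth knowing: a trained network never carries
exactly-zero weights on a null input, and permuting *any* feature the model
uses injects noise into the scores, so the expected AUC drop for a
carries-no-signal feature is a small positive number, not zero — it vanishes
only relative to the Monte-Carlo resolution of the held-out evaluation. A
first-layer weight-magnitude mode is provided for comparison; how a deep
network's "coefficient values" should be defined is genuinely
underdetermined, and permutation importance is the reproducible default.

## The synthetic survey generator

Because the motivating microdata are access-restricted, the package ships a
generator (`generate_survey()`) that emulates their statistical shape rather
than any real joint distribution:

* **Theme blocks.** Each planted theme has one standard-normal latent factor
  per respondent; each of the theme's variables thresholds a noisy copy of
  it into equal-probability ordered categories. Within-theme latent
  correlation defaults to 0.3 — enough block structure to resemble a
  questionnaire module without making its variables interchangeable.
* **Effects.** Outcome log-odds are linear in category scores spanning
  $[-a_t, +a_t]$ for a theme with magnitude $a_t$; defaults space the eight
  theme magnitudes evenly over 0.5–1.0. Noise variables (50 four-category
  variables, i.e. 200 dummy columns) carry exactly zero effect, and are
  grouped into pseudo-themes of five in the theme map so that theme recovery
  can be scored against a non-trivial alternative. Redundant variables are
  deterministic pairwise category merges of theme variables (the classic
  age-recorded-twice situation) and carry no effect of their own.
* **Prevalence.** The intercept is calibrated by bisection on the mean
  logistic response so the expected prevalence hits the target (2% by
  default) for the realized linear predictor; the empirical prevalence then
  differs only by binomial noise.
* **Scale.** Defaults are 20,000 respondents and 8 themes of 5 variables.
  That is one to two orders of magnitude below national-survey scale; it
  keeps a full multi-iteration analysis in the low minutes on one CPU while
  preserving the rare-outcome, correlated-block, noise-dominated character
  that makes the problem hard.
* **Seeding.** One run seed hierarchically derives independent stream seeds
  per component (latents, outcome draw, folds, split, network training,
  permutations), so any component is reproducible in isolation.

What the generator does **not** emulate: survey design (strata, clusters,
weights), structured DHS missingness patterns, measurement error correlated
across modules, and real questionnaire redundancy beyond simple recodes.
Tests passing on this generator demonstrate that the machinery recovers
planted structure under realistic noise and imbalance — not that any
substantive finding from real survey data would replicate.

## Numerical choices and degenerate inputs

* Standardization uses the population (1/n) standard deviation, matching the
  solver's convention; constant columns get scale 0 and are reported, kept,
  and neutralized by the penalty.
* A standardized coefficient below 1e-8 in magnitude counts as exactly zero
  when reporting the lasso support.
* Final fits use solver threshold 1e-10 (1e-8 for in-loop refits); CV fold
  fits use 1e-6 (1e-5 inside the ITA loop), where the held-out log-likelihood
  is insensitive to tighter tolerances.
* Separation at $\lambda = 0$ is reported as non-convergence rather than
  silently returned.
* Coefficient ties in the sorted curve break lexicographically by feature
  name, making curves and selections deterministic across runs.
* Ties exactly at the knee value are excluded from selection ("strictly
  above the knee").
* Missing categorical values become an explicit `missing` level (DHS recodes
  use structured missingness; imputation is out of scope); missing continuous
  values are an error.
* All-equal coefficient curves, sub-4-point curves, empty lasso supports and
  empty theme maps all take defined, logged exits rather than guessing.

## Open design points, resolved

* Whether sorting uses signed or absolute coefficients is not determined by
  the method's description; both are first-class (`ranking_mode`), absolute
  is the default for the reason above, and the mode is recorded on every
  curve.
* The printed likelihoods omit an intercept; it is treated as present and
  unpenalized, the convention of every mainstream implementation.
* $\lambda$ is re-tuned for each penalty in every iteration rather than
  frozen at round 1; the active set changes between iterations, so the
  round-1 optimum has no privileged status.
* Whether a theme drop should occur in an iteration that already satisfies a
  stopping rule is ambiguous; stopping is checked first, so a terminating
  iteration drops nothing.
* Records are not filtered on fecundity or sterilization status; the
  generator treats all records as at-risk, and eligibility filtering belongs
  in the caller's catalog.

## Problem sizes used in the test suite

The suite exercises the full pipeline at reduced scale chosen to keep a
complete run in tens of minutes on a single CPU: unit tests use 200–10,000
respondents; end-to-end recovery checks run the full 20,000-respondent
default conditions across ten seeds; the network validator runs ten seeds at
8,000 respondents with three strong themes. These sizes are the package's
own testing design; the generator accepts arbitrary `n`.

## Known limitations

* The theme map is an input. The package deliberately does not cluster or
  embed variables into themes; garbage maps yield garbage themes, reported
  honestly as such.
* Knee selection on smooth, noise-dominated coefficient curves remains the
  pipeline's most delicate stage: the knee moves with sampling noise, so the
  number of selected features — and hence which themes validate in a given
  iteration — varies across seeds, and weak themes (planted magnitude near
  the bottom of the 0.5–1.0 range) may only surface after several drops, or
  not at all if a stopping rule fires first.
* Unweighted likelihoods: complex-survey design features are out of scope,
  so estimates describe the sample, not a design-weighted population.
* The NN validator corroborates *selection*, not effect sizes; with four
  hidden layers on tabular dummies it is a sanity check against gross
  non-linearity, not a calibrated probability model.
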