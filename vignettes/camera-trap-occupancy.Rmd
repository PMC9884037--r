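---
title: "Camera-trap community metrics and single-season occupancy modelling with camoccu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-trap community metrics and single-season occupancy modelling with camoccu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camoccu)
```

camoccu implements the standard analysis chain for a single-season
camera-trap survey of a terrestrial mammal community: independent-event
extraction and trap rates, community richness/diversity/similarity,
detection-history construction, single-season occupancy models with
imperfect detection, parametric-bootstrap goodness-of-fit, and two-stage
QAICc covariate selection. This vignette explains the models and the
design decisions behind each stage; the worked example in the README
shows the code in action.

## From images to independent events

A camera records bursts of images when an animal lingers, so raw records
overstate activity. Within each (station, species) stream sorted by
time, `deduplicate_events()` starts a new *event* whenever the gap from
the previous retained image is at least the independence interval
(default 60 minutes). Two choices deserve note:

* **The gap is measured from the most recent image of the ongoing
  sequence**, not from the sequence start. This is the common
  camera-trap convention; the alternative (sequence-start anchoring)
  yields slightly more events for long visits. Stating it explicitly
  makes event counts reproducible.
* **A gap exactly equal to the interval opens a new event** (the rule
  is "at least"), and the rule does not reset at midnight or at camera
  service visits.

The relative abundance index is then
\(\mathrm{RAI} = 100 \times \text{events} / \text{trap-days}\), computed
per station and globally. RAI counts events, not individuals: the
per-image animal count is carried on each event but does not enter the
index. Effort (trap-days) comes from the station operation log, with
date intervals inclusive on both ends and a day counting as effort if
the camera ran during any part of it; the log is silent on partial days,
and whole-day counting is the simplest defensible rule.

## Community structure

All community metrics work from incidence (which stations detected a
species at least once) or from global RAI values; livestock and other
domestic species are excluded via a configurable blocklist because
fencing differences between land uses make their detectability
incomparable.

* **Richness.** Observed richness \(S_{obs}\) plus the first-order
  Jackknife correction
  \(\hat S = S_{obs} + f_1 (n-1)/n\), where \(f_1\) is the number of
  species seen at exactly one of \(n\) stations. Both values are
  reported; they coincide only when no species is a single-station
  unique.
* **Rarefaction.** Sample-based expected richness for a subsample of
  \(h\) stations is computed analytically,
  \(E[S_h] = \sum_j \bigl(1 - \binom{n-n_j}{h} / \binom{n}{h}\bigr)\),
  with \(n_j\) the number of stations occupied by species \(j\)
  (evaluated on the log scale for numerical safety). A seeded
  resampling mode exists purely as a cross-check; the analytic curve is
  exact and deterministic.
* **Diversity.** Shannon–Wiener \(H' = -\sum p_i \ln p_i\) (nats) and
  Simpson's index in the Gini–Simpson form \(D_s = 1 - \sum p_i^2\),
  with proportions \(p_i\) taken from global RAI values. The
  Gini–Simpson form is the one whose magnitudes (about 0.9 for a
  25-species community of fairly even trap rates) match how such
  surveys are usually summarised; the inverse form \(1/\sum p_i^2\) is
  available as an option. Both indices are scale-invariant in the
  weights, so using RAI rather than raw event counts changes nothing
  when effort is shared.
* **Similarity.** With \(A\) shared species and \(B, C\) unique to each
  community: Jaccard \(J = A/(A+B+C)\), Sørensen
  \(CC = 2A/(2A+B+C)\), and the Sørensen ecological distance
  \(D_{CC} = 1 - CC\). \(J \le CC\) always.

## Detection histories

`daily_history()` scores each station-day as 1 (at least one event), 0
(operational, no event) or missing (camera not operational) — at most
one detection per 24-hour period. `collapse_occasions()` merges days
into k-day sampling occasions; an occasion is 1 if any constituent day
is 1, 0 if at least one day was operational without a detection, and
missing only when no day was operational.

Occasion blocks are anchored at the survey start date and the final
partial block is kept as a shorter occasion: dropping it would silently
discard effort, and anchoring per-station first-active days instead
would give stations incomparable occasion grids. One consequence worth
knowing: cell-count monotonicity (fewer 1-cells and missing cells as k
grows) is guaranteed only along nested chains of occasion lengths
(k, 2k, 4k, ...), because non-nested grids can split a detection pair
differently. Naive occupancy, by contrast, is invariant to k.

`filter_stations()` drops sites operational for less than 80% of
occasions (configurable); the fraction is computed on the collapsed
history, matching how such filters are usually phrased ("fewer than 80%
of occasions").

## The occupancy model

For site \(i\) with detection history \(y_{it}\) over non-missing
occasions, occupancy \(\psi_i\) and detection \(p_i\) follow logit-linear
models in site covariates, and the likelihood contribution is

\[
L_i = \begin{cases}
\psi_i \prod_t p_i^{y_{it}} (1-p_i)^{1-y_{it}} & \text{if any } y_{it}=1,\\[4pt]
\psi_i \prod_t (1-p_i) + (1-\psi_i) & \text{otherwise.}
\end{cases}
\]

Missing occasions contribute nothing (missing-at-random). Logit links
are the universal convention for this model family. Fitting is
quasi-Newton (BFGS) from a multi-start set — the zero vector plus four
deterministic random jitters, so repeated fits are identical and the
caller's RNG stream is untouched — with convergence at a relative
objective tolerance of 1e-10 and standard errors from the inverse
central-difference Hessian. Fits with any coefficient beyond ±10 on the
logit scale are flagged as boundary cases (e.g. intercept-only fits
where every site was detected push \(\hat\psi \to 1\)); the naive
estimate \(\psi_{naive}\) (detected sites / sampled sites) is always
reported alongside, and the intercept-only MLE can never fall below it.

## Goodness-of-fit, overdispersion and occasion length

`mb_gof()` computes a Pearson chi-square over detection histories:
sites are grouped into cohorts sharing a missingness pattern; within a
cohort the observed count of each realised history is compared with its
expected count \(E_h = \sum_i P(h \mid \hat\psi_i, \hat p_i)\). Realised
histories with \(E_h < 0.5\) are pooled into a single cell, and the
probability mass of all unrealised histories forms a separate remainder
cell (observed zero, contributing its expected count). Pooling the
realised-but-rare cells keeps the statistic finite on sparse data; the
remainder must stay separate, since merging the two cancels the
statistic exactly whenever every realised history is rare.

The statistic is calibrated by a parametric bootstrap: simulate from
the fitted model (preserving the missingness pattern), refit, recompute.
The p-value is the proportion of replicate statistics at least as large
as the observed one, and the overdispersion statistic is
\(\hat c = \chi^2_{obs} / \overline{\chi^2_{boot}}\). Refit failures
inside the bootstrap are dropped and counted. The default is 1000
replicates; 100 is adequate for exploratory runs and is what the
package's own quick checks use. Note that \(\hat c\) is a ratio against
a right-skewed bootstrap mean: on long sparse histories it is noisy and
tends to sit below 1 even for well-specified models, which is one more
reason to collapse occasions.

`select_occasion_length()` runs collapse → filter → global-model fit →
bootstrap GoF for each candidate k (default 5–11 days) and picks the k
whose \(\hat c\) lies closest to 1 among those with
\(0.90 \le \hat c \le 3\) and \(p > 0.05\). Ties (after rounding the
distance to 9 decimals, so 0.9 and 1.1 tie exactly) go to the smaller
k. When no k qualifies the species is flagged for insufficient model
fit — a reported outcome, not an error, since excluding such species is
part of the method.

## Covariate screening and two-stage QAICc selection

Continuous covariates are z-scored (mean/sd recorded for
back-transformation), categoricals dummy-coded against a reference
level, and collinearity screened by variance inflation factors
(VIF \(= 1/(1-R^2)\) from regressing each design column on the rest).
The largest VIF above the threshold (default 3) is removed iteratively;
an exactly collinear pair yields an infinite VIF and the later column in
input order is dropped.

Model ranking uses
\(\mathrm{QAICc} = -2\log L/\hat c + 2K + 2K(K+1)/(n-K-1)\) with
\(n\) = number of sites (the standard effective sample size for
occupancy QAICc), \(\hat c\) floored at 1 (underdispersion is not used
to inflate the likelihood, though the raw value still drives the
occasion-length rule), and \(K\) incremented by one for the estimated
\(\hat c\) whenever \(\hat c > 1\). Akaike weights are
\(w = e^{-\Delta/2} / \sum e^{-\Delta/2}\); QAICc ties break by smaller
K, then input order.

Because the full candidate set over all covariates is combinatorially
vast, selection is two-stage: first detection structures are ranked
with occupancy held intercept-only; the best detection structure is
then fixed while occupancy structures are ranked. Additive models only,
capped at 4 terms by default — the cap is the reproducible surrogate for
the informal stepwise restrictions such studies apply. Models with
\(\Delta\mathrm{QAICc} < 2\) and \(w > 0.10\) are retained, and each
covariate in a retained model is classified by its Wald 95% CI:
**strong** when the CI excludes 0, **medium** when it overlaps 0 but the
estimate lies more than one standard error from 0, **weak** otherwise.
"Centred on 0" has no standard formula; the one-standard-error rule is
the documented operationalisation and is scale-equivariant. The
reported per-covariate weight is the summed weight of retained models
containing the term; non-converged candidates are listed but excluded
from ranking.

## The synthetic-survey generator

`generate_survey()` draws a landscape (continuous covariates from
stated distributions, categorical levels from stated probabilities,
binary flags as Bernoulli), truncates a station's operation interval at
a uniform day with the specified failure probability, then generates
each species from the same process the model assumes: occupancy
Bernoulli(\(\psi_i\)) from logit-linear covariates, daily detection
Bernoulli(\(p_i\)), and on each detected day 1 + Poisson extra image
timestamps inside a 2-hour burst window starting at a random time of
day — guaranteeing both sub-60-minute and over-60-minute gaps so event
de-duplication is genuinely exercised. Everything is reproducible from
a single seed.

The default configurations mirror a paired-region design: 73 stations
over 151 days with about one expected failure, and 64 stations over 132
days with about three. `generate_two_communities()` builds two full
surveys whose species pools overlap exactly as specified; pool members
without explicit parameters get moderate occupancy (logit-normal around
0.6) and daily detection around 0.12, high enough that at survey scale
every pool member is detected with near certainty, so similarity
metrics have exact expectations.

What the generator does *not* emulate: spatial autocorrelation between
stations (the model likewise treats sites as independent, which is why
estimates from clustered designs should be read as "space-use" rather
than occupancy), behavioural responses to cameras, temporal trends in
detectability within the season, and animal movement. Passing the
package's recovery tests therefore shows the estimators are correct for
the assumed process, not that the assumptions hold in any particular
field system.

## Numerical choices and problem sizes

* Likelihood evaluations clamp probabilities at 1e-300 before taking
  logs, so hard-boundary parameter values stay finite.
* Rarefaction uses `lchoose` differences rather than binomial
  coefficients directly.
* The package's statistical checks run at sizes chosen to give stable
  Monte-Carlo behaviour while staying quick: slope recovery over 50
  replicates of 200 sites × 10 occasions; GoF self-consistency over 20
  fits with 100 bootstrap replicates each; selection consistency over
  25 replicates with effect size 1.5 on the logit scale; rarefaction
  against a 10,000-permutation oracle.
* Intercept-only maximum-likelihood fits are verified against a dense
  grid search over \((\psi, p)\) at 1e-4 resolution.

## Known limitations

Single season only; site-level (not occasion-level) detection
covariates; additive candidate models only; no model averaging of
coefficients (directions and weights are reported instead); no
spatial-autocorrelation correction; no abundance-based rarefaction or
Chao-type estimators beyond Jackknife-1. The bootstrap \(\hat c\) is
noisy for species with long, information-rich histories — exactly the
situation the occasion-length selection is designed to avoid.
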