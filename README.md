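# camoccu

Community metrics and single-season occupancy modelling for camera-trap
surveys of terrestrial mammals.

Camera-trap studies of predators and their prey face two linked
problems. First, raw image counts conflate animal activity with camera
behaviour, so records must be collapsed into *independent events* (image
sequences separated by at least 60 minutes) before trap rates — relative
abundance indices, events per 100 trap-days — mean anything. Second,
animals present at a site are not always photographed, so the proportion
of sites with detections understates how much of the landscape a species
uses. camoccu implements the full analysis chain that addresses both:

* **Events and trap rates** — the ≥60-min independence rule (measured
  from the most recent image of the running sequence) and
  RAI = 100 × events / trap-days, per station and globally.
* **Community structure** — first-order Jackknife richness
  S&#770; = S<sub>obs</sub> + f₁(n−1)/n, analytic sample-based
  rarefaction, Shannon–Wiener H′ and Gini–Simpson D<sub>s</sub>
  diversity from RAI weights, and Jaccard J = A/(A+B+C) /
  Sørensen CC = 2A/(2A+B+C) similarity between communities.
* **Occupancy with imperfect detection** — detection histories (max one
  detection per 24 h, collapsed into 5–11-day occasions, stations with
  <80% operational occasions dropped) feed the single-season
  zero-inflated detection likelihood with logit-linear covariates on
  occupancy ψ and detection p, fitted by maximum likelihood.
* **Model checking and selection** — parametric-bootstrap
  goodness-of-fit with the overdispersion statistic
  ĉ = χ²<sub>obs</sub> / mean(χ²<sub>boot</sub>) (also used to choose
  the occasion length), VIF screening of z-scored covariates, two-stage
  (detection first, then occupancy) QAICc ranking with Akaike weights,
  and 95%-CI strength-of-evidence classes for covariates in retained
  models.
* **Synthetic surveys** — a generator with known parameters (landscape
  covariates, station failures, daily Bernoulli detections, within-day
  image bursts) so every stage of the pipeline is testable end to end.

The methods vignette (`vignettes/camera-trap-occupancy.Rmd`) documents
the models, defaults and design decisions in detail.

## Worked example

Simulate a 40-station, 90-day survey in which a leopard-like species
uses areas further from human habitation (true ψ slope 1.2 on the
z-scored logit scale, daily detection 0.06), then run the pipeline:

```r
library(camoccu)

spec <- sim_spec(
  n_stations = 40, survey_days = 90, failure_rate = 0.05,
  species = list(
    leopard = list(
      beta_psi = c("(Intercept)" = 0.8, dist_habitation_m = 1.2),
      beta_p   = c("(Intercept)" = qlogis(0.06)))))
survey <- generate_survey(spec, seed = 42)

events <- deduplicate_events(survey$records, interval_minutes = 60)
effort <- effort_days(survey$oplog, survey$window)
compute_rai(events, effort$per_station)
#> Relative abundance indices (events per 100 trap-days)
#>   1 species, 40 stations, 3544 total trap-days
#>  species events effort_days  rai
#>  leopard    169        3544 4.77
```

169 independent events over 3,544 trap-days give a trap rate of 4.77
events per 100 trap-days. Build a 7-day-occasion detection history,
drop poorly operational stations, and fit the occupancy model:

```r
daily <- daily_history(events, survey$oplog, "leopard", survey$window)
h     <- filter_stations(collapse_occasions(daily, 7), 0.80)$history
unlist(naive_occupancy(h))
#> n_detected_sites  n_sampled_sites        psi_naive
#>       25.0000000       39.0000000        0.6410256

screened <- screen_covariates(survey$covariates, threshold = 3)
fit <- fit_occupancy(h, screened$data, psi = ~ dist_habitation_m, p = ~ 1)
fit
#> Occupancy model: 39 sites, logLik -232.940, K = 3
#> Occupancy (psi), logit scale:
#>                   estimate     se
#> (Intercept)         1.1454 0.5566
#> dist_habitation_m   1.9887 0.9046
#> Detection (p), logit scale:
#>             estimate     se
#> (Intercept)  -0.5654 0.1162
```

Naive occupancy is 0.64, but accounting for imperfect detection the
occupancy intercept corresponds to ψ ≈ 0.76 at average distance from
habitation, with a positive habitation slope bracketing the generating
value (1.99 ± 0.90 vs. true 1.2). Check fit and rank candidate models:

```r
gof <- mb_gof(fit, n_boot = 100, seed = 1)
gof
#> Bootstrap GoF: chi2 = 3348.143, p = 0.420, c-hat = 1.006 (100 reps)

two_stage_selection(h, screened$data,
                    candidates_p   = "altitude",
                    candidates_psi = c("dist_habitation_m", "livestock"),
                    c_hat = gof$c_hat)
#> Two-stage QAICc selection (c-hat = 1.006, n = 39 sites)
#> Best detection structure: p(.)
#> Occupancy-stage ranking (top 5):
#>                                  model     logL K converged   QAICc delta_QAICc weight
#>            psi(dist_habitation_m) p(.) -232.940 4      TRUE 472.498       0.000  0.649
#>  psi(dist_habitation_m+livestock) p(.) -232.274 5      TRUE 473.814       1.317  0.336
#>                            psi(.) p(.) -238.318 3      TRUE 480.704       8.207  0.011
#>                    psi(livestock) p(.) -237.855 4      TRUE 482.275       9.777  0.005
#> Evidence for covariates in retained models:
#>          covariate parameter direction strength weight
#>  dist_habitation_m       psi         +   strong  0.984
#>          livestock       psi         +   medium  0.336
```

The bootstrap p-value (0.42) and ĉ ≈ 1.01 indicate an adequate global
model. QAICc ranking retains the habitation model (and its livestock
extension) and classifies the habitation effect as strong positive
evidence — the covariate that actually generated the data.

A thin command-line wrapper over the same functions is installed at
`inst/cli/camoccu.R`, with subcommands `simulate`, `events`, `rai`,
`community`, `history`, `fit` and `select` (each takes `--config`,
`--out`, `--seed`, `--log-level`).

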