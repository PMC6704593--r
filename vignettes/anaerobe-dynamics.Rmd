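---
title: "Modeling antibiotic effects on commensal anaerobes during HCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling antibiotic effects on commensal anaerobes during HCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaerodyn)
```

## The scientific problem

Hematopoietic cell transplantation (HCT) exposes the gut microbiota to
cytotoxic conditioning, immune ablation and layered broad-spectrum
antibiotics. The commensal obligate anaerobes — the *Clostridia* and
*Negativicutes* classes and the *Bacteroidetes* and *Fusobacteria* phyla,
which dominate a healthy colon and underpin colonization resistance — are
frequently decimated, and their loss is associated with bloodstream
infection, graft-versus-host disease and mortality. Attributing that loss
to *individual* drugs is hard: antibiotics overlap in time, prophylaxis
coincides with treatment phases, and 16S relative abundances alone cannot
distinguish anaerobe death from blooms of other taxa.

`anaerodyn` addresses this with three ingredients: (i) absolute densities,
reconstructed by multiplying 16S relative abundances by qPCR total 16S
copies per gram of stool; (ii) a growth-rate view of the dynamics, using
per-day log changes between closely spaced samples; and (iii) a Bayesian
hierarchical regression that allocates growth-rate changes to drugs,
phases and patients while sharing strength where data are thin.

## Absolute abundance, diversity, volatility

For a sample with composition $x_i$ and qPCR total $Q$ (16S copies/g wet
stool), taxon densities are $x_i Q$ and the anaerobe density is
$N = Q \sum_{i \in \text{anaerobes}} x_i$. 16S copies/g is used directly
as the community density axis — no per-taxon rRNA operon copy-number
correction is attempted, so "cells/g" should be read as "16S copies/g"
throughout; output headers say so.

Diversity is the inverse Simpson index $1/\sum_i p_i^2$, an effective
number of equally abundant taxa, computed here on the genus-grouped
composition. Day-to-day turnover between consecutive samples of one
patient is the volatility

$$V(t + \Delta t/2) = \frac{1}{2\,\Delta t} \sum_{i}
  \left| X_i(t + \Delta t) - X_i(t) \right|,$$

half the Manhattan distance between genus-level compositions divided by
the gap $\Delta t$ in days. $V$ ranges from 0 (no change) to 1 (complete
replacement of the community over one day); the $1/\Delta t$ factor makes
it a per-day turnover fraction, so consecutive samples are compared
regardless of gap length. Taxa lacking a genus name are grouped under
their lowest named rank (prefixed `unclassified-`) rather than discarded,
preserving compositional mass.

## The regression dataset ("deltas")

For every pair of *adjacent* samples of a patient at most 2 days apart and
inside the first hospitalization,

$$y = \frac{\log N(t_\mathrm{end}) - \log N(t_\mathrm{start})}{\Delta t}
  \quad [1/\mathrm{day}],$$

with natural logs (per-day e-fold rates). Binary covariates mark whether a
drug's administration interval intersects $[t_\mathrm{start},
t_\mathrm{end}]$, and whether the interval intersects phase I
(conditioning start to day 0) or phase II (day 0 to engraftment). Only
adjacent pairs are used — never all pairs within two days — so no day is
double-counted in overlapping intervals. The capacity regressor is the
start-of-interval density scaled by `N_ref` (default $10^{11}$ copies/g,
the order of a healthy community), which keeps the capacity coefficient
O(1) under its regularizing prior and is the only choice usable in forward
simulation (an end-of-interval regressor cannot be evaluated before the
step is taken).

**Below-detection densities.** A zero anaerobe density means the group fell
below the sequencing detection limit — a per-sample *fraction* of the
community, not a fixed density. By default such pairs are dropped
(`zero_policy = "drop"`): the remaining deltas are fully observed and
effect estimates are unbiased. The alternative `"floor"` policy imputes
zeros at half the smallest observed nonzero density before logging; it
retains detection-crossing intervals but exaggerates the implied drop
whenever the true density is above the global floor (e.g. when a bloom of
other taxa pushes the anaerobe *fraction* below detection while the
anaerobe *density* is unremarkable), inflating both effect magnitudes and
the residual sd — we verified this behavior on synthetic cohorts, which is
why it is not the default. Pairs with *both* endpoints censored carry no
rate information under either policy and are always dropped. A principled
treatment would be a censored (Tobit-type) likelihood; that is left as a
limitation.

## The hierarchical growth model

$$y_j \sim \mathcal{N}\!\left(
 r + \beta_{p1}\,\mathrm{phaseI}_j + \beta_{p2}\,\mathrm{phaseII}_j
 + \textstyle\sum_i \beta_{a_i} A_{ij}
 + \sum_g (\beta_o + o_g)\, O_{gj}
 + p_{\mathrm{pat}(j)} + \beta_c\, \tilde N_j,\; \sigma_m \right)$$

The seven empirical (fever-triggered) antibiotics get independent,
unpooled effects under effectively flat $\mathcal{N}(0, 100^2)$ priors, as
do $r$ and the phase effects. The four prophylactic agents share a pooled
effect $\beta_o$ with per-agent deviations $o_g$ — prophylaxis is
routine, collinear with the phases, and individually data-poor, so partial
pooling stabilizes it. Patients get partially pooled random intercepts.
$\beta_o$, $\beta_c$ and the hierarchy scales carry regularizing
$\mathcal{N}(0, 0.1)$ (sd $\approx 0.316$) priors; $\sigma_m$ and the two
hierarchy scales are half-Normal. Both hierarchies are parameterized
non-centered ($o_g = \eta_g \tau_O$, $\eta_g \sim \mathcal{N}(0,1)$), the
standard cure for funnel geometry with few groups. When two prophylactic
agents are co-administered both contribute $(\beta_o + o_g)$, mirroring
the additive treatment of empirical antibiotics.

Sampling uses Gibbs/slice MCMC via JAGS with 3 independent chains and
10,000 total post-warmup draws (1,000 warmup, 500 adaptation) by default;
a fit of a ~250-observation cohort takes a few seconds, and every fit
attaches split R-hat and effective sample sizes (`$diagnostics`). The
pooled prophylaxis effect mixes slowest (it trades off against its
deviations and the phase indicators); at the default draw count its R-hat
is ≤ 1.01 in our runs. Covariates never observed in a cohort are flagged:
their posteriors simply return the prior (intervals of roughly ±200),
which is the honest statement that the cohort contains no information
about them.

## Prediction

**Per-patient forward simulation** starts at the first observed anaerobe
density and advances along the observed sampling days: at each step, 100
parameter vectors are drawn jointly from the posterior, the per-day log
change $\mu$ is computed for each (without observation noise — the latent
density is being predicted, not a noisy measurement of it), and the
density advances by $\exp(\overline{\mu}\,\Delta t)$. The capacity term
uses the running simulated density.

**Course-resampling loss.** All maximal consecutive runs of administration
days of each drug class are compiled with their day-by-day context (phase
flags, coadministered covariates). Each Monte-Carlo resample picks a
course uniformly with replacement and one joint posterior draw, then
integrates the mean model daily from a normalized density of 1
(interpreted as `N_ref` on the capacity scale, so the capacity
contribution is $\beta_c$ times the running normalized density), recording
the end-of-course fold change $e^{\sum_d \mu_d}$. The residual fraction is
the mean fold change; percent loss is $100(1 - \text{residual})$. The
course patient's random intercept is included — courses are real
patient-context objects, and "parameters drawn jointly from the posterior"
naturally includes that patient's intercept; with intercept sds of ~0.1/day
this is second-order. Whether the reported distribution should be over
resamples (used here) or over posterior draws of the mean is ambiguous;
over-resamples matches the Monte-Carlo procedure described above.

## The synthetic cohort generator

No patient-level data ship with the package; the generator produces
cohorts with the statistical structure the analysis assumes, plus ground
truth, so the whole pipeline is testable. Defaults emulate the study
conditions of an 18-patient HCT inpatient cohort:

| quantity | default | rationale |
|---|---|---|
| patients | 18, 14 allogeneic | cohort composition |
| conditioning start | 7–10 d before day 0 | conditioning practice |
| engraftment day | uniform 10–20 | neutrophil recovery window |
| hospitalization | 20–38 d | admission-to-discharge range |
| sampling-day retention | 0.77 | fraction of inpatient days sampled |
| amplification success | 0.87 | fraction of samples yielding 16S |
| ciprofloxacin (po) | day −2 → engraftment, all patients | Gram-negative prophylaxis |
| vancomycin (iv) | admission → engraftment, allo only | viridans-streptococci prophylaxis |
| PJP prophylaxis | TMP-SMX 0.45 / atovaquone 0.25 / none 0.30; start early (p 0.3) or post-engraftment | practice varies |
| fever | p 0.85, uniform day in phase II | neutropenic fever |
| empirical course | pip-tazo 0.5 / cefepime 0.25 / meropenem 0.25; 5–10 d | empirical practice |
| generative effects | β_piptazo −1.5, β_mero −1.2, β_cefepime −0.6, β_p2 −0.3, σ_m 0.5 (per day) | strong/moderate bactericidal effects and a phase-II insult |

The latent anaerobe density evolves daily by exactly the fitted mean law
plus $\mathcal{N}(0, \sigma_m)$ log-space shocks — generation matches the
likelihood, so parameter recovery is well-posed by construction;
misspecification stress tests (heavier-tailed shocks, capacity feedback)
are config options, not defaults. Non-anaerobe density follows an
independent log10 random walk (sd 0.1/day). Observations add: a Dirichlet
compositional draw around the latent anaerobe/other split across a
27-taxon panel spanning all the classification groups, with concentration
5×10⁴ — the scale of a typical ~50k-read amplicon library, whose
multinomial noise a Dirichlet of that concentration approximates; a
read-depth detection limit of 10⁻⁴ (fractions below it read as zero,
~5 reads); and a log10-normal qPCR multiplier (sd 0.05, i.e. ~12%
technical noise). These observation layers are what make recovery a real
test rather than a tautology: they are small enough that $\sigma_m$
remains attributable to process noise, but nonzero so the estimators face
measurement error, censoring and compositional coupling.

What the generator does **not** emulate: read-count data (it emits
fractions, not counts), chimeras and sequencing error, antibiotic-driven
blooms of specific facultative taxa (the non-anaerobe walk is neutral),
inter-taxon ecological interactions, multiple admissions, and
time-varying qPCR efficiency. Passing recovery tests therefore shows the
inference machinery is correct under the stated noise model — not that the
model is a complete description of real HCT microbiota.

## Numerical choices and degenerate inputs

* Natural logs everywhere; rates are per-day e-folds.
* Closed whole-day administration intervals; phase windows are half-open
  ([conditioning, 0), [0, engraftment)), so day 0 belongs to phase II.
* Abundance vectors are renormalized at the IO boundary when their raw sum
  is within 0.05 of 1, rejected otherwise; samples without qPCR are
  dropped with a warning; unmapped drug names are a hard error.
* An empty delta table is allowed in `fit_anaerobe_model()` and returns
  prior draws (used by the prior-predictive test).
* `volatility()` errors on non-positive gaps; diversity errors on all-zero
  compositions; the generator refuses probabilities outside [0,1] and
  degenerate hospitalization windows.
* Monte-Carlo defaults: 10,000 course resamples, 100 forward-simulation
  draws per step; all entry points take explicit seeds and reruns are
  byte-identical (`manifest.json` records md5 checksums).

## Known limitations

* Censored (below-detection) endpoints are excluded rather than modeled;
  a Tobit likelihood would use them.
* Consecutive deltas share endpoints, so measurement error induces weak
  negative correlation between adjacent observations that the independent
  Gaussian likelihood ignores.
* Δt = 2 deltas average two daily shocks, halving their residual variance
  relative to Δt = 1 deltas; the single-σ_m likelihood ignores this (as
  does the averaging of the two days' exposure status).
* Drug→class mapping ships only for agents common on HCT services; it is
  user-extensible via the `map` argument of `read_cohort()`.
* The capacity term uses start-of-interval density; with the near-zero
  capacity coefficients typical of depleted cohorts the distinction from
  an instantaneous logistic term is negligible.
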