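# anaerodyn

Quantifying antibiotic-induced loss of commensal obligate anaerobes from
longitudinal stool microbiome time series of hematopoietic cell
transplantation (HCT) inpatients.

HCT patients receive cytotoxic conditioning and layered antibiotics while
their gut microbiota is sampled (near-)daily. `anaerodyn` is for analysts of
such cohorts who have, per patient: a 16S relative-abundance table, qPCR
total 16S copies per gram of stool, medication administration records, and
clinical milestones (conditioning start, cell infusion = day 0, neutrophil
engraftment, hospitalization window). The package reconstructs **absolute**
bacterial densities, quantifies community turnover, and attributes changes
in the commensal obligate anaerobe community (classes *Clostridia* and
*Negativicutes*, phyla *Bacteroidetes* and *Fusobacteria*) to individual
antibiotics and treatment phases.

## The model

For each pair of samples at most 2 days apart within the first
hospitalization, the per-day natural-log change of the anaerobe density
*N* is

    y = (log N(t_end) − log N(t_start)) / Δt

and is modeled as a Gaussian linear regression with a logistic-growth
capacity term:

    y ~ Normal( r + β_p1·phaseI + β_p2·phaseII + Σᵢ β_aᵢ·Aᵢ
                + Σ_g (β_o + o_dev_g)·O_g + p_int[patient]
                + β_c·N(t_start)/N_ref ,  σ_m )

* `r` — intrinsic growth rate (1/day)
* `β_p1`, `β_p2` — conditioning (phase I) and preengraftment neutropenia
  (phase II) effects
* `β_aᵢ` — unpooled effects of 7 empirical antibiotics
  (piperacillin-tazobactam, meropenem, metronidazole, cephalosporins
  generations 1–3, oral vancomycin, cefepime, linezolid)
* `β_o + o_dev_g` — partially pooled effects of 4 prophylactic agents
  (fluoroquinolones, i.v. vancomycin, trimethoprim-sulfamethoxazole,
  atovaquone)
* `p_int` — per-patient random intercept; `β_c` — capacity coefficient;
  `σ_m` — residual sd

Priors are Normal(0, 100²) on `r`, phase and empirical-antibiotic effects
and regularizing Normal(0, 0.1) on the pooled/hierarchical terms; the
posterior is sampled by MCMC (3 chains, 10,000 draws by default) with
R-hat/ESS diagnostics attached. The posterior then drives per-patient
forward simulation and a course-resampling estimate of the anaerobe loss
caused by a typical course of a given antibiotic.

Also included: inverse Simpson diversity, the compositional volatility
statistic V = (1/2Δt)·Σᵢ|xᵢ(t+Δt) − xᵢ(t)| (fraction of genus-level
community turnover per day, 0–1), and a synthetic-cohort generator with
known ground truth that emulates an 18-patient HCT cohort end to end.

## Worked example

```r
library(anaerodyn)

cohort    <- generate_cohort(cohort_config(), seed = 42)
density   <- density_series(cohort$samples)
deltas    <- build_deltas(density, cohort$exposures, cohort$metas)
posterior <- fit_anaerobe_model(deltas, chains = 3, draws = 10000,
                                warmup = 1000, seed = 42)
summary(posterior)
```

```
                       parameter         mean         lower         upper
1                growth rate (r)  0.282169842 -3.195450e-02   0.576950660
3                       phase II -0.158329304 -4.604554e-01   0.136187556
4        piperacillin-tazobactam -1.644276118 -1.945555e+00  -1.334274092
5                      meropenem -1.289622642 -1.752223e+00  -0.824307141
9                       cefepime -0.754995064 -1.237631e+00  -0.248998560
11              fluoroquinolones -0.205227604 -4.362094e-01  -0.016156062
17                       sigma_m  0.580254006  5.242009e-01   0.642318176
```

Each row is an effect on the anaerobe per-day log growth rate with its 95%
credible interval: here piperacillin-tazobactam multiplies the anaerobe
population by about e^(−1.64) ≈ 0.19 per day of exposure, and the interval
excludes zero decisively, while prophylactic fluoroquinolones have a much
smaller effect. (This synthetic cohort was generated with a true
piperacillin-tazobactam effect of −1.5/day; drugs never administered in a
cohort are reported with prior-width intervals of ±~200 and carry no
information.) Predicted loss over realistic courses:

```r
courses <- compile_courses(cohort$exposures, cohort$metas)
predict_course_loss(posterior, courses, "piperacillin-tazobactam",
                    n_resamples = 10000, seed = 42)
#> course loss for piperacillin-tazobactam: residual fraction 0.0001386
#> (99.99% loss) over 10000 resamples of 12 course(s)
```

i.e. after a typical piperacillin-tazobactam course (5–10 days, with its
real-life coadministrations and phase context) about 0.01% of the obligate
anaerobe population remains.

`run_pipeline(out_dir, ...)` chains every stage (densities, volatility,
deltas, fit, summaries, course loss) and writes `density.csv`,
`volatility.csv`, `deltas.csv`, `posterior.csv`, `summary.csv`, `loss.csv`
and a checksummed `manifest.json`; reruns with the same seed are
byte-identical.

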