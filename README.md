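# mtanc

Population PK/PD modelling of absolute neutrophil counts (ANC) during
oral 6-mercaptopurine (6MP) maintenance therapy of childhood acute
lymphoblastic leukemia.

Maintenance therapy steers daily oral 6MP by blood counts: the ANC should
stay below about 2 G/L (a surrogate of antileukemic activity) but above
0.5 G/L (to avoid dangerous neutropenia). `mtanc` is for modellers and
biostatisticians who want to study this feedback system quantitatively:
it couples a linear three-compartment PK model of 6MP and its active
metabolite 6-TGN to a transit-compartment (Friberg-type) myelosuppression
model, estimates population parameters by FOCE with eta–epsilon
interaction, and provides everything needed to exercise the analysis end
to end on virtual cohorts — closed-loop dose titration, CRP-based
measurement exclusion, chronological cross-validation, visual predictive
checks, and an in-silico comparison of constant mg/m² dosing protocols.

## The model

Eight coupled ODEs. PK (linear, per day):

    x6mpgut' = -ka x6mpgut            (+ F·dose impulses)
    x6mp'    =  ka x6mpgut - k20 x6mp
    x6tgn'   =  FM3 kme x6mp - CL(BSA) x6tgn,   CL(BSA) = 0.219 BSA^1.16

PD (transit chain with feedback and a linear drug effect
E = slope·x6tgn):

    xpr'  = ktr xpr (1 - E) (Base/xma)^gamma - ktr xpr
    xtr_i'= ktr (x_{i-1} - x_i)        (three maturation compartments)
    xma'  = ktr xtr3 - kma xma

The observed ANC is `xma`, with proportional residual error; the four PD
parameters (Base, ktr, gamma, slope) carry log-normal inter-individual
variability. The mean neutrophil maturation time is `3/ktr` (about 20.3
days, i.e. 487 h, at the default ktr = 0.148/day).

## Worked example

```r
library(mtanc)

pop <- population_model()          # typical population estimates
coh <- generate_cohort(pop, cohort_config(n_patients = 12), seed = 7)
flt <- filter_cohort(coh)          # drop CRP-flagged observations
flt$report
#> CRP exclusion filter: 92 of 628 observations excluded, 536 remaining

fit <- fit_population(flt$records, population_model(),
                      model = nlme_ode_model(h_rk4 = 0.2))
fit
#> FOCE-I population fit
#>   objective: 1541.031  (outer convergence code 0, 686 evaluations)
#>                 Base    k_tr  gamma   slope
#> fixed effect  2.7626  0.1650 0.7032  0.2721
#> IIV CV%      19.5197 13.9506 9.1711 44.6232
#>   residual variance sigma2 = 0.2169

accuracy_metrics(flt$records, fit, model = nlme_ode_model(h_rk4 = 0.2))
#> Accuracy (all, 12 patients): median MAE 0.830 (SD 0.221),
#>   median RMSE 1.031 (SD 0.266) G/L

vpc(flt$records, fit, n_sim = 200, seed = 1,
    model = nlme_ode_model(h_rk4 = 0.2))
#> VPC: 200 simulations, 14 bins; 94.8% of observations inside the
#>   2.5-97.5 percentile band
```

The cohort was generated at the default population values (Base 2.34
G/L, ktr 0.148/day, gamma 0.769, slope 0.242, residual variance 0.226),
so the fit is a small parameter-recovery experiment: at 12 patients the
fixed effects land within roughly 10–20 % of the generating values and
the slope IIV is correctly the dominant variance component; at study
scale (40+ patients, see the acceptance script) the biases shrink below
10 %. The per-patient median MAE/RMSE of about 0.8/1.0 G/L reflect the
47 % proportional residual noise, and the VPC confirms the simulated
percentile band covers its nominal 95 % of observations.

`simulate_protocols()` then re-simulates each fitted patient under
constant 25/50/75/100 mg/m² regimens; the cohort-median ANC falls
approximately linearly in dose (R² > 0.95), the in-silico counterpart of
the linear dose-effect relationship seen clinically.

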