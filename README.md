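# pnpcea

A decision-tree cost-utility model comparing a **single application of
capsaicin 8% patch** with **dose-optimized pregabalin** for adults with
peripheral neuropathic pain (PNP) who have failed conventional first- and
second-line systemic treatments, from a health-service payer perspective
(GBP 2013/14). It is written for health economists and HTA analysts who
want a scriptable, fully tested version of this class of model: the
deterministic cohort engine, scenario and structural analyses, one-way and
threshold sensitivity analyses, a seeded probabilistic sensitivity analysis
(PSA), and a patient-level microsimulation used as an independent
validation oracle.

## The model

Patients enter one of two arms and are classified at the 8-week assessment:

- **discontinuation** due to intolerable adverse events, with probability
  *p*<sub>disc</sub> (0% capsaicin, 8.5% pregabalin);
- otherwise **response** (≥30% reduction in the 24-hour average NPRS pain
  score) with probability *p*<sub>resp</sub>, conditional on continuing;
- non-responders and discontinuers switch to **last-line therapy**
  (duloxetine proxy), which itself succeeds with probability 20%.

Health benefit is a piecewise-linear utility trajectory per terminal
branch: responders ramp linearly from the baseline utility
*u*<sub>0</sub> = 0.57 to *u*<sub>0</sub> + Δ*u* over the median time to
onset (7.5 days capsaicin, 36 days pregabalin; Δ*u* = 0.2284 and 0.1989),
last-line responders step to *u*<sub>0</sub> + 0.2284 immediately after the
assessment. Discounted QALYs are the exact integral of the trajectory per
model year *y*, weighted by (1+*r*)<sup>−*y*</sup> with *r* = 3.5% over a
2-year horizon:

QALY = Σ<sub>y=1..H</sub> (1+r)<sup>−y</sup> · (1/365) ∫<sub>year y</sub> u(t) dt

Costs accrue per branch: capsaicin responders pay the per-application cost
(£349.99 = 1.3830 patches × £210 + 30 min of band-6 nurse time + gloves) at
the continuous retreatment rate 365/179 applications per year;
non-responders pay one application; pregabalin costs £839.50 per annum
(£1.15 × 2/day); last-line branches pay duloxetine (£361.35 per annum) from
the assessment day onward regardless of last-line response; discontinuers
see a GP (£45) and a pain specialist (£125) once. The incremental
comparison reports ΔC, ΔQ and the ICER = ΔC/ΔQ, or a dominance label.

## Worked example

```r
library(pnpcea)
params <- base_params()         # or load_config("inst/extdata/base_case.yaml")
ce <- evaluate_model(params)
print(ce$intervention); print(ce$comparator); print(ce)
```

```
Arm: capsaicin
  index therapy cost  GBP   904.65
  last-line cost      GBP   280.56
  GP/specialist cost  GBP     0.00
  total cost          GBP  1185.21
  total QALYs               1.3586
Arm: pregabalin
  index therapy cost  GBP   873.41
  last-line cost      GBP   310.51
  GP/specialist cost  GBP    13.96
  total cost          GBP  1197.88
  total QALYs               1.3097
capsaicin vs pregabalin
  incremental cost : GBP -12.67
  incremental QALYs: 0.0489
  result           : dominant
```

The patch costs slightly less over two years and gains 0.049 QALYs, so it
*dominates* pregabalin: no ICER is reported. Scenario, horizon, tornado,
threshold and PSA analyses follow the same pattern:

```r
run_scenarios(params)                      # 7 named scenarios + base case
horizon_sweep(params, 1:10)                # structural analysis
one_way(params, wtp = 20000)               # tornado, NMB-span ranked
threshold_solve(params, "costs.t_retreat_days", 20000)   # -> 77.44 days
psa <- run_psa(params, n = 10000, seed = 1)
prob_cost_effective(psa, 20000)            # -> 0.967
simulate_cohort(params, n = 50000, seed = 2)  # microsim validation oracle
```

A command-line front-end over the same functions ships at
`system.file("cli", "pnpcea.R", package = "pnpcea")`:

```sh
Rscript pnpcea.R psa --n 10000 --seed 1 --out results/
```

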