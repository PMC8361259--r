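# pulsekin

Kinetic analysis of in-vivo 6,6-²H₂-glucose pulse-chase labeling of blood
and airway granulocytes (eosinophils and basophils), as used in randomized
trials of anti-IL-5 therapy (mepolizumab) in eosinophilic asthma.

Subjects drink deuterated glucose over a few hours; cells that divide while
the label is available incorporate ²H into their DNA. Sampling blood and
induced sputum over the following weeks and measuring the labeled fraction
of DNA deoxyadenosine by GC-MS traces each cell population's production,
transit and disappearance — without radioactivity or ex-vivo manipulation.
`pulsekin` implements the full quantitative chain for such studies:

* **Enrichment pipeline** — raw isotopomer peak areas (m/z 435/437 for DNA
  adenosine, 328/330 for plasma glucose) → tracer-to-tracee ratios
  TTR = (m+2)/m → calibration against standards of known enrichment →
  subtraction of the subject's pre-label natural-abundance baseline →
  precursor–product normalization, dividing net enrichment by *b·p̄* where
  *b* = 0.65 is the de novo synthesis (versus base salvage) fraction of DNA
  adenosine and *p̄* the subject's mean plasma glucose enrichment during
  intake. The result estimates the fraction of cells whose DNA was
  synthesized during the labeling window.
* **Conveyor-belt forward model** — granulocyte production follows a
  first-in, first-out maturation rule: cohorts leave mitosis carrying label
  *b·u(t)*, transit the postmitotic marrow pool with a shifted-exponential
  delay (shift δ₀, tail mean θ), reside in blood with exponential half-life
  t½, and a fraction φ of blood egress feeds a well-mixed airway pool of
  relative size P (residence mean r) whose resident unlabeled cells dilute
  the arriving label. Deterministic expected-value cohort simulation with
  exact mass bookkeeping, plus a closed-form degenerate-limit oracle and
  bounded least-squares parameter fitting.
* **Trial synthesis** — a generator for the complete two-arm (placebo vs
  mepolizumab, n = 10 each), two-phase (label at days 0 and 84, doses at
  days 4/32/60/88) design, with staggered per-subject sampling, noisy GC-MS
  areas and cell counts, and a truth sidecar for validation.
* **Statistics** — phase-wise simple linear regressions of enrichment on
  day (uplabeling day 0–7, downlabeling day 8–22) compared between arms by
  classical two-line ANCOVA (slope test, then elevation test under a common
  slope); exact Mann-Whitney and Wilcoxon signed-rank tests (enumerated
  null distributions in the exact range); dilution ratios relative to the
  day-7 blood peak.
* **Pipeline** — `cmd_simulate()` → `cmd_enrich()` → `cmd_analyze()` →
  `cmd_report()`, fully determined by a YAML config and one master seed,
  with a thin shell wrapper in `inst/scripts/pulsekin`.

## Worked example

```r
library(pulsekin)

cfg <- default_config(master_seed = 1L, out_dir = "demo_run")
cmd_simulate(cfg)   # synthetic 20-subject trial: measurements.csv, counts.csv, ...
cmd_enrich(cfg)     # -> enrichment.csv (normalized enrichment per sample)
cmd_analyze(cfg)    # -> results.tsv, group_medians.csv, dilution_ratios.csv
cmd_report(cfg)     # -> report.md
```

The report for this seed reads (abridged):

```
- Model eosinophil blood label detectable from day 4 to day 28.
- Model basophil blood label detectable from day 6 to day 37.

- ancova_slope_blood_eosinophil phase 1 down window: F = 203, p = 1.65e-22
- ancova_slope_blood_basophil  phase 1 down window: F = 0.5147, p = 0.475
- ancova_slope_blood_eosinophil phase 2 down window: F = 2.333, p = 0.131

- blood day 7: 1.000
- blood day 10: 0.805
- blood day 14: 0.401
- blood day 22: 0.076
```

Reading it: under the default parameters, labeled eosinophils first reach
blood on day 4 and labeled basophils on day 6 (their postmitotic transit is
longer), and blood label falls below the 0.05% detection threshold before
day 32. In the synthetic trial, downlabeling of blood eosinophils during
the first treatment phase is significantly slower in the mepolizumab arm
(the anti-IL-5 effect), basophils are unaffected, and by the second phase —
twelve weeks into treatment — the remaining eosinophils again show
placebo-like kinetics. The dilution ratios quantify the decay of the blood
peak after day 7.

The forward model alone:

```r
curve <- simulate_blood_curve(default_kinetic_parameters("eosinophil"))
detection_days(curve, threshold = 5e-4, sampling_days = 1:60)
#> $first_day [1] 4      $last_day [1] 28
```

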