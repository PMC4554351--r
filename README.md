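# incidose

Incidental nodal dose, equivalent uniform dose (EUD) and tumour control
probability (TCP) analysis for involved-field radiotherapy (IF-RT) plans in
non-small-cell lung cancer.

## What it is for

IF-RT irradiates only PET-positive disease and relies on *incidental* dose
to control microscopic disease in the elective (uninvolved) hilar and
mediastinal lymph node stations. IMRT, being more conformal than 3D-CRT,
deposits less of that incidental dose — a potential hazard that is invisible
to conventional plan metrics. `incidose` is for medical physicists and
radiation oncology researchers who want to quantify this trade-off in paired
planning studies: it scores out-of-field nodal volumes under three plans per
patient (IMRT, 3D-CRT, and `IMRT_norm` — IMRT rescaled by fraction matching
to the 3D-CRT prescription) and runs normality-gated paired statistics
across the cohort. A synthetic cohort generator makes the entire pipeline
runnable and testable without any patient data.

## The models at its core

* **DVH metrics** — Dmean, Dmax, Dx, Vx on differential/cumulative DVHs
  built from dose grids + structure masks, and the van't Riet/Paddick
  conformation number CN = TV²\_PIV / (TV · PIV).
* **Generalized EUD** — the power mean
  EUD = (Σᵢ vᵢ Dᵢᵃ)^(1/a);
  a = 1 is the mean dose, negative *a* (default −8, a package default, not a
  literature value) emphasises cold spots as appropriate for target tissue.
* **Logistic TCP** — TCP(D) = 1 / (1 + (D₅₀/D)^(4γ)) evaluated at D = EUD,
  with microscopic-disease parameters D₅₀ = 36.5 Gy, γ = 0.72 (the
  normalized slope at D₅₀).
* **Plan operations** — organ-at-risk constraint checking (lung V20 ≤ 35%,
  MLD ≤ 20 Gy; cord Dmax ≤ 45 Gy; esophagus V50 ≤ 50% or Dmean ≤ 34 Gy, and
  Dmax ≤ 70 Gy; heart V45 ≤ 67%, V60 ≤ 33%), 2-Gy prescription escalation in
  [2, 110] Gy, and fraction-matched normalization.
* **Nodal grouping** — the 13 AJCC hilar/mediastinal stations (levels 10/11
  merged per side), an overridable adjacency graph, and the two elective
  groupings: `LN_all_el` (every uninvolved station) and `LN_adj_el`
  (level 7 + ipsilateral hilum + stations bordering involved levels).
* **Paired cohort statistics** — Shapiro–Wilk-gated paired t / Wilcoxon
  signed-rank tests at p < 0.05, with mean-of-per-patient-TCP summaries.

## Worked example

```r
library(incidose)

# a structure with 25% of its volume at 20 Gy and 75% at 60 Gy
d <- dvh_from_points(c(20, 60), c(0.25, 0.75), structure = "LN_adj_el")
eud(d, a = -8)                        # 23.78 Gy  (cold spot pulls it far
                                      #            below the 50 Gy mean)
100 * tcp_from_dvh(d, radiobio_params())  # 22.6 %

# end-to-end on a small synthetic cohort
st <- run_study(study_config(seed = 42, n_patients = 5))
st
```

which prints (abridged):

```
<ln_study> 5 patients (config 1ce4ab6a6c180c9a1f3128fb319aec25)
  prescriptions: IMRT 92.0 +/- 14.1 Gy vs 3D-CRT 71.2 +/- 5.9 Gy (p = 0.0545, wilcoxon)

Cohort summary (mean +/- SD):
    volume metric      plan n             value
 LN_adj_el    EUD IMRT_norm 5  10.596 +/- 4.919
 LN_adj_el    EUD    3D-CRT 5  35.212 +/- 8.000
 LN_adj_el    TCP IMRT_norm 5   3.859 +/- 3.594
 LN_adj_el    TCP    3D-CRT 5 46.299 +/- 15.835
 ...

Paired tests:
    volume metric          comparison test_used  statistic  p_value significant
 LN_adj_el    TCP IMRT_norm vs 3D-CRT  paired-t -5.9660590 0.003960        TRUE
 LN_adj_el    EUD IMRT_norm vs 3D-CRT  wilcoxon  0.0000000 0.062500       FALSE
 ...
```

Reading it: escalation pushes the IMRT prescriptions higher than 3D-CRT, but
at *matched* prescriptions (`IMRT_norm` vs `3D-CRT`) the adjacent elective
stations receive clearly less dose — EUD 10.6 vs 35.2 Gy, TCP 3.9% vs 46.3%.
With only 5 patients the exact Wilcoxon test cannot go below p = 0.0625 even
for a perfectly consistent effect; at the default cohort size of 41 these
comparisons are decisively significant. Per-patient tables are in
`st$per_patient`, `st$ptv`, `st$oar`.

A thin command-line wrapper is installed at `inst/cli/incidose.R`
(`simulate` / `analyze` / `run` subcommands over the same functions).

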