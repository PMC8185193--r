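# MenoRad

Ovarian dose, follicle survival and premature menopause modelling for
lymphoma radiotherapy.

## What it does, and for whom

Consolidation radiotherapy for infradiaphragmatic Hodgkin lymphoma can
push young women into premature menopause. How much of that risk depends
on the choice of target volume — the larger involved-field (IFRT) versus
the smaller involved-site (ISRT) concept? MenoRad answers this for
radiation oncologists and clinical researchers who have nothing more
exotic than their planning system's dose-volume histogram (DVH) exports.

The core is a chain of three empirical models:

1. **Follicle survival** — the percentage of non-growing follicles (NGF)
   surviving an ovarian dose *z* in Gy:
   log₁₀ *g*(*z*) = 2 − 0.15 *z*.
2. **DVH summation** — survival applied bin-wise over the combined
   both-ovaries differential DVH at 0.1 Gy resolution:
   *g* = Σᵢ 10^(2 − 0.15·(dᵢ + dᵢ₊₁)/2) · vᵢ / v_both ovaries.
3. **Menopause timing** — the age-matched NGF count
   log₁₀ *n* = −0.00019·age^2.452 + 5.717, scaled by *g*, inverted in
   closed form to an effective reproductive age *r*, giving a predicted
   time to menopause *t* = max(0, 50.4 − *r*).

Paired IFRT/ISRT plans are compared per organ at risk and per theoretical
age at treatment (18–48 in two-year steps) with the exact sign test. A
companion module fits the weighted least-squares regression of log FSH /
log LH on z-scored age, sex, their interaction, chemotherapy regimen
(ABVD vs 2+2) and field location (infra- vs supradiaphragmatic). Seeded
synthetic cohort generators stand in for patient-level data, so every
stage is testable end to end.

## Worked example

```r
library(MenoRad)

# 13 paired plans with the default calibration
cohort <- simulatePairedDvhCohort(dvhSimConfig(nPatients = 13, seed = 1))

compareOarDoses(cohort, metrics = c(ovaries = "mean"))
#   mean_ifrt sd_ifrt mean_isrt sd_isrt p_value
#     15.2129  5.5188    7.1354  4.8309   2e-04

survivingNgfSummary(cohort)[, c("mean_ifrt", "mean_isrt", "p_value")]
#   mean_ifrt mean_isrt p_value
#     31.7589   50.5463   2e-04

head(compareMenopause(cohort)[, c("age_years", "mean_ifrt", "mean_isrt",
                                  "mean_diff", "p_value")], 3)
#   age_years mean_ifrt mean_isrt mean_diff p_value
#          18   21.1008   24.9192    3.8184   2e-04
#          20   20.0442   23.6402    3.5961   2e-04
#          22   18.8884   22.2683    3.3799   2e-04
```

Reading: on this simulated cohort the smaller ISRT volume halves the mean
ovarian dose (15.2 → 7.1 Gy), raises the mean surviving follicle fraction
from 31.8% to 50.5%, and buys a woman treated at 18 about 3.8 extra years
before menopause; the advantage holds in all 13 patients, so every
sign-test p equals 2·(1/2)¹³ ≈ 0.00024. The gain shrinks with age at
treatment — older ovaries have less reserve left for either plan to save.

Single predictions use the chain directly:

```r
timeToMenopause(18, 11.87)$time_to_menopause  # 15.499 years
ngfLD50()                                     # 2.007 Gy
```

The full bundle — organ-at-risk table, menopause table, hormone
regression, group summaries and a JSON manifest — is produced by
`runFullAnalysis(outDir, seed = 1)`, or from a shell via the thin wrapper
`inst/scripts/menorad-cli.R` (subcommands `simulate-dvh`,
`simulate-hormones`, `compare-oar`, `compare-menopause`, `hormones-fit`,
`hormones-predict`, `report`).

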