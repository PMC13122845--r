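# craniospinal

Craniospinal compliance — the capacity of the combined cranial and spinal
CSF space to buffer volume loads — estimated two complementary ways and
compared across a cohort. The package targets researchers in CSF dynamics
and normal pressure hydrocephalus (NPH) work-up who hold (a) cine
phase-contrast MRI flow curves of the cerebral feeding arteries and (b)
lumbar constant-rate infusion ICP recordings for the same subjects.

## The two estimates

**Physiological (cardiac-cycle) compliance.** Per subject, the flow curves
of the left/right internal carotid and basilar arteries (32 frames over one
reconstructed cardiac cycle, mL/min) are summed to the total arterial
inflow Q_ART and integrated over the cycle; the amplitude of the resulting
volume curve is the cerebral arterial volume change ΔV_ART. From the
baseline stretch of the lumbar ICP recording, an FFT band-pass removes
respiration and noise, pulse peaks segment the signal into beats, and the
beats are ensemble-averaged onto a normalized 32-point cycle whose
amplitude is ΔP_CC. Then

    C_physio = ΔV_ART / ΔP_CC        [mL/mmHg]

**Infusion-derived compliance.** During constant-rate lumbar infusion
(rate r, clinically 1.5 mL/min) mean ICP rises from baseline ICP_b to a
plateau ICP_p, detected automatically on the smoothed trend. With Δt_INF
the time from infusion start to plateau onset,

    ΔV_INF = r · Δt_INF     ΔP_INF = ICP_p − ICP_b
    C_INF  = ΔV_INF / ΔP_INF          Rout = ΔP_INF / r

Cohort statistics follow standard practice: Shapiro–Wilk-gated paired
t / Wilcoxon signed-rank comparisons with Holm correction across the
outcome family, Spearman correlation matrices, and mean ± SD / Q1–Q3 / CV%
summaries.

Because clinical recordings of this kind cannot be shared, the package
includes a seeded synthetic-cohort generator (`simulate_cohort()`)
calibrated to an elderly suspected-NPH cohort (arterial flow
426 ± 102 mL/min, pulse amplitude 3.0 ± 1.5 mmHg, pressure rise
20 ± 9 mmHg, n = 108); it writes the same file formats the readers consume
and is the basis of the validation suite.

## Worked example

```r
library(craniospinal)

co  <- simulate_cohort(seed = 7)       # default calibration, n = 108
res <- analyze_cohort(co)
res
#> <cohort_analysis> 108 subject(s), 0 excluded
#>
#> Key metrics (mean +/- SD):
#>   delta_v_art_ml               5.93 +/- 1.66
#>   delta_p_cc_mmHg              2.99 +/- 1.10
#>   c_physio_ml_per_mmHg         2.39 +/- 1.49
#>   delta_p_inf_mmHg            19.64 +/- 7.30
#>   delta_v_inf_ml              16.36 +/- 3.24
#>   c_inf_ml_per_mmHg            0.93 +/- 0.33
#>
#> Paired comparisons:
#>   duration: infusion (min) vs cardiac cycle (s) paired-t  p_holm = 2.66e-74
#>   volume change: dV_INF vs dV_ART               paired-t  p_holm = 7.12e-55
#>   pressure change: dP_INF vs dP_CC              paired-t  p_holm = 9.6e-44
#>   compliance: C_INF vs C_physio                 wilcoxon  p_holm = 5.36e-17
#>   heart rate: MRI vs infusion                   paired-t  p_holm = 0.0956
```

Reading: on this synthetic cohort the pipeline recovers a mean arterial
volume change of ~5.9 mL absorbed with a ~3.0 mmHg pulse
(C_physio ≈ 2.4 mL/mmHg), while ~16 mL infused over ~11 minutes raise mean
ICP by ~20 mmHg (C_INF ≈ 0.9 mL/mmHg): the infusion-derived compliance is
far lower than the physiological one (Holm-corrected p ≪ 0.001), the
system appearing much stiffer under sustained loading than under a
sub-second pulsatile perturbation.

Per-subject analysis of real data goes through the same functions:

```r
flows <- read_flow_curves(c("ical.csv", "icar.csv", "ba.csv"))
rec   <- read_icp_recording("icp.csv", "icp.yaml")
analyze_subject(flows, rec, subject_id = "P001")
```

A thin command-line wrapper with `simulate` / `physio` / `infusion` /
`cohort` subcommands ships in `inst/cli/csc.R`. All pipeline thresholds
(filter band, peak prominence, plateau slope, ...) live in
`analysis_config()`; the methods vignette
(`vignettes/craniospinal-methods.Rmd`) documents each choice.

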