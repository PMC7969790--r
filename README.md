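# equigait

Inter- and intra-evaluator reliability of IMU-based equine gait analysis,
end to end: simulate six-sensor inertial recordings of trotting horses,
extract the standard temporal and spatial gait variables, and quantify how
much of the measured variation comes from the horses themselves rather than
from the people operating the analysis software.

## The problem

Extremity-mounted inertial measurement units (IMUs) — gyroscope plus
accelerometer packs strapped to the metacarpal, metatarsal and tibial
segments — are used for objective lameness examination in horses. The
analysis still involves a human step: an evaluator selects a window of
steady trot strides from which the software derives a representative
stride. If that choice mattered much, the promise of evaluator-independent
gait analysis would be lost. The standard study design for this question
trots J horses on each surface, hands I evaluators K blinded copies of
every processed recording, and partitions the variance of each extracted
gait variable.

`equigait` implements that entire pipeline with a synthetic-data module in
place of the (unavailable) horse recordings, so every stage is testable
against known ground truth.

## The model

Each gait variable `Y` from horse `j`, evaluator `i`, repetition `k` is
modelled additively:

    Y_ijk = mu + alpha_i + beta_j + eps_ijk        (i = 1..I, j = 1..J, k = 1..K)

A repeated-measures ANOVA gives mean squares, from which variance
components for horse, evaluator and repetition are formed (two divisor
conventions are provided; see `?variance_components`). Reliability is then

    ICC_inter = sigma2_H / (sigma2_H + sigma2_E + sigma2_R)
    ICC_intra = (sigma2_H + sigma2_E) / (sigma2_H + sigma2_E + sigma2_R)

and the variance partitioning coefficients (VPC) are each component over
the total, summing to one. An F-test of evaluator experience
(experienced vs. inexperienced, evaluator nested in type) completes the
analysis.

On the signal side, stride segmentation uses the maximal retraction of the
left hind metatarsus as the zero point; limb phasing is the circular
cross-correlation lag of each limb's lateromedial rotation velocity
against the left hind cycle, in percent of stride; protraction/retraction
timings are sagittal-angle extrema (late-cycle protraction is recoded,
98% -> 2%); ranges of motion are per-stride angle ranges; hock symmetry is
`|L - R| / mean(L, R) * 100`.

## Worked example

```r
library(equigait)

# one horse, one recording, the 19 analysed variables
ses <- simulate_session(horse_profile(), session_protocol(n_trot_strides = 20, seed = 1))
rec <- extract_record(ses)
dplyr::select(rec, stride_duration, limb_phasing_LF, limb_phasing_RF,
              limb_phasing_RH, rom_sag_hock_L, rom_sag_hock_R, symmetry_hock)
#>   stride_duration limb_phasing_LF limb_phasing_RF limb_phasing_RH rom_sag_hock_L
#> 1           0.732              63              14              50           42.1
#>   rom_sag_hock_R symmetry_hock
#> 1           37.1          12.4
```

The extracted values match the profile that generated the session: a
0.731 s stride, limb phases of 63.1 / 13.7 / 49.5 percent for LF / RF / RH,
and hock ranges of motion of 42.1 and 37.2 degrees whose asymmetry yields
the 12.4% symmetry index.

```r
# a full reliability table under the additive model, then the report
tab <- simulate_gait_table(table_sim_spec(seed = 1))   # 6 x 10 x 3 = 180 rows
rel <- reliability_report(tab)
glance(rel)
#>   surface   mean_icc_inter_temporal mean_icc_inter_spatial mean_icc_inter_total
#> 1 treadmill                   0.898                  0.892                0.895
#>   mean_icc_intra_temporal mean_icc_intra_spatial mean_icc_intra_total
#> 1                   0.966                  0.956                0.961
tidy(rel)       # per-variable ICCs, VPCs, descriptives, experience p-values
autoplot(rel)   # dot plot of ICCs; plot_vpc(rel) for the variance partition
```

A complete blinded study — simulate, copy and blind, extract per evaluator
with individual window habits, unblind, analyse — is one call:

```r
report <- run_study(study_config())   # 3 surfaces x 10 horses x 6 evaluators x 3 copies
report$reliability$summary
```

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `horse_profile()`, `simulate_horse_profile()`, `session_protocol()`, `simulate_session()`, `table_sim_spec()`, `simulate_gait_table()` |
| Gait extraction | `calibrate_orientation()`, `integrate_orientation()`, `segment_strides()`, `stride_cycles()`, `select_window()`, `representative_stride()`, `limb_phasing()`, `temporal_variables()`, `recode_protraction()`, `spatial_variables()`, `symmetry_index()`, `classify_gait()`, `extract_record()` |
| Reliability statistics | `anova_mean_squares()`, `variance_components()`, `icc()`, `vpc()`, `experience_effect()`, `describe_variable()`, `reliability_report()` |
| Study orchestration & I/O | `study_design()`, `blind_copies()`, `unblind_table()`, `study_config()`, `run_study()`, `write_study_report()`, `write_session()`, `read_session()`, `write_gait_table()`, `read_gait_table()` |

See `vignettes/equigait-methods.Rmd` for the modelling choices, defaults
and known limitations.
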