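# pulsekit

Timing analysis of synchronized cardiovascular waveforms in R: ECG, central
aortic pressure (CAP), radial artery pressure (RAP) and radial electrical
bioimpedance (EBI).

## The problem

Pulse wave velocity (PWV) is the reference marker of arterial stiffness, but
its invasive measurement requires catheterization, and the usual
carotid–femoral assessment is impractical for continuous or wearable
monitoring. A pulsatile bioimpedance signal recorded at the wrist carries
the same arrival-time information as an invasive radial pressure line. If
the delay from the ECG R peak to the arrival of the pulse at the wrist (the
pulse arrival time, PAT) can be read reliably off the EBI waveform, a
cuffless velocity surrogate becomes possible.

`pulsekit` implements the full waveform-processing chain this idea needs,
for researchers working with multi-channel cardiovascular recordings:

* **Preprocessing** — Savitzky–Golay smoothing (0.1 s window, order 3),
  resampling to a 150 samples/s working rate, and baseline removal by
  interpolation through per-beat minima or by Hankel (trajectory-matrix)
  low-rank decomposition.
* **Beat detection and ensembles** — slope-threshold onset detection
  (`L_B = 0.15 · max(S′)`), half-open beat segmentation, ECG windows
  back-shifted by 300 ms, cross-channel synchronization, and a three-step
  outlier rejection (length filter, PCA reconstruction error, empirical
  copula tail scores) followed by duration-normalized ensemble averaging.
* **Fiducial points** — onset **B**, maximum upstroke slope **C**, peak or
  inflection **D**, systolic maximum **F** and dicrotic notch **G**, located
  from Savitzky–Golay first and third derivatives with channel-specific
  rules for peripheral (EBI/RAP) and central (CAP) morphology.
* **Timing features** — per-beat R–B delays; PAT for each channel;

  * transit time `PTT = PAT_RAP − PAT_CAP`,
  * pulse wave velocity `PWV = L_av→ra / PTT` for a measured aortic-valve to
    radial path length `L_av→ra`, and
  * complementary pulse wave velocity `CPWV = 0.8 / PAT_EBI`, the
    EBI-derived surrogate using a fixed 0.8 m representative path.
* **Cohort statistics** — Spearman correlations with Fisher-z or bootstrap
  confidence intervals, coronary-disease staging (four angiographic groups),
  six-factor cardiovascular risk counts, and exact rank-sum group
  comparisons (full enumeration, ties handled).
* **A synthetic-recording generator** — four-channel recordings with known
  ground truth (R times, onset times, dense-grid fiducials, true PAT / PTT /
  PWV, labelled artifact beats) so every stage of the pipeline is testable
  end to end. The clinical recordings this kind of analysis targets are not
  generally shareable; the generator stands in for them with controlled,
  labelled data.

## Worked example

```r
library(pulsekit)

# a 12-beat synthetic patient: central pulse arrives 90 ms after the R peak,
# radial pressure 170 ms, radial bioimpedance 150 ms, over a 0.8 m path
cfg <- sim_config(n_beats = 12, pat_cap = 0.09, pat_rap = 0.17,
                  pat_ebi = 0.15, path_length = 0.8, seed = 3)
sim <- generate_recording(cfg)
sim$truth
#> <pw_ground_truth> 12 beats; PAT cap/rap/ebi = 0.090/0.170/0.150 s;
#>   PTT = 0.080 s; PWV = 10.00 m/s; 0 artifact beat(s)

features <- build_patient_features(sim$recording)
dplyr::select(features, n_beats, pat_ebi_s, ptt_s, pwv_mps, cpwv_mps)
#> # A tibble: 1 x 5
#>   n_beats pat_ebi_s  ptt_s pwv_mps cpwv_mps
#>     <int>     <dbl>  <dbl>   <dbl>    <dbl>
#> 1       8     0.150 0.0804    9.95     5.34
```

The configured ground truth (PTT 0.080 s, PWV 10 m/s, CPWV
0.8 / 0.15 = 5.33 m/s) is recovered by the full pipeline to well under a
percent: the printed estimates are 0.0804 s, 9.95 m/s and 5.34 m/s. The
ensemble-averaged fiducial times per channel are attached as
`attr(features, "fiducial_times")`, and every beat removed along the way is
logged with its stage and score in `attr(features, "removed")`.

Cohort-level analysis works the same way on a feature table:

```r
cohort <- generate_cohort(cohort_spec(seed = 1), signals = FALSE)
roster <- cohort_roster(cohort)
compare_groups(roster$true_cpwv, roster$cad_group)
ggplot2::autoplot(spearman_with_ci(roster$true_pat_rap, roster$true_pat_ebi))
```

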