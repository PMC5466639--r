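# polrpe

Polarimetric multimodal image analysis for detecting **intraretinal RPE
migration** in age-related macular degeneration (AMD).

In AMD, retinal pigment epithelium (RPE) cells can detach and migrate into
the neurosensory retina, where they appear on OCT as small bright lesions
(hyperreflective foci, HRF). Ordinary OCT cannot tell migrated RPE from
other HRF sources (lipid, inflammatory cells). Polarimetry can: melanin
scrambles the polarization of backscattered light, so melanin-bearing HRF
depolarize on polarization-sensitive OCT (PS-OCT) and on a
polarization-sensitive scanning laser ophthalmoscope (PS-SLO), and their
granule content shows up as hyper-autofluorescence at 787 nm (NIR-AF,
melanin) and 488 nm (SW-AF, lipofuscin). `polrpe` implements the full
analysis as a tested, reproducible pipeline for synthetic (and
user-supplied) volumes:

* **Synthetic data** — a deformable retina phantom (vitreous / retina /
  RPE / choroid, drusenoid or serous PED domes, HRF with
  melanin/lipofuscin/melanolipofuscin flags) rendered as two-channel
  complex circular-Gaussian speckle fields with repeats, plus co-registered
  PS-SLO frame stacks and 8-bit AF images, with ground truth.
* **Polarimetry** — Stokes vectors from the two detection channels
  (S0 = |E1|² + |E2|², Q = |E1|² − |E2|², U = 2 Re E1E2*, V = −2 Im E1E2*)
  and the **degree of polarization uniformity**

  DOPU = sqrt((ΣQ′)² + (ΣU′)² + (ΣV′)²) / ΣS0′,

  summed over a 3 (transverse) × 3 (depth) kernel pooled across 4 repeated
  B-scans, with additive-noise correction S0′ = S0 − (n1 + n2),
  Q′ = Q − (n1 − n2); the classic normalize-then-average estimator is also
  provided. DOPU is 1 for polarization-preserving tissue and falls toward
  0 in depolarizing (melanin-containing) tissue.
* **Projections** — composite B-scans with the low-DOPU (< 0.8) area
  overlaid in red, en-face minimum-DOPU projections over the whole depth
  and anterior to a (manual or truth) RPE segmentation, mean-intensity
  en-face projections.
* **PS-SLO** — the depolarized light image as the per-pixel minimum of the
  crossed-detector frames over input polarization angles, rescaled
  min–max to 0–255.
* **Lesion quantification** — Shanbhag fuzzy-information auto-threshold
  binarization of B-scans, HRF volumes by the voxel formula
  (11.7 µm × 23.5 µm × 3.6 µm × pixel count), PED volumes by the
  Cavalieri principle (slice spacing × Σ areas).
* **Classification** — each HRF is called *migration* only when all four
  modalities concur (low DOPU, PS-SLO depolarization, hyper-NIR-AF **and**
  hyper-SW-AF at the same location); HRF overlapped by a large low-DOPU
  mass (the hard-exudate confound) are excluded. Cohen's kappa measures
  agreement between automatic graders.
* **Cohort statistics** — per-group count/percentage tables, volume
  summaries, chi-square (group vs rest), Kruskal–Wallis / Mann–Whitney
  rank tests (exact enumeration at small n), Pearson correlation with R².

## Worked example

Bias of the two DOPU estimators on uniformly polarized tissue (true
DOPU = 1) versus signal-to-noise ratio:

```r
library(polrpe)
dopu_bias_experiment(snr_list = c(100, 10, 2, 1), n_trials = 2000, seed = 1)
#>   snr mean_corrected mean_uncorrected n_trials
#> 1 100          0.999            0.959     2000
#> 2  10          0.995            0.785     2000
#> 3   2          0.974            0.508     2000
#> 4   1          0.956            0.374     2000
```

The uncorrected estimator collapses as noise randomizes the per-speckle
Stokes directions; the noise-energy correction keeps the estimate near 1
even at SNR 1 — this is why the pipeline defaults to the corrected form.

A small end-to-end run (simulate → DOPU → classify → tally):

```r
cfg <- list(counts = c(remission = 4, geographic_atrophy = 3),
            params = optic_params(n_alines = 48, n_bscans = 24, n_depth = 64,
                                  noise_energy_ch1 = 1e-4, noise_energy_ch2 = 1e-4))
res <- run_pipeline(cfg, out_dir = "results/demo", seed = 7)
res$counts
#>                group n_eyes n_migrating pct_migrating n_nonmigrating pct_nonmigrating
#> 1          remission      4           3          75.0              1             25.0
#> 2 geographic_atrophy      3           1          33.3              1             33.3
#> 3            overall      7           4          57.1              2             28.6
```

Each row tallies eyes whose HRF were classified as migrated RPE
(four-modality concordance) versus eyes with only non-migrating HRF;
percentages are recomputed from the raw per-eye records. `res$volumes`
holds the per-group HRF volume summaries (mean / SD / range in mm³) and
`results/demo/` the CSV tables and a JSON run log. A thin CLI wrapper for
the same flow lives in `inst/scripts/polrpe`.

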