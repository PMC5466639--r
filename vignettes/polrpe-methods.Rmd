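---
title: "Methods: polarimetric detection of intraretinal RPE migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarimetric detection of intraretinal RPE migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polrpe)
```

## The measurement model

A Jones-matrix OCT records, for every voxel, two complex detection-channel
fields $(E_1, E_2)$. `polrpe` converts them to Stokes parameters

$$S_0 = |E_1|^2 + |E_2|^2,\quad Q = |E_1|^2 - |E_2|^2,\quad
U = 2\,\mathrm{Re}(E_1 E_2^*),\quad V = -2\,\mathrm{Im}(E_1 E_2^*),$$

a convention pinned by tests: $(1,0) \mapsto (1,1,0,0)$,
$(1,1)/\sqrt2 \mapsto (1,0,1,0)$, $(1,i)/\sqrt2 \mapsto (1,0,0,1)$.
Polarization-preserving tissue returns every speckle in one polarization
state; depolarizing tissue (multiple scattering in melanin) returns
speckles whose normalized Stokes directions are scattered over the
sphere. The degree of polarization uniformity (DOPU) quantifies this per
voxel over a small kernel: 1 for perfectly uniform states, near 0 for
fully scrambled ones.

Two estimators are exposed. The pipeline default is sum-then-normalize
with additive-noise correction,

$$\mathrm{DOPU} = \frac{\sqrt{(\Sigma Q')^2 + (\Sigma U')^2 + (\Sigma V')^2}}
{\Sigma S_0'},\qquad
S_0' = S_0 - (n_1 + n_2),\; Q' = Q - (n_1 - n_2),$$

where $n_i$ is the mean additive-noise energy of channel $i$, estimated
from a signal-free vitreous band (`estimate_noise()`). $U$ and $V$ need no
correction because their noise cross terms are zero-mean. The classic
normalize-then-average estimator ($\|\text{mean of } (Q,U,V)/S_0\|$) is
kept for comparison; `dopu_bias_experiment()` shows it biased far below 1
on uniformly polarized tissue at low SNR while the corrected form stays
near 1, which is the entire motivation for the correction.

The kernel is 3 pixels transverse by 3 pixels in depth **within** a
B-scan, pooled across the 4 repeated B-scans acquired at one location
(36 speckle samples). Pooling is the natural combined estimator given
that the repeats image the same tissue; per-repeat estimation (then
averaging) remains available via `kernel_spec(include_repeats = FALSE)`.

Numerical choices: the denominator is floored at
$\varepsilon = 10^{-12}\max S_0$; values are clamped to $[0,1]$ with the
pre-clamp overshoot count reported (`n_overshoot`), never silently
discarded; the kernel is cropped at volume borders rather than padded
(no fabricated samples); a voxel is *valid* when its pooled corrected
energy exceeds `validity_factor` (default 2) times the pooled expected
noise energy — noise-only voxels would otherwise show spurious low DOPU
and are flagged instead.

## Projections and the depolarized light image

The composite B-scan overlays DOPU < 0.8 in red on the log-compressed
intensity image; the comparison is strict (`< 0.8`), a pixel exactly at
0.8 is not flagged. En-face minimum-DOPU projections take the minimum
over valid voxels of the whole column, or only anterior to the RPE
segmentation (`z < line`, half-open) — the anterior restriction removes
the normal RPE/choroid depolarization so intraretinal foci stand out.
Invalid pixels render as 0 and are carried in a mask, never interpolated.
Display log-compression is $20\log_{10}(S_0/\max S_0)$ windowed over
$[-40, 0]$ dB.

The PS-SLO depolarized light image is the per-pixel minimum of the
crossed-detector frames over all input polarization angles: the
crosstalk of polarization-preserving structures varies sinusoidally with
the input angle (period $\pi$) while depolarizing structures return an
angle-independent floor, so the minimum isolates the floor. Display
rescaling maps min–max to 0–255 with half-away-from-zero rounding (a
constant image maps to all zeros); the rescale is monotone, so pixel
ordering is preserved.

## Lesion quantification

B-scans are binarized with Shanbhag's fuzzy-information auto-threshold:
for each candidate level the background/foreground classes get
information measures built from fuzzy memberships of the cumulative
histogram, and the chosen threshold minimizes their absolute difference
(ties to the lowest level; a single-level histogram is rejected as
degenerate). The implementation is pinned against an exhaustive
brute-force scan of the same criterion on random histograms. Two
behaviours worth knowing: on a two-level histogram the criterion is
identically zero between the levels, so the tie-break returns the lower
level (the binarization still separates the levels exactly); and the
split tracks histogram *balance*, so the image handed to it must not be
dominated by a single empty gray level. For that reason the 8-bit B-scan
used for binarization (`bscan_intensity_8bit()`) anchors its display
window at the 1st percentile of the nonzero intensities in dB — with a
max-referenced 40 dB window the vitreous collapses into level 0
(typically half the image) and any histogram-shape threshold degenerates.

HRF volume uses the printed voxel formula: pixel count ×
11.7 µm × 23.5 µm × 3.6 µm (989.82 µm³ per voxel), reported in mm³. The
pitches are stored independently of the grid counts: 6.0 mm / 512 is
11.72 µm, but the instrument's printed 11.7 µm value is used in all
volume formulas. The clinical workflow's manual selection of HRF loci on
the binary images is replaced by truth-guided selection (intersect the binary
foreground with ground-truth focus masks) for synthetic data, or by ROI
voxel sets for real use; on clean data at the default noise level the
binarized truth-guided path recovers the generator's focus voxels in
full, and the pure truth path recovers them exactly by construction.

PED volume uses the Cavalieri principle: slice spacing (default the
printed 23.5 µm inter-B-scan pitch; 6.0 mm / 256 = 23.4375 µm) times the
sum of per-B-scan cross-sectional areas between the elevated RPE
boundary and its baseline. On the full-width grid this lands within 3%
of the analytic volume of the generator's elliptical Gaussian dome
($2\pi H \sigma_x \sigma_y$); the residual is depth quantization (3.6 µm
steps) plus grid truncation of the Gaussian tails.

## Four-modality classification

Observer judgment is replaced by thresholded scores. Each focus gets its
minimum DOPU over valid focus voxels, and a z-score of its footprint
mean against a background annulus (default 40–160 µm beyond the focus,
excluding all focus footprints) on the PS-SLO depolarized image and both
AF images. The label is *migration* only if min DOPU < 0.8 **and** all
three en-face z-scores meet their thresholds (default 2); the NIR-AF and
SW-AF requirements are both mandatory, mirroring the biology (melanin
and lipofuscin, or melanolipofuscin).

The hard-exudate exclusion: a connected low-DOPU component (6-connected
in 3-D) of at least `mass_min_voxels` (default 200, chosen above the
largest single focus the generator produces) that overlaps the focus's
$(x,b)$ column at any depth forces the label *excluded*, regardless of
scores. Two guards keep this rule from firing on normal anatomy:

* the mass search runs at $z < \text{line} + \text{margin}$ with
  **margin −2 voxels**. The RPE band starts at the segmentation line and
  the DOPU kernel has a one-pixel depth half-width, so with any
  non-negative margin the normal RPE (and the low-DOPU halo it smears one
  voxel above the line) forms one grid-spanning component that would
  exclude every focus;
* the focus's own voxel set is dilated by the kernel half-widths before
  the search, because voxels within one half-width of a depolarizing
  focus read low on account of the focus itself.

Eye-level tallies use migration precedence (an eye with any migrating
focus counts only in the migration column; excluded foci are ignored),
which keeps the two columns mutually exclusive. Interobserver agreement
is emulated by two automatic graders with jittered thresholds and
summarized with Cohen's kappa ($\kappa = (p_o - p_e)/(1 - p_e)$; both
raters constant and identical is defined as $\kappa = 1$).

## The synthetic generator

The phantom is a flat layering — vitreous (signal-free), neurosensory
retina (polarization-preserving, reflectivity 1), RPE band
(depolarizing, reflectivity 5, ~10 µm), choroid band (depolarizing,
2.5, ~60 µm) — with depth indices increasing anterior→posterior and
"anterior to the RPE" meaning $z < \text{line}$ (half-open). Speckle is
modeled per voxel and repeat: preserving voxels are one complex
circular-Gaussian amplitude times a fixed per-layer unit Jones vector;
depolarizing voxels are two independent circular-Gaussian channels
(normalized Stokes directions uniform on the sphere — verified by a
mean-resultant-length test); every voxel gets independent additive
circular-Gaussian detector noise with the configured per-channel mean
energies (default 0.01, i.e. 20 dB below the retina).

PED domes are elliptical Gaussian elevations of the RPE boundary;
drusenoid defaults (H = 90 µm, σ = 180 µm) are smaller than serous ones
(H = 200 µm, σ = 320 µm) — only the relative size matters for the
correlation experiments. In the serous group the expected focus count
grows with the realized dome volume, giving the positive HRF–PED volume
coupling the correlation analysis expects. Foci are ellipsoids
(radius 18–30 µm) placed strictly anterior to the boundary with
*disjoint transverse footprints*: distinct HRF are physically separate
lesions, and stacked depolarizing foci would read as a single axial mass
under the exclusion rule. Focus reflectivity gain (3.5–5× retina) and AF
blob contrast (amplitude 80 over background 60, noise SD 4) are free
parameters — the source imagery does not quantify them — set so the
lesions are unambiguous at realistic noise. Hard-exudate masses are not
generated by default (eyes with apparent hard exudates are excluded from
the cohort definition); `add_exudate_mass()` injects one for testing the
exclusion rule.

The PS-SLO stack uses the minimal crosstalk model for which the
min-over-angles semantics are exact: frame $k$ = offset + floor(column
depolarizing energy) + amplitude(column preserving energy)
$\sin^2(\theta_k - \phi)$ + noise, with angles $(k-1)\pi/n$ and default
phase 0 so the first angle attains the exact sinusoid minimum. AF images
are background + per-focus Gaussian blobs (NIR iff melanin or
melanolipofuscin, SW iff lipofuscin or melanolipofuscin) + Gaussian
noise, quantized to 8 bits.

What the generator does **not** emulate: wave-optics rendering, nerve
fiber layer birefringence, eye motion, spectral (780/1048 nm) effects,
vessel-based registration (modalities are born co-registered; only pixel
offsets are supported), AF texture from real fundus autofluorescence,
and hard-exudate-laden active exudative disease. Passing tests therefore
demonstrate the correctness of the computations and the internal
consistency of the pipeline under its stated speckle/noise model — not
clinical performance on real images.

## Statistics

Count tables recompute percentages from raw per-eye records (one
decimal, half away from zero). Chi-square contrasts one group against
the rest on a 2×2 table (Pearson, no continuity correction by default —
exposed as a flag; each-vs-rest is the default contrast, combining
groups is an option). Mann–Whitney U reports the first sample's U with
exact p by full enumeration of group assignments (midranks, ties
handled) for pooled sizes ≤ 12, otherwise the tie-corrected normal
approximation without continuity correction; Kruskal–Wallis wraps
`stats::kruskal.test` with the all-identical degenerate case defined as
H = 0, p = 1. Pearson correlation reports $r$, $R^2$ and the two-sided
t-test p-value; constant input is rejected rather than returning NaN.
All statistics are pinned against independent brute-force recomputation
in the tests.

## Problem sizes

The package defaults to the full-scale acquisition geometry (512 × 256,
depth 128 of up to 583, 4 repeats). The test-suite and demo runs use
reduced grids chosen for the property under test: 48 × 24 × 64 eyes for
classification-recovery cohorts (large enough that footprints, annuli
and masses all fit; 30 eyes run in a few minutes), 96 × 48 × 128 for
serous-PED eyes with rendered fields (the dome needs transverse room),
and the full 512 × 256 transverse grid with 256 depth pixels for
geometry-only PED volumetry (no fields rendered, so it is cheap and the
Gaussian tails are not truncated). Monte-Carlo sizes (10³–10⁶) are
stated in each test next to the tolerance they support.

## Known limitations

* The DOPU kernel mixes layers at boundaries: a preserving focus
  adjacent to tissue with a different Jones state reads DOPU below 1 (a
  real effect of kernel estimators, but here the inter-layer state
  difference is arbitrary).
* Shanbhag thresholds are meaningful only for balanced histograms; the
  floor-anchored windowing makes the synthetic B-scans behave, but
  near-zero detector noise re-degenerates the histogram.
* The classification thresholds are surrogates for observer judgment;
  kappa between jittered graders is a consistency check, not a claim
  about human agreement.
* Serous-group coupling between dome volume and focus load is a modeling
  choice that produces a positive correlation; its strength is not
  calibrated to clinical data.
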