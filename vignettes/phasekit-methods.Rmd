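---
title: "phasekit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phasekit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasekit)
```

phasekit reimplements, as tested and reusable R code, the computational
stack behind a sticker–spacer analysis of the TDP43 C-terminal domain
(CTD): evolutionary sequence analytics and mutant design, live-cell
condensate quantification with saturation-concentration estimation,
half-bleach FRAP dynamics, and single-cell ratiometric splicing analysis.
This vignette explains each model, the tunable parameters with their
defaults and units, what the synthetic generators do and do not emulate,
and the choices made where the design was genuinely open.

## 1. Domain architecture and the packaged sequence

The packaged record is the human TDP43 CTD, UniProtKB Q13148 residues
267–414, carried with full-length numbering so that familiar landmarks
(G309, W334, G348, G368, W385, W412) keep their coordinates. The default
partition is IDR1 = 267–319, CR = 320–343 (the conserved, helix-prone
region), IDR2 = 344–414.

Disorder boundaries are a modelling choice, not a structural fact, so all
boundaries are configuration values (`domain_partition()`). The shipped
CTD start of 267 is the boundary most used for the TDP43 low-complexity
domain in the structural literature and is the unique choice consistent
with the residue accounting this package pins in its tests: 11 aromatic
(F, Y, W) and 9 aliphatic (V, L, I, M) residues across the two IDRs, ten
hydrophobic residues per IDR, and exactly two tryptophans in IDR2. A CTD
start at 274 would strand L270 outside IDR1 and break that accounting.

```{r}
views <- partition_domains(tdp43_ctd())
vapply(views, function(v) nchar(v$sequence), integer(1))
```

## 2. Divergence, composition, hydropathy

**Edit distance.** Sequence divergence is the Levenshtein distance
normalized to 100 aa. The normalizing length is the *mean* of the two
sequence lengths (switchable to the maximum): the mean is symmetric,
reduces to the common length for equal-length sequences, and keeps the
statistic interpretable as "substitutions + indels per 100 aligned
residues". `utils::adist()` supplies the distance; the test suite checks
it exhaustively against an independently written dynamic-programming
oracle.

**Composition.** Frequencies are reported per 100 residues and sum to 100
per sequence; collections are summarized as per-residue mean ± SD across
sequences.

**Hydropathy.** Residue hydrophobicities come from a registry of 15
literature scales, each min–max rescaled over its 20 values to [0, 1]
(hydrophilicity-oriented scales are sign-flipped on entry so larger always
means more hydrophobic). The default is the Fauchère–Pliska scale. The
profile is the mean rescaled value in a centered sliding window of
`window = 5` residues with no edge padding — values exist only where the
full window fits, so no terminal values are fabricated; the profile is
`window - 1` positions shorter than the sequence.

## 3. Cluster ("sticker") detection

Clusters are local maxima of the hydropathy profile subject to two
filters:

* **prominence** ≥ `prominence_min` (default **0.125** on the 0–1 scale),
  computed as standard topographic prominence (height above the key
  saddle toward the nearest higher peak, or above the boundary minimum);
* **separation** ≥ `min_separation` (default **5 residues**), enforced
  greedily from the most prominent peak down, ties toward the N-terminus.

Two non-obvious choices:

* **Edge maxima are eligible.** The profile stops at the last full
  window, but the C-terminal W412/G/M motif of TDP43 is a real sticker
  that would otherwise be invisible.
* **Region filtering precedes separation thinning.** When detection is
  restricted to the IDRs, peaks inside the CR are removed *before* the
  separation filter, so a prominent CR-edge peak can never suppress a
  genuine IDR sticker a few residues away.

The defaults were calibrated once against a single criterion — the human
WT CTD must yield exactly four major clusters in each IDR — and then
frozen; this 4+4 result is regression-pinned in the tests. On the
packaged CTD the eight cluster prominences are all ≥ 0.147, while the
strongest spacer-level bump (an alanine window exposed when a
neighbouring sticker is removed) reaches 0.120, so 0.125 separates the
two populations with a genuine margin. The spec-suggested 0.15 would drop
one true IDR1 cluster.

```{r}
ctd_clusters()
```

For homolog *ensembles*, `cluster_conservation()` scans with a more
permissive prominence (default 0.08) and scores anchors within a ±5
residue tolerance. The reason is empirical and visible in the generator:
spacer divergence erodes the *saddles* around a sticker (lowering its
prominence and jittering the called position) long before it erodes the
sticker itself, and the ensemble question is "is there a hydrophobic
elevation at this position", not "is this a major cluster of this
sequence".

## 4. Mutant design

Three mutant kinds cover the full catalog (`mutant_catalog()`):

* **Class substitutions** (Φ-S, F-S, FYW-L, VLIM-F, KRED-S, …) act only
  inside the stated region — by default IDR1 ∪ IDR2, leaving the CR
  untouched, because the CR mediates protein interactions that must not
  be confounded with phase effects.
* **Point mutations** use full-length coordinates and refuse to apply if
  the reference residue does not match the sequence, which catches
  numbering-offset mistakes immediately.
* **Cluster regrouping** (`regroup_clusters()`) reduces the eight IDR
  clusters to 6, 4 or 2 while preserving the residue multiset exactly:
  donor clusters are dismantled and their hydrophobic residues swapped
  with spacer residues adjacent to the retained anchor clusters. Anchors
  are allocated per IDR (alternating by prominence), donors move to the
  nearest anchor, ties break toward the N-terminus, and the result is
  validated by re-running detection. The exact construction used in the
  original mutant series is not published; this greedy realization is
  validated through its stated invariants (composition identity, target
  cluster counts, CR untouched).

One subtlety: "overall hydrophobicity unchanged" holds exactly at the
residue level (any permutation of the multiset preserves the mean residue
hydrophobicity). The mean of the *windowed profile*, however, weights the
first and last `window - 1` residues less, so relocating a terminal
sticker (W412/M414, unavoidable for the 2-cluster variant) shifts the
profile mean by ~1e-3. The package therefore pins the residue-level
invariant exactly and does not claim window-mean invariance.

## 5. Condensate imaging

The pipeline mirrors a high-throughput confocal reporter assay:
z-projection (maximum by default; a variance-of-Laplacian focus-weighted
mean is available), Otsu thresholding of the nuclear channel, hole
filling, connected components, and splitting of touching nuclei by
assigning pixels to the nearest local maximum of a 3-4 chamfer distance
transform (markers need distance value ≥ 4 px and separation ≥ 8 px).
Area limits (default 50–∞ px) remove debris. All images are numeric
matrices indexed 1-based `[row, col]`; no TIFF reader exists in the
target environment, so matrices and CSV are the interchange formats.

**Droplets** are detected per nucleus as connected pixels above
`median + k_mad × scale` (default `k_mad = 3`), where `scale` is a robust
SD estimated from the *upper* quartile only — dim nuclei clip at zero,
which halves a two-sided MAD and would inflate false positives. Accepted
droplets need area in [4, 400] px and circularity ≥ 0.7, where
circularity compares the area with that of a disk of equal radius of
gyration (plus a half-pixel extent correction). This moment-based measure
is ~1 for digitized disks of any sub-pixel phase — the perimeter-based
4πA/P² scores a radius-2.6 px disk at ~0.66 and is unusable at droplet
scale — while thin streaks score below 0.3.

**Classification and C_sat.** Nuclei at or below the 99th percentile of a
non-transfected control population are `Untransfected` and excluded; the
remainder are `Cond` (≥ 1 droplet) or `Diff`. C_sat is estimated by
logistic regression of condensate presence on nuclear intensity, read at
P = 0.5. This replaces a visual distribution comparison with a fitted,
uncertainty-aware quantity; the estimate is flagged degenerate when only
one class is present or the crossing falls outside the observed range.
The fraction of Diff cells above C_sat is reported because it is the
statistic used to call a variant separation-deficient despite sufficient
nuclear levels. Calibration against a 1/2/5/10 µM GFP titration is an
affine least-squares fit; inversion clips negative concentrations to zero
with a warning.

**Onset analysis.** In time-lapse focus counts, onset is the first frame
with ≥ 1 focus persisting ≥ `k = 2` frames (single-frame blips are
noise); groups are compared with two-sided unpaired Student t-tests.

## 6. FRAP normalization and fitting

For each time point the bleached-hemisphere intensity is divided by the
unbleached hemisphere, cancelling acquisition photofading and gain:
`I_t = bleached(t)/unbleached(t)`. Recovery is

FR(t) = (I_t − I_t0) / (I_before − I_t0),

with `t0` the first post-bleach frame and `I_before` the mean pre-bleach
ratio (averaging all pre-bleach frames rather than one reduces the noise
of the anchor). FR is 0 at t0 by construction and 1 at full return. The
published formula contains a typographical inconsistency in its
denominator; the adopted reading is the standard FRAP normalization
consistent with the surrounding text. A trace whose pre-bleach ratio does
not exceed the first post-bleach ratio is a degenerate bleach and errors.
FR values are not clipped under noise; curves with |FR| > 1.5 are flagged.

Recovery is summarized by `FR(t) = A(1 − e^{−kt})` fitted by bounded
least squares (A ∈ [0, 1.2], k > 0; initialization A = max(FR),
k = 1/t at half-max; a Nelder–Mead fallback runs if `nls` fails, flagged
as non-converged). A < 0.1 flags a solid-like droplet. The original work
plots mean ± SD recovery without fitting; the single-exponential summary
is this package's choice of a minimal parametric description — it is not
a diffusion model, and `A`/`k` should be read as comparative statistics,
not transport coefficients.

## 7. Flow-cytometry splicing analysis

Observed fluorescence is modelled as `observed = true × M` with spillover
matrix M (unit diagonal); compensation right-multiplies by M⁻¹. Gates run
sequentially — debris (scatter minima), singlets (FSC-H/FSC-A within 15%
of the population median), BFP-positive (expression threshold) — with a
conservation-checked per-gate report. The splicing readout is the
per-cell ratio r = mCherry/GFP; events with GFP at or below a floor
(default: 1st percentile of positive GFP) are excluded and counted rather
than producing unstable ratios. Summaries use 20 log-spaced BFP bins with
per-bin median, IQR and a kernel density for violins; variant comparisons
restrict to a common BFP window (a required user parameter — the
published expression window exists only as figure shading) and report
medians, rank order and pairwise Wilcoxon tests. No automatic outlier
removal is performed.

## 8. The synthetic world

Each generator states an explicit world and emits its ground truth; every
latent quantity is consumed by a recovery test.

* **Homologs**: template = packaged CTD; spacers mutate within {G, S, N,
  Q} at rate 0.3, stickers within the Φ class at 0.02, CR at 0.02.
  A and P are excluded from the spacer alphabet because both carry
  appreciable Fauchère–Pliska hydrophobicity and would erode the
  sticker/spacer contrast the ensemble is meant to conserve. A two-clade
  mode separates ancestors at a higher spacer rate, giving bimodal
  distance distributions.
* **Nucleus populations** (record level): log-normal expression (median
  300 a.u., sdlog 0.8) with a logistic condensation probability centered
  on the true C_sat (default 100 a.u., softness 15 a.u.) — the soft
  threshold models cell-to-cell variability; the default world places
  C_sat near a third of the mean expression, the wild-type regime. 20%
  untransfected cells and a matched control population sit at
  autofluorescence background.
* **Image fields**: disk nuclei (radius 13 px) with planted circular
  droplets (radius 2.6 px, dense/dilute ratio 5) in cells above C_sat.
  The SNR parameter is defined on the *faintest* planted droplet
  (contrast / noise SD), so "95% detection at SNR 5" is a statement about
  every object, not the median cell. Optics are not simulated (no PSF,
  no z-blur); a green detection test therefore certifies the
  segmentation and detection logic, not robustness to real microscope
  aberrations.
* **FRAP traces**: exponential recovery in hemisphere-ratio space
  (pre-bleach ratio 1.0, post-bleach floor 0.4) with Gaussian noise
  specified on the FR scale (default SD 0.02), 5 pre-bleach and 60
  post-bleach frames at 0.5 s.
* **Flow populations**: BFP log-normal (median 5000, sdlog 1.0), GFP
  proportional to BFP with log-normal scatter, and a saturating
  dose-response r(BFP) = baseline + r_max·BFP/(BFP + K) with
  multiplicative noise whose CV shrinks as (K/BFP)^0.35 — reproducing the
  convergence of splicing ratios toward a set-point at high expression.
  Debris, doublets, untransfected events and linear spillover are
  included; spectral overlap beyond the linear model is not.

## 9. Numerical and statistical choices

* Ties in peak detection break toward the N-terminus; plateau maxima are
  anchored at their most N-terminal position.
* Logistic C_sat fits suppress the perfect-separation warning and simply
  report the boundary crossing; degeneracy is flagged, not thrown.
* The null calibration of the flow comparison (identical variants, 100
  seeds) is asserted as *consistency with* the nominal 5% level via a
  one-sided binomial test, because the empirical rejection fraction of an
  exact 5%-level test over 100 replicates exceeds 0.05 about 40% of the
  time by construction; demanding the raw fraction be ≤ 0.05 would make
  the check a coin flip.
* All generators call `set.seed(seed)` internally; identical (seed,
  configuration) pairs give byte-identical outputs.

## 10. Known limitations

* Segmentation is 2-D; overlapping nuclei are split by distance-transform
  markers, which handles touching disks but not dense clumps.
* The FRAP model is single-exponential; reaction–diffusion kinetics and
  photofading beyond hemisphere normalization are out of scope.
* Homolog retrieval, multiple sequence alignment, disorder prediction and
  any wet-lab quantities (turbidity, phase diagrams, RT-PCR band
  intensities) are out of scope.
* The hydrophobicity registry stores literature scale values to their
  common published precision; only the Fauchère–Pliska default is
  load-bearing for the packaged analyses.
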