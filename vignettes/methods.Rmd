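---
title: "Methods: tonotopy, tuning and sound-ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tonotopy, tuning and sound-ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tonotopr` implements the downstream analysis of awake-mouse auditory
cortex calcium imaging: neuron-level quality filtering, frequency-tuning
classification, tonotopic-map heterogeneity, widefield best-frequency
parcellation, and sound-ensemble correlation/clustering with
cross-session stability. Upstream steps (motion correction, ROI
segmentation, spike deconvolution) are out of scope; the pipeline starts
from their outputs or from the package's own synthetic equivalents.

All frequency arithmetic runs on the octave axis $x = \log_2(f/4\,
\mathrm{kHz})$, so the 17-tone stimulus grid (4–64 kHz, four steps per
octave) becomes $0, 0.25, \dots, 4$ and bandwidths come out in octaves.

# Preprocessing

**PSNR filter.** A neuron is retained when
$\mathrm{PSNR} = 20\log_{10}\!\big(\max(F_\mathrm{raw}-F_n)/\sigma_n\big)
\ge 36\,$dB, with $F_\mathrm{raw}$ the ROI trace, $F_n$ the neuropil
trace, and $\sigma_n$ the standard deviation of the *full* neuropil trace
(whether $\sigma_n$ should be computed per segment is not specified
anywhere we could find; the full trace is the default and the choice is
exposed). Exactly 36 dB is retained — only values *below* threshold are
removed. Degenerate cases: $\sigma_n = 0$ flags the neuron (excluded,
with a warning); a non-positive peak yields $-\infty$ (excluded).

**Running exclusion.** A stimulus repetition is contaminated when
treadmill speed *exceeds* 1 cm/s (exactly 1 cm/s is retained) at any
frame of the stimulation window (tone onset–offset by default; a
response-window extension is available). A field of view is invalid when
any analyzed sound keeps fewer than 5 clean repetitions.

**Amplitude-rescaling control.** To test robustness against a uniform
reduction of calcium signal amplitude, traces are wavelet-denoised, the
denoised component is multiplied by 0.86, and the residual noise is added
back unchanged. The wavelet settings are not dictated by the analysis
contract (only the smooth/noise split matters), so we use a periodized
orthogonal DWT with the sym4 filter, reflection padding (to avoid the
wrap-around discontinuity), decomposition depth
$\lfloor\log_2 n\rfloor - 4$, noise scale from the MAD of the finest
detail level, and the universal soft threshold
$\hat\sigma\sqrt{2\ln n}$. Perfect reconstruction and the
smooth/noise-separation contract are property-tested.

# Frequency tuning

**Responsiveness.** For each of the 85 frequency × SPL combinations, the
per-repetition mean spike probabilities 400 ms pre- and post-onset are
compared by a one-way ANOVA with two groups (equivalent to a squared
pooled-t F test — whether the original analysis pooled differently is
unstated; the two-group reading is the natural one). A neuron is
PT-responsive when any combination reaches $p<0.01$; deliberately, no
multiple-comparison correction is applied. Under a pure null this fires
at $1-0.99^{85}\approx 0.57$ — the acceptance suite checks exactly that
calibration.

**FRA and classification.** Trial responses are averaged into the 17 × 5
grid; frequency means are then averaged across SPLs to one value per
frequency. This 17-point vector is fitted with a unimodal Gaussian
$A_1 e^{-((x-B_1)/C_1)^2}+D$ and a bimodal sum of two Gaussians plus
offset. Model choice uses the adjusted coefficient of determination with
$n = 17$ and $p$ = all fitted parameters (4 and 7): if both
$R^2_\mathrm{adj} < 0.4$, the neuron is *irregular*; otherwise the
higher $R^2_\mathrm{adj}$ decides *single* vs *double*.

Two numerical guards qualify a "double" call, and they are the package's
own design decisions (documented because the bare rule is fragile):

1. *Width floor.* $C \ge 0.25$ oct (one grid step). A fitted Gaussian
   narrower than the sampling step is pinned by a single sample and
   cannot represent a resolvable tuning peak.
2. *Minor-peak significance.* The smaller peak's amplitude must exceed
   4 Jacobian-based standard errors; peaks must also be separated,
   $|B_1-B_2| > \max(C_1, C_2)$.

Without these guards, the 7-parameter bimodal fit beats the 4-parameter
unimodal fit on $R^2_\mathrm{adj}$ for roughly half of genuinely
single-peaked noisy FRAs: the adjusted-$R^2$ comparison prefers the
bimodal model whenever $RSS_{bi} < 0.75\,RSS_{uni}$, which three extra
free parameters achieve about half the time under the null by parking a
sub-grid-width Gaussian on a noise bump. With the guards, recovery on
synthetic data is ~95% (single), ~100% (double, separation ≥ 1.5 oct)
and ~93% (flat-noise → irregular) at the stated noise level. When a
guard rejects the bimodal winner, the unimodal fit is used (or the
neuron is irregular if that fit is below threshold).

Optimization is multi-start (5 starts) bounded L-BFGS-B; starts seed $B$
at the top data maxima, $A$ at peak−min, $D$ at the minimum, $C$ at
0.25–1.5 oct; bounds $A \ge 0$, $B \in [-0.5, 4.5]$ oct,
$C \in [0.25, 4]$ oct.

**Best frequency** is the frequency of the largest cell of the full
17 × 5 grid, regardless of SPL; ties break toward the lowest frequency
(deterministic and documented).

**Bandwidth.** The printed source formula for the full width at half
maximum is typographically garbled, so the default is the analytic FWHM
of $e^{-((x-B)/C)^2}$: $BW = 2\sqrt{\ln 2}\,|C| \approx 1.6651\,|C|$.
The literal alternative reading ($\approx 1.0973\,|C|$) is selectable;
we make no claim about the original intent.

# Topography

FOV-local coordinates are shifted into a global frame (`to_global`),
preserving within-FOV distances exactly. For every single-peak neuron,
the BFs (octave scale — results are conventionally reported in octaves;
a kHz mode is available) of all single-peak neurons within 100 µm
*including itself* are collected; with at least 5 neurons the
interquartile range (linear-interpolation quartiles, `quantile` type 7)
is the local heterogeneity; otherwise no value is defined. Distance is
Euclidean in the imaging plane, radius inclusive; depth is ignored (one
depth per FOV). The statistic is rigid-motion invariant and strictly
increasing in planted BF scatter — the property the heterogeneity
comparison rests on.

Band fractions use low [4, 6), mid [6, 17], high [24, 64] kHz; the grid
tones at 19.03 and 22.63 kHz belong to no named band and are reported as
`other` rather than silently merged.

# Widefield pipeline

Per pixel, the baseline $F_0$ is a degree-3 polynomial fit in a centered
15 s sliding window (clipped at the movie edges, so ≥ 7.5 s always
supports the fit — edge handling is unspecified upstream and documented
here); the signal is $(F-F_0)/F_0 \cdot 100$. For each tone event,
baseline mean/sd come from the 2 s prestimulus frames (per repetition —
the pooled alternative is unstated upstream); the response is the
maximum over the 750 ms post-onset window of the frame value averaged
with its two neighbours; the repetition is evoked iff $z > 2$, strictly.
A tone's amplitude at a pixel is defined only when ≥ 4 of 16 repetitions
are evoked, as the mean of the evoked amplitudes; the pixel BF is the
tone with the highest mean amplitude (ties toward the lower frequency).
Overlapping FOVs are merged after per-FOV normalization; the higher
normalized amplitude wins.

**Reversal detection.** From each low-frequency hub, 1,440 directions
(0.25° steps) are scanned: octave BFs of responsive pixels within ±1°
are averaged in 1-pixel radial bins, gaps are filled (the wedge is too
thin to contain pixel centres at small radii, so the exact ray's nearest
pixel seeds every bin), the profile is smoothed with a 10-sample moving
average and then fitted with a sum of three Gaussians over radius
("Gaussian filter (Degree 3)" is ambiguous upstream — a pure-smoothing
mode is selectable, and we claim nothing about the original intent). The
first local maximum is the reversal point; a monotone profile yields
none, and a plateau only counts when a strictly lower value follows it.
The AC end along a direction is where 10 consecutive ray samples show no
evoked response. Hubs are detected as centroids of connected components
of the lowest-BF quintile after 3 × 3 median filtering, ranked by their
minimum BF (manual seeds can be supplied).

**Parcellation** is either `import` (externally drawn closed borders —
the manual step of the original workflow) or `auto`, which connects
reversal points by angular ordering into a closed border and assigns
A1/AAF/A2 by position relative to the hub. Auto mode is an explicit
heuristic approximation and is labelled as such in its output.

# Sound ensembles

Cell vectors average each neuron's spike probability over
$\lfloor w \cdot \mathrm{framerate}\rfloor$ frames from sound onset
($w$ = 0.4 s; 0.55 s for complex-only analyses). The sound × sound
matrix holds mean Pearson correlations over repetition pairs;
the diagonal (distinct pairs of the same sound) is the response
reliability. Note the matrix is invariant to a *common* affine gain but
not to per-neuron gains — Pearson correlation runs across the neuron
dimension, so per-neuron rescaling reweights neurons.

Dissimilarity is $1-r$ (anticorrelated ensembles must not cluster);
the tree is UPGMA; clusters come from a hybrid dynamic tree cut
reimplemented in the package (no tree-cut library exists in the target
environment). `deepSplit` follows the reference 0–4 convention with the
published core-scatter presets (0.64–0.95) linearly interpolated so the
fractional sensitivity 2.5 is meaningful; minimum cluster size is 2 (the
reference default of 20 exceeds the number of sounds presented). Two
defaults deviate deliberately from the reference implementation, both
because correlation-derived distances are bounded near 1:

* the branch *gap* is measured from the top of the branch core, so a
  straggler absorbed late does not erase the gap that made the branch a
  cluster;
* attachment (stage-1 absorption and the PAM stage) only admits an
  object that joins within the cluster's gap margin of its core —
  with the reference PAM radius (the cut height), sounds uncorrelated
  with *every* cluster would still be attached. Sounds admitted by no
  cluster stay `unclustered`.

Cross-session stability: (i) for each week-1 cluster, the week-2 cluster
sharing the largest fraction of its sounds is its counterpart, and the
FOV's similarity is the mean shared fraction ($|A\cap B|/|A|$ by
default; Jaccard selectable — the definition is not pinned down
upstream); ties prefer the smaller week-2 cluster, then the lowest
label. (ii) Matched-neuron correlation pairs the two sessions' cell
vectors per sound and *same repetition index* (all-pairs mode
available), never across sounds, and averages to one value per FOV.

# Statistics

Two-group comparisons follow a normality-gated rule: both samples are
tested with a Kolmogorov–Smirnov normality test; if both pass at
$\alpha = 0.05$ (the level is unstated upstream; configurable), a
two-tailed paired/unpaired t test is used, otherwise Wilcoxon signed
rank (paired) or Mann–Whitney U (unpaired). Because parameters are
estimated from the data, the naive KS test is anticonservative; the
default is therefore Lilliefors-corrected, with the null distribution of
the KS distance simulated once per sample size (2,000 draws, fixed
internal seed — deterministic) and cached. The naive KS branch is
selectable. Summaries are mean ± SEM; stars at 0.05/0.01/0.001; no
multiple-testing correction is applied anywhere, matching the upstream
convention — a caveat the reporting repeats prominently.

The pooling unit (neuron, FOV, animal) differs between analyses upstream
and is never implied: `compare_groups` takes exactly the two samples the
caller pools.

# The synthetic world

The generators state the recording world once and the tests recover it:

* **Two-photon:** 820 × 820 µm FOV at 29.76 frames/s; a tonotopic
  gradient spanning the full 4-octave axis across the FOV with local BF
  scatter (default sd 0.5 oct — chosen so that 100 µm neighbourhoods
  show heterogeneity of the order reported for mouse A1); class mixture
  60/15/25% single/double/irregular (majority single, as observed in
  cortex); 10 repetitions; trial noise sd 0.25 in spike-probability
  units; transient kernel a single exponential with τ = 0.5 s (only the
  PSNR contract depends on the trace model, not the kernel shape);
  neuropil = baseline + slow drift + white noise, raw =
  0.7·neuropil + transients + noise; planted PSNR ≈ 41 dB so healthy
  neurons pass the 36 dB filter.
* **SPL dependence** is a monotone saturating gain from 0.4 (30 dB) to
  1.0 (70 dB) — only monotonicity matters for BF recovery; no claim is
  made about real rate-level functions.
* **Widefield:** radial map — BF lowest at a hub, rising to 64 kHz at a
  planted crest (the reversal ring), falling beyond; responses driven by
  the *snapped* 5-tone field so every pixel has a unique best tone; a
  12-px silent margin plants the AC end; 5 tones × 16 reps, 500 ms tone,
  5 s pause, 10 Hz. A strictly noiseless movie has zero prestimulus sd,
  which makes the z > 2 rule undefined; "noiseless" checks therefore use
  a noise floor hundreds of times smaller than the signal.
* **Two sessions:** K latent ensembles; neuron loadings are uniform;
  responses are loading + noise, rectified; session 2 redraws the
  loadings of a configurable fraction of neurons. Drift by construction
  changes neuron-level patterns but not which sounds belong together, so
  cross-week *cluster* similarity stays at 1 along the drift ladder
  while matched-neuron correlation decays — the tests assert exactly
  that asymmetry.

What a green test does *not* establish: the generators contain no
behavioural state, no motion artifacts, no segmentation errors, no
correlated (shared) noise across neurons, and no biophysical indicator
model; recovery rates measured here are upper bounds on what real data
would give.

# Known limitations

* TIFF and HDF5 interchange are not provided (no reader exists in the
  target environment); movies stay in memory and maps/tables travel as
  CSV/JSON. A 256 × 256 widefield session at native length occupies
  ~2.3 GB as doubles — generate at 128 px or process in chunks on small
  machines.
* The hybrid tree cut is a reimplementation from the published
  algorithm, pinned by regression tests on fixed dissimilarity matrices;
  it is not guaranteed to reproduce the reference package's labels on
  arbitrary dendrograms, and two defaults deviate deliberately (see
  above).
* Auto-parcellation is a labelled heuristic; quantitative subfield
  claims should use imported borders.
* The responsiveness rule inherits the upstream decision to skip
  multiple-comparison correction; its null firing rate is ~57%, which is
  a *screening* property, not an error — downstream classification does
  the real filtering.
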