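---
title: "Quantifying local translation from Kaede photoconversion timelapses"
author: "kaedeFlux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local translation from Kaede photoconversion timelapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaedeFlux)
```

## The measurement problem

Kaede is a photoconvertible fluorescent protein: 405 nm light irreversibly
switches its emission from green to red. Photoconverting an axon therefore
zeroes the green signal at $t = 0$ while leaving a bright, stable red
reference distributed along the axon. Any green fluorescence that reappears
afterwards is newly made protein. If the Kaede transcript carries the
β-actin 3'UTR — which contains the bipartite zipcode element bound by
Igf2bp1/ZBP1 — green signal should reappear preferentially in the growth
cone, where the mRNA is localized and translated; without the 3'UTR, new
green protein can only arrive from the soma and the growth cone should stay
dark over a 90-minute timelapse.

The quantification task is to turn a two-channel confocal z-stack timelapse
(10 stacks at 10-minute intervals) plus a per-timepoint retrograde trace of
the axon into a per-axon number that distinguishes these two situations.

## The measurement chain

For each timepoint:

1. **Mask.** The red z-stack is auto-thresholded (Otsu by default) into a
   binary mask of the axon.
2. **Edit.** The green z-stack is restricted to the red-positive region
   (`restrict` mode). The alternative reading of mask "subtraction" —
   literal image-calculator arithmetic, clamped at zero — is available as
   `literal_subtract`, but it zeroes green *inside* the axon and destroys
   the measurement, so it is not the default. The mode used is recorded in
   the mask object of every run.
3. **Project.** SUM projections of the red stack and the edited green
   stack are computed in doubles, so 16-bit input cannot clip.
4. **Ratio.** The green SUM projection is divided by the red SUM
   projection wherever the red denominator reaches `minRed` (default 1
   count). Pixels below the floor are flagged invalid rather than divided;
   invalid pixels are excluded from all downstream means.
5. **Profile.** The retrograde trace (tip first; one trace per timepoint,
   because the growth cone advances) is resampled to exact 1-pixel
   arc-length spacing, truncated to 150 pixels (32 µm at the default
   calibration of 32/150 µm/px), and the ratio is read at each point with
   nearest-pixel lookup — the same literal pixel read a measurement macro
   performs. Bilinear interpolation is available for sub-pixel traces and
   agrees with nearest lookup at integer coordinates.
6. **Bin.** Each run of 10 consecutive pixels (1–10, 11–20, …, 141–150) is
   averaged into one of 15 bin means; bin 1 is the growth cone, bin 15 the
   proximal region. Bin means use only valid pixels; a bin with no valid
   pixel is missing.

Across timepoints the statistic is built in two regression levels:

* **Spatial gradient** (per timepoint): the OLS slope of the 15 bin means
  against bin-center position (5.5, 15.5, …, 145.5 px from the tip).
  Negative slope ⇔ ratio enriched at the growth cone.
* **Gradient rate** (per axon): the OLS slope of the spatial gradients
  against time in minutes (0, 10, …, 90, with $t = 0$ included by default
  since the first stack is acquired immediately after conversion).
  Negative rate ⇔ growth-cone enrichment increasing through the timelapse.

Group inference uses the exact two-sided Mann-Whitney U test on the
per-axon rates (+UTR vs −UTR) and, at the final timepoint, one-way ANOVA
with Tukey HSD across the four region groups (growth cone / proximal ×
condition).

### Conventions that matter

* Positions for the regression are bin centers in **pixels**; a micron
  option exists and rescales slopes linearly, so group inference is
  unaffected either way.
* The regression runs on the 15 bin means, not the 150 raw pixels.
* The Mann-Whitney p-value is exact — full enumeration of rank
  assignments — whenever $n_a + n_b \le 16$ and the data are tie-free, so
  the assay's 6-versus-10 design is always exact; with complete separation
  that design's smallest achievable two-sided p is $2/8008 \approx
  0.00025$. Ties or larger samples fall back to the tie-corrected normal
  approximation.
* Coordinates are 0-based (y, x) with origin top-left in all internal
  structures and file exports; bin pixel ranges are reported 1-based
  (1–10 … 141–150) to match the assay's labeling.
* Nearest-pixel lookup uses R's `round` (banker's rounding at exact .5);
  sub-pixel traces that care should use bilinear sampling.

## The synthetic-data generator

No imaging data are deposited with the study, so validation rests on a
simulator whose ground truth is known exactly.

### Kinetics

Concentrations live on the axon's 1-D arc length $s \in [0, L(t)]$, $s = 0$
at the soma-side boundary of the field, $L(t)$ the advancing tip. Three
pools are tracked:

* **New green** $G_{\mathrm{new}}$:
  $\partial_t G = D\,\partial_s^2 G - v\,\partial_s G +
  k_{\mathrm{local}}\mathbf{1}[s > L - \ell_{\mathrm{tip}}]$, with influx
  $J_{\mathrm{soma}}$ at $s = 0$ and zero flux at the tip.
* **Residual green** $G_{\mathrm{res}}$ (unconverted protein left by
  incomplete photoconversion): diffusion only.
* **Red** $R$: diffusion plus optional first-order bleaching.

Only the newly supplied pool is advected: anterograde transport moves new
protein (and, implicitly, its mRNA) toward the growth cone, whereas the
residual green and the converted red are old protein already spread along
the axon. Modeling them with advection and a closed tip would pile both up
at the tip and manufacture a growth-cone signal with no synthesis at all —
the opposite of what the photostable red reference is for. Reported
$G = G_{\mathrm{res}} + G_{\mathrm{new}}$; the initial state is the
post-conversion condition $G = \mathrm{residual} \cdot R_0$, $R = R_0$.
Kaede maturation is folded into $k_{\mathrm{local}}$ and $J_{\mathrm{soma}}$
(the assay measures net green appearance, not biochemistry).

### Defaults

In vivo values of $D$, $v$, $J_{\mathrm{soma}}$ and $k_{\mathrm{local}}$
are unknown. The defaults below were fixed once, by running the forward
model and checking the qualitative in vivo picture — +UTR growth-cone
ratio climbing from ~0.1 to a several-fold higher level by 90 min while
proximal bins and all −UTR bins stay flat — and are illustrative, not
measured.

| parameter | default | units | rationale |
|---|---|---|---|
| `diffusionUm2Min` (D) | 1 | µm²/min | slow effective mobility of a tetrameric protein in crowded axoplasm |
| `transportUmMin` (v) | 0.1 | µm/min | modest net anterograde drift of the new pool |
| `somaInflux` (J) | 0.05 | conc·µm/min | soma supply that cannot reach the 32 µm window within 90 min |
| `kLocal` | 0.015 | conc/min | tip synthesis giving a clear but not saturating 90-min rise; 0 in −UTR axons |
| `residualGreen` | 0.1 | — | conversion leaves ~10 % green ("green undetectable" by eye) |
| `bleachRate` | 0 | 1/min | red Kaede is photostable over 90 min |
| `tipSpeedUmMin` | 0.1 | µm/min | axons "growing noticeably": 9 µm over the timelapse |
| `axonLengthUm` | 60 | µm | measured window (32 µm) plus soma-side margin |
| `tipRegionUm` | 2 | µm | growth-cone synthesis zone |
| imaging | 2 ch × 5 z × 64 × 384 px, 32/150 µm/px, 10 frames / 10 min, 16-bit | | the assay's acquisition design |
| noise | gain 300, Poisson shot noise, read SD 1, background 1/slice | counts | shot-noise-limited confocal detection |

### Rendering

Concentration is painted onto a gently curved 2-D axon — a tube of the
axon radius whose pixels take the value of the nearest arc-length sample,
plus a disk of the growth-cone radius at the tip — then distributed over 5
z-slices with a Gaussian weight profile, blurred with a Gaussian PSF
(σ = 0.3 µm), scaled by the photon gain, Poisson-sampled, perturbed by
Gaussian read noise, offset by the background and quantized to 16 bits.
All randomness flows from one seeded generator; per-axon seeds are master
seed + axon index, so cohorts are bit-reproducible.

### What the simulator does and does not emulate

It emulates the features the pipeline is sensitive to: ratio formation
under shot noise, PSF mixing of neighboring positions, an advancing tip
with per-timepoint traces, incomplete conversion, and soma-derived supply.
It does **not** emulate tissue autofluorescence, z-drift or xy stage
drift, other labeled axons crossing the trace, depth-dependent scattering,
saturation, or tracing error (true traces are exact). Passing recovery
tests therefore show the measurement chain is faithful to its own model of
the assay — not that any particular in vivo number is reproduced.

## Numerical choices

* Kinetics use a conservative finite-volume form (interface fluxes, upwind
  advection), so with closed boundaries total mass is conserved to
  round-off, and with sources the booked mass $k_{\mathrm{local}} \ell_
  {\mathrm{tip}} t + J t$ is added exactly.
* Grid: `dsUm` = 0.25 µm; explicit substeps enforce
  $D\,\Delta t/\Delta s^2 \le 0.45$ (and the advective CFL), erroring out
  rather than running unstable if a frame would need more than 2×10⁵
  substeps. A 4× grid refinement moves the 90-min solution by under 2 %.
* Tip growth extends the domain after each frame; new cells take the
  linearly extrapolated tip-boundary value (the raw tip-cell value is a
  first-order underfill that visibly accumulates over nine extensions).
* Auto-thresholds operate on the discrete intensity histogram (exact
  levels when ≤ 4096 distinct values, else 256 equal bins, mirroring the
  8-bit histogram convention of common image software). Otsu ties take
  the lowest maximizing cut; a contrast-free stack has no foreground.
* The LoG spot detector maps blob radius $r$ to scale $\sigma = r/\sqrt 3$
  (the 3-D blob optimum), thresholds at a fraction (0.3) of the maximum
  response — making the detection set invariant to intensity rescaling —
  and suppresses non-maxima within the minimum separation. Its scale range
  (2–6 µm) is the cell-nucleus scale. These settings are validated on
  planted-truth fixtures only; no equivalence with any published in vivo
  count is claimed, since the original detector settings are unreported.
* Degenerate inputs fail loudly: traces shorter than 150 px name the
  available length, spatial fits require ≥ 3 non-missing bins, rate fits
  ≥ 3 timepoints and no duplicate times, manual thresholds must be given,
  empty samples are rejected.

## Problem sizes used by the test-suite

The validation suite runs entirely on generated data: unit tests use a
reduced scene (40 µm axon, 48 × 288 px, 3 z-slices) and the recovery
suite uses the full default scene. The cohort power check runs 20
independent cohorts of 10 +UTR and 6 −UTR axons at default effect size and
noise; the k-recovery check uses a 6-level synthesis-rate grid with two
replicates per level. These sizes were chosen to give stable pass/fail
behavior on a single CPU while preserving the study's 10 + 6 design.

## Known limitations

* The kinetic defaults are illustrative; absolute rates are not inferable
  from the published figures and no fit to in vivo data is attempted.
* Rendering is 2-D with a thin z-extent — sufficient because the pipeline
  only consumes SUM projections, but not a 3-D optics model.
* The ratio pipeline performs no background subtraction, bleaching
  correction or registration, matching the original analysis; the uniform
  background offset inflates both channels slightly and cancels only
  approximately in the ratio.
* Whether the original macro's mask was inverted before subtraction is
  unknowable from the text; both implemented modes are documented and the
  mode used is recorded per run.
* The zipcode scanner is sense-strand, literal-alphabet matching (IUPAC
  wildcards never match); it reports all overlapping hits and leaves
  filtering to the caller.
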