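---
title: "Methods: brightness-based stoichiometry of membrane-protein oligomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brightness-based stoichiometry of membrane-protein oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(smstoich)
```

`smstoich` determines how many copies of a fluorophore-tagged protein make up
each diffraction-limited spot in a single-molecule TIRF movie, and converts the
observed spot-brightness distribution into oligomer occurrence fractions. This
vignette documents the mathematical model behind every stage, the default
parameter values and why they were chosen, and the known limitations.

## 1. Image formation model (`generate_scene`, `render_movie`)

A scene is a set of point emitters on a supported lipid bilayer. Each particle
is an oligomer of order $n$ drawn from `oligomer_fractions`; each of its $n$
subunits independently carries a mature fluorophore with probability
`labeling_p`, so the number of labels is $k \sim \mathrm{Binomial}(n, p)$.
Particles with $k = 0$ are dark and invisible — this is the central nuisance
the analysis must undo. Positions are drawn by dart-throwing with a minimum
pairwise separation (`min_separation_nm`) and a border margin, mimicking a
spin-coated low-density sample.

Each frame is rendered as:

1. **PSF** — an integrated 2D Gaussian of width `psf_sigma_nm` (default 150 nm);
   the expected photon count in a pixel is the exact double integral of the
   Gaussian over the pixel area (differences of `pnorm`), not a point sample,
   so photometry is linear to well below 1%.
2. **Photon shot noise** — per-pixel photoelectrons
   $n_e \sim \mathrm{Poisson}(\lambda)$, where $\lambda$ includes the emitter
   signal (`photons_per_fluorophore` $\times\,k$ per frame, default 300
   photoelectrons per fluorophore) and a uniform optical background
   `bg_photons_per_px` (default 2 photoelectrons/pixel/frame — TIRF movies are
   never background-free; this keeps the single-frame peak-pixel SNR of a
   trimer near the ~5–6 regime typical of these experiments).
3. **EM gain** — stochastic electron multiplication modeled as
   $\mathrm{Gamma}(\text{shape} = n_e,\ \text{scale} = g/s)$ with EM gain
   $g = 65.4$ and sensitivity $s$ (counts per photoelectron). This reproduces
   the EMCCD excess-noise factor of 2 that doubles the variance of photometry.
4. **Readout** — additive Gaussian read noise (`read_noise_sd = 10` counts),
   camera offset (170 counts), rounding to integer counts, clamping to
   [0, 65535].

Per-fluorophore brightness additionally varies log-normally between emitters
(`brightness_cv = 0.25`, fixed per movie), reflecting orientation and
photophysics heterogeneity; this is what makes the calibrated monomer width
$\sigma_1$ substantially larger than shot noise alone.

Mobile emitters (fraction `mobile_fraction`) take Brownian steps with per-axis
standard deviation $\sqrt{2 D \Delta t}$ (`diffusion_um2s`, default
0.5 µm²/s at 30 ms exposure → 173 nm/step) and **reflect** at the field
boundaries, so ground-truth tracks remain in view. The movie carries a
ground-truth table (true position, $n$, $k$, mobility per emitter, per frame
for mobile ones).

Defaults reproduce a typical acquisition protocol throughout: 1500 frames, 30 ms exposure,
100 nm pixels, offset 170, EM gain 65.4, labeling probability 0.7,
dimer/trimer populations.

```{r quick-render}
sc <- generate_scene(scene_config(field_size_um = 9.6, n_emitters = 20,
                                  oligomer_fractions = c(0, 0.5, 0.5),
                                  min_separation_nm = 800), seed = 1)
mv <- render_movie(sc, n_frames = 20, seed = 2)
dim(mv$frames)
```

## 2. Detection and photometry (`detect_frame`, `fit_spot`)

For immobile-particle stoichiometry the movie is first averaged over frames
(`average_frames`), which suppresses shot noise by $\sqrt{N_\text{frames}}$.

* **Candidates** come from a difference-of-Gaussians filter with widths
  $(0.8, 1.6) \times \sigma_\text{PSF}$ in pixels, followed by strict
  8-neighbour local-maximum selection. The detection threshold is
  `threshold` (default 5) times a robust noise floor estimated by iterative
  sigma-clipped MAD of the DoG image (5 iterations, clipping at 4×), which
  keeps the floor stable in the presence of real spots.
* **Photometry** fits an integrated 2D Gaussian plus a constant to a 7×7 ROI
  (Levenberg–Marquardt, `minpack.lm`), after subtracting the median of a
  surrounding annulus as local background. The fitted volume is converted to
  photoelectrons with the inverse camera model
  $\text{photons} = (\text{counts} - \text{offset}) \cdot s / g$
  (`counts_to_photons`).
* **Quality filters** (`filter_localizations`): fits wider than
  `max_sigma_nm = 200` are rejected (aggregates/out-of-focus); fits narrower
  than `min_sigma_nm = 100` are rejected (sub-diffraction widths are noise
  spikes, not particles); pairs closer than `min_roi_distance_px = 7` are both
  rejected (overlapping ROIs bias photometry); and ROIs are rejected as
  multi-peak when, after subtracting the fitted primary Gaussian, the residual
  retains a non-adjacent local maximum above 30% of the fitted peak amplitude
  and above 4× the model-predicted per-pixel EMCCD noise
  $\sqrt{2 g \lambda + \sigma_\text{read}^2}$ (scaled by
  $1/\sqrt{n_\text{frames averaged}}$). Raw-ROI secondary maxima are not used:
  the PSF's own shoulder plus signal-dependent noise routinely forms spurious
  maxima that an annulus-based noise estimate cannot veto. A net-gradient
  score (`net_gradient`, box 7) is available as an additional spot-quality
  metric.

Detection performance is density-limited: above ~0.5 particles/µm² the
structured DoG residuals of neighbouring PSFs raise the effective noise floor
and recall degrades. The package's validated operating regime is ≤ 0.42
particles/µm², where recall and precision are both ≥ 95% (measured 100% on the
acceptance scenes).

## 3. Stoichiometry (`calibrate_monomer`, `fit_mixture`, `correct_labeling`)

1. **Monomer calibration.** A movie of purified monomeric fluorophore yields a
   brightness sample; `calibrate_monomer` fits a Gaussian mixture
   (`mclust`, 1–4 components) and takes the lowest-mean component with weight
   ≥ 0.1 as the monomer, merging components within 2.5 sd to protect against
   a skewed mode being split. This gives $\mu_1$ (≈ 300 photoelectrons/frame
   under defaults) and $\sigma_1$.
2. **Brightness density.** The sample brightness distribution is estimated by
   a Gaussian KDE (`build_pdf`, Silverman bandwidth $h$) on a regular grid.
3. **Mixture decomposition.** `fit_mixture` expresses the KDE as a nonnegative
   combination of unit-area Gaussians with means $n\mu_1$ and standard
   deviations $\sqrt{n\sigma_1^2 + h^2}$ for $n = 1 \dots$ `max_n` (default
   30), solved by nonnegative least squares. The $+h^2$ term
   (`kernel_broadening = TRUE`) accounts for the KDE kernel: the fit target is
   the data convolved with the kernel, so the model components must be
   broadened identically or widths are over-estimated. Setting the flag to
   `FALSE` recovers the plain $\sqrt{n}\,\sigma_1$ model. Weights below
   `min_fraction = 1e-3` are zeroed and the rest renormalized.
4. **Labeling correction.** The fitted fractions are over the number of
   *labels* $k$, not subunits $n$. With $M_{kn} = \binom{n}{k} p^k (1-p)^{n-k}$,
   `correct_labeling` solves $M f \approx o$ by NNLS and renormalizes. Because
   the unnormalized NNLS solution equals $f_\text{true}/(1 - \text{dark})$,
   the round trip forward-then-invert is exact to machine precision
   (verified to $4 \times 10^{-16}$ over random compositions). A residual
   above 0.05 triggers a warning that the observed distribution is not
   binomially consistent — expected for small samples (≲ 100 particles).
5. **Density.** `particle_density` = accepted particles / imaged area, with an
   optional `dilution_factor` (default 1; a diluted plate assay typically
   uses 10).

```{r stoich-demo}
cal <- structure(list(mu1 = 600, sigma1 = 150, n_particles = 1000L),
                 class = "monomer_calibration")
k <- sample(2:3, 2000, replace = TRUE)
b <- rnorm(2000, k * 600, sqrt(k) * 150)
res <- stoichiometry(b, cal, labeling_p = 1, max_n = 10)
round(res$corrected_fractions[1:4], 3)
```

## 4. Tracking and mobility (`link_tracks`, `classify_mobility`)

Per-frame localizations are linked by greedy nearest-neighbour assignment
(closest pair first) within `max_disp_px` (default 3 px; use ~6 px for
D = 0.5 µm²/s at 30 ms, where the expected per-axis step is 1.7 px), with gap
closing over up to `max_gap` missed frames (the displacement limit scales with
the bridged gap). Classification over the first `first_n_frames` (default 100,
≈ first 3 s):

* **immobile** — positional rms spread ≤ 2 × `precision_px` over ≥ 10 frames;
* **mobile** — ≥ 5 consecutive steps each > 4 × `precision_px`.

The step multiple is 4 (not 2) because under Rayleigh-distributed localization
noise a 2× single-step bound misfires on ~37% of steps of a truly immobile
particle; 4× drives the five-consecutive-step false-positive probability below
$10^{-8}$. Percentages are reported over classified tracks and sum to 100.

## 5. Liposome leakage (`calcein_release`)

For a calcein-loaded liposome dye-release assay,
$$\text{release}(t) = 100 \cdot \frac{F_\text{sample}(t) - F_\text{LUV}}{F_\text{Triton} - F_\text{LUV}},$$
which is exact at the anchors (0% at the intact-liposome baseline, 100% at
full Triton lysis) and invariant to affine shifts of the fluorimeter scale.
`leakage_quality_check` enforces the assay validity criterion
$F_\text{Triton}/F_\text{LUV} \ge 5$, and `score_leakage_plate` applies both
to a long-format plate table, warning on and skipping invalid wells.

## 6. Pipeline and I/O

`run_pipeline` chains average → detect → fit → filter → mixture fit → labeling
correction → density (and optionally per-frame detection → linking →
mobility). Configurations are plain flat-key YAML (`write_config` /
`read_config`, exact typed round-trip); movies are lossless 16-bit TIFF
stacks; results are written as CSV + JSON. All stochastic steps take explicit
seeds and are bit-reproducible (byte-identical output files for identical seed
and configuration). A command-line interface is installed at
`system.file("cli", "smstoich.R", package = "smstoich")`.

## 7. Key parameters

| Parameter | Default | Rationale |
|---|---|---|
| `photons_per_fluorophore` | 300 | detected photoelectrons/frame/fluorophore under typical TIRF illumination |
| `psf_sigma_nm` | 150 | diffraction-limited TIRF PSF at ~515 nm emission |
| `exposure_ms` / frames | 30 / 1500 | reference acquisition settings |
| camera offset / EM gain / read noise | 170 / 65.4 / 10 | reference EMCCD settings |
| `bg_photons_per_px` | 2 | realistic TIRF background; trimer peak SNR ~5–6/frame |
| `brightness_cv` | 0.25 | inter-emitter brightness heterogeneity; sets σ₁ > shot noise |
| `labeling_p` | 0.7 | fluorophore maturation efficiency |
| `max_n` | 30 | maximum mixture components |
| detection `threshold` | 5 | × robust DoG noise floor |
| `min_roi_distance_px` / box | 7 | ROI size for 150 nm PSF on 100 nm pixels |
| `max_sigma_nm` | 200 | width filter against aggregates |
| `precision_px` | 0.2 | localization precision at ~300 photons |
| immobile / mobile frame minima | 10 / 5 | persistence requirements |
| density regime | ≤ 0.42/µm² | validated full-recall single-molecule density |

## 8. What the simulation does and does not emulate

Included: binomial partial labeling with dark particles, EMCCD excess noise,
read noise and offset, integrated-pixel PSF, inter-emitter brightness
variability, uniform optical background, Brownian lateral diffusion with
reflecting boundaries.

Not modeled: photobleaching and blinking (frame-averaged brightness of a
bleaching emitter would bias stoichiometry low; real analyses restrict to
early frames), chromatic/field-dependent aberrations, nonuniform illumination,
vesicle or aggregate contaminants, axial motion, and camera pixel-response
nonuniformity. Recall is clutter-limited above ~0.5 particles/µm²; the
package does not attempt multi-emitter fitting of overlapping spots — it
rejects them, which is the correct behaviour for unbiased brightness
statistics but lowers yield in dense samples.
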