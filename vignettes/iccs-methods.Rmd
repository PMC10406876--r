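---
title: "Colocalization by image cross-correlation spectroscopy: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colocalization by image cross-correlation spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `iccscoloc`, the
numerical choices behind them, what the synthetic-data generator does and
does not emulate, and the known limitations. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The ICCS model

Two registered confocal channels image two labelled nuclear species as
fields of diffraction-limited foci. The spatial intensity-fluctuation
correlation between channels $i$ and $j$ is

$$G_{ij}(\delta_x, \delta_y) =
  \frac{\langle I_i(x,y)\, I_j(x+\delta_x, y+\delta_y)\rangle}
       {\langle I_i\rangle \langle I_j\rangle} - 1,$$

with averages over the selected (nuclear-mask) pixels. In the
fluorescence-correlation-spectroscopy formalism the autocorrelation
amplitude is inversely proportional to the number of independent emitters
in the observation area, $G_{ii}(0) \propto 1/N_i$, and the
cross-correlation amplitude scales with the co-occurring population,
$G_{12}(0) \propto N_{12}/(N_1 N_2)$. Radial profiles obtained by an
angular mean of the 2D maps are fitted with
$G_{ij}(r) = G_{ij}(0)\, e^{-r^2/w_{ij}^2} + G_{ij}(\infty)$,
and the colocalized fraction is

$$f = \tfrac12\left[\frac{G_{12}(0)}{G_{22}(0)} +
  \frac{G_{12}(0)}{G_{11}(0)}\right],$$

which reduces to $N_{12}/N$ for equal channel populations and is by
construction independent of foci density — the property that makes the
estimator preferable to object matching at high density.

### Assumptions

* The two channels are registered; chromatic shift is not corrected.
* Foci are approximately PSF-sized, so every correlation function is
  near-Gaussian with width set by the PSF ($w \approx 2\sigma_\mathrm{PSF}$
  for Gaussian spots).
* The nuclear mask delimits a statistically homogeneous region; nucleoli
  and large voids are not excluded (a documented non-goal).

## Numerical choices

**Masked normalization.** The printed correlation normalization uses a
single $\langle I\rangle^2$ without channel indices; for $i \neq j$ we use
$\langle I_i\rangle\langle I_j\rangle$, the standard cross-correlation
normalization, which coincides with the printed form for $i = j$ and makes
$G$ invariant to rescaling either channel. All averages — including the
means in the denominator — run over the pixel *pairs* with both endpoints
inside the mask, so each lag is normalized by its own pair population.
This removes the spurious long-range structure an irregular mask imprints
when a single global mean is used. The implementation evaluates four FFT
cross-correlations (pair count, product sum, and the two endpoint
intensity sums) on zero-padded arrays; the contract is the nested-loop
direct sum, against which the FFT path is tested to $10^{-10}$.
Autocorrelation maps are explicitly symmetrized so point symmetry holds
exactly rather than to rounding error.

**Pair-count filter.** Lags supported by fewer than `min_pairs = 100`
mask pixel pairs are discarded before radial averaging; estimates from a
handful of boundary pairs are unstable.

**Radial binning.** Bin width 1 px, bin value the unweighted mean of the
contributing lags. The *reported* radius of a bin is the mean radius of
its contributing lags, not the nominal bin centre: on the square lag grid
an annulus samples radii unevenly (the $r = 1$ bin contains the four unit
lags *and* the four $\sqrt 2$ diagonals), and the fit should see the
radius the bin actually averages. With bin centres instead, a noiseless
Gaussian profile misses its own binned means by ~5% at small radii; with
mean radii agreement is within 2%.

**Zero lag.** Excluded from the fit by default: uncorrelated shot noise
adds a delta spike at zero lag of the autocorrelations, which would bias
amplitudes upward. Configurable (`iccs_config(exclude_zero_lag=)`).

**Fit.** Port-algorithm nonlinear least squares with an L-BFGS-B fallback;
a failed optimization reports `converged = FALSE` instead of throwing.
Starting values: amplitude from the innermost fitted bin minus the tail
mean, width 3 px, offset from the outer 25% of fitted radii. The width is
bounded above by the fit range and below by the larger of 0.5 px and the
smallest fitted radius. The lower bound matters: with the zero-lag bin
excluded, the innermost sample sits near $r \approx 1.2$ px, and a fit
allowed to shrink $w$ to 0.5 px can represent a single noisy inner bin as
a delta-like spike whose extrapolated amplitude $G(0)$ is inflated by
$e^{(r_1/w)^2} \sim e^{6}$ — we observed exactly this failure on
independent-channel images, where it turned $f \approx 0$ cells into
$f = 1$ outliers. A width narrower than the innermost sample is
unresolvable, so it is excluded from the parameter space rather than
flagged after the fact. A constant profile is returned as an exact
zero-amplitude fit (degenerate gradient for the optimizer).

**Fraction.** $f$ is reported raw and clamped to $[0,1]$. Negative cross
amplitudes give $f = 0$ with an `anticorrelated` flag; non-positive
autocorrelation amplitudes make $f$ undefined (`NA`) with a flag rather
than an error; offsets above 10% of the amplitude are flagged. Whether the
original analysis clamped $f$, included the zero lag, or pooled the
denominator means is not recoverable; the choices above are recorded here
and exposed as configuration where meaningful.

**Defaults.** `max_lag_px = 32` and `fit_range_px = 20` at 40 nm pixels
(~0.8 µm, several PSF widths), chosen so the Gaussian decays fully inside
the fit range while the offset is still constrained by genuine tail bins.

## PLA spot counting

Puncta are counted by thresholding the z-stack (global Otsu by default —
the original plugin's threshold is not recoverable, so it is
configurable), labelling 3D connected components at 26-connectivity, and
discarding objects under `min_size_vox = 4`. Touching puncta merge into
one object; no watershed splitting is attempted (neither does the
reference plugin), a known undercount bias at high density. The assay's
~40 nm proximity requirement is chemistry, not an image-analysis
parameter. Counting can be restricted to a per-nucleus ROI when a DNA
channel is available; whole-field counting is the fallback.

## Group statistics

One-way fixed-effects ANOVA (explicit sums of squares) across all groups;
for each pair a two-sided F-test of variance equality at
$\alpha_\mathrm{var} = 0.05$ (unstated in the source procedure; 0.05 is
the conventional gate) selects the pooled or Welch t-test; pairs are
flagged significant below the Bonferroni level $\alpha/m$ applied at full
precision (0.05/3, printed as 0.0167). The omnibus p-value is reported
alongside but does not gate the pairwise flags — whether the original
marking conditioned post-hoc tests on the omnibus is unstated, and
reporting both is the transparent choice.

## The synthetic world

`simulate_two_channel()` emulates a single-nucleus two-colour acquisition:
an elliptical nucleus (default semi-axes 100 × 80 px ≈ 8 × 6.4 µm at the
40 nm pixels of the source acquisitions) in a 256 × 256 field, 50 foci per
channel, isotropic Gaussian PSF of σ = 2 px, log-normal amplitudes
(mean 100 counts, CV 0.3 — immunofluorescence brightness is
right-skewed), background 10 counts, shot noise. A fraction `f_true` of
foci is planted at *identical* coordinates — the idealization of
colocalized; `jitter_nm` probes sub-PSF displacement. Amplitudes are drawn
independently per channel even for shared foci (distinct fluorophores),
which biases $\hat f$ low by the factor
$\mathbb E[a]^2/\mathbb E[a^2] = 1/(1+\mathrm{CV}^2) \approx 0.92$: the
acceptance criterion of ±0.10 absorbs this known, physically real effect
(the same heterogeneity exists in real staining). The 256 px field (vs 512
in the source acquisitions) halves the linear field size for simulation
speed; the nucleus, not the field, sets the statistics.

`simulate_pla_stack()` emulates a counting-oriented stack at coarser
(~120 nm) lateral sampling: anisotropic Gaussian puncta (σ 1 px lateral,
1.2 px axial), amplitude 200 over background 10 (peak SNR ≈ 14 under shot
noise), placed by rejection sampling at pairwise distance ≥ 6 px — at
least six lateral sigmas, so threshold-level isophotes cannot bridge even
under noise. At tighter separations, merging becomes possible and exact
recovery is no longer guaranteed (we saw ~8 px fail occasionally with
σ = 2 px blur, which motivated stating the separation in units of σ).

`simulate_cohort()` draws per-cell values from group-wise normals
parameterized by the published per-line means and SDs (presets
`cohort_preset_h3k9ac()`, `cohort_preset_h3k27ac()`), counts rounded and
floored at zero, fractions clamped to $[0,1]$. Normality is the minimal
assumption consistent with mean ± SD summaries whose SDs (20–45% of the
means) are far from count-limited. Cells per group default to 20 — the
study does not report n, and the choice is surfaced in every report.

What the generator does **not** emulate: chromatin texture, nucleoli,
z-dependent aberrations, bleed-through, or antibody chemistry. A green
recovery test therefore establishes correctness of the estimator under
the stated statistical structure, not robustness to those effects.

## Known limitations

* The per-lag masked normalization is the contract; analyses done with a
  global-mean normalization will differ near the mask scale.
* $f$ inherits the amplitude-heterogeneity bias described above
  (~8% low at CV 0.3); it is a property of the estimator, not the code.
* Random co-proximity of independent foci produces a small positive $f$
  at high density (clamping at 0 also makes the mean of $\hat f$ slightly
  positive under independence).
* The TIFF codec reads/writes only uncompressed single-sample grayscale
  8/16-bit files — the raw-export subset — by design.
* Coordinates follow R's 1-based (row = y, col = x) convention throughout.
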