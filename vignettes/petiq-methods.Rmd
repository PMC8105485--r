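---
title: "Phantom-based evaluation of PET reconstruction algorithms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based evaluation of PET reconstruction algorithms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

`petiq` is a desk-scale re-creation of a standard scanner quality-assurance
experiment: fill a NEMA image-quality phantom and a Hoffman-style brain
phantom with tracer, acquire them on a clinical PET system, reconstruct the
data many ways — filtered back-projection (FBP) with 5/10/15 mm Gaussian
filters, OSEM with 4 iterations and 8 or 16 subsets, and a
penalized-likelihood BSREM family indexed by a penalty weight
$\beta \in \{100, \dots, 1000\}$ — and score every reconstruction with a
fixed set of image-quality metrics. Because scanner listmode data are not
public, the package simulates the whole chain: digital phantoms, a
parallel-beam acquisition model with Poisson count noise, and the three
reconstruction families, followed by the metric and comparison layers.

The claims such a study supports are *orderings and trends* (which
algorithm is sharper, how noise falls with the filter width or $\beta$),
not absolute clinical values: a desk simulation at $5\times 10^6$ counts
with a 2D acquisition model cannot reproduce the absolute SNR or
uniformity of a 40-minute scan on a physical scanner, and the package never
claims it does.

## Acquisition model

Acquisition is slice-wise 2D parallel beam. The system matrix is
pixel-driven with $3 \times 3$ subpixel supersampling: each subpixel centre
is projected onto the radial axis of each view and linearly interpolated
into the two neighbouring radial bins. Supersampling matters — plain
pixel-driven projection shows up to ~12% lattice ripple at oblique views,
which supersampling reduces to ~1% (measured against the analytic
chord-length profile of a partial-volume-weighted disk). Radial bin width
defaults to the in-plane voxel size; the bin count covers the grid
diagonal. There is no attenuation, scatter, randoms, depth-of-interaction
or time-of-flight modelling: the metrics under study respond to blur and
count noise, which this model produces, and the corrections are
scanner-side steps outside the comparison.

Count noise is Poisson: the noiseless sinogram is scaled to an expected
total (default $5\times 10^6$ per phantom, a level at which the
$\beta$-trends are clearly visible at desk scale) and independent Poisson
counts are drawn under an explicit seed, leaving the caller's RNG state
untouched.

The default number of views is 192 in the pipeline. A round number of 180
is common for parallel-beam work, but the OSEM design points use 8 and
16 subsets and ordered subsets must partition the view set; 192 is the
nearest count divisible by both. Suites that only run FBP or BSREM (whose
internal subset count is free) use 180 views with 12 BSREM subsets.

## Phantoms

**NEMA IQ surrogate.** An elliptical-cylinder warm body (semi-axes
150 × 110 mm, close to the physical phantom interior) at 5.6 kBq/mL with
six spheres (10, 13, 17, 22, 30, 39 mm) on a 57.2 mm ring; the four
smallest are hot at 4:1 (22.4 kBq/mL), the two largest cold (zero).
Voxelization is by the voxel-centre-inside rule; there is no lung insert.

**Hoffman surrogate.** The true Hoffman atlas is proprietary, so the
package generates a brain-like label map: an outer ellipsoid (semi-axes
70 × 85 × 60 mm) whose gray-matter shell is separated from the white
interior by a seeded, smoothly folded boundary (a short sum of angular
harmonics modulating the interface radius), two ellipsoidal putamina of
2400 mm³ each, and an ellipsoidal white-matter background VOI. Gray matter
(and the putamina) carry `gm_wm_ratio` (default 4) times the white-matter
activity; in the default `"devoid"` mode white matter carries exactly zero,
matching a water-only background compartment. The surrogate preserves what
the metrics need — gray/white contrast, a small bright nucleus, a
zero-activity region, structured edges for template matching — and nothing
anatomical beyond that.

## Reconstruction

**FBP** applies the band-limited spatial-domain ramp kernel by FFT
convolution per view and backprojects with the adjoint of the system
matrix; it is linear and may produce negative voxels. **OSEM** is the
standard multiplicative EM update over interleaved angle subsets (subset
$s$ takes views $\equiv s \bmod S$), initialized with ones; with one subset
it is exactly MLEM. Both apply an isotropic Gaussian post-filter
($\sigma = \mathrm{FWHM} / 2\sqrt{2\ln 2}$, mass-conserving away from the
boundary) after the last iteration.

**BSREM** maximizes the penalized Poisson log-likelihood
$L(x) - \beta_\mathrm{eff} R(x)$ with the relative-difference prior

$$R(x) = \sum_j \sum_{k \in N(j)} w_{jk}
  \frac{(x_j - x_k)^2}{x_j + x_k + \gamma |x_j - x_k|},$$

over the 3D 26-neighbourhood with inverse-distance weights and
$\gamma = 2$. Updates are relaxed preconditioned ascent,
$x \leftarrow x + \alpha_n (x / s_S)(\nabla L_s - \beta_\mathrm{eff}
\nabla R / S)$, clipped to a tiny positive floor ($10^{-10}$ of the
data-scale initialization — a voxel at exactly zero would freeze under the
multiplicative preconditioner), with $\alpha_n = 1/(1 + n/N)$ over a fixed
budget of $N = 25$ iterations standing in for "iterate to convergence";
the penalized objective is recorded per iteration and is non-decreasing in
practice. With $\beta = 0$ and a constant unit step the update reduces
exactly to OSEM, which the tests assert.

**The $\beta$ scale.** The clinical $\beta$ is a vendor-specific
dimensionless weight; this package keeps the familiar 100–1000 grid but
maps it internally through `beta_scale = 0.008`
($\beta_\mathrm{eff} = 0.008\,\beta$). The value was fixed once by
measuring the likelihood and prior gradient magnitudes at the default
count level: the grid then spans mild regularization ($\beta = 100$,
penalty gradient below the per-subset likelihood gradient) to strong
regularization ($\beta = 1000$, several times above it). Pushing further
exposes a degeneracy the physical experiment does not have: a synthetic
region whose true activity is exactly zero becomes prior-limited rather
than noise-limited, its voxel SD collapses, and the SNR metric diverges
and loses monotonicity. Real scans retain a scatter/randoms noise floor in
such regions; the mapping deliberately keeps the grid inside the
noise-limited regime. No numeric equivalence to any vendor scale is
claimed.

## Metrics

* **Percentage contrast** (hot): $100\,\frac{C_H/C_B - 1}{a_H/a_B - 1}$;
  (cold): $100\,(1 - C_C/C_B)$. Sphere ROIs are circles equal in diameter
  to each sphere on the sphere-centre slice, voxel-centre-inside, centred
  on the label centroid.
* **Background variability**: $100\,\mathrm{SD}/C_B$ with the sample
  ($K - 1$) SD over $K = 60$ background ROI means — 12 in-plane positions
  × 5 slices (centre, ±1 cm, ±2 cm; offsets rounded to the nearest slice,
  ties toward the centre). The in-plane positions are a package default
  chosen to clear every sphere and keep ≥ 15 mm from the phantom edge; reports of such
  analyses rarely print exact coordinates, so the list is configurable. ROI sets are concentric across sphere sizes, and cold
  spheres reuse the 60-ROI set of their diameter.
* **Resolution (FWHM)** by template matching: the digital phantom is
  convolved with separable Gaussians over an exhaustive 2D grid of
  (in-plane, axial) FWHM values (default 3–18 mm, step 0.5 mm — matching
  the 0.5 mm granularity of typical reported values), Pearson correlation
  with the measured image is computed over the phantom support, and the
  argmax pair is returned. Joint 2D search is the default (no local-optimum
  risk); a sequential mode (in-plane first, then axial) exists for
  sensitivity analysis and agrees with the joint search on cleanly blurred
  inputs.
* **Axial uniformity**: $100\,\sigma_p / C_P$ over the right-putamen VOI,
  with the population ($N$) SD — the defining equation does not specify
  $N$ vs $N-1$, so the choice is documented here.
* **SNR**: $(C_P - C_W)/\sigma_W$ with the sample ($N-1$) SD of the
  white-matter background VOI, the usual noise-estimator convention. A
  zero $\sigma_W$ raises an error rather than returning infinity.

Contrast, background variability and uniformity are scale-invariant; SNR
is invariant under positive rescaling and under global offsets. The tests
assert all of these.

## Comparison layer

The design matrix encodes the emulated cross-scanner layout: per dataset
(¹⁸F NEMA, ¹⁸F Hoffman, ¹¹C Hoffman), a PET-CT arm with 3 FBP + 3 OSEM
rows and a PET-MR arm with 3 OSEM + 10 BSREM rows (13 in total). NEMA
datasets use 8 OSEM subsets and Hoffman datasets 16. Differences are *reference minus method* against
`FBP_5mm` — so a method that beats the reference shows a negative difference —
and Bland-Altman analysis reports the bias, the sample SD of the paired
differences and $\pm 1.96\,\mathrm{SD}$ limits of agreement, paired
per-sphere. Summary statistics report mean, sample SD, median and
CV% $= 100\,\mathrm{SD}/\mathrm{mean}$.

## Problem sizes and reproducibility

The shipped suites run at sizes a laptop handles comfortably: blur
recovery on a 128 × 128 × 40 grid (1.5 × 1.5 × 3 mm), the
$\beta$-trend study on 96 × 96 × 24 (2 × 2 × 5 mm) with 180 views and
$5 \times 10^6$ counts over seeds 1–3, and the NEMA filter sweep on
128 × 128 × 32 (3 mm isotropic). Every stochastic step takes an explicit
seed, pipeline runs write a manifest (config hash, seeds, versions,
artifact list), and rerunning a configuration reproduces the metric tables
byte-for-byte.

## Known limitations

* 2D slice-wise acquisition without attenuation, scatter, randoms, PSF or
  TOF: absolute metric levels are not comparable to clinical scanners;
  orderings and trends are the supported claims.
* The Hoffman surrogate is brain-like, not anatomical; template-matching
  FWHM values depend on the surrogate's edge structure.
* The exactly-zero background compartment makes the SNR metric degenerate
  under very strong penalties (see the $\beta$-scale discussion).
* Registration between measured and digital volumes is assumed exact;
  real-data registration must happen upstream.
* The 60-ROI background layout follows the standard's constraints but not
  necessarily the exact unpublished coordinates of any specific analysis
  tool; the position list is configurable for that reason.
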