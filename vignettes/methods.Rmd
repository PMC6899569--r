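---
title: "Methods: porosity extraction, pore morphometry and Raman deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: porosity extraction, pore morphometry and Raman deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dimorphbone)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices made where a
published description leaves the details open.

## Intracortical porosity as a negative imprint

Cortical pores — osteocyte lacunae and vascular canals — are voids in an
otherwise solid shell, so they can be recovered by subtracting the
binarised bone from a solidified version of itself:

1. `binarize(volume, threshold)` — bone iff intensity ≥ threshold. The
   lower threshold is *inclusive*: "lower threshold of 80" is read as
   bone at or above 80. The threshold is a required, per-dataset
   parameter (8-bit lab-CT reconstructions commonly use 80; whether the
   same number applies to a synchrotron reconstruction depends entirely
   on its grey-value calibration, so there is no default).
2. Keep the largest 26-connected bone component. 26-connectivity is the
   particle-analysis default and the permissive choice for thin
   structures; a cortex fragmented by the threshold would silently lose
   fragments here, which is why the function logs voxel counts.
3. Morphological closing with a Euclidean ball: dilate then erode, both
   implemented by thresholding an exact squared distance transform
   (separable lower-envelope algorithm, in C++). "Eroded and dilated" in
   scanner-workflow descriptions is taken as an informal reference to
   closing — eroding first would destroy thin cortices; the order is
   still configurable (`order = "erode_dilate"`).
4. Porosity = closed cortex ∧ ¬bone.

The closing radius (default 15 voxels, meant for ~0.65 µm voxels) must
exceed the radius of the largest pore to be recovered and be smaller than
the marrow cavity radius; a warning fires when the closing more than
doubles the solid volume, the signature of a filled marrow cavity. At
array borders the outside is treated as carrying no information: erosion
does not eat into a cortex truncated by the scan window, so a 300-slice
analysis window keeps its end slices. The corollary is that the specimen
must be surrounded laterally by background padding wider than the closing
radius — the phantom generator enforces this through its `padding_vox`
field (default 20 voxels).

Two voxel-level subtleties are handled explicitly:

* **Surface nicks.** A discrete closing fills sub-voxel concavities of
  the rasterised bone surface, which would then reappear as spurious
  shallow "pores". Since intracortical porosity is by definition enclosed
  by bone, `extract_cortical_porosity()` drops porosity components that
  open onto the cortex surface (any voxel 26-adjacent to the outside of
  the closed mask); this removes the artefacts and, as a side effect,
  excludes voids connected to the marrow or the periosteal surface, which
  are not intracortical. Components touching the first/last *slice* are
  kept (the scan window cuts pores arbitrarily); `exclude_border_pores`
  drops them when a conservative census is wanted.
* **Idempotence.** Closing is idempotent, and the pipeline's invariants
  (porosity ∧ bone = ∅, porosity ⊆ cortex) hold voxel-exactly; on
  noise-free phantoms whose pores are all smaller than the closing ball
  and interior to the cortex, recovery is voxel-exact, which the test
  suite asserts literally (`expect_identical` on the voxel arrays).

## Pore morphometry and the lacuna/canal separation

Pores are 26-connected components. Per pore: volume = voxel count ×
voxel volume; equivalent spherical diameter (6V/π)^(1/3); elongation
√(λ₁/λ₃) from the eigenvalues of the voxel-cloud second-moment matrix
(a voxel self-moment of 1/12 voxel² is added per axis so single-voxel and
planar components stay finite); maximum extent = the largest coordinate
range along the three principal axes plus one voxel — an inscribed
approximation of the maximum Feret diameter that is cheap and exact for
axis-aligned shapes.

The canal criterion is shape and size: elongation ≥ 3 *and* extent
≥ 30 µm (both configurable; murine cortical canals are an order of
magnitude more elongated than lacunae, so the classifier is insensitive
to the exact cut). The separation threshold is then 0.99 × the volume of
the smallest canal candidate — "just below the smallest vascular canal",
with a 1% margin for numerical stability — computed once per specimen,
never pooled across animals. Classification is purely volume-wise:
below the noise floor (default 8 voxels) → noise; at or above the
threshold → canal (the boundary is inclusive); between → lacuna. With no
elongated pore the threshold is +∞ and nothing is a canal.

Number densities are normalised to the solid cortex volume (the closed
mask), the natural denominator the porosity extraction already provides;
a bone-volume denominator (cortex minus pores) can be obtained from the
same masks if wanted. 1 mm³ = 10⁹ µm³ converts Lc.Dn to the customary
per-mm³ scale.

## Lacunar-volume distributions

Densities are Gaussian KDEs of log₁₀ volume — lacunar volumes span
orders of magnitude and are conventionally displayed on a log scale —
with the Silverman reference bandwidth 0.9·min(sd, IQR/1.34)·n^(−1/5)
(`bw.nrd0`, the "default bandwidth" of standard density plotting) and
2048 evaluation points spanning the data range ± 3 bandwidths. Local
maxima count as modes only with prominence ≥ 5% of the peak density;
smaller ripples are estimation artefacts. A bimodal density is split at
the grid point of minimum density between the two highest modes (the
estimated antimode); `proportion_below` is the fraction of lacunae
strictly below the split. Densities are estimated per animal (one curve
per specimen); for group-level splits the volumes of a group's animals
are pooled before estimation — the package takes no position beyond
exposing both routes, and the tests exercise the pooled one.

## Cross-sectional geometry and BMD

Per requested axial position (% of the bone-containing slice span):
CSA = bone pixel count × pixel area; the area second-moment tensor about
the section centroid (including the per-pixel self-moment p²/12) is
diagonalised to I_min ≤ I_max, with J = I_min + I_max. Ellipticity is
defined here as √(I_max/I_min) — the axis ratio of the moment-equivalent
ellipse, ≥ 1 with 1 = circular — because scanner-software definitions
are not published; the definition is recorded in the output metadata by
construction (it is a documented column). Cortical thickness is twice
the mean distance-transform value over ridge pixels of the section
(medial-axis approximation), with a half-pixel correction converting
centre-to-centre distances to boundary distances; a sphere-fitting local
thickness is out of scope. BMD applies an affine attenuation→density map
fitted through hydroxyapatite phantom points (exact through two points,
least squares through more); negative mapped densities are clamped to
zero with a warning.

Slices are taken perpendicular to the stack axis; specimens are assumed
scanned axially, and no anatomical re-slicing is attempted.

## Raman preprocessing and phosphate deconvolution

Preprocessing: (1) despiking — replace points more than 8 robust sds
from a 5-point running median (isolated cosmic rays distort at most two
grid points); (2) denoising — periodised Daubechies-4 wavelet transform,
4 levels, *hard* thresholding at the universal threshold with the noise
scale from the finest detail level. Hard rather than soft thresholding
is deliberate: soft thresholding shrinks every coefficient by the
threshold and visibly biases weak band shoulders downwards, which
matters when a minority mineral species is quantified. (3) Background:
a 9th-order polynomial fitted by asymmetric iterative reweighting —
points above the current fit by more than ~2 noise sds are down-weighted
by 10⁻³, so the polynomial settles onto the band-free lower envelope.
The naive clip-to-fit iteration was rejected because it creeps upwards
under broad bands (amide I) and systematically eats their area.

Normalisation divides by the local maximum within 1004 ± 5 cm⁻¹
(phenylalanine ring breathing), the internal standard for cell spectra;
all downstream areas are therefore in phenylalanine-normalised units and
only ratios and fold changes are interpreted.

Deconvolution fits pseudo-Voigt profiles — h·[η·L + (1−η)·G], FWHM
parameterisation, areas computed analytically — by bounded
Levenberg–Marquardt (`minpack.lm`). The ν₁PO₄³⁻ envelope (window
935–985 cm⁻¹) carries three sub-bands at nominal centres ACP 950,
OCP 955, CAP 961 cm⁻¹ (the CAP centre may be placed anywhere in its
customary 959–962 range via the config), centres bounded to ±2 cm⁻¹,
widths to 3–14 cm⁻¹. Two choices stabilise this fit, and both are
recorded as design decisions rather than spectroscopy claims:

* **Shared band shape.** Sub-bands 4–6 cm⁻¹ apart with FWHM ~5–6 cm⁻¹
  overlap within their widths, and a fully free fit is not identifiable:
  near-zero-residual solutions exist with very different area splits,
  and weak bands latch onto noise. By default one width and one
  Lorentzian fraction are shared across the three phosphate sub-bands
  (`share_shape = TRUE`), which restores identifiability; set it to
  `FALSE` to reproduce a fully free fit.
* **Stagewise multistart.** Heights are first solved linearly with the
  shapes held fixed (a convex subproblem), then everything is refined;
  three initial widths are tried and the lowest-residual solution wins.

Matrix bands (amide I 1590–1720, CH₂ 1410–1495, amide III
1230–1330 cm⁻¹) are fitted one per window with a linear local offset
that absorbs residual baseline curvature. The mineral-to-matrix ratio is
the fitted phosphate-envelope area over the amide I area; amide I is
taken as the matrix denominator where a published choice is ambiguous.
Fold changes follow the signed reciprocal convention: +A/B for
increases, −B/A for decreases, +1 for equality, so magnitudes are
symmetric about 1 and never in (−1, 1).

## Statistics

Two-way sex × genotype ANOVA uses type-II sums of squares
(`car::Anova`), the appropriate choice for the unbalanced group sizes
(n = 3–8) typical of littermate designs; with zero residual variance the
F statistic is undefined and p is reported as 1. Paired one-tailed
littermate t tests require the direction to be declared per endpoint;
identical pairs give t = 0, p = 0.5 by the boundary convention. ΔΔCt
expression is 2^(−ΔΔCt) against a reference gene and calibrator-group
mean, invariant to Ct offsets applied equally to target and reference.
Heat-map bins: red p ≤ 10⁻⁴, yellow ≤ 0.01, green ≤ 0.05, blue above.
No multiple-testing correction is applied across axial positions,
matching per-position reporting; `p.adjust` can be applied upstream by
the caller when a corrected map is wanted.

## What the synthetic generators emulate — and what they do not

The cortex phantom is an annular cylinder populated with non-overlapping
prolate-ellipsoidal lacunae (truncated log-normal volumes, optionally
bimodal; axis ratios up to `max_elongation`, default 2.2) and
near-axial capsule canals (cylinder plus hemispherical caps), with an
8-bit two-level intensity model (bone 180, background 40, additive
Gaussian noise σ = 5 by default, so an intensity threshold of 80 sits
~23σ from both class means), and optional low-intensity osteoid halos
around pores. Canals are placed before lacunae — a long canal corridor
cannot be threaded through an already-seeded annulus — and lacunae are
placed largest-first by rejection sampling with a two-voxel clearance,
so ground-truth labels are unambiguous and no two pores ever merge under
26-connectivity. When a target canal:lacuna volume ratio is requested,
the canal count and lengths are derived from the analytic capsule
volume and the last canal is length-trimmed after the lacunae are
rasterised, so the voxel partition hits the target to within a
voxel-slice of one canal (~0.01 percentage points).

Deliberately absent: X-ray physics (beam hardening, rings, phase
contrast), merged lacuna–canal composites, canal branching and
curvature, cement lines, partial-volume grey levels. Passing the
recovery tests therefore demonstrates that the *analysis chain* is
correct and voxel-faithful, not that it is robust to every artefact of
real synchrotron reconstructions; the threshold, closing radius and
shape criterion remain per-dataset scientific choices.

The Raman generator writes spectra as polynomial baseline (degree ≤ 9)
plus pseudo-Voigt bands plus white Gaussian noise and optional one-point
cosmic spikes; per-spectrum band areas vary by a log-normal factor
(`area_cv`, 6% in the shipped fixtures) emulating biological spread.
Real cell spectra add quartz background, fluorescence transients,
band-shape heterogeneity and wavenumber miscalibration, none of which is
modelled. The shipped fixtures place the weakest quantified band well
above the residual baseline-systematics floor (its height several times
the ~1–2% structured residual the 9th-order baseline leaves); species at
or below that floor are not reliably quantifiable per-spectrum by this —
or the original — protocol.

## Fixtures and problem sizes

The shipped study fixtures encode the published summary values as
generator ground truth: the three cortex phantoms (~432×432×300 voxels
at 0.65 µm, ~950–1300 pores) carry lacuna/canal volume partitions set to
the printed wild-type female (75.8/22.0), wild-type male (75.4/23.1) and
knockout male (22.3/76.1) compositions, renormalised over the two
generated classes since the generator emits no noise class; the two
Raman fixtures (50 spectra per group, 1 cm⁻¹ grid, noise 1% of the
tallest peak) encode the printed fold changes (male ACP +23.6, female
CAP +10.5, female mineral/matrix +11.9, and the accompanying OCP and
mineral/matrix folds) exactly in their band-area ratios. The acceptance
script and test suite run these fixtures end to end; unit and property
tests use smaller phantoms (~100–140 voxels across, tens of pores) so
the default test run stays fast.

## Known limitations

* Canal-network topology (branching, connectivity) is out of scope; only
  scalar indices are reported.
* `Ct.Th` and ellipticity are pinned, package-specific operational
  definitions; compare across software with care.
* The separation threshold assumes at least one true canal in the
  volume; a canal-free specimen classifies everything as lacunae/noise,
  which is the documented and intended degenerate behaviour.
* The KDE split is undefined for unimodal densities (`NA`), and the
  small-population proportion is only meaningful when a split exists.
* Per-spectrum deconvolution of heavily overlapped sub-bands relies on
  the shared-shape constraint; spectra whose species genuinely differ in
  width or Lorentzian character need the free fit and more informative
  data (or mapping over many spectra) to be identifiable.
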