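---
title: "Models and numerical choices in restbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in restbold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restbold)
```

`restbold` implements the post-processing stages of a resting-state fMRI
analysis: denoising, voxel-wise spontaneous-activity metrics, ROI
connectivity, network analysis, quality control and group statistics. This
vignette explains the models behind each stage, the parameters that matter,
and the numerical decisions made where the standard definitions leave room.

## Conventions used everywhere

Voxels are linearised in column-major order (X fastest, then Y, then Z);
every mapping between a volume and a frames × voxels matrix uses this one
order, so column 1 is always the in-mask voxel with the smallest linear
index. World coordinates are voxel centers pushed through the affine, with
0-based voxel indices. Grids "match" when shapes are equal and affines
agree within 1e-4 mm per element. The repetition time (TR, seconds) is read
from the NIfTI header time step; an explicit argument overrides it with a
warning when the two disagree.

## Nuisance regression

Each voxel's series `y` is modelled as `y = Xβ + ε` and the residual `ε`
is the denoised signal. The design can include an intercept (always),
linear and quadratic trends, tissue mean series (white matter, CSF,
optionally the global signal), the six realignment parameters, and three
variant families: first derivatives (backward difference, zero at frame 1),
1-frame lags (zero at frame 1), and elementwise squares of every base and
variant column. With every block and the global signal enabled the design
has 1 + 2 + 3·6 + 6·6 = 57 columns; dropping the global signal removes its
six variants, leaving 51.

Two numerical points deserve emphasis. First, enabling derivatives and lags
*together* makes the design rank-deficient up to rounding, because
`lag = base − derivative` except at the first frame; the fit then falls
back to a minimum-norm pseudoinverse solution and warns, rather than
failing or silently dropping columns. Second, columns are rescaled to unit
norm before the QR factorisation, so rank detection is not distorted by
the tiny magnitudes of squared-derivative columns; the residuals are
unchanged by this rescaling.

Scrubbing runs before the regression: frames whose framewise displacement
(FD) exceeds a threshold (default 0.5 mm) are flagged, the regression
coefficients are estimated on the retained frames only, and residuals are
produced for *all* frames so the subsequent FFT-based filter sees an
unbroken series. Censored frames should be dropped again at metric time.
Whether coefficients should be refit without censored frames or frames
merely deleted afterwards is genuinely open in the field; we chose the
refit because it prevents high-motion frames from biasing β while keeping
the series contiguous. Filtering defaults to running after regression;
`denoise(order = "filter_then_regress")` exposes the other order.

## Ideal band-pass filter

The filter extends each length-T series with its time reverse (length 2T),
takes the FFT, zeroes every bin whose frequency falls outside
`[low, high]` (both signs; bin k of the extended series has frequency
`min(k, 2T−k) / (2T·TR)`), inverse-transforms and keeps the first T
samples. The mirrored extension removes the wrap-around discontinuity that
plain periodic filtering would introduce. `low = 0` keeps the DC bin; the
Nyquist bin is kept only when `high` equals the Nyquist frequency
`1/(2·TR)`. Band-edge comparisons use a 1e-12 Hz guard against floating-
point representation of the bin frequencies.

An ideal (brick-wall) filter necessarily rings: a pure in-band sinusoid
passes with its fitted amplitude within 1%, but the first and last few
samples show Gibbs overshoot of order 10% at the edges. This is inherent
to the sharp frequency cut, not an implementation artifact; the mirrored
extension keeps it much smaller than zero padding would.

## Voxel-wise metrics

**Amplitude (AM).** `AM_mean = mean(|x − x̄|)` and `AM_std` is the
corrected (N−1) standard deviation of the mean-subtracted series.

**ALFF / fALFF.** From the one-sided amplitude spectrum
`a_k = sqrt(F_k F̄_k / L)` of the unfiltered series, ALFF is the mean of
`a_k` over the bins inside the band (default 0.01–0.08 Hz) and fALFF is
the in-band amplitude sum divided by the sum over all bins with
`0 < f ≤ Nyquist` — the DC bin is excluded from the denominator and the
Nyquist bin included. Zero-signal voxels get fALFF 0. The `1/L` factor
sits inside the square root, matching the "averaged square root of the
power spectral density" reading; with white noise the expected fALFF is
the band's share of frequency bins, which the tests verify.

**ReHo.** Kendall's coefficient of concordance over a voxel and its
neighbors (face/edge/vertex schemes: K = 7, 19 or 27 series including the
seed; at mask boundaries K shrinks to the available members and the actual
K enters the formula). Ranks use midranks for ties and no tie-correction
term is applied in the denominator, matching the common neuroimaging
implementations; fully constant neighborhoods are assigned W = 0 with a
warning. W is invariant under any strictly monotone transform of each
series, which the suite checks.

**FCD.** For each seed voxel, gFCD counts voxels whose correlation with
the seed *strictly* exceeds the threshold (default r = 0.6); lFCD is the
size of the region grown from the seed by repeatedly adding voxels that
are spatially adjacent (vertex-connected by default) to a member *and*
supra-threshold correlated with the seed — admission is by correlation
with the seed, not with region members; lrFCD = gFCD − lFCD ≥ 0 by
construction. The binarized connectivity is stored bit-packed, one bit per
pair (1/32 of the bytes of a dense float32 store); the packed and dense
paths return identical maps, which the suite asserts on random fixtures.

**FCS.** Seed-wise sum of Fisher-z connectivity strictly above a z-scale
threshold (default 0.25), divided by V − 1 (the seed is excluded from both
the sum and the denominator; the normalisation choice is documented here
because the convention varies).

**Normalization.** Mean mode divides by the in-mask mean; z-score mode
standardises to in-mask mean 0, sd 1. Degenerate inputs (zero mean or zero
sd) are errors rather than silent NaN maps.

## ROI connectivity

Spheres use voxel-center Euclidean distance ≤ radius; cubes use per-axis
offsets ≤ half-width (the size parameter is a half-width in mm). Overlaps
resolve to the nearer center, exact ties to the lower ROI index. Partial
correlation between two ROIs conditions on the mean series of all other
ROIs plus an intercept, computed from the inverse covariance; the test
suite checks it against an explicit two-step residual regression. The
Fisher transform clips |r| = 1 to 1 − 1e-7 (with a warning) so downstream
t-tests receive finite values. Connectivity matrices store a zero
diagonal, which keeps thresholded networks free of self-loops.

## Network analysis

Intensity thresholding keeps edges strictly above the cut; sparsity keeps
the top `floor(s·N(N−1)/2)` edges with ties broken lexicographically by
(i, j), so the edge count is exactly reproducible from s. Weighted path
lengths use 1/weight as the edge distance. Disconnected pairs are excluded
from the characteristic path length and contribute zero to global
efficiency. Betweenness is normalised by (N−1)(N−2)/2. Fault tolerance
(mean over nodes of E₋ᵢ/E), vulnerability (max of (E − E₋ᵢ)/E) and the
resilience proxy (area under the largest-component fraction during
targeted removal of the currently highest-degree node, ties to the lowest
index) are not pinned down by the literature this module follows; each is
isolated in its own function so an alternative definition can be swapped
in. Null models are degree-preserving double-edge swaps (default 10 per
edge), and small-worldness is σ = (C/⟨C_null⟩)/(L/⟨L_null⟩) over the null
ensemble (default 100 nulls; the tests use 30 to stay fast). Standard
graph primitives (shortest paths, betweenness, transitivity, components,
assortativity) are delegated to igraph; the test oracles re-derive them
with hand-written Floyd–Warshall and path enumeration.

## Quality control

FD follows the sum-of-absolute-differences convention with rotations
converted to arc length on a 50 mm sphere. Head displacement per frame is
`sqrt(x² + y² + z²)`; the "mean head displacement" is the mean over frames
of that quantity (the other reading — rms of per-frame means — is noted as
ambiguous and not used). Micro displacements count inter-frame changes of
the displacement exceeding 0.1 mm. The composite rotation angle is
`arccos((cos p·cos y + cos p·cos r + cos y·cos r + sin p·sin y·sin r − 1)/2)`,
reported in degrees. TSNR is the series mean over its (N−1) standard
deviation; zero-variance voxels get 0 and are excluded from thresholded
masks; group-level masks threshold the across-subject mean TSNR map.

## Group statistics and meta-analysis

The voxel-wise t-test fits `[intercept, group, covariates]` by least
squares and tests the group coefficient with df = n − p and two-sided p by
default; rank-deficient designs are an error naming the collinear columns.
Voxels whose residual variance vanishes to rounding noise are reported as
t = 0, p = 1 rather than 0/0. Meta-analysis combiners: Stouffer
`Σz/√k`; Fisher `−2Σln p` against χ² with 2k df; fixed effects by inverse-
variance weighting; mixed effects adds the DerSimonian–Laird moment
estimate of between-study variance, floored at 0 (the estimator choice is
interchangeable by design); conjunction-style maximum-p combiners
`(max p)^k` and `max p`. For Stouffer, signed one-sided p-to-z conversion
preserves effect direction. Multiple-comparison corrections delegate to
the standard step-up adjusted-p recursions; note that Benjamini–Yekutieli
does not dominate Bonferroni (its harmonic constant can make the rank-1
criterion stricter than α/m), so only the BH ⊇ BY and BH ⊇ Bonferroni
containments hold and are tested.

## Synthetic phantoms and what the tests show

The generator plants sinusoids, polynomial drifts and white noise in
labelled regions of a 3 mm isotropic grid, produces 6-column motion traces
(random-walk drift plus step events), and grows connected, disjoint ROI
blobs by face-connected accretion. One explicit seed determines every
fixture; the caller's random state is saved and restored. Default study
conditions in the tests: TR 2 s, 40–200 frames, band 0.01–0.08 Hz,
FD threshold 0.5 mm, r-threshold 0.6 — the regime the method descriptions
assume.

These phantoms deliberately omit hemodynamic convolution, physiological
noise spectra (cardiac/respiratory), spatial autocorrelation and scanner
drift structure. Passing tests therefore demonstrate that the formulas,
thresholds, storage formats and pipelines behave exactly as specified on
signals with known ground truth — not that any metric is sensitive or
specific on real BOLD data.

## Problem sizes

The test suite and the acceptance script run on small grids (tens to a few
hundred voxels, 25–200 frames, graphs of 3–30 nodes, 2000-voxel null
simulations, 30–50 random fixtures per property). These sizes were chosen
so every check derives from an exact oracle or a well-powered simulation
while the whole suite completes in well under a minute per module; the
algorithms themselves are vectorised over voxels and scale to whole-brain
matrices (the bit-packed FCD store exists precisely for the ~50,000-voxel
case).

## Known limitations

Component-based (CompCor) and ICA-based denoising are out of scope, as are
first-level activation GLMs, multi-group ANOVA, permutation/cluster
inference, modularity/community detection and the network-based statistic.
The batch runner parallelises across subjects only; per-subject numerics
are single-threaded and independent of the worker count, which the
determinism tests enforce byte-for-byte.
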