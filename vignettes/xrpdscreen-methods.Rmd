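---
title: "Methods: screening in cellulo protein crystals by SAXS/XRPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening in cellulo protein crystals by SAXS/XRPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrpdscreen)
```

## The measurement being modelled

A dense suspension of baculovirus-infected insect cells flows through a
1.8 mm quartz capillary on a low-background bioSAXS beamline (10 keV photons,
1.24 Å; 3.00 m sample–detector distance; 0.20 × 0.12 mm beam). Forty detector
frames of 0.045 s are collected per sample, followed by forty frames of the
TBS buffer, 0.005 s readout each — 4 s of beam time per data set. If a
fraction of the cells contains protein microcrystals, the randomly oriented
crystallites produce Debye–Scherrer rings; azimuthal integration of the
summed frames, buffer subtraction and conversion to `I(2θ)` yield a powder
profile whose Bragg peaks fingerprint the crystalline phase. The irradiated
volume, `0.20 × 0.12 × 1.8 ≈ 0.043 mm³`, holds several thousand cells, so
the measurement probes a representative fraction of the culture at once.

`xrpdscreen` implements this chain — reduction, screening, PCA phase
clustering, Pawley refinement — together with a synthetic-data generator
that stands in for the beamline.

## Reduction

Pixels are mapped to scattering angle by `2θ = arctan(r/D)` with `r` the
in-plane distance of the pixel centre from the beam centre. Binning assigns
each unmasked pixel wholly to the bin containing its centre (no pixel
splitting): at a 3 m distance the angular bins are many pixels wide and the
simple scheme is exactly checkable against a per-pixel oracle, which the
test suite does. Bin intensity is the mean pixel count; its uncertainty is
the Poisson `√(Σcounts)/n_pix`. Empty bins are dropped. No polarization or
solid-angle corrections are applied: the analysis rests on relative peak
positions, which such smooth multiplicative corrections do not move.

Buffer subtraction is plain `sample − scale·buffer` on the identical grid
(`scale` defaults to 1; a transmission factor may be configured — whether
the beamline pipeline normalised before subtracting is not derivable from
the data, and the scale field covers both readings). Mismatched grids are an
error, never silently interpolated. Negative differences are retained: they
carry the noise statistics that peak significance testing needs.

## Screening

The cellular background under a profile is estimated by iterative
smooth-and-clip: the estimate is repeatedly replaced by the pointwise
minimum of itself and its centred rolling mean (windows shrink symmetrically
at the edges), which erodes narrow upward excursions while following the
smooth decay; a final smoothing pass and a median re-centring make the
residuals unbiased — without re-centring, the min-clip hugs the lower noise
envelope and inflates every residual by about one sigma. Local noise is
`1.4826 × MAD` of the residual in a sliding window, robust against the peaks
themselves; because the pipeline also propagates Poisson sigmas, screening
can alternatively use those (`noise = "sigma"`).

A peak is a run of at least `min_points = 3` consecutive points
`≥ k_sigma = 5` local sigmas above baseline, reported at its
intensity-weighted centroid. A sample is called crystal-positive when at
least `min_peaks = 2` significant peaks are present: one excursion is not
accepted as proof of crystallinity (configurable to 1 for genuinely sparse
patterns). On 200 simulated crystal-free samples the false-positive rate at
these defaults is ≤ 5% (tested).

Very strong neighbouring peaks with Lorentzian character can fuse into one
threshold run through their overlapping tails; the detector reports such a
run as a single call. This is a property of run-based detection, not of the
data model.

## PCA phase clustering

Profiles are restricted to the 0.4–2.0° 2θ fingerprint window, interpolated
to a common grid where needed, normalised to unit total intensity and
mean-centred; scores on the first three principal components are grouped by
average-linkage agglomerative clustering cut at a user-supplied `k`. The
normalisation makes the clustering respond to peak *positions* (the phase)
rather than to crystal-fraction amplitude differences — reducing the
crystalline fraction scales peak intensities but does not move them. `k` is
deliberately user-supplied (the screening campaign knows how many candidate
phases it loaded); a silhouette-based automatic choice exists but is never
the default, to avoid silent model selection.

## Pawley whole-powder-pattern fitting

The model is

```
y(2θ) = Σ_j c_j T_j(x(2θ))  +  Σ_k I_k m_k PV(2θ − (2θ_k + Z); Γ(θ_k), η)
```

with shifted-Chebyshev background (`x` maps the fit window onto [−1, 1];
12 terms by default, 10–14 typical), pseudo-Voigt peaks of common FWHM
`Γ(θ) = √(U tan²θ + V tanθ + W)`, zero shift `Z` (bounded to |Z| < 0.1°),
multiplicities `m_k`, and one free intensity per merged symmetry class —
no structural model. Peak positions come from the unit cell and the
reflection conditions of the four supported space groups; the closed-form
absence predicates are verified in the tests against a structure-factor
cancellation oracle built from the full operator sets. The exact width and
asymmetry parameterization of commercial packages is not published;
Caglioti plus an optional single asymmetry term (off by default — the
symmetric profile is the testable baseline) is this package's reading, and
the fit report says so.

### Refinement strategy

Release is staged, mirroring standard WPPF practice: (1) background
coefficients and intensities — a weighted linear problem solved exactly by
QR, with intensities projected onto the non-negative orthant by an active
set (negative intensities would otherwise oscillate against the
background); (2) zero shift and cell; (3) profile parameters (`W` and `η`
by default; `U`, `V` can be released). Stages 2–3 are Levenberg–Marquardt
(`minpack.lm`) over the nonlinear parameters only, with the linear
subproblem re-solved at every residual evaluation (separable least
squares); accepted steps therefore never increase the weighted sum of
squares. The reflection list is regenerated whenever a cell update moves
any predicted position by more than a tenth of a grid step, so reflections
can enter or leave the window during refinement.

A starting cell a few per cent off predicts peaks that do not overlap the
observed ones at all — the local optimiser then has no usable gradient.
Stage 2 is therefore preceded by a deterministic scan over a common scale
factor applied to all cell lengths (±3% in steps of 5×10⁻⁴, the linear
subproblem re-solved at each trial), which restores the basin of
attraction. The scan is exhaustive and seed-free, so refinement remains
deterministic given its inputs.

Initial intensities come from local background-subtracted observed areas;
reflections whose centres lie within half a mean FWHM are treated as one
unresolvable group whose area is equipartitioned among members, then
refined freely.

`R_wp = 100·√(Σw(y_o−y_c)²/Σw y_o²)` is reported in per cent;
`χ²_red = Σw(y_o−y_c)²/(N−P)`. With statistical weights `w = 1/σ²` the
`(R_wp/R_exp)²` goodness-of-fit convention coincides with `χ²_red`; both
names are emitted since powder programs differ in which they print.
Standard uncertainties come from the full-parameter Jacobian at the
solution (exact columns for linear parameters, central differences for
nonlinear ones), scaled by `χ²_red`. Convergence: relative reduction of the
weighted SSR below 1×10⁻⁸ or 200 iterations per stage; non-convergence is a
flag on the result, not an exception. A singular normal matrix raises an
error naming the dependent parameters.

### Recovery protocol and window choice

The synthetic recovery experiments refine from ±2%-perturbed starts on
Poisson-noisy patterns of the two best-characterised phases: CatB-like
(tetragonal P4₂2₁2, a = b = 125.69 Å, c = 54.408 Å) over 0.4–2.0° 2θ
(~19 reflection classes) and HEX-1-like (hexagonal P6₅22, a = b = 58.01 Å,
c = 195.2 Å) over 0.4–3.0° (17 classes). The wider HEX-1 window is a
conditioning choice: only four of its reflection classes fall below 2.0°,
which leaves cell and zero shift nearly collinear over so narrow a range;
rings out to 3° (physically present — they extend to the detector edge)
restore identifiability. Median recovery over 20 seeded replicates is a few
parts in 10⁵ for both axes, comfortably inside the 5×10⁻⁴ tolerance the
tests assert, with the zero shift recovered to ≲10⁻⁴ degrees.

## The synthetic-data generator

The generator emulates, with everything seeded and bit-reproducible:

* a smooth cellular/buffer background `I_bg(s) = A s⁻ᵖ + C` (Porod-like;
  the real cell-suspension background is featureless and monotone, which is
  all the screening logic relies on; defaults `A = 50`, `p = 3`, `C = 100`
  counts s⁻¹ per bin give full-fraction peak SNRs of ~30–60, matching the
  qualitative contrast of the deposited profiles);
* Bragg peaks at the positions of a chosen cell/space group with
  per-reflection mean intensities drawn log-normal (σ_log = 1). The draws
  are seeded by the *phantom*, not the measurement: relative intensities
  are a property of the phase, so replicate measurements share a
  fingerprint and differ only in counting noise. No structure factors are
  computed — the Pawley model treats intensities as free parameters, so a
  structured draw carries exactly the information content the refinement
  sees;
* linear scaling of the Bragg component with the crystal-cell fraction
  (crystal volume per cell held fixed), which is what a 1:2 dilution with
  mock-infected cells does to the signal;
* Poisson counting noise on expected counts accumulated over the frame
  scheme (40 × 0.045 s), with paired independent buffer realisations;
* granular 2D rings: each of `n_crystallites` contributes spots at ring
  radii `r_k = D tan 2θ_k` at independent random azimuths (per-crystallite,
  per-reflection Bernoulli with probability ∝ multiplicity × rocking
  fraction), so azimuthal spottiness decreases as the crystallite count
  grows — the tests verify this monotonicity at 10/100/1000 crystallites.

What the generator does **not** emulate: absorption, polarization and
solid-angle corrections, capillary scattering, detector module gaps and
point-spread, cell settling, and any absolute crystallite-count-to-SNR
calibration. The last point matters for interpretation: the instrument's
absolute sensitivity is not reproducible on synthetic data, so dilution
detection limits are validated *structurally* (SNR halving per 1:2 step, a
sharp last-positive step at the predicted boundary, scores monotone in
dilution) rather than as absolute percentages of crystal-containing cells.
Passing tests show the pipeline's logic is correct, not that a particular
beamline reaches a particular detection limit.

Test and acceptance fixtures use a scaled-down detector (192–320 px,
0.75–2 mm pixels at 3 m) rather than full Pilatus dimensions; the geometry
mapping is identical and the reduction is oracle-checked, so nothing about
the method depends on the detector scale.

## Numerical choices and degenerate inputs

* Chebyshev polynomials are evaluated by the `cos(j·acos x)` closed form;
  the tests compare against the three-term recurrence at 1×10⁻¹².
* Equivalent reflections merge on symmetry-class membership, never on
  d-spacing alone, so accidental degeneracies stay separate Pawley
  intensities; the class representative is the lexicographically greatest
  orbit member.
* The truncated pseudo-Voigt: within ±50Γ a unit-area Lorentzian carries
  only `(2/π)atan(100) ≈ 0.9936` of its mass; tests assert the exact
  truncated value rather than pretending the tails vanish.
* Identical patterns passed to the PCA are rejected as degenerate rather
  than clustered arbitrarily; `k` larger than the number of patterns is an
  error.
* All-masked frames, mismatched grids, non-positive sigmas, (0,0,0) indices
  and empty angular windows raise immediate validation errors; an empty
  reflection window returns an empty list, which is a valid result.

## Known limitations

* Only the four observed space groups plus primitive-lattice fallbacks are
  supported; there is no general space-group machinery, no centring, no
  anomalous effects.
* Ab initio indexing is out of scope by design — the low-angle windows hold
  too few peaks for it; the refinement always starts from a user-supplied
  cell (e.g. from a related crystal structure).
* Rietveld (structure-factor) refinement and microstructure analysis are
  not implemented; intensities are free parameters only.
* Run-based peak detection reports fused calls for strongly overlapping
  Lorentzian peaks, as noted above.
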