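---
title: "Structure determination from unindexed powder patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure determination from unindexed powder patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powsolve)
```

## The problem

Structure determination from powder diffraction normally starts by indexing
the pattern: finding the unit cell from the reflection positions. For
nanocrystalline samples with few, broad, overlapping reflections, indexing
fails, and with it every direct-space method that needs the cell as input.
`powsolve` attacks this case by fitting *everything at once* — unit cell,
molecular position, orientation and selected internal torsions — against the
raw pattern, using a similarity measure that stays informative even when the
simulated reflection positions are far from the observed ones.

## The similarity measure

Two patterns $I_1(2\theta)$, $I_2(2\theta)$ on a common grid are compared
through their weighted cross- and auto-correlations:

$$ S_{12} = \frac{\sum_k w_k\, c_{12,k}}
{\sqrt{\left(\sum_k w_k\, c_{11,k}\right)\left(\sum_k w_k\, c_{22,k}\right)}},
\qquad c_{12,k} = \sum_i I_1(\theta_i)\, I_2(\theta_i + k\Delta), $$

with the triangular weight $w_k = \max(0, 1 - |k\Delta|/l)$. The
*neighbouring range* $l$ (the FWHM of the weight triangle, in degrees
$2\theta$) sets the tolerance: a broad window ($l \approx 1\text{–}2^\circ$)
rewards patterns whose strong peaks are merely *near* each other, which is
what makes pre-selection of random trial structures possible at all; a narrow
window sharpens the comparison as a fit converges. In the $l \to 0$ limit the
measure becomes the uncentered cosine of the two intensity vectors — for
background-corrected (near mean-free) patterns this coincides with the
Pearson correlation coefficient, and the package exposes the centered variant
behind a flag. Evaluated at $l = 0$ over the full measured range it is called
the *reference similarity*, the scale-free figure of merit used for all
ranking, filtering and clustering. $S_{12}$ is symmetric, invariant under
rescaling of either pattern, 1 exactly for identical patterns and confined to
$[0, 1]$ for non-negative patterns.

The integrals of the underlying continuous definition are realized as sums on
the uniform grid with the lag step equal to the grid step. This makes every
value reproducible by a brute-force double loop, which the test suite
exploits (agreement to $10^{-10}$).

## Structure model

A trial structure is a z-matrix molecule placed in a cell:

* **cell** $a, b, c, \alpha, \beta, \gamma$, constrained by the crystal
  system (monoclinic fixes $\alpha = \gamma = 90^\circ$, orthorhombic all
  three);
* **position** $m_x, m_y, m_z$, the fractional coordinates of the anchor
  point (the centroid of the non-dummy atoms). Floating-origin directions of
  polar groups are pinned to 0, and special positions (inversion centre,
  2/m) fix the anchor entirely;
* **orientation** $\varphi_x, \varphi_y, \varphi_z$, applied as
  $R_z \, R_y \, R_x$ about the anchor. A site symmetry of 2, m or 2/m
  aligns the molecular axis with the crystallographic one and leaves a
  single free rotation;
* **torsions** $\tau_i$, the z-matrix rows flagged as free (bond lengths,
  angles or dihedrals).

The parameter-count rule (cell by crystal system + unpinned anchor
coordinates + unconstrained orientation angles + torsions) reproduces the
full published count table for the nine pigment-search symmetries
(9, 9, 9, 5, 7, 10, 7, 9, 6), which the acceptance suite asserts.

Molecules on special positions are handled by expansion-and-merge: the full
molecule is expanded by all space-group operators and copies that coincide
atom-by-atom (within 0.3 Å, under lattice translation) are merged; a model
whose molecule does not actually carry the site symmetry is rejected. The
anchor convention and rotation order are fixed here for reproducibility; the
method does not depend on them.

## Pattern simulation

Reflections are enumerated over the full sphere, reduced to symmetry-unique
representatives under the Laue group (multiplicity = orbit size, Friedel
pairs included), and screened for systematic absences by the general
operator test ($h R = h$ with non-integral $h \cdot t$). Intensities are

$$ I_{hkl} = s \cdot LP(\theta) \cdot A \cdot T \cdot M \cdot |F_{hkl}|^2, $$

with 4-term-Gaussian atomic scattering factors, one overall isotropic
displacement parameter ($B = 3$ Å$^2$ by default, typical for
room-temperature organics, not fitted), and the Lorentz–polarization factor
for a diffractometer with a primary monochromator
($2\theta_m = 27.26^\circ$, Ge(111) with Cu K$\alpha_1$; 0 gives the
unpolarized form). Absorption and preferred orientation default to identity:
the similarity measure is deliberately insensitive to such smooth intensity
modulations, and modelling them is the job of downstream Rietveld
refinement, not of this package. Peaks are rendered with a constant-FWHM
unit-area profile (pseudo-Voigt with $\eta = 0.5$ by default), truncated at
6 FWHM and normalized over the truncated support so the rendered area equals
the reflection intensity; enumeration extends 3 FWHM beyond the window so
edge tails are correct. Reflection geometry is cached on (cell, symmetry,
range), so moves that only change position/orientation/torsions re-use it.

## Preprocessing

* **Background**: iterative min-of-chords clipping with a decreasing window
  (SNIP-style), estimated on a lightly smoothed copy so the baseline does
  not track the lower noise envelope; the correction subtracts that baseline
  from the raw data and clamps at zero. The similarity measure tolerates
  imperfect background modelling by construction, so a deterministic,
  dependency-free estimator is adequate here.
* **Peaks**: local maxima above a prominence threshold (fraction of the
  pattern maximum), refined by a three-point parabola.
* **FWHM**: golden-section maximization of the narrow-window similarity
  between the pattern and a stick-pattern rendered from the extracted peaks
  — no indexing and no structural model involved.
* **Smoothing**: optional Savitzky–Golay (2nd order), off by default, used
  for very noisy data.

## Local fitting

The cost is $S_{12}$ between the simulated and the background-corrected
experimental pattern, maximized over the free parameter vector. Two
optimizers are provided: a conjugate-gradient ascent with numerical
gradients (finite-difference deltas of about a third of a coordinate step,
so the gradient sees over the grid discretization) for fast raw fits, and a
coordinate-wise *hill climb* (try $\pm$step per parameter, accept the best
improving move, halve all steps when nothing improves) which is slower but
markedly more robust on this rugged similarity surface. Default step sizes:
0.03 Å (lengths), 0.3° (cell angles), 0.01 (fractions), 3°
(orientations/torsions). Fits run on unwrapped angles; anchor fractions are
wrapped into $[0,1)$ between stages. Search-range boundaries act on the
*starting* structures only; trajectories that leave the range are damped by
a smooth multiplicative restraint $\exp(-( \text{excess}/w)^2)$ with $w$ =
10% of the range span, never clipped.

A staged schedule runs fits at non-increasing $l$ (the shipped raw-fit
cycle uses $l \times \{0.72, 0.58, 0.43\}$, the ratio ladder of the
published fit-evolution trace), and a fine fit ($l = 0.1\text{–}0.2^\circ$,
wider range, stricter convergence) may treat the profile FWHM as one extra
fitted scalar.

## The global search

Random trial structures flow through four stages of increasing cost:

1. **volume/geometry filter** — molar volume inside the window estimated
   from atomic volume increments (±10% by default, with an optional packing
   factor, e.g. 0.9 for densely π-stacked planar molecules), and no
   intermolecular contact below 0.7× the covalent-radius sum (hydrogens
   ignored). No pattern is simulated for rejected trials. Cell-length
   sampling ranges run from 3.2 Å (the π-stacking limit — a shorter axis
   would also push its first reflection outside a typical measurement
   window, leaving it undetermined by the data) up to the molecular
   diameter plus a margin.
2. **pre-selection** — simulate and score at a broad window
   ($l = 1.5^\circ$ initially); pass if above the gate $S_{sel}$.
3. **raw fit** — a fast, shallow local fit; pass if above $S_{opt}$. The
   default is a short coordinate hill climb: side-by-side runs from
   identical starts showed it reaching equal or better similarity than the
   numerical conjugate gradient at about two thirds of the evaluation
   count on this surface (central-difference gradients are expensive);
   the conjugate-gradient raw fit remains available by configuration.
4. **accurate fits** — hill-climb cycles with the narrowing-$l$ ladder.

Survivors become candidates; the integer weight $W_C$ counts the levels
passed. The two gates adapt during the run: costs are accounted in
pattern-simulation units (deterministic, unlike wall-clock), and a
proportional controller moves each gate to the empirical quantile of recent
gate scores that steers the three stage groups toward a 40/30/30 cost
split. At iteration points the candidate list is clustered (greedy leader
clustering in descending reference similarity at $l = 0.3^\circ$, threshold
0.995; merged candidates add their $W_C$ to the representative), every
candidate's cell is reduced, the search space is auto-focused, and the
pre-selection window narrows. Auto-focusing narrows a parameter's range to
median ± 2.5 IQR only when the qualified-candidate population looks
monomodal (IQR below half the populated range — a deliberately simple,
dependency-free concentration test standing in for a formal dip test), and
pushes a range edge outward when ≥10% of the population piles into the
outer 5%. A final phase re-explores ±5% neighbourhoods of the top
candidates. The whole run is a deterministic function of the configuration
and the master seed.

Re-evaluation merges runs across symmetries, filters by a reference-
similarity floor, the volume window and a top-N cap (400, matching the
published primary-selection count), fine-fits the leaders keeping the
better of old and new model, clusters once more, and ranks by reference
similarity with $W_C$ as tie-breaker. Screening mode replaces the random
generator with a user-supplied model list; the solution-fit / regional /
reduced modes are pure search-space presets over the same machinery.

### Cell reduction

Triclinic cells are Niggli-reduced with the Krivy–Gruber step algorithm,
ending in the all-obtuse (or all-acute) angle convention; monoclinic cells
are normalized to $\beta \ge 90^\circ$. When a structure model is reduced,
anchor and orientation are transformed along with the basis; an improper
accumulated transformation is composed with the lattice inversion, which
leaves every powder pattern invariant (Friedel symmetry), so reduction never
changes a model's simulated pattern (asserted to $10^{-9}$).

## The synthetic test bed

Real nanocrystalline pigment patterns are not distributable with this
package, so it ships a generator with known ground truth: an elongated
planar centrosymmetric C$_{10}$O$_2$ body (two fused six-rings with two
inversion-related oxygens — the shape anisotropy and scattering contrast of
a pigment molecule), a hinged fragment with two free dihedrals, and a
Cu–Cl/Cu–N coordination fragment with four internal degrees of freedom,
mirroring the three molecule classes the method targets. The rigid body's
elongation matters: a compact near-circular molecule packs into
near-equiaxial cells, whose powder patterns suffer from pseudo-homometric
lattice ambiguities (several distinct cells matching every peak), and its
orientation is invisible if the scattering contrast across the ring is
small. Toy structures are drawn from the same search space the solver
uses (contact-valid, volume inside the increment window), and patterns get
a smooth quadratic background plus Poisson counting noise. The simulated
measurement covers 5–45° 2θ (step 0.06°): wide enough that the ~10$^2$
reflections determine these lattices uniquely, as a real measurement
would be.

The signal-to-noise ratio is defined as the tallest peak height over the
counting-noise standard deviation at that peak, i.e. the peak registers
SNR$^2$ counts; a one-count floor keeps empty regions noisy. The shipped
suite uses SNR ∈ {50, 10, 4} on the molecule placed on inversion centres
in P-1, P2$_1$/c and Pbca (Z′ = 0.5; 9, 7 and 6 free parameters — the
symmetry hierarchy of published centrosymmetric pigment searches). At SNR 4
the strongest peak carries ~16 counts: controlled experiments in which the
fine fit is started *from the truth itself* cap at reference similarity
≈ 0.87–0.96 against the noise-free pattern (while cells still come back
within ~1%), so at that noise level a 0.98-similarity recovery bar is
information-limited — no search strategy can clear it, because the data do
not determine the structure that precisely. This is a property of the
noise condition, not of the optimizer.

Recovery at the shipped trial budget is partial by construction. The
production-scale method runs $10^6$–$10^7$ trials per symmetry; the suite
runs $2 \times 10^4$ so it completes in minutes, a 100–1000× scale-down of
a search whose pre-selection stage must find needles in a 6–9-dimensional
space. At that scale the broad-window scores of trials with a
nearly-correct cell but random orientation largely overlap the upper tail
of fully random trials, so only a fraction of runs feed a truth-basin
start into the fitting stages; which cases recover depends on the seed.
The recovery test reports the measured count; treat it as a
characterization of the scaled-down operating point, not of the method at
production scale.

What passing the toy suite does **not** show about real data: real patterns
have anisotropic and angle-dependent broadening, K$\alpha_2$ contamination,
texture and absorption effects, and phase impurities, none of which the
generator emulates (all are deliberately downstream concerns or out of
scope).

## Problem sizes and numerical choices

The shipped recovery suite runs each case with $2 \times 10^4$ trials on a
$5\text{–}45^\circ$ window at a 0.06° step (667 points, FWHM 0.3°) — sizes
chosen so a full nine-case suite is a coffee-break computation on one core.
The gate controller starts adapting after 100 trials; its cost priors make
earlier adaptation unnecessary, and a longer uncalibrated warm-up would
spend a large share of the budget fitting structures the calibrated gates
would reject.
Degenerate inputs are handled explicitly: identically-zero patterns are
rejected by the similarity (undefined normalization), cells whose metric
discriminant is non-positive are invalid, trial cells are rejected (not
clipped) until the volume window is met, with a hard failure after $10^5$
consecutive rejections diagnosing inconsistent ranges. Ties in clustering
are broken by candidate id; a contact exactly at the threshold passes
(strict inequality).

## Known limitations

* Z-matrix models with several independent molecules must be encoded as one
  ensemble with dummy-atom links; there is no multi-anchor support.
* The operator tables cover the eleven shipped space groups; others must be
  supplied as triplet strings.
* No energy descriptor: candidate plausibility rests on the pattern fit and
  the molar volume alone.
* Rietveld-grade profile physics (K$\alpha_2$, asymmetry, texture) is out
  of scope by design; the final structures are meant to be passed on to a
  refinement program.
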