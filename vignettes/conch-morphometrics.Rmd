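---
title: "Ontogenetic morphometrics of chambered conchs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontogenetic morphometrics of chambered conchs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(conchmorph)
```

`conchmorph` quantifies three characters of a chambered cephalopod conch
through ontogeny — suture-line shape, whorl cross-section shape, and septal
spacing — and summarizes their similarity structure across species and
growth stages. This vignette explains the statistical machinery, the
synthetic data generator that stands in for CT-derived specimens, every
numerical choice that was genuinely open, and what the passing test suite
does and does not establish about real data.

## 1. Shape analysis pipeline

### Equidistant semi-landmarks

Each suture line is a closed 3D curve (the intersection of a septum with the
outer shell wall); each whorl cross-section is a closed 2D outline. Curves
are densely sampled polylines (the generator emits 512 vertices; arc length
is piecewise linear, so resampling error is controlled by input density and
no spline dialect needs to be fixed). A curve is reduced to k equidistant
landmarks — 20 per suture, 40 per outline, the counts used throughout —
starting at the *venter*: the vertex farthest from the coiling axis in the
median plane, ties broken toward the lowest index. The starting rule matters
because landmark 1 anchors the correspondence around a closed curve; an
anatomical rule keeps configurations comparable across chambers and
specimens. Whether one should landmark the full closed suture or only one
half up to the symmetry plane is a genuinely open question; the full curve is
the default here and the resampler is agnostic to the choice.

### Sliding by bending-energy minimization

Equidistant points carry no point-wise homology, so they are slid along their
curve to optimize correspondence with a reference configuration. The
criterion is the thin-plate-spline bending energy: with L the k×k
bending-energy matrix of the reference (the upper-left block of the inverse
of the bordered TPS system; kernel U(r) = r² log r in 2D and U(r) = −r in 3D,
the sign chosen so that L is positive semidefinite — flipping the kernel sign
only rescales the quadratic form's sign convention, not the minimizer), the
energy of a target Y is Σ_d Y_dᵀ L Y_d. It is zero exactly on affine
transforms of the reference, which is also the package's primary correctness
oracle.

Sliding is tangential: each landmark gets one tangent direction from the
segment of its own curve it projects onto; the sliding magnitudes solve the
exact linear system of the quadratic objective (the Hessian is L ⊙ TTᵀ
restricted to the free landmarks, with a 1e-10 relative ridge for
rank-deficient cases); slid points are re-projected onto the curve; a
backtracking halving step guarantees the energy never increases after
projection. Defaults: 10 iterations, relative-energy tolerance 1e-8, only
the start landmark fixed. The reference is the configuration of median
centroid size among those analyzed (deterministic tie-break by label) —
a size-median reference avoids extremes, and because the minimizer of the
quadratic is invariant to rescaling of L and of the target, sliding is
insensitive to the size gap between a configuration and the reference.
Landmarks slide along each specimen's *own* outline while the energy is
measured against the reference; this is the standard reading of sliding
semi-landmarks on curves, the alternative (displacements constrained to the
reference outline itself) being geometrically ill-posed across specimens.

### Procrustes superimposition and its conventions

Generalized Procrustes analysis centers every configuration, scales it to
unit centroid size (full Procrustes; no partial option), and iteratively
rotates all configurations onto the running consensus with proper rotations
only (reflections are never matched). Two conventions deserve a note:

* **Consensus scale vs. zero-mean residuals.** The mean of unit-size
  configurations has centroid size slightly below one, so "aligned
  configurations have unit size", "the consensus has unit size" and
  "residuals average to zero" cannot all hold exactly. After convergence the
  whole set is rescaled by one common factor so the consensus has exactly
  unit centroid size and the residuals average exactly to zero; each aligned
  configuration then has a common size of 1 + O(shape variance).
* **Canonical orientation.** A Procrustes fit is defined only up to a joint
  rotation. The converged set is rotated so the consensus lies along its
  principal axes, with each axis's sign fixed by requiring the
  largest-magnitude projected coordinate to be positive and the last axis
  chosen to keep the determinant +1 (no reflection). With this, the entire
  GPA → PCA path is bit-reproducible and invariant to arbitrary similarity
  transforms of the inputs — a property the test suite checks to 1e-8. The
  sign rule can be unstable for configurations with near-symmetric consensus
  shapes; conch outlines and sutures are far from that regime.

### Ordination and phenograms

PCA is an eigendecomposition of the covariance of the flattened residuals,
with no variable rescaling; eigenvector signs are fixed by making each
loading's largest-magnitude element positive. All configurations of a
character (every chamber and section of every specimen) enter one pooled
PCA, so each specimen traces an ontogenetic trajectory in PC space; stage
analyses then slice this pooled space rather than re-ordinating per stage
(a per-stage PCA would reshuffle axes across stages and make trees harder to
compare; distances over *all* PCs are identical either way because they equal
centered-residual distances).

Trees are canonical neighbor joining on Euclidean distances over all PCs.
Determinism is pinned down by breaking Q-criterion ties toward the
lexicographically smallest label pair; negative branch lengths are clamped to
zero with the deficit moved to the sibling branch at the same join, which
preserves path lengths through the join (configurable off). On additive
matrices the implementation recovers the generating tree exactly, the
theorem-backed property the tests exercise on random trees. Stage trees take
the two configurations per specimen closest in conch diameter to the stage
proxy (20 mm, 50 mm, maximal; ties toward the smaller diameter; "maximal"
means the last two configurations), so every specimen contributes two tips.
Septal spacing is a scalar, so its tree distance is the absolute angle
difference between tips.

## 2. Septal-spacing statistics

Septal angles are successive differences of cumulative septal rotation about
the coiling axis; the angle at series position i belongs to chamber i+1 and
chamber 1 carries no angle (it is excluded throughout, as it is unreliable at
CT resolution). Chambers are staged by a three-part rule: the last two
chambers are mature; of the rest, diameter < 30 mm is pre-hatching and
≥ 30 mm juvenile–submature (exactly 30 mm is juvenile). Within each stage,
angles are pooled per species/population and compared by classical one-way
ANOVA followed by Tukey–Kramer comparisons (the studentized-range procedure
with the unbalanced-size correction; with two groups it reduces to the
pooled-variance t test, a closed-form identity the tests verify). Groups
with a single observation are excluded from pairwise tests with a warning.
Pooling several chambers per specimen within a stage means samples are not
independent within specimens; the package reproduces this pooled design
deliberately and does not model within-specimen correlation — a repeated-
measures extension would be the natural next step for real data.

Hatching is detected from the angle series as the first angle within the
first 12 chambers that falls at least 20% below the running early-ontogeny
maximum ("steep" is qualitative; 20% is the package's explicit, configurable
threshold). The detected chamber is the drop chamber.

## 3. The synthetic conch generator

The generator exists so the whole pipeline is testable end to end without
any deposited CT data; it emulates the *statistical structure* of a real
study — 9 species/populations × 2 specimens — not the anatomy of any real
species.

**Coiling.** A logarithmic spiral in cylindrical coordinates: conch diameter
d(θ) = d₀·W^(θ/360°) with whorl expansion rate W ≈ 3 per revolution and
d₀ = 17.5 mm at the first septum, giving ≈ 2 whorls, hatching near 30 mm and
maximal diameters near 160–180 mm over 27 chambers — the magnitudes typical
of modern nautilids. Conch diameter of a chamber or section is the maximum
distance across the spiral in the median plane (d(θ)·(1+W^(−1/2)) scaling is
folded into d); this is a declared convention, the standard conchometric one.

**Whorl outline.** An ellipse of height/width ratio `section_aspect`,
deformed radially by cosine harmonics c₂cos2φ + c₃cos3φ + c₄cos4φ (cosines
only, preserving bilateral symmetry), occupying the radial band between the
umbilicus (`umbilical_ratio`) and the outer spiral. Outlines whose harmonic
modulation would self-intersect are rejected with an error naming
`section_shape_coeffs`.

**Suture.** The outline swept into 3D at its chamber's azimuth, displaced
adapically by one shallow lateral lobe per flank
(arc displacement ∝ `suture_lobe_amplitude`·H·sin²φ, zero at venter and
dorsum) — the single-lobe geometry of nautilid sutures.

**Septal schedule.** Angles rise monotonically to a peak at chamber h−1
(h = hatching chamber, 7 by default), drop by ≥ 20% at chamber h, fluctuate
about `angle_mid` (default 25°, constrained to the 20–30° band and to at
most 0.8·`angle_pre` so the hatching drop always qualifies), and decrease
strictly over the final `crowding_chambers` angles (terminal septal
crowding). Chamber-to-chamber noise (1.2° sd) is clamped so the
rise–drop–plateau–crowding contract holds for every seed, a property the
tests check over 1000 seeds.

**Ontogenetic shape program and calibration.** Two ontogenetic signals are
built in. (i) A discrete shape change at each specimen's hatching diameter —
embryonic outlines are inflated (aspect ×1.5, strong positive cos2φ) and
sutures nearly lobeless; hatching in nautilids is an abrupt, recorded event
on the shell, and modelling it as a step means every configuration is
unambiguously pre- or post-hatching. (ii) Smooth drift that saturates by
≈ 40 mm, reproducing the published pattern of shape trajectories levelling
off in middle ontogeny. Species-level deviations from the genus base are
expressed progressively (factor 0.25 + 0.75·logistic((d−33)/2.5)), so before
hatching only a quarter of the species signal is visible while from ≈ 40 mm
it is fully expressed. The nine species deviation vectors were designed
against the *measured* geometry of the slid-and-superimposed shape space:
aspect and cos2φ act along nearly the same "elongation" axis (empirical
correlation 0.99 between their effect vectors), so deviations are laid out in
the three effective axes (elongation, cos3φ, cos4φ) by max–min spacing, with
the two conspecific populations and the two congeneric species placed as
nearest neighbors. With intraspecific CV 0.015 and 0.05 mm isotropic
coordinate noise, the realized calibration at the 50 mm stage is a
between-group to within-group distance ratio of ≈ 6 (and ≈ 1 at 20 mm,
where noise is proportionally larger and the species signal attenuated) —
enough that middle-ontogeny trees recover most groups as exclusive clades
while pre-hatching trees recover essentially none, the qualitative contrast
the package is designed to exhibit. These defaults were fixed once, from the
calibration above, and are not tuned per seed.

**What the generator does not emulate.** Real CT artifacts (partial-volume
effects, segmentation bias), allometry of the umbilicus, asymmetry,
pathological septa, within-curve correlated noise, and any hydrostatic or
physiological control of septation. Passing tests therefore demonstrate the
*method's* correctness and the pipeline's ability to recover structure of
the designed kind and magnitude — not that real nautilid species are
separable at any particular stage.

## 4. Numerical choices and degenerate inputs

* Polyline arc length everywhere; resampling gap uniformity is exact to
  1e-9·L by construction.
* TPS systems with duplicate landmarks fail with the offending pair named;
  bending energies are clamped at zero from below (eigenvalues of L are
  nonnegative up to −1e-10 round-off).
* GPA iterates to a consensus RMS change below 1e-12 (default cap 100
  iterations) — far tighter than the shape signal, so downstream scores are
  stable to the 1e-8 the invariance tests require. Zero-size configurations
  are rejected by label.
* All-identical ANOVA inputs define F = 0, p = 1; a zero within-group sum of
  squares with distinct means gives F = ∞, p = 0.
* The acceptance-style null calibration (9 groups × 4, 2000 replicates)
  checks the empirical size of the ANOVA at α = 0.05 within Monte-Carlo
  error; p-value uniformity is checked by Kolmogorov–Smirnov.
* Problem sizes in the test suite: the full default design (18 specimens,
  ≈ 770 landmark configurations, pooled trees of up to 468 tips) runs once
  and is shared across checks; unit tests use 3-species subsets and curves
  of 192 points, sizes at which every property being tested is already
  expressed.

## 5. File formats

TPS landmark records (`LM=`/`LM3=` with an `ID=` provenance line) round-trip
bit-identically at six decimals; pipeline intermediates use 12 decimals so a
file-based re-run reproduces the in-memory analysis to 1e-10. Newick output
quotes labels containing reserved characters (doubling embedded quotes) and
round-trips bit-identically; the bundled reader handles quoted labels.
Septal angles, PC scores and test tables are plain CSV; the full synthetic
dataset (curves included) serializes to JSON at full precision. Trees are
unrooted; serialization roots them arbitrarily at the last join.

## 6. Known limitations

Sliding is tangent-line only (curves, not surfaces); there are no deformation
grids or relative-warp visualizations; phenograms carry no bootstrap support
values and are similarity summaries, not phylogenies; the pooled-chamber
ANOVA ignores within-specimen correlation; and the stage proxies (20/50 mm,
last two chambers) are conventions inherited from conchometric practice, not
estimated change-points.
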