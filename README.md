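# conchmorph

Geometric morphometrics of nautilid conch ontogeny in R.

Externally shelled cephalopods build a chambered conch; the curve where each
septum meets the outer shell wall is the **suture line**, a character
taxonomists have leaned on for two centuries. `conchmorph` quantifies three
conch characters through ontogeny — suture-line shape, whorl cross-section
("conch geometry") and septal spacing — and asks at which growth stage each
character actually distinguishes species and populations. It is written for
morphologists and paleobiologists who have per-chamber curves (from CT
segmentation or any other source) and want a reproducible, scriptable version
of the landmark → slide → superimpose → ordinate → cluster workflow.

## The method

For each specimen the package takes an ontogenetic series of closed curves:
one 3D suture curve per chamber (chamber 1 excluded as unreliable at scan
resolution) and one 2D whorl cross-section outline every 45° of rotation from
the aperture. Each curve is resampled into equidistant landmarks
(k = 20 for sutures, k = 40 for outlines), starting at the venter. Because
equidistant points carry no point-wise homology, they are treated as
**sliding semi-landmarks**: each configuration's landmarks slide along the
tangent directions of its own curve to minimize the thin-plate-spline
**bending energy**

&nbsp;&nbsp;&nbsp;&nbsp;E(Y) = Σ_d Y_dᵀ L Y_d,

where L is the bending-energy matrix of a reference configuration (kernel
U(r) = r² log r in 2D, sign-corrected U(r) = r in 3D) — the quadratic form
that vanishes exactly on affine transforms of the reference. The slid
configurations are superimposed by **generalized Procrustes analysis**
(translation, scaling to unit centroid size, proper rotations onto an
iterated consensus) and the Procrustes residuals are ordinated by PCA.
Similarity among individuals at an ontogenetic stage is summarized by
**neighbor-joining phenograms** built from Euclidean distances over all PCs,
at three stage proxies: conch diameter 20 mm (pre-hatching), 50 mm (middle
ontogeny) and maximal diameter (maturity), taking the two configurations per
specimen closest to each proxy. Septal spacing (the rotational angle between
successive septa) is compared across species/populations with one-way ANOVA
plus Tukey–Kramer pairwise tests within three stages: diameter < 30 mm,
≥ 30 mm up to the third-from-last chamber, and the last two chambers.

Because real CT-derived data of this kind are not generally deposited, the
package ships a parametric **synthetic conch generator** (logarithmic-spiral
coiling, harmonically deformed elliptical whorl outlines, one shallow lateral
suture lobe per flank, a septal-spacing schedule with a hatching drop at
chamber 7–8, a stable 20–30° band and terminal crowding) whose defaults
emulate a study design of 9 species/populations × 2 specimens. All
intermediate formats are open (TPS, CSV, Newick, JSON), so real landmark data
can replace the simulator without code changes.

## A worked example

```r
library(conchmorph)

cfg <- pipeline_config(output = list(dir = "run1"))  # default study design
run_pipeline(cfg)
#> [simulate] 18 specimens from 9 specs
#> [landmark] suture: 468 configurations of 20 landmarks
#> [landmark] conch_geometry: 300 configurations of 40 landmarks
#> [analyze] suture: reference N_repertus_Australia_1|c15, 60 PCs, PC1 83.1%
#> [analyze] conch_geometry: reference N_pompilius_Philippines_2|s08, 80 PCs, PC1 86.4%
#> [trees] suture: 3 tree file(s)
#> [trees] conch_geometry: 3 tree file(s)
#> [trees] septal_spacing: 3 tree file(s)
#> [stats] ANOVA p by stage: pre_hatching=0.998, juvenile_submature=3.89e-82, mature=0.644
#> [done] 22 files in run1 (165.6 s)
```

The log already tells the scientific story: ontogeny dominates the pooled
shape variation (PC1 ≈ 83–86% of variance, so configurations cluster by
growth stage before they cluster by species), and septal spacing separates
the nine species/populations only in middle ontogeny (p ≈ 10⁻⁸²), not before
hatching (p ≈ 1) or at maturity (p ≈ 0.64). `run1/` then contains the TPS landmark
files, PC-score tables, one Newick phenogram per character and stage
(9 stage trees + 3 pooled trees), and the ANOVA/Tukey tables. For example:

```r
tr <- read_newick("run1/tree_conch_geometry_middle.nwk")
st <- read.csv("run1/scores_conch_geometry.csv")
sum(sapply(unique(st$group), function(g)
  is_exclusive_clade(tr, intersect(tr$tip.label, st$label[st$group == g]))))
#> [1] 8
```

— at the 50 mm stage 8 of the 9 species/populations form exclusive clades in
the conch-geometry tree; repeating this on
`tree_conch_geometry_pre_hatching.nwk` gives 0: before hatching the species
are morphologically indistinguishable.

The same machinery is exposed piecewise (`resample_equidistant()`,
`bending_energy_matrix()`, `slide_semilandmarks()`, `gpa()`, `shape_pca()`,
`neighbor_joining()`, `anova_oneway()`, ...), and a command-line wrapper
lives at `inst/cli/conchmorph.R`:

```sh
Rscript inst/cli/conchmorph.R all --config my_config.yaml --seed 42 --outdir run42
Rscript inst/cli/conchmorph.R trees --stage middle --character conch_geometry --outdir run42
```

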