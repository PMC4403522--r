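---
title: "Methods: morphometry of genotyped neurons in mosaic brains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry of genotyped neurons in mosaic brains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicmorph)
```

`mosaicmorph` quantifies basal dendritic structure and cell size of
individually genotyped neurons in X-inactivation mosaic brains, and
provides the statistical layer used to compare the wild-type-expressing
(MeCP2+), mutant-expressing (MeCP2-) and fully wild-type (MeCP2 WT)
genotypes.  This vignette is the package's account of the methods: the
conventions each computation follows, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where more than one convention was
defensible.

## Reconstructions and their validation

Input reconstructions are standard SWC: seven whitespace-separated
columns (`id type x y z radius parent`), `#` comments, one root with
parent −1, coordinates in micrometres in a right-handed frame (no axis
flips are applied).  `read_swc()` enforces unique positive ids, a single
root, and the parents-before-children ordering; that single ordering
rule also excludes cycles and disconnection, so a file that parses is a
tree.  Soma dialects differ between tracing tools, so the soma origin is
defined uniformly as the unweighted centroid of all type-1 node
coordinates — a single-node soma, a multi-node contour and a three-point
cylinder all reduce to sensible origins, and a single soma node
reproduces its coordinates exactly.

Only basal (type 3) subtrees enter morphometry.  Apical (type 4)
subtrees are parsed and retained, because the ≥ 75 µm apical-visibility
quality criterion refers to them, but they are excluded from every
basal statistic.  The five-point quality filter
(`filter_reconstruction()`) evaluates its criteria in a fixed order and
reports the first failure: genotype undetermined; fewer than three
intact primary dendrites; more than half the primaries chopped by
slicing; tips not visible; less than 75 µm of apical dendrite visible.
The apical criterion is taken from the metadata flag rather than
recomputed from the reconstruction: it describes visibility in the
slice, and the traced apical stub may be deliberately truncated.
Likewise the intact/chopped primary counts are metadata, since a
chopped dendrite may be digitised as a stub or omitted entirely — the
geometry cannot distinguish these.

## Morphometry conventions

**Branches and orders.**  A branch runs from the soma (or a branch
point) to the next branch point or tip.  Orders are centrifugal:
primary dendrites carry order 1 and the order increments by exactly one
at every node with two or more daughters — multifurcations also
increment by one.  The short segment joining the soma attachment node
to the first basal sample is counted as part of the primary branch, so
the same cable total is seen by branch paths, per-order sums and Sholl
shells (conservation is asserted at 1e-9 relative tolerance in the
tests, and holds to machine precision).

**Partition asymmetry.**  At each bifurcation,
`|T1 − T2| / (T1 + T2 − 2)` over the daughter subtree tip counts: 0 is
a symmetric split, 1 a maximally asymmetric one.  The (1, 1) case is
0/0 in the formula; both daughters being single tips is maximally
symmetric, so it is defined as 0.  Multifurcations have no two-way tip
split; they are recorded (`n_daughters` > 2) but excluded from
asymmetry means.

**Contraction.**  Euclidean end-to-end distance over along-path length
per branch, 1 for perfectly straight dendrites.  Zero-length branches
are a digitisation error and raise rather than return NaN.

**Sholl analysis.**  Shells are concentric spheres of width `w`
(default 10 µm) about the soma centroid, half-open `[k·w, (k+1)·w)` —
a branch point exactly on a boundary belongs to the outer shell.  Each
compartment is split analytically where it crosses shell spheres:
the segment's radial extremes locate the crossed boundaries, the
quadratic in the path parameter is solved for each crossing, and
sub-segment lengths are assigned by midpoint radius.  A compartment
whose interior passes closer to the soma than either endpoint is first
split at its radial minimum so each piece is monotone in radius.  This
conserves cable exactly and makes nested shell widths re-sum exactly
(5 µm shells pairwise-summed equal 10 µm shells), unlike midpoint
binning.  Per shell the profile reports cable length, branch-point
count, and the maximum branch order among compartments *intersecting*
the shell (not only branch points inside it, which would leave shells
between branch points empty).  Shell 0 is always emitted; reporting may
drop it.  The first occupied shells necessarily form a contiguous run,
because radial distance varies continuously along any root-to-tip path.

**Maximum radial distance** is the greatest Euclidean distance from the
soma centroid over basal compartments — a reach measure, deliberately
distinct from path length (a tightly curled dendrite has large cable
but small reach).

All of these are invariant under rigid rotation and translation of the
reconstruction, which the test suite asserts directly.

## Cell size and XCI

Soma and nucleus outlines are closed polygons in µm (an explicit
`pixel_size_um` calibration factor converts pixel-space traces; it
defaults to 1 and is deliberately a visible configuration field rather
than an assumed constant).  Areas use the shoelace formula;
self-intersecting outlines are rejected as tracing errors, and a
nucleus at least as large as its soma is logged but kept, since the
flag may reflect a focal-plane artefact rather than a bad trace.
Inclusion requires a sharply focused nucleus, an unoccluded soma and an
identifiable genotype.

The XCI fraction of an animal is the proportion of its genotyped
heterozygote cells that are MeCP2-; cells labelled WT come from
wild-type animals and are excluded by definition.  Size normalisation
divides the MeCP2- mean area by the MeCP2+ mean area.  The default
pools an animal's slices (`by = "animal"`), because downstream
regressions against XCI ratio use one point per animal; per-slice
normalisation (`by = "slice"`, slice ratios then averaged) is available
where slice-level fixation differences are a concern.  The phenotype
severity score sums six observational items (tremor 0–2, hind-limb
clasping 0–3, fur 0–2, activity 0–3, breathing 0–2, posture 0–2; total
0–14), each range-checked.

## Statistics

The experimental unit for arbor comparisons is the animal: cells are
averaged within animal at each Sholl shell or branch order
(`aggregate_per_animal()`).  A cell whose arbor does not reach a level
contributes the true value 0 there — absent cable is zero cable, not
missing data — so profile matrices are complete by construction;
an explicit `max_level` truncation is available for order profiles
where the deepest orders are sparsely populated (the pipeline default
truncates at order 6).

`rm_anova()` fits the mixed design with `stats::aov` error strata
(`Error(unit/level)`): genotype is tested against between-animal
variation, level and genotype × level against the within-animal
residual.  Degrees of freedom follow from this declared design — e.g.
3 genotypes × 5 animals × 23 shells gives an interaction F(44, 264) —
rather than being forced to match any published table.  Post-tests are
pooled-variance t contrasts between genotypes at each level, Bonferroni
adjusted over the full family (levels × genotype pairs, the
conservative reading of a per-level post-test) and capped at 1.  No
sphericity correction is applied by default, matching common practice
for these designs; a Greenhouse–Geisser option exists
(`gg_correct = TRUE`).  The genotype test's type-I error under the null
is simulated in the acceptance suite (1000 runs, 5 animals per
genotype, 15 levels) and stays near the nominal 0.05.

Rank tests wrap `stats::wilcox.test`: Mann–Whitney uses the exact null
distribution up to a combined n of 20 without ties and the
tie-corrected normal approximation with continuity correction beyond;
the signed-rank test drops zero differences, is exact to n = 15 without
tied magnitudes, and approximates beyond.  The crossover thresholds are
desk-scale exactness choices; both branches agree within 0.02 at the
crossover, and the exact branches are verified against brute-force
enumeration (all group assignments, all sign patterns) for every n ≤ 8.

Regression is ordinary least squares with the two-sided slope test;
slope equality between two fits is the textbook ANCOVA interaction F
with df (1, n_a + n_b − 4).  Size frequency distributions are binned at
a fixed width (default 10 µm²), expressed as percentage of cells so
groups of different size are comparable, and fitted by
`minpack.lm::nlsLM` with a Gaussian curve by default — a log-normal
shape (Gaussian in log-area) is available and is the better description
of right-skewed area distributions; the choice is a configuration
field, not a hidden constant.  Two distributions are compared by the
extra-sum-of-squares F test (shared versus separate curve parameters).
Non-convergence is reported with diagnostics instead of raising.

## The synthetic-data generator

The generator exists so that every stage — file parsing, morphometry,
aggregation, statistics, reporting — can be exercised and validated
end to end without tissue data.  It emulates the study design, not the
biophysics of dendritic growth.

**Arbors.**  Each cell draws its primary count around
`n_primary_mean = 5` (±1 jitter, exact mean preserved).  An order-k
branch bifurcates with probability `branch_prob_by_order[k]`; branch
path lengths are gamma (shape 3, scale 16.7 µm; mean ≈ 50 µm); paths
are persistent 3D random walks with 5 µm steps
(`tortuosity_kappa = 3.6` within branches, `daughter_kappa = 0.2`
across branch points).  The order-indexed branching process was chosen
over geometric growth models because the genotype difference being
emulated is localised at specific branch orders, which an order-indexed
bifurcation probability reproduces directly.  A straight 100 µm apical
stub satisfies the apical quality criterion and exercises the
type-4 exclusion path.

The calibration surface is the set of reference population means in
`reference_means()`.  The MeCP2+/WT arbor preset hits ≈ 1874 µm of
cumulative basal length and ≈ 16.2 branch points in expectation
(closed form in `preset_expectations()`); the MeCP2- preset lowers the
bifurcation probabilities at orders 2–3 only (0.531 → 0.453,
0.314 → 0.270), giving ≈ 13.8 branch points and ≈ 1631 µm with
unchanged primaries, branch-length distribution and tortuosity.  The
tortuosity parameters were set so mean contraction is ≈ 0.89 — within
the biological range and equal across genotypes — which puts the mean
radial reach near 164 µm.  Two calibration compromises are accepted
and worth knowing about: with equal mean branch lengths the simulated
MeCP2- cumulative length is ≈ 1631 µm rather than the reference
1600.6 µm (the reference means are themselves slightly inconsistent
with equal branch lengths), and the sparser MeCP2- trees end ≈ 8%
shallower in radial reach where tissue shows ≈ 4% (not significant);
no calibration target depends on absolute reach.

**Mosaic sizes.**  Heterozygous animals draw an XCI fraction uniformly
on [0.12, 0.56], an age on [5, 21] months, severity items, and a
log-normal between-animal size factor (`animal_effect_sd = 0.12` —
between-animal variability is deliberately visible, since it dominates
real size comparisons).  Cell genotypes are Bernoulli draws at the
animal's XCI fraction.  Soma areas are log-normal with within-animal
CV 0.15; the nucleus is conditionally linear in its soma
(slope = nucleus mean / soma mean ≈ 0.64, residual CV 0.08), so soma
area is a predictor of nucleus area with a well-defined generating
slope.  The MeCP2-/MeCP2+ size ratio varies with the animal's XCI
fraction: ratio(x) = 143.3/169.2 + 0.25·(x − 0.34).  The slope 0.25 and
reference point reproduce the published bracket — the deficit is
largest (≈ 20%) in brains highly skewed toward wild-type expression and
smallest (≈ 11%) at balanced XCI — and the within-animal CV is the
value at which a 24-animal regression of normalised ratio on XCI
recovers that slope with the published strength (R² ≈ 0.3–0.45).
Population CV comes out near 0.19 once animal effects and the genotype
mixture are included.  Outlines are noisy rotated ellipses rescaled to
the drawn area exactly, so the polygon-area path is exercised without
changing the size model.  WT-animal sizes use larger means
(soma 184.6 µm², nucleus 117.9 µm²), emulating the observed
wild-type > MeCP2+ shift.

**Reproducibility.**  Every cell has a private RNG stream seeded by an
integer hash of (master seed, animal index, cell index), kept below
2³¹; adding or removing cells therefore does not cascade into other
cells' draws, and (presets, spec, seed) maps to byte-identical SWC
output (coordinates are written at fixed 4-decimal precision).

**What passing tests do and do not show.**  The generator reproduces
the *design* of the study — group means, order-localised deficits,
mosaic composition, animal-level variance structure — but not
correlated dendritic waviness, tissue shrinkage, slicing truncation,
reconstruction errors, spines, or apical arbors.  A pipeline validated
against it is validated as an estimator of the statistics it computes,
under the variance structure described above; conclusions about real
tissue still depend on the real data's artefacts being handled by the
quality filters.

## Validation studies and problem sizes

`recovery_study()` is the package's end-to-end check: each replicate
simulates 5 animals × 20 cells per genotype with the calibrated
presets, summarises every cell, and tests the MeCP2- vs MeCP2+
contrast on four whole-cell parameters.  Across 100 replicates the two
built-in deficits (cumulative length, branch points) carry the correct
sign in ≥ 95% of replicates, while the two built-in nulls (mean branch
length, primary count) remain non-significant at α = 0.05 in ≥ 90%.
Sign recovery is the headline criterion because, at this design's
sample sizes and the calibrated cell-level variance (SD ≈ 600 µm for
total length — consistent with the animal-level standard errors the
means imply), the animal-level contrast runs at t ≈ 3, i.e. ≈ 80%
power; a significance-based detection rate of 95% is not attainable by
any correct test at these sizes, and the significant-deficit rate is
reported alongside for transparency.  Contrasts default to animal-level
units (the conservative choice for real analyses); cell-level units
are available where an analysis's error terms are cell-based.

Simulation sizes used throughout the tests and the acceptance script —
100–300 trees for population-mean checks, 1000 null runs for the
ANOVA error rate, 100 replicate cohorts for recovery — were chosen so
Monte-Carlo error is small against each tolerance while the whole
suite runs in minutes on one CPU.

## Known limitations

* The generator's branch-level randomness is independent across
  branches; real dendrites show correlated geometry (sibling-angle
  structure, taper, boundary effects from the pial surface) that is not
  modelled.
* The MeCP2- preset's radial reach is ≈ 8% below MeCP2+ (see above);
  analyses of absolute reach should not be calibrated against the
  generator.
* The RM-ANOVA assumes a complete balanced profile matrix; unbalanced
  designs (unequal animals per genotype) are fitted by `aov` but the
  hand-checked sums-of-squares identities in the tests cover the
  balanced case only.
* Exact rank tests switch to approximations in the presence of ties at
  any sample size; with heavily discretised measurements the exact
  branch is effectively unavailable.
* The quality filter trusts its metadata flags; it does not attempt to
  detect chopped dendrites or invisible tips from geometry.
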