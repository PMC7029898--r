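---
title: "Scoring hair cuticle damage from SEM image brightness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring hair cuticle damage from SEM image brightness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairsem)
```

## The measurement problem

Scanning electron micrographs of hair segments show cuticle damage — lifted
or torn scales, holes, adhering debris — as features that are *brighter* than
the dark-grey undamaged surface, because elevations and depressions change
the secondary-electron yield reaching the detector. `hairsem` turns that
observation into a per-image damage score without any predefined feature
catalogue: it measures the asymmetry of the pixel-brightness histogram inside
a standardized, normalized region of interest. This vignette documents the
model, every tunable parameter, the numerical choices, what the synthetic
generator does and does not emulate, and the known limitations.

## Region of interest

Raw micrographs cannot be compared directly: hair segments lie at arbitrary
angles, and the segment edges carry abnormally bright bands (up to roughly a
fifth of the apparent width on either side). Two user-drawn lines, supplied as
a sidecar file, fix the geometry:

* the **axis** line along the hair; the frame is rotated by minus its angle so
  the hair runs horizontally;
* the **diagonal** line spanning the segment's bounding corners, drawn on the
  rotated image.

From the diagonal's coordinate extremes the ROI is the centred rectangle with
origin $((7x_{min}+x_{max})/8,\,(7y_{min}+y_{max})/8)$, length
$l = \tfrac34(x_{max}-x_{min})$ and width $w = \tfrac34(y_{max}-y_{min})$:
three quarters of the segment extent in each direction, hence $9/16$ (56 %)
of the bounding-box area, which keeps the bright edge bands out of every
downstream statistic. Fractional bounds are floored — the construction is then
deterministic, and the area ratio stays within floor truncation of $9/16$
(never above it). Coordinates are 0-based pixel indices; the sidecar format
does not state a convention in its ancestry, and a one-pixel shift is
immaterial at ROI scale.

Rotation resamples bilinearly with clamping to $[0,255]$ and fill value 0
outside the original footprint. Two exact shortcuts keep geometry tests
bit-exact: angle 0 returns the input unchanged, and quarter-turn angles are
pure index permutations. `map_to_rotated()` exposes the identical coordinate
transform for points, which is how the synthetic generator emits its diagonal
annotation in the rotated frame.

## Row-wise normalization

Automatic brightness/contrast adjustment during acquisition makes absolute
brightness incomparable between images, and the tube shape of a hair adds a
brightness gradient across its width. Both are removed in two row-wise steps,
where a *row* is the line of $l$ pixels along the hair length at one
across-width position $j$:

1. **Centring.** Every pixel in row $j$ is multiplied by
   $109 / \bar I_j$, so each row's mean becomes exactly 109 — the empirical
   dark grey of undamaged cuticle, 43 % of the 8-bit maximum. Undamaged
   surface dominates every row, so this pins the background while preserving
   within-row brightness ratios.
2. **Upper-half min–max rescale.** In each row, values above 109 are mapped
   linearly so the row maximum reaches 255:
   $I' = 146\,(I-109)/(I_{max,j}-109) + 109$, with $146 = 255-109$. Values at
   or below 109 are untouched, so the dark background is never stretched.

Parameters: `center = 109` and the implied `span = 146` are constructor
defaults and can be overridden; `tol = 1` brightness unit guards the rescale —
a row whose maximum is within `tol` of 109 is left alone, since dividing by a
near-zero range would only amplify noise (the source formulation does not
address this degenerate case). Real-valued pixels are carried through all
stages; quantization back to 8-bit (round-half-up, clamped) happens only on
image export and before histogram binning, avoiding double rounding. Whether
the original workflow rounded between the two stages is unknown, so
`normalize(intermediate_rounding = TRUE)` exposes the other order; the default
is no intermediate rounding.

A consequence worth knowing: the rescale *always* stretches each row's
brightest content to 255. On images whose rows contain genuinely bright
structure (cuticle scale edges), the stretch factor is moderate and
comparable between images. On a hypothetical perfectly flat surface plus
sensor noise the same step would stretch noise across the full upper range —
normalized comparisons are only meaningful for images with real surface
structure, which every actual micrograph (and every synthetic fixture) has.

## Damage metrics

**Mean brightness** $\bar I = \frac{1}{lw}\sum_{j}\sum_{i} I_{i,j}$ is
reported but is not a damage score: normalization pins it near 109 by
construction, and on unnormalized data it tracks magnification (acquisition
auto-gain), which is why scoring is restricted to a magnification window
(default 1000–4000×, CLI-overridable) within which brightness and
magnification are uncorrelated.

**Average image roughness** treats each row's brightness profile as a
polyline. With section width $s = \lfloor l/n \rfloor$ (default $n = 100$
sections) and samples at single pixels $1, s+1, 2s+1, \dots$ and the row end
$l$, the row roughness is the arc length $\sum \sqrt{\Delta I^2 +
\mathrm{run}^2}$ divided by $l$, averaged over rows. A flat profile scores
exactly 1. Two readings of the section count exist when $s \nmid l$: the
default realizes $\lceil l/s \rceil$ sections with a final partial run (the
only reading whose final-term run $l - s(n_{actual}-1)$ is consistent), and
`roughness(rule = "exact-n")` keeps exactly $n$ sections; both are tested.
Sampling uses single-pixel values, not section means.

**Tailing factor** scores histogram asymmetry the way chromatography scores
peak shape. Pixels are binned into the 256 integer brightness bins; the apex
is the lowest-brightness mode (undamaged dark-grey mass dominates, and ties —
which are logged — are resolved toward it). Because secondary peaks skew a
naive apex, the apex is first *redefined*: the count-weighted mean brightness
$\bar I_H$ over the integer bins inside the full width at half maximum
replaces the mode $I_H$ whenever $|\bar I_H - I_H| > 3$ brightness units.
Crossings at a level (half height, and the fraction $f$ of peak height) are
found by scanning outward from the apex and linearly interpolating between
the bracketing bins — the outward scan guarantees the crossings bracket the
main peak even when secondary bumps exist, and interpolation removes the
one-unit quantization jumps a bin-resolution crossing would produce. Then

$$t_f = \frac{I_{lag,fH} - I_{lead,fH}}{2\,(I_h - I_{lead,fH})}.$$

A histogram symmetric about its apex scores exactly 1; bright-tailed
histograms score above 1. The default $f = 0.02$ (2 % of peak height) is the
value at which the score correlates best with ordinal SEM damage grades;
chromatographic practice uses 5 %, and any $0 < f < 0.5$ can be passed. If the
count profile never falls below the level inside $[0,255]$ the crossing is
clamped to the boundary with a warning; an apex that does not exceed the
leading crossing raises an explicit "degenerate peak" error rather than
returning NaN. No histogram smoothing is applied (none is described in the
method's ancestry).

## Grading and statistics

Tailing factors map to the ordinal Scu 1–4 cuticle damage scale (Scu 1 least
damaged, Scu 4 cuticle absent) with a k-nearest-neighbour vote: $k = 3$,
Euclidean distance on the single tailing-factor feature (so distance is
$|\Delta t_f|$), probability = winning votes / $k$. A 1-1-1 vote tie is
possible with three classes in a neighbourhood; it is broken by the nearest
neighbour's class and logged — a deterministic rule in place of a library's
random tie-breaking. The train/test split is 50/50, stratified so both halves
hold equal numbers of exploded and control images, deterministic in its seed;
an odd condition count sends the extra record to training with a warning.
`pearson_screen()` implements the metric-selection screen (product-moment $r$,
$t = r\sqrt{df/(1-r^2)}$, $df = n-2$, two-sided $p$); it is cross-checked
against `stats::cor.test` in the tests. Per-hair summaries (mean, n−1 sd,
min, max of tailing factors across a hair's images) describe severity and
uniformity of damage along a hair. The classifier ignores grade order, as a
majority vote does.

The packaged `table1_test_set()` transcribes the published 16-row test set;
blank probability cells are unanimous votes (1), consistent with the 0.667
entries being 2-of-3 votes. Its true-vs-predicted agreement, 13/16 = 81 %, is
a regression anchor for the grading module.

## The synthetic generator

`generate_fixture()` renders what the pipeline actually consumes — brightness
statistics — with simple parametric shapes:

* a tube at a chosen angle, in-tube base brightness 109, linear across-width
  gradient (amplitude 25 by default) emulating the tube-shading the row
  normalization exists to remove;
* bright edge bands (+80) beyond 82 % of the half-width, which the emitted
  diagonal annotation provably excludes from the ROI;
* bright curved cuticle scale edges (+50–90, ~1.5 per 100 px of length):
  real scale edges are genuinely bright, and their presence keeps the per-row
  rescale factor moderate and comparable between clean and damaged fixtures;
* a smooth surface-texture field (sd 12, correlation length 8 px) plus pixel
  noise (sd 4): real cuticle texture gives the histogram a broad peak, which
  is what makes a 2 %-of-peak-height crossing sensitive to damage mass;
* damage features: flat-top bright patches with a 3 px soft skirt (lifted
  cuticle), bright annuli with darker interiors (holes), near-white specks
  (debris). Contiguous, roughly uniform bright patches are what real damage
  looks like to a histogram; smooth blobs would smear their mass thinly
  across brightness and be invisible at the crossing level.

Fixtures are bit-exact functions of their seed. Ground truth comes from the
damage-area fraction (bright damage mass over the tube interior), graded
through documented config thresholds (`damage_grade_thresholds()`: 0.4 %,
1.5 %, 5 %) — these exist to make classifier tests meaningful, not to
reproduce any visual grading criteria. `generate_cohort()` renders balanced
per-grade regimes (feature counts per grade, area-scaled from a 240×320
reference canvas) and labels records with the regime grade; default cohorts
use 8 images per grade at 240×320 — small enough that a 200-replicate
end-to-end study runs in minutes on one CPU, while metric behaviour is
resolution-stable.

What the generator does *not* emulate: electron-optical shading, charging
artefacts, focus variation, curved fibres, magnification-dependent gain, or
textured damage interiors. Passing end-to-end tests therefore demonstrate
that the pipeline orders and separates *brightness-statistical* damage
signatures correctly; they do not validate performance on every real-world
imaging artefact.

## Numerical choices and degenerate inputs

* Quantization is round-half-up (`floor(x + 0.5)`), not banker's rounding —
  half-up is what image software does, and round-half-even would bias
  histogram bins.
* ROI bounds floor; clipping to the frame warns rather than errors.
* An all-zero pixel row is a hard normalization error naming the row (it
  cannot occur in plausible SEM data, and must not crash silently).
* Multi-mode histograms take the lowest-brightness mode, with a message.
* Rotation fill is 0; constant fields stay constant inside the footprint up
  to machine rounding of the bilinear weights.
* All randomness (fixtures, cohorts, splits) flows from explicit integer
  seeds; internal RNG use saves and restores the caller's RNG state.

## Problem sizes used by the test-suite studies

Property suites use ~300–1000 random small inputs per oracle comparison
(tolerance 1e-9); the end-to-end classifier study uses 200 replicates of a
16-image, 240×320 two-grade cohort; the frozen-seed damage-series fixtures
are 480×640 with cluster counts 0/4/10/20, chosen to realize about
0/2/5/10 % damage-area fractions. These sizes are the package's own choice of
desk-scale study conditions.

## Known limitations

* The tailing factor saturates once the bright tail reaches full scale:
  beyond roughly 10–15 % damage-area fraction, more damage may not raise the
  score further (crossings clamp at 255), and near-threshold regimes (~2 %
  vs ~5 %) are only weakly ordered under some seeds.
* Heavy tail mass above half height widens the FWHM window and legitimately
  moves the redefined apex, which can *lower* the score slightly — the apex
  redefinition trades a small non-monotonicity for robustness to secondary
  peaks.
* The score is magnification-sensitive outside the 1000–4000× window; filter
  first.
* A rectangular ROI under-serves strongly curved fibres; the geometry module
  does not follow curvature.
* Grading with a single feature inherits the overlaps of the underlying
  scale: adjacent grades (Scu 1 vs Scu 2) overlap in tailing factor on both
  real and synthetic data, which is where misclassifications concentrate.
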