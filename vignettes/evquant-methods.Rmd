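---
title: "Methods: how evquant measures vesicles, membranes, beads and motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how evquant measures vesicles, membranes, beads and motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evquant)
```

This vignette documents the models, conventions and numerical choices
behind each measurement stage, what the synthetic-data generator does
and does not emulate, and the known limitations.

## Vesicle morphometry

### Segmentation

Electron micrographs of EV preparations show vesicles as bright- (or
dark-) rimmed closed membranes on a noisy background. `segment_vesicles()`
uses a deliberately simple, fully deterministic recipe: optional
difference-of-Gaussians bandpass, Otsu or absolute thresholding, hole
filling (so a rimmed vesicle becomes one solid region), removal of
regions below a physical area floor, and 8-connected component
labelling. Labels are assigned in row-major order of each component's
first pixel, so segmentation output is reproducible down to label
numbering. Because any fixed segmentation recipe is a modelling choice,
all measurement functions also accept an externally supplied label
mask (`labels =`), so shape metrics can be validated or applied
independently of detection — e.g. on curated masks.

### Shape descriptors

For a region of `n` pixels at pixel size `s` (nm/px):

* area `A = n * s^2`; equivalent-circle diameter `d_eq = 2 * sqrt(A / pi)`;
* maximum and minimum Feret (caliper) diameters by rotating calipers
  on the convex hull of the pixel centres, **plus one pixel width**:
  the centres of the extreme pixels sit half a pixel inside each end
  of the physical extent, so the 1 px term makes a straight run of
  `n` pixels measure `n` px and a single pixel measure 1 px rather
  than 0. We use this centre-based convention rather than the convex
  hull of pixel *corner* points because corner hulls systematically
  inflate the maximum caliper of curved outlines (for a rasterized
  disc of radius 50 px, by about 1.2 px, i.e. ~2.4% on roundness),
  while the centre+1 convention reproduces closed-form disc and
  stadium geometry within ~1 px. The rotating-calipers values are
  property-tested against an independent 3600-direction projection
  oracle.
* roundness `R = 4A / (pi * Fmax^2)`. Roundness is not given a single
  universal definition in the imaging literature; this form is chosen
  because it equals 1 for a circle, decreases directly with
  elongation, and interacts cleanly with a tubulation threshold. The
  alternative axis-ratio definition `Fmin / Fmax` is available via
  `roundness_method = "axis_ratio"`, and the method used is recorded
  in report metadata.

A pixel belongs to a rendered shape iff its centre lies strictly
inside the continuous outline. Strict (rather than inclusive)
membership avoids a lattice resonance in which an integer-radius disc
at an integer centre acquires a 4-pixel cross of boundary points that
distorts both area and hull.

Quantization limits worth knowing: caliper values carry an inherent
±0.5-1 px phase dependence, so rotation changes Feret diameters by up
to ~1 px regardless of direction count — negligible for vesicles tens
of pixels across, but a 2% effect at 50 px width. Disc roundness
converges to 1 from below as the radius grows and stays within 0.02 of
1 for radii ≥ 50 px at generic sub-pixel placements; the exact
integer-centre/integer-radius resonance can exceed that by a few
thousandths.

### Classification and population rules

Two roundness thresholds (defaults 0.6 and 0.8) split fully visible
vesicles into `tubular` (R < 0.6), `non_round` (R ≤ 0.8) and
`spherical`; tubular vesicles are counted as a subset of non-round
ones. Regions touching the image border are `unclassified`: roundness
of a clipped outline is meaningless, but a diameter is still a usable
(under-)estimate, so population summaries report diameters over *all*
vesicles while morphology fractions use only the classified subset as
denominator. Diameters default to the equivalent-circle definition;
the minimum caliper is exported separately as the short-axis diameter,
which for tubulated vesicles estimates the tube width.

## Membrane area fraction

Membrane abundance per micrograph is the fraction of pixels occupied
by membrane features: `segment_membrane()` (same filtering/threshold
machinery, plus a minimum object size) followed by
`membrane_fraction()`, which is exact integer bookkeeping, optionally
within an ROI mask (for excluding grid bars or support-film edges).
Condition comparisons report the fold change of mean fractions plus an
unpaired two-tailed Mann-Whitney test; an optional mock-transfection
baseline mean can be subtracted at reporting time, and the output
records whether that was done, since background handling conventions
differ between studies.

## Bead-based fluorescence ratios

Beads are detected in the *reference* channel only (the bead-bound
normalizer), so fluorescent junk present only in the signal channel
can never be mistaken for a bead. Detections are filtered on an area
window, a roundness floor (default 0.85; resin beads are near-circular,
debris and bubbles usually are not) and border contact. Per bead, each
channel's background — by default the median over all non-bead pixels,
with a per-bead annulus mode for uneven illumination — is subtracted
per pixel before summation, and the bead's ratio is the corrected
integrated signal over the corrected integrated reference. Integrated
(rather than mean) intensities are used: the two are equivalent for
uniform discs, and sums are more robust to partial edge pixels. Ratios
are invariant to a common channel gain and to constant offsets in
either channel.

Condition-level QC flags beads whose reference integral deviates from
the condition median by more than 5 MADs (scaled by the usual 1.4826
constant) — an automated surrogate for the manual review step that
excludes air bubbles and other artifacts — and emits a review manifest
in which a human can mark `manual_reject` entries that are honored on
re-run. Summaries use only unflagged beads; when replicate ids are
present the reported mean is the mean of per-replicate means with SD
across replicates (n-1).

## Motif scanning and topology

CRAC (`[L/V]-X(1,5)-[Y/F]-X(1,5)-[K/R]`) and CARC (the mirrored
pattern) matching is defined on anchor triples, not on regular
expressions: every (p1, aromatic, p3) combination with both spacers in
1..5 is reported once, so overlapping and nested matches are all
enumerated — a greedy or lazy regex would silently drop some. The
scanner is property-tested for exact set equality against a naive
triple-loop enumerator and for CRAC/CARC mirror symmetry under
sequence reversal. Since published motif counts rarely state a
counting convention, `merge_motif_spans()` additionally collapses
overlapping hits into maximal spans, giving the smaller
"number of motif sites" count. `X` and other nonstandard residues
never satisfy anchor classes but may occupy spacer positions.

TM restriction keeps hits overlapping a transmembrane segment by at
least half the hit length (an explicit choice; "in the transmembrane
helix" is rarely operationalized in the literature), annotating each
kept hit with its TM index.

The prominin-family topology filter requires exactly five TM segments
whose four inter-TM loops are two extracellular loops each strictly
greater than 300 residues and two intracellular loops each strictly
less than 25 residues, with sidedness derived from the N-terminal side
and alternation. The thresholds are strict inequalities, so boundary
values (a 300-aa extracellular loop, a 25-aa intracellular loop) fail.
N- and C-terminal tails are not loops and are not checked. The
"2+2+1" helix-spacing pattern sometimes quoted for prominins is not
enforced: it describes helix grouping, not loop lengths, and has no
crisp operational definition; irregular spacing is a curation note,
not a rejection rule.

Alignment-column conservation uses the 10-property physicochemical
classification (hydrophobic, polar, small, proline, tiny, aliphatic,
aromatic, positive, negative, charged): a column's score is the number
of properties whose presence/absence is uniform across counted
residues, with 11 reserved for identity columns; gaps are ignored by
default, or force a 0 when counted. The property table ships as a CSV
pinned by checksum in the tests.

## Statistics and reporting

* `reconstruct_count()` inverts 1-decimal percentage reporting:
  `round(pct/100 * n)`, with a guard that errors (listing all
  consistent counts) if the reconstructed count does not re-round to
  the printed percentage.
* Fold changes between fraction records are reported exactly and at 2
  significant figures, the convention used when quoting such values.
* `student_t_test()` is the pooled-variance (Student's) two-tailed
  unpaired test — chosen over Welch because that is what figure
  legends citing "Student's t test" mean; Welch is available via
  `var_equal = FALSE`. Zero-variance degenerate inputs return p = 1
  (equal means) or p = 0 (unequal), flagged. The p value is verified
  against the regularized-incomplete-beta closed form to 1e-8.
* `mann_whitney_u()` uses midranks; the two-tailed p is exact by
  enumeration for combined n ≤ 12 without ties, otherwise a
  tie-corrected normal approximation with continuity correction. For
  fully separated tie-free samples the exact p equals
  `2 / choose(n1 + n2, n1)`.
* Bonferroni thresholds are `alpha / m` with m supplied by the user
  and recorded in the report — the number of comparisons behind a
  printed threshold family is an experimental-design fact, not
  something the package should guess.
* `build_report()` assembles all module outputs plus the parameter
  metadata (roundness definition, thresholds, background mode, m) into
  one JSON/CSV bundle; serialization contains no timestamps, so
  identical inputs give byte-identical reports.

## What the synthetic generator does and does not emulate

`render_vesicle_scene()` draws discs and spherocylinders (stadium
shapes) with a rim at full contrast and an interior at half contrast
on a constant background, plus additive Gaussian noise clipped only by
the output container's range. Ground truth carries continuous
geometry: disc area `pi r^2` and Feret `2r`; spherocylinder area
`w(L - w) + pi (w/2)^2`, Feret `L` and `w`. Rasterized masks agree
with these within 1% for features ≥ 20 px. Shapes may not overlap
unless explicitly allowed (overlap makes per-object truth ambiguous);
shapes extending past the image rectangle are clipped and flagged
truncated. `render_membrane_field()` thresholds smoothed Gaussian
noise at an order statistic, so the true foreground fraction matches
the target to within one pixel in the count. `render_bead_scene()`
adds uniform-disc beads (signal = ratio × reference) and
channel-specific artifacts on constant backgrounds.
`generate_motif_sequences()` samples background residues uniformly
(in strict mode, excluding all anchor residues L, V, Y, F, K, R so
planted motifs are provably the only matches) and derives ground truth
by exhaustive enumeration, so non-strict backgrounds list their
incidental matches too.

Deliberately not emulated: electron-optical image formation (CTF,
stain granularity, detector statistics), optical PSFs and uneven
illumination, correlated noise, vesicle shape classes beyond
disc/stadium, and realistic amino-acid composition. Passing tests on
these scenes therefore demonstrates correctness of the measurement
arithmetic and the detection logic under controlled degradation — not
segmentation robustness on real micrographs, which should be assessed
with curated masks via the `labels =` path.

## Problem sizes and determinism

The test-suite simulations use scenes sized to exercise the claims
they check: 512² membrane fields, 50-bead scenes at 470×270 px,
vesicles of 20-100 px radius, 500-sequence motif corpora, and 200
random polyomino regions for the caliper oracle. All generators take
explicit integer seeds and are bit-reproducible for a given seed;
`scripts/acceptance.R` derives every stream from its single `--seed`
argument.

## Known limitations

* Otsu thresholding assumes a reasonably bimodal intensity histogram;
  a rare bright outlier region can drag the threshold up. Absolute
  thresholds are accepted everywhere for such cases.
* Caliper quantization (±0.5-1 px) makes roundness unreliable below
  ~20 px width; the tubulation threshold should only be applied to
  vesicles comfortably above that.
* The bead detector assumes approximately uniform beads; strongly
  textured beads would need the annulus background mode and a lower
  roundness floor.
* Conservation scoring treats residues outside the 20-letter alphabet
  as property-less rather than excluding them.
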