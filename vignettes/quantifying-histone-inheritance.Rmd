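---
title: "Quantifying asymmetric histone inheritance from dual-colour imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying asymmetric histone inheritance from dual-colour imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymhist)
```

## Scope and model

`asymhist` quantifies how a dividing *Drosophila* intestinal stem cell
(ISC) partitions old (preexisting, eGFP-tagged) versus new (newly
synthesized, mCherry/mKO-tagged) histone between its daughters.  All
measurements reduce to one primitive — the background-corrected
integrated density of a channel over a region of interest (ROI) summed
across the z-slices containing the cell — and a small set of derived
statistics: correlation coefficients for spatial co-occupancy in early
mitosis, a max/min chromatid ratio in late mitosis, Delta-ordered log2
ratios in postmitotic pairs, and count/cluster/profile statistics at
tissue level.

The package deliberately does *not* segment real images: ROIs are
inputs (hand-outlined in practice), and the only segmentation helper
(`threshold_label()`) exists for synthetic fields.  This mirrors how the
measurements are actually made and keeps the measurement contract
explicit.

## Spatial conventions

* Arrays are indexed `(channel, z, y, x)`; pixel coordinates are
  0-based with y increasing downward; z-ranges are inclusive.
* A pixel belongs to a polygon or ellipse ROI iff its *centre* is
  inside the geometry.  This makes ROI pixel counts invariant under
  integer-pixel translation, which the equal-area background rule
  depends on.
* Calibration (`pixel_size_um`, `z_step_um`) is mandatory and there is
  no default: the 5 um pair-distance rule, the 10 um adjacency radius
  and the 150 um census regions are physical lengths, and a silently
  assumed 1 um/px would corrupt all of them.  A TIFF without embedded
  metadata must come with a JSON sidecar or the read fails.

## Measurement stages and their parameters

### Colocalization

`pearson_coloc()`/`spearman_coloc()` correlate two channels over all
ROI voxels pooled across the ROI z-range, with no intensity threshold
(no Costes-style auto-threshold: plain coefficients are reported).
Pooling across z, rather than correlating per slice and averaging, is
the default because the downstream interpretation is per *cell*; a
`per-slice` mode is provided for comparison.  Zero-variance channels
return `NA` with a warning rather than 0, because a silent 0 would bias
means toward "no colocalization".  Spearman uses mid-ranks (average
ranks on ties).

### Integrated density and background

`background_corrected_total()` subtracts the total of an equal-area
background ROI — the same outline moved to a signal-free area, spanning
a z-range of the same depth — from the raw ROI total.  Whether the
subtraction is done per slice or per stack is numerically identical
under this equal-area/equal-depth contract, so the per-stack form is
used.  Negative corrected totals are *kept and flagged*, not clamped:
clamping would bias ratio denominators upward.  Sums accumulate in
double precision, exact for integer data up to 2^53.

### Segregation ratios and asymmetry categories

`chromatid_ratio()` is `max(A,B)/min(A,B)` of the old-histone totals of
the two sister-chromatid sets; ratios use the old-histone channel only,
because new histone is still being deposited during mitosis.
`derive_thresholds()` fits the category boundaries from a control
histone (H2A) that is expected to segregate symmetrically:
`t_med = mean + 1 sd`, `t_high = mean + 2 sd`, with the sample (n-1)
standard deviation.  Only the published mean and sd (1.08, 0.07) are
needed to reproduce the canonical 1.15/1.22 boundaries at two decimals;
whether those were derived from rounded or full-precision statistics is
indistinguishable at that resolution, and classification always uses
unrounded thresholds.  Boundary semantics are taken literally from the
printed intervals: symmetric `<= t_med`, medium `(t_med, t_high]`,
high `> t_high`.

### Postmitotic pairs

`pair_filter()` enforces the four eligibility rules (distance <= 5 um,
diameter ratio <= 1.5 — excluding polyploid enterocytes —, both cells
EdU-negative, quantifiable old and new totals) and records the first
failed rule per rejected pair.  "Quantifiable" is not defined in the
source conventions; it is operationalised as corrected totals above a
configurable floor (default 0, i.e. strictly positive).  The
Delta-high cell is always cell 1; a Delta ratio exactly 2 is assigned
to the conservative `symmetric` class (the published rule names only
"> 2" asymmetric and "< 2" symmetric), and Delta ties are ordered by
cell id for determinism.  Fold changes are geometric, `2^|mean log2|` —
forced by the published correspondence of a 0.65 mean log2 ratio with a
~1.57-fold difference; an arithmetic mean of folds would not reproduce
it.  Class proportions are summarised per specimen and then averaged
(mean ± SEM of per-specimen percentages), with pooled counts reported
alongside for chi-square use.

### Tissue statistics

`cluster_cells()` forms single-linkage connected components of
marker-positive cell centroids at an adjacency radius whose default,
10 um, is roughly one ISC nucleus diameter.  The radius is an explicit,
recorded parameter because "adjacent" is not defined by the source
conventions (touching membranes, distance, or visual judgment would all
be defensible); making it a parameter makes the choice reportable.
`cluster_size_distribution()` uses clusters as the denominator,
`single_cell_fraction()` uses cells — the two summaries answer
different questions and are linked by the identity
`sum(size * count(size)) = total cells`.  Census counts
(`count_positive()`) operate on marker flags over 150 um regions from
`region_grid()`, which drops partial edge tiles so every region has the
identical pixel count.  `profile_trace()` max-projects the stack, walks
the midline in unit-pixel steps and averages a perpendicular 500 px
band, excluding out-of-field samples from the mean (zero-padding would
bias edge values downward); `block_average()` condenses every 1,000
positions into one value and discards the trailing partial block.

### Statistics

The decision tree is: Shapiro-Wilk at alpha = 0.05 (the gate level is a
package choice; the source states the gate but not its alpha) routes a
sample to a two-sided one-sample t-test (normal) or Wilcoxon
signed-rank (skewed) against a hypothesised location of 0 on the log2
scale; two independent samples use the unpaired Student t-test by
default (only "unpaired t-test" is specified), with a Welch flag;
categorical comparisons use the Pearson chi-square without continuity
correction, in independence mode (margins, `df = (R-1)(C-1)`) or
goodness-of-fit mode (`df = C-1`).  Both chi-square modes exist because
published X² values of the form "X²(1, n = 2,745)" cannot be
unambiguously reconstructed from pooled 2x2 summaries; no
multiple-testing correction is applied anywhere, matching the source
analyses.  Star mapping is strict at each cutoff (p = 0.05 is `ns`).

## The synthetic generator: what it emulates, and what not

Each generator plants ground truth *before* noise and records it in a
manifest, so downstream stages can be tested against known answers:

* `make_mitotic_early(overlap_mix)`: one nucleus, two channels; at
  `overlap_mix = 1` the channels share identical spatial weights
  (Pearson exactly 1 in the noiseless limit), at 0 they occupy disjoint
  half-nucleus domains (negative Pearson); expected Pearson is
  monotone in the mix.
* `make_mitotic_late(partition_fraction_f)`: two chromatid masses with
  the old channel split `f : 1-f` *exactly* (conservation before noise
  is an invariant); `f = 0.574` plants the canonical ratio 1.35.
* `make_pair()`: four channels (old, new, Dl-nLacZ, EdU), planted
  Delta levels, histone totals, separations, diameters and EdU flags.
* `make_midgut_field()`: a single-z field with Delta-positive cells in
  clusters drawn from a requested size distribution, optional
  enteroendocrine/mitotic/polyploid cells, and an eYFP amplitude
  profile along x.  Cluster sites sit on a jittered grid whose spacing
  guarantees that distinct planted clusters can never merge under the
  default 10 um adjacency radius, so the planted partition *is* the
  correct answer.  `render = FALSE` skips image synthesis for
  table-level simulations at large n.

Nuclei are Gaussian-profile ellipsoids with a hard edge at the stated
radius.  The hard edge is a deliberate simplification: it lets an ROI
at exactly the nucleus radius capture the cell's entire planted signal
with zero spill into a neighbour 4 um away, which keeps the
Monte-Carlo recovery tests sharp.  Real point-spread functions spill;
consequently a green recovery test establishes that the *measurement
conventions* are implemented correctly, not that the pipeline is robust
to real optics, stage drift, chromatic shift or segmentation error.

The noise model is `Poisson(gain * signal)/gain + N(0, read_sd) +
baseline`, clipped to `[0, 65535]` and quantised to integers (noiseless
mode stays continuous).  Defaults `gain = 1`, `read_sd = 2`,
`baseline = 100` give planted totals of ~2x10^4-2x10^5 photons per
cell a relative measurement error well under 1% — a bright, clean
confocal regime.  No acquisition SNR is stated for the real data, so
these defaults are the package's own stated world: the recovery
tolerances in the test suite (mean ratio within ±0.05 of 1.35 over 50
seeds; >= 95% class recovery) are calibrated to these defaults and are
properties of the simulator contract, not claims about the microscope.

## Numerical and design choices

* 16-bit TIFF I/O is implemented in base R (no TIFF package exists in
  the supported dependency set); files are plain baseline TIFF,
  verified interoperable with `tifffile`, with a JSON ImageDescription
  carrying axes, shape, channel names and calibration.  Reads accept
  both endiannesses and both `CZYX` and `ZCYX` (channel-fastest) page
  orders; writes are byte-deterministic.
* Configuration files are JSON rather than YAML: no YAML parser is
  available in the supported dependency set, and `jsonlite` round-trips
  the config exactly.
* Ellipse containment uses `<=` on the normalised radius; polygon
  containment uses even-odd ray casting, which matches the brute-force
  centre-in-polygon oracle by construction and handles the half-open
  boundary so translated ROIs keep their pixel count.
* The one-dimensional profile step is one pixel of arc length;
  perpendicular samples are rounded to the nearest pixel (no bilinear
  interpolation) — at a 500 px width the rounding error is far below
  the block-averaged variation.
* Degenerate inputs fail loudly: constant samples in the normality
  gate, non-positive totals in ratios, empty ROI pixel sets, missing
  channels, area-mismatched background ROIs, and out-of-range
  intensities at write time are all errors, not warnings.

## Synthetic supplementary tables

The published per-cell value tables are not redistributable, so
`synthetic_ratio_table_h3()` (n = 32; 59.4% / 15.6% / 25.0% high /
medium / symmetric, mean exactly 1.35), `synthetic_ratio_table_h2a()`
(n = 20; 90% / 5% / 5% symmetric / medium / high, mean 1.08) and
`synthetic_pair_log2_table()` (n = 33, mean exactly 0.65) construct
deterministic stand-ins that carry those published summaries; the
acceptance suite then *recomputes* the summaries from the per-cell
values through the classification pipeline.  These are labelled
synthetic throughout: they demonstrate that the computations reproduce
the printed summaries from per-cell data of the published shape, not
that the original data were re-analysed.

## Known limitations

* No real-image nucleus segmentation, deconvolution, or PSF modelling;
  ROIs are trusted inputs.
* The Delta level of a cell is a supplied scalar (reporter total);
  antibody puncta counting is out of scope.
* Enterocyte identification by nuclear size is a threshold convention
  (`polyploid` flag in the synthetic manifest), not a ploidy
  measurement.
* The qualitative none/mild/strong phenotype calls that accompany the
  tissue profiles in the source analyses are explicitly subjective and
  are not reproduced here.
* Proprietary microscope formats (LIF/CZI) and ImageJ binary `.roi`
  files are not parsed; convert to TIFF + JSON sidecar first.
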