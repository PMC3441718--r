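---
title: "Quantifying cell polarity and reversals in gliding bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell polarity and reversals in gliding bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarlapse)
```

## The biological problem

Rod-shaped gliding bacteria such as *Myxococcus xanthus* move along their
long axis with a defined leading and lagging pole. Polarity is read out
experimentally in two ways: by where fluorescently tagged polarity proteins
(the small GTPase MglA, its GAP MglB, the response regulator RomR) sit in
the cell, and by how often cells reverse — invert their leading/lagging
axis and glide back the way they came. `polarlapse` implements the
quantitative analyses around these readouts: polar cluster intensity
measurement and ratio-based classification, reversal-frequency statistics
from time-lapse tracks, colony-expansion quantification, and the
sequence/genome tabulations (logo information content, linker composition,
domain-architecture overlap resolution, marker co-occurrence counts) that
accompany a comparative-genomics treatment of the same proteins.

Because the underlying micrographs and genome sets are not distributed with
the package, a synthetic-data module generates every input with known
ground truth. All statements below about recovery and exactness are the
ones the test suite computes.

## Polar cluster quantification

For each cell the integrated fluorescence over each pole region and over a
cytoplasmic reference region of *identical pixel count* is summed; the
corrected polar intensity is

\[ I_{pole}^{corr} = \sum_{pole} I - \sum_{cyto} I . \]

Matching areas makes the subtraction a pure background correction with no
scaling factor; cells whose two pole regions end up with unequal pixel
counts (mask clipping) are rejected with an error naming the regions rather
than silently rescaled.

Classification uses the ratio \(r\) of the brighter to the dimmer corrected
intensity, rounded to one decimal:

| \(r\) (one decimal) | pattern |
|---|---|
| \(r \le 2.0\) | bipolar symmetric |
| \(2.1 \le r \le 10.0\) | bipolar asymmetric |
| \(r \ge 10.1\) | unipolar |

Two numerical choices close the gaps the raw-ratio intervals would leave.
First, \(r\) is rounded to one decimal with halves away from zero before
the rules apply, so the intervals tile \([1.0, \infty)\) exactly (a raw
ratio of 2.04 is symmetric, 2.05 is asymmetric). Second, a cluster
"exists" at a pole only when its corrected intensity exceeds a presence
floor (`presence_floor`, default 0 photons; a sensible field setting is
\(k\sigma\) of the cytoplasmic noise with \(k \approx 3\)): with no
cluster at either pole the cell is *diffuse*, with a cluster at exactly one
pole it is *unipolar* regardless of ratio. The ratio is always taken
max/min, so pole labelling does not matter, and the whole classification is
invariant to scaling both intensities by a positive constant.

`summarize_patterns()` turns per-cell classes into the per-strain
percentage table (the field convention reports percentages over a few
hundred cells per strain).

## Synthetic cells

Synthetic cells are axis-aligned capsules (rectangle plus semicircular
caps), the simplest shape with unambiguous poles. Pole measurement regions
are discs centred on the cap tips clipped to the mask; the right region is
the mirror image of the left, which guarantees equal pixel counts; the
cytoplasmic reference is the set of mask pixels nearest mid-cell with
exactly that pixel count. Planted cluster photons are spread over the pole
disc as evenly as integer counts allow, so before noise the integrated
intensity over a pole region equals the planted value plus cytoplasm ×
area, and a noiseless image measured downstream returns the planted
corrected intensities *exactly* (integer photons). Noise models are `none`,
pixel-wise Poisson (shot noise), or additive Gaussian (read noise, clamped
at zero and re-quantized). No point-spread function, cell crowding,
division, or stage drift is modelled — passing tests demonstrate correct
measurement arithmetic and classifier logic, not robustness to real
segmentation error.

Defaults (60×120 px image, 80×20 px cell, 100 photons/px cytoplasm, pole
disc radius 6 px) were chosen once to resemble a bacterial rod at
~0.1 µm/px with moderate expression levels; none of the package's
guarantees depend on them.

## Reversal analysis

Tracks follow the standard protocol: frames every 30 s for 15 min (31
frames), 50 cells per strain by default. Each frame-to-frame displacement
is projected onto the cell's long axis; a frame's direction is the sign of
the projection where its magnitude is at least `min_step` (default 1 px),
otherwise the frame is a pause. A reversal is scored when a run of at least
`min_run` frames of one sign follows a run of at least `min_run` frames of
the opposite sign, pauses between runs allowed; runs shorter than `min_run`
(sampling jitter) neither score nor reset the established direction. The
default `min_run = 2` (one minute of sustained movement) suppresses
jitter-induced sign flips at 30-s sampling. Detection depends only on
projected displacements, so it is invariant to translating or rotating the
track and to time reversal.

The synthetic track generator plants reversals as a Poisson process thinned
onto the frame grid: each interior frame boundary independently reverses
the direction with probability \(\lambda/(n_{int}-1)\), giving exactly
\(\lambda\) expected reversals per window. Events sit on interior
boundaries because a flip coincident with the first displacement is
observationally identical to starting in the other direction — it would be
a "reversal" no observer could count — and this convention makes the
number of sign changes of the noiseless displacement series equal the
number of planted events for every seed.

One consequence worth stating explicitly: the run-length filter trades
recall for robustness. An event whose neighbouring same-direction stretch
is shorter than `min_run` frames (an event in the last frame of the window,
or two events two frames apart) is deliberately not scored. The package's
rate-recovery experiments therefore run on noiseless tracks with
`min_run = 1`, where the filter guards against nothing and the detector
recovers every observable event; under those conditions the detected mean
matches the planted \(\lambda \in \{0,2,4,8\}\) within \(3\sqrt{\lambda/500}\)
across 500 cells. On noisy data the default `min_run = 2` should be kept.

Per-cell counts are summarized as the field's box plot: mean line, box at
the 25th/75th percentiles, whiskers at the 10th/90th, and outliers —
points strictly outside the whiskers — drawn individually. Percentiles use
linear interpolation between order statistics (the common spreadsheet
default; `stats::quantile` type 7), stated in the output metadata since
percentile conventions differ. Cells observed for at least 80% of the
window are normalized to reversals per window; shorter tracks are excluded
and logged. A stop without resumption of movement is not counted as a
reversal. `compare_strains()` orders strains by mean reversal frequency and
flags hyper-/hypo-reversing strains relative to a reference when means
differ by more than a configurable factor (default 2); no hypothesis test
is attached, matching field practice of displaying distributions.

## Colony expansion

Motility at the population level is quantified as the increase in colony
diameter over an incubation period. The diameter of one colony is the mean
of two chord lengths through the mask centroid — by convention two fixed
orthogonal chords (0° and 90°), a reproducible stand-in for measuring "at
two positions" with callipers. Chords are measured by sub-pixel sampling
(0.05 px steps against nearest-pixel membership), which keeps the error on
an analytic disc within one pixel at any angle; the residual error is the
rasterization itself (a diagonal chord of a pixelated disc is genuinely
about one pixel short). Expansion is diameter(t₂₄) − diameter(t₀) per
replicate colony, reported as mean ± sample (n−1) SD across replicates
(conventionally three); shrinkage is allowed but logged, and a single
replicate reports SD 0 with a warning.

## Sequence tabulations

**Logo information content.** For an alignment column with \(n\) non-gap
residues and frequencies \(f_a\): \(H = -\sum f_a \log_2 f_a\),
\(R = \log_2 20 - (H + e_n)\) with the small-sample correction
\(e_n = 19/(2 n \ln 2)\) (on by default, matching the standard logo tool),
and letter heights \(f_a R\). Gaps are excluded from \(n\); all-gap columns
are flagged and carry `NA`; ambiguity codes are rejected by default or
optionally treated as gaps; \(R\) is clamped to \([0, \log_2 20]\) (the
correction can push small-\(n\) uniform columns slightly negative).

**Composition by physicochemical class.** Residues pooled over sequences
are fractioned into classes. The partition is not standardized in the
field; the package default is hydrophobic AVLIMFWYC, polar uncharged STNQ,
acidic DE, basic KRH, special GP, and any total map over the 20 residues
can be supplied as a TSV, with results labelled by the map used.

**Domain architectures.** Overlapping domain hits are resolved greedily:
repeatedly accept the highest-scoring remaining hit and discard hits
sharing any residue with an accepted one; ties break by earlier start then
lexicographic domain name, making the output deterministic. This is
deliberately the field's stated convention (keep the highest-scoring
model), *not* the maximum-weight interval-scheduling optimum; the greedy
output is idempotent, disjoint, and sorted.

**Co-occurrence tables.** A genome × marker 0/1 table (default marker set
MglA, MglB, RomR-REC, RomR-C, Frz, Glt, T4P) is collapsed to
pattern → genome-count rows, ordered by count descending (ties by bit
string descending; the ordering is a package convention and configurable in
the sense that the caller can reorder). `query_cooccurrence()` answers
"how many genomes have all of these markers, and how many of those also
have that one" — the query form behind statements like "of the genomes
encoding both MglA and MglB, 26 also encode RomR". Pattern counts always
sum to the number of genomes.

## Pipeline and reproducibility

`run_pipeline()` (and the installed `polarity-lapse` script) dispatches the
eight subcommands, validates its configuration with explicit field checks,
refuses to overwrite outputs without `force`, and writes a `metadata.json`
(package version, seed, parameters, MD5 digests of inputs) next to every
result, so a run is reproducible from its metadata alone. All generators
take an explicit seed and restore the caller's RNG state; identical spec +
seed gives byte-identical outputs. Internal image/track CSVs use 0-based
pixel and frame coordinates; domain-hit TSVs are 1-based inclusive, the
common domain-table convention — each reader documents its convention.

## Problem sizes and limitations

The test suite exercises images of ~20×40 to 60×120 px, 500-cell track
ensembles, 1,000 random count lists, 500 random domain-hit sets, and 200
random co-occurrence tables; these sizes put Monte-Carlo checks at 3-SE
resolution while keeping the default run fast. Known limitations: no
automatic segmentation or pole detection (regions are inputs); no
two-channel colocalization beyond running the classifier per channel;
reversal detection assumes an externally supplied long-axis angle per
frame; the synthetic data's idealizations listed above mean green tests
certify the arithmetic, not performance on raw micrographs.
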