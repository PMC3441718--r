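# polarlapse

Quantitative analysis of cell polarity and motility in rod-shaped gliding
bacteria such as *Myxococcus xanthus*.

Cells of these species glide along their long axis with a defined leading
and lagging pole, and the polarity proteins that set this axis (the small
GTPase MglA, its GAP MglB, the response regulator RomR) form polar
fluorescent clusters whose arrangement — and whose occasional pole switch,
a *reversal* — is the experimental readout of the polarity machinery.
`polarlapse` implements the standard quantifications around that readout:

- **Polar cluster quantification.** The corrected polar intensity is the
  integrated fluorescence over a pole region minus that of an equal-area
  cytoplasmic region, `I_corr = Σ_pole I − Σ_cyto I`. The ratio
  `r = max(I_corr) / min(I_corr)` (one decimal) classifies each cell:
  `r ≤ 2.0` bipolar symmetric, `2.1 ≤ r ≤ 10.0` bipolar asymmetric,
  `r ≥ 10.1` unipolar; cells with no cluster above a presence floor are
  diffuse. Per-strain pattern percentages follow.
- **Reversal statistics.** Direction along the long axis per frame (30-s
  frames over 15 min by default), run-length filtered reversal detection,
  and the field's box-plot summary (mean, 25/75 box, 10/90 whiskers,
  outliers), plus hyper/hypo flags relative to a reference strain.
- **Colony expansion.** Increase in colony diameter (two chords through the
  centroid, in mm) over 24 h, mean ± sample SD across replicate colonies.
- **Sequence/genome tabulations.** Sequence-logo information content
  `R = log2(20) − (H + e_n)` with small-sample correction, amino-acid
  composition by physicochemical class, greedy domain-overlap resolution
  (highest-scoring model wins), and genome × marker co-occurrence pattern
  counts and queries.
- **Synthetic data.** Generators for rod-cell images, time-lapse tracks,
  alignments, and presence/absence tables with exact ground truth, so the
  whole pipeline is testable without external data.

## Worked example

```r
library(polarlapse)

# a synthetic cell with planted corrected pole intensities (500, 100)
# photons over a 100 photon/px cytoplasm, with Poisson shot noise
g  <- generate_cell_image(image_spec(pole_intensities = c(500, 100),
                                     noise_model = "poisson", seed = 42))
ci <- measure_polar_intensity(g$image)
ci
#> [1] 550 103
classify_localization(ci)
#> [1] "bipolar_asymmetric"
```

The measured corrected intensities (550, 103) scatter around the planted
(500, 100) because of shot noise; their ratio (5.3) lands in the bipolar
asymmetric class, as planted.

```r
# 50 cells tracked at 30-s intervals for 15 min, 4 reversals/window planted
tr <- generate_trajectories(track_spec(reversal_rate = 4, n_cells = 50,
                                       seed = 42))
reversal_stats(reversal_counts(tr, min_run = 1))
#> <reversal_summary> n = 50 cells; mean 4.02 reversals/window
#>   p10 2.00 | p25 3.00 | p75 5.00 | p90 6.10 | 8 outlier(s)

# co-occurrence query: of the genomes with both MglA and MglB, how many
# also carry RomR?
tab <- generate_presence_absence(pattern_spec(
  c("111" = 26, "110" = 34, "100" = 10, "000" = 5),
  markers = c("MglA", "MglB", "RomR"), seed = 42))
query_cooccurrence(tab, require = c("MglA", "MglB"), also = "RomR")
#> n_require    n_also
#>        60        26
```

A command-line wrapper is installed with the package
(`system.file("scripts", "polarity-lapse", package = "polarlapse")`):

```sh
polarity-lapse simulate --what tracks --reversal_rate 0 --n_cells 5 --seed 2 --out sim/
polarity-lapse reversals --tracks sim/tracks.csv --out results/
```

Every run writes a `metadata.json` (version, seed, parameters, input
digests) beside its outputs.

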