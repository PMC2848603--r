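# qicyte

Quantitative image cytometry for adherent cells in R.

Immunofluorescence imaging of fixed adherent cells can, in principle,
replace western blots and flow cytometry for quantifying signalling
activity — protein amount, phosphorylation, nuclear translocation — with
single-cell and subcellular resolution. The hard part is identifying the
*whole* cell: subconfluent adherent cells (PC12, HeLa, ...) touch each
other and have rough, dim boundaries, and the conventional high-content
screening (HCS) shortcut of summing intensity in a disk dilated around
each nucleus cross-contaminates neighbouring cells and misses cytoplasmic
signal. `qicyte` implements a precise cell-identification and
quantification pipeline for multi-channel fields (DNA stain, whole-cell
stain, one or two immunostain channels), the single-cell statistics built
on top of it, and a synthetic-field generator with exact ground truth that
makes the whole pipeline testable end to end.

## The method

**Segmentation.** For the nuclear channel, a pixel is foreground when it
exceeds the mean intensity of the 41 x 41 px window around it — a local
threshold that adapts to non-uniform illumination. Labelled objects must
be *bright* (object mean above the local background by 3 background SDs)
and non-trivial in size; clumps of adjacent nuclei are then split by a
*limited watershed*: an object is divided at the lowest intensity level
("watermark") that separates it into two components, but only when the
intensity above the watermark retains more than 85% of the object's total
— so single noisy nuclei never shatter. Objects with total DNA below half
of the typical G1-phase level (the mode of the per-object DNA-total
histogram) are removed as debris. For the cell channel, a pixel is
foreground when it exceeds the *local background mean* (mean of the
presumable background within a 41 x 41 window) by three times the *global
background SD* (the mode of the histogram of 5 x 5-window SDs — robust to
bright objects, unlike a local SD). Finally a marker-controlled watershed
descending the cell-stain intensity partitions the foreground among the
nuclei, so every cell contains exactly one nucleus.

**Per-cell quantification.** Signal amounts are raw intensity sums over
the cellular and nuclear masks. Shape is summarized by the roundness
`P^2 / (4*pi*A)` (Crofton perimeter estimate; 1 for a circle), with
roundness >= 1.2 flagging unresolved multi-nucleate objects. Nuclear
localization is the **NLI**, the cosine between the per-pixel
nuclear-stain and antigen vectors of the cell,

```
NLI = sum_p N(p) A(p) / ( sqrt(sum_p N(p)^2) * sqrt(sum_p A(p)^2) )
```

which runs from 0 (cytoplasmic) to 1 (nuclear) and is invariant to
staining level and antigen amount; a well-normalized variant corrects it
by the cell-stain NLI. Cells whose nuclear and cell-channel patterns do
not co-vary (chromatic displacement between channels) are flagged as
ill-identified. The conventional HCS baseline — amounts in a 16-px
dilated-nucleus ROI, translocation as the Circ/Ring average-intensity
ratio — is implemented alongside for comparison.

**Population statistics.** Per-cell totals are close to lognormal, so
averages are geometric; per-timepoint log-space SDs and the Pearson
correlation between log-transformed channel pairs (e.g. phospho-MEK vs
phospho-ERK) trace how tightly a substrate follows its kinase over time.
Replicate experiments measured in arbitrary units are put on a common
scale by least-squares per-experiment scaling factors.

## Worked example

```r
library(qicyte)

spec <- synthetic_field_spec(n_cells = 30L, touching_fraction = 0.2, seed = 42)
g <- generate_field(spec, well_id = "B02", time_min = 6)

seg <- identify_cells(g$field)
n_objects(seg$cells)
#> [1] 30

tab <- measure_cells(g$field, seg$nuclei, seg$cells)
head(tab[, c("cell_id", "area_px", "roundness", "total_pERK",
             "nuclear_pERK", "nli_pERK")], 4)
#>   cell_id area_px roundness total_pERK nuclear_pERK nli_pERK
#> 1       1     736     1.058     103995        40270   0.7546
#> 2       2     609     1.024     101215        40153   0.7655
#> 3       3     569     1.025      91668        37319   0.8198
#> 4       4     868     1.033     166054        68551   0.8806
```

All 30 planted cells are recovered, including the three touching pairs.
`total_pERK` is the raw summed fluorescence over the cell mask (arbitrary
units, background included), `nuclear_pERK` the sum over the nucleus, and
`nli_pERK` the cosine localization index — about 0.75–0.88 here because
half of each cell's antigen was planted in the nucleus on top of a shared
background. Three cells are flagged `flag_multi_nucleated` (roundness
above 1.2, the irregular halves of touching pairs); none is flagged
ill-identified.

Time-series statistics on a planted kinase–substrate population with a
rise-then-fall decoupling noise schedule:

```r
pop <- generate_population(2000, time_grid = c(0, 10, 20),
                           noise_schedule = c(0.05, 0.5, 0.2), seed = 1)
timepoint_stats(pop, c("pMEK", "pERK"))
#>   time_min n_cells n_excluded geo_mean_pMEK geo_mean_pERK log_sd_pMEK log_sd_pERK log_pearson
#> 1        0    2000          0           994           995       0.415       0.420       0.992
#> 2       10    2000          0           994           988       0.394       0.641       0.606
#> 3       20    2000          0           997           994       0.394       0.443       0.896
```

The correlation dips and the substrate's log-SD swells exactly when the
independent noise term dominates — the signature used to reason about
feedback in the pathway.

A thin command-line wrapper lives in `inst/cli/qicyte.R`
(`segment`, `run`, `stats`, `simulate` subcommands; see its header).

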