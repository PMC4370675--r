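---
title: "Methods: gating, counting and radar projection in leukogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating, counting and radar projection in leukogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukogate)
```

## The problem

Ten-color flow cytometry of unfractionated whole blood can resolve every
major leukocyte compartment in a handful of tubes, but only if three
things are done consistently: gates must partition events into
*non-overlapping* phenotypes, percentages must be reported against
explicit parent and grandparent populations, and — because percentages of
a shifting denominator mislead — phenotypes should be carried to absolute
concentrations (cells/ul) via counting beads. leukogate implements that
workflow end to end and validates it against a simulator whose ground
truth is known per event.

## Gating model

A gating tree is a rooted hierarchy of named nodes. Each node constrains
its parent by one or two half-open interval clauses on marker channels
(`value >= threshold` or `value < threshold`). Two conventions matter:

* **Half-open intervals.** An event exactly at a threshold belongs to the
  positive side. Sibling nodes generated from one histogram split or one
  quadrant plane are therefore mutually exclusive and exhaustive, and the
  package asserts partition conservation — child counts of an exclusive
  split sum to the parent count *exactly*, not approximately.
* **Data-driven thresholds.** Scatter and fluorescence units are
  arbitrary, so no constant is hard-coded. Thresholds come from three
  sources, in the order the staining design makes available:
  1. `fmo_quantile` — the 0.995 quantile of the matched
     fluorescence-minus-one control tube's channel. FMO tubes are the
     reference for dim markers without a clean negative in the tube
     (CD123, CD15 within the immature myeloid gate).
  2. `negative_population_quantile` — the same quantile on a designated
     in-tube negative population. The automatic map
     (`auto_thresholds()`) designates the events under the lowest
     density mode of the channel as that negative reference.
  3. `valley` — the deepest kernel-density minimum between the two
     largest modes, used for markers with a clearly separated bright
     population (the side-scatter class boundaries, the CD45 debris
     boundary, the CD14-bright/dim and LIN2-bright/dim monocyte
     cutpoints, and the gamma/delta TCR gate in the TBNK tree).

  The 0.995 quantile bounds the false-positive rate on true negatives at
  0.5%; it is the package default, adjustable per call. Density work is
  done on `asinh(x/150)` — the conventional cytometry display transform —
  with Silverman-bandwidth Gaussian kernels on a 512-point grid, and
  peaks below 1% of the tallest mode are ignored (0.1% where a rare
  population is the object of interest, e.g. the CD123 region or the
  gamma/delta TCR valley).

Three hierarchies are encoded. The TBNK/M/G counting tree (26 named
phenotypes): CD45+ leukocytes split by side scatter; mononuclear cells
split on a CD14 histogram; CD19xCD3, CD4xCD8 and CD16xCD56 quadrants for
the lymphoid compartment, with gamma/delta TCR reported as an overlay
within CD3+ rather than inside the CD4xCD8 quadrants (gamma/delta T cells
can carry CD4 or CD8 abnormally); CD14xCD16 monocyte subsets; CD15xCD16
within SS-high for neutrophils and eosinophils. The Myeloid tree: CD33+
myeloid cells from mononuclear cells, then LIN2xHLA-DR quadrants into
mature monocytes, HLA-DRlo/neg (suppressive) monocytes, dendritic cells
and the LIN2-HLA-DR- MDSC/imMC gate, whose SS-low subset is the immature
myeloid cell gate; LIN2 serves as the CD14 surrogate for monocyte
subsets on this panel. The Monocytes-1/-2 trees resolve CD14+ monocytes
both against HLA-DR and on CD14xCD16. CD33xCD11b is deliberately only a
diagnostic overlay, never a gating step: monocytes, DCs, MDSCs and
granulocytes overlap heavily on those two markers alone.

The HLA-DR-lo/neg boundary is placed from in-tube HLA-DR-negative cells
(no published rule exists); whether the original side-scatter gating was
linear or log is likewise unstated, so the class boundaries are placed by
valley detection on asinh-transformed SS — a choice that only assumes the
three scatter classes are separable, not any particular scale.

## Absolute counting

Lyse/no-wash tubes carry Flow-Count-style fluorospheres of known
concentration. Beads are engineered to be bright on every fluorescence
channel, so they are gated in two sequential steps — a bright FL2 band
across acquisition time, then the bright-FL4 x forward-scatter cluster
(the second step evicts any leukocyte that strayed into the band; the
FL4 cut is the 99.99th percentile of the non-band events' FL4). Then

    cells/ul = count(phenotype) x (fluorospheres/ul) / count(CAL)

with `count(CAL)` the beads counted during the run. The formula is linear
in the phenotype count and invariant under joint rescaling of phenotype
and bead counts. Because beads would also satisfy a CD45+ gate, the
analysis pipeline removes bead-gated events before applying a tree, and
derives thresholds from the bead-free events. Lyse/wash panels carry no
beads; their phenotypes are anchored through the counting tube:
`cells/ul = pct_of_CD45 / 100 x CD45_per_ul(TBNK)`. The bead lot
concentration is not a constant of the method — it is lot-assayed in
practice — so it is a required user input (fixtures use 1000/ul).

## Marker regions and the myeloid catalog

For each of the nine informative Myeloid-panel markers, expression
regions are derived from the density peaks on the asinh scale: the lowest
peak is the no-expression region N, successive peaks become R1..R3, with
boundaries at the density minima between peaks. Kernel ripples are not
peaks: adjacent maxima are merged unless the density between them dips
below 90% of the smaller peak. Back-gating each region onto FS x SS
reveals which scatter compartment its cells occupy.

The CM1-CM9 catalog maps region profiles to the nine common myeloid
phenotypes. The published level grid uses "-", "lo", "+", "++" (with
"+/-" wildcards and "lo/neg" spans); these are interpreted *per marker*:
the distinct positive levels appearing in a marker's column are ranked
(lo < + < ++) and assigned ascending regions, the highest level also
matching any brighter region. A flat mapping ("+" and "lo" both to R1)
would make intermediate (CD14+CD16+) and non-classical (CD14lo CD16+)
monocytes indistinguishable, contradicting the catalog's defining
property; the ordinal mapping keeps all nine classes pairwise disjoint,
which the test suite verifies exhaustively over the discriminating grid.
Basophils — which share the LIN- CD33+ HLA-DR- CD123+ profile — are
treated as a contamination flag within CM7, not a tenth class.

## Radar (star-coordinate) projection

Each of up to 13 axes carries a marker at an angle; an event's position
is the unnormalized vector sum of the axis unit vectors scaled by
`s_i = clip((asinh(x/150) - lo_i) / (hi_i - lo_i), 0, 1)`, with per-axis
anchors at the 1st/99th percentiles of a scaling tube. The vector sum is
adopted because it reproduces both documented behaviors of the display:
brighter markers push events outward, and full positivity on two axes
180 degrees apart cancels to the origin. The sum is deliberately not
normalized by axis count (the alternative would shrink radii as axes are
added, breaking visual comparability across configurations with
different axis counts). Rotating the configuration rotates the
projection rigidly — pairwise distances are preserved to numerical
precision — which is what makes axis-rotation animations interpretable.
The six-axis preset places CD3/CD19/CD56 at 90/210/330 degrees and
interleaves CD14/CD4/CD8.

## The synthetic cytometer

The simulator draws labeled tubes with the statistical structure the
gating method assumes — and its defaults are the study conditions of the
validation suite, not tuning knobs.

* **Populations.** Healthy blood: neutrophils 0.58, eosinophils 0.02,
  monocytes 0.08 (classical 0.85 / intermediate 0.05 / non-classical
  0.10 of monocytes, plus HLA-DRlo/neg monocytes 0.004), lymphocytes
  ~0.30 (T 0.21 with CD4:CD8 = 2:1 and 3% gamma/delta; B 0.036; NK
  0.045; small CD16+ and lineage-negative remainders), dendritic
  subsets, plasmacytoid DC and immature myeloid cells each at or below
  0.005, WBC 6000/ul. These are physiological defaults (no reference
  table of healthy ranges is published to copy); a lineage-negative
  filler absorbs the residual so abundances sum to exactly 1. Marrow and
  pleural profiles shift the same populations (marrow: granulocyte-rich,
  enlarged immature compartment, WBC 25000/ul; pleural: T-cell dominated,
  WBC 1500/ul).
* **Intensities.** Stained markers are log-normal per population
  (geometric mean, geometric CV 0.55 unless noted) on a typical
  digital-cytometer scale: background geometric mean 150 (CV 0.75), dim
  positives 30-60x background, main positives 600x, bright 2000x. The
  background is far enough below the dimmest positive that FMO
  thresholds separate cleanly. `LIN2` is the maximum of its four
  component draws — a cocktail reports the brightest bound antibody.
* **The CD123 compartment.** Immature myeloid cells carry CD123 at
  20-fold the monocyte/granulocyte level (which is background) and half
  the plasmacytoid-DC level. Their geometric CV of 0.84 places ~96% of
  them above the 0.995 FMO quantile: with background sdlog 0.668 the
  threshold sits at `exp(2.576 x 0.668) = 5.59x` background, and
  `P(lognormal(20x, sdlog 0.73) > 5.59x) = 0.96`. The basophil fraction
  (1.04e-4 of CD45+) was solved analytically so that CD15+CD123+ events
  are ~2.5% of the immature myeloid gate:
  `f_b = (0.025 - 0.0048) / (0.999 - 0.0048) = 0.0203` of the gate,
  given that basophils are CD15+ (100x background) CD123+ and immature
  myeloid cells contribute only the 0.5% FMO false-positive floor times
  their 96% CD123 positivity. Both constants were fixed from this
  arithmetic before any recovery run.
* **Mechanics.** One master seed per tube; labels, time, scatter and
  each fluorescence channel draw from separate substreams derived from
  it in fixed order. This makes tubes bit-reproducible and makes an FMO
  variant differ from its matched stained tube *only* on the omitted
  channel — the property the FMO tests assert. (A single sequential
  stream would re-align every draw after the omitted channel.) TIME is
  uniform over the acquisition; beads interleave uniformly. Debris (2%
  of non-bead events) is CD45-negative with low scatter and exercises
  the CD45/SS root gate. Beads are drawn with probability
  `p = 0.98r / (1 + 0.98r)`, `r = bead_conc / wbc`, which makes the
  expected bead count equal leukocyte events x `bead_conc/wbc`, so the
  counting formula is unbiased by construction. Doublets, spectral
  spillover, viability and acquisition drift are *not* simulated.

### What passing the synthetic suite does and does not show

The simulator reproduces the features the method relies on: well-formed
log-normal positive/negative populations, three scatter classes, an FMO
control that differs only in the omitted stain, beads at a known
concentration. Recovery results (per-population F1 at or above 0.95 for
all counting-tree leaves at 0.5%+ abundance over seeds 1-5; CD45+
concentration within 5%; the CD123 structure of the immature myeloid
gate) therefore validate the *algorithms* — threshold placement, tree
application, bead arithmetic — under the model's assumptions. They do not
establish performance on real instruments, where compensation error,
spectral spillover, doublets, dead cells and non-log-normal smearing all
exist. The delimited-text and FCS 3.1 interfaces are exactly the seam
where real data enters the same pipeline.

## Numerical choices and degenerate inputs

* Density estimation: `stats::density`, Gaussian kernel, Silverman
  bandwidth ("nrd0"), 512 grid points, on asinh scale; boundary bins may
  hold genuine modes (background piles up near zero).
* Valley placement errors on unimodal channels and recommends the
  quantile methods; bead gating converts that failure into a "no bead
  cluster" error.
* Empty gates: percentages of an empty parent are reported as 0;
  geometric MFI of an empty gate is `NA` with `n = 0`; back-gating an
  empty region returns a zero-row summary.
* Negative post-compensation intensities are clipped at 0 with a warning
  when an event table is built.
* Events exactly at a threshold are positive (half-open intervals).
* Spearman p-values: exact for n <= 10, t approximation above.

## Problem sizes

The validation suite simulates tubes of 20,000-50,000 events; recovery
claims use 50,000-event tubes over seeds 1-5 (gating F1) and 11 donors x
3 tubes (the CD123 analyses, mirroring the 11-donor design of the
underlying study). `scripts/acceptance.R` re-runs the 11-donor CD123
analysis from scratch at 50,000 events per tube.

## Known limitations

* Only the TBNK/M/G, Myeloid and Monocytes-1/-2 hierarchies are encoded;
  the T-cell, B-cell and Granulocyte panels are registered (so their
  tubes simulate, load and validate) but their published gating trees are
  not reproduced.
* Compensation is out of scope: inputs are assumed compensated, matching
  the per-protocol instrument settings workflow the panels were designed
  for.
* Granulocytic MDSCs cannot be separated from granulocytes by surface
  phenotype in whole blood; CM8/CM9 carry that caveat.
* The FCS support is deliberately minimal (3.1, list mode, 32-bit float,
  single data set) — an interchange format, not a general FCS library.
* The radar projection maps high-dimensional events to 2D by a fixed
  linear rule; axis arrangement is empirical, and populations bright on
  opposing axes collapse toward the origin by design.
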