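---
title: "Quantifying POPDC membrane trafficking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying POPDC membrane trafficking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

POPDC (Popeye domain containing) proteins are transmembrane cAMP effectors of
cardiac and skeletal muscle whose disease-associated variants perturb
trafficking to the sarcolemma. Assessing such variants rests on a small set
of quantitative readouts: how much of the protein sits in the sarcolemma of a
muscle fiber relative to a membrane reference (α-sarcoglycan, SGCA); how
strongly a reporter-tagged protein localizes to the plasma membrane of a
transfected cell relative to its cytoplasm; how strongly two proteins
interact (bimolecular fluorescence complementation, BiFC); and what the
stoichiometry of their complex is (type-1 quantitative BRET). `popdcquant`
implements these four quantification pipelines together with the
nonparametric statistics used to compare patient and control material, and a
set of seeded synthetic-data generators that provide known ground truth for
every stage.

This vignette records the models, the tunable parameters and the design
decisions, in particular the choices made where the underlying experimental
protocols leave details open.

## Muscle-fiber compartment quantification

A transverse muscle section is imaged with a membrane-marker channel (SGCA
immunostain) and a target channel (POPDC1 or POPDC2). The pipeline is:

1. **Segmentation** (`segment_fibers`). The membrane marker is thresholded —
   Otsu's method by default, or a fixed value — and fiber interiors are the
   connected components of the *sub*-threshold region. Components smaller
   than `min_fiber_area_um2` (default 100 µm², well below any real fiber)
   are discarded, and border-touching fibers can be excluded.
2. **Compartments** (`compartment_masks`). Each fiber's outline (the
   boundary pixels of its interior) is dilated by a Euclidean disk of radius
   `dilation_radius_px` (default 3 px) to form the sarcolemma ring; the
   cytoplasm is the interior minus the ring. Dilation is computed with exact
   integer squared distances, so ring membership is free of approximation.
   Where the rings of adjacent fibers compete for a pixel, the nearer
   outline wins, with ties going to the lower fiber id; this makes rings and
   interiors disjoint within and across fibers by construction. The ring
   deliberately includes the outline band itself as well as the dilated
   margin: outline-dilation protocols for enclosing the sarcolemma do not
   separate the two, so neither does this implementation.
3. **Measurement** (`quantify_fibers`). Per fiber: mean intensity of every
   channel over ring and cytoplasm; the cross-sectional area (the full
   segmented interior, before ring subtraction, times the squared pixel
   size); the marker-normalized sarcolemmal signal (target ring mean /
   marker ring mean), which cancels section-to-section staining efficiency;
   and the sarcolemma/cytoplasm enrichment of the target. Fibers with a zero
   marker ring mean carry undefined ratios, are flagged, and are excluded
   from downstream medians (their count is reported).

Background subtraction is *not* applied to tissue images — the transfected-
cell protocol prescribes it, the tissue protocol does not — though
`subtract_background` can be called explicitly.

## Single-cell localization ratios

For transfected cells carrying a membrane dye (DiD), a nuclear stain and one
or two fluorescent reporters, `segment_cell` supports two modes. The
faithful mode takes an operator-supplied closed boundary polygon (mirroring
manual outlining on the dye channel): the membrane mask is the rasterized
boundary dilated by `band_px` (default 1 px), and the cytoplasm is the
enclosed area minus the band minus the thresholded nucleus. A 1-px guard
margin is excluded between band and cytoplasm because the rasterized
boundary is only pixel-accurate; without it, membrane-intensity pixels leak
into the cytoplasm mean and bias high ratios downward by ~10%. The
automatic mode thresholds the dye channel (Otsu) and recovers the enclosed
area by hole filling; it exists because manual outlines are not
reproducible, but the polygon path takes precedence when both are given.

Background is estimated per channel as the median over pixels outside all
cell masks (5th percentile of the whole image as fallback), subtracted, and
floored at zero before quantification. The localization ratio (membrane
mean / cytoplasm mean per reporter) is then invariant to per-channel gain.

## BiFC quantification

Complementation fields are gated on the transfection control (mRFP):
`select_transfected` keeps pixels above the channel median plus 3 MAD (most
pixels at this magnification are background, so the median estimates the
background level), minus thresholded nuclei. The per-image signal is the
median Venus intensity over that mask divided by the median mRFP — the image,
not the cell, is the replication unit, matching how such assays are read out
(5–9 images per group). Group means are normalized so the wild-type pair is
exactly 1, and groups are compared on per-image values by one-way ANOVA with
Dunnett's many-to-one test against the wild type.

## Type-1 quantitative BRET

In a type-1 titration, donor- (NanoLuc) and acceptor-tagged (HaloTag)
constructs are co-expressed at varying plasmid ratio with total amount held
constant. After background subtraction (matched dye-free wells) and
calibration of luminescence and fluorescence onto a common expression scale
(user-supplied factors, default 1), each point yields a corrected BRET value
and an acceptor fraction $f$.

The ideal curves are, for an $n$-mer under random assembly,

$$B(f) = B_\max\,\bigl(1 - (1-f)^{\,n-1}\bigr),$$

the probability that a donor's complex contains at least one acceptor among
its $n-1$ partner slots. The dimer gives $B_\max f$ — a saturating hyperbola
when plotted against the acceptor:donor ratio $x = f/(1-f)$. The monomer has
no specific component; its bystander BRET from random proximity is modelled
as non-saturating and linear in the acceptor:donor ratio,

$$B(f) = s\,\frac{f}{1-f}.$$

The ratio-linear (rather than fraction-linear) bystander term is a
deliberate design choice: at constant total expression a fraction-linear
bystander would be the *same function* as the dimer curve, and no titration
could distinguish the two. Linearity in the expression ratio preserves the
qualitative signature the assay relies on — hyperbolic saturation for
specific complexes versus an unbounded straight line for bystander signal —
and makes generator and fitter self-consistent. The parameterization of the
referenced type-1 method may differ in detail; this package's claims are
internal-consistency claims, not reproductions of published curves.

Each candidate model ($n \in \{1,2,3,4\}$ by default) has one free
amplitude, fitted in closed form by least squares; the complex order is the
AICc minimizer. Classification is refused when the titration spans less than
0.4 in $f$, and a rapid-saturation caveat is attached when the best model has
$n \ge 3$ with sparse low-$f$ coverage (fewer than 3 points below 0.3),
since rapidly saturating curves carry little information about the exact
order. The design assumption — constant total expression — is tested by a
nested-model F-test of total expression against the expression ratio
(horizontal vs straight-line fit), restricted to points with acceptor:donor
ratio above 2 (strict), as recommended for such designs.

## Statistics layer

* `normalize_to_control`: division by the matched control median, so the
  control's own normalized median is exactly 1. Idempotent and
  scale-invariant.
* `median_ci`: distribution-free order-statistic interval — the widest
  symmetric pair of order statistics whose exact binomial coverage reaches
  95%. The interval is conservative by construction (e.g. 96.5% exact
  coverage at n = 100); for n < 6 a seeded 2000-resample bootstrap is used
  with a warning. The order-statistic construction was chosen because it
  matches the nonparametric framing of the group comparisons; the exact
  interval construction used in the original analyses is not recoverable.
* `mann_whitney`: two-sided Wilcoxon rank-sum via the standard sample-size
  rule (exact for small tie-free samples); fully tied data return p = 1
  with a flag.
* `kruskal_dunn`: Kruskal–Wallis with tie correction, then Dunn's z for the
  requested pairs with Holm adjustment — Holm because it dominates
  Bonferroni uniformly and the original adjustment is unspecified.
* `anova_dunnett`: one-way ANOVA with Dunnett's single-step many-to-one
  comparisons (via `multcomp`).

All tests are two-sided. Fibers and cells are treated as independent
replicates within a group, mirroring the source analyses; a mixed-effects
treatment of fiber-within-image correlation is out of scope.

## Synthetic data: what it emulates, and what it does not

All generators are seeded and bit-reproducible, and every generated object
carries exact ground truth (masks, noise-free compartment means, areas,
noise-free curves).

**Biopsy mosaics** (`generate_biopsy`). Fiber seed points are placed by dart
throwing and the field is partitioned by a weighted nearest-seed rule (power
diagram), with a few area-balancing iterations so that ground-truth fiber
areas follow the requested lognormal law (default meanlog = log 3000 µm²,
sdlog 0.3, matching normal adult fiber calibers at 1 µm/px). Each cell is
then eroded by the ring half-width (default 3 px) to carve the bright
sarcolemma network: the membrane marker is bright only there, and the
target channel carries per-fiber ring and interior means with a
multiplicative lognormal per-fiber factor (CV 0.1) shared by both
compartments, plus background and zero-clipped Gaussian noise. The group
effect multiplies the target ring intensity only.

Default intensities (ring 200, interior 5, background 2 a.u.) encode strong
sarcolemmal enrichment, as seen in SGCA/POPDC stains where the fiber
interior is nearly dark. This matters quantitatively: the measured ring mixes
true ring pixels with the outline band and inward dilation margin at
interior intensity (a mixing fraction of about 40% ring pixels with the
default geometry), so the control-normalized median recovers a group effect
$g$ with bias $(1-g)\,(bI + \beta)/(aR + bI + \beta)$, where $a$ is the
ring-pixel fraction, $b = 1-a$, $R$ and $I$ the ring and interior
intensities and $\beta$ the background. The defaults keep this bias near
+0.03 at $g = 0.5$ — within the ±0.05 recovery band the pipeline is
validated against. Tissue with weak sarcolemmal enrichment would be
quantified with a proportionally larger compartment-mixing bias; that is a
property of outline-dilation compartment analysis generally, not of this
implementation.

**Cell fields and BiFC fields** are non-overlapping discs with membrane
annulus, nucleus and reporter channels at specified membrane:cytoplasm
ratios (cells), or transfection-control and interaction channels with the
interaction signal equal to `efficiency` times the control in a configurable
transfected subset (BiFC). Ground truth includes mid-membrane boundary
polygons, which serve as the manual-ROI path in tests.

**BRET titrations** follow the ideal curves plus background and Gaussian
BRET noise; expression noise is a shared per-well lognormal factor
(cell-count/pipetting variation) multiplying both reads, so the
acceptor:donor ratio is exact while the apparent total fluctuates. Modelling
the expression noise per channel instead would correlate the
total-expression error with the ratio regressor and inflate the
constant-expression F-test's type-I rate above nominal — an
errors-in-variables effect worth keeping in mind when interpreting that
F-test on real plates with large channel-specific reading noise.

What the generators do **not** emulate: point-spread blur and chromatic
shifts, uneven illumination, t-tubule and perinuclear sub-compartments,
touching or irregularly shaped cells, fiber-type intensity classes, and
image-to-image staining batch effects. Passing the recovery suites therefore
demonstrates correctness of the measurement and statistics machinery on
idealized geometry, not robustness to every real-microscopy artifact.

## Numerical and interface choices

* Coordinates are pixel indices; masks are pixel sets; the structuring
  element is a Euclidean disk evaluated on exact integer squared distances.
* Generators emit non-negative real intensities; the TIFF writer quantizes
  to 16 bit with a recorded scale, and a JSON sidecar carries the
  channel-role map and pixel size so stacks round-trip.
* Problem sizes used in the validation suites — 150 fibers per arm for
  group-effect recovery, 30 cells per ratio condition, 12-point titrations
  with 200 seeded replicates per model, 500–1000 replicates for test
  calibration — match the scale of the corresponding real experiments while
  keeping a full run on a single CPU in well under an hour.
* Reports are written as CSV (per-object records) plus JSON (summaries,
  tests, configuration) and are byte-deterministic for fixed seeds.

## Known limitations

* The ring compartment mixes sarcolemma and near-membrane cytoplasm pixels
  (see above); marker normalization cancels staining efficiency but not
  this geometric mixing.
* Dunn's test uses the normal approximation for its z statistics; very
  small groups (< 5) are better served by exact pairwise tests.
* The automatic cell-boundary mode assumes an approximately closed, bright
  membrane-dye ring; fragmented dye staining requires the polygon path.
* qBRET classification assumes a single homogeneous complex species;
  mixtures of stoichiometries are reported as whichever single order fits
  best, with the rapid-saturation caveat as the only safeguard.
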