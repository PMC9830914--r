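# popdcquant

Quantification pipelines for studies of POPDC (Popeye domain containing)
protein membrane trafficking in muscle and cell models.

POPDC1/BVES and POPDC2 are transmembrane cAMP effector proteins of cardiac
and skeletal muscle that traffic to the sarcolemma as heteromeric complexes;
disease-associated variants perturb that trafficking to varying degrees.
Assessing a variant quantitatively requires four measurements, each of which
this package implements end to end:

* **Fiber compartment quantification** — segment muscle-fiber cross-sections
  from a membrane-marker channel (α-sarcoglycan, SGCA), split each fiber
  into a sarcolemma ring (outline dilated by a Euclidean disk, contended
  pixels going to the nearest fiber) and a cytoplasm, and record per fiber
  the marker-normalized sarcolemmal signal
  `target ring mean / marker ring mean`, the sarcolemma/cytoplasm
  enrichment, and the cross-sectional area.
* **Single-cell localization ratios** — for reporter-tagged proteins
  co-expressed in cells with a membrane dye (DiD) and nuclear stain:
  background subtraction, ROI- or dye-guided membrane/cytoplasm
  segmentation, and the plasma-membrane localization ratio
  `membrane mean / cytoplasm mean` per reporter.
* **BiFC quantification** — transfection-gated (control channel above
  background + 3·MAD), nucleus-excluded median interaction signal
  normalized to the internal transfection control per image, group means
  normalized to the wild-type pair (≡ 1), ANOVA + Dunnett.
* **Type-1 quantitative BRET** — background correction against matched
  dye-free wells, expression normalization, an F-test of the
  constant-total-expression design assumption, and least-squares fits of
  ideal stoichiometry curves `B(f) = Bmax (1 − (1 − f)^(n−1))` (acceptor
  fraction `f`; bystander-only monomer model linear in the acceptor:donor
  ratio), with the complex order classified by AICc.

A statistics layer provides the accompanying nonparametric machinery:
control-median normalization (control ≡ 1), distribution-free
order-statistic 95% CIs for medians, Mann–Whitney, Kruskal–Wallis + Dunn
(Holm-adjusted), and ANOVA + Dunnett. Seeded synthetic-data generators
(biopsy mosaics with lognormal fiber areas, cell fields, BiFC fields, BRET
titrations) supply exact ground truth so every stage is testable without any
external data. See `vignettes/popdcquant-methods.Rmd` for the models,
parameter choices and limitations.

## Worked example

Simulate a patient/control biopsy pair in which the variant reduces the
sarcolemmal target intensity to 75% of control, then run the full study:

```r
library(popdcquant)

mk <- function(effect, seed)
  generate_biopsy(biopsy_spec(n_fibers = 150, group_effect = effect,
                              seed = seed))$stack
study <- run_biopsy_study(list(mk(0.75, 1)),   # patient arm
                          list(mk(1.00, 2)))   # matched control
study
```

```
Biopsy study: 309 fibers across 2 images
Marker-normalized sarcolemmal signal (control median = 1):
   group   n median_normalized ci_low ci_high
 control 154            1.0000 0.9880  1.0223
 patient 155            0.7641 0.7523  0.7832
mann_whitney: statistic = 895, p = 6.851e-45
Fiber cross-sectional area (um^2):
   group   n median_um2 ci_low ci_high
 control 154       2969   2726    3142
 patient 155       2922   2746    3139
mann_whitney: statistic = 1.183e+04, p = 0.8956
```

The control median is pinned to 1 by construction; the patient arm's
normalized median (0.764, 95% CI 0.752–0.783) recovers the simulated 25%
reduction, highly significant by Mann–Whitney, while fiber areas —
unaffected in this simulation — do not differ.

Fitting a simulated dimer BRET titration:

```r
sim <- generate_bret_titration(bret_sim_spec(stoichiometry_n = 2, bmax = 0.5,
                                             noise_sd = 0.02, seed = 1))
fit <- fit_stoichiometry(sim)
summary(fit)
```

```
Candidate models (amplitude = bmax, or bystander slope for n = 1):
 model_n amplitude      rss   aicc delta_aicc
       1   0.07272 0.289324 -39.37      47.43
       2   0.49912 0.005555 -86.80       0.00
       3   0.37903 0.013712 -75.96      10.84
       4   0.33722 0.036433 -64.23      22.57
Type-1 BRET stoichiometry fit
  points: 12, acceptor-fraction span: 0.80
  classification: n = 2 (dimer)
```

The dimer model wins decisively (ΔAICc ≥ 10.8 to every alternative) and the
fitted amplitude 0.499 recovers the simulated `bmax = 0.5`.

A thin command-line front end is installed with the package
(`system.file("cli", "popdc", package = "popdcquant")`) with subcommands
`synth`, `fiberquant` and `qbret` for shell-driven use.

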