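---
title: "Methods: quantifying post-mitotic nuclear reassembly phenotypes"
author: "nucquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying post-mitotic nuclear reassembly phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nucquant` quantifies the imaging, timing and sequence readouts used to
characterize defects of nuclear reassembly after mitosis — the phenotype
cluster associated with loss of the H2A.Z chaperone VPS72: extended
telophase in live-cell movies, chromatin structures with DNA-staining voids
("holes") in cell-free nuclear assembly reactions, altered nucleolar
organization, changed nuclear size and marker intensities, and the
cross-species conservation of the VPS72 YL1-C domain. Because no raw imaging
data are publicly deposited for this phenotype family, every stage is paired
with a synthetic generator that produces images and track tables with exact
ground truth, so the whole pipeline is verifiable at desk scale.

# The synthetic generator

## What it emulates

* **Nuclei** are smoothed star-convex blobs: a base radius (default
  50 ± 5 px) modulated by a normalized random Fourier perturbation of
  harmonics 2–5 with relative amplitude `shape_irregularity` (default 0.08).
  Star-convex blobs rather than ellipses exercise the irregular outlines of
  assembled chromatin structures. Placement is rejection sampling with a
  minimum boundary gap (12 px), so nuclei never touch — declumping is
  deliberately out of scope.
* **Chromatin voids** of two kinds share one mechanism and differ only in
  size and prevalence: *nucleoli* (count distribution per nucleus, radii
  ~5–8 px) and *holes* (one per nucleus with probability `hole_prevalence`,
  default radius 12 px). Voids are painted at `void_level` (default 0.05
  against a chromatin level of 0.8) and placed strictly interior with an
  8-px minimum separation: dips closer than about two blur widths are not
  resolvable structures and would not be annotated as separate nucleoli by
  an expert either.
* **Markers** are piecewise-constant region means: cytoplasmic and nuclear
  levels, multiplicative enrichment over the 20-px periphery band and the
  ±5-px nuclear-envelope toroid, and an override factor inside voids. This
  reproduces the staining archetypes the measurement scheme was built for
  (chromatin-bound histone marks, pore-complex rim staining, nucleolar
  markers, inert substrates).
* **Noise** is additive Gaussian (camera read noise, default sd 0.05 on a
  0–1 scale), clipped at zero. Painted region means are exact before noise,
  which is what makes the zero-noise identities in the test-suite possible.
* **Tracks** emulate expert phase annotation of chromatin masses at a fixed
  acquisition cadence (default 3 min): a continuous exit duration D
  (anaphase onset to the first interphase morphology) and an anaphase
  segment A ≤ D are drawn per track; frames at multiples of the interval are
  labeled `ana` (t < A), `telo` (A ≤ t < D), `inter` (t ≥ D). The first
  interphase frame therefore falls at the smallest frame time ≥ D — measured
  durations are *ceilings* of continuous ones, and the quantization error is
  provably in [0, interval).

## What it does not emulate

No optics (PSF, Z sectioning, photobleaching), no shot noise, no cell
motion, division topology or tracking errors, no touching nuclei, no
texture within chromatin. Tests passing on this generator certify the
measurement arithmetic and its robustness to additive noise and irregular
shapes; they do not certify performance on crowded fields, low-SNR movies
or annotation noise.

## Fixture calibration

The packaged fixtures state the study conditions:

* `track_fixture()` draws continuous exit durations from a lognormal with
  `sdlog = 0.25`. Reported condition medians are 21 min (control), 31 min
  (H2A.Z siRNA oligo C; +10 over control), 30/39/36 min (pontin, reptin,
  double). Those reported values are medians of 3-min-quantized
  measurements, so a reported median m pins the continuous median only to
  the interval (m − 3, m]; the fixture uses the interval midpoint m − 1.5
  min. This keeps the quantized median stably equal to m instead of sitting
  on a knife edge where P(measured ≤ m) = 0.5 exactly.
* `invitro_fixture("vps72_depleted")` sets `hole_prevalence = 0.5` (half of
  the depleted-condition chromatin substrates carry a DNA-staining void)
  with 12-px holes; `"mock"` uses 0.05 — the mock rate is not a reported
  number, just a small background chosen so control populations are not
  identically zero.
* The lognormal family and `sdlog = 0.25` are generator choices (reported
  interquartile bars are wide and right-skewed; a lognormal is the simplest
  positive, right-skewed family). They were fixed once, before any
  recovery test was run, and are not tuned.
* All pixel geometry (radius 50 px, band 20 px, etc.) is a fixture: the
  source imaging has no published pixel calibration, so px defaults were
  chosen to make the 20-px band a realistic minority of nuclear area.

# Segmentation and ROIs

The chromatin channel is segmented with the classic primary-object recipe:
normalize to [0, 1] (making the result invariant to intensity scaling),
Gaussian blur (σ 2 px), global Otsu threshold, fill holes (so nucleolar
voids do not perforate the outline), 4-connected labeling, minimum-area
filter (500 px²), and border-object removal (derived ROIs would extend
off-field). Touching-object declumping and local thresholding are out of
scope. The σ 2 presmoothing shifts object boundaries by a sub-pixel fringe;
noiseless recovery is therefore essentially exact (IoU ≥ 0.995) but not
bit-exact.

Three measurement ROIs derive from each outline via the Euclidean distance
transform (iterative pixel erosion has a diagonal bias that would distort
band areas; "px" here are metric distances):

* **chromatin periphery band** — pixels inside the mask within 20 px of the
  boundary. The "shrink by 20 px" phrase is read as this *annulus*, not the
  shrunken core, because the derived statistic divides the band mean by the
  whole-nucleus mean to measure peripheral enrichment; the shrunken core
  would measure interior depletion instead. A nucleus with no interior
  beyond 20 px is flagged degenerate and its band equals the whole mask.
* **cytoplasm background ring** — outside pixels between the 5-px and 20-px
  expansions, minus any pixel within the 20-px expansion of another nucleus
  (background must not include a neighbor's signal). An empty ring (crowded
  neighborhood) flags the nucleus and disables background subtraction for
  it.
* **nuclear-envelope toroid** — pixels within 5 px of the boundary on either
  side.

# Per-cell metrics

For each nucleus × marker: `nuclear_intensity` = mean(nuclear) −
mean(ring); `ne_intensity` = mean(toroid) − mean(ring);
`radial_distribution` = `peripheral_distribution` = mean(band) /
mean(nuclear) on **raw** intensities. The ratios deliberately skip
background subtraction: the defining formulas are stated verbatim on mean
intensities, and only the two "intensity" metrics name a background term.
Consequences verified by tests: intensities are invariant to adding a
constant and equivariant under scaling; ratios are scale-invariant and tend
to 1 as a constant offset grows. The H2A.Z readout is the
background-subtracted nuclear mean of its channel — the cited original
quantitation is not recoverable, so the package uses the same convention as
every other intensity metric. Cross-sectional area is the label pixel count
times `pixel_size²`.

# Nucleoli as chromatin holes

The detector follows the manual Fiji workflow: 8-bit conversion, Gaussian
blur (1.5), Otsu auto-threshold, LUT inversion, particle analysis. Package
decisions on the recipe's silent points:

* conversion and threshold run **per nucleus** (min–max rescale of
  in-nucleus pixels), mirroring per-object display conversion; pixels
  outside the nucleus are padded with the in-nucleus median before blurring
  so the dark exterior cannot bleed in;
* the blur serves **detection only**: particle pixels and areas are
  measured on the unblurred 8-bit values inside each detected component.
  Blur would otherwise inflate sub-resolution dips past the size filter and
  erode genuine voids;
* particle filters: area ≥ 20 px² (the manual workflow's 0–∞ default would
  pass noise specks), area ≤ half the nucleus, and no contact with the
  nuclear boundary (boundary-touching dark regions are leakage, not
  nucleoli);
* an **Otsu separation guard**: the recipe run verbatim on a void-free noisy
  nucleus would happily split the noise histogram and report phantom
  particles. A nucleus is processed only when the between-class share of
  variance at the Otsu threshold is ≥ 0.8 (deep voids against bright
  chromatin score ≈ 0.99; pure Gaussian noise ≈ 0.64); otherwise it is
  flagged `weak_bimodality` with zero nucleoli.

The nucleolar fraction of a marker is sum(marker over nucleoli) /
sum(marker over nucleus): bounded in [0, 1] for nonnegative channels and
scale-invariant.

# Cell-free assay phenotypes

Holes and dextran penetration are scored visually at the bench; the package
formalizes both as relative-intensity rules with declared, tunable
constants (never hard-coded magic):

* **hole**: ≥ 1 interior connected region with blurred chromatin below 0.35
  × the in-nucleus median and area ≥ 100 px². Relative thresholds make the
  call scale-invariant.
* **dextran penetration**: interior dextran mean ≥ 0.5 × the mean in a
  5–20 px surrounding extract annulus. Monotone in the threshold and
  scale-invariant.
* population percentages are either pooled or averaged per experiment
  (mean ± SD of per-experiment percentages), the n-experiments convention
  of the assay figures.

# Mitotic-exit timing

* anaphase onset = first `ana` frame; end of telophase = first `inter`
  frame after onset. Tracks that never reach interphase are censored:
  excluded from medians, counted separately, and capping the cumulative
  curve below 100%.
* the cumulative interphase curve is exactly the ECDF of the measured
  durations scaled by the uncensored fraction (oracle-verified).
* medians use R's midpoint convention; interquartile ranges use the n+1
  percentile convention (type 6), matching the graphing software behind the
  summaries this reproduces (e.g., {18, 21, 24} → IQR 6, not 3).
* an optional width-1 majority filter smooths single-frame annotation
  flickers; it is off by default because the synthetic annotator never
  flickers.
* N/C ratio series shift the time axis to anaphase onset and drop frames
  with non-positive cytoplasmic means; import kinetics are summarized by a
  nonlinear least-squares fit of ratio(t) = 1 + (plateau − 1)(1 −
  exp(−rate·t)).

# Statistics

The comparison scheme is normality-gated: each group is tested with the
D'Agostino–Pearson K² omnibus test (implemented from the published
transformations, as no installed package provides it; verified against an
independent implementation's values frozen in the test-suite). The
parametric path (one-way ANOVA + Dunnett vs control, single-step) runs only
when **all** groups pass at p > 0.05 — the source convention does not state
how per-group results combine, and requiring all groups to pass is the
conservative reading. Otherwise, and whenever any group has n < 8 (the
normality test's validity floor), the nonparametric path runs:
Kruskal–Wallis, then Dunn's rank z tests versus the control with tie
correction and Bonferroni adjustment over the control comparisons (the
original's exact adjustment is unstated; only control comparisons are made,
so Bonferroni over that family is the transparent choice). The default
per-comparison alpha is 0.001. The two-group test is Welch's t by default
(pooled variance was not stated; unequal variances is the safer default)
with a pooled toggle.

# Sequence conservation

Percent identity/similarity are computed over a *provided* alignment
(building alignments is delegated to external aligners). Scoring counts
columns where both sequences carry residues; similarity uses the
physicochemical classes {AVLIM} {FYW} {ST} {KRH} {DE} {NQ} {C} {GP}
(swappable; identical residues always count). The denominator default is
the shorter ungapped sequence length over the region — the documented
default of the web scorer this emulates — with alignment-length and
mean-length conventions selectable, because published percentages are only
reproducible to the extent the alignment and denominator match. Domain
windows are specified as per-sequence ungapped residue spans (1-based,
inclusive, the NCBI convention) and mapped to the minimal covering column
window. The YL1-C comparison of VPS72 orthologs requires the user to supply
the aligned sequences of the cited accessions (see
`inst/extdata/README.txt`): reference protein sequences are not
redistributed with the package.

# Numerical choices and degenerate inputs

* All shrink/expand operations threshold the exact Euclidean distance
  transform; a boundary pixel has distance 1 to the exterior.
* Constant images segment to zero nuclei with a warning; empty masks are
  hard errors; zero nuclear means and empty rings flag rows rather than
  producing NaNs silently.
* All randomness flows from explicit integer seeds; identical config + seed
  gives bit-identical fields and tracks.
* Problem sizes in the test-suite (300–1000 tracks, 120–200 synthetic
  nuclei, 2000 null simulations for the type-I check) were chosen so each
  statistical assertion has comfortable Monte-Carlo margin at desk scale.

# Known limitations

Segmentation assumes non-touching, bright-on-dark nuclei. The nucleolus
detector requires genuine bimodality and will report zero nucleoli (with a
flag) on faint voids. Hole/penetration thresholds are declared stand-ins for
visual judgement and should be calibrated against a hand-scored sample
before use on real data. Published conservation percentages depend on the
exact alignment; integer-percent agreement should only be expected with a
ClustalO-style alignment of the cited accession sequences.
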