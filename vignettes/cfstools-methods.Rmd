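---
title: "Methods: models, parameters and design choices in cfstools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cfstools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfstools)
```

`cfstools` implements the computational side of a common-fragile-site (CFS)
interactome study: calling chromatin-associated interactors of a FANCD2
ChIP bait from triple-SILAC quantification, characterizing the called set
by term enrichment and a confidence-filtered network, quantifying the
imaging phenotypes (cell-cycle-resolved nuclear foci, colocalization,
micronuclei) and the cytogenetic ones (metaphase gaps/breaks, mitotic DNA
synthesis, fragile-locus breakage). This vignette records the models, the
parameters that matter, and the choices made where the design was genuinely
open.

## The SILAC channel model and the filtering cascade

Each MS experiment quantifies, per protein group, ratios between the three
SILAC channels: heavy (FANCD2 ChIP, synchronized, APH-treated), medium
(IgG ChIP, synchronized, APH-treated) and light (FANCD2 ChIP, untreated
asynchronous). H/M therefore measures bait-specific enrichment over the
antibody background under stress, and H/L measures stress-induced
recruitment. A pilot run searched together with the replicates contributes
only the H/M channel; the `experiment_design` object declares, per
experiment, which channels exist, and ratios are consumed as exported by
the search software — channel identity is declared, never inferred or
re-inverted.

The cascade has three levels:

1. **Identification filter** — at least two peptides, not a contaminant,
   not a decoy. Contaminants and decoys are recognized both by `"+"` flag
   columns and by `CON__`/`REV__` accession prefixes, tolerating dialect
   drift across MaxQuant versions.
2. **Potential interactor** — H/M ≥ `fold_threshold` (default 1.5; the
   comparison is `>=`, reading "at least") in *strictly more than half* of
   the experiments in which the ratio is quantified. Missing ratios do not
   count toward the denominator: 1 of 1 passes, 1 of 2 fails, 2 of 3
   passes. A protein with no quantified H/M ratio never passes and never
   raises an error. "Quantified" (ratio present) is used as the
   denominator; identification without quantification is not
   distinguishable in the protein-group table.
3. **Stress-induced recruit** — additionally the same majority rule on H/L,
   restricted to the experiments that carry an H/L channel. The
   aggregation rule for this tier is not independently specified anywhere;
   the majority rule is reused for symmetry with tier 2.

Calls are ranked by median log2(H/M) descending — "most enriched" needs a
statistic, and the median over quantified experiments is robust to a single
outlier ratio — with ties broken lexicographically by gene name so that
output order is deterministic. Normalized ratio columns are preferred over
raw ones when both are present, since the normalized variant corrects
channel loading.

Nesting (`stress-induced ⊆ potential ⊆ identified`), monotonicity in the
threshold, and invariance to row order are enforced by tests, and the
majority rule is checked against exhaustive enumeration of all
quantified/failing/passing patterns for up to four experiments.

## Enrichment and network

Term enrichment is the upper-tail hypergeometric test
\(P[X \ge k]\) with universe size \(N\), term size \(K\) and selection size
\(n\), with Benjamini–Hochberg correction across the tested terms. This is
a deliberate local stand-in for web-service enrichment tools (whose exact
statistic and background are not reproducible offline); the universe
defaults to all genes in the supplied annotation file, and terms are
intersected with the universe before testing (empty terms are skipped with
a log message). The implementation is validated against a draw-enumeration
oracle for all instances with \(N \le 12\) and by a type-I simulation
(random selections give uniform-or-conservative p-values).

The functional network keeps a user-supplied edge only when its confidence
score is at least `min_score` (default 0.4, the conventional
medium-confidence cut of functional-association databases) and both
endpoints are called genes; called genes without edges stay as isolated
nodes. Node attributes carry the enrichment level and the stress-induced
flag — the quantities a viewer would map to color and shape.

## QIBC: gating, foci, colocalization

Images are treated as max projections; stacks should be reduced before
analysis (the acquisition uses z-stacks, but detection operates in 2D).

**Segmentation** is a global Otsu threshold on DAPI, hole filling,
connected components and an area filter. Objects below `min_area` are kept
separately as micronucleus candidates rather than discarded: a
micronucleus is a small extra-nuclear DAPI body, and it is counted for the
nearest nucleus if its boundary distance (centroid distance minus the
nucleus equivalent-disk radius — exact for disk-shaped synthetic nuclei,
an approximation for real ones) is within `search_radius` (default 15 px)
and its area at most `max_mn_area` (default 60 px).

**Cell-cycle gating** splits cells into EdU-positive/negative with a
two-component Gaussian mixture on log EdU (a two-means split is the
fallback when the mixture degenerates), then locates the 2N and 4N DAPI
modes on the EdU-negative cells. G1/G2 are split at the geometric midpoint
of the modes; EdU-positive cells become early/mid/late S by terciles of the
DAPI span between the modes. If the EdU-negative DAPI distribution looks
unimodal (mode ratio < 1.25) gating aborts with instructions to pass
manual thresholds — silent mis-gating would poison every downstream
per-stage statistic. When scoring G1-specific structures (53BP1 nuclear
bodies), the `cyclinA_gate` option instead defines G1 as Cyclin A-negative
among EdU-negative cells, matching the standard marker-based gate.

**Focus detection** band-passes the channel with a difference of Gaussians
at `spot_sigma` (default 1.5 px, the rendered PSF scale; the second sigma
is 1.6× the first) and keeps 8-neighborhood local maxima exceeding
`rel_threshold` (default 5) times a per-nucleus robust background. The
background is the pixel-noise level estimated from horizontal first
differences of the raw channel within the nucleus
(\(\hat\sigma = \mathrm{median}|\Delta x| / (0.6745\sqrt2)\)), scaled by
the L2 norm of the band-pass kernel. A direct robust scale of the
band-pass response was rejected: in spot-dense nuclei the response of the
spots themselves contaminates any median/MAD-type estimate, while smooth
spot structure cancels in first differences. Because the threshold is
purely relative, detection is invariant to rescaling the image by a
positive constant. Maxima within \(2\sigma\) of the nucleus rim are
discarded (the band-pass responds to the nuclear boundary there), as are
maxima outside nuclei.

**Object colocalization** greedily matches A- and B-channel foci within a
cell in order of increasing centroid distance (ties: smaller channel-A
index), each focus used at most once; matched pairs at distance
≤ `overlap_radius` (default \(2\sigma\)) count as overlapping foci and
pairs in \((1, 2] \times\) `overlap_radius` as adjacent foci — the two
patterns seen for CFS factors at different processing stages. The overlap
count is symmetric in the channels.

**Pixel colocalization** uses a Costes-style block randomization: the
Pearson coefficient of the two channels over the region of interest is
compared with coefficients obtained after permuting `block_px`-sized
blocks (default 5 px ≈ the PSF footprint, so local pixel correlation is
preserved) of one channel within the region's bounding box, cropped to a
whole number of blocks; observed and randomized coefficients are evaluated
on the same pixel support. With `n_rand` permutations (default 1000) the
empirical upper-tail p-value has floor \(1/(n\_rand+1)\). A constant
channel within the region is an explicit error (undefined correlation),
and under a fixed seed the test is exactly reproducible.

## Cytogenetic statistics

Gaps and breaks are pooled into one count per spread (the scoring criteria
themselves are manual and out of scope). Summaries report mean, the
\(n-1\) sample SD and SEM. The unpaired t test defaults to the Welch
unequal-variance form — the safer default when no variance assumption is
stated — with a flag for the pooled-variance variant; two constant groups
with equal means return the conventional \(t = 0, p = 1\) with a message.
The fragile-locus contingency test is the Pearson chi-square without
continuity correction (a flag enables Yates' correction), with a message
recommending an exact test when an expected count falls below 1; equal
group proportions return \(\chi^2 = 0\) exactly. MiDAS fractions pool
breaks within a condition and attach a Wilson 95% interval, which behaves
sensibly at 0 and 1 where the Wald interval collapses.

## What the generators emulate — and what they do not

The synthetic generators exist to give every downstream stage inputs with
known ground truth, not to be photorealistic.

*Proteomics*: log-normal ratio noise (Normal on log2, default sd 0.3 —
replicate dispersion is a free parameter, not an estimate of any
particular dataset), background centred at log2 = 0, spiked interactors at
a default log2 effect of 1.5 on H/M (and on H/L for the stress-responsive
subset), per-protein-per-experiment missingness completely at random
(default 0.2), and a single-peptide fraction (default 0.25) that exercises
the identification filter. The margin fixture
(`simulate_cascade_fixture()`) instead *constrains* each row's pass/fail
pattern so that the cascade margins 894 → 665 → 226 → 45 hold exactly by
construction while ratio values and missingness patterns stay randomized —
it reproduces the published table's shape, not its biology.

*Imaging*: nuclei are non-overlapping disks (radius 18 px, consistent with
wide-field 40× sampling of HeLa nuclei) with integrated DAPI at a 2N mode
(5000 AU), a 4N mode (2× 2N) and S-phase stages interpolated at
0.25/0.5/0.75; EdU mean intensity separates 10-fold between replicating
and non-replicating cells; per-cell lognormal CVs are 5% (DAPI) and 10%
(EdU). Foci are isotropic Gaussians (σ = 1.5 px, amplitude 3 AU over
additive Gaussian pixel noise of 0.05 AU), planted uniformly at least 3σ
inside the nuclear rim, with per-stage Poisson rates that rise through S
phase and peak in late S/G2 (defaults 1/2/3/5/4, doubled under stress — the
canonical stress-response profile), and a controlled fraction of B foci
planted exactly on A foci. Two planting events closer than 2σ fuse into
one intensity maximum, so the truth records both planting events
(`n_foci_*`) and distinct resolvable spots (`n_spots_*`, single-linkage
clustering at 2σ); detector recovery is assessed against the latter.
The generator does not emulate uneven illumination, chromatin texture,
overlapping nuclei, 3D structure or autofluorescence — so passing tests
demonstrate correctness of the measurement chain on its stated model, not
robustness to every real-world artifact.

*Cytogenetics*: per-spread break counts are Poisson with per-condition
means (defaults 1/3/2/6 across control/stress × intact/depleted,
spanning the dynamic range such experiments show), EdU-positivity of each
break is Bernoulli (0.2–0.6), and fragile-locus breakage is Bernoulli per
scored locus (0.02–0.20 over 120 loci, matching the scale at which such
assays are scored).

## Numerical choices and degenerate inputs

- Ratio sentinels `"NaN"`, empty and `0` parse as missing; present ratios
  must be strictly positive.
- TIFF channels are stored as 32-bit samples after division by a fixed
  2^16 scale; the round trip is exact to ~3 × 10⁻⁵ intensity units.
- `kmeans`/mixture initializations use deterministic quantile-based
  centers, so gating has no hidden randomness.
- Blank DAPI images segment to an empty mask with a warning; overcrowded
  placement in the generator fails after bounded retries with a clear
  error.
- A single master seed fans out to per-stage seeds via a fixed affine map
  (`derive_seed`), keeping every derived seed within R's 32-bit integer
  range; identical configuration therefore reproduces identical output
  hashes, which the run report records per file.

## Problem sizes

The bundled validation suite runs at deliberately modest scale: margin
fixtures of 894 rows, recovery simulations of ~700 protein groups, imaging
fields of 100 cells at 768×768 px, 200-run randomization calibrations with
99–999 permutations each, and 2000-replicate t-test calibrations. These
sizes give standard errors small enough for the 3-s.e. checks used
throughout while keeping the full suite around a minute on one core.

## Known limitations

- The enrichment test is not a reproduction of any web service's statistic
  (EASE-style conservative variants differ); results on the same
  annotation differ accordingly.
- Boundary-distance micronucleus assignment assumes roughly convex nuclei.
- Focus detection counts distinct intensity maxima; planting events closer
  than the resolution limit are irrecoverable by construction, and real
  clustered foci will likewise be undercounted.
- Published image-derived percentages (e.g. locus-colocalization
  fractions and Pearson fold ratios over randomized images) depend on the
  original micrographs and are treated as qualitative direction checks
  only, not reproduction targets.
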