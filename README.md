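# cfstools

Quantitative analysis of common fragile site (CFS) interactome and
instability data.

Common fragile sites are chromosomal regions that break under mild
replication stress (experimentally: low-dose aphidicolin, APH) and drive
chromosomal instability in cancer. A powerful way to find the proteins that
guard them is chromatin immunoprecipitation of FANCD2 — which marks
challenged CFSs in G2/M — coupled to triple-SILAC mass spectrometry, read
out alongside quantitative image-based cytometry (QIBC) and cytogenetic
break scoring. `cfstools` packages that whole analysis chain as tested,
reusable R code for proteomics/imaging analysts, with seeded synthetic-data
generators so every stage can be validated against known ground truth.

## What it computes

**Interactome cascade.** From a MaxQuant-style `proteinGroups.txt` table
with per-experiment SILAC ratios H/M (bait + APH vs IgG + APH) and H/L
(bait, synchronized + APH vs untreated asynchronous):

1. keep protein groups with ≥ 2 peptides, non-contaminant, non-decoy;
2. *potential interactor*: ratio H/M ≥ 1.5 in **more than half** of the
   experiments in which the protein was quantified
   (`n_pass > n_quant / 2`);
3. *APH-induced recruit*: additionally ratio H/L ≥ 1.5 under the same
   majority rule over the experiments carrying an H/L channel.

**Enrichment and network.** Hypergeometric term enrichment
`P[X ≥ k]` with population `N`, successes `K`, draws `n`
(Benjamini–Hochberg across terms), and a functional network from a
user-supplied edge table keeping edges with confidence score ≥ 0.4 between
called genes.

**QIBC.** Nucleus segmentation (Otsu + size filter), DAPI/EdU cell-cycle
gating into G1 / early / mid / late S / G2 (optional Cyclin A-negative G1
gate), difference-of-Gaussians focus detection with per-nucleus robust
thresholds, micronucleus counting, object colocalization (overlap vs
adjacent foci), and a Costes-style block-randomization test
`p = (1 + #{r_rand ≥ r_obs}) / (n_rand + 1)` for pixel colocalization.

**Cytogenetics.** Per-condition gap/break summaries (mean, SD, SEM), EdU+
(MiDAS) break fractions with Wilson 95% intervals, Pearson chi-square for
fragile-locus breakage contingency tables, and Welch unpaired t tests.

## Worked example

```r
library(cfstools)

# a protein-group table constructed at the published cascade margins
fx <- simulate_cascade_fixture(seed = 2)
calls <- classify_interactors(fx$table)
cascade_summary(calls)
#>                total           identified potential_interactor
#>                  894                  665                  226
#>          aph_induced
#>                   45

head(calls[, c("gene_names", "median_log2_hm", "tier")], 3)
#>   gene_names median_log2_hm        tier
#> 1     FANCD2       3.169925 aph_induced
#> 2      FANCI       3.000000 aph_induced
#> 3   GENE0716       2.564014 potential_interactor
```

894 protein groups enter; 665 survive identification filtering; 226 clear
the 1.5-fold bait-vs-IgG majority rule; 45 are additionally enriched after
replication stress. The bait (FANCD2) and its constitutive partner (FANCI)
rank first by median log2 enrichment, as they should.

The full pipeline (generator → interactome → enrichment/network → QIBC →
break statistics) runs end-to-end on generated inputs:

```r
report <- cfs_demo(tempfile("demo"), seed = 1)
report
#> pipeline run (seed 1 ): 5 stage(s)
#>   synthetic_data       files=19
#>   interactome          total=894, identified=665, potential_interactor=226, aph_induced=45
#>   enrichment_network   terms_tested=7, terms_significant=3, nodes=226, edges=3070
#>   imaging_qibc         cells=50, foci=342
#>   cytogenetics_stats   groups=4, spreads=160, locus_groups=4
```

A thin shell wrapper lives at `inst/cli/cfs.R`
(`Rscript inst/cli/cfs.R demo`, `run --config config.yaml`,
`call-interactors --protein-groups FILE`).

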