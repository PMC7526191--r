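---
title: "Detecting selective sweeps with multi-statistic window scans"
author: "sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with multi-statistic window scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

When a beneficial allele rises rapidly in frequency in one population,
it drags its chromosomal neighbourhood with it. The local signature of
such a *selective sweep* is a coordinated set of anomalies relative to
a closely related population that did not experience the selection:
elevated allele-frequency differentiation (Fst), depressed
heterozygosity and nucleotide diversity in the selected population,
and unusually long stretches of haplotype homozygosity. `sweepscan`
scans a pair of populations — a *target* (the population suspected of
recent selection) and a *reference* — for loci where several of these
signatures coincide.

No single statistic is reliable on its own: each has a different power
profile and its own failure modes, and any outlier list contains false
positives. The pipeline therefore requires agreement: a genomic
interval becomes a *candidate selective region* only when at least two
of the four statistics flag it at the same threshold, and nearby
flagged intervals separated by less than 50 kb are merged before genes
are looked up.

## The four statistics

All four are computed in sliding windows of 50 kb with a 20 kb step
(both configurable), anchored at position 1 of each chromosome, with
truncated terminal windows kept and windows holding fewer than
`min_snps` (default 10) SNPs masked out of all downstream steps.

**Windowed Weir–Cockerham Fst.** For each biallelic site the
two-population (r = 2) moment estimator decomposes allele-frequency
variance into components *a* (among populations), *b* (among
individuals within populations) and *c* (within individuals), from
sample sizes, allele frequencies and observed heterozygote
proportions. A window's Fst is the "ratio of sums"
`sum(a) / sum(a + b + c)` over its sites — the weighted form, which is
less noisy at low per-site information than averaging per-site ratios
(a config switch provides the unweighted alternative). Negative window
values are retained, not clamped: clamping would distort the null
distribution that the Z-transformation below depends on.
Pooled-monomorphic sites and sites with an uncalled population are
excluded per site.

**Pooled heterozygosity Hp.** Within the target population only, each
window's major- and minor-allele counts are summed over sites and
combined as `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2`, which lies
in [0, 0.5]. Major/minor status is decided from the counts themselves,
so Hp does not depend on which allele is labelled reference. A swept
window has most sites near fixation, so `S_min` collapses and Hp drops
toward 0 — the sweep tail is the *lower* tail.

**π-ratio.** Nucleotide diversity per bp is
`pi = sum_j 2 j (n - j) / (n (n - 1)) / L` over window sites (j = alt
allele count, n = called alleles, L = window length). The window
contrast is `log2(pi_ref / pi_target)`: positive values mean the
target lost diversity relative to the reference. The log form is the
default because it makes the two populations' roles symmetric around 0
and stabilizes the heavy right tail of a raw ratio; a raw-ratio switch
exists. Windows with `pi_target = 0` are masked ("diversity zero" —
the contrast is unbounded there), as is a zero reference π under the
log form.

**XP-EHH.** At each site, extended haplotype homozygosity (EHH) — the
probability that two randomly drawn haplotypes are identical over the
span from the core site to a boundary — is traced marker-by-marker
outward in both directions, over *all* haplotypes of one population
(the cross-population convention does not partition by core allele).
The area under the EHH curve against physical distance (trapezoidal,
in bp) is iHH; the raw per-site score is
`ln(iHH_target) − ln(iHH_reference)`, computed in that form so that
swapping populations negates the score *exactly*, bit for bit.
Integration stops after the first marker where EHH falls below 0.05
(that terminal trapezoid is included), at 1 Mb from the core, at the
chromosome end (flagged, one-sided), or at an inter-marker gap above
200 kb (flagged). The cutoff, extension bound and gap bound are
config knobs; physical distance is used throughout since no genetic
map is assumed.

## From raw statistics to P-values

Each statistic's unmasked window values are standardized genome-wide:
`z = (x - mean) / sd` with the population (divide-by-N) standard
deviation, a choice that is visible in config and negligible at
genome scale. One-sided normal P-values follow: upper tail for ZFst,
the π-ratio and XP-EHH, lower tail for ZHp. At the conventional
threshold P < 0.005 the corresponding critical value is |z| = 2.576.

XP-EHH needs one extra step. Its per-site raw scores are first
Z-normalized genome-wide (a single bin — no frequency-binning, since
a single threshold is applied downstream), and the window statistic
is the mean normalized score over the window's sites. A mean of
unit-variance scores has standard deviation well below 1, so reading
its P-value directly from the standard normal would make XP-EHH
windows almost never significant at any fixed threshold. The window
means are therefore standardized genome-wide like the other three
statistics before the upper-tail P-value is taken. This is also why,
on real data of this kind, the P < 0.005 cut-off corresponds to a
smaller threshold on the window-average scale than 2.576.

Windows with P < 0.005 (strict inequality; a window exactly at the
threshold is not an outlier) are collected per method, overlapping or
nearby significant windows are merged, and base pairs covered by at
least `min_methods = 2` distinct methods' intervals become consensus
regions; regions separated by a gap of strictly less than 50 kb
(counting intervening bases) merge. Genes overlap a region by ≥ 1 bp
to be candidates — no promoter or flank extension, because candidate
lists here are defined by containment. No multiple-testing correction
is applied to window P-values; the design relies on the raw threshold
plus multi-method agreement.

## Site filters

Upstream of the scan, sites pass GATK-style hard filters: QD ≥ 2,
FS ≤ 60, MQRankSum ≥ −12.5, ReadPosRankSum ≥ −8, MQ ≥ 40, SOR ≤ 3,
site mean depth within [1/3, 3] × the genome-wide mean of site mean
depths, missing rate ≤ 0.1, biallelic SNPs only. Removal conditions
are strict inequalities, so a site exactly at a threshold passes. A
site missing an annotation skips that rule (the GATK convention:
rank-sum annotations are undefined without heterozygotes; failing such
sites would discard valid homozygous-alternate sites). The
MAF/missingness filter then keeps sites with pooled (both populations)
minor-allele frequency ≥ 0.05 and call rate ≥ 0.90; MAF is pooled
because the filter models a single-file preprocessing step. LD pruning
(50-variant windows, 5-variant shift, r² > 0.2 removes the later
member of a pair) is applied only before PCA, not before the scan; it
iterates to a fixed point so pruning is idempotent and its output
contains no offending pair.

## The synthetic-data generator

Because the pipeline's validation cannot rely on a resequencing
cohort, the package ships a two-population forward Wright–Fisher
simulator that plants a sweep with known ground truth. Its defaults
are the study conditions used by the test suite and the acceptance
script:

| parameter | default | meaning |
|---|---|---|
| `n_target`, `n_ref` | 15, 12 | sampled diploids per population |
| `chrom_length` | 2 Mb | one chromosome |
| `n_sites` | 2000 | segregating sites (~1 SNP/kb) |
| `ne` | 1500 | diploid size of each population |
| `split_generations` | 300 | time since the populations split |
| `n_founders` | 60 | founder haplotypes carrying standing variation |
| `recomb_rate` | 1e-7 /bp/gen | single-crossover meiosis model |
| `s` | 0.1 | additive selection (1, 1+s/2, 1+s), target only |
| `sweep_init_freq` | 0.05 | starting frequency of the sweep allele |
| `missing_rate` | 0 | genotype masking (haplotype statistics need 0) |

Site frequencies are seeded from a truncated 1/x-shaped spectrum (the
neutral site-frequency shape); the ancestral pool copies 60 founder
haplotypes, whose shared long segments provide the linkage
disequilibrium that EHH statistics require. The sweep allele sits on a
*single* founder background — a hard sweep from a low-frequency
standing variant — because selection on an allele spread over several
unrelated backgrounds barely depletes local diversity and would not
emulate the signature the scan is built to find. `ne = 1500` with a
300-generation split puts neutral differentiation at Fst ≈ T/2Ne ≈
0.1, a realistic divergence for two recently separated livestock
populations. Simulations with `s > 0` are conditioned on the sweep
allele surviving in the target population by bounded resimulation; the
retry count is recorded in the ground truth.

The recombination default is 1e-7 per bp per generation — ten times a
typical mammalian 1 cM/Mb — a deliberate rescaling: the sweep's
hitchhiking footprint is on the order of `s / (2 r ln 2Ns)`, about
0.9 Mb at 1e-8, which would cover nearly the whole simulated 2 Mb
segment and leave no neutral background for the genome-wide
Z-normalization to stand on. At 1e-7 the footprint is ~100–200 kb, so
the 2 Mb segment behaves like a sweep region embedded in a neutral
genome, which is the situation the scan addresses.

Internally the simulator records lineages instead of copying allele
matrices: each generation stores each gamete's parental haplotype
indices, its single-crossover breakpoint and its sweep-site allele
(needed for fitness weighting), and the sampled haplotypes are decoded
at the end by tracing ancestry back to the founders. This is exactly
equivalent to generation-by-generation allele copying (there is no
mutation after initialization) at a small fraction of the cost, which
is what makes 20-replicate calibration experiments practical on a
laptop.

What the generator does *not* emulate: new mutations after the split
(post-sweep diversity cannot recover, so the Hp signal is, if
anything, cleaner than in real data), gene conversion and double
crossovers, genotyping error, a realistic demographic history
(bottlenecks, migration), and the base-composition context of real
variants. Passing tests on these fixtures therefore demonstrate that
the statistics and their wiring are correct and calibrated under a
drift-plus-sweep null, not that the pipeline's error rates transfer
verbatim to any particular resequencing cohort.

`emit_fixture()` writes the simulated data as a phased VCF with
synthetic QD/FS/MQ/MQRankSum/ReadPosRankSum/SOR annotations drawn from
labelled passing/failing mixtures (a known ~5% of sites fail, so the
hard filters can be tested against an exact truth list), a population
map, a GFF3 of genes tiled along the chromosome with one gene centred
on the sweep site, and the ground truth as JSON. All emitted gene
models and annotations are synthetic.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; BED
  converts at the I/O boundary.
* Missing genotypes are a distinct `NA` state, never imputed; they are
  simply invisible to allele counts and to r² (pairwise-complete).
* `z_transform()` refuses fewer than 2 unmasked windows or a zero
  standard deviation ("degenerate score distribution") rather than
  returning NaNs.
* Region merging uses gap = intervening bases with a strict `< 50 kb`
  rule; a gap of exactly 50 kb stays split. Merging is idempotent and
  order-independent.
* PCA uses Patterson normalization with the shrinkage frequency
  `p = (1 + sum dosage) / (2 + 2 n_called)` to avoid division by zero
  at near-fixed sites; missing entries are 0 after centring; component
  signs are fixed (largest-magnitude score positive) so output is
  fully deterministic. A dataset with no polymorphic site yields the
  all-zero degenerate result rather than an error.
* Output tables are written with a fixed `%.6g` float format so that
  identical runs are byte-identical; the run manifest records the
  config, input checksums and package version, and deliberately
  contains no timestamps.

## Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` run the full pipeline on
20 neutral replicates and 20 sweep replicates at the default
conditions above (roughly 100 windows per replicate), which keeps the
whole validation within a few minutes while still giving ~2000 pooled
windows for tail calibration. The binomial tolerance for the
P < 0.005 exceedance uses the effective number of independent windows
(`n x step/size`, since 50 kb windows at a 20 kb step overlap
2.5-fold). The PCA separation check simulates 6 Mb / 6000 SNPs:
after fixed-point LD pruning a 2 Mb segment retains only ~140
quasi-independent SNPs, too few for reliable eigenvector separation
of 27 samples at Fst ≈ 0.1, while 6 Mb (~250 post-pruning) is
comfortably above that detection threshold.

## Known limitations

* **ZFst's normal tail is liberal.** Under the neutral simulations the
  windowed ratio-of-sums Fst distribution is right-skewed (skewness
  ~0.4–1.0), so the fraction of windows with upper-tail P < 0.005 is
  ~1.3–1.5% rather than 0.5% — in quantitative agreement with a
  Cornish–Fisher correction at the measured skewness. This is a
  property of Z-transforming a skewed statistic, shared by any scan
  that treats ZFst as standard normal, and is one reason the consensus
  rule demands a second supporting statistic. ZHp, the π-ratio and
  XP-EHH calibrate within binomial tolerance under the same
  simulations.
* The π-ratio's functional form (log2 of reference over target) is a
  convention of this package; only the direction (high = swept in
  target) is fixed by the method's logic. The raw-ratio switch changes
  threshold values but not the ranking of windows beyond ties.
* XP-EHH here uses physical distance and a single normalization bin;
  no genetic map, no frequency-bin normalization, no iHS/nSL variants.
* Window P-values are not corrected for multiple testing; the raw
  P < 0.005 threshold plus ≥ 2-method consensus is the error control,
  and per-method candidate lists should be read as enriched, not
  significant.

## Reproducing the pipeline on a fixture

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
sim <- simulate_pair(cfg)
files <- emit_fixture(sim, "fixture", cfg)

res <- run_scan(scan_config(
  vcf = files$vcf, popmap = files$popmap, genes = files$genes,
  outdir = "scan_out", target = "target_pop", reference = "ref_pop",
  chrom_lengths = c(chr1 = 2e6)))

res$regions          # consensus candidate regions
res$genes            # candidate genes with supporting methods
plot_scan(res$window_stats)
```
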