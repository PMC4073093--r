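---
title: "Pooled allele-frequency mapping and read-depth deletion screening on fragmented assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled allele-frequency mapping and read-depth deletion screening on fragmented assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmap)
```

## The problem

Cloning a recessive mutation in a large-genome crop such as barley rarely
enjoys the luxury of a finished reference sequence. What is available
instead is a fragmented whole-genome-shotgun assembly whose contigs are
anchored — at roughly centimorgan resolution — onto a genetic framework
map, plus an exome-capture assay that makes the gene space affordable to
resequence. `poolmap` implements bulked-segregant mapping-by-sequencing
for exactly this setting:

1. **Allele-frequency mapping.** An F2 population is raised from a cross
   of the homozygous mutant to a wildtype cultivar; DNA of phenotypic
   mutants and of wildtype segregants is pooled into two bulks and
   sequenced after exome capture. At every biallelic SNP the frequency
   of the mutant-linked (alternate) allele is `alt / (ref + alt)` per
   pool. Frequencies averaged in 1-cM bins along the genetic framework
   rise towards 1 in the mutant bulk — and drop towards 1/3 in the
   wildtype bulk — only around the causal locus.
2. **Read-depth deletion screening.** Ionising-radiation mutants often
   carry large deletions, so capture targets covered in the wildtype
   pool but (nearly) uncovered in the mutant pool directly expose
   candidate lesions.
3. **Candidate ranking.** Deletion calls are placed on the genetic map
   through their contig anchors, restricted to the interval around the
   allele-frequency peak, joined to gene models, and ordered by genetic
   distance to the peak.

A seeded generative model of the whole experiment (genotypes → bulks →
pooled counts and per-base depth) provides ground truth for every stage.

## Pool genetics

For a bulk containing $a$ homozygous-mutant, $b$ heterozygous and $c$
homozygous-wildtype plants, a marker at recombination fraction $r$ from
the causal locus is expected to show mutant-allele frequency

$$ f(r) = \frac{M(1-r) + W r}{2N}, \qquad M = 2a + b,\; W = 2N - M, $$

over the bulk's $2N$ chromosomes: a chromosome that is mutant at the
causal locus carries the linked marker allele with probability $1-r$, a
wildtype chromosome with probability $r$. Two consequences anchor the
analysis:

* a mutant bulk of 18 plants that accidentally includes one
  heterozygote has $M = 35$ of $2N = 36$ chromosomes, so the peak tops
  out at $35/36 \approx 97\%$ rather than 100% — and the same single
  heterozygote leaves $1/36$ of the chromosomes intact across a
  homozygous deletion, i.e. residual coverage $\approx 0.83\times$ at a
  30× pool mean;
* among the phenotypic wildtypes of a selfed heterozygote the expected
  heterozygote:homozygote ratio is 2:1, so the wildtype bulk converges
  on $f = 1/3$ at the causal locus and $1/2$ far from it.

Distances convert to recombination fractions with Haldane's map
function $r = (1 - e^{-2d})/2$ ($d$ in Morgans) for simulation (Poisson
crossovers, no interference — the process model the simulator uses) and
with Kosambi's for reporting distances on interference-aware maps.
Segregation ratios are tested with the Pearson goodness-of-fit
statistic on one degree of freedom *without* continuity correction;
`segregation_chi2(19, 81, 0.25)` gives $\chi^2 = 1.92$, $P = 0.166$,
whereas a Yates-corrected statistic (≈1.61) would not reproduce the
standard uncorrected convention for this design.

## Stage parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 30 reads | minimum total depth per pool at a SNP site |
| `both_high` | 0.80 | sites with frequency ≥ 80% in **both** pools are discarded (mutant-background variants, not segregating markers) |
| `bin_width` | 1 cM | half-open bins $[k, k+1)$ on the framework map |
| `min_snps` | 30 | bins holding fewer sites are dropped |
| `min_length` | 150 bp | minimum deletion-interval length (inclusive) |
| `wt_min_c1`, `wt_min_c2` | 5 reads/base | minimum wildtype mean depth |
| `mut_max` | 2 reads/base | maximum mutant mean depth under condition 2 |
| `ratio_min` | 4 | minimum wildtype/mutant depth ratio under condition 2 |
| `interval_half_width` | 15 cM | target interval around the peak when no explicit interval is given |

The deletion screen flags a contiguously covered interval (maximal run
of wildtype-covered bases, clipped to the capture targets) as

* **condition 1** — wildtype mean ≥ 5× and *no* mutant coverage
  (clean homozygous deletion), or
* **condition 2** — mutant mean ≤ 2×, wildtype mean ≥ 5× and wildtype
  ≥ 4 × mutant. Condition 2 is the contaminant-tolerant variant: it
  accepts the residual coverage a mis-phenotyped heterozygote leaves
  behind.

The ratio is deliberately oriented wildtype/mutant so it remains well
defined at zero mutant coverage; with the bounds above (mutant ≤ 2,
wildtype ≥ 5) this is the only orientation the two conditions can
jointly satisfy.

Coordinates are 1-based inclusive throughout; BED input/output is
converted at the boundary (a BED line `ctg 2106 2455` is base 2107
through 2455, length 349 bp). Interval-membership tests on the genetic
map are closed on both bounds. Ranking ties are broken by longest
deleted interval, then high-confidence genes first, then gene id, which
makes the candidate order a total order independent of input order.

## The generative model

`simulate_dataset()` draws the default scenario:

* two 150-cM chromosomes at 35 markers/cM, split into 300 contigs per
  chromosome (0.5 cM each, anchored at their midpoint); 5% of contigs
  are withheld from the anchor table to emulate unplaced contigs;
* 100 F2 individuals, each the union of two gametes from a
  heterozygous F1, generated marker-to-marker with Haldane-derived
  recombination probabilities; the causal locus sits at 97 cM on
  chromosome 1 and acts simultaneously as a SNP marker and as a
  two-exon homozygous deletion in a high-confidence gene;
* bulks of 18 (with one mis-phenotyped heterozygote) and 30 plants. A
  population draw that cannot fill the bulks (fewer than 17 phenotypic
  mutants out of 100) is redrawn, as an experiment would only proceed
  with a population that can be bulked;
* pooled SNP counts: site depth is negative binomial, NB(mean 60,
  size 20), so that essentially all marker sites clear the 30× site
  filter — the study design calls for well-covered markers, and a mean
  at the filter boundary would silently empty every bin; alternate
  reads are binomial with a 0.002 per-read allele error;
* per-base depth over capture targets: NB(mean 30, size 10) — the
  scale at which the published deletion thresholds (5×, 2×, ratio 4)
  are meaningful — times a per-target lognormal capture-efficiency
  factor (σ = 0.5, shared between pools) so the screen is not
  trivially clean, times the fraction of non-deleted chromosomes in
  the bulk within deleted exons.

What the generator does **not** model: read-level artefacts (mapping
bias, PCR duplicates, paralog collapse), linked-marker LD decay on a
physical scale, indels, multiallelic sites, and crossover interference.
Passing tests on simulated data therefore demonstrate the statistical
logic of the pipeline, not robustness to alignment pathology on real
data.

## Numerical and design choices

* **Peak statistic.** The published procedure identifies the peak
  visually; `detect_peak()` formalises it as the bin maximising
  `mean_freq_mut - mean_freq_wt`, which under the pool model is
  maximal at the causal locus and robust to the heterozygote
  contaminant. Ties break by chromosome order, then lower bin start.
  A best score below 0.2 triggers a no-convincing-peak warning —
  but note the converse does not hold: with bulks of 18/30 the
  bulk-composition sampling noise alone gives per-marker score
  standard deviation ≈ 0.1, and the genome-wide maximum |score| under
  the null typically reaches 0.2–0.35. The warning catches flat
  genomes, it does not certify linkage.
* **Mapping resolution.** With 36 + 60 bulk chromosomes, only ≈ 1–2
  crossovers are expected within ±2 cM of the causal locus, so the
  realized score surface is flat (steps of 1/36 and 1/60) over several
  centimorgan; the argmax bin regularly sits 2–8 cM from the true
  locus even at high depth, and a heterozygote crossover near the
  locus can create a 36/36 plateau that pulls the peak sideways. This
  is a property of the experimental design, not of the software — it
  is why the candidate interval for the deletion screen defaults to
  peak ± 15 cM rather than the peak bin itself.
* **Zero-coverage gaps.** Covered runs are not merged across
  zero-coverage bases (gap tolerance 0); whether to merge is a real
  degree of freedom, but not merging is the conservative choice and
  matches the per-base definition of the scan.
* **Unanchored contigs** are scanned and reported (as a separate list)
  rather than dropped: on a fragmented assembly, a causal deletion may
  well sit on an unplaced contig.
* **Problem sizes.** The shipped scenario (10,500 markers, ≈ 330
  capture targets, 100 plants) was chosen so a 20-replicate study of
  the full pipeline completes in well under a minute per stage on a
  laptop while keeping every bin above the 30-SNP rule; the statistical
  conclusions above were checked at these sizes.

## Worked example

```{r example, eval = FALSE}
simdir <- tempfile()
sim <- simulate_dataset(seed = 3, dir = simdir)

cfg <- run_config(vcf = file.path(simdir, "pools.vcf"),
                  depth = file.path(simdir, "depth.tsv"),
                  targets = file.path(simdir, "targets.bed"),
                  anchors = file.path(simdir, "anchors.tsv"),
                  genes = file.path(simdir, "genes.tsv"),
                  out_dir = tempfile())
res <- run_pipeline(cfg)
summary(res)
plot(res$bins)
```

The run reports the peak bin, the filter-boundary counts at every
stage (sites read / depth-filtered / shared-high-filtered / unanchored;
intervals found / length-filtered / called; calls in-interval /
elsewhere / unanchored) and the ranked candidate table with the
implanted cytochrome-P450 gene first.

## Known limitations

* Biallelic SNPs only; multiallelic records and indels are skipped and
  counted.
* The deletion screen detects absence of coverage, not breakpoints; a
  single large deletion appears as several deleted capture targets
  because introns are not captured.
* The segregation test and bulk-frequency model assume a single
  recessive locus with full penetrance (up to explicit mis-phenotyping).
* One anchor per contig: all sites of a contig inherit a single
  centimorgan position, so the bin resolution cannot exceed the
  anchoring resolution.
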