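---
title: "Detecting selective sweeps between two populations with sweepscan"
author: "sweepscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps between two populations with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

When one population of a species is moved into a new environment and bred
there — for example a highland-adapted livestock breed kept for many
generations at low altitude — natural and artificial selection leave
localized footprints in its genome. Two classic signals mark such a
*selective sweep*: allele frequencies at the swept loci diverge between the
two populations (high fixation index $F_{ST}$), and genetic diversity in
the selected population collapses locally (a depressed nucleotide diversity
$\theta_\pi$). `sweepscan` implements the windowed two-signal scan used in
comparative SNP-chip studies of this design, together with everything
around it: quality control, population structure, linkage-disequilibrium
(LD) decay, annotation of candidate SNPs against gene models, and
hypergeometric gene-set enrichment. A seeded simulator with planted sweeps
provides a truth set against which every stage is tested.

## The scan statistics

For each SNP $j$, let $\hat p_{1j}$ and $\hat p_{2j}$ be the
alternate-allele frequencies among called alleles in the two populations.
The per-SNP heterozygosities are

$$H_{s,j} = \tfrac12\left(2\hat p_{1j}(1-\hat p_{1j}) +
  2\hat p_{2j}(1-\hat p_{2j})\right), \qquad
H_{t,j} = 2\bar p_j(1-\bar p_j), \quad
\bar p_j = \tfrac12(\hat p_{1j}+\hat p_{2j}),$$

and a window's fixation index is the ratio of sums
$F_{ST} = (\sum_j H_{t,j} - \sum_j H_{s,j})/\sum_j H_{t,j}$, which is far
more stable at small SNP counts than averaging per-SNP ratios. Per-window
nucleotide diversity for one population is
$\theta_\pi = \sum_j \frac{n_j}{n_j-1}\,2\hat p_j(1-\hat p_j) / L$
with $n_j$ the called allele count and $L$ the window length in bp — the
unbiased expected heterozygosity summed over sites, per base pair. The
*diversity ratio* of a window is
$\theta_{\pi,\mathrm{pop1}}/\theta_{\pi,\mathrm{pop2}}$, where *pop1*, the
numerator population, must be named explicitly because the direction of a
call depends on it.

Windows slide along each chromosome with a fixed step; the defaults (5 Mb
window, 100 kb step) follow common practice for chip-density data, and the
reference simulation below scans 1 Mb windows with a 100 kb step, which
preserves the same SNPs-per-window regime on its scaled-down genome.

Selection thresholds are *empirical*: the nearest-rank 99th percentile of
window $F_{ST}$ and the 1st/99th percentiles of the diversity ratio,
computed over windows that pass the minimum SNP count (default 2). A window
is called swept in the numerator population when its $F_{ST}$ reaches the
top percentile **and** its ratio is at or below the bottom percentile
(diversity depleted in the numerator); swept in the denominator population
when $F_{ST}$ is extreme and the ratio is at or above the top percentile.
The intersection is the default because either signal alone is noisy; a
union mode exists for sensitivity analyses. Min–max scaling
$y_i = (x_i - \min x)/(\max x - \min x)$ is applied for display only — it
is strictly monotone, so thresholding scaled or raw values selects the same
windows, and the test suite asserts exactly that. Overlapping or book-ended
selected windows are merged into regions; SNPs inside regions become
candidate SNPs, and the genes they hit (or flank) become candidate genes.

### Which $F_{ST}$ estimator, and why there are two

The heterozygosity form above is the classical Nei-style $G_{ST}$. With
only two demes it does *not* estimate the drift parameter $F$ of the
generative model: under pure drift its expectation is approximately
$F/(2-F)$ (further modified by binomial sampling terms), roughly $0.020$
when $F = 0.03$ and $2\times50$ samples are genotyped. The Weir–Cockerham
variance-components estimator (`estimator = "wc"`) is the one that targets
$F$ itself, and it is the estimator used when we ask "is the scan
calibrated to the simulated drift?". The default for sweep calling remains
the heterozygosity form — thresholds are empirical quantiles, so any
monotone-equivalent estimator selects nearly the same extreme windows — but
both are exposed, and the test suite pins each to its own expectation
(the Weir–Cockerham mean to $F \pm 30\%$; the Nei-form mean to
$\big(F + (1-F)/m\big) \big/ 2\big(1 - F/2 - (1-F)/(2m)\big)$ with $m$ the
per-population allele count).

## What the simulator emulates

`simulate_genotypes()` draws, for each SNP, an ancestral frequency
$p \sim \mathrm{Uniform}(0.05, 0.95)$ and per-population frequencies from
the Balding–Nichols model
$\mathrm{Beta}\!\big(p(1-F)/F,\ (1-p)(1-F)/F\big)$, chosen because it gives
a closed-form expected differentiation ($\approx F$) to test against.
Inside a planted sweep interval the swept population uses a larger drift
parameter `f_sweep` and its frequency is pushed toward the nearer boundary
by an exponent (`q^k` below 0.5, `1-(1-q)^k` above), so that elevated
differentiation and depleted diversity co-occur at the same loci — the
joint signature the intersection rule requires. Genotypes are then
independent Binomial(2, freq) draws with Bernoulli missingness, and
everything is deterministic given the seed.

The reference study conditions (the `sim_params()` defaults) are: 50 + 50
samples; 18 autosomes of 40 Mb; SNP density $2.78\times10^{-5}$ per bp
(about 20,000 markers, i.e. ~28 SNPs per 1 Mb scan window, close to the
per-window marker count of a ~60K porcine chip scanned at full genome
scale); background drift $F = 0.03$ — the weak differentiation expected
between two recently separated populations of one breed; `f_sweep = 0.35`;
push exponent 3; 2% missing calls; three 2 Mb sweeps per population on
distinct chromosomes. The genome is deliberately sized so that the six
planted sweeps span just under 1% of the scan windows: an empirical top-1%
threshold can only ever select ~1% of windows, so a truth set much larger
than that is structurally impossible to recover — a property of the method,
not of any implementation.

What the simulator does **not** emulate: linkage disequilibrium beyond what
drift sampling induces (sites are independent given frequencies), ascertainment
bias of chip marker selection, genotyping error, related individuals, and
recombination-rate variation. Passing recovery tests on this model therefore
demonstrates that the scan statistics, thresholding and bookkeeping are
correct — not that real chip data will yield equally clean calls. LD-decay
behaviour on this simulator is pure sampling noise (mean $r^2 \approx 1/n$),
which the LD tests use as a null; block-structured fixtures exercise the
high-LD side.

## Quality control

`qc_filter()` applies the standard chip filters in a fixed order: call rate
$\ge 0.90$ per variant, autosome membership (chromosomes "1"–"18" by
default), pooled minor-allele frequency $\ge 0.05$, then the exact
Hardy–Weinberg test at $p \ge 10^{-6}$. The order is fixed so per-stage
removal counts are reproducible; the retained set is order-independent
because each criterion depends only on the variant itself. The HWE test is
the exact conditional test (sum of probabilities of heterozygote counts no
more likely than the observed one, given allele totals), computed in log
space and verified against a `choose()`-based enumeration. It is pooled
across samples by default, matching single-cohort QC tools; a
per-population option exists because pooling two diverged populations
produces spurious heterozygote deficits (the Wahlund effect), and the suite
demonstrates exactly that case.

## Population structure and LD

PCA uses Patterson scaling (center at $2\hat p$, divide by
$\sqrt{2\hat p(1-\hat p)}$) with mean imputation of missing calls and
dropping of monomorphic variants; `scaling = "unit"` and `"none"` are
available since chip studies differ in convention and the leading
eigenvalue's share of variance depends on it. Coordinates are scaled
eigenvectors, so the variance of each returned component is proportional to
its eigenvalue. The IBS distance uses pairwise-complete variants rather
than imputation — a distance between two individuals should not depend on a
third — and neighbor-joining is the Saitou–Nei agglomeration (exact on
additive distances), with NJ's occasional negative branch lengths clamped
to zero and the deficit moved to the sibling branch so local path lengths
are preserved.

Pairwise $r^2$ is the squared Pearson correlation of dosage vectors over
pairwise-complete samples (composite LD): phase is unknown on chip data, so
the haplotype-frequency (EM) variant is out of scope. Decay curves average
$r^2$ in distance bins (defaults: 500 kb maximum distance, 1 kb bins, both
configurable since "window" conventions differ between tools); empty bins
are flagged, never interpolated. The summary statistic $r^2_{0.3}$ is the
left edge of the first bin below 0.3 *whose later occupied bins all stay
below 0.3* — the persistence clause prevents a single noise dip from
declaring decay. Because small samples inflate $r^2$, the pipeline
downsamples the larger population to the smaller one's size (seeded,
without replacement) before comparing curves.

## Annotation and enrichment

Gene models come from GFF3 (`gene`/`exon` features) or BED12 (blocks as
exons), normalized to 1-based inclusive coordinates. Categories follow a
fixed precedence: inside a gene → `exonic` if in a recorded exon else
`intronic`; otherwise within 1 kb of a strand-aware gene start →
`upstream`, of a gene end → `downstream`, of both (possibly two different
genes) → `upstream/downstream`; else `intergenic`, with the nearest gene on
each side within 1 Mb recorded. Intergenic SNPs contribute their recorded
neighbors to the candidate-gene list by default — on sparse chips most
candidate SNPs are intergenic, and dropping them would empty the gene list
— with a flag to restrict to genic/flank hits. Enrichment is the upper-tail
hypergeometric test against a user-supplied GMT file, with the universe
defined as all genes in the gene-model file; raw $p < 0.05$ flags
significance (mirroring common practice in this literature) and a
Benjamini–Hochberg FDR is always reported alongside for honesty.

## Numerical and degenerate-input choices

* Nearest-rank quantiles with inclusive comparison: ties at the threshold
  are all selected, never split arbitrarily.
* Windows with fewer than `min_snps` SNPs, an undefined ratio
  (denominator diversity 0) or an undefined $F_{ST}$ (all included SNPs
  monomorphic) are excluded from threshold computation and from selection,
  and a degenerate statistic distribution (all values equal) yields an
  empty call set with a warning rather than calling everything.
* Fewer than 100 eligible windows triggers a quantile-resolution warning.
* `minmax_scale()` refuses fewer than two distinct values.
* Missing genotypes are propagated, never imputed (except PCA's explicit
  mean imputation); a sample pair with no jointly called variant is an
  error naming the pair.
* All randomness (simulation, downsampling, phenotype draws) flows from
  explicit seeds; the pipeline derives per-stage seeds from one global seed
  by fixed offsets and records MD5 checksums of every artifact in its
  manifest, so a rerun is bit-identical.

## Problem sizes used in the tests

Oracle-equivalence tests run on fixtures of up to ~1,000 SNPs and exhaustive
enumerations up to 60 alleles (HWE) or 40 genes (enrichment). Recovery and
calibration properties use the reference conditions above (10 replicate
seeds, median reported): ~20,000 SNPs per replicate, scanned in ~7,000
windows. These sizes keep a full suite run under a minute on one core while
the statistics of interest (quantile thresholds, drift calibration) are
already stable.

## Known limitations

* Sweep significance is purely empirical-quantile based; no simulation
  null or haplotype statistic (iHS, XP-EHH) is provided.
* The simulator's missingness is uniform, not batch- or cluster-structured.
* Exon assignment from GFF3 requires exons that name their gene directly
  (`Parent` or `gene_id`); transcript-nested hierarchies collapse to the
  gene span (SNPs in such genes report as intronic/exonic by the recorded
  exons only).
* Ancestry-fraction (admixture-style) estimation is out of scope; the
  exported VCF/PLINK files are suitable input for external tools.

## A worked miniature

```{r example, eval = FALSE}
sim <- simulate_genotypes(sim_params(seed = 1))
qc <- qc_filter(sim$genotypes)
w <- sweep_scan(qc$genotypes, "highland", "lowland",
  window = 1e6, step = 1e5, chrom_len = 40e6
)
calls <- call_sweeps(w)
sweep_recovery(calls, sim$truth)
```

The same flow, with structure, LD, annotation and enrichment stages and
all artifacts written to disk, is available as `run_pipeline()` from a
single YAML config, or from the shell via the `exec/sweepscan` dispatcher.
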