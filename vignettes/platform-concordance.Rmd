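---
title: "Quantifying technical reproducibility of metagenomic sequencing platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying technical reproducibility of metagenomic sequencing platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarep)
library(dplyr)
```

## The problem

A shotgun metagenomic measurement of a stool sample is a long chain of
noisy steps — library preparation, sequencing chemistry, base calling,
mapping to a gene catalog — and any platform comparison has to separate
three things: per-base read quality, the pure counting noise that even a
perfect instrument would show when the same library is sequenced twice, and
genuine platform-dependent quantification bias (classically, bias in gene
GC content). metarep implements that separation as a pipeline of small,
testable statistics over tidy tables: reads in, gene-by-sample counts in
the middle, per-gene and per-species inference out. A synthetic-data
generator with the same statistical structure stands in for sequencing
data, so every stage of the pipeline is exercised end to end at desk scale.

## Overall-accuracy read quality control

The per-base accuracy of a base called at Phred quality $Q$ is
$a = 1 - 10^{-Q/10}$. We define the *overall accuracy* (OA) of a read
fragment as the probability that the entire fragment is error-free,

$$\mathrm{OA}(i..j) = \prod_{t=i}^{j} a_t ,$$

and slide a window of `window` bases (default 10) along the read in steps
of one. The read is truncated immediately before the start of the first
window whose OA falls below `oa_threshold` (default 0.8); if the surviving
prefix is shorter than `min_length` (default 30 bp) the read is discarded.
Reads shorter than the window are judged as a single fragment of their own
length.

The product definition matters: a 100 bp read at ~Q30 throughout has a
whole-read OA near $0.999^{100} \approx 0.90$, so "average OA above 90%"
is an informative summary, whereas a mean-accuracy definition would sit at
0.999 and make any threshold vacuous. A window of ten Q17 bases has OA
$\approx 0.98^{10} \approx 0.82$, so the default threshold tolerates
mediocre stretches but cuts at genuine quality drops, wherever they sit in
the read — the point of the method is exactly that mid-read quality
collapses escape plain 3'-tail trimming. The sliding rule keeps the 5'
prefix, so retained reads are always unmodified prefixes of their inputs.
The window length and minimum retained length are not universal constants
of the method; both are exposed as parameters.

Whole-read and window OAs are accumulated in log space
(`log1p(-10^(-q/10))`), which keeps windows containing Q0 bases
well-defined ($-\infty$) and avoids underflow on long high-quality
prefixes.

## Rarefaction and relative abundance

Counts of uniquely mapped reads are equalised across samples by sampling
reads *without replacement* to a fixed depth (a multivariate
hypergeometric draw, implemented as sequential conditional hypergeometric
draws): reads are physical items being subsampled, and the draw keeps the
column total exactly at the target depth. Samples too shallow to rarefy
either raise an error or pass through unchanged (`on_short = "keep"`), the
usual concession for a shallow run.

Gene relative abundance uses the standard gene-catalog length
normalisation,

$$ a_g = \frac{c_g / L_g}{\sum_j c_j / L_j}, $$

which removes the recruitment advantage of long genes and is invariant to
global rescaling of counts.

## Read-count fluctuation intervals

Given a gene with $k$ mapped reads in replicate 1, which replicate-2
counts are consistent with counting noise alone? At catalog scale a gene's
count in an equal-depth replicate is very nearly Poisson. Three
exchangeable nulls are offered for the replicate-2 count, all as two-sided
equal-tail discrete quantile intervals with the CDF accumulated by direct
pmf summation and ties resolved toward the wider side:

* **predictive** (default): $X_2 \sim \mathrm{NB}(k, 1/2)$, the posterior
  predictive of an equal-depth Poisson replicate under a scale-invariant
  prior ($\lambda \mid k \sim \Gamma(k, 1)$, then
  $X_2 \mid \lambda \sim \mathrm{Pois}(\lambda)$). Its variance $2k$
  acknowledges that *both* replicates are noisy observations of the same
  unknown rate.
* **poisson**: $X_2 \sim \mathrm{Pois}(k)$, treating $k$ as the true rate.
* **binomial**: $X_2 \sim \mathrm{Bin}(D, k/D)$, the exact finite-depth
  thinning version of the Poisson null.

The default is a deliberate choice. For a gene with true rate $\lambda$,
the difference of two independent replicate counts has variance
$2\lambda$, while a level-0.99 interval built from the Poisson null covers
only about $2.58/\sqrt{2} \approx 1.8$ standard deviations of that
difference — for well-covered genes its twin-replicate concordance tops
out near 93–96%, never at the nominal level, no matter how good the
instrument. The predictive interval restores nominal (slightly
conservative) coverage in every count stratum, and it also reproduces the
detectability folklore of such comparisons: its lower bound first reaches
1 read at $k = 8$, so a gene seen ten times in one replicate is expected
to be seen at least once in the other. The package's tests verify both
properties by Monte Carlo against twin multinomial replicates.

`fluctuation_coverage()` evaluates, over genes with at least one
replicate-1 read, the fraction whose replicate-2 count falls inside the
interval; `detectability_threshold()` scans for the smallest count whose
interval excludes zero.

## Reproducibility statistics over HR genes

Ratio statistics need genes measured reliably in both members of a pair,
so analyses are restricted to *highly reproducible* (HR) genes: at least
`min_count` (default 10) reads in **both** members of a pair, and for
group-level tests, qualifying in at least `min_pairs` pairs (default 6,
capped at the number of pairs available).

* **Spearman correlation** of two profiles over HR genes, with average
  ranks for ties.
* **ALC**, the mean of $d_g = |\log_2(a_g / b_g)|$ over HR genes. The
  name comes from the equivalent geometric reading — the area left of the
  empirical cumulative curve of $d$ equals its mean — and $2^{\mathrm{ALC}}$
  is a mean fold change (1 = perfect agreement). The identity
  $\int_0^\infty (1 - F(x))\,dx = \bar d$ is asserted numerically in the
  tests.
* **Paired per-gene tests** between two platforms or replicate groups: a
  paired t test on the $\log_2$ relative abundances (log transformation
  because RA spans decades and per-pair ratios, not differences, are the
  stable quantity; skipped below 3 usable pairs) and an exact two-sided
  sign test on the signs of the per-pair differences (scale-free; zero
  differences dropped, the standard exact convention). Pairs in which a
  gene has a zero count contribute no difference for that gene.
  Benjamini–Hochberg adjustment is applied separately within the t family
  and the sign family — the two tests answer differently-powered questions
  and are reported as separate discovery lists — and a gene is significant
  when either family's FDR falls below `alpha`.

## GC-bias analyses

Two complementary views of platform GC bias are implemented.

**Per-species robust regression.** Within one species, gene abundances
should be roughly even and unrelated to gene GC; a platform that
over-recruits GC-rich fragments shows up as a positive slope of
$\log_{10}$ gene abundance on GC fraction, species by species.
`huber_fit()` is a one-predictor Huber M-estimator via iteratively
reweighted least squares: tuning constant $k = 1.345$ (95% Gaussian
efficiency), residual scale re-estimated each iteration as
$1.4826 \times \mathrm{MAD}$, convergence at a coefficient step below
1e-8, a 50-iteration cap that flags `converged = FALSE`, and an exact-fit
guard (near-zero MAD) that returns the least-squares solution. On data
whose scaled residuals all sit inside the Huber corner the estimate *is*
ordinary least squares, which the tests assert; a gross outlier is
down-weighted away. `species_slopes()` applies the fit per species
(log10 abundance on GC, positive-abundance genes only, at least 3 usable
genes) and summarises platforms by their median slope. When a "most
affected species" list is wanted, `top_species()` ranks species by their
number of significantly different genes, ties broken alphabetically —
the ranking rule is a package convention.

**Log-linear test on the abundance × GC × platform cube.** Species-level
observations (one abundance value per species per platform) are classified
high/low abundance and high/low GC against medians pooled over both
platforms ("high" = strictly above; the medians are recomputed from the
data at hand, not imported constants), giving a $2 \times 2 \times 2$
count cube. `loglinear_lrt()` fits the hierarchical log-linear model with
all three two-way margins but no three-way interaction, by iterative
proportional fitting (`stats::loglin`, margin tolerance tightened to
1e-10; margin preservation is re-checked on every fit), and compares it
with the saturated model:
$G^2 = 2\sum_{\text{cells}>0} O \log(O/\hat E)$ on 1 degree of freedom —
the single omitted term being exactly "the abundance–GC association
differs between platforms". IPF is used rather than a generic optimiser
because exact margin preservation is a clean, testable invariant.

## The synthetic generator

`simulate_catalog()` draws a gene catalog with log-series species sizes
(few large species, long tail), a two-component truncated-normal GC
mixture (defaults 0.40/0.60, the bimodal shape of large gut catalogs), and
log-normal lengths (median ~750 bp, floor 100 bp).
`simulate_abundances()` assigns independent log-normal masses (default
$\sigma = 2$, so most genes carry few reads at any desk-scale depth — the
characteristic skew of gut metagenomes) normalised to 1, independent of GC
by construction. `apply_platform_bias()` tilts a profile by
$a_g \propto a_g e^{\beta(\mathrm{gc}_g - 1/2)}$ — the simplest monotone
GC enrichment, and the null is exactly recovered at $\beta = 0$.
`simulate_replicate_counts()` draws multinomial replicates;
`simulate_fastq()` produces reads with a linear 5'→3' quality decay plus
Gaussian jitter and, with probability `drop_rate`, one contiguous
low-quality segment at a uniform random offset — precisely the failure
mode the OA filter exists to catch, which gives the QC tests a closed-form
expected retention rate. All generators are pure functions of their
parameters and seed (`withr::with_seed`, caller's RNG untouched).

What the generator deliberately does **not** emulate: overdispersion from
library preparation or PCR, mapping ambiguity and chimeras, species-level
GC compositional structure (gene GC is drawn independently of species), or
host contamination. Tests passing on this generator therefore demonstrate
that the statistics behave correctly under their own null and under a
known injected bias — not that any particular instrument meets a given
number on real data.

## Study scales used in the tests

The test-suite and acceptance analyses run at fixed desk scales, chosen
once as the package's study conditions: twin-replicate analyses use
100,000 genes with $\sigma = 2$ abundances at 1,000,000 reads per
replicate (8 pairs for group tests); GC-bias recovery uses 20,000 genes in
50 species at 500,000 reads with $\beta = 1$, and 20 independent seeds
for the slope-sign check; the shifted-gene power study uses 2,000 genes
with 5% of genes shifted 2-fold across 8 pairs.

One consequence of desk scale is worth spelling out. For an HR gene with
rate $\lambda$, shot noise alone gives
$E\,|\log_2(c_1/c_2)| \approx 1.149/\sqrt{\lambda}$, so with an HR floor
of 10 reads, per-pair ALC fold changes sit well above 1.0 (around 1.2
at these depths, as the acceptance analysis computes) and per-pair
HR-gene rank correlations land near 0.9 — not because the pipeline is
noisy, but because counting noise at tens of reads *is* that large.
Deeper per-gene coverage, not more genes, is what tightens those two
statistics.

## Known limitations

* The OA trimming rule (product-of-accuracies fragments, trim at first
  failing window, 5' prefix kept) is a from-first-principles
  reconstruction of the class of OA filters; field implementations vary
  in details such as an additional whole-read OA floor, which this
  package does not apply.
* The fluctuation null models counting noise only; genuine biological or
  preparation overdispersion would need a dispersion parameter the
  intra-platform setting gives no evidence for.
* The paired t test trusts approximate normality of per-pair log ratios;
  for HR genes (both counts ≥ 10) this is adequate, and the exact sign
  test is reported alongside precisely because it makes no such
  assumption.
* `read_fastq()` supports the modern 4-line FASTQ dialect only (bare `+`
  separator), with quality offsets 33 and 64 and a hard score ceiling of
  60 — scores above it almost always mean the wrong offset, so they are
  rejected rather than silently accepted.

## A worked run

```{r example, eval = FALSE}
catalog <- simulate_catalog(n_genes = 20000, n_species = 50, seed = 1)
profile <- simulate_abundances(catalog, sigma = 2, seed = 2)
counts <- simulate_replicate_table(profile, depth = 5e5, n_reps = 2,
                                   seed = 3)

glance(fluctuation_coverage(counts, "rep1", "rep2"))

hr <- hr_genes(counts, tibble::tibble(sample_a = "rep1",
                                      sample_b = "rep2"), min_pairs = 1)
ra <- relative_abundance(counts, catalog)
spearman_cor(ra, "rep1", "rep2", genes = hr$gene_id)
glance(alc(ra, "rep1", "rep2", genes = hr$gene_id))

tilted <- apply_platform_bias(profile, catalog, beta = 1)
glance(species_slopes(tilted, catalog))
```
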