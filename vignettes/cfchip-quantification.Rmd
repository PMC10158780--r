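---
title: "Quantifying gene expression from plasma H3K36me3 cfChIP-seq: models and design"
author: "cfChIPquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene expression from plasma H3K36me3 cfChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfChIPquant)
```

## The assay and the quantification problem

H3K36me3 is deposited over the bodies of actively transcribed genes,
increasingly towards the 3' end, and is depleted near the transcription
start site. Immunoprecipitating H3K36me3-bearing nucleosomes directly from
blood plasma and sequencing the captured fragments on a targeted cancer gene
panel yields, per gene, a deduplicated read count whose rate reflects the
transcriptional activity of the cells that shed the chromatin. Two
obstacles separate that count from an expression readout:

1. **Capture geometry.** Panel probes tile different numbers of bases per
   gene, and some genes are captured only near the TSS where the mark is
   absent regardless of transcription.
2. **Cellular origin.** Most plasma chromatin in anyone's blood is
   hematopoietic; the tumor contribution rides on top of that background.

`cfChIPquant` addresses the first with coverage-factor normalization and a
TSS-window exclusion rule, and the second with healthy-donor background
subtraction.

## Enrichment model

For one sample with counts $N_i$ over panel genes, enrichment of gene $i$ is

$$E_i = \frac{N_i \cdot 10^9}{T \, k_i}, \qquad T = \sum_{i \in \text{incl}} N_i,$$

where the coverage factor $k_i$ is the number of bases of gene $i$ sequenced
at depth strictly above 100 when purified genomic DNA is applied to the same
capture panel — an empirical, per-gene effective target size, treated as a
panel constant. $E_i$ is a reads-per-billion-per-captured-base rate,
comparable across genes of different footprints and across samples of
different depths (scaling all counts by a constant leaves $E$ unchanged).
The normalization implies the conservation identity
$\sum_i E_i k_i = 10^9$ over included genes, which the pipeline checks on
every sample and the test suite asserts to $10^{-6}$ relative tolerance.
The denominator couples $T$ and $k_i$ multiplicatively (an RPKM-like
reading); this is the only reading under which enrichment is comparable
across genes with different captured lengths and under which the
background-subtracted variant below is dimensionally coherent.

For patient plasma, the average healthy-donor count $\bar H_i$ is subtracted
gene-wise before normalizing:

$$E_i = \frac{(N_i - \bar H_i) \cdot 10^9}{\left(\sum_i N_i - \sum_i \bar H_i\right) k_i}.$$

Values can be negative — depletion below the hematopoietic background — and
are kept in linear space. With an all-zero background the formula reduces
exactly to the first form. The subtraction operates on raw counts, so it
presumes patient libraries larger than the healthy mean (biologically:
cancer patients carry much more cfDNA); a patient library smaller than
$\sum \bar H_i$ makes the denominator negative and the profile
uninterpretable, which the code treats as a degenerate-input error only at
exact zero and otherwise leaves to the user's judgment.

Group contrasts use
$\log_2 FC_i = \log_2(\bar E_i^a + \varepsilon) - \log_2(\bar E_i^b + \varepsilon)$
on arithmetic group means of per-sample enrichment, with negative means
clamped to zero. The pseudo-enrichment $\varepsilon$ defaults to half the
smallest positive group-mean value across both groups (fallback $10^{-3}$):
small enough not to shrink real ratios, large enough to keep zero-mean genes
finite. Exact zeros of the resulting fold change are treated as
*disagreement* in the concordance analysis — the conservative choice, since
a zero carries no directional evidence.

## TSS-window exclusion

A gene is excluded when **all** of its captured bases lie within the first
25% of the gene body walking from the TSS in the direction of transcription
(strand-aware; window length `floor(0.25 * gene_length)` bases; coordinates
0-based half-open throughout). Genes partially captured beyond the window
are kept. Whether the 25% should be measured on transcript or genomic
coordinates is not determined by the assay; the genomic span is used, since
capture geometry is defined there. Genes with $k_i = 0$ or without
assessable geometry are retained in the panel but never enter enrichment
sums; when geometry is unavailable the exclusion flag defaults to not
excluded (a precomputed flag column, e.g. from a serialized panel, is
honored).

## Expression side and tests

Expression enters as TPM and is analyzed on the $\log_2(TPM+1)$ scale. A
gene is *active* in a group when its group-mean transformed value strictly
exceeds 0.2; genes inactive in both groups are removed before testing. The
fold change is the difference of group means of the transformed replicate
values (mean of logs, not log of mean). Each retained gene is tested with a
two-sided Welch t-test — the unequal-variance form is the safer default
across cell lines with different dispersions — and Benjamini–Hochberg
adjustment runs across the retained genes only. Degenerate variance is
resolved by convention: both groups constant and equal means gives $p = 1$;
constant but unequal gives $p = 0$ with a warning (decisive but flagged).
The same convention applies to the paired MAF test below.

## Concordance statistics

* **Rank correlation** between enrichment and expression uses Spearman's
  rho with average ranks; p-values come from the exact permutation
  distribution for small untied samples and otherwise from the AS 89
  approximation (via `stats::cor.test`).
* **ROC analysis** scores each gene by enrichment against its activity
  label. AUC is computed by the Mann–Whitney identity with ties weighted
  1/2; its standard error by the Hanley–McNeil (1982) formula; the reported
  p is the two-tailed normal tail of $z = (AUC - 0.5)/SE$. The curve is the
  step function over distinct observed scores — no binormal smoothing, no
  interpolation — and "sensitivity at specificity $\geq c$" is the maximum
  sensitivity among qualifying operating points.
* **Agreement** designates an up-regulated gene as concordant when its
  relative enrichment fold change is strictly positive (strictly negative
  for the other direction). Per-direction sensitivity is the concordant
  fraction, and the $2 \times 2$ table of DE direction against enrichment
  sign is tested with Fisher's exact test in the probability-mass two-sided
  convention (sum over tables no more probable than the observed).
* **Allele fractions.** Variants seen in both the plasma input and the
  immunoprecipitated compartment are paired per (patient, variant) — one
  pair per mutation, with no per-gene collapsing, since each mutation is its
  own observation of allele-specific pulldown. Differences are reported in
  percentage points with a t-based 95% CI and a two-sided paired t-test.

## The synthetic-data generator

`simulateDataset()` emulates the study design end to end: a 197-gene panel
with 36 TSS-window-excluded genes and coverage factors uniform on
500–5000 bp; NSCLC and SCLC expression in triplicate; cell-line ChIP counts;
4 healthy donors and 8 + 4 patients in plasma; and allele-specific variant
depths. Its defaults are the package's model of the study conditions:

* **Expression.** Active genes (fraction 150/197) draw their baseline mean
  TPM from a log-normal (meanlog 1.5, sdlog 1.5 on the natural log — median
  TPM ≈ 4.5, upper tail a few hundred); inactive genes sit at
  $\log_2(TPM+1) = 0.05$. Replicates add Gaussian noise (sd 0.2) on the
  transformed scale. A fifth of active genes are differentially expressed
  with a 2-unit log2 shift, split evenly between directions.
* **Counts.** Expected counts are proportional to
  $k_i (\text{slope} \cdot TPM_i + b)$ scaled to the library size, with
  $b = 2$ TPM-equivalents per base of nonspecific pulldown — no ChIP is
  perfectly specific, and without this term active and inactive genes
  separate almost perfectly, which no real experiment shows. Counts are
  negative-binomial with size 8 (Poisson available as the
  `dispersion = Inf` limit for analytic checks). Patient and cell-line
  libraries are log-uniform on 0.5–2 million reads; healthy-donor libraries
  on 0.15–0.5 million, reflecting the much lower cfDNA content of healthy
  plasma — this asymmetry is what keeps the background-subtracted library
  size positive.
* **Plasma.** Patient expected counts mix a sparse hematopoietic profile
  (90% of genes at TPM 0.1, 10% at TPM 20–100) with the tumor profile at
  tumor fraction 0.2; healthy donors are pure background.
* **Variants.** Input-compartment alt depths are binomial at the configured
  MAF (depth 2000); the cfChIP compartment shifts the MAF on the logit
  scale by the variant's expression bias (default: nine TP53 variants,
  seven biased +0.3, two −0.2), with depths tied to the gene's plasma
  counts where available.

All randomness flows from one master seed through fixed per-stage offsets,
so identical configurations are byte-identical — the determinism contract
the pipeline tests assert. A few well-known lung-cancer gene names head the
panel (TP53, EGFR, KRAS, …) so variant fixtures can reference them; these
are never TSS-excluded, since excluding a mutation-carrying gene would make
its enrichment unassessable.

**What the generator does not emulate:** fragment-level structure (no read
positions, fragment lengths or sequence content), copy-number alterations,
capture-efficiency variation between samples, batch effects, and the
correlation structure of real transcriptomes (genes are independent given
their group means). Passing tests on synthetic data therefore demonstrate
the correctness and statistical calibration of the computations — not that
real plasma data will reach any particular sensitivity.

## Analytic ROC expectation

For parameter-recovery testing the package computes, per simulated sample,
the exact expected AUC of the enrichment classifier under the generative
model: the average over all (active, inactive) gene pairs of
$P(N_i/k_i > N_j/k_j) + \tfrac12 P(N_i/k_i = N_j/k_j)$, obtained by summing
over the negative-binomial probability mass of the inactive gene
(support truncated at the $1-10^{-9}$ quantile; supports longer than 512
points are mass-binned, a negligible approximation since the paired tail
function is smooth on that scale). `expectedRocAuc()` depends only on the
expected counts, never on the sampled ones, and the test suite checks it
against Monte-Carlo resampling and the observed AUC across seeds.

## Numerical conventions and edge cases

* Coordinates: 0-based half-open everywhere (BED convention).
* Coverage factors are integer base counts; `depth > threshold` is strict.
* Activity and DE thresholds are strict inequalities.
* Zero-variance p-value conventions as above; zero enrichment fold changes
  count as disagreement; unpaired variant records are dropped with a count.
* Ties in ROC scores are handled by average ranks (equivalently, half
  weight); ROC thresholds are the distinct observed values.
* Duplicate gene ids, duplicate (patient, variant, compartment) records,
  empty samples, degenerate background-subtracted library sizes, constant
  correlation inputs and single-class ROC labels are all hard errors.

## Problem sizes in the shipped tests

The suite exercises the default 197-gene configuration across 20 seeds for
parameter recovery (observed vs analytic AUC within ±0.05, ≥95% direction
recovery for strong-effect genes), 1000-gene null simulations for type-I
calibration of the gene-level Welch test, 1000 resampled null paired-MAF
tests, 200 random ROC instances against a brute-force pair-counting oracle,
100 random 2×2 tables against hypergeometric enumeration, and exhaustive
rank-permutation enumeration for small-sample Spearman p-values. Smaller
60-gene configurations drive the pipeline and I/O tests.

## Known limitations

* The background subtraction is a count-level operation; it does not model
  per-sample tumor fraction and can produce negative enrichment that the
  log-fold-change step must clamp. An explicit deconvolution is out of
  scope.
* Enrichment inference is panel-restricted; nothing is said about genes off
  the capture design.
* The t-tests are unmoderated; with triplicates, variance estimates are
  noisy, and shrinkage approaches would gain power at the cost of matching
  the plain-t definition of differential expression used here.
* BAM/VCF ingestion is out of scope for the core path: counts, TPM and
  variant depths arrive as TSV.
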