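---
title: "Spatial eQTL mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial eQTL mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(spaceqtl)
library(dplyr)
```

## The problem

Genome-wide association studies mark disease risk loci with SNPs, but a SNP's
nearest gene is often not the gene it regulates. Chromatin folds: a regulatory
element carrying a risk variant can sit in physical contact with a promoter
hundreds of kilobases away, or on another chromosome. `spaceqtl` implements
the two-stage strategy used in spatial regulatory genomics of autoimmune and
metabolic disease:

1. **Spatial stage.** Hi-C records contacts between restriction fragments —
   the intervals between consecutive enzyme cut sites. A SNP is assigned to
   the fragment containing it, a gene to every fragment overlapping its body.
   Any SNP-gene pair whose fragments appear together in the contact list is a
   candidate regulatory interaction: the two loci co-localize in the nucleus.
2. **eQTL stage.** Each candidate pair is tested, tissue by tissue, for an
   association between genotype dosage and the gene's expression. Pairs that
   survive multiple-testing correction are expression quantitative trait
   loci (eQTLs); the regulated genes are eGenes.

Supporting statistics ask whether the catalog SNPs are *enriched* for such
connections relative to random SNP sets (a Monte Carlo null), whether the
functionally "regulatory" subset of eQTL SNPs skews toward trans
interactions (a Fisher exact contrast), how the HLA locus' share of eQTLs
varies across tissues, how strongly the catalog SNPs are linked (pairwise
LD R²), and which pathways the eGenes over-represent (hypergeometric
gene-set enrichment).

Because the real inputs (GWAS catalogs, Hi-C libraries, population-scale
expression panels) are large and access-controlled, the package carries a
first-class synthetic-data module that generates every input with *planted*,
known-truth effects, so each stage is verifiable end to end.

## The association model

For a SNP with alternate-allele dosage $x \in \{0,1,2\}$ and a gene with
expression $y$ in one tissue, the engine fits ordinary least squares

$$ y = \alpha + \beta x + \varepsilon, \qquad \varepsilon \sim N(0,\sigma^2), $$

and reports the two-sided t test on $\hat\beta$ with $n-2$ degrees of
freedom. This is the standard additive eQTL model; covariate and
latent-factor correction (ancestry PCs, PEER-style factors) is deliberately
out of scope — the synthetic panels contain no such structure, and on real
data the package's results should be read as uncorrected associations.
Missing dosages are dropped pairwise. Tests are *gated*, not silently
estimated: a pair is skipped with a reason code when fewer than
`min_samples` complete pairs remain (default 70, the conventional donor
floor for tissue-level eQTL reporting) or when the SNP is monomorphic in
the tested samples.

The slope, its standard error and p-value are computed in closed form
(equivalent to `lm(y ~ x)`, against which the test suite checks them); the
closed form matters because the calibration suites run on the order of
$10^5$ fits.

### Multiple testing

All executed tests in a run form one Benjamini-Hochberg family by default
(`fdr_scope = "joint"`): the published criterion is a single $q < 0.05$ cut
across SNP × gene × tissue results, with no declared per-tissue family. A
`per_tissue` scope is available. `bh_fdr()` is one shared routine used by
the eQTL stage and the gene-set enrichment alike; the suite verifies it
against an independent brute-force step-up implementation on a thousand
random vectors.

### Cis versus trans

A significant association is **cis** when SNP and TSS are on the same
chromosome strictly less than 1 Mb apart, **trans** when exactly 1 Mb or
more apart or on different chromosomes. The anchor is the TSS (strand-aware;
the convention of eQTL catalogs), switchable to the nearest gene-body edge
via `distance_anchor = "gene_edge"`. The signed distance is TSS − SNP. The
1 Mb threshold, the strict inequality and the interchromosomal rule are
enumerated in the boundary tests. Because the count of eQTLs can be read at
two granularities, `eqtl_counts()` always reports both: SNP-gene-tissue
triples and distinct SNP-gene pairs.

## The spatial join

`assign_to_fragments()` uses interval overlap (GenomicRanges) under 0-based
half-open coordinates: a SNP at a fragment boundary belongs to the
downstream fragment; a gene maps to *all* fragments its body overlaps —
gene-body anchoring rather than TSS-only, since fragment-level contact data
gives no narrower rule. Unmappable positions are reported explicitly, never
dropped.

`find_spatial_pairs()` pools cell lines by default (union of contacts, with
provenance retained), qualifies a pair when any single cell line reaches
`min_count` summed contacts (default 1 — no published count threshold
exists, so the parameter is exposed rather than guessed), and sums support
across cell lines and gene fragments. A SNP located in a fragment that
itself overlaps a gene is trivially co-located with it; such pairs are
emitted with `same_fragment = TRUE` so that callers can exclude them
(`include_same_fragment = FALSE`) when only contact-evidenced pairs are
wanted.

## The synthetic-data generator

What it emulates, and with which defaults:

| quantity | default | why |
|---|---|---|
| fragment lengths | geometric around `fragment_size_mean`, truncated to tile exactly | a restriction digest's cut-site spacings are near-geometric; tiling is exact so assignment is total |
| dosages | Binomial(2, MAF), MAF ~ U(0.05, 0.5) | Hardy-Weinberg equilibrium; common variants |
| expression | gene-wise Gaussian noise, SD 1 + additive planted effects | residual-SD scale, so planted `beta` is directly in effect-size units |
| planted effect size | 2 in the demonstration study | a strong, unambiguous signal for exact-recovery testing |
| samples | 200 (demo), floor 70 per tissue | typical mid-size expression-panel tissue |
| contacts | every planted pair guaranteed; background pairs at `background_rate` per fragment pair | separates "spatial support exists" from "association exists" |

One global seed drives everything; every stage derives a deterministic
substream, so regenerating any single stage reproduces it bit for bit.

What it does **not** emulate: realistic LD blocks (only the controlled
two-locus haplotype simulator used by the LD tests), sequence content,
read-level Hi-C noise, distance-dependent contact decay, expression
covariance between genes, population structure. Passing the recovery tests
therefore demonstrates the pipeline's correctness, not its power on real
data, where confounding and LD would blur both stages.

### The demonstration study and exact recovery

The packaged demonstration study (`demo_study()`) plants five cis and two
trans effects, each in **every** tissue, with no background contacts and
same-fragment pairs excluded. Under that configuration every executed test
carries planted signal, and exact set recovery (sensitivity = specificity =
100%) is a deterministic property. This is intentional: BH at $q = 0.05$
*by design* admits an expected ~5% false discoveries among discoveries, so
any demonstration that interleaves null tests into the family fails "exact
equality" with substantial probability no matter how correct the code is.
Tissue-specificity of planted effects — absence of signal in unplanted
tissues — is validated separately, on slope magnitudes rather than on exact
BH set equality.

## The Monte Carlo enrichment null

The enrichment question: does the catalog SNP set have more significant
SNP-gene connections than equally sized random SNP sets drawn from a
control universe? `monte_carlo_enrichment()` reruns the user-supplied
spatial + eQTL counting function on `n_sets` random sets (default 100;
control draws exclude the catalog) and compares.

A naive one-sample t test of the null vector against the observed count
(i.e. $\mu_0 = \text{obs}$) is **anti-conservative**: its statistic is
$(\bar{x} - \text{obs})/(s/\sqrt{n})$, which ignores the sampling variance
of the observed count itself, so under the null it scales like
$\sqrt{n}\,Z$ and rejects almost always. The package therefore uses the
prediction-interval form of the one-sample t test,

$$ t = \frac{\text{obs} - \bar{x}_{\text{null}}}
           {s_{\text{null}}\sqrt{1 + 1/n_{\text{sets}}}},
   \qquad df = n_{\text{sets}} - 1, $$

which asks whether the observed count is consistent with the null count
distribution and is calibrated (the suite verifies ≈5% rejection under an
exchangeable catalog). A permutation p-value,
$(\#\{\text{null} \ge \text{obs}\} + 1)/(n_{\text{sets}} + 1)$, is reported
alongside as a distribution-free check. Control sets are matched on size
only; MAF- or density-matched sampling is a caller-side choice of
`snp_universe`.

## Fisher cis:trans contrast and the regulatory partition

SNPs with a functional regulatory score strictly below 0.05 are called
regulatory (`regulatory_partition()`; missing scores are non-regulatory,
flagged). The 2×2 table of cis/trans counts for regulatory versus
non-regulatory SNPs goes to a two-sided Fisher exact test
(`fisher_cis_trans()`). Two-sided Fisher conventions differ between tools;
this package follows the summed-probabilities rule — the p-value sums all
tables at fixed margins whose point probability does not exceed the
observed table's — and the suite pins that convention to an exhaustive
enumeration oracle on every table with margins ≤ 12. The operation takes
the four counts as explicit arguments precisely because published
contingency tables are often reconstructed from marginal counts, and the
reconstruction should be visible in the caller's code, not buried.

## Tissue contribution and LD

`tissue_contribution()` computes, per tissue, the percentage of significant
eQTLs whose SNP is HLA-class, then groups tissues by the ±1 SD rule (strict
inequalities; a zero-SD panel is all "mid"). Percentages are scale-free:
doubling every count changes nothing, which the suite asserts. Tissues with
zero significant eQTLs are excluded from the mean/SD with a message — a 0/0
percentage is undefined, not zero.

`pairwise_r2()` is the composite (genotypic) r²: the squared Pearson
correlation of dosage vectors. It needs no phasing and tracks haplotype r²
under HWE; under $D' = 1$ the haplotype closed form
$r^2 = pq/((1-p)(1-q))$ is recovered by simulation at $n = 10{,}000$.
Monomorphic pairs are reported as missing — an undefined correlation must
not masquerade as absence of LD. Labels: robust ($r^2 > 0.8$), weak
($r^2 \le 0.6$), intermediate otherwise.

## Worked example

```{r demo, fig.width = 6, fig.height = 4}
study <- demo_study()
cfg <- pipeline_config(include_same_fragment = FALSE, seed = 42L)
run <- run_pipeline(study, cfg)
run
glance(run$eqtl)
head(tidy_pairs <- as_tibble(run$spatial_pairs))
autoplot(run$tissue_summary)
```

## Numerical choices and degenerate inputs

* Perfect fits (zero residual) return `p = .Machine$double.xmin` rather
  than 0, keeping p-values in (0, 1].
* A zero Fisher-table margin returns p = 1 with a warning rather than an
  error mid-pipeline.
* `n_sets = 1` is refused (null variance undefined); a constant null vector
  degenerates the t-based p with a warning, while the permutation p remains
  usable.
* Fragment pairs are canonicalized (lexicographically smaller id first;
  ids are zero-padded so lexicographic equals numeric order), making
  results invariant to contact orientation and row order.
* BH q-values inherit `p.adjust`'s arithmetic exactly; the oracle tests
  use the same `(m/rank) * p` association so equality is bitwise.

## Problem sizes

The shipped suites use deliberately small panels — a two-chromosome
11 Mb genome, 60–600 SNPs, 80–260 genes, 100–200 samples, 200 calibration
replicates of 1,000 null tests, 200 Monte Carlo meta-replicates with 30
control sets each — sizes at which every statistical property under test
(tiling, exact recovery, FDR and type-I calibration, closed-form LD) is
already decisive while a full run stays in the minutes range on a laptop
core.

## Known limitations

* No covariate correction: on real expression panels the uncorrected model
  will inflate associations wherever ancestry or batch correlates with
  genotype.
* Contact lists are consumed as given: no normalization (ICE/KR), no
  distance-decay model, no TAD or loop calling.
* The Fisher contrast tests counts of pairs as if independent; eGenes
  shared between SNPs violate that mildly, as in the published analyses it
  mirrors.
* The composite r² is an unphased estimator; under strong departures from
  HWE it diverges from haplotype r² (an EM-based haplotype option would
  phase, and is not implemented).
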