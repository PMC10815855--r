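---
title: "Finding candidate upstream regulators of a focal cardiac gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding candidate upstream regulators of a focal cardiac gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sysgen)
```

# The problem

A gene of clinical interest — here the motivating case is *Rpl3l*, a
muscle-specific ribosomal protein gene implicated in dilated cardiomyopathy —
varies in expression across a recombinant inbred (RI) panel such as the BXD
family. Because every BXD strain is a fixed homozygous mosaic of the two
parental genomes (C57BL/6J, "B", and DBA/2J, "D"), that variation can be
mapped: loci whose genotype tracks the focal gene's expression are expression
QTLs (eQTLs), and genes under those loci that are themselves well expressed,
cis-regulated, polymorphic in coding sequence, correlated with the focal gene
and functionally tied to the phenotype are plausible upstream regulators.
`sysgen` implements that whole chain — correlation screens, LRS interval
mapping with permutation thresholds, 1.5-LOD support intervals, a 0–10
weighted prioritization score, over-representation analysis, and ssGSEA-based
immune-infiltration analysis for a human case/control cohort — together with
a synthetic-data module that makes every stage testable without any external
download.

# Models and conventions

## Normalization

`normalize_2z8()` rescales each gene row of a log2 expression matrix to mean
8 and standard deviation 2 (sample, $n-1$ convention): $x \mapsto 2z + 8$.
The shift keeps all intensities positive while preserving every
correlation-based and likelihood-ratio statistic downstream, both of which
are invariant to per-gene affine maps. Constant rows cannot be z-scored and
map to all 8s rather than erroring, which keeps matrices aligned.

## Correlation screens

`pearson_with_p()` computes the product-moment coefficient on
pairwise-complete observations and a two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. At $r = \pm 1$ the
p-value is clamped to the smallest positive double rather than underflowing
to zero. The screen in `correlate_focal_gene()` uses the field's two modes:
the RI-panel screen keeps partners with nominal $p < 0.05$ and mean
expression strictly above 7; the human (GTEx-style) screen adds an inclusive
$|r| \ge 0.5$ gate. No multiple-testing correction is applied by default —
the screen is deliberately nominal, as is conventional for these
transcriptome-wide shortlists — but Benjamini–Hochberg adjustment is
available behind the `adjust` flag. `fold_difference()` summarizes the
strain range as $2^{\max - \min}$ on the log2 scale.

## Interval mapping

At a biallelic homozygous marker the linkage model is a two-class Gaussian
mean model. `marker_lrs()` reports the likelihood ratio statistic

$$\mathrm{LRS} = n \,\ln\!\frac{SS_0}{SS_1},$$

with $SS_0$ the total sum of squares about the grand mean and $SS_1$ the
pooled within-genotype-class sum of squares, plus the additive effect
$\bar y_{D} - \bar y_{B}$ in log2 units. LOD $= \mathrm{LRS}/(2\ln 10)$.
Scans run at genotyped markers only: RI genotypes are homozygous and dense,
so classical interval mapping evaluated at marker positions reduces to
exactly this statistic. Monomorphic markers are flagged and skipped, not
errors; a perfect fit ($SS_1 = 0$) clamps the LRS at a configurable ceiling
(default $10^6$) with a warning; a constant trait scores 0.

Genome-wide thresholds come from `permutation_thresholds()`: the trait is
permuted across strains (seed mandatory), the genome-wide maximum LRS of
each permuted scan is recorded, and the significant and suggestive
thresholds are the empirical $1-\alpha$ quantiles (type-7, linear
interpolation) at genome-wide $\alpha = 0.05$ and $\alpha = 0.63$. The 0.63
convention is the "one false positive per genome scan" suggestive level used
by GeneNetwork and the classical linkage-threshold literature.

`support_interval()` implements the 1.5-LOD support interval with an
explicitly stated convention, because conventions differ between tools: the
interval extends to the outermost contiguous run of markers whose LOD stays
within 1.5 of the peak, then includes one additional flanking marker on each
side (the first marker failing the drop), clipped at the chromosome ends.
Ties at the peak break toward the smaller position. This is conservative:
the true locus is more likely to be inside a slightly wider interval.
`classify_cis_trans()` calls a peak cis for a gene when it lies on the
gene's chromosome within an inclusive 10 Mb window, trans otherwise.

## Candidate scoring

`score_candidates()` implements the five-parameter weighted scheme. Per
gene inside a support interval:

| parameter | criterion | score |
|---|---|---|
| heart expression | mean expression $\ge 8$ | 1 |
| coding variant | non-synonymous / frameshift / stop gain or loss | 1 |
| cis-regulation | gene's own eQTL peak within 10 Mb | 1 |
| correlation | significant ($p<0.05$) correlation with the focal gene | 2 |
| functional evidence | capped sum of source weights | up to 5 |

Disease-causal sources (RGD causal, GWAS Catalog) weigh 2; other sources
(MGI, IMPC, KEGG, Alliance, or a generic weight-1 source) weigh 1; the
functional sub-score is capped at 5, which is what makes the scheme's
ceiling exactly $1+1+1+2+5 = 10$. The cap is an inference from that stated
0–10 range — no published row exercises a source combination above 5 — and
is configurable in `scoring_weights()`. Selection keeps totals $\ge 5$
(half the ceiling) and ranks by total, then genomic order. Note the two
different expression gates are both intentional: the correlation screen uses
strictly $> 7$, the scoring gate uses $\ge 8$.

The shipped `candidate_indicators_example()` table carries the published
indicator columns of the twelve shortlisted candidates, and
`evidence_from_indicators()` + `score_candidates()` reproduce every printed
total from the indicators alone; the totals are never stored.

## Shortlisting intervals

`rank_focal_candidates()` pools candidates from the support intervals of
the two highest *trans*-acting peaks, plus any further peaks above the
suggestive threshold. Upstream-regulator hunting concerns loci distant from
the focal gene, so intervals classified cis for the focal gene are set
aside unless they are all that exists. Taking the top two trans peaks —
rather than only the genome-wide argmax chromosome — follows the motivating
study's own procedure, which scored genes from both of its trans-eQTL
intervals, and is robust to the common situation where two loci have
comparable support.

## Over-representation analysis

`ora_hypergeometric()` is the exact upper-tail hypergeometric test
$p = P(X \ge k)$ for the overlap $k$ between a deduplicated query and a
gene set within a fixed universe, with enrichment ratio $(k/n)/(K/N)$;
`enrich_collection()` applies it across a GMT collection, BH-adjusts across
tested sets, and sorts by FDR. The universe defaults, at the pipeline
level, to all genes measured on the platform — tools differ silently on
this choice, so it is explicit and overridable here.

## ssGSEA infiltration

`ssgsea_score()` is the integrated (Barbie-style) single-sample enrichment
score. Genes are ordered by expression, descending, ties averaged. With
rank weight $r_j$ (largest for the highest-expressed gene) the in-set
running sum weights member $j$ by $|r_j|^\alpha$, the out-set running sum
steps by $1/(N-K)$, and

$$ES = \sum_i \left(P^{in}(i) - P^{out}(i)\right).$$

$\alpha = 0.25$ by default, the exponent conventional for ssGSEA. The score
depends on a sample's expression only through its ranks, so any strictly
increasing transform leaves it unchanged — asserted as a property test.
Scores are reported raw, without per-sample rescaling across cell types:
the commercial infiltration tools rescale with proprietary compensation
references, which are deliberately out of scope; any GMT of cell-type
signatures is accepted instead. Differential infiltration uses a two-sided
Wilcoxon rank-sum test (exact for combined $n \le 20$ without ties, normal
approximation with tie correction otherwise); the motivating study does not
name its test, and a Welch t alternative sits behind a flag.

## Differential expression and sample exclusion

Cohort samples are first screened by `exclude_outlier_samples()`:
agglomerative clustering (Euclidean distance between sample columns,
average linkage) cut into two clusters, each cluster labelled by its
majority group, and samples disagreeing with their cluster's majority
excluded. The source study names only the distance metric; average linkage
is the robust default here and the linkage is a flag. A tied majority stops
with an error asking for manual review rather than guessing.
`differential_expression()` is a per-gene two-sided Welch t-test with BH
correction at FDR 0.05 — the study does not name its test either, and
moderated-variance models are deliberately out of scope; the Welch choice
is the simplest defensible one and is stated as such.

# The synthetic-data module

`sim_config()` + the `simulate_*()` generators emulate the study's inputs:

- **Genotypes** (`simulate_ri_genotypes()`): per strain and chromosome the
  first marker is Bernoulli(½) and each subsequent marker flips with
  probability $R = 4r/(1+6r)$ — the sib-mating RI map expansion — where $r$
  comes from the inter-marker cM distance via Haldane's map function
  $r = (1-e^{-2d/100})/2$. BXD strains are sib-mated, so this is the
  standard RI linkage model.
- **Expression** (`simulate_expression()`): planted targets follow
  $\text{baseline} + \beta\,g + \varepsilon$ with the baseline offset so
  gene means sit near 8 (the 2Z+8 scale); background genes come as one
  block with exchangeable correlation (single shared factor) plus
  independent null genes; cis targets are annotated within 10 Mb of their
  marker, trans targets on another chromosome.
- **Traits** (`simulate_traits()`): linear loadings on gene expression plus
  Gaussian noise.
- **Cohort** (`simulate_cohort()`): each sample mixes cell-type signature
  profiles by Dirichlet-distributed proportions around group means, so a
  signature gene's expression — and hence its rank — rises with its cell
  type's abundance; cases shift one cell type's mean proportion.

Defaults describe the study conditions: 40 strains; 20 chromosomes × 25
markers at 5 cM / 5 Mb spacing (500 markers — the density of an informative,
pruned RI marker map); planted eQTL effect $\beta = 1$ against residual sd
1 (log2 units); a 50-gene correlated block at $\rho = 0.6$ plus 500 null
genes; a 15 + 15 cohort with Dirichlet concentration 25 and a 0.2 case
shift in the first cell type. The planted-regulator scenario
(`simulate_focal_study()`) uses a strong cis effect ($\beta_{cis} = 2$) and
unit focal loading, calibrated so the focal gene's planted trans peak has
expected LRS near 16 — the magnitude of the suggestive trans-eQTLs in the
motivating study. All generators are bit-for-bit reproducible from the
config seed, each stage drawing from its own derived stream.

What the generators do *not* emulate: probe-level microarray artifacts,
batch effects, sex or other covariates, linkage-disequilibrium irregularity
of a real genetic map, or realistic gene-gene network structure beyond one
exchangeable block. Tests passing on these simulations therefore certify
the statistical machinery and its conventions, not robustness to the messy
features of real arrays.

# Numerical choices

- Quantiles: type 7 everywhere (R's default, linear interpolation).
- LRS ceiling $10^6$ for perfect separations; $SS_1$ clamped at 0 against
  floating-point cancellation; constant traits score 0.
- Correlation p-values clamp at the smallest positive double.
- Ranking ties: average ranks inside ssGSEA; stable ordering in candidate
  selection; peak ties break toward the smaller position.
- Constant rows normalize to all 8s; genes missing from the expression
  matrix score an automatic 0 on the expression gate with a warning.

# Limitations

- Localization power at small effects is intrinsically limited: with
  $\beta = 1$, residual sd 1 and 40 strains the planted locus explains 20%
  of variance (gene–marker $r = 0.447$), giving an expected LRS near 9 —
  below the typical genome-wide null maximum of a 500-marker scan. At that
  effect size the genome-wide argmax frequently lands on another
  chromosome; reliable single-locus localization at $n = 40$ needs
  variance shares nearer one third (LRS in the mid-teens). This is a
  property of the design, not of the implementation, and is why the
  pipeline shortlists two trans intervals rather than trusting the argmax.
- Scans fit no kinship or covariate structure (out of scope), so thresholds
  are valid under exchangeability of strains.
- The test-suite simulations use desk-scale problem sizes chosen as the
  package's own defaults: 500-marker maps, 500-permutation thresholds,
  100-replicate recovery experiments, 15 + 15 cohorts.
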