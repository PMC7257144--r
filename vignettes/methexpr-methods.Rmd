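---
title: "Methods: correlating DNA methylation with gene expression"
author: "methexpr developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlating DNA methylation with gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpr)
```

# The model

`methexpr` treats a methylome as a set of per-cytosine observations
$(m_i, t_i)$ — methylated and total read counts at position $i$ in one
of the contexts CG, CHG, CHH — and a transcriptome as a non-negative
value per gene. The quantity connecting them is the regional weighted
methylation level

$$ m(g, c, r) \;=\; \frac{\sum_{i \in r(g),\, c_i = c} m_i}
                        {\sum_{i \in r(g),\, c_i = c} t_i}, $$

the read-count-weighted mean over a gene's region (gene body, promoter,
exon union, introns, or a TE interval). All association analyses are
then bivariate statistics of $(m(g,c,r),\, e_g)$ across genes.

The weighted form is the field-standard estimator: it is the maximum
likelihood estimate of a shared binomial rate and is robust to shallow
sites. An unweighted per-site mean (`estimator = "site_mean"`) is kept
because the two differ exactly when coverage and methylation are
correlated within a region, and comparing them is a useful diagnostic.

## Assumptions

* Methylation calls are final: alignment, deduplication and
  methylation calling happen upstream. Levels are *recomputed from
  counts*; the rounded level column of CGmap files is never trusted.
* Region membership ignores strand — cytosines of both strands of a
  dyad inside an interval contribute. Records on the two strands of a
  CG dyad are deliberately not merged (their counts are independent
  observations of the same epiallele population; pooling would be a
  modelling choice we do not impose).
* Expression units are arbitrary (RPKM/FPKM/CPM alike): Pearson
  correlations are affine-invariant and Spearman/rank analyses are
  invariant under any monotone transform, so unit choice only matters
  for the reader's interpretation of fold changes.

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `promoter_bp` | 2000 | bp | the conventional plant/animal promoter window upstream of the oriented gene start |
| `min_coverage` | 4 | reads/site | below ~4 reads a site's level is mostly binomial noise; exposed because it changes every downstream number |
| `min_sites` | 1 | sites/cell | a cell with zero passing sites is missing, not 0 |
| `n_quantiles` / `n_groups` | 5 | — | non-expressed genes plus five expression quintiles |
| body windows | 30 | — | scaled metagene resolution over the gene body |
| flank windows | 15 (region), 10 (site) | — | flanks span half the body (region mode) or 2 kb (site mode) |
| `ma_window` | 200 | ranks | moving-average smoothing of the ordinal curve; the method fixes the shape, the width only the smoothness |
| `pseudocount` | 1.0 | expr units | keeps log2 fold changes finite at zero expression |
| `alpha` | 1e-6 | — | differential-gene cut-off on the density-tail p |
| `n_components` | 1 | — | mixture components of the change-cloud model |

## Decisions made where the design was open

* **Promoter anchor.** The promoter is anchored at the oriented
  gene-body start. When a GTF lacks UTRs the body start and the
  annotated TSS coincide, so the distinction is unobservable here.
* **Promoter masking.** Promoters of adjacent genes may overlap
  neighbouring gene bodies; no masking is applied — the simplest
  faithful reading of "2 kb upstream".
* **Clipping.** Promoters are clipped at chromosome position 1; no
  high-end clipping is possible because a GTF carries no chromosome
  lengths (documented rather than guessed).
* **Multiple transcripts.** One model per gene: the union of all
  transcripts' exons, gene body from the outermost exon coordinates.
  Deterministic, and consistent with a TSS-to-TES body definition.
* **Quantile ties.** Rank binning breaks ties by gene name, making
  group membership reproducible across runs; bin sizes differ by at
  most one, extra genes going to the lowest bins.
* **Metagene averaging.** Group profiles average *genes*, not
  cytosines, so long or deeply covered genes cannot dominate. Flanks in
  region mode span half of *each gene's own* body length (a per-gene
  reading of "half of the gene body"); genes shorter than the window
  count are excluded and counted.
* **Unexpressed boundary.** "Unexpressed" means expression exactly 0 —
  no epsilon.
* **Moving average.** Centred, with windows shrinking at the series
  edges; `ma_window = 1` is the identity.

# The differential-gene model

For two groups, each gene contributes a point
$(x_g, y_g) = (\log_2\frac{\bar e_A + 1}{\bar e_B + 1},\;
\bar m_A - \bar m_B)$. A bivariate Gaussian mixture with full
covariance is fitted to the cloud and a gene's p-value is the
*density tail*: the probability under the fitted model of falling in a
region of lower density than the gene's point.

* With one component (default) this has a closed form: the squared
  Mahalanobis distance of a bivariate Gaussian is $\chi^2_2$, so
  $p = \exp(-d^2/2)$ via the chi-square survival function. It is exact,
  fast, monotone in distance, and calibrated under the null (verified
  by simulation in the acceptance suite: the flagged fraction at
  $\alpha = 10^{-6}$ over $10^6$ null points stays within Monte-Carlo
  tolerance).
* With $k > 1$ components the tail has no closed form; it is estimated
  by Monte Carlo with $\ge 10^5$ seeded draws from the fitted mixture
  ($p_g$ = fraction of draws with density below the gene's). The EM fit
  is initialised by k-means++ seeding under the same seed, so results
  are reproducible.
* The mixture is fitted on the raw (unstandardised) change axes: a full
  covariance matrix absorbs scale differences between the two axes, so
  standardisation would be a no-op for $k = 1$ and an arbitrary choice
  for $k > 1$.
* A singular covariance receives a ridge of $10^{-8}$ with a warning.
* Quadrants follow the signs of $(x, y)$; a gene with either change
  exactly 0 sits on an axis, carries no quadrant and is excluded from
  quadrant counts.

Known behaviour worth stating: the single-Gaussian fit uses all points,
so a *large fraction* of strong outliers inflates the covariance and
masks itself (classical outlier masking). At the intended use — rare
differential genes among tens of thousands — the effect is negligible,
and the acceptance suite demonstrates ≥ 90% recovery of 20 planted
>6-sigma outliers among 20,000 nulls. With dense contamination a
higher `n_components` or upstream filtering is the right tool.

# Heatmap scaling

Methylation lives in [0, 1] and is shown raw. Expression is
$\log_2(x + 1)$-transformed and z-scored across the two cells of each
gene (population sd; a constant pair maps to 0, not NaN), so both data
types share a colour scale and the clustering distance is not dominated
by expression magnitude. This means the expression columns encode the
*direction and relative size* of a gene's change, not its absolute
level — a deliberate trade-off, documented because it shapes the
dendrogram.

# The synthetic-fixture generator

`synth_generate()` emulates a compact plant-like genome:

* genes laid head-to-tail with intergenic gaps, random strands, 1–4
  exons; GTF written from the exon layout;
* per-gene latent expression scores $z_e \sim N(0,1)$; promoter and
  body methylation latents are Gaussian-copula-correlated with $z_e$ at
  the planted `promoter_rho` (default −0.5) and `body_rho` (default
  +0.2);
* marginal maps are *near-linear truncated transforms*
  (methylation target $0.45 + 0.15 z$ clamped to [0.02, 0.98];
  expression $100 + 30 z_e$ clamped at 0.01), so the planted
  correlation survives as a Pearson coefficient on the emitted values.
  A copula with heavily non-linear marginals (uniform or lognormal)
  would preserve only rank correlation, which is not what the
  correlation-recovery checks measure;
* per-cytosine counts: $t_i \sim \text{Pois}(\text{coverage}) + 1$,
  $m_i \sim \text{Bin}(t_i, \text{target})$ — WGBS-like binomial
  sampling noise. CHG and CHH targets are scaled down (0.6×, 0.35×) as
  in plant methylomes; intergenic background is 0.1;
* the lowest-latent 10% of genes are set to expression exactly 0
  (the unexpressed block);
* two-group mode shifts a designated subset's methylation target and
  expression by a fixed effect, shared cytosine layout, independent
  read draws; a truth table records every latent for recovery tests.

What the generator does **not** emulate: chromatin-domain structure, TE
families, context-specific spatial autocorrelation, biological
replicate variance in expression (expression values are latent means),
or mappability artefacts. A green test therefore establishes numeric
and algorithmic correctness — estimators agree with a per-base oracle,
planted effects are recovered, symmetries hold — not biological realism
of any particular dataset.

In the correlation-recovery acceptance check the unexpressed fraction
is set to 0: genes forced to expression 0 leave the planted-correlation
population, so keeping them would measure a different (attenuated)
quantity than the planted $\rho$. The default fixture keeps 10%
unexpressed genes as the realistic stated world.

# Numerical choices and degenerate inputs

* Levels are recomputed as `meth/total`; the CGmap level column is
  written back rounded to 2 decimals (counts are canonical, so
  round-trips are exact on counts).
* Zero-coverage lines, unknown contexts (`--`), and malformed lines are
  skipped and counted; more than 1% malformed lines fails the read.
* Correlations require ≥ 3 genes; zero variance on either axis yields
  missing coefficients with a message rather than NaN.
* p-values for both Pearson and Spearman use the two-sided t
  construction with $n - 2$ df (Spearman on average ranks).
* The 2D KDE uses Scott's rule ($h_j = \hat\sigma_j n^{-1/6}$) and is
  plotting-only; no statistic consumes it.
* Chromosome-name mismatches between calls and annotation ("1" vs
  "Chr1") are never silently normalised: if fewer than half the genes
  have any cytosine coverage the run aborts with an overlap report.
* BigWig tracks are an optional cache (float32); analyses always use
  the exact count tables. A context with no sites is skipped with a
  warning because the UCSC kent library cannot encode an empty bigwig.

# Known limitations

* No DMR calling, smoothing or imputation — methylation inputs are
  consumed as called (METHimpute output is accepted as an *input*
  format only).
* No replicate-aware differential expression model: group comparison
  uses group means, by design.
* Promoter windows are fixed-width; no masking against neighbouring
  features.
* The k > 1 mixture path estimates tail probabilities no smaller than
  $1/n_{\text{draws}}$; at the default $\alpha = 10^{-6}$ use $\ge
  10^6$ draws or the closed-form single-component model.
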