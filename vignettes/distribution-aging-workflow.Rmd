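---
title: "Detecting age-related changes in single-cell expression distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting age-related changes in single-cell expression distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulk aging transcriptomics asks whether a gene's *mean* expression moves
with donor age. Single-cell data expose much more: a gene's expression over
the cells of one donor is a whole distribution, and aging can change that
distribution in ways that leave the mean untouched — cell-to-cell
variability can inflate, a positive subpopulation can appear or vanish, a
peak can shift while another stays. scAgeDist screens genes for *arbitrary
monotonic* age-related change in these distributions, without committing to
any parametric form of the change.

## The workflow

For each gene:

1. **Per-sample distributions.** The gene's expression over the cells of
   sample $s$ is treated as a statistical sample from an unknown
   distribution.
2. **Pairwise PMFs.** For every unordered pair of samples $(s, t)$, a grid
   of $k = 1000$ equally spaced points is laid over the exact range of the
   pooled values of the two samples (no tail padding). Each sample's values
   are smoothed with a Gaussian kernel (`stats::density`) and evaluated on
   this shared grid, and each curve is renormalised to sum to one, giving
   two comparable discrete probability mass functions $P$ and $Q$.
3. **Distribution distance.** The primary metric is the Hellinger distance
   $$H(P,Q) = \frac{1}{\sqrt 2}\sqrt{\sum_{m=1}^{k}\left(\sqrt{P_m}-\sqrt{Q_m}\right)^2},$$
   bounded in $[0,1]$, zero iff $P = Q$ and one iff the supports are
   disjoint. The Jensen–Shannon distance (square root of the JS divergence,
   base-2 logs so the range is also $[0,1]$) and the Kolmogorov–Smirnov
   distance (computed on the raw samples, no density step) are provided as
   interchangeable alternatives.
4. **Distance-matrix association.** The pairwise distances form a symmetric
   sample × sample matrix $D_g$. A second matrix $D_{\text{age}}$ holds
   $|{\rm age}_i - {\rm age}_j|$. The age-association score is Spearman's
   $\rho$ between the two strictly-upper triangles; a monotonic change of
   any shape in the per-sample distributions makes distribution distance
   grow with age separation, hence $\rho \to 1$, regardless of *which*
   feature of the distribution changes.
5. **Significance.** A Mantel permutation test: rows and columns of the age
   matrix are permuted together by a random sample relabelling, the
   statistic recomputed, and the one-sided p-value is
   $(1 + \#\{\rho_{\rm perm} \ge \rho_{\rm obs}\})/(1 + B)$ with $B = 1000$
   permutations by default. p-values are Benjamini–Hochberg adjusted across
   genes; genes are *classified* by the raw score ($\rho > 0.85$ by
   default), with the adjusted p reported alongside.

The pseudo-bulk comparator (`pseudobulk_correlation`) collapses each sample
to its mean and correlates means with age — exactly what a bulk assay
measures. Comparing the two on simulated data shows which signals are
mean-invisible.

### Assumptions and scope

The method assumes cells within a sample are exchangeable draws from one
distribution; it detects association, not causation or direction; it does
not distinguish expression shifts within a cell type from changes in cell
type composition (restrict to one annotated cell type with
`subset_dataset()` if that distinction matters). Expression values are used
as given — normalisation, batch correction and annotation belong upstream.
Because density estimation needs a reasonable number of expressing cells,
scans are usually restricted to highly expressed genes
(`filter_top_genes()`, default top 3000 per age category).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 1000 | grid points per pair; distances stabilise well below this, the default is conservative |
| `bandwidth_rule` | `nrd0` | Silverman's rule of thumb $0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$, the default of `stats::density`; `nrd`, `sj` available |
| `metric` | `hellinger` | `js` and `ks` rank genes concordantly (tested) |
| `n_perm` | 1000 | Mantel permutations; the attainable p floor is $1/(B+1)$ |
| `cutoff` | 0.85 | classification threshold on the raw Spearman score |
| `mantel_stat` | `spearman` | the classical Mantel test uses Pearson (`vegan`'s default); Spearman is this package's default so the permutation test addresses the same statistic that is reported as the score. Pearson is available via `mantel_stat = "pearson"`. |

Ages are in whatever unit the metadata carries (months for typical mouse
atlases, ordinal category labels in simulations); only their *ranks* and
the ranks of their differences enter the score, so the unit does not affect
$\rho$.

## The simulation generator

`sim_config()` / `simulate_dataset()` generate the validation conditions
used throughout the tests: four ordered age categories, per-gene per-sample
normal distributions where only the dispersion carries the age signal,

$$\mu_i \sim N(\mu_{\rm true} = 10,\ 0.1), \qquad
  \sigma_i \sim N(\sigma[{\rm age}_i],\ 0.1),$$

with three dispersion patterns over ages 1–4: monotonic
$(0.5, 1, 1.5, 2)$, non-monotonic $(0.5, 1, 1, 0.5)$ and stable
$(0.5, 0.5, 0.5, 0.5)$; 5% / 5% / 90% of genes respectively, 10 samples
per age, 1000 cells per sample. Because every pattern keeps $\mu$ fixed,
pseudo-bulk analysis should score near zero for all of them — the contrast
that motivates the distribution-level approach.

What this emulates: multi-donor designs with ordinal age groups, sampling
noise at both the donor level (the $\mu_i, \sigma_i$ draws) and the cell
level. What it does not: zero inflation and count discreteness of real
UMI data, multimodal mixtures (positive/negative subpopulations), unequal
cell numbers per donor, batch effects, or cell-composition change. Passing
the simulation-based tests therefore demonstrates that the statistical
machinery detects dispersion-type monotonic change at realistic noise
levels; it does not certify performance on any particular real dataset.

Generator choices: $\sigma_i$ is truncated at $0.01$ so the generator is
total (at the default parameters a draw that low is $>4.9$ sd below the
mean, so the truncation is effectively never exercised); pattern labels are
assigned in contiguous blocks for reproducible fixtures, with
`shuffle_genes = TRUE` available; simulated values may be negative, which
the pipeline accepts.

## Numerical choices

* **Grid endpoints** are the pooled minimum and maximum exactly. `k`
  counts *points*, not intervals.
* **Degenerate support.** If all pooled values of a pair coincide, both
  PMFs collapse to the same point mass and every distance is 0. If one
  sample is constant (sd and IQR both zero), the bandwidth falls back to
  $\max(10^{-8},\ 0.01 \times \text{grid range})$, which makes two
  separated constant samples nearly disjoint (distance $\approx 1$) and
  identical ones coincident (distance 0).
* **Mass clamping.** Density values below $10^{-300}$ are clamped to zero
  before normalisation; tiny negatives inside square roots are clamped in
  the metrics.
* **Cached KDE path.** A genome scan needs $O(n^2)$ KDE evaluations per
  gene on pair-specific grids. By default each sample's KDE is evaluated
  once on a 2048-point grid extended four bandwidths beyond the sample
  range and linearly interpolated onto each pair grid (zero outside the
  extension, where the kernel contributes $<4\times10^{-4}$ of its peak).
  Interpolation error is second order in the fine-grid spacing — orders of
  magnitude below the statistical error of the KDE itself — and agreement
  with the exact per-pair path (`kde = "pairwise"`) is enforced by tests at
  the $10^{-2}$ level on distances (observed differences are
  $\sim 10^{-4}$).
* **Permutation streams.** `run_workflow()` derives one seed per gene from
  the master seed, so results are reproducible, independent of gene
  subsetting order, and identical whether or not other metrics are scored
  in the same call.
* **Undefined scores.** A constant distance triangle (e.g. a gene
  identical in every sample) gives $\rho =$ `NA` and Mantel $p = 1$ by
  convention; such genes are retained and flagged, never dropped, so gene
  counts are stable.
* **Ties.** Spearman uses average ranks throughout; permutation statistics
  tied with the observed one count as exceedances (conservative).

## Design decisions

* **Per-age top-$k$ filter takes the union** of the per-age-category top
  sets: a gene highly expressed at any age stays in the analysis. The
  overall-mean variant is available (`per_age = FALSE`).
* **Mantel statistic is Spearman by default** (see the parameter table);
  both options permute the age matrix, rows and columns together, which is
  the exchangeable unit here (samples).
* **JS uses base-2 logarithms** so its range matches the other metrics;
  natural logs are one argument away.
* **KS operates on raw samples**, matching the usual definition of the
  two-sample statistic; routing it through the smoothed PMFs would only
  blur the ECDFs.
* **Classification is by raw $\rho$**, not adjusted p: with tens of
  samples the permutation floor makes p-values saturate for many genes,
  while the score still ranks them.

## Problem sizes

The test-suite and acceptance-script simulations use 200 genes (10
monotonic, 10 non-monotonic, 180 stable) at the full 4 × 10 × 1000
cells design with 200 Mantel permutations — enough genes per pattern for
stable medians and enough permutations for a p floor of $1/201$. The
KDE-oracle checks use 10,000-draw samples, where the pipeline's Hellinger
for two known normals sits within a few hundredths of the closed form
$\sqrt{1 - \sqrt{2\sigma_1\sigma_2/(\sigma_1^2+\sigma_2^2)}}$.

## Known limitations

Low-expression genes with few positive cells yield unstable densities
(filter first); the method reports association strength only — visualise
high-scoring genes with `gene_histogram()` / `gene_qq()` to see *what*
changed; with few donors the permutation p floor is coarse
($1/(B+1)$ at best, and fewer than ~5 donors makes the Mantel null nearly
degenerate); memory for the dense cells × genes matrix grows quickly
(the full 20,000-gene default configuration of `sim_config()` is several
GB — simulate gene subsets for desk-scale work).
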