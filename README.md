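# scAgeDist

Screening genes for **age-related changes in single-cell expression
distributions** — including changes a mean-based (bulk or pseudo-bulk)
analysis cannot see.

## The problem

In multi-donor single-cell RNA-seq, each gene × donor gives a whole
*distribution* of expression over cells. Aging can reshape that
distribution — inflate cell-to-cell variability, grow or shrink a positive
subpopulation, shift a peak — without moving the mean. scAgeDist scores
each gene for *arbitrary monotonic* association between donor age and the
shape of its single-cell expression distribution, for analysts working
with atlas-scale aging datasets (donors of several ages, thousands of
cells each).

## The method

Per gene, for every pair of samples the expression values are smoothed
with a Gaussian kernel (`stats::density`) on a shared 1,000-point grid
spanning the pooled range, renormalised into discrete probability mass
functions, and compared with the Hellinger distance

$$H(P,Q) = \tfrac{1}{\sqrt 2}\sqrt{\textstyle\sum_m (\sqrt{P_m}-\sqrt{Q_m})^2}\in[0,1],$$

(Jensen–Shannon and Kolmogorov–Smirnov variants included). The pairwise
distances form a sample × sample matrix, which is correlated (Spearman, on
upper triangles) against the matrix of absolute age differences: any
monotonic distributional change makes distance grow with age separation.
Significance comes from a Mantel permutation test (1,000 permutations by
default, one-sided), with Benjamini–Hochberg adjustment across genes;
genes with score $\rho >$ 0.85 are flagged. A hierarchical-normal
simulator with known age patterns of dispersion (monotonic /
non-monotonic / stable σ) validates the whole pipeline, and a pseudo-bulk
comparator shows which signals are invisible to means.

## Worked example

```r
library(scAgeDist)

sim <- simulate_dataset(sim_config(n_genes = 12, fraction_monotonic = 0.25,
                                   fraction_nonmonotonic = 0.25,
                                   samples_per_age = 5, cells_per_sample = 300,
                                   seed = 42))
sim
#> simulated_dataset: 12 genes ( 3 monotonic / 3 non-monotonic / 6 stable )
#> cell_dataset: 6000 cells x 12 genes; 20 samples
#>   donor ages: 1, 2, 3, 4

res <- run_workflow(sim$dataset, n_perm = 200, seed = 42)
head(as.data.frame(res)[order(-res$rho), c(1:4, 7)], 5)
#>     gene_id       rho    mantel_p adjusted_p    metric
#> 1 gene00001 0.8364464 0.004975124  0.0119403 hellinger
#> 3 gene00003 0.8279256 0.004975124  0.0119403 hellinger
#> 2 gene00002 0.8206254 0.004975124  0.0119403 hellinger
#> 4 gene00004 0.3177087 0.004975124  0.0119403 hellinger
#> 6 gene00006 0.2910314 0.004975124  0.0119403 hellinger

pattern_summary(sim, res)[, c("pattern", "n_genes", "rho_median", "p_median")]
#>        pattern n_genes rho_median    p_median
#> 1    monotonic       3  0.8279256 0.004975124
#> 2 nonmonotonic       3  0.2910314 0.004975124
#> 3       stable       6  0.0813784 0.136815920
```

The three genes with monotonically increasing dispersion score highest
(ρ ≈ 0.83), genes whose dispersion rises then falls score intermediate
(ρ ≈ 0.3), and genes with no age effect sit near zero; the Mantel
p-values of the affected genes sit at the permutation floor
(1/201 ≈ 0.005). With this few samples per age the scores sit a little
below the 0.85 cutoff used for genome-scale scans; the reference design
(10 samples per age) pushes monotonic genes above it.

Real datasets enter through `read_dataset()` (h5ad-dialect HDF5,
MatrixMarket, or dense TSV), typically followed by
`subset_dataset(ds, sex == "male")` and `filter_top_genes(ds, 3000)`;
inspect hits with `gene_histogram()` and `gene_qq()`. The same pipeline is
scriptable from a shell via `exec/scagedist`
(`analyze` / `simulate` / `plot`).

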