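# textileplot

Visualization of linkage disequilibrium (LD) in unphased multi-SNP genotype
data with the **textile plot** — a parallel-coordinate display whose axis
locations and scales are chosen by a constrained least-squares
*horizontalization* criterion, so that LD between adjacent loci shows up
directly as geometry: horizontal non-crossing ribbons for absolute LD
(r² = 1), crossings only between opposite homozygotes for complete LD
(|D′| = 1), and a dense weave of crossings under linkage equilibrium. The
package targets geneticists doing exploratory LD and haplotype analysis of
candidate regions (tens to a few hundred SNPs), optionally alongside a
case/control or quantitative phenotype.

## The model

Genotypes at axis *j* are encoded by an indicator matrix X<sub>j</sub> and a
contrast B<sub>j</sub>, giving individual coordinates
y<sub>j</sub> = α<sub>j</sub>1 + X<sub>j</sub>B<sub>j</sub>γ<sub>j</sub>.
All (α<sub>j</sub>, γ<sub>j</sub>) and per-individual levels h<sub>i</sub>
are chosen to minimize the weighted sum of squared deviations

&nbsp;&nbsp;Q = Σ<sub>j</sub> Σ<sub>i</sub> w<sub>ij</sub>(y<sub>ij</sub> − h<sub>i</sub>)²

subject to holding the total weighted dispersion of the plotted points equal
to the number of observed cells (0/1 weights w<sub>ij</sub> encode
missingness). Eliminating the weighted means α and h reduces this to a
symmetric generalized eigenproblem; the leading eigenvector, rescaled to the
constraint, is the global optimum. On complete data the category
coordinates are proportional to first-dimension multiple correspondence
analysis scores. Around the layout solver the package provides pairwise
D′/r² with a two-locus EM haplotype-frequency estimator, homozygous-stretch
haplotype frequency approximation √(count/N), an HWE genotype simulator
driven by haplotype pools (parameterized directly or via MAF and D′),
axis reordering by ordered single end-linkage clustering with Newick
dendrogram export, and a deterministic SVG renderer. See the methods
vignette (`vignettes/textile-plot-methods.Rmd`) for the full account.

## Worked example

The canonical two-SNP table of 10,000 HWE-simulated individuals
(`table1_counts()`) run through the whole pipeline:

```r
library(textileplot)

gm  <- geno_from_pair_counts(table1_counts())
fit <- textile_layout(gm)
tidy(fit)
#> # A tibble: 6 × 7
#>   axis  kind  category  coord count   alpha dispersion
#>   <chr> <chr> <chr>     <dbl> <dbl>   <dbl>      <dbl>
#> 1 SNP1  snp   AA        1.14   3796 -0.322       1.00
#> 2 SNP1  snp   Aa       -0.380  4739 -0.322       1.00
#> 3 SNP1  snp   aa       -1.73   1465 -0.322       1.00
#> 4 SNP2  snp   BB        1.34   2859 -0.0986      1.000
#> 5 SNP2  snp   Bb       -0.133  5036 -0.0986      1.000
#> 6 SNP2  snp   bb       -1.50   2105 -0.0986      1.000
```

The coordinates place AA vertically closer to BB than to bb (positive
covariance between the loci) and the heterozygote segment slopes upward
from Aa (−0.380) to Bb (−0.133), reflecting the allele-frequency
difference. The `count` column carries the circle areas: the smallest
circle is aa at SNP1 (1,465). Pair counts give the ribbon widths —
`pair_counts(gm, "SNP1", "SNP2")["Aa", "Bb"]` is the thickest ribbon at
2,583.

```r
glance(fit)
#> # A tibble: 1 × 6
#>       n     p lambda objective     m n_dropped
#>   <int> <int>  <dbl>     <dbl> <dbl>     <int>
#> 1 10000     2  0.634     7324. 20000         0

ld_from_genotypes(gm, "SNP1", "SNP2")
#> # A tibble: 1 × 6
#>        D Dprime     r2    pA    pB   pAB
#>    <dbl>  <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 0.0653  0.317 0.0726 0.617 0.538 0.397

crossing_count(fit, 1)
#> [1] 5902044
```

The weak r² (0.073) matches the many segment crossings. Render with
`render_svg(fit, "plot.svg")` or `autoplot(fit)`; simulate block designs
with `simulate_blocks()`; reorder clustered axes with `cluster_axes(fit)`.
A command-line interface covering the same pipeline is installed as
`exec/textileplot` (subcommands `plot`, `simulate`, `ld`, `haplo`,
`cluster`).

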