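---
title: "The textile plot: model, layout optimization and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The textile plot: model, layout optimization and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textileplot)
```

## The display and the problem it solves

A textile plot is a parallel-coordinate display of unphased multi-SNP
genotype data: one vertical axis per locus (plus optional phenotype axes),
one circle per genotype category on each axis, and ribbons connecting
genotype pairs on adjacent axes, with circle areas and ribbon widths
proportional to counts. Its point of difference from an ordinary parallel
coordinate plot is that the vertical position of every genotype category is
not fixed in advance: locations and scales of all axes are chosen jointly so
that each individual's polyline is as horizontal as the data allow. Strong
linkage disequilibrium (LD) between adjacent loci then appears as horizontal,
non-crossing ribbons, linkage equilibrium as a dense weave of crossings, and
the underlying haplotype structure as "stretches" of aligned homozygotes.

## Encoding

Genotypes at axis $j$ with $c_j$ categories are encoded by an $n \times c_j$
indicator matrix $X_j$ whose row $i$ is the unit vector of individual $i$'s
category, or all zeros when the call is missing. A $c_j \times (c_j - 1)$
contrast matrix $B_j$ — full column rank, columns linearly independent of the
ones vector — parameterizes the category coordinates as
$$v_j = \alpha_j 1 + B_j \gamma_j,$$
so individual coordinates are $y_j = \alpha_j 1 + X_j B_j \gamma_j$. The
package uses a Helmert basis by default; because only the span of
$(1, B_j)$ matters, any valid contrast yields identical coordinates (this is
enforced by a test, and `textile_layout()` accepts any `contrast_fun`).
A 0/1 weight vector $w_j$ marks observed entries; missing entries carry zero
weight everywhere.

Genotype categories are ordered by descending sample frequency of their
constituent alleles (major homozygote, heterozygote, minor homozygote for a
diallelic SNP), with lexicographic tie-breaks in the C locale so plots are
reproducible across machines. A categorical phenotype is encoded exactly
like a genotype axis. A quantitative phenotype enters as its raw data
vector, which the solver centers and scales to unit weighted variance; the
standardization stops a wide-ranged trait from absorbing the whole
dispersion budget, and makes a quantitative axis count like one
categorical scale dimension in the constraint. This scaling convention for
quantitative axes is a package decision — the display definition fixes only
the raw-vector substitution, not its normalization.

## The horizontalization criterion

With per-individual levels $h_i$, the lack of horizontalness is
$$Q = \sum_j \lVert y_j - h \rVert^2_{w_j}
    = \sum_j \sum_i w_{ij}\,(y_{ij} - h_i)^2 .$$
Minimizing $Q$ over $\alpha, \gamma, h$ is trivial ($Q = 0$ at
$\gamma = 0$), so the total dispersion is pinned:
$$\sum_j \lVert y_j - \bar y_j 1 \rVert^2_{w_j} = m,$$
where $\bar y_j$ is the weighted mean and $m$ is the effective number of
plotted points. We take $m = \sum_j \sum_i w_{ij}$, the total observed-cell
count over all axes (including monomorphic and quantitative axes);
individuals observed on fewer than two axes are dropped, with a warning,
before $m$ is computed, since a single observed point determines its own
level exactly and adds no information.

## Reduction to an eigenproblem

At any stationary point both $\alpha_j$ and $h_i$ are weighted means:
$h_i$ is the mean of individual $i$'s observed coordinates, $\alpha_j$
aligns axis $j$'s weighted mean with the levels. Eliminating them gives a
quadratic form in the stacked scale vector $\gamma$:
$$Q(\gamma) = \gamma^\top (G - T^\top S^{+} T)\,\gamma, \qquad
  \gamma^\top G \gamma = m,$$
with per-axis blocks $G_j = M_j^\top V_j M_j$, $T = [V_1 M_1 \mid \cdots
\mid V_p M_p]$, $M_j = X_j B_j$, $V_j = W_j - w_j w_j^\top / n_j$ and
$S = \sum_j V_j$. The minimizer is the leading generalized eigenvector of
$(T^\top S^{+} T, G)$, rescaled so the constraint holds exactly; the
objective equals $m(1 - \lambda)$ where $\lambda$ is the leading
eigenvalue. On complete data this is homogeneity analysis: the category
coordinates are proportional to first-dimension multiple correspondence
analysis scores, which the test suite checks against an independent
textbook CA construction. The whole solution path is validated against a
multi-start general-purpose constrained optimizer on dozens of random small
instances with and without missing values; that oracle, not the algebra
above, is the arbiter of correctness.

Numerical choices:

* $S$ is diagonal-minus-low-rank, so $S^{+}T$ is computed by the Woodbury
  identity in $O(np^2)$ without forming an $n \times n$ matrix; a dense
  eigendecomposition fallback handles the (pathological) case of a
  disconnected missingness pattern.
* Constraint blocks $G_j$ are reduced by eigendecomposition, discarding
  directions with zero dispersion (relative tolerance $10^{-10}$); this is
  how monomorphic axes participate with $\gamma_j = 0$ while still
  contributing their $\alpha_j$ term to the objective.
* The reduced symmetric eigenproblem is solved densely up to dimension
  2,000 and by power iteration (tolerance $10^{-10}$) above that.
* The eigenvector sign is fixed so that the first nonzero count-centered
  category offset — axes in lexicographic name order, categories in
  display order — is positive. We deliberately use centered offsets rather
  than $\gamma$ itself: $\gamma$'s sign and scale depend on the contrast
  basis and on input column order, so a rule stated on $\gamma$ would break
  the contrast- and order-invariance that the layout otherwise has.
* A leading-eigenvalue tie within $10^{-9}$ triggers a non-uniqueness
  warning. This happens when all axis pairs are empirically independent —
  in which case the display carries no multivariate information — and also
  for exactly duplicated axes, where any common category spacing is
  optimal.

Interpretive quantities derived from a fit: the per-axis dispersion
$d_j$ (weighted standard deviation of the axis coordinates, near zero for
axes in linkage equilibrium with everything else, and proportional to the
leading eigenvector of the dosage correlation matrix under HWE), the
crossing count between adjacent axes (computed from category pair counts,
so it costs $O(c^4)$ rather than $O(n^2)$), and the heterozygote midpoint
deviation (signed distance of the heterozygote from the homozygote
midpoint, normalized by the homozygote span; near zero under HWE, a
diagnostic for systematic HWE violation otherwise).

## LD statistics and haplotype machinery

Pairwise $D$, $D'$ and $r^2$ use the classical identities with
$D_{\max} = \min(p_A q_B, q_A p_B)$ for positive $D$ and
$\min(p_A p_B, q_A q_B)$ for negative $D$; $D = 0$ returns
$D' = r^2 = 0$ by convention and monomorphic loci are flagged missing.
From unphased genotypes, haplotype frequencies come from an EM algorithm
over diplotype expansions (initialized at linkage-equilibrium products,
converged when the largest frequency change is below $10^{-10}$, capped at
10,000 iterations). Whether published heat maps of this kind used EM or
composite estimators is generally unstated; EM is the default here and is
recorded in the `ld_matrix` metadata. Multi-allelic loci are excluded from
pairwise LD, which is defined for diallelic loci only.

Homozygous stretches approximate haplotype frequencies without phasing:
under HWE an individual is homozygous for haplotype $H$ across a locus
range with probability $\mathrm{freq}(H)^2$, so $\sqrt{\text{count}/N}$
estimates the frequency. $N$ is the number of individuals fully observed in
the range — "the total" is ambiguous in prose descriptions of this
estimator, and full observation is the choice consistent with excluding
partially missing individuals from the numerator. Stretch detection is
restricted to contiguous ranges in the current display order, matching the
visual definition. The estimator degrades as haplotype diversity rises and
LD weakens; the tests exercise it only in the low-diversity regime where it
is meaningful, against both simulation truth and the multi-locus EM
estimator.

## The synthetic-data generator

`simulate_genotypes()` draws two independent haplotypes per individual from
a haplotype pool (HWE by construction) and returns unordered genotype
pairs, retaining the drawn haplotypes for validation. Two-locus pools are
parameterized by MAF and $D'$ through the Fréchet-bound construction;
multi-locus block designs build the pool by a first-order Markov chain over
loci, hitting the requested $D'$ exactly for adjacent pairs (within-block
and at the block boundary) while long-range $D'$ decays with chain
distance — adequate for the two-block designs the generator emulates, and a
documented limitation otherwise. A single integer seed drives one RNG
stream, and the caller's RNG state is restored afterwards; the same seed
reproduces the genotype matrix bit for bit.

The generator's defaults mirror the simulation designs used throughout the
package's validation: $n = 10{,}000$ individuals, MAF 0.4, within-block
$D' = 0.8$ ($r^2 = 0.64$) and between-block $D' = 0.1$ ($r^2 = 0.01$), and
a three-haplotype pool with frequencies $(0.5, 0.3, 0.2)$ for the stretch
machinery. What these simulations do not emulate: genotyping error,
population structure or admixture, recombination/mutation history (no
coalescent), missingness mechanisms other than the caller's own masking,
and sex chromosomes. A passing suite therefore certifies the algorithmic
contracts, not robustness to those real-data features.

Smaller problem sizes appear in the test suite where the property being
checked is exact rather than statistical (tiny oracle instances with
$n \le 8$, block fits at $n$ in the hundreds or low thousands); the
$n = 10{,}000$ conditions are used wherever a quantitative tolerance
(±0.02 on $r^2$, ±0.02 on haplotype frequencies, cosine > 0.99) is
asserted.

## Axis reordering

The mean-absolute-deviation distance between axes,
$$d_{jk} = \frac{\sum_i w_{ij} w_{ik} |y_{ij} - y_{ik}|}
               {\sum_i w_{ij} w_{ik}},$$
feeds an ordered single end-linkage clustering: seed the chain with the
closest pair, then repeatedly attach the unplaced axis nearest to either
chain end. Ties are broken by original (physical) order, missing distances
are treated as infinite, and phenotype axes are excluded from clustering
and kept leftmost. The procedure returns both the new display order and a
caterpillar dendrogram; Newick branch lengths carry the raw merge
distances, since no canonical height convention exists for end-linkage
chains. Reordering never changes the solved coordinates — only adjacency,
crossing counts and rendering.

## Rendering

`render_svg()` writes deterministic SVG: one axis per column at equal
spacing, circles with area strictly proportional to genotype counts,
ribbons with stroke width strictly proportional to pair counts (scaled so
the thickest ribbon hits a configurable cap, thickest drawn first), larger
coordinates upward, phenotype axes leftmost, and an optional dendrogram
strip for clustered orders. All visual constants are exposed through
`plot_spec()`; the proportionality contracts are verified by parsing the
emitted SVG. Quantitative axes are drawn as bare axes (their encoding is
passed through the solver, but trait-specific rendering is out of scope).
`autoplot()` methods provide ggplot2 equivalents for interactive use.

## Known limitations

* Only the leading eigen-dimension is used; no biplot-style second axis.
* Pairwise LD and the haplotype machinery assume diallelic loci; the
  display itself handles multi-allelic loci and phenotypes.
* The multi-locus EM is exponential in the locus count (capped at 12 loci).
* Displays beyond a few hundred axes are impractical in a parallel
  coordinate system regardless of the solver.
* The plot never uses physical inter-SNP distances; axis spacing is
  uniform, and dispersion does not measure physical block size.
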