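---
title: "Perfect-LD block architectures: models, parameters and numerical choices"
author: "ldhier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfect-LD block architectures: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldhier)
```

## The problem

Commercial genotyping arrays deliver so many SNPs that the classical
triangular r² heatmap stops being interpretable, especially when perfectly
correlated SNPs are interspersed with unlinked ones across a large region.
`ldhier` replaces the triangle with a block view: SNPs in *perfect* linkage
disequilibrium (r² = 1) carry fully redundant information and are collapsed
into one visual unit — a cluster — and clusters are ordered by their mutual
LD. Because the output is plain BED12, the picture lands inside a genome
browser where regulatory and functional annotation is already available.

## Estimating r² from unphased genotypes

The input is a diploid genotype panel (PED plus MAP/INFO marker file, one
chromosome at a time), recoded at load time to minor-allele dosage
\(g \in \{0, 1, 2\}\). For a pair of loci the two-locus haplotype
frequencies \(p_{AB}, p_{Ab}, p_{aB}, p_{ab}\) are estimated by
expectation–maximization over the 3×3 genotype table: all classes except
the double heterozygote resolve into known haplotype counts; the double
heterozygote is split between the \(AB/ab\) and \(Ab/aB\) phases in
proportion to the current haplotype-product weights. Then

\[
D = p_{AB} - p_A p_B, \qquad
r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)} .
\]

Assumptions and conventions:

* **Hardy–Weinberg pairing of haplotypes** within each pair of loci (the
  standard EM likelihood). Panels are treated as unrelated individuals;
  pedigree columns are parsed and discarded, and no trio-aware phasing is
  attempted.
* **Missing data** are handled by pairwise-complete deletion, each pair
  keeping its own effective sample size. No imputation.
* **Determinism**: the EM starts at linkage equilibrium (products of sample
  allele frequencies) and has no random element, so every result is
  bit-for-bit reproducible. Defaults: `tol = 1e-10`, `max_iter = 1000`;
  hitting the cap sets a `converged` flag rather than failing.
* A loader for externally precomputed pairwise r² tables
  (`read_ld_table()`, columns `id1 id2 r2`) reproduces the workflow in
  which LD comes from another program and only block building happens here.

### Numerical choices worth knowing

* **Boundary snap.** When one locus duplicates another, the maximum of the
  likelihood sits on the boundary of the frequency simplex
  (\(p_{Ab} = p_{aB} = 0\)) and EM approaches it quadratically but never
  lands exactly. After convergence, if the solution is within `1e-8` of a
  Fréchet endpoint of \(p_{AB}\) and moving to the endpoint does not lower
  the observed-data likelihood, the endpoint is returned exactly. Interior
  stationary points are untouched: a table consisting only of double
  heterozygotes stays at the symmetric fixed point (all frequencies 0.25,
  r² = 0), which is the deterministic answer for a locus pair that carries
  no phase information.
* **Exact r² at the boundary.** \(D\) is computed as
  \(p_{AB}p_{ab} - p_{Ab}p_{aB}\) and the denominator as
  \((p_A q_A)(p_B q_B)\) with that exact multiplication grouping, so a
  perfect-LD solution yields exactly 1.0 in floating point rather than
  \(1 - 10^{-16}\).
* r² is clamped to \([0, 1]\) against rounding overshoot; pairs whose LD is
  undefined (a locus monomorphic in the pairwise-complete subsample) are
  *masked*, never silently zero.

## Clusters and their hierarchy

An edge joins two markers when their r² is defined and at least
\(1 - \varepsilon\); clusters are the connected components of size ≥ 2.
With complete data perfect correlation is transitive, so components are
automatically cliques; a verification pass warns about any non-clique
component, which can only arise from missing-data artifacts or sparse
external r² tables. Components rather than maximal cliques keep the
procedure \(O(E)\) and deterministic. Each cluster is named after its
first (leftmost) SNP.

* `epsilon` (default `1e-6`) absorbs floating-point noise in EM-derived
  r². With exact duplicate genotype columns even `epsilon = 0` clusters
  correctly, thanks to the boundary handling above.

Blocks are ordered by average-linkage (UPGMA) agglomeration of the distance
\(1 - r^2\). Two open points the method description leaves unstated were
resolved as follows:

* **Block-to-block distance.** The distance between two multi-SNP blocks is
  \(1 - \operatorname{mean}(r^2)\) over all defined cross-pairs. Under
  exact perfect LD every cross-pair is equal, so the mean coincides with
  any representative pair; under an ε-tolerant block definition the mean is
  the more robust collapse. A block pair with *no* defined cross-pair
  (possible only through sparse precomputed tables) is assigned the maximal
  distance 1 with a warning rather than being dropped, since removing a
  single pair from an agglomeration is not well defined.
* **Tie-breaking and leaf order.** Merges tie-break on the smallest
  (row, column) position pair, making the tree platform-independent. The
  leaf order traverses each internal node's child with the smaller minimum
  leaf index first; any nesting-consistent order would be acceptable, this
  one is deterministic. Merge heights are non-decreasing (average linkage
  admits no inversions), and the implementation is cross-checked in the
  test suite against both a naive recompute-everything oracle and
  `stats::hclust(method = "average")`.

## Architectures

* **Gene-centered**: clusters are built on the whole MAF-filtered panel and
  kept when at least one member falls inside
  \([tx_\mathrm{start} - \mathrm{flank}, tx_\mathrm{end} + \mathrm{flank}]\)
  (inclusive, 1-based); retained clusters are displayed *in full*, including
  members outside the window. Genes resolve by Entrez ID, then RefSeq ID,
  then case-insensitive symbol. `flank_bp` defaults to 10 kb — the method
  leaves the value to the user, and 10 kb is a conventional promoter-plus-
  regulatory margin for gene-proximal variation.
* **SNP-centered**: only markers with defined r² ≥ `r2_min` (default 0.5,
  the stated inclusion threshold) to the reference SNP are considered. The
  second track joins the reference with all its perfectly linked SNPs;
  every other block (and, if requested, singleton) gets its own track
  ordered by decreasing r² to the reference, the value rendered in the
  track name with three decimals, round half up. A block's r² to the
  reference is taken from its first member — all members tie under exact
  perfect LD, and under ε tolerance the first member is the documented
  representative. The reference SNP is retained even when its own MAF falls
  below `maf_min`, because the user explicitly selected it.
* **Region-centered** equals gene-centered with the window covering the
  panel; **chromosome-centered** puts all clusters into a single track with
  no dendrogram.

The MAF filter (`maf_min`, default 0 — i.e. only monomorphic markers are
dropped) is applied **before** cluster construction: the threshold excludes
rare SNPs from the analysis, and filtering afterwards could split blocks.
Window-then-MAF or MAF-then-window commute for per-marker filters; the
implementation filters by MAF first. The names track always lists every
displayed marker, whether or not singletons are shown.

MAF coloring uses five fixed bins of width 0.1 on \([0, 0.5]\) mapped to a
light-to-dark blue ramp; a cluster is colored by the mean MAF of its
members.

## BED12 export

Browser coordinates are 0-based half-open while panel positions are
1-based: the conversion is `pos − 1` at the record start and `pos` at the
end, stated once here and asserted throughout the tests. Every record is
12-column BED — a cluster spans `[min_pos − 1, max_pos)` with one 1-bp
block per member SNP, so the browser's connecting line between blocks *is*
the horizontal line that defines a cluster visually; singletons are
single-block BED12. Strand is fixed to `+` (SNP panels are strandless) and
score to 0. One `track` header line precedes each track; `itemRgb="On"` is
emitted only when coloring by MAF. Output is UTF-8 with Unix newlines,
tracks in architecture order, records sorted by start — two runs with the
same inputs are byte-identical. `check_bed12()` is the strict validator
used by the tests; per-cluster SNP-id lists export as
`<cluster_name>.txt`, and dendrograms as Newick via `ape`.

## The synthetic panel generator

`simulate_panel()` exists so that every module is testable without external
data, and it *plants* structure rather than modeling evolution — no
recombination maps, no demography, no allele-frequency spectrum. Each block
draws one latent binary indicator per chromosome (2n haplotypes) at the
block's minor allele frequency, and every SNP of the block copies it:
within-block r² is exactly 1 whenever nothing is missing. Consequences for
interpretation: a green planted-recovery test establishes that the
clustering machinery finds blocks that are perfect *by construction*; it
says nothing about the biological prevalence of perfect LD, about
epsilon-tolerant near-perfect blocks in real panels, or about genotyping
error, which the generator does not model.

Between-block correlation is induced by thresholding a multivariate
Gaussian; each pairwise latent correlation is solved numerically (1-D root
finding on the integrated bivariate-normal orthant probability) so the
binary indicators hit their target correlation in expectation. Two modes:

* a full target matrix, feasibility-checked before any sampling — targets
  outside the Fréchet bounds for the two frequencies, or a latent matrix
  with a materially negative eigenvalue, abort generation (eigenvalues
  above \(-10^{-8}\) are treated as numerically zero);
* `corr_to_first`, a single-factor mode fixing only each block's
  correlation to block 1. This exists because jointly prescribing *all*
  pairwise correlations of an outer-product binary target is genuinely
  infeasible under a Gaussian copula — the per-pair tetrachoric transform
  bends the matrix indefinite — while reference-vs-variant designs (the
  SNP-centered tests) only need the correlations to the reference.

Other defaults state the simulated world once: positions 1 kb apart from
10001, 100 samples, MAF 0.3, no missingness; sample sizes in tests range
from 50 to 4000 depending on how tightly a realized correlation must match
its target. All randomness flows from the mandatory seed, and the planted
partition is returned with the panel so tests never re-derive it.
`balanced_independent_pair()` constructs the exact-zero-LD fixture: the
four two-locus haplotypes in exactly equal counts, paired without double
heterozygotes (mixing locus-1- and locus-2-heterozygous individuals so
that, for n ≥ 8, both loci carry homozygote classes), giving sample r²
exactly 0 and one-iteration EM convergence.

## Degenerate inputs and edge behavior

* Monomorphic markers are retained by the readers (pure parsing) and
  excluded by the LD layer, where their r² is undefined.
* A marker pair with no jointly non-missing sample, or monomorphic within
  its pairwise-complete subsample, is masked in the LD matrix.
* Exact 0.5/0.5 allele-frequency ties recode deterministically
  (alphabetically first symbol is called major). A panel-wide allele swap
  therefore leaves dosages unchanged except at such ties, where the
  tie-break itself flips.
* Duplicate positions within a cluster collapse to one BED block with a
  warning; tied marker positions in a panel are an input error.
* An empty candidate set (gene window off the panel, or everything
  MAF-filtered) yields an empty architecture with a warning, not an error.
* A single cluster in hierarchical mode gets a trivial one-leaf dendrogram.

## Known limitations

* r² only: D′, LOD, and confidence-interval (Gabriel) haplotype blocks are
  out of scope, as are VCF input, multi-chromosome panels, X-chromosome
  hemizygotes, multi-allelic markers and HWE-violating composite-LD
  estimators.
* The pairwise EM is quadratic in the number of markers; chromosome-scale
  panels are better served by the precomputed-r² loader.
* No per-marker QC beyond the MAF threshold (no HWE or missingness
  filters); upstream QC is assumed.
* Coordinates in are coordinates out: the package is genome-build agnostic
  and performs no liftover.
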