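# ldhier

Hierarchical visualization of linkage disequilibrium as genome-browser
custom tracks.

Triangular correlation plots become unreadable when a region holds many
SNPs, or when perfectly linked SNPs are scattered rather than adjacent.
`ldhier` takes the opposite approach: it collapses SNPs in **perfect
linkage disequilibrium** (r² = 1) into *clusters* (LD blocks), orders those
blocks by their mutual LD with average-linkage hierarchical clustering, and
draws each block as one BED12 record whose intron-style horizontal line
joins the member SNPs — ready to load into the UCSC Genome Browser next to
regulation, conservation and expression tracks. It is aimed at geneticists
selecting tag SNPs for association studies or tracing putative causal
variants behind a significant index SNP.

## Model

For two biallelic loci with haplotype frequencies `p_AB, p_Ab, p_aB, p_ab`
(A/B major, a/b minor alleles):

    D  = p_AB − p_A·p_B,        p_A = p_AB + p_Ab,  p_B = p_AB + p_aB
    r² = D² / (p_A(1−p_A) · p_B(1−p_B))

Haplotype frequencies are estimated from unphased diploid genotypes by the
standard two-locus EM: only the double-heterozygote class is
phase-ambiguous and is split between AB/ab and Ab/aB in proportion to the
current haplotype-product weights. The EM starts at linkage equilibrium and
is fully deterministic.

Clusters are the connected components (size ≥ 2) of the graph joining
marker pairs with r² ≥ 1 − ε (default ε = 1e-6); with complete data perfect
correlation is transitive, so components are cliques. Blocks are then
hierarchically ordered by average linkage (UPGMA) on the distance
`1 − r²`, where the distance between two blocks is `1 − mean(r²)` over
their cross-pairs.

Four *architectures* are available:

| kind       | candidates                              | track layout |
|------------|-----------------------------------------|--------------|
| gene       | blocks with ≥ 1 SNP within `tx ± flank` | names track, one track per block in dendrogram order (or one flat track), singleton track |
| region     | every SNP in the panel                  | as gene |
| snp        | markers with r² ≥ 0.5 to a reference SNP| names track, reference + its perfect partners, then one track per block/singleton by decreasing r² (value embedded in the track name) |
| chromosome | every SNP in the panel                  | names track, one all-clusters track, singleton track |

Records can be colored by minor allele frequency (five bins on [0, 0.5],
light-to-dark blue).

## Worked example

```r
library(ldhier)

# three planted blocks (3 + 2 SNPs and one singleton), 150 samples
sim <- simulate_panel(block_spec(n_snps = c(3, 2, 1), maf = c(0.30, 0.25, 0.40),
                                 cross_corr = 0.5, n_samples = 150, seed = 33))
ldm <- r2_matrix(sim$panel, maf_min = 0.05)
round(ldm$r2, 3)
#>         rs01_01 rs01_02 rs01_03 rs02_01 rs02_02 rs03_01
#> rs01_01   1.000   1.000   1.000   0.290   0.290   0.199
#> rs01_02   1.000   1.000   1.000   0.290   0.290   0.199
#> rs01_03   1.000   1.000   1.000   0.290   0.290   0.199
#> rs02_01   0.290   0.290   0.290   1.000   1.000   0.276
#> rs02_02   0.290   0.290   0.290   1.000   1.000   0.276
#> rs03_01   0.199   0.199   0.199   0.276   0.276   1.000

cl <- build_clusters(ldm, markers = sim$panel$markers)
cl$clusters
#> cluster rs01_01 ( 3 SNPs, 1 : 10001 - 12001 )
#> cluster rs02_01 ( 2 SNPs, 1 : 13001 - 14001 )
cl$singletons
#> [1] "rs03_01"

arch <- region_centered(sim$panel)
arch
#> ld_architecture (region-centered on 1:10001-15001): 4 tracks
#>   SNP_names: 6 record(s)
#>   cluster_rs01_01: 1 record(s)
#>   cluster_rs02_01: 1 record(s)
#>   singletons: 1 record(s)
write_architecture(arch, "region.bed", newick_path = "region.nwk")
```

The two 1.000 off-diagonal blocks are the planted perfect-LD blocks: each
becomes one cluster named after its leftmost SNP and one BED12 record; the
weakly linked SNP `rs03_01` (r² ≈ 0.2–0.3 to the blocks) stays a singleton.
The exported `region.bed` passes `check_bed12()` and loads directly as a
UCSC custom track.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/ldhier.R simulate --seed 7 --out-dir demo
Rscript inst/cli/ldhier.R region --ped demo/simulated.ped \
    --markers demo/simulated.map --out-dir demo --newick --export-ids
Rscript inst/cli/ldhier.R --help
```

## Acceptance script

`scripts/acceptance.R` rebuilds, from scratch against the installed
package, the analytic check on the block-distance definition: it constructs
two 2-SNP perfect-LD blocks whose four two-locus haplotypes occur in
exactly equal counts (so their mutual sample r² is exactly zero),
re-estimates r² by EM, rebuilds the blocks, agglomerates the `1 − r²`
block distances, and reports the height of the single average-linkage
merge:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
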