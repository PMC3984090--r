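# haploviz

Region-based SNP haplotype clustering, haplogroup partitioning and
deterministic pictorial rendering for reference-anchored variant
panels.

## The problem

Resequencing panels deliver millions of SNPs expressed against one
reference genome. For a breeder or geneticist working on a candidate
gene, the useful question is much smaller: *within this gene's window,
how many distinct haplotypes exist, which accessions carry the
reference-like haplotype, and which carry a known causative allele?*
haploviz answers that question for tab-delimited SNP matrices (one
chromosome per file; columns: chromosome, position, reference sample,
then one column per sample; genotypes as IUPAC single- or two-letter
calls). It was built around the soybean maturity loci *E1*–*E4* and
the growth-habit gene *Dt1*, whose causative SNPs ship as a built-in
registry, but every stage is generic.

## The method

For samples *i*, *j* over the selected region, the genetic distance is
the identity distance

d(i,j) = (# positions with mismatched calls) / (# positions where both samples are called),

with missing data (`N`, `-`) excluded from both counts and zero-overlap
pairs conservatively assigned d = 1 with a warning. A rooted
ultrametric tree is built by UPGMA (size-weighted average linkage,
merge height = d/2) with published deterministic tie-breaking, and
*haplogroups* are the leaf sets obtained by cutting the tree at a
branching tier — tier 1 gives the reference-like clade versus the rest.
Around the clustering sit: multi-dataset merging with reference
fill-in, per-sample allele calls at registered causative SNPs,
deletion-candidate scanning over runs of missing calls, CDS codon
arithmetic, a seeded planted-structure simulator, and a
byte-deterministic PNG renderer (white/black/gray identity coloring or
per-nucleotide colors, dendrogram panel, gene/exon sidebar).

## Worked example

```r
library(haploviz)

# haplotype window: E1 gene span +/- the default 3,500 bp flank
win <- haplotype_window(region("Gm06", 20006928, 20007814))
win
#> <region> Gm06:20003428-20011314 (7887 bp)

# simulate a 12-sample panel with two founder haplotypes (8% divergence)
spec <- fixture_spec(n_samples = 12, n_sites = 100, region = win,
                     founders = 2, divergence = 0.08, missing = 0.1, seed = 42)
fx <- generate_matrix(spec)
dm <- distance_matrix(fx$matrix)
dm
#> <dist_matrix> 12 samples; distances in [0.0000, 0.1026]

tree <- upgma(dm)
partition_haplogroups(tree, "REF", tier = 1)
#> <haplogroup_partition> tier 1: 2 group(s); reference in group 1
#>   group 1 (6): REF, S02, S06, S07, S08, S09
#>   group 2 (6): S01, S03, S04, S05, S10, S11
```

The tier-1 groups recover the planted founder labels exactly
(`fx$truth` assigns S02, S06–S09 to the reference founder). Distances
land near the planted 8% divergence, shrunk slightly by the 10%
missingness. Calling the *E1* causative SNP after planting its variant
allele into two samples:

```r
e1 <- default_allele_registry()[[1]]   # E1/e1-as, Gm06:20007173 C<->G
m2 <- plant_allele(fx$matrix, e1, c("S03", "S04"))
head(call_allele(m2, e1), 5)
#>   sample  call observed
#> 1    REF e1-as        C
#> 2    S01 e1-as        C
#> 3    S02 e1-as        C
#> 4    S03    E1        G
#> 5    S04    E1        G
```

The reference genome itself carries the early-flowering *e1-as* allele
(C); samples with G at the causative site are called functional *E1*.
A pictorial render of the same panel:

```r
render_pictorial(fx$matrix, tree, models = NULL,
                 render_options(mode = "three_color", show_letters = TRUE),
                 "panel.png")
```

Command-line equivalents (`cluster`, `render`, `call`, `merge`,
`simulate` subcommands) live in the launcher:

```sh
Rscript inst/cli/haploviz.R simulate --chrom Gm06 --start 20003428 \
    --end 20011314 --n-samples 12 --n-sites 100 --seed 42 --out-prefix demo
Rscript inst/cli/haploviz.R cluster --snp demo.snp.tsv \
    --samples demo.samples.xml --out-prefix demo
```

which writes the distance matrix, Newick tree, haplogroup table and
per-position SNP report.

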