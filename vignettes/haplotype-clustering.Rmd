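---
title: "Region-based SNP haplotype clustering and haplogroup analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based SNP haplotype clustering and haplogroup analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploviz)
```

## The analysis model

haploviz analyzes *haplotypes*: the ordered combination of nucleotide
states a sample carries across the variant positions of a genomic
region. Its input is a reference-anchored SNP matrix — one chromosome's
variant positions by samples, each cell a single IUPAC symbol, with the
first sample being the reference genome every call is expressed
against. Because only variant positions are stored, the matrix is a
sparse surrogate for a multiple sequence alignment in which all
invariant columns have been removed.

The pipeline has four stages.

**1. Identity distance.** For samples $i, j$ the genetic distance is
the proportion of mismatched calls among the positions where both
samples have data:

$$ d_{ij} \;=\; \frac{\#\{p : x_{ip} \neq x_{jp}\}}{\#\{p : x_{ip}, x_{jp} \text{ both called}\}} $$

Positions where either sample is missing (`N` or `-`) are excluded
from numerator and denominator. No evolutionary-distance correction
(Kimura, gap penalties) is applied: over the short genic windows this
method targets, divergences are far below saturation and the mismatch
proportion is the quantity of interest itself. Ambiguity codes are
compared as ordinary symbols — `R` vs `A` is a mismatch — because a
heterozygous call genuinely differs from a homozygous one; their
biological interpretation is deferred entirely to the allele-calling
stage. A pair of samples with *zero* informative overlap has no defined
distance; we assign the maximal distance 1.0 and record a warning, on
the grounds that conservative separation is safer than silently
guessing similarity, and the warning keeps the decision auditable.

**2. UPGMA.** The tree is built by unweighted pair-group clustering
with arithmetic mean: repeatedly merge the two clusters with the
smallest average inter-member distance; the merge node sits at half the
merge distance, so the tree is rooted and ultrametric, and merge
heights are monotone non-decreasing. Cluster-to-cluster distances use
the size-weighted (textbook) update, which keeps them equal to the
plain arithmetic mean over all member pairs — the test suite enforces
this against a brute-force oracle that recomputes every average from
scratch at every step. Two determinism rules are part of the contract:
among tied minimal-distance pairs we merge the pair whose
(smaller, larger) original-sample-index signature is lexicographically
least, and within a merge node the child containing the
alphabetically first leaf is drawn first. Ties are measure-zero for
real data; the rules exist so that reruns, renders and Newick exports
are bit-identical.

**3. Haplogroup partition.** Haplogroups are defined by the tree's
first branching point: cutting at tier 1 splits the samples into the
clade containing the reference ("reference-like") and its complement.
Cutting at tier $k$ takes the leaf sets of the maximal subtrees rooted
at depth $k$; a leaf shallower than the cut forms its own singleton
group. Tier $k+1$ always refines tier $k$.

**4. Causative-SNP calls.** Independently of clustering, samples are
genotyped at registered causative SNPs of candidate genes. The
built-in registry covers the soybean maturity loci with biallelic
causative SNPs against the Williams 82 reference: *E1*/*e1-as*
(Gm06:20007173, C↔G; the reference itself carries *e1-as*),
*E2*/*e2* (Gm10:44732850, A↔T) and four *dt1* missense sites
(R62S, P113L, R130K, R166W on Gm19). R130K is registered for
completeness although it is rare in public resequencing panels. Per
sample the call is: reference symbol → reference allele name, variant
symbol → variant allele name, missing → `no_data`, the IUPAC code for
exactly the {ref, alt} pair → `heterozygous`, anything else →
`unknown_variant`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flank` | 3,500 bp | symmetric extension of a gene span into its haplotype window; matches the window convention of candidate-gene maturity studies |
| `tier` | 1 | tree cut depth for haplogroup definition |
| `threshold` | 0.9 | missing fraction at which a deletion scan flags a sample |
| `min_sites` | 3 | minimum scanned SNP sites before a deletion flag is possible |
| `cell_size` | 12 px | pictorial cell edge |

## Semantics worth knowing before trusting results

**Reference fill-in during merges.** When several datasets are merged,
positions absent from one dataset but present in another are filled
with the *reference* symbol for all samples of the lacking dataset —
absence from a variant-only matrix means "no variant reported", which
is evidence of reference state. This biases sparsely ascertained
datasets toward reference-likeness and therefore shrinks their
distances to the reference clade; it is the documented merge semantic,
not an imputation, and conflicting reference symbols at a shared
position abort the merge by default. The documented dataset-count
limit of three is treated as a soft warning: nothing in the algorithm
needs it.

**Assumed-reference allele calls.** If a registry site is absent from
the matrix, every sample is called with the reference allele name and
the table carries an explicit `assumed_reference` flag, preserving the
distinction between an observed reference base and an unobserved
position.

**Deletion signatures are candidates.** A genomic deletion manifests
as a contiguous run of missing calls in the affected samples. The scan
reports the missing fraction and longest run over a candidate region
and flags samples at `threshold`; the flag is labelled *candidate*
because runs of missingness can also arise from alignability or
coverage artifacts — confirmation needs an independent assay (e.g.
PCR), which is out of scope here.

**Coordinate conventions.** All coordinates are 1-based with both ends
inclusive, and chromosome labels are compared as exact trimmed strings
(`"Gm06"` ≠ `"6"`); no silent relabelling is ever performed. One
deliberate exception: deletion lengths in the allele literature this
registry mirrors are differences of printed end coordinates
(`end − start`, e.g. 47516697→47519330 = 2,633 bp), and
`interval_length()` fixes that convention in one place. CDS codon
arithmetic (`affected_codon`, `frameshift_intact_length`) operates on
spliced coding-sequence positions only; mapping genomic coordinates to
CDS positions via exon structures is intentionally unsupported. The
published truncation-length convention for nonsense mutations counts
the affected codon index itself (a stop at CDS 1561 is reported as a
521-residue protein although 520 residues precede the stop); we report
the affected codon index and note the off-by-one ambiguity rather than
resolving it.

## The synthetic generator

`fixture_spec()`/`generate_matrix()` produce planted-structure panels:
a uniform random reference haplotype; `founders − 1` divergent founder
haplotypes, each differing from the reference at a seeded
`divergence`-fraction site set; samples copy their founder and are then
perturbed by per-cell mutation (`noise`), per-cell missingness
(`missing`, written `N`) and contiguous deletion runs (written `-`), in
that order. One global seed drives a separate stream per stage, so
changing the missingness rate does not perturb the founder draws; the
stream order is part of the contract. Defaults (tens of samples, two
founders, 5–10% divergence, ≤20% missingness) mirror the structure of
reference-aligned resequencing panels used in candidate-gene haplotype
studies.

What the generator does *not* emulate: recombination and
linkage-disequilibrium decay, coalescent genealogies within
haplogroups, ascertainment bias of SNP arrays, or coverage-correlated
missingness. Passing the planted-recovery battery therefore shows the
clustering machinery is correct under clean two-founder structure; it
does not certify behavior on admixed or recombined real panels, where
first-tier groups can be less crisp.

## Numerical and degenerate-input choices

- Ultrametricity is exact by construction; tests assert root-to-leaf
  height agreement within 1e-9.
- Tie comparisons in UPGMA use a 1e-15 absolute band so that
  floating-point noise in averaged distances cannot flip a merge order.
- An empty region slice is a valid zero-position matrix; clustering an
  empty region is an error at the command level (`empty region`).
- A deletion scan over zero sites reports `n_sites = 0` and never
  flags.
- Renders refuse pixel areas above `max_pixels` (default 4e7); the
  text report has no cap and is the right output for huge regions.
- PNG output is byte-deterministic (pixels are written directly into a
  raster; text uses an embedded 5×7 bitmap font, no system fonts).
  JPEG is supported for parity but not under the byte-determinism
  guarantee, since JPEG encoders vary.

## Problem sizes in the test suite

The suite runs entirely on generated data: the UPGMA oracle battery
uses 200 random matrices of up to 8 samples; property batteries use
panels of 10–16 samples by 40–200 sites across 20 seeds. These sizes
were chosen because every property they exercise (oracle equality,
refinement monotonicity, planted recovery, byte determinism) is
scale-free; production use on hundreds of samples by thousands of
positions is limited only by the O(n²·p) distance computation.

## Known limitations

- Diploid phasing and multi-allelic sites are out of scope: one symbol
  per cell, heterozygotes as IUPAC codes.
- The haplogroup definition is tree-topological; it inherits UPGMA's
  sensitivity to rate heterogeneity between clades.
- Structural alleles that do not change any SNP call (retrotransposon
  insertions, single-base deletions absent from the matrix) cannot be
  genotyped from a SNP matrix; the registry documents them only where
  a SNP or a deletion signature is informative.
- Coordinate lift-over between genome builds is the user's
  responsibility; merges require all datasets on one build.
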