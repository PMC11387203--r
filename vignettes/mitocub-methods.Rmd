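---
title: "Methods: mitogenome composition and codon usage bias in mitoCUB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome composition and codon usage bias in mitoCUB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoCUB)
```

mitoCUB analyzes annotated animal mitochondrial genomes — typically insect
mitogenomes of 15–17 kb carrying 13 protein-coding genes (PCGs), 22 tRNAs,
2 rRNAs and a control region — for the signatures of codon usage bias and
the forces (mutation pressure versus natural selection) that shape it. This
vignette explains each statistic the package computes, the assumptions
behind it, the tunable parameters, and the design decisions taken where the
design was genuinely open.

## Composition and strand skews

For any sequence or region class the package reports base counts, A+T and
G+C content, and the strand-asymmetry skews

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C}.$$

Contents and skews are computed over non-N bases; a region with zero A+T
(or G+C) gets an undefined (`NA`) skew rather than a zero. Region
composition concatenates all features of a class in *sense* orientation:
minus-strand genes are reverse-complemented before counting. This choice
(the alternative is genome-strand orientation) flips the sign of skews for
minus-strand genes and makes per-class skews comparable across genomes
with different strand assignments. Overlapping features are each counted in
full in their own class; the package does not attempt to apportion shared
bases.

Skews are antisymmetric under reverse complementation, and the test suite
asserts this as a property over random sequences.

## Codon usage: RSCU and representation classes

Relative synonymous codon usage of codon $c$ in amino-acid family $F$ is

$$\mathrm{RSCU}_c = \frac{|F| \; n_c}{\sum_{c' \in F} n_{c'}},$$

the ratio of observed to expected-under-uniformity counts. The family map
is the invertebrate mitochondrial code (NCBI translation table 5: ATA =
Met, TGA = Trp, AGA/AGG = Ser, so Ser has an 8-codon family and there is no
single-codon family). Stop codons (TAA, TAG) are excluded from counting but
tallied separately; codons containing N are skipped. A family with zero
total count yields undefined (`NA`) RSCU values, never zeros. Within every
non-empty family the RSCU values sum to the family size, so the family mean
is 1; this conservation and scale invariance are asserted against direct
computation in the tests.

Codons with RSCU above 1.6 are called overrepresented and below 0.6
underrepresented (strict inequalities; both thresholds are arguments).
When a representation call is made across a set of genomes, the package
averages the per-species RSCU tables codon-by-codon (`meanRscu()`) and
classifies the means. Pooling raw counts across species or majority voting
are reasonable alternatives; averaging per-species RSCU was chosen because
it weights species equally regardless of genome size, and per-species
tables are always emitted so either alternative can be recomputed from the
output.

Start codons are included in the codon counts; codon-facing outputs use
the RNA alphabet (UUA, not TTA), as is conventional for RSCU displays.

## Start and stop codons

Mitochondrial PCGs start with ATN or TTG and terminate with TAA, TAG or a
truncated stop completed to TAA by post-transcriptional polyadenylation.
The package splits each gene into triplets from its first position; one or
two leftover nucleotides are the trailing partial. A trailing `T` is
reported as the incomplete stop `T--`, a trailing `TA` as `TA-`; any other
terminus (including a final complete codon that is not a stop) is counted
as `anomalous` rather than raising an error, since it usually indicates an
annotation problem the user should see in the summary table.

## PR2 bias and the neutrality plot

Both diagnostics work on positional composition: the third-position base
fractions A3, T3, G3, C3 and the per-position G+C fractions GC1, GC2, GC3
with GC12 = (GC1 + GC2)/2. Stop codons and N-containing codons are
excluded here too, for consistency with RSCU.

The PR2 (Parity Rule 2) plot places each gene/species at
$(A3/(A3+T3),\; G3/(G3+C3))$. Under strand-symmetric mutation and no
selection at synonymous sites both coordinates are 0.5; systematic
displacement indicates strand-specific mutation pressure and/or selection.

The neutrality plot regresses GC12 on GC3 across species (ordinary least
squares, with the Pearson correlation and its two-sided t-test p-value on
$n-2$ degrees of freedom). A slope near 1 with a significant correlation
means positions 1+2 track position 3 — mutation pressure dominates; a slope
near 0 means selection constrains positions 1+2 independently of the
third-position mutational drift. P-values are reported unadjusted with
significance tiers at .05 and .01; no multiple-testing correction is
applied across genes, matching common practice for this 13-gene panel.
The regression requires at least 3 points and non-degenerate GC3 variance;
both are validated.

## Correspondence analysis

Correspondence analysis of the codons-by-species RSCU matrix (one matrix
per gene) is implemented classically: with correspondence matrix
$P = X / \sum X$, row and column masses $r$ and $c$, the standardized
residual matrix $S = D_r^{-1/2}(P - r c^\top) D_c^{-1/2}$ is decomposed by
SVD; axis inertias are the squared singular values, axis percentages their
share of total inertia (which equals the chi-square statistic of $X$
divided by $\sum X$), and principal coordinates are
$D_r^{-1/2} U \Lambda$ and $D_c^{-1/2} V \Lambda$.

Numerical choices: stop-codon rows are deleted first, then all-zero rows
and columns (both reported in the result); the axis count is capped at
$\min(\text{rows},\text{cols}) - 1$ and singular values below a relative
tolerance are treated as zero, so an independence-structured matrix yields
a zero-axis result rather than numerical noise; and because CA axis signs
are arbitrary, each axis is oriented so that its largest-magnitude row
loading is positive, making outputs reproducible across BLAS/LAPACK
implementations. RSCU values (not raw counts) are the default input — the
per-gene axis percentages are then comparable across genes of different
lengths — with counts available via an argument. The tests check inertia
conservation, zero weighted means of principal coordinates, transpose
invariance of the spectrum, and agreement with an independent
eigen-decomposition oracle and with `MASS::corresp`.

## Hydropathy

Each PCG is translated under table 5 (terminal stop consumed, internal
stops kept as `*` with a warning, N-codons as `X`) and scored with the
Kyte–Doolittle scale, embedded as a pinned constant (Ile 4.5 … Arg −4.5;
all 20 values are asserted in the tests against an independently
transcribed copy). GRAVY is the mean hydropathy over scored residues;
`X`/`*` are excluded from numerator and denominator, and a trailing
incomplete stop contributes no residue. GRAVY of a concatenation equals
the length-weighted mean of the parts, which the tests assert exactly.

## Nucleotide diversity

Pi is the average pairwise proportion of differing sites:
$\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij}$ with $d_{ij}$ the fraction of
analyzed sites at which rows $i,j$ differ. The default site filter is
complete deletion — a column containing a gap or N in *any* row is excluded
for all pairs — matching the default of the standard sliding-window tools
for this analysis; pairwise deletion is available behind a flag. The
sliding window (defaults 200 bp width, 20 bp step) anchors at column 1,
advances by the step, drops a final partial window, and reports
start/end/midpoint in pre-deletion column coordinates while excluded
columns never enter the denominator. For genome-scale profiles the
per-gene alignments (PCGs plus rRNAs) are concatenated in the annotation
order of the reference genome, and the gene boundaries in concatenated
coordinates are emitted alongside so the profile can be segmented.
Per-gene tables report the alignment column count as the gene length.

The implementation aggregates per-column pair counts; the tests prove it
equal to a literal per-pair, per-column oracle on random alignments and to
`ape`'s raw pairwise distances.

## The synthetic-data generator

`generateMitogenome()` emulates the study system — an AT-rich insect
mitogenome — well enough that every analysis stage has a realistic,
fully-known input:

* 13 PCGs with canonical names and typical lengths (~11 kb total), 22
  tRNAs (66 bp), two rRNAs, and a control region absorbing the remaining
  length of the requested genome (default 15,500 bp);
* target whole-genome A+T of 0.78 (defaults; observed AT-rich insect
  mitogenomes run roughly 0.76–0.80), realized within ±0.01 at this
  genome size;
* codon-structured PCGs: positions 1+2 and position 3 are drawn from
  separate base distributions, with third-position A+T set high (default
  0.90) and positions 1+2 compensating so the overall A+T still meets the
  target — this is what makes A/U-ending codons overrepresented
  (RSCU > 1.6), as in real AT-biased mitogenomes;
* skew targets (+0.18 AT, −0.20 GC by default) parameterize the base
  distribution of plus-oriented material; genes on the minus strand
  (default: ND1, ND4, ND4L, ND5 and five tRNAs, mirroring the typical
  insect arrangement) are reverse-complemented onto the genome strand, so
  realized whole-genome skews attenuate toward zero but keep the
  characteristic signs (AT skew positive, GC skew negative);
* ATN/TTG starts (ND5 and ATP8 get TTG), TAA/TAG stops with two genes
  (COX2, ND5) ending on a truncated `T`;
* in-frame stop codons are avoided by an in-codon permutation
  (TAA→AAT, TAG→AGT) rather than rejection sampling, which preserves the
  drawn base multiset exactly and therefore does not bias the realized
  composition;
* everything is deterministic given the seed.

What the generator does **not** emulate: amino-acid composition (codons
are drawn independently, so synthetic proteins are not hydrophobic the way
real mitochondrial membrane proteins are, and synthetic GRAVY values are
typically negative); tRNA/rRNA secondary structure; control-region repeat
structure; and selection-aware codon evolution. Tests that pass on
synthetic data therefore validate the *computations*, not claims about any
real taxon.

`evolveFamily()` produces the multi-species alignments: each gene evolves
along a star phylogeny under Jukes–Cantor, every branch substituting each
site with probability $\tfrac34(1 - e^{-\frac43 d m/2})$ for pairwise
divergence $d$ and gene rate multiplier $m$ (substitutions uniform over
the other three bases, which is the exact JC transition kernel). The
expected pairwise diversity is then the closed form
`jcExpectedDiversity(d, m)` $= \tfrac34(1 - e^{-\frac43 dm})$, which the
tests and the acceptance script verify by simulation. A star tree (not a
realistic phylogeny) suffices because only pairwise expectations are
needed to validate Pi; no indels are introduced, so the output is aligned
by construction and Pi is isolated from aligner behavior. The default
rate-multiplier profile makes ND2/ATP8/ND6/ATP6 fast and COX1/ND1/lrRNA
slow, reproducing the qualitative per-gene diversity ordering seen in
leafhopper mitogenomes.

## The pipeline

`runAll()` orchestrates all stages over a list (or directory) of genomes
and writes one table per analysis plus a JSON manifest; it adds no
computation, and a rerun with the same configuration is byte-identical.
Headline numeric columns are rounded to conventional display precision
(skews and Pi 3 dp, RSCU 2 dp, GRAVY 3 dp, CA percentages 2 dp) with
full-precision `*_raw` companions. Per-genome failures are isolated; the
run fails only if no genome is analyzable. A thin command-line wrapper
(`inst/cli/mitocub.R`, subcommands `simulate` and `all`) exposes the same
functions to shell users.

## Problem sizes and determinism in the test suite

The test suite validates the oracles on deliberately small problems
(alignments up to 6×50 for the brute-force Pi oracle, matrices up to 8×6
for the CA oracle), uses 15.5 kb genomes and families of 8–26 taxa for
parameter recovery with 30–50 replicate simulations, and fixes every seed,
keeping a full run around half a minute. These sizes were chosen as the
smallest at which the law-of-large-numbers tolerances quoted above are
comfortably informative. The reproduction test against the published
26-genome leafhopper dataset runs only when the user has fetched those
GenBank flat files into `inst/extdata/accessions/`; the package ships no
third-party data.

## Known limitations

* The GenBank reader covers the subset of the format needed for
  mitogenome annotation (single- or two-interval locations, `complement`,
  `join` across the origin); it is not a general parser.
* Codon statistics assume the annotated reading frame starts at the
  feature's first base (`codon_start` offsets are not consumed).
* Complete deletion makes windowed Pi sensitive to gap-dense columns in
  ragged alignments; use pairwise deletion for such data.
* ENC, CAI, Tajima's D and phylogenetic inference are out of scope.
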