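---
title: "Classifying short genomic fragments with signature peptides"
author: "sigpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying short genomic fragments with signature peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigpep)
```

## The model

`sigpep` classifies DNA reads by exact amino-acid k-mer matching against
a precomputed database rather than by alignment scores. The underlying
observation is statistical: between two unrelated proteomes of $N_1$ and
$N_2$ residues, the expected number of shared k-mer position pairs under
an i.i.d. residue model with frequencies $f_a$ is

$$E(k) = N_1 N_2 \Big(\sum_a f_a^2\Big)^{k},$$

which for a uniform 20-letter alphabet is $N_1 N_2\, 20^{-k}$ — about
0.1 for two typical $10^6$-residue bacterial proteomes at $k = 10$. Real
proteome pairs, by contrast, share thousands of 10-mers because protein
folding and function constrain sequence space: the run-length
distribution of maximal exact matches is dominated by a roughly 20-fold
geometric falloff per residue in the random regime ($k \lesssim 7$) and
by a heavy functional tail beyond it. A 10-mer is therefore long enough
that a single exact match is strong evidence of homology, and short
enough to occur in most genes even across large phylogenetic distances.
All of this machinery — maximal-match enumeration, run-length
histograms, falloff fits, and the analytic expectation — is exposed in
`maximalMatches()`, `runLengthHistogram()`, `fitFalloff()` and
`expectedRandomMatches()` so the choice of $k$ can be re-examined on any
reference panel.

### Signature placement

Given per-leaf reference proteomes and a rooted phylogeny (only the
connectivity of the tree is used, never branch lengths), the database
build (`buildSignatureDB()`) keeps every k-mer that occurs in at least
two distinct leaves — within-leaf paralogs count once — and assigns it
to the least common ancestor of the leaves containing it. This is
deliberately conservative: a peptide seen in scattered leaves, whether
through deep conservation or horizontal transfer, lands near the root
and cannot generate false specificity. The filter counts *leaves* by
default; `genusLabels` switches the count to genera for panels with
multiple leaves per genus (on a genus-deduplicated panel the two
readings coincide).

### Read placement

A read is translated in six frames (`sixFrameTranslate()`), split into
putative peptide fragments at stop codons and ambiguity residues with a
15-residue minimum (`extractFragments()`), tokenized into overlapping
k-mers, and looked up. The matched node set is reduced by the
greatest-common-descendant rule (`gcdAssign()`): the deepest node when
the set is totally ordered by ancestry (monophyletic evidence),
otherwise the LCA of the maximal antichain — the branch point of the
conflicting paths. Because the maximal antichain has a unique LCA, no
tie-breaking is ever needed. A match of length $L$ is treated as
$L - k + 1$ overlapping signatures; for overlapping signatures the GCD
rule gives the same answer as treating the full-length match as one
signature, so no run merging is performed at classification time.

### Functional profiles

Signatures can carry subsystem labels: `annotateSignatureFunctions()`
marks each signature with every annotated gene set in which the exact
k-mer occurs. Per read, the subsystem sets of annotated signatures are
intersected within each reading frame and the per-frame results are
unioned across frames; each of the $n$ resulting subsystems receives
$1/n$ counts, so the functional profile total equals the number of
functionally assigned reads exactly. Frames whose matched signatures
all lack annotations are treated as contributing no information rather
than an empty set — the alternative (intersecting with the empty set)
would annihilate every read that touches an unannotated signature,
which cannot be the intended reading of the counting scheme.

### Comparing samples

Profiles are compared with the normalized dot product, with the root
node excluded by default for phylogeny vectors (root counts pool
deep conservation and ambiguity, and would inflate the similarity of
unrelated samples); `1 - dot` serves as a distance.
`rollupProfile()` aggregates subsystems into higher-level categories
conserving totals, and `nodeDifferential()` compares per-node recruitment
proportions between two samples. The differential test is a
two-proportion z-test (chi-square without continuity correction) with a
Fisher exact fallback when any expected cell is below 5; raw p-values
are reported by default and Benjamini–Hochberg adjustment is opt-in.
The choice of test is a documented stand-in: the per-node proportion
comparison is what the analysis depicts, but no specific test is
canonical for it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | signature peptide length (residues); the specificity/sensitivity pivot |
| `minFragmentLength` | 15 | minimum putative-fragment length (residues); discards fragments too short to be informative |
| `genusLabels` | none | optional leaf-to-genus map for the ≥ 2 filter |
| `excludeRoot` | `TRUE` for phylogeny vectors | drop the root before the dot product |
| `freqs` | uniform | residue frequencies for the random-match model and fixture backgrounds |

Smaller `k` (e.g. 8) floods the database with chance matches whose
conflicting placements drive reads to the root; larger `k` costs
sensitivity roughly geometrically. Both effects can be explored with
the fixture generators.

## Numerical and representational choices

* Node identifiers are assigned by deterministic preorder traversal of
  the input Newick (root = 1, clades in writing order), because no
  published numbering is derivable from a Newick file alone. The same
  tree text always produces the same ids, and `writeSignatureTree()`
  emits the ids as internal labels so profile files stay interpretable.
* Translation uses a direct codon-table lookup (standard genetic code
  by default, any `Biostrings` code table accepted). The bacterial
  table differs only in start-codon handling, which this method never
  uses. Codons containing ambiguity letters translate to `X`; `X` and
  every residue outside the closed 20-letter alphabet (U, O, B, Z, J)
  break fragments and disqualify reference k-mers, because exact
  matching requires a closed alphabet.
* Reverse-strand frames R1–R3 start at offsets 0–2 of the reverse
  complement (the common translator convention); this affects fragment
  offsets but never classification, which is strand-invariant.
* Maximal matches are maximal within protein boundaries (proteomes are
  compared gene-wise), and each position pair is reported once at its
  maximal extension. The falloff fit is unweighted least squares on
  natural-log counts — the simplest estimator consistent with an
  exponential fit with no stated weighting.
* The database serialization is sorted tab-separated text with `#`
  headers carrying `k` and a tree fingerprint, chosen to be diff-able
  and streamable; binary indexing is left open as an optimization.
* Degenerate inputs: empty node sets are errors; unknown leaves are
  configuration errors naming the leaf; reads with non-IUPAC characters
  are skipped and counted, not fatal; zero profiles compare with
  similarity 0 rather than NaN.

## The synthetic fixtures, and what they do not show

`makeToyReference()` plants known peptides into i.i.d.-uniform
background proteins across designated leaves, so the expected database
entry of every plant (its leaf-set LCA) is known by construction.
`simulateReads()` draws error-free fixed-length substrings from either
strand of a deterministic coding genome (each amino acid encoded by a
fixed codon, so fixtures are byte-reproducible), and `mutateReads()`
applies independent per-base substitutions. Uniform backgrounds are the
simplest null consistent with the random-match model; a frequency hook
exists for non-uniform compositions.

These fixtures validate the algorithmic contracts — filter, placement,
conservation, strand invariance, the $(1-e)^{3k}$ sensitivity decay
under errors — but they do not emulate real data: no codon-usage bias,
no gene-inventory differences, no horizontal transfer, no homopolymer
or quality-correlated sequencing errors, no realistic abundance
distributions. Passing tests therefore certify the machinery, not
field performance on soil reads.

One subtlety in the error model: the survival probability of a
signature under per-base substitution rate $e$ is exactly $(1-e)^{3k}$
only when no substitution in its coding bases is synonymous. The test
and acceptance probes therefore use a Met/Trp-only peptide
(`MWMWMWMWMW`), the two residues whose codons admit no synonymous
single-base change; for generic peptides measured survival exceeds the
bound slightly (third-position synonymy), which is the expected
direction of the approximation.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: toy
trees of 4–16 leaves, proteomes of a few hundred residues per leaf for
oracle comparisons, two random proteomes of $10^5$ residues for the
Monte-Carlo falloff, and read batches of a few hundred. These sizes
were chosen so that every claim is backed by an exhaustive or
closed-form oracle; the algorithms themselves stream reads and hold
only the k-mer table in memory, and nothing in the design caps the
reference panel size.

## Reproducing the genome-scale match statistics

The classic specificity demonstration — enumerating all maximal
amino-acid matches of length ≥ 10 between *Escherichia coli* K-12 and
*Bacillus subtilis* 168 — needs the two annotated proteomes, which are
not shipped. With downloaded FASTA files the recipe is:

```sh
Rscript -e 'library(sigpep)
  A <- Biostrings::readAAStringSet("ecoli_k12.faa")
  B <- Biostrings::readAAStringSet("bsubtilis_168.faa")
  mm <- maximalMatches(as.character(A), as.character(B), minK = 10)
  nrow(mm)                                  # matches >= 10 aa
  length(unique(paste(mm$seqA, mm$seqB)))   # connected gene pairs
'
```

Counts are sensitive to the annotation version used. Wrong-frame
controls can be built by translating each CDS in its five incorrect
frames and running the same enumeration.

## Known limitations

* The reference tree is consumed, not built; its quality bounds the
  quality of every placement.
* Signatures from mobile elements are not flagged; they are placed
  conservatively near the root like any other widely shared peptide.
* Placement resolution is capped by the reference panel: reads from
  organisms without close relatives land on deep nodes, which is the
  intended honest behavior rather than a defect.
* No paired-end awareness, no quality trimming, no BLAST fallback.
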