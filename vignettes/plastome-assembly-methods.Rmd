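---
title: "Assembling plastomes from shotgun reads: models, parameters and design choices"
author: "plastidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling plastomes from shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidkit)
```

## The problem

Chloroplast (plastid) genomes are small (120-170 kb), high-copy circular
molecules with a canonical quadripartite layout: a large and a small
single-copy region (LSC, SSC) separated by two inverted-repeat copies (IRa,
IRb) that are reverse complements of each other. Because plastid DNA is a
few percent of a total-DNA shotgun library, a plastome can be skimmed out of
ordinary whole-genome short-read sequencing without any organelle
enrichment; and because pooling several individuals into one library turns
pileup allele fractions into population allele-frequency estimates, the same
data yields chloroplast SNPs for phylogeography.

Two features make naive assembly fail. First, the IR is far longer than a
short-read insert, so any de Bruijn assembler collapses the two copies into
one contig and the assembly graph branches at the four single-copy/IR
junctions. Second, when no congeneric reference exists, contigs must be
ordered and oriented against a *distant* reference without letting that
reference's sequence leak into the consensus.

`plastidkit` implements the complete desk-scale workflow: simulate (or
read) paired shotgun data, trim, assemble with one de Bruijn unitig engine
run at two k-mer sizes, isolate chloroplast contigs with a Karlin-Altschul
"E-value of zero" filter, scaffold against a reference split into two
overlapping halves so both IR copies are rebuilt, then map reads back for
pooled SNP calling and summarise chlorotypes in a median-joining network.

## The simulator and what it does (and does not) emulate

`make_genome(lsc_len, ssc_len, ir_len, seed)` draws i.i.d. uniform DNA per
region and enforces IRa = revcomp(IRb); the full-size default layout
(87,022 / 18,352 / 27,070 bp; 159,514 bp total) matches a real
Meliaceae-scale plastome. `diverge()` emulates a distant scaffold reference
with per-site substitutions plus short (1-10 bp) indels; the fixture default
of 10% substitutions + 0.5% indels is a deliberate *guess* at a
different-family distance - no measured figure was available - and is fully
configurable. `make_pool()` models equimolar pooling: a planted variant
carried by one haplotype of four has a pooled frequency of exactly 25%.
`simulate_reads()` draws inserts Normal(460, 50) bp (clamped at the read
length), wraps fragments across the circular origin, reverse-complements
mate 2, applies a uniform per-base substitution error (default 0.2%, encoded
in the Phred+33 quality string), and can dilute plastid pairs to a
`cp_fraction` (default 5%, a typical chloroplast share of total reads) with
an i.i.d. uniform decoy background.

Deliberately not modelled: GC- or position-dependent error profiles,
indel sequencing errors, heteroplasmy, nuclear insertions of plastid DNA
(NUPTs), and pyrosequencing homopolymer errors. Passing tests therefore
demonstrate the pipeline's logic and bookkeeping, not robustness to every
artefact of real libraries; real decoy background is also *homologous*
(NUPTs) rather than random, which would make binning genuinely harder.

## Read preparation

Trimming is a modified-Mott running sum: each base scores
`p_limit - p(base)`, the retained window is the maximal-sum segment
(leftmost then longest on ties), and reads shorter than `min_len = 50` bp
after trimming are rejected. One numerical subtlety: a quality limit of
0.05 is, at Phred resolution, the integer score 13 (`floor(-10 log10
0.05)`), but `10^-1.3 = 0.0501 > 0.05`, so scoring the limit literally
would reject a uniform-Q13 read outright. The limit is therefore quantised
to its Phred-13 probability so that boundary bases score exactly zero and
the tie rule keeps the read whole - matching the stated equivalence between
the 0.05 limit and "Phred 13". Subsampling keeps every n-th pair starting
at the first (no RNG), so 1/2, 1/4 and 1/8 series are deterministic and
mates stay synchronised.

## The assembler

A single de Bruijn unitig engine stands in for "two independent
assemblers": it is run at two k values (default 31 and 41), and the two
contig sets confirm each other downstream exactly as two programs' output
would, by overlapping during scaffolding. Reads and their reverse
complements are inserted, so the graph is strand-symmetric; nodes are
(k-1)-mers, edges are observed k-mers, unitigs are maximal non-branching
edge paths, and each unitig is emitted once in canonical (lexicographically
smaller) orientation. K-mers seen once are dropped when mean k-mer coverage
exceeds 10 (a fixed, logged stand-in for an assembler's automatic cutoff);
dead-end chains shorter than 2k hanging off branch nodes are clipped; simple
two-path bubbles are resolved toward the higher-coverage branch. A unitig
and its own reverse complement share endpoint nodes whenever a single-copy
region is flanked by the IR - these pairs are explicitly exempted from
bubble popping, otherwise popping one strand dissolves the junction branches
and the whole circle assembles into a single walk.

On a quadripartite genome the engine deliberately emits the IR as *one*
contig: the four junction nodes have degree two, so the unitigs are
LSC ± (k-1) bases of IR context, SSC likewise, and the IR itself. The
duplication of the IR is the scaffolder's job, not the assembler's.
Paired-end distances are not used for graph resolution - a noted fidelity
gap versus production assemblers; pairs matter here only through coverage.

## Chloroplast binning and its statistics

Contigs are classified by ungapped seed-and-extend local alignment (word
length 11, +1/-2, X-drop 20) against a plastome database. E-values use
Karlin-Altschul statistics computed for the chosen scores: lambda solves
`sum p_i p_j exp(lambda s_ij) = 1` and K is evaluated from the classical
lattice series via k-fold convolutions of the step distribution (for +1/-1
this reproduces the closed form `(q-p)^2/q`, and for +1/-2 the familiar
1.33 / 0.62 pair). Because the extension is ungapped, a diverged homolog
fragments into one HSP per inter-indel segment; the contig-level decision
therefore chains collinear non-overlapping HSPs per genome and strand and
applies the E-value to the summed score, which is what lets a few-kb contig
at 10% divergence still reach the "E-value of zero" gate, operationalised
as `E <= 1e-180`. The gate is intentionally conservative: genuine plastid
fragments shorter than ~350 bp *cannot* reach 1e-180 even as perfect
matches (a perfect 300 bp hit scores about `E ~ 1e-169`), so
perfect separation should only be expected for contigs comfortably above
that, which the 200 bp minimum-contig-length assemblies of real plastomes
easily are.

## Two-half scaffolding and the consensus

`split_reference()` cuts the reference at coordinates derived from its IR
annotation: half A runs from base 1 through IRb and `ssc_overhang` bases
into the SSC; half B starts `overlap` bp (default 3,000) before the IRb/SSC
junction and runs to the reference end. A collapsed IR contig then receives
placements on *both* halves - forward at IRb, reverse-complemented at IRa -
which is precisely how the single IR unitig becomes two IR copies.

Placement uses an anchor-chain aligner: exact 11-mer runs are chained by a
scored dynamic programme (anchored bases minus gap and diagonal-drift
penalties, so chance off-diagonal word hits never join a chain), inter-
anchor gaps are filled with Needleman-Wunsch, and terminal stretches are
aligned with overhang detection. A placement is kept at >= 70% identity
over >= 50 aligned bp - permissive enough for a 10%-diverged reference,
strict enough that random contigs never place.

The consensus is contig-only: the reference orders and orients but never
votes, which prevents reference bleed-through. Per half, placements are
stitched in reference order into a column profile; overlapping columns are
resolved by vote majority with ties going to the lexicographically smallest
base and the position logged as ambiguous; contigs that abut without a
shared column are concatenated and the join recorded as a zero-length gap.
Columns live in the *layout* space of the contigs, not in reference
coordinates - a strict per-reference-column vote would silently delete any
contig insertion relative to the diverged reference and could never return
the true genome at 100% identity. After the two half-consensi are merged
across their shared overlap, the linearised circle carries an exact
terminal direct repeat (the k-1 junction overhangs wrapped around the
origin); it is trimmed, the sequence is rotated to start at LSC base 1, and
`detect_ir()` annotates the four regions and junctions. IRa is checked
against revcomp(IRb) with a 0.1% mismatch tolerance before a warning is
raised.

`detect_ir()` itself scans the sequence against its reverse complement with
24-mer seeds, joins collinear runs allowing up to 0.1% mismatches, takes
the maximal disjoint interval pair, and polishes the ends base-by-base so
it agrees exactly with an exhaustive maximal-pair scan (the property the
test suite checks on every small fixture). On random toy genomes the
annotated IR can exceed the constructed repeat by a base or two - a real
chance extension at the junctions, not an error; the maximal pair is the
defined answer.

## Pooled SNP detection

Mapping is seeded, ungapped, full-length placement with mismatch counting,
on the circularised consensus (reads spanning the origin map across the
seam). The acceptance rule is the literal two-threshold comparison:
aligned fraction >= `length_fraction` and identity >= `similarity`; the
default is the *optimised* stringency (0.9 similarity / 0.8 length
fraction) with the initial combination (0.8 / 0.9) available as a preset.
Since the simulator plants no read-level indels, an ungapped verifier is
exact for the data the package generates; for real indel-bearing reads it
under-maps around indels, which is documented as a fidelity gap. Reads
matching both IR copies equally well are assigned uniformly at random under
a seed (`match_mode = "random"`) or discarded (`"unique"`).

Pileups count bases at or above Q13 - consistent with the trim limit - with
no quality weighting beyond that cutoff. A SNP is called where depth >=
`min_cov` (default 10) and a non-reference base reaches the minimum variant
frequency `mvf` (default 20%); indels are never called. Pool comparison
reports shared versus pool-private sites, and fixed differences use a
configurable 99% cutoff (no published figure existed; 99% tolerates one
error read in a hundred).

The packaged recovery experiment (`snp_recovery_experiment()`) plants ten
variant sites in the single-copy regions of a 10.5 kb miniature genome,
each carried by one of four haplotypes in *each* of two pools (pooled
frequency 25% per pool), sequences both pools to 200x with 0.2% error, and
scores recovery on the union of the two pools' calls - mirroring discovery
across two mapped datasets in which variation was shared between sites and
no fixed differences existed. The union matters statistically: at 200x a
true 25% allele drops below the 20% cutoff in one pool with probability
around 4-5% (binomial sampling), but in both pools independently with
probability ~0.2%, so ten-for-ten retrieval with no false positives is the
overwhelmingly expected outcome, and the 0.2% error floor cannot push any
site past 20%.

## Chlorotypes and the median-joining network

Chlorotypes concatenate each individual's alleles over the scored loci;
loci in homopolymer regions can be excluded with a blacklist before
grouping. The network follows the Bandelt median-joining scheme with
epsilon defaulting to 0: links within epsilon of the minimum-spanning
threshold (bottleneck distance from the MST) are retained; for every
connected triplet the quasi-median (per-locus majority, ties spawning all
variants, candidates processed in sorted order for determinism) is added
when it shortens the total network; the loop runs to a fixpoint and medians
that no longer shorten the network are pruned. The classical
{110, 101, 011} triplet therefore gains the 111 median and becomes a
three-edge star, and tree-like data reduce exactly to the minimum spanning
tree. The original algorithm's maximum-parsimony post-processing step is
out of scope and documented as such.

## Numerical and degenerate-input policy

Coordinates are 1-based inclusive throughout, converted only at I/O
boundaries (BED export). Ties are deterministic everywhere: leftmost-
longest trim windows, lexicographic consensus bases with ambiguity logging,
smaller k on equal N50, sorted quasi-median candidates. All randomness is
seeded and restores the caller's RNG state, so identical seeds give
byte-identical FASTQ and reports. Empty inputs return empty typed tables;
a reference without a detectable IR, a half with no placements, or halves
that fail to overlap-align are structural errors that name the stage.

## Problem sizes used in tests and the acceptance script

The packaged experiments run at miniature scale chosen to exercise every
code path with comfortable statistical margins: end-to-end assembly uses a
20.5 kb quadripartite genome (12 kb / 2.5 kb / 3 kb) at 50x error-free
coverage with a 10%-diverged reference; the SNP experiment uses a 10.5 kb
genome at 200x per pool; subsampling and module tests use 4-7 kb fixtures.
The full-length 159,514 bp layout is exercised where only construction and
IR annotation are needed. These sizes are the package's own choice of
desk-scale study conditions; nothing in the method depends on them.

## Known limitations

Pure R throughout: genome-scale inputs (150 kb references, millions of
reads) work but are slow compared to C-backed assemblers and mappers. The
assembler ignores pair distances; the mapper is ungapped; binning has no
composition adjustment or masking; SSC orientation isomers are not
resolved (the consensus reports one orientation); gap filling by local
reassembly and the reference-free assembly route are out of scope.
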