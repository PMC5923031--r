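---
title: "Curating gene models by orthogroup alignment consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating gene models by orthogroup alignment consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(genemend)
```

This vignette is the package's own account of its method: the model and
its assumptions, the parameters that matter, what the synthetic data
emulate, the numerical choices, and the design decisions taken where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## The model

The working assumption is that intron/exon structure and protein sequence
are conserved across the members of a single-copy orthogroup, so that the
most mutually consistent set of gene models — the set maximising the
protein multiple-alignment score — is the best available estimate of the
true models when no transcript evidence exists. The objective is built
from BLOSUM62: a column of an alignment with rows $c_1,\dots,c_l$ scores
$\gamma = \sum_{i<j} \mathrm{Blos}(c_i,c_j)/l$, an alignment scores
$\alpha = \sum_n \gamma(C_n)$, and the adjusted score is
$\bar\alpha = \alpha/l$ with $l$ the number of columns. Three conventions
are fixed once and tested: the denominator of $\gamma$ is the number of
rows (not the number of pairs), pairs involving a gap score 0 (which keeps
$\alpha$ additive over column ranges and makes "all gaps" a clean zero),
and the ambiguity code X scores 0 against everything.

Gene models are constrained to canonical structure: ATG starts, GT/GC
donors, AG acceptors, TAA/TGA/TAG stops, CDS length divisible by three,
no internal in-frame stop. Non-canonical motifs can be supplied through
`site_alphabet()`. All optimisation happens in coding orientation inside
a buffered gene region (default 600 bp each side, the value suited to
compact plant/fungal genomes; genomes with long introns warrant more,
e.g. 2000 bp); only I/O converts strands, which removes strand branching
from the algorithm core. Coordinates are 0-based half-open internally and
1-based inclusive in GTF; the CDS includes the stop codon and translation
drops it.

## Pipeline stages and their open choices

**Discovery.** Three passes of spliced alignment collect candidate exons:
input proteins against the other genes' regions, then the protein
sequences recovered in pass one, then the individual exon peptides from
pass one. The bundled spliced aligner translates the region in its three
forward frames, splits at stop codons, and locally aligns the query
against every open segment (BLOSUM62, gap open −11, extend −1), keeping
hits of ≥10 residues and ≥40% identity; accepted hits are split into
exon-like blocks at insertion runs of ≥8 residues, the way a spliced
aligner models introns. Hit coordinates are recovered from the aligner's
insertion/deletion ranges rather than aligned strings (the latter are an
order of magnitude slower to extract).

**Prototypes.** Frame-compatible, non-overlapping part chains are
enumerated per region with a beamed dynamic programme. The beam prior is
coverage weighted by cross-species support (the number of independent
pass-one discoveries plus the original annotation backing an exact
interval), with a flat 20 nt penalty per part so short, weakly supported
parts only chain when their coverage earns it, and a down-weight for
parts more than 60 nt outside the annotated span (buffer junk that
correlated queries can all hit). One chain per region is carried forward:
the chain whose protein maximises the summed global alignment score
against the other regions, one pass against the input proteins and one
coordinate-ascent pass against the chosen prototypes. The incumbent
annotation survives unless an alternative beats it by more than 8 score
points: marginal gains at this scale are single-residue read-through
artefacts, not structural corrections, which gain tens of points.

**Adjacency groups.** Prototype proteins are aligned; each part's column
span enters an overlap graph (edge when one part overlaps the other by at
least a third of its length, gap columns counting toward span length).
Maximal cliques are the groups. A part in several cliques goes to the
clique with the smallest order key (minimum start column), then the
largest clique, then lexicographic member ids — a deterministic rule for
a case the grouping definition leaves open. Groups are processed in
ascending (min start, min end) order.

**Growth and the choice function.** Models grow left to right, group by
group. At each junction the donor and acceptor (or the start codon, for
the first exon) are wiggled within ±30 nt; motif-valid, cleanly
translating variants form each region's option set, capped at the 12
combinations nearest the anchors. Exons under 40 bp, or without any valid
junction, are probed for removal together with their predecessor. The
multipartite choice function selects one option per region: options are
aligned (MAFFT by default; see below), a column consensus is built by
maximising $\gamma$ per column with ties resolved toward gaps (so
spurious residues never define the consensus), options are binarised
against the consensus, and the stacked columns undergo a sequential
random reduction, 1000 independent repetitions by default, the result
contained in the most columns winning. All repetitions run as one
vectorised computation: because every reduction state is the intersection
of the start column with compatible original columns, the per-repetition
state is a single bit string, and candidate screening can always use the
original column set.

The final selection among the winner's options deliberately refines the
plain highest-$\alpha$ rule, for a reason worth spelling out. $\alpha$
has no gap penalty, so a variant that reads a few codons into an intron
ties with the clean variant ($\gamma$ of its extra columns is 0), and
such read-through is weakly *conserved*: every GT donor reads as valine,
every AG acceptor tail as K/Q/E. Collective read-through can therefore
genuinely out-score the truth by a few points — the precise failure mode
the change filters exist for. Three measures keep the selection sharp:
the enumeration pool per region is the winner's options plus near-winners
(within 3 agreement bits) plus always the most parsimonious option; the
decision score is $\alpha$ minus 0.3 per gapped cell in mixed columns;
and near-ties (within 2) resolve to the fewest residues before the seeded
RNG. Reported scores remain plain $\alpha$.

**Second pass, filters, reconstruction, polish.** New junctions are
compared against the original ones: per intron locus the option set is
{new, original} (paired when both ends lie within the wiggle window),
unpaired originals offer re-insertion, unpaired new introns removal, and
a differing original start a restored start; the choice function decides,
iterated to a fixed point. Structurally invalid candidates (an original
junction without a splice motif) never compete. Every localised change
(a maximal run of bases whose exonic state differs) is then judged *in
isolation*: the variant model carries only that change on the otherwise
original orthogroup background, which prevents a rejected spurious
neighbour from poisoning the flanks of a genuine change. The four
criteria: flanking 10-residue $\alpha$ non-decreasing; no gaps opened in
three or more sequences; micro-changes (≤2 residues, gapless to gapless)
discarded and larger gapless changes requiring $\Delta\alpha \ge 4$; and
the changed region plus its 5-residue flanks reaching $\bar\alpha \ge 3$
(or all gaps) for some three-sequence subset containing the changed one.
Rejected changes are reverted by splicing the original exonic state over
the rejected interval; a reconstructed model failing structural
validation falls back to the original annotation. Changed genes — and
genes whose structural proposals (exon/intron gain or loss, moved start)
were rejected — then have their junctions re-wiggled against the
filtered, now-clean context and are re-filtered, iterated to a fixed
point: this unwinds the collective read-through artefacts that distorted
the first-round proposals. One rule sits above the filters: a
structurally invalid input is never preferred over a valid correction, so
full-rejection identity holds for valid inputs and flagged valid
replacements stand in for broken ones.

## Alignment backends

MAFFT (auto mode; `--add` for reference extension) is the default
alignment backend when the binary is on the PATH. The bundled fallback is
a deterministic centre-star progressive aligner over Needleman–Wunsch
pairwise alignments (BLOSUM62, gap open −6, extend −1, centre = longest
sequence), adequate for pairwise-close sequences but not for the
60-option alignments the choice function builds — which is why the
external tool is the default rather than an option. Every backend call
falls back to the internal aligner with a warning on failure, and the
degapped rows of any output always reproduce the inputs exactly.
"Inconsistent regions" re-aligned during consensus construction are
maximal column runs with $\gamma < 0$ or gap fraction above one half — a
stated heuristic for a step whose criterion the method leaves open.

## The synthetic test bed

`generate_orthogroup()` emulates single-copy orthogroups with conserved
structure: an ancestral protein (default three exons of 60–90 nt) is
mutated per species at 5% per site, reverse-translated with a fixed
preferred-codon table (codon bias is deliberately not modelled), and
interrupted by introns at shared phase-0 positions. Introns fix only the
biologically constrained bases — GTN donor codon, [ACG]AG acceptor codon
— and are stop-free in frame with length divisible by three, so a
retained intron stays translatable (the realistic form of that
annotation error; an annotator would not emit a model with internal
stops). Genes alternate strands and sit in 750 nt random flanks, larger
than the default buffer. A methionine is planted four codons downstream
of the start as a decoy for the start-displacement error. Four error
classes mirror common annotation mistakes: frame-preserving boundary
shifts of 3–15 nt, internal exon deletion, intron deletion (merged
exons), and a start moved to the next in-frame ATG.

What passing tests on this bed do and do not show: the generator has no
paralogs, no indels within exons, no sequencing errors, no alternative
isoforms, uniform synthetic coverage, and species at uniform moderate
divergence. Recovery rates measured on it characterise the algorithm
under its own assumptions, not performance on any real genome.

Matched evaluation data come from `synth_rnaseq()`: exonic bases at the
requested depth, elsewhere `depth × noise`, junctions at the true introns.
By construction a truth model scores junction F = 1 and coverage = 1 on
its own data — the round-trip the evaluation tests assert.

## Problem sizes and numerical choices

The acceptance suite runs 50 orthogroups per error class plus 50 clean
controls (5 species, 3 exons, the generator defaults above), 100 random
choice-function instances (≤4 regions × ≤4 variants, proteins ≤30
residues, where exhaustive enumeration is tractable and, for equal-length
substitution variants, closed-form), 200 random alignments against a
pair-loop scoring oracle, and 100 random overlap graphs of ≤12 nodes
against subset-enumeration clique finding. Scoring comparisons use
tolerance 1e-9; entropy worked values 0.005. Random tie-breaks draw from
one RNG seeded by `run_config(seed = )` (default 42), making whole-pipeline
runs bit-reproducible; the reduction samples are independent seeded
restarts.

## Known limitations

Single best model per gene (no isoforms); fusion/fission surfaces only as
exon deletions; frameshift-type errors and reference-sequence indels are
out of scope; discovery cannot see exons absent from every annotation and
too diverged for local alignment; and the filters are deliberately
conservative — they trade recall for a low false-change rate, so some
genuine errors survive untouched, flagged by an unchanged status.
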