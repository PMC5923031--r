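# genemend

Cross-species refinement of protein-coding gene models by alignment
consensus.

## The problem

Computational genome annotation routinely gets the intron/exon structure
of genes wrong: exons are dropped or invented, splice boundaries drift,
introns are retained, and start codons land on the wrong in-frame ATG.
RNA-seq evidence fixes many of these mistakes but is often unavailable or
incomplete. `genemend` exploits a different source of evidence:
evolutionary conservation. For an *orthogroup* — one annotated gene per
species, all descended from a single ancestral gene — the gene models that
maximise the agreement of the aligned protein sequences across species are
far more likely to be correct than disparate alternatives. The package
corrects each gene's CDS coordinates (GTF in, GTF out) so that this
agreement is maximised, subject to canonical gene-structure constraints
(ATG starts, GT/GC donors, AG acceptors, TAA/TGA/TAG stops, no in-frame
stops), and ships the matching evaluation metrics.

## The objective and the algorithm

A protein multiple alignment A is scored column-wise with BLOSUM62:

- column score:  γ(C) = Σ_{i<j} Blos(c_i, c_j) / l   (l = rows)
- alignment score:  α(A) = Σ_n γ(C_n)
- adjusted score:  ᾱ = α / l   (l = columns)

For each gene a buffered *gene region* (default ±600 bp) is extracted in
coding orientation. Candidate exons ("gene parts") are discovered by
three passes of cross-species spliced alignment of protein queries against
all regions, pooled with the annotated exons, and assembled into prototype
models. The parts are partitioned into *adjacency groups* — maximal
cliques of an overlap graph on alignment coordinates (two exons are
connected when one overlaps the other by at least a third of its length) —
and added left to right. At every junction the splice sites (or start
codon) are "wiggled" within a ±30 nt window, and one variant per species
is selected with a *multipartite choice function*: options are aligned,
a column-wise consensus is built, options are binarised against it, and a
sequential random reduction (default 1000 repetitions) finds the option
subset that agrees with the most alignment columns, ties resolved by α.
New junctions are then re-evaluated against the original ones, and every
change must pass four conservative filters (non-decreasing flanking α, no
gap opening in three or more sequences, no micro-changes, adequate local
alignment quality) before the final models are reconstructed.

Evaluation metrics from the same framework:

- junction F-score: harmonic mean of the direction-aware overlap fractions
  between a model's intron boundaries and RNA-seq junctions with ≥10 reads;
- coverage score: mean per-feature agreement between exon/intron labels
  and per-base on/off classification against a rolling threshold χ/5,
  with χ(x) = min(max ρ left of x, max ρ right of x);
- orthogroup localisation entropy: Shannon entropy (base 2) of the
  predicted subcellular localisation categories across the orthogroup.

## A worked example

```r
library(genemend)

# a 5-species orthogroup with known truth, one gene corrupted by an
# exon deletion
og  <- generate_orthogroup(n_species = 5, n_exons = 3, seed = 21)
bad <- perturb_model(og, 3, "exon_delete")
entries <- lapply(1:5, function(s)
  list(model = if (s == 3) bad else og$species[[s]]$model,
       genome = og$species[[s]]$genome))

res <- run_pipeline(entries, run_config(seed = 42))
res$status
#> [1] "unchanged" "unchanged" "updated"   "unchanged" "unchanged"
subset(res$report, keep)
#>   gene_id   category start end keep reason  status
#> 1     sp3 exon added   774 834 TRUE   pass updated
identical(unname(res$models[[3]]$exons), unname(og$species[[3]]$model$exons))
#> [1] TRUE
```

The report row says an exon spanning region coordinates 774–834 was added
back to gene `sp3` and survived all four filters; the corrected model is
coordinate-identical to the truth the fixture was generated from. The
other four genes pass through untouched.

The same pipeline runs from the shell on a tab-delimited manifest of
(GTF, genome FASTA) pairs:

```sh
Rscript inst/cli/genemend run --manifest manifest.tsv --out results/
Rscript inst/cli/genemend eval --metric junction --gtf gene.gtf --genome genome.fa \
    --junctions junctions.tsv
Rscript inst/cli/genemend simulate --out sim/ --n-orthogroups 5 --error-class exon_delete
```

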