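# shared helpers for building tiny deterministic fixtures in code

# a gene_region directly from a sequence string (plus strand, full contig)
region_from_seq <- function(seq, strand = "+") {
  structure(list(seq = toupper(seq), contig = "ctg", strand = strand,
                 g_start = 0L, g_end = nchar(seq), buffer = 0L),
            class = "gene_region")
}

# encode a protein with the generator's preferred codons (no stop appended)
encode_protein <- function(protein) {
  codons <- genemend:::preferred_codons()
  paste(codons[strsplit(protein, "")[[1L]]], collapse = "")
}

# exon matrix helper
ex <- function(...) {
  matrix(as.integer(c(...)), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

# orthogroup -> pipeline entries, optionally with one perturbed gene
og_entries <- function(og, target = NULL, class = NULL) {
  lapply(seq_along(og$species), function(s) {
    model <- if (!is.null(target) && s == target) {
      perturb_model(og, s, class)
    } else {
      og$species[[s]]$model
    }
    list(model = model, genome = og$species[[s]]$genome)
  })
}

# all ways to partition n indistinguishable genes into at most k non-empty
# category sizes (used as a brute-force oracle for the entropy maximum)
partitions_of <- function(n, k, max_part = n) {
  if (n == 0L) return(list(integer()))
  if (k == 0L) return(list())
  out <- list()
  for (first in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - first, k - 1L, first)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}
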