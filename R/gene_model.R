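#' Gene models, gene regions and site alphabets
#'
#' A `gene_model` stores the CDS structure of one gene: an ordered set of
#' exon intervals on a contig, strand-aware. Coordinates are held 0-based
#' half-open internally; GTF I/O converts to and from 1-based inclusive.
#' The CDS is taken to include the terminal stop codon; translation drops
#' it.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per exon, sorted by genomic coordinate.
#' @param variants Optional list of alternative exon matrices (transcript
#'   variants sharing the gene id); the primary structure is `exons`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, variants = NULL) {
  exons <- as_exon_matrix(exons)
  if (nrow(exons) == 0L) stop("gene model '", gene_id, "' has no exons")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("gene model '", gene_id, "': exon with non-positive length")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene model '", gene_id, "': overlapping exons")
  variants <- lapply(variants, as_exon_matrix)
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons, variants = variants),
            class = "gene_model")
}

as_exon_matrix <- function(x) {
  m <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model ", x$gene_id, ": ", x$contig, " (", x$strand, "), ",
      nrow(x$exons), " exon(s), CDS ", sum(x$exons[, 2L] - x$exons[, 1L]),
      " nt", sep = "")
  if (length(x$variants)) cat(", ", length(x$variants), " variant(s)", sep = "")
  cat("\n")
  invisible(x)
}

model_span <- function(model) c(min(model$exons[, 1L]), max(model$exons[, 2L]))
model_cds_length <- function(model) sum(model$exons[, 2L] - model$exons[, 1L])

#' Site alphabet for gene-model construction
#'
#' The motif constraints used when building and validating models: ATG
#' start codons, GT/GC splice donors, AG acceptors and TAA/TGA/TAG stops by
#' default. Non-canonical sites can be supplied.
#'
#' @param starts,donors,acceptors,stops Character vectors of DNA motifs
#'   (starts/stops are trinucleotides, donors/acceptors dinucleotides).
#' @return An object of class `site_alphabet`.
#' @export
site_alphabet <- function(starts = "ATG", donors = c("GT", "GC"),
                          acceptors = "AG", stops = c("TAA", "TGA", "TAG")) {
  chk <- function(x, n, what) {
    x <- toupper(x)
    if (!length(x)) stop("empty ", what, " set")
    if (any(nchar(x) != n) || any(grepl("[^ACGT]", x)))
      stop(what, " motifs must be DNA strings of length ", n)
    x
  }
  structure(list(starts = chk(starts, 3L, "start"),
                 donors = chk(donors, 2L, "donor"),
                 acceptors = chk(acceptors, 2L, "acceptor"),
                 stops = chk(stops, 3L, "stop")),
            class = "site_alphabet")
}

#' Extract a buffered gene region
#'
#' Returns the genomic window spanning all candidate models of a gene plus
#' `buffer` bases each side, clamped to the contig, as a sequence in coding
#' orientation: minus-strand genes are reverse-complemented so that all
#' downstream optimisation is strand-free.
#'
#' @param model A [gene_model()] (its `variants` are included in the span).
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param buffer Bases added each side (default 600).
#' @return An object of class `gene_region` with elements `seq` (character,
#'   coding orientation), `contig`, `strand`, `g_start`, `g_end` (0-based
#'   half-open genomic span) and `buffer`.
#' @export
extract_gene_region <- function(model, genome, buffer = 600L) {
  if (buffer < 0L) stop("buffer must be >= 0")
  contig_seq <- get_contig(genome, model$contig)
  clen <- nchar(contig_seq)
  spans <- c(list(model$exons), model$variants)
  lo <- min(vapply(spans, function(e) min(e[, 1L]), integer(1)))
  hi <- max(vapply(spans, function(e) max(e[, 2L]), integer(1)))
  g_start <- max(0L, lo - as.integer(buffer))
  g_end <- min(clen, hi + as.integer(buffer))
  s <- substr(contig_seq, g_start + 1L, g_end)
  if (model$strand == "-") s <- revcomp(s)
  structure(list(seq = toupper(s), contig = model$contig,
                 strand = model$strand, g_start = g_start, g_end = g_end,
                 buffer = as.integer(buffer)),
            class = "gene_region")
}

#' @export
print.gene_region <- function(x, ...) {
  cat("gene_region: ", x$contig, ":", x$g_start, "-", x$g_end, " (", x$strand,
      "), ", nchar(x$seq), " nt, buffer ", x$buffer, "\n", sep = "")
  invisible(x)
}

get_contig <- function(genome, contig) {
  if (inherits(genome, "DNAStringSet")) {
    if (!contig %in% names(genome))
      stop("contig '", contig, "' absent from genome")
    return(as.character(genome[[contig]]))
  }
  if (!contig %in% names(genome))
    stop("contig '", contig, "' absent from genome")
  toupper(genome[[contig]])
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

region_length <- function(region) nchar(region$seq)

#' Map region-local coordinates to genomic coordinates
#'
#' Region-local positions are 0-based along the coding-orientation sequence;
#' genomic positions are 0-based on the plus strand. The mapping is a
#' bijection over the region on both strands. `genomic_to_region` is its
#' inverse.
#'
#' @param region A [gene_region()].
#' @param pos Integer vector of 0-based base positions.
#' @return Integer vector of mapped 0-based positions.
#' @export
region_to_genomic <- function(region, pos) {
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= region_length(region)))
    stop("position outside region")
  if (region$strand == "+") region$g_start + pos else region$g_end - 1L - pos
}

#' @rdname region_to_genomic
#' @export
genomic_to_region <- function(region, pos) {
  pos <- as.integer(pos)
  if (any(pos < region$g_start | pos >= region$g_end))
    stop("position outside region")
  if (region$strand == "+") pos - region$g_start else region$g_end - 1L - pos
}

# interval versions: m is a matrix [start, end) in one system; returns the
# interval in the other system, still [start, end) with start < end.
region_interval_to_genomic <- function(region, m) {
  m <- as_exon_matrix(m)
  if (region$strand == "+") {
    cbind(start = region$g_start + m[, 1L], end = region$g_start + m[, 2L])
  } else {
    cbind(start = region$g_end - m[, 2L], end = region$g_end - m[, 1L])
  }
}

genomic_interval_to_region <- function(region, m) {
  m <- as_exon_matrix(m)
  if (region$strand == "+") {
    cbind(start = m[, 1L] - region$g_start, end = m[, 2L] - region$g_start)
  } else {
    cbind(start = region$g_end - m[, 2L], end = region$g_end - m[, 1L])
  }
}

# model exons in region coordinates, ascending along coding orientation
model_exons_region <- function(model, region) {
  m <- genomic_interval_to_region(region, model$exons)
  m[order(m[, 1L]), , drop = FALSE]
}

# build a gene_model back from region-coordinate exons
model_from_region_exons <- function(region, exons_r, gene_id) {
  g <- region_interval_to_genomic(region, exons_r)
  gene_model(gene_id, region$contig, region$strand, g)
}

region_exon_seq <- function(region, exons_r) {
  paste(substring(region$seq, exons_r[, 1L] + 1L, exons_r[, 2L]), collapse = "")
}

# --- translation -----------------------------------------------------------

codon_table <- function() {
  if (is.null(.genemend_env$codons)) {
    .genemend_env$codons <- Biostrings::GENETIC_CODE
  }
  .genemend_env$codons
}

# translate a CDS nucleotide string; returns list(protein, internal_stop,
# incomplete). Terminal stop (if present) is dropped from the protein.
translate_cds <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n == 0L) return(list(protein = "", internal_stop = FALSE, incomplete = FALSE))
  incomplete <- (n %% 3L) != 0L
  n3 <- n - (n %% 3L)
  if (n3 == 0L) return(list(protein = "", internal_stop = FALSE, incomplete = TRUE))
  starts <- seq.int(1L, n3 - 2L, 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(codon_table()[codons])
  aa[is.na(aa)] <- "X"
  k <- length(aa)
  terminal_stop <- aa[k] == "*" && !incomplete
  if (terminal_stop) aa <- aa[-k]
  internal_stop <- any(aa == "*")
  list(protein = paste(aa, collapse = ""), internal_stop = internal_stop,
       incomplete = incomplete)
}

#' Translate a gene model within its region
#'
#' Concatenates the exon sequence in coding orientation and translates it
#' with the standard genetic code, dropping the terminal stop codon.
#'
#' @param model A [gene_model()].
#' @param region The matching [gene_region()].
#' @return A list with `protein` (amino-acid string), `internal_stop` and
#'   `incomplete` (non-triplet CDS length) failure flags.
#' @export
translate_model <- function(model, region) {
  ex <- model_exons_region(model, region)
  if (any(ex[, 1L] < 0L) || any(ex[, 2L] > region_length(region)))
    stop("model coordinates outside region")
  translate_cds(region_exon_seq(region, ex))
}

#' Structurally validate a gene model
#'
#' Checks the construction constraints: start codon in the start set, every
#' intron beginning with a donor motif and ending with an acceptor motif,
#' the final codon in the stop set, CDS length divisible by three and no
#' internal in-frame stop codon. Violations are reported as data, not
#' raised.
#'
#' @param model A [gene_model()].
#' @param region The matching [gene_region()].
#' @param alphabet A [site_alphabet()].
#' @return A list with `valid` (logical) and `violations` (character
#'   vector, empty when valid).
#' @export
validate_model <- function(model, region, alphabet = site_alphabet()) {
  ex <- model_exons_region(model, region)
  v <- character()
  s <- region$seq
  first3 <- substring(s, ex[1L, 1L] + 1L, ex[1L, 1L] + 3L)
  if (!first3 %in% alphabet$starts)
    v <- c(v, sprintf("start codon '%s' not in {%s}", first3,
                      paste(alphabet$starts, collapse = ",")))
  if (nrow(ex) > 1L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      don <- substring(s, ex[i, 2L] + 1L, ex[i, 2L] + 2L)
      acc <- substring(s, ex[i + 1L, 1L] - 1L, ex[i + 1L, 1L])
      if (!don %in% alphabet$donors)
        v <- c(v, sprintf("intron %d donor '%s' not in {%s}", i, don,
                          paste(alphabet$donors, collapse = ",")))
      if (!acc %in% alphabet$acceptors)
        v <- c(v, sprintf("intron %d acceptor '%s' not in {%s}", i, acc,
                          paste(alphabet$acceptors, collapse = ",")))
    }
  }
  cds <- region_exon_seq(region, ex)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    v <- c(v, sprintf("CDS length %d not divisible by 3", n))
  } else {
    last3 <- substring(cds, n - 2L, n)
    if (!last3 %in% alphabet$stops)
      v <- c(v, sprintf("final codon '%s' not in {%s}", last3,
                        paste(alphabet$stops, collapse = ",")))
    tr <- translate_cds(cds)
    if (tr$internal_stop) v <- c(v, "internal in-frame stop codon")
  }
  list(valid = length(v) == 0L, violations = v)
}
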