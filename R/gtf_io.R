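#' Read a single-gene GTF (or GFF3 CDS dialect)
#'
#' Parses the CDS features of one gene from a GTF file. Coordinates are
#' converted from 1-based inclusive to the package's 0-based half-open
#' convention. Multiple `transcript_id`s are merged as variants of a single
#' gene; the variant with the longest total CDS becomes the primary
#' structure. GFF3-style attribute syntax (`ID=`/`Parent=`) is accepted as
#' a reader dialect for files holding the CDS lines of a single gene.
#'
#' @param path GTF file path.
#' @return A [gene_model()].
#' @export
read_gene_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, " in '", path, "': expected 9 tab-separated fields")
    if (!(tolower(f[[3L]]) %in% c("cds"))) next
    start <- suppressWarnings(as.integer(f[[4L]]))
    end <- suppressWarnings(as.integer(f[[5L]]))
    if (is.na(start) || is.na(end) || start > end)
      stop("malformed GTF line ", i, " in '", path, "': bad coordinates")
    if (!f[[7L]] %in% c("+", "-"))
      stop("malformed GTF line ", i, " in '", path, "': bad strand '", f[[7L]], "'")
    at <- parse_attributes(f[[9L]])
    rows[[length(rows) + 1L]] <- list(
      contig = f[[1L]], start = start - 1L, end = end, strand = f[[7L]],
      gene_id = at$gene_id, transcript_id = at$transcript_id)
  }
  if (!length(rows)) stop("no CDS features in '", path, "'")
  contig <- unique(vapply(rows, `[[`, "", "contig"))
  strand <- unique(vapply(rows, `[[`, "", "strand"))
  if (length(contig) != 1L || length(strand) != 1L)
    stop("'", path, "' mixes contigs or strands; one gene per GTF expected")
  gene_ids <- unique(vapply(rows, `[[`, "", "gene_id"))
  gene_ids <- gene_ids[!is.na(gene_ids)]
  gene_id <- if (length(gene_ids)) gene_ids[[1L]] else
    tools::file_path_sans_ext(basename(path))
  tx <- vapply(rows, function(r) r$transcript_id %||% gene_id, "")
  exon_sets <- lapply(split(rows, tx), function(rs) {
    m <- cbind(start = vapply(rs, `[[`, 0L, "start"),
               end = vapply(rs, `[[`, 0L, "end"))
    m[order(m[, 1L]), , drop = FALSE]
  })
  lens <- vapply(exon_sets, function(m) sum(m[, 2L] - m[, 1L]), 0L)
  primary <- which.max(lens)
  variants <- if (length(exon_sets) > 1L) unname(exon_sets[-primary]) else NULL
  gene_model(gene_id, contig, strand, exon_sets[[primary]], variants = variants)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

parse_attributes <- function(s) {
  out <- list(gene_id = NA_character_, transcript_id = NA_character_)
  if (grepl("\"", s)) {                       # GTF dialect: key "value";
    m <- regmatches(s, gregexpr('(\\w+)\\s+"([^"]*)"', s))[[1L]]
    for (kv in m) {
      key <- sub('\\s+.*$', "", kv)
      val <- sub('^[^"]*"([^"]*)".*$', "\\1", kv)
      if (key == "gene_id") out$gene_id <- val
      if (key == "transcript_id") out$transcript_id <- val
    }
  } else if (grepl("=", s, fixed = TRUE)) {   # GFF3 dialect
    kvs <- strsplit(s, ";", fixed = TRUE)[[1L]]
    for (kv in kvs) {
      kv <- trimws(kv)
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      if (key %in% c("gene_id", "ID")) out$gene_id <- out$gene_id %||% val
      if (key %in% c("transcript_id", "Parent")) out$transcript_id <- val
    }
    if (!is.na(out$transcript_id) && is.na(out$gene_id))
      out$gene_id <- out$transcript_id
  }
  out
}

#' Read an orthogroup manifest
#'
#' The manifest is a tab-delimited file with one line per gene: the path to
#' that gene's GTF, a tab, and the path to the genome FASTA it refers to.
#' Relative paths are resolved against the manifest's directory. Genome
#' FASTAs are read once and cached per call.
#'
#' @param path Manifest file path.
#' @return A list with one element per line, each a list of `model`
#'   ([gene_model()]) and `genome` (named character vector of contigs).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  base <- dirname(normalizePath(path))
  genomes <- new.env(parent = emptyenv())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L)
      stop("manifest line ", i, ": expected two tab-separated paths")
    gtf <- resolve_path(f[[1L]], base)
    fasta <- resolve_path(f[[2L]], base)
    if (!file.exists(gtf)) stop("manifest line ", i, ": GTF not found: ", gtf)
    if (!file.exists(fasta)) stop("manifest line ", i, ": FASTA not found: ", fasta)
    model <- read_gene_gtf(gtf)
    key <- normalizePath(fasta)
    if (is.null(genomes[[key]])) genomes[[key]] <- read_genome_fasta(fasta)
    genome <- genomes[[key]]
    if (!model$contig %in% names(genome))
      stop("manifest line ", i, ": contig '", model$contig,
           "' absent from FASTA '", fasta, "'")
    out[[i]] <- list(model = model, genome = genome)
  }
  out
}

resolve_path <- function(p, base) {
  if (grepl("^(/|~)", p)) p else file.path(base, p)
}

read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  out <- as.character(x)
  names(out) <- names(x)
  toupper(out)
}

#' Write corrected gene models
#'
#' Writes one GTF per gene (CDS features, 1-based inclusive, ascending
#' coordinates) plus one amino-acid FASTA and one CDS FASTA for the whole
#' orthogroup. Written GTFs round-trip losslessly through
#' [read_gene_gtf()].
#'
#' @param models List of [gene_model()]s.
#' @param regions Matching list of [gene_region()]s (used for sequence
#'   output).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(models, regions, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  paths <- character()
  aa <- character()
  cds <- character()
  for (i in seq_along(models)) {
    m <- models[[i]]
    p <- file.path(out_dir, paste0(m$gene_id, ".gtf"))
    writeLines(format_gtf(m), p)
    paths <- c(paths, p)
    ex <- model_exons_region(m, regions[[i]])
    nt <- region_exon_seq(regions[[i]], ex)
    cds <- c(cds, paste0(">", m$gene_id), nt)
    aa <- c(aa, paste0(">", m$gene_id), translate_cds(nt)$protein)
  }
  aa_path <- file.path(out_dir, "orthogroup.aa.fasta")
  cds_path <- file.path(out_dir, "orthogroup.cds.fasta")
  writeLines(aa, aa_path)
  writeLines(cds, cds_path)
  invisible(c(paths, aa_path, cds_path))
}

format_gtf <- function(model, source = "genemend") {
  ex <- model$exons
  sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          model$contig, source, ex[, 1L] + 1L, ex[, 2L], model$strand,
          model$gene_id, model$gene_id)
}

#' Write a gene model as a GTF file
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @export
write_gene_gtf <- function(model, path) {
  writeLines(format_gtf(model), path)
  invisible(path)
}

write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}
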