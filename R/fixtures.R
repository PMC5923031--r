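#' Synthetic orthogroups with known truth
#'
#' Generates a single-copy orthogroup of `n_species` genes that share a
#' conserved exon structure: an ancestral protein is sampled, mutated
#' independently per species at `sub_rate` substitutions per site,
#' reverse-translated with a fixed preferred-codon table, and split into
#' exons at shared phase-0 positions. Introns carry canonical GT...AG
#' motifs, have lengths divisible by three and contain no stop codon in
#' the reading frame, so a retained intron stays translatable (the
#' annotation-error case the perturbations exercise). Genes sit on
#' alternating strands inside random intergenic flanks larger than the
#' default region buffer. A methionine is planted a few codons downstream
#' of the start to provide a plausible decoy start codon.
#'
#' @param n_species Number of species/genes (default 5).
#' @param n_exons Exons per gene (default 3).
#' @param exon_len Range of exon lengths in nt, rounded to codons
#'   (default c(60, 90)).
#' @param intron_len Range of intron lengths in nt, rounded to codons
#'   (default c(60, 90)).
#' @param sub_rate Per-site amino-acid substitution probability (default
#'   0.05).
#' @param flank Intergenic flank each side in nt (default 750, larger than
#'   the 600 bp buffer).
#' @param seed Optional RNG seed for a self-contained draw.
#' @return An object of class `orthogroup`: a list with `species`, each
#'   holding `model` ([gene_model()]), `genome`, `protein` and
#'   coding-orientation truth coordinates.
#' @export
generate_orthogroup <- function(n_species = 5L, n_exons = 3L,
                                exon_len = c(60L, 90L), intron_len = c(60L, 90L),
                                sub_rate = 0.05, flank = 750L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_species < 2L) stop("need at least two species")
  if (n_exons < 1L) stop("need at least one exon")
  exon_nt <- round_codon(sample_range(exon_len, n_exons))
  if (any(exon_nt < 24L)) stop("exon length range too small (need >= 24 nt)")
  intron_nt <- if (n_exons > 1L) round_codon(sample_range(intron_len, n_exons - 1L))
               else integer()
  if (n_exons > 1L && any(intron_nt < 12L))
    stop("intron length range too small (need >= 12 nt)")
  n_aa <- sum(exon_nt) %/% 3L
  aas <- setdiff(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1L]], NULL)
  anc <- sample(aas, n_aa, replace = TRUE)
  anc[[1L]] <- "M"
  anc[[5L]] <- "M"                      # decoy in-frame start 12 nt downstream
  species <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    prot <- anc
    mut <- which(stats::runif(n_aa) < sub_rate)
    mut <- setdiff(mut, c(1L, 5L))
    for (p in mut) prot[[p]] <- sample(setdiff(aas, prot[[p]]), 1L)
    cds <- c(vapply(prot, function(a) preferred_codons()[[a]], ""), "TAA")
    cds <- paste(cds, collapse = "")
    # split into exons; last exon carries the stop codon
    exon_nt_i <- exon_nt
    exon_nt_i[n_exons] <- exon_nt_i[n_exons] + 3L
    cuts <- cumsum(exon_nt_i)
    exon_seqs <- substring(cds, c(1L, cuts[-n_exons] + 1L), cuts)
    introns <- vapply(intron_nt, random_intron, "")
    gene_nt <- paste(as.vector(rbind(exon_seqs, c(introns, "")))[
      seq_len(2L * n_exons - 1L)], collapse = "")
    construct <- paste0(random_dna(flank), gene_nt, random_dna(flank))
    # coding-orientation exon coordinates within the construct
    starts <- flank + c(0L, cumsum(exon_nt_i[-n_exons] + intron_nt))
    exons_c <- cbind(start = starts, end = starts + exon_nt_i)
    strand <- if (i %% 2L == 0L) "-" else "+"
    contig <- paste0("chr_sp", i)
    L <- nchar(construct)
    if (strand == "+") {
      contig_seq <- construct
      exons_g <- exons_c
    } else {
      contig_seq <- revcomp(construct)
      exons_g <- cbind(start = L - exons_c[, 2L], end = L - exons_c[, 1L])
    }
    genome <- stats::setNames(contig_seq, contig)
    model <- gene_model(paste0("sp", i), contig, strand, exons_g)
    species[[i]] <- list(model = model, genome = genome,
                         protein = paste(prot, collapse = ""),
                         construct = construct, exons_construct = exons_c,
                         strand = strand, flank = flank)
  }
  structure(list(species = species,
                 params = list(n_species = n_species, n_exons = n_exons,
                               exon_nt = exon_nt, intron_nt = intron_nt,
                               sub_rate = sub_rate, flank = flank)),
            class = "orthogroup")
}

sample_range <- function(rng, n) {
  rng <- as.integer(rng)
  if (length(rng) == 1L) rng <- c(rng, rng)
  if (rng[2L] < rng[1L]) stop("bad length range")
  vals <- seq.int(rng[1L], rng[2L])
  vals[sample.int(length(vals), n, replace = TRUE)]
}

round_codon <- function(x) pmax(3L, as.integer(round(x / 3)) * 3L)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# safe (stop-free) codons for intron interiors
safe_codons <- function() {
  if (is.null(.genemend_env$safe_codons)) {
    all3 <- names(codon_table())
    .genemend_env$safe_codons <- all3[codon_table() != "*"]
  }
  .genemend_env$safe_codons
}

# GT...AG intron, length divisible by 3, no in-frame stop codon; only the
# biologically constrained bases are fixed (GT donor, AG acceptor), the
# rest is random so read-through translations diverge between species
random_intron <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 12L)
  n_mid <- len %/% 3L - 2L
  first <- paste0("GT", sample(c("A", "C", "G", "T"), 1L))
  last <- sample(c("AAG", "CAG", "GAG"), 1L)    # TAG excluded: in-frame stop
  mid <- sample(safe_codons(), n_mid, replace = TRUE)
  paste(c(first, mid, last), collapse = "")
}

preferred_codons <- function() {
  c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
    H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
    P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
    W = "TGG", Y = "TAT")
}

#' Plant a single annotation error in a truth gene model
#'
#' Produces a corrupted but syntactically legal gene model for one species
#' of a generated orthogroup. Error classes mirror the common annotation
#' mistakes: `boundary_shift` moves one internal splice junction by a
#' frame-preserving 3-15 nt; `exon_delete` drops an internal exon from the
#' annotation; `intron_delete` merges two adjacent exons (a retained
#' intron); `start_move` moves the start codon to the next in-frame ATG
#' downstream.
#'
#' @param og An [generate_orthogroup()] result.
#' @param species Index of the species to corrupt.
#' @param class One of `"boundary_shift"`, `"exon_delete"`,
#'   `"intron_delete"`, `"start_move"`.
#' @return The corrupted [gene_model()].
#' @export
perturb_model <- function(og, species,
                          class = c("boundary_shift", "exon_delete",
                                    "intron_delete", "start_move")) {
  class <- match.arg(class)
  sp <- og$species[[species]]
  ex <- sp$exons_construct
  n <- nrow(ex)
  if (class == "boundary_shift") {
    if (n < 2L) stop("boundary_shift needs a spliced gene")
    for (try in 1:50) {
      j <- if (n == 2L) 1L else sample(n - 1L, 1L)
      side <- sample(c("donor", "acceptor"), 1L)
      delta <- sample(c(-1L, 1L), 1L) * 3L * sample(1:5, 1L)
      ex2 <- ex
      if (side == "donor") {
        newend <- ex[j, 2L] + delta
        if (newend >= ex[j, 1L] + 9L && newend <= ex[j + 1L, 1L] - 12L) {
          ex2[j, 2L] <- newend
          return(rebuild_model(sp, ex2))
        }
      } else {
        newstart <- ex[j + 1L, 1L] + delta
        if (newstart >= ex[j, 2L] + 12L && newstart <= ex[j + 1L, 2L] - 9L) {
          ex2[j + 1L, 1L] <- newstart
          return(rebuild_model(sp, ex2))
        }
      }
    }
    stop("could not place a boundary shift")
  }
  if (class == "exon_delete") {
    if (n < 2L) stop("cannot delete an exon from a single-exon gene")
    j <- if (n == 2L) 2L else {
      js <- seq.int(2L, n - 1L)
      js[sample.int(length(js), 1L)]
    }
    return(rebuild_model(sp, ex[-j, , drop = FALSE]))
  }
  if (class == "intron_delete") {
    if (n < 2L) stop("intron_delete needs a spliced gene")
    j <- if (n == 2L) 1L else sample(n - 1L, 1L)
    ex2 <- ex[-(j + 1L), , drop = FALSE]
    ex2[j, 2L] <- ex[j + 1L, 2L]
    return(rebuild_model(sp, ex2))
  }
  # start_move: next in-frame ATG strictly downstream of the start
  s <- ex[1L, 1L]
  limit <- ex[1L, 2L] - 6L
  pos <- seq.int(s + 3L, limit, 3L)
  codons <- substring(sp$construct, pos + 1L, pos + 3L)
  hit <- pos[codons == "ATG"]
  if (!length(hit)) stop("no downstream in-frame ATG available")
  ex2 <- ex
  ex2[1L, 1L] <- hit[[1L]]
  rebuild_model(sp, ex2)
}

rebuild_model <- function(sp, exons_c) {
  L <- nchar(sp$construct)
  exons_g <- if (sp$strand == "+") exons_c else
    cbind(start = L - exons_c[, 2L], end = L - exons_c[, 1L])
  gene_model(sp$model$gene_id, sp$model$contig, sp$strand, exons_g)
}

#' Synthetic coverage and junction tables for a gene
#'
#' Emulates the tabular outputs of a pileup plus a splice-junction
#' extractor for one gene region: exonic bases of the truth model get
#' `depth` reads, all other region bases `round(depth * noise)`, and every
#' truth intron contributes a directed junction pair supported by `depth`
#' reads.
#'
#' @param model Truth [gene_model()].
#' @param region The matching [gene_region()].
#' @param depth Exonic read depth (default 50).
#' @param noise Intronic/intergenic depth as a fraction of `depth`
#'   (default 0).
#' @return List with `rho` (per-base counts along the region, coding
#'   orientation) and `junctions` (data frame `pos`, `direction`, `count`).
#' @export
synth_rnaseq <- function(model, region, depth = 50L, noise = 0) {
  n <- region_length(region)
  rho <- rep(as.integer(round(depth * noise)), n)
  ex <- model_exons_region(model, region)
  for (i in seq_len(nrow(ex))) rho[seq.int(ex[i, 1L] + 1L, ex[i, 2L])] <- depth
  jn <- model_junctions(model, region)
  jn$count <- rep(as.integer(depth), nrow(jn))
  list(rho = rho, junctions = jn)
}

#' Write an orthogroup to disk as manifest + GTF + FASTA files
#'
#' @param og An [generate_orthogroup()] result.
#' @param dir Output directory (created if needed).
#' @param models Optional list of models to write instead of the truth
#'   models (e.g. perturbed ones).
#' @return The manifest path.
#' @export
write_orthogroup_files <- function(og, dir, models = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lines <- character()
  for (i in seq_along(og$species)) {
    sp <- og$species[[i]]
    model <- if (is.null(models)) sp$model else models[[i]]
    gtf <- file.path(dir, paste0(model$gene_id, ".gtf"))
    fasta <- file.path(dir, paste0(model$gene_id, ".genome.fasta"))
    write_gene_gtf(model, gtf)
    write_fasta(sp$genome, fasta)
    lines <- c(lines, paste(basename(gtf), basename(fasta), sep = "\t"))
  }
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(lines, manifest)
  manifest
}
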