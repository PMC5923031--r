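#' Multiple protein alignment engine
#'
#' Alignments are produced either by an external MSA tool (MAFFT, the
#' default when available) or by the package's internal deterministic
#' centre-star progressive aligner built on Needleman-Wunsch pairwise
#' alignment (BLOSUM62, gap open -6, extend -1). The external backend
#' falls back to the internal aligner automatically (with a warning) when
#' the binary is missing or fails, so the package never hard-depends on
#' it. Select with `options(genemend.aligner = "internal")` or the
#' `aligner` field of [run_config()].
#'
#' @param seqs Character vector of ungapped protein sequences, named by id.
#' @param backend `"internal"` or `"external"`.
#' @return A [protein_alignment()]; degapping any row reproduces its input.
#' @export
align_proteins <- function(seqs, backend = getOption("genemend.aligner", "external")) {
  if (!length(seqs)) stop("no sequences to align")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  if (backend == "external") {
    out <- try(mafft_align(seqs), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
    warning("external aligner failed; falling back to internal aligner")
  }
  centre_star_align(seqs)
}

#' Add sequences to a reference alignment
#'
#' The reference rows are preserved as a sub-alignment (columns may gain
#' all-gap insertions); the new rows are appended.
#'
#' @param reference A [protein_alignment()].
#' @param new_seqs Named character vector of ungapped proteins.
#' @inheritParams align_proteins
#' @return A [protein_alignment()] with `nrow(reference) + length(new_seqs)`
#'   rows.
#' @export
add_to_reference <- function(reference, new_seqs,
                             backend = getOption("genemend.aligner", "external")) {
  if (!length(new_seqs)) return(reference)
  if (is.null(names(new_seqs))) names(new_seqs) <- paste0("new", seq_along(new_seqs))
  new_seqs <- toupper(new_seqs)
  if (backend == "external") {
    out <- try(mafft_add(reference, new_seqs), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
    warning("external aligner failed; falling back to internal aligner")
  }
  add_to_reference_internal(reference, new_seqs)
}

#' Re-align a column window in place
#'
#' Columns outside the window are untouched; the window content is degapped
#' per row and re-aligned. Total degapped content is unchanged.
#'
#' @param aln A [protein_alignment()].
#' @param columns Integer vector of contiguous column indices.
#' @inheritParams align_proteins
#' @return A [protein_alignment()].
#' @export
realign_window <- function(aln, columns,
                           backend = getOption("genemend.aligner", "external")) {
  columns <- sort(unique(as.integer(columns)))
  columns <- columns[columns >= 1L & columns <= aln_ncol(aln)]
  if (!length(columns)) return(aln)
  sub <- aln$mat[, columns, drop = FALSE]
  degapped <- apply(sub, 1L, function(r) paste(r[r != "-"], collapse = ""))
  if (all(!nzchar(degapped))) return(aln)
  nonempty <- which(nzchar(degapped))
  inner <- align_proteins(stats::setNames(degapped[nonempty],
                                          aln$ids[nonempty]), backend)
  w <- aln_ncol(inner)
  new_block <- matrix("-", nrow(aln$mat), w)
  new_block[nonempty, ] <- inner$mat
  left <- aln$mat[, seq_len(min(columns) - 1L), drop = FALSE]
  right <- if (max(columns) < aln_ncol(aln))
    aln$mat[, seq.int(max(columns) + 1L, aln_ncol(aln)), drop = FALSE]
  else matrix(character(), nrow(aln$mat), 0L)
  out <- aln
  out$mat <- cbind(left, new_block, right)
  out
}

# --- internal centre-star aligner -----------------------------------------

pairwise_align <- function(pattern, subject, type = "global") {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    substitutionMatrix = pairwise_matrix(), gapOpening = 6, gapExtension = 1,
    type = type)
  list(pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# one vectorised call aligning many patterns to one subject; returns a list
# of aligned string pairs in input order
pairwise_align_many <- function(patterns, subject) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = pairwise_matrix(), gapOpening = 6, gapExtension = 1,
    type = "global")
  ap <- as.character(Biostrings::alignedPattern(pa))
  asub <- as.character(Biostrings::alignedSubject(pa))
  lapply(seq_along(patterns), function(i)
    list(pattern = ap[[i]], subject = asub[[i]]))
}

# insertion profile of an aligned pair relative to the subject: for subject
# of length L, a list per position j = 1..L+1 of the pattern characters
# falling in the gap run before subject residue j (j = L+1: after the last).
pair_insertions <- function(aligned_pattern, aligned_subject) {
  pc <- strsplit(aligned_pattern, "", fixed = TRUE)[[1L]]
  sc <- strsplit(aligned_subject, "", fixed = TRUE)[[1L]]
  L <- sum(sc != "-")
  ins <- vector("list", L + 1L)
  match_char <- character(L)
  j <- 1L
  buf <- character()
  for (k in seq_along(sc)) {
    if (sc[[k]] == "-") {
      buf <- c(buf, pc[[k]])
    } else {
      ins[[j]] <- buf
      buf <- character()
      match_char[[j]] <- pc[[k]]
      j <- j + 1L
    }
  }
  ins[[L + 1L]] <- buf
  list(ins = ins, match = match_char)
}

centre_star_align <- function(seqs) {
  ids <- names(seqs)
  n <- length(seqs)
  if (n == 1L) return(protein_alignment(seqs, ids))
  lens <- nchar(seqs)
  if (all(lens == 0L))
    return(structure(list(ids = ids, mat = matrix(character(), n, 0L)),
                     class = "protein_alignment"))
  centre <- which.max(lens)
  cseq <- seqs[[centre]]
  L <- nchar(cseq)
  others <- setdiff(seq_len(n), centre)
  profs <- vector("list", n)
  nonempty <- others[nchar(seqs[others]) > 0L]
  if (length(nonempty)) {
    pas <- pairwise_align_many(seqs[nonempty], cseq)
    for (ii in seq_along(nonempty)) {
      profs[[nonempty[[ii]]]] <- pair_insertions(pas[[ii]]$pattern,
                                                 pas[[ii]]$subject)
    }
  }
  for (i in setdiff(others, nonempty)) {
    profs[[i]] <- list(ins = rep(list(character()), L + 1L),
                       match = rep("-", L))
  }
  ins_len <- rep(0L, L + 1L)
  for (i in others) {
    il <- lengths(profs[[i]]$ins)
    ins_len <- pmax(ins_len, il)
  }
  width <- L + sum(ins_len)
  mat <- matrix("-", n, width)
  # column layout: [ins block 1] c1 [ins block 2] c2 ... cL [ins block L+1]
  block_start <- cumsum(c(1L, ins_len[-(L + 1L)] + 1L))  # start col of block j
  centre_cols <- block_start[seq_len(L)] + ins_len[seq_len(L)]
  cchars <- strsplit(cseq, "", fixed = TRUE)[[1L]]
  mat[centre, centre_cols] <- cchars
  for (i in others) {
    p <- profs[[i]]
    for (j in seq_len(L)) {
      b <- p$ins[[j]]
      if (length(b))
        mat[i, seq.int(block_start[[j]], length.out = length(b))] <- b
      mat[i, centre_cols[[j]]] <- p$match[[j]]
    }
    b <- p$ins[[L + 1L]]
    if (length(b))
      mat[i, seq.int(width - ins_len[[L + 1L]] + 1L, length.out = length(b))] <- b
  }
  structure(list(ids = ids, mat = mat), class = "protein_alignment")
}

add_to_reference_internal <- function(reference, new_seqs) {
  mat <- reference$mat
  resid_count <- rowSums(mat != "-")
  anchor <- which.max(resid_count)
  anchor_cols <- which(mat[anchor, ] != "-")
  aseq <- paste(mat[anchor, anchor_cols], collapse = "")
  L <- length(anchor_cols)
  if (L == 0L) {                      # degenerate: reference holds no residues
    fresh <- centre_star_align(new_seqs)
    top <- cbind(mat, matrix("-", nrow(mat), aln_ncol(fresh)))
    bottom <- cbind(matrix("-", nrow(fresh$mat), ncol(mat)), fresh$mat)
    return(structure(list(ids = c(reference$ids, fresh$ids),
                          mat = rbind(top, bottom)),
                     class = "protein_alignment"))
  }
  profs <- vector("list", length(new_seqs))
  nonempty <- which(nchar(new_seqs) > 0L)
  if (length(nonempty)) {
    pas <- pairwise_align_many(new_seqs[nonempty], aseq)
    for (ii in seq_along(nonempty)) {
      profs[[nonempty[[ii]]]] <- pair_insertions(pas[[ii]]$pattern,
                                                 pas[[ii]]$subject)
    }
  }
  for (i in setdiff(seq_along(new_seqs), nonempty)) {
    profs[[i]] <- list(ins = rep(list(character()), L + 1L), match = rep("-", L))
  }
  ins_len <- rep(0L, L + 1L)
  for (p in profs) ins_len <- pmax(ins_len, lengths(p$ins))
  # expand reference with all-gap columns before each anchor residue column
  width <- ncol(mat) + sum(ins_len)
  nref <- nrow(mat)
  out <- matrix("-", nref + length(new_seqs), width)
  # map old columns to new positions
  shift <- rep(0L, ncol(mat))
  if (L > 0L) {
    add_before <- rep(0L, ncol(mat) + 1L)
    add_before[anchor_cols] <- ins_len[seq_len(L)]
    shift <- cumsum(add_before[seq_len(ncol(mat))])
  }
  new_pos <- seq_len(ncol(mat)) + shift
  out[seq_len(nref), new_pos] <- mat
  # place new rows
  anchor_new_cols <- new_pos[anchor_cols]
  for (k in seq_along(profs)) {
    p <- profs[[k]]
    row <- nref + k
    for (j in seq_len(L)) {
      b <- p$ins[[j]]
      if (length(b))
        out[row, seq.int(anchor_new_cols[[j]] - length(b), length.out = length(b))] <- b
      out[row, anchor_new_cols[[j]]] <- p$match[[j]]
    }
    b <- p$ins[[L + 1L]]
    if (length(b))
      out[row, seq.int(width - ins_len[[L + 1L]] + 1L, length.out = length(b))] <- b
  }
  structure(list(ids = c(reference$ids, names(new_seqs)), mat = out),
            class = "protein_alignment")
}

# --- MAFFT adapter ---------------------------------------------------------

mafft_align <- function(seqs) {
  exe <- Sys.which("mafft")
  if (!nzchar(exe)) stop("mafft not found")
  nonempty <- which(nchar(seqs) > 0L)
  if (length(nonempty) <= 1L) return(centre_star_align(seqs))
  inp <- tempfile(fileext = ".fasta")
  on.exit(unlink(inp), add = TRUE)
  write_fasta(stats::setNames(seqs[nonempty], paste0("s", seq_along(nonempty))),
              inp)
  out <- system2(exe, c("--quiet", "--auto", "--amino", inp), stdout = TRUE)
  inner <- parse_fasta_alignment(out, names(seqs)[nonempty])
  if (length(nonempty) == length(seqs)) return(inner)
  mat <- matrix("-", length(seqs), aln_ncol(inner))
  mat[nonempty, ] <- inner$mat
  structure(list(ids = names(seqs), mat = mat), class = "protein_alignment")
}

mafft_add <- function(reference, new_seqs) {
  exe <- Sys.which("mafft")
  if (!nzchar(exe)) stop("mafft not found")
  if (any(nchar(new_seqs) == 0L) || !length(reference$ids) ||
      all(reference$mat == "-"))
    return(add_to_reference_internal(reference, new_seqs))
  ref <- tempfile(fileext = ".fasta")
  inp <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(ref, inp)), add = TRUE)
  write_fasta(stats::setNames(aln_rows(reference),
                              paste0("r", seq_along(reference$ids))), ref)
  write_fasta(stats::setNames(new_seqs, paste0("n", seq_along(new_seqs))), inp)
  out <- system2(exe, c("--quiet", "--amino", "--add", inp, ref), stdout = TRUE)
  parse_fasta_alignment(out, c(reference$ids, names(new_seqs)))
}

parse_fasta_alignment <- function(lines, ids) {
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  if (length(seqs) != length(ids)) stop("aligner returned wrong sequence count")
  protein_alignment(toupper(seqs), ids)
}
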