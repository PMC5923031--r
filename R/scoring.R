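#' Protein alignments
#'
#' A `protein_alignment` is the package's container for a protein multiple
#' sequence alignment: a character matrix of single residues/gaps with one
#' row per sequence, plus row identifiers. It is the object every scoring
#' and choice operation works on.
#'
#' @param seqs Character vector of aligned sequences (equal length, gaps as
#'   `-`), optionally named.
#' @param ids Row identifiers; defaults to `names(seqs)` or `seq1..seqN`.
#' @return An object of class `protein_alignment` with elements `ids`
#'   (character) and `mat` (character matrix, rows = sequences).
#' @export
protein_alignment <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  seqs <- toupper(as.character(seqs))
  lens <- nchar(seqs)
  if (length(seqs) && length(unique(lens)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  mat <- if (length(seqs)) {
    do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  } else {
    matrix(character(), 0L, 0L)
  }
  structure(list(ids = as.character(ids), mat = mat), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment: ", nrow(x$mat), " sequences x ", ncol(x$mat),
      " columns\n", sep = "")
  seqs <- aln_rows(x)
  show <- utils::head(seq_along(seqs), 8L)
  for (i in show) {
    s <- seqs[[i]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(format(x$ids[[i]], width = 14), s, "\n")
  }
  if (length(seqs) > 8L) cat("...\n")
  invisible(x)
}

aln_ncol <- function(aln) ncol(aln$mat)

# aligned rows as strings, named by sequence id
aln_rows <- function(aln) {
  if (nrow(aln$mat) == 0L) return(character())
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$ids)
}

# ungapped sequences
aln_degap <- function(aln) gsub("-", "", aln_rows(aln), fixed = TRUE)

#' Column score of an alignment column
#'
#' The column score gamma is the sum of BLOSUM62 scores over all unordered
#' residue pairs in the column, divided by the number of rows. Pairs
#' involving a gap contribute 0.
#'
#' @param column Character vector of single residues/gaps (one per row).
#' @param matrix Substitution matrix, see [default_substitution_matrix()].
#' @return Numeric score.
#' @export
column_score <- function(column, matrix = default_substitution_matrix()) {
  l <- length(column)
  if (l < 1L) stop("column must have at least one row")
  column <- toupper(column)
  bad <- setdiff(unique(column), rownames(matrix))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  if (l == 1L) return(0)
  pairs <- utils::combn(column, 2L)
  sum(matrix[cbind(pairs[1L, ], pairs[2L, ])]) / l
}

#' Alignment score
#'
#' The alignment score alpha is the sum of column scores over all columns.
#'
#' @param aln A [protein_alignment()].
#' @param matrix Substitution matrix.
#' @return Numeric score (0 for an empty alignment).
#' @export
alignment_score <- function(aln, matrix = default_substitution_matrix()) {
  score_columns(aln$mat, matrix)
}

# Vectorised alpha over a character matrix of residues: for every unordered
# row pair, look up all columns at once.
score_columns <- function(mat, matrix) {
  n <- nrow(mat)
  if (is.null(n) || n == 0L || ncol(mat) == 0L) return(0)
  bad <- setdiff(unique(as.vector(mat)), rownames(matrix))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  if (n == 1L) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      total <- total + sum(matrix[cbind(mat[i, ], mat[j, ])])
    }
  }
  total / n
}

#' Adjusted alignment score
#'
#' alpha divided by the number of columns; 0 for an empty alignment. The
#' attribute `all_gaps` flags alignments consisting solely of gap
#' characters, which some filters treat as acceptable regardless of score.
#'
#' @inheritParams alignment_score
#' @return Numeric score with logical attribute `all_gaps`.
#' @export
adjusted_score <- function(aln, matrix = default_substitution_matrix()) {
  l <- aln_ncol(aln)
  if (is.null(l) || l == 0L) {
    return(structure(0, all_gaps = TRUE))
  }
  val <- alignment_score(aln, matrix) / l
  structure(val, all_gaps = all(aln$mat == "-"))
}

#' Windowed alignment score
#'
#' alpha restricted to a column window and optionally a subset of rows;
#' used by the change filters.
#'
#' @param aln A [protein_alignment()].
#' @param columns Integer vector of column indices (empty window scores 0).
#' @param rows Optional integer vector of row indices (default all rows).
#' @param matrix Substitution matrix.
#' @param adjusted If `TRUE` return the per-column (adjusted) score.
#' @return Numeric score.
#' @export
windowed_score <- function(aln, columns = seq_len(aln_ncol(aln)), rows = NULL,
                           matrix = default_substitution_matrix(),
                           adjusted = FALSE) {
  mat <- aln$mat
  if (!is.null(rows)) mat <- mat[rows, , drop = FALSE]
  columns <- columns[columns >= 1L & columns <= ncol(mat)]
  mat <- mat[, columns, drop = FALSE]
  a <- score_columns(mat, matrix)
  if (adjusted) {
    if (ncol(mat) == 0L) return(structure(0, all_gaps = TRUE))
    return(structure(a / ncol(mat), all_gaps = all(mat == "-")))
  }
  a
}
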