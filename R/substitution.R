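#' Substitution matrices for the alignment objective
#'
#' The objective function scores protein alignment columns with BLOSUM62.
#' `default_substitution_matrix()` returns the canonical BLOSUM62 matrix
#' (from Biostrings) adapted to the package's conventions: the ambiguity
#' code `X` scores 0 against everything, and a gap row/column `-` scoring 0
#' is present so column scoring never needs a special case.
#'
#' @return A symmetric numeric matrix with amino-acid one-letter codes,
#'   `X`, `*` and `-` as dimnames.
#' @export
default_substitution_matrix <- function() {
  mat <- get_blosum62()
  adapt_substitution_matrix(mat)
}

# cache: loading + adapting once per session
.genemend_env <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(.genemend_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .genemend_env$blosum62 <- e$BLOSUM62
  }
  .genemend_env$blosum62
}

#' Read a substitution matrix from a plain-text table
#'
#' Accepts the standard whitespace-separated square matrix layout used by
#' NCBI (`#` comments, one header row of residue codes, one labelled row per
#' residue). Use this to override the default BLOSUM62 objective.
#'
#' @param path Path to the text file.
#' @return A symmetric numeric matrix adapted as in
#'   [default_substitution_matrix()].
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("substitution matrix file '", path, "' has no table")
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  mat <- matrix(0, length(rows), length(header),
                dimnames = list(vapply(rows, `[[`, "", 1L), header))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1L]
    if (length(vals) != length(header))
      stop("substitution matrix row ", i, " has ", length(vals),
           " values, expected ", length(header))
    mat[i, ] <- as.numeric(vals)
  }
  if (!identical(rownames(mat), colnames(mat)))
    stop("substitution matrix is not square with matching labels")
  adapt_substitution_matrix(mat)
}

adapt_substitution_matrix <- function(mat) {
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  if (!isTRUE(all.equal(mat, t(mat)))) stop("substitution matrix must be symmetric")
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0
    mat[, "X"] <- 0
  } else {
    mat <- extend_matrix(mat, "X")
  }
  if (!("-" %in% rownames(mat))) mat <- extend_matrix(mat, "-")
  mat["-", ] <- 0
  mat[, "-"] <- 0
  mat
}

extend_matrix <- function(mat, code) {
  n <- nrow(mat)
  out <- rbind(cbind(mat, 0), 0)
  rownames(out) <- c(rownames(mat), code)
  colnames(out) <- c(colnames(mat), code)
  out
}

# Matrix used for Biostrings pairwise alignment calls (no gap row; native
# BLOSUM62 X/* values so the aligner behaves conventionally).
pairwise_matrix <- function() {
  if (is.null(.genemend_env$pairwise_mat)) {
    .genemend_env$pairwise_mat <- get_blosum62()
  }
  .genemend_env$pairwise_mat
}
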