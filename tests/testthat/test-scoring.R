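test_that("column scores match hand-checked BLOSUM62 values", {
  expect_equal(column_score(c("A", "A")), 2)        # one pair, Blos(A,A)=4, l=2
  expect_equal(column_score(c("C", "C", "C")), 9)   # 3 pairs x 9 / 3
  expect_equal(column_score(c("-", "-")), 0)
  expect_equal(column_score("W"), 0)                # no pairs
  expect_error(column_score(c("A", "@")), "unknown residue")
})

test_that("gap and ambiguity conventions: pairs with - or X score zero", {
  m <- default_substitution_matrix()
  expect_true(all(m["X", ] == 0))
  expect_true(all(m["-", ] == 0))
  expect_equal(column_score(c("A", "-", "A")), 4 / 3)
  expect_equal(column_score(c("X", "W")), 0)
})

test_that("alignment score is the column sum and is additive over splits", {
  expect_equal(alignment_score(protein_alignment(character())), 0)
  one <- protein_alignment(c("A", "A"))
  expect_equal(alignment_score(one), column_score(c("A", "A")))
  two <- protein_alignment(c("AA", "AA"))
  expect_equal(alignment_score(two), 2 * alignment_score(one))
  expect_error(protein_alignment(c("AA", "A")), "ragged")
  set.seed(11)
  aas <- c(rownames(default_substitution_matrix()), "-")
  aas <- setdiff(aas, c("B", "Z", "*", "J", "U", "O"))
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    L <- sample(5:40, 1)
    mat <- matrix(sample(aas, n * L, TRUE), n, L)
    aln <- protein_alignment(apply(mat, 1, paste, collapse = ""))
    k <- sample(seq_len(L - 1), 1)
    left <- protein_alignment(apply(mat[, 1:k, drop = FALSE], 1, paste, collapse = ""))
    right <- protein_alignment(apply(mat[, (k + 1):L, drop = FALSE], 1, paste, collapse = ""))
    expect_equal(alignment_score(aln),
                 alignment_score(left) + alignment_score(right))
    # permutation invariance of each column score
    j <- sample(L, 1)
    expect_equal(column_score(mat[, j]), column_score(sample(mat[, j])))
  }
})

test_that("adjusted score divides by columns and flags all-gap alignments", {
  aln <- protein_alignment(c("AA", "AA"))
  expect_equal(as.numeric(adjusted_score(aln)), 2)
  gaps <- protein_alignment(c("--", "--"))
  s <- adjusted_score(gaps)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "all_gaps"))
  one_col <- protein_alignment(c("C", "C"))
  expect_equal(as.numeric(adjusted_score(one_col)), alignment_score(one_col))
  # removing an all-gap column leaves alpha unchanged, raises the mean
  with_gap <- protein_alignment(c("A-A", "A-A"))
  without <- protein_alignment(c("AA", "AA"))
  expect_equal(alignment_score(with_gap), alignment_score(without))
  expect_lt(as.numeric(adjusted_score(with_gap)),
            as.numeric(adjusted_score(without)))
})

test_that("windowed score restricts to columns and rows", {
  aln <- protein_alignment(c("AWC", "AWC", "AW-"))
  expect_equal(windowed_score(aln), alignment_score(aln))
  expect_equal(windowed_score(aln, integer()), 0)
  expect_equal(windowed_score(aln, 1L, rows = c(1L, 2L)), 2)
  expect_equal(windowed_score(aln, 2:3),
               alignment_score(aln) - windowed_score(aln, 1L))
})
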