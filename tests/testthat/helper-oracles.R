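# independent oracles shared by unit and acceptance tests

# brute-force maximal-clique enumeration over all vertex subsets (n <= 12)
brute_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  for (code in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(members) < 1L) next
    pairs_ok <- all(adj[members, members][upper.tri(diag(length(members)))] == 1)
    if (!pairs_ok) next
    maximal <- all(vapply(setdiff(seq_len(n), members), function(v)
      !all(adj[v, members] == 1), TRUE))
    if (maximal) out[[length(out) + 1L]] <- members
  }
  out
}

graph_adj <- function(g) as.matrix(igraph::as_adjacency_matrix(g))

# pair-loop column/alignment scorer, written independently of the package's
# vectorised implementation
oracle_gamma <- function(column, m) {
  l <- length(column)
  total <- 0
  if (l >= 2L) {
    for (i in 1:(l - 1)) {
      for (j in (i + 1):l) {
        a <- column[[i]]
        b <- column[[j]]
        if (a != "-" && b != "-") total <- total + m[a, b]
      }
    }
  }
  total / l
}

oracle_alpha <- function(mat, m) {
  s <- 0
  for (j in seq_len(ncol(mat))) s <- s + oracle_gamma(mat[, j], m)
  s
}

# random protein-variant instance for the choice function: equal-length
# substitution variants of a shared base, so exhaustive alpha maximisation
# is closed-form (the optimal alignment of equal-length variants is gapless)
choice_instance <- function(k = NULL, lmax = 4L, plen = NULL) {
  aas <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1L]]
  if (is.null(k)) k <- sample(2:4, 1)
  if (is.null(plen)) plen <- sample(12:30, 1)
  base <- sample(aas, plen, TRUE)
  lapply(seq_len(k), function(i) {
    l_i <- sample(seq_len(lmax), 1)
    vapply(seq_len(l_i), function(j) {
      v <- base
      nmut <- if (j == 1L) sample(0:1, 1) else sample(2:6, 1)
      pos <- sample(plen, min(nmut, plen))
      for (p in pos) v[p] <- sample(setdiff(aas, v[p]), 1)
      paste(v, collapse = "")
    }, "")
  })
}

choice_oracle_max <- function(options) {
  combos <- expand.grid(lapply(options, seq_along))
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    seqs <- vapply(seq_along(options), function(i)
      options[[i]][[combos[r, i]]], "")
    a <- alignment_score(protein_alignment(seqs))
    if (a > best) best <- a
  }
  best
}
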