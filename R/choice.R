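#' Variant sets for the multipartite choice function
#'
#' A `variant_set` holds, for each of `k` gene regions, one or more
#' candidate protein fragments, plus an optional reference alignment the
#' options are aligned against (the alignment of the current models).
#'
#' @param options List of length `k`; element `i` is a character vector of
#'   the candidate proteins for region `i` (at least one each).
#' @param region_ids Identifiers for the regions (default `region1..k`).
#' @param reference Optional [protein_alignment()] used as the alignment
#'   scaffold.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(options, region_ids = NULL, reference = NULL) {
  if (!length(options)) stop("variant set needs at least one region")
  if (any(!lengths(options))) stop("every region needs at least one option")
  if (is.null(region_ids)) region_ids <- paste0("region", seq_along(options))
  options <- lapply(options, toupper)
  structure(list(options = options, region_ids = as.character(region_ids),
                 reference = reference),
            class = "variant_set")
}

# per-column gamma scores for a residue matrix
column_scores_vec <- function(mat, matrix) {
  n <- nrow(mat)
  p <- ncol(mat)
  if (n == 0L || p == 0L) return(numeric(0))
  if (n == 1L) return(rep(0, p))
  tot <- rep(0, p)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + matrix[cbind(mat[i, ], mat[j, ])]
    }
  }
  tot / n
}

# maximal column runs considered inconsistent: negative column score or
# gap fraction above one half
inconsistent_runs <- function(aln, matrix) {
  g <- column_scores_vec(aln$mat, matrix)
  gapfrac <- colMeans(aln$mat == "-")
  bad <- which(g < 0 | gapfrac > 0.5)
  if (!length(bad)) return(list())
  splits <- cumsum(c(1L, diff(bad) != 1L))
  unname(split(bad, splits))
}

# align all options of a variant set, via the reference when present;
# returns list(aln = option-row alignment, region_of_row = integer vector)
align_variant_set <- function(vs, matrix = default_substitution_matrix(),
                              backend = getOption("genemend.aligner", "external")) {
  k <- length(vs$options)
  region_of_row <- rep(seq_len(k), lengths(vs$options))
  ids <- unlist(lapply(seq_len(k), function(i)
    paste0(vs$region_ids[[i]], ".opt", seq_along(vs$options[[i]]))))
  seqs <- stats::setNames(unlist(vs$options), ids)
  if (!is.null(vs$reference)) {
    nref <- length(vs$reference$ids)
    aln <- add_to_reference(vs$reference, seqs, backend = backend)
    for (run in rev(inconsistent_runs(aln, matrix))) {
      aln <- realign_window(aln, run, backend = backend)
    }
    aln$mat <- aln$mat[-seq_len(nref), , drop = FALSE]
    aln$ids <- aln$ids[-seq_len(nref)]
  } else {
    aln <- align_proteins(seqs, backend = backend)
  }
  keep <- colSums(aln$mat != "-") > 0L
  aln$mat <- aln$mat[, keep, drop = FALSE]
  list(aln = aln, region_of_row = region_of_row)
}

#' Column-wise consensus of a variant alignment
#'
#' For every alignment column independently, picks one residue per gene
#' region (from the residues its options display in that column) so that
#' the column score of the chosen combination is maximal. Small search
#' spaces are enumerated exhaustively; larger ones use iterated local
#' improvement from the most frequent residues.
#'
#' @param aln [protein_alignment()] of all option rows.
#' @param region_of_row Integer vector mapping alignment rows to regions.
#' @param matrix Substitution matrix.
#' @return Character matrix `k x ncol(aln)` of consensus residues.
#' @export
consensus_alignment <- function(aln, region_of_row,
                                matrix = default_substitution_matrix()) {
  k <- max(region_of_row)
  p <- aln_ncol(aln)
  cons <- matrix("-", k, p)
  if (p == 0L) return(cons)
  rows_by_region <- split(seq_len(nrow(aln$mat)), region_of_row)
  for (j in seq_len(p)) {
    col <- aln$mat[, j]
    choices <- lapply(rows_by_region, function(r) unique(col[r]))
    n_comb <- prod(lengths(choices))
    if (n_comb == 1L) {
      cons[, j] <- vapply(choices, `[[`, "", 1L)
    } else if (n_comb <= 2048) {
      combos <- as.matrix(expand.grid(choices, stringsAsFactors = FALSE))
      sc <- combo_scores(combos, matrix)
      top <- which(sc > max(sc) - 1e-9)
      if (length(top) > 1L) {
        # prefer gaps on ties so spurious residues never define the consensus
        gaps <- rowSums(combos[top, , drop = FALSE] == "-")
        top <- top[order(-gaps)]
      }
      cons[, j] <- combos[top[[1L]], ]
    } else {
      cons[, j] <- greedy_consensus(choices, col, rows_by_region, matrix)
    }
  }
  cons
}

combo_scores <- function(combos, matrix) {
  k <- ncol(combos)
  sc <- rep(0, nrow(combos))
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      sc <- sc + matrix[cbind(combos[, a], combos[, b])]
    }
  }
  sc / k
}

greedy_consensus <- function(choices, col, rows_by_region, matrix) {
  k <- length(choices)
  cur <- vapply(seq_len(k), function(i) {
    tab <- table(col[rows_by_region[[i]]])
    names(tab)[which.max(tab)]
  }, "")
  for (pass in 1:10) {
    changed <- FALSE
    for (i in seq_len(k)) {
      best <- cur[[i]]
      best_s <- -Inf
      for (cand in choices[[i]]) {
        trial <- cur
        trial[[i]] <- cand
        s <- combo_scores(matrix(trial, 1L), matrix)
        better <- s > best_s + 1e-12 ||
          (abs(s - best_s) <= 1e-12 && cand == "-" && best != "-")
        if (better) {
          best_s <- s
          best <- cand
        }
      }
      if (!identical(best, cur[[i]])) {
        cur[[i]] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cur
}

#' Binarise options against the consensus
#'
#' One bit per (option row, column): 1 where the option's residue equals
#' its region's consensus residue.
#'
#' @inheritParams consensus_alignment
#' @param consensus Output of [consensus_alignment()].
#' @return Logical matrix, options x columns.
#' @export
binarise <- function(aln, region_of_row, consensus) {
  m <- nrow(aln$mat)
  H <- matrix(FALSE, m, aln_ncol(aln))
  for (i in seq_len(m)) {
    H[i, ] <- aln$mat[i, ] == consensus[region_of_row[[i]], ]
  }
  H
}

#' Binary profile of a variant set
#'
#' Stacks the per-option match strings into columns and records the region
#' membership masks used by the reduction step.
#'
#' @param H Logical matrix from [binarise()].
#' @param region_of_row Integer vector mapping rows of `H` to regions.
#' @return An object of class `binary_profile` with the distinct non-all-1
#'   columns (`V`), their multiplicities (`weights`) and `region_of_option`.
#' @export
binary_profile <- function(H, region_of_row) {
  m <- nrow(H)
  all1 <- colSums(H) == m
  V <- H[, !all1, drop = FALSE]
  key <- apply(V, 2L, paste, collapse = "")
  if (ncol(V)) {
    tab <- table(key)
    uniq <- !duplicated(key)
    Vd <- V[, uniq, drop = FALSE]
    w <- as.numeric(tab[key[uniq]])
  } else {
    Vd <- V
    w <- numeric()
  }
  structure(list(V = Vd, weights = w, region_of_option = region_of_row,
                 n_options = m, packed = pack_profile(Vd, region_of_row)),
            class = "binary_profile")
}

# bit-packed representation: options as bits spread over 30-bit integer
# words, so the reduction loop runs on vectorised bitwAnd calls
pack_profile <- function(V, reg) {
  m <- length(reg)
  nw <- max(1L, ceiling(m / 30))
  word <- (seq_len(m) - 1L) %/% 30L + 1L
  bit <- bitwShiftL(1L, (seq_len(m) - 1L) %% 30L)
  pack_vec <- function(bits) {
    out <- integer(nw)
    on <- which(bits)
    for (o in on) out[word[[o]]] <- bitwOr(out[[word[[o]]]], bit[[o]])
    out
  }
  Vp <- if (ncol(V)) vapply(seq_len(ncol(V)), function(j) pack_vec(V[, j]),
                            integer(nw)) else matrix(integer(), nw, 0L)
  if (nw == 1L) Vp <- matrix(Vp, nrow = 1L)
  k <- max(reg)
  masks <- vapply(seq_len(k), function(r) pack_vec(reg == r), integer(nw))
  if (nw == 1L) masks <- matrix(masks, nrow = 1L)
  list(V = Vp, masks = masks, word = word, bit = bit, nw = nw, k = k, m = m)
}

unpack_bits <- function(wvec, pk) {
  bitwAnd(wvec[pk$word], pk$bit) != 0L
}

# columns of packed matrix A whose intersection keeps >= 1 bit per region
packed_region_ok <- function(A, pk) {
  ok <- rep(TRUE, ncol(A))
  for (r in seq_len(pk$k)) {
    anded <- bitwAnd(A, pk$masks[, r])
    dim(anded) <- dim(A)
    nz <- colSums(anded != 0L) > 0L
    ok <- ok & nz
  }
  ok
}

#' One sequential random reduction
#'
#' Starting from a random stacked column, repeatedly intersects with
#' compatible columns (those whose intersection with the current string
#' retains at least one bit in every region) until the string stops
#' changing. Uses the current R random number generator state.
#'
#' @param profile A [binary_profile()].
#' @return Logical vector over options, with at least one bit per region
#'   (all-1 when no usable columns exist).
#' @export
reduce_once <- function(profile) {
  pk <- profile$packed
  m <- profile$n_options
  if (!ncol(pk$V)) return(rep(TRUE, m))
  usable <- which(packed_region_ok(pk$V, pk))
  if (!length(usable)) return(rep(TRUE, m))
  j0 <- if (length(usable) == 1L) usable else
    sample(usable, 1L, prob = profile$weights[usable])
  W <- pk$V[, j0]
  A <- pk$V
  repeat {
    cand <- bitwAnd(A, W)
    dim(cand) <- dim(A)
    compat <- which(packed_region_ok(cand, pk))
    if (!length(compat)) return(unpack_bits(W, pk))
    A <- cand[, compat, drop = FALSE]
    jn <- if (ncol(A) == 1L) 1L else sample(ncol(A), 1L)
    W_new <- A[, jn]
    if (identical(W_new, W)) return(unpack_bits(W, pk))
    W <- W_new
  }
}

# All `reps` reductions run simultaneously: since every A_n element is the
# intersection of W with an original column that stayed compatible, the
# per-rep state is just the current string W, and candidate screening can
# use the full original column set each round. Returns distinct results
# with their multiplicities.
reduce_many <- function(profile, reps) {
  pk <- profile$packed
  m <- profile$n_options
  nw <- pk$nw
  if (!ncol(pk$V)) return(list(list(bits = rep(TRUE, m), n = reps)))
  usable <- which(packed_region_ok(pk$V, pk))
  if (!length(usable)) return(list(list(bits = rep(TRUE, m), n = reps)))
  p <- ncol(pk$V)
  j0 <- if (length(usable) == 1L) rep(usable, reps) else
    sample(usable, reps, replace = TRUE, prob = profile$weights[usable])
  W <- pk$V[, j0, drop = FALSE]          # nw x reps
  active <- seq_len(reps)
  final <- matrix(0L, nw, reps)
  for (iter in 1:100) {
    R <- length(active)
    if (!R) break
    # compat[j, rep]: does V_j cut W down while keeping every region?
    compat <- matrix(TRUE, p, R)
    for (r in seq_len(pk$k)) {
      acc <- matrix(FALSE, p, R)
      for (w in seq_len(nw)) {
        vv <- bitwAnd(pk$V[w, ], pk$masks[w, r])
        ww <- W[w, active]
        acc <- acc | (outer(vv, ww, bitwAnd) != 0L)
      }
      compat <- compat & acc
    }
    pick_score <- matrix(stats::runif(p * R), p, R) * compat
    picked <- max.col(t(pick_score), ties.method = "first")
    has_cand <- colSums(compat) > 0L
    Wnew <- W[, active, drop = FALSE]
    for (w in seq_len(nw)) {
      Wnew[w, has_cand] <- bitwAnd(Wnew[w, has_cand],
                                   pk$V[w, picked[has_cand]])
    }
    unchanged <- colSums(Wnew != W[, active, drop = FALSE]) == 0L
    done <- !has_cand | unchanged
    W[, active] <- Wnew
    final[, active[done]] <- W[, active[done]]
    active <- active[!done]
  }
  if (length(active)) final[, active] <- W[, active]
  keys <- apply(final, 2L, paste, collapse = ",")
  tab <- table(keys)
  uniq <- !duplicated(keys)
  lapply(which(uniq), function(j)
    list(bits = unpack_bits(final[, j], pk), n = as.integer(tab[[keys[[j]]]])))
}

#' Choose one variant per gene region
#'
#' The multipartite choice function: aligns all options (against the
#' reference when given), builds the column consensus, binarises, runs the
#' random reduction `reps` times, and declares the result that is a subset
#' of the largest number of stacked columns the winner. If the winner
#' leaves several options in some region, the remaining one-per-region
#' combinations are enumerated and the combination with the highest
#' alignment score alpha wins, ties broken at random.
#'
#' Randomness is drawn from R's RNG; seed it (or let [run_pipeline()] do
#' so) for reproducible selections.
#'
#' @param vs A [variant_set()].
#' @param reps Number of reduction repetitions (default 1000).
#' @param matrix Substitution matrix.
#' @param backend MSA backend, see [align_proteins()].
#' @return A list with `selection` (integer option index per region),
#'   `proteins` (the chosen sequences) and `alpha` (alignment score of the
#'   chosen rows in the option alignment).
#' @export
choose_variants <- function(vs, reps = 1000L,
                            matrix = default_substitution_matrix(),
                            backend = getOption("genemend.aligner", "external")) {
  k <- length(vs$options)
  l <- lengths(vs$options)
  if (all(l == 1L)) {
    return(list(selection = rep(1L, k),
                proteins = vapply(vs$options, `[[`, "", 1L),
                alpha = NA_real_))
  }
  av <- align_variant_set(vs, matrix, backend)
  aln <- av$aln
  reg <- av$region_of_row
  cons <- consensus_alignment(aln, reg, matrix)
  H <- binarise(aln, reg, cons)
  prof <- binary_profile(H, reg)
  m <- nrow(H)
  if (!ncol(prof$V)) {
    sel_bits <- rep(TRUE, m)
  } else {
    results <- reduce_many(prof, reps)
    cover <- vapply(results, function(res) {
      superset <- colSums((!prof$V) & res$bits) == 0L  # columns containing W
      sum(prof$weights[superset])
    }, numeric(1))
    keys <- vapply(results, function(res)
      paste(as.integer(res$bits), collapse = ""), "")
    sel_bits <- results[[order(-cover, keys)[[1L]]]]$bits
  }
  sel_by_region <- split(seq_len(m), reg)
  bits <- rowSums(H)
  # candidate options per region: the winner's options plus any option
  # within a small agreement slack (the bit count is noisy where the
  # option alignment is imperfect); alpha decides among them, ties go to
  # the most parsimonious option (fewest residues), then the seeded RNG
  selected <- lapply(seq_len(k), function(i) {
    opts <- sel_by_region[[i]]
    hit <- which(sel_bits[opts])
    if (!length(hit)) hit <- seq_along(opts)
    near <- which(bits[opts] >= max(bits[opts]) - 3L)
    cand <- union(hit, near)
    if (length(cand) > 4L) {
      ord <- cand[order(-bits[opts][cand])]
      cand <- union(hit, ord)[seq_len(max(4L, length(hit)))]
    }
    # the most parsimonious option always competes: when most options
    # carry read-through junk the consensus leans towards the junk and
    # the clean variant would otherwise never reach the alpha comparison
    cand <- union(cand, which.min(nchar(vs$options[[i]])))
    sort(cand)
  })
  while (prod(lengths(selected)) > 5000) {
    widest <- which.max(lengths(selected))
    selected[[widest]] <- selected[[widest]][
      seq_len(max(1L, length(selected[[widest]]) - 1L))]
  }
  row_of <- function(region, opt) sel_by_region[[region]][[opt]]
  if (prod(lengths(selected)) == 1L) {
    sel <- vapply(selected, `[[`, 0L, 1L)
  } else {
    combos <- as.matrix(expand.grid(selected))
    # decision score: alpha with a small penalty per gapped cell in mixed
    # columns, so residues unsupported by the other regions never win on
    # a pure tie; near-ties (within 2) resolve to the fewest residues
    alphas <- apply(combos, 1L, function(cc) {
      rows <- vapply(seq_len(k), function(i) row_of(i, cc[[i]]), 0L)
      sub <- aln$mat[rows, , drop = FALSE]
      gaps <- sub == "-"
      mixed <- colSums(gaps) %in% seq_len(k - 1L)
      score_columns(sub, matrix) - 0.3 * sum(gaps[, mixed])
    })
    nres <- apply(combos, 1L, function(cc) {
      sum(vapply(seq_len(k), function(i)
        nchar(vs$options[[i]][[cc[[i]]]]), 0L))
    })
    top <- which(alphas > max(alphas) - 2)
    top <- top[nres[top] == min(nres[top])]
    pick <- if (length(top) == 1L) top else sample(top, 1L)
    sel <- as.integer(combos[pick, ])
  }
  rows <- vapply(seq_len(k), function(i) row_of(i, sel[[i]]), 0L)
  list(selection = sel,
       proteins = vapply(seq_len(k), function(i) vs$options[[i]][[sel[[i]]]], ""),
       alpha = score_columns(aln$mat[rows, , drop = FALSE], matrix))
}
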