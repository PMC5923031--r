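#' Filter candidate gene-model changes
#'
#' Applies four conservative criteria to every localised change between
#' the original and the optimised models, judged on the protein multiple
#' alignments of the whole orthogroup before and after:
#'
#' 1. the alignment score of the 10-residue flanks either side of the
#'    change must not have decreased;
#' 2. the change must not have opened gaps in three or more sequences;
#' 3. micro-changes (two or fewer residues changed, gapless before and
#'    after) are discarded, and larger gapless-to-gapless changes need an
#'    alignment-score increase of at least 4;
#' 4. the 5-residue unchanged flanks and the changed region itself must
#'    reach an adjusted score of 3 or more (or be all gaps) for some
#'    subset of three sequences containing the changed one.
#'
#' @param genes List of `model`/`region`/`protein` entries.
#' @param old_models,new_models Lists of exon matrices (region
#'   coordinates).
#' @param config A [run_config()].
#' @param matrix Substitution matrix.
#' @return List per gene: the [compute_changes()] records with `keep` and
#'   `reason` columns.
#' @export
filter_changes <- function(genes, old_models, new_models,
                           config = run_config(),
                           matrix = default_substitution_matrix()) {
  k <- length(genes)
  old_prot <- vapply(seq_len(k), function(g)
    partial_protein(genes[[g]]$region, old_models[[g]])$protein, "")
  ids <- vapply(genes, function(g) g$model$gene_id, "")
  old_aln <- align_proteins(stats::setNames(old_prot, ids),
                            backend = config$aligner)
  out <- vector("list", k)
  for (g in seq_len(k)) {
    recs <- compute_changes(old_models[[g]], new_models[[g]])
    if (nrow(recs)) {
      # each change is judged in isolation: the variant model carries only
      # this change on the otherwise original orthogroup background
      verdicts <- vapply(seq_len(nrow(recs)), function(i) {
        variant <- splice_exon_state(old_models[[g]], new_models[[g]],
                                     recs$start[[i]], recs$end[[i]])
        if (is.null(variant) ||
            !partial_protein(genes[[g]]$region, variant)$ok)
          return("broken variant translation")
        vprot <- old_prot
        vprot[[g]] <- partial_protein(genes[[g]]$region, variant)$protein
        new_aln <- align_proteins(stats::setNames(vprot, ids),
                                  backend = config$aligner)
        judge_change(recs$start[[i]], recs$end[[i]], g,
                     old_models[[g]], variant, old_aln, new_aln, matrix)
      }, "")
      recs$keep <- verdicts == "pass"
      recs$reason <- verdicts
    } else {
      recs$keep <- logical(0)
      recs$reason <- character(0)
    }
    out[[g]] <- recs
  }
  out
}

# exon matrix equal to `base` everywhere except [lo, hi), where the exonic
# state of `donor` is spliced in; NULL when the result has no exon
splice_exon_state <- function(base, donor, lo, hi) {
  n <- max(base[, 2L], donor[, 2L], hi) + 1L
  st <- logical(n)
  for (i in seq_len(nrow(base))) st[seq.int(base[i, 1L] + 1L, base[i, 2L])] <- TRUE
  dn <- logical(n)
  for (i in seq_len(nrow(donor))) dn[seq.int(donor[i, 1L] + 1L, donor[i, 2L])] <- TRUE
  st[seq.int(lo + 1L, hi)] <- dn[seq.int(lo + 1L, hi)]
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(NULL)
  cbind(start = starts[runs] - 1L, end = ends[runs])
}

# residue index range (0-based, half-open) of a region interval in a model
aa_range_for_interval <- function(exons, lo, hi) {
  cum <- 0L
  cds_lo <- NA_integer_
  cds_hi <- NA_integer_
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1L]
    e <- exons[i, 2L]
    olo <- max(s, lo)
    ohi <- min(e, hi)
    if (ohi > olo) {
      if (is.na(cds_lo)) cds_lo <- cum + (olo - s)
      cds_hi <- cum + (ohi - s)
    }
    if (is.na(cds_lo) && s >= hi) {
      # interval precedes this exon: insertion point
      cds_lo <- cum
      cds_hi <- cum
      break
    }
    cum <- cum + (e - s)
  }
  if (is.na(cds_lo)) {
    cds_lo <- cum
    cds_hi <- cum
  }
  c(cds_lo %/% 3L, max(cds_lo %/% 3L, (cds_hi + 2L) %/% 3L))
}

judge_change <- function(lo, hi, g, old_ex, new_ex, old_aln, new_aln, matrix) {
  ao <- aa_range_for_interval(old_ex, lo, hi)
  an <- aa_range_for_interval(new_ex, lo, hi)
  len_old_prot <- sum(old_aln$mat[g, ] != "-")
  len_new_prot <- sum(new_aln$mat[g, ] != "-")
  ao[2L] <- min(ao[2L], len_old_prot)
  an[2L] <- min(an[2L], len_new_prot)
  cols_of <- function(aln, row, aa_from, aa_to) {
    # columns of residues [aa_from, aa_to) of `row` (0-based residues)
    rescols <- which(aln$mat[row, ] != "-")
    if (aa_to <= aa_from) return(integer())
    idx <- seq.int(aa_from + 1L, aa_to)
    idx <- idx[idx >= 1L & idx <= length(rescols)]
    rescols[idx]
  }
  flank_cols <- function(aln, row, aa_lo, aa_hi, w, len) {
    left <- cols_of(aln, row, max(0L, aa_lo - w), aa_lo)
    right <- cols_of(aln, row, aa_hi, min(len, aa_hi + w))
    list(left = left, right = right)
  }
  old_chg <- cols_of(old_aln, g, ao[1L], ao[2L])
  new_chg <- cols_of(new_aln, g, an[1L], an[2L])
  of <- flank_cols(old_aln, g, ao[1L], ao[2L], 10L, len_old_prot)
  nf <- flank_cols(new_aln, g, an[1L], an[2L], 10L, len_new_prot)
  # (1) flanking alignment score must not decrease
  a_old <- windowed_score(old_aln, c(of$left, of$right), matrix = matrix)
  a_new <- windowed_score(new_aln, c(nf$left, nf$right), matrix = matrix)
  if (a_new < a_old - 1e-9) return("flank score decreased")
  # (2) gaps opened in >= 3 sequences across the changed window
  expand1 <- function(cols, aln) {
    if (!length(cols)) return(cols)
    seq.int(max(1L, min(cols) - 1L), min(aln_ncol(aln), max(cols) + 1L))
  }
  ow <- expand1(old_chg, old_aln)
  nw <- expand1(new_chg, new_aln)
  gap_old <- if (length(ow)) rowSums(old_aln$mat[, ow, drop = FALSE] == "-") > 0L
             else rep(FALSE, nrow(old_aln$mat))
  gap_new <- if (length(nw)) rowSums(new_aln$mat[, nw, drop = FALSE] == "-") > 0L
             else rep(FALSE, nrow(new_aln$mat))
  if (sum(gap_new & !gap_old) >= 3L) return("opened gaps in 3+ sequences")
  # (3) micro-changes in gapless regions
  of5 <- flank_cols(old_aln, g, ao[1L], ao[2L], 5L, len_old_prot)
  nf5 <- flank_cols(new_aln, g, an[1L], an[2L], 5L, len_new_prot)
  owin <- c(of5$left, old_chg, of5$right)
  nwin <- c(nf5$left, new_chg, nf5$right)
  gapless_old <- length(owin) > 0L && all(old_aln$mat[, owin] != "-")
  gapless_new <- length(nwin) > 0L && all(new_aln$mat[, nwin] != "-")
  n_changed <- max(ao[2L] - ao[1L], an[2L] - an[1L])
  if (gapless_old && gapless_new) {
    if (n_changed <= 2L) return("micro-change in gapless region")
    d_alpha <- windowed_score(new_aln, nwin, matrix = matrix) -
      windowed_score(old_aln, owin, matrix = matrix)
    if (d_alpha < 4) return("gapless change with alpha gain < 4")
  }
  # (4) local alignment quality around the change in the new alignment
  if (!region_quality_ok(new_aln, g, nf5$left, matrix) ||
      !region_quality_ok(new_aln, g, nf5$right, matrix) ||
      !region_quality_ok(new_aln, g, new_chg, matrix))
    return("low-quality local alignment")
  "pass"
}

# adjusted score >= 3 (or all gaps) for some 3-row subset containing `g`
region_quality_ok <- function(aln, g, cols, matrix) {
  if (!length(cols)) return(TRUE)
  n <- nrow(aln$mat)
  if (n < 3L) return(TRUE)
  others <- setdiff(seq_len(n), g)
  for (pair in utils::combn(others, 2L, simplify = FALSE)) {
    rows <- c(g, pair)
    sub <- aln$mat[rows, cols, drop = FALSE]
    if (all(sub == "-")) return(TRUE)
    if (score_columns(sub, matrix) / length(cols) >= 3) return(TRUE)
  }
  FALSE
}

#' Reconstruct final models from surviving changes
#'
#' Rejected changes are reverted by restoring the original exonic state
#' over the rejected interval; every junction of the result therefore
#' comes from either a surviving new junction or the original annotation.
#' Models that fail structural validation afterwards fall back to the
#' original annotation, flagged.
#'
#' @param genes List of `model`/`region`/`protein` entries.
#' @param old_models,new_models Lists of exon matrices.
#' @param records Output of [filter_changes()].
#' @param config A [run_config()].
#' @return List per gene: `exons` (final matrix), `status` (`unchanged`,
#'   `updated`, `reverted`).
#' @export
final_reconstruction <- function(genes, old_models, new_models, records,
                                 config = run_config()) {
  k <- length(genes)
  out <- vector("list", k)
  for (g in seq_len(k)) {
    recs <- records[[g]]
    old <- old_models[[g]]
    new <- new_models[[g]]
    if (nrow(recs) == 0L) {
      out[[g]] <- list(exons = old, status = "unchanged")
      next
    }
    if (all(recs$keep)) {
      final <- new
    } else if (!any(recs$keep)) {
      final <- old
    } else {
      hi <- max(old[, 2L], new[, 2L]) + 1L
      ex_state <- logical(hi)
      for (i in seq_len(nrow(new)))
        ex_state[seq.int(new[i, 1L] + 1L, new[i, 2L])] <- TRUE
      old_state <- logical(hi)
      for (i in seq_len(nrow(old)))
        old_state[seq.int(old[i, 1L] + 1L, old[i, 2L])] <- TRUE
      for (i in which(!recs$keep)) {
        idx <- seq.int(recs$start[[i]] + 1L, recs$end[[i]])
        ex_state[idx] <- old_state[idx]
      }
      r <- rle(ex_state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      final <- cbind(start = starts[runs] - 1L, end = ends[runs])
    }
    valid_exons <- function(ex) {
      m <- model_from_region_exons(genes[[g]]$region, ex,
                                   genes[[g]]$model$gene_id)
      validate_model(m, genes[[g]]$region, config$alphabet)$valid
    }
    status <- if (chains_equal(final, old)) "unchanged" else "updated"
    if (status == "updated" && !valid_exons(final)) {
      final <- old
      status <- "reverted"
    }
    # a structurally invalid input is never preferred over a valid
    # correction: when the filters would keep (or revert to) a broken
    # original, the optimised model stands in, flagged
    if (chains_equal(final, old) && !chains_equal(new, old) &&
        !valid_exons(old) && valid_exons(new)) {
      final <- new
      status <- "updated"
    }
    out[[g]] <- list(exons = final, status = status)
  }
  out
}
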