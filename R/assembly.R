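#' Enumerate junction or start-codon candidates near an anchor
#'
#' Scans the region sequence for motif positions of the requested kind
#' within `window` nt of `anchor`. Positions are region-local and 0-based:
#' a donor position is the first base of the intron, an acceptor position
#' the first base of the following exon, a start position the first base
#' of the ATG.
#'
#' @param region A [gene_region()].
#' @param anchor Region-local position the search is centred on.
#' @param kind `"start_codon"`, `"donor"` or `"acceptor"`.
#' @param window Search radius in nt.
#' @param alphabet A [site_alphabet()].
#' @return Data frame with `pos` (ascending), `motif` and `frame`
#'   (`pos %% 3`).
#' @export
enumerate_junction_options <- function(region, anchor, kind, window = 30L,
                                       alphabet = site_alphabet()) {
  n <- region_length(region)
  lo <- max(0L, anchor - as.integer(window))
  hi <- min(n, anchor + as.integer(window))
  pos <- seq.int(lo, hi)
  motif <- switch(kind,
    start_codon = substring(region$seq, pos + 1L, pos + 3L),
    donor = substring(region$seq, pos + 1L, pos + 2L),
    acceptor = substring(region$seq, pos - 1L, pos),
    stop("unknown kind: ", kind))
  set <- switch(kind, start_codon = alphabet$starts, donor = alphabet$donors,
                acceptor = alphabet$acceptors)
  keep <- motif %in% set
  if (kind == "acceptor") keep <- keep & pos >= 2L
  if (kind == "start_codon") keep <- keep & pos + 3L <= n
  if (kind == "donor") keep <- keep & pos + 2L <= n
  data.frame(pos = pos[keep], motif = motif[keep],
             frame = as.integer(pos[keep] %% 3L))
}

# translation of a partial exon chain; trailing incomplete codon trimmed
partial_protein <- function(region, exons) {
  if (is.null(exons) || nrow(exons) == 0L)
    return(list(protein = "", ok = TRUE))
  nt <- region_exon_seq(region, exons)
  tr <- translate_cds(nt)
  list(protein = gsub("*", "", tr$protein, fixed = TRUE),
       ok = !tr$internal_stop)
}

# candidate extensions of a partial model with a new part
extension_options <- function(region, exons, part, config) {
  W <- config$wiggle_window
  alphabet <- config$alphabet
  opts <- list()
  if (is.null(exons) || nrow(exons) == 0L) {
    starts <- enumerate_junction_options(region, part$start, "start_codon", W,
                                         alphabet)
    starts <- starts[part$end - starts$pos >= 6L, , drop = FALSE]
    if (nrow(starts) > config$max_junction_options) {
      starts <- starts[order(abs(starts$pos - part$start))[
        seq_len(config$max_junction_options)], , drop = FALSE]
    }
    for (p in starts$pos) {
      opts[[length(opts) + 1L]] <- cbind(start = p, end = part$end)
    }
    return(opts)
  }
  ls <- exons[nrow(exons), 1L]
  le <- exons[nrow(exons), 2L]
  donors <- enumerate_junction_options(region, le, "donor", W, alphabet)
  donors <- donors[donors$pos >= ls + 3L, , drop = FALSE]
  if (nrow(donors) > 6L)
    donors <- donors[order(abs(donors$pos - le))[1:6], , drop = FALSE]
  acceptors <- enumerate_junction_options(region, part$start, "acceptor", W,
                                          alphabet)
  acceptors <- acceptors[acceptors$pos <= part$end - 3L, , drop = FALSE]
  if (nrow(acceptors) > 6L)
    acceptors <- acceptors[order(abs(acceptors$pos - part$start))[1:6], ,
                           drop = FALSE]
  if (!nrow(donors) || !nrow(acceptors)) return(opts)
  cand <- expand.grid(d = donors$pos, a = acceptors$pos)
  cand <- cand[cand$a - cand$d >= config$min_intron, , drop = FALSE]
  if (nrow(cand) > config$max_junction_options) {
    dist <- abs(cand$d - le) + abs(cand$a - part$start)
    cand <- cand[order(dist)[seq_len(config$max_junction_options)], ,
                 drop = FALSE]
  }
  for (i in seq_len(nrow(cand))) {
    e2 <- exons
    e2[nrow(e2), 2L] <- cand$d[[i]]
    opts[[length(opts) + 1L]] <- rbind(e2, c(cand$a[[i]], part$end))
  }
  opts
}

#' Probe a small or junction-less exon for removal
#'
#' When an incoming exon is shorter than the small-exon threshold, or
#' yields no valid junction options at all, removal variants join the
#' option set: one keeping the model as it is (the part is skipped) and,
#' when a previous exon exists, variants that also drop that previous exon
#' and re-attach the incoming part to the exon before it.
#'
#' @param region A [gene_region()].
#' @param exons Current partial exon matrix (or `NULL`).
#' @param part One-row data frame with `start`, `end` (the incoming part).
#' @param config A [run_config()].
#' @param n_options Number of regular junction options found for the part;
#'   probing triggers when 0 or when the part is below the threshold.
#' @return List of alternative partial models (possibly empty; `NULL`
#'   entries mean "leave the model unchanged").
#' @export
probe_small_exons <- function(region, exons, part, config = run_config(),
                              n_options = 1L) {
  if ((part$end - part$start) >= config$small_exon && n_options > 0L)
    return(list())
  out <- list(exons)                               # skip the part entirely
  if (!is.null(exons) && nrow(exons) >= 1L) {
    prev <- exons[-nrow(exons), , drop = FALSE]
    if (nrow(prev)) {
      out <- c(out, extension_options(region, prev, part, config))
    } else {
      out <- c(out, extension_options(region, NULL, part, config))
    }
  }
  out
}

#' Grow gene models by sequential addition of adjacency groups
#'
#' Starting from empty models, adds the parts of each adjacency group left
#' to right. At every addition the splice junctions (or the start codon,
#' for the first exon) are "wiggled": all motif-valid positions within the
#' wiggle window form the option set, options that translate without an
#' internal stop survive, and the multipartite choice function picks one
#' option per region. Exons shorter than the small-exon threshold, or
#' without any valid junction, are probed for removal together with their
#' predecessor.
#'
#' @param genes List of `model`/`region`/`protein` entries.
#' @param groups Ordered list of group data frames (`region`, `start`,
#'   `end`, `frame`).
#' @param config A [run_config()].
#' @return List per region of exon matrices (region coordinates; the final
#'   exon end is provisional until [finalize_stop()]).
#' @export
grow_models <- function(genes, groups, config = run_config()) {
  k <- length(genes)
  state <- rep(list(NULL), k)
  for (grp in groups) {
    options <- vector("list", k)
    changed <- rep(FALSE, k)
    for (g in seq_len(k)) {
      cur <- list(state[[g]])
      rows <- which(grp$region == g)
      if (!length(rows)) {
        options[[g]] <- cur
        next
      }
      part <- grp[rows[order(grp$start[rows])][1L], , drop = FALSE]
      opts <- extension_options(genes[[g]]$region, state[[g]], part, config)
      opts <- c(opts, probe_small_exons(genes[[g]]$region, state[[g]], part,
                                        config, n_options = length(opts)))
      # drop options whose translation breaks
      keep <- list()
      for (o in opts) {
        if (is.null(o)) { keep[[length(keep) + 1L]] <- o; next }
        if (partial_protein(genes[[g]]$region, o)$ok)
          keep[[length(keep) + 1L]] <- o
      }
      if (!length(keep)) keep <- cur
      options[[g]] <- keep
      changed[[g]] <- length(keep) > 1L ||
        !identical(keep[[1L]], state[[g]])
    }
    if (!any(changed)) next
    state <- select_option_set(genes, options, config)
  }
  state
}

# run the multipartite choice function over per-region option lists of
# exon matrices; returns the selected matrices
select_option_set <- function(genes, options, config) {
  k <- length(genes)
  proteins <- vector("list", k)
  for (g in seq_len(k)) {
    proteins[[g]] <- vapply(options[[g]], function(o)
      partial_protein(genes[[g]]$region, o)$protein, "")
    # dedupe options with identical protein products
    d <- !duplicated(proteins[[g]])
    options[[g]] <- options[[g]][d]
    proteins[[g]] <- proteins[[g]][d]
  }
  if (all(lengths(options) == 1L)) return(lapply(options, `[[`, 1L))
  vs <- variant_set(proteins,
                    region_ids = vapply(genes, function(g) g$model$gene_id, ""))
  sel <- choose_variants(vs, reps = config$choice_reps,
                         backend = config$aligner)$selection
  lapply(seq_len(k), function(g) options[[g]][[sel[[g]]]])
}

#' Extend the final exon to the first in-frame stop codon
#'
#' The growth loop leaves the final exon end at the last part's boundary;
#' the model is completed by reading on in frame from the final exon and
#' ending at the first stop codon (which the CDS includes). Failure to
#' find one within the region returns `NULL`.
#'
#' @param region A [gene_region()].
#' @param exons Exon matrix in region coordinates.
#' @param alphabet A [site_alphabet()].
#' @return The completed exon matrix, or `NULL`.
#' @export
finalize_stop <- function(region, exons, alphabet = site_alphabet()) {
  if (is.null(exons) || nrow(exons) == 0L) return(NULL)
  n <- nrow(exons)
  cum_before <- sum(exons[-n, 2L] - exons[-n, 1L])
  need <- (3L - (cum_before %% 3L)) %% 3L
  fcp <- exons[n, 1L] + need
  L <- region_length(region)
  pos <- fcp
  while (pos + 3L <= L) {
    codon <- substring(region$seq, pos + 1L, pos + 3L)
    if (codon %in% alphabet$stops) {
      out <- exons
      out[n, 2L] <- pos + 3L
      if (out[n, 2L] <= out[n, 1L]) return(NULL)
      return(out)
    }
    pos <- pos + 3L
  }
  NULL
}

# introns of an exon matrix as (donor pos, acceptor pos) pairs
model_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(cbind(d = integer(), a = integer()))
  cbind(d = exons[-n, 2L], a = exons[-1L, 1L])
}

#' Re-evaluate new junctions against the original ones
#'
#' For every junction locus the option set is the new position and the
#' original position (junctions pair when both ends lie within the wiggle
#' window); unpaired original introns offer a re-insertion variant,
#' unpaired new introns a removal variant, and a differing original start
#' codon a restored-start variant. Variants compete region-wise through
#' the multipartite choice function, iterated to a fixed point.
#'
#' @param genes List of `model`/`region`/`protein` entries.
#' @param models List of exon matrices (region coordinates) from
#'   [grow_models()] + [finalize_stop()].
#' @param config A [run_config()].
#' @return List of exon matrices.
#' @export
second_pass <- function(genes, models, config = run_config()) {
  k <- length(genes)
  for (iter in 1:3) {
    options <- vector("list", k)
    for (g in seq_len(k)) {
      region <- genes[[g]]$region
      orig <- model_exons_region(genes[[g]]$model, region)
      cur <- models[[g]]
      cands <- c(list(cur), junction_swap_variants(region, cur, orig, config))
      if (!chains_equal(cur, orig)) cands <- c(cands, list(orig))
      keep <- list()
      for (o in cands) {
        if (is.null(o) || !nrow(o) || !partial_protein(region, o)$ok) next
        # structurally broken candidates (e.g. an original junction with no
        # splice motif) never compete: they could only re-corrupt the model
        m <- model_from_region_exons(region, o, genes[[g]]$model$gene_id)
        if (!validate_model(m, region, config$alphabet)$valid) next
        keep[[length(keep) + 1L]] <- o
      }
      options[[g]] <- if (length(keep)) keep else list(cur)
    }
    new_models <- select_option_set(genes, options, config)
    if (all(vapply(seq_len(k), function(g)
      chains_equal(new_models[[g]], models[[g]]), TRUE))) {
      return(new_models)
    }
    models <- new_models
  }
  models
}

chains_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  nrow(a) == nrow(b) && all(a == b)
}

# single-locus hybrids between a model and the original annotation
junction_swap_variants <- function(region, cur, orig, config) {
  W <- config$wiggle_window
  out <- list()
  if (is.null(cur) || nrow(cur) == 0L) return(out)
  in_cur <- model_introns(cur)
  in_orig <- model_introns(orig)
  paired_orig <- rep(FALSE, nrow(in_orig))
  for (i in seq_len(nrow(in_cur))) {
    j <- which(abs(in_orig[, "d"] - in_cur[i, "d"]) <= W &
               abs(in_orig[, "a"] - in_cur[i, "a"]) <= W)
    if (length(j)) {
      j <- j[[1L]]
      paired_orig[[j]] <- TRUE
      if (in_orig[j, "d"] != in_cur[i, "d"] ||
          in_orig[j, "a"] != in_cur[i, "a"]) {
        v <- cur
        v[i, 2L] <- in_orig[j, "d"]
        v[i + 1L, 1L] <- in_orig[j, "a"]
        if (v[i, 2L] > v[i, 1L] && v[i + 1L, 2L] > v[i + 1L, 1L])
          out[[length(out) + 1L]] <- v
      }
    } else {
      # new intron with no original counterpart: offer removal
      v <- cur
      v[i, 2L] <- v[i + 1L, 2L]
      out[[length(out) + 1L]] <- v[-(i + 1L), , drop = FALSE]
    }
  }
  # original introns absent from the model: offer re-insertion
  for (j in which(!paired_orig)) {
    d <- in_orig[j, "d"]
    a <- in_orig[j, "a"]
    host <- which(cur[, 1L] + 3L <= d & cur[, 2L] - 3L >= a)
    if (length(host) == 1L) {
      v <- rbind(cur[seq_len(host - 1L), , drop = FALSE],
                 c(cur[host, 1L], d), c(a, cur[host, 2L]),
                 if (host < nrow(cur))
                   cur[seq.int(host + 1L, nrow(cur)), , drop = FALSE])
      out[[length(out) + 1L]] <- v
    }
  }
  # start codon
  if (cur[1L, 1L] != orig[1L, 1L] && orig[1L, 1L] < cur[1L, 2L] - 3L) {
    v <- cur
    v[1L, 1L] <- orig[1L, 1L]
    out[[length(out) + 1L]] <- v
  }
  out
}

# junction-wiggle variants of a complete model: every intron's donor and
# acceptor, and the start codon, re-offered within the wiggle window
polish_variants <- function(region, exons, config) {
  out <- list(exons)
  if (is.null(exons) || nrow(exons) == 0L) return(out)
  W <- config$wiggle_window
  alphabet <- config$alphabet
  n <- nrow(exons)
  for (i in seq_len(max(0L, n - 1L))) {
    d0 <- exons[i, 2L]
    a0 <- exons[i + 1L, 1L]
    donors <- enumerate_junction_options(region, d0, "donor", W, alphabet)
    donors <- donors$pos[donors$pos >= exons[i, 1L] + 3L]
    acceptors <- enumerate_junction_options(region, a0, "acceptor", W, alphabet)
    acceptors <- acceptors$pos[acceptors$pos <= exons[i + 1L, 2L] - 3L]
    cand <- expand.grid(d = donors, a = acceptors)
    cand <- cand[cand$a - cand$d >= config$min_intron &
                 !(cand$d == d0 & cand$a == a0), , drop = FALSE]
    if (nrow(cand) > config$max_junction_options) {
      dist <- abs(cand$d - d0) + abs(cand$a - a0)
      cand <- cand[order(dist)[seq_len(config$max_junction_options)], ,
                   drop = FALSE]
    }
    for (j in seq_len(nrow(cand))) {
      v <- exons
      v[i, 2L] <- cand$d[[j]]
      v[i + 1L, 1L] <- cand$a[[j]]
      out[[length(out) + 1L]] <- v
    }
  }
  starts <- enumerate_junction_options(region, exons[1L, 1L], "start_codon",
                                       W, alphabet)
  starts <- starts$pos[starts$pos != exons[1L, 1L] &
                       starts$pos <= exons[1L, 2L] - 6L]
  for (p in starts) {
    v <- exons
    v[1L, 1L] <- p
    out[[length(out) + 1L]] <- v
  }
  out
}

#' Localised differences between two exon structures
#'
#' Returns one record per maximal run of bases whose exonic state differs
#' between the old and new model, classified into the standard change
#' categories (exon boundary contraction/extension, exon added/deleted,
#' intron added/deleted, moved start, complex).
#'
#' @param old,new Exon matrices in region coordinates.
#' @return Data frame with `start`, `end` (region coordinates of the
#'   changed bases) and `category`; zero rows when the models are
#'   identical.
#' @export
compute_changes <- function(old, new) {
  empty <- data.frame(start = integer(), end = integer(),
                      category = character())
  if (chains_equal(old, new)) return(empty)
  hi <- max(old[, 2L], new[, 2L]) + 1L
  ov <- logical(hi)
  nv <- logical(hi)
  for (i in seq_len(nrow(old))) ov[seq.int(old[i, 1L] + 1L, old[i, 2L])] <- TRUE
  for (i in seq_len(nrow(new))) nv[seq.int(new[i, 1L] + 1L, new[i, 2L])] <- TRUE
  diff <- ov != nv
  if (!any(diff)) return(empty)
  r <- rle(diff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  recs <- data.frame(start = starts[runs] - 1L, end = ends[runs])
  recs$category <- vapply(seq_len(nrow(recs)), function(i)
    classify_interval(recs$start[[i]], recs$end[[i]], old, new), "")
  recs
}

classify_interval <- function(lo, hi, old, new) {
  old_started <- lo < old[1L, 1L] + 1L || hi <= old[1L, 1L]
  covers <- function(ex, lo, hi)
    any(ex[, 1L] <= lo & ex[, 2L] >= hi)       # interval inside one exon
  equals_exon <- function(ex, lo, hi) any(ex[, 1L] == lo & ex[, 2L] == hi)
  old_exonic <- interval_exonic(old, lo, hi)
  new_exonic <- interval_exonic(new, lo, hi)
  first_old <- old[1L, 1L]
  first_new <- new[1L, 1L]
  if (lo == min(first_old, first_new) && hi == max(first_old, first_new) &&
      old_exonic != new_exonic)
    return("moved start")
  if (old_exonic && !new_exonic) {
    if (equals_exon(old, lo, hi)) return("exon deleted")
    if (covers(new, lo - 1L, hi + 1L) ||
        (any(new[, 2L] == lo) && any(new[, 1L] == hi))) {
      # bases inside a new exon pair boundary: a new intron appeared
      if (any(old[, 1L] <= lo - 1L & old[, 2L] >= hi + 1L) ||
          (any(old[, 1L] < lo) && any(old[, 2L] > hi)))
        return(if (interval_inside_exon(old, lo, hi)) "intron added"
               else "exon boundary contraction")
    }
    return("exon boundary contraction")
  }
  if (!old_exonic && new_exonic) {
    if (equals_exon(new, lo, hi)) return("exon added")
    if (interval_inside_exon(new, lo, hi)) return("intron deleted")
    return("exon boundary extension")
  }
  "complex"
}

interval_exonic <- function(ex, lo, hi) {
  any(pmin(ex[, 2L], hi) - pmax(ex[, 1L], lo) > 0L)
}

interval_inside_exon <- function(ex, lo, hi) {
  any(ex[, 1L] < lo & ex[, 2L] > hi)
}

#' Classify the change between two gene models
#'
#' @param old,new Exon matrices in region coordinates (or [gene_model()]s
#'   with a shared `region`).
#' @param region Optional [gene_region()] when models are passed.
#' @return A single category string: the record's category for a single
#'   localised change, `"none"` for identical models, `"complex"`
#'   otherwise.
#' @export
classify_change <- function(old, new, region = NULL) {
  if (inherits(old, "gene_model")) old <- model_exons_region(old, region)
  if (inherits(new, "gene_model")) new <- model_exons_region(new, region)
  recs <- compute_changes(old, new)
  if (nrow(recs) == 0L) return("none")
  if (nrow(recs) == 1L) return(recs$category[[1L]])
  cats <- unique(recs$category)
  if (identical(cats, "moved start")) return("moved start")
  "complex"
}
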