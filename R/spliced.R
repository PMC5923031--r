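#' Spliced alignment of a protein against a gene region
#'
#' Finds candidate exonic intervals ("gene parts") for a protein in a gene
#' region. The internal backend translates the region in its three forward
#' reading frames (the region is already in coding orientation), splits
#' each translation at stop codons, and locally aligns the protein against
#' every resulting open segment (BLOSUM62, gap open -11, extend -1); hits
#' of at least `min_len` aligned residues and `min_identity` identity are
#' kept, and each segment is probed repeatedly so several exons falling in
#' one open segment can all be recovered.
#'
#' @param protein Amino-acid string (no gaps).
#' @param region A [gene_region()].
#' @param min_len Minimum hit length in residues (default 10).
#' @param min_identity Minimum hit identity in `[0,1]` (default 0.4).
#' @param provenance Label stored on returned parts.
#' @return Data frame with columns `start`, `end` (region-local, 0-based
#'   half-open), `frame` (0..2) and `provenance`; zero rows when nothing
#'   aligns.
#' @export
spliced_align <- function(protein, region, min_len = 10L, min_identity = 0.4,
                          provenance = "pass1") {
  protein <- gsub("-", "", toupper(protein), fixed = TRUE)
  segs <- region_open_segments(region, min_len)
  if (nrow(segs)) segs$region <- 1L
  pairs <- if (nchar(protein) >= min_len && nrow(segs))
    cbind(segs, query = protein, stringsAsFactors = FALSE) else segs[0, ]
  hits <- batch_local_rounds(pairs, min_len, min_identity)
  out <- hits[, c("start", "end", "frame"), drop = FALSE]
  out$provenance <- rep(provenance, nrow(out))
  out <- out[!duplicated(out[c("start", "end", "frame")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# open (stop-free) translated segments of the region in all three frames
region_open_segments <- function(region, min_len) {
  out <- list()
  for (f in 0:2) {
    aa <- translate_frame(region$seq, f)
    if (!nchar(aa)) next
    pieces <- strsplit(aa, "*", fixed = TRUE)[[1L]]
    off <- 0L
    for (p in pieces) {
      if (nchar(p) >= min_len)
        out[[length(out) + 1L]] <- data.frame(seq = p, frame = f, aa_off = off)
      off <- off + nchar(p) + 1L
    }
  }
  if (!length(out)) return(data.frame(seq = character(), frame = integer(),
                                      aa_off = integer()))
  do.call(rbind, out)
}

translate_frame <- function(seq, f) {
  n <- nchar(seq)
  n3 <- n - f
  n3 <- n3 - (n3 %% 3L)
  if (n3 < 3L) return("")
  starts <- seq.int(f + 1L, f + n3 - 2L, 3L)
  aa <- unname(codon_table()[substring(seq, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Repeated rounds of batched elementwise local alignment: `pairs` has one
# row per (open segment, query protein) with columns seq, frame, aa_off,
# region, query. Returns hit intervals per region. After each round the
# unmatched segment flanks re-enter the next round so that several exons
# inside one open segment are all found.
batch_local_rounds <- function(pairs, min_len, min_identity, max_rounds = 3L) {
  hit_list <- list()
  for (round in seq_len(max_rounds)) {
    if (!nrow(pairs)) break
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pairs$seq), Biostrings::AAStringSet(pairs$query),
      substitutionMatrix = pairwise_matrix(), gapOpening = 11,
      gapExtension = 1, type = "local")
    ps <- Biostrings::start(Biostrings::pattern(pa))
    pe <- Biostrings::end(Biostrings::pattern(pa))
    nmatch <- Biostrings::nmatch(pa)
    alen <- Biostrings::nchar(pa)
    ok <- which(alen >= min_len & nmatch / pmax(alen, 1L) >= min_identity)
    if (!length(ok)) break
    idl <- Biostrings::indel(pa)
    ins_s <- as.list(BiocGenerics::start(Biostrings::insertion(idl)))
    ins_w <- as.list(BiocGenerics::width(Biostrings::insertion(idl)))
    del_p <- as.list(BiocGenerics::start(Biostrings::deletion(idl)))
    del_w <- as.list(BiocGenerics::width(Biostrings::deletion(idl)))
    for (i in ok) {
      plen <- pe[[i]] - ps[[i]] + 1L
      blocks <- split_hit_blocks(plen, ins_s[[i]], ins_w[[i]],
                                 del_p[[i]], del_w[[i]], min_len)
      for (b in blocks) {
        aa_lo <- pairs$aa_off[[i]] + ps[[i]] - 1L + b[[1L]]  # 0-based offsets
        aa_hi <- pairs$aa_off[[i]] + ps[[i]] - 1L + b[[2L]]
        hit_list[[length(hit_list) + 1L]] <-
          c(pairs$region[[i]], pairs$frame[[i]] + 3L * aa_lo,
            pairs$frame[[i]] + 3L * aa_hi, pairs$frame[[i]])
      }
    }
    nxt <- list()
    for (i in ok) {
      left <- substr(pairs$seq[[i]], 1L, ps[[i]] - 1L)
      right <- substr(pairs$seq[[i]], pe[[i]] + 1L, nchar(pairs$seq[[i]]))
      if (nchar(left) >= min_len)
        nxt[[length(nxt) + 1L]] <- data.frame(
          seq = left, frame = pairs$frame[[i]], aa_off = pairs$aa_off[[i]],
          region = pairs$region[[i]], query = pairs$query[[i]])
      if (nchar(right) >= min_len)
        nxt[[length(nxt) + 1L]] <- data.frame(
          seq = right, frame = pairs$frame[[i]],
          aa_off = pairs$aa_off[[i]] + pe[[i]],
          region = pairs$region[[i]], query = pairs$query[[i]])
    }
    pairs <- if (length(nxt)) do.call(rbind, nxt) else pairs[0, ]
  }
  if (!length(hit_list))
    return(data.frame(region = integer(), start = integer(), end = integer(),
                      frame = integer()))
  m <- do.call(rbind, hit_list)
  data.frame(region = m[, 1L], start = m[, 2L], end = m[, 3L], frame = m[, 4L])
}

# Split one accepted local hit into exon-like blocks at insertion runs of
# gap_split or more residues (segment residues absent from the query: the
# way a spliced aligner models introns inside a target segment).
# Biostrings reports insertions in subject coordinates and deletions in
# pattern coordinates; the two event streams are merged to place each
# insertion run in pattern space. Returns a list of 0-based (start, end)
# offsets relative to the hit's pattern start.
split_hit_blocks <- function(plen, ins_s, ins_w, del_p, del_w, min_len,
                             gap_split = 8L) {
  cuts_lo <- integer()
  cuts_w <- integer()
  qi <- 1L
  di <- 1L
  delta <- 0L                      # pattern-minus-subject consumed offset
  while (qi <= length(ins_s) || di <= length(del_p)) {
    p_ins <- if (qi <= length(ins_s)) ins_s[[qi]] + delta else NA_integer_
    p_del <- if (di <= length(del_p)) del_p[[di]] else NA_integer_
    if (!is.na(p_ins) && (is.na(p_del) || p_ins <= p_del)) {
      if (ins_w[[qi]] >= gap_split) {
        cuts_lo <- c(cuts_lo, p_ins - 1L)   # 0-based start of the run
        cuts_w <- c(cuts_w, ins_w[[qi]])
      }
      delta <- delta + ins_w[[qi]]
      qi <- qi + 1L
    } else {
      delta <- delta - del_w[[di]]
      di <- di + 1L
    }
  }
  bounds_lo <- c(0L, cuts_lo + cuts_w)
  bounds_hi <- c(cuts_lo, plen)
  out <- list()
  for (bi in seq_along(bounds_lo)) {
    if (bounds_hi[[bi]] - bounds_lo[[bi]] >= min_len)
      out[[length(out) + 1L]] <- c(bounds_lo[[bi]], bounds_hi[[bi]])
  }
  out
}

# reading frames of a model's exons in region coordinates: frame of the
# first complete codon of each exon, given the phase carried into it
exon_frames <- function(exons_r) {
  lens <- exons_r[, 2L] - exons_r[, 1L]
  cum <- c(0L, cumsum(lens))[seq_len(nrow(exons_r))]
  need <- (3L - (cum %% 3L)) %% 3L
  as.integer((exons_r[, 1L] + need) %% 3L)
}

#' Three-pass candidate exon discovery
#'
#' Pass 1 cross-aligns every input protein against every other gene's
#' region; pass 2 re-aligns the protein sequences recovered in pass 1
#' (per source and target region); pass 3 aligns the individual exon
#' peptides from pass 1. The union of all hits with the original annotated
#' exons, de-duplicated by (interval, frame), is the part pool per region.
#' All query/segment pairs of a pass run as one vectorised alignment call.
#'
#' @param genes List of entries with elements `model` ([gene_model()]),
#'   `region` ([gene_region()]) and `protein` (its translation).
#' @param min_len,min_identity Hit thresholds, see [spliced_align()].
#' @return List (one per gene) of part data frames with columns `start`,
#'   `end`, `frame`, `provenance`.
#' @export
three_pass_discovery <- function(genes, min_len = 10L, min_identity = 0.4) {
  k <- length(genes)
  parts <- vector("list", k)
  for (g in seq_len(k)) {
    ex <- model_exons_region(genes[[g]]$model, genes[[g]]$region)
    parts[[g]] <- data.frame(start = ex[, 1L], end = ex[, 2L],
                             frame = exon_frames(ex), provenance = "original")
  }
  segs <- lapply(seq_len(k), function(g) {
    s <- region_open_segments(genes[[g]]$region, min_len)
    if (nrow(s)) s$region <- g
    s
  })
  queries1 <- vapply(genes, `[[`, "", "protein")
  run_pass <- function(queries, targets_of, tag, max_rounds = 2L) {
    plist <- list()
    for (qi in seq_along(queries)) {
      q <- queries[[qi]]
      if (nchar(q) < min_len) next
      for (tgt in targets_of(qi)) {
        s <- segs[[tgt]]
        if (nrow(s)) plist[[length(plist) + 1L]] <- cbind(s, query = q)
      }
    }
    if (!length(plist)) return(NULL)
    h <- batch_local_rounds(do.call(rbind, plist), min_len, min_identity,
                            max_rounds)
    if (nrow(h)) h$provenance <- tag
    h
  }
  h1 <- run_pass(queries1, function(qi) setdiff(seq_len(k), qi), "pass1", 3L)
  found_proteins <- character()
  found_src <- integer()
  exon_peptides <- character()
  pep_src <- integer()
  if (!is.null(h1) && nrow(h1)) {
    for (g in seq_len(k)) parts[[g]] <-
      rbind(parts[[g]], h1[h1$region == g, names(parts[[g]]), drop = FALSE])
    for (tgt in unique(h1$region)) {
      h <- h1[h1$region == tgt, , drop = FALSE]
      h <- h[!duplicated(h[c("start", "end", "frame")]), , drop = FALSE]
      h <- h[order(h$start, -h$end), , drop = FALSE]
      peps <- vapply(seq_len(nrow(h)), function(i)
        translate_frame(substring(genes[[tgt]]$region$seq, h$start[[i]] + 1L,
                                  h$end[[i]]), 0L), "")
      peps <- gsub("*", "", peps, fixed = TRUE)
      # keep one peptide per ~30 nt start bucket (the longest): overlapping
      # hits of the same exon add nothing but alignment work downstream
      keep <- which(nchar(peps) >= min_len)
      if (length(keep)) {
        bucket <- floor(h$start[keep] / 30)
        best <- vapply(split(keep, bucket), function(idx)
          idx[which.max(nchar(peps[idx]))], 0L)
        exon_peptides <- c(exon_peptides, peps[best])
        pep_src <- c(pep_src, rep(tgt, length(best)))
      }
      # one recovered protein per target: greedy non-overlapping hit chain
      last_end <- -1L
      take <- logical(nrow(h))
      for (i in seq_len(nrow(h))) {
        if (h$start[[i]] >= last_end) {
          take[[i]] <- TRUE
          last_end <- h$end[[i]]
        }
      }
      conc <- paste(peps[take], collapse = "")
      if (nchar(conc) >= min_len && !conc %in% queries1) {
        found_proteins <- c(found_proteins, conc)
        found_src <- c(found_src, tgt)
      }
    }
  }
  dup <- duplicated(found_proteins)
  h2 <- run_pass(found_proteins[!dup],
                 local({src <- found_src[!dup]
                        function(qi) setdiff(seq_len(k), src[[qi]])}), "pass2")
  dup <- duplicated(exon_peptides) | exon_peptides %in% queries1
  h3 <- run_pass(exon_peptides[!dup],
                 local({src <- pep_src[!dup]
                        function(qi) setdiff(seq_len(k), src[[qi]])}),
                 "pass3", 1L)
  for (h in list(h2, h3)) {
    if (is.null(h) || !nrow(h)) next
    for (g in unique(h$region)) parts[[g]] <-
      rbind(parts[[g]], h[h$region == g, names(parts[[g]]), drop = FALSE])
  }
  lapply(parts, dedupe_parts)
}

dedupe_parts <- function(df) {
  key <- paste(df$start, df$end, df$frame)
  groups <- split(df$provenance, key)
  prov <- vapply(groups, function(p) paste(sort(unique(p)), collapse = "+"), "")
  n <- lengths(groups)
  # support: how many independent pass-1 discoveries (one per source gene)
  # plus the original annotation back this exact interval
  supp <- vapply(groups, function(p) sum(p == "pass1") + any(p == "original"), 0)
  out <- df[!duplicated(key), , drop = FALSE]
  kk <- paste(out$start, out$end, out$frame)
  out$provenance <- prov[kk]
  out$n_hits <- as.integer(n[kk])
  out$support <- as.integer(supp[kk])
  out <- out[order(out$start, out$end, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# translation of a part chain; first part trimmed to its first complete
# codon. Returns list(protein, ok) where ok = no internal stop.
chain_translation <- function(region, chain) {
  s1 <- chain$start[[1L]]
  fcp <- s1 + ((chain$frame[[1L]] - s1) %% 3L)
  iv <- cbind(start = c(fcp, chain$start[-1L]), end = chain$end)
  nt <- region_exon_seq(region, iv)
  tr <- translate_cds(nt)
  prot <- gsub("*", "", tr$protein, fixed = TRUE)
  list(protein = tr$protein, ok = !tr$internal_stop, degapped = prot)
}

#' Assemble prototype gene models from the part pool
#'
#' Enumerates frame-compatible, non-overlapping chains of parts per region
#' (beam search over coverage weighted by part support) and carries
#' forward, for each region, the chain whose protein maximises the summed
#' global alignment score against the other regions: one pass against the
#' input proteins, then one coordinate-ascent pass against the chosen
#' prototypes. Score ties are broken by the seeded RNG. The chain made of
#' the original annotated exons is always among the candidates; if no
#' valid alternative exists the original model is returned, flagged.
#'
#' @param genes As in [three_pass_discovery()].
#' @param parts Output of [three_pass_discovery()].
#' @param config A [run_config()].
#' @return List per region: `chain` (part data frame), `protein`,
#'   `fallback` (logical).
#' @export
assemble_prototypes <- function(genes, parts, config = run_config()) {
  k <- length(genes)
  cand <- vector("list", k)
  for (g in seq_len(k)) {
    cand[[g]] <- region_chain_candidates(genes[[g]], parts[[g]], config)
  }
  sel <- rep(1L, k)
  refs <- vapply(genes, `[[`, "", "protein")
  for (pass in 1:2) {
    for (g in seq_len(k)) {
      nch <- length(cand[[g]]$proteins)
      if (nch == 1L) next
      others <- setdiff(seq_len(k), g)
      others <- others[nchar(refs[others]) > 0L]
      if (!length(others)) next
      pats <- Biostrings::AAStringSet(rep(cand[[g]]$proteins, length(others)))
      subs <- Biostrings::AAStringSet(rep(refs[others], each = nch))
      sall <- Biostrings::pairwiseAlignment(
        pats, subs, substitutionMatrix = pairwise_matrix(),
        gapOpening = 6, gapExtension = 1, type = "global", scoreOnly = TRUE)
      sc <- rowSums(matrix(sall, nrow = nch))
      # the incumbent annotation stands unless an alternative clearly beats
      # it: marginal gains at this scale are single-residue read-through
      # artefacts, not structural corrections (which gain tens of points)
      if (sc[[cand[[g]]$original_idx]] >= max(sc) - 8) {
        sel[[g]] <- cand[[g]]$original_idx
      } else {
        top <- which(sc > max(sc) - 1e-9)
        sel[[g]] <- if (length(top) == 1L) top
                    else top[sample.int(length(top), 1L)]
      }
      refs[[g]] <- cand[[g]]$proteins[[sel[[g]]]]
    }
  }
  lapply(seq_len(k), function(g) {
    list(chain = cand[[g]]$chains[[sel[[g]]]],
         protein = cand[[g]]$proteins[[sel[[g]]]],
         fallback = cand[[g]]$fallback)
  })
}

# enumerate frame-compatible non-overlapping chains of parts for one region
region_chain_candidates <- function(gene, parts, config) {
  region <- gene$region
  ex <- model_exons_region(gene$model, region)
  orig_chain <- data.frame(start = ex[, 1L], end = ex[, 2L],
                           frame = exon_frames(ex))
  parts <- parts[order(parts$start, parts$end), , drop = FALSE]
  n <- nrow(parts)
  # DP over parts: states carry (part, parent state, end, coding length);
  # a per-part beam keeps the highest-coverage states ending at each part,
  # so kept states never lose their ancestors
  per_part_beam <- max(8L, config$beam %/% 5L)
  # beam ranking weights coverage by part support: parts seen in pass 1 or
  # the original annotation count in full, parts only seen in the derived
  # passes count a quarter (they are enriched for spurious local matches)
  # beam prior: coverage weighted by cross-species support (independent
  # pass-1 discoveries plus the original annotation), minus a flat
  # junction penalty so weak parts only chain when coverage earns it
  supp <- if (!is.null(parts$support)) parts$support else
    as.integer(grepl("original|pass1", parts$provenance))
  ws <- ifelse(supp == 0L, 0.25, supp - 0.5)
  # parts well outside the annotated gene span sit in the buffer: almost
  # always spurious matches, so they are weakly weighted regardless of
  # apparent support (correlated queries can all hit the same junk)
  span_lo <- min(ex[, 1L]) - 60L
  span_hi <- max(ex[, 2L]) + 60L
  outside <- parts$end <= span_lo | parts$start >= span_hi
  ws[outside] <- pmin(ws[outside], 0.25)
  wlen <- (parts$end - parts$start) * ws - 20
  st_part <- integer()
  st_parent <- integer()
  st_end <- integer()
  st_cum <- integer()                    # true coding length (phase)
  st_score <- numeric()                  # weighted coverage (ranking)
  for (i in seq_len(n)) {
    s_i <- parts$start[[i]]
    e_i <- parts$end[[i]]
    f_i <- parts$frame[[i]]
    ok <- which(st_end <= s_i - config$min_intron &
                ((s_i + (3L - (st_cum %% 3L)) %% 3L) %% 3L) == f_i)
    if (length(ok) > per_part_beam)
      ok <- ok[order(-st_score[ok])[seq_len(per_part_beam)]]
    n_new <- length(ok) + 1L
    st_part <- c(st_part, rep(i, n_new))
    st_parent <- c(st_parent, ok, 0L)    # 0 = chain starts here
    st_end <- c(st_end, rep(e_i, n_new))
    st_cum <- c(st_cum, st_cum[ok] + (e_i - s_i), e_i - s_i)
    st_score <- c(st_score, st_score[ok] + wlen[[i]], wlen[[i]])
  }
  top <- order(-st_score)
  if (length(top) > config$beam) top <- top[seq_len(config$beam)]
  chains <- lapply(top, function(s) {
    rows <- integer()
    while (s > 0L) {
      rows <- c(st_part[[s]], rows)
      s <- st_parent[[s]]
    }
    parts[rows, c("start", "end", "frame"), drop = FALSE]
  })
  chains <- c(list(orig_chain), chains)
  proteins <- character(length(chains))
  ok <- logical(length(chains))
  for (i in seq_along(chains)) {
    tr <- chain_translation(region, chains[[i]])
    proteins[[i]] <- tr$degapped
    ok[[i]] <- tr$ok && nchar(tr$degapped) > 0L
  }
  ok[[1L]] <- TRUE                     # original chain always available
  chains <- chains[ok]
  proteins <- proteins[ok]
  dup <- duplicated(proteins)
  dup[[1L]] <- FALSE
  list(chains = chains[!dup], proteins = proteins[!dup],
       original_idx = 1L, fallback = length(chains) == 1L)
}
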