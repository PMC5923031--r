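#' Splice-junction F-score
#'
#' Compares the directed intron boundary coordinates of a gene model
#' (`j_model`) with RNA-seq-derived junctions (`j_rna`). Direction
#' (`intron_start` vs `intron_end`) is part of a junction's identity. RNA
#' junctions supported by fewer than `min_support` reads are excluded
#' before comparison. The two overlap fractions are
#' `jP = |intersection| / |J_R|` and `jR = |intersection| / |J_G|`, and the
#' score is their harmonic mean; when both sets are empty there is nothing
#' to disagree about and the score is 1.
#'
#' @param j_model Data frame with columns `pos` and `direction`
#'   (`"intron_start"`/`"intron_end"`), the model's junctions.
#' @param j_rna Data frame with columns `pos`, `direction` and optionally
#'   `count` (read support).
#' @param min_support Minimum read support for an RNA junction (default 10).
#' @return Numeric in `[0, 1]`.
#' @export
junction_f_score <- function(j_model, j_rna, min_support = 10L) {
  jg <- unique(paste(j_model$pos, j_model$direction))
  if (!is.null(j_rna$count)) j_rna <- j_rna[j_rna$count >= min_support, , drop = FALSE]
  jr <- unique(paste(j_rna$pos, j_rna$direction))
  if (!length(jg) && !length(jr)) return(1)
  if (!length(jg) || !length(jr)) return(0)
  inter <- length(intersect(jg, jr))
  if (inter == 0L) return(0)
  jp <- inter / length(jr)
  jrec <- inter / length(jg)
  2 * jp * jrec / (jp + jrec)
}

#' Rolling-threshold expression characteristic
#'
#' For position `x` of a per-base read-count profile, chi is the smaller of
#' the maximum count strictly left of `x` and the maximum strictly right
#' of `x`; an empty side contributes 0. `expression_characteristic_all`
#' returns the whole chi vector in linear time.
#'
#' @param rho Numeric vector of per-base read counts over a gene region.
#' @param x Position index (1-based into `rho`).
#' @return Numeric chi value (or vector).
#' @export
expression_characteristic <- function(rho, x) {
  if (x < 1L || x > length(rho)) stop("x outside profile")
  left <- if (x > 1L) max(rho[seq_len(x - 1L)]) else 0
  right <- if (x < length(rho)) max(rho[seq.int(x + 1L, length(rho))]) else 0
  min(left, right)
}

#' @rdname expression_characteristic
#' @export
expression_characteristic_all <- function(rho) {
  n <- length(rho)
  if (!n) return(numeric())
  left <- c(0, cummax(rho)[-n])
  right <- rev(c(0, cummax(rev(rho))[-n]))
  pmin(left, right)
}

#' Classify region bases as exonic (on) or intronic (off)
#'
#' A base is `on` when its read count strictly exceeds chi/5 and `off`
#' otherwise (equality counts as off).
#'
#' @param rho Numeric per-base read counts.
#' @return Character vector of `"on"`/`"off"`.
#' @export
classify_bases <- function(rho) {
  chi <- expression_characteristic_all(rho)
  ifelse(rho > chi / 5, "on", "off")
}

#' Coverage score of a gene model
#'
#' The model's features (exons and the introns between them, alternately)
#' are each scored by the fraction of their bases whose on/off
#' classification agrees with the feature type; the coverage score is the
#' unweighted mean over features.
#'
#' @param model A [gene_model()].
#' @param region The matching [gene_region()].
#' @param rho Numeric per-base read counts along the region (index 1 =
#'   region base 0, coding orientation).
#' @return Numeric in `[0, 1]`.
#' @export
coverage_score <- function(model, region, rho) {
  if (length(rho) != region_length(region))
    stop("profile length must equal region length")
  states <- classify_bases(rho)
  ex <- model_exons_region(model, region)
  fractions <- numeric()
  for (i in seq_len(nrow(ex))) {
    idx <- seq.int(ex[i, 1L] + 1L, ex[i, 2L])
    fractions <- c(fractions, mean(states[idx] == "on"))
    if (i < nrow(ex)) {
      idx <- seq.int(ex[i, 2L] + 1L, ex[i + 1L, 1L])
      fractions <- c(fractions, mean(states[idx] == "off"))
    }
  }
  mean(fractions)
}

#' Orthogroup localisation entropy
#'
#' Shannon entropy (base-2) of the proportions of the orthogroup's
#' predicted subcellular localisation categories: 0 when all genes share a
#' category, increasing with disagreement.
#'
#' @param table Data frame with columns `gene_id` and `category`, or a
#'   character vector of categories.
#' @param genes Optional subset of gene ids to score (default all).
#' @return Numeric entropy in bits.
#' @export
localisation_entropy <- function(table, genes = NULL) {
  cats <- if (is.data.frame(table)) {
    if (!is.null(genes)) {
      missing <- setdiff(genes, table$gene_id)
      if (length(missing)) stop("no localisation category for: ",
                                paste(missing, collapse = ", "))
      table$category[match(genes, table$gene_id)]
    } else table$category
  } else as.character(table)
  if (!length(cats)) stop("empty orthogroup")
  p <- as.numeric(table(cats)) / length(cats)
  max(0, -sum(p * log2(p)))     # max() also normalises R's negative zero
}

#' Assessability of a gene region
#'
#' A region is unassessable when it lies within `min_edge` bases of a
#' contig end or contains a run of `max_n_run` or more `N` bases;
#' junction scoring additionally requires at least one base with read
#' depth `min_depth` or more.
#'
#' @param region A [gene_region()].
#' @param contig_length Length of the region's contig.
#' @param rho Optional per-base read counts (for the depth rule).
#' @param min_edge,max_n_run,min_depth Rule thresholds (defaults 1000, 10,
#'   10).
#' @return List with `assessable`, `junction_assessable` and `reasons`.
#' @export
assessability_filter <- function(region, contig_length, rho = NULL,
                                 min_edge = 1000L, max_n_run = 10L,
                                 min_depth = 10L) {
  reasons <- character()
  if (region$g_start < min_edge || (contig_length - region$g_end) < min_edge)
    reasons <- c(reasons, sprintf("within %d bp of contig end", min_edge))
  if (grepl(sprintf("N{%d,}", max_n_run), region$seq))
    reasons <- c(reasons, sprintf("contains a run of %d or more N bases", max_n_run))
  junction_ok <- TRUE
  if (!is.null(rho) && (!length(rho) || max(rho) < min_depth)) {
    junction_ok <- FALSE
    reasons <- c(reasons, sprintf("no base with read depth >= %d", min_depth))
  }
  list(assessable = !any(grepl("contig end|N bases", reasons)),
       junction_assessable = junction_ok && !any(grepl("contig end|N bases", reasons)),
       reasons = reasons)
}

#' Directed junction set of a gene model
#'
#' Returns the model's intron boundaries as directed genomic coordinates:
#' the first base of each intron (`intron_start`) and its last base
#' (`intron_end`), both 0-based, in coding orientation.
#'
#' @param model A [gene_model()].
#' @param region The matching [gene_region()].
#' @return Data frame with columns `pos` (genomic) and `direction`.
#' @export
model_junctions <- function(model, region) {
  ex <- model_exons_region(model, region)
  if (nrow(ex) < 2L)
    return(data.frame(pos = integer(), direction = character()))
  starts_r <- ex[-nrow(ex), 2L]          # first intron base, region coords
  ends_r <- ex[-1L, 1L] - 1L             # last intron base
  data.frame(pos = c(region_to_genomic(region, starts_r),
                     region_to_genomic(region, ends_r)),
             direction = rep(c("intron_start", "intron_end"),
                             each = nrow(ex) - 1L))
}
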