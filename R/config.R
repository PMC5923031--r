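#' Pipeline configuration
#'
#' Collects every tunable of the correction pipeline with its default:
#' 600 bp region buffer, 1000 choice-function repetitions, a +/-30 nt
#' junction wiggle window, the 40 bp small-exon probe threshold, a 20 nt
#' minimum intron, the canonical site alphabet and seed 42. One RNG seeded
#' from `seed` drives every random tie-break tool-wide.
#'
#' @param buffer Bases added each side of a gene span (default 600).
#' @param choice_reps Repetitions of the random reduction (default 1000).
#' @param wiggle_window Junction/start search radius in nt (default 30).
#' @param seed Integer RNG seed (default 42).
#' @param small_exon Exons shorter than this (nt) are probed for removal
#'   (default 40).
#' @param min_intron Minimum intron length in nt (default 20).
#' @param beam Beam width for prototype chain enumeration (default 50).
#' @param max_chain_candidates Chain candidates per region offered to the
#'   choice function (default 6).
#' @param max_junction_options Junction-pair options kept per locus per
#'   region (default 12).
#' @param aligner MSA backend, `"internal"` or `"external"`.
#' @param spliced_aligner Spliced-alignment backend (only `"internal"` is
#'   bundled).
#' @param alphabet A [site_alphabet()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(buffer = 600L, choice_reps = 1000L, wiggle_window = 30L,
                       seed = 42L, small_exon = 40L, min_intron = 20L,
                       beam = 50L, max_chain_candidates = 6L,
                       max_junction_options = 12L,
                       aligner = "external", spliced_aligner = "internal",
                       alphabet = site_alphabet()) {
  num <- list(buffer = buffer, choice_reps = choice_reps,
              wiggle_window = wiggle_window, seed = seed,
              small_exon = small_exon, min_intron = min_intron, beam = beam,
              max_chain_candidates = max_chain_candidates,
              max_junction_options = max_junction_options)
  for (nm in names(num)) {
    if (!is.numeric(num[[nm]]) || num[[nm]] < 0)
      stop("config parameter '", nm, "' must be a non-negative number")
  }
  structure(c(lapply(num, as.integer),
              list(aligner = aligner, spliced_aligner = spliced_aligner,
                   alphabet = alphabet)),
            class = "run_config")
}
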