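test_that("junction option scans find motif positions near the anchor", {
  region <- region_from_seq("AAAGTAAA")
  donors <- enumerate_junction_options(region, 3, "donor", window = 4)
  expect_identical(donors$pos, 3L)
  expect_identical(donors$motif, "GT")
  none <- enumerate_junction_options(region_from_seq("AAAAAAAA"), 4, "donor",
                                     window = 3)
  expect_identical(nrow(none), 0L)
  # GC donors are found when the alphabet includes them
  gc <- enumerate_junction_options(region_from_seq("AAAGCAAA"), 3, "donor",
                                   window = 4)
  expect_identical(gc$motif, "GC")
  strict <- enumerate_junction_options(region_from_seq("AAAGCAAA"), 3, "donor",
                                       window = 4,
                                       alphabet = site_alphabet(donors = "GT"))
  expect_identical(nrow(strict), 0L)
  starts <- enumerate_junction_options(region_from_seq("CCATGCC"), 2,
                                       "start_codon", window = 3)
  expect_identical(starts$pos, 2L)
  acc <- enumerate_junction_options(region_from_seq("CCAGTTT"), 4, "acceptor",
                                    window = 3)
  expect_identical(acc$pos, 4L)      # AG ends just before position 4
})

test_that("small or option-less exons are probed for removal", {
  cfg <- run_config()
  region <- region_from_seq(strrep("A", 400))
  exons <- ex(10, 100, 150, 250)
  part39 <- data.frame(start = 300, end = 339)
  probes <- probe_small_exons(region, exons, part39, cfg, n_options = 5L)
  expect_gte(length(probes), 1L)                 # < 40 bp: probing triggers
  expect_identical(probes[[1]], exons)           # first variant skips the part
  part40 <- data.frame(start = 300, end = 340)
  expect_length(probe_small_exons(region, exons, part40, cfg, n_options = 5L),
                0L)                              # 40 bp with options: no probe
  expect_gte(length(probe_small_exons(region, exons, part40, cfg,
                                      n_options = 0L)), 1L)
})

test_that("stop finalisation extends the last exon to the first in-frame stop", {
  nt <- paste0("ATGAAACCC", "TTTTGA", "GGG")
  region <- region_from_seq(nt)
  out <- finalize_stop(region, ex(0, 9))
  expect_identical(unname(out), unname(ex(0, 15)))   # ends on TGA, included
  expect_null(finalize_stop(region_from_seq("ATGAAACCCAAACCC"), ex(0, 9)))
  expect_null(finalize_stop(region, NULL))
})

test_that("localised differences classify into the standard categories", {
  base <- ex(100, 200, 300, 400, 500, 600)
  expect_identical(classify_change(base, base), "none")
  moved <- base; moved[1, 1] <- 130L
  expect_identical(classify_change(base, moved), "moved start")
  contracted <- base; contracted[2, 2] <- 380L
  expect_identical(classify_change(base, contracted),
                   "exon boundary contraction")
  extended <- base; extended[2, 1] <- 280L
  expect_identical(classify_change(base, extended), "exon boundary extension")
  expect_identical(classify_change(base, base[-2, ]), "exon deleted")
  expect_identical(classify_change(base[-2, ], base), "exon added")
  expect_identical(classify_change(ex(100, 200, 300, 600),
                                   ex(100, 200, 300, 400, 500, 600)),
                   "intron added")
  expect_identical(classify_change(ex(100, 200, 300, 400, 500, 600),
                                   ex(100, 200, 300, 600)),
                   "intron deleted")
  two <- base; two[1, 1] <- 130L; two[2, 2] <- 380L
  expect_identical(classify_change(base, two), "complex")
  recs <- compute_changes(base, two)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$category, c("moved start", "exon boundary contraction"))
})

test_that("the second pass restores an original junction that scores higher", {
  # corrupt one acceptor in the optimised models of every-but-one gene is not
  # needed: shift one junction of one gene and let the originals compete
  og <- generate_orthogroup(seed = 28)
  cfg <- run_config()
  set.seed(cfg$seed)
  genes <- lapply(og$species, function(sp) {
    region <- extract_gene_region(sp$model, sp$genome, cfg$buffer)
    list(model = sp$model, region = region,
         protein = translate_model(sp$model, region)$protein)
  })
  models <- lapply(genes, function(g)
    genemend:::model_exons_region(g$model, g$region))
  # displace one donor of gene 1 to the nearest other valid donor, if any
  found <- FALSE
  for (target_intron in 1:2) {
    d0 <- models[[1]][target_intron, 2]
    cand <- enumerate_junction_options(genes[[1]]$region, d0, "donor",
                                       cfg$wiggle_window, cfg$alphabet)
    cand <- cand$pos[cand$pos != d0 & abs(cand$pos - d0) %% 3 == 0 &
                     cand$pos > models[[1]][target_intron, 1] + 3 &
                     cand$pos < models[[1]][target_intron + 1, 1] - 20]
    if (length(cand)) {
      shifted <- models
      shifted[[1]][target_intron, 2] <- cand[[1]]
      if (genemend:::partial_protein(genes[[1]]$region, shifted[[1]])$ok) {
        out <- second_pass(genes, shifted, cfg)
        expect_identical(unname(out[[1]]), unname(models[[1]]))
        found <- TRUE
        break
      }
    }
  }
  expect_true(found)
  # new identical to original stays unchanged
  out2 <- second_pass(genes, models, cfg)
  for (g in seq_along(models)) {
    expect_identical(unname(out2[[g]]), unname(models[[g]]))
  }
})
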