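test_that("generated orthogroups honour the stated conditions", {
  og <- generate_orthogroup(n_species = 4, n_exons = 3, sub_rate = 0,
                            seed = 20)
  prots <- vapply(og$species, `[[`, "", "protein")
  expect_length(unique(prots), 1L)               # rate 0: identical proteins
  one <- generate_orthogroup(n_exons = 1, seed = 21)
  sp <- one$species[[1]]
  region <- extract_gene_region(sp$model, sp$genome, 600)
  expect_identical(nrow(model_junctions(sp$model, region)), 0L)
  og2 <- generate_orthogroup(seed = 22)
  for (sp in og2$species) {
    region <- extract_gene_region(sp$model, sp$genome, 600)
    v <- validate_model(sp$model, region)
    expect_true(v$valid)
    tr <- translate_model(sp$model, region)
    expect_identical(tr$protein, sp$protein)
  }
  # deterministic per seed
  a <- generate_orthogroup(seed = 23)
  b <- generate_orthogroup(seed = 23)
  expect_identical(a, b)
  expect_error(generate_orthogroup(n_species = 1), "two species")
})

test_that("perturbations plant exactly one structural error each", {
  og <- generate_orthogroup(seed = 24)
  region <- extract_gene_region(og$species[[1]]$model, og$species[[1]]$genome,
                                600)
  truth <- genemend:::model_exons_region(og$species[[1]]$model, region)

  set.seed(1)
  mv <- perturb_model(og, 1, "start_move")
  mex <- genemend:::model_exons_region(mv, region)
  expect_gt(mex[1, 1], truth[1, 1])              # start moved downstream
  expect_identical(mex[-1, ], truth[-1, ])
  tr <- translate_model(mv, region)
  expect_true(startsWith(og$species[[1]]$protein,
                         substr(og$species[[1]]$protein, 1, 1)))
  expect_true(endsWith(og$species[[1]]$protein, tr$protein))  # lost N-prefix

  dl <- perturb_model(og, 1, "exon_delete")
  expect_identical(nrow(dl$exons), nrow(truth) - 1L)

  it <- perturb_model(og, 1, "intron_delete")
  expect_identical(nrow(it$exons), nrow(truth) - 1L)
  itx <- genemend:::model_exons_region(it, region)
  expect_identical(min(itx), min(truth))
  expect_identical(max(itx), max(truth))
  # the retained intron keeps the reading frame and stays translatable
  expect_false(translate_model(it, region)$internal_stop)

  set.seed(2)
  bs <- perturb_model(og, 1, "boundary_shift")
  bex <- genemend:::model_exons_region(bs, region)
  delta <- sum(bex[, 2] - bex[, 1]) - sum(truth[, 2] - truth[, 1])
  expect_identical(delta %% 3L, 0L)              # frame preserving
  expect_false(identical(bex, truth))

  single <- generate_orthogroup(n_exons = 1, seed = 25)
  expect_error(perturb_model(single, 1, "exon_delete"), "single-exon")
  expect_error(perturb_model(single, 1, "boundary_shift"), "spliced")
})

test_that("corrupted models survive a GTF round-trip", {
  og <- generate_orthogroup(seed = 26)
  set.seed(3)
  for (cls in c("boundary_shift", "exon_delete", "intron_delete", "start_move")) {
    bad <- perturb_model(og, 2, cls)
    path <- withr::local_tempfile(fileext = ".gtf")
    write_gene_gtf(bad, path)
    back <- read_gene_gtf(path)
    expect_identical(unname(back$exons), unname(bad$exons))
  }
})

test_that("zero depth makes a region unassessable for junction scoring", {
  og <- generate_orthogroup(seed = 27)
  sp <- og$species[[1]]
  region <- extract_gene_region(sp$model, sp$genome, 600)
  rs <- synth_rnaseq(sp$model, region, depth = 0)
  flag <- assessability_filter(region, contig_length = nchar(sp$genome),
                               rho = rs$rho)
  expect_false(flag$junction_assessable)
})
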