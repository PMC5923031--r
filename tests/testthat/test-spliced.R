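test_that("a contiguously encoded protein is found as a single self-hit", {
  protein <- "MHELKWFNDPHTRSAYCQIV"
  nt <- encode_protein(protein)
  seq <- paste0(strrep("T", 60), nt, strrep("T", 60))
  region <- region_from_seq(seq)
  hits <- spliced_align(protein, region)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$end - hits$start), ]
  expect_equal(best$start, 60)
  expect_equal(best$end, 60 + nchar(nt))
  aa <- genemend:::translate_frame(substr(seq, best$start + 1, best$end), 0)
  expect_identical(aa, protein)
})

test_that("an unrelated protein yields no hits", {
  region <- region_from_seq(paste(rep("ACGT", 60), collapse = ""))
  hits <- spliced_align(strrep("W", 30), region)
  expect_identical(nrow(hits), 0L)
  expect_identical(nrow(spliced_align("", region)), 0L)
})

test_that("a planted intron splits the hit into parts that concatenate back", {
  left <- "MHELKWFNDPHTRSAYCQIV"
  right <- "WWKEYLDNRAHGPQSTFMCI"
  intron <- paste0("GTA", strrep("CTT", 15), "CAG")   # 51 nt, stop-free
  seq <- paste0(strrep("A", 30), encode_protein(left), intron,
                encode_protein(right), strrep("A", 30))
  region <- region_from_seq(seq)
  hits <- spliced_align(paste0(left, right), region)
  expect_gte(nrow(hits), 2L)
  hits <- hits[order(hits$start), ]
  pep <- vapply(seq_len(nrow(hits)), function(i)
    genemend:::translate_frame(substr(seq, hits$start[i] + 1, hits$end[i]), 0),
    "")
  expect_identical(paste(pep, collapse = ""), paste0(left, right))
})

test_that("discovery always retains the original exons and de-duplicates", {
  og <- generate_orthogroup(seed = 8)
  genes <- lapply(og$species, function(sp) {
    region <- extract_gene_region(sp$model, sp$genome, 600)
    list(model = sp$model, region = region,
         protein = translate_model(sp$model, region)$protein)
  })
  parts <- three_pass_discovery(genes)
  for (g in seq_along(genes)) {
    orig <- genemend:::model_exons_region(genes[[g]]$model, genes[[g]]$region)
    key <- paste(parts[[g]]$start, parts[[g]]$end)
    expect_true(all(paste(orig[, 1], orig[, 2]) %in% key))
    expect_false(anyDuplicated(paste(key, parts[[g]]$frame)) > 0)
  }
})

test_that("an exon missing from one annotation is rediscovered from the others", {
  og <- generate_orthogroup(seed = 9)
  bad <- perturb_model(og, 3, "exon_delete")
  genes <- lapply(seq_along(og$species), function(i) {
    m <- if (i == 3) bad else og$species[[i]]$model
    region <- extract_gene_region(m, og$species[[i]]$genome, 600)
    list(model = m, region = region,
         protein = translate_model(m, region)$protein)
  })
  parts <- three_pass_discovery(genes)
  truth <- genemend:::model_exons_region(og$species[[3]]$model,
                                         genes[[3]]$region)
  deleted <- truth[2, ]                     # the internal exon that was lost
  overlap <- pmin(parts[[3]]$end, deleted[2]) - pmax(parts[[3]]$start, deleted[1])
  expect_true(any(overlap >= 0.8 * (deleted[2] - deleted[1])))
})

test_that("prototypes equal the inputs when all annotations agree", {
  og <- generate_orthogroup(seed = 10)
  genes <- lapply(og$species, function(sp) {
    region <- extract_gene_region(sp$model, sp$genome, 600)
    list(model = sp$model, region = region,
         protein = translate_model(sp$model, region)$protein)
  })
  parts <- three_pass_discovery(genes)
  set.seed(42)
  protos <- assemble_prototypes(genes, parts, run_config())
  for (g in seq_along(genes)) {
    truth <- genemend:::model_exons_region(genes[[g]]$model, genes[[g]]$region)
    expect_identical(unname(as.matrix(protos[[g]]$chain[, c("start", "end")])),
                     unname(truth))
    expect_false(protos[[g]]$fallback)
    tr <- genemend:::chain_translation(genes[[g]]$region, protos[[g]]$chain)
    expect_true(tr$ok)
  }
})
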