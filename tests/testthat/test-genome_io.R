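test_that("manifest parsing returns one entry per line and merges transcripts", {
  og <- generate_orthogroup(seed = 5)
  dir <- withr::local_tempdir()
  manifest <- write_orthogroup_files(og, dir)
  entries <- read_manifest(manifest)
  expect_length(entries, 5L)
  for (i in 1:5) {
    expect_identical(unname(entries[[i]]$model$exons),
                     unname(og$species[[i]]$model$exons))
  }
  # a GTF holding two transcript_ids becomes one gene with a variant
  two_tx <- file.path(dir, "two_tx.gtf")
  writeLines(c(
    'chr1\tx\tCDS\t11\t40\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\tCDS\t61\t90\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\tCDS\t11\t90\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'),
    two_tx)
  m <- read_gene_gtf(two_tx)
  expect_identical(m$gene_id, "g1")
  expect_length(m$variants, 1L)
  expect_identical(unname(m$exons), unname(ex(10, 90)))  # longest is primary
  expect_identical(unname(m$variants[[1]]), unname(ex(10, 40, 60, 90)))
})

test_that("manifest errors name the offending line and contig", {
  dir <- withr::local_tempdir()
  gtf <- file.path(dir, "g.gtf")
  fasta <- file.path(dir, "g.fasta")
  writeLines('chrZ\tx\tCDS\t1\t9\t.\t+\t.\tgene_id "g";', gtf)
  write(paste0(">chrA\n", strrep("ACGT", 10)), fasta)
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(paste(gtf, fasta, sep = "\t"), manifest)
  expect_error(read_manifest(manifest), "chrZ")
  writeLines("only_one_field", manifest)
  expect_error(read_manifest(manifest), "line 1")
  bad <- file.path(dir, "bad.gtf")
  writeLines("chr1\tonly\tthree", bad)
  expect_error(read_gene_gtf(bad), "line 1")
})

test_that("gene regions use the stated buffer, clamp at contig ends, and
           read minus-strand genes in coding orientation", {
  contig <- paste(rep("ACGT", 1250), collapse = "")   # 5000 bp
  genome <- c(chr = contig)
  m <- gene_model("g", "chr", "+", ex(1000, 2000))
  r <- extract_gene_region(m, genome, buffer = 600)
  expect_identical(c(r$g_start, r$g_end), c(400L, 2600L))
  expect_identical(r$seq, substr(contig, 401, 2600))
  m2 <- gene_model("g2", "chr", "+", ex(100, 500))
  r2 <- extract_gene_region(m2, genome, buffer = 600)
  expect_identical(r2$g_start, 0L)
  m3 <- gene_model("g3", "chr", "-", ex(1000, 2000))
  r3 <- extract_gene_region(m3, genome, buffer = 600)
  expect_identical(r3$seq, genemend:::revcomp(substr(contig, 401, 2600)))
})

test_that("region/genomic coordinate maps are mutually inverse bijections", {
  genome <- c(chr = paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  for (strand in c("+", "-")) {
    m <- gene_model("g", "chr", strand, ex(100, 160))
    r <- extract_gene_region(m, genome, buffer = 50)
    pos <- seq.int(0L, genemend:::region_length(r) - 1L)
    expect_identical(genomic_to_region(r, region_to_genomic(r, pos)), pos)
  }
})

test_that("translation follows the standard code and flags failures", {
  r <- region_from_seq("ATGGCCTAAGG")
  m <- gene_model("g", "ctg", "+", ex(0, 9))
  tr <- translate_model(m, r)
  expect_identical(tr$protein, "MA")
  expect_false(tr$internal_stop)
  r2 <- region_from_seq("ATGTAACCC")
  tr2 <- translate_model(gene_model("g", "ctg", "+", ex(0, 9)), r2)
  expect_true(tr2$internal_stop)
  expect_identical(genemend:::translate_cds("")$protein, "")
  expect_true(genemend:::translate_cds("ATGGC")$incomplete)
  expect_error(translate_model(gene_model("g", "ctg", "+", ex(0, 20)), r2),
               "outside region")
})

test_that("structural validation reports each violation as data", {
  r <- region_from_seq("ATGAAATAACCC")
  good <- validate_model(gene_model("g", "ctg", "+", ex(0, 9)), r)
  expect_true(good$valid)
  r2 <- region_from_seq("CCCAAATAACCC")
  bad <- validate_model(gene_model("g", "ctg", "+", ex(3, 9)), r2)
  expect_false(bad$valid)
  expect_match(bad$violations, "start codon", all = FALSE)
  # two-exon gene with GT...AG intron: no splice violations
  nt <- paste0("ATGAAA", "GT", strrep("C", 16), "AG", "GAATAA")
  r3 <- region_from_seq(nt)
  v <- validate_model(gene_model("g", "ctg", "+", ex(0, 6, 26, 32)), r3)
  expect_true(v$valid)
  # intron beginning CT: donor violation
  nt2 <- paste0("ATGAAA", "CT", strrep("C", 16), "AG", "GAATAA")
  v2 <- validate_model(gene_model("g", "ctg", "+", ex(0, 6, 26, 32)),
                       region_from_seq(nt2))
  expect_match(v2$violations, "donor", all = FALSE)
})

test_that("write/read round-trips preserve exon coordinates exactly", {
  og <- generate_orthogroup(seed = 6)
  dir <- withr::local_tempdir()
  regions <- lapply(og$species, function(sp)
    extract_gene_region(sp$model, sp$genome, 600))
  models <- lapply(og$species, `[[`, "model")
  write_outputs(models, regions, dir)
  for (i in seq_along(models)) {
    back <- read_gene_gtf(file.path(dir, paste0(models[[i]]$gene_id, ".gtf")))
    expect_identical(unname(back$exons), unname(models[[i]]$exons))
    expect_identical(back$strand, models[[i]]$strand)
    # GTF coordinates ascending regardless of strand
    lines <- readLines(file.path(dir, paste0(models[[i]]$gene_id, ".gtf")))
    expect_length(lines, nrow(models[[i]]$exons))  # one CDS line per exon
    starts <- as.integer(vapply(strsplit(lines, "\t"), `[[`, "", 4L))
    expect_false(is.unsorted(starts))
  }
  aa <- readLines(file.path(dir, "orthogroup.aa.fasta"))
  expect_identical(sum(grepl("^>", aa)), 5L)
})
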