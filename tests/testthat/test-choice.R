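random_instance <- choice_instance         # see helper-oracles.R
exhaustive_max_alpha <- choice_oracle_max

test_that("consensus picks the column-score-maximising residue combination", {
  aln <- protein_alignment(c("A", "V", "A"))
  cons <- consensus_alignment(aln, c(1, 1, 2))
  expect_identical(as.vector(cons), c("A", "A"))   # gamma(A,A)=2 > gamma(V,A)
  same <- protein_alignment(c("MK", "MK", "MK"))
  expect_identical(consensus_alignment(same, c(1, 2, 3)),
                   matrix(c("M", "K"), 3, 2, byrow = TRUE))
  gaps <- protein_alignment(c("-", "-"))
  expect_identical(as.vector(consensus_alignment(gaps, c(1, 2))), c("-", "-"))
})

test_that("binarisation marks agreement with the consensus per column", {
  # region 1 has two options; K beats W in the column consensus, so the
  # second option carries exactly one 0 bit
  aln <- protein_alignment(c("MKV", "MWV", "MKV"))
  reg <- c(1, 1, 2)
  cons <- consensus_alignment(aln, reg)
  expect_identical(cons[1, 2], "K")
  H <- binarise(aln, reg, cons)
  expect_identical(H[1, ], rep(TRUE, 3))            # identical to consensus
  expect_identical(sum(!H[2, ]), 1L)                # exactly one mismatch
  allsame <- protein_alignment(c("AAA", "AAA"))
  expect_true(all(binarise(allsame, c(1, 2),
                           consensus_alignment(allsame, c(1, 2)))))
})

test_that("every reduction keeps at least one option per region", {
  set.seed(7)
  for (rep in 1:25) {
    options <- random_instance(k = 3, lmax = 3, plen = 12)
    vs <- variant_set(options)
    av <- genemend:::align_variant_set(vs)
    H <- binarise(av$aln, av$region_of_row,
                  consensus_alignment(av$aln, av$region_of_row))
    prof <- binary_profile(H, av$region_of_row)
    for (i in 1:4) {
      w <- reduce_once(prof)
      expect_true(all(tapply(w, av$region_of_row, any)))
    }
  }
})

test_that("degenerate variant sets are handled without reduction", {
  vs <- variant_set(list("MKV", "MKA", "MKW"))
  out <- choose_variants(vs, reps = 10)
  expect_identical(out$selection, rep(1L, 3))
  expect_identical(out$proteins, c("MKV", "MKA", "MKW"))
  # every option matching the consensus everywhere: no usable columns, the
  # reduction degenerates to the all-ones string
  H <- matrix(TRUE, 4, 6)
  prof <- binary_profile(H, c(1, 1, 2, 2))
  expect_identical(reduce_once(prof), rep(TRUE, 4))
})

test_that("options can be aligned through a reference alignment", {
  ref <- align_proteins(c(a = "MKVLLAGWD", b = "MKVLAGWD"),
                        backend = "internal")
  vs <- variant_set(list(c("MKVLLAGWD", "MKVLLAGPPWD"), "MKVLAGWD"),
                    region_ids = c("a", "b"), reference = ref)
  av <- genemend:::align_variant_set(vs, backend = "internal")
  expect_identical(nrow(av$aln$mat), 3L)           # option rows only
  expect_identical(unname(genemend:::aln_degap(av$aln)),
                   c("MKVLLAGWD", "MKVLLAGPPWD", "MKVLAGWD"))
  expect_identical(av$region_of_row, c(1L, 1L, 2L))
  sel <- choose_variants(vs, reps = 100)
  expect_identical(sel$selection[[2]], 1L)
})

test_that("the selection attains the exhaustive maximum on small instances", {
  set.seed(31)
  hits <- 0L
  n <- 20L
  for (rep in seq_len(n)) {
    options <- random_instance()
    best <- exhaustive_max_alpha(options)
    sel <- choose_variants(variant_set(options), reps = 1000)$selection
    seqs <- vapply(seq_along(options), function(i) options[[i]][[sel[[i]]]], "")
    attained <- alignment_score(protein_alignment(seqs))
    hits <- hits + (attained >= best - 1e-9)
  }
  expect_gte(hits, n - 1L)
})

test_that("selections are reproducible under a fixed seed", {
  set.seed(5)
  options <- random_instance(k = 4, lmax = 4, plen = 20)
  vs <- variant_set(options)
  set.seed(123)
  a <- choose_variants(vs, reps = 300)
  set.seed(123)
  b <- choose_variants(vs, reps = 300)
  expect_identical(a$selection, b$selection)
  expect_identical(a$proteins, b$proteins)
})

test_that("duplicating the winning option leaves the winning content fixed", {
  set.seed(17)
  options <- random_instance(k = 3, lmax = 3, plen = 15)
  vs <- variant_set(options)
  set.seed(1)
  first <- choose_variants(vs, reps = 500)
  dup <- options
  dup[[1]] <- c(dup[[1]][first$selection[1]], dup[[1]])
  set.seed(1)
  second <- choose_variants(variant_set(dup), reps = 500)
  expect_identical(second$proteins, first$proteins)
})
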