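jn <- function(pos, dir, count = NULL) {
  out <- data.frame(pos = pos, direction = dir)
  if (!is.null(count)) out$count <- count
  out
}

test_that("junction F-score follows the printed overlap fractions", {
  a <- jn(c(10, 19, 30, 39), rep(c("intron_start", "intron_end"), 2))
  expect_equal(junction_f_score(a, a), 1)
  b <- jn(c(100, 109), c("intron_start", "intron_end"))
  expect_equal(junction_f_score(a, b), 0)
  # |J_G| = 4, |J_R| = 5, intersection 3 -> 2*(3/5)*(3/4)/((3/5)+(3/4))
  jg <- jn(1:4, rep("intron_start", 4))
  jr <- jn(c(1:3, 50, 60), rep("intron_start", 5))
  expect_equal(junction_f_score(jg, jr), 2 / 3, tolerance = 1e-9)
  # direction-aware: same positions, opposite direction, no overlap
  flip <- jn(c(10, 19, 30, 39), rep(c("intron_end", "intron_start"), 2))
  expect_equal(junction_f_score(a, flip), 0)
  # symmetry and the empty-set conventions
  expect_equal(junction_f_score(jg, jr), junction_f_score(jr, jg))
  none <- jn(integer(), character())
  expect_equal(junction_f_score(none, none), 1)
  expect_equal(junction_f_score(jg, none), 0)
  # read support below 10 removes RNA junctions before comparison
  weak <- jn(1:4, rep("intron_start", 4), count = c(50, 50, 9, 9))
  expect_equal(junction_f_score(jg, weak), 2 * (2 / 2) * (2 / 4) / (1 + 2 / 4))
})

test_that("the expression characteristic is the min of flanking maxima", {
  rho <- c(0, 5, 0, 10, 0)
  expect_equal(expression_characteristic(rho, 3), 5)
  expect_equal(expression_characteristic(rho, 1), 0)   # empty left side
  expect_equal(expression_characteristic(rho, 5), 0)   # empty right side
  flat <- rep(7, 9)
  expect_equal(expression_characteristic(flat, 5), 7)
  expect_identical(expression_characteristic_all(rho),
                   vapply(seq_along(rho), function(x)
                     expression_characteristic(rho, x), numeric(1)))
  expect_error(expression_characteristic(rho, 0), "outside")
})

test_that("bases classify as on only strictly above chi/5 (equality is off)", {
  rho <- c(5, 0, 2, 1, 5)        # interior positions all have chi = 5
  states <- classify_bases(rho)
  # position 3: chi = min(5,5) = 5; 2 > 1 -> on
  expect_identical(states[3], "on")
  # position 4: chi = 5; 1 == 5/5 -> off (equality)
  expect_identical(states[4], "off")
  # position 2: 0 < 1 -> off
  expect_identical(states[2], "off")
})

test_that("coverage score averages per-feature agreement fractions", {
  # exon(5) + intron(5) + exon(5); plateau 50, threshold 10
  rho <- c(50, 50, 50, 50, 9, 50, 50, 9, 9, 9, 50, 50, 50, 50, 50)
  region <- region_from_seq(strrep("A", 15))
  model <- gene_model("g", "ctg", "+", ex(0, 5, 10, 15))
  expect_equal(coverage_score(model, region, rho), (0.8 + 0.6 + 1.0) / 3)
  # perfect separation scores 1, total miss scores 0
  perfect <- c(rep(50, 5), rep(0, 5), rep(50, 5))
  expect_equal(coverage_score(model, region, perfect), 1)
  single <- gene_model("g", "ctg", "+", ex(5, 10))
  off <- c(rep(50, 5), rep(1, 5), rep(50, 5))
  expect_equal(coverage_score(single, region, off), 0)
  expect_error(coverage_score(model, region, rho[1:3]), "length")
})

test_that("localisation entropy reproduces the worked values", {
  expect_equal(localisation_entropy(rep("mito", 5)), 0)
  expect_equal(localisation_entropy(c(rep("secreted", 4), "cytosolic")),
               0.72, tolerance = 0.005)
  expect_equal(localisation_entropy(c("a", "a", "b", "c", "d")),
               1.92, tolerance = 0.005)
  tab <- data.frame(gene_id = paste0("g", 1:5),
                    category = c("chloroplast", "chloroplast", "mito",
                                 "secreted", "cytosolic"))
  expect_equal(localisation_entropy(tab, genes = paste0("g", 1:5)),
               1.92, tolerance = 0.005)
  expect_error(localisation_entropy(character()), "empty")
  expect_error(localisation_entropy(tab, genes = "missing"), "missing")
})

test_that("assessability rules: contig edge, N runs, and read depth", {
  region <- structure(list(seq = strrep("A", 500), contig = "c", strand = "+",
                           g_start = 2000L, g_end = 2500L, buffer = 0L),
                      class = "gene_region")
  ok <- assessability_filter(region, contig_length = 10000L, rho = rep(50, 500))
  expect_true(ok$assessable)
  expect_true(ok$junction_assessable)
  near <- structure(list(seq = strrep("A", 500), contig = "c", strand = "+",
                         g_start = 500L, g_end = 1000L, buffer = 0L),
                    class = "gene_region")
  expect_false(assessability_filter(near, contig_length = 10000L)$assessable)
  withN <- region
  withN$seq <- paste0(strrep("A", 100), strrep("N", 10), strrep("A", 390))
  expect_false(assessability_filter(withN, contig_length = 10000L)$assessable)
  shallow <- assessability_filter(region, contig_length = 10000L,
                                  rho = rep(9, 500))
  expect_true(shallow$assessable)
  expect_false(shallow$junction_assessable)
})

test_that("synthetic read data give the truth model perfect scores", {
  og <- generate_orthogroup(seed = 14)
  for (i in c(1, 2)) {
    sp <- og$species[[i]]
    region <- extract_gene_region(sp$model, sp$genome, 600)
    rs <- synth_rnaseq(sp$model, region, depth = 50, noise = 0)
    expect_equal(coverage_score(sp$model, region, rs$rho), 1)
    expect_equal(junction_f_score(model_junctions(sp$model, region),
                                  rs$junctions), 1)
    # a corrupted model disagrees with truth-derived junctions
    bad <- perturb_model(og, i, "boundary_shift")
    expect_lt(junction_f_score(model_junctions(bad, region), rs$junctions), 1)
  }
})
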