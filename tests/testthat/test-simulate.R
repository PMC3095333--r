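test_that("generators are pure functions of (parameters, seed)", {
  a <- gen_repeat_protein(n_units = 4, seed = 5)
  b <- gen_repeat_protein(n_units = 4, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$protein,
                         gen_repeat_protein(n_units = 4, seed = 6)$protein))
  expect_identical(gen_cds_pair(n_codons = 50, seed = 5),
                   gen_cds_pair(n_codons = 50, seed = 5))
  expect_identical(gen_tree_sequences(n_taxa = 5, seq_len = 40, seed = 5),
                   gen_tree_sequences(n_taxa = 5, seq_len = 40, seed = 5))
  expect_identical(gen_promoter_set(n_background = 5, length = 50, seed = 5),
                   gen_promoter_set(n_background = 5, length = 50, seed = 5))
  expect_identical(synthetic_supplement(9), synthetic_supplement(9))
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_repeat_protein(n_units = 3, seed = 99))
  invisible(gen_promoter_set(n_background = 3, length = 30, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("zero mutation rate plants exact consensus units", {
  g <- gen_repeat_protein(n_units = 3, unit_mutation_rate = 0, seed = 7)
  s <- unclass(g$protein)[[1]]
  for (k in seq_along(g$truth$starts))
    expect_identical(substr(s, g$truth$starts[k], g$truth$ends[k]),
                     tpr_consensus())
  expect_error(gen_repeat_protein(3, unit_mutation_rate = 0.7), "rates")
})

test_that("tree sequence evolution matches the Poisson model it feeds", {
  flat <- ape::read.tree(text = "(a:0,b:0,c:0);")
  g <- gen_tree_sequences(flat, seq_len = 50, seed = 8)
  expect_length(unique(unclass(g$alignment)), 1)
  expect_true(all(poisson_distance(g$alignment) == 0))

  two <- ape::read.tree(text = "(a:0.1,b:0.1);")
  g2 <- gen_tree_sequences(two, seq_len = 10000, seed = 9)
  d <- poisson_distance(g2$alignment)["a", "b"]
  p <- 1 - exp(-0.2)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs((1 - exp(-d)) - p), 3 * se)
})

test_that("planted omega = 0 yields Ka = 0", {
  g <- gen_cds_pair(n_codons = 300, omega = 0, target_divergence = 0.05,
                    seed = 10)
  expect_equal(kaks(g$cds_a, g$cds_b)$Ka, 0)
})

test_that("promoter planting respects counts and feasibility", {
  pm <- gen_promoter_set(n_background = 5, length = 200,
                         planted = list(pattern = "TGACGT", copies = 4,
                                        n_targets = 2), seed = 11)
  expect_length(pm$targets, 2)
  for (t in 1:2) {
    expect_gte(count_motif(unclass(pm$targets)[[t]], "TGACGT"), 4)
    expect_length(pm$truth$planted_positions[[t]], 4)
  }
  expect_error(gen_promoter_set(n_background = 2, length = 20,
                                planted = list(pattern = "TGACGT",
                                               copies = 10, n_targets = 1),
                                seed = 1), "fit")
  none <- gen_promoter_set(n_background = 3, length = 100, seed = 12)
  expect_null(none$targets)
})

test_that("the synthetic supplement has the documented census and architectures", {
  supp <- synthetic_supplement(13)
  expect_identical(lengths(supp$tpr_families),
                   c(CDC27 = 15L, APC5 = 11L, CDC16 = 12L, APC7 = 9L,
                     CDC23 = 14L))
  expect_true(all(unlist(supp$tpr_families) %in% names(supp$proteins)))
  expect_false(scan_protein_motifs(supp$proteins["AtCDC20_6"])$has_c_box)
  expect_length(scan_protein_motifs(supp$proteins["AtCDC20_6"])$ken_boxes, 0)
  expect_false(scan_protein_motifs(supp$proteins["PtCDC20_5"])$has_c_box)
  expect_true(scan_protein_motifs(supp$proteins["AtCDC20_1"])$has_c_box)
})
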