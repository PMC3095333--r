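test_that("planted repeats are detected at their planted coordinates", {
  g <- gen_repeat_protein(n_units = 5, unit_mutation_rate = 0,
                          linker_len = 15, seed = 3)
  d <- detect_tpr(g$protein)
  expect_equal(nrow(d), 5)
  expect_identical(d$start, g$truth$starts)
  expect_identical(d$end, g$truth$ends)
  expect_true(all(d$end - d$start + 1L == 34L))
})

test_that("short proteins yield an empty domain table, not an error", {
  expect_equal(nrow(detect_tpr("MKVLA")), 0)
})

test_that("detected domains never overlap and stay in bounds", {
  for (seed in 1:8) {
    g <- gen_repeat_protein(n_units = sample(2:6, 1),
                            unit_mutation_rate = 0.25, seed = seed)
    d <- detect_tpr(g$protein)
    expect_true(all(d$start >= 1 & d$end <= nchar(unclass(g$protein)[[1]])))
    if (nrow(d) > 1) {
      expect_true(all(diff(d$start) > 0))
      expect_true(all(d$start[-1] > d$end[-nrow(d)]))
    }
  }
})

test_that("extracted units re-detect above threshold and errors are caught", {
  g <- gen_repeat_protein(n_units = 4, unit_mutation_rate = 0.15, seed = 5)
  d <- detect_tpr(g$protein)
  units <- extract_domains(g$protein, d)
  expect_length(units, nrow(d))
  expect_true(all(nchar(unclass(units)) == 34))
  prof <- tpr_profile()
  for (i in seq_along(units)) {
    sc <- detect_tpr(unclass(units)[[i]], prof)$score
    expect_gte(sc, 60)
  }
  expect_identical(extract_domains(g$protein, d[0, ]), list())
  bad <- d; bad$end[1] <- nchar(unclass(g$protein)[[1]]) + 5L
  expect_error(extract_domains(g$protein, bad), "bounds")
})

test_that("self score matrix is symmetric with dominant diagonal; shading tracks score", {
  g <- gen_repeat_protein(n_units = 5, unit_mutation_rate = 0.2, seed = 8)
  units <- extract_domains(g$protein, detect_tpr(g$protein))
  m <- build_matrix(units)
  expect_true(m$self)
  expect_equal(m$scores, t(m$scores))
  for (i in seq_len(nrow(m$scores)))
    expect_equal(max(m$scores[i, ]), m$scores[i, i])
  expect_identical(rank(m$shading, ties.method = "average"),
                   rank(m$scores, ties.method = "average"))
  expect_true(all(m$shading >= 0 & m$shading <= 1))
})

test_that("a planted duplicated pair is the off-diagonal maximum", {
  g <- gen_repeat_protein(n_units = 6, unit_mutation_rate = 0.2,
                          duplicated_pairs = list(c(2L, 5L)),
                          dup_divergence = 0.1, seed = 12)
  units <- extract_domains(g$protein, detect_tpr(g$protein))
  expect_length(units, 6)
  m <- build_matrix(units)
  off <- m$scores[upper.tri(m$scores)]
  expect_equal(max(off), m$scores[2, 5])
})

test_that("find_blocks reports exactly a planted diagonal run", {
  sc <- matrix(50, 6, 6) + diag(100, 6)
  for (t in 0:2) sc[2 + t, 4 + t] <- sc[4 + t, 2 + t] <- 120
  m <- structure(list(scores = sc, shading = sc / max(sc),
                      rows_parent = "x", cols_parent = "x", self = TRUE),
                 class = "domain_score_matrix")
  b <- find_blocks(m, score_quantile = 0.75, min_run = 2)
  expect_equal(nrow(b), 1)
  expect_equal(unlist(b[1, 1:4]),
               c(row_start = 2, row_end = 4, col_start = 4, col_end = 6))
  flat <- structure(list(scores = matrix(50, 5, 5) + diag(100, 5),
                         shading = diag(5), rows_parent = "x",
                         cols_parent = "x", self = TRUE),
                    class = "domain_score_matrix")
  expect_equal(nrow(find_blocks(flat)), 0)
})

test_that("protein motif scan finds C-box, KEN, D-box and IR tail", {
  r <- scan_protein_motifs("MDRFIPSRKENAAARVVLAAIR", parent_id = "toy")
  expect_true(r$has_c_box)
  expect_equal(r$c_box_pos, 2L)
  expect_identical(r$ken_boxes, 9L)
  expect_true(r$has_ir_tail)
  expect_true(15L %in% r$d_boxes) # RVVL
  r2 <- scan_protein_motifs("MKVLAWT")
  expect_false(r2$has_c_box)
  expect_false(r2$has_ir_tail)
  # overlapping D-boxes are all reported
  r3 <- scan_protein_motifs("ARRALLA")
  expect_identical(r3$d_boxes, c(2L, 3L))
})
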