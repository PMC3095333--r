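test_that("motif counting follows the overlap convention and N never matches", {
  expect_equal(count_motif("TGACGTTGACGT", "TGACGT"), 2L)
  expect_equal(count_motif("AAAA", "AAA"), 2L)
  expect_equal(count_motif("AANA", "AAAA"), 0L)
  expect_equal(count_motif("ACG", "ACGT"), 0L) # pattern longer than promoter
  expect_equal(count_motif("TAACCA", "WAACCA"), 1L)
  expect_equal(count_motif("GAACCA", "WAACCA"), 0L)
})

test_that("count_motif equals the naive scan oracle on random promoters", {
  set.seed(71)
  pats <- c("WAACCA", "CANNTG", "GRWAAW", "TGACY", "GATA")
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 500, TRUE,
                      prob = c(.29, .2, .2, .29, .02)), collapse = "")
    for (p in pats)
      expect_equal(count_motif(s, p), oracle_count_motif(s, p),
                   label = paste(p, rep))
  }
})

test_that("both-strand counting adds reverse-complement occurrences", {
  s <- paste0(strrep("A", 20), "TGACGT", strrep("A", 20), "ACGTCA",
              strrep("A", 20))
  expect_equal(count_motif(s, "TGACGT", "forward"), 1L)
  expect_equal(count_motif(s, "TGACGT", "both"), 2L)
})

test_that("surrogate null summarises per-promoter counts with sd n-1", {
  base <- strrep("A", 100)
  with_copies <- function(k) {
    s <- base
    for (i in seq_len(k)) substr(s, i * 10, i * 10 + 5) <- "TGACGT"
    s
  }
  bg <- seq_set(vapply(0:3, with_copies, character(1)),
                ids = paste0("p", 0:3), alphabet = "dna")
  null <- surrogate_null("TGACGT", bg)
  expect_identical(null$counts, 0:3)
  expect_equal(null$mean, 1.5)
  expect_equal(null$sd, sd(0:3))
  expect_equal(null$sd, 1.29099, tolerance = 1e-5)
  same <- seq_set(rep(base, 3), ids = paste0("q", 1:3), alphabet = "dna")
  expect_equal(surrogate_null("TGACGT", same)$sd, 0)
  expect_error(surrogate_null("TGACGT", same[1]), ">= 2")
})

test_that("z and one-tailed p follow the surrogate-null formula", {
  # null with mean 2, sd 1; promoter with 5 copies -> z = 3
  bg <- seq_set(c(a = paste0("TGACGT", strrep("C", 94)),
                  b = paste0(strrep("TGACGT", 2), strrep("C", 88)),
                  c = paste0(strrep("TGACGT", 3), strrep("C", 82))),
                alphabet = "dna")
  null <- surrogate_null("TGACGT", bg)
  expect_equal(null$mean, 2); expect_equal(null$sd, 1)
  prom <- paste0(strrep("TGACGT", 5), strrep("C", 70))
  r <- enrichment_test(prom, "TGACGT", null, empirical = TRUE)
  expect_equal(r$z, 3)
  expect_equal(r$p_one_tailed, pnorm(3, lower.tail = FALSE))
  expect_equal(r$p_one_tailed, 0.00135, tolerance = 1e-2)
  expect_true(r$significant)
  expect_equal(r$p_empirical, (1 + 0) / 4)
  # c_true equal to the mean -> z = 0, p = 0.5, not significant
  r2 <- enrichment_test(paste0(strrep("TGACGT", 2), strrep("C", 88)),
                        "TGACGT", null)
  expect_equal(r2$z, 0); expect_equal(r2$p_one_tailed, 0.5)
  expect_false(r2$significant)
})

test_that("a degenerate null (sd 0) is handled by sign rules", {
  bg <- seq_set(rep(strrep("C", 50), 3), ids = paste0("p", 1:3),
                alphabet = "dna")
  null <- surrogate_null("TGAC", bg)
  hi <- enrichment_test(paste0("TGAC", strrep("C", 46)), "TGAC", null)
  expect_true(is.na(hi$z)); expect_equal(hi$p_one_tailed, 0)
  eq <- enrichment_test(strrep("C", 50), "TGAC", null)
  expect_equal(eq$p_one_tailed, 0.5)
})

test_that("shared elements are the intersection of significant calls", {
  pm <- gen_promoter_set(n_background = 60, length = 600,
                         planted = list(pattern = "TGACGT", copies = 10,
                                        n_targets = 2), seed = 72)
  motifs <- data.frame(name = c("CBOXLIKE", "GATABOX"),
                       pattern = c("TGACGT", "GATA"))
  res <- enrich_promoters(pm$targets, motifs, pm$background)
  a <- res[res$gene_id == "target01", ]
  b <- res[res$gene_id == "target02", ]
  expect_identical(shared_elements(a, b), "CBOXLIKE")
  expect_identical(shared_elements(a, a), a$motif_name[a$significant])
  expect_error(shared_elements(a, b[b$motif_name == "GATABOX", ]),
               "different motif tables")
})
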