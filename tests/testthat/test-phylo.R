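test_that("Poisson distance matches the closed form and a naive site count", {
  aln <- seq_set(c(a = paste(rep("A", 10), collapse = ""),
                   b = paste(c(rep("A", 9), "C"), collapse = "")),
                 alphabet = "protein", aligned = TRUE)
  D <- poisson_distance(aln)
  expect_equal(D["a", "b"], -log(0.9), tolerance = 1e-12)
  expect_equal(D["a", "a"], 0)

  set.seed(21)
  for (rep in 1:5) {
    g <- gen_tree_sequences(n_taxa = 5, seq_len = 80, seed = rep)
    D <- poisson_distance(g$alignment)
    mat <- do.call(rbind, strsplit(unclass(g$alignment), ""))
    for (i in 1:4) for (j in (i + 1):5) { # naive column loop
      mis <- 0; tot <- 0
      for (col in seq_len(ncol(mat))) {
        tot <- tot + 1
        if (mat[i, col] != mat[j, col]) mis <- mis + 1
      }
      expect_equal(D[i, j], -log(1 - mis / tot))
    }
  }
})

test_that("gap policy drops columns and saturated pairs error informatively", {
  aln <- seq_set(c(a = "AK-VA", b = "AKWVA", c = "AKWVC"),
                 alphabet = "protein", aligned = TRUE)
  Dc <- poisson_distance(aln, "complete") # 4 usable columns
  expect_equal(Dc["a", "b"], 0)
  expect_equal(Dc["b", "c"], -log(1 - 1 / 4))
  Dp <- poisson_distance(aln, "pairwise") # b vs c keeps 5 columns
  expect_equal(Dp["b", "c"], -log(1 - 1 / 5))
  sat <- seq_set(c(a = "AAAA", b = "CCCC"), alphabet = "protein",
                 aligned = TRUE)
  expect_error(poisson_distance(sat), "a / b")
})

test_that("3-taxon NJ has closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on additive matrices and matches the exhaustive oracle", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- ape::rtree(5, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(ape::dist.topo(nj, tr), 0, ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] -
                        D)), 1e-9)
    oracle <- bf_nj_topology(D)
    expect_lt(oracle$rss, 1e-16)
    expect_equal(ape::dist.topo(nj, oracle$tree), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic given the seed and saturate on constant signal", {
  # every column identical: any resample reproduces the same alignment,
  # hence the same tree, so every bipartition appears in every replicate
  aln <- seq_set(rep(strrep("A", 60), 4), ids = paste0("t", 1:4),
                 alphabet = "protein", aligned = TRUE)
  tr <- bootstrap_support(aln, B = 25, seed = 9)
  supp <- as.numeric(tr$node.label[nzchar(tr$node.label)])
  expect_true(all(supp == 100))

  g2 <- gen_tree_sequences(n_taxa = 6, seq_len = 150, seed = 42)
  t1 <- bootstrap_support(g2$alignment, B = 40, seed = 7)
  t2 <- bootstrap_support(g2$alignment, B = 40, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  s1 <- as.numeric(t1$node.label[nzchar(t1$node.label)])
  expect_true(all(s1 >= 0 & s1 <= 100))
})

test_that("condense collapses exactly the sub-threshold bipartitions", {
  tr <- ape::read.tree(
    text = "((A:1,B:1)90:1,((C:1,D:1)49:1,(E:1,F:1)75:1)60:1,G:1);")
  ct <- condense(tr, 50)
  expect_identical(sort(ct$tip.label), sort(tr$tip.label))
  keys <- oracle_bipartitions(tr)
  low <- oracle_bipartitions(ape::keep.tip(tr, c("C", "D", "E", "F", "G")))
  kept <- oracle_bipartitions(ct)
  expect_true(!paste(sort(c("C", "D")), collapse = "|") %in% kept)
  expect_setequal(kept, setdiff(keys, paste(sort(c("C", "D")),
                                            collapse = "|")))
  # idempotent, and a no-op when everything is supported
  expect_identical(ape::write.tree(condense(ct, 50)), ape::write.tree(ct))
  hi <- ape::read.tree(text = "((A:1,B:1)90:1,(C:1,D:1)80:1,E:1);")
  expect_setequal(oracle_bipartitions(condense(hi, 50)),
                  oracle_bipartitions(hi))
})

test_that("condense keeps the original minus sub-threshold set on random supports", {
  set.seed(51)
  for (rep in 1:5) {
    g <- gen_tree_sequences(n_taxa = 7, seq_len = 120, seed = 60 + rep)
    tr <- neighbor_joining(poisson_distance(g$alignment))
    n <- length(tr$tip.label)
    supports <- sample(0:100, tr$Nnode, replace = TRUE)
    tr$node.label <- as.character(supports)
    tr$node.label[1] <- "" # root carries no support
    ct <- condense(tr, 50)
    all_keys <- oracle_bipartitions(tr)
    # map each internal node's key to its support via the package view
    keys <- apcevol:::bipartitions(tr)
    drop <- keys[supports[as.integer(names(keys)) - n] < 50]
    expect_setequal(oracle_bipartitions(ct), setdiff(all_keys, drop))
  }
})

test_that("NJ + bootstrap recovers a known 8-taxon topology from simulated data", {
  hits <- 0; total <- 0
  for (rep in 1:20) {
    g <- gen_tree_sequences(n_taxa = 8, branch_length = c(0.05, 0.3),
                            seq_len = 300, seed = 500 + rep)
    bt <- bootstrap_support(g$alignment, B = 200, seed = 900 + rep)
    truth <- oracle_bipartitions(g$tree)
    keys <- apcevol:::bipartitions(bt)
    supp <- setNames(as.numeric(bt$node.label[as.integer(names(keys)) -
                                                length(bt$tip.label)]),
                     keys)
    total <- total + length(truth)
    hits <- hits + sum(truth %in% names(supp)[supp >= 50])
  }
  expect_gte(hits / total, 0.8)
})
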