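# Independent oracles. These deliberately avoid the package's algorithms:
# alignments are scored by exhaustive recursion over all gapped alignments,
# NJ is checked against least-squares fits over every 5-taxon topology,
# codon counts are re-derived by direct enumeration, and motif counts by a
# position-by-position set-membership scan.

# ---- exhaustive alignment oracles -----------------------------------------

# maximum score over all global alignments of a vs b (affine gaps: a run of
# L gap columns costs open + (L-1)*ext; end gaps charged).
bf_global <- function(av, bv, sub, open, ext) {
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- sub[av[i], bv[j]] + rec(i + 1L, j + 1L, 0L)
      if (s > best) best <- s
    }
    if (i <= n) {
      s <- -(if (prev == 1L) ext else open) + rec(i + 1L, j, 1L)
      if (s > best) best <- s
    }
    if (j <= m) {
      s <- -(if (prev == 2L) ext else open) + rec(i, j + 1L, 2L)
      if (s > best) best <- s
    }
    best
  }
  rec(1L, 1L, 0L)
}

# maximum over all substring pairs of the global score (an optimal local
# alignment has no terminal gaps, so this sweep covers it), floored at 0.
bf_local <- function(av, bv, sub, open, ext) {
  best <- 0
  n <- length(av); m <- length(bv)
  for (i1 in seq_len(n)) for (i2 in i1:n)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      s <- bf_global(av[i1:i2], bv[j1:j2], sub, open, ext)
      if (s > best) best <- s
    }
  best
}

# ---- NJ topology oracle ----------------------------------------------------

# edges on the tip-to-tip path, found by BFS on the (undirected) edge list
path_edges <- function(tree, from_tip, to_tip) {
  e <- tree$edge
  nn <- max(e)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], k))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], k))
  }
  start <- which(tree$tip.label == from_tip)
  goal <- which(tree$tip.label == to_tip)
  prev <- rep(NA_integer_, nn); prev_edge <- rep(NA_integer_, nn)
  queue <- start; seen <- rep(FALSE, nn); seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == goal) break
    for (r in seq_len(NROW(adj[[v]]))) {
      w <- adj[[v]][r, 1]
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- v; prev_edge[w] <- adj[[v]][r, 2]
        queue <- c(queue, w)
      }
    }
  }
  path <- integer(0); v <- goal
  while (v != start) { path <- c(path, prev_edge[v]); v <- prev[v] }
  path
}

# best-fitting topology among all 15 unrooted 5-taxon trees: solve least
# squares for edge lengths per topology and pick the (additive) zero-residual
# fit.
bf_nj_topology <- function(D) {
  taxa <- rownames(D)
  tops <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
  pairs <- t(combn(taxa, 2))
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(tops)) {
    tr <- tops[[ti]] # `[[` restores the compressed multiPhylo tip labels
    X <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (p in seq_len(nrow(pairs)))
      X[p, path_edges(tr, pairs[p, 1], pairs[p, 2])] <- 1
    y <- D[pairs]
    fit <- stats::lsfit(X, y, intercept = FALSE)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- tr }
  }
  list(tree = best, rss = best_rss)
}

# canonical bipartition keys of a tree, independent of the package helper
oracle_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- sort(labs)[1]
  n <- length(labs)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, 1L)
  unique(keys[sizes >= 2 & sizes <= n - 2])
}

# ---- codon-count oracles ---------------------------------------------------

oracle_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) for (nt in nts) {
    if (nt == ch[pos]) next
    alt <- ch; alt[pos] <- nt
    if (gc[[paste(alt, collapse = "")]] == gc[[codon]]) syn <- syn + 1
  }
  syn / 3
}

# pathway-averaged differences for a codon pair, by direct permutation walk
oracle_pair_diffs <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  dp <- which(ca != cb)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  ords <- perms(dp)
  sy <- ny <- 0
  for (ord in ords) {
    cur <- ca
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- cb[pos]
      if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]])
        sy <- sy + 1 else ny <- ny + 1
      cur <- nxt
    }
  }
  c(Sd = sy / length(ords), Nd = ny / length(ords))
}

# ---- motif scan oracle -----------------------------------------------------

oracle_count_motif <- function(seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sv <- strsplit(toupper(seq), "")[[1]]
  pv <- strsplit(toupper(pattern), "")[[1]]
  w <- length(pv); n <- length(sv)
  if (w > n) return(0L)
  cnt <- 0L
  for (i in seq_len(n - w + 1L)) {
    ok <- TRUE
    for (k in seq_len(w))
      if (!(sv[i + k - 1L] %in% sets[[pv[k]]])) { ok <- FALSE; break }
    if (ok) cnt <- cnt + 1L
  }
  cnt
}

# random protein over a reduced alphabet (for alignment oracle tests)
rand_chars <- function(n, alphabet = c("A", "R", "N", "D")) {
  sample(alphabet, n, replace = TRUE)
}
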