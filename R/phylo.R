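#' Poisson-corrected protein distances
#'
#' For each taxon pair the proportion of differing residues p over usable
#' columns is converted to an expected number of substitutions per site,
#' d = -ln(1 - p). Columns containing a gap or `X` are unusable: under
#' `"complete"` deletion (default, as in MEGA) a column with a gap/`X` in
#' any row is dropped for all pairs; under `"pairwise"` deletion columns
#' are dropped per pair.
#'
#' @param aln an aligned protein [seq_set].
#' @param site_policy `"complete"` or `"pairwise"`.
#' @return a symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
poisson_distance <- function(aln, site_policy = c("complete", "pairwise")) {
  site_policy <- match.arg(site_policy)
  if (!is_aligned(aln)) stop("aln must be an aligned seq_set")
  mat <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(mat) <- names(aln)
  usable <- !(mat == "-" | mat == "X")
  if (site_policy == "complete") {
    keep <- apply(usable, 2, all)
    if (sum(keep) < 2) stop("fewer than 2 usable columns after gap policy")
    mat <- mat[, keep, drop = FALSE]
    usable <- usable[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- usable[i, ] & usable[j, ]
      if (sum(ok) < 1) stop("no usable sites for pair ", rownames(mat)[i],
                            " / ", rownames(mat)[j])
      p <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
      if (p >= 1) stop("p-distance >= 1 for pair ", rownames(mat)[i], " / ",
                       rownames(mat)[j], "; Poisson correction undefined")
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || is.null(rownames(D)))
    stop("D must be a square matrix with taxon dimnames")
  if (!all(is.finite(D))) stop("non-finite distances")
  if (any(abs(D - t(D)) > 1e-12)) stop("D must be symmetric")
  invisible(D)
}

fmt_bl <- function(x) sprintf("%.15g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration. Ties in the Q criterion are broken toward the
#' lowest (row, column) index pair, and negative intermediate branch lengths
#' are clamped to zero, so the result is deterministic. The returned tree is
#' unrooted (basal trifurcation).
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  lab <- rownames(D)
  # each active node is represented by its (rooted) newick fragment
  node <- lab
  d <- D
  while (length(node) > 3) {
    r <- length(node)
    R <- rowSums(d)
    # Q matrix; scan i<j row-major for the first minimum
    best <- c(NA, NA); bq <- Inf
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        q <- (r - 2) * d[i, j] - R[i] - R[j]
        if (q < bq - 1e-12) { bq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    merged <- sprintf("(%s:%s,%s:%s)", node[i], fmt_bl(bi), node[j], fmt_bl(bj))
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], merged)
    d <- d2
  }
  # final 3-way join: closed-form terminal lengths
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt_bl(b1),
                 node[2], fmt_bl(b2), node[3], fmt_bl(b3))
  ape::read.tree(text = nwk)
}

# canonical bipartition keys for all internal, non-root edges of a tree:
# each key is the sorted leaf set of the side not containing the first
# taxon (alphabetically), pasted with '|'. Named by child node number.
bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  anchor <- sort(tree$tip.label)[1]
  internal_children <- tree$edge[tree$edge[, 2] > n, 2]
  tips_below <- clade_tips(tree)
  keys <- vapply(internal_children, function(nd) {
    side <- tips_below[[nd]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  names(keys) <- internal_children
  # a bipartition with an empty or full side is not informative
  keys[nzchar(keys) & vapply(strsplit(keys, "|", fixed = TRUE), length,
                             1L) < n]
}

# list mapping node number -> tip labels below it
clade_tips <- function(tree) {
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  below <- vector("list", m)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  # process edges child-before-parent (reverse cladewise works for trees
  # from read.tree; fall back to iterating until stable)
  e <- tree$edge
  ord <- rev(seq_len(nrow(e)))
  for (k in ord) {
    p <- e[k, 1]; c <- e[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  below
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `B` times, rebuilds the NJ tree per replicate,
#' and labels each internal edge of the original tree with the percentage
#' of replicates containing its bipartition. Replicate `r` seeds the RNG
#' with `bitwXor(seed, r)`, so results are reproducible.
#'
#' @param aln aligned protein [seq_set].
#' @param B number of replicates (the study default is 2000).
#' @param seed integer RNG seed.
#' @param site_policy passed to [poisson_distance].
#' @return an [ape::phylo] tree whose `node.label` holds integer percent
#'   supports (`""` for the root).
#' @export
bootstrap_support <- function(aln, B = 2000L, seed = 1L,
                              site_policy = c("complete", "pairwise")) {
  site_policy <- match.arg(site_policy)
  if (B < 1) stop("B must be >= 1")
  tree <- neighbor_joining(poisson_distance(aln, site_policy))
  L <- aln_length(aln)
  if (L < 2) stop("degenerate alignment: fewer than 2 columns")
  obs <- bipartitions(tree)
  hits <- setNames(numeric(length(obs)), obs)
  used <- 0L
  mat <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(mat) <- names(aln)
  for (r in seq_len(B)) {
    cols <- with_seed(bitwXor(as.integer(seed), r),
                      sample.int(L, L, replace = TRUE))
    rep_aln <- seq_set(apply(mat[, cols, drop = FALSE], 1, paste,
                             collapse = ""),
                       alphabet = seq_alphabet(aln), aligned = TRUE)
    rep_tree <- tryCatch(
      neighbor_joining(poisson_distance(rep_aln, site_policy)),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    used <- used + 1L
    bp <- bipartitions(rep_tree)
    seen <- obs %in% bp
    hits[seen] <- hits[seen] + 1
  }
  if (used == 0) stop("all bootstrap replicates failed")
  if (used < B) warning(B - used, " bootstrap replicate(s) dropped ",
                        "(undefined distances)")
  supp <- round(100 * hits / used)
  n <- length(tree$tip.label)
  labels <- character(tree$Nnode)
  for (k in seq_along(obs)) {
    nd <- as.integer(names(obs)[k])
    labels[nd - n] <- as.character(supp[k])
  }
  tree$node.label <- labels
  tree
}

#' Collapse poorly supported edges into polytomies
#'
#' Internal edges whose bootstrap support is below `min_support` are
#' removed and their child clades reattached to the parent (the condensed
#' trees of the study's figures). Leaves are never removed; edges without a
#' support label are kept. Idempotent.
#'
#' @param tree an [ape::phylo] with integer `node.label` supports.
#' @param min_support threshold percentage (default 50).
#' @return the condensed [ape::phylo].
#' @export
condense <- function(tree, min_support = 50) {
  if (is.null(tree$node.label)) stop("tree has no support labels")
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- if (is.null(tree$edge.length)) NULL else
    setNames(tree$edge.length, tree$edge[, 2])
  supp <- tree$node.label
  quote_label <- function(lab) {
    if (grepl("[^A-Za-z0-9_.|-]", lab)) sprintf("'%s'", lab) else lab
  }
  rec <- function(nd) {
    if (nd <= n) return(quote_label(tree$tip.label[nd]))
    parts <- character(0)
    stack <- kids[[as.character(nd)]]
    while (length(stack)) {
      c1 <- stack[1]; stack <- stack[-1]
      s <- if (c1 > n) supp[c1 - n] else ""
      collapse <- c1 > n && nzchar(s) && !is.na(suppressWarnings(as.numeric(s))) &&
        as.numeric(s) < min_support
      if (collapse) {
        stack <- c(kids[[as.character(c1)]], stack)
      } else {
        frag <- rec(c1)
        if (!is.null(blen))
          frag <- sprintf("%s:%s", frag, sprintf("%.15g", blen[[as.character(c1)]]))
        parts <- c(parts, frag)
      }
    }
    lab <- if (nd > n) supp[nd - n] else ""
    sprintf("(%s)%s", paste(parts, collapse = ","), lab)
  }
  nwk <- paste0(rec(n + 1L), ";")
  ape::read.tree(text = nwk)
}
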