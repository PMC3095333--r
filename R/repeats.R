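#' TPR position model
#'
#' The packaged repeat model scores a 34-residue window against the
#' idealized TPR consensus with BLOSUM62 log-odds: column i of the profile
#' is the BLOSUM62 row of consensus residue i. A window's profile score is
#' the sum over the 34 positions. The consensus is shipped as a versioned
#' plain-text fixture under `extdata/`.
#'
#' @param consensus optional 34-residue string overriding the packaged
#'   consensus.
#' @return a 34 x 21 numeric matrix (rows = repeat positions, columns = the
#'   20 amino acids plus `X`), with the consensus attached as attribute
#'   `"consensus"`.
#' @export
tpr_profile <- function(consensus = NULL) {
  if (is.null(consensus)) consensus <- tpr_consensus()
  if (nchar(consensus) != 34) stop("TPR consensus must be 34 residues")
  b62 <- blosum62()
  cons <- strsplit(consensus, "")[[1]]
  prof <- b62[cons, c(AA20, "X"), drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "consensus") <- consensus
  prof
}

#' The packaged 34-residue TPR consensus
#' @return a 34-character string.
#' @export
tpr_consensus <- function() {
  path <- system.file("extdata", "tpr_consensus.txt", package = "apcevol")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  toupper(lines[1])
}

# score every 34-residue window of `res` (character vector of residues)
tpr_window_scores <- function(res, profile) {
  L <- length(res)
  u <- 34L
  if (L < u) return(numeric(0))
  col <- match(res, c(AA20, "X"))
  col[is.na(col)] <- 21L # unknowns score as X
  n <- L - u + 1L
  sc <- numeric(n)
  # one pass per repeat position, vectorised over window starts
  for (i in seq_len(u)) sc <- sc + profile[i, col[seq_len(n) + i - 1L]]
  sc
}

#' Detect 34-residue TPR units in a protein
#'
#' Scores every 34-residue window against the packaged position model and
#' greedily keeps non-overlapping windows in descending score order (ties
#' broken toward the N-terminus), reporting the survivors N-to-C. Proteins
#' shorter than 34 residues yield an empty result.
#'
#' @param protein a single-record protein [seq_set] or residue string.
#' @param profile position model from [tpr_profile].
#' @param threshold minimum profile score for a reported unit. The default
#'   is calibrated so that the synthetic reference bundle reproduces the
#'   published Arabidopsis repeat counts.
#' @param parent_id id used in the output when `protein` is a plain string.
#' @return data.frame with columns `parent_id`, `index`, `start`, `end`,
#'   `score` (1-based inclusive coordinates, `end - start + 1 == 34`).
#' @export
detect_tpr <- function(protein, profile = tpr_profile(), threshold = 60,
                       parent_id = NULL) {
  if (inherits(protein, "seq_set")) {
    if (is.null(parent_id)) parent_id <- names(protein)[1]
    protein <- resolve_seq(protein)
  }
  if (is.null(parent_id)) parent_id <- "protein"
  res <- strsplit(toupper(protein), "")[[1]]
  sc <- tpr_window_scores(res, profile)
  empty <- data.frame(parent_id = character(0), index = integer(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0))
  if (!length(sc)) return(empty)
  cand <- which(sc >= threshold)
  if (!length(cand)) return(empty)
  cand <- cand[order(-sc[cand], cand)]
  taken <- logical(length(res))
  starts <- integer(0)
  for (s in cand) {
    win <- s:(s + 33L)
    if (!any(taken[win])) { taken[win] <- TRUE; starts <- c(starts, s) }
  }
  starts <- sort(starts)
  data.frame(parent_id = parent_id, index = seq_along(starts),
             start = starts, end = starts + 33L, score = sc[starts])
}

#' Extract detected repeat units as sequences
#'
#' @param protein the parent protein (single-record [seq_set] or string).
#' @param domains data.frame from [detect_tpr].
#' @return a protein [seq_set] of 34-residue records, ids
#'   `<parent>_tpr<index>`; empty domain tables give a zero-length list.
#' @export
extract_domains <- function(protein, domains) {
  if (inherits(protein, "seq_set")) protein <- resolve_seq(protein)
  if (nrow(domains) == 0) return(list())
  if (any(domains$start < 1 | domains$end > nchar(protein)))
    stop("domain coordinates out of bounds")
  units <- substring(protein, domains$start, domains$end)
  seq_set(units, ids = sprintf("%s_tpr%d", domains$parent_id, domains$index),
          alphabet = "protein")
}

#' All-vs-all local-alignment score matrix between repeat units
#'
#' Reproduces the internal-duplication matrices: cell (i, j) holds the
#' Smith-Waterman score of unit i of set A against unit j of set B, and a
#' parallel `shading` matrix min-max normalises the scores to `[0, 1]` (dark
#' = similar).
#'
#' @param domains_a,domains_b protein [seq_set]s of repeat units (e.g. from
#'   [extract_domains]); comparing a set to itself yields a symmetric
#'   matrix.
#' @param params local-mode [alignment_params].
#' @return a `domain_score_matrix`: list with `scores`, `shading`,
#'   `rows_parent`, `cols_parent`, `self` (logical).
#' @export
build_matrix <- function(domains_a, domains_b = domains_a,
                         params = alignment_params(mode = "local")) {
  if (params$mode != "local") stop("params$mode must be 'local'")
  if (!length(domains_a) || !length(domains_b))
    stop("need at least one domain per side")
  self <- identical(unclass(domains_a), unclass(domains_b))
  a <- unclass(domains_a); b <- unclass(domains_b)
  sc <- matrix(0, length(a), length(b),
               dimnames = list(names(domains_a), names(domains_b)))
  for (i in seq_along(a)) {
    jj <- if (self) i:length(b) else seq_along(b)
    for (j in jj) {
      s <- align_local(a[[i]], b[[j]], params)$score
      sc[i, j] <- s
      if (self) sc[j, i] <- s
    }
  }
  rng <- range(sc)
  shading <- if (diff(rng) > 0) (sc - rng[1]) / diff(rng) else sc * 0
  structure(list(scores = sc, shading = shading,
                 rows_parent = sub("_tpr\\d+$", "", names(domains_a)[1]),
                 cols_parent = sub("_tpr\\d+$", "", names(domains_b)[1]),
                 self = self),
            class = "domain_score_matrix")
}

#' @export
print.domain_score_matrix <- function(x, ...) {
  cat(sprintf("domain score matrix: %s (%d) vs %s (%d)%s\n", x$rows_parent,
              nrow(x$scores), x$cols_parent, ncol(x$scores),
              if (x$self) " [self]" else ""))
  print(round(x$scores, 1))
  invisible(x)
}

#' Call duplication blocks from a domain score matrix
#'
#' A duplication block is a maximal diagonal run of at least `min_run`
#' cells whose scores exceed the per-matrix quantile threshold. For
#' self-comparison matrices the main diagonal is excluded (from both the
#' threshold computation and the runs) and only offsets above the diagonal
#' are reported, since the matrix is symmetric.
#'
#' @param m a `domain_score_matrix`.
#' @param score_quantile quantile of the (off-diagonal) scores used as the
#'   block threshold.
#' @param min_run minimum run length.
#' @return data.frame with `row_start`, `row_end`, `col_start`, `col_end`,
#'   `mean_score`, one row per block.
#' @export
find_blocks <- function(m, score_quantile = 0.75, min_run = 2L) {
  sc <- m$scores
  pool <- if (m$self) sc[row(sc) != col(sc)] else as.vector(sc)
  out <- data.frame(row_start = integer(0), row_end = integer(0),
                    col_start = integer(0), col_end = integer(0),
                    mean_score = numeric(0))
  if (!length(pool)) return(out)
  thr <- quantile(pool, score_quantile, names = FALSE)
  offs <- if (m$self) seq_len(ncol(sc) - 1L) else (1L - nrow(sc)):(ncol(sc) - 1L)
  for (d in offs) {
    ii <- seq_len(nrow(sc))
    jj <- ii + d
    keep <- jj >= 1L & jj <= ncol(sc)
    ii <- ii[keep]; jj <- jj[keep]
    if (length(ii) < min_run) next
    hot <- sc[cbind(ii, jj)] > thr
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      sel <- starts[k]:ends[k]
      out <- rbind(out, data.frame(
        row_start = ii[sel[1]], row_end = ii[sel[length(sel)]],
        col_start = jj[sel[1]], col_end = jj[sel[length(sel)]],
        mean_score = mean(sc[cbind(ii[sel], jj[sel])])))
    }
  }
  out
}

#' Scan a protein for APC docking and degron motifs
#'
#' Flags the activator docking elements — the C-box (consensus
#' `DR[FY]IPxR`) and the C-terminal IR tail — plus KEN-box (`KEN`) and
#' minimal D-box (`RxxL`) degron positions.
#'
#' @param protein single-record protein [seq_set] or residue string.
#' @param parent_id id for the report when `protein` is a plain string.
#' @return a `protein_motif_report` list: `parent_id`, `has_c_box`,
#'   `c_box_pos`, `has_ir_tail`, `ken_boxes`, `d_boxes`.
#' @export
scan_protein_motifs <- function(protein, parent_id = NULL) {
  if (inherits(protein, "seq_set")) {
    if (is.null(parent_id)) parent_id <- names(protein)[1]
    protein <- resolve_seq(protein)
  }
  if (is.null(parent_id)) parent_id <- "protein"
  s <- toupper(protein)
  find_all <- function(pat) {
    m <- gregexpr(sprintf("(?=%s)", pat), s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  cbox <- find_all("DR[FY]IP.R")
  structure(list(parent_id = parent_id,
                 has_c_box = length(cbox) > 0,
                 c_box_pos = if (length(cbox)) cbox[1] else NA_integer_,
                 has_ir_tail = nchar(s) >= 2 &&
                   substr(s, nchar(s) - 1, nchar(s)) == "IR",
                 ken_boxes = find_all("KEN"),
                 d_boxes = find_all("R..L")),
            class = "protein_motif_report")
}

#' @export
print.protein_motif_report <- function(x, ...) {
  cat(sprintf("%s: C-box %s%s, IR tail %s, %d KEN box(es), %d D-box(es)\n",
              x$parent_id, if (x$has_c_box) "yes" else "no",
              if (x$has_c_box) sprintf(" @%d", x$c_box_pos) else "",
              if (x$has_ir_tail) "yes" else "no",
              length(x$ken_boxes), length(x$d_boxes)))
  invisible(x)
}
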