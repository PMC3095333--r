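#' Alignment parameters
#'
#' Bundles a symmetric protein substitution matrix with affine gap penalties.
#' Defaults mirror the EMBOSS `needle`/`water` defaults: BLOSUM62, gap open
#' 10, gap extend 0.5. A gap of length L costs `gap_open + (L-1) *
#' gap_extend`; end gaps are charged in global mode.
#'
#' @param substitution_matrix named square numeric matrix (rows/columns are
#'   residue letters). Defaults to BLOSUM62 as shipped with Biostrings.
#' @param gap_open,gap_extend non-negative penalties, `gap_extend <=
#'   gap_open`.
#' @param mode `"global"` (Needleman-Wunsch) or `"local"` (Smith-Waterman).
#' @return an `alignment_params` object.
#' @export
alignment_params <- function(substitution_matrix = NULL, gap_open = 10,
                             gap_extend = 0.5,
                             mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  m <- substitution_matrix
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m)))
    stop("substitution_matrix must be a named square matrix")
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution_matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0 || gap_extend > gap_open)
    stop("need 0 <= gap_extend <= gap_open")
  structure(list(substitution_matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode),
            class = "alignment_params")
}

#' BLOSUM62 substitution matrix
#' @return the 20-residue (+X) BLOSUM62 integer matrix from Biostrings.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  keep <- c(AA20, "X")
  e$BLOSUM62[keep, keep]
}

# expand a named substitution matrix to the 26x26 A..Z layout the C++ core
# indexes; letters absent from the matrix score the matrix minimum.
expand_submat <- function(m) {
  full <- matrix(min(m), 26, 26, dimnames = list(LETTERS, LETTERS))
  keep <- intersect(rownames(m), LETTERS)
  full[keep, keep] <- m[keep, keep]
  full
}

align_stats <- function(aligned_a, aligned_b, submat) {
  len <- nchar(aligned_a)
  if (len == 0)
    return(list(length = 0L, identity_pct = NA_real_,
                similarity_pct = NA_real_))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  resid <- ca != "-" & cb != "-"
  ident <- sum(resid & ca == cb)
  simil <- ident
  both <- which(resid & ca != cb)
  if (length(both)) {
    sc <- submat[cbind(match(ca[both], rownames(submat)),
                       match(cb[both], colnames(submat)))]
    simil <- simil + sum(sc > 0, na.rm = TRUE)
  }
  list(length = len, identity_pct = 100 * ident / len,
       similarity_pct = 100 * simil / len)
}

align_one <- function(a, b, params, local) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  full <- expand_submat(params$substitution_matrix)
  r <- .align_pair_cpp(a, b, full, params$gap_open, params$gap_extend, local)
  st <- align_stats(r$aligned_a, r$aligned_b, params$substitution_matrix)
  structure(list(aligned_a = r$aligned_a, aligned_b = r$aligned_b,
                 score = r$score, identity_pct = st$identity_pct,
                 similarity_pct = st$similarity_pct, length = st$length,
                 mode = if (local) "local" else "global"),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment: score %.1f, length %d, identity %.1f%%, similarity %.1f%%\n",
              x$mode, x$score, x$length, x$identity_pct, x$similarity_pct))
  invisible(x)
}

resolve_seq <- function(s) {
  if (inherits(s, "seq_set")) {
    if (length(s) != 1) stop("expected a single sequence record")
    unclass(s)[[1]]
  } else if (is.character(s) && length(s) == 1) toupper(s)
  else stop("sequence must be a 1-record seq_set or a string")
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment with end gaps charged. `identity_pct` is the
#' percentage of alignment columns (gap columns included in the denominator,
#' the EMBOSS convention) with identical residues; `similarity_pct`
#' additionally counts residue pairs with a positive substitution score.
#'
#' @param a,b single-record [seq_set]s or plain residue strings.
#' @param params an [alignment_params]; mode must be `"global"`.
#' @return an `alignment_result` with elements `aligned_a`, `aligned_b`,
#'   `score`, `identity_pct`, `similarity_pct`, `length`.
#' @export
align_global <- function(a, b, params = alignment_params(mode = "global")) {
  if (params$mode != "global") stop("params$mode must be 'global'")
  align_one(resolve_seq(a), resolve_seq(b), params, local = FALSE)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment; the empty alignment (score 0) is returned when
#' no residue pair scores positively.
#'
#' @inheritParams align_global
#' @param params an [alignment_params]; mode must be `"local"`.
#' @return an `alignment_result`; `score >= 0`.
#' @export
align_local <- function(a, b, params = alignment_params(mode = "local")) {
  if (params$mode != "local") stop("params$mode must be 'local'")
  r <- align_one(resolve_seq(a), resolve_seq(b), params, local = TRUE)
  if (r$length == 0) { r$identity_pct <- 0; r$similarity_pct <- 0 }
  r
}
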