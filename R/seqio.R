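#' @useDynLib apcevol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd qnorm pnorm quantile median setNames rbinom runif reorder
#' @importFrom utils read.delim write.table packageVersion
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA4 <- c("A", "C", "G", "T")
IUPAC_DNA <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Construct a sequence set
#'
#' A `seq_set` is the package's light-weight container for a collection of
#' named sequences of one alphabet: a named character vector of residue
#' strings carrying the alphabet ("protein" or "dna"), per-record
#' descriptions, and an `aligned` flag (gap character `-` permitted only
#' when aligned).
#'
#' @param residues character vector of residue strings.
#' @param ids unique record identifiers (defaults to `names(residues)`).
#' @param desc optional per-record descriptions.
#' @param alphabet `"protein"` or `"dna"`.
#' @param aligned logical; if `TRUE` all records must share one length and
#'   `-` is a legal character.
#' @return an object of class `seq_set`.
#' @export
seq_set <- function(residues, ids = names(residues), desc = NULL,
                    alphabet = c("protein", "dna"), aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (is.null(ids)) stop("sequence ids are required")
  if (length(ids) != length(residues)) stop("ids/residues length mismatch")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(residues))) stop("empty sequence(s) not allowed")
  residues <- toupper(residues)
  if (is.null(desc)) desc <- rep("", length(ids))
  legal <- if (alphabet == "protein") c(AA20, "X") else c(DNA4, "N")
  if (aligned) legal <- c(legal, "-")
  seen <- unique(strsplit(paste(residues, collapse = ""), "")[[1]])
  bad <- setdiff(seen, legal)
  if (length(bad))
    stop("illegal ", alphabet, " residue(s): ", paste(bad, collapse = ", "))
  if (aligned) {
    if (length(residues) < 2) stop("an alignment needs >= 2 records")
    if (length(unique(nchar(residues))) != 1)
      stop("aligned records must all have the same length")
  }
  structure(setNames(as.character(residues), ids),
            desc = setNames(desc, ids), alphabet = alphabet,
            aligned = aligned, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d %s record(s)%s\n", length(x),
              attr(x, "alphabet"), if (attr(x, "aligned")) " (aligned)" else ""))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    r <- unclass(x)[[i]]
    cat(sprintf("  %s (%d): %s%s\n", names(x)[i], nchar(r),
                substr(r, 1, 40), if (nchar(r) > 40) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  y <- unclass(x)[i]
  if (anyNA(names(y))) stop("unknown record id(s)")
  seq_set(y, desc = attr(x, "desc")[names(y)],
          alphabet = attr(x, "alphabet"), aligned = attr(x, "aligned"))
}

seq_alphabet <- function(x) attr(x, "alphabet")
is_aligned <- function(x) isTRUE(attr(x, "aligned"))

#' Alignment length in columns
#' @param x an aligned `seq_set`.
#' @return integer number of columns.
#' @export
aln_length <- function(x) {
  if (!is_aligned(x)) stop("not an aligned seq_set")
  nchar(unclass(x)[[1]])
}

#' Read sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited header token; the remainder
#' of the header is kept as the description. `.` gap characters are
#' normalised to `-`; selenocysteine `U` in protein input is mapped to `X`
#' with a warning. Duplicate ids, empty files and residues illegal for the
#' alphabet are errors.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @param aligned read as an aligned set (gaps allowed, equal lengths
#'   enforced).
#' @return a [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- toupper(as.character(set))
  res <- gsub(".", "-", res, fixed = TRUE)
  if (alphabet == "protein" && any(grepl("U", res, fixed = TRUE))) {
    warning("'U' residue(s) mapped to 'X'")
    res <- gsub("U", "X", res, fixed = TRUE)
  }
  seq_set(res, ids = ids, desc = desc, alphabet = alphabet, aligned = aligned)
}

#' Write a sequence set to FASTA
#' @param x a [seq_set].
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  ids <- names(x)
  desc <- attr(x, "desc")
  con <- file(path, "wb") # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(x)) {
    hdr <- if (nzchar(desc[i])) paste(ids[i], desc[i]) else ids[i]
    r <- unclass(x)[[i]]
    starts <- seq(1, nchar(r), by = width)
    lines <- substring(r, starts, pmin(starts + width - 1L, nchar(r)))
    writeLines(c(paste0(">", hdr), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read a motif table (PLACE-style)
#'
#' Two-column tab-separated file: motif name and IUPAC nucleotide pattern.
#' Patterns must be at least 4 characters from the 15-letter IUPAC code.
#'
#' @param path TSV file; a header line `name<TAB>pattern` is optional.
#' @return data.frame with columns `name` and `pattern`.
#' @export
read_motif_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("motif table must have two tab-separated columns")
  tab <- tab[, 1:2]
  names(tab) <- c("name", "pattern")
  if (nrow(tab) && identical(tolower(tab$name[1]), "name"))
    tab <- tab[-1, , drop = FALSE]
  tab$pattern <- toupper(tab$pattern)
  ok <- grepl(sprintf("^[%s]+$", paste(names(IUPAC_DNA), collapse = "")),
              tab$pattern)
  if (any(!ok))
    stop("non-IUPAC motif pattern(s): ",
         paste(tab$pattern[!ok], collapse = ", "))
  if (any(nchar(tab$pattern) < 4))
    stop("motif patterns must be at least 4 nt long")
  if (anyDuplicated(tab$name))
    stop("duplicate motif name(s)")
  rownames(tab) <- NULL
  tab
}

#' Write a support tree to Newick
#'
#' Internal-node labels carry integer bootstrap percentages, so the file
#' round-trips through [read_newick] with topology, branch lengths and
#' supports intact.
#'
#' @param tree an [ape::phylo] tree, optionally with integer `node.label`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file; internal node labels are parsed as bootstrap
#'   percentages where they are integers.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ape::read.tree(path)
}
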