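iupac_charclass <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  sets <- IUPAC_DNA[chars]
  if (anyNA(sets)) stop("non-IUPAC character in motif pattern: ", pattern)
  paste(ifelse(nchar(sets) == 1, sets, paste0("[", sets, "]")), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

#' Count occurrences of an IUPAC motif in a promoter
#'
#' Counts every (possibly overlapping) start position where the motif's
#' IUPAC expansion matches. An `N` in the promoter never matches any
#' pattern symbol. Patterns longer than the promoter yield 0.
#'
#' @param promoter single-record dna [seq_set] or sequence string.
#' @param pattern IUPAC nucleotide pattern (string) or one-row motif-table
#'   data.frame.
#' @param strand `"forward"` (default; PLACE elements are strand-specific)
#'   or `"both"` to also scan the reverse complement.
#' @return integer count.
#' @export
count_motif <- function(promoter, pattern, strand = c("forward", "both")) {
  strand <- match.arg(strand)
  if (is.data.frame(pattern)) pattern <- pattern$pattern[1]
  s <- toupper(if (inherits(promoter, "seq_set")) resolve_seq(promoter)
               else promoter)
  if (nchar(pattern) > nchar(s)) return(0L)
  rx <- sprintf("(?=%s)", iupac_charclass(pattern))
  cnt <- function(x) {
    m <- gregexpr(rx, x, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  n <- cnt(s)
  if (strand == "both") n <- n + cnt(revcomp(s))
  n
}

#' Surrogate null distribution of a motif count
#'
#' Counts the motif in every background promoter; the per-promoter counts
#' are the surrogate null, summarised by their sample mean and standard
#' deviation (n - 1 denominator).
#'
#' @param motif IUPAC pattern string or one-row motif-table data.frame.
#' @param background dna [seq_set] of background promoters (>= 2; the study
#'   used 1000 rice gene promoters).
#' @param strand passed to [count_motif].
#' @return a `motif_null` list: `pattern`, `counts`, `mean`, `sd`, `n`.
#' @export
surrogate_null <- function(motif, background, strand = c("forward", "both")) {
  strand <- match.arg(strand)
  if (is.data.frame(motif)) motif <- motif$pattern[1]
  if (length(background) < 2) stop("background must hold >= 2 promoters")
  counts <- vapply(seq_along(background),
                   function(i) count_motif(unclass(background)[[i]], motif,
                                           strand),
                   integer(1))
  structure(list(pattern = motif, counts = counts, mean = mean(counts),
                 sd = sd(counts), n = length(counts), strand = strand),
            class = "motif_null")
}

#' Motif over-representation test against a surrogate null
#'
#' Computes `Z = (Ctrue - Csurr) / SDsurr` and a one-tailed p value as the
#' right-tail standard-normal probability at Z; the motif is called
#' significantly over-represented when p < `alpha` (the study's 5% rule,
#' per motif, uncorrected). When the surrogate standard deviation is zero
#' the z score is flagged degenerate and p is 0, 1 or 0.5 according to the
#' sign of `Ctrue - Csurr`.
#'
#' @param promoter single-record dna [seq_set] or string.
#' @param motif IUPAC pattern string or one-row motif-table data.frame.
#' @param null a `motif_null` from [surrogate_null] for the same motif.
#' @param alpha significance level.
#' @param empirical also report the empirical p,
#'   `(1 + #\{surrogate counts >= Ctrue\}) / (n + 1)`.
#' @param gene_id,motif_name labels for the result.
#' @return a one-row data.frame: `gene_id`, `motif_name`, `c_true`,
#'   `c_surr_mean`, `sd_surr`, `z`, `p_one_tailed`, `significant`,
#'   `n_surrogates` (plus `p_empirical` if requested).
#' @export
enrichment_test <- function(promoter, motif, null, alpha = 0.05,
                            empirical = FALSE, gene_id = NULL,
                            motif_name = NULL) {
  if (is.data.frame(motif)) {
    if (is.null(motif_name)) motif_name <- motif$name[1]
    motif <- motif$pattern[1]
  }
  if (!identical(motif, null$pattern))
    stop("null was built for a different motif pattern")
  if (is.null(gene_id))
    gene_id <- if (inherits(promoter, "seq_set")) names(promoter)[1] else "promoter"
  if (is.null(motif_name)) motif_name <- motif
  c_true <- count_motif(promoter, motif, null$strand)
  if (null$sd > 0) {
    z <- (c_true - null$mean) / null$sd
    p <- pnorm(z, lower.tail = FALSE)
  } else {
    z <- NA_real_ # degenerate: all surrogates identical
    p <- if (c_true > null$mean) 0 else if (c_true < null$mean) 1 else 0.5
  }
  out <- data.frame(gene_id = gene_id, motif_name = motif_name,
                    c_true = c_true, c_surr_mean = null$mean,
                    sd_surr = null$sd, z = z, p_one_tailed = p,
                    significant = p < alpha, n_surrogates = null$n)
  if (empirical)
    out$p_empirical <- (1 + sum(null$counts >= c_true)) / (null$n + 1)
  out
}

#' Run the over-representation test for every promoter x motif combination
#'
#' @param promoters dna [seq_set] of promoters to test.
#' @param motifs motif table (data.frame from [read_motif_table]).
#' @param background dna [seq_set] used for the surrogate null.
#' @inheritParams enrichment_test
#' @param strand passed to [count_motif].
#' @return data.frame of [enrichment_test] rows, with an informational
#'   Benjamini-Hochberg column `p_bh` (the per-motif 5% rule is what
#'   `significant` reports).
#' @export
enrich_promoters <- function(promoters, motifs, background,
                             strand = c("forward", "both"), alpha = 0.05,
                             empirical = FALSE) {
  strand <- match.arg(strand)
  rows <- list()
  for (m in seq_len(nrow(motifs))) {
    null <- surrogate_null(motifs$pattern[m], background, strand)
    for (g in seq_along(promoters)) {
      rows[[length(rows) + 1L]] <-
        enrichment_test(unclass(promoters)[[g]], motifs[m, , drop = FALSE],
                        null, alpha = alpha, empirical = empirical,
                        gene_id = names(promoters)[g])
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_one_tailed, method = "BH")
  rownames(out) <- NULL
  out
}

#' Cis-elements significantly over-represented in both of two promoters
#'
#' @param results_a,results_b [enrich_promoters]/[enrichment_test] result
#'   data.frames computed over the same motif table.
#' @return character vector of motif names significant in both.
#' @export
shared_elements <- function(results_a, results_b) {
  if (!setequal(results_a$motif_name, results_b$motif_name))
    stop("results were computed over different motif tables")
  intersect(results_a$motif_name[results_a$significant],
            results_b$motif_name[results_b$significant])
}
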