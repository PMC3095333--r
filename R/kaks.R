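# Nei-Gojobori (1986) machinery. All counting tables are derived once per
# session from the standard genetic code and cached.

.kaks_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

# fractional synonymous sites per sense codon: at each position, the
# fraction of the three single-nucleotide changes that preserve the amino
# acid (changes to stop codons count as nonsynonymous).
codon_site_counts <- function() {
  if (!is.null(.kaks_cache$sites)) return(.kaks_cache$sites)
  gc <- genetic_code()
  nts <- DNA4
  s <- setNames(numeric(length(sense_codons())), sense_codons())
  for (cod in sense_codons()) {
    chars <- strsplit(cod, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, chars[pos])) {
        alt <- chars; alt[pos] <- nt
        alt <- paste(alt, collapse = "")
        if (gc[[alt]] == gc[[cod]]) syn <- syn + 1
      }
    }
    s[cod] <- syn / 3
  }
  .kaks_cache$sites <- s
  s
}

# pathway-averaged (Sd, Nd) for every ordered pair of sense codons:
# enumerate all orderings of the differing positions with equal weight; a
# step is synonymous iff it leaves the encoded amino acid unchanged (stop
# codons translate to '*', so steps into or out of a stop are
# nonsynonymous).
codon_pair_diffs <- function() {
  if (!is.null(.kaks_cache$pairs)) return(.kaks_cache$pairs)
  gc <- genetic_code()
  sc <- sense_codons()
  k <- length(sc)
  Sd <- matrix(0, k, k, dimnames = list(sc, sc))
  Nd <- matrix(0, k, k, dimnames = list(sc, sc))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (a in sc) {
    ca <- strsplit(a, "")[[1]]
    for (b in sc) {
      if (a == b) next
      cb <- strsplit(b, "")[[1]]
      diffp <- which(ca != cb)
      ords <- perms[[as.character(length(diffp))]]
      sy <- ny <- 0
      for (ord in ords) {
        cur <- ca
        for (pos in diffp[ord]) {
          nxt <- cur; nxt[pos] <- cb[pos]
          if (gc[[paste(cur, collapse = "")]] ==
              gc[[paste(nxt, collapse = "")]]) sy <- sy + 1 else ny <- ny + 1
          cur <- nxt
        }
      }
      Sd[a, b] <- sy / length(ords)
      Nd[a, b] <- ny / length(ords)
    }
  }
  .kaks_cache$pairs <- list(Sd = Sd, Nd = Nd)
  .kaks_cache$pairs
}

split_codons <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

jc_correct <- function(p) {
  if (p >= 0.75) stop("proportion of differences >= 3/4; ",
                      "Jukes-Cantor correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts fractional synonymous (S) and nonsynonymous (N) sites per codon
#' (averaged between the two sequences), pathway-averaged synonymous and
#' nonsynonymous differences (Sd, Nd) with all single-step orders weighted
#' equally, and applies the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - 4p/3)` to each proportion. Codons containing a gap,
#' `N`, or a stop codon in either sequence are excluded pairwise.
#'
#' @param cds_a,cds_b in-frame coding sequences (single-record dna
#'   [seq_set]s or strings) of equal length divisible by 3 with no internal
#'   stop codons.
#' @return a `kaks_result` list: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `ratio` (`NA` when `Ks == 0`), `codons_used`.
#' @export
kaks <- function(cds_a, cds_b) {
  a <- toupper(if (inherits(cds_a, "seq_set")) resolve_seq(cds_a) else cds_a)
  b <- toupper(if (inherits(cds_b, "seq_set")) resolve_seq(cds_b) else cds_b)
  if (nchar(a) != nchar(b)) stop("coding sequences must have equal length")
  if (nchar(a) %% 3 != 0) stop("length must be a multiple of 3")
  gc <- genetic_code()
  cod_a <- split_codons(a)
  cod_b <- split_codons(b)
  clean <- function(cods, who) {
    plain <- grepl("^[ACGT]{3}$", cods)
    aa <- rep(NA_character_, length(cods))
    aa[plain] <- gc[cods[plain]]
    if (any(aa[-length(aa)] == "*", na.rm = TRUE))
      stop("internal stop codon in ", who)
    aa
  }
  aa_a <- clean(cod_a, "first sequence")
  aa_b <- clean(cod_b, "second sequence")
  use <- !is.na(aa_a) & !is.na(aa_b) & aa_a != "*" & aa_b != "*"
  if (!any(use)) stop("no comparable codons")
  cod_a <- cod_a[use]; cod_b <- cod_b[use]
  sites <- codon_site_counts()
  S <- (sum(sites[cod_a]) + sum(sites[cod_b])) / 2
  N <- 3 * length(cod_a) - S
  pd <- codon_pair_diffs()
  Sd <- sum(pd$Sd[cbind(cod_a, cod_b)])
  Nd <- sum(pd$Nd[cbind(cod_a, cod_b)])
  pS <- Sd / S
  pN <- Nd / N
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka,
                 ratio = if (Ks > 0) Ka / Ks else NA_real_,
                 codons_used = length(cod_a)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka/Ks (NG86, %d codons): Ka %.4f, Ks %.4f, ratio %s\n",
              x$codons_used, x$Ka, x$Ks,
              if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio)))
  cat(sprintf("  S %.2f  N %.2f  Sd %.2f  Nd %.2f\n", x$S, x$N, x$Sd, x$Nd))
  invisible(x)
}
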