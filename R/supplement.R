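# Synthetic stand-in for the study's sequence supplement. The real
# supplementary FASTA is not redistributable here, so this generator builds
# a sequence bundle with the *published properties* of that file: the five
# TPR subunit families with 15/11/12/9/14 members (61 records), paralog
# pairs mutated to the printed identity/similarity percentages, Arabidopsis
# TPR architectures with the published repeat counts, and activator
# proteins with (or deliberately without) the C-box, KEN-box and IR-tail
# elements. Every record is labelled synthetic in its description.

supp_family_members <- function() {
  list(
    CDC27 = c("AtCDC27a", "AtCDC27b", "OsCDC27", "PtCDC27_1", "PtCDC27_2",
              "VvCDC27", "SbCDC27", "PpCDC27_1", "PpCDC27_2", "SmCDC27",
              "MspCDC27", "OspCDC27", "CspCDC27", "VcCDC27", "CmCDC27"),
    APC5 = c("AtAPC5", "OsAPC5", "PtAPC5", "VvAPC5", "SbAPC5", "PpAPC5",
             "SmAPC5", "MspAPC5", "OspAPC5", "VcAPC5", "CmAPC5"),
    CDC16 = c("AtCDC16", "OsCDC16", "PtCDC16", "VvCDC16", "SbCDC16",
              "PpCDC16", "SmCDC16", "MspCDC16", "OspCDC16", "CspCDC16",
              "VcCDC16", "CmCDC16"),
    APC7 = c("AtAPC7", "OsAPC7", "PtAPC7", "VvAPC7", "SbAPC7", "PpAPC7",
             "SmAPC7", "MspAPC7", "OspAPC7"),
    CDC23 = c("AtCDC23", "OsCDC23_1", "OsCDC23_2", "PtCDC23", "VvCDC23_1",
              "VvCDC23_2", "SbCDC23", "PpCDC23", "SmCDC23", "MspCDC23",
              "OspCDC23", "CspCDC23", "VcCDC23", "CmCDC23"))
}

supp_unit_counts <- c(CDC27 = 9L, APC5 = 2L, CDC16 = 9L, APC7 = 10L,
                      CDC23 = 10L)

# mutate exactly k positions of a paralog copy, a fraction of them to
# conservative (positive-BLOSUM) partners, optionally sparing repeat units
# beyond a per-unit cap so the copy keeps detectable repeats.
derive_paralog <- function(chars, k, conserve_frac, unit_ranges = NULL,
                           unit_cap = 0.25, b62 = blosum62()) {
  L <- length(chars)
  in_unit <- rep(FALSE, L)
  for (r in unit_ranges) in_unit[r[1]:r[2]] <- TRUE
  k_unit <- min(k, floor(sum(in_unit) * unit_cap))
  k_rest <- min(k - k_unit, sum(!in_unit))
  pos <- c(if (k_unit > 0) sample(which(in_unit), k_unit),
           if (k_rest > 0) sample(which(!in_unit), k_rest))
  cons <- sample(pos, round(conserve_frac * length(pos)))
  for (p in pos)
    chars[p] <- replacement_for(chars[p],
                                if (p %in% cons) "conservative"
                                else "nonconservative", b62)
  chars
}

build_tpr_member <- function(base_units, species_rate, family) {
  n_units <- length(base_units)
  units <- lapply(base_units, mutate_chars, rate = species_rate)
  if (family == "APC5") {
    nterm <- sample(AA20, 180, TRUE)
    mid <- sample(AA20, 150, TRUE)
    tail <- sample(AA20, 6, TRUE)
    chars <- c(nterm, units[[1]], mid, units[[2]], tail)
    starts <- c(181L, 181L + 34L + 150L)
  } else {
    nterm <- sample(AA20, 120, TRUE)
    chars <- nterm
    starts <- integer(n_units)
    for (u in seq_len(n_units)) {
      starts[u] <- length(chars) + 1L
      chars <- c(chars, units[[u]])
      if (u < n_units) chars <- c(chars, sample(AA20, 12, TRUE))
    }
    chars <- c(chars, sample(AA20, 12, TRUE))
  }
  list(chars = chars, unit_ranges = lapply(starts, function(s) c(s, s + 33L)))
}

scrub_pattern <- function(s, pattern) {
  repeat {
    m <- regexpr(pattern, s, perl = TRUE)
    if (m == -1) return(s)
    substr(s, m, m) <- "A"
  }
}

build_activator <- function(len = 450L, c_box = TRUE, ken = TRUE,
                            ir = TRUE) {
  s <- paste(sample(AA20, len, TRUE), collapse = "")
  s <- scrub_pattern(s, "DR[FY]IP.R")
  s <- scrub_pattern(s, "KEN")
  if (ken) substr(s, 30, 32) <- "KEN"
  if (c_box) substr(s, 60, 66) <- "DRYIPNR"
  if (ir) substr(s, len - 1L, len) <- "IR"
  else if (substr(s, len - 1L, len) == "IR") substr(s, len, len) <- "A"
  s
}

#' Synthetic stand-in for the study's APC/activator sequence bundle
#'
#' Deterministically (given `seed`) generates a protein collection with the
#' published summary properties of the comparative dataset: the five TPR
#' subunit families (CDC27 15, APC5 11, CDC16 12, APC7 9, CDC23 14 members
#' = 61 records); duplicated-gene pairs mutated to the printed identity
#' percentages (OsCDC23 92%, OsAPC11 97%, AtCDC27 47% identity / 64%
#' similarity, PtCDC27 88%, PtAPC13 95%); Arabidopsis TPR architectures
#' with 9/9/2/9/10/10 repeat units for CDC27a/CDC27b/APC5/CDC16/APC7/CDC23;
#' and activator records in which AtCDC20_6 lacks the C-box and KEN-box and
#' PtCDC20_5 lacks the C-box. It is a synthetic fixture, not the real
#' supplementary data.
#'
#' @param seed integer RNG seed.
#' @return list with `proteins` (one protein [seq_set] of all records),
#'   `tpr_families` (named list of record ids per family), `paralog_pairs`
#'   (data.frame of pair ids with planted identity/similarity targets), and
#'   `truth` (generation parameters).
#' @export
synthetic_supplement <- function(seed = 101L) {
  with_seed(seed, {
    b62 <- blosum62()
    cons <- strsplit(tpr_consensus(), "")[[1]]
    fams <- supp_family_members()
    seqs <- character(0); ids <- character(0)
    unit_ranges <- list() # per record, for paralog derivation
    add <- function(id, chars) {
      seqs <<- c(seqs, paste(chars, collapse = "")); ids <<- c(ids, id)
    }
    for (fam in names(fams)) {
      nu <- supp_unit_counts[[fam]]
      base_units <- lapply(seq_len(nu), function(u)
        mutate_chars(cons, rate = 0.15))
      for (id in fams[[fam]]) {
        # paralog copies are derived from their partner below, not drawn
        if (id %in% c("AtCDC27b", "PtCDC27_2", "PpCDC27_2", "OsCDC23_2",
                      "VvCDC23_2")) next
        rate <- if (startsWith(id, "At")) 0.08 else 0.25
        mb <- build_tpr_member(base_units, rate, fam)
        add(id, mb$chars)
        unit_ranges[[id]] <- mb$unit_ranges
      }
    }
    pair_spec <- list(
      list(a = "AtCDC27a",  b = "AtCDC27b",  identity = 47, similarity = 64),
      list(a = "OsCDC23_1", b = "OsCDC23_2", identity = 92, similarity = 95),
      list(a = "PtCDC27_1", b = "PtCDC27_2", identity = 88, similarity = 92),
      list(a = "PpCDC27_1", b = "PpCDC27_2", identity = 80, similarity = 86),
      list(a = "VvCDC23_1", b = "VvCDC23_2", identity = 90, similarity = 94))
    for (ps in pair_spec) {
      chars <- strsplit(seqs[match(ps$a, ids)], "")[[1]]
      L <- length(chars)
      k <- L - round(ps$identity / 100 * L)
      cf <- (round(ps$similarity / 100 * L) - (L - k)) / k
      add(ps$b, derive_paralog(chars, k, cf, unit_ranges[[ps$a]], b62 = b62))
    }
    # small non-TPR duplicated subunits: RING-finger APC11, tiny APC13
    small <- function(len) sample(AA20, len, TRUE)
    ap11 <- small(96)
    add("OsAPC11_1", ap11)
    add("OsAPC11_2", derive_paralog(ap11, 96 - round(0.97 * 96), 0.5,
                                    b62 = b62))
    ap13 <- small(78)
    add("PtAPC13_1", ap13)
    add("PtAPC13_2", derive_paralog(ap13, 78 - round(0.95 * 78), 0.5,
                                    b62 = b62))
    # activators: CDC20/CCS52-like WD40 proteins with docking motifs
    for (i in 1:5) add(sprintf("AtCDC20_%d", i), build_activator())
    add("AtCDC20_6", build_activator(c_box = FALSE, ken = FALSE))
    for (i in 1:4) add(sprintf("PtCDC20_%d", i), build_activator())
    add("PtCDC20_5", build_activator(c_box = FALSE))
    for (i in 1:3) add(sprintf("OsCDC20_%d", i), build_activator())
    for (id in c("AtCCS52A1", "AtCCS52A2", "AtCCS52B", "OsCCS52A",
                 "OsCCS52B"))
      add(id, build_activator())
    proteins <- seq_set(seqs, ids = ids,
                        desc = rep("synthetic stand-in record", length(ids)),
                        alphabet = "protein")
    pairs <- do.call(rbind, lapply(pair_spec, as.data.frame))
    pairs <- rbind(pairs,
                   data.frame(a = c("OsAPC11_1", "PtAPC13_1"),
                              b = c("OsAPC11_2", "PtAPC13_2"),
                              identity = c(97, 95), similarity = c(98, 97)))
    list(proteins = proteins, tpr_families = fams, paralog_pairs = pairs,
         truth = list(scenario = "supplement", parameters = list(seed = seed),
                      unit_ranges = unit_ranges))
  })
}
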