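# Seeded generators. Every generator is a pure function of (parameters,
# seed): it saves and restores the caller's RNG state, and returns a truth
# record sufficient to recompute the expected downstream quantities.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# replace residue `orig` with a random different one; conservative draws
# from positive BLOSUM62 partners, non-conservative from the rest.
replacement_for <- function(orig, mode = c("uniform", "conservative",
                                           "nonconservative"), b62) {
  mode <- match.arg(mode)
  others <- setdiff(AA20, orig)
  cand <- switch(mode,
    uniform = others,
    conservative = others[b62[orig, others] > 0],
    nonconservative = others[b62[orig, others] <= 0])
  if (!length(cand)) cand <- others
  cand[sample.int(length(cand), 1)]
}

mutate_chars <- function(chars, rate = NULL, k = NULL, conserve_frac = 0,
                         b62 = blosum62()) {
  pos <- if (!is.null(k)) sample(length(chars), k)
         else which(runif(length(chars)) < rate)
  if (!length(pos)) return(chars)
  ncons <- round(conserve_frac * length(pos))
  cons <- if (ncons > 0) sample(pos, ncons) else integer(0)
  for (p in pos) {
    mode <- if (conserve_frac == 0 && is.null(k)) "uniform"
            else if (p %in% cons) "conservative" else "nonconservative"
    chars[p] <- replacement_for(chars[p], mode, b62)
  }
  chars
}

#' Generate a synthetic TPR-repeat protein with planted duplications
#'
#' Builds a protein from `n_units` copies of the 34-residue TPR consensus,
#' each independently mutated at `unit_mutation_rate` (uniform replacement),
#' joined by random low-complexity linkers. For every pair `(i, j)` in
#' `duplicated_pairs`, unit j is re-derived from unit i at
#' `dup_divergence`, planting extra similarity that [build_matrix] /
#' [find_blocks] should recover.
#'
#' @param n_units number of repeat units (>= 1).
#' @param unit_mutation_rate per-position mutation probability in `[0, 0.5)`.
#' @param duplicated_pairs list of integer pairs `c(i, j)`, `i < j`.
#' @param dup_divergence per-position divergence of a duplicated copy from
#'   its source unit.
#' @param linker_len length of each inter-unit linker (also used for the
#'   N-/C-terminal flanks).
#' @param seed integer RNG seed.
#' @return list with `protein` (single-record [seq_set]) and `truth`
#'   (scenario, parameters, planted unit `starts`/`ends`).
#' @export
gen_repeat_protein <- function(n_units, unit_mutation_rate = 0.2,
                               duplicated_pairs = list(),
                               dup_divergence = 0.15, linker_len = 15L,
                               seed = 1L) {
  if (n_units < 1) stop("n_units must be >= 1")
  if (unit_mutation_rate < 0 || unit_mutation_rate >= 0.5 ||
      dup_divergence < 0 || dup_divergence >= 0.5)
    stop("mutation rates must lie in [0, 0.5)")
  with_seed(seed, {
    cons <- strsplit(tpr_consensus(), "")[[1]]
    units <- lapply(seq_len(n_units), function(u)
      mutate_chars(cons, rate = unit_mutation_rate))
    for (pr in duplicated_pairs) {
      if (length(pr) != 2 || pr[1] >= pr[2] || pr[2] > n_units)
        stop("duplicated_pairs entries must be c(i, j) with i < j <= n_units")
      units[[pr[2]]] <- mutate_chars(units[[pr[1]]], rate = dup_divergence)
    }
    low <- c("G", "S", "P", "A", "T", "N")
    linker <- function() paste(sample(low, linker_len, TRUE), collapse = "")
    parts <- character(0)
    starts <- integer(n_units)
    pos <- 0L
    for (u in seq_len(n_units)) {
      lk <- linker(); parts <- c(parts, lk); pos <- pos + nchar(lk)
      starts[u] <- pos + 1L
      parts <- c(parts, paste(units[[u]], collapse = "")); pos <- pos + 34L
    }
    parts <- c(parts, linker())
    protein <- seq_set(paste(parts, collapse = ""), ids = "synthetic_repeat",
                       desc = "synthetic TPR repeat protein",
                       alphabet = "protein")
    list(protein = protein,
         truth = list(scenario = "repeat_protein",
                      parameters = list(seed = seed, n_units = n_units,
                                        unit_mutation_rate = unit_mutation_rate,
                                        dup_divergence = dup_divergence,
                                        linker_len = linker_len,
                                        duplicated_pairs = duplicated_pairs),
                      starts = starts, ends = starts + 33L))
  })
}

#' Evolve protein sequences along a tree under a Poisson model
#'
#' The root sequence is uniform over the 20 amino acids; along each edge of
#' length b every site substitutes independently with probability
#' `1 - exp(-b)` to a uniformly chosen different residue. Observed pairwise
#' p-distances then match path lengths via `p ~= 1 - exp(-d)` (exact up to
#' the small back-substitution term of a 20-letter alphabet), which is the
#' model [poisson_distance] inverts.
#'
#' @param topology an [ape::phylo] with edge lengths, or `"random"`.
#' @param n_taxa number of taxa when `topology = "random"`.
#' @param branch_length scalar, or length-2 range to draw uniform edge
#'   lengths from, when `topology = "random"`.
#' @param seq_len number of sites.
#' @param seed integer RNG seed.
#' @return list with `alignment` (aligned protein [seq_set]), `tree`, and
#'   `truth`.
#' @export
gen_tree_sequences <- function(topology = "random", n_taxa = 8L,
                               branch_length = c(0.05, 0.3), seq_len = 500L,
                               seed = 1L) {
  if (seq_len < 1) stop("seq_len must be positive")
  with_seed(seed, {
    if (identical(topology, "random")) {
      tree <- ape::rtree(n_taxa, rooted = FALSE, br = NULL)
      ne <- nrow(tree$edge)
      tree$edge.length <- if (length(branch_length) == 1)
        rep(branch_length, ne)
      else runif(ne, branch_length[1], branch_length[2])
    } else {
      tree <- topology
      if (is.null(tree$edge.length)) stop("topology must carry edge lengths")
    }
    tree <- reorder(tree, "cladewise") # parents before children
    n <- length(tree$tip.label)
    seqs <- vector("list", n + tree$Nnode)
    root <- n + 1L
    seqs[[root]] <- sample(AA20, seq_len, replace = TRUE)
    for (k in seq_len(nrow(tree$edge))) { # cladewise: parent precedes child
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      b <- tree$edge.length[k]
      s <- seqs[[p]]
      hit <- runif(seq_len) < 1 - exp(-b)
      if (any(hit))
        s[hit] <- vapply(s[hit], function(x)
          sample(setdiff(AA20, x), 1), character(1))
      seqs[[ch]] <- s
    }
    aln <- seq_set(vapply(seq_len(n), function(i)
      paste(seqs[[i]], collapse = ""), character(1)),
      ids = tree$tip.label, alphabet = "protein", aligned = TRUE)
    list(alignment = aln, tree = tree,
         truth = list(scenario = "tree_sequences",
                      parameters = list(seed = seed, seq_len = seq_len),
                      newick = ape::write.tree(tree)))
  })
}

#' Generate a coding-sequence pair with a planted Ka/Ks ratio
#'
#' An ancestral CDS of random sense codons is evolved along two independent
#' branches. Point mutations are proposed uniformly over sites and target
#' nucleotides; proposals creating stop codons are rejected, and
#' synonymous/nonsynonymous proposals are accepted in a ratio calibrated to
#' the planted `omega` (for `omega <= 1` nonsynonymous changes are accepted
#' with probability `omega`; for `omega > 1` synonymous changes with
#' probability `1/omega`). Each branch fixes
#' `round(3 * n_codons * target_divergence / 2)` substitutions.
#'
#' @param n_codons number of codons.
#' @param omega planted Ka/Ks (>= 0; 0 means no nonsynonymous changes).
#' @param target_divergence expected total nucleotide divergence between
#'   the two sequences (must keep p < 3/4).
#' @param seed integer RNG seed.
#' @return list with `cds_a`, `cds_b` (single-record dna [seq_set]s) and
#'   `truth`.
#' @export
gen_cds_pair <- function(n_codons = 2000L, omega = 1, target_divergence = 0.1,
                         seed = 1L) {
  if (omega < 0) stop("omega must be >= 0")
  if (target_divergence <= 0 || target_divergence >= 0.75)
    stop("target_divergence must lie in (0, 0.75)")
  gc <- genetic_code()
  with_seed(seed, {
    anc <- sample(sense_codons(), n_codons, replace = TRUE)
    evolve <- function(cod) {
      nt_target <- round(3 * n_codons * target_divergence / 2)
      acc <- 0L; tries <- 0L
      p_syn <- if (omega > 1) 1 / omega else 1
      p_non <- if (omega > 1) 1 else omega
      while (acc < nt_target) {
        tries <- tries + 1L
        if (tries > 1000 * (nt_target + 10))
          stop("substitution target infeasible for these parameters")
        ci <- sample.int(n_codons, 1)
        pos <- sample.int(3, 1)
        chars <- strsplit(cod[ci], "")[[1]]
        nt <- sample(setdiff(DNA4, chars[pos]), 1)
        new <- chars; new[pos] <- nt
        new <- paste(new, collapse = "")
        if (gc[[new]] == "*") next
        syn <- gc[[new]] == gc[[cod[ci]]]
        if (runif(1) < (if (syn) p_syn else p_non)) {
          cod[ci] <- new; acc <- acc + 1L
        }
      }
      cod
    }
    a <- evolve(anc); b <- evolve(anc)
    list(cds_a = seq_set(paste(a, collapse = ""), ids = "cds_a",
                         desc = "synthetic CDS", alphabet = "dna"),
         cds_b = seq_set(paste(b, collapse = ""), ids = "cds_b",
                         desc = "synthetic CDS", alphabet = "dna"),
         truth = list(scenario = "cds_pair",
                      parameters = list(seed = seed, n_codons = n_codons,
                                        omega = omega,
                                        target_divergence = target_divergence)))
  })
}

# sample one concrete instance of an IUPAC pattern
realize_motif <- function(pattern) {
  paste(vapply(strsplit(toupper(pattern), "")[[1]], function(ch) {
    set <- strsplit(IUPAC_DNA[[ch]], "")[[1]]
    set[sample.int(length(set), 1)]
  }, character(1)), collapse = "")
}

#' Generate background and motif-planted promoter sets
#'
#' Background promoters are i.i.d. under `base_composition`. When `planted`
#' is given, `planted$n_targets` additional target promoters each receive
#' `planted$copies` realisations of `planted$pattern` at non-overlapping
#' random positions.
#'
#' @param n_background number of background promoters (the study used 1000).
#' @param length promoter length in bp (the study used 1000 bp upstream
#'   windows).
#' @param base_composition named A/C/G/T probabilities; the default is
#'   mildly AT-rich, as plant promoters are.
#' @param planted `NULL` or `list(pattern =, copies =, n_targets =)`.
#' @param seed integer RNG seed.
#' @return list with `background` ([seq_set]), `targets` ([seq_set] or
#'   `NULL`) and `truth` (with planted positions per target).
#' @export
gen_promoter_set <- function(n_background = 1000L, length = 1000L,
                             base_composition = c(A = 0.3, C = 0.2,
                                                  G = 0.2, T = 0.3),
                             planted = NULL, seed = 1L) {
  stopifnot(setequal(names(base_composition), DNA4))
  with_seed(seed, {
    rand_prom <- function() paste(sample(names(base_composition), length,
                                         TRUE, prob = base_composition),
                                  collapse = "")
    bg <- vapply(seq_len(n_background), function(i) rand_prom(),
                 character(1))
    background <- seq_set(bg, ids = sprintf("bg%04d", seq_len(n_background)),
                          alphabet = "dna")
    targets <- NULL
    positions <- NULL
    if (!is.null(planted)) {
      w <- nchar(planted$pattern)
      if (planted$copies * w > length)
        stop("planted copies do not fit in the promoter")
      nt <- if (is.null(planted$n_targets)) 1L else planted$n_targets
      tg <- character(nt)
      positions <- vector("list", nt)
      for (t in seq_len(nt)) {
        s <- rand_prom()
        pos <- integer(0)
        tries <- 0
        while (base::length(pos) < planted$copies) {
          tries <- tries + 1
          if (tries > 10000) stop("could not place planted copies")
          cand <- sample.int(length - w + 1L, 1)
          if (!any(abs(cand - pos) < w)) pos <- c(pos, cand)
        }
        for (p in pos)
          substr(s, p, p + w - 1L) <- realize_motif(planted$pattern)
        tg[t] <- s
        positions[[t]] <- sort(pos)
      }
      targets <- seq_set(tg, ids = sprintf("target%02d", seq_len(nt)),
                         alphabet = "dna")
    }
    list(background = background, targets = targets,
         truth = list(scenario = "promoter_set",
                      parameters = list(seed = seed,
                                        n_background = n_background,
                                        length = length,
                                        base_composition = base_composition,
                                        planted = planted),
                      planted_positions = positions))
  })
}
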