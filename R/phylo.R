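#' Multiple sequence alignments as character matrices
#'
#' Alignments are plain character matrices (rows = taxa, columns = alignment
#' columns, gap = `-`).  `msa_from_seqs` splits equal-length or unaligned
#' sequences into a matrix; `msa_to_seqs` collapses back to strings.
#'
#' @param seqs Named character vector of (aligned) sequences.
#' @return A character matrix with taxon rownames.
#' @export
msa_from_seqs <- function(seqs) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences have unequal lengths; align them first")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' @rdname msa_from_seqs
#' @param msa Character matrix alignment.
#' @export
msa_to_seqs <- function(msa) {
  stats::setNames(apply(msa, 1L, paste, collapse = ""), rownames(msa))
}

# ---- protein alignment (center-star) ----------------------------------------

# Global pairwise protein alignments of every sequence against the longest
# one (BLOSUM62), merged star-wise into a single multiple alignment.
align_proteins <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  if (length(seqs) == 1L) {
    return(msa_from_seqs(seqs))
  }
  center_i <- which.max(nchar(seqs))
  center <- seqs[[center_i]]
  n <- nchar(center)
  others <- seqs[-center_i]
  parsed <- lapply(others, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(center),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 12, gapExtension = 2)
    list(pal = strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]],
         sal = strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]])
  })
  ins <- integer(n + 1L)      # insertion width before center position i
  for (pr in parsed) {
    cpos <- 1L; run <- 0L
    for (k in seq_along(pr$sal)) {
      if (pr$sal[k] == "-") run <- run + 1L
      else { ins[cpos] <- max(ins[cpos], run); run <- 0L; cpos <- cpos + 1L }
    }
    ins[n + 1L] <- max(ins[n + 1L], run)
  }
  center_chars <- strsplit(center, "", fixed = TRUE)[[1]]
  build_center <- function() {
    out <- character(0)
    for (i in seq_len(n)) out <- c(out, rep("-", ins[i]), center_chars[i])
    c(out, rep("-", ins[n + 1L]))
  }
  build_row <- function(pr) {
    out <- character(0); buf <- character(0); cpos <- 1L
    for (k in seq_along(pr$sal)) {
      if (pr$sal[k] == "-") buf <- c(buf, pr$pal[k])
      else {
        out <- c(out, buf, rep("-", ins[cpos] - length(buf)), pr$pal[k])
        buf <- character(0); cpos <- cpos + 1L
      }
    }
    c(out, buf, rep("-", ins[n + 1L] - length(buf)))
  }
  rows <- vector("list", length(seqs))
  rows[[center_i]] <- build_center()
  oi <- setdiff(seq_along(seqs), center_i)
  for (k in seq_along(oi)) rows[[oi[k]]] <- build_row(parsed[[k]])
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  m
}

#' Protein-guided codon alignment
#'
#' Translates each CDS (incomplete terminal codons and the terminal stop are
#' trimmed; sequences with internal stops are dropped with a warning),
#' aligns the proteins star-wise against the longest sequence (BLOSUM62),
#' and back-translates so every aligned residue corresponds to its source
#' codon; gaps therefore come in multiples of 3.
#'
#' @param cds_set Named character vector of coding sequences.
#' @return A nucleotide alignment matrix (see [msa_from_seqs()]) with the
#'   protein alignment in attribute `aa_alignment`.
#' @export
protein_guided_align <- function(cds_set) {
  stopifnot(!is.null(names(cds_set)))
  cds_trim <- vapply(cds_set, function(s)
    substr(s, 1L, 3L * (nchar(s) %/% 3L)), "")
  aa <- vapply(cds_trim, translate_str, "")
  has_term_stop <- endsWith(aa, "*")
  aa[has_term_stop] <- substr(aa[has_term_stop], 1L,
                              nchar(aa[has_term_stop]) - 1L)
  internal <- grepl("\\*", aa)
  if (any(internal)) {
    warning("dropping sequences with internal stop codons: ",
            paste(names(aa)[internal], collapse = ", "))
    aa <- aa[!internal]; cds_trim <- cds_trim[!internal]
  }
  if (length(aa) < 2L) stop("need at least two translatable sequences")
  paln <- align_proteins(aa)
  ncol_nt <- 3L * ncol(paln)
  m <- matrix("-", nrow(paln), ncol_nt, dimnames = list(rownames(paln), NULL))
  for (tx in rownames(paln)) {
    codons <- substring(cds_trim[[tx]], seq(1L, nchar(cds_trim[[tx]]) - 2L, 3L),
                        seq(3L, nchar(cds_trim[[tx]]), 3L))
    ci <- 0L
    for (j in seq_len(ncol(paln))) {
      if (paln[tx, j] != "-") {
        ci <- ci + 1L
        m[tx, (3L * j - 2L):(3L * j)] <-
          strsplit(codons[ci], "", fixed = TRUE)[[1]]
      }
    }
  }
  attr(m, "aa_alignment") <- paln
  m
}

#' Remove alignment columns with excess missing data
#'
#' Columns where the fraction of gap or ambiguous characters exceeds
#' `max_missing` are removed; the old-to-new coordinate mapping is kept in
#' attribute `col_map` (original column index of every surviving column).
#'
#' @param msa Alignment matrix.
#' @param max_missing Maximum tolerated missing fraction (default 0.5,
#'   strict `>` removal).
#' @return The masked alignment.
#' @export
mask_columns <- function(msa, max_missing = 0.5) {
  missing <- !msa %in% BASES
  frac <- colMeans(matrix(missing, nrow = nrow(msa)))
  keep <- which(frac <= max_missing)
  if (!length(keep)) stop("all columns removed by missing-data mask")
  out <- msa[, keep, drop = FALSE]
  attr(out, "col_map") <- keep
  out
}

msa_encode <- function(msa) {
  codes <- match(msa, BASES) - 1L
  codes[is.na(codes)] <- 4L
  matrix(codes, nrow = nrow(msa), dimnames = dimnames(msa))
}

#' Kimura two-parameter distances
#'
#' Pairwise K2P distances with pairwise deletion of gap/ambiguous sites:
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with P and Q the transition and
#' transversion proportions.  Saturated pairs (non-positive logarithm
#' argument) are set to `ceiling` and flagged in attribute `saturated`.
#'
#' @param msa Alignment matrix (>= 2 taxa).
#' @param ceiling Distance assigned to saturated pairs (default 5).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
k2p_distance <- function(msa, ceiling = 5) {
  stopifnot(nrow(msa) >= 2L)
  cnt <- .k2p_counts_cpp(msa_encode(msa))
  P <- cnt$P; Q <- cnt$Q
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(arg1 * sqrt(pmax(arg2, 0))))
  sat <- !is.na(arg1) & (arg1 <= 0 | arg2 <= 0)
  d[sat] <- ceiling
  d[is.na(d) & row(d) != col(d)] <- ceiling
  diag(d) <- 0
  dimnames(d) <- list(rownames(msa), rownames(msa))
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining on a distance matrix, with taxa processed in
#' label order for deterministic tie-breaking; negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch.
#'
#' @param dist Symmetric distance matrix with taxon dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  stopifnot(nrow(dist) >= 3L)
  if (any(!is.finite(dist))) {
    bad <- which(!is.finite(dist), arr.ind = TRUE)[1, ]
    stop("non-finite distance between ", rownames(dist)[bad[1]], " and ",
         colnames(dist)[bad[2]])
  }
  ord <- order(rownames(dist))
  dist <- dist[ord, ord]
  tree <- ape::nj(stats::as.dist(dist))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
  }
  tree
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds a
#' K2P + neighbor-joining tree per replicate, and records for every internal
#' branch of the original tree the percentage of replicates containing the
#' same bipartition (stored in `node.label`).
#'
#' @param msa Alignment matrix.
#' @param n_reps Number of replicates (default 1000).
#' @param seed RNG seed (recorded in attribute `seed`).
#' @return The original tree (`phylo`) with integer percent supports as
#'   `node.label` (root label empty).
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L) {
  tree <- nj_tree(k2p_distance(msa))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(msa), replace = TRUE)
    reps[[r]] <- nj_tree(k2p_distance(msa[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / n_reps)
  tree$node.label <- as.character(supports)
  tree$node.label[1] <- ""                 # root of the unrooted tree
  attr(tree, "seed") <- seed
  attr(tree, "n_reps") <- n_reps
  tree
}

#' Read an externally computed support tree
#'
#' Adapter for slotting in trees inferred by external maximum-likelihood
#' software: any Newick file whose internal node labels are bootstrap
#' percentages can be consumed by [grouping_test()].
#'
#' @param path Newick file path.
#' @return A `phylo` tree.
#' @export
read_support_tree <- function(path) {
  ape::read.tree(path)
}

node_support <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (is.null(tree$node.label) || node <= n_tip) return(NA_real_)
  suppressWarnings(as.numeric(tree$node.label[node - n_tip]))
}

clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Vertical-vs-horizontal grouping test
#'
#' Roots the tree on the outgroup and tests whether the focal taxa group
#' with their expected relatives: the verdict is `vertical` when the focal
#' taxa are monophyletic and the clade of focal plus expected sister has
#' support above `threshold`, or when the smallest supported clade
#' containing the focal taxa lies within the expected group;
#' `hgt_candidate` when that clade instead falls inside a single different
#' labeled group; `unresolved` otherwise.
#'
#' @param tree A `phylo` with percent supports as `node.label` (e.g. from
#'   [bootstrap_support()] or [read_support_tree()]).
#' @param focal_taxa Character vector of focal tip labels.
#' @param expected_sister Tip label(s) of the expected sister.
#' @param groups Named list: clade label -> tip set, including the focal
#'   taxa's own group (the one containing `expected_sister`).
#' @param threshold Support threshold (default 80, strict `>`).
#' @param outgroup Tip label(s) to root on.
#' @return A list of class `grouping_verdict` with `verdict`,
#'   `focal_monophyly_support`, `sister_clade`, `sister_support`.
#' @export
grouping_test <- function(tree, focal_taxa, expected_sister, groups = list(),
                          threshold = 80, outgroup = NULL) {
  if (!all(focal_taxa %in% tree$tip.label)) {
    stop("focal taxa absent from tree: ",
         paste(setdiff(focal_taxa, tree$tip.label), collapse = ", "))
  }
  if (!is.null(outgroup)) {
    outgroup <- intersect(outgroup, tree$tip.label)
    if (length(outgroup)) {
      tree <- ape::root(tree, outgroup, resolve.root = TRUE,
                        edgelabel = TRUE)
    }
  }
  n_tip <- length(tree$tip.label)
  own_label <- NA_character_
  for (lab in names(groups)) {
    if (any(expected_sister %in% groups[[lab]])) own_label <- lab
  }
  focal_mono <- ape::is.monophyletic(tree, focal_taxa)
  focal_support <- NA_real_
  if (focal_mono && length(focal_taxa) > 1L) {
    focal_support <- node_support(tree, ape::getMRCA(tree, focal_taxa))
  }
  # support of the exact clade focal + expected sister
  want <- union(focal_taxa, expected_sister)
  sister_support <- NA_real_
  if (all(want %in% tree$tip.label) && length(want) > 1L) {
    mrca <- ape::getMRCA(tree, want)
    if (setequal(clade_tips(tree, mrca), want)) {
      sister_support <- node_support(tree, mrca)
    }
  }
  verdict <- "unresolved"; sister_clade <- NA_character_
  if (!is.na(sister_support) && sister_support > threshold &&
      (length(focal_taxa) == 1L || focal_mono)) {
    verdict <- "vertical"
    sister_clade <- paste(expected_sister, collapse = ",")
  } else {
    # smallest supported clade containing all focal taxa
    node <- if (length(focal_taxa) > 1L) ape::getMRCA(tree, focal_taxa)
            else which(tree$tip.label == focal_taxa)
    root_node <- n_tip + 1L
    anc <- node
    found <- NULL
    while (anc != root_node) {
      parent <- tree$edge[tree$edge[, 2] == anc, 1]
      if (!length(parent)) break
      anc <- parent
      sup <- node_support(tree, anc)
      if (!is.na(sup) && sup > threshold) { found <- anc; break }
    }
    if (!is.null(found)) {
      others <- setdiff(clade_tips(tree, found), focal_taxa)
      sup <- node_support(tree, found)
      memberships <- names(groups)[vapply(names(groups), function(lab)
        length(others) > 0 && all(others %in% groups[[lab]]), TRUE)]
      if (length(memberships) >= 1L) {
        lab <- memberships[1]
        sister_clade <- lab
        sister_support <- sup
        verdict <- if (!is.na(own_label) && lab == own_label) "vertical"
                   else "hgt_candidate"
      }
    }
  }
  structure(list(verdict = verdict,
                 focal_monophyly_support = focal_support,
                 sister_clade = sister_clade,
                 sister_support = sister_support,
                 threshold = threshold),
            class = "grouping_verdict")
}

#' @export
print.grouping_verdict <- function(x, ...) {
  cat(sprintf("<grouping_verdict> %s (sister: %s, support %s; focal support %s)\n",
              x$verdict, x$sister_clade,
              ifelse(is.na(x$sister_support), "NA", x$sister_support),
              ifelse(is.na(x$focal_monophyly_support), "NA",
                     x$focal_monophyly_support)))
  invisible(x)
}

#' Concatenate alignments over a shared taxon namespace
#'
#' Taxa missing from an input alignment are gap-filled for that block.  The
#' per-gene column ranges are retained in attribute `partition` so the
#' inputs can be reconstructed.
#'
#' @param msas Named list of alignment matrices.
#' @return The concatenated alignment.
#' @export
concatenate_msa <- function(msas) {
  stopifnot(length(msas) >= 1L)
  taxa <- sort(unique(unlist(lapply(msas, rownames))))
  blocks <- list(); partition <- list(); at <- 0L
  for (nm in names(msas)) {
    m <- msas[[nm]]
    block <- matrix("-", length(taxa), ncol(m),
                    dimnames = list(taxa, NULL))
    block[rownames(m), ] <- m
    blocks[[nm]] <- block
    partition[[nm]] <- c(start = at, end = at + ncol(m))
    at <- at + ncol(m)
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- taxa
  attr(out, "partition") <- partition
  out
}

#' Permutation scan for gene conversion
#'
#' Restricted to gap-free polymorphic columns, every taxon pair is scored by
#' its longest run of identical polymorphic sites (a long shared fragment
#' across otherwise polymorphic sequence is the conversion signal).  The
#' null distribution is obtained by global column permutation (all pairs
#' share each permutation), p-values are Bonferroni-corrected over pairs,
#' and fragments significant at `alpha` are reported.  Pairs identical at
#' every polymorphic site carry no contrast and are excluded.
#'
#' @param msa Alignment matrix (>= 3 taxa).
#' @param n_perms Number of permutations (default 10000).
#' @param seed RNG seed for the permutation stream.
#' @param alpha Significance level after correction (default 0.05).
#' @param mask Optional list of 0-based half-open column intervals to remove
#'   before scanning (e.g. known co-conversion tracts), as two-column
#'   matrices or `c(start, end)` pairs.
#' @return Data frame with `taxon_a`, `taxon_b`, `frag_start`, `frag_end`
#'   (0-based half-open alignment columns), `max_run`, `p_value`,
#'   `p_adjusted`, `significant`.  Attribute `note` explains empty results.
#' @export
geneconv_scan <- function(msa, n_perms = 10000L, seed = 1L, alpha = 0.05,
                          mask = list()) {
  stopifnot(nrow(msa) >= 3L)
  if (length(mask)) {
    drop <- unlist(lapply(mask, function(iv) (iv[1] + 1L):iv[2]))
    keep <- setdiff(seq_len(ncol(msa)), drop)
    msa <- msa[, keep, drop = FALSE]
    orig_cols <- keep
  } else {
    orig_cols <- seq_len(ncol(msa))
  }
  clean <- apply(msa, 2L, function(col) all(col %in% BASES))
  poly <- clean & apply(msa, 2L, function(col) length(unique(col)) > 1L)
  empty <- data.frame(taxon_a = character(), taxon_b = character(),
                      frag_start = integer(), frag_end = integer(),
                      max_run = integer(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (sum(poly) < 2L) {
    attr(empty, "note") <- "fewer than 2 polymorphic columns"
    return(empty)
  }
  sub <- msa[, poly, drop = FALSE]
  poly_cols <- orig_cols[poly]
  taxa <- rownames(msa)
  combs <- utils::combn(length(taxa), 2L)
  eq_rows <- list(); pair_idx <- list()
  for (k in seq_len(ncol(combs))) {
    a <- combs[1, k]; b <- combs[2, k]
    eq <- as.integer(sub[a, ] == sub[b, ])
    if (all(eq == 1L)) next      # identical pair: no polymorphic contrast
    eq_rows[[length(eq_rows) + 1L]] <- eq
    pair_idx[[length(pair_idx) + 1L]] <- c(a, b)
  }
  if (!length(eq_rows)) {
    attr(empty, "note") <- "no pair with polymorphic contrast"
    return(empty)
  }
  eqm <- do.call(rbind, eq_rows)
  res <- .geneconv_perm_cpp(eqm, as.integer(n_perms), as.integer(seed))
  np <- nrow(eqm)
  out <- data.frame(
    taxon_a = taxa[vapply(pair_idx, `[`, 0L, 1L)],
    taxon_b = taxa[vapply(pair_idx, `[`, 0L, 2L)],
    frag_start = poly_cols[res$run_start + 1L] - 1L,
    frag_end = poly_cols[res$run_end + 1L],
    max_run = res$max_run,
    p_value = res$p_value,
    p_adjusted = pmin(1, res$p_value * np),
    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, -out$max_run), , drop = FALSE]
  rownames(out) <- NULL
  out
}
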