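#' Find open reading frames
#'
#' Scans all six frames for ORFs (ATG through the next in-frame stop with no
#' internal stop).  Within a stop-bounded segment the outermost ATG is
#' reported.  Circular genomes are scanned across the origin on a doubled
#' sequence.
#'
#' @param g A [genome].
#' @param min_aa Minimum protein length in residues (excluding the stop).
#' @return A [features] table (type `other`), one row per ORF, with a
#'   `frame=` qualifier; ORF intervals include the stop codon.
#' @export
find_orfs <- function(g, min_aa = 30L) {
  g <- as_genome(g)
  stopifnot(min_aa >= 1L)
  L <- nchar(g$sequence)
  seqs <- list(`+` = g$sequence, `-` = revcomp(g$sequence))
  rows <- list()
  for (strand in c("+", "-")) {
    s <- seqs[[strand]]
    scan_len <- L
    if (g$circular) { s <- paste0(s, s); scan_len <- 2L * L }
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    for (f in 0:2) {
      starts <- seq(f + 1L, scan_len - 2L, by = 3L)
      codons <- paste0(x[starts], x[starts + 1L], x[starts + 2L])
      is_stop <- codons %in% STOPS
      is_atg <- codons == "ATG"
      seg <- cumsum(is_stop)             # stop-bounded segment index
      seg_shift <- c(0L, seg[-length(seg)])
      for (sg in unique(seg_shift[is_atg])) {
        in_seg <- which(seg_shift == sg)
        atg_i <- in_seg[is_atg[in_seg]][1]
        if (is.na(atg_i)) next
        stop_i <- in_seg[is_stop[in_seg]][1]
        if (is.na(stop_i)) next         # no stop before sequence end
        n_codons <- stop_i - atg_i      # excluding stop
        if (n_codons < min_aa) next
        a <- starts[atg_i] - 1L         # 0-based on working strand
        b <- starts[stop_i] + 2L
        if (g$circular && a >= L) next  # canonical copy only
        if (b - a > L) next
        if (strand == "+") {
          st <- a; en <- b
        } else {
          st <- scan_len - b; en <- scan_len - a
          if (g$circular && st >= L) next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          start = st, end = en, strand = strand, frame = f,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_features())
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end), , drop = FALSE]
  features(gene = paste0("orf_", seq_len(nrow(df))), type = "other",
           start = df$start, end = df$end, strand = df$strand,
           qualifiers = paste0("frame=", df$frame))
}

translate_str <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, 3L * n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %s, %d piece(s), coding length %d\n",
              x$gene, x$completeness, nrow(x$exon_loci), x$coding_length))
  invisible(x)
}

new_gene_model <- function(gene, exon_loci, completeness, coding_length = 0L,
                           intron_layout = character(), defects = list(),
                           flags = character()) {
  structure(list(gene = gene, exon_loci = exon_loci,
                 completeness = completeness,
                 coding_length = as.integer(coding_length),
                 intron_layout = intron_layout, defects = defects,
                 flags = flags),
            class = "gene_model")
}

empty_exon_loci <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             ref_start = integer(), ref_end = integer(),
             identity_percent = numeric(), stringsAsFactors = FALSE)
}

# chain reference-vs-genome hits into non-redundant pieces ordered by
# reference coordinate
chain_gene_hits <- function(hits) {
  if (!nrow(hits)) return(empty_exon_loci())
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i] || i == nrow(hits)) next
    j <- (i + 1L):nrow(hits)
    ov <- pmin(hits$q_end[j], hits$q_end[i]) - pmax(hits$q_start[j], hits$q_start[i])
    frac <- ov / pmax(1L, hits$q_end[j] - hits$q_start[j])
    keep[j][keep[j] & frac >= 0.5] <- FALSE   # redundant on the reference
  }
  h <- hits[keep, , drop = FALSE]
  h <- h[order(h$q_start), , drop = FALSE]
  data.frame(start = h$s_start, end = h$s_end, strand = h$strand,
             ref_start = h$q_start, ref_end = h$q_end,
             identity_percent = h$identity_percent, stringsAsFactors = FALSE)
}

ref_coverage <- function(loci, ref_len) {
  if (!nrow(loci)) return(0)
  interval_union_width(loci$ref_start, loci$ref_end) / ref_len
}

# extend the outer pieces of a chain to the full reference span (local
# alignment trims mismatching ends; gene boundaries are set from the
# reference, the way similarity-based annotators do)
extrapolate_loci <- function(loci, ref_len, genome_len) {
  if (!nrow(loci)) return(loci)
  first <- which.min(loci$ref_start)
  last <- which.max(loci$ref_end)
  lo <- loci$ref_start[first]          # untrimmed reference overhangs
  hi <- ref_len - loci$ref_end[last]
  if (lo > 0) {
    if (loci$strand[first] == "+") {
      loci$start[first] <- max(0L, loci$start[first] - lo)
    } else {
      loci$end[first] <- min(genome_len, loci$end[first] + lo)
    }
    loci$ref_start[first] <- 0L
  }
  if (hi > 0) {
    if (loci$strand[last] == "+") {
      loci$end[last] <- min(genome_len, loci$end[last] + hi)
    } else {
      loci$start[last] <- max(0L, loci$start[last] - hi)
    }
    loci$ref_end[last] <- ref_len
  }
  loci
}

#' Similarity-based gene annotation
#'
#' For every reference CDS, locates the best-supported exon chain in the
#' genome by local search, and classifies completeness: `intact` (a single
#' locus covering at least 95% of the reference), `fragmented` (several
#' loci, or a locus abutting a contig break), or `absent` (no qualifying
#' hit).  Pseudogene calls are layered on by [call_pseudogene()].
#' Overlapping assignments of different genes are both reported and flagged
#' ambiguous.
#'
#' @param g A [genome].
#' @param ref_cds Named character vector of reference CDS sequences (names
#'   are gene names).
#' @param p [search_params]; defaults use a 50 bp / 60% identity floor.
#' @return A named list of `gene_model` objects.
#' @export
annotate_genome <- function(g, ref_cds,
                            p = search_params(min_len_bp = 50L,
                                              min_identity_percent = 60,
                                              min_score = 50L)) {
  g <- as_genome(g)
  stopifnot(length(ref_cds) > 0, !is.null(names(ref_cds)))
  models <- list()
  for (gene in names(ref_cds)) {
    hits <- local_search(genome(gene, ref_cds[[gene]]), g, p)
    loci <- chain_gene_hits(hits)
    ref_len <- nchar(ref_cds[[gene]])
    cov <- ref_coverage(loci, ref_len)
    near_break <- FALSE
    if (length(g$contig_breaks) && nrow(loci)) {
      crossed <- any(vapply(g$contig_breaks, function(b)
        any(loci$start < b & loci$end > b), TRUE))
      contigs <- findInterval(loci$start, c(0L, g$contig_breaks))
      near_break <- crossed || length(unique(contigs)) > 1L
    }
    completeness <-
      if (!nrow(loci) || cov < 0.2) "absent"
      else if (nrow(loci) == 1L && cov >= 0.95 && !near_break) "intact"
      else "fragmented"
    coding_length <- if (completeness == "absent") 0L
      else sum(loci$end - loci$start)
    models[[gene]] <- new_gene_model(
      gene, if (completeness == "absent") empty_exon_loci() else loci,
      completeness, coding_length)
  }
  # flag conflicting overlapping assignments
  tab <- model_table(models)
  if (nrow(tab) > 1L) {
    for (i in seq_len(nrow(tab) - 1L)) {
      for (j in (i + 1L):nrow(tab)) {
        if (tab$gene[i] == tab$gene[j]) next
        if (min(tab$end[i], tab$end[j]) > max(tab$start[i], tab$start[j])) {
          models[[tab$gene[i]]]$flags <-
            union(models[[tab$gene[i]]]$flags, "ambiguous")
          models[[tab$gene[j]]]$flags <-
            union(models[[tab$gene[j]]]$flags, "ambiguous")
        }
      }
    }
  }
  models
}

model_table <- function(models) {
  rows <- lapply(models, function(m) {
    if (!nrow(m$exon_loci)) return(NULL)
    data.frame(gene = m$gene, start = m$exon_loci$start,
               end = m$exon_loci$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(gene = character(), start = integer(),
                               end = integer()) else out
}

# concatenated genomic CDS of a model, pieces in reference order
extract_model_cds <- function(model, g) {
  g <- as_genome(g)
  loci <- model$exon_loci[order(model$exon_loci$ref_start), , drop = FALSE]
  paste(vapply(seq_len(nrow(loci)), function(i) {
    sq <- subseq_str(g$sequence, loci$start[i], loci$end[i])
    if (loci$strand[i] == "-") revcomp(sq) else sq
  }, ""), collapse = "")
}

#' Call pseudogenes from conceptual translation
#'
#' Downgrades the model to `pseudogene` when it shows a net frameshift
#' (the genomic span differs from the aligned reference span by an amount
#' not divisible by 3 - robust to a few trimmed alignment ends, which
#' shorten both spans equally) and/or internal stop codons in the
#' conceptual translation, taken in the reference reading frame.  Defect
#' positions are recorded.
#'
#' @param model A `gene_model` with exon loci.
#' @param g The [genome].
#' @return The (possibly updated) `gene_model`.
#' @export
call_pseudogene <- function(model, g) {
  if (!nrow(model$exon_loci)) return(model)
  loci <- model$exon_loci
  defects <- list()
  net_indel <- sum(loci$end - loci$start) - sum(loci$ref_end - loci$ref_start)
  if (net_indel %% 3L != 0L) {
    defects$frameshift <- net_indel
  }
  cds <- extract_model_cds(model, g)
  frame_off <- (3L - min(loci$ref_start) %% 3L) %% 3L
  aa <- translate_str(substr(cds, frame_off + 1L, nchar(cds)))
  if (nchar(aa) > 1L) {
    internal <- substr(aa, 1L, nchar(aa) - 1L)
    stops <- which(strsplit(internal, "", fixed = TRUE)[[1]] == "*")
    if (length(stops)) defects$internal_stops <- stops
  }
  if (length(defects)) {
    model$completeness <- "pseudogene"
    model$defects <- defects
  }
  model
}

#' Detect split (possibly trans-spliced) gene structure
#'
#' Aligns an intron-less reference CDS to the genome and orders the pieces
#' by reference coordinate.  Adjacent pieces on the same strand and contig
#' within `min_separation_bp` are classified as a cis intron; pieces
#' separated farther, on opposite strands, or on different contigs are
#' trans.  Two pieces that abut on the reference with no intervening
#' reference gap indicate a split within an exon, reported in `flags` -
#' unless the junction coincides with a known intron insertion site
#' (`intron_ref_pos`, taken from reference annotations), where contiguity on
#' the intron-less reference is expected.
#'
#' @param gene Gene name.
#' @param ref_cds Intron-less reference CDS sequence.
#' @param g The [genome].
#' @param p [search_params].
#' @param min_separation_bp Genomic distance beyond which a junction is
#'   trans (default 5000).
#' @param intron_ref_pos Known intron positions on the reference CDS
#'   (0-based), with a 10 bp tolerance.
#' @return A `gene_model` with `intron_layout` (one of cis/trans per
#'   junction) and split-exon flags.
#' @export
detect_split_gene <- function(gene, ref_cds, g,
                              p = search_params(min_len_bp = 50L,
                                                min_identity_percent = 60,
                                                min_score = 50L),
                              min_separation_bp = 5000L,
                              intron_ref_pos = integer()) {
  g <- as_genome(g)
  hits <- local_search(genome(gene, ref_cds), g, p)
  loci <- chain_gene_hits(hits)
  ref_len <- nchar(ref_cds)
  cov <- ref_coverage(loci, ref_len)
  if (nrow(loci) < 2L) {
    completeness <- if (!nrow(loci) || cov < 0.2) "absent" else
      if (cov >= 0.95) "intact" else "fragmented"
    return(new_gene_model(gene, loci, completeness,
                          if (nrow(loci)) sum(loci$end - loci$start) else 0L))
  }
  contig_of <- function(pos) findInterval(pos, c(0L, g$contig_breaks))
  layout <- character(nrow(loci) - 1L)
  flags <- character()
  for (k in seq_len(nrow(loci) - 1L)) {
    a <- loci[k, ]; b <- loci[k + 1L, ]
    gap_genomic <- max(0L, max(a$start, b$start) - min(a$end, b$end))
    trans <- a$strand != b$strand ||
      contig_of(a$start) != contig_of(b$start) ||
      gap_genomic > min_separation_bp
    layout[k] <- if (trans) "trans" else "cis"
    ref_gap <- b$ref_start - a$ref_end
    at_intron <- length(intron_ref_pos) &&
      any(abs(intron_ref_pos - a$ref_end) <= 10L)
    if (ref_gap <= 5L && !at_intron) {
      flags <- c(flags, sprintf("split_exon_junction_%d", k))
    }
  }
  new_gene_model(gene, loci,
                 completeness = if (cov >= 0.95) "intact" else "fragmented",
                 coding_length = sum(loci$end - loci$start),
                 intron_layout = layout, flags = flags)
}

#' Read support for gene-piece junctions
#'
#' Anchors every transcript read in the model's pieces (local search, at
#' least `min_anchor_bp` aligned at `min_identity` percent identity) and
#' counts, for every pair of pieces, the read pairs whose mates anchor in
#' different pieces and the single reads that cross a junction (split
#' reads).  A low-coverage flag is set when no read anchors at all.
#'
#' @param model A `gene_model` with at least 2 pieces.
#' @param g The [genome].
#' @param reads List of paired [read_record]s (mate linked via
#'   `paired_with`, or ids sharing a prefix before `/1`, `/2`).
#' @param min_anchor_bp,min_identity Anchor thresholds (30 bp, 90%).
#' @return A data frame with `piece_a`, `piece_b`, `n_pairs`,
#'   `n_split_reads` and attribute `low_coverage`.
#' @export
junction_support <- function(model, g, reads, min_anchor_bp = 30L,
                             min_identity = 90) {
  stopifnot(nrow(model$exon_loci) >= 2L)
  g <- as_genome(g)
  loci <- model$exon_loci[order(model$exon_loci$ref_start), , drop = FALSE]
  n_p <- nrow(loci)
  piece_seqs <- vapply(seq_len(n_p), function(i) {
    sq <- subseq_str(g$sequence, loci$start[i], loci$end[i])
    if (loci$strand[i] == "-") revcomp(sq) else sq
  }, "")
  p <- search_params(word_size = 11L, min_len_bp = min_anchor_bp,
                     min_identity_percent = min_identity, min_score = 40L)
  # piece assignment per read: list of data frames (piece, q_start, q_end)
  anchors <- lapply(reads, function(rd) {
    res <- list()
    for (i in seq_len(n_p)) {
      if (nchar(rd$sequence) < p$word_size) next
      h <- local_search(rd$sequence, piece_seqs[i], p)
      if (nrow(h)) {
        res[[length(res) + 1L]] <- data.frame(
          piece = i, q_start = h$q_start[1], q_end = h$q_end[1],
          score = h$score[1], stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  names(anchors) <- vapply(reads, `[[`, "", "id")
  covered <- !vapply(anchors, is.null, TRUE)
  pair_key <- function(id) sub("/[12]$", "", id)
  pairs <- split(seq_along(reads), vapply(reads, function(r)
    pair_key(r$id), ""))
  counts <- matrix(0L, n_p, n_p)
  splits <- matrix(0L, n_p, n_p)
  best_piece <- function(a) if (is.null(a)) NA_integer_ else
    a$piece[which.max(a$score)]
  for (pr in pairs) {
    ps <- unique(stats::na.omit(vapply(pr, function(i)
      best_piece(anchors[[i]]), 0L)))
    if (length(ps) == 2L) {
      counts[min(ps), max(ps)] <- counts[min(ps), max(ps)] + 1L
    }
    # split reads: one read anchored in two pieces at distinct read segments
    for (i in pr) {
      a <- anchors[[i]]
      if (is.null(a) || length(unique(a$piece)) < 2L) next
      for (x in seq_len(nrow(a) - 1L)) {
        for (y in (x + 1L):nrow(a)) {
          if (a$piece[x] == a$piece[y]) next
          ov <- min(a$q_end[x], a$q_end[y]) - max(a$q_start[x], a$q_start[y])
          if (ov <= 10L) {
            i1 <- min(a$piece[x], a$piece[y]); i2 <- max(a$piece[x], a$piece[y])
            splits[i1, i2] <- splits[i1, i2] + 1L
          }
        }
      }
    }
  }
  idx <- which(upper.tri(counts), arr.ind = TRUE)
  out <- data.frame(piece_a = idx[, 1], piece_b = idx[, 2],
                    n_pairs = counts[idx], n_split_reads = splits[idx])
  out <- out[order(out$piece_a, out$piece_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "low_coverage") <- !any(covered)
  out
}

#' Predict C-to-U editing sites from homolog conservation
#'
#' A conservation-restoration scorer: for every genomic C in the focal CDS,
#' the codon is edited in silico (C to T) and the site is scored by the
#' fraction of non-gap homologs whose aligned residue matches the edited
#' residue.  Sites are predicted when the edit changes the residue and the
#' score reaches `min_score` (default 0.5); all-gap columns are left
#' unscored.
#'
#' @param focal_cds In-frame CDS sequence of the focal gene.
#' @param homolog_proteins Named character vector of homolog protein
#'   sequences (aligned on the fly together with the focal translation).
#' @param min_score Prediction threshold in `[0, 1]`.
#' @return A data frame of predicted sites: `cds_pos` (0-based), `codon_pos`
#'   (1-3), `predicted_score`, `status`.
#' @export
predict_edit_sites <- function(focal_cds, homolog_proteins, min_score = 0.5) {
  n_cod <- nchar(focal_cds) %/% 3L
  focal_aa <- translate_str(focal_cds)
  aln <- align_proteins(c(focal_protein_ = focal_aa, homolog_proteins))
  fa <- aln["focal_protein_", ]
  focal_cols <- which(fa != "-")           # columns holding focal residues
  hom <- aln[setdiff(rownames(aln), "focal_protein_"), , drop = FALSE]
  x <- strsplit(focal_cds, "", fixed = TRUE)[[1]]
  rows <- list()
  for (pos0 in which(x == "C") - 1L) {
    cod_i <- pos0 %/% 3L + 1L             # 1-based codon index
    if (cod_i > n_cod || cod_i > length(focal_cols)) next
    codon_pos <- pos0 %% 3L + 1L
    cod <- substr(focal_cds, 3L * cod_i - 2L, 3L * cod_i)
    edited <- cod
    substr(edited, codon_pos, codon_pos) <- "T"
    aa0 <- translate_str(cod); aa1 <- translate_str(edited)
    if (aa0 == aa1) next                  # synonymous edit: never predicted
    col <- focal_cols[cod_i]
    res <- hom[, col]
    res <- res[res != "-"]
    if (!length(res)) next                # all-gap column: unscored
    score <- sum(res == aa1) / length(res)
    if (score >= min_score) {
      rows[[length(rows) + 1L]] <- data.frame(
        cds_pos = pos0, codon_pos = codon_pos, predicted_score = score,
        status = "predicted_only", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cds_pos = integer(), codon_pos = integer(),
                      predicted_score = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Observe editing sites in mapped transcript reads
#'
#' Maps transcript reads to each model piece (local alignment at >= 90%
#' identity, both orientations tried) and piles up mismatches.  A site is
#' observed when the genomic base is C on the coding strand, coverage is at
#' least `min_cov` and the T fraction reaches `min_fraction`.
#'
#' @param g The [genome].
#' @param model A `gene_model`.
#' @param reads List of [read_record] transcript reads.
#' @param min_cov Minimum read coverage (default 5).
#' @param min_fraction Minimum T fraction (default 0.5).
#' @return A data frame of observed sites: `cds_pos`, `codon_pos`,
#'   `genome_pos`, `coverage`, `observed_fraction`, `status`.
#' @export
observe_edit_sites <- function(g, model, reads, min_cov = 5L,
                               min_fraction = 0.5) {
  g <- as_genome(g)
  loci <- model$exon_loci[order(model$exon_loci$ref_start), , drop = FALSE]
  submat <- nucleotide_submat()
  rows <- list()
  cds_offset <- 0L
  read_set <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "sequence"))
  read_rc <- Biostrings::reverseComplement(read_set)
  for (i in seq_len(nrow(loci))) {
    piece <- subseq_str(g$sequence, loci$start[i], loci$end[i])
    if (loci$strand[i] == "-") piece <- revcomp(piece)
    plen <- nchar(piece)
    pa_f <- Biostrings::pairwiseAlignment(read_set, piece, type = "local",
                                          substitutionMatrix = submat,
                                          gapOpening = 5, gapExtension = 2)
    pa_r <- Biostrings::pairwiseAlignment(read_rc, piece, type = "local",
                                          substitutionMatrix = submat,
                                          gapOpening = 5, gapExtension = 2)
    use_r <- Biostrings::score(pa_r) > Biostrings::score(pa_f)
    cov <- integer(plen)
    t_cnt <- integer(plen)
    collect <- function(pa, sel) {
      if (!any(sel)) return(invisible())
      pa <- pa[sel]
      ok <- Biostrings::nchar(pa) >= 40 & Biostrings::pid(pa) >= 90
      if (!any(ok)) return(invisible())
      pa <- pa[ok]
      rng_s <- IRanges::start(Biostrings::subject(pa))
      rng_e <- IRanges::end(Biostrings::subject(pa))
      for (k in seq_along(pa)) {
        cov[rng_s[k]:rng_e[k]] <<- cov[rng_s[k]:rng_e[k]] + 1L
      }
      mt <- Biostrings::mismatchTable(pa)
      if (nrow(mt)) {
        tt <- mt[mt$PatternSubstring == "T", , drop = FALSE]
        if (nrow(tt)) {
          tab <- table(tt$SubjectStart)
          pos <- as.integer(names(tab))
          t_cnt[pos] <<- t_cnt[pos] + as.integer(tab)
        }
      }
      invisible()
    }
    collect(pa_f, !use_r)
    collect(pa_r, use_r)
    xp <- strsplit(piece, "", fixed = TRUE)[[1]]
    cand <- which(xp == "C" & cov >= min_cov & t_cnt / pmax(1L, cov) >= min_fraction)
    for (pos in cand) {
      cds_pos <- cds_offset + pos - 1L
      gpos <- if (loci$strand[i] == "+") loci$start[i] + pos - 1L
              else loci$end[i] - pos
      rows[[length(rows) + 1L]] <- data.frame(
        cds_pos = cds_pos, codon_pos = cds_pos %% 3L + 1L, genome_pos = gpos,
        coverage = cov[pos], observed_fraction = t_cnt[pos] / cov[pos],
        status = "observed_only", stringsAsFactors = FALSE)
    }
    cds_offset <- cds_offset + plen
  }
  if (!length(rows)) {
    return(data.frame(cds_pos = integer(), codon_pos = integer(),
                      genome_pos = integer(), coverage = integer(),
                      observed_fraction = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Merge predicted and observed editing sites
#'
#' Full join on CDS position; sites present in both lists get status
#' `both`, otherwise `predicted_only` / `observed_only`.
#'
#' @param predicted Output of [predict_edit_sites()].
#' @param observed Output of [observe_edit_sites()].
#' @return Combined data frame with a `status` column.
#' @export
merge_edit_sites <- function(predicted, observed) {
  p <- predicted[, c("cds_pos", "codon_pos", "predicted_score"), drop = FALSE]
  o <- observed[, c("cds_pos", "observed_fraction"), drop = FALSE]
  m <- merge(p, o, by = "cds_pos", all = TRUE)
  m$status <- ifelse(!is.na(m$predicted_score) & !is.na(m$observed_fraction),
                     "both",
                     ifelse(!is.na(m$predicted_score), "predicted_only",
                            "observed_only"))
  m[order(m$cds_pos), , drop = FALSE]
}
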