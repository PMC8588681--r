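#' Search parameters for local similarity search
#'
#' Scoring follows the common nucleotide BLAST convention: +2 match, -3
#' mismatch, affine gaps where a gap of length k costs
#' `gap_open + k * gap_extend`.  In place of an E-value cutoff, a raw-score
#' threshold `min_score` is applied; the default (50) was calibrated so that
#' self-contained searches of independent random 10 kb sequence pairs return
#' no hits, emulating a stringent (about 1e-10) E-value regime without a
#' database-size context.
#'
#' @param word_size Exact-match seed length (>= 4).
#' @param match,mismatch Match/mismatch scores.
#' @param gap_open,gap_extend Gap penalties (negative).
#' @param xdrop Ungapped extension drop-off.
#' @param min_len_bp Minimum alignment length retained.
#' @param min_identity_percent Minimum percent identity retained (gap columns
#'   count as non-matches).
#' @param min_score Minimum alignment score retained.
#' @param full_dp_cells Windows with at most this many DP cells are polished
#'   with a full local alignment; larger windows use a banded alignment
#'   around the seed diagonal.
#' @return A list of class `search_params`.
#' @export
search_params <- function(word_size = 11L, match = 2L, mismatch = -3L,
                          gap_open = -5L, gap_extend = -2L, xdrop = 20L,
                          min_len_bp = 1L, min_identity_percent = 0,
                          min_score = 50L, full_dp_cells = 4e6) {
  stopifnot(word_size >= 4L, min_identity_percent >= 0,
            min_identity_percent <= 100, match > 0, mismatch < 0,
            gap_open <= 0, gap_extend < 0)
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 xdrop = as.integer(xdrop),
                 min_len_bp = as.integer(min_len_bp),
                 min_identity_percent = as.numeric(min_identity_percent),
                 min_score = as.integer(min_score),
                 full_dp_cells = as.numeric(full_dp_cells)),
            class = "search_params")
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), strand = character(), length_bp = integer(),
             n_matches = integer(), identity_percent = numeric(),
             score = integer(), stringsAsFactors = FALSE)
}

#' Local similarity search (seed-and-extend)
#'
#' Finds local alignments between two nucleotide sequences on both strands
#' by exact-word seeding, ungapped x-drop extension and gapped
#' Smith-Waterman polishing around each extended segment.  Overlapping
#' extensions of the same region are deduplicated to the best-scoring hit.
#' Hits are reported in 0-based half-open coordinates on the plus strand of
#' both sequences (`strand == "-"` means the reverse complement of the query
#' interval matches the subject interval) and sorted by descending score.
#'
#' @param query,subject [genome] objects (or plain sequence strings).
#' @param p A [search_params] object.
#' @param self Set TRUE when query and subject are the same molecule: the
#'   trivial full-length self match is suppressed.
#' @return A data frame of hits: `query_id`, `subject_id`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `strand`, `length_bp` (alignment columns),
#'   `n_matches`, `identity_percent`, `score`.
#' @export
local_search <- function(query, subject, p = search_params(), self = FALSE) {
  query <- as_genome(query, "query")
  subject <- as_genome(subject, "subject")
  if (nchar(query$sequence) == 0L || nchar(subject$sequence) == 0L) {
    stop("both sequences must be non-empty")
  }
  if (p$word_size > min(nchar(query$sequence), nchar(subject$sequence))) {
    warning("word_size exceeds a sequence length; returning no hits")
    return(empty_hits())
  }
  df <- .seed_extend_cpp(query$sequence, subject$sequence, p$word_size,
                         p$match, p$mismatch, p$gap_open, p$gap_extend,
                         p$xdrop, p$min_score, isTRUE(self),
                         max_full_cells = p$full_dp_cells %||% 4e6)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty_hits())
  df$query_id <- query$id
  df$subject_id <- subject$id
  df$identity_percent <- 100 * df$n_matches / df$length_bp
  df <- df[df$length_bp >= p$min_len_bp &
             df$identity_percent >= p$min_identity_percent &
             df$score >= p$min_score, , drop = FALSE]
  df <- df[order(-df$score, df$s_start, df$q_start), , drop = FALSE]
  rownames(df) <- NULL
  df[, names(empty_hits())]
}

#' Filter hits by length and identity
#'
#' Keeps hits with `length_bp >= min_len_bp` and `identity_percent >=
#' min_identity_percent` (removal thresholds are strict "less than", so a
#' hit exactly at a threshold is retained).  Input order is preserved.
#'
#' @param hits A hit data frame from [local_search()].
#' @param min_len_bp,min_identity_percent Removal thresholds.
#' @return The retained subset.
#' @export
filter_hits <- function(hits, min_len_bp, min_identity_percent) {
  if (!nrow(hits)) return(hits)
  keep <- hits$length_bp >= min_len_bp &
    hits$identity_percent >= min_identity_percent
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove near-top hits of lower identity along an assembly
#'
#' Hits are grouped by single-linkage overlap (>= 1 bp shared subject span).
#' Within each group the top hit is the one with the highest identity (ties:
#' longer alignment, then earlier subject start).  A hit is removed iff its
#' length is at most `top_length + len_window_bp` ("equivalent length or
#' less") AND its identity is more than `identity_margin` points below the
#' top hit's identity.
#'
#' @param hits Hit data frame; subject coordinates index the assembly.
#' @param len_window_bp Length-equivalence window (bp).
#' @param identity_margin Identity margin (percentage points).
#' @return The retained subset, input order preserved.
#' @export
near_top_filter <- function(hits, len_window_bp = 50, identity_margin = 2.0) {
  if (nrow(hits) <= 1L) return(hits)
  grp <- overlap_groups(hits$s_start, hits$s_end)
  keep <- rep(TRUE, nrow(hits))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- hits[idx, , drop = FALSE]
    ord <- order(-sub$identity_percent, -sub$length_bp, sub$s_start)
    top <- sub[ord[1], ]
    drop <- sub$length_bp <= top$length_bp + len_window_bp &
      sub$identity_percent < top$identity_percent - identity_margin
    keep[idx[drop]] <- FALSE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# single-linkage grouping of intervals by >= 1 bp overlap
overlap_groups <- function(start, end) {
  n <- length(start)
  ord <- order(start, end)
  grp <- integer(n)
  cur <- 0L; cur_end <- -Inf
  for (i in ord) {
    if (start[i] >= cur_end) {
      cur <- cur + 1L
      cur_end <- end[i]
    } else {
      cur_end <- max(cur_end, end[i])
    }
    grp[i] <- cur
  }
  grp
}

# union of 0-based half-open intervals as a two-column matrix
interval_union <- function(start, end) {
  if (!length(start)) return(cbind(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# total bases of [start,end) unions
interval_union_width <- function(start, end) {
  u <- interval_union(start, end)
  sum(u[, "end"] - u[, "start"])
}

# subtract union(bs,be) from union(as,ae); returns two-column matrix
interval_setdiff <- function(as, ae, bs, be) {
  if (!length(as)) return(cbind(start = integer(), end = integer()))
  a <- IRanges::reduce(IRanges::IRanges(start = as + 1L, end = ae))
  if (!length(bs)) {
    return(cbind(start = IRanges::start(a) - 1L, end = IRanges::end(a)))
  }
  b <- IRanges::reduce(IRanges::IRanges(start = bs + 1L, end = be))
  d <- IRanges::setdiff(a, b)
  cbind(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

#' Fraction of a genome covered by hits
#'
#' Computes the fraction of genome positions covered by at least one hit
#' (union, not sum), after subtracting excluded feature intervals from both
#' the covered set and the genome length.
#'
#' @param hits Hit data frame; subject coordinates index `g`.
#' @param g The [genome] (or its length as an integer).
#' @param exclude Optional [features] table of intervals to exclude.
#' @return A fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(hits, g, exclude = NULL) {
  glen <- if (is.numeric(g)) as.integer(g) else nchar(as_genome(g)$sequence)
  ex_s <- integer(); ex_e <- integer()
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- interval_union(exclude$start, exclude$end)
    ex_s <- ex[, "start"]; ex_e <- ex[, "end"]
  }
  denom <- glen - sum(ex_e - ex_s)
  if (denom <= 0) return(NA_real_)
  if (!nrow(hits)) return(0)
  cov <- interval_setdiff(hits$s_start, hits$s_end, ex_s, ex_e)
  sum(cov[, "end"] - cov[, "start"]) / denom
}

#' Write hits as a BLAST-style tabular file
#'
#' Twelve outfmt-6-compatible columns plus a strand column; coordinates are
#' 1-based inclusive in the file.
#'
#' @param hits Hit data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  mm <- hits$length_bp - hits$n_matches
  out <- data.frame(query_id = hits$query_id, subject_id = hits$subject_id,
                    identity_percent = round(hits$identity_percent, 2),
                    length_bp = hits$length_bp, mismatches = mm,
                    gap_opens = NA_integer_,
                    q_start = hits$q_start + 1L, q_end = hits$q_end,
                    s_start = hits$s_start + 1L, s_end = hits$s_end,
                    evalue = NA_real_, score = hits$score,
                    strand = hits$strand, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
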