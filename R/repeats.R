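#' Dispersed repeat detection by genome self-search
#'
#' Searches a genome against itself with [local_search()], suppressing the
#' trivial full-length self match, and reports repeat pairs passing the
#' configured thresholds (default: at least 50 bp and at least 90%
#' identity).  Circular genomes are searched on a doubled sequence and hits
#' are canonicalized back to the original coordinates, so origin-spanning
#' repeats are found.  Symmetric duplicates (a,b)/(b,a) are collapsed.
#'
#' @param g A [genome].
#' @param p [search_params]; the defaults apply the 50 bp / 90% filter.
#' @return A data frame of repeat pairs: `repeat_id`, `a_start`, `a_end`,
#'   `b_start`, `b_end` (0-based half-open; ends may exceed the genome
#'   length for origin-spanning copies of circular genomes), `length_bp`,
#'   `identity_percent`, `strand_relation` (direct/inverted), `score`.
#' @export
dispersed_repeats <- function(g, p = search_params(min_len_bp = 50L,
                                                   min_identity_percent = 90)) {
  g <- as_genome(g)
  L <- nchar(g$sequence)
  seq <- if (g$circular) paste0(g$sequence, g$sequence) else g$sequence
  gg <- genome(g$id, seq)
  hits <- local_search(gg, gg, p, self = TRUE)
  if (!nrow(hits)) return(empty_repeat_pairs())
  if (g$circular) {
    hits <- hits[hits$length_bp <= L, , drop = FALSE]
    # drop the artifact matches of the doubling (same circle position)
    art <- (hits$s_start - hits$q_start) %% L == 0L &
      (hits$s_end - hits$q_end) %% L == 0L
    hits <- hits[!art, , drop = FALSE]
    if (!nrow(hits)) return(empty_repeat_pairs())
  }
  # orient pairs so copy a starts first
  swap <- hits$q_start > hits$s_start
  a_s <- ifelse(swap, hits$s_start, hits$q_start)
  a_e <- ifelse(swap, hits$s_end, hits$q_end)
  b_s <- ifelse(swap, hits$q_start, hits$s_start)
  b_e <- ifelse(swap, hits$q_end, hits$s_end)
  if (g$circular) {
    # shift both copies together so copy a starts in [0, L)
    shift <- (a_s %/% L) * L
    a_s <- a_s - shift; a_e <- a_e - shift
    b_s <- b_s - shift; b_e <- b_e - shift
  }
  pairs <- data.frame(a_start = a_s, a_end = a_e, b_start = b_s, b_end = b_e,
                      length_bp = hits$length_bp,
                      identity_percent = hits$identity_percent,
                      strand_relation = ifelse(hits$strand == "+",
                                               "direct", "inverted"),
                      score = hits$score, stringsAsFactors = FALSE)
  pairs <- pairs[!(pairs$a_start == pairs$b_start &
                     pairs$a_end == pairs$b_end), , drop = FALSE]
  # collapse symmetric/near-duplicate pairs, best score first; on circular
  # genomes overlap is evaluated modulo L and in both copy orientations
  pairs <- pairs[order(-pairs$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(pairs))
  ov_frac <- function(s1, e1, s2, e2) {
    ov <- pmin(e1, e2) - pmax(s1, s2)
    f <- pmax(ov, 0) / pmax(1, pmin(e1 - s1, e2 - s2))
    if (g$circular) {
      for (off in c(-L, L)) {
        ov2 <- pmin(e1, e2 + off) - pmax(s1, s2 + off)
        f <- pmax(f, pmax(ov2, 0) / pmax(1, pmin(e1 - s1, e2 - s2)))
      }
    }
    f
  }
  for (i in seq_len(nrow(pairs))) {
    if (!keep[i]) next
    if (i < nrow(pairs)) {
      j <- (i + 1L):nrow(pairs)
      same <- pairs$strand_relation[j] == pairs$strand_relation[i]
      dup_fwd <- ov_frac(pairs$a_start[j], pairs$a_end[j],
                         pairs$a_start[i], pairs$a_end[i]) >= 0.8 &
        ov_frac(pairs$b_start[j], pairs$b_end[j],
                pairs$b_start[i], pairs$b_end[i]) >= 0.8
      dup_rev <- ov_frac(pairs$a_start[j], pairs$a_end[j],
                         pairs$b_start[i], pairs$b_end[i]) >= 0.8 &
        ov_frac(pairs$b_start[j], pairs$b_end[j],
                pairs$a_start[i], pairs$a_end[i]) >= 0.8
      keep[j][keep[j] & same & (dup_fwd | dup_rev)] <- FALSE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$a_start, pairs$b_start), , drop = FALSE]
  if (nrow(pairs)) pairs$repeat_id <- paste0("rep_", seq_len(nrow(pairs)))
  else pairs$repeat_id <- character()
  rownames(pairs) <- NULL
  pairs[, c("repeat_id", "a_start", "a_end", "b_start", "b_end", "length_bp",
            "identity_percent", "strand_relation", "score")]
}

empty_repeat_pairs <- function() {
  data.frame(repeat_id = character(), a_start = integer(), a_end = integer(),
             b_start = integer(), b_end = integer(), length_bp = integer(),
             identity_percent = numeric(), strand_relation = character(),
             score = integer(), stringsAsFactors = FALSE)
}

#' Percent of a genome inside dispersed repeats
#'
#' The union (not the sum) of all repeat copy intervals, as a percentage of
#' genome length; both copies of every pair count.
#'
#' @param pairs Repeat pairs from [dispersed_repeats()].
#' @param g The [genome].
#' @return Percent in `[0, 100]`.
#' @export
repeat_content <- function(pairs, g) {
  g <- as_genome(g)
  L <- nchar(g$sequence)
  if (!nrow(pairs)) return(0)
  st <- c(pairs$a_start, pairs$b_start)
  en <- c(pairs$a_end, pairs$b_end)
  # map copies of circular genomes back into [0, L), splitting intervals
  # that wrap the origin
  shift <- ifelse(st >= L, -L, 0L)
  st <- st + shift; en <- en + shift
  wrap <- en > L
  if (any(wrap)) {
    st <- c(st[!wrap], st[wrap], rep(0L, sum(wrap)))
    en <- c(en[!wrap], rep(L, sum(wrap)), pmin(en[wrap] - L, L))
  }
  100 * interval_union_width(pmax(st, 0L), pmin(en, L)) / L
}

#' Tandem repeat scan parameters
#'
#' Mirrors the conventional tandem-repeat-finder setting vector
#' (match, mismatch penalty, indel penalty, match probability, indel
#' probability, minimum score, maximum period) = 2 7 7 80 10 50 500.  The
#' scan implemented here scores substitution-only alignment of each position
#' against the position one period earlier, so the indel parameters are
#' carried for interface compatibility but do not enter the score.
#'
#' @param match,mismatch_penalty,indel_penalty,match_probability,
#'   indel_probability,min_score,max_period Setting vector components.
#' @return A list of class `tandem_params`.
#' @export
tandem_params <- function(match = 2L, mismatch_penalty = 7L,
                          indel_penalty = 7L, match_probability = 80L,
                          indel_probability = 10L, min_score = 50L,
                          max_period = 500L) {
  structure(list(match = as.integer(match),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 indel_penalty = as.integer(indel_penalty),
                 match_probability = as.integer(match_probability),
                 indel_probability = as.integer(indel_probability),
                 min_score = as.integer(min_score),
                 max_period = as.integer(max_period)),
            class = "tandem_params")
}

#' Detect tandem repeat arrays
#'
#' For every candidate period up to `max_period`, positions are compared
#' with the position one period earlier and maximal positively scoring
#' segments are collected (match `+2`, mismatch `-7` by default); arrays
#' reaching `min_score` are reported with period, copy number and percent
#' identity, and overlapping reports are merged to the best-scoring one.
#'
#' @param g A [genome].
#' @param tp [tandem_params].
#' @return A [features] table (type `repeat`) with `period=`, `copies=`,
#'   `identity=` and `score=` qualifiers.
#' @export
tandem_repeats <- function(g, tp = tandem_params()) {
  g <- as_genome(g)
  cand <- as.data.frame(.tandem_scan_cpp(g$sequence, tp$match,
                                         tp$mismatch_penalty, tp$min_score,
                                         tp$max_period))
  if (nrow(cand)) {
    cand <- cand[cand$end - cand$start >= 1.5 * cand$period, , drop = FALSE]
  }
  if (!nrow(cand)) return(empty_features())
  cand <- cand[order(-cand$score, cand$period), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1L):nrow(cand)
      ov <- pmin(cand$end[j], cand$end[i]) - pmax(cand$start[j], cand$start[i])
      keep[j][keep[j] & ov > 0] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  quals <- sprintf("period=%d;copies=%.1f;identity=%.1f;score=%d",
                   cand$period, (cand$end - cand$start) / cand$period,
                   100 * cand$n_matches / pmax(1L, cand$n_compared),
                   cand$score)
  features(gene = paste0("tandem_", seq_len(nrow(cand))), type = "repeat",
           start = cand$start, end = cand$end, strand = "+",
           qualifiers = quals)
}

#' Extract long repeats for the recombination proxy
#'
#' Applies the strict thresholds (length > `min_len_bp` and identity >
#' `min_identity_percent`, both exclusive) and reduces overlapping
#' qualifying pairs to a non-overlapping set by descending length.
#'
#' @param pairs Repeat pairs from [dispersed_repeats()].
#' @param min_len_bp,min_identity_percent Strict lower bounds (defaults
#'   500 bp, 90%).
#' @return The qualifying non-overlapping subset.
#' @export
long_repeats <- function(pairs, min_len_bp = 500L, min_identity_percent = 90) {
  keep <- pairs$length_bp > min_len_bp &
    pairs$identity_percent > min_identity_percent
  sub <- pairs[keep, , drop = FALSE]
  if (nrow(sub) <= 1L) { rownames(sub) <- NULL; return(sub) }
  sub <- sub[order(-sub$length_bp), , drop = FALSE]
  chosen <- logical(nrow(sub))
  used_s <- integer(); used_e <- integer()
  for (i in seq_len(nrow(sub))) {
    iv_s <- c(sub$a_start[i], sub$b_start[i])
    iv_e <- c(sub$a_end[i], sub$b_end[i])
    clash <- FALSE
    if (length(used_s)) {
      for (k in 1:2) {
        if (any(pmin(used_e, iv_e[k]) > pmax(used_s, iv_s[k]))) clash <- TRUE
      }
    }
    if (!clash) {
      chosen[i] <- TRUE
      used_s <- c(used_s, iv_s); used_e <- c(used_e, iv_e)
    }
  }
  out <- sub[chosen, , drop = FALSE]
  out <- out[order(out$a_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-read proxy for recombinational activity at a repeat
#'
#' A read is *spanning* if it covers the full repeat plus at least
#' `anchor_bp` on both sides.  Each side of a sampled spanning read is
#' assigned to repeat copy A or B by the higher flank identity (global
#' alignment of the read flank against each copy's genomic flank); a
#' difference below 2 percentage points leaves the side ambiguous.  Reads
#' whose two sides phase with different copies are incongruent (crossover
#' products), and the activity proxy is the percentage of incongruent reads
#' among classified (congruent + incongruent) reads.  Up to `sample_cap`
#' spanning reads are sampled without replacement under the given seed.
#'
#' @param r One row of a repeat-pair data frame (direct repeats; the proxy
#'   is not computed for inverted pairs).
#' @param g The [genome].
#' @param reads List of [read_record] long reads.
#' @param anchor_bp Minimum flank anchor (default 100).
#' @param sample_cap Maximum reads evaluated (default 50).
#' @param seed Sampling seed (recorded in the result).
#' @param margin_points Ambiguity margin in identity points (default 2).
#' @return A list of class `repeat_activity`: `repeat_id`,
#'   `n_spanning_reads`, `n_sampled`, `n_congruent`, `n_incongruent`,
#'   `n_ambiguous`, `activity_percent`, `flag`, `seed`.
#' @export
repeat_activity <- function(r, g, reads, anchor_bp = 100L, sample_cap = 50L,
                            seed = 1L, margin_points = 2) {
  g <- as_genome(g)
  if (is.data.frame(r)) r <- as.list(r[1, ])
  out <- list(repeat_id = r$repeat_id, n_spanning_reads = 0L, n_sampled = 0L,
              n_congruent = 0L, n_incongruent = 0L, n_ambiguous = 0L,
              activity_percent = NA_real_, flag = NA_character_, seed = seed)
  class(out) <- "repeat_activity"
  if (identical(r$strand_relation, "inverted")) {
    out$flag <- "inverted_pair_unsupported"
    warning("activity proxy is defined for direct repeat pairs only")
    return(out)
  }
  L <- nchar(g$sequence)
  rep_len <- r$a_end - r$a_start
  repA <- subseq_str(g$sequence, r$a_start, r$a_end)
  flank <- function(st, en) subseq_str(g$sequence, max(0L, st), min(L, en))
  fl <- list(A_left = flank(r$a_start - anchor_bp, r$a_start),
             A_right = flank(r$a_end, r$a_end + anchor_bp),
             B_left = flank(r$b_start - anchor_bp, r$b_start),
             B_right = flank(r$b_end, r$b_end + anchor_bp))
  p_loc <- search_params(min_len_bp = as.integer(0.9 * rep_len),
                         min_identity_percent = 70, min_score = 50L,
                         full_dp_cells = 1e5)
  # locate the repeat inside each read and collect spanning reads
  span <- list()
  for (rd in reads) {
    if (nchar(rd$sequence) < rep_len + 2L * anchor_bp) next
    h <- local_search(repA, rd$sequence, p_loc)
    if (!nrow(h)) next
    h <- h[1, ]
    if (h$q_end - h$q_start < 0.95 * rep_len) next
    sq <- rd$sequence
    s_start <- h$s_start; s_end <- h$s_end
    if (h$strand == "-") {
      sq <- revcomp(sq)
      n <- nchar(rd$sequence)
      s_start <- n - h$s_end; s_end <- n - h$s_start
    }
    # extrapolate to the full repeat boundary in read coordinates
    s_start <- s_start - h$q_start
    s_end <- s_end + (rep_len - h$q_end)
    if (s_start < anchor_bp || nchar(sq) - s_end < anchor_bp) next
    span[[length(span) + 1L]] <- list(seq = sq, s = s_start, e = s_end)
  }
  out$n_spanning_reads <- length(span)
  if (!length(span)) {
    out$flag <- "no_spanning_reads"
    return(out)
  }
  set.seed(seed)
  idx <- if (length(span) > sample_cap) sample(length(span), sample_cap)
         else seq_along(span)
  out$n_sampled <- length(idx)
  lsegs <- vapply(span[idx], function(sp)
    substr(sp$seq, max(1L, sp$s - anchor_bp + 1L), sp$s), "")
  rsegs <- vapply(span[idx], function(sp)
    substr(sp$seq, sp$e + 1L, min(nchar(sp$seq), sp$e + anchor_bp)), "")
  flank_identities <- function(segs, ref) {
    ok <- nchar(segs) >= 20L & nchar(ref) >= 20L
    res <- rep(NA_real_, length(segs))
    if (any(ok)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(segs[ok]), ref, type = "global",
        substitutionMatrix = nucleotide_submat(), gapOpening = 5,
        gapExtension = 2)
      res[ok] <- Biostrings::pid(pa)
    }
    res
  }
  laA <- flank_identities(lsegs, fl$A_left)
  laB <- flank_identities(lsegs, fl$B_left)
  raA <- flank_identities(rsegs, fl$A_right)
  raB <- flank_identities(rsegs, fl$B_right)
  side <- function(ia, ib) {
    ifelse(is.na(ia) | is.na(ib) | abs(ia - ib) < margin_points, NA,
           ifelse(ia > ib, "A", "B"))
  }
  left <- side(laA, laB); right <- side(raA, raB)
  amb <- is.na(left) | is.na(right)
  out$n_ambiguous <- sum(amb)
  out$n_congruent <- sum(!amb & left == right)
  out$n_incongruent <- sum(!amb & left != right)
  denom <- out$n_congruent + out$n_incongruent
  if (denom > 0) out$activity_percent <- 100 * out$n_incongruent / denom
  else out$flag <- "all_reads_ambiguous"
  out
}

#' @export
print.repeat_activity <- function(x, ...) {
  cat(sprintf(
    "<repeat_activity> %s: %d spanning, %d sampled, %d congruent, %d incongruent, %d ambiguous, activity %.1f%%%s\n",
    x$repeat_id, x$n_spanning_reads, x$n_sampled, x$n_congruent,
    x$n_incongruent, x$n_ambiguous,
    ifelse(is.na(x$activity_percent), NaN, x$activity_percent),
    ifelse(is.na(x$flag), "", paste0(" [", x$flag, "]"))))
  invisible(x)
}

nucleotide_submat <- function(match = 2, mismatch = -3) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

#' Tabulate repeat activity over all long repeats
#'
#' Runs [repeat_activity()] for every direct pair in `pairs` and returns a
#' table mirroring the per-repeat activity report (repeat id, length,
#' identity, reads sampled, incongruent fraction).
#'
#' @inheritParams repeat_activity
#' @param pairs Repeat pairs (typically from [long_repeats()]).
#' @return A data frame with one row per assessed repeat.
#' @export
repeat_activity_table <- function(pairs, g, reads, anchor_bp = 100L,
                                  sample_cap = 50L, seed = 1L) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    if (pairs$strand_relation[i] != "direct") next
    ra <- repeat_activity(pairs[i, ], g, reads, anchor_bp = anchor_bp,
                          sample_cap = sample_cap, seed = seed + i)
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_id = pairs$repeat_id[i], length_bp = pairs$length_bp[i],
      identity_percent = pairs$identity_percent[i],
      n_spanning_reads = ra$n_spanning_reads, n_sampled = ra$n_sampled,
      n_congruent = ra$n_congruent, n_incongruent = ra$n_incongruent,
      n_ambiguous = ra$n_ambiguous, activity_percent = ra$activity_percent,
      flag = ifelse(is.na(ra$flag), "", ra$flag), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
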