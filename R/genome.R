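#' Construct a genome object
#'
#' A genome is a named nucleotide sequence over the alphabet A, C, G, T, N,
#' optionally circular, with optional contig boundaries recorded as 0-based
#' positions at which a new contig starts.  All coordinates used internally
#' by the package are 0-based half-open; file readers and writers convert
#' from/to the 1-based inclusive convention.
#'
#' @param id Character scalar, sequence identifier.
#' @param sequence Character scalar, DNA sequence.  Lowercase is uppercased
#'   and U is mapped to T.
#' @param circular Logical, is the molecule circular?
#' @param contig_breaks Integer vector of 0-based positions (strictly
#'   increasing, each `> 0` and `< nchar(sequence)`) where contigs start;
#'   empty for a single contig.
#' @return An object of class `genome`.
#' @export
genome <- function(id, sequence, circular = FALSE, contig_breaks = integer()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome '", id, "' contains characters outside {A,C,G,T,N}")
  }
  contig_breaks <- as.integer(contig_breaks)
  if (length(contig_breaks)) {
    if (is.unsorted(contig_breaks, strictly = TRUE) ||
        any(contig_breaks <= 0L) || any(contig_breaks >= nchar(sequence))) {
      stop("contig_breaks must be strictly increasing, > 0 and < sequence length")
    }
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 contig_breaks = contig_breaks),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %s, %d contig(s)\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              length(x$contig_breaks) + 1L))
  invisible(x)
}

#' @export
length.genome <- function(x) nchar(x$sequence)

as_genome <- function(x, id = "seq") {
  if (inherits(x, "genome")) return(x)
  if (is.character(x) && length(x) == 1L) return(genome(id, x))
  stop("cannot coerce to genome")
}

#' Construct a read record
#'
#' @param id Read identifier.
#' @param sequence DNA sequence.
#' @param qualities Optional integer vector of per-base qualities (same
#'   length as the sequence).
#' @param paired_with Optional id of the mate read.
#' @return An object of class `read_record`.
#' @export
read_record <- function(id, sequence, qualities = NULL, paired_with = NULL) {
  sequence <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  if (!is.null(qualities) && length(qualities) != nchar(sequence)) {
    stop("qualities must have one entry per base")
  }
  structure(list(id = id, sequence = sequence, qualities = qualities,
                 paired_with = paired_with),
            class = "read_record")
}

#' Construct a feature table
#'
#' Features are annotated intervals on a genome, held as a data frame with
#' one row per interval; multi-interval (e.g. trans-spliced) features share a
#' `feature_id`.  Coordinates are 0-based half-open.
#'
#' @param gene Gene (or element) labels, one per interval.
#' @param type Feature types; one of CDS, rRNA, tRNA, exon, intron,
#'   pseudogene, fragment, repeat, other.
#' @param start,end Integer vectors of 0-based half-open interval bounds.
#' @param strand "+" or "-".
#' @param feature_id Grouping id; defaults to one feature per row.
#' @param qualifiers Character vector of `key=value` pairs separated by `;`,
#'   or "".
#' @return A `data.frame` with class `feature_table`.
#' @export
features <- function(gene, type = "other", start, end, strand = "+",
                     feature_id = NULL, qualifiers = "") {
  n <- length(start)
  type <- rep_len(type, n); strand <- rep_len(strand, n)
  gene <- rep_len(gene, n); qualifiers <- rep_len(qualifiers, n)
  if (is.null(feature_id)) feature_id <- paste0(gene, "_", seq_len(n))
  ok_types <- c("CDS", "rRNA", "tRNA", "exon", "intron", "pseudogene",
                "fragment", "repeat", "other")
  if (!all(type %in% ok_types)) {
    stop("unknown feature type: ", paste(setdiff(type, ok_types), collapse = ", "))
  }
  if (any(start >= end)) stop("feature intervals must have start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(feature_id = feature_id, gene = gene, type = type,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, qualifiers = qualifiers,
                   stringsAsFactors = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

empty_features <- function() {
  features(gene = character(), type = character(), start = integer(),
           end = integer(), strand = character(), feature_id = character(),
           qualifiers = character())
}

#' Basic genome statistics
#'
#' GC content is computed over unambiguous bases only: N is excluded from
#' both numerator and denominator.  An all-N sequence yields `gc_percent =
#' NA` with `gc_defined = FALSE` rather than NaN.
#'
#' @param g A [genome].
#' @return A list with `length_bp`, `gc_percent` (rounded to 1 decimal),
#'   `gc_defined` and `n_contigs`.
#' @export
genome_stats <- function(g) {
  g <- as_genome(g)
  counts <- base_counts(g$sequence)
  denom <- sum(counts[c("A", "C", "G", "T")])
  gc <- if (denom > 0) 100 * sum(counts[c("G", "C")]) / denom else NA_real_
  list(length_bp = nchar(g$sequence),
       gc_percent = if (is.na(gc)) NA_real_ else round(gc, 1),
       gc_defined = denom > 0,
       n_contigs = length(g$contig_breaks) + 1L)
}

base_counts <- function(seq) {
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  out <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  out[names(tab)[names(tab) %in% names(out)]] <-
    tab[names(tab) %in% names(out)]
  out
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

subseq_str <- function(seq, start, end) {
  # 0-based half-open extraction
  substr(seq, start + 1L, end)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
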