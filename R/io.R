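#' Read sequences from FASTA or FASTQ
#'
#' Records are returned in file order with sequences uppercased and U mapped
#' to T.  FASTA records become [genome] objects (a `circular` token or a
#' `contig_breaks=` key in the description is honoured, as written by
#' [write_sequences()]); FASTQ records become [read_record] objects with
#' integer Phred qualities.  An empty file yields an empty list.
#'
#' @param path File path.
#' @param format `"fasta"` or `"fastq"`.
#' @return A list of [genome] or [read_record] objects.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0L) return(list())
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) {
                      stop("parse error in FASTA '", path, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
    headers <- names(set)
    out <- vector("list", length(set))
    for (i in seq_along(set)) {
      hd <- headers[i]
      toks <- strsplit(hd, "\\s+")[[1]]
      id <- toks[1]
      circ <- any(toks == "circular")
      cb <- integer()
      cb_tok <- grep("^contig_breaks=", toks, value = TRUE)
      if (length(cb_tok)) {
        cb <- as.integer(strsplit(sub("^contig_breaks=", "", cb_tok[1]),
                                  ",")[[1]])
      }
      out[[i]] <- genome(id, as.character(set[[i]]), circular = circ,
                         contig_breaks = cb)
    }
    out
  } else {
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) {
        stop("parse error in FASTQ '", path, "': ", conditionMessage(e),
             call. = FALSE)
      })
    quals <- S4Vectors::mcols(set)$qualities
    out <- vector("list", length(set))
    for (i in seq_along(set)) {
      qraw <- tryCatch(charToRaw(as.character(quals[[i]])),
                       error = function(e) raw(0))
      if (length(qraw) != length(set[[i]]) ||
          any(qraw < charToRaw("!") | qraw > charToRaw("~"))) {
        stop("parse error in FASTQ '", path, "', record ", i,
             ": quality string malformed or of different length",
             call. = FALSE)
      }
      q <- as.integer(qraw) - 33L
      out[[i]] <- read_record(sub("\\s.*$", "", names(set)[i]),
                              as.character(set[[i]]), qualities = q)
    }
    out
  }
}

#' Write sequences to FASTA or FASTQ
#'
#' The inverse of [read_sequences()]: genome provenance (circularity and
#' contig breaks) is encoded in the FASTA description line so that a
#' read/write round trip reproduces the records.
#'
#' @param x A list of [genome] / [read_record] objects, or a named character
#'   vector of sequences.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @param width Line-wrap width for FASTA.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("fasta", "fastq"),
                            width = 70L) {
  format <- match.arg(format)
  if (is.character(x)) {
    ids <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
    x <- Map(function(id, s) genome(id, s), ids, unname(x))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in x) {
    if (format == "fasta") {
      hd <- rec$id
      if (inherits(rec, "genome")) {
        if (isTRUE(rec$circular)) hd <- paste(hd, "circular")
        if (length(rec$contig_breaks)) {
          hd <- paste0(hd, " contig_breaks=",
                       paste(rec$contig_breaks, collapse = ","))
        }
      }
      writeLines(paste0(">", hd), con)
      s <- rec$sequence
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      q <- rec$qualities
      if (is.null(q)) q <- rep(40L, nchar(rec$sequence))
      writeLines(c(paste0("@", rec$id), rec$sequence, "+",
                   intToUtf8(pmin(q, 93L) + 33L)), con)
    }
  }
  invisible(path)
}

# ---- coordinate conversions ------------------------------------------------

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Internal package coordinates are 0-based half-open; all file formats use
#' 1-based inclusive.  The two functions are mutual inverses.
#'
#' @param start,end Interval bounds in the source convention.
#' @return A list with converted `start` and `end`.
#' @export
coords_to_internal <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname coords_to_internal
#' @export
coords_to_external <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

# ---- feature tables --------------------------------------------------------

#' Read a feature table
#'
#' Two dialects are supported, both with 1-based inclusive coordinates in the
#' file: a tab-separated table with header
#' `seqid gene type start end strand qualifiers`, and a GenBank-style flat
#' file subset (LOCUS / FEATURES / ORIGIN) whose `join()` / `complement()`
#' location strings are decomposed into intervals and strand.  Unknown
#' feature keys are retained with type `other`; labels (including `_frag`
#' suffixes) are preserved verbatim.
#'
#' @param path File path.
#' @param dialect `"feature_tsv"` or `"genbank_flat"`.
#' @param genome_length Optional known genome length; intervals extending
#'   beyond it raise a coordinate error.  For GenBank input the LOCUS length
#'   is used when available.
#' @return A [features] table (0-based half-open coordinates) with attributes
#'   `seqid` and `genome_length`.
#' @export
read_features <- function(path, dialect = c("feature_tsv", "genbank_flat"),
                          genome_length = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "feature_tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("seqid", "gene", "type", "start", "end", "strand", "qualifiers")
    if (!all(need %in% names(df))) {
      stop("feature TSV must have columns: ", paste(need, collapse = ", "))
    }
    df$qualifiers[is.na(df$qualifiers)] <- ""
    fid <- qualifier_get(df$qualifiers, "id")
    fid[is.na(fid)] <- paste0(df$gene[is.na(fid)], "_", which(is.na(fid)))
    conv <- coords_to_internal(df$start, df$end)
    ft <- features(gene = df$gene, type = df$type, start = conv$start,
                   end = conv$end, strand = df$strand, feature_id = fid,
                   qualifiers = df$qualifiers)
    attr(ft, "seqid") <- if (nrow(df)) df$seqid[1] else NA_character_
    attr(ft, "genome_length") <- genome_length
    check_feature_bounds(ft, genome_length, path)
    ft
  } else {
    read_genbank_features(path, genome_length)
  }
}

check_feature_bounds <- function(ft, genome_length, path) {
  if (!is.null(genome_length) && nrow(ft) &&
      any(ft$end > genome_length | ft$start < 0L)) {
    stop("coordinate error in '", path, "': interval outside genome length ",
         genome_length)
  }
  invisible(ft)
}

qualifier_get <- function(quals, key) {
  out <- rep(NA_character_, length(quals))
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(quals, regexec(pat, quals))
  hit <- lengths(m) == 2L
  out[hit] <- vapply(m[hit], `[`, "", 2L)
  out
}

qualifier_set <- function(quals, key, value) {
  add <- paste0(key, "=", value)
  ifelse(quals == "" | is.na(quals), add, paste0(quals, ";", add))
}

#' Write a feature table
#'
#' Writes the tab-separated dialect read by [read_features()], converting to
#' 1-based inclusive coordinates.  Multi-interval features keep their
#' grouping through an `id=` qualifier.
#'
#' @param ft A [features] table.
#' @param path Output path.
#' @param seqid Sequence id column value.
#' @return `path`, invisibly.
#' @export
write_features <- function(ft, path, seqid = attr(ft, "seqid")) {
  if (is.null(seqid) || is.na(seqid)) seqid <- "seq"
  conv <- coords_to_external(ft$start, ft$end)
  quals <- ft$qualifiers
  dup <- ft$feature_id %in% ft$feature_id[duplicated(ft$feature_id)]
  need_id <- dup & is.na(qualifier_get(quals, "id"))
  quals[need_id] <- qualifier_set(quals[need_id], "id", ft$feature_id[need_id])
  out <- data.frame(seqid = seqid, gene = ft$gene, type = ft$type,
                    start = conv$start, end = conv$end, strand = ft$strand,
                    qualifiers = quals, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GenBank flat-file subset ---------------------------------------------

parse_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ivs <- lapply(parts, function(p) {
    st <- "+"
    if (grepl("^complement\\(", p)) {
      st <- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    nums <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (any(is.na(nums)) || nums[1] > nums[2]) {
      stop("cannot parse location: ", loc)
    }
    list(start = nums[1], end = nums[2],
         strand = if (strand == "-") "-" else st)
  })
  ivs
}

read_genbank_features <- function(path, genome_length = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus)) {
    lt <- strsplit(locus[1], "\\s+")[[1]]
    bp_i <- which(lt == "bp")
    if (length(bp_i) && bp_i[1] > 1) {
      gl <- suppressWarnings(as.integer(lt[bp_i[1] - 1]))
      if (!is.na(gl)) genome_length <- gl
    }
  }
  f_start <- grep("^FEATURES", lines)
  if (!length(f_start)) stop("no FEATURES block in '", path, "'")
  f_end <- grep("^(ORIGIN|//)", lines)
  f_end <- if (length(f_end)) min(f_end[f_end > f_start[1]]) else length(lines) + 1L
  block <- lines[(f_start[1] + 1L):(f_end - 1L)]

  recs <- list(); cur <- NULL
  for (ln in block) {
    if (grepl("^ {1,10}\\S", ln) && !grepl("^\\s+/", ln)) {
      # new feature: key starts before column 21
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = toks[1], loc = paste(toks[-1], collapse = ""),
                  quals = character())
    } else if (!is.null(cur)) {
      t <- trimws(ln)
      if (startsWith(t, "/")) cur$quals <- c(cur$quals, t)
      else cur$loc <- paste0(cur$loc, t)  # continued location
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur

  known <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA", exon = "exon",
             intron = "intron", repeat_region = "repeat")
  rows <- list()
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    if (r$key == "source") next
    ivs <- tryCatch(parse_location(r$loc),
                    error = function(e) stop("parse error in '", path,
                                             "' feature ", k, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    qmap <- parse_genbank_qualifiers(r$quals)
    type <- if (r$key %in% names(known)) known[[r$key]] else "other"
    if (!is.null(qmap$pseudo) || r$key == "pseudogene") type <- "pseudogene"
    gene <- qmap$gene %||% qmap$label %||% r$key
    if (endsWith(gene, "_frag") && type == "CDS") type <- "fragment"
    qual_str <- paste(vapply(names(qmap), function(nm)
      paste0(nm, "=", qmap[[nm]]), ""), collapse = ";")
    for (iv in ivs) {
      conv <- coords_to_internal(iv$start, iv$end)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0(gene, "_f", k), gene = gene, type = type,
        start = conv$start, end = conv$end, strand = iv$strand,
        qualifiers = qual_str, stringsAsFactors = FALSE)
    }
    if (length(ivs) > 1L) {
      rows[[length(rows)]]$qualifiers <-
        qualifier_set(rows[[length(rows)]]$qualifiers, "multi_interval", "true")
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(empty_features())
  ft <- features(gene = df$gene, type = df$type, start = df$start,
                 end = df$end, strand = df$strand, feature_id = df$feature_id,
                 qualifiers = df$qualifiers)
  attr(ft, "seqid") <- if (length(locus))
    strsplit(locus[1], "\\s+")[[1]][2] else NA_character_
  attr(ft, "genome_length") <- genome_length
  check_feature_bounds(ft, genome_length, path)
  ft
}

parse_genbank_qualifiers <- function(quals) {
  out <- list()
  for (q in quals) {
    m <- regexec("^/([A-Za-z_]+)(=(.*))?$", q)
    g <- regmatches(q, m)[[1]]
    if (length(g) < 2) next
    key <- g[2]
    val <- if (length(g) >= 4 && nzchar(g[4])) gsub('^"|"$', "", g[4]) else "true"
    out[[key]] <- val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
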