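#' Screen a mitogenome for plastid-derived regions
#'
#' Searches each reference plastome against the mitogenome, removes hits
#' overlapping ribosomal RNA genes or `atp1` (whose plastid counterparts are
#' ancient homologs, not transfers), and merges the remaining hits into
#' regions separated by less than `merge_gap_bp`.
#'
#' @param mito The mitochondrial [genome].
#' @param plastome_refs List of plastome [genome]s.
#' @param mito_features [features] table of the mitogenome annotation (used
#'   for the exclusion rule).
#' @param p [search_params].
#' @param exclude_genes Gene labels excluded in addition to all `rRNA`
#'   features (default `atp1`).
#' @param merge_gap_bp Hits closer than this are merged into one region.
#' @return A list with `hits` (post-exclusion) and `regions` (merged, with
#'   per-region length and identity range).
#' @export
plastid_hit_screen <- function(mito, plastome_refs, mito_features = NULL,
                               p = search_params(min_len_bp = 40L,
                                                 min_identity_percent = 60),
                               exclude_genes = "atp1", merge_gap_bp = 100L) {
  mito <- as_genome(mito)
  hits <- do.call(rbind, lapply(plastome_refs, function(ref)
    local_search(as_genome(ref), mito, p)))
  if (is.null(hits) || !nrow(hits)) {
    return(list(hits = empty_hits(), regions = empty_regions()))
  }
  if (!is.null(mito_features) && nrow(mito_features)) {
    ex <- mito_features[mito_features$type == "rRNA" |
                          mito_features$gene %in% exclude_genes, ,
                        drop = FALSE]
    if (nrow(ex)) {
      bad <- rep(FALSE, nrow(hits))
      for (k in seq_len(nrow(ex))) {
        bad <- bad | (hits$s_start < ex$end[k] & hits$s_end > ex$start[k])
      }
      hits <- hits[!bad, , drop = FALSE]
    }
  }
  if (!nrow(hits)) return(list(hits = hits, regions = empty_regions()))
  hits <- hits[order(hits$s_start), , drop = FALSE]
  grp <- cumsum(c(1L, diff(hits$s_start) > 0 &
                    hits$s_start[-1] - cummax(hits$s_end[-nrow(hits)]) >=
                    merge_gap_bp))
  regions <- do.call(rbind, lapply(split(hits, grp), function(h) {
    data.frame(start = min(h$s_start), end = max(h$s_end),
               length_bp = max(h$s_end) - min(h$s_start),
               identity_min = min(h$identity_percent),
               identity_max = max(h$identity_percent),
               n_hits = nrow(h),
               queries = paste(unique(h$query_id), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  regions$region_id <- paste0("region_", seq_len(nrow(regions)))
  rownames(regions) <- NULL
  list(hits = hits,
       regions = regions[, c("region_id", "start", "end", "length_bp",
                             "identity_min", "identity_max", "n_hits",
                             "queries")])
}

empty_regions <- function() {
  data.frame(region_id = character(), start = integer(), end = integer(),
             length_bp = integer(), identity_min = numeric(),
             identity_max = numeric(), n_hits = integer(),
             queries = character(), stringsAsFactors = FALSE)
}

#' Classify a plastid-hit region by putative origin
#'
#' Decision cascade over four origin categories:
#' \enumerate{
#'   \item `mitogenome` - the region is at least `mito_identity_threshold`
#'     percent identical (over at least 80% of its length) to a related
#'     reference mitogenome, i.e. it is ordinary mitochondrial sequence with
#'     incidental plastome similarity;
#'   \item `homology` - the region overlaps a mitochondrial gene with a
#'     known plastid homolog (ancient similarity, e.g. ribosomal genes,
#'     `atp1`/`atpA`, `nad5`/`ndhF`);
#'   \item `intracellular` - phylogenetic placement groups the region with
#'     the own-lineage plastome;
#'   \item `HGT_candidate` - placement groups it with a distant lineage, or
#'     the matched plastid gene is absent/pseudogenized in the own plastome.
#' }
#' An unresolved placement falls back to the lowest-commitment applicable
#' category (`homology`) with an `unresolved_placement` evidence code; a
#' missing placement withholds the category.
#'
#' @param region One row of the `regions` table from
#'   [plastid_hit_screen()] (or a list with `start`, `end`).
#' @param g The mitochondrial [genome].
#' @param placement Optional `grouping_verdict` for the region from a
#'   plastid phylogeny ([grouping_test()]).
#' @param related_mitos List of related-lineage mitochondrial [genome]s.
#' @param annotations Optional [features] table (gene context).
#' @param matched_plastid_gene Name of the plastid gene the region matches,
#'   if known.
#' @param own_plastome_has_gene Is that gene intact in the own plastome?
#' @param known_homolog_genes Mitochondrial genes with recognized plastid
#'   homologs.
#' @param mito_identity_threshold Identity bound for the `mitogenome`
#'   category (default 98).
#' @param p [search_params] for the related-mitogenome comparison.
#' @return A list of class `transfer_call`: `category`, `evidence`,
#'   `start`, `end`, `length_bp`.
#' @export
classify_transfer <- function(region, g, placement = NULL,
                              related_mitos = list(), annotations = NULL,
                              matched_plastid_gene = NA_character_,
                              own_plastome_has_gene = TRUE,
                              known_homolog_genes = c("nad5", "atp1", "rrn5",
                                                      "rrn18", "rrn26"),
                              mito_identity_threshold = 98,
                              p = search_params(min_len_bp = 50L)) {
  g <- as_genome(g)
  region <- as.list(region)
  seq <- subseq_str(g$sequence, region$start, region$end)
  len <- region$end - region$start
  evidence <- character()
  category <- NA_character_

  # (i) indistinguishable from related mitogenomes
  if (length(related_mitos)) {
    best <- 0
    for (rm in related_mitos) {
      h <- local_search(seq, as_genome(rm), p)
      h <- h[h$q_end - h$q_start >= 0.8 * len, , drop = FALSE]
      if (nrow(h)) best <- max(best, h$identity_percent[1])
    }
    if (best >= mito_identity_threshold) {
      category <- "mitogenome"
      evidence <- c(evidence, sprintf("identity_to_related_mitogenomes=%.1f",
                                      best))
    }
  }
  # (ii) ancient plastid/mitochondrial homology through a gene overlap
  if (is.na(category) && !is.null(annotations) && nrow(annotations)) {
    ov <- annotations[annotations$end > region$start &
                        annotations$start < region$end, , drop = FALSE]
    hom <- intersect(unique(ov$gene), known_homolog_genes)
    if (length(hom)) {
      category <- "homology"
      evidence <- c(evidence, paste0("overlaps_gene=", hom[1]))
    }
  }
  if (is.na(category)) {
    if (is.null(placement)) {
      return(structure(list(category = NA_character_,
                            evidence = "no placement",
                            start = region$start, end = region$end,
                            length_bp = len),
                       class = "transfer_call"))
    }
    if (placement$verdict == "vertical") {
      category <- "intracellular"
      evidence <- c(evidence, sprintf("placement=own_lineage(support=%s)",
                                      placement$sister_support))
    } else if (placement$verdict == "hgt_candidate" ||
               !isTRUE(own_plastome_has_gene)) {
      category <- "HGT_candidate"
      if (placement$verdict == "hgt_candidate") {
        evidence <- c(evidence, sprintf("placement=%s(support=%s)",
                                        placement$sister_clade,
                                        placement$sister_support))
      }
      if (!isTRUE(own_plastome_has_gene)) {
        evidence <- c(evidence, sprintf("gene_missing_from_own_plastome=%s",
                                        matched_plastid_gene))
      }
    } else {
      category <- "homology"
      evidence <- c(evidence, "unresolved_placement")
    }
  }
  structure(list(category = category, evidence = evidence,
                 start = region$start, end = region$end, length_bp = len),
            class = "transfer_call")
}

#' @export
print.transfer_call <- function(x, ...) {
  cat(sprintf("<transfer_call> [%d, %d) %d bp: %s (%s)\n", x$start, x$end,
              x$length_bp, x$category, paste(x$evidence, collapse = "; ")))
  invisible(x)
}

#' Order-level intergenic HGT screen
#'
#' Searches reference mitogenomes, grouped by order, against the focal
#' assembly; hits below 250 bp or 80% identity are removed and the near-top
#' display filter is applied across orders.  Positions covered by the focal
#' order form a mask, and any non-focal hit with at least
#' `min_candidate_bp` contiguous bases outside that mask becomes an HGT
#' candidate tract.
#'
#' @param mito The focal [genome].
#' @param ref_mitos_by_order Named list (order -> [genome] or list of
#'   genomes).
#' @param focal_order Name of the focal order (must be present).
#' @param p [search_params] for the reference searches.
#' @param min_len_bp,min_identity_percent The hit filter (250 bp, 80%).
#' @param min_candidate_bp Contiguous escape length for a candidate (500).
#' @return A list with `tracks` (per-order hit tables after filtering),
#'   `candidates` (tract table with donor order), `candidate_percent`
#'   (cumulative percent of the genome in candidate tracts) and
#'   `focal_coverage_percent`.
#' @export
intergenic_order_screen <- function(mito, ref_mitos_by_order, focal_order,
                                    p = search_params(min_len_bp = 100L,
                                                      min_identity_percent = 70),
                                    min_len_bp = 250L,
                                    min_identity_percent = 80,
                                    min_candidate_bp = 500L) {
  mito <- as_genome(mito)
  stopifnot(focal_order %in% names(ref_mitos_by_order))
  L <- nchar(mito$sequence)
  tracks <- list()
  for (ord in names(ref_mitos_by_order)) {
    refs <- ref_mitos_by_order[[ord]]
    if (inherits(refs, "genome")) refs <- list(refs)
    hits <- do.call(rbind, lapply(refs, function(r)
      local_search(as_genome(r), mito, p)))
    if (is.null(hits)) hits <- empty_hits()
    hits <- filter_hits(hits, min_len_bp, min_identity_percent)
    hits$order <- if (nrow(hits)) ord else character(0)
    tracks[[ord]] <- hits
  }
  all_hits <- do.call(rbind, tracks)
  if (nrow(all_hits)) {
    all_hits <- near_top_filter(all_hits)
  }
  tracks <- split(all_hits, all_hits$order)
  focal_hits <- tracks[[focal_order]]
  if (is.null(focal_hits)) focal_hits <- empty_hits()
  fmask <- interval_union(focal_hits$s_start, focal_hits$s_end)
  cand_rows <- list()
  for (ord in setdiff(names(ref_mitos_by_order), focal_order)) {
    h <- tracks[[ord]]
    if (is.null(h) || !nrow(h)) next
    for (k in seq_len(nrow(h))) {
      esc <- interval_setdiff(h$s_start[k], h$s_end[k],
                              fmask[, "start"], fmask[, "end"])
      esc <- esc[esc[, "end"] - esc[, "start"] >= min_candidate_bp, ,
                 drop = FALSE]
      for (r in seq_len(nrow(esc))) {
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          start = esc[r, "start"], end = esc[r, "end"],
          length_bp = esc[r, "end"] - esc[r, "start"],
          donor_order = ord, identity_percent = h$identity_percent[k],
          ref_id = h$query_id[k], stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(start = integer(), end = integer(), length_bp = integer(),
               donor_order = character(), identity_percent = numeric(),
               ref_id = character(), stringsAsFactors = FALSE)
  cand_pct <- if (nrow(candidates))
    100 * interval_union_width(candidates$start, candidates$end) / L else 0
  focal_pct <- 100 * sum(fmask[, "end"] - fmask[, "start"]) / L
  list(tracks = tracks, candidates = candidates,
       candidate_percent = cand_pct, focal_coverage_percent = focal_pct)
}

#' Search nuclear assemblies for copies of missing mitochondrial genes
#'
#' Per gene, finds the best nuclear locus at or above 50% identity (hits
#' below are ignored), reports the copy length, and assesses whether the
#' copy retains an intact open reading frame: a start codon, no internal
#' stops and no net frameshift.
#'
#' @param missing_genes Named character vector of reference CDS of the
#'   missing genes.
#' @param nuclear_genomes List of nuclear [genome]s (or one genome).
#' @param p [search_params]; identity floor 50%.
#' @return A data frame: `gene`, `found`, `copy_length_bp`,
#'   `identity_percent`, `orf_intact`, `defects`.
#' @export
nuclear_copy_search <- function(missing_genes, nuclear_genomes,
                                p = search_params(min_len_bp = 50L,
                                                  min_identity_percent = 50,
                                                  min_score = 50L)) {
  if (inherits(nuclear_genomes, "genome")) {
    nuclear_genomes <- list(nuclear_genomes)
  }
  rows <- list()
  for (gene in names(missing_genes)) {
    best <- NULL; best_g <- NULL
    for (ng in nuclear_genomes) {
      ng <- as_genome(ng)
      hits <- local_search(genome(gene, missing_genes[[gene]]), ng, p)
      if (nrow(hits) && (is.null(best) || hits$score[1] > best$score[1])) {
        best <- hits; best_g <- ng
      }
    }
    if (is.null(best)) {
      rows[[gene]] <- data.frame(gene = gene, found = FALSE,
                                 copy_length_bp = 0L,
                                 identity_percent = NA_real_,
                                 orf_intact = NA, defects = "",
                                 stringsAsFactors = FALSE)
      next
    }
    loci <- chain_gene_hits(best)
    loci <- extrapolate_loci(loci, nchar(missing_genes[[gene]]),
                             nchar(best_g$sequence))
    model <- new_gene_model(gene, loci, "intact",
                            sum(loci$end - loci$start))
    model <- call_pseudogene(model, best_g)
    cds <- extract_model_cds(model, best_g)
    has_start <- startsWith(cds, "ATG")
    defects <- names(model$defects)
    if (!has_start) defects <- c(defects, "no_start_codon")
    rows[[gene]] <- data.frame(
      gene = gene, found = TRUE,
      copy_length_bp = sum(loci$end - loci$start),
      identity_percent = best$identity_percent[1],
      orf_intact = length(defects) == 0L,
      defects = paste(defects, collapse = ","), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative nuclear coverage of the mitogenome
#'
#' Fraction of the mitochondrial assembly covered by nuclear-genome hits
#' after the 250 bp / 80% identity filter.
#'
#' @param nuclear_genomes List of nuclear [genome]s.
#' @param mito The mitochondrial [genome].
#' @param p [search_params].
#' @param min_len_bp,min_identity_percent The hit filter.
#' @return Coverage fraction in `[0, 1]`.
#' @export
nuclear_mito_coverage <- function(nuclear_genomes, mito,
                                  p = search_params(min_len_bp = 100L,
                                                    min_identity_percent = 70),
                                  min_len_bp = 250L,
                                  min_identity_percent = 80) {
  mito <- as_genome(mito)
  if (inherits(nuclear_genomes, "genome")) {
    nuclear_genomes <- list(nuclear_genomes)
  }
  hits <- do.call(rbind, lapply(nuclear_genomes, function(ng)
    local_search(as_genome(ng), mito, p)))
  if (is.null(hits)) hits <- empty_hits()
  hits <- filter_hits(hits, min_len_bp, min_identity_percent)
  coverage_fraction(hits, mito)
}
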