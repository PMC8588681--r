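#' Pipeline run configuration
#'
#' Bundles the inputs and thresholds of a full interrogation run.  Inputs
#' may be in-memory objects or file paths (FASTA/FASTQ, read with
#' [read_sequences()]).  Threshold defaults follow the package-wide
#' conventions: 50 bp / 90% identity for dispersed repeats, 250 bp / 80% for
#' the order-level screens, > 500 bp / > 90% for long repeats, a 50-read
#' sampling cap for the recombination proxy, > 80% bootstrap support for the
#' grouping test, 0.5 for edit-site prediction, 50% column masking and a 50%
#' identity floor for nuclear gene searches.
#'
#' @param genome Recipient [genome] or FASTA path.
#' @param ref_cds Named character vector of reference CDS, or FASTA path.
#' @param ref_mitos_by_order Named list (order -> genome(s)) for the
#'   intergenic screen; empty to skip.
#' @param plastome_refs List of plastome genomes; empty to skip.
#' @param long_reads List of [read_record]s or FASTQ path; empty to skip.
#' @param transcript_reads List of paired [read_record]s or FASTQ path.
#' @param nuclear Optional nuclear [genome] (or list).
#' @param panel_genes Optional list gene -> named vector of panel CDS for
#'   the phylogenetic stage.
#' @param focal_order Focal order name (required when
#'   `ref_mitos_by_order` is non-empty).
#' @param focal_taxa,expected_sister,groups,outgroup Grouping-test inputs
#'   (see [grouping_test()]); the recipient's sequences are added to the
#'   panel under the taxon name `recipient`.
#' @param seed Root seed for all stochastic stages.
#' @param out_dir Run directory (created).
#' @param thresholds Named list overriding individual defaults.
#' @param n_boot Bootstrap replicates for gene trees.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome, ref_cds, ref_mitos_by_order = list(),
                       plastome_refs = list(), long_reads = list(),
                       transcript_reads = list(), nuclear = NULL,
                       panel_genes = NULL, focal_order = NULL,
                       focal_taxa = "recipient", expected_sister = NULL,
                       groups = list(), outgroup = NULL, seed = 1L,
                       out_dir = tempfile("mitoscreen_run_"),
                       thresholds = list(), n_boot = 200L) {
  defaults <- list(repeat_min_len = 50L, repeat_min_identity = 90,
                   screen_min_len = 250L, screen_min_identity = 80,
                   long_repeat_min_len = 500L, long_repeat_min_identity = 90,
                   sample_cap = 50L, anchor_bp = 100L,
                   support_threshold = 80, edit_min_score = 0.5,
                   max_missing = 0.5, nuclear_min_identity = 50,
                   min_candidate_bp = 500L)
  thresholds <- utils::modifyList(defaults, thresholds)
  if (length(ref_mitos_by_order) && is.null(focal_order)) {
    stop("config error: focal_order is required for the order-level screen")
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_sequences(genome, "fasta")[[1]]
  }
  if (is.character(ref_cds) && length(ref_cds) == 1L && file.exists(ref_cds)) {
    recs <- read_sequences(ref_cds, "fasta")
    ref_cds <- stats::setNames(vapply(recs, `[[`, "", "sequence"),
                               vapply(recs, `[[`, "", "id"))
  }
  if (is.character(long_reads) && length(long_reads) == 1L) {
    long_reads <- read_sequences(long_reads, "fastq")
  }
  if (is.character(transcript_reads) && length(transcript_reads) == 1L) {
    transcript_reads <- read_sequences(transcript_reads, "fastq")
  }
  structure(list(genome = as_genome(genome), ref_cds = ref_cds,
                 ref_mitos_by_order = ref_mitos_by_order,
                 plastome_refs = plastome_refs, long_reads = long_reads,
                 transcript_reads = transcript_reads, nuclear = nuclear,
                 panel_genes = panel_genes, focal_order = focal_order,
                 focal_taxa = focal_taxa, expected_sister = expected_sister,
                 groups = groups, outgroup = outgroup,
                 seed = as.integer(seed), out_dir = out_dir,
                 thresholds = thresholds, n_boot = as.integer(n_boot)),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[setdiff(names(cfg), "out_dir")], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

stage_done <- function(dir, stage, hash) {
  writeLines(hash, file.path(dir, paste0(stage, ".hash")))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

models_to_features <- function(models) {
  rows <- list()
  for (m in models) {
    if (!nrow(m$exon_loci)) next
    type <- switch(m$completeness, pseudogene = "pseudogene",
                   fragmented = "fragment", "CDS")
    for (i in seq_len(nrow(m$exon_loci))) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = paste0(m$gene, "_m"), gene = m$gene, type = type,
        start = m$exon_loci$start[i], end = m$exon_loci$end[i],
        strand = m$exon_loci$strand[i],
        qualifiers = paste0("completeness=", m$completeness),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_features())
  df <- do.call(rbind, rows)
  features(gene = df$gene, type = df$type, start = df$start, end = df$end,
           strand = df$strand, feature_id = df$feature_id,
           qualifiers = df$qualifiers)
}

#' Run the interrogation pipeline
#'
#' Executes the stages in dependency order - annotate, repeats,
#' recombination, transfer screens, phylogenetics, editing - writing every
#' stage artifact as TSV into the run directory, each stamped with the
#' config hash and seed.  Runs are fully deterministic under a fixed config
#' and seed: a rerun reproduces every artifact byte-identically, so cached
#' outputs can be compared or reused by hash.  A stage failure halts the run
#' with the completed stage outputs intact.
#'
#' @param cfg A [run_config].
#' @return The run directory path, invisibly; stage results are also
#'   returned in attribute `results`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  writeLines(c(paste0("config_hash\t", hash), paste0("seed\t", cfg$seed)),
             file.path(cfg$out_dir, "provenance.tsv"))
  th <- cfg$thresholds
  res <- list()

  # ---- annotate ----
  models <- lapply(annotate_genome(cfg$genome, cfg$ref_cds), function(m)
    call_pseudogene(m, cfg$genome))
  gene_tab <- do.call(rbind, lapply(models, function(m) data.frame(
    gene = m$gene, completeness = m$completeness,
    coding_length = m$coding_length, n_pieces = nrow(m$exon_loci),
    flags = paste(m$flags, collapse = ","), stringsAsFactors = FALSE)))
  write_tsv(gene_tab, file.path(cfg$out_dir, "genes.tsv"))
  feats <- models_to_features(models)
  write_features(feats, file.path(cfg$out_dir, "features.tsv"),
                 seqid = cfg$genome$id)
  res$models <- models

  # ---- repeats ----
  pairs <- dispersed_repeats(cfg$genome,
                             search_params(min_len_bp = th$repeat_min_len,
                                           min_identity_percent =
                                             th$repeat_min_identity))
  write_tsv(pairs, file.path(cfg$out_dir, "repeats.tsv"))
  tand <- tandem_repeats(cfg$genome)
  write_tsv(as.data.frame(tand), file.path(cfg$out_dir, "tandem.tsv"))
  longs <- long_repeats(pairs, th$long_repeat_min_len,
                        th$long_repeat_min_identity)
  stats <- genome_stats(cfg$genome)
  tand_bp <- if (nrow(tand)) interval_union_width(tand$start, tand$end) else 0
  write_tsv(data.frame(length_bp = stats$length_bp,
                       gc_percent = stats$gc_percent,
                       n_contigs = stats$n_contigs,
                       repeat_content_percent = repeat_content(pairs,
                                                               cfg$genome),
                       tandem_percent = 100 * tand_bp / stats$length_bp),
            file.path(cfg$out_dir, "genome_stats.tsv"))
  res$repeats <- pairs; res$long_repeats <- longs

  # ---- recombination ----
  if (length(cfg$long_reads) && nrow(longs)) {
    act <- repeat_activity_table(longs, cfg$genome, cfg$long_reads,
                                 anchor_bp = th$anchor_bp,
                                 sample_cap = th$sample_cap, seed = cfg$seed)
    write_tsv(act, file.path(cfg$out_dir, "activity.tsv"))
    res$activity <- act
  }

  # ---- transfer screens ----
  if (length(cfg$plastome_refs)) {
    ps <- plastid_hit_screen(cfg$genome, cfg$plastome_refs, feats)
    write_tsv(ps$regions, file.path(cfg$out_dir, "plastid_regions.tsv"))
    res$plastid <- ps
  }
  if (length(cfg$ref_mitos_by_order)) {
    sc <- intergenic_order_screen(cfg$genome, cfg$ref_mitos_by_order,
                                  cfg$focal_order,
                                  min_len_bp = th$screen_min_len,
                                  min_identity_percent =
                                    th$screen_min_identity,
                                  min_candidate_bp = th$min_candidate_bp)
    write_tsv(sc$candidates, file.path(cfg$out_dir, "hgt_candidates.tsv"))
    res$order_screen <- sc
  }
  if (!is.null(cfg$nuclear)) {
    missing <- names(cfg$ref_cds)[vapply(models, function(m)
      m$completeness %in% c("absent", "pseudogene"), TRUE)]
    if (length(missing)) {
      nuc <- nuclear_copy_search(cfg$ref_cds[missing], cfg$nuclear,
                                 search_params(min_len_bp = 50L,
                                               min_identity_percent =
                                                 th$nuclear_min_identity))
      write_tsv(nuc, file.path(cfg$out_dir, "nuclear_copies.tsv"))
      res$nuclear <- nuc
    }
  }

  # ---- phylogenetics ----
  if (!is.null(cfg$panel_genes)) {
    verdicts <- list()
    for (gene in names(cfg$panel_genes)) {
      m <- models[[gene]]
      if (is.null(m) || m$completeness == "absent") next
      seqs <- c(stats::setNames(extract_model_cds(m, cfg$genome),
                                "recipient"),
                cfg$panel_genes[[gene]])
      msa <- tryCatch(suppressWarnings(protein_guided_align(seqs)),
                      error = function(e) NULL)
      if (is.null(msa) || !"recipient" %in% rownames(msa)) next
      msa <- mask_columns(msa, th$max_missing)
      tree <- bootstrap_support(msa, n_reps = cfg$n_boot,
                                seed = cfg$seed + match(gene,
                                                        names(cfg$panel_genes)))
      gv <- grouping_test(tree, intersect(cfg$focal_taxa, rownames(msa)),
                          cfg$expected_sister, cfg$groups,
                          threshold = th$support_threshold,
                          outgroup = cfg$outgroup)
      verdicts[[gene]] <- data.frame(
        gene = gene, verdict = gv$verdict,
        focal_monophyly_support = gv$focal_monophyly_support,
        sister_clade = gv$sister_clade, sister_support = gv$sister_support,
        stringsAsFactors = FALSE)
      ape::write.tree(tree, file.path(cfg$out_dir,
                                      paste0("tree_", gene, ".nwk")))
    }
    if (length(verdicts)) {
      vt <- do.call(rbind, verdicts)
      write_tsv(vt, file.path(cfg$out_dir, "verdicts.tsv"))
      res$verdicts <- vt
    }
  }

  # ---- editing evidence ----
  if (length(cfg$transcript_reads)) {
    ed_rows <- list()
    for (gene in names(models)) {
      m <- models[[gene]]
      if (m$completeness != "intact") next
      obs <- observe_edit_sites(cfg$genome, m, cfg$transcript_reads)
      if (!is.null(cfg$panel_genes) && gene %in% names(cfg$panel_genes)) {
        homs <- vapply(cfg$panel_genes[[gene]], function(s) {
          aa <- translate_str(s); sub("\\*$", "", aa)
        }, "")
        pred <- predict_edit_sites(extract_model_cds(m, cfg$genome), homs,
                                   th$edit_min_score)
        merged <- merge_edit_sites(pred, obs)
      } else {
        merged <- obs
      }
      if (nrow(merged)) {
        merged$gene <- gene
        ed_rows[[gene]] <- merged
      }
    }
    if (length(ed_rows)) {
      et <- do.call(rbind, lapply(ed_rows, function(d)
        d[, c("gene", "cds_pos", "codon_pos",
              intersect(c("predicted_score", "observed_fraction", "status"),
                        names(d)))]))
      write_tsv(et, file.path(cfg$out_dir, "edit_sites.tsv"))
      res$edits <- et
    }
  }

  stage_done(cfg$out_dir, "run", hash)
  out <- cfg$out_dir
  attr(out, "results") <- res
  invisible(out)
}

#' Assemble report tables from a run directory
#'
#' Regenerates the human-facing report from the stage TSVs alone: genome
#' statistics, gene content (coding lengths with a `(pseudo)` marker),
#' repeat and recombination-activity tables, transfer candidates and
#' per-gene grouping verdicts.  Sections whose stage did not run are marked
#' `not run`.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Path of the written `report.txt`, invisibly; the tables are
#'   returned in attribute `tables`.
#' @export
make_report <- function(run_dir) {
  rd <- function(name) {
    f <- file.path(run_dir, name)
    if (!file.exists(f)) return(NULL)
    utils::read.delim(f, stringsAsFactors = FALSE)
  }
  tables <- list(genome = rd("genome_stats.tsv"), genes = rd("genes.tsv"),
                 repeats = rd("repeats.tsv"), activity = rd("activity.tsv"),
                 plastid = rd("plastid_regions.tsv"),
                 hgt = rd("hgt_candidates.tsv"),
                 nuclear = rd("nuclear_copies.tsv"),
                 verdicts = rd("verdicts.tsv"), edits = rd("edit_sites.tsv"))
  if (!is.null(tables$genes)) {
    tables$genes$display_length <- ifelse(
      tables$genes$completeness == "pseudogene",
      paste0(tables$genes$coding_length, " (pseudo)"),
      ifelse(tables$genes$completeness == "absent", "-",
             as.character(tables$genes$coding_length)))
  }
  lines <- character()
  emit <- function(title, df, cols = NULL) {
    lines <<- c(lines, paste0("== ", title, " =="))
    if (is.null(df) || !nrow(df)) {
      lines <<- c(lines, if (is.null(df)) "not run" else "none", "")
      return(invisible())
    }
    if (!is.null(cols)) df <- df[, intersect(cols, names(df)), drop = FALSE]
    txt <- utils::capture.output(print(df, row.names = FALSE))
    lines <<- c(lines, txt, "")
  }
  emit("Genome", tables$genome)
  emit("Gene content", tables$genes,
       c("gene", "display_length", "completeness", "n_pieces"))
  emit("Dispersed repeats", tables$repeats)
  emit("Recombinational activity", tables$activity)
  emit("Plastid-derived regions", tables$plastid)
  emit("HGT candidate tracts", tables$hgt)
  emit("Nuclear copies of missing genes", tables$nuclear)
  emit("Grouping verdicts", tables$verdicts)
  emit("RNA editing sites", tables$edits)
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(structure(out, tables = tables))
}
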