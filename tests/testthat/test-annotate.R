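test_that("ORF finding handles minimal and empty cases", {
  orfs <- find_orfs(genome("g", "ATGAAATAA"), min_aa = 1L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(c(orfs$start, orfs$end), c(0L, 9L))
  s <- substr(genome("g", "ATGAAATAA")$sequence, 1, 6)
  expect_equal(mitoscreen:::translate_str(s), "MK")
  # no ATG anywhere -> no ORFs
  expect_equal(nrow(find_orfs(genome("g", strrep("C", 300)), 1L)), 0L)
})

test_that("ORFs match a brute-force frame enumeration on random sequence", {
  set.seed(3)
  g <- rnd_dna(5000)
  got <- find_orfs(genome("g", g), min_aa = 25L)
  # independent oracle: walk each frame/strand explicitly
  oracle <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g else rc(g)
    for (f in 0:2) {
      i <- f + 1L
      open_at <- NA
      while (i + 2 <= nchar(s)) {
        cod <- substr(s, i, i + 2)
        if (is.na(open_at) && cod == "ATG") open_at <- i
        if (!is.na(open_at) && cod %in% c("TAA", "TAG", "TGA")) {
          n_aa <- (i - open_at) / 3
          if (n_aa >= 25) {
            a <- open_at - 1L; b <- i + 2L
            if (strand == "-") { t <- a; a <- nchar(s) - b; b <- nchar(s) - t }
            oracle[[length(oracle) + 1L]] <- c(a, b)
          }
          open_at <- NA
        }
        i <- i + 3L
      }
    }
  }
  want <- unique(do.call(rbind, oracle))
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start, unname(want[, 1]))
  expect_equal(got$end, unname(want[, 2]))
})

test_that("annotation recovers planted genes with name, strand and length", {
  b <- small_bundle(seed = 31)
  ref <- panel_ref_cds(b$panel)
  models <- annotate_genome(b$rec$genome, ref)
  tr <- b$rec$truth$genes
  for (i in seq_len(nrow(tr))) {
    m <- models[[tr$gene[i]]]
    expect_equal(m$completeness, "intact")
    expect_equal(m$exon_loci$strand[1], tr$strand[i])
    expect_equal(m$coding_length, tr$end[i] - tr$start[i])
    expect_equal(c(m$exon_loci$start[1], m$exon_loci$end[1]),
                 c(tr$start[i], tr$end[i]))
  }
})

test_that("a gene absent from the genome is called absent", {
  b <- small_bundle(seed = 33, missing_genes = "mtgene6")
  ref <- panel_ref_cds(b$panel)
  models <- annotate_genome(b$rec$genome, ref)
  expect_equal(models[["mtgene6"]]$completeness, "absent")
  expect_equal(models[["mtgene6"]]$coding_length, 0L)
})

test_that("a gene crossing a simulated contig break is fragmented", {
  b <- small_bundle(seed = 35)
  ref <- panel_ref_cds(b$panel)
  tr <- b$rec$truth$genes[1, ]
  brk <- as.integer((tr$start + tr$end) %/% 2)
  g2 <- genome(b$rec$genome$id, b$rec$genome$sequence,
               contig_breaks = brk)
  models <- annotate_genome(g2, ref[tr$gene])
  expect_equal(models[[tr$gene]]$completeness, "fragmented")
})

test_that("pseudogene calls fire on frameshifts and internal stops only", {
  b <- small_bundle(seed = 37)
  ref <- panel_ref_cds(b$panel)
  g <- b$rec$genome
  tr <- b$rec$truth$genes
  # intact planted CDS: unchanged across all genes
  models <- annotate_genome(g, ref)
  for (gene in tr$gene) {
    m <- call_pseudogene(models[[gene]], g)
    expect_equal(m$completeness, "intact")
  }
  # single inserted base -> frameshift
  row <- tr[tr$strand == "+", ][1, ]
  s <- g$sequence
  ins_at <- row$start + 150L
  s2 <- paste0(substr(s, 1, ins_at), "A", substr(s, ins_at + 1, nchar(s)))
  g2 <- genome("g2", s2)
  m2 <- call_pseudogene(annotate_genome(g2, ref[row$gene])[[1]], g2)
  expect_equal(m2$completeness, "pseudogene")
  expect_true("frameshift" %in% names(m2$defects))
  # TAA at codon 20 -> internal stop
  s3 <- s
  cod20 <- row$start + 3L * 19L
  substr(s3, cod20 + 1L, cod20 + 3L) <- "TAA"
  g3 <- genome("g3", s3)
  m3 <- call_pseudogene(annotate_genome(g3, ref[row$gene])[[1]], g3)
  expect_equal(m3$completeness, "pseudogene")
  expect_true("internal_stops" %in% names(m3$defects))
  expect_true(20L %in% m3$defects$internal_stops)
})

test_that("pseudogene calls never fire on intact plants across seeds", {
  for (seed in 101:110) {
    b <- small_bundle(seed = seed, n_genes = 4L)
    ref <- panel_ref_cds(b$panel)
    models <- annotate_genome(b$rec$genome, ref)
    for (gene in b$rec$truth$genes$gene) {
      m <- call_pseudogene(models[[gene]], b$rec$genome)
      expect_equal(m$completeness, "intact")
    }
  }
})

test_that("a three-locus trans-spliced layout is detected with its split exon", {
  b <- small_bundle(seed = 41, transsplice_gene = "mtgene2")
  ref <- panel_ref_cds(b$panel)
  ts <- b$rec$truth$transsplice
  # intron position on the intron-less reference: the exon1b/exon2 boundary
  intron_pos <- sum(ts$end[ts$piece != "exon2"] - ts$start[ts$piece != "exon2"])
  m <- detect_split_gene("mtgene2", ref[["mtgene2"]], b$rec$genome,
                         intron_ref_pos = intron_pos)
  expect_equal(nrow(m$exon_loci), 3L)
  expect_equal(m$intron_layout, c("trans", "trans"))
  expect_equal(m$flags, "split_exon_junction_1")
})

test_that("a cis intron within the separation window is classified cis", {
  set.seed(43)
  cds <- mitoscreen:::random_cds(600L)
  exon1 <- substr(cds, 1, 300); exon2 <- substr(cds, 301, 600)
  g <- genome("g", paste0(rnd_dna(1500), exon1, rnd_dna(800), exon2,
                          rnd_dna(1500)))
  m <- detect_split_gene("x", cds, g)
  expect_equal(nrow(m$exon_loci), 2L)
  expect_equal(m$intron_layout, "cis")
  expect_equal(m$completeness, "intact")
})

test_that("a reverse-oriented nearby exon forces a trans call", {
  set.seed(45)
  cds <- mitoscreen:::random_cds(600L)
  exon4 <- substr(cds, 1, 400); exon5 <- substr(cds, 401, 600)
  g <- genome("g", paste0(rnd_dna(1500), exon4, rnd_dna(500), rc(exon5),
                          rnd_dna(1500)))
  m <- detect_split_gene("nad1_like", cds, g)
  expect_equal(nrow(m$exon_loci), 2L)
  expect_equal(m$intron_layout, "trans")
  expect_equal(sort(m$exon_loci$strand), c("+", "-"))
})

test_that("junction support counts pairs across the trans-spliced junction only", {
  cfg <- sim_config(seed = 47, transsplice_gene = "mtgene2",
                    genome_length_bp = 20000L, n_genes = 3L,
                    transcript_coverage = 25)
  panel <- simulate_reference_set(cfg)
  rec <- build_recipient_genome(cfg, panel)
  tx <- simulate_transcript_reads(rec$genome, rec$truth, cfg)
  ref <- panel_ref_cds(panel)
  m <- detect_split_gene("mtgene2", ref[["mtgene2"]], rec$genome)
  js <- junction_support(m, rec$genome, tx$reads)
  j12 <- js[js$piece_a == 1 & js$piece_b == 2, ]
  j23 <- js[js$piece_a == 2 & js$piece_b == 3, ]
  expect_gte(j23$n_pairs + j23$n_split_reads, 1L)   # exon1b <-> exon2 joined
  expect_equal(j12$n_pairs, 0L)                     # exon1a never joined
  expect_equal(j12$n_split_reads, 0L)
  expect_false(attr(js, "low_coverage"))
  # shuffled read sequences are a negative control
  set.seed(5)
  shuf <- lapply(tx$reads[1:60], function(r) {
    read_record(r$id, paste(sample(strsplit(r$sequence, "")[[1]]),
                            collapse = ""), paired_with = r$paired_with)
  })
  js0 <- junction_support(m, rec$genome, shuf)
  expect_true(all(js0$n_pairs == 0L))
  expect_true(all(js0$n_split_reads == 0L))
})

test_that("zero-coverage junction support is flagged", {
  b <- small_bundle(seed = 49, transsplice_gene = "mtgene2")
  ref <- panel_ref_cds(b$panel)
  m <- detect_split_gene("mtgene2", ref[["mtgene2"]], b$rec$genome)
  reads <- lapply(1:10, function(i) read_record(paste0("x", i), rnd_dna(150)))
  js <- junction_support(m, b$rec$genome, reads)
  expect_true(all(js$n_pairs == 0L))
  expect_true(attr(js, "low_coverage"))
})

test_that("the conservation scorer follows the forced-prediction rule", {
  # focal codon CCT (Pro); edit at codon position 2 gives CTT (Leu);
  # all 10 homologs have Leu -> score 1.0, predicted
  focal <- "ATGCCTAAGGAA"        # M P K E
  homs <- setNames(rep("MLKE", 10), paste0("h", 1:10))
  pred <- predict_edit_sites(focal, homs)
  expect_true(4L %in% pred$cds_pos)    # 0-based position of the edited C
  expect_equal(pred$predicted_score[pred$cds_pos == 4L], 1.0)
  expect_equal(pred$codon_pos[pred$cds_pos == 4L], 2L)
  # focal codon already matching the consensus is not predicted
  focal2 <- "ATGCTTAAGGAA"       # M L K E (already Leu)
  pred2 <- predict_edit_sites(focal2, homs)
  expect_false(any(pred2$codon_pos[pred2$cds_pos %in% c(3, 4, 5)] == 2))
})

test_that("planted edit sites are recovered by prediction and observation", {
  cfg <- sim_config(seed = 13, n_edit_sites = 20L, edit_gene = "mtgene1",
                    genome_length_bp = 20000L, n_genes = 4L)
  panel <- simulate_reference_set(cfg)
  rec <- build_recipient_genome(cfg, panel)
  ref <- panel_ref_cds(panel)
  m <- annotate_genome(rec$genome, ref["mtgene1"])[[1]]
  cds <- mitoscreen:::extract_model_cds(m, rec$genome)
  others <- setdiff(names(panel$genes[["mtgene1"]]), taxon1("Order_1"))
  homs <- vapply(panel$genes[["mtgene1"]][others], function(s)
    sub("\\*$", "", mitoscreen:::translate_str(s)), "")
  pred <- predict_edit_sites(cds, homs)
  truth <- rec$truth$edits$cds_pos
  expect_gte(mean(truth %in% pred$cds_pos), 0.8)   # recall
  # observation from transcript reads
  tx <- simulate_transcript_reads(rec$genome, rec$truth, cfg)
  obs <- observe_edit_sites(rec$genome, m, tx$reads)
  expect_gte(mean(truth %in% obs$cds_pos), 0.8)     # recall
  expect_lte(length(setdiff(obs$cds_pos, truth)), 1L)
  # every truth site the reads actually cover at depth is observed: missed
  # sites must be explainable by coverage alone, not by the caller
  lax <- observe_edit_sites(rec$genome, m, tx$reads, min_cov = 1L,
                            min_fraction = 0.5)
  covered <- lax$cds_pos[lax$coverage >= 5L]
  expect_true(all(intersect(truth, covered) %in% obs$cds_pos))
  merged <- merge_edit_sites(pred, obs)
  expect_true(all(merged$status %in%
                    c("both", "predicted_only", "observed_only")))
  expect_gte(sum(merged$status == "both"), 0.7 * length(truth))
})

test_that("low-fraction mismatches are not called as observed edits", {
  set.seed(51)
  cds <- mitoscreen:::random_cds(300L)
  g <- genome("g", paste0(rnd_dna(500), cds, rnd_dna(500)))
  m <- annotate_genome(g, c(x = cds))[[1]]
  cpos <- which(strsplit(cds, "")[[1]] == "C")[5]
  mk_read <- function(i, edited) {
    s <- substr(cds, max(1, cpos - 70), min(nchar(cds), cpos + 70))
    if (edited) substr(s, cpos - max(1, cpos - 70) + 1,
                       cpos - max(1, cpos - 70) + 1) <- "T"
    read_record(paste0("r", i), s)
  }
  reads_hi <- lapply(1:10, mk_read, edited = TRUE)
  obs_hi <- observe_edit_sites(g, m, reads_hi)
  expect_true((cpos - 1L) %in% obs_hi$cds_pos)   # 10/10 reads show T
  reads_lo <- c(lapply(1:2, mk_read, edited = TRUE),
                lapply(3:10, mk_read, edited = FALSE))
  obs_lo <- observe_edit_sites(g, m, reads_lo)
  expect_false((cpos - 1L) %in% obs_lo$cds_pos)  # 2/10 below threshold
})
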