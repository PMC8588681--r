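test_that("zero substitution rate leaves all panel taxa identical to the root", {
  cfg <- sim_config(seed = 1, subst_rate_per_branch = 0, n_genes = 2L)
  panel <- simulate_reference_set(cfg)
  for (gene in names(panel$genes)) {
    expect_true(all(panel$genes[[gene]] == panel$root_genes[[gene]]))
  }
})

test_that("the panel tree has the configured order-labeled leaves", {
  cfg <- sim_config(seed = 1, n_orders = 5L, taxa_per_order = 2L)
  panel <- simulate_reference_set(cfg)
  tips <- panel$tree$tip.label
  ingroup <- grep("^Order_", tips, value = TRUE)
  expect_length(ingroup, 10L)
  expect_true(all(grepl("^Order_[0-9]+\\|taxon_[0-9]+$", ingroup)))
  expect_true(any(grepl("^Outgroup", tips)))
})

test_that("pairwise differences follow the Jukes-Cantor expectation", {
  # direct closed-form check of the substitution engine at branch length 2r
  set.seed(1)
  L <- 9999L
  root <- rnd_dna(L)
  for (r in c(0.02, 0.05)) {
    mut <- mitoscreen:::jc_mutate(mitoscreen:::jc_mutate(root, r), r)
    p_hat <- 1 - hamming_identity(root, mut) / 100
    p_exp <- 0.75 * (1 - exp(-4 / 3 * 2 * r))
    se <- sqrt(p_exp * (1 - p_exp) / L)
    expect_lt(abs(p_hat - p_exp), 3 * se)
  }
})

test_that("panel divergence is monotone in path length", {
  cfg <- sim_config(seed = 3, n_orders = 4L, taxa_per_order = 2L,
                    subst_rate_per_branch = 0.05, n_genes = 1L)
  panel <- simulate_reference_set(cfg)
  g <- panel$genes[[1]]
  d_within <- 100 - hamming_identity(g[["Order_1|taxon_1"]],
                                     g[["Order_1|taxon_2"]])
  d_between <- 100 - hamming_identity(g[["Order_1|taxon_1"]],
                                      g[["Order_4|taxon_1"]])
  d_out <- 100 - hamming_identity(g[["Order_1|taxon_1"]],
                                  g[["Outgroup|taxon_1"]])
  expect_lt(d_within, d_between)
  expect_lt(d_between, d_out)
})

test_that("planted repeats are recorded in the truth set at target identity", {
  b <- small_bundle(seed = 7, repeat_spec = list(
    list(length_bp = 1000L, identity_percent = 100, n_copies = 2L)))
  tr <- b$rec$truth$repeats
  expect_equal(nrow(tr), 2L)
  expect_true(all(tr$end - tr$start == 1000L))
  s <- b$rec$genome$sequence
  c1 <- substr(s, tr$start[1] + 1, tr$end[1])
  c2 <- substr(s, tr$start[2] + 1, tr$end[2])
  expect_equal(c1, c2)          # 100% identity plant is an exact copy
  # diverged plant hits its identity target within half a point
  b2 <- small_bundle(seed = 8, repeat_spec = list(
    list(length_bp = 800L, identity_percent = 93, n_copies = 2L)))
  tr2 <- b2$rec$truth$repeats
  s2 <- b2$rec$genome$sequence
  id <- hamming_identity(substr(s2, tr2$start[1] + 1, tr2$end[1]),
                         substr(s2, tr2$start[2] + 1, tr2$end[2]))
  expect_lt(abs(id - 93), 0.5)
})

test_that("every truth interval is recoverable from the emitted sequence", {
  b <- small_bundle(seed = 9,
                    hgt_spec = list(list(donor_order = "Order_3",
                                         length_bp = 700L)),
                    mtpt_spec = list(list(donor = "self_plastome",
                                          length_bp = 400L)))
  s <- b$rec$genome$sequence
  tr <- b$rec$truth
  # HGT tract is a verbatim substring of the donor reference and nothing else
  tract <- substr(s, tr$hgt$start + 1, tr$hgt$end)
  expect_true(grepl(tract, b$rec$references[["Order_3"]]$sequence,
                    fixed = TRUE))
  expect_false(grepl(tract, b$rec$references[["Order_2"]]$sequence,
                     fixed = TRUE))
  # MTPT tract comes from the own plastome
  mt <- substr(s, tr$mtpt$start + 1, tr$mtpt$end)
  expect_true(grepl(mt, b$rec$own_plastome$sequence, fixed = TRUE))
  # genes are present at their recorded strand-aware positions
  for (i in seq_len(nrow(tr$genes))) {
    sq <- substr(s, tr$genes$start[i] + 1, tr$genes$end[i])
    if (tr$genes$strand[i] == "-") sq <- rc(sq)
    expect_equal(sq, unname(b$rec$recipient_genes[[tr$genes$gene[i]]]))
  }
})

test_that("a recipient with empty specs contains no qualifying self-repeat", {
  b <- small_bundle(seed = 19)
  expect_equal(nrow(dispersed_repeats(b$rec$genome)), 0L)
  # brute-force confirmation: no pair of distinct 60 bp windows (step 30)
  # reaches 90% ungapped identity at zero offset
  s <- b$rec$genome$sequence
  starts <- seq(1, nchar(s) - 59, by = 30)
  win <- substring(s, starts, starts + 59)
  enc <- do.call(rbind, strsplit(win, "", fixed = TRUE))
  best <- 0
  for (i in seq_len(nrow(enc) - 1)) {
    m <- sweep(enc[(i + 1):nrow(enc), , drop = FALSE], 2, enc[i, ], "==")
    best <- max(best, max(rowMeans(m)))
  }
  expect_lt(best, 0.9)
})

test_that("long-read crossover labels follow the configured fraction", {
  cfg <- sim_config(seed = 11, genome_length_bp = 18000L,
                    repeat_spec = list(list(length_bp = 600L,
                                            identity_percent = 98,
                                            n_copies = 2L)),
                    recomb_fraction = 0.3, n_long_reads = 900L)
  panel <- simulate_reference_set(cfg)
  rec <- build_recipient_genome(cfg, panel)
  lr <- simulate_long_reads(rec$genome, rec$truth, cfg)
  span <- lr$truth[!is.na(lr$truth$repeat_id), ]
  expect_gt(nrow(span), 100L)
  n <- nrow(span); k <- sum(span$crossover)
  expect_lt(abs(k - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
  # extreme fractions
  for (f in c(0, 1)) {
    cfg2 <- cfg; cfg2$recomb_fraction <- f; cfg2$n_long_reads <- 150L
    lr2 <- simulate_long_reads(rec$genome, rec$truth, cfg2)
    sp2 <- lr2$truth[!is.na(lr2$truth$repeat_id), ]
    expect_true(all(sp2$crossover == (f == 1)))
  }
})

test_that("recombination without a long repeat is rejected", {
  b <- small_bundle(seed = 2)
  cfg <- b$cfg; cfg$recomb_fraction <- 0.5
  expect_error(simulate_long_reads(b$rec$genome, b$rec$truth, cfg),
               "repeat")
})

test_that("transcripts carry the planted edits and trans-spliced junction", {
  cfg <- sim_config(seed = 13, n_edit_sites = 10L, edit_gene = "mtgene1",
                    transsplice_gene = "mtgene2", genome_length_bp = 20000L)
  panel <- simulate_reference_set(cfg)
  rec <- build_recipient_genome(cfg, panel)
  tx <- simulate_transcript_reads(rec$genome, rec$truth, cfg)
  tn <- unique(tx$truth$transcript)
  expect_true("mtgene2_mature" %in% tn)   # exon1b + exon2 product exists
  expect_true("mtgene2_exon1a" %in% tn)   # exon1a is a separate product
  # no transcript joins the two portions of exon 1
  expect_false(any(grepl("exon1a.*exon1b|exon1b.*exon1a", tn)))
  # edit sites are genomic C on the coding strand
  ed <- rec$truth$edits
  gr <- rec$truth$genes[rec$truth$genes$gene == "mtgene1", ]
  cds <- substr(rec$genome$sequence, gr$start + 1, gr$end)
  if (gr$strand == "-") cds <- rc(cds)
  expect_true(all(substring(cds, ed$cds_pos + 1, ed$cds_pos + 1) == "C"))
})

test_that("identical configurations reproduce identical outputs", {
  cfg <- sim_config(seed = 21, genome_length_bp = 15000L, n_genes = 4L,
                    repeat_spec = list(list(length_bp = 600L,
                                            identity_percent = 95,
                                            n_copies = 2L)),
                    recomb_fraction = 0.2, n_long_reads = 50L)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$recipient$genome$sequence, b2$recipient$genome$sequence)
  expect_identical(b1$recipient$truth, b2$recipient$truth)
  expect_identical(vapply(b1$long_reads$reads, `[[`, "", "sequence"),
                   vapply(b2$long_reads$reads, `[[`, "", "sequence"))
  expect_identical(b1$panel$newick, b2$panel$newick)
})
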