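test_that("a planted MTPT is recovered as a merged region", {
  b <- small_bundle(seed = 61,
                    mtpt_spec = list(list(donor = "self_plastome",
                                          length_bp = 150L)))
  ps <- plastid_hit_screen(b$rec$genome,
                           c(list(b$rec$own_plastome),
                             b$rec$foreign_plastomes))
  tr <- b$rec$truth$mtpt
  hit <- ps$regions[ps$regions$end > tr$start & ps$regions$start < tr$end, ]
  expect_equal(nrow(hit), 1L)
  expect_gte(hit$length_bp, 140L)
})

test_that("hits inside excluded genes are removed from the plastid screen", {
  b <- small_bundle(seed = 63,
                    mtpt_spec = list(list(donor = "self_plastome",
                                          length_bp = 300L)))
  tr <- b$rec$truth$mtpt
  # declare the planted region an rRNA gene: the screen must drop it
  feats <- features(gene = "rrn18", type = "rRNA",
                    start = tr$start, end = tr$end)
  ps <- plastid_hit_screen(b$rec$genome,
                           c(list(b$rec$own_plastome),
                             b$rec$foreign_plastomes),
                           mito_features = feats)
  ov <- ps$regions[ps$regions$end > tr$start & ps$regions$start < tr$end, ]
  expect_equal(nrow(ov), 0L)
  # same via the atp1 exclusion label
  feats2 <- features(gene = "atp1", type = "CDS",
                     start = tr$start, end = tr$end)
  ps2 <- plastid_hit_screen(b$rec$genome,
                            c(list(b$rec$own_plastome),
                              b$rec$foreign_plastomes),
                            mito_features = feats2)
  ov2 <- ps2$regions[ps2$regions$end > tr$start & ps2$regions$start < tr$end, ]
  expect_equal(nrow(ov2), 0L)
})

test_that("a recipient without plants has no plastid regions", {
  b <- small_bundle(seed = 65)
  ps <- plastid_hit_screen(b$rec$genome,
                           c(list(b$rec$own_plastome),
                             b$rec$foreign_plastomes))
  expect_equal(nrow(ps$regions), 0L)
})

test_that("transfer classification follows the decision cascade", {
  b <- small_bundle(seed = 67,
                    mtpt_spec = list(list(donor = "self_plastome",
                                          length_bp = 400L)))
  g <- b$rec$genome
  tr <- b$rec$truth$mtpt
  region <- list(start = tr$start, end = tr$end)
  # own-lineage placement -> intracellular
  own <- structure(list(verdict = "vertical", sister_clade = "own_plastomes",
                        sister_support = 96, focal_monophyly_support = NA,
                        threshold = 80), class = "grouping_verdict")
  call1 <- classify_transfer(region, g, placement = own)
  expect_equal(call1$category, "intracellular")
  # distant-lineage placement or a gene absent from the own plastome -> HGT
  far <- structure(list(verdict = "hgt_candidate", sister_clade = "Order_3",
                        sister_support = 92, focal_monophyly_support = NA,
                        threshold = 80), class = "grouping_verdict")
  call2 <- classify_transfer(region, g, placement = far)
  expect_equal(call2$category, "HGT_candidate")
  call2b <- classify_transfer(region, g, placement = own,
                              matched_plastid_gene = "ndhB_like",
                              own_plastome_has_gene = FALSE)
  expect_equal(call2b$category, "intracellular")  # placement wins when vertical
  unres <- structure(list(verdict = "unresolved", sister_clade = NA,
                          sister_support = NA, focal_monophyly_support = NA,
                          threshold = 80), class = "grouping_verdict")
  call2c <- classify_transfer(region, g, placement = unres,
                              matched_plastid_gene = "ndhB_like",
                              own_plastome_has_gene = FALSE)
  expect_equal(call2c$category, "HGT_candidate")
  expect_true(any(grepl("gene_missing_from_own_plastome", call2c$evidence)))
  # indistinguishable from related mitogenomes -> mitogenome, before placement
  rel <- genome("rel", paste0(rnd_dna(300),
                              substr(g$sequence, tr$start + 1, tr$end),
                              rnd_dna(300)))
  call3 <- classify_transfer(region, g, placement = far,
                             related_mitos = list(rel))
  expect_equal(call3$category, "mitogenome")
  # gene-context homology beats placement
  ann <- features(gene = "nad5", type = "CDS", start = tr$start - 50L,
                  end = tr$end + 50L)
  call4 <- classify_transfer(region, g, placement = far, annotations = ann)
  expect_equal(call4$category, "homology")
  # missing placement withholds the category
  call5 <- classify_transfer(region, g)
  expect_true(is.na(call5$category))
  expect_equal(call5$evidence, "no placement")
  # unresolved placement with no other evidence falls back to homology
  call6 <- classify_transfer(region, g, placement = unres)
  expect_equal(call6$category, "homology")
  expect_true("unresolved_placement" %in% call6$evidence)
})

test_that("the order screen recovers a planted foreign tract and its donor", {
  b <- small_bundle(seed = 69,
                    hgt_spec = list(list(donor_order = "Order_3",
                                         length_bp = 800L)))
  sc <- intergenic_order_screen(b$rec$genome, b$rec$references, "Order_1")
  expect_equal(nrow(sc$candidates), 1L)
  expect_equal(sc$candidates$donor_order, "Order_3")
  tr <- b$rec$truth$hgt
  expect_lt(abs(sc$candidates$start - tr$start), 30L)
  expect_lt(abs(sc$candidates$end - tr$end), 30L)
  expect_gt(sc$candidate_percent, 0)
})

test_that("non-focal hits covered by the focal order are not candidates", {
  b <- small_bundle(seed = 71)
  # copy 600 bp of the recipient into a non-focal reference: the non-focal
  # hit is real but fully inside focal coverage (the focal reference shares
  # the whole scaffold), so no candidate may be emitted
  g <- b$rec$genome
  seg <- substr(g$sequence, 2001, 2600)
  refs <- b$rec$references
  fake <- genome("Order_2_mito",
                 paste0(refs[["Order_2"]]$sequence, seg))
  refs[["Order_2"]] <- fake
  sc <- intergenic_order_screen(g, refs, "Order_1")
  expect_equal(nrow(sc$candidates), 0L)
  expect_equal(sc$candidate_percent, 0)
})

test_that("a clean recipient yields zero candidate percent", {
  b <- small_bundle(seed = 73)
  sc <- intergenic_order_screen(b$rec$genome, b$rec$references, "Order_1")
  expect_equal(nrow(sc$candidates), 0L)
  expect_equal(sc$candidate_percent, 0)
})

test_that("nuclear copies of missing genes are found and assessed", {
  b <- small_bundle(seed = 75, missing_genes = c("mtgene5", "mtgene6"),
                    nuclear_spec = list(
                      list(gene = "mtgene5", identity_percent = 70,
                           intact = TRUE),
                      list(gene = "mtgene6", identity_percent = 70,
                           intact = FALSE)))
  ref <- panel_ref_cds(b$panel)
  rep <- nuclear_copy_search(ref[c("mtgene5", "mtgene6", "mtgene1")],
                             b$rec$nuclear)
  r5 <- rep[rep$gene == "mtgene5", ]
  expect_true(r5$found)
  expect_true(r5$orf_intact)
  expect_gte(r5$identity_percent, 60)
  r6 <- rep[rep$gene == "mtgene6", ]
  expect_true(r6$found)
  expect_false(r6$orf_intact)   # planted internal stop
  # mtgene1 has no nuclear copy: the random nuclear scaffold misses it
  r1 <- rep[rep$gene == "mtgene1", ]
  expect_false(r1$found)
})

test_that("nuclear coverage of the mitogenome uses the 250 bp / 80% filter", {
  b <- small_bundle(seed = 77)
  g <- b$rec$genome
  # nuclear genome = random scaffold + a verbatim 2 kb mitochondrial block
  nuc <- genome("nuc", paste0(rnd_dna(3000),
                              substr(g$sequence, 5001, 7000),
                              rnd_dna(3000)))
  cov <- nuclear_mito_coverage(nuc, g)
  expect_equal(cov, 2000 / nchar(g$sequence), tolerance = 0.05)
  # a 200 bp block alone is below the length filter
  nuc2 <- genome("nuc2", paste0(rnd_dna(3000),
                                substr(g$sequence, 5001, 5200),
                                rnd_dna(3000)))
  expect_equal(nuclear_mito_coverage(nuc2, g), 0)
})
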