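test_that("identical CDS align without gaps and back-translate exactly", {
  cds <- mitoscreen:::random_cds(300L)
  set <- setNames(rep(cds, 4), paste0("t", 1:4))
  aln <- protein_guided_align(set)
  expect_false(any(aln == "-"))
  expect_equal(unname(msa_to_seqs(aln)["t1"]),
               substr(cds, 1, 297))   # terminal stop codon trimmed
})

test_that("a clean one-codon deletion yields a single 3-column gap", {
  set.seed(1)
  cds <- mitoscreen:::random_cds(300L)
  del <- paste0(substr(cds, 1, 150), substr(cds, 154, 300))
  aln <- protein_guided_align(c(a = cds, b = del, cc = cds))
  expect_equal(sum(aln["b", ] == "-"), 3L)
  gaps <- which(aln["b", ] == "-")
  expect_equal(diff(gaps), c(1L, 1L))
  expect_false(any(aln["a", ] == "-"))
})

test_that("sequences with internal stops are dropped with a warning", {
  cds <- mitoscreen:::random_cds(300L)
  bad <- cds
  substr(bad, 90 + 1, 90 + 3) <- "TAA"
  expect_warning(aln <- protein_guided_align(c(a = cds, b = bad, cc = cds)),
                 "internal stop")
  expect_false("b" %in% rownames(aln))
})

test_that("indel-free panel alignments preserve pairwise identity", {
  cfg <- sim_config(seed = 2, n_orders = 3L, taxa_per_order = 2L,
                    subst_rate_per_branch = 0.04, n_genes = 1L)
  panel <- simulate_reference_set(cfg)
  seqs <- panel$genes[[1]]
  aln <- suppressWarnings(protein_guided_align(seqs))
  expect_false(any(aln == "-"))   # substitution-only evolution, no gaps
  a <- rownames(aln)[1]; b <- rownames(aln)[2]
  expect_equal(hamming_identity(paste(aln[a, ], collapse = ""),
                                paste(aln[b, ], collapse = "")),
               hamming_identity(substr(seqs[[a]], 1, ncol(aln)),
                                substr(seqs[[b]], 1, ncol(aln))))
})

test_that("column masking applies the strict missing-data rule", {
  m <- rbind(a = c("A", "A", "-", "A"),
             b = c("C", "-", "-", "C"),
             cc = c("G", "-", "-", "G"),
             d = c("T", "T", "N", "T"))
  out <- mask_columns(m, 0.5)
  # col 2: 2/4 missing = 0.5, not > 0.5 -> retained; col 3: 3/4 gaps + N -> removed
  expect_equal(attr(out, "col_map"), c(1L, 2L, 4L))
  # random masks agree with a brute-force recount
  set.seed(4)
  for (r in 1:10) {
    mm <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 120, TRUE,
                        prob = c(rep(0.2, 4), 0.15, 0.05)), nrow = 6)
    rownames(mm) <- paste0("t", 1:6)
    frac <- colMeans(!(mm %in% c("A", "C", "G", "T")) |> matrix(nrow = 6))
    want <- which(frac <= 0.5)
    if (!length(want)) {
      expect_error(mask_columns(mm, 0.5), "all columns")
    } else {
      expect_equal(attr(mask_columns(mm, 0.5), "col_map"), want)
    }
  }
})

test_that("K2P distances match the closed form and an independent engine", {
  # identical sequences -> 0
  m0 <- rbind(a = strsplit(strrep("ACGT", 25), "")[[1]],
              b = strsplit(strrep("ACGT", 25), "")[[1]])
  expect_equal(k2p_distance(m0)[1, 2], 0)
  # 100 sites, 10 transitions, 5 transversions: closed form gives
  # -0.5*log((1-2*0.1-0.05)*sqrt(1-2*0.05)) = 0.170181
  m <- matrix("A", 2, 100, dimnames = list(c("a", "b"), NULL))
  m[2, 1:10] <- "G"      # transitions
  m[2, 11:15] <- "C"     # transversions
  d <- k2p_distance(m)
  expect_equal(d[1, 2], -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_equal(d[1, 2], 0.170181, tolerance = 1e-5)
  # random alignments agree with ape's K80 engine (pairwise deletion)
  set.seed(6)
  base <- rnd_dna(300)
  seqs <- setNames(vapply(1:4, function(i) mutate_rate(base, 0.05), ""),
                   paste0("t", 1:4))
  mm <- msa_from_seqs(seqs)
  d1 <- k2p_distance(mm)
  d2 <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(mm)), model = "K80",
                                pairwise.deletion = TRUE))
  expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-12,
               ignore_attr = TRUE)
  # symmetry and zero diagonal
  expect_true(isSymmetric(unname(d1)))
  expect_true(all(diag(d1) == 0))
})

test_that("gap sites are excluded pairwise and saturation is flagged", {
  m <- rbind(a = c("A", "A", "-", "A", "C", "G", "T", "A"),
             b = c("A", "G", "C", "A", "C", "G", "T", "-"))
  d <- k2p_distance(m)
  # 6 comparable sites, 1 transition
  P <- 1 / 6
  expect_equal(d[1, 2], -0.5 * log((1 - 2 * P) * 1))
  # saturated pair hits the ceiling
  ms <- rbind(a = strsplit(strrep("A", 40), "")[[1]],
              b = strsplit(strrep("G", 40), "")[[1]])
  ds <- k2p_distance(ms, ceiling = 5)
  expect_equal(ds[1, 2], 5)
  expect_true(attr(ds, "saturated")[1, 2])
})

test_that("neighbor joining recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  dm <- ape::cophenetic.phylo(tr)
  nt <- nj_tree(dm)
  expect_equal(ape::dist.topo(ape::unroot(tr), nt), 0,
               ignore_attr = TRUE)
  # branch lengths are recovered: path lengths reproduce the input metric
  expect_equal(ape::cophenetic.phylo(nt)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)
  # 3 taxa: the unique unrooted topology
  nt3 <- nj_tree(dm[1:3, 1:3])
  expect_equal(length(nt3$tip.label), 3L)
  # permuting taxon order leaves the unrooted topology invariant
  p <- c(3, 1, 4, 2)
  nt_p <- nj_tree(dm[p, p])
  expect_equal(ape::dist.topo(nt, nt_p), 0, ignore_attr = TRUE)
  # non-finite entries name the offending pair
  dm_bad <- dm; dm_bad["A", "C"] <- dm_bad["C", "A"] <- Inf
  expect_error(nj_tree(dm_bad), "A.*C|C.*A")
})

test_that("bootstrap supports are deterministic and resolve deep splits", {
  cfg <- sim_config(seed = 31, n_orders = 3L, taxa_per_order = 2L,
                    subst_rate_per_branch = 0.05, n_genes = 1L)
  panel <- simulate_reference_set(cfg)
  msa <- msa_from_seqs(panel$genes[[1]])
  t1 <- bootstrap_support(msa, n_reps = 300L, seed = 31)
  t2 <- bootstrap_support(msa, n_reps = 300L, seed = 31)
  expect_identical(t1$node.label, t2$node.label)
  # the outgroup/ingroup split is deep and must be near-fully supported
  n_tip <- length(t1$tip.label)
  out_tips <- grep("^Outgroup", t1$tip.label, value = TRUE)
  in_tips <- setdiff(t1$tip.label, out_tips)
  sup <- NA_real_
  for (nd in (n_tip + 2L):(n_tip + t1$Nnode)) {
    tips <- ape::extract.clade(t1, nd)$tip.label
    if (setequal(tips, out_tips) || setequal(tips, in_tips)) {
      sup <- as.numeric(t1$node.label[nd - n_tip])
    }
  }
  expect_gte(sup, 95)
  # supports are invariant to taxon input order under a fixed seed
  perm <- sample(rownames(msa))
  t3 <- bootstrap_support(msa[perm, ], n_reps = 300L, seed = 31)
  expect_identical(sort(t1$node.label), sort(t3$node.label))
})

test_that("grouping verdicts follow the support rules", {
  groups <- list(Solanales = c("Ipo", "CusA", "CusB"), Fabales = "Fab")
  t1 <- ape::read.tree(text = "(Out:1,((CusA:1,CusB:1)95:1,Ipo:1)92:1,Fab:1);")
  v1 <- grouping_test(t1, c("CusA", "CusB"), "Ipo", groups, outgroup = "Out")
  expect_equal(v1$verdict, "vertical")
  expect_equal(v1$focal_monophyly_support, 95)
  expect_equal(v1$sister_support, 92)
  # nested inside a different order with high support
  t2 <- ape::read.tree(text = "(Out:1,Ipo:1,((CusA:1,CusB:1)99:1,Fab:1)97:1);")
  v2 <- grouping_test(t2, c("CusA", "CusB"), "Ipo",
                      list(Solanales = "Ipo", Fabales = "Fab"),
                      outgroup = "Out")
  expect_equal(v2$verdict, "hgt_candidate")
  expect_equal(v2$sister_clade, "Fabales")
  # sister support 66 and no alternative above threshold -> unresolved
  t3 <- ape::read.tree(text = "(Out:1,((CusA:1,CusB:1)95:1,Ipo:1)66:1,Fab:1);")
  v3 <- grouping_test(t3, c("CusA", "CusB"), "Ipo", groups, outgroup = "Out")
  expect_equal(v3$verdict, "unresolved")
  # grouping within the expected higher clade also counts as vertical
  t4 <- ape::read.tree(
    text = "(Out:1,(((CusA:1,CusB:1)95:1,Sol2:1)90:1,Ipo:1)88:1,Fab:1);")
  v4 <- grouping_test(t4, c("CusA", "CusB"), "Ipo",
                      list(Solanales = c("Ipo", "Sol2"), Fabales = "Fab"),
                      outgroup = "Out")
  expect_equal(v4$verdict, "vertical")
  # absent focal taxa raise an error
  expect_error(grouping_test(t1, c("CusA", "Nope"), "Ipo", groups), "absent")
})

test_that("concatenation gap-fills missing taxa and keeps the partition map", {
  m1 <- msa_from_seqs(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  m2 <- msa_from_seqs(c(a = "TTTTTTTTTT", cc = "TTTTTTTTTT"))
  cc <- concatenate_msa(list(g1 = m1, g2 = m2))
  expect_equal(ncol(cc), 20L)
  expect_equal(sort(rownames(cc)), c("a", "b", "cc"))
  expect_true(all(cc["cc", 1:10] == "-"))
  expect_true(all(cc["b", 11:20] == "-"))
  # partition map reconstructs the originals
  part <- attr(cc, "partition")
  back1 <- cc[rownames(m1), (part$g1["start"] + 1):part$g1["end"]]
  expect_equal(unname(back1), unname(m1))
  back2 <- cc[rownames(m2), (part$g2["start"] + 1):part$g2["end"]]
  expect_equal(unname(back2), unname(m2))
})

test_that("the conversion scan flags a planted transfer and only that", {
  cfg <- sim_config(seed = 37, n_orders = 4L, taxa_per_order = 2L,
                    subst_rate_per_branch = 0.05, n_genes = 1L,
                    gene_length_bp = 1200L)
  panel <- simulate_reference_set(cfg)
  m <- msa_from_seqs(panel$genes[[1]])
  # clock-like data: no conversion signal
  g0 <- geneconv_scan(m, n_perms = 2000L, seed = 37)
  expect_equal(sum(g0$significant), 0L)
  # copy the first 40% of a distant taxon into one sequence
  donor <- "Order_4|taxon_1"; recv <- "Order_1|taxon_1"
  k <- round(ncol(m) * 0.4)
  m2 <- m; m2[recv, 1:k] <- m[donor, 1:k]
  g1 <- geneconv_scan(m2, n_perms = 2000L, seed = 37)
  sig <- g1[g1$significant, ]
  expect_gte(nrow(sig), 1L)
  expect_true(any(sig$taxon_a == recv & sig$taxon_b == donor |
                    sig$taxon_a == donor & sig$taxon_b == recv))
  # the reported fragment lies in the converted region
  frag <- sig[sig$taxon_a %in% c(recv, donor) &
                sig$taxon_b %in% c(recv, donor), ][1, ]
  expect_lt(frag$frag_start, k)
})

test_that("identical taxa are excluded from the conversion pair scan", {
  set.seed(9)
  base <- rnd_dna(400)
  seqs <- c(a = base, b = base, cc = mutate_rate(base, 0.1),
            d = mutate_rate(base, 0.1))
  g <- geneconv_scan(msa_from_seqs(seqs), n_perms = 500L, seed = 9)
  expect_false(any(g$taxon_a == "a" & g$taxon_b == "b"))
})

test_that("an alignment without polymorphic columns returns an empty note", {
  m <- msa_from_seqs(c(a = "ACGTACGT", b = "ACGTACGT", cc = "ACGTACGT"))
  g <- geneconv_scan(m, n_perms = 100L, seed = 1)
  expect_equal(nrow(g), 0L)
  expect_match(attr(g, "note"), "polymorphic")
})

test_that("masked intervals are removed before the conversion scan", {
  set.seed(11)
  base <- rnd_dna(300)
  seqs <- c(a = mutate_rate(base, 0.08), b = mutate_rate(base, 0.08),
            cc = mutate_rate(base, 0.08), d = mutate_rate(base, 0.08))
  m <- msa_from_seqs(seqs)
  g_all <- geneconv_scan(m, n_perms = 200L, seed = 2)
  g_mask <- geneconv_scan(m, n_perms = 200L, seed = 2,
                          mask = list(c(0L, 150L)))
  if (nrow(g_mask)) expect_true(all(g_mask$frag_start >= 150L))
})
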