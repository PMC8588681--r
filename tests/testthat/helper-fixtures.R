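# shared fixture builders (everything generated in code, nothing on disk)

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

mutate_rate <- function(s, rate) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- which(runif(length(x)) < rate)
  x[i] <- vapply(x[i], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(x, collapse = "")
}

rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# optimal local alignment score over both strands (independent oracle)
sw_best_score <- function(q, s, match = 2, mismatch = -3, go = 5, ge = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  fwd <- Biostrings::score(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = sm,
    gapOpening = go, gapExtension = ge))
  rev <- Biostrings::score(Biostrings::pairwiseAlignment(
    rc(q), s, type = "local", substitutionMatrix = sm,
    gapOpening = go, gapExtension = ge))
  max(fwd, rev)
}

hamming_identity <- function(a, b) {
  xa <- strsplit(a, "", fixed = TRUE)[[1]]
  xb <- strsplit(b, "", fixed = TRUE)[[1]]
  100 * mean(xa == xb)
}

# default synthetic bundle used by several test files
small_bundle <- function(seed = 5, ...) {
  args <- list(seed = seed, n_orders = 4L, taxa_per_order = 3L,
               genome_length_bp = 20000L, n_genes = 6L)
  dots <- list(...)
  args[names(dots)] <- dots
  cfg <- do.call(sim_config, args)
  panel <- simulate_reference_set(cfg)
  rec <- build_recipient_genome(cfg, panel)
  list(cfg = cfg, panel = panel, rec = rec)
}

taxon1 <- function(ord) paste0(ord, "|taxon_1")

panel_ref_cds <- function(panel, ord = "Order_1") {
  vapply(panel$genes, function(x) x[[taxon1(ord)]], "")
}
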