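#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator: an
#' order-level reference phylogeny with several taxa per order, a recipient
#' mitogenome carrying a standard gene set in intergenic scaffold DNA,
#' dispersed repeats of controlled identity, plastid-derived inserts (MTPTs),
#' optional foreign (HGT) tracts from a known donor order, long reads
#' spanning repeats with a controllable crossover fraction, and transcript
#' reads carrying C-to-U edits and a trans-spliced junction.
#'
#' All randomness flows from `seed`; each generator stage derives its own
#' stream (`seed + stage offset`) so stages are individually reproducible.
#'
#' @param seed Integer root seed.
#' @param n_orders Number of ingroup orders in the reference panel (>= 3).
#' @param taxa_per_order Taxa per order (>= 1).
#' @param subst_rate_per_branch Expected substitutions/site per backbone
#'   branch (Jukes-Cantor).
#' @param genome_length_bp Approximate recipient genome length (scaffold
#'   DNA plus planted elements).
#' @param n_genes,gene_length_bp Size of the simulated mitochondrial gene
#'   set (codon-structured CDS).
#' @param repeat_spec List of repeat plans:
#'   `list(length_bp=, identity_percent=, n_copies=, inverted=FALSE)`.
#' @param mtpt_spec List of plastid-insert plans:
#'   `list(donor = "self_plastome"|"foreign_plastome", length_bp=,
#'   donor_order=)` (donor_order used for foreign donors).
#' @param hgt_spec List of foreign-tract plans:
#'   `list(donor_order=, length_bp=, contains_gene=FALSE)`.
#' @param recomb_fraction Fraction of repeat-spanning long reads that are
#'   crossover products, in `[0, 1]`.
#' @param n_long_reads,long_read_length_mean,long_read_error Long-read set
#'   size, mean length and per-base substitution error rate.
#' @param n_edit_sites Number of C-to-U edit sites planted in `edit_gene`.
#' @param edit_gene Gene carrying the planted edit sites.
#' @param transsplice_gene Optional gene split into a three-locus
#'   (exon1a / exon1b / exon2) trans-spliced layout.
#' @param missing_genes Genes withheld from the recipient (simulated losses).
#' @param nuclear_spec Optional nuclear-copy plans:
#'   `list(gene=, identity_percent=, intact=TRUE)`.
#' @param transcript_coverage,transcript_read_length,transcript_error,
#'   insert_mean Transcript read-pair simulation settings.
#' @param focal_order Name of the recipient's own order.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_orders = 5L,
                       taxa_per_order = 3L,
                       subst_rate_per_branch = 0.03,
                       genome_length_bp = 30000L,
                       n_genes = 8L,
                       gene_length_bp = 900L,
                       repeat_spec = list(),
                       mtpt_spec = list(),
                       hgt_spec = list(),
                       recomb_fraction = 0,
                       n_long_reads = 500L,
                       long_read_length_mean = 3000L,
                       long_read_error = 0.02,
                       n_edit_sites = 0L,
                       edit_gene = "mtgene1",
                       transsplice_gene = NULL,
                       missing_genes = character(),
                       nuclear_spec = list(),
                       transcript_coverage = 40,
                       transcript_read_length = 150L,
                       transcript_error = 0.005,
                       insert_mean = 320L,
                       focal_order = "Order_1") {
  stopifnot(n_orders >= 3L, taxa_per_order >= 1L,
            recomb_fraction >= 0, recomb_fraction <= 1,
            genome_length_bp > 0, gene_length_bp %% 3 == 0,
            seed == as.integer(seed))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

sim_seed <- function(cfg, stage) {
  (cfg$seed * 97L + stage) %% .Machine$integer.max
}

# ---- Jukes-Cantor machinery -------------------------------------------------

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

# substitute the bases at `pos`, each to a uniformly chosen different base
substitute_at <- function(x, pos) {
  if (!length(pos)) return(x)
  cur <- match(x[pos], BASES)
  step <- sample.int(3L, length(pos), replace = TRUE)
  ok <- !is.na(cur)                      # leave N untouched
  x[pos[ok]] <- BASES[((cur[ok] - 1L + step[ok]) %% 4L) + 1L]
  x
}

# substitute each site with the JC probability implied by branch length b
jc_mutate <- function(seq, b) {
  if (b <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 / 3 * b))
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < p)
  paste(substitute_at(x, hit), collapse = "")
}

# substitute an exact number of positions (each to a different base)
mutate_n <- function(seq, n_subs) {
  if (n_subs <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(substitute_at(x, sample(length(x), n_subs)), collapse = "")
}

# repair codon structure after substitution: internal stop codons are
# defused (third base -> C) and the terminal stop is restored, so evolved
# CDS stay translatable end to end
fix_internal_stops <- function(seq) {
  n_codons <- nchar(seq) %/% 3
  if (n_codons <= 2) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (k in seq_len(n_codons - 1L)) {
    cod <- paste(x[(3 * k - 2):(3 * k)], collapse = "")
    if (cod %in% STOPS) x[3 * k] <- "C"
  }
  last <- paste(x[(3 * n_codons - 2):(3 * n_codons)], collapse = "")
  if (!last %in% STOPS) x[(3 * n_codons - 2):(3 * n_codons)] <-
    c("T", "A", "A")
  paste(x, collapse = "")
}

# random CDS: ATG + non-stop codons + TAA
random_cds <- function(len_bp) {
  n_codons <- len_bp %/% 3
  mids <- character(n_codons - 2L)
  for (i in seq_along(mids)) {
    repeat {
      cod <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
      if (!cod %in% STOPS) break
    }
    mids[i] <- cod
  }
  paste0("ATG", paste(mids, collapse = ""), "TAA")
}

# ---- reference panel --------------------------------------------------------

order_clade_newick <- function(order, k, br) {
  tips <- paste0(order, "|taxon_", seq_len(k), ":", br)
  if (k == 1L) return(tips)
  node <- paste0("(", tips[1], ",", tips[2], "):", br)
  if (k > 2L) {
    for (j in 3:k) node <- paste0("(", node, ",", tips[j], "):", br)
  }
  node
}

panel_newick <- function(cfg) {
  r <- cfg$subst_rate_per_branch
  ri <- r / 5
  clades <- vapply(seq_len(cfg$n_orders), function(k)
    order_clade_newick(paste0("Order_", k), cfg$taxa_per_order, ri), "")
  # ladder of orders: Order_1 closest to Order_2, etc.
  node <- paste0("(", clades[1], ",", clades[2], "):", r)
  if (cfg$n_orders > 2L) {
    for (k in 3:cfg$n_orders) node <- paste0("(", node, ",", clades[k], "):", r)
  }
  out <- order_clade_newick("Outgroup", max(2L, min(2L, cfg$taxa_per_order)), ri)
  paste0("(", out, ":", 2 * r, ",", node, ":", r, ");")
}

evolve_along_tree <- function(tree, root_seq) {
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  n_tip <- length(tr$tip.label)
  seqs <- vector("list", n_tip + tr$Nnode)
  seqs[[n_tip + 1L]] <- root_seq
  for (i in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[i, 1]; child <- tr$edge[i, 2]
    seqs[[child]] <- fix_internal_stops(jc_mutate(seqs[[parent]],
                                                  tr$edge.length[i]))
  }
  out <- vapply(seq_len(n_tip), function(i) seqs[[i]], "")
  names(out) <- tr$tip.label
  out
}

#' Simulate the order-labeled reference panel
#'
#' Generates a ladder-shaped order-level phylogeny with an outgroup clade,
#' then evolves a random root gene set (and a small plastid gene set) along
#' it under Jukes-Cantor substitution with the configured branch rates; the
#' same topology is used for all genes (no transfer within the panel).
#' Internal stop codons arising from substitution are repaired so that every
#' panel sequence stays translatable.
#'
#' @param cfg A [sim_config].
#' @return A list with `tree` (ape `phylo`), `newick`, `genes` (per-gene
#'   named vectors taxon -> CDS), `plastid_genes`, `root_genes` and
#'   `provenance` (including a divergence warning when the expected pairwise
#'   identity falls below 50%).
#' @export
simulate_reference_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 1L))
  nwk <- panel_newick(cfg)
  tree <- ape::read.tree(text = nwk)
  root_genes <- stats::setNames(
    lapply(seq_len(cfg$n_genes), function(i) random_cds(cfg$gene_length_bp)),
    paste0("mtgene", seq_len(cfg$n_genes)))
  plastid_names <- c("psbB_like", "ndhB_like", "rbcL_like")
  root_plastid <- stats::setNames(
    lapply(plastid_names, function(i) random_cds(cfg$gene_length_bp)),
    plastid_names)
  genes <- lapply(root_genes, function(rs) evolve_along_tree(tree, rs))
  plastid_genes <- lapply(root_plastid, function(rs)
    evolve_along_tree(tree, rs))
  depth <- max(ape::node.depth.edgelength(tree)) * 2
  exp_diff <- 0.75 * (1 - exp(-4 / 3 * depth))
  prov <- list(seed = cfg$seed, newick = nwk,
               warning = if (exp_diff > 0.5)
                 "expected pairwise identity below 50% at configured rates"
               else NULL)
  list(tree = tree, newick = nwk, genes = genes,
       plastid_genes = plastid_genes, root_genes = root_genes,
       provenance = prov)
}

# ---- recipient genome -------------------------------------------------------

# assemble elements separated by scaffold chunks; returns genome string and
# element coordinates (0-based half-open)
assemble_blocks <- function(scaffold_chunks, elements) {
  n_el <- length(elements)
  stopifnot(length(scaffold_chunks) == n_el + 1L)
  pieces <- character(2L * n_el + 1L)
  coords <- data.frame(label = character(n_el), start = integer(n_el),
                       end = integer(n_el), stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_len(n_el)) {
    pieces[2L * i - 1L] <- scaffold_chunks[i]
    pos <- pos + nchar(scaffold_chunks[i])
    pieces[2L * i] <- elements[[i]]$seq
    coords$label[i] <- elements[[i]]$label
    coords$start[i] <- pos
    pos <- pos + nchar(elements[[i]]$seq)
    coords$end[i] <- pos
  }
  pieces[2L * n_el + 1L] <- scaffold_chunks[n_el + 1L]
  list(sequence = paste(pieces, collapse = ""), coords = coords)
}

split_scaffold <- function(scaffold, n_chunks) {
  L <- nchar(scaffold)
  if (n_chunks == 1L) return(scaffold)
  # roughly even chunks with jitter, so planted elements spread along the
  # genome instead of clumping
  base <- L * seq_len(n_chunks - 1L) / n_chunks
  jit <- stats::runif(n_chunks - 1L, -L / (4 * n_chunks), L / (4 * n_chunks))
  cuts <- sort(pmin(pmax(round(base + jit), 1L), L - 1L))
  if (any(diff(cuts) <= 0)) cuts <- pmin(pmax(round(base), 1L), L - 1L)
  starts <- c(0L, cuts)
  ends <- c(cuts, L)
  substring(scaffold, starts + 1L, ends)
}

norm_spec <- function(spec, defaults) {
  lapply(spec, function(s) {
    s <- as.list(s)
    if (is.null(names(s)) || any(names(s) == "")) names(s) <- names(defaults)[seq_along(s)]
    utils::modifyList(defaults, s)
  })
}

#' Build the recipient mitogenome and its truth set
#'
#' Assembles a recipient genome that carries its own order's gene set in
#' intergenic scaffold DNA, plants dispersed repeats at controlled identity,
#' copies MTPT tracts from the simulated own or foreign plastome, and copies
#' HGT tracts from a designated donor order's reference mitogenome.  Also
#' builds one reference mitogenome per panel order (the focal order's
#' reference shares scaffold ancestry with the recipient), the plastomes,
#' and an optional nuclear genome carrying diverged copies of withheld
#' genes.  Every planted interval is recorded in the returned truth set.
#'
#' @param cfg A [sim_config].
#' @param panel Output of [simulate_reference_set()] (same config).
#' @return A list with `genome`, `truth`, `references` (per-order genomes),
#'   `own_plastome`, `foreign_plastomes`, `nuclear`, `recipient_genes`.
#' @export
build_recipient_genome <- function(cfg, panel) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 2L))
  focal <- cfg$focal_order
  orders <- paste0("Order_", seq_len(cfg$n_orders))
  taxon1 <- function(ord) paste0(ord, "|taxon_1")

  present_genes <- setdiff(names(panel$genes), cfg$missing_genes)
  rep_spec <- norm_spec(cfg$repeat_spec,
                        list(length_bp = 1000L, identity_percent = 100,
                             n_copies = 2L, inverted = FALSE))
  mtpt_spec <- norm_spec(cfg$mtpt_spec,
                         list(donor = "self_plastome", length_bp = 500L,
                              donor_order = orders[min(3L, cfg$n_orders)]))
  hgt_spec <- norm_spec(cfg$hgt_spec,
                        list(donor_order = orders[min(3L, cfg$n_orders)],
                             length_bp = 800L, contains_gene = FALSE))

  # recipient's own gene versions: one short extra branch from focal taxon 1
  recipient_genes <- vapply(panel$genes, function(g)
    fix_internal_stops(jc_mutate(g[[taxon1(focal)]],
                                 cfg$subst_rate_per_branch / 10)), "")

  # plastomes: scaffold + plastid genes, one per order (own = focal order)
  plastome_len <- 8000L
  plastomes <- list()
  for (ord in orders) {
    pg <- vapply(panel$plastid_genes, function(g) g[[taxon1(ord)]], "")
    scaf <- split_scaffold(random_dna(plastome_len), length(pg) + 1L)
    els <- Map(function(nm, sq) list(label = nm, seq = sq), names(pg), pg)
    asm <- assemble_blocks(scaf, unname(els))
    plastomes[[ord]] <- list(
      genome = genome(paste0(ord, "_plastome"), asm$sequence),
      coords = asm$coords)
  }

  # per-order reference mitogenomes; the focal scaffold seeds the recipient
  intergenic_total <- max(2000L, cfg$genome_length_bp -
                            sum(nchar(recipient_genes[present_genes])))
  ref_mitos <- list()
  focal_scaffold <- NULL
  for (ord in orders) {
    scaf_seq <- random_dna(intergenic_total)
    if (ord == focal) focal_scaffold <- scaf_seq
    og <- vapply(panel$genes, function(g) g[[taxon1(ord)]], "")
    els <- Map(function(nm, sq) list(label = nm, seq = sq), names(og), og)
    scaf <- split_scaffold(scaf_seq, length(els) + 1L)
    asm <- assemble_blocks(scaf, unname(els))
    ref_mitos[[ord]] <- genome(paste0(ord, "_mito"), asm$sequence)
  }

  # ---- recipient elements ----
  elements <- list()
  truth_repeats <- truth_mtpt <- truth_hgt <- NULL

  hgt_genes <- character()
  for (i in seq_along(hgt_spec)) {
    hs <- hgt_spec[[i]]
    donor <- hs$donor_order
    stopifnot(donor %in% orders, donor != focal)
    dseq <- ref_mitos[[donor]]$sequence
    if (isTRUE(hs$contains_gene)) {
      gene_pick <- present_genes[length(present_genes)]
      hgt_genes <- c(hgt_genes, gene_pick)
      donor_gene <- panel$genes[[gene_pick]][[taxon1(donor)]]
      gpos <- regexpr(donor_gene, dseq, fixed = TRUE)[[1]] - 1L
      flank <- max(0L, (hs$length_bp - nchar(donor_gene)) %/% 2L)
      st <- max(0L, gpos - flank)
      en <- min(nchar(dseq), st + max(hs$length_bp, nchar(donor_gene)))
      tract <- subseq_str(dseq, st, en)
    } else {
      # intergenic tract: take from the leading scaffold chunk of the donor
      st <- sample(200L, 1L)
      tract <- subseq_str(dseq, st, st + hs$length_bp)
      gene_pick <- NA_character_
    }
    elements[[length(elements) + 1L]] <-
      list(label = paste0("hgt_", i), seq = tract,
           meta = list(kind = "hgt", donor_order = donor, gene = gene_pick))
  }
  present_genes <- setdiff(present_genes, hgt_genes)

  for (i in seq_along(mtpt_spec)) {
    ms <- mtpt_spec[[i]]
    src_ord <- if (ms$donor == "self_plastome") focal else ms$donor_order
    pl <- plastomes[[src_ord]]
    gene_row <- pl$coords[1 + (i - 1L) %% nrow(pl$coords), ]
    center <- (gene_row$start + gene_row$end) %/% 2L
    st <- max(0L, center - ms$length_bp %/% 2L)
    en <- min(nchar(pl$genome$sequence), st + ms$length_bp)
    tract <- subseq_str(pl$genome$sequence, st, en)
    elements[[length(elements) + 1L]] <-
      list(label = paste0("mtpt_", i), seq = tract,
           meta = list(kind = "mtpt", donor = ms$donor,
                       donor_order = src_ord, plastid_gene = gene_row$label))
  }

  src_off <- nchar(focal_scaffold) %/% 2L
  for (i in seq_along(rep_spec)) {
    rs <- rep_spec[[i]]
    if (src_off + rs$length_bp > nchar(focal_scaffold)) {
      stop("config error: requested insertions exceed genome length")
    }
    src <- subseq_str(focal_scaffold, src_off, src_off + rs$length_bp)
    # the source chunk of the scaffold is replaced so the copies only occur
    # where planted
    substr(focal_scaffold, src_off + 1L, src_off + rs$length_bp) <-
      random_dna(rs$length_bp)
    src_off <- src_off + rs$length_bp + 200L
    n_sub <- round(rs$length_bp * (100 - rs$identity_percent) / 100)
    for (cp in seq_len(rs$n_copies)) {
      sq <- if (cp == 1L) src else mutate_n(src, n_sub)
      if (cp > 1L && isTRUE(rs$inverted)) sq <- revcomp(sq)
      elements[[length(elements) + 1L]] <-
        list(label = paste0("repeat_", i, "_copy_", cp), seq = sq,
             meta = list(kind = "repeat", repeat_id = paste0("repeat_", i),
                         copy = cp, identity = rs$identity_percent,
                         inverted = cp > 1L && isTRUE(rs$inverted)))
    }
  }

  # trans-spliced gene: split into exon1a / exon1b / exon2 loci
  ts <- NULL
  if (!is.null(cfg$transsplice_gene)) {
    tg <- cfg$transsplice_gene
    stopifnot(tg %in% present_genes)
    cds <- recipient_genes[[tg]]
    L <- nchar(cds)
    e1_end <- 3L * round(L * 0.6 / 3)
    e1a_end <- 3L * round(e1_end * 0.75 / 3)
    ts <- list(gene = tg,
               pieces = c("exon1a", "exon1b", "exon2"),
               cds_bounds = rbind(c(0L, e1a_end), c(e1a_end, e1_end),
                                  c(e1_end, L)))
    present_genes <- setdiff(present_genes, tg)
    for (k in 1:3) {
      sq <- subseq_str(cds, ts$cds_bounds[k, 1], ts$cds_bounds[k, 2])
      strand <- if (k == 3L) "-" else "+"
      elements[[length(elements) + 1L]] <-
        list(label = paste0(tg, "_", ts$pieces[k]),
             seq = if (strand == "-") revcomp(sq) else sq,
             meta = list(kind = "ts_piece", gene = tg, piece = ts$pieces[k],
                         strand = strand))
    }
  }

  # planted edit sites: genomic T -> C at codon position 2 of the edit gene
  truth_edits <- NULL
  edit_cds_pos <- integer()
  if (cfg$n_edit_sites > 0L) {
    eg <- cfg$edit_gene
    stopifnot(eg %in% present_genes)
    cds <- recipient_genes[[eg]]
    x <- strsplit(cds, "", fixed = TRUE)[[1]]
    cand <- which(x == "T")
    cand <- cand[(cand - 2L) %% 3L == 0L]          # codon position 2
    cand <- cand[cand > 3L & cand < nchar(cds) - 3L]
    # keep sites where the T->C change alters the residue (always at pos 2)
    n_take <- min(cfg$n_edit_sites, length(cand))
    pick <- sort(sample(cand, n_take))
    x[pick] <- "C"
    cds2 <- fix_internal_stops(paste(x, collapse = ""))
    # drop sites destroyed by stop repair
    x2 <- strsplit(cds2, "", fixed = TRUE)[[1]]
    pick <- pick[x2[pick] == "C"]
    recipient_genes[[eg]] <- cds2
    edit_cds_pos <- pick - 1L                       # 0-based CDS coordinate
  }

  # ordinary genes (random strand)
  for (nm in present_genes) {
    strand <- sample(c("+", "-"), 1L)
    sq <- recipient_genes[[nm]]
    elements[[length(elements) + 1L]] <-
      list(label = nm, seq = if (strand == "-") revcomp(sq) else sq,
           meta = list(kind = "gene", gene = nm, strand = strand))
  }

  elements <- elements[sample(length(elements))]
  # trans-spliced pieces must be remotely located: pin them to the start,
  # middle and end of the element order
  ts_idx <- which(vapply(elements, function(e)
    identical(e$meta$kind, "ts_piece"), TRUE))
  if (length(ts_idx) == 3L) {
    pieces <- elements[ts_idx]
    pieces <- pieces[order(vapply(pieces, function(e) e$meta$piece, ""))]
    rest <- elements[-ts_idx]
    mid <- max(1L, length(rest) %/% 2L)
    elements <- c(pieces[1], rest[seq_len(mid)], pieces[2],
                  if (mid < length(rest)) rest[(mid + 1L):length(rest)],
                  pieces[3])
  }
  scaf <- split_scaffold(jc_mutate(focal_scaffold, 0.02),
                         length(elements) + 1L)
  asm <- assemble_blocks(scaf, elements)
  g <- genome("recipient", asm$sequence)

  # ---- truth tables ----
  coords <- asm$coords
  meta <- lapply(elements, `[[`, "meta")
  kind <- vapply(meta, `[[`, "", "kind")
  truth_genes <- NULL
  gi <- which(kind == "gene")
  if (length(gi)) {
    truth_genes <- data.frame(
      gene = vapply(meta[gi], `[[`, "", "gene"),
      start = coords$start[gi], end = coords$end[gi],
      strand = vapply(meta[gi], `[[`, "", "strand"),
      stringsAsFactors = FALSE)
  }
  ri <- which(kind == "repeat")
  if (length(ri)) {
    truth_repeats <- data.frame(
      repeat_id = vapply(meta[ri], `[[`, "", "repeat_id"),
      copy = vapply(meta[ri], function(m) m$copy, 0L),
      start = coords$start[ri], end = coords$end[ri],
      identity_percent = vapply(meta[ri], function(m) m$identity, 0),
      inverted = vapply(meta[ri], function(m) isTRUE(m$inverted), TRUE),
      stringsAsFactors = FALSE)
  }
  mi <- which(kind == "mtpt")
  if (length(mi)) {
    truth_mtpt <- data.frame(
      mtpt_id = coords$label[mi],
      start = coords$start[mi], end = coords$end[mi],
      donor = vapply(meta[mi], `[[`, "", "donor"),
      donor_order = vapply(meta[mi], `[[`, "", "donor_order"),
      plastid_gene = vapply(meta[mi], `[[`, "", "plastid_gene"),
      stringsAsFactors = FALSE)
  }
  hi <- which(kind == "hgt")
  if (length(hi)) {
    truth_hgt <- data.frame(
      hgt_id = coords$label[hi],
      start = coords$start[hi], end = coords$end[hi],
      donor_order = vapply(meta[hi], `[[`, "", "donor_order"),
      gene = vapply(meta[hi], `[[`, "", "gene"),
      stringsAsFactors = FALSE)
  }
  truth_ts <- NULL
  ti <- which(kind == "ts_piece")
  if (length(ti)) {
    truth_ts <- data.frame(
      gene = vapply(meta[ti], `[[`, "", "gene"),
      piece = vapply(meta[ti], `[[`, "", "piece"),
      start = coords$start[ti], end = coords$end[ti],
      strand = vapply(meta[ti], `[[`, "", "strand"),
      stringsAsFactors = FALSE)
    truth_ts <- truth_ts[order(match(truth_ts$piece,
                                     c("exon1a", "exon1b", "exon2"))), ]
  }
  if (length(edit_cds_pos)) {
    eg <- cfg$edit_gene
    gr <- truth_genes[truth_genes$gene == eg, ]
    gpos <- if (gr$strand == "+") gr$start + edit_cds_pos
            else gr$end - 1L - edit_cds_pos
    truth_edits <- data.frame(gene = eg, cds_pos = edit_cds_pos,
                              genome_pos = gpos, strand = gr$strand,
                              stringsAsFactors = FALSE)
  }

  # nuclear genome with diverged copies of withheld genes
  nuclear <- NULL; truth_nuclear <- NULL
  if (length(cfg$nuclear_spec)) {
    nspec <- norm_spec(cfg$nuclear_spec,
                       list(gene = cfg$missing_genes[1],
                            identity_percent = 70, intact = TRUE))
    nels <- list()
    for (i in seq_along(nspec)) {
      ns <- nspec[[i]]
      src <- panel$genes[[ns$gene]][[taxon1(focal)]]
      n_sub <- round(nchar(src) * (100 - ns$identity_percent) / 100)
      sq <- fix_internal_stops(mutate_n(src, n_sub))
      substr(sq, 1L, 3L) <- "ATG"                     # keep the ORF assessable
      substr(sq, nchar(sq) - 2L, nchar(sq)) <- "TAA"
      if (!isTRUE(ns$intact)) {
        # plant an internal stop one third of the way in
        k <- (nchar(sq) %/% 3L) %/% 3L
        substr(sq, 3 * k - 2, 3 * k) <- "TAA"
      }
      nels[[i]] <- list(label = paste0("nuc_", ns$gene), seq = sq,
                        meta = list(gene = ns$gene, intact = isTRUE(ns$intact)))
    }
    nscaf <- split_scaffold(random_dna(20000L), length(nels) + 1L)
    nasm <- assemble_blocks(nscaf, nels)
    nuclear <- genome("nuclear", nasm$sequence)
    truth_nuclear <- data.frame(
      gene = vapply(nels, function(e) e$meta$gene, ""),
      start = nasm$coords$start, end = nasm$coords$end,
      intact = vapply(nels, function(e) e$meta$intact, TRUE),
      stringsAsFactors = FALSE)
  }

  truth <- list(genes = truth_genes, repeats = truth_repeats,
                mtpt = truth_mtpt, hgt = truth_hgt,
                transsplice = truth_ts, edits = truth_edits,
                nuclear = truth_nuclear,
                recomb_fraction = cfg$recomb_fraction,
                seed = cfg$seed)
  list(genome = g, truth = truth, references = ref_mitos,
       own_plastome = plastomes[[focal]]$genome,
       foreign_plastomes = lapply(plastomes[setdiff(orders, focal)],
                                  function(p) p$genome),
       plastome_coords = lapply(plastomes, `[[`, "coords"),
       nuclear = nuclear,
       recipient_genes = recipient_genes)
}

# ---- long reads -------------------------------------------------------------

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < rate)
  paste(substitute_at(x, hit), collapse = "")
}

#' Simulate long reads with repeat-mediated crossovers
#'
#' Draws reads of approximately `long_read_length_mean` bases uniformly from
#' the recipient genome.  A read that fully spans a planted repeat copy with
#' at least `anchor_bp` of flank on both sides is, with probability
#' `recomb_fraction`, converted into a crossover product: its left flank
#' stays at the sampled copy, and from a uniformly chosen point inside the
#' repeat onwards the sequence continues through the other copy and its
#' right flank.  Per-base substitution errors are applied at
#' `long_read_error`, and each read is emitted on a random strand.
#'
#' @param g Recipient [genome].
#' @param truth Truth set from [build_recipient_genome()].
#' @param cfg The [sim_config].
#' @param anchor_bp Minimum flank on each side for a read to count as
#'   spanning.
#' @return A list with `reads` (list of [read_record]) and `truth` (per-read
#'   data frame: start, length, repeat id, sampled copy, crossover flag).
#' @export
simulate_long_reads <- function(g, truth, cfg, anchor_bp = 100L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 3L))
  L <- nchar(g$sequence)
  reps <- truth$repeats
  if (cfg$recomb_fraction > 0 &&
      (is.null(reps) || !any(reps$end - reps$start >= 500L))) {
    stop("recomb_fraction > 0 requires at least one planted repeat >= 500 bp")
  }
  if (!is.null(reps) &&
      cfg$long_read_length_mean < max(reps$end - reps$start) + 2L * anchor_bp) {
    warning("read length below repeat + 2*anchor; repeats unassessable")
  }
  n <- cfg$n_long_reads
  lens <- pmax(200L, round(stats::rnorm(n, cfg$long_read_length_mean,
                                        0.1 * cfg$long_read_length_mean)))
  lens <- pmin(lens, L)
  starts <- vapply(lens, function(l) sample(L - l + 1L, 1L) - 1L, 0L)
  reads <- vector("list", n)
  tr <- data.frame(read_id = paste0("lr_", seq_len(n)), start = starts,
                   length = lens, repeat_id = NA_character_,
                   copy = NA_integer_, crossover = FALSE,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    st <- starts[i]; en <- st + lens[i]
    sq <- subseq_str(g$sequence, st, en)
    if (!is.null(reps)) {
      sp <- which(reps$start - st >= anchor_bp & en - reps$end >= anchor_bp)
      if (length(sp)) {
        j <- sp[1]
        tr$repeat_id[i] <- reps$repeat_id[j]
        tr$copy[i] <- reps$copy[j]
        mates <- which(reps$repeat_id == reps$repeat_id[j] &
                         reps$copy != reps$copy[j])
        if (length(mates) && stats::runif(1) < cfg$recomb_fraction) {
          k <- mates[1]
          rep_len <- reps$end[j] - reps$start[j]
          cross <- sample(rep_len - 1L, 1L)       # uniform inside the repeat
          left <- subseq_str(g$sequence, st, reps$start[j] + cross)
          right_need <- lens[i] - nchar(left)
          right_from <- reps$start[k] + cross
          right <- subseq_str(g$sequence, right_from,
                              min(L, right_from + right_need))
          sq <- paste0(left, right)
          tr$crossover[i] <- TRUE
          tr$length[i] <- nchar(sq)
        }
      }
    }
    sq <- apply_errors(sq, cfg$long_read_error)
    if (stats::runif(1) < 0.5) sq <- revcomp(sq)
    reads[[i]] <- read_record(tr$read_id[i], sq)
  }
  list(reads = reads, truth = tr)
}

# ---- transcript reads -------------------------------------------------------

#' Simulate edited, trans-spliced transcript read pairs
#'
#' Builds mature transcripts for every annotated gene in the truth set: the
#' coding-strand CDS with C-to-T substitutions applied at the planted edit
#' sites.  For the trans-spliced gene, two products are emitted - the
#' spliced exon1b+exon2 mRNA and a separate exon1a product - so read pairs
#' exist across the trans-spliced junction but none join the two portions of
#' exon 1.  Paired 150 bp reads are drawn at the configured coverage with
#' substitution errors.
#'
#' @param g Recipient [genome].
#' @param truth Truth set from [build_recipient_genome()].
#' @param cfg The [sim_config].
#' @return A list with `reads` (list of paired [read_record]) and `truth`
#'   (per-pair transcript of origin and fragment coordinates).
#' @export
simulate_transcript_reads <- function(g, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 4L))
  transcripts <- list()
  if (!is.null(truth$genes)) {
    for (r in seq_len(nrow(truth$genes))) {
      gene <- truth$genes$gene[r]
      sq <- subseq_str(g$sequence, truth$genes$start[r], truth$genes$end[r])
      if (truth$genes$strand[r] == "-") sq <- revcomp(sq)
      if (!is.null(truth$edits) && gene %in% truth$edits$gene) {
        pos <- truth$edits$cds_pos[truth$edits$gene == gene]
        x <- strsplit(sq, "", fixed = TRUE)[[1]]
        if (any(x[pos + 1L] != "C")) {
          stop("config error: edit site is not a C on the coding strand")
        }
        x[pos + 1L] <- "T"
        sq <- paste(x, collapse = "")
      }
      transcripts[[gene]] <- sq
    }
  }
  if (!is.null(truth$transsplice)) {
    ts <- truth$transsplice
    piece_seq <- function(piece) {
      r <- ts[ts$piece == piece, ]
      sq <- subseq_str(g$sequence, r$start, r$end)
      if (r$strand == "-") revcomp(sq) else sq
    }
    tg <- ts$gene[1]
    transcripts[[paste0(tg, "_mature")]] <-
      paste0(piece_seq("exon1b"), piece_seq("exon2"))
    transcripts[[paste0(tg, "_exon1a")]] <- piece_seq("exon1a")
  }
  rl <- cfg$transcript_read_length
  reads <- list(); rows <- list()
  for (tn in names(transcripts)) {
    tl <- nchar(transcripts[[tn]])
    if (tl < rl) next
    n_frag <- max(3L, round(cfg$transcript_coverage * tl / (2 * rl)))
    for (k in seq_len(n_frag)) {
      fl <- min(tl, max(rl, round(stats::rnorm(1, cfg$insert_mean, 30))))
      fs <- sample(tl - fl + 1L, 1L) - 1L
      frag <- subseq_str(transcripts[[tn]], fs, fs + fl)
      r1 <- apply_errors(substr(frag, 1L, rl), cfg$transcript_error)
      r2 <- apply_errors(revcomp(substr(frag, nchar(frag) - rl + 1L,
                                        nchar(frag))), cfg$transcript_error)
      id <- paste0("tr_", tn, "_", k)
      reads[[length(reads) + 1L]] <-
        read_record(paste0(id, "/1"), r1, paired_with = paste0(id, "/2"))
      reads[[length(reads) + 1L]] <-
        read_record(paste0(id, "/2"), r2, paired_with = paste0(id, "/1"))
      rows[[length(rows) + 1L]] <-
        data.frame(pair_id = id, transcript = tn, frag_start = fs,
                   frag_end = fs + fl, stringsAsFactors = FALSE)
    }
  }
  list(reads = reads,
       truth = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Generate a complete synthetic bundle
#'
#' Convenience wrapper running [simulate_reference_set()],
#' [build_recipient_genome()], [simulate_long_reads()] and
#' [simulate_transcript_reads()] under one configuration.
#'
#' @param cfg A [sim_config].
#' @return A list with `panel`, `recipient` (genome + truth + references),
#'   `long_reads`, `transcript_reads` and the `config`.
#' @export
simulate_bundle <- function(cfg) {
  panel <- simulate_reference_set(cfg)
  rec <- build_recipient_genome(cfg, panel)
  lr <- simulate_long_reads(rec$genome, rec$truth, cfg)
  tx <- simulate_transcript_reads(rec$genome, rec$truth, cfg)
  list(panel = panel, recipient = rec, long_reads = lr,
       transcript_reads = tx, config = cfg)
}
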