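test_that("anchor alignment recovers identity, reverse complement and rearranged halves", {
  set.seed(42)
  a <- rand_dna(10000)
  gA <- dna_set(c(chrA = a))

  # identical sequences -> one forward full-length block at identity 100
  b1 <- anchor_align(gA, dna_set(c(chrB = a)), min_block = 1000)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$ref_start, 0)
  expect_equal(b1$ref_end, 10000)
  expect_equal(b1$orientation, "forward")
  expect_equal(b1$pct_identity, 100)

  # reverse complement -> one reverse block at identity 100
  b2 <- anchor_align(gA, dna_set(c(chrB = revcomp(a))), min_block = 1000)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$orientation, "reverse")
  expect_equal(b2$pct_identity, 100)
  expect_equal(b2$ref_end - b2$ref_start, 10000)

  # two 5-kb halves swapped -> two forward blocks, each mapping one half
  swapped <- paste0(substr(a, 5001, 10000), substr(a, 1, 5000))
  b3 <- anchor_align(gA, dna_set(c(chrB = swapped)), min_block = 1000)
  expect_equal(nrow(b3), 2L)
  b3 <- b3[order(b3$ref_start), ]
  expect_equal(b3$ref_start, c(0, 5000))
  expect_equal(b3$qry_start, c(5000, 0))
  # verify by direct substring comparison
  for (i in 1:2) {
    expect_identical(substr(a, b3$ref_start[i] + 1, b3$ref_end[i]),
                     substr(swapped, b3$qry_start[i] + 1, b3$qry_end[i]))
  }

  # self-alignment gives a full-length identity-100 self block
  bs <- anchor_align(gA, gA, min_block = 1000)
  expect_equal(nrow(bs), 1L)
  expect_equal(bs$pct_identity, 100)
  expect_equal(c(bs$ref_start, bs$ref_end), c(bs$qry_start, bs$qry_end))
})

test_that("block filtering applies strict thresholds at the boundaries", {
  b <- data.frame(ref_seqid = "c", ref_start = c(0, 0, 0),
                  ref_end = c(5000, 3999, 5000), qry_seqid = "c",
                  qry_start = 0, qry_end = c(5000, 3999, 5000),
                  orientation = "forward",
                  pct_identity = c(95, 99, 94.9), stringsAsFactors = FALSE)
  f <- filter_blocks(b, 95, 4000)
  expect_equal(nrow(f), 1L)
  expect_equal(f$pct_identity, 95)
  expect_equal(nrow(filter_blocks(b[0, ], 95, 4000)), 0L)
})

test_that("specific regions are the merged complement of block coverage", {
  g <- dna_set(c(chr1 = rand_dna(10000, seed = 1)))
  cover <- function(ivs) data.frame(
    ref_seqid = "chr1", ref_start = sapply(ivs, `[`, 1),
    ref_end = sapply(ivs, `[`, 2), qry_seqid = "x",
    qry_start = sapply(ivs, `[`, 1), qry_end = sapply(ivs, `[`, 2),
    orientation = "forward", pct_identity = 99, stringsAsFactors = FALSE)

  r <- detect_specific_regions(g, list(cover(list(c(0, 4000), c(6000, 10000)))),
                               min_region = 1000, merge_gap = 0)
  expect_equal(r$start, 4000)
  expect_equal(r$end, 6000)

  # full coverage -> nothing
  r2 <- detect_specific_regions(g, list(cover(list(c(0, 10000)))),
                                min_region = 1000, merge_gap = 0)
  expect_equal(nrow(r2), 0L)

  # specific means uncovered by EVERY comparator
  r3 <- detect_specific_regions(
    g, list(cover(list(c(0, 4000), c(6000, 10000))),   # hole [4000,6000)
            cover(list(c(0, 10000)))),                 # covers everything
    min_region = 1000, merge_gap = 0)
  expect_equal(nrow(r3), 0L)

  expect_error(detect_specific_regions(g, list(cover(list(c(0, 10))) |>
    transform(ref_seqid = "nope")), 1, 0), "unknown")
})

test_that("specific-region calls match brute-force per-base counting on fuzzed inputs", {
  set.seed(7)
  for (trial in 1:25) {
    L <- sample(2000:100000, 1)
    g <- dna_set(setNames(list(Biostrings::DNAString(paste(rep("A", L), collapse = ""))), "c"))
    n_blocks <- sample(0:12, 1)
    ivs <- lapply(seq_len(n_blocks), function(i) {
      s <- sample(0:(L - 10), 1)
      e <- min(L, s + sample(10:20000, 1))
      c(s, e)
    })
    blocks <- if (n_blocks) data.frame(
      ref_seqid = "c", ref_start = sapply(ivs, `[`, 1),
      ref_end = sapply(ivs, `[`, 2), qry_seqid = "q",
      qry_start = sapply(ivs, `[`, 1), qry_end = sapply(ivs, `[`, 2),
      orientation = "forward", pct_identity = 99, stringsAsFactors = FALSE)
    else data.frame(ref_seqid = character(),
      ref_start = numeric(), ref_end = numeric(), qry_seqid = character(),
      qry_start = numeric(), qry_end = numeric(), orientation = character(),
      pct_identity = numeric(), stringsAsFactors = FALSE)
    min_region <- sample(c(1, 100, 5000), 1)
    merge_gap <- sample(c(0, 50, 1000), 1)
    got <- detect_specific_regions(g, list(blocks), min_region, merge_gap)
    want <- brute_force_regions(L, ivs, min_region, merge_gap)
    expect_equal(nrow(got), nrow(want), info = sprintf("trial %d", trial))
    if (nrow(got)) {
      expect_equal(got$start, want$start, info = sprintf("trial %d", trial))
      expect_equal(got$end, want$end, info = sprintf("trial %d", trial))
    }
    # coverage partition: covered union + complement tile [0, L)
    covered <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(blocks$ref_start + 1, blocks$ref_end))))
    complement <- brute_force_regions(L, ivs, 1, 0)
    expect_equal(covered + sum(complement$end - complement$start), L)
  }
})

test_that("raising thresholds never adds blocks or regions", {
  set.seed(11)
  blocks <- data.frame(
    ref_seqid = "c", ref_start = cumsum(sample(1000:5000, 10)),
    qry_seqid = "q", orientation = "forward",
    pct_identity = runif(10, 90, 100), stringsAsFactors = FALSE)
  blocks$ref_end <- blocks$ref_start + sample(1000:10000, 10)
  blocks$qry_start <- blocks$ref_start
  blocks$qry_end <- blocks$ref_end
  for (id in c(92, 95, 98)) {
    f1 <- filter_blocks(blocks, id, 2000)
    f2 <- filter_blocks(blocks, id + 1, 2000)
    expect_true(all(paste(f2$ref_start) %in% paste(f1$ref_start)))
    f3 <- filter_blocks(blocks, id, 3000)
    expect_true(all(paste(f3$ref_start) %in% paste(f1$ref_start)))
  }
  g <- dna_set(c(c = paste(rep("A", 60000), collapse = "")))
  r_small <- detect_specific_regions(g, list(blocks), 100, 0)
  r_big <- detect_specific_regions(g, list(blocks), 5000, 0)
  expect_true(all(r_big$start %in% r_small$start))
  # larger merge gaps only grow regions
  r_g1 <- detect_specific_regions(g, list(blocks), 100, 100)
  r_g2 <- detect_specific_regions(g, list(blocks), 100, 2000)
  for (i in seq_len(nrow(r_g1))) {
    expect_true(any(r_g2$start <= r_g1$start[i] & r_g2$end >= r_g1$end[i]))
  }
})

test_that("inversion chaining follows the anti-collinearity predicate", {
  rev_block <- function(rs, re, qs, qe) data.frame(
    ref_seqid = "c", ref_start = rs, ref_end = re, qry_seqid = "q",
    qry_start = qs, qry_end = qe, orientation = "reverse",
    pct_identity = 99, stringsAsFactors = FALSE)

  # one reverse block -> one call with those exact intervals
  one <- detect_inversions(rev_block(100, 200, 500, 600), chain_gap = 1000)
  expect_equal(nrow(one), 1L)
  expect_equal(one$ref_start, 100); expect_equal(one$ref_end, 200)
  expect_equal(one$qry_start, 500); expect_equal(one$qry_end, 600)
  expect_equal(one$n_blocks, 1L)

  # all-forward input -> nothing
  fwd <- rev_block(0, 100, 0, 100); fwd$orientation <- "forward"
  expect_equal(nrow(detect_inversions(fwd, 1000)), 0L)

  # two nearby anti-collinear blocks chain into one call
  two <- rbind(rev_block(1000, 2000, 9000, 10000),
               rev_block(2100, 3000, 7900, 8900))
  got <- detect_inversions(two, chain_gap = 500)
  expect_equal(nrow(got), 1L)
  expect_equal(got$n_blocks, 2L)
  expect_equal(got$ref_start, 1000); expect_equal(got$ref_end, 3000)
  expect_equal(got$qry_start, 7900); expect_equal(got$qry_end, 10000)

  # separated by more than chain_gap -> two calls
  far <- rbind(rev_block(1000, 2000, 9000, 10000),
               rev_block(5000, 6000, 4000, 5000))
  expect_equal(nrow(detect_inversions(far, chain_gap = 500)), 2L)

  # collinear (qry increasing) reverse blocks do not chain
  col <- rbind(rev_block(1000, 2000, 4000, 5000),
               rev_block(2100, 3000, 5100, 6000))
  expect_equal(nrow(detect_inversions(col, chain_gap = 500)), 2L)
})

test_that("region summaries count bases and clipped features correctly", {
  g <- dna_set(c(chr1 = paste0("NNNNNAAAAA", rand_dna(1990, seed = 2))))
  ann <- data.frame(seqid = "chr1", source = "s",
                    type = c("gene", "gene", "LTR_gypsy", "rDNA_45S"),
                    start = c(101, 951, 401, 1500), end = c(200, 1050, 600, 1600),
                    score = NA_real_, strand = "+", phase = ".",
                    attributes = "ID=x", stringsAsFactors = FALSE)

  head10 <- summarize_region(list(seqid = "chr1", start = 0, end = 10), g, ann)
  expect_equal(head10$pct_n, 50)
  expect_equal(head10$pct_gc, 0)

  s <- summarize_region(list(seqid = "chr1", start = 0, end = 1000), g, ann)
  expect_equal(s$n_genes, 2)
  expect_equal(s$cum_gene_len_bp, 100 + 50)   # second gene clipped at 1000
  expect_equal(s$n_tes, 1)
  expect_equal(s$cum_te_len_bp, 200)
  expect_equal(s$n_rdna, 0)

  # brute-force per-base check of the gene cumulative length
  per_base <- logical(1000)
  for (i in which(ann$type == "gene")) {
    lo <- max(1, ann$start[i]); hi <- min(1000, ann$end[i])
    if (lo <= hi) per_base[lo:hi] <- TRUE
  }
  expect_equal(s$cum_gene_len_bp, sum(per_base))

  none <- summarize_region(list(seqid = "chr1", start = 1700, end = 1800), g, ann)
  expect_equal(none$n_genes + none$n_tes + none$n_rdna, 0)
  expect_equal(none$cum_gene_len_bp + none$cum_te_len_bp + none$cum_rdna_len_bp, 0)

  expect_error(summarize_region(list(seqid = "chr1", start = 0, end = 99999), g, ann),
               "out of bounds")
})

test_that("column statistics follow the reporting conventions", {
  tab <- data.frame(length_bp = c(7268248, 6383565, 14501503, 30238921,
                                  2328069, 12354515),
                    n_genes = c(230, 118, 153, 419, 8, 35),
                    n_rdna = c(47, 7, 18, 61, 0, 20),
                    pct_n = c(25.51, 24.99, 21.90, 29.87, 27.25, 54.00))
  st <- summarize_table(tab)
  get <- function(col, what) st[st$column == col, what]
  # bp statistics truncate toward zero
  expect_equal(get("length_bp", "mean"), 12179136)
  expect_equal(get("length_bp", "median"), 9811381)
  # counts at 2 decimals; even-count median is the midpoint
  expect_equal(get("n_genes", "sum"), 963)
  expect_equal(get("n_genes", "mean"), 160.5)
  expect_equal(get("n_genes", "median"), 135.5)
  expect_equal(get("n_rdna", "mean"), 25.5)
  expect_equal(get("n_rdna", "median"), 19)
  # percents at 2 decimals
  expect_equal(get("pct_n", "mean"), 30.59)
  expect_equal(get("pct_n", "median"), 26.38)
  expect_error(summarize_table(tab[0, ]), "empty")
})

test_that("planted events are recovered end to end on a small genome pair", {
  cfg <- simulation_config(
    seed = 7, n_chromosomes = 2L, chrom_length = 3e5, n_genes = 10L,
    te_library = data.frame(family = c("gypsy1", "copia1"),
                            class = c("LTR_gypsy", "LTR_copia"),
                            consensus_length = c(3000, 2000),
                            copies_A = c(4L, 3L), copies_B = c(6L, 3L),
                            stringsAsFactors = FALSE),
    rdna_unit_length = 5000L, rdna_array_copies_A = 2L, rdna_array_copies_B = 2L,
    planted_insertions = data.frame(chrom = c(1L, 2L),
                                    position = c(1e5, 15e4),
                                    length = c(3e4, 4e4),
                                    w_rdna = c(0.4, 0.3), w_te = c(0.3, 0.3),
                                    w_random = c(0.3, 0.4)),
    planted_inversions = data.frame(chrom = 1L, start = 2e5, length = 25e3),
    snp_divergence = 0.01)
  sim <- simulate_genome_pair(cfg)
  blocks <- anchor_align(sim$genome_B, sim$genome_A, min_block = 1000)
  f <- filter_blocks(blocks, 95, 4000)
  regions <- detect_specific_regions(sim$genome_B, list(f),
                                     min_region = 2e4, merge_gap = 5000)
  planted <- sim$truth$insertions[sim$truth$insertions$kind == "planted", ]
  for (i in seq_len(nrow(planted))) {
    hit <- regions[regions$seqid == planted$seqid[i] &
                   abs(regions$start - planted$start[i]) <= 5000 &
                   abs(regions$end - planted$end[i]) <= 5000, ]
    expect_equal(nrow(hit), 1L, info = sprintf("insertion %d", i))
  }
  inv <- detect_inversions(f, chain_gap = 10000)
  tru <- sim$truth$inversions
  for (i in seq_len(nrow(tru))) {
    hit <- inv[inv$ref_seqid == tru$seqid[i] &
               abs(inv$ref_start - tru$b_start[i]) <= 10000 &
               abs(inv$ref_end - tru$b_end[i]) <= 10000, ]
    expect_equal(nrow(hit), 1L, info = sprintf("inversion %d", i))
  }
})
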