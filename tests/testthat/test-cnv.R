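# mutate a string at given 1-based positions (to a fixed different base)
sub_at <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  v[pos] <- ifelse(v[pos] == "A", "C", "A")
  paste(v, collapse = "")
}

test_that("global-alignment identity handles matches, mismatches and disjoint inputs", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwise_identity("AAAA", "AATA"), 75)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
})

test_that("single-linkage clustering joins through intermediates only", {
  set.seed(5)
  base <- rand_dna(100)
  idm3 <- dna_set(c(s1 = base, s2 = base, s3 = base))
  cl <- cluster_sequences(idm3, 90)
  expect_equal(length(cl), 1L)
  expect_equal(sort(cl[[1]]$members), c("s1", "s2", "s3"))

  # A-B 92%, B-C 92%, A-C 84%: single linkage still gives one cluster
  A <- sub_at(base, 1:8)        # 8 subs in the first half
  C <- sub_at(base, 93:100)     # 8 subs in the last positions
  tri <- dna_set(c(A = A, B = base, C = C))
  expect_gt(pairwise_identity(A, base), 90)
  expect_gt(pairwise_identity(C, base), 90)
  expect_lt(pairwise_identity(A, C), 90)
  cl2 <- cluster_sequences(tri, 90)
  expect_equal(length(cl2), 1L)
  expect_equal(sort(cl2[[1]]$members), c("A", "B", "C"))

  # two sequences at 85% stay apart
  far <- dna_set(c(x = base, y = sub_at(base, seq(1, 99, length.out = 15))))
  expect_equal(length(cluster_sequences(far, 90)), 2L)
})

test_that("consensus follows majority rule with alphabetical ties", {
  s <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
  same <- dna_set(c(a = s, b = s, c = s))
  cons <- build_consensus(same)
  expect_equal(as.character(cons[[1]]), s)

  # one site differs: majority A over G
  v <- strsplit(s, "")[[1]]
  v[5] <- "G"
  maj <- dna_set(c(a = s, b = s, c = paste(v, collapse = "")))
  expect_equal(as.character(build_consensus(maj)[[1]]), s)

  # two-member tie at a site: alphabetical winner (A beats G)
  tie <- dna_set(c(a = s, b = paste(v, collapse = "")))
  expect_equal(substr(as.character(build_consensus(tie)[[1]]), 5, 5), "A")
})

test_that("mean depth from an exact tiling and tie-splitting behave as defined", {
  set.seed(9)
  ref <- rand_dna(500)
  # 5 copies of each of the 5 non-overlapping 100-bp tiles -> depth 5.0
  tiles <- substring(ref, seq(1, 401, by = 100), seq(100, 500, by = 100))
  reads <- Biostrings::DNAStringSet(rep(tiles, each = 5))
  names(reads) <- paste0("r", seq_along(reads))
  d <- map_reads_depth(reads, dna_set(c(ref1 = ref)), k = 21)
  expect_equal(unname(d["ref1"]), 5.0)

  # unrelated reads find nothing
  noise <- Biostrings::DNAStringSet(setNames(rand_dna(100), "n1"))
  expect_equal(unname(map_reads_depth(noise, dna_set(c(ref1 = ref)), k = 21)["ref1"]), 0)

  # a read matching two identical references accrues 0.5 to each
  two <- dna_set(c(refA = ref, refB = ref))
  one_read <- Biostrings::DNAStringSet(setNames(substring(ref, 1, 100), "r1"))
  d2 <- map_reads_depth(one_read, two, k = 21)
  expect_equal(unname(d2["refA"]), unname(d2["refB"]))
  expect_equal(unname(d2["refA"]), 0.5 * 100 / 500)

  expect_error(map_reads_depth(one_read, dna_set(character(0)), k = 21),
               "empty reference")
})

test_that("reverse-complement reads map at the correct position", {
  set.seed(10)
  ref <- rand_dna(300)
  rc_read <- revcomp(substring(ref, 101, 200))
  d <- map_reads_depth(Biostrings::DNAStringSet(setNames(rc_read, "r1")),
                       dna_set(c(ref1 = ref)), k = 21)
  expect_equal(unname(d["ref1"]), 100 / 300)
})

test_that("single-copy calibration is the median of per-gene depths", {
  expect_equal(calibrate_single_copy(c(9, 10, 11)), 10)
  expect_equal(calibrate_single_copy(10), 10)
  expect_equal(calibrate_single_copy(c(8, 12)), 10)
  expect_error(calibrate_single_copy(numeric(0)), "no gene depths")
})

test_that("copy number is the depth ratio with guarded calibration", {
  expect_equal(estimate_copy_number(100, 10), 10)
  expect_equal(estimate_copy_number(0, 10), 0)
  expect_error(estimate_copy_number(10, 0), "calibration")
})

test_that("clustering the consensus set again yields singletons", {
  set.seed(21)
  fams <- dna_set(c(f1_a = rand_dna(300), f2_a = rand_dna(300),
                    f3_a = rand_dna(300)))
  cl <- cluster_sequences(fams, 90)
  consensi <- do.call(c, lapply(cl, build_consensus, seqs = fams))
  cl2 <- cluster_sequences(consensi, 90)
  expect_equal(length(cl2), length(consensi))
})

test_that("doubling the read set leaves copy-number estimates unchanged", {
  set.seed(33)
  genome_len <- 40000
  g <- rand_dna(genome_len)
  # plant one 500-bp repeat at 8 copies and 6 single-copy genes of 500 bp
  rep_seq <- rand_dna(500)
  genes <- replicate(6, rand_dna(500))
  pieces <- character()
  pos <- seq(1, 39000, by = 2800)[1:14]
  planted <- c(rep(list(rep_seq), 8), lapply(seq_len(6), function(i) genes[i]))
  gv <- strsplit(g, "")[[1]]
  for (i in seq_along(pos)) {
    s <- pos[i]
    seg <- strsplit(planted[[i]], "")[[1]]
    gv[s:(s + 499)] <- seg
  }
  g <- paste(gv, collapse = "")
  sim_reads <- function(cov, seed) {
    set.seed(seed)
    n <- floor(cov * genome_len / 100)
    starts <- sample(genome_len - 99, n, replace = TRUE)
    out <- substring(g, starts, starts + 99)
    rev <- runif(n) < 0.5
    out[rev] <- vapply(out[rev], revcomp, character(1), USE.NAMES = FALSE)
    Biostrings::DNAStringSet(setNames(out, paste0("r", seq_len(n))))
  }
  refs <- dna_set(c(rep1 = rep_seq))
  gene_refs <- dna_set(setNames(genes, paste0("gene", 1:6)))
  run <- function(reads) {
    estimate_family_copy_numbers(reads, refs, gene_refs, family = "rep")
  }
  r10 <- sim_reads(10, 1)
  res10 <- run(r10)
  # doubling the read set (c = 2) doubles every depth and leaves the
  # copy-number ratio untouched
  doubled <- c(r10, r10)
  names(doubled) <- paste0("d", seq_along(doubled))
  res20 <- run(doubled)
  expect_equal(res20$table$mean_depth, 2 * res10$table$mean_depth,
               tolerance = 1e-9)
  expect_lt(abs(res20$table$copy_number - res10$table$copy_number) /
              res10$table$copy_number, 0.05)
  expect_equal(round(res10$table$copy_number), 8)
  # the calibration genes themselves sit at copy number 1 exactly
  expect_equal(median(res10$gene_depths_effective) / res10$calibration_depth, 1)
})
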