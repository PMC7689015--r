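msa_from <- function(x) as_alignment(x)

test_that("alignment trimming applies the end-presence and gap-column rules", {
  clean <- msa_from(c(a = "ACGT", b = "ACGA", c = "ACGG", d = "ACGC"))
  expect_identical(trim_alignment(clean), clean)

  # first column present in exactly 1 of 4 rows (25%): the end rule keeps
  # it (strictly-less-than strip), which shows when the internal gap
  # filter is disabled; with the default gap filter it is then removed
  # as a 75%-gap column
  kept <- msa_from(c(a = "ACGT", b = "-CGA", c = "-CGG", d = "-CGC"))
  expect_equal(ncol(trim_alignment(kept, gap_col_frac = 1)), 4)
  expect_equal(ncol(trim_alignment(kept)), 3)

  # leading column present in 0 rows is stripped
  lead <- msa_from(c(a = "-CGT", b = "-CGA", c = "-CGG", d = "-CGC"))
  expect_equal(ncol(trim_alignment(lead)), 3)

  # internal column with gaps in 2 of 4 rows (50% > 25%) is removed
  gappy <- msa_from(c(a = "AC-T", b = "AC-A", c = "ACGG", d = "ACGC"))
  tr <- trim_alignment(gappy)
  expect_equal(ncol(tr), 3)

  # trimming never lengthens and is idempotent
  set.seed(3)
  rows <- replicate(5, paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                                    prob = c(0.2, 0.2, 0.2, 0.2, 0.2)),
                             collapse = ""))
  m <- msa_from(setNames(rows, paste0("t", 1:5)))
  t1 <- trim_alignment(m)
  expect_lte(ncol(t1), ncol(m))
  expect_identical(trim_alignment(t1), t1)

  allgap <- msa_from(c(a = "----", b = "----", c = "----"))
  expect_error(trim_alignment(allgap), "every column")
})

test_that("Jukes-Cantor distances follow the closed form with pairwise deletion", {
  same <- msa_from(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(jc_distance(same)["a", "b"], 0)

  # p = 0.1 over 10 comparable sites
  one <- msa_from(c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  expect_equal(round(jc_distance(one)["a", "b"], 5), 0.10733)

  # saturation: p >= 0.75 capped with a warning
  sat <- msa_from(c(a = "AAAAAAAA", b = "CCCCCCGG"))
  expect_warning(d <- jc_distance(sat), "capped")
  expect_equal(d["a", "b"], 5)

  # pairwise deletion: gaps in one row do not kill the comparison
  gap <- msa_from(c(a = "AC--ACGT", b = "ACGTACGT", c = "ACGTACGA"))
  expect_equal(jc_distance(gap)["a", "b"], 0)

  none <- msa_from(c(a = "AC--", b = "--GT", c = "ACGT"))
  expect_error(jc_distance(none), "no comparable sites")

  # monotonicity of d in p on [0, 0.75)
  p <- seq(0, 0.74, by = 0.02)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  # hand-built additive matrix from ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(D)
  expect_equal(tree_path_lengths(tree)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # AB|CD split present: drop one edge and check the bipartition
  want <- ape::read.tree(text = "((A:1,B:2):0.5,(C:3,D:4):0.5);")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(want)), 0,
               ignore_attr = TRUE)

  # three taxa: closed-form star lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  pl <- tree_path_lengths(t3)
  expect_equal(pl["a", "b"], 2, tolerance = 1e-9)
  expect_equal(pl["a", "c"], 3, tolerance = 1e-9)
  expect_equal(pl["b", "c"], 3, tolerance = 1e-9)

  bad <- D; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), "symmetric")

  # all-equal distances: all terminal branches equal
  De <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  te <- neighbor_joining(De)
  term <- te$edge.length[match(seq_len(4), te$edge[, 2])]
  expect_true(all(abs(term - term[1]) < 1e-9))
})

test_that("neighbor joining is consistent on random additive matrices", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    ref <- random_additive_matrix(n)
    got <- neighbor_joining(ref$D)
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(ref$tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(tree_path_lengths(got)[rownames(ref$D), colnames(ref$D)],
                 ref$D, tolerance = 1e-9)
  }
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  # two clades separated by many diagnostic columns, plus private sites
  set.seed(12)
  anc <- strsplit(rand_dna(120), "")[[1]]
  other <- function(x) vapply(x, function(b) setdiff(c("A","C","G","T"), b)[1], "")
  div <- anc; div[1:45] <- other(anc[1:45])
  mm <- rbind(t1 = anc, t2 = anc, t3 = anc, t4 = div, t5 = div)
  for (i in 1:5) mm[i, 50 + i] <- other(mm[i, 50 + i])
  tr <- bootstrap_support(mm, n_reps = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup == 100))

  tr2 <- bootstrap_support(mm, n_reps = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)

  plain <- bootstrap_support(mm, n_reps = 0)
  expect_null(plain$node.label)
})

test_that("long-branch pruning removes outlier taxa and rebuilds", {
  set.seed(8)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  mutate_str <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), n)
    v[pos] <- vapply(v[pos], function(x) setdiff(c("A", "C", "G", "T"), x)[1], "")
    paste(v, collapse = "")
  }
  taxa <- c(t1 = mutate_str(base, 2), t2 = mutate_str(base, 3),
            t3 = mutate_str(base, 2), t4 = mutate_str(base, 3),
            t5 = mutate_str(base, 4),
            weird = mutate_str(base, 120))   # wildly divergent leaf
  m <- msa_from(taxa)
  tree <- suppressWarnings(neighbor_joining(jc_distance(m)))
  res <- suppressWarnings(prune_long_branches(tree, m, factor = 10))
  expect_true("weird" %in% res$removed)
  expect_false("weird" %in% res$tree$tip.label)
  expect_equal(sort(rownames(res$msa)), sort(setdiff(names(taxa), res$removed)))

  # balanced data: nothing pruned; infinite factor: nothing pruned
  bal <- msa_from(taxa[1:5])
  btree <- neighbor_joining(jc_distance(bal))
  expect_length(prune_long_branches(btree, bal, factor = 10)$removed, 0)
  expect_length(suppressWarnings(prune_long_branches(tree, m, factor = Inf))$removed, 0)
})
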