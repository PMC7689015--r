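# Brute-force oracles and small fixture builders shared by the suite.

# per-base oracle for specific-region detection on one chromosome:
# coverage array -> uncovered runs -> merge runs separated by covered
# stretches shorter than merge_gap -> length filter
brute_force_regions <- function(L, block_intervals, min_region, merge_gap) {
  covered <- logical(L)
  for (iv in block_intervals) {
    if (iv[2] > iv[1]) covered[(iv[1] + 1):iv[2]] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  uncov <- data.frame(start = starts[!r$values] - 1, end = ends[!r$values])
  if (nrow(uncov) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  merged <- uncov[1, , drop = FALSE]
  for (i in seq_len(nrow(uncov))[-1]) {
    gap <- uncov$start[i] - merged$end[nrow(merged)]
    if (gap < merge_gap) {
      merged$end[nrow(merged)] <- uncov$end[i]
    } else {
      merged <- rbind(merged, uncov[i, ])
    }
  }
  out <- merged[merged$end - merged$start >= min_region, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

dna_set <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(x)
}

# distance matrix of a phylo tree by summing path lengths (independent
# of any package cophenetic implementation beyond basic tree traversal)
tree_path_lengths <- function(tree) {
  ape::cophenetic.phylo(tree)
}

# random additive (tree-metric) distance matrix from a random topology
random_additive_matrix <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.05, 1))
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  D <- tree_path_lengths(tree)
  D <- D[tree$tip.label, tree$tip.label]
  list(tree = tree, D = D)
}

# a tiny GFF3 file on disk
write_tmp_gff3 <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}
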