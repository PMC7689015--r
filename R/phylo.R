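# Neighbor-joining phylogenies of repeat sequences under the
# Jukes-Cantor model: end/gap trimming of the alignment, pairwise JC
# distances with pairwise deletion, NJ with non-negative branch
# post-processing, column-bootstrap supports, and long-branch pruning.

#' Coerce an aligned FASTA or sequence set to an alignment matrix
#'
#' @param x Path to an aligned FASTA, a [Biostrings::DNAStringSet], a
#'   named character vector of equal-length gapped rows, or already a
#'   character matrix.
#' @return Character matrix (rows = taxa) over `A,C,G,T,N,-`.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      x <- Biostrings::readBStringSet(x)
    }
    if (inherits(x, "XStringSet")) x <- setNames(as.character(x), names(x))
    rows <- strsplit(toupper(x), "")
    if (length(unique(lengths(rows))) != 1L) {
      stop_format("alignment rows differ in length")
    }
    m <- do.call(rbind, rows)
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop_format("alignment requires unique row (taxon) names")
  }
  m
}

#' Trim an alignment's sparse ends and gappy columns
#'
#' Leading and trailing columns are stripped while the fraction of rows
#' with a residue is strictly below `end_presence_frac` (a column at
#' exactly the threshold is kept); remaining columns whose gap fraction
#' is strictly above `gap_col_frac` are removed.
#'
#' @param msa Alignment (anything [as_alignment()] accepts).
#' @param end_presence_frac Minimum residue presence at the ends.
#' @param gap_col_frac Maximum tolerated internal gap fraction.
#' @return Trimmed character matrix.
#' @export
trim_alignment <- function(msa, end_presence_frac = 0.25, gap_col_frac = 0.25) {
  m <- as_alignment(msa)
  presence <- colMeans(m != "-")
  dense <- which(presence >= end_presence_frac)
  if (length(dense) == 0L) stop_format("trimming removed every column")
  m <- m[, dense[1L]:dense[length(dense)], drop = FALSE]
  gap_frac <- colMeans(m == "-")
  m <- m[, gap_frac <= gap_col_frac, drop = FALSE]
  if (ncol(m) == 0L) stop_format("trimming removed every column")
  m
}

#' Jukes-Cantor distance matrix with pairwise deletion
#'
#' For each pair, sites where both rows carry a residue (`A,C,G,T`) are
#' compared; with mismatch fraction `p`, `d = -(3/4) log(1 - (4/3) p)`.
#' Saturated pairs (`p >= 0.75`) get the finite `cap` with a warning.
#'
#' @param msa Alignment (anything [as_alignment()] accepts).
#' @param cap Distance assigned to saturated pairs.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
jc_distance <- function(msa, cap = 5) {
  m <- as_alignment(msa)
  n <- nrow(m)
  res <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  is_res <- matrix(m %in% DNA_BASES, nrow = n)
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- is_res[i, ] & is_res[j, ]
    nc <- sum(both)
    if (nc == 0L) {
      stop_format("no comparable sites between '%s' and '%s'",
                  rownames(m)[i], rownames(m)[j])
    }
    p <- sum(m[i, both] != m[j, both]) / nc
    if (p >= 0.75) {
      if (!warned) {
        warning(sprintf("saturated pair (p >= 0.75); distance capped at %g", cap),
                call. = FALSE)
        warned <- TRUE
      }
      d <- cap
    } else {
      d <- -0.75 * log(1 - 4 * p / 3)
    }
    res[i, j] <- res[j, i] <- d
  }
  res
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard agglomerative NJ on a symmetric distance matrix (the
#' Q-criterion, via [ape::nj()]); any negative branch length is then
#' clamped to zero with the deficit transferred to the adjacent branch
#' at the same node, preserving path lengths between the taxa joined
#' there.  The result is unrooted.
#'
#' @param D Symmetric numeric matrix (or `dist`) with zero diagonal.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop_format("distance matrix must be symmetric")
  }
  if (nrow(D) < 3L) stop_format("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(as.dist(D))
  clamp_negative_branches(tree)
}

# zero out negative edges, moving the deficit to the sibling edge(s)
# sharing the child node (the classical NJ negative-branch fix-up)
clamp_negative_branches <- function(tree) {
  el <- tree$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    deficit <- el[e]
    el[e] <- 0
    child <- tree$edge[e, 2L]
    sib <- which(tree$edge[, 1L] == child)
    if (length(sib)) el[sib] <- el[sib] + deficit
    else {
      # terminal negative edge: push the deficit to the sibling under
      # the same parent instead
      parent <- tree$edge[e, 1L]
      sib <- setdiff(which(tree$edge[, 1L] == parent), e)
      if (length(sib)) el[sib[1L]] <- el[sib[1L]] + deficit
    }
  }
  tree$edge.length <- pmax(el, 0)
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Columns are resampled with replacement `n_reps` times; each
#' replicate alignment is rebuilt (`jc_distance` then
#' `neighbor_joining`) and the support of every internal branch of the
#' original tree is the percentage of replicates containing the same
#' bipartition.  Deterministic for a given seed.
#'
#' @param msa Alignment (anything [as_alignment()] accepts), already
#'   trimmed.
#' @param n_reps Number of bootstrap replicates (0 returns the plain
#'   tree).
#' @param seed Integer seed.
#' @param cap Saturation cap passed to [jc_distance()].
#' @return An [ape::phylo] with integer percent supports in
#'   `node.label` (root label empty).
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L, cap = 5) {
  m <- as_alignment(msa)
  tree <- neighbor_joining(jc_distance(m, cap = cap))
  if (n_reps == 0L) return(tree)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      suppressWarnings(neighbor_joining(jc_distance(m[, cols, drop = FALSE],
                                                    cap = cap)))
    })
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps)
  labels <- as.character(support)
  labels[1L] <- ""                       # root of the unrooted representation
  tree$node.label <- labels
  tree
}

#' Remove long-branch leaves and rebuild
#'
#' Leaves whose terminal branch exceeds `factor` times the median
#' terminal branch length are removed and the tree is rebuilt from the
#' reduced alignment; at most `max_iter` rounds.
#'
#' @param tree [ape::phylo] built from `msa`.
#' @param msa The alignment the tree was built from.
#' @param factor Multiplier of the median terminal branch length.
#' @param max_iter Maximum pruning rounds.
#' @param cap Saturation cap for [jc_distance()].
#' @return `list(msa, tree, removed)` with the kept alignment, the
#'   rebuilt tree and the names of removed taxa.
#' @export
prune_long_branches <- function(tree, msa, factor = 10, max_iter = 2L, cap = 5) {
  m <- as_alignment(msa)
  removed <- character(0)
  for (it in seq_len(max_iter)) {
    term <- terminal_branch_lengths(tree)
    med <- median(term)
    drop <- names(term)[term > factor * med]
    if (length(drop) == 0L) break
    if (nrow(m) - length(drop) < 3L) {
      stop_format("pruning would leave fewer than 3 taxa")
    }
    removed <- c(removed, drop)
    m <- m[setdiff(rownames(m), drop), , drop = FALSE]
    tree <- suppressWarnings(neighbor_joining(jc_distance(m, cap = cap)))
  }
  list(msa = m, tree = tree, removed = removed)
}

terminal_branch_lengths <- function(tree) {
  tip_edges <- match(seq_along(tree$tip.label), tree$edge[, 2L])
  setNames(tree$edge.length[tip_edges], tree$tip.label)
}
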