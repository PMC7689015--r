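# Read-depth copy-number estimation of repeat families, calibrated on
# single-copy genes: identity clustering of repeat copies, majority-rule
# consensus building, a seed-and-extend read mapper, and the
# depth-ratio estimator.

#' Percent identity between two sequences under a global alignment
#'
#' Identity is matches over alignment length (gap columns included)
#' from a Needleman-Wunsch alignment with unit match/mismatch/gap
#' costs.
#'
#' @param a,b Character scalars or [Biostrings::DNAString]s.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- Biostrings::DNAString(as.character(a))
  b <- Biostrings::DNAString(as.character(b))
  stopifnot(length(a) > 0L, length(b) > 0L)
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = 0, gapExtension = 1)
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Cluster sequences by single-linkage at an identity threshold
#'
#' Edges connect pairs with global-alignment identity strictly above
#' `min_identity`; connected components are clusters (singletons
#' allowed).  A k-mer prefilter skips alignments between pairs sharing
#' no k-mers, which cannot reach the threshold.
#'
#' @param seqs Named [Biostrings::DNAStringSet] (or named character).
#' @param min_identity Threshold percent; default 90.
#' @return List of clusters, each a list with `members` (names) and
#'   `identities` (matrix of the computed pairwise identities).
#' @export
cluster_sequences <- function(seqs, min_identity = 90) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  stopifnot(n >= 1L, !is.null(names(seqs)))
  if (n == 1L) {
    return(list(list(members = names(seqs),
                     identities = matrix(100, 1, 1,
                                         dimnames = list(names(seqs), names(seqs))))))
  }
  # prefilter: pairs must share at least one 15-mer to be worth aligning
  k <- 15L
  kms <- lapply(seq_len(n), function(i) {
    s <- as.character(seqs[[i]])
    if (nchar(s) < k) return(s)
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  idm <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  diag(idm) <- 100
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!any(kms[[i]] %in% kms[[j]])) next
    pid <- pairwise_identity(seqs[[i]], seqs[[j]])
    idm[i, j] <- idm[j, i] <- pid
    if (pid > min_identity) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    list(members = names(seqs)[idx],
         identities = idm[idx, idx, drop = FALSE])
  })
}

#' Majority-rule consensus of a cluster
#'
#' Center-star construction: the member with the highest mean identity
#' to the others is the center; every member is globally aligned to the
#' center and projected onto center coordinates (insertions relative to
#' the center are dropped, deletions become gaps).  Per column the
#' majority residue wins, ties break alphabetically, and columns with
#' more than 50% gaps are removed.
#'
#' @param cluster One cluster from [cluster_sequences()], or a named
#'   [Biostrings::DNAStringSet] of members.
#' @param seqs When `cluster` is a cluster record, the full sequence set
#'   its `members` refer to.
#' @return A [Biostrings::DNAStringSet] of length 1 holding the
#'   consensus.
#' @export
build_consensus <- function(cluster, seqs = NULL) {
  if (is.list(cluster) && !is.null(cluster$members)) {
    stopifnot(!is.null(seqs))
    members <- seqs[cluster$members]
    idm <- cluster$identities
  } else {
    members <- cluster
    idm <- NULL
  }
  if (is.character(members)) members <- Biostrings::DNAStringSet(members)
  n <- length(members)
  stopifnot(n >= 1L)
  if (n == 1L) {
    out <- members
    names(out) <- paste0(names(members), "_consensus")
    return(out)
  }
  if (is.null(idm) || any(idm[upper.tri(idm)] == 0)) {
    idm <- matrix(100, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      idm[i, j] <- idm[j, i] <- pairwise_identity(members[[i]], members[[j]])
    }
  }
  center <- which.max(rowMeans(idm))
  cen <- members[[center]]
  Lc <- length(cen)
  # residue matrix in center coordinates; "-" marks a deletion
  mat <- matrix("-", nrow = n, ncol = Lc)
  mat[center, ] <- strsplit(as.character(cen), "")[[1L]]
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in setdiff(seq_len(n), center)) {
    aln <- Biostrings::pairwiseAlignment(members[[i]], cen, type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 0, gapExtension = 1)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    subj <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    keep <- subj != "-"                      # columns that exist in the center
    mat[i, ] <- pat[keep]
  }
  cons <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("-")
    tab <- table(col)
    names(tab)[tab == max(tab)][1L]           # alphabetical tie-break
  })
  gap_frac <- colMeans(mat == "-")
  cons <- cons[gap_frac <= 0.5 & cons != "-"]
  out <- Biostrings::DNAStringSet(paste(cons, collapse = ""))
  names(out) <- paste0(names(members)[center], "_consensus")
  out
}

#' Map reads to references by seed-and-extend and report mean depths
#'
#' Each read is seeded by exact k-mer lookup at several offsets on both
#' strands, extended without gaps over its full length, and assigned to
#' the reference(s) with the fewest mismatches provided the mismatch
#' fraction does not exceed `max_mismatch_frac`.  Ties are split
#' fractionally (1/n of the read to each of the n best references).
#' Mean depth of a reference is total aligned bp divided by reference
#' length.
#'
#' @param reads [Biostrings::DNAStringSet] of equal-length reads.
#' @param references Named [Biostrings::DNAStringSet].
#' @param k Seed length (<= read length).
#' @param max_mismatch_frac Maximum mismatch fraction for a valid hit.
#' @return Named numeric vector of mean depths (one per reference).
#' @export
map_reads_depth <- function(reads, references, k = 21L,
                            max_mismatch_frac = 0.1) {
  if (length(references) == 0L) stop_format("empty reference set")
  read_len <- unique(Biostrings::width(reads))
  stopifnot(length(read_len) == 1L, k <= read_len)
  n_reads <- length(reads)
  depths <- setNames(numeric(length(references)), names(references))
  if (n_reads == 0L) return(depths)

  ref_chr <- as.character(references)
  ref_lens <- Biostrings::width(references)

  # reference k-mer index over both strands, built once
  idx_parts <- list()
  for (r in seq_along(references)) {
    s <- ref_chr[[r]]
    L <- ref_lens[r]
    if (L < k) next
    km_f <- substring(s, 1:(L - k + 1L), k:L)
    rc <- revcomp(s)
    km_r <- substring(rc, 1:(L - k + 1L), k:L)
    idx_parts[[length(idx_parts) + 1L]] <- data.frame(
      key = c(km_f, km_r), ref = r,
      pos = c(seq_len(L - k + 1L), L - k + 2L - seq_len(L - k + 1L)),
      strand = rep(c(1L, -1L), each = L - k + 1L), stringsAsFactors = FALSE)
    # for the reverse strand, `pos` is the start on the FORWARD reference
    # of the window whose reverse complement equals the k-mer
  }
  index <- do.call(rbind, idx_parts)

  offsets <- unique(round(seq(1L, read_len - k + 1L, length.out = 8L)))
  read_chr <- as.character(reads)
  read_rc <- vapply(read_chr, revcomp, character(1), USE.NAMES = FALSE)

  # collect candidate placements: (read, ref, strand, ref start of read)
  cand <- list()
  for (off in offsets) {
    seeds <- substring(read_chr, off, off + k - 1L)
    hit <- findMatches_all(seeds, index$key)
    if (nrow(hit)) {
      strand <- index$strand[hit$table_idx]
      pos <- index$pos[hit$table_idx]
      start <- ifelse(strand == 1L, pos - off + 1L,
                      pos - (read_len - (off + k - 1L)))
      cand[[length(cand) + 1L]] <- data.frame(
        read = hit$query_idx, ref = index$ref[hit$table_idx],
        strand = strand, start = start)
    }
  }
  if (length(cand) == 0L) return(depths)
  cand <- unique(do.call(rbind, cand))
  ok <- cand$start >= 1L & cand$start + read_len - 1L <= ref_lens[cand$ref]
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(depths)

  # mismatch count by raw byte comparison of equal-length strings
  ref_sub <- substring(ref_chr[cand$ref], cand$start,
                       cand$start + read_len - 1L)
  qry <- ifelse(cand$strand == 1L, read_chr[cand$read], read_rc[cand$read])
  mm <- count_mismatches(qry, ref_sub, read_len)
  cand$mm <- mm
  cand <- cand[cand$mm <= max_mismatch_frac * read_len, , drop = FALSE]
  if (nrow(cand) == 0L) return(depths)

  # best placement(s) per read; one placement per (read, ref) at the
  # read's minimal mismatch count, weight split over distinct refs
  best <- tapply(cand$mm, cand$read, min)
  cand <- cand[cand$mm == best[as.character(cand$read)], , drop = FALSE]
  key <- paste(cand$read, cand$ref)
  cand <- cand[!duplicated(key), , drop = FALSE]
  n_best <- table(cand$read)
  w <- 1 / as.numeric(n_best[as.character(cand$read)])
  bp <- tapply(w * read_len, cand$ref, sum)
  aligned_bp <- setNames(numeric(length(references)), names(references))
  aligned_bp[as.integer(names(bp))] <- as.numeric(bp)
  depths <- aligned_bp / ref_lens
  attr(depths, "aligned_bp") <- aligned_bp
  attr(depths, "read_length") <- read_len
  depths
}

# Effective-length depth: a read only counts when fully contained, so a
# reference of length L offers L - l + 1 valid starts; dividing aligned
# bp by the effective length removes the edge attenuation that would
# otherwise bias depth ratios between references of different lengths.
effective_depth <- function(depths, references) {
  bp <- attr(depths, "aligned_bp")
  rl <- attr(depths, "read_length")
  L <- Biostrings::width(references)
  eff <- pmax(L - rl + 1, 1)
  setNames(as.numeric(bp) / eff, names(depths))
}

# vectorised "find all occurrences of each query in a table" via match
# over successive deletions; returns data.frame(query_idx, table_idx)
findMatches_all <- function(queries, table) {
  hits <- S4Vectors::findMatches(queries, table)
  data.frame(query_idx = S4Vectors::queryHits(hits),
             table_idx = S4Vectors::subjectHits(hits))
}

# mismatches between equal-length string pairs, fully vectorised
count_mismatches <- function(a, b, len) {
  if (length(a) == 0L) return(integer(0))
  ar <- charToRaw(paste(a, collapse = ""))
  br <- charToRaw(paste(b, collapse = ""))
  colSums(matrix(ar != br, nrow = len))
}

#' Calibration depth from single-copy genes
#'
#' The median of per-gene mean depths is the read depth corresponding to
#' copy number one; the median is robust to the occasional
#' mis-annotated multi-copy gene.
#'
#' @param gene_depths Numeric vector of per-gene mean depths.
#' @return The calibration depth (median).
#' @export
calibrate_single_copy <- function(gene_depths) {
  if (length(gene_depths) == 0L) stop_format("no gene depths supplied")
  median(gene_depths)
}

#' Copy number from a depth ratio
#'
#' @param mean_depth Mean depth over a consensus.
#' @param calibration_depth Depth corresponding to copy number 1.
#' @return `copies = mean_depth / calibration_depth` (unrounded; see
#'   [copy_number_table()] for reporting).
#' @export
estimate_copy_number <- function(mean_depth, calibration_depth) {
  if (any(calibration_depth <= 0)) stop_format("calibration depth must be > 0")
  mean_depth / calibration_depth
}

#' Full copy-number pipeline over repeat sequences and reads
#'
#' Clusters the repeat sequences at `min_identity`, builds one consensus
#' per cluster, maps the reads to the consensus set together with the
#' single-copy genes, calibrates on the genes and reports per-consensus
#' and per-family copy numbers.
#'
#' @param reads [Biostrings::DNAStringSet].
#' @param repeats Named [Biostrings::DNAStringSet] of repeat copies;
#'   `family` gives each copy's family label (recycled from names when
#'   `NULL`: the part before the last underscore).
#' @param single_copy_genes Named [Biostrings::DNAStringSet].
#' @param family Optional character vector parallel to `repeats`.
#' @param min_identity Clustering threshold.
#' @param k,max_mismatch_frac Mapper parameters.
#' @return `list(table, calibration_depth, clusters)` where `table` has
#'   columns `consensus_id, family, mean_depth, calibration_depth,
#'   copy_number, copy_number_int, family_total`.
#' @export
estimate_family_copy_numbers <- function(reads, repeats, single_copy_genes,
                                         family = NULL, min_identity = 90,
                                         k = 21L, max_mismatch_frac = 0.1) {
  if (is.null(family)) family <- sub("_[^_]*$", "", names(repeats))
  names(family) <- names(repeats)
  clusters <- cluster_sequences(repeats, min_identity = min_identity)
  consensi <- lapply(clusters, build_consensus, seqs = repeats)
  cons_set <- do.call(c, consensi)
  names(cons_set) <- sprintf("consensus_%02d", seq_along(cons_set))
  cons_family <- vapply(clusters, function(cl) {
    fams <- family[cl$members]
    names(sort(table(fams), decreasing = TRUE))[1L]
  }, character(1))

  refs <- c(cons_set, single_copy_genes)
  depths <- map_reads_depth(reads, refs, k = k,
                            max_mismatch_frac = max_mismatch_frac)
  # copy-number ratios use effective-length depths so that references of
  # different lengths see the same edge attenuation (see effective_depth)
  eff <- effective_depth(depths, refs)
  gene_depths <- depths[names(single_copy_genes)]
  calib <- calibrate_single_copy(eff[names(single_copy_genes)])
  cons_depths <- depths[names(cons_set)]
  cn <- estimate_copy_number(eff[names(cons_set)], calib)
  tab <- data.frame(consensus_id = names(cons_set), family = cons_family,
                    mean_depth = unname(cons_depths),
                    calibration_depth = calib,
                    copy_number = round(unname(cn), 1),
                    copy_number_int = round(unname(cn)),
                    stringsAsFactors = FALSE)
  fam_tot <- tapply(tab$copy_number, tab$family, sum)
  tab$family_total <- as.numeric(fam_tot[tab$family])
  list(table = tab, calibration_depth = calib, clusters = clusters,
       gene_depths = gene_depths,
       gene_depths_effective = eff[names(single_copy_genes)])
}
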