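# Structural comparison of two genomes: unique-anchor alignment into
# collinear blocks, identity/length filtering, genome-specific region
# detection, inversion chaining, and Table-style region summaries.

# 2-bit-encode every k-mer of an integer base vector as a double (exact
# for k <= 26 since 4^26 < 2^53); windows containing N become NA.
encode_kmers <- function(x, k) {
  code <- rep(NA_real_, length(x))
  code[x == BASE_INT[1L]] <- 0; code[x == BASE_INT[2L]] <- 1
  code[x == BASE_INT[3L]] <- 2; code[x == BASE_INT[4L]] <- 3
  n <- length(x) - k + 1L
  if (n < 1L) return(numeric(0))
  acc <- numeric(n)
  for (t in seq_len(k)) {
    acc <- acc + code[t:(t + n - 1L)] * 4^(k - t)
  }
  acc
}

# k-mers of all chromosomes of a genome -> data.frame(key, chrom, pos0)
genome_kmers <- function(ints, k) {
  parts <- lapply(seq_along(ints), function(i) {
    key <- encode_kmers(ints[[i]], k)
    data.frame(key = key, chrom = i, pos = seq_along(key) - 1)
  })
  do.call(rbind, parts)
}

unique_rows <- function(df) {
  dup <- duplicated(df$key) | duplicated(df$key, fromLast = TRUE)
  df[!dup & !is.na(df$key), , drop = FALSE]
}

#' Align two genomes with unique exact anchors chained into blocks
#'
#' A desk-scale surrogate for a whole-genome aligner: k-mers occurring
#' exactly once in the reference and exactly once in the query (counting
#' both query strands) are paired as anchors, anchors on a common
#' diagonal (forward) or anti-diagonal (reverse) within `max_anchor_gap`
#' are chained, and each chain spanning at least `min_block` bp becomes
#' an alignment block.  Percent identity is computed by ungapped
#' column-wise comparison over the chained span.  Users with real
#' aligner output can instead load it via [read_alignment_blocks()].
#'
#' @param ref_genome,qry_genome Named [Biostrings::DNAStringSet]s.
#' @param k Anchor length (>= 15).
#' @param min_block Minimum chained span (bp) to report.
#' @param max_anchor_gap Maximum distance (bp) between consecutive
#'   anchors of a chain.
#' @return A block `data.frame` with 0-based half-open coordinates,
#'   `orientation` in `{forward, reverse}` and `pct_identity`.
#' @export
anchor_align <- function(ref_genome, qry_genome, k = 21L, min_block = 1000L,
                         max_anchor_gap = 5000L) {
  stopifnot(k >= 15L, length(ref_genome) > 0L, length(qry_genome) > 0L)
  ref_ints <- lapply(seq_along(ref_genome), function(i)
    utf8ToInt(as.character(ref_genome[[i]])))
  qry_ints <- lapply(seq_along(qry_genome), function(i)
    utf8ToInt(as.character(qry_genome[[i]])))

  kr <- genome_kmers(ref_ints, k)
  kq_f <- genome_kmers(qry_ints, k)
  kq_f$strand <- 1L
  qry_rc <- lapply(qry_ints, revcomp_int)
  kq_r <- genome_kmers(qry_rc, k)
  # map revcomp positions back to forward-strand query coordinates: a
  # k-mer at 0-based position p of revcomp(Q) covers [Lq - p - k, Lq - p)
  lq <- vapply(qry_ints, length, integer(1))
  kq_r$pos <- lq[kq_r$chrom] - kq_r$pos - k
  kq_r$strand <- -1L
  kq <- rbind(kq_f, kq_r)

  kr <- unique_rows(kr)
  kq <- unique_rows(kq)
  hit <- match(kr$key, kq$key)
  sel <- !is.na(hit)
  if (!any(sel)) return(new_blocks())
  anchors <- data.frame(
    rchrom = kr$chrom[sel], rpos = kr$pos[sel],
    qchrom = kq$chrom[hit[sel]], qpos = kq$pos[hit[sel]],
    strand = kq$strand[hit[sel]]
  )

  # chain: constant diagonal (forward) / anti-diagonal (reverse)
  diag <- ifelse(anchors$strand == 1L, anchors$qpos - anchors$rpos,
                 anchors$qpos + anchors$rpos)
  o <- order(anchors$rchrom, anchors$qchrom, anchors$strand, diag, anchors$rpos)
  a <- anchors[o, ]
  dg <- diag[o]
  same <- c(FALSE, a$rchrom[-1L] == a$rchrom[-nrow(a)] &
                   a$qchrom[-1L] == a$qchrom[-nrow(a)] &
                   a$strand[-1L] == a$strand[-nrow(a)] &
                   dg[-1L] == dg[-nrow(a)] &
                   (a$rpos[-1L] - a$rpos[-nrow(a)]) <= max_anchor_gap)
  chain_id <- cumsum(!same)

  r1 <- tapply(a$rpos, chain_id, min)
  r2 <- tapply(a$rpos, chain_id, max) + k
  q1 <- tapply(a$qpos, chain_id, min)
  q2 <- tapply(a$qpos, chain_id, max) + k
  rch <- tapply(a$rchrom, chain_id, function(z) z[1L])
  qch <- tapply(a$qchrom, chain_id, function(z) z[1L])
  strand <- tapply(a$strand, chain_id, function(z) z[1L])

  keep <- (r2 - r1) >= min_block
  if (!any(keep)) return(new_blocks())
  r1 <- r1[keep]; r2 <- r2[keep]; q1 <- q1[keep]; q2 <- q2[keep]
  rch <- rch[keep]; qch <- qch[keep]; strand <- strand[keep]

  pid <- vapply(seq_along(r1), function(i) {
    rseg <- ref_ints[[rch[i]]][(r1[i] + 1L):r2[i]]
    qseg <- qry_ints[[qch[i]]][(q1[i] + 1L):q2[i]]
    if (strand[i] == -1L) qseg <- revcomp_int(qseg)
    100 * sum(rseg == qseg) / length(rseg)
  }, numeric(1))

  out <- new_blocks(
    ref_seqid = names(ref_genome)[rch], ref_start = unname(r1),
    ref_end = unname(r2), qry_seqid = names(qry_genome)[qch],
    qry_start = unname(q1), qry_end = unname(q2),
    orientation = ifelse(strand == 1L, "forward", "reverse"),
    pct_identity = pid
  )
  out <- out[order(out$ref_seqid, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter alignment blocks on identity and length
#'
#' Mirrors the usual whole-genome comparison regime of keeping only
#' blocks with at least 95% identity and a 4-kb reference span.
#'
#' @param blocks Block `data.frame`.
#' @param min_identity Minimum percent identity (kept when `>=`).
#' @param min_len Minimum reference span in bp (kept when `>=`).
#' @return The filtered blocks, order preserved.
#' @export
filter_blocks <- function(blocks, min_identity = 95, min_len = 4000) {
  keep <- blocks$pct_identity >= min_identity &
    (blocks$ref_end - blocks$ref_start) >= min_len
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect genome-specific regions from block coverage
#'
#' A reference interval is specific when no alignment block of any
#' comparator covers it: the union of covered intervals over all block
#' sets is complemented per chromosome, complement intervals separated
#' by covered stretches shorter than `merge_gap` are merged, and merged
#' intervals of at least `min_region` bp are reported.
#'
#' @param ref_genome Named [Biostrings::DNAStringSet] (the genome whose
#'   specific regions are sought).
#' @param block_sets A list of block `data.frame`s, one per comparator
#'   genome, with `ref_seqid` referring to `ref_genome`.
#' @param min_region Minimum reported region length (bp).
#' @param merge_gap Covered stretches shorter than this merge adjacent
#'   uncovered intervals.
#' @return `data.frame(seqid, start, end, length)` in 0-based half-open
#'   coordinates.
#' @export
detect_specific_regions <- function(ref_genome, block_sets,
                                    min_region = 1e6, merge_gap = 50000) {
  if (is.data.frame(block_sets)) block_sets <- list(block_sets)
  lens <- setNames(Biostrings::width(ref_genome), names(ref_genome))
  all_blocks <- do.call(rbind, lapply(block_sets, function(b) b[BLOCK_COLS]))
  unknown <- setdiff(unique(all_blocks$ref_seqid), names(lens))
  if (length(unknown)) {
    stop_format("block refers to unknown ref seqid '%s'", unknown[1L])
  }
  out <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    b <- all_blocks[all_blocks$ref_seqid == ch, , drop = FALSE]
    covered <- IRanges::reduce(ranges0(b$ref_start, b$ref_end))
    uncovered <- IRanges::setdiff(IRanges::IRanges(1L, L), covered)
    # merge uncovered intervals separated by < merge_gap covered bases
    if (merge_gap > 0) {
      merged <- IRanges::reduce(uncovered, min.gapwidth = merge_gap)
    } else {
      merged <- IRanges::reduce(uncovered)
    }
    merged <- merged[IRanges::width(merged) >= min_region]
    if (length(merged)) {
      out[[ch]] <- data.frame(seqid = ch,
                              start = IRanges::start(merged) - 1,
                              end = IRanges::end(merged),
                              stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seqid = character(), start = numeric(), end = numeric())
  res$length <- res$end - res$start
  rownames(res) <- NULL
  res
}

#' Chain reverse-orientation blocks into inversion calls
#'
#' Reverse blocks on the same chromosome pair are sorted by reference
#' start and chained while consecutive blocks lie within `chain_gap` on
#' both genomes and their query coordinates decrease as reference
#' coordinates increase.  Isolated reverse blocks are reported as
#' single-block inversions.
#'
#' @param blocks Filtered block `data.frame`.
#' @param chain_gap Maximum gap (bp) between chained blocks on either
#'   genome.
#' @return `data.frame(ref_seqid, ref_start, ref_end, qry_seqid,
#'   qry_start, qry_end, n_blocks)`, 0-based half-open.
#' @export
detect_inversions <- function(blocks, chain_gap = 100000) {
  rev <- blocks[blocks$orientation == "reverse", , drop = FALSE]
  empty <- data.frame(ref_seqid = character(), ref_start = numeric(),
                      ref_end = numeric(), qry_seqid = character(),
                      qry_start = numeric(), qry_end = numeric(),
                      n_blocks = integer(), stringsAsFactors = FALSE)
  if (nrow(rev) == 0L) return(empty)
  rev <- rev[order(rev$ref_seqid, rev$qry_seqid, rev$ref_start), , drop = FALSE]
  n <- nrow(rev)
  link <- c(FALSE, rev$ref_seqid[-1L] == rev$ref_seqid[-n] &
                   rev$qry_seqid[-1L] == rev$qry_seqid[-n] &
                   (rev$ref_start[-1L] - rev$ref_end[-n]) <= chain_gap &
                   rev$qry_end[-1L] <= rev$qry_start[-n] &          # qry decreasing
                   (rev$qry_start[-n] - rev$qry_end[-1L]) <= chain_gap)
  id <- cumsum(!link)
  data.frame(
    ref_seqid = tapply(rev$ref_seqid, id, function(z) z[1L]),
    ref_start = as.numeric(tapply(rev$ref_start, id, min)),
    ref_end = as.numeric(tapply(rev$ref_end, id, max)),
    qry_seqid = tapply(rev$qry_seqid, id, function(z) z[1L]),
    qry_start = as.numeric(tapply(rev$qry_start, id, min)),
    qry_end = as.numeric(tapply(rev$qry_end, id, max)),
    n_blocks = as.integer(tapply(id, id, length)),
    stringsAsFactors = FALSE, row.names = NULL
  ) -> calls
  calls <- calls[order(calls$ref_seqid, calls$ref_start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Summarise one region: base composition and feature content
#'
#' A feature counts when it overlaps the region by at least 1 bp;
#' cumulative lengths clip each feature to the region.  GC percent uses
#' all bases (including N) in the denominator.
#'
#' @param region A list or one-row `data.frame` with `seqid, start, end`
#'   (0-based half-open).
#' @param genome Named [Biostrings::DNAStringSet] containing
#'   `region$seqid`.
#' @param annotations GFF3 `data.frame` (1-based inclusive).
#' @param class_map Vocabulary mapping for [classify_features()].
#' @return One-row `data.frame` with `seqid, start, end, length_bp,
#'   pct_n, pct_gc, n_genes, cum_gene_len_bp, n_tes, cum_te_len_bp,
#'   n_rdna, cum_rdna_len_bp`.
#' @export
summarize_region <- function(region, genome, annotations,
                             class_map = default_class_map()) {
  seqid <- as.character(region$seqid)
  start <- as.numeric(region$start)
  end <- as.numeric(region$end)
  if (!seqid %in% names(genome)) stop_format("unknown seqid '%s'", seqid)
  L <- Biostrings::width(genome)[match(seqid, names(genome))]
  if (start < 0 || end > L || end <= start) {
    stop_format("region [%s,%s) out of bounds for %s (length %d)",
                format(start, scientific = FALSE),
                format(end, scientific = FALSE), seqid, L)
  }
  seg <- Biostrings::subseq(genome[[seqid]], start + 1L, end)
  fr <- Biostrings::alphabetFrequency(seg)
  len <- end - start
  pct_n <- 100 * fr[["N"]] / len
  pct_gc <- 100 * (fr[["G"]] + fr[["C"]]) / len

  ann <- annotations[annotations$seqid == seqid, , drop = FALSE]
  cls <- classify_features(ann$type, class_map)
  reg_r <- ranges0(start, end)
  feat_r <- ranges1(ann$start, ann$end)
  ov <- IRanges::overlapsAny(feat_r, reg_r)
  clip <- IRanges::pintersect(feat_r, rep(reg_r, length(feat_r)),
                              resolve.empty = "start.x")
  clip_w <- ifelse(ov, IRanges::width(clip), 0)

  tally <- function(sel) c(n = sum(ov & sel), bp = sum(clip_w[ov & sel]))
  g <- tally(cls == "gene")
  te <- tally(is_te_class(cls))
  rd <- tally(is_rdna_class(cls))
  data.frame(seqid = seqid, start = start, end = end, length_bp = len,
             pct_n = pct_n, pct_gc = pct_gc,
             n_genes = unname(g["n"]), cum_gene_len_bp = unname(g["bp"]),
             n_tes = unname(te["n"]), cum_te_len_bp = unname(te["bp"]),
             n_rdna = unname(rd["n"]), cum_rdna_len_bp = unname(rd["bp"]),
             stringsAsFactors = FALSE)
}

#' Column statistics of a region-summary table
#'
#' Computes sum, mean and median per numeric column with the reporting
#' conventions used for headline numbers: bp-valued statistics truncated
#' toward zero to integer bp, count statistics to 2 decimals, percent
#' statistics to 2 decimals.  The median of an even number of rows is
#' the midpoint of the two central values.
#'
#' @param rows `data.frame` of region summaries (any subset of numeric
#'   columns is accepted).
#' @return `data.frame(column, sum, mean, median)` with the convention
#'   applied per column class; raw (unrounded) values are attached as
#'   columns `mean_raw` and `median_raw`.
#' @export
summarize_table <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) stop_format("summarize_table: empty input")
  num <- rows[vapply(rows, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("start", "end"))]
  fmt <- function(col, x) {
    if (grepl("pct|percent", col)) round(x, 2)
    else if (grepl("bp|length", col)) trunc0(x)
    else round(x, 2)
  }
  out <- lapply(names(num), function(col) {
    v <- num[[col]]
    data.frame(column = col, sum = sum(v),
               mean = fmt(col, mean(v)), median = fmt(col, median(v)),
               mean_raw = mean(v), median_raw = median(v),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
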